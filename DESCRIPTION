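Package: sweepscan
Title: Selective Sweep Scans, LD Profiling and Mixed-Model GWAS for Phased
    Haplotype Panels
Version: 0.1.0
Authors@R:
    person("Analysis", "Pipeline", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects signatures of classic selective sweeps in phased,
    polarized SNP haplotype panels. Implements haplotype-homozygosity scans
    (EHH, iHS, nSL), site-frequency-spectrum statistics (Tajima's D,
    Fay and Wu's H, windowed heterozygosity), a SweepFinder-style composite
    likelihood ratio scan against a genome-wide background spectrum,
    genome-wide empirical p-values with top-percentile candidate region
    calling, linkage-disequilibrium decay profiling with SNP-array
    ascertainment comparisons, a two-population F_ST scan, a mixed-model
    (EMMAX-style) association scan with a realized genomic relationship
    matrix, and a permutation test for overlap between association hits and
    sweep candidate windows. A compiled forward Wright-Fisher simulator with
    selection, recombination and infinite-sites mutation provides
    ground-truth panels for calibration and power testing.
License: MIT
Encoding: UTF-8
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    VariantAnnotation,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
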