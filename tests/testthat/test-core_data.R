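test_that("phased VCF reading: shape, filtering, unphased error, region", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", "s2", sep = "\t"),
    "chr1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0|1\t1|1",
    "chr1\t200\t.\tC\tT\t.\tPASS\t.\tGT\t0|0\t0|1",
    "chr1\t300\t.\tG\tA,T\t.\tPASS\t.\tGT\t0|1\t0|2",  # triallelic: skipped
    "chr1\t400\t.\tT\tC\t.\tPASS\t.\tGT\t1|0\t0|0"), vcf)
  panel <- suppressMessages(read_phased_haplotypes(vcf))
  expect_equal(dim(panel$haplotypes), c(4L, 3L))  # 2 samples x 2 haps, 3 SNPs
  expect_equal(panel$sites$pos, c(100L, 200L, 400L))
  expect_equal(panel$haplotypes[, 1], c(0L, 1L, 1L, 1L))
  expect_message(read_phased_haplotypes(vcf), "skipped 1")

  sub <- suppressMessages(read_phased_haplotypes(vcf, region = "chr1:150-400"))
  expect_equal(sub$sites$pos, c(200L, 400L))
  expect_error(suppressMessages(read_phased_haplotypes(vcf, region = "chr2:1-10")),
               "no records")

  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", sep = "\t"),
    "chr1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0/1"), vcf)
  expect_error(suppressMessages(read_phased_haplotypes(vcf)), "unphased.*chr1:100")
})

test_that("VCF round trip reproduces the haplotype matrix exactly", {
  set.seed(11)
  panel <- simulate_neutral_panel(sim_params(n_diploids = 50, sample_hap = 20,
                                             seq_len = 50000, seed = 11))
  vcf <- tempfile(fileext = ".vcf")
  write_panel_vcf(panel, vcf)
  back <- read_phased_haplotypes(vcf)
  expect_identical(unname(back$haplotypes), unname(panel$haplotypes))
  expect_equal(back$sites$pos, panel$sites$pos)
  expect_equal(back$sites$ref, panel$sites$ref)
})

test_that("polarization: recode rules, mismatch flag, involution", {
  mat <- rbind(c(0L, 0L, 0L), c(0L, 1L, 1L), c(1L, 1L, 0L), c(1L, 1L, 1L))
  sites <- data.frame(chrom = "chr1", pos = c(10L, 20L, 30L),
                      ref = c("A", "A", "A"), alt = c("G", "G", "G"))
  panel <- haplotype_panel(mat, sites)
  anc <- data.frame(chrom = "chr1", pos = c(10L, 20L, 30L),
                    allele = c("A", "G", "C"))
  pol <- suppressMessages(polarize_sites(panel, anc))
  # ancestral == ref: unchanged, daf = alt frequency
  expect_equal(pol$haplotypes[, 1], mat[, 1])
  expect_equal(pol$sites$daf[1], 0.5)
  # ancestral == alt: flipped, ref/alt swapped, daf = old ref frequency
  expect_equal(pol$haplotypes[, 2], 1L - mat[, 2])
  expect_equal(pol$sites$ref[2], "G")
  expect_equal(pol$sites$daf[2], 0.25)
  # ancestral matches neither: flagged unknown, counted
  expect_false(pol$sites$ancestral_known[3])
  expect_message(polarize_sites(panel, anc), "1 site")
  # involution: polarizing twice with the same table changes nothing more
  pol2 <- suppressMessages(polarize_sites(pol, anc))
  expect_identical(pol2$haplotypes, pol$haplotypes)
  expect_equal(pol2$sites$daf, pol$sites$daf)
})

test_that("window grids: anchoring, overlap, tiling, errors", {
  sites <- data.frame(chrom = "chr1", pos = c(1L, 50000L, 100000L),
                      ref = "A", alt = "T")
  g1 <- build_window_grid(sites, 40000)
  expect_equal(nrow(g1), 3L)
  expect_equal(g1$start, c(0L, 40000L, 80000L))
  expect_equal(g1$end, c(40000L, 80000L, 120000L))

  g2 <- build_window_grid(sites, 40000, 5000)
  expect_equal(nrow(g2), 21L)                    # starts 0, 5000, ..., 100000
  expect_equal(g2$start, seq(0L, 100000L, by = 5000L))

  expect_error(build_window_grid(sites, 40000, 50000), "must not exceed")
  expect_error(build_window_grid(sites, 40000, 0), "positive")

  # tiling: every SNP of a simulated panel maps to exactly one window
  panel <- fixture("tiling_panel", function()
    simulate_neutral_panel(sim_params(n_diploids = 50, sample_hap = 20,
                                      seq_len = 100000, seed = 4)))
  grid <- build_window_grid(panel$sites, 40000)
  idx <- sweepscan:::window_site_index(panel$sites$pos, panel$sites$chrom, grid)
  per_site <- tabulate(unlist(idx), nbins = nrow(panel$sites))
  expect_true(all(per_site == 1))                # each SNP in exactly one window

  # overlapping grid (40 kb / 5 kb): interior sites fall in exactly 8 windows
  g2b <- build_window_grid(panel$sites, 40000, 5000)
  idx2 <- sweepscan:::window_site_index(panel$sites$pos, panel$sites$chrom, g2b)
  per_site2 <- tabulate(unlist(idx2), nbins = nrow(panel$sites))
  interior <- panel$sites$pos >= 40000 & panel$sites$pos < 60000
  expect_true(all(per_site2[interior] == 8))
})

test_that("interval overlap: half-open semantics and brute-force agreement", {
  a <- interval_set("chr1", 100, 200)
  expect_equal(nrow(interval_overlap(a, interval_set("chr1", 150, 250))), 1L)
  expect_equal(nrow(interval_overlap(a, interval_set("chr1", 200, 300))), 0L)
  expect_equal(nrow(interval_overlap(interval_set(character(), numeric(),
                                                  numeric()), a)), 0L)
  set.seed(21)
  r <- interval_set(sample(c("c1", "c2"), 30, TRUE),
                    s <- sample(1000, 30), s + sample(200, 30))
  f <- interval_set(sample(c("c1", "c2"), 30, TRUE),
                    s2 <- sample(1000, 30), s2 + sample(200, 30))
  got <- interval_overlap(r, f)
  brute <- 0L
  for (i in seq_len(nrow(r))) for (j in seq_len(nrow(f)))
    if (r$chrom[i] == f$chrom[j] &&
        max(r$start[i], f$start[j]) < min(r$end[i], f$end[j]))
      brute <- brute + 1L
  expect_equal(nrow(got), brute)
})

test_that("panel validation rejects malformed inputs", {
  expect_error(haplotype_panel(matrix(0L, 2, 2),
                               data.frame(chrom = "c", pos = 1,
                                          ref = "A", alt = "T")),
               "site table")
  expect_error(haplotype_panel(matrix(2L, 2, 1),
                               data.frame(chrom = "c", pos = 1,
                                          ref = "A", alt = "T")),
               "0 or 1")
  expect_error(haplotype_panel(matrix(0L, 2, 2),
                               data.frame(chrom = "c", pos = c(5, 5),
                                          ref = "A", alt = "T")),
               "strictly increasing")
})

test_that("BED and score-track writers round-trip through their readers", {
  x <- interval_set(c("chr1", "chr2"), c(0, 100), c(50, 300), c("a", "b"))
  bed <- tempfile(fileext = ".bed")
  write_bed(x, bed)
  back <- read_bed(bed)
  expect_equal(back$start, x$start)
  expect_equal(back$name, x$name)
})
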