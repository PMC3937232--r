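# Core containers and I/O: haplotype panels, site tables, window grids,
# interval sets. Interval arithmetic is half-open; SNP positions are kept
# 1-based as in VCF and a site at position p is treated as falling in the
# window [start, end) iff start <= p < end.

#' Construct a haplotype panel
#'
#' The substrate of every scan in the package: a phased binary haplotype
#' matrix (rows = haplotypes, columns = SNP sites, entries 0/1 with `NA` for
#' missing) plus a per-site metadata table.
#'
#' @param haplotypes integer/numeric matrix of 0/1 allele codes; two rows per
#'   diploid individual. After polarization code 1 means the derived allele at
#'   sites where the ancestral state is known.
#' @param sites data.frame with at least `chrom`, `pos` (1-based bp), `ref`,
#'   `alt`. Columns `ancestral_known`, `derived_count`, `daf`, `maf` are
#'   (re)computed.
#' @param sample_ids character vector of individual identifiers, one per pair
#'   of haplotype rows, or `NULL`.
#' @return an object of class `haplotype_panel` with elements `haplotypes`,
#'   `sites` (a `data.table`), `sample_ids`, `n_hap`.
#' @export
haplotype_panel <- function(haplotypes, sites, sample_ids = NULL) {
  haplotypes <- as.matrix(haplotypes)
  storage.mode(haplotypes) <- "integer"
  sites <- data.table::as.data.table(sites)
  if (ncol(haplotypes) != nrow(sites))
    stop("haplotype matrix has ", ncol(haplotypes), " columns but site table has ",
         nrow(sites), " rows")
  vals <- haplotypes[!is.na(haplotypes)]
  if (length(vals) && !all(vals %in% c(0L, 1L)))
    stop("non-missing haplotype entries must be 0 or 1")
  for (col in c("chrom", "pos", "ref", "alt"))
    if (is.null(sites[[col]])) stop("site table lacks column '", col, "'")
  sites[, chrom := as.character(chrom)]
  sites[, pos := as.integer(pos)]
  bad <- sites[, any(diff(pos) <= 0), by = chrom]$V1
  if (any(bad)) stop("positions must be strictly increasing within chromosome")
  if (!is.null(sample_ids) && length(sample_ids) * 2L != nrow(haplotypes))
    stop("need exactly two haplotype rows per sample id")
  if (is.null(sites$ancestral_known)) sites[, ancestral_known := FALSE]
  panel <- structure(
    list(haplotypes = haplotypes, sites = sites, sample_ids = sample_ids,
         n_hap = nrow(haplotypes)),
    class = "haplotype_panel")
  refresh_site_freqs(panel)
}

# recompute derived_count/daf/maf from the matrix; daf only where polarized
refresh_site_freqs <- function(panel) {
  h <- panel$hap
  nonmiss <- colSums(!is.na(h))
  ones <- colSums(h, na.rm = TRUE)
  s <- panel$sites
  s[, derived_count := ifelse(ancestral_known, ones, NA_integer_)]
  s[, daf := ifelse(ancestral_known, ones / nonmiss, NA_real_)]
  s[, maf := pmin(ones / nonmiss, 1 - ones / nonmiss)]
  panel$sites <- s
  panel
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat("haplotype_panel:", x$n_hap, "haplotypes x", ncol(x$haplotypes), "sites on",
      length(unique(x$sites$chrom)), "chromosome(s);",
      sum(x$sites$ancestral_known), "sites polarized\n")
  invisible(x)
}

#' Number of sites in a panel
#' @param panel a `haplotype_panel`
#' @return integer site count
#' @export
n_sites <- function(panel) ncol(panel$haplotypes)

#' Subset a panel by site index
#' @param panel a `haplotype_panel`
#' @param idx integer or logical index into the site columns
#' @return a `haplotype_panel` with the selected sites
#' @export
subset_sites <- function(panel, idx) {
  haplotype_panel(panel$haplotypes[, idx, drop = FALSE], panel$sites[idx],
                  panel$sample_ids)
}

#' Read phased haplotypes from a VCF file
#'
#' Builds a [haplotype_panel()] from the phased diploid genotypes of a VCF.
#' Multiallelic records and indels are skipped (their count is reported via
#' `message()`); an unphased genotype is an error, since haplotype statistics
#' are meaningless on unphased data. Sites with more than
#' `max_missing` missing genotype fraction are dropped.
#'
#' @param path VCF file (plain text or bgzipped)
#' @param region optional `"chrom:start-end"` string restricting the sites
#' @param max_missing maximum tolerated fraction of missing haplotypes per
#'   site (default 0.1)
#' @return a `haplotype_panel`; allele code 0 = REF, 1 = ALT (not yet
#'   polarized: see [polarize_sites()])
#' @export
read_phased_haplotypes <- function(path, region = NULL, max_missing = 0.1) {
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  rr <- SummarizedExperiment::rowRanges(vcf)
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("VCF has no GT field")
  alt_list <- VariantAnnotation::alt(vcf)
  ref <- as.character(VariantAnnotation::ref(vcf))
  multi <- S4Vectors::elementNROWS(alt_list) != 1L
  alt <- rep(NA_character_, length(ref))
  alt[!multi] <- as.character(unlist(alt_list[!multi]))
  snp <- !multi & nchar(ref) == 1L & !is.na(alt) & nchar(alt) == 1L &
    alt %in% c("A", "C", "G", "T")
  n_skip <- sum(!snp)
  if (n_skip > 0)
    message("skipped ", n_skip, " non-biallelic-SNP record(s)")
  keep <- which(snp)
  chrom <- as.character(GenomicRanges::seqnames(rr))[keep]
  pos <- GenomicRanges::start(rr)[keep]
  gt <- gt[keep, , drop = FALSE]
  if (!is.null(region)) {
    m <- regmatches(region, regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1]]
    if (length(m) != 4) stop("region must be 'chrom:start-end'")
    sel <- chrom == m[2] & pos >= as.integer(m[3]) & pos <= as.integer(m[4])
    if (!any(sel)) stop("no records in region ", region)
    chrom <- chrom[sel]; pos <- pos[sel]
    gt <- gt[sel, , drop = FALSE]
    keep <- keep[sel]
  }
  unphased <- matrix(grepl("/", gt, fixed = TRUE) & !gt %in% c("./.", "."),
                     nrow = nrow(gt))
  if (any(unphased)) {
    i <- which(unphased, arr.ind = TRUE)[1, ]
    stop("unphased genotype at ", chrom[i[1]], ":", pos[i[1]],
         " (sample ", colnames(gt)[i[2]], ")")
  }
  samples <- colnames(gt)
  n_ind <- length(samples)
  hap <- matrix(NA_integer_, nrow = 2L * n_ind, ncol = nrow(gt))
  a1 <- substr(gt, 1L, 1L)
  a2 <- substr(gt, 3L, 3L)
  code <- function(x) ifelse(x == "0", 0L, ifelse(x == "1", 1L, NA_integer_))
  hap[seq(1L, 2L * n_ind, by = 2L), ] <- t(matrix(code(a1), nrow = nrow(gt)))
  hap[seq(2L, 2L * n_ind, by = 2L), ] <- t(matrix(code(a2), nrow = nrow(gt)))
  miss <- colMeans(is.na(hap))
  if (any(miss > max_missing)) {
    message("dropped ", sum(miss > max_missing), " site(s) with missingness > ",
            max_missing)
    sel <- miss <= max_missing
    hap <- hap[, sel, drop = FALSE]
    chrom <- chrom[sel]; pos <- pos[sel]
    keep <- keep[sel]
  }
  sites <- data.table::data.table(chrom = chrom, pos = pos,
                                  ref = ref[keep], alt = alt[keep])
  ord <- order(sites$chrom, sites$pos)
  haplotype_panel(hap[, ord, drop = FALSE], sites[ord], sample_ids = samples)
}

#' Write a panel to a phased VCF file
#'
#' @param panel a `haplotype_panel`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_panel_vcf <- function(panel, path) {
  ids <- panel$sample_ids
  if (is.null(ids)) ids <- sprintf("ind%03d", seq_len(panel$n_hap / 2))
  h <- panel$haplotypes
  a1 <- h[seq(1, nrow(h), by = 2), , drop = FALSE]
  a2 <- h[seq(2, nrow(h), by = 2), , drop = FALSE]
  fmt <- function(x) ifelse(is.na(x), ".", as.character(x))
  gt <- matrix(paste0(fmt(t(a1)), "|", fmt(t(a2))), nrow = ncol(h))
  gt[gt == ".|."] <- ".|."
  s <- panel$sites
  lines <- c("##fileformat=VCFv4.2",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", ids), collapse = "\t"))
  body <- paste(s$chrom, s$pos, ".", s$ref, s$alt, ".", "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Read an ancestral-allele table
#'
#' @param path TSV with columns chrom, pos, allele (header optional)
#' @return data.table with columns `chrom`, `pos`, `allele`
#' @export
read_ancestral_table <- function(path) {
  dt <- data.table::fread(path, header = "auto")
  if (ncol(dt) < 3) stop("ancestral table needs 3 columns: chrom, pos, allele")
  dt <- dt[, 1:3]
  data.table::setnames(dt, c("chrom", "pos", "allele"))
  dt[, chrom := as.character(chrom)]
  dt[, pos := as.integer(pos)]
  dt[, allele := toupper(as.character(allele))]
  dt
}

#' Polarize panel sites against an ancestral-allele table
#'
#' Recodes alleles so that code 1 is the derived allele wherever the
#' ancestral state is known. When the ancestral allele equals ALT the column
#' is flipped and REF/ALT are swapped, so that code 0 (REF) always denotes
#' the ancestral allele at polarized sites. Sites whose ancestral allele is
#' absent from the table, or matches neither REF nor ALT, are flagged
#' `ancestral_known = FALSE` and excluded from polarization-dependent
#' statistics downstream. The operation is idempotent.
#'
#' @param panel a `haplotype_panel`
#' @param ancestral data.table/data.frame with columns chrom, pos, allele
#' @return the polarized `haplotype_panel`; the number of mismatching sites is
#'   reported with `message()`
#' @export
polarize_sites <- function(panel, ancestral) {
  anc <- data.table::as.data.table(ancestral)
  s <- data.table::copy(panel$sites)
  key <- paste(s$chrom, s$pos)
  m <- match(key, paste(anc$chrom, anc$pos))
  aa <- toupper(anc$allele[m])
  is_ref <- !is.na(aa) & aa == toupper(s$ref)
  is_alt <- !is.na(aa) & aa == toupper(s$alt)
  n_bad <- sum(!is.na(aa) & !is_ref & !is_alt)
  if (n_bad > 0)
    message(n_bad, " site(s) with ancestral allele matching neither REF nor ALT")
  h <- panel$haplotypes
  flip <- which(is_alt)
  if (length(flip)) {
    h[, flip] <- 1L - h[, flip, drop = FALSE]
    tmp <- s$ref[flip]
    s[flip, ref := s$alt[flip]]
    s[flip, alt := tmp]
  }
  s[, ancestral_known := is_ref | is_alt]
  refresh_site_freqs(structure(
    list(haplotypes = h, sites = s, sample_ids = panel$sample_ids,
         n_hap = panel$n_hap),
    class = "haplotype_panel"))
}

#' Build a genome window grid
#'
#' Windows are half-open `[start, end)` intervals anchored at coordinate 0 on
#' every chromosome (independent of the SNP subset) and extended until the
#' last window whose start does not exceed the maximal SNP position. With
#' `step < window_size` the grid is overlapping (sliding windows).
#'
#' @param sites site table (or `haplotype_panel`) providing `chrom` and `pos`
#' @param window_size window width in bp
#' @param step distance between window starts in bp; defaults to
#'   `window_size` (non-overlapping tiling)
#' @return data.table of class `window_grid` with columns `chrom`, `start`,
#'   `end` and attributes `window_size`, `step`
#' @export
build_window_grid <- function(sites, window_size, step = window_size) {
  if (inherits(sites, "haplotype_panel")) sites <- sites$sites
  if (step <= 0) stop("step must be positive")
  if (step > window_size) stop("step (", step, ") must not exceed window_size (",
                               window_size, ")")
  dt <- data.table::as.data.table(sites)[, .(max_pos = max(pos)), by = chrom]
  grids <- dt[, .(start = seq(0L, as.integer(floor(max_pos / step)) * as.integer(step),
                              by = as.integer(step))), by = chrom]
  grids[, end := start + as.integer(window_size)]
  data.table::setattr(grids, "window_size", as.integer(window_size))
  data.table::setattr(grids, "step", as.integer(step))
  data.table::setattr(grids, "class", c("window_grid", class(grids)))
  grids[]
}

#' Assign sites to the windows of a grid
#'
#' @param pos integer positions (1-based bp)
#' @param chrom chromosome labels, recycled if length 1
#' @param grid a `window_grid`
#' @return integer list: for each window, the indices of contained sites
#' @keywords internal
window_site_index <- function(pos, chrom, grid) {
  if (length(chrom) == 1L) chrom <- rep(chrom, length(pos))
  lapply(seq_len(nrow(grid)), function(w)
    which(chrom == grid$chrom[w] & pos >= grid$start[w] & pos < grid$end[w]))
}

#' Construct an interval set
#'
#' @param chrom chromosome labels
#' @param start,end half-open 0-based interval bounds
#' @param name optional record names
#' @return data.table of class `interval_set`, sorted by (chrom, start)
#' @export
interval_set <- function(chrom, start, end, name = NULL) {
  if (any(start > end)) stop("interval starts must not exceed ends")
  dt <- data.table::data.table(
    chrom = as.character(chrom), start = as.numeric(start),
    end = as.numeric(end),
    name = if (is.null(name)) rep(NA_character_, length(chrom)) else
      as.character(name))
  data.table::setorder(dt, chrom, start)
  data.table::setattr(dt, "class", c("interval_set", class(dt)))
  dt[]
}

#' Read intervals from BED (3 or 4 columns)
#' @param path BED file (0-based half-open, as usual)
#' @return an `interval_set`
#' @export
read_bed <- function(path) {
  dt <- data.table::fread(path, header = FALSE)
  interval_set(dt[[1]], dt[[2]], dt[[3]],
               name = if (ncol(dt) >= 4) dt[[4]] else NULL)
}

#' Read intervals from GFF3
#' @param path GFF3 file; `start`/`end` are converted from 1-based closed to
#'   0-based half-open
#' @return an `interval_set`
#' @export
read_gff3 <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t", skip = "#",
                          fill = TRUE)
  if (ncol(dt) < 9) stop("not a GFF3 file: fewer than 9 columns")
  nm <- sub('.*(?:ID|Name)=([^;]+).*', '\\1', dt[[9]])
  interval_set(dt[[1]], as.numeric(dt[[4]]) - 1, as.numeric(dt[[5]]), name = nm)
}

#' Write an interval set (or called regions) as BED
#' @param x `interval_set` or `sweep_region` table with chrom/start/end
#' @param path output path
#' @return `path`, invisibly
#' @export
write_bed <- function(x, path) {
  cols <- intersect(c("chrom", "start", "end", "name"), names(x))
  data.table::fwrite(data.table::as.data.table(x)[, cols, with = FALSE], path,
                     sep = "\t", col.names = FALSE)
  invisible(path)
}

#' All pairs of overlapping intervals between two sets
#'
#' Overlap means at least 1 bp shared under half-open coordinates; touching
#' intervals (`end == start`) do not overlap.
#'
#' @param regions,features `interval_set` objects
#' @return data.table with indices `region_idx`, `feature_idx` into the two
#'   (sorted) inputs plus their coordinates
#' @export
interval_overlap <- function(regions, features) {
  if (nrow(regions) == 0 || nrow(features) == 0)
    return(data.table::data.table(region_idx = integer(), feature_idx = integer()))
  gr <- function(x) GenomicRanges::GRanges(
    x$chrom, IRanges::IRanges(start = x$start + 1, end = x$end))
  hits <- GenomicRanges::findOverlaps(gr(regions), gr(features), minoverlap = 1L)
  data.table::data.table(
    region_idx = S4Vectors::queryHits(hits),
    feature_idx = S4Vectors::subjectHits(hits),
    chrom = regions$chrom[S4Vectors::queryHits(hits)],
    region_start = regions$start[S4Vectors::queryHits(hits)],
    region_end = regions$end[S4Vectors::queryHits(hits)],
    feature_start = features$start[S4Vectors::subjectHits(hits)],
    feature_end = features$end[S4Vectors::subjectHits(hits)])
}

#' Write a score track as TSV
#' @param track a score track (see [aggregate_windows()])
#' @param path output path
#' @return `path`, invisibly
#' @export
write_track_tsv <- function(track, path) {
  data.table::fwrite(data.table::as.data.table(track), path, sep = "\t")
  invisible(path)
}
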