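# Linkage disequilibrium decay profiling and two-population F_ST scans.

#' Haplotype r-squared between two sites
#'
#' From the 2x2 haplotype count table over jointly non-missing haplotypes:
#' `D = p_AB - p_A * p_B`, `r2 = D^2 / (p_A (1-p_A) p_B (1-p_B))`.
#'
#' @param panel a `haplotype_panel`
#' @param site_i,site_j site column indices
#' @return r-squared, or `NA` if either site is monomorphic among the
#'   jointly non-missing haplotypes
#' @export
haplotype_r2 <- function(panel, site_i, site_j) {
  x <- panel$haplotypes[, site_i]
  y <- panel$haplotypes[, site_j]
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  pa <- mean(x); pb <- mean(y)
  if (pa %in% c(0, 1) || pb %in% c(0, 1)) return(NA_real_)
  D <- mean(x * y) - pa * pb
  D^2 / (pa * (1 - pa) * pb * (1 - pb))
}

# all pairwise r2 between columns of a complete 0/1 matrix (via correlation)
pairwise_r2 <- function(h) {
  suppressWarnings(cor(h))^2
}

#' LD decay profile: r-squared by distance bin
#'
#' Samples up to `n_snps_sample` sites per segment (seeded), computes
#' r-squared for every within-segment pair closer than `max_dist`, assigns
#' pairs to distance bins and reports mean/SD/count per bin. Pair-level
#' values are retained (optionally downsampled to `pair_cap` per bin) so
#' that two profiles can be compared bin-wise with a rank test.
#'
#' @param panel a `haplotype_panel`
#' @param segments optional `interval_set` restricting sites to genomic
#'   segments (default: the whole panel as one segment per chromosome)
#' @param n_snps_sample sites sampled per segment (default 2000)
#' @param breaks distance bin breakpoints in bp; default 20 equal bins over
#'   (0, 100 kb] plus coarse bins to 250 kb
#' @param max_dist maximum pair distance considered (default 250 kb)
#' @param pair_cap per-bin downsampling cap on retained pair values
#'   (default 10000)
#' @param seed optional RNG seed for site and pair sampling
#' @return object of class `ld_curve`: data.table with bin bounds,
#'   mean_r2, sd_r2, n_pairs; attribute `pair_values` holds the per-bin
#'   retained r-squared samples
#' @export
ld_decay_profile <- function(panel, segments = NULL, n_snps_sample = 2000,
                             breaks = c(seq(0, 1e5, by = 5e3), 1.5e5, 2e5, 2.5e5),
                             max_dist = 2.5e5, pair_cap = 10000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  s <- panel$sites
  if (is.null(segments)) {
    rng <- s[, .(start = 0, end = max(pos) + 1), by = chrom]
    segments <- interval_set(rng$chrom, rng$start, rng$end)
  }
  poly <- which(s$maf > 0)
  dist_all <- numeric(0)
  r2_all <- numeric(0)
  for (k in seq_len(nrow(segments))) {
    in_seg <- poly[s$chrom[poly] == segments$chrom[k] &
                     s$pos[poly] > segments$start[k] &
                     s$pos[poly] <= segments$end[k]]
    if (length(in_seg) < 2) {
      warning("segment ", k, " has fewer than 2 usable sites; skipped")
      next
    }
    if (length(in_seg) > n_snps_sample)
      in_seg <- sort(sample(in_seg, n_snps_sample))
    h <- panel$haplotypes[, in_seg, drop = FALSE]
    r2m <- pairwise_r2(h)
    dm <- abs(outer(s$pos[in_seg], s$pos[in_seg], "-"))
    ut <- upper.tri(r2m)
    sel <- ut & dm <= max_dist & !is.na(r2m)
    dist_all <- c(dist_all, dm[sel])
    r2_all <- c(r2_all, r2m[sel])
  }
  bin <- cut(dist_all, breaks = breaks, include.lowest = FALSE)
  curve <- data.table::data.table(
    bin = levels(bin),
    low = head(breaks, -1), high = tail(breaks, -1))
  pair_values <- lapply(levels(bin), function(b) {
    v <- r2_all[!is.na(bin) & bin == b]
    if (length(v) > pair_cap) v <- sample(v, pair_cap)
    v
  })
  curve[, n_pairs := lengths(pair_values)]
  curve[, mean_r2 := vapply(pair_values, function(v)
    if (length(v)) mean(v) else NA_real_, numeric(1))]
  curve[, sd_r2 := vapply(pair_values, function(v)
    if (length(v) > 1) sd(v) else NA_real_, numeric(1))]
  data.table::setattr(curve, "pair_values", pair_values)
  data.table::setattr(curve, "class", c("ld_curve", class(curve)))
  curve[]
}

#' Compare two LD decay profiles bin by bin
#'
#' For each distance bin present in both curves, a two-sample Wilcoxon rank
#' test on the retained pair-level r-squared samples. Used to quantify how
#' array-like SNP ascertainment inflates LD relative to full-sequence
#' panels.
#'
#' @param curve_a,curve_b `ld_curve` objects from [ld_decay_profile()]
#' @return data.table per shared bin: means, mean difference (a - b), W
#'   statistic and p-value
#' @export
compare_ld_bins <- function(curve_a, curve_b) {
  pa <- attr(curve_a, "pair_values")
  pb <- attr(curve_b, "pair_values")
  shared <- intersect(curve_a$bin[curve_a$n_pairs > 0],
                      curve_b$bin[curve_b$n_pairs > 0])
  out <- data.table::rbindlist(lapply(shared, function(b) {
    va <- pa[[match(b, curve_a$bin)]]
    vb <- pb[[match(b, curve_b$bin)]]
    wt <- suppressWarnings(wilcox.test(va, vb))
    data.table::data.table(bin = b, mean_a = mean(va), mean_b = mean(vb),
                           diff = mean(va) - mean(vb),
                           statistic = unname(wt$statistic),
                           p_value = wt$p.value)
  }))
  out[]
}

#' Per-SNP and sliding-window F_ST between two populations
#'
#' The two-population variance-components estimator applied to haploid
#' allele counts: with `r = 2` populations, sizes `n_i`, allele frequencies
#' `p_i` and mean `p_bar`,
#' `MSG = sum n_i p_i (1 - p_i) / sum (n_i - 1)`,
#' `MSP = sum n_i (p_i - p_bar)^2 / (r - 1)`,
#' `n_c = (sum n_i - sum n_i^2 / sum n_i) / (r - 1)`,
#' `F_ST = (MSP - MSG) / (MSP + (n_c - 1) MSG)`.
#' Negative estimates are reported as-is unless `truncate = TRUE`.
#'
#' @param counts1,counts2 data.frames with columns `chrom`, `pos`,
#'   `n` (haplotypes observed) and `count` (allele-1 count) at shared sites,
#'   or `haplotype_panel` objects. Panels are compared over the union of
#'   their sites: a site absent from one panel's records is counted as
#'   REF-fixed there (count 0), which is what absence of a variant record
#'   means for sequence-derived calls. Count tables are joined on shared
#'   sites only.
#' @param sliding_k sliding window size in SNPs (default 3); sliding values
#'   are means of each k consecutive single-SNP values
#' @param top_fraction quantile for the reported cutoff (default 0.001, the
#'   top 0.1 percent of sliding values)
#' @param truncate truncate negative single-SNP estimates to 0?
#' @return object of class `fst_track`: list with `snp` (per-SNP table),
#'   `sliding` (k-SNP means, positioned at the central SNP) and `cutoff`
#' @export
fst_scan <- function(counts1, counts2, sliding_k = 3, top_fraction = 0.001,
                     truncate = FALSE) {
  as_counts <- function(x) {
    if (inherits(x, "haplotype_panel")) {
      h <- x$haplotypes
      data.table::data.table(chrom = x$sites$chrom, pos = x$sites$pos,
                             n = colSums(!is.na(h)),
                             count = colSums(h, na.rm = TRUE))
    } else data.table::as.data.table(x)
  }
  c1 <- as_counts(counts1)
  c2 <- as_counts(counts2)
  both_panels <- inherits(counts1, "haplotype_panel") &&
    inherits(counts2, "haplotype_panel")
  m <- merge(c1, c2, by = c("chrom", "pos"), suffixes = c("1", "2"),
             all = both_panels)
  if (both_panels) {
    m[is.na(n1), n1 := counts1$n_hap]
    m[is.na(count1), count1 := 0L]
    m[is.na(n2), n2 := counts2$n_hap]
    m[is.na(count2), count2 := 0L]
  }
  if (nrow(m) == 0) stop("no shared sites between the two populations")
  p1 <- m$count1 / m$n1
  p2 <- m$count2 / m$n2
  mono <- (p1 %in% c(0, 1)) & (p2 %in% c(0, 1)) & p1 == p2
  pbar <- (m$count1 + m$count2) / (m$n1 + m$n2)
  msg <- (m$n1 * p1 * (1 - p1) + m$n2 * p2 * (1 - p2)) / (m$n1 - 1 + m$n2 - 1)
  msp <- m$n1 * (p1 - pbar)^2 + m$n2 * (p2 - pbar)^2
  ntot <- m$n1 + m$n2
  nc <- (ntot - (m$n1^2 + m$n2^2) / ntot)
  fst <- (msp - msg) / (msp + (nc - 1) * msg)
  fst[mono] <- NA_real_
  if (truncate) fst <- pmax(fst, 0)
  snp <- data.table::data.table(chrom = m$chrom, pos = m$pos, p1 = p1, p2 = p2,
                                fst = fst)[!is.na(fst)]
  data.table::setorder(snp, chrom, pos)
  k <- as.integer(sliding_k)
  sliding <- snp[, {
    if (.N >= k) {
      mavg <- vapply(seq_len(.N - k + 1),
                     function(i) mean(fst[i:(i + k - 1)]), numeric(1))
      .(pos = pos[seq_len(.N - k + 1) + (k %/% 2)], fst_sliding = mavg)
    } else .(pos = integer(0), fst_sliding = numeric(0))
  }, by = chrom]
  cutoff <- if (nrow(sliding)) quantile(sliding$fst_sliding, 1 - top_fraction,
                                        names = FALSE) else NA_real_
  structure(list(snp = snp, sliding = sliding, cutoff = cutoff,
                 sliding_k = k, top_fraction = top_fraction),
            class = "fst_track")
}
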