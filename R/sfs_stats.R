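# Site-frequency-spectrum statistics: spectrum construction, Tajima's D,
# Fay & Wu's H, and windowed (Z-standardized) heterozygosity.

#' Site frequency spectrum of a panel
#'
#' Unfolded spectra count sites by derived-allele count (1..n-1) and use only
#' sites with a known ancestral state; folded spectra count by minor-allele
#' count (1..floor(n/2)) and use every polymorphic site. Monomorphic columns
#' are excluded.
#'
#' @param panel a `haplotype_panel` (complete, i.e. no missing calls; frequency
#'   counts refer to the full haplotype sample size)
#' @param folded fold the spectrum?
#' @return object of class `sfspectrum`: list with `n`, `counts`
#'   (named vector indexed by allele count), `folded`
#' @export
compute_sfs <- function(panel, folded = FALSE) {
  n <- panel$n_hap
  if (n < 2) stop("need at least 2 haplotypes")
  h <- panel$haplotypes
  use <- if (folded) rep(TRUE, ncol(h)) else panel$sites$ancestral_known
  cnt <- colSums(h[, use, drop = FALSE], na.rm = TRUE)
  cnt <- cnt[cnt > 0 & cnt < n]
  if (folded) cnt <- pmin(cnt, n - cnt)
  kmax <- if (folded) floor(n / 2) else n - 1
  counts <- tabulate(cnt, nbins = kmax)
  names(counts) <- seq_len(kmax)
  structure(list(n = n, counts = counts, folded = folded), class = "sfspectrum")
}

#' Fold an unfolded spectrum
#' @param spectrum an unfolded `sfspectrum`
#' @return the folded `sfspectrum`: counts at i and n-i are pooled for
#'   i < n/2, the class at n/2 (even n) is unchanged
#' @export
fold_sfs <- function(spectrum) {
  if (spectrum$folded) return(spectrum)
  n <- spectrum$n
  kmax <- floor(n / 2)
  counts <- vapply(seq_len(kmax), function(i)
    if (i < n - i) spectrum$counts[i] + spectrum$counts[n - i]
    else spectrum$counts[i], numeric(1))
  names(counts) <- seq_len(kmax)
  structure(list(n = n, counts = counts, folded = TRUE), class = "sfspectrum")
}

# pairwise diversity (pi) and segregating sites from a spectrum; both are
# invariant under folding
sfs_pi_s <- function(spectrum) {
  n <- spectrum$n
  i <- as.integer(names(spectrum$counts))
  S <- sum(spectrum$counts)
  pi <- sum(spectrum$counts * i * (n - i)) / choose(n, 2)
  list(pi = pi, S = S)
}

#' Tajima's (1989) constants as a function of sample size
#' @param n haplotype sample size
#' @return list a1, a2, b1, b2, c1, c2, e1, e2
#' @export
tajima_constants <- function(n) {
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2, e1 = e1, e2 = e2)
}

#' Tajima's D
#'
#' `D = (pi - S/a1) / sqrt(e1*S + e2*S*(S-1))`. Both pi and S are invariant
#' under folding, so folded and unfolded spectra of the same data give
#' identical values.
#'
#' @param x an `sfspectrum`, or a `haplotype_panel` (its folded spectrum is
#'   used so no polarization is required)
#' @return D, or `NA` when `S = 0` (undefined, not an error)
#' @export
tajimas_d <- function(x) {
  if (inherits(x, "haplotype_panel")) x <- compute_sfs(x, folded = TRUE)
  ps <- sfs_pi_s(x)
  if (ps$S == 0) return(NA_real_)
  k <- tajima_constants(x$n)
  (ps$pi - ps$S / k$a1) / sqrt(k$e1 * ps$S + k$e2 * ps$S * (ps$S - 1))
}

#' Fay & Wu's H
#'
#' `H = theta_pi - theta_H` with
#' `theta_pi = sum 2*S_i*i*(n-i) / (n*(n-1))` and
#' `theta_H = sum 2*S_i*i^2 / (n*(n-1))`. An excess of high-frequency derived
#' alleles (the hallmark of hitchhiking) makes H negative. Requires a
#' polarized (unfolded) spectrum.
#'
#' @param spectrum an unfolded `sfspectrum`
#' @return H, or `NA` when `S = 0`
#' @export
fay_wu_h <- function(spectrum) {
  if (inherits(spectrum, "haplotype_panel"))
    spectrum <- compute_sfs(spectrum, folded = FALSE)
  if (spectrum$folded) stop("Fay & Wu's H requires an unfolded spectrum")
  n <- spectrum$n
  i <- as.integer(names(spectrum$counts))
  if (sum(spectrum$counts) == 0) return(NA_real_)
  theta_pi <- sum(2 * spectrum$counts * i * (n - i)) / (n * (n - 1))
  theta_h <- sum(2 * spectrum$counts * i^2) / (n * (n - 1))
  theta_pi - theta_h
}

# spectrum of a subset of sites (by index), used by windowed statistics
sfs_of_sites <- function(panel, idx, folded) {
  n <- panel$n_hap
  cnt <- colSums(panel$haplotypes[, idx, drop = FALSE], na.rm = TRUE)
  if (!folded) {
    ok <- panel$sites$ancestral_known[idx]
    cnt <- cnt[ok]
  }
  cnt <- cnt[cnt > 0 & cnt < n]
  if (folded) cnt <- pmin(cnt, n - cnt)
  kmax <- if (folded) floor(n / 2) else n - 1
  counts <- tabulate(cnt, nbins = kmax)
  names(counts) <- seq_len(kmax)
  structure(list(n = n, counts = counts, folded = folded), class = "sfspectrum")
}

#' Per-window SFS statistic track
#'
#' Computes Tajima's D or Fay & Wu's H from each window's own site list.
#' Windows with fewer than `min_sites` usable sites are reported missing
#' (`NA`), which stabilizes the window means.
#'
#' @param panel a `haplotype_panel`
#' @param grid a `window_grid`
#' @param stat `"tajd"` or `"faywuh"`
#' @param min_sites minimum usable sites per window (default 10)
#' @return data.table with chrom, start, end, n_sites, value
#' @export
window_sfs_stat <- function(panel, grid, stat = c("tajd", "faywuh"),
                            min_sites = 10) {
  stat <- match.arg(stat)
  folded <- stat == "tajd"
  idx_list <- window_site_index(panel$sites$pos, panel$sites$chrom, grid)
  fun <- if (stat == "tajd") tajimas_d else fay_wu_h
  res <- data.table::as.data.table(grid[, c("chrom", "start", "end")])
  usable <- vapply(idx_list, function(ix) {
    if (!folded) ix <- ix[panel$sites$ancestral_known[ix]]
    length(ix)
  }, integer(1))
  res[, n_sites := usable]
  res[, value := vapply(seq_along(idx_list), function(w) {
    if (usable[w] < min_sites) return(NA_real_)
    fun(sfs_of_sites(panel, idx_list[[w]], folded))
  }, numeric(1))]
  res[, stat := stat]
  res[]
}

#' Windowed heterozygosity and its genome-wide Z score
#'
#' Per window, Het is the mean over polymorphic sites of the expected
#' heterozygosity `2*p*(1-p)` computed from haplotype allele frequencies
#' (the panel is phased, so haplotype frequencies are the natural choice; an
#' alternative diploid observed-heterozygosity mode counts heterozygous
#' individuals instead). ZHet standardizes Het by the genome-wide mean and SD
#' over non-missing windows, so a sweep shows up as a strongly negative ZHet.
#'
#' @param panel a `haplotype_panel`
#' @param grid a `window_grid`
#' @param min_sites minimum polymorphic sites per window (default 10)
#' @param mode `"expected"` (2pq from haplotype frequencies, default) or
#'   `"observed"` (fraction of heterozygous diploids)
#' @return data.table with chrom, start, end, n_sites, het, zhet
#' @export
window_heterozygosity <- function(panel, grid, min_sites = 10,
                                  mode = c("expected", "observed")) {
  mode <- match.arg(mode)
  h <- panel$haplotypes
  n <- panel$n_hap
  p <- colMeans(h, na.rm = TRUE)
  poly <- p > 0 & p < 1
  site_het <- if (mode == "expected") {
    2 * p * (1 - p)
  } else {
    a1 <- h[seq(1, n, by = 2), , drop = FALSE]
    a2 <- h[seq(2, n, by = 2), , drop = FALSE]
    colMeans(a1 != a2, na.rm = TRUE)
  }
  idx_list <- window_site_index(panel$sites$pos, panel$sites$chrom, grid)
  res <- data.table::as.data.table(grid[, c("chrom", "start", "end")])
  res[, n_sites := vapply(idx_list, function(ix) sum(poly[ix]), integer(1))]
  res[, het := vapply(seq_along(idx_list), function(w) {
    ix <- idx_list[[w]][poly[idx_list[[w]]]]
    if (length(ix) < min_sites) return(NA_real_)
    mean(site_het[ix])
  }, numeric(1))]
  mu <- mean(res$het, na.rm = TRUE)
  sg <- sd(res$het, na.rm = TRUE)
  res[, zhet := (het - mu) / sg]
  res[]
}
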