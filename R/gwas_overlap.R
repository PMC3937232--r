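# Mixed-model association scan (EMMAX-style: variance components estimated
# once under the null, then per-SNP generalized least squares) and the
# permutation test for overlap between association hits and sweep-candidate
# windows.

#' Realized genomic relationship matrix
#'
#' `G = Z Z' / c` where Z is the dosage matrix centered by twice the allele
#' frequency and `c = sum 2 p_k (1 - p_k)`. Monomorphic SNPs are excluded.
#'
#' @param dosages individuals x SNPs matrix of 0/1/2 allele dosages
#' @return object of class `grm`: list with `G` (symmetric matrix), `p`
#'   (allele frequencies used) and `scale_const` c
#' @export
genomic_relationship_matrix <- function(dosages) {
  dosages <- as.matrix(dosages)
  p <- colMeans(dosages) / 2
  keep <- p > 0 & p < 1
  if (!any(keep)) stop("all SNPs are monomorphic")
  Z <- sweep(dosages[, keep, drop = FALSE], 2, 2 * p[keep])
  cc <- sum(2 * p[keep] * (1 - p[keep]))
  G <- tcrossprod(Z) / cc
  structure(list(G = (G + t(G)) / 2, p = p[keep], scale_const = cc),
            class = "grm")
}

# REML profile log-likelihood in delta = sigma_e^2 / sigma_a^2 for the null
# model y = mu + u + e, u ~ N(0, sigma_a^2 G), after rotation by the
# eigenvectors of G (EMMA formulation, constants dropped)
reml_ll <- function(log_delta, lambda, ys, Xs) {
  delta <- exp(log_delta)
  w <- 1 / (lambda + delta)
  XtWX <- crossprod(Xs, Xs * w)
  beta <- solve(XtWX, crossprod(Xs, ys * w))
  r <- ys - Xs %*% beta
  rss <- sum(w * r^2)
  nq <- length(ys) - ncol(Xs)
  -0.5 * (nq * log(rss / nq) + sum(log(lambda + delta)) +
            determinant(XtWX, logarithm = TRUE)$modulus)
}

#' Mixed-model association scan (EMMAX approximation)
#'
#' Fits `y = mu + s b + u + e` with `u ~ N(0, sigma_a^2 G)`. Variance
#' components are estimated once by REML under the null (no SNP) via
#' eigendecomposition of G and one-dimensional optimization in the variance
#' ratio; every SNP is then tested by generalized least squares with the
#' covariance fixed at the null estimate (a Wald t-test). This is the
#' standard fast approximation for dense scans; it is exact when SNP effects
#' are small.
#'
#' @param y numeric phenotype vector (one value per individual)
#' @param dosages individuals x SNPs dosage matrix
#' @param grm a [genomic_relationship_matrix()] (or plain matrix)
#' @return object of class `gwas_result`: data.table with beta, se, p per
#'   SNP plus attributes `sigma_a2`, `sigma_e2`, `delta`, `boundary`
#'   (TRUE when sigma_a2 hit the zero boundary and the scan reduces to OLS)
#' @export
emmax_scan <- function(y, dosages, grm) {
  G <- if (inherits(grm, "grm")) grm$G else as.matrix(grm)
  dosages <- as.matrix(dosages)
  n <- length(y)
  if (nrow(dosages) != n || nrow(G) != n)
    stop("dimension mismatch between y, dosages and GRM")
  if (var(y) == 0) stop("phenotype has zero variance")
  eig <- eigen(G, symmetric = TRUE)
  lambda <- pmax(eig$values, 0)
  U <- eig$vectors
  ys <- drop(crossprod(U, y))
  Xs <- crossprod(U, matrix(1, n, 1))
  opt <- optimize(reml_ll, c(-12, 12), lambda = lambda, ys = ys, Xs = Xs,
                  maximum = TRUE, tol = 1e-6)
  if (!is.finite(opt$objective))
    stop("REML optimization failed: non-finite profile likelihood")
  delta <- exp(opt$maximum)
  boundary <- opt$maximum > 11            # sigma_a^2 ~ 0: effectively OLS
  w <- 1 / (lambda + delta)
  XtWX <- sum(w * Xs^2)
  b0 <- sum(w * Xs * ys) / XtWX
  rss <- sum(w * (ys - Xs * b0)^2)
  sigma_a2 <- rss / (n - 1)
  sigma_e2 <- delta * sigma_a2
  Gs <- crossprod(U, dosages)
  mono <- apply(dosages, 2, function(g) var(g) == 0)
  beta <- se <- pval <- rep(NA_real_, ncol(dosages))
  df <- n - 2
  for (j in seq_len(ncol(dosages))) {
    if (mono[j]) next
    gs <- Gs[, j]
    # GLS of ys on [Xs, gs] with weights w; covariance sigma_a2 * (X'WX)^-1
    a11 <- XtWX
    a12 <- sum(w * Xs * gs)
    a22 <- sum(w * gs^2)
    det <- a11 * a22 - a12^2
    if (det <= 0) next
    r1 <- sum(w * Xs * ys)
    r2 <- sum(w * gs * ys)
    b <- c(a22 * r1 - a12 * r2, a11 * r2 - a12 * r1) / det
    beta[j] <- b[2]
    se[j] <- sqrt(sigma_a2 * a11 / det)
    pval[j] <- 2 * pt(abs(beta[j] / se[j]), df = df, lower.tail = FALSE)
  }
  res <- data.table::data.table(snp = seq_len(ncol(dosages)),
                                beta = beta, se = se, p = pval)
  data.table::setattr(res, "sigma_a2", sigma_a2)
  data.table::setattr(res, "sigma_e2", sigma_e2)
  data.table::setattr(res, "delta", delta)
  data.table::setattr(res, "boundary", boundary)
  data.table::setattr(res, "class", c("gwas_result", class(res)))
  res[]
}

#' Fraction of phenotypic variance explained by one SNP
#'
#' The single-SNP approximation `2 p (1 - p) beta^2 / var_y`.
#'
#' @param beta estimated allele substitution effect
#' @param p allele frequency
#' @param var_y phenotypic variance
#' @return fraction in [0, Inf)
#' @export
snp_variance_explained <- function(beta, p, var_y) {
  if (var_y <= 0) stop("var_y must be positive")
  2 * p * (1 - p) * beta^2 / var_y
}

#' Permutation test for GWAS / selection-scan overlap
#'
#' Counts GWAS associations (`p < gwas_threshold`) that fall inside
#' top-percentile selection windows and compares the count with its
#' permutation distribution obtained by shuffling the p-values across units
#' (SNPs or windows). `emp_p = (#{perm >= observed} + 1) / (n_perm + 1)`, so
#' the smallest attainable value is `1/(n_perm + 1)`.
#'
#' @param gwas data.frame with `chrom`, `pos`, `p` for every tested SNP
#' @param selection a window score track (with or without `emp_p`)
#' @param gwas_threshold association significance threshold (default 1e-6,
#'   a Bonferroni-style genome-wide cutoff)
#' @param selection_percentile candidate-window quantile (default 0.99)
#' @param unit `"snp"` (permute across SNPs) or `"window"` (collapse SNPs to
#'   windows by their minimum p, permute across windows)
#' @param n_perm number of permutations (default 10000)
#' @param seed optional RNG seed
#' @return object of class `overlap_result`: list with `observed_overlap`,
#'   `perm_counts`, `emp_p`, `n_perm`, thresholds and unit bookkeeping
#' @export
overlap_permutation_test <- function(gwas, selection, gwas_threshold = 1e-6,
                                     selection_percentile = 0.99,
                                     unit = c("snp", "window"),
                                     n_perm = 10000, seed = NULL) {
  unit <- match.arg(unit)
  if (!is.null(seed)) set.seed(seed)
  gwas <- data.table::as.data.table(gwas)
  selection <- data.table::copy(data.table::as.data.table(selection))
  if (is.null(selection$emp_p)) selection <- empirical_pvalues(selection)
  selection[, cand := !is.na(emp_p) & emp_p <= (1 - selection_percentile) + 1e-9]
  # map each SNP to its (non-overlapping) window
  win_of <- rep(NA_integer_, nrow(gwas))
  for (ch in unique(gwas$chrom)) {
    wi <- which(selection$chrom == ch)
    gi <- which(gwas$chrom == ch)
    if (!length(wi) || !length(gi)) next
    k <- findInterval(gwas$pos[gi], selection$start[wi])
    inside <- k >= 1 & gwas$pos[gi] < selection$end[wi][pmax(k, 1)]
    win_of[gi[inside]] <- wi[k[inside]]
  }
  if (unit == "snp") {
    keep <- !is.na(win_of)
    pvals <- gwas$p[keep]
    in_cand <- selection$cand[win_of[keep]]
  } else {
    dt <- data.table::data.table(w = win_of, p = gwas$p)[!is.na(w)]
    units <- dt[, .(p = min(p)), by = w]
    pvals <- units$p
    in_cand <- selection$cand[units$w]
  }
  hit <- pvals < gwas_threshold
  h <- sum(hit)
  if (h == 0) stop("no GWAS hit below threshold ", gwas_threshold,
                   ": nothing to test")
  observed <- sum(hit & in_cand)
  n_units <- length(pvals)
  # permuting p-values across units lands the h hits on a uniform random
  # subset of units, so the permuted count is the candidate total among h
  # draws without replacement
  perm_counts <- vapply(seq_len(n_perm), function(r)
    sum(in_cand[sample.int(n_units, h)]), integer(1))
  structure(list(observed_overlap = observed, perm_counts = perm_counts,
                 emp_p = (sum(perm_counts >= observed) + 1) / (n_perm + 1),
                 n_perm = n_perm, gwas_threshold = gwas_threshold,
                 selection_percentile = selection_percentile, unit = unit,
                 n_units = n_units, n_hits = h,
                 n_candidate_units = sum(in_cand)),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat("overlap_result:", x$observed_overlap, "of", x$n_hits,
      "hits in candidate windows;",
      "emp_p =", signif(x$emp_p, 3), "(", x$n_perm, "permutations,",
      x$unit, "units )\n")
  invisible(x)
}
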