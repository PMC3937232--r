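# SweepFinder-style composite likelihood ratio scan. The sweep model: each
# of the n sampled lineages escapes the sweep at map distance d with
# probability p_e = 1 - exp(-alpha * d); the n - k non-escaping lineages all
# inherit the allele of a single ancestral lineage, so conditional on k
# escapees the post-sweep sample is equivalent to k + 1 draws from the
# pre-sweep population, one of which is copied into the trapped lineages.
# Pre-sweep draws come from the genome-wide background spectrum via
# hypergeometric downsampling.

#' Genome-wide background site frequency spectrum
#'
#' @param panel a `haplotype_panel`
#' @param min_sites minimum polarized polymorphic sites required for a
#'   usable calibration (default 100)
#' @param pseudocount added to every derived-count class before normalizing
#'   (default 0.5). A finite calibration panel can leave frequency classes
#'   empty that a scanned region does populate; an empty class would give the
#'   background model probability zero and an infinite likelihood ratio.
#' @param include_fixed also model the sample-fixed derived class (count n,
#'   i.e. substitutions relative to the ancestral state). Requires a panel
#'   built with `keep_monomorphic = TRUE`. After a completed sweep the
#'   trapped lineages all carry the derived allele, so substitutions are
#'   where much of the post-fixation signal lives.
#' @return object of class `background_sfs`: list with `n`, `probs`
#'   (normalized over derived counts 1..n-1, or 1..n when
#'   `include_fixed = TRUE`), `S`
#' @export
background_sfs <- function(panel, min_sites = 100, pseudocount = 0.5,
                           include_fixed = FALSE) {
  n <- panel$n_hap
  cnt <- colSums(panel$haplotypes, na.rm = TRUE)
  ok <- panel$sites$ancestral_known & cnt > 0 &
    (if (include_fixed) cnt <= n else cnt < n)
  kmax <- if (include_fixed) n else n - 1
  counts <- tabulate(cnt[ok], nbins = kmax)
  names(counts) <- seq_len(kmax)
  S <- sum(counts)
  if (S < min_sites)
    stop("only ", S, " polarized variant sites; need >= ", min_sites,
         " to calibrate a background spectrum")
  probs <- (counts + pseudocount) / (S + pseudocount * kmax)
  structure(list(n = n, probs = probs, S = S, include_fixed = include_fixed),
            class = "background_sfs")
}

# Precompute the escape-mixture matrix V: row k+1 (k = 0..n escapees) holds
# the distribution of the post-sweep derived count (columns c = 0..n) given
# exactly k escapees. Depends only on the background spectrum.
sweep_escape_matrix <- function(background) {
  n <- background$n
  probs <- background$probs
  b <- as.integer(names(probs))   # 1..n-1, plus n when substitutions modeled
  V <- matrix(0, nrow = n + 1, ncol = n + 1) # rows k = 0..n, cols c = 0..n
  for (k in 0:(n - 1)) {
    m <- k + 1
    # P_m(j): derived count j among m hypergeometric draws from a sample of
    # size n distributed as the background spectrum
    D <- outer(0:m, b, function(j, bb) dhyper(j, bb, n - bb, m))
    Pm <- as.numeric(D %*% probs)
    for (j in 0:m) {
      if (Pm[j + 1] == 0) next
      w_anc <- j / m                       # the ancestor draw is derived
      if (j <= n) V[k + 1, j + 1] <- V[k + 1, j + 1] + Pm[j + 1] * (1 - w_anc)
      cc <- j - 1 + n - k                  # trapped lineages copy the ancestor
      if (w_anc > 0) V[k + 1, cc + 1] <- V[k + 1, cc + 1] + Pm[j + 1] * w_anc
    }
  }
  V[n + 1, b + 1] <- probs                 # all lineages escape: background
  V
}

#' Sweep-transformed site frequency spectrum
#'
#' Distribution of the derived-allele count (0..n) at a site a map distance
#' `d` from a completed sweep of intensity `alpha`, mixing the per-k escape
#' distributions by the binomial law with `p_e = 1 - exp(-alpha * d)`.
#' At `p_e = 1` the background spectrum is recovered; as `p_e -> 0` the mass
#' concentrates on the monomorphic classes 0 and n (plus singleton-type
#' classes contributed by the single surviving ancestral lineage).
#'
#' @param background a `background_sfs`
#' @param alpha sweep intensity parameter (> 0, per bp)
#' @param d distance from the sweep in bp (>= 0)
#' @param V optional precomputed [sweep_escape_matrix()] for repeated calls
#' @return numeric probability vector over derived counts 0..n (sums to 1)
#' @export
sweep_transformed_sfs <- function(background, alpha, d, V = NULL) {
  if (alpha <= 0) stop("alpha must be positive")
  if (d < 0) stop("d must be non-negative")
  n <- background$n
  if (is.null(V)) V <- sweep_escape_matrix(background)
  p_e <- -expm1(-alpha * d)                # saturates at 1 for large alpha*d
  w <- dbinom(0:n, n, p_e)
  as.numeric(w %*% V)
}

# Composite log likelihood under the sweep model at one grid position.
# Only the transformed probability of each site's observed count and the
# total polymorphic mass are needed, so instead of the full mixture-matrix
# product we use per-site columns of V (Vc = V[, counts + 1]) and the
# per-k polymorphic row sum u = rowSums(V[, 2:n]).
sweep_logcl <- function(n, counts, dists, alpha, Vc, u, lbgc) {
  p_e <- -expm1(-alpha * dists)
  # sites that escape with p_e ~ 1 are background-distributed after
  # conditioning: their log-ratio contribution is ~ 0, so score them by the
  # background directly instead of building their binomial mixture
  act <- p_e < 0.999999
  ll <- sum(lbgc[!act])
  mix_ll <- function(idx, kmax) {
    pe <- p_e[idx]
    kk <- 0:kmax
    W <- matrix(dbinom(rep(kk, times = length(pe)), n,
                       rep(pe, each = kmax + 1)), nrow = kmax + 1)
    num <- colSums(Vc[kk + 1, idx, drop = FALSE] * W)
    # condition on polymorphism; the polymorphic mass can underflow to 0 for
    # tiny alpha * d, in which case the observed (polymorphic) data get the
    # floor probability
    poly <- pmax(colSums(u[kk + 1] * W), 1e-300)
    sum(log(pmax(num / poly, 1e-300)))
  }
  # for small escape probabilities the binomial mixture is concentrated on
  # few escapees: truncating at k ~ 30 leaves < 1e-12 of the mass out
  small <- act & p_e < 0.1
  if (any(small)) ll <- ll + mix_ll(which(small), min(n, 30L))
  if (any(act & !small)) ll <- ll + mix_ll(which(act & !small), n)
  ll
}

#' Composite likelihood ratio scan
#'
#' At each grid position, the composite likelihood under the sweep model is
#' the product over polarized sites within `window_radius` of the
#' sweep-transformed spectrum probability of the observed derived count,
#' conditioned on polymorphism (classes 1..n-1 renormalized; input sites are
#' polymorphic by construction). `clr = 2 * (max_alpha log CL_sweep - log
#' CL_background)`, maximized by a log-spaced grid search refined with
#' golden-section. The boundary alpha -> infinity recovers the background
#' model, so clr >= 0 everywhere.
#'
#' @param panel a `haplotype_panel`
#' @param background a `background_sfs` computed from the same panel (or a
#'   superset of it)
#' @param grid either a `window_grid` (positions = window midpoints) or a
#'   data.frame with columns `chrom`, `pos`
#' @param window_radius sites farther than this from the grid position are
#'   ignored (default 100 kb; under relevant alphas they escape with
#'   probability ~ 1 and carry no signal)
#' @param alpha_range search range for alpha, per bp (default 1e-8..1e-2)
#' @param n_alpha number of log-spaced grid points (default 30)
#' @param trim_to_data drop grid positions outside the span of usable sites
#'   on their chromosome (default TRUE). Positions beyond the data see only
#'   a one-sided, shrinking site set and produce inflated edge artifacts.
#' @return data.table of class `clr_track`: chrom, pos, clr, alpha_hat,
#'   n_sites, boundary flag; positions with no sites in range have `NA` clr
#' @export
clr_scan <- function(panel, background, grid, window_radius = 1e5,
                     alpha_range = c(1e-8, 1e-2), n_alpha = 30,
                     trim_to_data = TRUE) {
  if (!is.data.frame(grid)) stop("grid must be a window_grid or data.frame")
  gp <- data.table::as.data.table(grid)
  if (!is.null(gp$start) && is.null(gp$pos))
    gp <- gp[, .(chrom, pos = (start + end) / 2)]
  s <- panel$sites
  n <- background$n
  K <- length(background$probs)            # n-1, or n with substitutions
  V <- sweep_escape_matrix(background)
  # conditioning is on "observed as a variant record": classes 1..K
  u <- rowSums(V[, 1 + seq_len(K), drop = FALSE])
  lbg <- log(background$probs)
  alphas <- exp(seq(log(alpha_range[1]), log(alpha_range[2]),
                    length.out = n_alpha))
  ok <- s$ancestral_known & !is.na(s$derived_count) &
    s$derived_count > 0 & s$derived_count <= K
  if (trim_to_data) {
    span <- s[ok, .(lo = min(pos), hi = max(pos)), by = chrom]
    m <- match(gp$chrom, span$chrom)
    gp <- gp[!is.na(m) & gp$pos >= span$lo[m] & gp$pos <= span$hi[m]]
  }
  out <- data.table::data.table(chrom = gp$chrom, pos = gp$pos,
                                clr = NA_real_, alpha_hat = NA_real_,
                                n_sites = 0L, boundary = NA)
  for (g in seq_len(nrow(gp))) {
    sel <- which(ok & s$chrom == gp$chrom[g] &
                   abs(s$pos - gp$pos[g]) <= window_radius)
    if (!length(sel)) next
    counts <- s$derived_count[sel]
    dists <- abs(s$pos[sel] - gp$pos[g])
    Vc <- V[, counts + 1L, drop = FALSE]
    ll_bg <- sum(lbg[counts])
    lbgc <- lbg[counts]
    ll <- vapply(alphas, function(a)
      sweep_logcl(n, counts, dists, a, Vc, u, lbgc), numeric(1))
    i <- which.max(ll)
    lo <- log(alphas[max(1, i - 1)])
    hi <- log(alphas[min(n_alpha, i + 1)])
    opt <- optimize(function(la)
      sweep_logcl(n, counts, dists, exp(la), Vc, u, lbgc),
      c(lo, hi), maximum = TRUE, tol = 1e-3)
    best <- max(opt$objective, ll[i])
    a_hat <- if (opt$objective >= ll[i]) exp(opt$maximum) else alphas[i]
    data.table::set(out, g, "clr", max(0, 2 * (best - ll_bg)))
    data.table::set(out, g, "alpha_hat", a_hat)
    data.table::set(out, g, "n_sites", length(sel))
    data.table::set(out, g, "boundary", i == 1L || i == n_alpha)
  }
  out[]
}
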