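# Shared fixtures and independent oracle implementations. Simulation sets
# used by several test files are generated once per test run and memoized.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, fun) {
  if (!exists(name, envir = .fixture_env))
    assign(name, fun(), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# hand-built panel: matrix rows = haplotypes, columns = sites
make_panel <- function(mat, pos = NULL, chrom = "chr1", polarized = TRUE) {
  mat <- as.matrix(mat)
  if (is.null(pos)) pos <- seq_len(ncol(mat)) * 1000L
  k <- ncol(mat)
  sites <- data.frame(chrom = rep(chrom, k), pos = pos,
                      ref = rep("A", k), alt = rep("T", k),
                      ancestral_known = rep(polarized, k))
  haplotype_panel(mat, sites)
}

# 25 neutral replicate panels under the default stated world (N = 200,
# 200 kb, theta_L = 200); used by Tajima/CLR calibration and LD tests
neutral_reps <- function() fixture("neutral_reps", function() {
  lapply(1:25, function(r)
    simulate_neutral_panel(sim_params(seed = 9000 + r)))
})

# 25 conditioned hard sweeps run to fixation (CLR / het-dip regime)
sweep_reps_fixed <- function() fixture("sweep_reps_fixed", function() {
  lapply(1:25, function(r)
    simulate_sweep_panel(sim_params(s = 0.1, end_freq = 1, seed = 7000 + r)))
})

# 25 conditioned sweeps stopped at derived frequency 0.7 (iHS regime)
sweep_reps_mid <- function() fixture("sweep_reps_mid", function() {
  lapply(1:25, function(r)
    simulate_sweep_panel(sim_params(s = 0.1, end_freq = 0.7, seed = 8000 + r)))
})

# genome-wide background spectrum calibrated on the neutral replicate set
neutral_background <- function() fixture("neutral_background", function() {
  panels <- neutral_reps()
  h <- do.call(cbind, lapply(panels, function(p) p$haplotypes))
  pos <- unlist(lapply(seq_along(panels), function(i)
    panels[[i]]$sites$pos + (i - 1) * 200000L))
  sites <- data.frame(chrom = "bgchrom", pos = pos, ref = "A", alt = "T",
                      ancestral_known = TRUE)
  background_sfs(haplotype_panel(h, sites))
})

## ---- independent oracles ----------------------------------------------

# EHH by explicit haplotype-prefix enumeration: probability that two random
# carriers are identical from the core through site j
oracle_ehh <- function(h, carriers, core, j) {
  cols <- if (j >= core) core:j else j:core
  keys <- apply(h[carriers, cols, drop = FALSE], 1, paste, collapse = ",")
  tab <- table(keys)
  nc <- length(carriers)
  sum(choose(tab, 2)) / choose(nc, 2)
}

# one-sided iHH oracle: walk every site outward, enumerate prefixes, stop at
# the interpolated cutoff crossing or the chromosome end
oracle_ihh_side <- function(panel, core, allele, step, cutoff = 0.05,
                            max_gap = 1e5) {
  h <- panel$haplotypes
  pos <- panel$sites$pos
  carriers <- which(h[, core] == allele)
  xs <- 0
  vs <- 1
  j <- core
  censored <- TRUE
  repeat {
    nxt <- j + step
    if (nxt < 1 || nxt > ncol(h)) break
    if (abs(pos[nxt] - pos[j]) > max_gap) break
    xs <- c(xs, abs(pos[nxt] - pos[core]))
    vs <- c(vs, oracle_ehh(h, carriers, core, nxt))
    j <- nxt
    if (vs[length(vs)] < cutoff) { censored <- FALSE; break }
  }
  if (!censored) {
    k <- length(vs)
    xc <- xs[k - 1] + (vs[k - 1] - cutoff) / (vs[k - 1] - vs[k]) * (xs[k] - xs[k - 1])
    xs <- c(xs[1:(k - 1)], xc)
    vs <- c(vs[1:(k - 1)], cutoff)
  }
  sum(diff(xs) * (head(vs, -1) + tail(vs, -1)) / 2)
}

oracle_ihs_raw <- function(panel, core, cutoff = 0.05, max_gap = 1e5) {
  iha <- oracle_ihh_side(panel, core, 0, 1L, cutoff, max_gap) +
    oracle_ihh_side(panel, core, 0, -1L, cutoff, max_gap)
  ihd <- oracle_ihh_side(panel, core, 1, 1L, cutoff, max_gap) +
    oracle_ihh_side(panel, core, 1, -1L, cutoff, max_gap)
  if (iha <= 0 || ihd <= 0) return(NA_real_)
  log(iha / ihd)
}

# nSL oracle by direct pair scan
oracle_nsl_class <- function(h, carriers, core) {
  nc <- length(carriers)
  if (nc < 2) return(NA_real_)
  pairs <- utils::combn(carriers, 2)
  L <- apply(pairs, 2, function(pr) {
    a <- h[pr[1], ]
    b <- h[pr[2], ]
    l <- core
    while (l > 1 && identical(a[l - 1], b[l - 1])) l <- l - 1
    r <- core
    while (r < length(a) && identical(a[r + 1], b[r + 1])) r <- r + 1
    r - l + 1
  })
  mean(L)
}

oracle_nsl_raw <- function(panel, core) {
  h <- panel$haplotypes
  sa <- oracle_nsl_class(h, which(h[, core] == 0), core)
  sd_ <- oracle_nsl_class(h, which(h[, core] == 1), core)
  log(sa / sd_)
}

# Tajima's D oracle: direct evaluation of the 1989 constants from scratch
oracle_tajd <- function(counts, n) {
  i <- seq_along(counts)
  S <- sum(counts)
  if (S == 0) return(NA_real_)
  pi <- sum(counts * i * (n - i)) / (n * (n - 1) / 2)
  a1 <- sum(1 / (1:(n - 1)))
  a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  (pi - S / a1) / sqrt(c1 / a1 * S + c2 / (a1^2 + a2) * S * (S - 1))
}

# r2 oracle from the explicit 2x2 haplotype contingency table
oracle_r2 <- function(x, y) {
  tab <- table(factor(x, 0:1), factor(y, 0:1)) / length(x)
  pA <- sum(tab[2, ])
  pB <- sum(tab[, 2])
  D <- tab[2, 2] - pA * pB
  D^2 / (pA * (1 - pA) * pB * (1 - pB))
}
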