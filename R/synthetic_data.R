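# Ground-truth data generation: forward Wright-Fisher panels (neutral or
# hard sweep), array-like SNP ascertainment, and polygenic-plus-QTL
# phenotypes. The simulator is the compiled routine in src/wf_sim.cpp; all
# randomness flows through R's RNG, so results are bit-reproducible under
# set.seed().

#' Simulation parameter set
#'
#' Desk-scale defaults: 200 diploids, a 200-kb region, and per-site rates
#' chosen so that a sample of 86 haplotypes (the analogue of 43 resequenced
#' diploids) segregates roughly 1000 SNPs -- about one SNP per 200 bp,
#' comparable to the density of a deep resequencing panel.
#'
#' @param n_diploids population size N (Wright-Fisher diploids)
#' @param sample_hap number of haplotypes sampled from the final generation
#' @param seq_len region length in bp
#' @param mu per-bp per-generation mutation rate (infinite sites)
#' @param rho per-bp per-generation crossover rate
#' @param s selection coefficient of the beneficial allele; fitnesses are
#'   1, 1+s, 1+2s for carrying 0/1/2 copies. `s = 0` means neutral.
#' @param sweep_pos position (bp) at which the beneficial mutation is injected
#' @param end_freq population derived-allele frequency at which a sweep
#'   simulation stops (1 = fixation)
#' @param burnin_gens burn-in generations from a monomorphic start; default
#'   `10 * n_diploids`
#' @param seed optional RNG seed applied with `set.seed()` by the simulators
#' @return a list of class `sim_params`
#' @export
sim_params <- function(n_diploids = 200, sample_hap = 86, seq_len = 200000,
                       mu = 1.25e-6, rho = 1.25e-6, s = 0,
                       sweep_pos = floor(seq_len / 2), end_freq = 1,
                       burnin_gens = 10 * n_diploids, seed = NULL) {
  if (seq_len <= 0) stop("seq_len must be positive")
  if (mu < 0) stop("mu must be non-negative")
  if (rho < 0) stop("rho must be non-negative")
  if (s < 0) stop("s must be non-negative")
  if (end_freq <= 0 || end_freq > 1) stop("end_freq must be in (0, 1]")
  if (sample_hap > 2 * n_diploids)
    stop("sample_hap cannot exceed 2 * n_diploids")
  structure(list(n_diploids = as.integer(n_diploids),
                 sample_hap = as.integer(sample_hap),
                 seq_len = as.integer(seq_len), mu = mu, rho = rho, s = s,
                 sweep_pos = as.integer(sweep_pos), end_freq = end_freq,
                 burnin_gens = as.integer(burnin_gens), seed = seed),
            class = "sim_params")
}

wf_run <- function(p) {
  if (!is.null(p$seed)) set.seed(p$seed)
  .wf_simulate_cpp(p$n_diploids, p$seq_len, p$mu, p$rho, p$burnin_gens,
                   p$s, p$sweep_pos, p$end_freq, p$sample_hap, 1000L)
}

panel_from_sim <- function(raw, p, chrom = "sim1", keep_monomorphic = FALSE) {
  n <- p$sample_hap
  cnt <- colSums(raw$geno)
  keep <- cnt > 0L & (keep_monomorphic | cnt < n)
  pos <- raw$positions[keep]
  h <- raw$geno[, keep, drop = FALSE]
  sites <- data.table::data.table(chrom = chrom, pos = pos,
                                  ref = "A", alt = "T",
                                  ancestral_known = TRUE)
  haplotype_panel(h, sites, sample_ids = sprintf("sim%03d", seq_len(n / 2)))
}

#' Simulate a neutral haplotype panel
#'
#' Forward Wright-Fisher simulation under neutrality: burn-in from a
#' monomorphic start, then `sample_hap` haplotypes drawn without
#' replacement. The ancestral state of every site is known by construction
#' (allele 0), so all panels come back fully polarized.
#'
#' @param params a [sim_params()] object with `s = 0`
#' @param keep_monomorphic also keep sites where the derived allele is fixed
#'   in the sample (as a joint variant calling across populations would);
#'   default FALSE, polymorphic sites only
#' @return a `haplotype_panel` of the sites segregating in the sample
#' @export
simulate_neutral_panel <- function(params, keep_monomorphic = FALSE) {
  if (params$s != 0) stop("simulate_neutral_panel requires s == 0; use simulate_sweep_panel")
  panel_from_sim(wf_run(params), params, keep_monomorphic = keep_monomorphic)
}

#' Simulate a hard selective sweep
#'
#' After neutral burn-in a beneficial mutation is injected at `sweep_pos` on
#' one random haplotype and the population evolves under additive diploid
#' selection (fitness 1, 1+s, 1+2s). Trajectories that lose the allele are
#' rejected and restarted from the post-burn-in state, i.e. the run is
#' conditioned on the allele reaching `end_freq`. The panel is sampled in the
#' first generation at which the population frequency reaches `end_freq`.
#'
#' @param params a [sim_params()] object with `s > 0`
#' @param keep_monomorphic also keep sample-fixed derived sites (see
#'   [simulate_neutral_panel()]); the strongest between-population F_ST
#'   signals of a completed sweep live at exactly such sites
#' @return list with `panel` (a `haplotype_panel`) and `truth`, a record of
#'   the simulated sweep: `sweep_pos`, `s`, `fixation_generation`,
#'   `trajectory` (per-generation population frequency starting at 1/2N),
#'   `attempts` (rejected trials + 1) and `sample_derived_freq`, the
#'   frequency of the beneficial allele among the sampled haplotypes
#' @export
simulate_sweep_panel <- function(params, keep_monomorphic = FALSE) {
  if (params$s <= 0) stop("simulate_sweep_panel requires s > 0")
  raw <- wf_run(params)
  n <- params$sample_hap
  sw_col <- match(params$sweep_pos, raw$positions)
  sfreq <- if (is.na(sw_col)) 0 else sum(raw$geno[, sw_col]) / n
  truth <- structure(list(sweep_pos = params$sweep_pos, s = params$s,
                          fixation_generation = length(raw$trajectory) - 1L,
                          trajectory = raw$trajectory,
                          attempts = raw$attempts,
                          sample_derived_freq = sfreq),
                     class = "sim_truth")
  list(panel = panel_from_sim(raw, params, keep_monomorphic = keep_monomorphic),
       truth = truth)
}

#' Simulate a recent two-population split with a breed-specific sweep
#'
#' Both populations descend from a common ancestor (shared neutral burn-in).
#' After the split, population 2 experiences a conditioned hard sweep at
#' `sweep_pos` while population 1 drifts neutrally for the same number of
#' generations. This is the desk-scale stand-in for a two-breed contrast in
#' which selection fixed a variant in one breed only: background
#' differentiation is the mild drift of a recent split, and the strongest
#' F_ST signal sits at the swept locus.
#'
#' @param params a [sim_params()] object with `s > 0`
#' @param keep_monomorphic keep sample-fixed derived sites (joint-calling
#'   view; default TRUE since fixed differences are the F_ST signal)
#' @param min_split_gens lower bound on the number of post-split
#'   generations (default 0: the sweep duration)
#' @return list with `panel1` (neutral daughter), `panel2` (swept daughter)
#'   and `truth` (as for [simulate_sweep_panel()], plus `split_gens`)
#' @export
simulate_split_pair <- function(params, keep_monomorphic = TRUE,
                                min_split_gens = 0) {
  if (params$s <= 0) stop("simulate_split_pair requires s > 0")
  p <- params
  if (!is.null(p$seed)) set.seed(p$seed)
  raw <- .wf_simulate_pair_cpp(p$n_diploids, p$seq_len, p$mu, p$rho,
                               p$burnin_gens, p$s, p$sweep_pos, p$end_freq,
                               p$sample_hap, 1000L, as.integer(min_split_gens))
  mk <- function(pos, geno, chrom) {
    n <- p$sample_hap
    cnt <- colSums(geno)
    keep <- cnt > 0L & (keep_monomorphic | cnt < n)
    sites <- data.table::data.table(chrom = chrom, pos = pos[keep],
                                    ref = "A", alt = "T",
                                    ancestral_known = TRUE)
    haplotype_panel(geno[, keep, drop = FALSE], sites,
                    sample_ids = sprintf("sim%03d", seq_len(n / 2)))
  }
  truth <- structure(list(sweep_pos = p$sweep_pos, s = p$s,
                          fixation_generation = length(raw$trajectory) - 1L,
                          trajectory = raw$trajectory,
                          attempts = raw$attempts,
                          split_gens = raw$split_gens),
                     class = "sim_truth")
  list(panel1 = mk(raw$positions1, raw$geno1, "sim1"),
       panel2 = mk(raw$positions2, raw$geno2, "sim1"),
       truth = truth)
}

#' Thin a panel to an array-like ascertained SNP set
#'
#' Emulates the SNP-discovery scheme of genotyping arrays: keep only common
#' variants (`maf >= maf_min`), then enforce roughly uniform spacing by
#' keeping the single highest-MAF site within each consecutive
#' `target_spacing`-bp bin. Used to study how ascertainment inflates LD
#' relative to full-sequence panels.
#'
#' @param panel a `haplotype_panel`
#' @param maf_min minimum minor allele frequency retained
#' @param target_spacing bin width in bp; one site kept per bin
#' @return the ascertained `haplotype_panel`
#' @export
ascertain_array_sites <- function(panel, maf_min = 0.2, target_spacing = 1) {
  s <- panel$sites
  cand <- which(s$maf >= maf_min)
  if (!length(cand)) stop("no site survives the MAF filter")
  bin <- floor(s$pos[cand] / target_spacing)
  key <- paste(s$chrom[cand], bin)
  ord <- cand[order(key, -s$maf[cand], s$pos[cand])]
  keep <- sort(ord[!duplicated(paste(s$chrom[ord], floor(s$pos[ord] / target_spacing)))])
  subset_sites(panel, keep)
}

#' Individual allele-dosage matrix
#'
#' @param panel a `haplotype_panel` built from diploids (even `n_hap`)
#' @return integer matrix individuals x sites with entries 0/1/2 counting
#'   allele-1 copies
#' @export
dosage_matrix <- function(panel) {
  h <- panel$haplotypes
  if (nrow(h) %% 2L != 0L) stop("panel must have an even number of haplotypes")
  d <- h[seq(1, nrow(h), by = 2), , drop = FALSE] +
    h[seq(2, nrow(h), by = 2), , drop = FALSE]
  rownames(d) <- panel$sample_ids
  d
}

#' Simulate phenotypes with major QTL plus polygenic background
#'
#' Per individual, `y = sum(effect * dosage) + g + e` where `g` is a
#' polygenic term (a random effect summed over all panel sites, rescaled so
#' that `var(g) = h2_poly / (1 - h2_poly) * noise_var`) and
#' `e ~ N(0, noise_var)`. With `h2_poly = 0` and no QTL, `y` is pure noise.
#'
#' @param panel a `haplotype_panel`
#' @param qtl data.frame/list with columns `site` (site index) and `effect`
#'   (allelic substitution effect), or `NULL` for none
#' @param h2_poly heritability of the non-QTL (residual) part of the
#'   phenotype attributable to the polygenic term, in [0, 1)
#' @param noise_var environmental variance (default 1)
#' @param seed optional RNG seed
#' @return list with `y` (named numeric vector) and `truth` (per-QTL
#'   variance fractions and realized variance components)
#' @export
simulate_phenotypes <- function(panel, qtl = NULL, h2_poly = 0,
                                noise_var = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (h2_poly < 0 || h2_poly >= 1) stop("h2_poly must be in [0, 1)")
  d <- dosage_matrix(panel)
  n_ind <- nrow(d)
  y_qtl <- rep(0, n_ind)
  qtl_df <- NULL
  if (!is.null(qtl) && NROW(qtl) > 0) {
    qtl_df <- as.data.frame(qtl)
    if (any(qtl_df$site < 1 | qtl_df$site > ncol(d)))
      stop("qtl site index out of range")
    for (k in seq_len(nrow(qtl_df)))
      y_qtl <- y_qtl + qtl_df$effect[k] * d[, qtl_df$site[k]]
  }
  g <- rep(0, n_ind)
  if (h2_poly > 0) {
    u <- rnorm(ncol(d), 0, 1)
    z <- scale(d, center = TRUE, scale = FALSE)
    g <- as.numeric(z %*% u)
    target_var <- h2_poly / (1 - h2_poly) * noise_var
    if (sd(g) > 0) g <- g * sqrt(target_var) / sd(g)
  }
  e <- rnorm(n_ind, 0, sqrt(noise_var))
  y <- y_qtl + g + e
  names(y) <- rownames(d)
  truth <- list(
    qtl = qtl_df, h2_poly = h2_poly, noise_var = noise_var,
    var_qtl = var(y_qtl), var_poly = var(g), var_e = var(e), var_y = var(y),
    qtl_fraction = if (is.null(qtl_df)) numeric(0) else
      vapply(seq_len(nrow(qtl_df)), function(k) {
        p <- mean(d[, qtl_df$site[k]]) / 2
        2 * p * (1 - p) * qtl_df$effect[k]^2 / var(y)
      }, numeric(1)))
  list(y = y, truth = truth)
}
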