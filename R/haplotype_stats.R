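# Haplotype-homozygosity statistics: EHH decay curves, integrated haplotype
# homozygosity (iHH), raw and standardized iHS, and the segregating-sites
# analogue nSL.

#' EHH decay curve for one core allele on one side
#'
#' Among the carriers of `allele` at the core site, EHH at a site is the
#' probability that two randomly drawn carriers are identical over every
#' site from the core to that site:
#' `EHH = sum_g C(e_g, 2) / C(n_c, 2)` where `e_g` are the multiplicities of
#' the distinct extended haplotypes. The walk stops when EHH drops below
#' `cutoff`, at the chromosome end, or when the gap to the next site exceeds
#' `max_gap` (stop reason recorded).
#'
#' @param panel a `haplotype_panel`
#' @param core_index site column index of the core SNP
#' @param allele 0 (ancestral) or 1 (derived)
#' @param side `"down"` (increasing position) or `"up"` (decreasing)
#' @param cutoff EHH threshold below which the walk stops (default 0.05)
#' @param max_gap maximum tolerated inter-site gap in bp (default 100 kb)
#' @param .rng internal use: precomputed contiguous column range of the
#'   core site's chromosome, to spare genome scans the per-site lookup
#' @return object of class `ehh_curve`: list with `core_index`, `allele`,
#'   `side`, `offsets` (bp from core, 0 first, negative upstream), `values`
#'   (EHH, starting at 1) and `stop_reason` (`"cutoff"`, `"edge"` or `"gap"`)
#' @export
ehh_curve <- function(panel, core_index, allele, side = c("down", "up"),
                      cutoff = 0.05, max_gap = 1e5, .rng = NULL) {
  side <- match.arg(side)
  h <- panel$haplotypes
  s <- panel$sites
  carriers <- which(!is.na(h[, core_index]) & h[, core_index] == allele)
  nc <- length(carriers)
  if (nc < 2) stop("fewer than 2 carriers of allele ", allele, " at core site")
  # sites are sorted by (chrom, pos), so a chromosome is a contiguous range;
  # genome scans pass the range in to avoid recomputing it per walk
  rng <- if (is.null(.rng)) range(which(s$chrom == s$chrom[core_index])) else .rng
  step <- if (side == "down") 1L else -1L
  w <- .ehh_walk_cpp(h, carriers - 1L, core_index - 1L, step,
                     rng[1] - 1L, rng[2] - 1L, as.numeric(s$pos),
                     cutoff, max_gap)
  structure(list(core_index = core_index, allele = allele, side = side,
                 offsets = w$offsets, values = w$values,
                 stop_reason = w$stop_reason),
            class = "ehh_curve")
}

#' Integrate an EHH curve to the cutoff crossing
#'
#' Trapezoid integration of EHH against physical distance, from the core out
#' to the point where the curve crosses `cutoff` (linearly interpolated
#' between the last value at or above the cutoff and the first value below).
#' A curve truncated by the chromosome edge or a gap before reaching the
#' cutoff is integrated to the truncation point and flagged censored.
#'
#' @param curve an `ehh_curve`
#' @param cutoff EHH threshold (should match the one used to build the curve)
#' @return list with `ihh` (bp x homozygosity) and `censored` flag
#' @export
integrate_ihh <- function(curve, cutoff = 0.05) {
  integrate_xv(abs(curve$offsets), curve$values, cutoff)
}

integrate_xv <- function(x, v, cutoff) {
  k <- which(v < cutoff)[1]
  censored <- FALSE
  if (!is.na(k)) {
    if (k == 1) return(list(ihh = 0, censored = FALSE))
    xs <- x[seq_len(k - 1)]
    vs <- v[seq_len(k - 1)]
    xc <- x[k - 1] + (v[k - 1] - cutoff) / (v[k - 1] - v[k]) * (x[k] - x[k - 1])
    xs <- c(xs, xc)
    vs <- c(vs, cutoff)
  } else {
    xs <- x
    vs <- v
    # reached the edge or a gap while still at/above the cutoff
    censored <- !isTRUE(all.equal(v[length(v)], cutoff))
  }
  ihh <- if (length(xs) < 2) 0 else
    sum(diff(xs) * (head(vs, -1) + tail(vs, -1)) / 2)
  list(ihh = ihh, censored = censored)
}

# iHH for one allele class: both sides summed
ihh_allele <- function(panel, core_index, allele, cutoff, max_gap, .rng = NULL) {
  dn <- integrate_ihh(ehh_curve(panel, core_index, allele, "down", cutoff,
                                max_gap, .rng = .rng), cutoff)
  up <- integrate_ihh(ehh_curve(panel, core_index, allele, "up", cutoff,
                                max_gap, .rng = .rng), cutoff)
  list(ihh = dn$ihh + up$ihh, censored = dn$censored || up$censored)
}

#' Raw (unstandardized) iHS at one core site
#'
#' `iHS_raw = ln(iHH_A / iHH_D)`: the log-ratio of integrated EHH for
#' carriers of the ancestral versus the derived allele. Long derived-allele
#' haplotypes (an ongoing sweep) give strongly negative values. Sides
#' censored by the chromosome edge or a gap are integrated to the truncation
#' point and the score flagged; set `drop_censored = TRUE` to discard such
#' scores instead.
#'
#' @param panel a `haplotype_panel`
#' @param core_index site column index (must be polarized)
#' @param cutoff EHH integration cutoff (default 0.05)
#' @param max_gap maximum inter-site gap in bp (default 100 kb)
#' @param drop_censored return `NA` for scores with a censored side?
#' @param .rng internal use: precomputed contiguous column range of the
#'   core site's chromosome, to spare genome scans the per-site lookup
#' @return list with `ihh_a`, `ihh_d`, `raw`, `censored`; `raw` is `NA` when
#'   either allele class has fewer than 2 carriers or a zero iHH
#' @export
ihs_raw <- function(panel, core_index, cutoff = 0.05, max_gap = 1e5,
                    drop_censored = FALSE, .rng = NULL) {
  if (!panel$sites$ancestral_known[core_index])
    stop("core site ", core_index, " is not polarized")
  h <- panel$haplotypes[, core_index]
  n0 <- sum(h == 0, na.rm = TRUE)
  n1 <- sum(h == 1, na.rm = TRUE)
  if (n0 < 2 || n1 < 2)
    return(list(ihh_a = NA_real_, ihh_d = NA_real_, raw = NA_real_,
                censored = NA))
  a <- ihh_allele(panel, core_index, 0L, cutoff, max_gap, .rng = .rng)
  d <- ihh_allele(panel, core_index, 1L, cutoff, max_gap, .rng = .rng)
  censored <- a$censored || d$censored
  raw <- if (a$ihh <= 0 || d$ihh <= 0 || (censored && drop_censored))
    NA_real_ else log(a$ihh / d$ihh)
  list(ihh_a = a$ihh, ihh_d = d$ihh, raw = raw, censored = censored)
}

#' Raw nSL at one core site
#'
#' Like iHS but with haplotype-sharing length measured in numbers of
#' consecutive segregating sites rather than base pairs: for each pair of
#' haplotypes within an allele class, `L` is the number of sites in the
#' maximal interval around the core (core included) over which the pair is
#' identical; `SL_c` is the mean over pairs and
#' `nSL_raw = ln(SL_A / SL_D)`. No map distance, cutoff or gap rule enters.
#'
#' @param panel a `haplotype_panel`
#' @param core_index site column index (must be polarized)
#' @param .rng internal use: precomputed contiguous column range of the
#'   core site's chromosome, to spare genome scans the per-site lookup
#' @return list with `sl_a`, `sl_d`, `raw` (`NA` if either class has fewer
#'   than 2 carriers)
#' @export
nsl_raw <- function(panel, core_index, .rng = NULL) {
  if (!panel$sites$ancestral_known[core_index])
    stop("core site ", core_index, " is not polarized")
  h <- panel$haplotypes
  s <- panel$sites
  rng <- if (is.null(.rng)) range(which(s$chrom == s$chrom[core_index])) else .rng
  sl_class <- function(allele) {
    carriers <- which(!is.na(h[, core_index]) & h[, core_index] == allele)
    nc <- length(carriers)
    if (nc < 2) return(NA_real_)
    npairs <- nc * (nc - 1) / 2
    walk_sum <- function(step)
      .nsl_side_sum_cpp(h, carriers - 1L, core_index - 1L, step,
                        rng[1] - 1L, rng[2] - 1L)
    1 + (walk_sum(1L) + walk_sum(-1L)) / npairs
  }
  sl_a <- sl_class(0L)
  sl_d <- sl_class(1L)
  raw <- if (is.na(sl_a) || is.na(sl_d)) NA_real_ else log(sl_a / sl_d)
  list(sl_a = sl_a, sl_d = sl_d, raw = raw)
}

#' Genome-wide raw iHS / nSL scan
#'
#' Scores every polarized site with derived-allele frequency inside
#' `[min_daf, 1 - min_daf]` and at least two carriers of each allele.
#'
#' @param panel a `haplotype_panel`
#' @param stat `"ihs"` or `"nsl"`
#' @param min_daf minimum derived allele frequency (default 0.05)
#' @param cutoff,max_gap,drop_censored passed to [ihs_raw()] (ignored for nSL)
#' @return data.table of site scores: site, chrom, pos, daf, raw, censored
#' @export
site_score_scan <- function(panel, stat = c("ihs", "nsl"), min_daf = 0.05,
                            cutoff = 0.05, max_gap = 1e5,
                            drop_censored = FALSE) {
  stat <- match.arg(stat)
  s <- panel$sites
  h <- panel$haplotypes
  n0 <- colSums(h == 0, na.rm = TRUE)
  n1 <- colSums(h == 1, na.rm = TRUE)
  elig <- which(s$ancestral_known & !is.na(s$daf) &
                  s$daf >= min_daf & s$daf <= 1 - min_daf &
                  n0 >= 2 & n1 >= 2)
  res <- data.table::data.table(site = elig, chrom = s$chrom[elig],
                                pos = s$pos[elig], daf = s$daf[elig],
                                raw = NA_real_, censored = NA)
  # hoist everything reused across sites out of the loop: the haplotype
  # matrix, numeric positions, and per-chromosome contiguous column ranges
  chroms <- s$chrom
  posn <- as.numeric(s$pos)
  first <- !duplicated(chroms)
  last <- !duplicated(chroms, fromLast = TRUE)
  lo0 <- setNames(which(first) - 1L, chroms[first])
  hi0 <- setNames(which(last) - 1L, chroms[last])
  raw <- rep(NA_real_, length(elig))
  cens <- rep(NA, length(elig))
  for (k in seq_along(elig)) {
    i <- elig[k]
    l0 <- lo0[[chroms[i]]]
    h0 <- hi0[[chroms[i]]]
    col <- h[, i]
    if (stat == "ihs") {
      one_side <- function(allele, step) {
        carriers0 <- which(!is.na(col) & col == allele) - 1L
        w <- .ehh_walk_cpp(h, carriers0, i - 1L, step, l0, h0, posn,
                           cutoff, max_gap)
        integrate_xv(abs(w$offsets), w$values, cutoff)
      }
      a_dn <- one_side(0L, 1L); a_up <- one_side(0L, -1L)
      d_dn <- one_side(1L, 1L); d_up <- one_side(1L, -1L)
      iha <- a_dn$ihh + a_up$ihh
      ihd <- d_dn$ihh + d_up$ihh
      censored <- a_dn$censored || a_up$censored || d_dn$censored ||
        d_up$censored
      cens[k] <- censored
      if (iha > 0 && ihd > 0 && !(censored && drop_censored))
        raw[k] <- log(iha / ihd)
    } else {
      sl <- vapply(0:1, function(allele) {
        carriers0 <- which(!is.na(col) & col == allele) - 1L
        np <- length(carriers0) * (length(carriers0) - 1) / 2
        1 + (.nsl_side_sum_cpp(h, carriers0, i - 1L, 1L, l0, h0) +
               .nsl_side_sum_cpp(h, carriers0, i - 1L, -1L, l0, h0)) / np
      }, numeric(1))
      raw[k] <- log(sl[1] / sl[2])
      cens[k] <- FALSE
    }
  }
  data.table::set(res, j = "raw", value = raw)
  data.table::set(res, j = "censored", value = cens)
  res[]
}

#' Standardize site scores within derived-allele-frequency bins
#'
#' Raw iHS/nSL depends systematically on the derived allele frequency, so
#' scores are standardized to mean 0, SD 1 (sample SD) within equal-width
#' DAF bins. Bins holding fewer than `min_bin` scored sites are merged with
#' their nearest neighboring occupied bin before standardization.
#'
#' @param scores data.table with columns `raw` and `daf` (as from
#'   [site_score_scan()])
#' @param bin_width DAF bin width (default 0.025, i.e. 40 bins)
#' @param min_bin minimum scored sites per bin (default 20)
#' @return the input with columns `daf_bin` (merged bin id) and `std` added
#' @export
standardize_by_daf <- function(scores, bin_width = 0.025, min_bin = 20) {
  scores <- data.table::as.data.table(scores)
  ok <- !is.na(scores$raw)
  bin <- pmin(floor(scores$daf / bin_width), ceiling(1 / bin_width) - 1) + 1L
  # merge under-filled bins with their nearest occupied neighbor
  grp <- bin
  repeat {
    tab <- table(grp[ok])
    occupied <- as.integer(names(tab))
    small <- occupied[tab < min_bin]
    if (!length(small) || length(occupied) == 1L) break
    b <- small[which.min(tab[as.character(small)])]
    others <- setdiff(occupied, b)
    nb <- others[which.min(abs(others - b))]
    grp[grp == b] <- nb
  }
  scores[, daf_bin := grp]
  scores[, std := NA_real_]
  for (b in unique(grp[ok])) {
    ix <- which(ok & grp == b)
    m <- mean(scores$raw[ix])
    sdev <- sd(scores$raw[ix])
    if (is.na(sdev) || sdev == 0) {
      warning("bin ", b, " has zero score variance; std undefined")
      next
    }
    data.table::set(scores, ix, "std", (scores$raw[ix] - m) / sdev)
  }
  scores[]
}
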