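# Window-level aggregation of site scores, genome-wide empirical p-values,
# top-percentile candidate region calling and the window-coherence variance
# check.

#' Aggregate site scores into a window track
#'
#' Per window, the mean of `transform(score)` over contained sites. For iHS
#' the conventional transform is the absolute value, so that windows
#' enriched for extreme scores of either sign rank high. Windows with fewer
#' than `min_sites` scored sites are reported missing.
#'
#' @param site_scores data.table with columns `chrom`, `pos` and the score
#'   column
#' @param grid a `window_grid`
#' @param value_col name of the score column (default `"std"`)
#' @param transform `"abs"` or `"identity"`
#' @param min_sites minimum scored sites per window (default 10)
#' @param stat_name label stored in the output `stat` column
#' @return data.table score track: chrom, start, end, n_sites, value, stat
#' @export
aggregate_windows <- function(site_scores, grid, value_col = "std",
                              transform = c("abs", "identity"),
                              min_sites = 10, stat_name = value_col) {
  transform <- match.arg(transform)
  ss <- data.table::as.data.table(site_scores)
  if (nrow(ss) == 0) stop("empty site score list")
  v <- ss[[value_col]]
  if (is.null(v)) stop("no column '", value_col, "' in site_scores")
  if (transform == "abs") v <- abs(v)
  idx_list <- window_site_index(ss$pos, ss$chrom, grid)
  res <- data.table::as.data.table(grid[, c("chrom", "start", "end")])
  res[, n_sites := vapply(idx_list, function(ix) sum(!is.na(v[ix])), integer(1))]
  res[, value := vapply(seq_along(idx_list), function(w) {
    x <- v[idx_list[[w]]]
    x <- x[!is.na(x)]
    if (length(x) < min_sites) return(NA_real_)
    mean(x)
  }, numeric(1))]
  res[, stat := stat_name]
  res[]
}

#' Genome-wide empirical p-values for a window track
#'
#' Windows are ranked by value in descending order over the N non-missing
#' windows and `emp_p = rank / N`; tied values share the maximal rank of
#' their group. The best of 100 windows thus gets `emp_p = 0.01`.
#'
#' @param track a window score track with a `value` column (or the column
#'   named by `value_col`)
#' @param value_col column to rank (default `"value"`)
#' @return the track with an `emp_p` column added (`NA` for missing windows)
#' @export
empirical_pvalues <- function(track, value_col = "value") {
  track <- data.table::copy(data.table::as.data.table(track))
  v <- track[[value_col]]
  N <- sum(!is.na(v))
  if (N == 0) stop("no non-missing windows to rank")
  r <- data.table::frank(-v, ties.method = "max", na.last = "keep")
  track[, emp_p := r / N]
  track[]
}

#' Call top-percentile candidate sweep regions
#'
#' Retains the windows whose value falls in the top `1 - percentile` tail of
#' the genome-wide empirical distribution (i.e. `emp_p <= 1 - percentile`)
#' and merges retained windows on the same chromosome separated by at most
#' `merge_gap` intervening grid windows into maximal runs. Intended for
#' non-overlapping grids.
#'
#' @param track a window score track (emp_p computed on the fly if absent)
#' @param percentile retention quantile (default 0.99, the top 1 percent)
#' @param merge_gap maximum number of intervening non-retained windows
#'   bridged when merging (default 0: only adjacent windows merge)
#' @param source label stored in the `source` column (e.g. "iHS", "CLR")
#' @return data.table of class `sweep_region`: chrom, start, end, n_windows,
#'   best_value, best_emp_p, source; disjoint and sorted
#' @export
call_regions <- function(track, percentile = 0.99, merge_gap = 0,
                         source = NA_character_) {
  if (percentile <= 0 || percentile >= 1) stop("percentile must be in (0, 1)")
  track <- data.table::copy(data.table::as.data.table(track))
  if (is.null(track$emp_p)) track <- empirical_pvalues(track)
  track[, .win_idx := seq_len(.N)]
  # tolerance keeps boundary windows: 1 - 0.8 is 0.1999... in floating point
  keep <- track[!is.na(emp_p) & emp_p <= (1 - percentile) + 1e-9]
  if (nrow(keep) == 0)
    return(data.table::data.table(chrom = character(), start = numeric(),
                                  end = numeric(), n_windows = integer(),
                                  best_value = numeric(), best_emp_p = numeric(),
                                  source = character()))
  data.table::setorder(keep, chrom, start)
  keep[, run := cumsum(c(1, diff(.win_idx) > merge_gap + 1)) , by = chrom]
  regions <- keep[, .(start = min(start), end = max(end), n_windows = .N,
                      best_value = max(value), best_emp_p = min(emp_p)),
                  by = .(chrom, run)]
  regions[, run := NULL]
  regions[, source := source]
  data.table::setorder(regions, chrom, start)
  regions[]
}

#' Merge candidate regions from several statistics into union regions
#'
#' Overlapping spans (half-open coordinates) from any source are merged into
#' single regions; disjoint regions are kept as-is.
#'
#' @param ... `sweep_region` tables (e.g. from iHS and CLR scans)
#' @return merged data.table with chrom, start, end, n_sources, sources
#' @export
union_regions <- function(...) {
  all <- data.table::rbindlist(list(...), fill = TRUE)
  if (nrow(all) == 0) return(all)
  data.table::setorder(all, chrom, start)
  all[, grp := {
    g <- integer(.N)
    cur <- 1L
    hi <- end[1]
    g[1] <- 1L
    if (.N > 1) for (i in 2:.N) {
      if (start[i] < hi) { g[i] <- cur; hi <- max(hi, end[i]) }
      else { cur <- cur + 1L; g[i] <- cur; hi <- end[i] }
    }
    g
  }, by = chrom]
  out <- all[, .(start = min(start), end = max(end), n_sources = .N,
                 sources = paste(sort(unique(source)), collapse = "+")),
             by = .(chrom, grp)]
  out[, grp := NULL]
  data.table::setorder(out, chrom, start)
  out[]
}

#' Window-coherence variance check
#'
#' Tests whether SNP scores inside windows are more homogeneous than random
#' site groups of the same sizes: `var_within` is the mean within-window
#' variance of `|score|`; the null distribution is obtained by permuting the
#' scores across sites and recomputing. A small p-value confirms that the
#' windows group SNPs with similar statistic values (spatial coherence).
#'
#' @param site_scores data.table with `chrom`, `pos` and the score column
#' @param grid a `window_grid`
#' @param value_col score column name (default `"std"`)
#' @param n_random_groups number of permutation replicates (default 200)
#' @param seed optional RNG seed
#' @return list with `var_within`, `var_random` (mean of the permutation
#'   distribution), `p_value` and the permutation vector `null_dist`
#' @export
window_variance_check <- function(site_scores, grid, value_col = "std",
                                  n_random_groups = 200, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ss <- data.table::as.data.table(site_scores)
  v <- abs(ss[[value_col]])
  ok <- !is.na(v)
  v <- v[ok]
  idx_list <- window_site_index(ss$pos[ok], ss$chrom[ok], grid)
  sizes <- lengths(idx_list)
  use <- sizes >= 2
  if (!any(use)) stop("no window holds at least 2 scored sites")
  mean_within <- function(x) mean(vapply(idx_list[use], function(ix) var(x[ix]),
                                         numeric(1)))
  var_within <- mean_within(v)
  null_dist <- vapply(seq_len(n_random_groups),
                      function(r) mean_within(sample(v)), numeric(1))
  list(var_within = var_within, var_random = mean(null_dist),
       p_value = (1 + sum(null_dist <= var_within)) / (n_random_groups + 1),
       null_dist = null_dist)
}

#' Read a published window score table (CSV/TSV)
#'
#' Lenient reader for externally published genome-wide window score files
#' (e.g. supplementary per-window |iHS| or CLR scores): the first column is
#' taken as the chromosome, the first numeric column as the window position
#' and the last numeric column as the score.
#'
#' @param path CSV/TSV file
#' @return data.table with chrom, pos, value
#' @export
read_window_scores <- function(path) {
  dt <- data.table::fread(path)
  if (ncol(dt) < 2) stop("expected at least two columns")
  numcols <- names(dt)[vapply(dt, is.numeric, logical(1))]
  if (length(numcols) < 2) stop("expected a position and a score column")
  data.table::data.table(chrom = as.character(dt[[1]]),
                         pos = dt[[numcols[1]]],
                         value = dt[[numcols[length(numcols)]]])
}
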