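test_that("haplotype r2: worked tables, symmetry, label invariance", {
  # {AB, AB, ab, ab}: perfect LD
  p1 <- make_panel(cbind(c(1L, 1L, 0L, 0L), c(1L, 1L, 0L, 0L)))
  expect_equal(haplotype_r2(p1, 1, 2), 1)
  # {AB, Ab, aB, ab}: D = 0
  p2 <- make_panel(cbind(c(1L, 1L, 0L, 0L), c(1L, 0L, 1L, 0L)))
  expect_equal(haplotype_r2(p2, 1, 2), 0)
  # {AB, Ab, aB, AB}: r2 = 1/9
  p3 <- make_panel(cbind(c(1L, 1L, 0L, 1L), c(1L, 0L, 1L, 1L)))
  expect_equal(haplotype_r2(p3, 1, 2), 1 / 9)
  expect_equal(haplotype_r2(p3, 1, 2), oracle_r2(c(1, 1, 0, 1), c(1, 0, 1, 1)))
  # symmetry and allele-label invariance
  expect_equal(haplotype_r2(p3, 2, 1), haplotype_r2(p3, 1, 2))
  p3f <- p3
  p3f$haplotypes[, 1] <- 1L - p3f$haplotypes[, 1]
  expect_equal(haplotype_r2(p3f, 1, 2), haplotype_r2(p3, 1, 2))
  # monomorphic site: undefined
  p4 <- make_panel(cbind(c(1L, 1L, 1L, 1L), c(1L, 0L, 1L, 1L)))
  expect_true(is.na(haplotype_r2(p4, 1, 2)))
  # random panels against the contingency-table oracle
  set.seed(41)
  for (r in 1:10) {
    m <- matrix(rbinom(40, 1, 0.5), 20, 2)
    if (any(colMeans(m) %in% c(0, 1))) next
    pp <- make_panel(m)
    expect_equal(haplotype_r2(pp, 1, 2), oracle_r2(m[, 1], m[, 2]))
  }
})

test_that("LD decay profile: determinism, perfect-LD bin, decay shape", {
  panel <- neutral_reps()[[8]]
  c1 <- ld_decay_profile(panel, n_snps_sample = 300, seed = 7)
  c2 <- ld_decay_profile(panel, n_snps_sample = 300, seed = 7)
  expect_identical(c1$mean_r2, c2$mean_r2)
  expect_true(all(c1$mean_r2 >= 0 & c1$mean_r2 <= 1, na.rm = TRUE))

  # constructed perfect LD: every pair r2 = 1
  mat <- rbind(matrix(1L, 4, 10), matrix(0L, 4, 10))
  pp <- make_panel(mat, pos = seq(1000, 10000, by = 1000))
  cp <- ld_decay_profile(pp, breaks = c(0, 5000, 10000), max_dist = 10000,
                         seed = 1)
  expect_equal(cp$mean_r2[cp$n_pairs > 0], c(1, 1))
  expect_equal(cp$sd_r2[cp$n_pairs > 0], c(0, 0))

  # recombining neutral panels: near LD exceeds far LD
  near_far <- vapply(neutral_reps()[1:10], function(p) {
    cv <- ld_decay_profile(p, n_snps_sample = 250,
                           breaks = c(0, 2e4, 8e4, 1e5), max_dist = 1e5,
                           seed = 3)
    c(cv$mean_r2[1], cv$mean_r2[3])
  }, numeric(2))
  expect_true(all(near_far[1, ] > near_far[2, ]))
})

test_that("ascertained panels show inflated LD at 10-20 kb", {
  res <- vapply(neutral_reps()[1:10], function(p) {
    asc <- ascertain_array_sites(p, maf_min = 0.2, target_spacing = 1)
    br <- c(1e4, 2e4)
    full <- ld_decay_profile(p, n_snps_sample = 400, breaks = br,
                             max_dist = 2e4, seed = 11)
    arr <- ld_decay_profile(asc, n_snps_sample = 400, breaks = br,
                            max_dist = 2e4, seed = 11)
    arr$mean_r2[1] > full$mean_r2[1]
  }, logical(1))
  expect_gte(mean(res), 0.9)
})

test_that("bin-wise LD comparison: null and constructed differences", {
  panel <- neutral_reps()[[9]]
  a <- ld_decay_profile(panel, n_snps_sample = 300, seed = 5)
  same <- compare_ld_bins(a, a)
  expect_true(all(same$p_value > 0.99))
  # shifted samples: strongly significant in every populated bin
  b <- data.table::copy(a)
  pv <- lapply(attr(a, "pair_values"), function(v) pmin(v + 0.2, 1))
  data.table::setattr(b, "pair_values", pv)
  shift <- compare_ld_bins(a, b)
  big <- shift[!is.na(p_value) & abs(mean_a - mean_b) > 0.05]
  expect_true(all(big$p_value < 0.001))
})

test_that("F_ST: worked values, sliding windows, cutoff", {
  cts <- function(p, n) data.frame(chrom = "c1", pos = c(100L, 200L, 300L),
                                   n = n, count = round(p * n))
  # fixed difference: F_ST = 1
  one <- fst_scan(cts(c(1, 1, 1), 10), cts(c(0, 0, 0), 10), sliding_k = 1)
  expect_equal(one$snp$fst, c(1, 1, 1))
  # equal intermediate frequencies, n1 = n2 = 10: F_ST = -1/9
  eq <- fst_scan(cts(c(0.5, 0.5, 0.5), 10), cts(c(0.5, 0.5, 0.5), 10),
                 sliding_k = 1)
  expect_equal(eq$snp$fst, rep(-1 / 9, 3))
  expect_equal(fst_scan(cts(c(0.5, 0.5, 0.5), 10), cts(c(0.5, 0.5, 0.5), 10),
                        sliding_k = 1, truncate = TRUE)$snp$fst, rep(0, 3))
  # a population against itself is never positive
  p <- neutral_reps()[[10]]
  self <- fst_scan(p, p, sliding_k = 1)
  expect_true(all(self$snp$fst <= 1e-12))
  # sliding k = 3 over singles {0.1, 0.2, 0.6}: one window, mean 0.3
  snp <- data.table::data.table(chrom = "c1", pos = c(1L, 2L, 3L),
                                n = 10L, count = c(1L, 2L, 6L))
  tr <- fst_scan(cts(c(0.1, 0.2, 0.6), 10), cts(c(0.6, 0.2, 0.1), 10))
  expect_equal(nrow(tr$sliding), 1L)
  expect_equal(tr$sliding$fst_sliding, mean(tr$snp$fst))
  expect_equal(tr$sliding$pos, tr$snp$pos[2])
})

test_that("sliding F_ST localizes a breed-specific sweep after a split", {
  hits <- vapply(1:10, function(r) {
    sp <- simulate_split_pair(sim_params(n_diploids = 100, sample_hap = 60,
                                         seq_len = 100000, s = 0.15,
                                         sweep_pos = 50000, seed = 1800 + r))
    tr <- fst_scan(sp$panel1, sp$panel2, sliding_k = 3)
    top <- tr$sliding[which.max(fst_sliding)]
    abs(top$pos - 50000) <= 25000
  }, logical(1))
  expect_gte(mean(hits), 0.7)
})

test_that("split-pair simulator: shared ancestry and determinism", {
  p <- sim_params(n_diploids = 60, sample_hap = 30, seq_len = 50000,
                  s = 0.2, seed = 77)
  a <- simulate_split_pair(p)
  b <- simulate_split_pair(p)
  expect_identical(a$panel1$haplotypes, b$panel1$haplotypes)
  expect_identical(a$panel2$sites$pos, b$panel2$sites$pos)
  # recent split: the daughters still share a sizable set of sites (the
  # split lasts ~ the sweep duration, here roughly half the 2N coalescent
  # timescale, so a minority-but-substantial overlap is expected)
  shared <- length(intersect(a$panel1$sites$pos, a$panel2$sites$pos))
  expect_gt(shared, 10)
  expect_gt(shared / n_sites(a$panel1), 0.1)
  # the beneficial allele is present in daughter 2 only
  expect_true(p$sweep_pos %in% a$panel2$sites$pos)
  expect_false(p$sweep_pos %in% a$panel1$sites$pos)
})
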