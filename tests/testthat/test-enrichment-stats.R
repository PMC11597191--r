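test_that("cross-product odds ratios reproduce direct arithmetic", {
  expect_equal(round(odds_ratio_manual(106, 578, 100, 869)$odds_ratio, 2), 1.59)
  expect_equal(round(odds_ratio_manual(67, 93, 62, 533)$odds_ratio, 2), 6.19)
  expect_identical(odds_ratio_manual(1, 1, 1, 1)$odds_ratio, 1)
  # adjustment applied to all cells when forced
  r <- odds_ratio_manual(0, 10, 5, 5, adjust = "always")
  expect_equal(r$odds_ratio, (0.1 * 5.1) / (10.1 * 5.1))
  # default policy adjusts only when a cell is zero
  expect_equal(odds_ratio_manual(0, 10, 5, 5)$odds_ratio,
               (0.1 * 5.1) / (10.1 * 5.1))
  expect_equal(odds_ratio_manual(2, 10, 5, 5)$odds_ratio, 0.2)
  # all-zero table is undefined
  expect_true(odds_ratio_manual(0, 0, 0, 0)$undefined)
})

test_that("odds-ratio reciprocity and Wald interval ordering", {
  set.seed(8)
  for (t in 1:30) {
    cells <- sample(1:200, 4, replace = TRUE)
    r1 <- odds_ratio_manual(cells[1], cells[2], cells[3], cells[4])
    r2 <- odds_ratio_manual(cells[3], cells[4], cells[1], cells[2])
    expect_equal(r1$odds_ratio * r2$odds_ratio, 1)
    expect_lte(r1$ci_low, r1$odds_ratio)
    expect_gte(r1$ci_high, r1$odds_ratio)
  }
})

test_that("GLM estimator agrees with the cross-product on 2x2 tables", {
  set.seed(9)
  for (t in 1:20) {
    cells <- sample(1:500, 4, replace = TRUE)
    man <- odds_ratio_manual(cells[1], cells[2], cells[3], cells[4])
    glm_ <- odds_ratio_glm(cells[1], cells[2], cells[3], cells[4])
    expect_equal(glm_$odds_ratio, man$odds_ratio, tolerance = 1e-6)
  }
  expect_equal(round(odds_ratio_glm(67, 93, 62, 533)$odds_ratio, 2), 6.19)
  # a single stratum equals the unstratified fit
  s1 <- odds_ratio_glm(10, 20, 5, 40, strata = "IGK")
  s0 <- odds_ratio_glm(10, 20, 5, 40)
  expect_equal(s1$odds_ratio, s0$odds_ratio)
  # separation falls back to the adjusted manual estimator
  expect_warning(fb <- odds_ratio_glm(0, 10, 5, 5), "zero cell")
  expect_identical(fb$method, "manual_adjusted")
})

test_that("stratified GLM pools strata rather than collapsing them", {
  r <- odds_ratio_glm(c(30, 5), c(70, 95), c(20, 2), c(80, 98),
                      strata = c("IGK", "IGL"))
  expect_identical(r$method, "glm")
  expect_true(r$odds_ratio > 1)
})

test_that("BH adjustment matches the hand step-up computation", {
  expect_identical(bh_adjust(0.01), 0.01)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.074, 0.205)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p), all(adj <= 1))
  expect_false(is.unsorted(adj))
  # permutation invariance
  perm <- sample(seq_along(p))
  expect_equal(bh_adjust(p[perm])[order(perm)], adj)
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("Wilcoxon rank-sum: exact tail enumerated by hand", {
  out <- wilcoxon_rank_sum(c(1, 2, 3), c(10, 11, 12))
  expect_true(out$exact)
  # enumeration oracle over all C(6,3) = 20 rank assignments
  ranks <- 1:6
  sums <- apply(utils::combn(6, 3), 2, function(ix) sum(ranks[ix]))
  obs <- sum(rank(c(1, 2, 3, 10, 11, 12))[1:3])
  p_exact <- mean(sums <= obs) + mean(sums >= sum(range(sums)) - obs)
  expect_equal(out$p_value, p_exact)
  expect_equal(out$p_value, 0.1)
  # identical multisets give p ~ 1
  same <- wilcoxon_rank_sum(c(1, 2, 2, 3), c(1, 2, 2, 3))
  expect_gt(same$p_value, 0.9)
  expect_error(wilcoxon_rank_sum(numeric(0), 1), "non-empty")
})

test_that("positional Pearson correlation has its closed-form extremes", {
  a <- c(3, 1, 4, 1, 5)
  expect_equal(pearson_position_correlation(a, a)$r, 1)
  one_hot_a <- c(1, rep(0, 124))
  one_hot_b <- c(0, 1, rep(0, 123))
  r <- pearson_position_correlation(one_hot_a, one_hot_b)$r
  expect_equal(r, -1 / 124)
  expect_warning(z <- pearson_position_correlation(rep(0, 125), one_hot_a),
                 "zero-variance")
  expect_true(z$undefined)
  expect_error(pearson_position_correlation(1:3, 1:4), "equal length")
})

test_that("logo matrices are per-offset frequencies excluding padding", {
  h <- detect_sequons("NGSAAAAANGT")
  lm <- logo_matrix(h$context)
  expect_equal(unname(lm["N", "0"]), 1)
  sums <- colSums(lm)
  expect_equal(unname(sums), rep(1, ncol(lm)), tolerance = 1e-9)
  # single context: every observed offset has one residue at frequency 1
  lm1 <- logo_matrix("----ANGS---")
  expect_true(all(lm1 %in% c(0, 1)))
  # +2 threonine frequency reproduces plus2_threonine_fraction
  p2 <- plus2_threonine_fraction(h)
  expect_equal(unname(lm["T", "2"]), p2$fraction)
  expect_error(logo_matrix("AGS"), "centred on N")
})
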