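test_that("paired t-tests report the Bonferroni-adjusted level", {
  set.seed(51)
  m <- cbind(csart = rnorm(10, 8.5), utr = rnorm(10, 6.4), fbp = rnorm(10, 5.6))
  pt <- paired_ttests_bonferroni(m)
  expect_equal(pt$adjusted_alpha, 0.05 / 3)
  expect_equal(round(pt$adjusted_alpha, 3), 0.017)
  expect_equal(nrow(pt$tests), 3)
  # closed-form oracle for each pair
  for (j in 1:3) {
    pair <- utils::combn(3, 2)[, j]
    d <- m[, pair[1]] - m[, pair[2]]
    tstat <- mean(d) / (sd(d) / sqrt(length(d)))
    p <- 2 * stats::pt(-abs(tstat), df = length(d) - 1)
    expect_equal(pt$tests$t[j], tstat, tolerance = 1e-12)
    expect_equal(pt$tests$p_value[j], p, tolerance = 1e-12)
  }
  expect_error(paired_ttests_bonferroni(cbind(1:5, 1:5, 2:6)),
               class = "pbct_degenerate_test")
})

test_that("ICC(A,1) matches an ANOVA mean-squares oracle", {
  # perfect agreement: identical readers, varying cases
  m1 <- matrix(rep(c(1, 2, 3, 4), 3), ncol = 3)
  expect_equal(icc_two_way(m1)$icc, 1)
  # 4 x 3 fixture against an aov()-based computation
  m <- matrix(c(9, 6, 8, 7, 2, 1, 4, 1, 5, 3, 6, 2), nrow = 4)
  d <- data.frame(y = as.numeric(m),
                  case = factor(rep(1:4, 3)),
                  reader = factor(rep(1:3, each = 4)))
  ms <- summary(stats::aov(y ~ case + reader, data = d))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  n <- 4; k <- 3
  oracle <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  expect_equal(icc_two_way(m)$icc, oracle, tolerance = 1e-10)
  expect_error(icc_two_way(matrix(2, 4, 3)), "undefined")
  expect_error(icc_two_way(matrix(c(1, NA, 2, 3), 2)), "missing|complete")
})

test_that("reliability bands cover the ICC range with upward boundaries", {
  expect_equal(pbct:::.icc_bands(0.62), "good")
  expect_equal(pbct:::.icc_bands(0.39), "poor")
  expect_equal(pbct:::.icc_bands(0.4), "fair")
  expect_equal(pbct:::.icc_bands(0.6), "good")
  expect_equal(pbct:::.icc_bands(0.75), "excellent")
  expect_equal(pbct:::.icc_bands(-0.2), "poor")
  expect_equal(pbct:::.icc_bands(1), "excellent")
  # no gaps across the whole range
  for (x in seq(-1, 1, by = 0.01))
    expect_true(pbct:::.icc_bands(x) %in% c("poor", "fair", "good", "excellent"))
})

test_that("Cronbach's alpha matches the variance formula and its limits", {
  # identical reader columns (nonconstant across cases) -> alpha 1
  m1 <- matrix(rep(c(1, 3, 2, 5), 4), ncol = 4)
  expect_equal(cronbach_alpha(m1)$alpha, 1)
  # independent random columns: alpha near 0
  set.seed(52)
  m0 <- matrix(rnorm(200 * 3), 200, 3)
  expect_lt(abs(cronbach_alpha(m0)$alpha), 0.15)
  # 5 x 3 fixture vs long-hand computation
  m <- matrix(c(1, 2, 0, -1, 2, 2, 1, 0, -2, 1, 0, 2, 1, -1, 2), nrow = 5)
  k <- 3
  oracle <- k / (k - 1) * (1 - sum(apply(m, 2, var)) / var(rowSums(m)))
  ca <- cronbach_alpha(m)
  expect_equal(ca$alpha, oracle, tolerance = 1e-12)
  expect_length(ca$leave_one_out, 3)
  # leave-one-out recomputes alpha on the reduced matrix
  expect_equal(ca$leave_one_out[[1]],
               cronbach_alpha(m[, -1])$alpha, tolerance = 1e-12)
  expect_error(cronbach_alpha(matrix(1, 4, 3)), "variance")
})

test_that("VGC AUC anchors, antisymmetry and bootstrap determinism hold", {
  expect_equal(vgc_auc(rep(0, 12), n_boot = 200, seed = 1)$auc, 0.5)
  expect_equal(vgc_auc(rep(2, 12), n_boot = 200, seed = 1)$auc, 1.0)
  suppressMessages(
    expect_equal(vgc_auc(c(1, 1, 0, -1), n_boot = 200, seed = 1)$auc, 0.625))
  # antisymmetry: negating ratings maps AUC -> 1 - AUC
  set.seed(53)
  r <- sample(-2:2, 40, TRUE)
  rid <- rep(1:4, each = 10); cid <- rep(1:10, 4)
  a1 <- vgc_auc(r, rid, cid, n_boot = 200, seed = 2)
  a2 <- vgc_auc(-r, rid, cid, n_boot = 200, seed = 2)
  expect_equal(a1$auc, 1 - a2$auc)
  # determinism of the bootstrap interval
  b1 <- vgc_auc(r, rid, cid, n_boot = 500, seed = 9)
  b2 <- vgc_auc(r, rid, cid, n_boot = 500, seed = 9)
  expect_identical(b1$ci_lo, b2$ci_lo)
  expect_identical(b1$ci_hi, b2$ci_hi)
  expect_true(b1$ci_lo <= b1$auc && b1$auc <= b1$ci_hi)
  expect_warning(vgc_auc(r, rid, cid, n_boot = 50, seed = 1), "100")
  expect_message(vgc_auc(c(1, -1, 0, 2), n_boot = 200, seed = 1), "single")
  expect_error(vgc_auc(c(0, 3)), "scale")
})

test_that("the VGC point estimate equals the trapezoid-over-CDFs area", {
  # independent oracle: build the VGC curve from the cumulative distributions
  # of test scores (shifted by ratings) against a degenerate reference at 0
  trapezoid_auc <- function(r) {
    # empirical step CDFs of the test scores and of the degenerate reference
    # (all zeros) on the common ordinal axis, connected by straight segments
    # through ties; the trapezoidal area is int F_test dF_ref, i.e.
    # P(test < ref) + 0.5 P(test = ref) = 1 - AUC_VGC
    vals <- sort(unique(c(r, 0)))
    xs <- c(0, vapply(vals, function(v) mean(0 <= v), numeric(1)))
    ys <- c(0, vapply(vals, function(v) mean(r <= v), numeric(1)))
    sum(diff(xs) * (utils::head(ys, -1) + utils::tail(ys, -1)) / 2)
  }
  set.seed(54)
  for (i in 1:5) {
    r <- sample(-2:2, 30, TRUE)
    a <- suppressMessages(vgc_auc(r, n_boot = 100, seed = 1)$auc)
    expect_equal(a, 1 - trapezoid_auc(r), tolerance = 1e-12)
  }
})

test_that("synthetic rating tables respect the scale and respond to shifts", {
  rt <- simulate_rating_table(n_cases = 12, n_readers = 5, pair_shift = 1,
                              seed = 3)
  expect_true(all(rt$score %in% -2:2))
  expect_equal(nrow(rt), 60)
  a_pos <- vgc_auc(rt$score, rt$reader_id, rt$case_id, n_boot = 200, seed = 1)
  rt0 <- simulate_rating_table(n_cases = 12, n_readers = 5, pair_shift = -1,
                               seed = 3)
  a_neg <- vgc_auc(rt0$score, rt0$reader_id, rt0$case_id, n_boot = 200, seed = 1)
  expect_gt(a_pos$auc, 0.5)
  expect_lt(a_neg$auc, 0.5)
})
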