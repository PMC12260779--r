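test_that("the default parameter grid enumerates 1800 exact combinations", {
  g <- csart_parameter_grid()
  expect_equal(nrow(g), 1800)
  expect_equal(nrow(unique(g)), 1800)
  # the two optima reported for the study's projection counts are present
  expect_true(any(g$sigma_xyz == 10 & g$sigma_v == 0.20 & g$w == 0.04))
  expect_true(any(g$sigma_xyz == 10 & g$sigma_v == 0.07 & g$w == 0.06))
  # integer-indexed steps: exact values, no accumulation error
  expect_true(all(sort(unique(g$sigma_v)) == (1:20) / 100))
  expect_true(all(sort(unique(g$w)) == seq(4, 20, by = 2) / 100))
  # documented ordering: sigma outer, sigma_v middle, w inner
  expect_equal(g$sigma_xyz[1:9], rep(1, 9))
  expect_equal(g$w[1:9], seq(0.04, 0.20, by = 0.02))
  # order-stable across calls
  expect_identical(g, csart_parameter_grid())
})

test_that("the NPS gate keeps records strictly within the relative threshold", {
  rec <- data.frame(id = 1:4,
                    nps_peak_freq = c(1, 1.2, 1.15, 0.9))
  kept <- nps_gate(rec, fbp_peak_freq = 1, threshold = 0.15)
  expect_equal(kept$id, c(1, 4))          # 1.2 out; 1.15 out (strict <)
  # monotone: larger threshold never drops a kept record
  kept2 <- nps_gate(rec, 1, threshold = 0.25)
  expect_true(all(kept$id %in% kept2$id))
  expect_error(nps_gate(data.frame(nps_peak_freq = 2), 1, 0.15),
               class = "pbct_empty_gate")
  expect_error(nps_gate(rec, 0), "positive")
})

test_that("best-record selection is Pareto-then-scalarize with documented ties", {
  # a single dominator is returned directly
  rec <- data.frame(sigma_xyz = 1:3, sigma_v = 0.1, w = c(0.04, 0.06, 0.08),
                    snr = c(10, 8, 9), res = c(1.5, 2, 1.8))
  expect_equal(select_best(rec)$sigma_xyz, 1)
  # two-record front: scalarization by snr/res^1.5 picks (8, 1)
  rec2 <- data.frame(sigma_xyz = 1:2, sigma_v = 0.1, w = 0.04,
                     snr = c(10, 8), res = c(2, 1))
  expect_equal(select_best(rec2)$snr, 8)
  expect_error(select_best(rec2[0, ]), "empty")
})

test_that("selection matches a brute-force front-then-scalarize oracle", {
  set.seed(17)
  rec <- data.frame(sigma_xyz = sample(1:10, 50, TRUE),
                    sigma_v = sample((1:20) / 100, 50, TRUE),
                    w = sample(seq(0.04, 0.2, 0.02), 50, TRUE),
                    snr = runif(50, 2, 12), res = runif(50, 1, 4))
  oracle <- function(d) {
    keep <- rep(TRUE, nrow(d))
    for (i in seq_len(nrow(d))) for (j in seq_len(nrow(d))) {
      if (i != j && d$snr[j] >= d$snr[i] && d$res[j] <= d$res[i] &&
          (d$snr[j] > d$snr[i] || d$res[j] < d$res[i])) keep[i] <- FALSE
    }
    f <- d[keep, ]
    sc <- f$snr / f$res^1.5
    cand <- f[sc == max(sc), ]
    cand <- cand[cand$w == min(cand$w), ]
    cand <- cand[cand$sigma_v == min(cand$sigma_v), ]
    cand[1, ]
  }
  expect_equal(select_best(rec), oracle(rec), ignore_attr = TRUE)
})

test_that("a reduced tuning run beats FBP's SNR end to end", {
  ph <- desk_phantom()
  g <- scan_geometry(angles_deg = seq(0, 179, by = 1))   # 180 angles
  ps <- simulate_projections(ph, g, 300, "tie", seed = 3)
  sn <- retrieve_projections(ps, gamma = 275)
  rois <- desk_rois()
  grid <- csart_parameter_grid(c(2, 6, 10), c(0.05, 0.20), c(0.04, 0.12))
  tn <- tune_csart(sn, rois$flat, grid, order_seed = 4)
  expect_equal(nrow(tn$records), 12)
  expect_false(is.null(tn$best))
  expect_gte(tn$best$snr, tn$fbp$snr)
  expect_true(all(c("nps_peak_freq", "snr", "res", "passed_gate") %in%
                    names(tn$records)))
})
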