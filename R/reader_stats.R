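#' Paired t-tests across three algorithms with Bonferroni correction
#'
#' Classical paired-sample t-tests for every pair of the three algorithm
#' columns (cSART vs UTR-style gridding, cSART vs FBP, gridding vs FBP in the
#' usual layout), two-sided, with the significance level divided by the
#' number of comparisons: `alpha / m = 0.05 / 3 ~ 0.017`.
#'
#' @param metric_table Numeric matrix or data.frame, one row per sample and
#'   exactly three algorithm columns.
#' @param alpha Family significance level (default 0.05).
#' @param m Number of comparisons (default 3).
#' @return List of class `"paired_tests"`: `tests` data.frame (pair, t, df,
#'   p_value, significant), `adjusted_alpha`.
#' @export
paired_ttests_bonferroni <- function(metric_table, alpha = 0.05, m = 3L) {
  x <- as.matrix(metric_table)
  .stop_if(ncol(x) != 3, "expected exactly three algorithm columns")
  .stop_if(nrow(x) < 3, "need at least 3 paired samples")
  .stop_if(any(!is.finite(x)), "non-finite metric values")
  if (is.null(colnames(x))) colnames(x) <- paste0("algo", 1:3)
  pairs <- utils::combn(3, 2)
  res <- data.frame(pair = character(0), t = numeric(0), df = numeric(0),
                    p_value = numeric(0))
  for (j in seq_len(ncol(pairs))) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    d <- x[, i1] - x[, i2]
    if (var(d) == 0)
      stop(errorCondition(
        sprintf("zero variance of paired differences for %s vs %s",
                colnames(x)[i1], colnames(x)[i2]),
        class = c("pbct_degenerate_test", "error", "condition")))
    tt <- stats::t.test(x[, i1], x[, i2], paired = TRUE)
    res <- rbind(res, data.frame(
      pair = paste(colnames(x)[i1], "vs", colnames(x)[i2]),
      t = unname(tt$statistic), df = unname(tt$parameter),
      p_value = tt$p.value))
  }
  adj <- alpha / m
  res$significant <- res$p_value < adj
  structure(list(tests = res, adjusted_alpha = adj, alpha = alpha, m = m),
            class = "paired_tests")
}

#' @export
print.paired_tests <- function(x, ...) {
  cat(sprintf("paired t-tests, Bonferroni-adjusted alpha = %.4f (%.3g/%d)\n",
              x$adjusted_alpha, x$alpha, x$m))
  print(x$tests, row.names = FALSE)
  invisible(x)
}

.icc_bands <- function(icc) {
  # boundaries assigned upward: 0.6 is "good"
  if (icc < 0.4) "poor" else if (icc < 0.6) "fair"
  else if (icc < 0.75) "good" else "excellent"
}

#' Two-way intraclass correlation for absolute agreement
#'
#' ICC(A,1): two-way model, absolute agreement, single-rater form, from the
#' ANOVA mean squares of a complete cases x readers matrix:
#' `(MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`.
#' Reliability bands: below 0.4 poor, 0.4-0.6 fair, 0.6-0.75 good, above
#' 0.75 excellent (boundaries assigned upward).
#'
#' @param ratings_matrix Complete numeric matrix, rows = cases, columns =
#'   readers; missing cells are rejected.
#' @return List of class `"icc_result"`: `icc`, `band`, mean squares,
#'   `variant = "ICC(A,1)"`.
#' @export
icc_two_way <- function(ratings_matrix) {
  x <- as.matrix(ratings_matrix)
  .stop_if(any(is.na(x)), "missing cells are not supported; supply a complete matrix")
  n <- nrow(x); k <- ncol(x)
  .stop_if(n < 2 || k < 2, "need at least 2 cases and 2 readers")
  grand <- mean(x)
  row_m <- rowMeans(x); col_m <- colMeans(x)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((x - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k * (msc - mse) / n
  .stop_if(denom == 0,
           "degenerate ratings (no variance anywhere): ICC undefined")
  icc <- (msr - mse) / denom
  structure(list(icc = icc, band = .icc_bands(icc),
                 ms = c(rows = msr, cols = msc, error = mse),
                 n_cases = n, n_readers = k, variant = "ICC(A,1)"),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("%s = %.3f (%s reliability; %d cases x %d readers)\n",
              x$variant, x$icc, x$band, x$n_cases, x$n_readers))
  invisible(x)
}

#' Cronbach's alpha with leave-one-out sensitivity
#'
#' `alpha = k/(k-1) * (1 - sum(item variances) / var(total))` treating
#' readers as items, plus the vector of alphas recomputed with each reader
#' excluded (outlier sensitivity analysis).
#'
#' @param ratings_matrix Numeric matrix, rows = cases, columns = readers
#'   (at least 2).
#' @return List of class `"cronbach_result"`: `alpha`, `leave_one_out`
#'   (named by dropped reader).
#' @export
cronbach_alpha <- function(ratings_matrix) {
  x <- as.matrix(ratings_matrix)
  k <- ncol(x)
  .stop_if(k < 2, "need at least 2 readers")
  .stop_if(any(is.na(x)), "missing cells are not supported")
  one <- function(m) {
    kk <- ncol(m)
    tot <- var(rowSums(m))
    .stop_if(tot == 0, "zero total variance: alpha undefined")
    kk / (kk - 1) * (1 - sum(apply(m, 2, var)) / tot)
  }
  loo <- if (k > 2) {
    vapply(seq_len(k), function(j) one(x[, -j, drop = FALSE]), numeric(1))
  } else rep(NA_real_, k)
  names(loo) <- colnames(x) %||% paste0("reader", seq_len(k))
  structure(list(alpha = one(x), leave_one_out = loo, n_readers = k),
            class = "cronbach_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Visual grading characteristics AUC for relative ratings
#'
#' Relative five-point ratings (-2..+2 against a reference shown
#' simultaneously) have a degenerate reference distribution, for which the
#' trapezoidal area under the VGC curve (cumulative test distribution vs
#' cumulative reference distribution) reduces to the rank estimator
#' `AUC = (#\{r > 0\} + 0.5 #\{r = 0\}) / N`: 0.5 denotes equivalence, above
#' 0.5 superiority of the test images. Confidence intervals and the p-value
#' against 0.5 come from a two-level nonparametric bootstrap: readers are
#' resampled with replacement (random-reader generalization), then each
#' sampled reader's cases are resampled with replacement; percentile CI.
#'
#' @param ratings Vector of scores in \{-2, -1, 0, 1, 2\}.
#' @param reader_ids,case_ids Vectors tagging each rating (recycled against
#'   `ratings`).
#' @param n_boot Bootstrap resamples (default 2000; below 100 warns).
#' @param conf_level CI level (default 0.95).
#' @param seed RNG seed for the bootstrap.
#' @return An object of class `"vgc_result"`: `auc`, `ci_lo`, `ci_hi`,
#'   `p_value`, `n_boot`, `boot` (the resampled AUCs).
#' @export
vgc_auc <- function(ratings, reader_ids = NULL, case_ids = NULL,
                    n_boot = 2000L, conf_level = 0.95, seed = 1L) {
  .stop_if(!all(ratings %in% -2:2), "ratings must lie on the -2..+2 scale")
  n <- length(ratings)
  .stop_if(n < 1, "no ratings")
  if (is.null(reader_ids)) reader_ids <- rep(1L, n)
  if (is.null(case_ids)) case_ids <- seq_len(n)
  .stop_if(length(reader_ids) != n || length(case_ids) != n,
           "reader/case ids must match the ratings length")
  if (n_boot < 100) warning("fewer than 100 bootstrap resamples")
  point <- .vgc_point(ratings)
  readers <- unique(reader_ids)
  by_reader <- split(ratings, factor(reader_ids, levels = readers))
  single_reader <- length(readers) == 1
  if (single_reader)
    message("single reader: reader-level bootstrap disabled, resampling cases only")
  set.seed(seed)
  boot <- vapply(seq_len(n_boot), function(b) {
    rs <- if (single_reader) 1L else
      sample.int(length(readers), replace = TRUE)
    samp <- unlist(lapply(rs, function(r) {
      v <- by_reader[[r]]
      v[sample.int(length(v), replace = TRUE)]
    }), use.names = FALSE)
    .vgc_point(samp)
  }, numeric(1))
  qs <- quantile(boot, c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2),
                 names = FALSE)
  p <- 2 * min(mean(boot <= 0.5), mean(boot >= 0.5))
  structure(list(auc = point, ci_lo = qs[1], ci_hi = qs[2],
                 p_value = min(p, 1), n_boot = n_boot,
                 conf_level = conf_level, boot = boot,
                 n_readers = length(readers)),
            class = "vgc_result")
}

.vgc_point <- function(r) (sum(r > 0) + 0.5 * sum(r == 0)) / length(r)

#' @export
print.vgc_result <- function(x, ...) {
  cat(sprintf("AUC_VGC = %.3f (%d%% CI %.3f-%.3f, p = %.3g vs 0.5; %d resamples, %d readers)\n",
              x$auc, round(100 * x$conf_level), x$ci_lo, x$ci_hi, x$p_value,
              x$n_boot, x$n_readers))
  invisible(x)
}

#' Simulate a synthetic reader-study rating table
#'
#' Generates ordinal -2..+2 ratings for a multi-reader multi-case comparison
#' from a simple latent model: latent score = pair effect + reader bias +
#' case effect + noise, rounded and clamped to the scale. Synthetic data for
#' exercising the reader statistics; it does not model real observer
#' behavior.
#'
#' @param n_cases,n_readers Study size.
#' @param pair_shift Latent mean difference of the test images against the
#'   reference (0 = equivalence).
#' @param reader_sd,case_sd,noise_sd Standard deviations of the latent
#'   components.
#' @param seed RNG seed.
#' @return Data.frame with columns `case_id`, `reader_id`, `score`.
#' @export
simulate_rating_table <- function(n_cases = 10L, n_readers = 7L,
                                  pair_shift = 0, reader_sd = 0.3,
                                  case_sd = 0.5, noise_sd = 0.6, seed = 1L) {
  set.seed(seed)
  rb <- rnorm(n_readers, 0, reader_sd)
  ce <- rnorm(n_cases, 0, case_sd)
  grid <- expand.grid(case_id = seq_len(n_cases), reader_id = seq_len(n_readers))
  latent <- pair_shift + rb[grid$reader_id] + ce[grid$case_id] +
    rnorm(nrow(grid), 0, noise_sd)
  grid$score <- pmin(pmax(round(latent), -2L), 2L)
  grid
}
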