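test_that("variance filter applies the strictly-above-mean rule", {
  # columns with variances exactly {1, 1, 10}; mean 4 -> only the third kept
  mat <- cbind(c(1, 2, 3), c(4, 5, 6), sqrt(10) * c(1, 2, 3))
  fm <- make_fm(mat)
  vf <- variance_filter(fm)
  expect_equal(unname(vf$variances), c(1, 1, 10))
  expect_equal(vf$threshold, 4)
  expect_equal(vf$kept_idx, 3L)

  # equal variances: nothing is strictly above the mean
  eq <- make_fm(cbind(c(1, 2, 3), c(2, 3, 4)))
  expect_length(variance_filter(eq)$kept_idx, 0L)

  # constant features are never kept
  cst <- make_fm(cbind(c(5, 5, 5), c(1, 9, 2)))
  expect_false(1L %in% variance_filter(cst)$kept_idx)

  expect_error(variance_filter(make_fm(matrix(1, 1, 3),
                                       sheet = flat_sheet("s1"))),
               "2 samples")
})

test_that("adding inert features lowers the threshold, growing the kept set", {
  # near-zero-variance features pull the mean variance down, so every
  # previously kept feature stays kept (the kept set is monotone under
  # dilution with inert features)
  set.seed(3)
  active <- matrix(rnorm(40, sd = 4), 8, 5) + 20
  runs <- lapply(c(0, 5, 20, 50), function(n_inert) {
    inert <- matrix(rnorm(8 * n_inert, sd = 0.05), 8, n_inert) + 20
    variance_filter(make_fm(cbind(active, inert),
                            sheet = flat_sheet(paste0("s", 1:8))))
  })
  thresholds <- vapply(runs, `[[`, numeric(1), "threshold")
  expect_true(all(diff(thresholds) <= 0))
  for (i in 2:4) {
    expect_true(all(runs[[i - 1]]$kept_idx %in% runs[[i]]$kept_idx))
  }
})

test_that("technical-replicate averaging collapses groups correctly", {
  sheet <- as_sample_sheet(data.frame(
    sample_id = paste0("s", 1:4), compound = "drug",
    concentration_molar = c(1e-6, 1e-6, 1e-5, 1e-5),
    tech_rep = c(1L, 2L, 1L, 2L), bio_rep = 1L))
  fm <- make_fm(rbind(c(2, 8), c(4, 8), c(6, 1), c(6, 3)), sheet = sheet)
  avg <- average_technical_replicates(fm)
  expect_equal(nrow(avg$intensities), 2L)
  expect_equal(unname(avg$intensities), rbind(c(3, 8), c(6, 2)))

  # identical replicates: unchanged values
  same <- make_fm(matrix(5, 8, 2),
                  sheet = flat_sheet(paste0("s", 1:8), conc = 1e-6))
  avg2 <- average_technical_replicates(same)
  expect_equal(unname(avg2$intensities), matrix(5, 1, 2))
})

test_that("averaging beats single replicates in distance to truth", {
  # feature-rich truth: with many features the averaged row concentrates
  # around the truth while single replicates keep their full scatter
  set.seed(42)
  truth <- runif(20, 1, 10)
  hits <- 0L
  for (trial in 1:100) {
    reps <- t(replicate(8, truth * rlnorm(20, sdlog = 0.15)))
    avg <- colMeans(reps)
    d_avg <- sqrt(sum((avg - truth)^2))
    d_single <- apply(reps, 1, function(r) sqrt(sum((r - truth)^2)))
    if (d_avg < min(d_single)) hits <- hits + 1L
  }
  expect_gte(hits, 90L)
})

test_that("truncation keeps through the last maximum and is idempotent", {
  s <- conc_series(1:4, c(1, 2, 3, 4))
  expect_equal(truncate_after_max(s)$y, c(1, 2, 3, 4))
  expect_false(truncate_after_max(s)$truncated)

  # biphasic: rise to a maximum, then toxic decline; only the rise is kept
  b <- conc_series(1:5, c(1, 5, 9, 4, 2))
  tb <- truncate_after_max(b)
  expect_equal(tb$y, c(1, 5, 9))
  expect_true(tb$truncated)

  ties <- conc_series(1:3, c(3, 3, 3))
  expect_equal(truncate_after_max(ties)$y, c(3, 3, 3))

  expect_equal(truncate_after_max(tb), tb)
})

test_that("noise-free logistic data is recovered to numerical precision", {
  x <- seq(-8.5, -5, by = 0.5) # 8 doses
  truth <- c(top = 10, bottom = 2, log_ic50 = -6.3, hill_slope = 1)
  y <- logistic4(x, 10, 2, -6.3, 1)
  fit <- fit_descending(conc_series(x, y))
  expect_true(fit$converged)
  expect_lt(max(abs(coef(fit) - truth) / abs(truth)), 1e-4)
  expect_gte(fit$r2, 1 - 1e-9)
  expect_equal(pic50(fit), 6.3, tolerance = 1e-4)

  # ascending form, 6 doses
  ya <- logistic4(seq(-8, -5.5, by = 0.5), 9, 1, -6.8, 1.4, ascending = TRUE)
  fa <- fit_ascending(conc_series(seq(-8, -5.5, by = 0.5), ya))
  expect_lt(abs(fa$log_ic50 + 6.8), 1e-4)
  expect_gte(fa$r2, 1 - 1e-9)
  expect_equal(fa$direction, "ascending")
})

test_that("noisy logistic data recovers LogIC50 within the expected band", {
  set.seed(7)
  x <- seq(-8.5, -5, by = 0.5)
  y <- pmax(logistic4(x, 10, 2, -6.3, 1) + rnorm(8, sd = 0.2), 0)
  fit <- fit_descending(conc_series(x, y))
  expect_true(fit$converged)
  expect_lt(abs(fit$log_ic50 + 6.3), 0.2)
})

test_that("biphasic series truncate then recover the ascending LogIC50", {
  x <- seq(-9, -5, by = 0.5) # 9 doses
  rise <- logistic4(x, 8, 1, -7.2, 1, ascending = TRUE)
  y <- rise
  y[7:9] <- rise[6] * c(0.7, 0.4, 0.2) # toxic collapse after the maximum
  ser <- truncate_after_max(conc_series(x, y))
  expect_equal(length(ser$x), 6L)
  fit <- fit_ascending(ser)
  expect_lt(abs(fit$log_ic50 + 7.2), 0.05)

  # fewer than five points after truncation: skipped, not an error
  short <- truncate_after_max(conc_series(1:6, c(1, 4, 9, 5, 3, 2)))
  sk <- fit_ascending(short)
  expect_false(sk$converged)
  expect_identical(sk$r2, -Inf)
  expect_match(sk$reason, "insufficient")
})

test_that("fit SS matches an independent dense grid-search oracle", {
  set.seed(19)
  x <- seq(-8, -5.5, by = 0.5) # 6 points
  y <- pmax(logistic4(x, 7, 2, -6.6, 1.3) + rnorm(6, sd = 0.15), 0)
  fit <- fit_descending(conc_series(x, y))

  # oracle: exhaustive grid over (LogIC50, HillSlope) with (top, bottom)
  # profiled by unconstrained linear least squares, then local refinement
  grid_ss <- function(Ls, hs) {
    best <- Inf
    for (L in Ls) for (h in hs) {
      w <- 1 / (1 + 10^((L - x) * h))
      q <- cbind(1 - w, w)
      cf <- qr.coef(qr(q), y)
      if (anyNA(cf)) next
      ss <- sum((y - q %*% cf)^2)
      if (ss < best) { best <- ss; at <- c(L, h) }
    }
    list(ss = best, at = at)
  }
  g1 <- grid_ss(seq(-10, -3.5, by = 0.05), seq(0.1, 10, by = 0.05))
  g2 <- grid_ss(seq(g1$at[1] - 0.1, g1$at[1] + 0.1, by = 0.001),
                seq(max(g1$at[2] - 0.1, 0.05), g1$at[2] + 0.1, by = 0.001))
  g3 <- grid_ss(seq(g2$at[1] - 0.002, g2$at[1] + 0.002, by = 2e-5),
                seq(g2$at[2] - 0.002, g2$at[2] + 0.002, by = 2e-5))
  expect_lt(abs(fit$ss_res - g3$ss), 1e-6)
})

test_that("generated direction wins the direction classification", {
  # on noise-free descending data the ascending route never scores higher
  set.seed(23)
  x <- seq(-8.5, -5, by = 0.5)
  for (i in 1:10) {
    top <- runif(1, 5, 20); bottom <- runif(1, 0, 0.5 * top)
    y <- logistic4(x, top, bottom, runif(1, -7.5, -6), runif(1, 0.6, 2.5))
    ser <- conc_series(x, y)
    fd <- fit_descending(ser)
    fa <- fit_ascending(truncate_after_max(ser))
    expect_gte(fd$r2, fa$r2)
  }
})

test_that("failed and degenerate fits are flagged, never thrown", {
  flat <- conc_series(1:6, rep(2, 6))
  f <- fit_descending(flat)
  expect_false(f$converged)
  expect_match(f$reason, "constant")
  expect_true(is.na(pic50(f)))

  few <- conc_series(1:4, c(4, 3, 2, 1))
  expect_false(fit_descending(few)$converged)
})

test_that("marker ranking requires all replicates to pass with one direction", {
  fits <- list(
    good = list(fake_fit(0.95), fake_fit(0.93), fake_fit(0.97)),
    one_bad = list(fake_fit(0.95), fake_fit(0.85), fake_fit(0.97)),
    mixed_dir = list(fake_fit(0.95), fake_fit(0.93, "ascending"),
                     fake_fit(0.97)),
    two_reps = list(fake_fit(0.99), fake_fit(0.98)))
  rep <- rank_and_call_markers(fits, r2_min = 0.9, n_reps_required = 3L)
  expect_true(rep["good", "reproducible"])
  expect_false(rep["one_bad", "reproducible"])
  expect_false(rep["mixed_dir", "reproducible"])
  expect_false(rep["two_reps", "reproducible"])
  # sorted by mean r2, descending
  expect_equal(rownames(rep)[1], "two_reps")
})

test_that("pIC50 is the negated LogIC50 and preserves potency order", {
  f <- fake_fit(0.99, log_ic50 = -6)
  expect_equal(pic50(f), 6)

  # fit to noise-free data generated at IC50 = 10 nM
  x <- seq(-9.5, -6, by = 0.5)
  y <- logistic4(x, 12, 1, -8, 1)
  fit <- fit_descending(conc_series(x, y))
  expect_equal(pic50(fit), 8, tolerance = 0.01)

  # 1 nM inhibitor ranks above 1 uM inhibitor
  strong <- fit_descending(conc_series(x, logistic4(x, 10, 1, -9, 1)))
  weak <- fit_descending(conc_series(seq(-7.5, -4, by = 0.5),
                                     logistic4(seq(-7.5, -4, by = 0.5),
                                               10, 1, -6, 1)))
  expect_gt(pic50(strong), pic50(weak))
})
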