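# Brute-force morphological opening: the oracle for Top-Hat tests.
brute_opening <- function(x, h) {
  n <- length(x)
  er <- sapply(seq_len(n), function(i) min(x[max(1, i - h):min(n, i + h)]))
  sapply(seq_len(n), function(i) max(er[max(1, i - h):min(n, i + h)]))
}

test_that("TIC normalization is exact, scale-invariant and idempotent", {
  s <- new_spectrum(1:3, c(1, 2, 3))
  expect_equal(tic_normalize(s)$intensity, c(1, 2, 3) / 6)
  expect_equal(sum(tic_normalize(s, target = 7)$intensity), 7)

  s2 <- s; s2$intensity <- s2$intensity * 13.7
  expect_equal(tic_normalize(s2)$intensity, tic_normalize(s)$intensity)
  expect_equal(tic_normalize(tic_normalize(s)), tic_normalize(s))

  zero <- new_spectrum(1:3, c(0, 0, 0))
  expect_error(tic_normalize(zero), "all-zero")
})

test_that("Top-Hat opening matches the brute-force oracle and its contracts", {
  # constant spectrum: baseline == signal, corrected == 0
  s <- make_profile(offset = 3.2)
  th <- tophat_baseline(s, 10)
  expect_equal(th$baseline, rep(3.2, length(s$mz)))
  expect_equal(max(abs(th$corrected$intensity)), 0)

  # narrow Gaussian on flat offset: baseline identically the offset
  s <- make_profile(offset = 2, peaks = data.frame(mz = 150, height = 50,
                                                   sigma = 0.2))
  th <- tophat_baseline(s, 75) # element 151 pts = 7.55 Th >> peak width
  expect_equal(th$baseline, rep(2, length(s$mz)), tolerance = 1e-12)

  # random signals: equals brute-force opening; baseline <= signal;
  # corrected >= 0; idempotent on its own output
  for (seed in 1:3) {
    set.seed(seed)
    x <- abs(rnorm(400)) + 5 * exp(-((1:400) - 200)^2 / 18)
    s <- new_spectrum(seq_len(400), x)
    th <- tophat_baseline(s, 12)
    expect_equal(th$baseline, brute_opening(x, 12))
    expect_true(all(th$baseline <= x + 1e-12))
    expect_true(all(th$corrected$intensity >= 0))
    again <- tophat_baseline(th$corrected, 12)
    # opening idempotence: re-estimated baseline is (numerically) zero
    expect_lt(max(again$baseline), 1e-9 * max(x))
  }

  expect_error(tophat_baseline(make_profile(mz_to = 101), 75), "shorter")
})

test_that("noise estimate is MAD-consistent, floored and homogeneous", {
  set.seed(99)
  sigma <- 2.5
  draw <- abs(rnorm(5000, sd = sigma))
  s <- new_spectrum(seq_len(5000), draw)
  noise <- estimate_noise(s, half_window = 100)
  # oracle: same estimator applied by hand at sampled positions
  at <- c(500, 2500, 4500)
  by_hand <- sapply(at, function(i)
    1.4826 * median(draw[(i - 100):(i + 100)]))
  expect_equal(noise[at], by_hand, tolerance = 1e-9)
  # half-normal: 1.4826 * median(|x|) estimates sigma itself
  expect_lt(abs(median(noise) - sigma) / sigma, 0.25)

  zero <- new_spectrum(1:100, rep(0, 100))
  expect_true(all(estimate_noise(zero) == .Machine$double.eps))

  s2 <- s; s2$intensity <- 2 * s2$intensity
  expect_equal(estimate_noise(s2, 100), 2 * noise)
})

test_that("peak picking applies SNR threshold and window dominance", {
  set.seed(4)
  n <- 4000
  sigma_noise <- 1
  base <- abs(rnorm(n, sd = sigma_noise))
  apex <- 2000
  x <- base
  x[apex] <- x[apex] + 100 * sigma_noise
  s <- new_spectrum(seq_len(n), x)
  pk <- pick_peaks(s, snr_min = 5, half_window = 20)
  expect_equal(length(pk$mz), 1L)
  expect_equal(pk$mz, apex)
  expect_equal(pk$intensity, x[apex])
  expect_true(all(pk$snr > 5))

  # a 3-sigma bump never clears snr_min = 5
  y <- base; y[apex] <- y[apex] + 3 * sigma_noise
  expect_equal(length(pick_peaks(new_spectrum(seq_len(n), y))$mz), 0L)

  # two maxima 10 points apart, half_window 20: only the larger reported
  z <- rep(0.01, 500)
  z[200] <- 8; z[210] <- 6
  s <- new_spectrum(seq_len(500), z)
  pk <- pick_peaks(s, snr_min = 5, half_window = 20, noise_half_window = 50)
  expect_equal(pk$mz, 200)
})

test_that("binning respects the relative tolerance and per-sample uniqueness", {
  pl <- function(mz, int, id) structure(
    list(mz = mz, intensity = int, snr = rep(10, length(mz)),
         sample_id = id), class = "peak_list")

  # spread 0.001 <= 0.002: one shared bin at the mean m/z
  fm <- bin_peaks(list(pl(1000.0, 5, "a"), pl(1001.0, 7, "b")))
  expect_equal(fm$features, 1000.5)
  expect_equal(as.vector(fm$intensities), c(5, 7))

  # spread 0.003 > 0.002: two bins, absent cells are zero
  fm <- bin_peaks(list(pl(1000.0, 5, "a"), pl(1003.0, 7, "b")))
  expect_equal(fm$features, c(1000, 1003))
  expect_equal(fm$intensities, matrix(c(5, 0, 0, 7), 2, 2,
                                      dimnames = dimnames(fm$intensities)))

  # single peak list: identity
  fm <- bin_peaks(list(pl(c(300, 400.5), c(1, 2), "a")))
  expect_equal(fm$features, c(300, 400.5))
  expect_equal(as.vector(fm$intensities), c(1, 2))

  # property: every bin within tolerance, never two peaks of one sample,
  # every pooled peak assigned to exactly one bin
  set.seed(8)
  for (trial in 1:5) {
    lists <- lapply(1:6, function(i)
      pl(sort(runif(30, 400, 410)), runif(30), paste0("s", i)))
    fm <- bin_peaks(lists, tolerance = 0.002)
    members <- attr(fm, "members")
    widths_ok <- vapply(members, function(b)
      (max(b$mz) - min(b$mz)) / mean(b$mz) <= 0.002 || nrow(b) == 1L,
      logical(1))
    expect_true(all(widths_ok))
    unique_ok <- vapply(members, function(b) !anyDuplicated(b$sample),
                        logical(1))
    expect_true(all(unique_ok))
    expect_equal(sum(vapply(members, nrow, integer(1))), 6L * 30L)
    expect_equal(fm$features,
                 vapply(members, function(b) mean(b$mz), numeric(1)))
  }
})

test_that("pipeline is order-invariant and recovers planted peaks exactly", {
  cfg <- mini_config(seed = 21, n_tech = 2L, n_bio = 1L,
                     doses = c(1e-7, 1e-6, 1e-5),
                     tech_cv = 0, bio_cv = 0, noise_sd = 0)
  sim <- simulate_experiment(cfg)
  fm <- preprocess_pipeline(sim$spectra, sim$sheet)

  # noise-free: every planted analyte and matrix ion is exactly one feature
  planted <- sort(c(cfg$analytes$mz, cfg$matrix_ions$mz))
  expect_equal(length(fm$features), length(planted))
  expect_true(all(abs(fm$features - planted) / planted <= 0.002))

  # permuting the input spectra changes nothing (sheet defines row order)
  fm2 <- preprocess_pipeline(rev(sim$spectra), sim$sheet)
  expect_equal(fm2, fm, ignore_attr = TRUE)

  expect_error(preprocess_pipeline(list(), sim$sheet), "no spectra")
})

test_that("planted dose gradients survive preprocessing monotonically", {
  cfg <- mini_config(seed = 31, n_tech = 1L, n_bio = 1L,
                     tech_cv = 0, bio_cv = 0, noise_sd = 0)
  sim <- simulate_experiment(cfg)
  fm <- preprocess_pipeline(sim$spectra, sim$sheet)
  truth <- sim$truth
  # per planted analyte: Spearman correlation between planted per-sample
  # heights and the recovered feature intensities across doses
  for (i in seq_len(nrow(truth$analytes))) {
    target <- truth$analytes$mz[i]
    col <- which.min(abs(fm$features - target))
    expect_lt(abs(fm$features[col] - target) / target, 0.002)
    planted <- truth$heights[, i]
    got <- fm$intensities[, col]
    if (sd(planted) > 0) {
      expect_gt(cor(planted, got, method = "spearman"), 0.95)
    }
  }
})
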