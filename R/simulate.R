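# Synthetic whole-cell MALDI-TOF profile spectra with planted dose-response
# structure. The generator emulates reflector-positive acquisitions over
# m/z 200-2,000: Gaussian analyte peaks whose FWHM grows linearly with m/z,
# DHB-like matrix cluster ions suppressed by analyte load, an exponentially
# decaying chemical baseline, lognormal biological/technical replicate
# variability, and additive detector noise.

#' Simulation configuration
#'
#' Defaults describe the emulated study conditions: 8 half-log doses up to
#' 30 uM, 8 technical and 3 biological replicates, 15% technical and 10%
#' biological intensity CV, one descending marker (PC-lipid-like potassium
#' adduct at m/z 826.57), one biphasic marker (heme-B-like at m/z 616.18),
#' a panel of inert lipid peaks, and DHB matrix cluster ions.
#'
#' @param seed Integer RNG seed (mandatory; all randomness flows from it).
#' @param mz_range Acquisition window, Th (default `c(200, 2000)`).
#' @param mz_step Uniform grid spacing, Th (default 0.02).
#' @param resolution TOF resolving power: peak FWHM = m/z / resolution
#'   (default 1000).
#' @param analytes Data frame: `mz`, `intensity` (peak height at full
#'   response), `response` (`"none"`, `"descending"`, `"ascending"`,
#'   `"biphasic"`), `log_ic50`, `hill_slope`, `top_frac`, `bottom_frac`
#'   (plateau heights as fractions of `intensity`). `NULL` = default panel.
#' @param matrix_ions Data frame `mz`, `intensity` of matrix cluster ions;
#'   `NULL` = DHB defaults.
#' @param suppression_k Matrix-suppression constant: matrix heights are
#'   divided by `1 + suppression_k * load` with load = analyte height sum
#'   relative to the default panel's full load, times `cell_load`.
#' @param cell_load Spotted cell number in units of the reference count
#'   (1000 cells). The default 5 emulates the optimized protocol of 5,000
#'   cells per spot, at which matrix ions are strongly suppressed.
#' @param baseline_amplitude,baseline_offset,baseline_scale Chemical
#'   baseline `A * exp(-(mz - mz_min)/scale) + offset`; the constant offset
#'   is the chemical-noise pedestal a real detector sits on (profiles do not
#'   fall to exact zero).
#' @param noise_sd Additive Gaussian noise SD (intensity units).
#' @param tech_cv,bio_cv Lognormal coefficients of variation of technical
#'   and biological replicate factors.
#' @param doses Molar concentrations (default 8 half-log steps, 10 nM-30 uM).
#' @param n_tech,n_bio Technical / biological replicate counts (8 and 3).
#' @param compound Compound label written to the sample sheet.
#' @param include_vehicle Add concentration-0 rows (default FALSE).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed,
                       mz_range = c(200, 2000), mz_step = 0.02,
                       resolution = 1000,
                       analytes = NULL, matrix_ions = NULL,
                       suppression_k = 4, cell_load = 5,
                       baseline_amplitude = 20,
                       baseline_offset = 2, baseline_scale = 300,
                       noise_sd = 1,
                       tech_cv = 0.15, bio_cv = 0.10,
                       doses = c(0.01, 0.0316, 0.1, 0.316, 1, 3.16, 10, 30) * 1e-6,
                       n_tech = 8L, n_bio = 3L,
                       compound = "imatinib", include_vehicle = FALSE) {
  if (missing(seed)) stop("sim_config: 'seed' is mandatory")
  if (is.null(analytes)) analytes <- default_analyte_panel()
  if (is.null(matrix_ions)) {
    # DHB cluster ions dominate a low-load spectrum by orders of magnitude
    matrix_ions <- data.frame(mz = dhb_matrix_ions(),
                              intensity = c(8e4, 6e4, 4e4, 2e4))
  }
  stopifnot(length(mz_range) == 2L, mz_range[2] > mz_range[1], mz_step > 0,
            resolution > 0, all(doses >= 0), !is.unsorted(doses),
            n_tech >= 1L, n_bio >= 1L, tech_cv >= 0, bio_cv >= 0,
            noise_sd >= 0)
  if (any(analytes$mz < mz_range[1] | analytes$mz > mz_range[2])) {
    stop("analyte m/z outside mz_range")
  }
  structure(list(seed = as.integer(seed), mz_range = mz_range,
                 mz_step = mz_step, resolution = resolution,
                 analytes = analytes, matrix_ions = matrix_ions,
                 suppression_k = suppression_k, cell_load = cell_load,
                 baseline_amplitude = baseline_amplitude,
                 baseline_offset = baseline_offset,
                 baseline_scale = baseline_scale, noise_sd = noise_sd,
                 tech_cv = tech_cv, bio_cv = bio_cv, doses = doses,
                 n_tech = as.integer(n_tech), n_bio = as.integer(n_bio),
                 compound = compound, include_vehicle = include_vehicle),
            class = "sim_config")
}

#' @rdname sim_config
#' @export
default_analyte_panel <- function() {
  inert <- data.frame(
    mz = c(496.34, 520.34, 577.52, 703.57, 734.57, 760.58, 782.57,
           798.54, 810.60, 844.53, 868.53, 907.61),
    intensity = c(3000, 2500, 4000, 5000, 7000, 6500, 4500, 3500, 3000,
                  2500, 2000, 1500),
    response = "none", log_ic50 = NA_real_, hill_slope = NA_real_,
    top_frac = 1, bottom_frac = 1, stringsAsFactors = FALSE)
  responsive <- data.frame(
    mz = c(826.57, 616.18),
    intensity = c(4000, 4000),
    response = c("descending", "biphasic"),
    log_ic50 = c(-6.5, -6.5), hill_slope = c(1, 1),
    top_frac = c(1, 1), bottom_frac = c(0.28, 0.15),
    stringsAsFactors = FALSE)
  rbind(responsive, inert)
}

# True mean peak height of one analyte at one dose (molar).
.response_height <- function(analyte, dose) {
  shape <- analyte$response
  if (shape == "none" || dose <= 0) {
    # vehicle/low-dose limit: descending and biphasic sit at their top/bottom
    return(switch(shape,
                  none = analyte$intensity,
                  descending = analyte$intensity * analyte$top_frac,
                  analyte$intensity * analyte$bottom_frac))
  }
  x <- log10(dose)
  w <- 1 / (1 + 10^((analyte$log_ic50 - x) * analyte$hill_slope))
  top <- analyte$intensity * analyte$top_frac
  bottom <- analyte$intensity * analyte$bottom_frac
  if (shape == "descending") {
    top * (1 - w) + bottom * w
  } else if (shape == "ascending") {
    bottom * (1 - w) + top * w
  } else { # biphasic: ascending limb times a delayed toxicity decline
    tox_w <- 1 / (1 + 10^(((analyte$log_ic50 + 1.2) - x) * 3))
    (bottom * (1 - w) + top * w) * (1 - 0.9 * tox_w)
  }
}

# Render one profile spectrum from per-analyte peak heights. `load_scale`
# converts the relative analyte load (height sum over the panel's full-
# response sum) into suppression units of the reference cell number.
.render_spectrum <- function(grid, analyte_mz, heights, matrix_tab,
                             cfg, load_scale = 1, rng_noise = TRUE) {
  intensity <- cfg$baseline_offset + cfg$baseline_amplitude *
    exp(-(grid - cfg$mz_range[1]) / cfg$baseline_scale)
  add_peak <- function(center, h) {
    if (h <= 0) return()
    sigma <- (center / cfg$resolution) / 2.35482
    lo <- max(1L, ceiling((center - 6 * sigma - grid[1L]) / cfg$mz_step) + 1L)
    hi <- min(length(grid),
              floor((center + 6 * sigma - grid[1L]) / cfg$mz_step) + 1L)
    if (lo > hi) return()
    idx <- lo:hi
    intensity[idx] <<- intensity[idx] +
      h * exp(-(grid[idx] - center)^2 / (2 * sigma^2))
  }
  load <- load_scale * sum(heights) / sum(cfg$analytes$intensity)
  supp <- 1 / (1 + cfg$suppression_k * load)
  for (i in seq_along(analyte_mz)) add_peak(analyte_mz[i], heights[i])
  for (i in seq_len(nrow(matrix_tab))) {
    add_peak(matrix_tab$mz[i], matrix_tab$intensity[i] * supp)
  }
  if (rng_noise && cfg$noise_sd > 0) {
    intensity <- intensity + stats::rnorm(length(grid), sd = cfg$noise_sd)
  }
  pmax(intensity, 0)
}

.lognormal_factor <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate a concentration-response experiment
#'
#' Generates one profile spectrum per (dose, technical replicate, biological
#' replicate) cell: per-analyte true heights follow the configured response
#' curves, multiplied by a per-(analyte, bio rep) lognormal biological
#' factor and a per-(analyte, spectrum) lognormal technical factor; matrix
#' ions are suppressed as analyte load rises; baseline and additive noise
#' complete the profile. Deterministic given `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return List: `spectra` (list of `spectrum`), `sheet` (`sample_sheet`),
#'   `truth` (list with the analyte table, per-sample drawn heights, and the
#'   config).
#' @export
simulate_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(cfg$seed)

  grid <- seq(cfg$mz_range[1], cfg$mz_range[2], by = cfg$mz_step)
  doses <- cfg$doses
  if (cfg$include_vehicle) doses <- c(0, doses)
  na <- nrow(cfg$analytes)
  design <- expand.grid(tech_rep = seq_len(cfg$n_tech),
                        dose_idx = seq_along(doses),
                        bio_rep = seq_len(cfg$n_bio))
  n_samples <- nrow(design)
  bio_factors <- matrix(.lognormal_factor(na * cfg$n_bio, cfg$bio_cv),
                        nrow = na, ncol = cfg$n_bio)
  true_heights <- matrix(0, nrow = n_samples, ncol = na)
  spectra <- vector("list", n_samples)
  ids <- character(n_samples)
  for (k in seq_len(n_samples)) {
    d <- design[k, ]
    dose <- doses[d$dose_idx]
    mean_h <- vapply(seq_len(na), function(i)
      .response_height(cfg$analytes[i, ], dose), numeric(1))
    h <- mean_h * bio_factors[, d$bio_rep] *
      .lognormal_factor(na, cfg$tech_cv)
    true_heights[k, ] <- h
    ids[k] <- sprintf("%s_d%02d_t%d_b%d", cfg$compound, d$dose_idx,
                      d$tech_rep, d$bio_rep)
    spectra[[k]] <- new_spectrum(
      grid, .render_spectrum(grid, cfg$analytes$mz, h, cfg$matrix_ions, cfg,
                             load_scale = cfg$cell_load),
      sample_id = ids[k])
  }
  sheet <- as_sample_sheet(data.frame(
    sample_id = ids, compound = cfg$compound,
    concentration_molar = doses[design$dose_idx],
    tech_rep = design$tech_rep, bio_rep = design$bio_rep,
    stringsAsFactors = FALSE))
  truth <- list(analytes = cfg$analytes, heights = true_heights,
                config = cfg)
  list(spectra = spectra, sheet = sheet, truth = truth)
}

#' Simulate a cell-number dilution series
#'
#' One spectrum per spotted cell count: analyte peak heights scale linearly
#' with cell count (relative to `ref_cells`), matrix-ion heights are divided
#' by `1 + suppression_k * load`. This reproduces the saturation logic of
#' matrix suppression: the analyte TIC share (the matrix-suppression score)
#' rises with cell number and plateaus once `k * load >> 1`.
#'
#' @param cfg A [sim_config()] (dose-response fields are ignored; analytes
#'   are rendered at their full intensity).
#' @param cell_counts Non-negative cell counts per spot.
#' @param ref_cells Cell count corresponding to unit analyte load
#'   (default 1000).
#' @return List with `spectra` (one per count) and `cell_counts`.
#' @export
simulate_cell_dilution <- function(cfg, cell_counts, ref_cells = 1000) {
  stopifnot(inherits(cfg, "sim_config"), all(cell_counts >= 0))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(cfg$seed)
  grid <- seq(cfg$mz_range[1], cfg$mz_range[2], by = cfg$mz_step)
  spectra <- vector("list", length(cell_counts))
  for (k in seq_along(cell_counts)) {
    scale <- cell_counts[k] / ref_cells
    h <- cfg$analytes$intensity * scale
    spectra[[k]] <- new_spectrum(
      grid, .render_spectrum(grid, cfg$analytes$mz, h, cfg$matrix_ions, cfg),
      sample_id = sprintf("cells_%06d", cell_counts[k]))
  }
  list(spectra = spectra, cell_counts = cell_counts)
}

#' Write a simulated experiment to disk
#'
#' Spectra as two-column text files (or one mzML when `format = "mzml"`),
#' the sample sheet as CSV, and the ground truth as JSON.
#'
#' @param sim Result of [simulate_experiment()].
#' @param dir Output directory (created if needed).
#' @param format `"text"` or `"mzml"`.
#' @return `dir`, invisibly.
#' @export
write_simulated_experiment <- function(sim, dir, format = c("text", "mzml")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (format == "text") {
    for (s in sim$spectra) {
      write_spectrum_text(s, file.path(dir, paste0(s$sample_id, ".txt")))
    }
  } else {
    write_spectra_mzml(sim$spectra, file.path(dir, "spectra.mzML"))
  }
  utils::write.csv(sim$sheet, file.path(dir, "sample_sheet.csv"),
                   row.names = FALSE)
  truth <- sim$truth
  truth$config <- unclass(truth$config)
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}
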