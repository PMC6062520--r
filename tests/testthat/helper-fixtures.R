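# Shared fixture builders. Everything is generated in code; no data files.

# Flat spectrum with optional Gaussian peaks on a uniform grid.
make_profile <- function(mz_from = 100, mz_to = 200, step = 0.05,
                         offset = 0, peaks = NULL, noise_sd = 0,
                         sample_id = "s1", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mz <- seq(mz_from, mz_to, by = step)
  intensity <- rep(offset, length(mz))
  if (!is.null(peaks)) {
    for (i in seq_len(nrow(peaks))) {
      intensity <- intensity + peaks$height[i] *
        exp(-(mz - peaks$mz[i])^2 / (2 * peaks$sigma[i]^2))
    }
  }
  if (noise_sd > 0) intensity <- intensity + abs(rnorm(length(mz), sd = noise_sd))
  new_spectrum(mz, intensity, sample_id)
}

# Minimal sample sheet for n samples in one experimental cell.
flat_sheet <- function(ids, compound = "drug", conc = 0, tech = NULL,
                       bio = 1L) {
  n <- length(ids)
  as_sample_sheet(data.frame(
    sample_id = ids, compound = compound,
    concentration_molar = rep_len(conc, n),
    tech_rep = if (is.null(tech)) seq_len(n) else rep_len(tech, n),
    bio_rep = rep_len(bio, n), stringsAsFactors = FALSE))
}

# Feature matrix built directly from a plain intensity matrix.
make_fm <- function(mat, features = NULL, sheet = NULL) {
  if (is.null(features)) features <- 500 + seq_len(ncol(mat))
  if (is.null(sheet)) {
    sheet <- flat_sheet(paste0("s", seq_len(nrow(mat))))
  }
  new_feature_matrix(mat, features, sheet)
}

# Reduced-scale simulation config for unit tests: same physics, narrower
# window and coarser grid than the full study-scale default.
mini_config <- function(seed, ...) {
  panel <- default_analyte_panel()
  panel <- panel[panel$mz < 900, ]
  sim_config(seed = seed, mz_range = c(250, 900), mz_step = 0.05,
             analytes = panel, ...)
}

# Descending four-parameter logistic, the generating model for fit tests.
logistic4 <- function(x, top, bottom, log_ic50, hill, ascending = FALSE) {
  w <- 1 / (1 + 10^((log_ic50 - x) * hill))
  if (ascending) bottom + (top - bottom) * w else top + (bottom - top) * w
}

# Minimal stand-in dr_fit for ranking-logic tests.
fake_fit <- function(r2, direction = "descending", log_ic50 = -6) {
  structure(list(top = 1, bottom = 0, log_ic50 = log_ic50, hill_slope = 1,
                 direction = direction, r2 = r2, n_points = 8L,
                 truncated = FALSE, converged = is.finite(r2),
                 reason = NA_character_, ss_res = 0,
                 x = numeric(0), y = numeric(0), fitted = numeric(0)),
            class = "dr_fit")
}
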