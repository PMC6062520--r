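#' Run the full marker-discovery workflow
#'
#' Binds the stages end to end: preprocessing (TIC normalization, Top-Hat
#' baseline, SNR peak picking, binning), multivariate scores (sqrt transform
#' + PCA), two-step marker calling (variance filter + concentration-response
#' fits), and optional accurate-mass annotation of the called markers.
#'
#' @param spectra List of `spectrum` objects.
#' @param sheet A `sample_sheet` covering them.
#' @param snr_min,peak_half_window,baseline_half_window,tolerance
#'   Preprocessing settings (defaults: SNR > 5, half window 20, Top-Hat half
#'   window 75, relative bin tolerance 0.002).
#' @param r2_min,n_reps_required,exclude_mz,vehicle Marker-calling settings
#'   (defaults: R2 >= 0.9, 3 biological replicates, no exclusions, vehicle
#'   rows anchored 2 decades below the lowest dose).
#' @param compound_table Optional compound table (see
#'   [read_compound_table()]) for annotating marker m/z values.
#' @param max_ppm Annotation mass tolerance, ppm (default 3).
#' @param n_components PCA components to report (default 2).
#' @return Object of class `"wc_run"`: list with `feature_matrix`, `pca`,
#'   `markers`, `annotations`, `counts` and the resolved `params`.
#' @export
run_workflow <- function(spectra, sheet, snr_min = 5, peak_half_window = 20L,
                         baseline_half_window = 75L, tolerance = 0.002,
                         r2_min = 0.9, n_reps_required = 3L,
                         exclude_mz = numeric(0),
                         vehicle = c("anchor", "exclude"),
                         compound_table = NULL, max_ppm = 3,
                         n_components = 2L) {
  vehicle <- match.arg(vehicle)
  fm <- preprocess_pipeline(spectra, sheet, snr_min = snr_min,
                            peak_half_window = peak_half_window,
                            baseline_half_window = baseline_half_window,
                            tolerance = tolerance)
  n_components <- min(n_components, nrow(fm$intensities) - 1L,
                      ncol(fm$intensities))
  pca <- pca_scores(sqrt_transform(fm), n_components)
  markers <- call_markers(fm, r2_min = r2_min,
                          n_reps_required = n_reps_required,
                          exclude_mz = exclude_mz, vehicle = vehicle)
  annotations <- NULL
  called <- markers$report[markers$report$reproducible, , drop = FALSE]
  if (!is.null(compound_table) && nrow(called)) {
    ann <- lapply(called$feature_mz, function(m) {
      hits <- search_compounds(m, compound_table, max_ppm = max_ppm)
      if (nrow(hits)) cbind(feature_mz = m, hits) else NULL
    })
    ann <- ann[!vapply(ann, is.null, logical(1))]
    if (length(ann)) annotations <- do.call(rbind, ann)
  }
  params <- list(snr_min = snr_min, peak_half_window = peak_half_window,
                 baseline_half_window = baseline_half_window,
                 tolerance = tolerance, r2_min = r2_min,
                 n_reps_required = n_reps_required, exclude_mz = exclude_mz,
                 vehicle = vehicle, max_ppm = max_ppm)
  structure(list(feature_matrix = fm, pca = pca, markers = markers,
                 annotations = annotations,
                 counts = c(attr(fm, "log")[c("n_spectra", "n_peaks_total",
                                              "n_features")],
                            markers$counts),
                 params = params),
            class = "wc_run")
}

#' @export
print.wc_run <- function(x, ...) {
  cat("Whole-cell MALDI marker-discovery run\n")
  cat(sprintf("  spectra: %d   peaks: %d   features: %d\n",
              x$counts$n_spectra, x$counts$n_peaks_total,
              x$counts$n_features))
  cat(sprintf("  after variance filter: %d   markers: %d\n",
              x$counts$n_after_variance, x$counts$n_markers))
  print(x$markers)
  if (!is.null(x$annotations)) {
    cat("annotations:\n")
    print(x$annotations, digits = 7)
  }
  invisible(x)
}

#' Write workflow reports
#'
#' Marker report and PCA scores as CSV, fit parameters plus the resolved
#' configuration and per-stage counts as JSON.
#'
#' @param run A `wc_run` from [run_workflow()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run_report <- function(run, dir) {
  stopifnot(inherits(run, "wc_run"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(run$markers$report, file.path(dir, "markers.csv"),
                   row.names = FALSE)
  scores <- data.frame(sample_id = rownames(run$pca$scores), run$pca$scores)
  names(scores)[-1L] <- paste0("PC", seq_len(ncol(run$pca$scores)))
  utils::write.csv(scores, file.path(dir, "pca_scores.csv"),
                   row.names = FALSE)
  if (!is.null(run$annotations)) {
    utils::write.csv(run$annotations, file.path(dir, "annotations.csv"),
                     row.names = FALSE)
  }
  fit_dump <- lapply(run$markers$fits, function(rep_fits) {
    lapply(rep_fits, function(f)
      f[c("top", "bottom", "log_ic50", "hill_slope", "direction", "r2",
          "n_points", "truncated", "converged", "x", "y")])
  })
  jsonlite::write_json(
    list(params = run$params, counts = run$counts, fits = fit_dump),
    file.path(dir, "run.json"), auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}

#' Load spectra and sample sheet from a dataset directory
#'
#' Expects `sample_sheet.csv` plus either one `<sample_id>.txt` two-column
#' spectrum per sample or a single `spectra.mzML` whose scan order matches
#' the sheet rows.
#'
#' @param dir Dataset directory (as written by
#'   [write_simulated_experiment()]).
#' @return List with `spectra` and `sheet`.
#' @export
read_experiment_dir <- function(dir) {
  sheet_path <- file.path(dir, "sample_sheet.csv")
  if (!file.exists(sheet_path)) stop("no sample_sheet.csv in ", dir)
  sheet <- read_sample_sheet(sheet_path)
  mzml <- file.path(dir, "spectra.mzML")
  if (file.exists(mzml)) {
    spectra <- lapply(seq_len(nrow(sheet)), function(i)
      read_spectrum_mzml(mzml, i, sample_id = sheet$sample_id[i]))
  } else {
    spectra <- lapply(sheet$sample_id, function(id) {
      p <- file.path(dir, paste0(id, ".txt"))
      if (!file.exists(p)) stop("missing spectrum file for sample ", id)
      read_spectrum_text(p, sample_id = id)
    })
  }
  list(spectra = spectra, sheet = sheet)
}
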