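# Four-parameter logistic concentration-response fitting.
#
# Both curve directions are members of one family
#   f(x) = plateau_low * (1 - w) + plateau_high * w,
#   w(x) = 1 / (1 + 10^((LogIC50 - x) * HillSlope)),  HillSlope > 0,
# where plateau_low is the response at low dose and plateau_high at high
# dose. Descending curves have plateau_low = top >= plateau_high = bottom;
# ascending curves the reverse. For fixed (LogIC50, HillSlope) the plateaus
# enter linearly, so they are profiled out by an exact constrained
# least-squares solve and the numerical search runs over two parameters only.

.logistic_w <- function(x, log_ic50, hill) {
  1 / (1 + 10^((log_ic50 - x) * hill))
}

# Constrained linear solve for (lo, hi) >= 0 with lo >= hi (descending) or
# hi >= lo (ascending). Exact: enumerates the KKT candidates of the 2-var QP.
.profile_plateaus <- function(y, w, direction) {
  a_col <- 1 - w # multiplies plateau_low
  b_col <- w
  cands <- list()
  aa <- sum(a_col^2); bb <- sum(b_col^2); ab <- sum(a_col * b_col)
  ay <- sum(a_col * y); by <- sum(b_col * y)
  det <- aa * bb - ab * ab
  if (det > 1e-12 * aa * bb) {
    cands[[1L]] <- c((ay * bb - by * ab) / det, (by * aa - ay * ab) / det)
  }
  cands <- c(cands, list(
    rep(mean(y), 2L),                               # plateaus equal
    c(if (aa > 0) max(ay / aa, 0) else 0, 0),       # hi = 0
    c(0, if (bb > 0) max(by / bb, 0) else 0),       # lo = 0
    c(0, 0)))
  feasible <- function(p) {
    p[1L] >= 0 && p[2L] >= 0 &&
      (if (direction == "descending") p[1L] >= p[2L] else p[2L] >= p[1L])
  }
  best <- NULL; best_ss <- Inf
  for (p in cands) {
    if (!feasible(p)) next
    ss <- sum((y - p[1L] * a_col - p[2L] * b_col)^2)
    if (ss < best_ss - 1e-15) { best <- p; best_ss <- ss }
  }
  list(lo = best[1L], hi = best[2L], ss = best_ss)
}

#' Concentration series
#'
#' One feature's mean intensity (over technical replicates) against the
#' decadal logarithm of molar drug concentration, for one biological
#' replicate.
#'
#' @param x Numeric vector of log10 molar concentrations, strictly increasing.
#' @param y Non-negative mean intensities, same length.
#' @param feature_mz Bin-center m/z the series belongs to.
#' @param bio_rep Biological replicate label.
#' @return Object of class `"conc_series"`.
#' @export
conc_series <- function(x, y, feature_mz = NA_real_, bio_rep = NA_integer_) {
  stopifnot(length(x) == length(y))
  if (is.unsorted(x, strictly = TRUE)) {
    stop("concentrations must be strictly increasing on the log scale")
  }
  if (any(y < 0)) stop("negative intensities")
  structure(list(x = as.numeric(x), y = as.numeric(y),
                 feature_mz = feature_mz, bio_rep = bio_rep,
                 truncated = FALSE),
            class = "conc_series")
}

#' Truncate a series after its maximum
#'
#' Biphasic responses (signal rising then falling under overt toxicity) are
#' fitted only up to their maximum: all concentrations after the highest
#' data point are excluded. Ties keep every point through the last maximal
#' one. Idempotent.
#'
#' @param series A [conc_series()].
#' @return The truncated series; `$truncated` is `TRUE` when points were
#'   removed.
#' @export
truncate_after_max <- function(series) {
  stopifnot(inherits(series, "conc_series"))
  last_max <- max(which(series$y == max(series$y)))
  if (last_max < length(series$y)) {
    series$x <- series$x[seq_len(last_max)]
    series$y <- series$y[seq_len(last_max)]
    series$truncated <- TRUE
  }
  series
}

.failed_fit <- function(series, direction, reason) {
  structure(list(top = NA_real_, bottom = NA_real_, log_ic50 = NA_real_,
                 hill_slope = NA_real_, direction = direction, r2 = -Inf,
                 n_points = length(series$x), truncated = series$truncated,
                 converged = FALSE, reason = reason, ss_res = NA_real_,
                 x = series$x, y = series$y, fitted = rep(NA_real_,
                                                          length(series$x))),
            class = "dr_fit")
}

#' Fit a four-parameter logistic concentration-response curve
#'
#' Least-squares fit of the sigmoid
#' `f(x) = top + (bottom - top) / (1 + 10^((LogIC50 - x) * HillSlope))`
#' (descending; the ascending form swaps top and bottom) to a concentration
#' series. The plateau parameters are profiled out analytically under the
#' constraints `top, bottom >= 0` (and the direction's plateau ordering);
#' the remaining (LogIC50, HillSlope) surface is minimized by bounded
#' quasi-Newton search from a multi-start grid: HillSlope in
#' `{0.5, 1, 2}` crossed with LogIC50 in `{min(x), median(x), max(x)}`.
#' The best (lowest SS) start wins; ties go to the smaller HillSlope.
#' Bounds: `LogIC50` in `[min(x) - 2, max(x) + 2]`, `HillSlope` in
#' `[0.05, 10]`.
#'
#' A fit needs at least 5 points and non-constant y; otherwise (or if no
#' start converges) a failed fit with `r2 = -Inf` and a `reason` is returned
#' rather than an error.
#'
#' @param series A [conc_series()] (for ascending fits, typically after
#'   [truncate_after_max()]).
#' @param direction `"descending"` (signal falls with dose) or
#'   `"ascending"`.
#' @return Object of class `"dr_fit"` with elements `top`, `bottom`,
#'   `log_ic50`, `hill_slope`, `direction`, `r2`, `n_points`, `truncated`,
#'   `converged`, `ss_res`, and the data (`x`, `y`, `fitted`).
#' @examples
#' x <- seq(-8, -4.5, by = 0.5)
#' y <- 10 + (2 - 10) / (1 + 10^((-6.3 - x) * 1))
#' fit <- fit_dose_response(conc_series(x, y), "descending")
#' coef(fit)
#' @export
fit_dose_response <- function(series,
                              direction = c("descending", "ascending")) {
  stopifnot(inherits(series, "conc_series"))
  direction <- match.arg(direction)
  x <- series$x; y <- series$y
  n <- length(x)
  if (n < 5L) return(.failed_fit(series, direction, "insufficient points"))
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot <= 0) return(.failed_fit(series, direction, "constant response"))

  lower <- c(min(x) - 2, 0.05)
  upper <- c(max(x) + 2, 10)
  objective <- function(par) {
    w <- .logistic_w(x, par[1L], par[2L])
    .profile_plateaus(y, w, direction)$ss
  }
  starts <- expand.grid(L = c(min(x), stats::median(x), max(x)),
                        h = c(0.5, 1, 2))
  best <- NULL
  for (k in seq_len(nrow(starts))) {
    opt <- tryCatch(
      stats::optim(c(starts$L[k], starts$h[k]), objective,
                   method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(factr = 1e3, maxit = 500L)),
      error = function(e) NULL)
    if (is.null(opt)) next
    if (is.null(best) || opt$value < best$value - 1e-12 ||
        (abs(opt$value - best$value) <= 1e-12 &&
         abs(opt$par[2L]) < abs(best$par[2L]))) {
      best <- opt
    }
  }
  if (is.null(best)) return(.failed_fit(series, direction, "no start converged"))

  log_ic50 <- best$par[1L]; hill <- best$par[2L]
  w <- .logistic_w(x, log_ic50, hill)
  pl <- .profile_plateaus(y, w, direction)
  top <- if (direction == "descending") pl$lo else pl$hi
  bottom <- if (direction == "descending") pl$hi else pl$lo
  fitted <- pl$lo * (1 - w) + pl$hi * w
  structure(list(top = top, bottom = bottom, log_ic50 = log_ic50,
                 hill_slope = hill, direction = direction,
                 r2 = 1 - pl$ss / ss_tot, n_points = n,
                 truncated = series$truncated, converged = TRUE,
                 reason = NA_character_, ss_res = pl$ss,
                 x = x, y = y, fitted = fitted),
            class = "dr_fit")
}

#' @rdname fit_dose_response
#' @export
fit_descending <- function(series) fit_dose_response(series, "descending")

#' @rdname fit_dose_response
#' @details `fit_ascending()` expects [truncate_after_max()] to have been
#'   applied already; with fewer than 5 remaining points the fit is skipped
#'   (failed fit, reason `"insufficient points"`), mirroring the rule that a
#'   curve must be defined by at least five data points.
#' @export
fit_ascending <- function(series) fit_dose_response(series, "ascending")

#' @export
print.dr_fit <- function(x, digits = 4, ...) {
  if (!x$converged) {
    cat(sprintf("<dr_fit (%s): FAILED - %s, n = %d>\n", x$direction,
                x$reason, x$n_points))
    return(invisible(x))
  }
  cat(sprintf(
    "<dr_fit (%s): top %.4g, bottom %.4g, LogIC50 %.*f, HillSlope %.*f, R2 %.*f, n %d%s>\n",
    x$direction, x$top, x$bottom, digits, x$log_ic50, digits, x$hill_slope,
    digits, x$r2, x$n_points, if (x$truncated) ", truncated" else ""))
  invisible(x)
}

#' @export
coef.dr_fit <- function(object, ...) {
  c(top = object$top, bottom = object$bottom, log_ic50 = object$log_ic50,
    hill_slope = object$hill_slope)
}

#' @export
predict.dr_fit <- function(object, newdata = NULL, ...) {
  if (!object$converged) stop("cannot predict from a failed fit")
  x <- if (is.null(newdata)) object$x else newdata
  w <- .logistic_w(x, object$log_ic50, object$hill_slope)
  if (object$direction == "descending") {
    object$top * (1 - w) + object$bottom * w
  } else {
    object$bottom * (1 - w) + object$top * w
  }
}

#' @export
residuals.dr_fit <- function(object, ...) object$y - object$fitted

#' @export
summary.dr_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.dr_fit")
}

#' @export
print.summary.dr_fit <- function(x, ...) {
  f <- x$fit
  print(f)
  if (f$converged) {
    cat(sprintf("  pIC50: %.3f   residual SS: %.4g   residual SD: %.4g\n",
                pic50(f), f$ss_res, sqrt(f$ss_res / max(f$n_points - 4, 1))))
  }
  invisible(x)
}

#' @export
plot.dr_fit <- function(x, n_grid = 200, xlab = "log10 [drug] (M)",
                        ylab = "intensity (a.u.)", ...) {
  graphics::plot(x$x, x$y, xlab = xlab, ylab = ylab, pch = 19, ...)
  if (x$converged) {
    xs <- seq(min(x$x), max(x$x), length.out = n_grid)
    graphics::lines(xs, predict(x, xs))
  }
  invisible(x)
}

#' @export
simulate.dr_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!object$converged) stop("cannot simulate from a failed fit")
  if (!is.null(seed)) set.seed(seed)
  sd <- sqrt(object$ss_res / max(object$n_points - 4L, 1L))
  mu <- object$fitted
  out <- as.data.frame(replicate(nsim, pmax(mu + stats::rnorm(length(mu),
                                                              sd = sd), 0)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' pIC50 of a fit
#'
#' `pIC50 = -LogIC50` when concentrations entered the fit as log10 molar.
#'
#' @param fit A `dr_fit`.
#' @return Numeric; `NA` for a failed fit.
#' @export
pic50 <- function(fit) {
  stopifnot(inherits(fit, "dr_fit"))
  if (!fit$converged) return(NA_real_)
  -fit$log_ic50
}

#' Variance-based feature filtration
#'
#' First filtration step for drug-sensitive features: the per-feature sample
#' variance of intensities across all spectra is computed; since most
#' features are unaffected by drug, the variance histogram is right-skewed
#' and its arithmetic mean falls right of the histogram peak. That mean is
#' the threshold; features with variance strictly above it are kept.
#'
#' @param fm A `feature_matrix` with >= 2 samples.
#' @return List: `kept_features` (m/z values), `kept_idx` (column indices),
#'   `variances` (all features), `threshold`.
#' @export
variance_filter <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (nrow(fm$intensities) < 2L) {
    stop("variance filter needs at least 2 samples")
  }
  variances <- unname(apply(fm$intensities, 2L, stats::var))
  threshold <- mean(variances)
  kept_idx <- which(variances > threshold)
  list(kept_features = fm$features[kept_idx], kept_idx = kept_idx,
       variances = variances, threshold = threshold)
}

#' Average technical replicates
#'
#' Collapses the feature matrix to one row per (compound, concentration,
#' biological replicate) cell by arithmetic mean over technical replicates.
#'
#' @param fm A `feature_matrix`.
#' @return A `feature_matrix` with averaged rows and a rebuilt sheet
#'   (`tech_rep` set to 1; `n_tech` column records the group size).
#' @export
average_technical_replicates <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  sh <- fm$sheet
  key <- paste(sh$compound, sh$concentration_molar, sh$bio_rep, sep = "\r")
  groups <- split(seq_len(nrow(sh)), key)
  if (any(lengths(groups) == 0L)) stop("empty replicate group")
  first <- vapply(groups, `[`, integer(1), 1L)
  ord <- order(sh$compound[first], sh$bio_rep[first],
               sh$concentration_molar[first])
  groups <- groups[ord]; first <- first[ord]
  mat <- t(vapply(groups,
                  function(ix) colMeans(fm$intensities[ix, , drop = FALSE]),
                  numeric(ncol(fm$intensities))))
  new_sheet <- data.frame(
    sample_id = paste(sh$compound[first],
                      signif(sh$concentration_molar[first], 6),
                      paste0("b", sh$bio_rep[first]), sep = "_"),
    compound = sh$compound[first],
    concentration_molar = sh$concentration_molar[first],
    tech_rep = 1L, bio_rep = sh$bio_rep[first],
    group = sh$group[first], stringsAsFactors = FALSE)
  out <- new_feature_matrix(mat, fm$features, as_sample_sheet(new_sheet))
  attr(out, "n_tech") <- lengths(groups)
  out
}

# Build the per-bio-rep concentration series of one feature column.
# Vehicle rows (concentration 0) cannot enter a log axis; they either anchor
# the low-dose plateau at log10(lowest nonzero dose) - vehicle_offset
# decades, or are excluded.
.make_series <- function(avg_fm, col, compound, bio_rep,
                         vehicle = c("anchor", "exclude"),
                         vehicle_offset = 2) {
  vehicle <- match.arg(vehicle)
  sh <- avg_fm$sheet
  sel <- sh$compound == compound & sh$bio_rep == bio_rep
  conc <- sh$concentration_molar[sel]
  y <- avg_fm$intensities[sel, col]
  nz <- conc > 0
  if (!any(nz)) return(NULL)
  x <- numeric(length(conc))
  x[nz] <- log10(conc[nz])
  if (any(!nz)) {
    if (vehicle == "exclude") {
      x <- x[nz]; y <- y[nz]
    } else {
      x[!nz] <- log10(min(conc[nz])) - vehicle_offset
    }
  }
  ord <- order(x)
  x <- x[ord]; y <- y[ord]
  if (anyDuplicated(x)) return(NULL)
  conc_series(x, y, feature_mz = avg_fm$features[col], bio_rep = bio_rep)
}

# Best-direction fit of one series: Eq. 1 on the full series vs Eq. 2 on the
# truncated series; the higher-R2 fit wins.
.best_fit <- function(series) {
  fd <- fit_descending(series)
  fa <- fit_ascending(truncate_after_max(series))
  if (fa$r2 > fd$r2) fa else fd
}

#' Rank fits and call markers
#'
#' Given per-feature, per-biological-replicate best fits, sorts features by
#' mean R2 (descending) and flags a feature as a reproducible marker when
#' every replicate fit reaches `r2_min`, at least `n_reps_required`
#' replicates were fitted, and all passing fits share one direction.
#'
#' @param fits Named list: one entry per candidate feature, each a list of
#'   `dr_fit` objects (one per biological replicate).
#' @param r2_min Minimum per-replicate R2 (default 0.9).
#' @param n_reps_required Replicates that must pass (default 3).
#' @param meta Optional named list parallel to `fits` with elements
#'   `feature_mz` and `compound` per entry.
#' @return Data frame, one row per entry of `fits`, ordered by `mean_r2`
#'   descending, with a logical `reproducible` column.
#' @export
rank_and_call_markers <- function(fits, r2_min = 0.9, n_reps_required = 3L,
                                  meta = NULL) {
  rows <- vector("list", length(fits))
  for (i in seq_along(fits)) {
    rep_fits <- fits[[i]]
    r2s <- vapply(rep_fits, function(f) f$r2, numeric(1))
    dirs <- vapply(rep_fits, function(f) f$direction, character(1))
    pic <- vapply(rep_fits, pic50, numeric(1))
    passing <- is.finite(r2s) & r2s >= r2_min
    reproducible <- sum(passing) >= n_reps_required &&
      sum(passing) == length(rep_fits) &&
      length(unique(dirs[passing])) == 1L
    mi <- if (!is.null(meta)) meta[[i]] else
      list(feature_mz = NA_real_, compound = NA_character_)
    rows[[i]] <- data.frame(
      feature_mz = mi$feature_mz, compound = mi$compound,
      direction = names(sort(table(dirs), decreasing = TRUE))[1L],
      n_reps = length(rep_fits),
      min_r2 = min(r2s), mean_r2 = mean(pmax(r2s, 0)),
      mean_pic50 = if (all(is.finite(pic))) mean(pic) else NA_real_,
      sd_pic50 = if (all(is.finite(pic)) && length(pic) > 1L)
        stats::sd(pic) else NA_real_,
      reproducible = reproducible, stringsAsFactors = FALSE)
  }
  report <- if (length(rows)) do.call(rbind, rows) else
    data.frame(feature_mz = numeric(0), compound = character(0),
               direction = character(0), n_reps = integer(0),
               min_r2 = numeric(0), mean_r2 = numeric(0),
               mean_pic50 = numeric(0), sd_pic50 = numeric(0),
               reproducible = logical(0))
  rownames(report) <- names(fits)
  report <- report[order(-report$mean_r2), , drop = FALSE]
  report
}

#' Two-step marker calling
#'
#' The full drug-sensitive feature filtration: (1) variance filtering of the
#' feature matrix, (2) technical-replicate averaging followed by
#' concentration-response fits per biological replicate. Each surviving
#' feature is fitted with the descending sigmoid on the full series and the
#' ascending sigmoid on the max-truncated series; the better fit per
#' replicate counts. A feature is called a marker when, in at least
#' `n_reps_required` biological replicates, its fit reaches `r2_min` with a
#' consistent direction. Features are ranked by mean R2, descending.
#'
#' @param fm Preprocessed `feature_matrix` (TIC-normalized intensities; the
#'   variance filter runs on the non-square-rooted matrix).
#' @param r2_min Minimum per-replicate coefficient of determination
#'   (default 0.9).
#' @param n_reps_required Biological replicates that must pass (default 3).
#' @param exclude_mz m/z values (e.g. the drug's own ion) removed from the
#'   candidate list before fitting.
#' @param exclude_tol Relative matching tolerance for `exclude_mz`
#'   (default 0.002).
#' @param vehicle How concentration-0 rows enter the log-dose axis:
#'   `"anchor"` (at `log10(min dose) - vehicle_offset`) or `"exclude"`.
#' @param vehicle_offset Decades below the lowest nonzero dose for anchoring.
#' @return Object of class `"marker_calls"`: a data frame `report` (one row
#'   per feature x compound, columns feature_mz, compound, direction,
#'   per-rep r2 and pIC50, mean_r2, mean_pic50, reproducible) plus `fits`,
#'   `filter` (the variance-filter result) and `counts`.
#' @export
call_markers <- function(fm, r2_min = 0.9, n_reps_required = 3L,
                         exclude_mz = numeric(0), exclude_tol = 0.002,
                         vehicle = c("anchor", "exclude"),
                         vehicle_offset = 2) {
  vehicle <- match.arg(vehicle)
  stopifnot(inherits(fm, "feature_matrix"))
  vf <- variance_filter(fm)
  keep <- vf$kept_idx
  if (length(exclude_mz) && length(keep)) {
    excl <- vapply(fm$features[keep], function(m)
      any(abs(m - exclude_mz) <= exclude_tol * m), logical(1))
    keep <- keep[!excl]
  }
  avg <- average_technical_replicates(fm)
  sh <- avg$sheet
  compounds <- unique(sh$compound[sh$concentration_molar > 0])

  fits <- list(); meta <- list()
  for (cmp in compounds) {
    bio_reps <- sort(unique(sh$bio_rep[sh$compound == cmp]))
    for (col in keep) {
      rep_fits <- list()
      for (br in bio_reps) {
        ser <- .make_series(avg, col, cmp, br, vehicle, vehicle_offset)
        if (is.null(ser) || length(ser$x) < 5L) next
        rep_fits[[as.character(br)]] <- .best_fit(ser)
      }
      if (!length(rep_fits)) next
      key <- sprintf("%s@%.4f", cmp, fm$features[col])
      fits[[key]] <- rep_fits
      meta[[key]] <- list(feature_mz = fm$features[col], compound = cmp)
    }
  }
  report <- rank_and_call_markers(fits, r2_min = r2_min,
                                  n_reps_required = n_reps_required,
                                  meta = meta)
  structure(list(report = report, fits = fits, filter = vf,
                 counts = list(n_features = ncol(fm$intensities),
                               n_after_variance = length(vf$kept_idx),
                               n_candidates = length(keep),
                               n_markers = sum(report$reproducible))),
            class = "marker_calls")
}

#' @export
print.marker_calls <- function(x, ...) {
  cat(sprintf(
    "<marker_calls: %d features -> %d after variance filter -> %d markers>\n",
    x$counts$n_features, x$counts$n_after_variance, x$counts$n_markers))
  mk <- x$report[x$report$reproducible, , drop = FALSE]
  if (nrow(mk)) {
    print(mk[, c("feature_mz", "compound", "direction", "min_r2",
                 "mean_pic50")], digits = 4)
  }
  invisible(x)
}
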