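# Running window extrema (van Herk block algorithm, O(n) in pure R).
# Windows are clipped at the array edges, i.e. the extreme is taken over the
# available points only.
.running_extreme <- function(x, half_window, maximum = FALSE) {
  n <- length(x)
  w <- 2L * half_window + 1L
  if (w >= 2L * n) {
    v <- if (maximum) max(x) else min(x)
    return(rep(v, n))
  }
  pad <- if (maximum) -Inf else Inf
  cumfun <- if (maximum) cummax else cummin
  pairfun <- if (maximum) pmax else pmin
  # pad left by half_window, right up to a multiple of w; block-wise
  # prefix/suffix cumulative extrema via a w x n_blocks matrix
  extra <- (-(n + 2L * half_window)) %% w
  xp <- c(rep(pad, half_window), x, rep(pad, half_window + extra))
  m <- matrix(xp, nrow = w)
  prefix <- as.vector(apply(m, 2L, cumfun))
  suffix <- as.vector(apply(m[w:1L, , drop = FALSE], 2L, cumfun)[w:1L, ,
                                                                 drop = FALSE])
  i <- seq_len(n)
  pairfun(suffix[i], prefix[i + 2L * half_window])
}

#' Total-ion-current normalization
#'
#' Divides intensities so that their sum (TIC) equals `target`.
#'
#' @param s A `spectrum`.
#' @param target Positive target TIC (default 1).
#' @return Normalized `spectrum`.
#' @export
tic_normalize <- function(s, target = 1.0) {
  stopifnot(inherits(s, "spectrum"), target > 0)
  tic <- sum(s$intensity)
  if (tic <= 0) stop("cannot TIC-normalize an all-zero spectrum")
  s$intensity <- s$intensity * (target / tic)
  s
}

#' Top-Hat baseline estimation and subtraction
#'
#' The baseline is the morphological opening of the intensity profile:
#' grey-scale erosion (running minimum) followed by dilation (running
#' maximum), both with a flat structuring element of `2 * half_window + 1`
#' points. The opening never exceeds the signal, so the corrected intensities
#' are non-negative. Peaks narrower than the structuring element are removed
#' from the baseline; the operation is idempotent.
#'
#' @param s A `spectrum`.
#' @param half_window Structuring-element half width in points (default 75).
#' @return List with `baseline` (numeric vector) and `corrected` (`spectrum`).
#' @export
tophat_baseline <- function(s, half_window = 75L) {
  stopifnot(inherits(s, "spectrum"), half_window >= 1L)
  n <- length(s$mz)
  if (n <= 2L * half_window) {
    stop("spectrum (", n, " points) shorter than structuring element (",
         2L * half_window + 1L, " points)")
  }
  eroded <- .running_extreme(s$intensity, half_window, maximum = FALSE)
  baseline <- .running_extreme(eroded, half_window, maximum = TRUE)
  corrected <- s
  corrected$intensity <- pmax(s$intensity - baseline, 0)
  list(baseline = baseline, corrected = corrected)
}

#' Local noise estimate
#'
#' Robust running noise curve: `1.4826 *` running median of the absolute
#' intensities over a `2 * half_window + 1` window (MAD-consistent scale for
#' Gaussian noise), floored at `1e-12 *` the maximum intensity so that SNR
#' ratios are always defined. On an all-zero spectrum the curve equals the
#' machine-epsilon floor.
#'
#' The window must be several times wider than a peak, so that the median is
#' carried by the inter-peak floor rather than the peak flanks; the default
#' (250 points, i.e. 10 Th at a 0.02 Th grid against sub-Da TOF peak widths)
#' is deliberately much wider than the peak-picking dominance window.
#'
#' @param s A baseline-corrected `spectrum`.
#' @param half_window Running-median half width in points (default 250).
#' @return Strictly positive numeric vector, one value per spectrum point.
#' @export
estimate_noise <- function(s, half_window = 250L) {
  stopifnot(inherits(s, "spectrum"), half_window >= 1L)
  x <- abs(s$intensity)
  k <- min(2L * half_window + 1L, length(x))
  if (k %% 2L == 0L) k <- k - 1L
  noise <- if (k >= 3L) {
    1.4826 * stats::runmed(x, k, endrule = "constant")
  } else {
    1.4826 * x
  }
  floor_val <- 1e-12 * max(x)
  if (floor_val <= 0) floor_val <- .Machine$double.eps
  pmax(noise, floor_val)
}

#' Peak picking
#'
#' Detects strict local maxima: a point is a peak when its intensity exceeds
#' every other point within `half_window` points on either side and its
#' signal-to-noise ratio `intensity / noise` exceeds `snr_min`. Among equal-
#' height points within one window, only the first is reported. The centroid
#' m/z is the m/z of the maximum point; the height its intensity.
#'
#' @param s Baseline-corrected `spectrum`.
#' @param snr_min SNR threshold (default 5, exclusive).
#' @param half_window Dominance half window in points (default 20).
#' @param noise_half_window Half window for [estimate_noise()] (default 250,
#'   much wider than a peak).
#' @return A `peak_list`: list with `mz`, `intensity`, `snr`, `sample_id`.
#' @export
pick_peaks <- function(s, snr_min = 5, half_window = 20L,
                       noise_half_window = 250L) {
  stopifnot(inherits(s, "spectrum"))
  x <- s$intensity
  noise <- estimate_noise(s, noise_half_window)
  runmax <- .running_extreme(x, half_window, maximum = TRUE)
  cand <- which(x > 0 & x == runmax)
  # dominance is undefined within half_window of the spectrum edges
  cand <- cand[cand > half_window & cand <= length(x) - half_window]
  if (length(cand) > 1L) {
    # equal-height ties within one window: keep the first occurrence
    keep <- c(TRUE, diff(cand) > half_window | diff(x[cand]) != 0)
    cand <- cand[keep]
  }
  snr <- x[cand] / noise[cand]
  sel <- snr > snr_min
  structure(list(mz = s$mz[cand[sel]], intensity = x[cand[sel]],
                 snr = snr[sel], sample_id = s$sample_id),
            class = "peak_list")
}

#' @export
print.peak_list <- function(x, ...) {
  cat(sprintf("<peak_list '%s': %d peaks>\n", x$sample_id, length(x$mz)))
  invisible(x)
}

#' Feature matrix constructor
#'
#' Samples-by-features intensity table: one column per m/z bin (strictly
#' increasing bin centers), one row per sample in sample-sheet order; 0 means
#' the peak was absent in that sample.
#'
#' @param intensities Numeric matrix, rows named by sample_id.
#' @param features Numeric vector of bin-center m/z values.
#' @param sheet A `sample_sheet` whose rows match the matrix rows.
#' @return Object of class `"feature_matrix"`.
#' @export
new_feature_matrix <- function(intensities, features, sheet) {
  stopifnot(is.matrix(intensities), length(features) == ncol(intensities),
            nrow(sheet) == nrow(intensities))
  if (is.unsorted(features, strictly = TRUE)) {
    stop("feature m/z must be strictly increasing")
  }
  if (any(intensities < 0)) stop("negative intensities")
  rownames(intensities) <- sheet$sample_id
  colnames(intensities) <- sprintf("%.4f", features)
  structure(list(intensities = intensities, features = features,
                 sheet = sheet),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix: %d samples x %d features, m/z %.1f-%.1f>\n",
              nrow(x$intensities), ncol(x$intensities),
              min(x$features), max(x$features)))
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$intensities)

#' Bin peak lists into a feature matrix
#'
#' Greedy hierarchical binning of the pooled peaks of all samples: the sorted
#' pooled peak set is recursively split at its largest internal m/z gap until
#' every bin satisfies `(max_mz - min_mz) / mean_mz <= tolerance` and holds
#' at most one peak per sample. The bin center is the mean member m/z; matrix
#' cells carry member peak heights (0 when a sample has no peak in a bin).
#'
#' @param lists List of `peak_list` objects (at least one non-empty).
#' @param tolerance Relative bin-width tolerance (default 0.002).
#' @param sheet Optional `sample_sheet` defining row order; defaults to a
#'   minimal sheet in input order.
#' @return A [new_feature_matrix()]; its `"members"` attribute is a list
#'   (one element per bin) of data frames with the member `mz`, `intensity`
#'   and `sample` index of every pooled peak in that bin.
#' @export
bin_peaks <- function(lists, tolerance = 0.002, sheet = NULL) {
  stopifnot(length(lists) >= 1L)
  ids <- vapply(lists, function(p) p$sample_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate sample_id among peak lists")
  pool_mz <- unlist(lapply(lists, `[[`, "mz"), use.names = FALSE)
  if (!length(pool_mz)) stop("no peaks to bin")
  pool_int <- unlist(lapply(lists, `[[`, "intensity"), use.names = FALSE)
  pool_smp <- rep(seq_along(lists),
                  vapply(lists, function(p) length(p$mz), integer(1)))
  ord <- order(pool_mz)
  pool_mz <- pool_mz[ord]; pool_int <- pool_int[ord]; pool_smp <- pool_smp[ord]

  bins <- list()
  stack <- list(c(1L, length(pool_mz)))
  while (length(stack)) {
    seg <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- seg[1L]; j <- seg[2L]
    mzs <- pool_mz[i:j]
    ok <- (mzs[length(mzs)] - mzs[1L]) / mean(mzs) <= tolerance &&
      !anyDuplicated(pool_smp[i:j])
    if (ok || i == j) {
      bins[[length(bins) + 1L]] <- c(i, j)
    } else {
      gaps <- diff(mzs)
      cut <- which.max(gaps) # first largest gap: deterministic
      stack[[length(stack) + 1L]] <- c(i + cut, j)
      stack[[length(stack) + 1L]] <- c(i, i + cut - 1L)
    }
  }
  starts <- vapply(bins, `[`, integer(1), 1L)
  bins <- bins[order(pool_mz[starts])]

  features <- vapply(bins, function(b) mean(pool_mz[b[1L]:b[2L]]), numeric(1))
  mat <- matrix(0, nrow = length(lists), ncol = length(bins))
  for (k in seq_along(bins)) {
    idx <- bins[[k]][1L]:bins[[k]][2L]
    mat[pool_smp[idx], k] <- pool_int[idx]
  }
  if (is.null(sheet)) {
    sheet <- as_sample_sheet(data.frame(
      sample_id = ids, compound = NA_character_, concentration_molar = 0,
      tech_rep = 1L, bio_rep = 1L, stringsAsFactors = FALSE))
  } else {
    pos <- match(sheet$sample_id, ids)
    if (anyNA(pos)) {
      stop("sample sheet lists sample_id absent from peak lists: ",
           sheet$sample_id[which(is.na(pos))[1L]])
    }
    mat <- mat[pos, , drop = FALSE]
  }
  out <- new_feature_matrix(mat, features, sheet)
  attr(out, "members") <- lapply(bins, function(b) {
    idx <- b[1L]:b[2L]
    data.frame(mz = pool_mz[idx], intensity = pool_int[idx],
               sample = pool_smp[idx])
  })
  out
}

#' Full preprocessing pipeline
#'
#' Applies, in order: TIC normalization, Top-Hat baseline subtraction, SNR
#' peak picking, and relative-tolerance peak binning, reducing a set of raw
#' profile spectra to a single feature matrix.
#'
#' @param spectra List of `spectrum` objects.
#' @param sheet `sample_sheet` covering every spectrum's sample_id.
#' @param snr_min Peak-picking SNR threshold (default 5).
#' @param peak_half_window Peak-picking dominance half window, points
#'   (default 20).
#' @param baseline_half_window Top-Hat half window, points (default 75).
#' @param noise_half_window Noise-median half window, points (default 250).
#' @param tolerance Relative binning tolerance (default 0.002).
#' @param tic_target Target TIC after normalization (default 1).
#' @return A `feature_matrix` with a `"log"` attribute of per-stage counts.
#' @export
preprocess_pipeline <- function(spectra, sheet, snr_min = 5,
                                peak_half_window = 20L,
                                baseline_half_window = 75L,
                                noise_half_window = 250L,
                                tolerance = 0.002, tic_target = 1.0) {
  if (!length(spectra)) stop("no spectra supplied")
  ids <- vapply(spectra, function(s) s$sample_id, character(1))
  pos <- match(sheet$sample_id, ids)
  if (anyNA(pos)) {
    stop("sample sheet covers sample_id with no spectrum: ",
         sheet$sample_id[which(is.na(pos))[1L]])
  }
  spectra <- spectra[pos] # canonical order: the sheet's
  peak_lists <- vector("list", length(spectra))
  for (i in seq_along(spectra)) {
    s <- tic_normalize(spectra[[i]], tic_target)
    s <- tophat_baseline(s, baseline_half_window)$corrected
    peak_lists[[i]] <- pick_peaks(s, snr_min = snr_min,
                                  half_window = peak_half_window,
                                  noise_half_window = noise_half_window)
  }
  fm <- bin_peaks(peak_lists, tolerance = tolerance, sheet = sheet)
  attr(fm, "log") <- list(
    n_spectra = length(spectra),
    n_peaks_total = sum(vapply(peak_lists, function(p) length(p$mz),
                               integer(1))),
    n_features = length(fm$features),
    snr_min = snr_min, peak_half_window = peak_half_window,
    baseline_half_window = baseline_half_window, tolerance = tolerance)
  fm
}

#' Serialize a feature matrix to CSV
#'
#' First column `sample_id`, then one column per bin named by the bin-center
#' m/z to 4 decimals.
#'
#' @param fm A `feature_matrix`.
#' @param path Output CSV path.
#' @export
write_feature_matrix <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  df <- data.frame(sample_id = fm$sheet$sample_id, fm$intensities,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
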