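#' Square-root transform of a feature matrix
#'
#' Variance-stabilizing transform applied before multivariate analysis.
#'
#' @param fm A `feature_matrix` with non-negative intensities.
#' @return A `feature_matrix` with element-wise square-rooted intensities.
#' @export
sqrt_transform <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (any(fm$intensities < 0)) stop("negative intensities")
  fm$intensities <- sqrt(fm$intensities)
  fm
}

#' Principal component analysis of a feature matrix
#'
#' PCA by singular value decomposition of the column-centered intensity
#' matrix; variables are centered but not scaled. Scores are `U %*% S`
#' (sample coordinates), loadings the right singular vectors.
#'
#' @param fm A `feature_matrix`.
#' @param n_components Number of components to keep.
#' @return Object of class `"wc_pca"`: list with `scores`
#'   (samples x components), `loadings` (features x components) and
#'   `explained_variance` (fractions of total centered variance).
#' @export
pca_scores <- function(fm, n_components = 2L) {
  stopifnot(inherits(fm, "feature_matrix"))
  x <- fm$intensities
  if (nrow(x) < 2L) stop("PCA needs at least 2 samples")
  max_k <- min(nrow(x) - 1L, ncol(x))
  if (n_components > max_k) {
    stop("n_components (", n_components, ") exceeds min(samples-1, features) = ",
         max_k)
  }
  xc <- sweep(x, 2L, colMeans(x))
  sv <- svd(xc, nu = n_components, nv = n_components)
  d <- sv$d[seq_len(n_components)]
  total_ss <- sum(xc^2)
  scores <- sv$u %*% diag(d, n_components, n_components)
  rownames(scores) <- rownames(x)
  rownames(sv$v) <- colnames(x)
  structure(list(scores = scores, loadings = sv$v,
                 explained_variance = if (total_ss > 0) d^2 / total_ss
                                      else rep(0, n_components)),
            class = "wc_pca")
}

#' @export
print.wc_pca <- function(x, ...) {
  cat(sprintf("<wc_pca: %d samples, %d components, explained %s>\n",
              nrow(x$scores), ncol(x$scores),
              paste(sprintf("%.1f%%", 100 * x$explained_variance),
                    collapse = " + ")))
  invisible(x)
}

#' Cluster-separation score in PCA space
#'
#' Scatter-ratio score of how well labeled groups separate:
#' `J = trace(S_between) / trace(S_within)`, where `S_within` sums the
#' within-group scatter matrices (deviations from group means) and
#' `S_between` the group-size-weighted scatter of group means around the
#' grand mean. Higher values mean better-separated, tighter clusters; the
#' score is invariant to rigid rotation of the score space. Used for ranking
#' experimental setups, so only its monotone ordering matters.
#'
#' @param scores Numeric matrix (samples x components) or a `wc_pca`.
#' @param labels Group labels, one per sample; every group needs >= 2 members.
#' @return Non-negative scalar.
#' @export
j_overlap <- function(scores, labels) {
  if (inherits(scores, "wc_pca")) scores <- scores$scores
  scores <- as.matrix(scores)
  labels <- as.factor(labels)
  stopifnot(nrow(scores) == length(labels))
  if (nlevels(labels) < 2L) stop("need at least 2 groups")
  sizes <- table(labels)
  if (any(sizes < 2L)) {
    stop("every group needs at least 2 members; offending group: ",
         names(sizes)[sizes < 2L][1L])
  }
  grand <- colMeans(scores)
  s_within <- 0
  s_between <- 0
  for (g in levels(labels)) {
    xg <- scores[labels == g, , drop = FALSE]
    mg <- colMeans(xg)
    s_within <- s_within + sum(sweep(xg, 2L, mg)^2)
    s_between <- s_between + nrow(xg) * sum((mg - grand)^2)
  }
  if (s_within <= 0) return(Inf)
  s_between / s_within
}

#' Matrix suppression score
#'
#' Fraction of the total ion current NOT attributable to MALDI matrix ions:
#' `MSE_mod = 1 - sum(intensity within +/- tolerance of any matrix ion) / TIC`,
#' clipped to `[0, 1]`. A value of 1 means complete matrix suppression (all
#' signal is analyte); 0 means pure matrix spectrum. Invariant to global
#' intensity scaling.
#'
#' @param s A `spectrum` with positive TIC.
#' @param matrix_ions Numeric vector of matrix-ion m/z values (e.g. DHB
#'   cluster ions, see [dhb_matrix_ions()]).
#' @param tolerance Relative half-width of each matrix window (default 0.002).
#' @return Scalar in `[0, 1]`.
#' @export
mse_mod <- function(s, matrix_ions = dhb_matrix_ions(), tolerance = 0.002) {
  stopifnot(inherits(s, "spectrum"))
  if (!length(matrix_ions)) stop("empty matrix-ion list")
  stopifnot(tolerance > 0)
  tic <- sum(s$intensity)
  if (tic <= 0) stop("spectrum TIC must be positive")
  in_window <- rep(FALSE, length(s$mz))
  for (m in matrix_ions) {
    in_window <- in_window | abs(s$mz - m) <= tolerance * m
  }
  min(max(1 - sum(s$intensity[in_window]) / tic, 0), 1)
}

#' Default DHB matrix-ion m/z list
#'
#' Cluster ions of 2,5-dihydroxybenzoic acid (DHB) matrix observed in
#' reflector positive mode above m/z 200 (dimer/trimer related species).
#' Override freely for other matrices.
#'
#' @return Numeric vector of m/z values.
#' @export
dhb_matrix_ions <- function() {
  c(273.0394, 309.0601, 331.0420, 427.0660)
}

#' Spot-to-spot repeatability R-squared
#'
#' Coefficient of determination of the least-squares line through the paired
#' per-feature intensities of two samples of a feature matrix; a scatter-plot
#' summary of fingerprint repeatability.
#'
#' @param fm A `feature_matrix`.
#' @param sample_a,sample_b sample_id strings present in `fm`.
#' @return R-squared in `[0, 1]`.
#' @export
repeatability_r2 <- function(fm, sample_a, sample_b) {
  stopifnot(inherits(fm, "feature_matrix"))
  rows <- rownames(fm$intensities)
  ia <- match(sample_a, rows); ib <- match(sample_b, rows)
  if (is.na(ia)) stop("sample not in feature matrix: ", sample_a)
  if (is.na(ib)) stop("sample not in feature matrix: ", sample_b)
  a <- fm$intensities[ia, ]; b <- fm$intensities[ib, ]
  if (stats::var(a) == 0 || stats::var(b) == 0) {
    stop("zero-variance feature vector; repeatability R2 undefined")
  }
  stats::cor(a, b)^2
}
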