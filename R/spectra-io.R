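#' Construct a mass spectrum
#'
#' Profile-mode spectrum: paired m/z (Th, strictly increasing) and intensity
#' (arbitrary units, non-negative) arrays plus a sample identifier. Input
#' pairs are sorted by m/z and duplicate m/z values are collapsed by summing
#' their intensities (profile accumulation).
#'
#' @param mz Numeric vector of m/z values.
#' @param intensity Numeric vector, same length.
#' @param sample_id Sample identifier string.
#' @return Object of class `"spectrum"`.
#' @export
new_spectrum <- function(mz, intensity, sample_id = "") {
  if (length(mz) != length(intensity)) {
    stop("mz and intensity must have the same length")
  }
  if (length(mz) < 1L) stop("empty spectrum")
  if (anyNA(mz) || anyNA(intensity)) stop("NA values in spectrum")
  if (is.unsorted(mz)) {
    ord <- order(mz)
    mz <- mz[ord]; intensity <- intensity[ord]
  }
  if (anyDuplicated(mz)) {
    intensity <- as.vector(rowsum(intensity, group = mz))
    mz <- sort(unique(mz))
  }
  structure(list(mz = mz, intensity = intensity,
                 sample_id = as.character(sample_id)),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum '%s': %d points, m/z %.2f-%.2f, TIC %.4g>\n",
              x$sample_id, length(x$mz), min(x$mz), max(x$mz),
              sum(x$intensity)))
  invisible(x)
}

#' @export
length.spectrum <- function(x) length(x$mz)

#' Read a two-column text spectrum
#'
#' Accepts whitespace- or comma-separated (m/z, intensity) rows, as exported
#' by vendor batch conversion. Lines starting with `#` are skipped. Rows out
#' of order are sorted; duplicate m/z collapse by summing intensity.
#'
#' @param path File path.
#' @param sample_id Sample id to attach; defaults to the file base name.
#' @return A [new_spectrum()] object.
#' @export
read_spectrum_text <- function(path, sample_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) < 2L) stop("spectrum file needs at least 2 data rows: ", path)
  parts <- strsplit(trimws(lines), "[,[:space:]]+")
  n <- lengths(parts)
  bad <- which(n < 2L)
  mz <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 1L)))
  it <- rep(NA_real_, length(parts))
  it[n >= 2L] <- suppressWarnings(
    as.numeric(vapply(parts[n >= 2L], `[[`, "", 2L)))
  bad <- sort(unique(c(bad, which(is.na(mz) | is.na(it)))))
  if (length(bad)) {
    stop("malformed spectrum row at line ", lineno[bad[1L]], " of ", path)
  }
  if (is.null(sample_id)) {
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  }
  new_spectrum(mz, it, sample_id)
}

#' Write a two-column text spectrum
#'
#' @param s A `spectrum`.
#' @param path Output path.
#' @export
write_spectrum_text <- function(s, path) {
  stopifnot(inherits(s, "spectrum"))
  utils::write.table(
    data.frame(mz = s$mz, intensity = s$intensity),
    path, sep = " ", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

.require_mzr <- function() {
  if (!requireNamespace("mzR", quietly = TRUE)) {
    stop("mzML support requires the 'mzR' package")
  }
}

#' Read one spectrum from an mzML file
#'
#' @param path mzML file.
#' @param index 1-based spectrum index within the file.
#' @param sample_id Sample id; defaults to `<basename>#<index>`.
#' @return A [new_spectrum()] object. Centroided files are accepted with a
#'   warning (binning downstream still works on stick data).
#' @export
read_spectrum_mzml <- function(path, index = 1L, sample_id = NULL) {
  .require_mzr()
  if (!file.exists(path)) stop("file not found: ", path)
  h <- mzR::openMSfile(path)
  on.exit(mzR::close(h))
  n <- length(h)
  if (index < 1L || index > n) {
    stop("spectrum index ", index, " out of range (file has ", n, ")")
  }
  hdr <- mzR::header(h, index)
  if (isTRUE(hdr$centroided)) {
    warning("spectrum ", index, " in ", basename(path), " is centroided")
  }
  p <- mzR::peaks(h, index)
  if (is.null(sample_id)) {
    sample_id <- paste0(sub("\\.[^.]*$", "", basename(path)), "#", index)
  }
  new_spectrum(p[, 1L], p[, 2L], sample_id)
}

#' Write spectra to an mzML file
#'
#' @param spectra A `spectrum` or list of them.
#' @param path Output mzML path.
#' @export
write_spectra_mzml <- function(spectra, path) {
  .require_mzr()
  if (inherits(spectra, "spectrum")) spectra <- list(spectra)
  n <- length(spectra)
  hdr <- data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n), msLevel = 1L,
    polarity = 1L,
    peaksCount = vapply(spectra, function(s) length(s$mz), integer(1)),
    totIonCurrent = vapply(spectra, function(s) sum(s$intensity), numeric(1)),
    retentionTime = as.numeric(seq_len(n)),
    basePeakMZ = vapply(spectra, function(s) s$mz[which.max(s$intensity)],
                        numeric(1)),
    basePeakIntensity = vapply(spectra, function(s) max(s$intensity),
                               numeric(1)),
    collisionEnergy = 0, ionisationEnergy = 0,
    lowMZ = vapply(spectra, function(s) min(s$mz), numeric(1)),
    highMZ = vapply(spectra, function(s) max(s$mz), numeric(1)),
    precursorScanNum = 0L, precursorMZ = 0, precursorCharge = 0L,
    precursorIntensity = 0, mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = 0, filterString = NA_character_,
    spectrumId = paste0("scan=", seq_len(n)), centroided = FALSE,
    ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = NA_real_, isolationWindowLowerOffset = NA_real_,
    isolationWindowUpperOffset = NA_real_,
    scanWindowLowerLimit = NA_real_, scanWindowUpperLimit = NA_real_,
    stringsAsFactors = FALSE)
  mzR::writeMSData(lapply(spectra, function(s) cbind(s$mz, s$intensity)),
                   file = path, header = hdr)
  invisible(path)
}

#' Read and validate a sample sheet
#'
#' The sample sheet maps each spectrum to its experimental cell: compound,
#' molar concentration (0 allowed for vehicle control), technical replicate
#' and biological replicate.
#'
#' @param path CSV with header columns `sample_id, compound,
#'   concentration_molar, tech_rep, bio_rep` (optional `group`).
#' @return Validated data frame of class `c("sample_sheet", "data.frame")`.
#' @export
read_sample_sheet <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_sample_sheet(tab)
}

#' @rdname read_sample_sheet
#' @param tab A data frame with the sample-sheet columns.
#' @export
as_sample_sheet <- function(tab) {
  need <- c("sample_id", "compound", "concentration_molar", "tech_rep",
            "bio_rep")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols)) {
    stop("sample sheet is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  tab$sample_id <- as.character(tab$sample_id)
  dup <- tab$sample_id[duplicated(tab$sample_id)]
  if (length(dup)) stop("duplicated sample_id: ", dup[1L])
  conc <- suppressWarnings(as.numeric(tab$concentration_molar))
  if (anyNA(conc)) stop("non-numeric concentration_molar")
  if (any(conc < 0)) stop("negative concentration_molar")
  tab$concentration_molar <- conc
  for (col in c("tech_rep", "bio_rep")) {
    v <- suppressWarnings(as.numeric(tab[[col]]))
    if (anyNA(v) || any(v != round(v))) {
      stop("non-integer ", col, " labels")
    }
    tab[[col]] <- as.integer(v)
  }
  if (is.null(tab$group)) tab$group <- NA_character_
  class(tab) <- c("sample_sheet", "data.frame")
  tab
}
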