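#' Parse an elemental formula
#'
#' Parses a Hill-style elemental formula string such as `"C34H32FeN4O4"` into
#' a named integer vector of element counts. Only elements with bundled
#' isotope data are accepted (see [supported_elements()]).
#'
#' @param formula Character scalar, e.g. `"C42H82NO8P"`.
#' @return Named integer vector of element counts, class `"elemental_formula"`.
#' @examples
#' parse_formula("C34H32FeN4O4")
#' @export
parse_formula <- function(formula) {
  if (!is.character(formula) || length(formula) != 1L || is.na(formula) ||
      !nzchar(formula)) {
    stop("'formula' must be a single non-empty string")
  }
  if (grepl("[^A-Za-z0-9]", formula)) {
    stop("formula contains unsupported characters: ", formula)
  }
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  tokens <- regmatches(formula, list(m))[[1]]
  if (sum(nchar(tokens)) != nchar(formula)) {
    stop("could not parse formula: ", formula)
  }
  counts <- integer(0)
  for (tok in tokens) {
    sym <- sub("[0-9]+$", "", tok)
    n <- sub("^[A-Za-z]+", "", tok)
    n <- if (nzchar(n)) as.integer(n) else 1L
    if (!sym %in% names(.isotopes)) {
      stop("unsupported element '", sym, "' in formula ", formula)
    }
    if (n < 1L) stop("element count must be positive for ", sym)
    counts[sym] <- (if (sym %in% names(counts)) counts[[sym]] else 0L) + n
  }
  structure(counts, class = "elemental_formula")
}

#' Monoisotopic mass of a formula
#'
#' Sum of most-abundant-isotope atomic masses over the elements of a neutral
#' formula.
#'
#' @param f An `elemental_formula` (from [parse_formula()]) or a formula string.
#' @return Monoisotopic mass in Da.
#' @examples
#' monoisotopic_mass("C34H32FeN4O4") # heme B, 616.1773
#' @export
monoisotopic_mass <- function(f) {
  if (is.character(f)) f <- parse_formula(f)
  sum(.mono_masses[names(f)] * as.numeric(f))
}

#' Adduct specifications
#'
#' An adduct specification carries the exact mass delta between the neutral
#' molecule and the observed ion, with explicit electron-mass bookkeeping:
#' `[M+H]+` adds one proton (1.007276 Da), `[M+K]+` adds a potassium atom
#' minus one electron, the radical cation `[M]+.` subtracts one electron,
#' and `[M-H]-` removes a proton.
#'
#' @param name Adduct label, one of the names returned by `default_adducts()`
#'   for the built-in set.
#' @param mass_delta Mass difference (Da) added to the neutral monoisotopic
#'   mass, electron mass included.
#' @param charge Signed integer charge (+1 or -1 for the built-ins).
#' @return An `adduct_spec` object (named list).
#' @export
adduct_spec <- function(name, mass_delta, charge = 1L) {
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(mass_delta), length(mass_delta) == 1L,
            charge %in% c(-1L, 1L))
  structure(list(name = name, mass_delta = mass_delta,
                 charge = as.integer(charge)),
            class = "adduct_spec")
}

#' @rdname adduct_spec
#' @export
default_adducts <- function() {
  k <- .mono_masses[["K"]]
  na <- .mono_masses[["Na"]]
  list(
    `M+H`  = adduct_spec("M+H", PROTON_MASS, 1L),
    `M+Na` = adduct_spec("M+Na", na - ELECTRON_MASS, 1L),
    `M+K`  = adduct_spec("M+K", k - ELECTRON_MASS, 1L),
    `M+.`  = adduct_spec("M+.", -ELECTRON_MASS, 1L),
    `M-H`  = adduct_spec("M-H", -PROTON_MASS, -1L)
  )
}

#' m/z of an adducted ion
#'
#' @param neutral Neutral monoisotopic mass (Da), positive.
#' @param adduct An [adduct_spec()] or the name of a built-in adduct.
#' @return m/z (Th) of the singly charged ion.
#' @examples
#' adduct_mz(monoisotopic_mass("C34H32FeN4O4"), "M+.") # 616.1767
#' @export
adduct_mz <- function(neutral, adduct) {
  if (is.character(adduct)) {
    adducts <- default_adducts()
    if (!adduct %in% names(adducts)) stop("unknown adduct: ", adduct)
    adduct <- adducts[[adduct]]
  }
  stopifnot(inherits(adduct, "adduct_spec"), neutral > 0)
  (neutral + adduct$mass_delta) / abs(adduct$charge)
}

#' Relative mass error in parts per million
#'
#' The denominator is the theoretical mass (convention; the error is not
#' symmetric under swapping arguments, though the difference is second order).
#'
#' @param measured,theoretical m/z values (Th); `theoretical` must be > 0.
#' @return Absolute relative deviation in ppm.
#' @export
ppm_error <- function(measured, theoretical) {
  stopifnot(all(theoretical > 0))
  abs(measured - theoretical) / theoretical * 1e6
}

#' Read a compound table
#'
#' Reads a CSV with columns `name, formula, class, acyl_carbons` (the last
#' may be empty for non-lipids). A small table with the study compounds ships
#' with the package; see the example.
#'
#' @param path CSV file path.
#' @return Data frame with an added `neutral_mass` column.
#' @examples
#' tab <- read_compound_table(system.file("extdata", "compounds.csv",
#'                                        package = "wcmaldi"))
#' @export
read_compound_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "formula", "class")
  if (!all(need %in% names(tab))) {
    stop("compound table must have columns: ", paste(need, collapse = ", "))
  }
  if (is.null(tab$acyl_carbons)) tab$acyl_carbons <- NA_integer_
  tab$acyl_carbons <- suppressWarnings(as.integer(tab$acyl_carbons))
  tab$neutral_mass <- vapply(tab$formula, monoisotopic_mass, numeric(1))
  tab
}

#' Accurate-mass compound search
#'
#' Matches a measured m/z against every (compound, adduct) pair, keeping hits
#' within `max_ppm` and ranking them by ascending ppm error. When
#' `exclude_odd_acyl` is `TRUE`, lipid records carrying an odd `acyl_carbons`
#' count are removed (biosynthetic even-chain rule); records without
#' `acyl_carbons` metadata are never touched by the rule.
#'
#' @param measured Measured m/z (Th).
#' @param table Compound table (see [read_compound_table()]).
#' @param adducts List of [adduct_spec()]s; defaults to the built-in set.
#' @param max_ppm Maximum acceptable mass error, ppm.
#' @param exclude_odd_acyl Apply the odd-carbon exclusion rule.
#' @return Data frame of hits: name, adduct, theoretical_mz, ppm, class;
#'   zero rows when nothing matches.
#' @export
search_compounds <- function(measured, table, adducts = default_adducts(),
                             max_ppm = 3, exclude_odd_acyl = TRUE) {
  stopifnot(nrow(table) >= 1L)
  if (is.null(table$neutral_mass)) {
    table$neutral_mass <- vapply(table$formula, monoisotopic_mass, numeric(1))
  }
  if (exclude_odd_acyl && !is.null(table$acyl_carbons)) {
    odd <- !is.na(table$acyl_carbons) & table$acyl_carbons %% 2L == 1L
    table <- table[!odd, , drop = FALSE]
  }
  hits <- list()
  for (i in seq_len(nrow(table))) {
    for (ad in adducts) {
      th <- adduct_mz(table$neutral_mass[i], ad)
      ppm <- ppm_error(measured, th)
      if (ppm <= max_ppm) {
        hits[[length(hits) + 1L]] <- data.frame(
          name = table$name[i], adduct = ad$name, theoretical_mz = th,
          ppm = ppm, class = table$class[i], stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(name = character(0), adduct = character(0),
                      theoretical_mz = numeric(0), ppm = numeric(0),
                      class = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  # stable ordering: ppm, then name/adduct so table order never matters
  out <- out[order(out$ppm, out$name, out$adduct), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Predicted isotope pattern
#'
#' Exact expansion of the isotope distribution of a formula over natural
#' abundances, aggregated by nucleon number (no fine structure), truncated to
#' the monoisotopic peak and the `n_peaks - 1` following nucleon numbers, and
#' renormalized. Peak m/z values are abundance-weighted mean masses within
#' each nucleon bin; `charge` subtracts/adds electron masses and divides by
#' `|charge|` (0 = neutral molecule).
#'
#' @param f Formula string or `elemental_formula`.
#' @param n_peaks Number of peaks (M, M+1, ...) to return.
#' @param charge Ion charge; 0 for the neutral pattern.
#' @return Data frame with columns `mz` and `abundance` (summing to 1).
#' @export
isotope_pattern <- function(f, n_peaks = 3L, charge = 0L) {
  if (is.character(f)) f <- parse_formula(f)
  stopifnot(n_peaks >= 1L)
  # distribution over nucleon offsets as a named vector offset -> (prob, mass moment)
  conv <- function(a, b) {
    # a, b: lists with $off (int), $p (prob), $m (prob-weighted mass sums)
    off <- outer(a$off, b$off, `+`)
    p <- outer(a$p, b$p)
    m <- outer(a$m, b$p) + outer(a$p, b$m)
    key <- as.vector(off)
    list(off = as.integer(names(tp <- tapply(as.vector(p), key, sum))),
         p = as.vector(tp),
         m = as.vector(tapply(as.vector(m), key, sum)))
  }
  unit <- list(off = 0L, p = 1, m = 0)
  total <- unit
  prune <- function(d, eps = 1e-12) {
    keep <- d$p > eps * max(d$p)
    list(off = d$off[keep], p = d$p[keep], m = d$m[keep])
  }
  for (sym in names(f)) {
    tab <- .isotopes[[sym]]
    atom <- list(off = tab$offset, p = tab$abundance,
                 m = tab$mass * tab$abundance)
    # n-fold self-convolution by binary exponentiation
    n <- as.integer(f[[sym]])
    acc <- unit
    base <- atom
    while (n > 0L) {
      if (n %% 2L == 1L) acc <- prune(conv(acc, base))
      n <- n %/% 2L
      if (n > 0L) base <- prune(conv(base, base))
    }
    total <- prune(conv(total, acc))
  }
  mean_mass <- total$m / total$p
  keep <- total$off >= 0L & total$off <= (n_peaks - 1L)
  off <- total$off[keep]
  p <- total$p[keep]
  mz <- mean_mass[keep]
  ord <- order(off)
  off <- off[ord]; p <- p[ord]; mz <- mz[ord]
  if (charge != 0L) {
    mz <- (mz - sign(charge) * abs(charge) * ELECTRON_MASS) / abs(charge)
  }
  data.frame(mz = mz, abundance = p / sum(p))
}

#' Assign CID neutral-loss fragments
#'
#' For every combination of the named neutral losses up to `depth` (with
#' repetition, e.g. two carboxymethyl side chains), the expected fragment is
#' the precursor m/z minus the summed loss masses; an observed fragment is
#' assigned to the combination whose expected m/z lies within `tol_mda` mDa.
#'
#' @param precursor_mz Precursor ion m/z (Th).
#' @param fragment_mzs Numeric vector of observed fragment m/z values.
#' @param losses Named list/vector of neutral-loss formula strings, e.g.
#'   `c(CH2COOH = "C2H3O2", trimethylamine = "C3H9N")`.
#' @param tol_mda Assignment tolerance in milli-Dalton.
#' @param depth Maximum number of simultaneous losses.
#' @return Data frame: fragment_mz, loss (label, "+"-joined), expected_mz,
#'   error_mda, assigned (logical). Unassigned fragments get NA loss.
#' @export
match_fragments <- function(precursor_mz, fragment_mzs, losses,
                            tol_mda = 1.5, depth = 2L) {
  stopifnot(length(losses) >= 1L, !is.null(names(losses)))
  loss_mass <- vapply(losses, monoisotopic_mass, numeric(1))
  # multisets of losses of size 1..depth
  combos <- list()
  idx <- seq_along(losses)
  grow <- function(prefix, start, d) {
    for (i in idx[idx >= start]) {
      cur <- c(prefix, i)
      combos[[length(combos) + 1L]] <<- cur
      if (d > 1L) grow(cur, i, d - 1L)
    }
  }
  grow(integer(0), 1L, depth)
  combo_mass <- vapply(combos, function(ix) sum(loss_mass[ix]), numeric(1))
  combo_label <- vapply(combos, function(ix)
    paste(names(losses)[ix], collapse = " + "), character(1))
  out <- lapply(fragment_mzs, function(fmz) {
    expected <- precursor_mz - combo_mass
    err <- (fmz - expected) * 1000
    best <- which.min(abs(err))
    if (abs(err[best]) <= tol_mda) {
      data.frame(fragment_mz = fmz, loss = combo_label[best],
                 expected_mz = expected[best], error_mda = err[best],
                 assigned = TRUE, stringsAsFactors = FALSE)
    } else {
      data.frame(fragment_mz = fmz, loss = NA_character_,
                 expected_mz = NA_real_, error_mda = NA_real_,
                 assigned = FALSE, stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, out)
}
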