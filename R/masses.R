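# Physical constants and isotope data.
#
# Monoisotopic masses are the IUPAC/CODATA masses of the most abundant
# isotope of each element. Isotope tables list (nucleon offset from the
# most abundant isotope, exact mass, natural abundance); offsets may be
# negative (e.g. 54Fe below 56Fe).

ELECTRON_MASS <- 0.00054857990907
PROTON_MASS <- 1.007276466621

.isotopes <- list(
  C  = data.frame(offset = c(0L, 1L),
                  mass = c(12.0, 13.00335483507),
                  abundance = c(0.9893, 0.0107)),
  H  = data.frame(offset = c(0L, 1L),
                  mass = c(1.00782503207, 2.01410177812),
                  abundance = c(0.999885, 0.000115)),
  N  = data.frame(offset = c(0L, 1L),
                  mass = c(14.0030740048, 15.0001088989),
                  abundance = c(0.99636, 0.00364)),
  O  = data.frame(offset = c(0L, 1L, 2L),
                  mass = c(15.9949146196, 16.9991317565, 17.9991596129),
                  abundance = c(0.99757, 0.00038, 0.00205)),
  P  = data.frame(offset = 0L, mass = 30.9737619984, abundance = 1.0),
  S  = data.frame(offset = c(0L, 1L, 2L, 4L),
                  mass = c(31.9720711744, 32.9714589098, 33.967867004, 35.96708071),
                  abundance = c(0.9499, 0.0075, 0.0425, 0.0001)),
  K  = data.frame(offset = c(0L, 1L, 2L),
                  mass = c(38.9637064864, 39.963998166, 40.9618252579),
                  abundance = c(0.932581, 0.000117, 0.067302)),
  Na = data.frame(offset = 0L, mass = 22.9897692820, abundance = 1.0),
  Fe = data.frame(offset = c(-2L, 0L, 1L, 2L),
                  mass = c(53.9396090, 55.9349363, 56.9353928, 57.9332744),
                  abundance = c(0.05845, 0.91754, 0.02119, 0.00282)),
  Cl = data.frame(offset = c(0L, 2L),
                  mass = c(34.96885268, 36.96590260),
                  abundance = c(0.7576, 0.2424)),
  Br = data.frame(offset = c(0L, 2L),
                  mass = c(78.9183376, 80.9162906),
                  abundance = c(0.5069, 0.4931)),
  F  = data.frame(offset = 0L, mass = 18.9984031627, abundance = 1.0),
  I  = data.frame(offset = 0L, mass = 126.9044719, abundance = 1.0)
)

.mono_masses <- vapply(.isotopes, function(tab) tab$mass[tab$offset == 0L],
                       numeric(1))

#' Supported chemical elements
#'
#' @return Character vector of element symbols the formula parser accepts.
#' @export
supported_elements <- function() names(.isotopes)
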