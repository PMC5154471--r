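#' Unit conventions
#'
#' All quantities in hybridrd carry fixed units: lengths in micrometres
#' (\eqn{\mu m}), time in seconds, volume concentrations in micromolar
#' (\eqn{\mu M}), surface densities in \eqn{\mu m^{-2}}, and particle counts
#' dimensionless.  Conversion between concentration and number density uses
#' the rounded constant \eqn{1\,\mu M \approx 602} molecules per \eqn{\mu m^3}.
#'
#' @format `MOLECULES_PER_UMOLAR_UM3` is a numeric scalar, 602.
#' @name units
NULL

#' @rdname units
#' @export
MOLECULES_PER_UMOLAR_UM3 <- 602
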