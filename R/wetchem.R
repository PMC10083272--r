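#' Chemistry constants for the pH-differential anthocyanin assay
#'
#' Defaults follow the cyanidin-3-glucoside convention: molecular weight
#' 449.2 g/mol, dilution factor 25, original extract volume 10 ml, molar
#' extinction coefficient 26900 l/(mol cm), a 1 cm path length, and a
#' 0.5 g fresh sample mass. Other anthocyanin references use different
#' MW/epsilon, so all constants are arguments.
#'
#' @param MW molecular weight, g/mol.
#' @param DF dilution factor.
#' @param V original volume, ml.
#' @param epsilon molar extinction coefficient.
#' @param path_length cuvette path length, cm.
#' @param M sample mass, g.
#' @return A named list of class `chem_constants`.
#' @export
chem_constants <- function(MW = 449.2, DF = 25, V = 10, epsilon = 26900,
                           path_length = 1, M = 0.5) {
  x <- list(MW = MW, DF = DF, V = V, epsilon = epsilon,
            path_length = path_length, M = M)
  if (any(unlist(x) <= 0)) stop("all chemistry constants must be > 0", call. = FALSE)
  structure(x, class = "chem_constants")
}

#' pH-differential absorbance
#'
#' `A = (A520 - A700) at pH 1.0  -  (A520 - A700) at pH 4.5`. A negative
#' result (possible under measurement noise near zero pigment) is
#' propagated, not clamped, so downstream noise statistics stay honest.
#'
#' @param a520_ph1,a700_ph1 absorbance at 520/700 nm in the pH 1.0 buffer.
#' @param a520_ph45,a700_ph45 absorbance at 520/700 nm in the pH 4.5 buffer.
#' @return Differential absorbance (vectorized).
#' @export
differential_absorbance <- function(a520_ph1, a700_ph1, a520_ph45, a700_ph45) {
  stopifnot(all(is.finite(c(a520_ph1, a700_ph1, a520_ph45, a700_ph45))))
  (a520_ph1 - a700_ph1) - (a520_ph45 - a700_ph45)
}

#' Total anthocyanin content from differential absorbance
#'
#' `content (mg/g) = A * MW * DF * V / (epsilon * path_length * M)`.
#'
#' @param A differential absorbance (see [differential_absorbance()]).
#' @param constants a [chem_constants()] object.
#' @return Anthocyanin content in mg/g fresh weight (vectorized). Negative
#'   absorbance yields negative content with a warning.
#' @export
anthocyanin_content <- function(A, constants = chem_constants()) {
  stopifnot(inherits(constants, "chem_constants"))
  if (any(A < 0))
    warning("negative differential absorbance: negative content propagated")
  A * constants$MW * constants$DF * constants$V /
    (constants$epsilon * constants$path_length * constants$M)
}

#' Differential absorbance that would produce a given content
#'
#' Exact inverse of [anthocyanin_content()]; used by the synthetic study
#' generator to emit wet-chemistry readings consistent with a scene's true
#' mean content.
#'
#' @param content anthocyanin content, mg/g.
#' @param constants a [chem_constants()] object.
#' @return Differential absorbance.
#' @export
absorbance_for_content <- function(content, constants = chem_constants()) {
  stopifnot(inherits(constants, "chem_constants"))
  content * constants$epsilon * constants$path_length * constants$M /
    (constants$MW * constants$DF * constants$V)
}
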