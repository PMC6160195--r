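#' Anthocyanin concentration by the pH-differential method
#'
#' Spectrophotometric quantification of monomeric anthocyanin as
#' cyanidin-3-glucoside equivalents. The pigment absorbs at 520 nm in its
#' coloured (pH 1.0) form and is colourless at pH 4.5; 700 nm readings
#' correct for haze:
#' \deqn{A = (A_{520} - A_{700})_{pH 1.0} - (A_{520} - A_{700})_{pH 4.5}}
#' \deqn{c \; [mg/L] = \frac{A \cdot MW \cdot DF \cdot 10^3}{\varepsilon \cdot l}}
#' where MW is the molecular weight of cyanidin-3-glucoside (449.2 g/mol),
#' DF the dilution factor, \eqn{\varepsilon} its molar extinction
#' coefficient (default 26900 L mol^-1 cm^-1) and l the path length in cm.
#' A negative net absorbance is clamped to 0 with a warning.
#'
#' @param a520_ph1,a700_ph1,a520_ph45,a700_ph45 Absorbances (vectors
#'   recycle).
#' @param dilution_factor Dilution factor DF (>= 1).
#' @param path_length_cm Cuvette path length l in cm (> 0).
#' @param molecular_weight MW in g/mol (default 449.2).
#' @param extinction_coefficient Molar extinction coefficient in
#'   L mol^-1 cm^-1 (default 26900).
#' @return Concentration in mg/L as cyanidin-3-glucoside equivalents.
#' @export
anthocyanin_concentration <- function(a520_ph1, a700_ph1 = 0,
                                      a520_ph45 = 0, a700_ph45 = 0,
                                      dilution_factor = 1,
                                      path_length_cm = 1,
                                      molecular_weight = 449.2,
                                      extinction_coefficient = 26900) {
  if (any(extinction_coefficient <= 0)) stop("extinction coefficient must be > 0")
  if (any(path_length_cm <= 0)) stop("path length must be > 0")
  stopifnot(all(dilution_factor >= 1),
            all(c(a520_ph1, a700_ph1, a520_ph45, a700_ph45) >= 0))
  a <- (a520_ph1 - a700_ph1) - (a520_ph45 - a700_ph45)
  if (any(a < 0)) {
    warning("negative net absorbance clamped to 0")
    a <- pmax(a, 0)
  }
  a * molecular_weight * dilution_factor * 1000 /
    (extinction_coefficient * path_length_cm)
}
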