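# Goldman-Hodgkin-Katz dilution-potential analysis for a single cation X
# plus Cl-: reversal-potential shifts <-> P_Cl/P_X permeability ratios.
#
# The bi-ionic form used throughout:
#   dErev = rtf * ln[(X_o + Cl_i * r) / (X_i + Cl_o * r)],  r = P_Cl/P_X
# with rtf = RT/F = 25.7 mV at room temperature.

.checkConc <- function(...) {
  v <- c(...)
  if (any(!is.finite(v)) || any(v <= 0))
    stop("concentrations and permeability ratios must be positive")
}

#' Reversal-potential shift from a permeability ratio
#'
#' @param ratio P_Cl/P_X (dimensionless, > 0).
#' @param X_o,X_i extracellular/intracellular cation concentrations, mM.
#' @param Cl_o,Cl_i chloride concentrations, mM; default follow the cation
#'   (mannitol-compensated dilution of the XCl salt).
#' @param rtf RT/F in mV (default 25.7).
#' @return shift of the zero-current reversal potential, mV.
#' @export
ghkShift <- function(ratio, X_o, X_i, Cl_o = X_o, Cl_i = X_i, rtf = 25.7) {
  .checkConc(ratio, X_o, X_i, Cl_o, Cl_i)
  rtf * log((X_o + Cl_i * ratio) / (X_i + Cl_o * ratio))
}

#' Permeability ratio from a reversal-potential shift
#'
#' Closed-form inversion of [ghkShift()]:
#' `r = (X_o - X_i e^(d/rtf)) / (Cl_o e^(d/rtf) - Cl_i)`.
#' The shift must lie strictly between the two single-ion limits
#' `rtf*ln(X_o/X_i)` (r -> 0) and `rtf*ln(Cl_i/Cl_o)` (r -> Inf), else the
#' implied ratio is not positive and an error names the bounds.
#'
#' @param dErev reversal-potential shift, mV.
#' @inheritParams ghkShift
#' @return the permeability ratio P_Cl/P_X.
#' @export
ghkRatio <- function(dErev, X_o, X_i, Cl_o = X_o, Cl_i = X_i, rtf = 25.7) {
  .checkConc(X_o, X_i, Cl_o, Cl_i)
  e <- exp(dErev / rtf)
  lim <- sort(c(rtf * log(X_o / X_i), rtf * log(Cl_i / Cl_o)))
  num <- X_o - X_i * e
  den <- Cl_o * e - Cl_i
  # fully symmetric solutions at zero shift: every ratio fits; report unity
  if (abs(num) < 1e-12 * X_o && abs(den) < 1e-12 * Cl_i) return(1)
  r <- num / den
  if (!is.finite(r) || r <= 0)
    stop(sprintf(paste0("shift %.3g mV outside the achievable range ",
                        "(%.3g, %.3g) mV for these concentrations"),
                 dErev, lim[1], lim[2]))
  r
}

#' Fold change in anion selectivity between two permeability ratios
#'
#' @param ratio_before,ratio_after P_Cl/P_X before and after (e.g. before
#'   and after scrambling activates).
#' @return `ratio_before / ratio_after`.
#' @export
selectivityFoldChange <- function(ratio_before, ratio_after) {
  .checkConc(ratio_before, ratio_after)
  ratio_before / ratio_after
}
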