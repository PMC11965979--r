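#' Physical constants and unit conversions
#'
#' All internal computation uses Angstrom, kcal/mol and picoseconds.
#' `KB_KCAL` is Boltzmann's constant in kcal/(mol K); `KCAL_PER_KJ`
#' converts kJ/mol inputs (common in GROMACS-style configurations) to
#' kcal/mol; `ACC_FACTOR` converts a force in kcal/(mol A) acting on a
#' mass in amu to an acceleration in A/ps^2.
#'
#' @format Named numeric constants.
#' @name constants
#' @keywords internal
NULL

KB_KCAL <- 0.0019872
KCAL_PER_KJ <- 1 / 4.184
ACC_FACTOR <- 418.4

#' Convert an energy-like quantity from kJ/mol to kcal/mol
#'
#' @param x numeric, kJ/mol
#' @return numeric, kcal/mol
#' @examples
#' kj_to_kcal(10000) # 2390.1
#' @export
kj_to_kcal <- function(x) x * KCAL_PER_KJ

# stable log(sum(exp(x)))
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
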