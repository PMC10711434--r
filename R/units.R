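#' Physical constants and unit conversions
#'
#' Boltzmann's constant in kcal/(mol K) and the fixed kJ/mol to kcal/mol
#' conversion used throughout. All free energies are reported in kcal/mol;
#' engine-side work is accepted in kJ/mol and converted on entry.
#'
#' @param temperature Temperature in Kelvin.
#' @return `kT_kcal()` returns k_B T in kcal/mol.
#' @examples
#' kT_kcal(298) # ~0.592 kcal/mol
#' @export
kT_kcal <- function(temperature) {
  stopifnot(is.numeric(temperature), temperature > 0)
  KB_KCAL * temperature
}

#' @rdname kT_kcal
#' @format NULL
#' @export
KB_KCAL <- 0.0019872041

#' @rdname kT_kcal
#' @format NULL
#' @export
KJ_PER_KCAL <- 4.184

#' @rdname kT_kcal
#' @param x Energy values in kJ/mol.
#' @export
kj_to_kcal <- function(x) x / KJ_PER_KCAL

# numerically stable log(sum(exp(x)))
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}
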