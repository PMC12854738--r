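## Physical constants. All package energies are kcal/mol, temperatures K,
## rates s^-1.

#' Physical constants used throughout the package
#'
#' `kB_kcal` is the Boltzmann constant in kcal mol^-1 K^-1; rate prefactors
#' use the SI Boltzmann and Planck constants so that `kT_over_h()` is in s^-1.
#'
#' @keywords internal
#' @name constants
NULL

.kB_kcal <- 0.0019872041      # kcal mol^-1 K^-1
.kB_J    <- 1.380649e-23      # J K^-1
.h_J     <- 6.62607015e-34    # J s

#' Thermal energy in kcal/mol
#' @param temperature Temperature in K.
#' @return k_B T in kcal/mol.
#' @export
kT_kcal <- function(temperature) {
  stopifnot(is.numeric(temperature))
  if (any(temperature <= 0)) stop("temperature must be positive")
  .kB_kcal * temperature
}

#' Eyring frequency prefactor k_B T / h
#' @param temperature Temperature in K.
#' @return k_B T / h in s^-1.
#' @export
kT_over_h <- function(temperature) {
  if (any(temperature <= 0)) stop("temperature must be positive")
  .kB_J * temperature / .h_J
}

## numerically stable log(sum(exp(x)))
logsumexp <- function(x) {
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}
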