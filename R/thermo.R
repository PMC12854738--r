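## Harmonic-superposition thermodynamics.
##
## The total partition function is approximated as a sum of per-minimum
## classical harmonic-well contributions,
##   Z = sum_i exp(-V_i / kT) / (pg_i * prod_j (beta h nu_ij)),
## so the log-weight of minimum i, after dropping the kappa*ln(beta h) term
## common to all minima, is
##   ln w_i = -V_i / kT - logProd_i - ln(pg_i).
## Only free-energy DIFFERENCES between minima are meaningful outputs.

#' Harmonic log-weight of minima at a temperature
#'
#' @param net A `ktn` object (or any data.frame with `V`, `logProd`,
#'   `pgOrder` columns).
#' @param temperature Temperature in K (> 0).
#' @return Numeric vector of dimensionless log-weights, one per minimum.
#'   Terms common to all minima (kappa * ln(beta h)) are dropped.
#' @export
log_weight <- function(net, temperature) {
  tab <- if (inherits(net, "ktn")) net$minima else as.data.frame(net)
  if (any(temperature <= 0)) stop("temperature must be positive")
  -tab$V / kT_kcal(temperature) - tab$logProd - log(tab$pgOrder)
}

## log-weight of the transition-state ensemble rows (kappa - 1 modes)
.log_weight_ts <- function(ts, temperature) {
  -ts$V / kT_kcal(temperature) - ts$logProd - log(ts$pgOrder)
}

#' Equilibrium occupation probabilities and free energies
#'
#' @inheritParams log_weight
#' @return data.frame with columns `id`, `p` (occupation probability,
#'   normalised to 1) and `F` (free energy in kcal/mol up to a common
#'   additive constant); attribute `"temperature"` carries T.
#' @export
equilibrium_occupations <- function(net, temperature) {
  stopifnot(inherits(net, "ktn"))
  if (n_minima(net) == 0L) stop("KTN has no minima")
  lw <- log_weight(net, temperature)
  lse <- logsumexp(lw)
  out <- data.frame(id = net$minima$id,
                    p = exp(lw - lse),
                    F = -kT_kcal(temperature) * lw)
  attr(out, "temperature") <- temperature
  out
}

#' Heat-capacity curve from the harmonic superposition
#'
#' Classical harmonic wells contribute `kappa * k_B` each; the landscape adds
#' the inter-well potential-energy fluctuation term:
#'   C_v(T) / k_B = kappa + (<V^2> - <V>^2) / (k_B T)^2,
#' with averages over the equilibrium occupations at T. Convergence of
#' landscape sampling is conventionally monitored through this curve.
#'
#' @param net A `ktn` with `kappa` set.
#' @param T_grid Temperatures in K.
#' @return data.frame with columns `T` and `Cv` (units of k_B).
#' @export
heat_capacity_curve <- function(net, T_grid) {
  stopifnot(inherits(net, "ktn"))
  if (is.na(net$kappa)) stop("kappa is unset on this KTN")
  if (any(T_grid <= 0)) stop("temperatures must be positive")
  cv <- vapply(T_grid, function(tt) {
    occ <- equilibrium_occupations(net, tt)
    v <- net$minima$V
    m1 <- sum(occ$p * v)
    var <- sum(occ$p * (v - m1)^2)
    net$kappa + var / kT_kcal(tt)^2
  }, numeric(1))
  data.frame(T = T_grid, Cv = cv)
}

#' Mean potential energy curve (finite-difference oracle support)
#'
#' `<V>(T) + kappa * k_B * T`: the total internal energy of the classical
#' harmonic superposition up to a constant; its temperature derivative is the
#' heat capacity.
#'
#' @inheritParams heat_capacity_curve
#' @return data.frame with columns `T` and `U` (kcal/mol).
#' @export
internal_energy_curve <- function(net, T_grid) {
  stopifnot(inherits(net, "ktn"))
  if (is.na(net$kappa)) stop("kappa is unset on this KTN")
  u <- vapply(T_grid, function(tt) {
    occ <- equilibrium_occupations(net, tt)
    sum(occ$p * net$minima$V) + net$kappa * kT_kcal(tt)
  }, numeric(1))
  data.frame(T = T_grid, U = u)
}
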