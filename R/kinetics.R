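## Harmonic transition-state-theory kinetics.
##
## Rate constants between adjacent minima follow harmonic TST,
##   k(a -> b) = (pg_a / pg_ts) * exp(logProd_a - logProd_ts)
##               * exp(-(V_ts - V_a) / kT),
## which satisfies detailed balance with the harmonic superposition weights
## by construction. Effective two-state rates are obtained from mean first
## passage times; Eyring conversions relate rates to free-energy barriers.

#' Harmonic TST rate through one transition state
#'
#' @param net A `ktn` object.
#' @param from Minimum id (must be one of the two minima the transition
#'   state connects).
#' @param ts_id Transition-state id.
#' @param temperature Temperature in K.
#' @return Rate constant in s^-1.
#' @export
tst_rate <- function(net, from, ts_id, temperature) {
  stopifnot(inherits(net, "ktn"))
  if (temperature <= 0) stop("temperature must be positive")
  ts <- net$ts[net$ts$id == ts_id, ]
  if (nrow(ts) != 1L) stop("no transition state with id ", ts_id)
  if (!(from %in% c(ts$min1, ts$min2)))
    stop("transition state ", ts_id, " is not adjacent to minimum ", from)
  m <- net$minima[from, ]
  (m$pgOrder / ts$pgOrder) * exp(m$logProd - ts$logProd) *
    exp(-(ts$V - m$V) / kT_kcal(temperature))
}

#' Split a two-state exchange rate into forward and reverse rates
#'
#' For two-state chemical exchange, `k_ex = k_f + k_r` and the minor-state
#' population fixes the split: `k_f = p_minor * k_ex`,
#' `k_r = (1 - p_minor) * k_ex`.
#'
#' @param k_ex Exchange rate in s^-1.
#' @param p_minor Minor-state (excited-state) equilibrium population,
#'   strictly between 0 and 1.
#' @return Named list with `k_f` and `k_r` (s^-1).
#' @export
exchange_to_microrates <- function(k_ex, p_minor) {
  if (k_ex <= 0) stop("k_ex must be positive")
  if (p_minor <= 0 || p_minor >= 1) stop("p_minor must be in (0, 1)")
  list(k_f = p_minor * k_ex, k_r = (1 - p_minor) * k_ex)
}

#' Eyring barrier from a rate constant (and back)
#'
#' `eyring_barrier()` converts a first-order rate constant into an effective
#' free-energy barrier with transmission coefficient 1:
#' `dG = k_B T ln(k_B T / (h k))`. `barrier_to_rate()` is the exact inverse.
#'
#' @param k Rate constant in s^-1 (> 0).
#' @param temperature Temperature in K.
#' @return Barrier in kcal/mol (`eyring_barrier`) or rate in s^-1
#'   (`barrier_to_rate`).
#' @export
eyring_barrier <- function(k, temperature) {
  if (any(k <= 0)) stop("rate constant must be positive")
  kT_kcal(temperature) * log(kT_over_h(temperature) / k)
}

#' @rdname eyring_barrier
#' @param dG Barrier in kcal/mol.
#' @export
barrier_to_rate <- function(dG, temperature) {
  kT_over_h(temperature) * exp(-dG / kT_kcal(temperature))
}

#' Build the full inter-minimum rate matrix
#'
#' Returns the master-equation generator `K` with `K[b, a]` the rate from
#' minimum `a` to minimum `b` (columns index the source state), summed over
#' all transition states connecting the pair; the diagonal holds minus the
#' column escape sums so that columns sum to zero. Degenerate-rearrangement
#' transition states are excluded.
#'
#' @param net A `ktn` object.
#' @param temperature Temperature in K.
#' @return A square numeric matrix with attribute `"temperature"`.
#' @export
build_rate_matrix <- function(net, temperature) {
  stopifnot(inherits(net, "ktn"))
  n <- n_minima(net)
  K <- matrix(0, n, n)
  ets <- .edge_ts(net)
  if (nrow(ets)) {
    for (r in seq_len(nrow(ets))) {
      a <- ets$min1[r]; b <- ets$min2[r]
      K[b, a] <- K[b, a] + tst_rate(net, a, ets$id[r], temperature)
      K[a, b] <- K[a, b] + tst_rate(net, b, ets$id[r], temperature)
    }
  }
  diag(K) <- -colSums(K)
  attr(K, "temperature") <- temperature
  K
}

#' Effective two-state rates between two sets of minima
#'
#' The rate from set A to set B is the inverse of the mean first passage
#' time to an absorbing B, averaged over starting minima in A with
#' equilibrium weights conditioned on A; the reverse rate is computed
#' analogously. Barriers are the Eyring conversions of the two rates.
#'
#' @param net A `ktn` object.
#' @param setA,setB Disjoint, non-empty vectors of minimum ids.
#' @param temperature Temperature in K.
#' @return List with `k_f`, `k_r` (s^-1), `dG_f`, `dG_r` (kcal/mol),
#'   `mfpt_AB`, `mfpt_BA` (s) and `temperature`.
#' @export
two_state_rates <- function(net, setA, setB, temperature) {
  stopifnot(inherits(net, "ktn"))
  setA <- as.integer(setA); setB <- as.integer(setB)
  if (!length(setA) || !length(setB)) stop("setA and setB must be non-empty")
  if (length(intersect(setA, setB))) stop("setA and setB must be disjoint")
  K <- build_rate_matrix(net, temperature)
  occ <- equilibrium_occupations(net, temperature)
  mfpt_AB <- .mean_fpt(K, occ$p, from = setA, to = setB)
  mfpt_BA <- .mean_fpt(K, occ$p, from = setB, to = setA)
  k_f <- 1 / mfpt_AB
  k_r <- 1 / mfpt_BA
  list(k_f = k_f, k_r = k_r,
       dG_f = eyring_barrier(k_f, temperature),
       dG_r = eyring_barrier(k_r, temperature),
       mfpt_AB = mfpt_AB, mfpt_BA = mfpt_BA,
       temperature = temperature)
}

## equilibrium-weighted mean first passage time from `from` to absorbing `to`
.mean_fpt <- function(K, p, from, to) {
  n <- nrow(K)
  keep <- setdiff(seq_len(n), to)
  A <- t(K)[keep, keep, drop = FALSE]
  tau <- tryCatch(solve(A, rep(-1, length(keep))),
                  error = function(e) {
                    stop("target set unreachable from some source minima ",
                         "(singular first-passage system): ",
                         conditionMessage(e))
                  })
  tau_full <- numeric(n)
  tau_full[keep] <- tau
  w <- p[from] / sum(p[from])
  sum(w * tau_full[from])
}

#' Fastest path between two minima
#'
#' Finds the path maximising the product of branching probabilities
#' `P(a -> b) = k(a -> b) / sum_c k(a -> c)` (equivalently minimising the sum
#' of `-ln P` over directed steps), the "best path" notion of discrete path
#' sampling. Waiting times are ignored. Ties between parallel transition
#' states are broken by the highest individual rate, then the smallest
#' transition-state id; ties between minima by the smallest id.
#'
#' @param net A `ktn` object.
#' @param from,to Minimum ids.
#' @param temperature Temperature in K.
#' @return data.frame with columns `step`, `min` (minimum id) and `ts`
#'   (transition-state id taken to arrive there; `NA` for the first row).
#' @export
fastest_path <- function(net, from, to, temperature) {
  stopifnot(inherits(net, "ktn"))
  n <- n_minima(net)
  if (from == to)
    return(data.frame(step = 1L, min = as.integer(from), ts = NA_integer_))
  K <- build_rate_matrix(net, temperature)
  esc <- -diag(K)
  ## directed edge weights -ln P between adjacent pairs
  W <- matrix(Inf, n, n)
  adj <- which(K > 0 & row(K) != col(K), arr.ind = TRUE)
  for (r in seq_len(nrow(adj))) {
    b <- adj[r, 1]; a <- adj[r, 2]
    W[a, b] <- -log(K[b, a] / esc[a])
  }
  g <- igraph::make_empty_graph(n = n, directed = TRUE)
  if (nrow(adj)) {
    g <- igraph::add_edges(g, rbind(adj[, 2], adj[, 1]))
    igraph::E(g)$weight <- W[cbind(adj[, 2], adj[, 1])]
  }
  d_to <- igraph::distances(g, to = to, mode = "out",
                            weights = igraph::E(g)$weight)[, 1]
  if (!is.finite(d_to[from]))
    stop("no path from minimum ", from, " to minimum ", to)
  ## greedy reconstruction with deterministic tie-breaks
  path <- from
  cur <- from
  while (cur != to) {
    nb <- which(is.finite(W[cur, ]))
    tot <- W[cur, nb] + d_to[nb]
    best <- nb[tot <= min(tot) + 1e-12]
    nxt <- min(best)
    path <- c(path, nxt)
    cur <- nxt
  }
  ## transition state taken on each step: highest rate, then smallest id
  ts_ids <- c(NA_integer_, vapply(seq_len(length(path) - 1L), function(i) {
    a <- path[i]; b <- path[i + 1L]
    ets <- .edge_ts(net)
    cand <- ets[(ets$min1 == a & ets$min2 == b) |
                (ets$min1 == b & ets$min2 == a), ]
    rates <- vapply(cand$id, function(id)
      tst_rate(net, a, id, temperature), numeric(1))
    cand$id[order(-rates, cand$id)][1]
  }, integer(1)))
  data.frame(step = seq_along(path), min = as.integer(path), ts = ts_ids)
}

#' Base-pair annotation along a path
#'
#' Annotates the base pairing of every minimum on a path (as returned by
#' [fastest_path()]) from its referenced PDB structure.
#'
#' @param net A `ktn` whose minima carry `coordsRef` paths.
#' @param path data.frame as returned by [fastest_path()], or a vector of
#'   minimum ids.
#' @param ... Passed on to [annotate_base_pairs()].
#' @return data.frame with columns `step`, `min`, and the columns of
#'   [annotate_base_pairs()].
#' @export
path_annotation <- function(net, path, ...) {
  stopifnot(inherits(net, "ktn"))
  ids <- if (is.data.frame(path)) path$min else as.integer(path)
  out <- lapply(seq_along(ids), function(i) {
    ref <- net$minima$coordsRef[ids[i]]
    if (is.na(ref) || !file.exists(ref))
      stop("no structure available for minimum ", ids[i])
    bp <- annotate_base_pairs(bio3d::read.pdb(ref, verbose = FALSE), ...)
    if (nrow(bp)) cbind(step = i, min = ids[i], bp)
    else cbind(data.frame(step = integer(0), min = integer(0)), bp)
  })
  do.call(rbind, out)
}
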