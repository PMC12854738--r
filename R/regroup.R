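## Free-energy regrouping of minima into kinetic groups.
##
## At a temperature T, minima are lumped whenever the free-energy barrier
## separating them falls below a threshold in BOTH directions. Group free
## energies are -kT * logsumexp over member harmonic weights; the
## transition-state ensemble between two groups is pooled the same way over
## every transition state connecting them, so parallel-path entropy is
## included. Barriers between surviving groups are reported on the Eyring
## scale (directly comparable with barriers derived from experimental rates).

#' Regroup minima into free-energy groups
#'
#' Iteratively merges any two groups I, J whose pooled transition-state
#' ensemble lies less than `dG_thresh` above BOTH group free energies, i.e.
#' merge when `min(F_ts - F_I, F_ts - F_J) < dG_thresh` holds in each
#' direction, recomputing free energies by logsumexp after every merge until
#' a fixed point. Among qualifying pairs the one with the smallest larger
#' barrier is merged first (a deterministic order; the fixed point is
#' checked for merge-order independence in the test-suite).
#'
#' @param net A `ktn` object.
#' @param temperature Temperature in K.
#' @param dG_thresh Regrouping threshold in kcal/mol (>= 0).
#' @return A `grouped_network`: list with `groups` (list of member id
#'   vectors), `assignment` (group index per minimum), `F_group` (kcal/mol,
#'   same additive convention as [equilibrium_occupations()]), `F_ts`
#'   (matrix of pooled inter-group transition-state free energies, `Inf`
#'   where non-adjacent), `temperature`, `dG_thresh` and the source `ktn`.
#' @export
regroup_free_energy <- function(net, temperature, dG_thresh) {
  stopifnot(inherits(net, "ktn"))
  if (dG_thresh < 0) stop("dG_thresh must be >= 0")
  kT <- kT_kcal(temperature)
  off <- kT * log(kT_over_h(temperature))  # kappa-1 vs kappa mode offset:
  ## puts pooled TS free energies on the Eyring scale, so barriers
  ## F_ts - F_group are directly comparable with exchange-derived barriers
  lw_min <- log_weight(net, temperature)
  ets <- .edge_ts(net)
  lw_ts <- .log_weight_ts(ets, temperature)

  assignment <- seq_len(n_minima(net))
  repeat {
    groups <- split(seq_along(assignment), assignment)
    gid <- as.integer(names(groups))
    ng <- length(groups)
    lse_g <- vapply(groups, function(m) logsumexp(lw_min[m]), numeric(1))
    F_g <- -kT * lse_g
    ## pooled TS free energy between groups
    gi <- match(assignment[ets$min1], gid)
    gj <- match(assignment[ets$min2], gid)
    lo <- pmin(gi, gj); hi <- pmax(gi, gj)
    Fts <- matrix(Inf, ng, ng)
    if (nrow(ets)) {
      for (key in unique(paste(lo, hi))) {
        idx <- which(paste(lo, hi) == key & lo != hi)
        if (!length(idx)) next
        i <- lo[idx[1]]; j <- hi[idx[1]]
        Fts[i, j] <- Fts[j, i] <- -kT * logsumexp(lw_ts[idx]) + off
      }
    }
    ## find qualifying pairs (both-direction criterion)
    cand <- which(upper.tri(Fts) & is.finite(Fts), arr.ind = TRUE)
    if (!nrow(cand)) break
    bf <- Fts[cand] - F_g[cand[, 1]]
    br <- Fts[cand] - F_g[cand[, 2]]
    ok <- bf < dG_thresh & br < dG_thresh
    if (!any(ok)) break
    cand <- cand[ok, , drop = FALSE]
    worst <- pmax(bf[ok], br[ok])
    pick <- order(worst, cand[, 1], cand[, 2])[1]
    i <- cand[pick, 1]; j <- cand[pick, 2]
    assignment[assignment == gid[j]] <- gid[i]
  }
  groups <- unname(split(seq_along(assignment), assignment))
  ## renumber groups by their lowest member id
  groups <- groups[order(vapply(groups, min, numeric(1)))]
  assignment <- integer(length(assignment))
  for (g in seq_along(groups)) assignment[groups[[g]]] <- g
  ng <- length(groups)
  F_g <- vapply(groups, function(m) -kT * logsumexp(lw_min[m]), numeric(1))
  Fts <- matrix(Inf, ng, ng)
  if (nrow(ets)) {
    gi <- assignment[ets$min1]; gj <- assignment[ets$min2]
    lo <- pmin(gi, gj); hi <- pmax(gi, gj)
    for (key in unique(paste(lo, hi))) {
      idx <- which(paste(lo, hi) == key & lo != hi)
      if (!length(idx)) next
      i <- lo[idx[1]]; j <- hi[idx[1]]
      Fts[i, j] <- Fts[j, i] <- -kT * logsumexp(lw_ts[idx]) + off
    }
  }
  structure(list(groups = groups, assignment = assignment, F_group = F_g,
                 F_ts = Fts, temperature = temperature,
                 dG_thresh = dG_thresh, ktn = net),
            class = "grouped_network")
}

#' @export
print.grouped_network <- function(x, ...) {
  cat(sprintf("<grouped_network> %d groups over %d minima at T = %g K (threshold %g kcal/mol)\n",
              length(x$groups), length(x$assignment), x$temperature,
              x$dG_thresh))
  invisible(x)
}

#' Group containing a given minimum
#' @param gn A `grouped_network`.
#' @param min_id Minimum id.
#' @return Group index.
#' @export
group_of <- function(gn, min_id) gn$assignment[min_id]

#' Equilibrium group occupation probabilities
#' @param gn A `grouped_network`.
#' @return Numeric vector, one probability per group.
#' @export
group_occupations <- function(gn) {
  kT <- kT_kcal(gn$temperature)
  lw <- -gn$F_group / kT
  exp(lw - logsumexp(lw))
}

#' Effective free-energy barriers between two groups
#'
#' The forward barrier is the pooled transition-state free energy minus the
#' free energy of the source group, reported on the Eyring scale so that
#' `barrier_to_rate()` of the result is the harmonic-TST inter-group rate.
#'
#' @param gn A `grouped_network`.
#' @param groupA,groupB Group indices (see [group_of()]).
#' @return Named list `dG_f` (A to B), `dG_r` (B to A), in kcal/mol.
#' @export
effective_barriers <- function(gn, groupA, groupB) {
  Fts <- gn$F_ts[groupA, groupB]
  if (!is.finite(Fts))
    stop("groups ", groupA, " and ", groupB, " share no transition state; ",
         "use two_state_rates() for path-mediated kinetics")
  list(dG_f = Fts - gn$F_group[groupA],
       dG_r = Fts - gn$F_group[groupB])
}

#' Quotient KTN of a grouped network
#'
#' Collapses each group to one node at its group free energy and each
#' adjacent group pair to one transition state at the pooled ensemble free
#' energy (Eyring scale, consistent with [effective_barriers()]). Useful for
#' free-energy disconnectivity trees.
#'
#' @param gn A `grouped_network`.
#' @return A `ktn` whose `V` column holds free energies in kcal/mol.
#' @export
quotient_ktn <- function(gn) {
  ng <- length(gn$groups)
  mins <- data.frame(V = gn$F_group, logProd = 0, pgOrder = 1)
  pairs <- which(upper.tri(gn$F_ts) & is.finite(gn$F_ts), arr.ind = TRUE)
  ts <- if (nrow(pairs)) {
    data.frame(V = gn$F_ts[pairs], logProd = 0, pgOrder = 1,
               min1 = pairs[, 1], min2 = pairs[, 2])
  } else NULL
  ktn(mins, ts, kappa = gn$ktn$kappa)
}

#' Scan regrouping thresholds
#'
#' Runs [regroup_free_energy()] over a grid of thresholds and reports the
#' effective barriers between the groups containing two anchor minima. Used
#' to locate the threshold reproducing a target pair of barriers when no
#' threshold is prescribed.
#'
#' @param net A `ktn` object.
#' @param temperature Temperature in K.
#' @param thresholds Numeric vector of thresholds (kcal/mol).
#' @param anchorA,anchorB Minimum ids anchoring the two states of interest.
#' @return data.frame with columns `threshold`, `n_groups`, `dG_f`, `dG_r`
#'   (NA when the anchors share a group or their groups are not adjacent).
#' @export
regroup_scan <- function(net, temperature, thresholds, anchorA, anchorB) {
  rows <- lapply(thresholds, function(th) {
    gn <- regroup_free_energy(net, temperature, th)
    ga <- group_of(gn, anchorA); gb <- group_of(gn, anchorB)
    if (ga == gb || !is.finite(gn$F_ts[ga, gb])) {
      data.frame(threshold = th, n_groups = length(gn$groups),
                 dG_f = NA_real_, dG_r = NA_real_)
    } else {
      b <- effective_barriers(gn, ga, gb)
      data.frame(threshold = th, n_groups = length(gn$groups),
                 dG_f = b$dG_f, dG_r = b$dG_r)
    }
  })
  do.call(rbind, rows)
}
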