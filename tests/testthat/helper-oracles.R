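## Independent oracles used across the suite. These deliberately avoid the
## package's own code paths (and, where possible, igraph) so that agreement
## is informative.

kB <- 0.0019872041

## brute-force reachability under a transition-state energy filter:
## breadth-first search over the raw ts table
bf_superbasin <- function(net, E) {
  n <- n_minima(net)
  ts <- net$ts[net$ts$min1 != net$ts$min2 & net$ts$V <= E, , drop = FALSE]
  lab <- rep(NA_integer_, n)
  for (start in seq_len(n)) {
    if (net$minima$V[start] > E || !is.na(lab[start])) next
    comp <- start
    frontier <- start
    while (length(frontier)) {
      nxt <- unique(c(ts$min2[ts$min1 %in% frontier],
                      ts$min1[ts$min2 %in% frontier]))
      nxt <- setdiff(nxt, comp)
      comp <- c(comp, nxt)
      frontier <- nxt
    }
    lab[comp] <- min(comp)
  }
  ## minima above the threshold stay excluded even if an edge touches them
  lab[net$minima$V > E] <- NA_integer_
  lab
}

## exact minimax path value (lowest possible maximum transition-state
## energy over all simple paths) by depth-first enumeration
bf_minimax <- function(net, a, b) {
  ts <- net$ts[net$ts$min1 != net$ts$min2, , drop = FALSE]
  best <- Inf
  recurse <- function(cur, visited, worst) {
    if (worst >= best) return()
    if (cur == b) { best <<- worst; return() }
    rows <- which(ts$min1 == cur | ts$min2 == cur)
    for (r in rows) {
      nxt <- if (ts$min1[r] == cur) ts$min2[r] else ts$min1[r]
      if (nxt %in% visited) next
      recurse(nxt, c(visited, nxt), max(worst, ts$V[r]))
    }
  }
  recurse(a, a, -Inf)
  best
}

## enumerate all simple paths from a to b and score each by the sum of
## -ln(branching probability); returns the best score and one best path
bf_fastest_path <- function(net, a, b, temperature) {
  K <- build_rate_matrix(net, temperature)
  esc <- -diag(K)
  n <- n_minima(net)
  best <- list(score = Inf, path = NULL)
  recurse <- function(cur, visited, score) {
    if (score >= best$score) return()
    if (cur == b) { best <<- list(score = score, path = visited); return() }
    for (nxt in seq_len(n)) {
      if (nxt %in% visited || K[nxt, cur] <= 0) next
      recurse(nxt, c(visited, nxt), score - log(K[nxt, cur] / esc[cur]))
    }
  }
  recurse(a, a, 0)
  best
}

## relaxation-rate oracle: propagate the master equation with a dense
## matrix exponential and fit the slow log-linear decay of the A population
expm_rate_oracle <- function(net, setA, setB, temperature) {
  K <- build_rate_matrix(net, temperature)
  occ <- equilibrium_occupations(net, temperature)
  p0 <- numeric(n_minima(net))
  p0[setA] <- occ$p[setA] / sum(occ$p[setA])
  guess <- two_state_rates(net, setA, setB, temperature)
  kex <- guess$k_f + guess$k_r
  times <- exp(seq(log(0.05 / kex), log(2 / kex), length.out = 20))
  pA <- vapply(times, function(t)
    sum((Matrix::expm(K * t) %*% p0)[setA]), numeric(1))
  pA_eq <- sum(occ$p[setA])
  fit <- stats::lm(log(pA - pA_eq) ~ times)
  lambda <- -unname(stats::coef(fit)[2])
  ## two-state decomposition of the relaxation rate
  pB_eq <- sum(occ$p[setB])
  list(k_f = lambda * pB_eq / (pA_eq + pB_eq),
       k_r = lambda * pA_eq / (pA_eq + pB_eq),
       lambda = lambda)
}

## independent dihedral (acos magnitude + triple-product sign), used to
## cross-check the pucker torsions
oracle_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cr <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                         u[3] * v[1] - u[1] * v[3],
                         u[1] * v[2] - u[2] * v[1])
  n1 <- cr(b1, b2); n2 <- cr(b2, b3)
  cosang <- sum(n1 * n2) / sqrt(sum(n1^2) * sum(n2^2))
  ang <- acos(max(-1, min(1, cosang))) * 180 / pi
  if (sum(cr(n2, n1) * b2) < 0) ang <- -ang
  ang
}

oracle_pucker <- function(xyz) {
  at <- function(a) xyz[a, ]
  nu <- c(oracle_dihedral(at("C4'"), at("O4'"), at("C1'"), at("C2'")),
          oracle_dihedral(at("O4'"), at("C1'"), at("C2'"), at("C3'")),
          oracle_dihedral(at("C1'"), at("C2'"), at("C3'"), at("C4'")),
          oracle_dihedral(at("C2'"), at("C3'"), at("C4'"), at("O4'")),
          oracle_dihedral(at("C3'"), at("C4'"), at("O4'"), at("C1'")))
  P <- atan((nu[5] + nu[2] - nu[4] - nu[1]) /
              (2 * nu[3] * (sin(36 * pi / 180) + sin(72 * pi / 180)))) *
    180 / pi
  if (nu[3] < 0) P <- P + 180
  P %% 360
}

## regrouping with a randomised merge order (same criterion, random
## qualifying pair each step) to probe merge-order independence
regroup_random_order <- function(net, temperature, dG_thresh, order_seed) {
  kT <- kB * temperature
  off <- kT * log(kT_over_h(temperature))
  lw_min <- log_weight(net, temperature)
  ets <- net$ts[net$ts$min1 != net$ts$min2, , drop = FALSE]
  lw_ts <- -ets$V / kT - ets$logProd - log(ets$pgOrder)
  lse <- function(x) { m <- max(x); m + log(sum(exp(x - m))) }
  assignment <- seq_len(n_minima(net))
  set.seed(order_seed)
  repeat {
    gid <- sort(unique(assignment))
    F_g <- vapply(gid, function(g)
      -kT * lse(lw_min[assignment == g]), numeric(1))
    qual <- NULL
    for (ii in seq_along(gid)) for (jj in seq_along(gid)) {
      if (jj <= ii) next
      sel <- (assignment[ets$min1] == gid[ii] &
                assignment[ets$min2] == gid[jj]) |
             (assignment[ets$min1] == gid[jj] &
                assignment[ets$min2] == gid[ii])
      if (!any(sel)) next
      Fts <- -kT * lse(lw_ts[sel]) + off
      if (Fts - F_g[ii] < dG_thresh && Fts - F_g[jj] < dG_thresh)
        qual <- rbind(qual, c(gid[ii], gid[jj]))
    }
    if (is.null(qual)) break
    pick <- qual[sample(nrow(qual), 1), ]
    assignment[assignment == pick[2]] <- pick[1]
  }
  ## canonical labels for comparison
  match(assignment, sort(unique(assignment)))
}

## partitions equal up to labelling
same_partition <- function(a, b) {
  all(outer(a, a, "==") == outer(b, b, "=="))
}
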