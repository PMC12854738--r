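## Desk-scale stationary-point search: DNEB candidate generation, hybrid
## eigenvector-following refinement, steepest-descent connection, and an
## exploration loop emitting a kinetic transition network.

#' Minimise a potential from a starting point
#'
#' BFGS with analytic gradient, polished by Newton steps to tight gradient
#' norms.
#'
#' @param pot A `potential`.
#' @param x0 Starting coordinates.
#' @param gtol Gradient-norm convergence target.
#' @return List with `x`, `energy`, `gradient_norm`, `eigenvalues`.
#' @export
find_minimum <- function(pot, x0, gtol = 1e-9) {
  fit <- stats::optim(x0, fn = pot$energy, gr = pot$gradient,
                      method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  x <- fit$par
  for (i in 1:50) {
    g <- pot$gradient(x)
    if (sqrt(sum(g^2)) < gtol) break
    H <- pot$hessian(x)
    step <- tryCatch(solve(H, g), error = function(e) g * 0.1)
    if (sqrt(sum(step^2)) > 0.5) step <- step * 0.5 / sqrt(sum(step^2))
    x <- x - step
  }
  g <- pot$gradient(x)
  list(x = x, energy = pot$energy(x), gradient_norm = sqrt(sum(g^2)),
       eigenvalues = sort(eigen(pot$hessian(x), symmetric = TRUE,
                                only.values = TRUE)$values))
}

## upwind-style central tangent, normalised
.band_tangent <- function(band, i) {
  tau <- band[i + 1L, ] - band[i - 1L, ]
  tau / sqrt(sum(tau^2))
}

#' Doubly nudged elastic band between two minima
#'
#' Builds a straight-line chain of images between two minima and relaxes it
#' with the doubly nudged projection: the perpendicular true gradient, the
#' parallel spring force, plus the portion of the perpendicular spring force
#' orthogonal to the perpendicular gradient (which stabilises the band
#' against corner cutting). Interior local energy maxima of the relaxed band
#' are returned as transition-state candidates.
#'
#' @param pot A `potential`.
#' @param x_a,x_b Endpoint coordinates; must be minima (gradient norm below
#'   `endpoint_gtol`).
#' @param n_images Number of images including endpoints.
#' @param k_spring Spring constant.
#' @param max_iter Relaxation iterations.
#' @param endpoint_gtol Gradient-norm bound defining a valid endpoint.
#' @param climb_iter Climbing-image iterations: after the band relaxes,
#'   interior energy maxima climb along the path tangent (parallel force
#'   reversed, springs released) so that candidate energies converge onto
#'   the saddle instead of undershooting it by the image-spacing
#'   discretisation error.
#' @return List with `band` (images x dim matrix), `energies` and
#'   `candidates` (indices of interior maxima, possibly empty).
#' @export
dneb <- function(pot, x_a, x_b, n_images = 15, k_spring = 1,
                 max_iter = 2000, endpoint_gtol = 1e-4, climb_iter = 600) {
  for (x in list(x_a, x_b)) {
    g <- pot$gradient(x)
    if (sqrt(sum(g^2)) > endpoint_gtol)
      stop("DNEB endpoints must be minima (|grad| = ",
           format(sqrt(sum(g^2))), ")")
  }
  d <- pot$dim
  if (sqrt(sum((x_a - x_b)^2)) < 1e-10) {
    band <- rbind(x_a, x_b)
    return(list(band = band, energies = apply(band, 1, pot$energy),
                candidates = integer(0)))
  }
  lam <- seq(0, 1, length.out = n_images)
  band <- t(matrix(vapply(lam, function(l) (1 - l) * x_a + l * x_b,
                          numeric(d)), nrow = d))
  step <- 0.01
  prev_fnorm <- Inf
  for (it in seq_len(max_iter)) {
    forces <- matrix(0, n_images, d)
    for (i in 2:(n_images - 1L)) {
      tau <- .band_tangent(band, i)
      g <- pot$gradient(band[i, ])
      g_perp <- g - sum(g * tau) * tau
      f_spring <- k_spring *
        (sqrt(sum((band[i + 1L, ] - band[i, ])^2)) -
         sqrt(sum((band[i, ] - band[i - 1L, ])^2)))
      fs_full <- k_spring * ((band[i + 1L, ] - band[i, ]) -
                             (band[i, ] - band[i - 1L, ]))
      fs_perp <- fs_full - sum(fs_full * tau) * tau
      gp_norm <- sqrt(sum(g_perp^2))
      fs_dn <- if (gp_norm > 1e-12) {
        ghat <- g_perp / gp_norm
        fs_perp - sum(fs_perp * ghat) * ghat
      } else fs_perp
      forces[i, ] <- -g_perp + f_spring * tau + fs_dn
    }
    fnorm <- sqrt(sum(forces^2))
    if (fnorm < 1e-6) break
    ## crude adaptive step
    step <- if (fnorm < prev_fnorm) min(step * 1.05, 0.05) else step * 0.5
    prev_fnorm <- fnorm
    move <- forces * step
    mn <- sqrt(rowSums(move^2))
    cap <- 0.1
    scale <- ifelse(mn > cap, cap / mn, 1)
    band <- band + move * scale
  }
  energies <- apply(band, 1L, pot$energy)
  maxima <- function(e) which(vapply(2:(n_images - 1L), function(i)
    e[i] > e[i - 1L] && e[i] > e[i + 1L], logical(1))) + 1L
  ## climbing phase: maxima ascend the reversed parallel force
  climbers <- maxima(energies)
  if (length(climbers) && climb_iter > 0L) {
    for (ci in climbers) {
      x <- band[ci, ]
      step <- 0.005
      prev <- Inf
      for (it in seq_len(climb_iter)) {
        tau <- .band_tangent(band, ci)
        g <- pot$gradient(x)
        f <- -g + 2 * sum(g * tau) * tau
        fn <- sqrt(sum(f^2))
        if (fn < 1e-8) break
        step <- if (fn < prev) min(step * 1.1, 0.05) else step * 0.5
        prev <- fn
        dx <- f * step
        dn <- sqrt(sum(dx^2))
        if (dn > 0.05) dx <- dx * 0.05 / dn
        x <- x + dx
      }
      band[ci, ] <- x
      energies[ci] <- pot$energy(x)
    }
  }
  candidates <- maxima(energies)
  list(band = band, energies = energies, candidates = candidates)
}

#' Hybrid eigenvector-following refinement of a saddle candidate
#'
#' Maximises the energy along the lowest Hessian eigenvector while
#' minimising in the orthogonal complement, until the gradient norm falls
#' below `gtol` and the Hessian index is exactly 1.
#'
#' @param pot A `potential`.
#' @param x0 Starting coordinates (near a candidate).
#' @param gtol Gradient-norm convergence target.
#' @param max_iter Iteration cap.
#' @param trust Trust-radius step cap.
#' @return List with `x`, `energy`, `eigenvalues`, `index`, `converged`
#'   (logical) and `message`. Convergence to an index other than 1 is
#'   reported as `converged = FALSE` with a diagnostic.
#' @export
hef_refine <- function(pot, x0, gtol = 1e-7, max_iter = 200, trust = 0.1) {
  x <- x0
  d <- pot$dim
  for (it in seq_len(max_iter)) {
    g <- pot$gradient(x)
    H <- pot$hessian(x)
    eg <- eigen(H, symmetric = TRUE)
    lam <- eg$values
    vmin <- eg$vectors[, d]       # lowest eigenvalue last in R's ordering
    lmin <- lam[d]
    if (sqrt(sum(g^2)) < gtol) break
    gpar <- sum(g * vmin)
    ## uphill along the softest mode, Newton-like when curvature negative
    step_par <- if (lmin < -1e-10) -gpar / lmin else
      gpar / max(abs(lmin), 1e-3)
    dx <- step_par * vmin
    if (d > 1L) {
      ## Newton step in the orthogonal complement with shifted curvature
      rest <- seq_len(d - 1L)
      V <- eg$vectors[, rest, drop = FALSE]
      gr <- drop(crossprod(V, g))
      lr <- pmax(lam[rest], 1e-3)
      dx <- dx - V %*% (gr / lr)
    }
    dn <- sqrt(sum(dx^2))
    if (dn > trust) dx <- dx * trust / dn
    x <- x + drop(dx)
  }
  g <- pot$gradient(x)
  eg <- eigen(pot$hessian(x), symmetric = TRUE, only.values = TRUE)
  idx <- sum(eg$values < -1e-8)
  conv <- sqrt(sum(g^2)) < gtol && idx == 1L
  msg <- if (conv) "converged index-1 saddle"
         else if (sqrt(sum(g^2)) >= gtol) "gradient not converged"
         else sprintf("converged to Hessian index %d, rejected", idx)
  list(x = x, energy = pot$energy(x), eigenvalues = sort(eg$values),
       index = idx, converged = conv, message = msg)
}

#' Connect a saddle to its two minima by steepest descent
#'
#' Starts two minimisations from the saddle displaced by `eps` along +- the
#' negative-curvature eigenvector (short steepest-descent leg first, then
#' quasi-Newton).
#'
#' @param pot A `potential`.
#' @param saddle Coordinates of a valid index-1 saddle.
#' @param eps Displacement along the unique negative eigendirection.
#' @return List of two minima (`minus`, `plus`), each as returned by
#'   [find_minimum()]; they may coincide for a degenerate rearrangement.
#' @export
descend_connect <- function(pot, saddle, eps = 1e-3) {
  H <- pot$hessian(saddle)
  eg <- eigen(H, symmetric = TRUE)
  if (sum(eg$values < -1e-8) != 1L)
    stop("descend_connect requires an index-1 saddle (index ",
         sum(eg$values < -1e-8), ")")
  v <- eg$vectors[, pot$dim]
  scale <- max(1, sqrt(sum(saddle^2)))
  one_side <- function(sgn) {
    x <- saddle + sgn * eps * scale * v
    ## a few small steepest-descent steps to commit to the basin
    for (i in 1:25) {
      g <- pot$gradient(x)
      gn <- sqrt(sum(g^2))
      if (gn < 1e-10) break
      x <- x - g * min(0.01 / gn, 0.05)
    }
    find_minimum(pot, x)
  }
  list(minus = one_side(-1), plus = one_side(+1))
}

#' Grid + Newton stationary-point oracle
#'
#' Independent brute-force location of all stationary points in a box:
#' evaluates the squared gradient norm on a dense grid, polishes every local
#' grid minimum of |grad|^2 with damped Newton iterations on grad = 0,
#' deduplicates, and classifies by Hessian index. Used as the in-repo
#' reference for the saddle-search pipeline.
#'
#' @param pot A `potential` (dimension 1 or 2).
#' @param lower,upper Box bounds (length = dim).
#' @param n_grid Grid points per dimension.
#' @return data.frame with coordinates (`x1`, ...), `energy`, `index` and
#'   `gradient_norm`, sorted by energy.
#' @export
grid_newton_search <- function(pot, lower, upper, n_grid = 201) {
  d <- pot$dim
  axes <- lapply(seq_len(d), function(i)
    seq(lower[i], upper[i], length.out = n_grid))
  grid <- as.matrix(expand.grid(axes))
  gn2 <- apply(grid, 1L, function(x) sum(pot$gradient(x)^2))
  gn2a <- array(gn2, dim = rep(n_grid, d))
  ## local minima of |grad|^2 on the grid
  starts <- list()
  if (d == 1L) {
    for (i in 2:(n_grid - 1L))
      if (gn2a[i] <= gn2a[i - 1L] && gn2a[i] <= gn2a[i + 1L])
        starts[[length(starts) + 1L]] <- grid[i, ]
  } else {
    for (i in 2:(n_grid - 1L)) for (j in 2:(n_grid - 1L)) {
      v <- gn2a[i, j]
      if (v <= min(gn2a[(i - 1):(i + 1), (j - 1):(j + 1)]))
        starts[[length(starts) + 1L]] <-
          c(axes[[1]][i], axes[[2]][j])
    }
  }
  found <- list()
  for (x0 in starts) {
    x <- x0
    ok <- TRUE
    for (it in 1:100) {
      g <- pot$gradient(x)
      if (sqrt(sum(g^2)) < 1e-12) break
      H <- pot$hessian(x)
      step <- tryCatch(solve(H, g), error = function(e) NULL)
      if (is.null(step)) { ok <- FALSE; break }
      sn <- sqrt(sum(step^2))
      if (sn > 0.2) step <- step * 0.2 / sn
      x <- x - step
    }
    if (!ok || sqrt(sum(pot$gradient(x)^2)) > 1e-9) next
    if (any(x < lower - 1e-6) || any(x > upper + 1e-6)) next
    dup <- any(vapply(found, function(f)
      sqrt(sum((f$x - x)^2)) < 1e-5, logical(1)))
    if (dup) next
    ev <- eigen(pot$hessian(x), symmetric = TRUE, only.values = TRUE)$values
    found[[length(found) + 1L]] <-
      list(x = x, energy = pot$energy(x), index = sum(ev < -1e-8),
           gnorm = sqrt(sum(pot$gradient(x)^2)))
  }
  if (!length(found))
    return(data.frame(energy = numeric(0), index = integer(0),
                      gradient_norm = numeric(0)))
  out <- data.frame(do.call(rbind, lapply(found, function(f) f$x)))
  names(out) <- paste0("x", seq_len(d))
  out$energy <- vapply(found, `[[`, numeric(1), "energy")
  out$index <- vapply(found, `[[`, numeric(1), "index")
  out$gradient_norm <- vapply(found, `[[`, numeric(1), "gnorm")
  out[order(out$energy), ]
}

## log product of harmonic frequencies nu_j = sqrt(lambda_j) / (2 pi) over
## the positive Hessian eigenvalues
.log_prod_freq <- function(eigenvalues, skip_lowest = FALSE) {
  lam <- sort(eigenvalues)
  if (skip_lowest) lam <- lam[-1]
  if (any(lam <= 0)) stop("non-positive curvature among retained modes")
  sum(log(sqrt(lam) / (2 * pi)))
}

#' Explore a potential into a kinetic transition network
#'
#' Repeated DNEB -> HEF -> steepest-descent cycles over unconnected (then
#' nearest unattempted) minimum pairs, until the connection budget is
#' exhausted or the heat-capacity curve on `T_grid` is converged between
#' successive rounds. Vibrational log-products come from the Hessian
#' eigenvalues at each stationary point (nu = sqrt(lambda)/2pi); point-group
#' orders are set to 1.
#'
#' @param pot A `potential`.
#' @param seeds List (or matrix rows) of starting coordinates; each is
#'   minimised and must reach a minimum.
#' @param budget Maximum number of DNEB connection attempts.
#' @param T_grid Temperatures for the convergence check.
#' @param cv_rtol Relative heat-capacity change defining convergence.
#' @param n_images,k_spring Passed to [dneb()].
#' @return A `ktn` with `kappa = pot$dim`; attribute `"search"` carries
#'   `converged`, `attempts` and the stationary-point coordinates.
#' @export
explore <- function(pot, seeds, budget = 30, T_grid = c(0.5, 1, 2, 5, 10),
                    cv_rtol = 1e-6, n_images = 15, k_spring = 1) {
  if (is.matrix(seeds)) seeds <- lapply(seq_len(nrow(seeds)),
                                        function(i) seeds[i, ])
  minima <- list()
  add_min <- function(m) {
    for (i in seq_along(minima)) {
      if (sqrt(sum((minima[[i]]$x - m$x)^2)) < 1e-4 &&
          abs(minima[[i]]$energy - m$energy) < 1e-6)
        return(i)
    }
    minima[[length(minima) + 1L]] <<- m
    length(minima)
  }
  for (s in seeds) add_min(find_minimum(pot, s))
  saddles <- list()   # each: x, energy, eigenvalues, min1, min2
  attempted <- character(0)
  attempts <- 0L
  prev_cv <- NULL
  converged <- FALSE

  build_ktn <- function() {
    mins <- data.frame(
      V = vapply(minima, `[[`, numeric(1), "energy"),
      logProd = vapply(minima, function(m)
        .log_prod_freq(m$eigenvalues), numeric(1)),
      pgOrder = 1)
    ts <- if (length(saddles)) data.frame(
      V = vapply(saddles, `[[`, numeric(1), "energy"),
      logProd = vapply(saddles, function(s)
        .log_prod_freq(s$eigenvalues, skip_lowest = TRUE), numeric(1)),
      pgOrder = 1,
      min1 = vapply(saddles, `[[`, numeric(1), "min1"),
      min2 = vapply(saddles, `[[`, numeric(1), "min2")) else NULL
    ktn(mins, ts, kappa = pot$dim)
  }

  pick_pair <- function() {
    n <- length(minima)
    if (n < 2L) return(NULL)
    net <- build_ktn()
    comp <- igraph::components(ktn_graph(net))$membership
    pairs <- utils::combn(n, 2)
    keys <- apply(pairs, 2L, paste, collapse = "-")
    dists <- apply(pairs, 2L, function(p)
      sqrt(sum((minima[[p[1]]]$x - minima[[p[2]]]$x)^2)))
    fresh <- !(keys %in% attempted)
    cross <- comp[pairs[1, ]] != comp[pairs[2, ]]
    cand <- which(fresh & cross)
    if (!length(cand)) cand <- which(fresh)
    if (!length(cand)) return(NULL)
    pairs[, cand[which.min(dists[cand])]]
  }

  while (attempts < budget) {
    pr <- pick_pair()
    if (is.null(pr)) break
    attempts <- attempts + 1L
    attempted <- c(attempted, paste(pr, collapse = "-"))
    band <- dneb(pot, minima[[pr[1]]]$x, minima[[pr[2]]]$x,
                 n_images = n_images, k_spring = k_spring)
    for (ci in band$candidates) {
      ref <- hef_refine(pot, band$band[ci, ])
      if (!ref$converged) next
      dup <- any(vapply(saddles, function(s)
        sqrt(sum((s$x - ref$x)^2)) < 1e-4, logical(1)))
      if (dup) next
      conn <- descend_connect(pot, ref$x)
      i1 <- add_min(conn$minus)
      i2 <- add_min(conn$plus)
      saddles[[length(saddles) + 1L]] <-
        list(x = ref$x, energy = ref$energy,
             eigenvalues = ref$eigenvalues, min1 = i1, min2 = i2)
    }
    ## convergence: connected network and stable heat-capacity curve
    net <- build_ktn()
    if (igraph::components(ktn_graph(net))$no == 1L && length(saddles)) {
      cv <- heat_capacity_curve(net, T_grid)$Cv
      if (!is.null(prev_cv) && length(prev_cv) == length(cv) &&
          max(abs(cv - prev_cv) / pmax(abs(prev_cv), 1e-12)) < cv_rtol) {
        converged <- TRUE
        break
      }
      prev_cv <- cv
    }
  }
  net <- build_ktn()
  attr(net, "search") <- list(
    converged = converged, attempts = attempts,
    min_coords = lapply(minima, `[[`, "x"),
    ts_coords = lapply(saddles, `[[`, "x"))
  net
}
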