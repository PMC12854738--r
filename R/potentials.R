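## Pluggable analytic potentials for the desk-scale saddle search.

#' Construct a potential
#'
#' @param energy Function of a coordinate vector returning a scalar.
#' @param gradient Optional analytic gradient; defaults to central
#'   differences.
#' @param hessian Optional analytic Hessian; defaults to central differences
#'   of the gradient.
#' @param dim Dimensionality.
#' @param name Display name.
#' @return A `potential` object with callable fields.
#' @export
potential <- function(energy, gradient = NULL, hessian = NULL, dim,
                      name = "custom") {
  h <- 1e-5
  if (is.null(gradient)) {
    gradient <- function(x) {
      vapply(seq_len(dim), function(i) {
        e <- replace(numeric(dim), i, h)
        (energy(x + e) - energy(x - e)) / (2 * h)
      }, numeric(1))
    }
  }
  grad_fun <- gradient
  if (is.null(hessian)) {
    hessian <- function(x) {
      H <- vapply(seq_len(dim), function(i) {
        e <- replace(numeric(dim), i, h)
        (grad_fun(x + e) - grad_fun(x - e)) / (2 * h)
      }, numeric(dim))
      H <- matrix(H, dim, dim)
      (H + t(H)) / 2
    }
  }
  structure(list(energy = energy, gradient = gradient, hessian = hessian,
                 dim = dim, name = name), class = "potential")
}

#' @export
print.potential <- function(x, ...) {
  cat(sprintf("<potential> %s (dim %d)\n", x$name, x$dim))
  invisible(x)
}

#' Check gradient consistency against central differences
#'
#' @param pot A `potential`.
#' @param x Point at which to test.
#' @param h Finite-difference step.
#' @return Maximum relative component error.
#' @export
check_gradient <- function(pot, x, h = 1e-6) {
  g <- pot$gradient(x)
  fd <- vapply(seq_len(pot$dim), function(i) {
    e <- replace(numeric(pot$dim), i, h)
    (pot$energy(x + e) - pot$energy(x - e)) / (2 * h)
  }, numeric(1))
  max(abs(g - fd) / pmax(abs(fd), 1e-8))
}

#' One-dimensional double well
#'
#' `V(x) = x^4 - x^2`: minima at x = +-1/sqrt(2) (V = -1/4), saddle at
#' x = 0 (V = 0).
#'
#' @return A `potential` of dimension 1.
#' @export
double_well_1d <- function() {
  potential(energy = function(x) x[1]^4 - x[1]^2,
            gradient = function(x) 4 * x[1]^3 - 2 * x[1],
            hessian = function(x) matrix(12 * x[1]^2 - 2, 1, 1),
            dim = 1L, name = "double well x^4 - x^2")
}

## coefficients of the standard four-term exponential 2D benchmark surface
.MB_A  <- c(-200, -100, -170, 15)
.MB_a  <- c(-1, -1, -6.5, 0.7)
.MB_b  <- c(0, 0, 11, 0.6)
.MB_c  <- c(-10, -10, -6.5, 0.7)
.MB_x0 <- c(1, 0, -0.5, -1)
.MB_y0 <- c(0, 0.5, 1.5, 1)

#' Two-dimensional four-term exponential benchmark surface
#'
#' The standard two-dimensional saddle-search test surface built from four
#' anisotropic exponential terms; it has three minima and two index-1
#' saddles inside the region x in [-1.7, 1.3], y in [-0.4, 2.1]. All
#' stationary-point values used in tests are established by the in-repo
#' grid+Newton oracle ([grid_newton_search()]), not hard-coded.
#'
#' @return A `potential` of dimension 2.
#' @export
benchmark_surface_2d <- function() {
  terms <- function(x) {
    dx <- x[1] - .MB_x0; dy <- x[2] - .MB_y0
    .MB_A * exp(.MB_a * dx^2 + .MB_b * dx * dy + .MB_c * dy^2)
  }
  energy <- function(x) sum(terms(x))
  gradient <- function(x) {
    dx <- x[1] - .MB_x0; dy <- x[2] - .MB_y0
    tt <- terms(x)
    c(sum(tt * (2 * .MB_a * dx + .MB_b * dy)),
      sum(tt * (.MB_b * dx + 2 * .MB_c * dy)))
  }
  hessian <- function(x) {
    dx <- x[1] - .MB_x0; dy <- x[2] - .MB_y0
    tt <- terms(x)
    gx <- 2 * .MB_a * dx + .MB_b * dy
    gy <- .MB_b * dx + 2 * .MB_c * dy
    hxx <- sum(tt * (gx^2 + 2 * .MB_a))
    hyy <- sum(tt * (gy^2 + 2 * .MB_c))
    hxy <- sum(tt * (gx * gy + .MB_b))
    matrix(c(hxx, hxy, hxy, hyy), 2, 2)
  }
  potential(energy, gradient, hessian, dim = 2L,
            name = "four-term exponential 2D benchmark")
}
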