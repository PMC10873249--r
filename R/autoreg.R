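#' Cubic autoregulation function
#'
#' Constructs the nonlinear self-regulation term \eqn{f(x)} of the
#' gene-expression model \eqn{dx/dt = \lambda + f(x) - x}.  The function is a
#' cubic polynomial with strictly negative leading coefficient, which
#' guarantees that \eqn{g(x) = x - f(x)} diverges to \eqn{\pm\infty} with the
#' correct signs and that the drift has at most three zeros, the minimal
#' structure required for bistability.
#'
#' The default, \eqn{f(x) = -(x-2)^3 + 2(x-2)}, is the canonical
#' worked example of this package: it yields fixed points \{1, 2, 3\} at
#' \eqn{\lambda = 2} and a bistable window \eqn{\lambda \in (2 - 2/(3\sqrt 3),
#' \; 2 + 2/(3\sqrt 3)) \approx (1.6, 2.4)}.
#'
#' @param coefficients numeric length-4 vector of polynomial coefficients in
#'   ascending powers, \code{c(c0, c1, c2, c3)} for
#'   \eqn{f(x) = c_0 + c_1 x + c_2 x^2 + c_3 x^3}.  The default expands
#'   \eqn{-(x-2)^3 + 2(x-2)}.
#' @return an object of class \code{autoreg_cubic}.
#' @examples
#' f <- autoreg_cubic()
#' eval_autoregulation(2, f)  # 0: f is odd about x = 2
#' @export
autoreg_cubic <- function(coefficients = c(4, -10, 6, -1)) {
  coefficients <- as.numeric(coefficients)
  if (length(coefficients) != 4L || any(!is.finite(coefficients)))
    stop("'coefficients' must be 4 finite numbers (ascending powers)")
  if (coefficients[4] >= 0)
    stop("leading (cubic) coefficient must be strictly negative")
  structure(list(coefficients = coefficients), class = "autoreg_cubic")
}

#' @export
print.autoreg_cubic <- function(x, ...) {
  co <- x$coefficients
  cat(sprintf("<autoreg_cubic> f(x) = %g + %g*x + %g*x^2 + %g*x^3\n",
              co[1], co[2], co[3], co[4]))
  invisible(x)
}

poly_eval <- function(coefficients, x) {
  # Horner, vectorized in x
  out <- rep(0, length(x))
  for (c_k in rev(coefficients)) out <- out * x + c_k
  out
}

#' Evaluate the autoregulation function
#'
#' @param x expression level(s), finite numeric.
#' @param f an [autoreg_cubic()] object.
#' @return \eqn{f(x)}, vectorized over \code{x}.
#' @export
eval_autoregulation <- function(x, f = autoreg_cubic()) {
  stopifnot(inherits(f, "autoreg_cubic"), is.numeric(x), all(is.finite(x)))
  poly_eval(f$coefficients, x)
}

#' Drift of the bistable expression model
#'
#' Right-hand side of \eqn{dx/dt = \lambda + f(x) - x}, where time has been
#' rescaled so the linear degradation rate equals one and \eqn{\lambda} is the
#' (dimensionless) production rate set by the cell's mutation state.
#'
#' @param x expression level(s).
#' @param lambda production rate (scalar).
#' @param f an [autoreg_cubic()] object.
#' @return \eqn{\lambda + f(x) - x}, vectorized over \code{x}.
#' @export
drift <- function(x, lambda, f = autoreg_cubic()) {
  stopifnot(is.numeric(lambda), length(lambda) == 1L, is.finite(lambda))
  lambda + eval_autoregulation(x, f) - x
}

#' Potential of the bistable expression model
#'
#' The drift is a gradient flow in one dimension, \eqn{dx/dt = -U'(x)}, with
#' \eqn{U(x) = -\int_0^x (\lambda + f(s) - s)\,ds}.  The integration constant
#' is fixed by the convention \eqn{U(0) = 0}.  Stable fixed points are local
#' minima of \eqn{U}; the unstable intermediate fixed point (when present) is
#' a local maximum.
#'
#' @inheritParams drift
#' @return \eqn{U(x)}, vectorized over \code{x}.
#' @export
potential <- function(x, lambda, f = autoreg_cubic()) {
  stopifnot(is.numeric(lambda), length(lambda) == 1L, is.finite(lambda))
  co <- f$coefficients
  # drift polynomial: (lambda + c0) + (c1 - 1) x + c2 x^2 + c3 x^3
  dp <- c(lambda + co[1], co[2] - 1, co[3], co[4])
  # antiderivative with zero constant, negated
  anti <- c(0, dp / seq_along(dp))
  -poly_eval(anti, x)
}

# derivative of the drift w.r.t. x (stability: negative => stable)
drift_deriv <- function(x, f) {
  co <- f$coefficients
  co[2] - 1 + 2 * co[3] * x + 3 * co[4] * x^2
}
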