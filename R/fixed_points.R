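#' Fixed points of the bistable expression model
#'
#' Finds all real roots of \eqn{\lambda + f(x) - x = 0} and labels their
#' stability from the sign of the drift derivative (negative derivative means
#' stable).  Roots are computed analytically with [polyroot()] and polished
#' with a few Newton steps so that the drift residual at every reported root
#' is below \code{1e-12} in well-conditioned cases.  Real roots closer than
#' \code{merge_tol} are reported as a single degenerate root: this happens at
#' a saddle-node threshold, where a stable and an unstable fixed point
#' collide; the degenerate (marginal) root is labelled \code{"stable"} so
#' that branch continuation treats it as still existing exactly at the
#' threshold.
#'
#' @inheritParams drift
#' @param tol numeric tolerance (> 0) recorded with the result and used for
#'   the degenerate-root stability call.
#' @param merge_tol roots separated by less than this are merged (default
#'   \code{1e-7}).
#' @return a \code{fixed_point_set}: a data frame with columns \code{x}
#'   (ascending), \code{stability} (\code{"stable"}/\code{"unstable"}) and
#'   \code{degenerate} (logical), with attributes \code{lambda} and
#'   \code{tol}.  It has 1, 2 (only exactly at a threshold) or 3 rows; with 3
#'   rows the pattern is stable/unstable/stable.
#' @examples
#' find_fixed_points(2)   # x = 1, 2, 3
#' find_fixed_points(3)   # single high state ~ 3.325
#' @export
find_fixed_points <- function(lambda, f = autoreg_cubic(), tol = 1e-9,
                              merge_tol = 1e-7) {
  stopifnot(is.numeric(lambda), length(lambda) == 1L, is.finite(lambda),
            tol > 0)
  co <- f$coefficients
  dp <- c(lambda + co[1], co[2] - 1, co[3], co[4])  # drift polynomial
  rts <- polyroot(dp)
  scale <- max(1, Mod(rts))
  re <- sort(Re(rts[abs(Im(rts)) < 1e-7 * scale]))
  # Newton polish
  for (i in seq_along(re)) {
    for (k in 1:3) {
      d <- drift(re[i], lambda, f)
      dd <- drift_deriv(re[i], f)
      if (abs(dd) > 1e-12) re[i] <- re[i] - d / dd
    }
  }
  re <- sort(re)
  # merge near-coincident (double) roots
  x <- c(); degen <- c()
  i <- 1L
  while (i <= length(re)) {
    j <- i
    while (j < length(re) && re[j + 1] - re[j] < merge_tol) j <- j + 1L
    x <- c(x, mean(re[i:j]))
    degen <- c(degen, j > i)
    i <- j + 1L
  }
  deriv <- drift_deriv(x, f)
  stability <- ifelse(degen, "stable", ifelse(deriv < 0, "stable", "unstable"))
  structure(
    data.frame(x = x, stability = stability, degenerate = degen),
    lambda = lambda, tol = tol,
    class = c("fixed_point_set", "data.frame")
  )
}

#' Saddle-node bifurcation thresholds
#'
#' The fixed-point equation \eqn{\lambda = g(x)} with \eqn{g(x) = x - f(x)}
#' acquires/loses a pair of roots where \eqn{g'(x) = 0}.  For a cubic
#' \eqn{f}, \eqn{g'} is a quadratic; when it has two distinct real roots
#' \eqn{x_\dagger} the two saddle-node thresholds are
#' \eqn{\lambda = g(x_\dagger)}.  Between the thresholds the model is
#' bistable (three fixed points); outside it is monostable.  For the default
#' cubic these are \eqn{2 \mp 2/(3\sqrt 3)}, printed as 1.6 and 2.4.
#'
#' @param f an [autoreg_cubic()] object.
#' @return a \code{bifurcation_thresholds} list with \code{lambda_low},
#'   \code{lambda_high} and the critical expression levels \code{x_at_low},
#'   \code{x_at_high} where each collision happens.
#' @examples
#' th <- saddle_node_thresholds()
#' c(th$lambda_low, th$lambda_high)  # 2 -/+ 2/(3*sqrt(3))
#' @export
saddle_node_thresholds <- function(f = autoreg_cubic()) {
  stopifnot(inherits(f, "autoreg_cubic"))
  co <- f$coefficients
  # g'(x) = 1 - f'(x) = (1 - c1) - 2 c2 x - 3 c3 x^2
  a <- -3 * co[4]; b <- -2 * co[3]; cc <- 1 - co[2]
  disc <- b^2 - 4 * a * cc
  if (disc <= 0)
    stop("no bistable window: g(x) = x - f(x) has no pair of critical points")
  xc <- sort((-b + c(-1, 1) * sqrt(disc)) / (2 * a))
  g <- function(x) x - eval_autoregulation(x, f)
  lam <- g(xc)
  # leading coefficient of f negative => g increasing at both ends;
  # the local max of g (lower x critical point) gives lambda_high.
  structure(list(lambda_low  = min(lam), lambda_high = max(lam),
                 x_at_low  = xc[which.min(lam)],
                 x_at_high = xc[which.max(lam)]),
            class = "bifurcation_thresholds")
}

#' @export
print.bifurcation_thresholds <- function(x, ...) {
  cat(sprintf("<bifurcation_thresholds> lambda_low = %.6f, lambda_high = %.6f\n",
              x$lambda_low, x$lambda_high))
  invisible(x)
}

#' Bifurcation diagram over a production-rate grid
#'
#' Tabulates all fixed points with stability labels on a grid of
#' \eqn{\lambda} values; the standard way to visualize the low- and
#' high-expression branches and the unstable middle branch connecting them.
#'
#' @param lambda_min,lambda_max,step grid specification.
#' @param f an [autoreg_cubic()] object.
#' @return data frame with columns \code{lambda}, \code{x_star},
#'   \code{stability}.
#' @export
bifurcation_diagram <- function(lambda_min = 0, lambda_max = 4, step = 0.01,
                                f = autoreg_cubic()) {
  stopifnot(lambda_max > lambda_min, step > 0)
  grid <- seq(lambda_min, lambda_max, by = step)
  rows <- lapply(grid, function(l) {
    fp <- find_fixed_points(l, f)
    data.frame(lambda = l, x_star = fp$x, stability = fp$stability)
  })
  do.call(rbind, rows)
}
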