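#' Mutation states
#'
#' The five cell mutation states distinguished throughout the package:
#' wild-type (\code{"O"}), JAK2-only (\code{"J"}), TET2-only (\code{"T"}),
#' JAK2-then-TET2 (\code{"JT"}) and TET2-then-JAK2 (\code{"TJ"}).
#'
#' @return character vector of the five state labels, in canonical order.
#' @export
mutation_states <- function() c("O", "J", "T", "JT", "TJ")

check_state <- function(state) {
  state <- match.arg(state, mutation_states(), several.ok = TRUE)
  state
}

#' Mutation indicator accessors
#'
#' \code{has_jak2} and \code{has_tet2} return the Boolean indicators
#' \eqn{1_J} and \eqn{1_T} of a mutation state; both are 1 for the
#' double-mutant states \code{"JT"} and \code{"TJ"}.
#'
#' @param state character vector of states from [mutation_states()].
#' @return integer 0/1 vector.
#' @export
has_jak2 <- function(state) as.integer(check_state(state) %in% c("J", "JT", "TJ"))

#' @rdname has_jak2
#' @export
has_tet2 <- function(state) as.integer(check_state(state) %in% c("T", "JT", "TJ"))

#' Boolean-controlled production rate specification
#'
#' Defines the production rate of the bistable gene as a Boolean control
#' operator over the cell's mutations,
#' \eqn{\lambda = \lambda_0 + \lambda_J 1_J + \lambda_T 1_T}.
#' Because the indicators saturate, the double-mutant states JT and TJ share
#' the same rate; order effects enter only through hysteresis of the
#' bistable dynamics, not through the rate itself.
#'
#' @param lambda0 basal dimensionless production rate.
#' @param lambda_J additive increment when the JAK2 mutation is present.
#' @param lambda_T additive increment when the TET2 mutation is present.
#' @return a \code{regulation_spec} object.
#' @examples
#' production_rate(regulation_spec(0.5, 1, 1), "JT")  # 2.5
#' @export
regulation_spec <- function(lambda0, lambda_J, lambda_T) {
  stopifnot(is.finite(lambda0), is.finite(lambda_J), is.finite(lambda_T))
  structure(list(lambda0 = lambda0, lambda_J = lambda_J, lambda_T = lambda_T),
            class = "regulation_spec")
}

#' @export
print.regulation_spec <- function(x, ...) {
  cat(sprintf("<regulation_spec> lambda = %g %+g*1_J %+g*1_T\n",
              x$lambda0, x$lambda_J, x$lambda_T))
  invisible(x)
}

#' Production rate for a mutation state
#'
#' @param spec a [regulation_spec()].
#' @param state character vector of states from [mutation_states()].
#' @return numeric \eqn{\lambda} value(s).
#' @export
production_rate <- function(spec, state) {
  stopifnot(inherits(spec, "regulation_spec"))
  spec$lambda0 + spec$lambda_J * has_jak2(state) + spec$lambda_T * has_tet2(state)
}

# deterministic relaxation target: the stable fixed point whose basin
# contains x, read off the sorted fixed-point set (1-D basins are intervals
# bounded by the unstable point / the degenerate root).
relax_target <- function(x, fp) {
  n <- nrow(fp)
  if (n == 1L) return(fp$x[1])
  if (n == 3L) {
    # stable / unstable / stable; the unstable middle is the separatrix
    if (x <= fp$x[2]) fp$x[1] else fp$x[3]
  } else {
    # exactly at a saddle-node threshold: a degenerate (semistable) root D
    # and a simple stable root S.  D attracts from the side facing away
    # from S and repels toward S.
    d <- which(fp$degenerate)[1]
    s <- setdiff(seq_len(n), d)[1]
    if (fp$x[s] > fp$x[d]) {
      if (x <= fp$x[d]) fp$x[d] else fp$x[s]
    } else {
      if (x >= fp$x[d]) fp$x[d] else fp$x[s]
    }
  }
}

#' Quasi-static branch following over a production-rate path
#'
#' Emulates a cell lineage whose production rate \eqn{\lambda} jumps
#' discretely at mutation events while the expression level relaxes to a
#' stable fixed point between events.  Starting from \code{x_init} at
#' \code{lambda_path[1]}, the state relaxes to the stable fixed point whose
#' basin of attraction contains the current level; at each subsequent
#' \eqn{\lambda} the branch containing the current state is kept if it still
#' exists, and when it has disappeared past a saddle-node the state jumps to
#' the remaining stable branch.  This is the source of hysteresis: paths
#' ending at the same \eqn{\lambda} can end on different branches.
#'
#' @param lambda_path numeric vector of successive production rates.
#' @param x_init initial expression level (must lie in the basin of some
#'   stable fixed point at \code{lambda_path[1]}).
#' @param f an [autoreg_cubic()] object.
#' @return the final stable expression level (scalar).
#' @examples
#' follow_branch(c(2, 3, 2), 1)  # 3: up-then-down path ends high
#' follow_branch(c(2, 1, 2), 1)  # 1: down-then-up path stays low
#' @export
follow_branch <- function(lambda_path, x_init, f = autoreg_cubic()) {
  stopifnot(is.numeric(lambda_path), length(lambda_path) >= 1L,
            all(is.finite(lambda_path)), is.finite(x_init))
  x <- x_init
  for (l in lambda_path) x <- relax_target(x, find_fixed_points(l, f))
  x
}

#' Steady-state expression over all mutation histories
#'
#' Computes the stationary expression level reached by each of the five
#' mutation histories O, O\eqn{\to}J, O\eqn{\to}T, O\eqn{\to}J\eqn{\to}JT and
#' O\eqn{\to}T\eqn{\to}TJ, by [follow_branch()] along the corresponding
#' \eqn{\lambda} sequence.  The pre-mutation cell is placed on the stable
#' fixed point reached by relaxing from \eqn{x = 0} at the wild-type
#' \eqn{\lambda} (this selects the low branch when the wild-type rate falls
#' inside the bistable window).  JT and TJ are computed separately; they
#' differ exactly when the two histories end on different branches.
#'
#' @param spec a [regulation_spec()].
#' @param f an [autoreg_cubic()] object.
#' @return an \code{expression_table}: named numeric vector over
#'   \code{c("O","J","T","JT","TJ")} with the per-state \eqn{\lambda} values
#'   as attribute \code{lambda}.
#' @examples
#' mutation_trajectory_steady_states(regulation_spec(2, 1, -1))
#' @export
mutation_trajectory_steady_states <- function(spec, f = autoreg_cubic()) {
  lam <- vapply(mutation_states(), function(s) production_rate(spec, s), 0)
  paths <- list(O  = lam["O"],
                J  = c(lam["O"], lam["J"]),
                T  = c(lam["O"], lam["T"]),
                JT = c(lam["O"], lam["J"], lam["JT"]),
                TJ = c(lam["O"], lam["T"], lam["TJ"]))
  x <- vapply(paths, follow_branch, 0, x_init = 0, f = f)
  structure(x, lambda = lam, class = "expression_table")
}

#' @export
print.expression_table <- function(x, ...) {
  cat("<expression_table>\n")
  print(round(unclass(x), 4))
  invisible(x)
}

#' Coupled two-gene model specification
#'
#' A bistable gene Y, \eqn{dy/dt = \lambda + f(y) - y} with
#' \eqn{\lambda = \lambda_0 + \lambda_J 1_J + \lambda_T 1_T}, drives a linear
#' gene X, \eqn{dx/dt = basal + direct\cdot 1_J + coupling\cdot y - x}.  With
#' the default parameters (basal 1, direct JAK2 effect \eqn{-1}, coupling 1,
#' \eqn{\lambda_Y = 1.5 + 1_J - 1_T}) the JAK2 mutation up-regulates X in a
#' TET2-wild-type background but down-regulates it when the TET2 mutation is
#' already present, i.e. the sign of the JAK2 effect is inverted by TET2.
#'
#' @param y_spec [regulation_spec()] for gene Y.
#' @param basal basal production rate of X.
#' @param direct direct additive JAK2 effect on X production.
#' @param coupling strength of the Y \eqn{\to} X coupling.
#' @param f an [autoreg_cubic()] object for Y's autoregulation.
#' @return a \code{coupled_model_spec} object.
#' @export
coupled_model_spec <- function(y_spec = regulation_spec(1.5, 1, -1),
                               basal = 1, direct = -1, coupling = 1,
                               f = autoreg_cubic()) {
  stopifnot(inherits(y_spec, "regulation_spec"),
            is.finite(basal), is.finite(direct), is.finite(coupling))
  structure(list(y_spec = y_spec, basal = basal, direct = direct,
                 coupling = coupling, f = f),
            class = "coupled_model_spec")
}

#' Steady states of the coupled two-gene model
#'
#' Y steady states come from [mutation_trajectory_steady_states()] applied to
#' the Y specification; since X is linear, its steady state is affine in Y's:
#' \eqn{x^* = basal + direct\cdot 1_J + coupling\cdot y^*}.
#'
#' @param model a [coupled_model_spec()].
#' @return list with \code{y} and \code{x}, each an \code{expression_table}.
#' @examples
#' coupled_steady_states(coupled_model_spec())
#' @export
coupled_steady_states <- function(model = coupled_model_spec()) {
  stopifnot(inherits(model, "coupled_model_spec"))
  y <- mutation_trajectory_steady_states(model$y_spec, model$f)
  states <- mutation_states()
  x <- model$basal + model$direct * has_jak2(states) +
    model$coupling * unclass(y)[states]
  names(x) <- states
  list(y = y,
       x = structure(x, lambda = attr(y, "lambda"), class = "expression_table"))
}

#' Classify an expression table against the clinical observation patterns
#'
#' Tests a table of stationary expression levels for non-additivity and
#' non-commutativity, and assigns the qualitative observation pattern
#' reported for MPN patient samples:
#' \describe{
#'   \item{1}{JAK2 changes expression only without TET2
#'     (\eqn{x^*_T \approx x^*_{TJ}}, \eqn{x^*_O \ne x^*_J}).}
#'   \item{2}{JAK2 changes expression only with TET2
#'     (\eqn{x^*_O \approx x^*_J}, \eqn{x^*_T \ne x^*_{TJ}}).}
#'   \item{3}{JAK2 up-regulates without TET2 but down-regulates with TET2
#'     (\eqn{x^*_O < x^*_J}, \eqn{x^*_T > x^*_{TJ}}).}
#'   \item{4}{Order effect: \eqn{x^*_{JT} \ne x^*_{TJ}}.}
#' }
#' Two tolerances are used.  \code{tol} (default 0.05 expression units)
#' decides the quantitative non-additivity and non-commutativity flags.
#' \code{label_tol} (default 0.5, about half the gap between the low and high
#' expression branches) decides the qualitative pattern label, because the
#' published patterns call small same-branch shifts (e.g. 0.6 vs 0.8)
#' "unchanged" while branch switches (0.8 vs 3.2) are "changed".  Pattern 4
#' takes priority; then 3, 1, 2; \code{"none"} if no pattern matches.
#'
#' @param table an \code{expression_table} (or named numeric with entries
#'   O, J, T, JT, TJ).
#' @param tol tolerance for the non-additivity/non-commutativity flags.
#' @param label_tol tolerance separating "unchanged" from "changed" for the
#'   qualitative pattern label.
#' @return list with logical \code{non_additive}, \code{non_commutative} and
#'   character \code{observation} in \code{c("1","2","3","4","none")}.
#' @export
classify_observation <- function(table, tol = 0.05, label_tol = 0.5) {
  stopifnot(tol > 0, label_tol > 0)
  x <- unclass(table)[mutation_states()]
  if (any(is.na(x))) stop("table must contain entries O, J, T, JT, TJ")
  add_J <- (x["J"] - x["O"]) - (x["TJ"] - x["T"])  # JAK2 effect, +/- TET2
  add_T <- (x["T"] - x["O"]) - (x["JT"] - x["J"])  # TET2 effect, +/- JAK2
  non_additive <- abs(add_J) > tol || abs(add_T) > tol
  non_commutative <- abs(x["JT"] - x["TJ"]) > tol
  dJ_noT <- x["J"] - x["O"]    # effect of gaining JAK2 without TET2
  dJ_wT  <- x["TJ"] - x["T"]   # effect of gaining JAK2 on a TET2 background
  observation <-
    if (abs(x["JT"] - x["TJ"]) > label_tol) "4"
    else if (dJ_noT > label_tol && dJ_wT < -label_tol) "3"
    else if (abs(dJ_wT) <= label_tol && abs(dJ_noT) > label_tol) "1"
    else if (abs(dJ_noT) <= label_tol && abs(dJ_wT) > label_tol) "2"
    else "none"
  list(non_additive = unname(non_additive),
       non_commutative = unname(non_commutative),
       observation = observation)
}

#' Published scenario presets
#'
#' Named presets for the regulation specifications used in the published
#' steady-state tables: four gating scenarios (\code{"fig2a"}--\code{"fig2d"}),
#' the two order-dependent scenarios (\code{"fig4a"}, \code{"fig4b"}) and the
#' coupled two-gene model (\code{"fig3"}).
#'
#' @param name preset name.
#' @return for \code{"fig3"} a [coupled_model_spec()]; otherwise a
#'   [regulation_spec()].
#' @export
scenario_preset <- function(name = c("fig2a", "fig2b", "fig2c", "fig2d",
                                     "fig4a", "fig4b", "fig3")) {
  name <- match.arg(name)
  switch(name,
         fig2a = regulation_spec(0.5,  1,  1),
         fig2b = regulation_spec(3.5, -1, -1),
         fig2c = regulation_spec(1.5,  1, -1),
         fig2d = regulation_spec(2.5, -1,  1),
         fig4a = regulation_spec(2,    1, -1),
         fig4b = regulation_spec(2,   -1,  1),
         fig3  = coupled_model_spec())
}
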