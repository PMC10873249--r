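#' Parameters of the generalized five-type Moran process
#'
#' A constant-population birth-death-mutation process over the five mutation
#' states O, J, T, JT, TJ.  At each discrete replacement step one cell is
#' chosen for removal with probability proportional to \eqn{n_i d_i} and one
#' cell is chosen for division with probability proportional to \eqn{n_i b_i};
#' one daughter keeps the mother's type while the other may acquire a single
#' extra mutation (O\eqn{\to}J, O\eqn{\to}T, J\eqn{\to}JT or T\eqn{\to}TJ)
#' with the given per-birth probability.  The total population \eqn{n} is
#' conserved.
#'
#' By default the dying cell is excluded from the birth draw
#' (\code{birth_exclusive = TRUE}): the cell removed at a step cannot
#' simultaneously be the one that divides, so birth weights are evaluated on
#' the post-death counts.  Setting \code{birth_exclusive = FALSE} in the
#' step/propagation functions selects the fully independent reading instead;
#' the two differ at order \eqn{1/n}.
#'
#' @param birth named or positional numeric(5) birth coefficients
#'   \code{(b_O, b_J, b_T, b_JT, b_TJ)}, all > 0.
#' @param death numeric(5) death coefficients, all > 0 (default all 1).
#' @param mutation numeric(4) mutation probabilities
#'   \code{(m_OJ, m_OT, m_JJT, m_TTJ)}, each in \[0,1\] with
#'   \code{m_OJ + m_OT <= 1}.
#' @param n total population size (>= 2).
#' @return a \code{moran_parameters} object.
#' @seealso [make_scenario()] for the published mechanism presets.
#' @export
moran_parameters <- function(birth, death = rep(1, 5), mutation, n) {
  birth <- as.numeric(birth); death <- as.numeric(death)
  mutation <- as.numeric(mutation)
  if (length(birth) != 5L || any(birth <= 0))
    stop("'birth' must be 5 positive coefficients (O, J, T, JT, TJ)")
  if (length(death) != 5L || any(death <= 0))
    stop("'death' must be 5 positive coefficients")
  if (length(mutation) != 4L || any(mutation < 0) || any(mutation > 1))
    stop("'mutation' must be 4 probabilities (O->J, O->T, J->JT, T->TJ)")
  if (mutation[1] + mutation[2] > 1)
    stop("m_OJ + m_OT must not exceed 1")
  n <- as.integer(n)
  if (is.na(n) || n < 2L) stop("'n' must be an integer >= 2")
  names(birth) <- names(death) <- mutation_states()
  names(mutation) <- c("O_J", "O_T", "J_JT", "T_TJ")
  structure(list(birth = birth, death = death, mutation = mutation, n = n),
            class = "moran_parameters")
}

#' @export
print.moran_parameters <- function(x, ...) {
  cat(sprintf("<moran_parameters> n = %d\n", x$n))
  cat("  birth:    ", paste(sprintf("%s=%g", names(x$birth), x$birth),
                            collapse = " "), "\n")
  cat("  death:    ", paste(sprintf("%s=%g", names(x$death), x$death),
                            collapse = " "), "\n")
  cat("  mutation: ", paste(sprintf("%s=%g", names(x$mutation), x$mutation),
                            collapse = " "), "\n")
  invisible(x)
}

#' Published mechanism presets for the Moran process
#'
#' The three mechanistic scenarios explored for the order-of-mutation
#' observations, with all death coefficients equal to 1:
#' \describe{
#'   \item{A}{proliferation advantage of TET2-mutated cells:
#'     b = (1,2,4,4,4), all m = 0.1.}
#'   \item{B}{asymmetric mutation rates (TET2 mutates more readily):
#'     b = (1,2,2,2,2), m = (0.1, 0.2, 0.2, 0.1).}
#'   \item{C}{cooperative mutation (JAK2 raises the TET2 mutation rate):
#'     b = (1,2,2,2,2), m = (0.1, 0.1, 0.2, 0.1).}
#' }
#'
#' @param name \code{"A"}, \code{"B"} or \code{"C"}.
#' @param n population size (default 100).
#' @return a [moran_parameters()] object.
#' @export
make_scenario <- function(name = c("A", "B", "C"), n = 100) {
  name <- match.arg(name)
  switch(name,
         A = moran_parameters(c(1, 2, 4, 4, 4), mutation = c(0.1, 0.1, 0.1, 0.1), n = n),
         B = moran_parameters(c(1, 2, 2, 2, 2), mutation = c(0.1, 0.2, 0.2, 0.1), n = n),
         C = moran_parameters(c(1, 2, 2, 2, 2), mutation = c(0.1, 0.1, 0.2, 0.1), n = n))
}

#' A population state of the Moran process
#'
#' @param n_O,n_J,n_T,n_JT,n_TJ non-negative cell counts.
#' @return named integer vector of length 5.
#' @export
population_state <- function(n_O, n_J = 0, n_T = 0, n_JT = 0, n_TJ = 0) {
  s <- as.integer(c(O = n_O, J = n_J, T = n_T, JT = n_JT, TJ = n_TJ))
  if (any(is.na(s)) || any(s < 0)) stop("counts must be non-negative integers")
  names(s) <- mutation_states()
  s
}

check_population <- function(state, params) {
  if (is.null(names(state))) names(state) <- mutation_states()
  state <- state[mutation_states()]
  if (any(is.na(state)) || any(state < 0))
    stop("state must give non-negative counts for O, J, T, JT, TJ")
  if (sum(state) != params$n)
    stop(sprintf("state must conserve the population: sum = %d, n = %d",
                 sum(state), params$n))
  state
}

# probabilities of the daughter's type given post-/pre-death counts `cnt`
birth_outcome_probs <- function(cnt, params) {
  b <- params$birth; m <- params$mutation
  w <- cnt * b
  B <- sum(w)
  if (B <= 0) stop("total birth weight is zero")
  c(O  = unname(w["O"] * (1 - m["O_J"] - m["O_T"]) / B),
    J  = unname((w["O"] * m["O_J"] + w["J"] * (1 - m["J_JT"])) / B),
    T  = unname((w["O"] * m["O_T"] + w["T"] * (1 - m["T_TJ"])) / B),
    JT = unname((w["J"] * m["J_JT"] + w["JT"]) / B),
    TJ = unname((w["T"] * m["T_TJ"] + w["TJ"]) / B))
}

#' One-step transition distribution of the Moran process
#'
#' Composes the death draw (type removed with probability
#' \eqn{n_i d_i / \sum_j n_j d_j}) with the birth-and-mutation draw for the
#' added daughter, returning the exact distribution over successor
#' population states.  Successors reached by several (death, birth)
#' combinations are merged.
#'
#' @param state population state ([population_state()] or named counts).
#' @param params a [moran_parameters()] object.
#' @param birth_exclusive if \code{TRUE} (default) the dying cell is removed
#'   before the birth draw; if \code{FALSE} the two draws are independent.
#' @return data frame with columns \code{O, J, T, JT, TJ, prob}; the
#'   probabilities sum to 1.
#' @examples
#' p <- make_scenario("B", n = 100)
#' step_distribution(population_state(100), p)
#' @export
step_distribution <- function(state, params, birth_exclusive = TRUE) {
  stopifnot(inherits(params, "moran_parameters"))
  state <- check_population(state, params)
  d <- params$death
  dw <- state * d
  D <- sum(dw)
  succ <- list(); probs <- c()
  for (di in mutation_states()) {
    pd <- dw[di] / D
    if (pd == 0) next
    cnt <- state
    if (birth_exclusive) cnt[di] <- cnt[di] - 1L
    pb <- birth_outcome_probs(cnt, params)
    for (bi in mutation_states()) {
      if (pb[bi] == 0) next
      s2 <- state
      s2[di] <- s2[di] - 1L
      s2[bi] <- s2[bi] + 1L
      succ[[length(succ) + 1L]] <- s2
      probs <- c(probs, pd * pb[bi])
    }
  }
  out <- as.data.frame(do.call(rbind, succ))
  out$prob <- probs
  agg <- stats::aggregate(prob ~ O + J + T + JT + TJ, data = out, FUN = sum)
  agg[order(-agg$prob), , drop = FALSE]
}

#' Simulate the Moran process to the first double-mutant
#'
#' Monte-Carlo simulation of replacement steps until the first JT or TJ cell
#' appears, using the exact one-step transition probabilities.  Each
#' trajectory is classified on the post-step population: a pure JAK2-first
#' outcome has \eqn{n_{JT} = 1} and \eqn{n_T = 0} (record \eqn{n_J}), a pure
#' TET2-first outcome has \eqn{n_{TJ} = 1} and \eqn{n_J = 0} (record
#' \eqn{n_T}); anything else is ambiguous (both single-mutant types present)
#' and its count is recorded as \code{NA}.  The absorbing step is counted in
#' the absorption time \code{T} (the initial state is step 0).
#'
#' @param object a [moran_parameters()] object.
#' @param nsim number of independent trajectories.
#' @param seed optional integer seed (set once before all trajectories).
#' @param initial initial population state (default all wild-type).
#' @param birth_exclusive step semantics, see [step_distribution()].
#' @param max_steps guard against non-absorbing parameter sets (e.g. both
#'   double-mutation probabilities zero); exceeding it is an error.
#' @param ... unused.
#' @return data frame with one row per trajectory: \code{class}
#'   (\code{"JAK2_first_pure"}, \code{"TET2_first_pure"} or
#'   \code{"ambiguous"}), \code{count} (single-mutant cells of the matching
#'   type at absorption; \code{NA} for ambiguous) and \code{T} (absorption
#'   step).
#' @examples
#' p <- make_scenario("B", n = 20)
#' simulate(p, nsim = 5, seed = 1)
#' @export
simulate.moran_parameters <- function(object, nsim = 1, seed = NULL,
                                      initial = NULL, birth_exclusive = TRUE,
                                      max_steps = 1e6, ...) {
  params <- object
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (is.null(initial)) initial <- population_state(params$n)
  initial <- check_population(initial, params)
  b <- params$birth; d <- params$death; m <- params$mutation
  states <- mutation_states()
  cls <- character(nsim); cnt <- integer(nsim); tt <- integer(nsim)
  for (r in seq_len(nsim)) {
    s <- initial
    t <- 0L
    repeat {
      t <- t + 1L
      if (t > max_steps)
        stop("max_steps exceeded before absorption; check mutation probabilities")
      di <- sample.int(5L, 1L, prob = s * d)
      post <- s
      post[di] <- post[di] - 1L
      pb <- birth_outcome_probs(if (birth_exclusive) post else s, params)
      bi <- sample.int(5L, 1L, prob = pb)
      post[bi] <- post[bi] + 1L
      s <- post
      if (s[["JT"]] >= 1L || s[["TJ"]] >= 1L) break
    }
    if (s[["JT"]] >= 1L && s[["T"]] == 0L) {
      cls[r] <- "JAK2_first_pure"; cnt[r] <- s[["J"]]
    } else if (s[["TJ"]] >= 1L && s[["J"]] == 0L) {
      cls[r] <- "TET2_first_pure"; cnt[r] <- s[["T"]]
    } else {
      cls[r] <- "ambiguous"; cnt[r] <- NA_integer_
    }
    tt[r] <- t
  }
  data.frame(class = cls, count = cnt, T = tt)
}
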