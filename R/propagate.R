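# Exact transient propagation of the Moran process to the first double-mutant.
#
# Before absorption only O, J and T cells exist, so the reachable state space
# is {(n_J, n_T) : n_J + n_T <= n} with n_O = n - n_J - n_T -- choose(n+2, 2)
# configurations (5151 for n = 100).  The one-step kernel restricted to this
# space is time-homogeneous, so it is assembled once as a sparse matrix and
# the state-probability vector is pushed forward step by step, splitting off
# the mass that flows into absorbing events (a JT or TJ daughter).

build_propagation_kernel <- function(params, birth_exclusive = TRUE) {
  n <- params$n
  b <- params$birth; d <- params$death; m <- params$mutation
  nJ <- integer(0); nT <- integer(0)
  for (i in 0:n) {
    nJ <- c(nJ, rep(i, n - i + 1L))
    nT <- c(nT, 0:(n - i))
  }
  K <- length(nJ)
  nO <- n - nJ - nT
  idx <- matrix(NA_integer_, n + 1L, n + 1L)
  idx[cbind(nJ + 1L, nT + 1L)] <- seq_len(K)

  D <- nO * d["O"] + nJ * d["J"] + nT * d["T"]
  Pi <- integer(0); Pj <- integer(0); Px <- numeric(0)   # transition triplets
  aJ_row <- integer(0); aJ_col <- integer(0); aJ_x <- numeric(0)
  aT_row <- integer(0); aT_col <- integer(0); aT_x <- numeric(0)
  amb <- numeric(K)

  for (di in c("O", "J", "T")) {
    nd <- switch(di, O = nO, J = nJ, T = nT)
    pd <- nd * d[di] / D
    o <- nO - (di == "O"); j <- nJ - (di == "J"); t <- nT - (di == "T")
    if (birth_exclusive) { bo <- o; bj <- j; bt <- t } else { bo <- nO; bj <- nJ; bt <- nT }
    B <- bo * b["O"] + bj * b["J"] + bt * b["T"]
    B[B == 0] <- NA  # only when n - 1 = 0; excluded by n >= 2
    pbO <- bo * b["O"] * (1 - m["O_J"] - m["O_T"]) / B
    pbJ <- (bo * b["O"] * m["O_J"] + bj * b["J"] * (1 - m["J_JT"])) / B
    pbT <- (bo * b["O"] * m["O_T"] + bt * b["T"] * (1 - m["T_TJ"])) / B
    pJT <- bj * b["J"] * m["J_JT"] / B
    pTJ <- bt * b["T"] * m["T_TJ"] / B
    for (bi in c("O", "J", "T")) {
      pr <- pd * switch(bi, O = pbO, J = pbJ, T = pbT)
      keep <- which(pr > 0)
      if (!length(keep)) next
      j2 <- j[keep] + (bi == "J"); t2 <- t[keep] + (bi == "T")
      Pi <- c(Pi, idx[cbind(j2 + 1L, t2 + 1L)])
      Pj <- c(Pj, keep)
      Px <- c(Px, pr[keep])
    }
    # absorbing events, classified on the post-death single-mutant counts
    prJT <- pd * pJT
    keep <- which(prJT > 0)
    if (length(keep)) {
      pure <- t[keep] == 0
      if (any(pure)) {
        aJ_row <- c(aJ_row, j[keep][pure] + 1L)
        aJ_col <- c(aJ_col, keep[pure])
        aJ_x <- c(aJ_x, prJT[keep][pure])
      }
      if (any(!pure)) amb[keep[!pure]] <- amb[keep[!pure]] + prJT[keep][!pure]
    }
    prTJ <- pd * pTJ
    keep <- which(prTJ > 0)
    if (length(keep)) {
      pure <- j[keep] == 0
      if (any(pure)) {
        aT_row <- c(aT_row, t[keep][pure] + 1L)
        aT_col <- c(aT_col, keep[pure])
        aT_x <- c(aT_x, prTJ[keep][pure])
      }
      if (any(!pure)) amb[keep[!pure]] <- amb[keep[!pure]] + prTJ[keep][!pure]
    }
  }
  list(K = K, idx = idx, nJ = nJ, nT = nT,
       P = Matrix::sparseMatrix(i = Pi, j = Pj, x = Px, dims = c(K, K)),
       A_J = Matrix::sparseMatrix(i = aJ_row, j = aJ_col, x = aJ_x,
                                  dims = c(n + 1L, K)),
       A_T = Matrix::sparseMatrix(i = aT_row, j = aT_col, x = aT_x,
                                  dims = c(n + 1L, K)),
       amb = amb)
}

#' Exact transient propagation to the first double-mutant
#'
#' Deterministically propagates the state-probability vector of the Moran
#' process over all non-absorbed configurations, recording at every step the
#' probability mass that produces the first JT or TJ daughter jointly with
#' the post-step single-mutant count and the step index.  Outcomes with both
#' single-mutant types present at absorption are accumulated as ambiguous
#' (they would not allow the mutation order to be inferred).  Propagation
#' stops once the survival probability \eqn{S(t)} (no double-mutant yet)
#' satisfies \eqn{S(t) <} \code{survival_tol} \emph{and} \eqn{t >}
#' \code{min_steps}; the defaults bound the truncation error of the count
#' expectations by about \eqn{n \cdot 10^{-8}}.
#'
#' @param params a [moran_parameters()] object.
#' @param survival_tol stop threshold for \eqn{S(t)}, in (0,1).
#' @param min_steps minimum number of steps before stopping.
#' @param birth_exclusive step semantics, see [step_distribution()].
#' @param max_steps hard cap; exceeding it raises an error.
#' @param initial optional initial state (default all wild-type); must have
#'   no double-mutant cells.
#' @return an \code{absorption_distribution}: a list with per-class
#'   absorption mass (\code{class_mass}), single-mutant count distributions
#'   (\code{count_dist}, indexed 0..n), absorption-time distributions
#'   (\code{time_dist}, indexed 1..steps), the survival trace
#'   (\code{survival}), \code{residual_survival} and \code{steps}.
#' @examples
#' d <- propagate_exact(make_scenario("B", n = 20))
#' absorption_statistics(d)
#' @export
propagate_exact <- function(params, survival_tol = 1e-8, min_steps = 400,
                            birth_exclusive = TRUE, max_steps = 1e6,
                            initial = NULL) {
  stopifnot(inherits(params, "moran_parameters"),
            survival_tol > 0, survival_tol < 1, min_steps >= 0)
  n <- params$n
  ker <- build_propagation_kernel(params, birth_exclusive)
  p <- numeric(ker$K)
  if (is.null(initial)) {
    start <- ker$idx[1L, 1L]  # (n_J, n_T) = (0, 0)
    p[start] <- 1
  } else {
    initial <- check_population(initial, params)
    if (initial[["JT"]] > 0 || initial[["TJ"]] > 0)
      stop("initial state must contain no double-mutant cells")
    p[ker$idx[initial[["J"]] + 1L, initial[["T"]] + 1L]] <- 1
  }
  countJ <- numeric(n + 1L); countT <- numeric(n + 1L)
  cap <- 4096L
  tmassJ <- numeric(cap); tmassT <- numeric(cap); tmassA <- numeric(cap)
  Strace <- numeric(cap)
  t <- 0L; S <- 1
  while (!(S < survival_tol && t > min_steps)) {
    t <- t + 1L
    if (t > max_steps)
      stop(sprintf("propagation did not converge within %d steps (S = %.3g)",
                   as.integer(max_steps), S))
    if (t > cap) {
      cap <- cap * 2L
      length(tmassJ) <- cap; length(tmassT) <- cap
      length(tmassA) <- cap; length(Strace) <- cap
      tmassJ[is.na(tmassJ)] <- 0; tmassT[is.na(tmassT)] <- 0
      tmassA[is.na(tmassA)] <- 0; Strace[is.na(Strace)] <- 0
    }
    vJ <- as.numeric(ker$A_J %*% p)
    vT <- as.numeric(ker$A_T %*% p)
    countJ <- countJ + vJ
    countT <- countT + vT
    tmassJ[t] <- sum(vJ)
    tmassT[t] <- sum(vT)
    tmassA[t] <- sum(ker$amb * p)
    p <- as.numeric(ker$P %*% p)
    S <- sum(p)
    Strace[t] <- S
  }
  structure(list(
    class_mass = c(JAK2_first_pure = sum(countJ),
                   TET2_first_pure = sum(countT),
                   ambiguous = sum(tmassA[seq_len(t)])),
    count_dist = list(JAK2_first_pure = countJ, TET2_first_pure = countT),
    time_dist = list(JAK2_first_pure = tmassJ[seq_len(t)],
                     TET2_first_pure = tmassT[seq_len(t)],
                     ambiguous = tmassA[seq_len(t)]),
    survival = Strace[seq_len(t)],
    residual_survival = S,
    steps = t,
    n = n,
    birth_exclusive = birth_exclusive,
    survival_tol = survival_tol,
    min_steps = min_steps,
    params = params), class = "absorption_distribution")
}

#' @export
print.absorption_distribution <- function(x, ...) {
  cat(sprintf("<absorption_distribution> n = %d, %d steps, residual S = %.3g\n",
              x$n, x$steps, x$residual_survival))
  cat("  class mass:", paste(sprintf("%s=%.4f", names(x$class_mass),
                                     x$class_mass), collapse = " "), "\n")
  invisible(x)
}

moments_from_dist <- function(mass, values) {
  m0 <- sum(mass)
  mu <- sum(mass * values) / m0
  v <- sum(mass * values^2) / m0 - mu^2
  c(mean = mu, sd = sqrt(max(v, 0)))
}

#' Conditional absorption statistics
#'
#' Conditional mean and standard deviation of the single-mutant count and of
#' the absorption time \code{T}, per pure outcome class, together with each
#' class's absorption probability.  Ambiguous outcomes are reported in the
#' attributes but excluded from the conditionals.  Works on the exact
#' [propagate_exact()] output or on a data frame of Monte-Carlo records from
#' [simulate.moran_parameters()] (where sample standard deviations are used).
#'
#' @param dist an \code{absorption_distribution} or a record data frame.
#' @param classes which classes to report (default both pure classes); a
#'   requested class with zero mass is an error.
#' @return data frame with columns \code{class}, \code{probability},
#'   \code{mean_count}, \code{sd_count}, \code{mean_T}, \code{sd_T};
#'   attributes \code{ambiguous} (mass or record count) and, for the exact
#'   route, \code{residual_survival}.
#' @export
absorption_statistics <- function(dist,
                                  classes = c("JAK2_first_pure",
                                              "TET2_first_pure")) {
  UseMethod("absorption_statistics")
}

#' @export
absorption_statistics.absorption_distribution <- function(dist,
    classes = c("JAK2_first_pure", "TET2_first_pure")) {
  classes <- match.arg(classes, several.ok = TRUE)
  rows <- lapply(classes, function(cl) {
    mass <- dist$class_mass[[cl]]
    if (mass <= 0)
      stop(sprintf("zero conditional mass for class '%s'", cl))
    cm <- moments_from_dist(dist$count_dist[[cl]],
                            seq_along(dist$count_dist[[cl]]) - 1)
    tm <- moments_from_dist(dist$time_dist[[cl]],
                            seq_along(dist$time_dist[[cl]]))
    data.frame(class = cl, probability = mass,
               mean_count = cm[["mean"]], sd_count = cm[["sd"]],
               mean_T = tm[["mean"]], sd_T = tm[["sd"]])
  })
  out <- do.call(rbind, rows)
  attr(out, "ambiguous") <- unname(dist$class_mass[["ambiguous"]])
  attr(out, "residual_survival") <- dist$residual_survival
  out
}

#' @export
absorption_statistics.data.frame <- function(dist,
    classes = c("JAK2_first_pure", "TET2_first_pure")) {
  stopifnot(all(c("class", "count", "T") %in% names(dist)))
  classes <- match.arg(classes, several.ok = TRUE)
  rows <- lapply(classes, function(cl) {
    sub <- dist[dist$class == cl, , drop = FALSE]
    if (nrow(sub) == 0)
      stop(sprintf("zero conditional mass for class '%s'", cl))
    data.frame(class = cl, probability = nrow(sub) / nrow(dist),
               mean_count = mean(sub$count),
               sd_count = if (nrow(sub) > 1) stats::sd(sub$count) else 0,
               mean_T = mean(sub$T),
               sd_T = if (nrow(sub) > 1) stats::sd(sub$T) else 0)
  })
  out <- do.call(rbind, rows)
  attr(out, "ambiguous") <- sum(dist$class == "ambiguous")
  out
}

#' Absorption statistics across population sizes
#'
#' Runs [propagate_exact()] for each population size and stacks the
#' conditional statistics, to examine how the JAK2-first / TET2-first
#' contrasts depend on the total cell number \eqn{n}.
#'
#' @param scenario mechanism preset name (\code{"A"}, \code{"B"},
#'   \code{"C"}) or a function \code{(n) -> moran_parameters}.
#' @param n_list population sizes (each >= 2).
#' @param ... passed to [propagate_exact()].
#' @return data frame with a leading \code{n} column followed by the
#'   [absorption_statistics()] columns.
#' @export
system_size_sweep <- function(scenario, n_list, ...) {
  stopifnot(length(n_list) >= 1L, all(n_list >= 2))
  maker <- if (is.function(scenario)) scenario
           else function(n) make_scenario(scenario, n = n)
  rows <- lapply(n_list, function(n) {
    st <- absorption_statistics(propagate_exact(maker(n), ...))
    cbind(n = n, st)
  })
  do.call(rbind, rows)
}

#' Per-group sample size for a two-sample t-test
#'
#' Normal-approximation sample size for detecting the difference between two
#' means with a two-sided two-sample t-test:
#' \eqn{n \approx (z_{1-\alpha/2} + z_{power})^2 (s_1^2 + s_2^2) / \Delta^2},
#' rounded up, with a floor of 2 per group.  Used to gauge how many
#' JAK2-first and TET2-first patients would be needed to resolve the
#' conditional contrasts predicted by each mechanism.
#'
#' @param mean1,sd1 mean and standard deviation of group 1.
#' @param mean2,sd2 mean and standard deviation of group 2.
#' @param alpha two-sided significance level (default 0.01).
#' @param power target power (default 0.80).
#' @return integer per-group sample size.
#' @examples
#' required_sample_size(2.34, 1.65, 6.49, 5.09)
#' @export
required_sample_size <- function(mean1, sd1, mean2, sd2,
                                 alpha = 0.01, power = 0.80) {
  stopifnot(sd1 > 0, sd2 > 0, alpha > 0, alpha < 1, power > 0, power < 1)
  delta <- mean1 - mean2
  if (delta == 0) stop("means are equal: no sample size can resolve them")
  z <- stats::qnorm(1 - alpha / 2) + stats::qnorm(power)
  max(2L, as.integer(ceiling(z^2 * (sd1^2 + sd2^2) / delta^2)))
}
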