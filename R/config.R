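#' Load a run configuration
#'
#' Reads a JSON configuration file describing one or both model families and
#' validates it strictly: unknown keys are rejected with a message naming
#' the offending field.  The schema is
#' \preformatted{
#' {
#'   "seed": 1,
#'   "model": {
#'     "cubic": [4, -10, 6, -1],
#'     "regulation": {"lambda0": 2, "lambda_J": 1, "lambda_T": -1},
#'     "coupled": {"basal": 1, "direct": -1, "coupling": 1},
#'     "tol": 1e-9
#'   },
#'   "moran": {
#'     "scenario": "B",              // or explicit birth/death/mutation
#'     "n": 100,
#'     "birth": [1, 2, 2, 2, 2],
#'     "death": [1, 1, 1, 1, 1],
#'     "mutation": [0.1, 0.2, 0.2, 0.1],
#'     "survival_tol": 1e-8,
#'     "min_steps": 400,
#'     "birth_exclusive": true
#'   }
#' }
#' }
#' All sections and most keys are optional, but at least one of
#' \code{model} / \code{moran} must be present.  A \code{moran} section with
#' a \code{scenario} name is expanded to the corresponding preset; explicit
#' parameter arrays override nothing and may not be combined with
#' \code{scenario}.
#'
#' @param path path to the JSON file.
#' @return a \code{run_config} list with elements \code{seed}, \code{model}
#'   (containing an [autoreg_cubic()], optional [regulation_spec()],
#'   optional [coupled_model_spec()], and \code{tol}) and \code{moran}
#'   (containing a [moran_parameters()] object plus propagation settings).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  check_keys(cfg, c("seed", "model", "moran"), "top level")
  if (is.null(cfg$model) && is.null(cfg$moran))
    stop("config must contain at least one of 'model' or 'moran'")
  out <- list(seed = if (is.null(cfg$seed)) 1L else as.integer(cfg$seed),
              model = NULL, moran = NULL)

  if (!is.null(cfg$model)) {
    mc <- cfg$model
    check_keys(mc, c("cubic", "regulation", "coupled", "tol"), "model")
    f <- if (is.null(mc$cubic)) autoreg_cubic() else autoreg_cubic(mc$cubic)
    reg <- NULL
    if (!is.null(mc$regulation)) {
      check_keys(mc$regulation, c("lambda0", "lambda_J", "lambda_T"),
                 "model.regulation")
      reg <- regulation_spec(num_field(mc$regulation, "lambda0"),
                             num_field(mc$regulation, "lambda_J"),
                             num_field(mc$regulation, "lambda_T"))
    }
    coup <- NULL
    if (!is.null(mc$coupled)) {
      check_keys(mc$coupled, c("basal", "direct", "coupling"), "model.coupled")
      if (is.null(reg))
        stop("model.coupled requires model.regulation (the Y-gene spec)")
      coup <- coupled_model_spec(
        y_spec = reg,
        basal = num_field(mc$coupled, "basal"),
        direct = num_field(mc$coupled, "direct"),
        coupling = num_field(mc$coupled, "coupling"),
        f = f)
    }
    out$model <- list(f = f, regulation = reg, coupled = coup,
                      tol = if (is.null(mc$tol)) 1e-9 else as.numeric(mc$tol))
  }

  if (!is.null(cfg$moran)) {
    mo <- cfg$moran
    check_keys(mo, c("scenario", "n", "birth", "death", "mutation",
                     "survival_tol", "min_steps", "birth_exclusive"), "moran")
    n <- if (is.null(mo$n)) 100L else as.integer(mo$n)
    if (!is.null(mo$scenario)) {
      if (!is.null(mo$birth) || !is.null(mo$mutation))
        stop("moran.scenario may not be combined with explicit parameters")
      params <- make_scenario(mo$scenario, n = n)
    } else {
      if (is.null(mo$birth) || is.null(mo$mutation))
        stop("moran needs either 'scenario' or explicit 'birth' and 'mutation'")
      params <- moran_parameters(
        birth = mo$birth,
        death = if (is.null(mo$death)) rep(1, 5) else mo$death,
        mutation = mo$mutation, n = n)
    }
    out$moran <- list(
      params = params,
      survival_tol = if (is.null(mo$survival_tol)) 1e-8
                     else as.numeric(mo$survival_tol),
      min_steps = if (is.null(mo$min_steps)) 400L else as.integer(mo$min_steps),
      birth_exclusive = if (is.null(mo$birth_exclusive)) TRUE
                        else isTRUE(mo$birth_exclusive))
  }
  structure(out, class = "run_config")
}

check_keys <- function(x, allowed, where) {
  extra <- setdiff(names(x), allowed)
  if (length(extra))
    stop(sprintf("unknown key%s in %s: %s", if (length(extra) > 1) "s" else "",
                 where, paste(extra, collapse = ", ")))
  invisible(TRUE)
}

num_field <- function(x, key) {
  if (is.null(x[[key]])) stop(sprintf("missing required field '%s'", key))
  v <- as.numeric(x[[key]])
  if (length(v) != 1L || !is.finite(v))
    stop(sprintf("field '%s' must be a single finite number", key))
  v
}
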