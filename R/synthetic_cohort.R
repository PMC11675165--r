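#' Default configuration for a PBIHB-like synthetic cohort
#'
#' Returns the generator configuration used throughout the package's
#' simulation studies. It mirrors the PBIHB questionnaire cohort: N = 60
#' healthy adults; age continuous (mean 30, sd 8); gender Bernoulli(0.5);
#' metacognition of allostatic control (M, sum of two MAIA subscale means,
#' range 0-10), fatigue (F, FSS mean score, range 1-7), general self-efficacy
#' (S, GSES total, range 10-40) and depression (D, CES-D total, range 0-60)
#' generated by the linear-Gaussian ASE structural equations.
#'
#' The metacognition-to-fatigue coefficient defaults to `theta3 = -0.48`
#' (a plausible true effect at the scale reported for this cohort) and the
#' fatigue x self-efficacy interaction on depression defaults to
#' `theta10 = 0`. The remaining coefficients and noise scales are documented
#' package constants chosen so each structural equation has a demographic
#' R-squared typical of questionnaire data (roughly 0.1-0.3) and column
#' means/sds sit mid-scale for each instrument; they are not estimates from
#' any dataset. Questionnaire-range mode (clip to instrument bounds, then
#' round to instrument granularity) is off by default.
#'
#' @param n cohort size (default 60).
#' @param seed integer seed (default 1).
#' @param theta named numeric overrides for any of `theta1` .. `theta12`.
#' @param range_mode logical; clip-and-round to questionnaire ranges.
#' @return A `ase_generator_config` list with elements `n`, `seed`, `theta`,
#'   `noise`, `intercepts`, `range_mode`, `bounds`, `granularity`.
#' @examples
#' cfg <- default_pbihb_like_config()
#' cohort <- generate_cohort(cfg)
#' @export
default_pbihb_like_config <- function(n = 60, seed = 1, theta = numeric(0),
                                      range_mode = FALSE) {
  th <- c(
    theta1 = 0.06,   # A -> M
    theta2 = 0.8,    # G -> M
    theta3 = -0.48,  # M -> F
    theta4 = 0.06,   # A -> F
    theta5 = 0.6,    # G -> F
    theta6 = 0.15,   # A -> S
    theta7 = 2.0,    # G -> S
    theta8 = 2.0,    # F -> D
    theta9 = -0.6,   # S -> D
    theta10 = 0,     # (F*S) -> D interaction
    theta11 = -0.05, # A -> D
    theta12 = 1.5    # G -> D
  )
  if (length(theta) > 0) {
    bad <- setdiff(names(theta), names(th))
    if (length(bad) > 0) stop("unknown theta name(s): ", paste(bad, collapse = ", "))
    th[names(theta)] <- theta
  }
  cfg <- list(
    n = as.integer(n),
    seed = as.integer(seed),
    theta = th,
    noise = list(
      A = list(dist = "gaussian", mean = 30, sd = 8),
      G = list(dist = "bernoulli", p = 0.5),
      M = list(dist = "gaussian", mean = 0, sd = 1.5),
      F = list(dist = "gaussian", mean = 0, sd = 1.1),
      S = list(dist = "gaussian", mean = 0, sd = 4.5),
      D = list(dist = "gaussian", mean = 0, sd = 5)
    ),
    intercepts = c(A = 0, G = 0, M = 3, F = 3.7, S = 24.5, D = 22),
    range_mode = isTRUE(range_mode),
    bounds = list(A = c(18, 65), M = c(0, 10), F = c(1, 7), S = c(10, 40), D = c(0, 60)),
    granularity = c(A = 1, M = 0.5, F = 1 / 9, S = 1, D = 1)
  )
  validate_generator_config(cfg)
  structure(cfg, class = "ase_generator_config")
}

validate_generator_config <- function(cfg) {
  if (cfg$n <= 0) stop("n must be positive")
  for (v in names(cfg$bounds)) {
    b <- cfg$bounds[[v]]
    if (length(b) != 2 || b[1] > b[2]) stop("infeasible bounds for ", v)
  }
  for (v in names(cfg$noise)) {
    nv <- cfg$noise[[v]]
    if (identical(nv$dist, "gaussian") && nv$sd <= 0) stop("noise sd must be positive for ", v)
  }
  invisible(cfg)
}

#' Build the ASE structural causal model from a generator configuration
#'
#' @param config an `ase_generator_config`, or individual `theta` overrides
#'   passed to [default_pbihb_like_config()].
#' @return An `ase_scm` over the graph of [dag_j0()], with the
#'   fatigue x self-efficacy interaction on depression attached (coefficient
#'   `theta10`, possibly 0).
#' @export
config_to_scm <- function(config = default_pbihb_like_config()) {
  th <- config$theta
  coefs <- c(
    "A->M" = th[["theta1"]], "G->M" = th[["theta2"]],
    "M->F" = th[["theta3"]], "A->F" = th[["theta4"]], "G->F" = th[["theta5"]],
    "A->S" = th[["theta6"]], "G->S" = th[["theta7"]],
    "F->D" = th[["theta8"]], "S->D" = th[["theta9"]],
    "A->D" = th[["theta11"]], "G->D" = th[["theta12"]]
  )
  linear_gaussian_scm(
    dag_j0(), coefs, config$noise, config$intercepts,
    interaction = list(parents = c("F", "S"), child = "D", coef = th[["theta10"]])
  )
}

# Half-away-from-zero rounding to a grid step, the documented tie rule for
# questionnaire-range mode (base round() rounds half to even).
round_to_grid <- function(x, step) {
  sign(x) * floor(abs(x) / step + 0.5) * step
}

#' Generate a synthetic questionnaire cohort
#'
#' Samples the observational distribution of the configured ASE structural
#' causal model. With `range_mode` on, each questionnaire column is first
#' clipped to its instrument bounds and then rounded to the instrument's
#' granularity (integers for the GSES and CES-D totals, 1/9 for the FSS mean
#' score, 0.5 for the MAIA subscale-sum; ties round half away from zero);
#' age is likewise restricted to 18-65 whole years, matching an adult
#' volunteer cohort.
#'
#' @param config an `ase_generator_config` from
#'   [default_pbihb_like_config()].
#' @return A data.frame with columns A, G, M, F, S, D and `config$n` rows;
#'   deterministic per seed, no missing values.
#' @export
generate_cohort <- function(config = default_pbihb_like_config()) {
  validate_generator_config(config)
  scm <- config_to_scm(config)
  tab <- sample_observational(scm, config$n, config$seed)
  if (config$range_mode) {
    for (v in names(config$bounds)) {
      b <- config$bounds[[v]]
      tab[[v]] <- round_to_grid(pmin(pmax(tab[[v]], b[1]), b[2]), config$granularity[[v]])
    }
  }
  attr(tab, "source") <- list(generator = "ase_scm", n = config$n, seed = config$seed,
                              range_mode = config$range_mode)
  tab
}
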