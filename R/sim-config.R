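#' Configuration of the structural substitution simulator
#'
#' Bundles the structural-equation coefficients, noise scale and seed that
#' govern the period-level causal model behind the simulator: the second half
#' of a match is cut into `n_periods` five-minute periods (`W1`), each period
#' carries a count of substitutes already on the pitch (`W2`), an indicator of
#' a substitution happening in the current period (`W3`), a binary treatment
#' `A` (substitution in the *previous* period) and a continuous outcome `Y`,
#' the total distance covered by the team in that period.
#'
#' The structural order is `W1 -> W2 -> (W3, A) -> Y`:
#' \itemize{
#'   \item `W1 ~ DiscreteUniform{1..n_periods}`;
#'   \item `W2 ~ Binomial(max_subs, expit(b0 + b1 W1))` — substitutes
#'     accumulate as the half progresses;
#'   \item `W3 ~ Bernoulli(expit(c0 + c1 W1))`, drawn independently of `A`
#'     given `W1` (a current-period substitution is a dead-ball event, a
#'     distance cost, but not a confounder of the previous-period treatment);
#'   \item `A ~ Bernoulli(expit(a0 + a1 W1 - a2 W2))` — substitutions become
#'     more likely late in the half and less likely when the bench has
#'     already been used;
#'   \item `Y_raw = mu(W1, W2, W3, A) + Normal(0, noise_sd)` in meters, where
#'     `mu` contains a declining (curved) period trend, a substitutes-present
#'     term, a negative current-period-substitution term, and a treatment
#'     main effect plus a treatment-by-`W2` interaction (fresh legs help more
#'     when more substitutes are on the pitch).
#' }
#'
#' The default coefficients are calibrated so that (i) treatment probability
#' rises with `W1` and falls with `W2` while staying well inside (0, 1) in
#' every attainable stratum (positivity by construction), (ii) the
#' treatment-effect heterogeneity (`A x W2`) and the curved period trend make
#' a main-effects linear outcome model biased for the ATE even when given all
#' three confounders, and (iii) the ground-truth ATE on the normalized
#' outcome scale is approximately 0.065 for analysis datasets of 5,000 rows.
#'
#' @param n_periods Number of five-minute periods in the half (default 9).
#' @param max_subs Maximum number of substitutes a team may use (default 3,
#'   the limit in the league season the model describes).
#' @param coef_A Length-3 numeric `(a0, a1, a2)`: treatment logit is
#'   `a0 + a1*W1 - a2*W2`.
#' @param coef_W2 Length-2 numeric `(b0, b1)`: per-substitute success logit
#'   `b0 + b1*W1` in the Binomial model for `W2`.
#' @param coef_W3 Length-2 numeric `(c0, c1)`: current-period substitution
#'   logit `c0 + c1*W1`.
#' @param coef_Y Named length-7 numeric: `intercept`, `W1`, `W1sq`, `W2`,
#'   `W3`, `A`, `A_W2` — coefficients of the raw-scale outcome mean (meters).
#' @param noise_sd Outcome noise standard deviation in meters (> 0).
#' @param seed Default RNG seed used when an operation is not given one.
#' @return An object of class `sim_config` (a validated named list).
#' @seealso [simulate_periods()], [true_ate()]
#' @examples
#' cfg <- sim_config()
#' cfg
#' dat <- simulate_periods(cfg, n = 100, seed = 1)
#' head(dat)
#' @export
sim_config <- function(n_periods = 9L,
                       max_subs = 3L,
                       coef_A = c(-2.6, 0.50, 0.35),
                       coef_W2 = c(-1.2, 0.25),
                       coef_W3 = c(-2.5, 0.25),
                       coef_Y = c(intercept = 5800, W1 = -160, W1sq = 14,
                                  W2 = 40, W3 = -220, A = -9, A_W2 = 45.2),
                       noise_sd = 60,
                       seed = 1L) {
  cfg <- list(
    n_periods = as.integer(n_periods),
    max_subs = as.integer(max_subs),
    coef_A = as.numeric(coef_A),
    coef_W2 = as.numeric(coef_W2),
    coef_W3 = as.numeric(coef_W3),
    coef_Y = coef_Y,
    noise_sd = as.numeric(noise_sd),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' Validate a simulator configuration
#'
#' Checks the structural constraints: positive counts, positive noise scale,
#' complete outcome coefficients, and positivity by construction — the
#' treatment propensity implied by `coef_A`, enumerated over every attainable
#' `(W1, W2)` stratum, must lie strictly inside (0, 1).
#'
#' @param cfg A `sim_config`.
#' @return `cfg`, invisibly, if valid; otherwise an error.
#' @export
validate_sim_config <- function(cfg) {
  if (!inherits(cfg, "sim_config")) stop_invalid("not a sim_config object")
  if (cfg$n_periods < 1L) stop_invalid("n_periods must be >= 1")
  if (cfg$max_subs < 1L) stop_invalid("max_subs must be >= 1")
  if (!is.finite(cfg$noise_sd) || cfg$noise_sd <= 0)
    stop_invalid("noise_sd must be > 0")
  if (length(cfg$coef_A) != 3L) stop_invalid("coef_A must have length 3")
  if (length(cfg$coef_W2) != 2L) stop_invalid("coef_W2 must have length 2")
  if (length(cfg$coef_W3) != 2L) stop_invalid("coef_W3 must have length 2")
  need <- c("intercept", "W1", "W1sq", "W2", "W3", "A", "A_W2")
  if (!all(need %in% names(cfg$coef_Y)))
    stop_invalid("coef_Y must contain named coefficients: ",
                 paste(setdiff(need, names(cfg$coef_Y)), collapse = ", "))
  g <- propensity_grid(cfg)
  if (any(!is.finite(g$g1)) || any(g$g1 <= 0) || any(g$g1 >= 1))
    stop_invalid("treatment propensity leaves (0,1) on some (W1,W2) stratum")
  invisible(cfg)
}

# Enumerate P(A=1 | W1, W2) over every attainable stratum.
propensity_grid <- function(cfg) {
  grid <- expand.grid(W1 = seq_len(cfg$n_periods), W2 = 0:cfg$max_subs)
  grid$g1 <- expit(cfg$coef_A[1] + cfg$coef_A[2] * grid$W1 -
                     cfg$coef_A[3] * grid$W2)
  grid
}

# Raw-scale structural outcome mean mu(W1, W2, W3, A), in meters.
outcome_mean <- function(cfg, W1, W2, W3, A) {
  b <- cfg$coef_Y
  unname(b["intercept"] + b["W1"] * W1 + b["W1sq"] * W1^2 + b["W2"] * W2 +
           b["W3"] * W3 + b["A"] * A + b["A_W2"] * A * W2)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Substitution simulator configuration\n")
  cat(sprintf("  periods: %d, max substitutes: %d, noise sd: %.3g m\n",
              x$n_periods, x$max_subs, x$noise_sd))
  cat(sprintf("  treatment logit: %.3g + %.3g*W1 - %.3g*W2\n",
              x$coef_A[1], x$coef_A[2], x$coef_A[3]))
  cat(sprintf("  substitutes-present logit: %.3g + %.3g*W1 (Binomial %d)\n",
              x$coef_W2[1], x$coef_W2[2], x$max_subs))
  cat(sprintf("  current-period logit: %.3g + %.3g*W1\n",
              x$coef_W3[1], x$coef_W3[2]))
  cat("  outcome mean coefficients (m):\n")
  print(round(x$coef_Y, 3))
  invisible(x)
}

#' Write a simulator configuration to YAML
#'
#' @param cfg A `sim_config`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sim_config <- function(cfg, path) {
  validate_sim_config(cfg)
  out <- unclass(cfg)
  out$coef_Y <- as.list(out$coef_Y)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Read a simulator configuration from YAML
#'
#' @param path YAML file written by [write_sim_config()] (or hand-edited with
#'   the same keys).
#' @return A validated `sim_config`.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  coef_Y <- unlist(raw$coef_Y)
  sim_config(
    n_periods = raw$n_periods, max_subs = raw$max_subs,
    coef_A = unlist(raw$coef_A), coef_W2 = unlist(raw$coef_W2),
    coef_W3 = unlist(raw$coef_W3), coef_Y = coef_Y,
    noise_sd = raw$noise_sd, seed = if (is.null(raw$seed)) 1L else raw$seed
  )
}
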