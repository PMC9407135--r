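#' Estimate the treatment mechanism g(A = 1 | W)
#'
#' Super-learner (probability task) fit of the binary treatment on the
#' adjustment covariates, with predictions truncated to
#' `[lb, 1 - lb]`.  Truncation bounds the clever covariate (its magnitude is
#' at most `1/lb`) and controls the variance of the targeting step.
#'
#' @param data Observation table.
#' @param adjustment Confounder columns used to model the treatment.
#' @param roster A probability-task [learner_library()]; default the
#'   `"reduced"` roster.
#' @param folds Optional [make_folds()]; default 10-fold.
#' @param lb Truncation bound, `0 < lb < 0.5` (default 0.025).
#' @param seed RNG seed for folds and learners.
#' @return An object of class `propensity_fit`: `g1` (per-row truncated
#'   `P(A=1|W)`), `lb`, the SL `weights`, and `predict_fn`.
#' @export
estimate_propensity <- function(data, adjustment = c("W1", "W2", "W3"),
                                roster = NULL, folds = NULL, lb = 0.025,
                                seed = 1L) {
  validate_observation_table(data)
  if (lb <= 0 || lb >= 0.5) stop_invalid("lb must be in (0, 0.5)")
  if (length(unique(data$A)) < 2L)
    stop_invalid("treatment A does not vary: positivity violated globally")
  if (is.null(roster)) roster <- sl_roster("reduced", task = "probability")
  if (roster$task != "probability")
    stop_invalid("propensity roster must be a probability-task library")
  x <- data[, adjustment, drop = FALSE]
  if (is.null(folds))
    folds <- make_folds(nrow(data), min(10L, nrow(data)),
                        seed = child_seed(seed, 11L))
  sl <- sl_fit_predict(roster, folds, x, data$A, seed = child_seed(seed, 12L))
  g1 <- clip(sl$pred, lb, 1 - lb)
  pf <- function(newdata) {
    clip(sl$predict_fn(newdata[, adjustment, drop = FALSE]), lb, 1 - lb)
  }
  structure(list(g1 = g1, lb = lb, estimator = "SL",
                 weights = sl$weights, predict_fn = pf),
            class = "propensity_fit")
}

#' Clever covariate of the ATE fluctuation
#'
#' `H_i = 1 / g1_i` for treated rows and `-1 / (1 - g1_i)` for control rows:
#' the signed inverse-propensity direction along which the initial outcome
#' fit is fluctuated.
#'
#' @param data Observation table (only `A` is used).
#' @param g A [estimate_propensity()] result aligned with `data`.
#' @return Numeric vector `H` with the sign of `2A - 1` and magnitude at
#'   most `1/lb`.
#' @export
clever_covariate <- function(data, g) {
  if (length(g$g1) != nrow(data))
    stop_invalid("propensity fit is not aligned with the data")
  ifelse(data$A == 1, 1 / g$g1, -1 / (1 - g$g1))
}

#' Logistic fluctuation of the initial outcome fit
#'
#' Solves for the maximum-likelihood coefficient `epsilon` of a
#' single-covariate, intercept-free logistic regression of the bounded
#' outcome on the clever covariate with `logit(qa)` as offset, then updates
#' the counterfactual predictions on the logistic scale:
#' `q1* = expit(logit(q1) + eps / g1)`,
#' `q0* = expit(logit(q0) - eps / (1 - g1))`.
#' The update solves the efficient-influence-curve score equation
#' `mean(H * (Y - qa*)) = 0`; the logistic scale keeps every targeted
#' prediction strictly inside (0, 1), which is the point of min-max
#' normalizing the outcome.
#'
#' `epsilon` is found by Newton iteration on the score (at most `max_iter`
#' steps, tolerance `tol`), with a bracketed `uniroot` fallback.
#'
#' @param data Observation table (`A`, `Y` used); `Y` must lie in `[0, 1]`.
#' @param q1,q0,qa Initial counterfactual / factual predictions, clipped to
#'   `[1e-6, 1 - 1e-6]` before the logit.
#' @param H Clever covariate from [clever_covariate()].
#' @param g The [estimate_propensity()] used to build `H`.
#' @param max_iter,tol Newton controls.
#' @return List with `fluctuation` (class `fluctuation`: `epsilon`,
#'   `converged`, `score_residual`) and `targeted` (class
#'   `targeted_outcome`: `q1_star`, `q0_star`, `qa_star`).
#' @export
fluctuate <- function(data, q1, q0, qa, H, g, max_iter = 100L, tol = 1e-8) {
  y <- data$Y
  if (min(y) < 0 || max(y) > 1) stop_invalid("Y must lie in [0, 1]")
  q1 <- bound_probs(q1); q0 <- bound_probs(q0); qa <- bound_probs(qa)
  off <- logit(qa)

  score <- function(eps) mean(H * (y - expit(off + eps * H)))
  dscore <- function(eps) {
    p <- expit(off + eps * H)
    -mean(H^2 * p * (1 - p))
  }

  eps <- 0
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    s <- score(eps)
    if (abs(s) <= tol) { converged <- TRUE; break }
    d <- dscore(eps)
    if (!is.finite(d) || d == 0) break
    step_new <- eps - s / d
    if (!is.finite(step_new)) break
    eps <- step_new
  }
  if (!converged && abs(score(eps)) > tol) {
    # Bracketed fallback: the score is monotone decreasing in eps.
    root <- tryCatch(
      uniroot(score, lower = -50, upper = 50, tol = 1e-12, extendInt = "yes"),
      error = function(e) NULL)
    if (is.null(root))
      stop_invalid("fluctuation did not converge; last epsilon = ",
                   signif(eps, 6))
    eps <- root$root
    converged <- abs(score(eps)) <= 1e-6
  } else {
    converged <- TRUE
  }

  q1_star <- expit(logit(q1) + eps / g$g1)
  q0_star <- expit(logit(q0) - eps / (1 - g$g1))
  qa_star <- ifelse(data$A == 1, q1_star, q0_star)
  fl <- structure(list(epsilon = eps, converged = converged,
                       score_residual = score(eps)),
                  class = "fluctuation")
  tg <- structure(list(q1_star = q1_star, q0_star = q0_star,
                       qa_star = qa_star),
                  class = "targeted_outcome")
  list(fluctuation = fl, targeted = tg)
}

#' Targeted ATE from the fluctuated outcome fit
#'
#' `psi* = mean(q1* - q0*)`: the plug-in contrast of the targeted
#' counterfactual predictions.  Confidence bounds come from
#' [ic_variance()] when `data`, `H` are supplied.
#'
#' @param targeted A `targeted_outcome` from [fluctuate()].
#' @param data,H Optional; enable influence-curve confidence bounds.
#' @param estimator,adjustment Reporting labels.
#' @return An [ate_result()].
#' @export
ate_tmle <- function(targeted, data = NULL, H = NULL,
                     estimator = "TMLE", adjustment = "correct") {
  if (is.null(targeted$q1_star)) stop_invalid("targeted predictions missing")
  est <- mean(targeted$q1_star - targeted$q0_star)
  ci <- c(NA_real_, NA_real_)
  if (!is.null(data) && !is.null(H))
    ci <- ic_variance(data, targeted, H, est)
  ate_result(estimate = est, ci_low = ci[1], ci_high = ci[2],
             estimator = estimator, adjustment = adjustment,
             n = length(targeted$q1_star))
}

#' Influence-curve 95% confidence interval for the targeted ATE
#'
#' Per-row efficient influence value
#' `D_i = H_i (Y_i - qa*_i) + (q1*_i - q0*_i) - estimate`;
#' the interval is `estimate +/- 1.96 sd(D) / sqrt(n)`.
#'
#' @param data Observation table.
#' @param targeted `targeted_outcome` from [fluctuate()].
#' @param H Clever covariate.
#' @param estimate Targeted point estimate.
#' @return Numeric `c(ci_low, ci_high)`.
#' @export
ic_variance <- function(data, targeted, H, estimate) {
  n <- nrow(data)
  if (n < 2L) stop_invalid("need at least 2 rows for influence-curve inference")
  D <- H * (data$Y - targeted$qa_star) +
    (targeted$q1_star - targeted$q0_star) - estimate
  se <- sd(D) / sqrt(n)
  c(estimate - 1.96 * se, estimate + 1.96 * se)
}

#' Targeted maximum likelihood estimate of the substitution ATE
#'
#' The full targeting pipeline on one dataset: super-learner initial fit of
#' the outcome regression `Qbar(A, W)` (regression task, features `A` plus
#' the adjustment covariates), super-learner propensity fit `g(A|W)`,
#' clever covariate, logistic fluctuation, targeted contrast and
#' influence-curve interval.
#'
#' @param data Observation table.
#' @param adjustment Confounder columns (drop `"W3"` for the misspecified
#'   analysis).
#' @param q_roster Regression-task [learner_library()] for the outcome fit;
#'   default the `"reduced"` roster.
#' @param g_roster Probability-task library for the propensity; default the
#'   `"reduced"` probability roster.
#' @param V Number of CV folds (default 10).
#' @param lb Propensity truncation bound (default 0.025).
#' @param seed Master seed for folds and learners.
#' @param estimator Label stored on the result (`"TMLE"` or `"TMLEH"`).
#' @param adjustment_label Reporting label; derived from `adjustment` when
#'   `NULL`.
#' @return An [ate_result()] with attributes `fluctuation`, `sl_weights`
#'   (outcome-fit weights) and `initial_estimate` (the un-targeted SL
#'   plug-in ATE).
#' @examples
#' dat <- simulate_periods(sim_config(), 400, seed = 2)
#' tmle_ate(dat, V = 5, seed = 3)
#' @export
tmle_ate <- function(data, adjustment = c("W1", "W2", "W3"),
                     q_roster = NULL, g_roster = NULL, V = 10L, lb = 0.025,
                     seed = 1L, estimator = "TMLE", adjustment_label = NULL) {
  validate_observation_table(data)
  if (is.null(adjustment_label))
    adjustment_label <- if ("W3" %in% adjustment) "correct" else "misspecified"
  if (is.null(q_roster)) q_roster <- sl_roster("reduced", task = "regression")
  if (is.null(g_roster)) g_roster <- sl_roster("reduced", task = "probability")

  x_q <- data[, c("A", adjustment), drop = FALSE]
  folds_q <- make_folds(nrow(data), min(V, nrow(data)),
                        seed = child_seed(seed, 1L))
  sl_q <- sl_fit_predict(q_roster, folds_q, x_q, data$Y,
                         seed = child_seed(seed, 2L))
  d1 <- x_q; d1$A <- 1
  d0 <- x_q; d0$A <- 0
  q1 <- clip(sl_q$predict_fn(d1), 0, 1)
  q0 <- clip(sl_q$predict_fn(d0), 0, 1)
  qa <- ifelse(data$A == 1, q1, q0)

  folds_g <- make_folds(nrow(data), min(V, nrow(data)),
                        seed = child_seed(seed, 3L))
  g <- estimate_propensity(data, adjustment, roster = g_roster,
                           folds = folds_g, lb = lb,
                           seed = child_seed(seed, 4L))
  H <- clever_covariate(data, g)
  fl <- fluctuate(data, q1, q0, qa, H, g)
  res <- ate_tmle(fl$targeted, data = data, H = H,
                  estimator = estimator, adjustment = adjustment_label)
  attr(res, "fluctuation") <- fl$fluctuation
  attr(res, "sl_weights") <- sl_q$weights
  attr(res, "initial_estimate") <- mean(q1 - q0)
  res
}
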