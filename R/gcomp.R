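#' Fit the parametric linear outcome model for G-computation
#'
#' Ordinary least squares of the (normalized) outcome on an intercept, the
#' binary treatment `A` and the listed confounder main effects — the
#' "simplistic parametric linear model" comparator.  The period index `W1`
#' enters as a numeric covariate, not as factor dummies.
#'
#' @param data An observation table with columns `A`, `Y` and the adjustment
#'   covariates.
#' @param adjustment Character vector of confounder columns, a subset of
#'   `c("W1", "W2", "W3")`.  `c("W1", "W2", "W3")` is the full ("correct")
#'   set; dropping `"W3"` gives the misspecified set.
#' @return An object of class `outcome_fit`: the `lm` fit plus the ordered
#'   term list.
#' @examples
#' dat <- simulate_periods(sim_config(), 500, seed = 1)
#' fit <- fit_outcome_glm(dat, c("W1", "W2", "W3"))
#' coef(fit$fit)
#' @export
fit_outcome_glm <- function(data, adjustment = c("W1", "W2", "W3")) {
  validate_observation_table(data)
  terms_all <- c("A", adjustment)
  if (nrow(data) <= length(terms_all) + 1L)
    stop_invalid("need more rows than model terms")
  if (length(unique(data$A)) < 2L)
    stop_invalid("treatment A does not vary")
  fml <- as.formula(paste("Y ~", paste(terms_all, collapse = " + ")))
  fit <- lm(fml, data = data)
  cf <- coef(fit)
  if (anyNA(cf)) {
    bad <- names(cf)[is.na(cf)]
    stop_invalid("degenerate (rank-deficient) design; collinear term(s): ",
                 paste(bad, collapse = ", "))
  }
  structure(list(fit = fit, adjustment = adjustment, terms = terms_all,
                 coefficients = cf, fitted = TRUE),
            class = "outcome_fit")
}

#' @export
print.outcome_fit <- function(x, ...) {
  cat("Linear outcome model (G-computation comparator)\n")
  cat("  adjustment:", paste(x$adjustment, collapse = ", "), "\n")
  print(round(x$coefficients, 5))
  invisible(x)
}

#' Predict both counterfactual outcomes per row
#'
#' Evaluates a fitted outcome model twice per observation, with the
#' treatment column forced to 1 and to 0 (the original values of `A` are
#' discarded), yielding the two counterfactual predictions the plug-in ATE
#' averages over.
#'
#' @param fit An [fit_outcome_glm()] result (or any object with `fitted` and
#'   a `fit` usable by `predict`).
#' @param data Observation table with the covariates the fit requires.
#' @return A `data.frame` with columns `y1` and `y0`, one row per input row.
#' @export
predict_counterfactuals <- function(fit, data) {
  if (!isTRUE(fit$fitted)) stop_invalid("outcome model is not fitted")
  d1 <- data; d1$A <- 1
  d0 <- data; d0$A <- 0
  data.frame(y1 = unname(predict(fit$fit, newdata = d1)),
             y0 = unname(predict(fit$fit, newdata = d0)))
}

#' Plug-in (G-computation) ATE from counterfactual prediction pairs
#'
#' `estimate = mean(y1 - y0)`, averaging the counterfactual contrast over
#' the empirical confounder distribution (each observation weighted `1/n`).
#' For a main-effects linear fit this is algebraically identical to the
#' coefficient on `A`, so the 95% confidence interval uses the classical OLS
#' standard error of that coefficient when `fit` is supplied; otherwise the
#' CI is `NA`.
#'
#' @param pairs `data.frame` from [predict_counterfactuals()].
#' @param fit Optional [fit_outcome_glm()] result used for the CI.
#' @param adjustment_label `"correct"` or `"misspecified"` (bookkeeping).
#' @return An [ate_result()] with `estimator = "GLM"`.
#' @export
ate_plugin <- function(pairs, fit = NULL, adjustment_label = "correct") {
  if (!nrow(pairs)) stop_invalid("no prediction pairs supplied")
  est <- mean(pairs$y1 - pairs$y0)
  ci <- c(NA_real_, NA_real_)
  if (!is.null(fit)) {
    se <- sqrt(vcov(fit$fit)["A", "A"])
    ci <- est + c(-1, 1) * 1.96 * se
  }
  ate_result(estimate = est, ci_low = ci[1], ci_high = ci[2],
             estimator = "GLM", adjustment = adjustment_label,
             n = nrow(pairs))
}

#' Container for an ATE estimate
#'
#' @param estimate Point estimate on the normalized outcome scale.
#' @param ci_low,ci_high 95% confidence bounds (`ci_low <= estimate <=
#'   ci_high` when both are finite).
#' @param estimator Label: `"GLM"`, `"TMLE"` or `"TMLEH"`.
#' @param adjustment Label: `"correct"` or `"misspecified"`.
#' @param n Rows used.
#' @return An object of class `ate_result`.
#' @export
ate_result <- function(estimate, ci_low, ci_high, estimator, adjustment, n) {
  if (is.finite(ci_low) && is.finite(ci_high) &&
      (ci_low > estimate || ci_high < estimate))
    stop_invalid("confidence interval does not contain the estimate")
  structure(list(estimate = estimate, ci_low = ci_low, ci_high = ci_high,
                 estimator = estimator, adjustment = adjustment,
                 n = as.integer(n)),
            class = "ate_result")
}

#' @export
print.ate_result <- function(x, ...) {
  cat(sprintf("%s (%s adjustment): ATE = %.4f, 95%% CI [%.4f, %.4f], n = %d\n",
              x$estimator, x$adjustment, x$estimate, x$ci_low, x$ci_high,
              x$n))
  invisible(x)
}

#' One-call GLM G-computation ATE
#'
#' Convenience wrapper: fit the linear outcome model, predict both
#' counterfactuals, average the contrast.
#'
#' @inheritParams fit_outcome_glm
#' @param adjustment_label Reporting label; defaults to `"correct"` when
#'   `W3` is in the adjustment set and `"misspecified"` otherwise.
#' @return An [ate_result()].
#' @export
ate_glm <- function(data, adjustment = c("W1", "W2", "W3"),
                    adjustment_label = NULL) {
  if (is.null(adjustment_label))
    adjustment_label <- if ("W3" %in% adjustment) "correct" else "misspecified"
  fit <- fit_outcome_glm(data, adjustment)
  pairs <- predict_counterfactuals(fit, data)
  ate_plugin(pairs, fit = fit, adjustment_label = adjustment_label)
}
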