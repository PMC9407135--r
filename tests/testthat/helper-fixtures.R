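# Small in-code fixtures shared across test files.

# Observation table built directly from vectors (bypasses the simulator).
make_obs <- function(W1, W2, W3, A, Y) {
  df <- data.frame(W1 = W1, W2 = W2, W3 = W3, A = A, Y = Y)
  tmlesoccer:::as_observation_table(df, y_min = 0, y_max = 1)
}

# Deterministic linear toy: Y = 0.2 + 0.3*x1 - 0.1*x2, optional noise.
linear_toy <- function(n, seed, noise_sd = 0) {
  set.seed(seed)
  x <- data.frame(x1 = runif(n), x2 = runif(n))
  y <- 0.2 + 0.3 * x$x1 - 0.1 * x$x2 + rnorm(n, 0, noise_sd)
  list(x = x, y = y)
}

# A minimal regression-task library of named closures built through the
# public constructor (kept independent of the package's roster internals).
toy_library <- function(task = "regression") {
  lin <- sl_learner("lin",
    fit = function(x, y) lm(y ~ ., data = cbind(y = y, x)),
    predict = function(fit, newx) unname(predict(fit, newdata = newx)))
  mn <- sl_learner("mn",
    fit = function(x, y) mean(y),
    predict = function(fit, newx) rep(fit, nrow(newx)))
  learner_library(list(mn, lin), task = task)
}

# RCT-like configuration: treatment randomized by a fair coin, everything
# else at the simulator defaults.
rct_config <- function() sim_config(coef_A = c(0, 0, 0))

# Null-effect configuration: treatment has no effect on the outcome, and
# the period trend is linear so the main-effects adjustment is correctly
# specified (every estimator should then recover zero).
null_config <- function() {
  cy <- c(intercept = 5800, W1 = -60, W1sq = 0, W2 = 40, W3 = -220,
          A = 0, A_W2 = 0)
  sim_config(coef_Y = cy)
}
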