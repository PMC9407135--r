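test_that("clever covariate values are forced by the formula", {
  dat <- make_obs(W1 = c(1L, 1L, 1L), W2 = c(0L, 0L, 0L), W3 = c(0L, 0L, 0L),
                  A = c(1L, 0L, 1L), Y = c(0.5, 0.5, 0.5))
  g <- structure(list(g1 = c(0.5, 0.75, 0.025), lb = 0.025),
                 class = "propensity_fit")
  H <- clever_covariate(dat, g)
  expect_equal(H[1], 2)    # A=1, g1=0.5 -> 1/0.5
  expect_equal(H[2], -4)   # A=0, g1=0.75 -> -1/0.25
  expect_equal(H[3], 40)   # A=1, g1 at the truncation bound -> maximal
  # sign structure and truncation bound on the magnitude
  expect_true(all(H[dat$A == 1] > 0) && all(H[dat$A == 0] < 0))
  expect_lte(max(abs(H)), 1 / g$lb)
})

test_that("propensity estimates are truncated and recover a randomized design", {
  dat <- simulate_periods(rct_config(), 5000, seed = 6)
  g <- estimate_propensity(dat, roster = sl_roster("parametric", "probability"),
                           lb = 0.025, seed = 2)
  expect_gte(min(g$g1), 0.025)
  expect_lte(max(g$g1), 0.975)
  expect_lt(abs(mean(g$g1) - 0.5), 3 * sqrt(0.25 / nrow(dat)) + 0.01)
})

test_that("parametric propensity fit recovers the true stratum expits", {
  cfg <- sim_config()
  dat <- simulate_periods(cfg, 10000, seed = 10)
  glm_only <- learner_library(list(sl_learner("logit",
    fit = function(x, y) glm(y ~ ., data = cbind(y = y, x), family = binomial()),
    predict = function(fit, newx) unname(predict(fit, newx, type = "response")))),
    "probability")
  g <- estimate_propensity(dat, adjustment = c("W1", "W2"),
                           roster = glm_only, lb = 0.01, seed = 3)
  strata <- unique(dat[, c("W1", "W2")])
  for (i in seq_len(nrow(strata))) {
    idx <- dat$W1 == strata$W1[i] & dat$W2 == strata$W2[i]
    if (sum(idx) < 200) next
    g_true <- plogis(cfg$coef_A[1] + cfg$coef_A[2] * strata$W1[i] -
                       cfg$coef_A[3] * strata$W2[i])
    se <- sqrt(g_true * (1 - g_true) / sum(idx))
    expect_lt(abs(mean(g$g1[idx]) - g_true), 3 * se + 0.01)
  }
  expect_error(
    estimate_propensity(make_obs(1:4, rep(0L, 4), rep(0L, 4), rep(1L, 4),
                                 runif(4))),
    "does not vary")
})

test_that("fluctuation solves the score equation on random instances", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- 100
    A <- rbinom(n, 1, 0.5)
    Y <- runif(n)
    dat <- make_obs(W1 = sample(1:5, n, TRUE), W2 = rep(0L, n),
                    W3 = rep(0L, n), A = A, Y = Y)
    g <- structure(list(g1 = runif(n, 0.1, 0.9), lb = 0.025),
                   class = "propensity_fit")
    H <- clever_covariate(dat, g)
    q1 <- runif(n, 0.2, 0.8); q0 <- runif(n, 0.2, 0.8)
    qa <- ifelse(A == 1, q1, q0)
    fl <- fluctuate(dat, q1, q0, qa, H, g)
    expect_true(fl$fluctuation$converged)
    expect_lte(abs(fl$fluctuation$score_residual), 1e-6)
    expect_lte(abs(mean(H * (Y - fl$targeted$qa_star))), 1e-6)
    expect_true(all(fl$targeted$q1_star > 0 & fl$targeted$q1_star < 1))
    expect_true(all(fl$targeted$q0_star > 0 & fl$targeted$q0_star < 1))
  }
})

test_that("an initial fit already solving the score equation is a fixed point", {
  n <- 50
  set.seed(3)
  A <- rep(c(1L, 0L), n / 2)
  Y <- runif(n)
  dat <- make_obs(W1 = rep(1L, n), W2 = rep(0L, n), W3 = rep(0L, n),
                  A = A, Y = Y)
  g <- structure(list(g1 = rep(0.5, n), lb = 0.025), class = "propensity_fit")
  H <- clever_covariate(dat, g)
  qa <- Y                      # perfect factual fit: score(0) = 0 exactly
  q1 <- ifelse(A == 1, Y, 0.5)
  q0 <- ifelse(A == 0, Y, 0.5)
  fl <- fluctuate(dat, q1, q0, qa, H, g)
  expect_lt(abs(fl$fluctuation$epsilon), 1e-6)
  expect_equal(fl$targeted$q1_star, pmin(pmax(q1, 1e-6), 1 - 1e-6),
               tolerance = 1e-4)
  # zero fluctuation leaves the plug-in contrast unchanged
  expect_equal(ate_tmle(fl$targeted)$estimate, mean(q1 - q0),
               tolerance = 1e-4)
})

test_that("epsilon matches a 1-D quasi-likelihood search on an 8-row example", {
  dat <- make_obs(W1 = c(1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L),
                  W2 = rep(0L, 8), W3 = rep(0L, 8),
                  A = c(1L, 0L, 1L, 0L, 1L, 0L, 1L, 0L),
                  Y = c(0.9, 0.3, 0.7, 0.4, 0.8, 0.2, 0.6, 0.5))
  g <- structure(list(g1 = c(0.6, 0.4, 0.5, 0.55, 0.7, 0.3, 0.45, 0.5),
                      lb = 0.025), class = "propensity_fit")
  H <- clever_covariate(dat, g)
  q1 <- rep(0.6, 8); q0 <- rep(0.45, 8)
  qa <- ifelse(dat$A == 1, q1, q0)
  fl <- fluctuate(dat, q1, q0, qa, H, g)
  # independent oracle: golden-section maximization of the Bernoulli
  # quasi-log-likelihood in epsilon
  qll <- function(eps) {
    p <- plogis(qlogis(qa) + eps * H)
    sum(dat$Y * log(p) + (1 - dat$Y) * log(1 - p))
  }
  eps_opt <- optimize(qll, interval = c(-5, 5), maximum = TRUE,
                      tol = 1e-10)$maximum
  expect_lt(abs(fl$fluctuation$epsilon - eps_opt), 1e-5)
})

test_that("influence-curve CI collapses when the influence values are constant", {
  n <- 20
  dat <- make_obs(W1 = rep(1L, n), W2 = rep(0L, n), W3 = rep(0L, n),
                  A = rep(c(1L, 0L), n / 2), Y = rep(0.5, n))
  targeted <- structure(list(q1_star = rep(0.7, n), q0_star = rep(0.6, n),
                             qa_star = dat$Y),
                        class = "targeted_outcome")
  H <- rep(1, n)  # any constant H works: Y - qa* = 0 row by row
  ci <- ic_variance(dat, targeted, H, estimate = 0.1)
  expect_equal(ci[1], ci[2], tolerance = 1e-12)
  expect_equal(ci[1], 0.1, tolerance = 1e-12)
  expect_error(ic_variance(dat[1, , drop = FALSE], targeted, H, 0.1),
               "at least 2 rows")
})

test_that("influence-curve CI width shrinks at the root-n rate", {
  widths <- vapply(c(500L, 2000L, 8000L), function(n) {
    dat <- simulate_periods(sim_config(), n, seed = 70)
    res <- tmle_ate(dat, q_roster = sl_roster("parametric", "regression"),
                    g_roster = sl_roster("parametric", "probability"),
                    V = 5, seed = 71)
    res$ci_high - res$ci_low
  }, numeric(1))
  expect_lt(abs(widths[1] / widths[2] - 2) / 2, 0.2)
  expect_lt(abs(widths[2] / widths[3] - 2) / 2, 0.2)
})

test_that("TMLE estimate is invariant to row permutation of the data", {
  # single-learner libraries: the fit is a deterministic function of the
  # rows, so permuting them must not move the estimate
  q_lib <- learner_library(list(sl_learner("lin",
    fit = function(x, y) lm(y ~ ., data = cbind(y = y, x)),
    predict = function(fit, newx) unname(predict(fit, newx)))),
    "regression")
  g_lib <- learner_library(list(sl_learner("logit",
    fit = function(x, y) glm(y ~ ., data = cbind(y = y, x), family = binomial()),
    predict = function(fit, newx) unname(predict(fit, newx, type = "response")))),
    "probability")
  dat <- simulate_periods(sim_config(), 600, seed = 15)
  set.seed(1)
  perm <- dat[sample(nrow(dat)), ]
  attr(perm, "y_min") <- attr(dat, "y_min")
  attr(perm, "y_max") <- attr(dat, "y_max")
  r1 <- tmle_ate(dat, q_roster = q_lib, g_roster = g_lib, V = 5, seed = 5)
  r2 <- tmle_ate(perm, q_roster = q_lib, g_roster = g_lib, V = 5, seed = 5)
  expect_equal(r1$estimate, r2$estimate, tolerance = 1e-8)
})

test_that("TMLE is doubly robust: correct propensity rescues a misspecified outcome model", {
  # outcome library: main-effects linear learner only (misses the curved
  # period trend and the A x W2 interaction); propensity library: the
  # correctly specified logistic form
  q_lib <- learner_library(list(sl_learner("lin",
    fit = function(x, y) lm(y ~ ., data = cbind(y = y, x)),
    predict = function(fit, newx) unname(predict(fit, newx)))),
    "regression")
  g_lib <- learner_library(list(sl_learner("logit",
    fit = function(x, y) glm(y ~ ., data = cbind(y = y, x), family = binomial()),
    predict = function(fit, newx) unname(predict(fit, newx, type = "response")))),
    "probability")
  cfg <- sim_config()
  reps <- 60
  n <- 800
  tmle_est <- glm_est <- numeric(reps)
  for (r in seq_len(reps)) {
    dat <- simulate_periods(cfg, n, seed = 3000 + r)
    tmle_est[r] <- tmle_ate(dat, q_roster = q_lib, g_roster = g_lib,
                            V = 5, seed = 3000 + r)$estimate
    glm_est[r] <- ate_glm(dat)$estimate
  }
  truth <- true_ate(cfg, mc_draws = 5e5, seed = 77, norm_n = n)$value
  mc_se_t <- sd(tmle_est) / sqrt(reps)
  mc_se_g <- sd(glm_est) / sqrt(reps)
  expect_lt(abs(mean(tmle_est) - truth), 3 * mc_se_t)
  expect_gt(abs(mean(glm_est) - truth), 5 * mc_se_g)
})
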