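test_that("make_folds yields an exact partition with near-equal fold sizes", {
  f <- make_folds(10, 5, seed = 1)
  expect_identical(sort(unique(f$assignment)), 1:5)
  expect_true(all(table(f$assignment) == 2))
  # leave-one-out boundary
  loo <- make_folds(7, 7, seed = 2)
  expect_identical(sort(loo$assignment), 1:7)
  # unbalanced n: sizes differ by at most one
  f2 <- make_folds(23, 4, seed = 3)
  expect_lte(diff(range(table(f2$assignment))), 1)
  expect_error(make_folds(5, 6), "V must satisfy")
  expect_error(make_folds(5, 1), "V must satisfy")
})

test_that("fold assignment is deterministic given the seed", {
  a <- make_folds(100, 10, seed = 3)
  b <- make_folds(100, 10, seed = 3)
  expect_identical(a, b)
  expect_false(identical(a$assignment, make_folds(100, 10, seed = 4)$assignment))
})

test_that("cv risk of the mean learner equals the validation-half variance computed by hand", {
  # two interleaved halves of identical composition: each training half has
  # mean 0.5, so each validation loss is mean((y - 0.5)^2) = 0.25
  y <- rep(c(0, 1), 10)
  folds <- structure(list(n = 20L, V = 2L,
                          assignment = rep(c(1L, 1L, 2L, 2L), 5)),
                     class = "cv_folds")
  lib <- learner_library(list(sl_learner("mn",
    fit = function(x, y) mean(y),
    predict = function(fit, newx) rep(fit, nrow(newx)))), "regression")
  cr <- cv_risks(lib, folds, data.frame(x = seq_along(y)), y)
  expect_equal(unname(cr$risks[1, ]), c(0.25, 0.25), tolerance = 1e-12)
  # constant target: risk identically zero
  cr0 <- cv_risks(lib, folds, data.frame(x = seq_along(y)), rep(0.7, 20))
  expect_equal(max(abs(cr0$risks)), 0, tolerance = 1e-15)
})

test_that("a realizable learner attains (near) zero cv risk and full weight", {
  toy <- linear_toy(120, seed = 4, noise_sd = 0)
  lib <- toy_library()
  folds <- make_folds(120, 5, seed = 1)
  cr <- cv_risks(lib, folds, toy$x, toy$y)
  expect_lt(max(cr$risks["lin", ]), 1e-20)
  w <- continuous_sl_weights(cr, toy$y)
  expect_gte(unname(w$alpha["lin"]), 1 - 1e-6)
  # out-of-sample ensemble recovery
  new_toy <- linear_toy(50, seed = 9, noise_sd = 0)
  sl <- sl_fit_predict(lib, folds, toy$x, toy$y, new_x = new_toy$x)
  expect_lt(max(abs(sl$pred - new_toy$y)), 1e-6)
})

test_that("discrete super learner is the argmin of mean fold risk, ties to the first learner", {
  expect_identical(discrete_sl(matrix(c(1, 1, 0.5, 0.5), 2, byrow = TRUE)), 2L)
  expect_identical(discrete_sl(matrix(c(0.3, 0.3, 0.3, 0.3), 2, byrow = TRUE)), 1L)
  set.seed(6)
  r <- matrix(runif(50), 5, 10)
  expect_identical(discrete_sl(r), which.min(rowMeans(r))[[1]])
})

test_that("continuous weights live on the simplex and match a dense grid search (m = 3)", {
  set.seed(12)
  n <- 60
  truth <- runif(n)
  Z <- cbind(truth + rnorm(n, 0, 0.10),
             truth + rnorm(n, 0, 0.20),
             rnorm(n, 0.5, 0.15))
  w <- continuous_sl_weights(Z, truth)
  expect_true(all(w$alpha >= 0))
  expect_equal(sum(w$alpha), 1, tolerance = 1e-8)
  # grid over the simplex at 0.01 resolution
  grid_best <- Inf
  for (a1 in seq(0, 1, 0.01)) {
    for (a2 in seq(0, 1 - a1, 0.01)) {
      loss <- mean((truth - Z %*% c(a1, a2, 1 - a1 - a2))^2)
      if (loss < grid_best) grid_best <- loss
    }
  }
  expect_lte(w$cv_loss, grid_best + 1e-10)
  expect_lt(abs(w$cv_loss - grid_best), 1e-4)
})

test_that("single learner gets weight one; identical learners make alpha irrelevant", {
  y <- runif(30)
  expect_equal(unname(continuous_sl_weights(matrix(y + 0.1, ncol = 1), y)$alpha), 1)
  Z <- matrix(rep(y + 0.05, 3), ncol = 3)
  w <- continuous_sl_weights(Z, y)
  expect_equal(as.numeric(Z %*% w$alpha), y + 0.05, tolerance = 1e-10)
})

test_that("convex-ensemble cv loss never exceeds any single learner's (random instances)", {
  for (seed in 1:8) {
    set.seed(seed)
    n <- 40; m <- 4
    y <- runif(n)
    Z <- matrix(runif(n * m), n, m)
    w <- continuous_sl_weights(Z, y)
    expect_lte(w$cv_loss, min(colMeans((y - Z)^2)) + 1e-12)
  }
})

test_that("permuting the learner order permutes the weights identically", {
  set.seed(30)
  n <- 80
  truth <- runif(n)
  Z <- cbind(a = truth + rnorm(n, 0, 0.1), b = truth + rnorm(n, 0, 0.3),
             c = rnorm(n))
  w1 <- continuous_sl_weights(Z, truth)$alpha
  w2 <- continuous_sl_weights(Z[, c(3, 1, 2)], truth)$alpha
  expect_equal(unname(w2[c(2, 3, 1)]), unname(w1), tolerance = 1e-8)
})

test_that("the generating learner's weight grows with sample size", {
  mean_w <- function(n) {
    ws <- vapply(1:10, function(s) {
      toy <- linear_toy(n, seed = 100 + s, noise_sd = 0.15)
      folds <- make_folds(n, 5, seed = s)
      cr <- cv_risks(toy_library(), folds, toy$x, toy$y)
      unname(continuous_sl_weights(cr, toy$y)$alpha["lin"])
    }, numeric(1))
    mean(ws)
  }
  expect_gte(mean_w(2000), mean_w(200))
  expect_gte(mean_w(2000), 0.95)
})

test_that("a failing learner falls back to the marginal mean instead of aborting", {
  broken <- sl_learner("broken",
    fit = function(x, y) stop("boom"),
    predict = function(fit, newx) stop("boom"))
  lib <- learner_library(list(broken,
    sl_learner("mn", fit = function(x, y) mean(y),
               predict = function(fit, newx) rep(fit, nrow(newx)))),
    "regression")
  toy <- linear_toy(40, seed = 2, noise_sd = 0.1)
  folds <- make_folds(40, 4, seed = 1)
  cr <- cv_risks(lib, folds, toy$x, toy$y)
  expect_equal(unname(cr$risks["broken", ]), unname(cr$risks["mn", ]),
               tolerance = 1e-12)
  sl <- sl_fit_predict(lib, folds, toy$x, toy$y)
  expect_true(all(is.finite(sl$pred)))
})

test_that("probability-task predictions are clipped into (0, 1)", {
  set.seed(44)
  n <- 200
  x <- data.frame(x1 = rnorm(n))
  y <- rbinom(n, 1, plogis(3 * x$x1))
  lib <- sl_roster("parametric", task = "probability")
  folds <- make_folds(n, 5, seed = 2)
  sl <- sl_fit_predict(lib, folds, x, y)
  expect_true(all(sl$pred >= 1e-6 & sl$pred <= 1 - 1e-6))
})
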