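#' Build V-fold cross-validation folds
#'
#' Randomly partitions `1:n` into `V` folds of as-equal-as-possible size;
#' every observation falls in the validation set of exactly one fold and in
#' the training set of the remaining `V - 1`.
#'
#' @param n Number of observations.
#' @param V Number of folds, `2 <= V <= n`.
#' @param seed RNG seed; the assignment is deterministic given the seed.
#' @return An object of class `cv_folds`: list with `n`, `V` and the
#'   per-observation fold `assignment`.
#' @examples
#' f <- make_folds(10, 5, seed = 1)
#' table(f$assignment)
#' @export
make_folds <- function(n, V, seed = 1L) {
  if (length(n) != 1L || length(V) != 1L || !is.finite(n) || !is.finite(V))
    stop_invalid("n and V must be single finite numbers")
  n <- as.integer(n); V <- as.integer(V)
  if (V < 2L || V > n) stop_invalid("V must satisfy 2 <= V <= n")
  set.seed(seed)
  assignment <- sample(rep(seq_len(V), length.out = n))
  structure(list(n = n, V = V, assignment = assignment), class = "cv_folds")
}

# Loss functions -----------------------------------------------------------

# Squared error for the regression task, negative Bernoulli log-likelihood
# (with bounded predictions) for the probability task.
sl_loss <- function(pred, target, task) {
  if (task == "probability") {
    p <- bound_probs(pred)
    -(target * log(p) + (1 - target) * log(1 - p))
  } else {
    (target - pred)^2
  }
}

# Fit one learner with the failure policy: on error (or non-finite
# predictions) fall back to the marginal-mean learner so a single fragile
# library member cannot abort the ensemble.
fit_with_fallback <- function(learner, x, y, task, seed) {
  set.seed(seed)
  fit <- tryCatch(learner$fit(x, y), error = function(e) NULL)
  if (is.null(fit)) {
    return(list(failed = TRUE, mean = mean(y)))
  }
  list(failed = FALSE, fit = fit, learner = learner, mean = mean(y))
}

predict_with_fallback <- function(wrapped, newx, task) {
  p <- if (wrapped$failed) {
    rep(wrapped$mean, nrow(newx))
  } else {
    tryCatch(wrapped$learner$predict(wrapped$fit, newx),
             error = function(e) rep(wrapped$mean, nrow(newx)))
  }
  if (length(p) != nrow(newx) || any(!is.finite(p)))
    p <- rep(wrapped$mean, nrow(newx))
  if (task == "probability") p <- bound_probs(p)
  p
}

#' Cross-validated risks and validation-fold predictions for a library
#'
#' Trains every learner on each training set (all folds but `v`) and records
#' its mean validation loss, entry `(m, v)` of the risk matrix, together with
#' the stacked out-of-fold predictions needed by the continuous super
#' learner.  A learner that fails to fit on some fold is replaced, for that
#' fold, by the marginal-mean learner (its loss and predictions).
#'
#' @param library A [learner_library()].
#' @param folds A [make_folds()] object aligned with the data.
#' @param x Feature `data.frame`.
#' @param y Numeric target, row-aligned with `x`.
#' @param seed Seed from which per-learner, per-fold child seeds are derived.
#' @return An object of class `cv_risks`: list with `risks` (m x V matrix),
#'   `cv_pred` (n x m matrix of out-of-fold predictions), `loss_name`,
#'   `learner_names`.
#' @export
cv_risks <- function(library, folds, x, y, seed = 1L) {
  stopifnot(inherits(library, "learner_library"), inherits(folds, "cv_folds"))
  if (nrow(x) != length(y) || nrow(x) != folds$n)
    stop_invalid("features, target and folds are not row-aligned")
  m <- length(library$learners)
  risks <- matrix(NA_real_, m, folds$V,
                  dimnames = list(library$names, NULL))
  cv_pred <- matrix(NA_real_, folds$n, m,
                    dimnames = list(NULL, library$names))
  n_failed <- 0L
  for (v in seq_len(folds$V)) {
    idx_val <- which(folds$assignment == v)
    idx_tr <- which(folds$assignment != v)
    for (j in seq_len(m)) {
      w <- fit_with_fallback(library$learners[[j]], x[idx_tr, , drop = FALSE],
                             y[idx_tr], library$task,
                             seed = child_seed(seed, v * 1000L + j))
      if (w$failed) n_failed <- n_failed + 1L
      p <- predict_with_fallback(w, x[idx_val, , drop = FALSE], library$task)
      cv_pred[idx_val, j] <- p
      risks[j, v] <- mean(sl_loss(p, y[idx_val], library$task))
    }
  }
  if (n_failed == m * folds$V)
    stop_invalid("every learner failed on every fold")
  structure(list(risks = risks, cv_pred = cv_pred,
                 loss_name = if (library$task == "probability")
                   "neg-bernoulli-loglik" else "squared-error",
                 learner_names = library$names,
                 n_failed = n_failed),
            class = "cv_risks")
}

#' Discrete super learner: pick the lowest cross-validated risk
#'
#' Averages each learner's risk across folds and returns the index of the
#' minimizer; exact ties go to the lowest library index.
#'
#' @param risks A [cv_risks()] object or a bare m x V risk matrix.
#' @return Integer learner index.
#' @export
discrete_sl <- function(risks) {
  r <- if (inherits(risks, "cv_risks")) risks$risks else risks
  if (!length(r)) stop_invalid("empty risk matrix")
  mean_risk <- rowMeans(r)
  which.min(mean_risk)[[1]]
}

#' Continuous super learner weights on the probability simplex
#'
#' Finds the convex combination of the learners' out-of-fold predictions that
#' minimizes the cross-validated loss: non-negative least squares of the
#' target on the stacked validation predictions, renormalized to sum to one
#' (the standard super-learner weight solver; also used, on the probability
#' scale, for the log-loss task), then polished by a quasi-Newton step in a
#' softmax parametrization of the simplex so the returned weights are the
#' actual constrained minimizer.  If NNLS returns the zero vector the
#' single best learner gets weight one.
#'
#' @param cv_predictions n x m matrix of out-of-fold predictions (column per
#'   learner), or a [cv_risks()] object.
#' @param target Numeric target aligned with the rows.
#' @return An object of class `sl_weights`: numeric `alpha` (non-negative,
#'   sums to 1) plus the achieved cross-validated loss.
#' @export
continuous_sl_weights <- function(cv_predictions, target) {
  Z <- if (inherits(cv_predictions, "cv_risks")) cv_predictions$cv_pred
       else as.matrix(cv_predictions)
  if (any(!is.finite(Z))) stop_invalid("non-finite cross-validated predictions")
  if (nrow(Z) != length(target))
    stop_invalid("predictions and target are not row-aligned")
  m <- ncol(Z)
  if (m == 1L) {
    alpha <- 1
  } else {
    nn <- tryCatch(pracma::lsqnonneg(Z, target)$x,
                   error = function(e) NULL)
    if (is.null(nn) || sum(nn) <= 0) {
      # Degenerate system: fall back to the discrete selection.
      mse <- colMeans((target - Z)^2)
      alpha <- rep(0, m)
      alpha[which.min(mse)] <- 1
    } else {
      alpha <- nn / sum(nn)
      alpha <- polish_simplex_weights(Z, target, alpha)
    }
  }
  # The simplex contains every vertex: never do worse than the single best
  # learner (guards the rare case where renormalized NNLS lands elsewhere).
  loss <- mean((target - as.numeric(Z %*% alpha))^2)
  vertex_loss <- colMeans((target - Z)^2)
  if (min(vertex_loss) < loss) {
    alpha <- rep(0, m)
    alpha[which.min(vertex_loss)] <- 1
    loss <- min(vertex_loss)
  }
  names(alpha) <- colnames(Z)
  structure(list(alpha = alpha, cv_loss = loss), class = "sl_weights")
}

# Quasi-Newton polish of simplex-constrained least squares in a softmax
# parametrization (renormalized NNLS is a good warm start but not the exact
# constrained minimizer).
polish_simplex_weights <- function(Z, target, alpha0) {
  eps <- 1e-8
  theta0 <- log(pmax(alpha0, eps))
  obj <- function(theta) {
    w <- exp(theta - max(theta)); w <- w / sum(w)
    mean((target - as.numeric(Z %*% w))^2)
  }
  opt <- tryCatch(
    stats::optim(theta0, obj, method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-14)),
    error = function(e) NULL)
  if (is.null(opt)) return(alpha0)
  w <- exp(opt$par - max(opt$par)); w <- w / sum(w)
  if (obj(opt$par) <= mean((target - as.numeric(Z %*% alpha0))^2)) w
  else alpha0
}

#' @export
print.sl_weights <- function(x, ...) {
  cat("Super learner weights:\n")
  print(round(x$alpha, 4))
  cat(sprintf("  cross-validated loss: %.6g\n", x$cv_loss))
  invisible(x)
}

#' Fit the continuous super learner and predict
#'
#' Computes cross-validated weights, refits every learner on the full data,
#' and returns the alpha-weighted combination of their predictions on
#' `new_x`.  Probability-task output is clipped to `[1e-6, 1 - 1e-6]`.
#'
#' @inheritParams cv_risks
#' @param new_x Feature `data.frame` to predict on (defaults to `x`).
#' @param weights Optional precomputed [continuous_sl_weights()]; when `NULL`
#'   they are computed from the cross-validated predictions.
#' @return List with `pred` (numeric predictions on `new_x`), `weights`
#'   (`sl_weights`), `risks` (`cv_risks`), and `predict_fn`, a closure that
#'   evaluates the fitted ensemble on any new feature table.
#' @export
sl_fit_predict <- function(library, folds, x, y, new_x = x, seed = 1L,
                           weights = NULL) {
  cr <- cv_risks(library, folds, x, y, seed = seed)
  if (is.null(weights)) weights <- continuous_sl_weights(cr, y)
  full_fits <- lapply(seq_along(library$learners), function(j) {
    fit_with_fallback(library$learners[[j]], x, y, library$task,
                      seed = child_seed(seed, 777000L + j))
  })
  task <- library$task
  alpha <- weights$alpha
  predict_fn <- function(newdata) {
    P <- vapply(full_fits, function(w)
      predict_with_fallback(w, newdata, task), numeric(nrow(newdata)))
    if (nrow(newdata) == 1L) P <- matrix(P, nrow = 1L)
    out <- as.numeric(P %*% alpha)
    if (task == "probability") out <- bound_probs(out)
    out
  }
  list(pred = predict_fn(new_x), weights = weights, risks = cr,
       predict_fn = predict_fn)
}
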