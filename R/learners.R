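#' Define a base learner for the super learner
#'
#' A base learner is a named pair of closures: `fit(x, y)` returning an
#' arbitrary fitted object and `predict(fit, newx)` returning numeric
#' predictions.  `x` is always a plain `data.frame` of numeric features and
#' `y` a numeric vector (`0/1` for probability-task learners).
#'
#' @param name Unique learner name.
#' @param fit Function `(x, y)` -> fitted object.
#' @param predict Function `(fit, newx)` -> numeric vector.
#' @return An object of class `sl_learner`.
#' @export
sl_learner <- function(name, fit, predict) {
  stopifnot(is.character(name), length(name) == 1L,
            is.function(fit), is.function(predict))
  structure(list(name = name, fit = fit, predict = predict),
            class = "sl_learner")
}

#' Assemble a learner library
#'
#' @param learners List of [sl_learner()] objects with unique names.
#' @param task `"regression"` (squared-error loss, conditional mean of a
#'   bounded outcome) or `"probability"` (negative Bernoulli log-likelihood,
#'   predictions clipped to (0, 1)).
#' @return An object of class `learner_library`.
#' @export
learner_library <- function(learners, task = c("regression", "probability")) {
  task <- match.arg(task)
  if (!length(learners)) stop_invalid("learner library is empty")
  nm <- vapply(learners, function(l) l$name, character(1))
  if (anyDuplicated(nm)) stop_invalid("learner names must be unique")
  structure(list(learners = learners, names = nm, task = task),
            class = "learner_library")
}

#' @export
print.learner_library <- function(x, ...) {
  cat(sprintf("Learner library (%s task): %s\n", x$task,
              paste(x$names, collapse = ", ")))
  invisible(x)
}

# ---- individual learner constructors -------------------------------------

# All parametric learners build formulas from the feature names so they work
# for any adjustment set.  Probability-task variants use binomial glms where
# a likelihood is defined; tree/forest learners regress on the 0/1 target
# and are clipped downstream.

make_learner_mean <- function(task) {
  sl_learner("mean",
    fit = function(x, y) mean(y),
    predict = function(fit, newx) rep(fit, nrow(newx)))
}

# Right-hand side spelled out from feature names (so it also works as a
# `step()` scope, where `.` would not expand).
rhs_terms <- function(x, interactions = FALSE) {
  main <- paste(names(x), collapse = " + ")
  if (interactions && ncol(x) > 1L) sprintf("(%s)^2", main) else main
}

lm_formula <- function(x, interactions = FALSE) {
  as.formula(paste("..y ~", rhs_terms(x, interactions)))
}

make_learner_glm <- function(task, interactions = FALSE) {
  name <- if (interactions) "glm.interaction" else "glm"
  sl_learner(name,
    fit = function(x, y) {
      dat <- cbind(..y = y, x)
      if (task == "probability") {
        glm(lm_formula(x, interactions), data = dat, family = binomial())
      } else {
        lm(lm_formula(x, interactions), data = dat)
      }
    },
    predict = function(fit, newx) {
      unname(predict(fit, newdata = newx, type = "response"))
    })
}

make_learner_step <- function(task, interactions = FALSE) {
  name <- if (interactions) "step.interaction" else "step"
  sl_learner(name,
    fit = function(x, y) {
      dat <- cbind(..y = y, x)
      null_fit <- if (task == "probability") {
        glm(..y ~ 1, data = dat, family = binomial())
      } else {
        lm(..y ~ 1, data = dat)
      }
      scope <- list(lower = ~1,
                    upper = as.formula(paste("~", rhs_terms(x, interactions))))
      step(null_fit, scope = scope, direction = "both", trace = 0)
    },
    predict = function(fit, newx) {
      unname(predict(fit, newdata = newx, type = "response"))
    })
}

# Additive model: smooth terms for features with enough distinct values,
# linear terms otherwise (counts and indicators stay linear).
make_learner_gam <- function(task) {
  sl_learner("gam",
    fit = function(x, y) {
      dat <- cbind(..y = y, x)
      terms <- vapply(names(x), function(v) {
        nu <- length(unique(x[[v]]))
        if (nu >= 5L) sprintf("s(%s, k = %d)", v, min(5L, nu - 1L)) else v
      }, character(1))
      fml <- as.formula(paste("..y ~", paste(terms, collapse = " + ")))
      fam <- if (task == "probability") binomial() else gaussian()
      mgcv::gam(fml, data = dat, family = fam, method = "REML")
    },
    predict = function(fit, newx) {
      as.numeric(predict(fit, newdata = newx, type = "response"))
    })
}

make_learner_randomforest <- function(task, ntree = 200L) {
  sl_learner("randomForest",
    fit = function(x, y) {
      if (task == "probability") {
        randomForest::randomForest(x = x, y = factor(y, levels = c(0, 1)),
                                   ntree = ntree)
      } else {
        randomForest::randomForest(x = x, y = y, ntree = ntree)
      }
    },
    predict = function(fit, newx) {
      if (task == "probability") {
        as.numeric(predict(fit, newdata = newx, type = "prob")[, "1"])
      } else {
        as.numeric(predict(fit, newdata = newx))
      }
    })
}

make_learner_rpart <- function(task) {
  sl_learner("rpart",
    fit = function(x, y) {
      dat <- cbind(..y = y, x)
      rpart::rpart(..y ~ ., data = dat, method = "anova",
                   control = rpart::rpart.control(cp = 0.001, minbucket = 10))
    },
    predict = function(fit, newx) {
      as.numeric(predict(fit, newdata = newx))
    })
}

#' Build a preset learner roster
#'
#' Three presets are provided:
#' \describe{
#'   \item{`default`}{marginal mean, main-effects linear/logistic model,
#'     all-pairwise-interactions model, forward/backward stepwise (AIC) with
#'     and without interactions, spline-based additive model, random forest,
#'     and a single regression tree — the full roster.}
#'   \item{`handpicked`}{the hand-picked comparison roster: linear model,
#'     interactions model, stepwise with and without interactions, additive
#'     model, random forest, regression tree (no marginal mean).}
#'   \item{`reduced`}{marginal mean, linear model, interactions model,
#'     additive model — a fast parametric roster for large replication
#'     studies.}
#'   \item{`parametric`}{marginal mean and main-effects linear/logistic
#'     model only.}
#' }
#'
#' @param preset Roster name.
#' @param task Passed to [learner_library()].
#' @param rf_ntree Trees for the random forest member (default 200).
#' @return A [learner_library()].
#' @export
sl_roster <- function(preset = c("default", "handpicked", "reduced",
                                 "parametric"),
                      task = c("regression", "probability"),
                      rf_ntree = 200L) {
  preset <- match.arg(preset)
  task <- match.arg(task)
  ls <- switch(preset,
    default = list(
      make_learner_mean(task),
      make_learner_glm(task),
      make_learner_glm(task, interactions = TRUE),
      make_learner_step(task),
      make_learner_step(task, interactions = TRUE),
      make_learner_gam(task),
      make_learner_randomforest(task, ntree = rf_ntree),
      make_learner_rpart(task)
    ),
    handpicked = list(
      make_learner_glm(task),
      make_learner_glm(task, interactions = TRUE),
      make_learner_step(task),
      make_learner_step(task, interactions = TRUE),
      make_learner_gam(task),
      make_learner_randomforest(task, ntree = rf_ntree),
      make_learner_rpart(task)
    ),
    reduced = list(
      make_learner_mean(task),
      make_learner_glm(task),
      make_learner_glm(task, interactions = TRUE),
      make_learner_gam(task)
    ),
    parametric = list(
      make_learner_mean(task),
      make_learner_glm(task)
    )
  )
  learner_library(ls, task = task)
}
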