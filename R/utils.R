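#' @keywords internal
"_PACKAGE"

#' @importFrom stats aggregate as.formula binomial coef gaussian glm lm
#'   model.matrix optimize plogis predict qlogis quantile rbinom rnorm runif
#'   sd step terms uniroot var vcov
#' @importFrom utils read.csv write.csv head
NULL

# Column names used in ggplot2 non-standard evaluation.
utils::globalVariables(c("label", "mean_ate", "ci_low", "ci_high"))

# Inverse logit / logit, named as in the targeted-learning literature.
expit <- plogis
logit <- qlogis

#' Derive a reproducible child seed from a master seed
#'
#' All randomness in the package flows from a single master seed; independent
#' random streams (data draws, CV folds, learner fits, replicates) use child
#' seeds derived deterministically from it so that no two streams collide and
#' every run is reproducible end to end.
#'
#' @param seed Master seed (integer).
#' @param offset Non-negative integer identifying the stream.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
child_seed <- function(seed, offset) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(offset))
  # Weyl-style mixing; kept in double precision, result < 2^31 - 1.
  m <- 2147483647
  x <- (abs(seed) %% m)
  for (k in seq_len(2L)) {
    x <- (x * 48271 + offset * 9349 + 1) %% m
  }
  as.integer(x)
}

# Clip numeric vector into [lo, hi].
clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Bound predictions away from 0/1 before taking logits.
bound_probs <- function(p, eps = 1e-6) clip(p, eps, 1 - eps)

stop_invalid <- function(...) stop(..., call. = FALSE)
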