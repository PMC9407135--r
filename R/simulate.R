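#' Simulate period-level observations from the structural causal model
#'
#' Draws `n` i.i.d. team-period observations `O = (W1, W2, W3, A, Y)`
#' following the structural order `W1 -> W2 -> (W3, A) -> Y` described in
#' [sim_config()].  The raw outcome (meters) is min-max normalized to `[0,1]`
#' over the generated dataset, matching the dataset-level normalization used
#' throughout the estimators; the raw outcome is kept in `Y_raw` and the
#' normalization bounds are stored as attributes `y_min` / `y_max` so the
#' transform is invertible.
#'
#' @param cfg A [sim_config()].
#' @param n Number of rows to draw (>= 0).
#' @param seed RNG seed; defaults to `cfg$seed`.  Identical `(cfg, n, seed)`
#'   reproduce the table exactly.
#' @return A `data.frame` of class `observation_table` with integer columns
#'   `W1`, `W2`, binary `W3`, `A`, and numeric `Y` (normalized), `Y_raw`
#'   (meters).
#' @examples
#' dat <- simulate_periods(sim_config(), n = 500, seed = 42)
#' summary(dat$Y)
#' @export
simulate_periods <- function(cfg, n, seed = cfg$seed) {
  validate_sim_config(cfg)
  if (length(n) != 1L || !is.finite(n) || n < 0)
    stop_invalid("n must be a single non-negative number")
  n <- as.integer(n)
  if (n == 0L) {
    out <- data.frame(W1 = integer(0), W2 = integer(0), W3 = integer(0),
                      A = integer(0), Y = numeric(0), Y_raw = numeric(0))
    return(as_observation_table(out, y_min = NA_real_, y_max = NA_real_))
  }
  set.seed(seed)
  W1 <- sample.int(cfg$n_periods, n, replace = TRUE)
  W2 <- rbinom(n, cfg$max_subs, expit(cfg$coef_W2[1] + cfg$coef_W2[2] * W1))
  # W3 and A are independent given W1 (and W2): W3 is a distance cost of the
  # current period, not a confounder of the previous-period treatment.
  W3 <- rbinom(n, 1L, expit(cfg$coef_W3[1] + cfg$coef_W3[2] * W1))
  A <- rbinom(n, 1L, expit(cfg$coef_A[1] + cfg$coef_A[2] * W1 -
                             cfg$coef_A[3] * W2))
  Y_raw <- outcome_mean(cfg, W1, W2, W3, A) + rnorm(n, 0, cfg$noise_sd)
  nrm <- normalize_minmax(Y_raw)
  out <- data.frame(W1 = W1, W2 = W2, W3 = W3, A = A,
                    Y = nrm$y, Y_raw = Y_raw)
  as_observation_table(out, y_min = nrm$y_min, y_max = nrm$y_max)
}

# Min-max normalize; a constant (or single-row) vector maps to 0.5.
normalize_minmax <- function(y_raw) {
  y_min <- min(y_raw)
  y_max <- max(y_raw)
  if (y_max > y_min) {
    y <- (y_raw - y_min) / (y_max - y_min)
  } else {
    y <- rep(0.5, length(y_raw))
  }
  list(y = y, y_min = y_min, y_max = y_max)
}

#' Back-transform a normalized outcome to meters
#'
#' @param y Normalized outcome values.
#' @param y_min,y_max Normalization bounds; default to the attributes stored
#'   on an [observation table][simulate_periods()].
#' @param data Optional `observation_table` carrying `y_min`/`y_max`.
#' @return Outcome values in meters.
#' @export
denormalize_y <- function(y, y_min = NULL, y_max = NULL, data = NULL) {
  if (!is.null(data)) {
    y_min <- attr(data, "y_min")
    y_max <- attr(data, "y_max")
  }
  if (is.null(y_min) || is.null(y_max))
    stop_invalid("normalization bounds missing")
  y * (y_max - y_min) + y_min
}

as_observation_table <- function(df, y_min = NA_real_, y_max = NA_real_) {
  attr(df, "y_min") <- y_min
  attr(df, "y_max") <- y_max
  class(df) <- c("observation_table", "data.frame")
  df
}

#' Validate an observation table
#'
#' Checks the schema contract shared by the simulator and the observed-data
#' reader: columns `W1, W2, W3, A, Y` present and complete, `A` and `W3`
#' binary, `Y` inside `[0, 1]`.
#'
#' @param data A data frame.
#' @return `data`, invisibly, on success; an error describing the violation
#'   (including offending row numbers for non-binary `A`/`W3`) otherwise.
#' @export
validate_observation_table <- function(data) {
  need <- c("W1", "W2", "W3", "A", "Y")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols))
    stop_invalid("missing column(s): ", paste(missing_cols, collapse = ", "))
  for (col in need) {
    if (anyNA(data[[col]]))
      stop_invalid("missing values in column ", col)
  }
  for (col in c("A", "W3")) {
    bad <- which(!(data[[col]] %in% c(0, 1)))
    if (length(bad))
      stop_invalid("column ", col, " must be binary; offending row(s): ",
                   paste(head(bad, 10L), collapse = ", "))
  }
  if (nrow(data) > 0 && (min(data$Y) < 0 || max(data$Y) > 1))
    stop_invalid("Y must lie in [0, 1]")
  invisible(data)
}

#' Ground-truth ATE of the simulator by Monte-Carlo counterfactual contrast
#'
#' Draws `mc_draws` units from the structural model, evaluates both
#' counterfactual outcomes `Y(1)` and `Y(0)` per unit with shared noise, and
#' averages the difference.  The contrast is mapped onto the normalized
#' outcome scale by dividing by the *expected min-max range of an analysis
#' dataset of `norm_n` rows*, estimated by cutting the factual Monte-Carlo
#' sample into blocks of `norm_n` and averaging the block ranges.  This makes
#' the truth live on the same scale as estimates computed from size-`norm_n`
#' datasets normalized by their own min-max (a sample min-max range grows
#' slowly with sample size, so normalizing the truth by the range of the full
#' Monte-Carlo sample would shift the scale of every comparison).
#'
#' @param cfg A [sim_config()].
#' @param mc_draws Number of Monte-Carlo units (>= 1).
#' @param seed RNG seed.
#' @param norm_n Size of the analysis datasets whose normalization scale the
#'   truth should match (default 5000, the default study size).
#' @return An object of class `true_ate` with fields `value` (normalized
#'   scale), `value_raw` (meters), `mc_draws`, `mc_se` (normalized scale),
#'   `norm_range` (meters).
#' @examples
#' true_ate(sim_config(), mc_draws = 1e4, seed = 1)
#' @export
true_ate <- function(cfg, mc_draws, seed = cfg$seed, norm_n = 5000L) {
  validate_sim_config(cfg)
  if (length(mc_draws) != 1L || !is.finite(mc_draws) || mc_draws < 1)
    stop_invalid("mc_draws must be >= 1")
  mc_draws <- as.integer(mc_draws)
  set.seed(seed)
  W1 <- sample.int(cfg$n_periods, mc_draws, replace = TRUE)
  W2 <- rbinom(mc_draws, cfg$max_subs,
               expit(cfg$coef_W2[1] + cfg$coef_W2[2] * W1))
  W3 <- rbinom(mc_draws, 1L, expit(cfg$coef_W3[1] + cfg$coef_W3[2] * W1))
  A <- rbinom(mc_draws, 1L, expit(cfg$coef_A[1] + cfg$coef_A[2] * W1 -
                                    cfg$coef_A[3] * W2))
  noise <- rnorm(mc_draws, 0, cfg$noise_sd)
  # Shared noise: counterfactual consistency holds unit by unit.
  y1 <- outcome_mean(cfg, W1, W2, W3, 1L) + noise
  y0 <- outcome_mean(cfg, W1, W2, W3, 0L) + noise
  y_fact <- ifelse(A == 1L, y1, y0)
  diff_raw <- y1 - y0

  norm_n <- min(as.integer(norm_n), mc_draws)
  n_blocks <- max(1L, mc_draws %/% norm_n)
  block_ranges <- vapply(seq_len(n_blocks), function(b) {
    idx <- ((b - 1L) * norm_n + 1L):(b * norm_n)
    diff(range(y_fact[idx]))
  }, numeric(1))
  norm_range <- mean(block_ranges)
  if (!is.finite(norm_range) || norm_range <= 0) norm_range <- 1

  value_raw <- mean(diff_raw)
  mc_se_raw <- if (mc_draws > 1) sd(diff_raw) / sqrt(mc_draws) else Inf
  out <- list(
    value = value_raw / norm_range,
    value_raw = value_raw,
    mc_draws = mc_draws,
    mc_se = mc_se_raw / norm_range,
    norm_range = norm_range,
    norm_n = norm_n
  )
  class(out) <- "true_ate"
  out
}

#' @export
print.true_ate <- function(x, ...) {
  cat(sprintf(
    "True ATE (normalized scale): %.5f  [mc se %.2g, %d draws]\n",
    x$value, x$mc_se, x$mc_draws))
  cat(sprintf("  raw scale: %.2f m over expected range %.1f m (n=%d)\n",
              x$value_raw, x$norm_range, x$norm_n))
  invisible(x)
}
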