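#' Configuration of a simulation/misspecification study
#'
#' @param replications Number of simulated datasets (default 200).
#' @param n_per_replicate Rows per dataset (default 5000, the order of the
#'   observed dataset).
#' @param estimators Subset of `c("GLM", "TMLE", "TMLEH")`.
#' @param adjustments Subset of `c("correct", "misspecified")` — the full
#'   confounder set `{W1, W2, W3}` vs. the set with the current-period
#'   substitution `W3` dropped.
#' @param sim A [sim_config()].
#' @param master_seed Single seed from which every replicate's data, folds
#'   and learner seeds are derived.
#' @param V CV folds for the super-learner estimators (default 10).
#' @param lb Propensity truncation bound.
#' @param tmle_roster,tmleh_roster Roster preset names for the `TMLE` and
#'   `TMLEH` estimators (defaults `"default"` and `"handpicked"`).
#' @param mc_draws Monte-Carlo draws for the ground-truth ATE (default 1e6).
#' @return An object of class `study_config`.
#' @export
study_config <- function(replications = 200L, n_per_replicate = 5000L,
                         estimators = c("GLM", "TMLE", "TMLEH"),
                         adjustments = c("correct", "misspecified"),
                         sim = sim_config(), master_seed = 1L, V = 10L,
                         lb = 0.025, tmle_roster = "default",
                         tmleh_roster = "handpicked", mc_draws = 1e6) {
  estimators <- match.arg(estimators, several.ok = TRUE)
  adjustments <- match.arg(adjustments, several.ok = TRUE)
  if (replications < 1L) stop_invalid("replications must be >= 1")
  if (!length(adjustments)) stop_invalid("adjustments must be non-empty")
  validate_sim_config(sim)
  structure(list(replications = as.integer(replications),
                 n_per_replicate = as.integer(n_per_replicate),
                 estimators = estimators, adjustments = adjustments,
                 sim = sim, master_seed = as.integer(master_seed),
                 V = as.integer(V), lb = lb,
                 tmle_roster = tmle_roster, tmleh_roster = tmleh_roster,
                 mc_draws = mc_draws),
            class = "study_config")
}

adjustment_terms <- function(label) {
  switch(label,
         correct = c("W1", "W2", "W3"),
         misspecified = c("W1", "W2"),
         stop_invalid("unknown adjustment label: ", label))
}

# Run one estimator on one dataset; returns an ate_result.
run_one_estimator <- function(data, estimator, adj_label, cfg, seed) {
  terms <- adjustment_terms(adj_label)
  switch(estimator,
    GLM = ate_glm(data, terms, adjustment_label = adj_label),
    TMLE = tmle_ate(data, terms,
                    q_roster = sl_roster(cfg$tmle_roster, "regression"),
                    g_roster = sl_roster(cfg$tmle_roster, "probability"),
                    V = cfg$V, lb = cfg$lb, seed = seed,
                    estimator = "TMLE", adjustment_label = adj_label),
    TMLEH = tmle_ate(data, terms,
                     q_roster = sl_roster(cfg$tmleh_roster, "regression"),
                     g_roster = sl_roster(cfg$tmleh_roster, "probability"),
                     V = cfg$V, lb = cfg$lb, seed = seed,
                     estimator = "TMLEH", adjustment_label = adj_label),
    stop_invalid("unknown estimator: ", estimator))
}

#' Run the simulation / misspecification bias study
#'
#' For each replicate: simulate a dataset from the structural model, run
#' every requested estimator under every requested adjustment set, and
#' aggregate the estimates against the simulator's ground-truth ATE into a
#' bias table (mean ATE, mean 95% CI, bias, bias %, Monte-Carlo SE).  An
#' estimator failure inside a replicate excludes that replicate for that
#' estimator/adjustment cell and is counted in the table.
#'
#' @param cfg A [study_config()].
#' @param verbose Print a line per replicate block.
#' @return An object of class `bias_table`: `table` (`data.frame` with one
#'   row per estimator x adjustment), `true_ate`, `estimates` (long
#'   `data.frame` of per-replicate estimates), `config`.
#' @export
run_simulation_study <- function(cfg, verbose = FALSE) {
  stopifnot(inherits(cfg, "study_config"))
  truth <- true_ate(cfg$sim, mc_draws = cfg$mc_draws,
                    seed = child_seed(cfg$master_seed, 91L),
                    norm_n = cfg$n_per_replicate)
  rows <- list()
  k <- 0L
  for (r in seq_len(cfg$replications)) {
    dat <- simulate_periods(cfg$sim, cfg$n_per_replicate,
                            seed = child_seed(cfg$master_seed, 1000L + r))
    for (est in cfg$estimators) {
      for (adj in cfg$adjustments) {
        res <- tryCatch(
          run_one_estimator(dat, est, adj, cfg,
                            seed = child_seed(cfg$master_seed, 5000L + r)),
          error = function(e) e)
        k <- k + 1L
        if (inherits(res, "error")) {
          rows[[k]] <- data.frame(replicate = r, estimator = est,
                                  adjustment = adj, estimate = NA_real_,
                                  ci_low = NA_real_, ci_high = NA_real_,
                                  error = conditionMessage(res))
        } else {
          rows[[k]] <- data.frame(replicate = r, estimator = est,
                                  adjustment = adj, estimate = res$estimate,
                                  ci_low = res$ci_low, ci_high = res$ci_high,
                                  error = NA_character_)
        }
      }
    }
    if (verbose && r %% 10L == 0L)
      message(sprintf("replicate %d / %d", r, cfg$replications))
  }
  estimates <- do.call(rbind, rows)
  tab <- aggregate_bias_table(estimates, truth)
  structure(list(table = tab, true_ate = truth, estimates = estimates,
                 config = cfg),
            class = "bias_table")
}

aggregate_bias_table <- function(estimates, truth) {
  cells <- unique(estimates[, c("estimator", "adjustment")])
  out <- lapply(seq_len(nrow(cells)), function(i) {
    sub <- estimates[estimates$estimator == cells$estimator[i] &
                       estimates$adjustment == cells$adjustment[i], ]
    ok <- sub[!is.na(sub$estimate), ]
    mean_ate <- mean(ok$estimate)
    mc_se <- if (nrow(ok) > 1) sd(ok$estimate) / sqrt(nrow(ok)) else NA_real_
    data.frame(
      estimator = cells$estimator[i], adjustment = cells$adjustment[i],
      mean_ate = mean_ate,
      ci_low = mean(ok$ci_low), ci_high = mean(ok$ci_high),
      bias = mean_ate - truth$value,
      bias_pct = 100 * (mean_ate - truth$value) / truth$value,
      mc_se = mc_se,
      n_replicates = nrow(ok),
      n_excluded = nrow(sub) - nrow(ok))
  })
  out <- do.call(rbind, out)
  attr(out, "true_ate") <- truth$value
  out
}

#' @export
print.bias_table <- function(x, ...) {
  cat(sprintf("Simulation study: %d replicates of n = %d\n",
              x$config$replications, x$config$n_per_replicate))
  cat(sprintf("True ATE: %.4f (mc se %.2g)\n", x$true_ate$value,
              x$true_ate$mc_se))
  df <- x$table
  df[, sapply(df, is.numeric)] <- round(df[, sapply(df, is.numeric)], 4)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Observed-data analysis (GLM / TMLE / TMLEH under both adjustments)
#'
#' Computes every requested estimator's ATE with its 95% CI under the full
#' ("correct") and `W3`-dropped ("misspecified") adjustment sets, plus the
#' between-adjustment difference rows (`misspecified - correct` and its
#' percentage of the correct-model ATE).
#'
#' @param data Observation table (schema-validated).
#' @param cfg A [study_config()] supplying estimator settings; replications
#'   are ignored.
#' @return An object of class `observed_report`: `results` (`data.frame`
#'   with estimate and CI per estimator x adjustment) and `differences`.
#' @export
run_observed_analysis <- function(data, cfg = study_config()) {
  validate_observation_table(data)
  rows <- list(); k <- 0L
  for (est in cfg$estimators) {
    for (adj in cfg$adjustments) {
      res <- run_one_estimator(data, est, adj, cfg,
                               seed = child_seed(cfg$master_seed, 42L))
      k <- k + 1L
      rows[[k]] <- data.frame(estimator = est, adjustment = adj,
                              estimate = res$estimate, ci_low = res$ci_low,
                              ci_high = res$ci_high, n = res$n)
    }
  }
  results <- do.call(rbind, rows)
  differences <- NULL
  if (all(c("correct", "misspecified") %in% cfg$adjustments)) {
    differences <- do.call(rbind, lapply(cfg$estimators, function(est) {
      co <- results$estimate[results$estimator == est &
                               results$adjustment == "correct"]
      mi <- results$estimate[results$estimator == est &
                               results$adjustment == "misspecified"]
      data.frame(estimator = est, difference = mi - co,
                 difference_pct = 100 * (mi - co) / co)
    }))
  }
  structure(list(results = results, differences = differences,
                 n = nrow(data)),
            class = "observed_report")
}

#' @export
print.observed_report <- function(x, ...) {
  cat(sprintf("Observed-data analysis (n = %d)\n", x$n))
  df <- x$results
  df[, sapply(df, is.numeric)] <- round(df[, sapply(df, is.numeric)], 4)
  print(df, row.names = FALSE)
  if (!is.null(x$differences)) {
    cat("Misspecified - correct differences:\n")
    dd <- x$differences
    dd[, sapply(dd, is.numeric)] <- round(dd[, sapply(dd, is.numeric)], 4)
    print(dd, row.names = FALSE)
  }
  invisible(x)
}

#' Positivity diagnostic over (W1, W2) strata
#'
#' Cross-tabulates treated and control counts within every observed
#' `(W1, W2)` stratum (`W3` is collapsed to avoid sparse cells) and flags
#' strata in which either arm is empty — the strata for which the
#' treatment-positivity assumption has no empirical support.
#'
#' @param data Observation table.
#' @return An object of class `positivity_report`: `strata` (`data.frame`
#'   with `W1`, `W2`, `n_treated`, `n_control`, `flag`) and `n_flagged`.
#' @export
positivity_check <- function(data) {
  validate_observation_table(data)
  if (!nrow(data)) stop_invalid("empty data")
  agg <- aggregate(cbind(n_treated = data$A, n_control = 1 - data$A),
                   by = list(W1 = data$W1, W2 = data$W2), FUN = sum)
  agg <- agg[order(agg$W1, agg$W2), ]
  agg$flag <- agg$n_treated == 0L | agg$n_control == 0L
  rownames(agg) <- NULL
  structure(list(strata = agg, n_flagged = sum(agg$flag), n = nrow(data)),
            class = "positivity_report")
}

#' @export
print.positivity_report <- function(x, ...) {
  cat(sprintf("Positivity check over %d (W1, W2) strata: %d flagged\n",
              nrow(x$strata), x$n_flagged))
  if (x$n_flagged > 0) print(x$strata[x$strata$flag, ], row.names = FALSE)
  invisible(x)
}

# ---- report serialization ------------------------------------------------

#' Write a bias table (or observed report) to CSV
#'
#' @param x A `bias_table` or `observed_report`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_report_csv <- function(x, path) {
  df <- if (inherits(x, "bias_table")) {
    cbind(x$table, true_ate = x$true_ate$value)
  } else if (inherits(x, "observed_report")) {
    x$results
  } else stop_invalid("unsupported report type")
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a bias-table CSV back into a data frame
#'
#' Round-trips the output of [write_report_csv()] losslessly (numeric
#' columns at full precision as written by `write.csv`).
#'
#' @param path CSV path.
#' @return A `data.frame`.
#' @export
read_report_csv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Point-and-interval plot of a simulation study
#'
#' Renders the mean ATE and mean 95% CI of every estimator/adjustment cell
#' against the ground-truth ATE (dashed line) — the standard visual for the
#' misspecification comparison.
#'
#' @param study A `bias_table` from [run_simulation_study()].
#' @param path Optional output file (PNG or SVG by extension); when `NULL`
#'   the ggplot object is returned unrendered.
#' @return The ggplot object, invisibly when written to file.
#' @export
plot_ate_comparison <- function(study, path = NULL) {
  stopifnot(inherits(study, "bias_table"))
  df <- study$table
  df$label <- paste0(df$estimator,
                     ifelse(df$adjustment == "misspecified", " miss", ""))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = label, y = mean_ate)) +
    ggplot2::geom_hline(yintercept = study$true_ate$value,
                        linetype = "dashed", colour = "grey40") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = ci_low, ymax = ci_high)) +
    ggplot2::labs(x = NULL, y = "ATE (normalized outcome scale)",
                  title = "Estimated ATE vs. ground truth",
                  subtitle = sprintf("dashed line: true ATE = %.4f",
                                     study$true_ate$value)) +
    ggplot2::theme_minimal()
  if (!is.null(path)) {
    ggplot2::ggsave(path, p, width = 7, height = 4.5, dpi = 150)
    return(invisible(p))
  }
  p
}
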