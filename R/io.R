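#' Schema of an observed per-period dataset
#'
#' Maps the column names of a delimited per-team-period file onto the
#' canonical roles: `W1` (five-minute period index), `W2` (substitutes
#' present), `W3` (substitution in the current period), `A` (substitution in
#' the previous period) and `Y` (team distance).  The default mapping
#' assumes the file already uses the canonical names; real files with other
#' headers are mapped explicitly (or via YAML, see
#' [read_observed_schema()]).  Mismatches fail loudly — the reader never
#' guesses silently.
#'
#' @param W1,W2,W3,A,Y Source column names for each role.
#' @param delimiter Field delimiter (default `","`).
#' @return An object of class `observed_schema`.
#' @export
observed_schema <- function(W1 = "W1", W2 = "W2", W3 = "W3", A = "A",
                            Y = "Y", delimiter = ",") {
  structure(list(mapping = c(W1 = W1, W2 = W2, W3 = W3, A = A, Y = Y),
                 delimiter = delimiter),
            class = "observed_schema")
}

#' Read an observed-schema mapping from YAML
#'
#' @param path YAML file with keys `W1, W2, W3, A, Y` (and optionally
#'   `delimiter`).
#' @return An [observed_schema()].
#' @export
read_observed_schema <- function(path) {
  raw <- yaml::read_yaml(path)
  observed_schema(
    W1 = raw$W1 %||% "W1", W2 = raw$W2 %||% "W2", W3 = raw$W3 %||% "W3",
    A = raw$A %||% "A", Y = raw$Y %||% "Y",
    delimiter = raw$delimiter %||% ","
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read and validate an observed per-period dataset
#'
#' Loads a delimited table, maps columns through the schema, drops rows
#' with missing values in mapped columns (logging the count), validates the
#' observation-table contract (binary `A`/`W3`, no missing values), and
#' min-max normalizes the outcome over the loaded dataset.  Whether the
#' source outcome is raw meters or already normalized is auto-detected:
#' values outside `[0, 1]` mean raw, and the decision is logged.
#'
#' @param path Delimited text file.
#' @param schema An [observed_schema()].
#' @param quiet Suppress log messages.
#' @return An `observation_table` with `Y` normalized, `Y_raw` in source
#'   units, and normalization bounds stored as attributes.
#' @export
read_observed <- function(path, schema = observed_schema(), quiet = FALSE) {
  if (!file.exists(path)) stop_invalid("file not found: ", path)
  raw <- read.csv(path, sep = schema$delimiter, stringsAsFactors = FALSE)
  if (!nrow(raw)) stop_invalid("empty input: ", path, " has no data rows")
  missing_cols <- setdiff(unname(schema$mapping), names(raw))
  if (length(missing_cols))
    stop_invalid("schema column(s) not found in file: ",
                 paste(missing_cols, collapse = ", "))
  df <- data.frame(
    W1 = raw[[schema$mapping[["W1"]]]],
    W2 = raw[[schema$mapping[["W2"]]]],
    W3 = raw[[schema$mapping[["W3"]]]],
    A = raw[[schema$mapping[["A"]]]],
    Y_src = raw[[schema$mapping[["Y"]]]]
  )
  complete <- stats::complete.cases(df)
  n_dropped <- sum(!complete)
  if (n_dropped > 0 && !quiet)
    message(sprintf("read_observed: dropped %d row(s) with missing values",
                    n_dropped))
  df <- df[complete, , drop = FALSE]
  if (!nrow(df)) stop_invalid("empty input: no complete rows in ", path)
  for (col in c("A", "W3")) {
    bad <- which(!(df[[col]] %in% c(0, 1)))
    if (length(bad))
      stop_invalid("column ", schema$mapping[[col]],
                   " must be binary (0/1); offending row(s): ",
                   paste(head(bad, 10L), collapse = ", "))
  }
  y_src <- df$Y_src
  already_normalized <- min(y_src) >= 0 && max(y_src) <= 1
  if (!quiet)
    message(sprintf(
      "read_observed: %d rows; outcome treated as %s", nrow(df),
      if (already_normalized) "already normalized" else
        "raw units (min-max normalizing)"))
  nrm <- normalize_minmax(y_src)
  out <- data.frame(W1 = as.integer(df$W1), W2 = as.integer(df$W2),
                    W3 = as.integer(df$W3), A = as.integer(df$A),
                    Y = nrm$y, Y_raw = y_src)
  out <- as_observation_table(out, y_min = nrm$y_min, y_max = nrm$y_max)
  validate_observation_table(out)
  out
}

#' Write a simulated fixture in the observed-data dialect
#'
#' Generates a dataset from the simulator and writes it as CSV with header
#' `W1,W2,W3,A,Y,Y_raw`, so every downstream stage can be exercised without
#' any external download.  Deterministic: two writes with the same
#' `(config, n, seed)` are byte-identical.
#'
#' @param cfg A [sim_config()].
#' @param n Rows to generate.
#' @param seed RNG seed.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_fixture <- function(cfg, n, seed, path) {
  dat <- simulate_periods(cfg, n, seed = seed)
  dat_out <- as.data.frame(dat)
  # Fixed-format outcome columns keep the file byte-stable across platforms.
  dat_out$Y <- sprintf("%.10f", dat_out$Y)
  dat_out$Y_raw <- sprintf("%.6f", dat_out$Y_raw)
  ok <- tryCatch({
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines("W1,W2,W3,A,Y,Y_raw", con)
    if (nrow(dat_out))
      writeLines(do.call(paste, c(dat_out, sep = ",")), con)
    TRUE
  }, error = function(e) {
    stop_invalid("failed writing fixture to ", path, ": ",
                 conditionMessage(e))
  })
  invisible(path)
}
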