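# Reading, validating and summarizing effect-size tables.
#
# The expected layout is one row per intervention arm ("nudge"): an estimated
# treatment effect in percentage points, its standard error, a trial
# identifier and an optional domain label. Effects and standard errors are
# kept in percentage points throughout; nothing is rescaled internally.

#' Construct an effect-size dataset
#'
#' Builds the canonical container used by every downstream function: a
#' validated data frame of effect estimates with class `effect_dataset`.
#'
#' @param effect numeric vector of effect estimates (percentage points).
#' @param se numeric vector of standard errors (percentage points, > 0).
#' @param trial_id trial labels (coerced to character); defaults to one
#'   trial per effect.
#' @param domain optional domain/category labels; defaults to `"all"`.
#' @param nudge_id unique per-effect labels; defaults to `"effect_<i>"`.
#' @return An object of class `effect_dataset`: a data frame with columns
#'   `effect`, `se`, `trial_id`, `domain`, `nudge_id` and attributes
#'   `n_effects`, `n_trials`, `domains`.
#' @examples
#' d <- effect_dataset(effect = c(1, -0.5, 2), se = c(0.5, 0.5, 1),
#'                     trial_id = c("t1", "t1", "t2"))
#' attr(d, "n_trials")
#' @export
effect_dataset <- function(effect, se, trial_id = NULL, domain = NULL,
                           nudge_id = NULL) {
  n <- length(effect)
  if (n < 1L) stop_selmix("an effect dataset needs at least one record")
  effect <- as.numeric(effect)
  se <- as.numeric(se)
  if (length(se) != n) stop_selmix("'effect' and 'se' lengths differ")
  if (anyNA(effect) || any(!is.finite(effect)))
    stop_selmix("non-finite effect values at rows: ",
                paste(which(!is.finite(effect)), collapse = ", "))
  bad_se <- !is.finite(se) | se <= 0
  if (any(bad_se))
    stop_selmix("standard errors must be positive and finite; offending rows: ",
                paste(which(bad_se), collapse = ", "))
  trial_id <- if (is.null(trial_id)) paste0("trial_", seq_len(n))
              else as.character(trial_id)
  domain <- if (is.null(domain)) rep("all", n) else as.character(domain)
  nudge_id <- if (is.null(nudge_id)) paste0("effect_", seq_len(n))
              else as.character(nudge_id)
  if (anyDuplicated(nudge_id))
    stop_selmix("nudge_id values must be unique")
  if (length(trial_id) != n || length(domain) != n || length(nudge_id) != n)
    stop_selmix("label columns must match the number of effects")
  out <- data.frame(effect = effect, se = se, trial_id = trial_id,
                    domain = domain, nudge_id = nudge_id,
                    stringsAsFactors = FALSE)
  structure(out,
            n_effects = n,
            n_trials = length(unique(trial_id)),
            domains = sort(unique(domain)),
            class = c("effect_dataset", "data.frame"))
}

#' @export
print.effect_dataset <- function(x, ...) {
  cat(sprintf("<effect_dataset> %d effects, %d trials, %d domain(s)\n",
              attr(x, "n_effects"), attr(x, "n_trials"),
              length(attr(x, "domains"))))
  print.data.frame(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat(sprintf("... (%d more rows)\n", nrow(x) - 6L))
  invisible(x)
}

#' Read an effect-size table from CSV
#'
#' Reads a comma-separated file with a header row (UTF-8, decimal point) and
#' maps its columns onto the canonical effect/se/trial/domain schema. Rows
#' with missing effect or standard error are dropped with a warning that
#' names them; a non-positive or non-numeric standard error on a complete
#' row is an error.
#'
#' @param path path to the CSV file.
#' @param column_map named character vector mapping logical names
#'   (`effect`, `se`, and optionally `trial_id`, `domain`, `nudge_id`) to
#'   the file's column headers.
#' @return An [effect_dataset()]; the number of dropped rows is stored in
#'   attribute `n_dropped`.
#' @export
read_effect_table <- function(path,
                              column_map = c(effect = "effect", se = "se",
                                             trial_id = "trial_id",
                                             domain = "domain",
                                             nudge_id = "nudge_id")) {
  if (!file.exists(path)) stop_selmix("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  for (logical_name in c("effect", "se")) {
    if (!logical_name %in% names(column_map))
      stop_selmix("column_map must map '", logical_name, "'")
    if (!column_map[[logical_name]] %in% names(raw))
      stop_selmix("mapped column '", column_map[[logical_name]],
                  "' (for ", logical_name, ") not present in ", path)
  }
  effect <- suppressWarnings(as.numeric(raw[[column_map[["effect"]]]]))
  se <- suppressWarnings(as.numeric(raw[[column_map[["se"]]]]))
  keep <- !is.na(effect) & !is.na(se)
  if (!all(keep)) {
    dropped <- which(!keep)
    warning(sprintf("dropping %d row(s) with missing effect or se: %s",
                    length(dropped),
                    paste(utils::head(dropped, 20L), collapse = ", ")),
            call. = FALSE)
  }
  if (!any(keep)) stop_selmix("no complete rows in ", path)
  bad_se <- keep & se <= 0
  if (any(bad_se))
    stop_selmix("non-positive se in rows: ",
                paste(which(bad_se), collapse = ", "))
  opt_col <- function(name) {
    if (name %in% names(column_map) && column_map[[name]] %in% names(raw))
      as.character(raw[[column_map[[name]]]])[keep] else NULL
  }
  ds <- effect_dataset(effect = effect[keep], se = se[keep],
                       trial_id = opt_col("trial_id"),
                       domain = opt_col("domain"),
                       nudge_id = opt_col("nudge_id"))
  attr(ds, "n_dropped") <- sum(!keep)
  ds
}

#' Write an effect-size table to CSV
#'
#' Writes the canonical schema (`effect`, `se`, `trial_id`, `domain`,
#' `nudge_id`) so that [read_effect_table()] round-trips the dataset at
#' full precision.
#'
#' @param dataset an [effect_dataset()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_effect_table <- function(dataset, path) {
  stopifnot(inherits(dataset, "effect_dataset"))
  df <- as.data.frame(dataset)
  df$effect <- format(df$effect, digits = 17, trim = TRUE, scientific = FALSE)
  df$se <- format(df$se, digits = 17, trim = TRUE, scientific = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Summarize an effect-size dataset
#'
#' Counts and moments used for dataset sanity checks: effect and trial
#' counts, per-domain counts, tail counts (strictly below -10 / strictly
#' above +10 percentage points, the convention used when a histogram is
#' clipped to the [-10, 10] display range), mean effect and mean standard
#' error.
#'
#' @param dataset an [effect_dataset()].
#' @return A list with elements `n_effects`, `n_trials`, `n_dropped`,
#'   `per_domain`, `n_below_minus10`, `n_above_plus10`, `mean_effect`,
#'   `mean_se`.
#' @export
summarize_effects <- function(dataset) {
  stopifnot(inherits(dataset, "effect_dataset"))
  if (nrow(dataset) < 1L) stop_selmix("empty dataset")
  y <- dataset$effect
  list(
    n_effects = attr(dataset, "n_effects"),
    n_trials = attr(dataset, "n_trials"),
    n_dropped = attr(dataset, "n_dropped") %||% 0L,
    per_domain = as.list(table(dataset$domain)),
    n_below_minus10 = sum(y < -10),
    n_above_plus10 = sum(y > 10),
    mean_effect = mean(y),
    mean_se = mean(dataset$se)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
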