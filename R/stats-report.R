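#' Summary statistics for one condition group
#'
#' @param values numeric vector, `n >= 1`.
#' @param label group label.
#' @return An object of class `group_summary` (also a one-row data
#'   frame): `label`, `n`, `mean`, `sd` (sample, n-1 denominator),
#'   `sem`, `median`, `q1`, `q3` (linear interpolation),
#'   `whisker_low`/`whisker_high` (min/max).
#' @export
group_summary <- function(values, label = NA_character_) {
  if (!is.numeric(values) || !length(values)) stopf("values must be non-empty numeric")
  if (any(!is.finite(values))) stopf("values must be finite")
  n <- length(values)
  s <- if (n > 1) sd(values) else 0
  q <- quantile(values, c(0.25, 0.5, 0.75), names = FALSE)
  out <- data.frame(label = label, n = n, mean = mean(values), sd = s,
                    sem = s / sqrt(n), median = q[2], q1 = q[1], q3 = q[3],
                    whisker_low = min(values), whisker_high = max(values),
                    stringsAsFactors = FALSE)
  class(out) <- c("group_summary", "data.frame")
  out
}

#' Two-group comparison of diffusion coefficients
#'
#' Two-sided Welch unequal-variance t-test, with significance flags at
#' the conventional 0.05 / 0.01 / 0.001 thresholds.  Two constant
#' groups with equal means are reported as `p = 1` (no evidence of a
#' difference); constant groups with different means as `p = 0`.
#'
#' @param a,b numeric vectors, `n >= 2` each.
#' @param labels length-2 character vector naming the groups.
#' @return An object of class `comparison_result`: `labels`,
#'   `statistic`, `df`, `p_value`, `significant_at` (subset of
#'   `c(0.05, 0.01, 0.001)`).
#' @export
compare_groups <- function(a, b, labels = c("A", "B")) {
  if (length(a) < 2 || length(b) < 2) stopf("need n >= 2 per group")
  if (sd(a) == 0 && sd(b) == 0) {
    equal <- mean(a) == mean(b)
    res <- list(statistic = if (equal) 0 else sign(mean(a) - mean(b)) * Inf,
                df = NA_real_, p_value = if (equal) 1 else 0)
  } else {
    ht <- t.test(a, b, var.equal = FALSE)
    res <- list(statistic = unname(ht$statistic), df = unname(ht$parameter),
                p_value = ht$p.value)
  }
  thresholds <- c(0.05, 0.01, 0.001)
  structure(list(labels = labels, statistic = res$statistic, df = res$df,
                 p_value = res$p_value,
                 significant_at = thresholds[res$p_value < thresholds]),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison> %s vs %s: t = %.3f, p = %.4g%s\n",
              x$labels[1], x$labels[2], x$statistic, x$p_value,
              if (length(x$significant_at))
                sprintf(" (significant at %s)", min(x$significant_at)) else ""))
  invisible(x)
}

#' Write a deterministic analysis report
#'
#' Writes the per-vesicle results table, the per-condition summaries
#' and any two-group comparisons as TSV files, plus a JSON report that
#' bundles summaries, comparisons and run metadata (seed, config hash,
#' package version).  Output is byte-identical across re-runs with the
#' same inputs: no timestamps are written.
#'
#' @param results per-vesicle results data frame (see
#'   [analyze_cohort()]), or `NULL`.
#' @param summaries data frame of group summaries (rows of
#'   [group_summary()]), or `NULL`.
#' @param comparisons list of [compare_groups()] results (may be
#'   empty).
#' @param path output directory (created if absent).
#' @param seed seed recorded in the metadata block.
#' @param config_hash hash of the run configuration, if any.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(results = NULL, summaries = NULL,
                         comparisons = list(), path, seed = NA_integer_,
                         config_hash = NA_character_) {
  if (is.null(results) && is.null(summaries)) stopf("nothing to report")
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  tsv <- function(df, file) {
    p <- file.path(path, file)
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  if (!is.null(results)) written <- c(written, tsv(results, "results.tsv"))
  if (!is.null(summaries)) written <- c(written, tsv(summaries, "summaries.tsv"))
  comp_df <- if (length(comparisons)) {
    do.call(rbind, lapply(comparisons, function(cmp) data.frame(
      group_a = cmp$labels[1], group_b = cmp$labels[2],
      statistic = cmp$statistic, df = cmp$df, p_value = cmp$p_value,
      significant_at = if (length(cmp$significant_at))
        min(cmp$significant_at) else NA_real_,
      stringsAsFactors = FALSE)))
  } else NULL
  if (!is.null(comp_df)) written <- c(written, tsv(comp_df, "comparisons.tsv"))

  report <- list(
    metadata = list(package = "guvfrap",
                    version = as.character(packageVersion("guvfrap")),
                    seed = seed, config_hash = config_hash),
    summaries = summaries,
    comparisons = comp_df)
  json_path <- file.path(path, "report.json")
  jsonlite::write_json(report, json_path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  written <- c(written, json_path)
  invisible(written)
}

#' Read a report JSON back into its data frames
#'
#' @param path the report directory or the `report.json` file itself.
#' @return A list with `metadata`, `summaries`, `comparisons`.
#' @export
read_report <- function(path) {
  file <- if (dir.exists(path)) file.path(path, "report.json") else path
  if (!file.exists(file)) stopf("no report found at %s", file)
  jsonlite::fromJSON(file)
}
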