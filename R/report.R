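#' Week-wise threshold sweep across metrics
#'
#' For every cumulative gestational-week group and every metric, fits the
#' MCC-optimal threshold and records the evaluation parameters and the
#' extent of segregation — the machine-readable twin of a week-by-metric
#' MCC table. Groups that are empty or single-class yield `NA` rows.
#'
#' @param x a `ptd_cohort` with metadata.
#' @param metrics metric names (default all nine).
#' @param n_min,n_max week bounds (defaults 8 and 40: 33 groups).
#' @param epsilon,tcs_variant,simpson_variant passed to [metric_matrix()].
#' @return `data.frame` of class `ptd_sweep` with columns `week`, `metric`,
#'   `n_ptd`, `n_term`, `mcc`, `es`, `threshold`, `direction`.
#' @export
week_sweep <- function(x, metrics = ptd_metrics(), n_min = 8, n_max = 40,
                       epsilon = 0.5, tcs_variant = "default",
                       simpson_variant = "gini_simpson") {
  if (is.null(x$meta)) stop("cohort has no metadata")
  mm <- metric_matrix(x, metrics, epsilon, tcs_variant, simpson_variant)
  groups <- cumulative_week_groups(x, n_min, n_max)
  y_all <- stats::setNames(x$meta$outcome, x$meta$sample_id)
  rows <- list()
  for (g in groups) {
    N <- as.integer(sub("Week_", "", g$label))
    y <- y_all[g$members]
    two_class <- length(g$members) > 0 && length(unique(y)) == 2
    for (met in metrics) {
      if (two_class) {
        fit <- fit_best_threshold(mm[g$members, met], y, metric = met)
        r <- fit$report
        rows[[length(rows) + 1]] <-
          data.frame(week = N, metric = met, n_ptd = r$n_ptd,
                     n_term = r$n_term, mcc = r$mcc, es = r$es,
                     threshold = r$threshold, direction = r$direction,
                     stringsAsFactors = FALSE)
      } else {
        rows[[length(rows) + 1]] <-
          data.frame(week = N, metric = met,
                     n_ptd = sum(y == "PTD"), n_term = sum(y == "TERM"),
                     mcc = NA_real_, es = NA_real_, threshold = NA_real_,
                     direction = NA_character_, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("ptd_sweep", "data.frame")
  out
}

#' Format a sweep as a printable week-by-metric table
#'
#' One row per week group with sample counts and each metric's best MCC to
#' three decimals; where a metric separates the classes completely
#' (MCC = 1) the extent of segregation is appended in brackets. The
#' row-best metric is flagged in the `best` column.
#'
#' @param sweep a `ptd_sweep`.
#' @return character `data.frame`, one row per week.
#' @export
format_sweep <- function(sweep) {
  metrics <- unique(sweep$metric)
  weeks <- sort(unique(sweep$week))
  out <- data.frame(week = weeks)
  first <- sweep[!duplicated(sweep$week), , drop = FALSE]
  out$n_ptd <- first$n_ptd[match(weeks, first$week)]
  out$n_term <- first$n_term[match(weeks, first$week)]
  out$total <- out$n_ptd + out$n_term
  for (met in metrics) {
    d <- sweep[sweep$metric == met, , drop = FALSE]
    d <- d[match(weeks, d$week), , drop = FALSE]
    cell <- ifelse(is.na(d$mcc), "NA",
                   ifelse(d$mcc == 1 & !is.na(d$es),
                          sprintf("1 (%.2f)", d$es),
                          sprintf("%.3f", d$mcc)))
    out[[met]] <- cell
  }
  out$best <- vapply(weeks, function(w) {
    d <- sweep[sweep$week == w, , drop = FALSE]
    if (all(is.na(d$mcc))) return(NA_character_)
    d$metric[which.max(d$mcc)]
  }, "")
  out
}

#' Write / read a sweep as TSV (full precision, round-trip safe)
#' @param sweep a `ptd_sweep`.
#' @param path file path.
#' @export
write_sweep <- function(sweep, path) {
  df <- as.data.frame(sweep)
  for (col in c("mcc", "es", "threshold"))
    df[[col]] <- sprintf("%.17g", df[[col]])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sweep
#' @export
read_sweep <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  for (col in c("mcc", "es", "threshold")) df[[col]] <- as.numeric(df[[col]])
  class(df) <- c("ptd_sweep", "data.frame")
  df
}

#' Wide week-by-metric matrix of one sweep statistic
#' @param sweep a `ptd_sweep`.
#' @param stat column to spread (default `"mcc"`).
#' @return `data.frame` with a `week` column and one column per metric,
#'   ready for [compare_metric_mcc_over_weeks()].
#' @export
sweep_matrix <- function(sweep, stat = "mcc") {
  stopifnot(stat %in% colnames(sweep))
  weeks <- sort(unique(sweep$week))
  out <- data.frame(week = weeks)
  for (met in unique(sweep$metric)) {
    d <- sweep[sweep$metric == met, , drop = FALSE]
    out[[met]] <- d[[stat]][match(weeks, d$week)]
  }
  out
}

#' Per-arm diversity trend over sliding gestational-week windows
#'
#' Mean metric value per outcome arm in each overlapping window — the
#' numeric backbone of a diversity-vs-gestation trend figure.
#'
#' @param x a `ptd_cohort` with metadata.
#' @param metric metric name (default `"shannon"`).
#' @param ... window parameters passed to [sliding_week_windows()].
#' @return `data.frame` with window bounds, per-arm means and sizes.
#' @export
diversity_trend <- function(x, metric = "shannon", ...) {
  mm <- metric_matrix(x, metric)
  wins <- sliding_week_windows(x, ...)
  y <- stats::setNames(x$meta$outcome, x$meta$sample_id)
  do.call(rbind, lapply(wins, function(g) {
    v <- mm[g$members, 1]
    arm <- y[g$members]
    data.frame(window = g$label, lo = attr(g, "lo"), hi = attr(g, "hi"),
               mean_term = mean(v[arm == "TERM"], na.rm = TRUE),
               mean_ptd = mean(v[arm == "PTD"], na.rm = TRUE),
               n_term = sum(arm == "TERM"), n_ptd = sum(arm == "PTD"),
               row.names = NULL, stringsAsFactors = FALSE)
  }))
}

#' Formatted cross-validation summary table
#'
#' Mean (SD) of the six evaluation parameters per metric, three decimals —
#' the printable counterpart of a [internal_cv()] summary.
#'
#' @param cv a `ptd_cv`.
#' @return character `data.frame`, one row per metric.
#' @export
crossval_table <- function(cv) {
  stopifnot(inherits(cv, "ptd_cv"))
  s <- cv$summary
  params <- c("accuracy", "sensitivity", "specificity", "ppv", "npv", "mcc")
  out <- data.frame(metric = s$metric, stringsAsFactors = FALSE)
  for (p in params)
    out[[p]] <- sprintf("%.3f (%.2f)", s[[paste0(p, "_mean")]],
                        s[[paste0(p, "_sd")]])
  out
}

#' Write an evaluation table as TSV + full-precision JSON pair
#' @param df any report `data.frame`.
#' @param path_tsv TSV output path (3-decimal numeric formatting is left to
#'   the caller; numbers are written in full precision here).
#' @param path_json JSON output path, or `NULL` to skip.
#' @export
write_report <- function(df, path_tsv, path_json = NULL) {
  utils::write.table(df, path_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(path_json))
    jsonlite::write_json(df, path_json, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", na = "null", pretty = TRUE)
  invisible(path_tsv)
}
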