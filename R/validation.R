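#' Configuration for repeated-holdout internal cross-validation
#'
#' Two-thirds of the samples form the training corpus on which the
#' MCC-optimal threshold is fitted; the frozen rule is then scored on the
#' remaining third. The split-fit-score cycle is repeated `n_iterations`
#' times. Splits are stratified by outcome by default, which guarantees
#' both classes in every train and test corpus; `stratified = FALSE` gives
#' the plain random split (single-class test corpora are then resampled,
#' up to a retry cap).
#'
#' @param train_fraction fraction of samples used for training (default 2/3).
#' @param n_iterations number of holdout repetitions (default 1000).
#' @param stratified stratify splits by outcome (default `TRUE`).
#' @param seed master RNG seed; iteration `i` uses the derived child seed
#'   `seed + i`, so any iteration is reproducible in isolation.
#' @param week_cutoff gestational-week cutoff defining the sample set
#'   (default 15; the companion analysis window is 20).
#' @export
cv_config <- function(train_fraction = 2 / 3, n_iterations = 1000,
                      stratified = TRUE, seed = 1, week_cutoff = 15) {
  stopifnot(train_fraction > 0, train_fraction < 1, n_iterations >= 1)
  structure(list(train_fraction = train_fraction,
                 n_iterations = n_iterations, stratified = stratified,
                 seed = as.integer(seed), week_cutoff = week_cutoff),
            class = "ptd_cv_config")
}

child_seed <- function(seed, i) (as.numeric(seed) + i) %% 2147483647

split_indices <- function(y, train_fraction, stratified, max_retry = 100) {
  n <- length(y)
  if (stratified) {
    tr <- unlist(lapply(split(seq_len(n), y), function(ix) {
      k <- max(1, min(length(ix) - 1, round(train_fraction * length(ix))))
      sample(ix, k)
    }), use.names = FALSE)
    return(sort(tr))
  }
  for (r in seq_len(max_retry)) {
    tr <- sort(sample(n, max(1, min(n - 1, round(train_fraction * n)))))
    if (length(unique(y[tr])) == 2 && length(unique(y[-tr])) == 2) return(tr)
    message("single-class split resampled (retry ", r, ")")
  }
  stop("could not draw a two-class split after ", max_retry, " retries")
}

#' Internal repeated-holdout cross-validation
#'
#' For every iteration and metric: fit the MCC-optimal threshold on the
#' training corpus, freeze it, and score it on the test corpus with the six
#' evaluation parameters (accuracy, sensitivity, specificity, PPV, NPV,
#' MCC). Per-metric summaries report the mean and standard deviation of
#' each parameter across iterations together with the mean fitted
#' threshold and the majority direction, which downstream external
#' validation transfers to unseen cohorts.
#'
#' @param x a `ptd_cohort` with metadata.
#' @param week_cutoff use only samples with `gestation_week <= week_cutoff`;
#'   defaults to the value in `config`.
#' @param metrics metric names (default all nine).
#' @param config a [cv_config()].
#' @param epsilon,tcs_variant,simpson_variant passed to [metric_matrix()].
#' @return object of class `ptd_cv`: `$iterations` (long per-iteration
#'   `data.frame`), `$summary` (one row per metric), `$config`.
#' @export
internal_cv <- function(x, week_cutoff = NULL, metrics = ptd_metrics(),
                        config = cv_config(), epsilon = 0.5,
                        tcs_variant = "default",
                        simpson_variant = "gini_simpson") {
  if (is.null(x$meta)) stop("cohort has no metadata")
  if (is.null(week_cutoff)) week_cutoff <- config$week_cutoff
  ids <- x$meta$sample_id[x$meta$gestation_week <= week_cutoff]
  if (!length(ids)) stop("no samples at or before week ", week_cutoff)
  sub <- subset_samples(x, ids)
  y <- sub$meta$outcome
  if (length(unique(y)) < 2)
    stop("both outcome classes must be present at week cutoff ", week_cutoff)
  mm <- metric_matrix(sub, metrics, epsilon, tcs_variant, simpson_variant)
  rows <- vector("list", config$n_iterations * length(metrics))
  k <- 0
  for (i in seq_len(config$n_iterations)) {
    set.seed(child_seed(config$seed, i))
    tr <- split_indices(y, config$train_fraction, config$stratified)
    te <- setdiff(seq_along(y), tr)
    for (met in metrics) {
      fit <- fit_best_threshold(mm[tr, met], y[tr], metric = met)
      cc <- confusion(fit$rule, mm[te, met], y[te])
      rep_row <- eval_report(cc)
      rep_row$es <- NULL
      rep_row <- cbind(data.frame(iteration = i, metric = met,
                                  threshold = fit$rule$threshold,
                                  direction = fit$rule$direction,
                                  stringsAsFactors = FALSE),
                       rep_row)
      k <- k + 1
      rows[[k]] <- rep_row
    }
  }
  iters <- do.call(rbind, rows)
  params <- c("mcc", "accuracy", "sensitivity", "specificity", "ppv", "npv")
  summ <- do.call(rbind, lapply(metrics, function(met) {
    d <- iters[iters$metric == met, , drop = FALSE]
    out <- data.frame(metric = met, stringsAsFactors = FALSE)
    for (p in params) {
      out[[paste0(p, "_mean")]] <- mean(d[[p]], na.rm = TRUE)
      out[[paste0(p, "_sd")]] <- stats::sd(d[[p]], na.rm = TRUE)
    }
    out$mean_threshold <- mean(d$threshold)
    maj <- names(sort(table(d$direction), decreasing = TRUE))[1]
    out$direction <- maj
    out$direction_disagreement <- mean(d$direction != maj)
    out
  }))
  rownames(summ) <- NULL
  structure(list(iterations = iters, summary = summ, config = config,
                 week_cutoff = week_cutoff), class = "ptd_cv")
}

#' @export
print.ptd_cv <- function(x, ...) {
  cat(sprintf("ptd_cv: %d iterations, week cutoff %g\n",
              x$config$n_iterations, x$week_cutoff))
  print(x$summary[, c("metric", "mcc_mean", "mcc_sd", "mean_threshold",
                      "direction")], digits = 3)
  invisible(x)
}

#' Frozen mean-threshold rules from a cross-validation result
#'
#' One rule per metric: the arithmetic mean of the per-iteration fitted
#' thresholds with the majority direction across iterations (the
#' disagreement rate is carried along).
#'
#' @param cv a `ptd_cv` object.
#' @return `data.frame` with columns `metric`, `threshold`, `direction`,
#'   `direction_disagreement`.
#' @export
mean_threshold_rules <- function(cv) {
  stopifnot(inherits(cv, "ptd_cv"))
  data.frame(metric = cv$summary$metric,
             threshold = cv$summary$mean_threshold,
             direction = cv$summary$direction,
             direction_disagreement = cv$summary$direction_disagreement,
             stringsAsFactors = FALSE)
}

#' External validation with frozen thresholds
#'
#' Applies the frozen mean-threshold rules (from [mean_threshold_rules()])
#' to an independent cohort and reports the six evaluation parameters per
#' metric. Parameters with empty denominators (e.g. no preterm samples in
#' the external cohort) are reported `NA`.
#'
#' @param rules `data.frame` with columns `metric`, `threshold`,
#'   `direction` (extra columns ignored).
#' @param x external `ptd_cohort` with metadata.
#' @param week_cutoff use samples with `gestation_week <= week_cutoff`.
#' @param epsilon,tcs_variant,simpson_variant passed to [metric_matrix()].
#' @return `data.frame`, one row per metric, Tables-style layout.
#' @export
external_validate <- function(rules, x, week_cutoff, epsilon = 0.5,
                              tcs_variant = "default",
                              simpson_variant = "gini_simpson") {
  need <- c("metric", "threshold", "direction")
  miss <- setdiff(need, colnames(rules))
  if (length(miss))
    stop("rules table missing field(s): ", paste(miss, collapse = ", "))
  if (is.null(x$meta)) stop("external cohort has no metadata")
  ids <- x$meta$sample_id[x$meta$gestation_week <= week_cutoff]
  if (!length(ids)) stop("external cohort empty at week cutoff ", week_cutoff)
  sub <- subset_samples(x, ids)
  mm <- metric_matrix(sub, rules$metric, epsilon, tcs_variant,
                      simpson_variant)
  y <- sub$meta$outcome
  out <- do.call(rbind, lapply(seq_len(nrow(rules)), function(i) {
    rule <- threshold_rule(rules$metric[i], rules$threshold[i],
                           rules$direction[i])
    cc <- confusion(rule, mm[, rule$metric], y)
    r <- eval_report(cc)
    r$es <- NULL
    cbind(data.frame(metric = rule$metric, threshold = rule$threshold,
                     direction = rule$direction, stringsAsFactors = FALSE), r)
  }))
  rownames(out) <- NULL
  out
}

# Exact null distribution of the signed-rank statistic (sum of positive
# signed ranks) as integer counts over 2*W, by generating-function DP.
# Handles tied (midpoint) ranks exactly, matching full 2^n enumeration.
signedrank_counts <- function(ranks2) {
  total <- sum(ranks2)
  f <- numeric(total + 1)
  f[1] <- 1
  for (r in ranks2) {
    g <- f
    g[(r + 1):(total + 1)] <- g[(r + 1):(total + 1)] + f[1:(total + 1 - r)]
    f <- g
  }
  f
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided test of symmetric paired differences about zero. Zero
#' differences are dropped (standard signed-rank convention). For n <= 25
#' nonzero differences the exact null distribution is used — computed by
#' dynamic programming over sign assignments, so tied absolute differences
#' (midpoint ranks) are handled exactly; for larger n a normal
#' approximation with continuity and tie correction applies. All
#' differences zero gives p = 1.
#'
#' @param a,b paired numeric vectors of equal length.
#' @param exact_max largest n for which the exact distribution is used.
#' @return two-sided p-value.
#' @export
wilcoxon_signed_rank <- function(a, b, exact_max = 25) {
  stopifnot(length(a) == length(b))
  d <- a - b
  d <- d[!is.na(d) & d != 0]
  n <- length(d)
  if (n == 0) return(1)
  if (n < 5) warning("fewer than 5 nonzero differences; p-value unstable")
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= exact_max) {
    r2 <- round(2 * r)
    f <- signedrank_counts(r2)
    w2 <- round(2 * W)
    p_le <- sum(f[seq_len(w2 + 1)]) / 2^n
    p_ge <- sum(f[(w2 + 1):length(f)]) / 2^n
    return(min(1, 2 * min(p_le, p_ge)))
  }
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' False-discovery-rate adjusted p-values (monotone, clipped at 1), via
#' [stats::p.adjust()].
#' @param p numeric vector of p-values in [0, 1].
#' @export
benjamini_hochberg <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}

#' Compare a reference metric's week-wise MCC against competitors
#'
#' Pairs the reference column against each competitor across the cumulative
#' week groups (weeks `week_min`..`week_cap`, 13 pairs by default), applies
#' the paired Wilcoxon signed-rank test, and Benjamini-Hochberg-adjusts the
#' p-values across competitors. The same machinery applies to any week-by-
#' metric value matrix, e.g. extent-of-segregation columns.
#'
#' @param tab `data.frame` with a `week` column and one numeric column per
#'   metric (a week-by-metric MCC matrix in tidy form).
#' @param reference reference metric column name (default `"tcs"`).
#' @param week_cap,week_min inclusive week range used for pairing
#'   (defaults 20 and 8).
#' @return `data.frame` with columns `metric`, `p`, `p_adj`, `direction`
#'   (sign of the mean paired difference reference - competitor).
#' @export
compare_metric_mcc_over_weeks <- function(tab, reference = "tcs",
                                          week_cap = 20, week_min = 8) {
  stopifnot("week" %in% colnames(tab), reference %in% colnames(tab))
  d <- tab[tab$week >= week_min & tab$week <= week_cap, , drop = FALSE]
  if (nrow(d) < 5) stop("fewer than 5 paired weeks in range")
  comp <- setdiff(colnames(d), c("week", reference))
  p <- vapply(comp, function(m)
    suppressWarnings(wilcoxon_signed_rank(d[[reference]], d[[m]])), 0)
  delta <- vapply(comp, function(m) mean(d[[reference]] - d[[m]]), 0)
  data.frame(metric = comp, p = p, p_adj = benjamini_hochberg(p),
             direction = ifelse(delta > 0, "higher",
                                ifelse(delta < 0, "lower", "equal")),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Compare per-iteration CV parameters against a reference metric
#'
#' For each evaluation parameter, pairs the reference metric's
#' per-iteration values with each competitor's (pairing by iteration) and
#' tests the paired difference with the Wilcoxon signed-rank test;
#' adjustment is Benjamini-Hochberg across competitors within each
#' parameter.
#'
#' @param cv a `ptd_cv` object.
#' @param reference reference metric (default `"tcs"`).
#' @return `data.frame` with columns `metric`, `parameter`, `p`, `p_adj`,
#'   `direction`.
#' @export
compare_cv_parameters <- function(cv, reference = "tcs") {
  stopifnot(inherits(cv, "ptd_cv"))
  it <- cv$iterations
  metrics <- setdiff(unique(it$metric), reference)
  if (!reference %in% it$metric) stop("reference metric not in CV result")
  params <- c("accuracy", "sensitivity", "specificity", "ppv", "npv", "mcc")
  ref <- it[it$metric == reference, , drop = FALSE]
  ref <- ref[order(ref$iteration), , drop = FALSE]
  out <- do.call(rbind, lapply(params, function(p) {
    rows <- do.call(rbind, lapply(metrics, function(m) {
      d <- it[it$metric == m, , drop = FALSE]
      d <- d[order(d$iteration), , drop = FALSE]
      ok <- stats::complete.cases(ref[[p]], d[[p]])
      pv <- suppressWarnings(wilcoxon_signed_rank(ref[[p]][ok], d[[p]][ok]))
      delta <- mean(ref[[p]][ok] - d[[p]][ok])
      data.frame(metric = m, parameter = p, p = pv,
                 direction = ifelse(delta > 0, "higher",
                                    ifelse(delta < 0, "lower", "equal")),
                 stringsAsFactors = FALSE)
    }))
    rows$p_adj <- benjamini_hochberg(rows$p)
    rows
  }))
  rownames(out) <- NULL
  out[, c("metric", "parameter", "p", "p_adj", "direction")]
}
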