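#' Threshold rules for preterm-delivery classification
#'
#' A rule predicts the preterm (PTD, positive) class from one metric value:
#' either values strictly below the threshold are called PTD
#' (`"ptd_if_below"`) or values at or above it are (`"ptd_if_above"`).
#' Values exactly at the threshold always fall on the above-or-equal side.
#'
#' @param metric metric name (see [ptd_metrics()]).
#' @param threshold numeric cut value.
#' @param direction `"ptd_if_below"` or `"ptd_if_above"`.
#' @export
threshold_rule <- function(metric, threshold,
                           direction = c("ptd_if_below", "ptd_if_above")) {
  direction <- match.arg(direction)
  stopifnot(is.numeric(threshold), length(threshold) == 1)
  structure(list(metric = metric, threshold = threshold,
                 direction = direction), class = "ptd_rule")
}

#' @export
print.ptd_rule <- function(x, ...) {
  cat(sprintf("rule: PTD if %s %s %g\n", x$metric,
              if (x$direction == "ptd_if_below") "<" else ">=", x$threshold))
  invisible(x)
}

#' @rdname threshold_rule
#' @param rule a `ptd_rule`.
#' @param values numeric metric values.
#' @return `apply_rule`: character vector of predicted labels (`NA` where
#'   the value is missing).
#' @export
apply_rule <- function(rule, values) {
  pred <- if (rule$direction == "ptd_if_below") values < rule$threshold
          else values >= rule$threshold
  ifelse(is.na(values), NA_character_, ifelse(pred, "PTD", "TERM"))
}

#' Confusion counts for a threshold rule
#'
#' PTD is the positive class throughout. Samples with missing metric values
#' are excluded from the counts and reported in `n_missing`.
#'
#' @param rule a `ptd_rule`.
#' @param values numeric metric values.
#' @param labels outcome labels aligned with `values` (any case; normalized
#'   to PTD/TERM).
#' @return list with integer fields `TP`, `TN`, `FP`, `FN`, `n_missing`.
#' @export
confusion <- function(rule, values, labels) {
  if (length(values) == 0) stop("empty input")
  stopifnot(length(values) == length(labels))
  labels <- normalize_outcome(labels)
  ok <- !is.na(values)
  pred <- apply_rule(rule, values[ok])
  y <- labels[ok]
  list(TP = sum(pred == "PTD" & y == "PTD"),
       TN = sum(pred == "TERM" & y == "TERM"),
       FP = sum(pred == "PTD" & y == "TERM"),
       FN = sum(pred == "TERM" & y == "PTD"),
       n_missing = sum(!ok))
}

#' Evaluation parameters from confusion counts
#'
#' `mcc` implements the Matthews correlation coefficient
#' \deqn{MCC = \frac{TP \cdot TN - FP \cdot FN}
#'   {\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}}
#' returning 0 when any factor of the denominator is zero. The remaining
#' parameters are the usual confusion-matrix ratios; a 0/0 ratio is
#' reported as `NA`.
#'
#' @param cc confusion counts (list with `TP`, `TN`, `FP`, `FN`).
#' @return a numeric scalar.
#' @export
mcc <- function(cc) {
  with(cc, {
    den <- as.numeric(TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
    if (den == 0) return(0)
    (as.numeric(TP) * TN - as.numeric(FP) * FN) / sqrt(den)
  })
}

ratio_or_na <- function(num, den) if (den == 0) NA_real_ else num / den

#' @rdname mcc
#' @export
accuracy <- function(cc)
  with(cc, ratio_or_na(TP + TN, TP + TN + FP + FN))

#' @rdname mcc
#' @export
sensitivity <- function(cc) with(cc, ratio_or_na(TP, TP + FN))

#' @rdname mcc
#' @export
specificity <- function(cc) with(cc, ratio_or_na(TN, TN + FP))

#' @rdname mcc
#' @export
ppv <- function(cc) with(cc, ratio_or_na(TP, TP + FP))

#' @rdname mcc
#' @export
npv <- function(cc) with(cc, ratio_or_na(TN, TN + FN))

#' Extent of segregation between term and preterm value sets
#'
#' For the sets of metric values of term (\eqn{D_{TD}}) and preterm
#' (\eqn{D_{PTD}}) samples, with \eqn{\delta(a,b) = |a-b|},
#' \deqn{ES = \frac{\min[\delta(\max D_{TD}, \min D_{PTD}),
#'   \delta(\max D_{PTD}, \min D_{TD})]}
#'   {\max[\delta(\max D_{TD}, \min D_{PTD}),
#'   \delta(\max D_{PTD}, \min D_{TD})]} \times 100.}
#' ES lies in [0, 100]; higher values indicate cleaner separation; it is
#' symmetric under swapping the two sets. `NA` when both gaps are zero
#' (all values identical).
#'
#' @param d_term,d_ptd numeric vectors of metric values for term and
#'   preterm samples; both must be non-empty.
#' @export
extent_of_segregation <- function(d_term, d_ptd) {
  if (!length(d_term) || !length(d_ptd))
    stop("both value sets must be non-empty")
  g1 <- abs(max(d_term) - min(d_ptd))
  g2 <- abs(max(d_ptd) - min(d_term))
  if (max(g1, g2) == 0) return(NA_real_)
  min(g1, g2) / max(g1, g2) * 100
}

#' One-row evaluation report from confusion counts
#' @param cc confusion counts.
#' @param es optional extent of segregation to attach.
#' @return `data.frame` with the six evaluation parameters, `es`, and the
#'   class sizes `n_ptd`/`n_term`.
#' @export
eval_report <- function(cc, es = NA_real_) {
  data.frame(n_ptd = cc$TP + cc$FN, n_term = cc$TN + cc$FP,
             mcc = mcc(cc), accuracy = accuracy(cc),
             sensitivity = sensitivity(cc), specificity = specificity(cc),
             ppv = ppv(cc), npv = npv(cc), es = es)
}

#' Fit the MCC-optimal threshold for one metric
#'
#' Scans every candidate threshold (midpoints between consecutive sorted
#' unique values, plus -Inf/+Inf sentinels) in both directions and returns
#' the rule maximizing MCC. Ties are broken deterministically: larger
#' extent of segregation, then smaller threshold, then `"ptd_if_below"`.
#' Midpoint candidates keep transferred thresholds in the interior of the
#' separating gap, which matters when a fitted rule is later applied to
#' external data.
#'
#' @param values numeric metric values (missing values are dropped and
#'   counted).
#' @param labels outcome labels aligned with `values`.
#' @param metric metric name recorded in the returned rule.
#' @return list with elements `rule` (a [threshold_rule()]) and `report`
#'   (an [eval_report()] row including `es`, `threshold`, `direction` and
#'   `n_missing`).
#' @export
fit_best_threshold <- function(values, labels, metric = "metric") {
  stopifnot(length(values) == length(labels))
  labels <- normalize_outcome(labels)
  ok <- !is.na(values)
  n_missing <- sum(!ok)
  v <- values[ok]
  y <- labels[ok]
  if (!length(v)) stop("no non-missing values")
  if (length(unique(y)) < 2) stop("both outcome classes must be present")
  u <- sort(unique(v))
  m <- length(u)
  cand <- c(-Inf, if (m > 1) (u[-m] + u[-1]) / 2, Inf)
  idx <- match(v, u)
  nP <- tabulate(idx[y == "PTD"], nbins = m)
  nT <- tabulate(idx[y == "TERM"], nbins = m)
  cumP <- c(0, cumsum(as.numeric(nP)))  # PTD count strictly below candidate
  cumT <- c(0, cumsum(as.numeric(nT)))
  P <- sum(nP); Tt <- sum(nT)
  mcc_vec <- function(TP, FP, TN, FN) {
    den <- (TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
    ifelse(den == 0, 0, (TP * TN - FP * FN) / sqrt(den))
  }
  # ptd_if_below: predict PTD when value < t
  mcc_below <- mcc_vec(cumP, cumT, Tt - cumT, P - cumP)
  # ptd_if_above: predict PTD when value >= t
  mcc_above <- mcc_vec(P - cumP, Tt - cumT, cumT, cumP)
  all_mcc <- c(mcc_below, mcc_above)
  all_thr <- c(cand, cand)
  all_dir <- rep(c("ptd_if_below", "ptd_if_above"), each = length(cand))
  best <- order(-all_mcc, all_thr, all_dir)[1]
  rule <- threshold_rule(metric, all_thr[best], all_dir[best])
  cc <- confusion(rule, v, y)
  es <- extent_of_segregation(v[y == "TERM"], v[y == "PTD"])
  rep_row <- eval_report(cc, es = es)
  rep_row$threshold <- rule$threshold
  rep_row$direction <- rule$direction
  rep_row$n_missing <- n_missing
  list(rule = rule, report = rep_row)
}
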