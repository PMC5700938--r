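#' Diversity and inequality measures on taxonomic abundance vectors
#'
#' Nine per-sample measures are available: three alpha-diversity indices
#' (Shannon, Simpson, Chao1), five econometric inequality indices applied
#' to the abundance vector (Gini, Atkinson, Theil, Ricci-Schutz, 90:10
#' decile ratio), and the taxonomic composition skew (TCS), a skewness
#' statistic of the abundance distribution. Apart from Chao1 (which needs
#' integer counts) every measure is scale invariant, so counts and relative
#' abundances give identical values. Inequality indices are computed over
#' the full vector, zero-abundance taxa included, mirroring inequality
#' measures on a fixed population; the decile ratio alone restricts to
#' nonzero abundances to avoid division by zero.
#'
#' @param x numeric vector of non-negative counts or relative abundances
#'   over the cohort's taxon universe.
#' @return a single numeric value.
#' @name diversity-metrics
NULL

check_profile <- function(x) {
  if (anyNA(x) || any(x < 0)) stop("abundances must be non-negative")
  if (sum(x) == 0) stop("zero-depth profile")
  x
}

#' @describeIn diversity-metrics Shannon entropy, natural log:
#'   \eqn{H = -\sum_i p_i \ln p_i} over nonzero relative abundances.
#' @export
shannon <- function(x) {
  p <- check_profile(x) / sum(x)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' @describeIn diversity-metrics Gini-Simpson evenness \eqn{1 - \sum_i p_i^2}
#'   (default), or its inverse form \eqn{1/\sum p_i^2}.
#' @param variant for `simpson`, `"gini_simpson"` (default) or `"inverse"`;
#'   for `tcs`, the name of a registered skew strategy (default `"default"`,
#'   the Fisher-Pearson moment skewness).
#' @export
simpson <- function(x, variant = c("gini_simpson", "inverse")) {
  variant <- match.arg(variant)
  p <- check_profile(x) / sum(x)
  D <- sum(p^2)
  if (variant == "gini_simpson") 1 - D else 1 / D
}

#' @describeIn diversity-metrics Bias-corrected Chao1 richness
#'   \eqn{S_{obs} + F_1(F_1-1)/(2(F_2+1))} with \eqn{F_1}/\eqn{F_2} the
#'   singleton/doubleton counts; requires integer counts; 0 for an empty
#'   profile.
#' @export
chao1 <- function(x) {
  if (anyNA(x) || any(x < 0)) stop("counts must be non-negative")
  if (any(abs(x - round(x)) > 1e-8))
    stop("chao1 requires integer counts, not relative abundances")
  x <- round(x)
  if (sum(x) == 0) return(0)
  f1 <- sum(x == 1)
  f2 <- sum(x == 2)
  sum(x > 0) + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' @describeIn diversity-metrics Gini coefficient, mean-absolute-difference
#'   form \eqn{\sum_{ij}|x_i-x_j| / (2 n^2 \mu)}, zeros included, no
#'   small-sample correction.
#' @export
gini <- function(x) {
  x <- check_profile(x)
  n <- length(x)
  xs <- sort(x)
  # identical to the O(n^2) pairwise sum, computed from the sorted vector
  2 * sum(seq_len(n) * xs) / (n * sum(xs)) - (n + 1) / n
}

#' @describeIn diversity-metrics Ricci-Schutz (Pietra) coefficient
#'   \eqn{\sum_i |x_i - \mu| / (2 n \mu)}.
#' @export
ricci_schutz <- function(x) {
  x <- check_profile(x)
  mu <- mean(x)
  sum(abs(x - mu)) / (2 * length(x) * mu)
}

#' @describeIn diversity-metrics Atkinson index with inequality-aversion
#'   `epsilon` (default 0.5):
#'   \eqn{1 - [\frac{1}{n}\sum_i x_i^{1-\epsilon}]^{1/(1-\epsilon)} / \mu}.
#'   At `epsilon = 1` the geometric-mean limit applies, and any zero
#'   abundance drives the index to 1 for `epsilon >= 1`.
#' @param epsilon inequality-aversion parameter, positive; default 0.5.
#' @export
atkinson <- function(x, epsilon = 0.5) {
  if (epsilon <= 0) stop("epsilon must be positive")
  x <- check_profile(x)
  mu <- mean(x)
  if (epsilon == 1) {
    if (any(x == 0)) return(1)
    return(1 - exp(mean(log(x))) / mu)
  }
  if (epsilon > 1 && any(x == 0)) return(1)
  1 - mean(x^(1 - epsilon))^(1 / (1 - epsilon)) / mu
}

#' @describeIn diversity-metrics Theil T index
#'   \eqn{\frac{1}{n}\sum_i (x_i/\mu)\ln(x_i/\mu)} with \eqn{0\ln 0 = 0}.
#' @export
theil <- function(x) {
  x <- check_profile(x)
  r <- x / mean(x)
  r <- r[r > 0]
  sum(r * log(r)) / length(x)
}

#' @describeIn diversity-metrics 90:10 decile ratio of the nonzero
#'   abundances (linear-interpolation quantiles); `NA` when fewer than two
#'   taxa are present.
#' @export
decile_ratio <- function(x) {
  x <- check_profile(x)
  nz <- x[x > 0]
  if (length(nz) < 2) return(NA_real_)
  q <- stats::quantile(nz, c(0.1, 0.9), names = FALSE, type = 7)
  q[2] / q[1]
}

.tcs_registry <- new.env(parent = emptyenv())

#' Register a taxonomic-composition-skew strategy
#'
#' TCS is a pluggable statistic: any function mapping a relative-abundance
#' vector to a scalar skew value can be registered under a variant name and
#' selected via the `variant` argument of [tcs()]. All threshold and
#' validation machinery is agnostic to the variant in use.
#'
#' @param name variant name.
#' @param fun function of one numeric argument (relative abundances summing
#'   to one over the taxon universe) returning a scalar.
#' @export
tcs_register_variant <- function(name, fun) {
  stopifnot(is.character(name), length(name) == 1, is.function(fun))
  assign(name, fun, envir = .tcs_registry)
  invisible(name)
}

tcs_default <- function(p) {
  d <- p - mean(p)
  m2 <- mean(d^2)
  if (m2 == 0) return(0)   # constant vector: no skew by convention
  mean(d^3) / m2^1.5
}

#' @describeIn diversity-metrics Taxonomic composition skew. The shipped
#'   `"default"` variant is the Fisher-Pearson moment skewness
#'   \eqn{g_1 = m_3 / m_2^{3/2}} of the full relative-abundance vector over
#'   the taxon universe (zeros included); 0 for a constant vector. Further
#'   variants can be added with [tcs_register_variant()].
#' @export
tcs <- function(x, variant = "default") {
  p <- check_profile(x) / sum(x)
  if (!exists(variant, envir = .tcs_registry, inherits = FALSE))
    stop("unknown TCS variant '", variant, "'; registered: ",
         paste(ls(.tcs_registry), collapse = ", "))
  get(variant, envir = .tcs_registry)(p)
}

#' Names of the nine supported metrics
#' @export
ptd_metrics <- function() {
  c("tcs", "shannon", "simpson", "chao1", "gini",
    "ricci_schutz", "atkinson", "theil", "decile_ratio")
}

metric_fun <- function(metric, epsilon = 0.5, tcs_variant = "default",
                       simpson_variant = "gini_simpson") {
  switch(metric,
    shannon      = shannon,
    simpson      = function(x) simpson(x, simpson_variant),
    chao1        = chao1,
    gini         = gini,
    ricci_schutz = ricci_schutz,
    atkinson     = function(x) atkinson(x, epsilon),
    theil        = theil,
    decile_ratio = decile_ratio,
    tcs          = function(x) tcs(x, tcs_variant),
    stop("unknown metric '", metric, "'"))
}

#' Compute all metrics for every sample of a cohort
#'
#' @param x a `ptd_cohort`.
#' @param metrics character vector of metric names (default all nine).
#' @param epsilon Atkinson inequality aversion (default 0.5).
#' @param tcs_variant TCS strategy name (default `"default"`).
#' @param simpson_variant `"gini_simpson"` (default) or `"inverse"`.
#' @return `compute_all_metrics`: long `data.frame` with columns
#'   `sample_id`, `metric`, `value`; `metric_matrix`: samples-by-metrics
#'   numeric matrix. Undefined values (e.g. the decile ratio of a
#'   single-taxon sample) are `NA` and are excluded pairwise downstream.
#' @export
compute_all_metrics <- function(x, metrics = ptd_metrics(), epsilon = 0.5,
                                tcs_variant = "default",
                                simpson_variant = "gini_simpson") {
  m <- metric_matrix(x, metrics, epsilon, tcs_variant, simpson_variant)
  data.frame(sample_id = rep(rownames(m), times = ncol(m)),
             metric = rep(colnames(m), each = nrow(m)),
             value = as.vector(m), stringsAsFactors = FALSE)
}

#' @rdname compute_all_metrics
#' @export
metric_matrix <- function(x, metrics = ptd_metrics(), epsilon = 0.5,
                          tcs_variant = "default",
                          simpson_variant = "gini_simpson") {
  if (ncol(x$counts) == 0) stop("empty cohort")
  bad <- setdiff(metrics, ptd_metrics())
  if (length(bad)) stop("unknown metric(s): ", paste(bad, collapse = ", "))
  out <- matrix(NA_real_, ncol(x$counts), length(metrics),
                dimnames = list(sample_ids(x), metrics))
  for (met in metrics) {
    f <- metric_fun(met, epsilon, tcs_variant, simpson_variant)
    out[, met] <- apply(x$counts, 2, f)
  }
  out
}

#' Export metric values as long-format TSV
#' @param values long `data.frame` from [compute_all_metrics()].
#' @param path output path.
#' @export
write_metric_table <- function(values, path) {
  utils::write.table(values, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Rarefy a cohort to even depth
#'
#' Optional preprocessor: subsamples each profile without replacement to a
#' common depth (profiles below the target are dropped). Off by default in
#' all pipelines; provided for users who want depth-standardized indices.
#'
#' @param x a `ptd_cohort`.
#' @param depth target depth; default the minimum observed depth.
#' @param seed integer seed for the subsampling RNG.
#' @export
rarefy_cohort <- function(x, depth = min(sample_depths(x)), seed = 1) {
  keep <- sample_depths(x) >= depth
  if (any(!keep)) message(sum(!keep), " sample(s) below depth ", depth,
                          " dropped before rarefaction")
  x <- subset_samples(x, sample_ids(x)[keep])
  set.seed(seed)
  x$counts <- apply(x$counts, 2, function(cnt) {
    picked <- sample(rep.int(seq_along(cnt), cnt), depth)
    tabulate(picked, nbins = length(cnt))
  })
  rownames(x$counts) <- taxon_ids(x)
  x
}
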