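# Shared fixtures: tiny hand-built cohorts plus memoized expensive objects
# (default synthetic cohort, its sweep and CV) reused across test files.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache, inherits = FALSE))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

tiny_counts <- function() {
  m <- matrix(c(5L, 3L, 2L,
                10L, 6L, 4L), nrow = 3,
              dimnames = list(c("OTU_A", "OTU_B", "OTU_C"), c("s1", "s2")))
  m
}

tiny_meta <- function(ids = c("s1", "s2"),
                      weeks = c(10, 20),
                      outcomes = c("PTD", "TERM")) {
  data.frame(sample_id = ids, subject_id = paste0("subj_", ids),
             study_id = "toy", gestation_week = weeks, outcome = outcomes,
             stringsAsFactors = FALSE)
}

# random small cohort with explicit weeks/outcomes, for grouping tests
random_cohort <- function(n = 20, n_taxa = 10, seed = 1) {
  set.seed(seed)
  m <- matrix(rpois(n * n_taxa, 30), nrow = n_taxa,
              dimnames = list(sprintf("OTU_%02d", 1:n_taxa),
                              sprintf("s%02d", 1:n)))
  meta <- data.frame(sample_id = colnames(m),
                     subject_id = sprintf("subj%02d", sample(1:8, n, TRUE)),
                     study_id = "rand",
                     gestation_week = round(runif(n, 4, 40), 2),
                     outcome = sample(c("PTD", "TERM"), n, TRUE),
                     stringsAsFactors = FALSE)
  cohort(m, meta)
}

default_cohort <- function()
  memo("default_cohort", generate_cohort(synthetic_config()))

default_sweep <- function()
  memo("default_sweep", week_sweep(default_cohort()))

default_cv <- function()
  memo("default_cv",
       internal_cv(default_cohort(), week_cutoff = 15,
                   config = cv_config(n_iterations = 100, seed = 2)))

# brute-force oracles ------------------------------------------------------

gini_pairwise <- function(x) {
  n <- length(x)
  s <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) s <- s + abs(x[i] - x[j])
  s / (2 * n^2 * mean(x))
}

mcc_arith <- function(TP, TN, FP, FN) {
  den <- sqrt(TP + FP) * sqrt(TP + FN) * sqrt(TN + FP) * sqrt(TN + FN)
  if (den == 0) 0 else (TP * TN - FP * FN) / den
}

# exhaustive best-threshold scan: every observed value as cut, both
# directions, per-sample confusion loop
best_mcc_exhaustive <- function(v, y) {
  best <- -2
  for (t in c(v, -Inf, Inf)) for (dir in c("ptd_if_below", "ptd_if_above")) {
    TP <- TN <- FP <- FN <- 0
    for (k in seq_along(v)) {
      pred <- if (dir == "ptd_if_below") v[k] < t else v[k] >= t
      if (pred && y[k] == "PTD") TP <- TP + 1
      else if (pred && y[k] == "TERM") FP <- FP + 1
      else if (!pred && y[k] == "PTD") FN <- FN + 1
      else TN <- TN + 1
    }
    best <- max(best, mcc_arith(TP, TN, FP, FN))
  }
  best
}

# exact signed-rank p by full 2^n sign-pattern enumeration
wilcoxon_enum <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Wall <- as.vector(signs %*% r)
  p_le <- mean(Wall <= W + 1e-12)
  p_ge <- mean(Wall >= W - 1e-12)
  min(1, 2 * min(p_le, p_ge))
}

bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in m:1) {
    val <- min(prev, m * p[o[i]] / i)
    adj[o[i]] <- val
    prev <- val
  }
  pmin(adj, 1)
}
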