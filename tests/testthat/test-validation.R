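test_that("signed-rank p-values match exhaustive sign-pattern enumeration", {
  a <- c(5, 3, 8, 1, 9, 4, 7, 2, 6, 10)
  expect_equal(wilcoxon_signed_rank(a + 1, a), 2 / 2^10, tolerance = 1e-12)
  expect_equal(wilcoxon_signed_rank(a, a), 1)

  set.seed(55)
  for (i in 1:200) {
    n <- sample(5:10, 1)
    a <- rnorm(n)
    b <- rnorm(n)
    if (i %% 3 == 0) b <- a + round(rnorm(n), 1)   # induce tied |d| and zeros
    expect_equal(suppressWarnings(wilcoxon_signed_rank(a, b)),
                 wilcoxon_enum(a, b), tolerance = 1e-9)
  }

  # agrees with stats::wilcox.test when the exact path is available there
  set.seed(56)
  a <- rnorm(12); b <- rnorm(12)
  expect_equal(wilcoxon_signed_rank(a, b),
               wilcox.test(a, b, paired = TRUE, exact = TRUE)$p.value,
               tolerance = 1e-12)
  # large-n path is a sane approximation of the exact value
  set.seed(57)
  a <- rnorm(40); b <- rnorm(40, 0.2)
  expect_equal(wilcoxon_signed_rank(a, b),
               wilcox.test(a, b, paired = TRUE, exact = FALSE,
                           correct = TRUE)$p.value,
               tolerance = 1e-9)
})

test_that("Benjamini-Hochberg matches the step-up formula and its invariants", {
  expect_equal(benjamini_hochberg(0.03), 0.03)
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(61)
  for (i in 1:200) {
    p <- runif(sample(1:20, 1))
    adj <- benjamini_hochberg(p)
    expect_equal(adj, bh_stepup(p), tolerance = 1e-9)
    expect_true(all(adj >= p - 1e-12))
    expect_true(all(adj <= 1))
    perm <- sample(length(p))
    expect_equal(benjamini_hochberg(p[perm]), adj[perm], tolerance = 1e-12)
  }
})

test_that("internal CV is deterministic, split-invariant on separable data", {
  # complete class separation on every metric value: mean MCC 1, SD 0
  m <- matrix(0L, 3, 30, dimnames = list(paste0("OTU_", 1:3),
                                         sprintf("s%02d", 1:30)))
  out <- rep(c("PTD", "TERM"), c(8, 22))
  m[1, ] <- ifelse(out == "PTD", 980L, 400L)
  m[2, ] <- ifelse(out == "PTD", 15L, 300L)
  m[3, ] <- ifelse(out == "PTD", 5L, 300L)
  m <- m + matrix(sample(0:5, 90, TRUE), 3)
  coh <- cohort(m, tiny_meta(sprintf("s%02d", 1:30), rep(10, 30), out))
  cv <- internal_cv(coh, 15, metrics = c("shannon", "gini"),
                    config = cv_config(n_iterations = 10, seed = 9))
  expect_equal(cv$summary$mcc_mean, c(1, 1))
  expect_equal(cv$summary$mcc_sd, c(0, 0))

  cv2 <- internal_cv(coh, 15, metrics = c("shannon", "gini"),
                     config = cv_config(n_iterations = 10, seed = 9))
  expect_identical(cv, cv2)
})

test_that("CV test-mean MCC agrees with an independent re-implementation", {
  coh <- generate_cohort(synthetic_config(
    n_subjects = 60, evenness_alpha_ptd_early = 0.03, seed = 14))
  cfg <- cv_config(n_iterations = 50, seed = 3)
  cv <- internal_cv(coh, 15, metrics = "shannon", config = cfg)

  # second, straightforward implementation of the same loop
  ids <- coh$meta$sample_id[coh$meta$gestation_week <= 15]
  sub <- subset_samples(coh, ids)
  v <- metric_matrix(sub, "shannon")[, 1]
  y <- sub$meta$outcome
  ref <- sapply(seq_len(50), function(i) {
    set.seed((3 + i) %% 2147483647)
    tr <- sort(unlist(lapply(split(seq_along(y), y), function(ix)
      sample(ix, max(1, min(length(ix) - 1, round(2 / 3 * length(ix))))))))
    te <- setdiff(seq_along(y), tr)
    fit <- fit_best_threshold(v[tr], y[tr])
    mcc(confusion(fit$rule, v[te], y[te]))
  })
  expect_equal(cv$summary$mcc_mean, mean(ref), tolerance = 1e-12)
  # and the summary is recomputable from the per-iteration rows
  expect_equal(cv$summary$mcc_sd, sd(cv$iterations$mcc), tolerance = 1e-12)
  expect_equal(cv$summary$mean_threshold, mean(cv$iterations$threshold),
               tolerance = 1e-12)
})

test_that("stratified splits always contain both classes in train and test", {
  y <- rep(c("PTD", "TERM"), c(6, 40))
  for (i in 1:50) {
    set.seed(i)
    tr <- ptdiv:::split_indices(y, 2 / 3, stratified = TRUE)
    expect_setequal(unique(y[tr]), c("PTD", "TERM"))
    expect_setequal(unique(y[-tr]), c("PTD", "TERM"))
  }
})

test_that("frozen rules transfer to external data as expected", {
  # a frozen perfect rule on a same-generator external cohort: all six = 1
  rules <- data.frame(metric = "shannon", threshold = 0.96,
                      direction = "ptd_if_below")
  coh <- generate_cohort(synthetic_config(n_subjects = 60, seed = 15))
  er <- external_validate(rules, coh, 10)
  expect_equal(unlist(er[, c("mcc", "accuracy", "sensitivity",
                             "specificity", "ppv", "npv")]),
               rep(1, 6), ignore_attr = TRUE)

  # label-independent values: accuracy tends to the majority-class share
  set.seed(66)
  n <- 4000
  m <- matrix(rpois(2 * n, 50) + 1L, nrow = 2,
              dimnames = list(c("OTU_1", "OTU_2"), sprintf("s%04d", 1:n)))
  out <- sample(c("PTD", "TERM"), n, TRUE, prob = c(0.2, 0.8))
  coh0 <- cohort(m, tiny_meta(sprintf("s%04d", 1:n), rep(10, n), out))
  er0 <- external_validate(data.frame(metric = "shannon", threshold = 0.5,
                                      direction = "ptd_if_below"),
                           coh0, 15)
  expect_equal(er0$accuracy, mean(out == "TERM"), tolerance = 0.05)

  expect_error(external_validate(rules[, c("metric", "threshold")], coh, 10),
               "direction")
  expect_error(external_validate(rules, coh, 2), "empty")
})

test_that("week-wise metric comparison flags a dominating reference", {
  set.seed(91)
  weeks <- 8:20
  tab <- data.frame(week = weeks, tcs = 0.9 - 0.01 * seq_along(weeks))
  for (m in paste0("m", 1:8))
    tab[[m]] <- tab$tcs - runif(length(weeks), 0.05, 0.2)
  res <- compare_metric_mcc_over_weeks(tab, "tcs", week_cap = 20)
  expect_equal(nrow(res), 8)
  expect_true(all(res$p_adj < 0.05))
  expect_true(all(res$direction == "higher"))
  # a strict one-sided sweep of 13 pairs has exact two-sided p = 2/2^13
  expect_equal(res$p, rep(2 / 2^13, 8), tolerance = 1e-12)

  tab$m1 <- tab$tcs
  res2 <- compare_metric_mcc_over_weeks(tab, "tcs")
  expect_equal(res2$p[res2$metric == "m1"], 1)

  perm <- sample(nrow(tab))
  res3 <- compare_metric_mcc_over_weeks(tab[perm, ], "tcs")
  expect_equal(res3$p, res2$p, tolerance = 1e-12)

  expect_error(compare_metric_mcc_over_weeks(tab[1:3, ], "tcs"), "fewer")
})

test_that("per-iteration CV comparison favors the better metric", {
  coh <- generate_cohort(synthetic_config(n_subjects = 80, seed = 23))
  cv <- internal_cv(coh, 15, metrics = c("shannon", "decile_ratio"),
                    config = cv_config(n_iterations = 40, seed = 6))
  cmp <- compare_cv_parameters(cv, reference = "shannon")
  expect_equal(nrow(cmp), 6)
  row <- cmp[cmp$parameter == "mcc", ]
  expect_equal(row$direction, "higher")
  expect_lt(row$p_adj, 0.01)
  expect_true(all(cmp$p_adj >= cmp$p - 1e-12))
})
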