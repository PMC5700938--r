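test_that("TSV count tables read with correct depths and round-trip exactly", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("#OTU_ID\ts1\ts2",
               "OTU_A\t5\t10",
               "OTU_B\t3\t6",
               "OTU_C\t2\t4"), path)
  coh <- read_count_table(path)
  expect_equal(unname(sample_depths(coh)), c(10, 20))
  expect_equal(taxon_ids(coh), c("OTU_A", "OTU_B", "OTU_C"))

  out <- withr::local_tempfile(fileext = ".tsv")
  write_count_table(coh, out)
  coh2 <- read_count_table(out)
  expect_identical(coh2$counts, coh$counts)

  # generated cohort round-trip is bit exact for integer tables
  g <- generate_cohort(synthetic_config(n_subjects = 5, seed = 11))
  write_count_table(g, out)
  expect_identical(read_count_table(out)$counts, g$counts)
})

test_that("malformed count tables are rejected with the offending cell named", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("#OTU_ID\ts1\ts2", "OTU_A\t5\tx7", "OTU_B\t3\t6"), path)
  expect_error(read_count_table(path), "OTU_A.*s2")

  writeLines(c("#OTU_ID\ts1\ts2", "OTU_A\t5\t-1", "OTU_B\t3\t6"), path)
  expect_error(read_count_table(path), "negative count.*OTU_A.*s2")

  writeLines(c("#OTU_ID\ts1\ts1", "OTU_A\t5\t7"), path)
  expect_error(read_count_table(path), "duplicate sample ids")

  expect_error(read_count_table(file.path(tempdir(), "nope.tsv")),
               "not found")
})

test_that("metadata joins by sample id with case-normalized outcomes", {
  coh <- cohort(tiny_counts())
  meta <- tiny_meta(outcomes = c("preterm", "full-term"))
  coh <- attach_metadata(coh, meta)
  expect_equal(coh$meta$outcome, c("PTD", "TERM"))
  expect_equal(coh$meta$sample_id, c("s1", "s2"))

  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(meta, path, row.names = FALSE)
  coh2 <- attach_metadata(cohort(tiny_counts()), path)
  expect_identical(coh2$meta, coh$meta)

  expect_error(attach_metadata(cohort(tiny_counts()),
                               tiny_meta("s1", 10, "PTD")),
               "missing column|without metadata")
  expect_error(attach_metadata(cohort(tiny_counts()),
                               tiny_meta(outcomes = c("early", "TERM"))),
               "unrecognized outcome")
  bad <- tiny_meta(); bad$gestation_week <- c("ten", "20")
  expect_error(attach_metadata(cohort(tiny_counts()), bad),
               "non-numeric gestation_week.*s1")
  orphan <- tiny_meta()[1, , drop = FALSE]
  expect_error(attach_metadata(cohort(tiny_counts()), orphan),
               "without metadata: s2")
})

test_that("minimum-depth filter keeps the inclusive 500-read boundary and is idempotent", {
  m <- matrix(c(499L, 500L, 501L), nrow = 1,
              dimnames = list("OTU_A", c("a", "b", "c")))
  coh <- cohort(m, tiny_meta(c("a", "b", "c"), c(8, 9, 10),
                             c("PTD", "TERM", "TERM")))
  expect_message(f <- filter_min_depth(coh), "1 sample")
  expect_equal(sample_ids(f), c("b", "c"))
  expect_identical(filter_min_depth(f)$counts, f$counts)
  expect_equal(sample_ids(filter_min_depth(coh, 0)), c("a", "b", "c"))

  # brute-force count on random depths
  set.seed(7)
  depths <- sample(0:1000, 100, replace = TRUE)
  m2 <- matrix(depths, nrow = 1,
               dimnames = list("OTU_A", sprintf("r%03d", 1:100)))
  coh2 <- cohort(m2)
  expect_equal(ncol(suppressMessages(filter_min_depth(coh2))$counts),
               sum(depths >= 500))
})

test_that("cumulative week groups are inclusive, nested and monotone", {
  coh <- cohort(matrix(1L, 1, 4, dimnames = list("OTU_A", paste0("s", 1:4))),
                tiny_meta(paste0("s", 1:4), c(8, 12, 19, 25),
                          c("PTD", "TERM", "TERM", "PTD")))
  g <- cumulative_week_groups(coh, 8, 40)
  expect_length(g, 33)
  expect_setequal(g[["Week_15"]]$members, c("s1", "s2"))
  expect_setequal(g[["Week_40"]]$members, paste0("s", 1:4))
  expect_setequal(g[["Week_8"]]$members, "s1")

  rc <- random_cohort(40, seed = 3)
  gr <- cumulative_week_groups(rc, 8, 40)
  sizes <- vapply(gr, function(x) length(x$members), 0L)
  expect_true(all(diff(sizes) >= 0))
  for (i in seq_len(length(gr) - 1))
    expect_true(all(gr[[i]]$members %in% gr[[i + 1]]$members))
  for (g1 in gr)
    expect_true(all(rc$meta$gestation_week[
      match(g1$members, rc$meta$sample_id)] <=
        as.numeric(sub("Week_", "", g1$label))))
})

test_that("per-subject grouping keeps one latest sample per subject", {
  meta <- data.frame(sample_id = paste0("s", 1:4),
                     subject_id = c("A", "A", "B", "B"), study_id = "t",
                     gestation_week = c(8, 12, 9, 30),
                     outcome = c("PTD", "PTD", "TERM", "TERM"))
  coh <- cohort(matrix(1L, 1, 4,
                       dimnames = list("OTU_A", paste0("s", 1:4))), meta)
  g <- cumulative_week_groups(coh, 15, 15, per_subject = TRUE)
  expect_setequal(g[["Week_15"]]$members, c("s2", "s3"))
})

test_that("sliding windows overlap, cover the range, and share samples", {
  rc <- random_cohort(30, seed = 9)
  rc$meta$gestation_week <- c(1, 40, runif(28, 1, 40))
  w <- sliding_week_windows(rc, n_windows = 15, width = 6, step = 2.5,
                            start = 1)
  expect_length(w, 15)
  expect_equal(attr(w[[1]], "lo"), 1)
  expect_equal(attr(w[[1]], "hi"), 7)
  expect_gte(attr(w[[15]], "hi"), 40)

  coh <- cohort(matrix(1L, 1, 1, dimnames = list("OTU_A", "s1")),
                tiny_meta("s1", 10, "TERM"))
  w2 <- sliding_week_windows(coh, n_windows = 2, width = 6, step = 2,
                             start = 8)
  expect_true(all(vapply(w2, function(g) "s1" %in% g$members, TRUE)))

  expect_error(sliding_week_windows(rc, width = 2, step = 2.5), "overlap")
  expect_error(sliding_week_windows(rc, n_windows = 3, width = 2,
                                    step = 1, start = 1), "cannot cover")
})

test_that("BIOM v1 tables load when biomformat is available", {
  skip_if_not_installed("biomformat")
  g <- generate_cohort(synthetic_config(n_subjects = 3, seed = 5))
  b <- biomformat::make_biom(g$counts)
  path <- withr::local_tempfile(fileext = ".biom")
  biomformat::write_biom(b, path)
  coh <- read_count_table(path, format = "biom")
  expect_equal(coh$counts[taxon_ids(g), sample_ids(g)], g$counts)
})
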