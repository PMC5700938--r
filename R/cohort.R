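#' Construct a cohort of taxonomic profiles
#'
#' A cohort bundles an OTU-level count matrix (taxa as rows, samples as
#' columns, shared taxon universe) with optional per-sample metadata
#' (subject, study, gestational week at sampling, delivery outcome).
#'
#' @param counts numeric matrix of non-negative counts; rownames are OTU
#'   identifiers, colnames are sample identifiers.
#' @param meta optional `data.frame` with columns `sample_id`, `subject_id`,
#'   `study_id`, `gestation_week`, `outcome` (one row per sample, same order
#'   not required).
#' @return an object of class `ptd_cohort`.
#' @export
cohort <- function(counts, meta = NULL) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("count matrix must carry taxon rownames and sample colnames")
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]),
               collapse = ", "))
  if (anyDuplicated(rownames(counts)))
    stop("duplicate taxon ids in count table")
  if (anyNA(counts)) stop("count matrix contains missing values")
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative count at row '%s', column '%s'",
                 rownames(counts)[bad[1]], colnames(counts)[bad[2]]))
  }
  obj <- structure(list(counts = counts, meta = NULL), class = "ptd_cohort")
  if (!is.null(meta)) obj <- attach_metadata(obj, meta)
  obj
}

#' @export
print.ptd_cohort <- function(x, ...) {
  cat(sprintf("ptd_cohort: %d taxa x %d samples%s\n",
              nrow(x$counts), ncol(x$counts),
              if (is.null(x$meta)) " (no metadata)" else ""))
  if (!is.null(x$meta)) {
    tab <- table(x$meta$outcome)
    cat(sprintf("  outcomes: %s; gestation weeks %.1f-%.1f\n",
                paste(names(tab), tab, sep = "=", collapse = ", "),
                min(x$meta$gestation_week), max(x$meta$gestation_week)))
  }
  invisible(x)
}

#' @rdname cohort
#' @param x a `ptd_cohort`.
#' @export
sample_ids <- function(x) colnames(x$counts)

#' @rdname cohort
#' @export
taxon_ids <- function(x) rownames(x$counts)

#' Total assigned reads per sample
#' @param x a `ptd_cohort`.
#' @return named integer vector of per-sample depths (column sums).
#' @export
sample_depths <- function(x) colSums(x$counts)

#' Relative-abundance matrix of a cohort
#'
#' Columns are scaled to sum to one; zero-depth samples are not allowed.
#' @param x a `ptd_cohort`.
#' @export
rel_abundance <- function(x) {
  d <- sample_depths(x)
  if (any(d == 0))
    stop("zero-depth sample(s): ",
         paste(names(d)[d == 0], collapse = ", "))
  sweep(x$counts, 2, d, "/")
}

outcome_levels <- c("PTD", "TERM")

normalize_outcome <- function(x) {
  z <- toupper(trimws(as.character(x)))
  z[z %in% c("TERM", "FULL-TERM", "FULLTERM", "FULL TERM", "TD")] <- "TERM"
  z[z %in% c("PTD", "PRETERM", "PRE-TERM", "PRE TERM")] <- "PTD"
  bad <- !(z %in% outcome_levels)
  if (any(bad))
    stop("unrecognized outcome value(s): ",
         paste(unique(x[bad]), collapse = ", "),
         " (expected TERM/full-term or PTD/preterm)")
  z
}

#' Read an OTU count table
#'
#' Reads a taxa-by-samples table. The TSV dialect is BIOM-classic
#' compatible: first header cell `#OTU_ID`, remaining header cells are
#' sample ids, first column holds OTU identifiers. BIOM v1 (JSON) files are
#' supported through the `biomformat` package when installed.
#'
#' @param path path to the table.
#' @param format `"tsv"` (default) or `"biom"`.
#' @return a `ptd_cohort` without metadata.
#' @export
read_count_table <- function(path, format = c("tsv", "biom")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop("BIOM input requires the 'biomformat' package")
    b <- biomformat::read_biom(path)
    m <- as.matrix(biomformat::biom_data(b))
    return(cohort(m))
  }
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, comment.char = "",
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(raw) < 2) stop("count table needs an OTU id column plus samples")
  taxa <- raw[[1]]
  samples <- colnames(raw)[-1]
  mat <- matrix(NA_real_, nrow(raw), length(samples),
                dimnames = list(taxa, samples))
  for (j in seq_along(samples)) {
    col <- raw[[j + 1]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num) & !is.na(col))
    if (length(bad))
      stop(sprintf("unparseable numeric cell '%s' at row '%s', column '%s'",
                   col[bad[1]], taxa[bad[1]], samples[j]))
    mat[, j] <- num
  }
  if (all(mat == round(mat)) && max(mat) < .Machine$integer.max)
    storage.mode(mat) <- "integer"
  cohort(mat)
}

#' Write an OTU count table as BIOM-classic TSV
#'
#' Inverse of [read_count_table()]: integer tables round-trip bit-exactly.
#' @param x a `ptd_cohort`.
#' @param path output path.
#' @export
write_count_table <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("#OTU_ID", colnames(x$counts)), collapse = "\t"), con)
  body <- apply(x$counts, 1, function(r)
    paste(format(r, scientific = FALSE, trim = TRUE), collapse = "\t"))
  writeLines(paste(rownames(x$counts), body, sep = "\t"), con)
  invisible(path)
}

#' Attach per-sample metadata to a cohort
#'
#' Metadata must provide `sample_id`, `subject_id`, `study_id`,
#' `gestation_week` and `outcome`. Outcomes are normalized
#' case-insensitively: term/full-term map to `TERM`, ptd/preterm to `PTD`.
#' Every profile must be matched; metadata rows without a profile are
#' dropped with a warning.
#'
#' @param x a `ptd_cohort`.
#' @param meta a `data.frame` or a path to a CSV file.
#' @return the cohort with `$meta` aligned to the count-matrix columns.
#' @export
attach_metadata <- function(x, meta) {
  if (is.character(meta)) {
    if (!file.exists(meta)) stop("metadata file not found: ", meta)
    meta <- utils::read.csv(meta, stringsAsFactors = FALSE)
  }
  need <- c("sample_id", "subject_id", "study_id", "gestation_week", "outcome")
  miss <- setdiff(need, colnames(meta))
  if (length(miss)) stop("metadata missing column(s): ",
                         paste(miss, collapse = ", "))
  meta$sample_id <- as.character(meta$sample_id)
  if (anyDuplicated(meta$sample_id))
    stop("duplicate sample_id in metadata")
  gw <- suppressWarnings(as.numeric(meta$gestation_week))
  if (anyNA(gw)) stop("non-numeric gestation_week for sample(s): ",
                      paste(meta$sample_id[is.na(gw)], collapse = ", "))
  if (any(gw <= 0) || any(gw > 45))
    stop("gestation_week must lie in (0, 45] weeks")
  meta$gestation_week <- gw
  meta$outcome <- normalize_outcome(meta$outcome)
  orphan <- setdiff(sample_ids(x), meta$sample_id)
  if (length(orphan))
    stop("profiles without metadata: ", paste(orphan, collapse = ", "))
  extra <- setdiff(meta$sample_id, sample_ids(x))
  if (length(extra))
    warning(length(extra), " metadata row(s) without a profile dropped: ",
            paste(utils::head(extra, 5), collapse = ", "))
  meta <- meta[match(sample_ids(x), meta$sample_id), need, drop = FALSE]
  rownames(meta) <- NULL
  x$meta <- meta
  x
}

#' Apply the minimum-depth inclusion filter
#'
#' Retains samples with at least `min_reads` taxonomically assigned
#' sequences (depth, i.e. column sum). The default of 500 reads is the
#' customary inclusion threshold for these vaginal-microbiome profiles;
#' the boundary is inclusive.
#'
#' @param x a `ptd_cohort`.
#' @param min_reads non-negative integer, default 500.
#' @export
filter_min_depth <- function(x, min_reads = 500) {
  stopifnot(min_reads >= 0)
  keep <- sample_depths(x) >= min_reads
  removed <- sum(!keep)
  if (removed) message(removed, " sample(s) below ", min_reads,
                       " reads removed")
  x$counts <- x$counts[, keep, drop = FALSE]
  if (!is.null(x$meta)) {
    x$meta <- x$meta[keep, , drop = FALSE]
    rownames(x$meta) <- NULL
  }
  x
}

#' Subset a cohort by sample id
#' @param x a `ptd_cohort`.
#' @param ids sample ids to keep (order preserved as given).
#' @export
subset_samples <- function(x, ids) {
  miss <- setdiff(ids, sample_ids(x))
  if (length(miss)) stop("unknown sample id(s): ", paste(miss, collapse = ", "))
  x$counts <- x$counts[, ids, drop = FALSE]
  if (!is.null(x$meta)) {
    x$meta <- x$meta[match(ids, x$meta$sample_id), , drop = FALSE]
    rownames(x$meta) <- NULL
  }
  x
}

week_group <- function(label, members) {
  structure(list(label = label, members = members), class = "ptd_week_group")
}

#' @export
print.ptd_week_group <- function(x, ...) {
  cat(sprintf("%s: %d samples\n", x$label, length(x$members)))
  invisible(x)
}

#' Cumulative gestational-week sample groups
#'
#' Group `Week_N` contains every sample collected at any time point on or
#' before the Nth gestational week (inclusive boundary; fractional weeks
#' allowed). Groups are nested: `Week_N` is a subset of `Week_(N+1)`.
#'
#' @param x a `ptd_cohort` with metadata.
#' @param n_min,n_max integer week bounds (defaults 8 and 40 give 33 groups).
#' @param per_subject if `TRUE`, keep only each subject's latest sample at or
#'   before week N (a leakage-averse alternative to the default per-sample
#'   grouping).
#' @return a named list of `ptd_week_group` objects.
#' @export
cumulative_week_groups <- function(x, n_min = 8, n_max = 40,
                                   per_subject = FALSE) {
  if (is.null(x$meta)) stop("cohort has no metadata")
  stopifnot(n_min <= n_max)
  out <- vector("list", n_max - n_min + 1)
  labels <- paste0("Week_", n_min:n_max)
  for (i in seq_along(out)) {
    N <- n_min + i - 1
    sel <- x$meta$gestation_week <= N
    ids <- x$meta$sample_id[sel]
    if (per_subject && length(ids)) {
      m <- x$meta[sel, , drop = FALSE]
      m <- m[order(m$subject_id, -m$gestation_week), , drop = FALSE]
      ids <- m$sample_id[!duplicated(m$subject_id)]
    }
    if (!length(ids)) message("empty group ", labels[i])
    out[[i]] <- week_group(labels[i], ids)
  }
  names(out) <- labels
  out
}

#' Overlapping sliding gestational-week windows
#'
#' Builds `n_windows` half-open windows `[start + (i-1)*step, ... + width)`
#' (the last window is closed on the right so the range endpoint is kept).
#' Samples may fall in several windows; used for diversity-trend summaries.
#'
#' @param x a `ptd_cohort` with metadata.
#' @param n_windows number of windows (default 15).
#' @param width window width in weeks (default 6).
#' @param step offset between consecutive window starts (default 2.5);
#'   must satisfy `0 < step < width` so that windows overlap.
#' @param start left edge of the first window; defaults to the smallest
#'   observed gestational week.
#' @return a list of `ptd_week_group`s with `lo`/`hi` attributes.
#' @export
sliding_week_windows <- function(x, n_windows = 15, width = 6, step = 2.5,
                                 start = NULL) {
  if (is.null(x$meta)) stop("cohort has no metadata")
  if (!(step > 0 && width > step))
    stop("need width > step > 0 so that consecutive windows overlap")
  wk <- x$meta$gestation_week
  if (is.null(start)) start <- min(wk)
  last_end <- start + (n_windows - 1) * step + width
  if (last_end < max(wk))
    stop(sprintf(paste0("%d windows of width %g at step %g starting at %g ",
                        "end at week %g and cannot cover the observed range ",
                        "(max week %g)"),
                 n_windows, width, step, start, last_end, max(wk)))
  out <- vector("list", n_windows)
  for (i in seq_len(n_windows)) {
    lo <- start + (i - 1) * step
    hi <- lo + width
    sel <- wk >= lo & (wk < hi | (i == n_windows & wk <= hi))
    g <- week_group(sprintf("Window_%02d_[%g,%g)", i, lo, hi),
                    x$meta$sample_id[sel])
    attr(g, "lo") <- lo
    attr(g, "hi") <- hi
    out[[i]] <- g
  }
  names(out) <- vapply(out, `[[`, "", "label")
  out
}
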