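#' Configuration for the synthetic vaginal-microbiome cohort generator
#'
#' The generator emulates the statistical structure the analysis pipeline
#' assumes: Lactobacillus-style dominated compositions (one dominant taxon,
#' a long minority tail — a highly skewed Lorenz curve), a preterm arm whose
#' tail evenness is depressed in early gestation (hence lower diversity
#' than the term arm before ~week 15-20), and convergence of the two arms
#' at and beyond `convergence_week`. Compositions are Dirichlet-multinomial:
#' one dominant component with concentration `dominance_alpha` and
#' `n_taxa - 1` tail components at the arm/week-specific evenness
#' concentration; counts are multinomial at a depth uniform on
#' `depth_range`. Samples are conditionally independent given arm and week.
#'
#' @param n_subjects number of subjects (default 300).
#' @param ptd_fraction probability a subject has a preterm outcome
#'   (default 0.138, matching a 224/1621 preterm sample share).
#' @param n_taxa taxa in the universe (default 200).
#' @param depth_range integer depth interval (default `c(500, 50000)`, so
#'   every profile passes the 500-read inclusion filter).
#' @param dominance_alpha Dirichlet concentration of the dominant taxon
#'   (default 100; with the default term tail this puts the dominant
#'   taxon's median relative abundance near 0.63).
#' @param evenness_alpha_term tail concentration of the term arm
#'   (default 0.3).
#' @param evenness_alpha_ptd_early early-gestation tail concentration of
#'   the preterm arm (default 0.003; must not exceed
#'   `evenness_alpha_term`, encoding the lower early diversity of the
#'   preterm arm).
#' @param effect_onset_week week until which the preterm tail concentration
#'   stays at its early value (default 12).
#' @param convergence_week week at which the arms have converged
#'   (default 20).
#' @param samples_per_subject integer range of samples per subject
#'   (default `c(2, 8)`).
#' @param week_range sampling-week range (default `c(4, 40)`); sampling
#'   days are drawn uniformly and weeks are fractional (day / 7).
#' @param seed integer RNG seed.
#' @export
synthetic_config <- function(n_subjects = 300, ptd_fraction = 0.138,
                             n_taxa = 200, depth_range = c(500, 50000),
                             dominance_alpha = 100,
                             evenness_alpha_term = 0.3,
                             evenness_alpha_ptd_early = 0.003,
                             effect_onset_week = 12, convergence_week = 20,
                             samples_per_subject = c(2, 8),
                             week_range = c(4, 40), seed = 1) {
  stopifnot(n_subjects >= 1, ptd_fraction > 0, ptd_fraction < 1,
            n_taxa >= 2, length(depth_range) == 2,
            depth_range[1] <= depth_range[2], dominance_alpha > 0,
            evenness_alpha_term > 0, evenness_alpha_ptd_early > 0,
            evenness_alpha_ptd_early <= evenness_alpha_term,
            effect_onset_week <= convergence_week,
            length(samples_per_subject) == 2,
            samples_per_subject[1] >= 1,
            samples_per_subject[1] <= samples_per_subject[2],
            length(week_range) == 2, week_range[1] > 0,
            week_range[1] < week_range[2])
  structure(as.list(environment()), class = "ptd_syn_config")
}

#' Preterm-arm evenness trajectory over gestation
#'
#' Returns a vectorized function of gestational week giving the preterm
#' arm's tail concentration: constant at `evenness_alpha_ptd_early` up to
#' `effect_onset_week`, log-linear interpolation to
#' `evenness_alpha_term` at `convergence_week`, and equal to the term
#' value beyond it. Monotone non-decreasing in week by construction.
#'
#' @param config a [synthetic_config()].
#' @export
effect_trajectory <- function(config) {
  early <- config$evenness_alpha_ptd_early
  term <- config$evenness_alpha_term
  on <- config$effect_onset_week
  cv <- config$convergence_week
  function(week) {
    frac <- if (cv > on) pmin(1, pmax(0, (week - on) / (cv - on))) else
      as.numeric(week >= cv)
    exp(log(early) + frac * (log(term) - log(early)))
  }
}

#' Generate a seeded synthetic cohort
#'
#' See [synthetic_config()] for the generative model. Deterministic under
#' the config seed: two calls with the same config yield bit-identical
#' cohorts.
#'
#' @param config a [synthetic_config()].
#' @param study_id study label written into the metadata
#'   (default `"synthetic"`).
#' @return a `ptd_cohort` with metadata; the config is attached as the
#'   `"config"` attribute.
#' @export
generate_cohort <- function(config = synthetic_config(),
                            study_id = "synthetic") {
  stopifnot(inherits(config, "ptd_syn_config"))
  set.seed(config$seed)
  traj <- effect_trajectory(config)
  spm <- config$samples_per_subject
  days <- (ceiling(config$week_range[1] * 7)):(floor(config$week_range[2] * 7))
  depths <- config$depth_range[1]:config$depth_range[2]
  counts_cols <- list()
  meta_rows <- list()
  for (s in seq_len(config$n_subjects)) {
    subject <- sprintf("SUBJ%04d", s)
    outcome <- if (stats::runif(1) < config$ptd_fraction) "PTD" else "TERM"
    k <- sample(spm[1]:spm[2], 1)
    weeks <- round(sample(days, k, replace = FALSE) / 7, 2)
    for (j in seq_len(k)) {
      w <- weeks[j]
      tail_alpha <- if (outcome == "PTD") traj(w) else
        config$evenness_alpha_term
      alphas <- c(config$dominance_alpha,
                  rep(tail_alpha, config$n_taxa - 1))
      g <- stats::rgamma(config$n_taxa, shape = alphas)
      p <- g / sum(g)
      depth <- sample(depths, 1)
      sid <- sprintf("%s_T%02d", subject, j)
      counts_cols[[sid]] <- stats::rmultinom(1, depth, p)[, 1]
      meta_rows[[sid]] <- data.frame(sample_id = sid, subject_id = subject,
                                     study_id = study_id,
                                     gestation_week = w, outcome = outcome,
                                     stringsAsFactors = FALSE)
    }
  }
  counts <- do.call(cbind, counts_cols)
  rownames(counts) <- sprintf("OTU_%04d", seq_len(config$n_taxa))
  colnames(counts) <- names(counts_cols)
  out <- cohort(counts, do.call(rbind, meta_rows))
  attr(out, "config") <- config
  out
}

#' Nuisance-parameter perturbation for external cohorts
#'
#' Describes how an external cohort's generative nuisance parameters
#' differ from the base configuration while keeping the outcome-effect
#' structure intact (emulating an external study with different protocol,
#' sequencing depth and taxon inventory). The neutral shift (all scales 1,
#' `n_taxa = NULL`) reproduces the base generator exactly.
#'
#' @param depth_scale multiplier on both depth-range ends (default 0.5).
#' @param dominance_scale multiplier on `dominance_alpha` (default 1.25).
#' @param evenness_scale multiplier on both evenness concentrations
#'   (default 1).
#' @param n_taxa replacement taxon count, or `NULL` to keep the base value.
#' @export
external_shift <- function(depth_scale = 0.5, dominance_scale = 1.25,
                           evenness_scale = 1, n_taxa = NULL) {
  stopifnot(depth_scale > 0, dominance_scale > 0, evenness_scale > 0)
  structure(list(depth_scale = depth_scale,
                 dominance_scale = dominance_scale,
                 evenness_scale = evenness_scale, n_taxa = n_taxa),
            class = "ptd_ext_shift")
}

#' Generate a distribution-shifted external cohort
#'
#' Same generative family and outcome-effect structure as
#' [generate_cohort()], with nuisance parameters perturbed per `shift`.
#' With the neutral shift and the same seed the output equals
#' [generate_cohort()] exactly.
#'
#' @param config base [synthetic_config()].
#' @param shift an [external_shift()].
#' @param seed optional seed override for the external draw (defaults to
#'   the config seed).
#' @param study_id study label (default `"external"`).
#' @export
generate_external_cohort <- function(config = synthetic_config(),
                                     shift = external_shift(),
                                     seed = NULL, study_id = "external") {
  stopifnot(inherits(shift, "ptd_ext_shift"))
  cfg <- config
  cfg$depth_range <- pmax(1L, as.integer(round(
    config$depth_range * shift$depth_scale)))
  cfg$dominance_alpha <- config$dominance_alpha * shift$dominance_scale
  cfg$evenness_alpha_term <- config$evenness_alpha_term *
    shift$evenness_scale
  cfg$evenness_alpha_ptd_early <- config$evenness_alpha_ptd_early *
    shift$evenness_scale
  if (!is.null(shift$n_taxa)) cfg$n_taxa <- shift$n_taxa
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  generate_cohort(cfg, study_id = study_id)
}

#' Write a cohort to disk (count table, metadata, manifest)
#'
#' Emits the canonical BIOM-classic TSV count table, the metadata CSV, and
#' a JSON manifest recording the full generator configuration and seed
#' when the cohort carries one.
#'
#' @param x a `ptd_cohort`.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix (default `"cohort"`).
#' @return invisibly, the named vector of written paths.
#' @export
write_cohort <- function(x, dir, prefix = "cohort") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(counts = file.path(dir, paste0(prefix, "_counts.tsv")),
             metadata = file.path(dir, paste0(prefix, "_metadata.csv")),
             manifest = file.path(dir, paste0(prefix, "_manifest.json")))
  write_count_table(x, paths["counts"])
  if (is.null(x$meta)) stop("cohort has no metadata to write")
  utils::write.csv(x$meta, paths["metadata"], row.names = FALSE,
                   quote = FALSE)
  cfg <- attr(x, "config")
  manifest <- list(n_taxa = nrow(x$counts), n_samples = ncol(x$counts),
                   config = if (is.null(cfg)) NULL else unclass(cfg))
  jsonlite::write_json(manifest, paths["manifest"], auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(paths)
}

#' Read a cohort back from a count table plus metadata file
#' @param counts_path TSV count table path.
#' @param metadata_path metadata CSV path.
#' @param format count-table format, `"tsv"` or `"biom"`.
#' @export
read_cohort <- function(counts_path, metadata_path, format = "tsv") {
  attach_metadata(read_count_table(counts_path, format), metadata_path)
}
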