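# End-to-end pipeline: generate -> ADD -> episodes -> fit -> post-hoc ->
# annotate, with TSV interchange, a seeded-stage manifest and byte-identical
# replay under a fixed config.

#' Write a synthetic cohort as a directory of TSV files
#'
#' Emits `admissions.tsv`, `prescriptions.tsv`, `diagnoses.tsv`,
#' `blood_tests.tsv`, `ddi.tsv`, `pk.tsv`, `comentions.tsv`, `truth.tsv`, the
#' config as `config.json`, and a `data_dictionary.tsv` describing every
#' column.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(admissions = "admissions.tsv", prescriptions = "prescriptions.tsv",
             diagnoses = "diagnoses.tsv", blood_tests = "blood_tests.tsv",
             ddi_reference = "ddi.tsv", pk_annotations = "pk.tsv",
             comention_counts = "comentions.tsv", truth = "truth.tsv")
  for (nm in names(files)) {
    write_tsv(cohort[[nm]], file.path(dir, files[[nm]]))
  }
  cfg <- cohort$config
  cfg$planted_effects <- as.data.frame(cfg$planted_effects)
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_tsv(.data_dictionary(), file.path(dir, "data_dictionary.tsv"))
  invisible(dir)
}

.data_dictionary <- function() {
  tibble::tribble(
    ~file, ~column, ~description,
    "admissions.tsv", "admission_id", "admission key",
    "admissions.tsv", "patient_id", "patient key",
    "admissions.tsv", "admit_time", "admission start, minutes since epoch",
    "admissions.tsv", "discharge_time", "admission end (half-open), minutes",
    "admissions.tsv", "age", "age at admission, years",
    "admissions.tsv", "sex", "F or M",
    "admissions.tsv", "hospital", "hospital code",
    "admissions.tsv", "year", "calendar year of admission",
    "admissions.tsv", "diag_chapter", "primary diagnosis, ICD-10 chapter level",
    "admissions.tsv", "charlson", "weighted Charlson comorbidity score",
    "admissions.tsv", "med_burden", "number of unique drugs in the admission",
    "admissions.tsv", "los_days", "length of stay, days",
    "admissions.tsv", "death_time", "death, minutes after admission start; NA if none within 30 days",
    "admissions.tsv", "readmit_gap_days", "days from discharge to readmission; NA if none within 30 days",
    "admissions.tsv", "exposed_pair", "drug pair carried by the admission (generator truth)",
    "prescriptions.tsv", "rx_id", "prescription key",
    "prescriptions.tsv", "drug_atc", "ATC code",
    "prescriptions.tsv", "start", "validity start, minutes (half-open)",
    "prescriptions.tsv", "end", "validity end, minutes (half-open)",
    "prescriptions.tsv", "dose", "dose per administration",
    "prescriptions.tsv", "unit", "dose unit",
    "prescriptions.tsv", "freq", "administrations per dose interval",
    "prescriptions.tsv", "interval_hours", "dose interval, hours",
    "prescriptions.tsv", "rx_type", "scheduled, one-time, PN or VAO",
    "prescriptions.tsv", "strength", "package strength per unit volume",
    "prescriptions.tsv", "volume", "prescribed volume",
    "diagnoses.tsv", "icd_code", "secondary diagnosis code",
    "blood_tests.tsv", "test_code", "blood test code (absent row = not taken)",
    "blood_tests.tsv", "abnormal", "1 = outside reference range",
    "ddi.tsv", "has_ddi", "known interaction flag (symmetric)",
    "pk.tsv", "protein", "CYP enzyme or transporter",
    "pk.tsv", "role", "inducer, inhibitor or substrate",
    "comentions.tsv", "n_articles", "literature co-mention count",
    "truth.tsv", "log_odds_effect", "planted concomitant-drug effect"
  )
}

#' @rdname write_cohort
#' @param x a data frame; `path` a file path.
#' @param path output file.
#' @export
write_tsv <- function(x, path) {
  df <- as.data.frame(x)
  for (j in seq_along(df)) {
    if (is.list(df[[j]])) {
      df[[j]] <- vapply(df[[j]], function(v) paste(v, collapse = ";"),
                        character(1))
    }
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_tsv <- function(path) {
  tibble::as_tibble(utils::read.delim(path, sep = "\t", na.strings = "NA",
                                      stringsAsFactors = FALSE))
}

#' Pipeline configuration
#'
#' @param out_dir run directory.
#' @param cohort a [cohort_config()] (the pipeline generates its inputs) or
#'   `NULL` to read pre-existing TSVs from `out_dir/cohort`.
#' @param min_mono_patients,min_pair_patients,one_time_max_frac selection
#'   thresholds (defaults 50, 50, 0.70).
#' @param downsample_threshold,top_comedications down-sampling controls
#'   (defaults 500000, 300).
#' @param spec a [model_spec()].
#' @param posthoc_min_patients presence threshold for enrichment endpoints.
#' @param seed global seed; per-stage seeds are derived from it.
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(out_dir, cohort = cohort_config(),
                            min_mono_patients = 50, min_pair_patients = 50,
                            one_time_max_frac = 0.70,
                            downsample_threshold = 500000,
                            top_comedications = 300,
                            spec = model_spec(), posthoc_min_patients = 50,
                            seed = 1L) {
  if (min_mono_patients <= 0 || min_pair_patients <= 0 ||
      downsample_threshold <= 0 || top_comedications <= 0) {
    stop_config("all thresholds must be positive")
  }
  if (!(spec$rope[1] < 0 && 0 < spec$rope[2])) {
    stop_config("rope bounds must satisfy low < 0 < high")
  }
  structure(list(out_dir = out_dir, cohort = cohort,
                 min_mono_patients = min_mono_patients,
                 min_pair_patients = min_pair_patients,
                 one_time_max_frac = one_time_max_frac,
                 downsample_threshold = downsample_threshold,
                 top_comedications = top_comedications,
                 spec = spec, posthoc_min_patients = posthoc_min_patients,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Stages: cohort generation (or ingest), ADD computation, admission merging
#' and episode construction, selection filters, per-index-drug Bayesian fits
#' (with stratified down-sampling when oversized), post-hoc association
#' analyses on every significant pair, and DDI/pharmacokinetic annotation with
#' group comparisons. All stage outputs are written as TSV under `out_dir`,
#' plus `run_manifest.json` with the seed, per-stage row counts and a content
#' digest per file.
#'
#' @param config a [pipeline_config()].
#' @return list with all stage results (invisibly also written to
#'   `config$out_dir`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_file <- file.path(config$out_dir, "pipeline.log")
  logf <- function(...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(...))
    cat(msg, "\n", file = log_file, append = TRUE)
    message(msg)
  }

  cohort_dir <- file.path(config$out_dir, "cohort")
  if (!is.null(config$cohort)) {
    logf("stage generate: %d patients, %d drugs", config$cohort$n_patients,
         config$cohort$n_drugs)
    cohort <- generate_cohort(config$cohort)
    write_cohort(cohort, cohort_dir)
  } else {
    logf("stage ingest: reading %s", cohort_dir)
    cohort <- list(
      admissions = read_tsv(file.path(cohort_dir, "admissions.tsv")),
      prescriptions = read_tsv(file.path(cohort_dir, "prescriptions.tsv")),
      diagnoses = read_tsv(file.path(cohort_dir, "diagnoses.tsv")),
      blood_tests = read_tsv(file.path(cohort_dir, "blood_tests.tsv")),
      ddi_reference = read_tsv(file.path(cohort_dir, "ddi.tsv")),
      pk_annotations = read_tsv(file.path(cohort_dir, "pk.tsv")),
      comention_counts = read_tsv(file.path(cohort_dir, "comentions.tsv")))
  }
  for (nm in c("admissions", "prescriptions")) {
    if (is.null(cohort[[nm]]) || nrow(cohort[[nm]]) == 0L) {
      stop_data(sprintf("missing or empty input table: %s", nm))
    }
  }

  admissions <- merge_readmissions(cohort$admissions)
  for (nm in c("prescriptions", "diagnoses", "blood_tests")) {
    if (!is.null(cohort[[nm]]) && nrow(cohort[[nm]]) > 0L) {
      cohort[[nm]] <- remap_admissions(cohort[[nm]], admissions)
    }
  }

  logf("stage add: %d prescriptions", nrow(cohort$prescriptions))
  add <- compute_add_table(cohort$prescriptions)
  write_tsv(add, file.path(config$out_dir, "add.tsv"))

  logf("stage episodes")
  episodes <- build_episodes(cohort$prescriptions, add)
  sel <- apply_selection_filters(
    episodes, cohort$prescriptions,
    min_mono_patients = config$min_mono_patients,
    min_pair_patients = config$min_pair_patients,
    one_time_max_frac = config$one_time_max_frac)
  logf("selection: %d/%d drugs, %d/%d pairs retained",
       sel$report$drugs_retained, sel$report$drugs_considered,
       sel$report$pairs_retained, sel$report$pairs_considered)
  write_tsv(dplyr::select(episodes, -"add_values"),
            file.path(config$out_dir, "episodes.tsv"))
  rep_out <- tibble::as_tibble(as.list(sel$report$exclusions[[1]]))
  rep_out <- dplyr::bind_cols(sel$report[, 1:4], rep_out)
  write_tsv(rep_out, file.path(config$out_dir, "selection_report.tsv"))

  logf("stage fit")
  fit_eps <- sel$episodes
  kept <- lapply(sort(unique(fit_eps$index_drug)), function(d) {
    stratified_downsample(
      fit_eps[fit_eps$index_drug == d, ], admissions,
      threshold = config$downsample_threshold,
      top_comedications = config$top_comedications,
      min_pair_patients = config$min_pair_patients,
      seed = derive_seed(config$seed, 21L))
  })
  fit_eps <- dplyr::bind_rows(kept)
  posteriors <- fit_all_pairs(fit_eps, admissions, config$spec,
                              seed = derive_seed(config$seed, 22L))
  write_tsv(posteriors, file.path(config$out_dir, "pair_posteriors.tsv"))
  write_tsv(posteriors[, c("index_drug", "co_med", "converged", "rhat_max",
                           "divergences", "ess_bulk_min")],
            file.path(config$out_dir, "diagnostics.tsv"))
  jsonlite::write_json(unclass(config$spec),
                       file.path(config$out_dir, "model_config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  sig <- posteriors[posteriors$significant %in% TRUE, ]
  logf("stage posthoc: %d significant pairs", nrow(sig))
  assoc <- list(); matched_all <- list()
  if (nrow(sig) > 0L) {
    for (i in seq_len(nrow(sig))) {
      pr <- c(sig$index_drug[i], sig$co_med[i])
      mc <- match_cohort(pr, sel$episodes, admissions,
                         seed = derive_seed(config$seed, 30L + i))
      if (is.null(mc)) next
      matched_all[[length(matched_all) + 1L]] <- mc
      assoc[[length(assoc) + 1L]] <- dplyr::bind_rows(
        test_discontinuation(mc, sel$episodes),
        test_outcomes(mc, admissions),
        test_enrichment(mc, cohort$diagnoses, cohort$blood_tests,
                        min_patients = config$posthoc_min_patients))
    }
  }
  associations <- if (length(assoc)) bonferroni_family(dplyr::bind_rows(assoc))
                  else tibble::tibble()
  write_tsv(associations, file.path(config$out_dir, "associations.tsv"))
  if (length(matched_all)) {
    write_tsv(dplyr::bind_rows(matched_all),
              file.path(config$out_dir, "matched_cohorts.tsv"))
  }

  logf("stage annotate")
  pair_counts <- dplyr::count(
    sel$episodes[sel$episodes$co_med != MONOTHERAPY, ],
    .data$index_drug, .data$co_med, name = "n_episodes")
  ann_in <- if (nrow(sig) > 0L) sig else posteriors
  annotations <- comparisons <- tibble::tibble()
  if (nrow(ann_in) > 0L) {
    annotations <- annotate_pairs(ann_in, cohort$ddi_reference,
                                  cohort$pk_annotations,
                                  cohort$comention_counts)
    if (nrow(annotations) > 0L && length(unique(annotations$has_ddi)) == 2L) {
      comparisons <- compare_groups(annotations, posteriors)
    }
  }
  write_tsv(annotations, file.path(config$out_dir, "annotations.tsv"))
  write_tsv(comparisons, file.path(config$out_dir, "comparisons.tsv"))

  files <- list.files(config$out_dir, recursive = TRUE, pattern = "\\.tsv$")
  manifest <- list(
    seed = config$seed,
    created = format(Sys.time()),
    r_version = as.character(getRversion()),
    rows = list(prescriptions = nrow(cohort$prescriptions),
                episodes = nrow(episodes),
                episodes_retained = nrow(sel$episodes),
                pairs = nrow(posteriors),
                significant_pairs = nrow(sig),
                associations = nrow(associations)),
    files = lapply(setNames(files, files), function(f) {
      unname(tools::md5sum(file.path(config$out_dir, f)))
    }))
  jsonlite::write_json(manifest, file.path(config$out_dir,
                                           "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  logf("done")
  invisible(list(cohort = cohort, add = add, episodes = episodes,
                 selection = sel, posteriors = posteriors,
                 associations = associations, annotations = annotations,
                 comparisons = comparisons,
                 matched = if (length(matched_all))
                   dplyr::bind_rows(matched_all) else NULL))
}
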