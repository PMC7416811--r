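#' Read a cohort table from CSV or TSV
#'
#' The delimiter is taken from the file extension (`.tsv`/`.tab` = tab,
#' otherwise comma) unless given explicitly. The table is validated: the
#' survival columns must exist, event codes must be 0/1 (hard error),
#' non-positive survival times are an error listing the offending patient ids,
#' and per-column missingness is recorded in the `validation` attribute (with
#' one warning per affected column).
#'
#' @param path File path.
#' @param time_col,event_col Survival column names.
#' @param id_col Patient identifier column (created as row numbers when
#'   absent).
#' @param delim Optional delimiter override.
#' @return A validated cohort tibble with a `validation` attribute (tibble of
#'   per-column missing counts).
#' @export
read_cohort <- function(path, time_col = "time", event_col = "event",
                        id_col = "patient_id", delim = NULL) {
  rc_assert(file.exists(path), sprintf("file not found: %s", path))
  if (is.null(delim)) {
    delim <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  }
  cohort <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                              progress = FALSE)
  for (col in c(time_col, event_col)) {
    if (!col %in% names(cohort)) {
      rc_abort(sprintf("cohort file is missing required column `%s`", col),
               class = "riskclust_missing_column")
    }
  }
  ev <- cohort[[event_col]]
  if (!all(ev %in% c(0, 1))) {
    rc_abort(sprintf("malformed event codes in `%s`: must be 0/1", event_col))
  }
  if (!id_col %in% names(cohort)) {
    cohort[[id_col]] <- sprintf("P%03d", seq_len(nrow(cohort)))
  }
  rc_assert(!anyDuplicated(cohort[[id_col]]), "patient ids must be unique")
  bad_time <- cohort[[time_col]] <= 0 | !is.finite(cohort[[time_col]])
  if (any(bad_time)) {
    rc_abort(sprintf("non-positive survival time for patient(s): %s",
                     paste(cohort[[id_col]][bad_time], collapse = ", ")))
  }
  miss <- vapply(cohort, function(x) sum(is.na(x)), integer(1))
  validation <- tibble::tibble(column = names(miss), n_missing = unname(miss))
  for (col in names(miss)[miss > 0]) {
    rlang::warn(sprintf("column `%s` has %d missing value(s)", col, miss[col]))
  }
  attr(cohort, "validation") <- validation
  cohort
}

#' Write a cohort table as CSV
#'
#' @param cohort Cohort data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_csv(cohort, path, progress = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Collects every setting of the end-to-end analysis. Defaults reproduce the
#' published design: consensus clustering with 100 resampling repeats over
#' k = 2..5, per-biomarker Cox models adjusted for age, gender, therapy and
#' primary-tumour diagnosis with candidate biomarker-by-therapy and
#' biomarker-by-diagnosis interactions.
#'
#' @param biomarkers Biomarker column names.
#' @param confounders Confounders entering the Cox models.
#' @param interaction_with Confounders whose interaction with each biomarker is
#'   a candidate model term.
#' @param test_confounders Confounders for the cluster-association tests.
#' @param k_values,n_resamples,subsample_fraction,linkage,distance,tau
#'   Consensus-clustering settings (see [consensus_cluster()]).
#' @param scaling Risk-profile column scaling (see [build_risk_profiles()]).
#' @param ties Tie handling for the Cox fits.
#' @param bh_family Benjamini-Hochberg family (see [characterize()]).
#' @param time_col,event_col Survival column names.
#' @param seed Integer seed for the consensus resampling.
#' @param out_dir Output directory (`NULL` = do not write files).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(biomarkers = default_biomarkers(),
                            confounders = c("age", "gender", "therapy",
                                            "diagnosis"),
                            interaction_with = c("therapy", "diagnosis"),
                            test_confounders = c("age", "gender", "therapy",
                                                 "diagnosis", "comorbidities"),
                            k_values = 2:5, n_resamples = 100,
                            subsample_fraction = 0.8, linkage = "average",
                            distance = "euclidean", tau = 0.1,
                            scaling = "zscore", ties = "efron",
                            bh_family = "global",
                            time_col = "time", event_col = "event",
                            seed = 1L, out_dir = NULL) {
  cfg <- list(biomarkers = biomarkers, confounders = confounders,
              interaction_with = interaction_with,
              test_confounders = test_confounders,
              k_values = as.integer(k_values),
              n_resamples = as.integer(n_resamples),
              subsample_fraction = subsample_fraction, linkage = linkage,
              distance = distance, tau = tau, scaling = scaling, ties = ties,
              bh_family = bh_family, time_col = time_col,
              event_col = event_col, seed = as.integer(seed),
              out_dir = out_dir)
  rc_assert(!anyDuplicated(c(cfg$time_col, cfg$event_col, cfg$biomarkers,
                             cfg$confounders)),
            "referenced columns must be distinct")
  rc_assert(cfg$k_values[1] == 2 && all(diff(cfg$k_values) == 1),
            "k_values must be ascending consecutive, starting at 2")
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from JSON
#'
#' @param path JSON file whose fields override the [pipeline_config()]
#'   defaults.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  rc_assert(file.exists(path), sprintf("file not found: %s", path))
  overrides <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, overrides)
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(path)
}

#' Run the full stratification pipeline
#'
#' Executes the whole analysis on a cohort: per-biomarker stepwise Cox models
#' and risk-profile assembly ([build_risk_profiles()]), consensus hierarchical
#' clustering with delta-area selection of k ([consensus_cluster()]), and
#' statistical characterisation of the selected clustering ([characterize()]).
#' When `config$out_dir` is set, all artifacts are written under it
#' (`profiles/`, `consensus/`, `report/`, `manifest.json`); outputs carry no
#' timestamps, so identical cohort + config + seed give byte-identical files.
#'
#' @param cohort Cohort data frame (e.g. from [generate_cohort()] or
#'   [read_cohort()]).
#' @param config A [pipeline_config()].
#' @return List with `profiles` (risk_profile_matrix), `consensus`
#'   (consensus_result), `report` (characterization_report) and `manifest`.
#' @export
run_pipeline <- function(cohort, config = pipeline_config()) {
  rc_assert(inherits(config, "pipeline_config"),
            "`config` must be a pipeline_config")
  warnings_log <- character()
  stage <- function(name, expr) {
    withCallingHandlers(
      tryCatch(expr, error = function(e) {
        rc_abort(sprintf("pipeline stage `%s` failed: %s", name,
                         conditionMessage(e)))
      }),
      warning = function(w) {
        warnings_log <<- c(warnings_log,
                           sprintf("[%s] %s", name, conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
  }
  scopes <- default_scopes(config$biomarkers, confounders = config$confounders,
                           interaction_with = config$interaction_with)
  profiles <- stage("risk_profiles",
    build_risk_profiles(cohort, scopes, scaling = config$scaling,
                        ties = config$ties, time_col = config$time_col,
                        event_col = config$event_col))
  consensus <- stage("consensus_clustering",
    consensus_cluster(profiles, k_values = config$k_values,
                      n_resamples = config$n_resamples,
                      subsample_fraction = config$subsample_fraction,
                      linkage = config$linkage, distance = config$distance,
                      tau = config$tau, seed = config$seed))
  assignment <- consensus_assignment(consensus)
  report <- stage("characterization",
    characterize(cohort, unname(assignment), biomarkers = config$biomarkers,
                 confounders = config$test_confounders,
                 bh_family = config$bh_family, fits = profiles$fits,
                 time_col = config$time_col, event_col = config$event_col))
  manifest_config <- unclass(config)
  manifest_config$out_dir <- NULL  # path varies per run; would break rerun byte-identity
  manifest <- list(
    package = "riskclust",
    version = as.character(utils::packageVersion("riskclust")),
    config = manifest_config, seed = config$seed,
    n_patients = nrow(cohort), selected_k = consensus$selected_k,
    warnings = warnings_log)
  result <- list(profiles = profiles, consensus = consensus, report = report,
                 manifest = manifest)
  if (!is.null(config$out_dir)) write_pipeline_outputs(result, config$out_dir)
  result
}

write_pipeline_outputs <- function(result, out_dir) {
  for (sub in c("profiles", "consensus", "report")) {
    dir.create(file.path(out_dir, sub), recursive = TRUE, showWarnings = FALSE)
  }
  readr::write_csv(result$profiles$profiles,
                   file.path(out_dir, "profiles", "risk_profiles.csv"))
  readr::write_csv(tidy(result$profiles),
                   file.path(out_dir, "profiles", "model_summary.csv"))
  cons <- result$consensus
  for (k in cons$k_values) {
    M <- cons$consensus[[paste0("k", k)]]
    readr::write_csv(
      dplyr::bind_cols(tibble::tibble(patient_id = rownames(M)),
                       tibble::as_tibble(M)),
      file.path(out_dir, "consensus", sprintf("consensus_k%d.csv", k)))
  }
  readr::write_csv(cons$assignments,
                   file.path(out_dir, "consensus", "assignments.csv"))
  write_json_file(list(
    k_values = cons$k_values, areas = cons$areas,
    selected_k = cons$selected_k,
    cluster_consensus = cons$cluster_consensus,
    params = cons$params, valid = cons$valid),
    file.path(out_dir, "consensus", "summary.json"))
  rep <- result$report
  write_json_file(list(
    logrank = rep$logrank, confounder_tests = rep$confounder_tests,
    biomarker_tests = rep$biomarker_tests,
    cluster_survival = rep$cluster_survival, bh_family = rep$bh_family),
    file.path(out_dir, "report", "report.json"))
  readr::write_csv(rep$cluster_summaries,
                   file.path(out_dir, "report", "cluster_summaries.csv"))
  readr::write_csv(rep$normalized_biomarkers,
                   file.path(out_dir, "report", "normalized_biomarkers.csv"))
  writeLines(report_markdown(rep), file.path(out_dir, "report", "report.md"))
  write_json_file(result$manifest, file.path(out_dir, "manifest.json"))
  invisible(out_dir)
}

report_markdown <- function(rep) {
  sig <- rep$biomarker_tests[rep$biomarker_tests$p.adjusted < 0.05, ]
  c("# Cluster characterisation report",
    "",
    sprintf("Clusters: %d (label 1 = shortest median survival)",
            length(unique(rep$assignment))),
    "",
    "## Survival separation (log-rank)",
    sprintf("chi-square = %.4f, df = %d, p = %.4g",
            rep$logrank$statistic, rep$logrank$df, rep$logrank$p.value),
    "",
    "## Cluster survival",
    knit_table(rep$cluster_survival),
    "",
    "## Confounder associations",
    knit_table(rep$confounder_tests),
    "",
    sprintf("## Pairwise biomarker tests (BH family: %s)", rep$bh_family),
    sprintf("%d of %d tests with adjusted p < 0.05", nrow(sig),
            nrow(rep$biomarker_tests)),
    "",
    knit_table(rep$biomarker_tests))
}

# minimal markdown table renderer (keeps report generation dependency-free)
knit_table <- function(df) {
  fmt <- function(x) {
    if (is.numeric(x)) formatC(x, digits = 4, format = "g") else as.character(x)
  }
  cells <- vapply(df, fmt, character(nrow(df)))
  if (nrow(df) == 1) cells <- matrix(cells, nrow = 1)
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  rows <- apply(cells, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, sep, rows)
}
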