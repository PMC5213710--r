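#' Read and write choice datasets as delimited text
#'
#' The canonical interchange format is CSV with one row per trial and the
#' column dictionary: `participant_id`, `group`, `session`, `trial`,
#' `trial_type` (`standard`/`special`/`attention`), `prob_A`, `prob_B`,
#' `rm_A`, `rm_B`, `em_A`, `em_B` (observed outcome magnitudes for both
#' options), `fixed_option` (`A`/`B`/empty), `choice` (`A`/`B`/empty on
#' attention trials), `reward_real` (0/1/empty).  Unknown columns are
#' preserved; a write-read round trip is lossless.
#'
#' @param path file path.
#' @param data a `choice_data` data frame.
#' @return `read_choice_table` returns a `choice_data` data frame.
#' @export
read_choice_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  mandatory <- c("participant_id", "session", "trial", "trial_type",
                 "prob_A", "prob_B", "rm_A", "rm_B", "em_A", "em_B",
                 "choice")
  miss <- setdiff(mandatory, names(df))
  if (length(miss))
    stopf("choice table %s is missing mandatory column(s): %s", path,
          paste(miss, collapse = ", "))
  if (!"fixed_option" %in% names(df)) df$fixed_option <- NA_character_
  df$fixed_option[!is.na(df$fixed_option) & df$fixed_option == ""] <- NA
  df$choice[!is.na(df$choice) & df$choice == ""] <- NA
  structure(df, class = c("choice_data", "data.frame"))
}

#' @rdname read_choice_table
#' @export
write_choice_table <- function(data, path) {
  write.csv(as.data.frame(data), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Split a multi-participant choice table into per-participant datasets
#'
#' @param data a `choice_data` data frame holding several participants.
#' @return a named list of `choice_data`, one per `participant_id`.
#' @export
split_participants <- function(data) {
  lapply(split(as.data.frame(data), data$participant_id), function(d)
    structure(d[order(d$session, d$trial), ],
              class = c("choice_data", "data.frame")))
}

# ---------------------------------------------------------------------------
# Article-style source-data import.  The study's source-data spreadsheets
# hold per-participant regression weights (Figure 2), simulated/fitted
# parameters, model fits, and spectroscopy values (Figure 3).  Converted
# CSVs (or the original .xlsx, when the readxl package is available) are
# mapped onto the package's tables through the column dictionaries below.

read_table_any <- function(path, sheet = 1) {
  if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("readxl", quietly = TRUE))
      stopf("reading %s needs the readxl package; convert it to CSV instead",
            path)
    as.data.frame(readxl::read_excel(path, sheet = sheet))
  } else read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Import per-participant stay/switch regression weights
#'
#' Expects columns (case-insensitive, in any order): a participant
#' identifier, a group label, `prob`, and `RM_1` .. `RM_4`, `EM_1` ..
#' `EM_4` (aliases `RM_t-1` etc. are accepted).
#'
#' @param path CSV or xlsx file.
#' @param sheet sheet index for xlsx input.
#' @return a list with `weights` (matrix) and `group` (vector).
#' @export
read_source_weights <- function(path, sheet = 1) {
  df <- read_table_any(path, sheet)
  names(df) <- sub("^rm[._ -]*t?[-._ ]*", "RM_", names(df),
                   ignore.case = TRUE)
  names(df) <- sub("^em[._ -]*t?[-._ ]*", "EM_", names(df),
                   ignore.case = TRUE)
  names(df)[grepl("^prob", names(df), ignore.case = TRUE)] <- "prob"
  names(df)[grepl("group|drug", names(df), ignore.case = TRUE)] <- "group"
  need <- c("prob", paste0("RM_", 1:4), paste0("EM_", 1:4))
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("weight table %s lacks column(s): %s", path,
                          paste(miss, collapse = ", "))
  list(weights = df[, need, drop = FALSE], group = df$group)
}

#' Import per-participant model-parameter tables
#'
#' Maps parameter columns (`gamma`, `beta`, `alpha`, `lambda`, possibly
#' suffixed by a session tag such as `_ms` for the scanner session or
#' `_os` for the session outside the scanner) onto `fit_result`-style
#' estimate tables, one per session tag found.
#'
#' @param path CSV or xlsx file.
#' @param sheet sheet index for xlsx input.
#' @return a named list of data frames, one per session tag (`both` for
#'   untagged columns), each with `participant_id` and parameter columns.
#' @export
read_source_params <- function(path, sheet = 1) {
  df <- read_table_any(path, sheet)
  nm <- tolower(names(df))
  pid <- if (any(grepl("participant|subject|id", nm)))
    df[[which(grepl("participant|subject|id", nm))[1]]]
  else seq_len(nrow(df))
  pars <- c("alpha", "gamma", "lambda", "beta")
  tags <- unique(unlist(regmatches(nm, regexpr("_(bs|ms|os)$", nm))))
  out <- list()
  grab <- function(suffix, label) {
    cols <- lapply(pars, function(p) {
      hit <- which(nm == paste0(p, suffix))
      if (length(hit)) df[[hit[1]]] else NULL
    })
    names(cols) <- pars
    cols <- cols[!vapply(cols, is.null, logical(1))]
    if (length(cols))
      out[[label]] <<- data.frame(participant_id = as.character(pid), cols)
  }
  grab("", "both")
  for (tg in tags) grab(tg, sub("^_", "", tg))
  if (!length(out)) stopf("no recognisable parameter columns in %s", path)
  out
}

#' Import a spectroscopy source-data table
#'
#' Expects per-participant columns for glutamate, GABA and creatine (raw
#' amplitudes or pre-divided creatine ratios), tissue fractions, optional
#' CRLB fields and a group label; missing creatine is treated as already
#' creatine-normalised (creatine set to 1).
#'
#' @param path CSV or xlsx file.
#' @param sheet sheet index for xlsx input.
#' @return an `mrs_records` data frame.
#' @export
read_source_spectroscopy <- function(path, sheet = 1) {
  df <- read_table_any(path, sheet)
  nm <- tolower(names(df))
  pick <- function(pattern) {
    hit <- which(grepl(pattern, nm))
    if (length(hit)) df[[hit[1]]] else NULL
  }
  n <- nrow(df)
  glu_hit <- which(grepl("glu", nm) & !grepl("gaba|crlb", nm))
  glu <- if (length(glu_hit)) df[[glu_hit[1]]] else NULL
  gaba_hit <- which(grepl("gaba", nm) & !grepl("crlb", nm))
  gaba <- if (length(gaba_hit)) df[[gaba_hit[1]]] else NULL
  if (is.null(glu) || is.null(gaba))
    stopf("%s lacks glutamate/GABA columns", path)
  structure(data.frame(
    participant_id = as.character(pick("participant|subject|id") %||% seq_len(n)),
    group = as.integer(pick("group|drug") %||% rep(0L, n)),
    glutamate_raw = glu, gaba_raw = gaba,
    creatine_raw = pick("creatine|^cr$") %||% rep(1, n),
    crlb_glutamate = pick("crlb.*glu") %||% rep(0, n),
    crlb_gaba = pick("crlb.*gaba") %||% rep(0, n),
    grey_frac = pick("grey|gray") %||% rep(0.55, n),
    white_frac = pick("white") %||% rep(0.30, n),
    csf_frac = pick("csf") %||% rep(0.15, n)),
    class = c("mrs_records", "data.frame"))
}

#' Recompute the article-level statistics from source-data files
#'
#' Given a directory holding the study's source-data tables (as CSV or
#' xlsx: `figure2_weights.*` with the stay/switch regression weights,
#' `figure2_params.*` with per-session model parameters, and
#' `figure3_spectroscopy.*` with the spectroscopy measures), recomputes
#' the group-level behavioral statistics, the test-retest stability of
#' `gamma`, and the neurochemistry-behavior partial correlations.
#'
#' @param dir directory containing the three tables.
#' @return a list: `group_tests`, `gamma_stability`, `neurochem`.
#' @export
reproduce_source_stats <- function(dir) {
  find1 <- function(stem) {
    hits <- list.files(dir, pattern = paste0("^", stem, "\\.(csv|xlsx?)$"),
                       full.names = TRUE, ignore.case = TRUE)
    if (!length(hits))
      stopf("source-data file `%s.(csv|xlsx)` not found under %s", stem, dir)
    hits[1]
  }
  w <- read_source_weights(find1("figure2_weights"))
  gt <- group_tests(w$weights, w$group)
  pars <- read_source_params(find1("figure2_params"))
  stab <- NULL
  if (all(c("ms", "os") %in% names(pars)))
    stab <- parameter_stability(list(estimates = pars$ms),
                                list(estimates = pars$os))
  spec_rec <- read_source_spectroscopy(find1("figure3_spectroscopy"))
  est <- pars$both %||% pars$ms
  nc <- neurochem_behavior_analysis(spec_rec, list(estimates = est), "A")
  list(group_tests = gt, gamma_stability = stab, neurochem = nc)
}

# ---------------------------------------------------------------------------

#' Run the full synthetic study pipeline
#'
#' Simulates a cohort, fits the requested models hierarchically, compares
#' them (summed BIC over ML fits and half-split cross-validation), runs
#' the stay/switch validation regression with group-level tests, generates
#' a synthetic MRS cohort keyed to the fitted `gamma` values, and runs the
#' neurochemistry-behavior analysis.  Every stage's output is written
#' under `out_dir` as CSV/JSON, and a manifest records the master seed,
#' derived stage seeds, package version and a hash of the configuration.
#' All randomness derives from `seed`, so a repeated run reproduces every
#' number.
#'
#' @param cohort a [cohort_spec()] for the simulated participants.
#' @param schedule_cfg a [schedule_config()].
#' @param fit_cfg a [fit_config()].
#' @param mrs an [mrs_spec()] (its `n_participants` is overridden to the
#'   cohort size).
#' @param models models to fit and compare (first one is used for the
#'   downstream analyses).
#' @param out_dir output directory (created if needed); `NULL` skips
#'   writing.
#' @param seed master seed.
#' @return a `pipeline_result` list with every stage's objects and the
#'   manifest.
#' @export
run_full_pipeline <- function(cohort = cohort_spec(),
                              schedule_cfg = schedule_config(),
                              fit_cfg = fit_config(),
                              mrs = mrs_spec(),
                              models = c("M1", "M4"),
                              out_dir = NULL, seed = 1) {
  stage <- "simulate"
  res <- list()
  on.exit(if (!is.null(out_dir))
    message(sprintf("pipeline stopped in stage `%s`", stage)), add = TRUE)
  cohort$seed <- derive_seed(seed, 11)
  sim <- simulate_cohort(cohort, schedule_cfg = schedule_cfg)
  res$simulation <- sim

  stage <- "fit"
  fit_cfg$seed <- derive_seed(seed, 12)
  fits <- lapply(models, function(m) fit_hierarchical(sim$datasets, m, fit_cfg))
  names(fits) <- models
  res$fits <- fits

  stage <- "compare"
  cmp_cfg <- fit_config(n_restarts = fit_cfg$n_restarts,
                        seed = derive_seed(seed, 13),
                        beta_max = fit_cfg$beta_max)
  res$bic <- compare_models_bic(sim$datasets, models, cmp_cfg)
  res$cv <- lapply(models, function(m)
    half_split_cv(sim$datasets, m, fit_cfg, method = "ml"))
  names(res$cv) <- models

  stage <- "regress"
  designs <- lapply(sim$datasets, build_stay_switch_design)
  weights <- do.call(rbind, lapply(designs, fit_stay_switch))
  res$weights <- weights
  res$group_tests <- group_tests(as.data.frame(weights), sim$params$group)

  stage <- "mrs"
  mrs$n_participants <- cohort$n_participants
  mrs$seed <- derive_seed(seed, 14)
  gam <- fits[[1]]$estimates$gamma
  if (is.null(gam)) stopf("first model has no gamma; use a linear model first")
  records <- generate_mrs_cohort(mrs, gam,
                                 group = sim$params$group,
                                 participant_id = fits[[1]]$estimates$participant_id)
  res$mrs_records <- records

  stage <- "neurochem"
  res$neurochem <- neurochem_behavior_analysis(records, fits[[1]], "A")

  stage <- "write"
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_choice_table(do.call(rbind, lapply(sim$datasets, as.data.frame)),
                       file.path(out_dir, "choices.csv"))
    write.csv(sim$params, file.path(out_dir, "true_params.csv"),
              row.names = FALSE)
    for (m in models)
      write.csv(fits[[m]]$estimates,
                file.path(out_dir, sprintf("estimates_%s.csv", m)),
                row.names = FALSE)
    write.csv(as.data.frame(res$bic), file.path(out_dir, "bic.csv"),
              row.names = FALSE)
    write.csv(cbind(participant_id = sim$params$participant_id,
                    as.data.frame(weights)),
              file.path(out_dir, "stay_switch_weights.csv"),
              row.names = FALSE)
    write.csv(as.data.frame(records), file.path(out_dir, "mrs_records.csv"),
              row.names = FALSE)
    write.csv(res$neurochem$correlations,
              file.path(out_dir, "neurochem_correlations.csv"),
              row.names = FALSE)
    cfg_path <- file.path(out_dir, "config.json")
    cfg <- list(cohort = unclass(cohort), schedule = unclass(schedule_cfg),
                fit = unclass(fit_cfg), mrs = unclass(mrs),
                models = models, seed = seed)
    jsonlite::write_json(cfg, cfg_path, auto_unbox = TRUE, digits = NA)
    manifest <- list(
      package_version = as.character(utils::packageVersion("relmrs")),
      master_seed = seed,
      stage_seeds = list(simulate = cohort$seed, fit = fit_cfg$seed,
                         compare = derive_seed(seed, 13),
                         mrs = mrs$seed),
      config_hash = unname(tools::md5sum(cfg_path)),
      cv_deviance = vapply(res$cv, `[[`, numeric(1), "cv_deviance"),
      summed_bic = stats::setNames(res$bic$summed_bic, res$bic$model_id))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    res$manifest <- manifest
  }
  stage <- "done"
  on.exit()
  class(res) <- "pipeline_result"
  res
}
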