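#' Clean and parameterize one recording
#'
#' Convenience composition of [clean_recording()], [welch_psd()] and
#' [parameterize_spectrum()].
#'
#' @param recording an `stn_recording`.
#' @param ... passed to [clean_recording()].
#' @return list with `model` (`stn_spectral_model`), `psd` (`stn_psd`) and
#'   `log` (`stn_cleaning_log`).
#' @export
analyze_recording <- function(recording, ...) {
  cl <- clean_recording(recording, ...)
  psd <- welch_psd(cl$segments$segments, fs = recording$fs)
  model <- parameterize_spectrum(psd)
  list(model = model, psd = psd, log = cl$log)
}

# analysis task of a recording for a given hemisphere, or NA when the
# recording is not analyzed for that hemisphere (ipsilateral finger-to-nose)
analysis_task <- function(task, hemisphere) {
  switch(task,
         rest = "rest",
         speech = "speech",
         finger_to_nose_left = if (hemisphere == "R") "finger_to_nose" else NA,
         finger_to_nose_right = if (hemisphere == "L") "finger_to_nose" else NA,
         NA)
}

#' Analyze a full cohort: spectra, physiomarkers, feature table
#'
#' Runs the cleaning chain and spectral decomposition on every analyzable
#' recording (the finger-to-nose task only for the hemisphere
#' contralateral to the moving hand), tracks beta peaks across visits in
#' the OFF-stimulation rest condition, computes 4 Hz band powers with the
#' center frequency frozen per hemisphere and visit from that visit's
#' OFF-rest fit, scores stimulation responsiveness against the natural
#' between-visit fluctuation, and selects the most responsive peak per
#' hemisphere.
#'
#' @param cohort an `stn_cohort` (or a list of `stn_recording`s plus a
#'   manifest in the same shape).
#' @param tolerance between-visit peak-frequency tolerance (Hz).
#' @param on_error `"abort"` (default): any per-recording failure stops
#'   the analysis naming the failing cell; `"skip"`: the cell is dropped
#'   and recorded in the returned `skipped` table (the real-data
#'   behaviour when a recording has no artifact-free segment).
#' @param ... passed to [clean_recording()].
#' @return list with `features` (long data.frame: `hemisphere_id`,
#'   `peak_id`, `visit`, `stim_state`, `task`, `feature`, `value`),
#'   `matches` (per-hemisphere consistent peaks with suppression scores
#'   and a `selected` flag), `models`, `logs`, `ftg` (per hemisphere x
#'   visit), `n_peaks_offrest` (per hemisphere x visit beta-peak counts).
#' @export
analyze_cohort <- function(cohort, tolerance = 2.5,
                           on_error = c("abort", "skip"), ...) {
  stopifnot(inherits(cohort, "stn_cohort"))
  on_error <- match.arg(on_error)
  man <- cohort$manifest
  keyfun <- function(s, h, v, st, tk) paste(s, h, v, st, tk, sep = "|")
  models <- list()
  psds <- list()
  logs <- list()
  skipped <- list()
  for (i in seq_len(nrow(man))) {
    g <- man[i, ]
    atask <- analysis_task(g$task, g$hemisphere)
    if (is.na(atask)) next
    res <- tryCatch(analyze_recording(cohort$recordings[[i]], ...),
                    error = function(e) e)
    if (inherits(res, "error")) {
      cell <- sprintf("%s %s visit %s %s-%s", g$subject_id, g$hemisphere,
                      g$visit, g$stim_state, g$task)
      if (on_error == "abort") {
        stopf("analysis failed for %s: %s", cell, conditionMessage(res))
      }
      skipped[[length(skipped) + 1]] <- data.frame(
        cell = cell, message = conditionMessage(res))
      next
    }
    k <- keyfun(g$subject_id, g$hemisphere, g$visit, g$stim_state, atask)
    models[[k]] <- res$model
    psds[[k]] <- res$psd
    logs[[k]] <- res$log
  }

  hemis <- unique(man[, c("subject_id", "hemisphere")])
  visits <- sort(unique(man$visit))
  stims <- c("OFF", "ON")
  tasks <- c("rest", "finger_to_nose", "speech")

  feat <- list()
  matches_all <- list()
  ftg_rows <- list()
  npk_rows <- list()
  add_feat <- function(hid, pid, v, st, tk, feature, value) {
    feat[[length(feat) + 1]] <<- data.frame(
      hemisphere_id = hid, peak_id = pid, visit = v, stim_state = st,
      task = tk, feature = feature, value = value)
  }

  for (r in seq_len(nrow(hemis))) {
    sid <- hemis$subject_id[r]
    h <- hemis$hemisphere[r]
    hid <- paste(sid, h, sep = "_")

    for (v in visits) for (st in stims) for (tk in tasks) {
      m <- models[[keyfun(sid, h, v, st, tk)]]
      if (is.null(m)) next
      add_feat(hid, NA, v, st, tk, "offset", m$aperiodic$offset)
      add_feat(hid, NA, v, st, tk, "exponent", m$aperiodic$exponent)
    }

    # beta-peak tracking in OFF-rest
    bp <- lapply(visits, function(v) {
      m <- models[[keyfun(sid, h, v, "OFF", "rest")]]
      if (is.null(m)) data.frame() else beta_peaks(m)
    })
    for (v in visits) {
      npk_rows[[length(npk_rows) + 1]] <- data.frame(
        hemisphere_id = hid, visit = v, n_beta_peaks = nrow(bp[[v]]))
    }
    if (length(visits) < 2) next
    mt <- match_across_visits(bp[[1]], bp[[2]], tolerance = tolerance)
    if (nrow(mt)) {
      mt$hemisphere_id <- hid
      mt$peak_id <- seq_len(nrow(mt))
      mt$natural_fluctuation <- NA_real_
      mt$suppression_percent <- NA_real_
      for (p in seq_len(nrow(mt))) {
        cf <- c(mt$cf_visit1[p], mt$cf_visit2[p])
        pow <- array(NA_real_, dim = c(2, 2, 3),
                     dimnames = list(visits, stims, tasks))
        for (v in visits) for (st in stims) for (tk in tasks) {
          ps <- psds[[keyfun(sid, h, v, st, tk)]]
          if (!is.null(ps)) pow[v, st, tk] <- band_power(ps, cf[v])
        }
        for (v in visits) for (st in stims) for (tk in tasks) {
          if (!is.na(pow[v, st, tk])) {
            add_feat(hid, p, v, st, tk, "band_power", pow[v, st, tk])
          }
        }
        add_feat(hid, p, 1, "OFF", "rest", "peak_width", mt$width_visit1[p])
        add_feat(hid, p, 2, "OFF", "rest", "peak_width", mt$width_visit2[p])
        resp <- tryCatch(
          responsiveness(pow[1, "OFF", "rest"], pow[1, "ON", "rest"],
                         pow[2, "OFF", "rest"], pow[2, "ON", "rest"]),
          error = function(e) list(natural_fluctuation = NA_real_,
                                   suppression_percent = NA_real_))
        mt$natural_fluctuation[p] <- resp$natural_fluctuation
        mt$suppression_percent[p] <- resp$suppression_percent
      }
      mt$selected <- FALSE
      sel_try <- tryCatch(select_responsive_peak(mt), error = function(e) NULL)
      if (!is.null(sel_try)) mt$selected[mt$peak_id == sel_try$peak_id] <- TRUE
      matches_all[[length(matches_all) + 1]] <- mt
    }

    for (v in visits) {
      lg <- logs[[keyfun(sid, h, v, "ON", "rest")]]
      sf <- man$stim_frequency[man$subject_id == sid &
                                 man$hemisphere == h][1]
      ftg_rows[[length(ftg_rows) + 1]] <- data.frame(
        hemisphere_id = hid, visit = v,
        ftg = if (is.null(lg)) NA else detect_ftg(lg, sf))
    }
  }

  features <- do.call(rbind, feat)
  matches <- if (length(matches_all)) do.call(rbind, matches_all) else
    data.frame()
  list(features = features, matches = matches, models = models,
       logs = logs, ftg = do.call(rbind, ftg_rows),
       n_peaks_offrest = do.call(rbind, npk_rows),
       skipped = if (length(skipped)) do.call(rbind, skipped) else
         data.frame(cell = character(), message = character()))
}

#' Run the full pipeline: simulate, clean, fit, feature-extract, test
#'
#' End-to-end composition: [generate_cohort()] then [analyze_cohort()]
#' then [consistency_report()]. With `out_dir` given, the feature table,
#' consistent-peak table, ICC tables and a JSON run summary are written;
#' re-running with the identical configuration reproduces identical
#' outputs.
#'
#' @param config an [cohort_config()].
#' @param out_dir optional output directory.
#' @param tolerance peak-matching tolerance (Hz).
#' @param on_error see [analyze_cohort()].
#' @return list with `cohort`, `analysis`, `stats`.
#' @export
run_pipeline <- function(config, out_dir = NULL, tolerance = 2.5,
                         on_error = c("abort", "skip")) {
  cohort <- generate_cohort(config)
  analysis <- analyze_cohort(cohort, tolerance = tolerance,
                             on_error = on_error)
  stats <- consistency_report(analysis$features)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(analysis$features, file.path(out_dir, "features.csv"),
              row.names = FALSE)
    write.csv(analysis$matches, file.path(out_dir, "consistent_peaks.csv"),
              row.names = FALSE)
    export_tables(stats, out_dir)
    jsonlite::write_json(
      list(seed = config$seed, n_subjects = config$n_subjects,
           n_recordings = length(cohort$recordings),
           n_consistent_peaks = nrow(analysis$matches)),
      file.path(out_dir, "run_summary.json"), auto_unbox = TRUE)
  }
  list(cohort = cohort, analysis = analysis, stats = stats)
}

#' Read a cohort configuration from a YAML file
#'
#' Loads a YAML file whose top-level keys are [cohort_config()] arguments
#' (unknown keys are an error; omitted keys take the package defaults) and
#' returns the validated configuration.
#'
#' @param path YAML file.
#' @return an `stn_cohort_config`.
#' @export
read_cohort_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(cohort_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stopf("unknown config keys: %s", paste(bad, collapse = ", "))
  do.call(cohort_config, vals)
}

#' Read a written cohort back from disk
#'
#' Loads the manifest written by [write_cohort()] and every recording it
#' references; a missing file aborts with the identity of the missing
#' cell.
#'
#' @param dir directory containing `manifest.json` and the signal files.
#' @return list with `recordings` and `manifest` (no ledger: reading back
#'   is the real-data entry point and ground truth may not exist).
#' @export
read_cohort <- function(dir) {
  man_path <- file.path(dir, "manifest.json")
  if (!file.exists(man_path)) stopf("no manifest.json in %s", dir)
  man <- jsonlite::read_json(man_path, simplifyVector = TRUE)
  recordings <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    g <- man[i, ]
    if (!file.exists(g$file_path)) {
      stopf("missing recording for %s %s visit %s %s-%s: %s",
            g$subject_id, g$hemisphere, g$visit, g$stim_state, g$task,
            g$file_path)
    }
    recordings[[i]] <- read_recording(g$file_path, g)
  }
  list(recordings = recordings, manifest = man)
}

#' Reference cohort characteristics
#'
#' The packaged per-patient characteristics of the twelve-patient
#' reference cohort (chronically implanted bilateral STN-DBS patients with
#' Parkinson's disease): demographics, levodopa-equivalent dose,
#' inter-visit intervals, per-visit stimulation settings and selected
#' beta-peak frequencies per hemisphere.
#'
#' @return data.frame with 12 rows.
#' @export
patient_characteristics <- function() {
  read.csv(system.file("extdata", "patient_characteristics.csv",
                       package = "stnlfp"))
}

#' Summary statistics of a cohort characteristics table
#'
#' Recomputes the marginal summaries of the characteristics table: means
#' and SDs of the demographic and interval columns, the LEDD median and
#' IQR, and the per-side beta-peak selection means. `printed` holds the
#' values rounded the way such cohort tables conventionally report them
#' (days and years to the nearest unit, LEDD to the nearest 10 mg).
#'
#' @param fixture data.frame as returned by [patient_characteristics()].
#' @return list with `raw` (named list of unrounded summaries) and
#'   `printed` (rounded).
#' @export
summarize_cohort <- function(fixture = patient_characteristics()) {
  if (nrow(fixture) != 12) stopf("expected 12 rows, got %d", nrow(fixture))
  need <- c("age_yrs", "disease_duration_yrs", "years_since_initial_surgery",
            "ledd_mg", "days_after_implantation", "days_after_visit1")
  if (!all(need %in% names(fixture))) stopf("fixture is missing columns")
  raw <- list(
    age_mean = mean(fixture$age_yrs), age_sd = sd(fixture$age_yrs),
    disease_duration_mean = mean(fixture$disease_duration_yrs),
    disease_duration_sd = sd(fixture$disease_duration_yrs),
    years_since_surgery_mean = mean(fixture$years_since_initial_surgery),
    years_since_surgery_sd = sd(fixture$years_since_initial_surgery),
    ledd_median = median(fixture$ledd_mg),
    ledd_iqr = unname(quantile(fixture$ledd_mg, c(0.25, 0.75))),
    days_to_visit1_mean = mean(fixture$days_after_implantation),
    days_to_visit1_sd = sd(fixture$days_after_implantation),
    intervisit_mean = mean(fixture$days_after_visit1),
    intervisit_sd = sd(fixture$days_after_visit1),
    beta_peak_v1_l_mean = mean(fixture$beta_peak_v1_l),
    beta_peak_v1_r_mean = mean(fixture$beta_peak_v1_r),
    beta_peak_v2_l_mean = mean(fixture$beta_peak_v2_l),
    beta_peak_v2_r_mean = mean(fixture$beta_peak_v2_r))
  printed <- list(
    age_mean = round(raw$age_mean),
    disease_duration_mean = round(raw$disease_duration_mean),
    years_since_surgery_mean = round(raw$years_since_surgery_mean),
    ledd_median = round(raw$ledd_median / 10) * 10,
    days_to_visit1_mean = round(raw$days_to_visit1_mean),
    intervisit_mean = round(raw$intervisit_mean))
  list(raw = raw, printed = printed)
}

#' Export the consistency-report tables
#'
#' Writes one ICC table per feature as CSV plus a JSON summary of test
#' results and verdicts.
#'
#' @param stats result of [consistency_report()].
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
export_tables <- function(stats, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (feat in names(stats)) {
    p <- file.path(dir, sprintf("icc_%s.csv", feat))
    write.csv(stats[[feat]]$icc, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  summary <- lapply(stats, function(s) {
    list(branch = s$branch, consistent = s$consistent, tests = s$tests)
  })
  jp <- file.path(dir, "stats_summary.json")
  jsonlite::write_json(summary, jp, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  invisible(c(paths, jp))
}
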