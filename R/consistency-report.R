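#' Between-visit ICC table for one feature
#'
#' Computes the ICC (two-way, absolute agreement, single measurement) over
#' visits for each task x stimulation condition, plus delta rows for
#' task-induced changes (rest to finger-to-nose and rest to speech, with
#' stimulation OFF) and stimulation-induced changes (OFF minus ON per
#' task): 6 condition rows + 5 delta rows.
#'
#' @param df long-format data.frame with columns `unit`, `visit`,
#'   `stim_state`, `task`, `value` (one row per unit x visit x condition).
#' @return data.frame with columns `condition`, `icc`, `ci_low`,
#'   `ci_high`, `n`, `category`.
#' @export
icc_table <- function(df) {
  stopifnot(all(c("unit", "visit", "stim_state", "task", "value") %in%
                  names(df)))
  wide <- function(sub) {
    m <- tapply(sub$value, list(sub$unit, sub$visit), mean)
    m[complete.cases(m), , drop = FALSE]
  }
  delta <- function(a, b) {
    # per unit x visit difference a - b (each a condition subset)
    key <- function(s) paste(s$unit, s$visit)
    av <- setNames(a$value, key(a))
    bv <- setNames(b$value, key(b))
    common <- intersect(names(av), names(bv))
    parts <- do.call(rbind, strsplit(common, " "))
    data.frame(unit = parts[, 1], visit = parts[, 2],
               value = av[common] - bv[common])
  }
  cond <- function(st, tk) df[df$stim_state == st & df$task == tk, ]
  rows <- list()
  add <- function(label, sub) {
    m <- wide(sub)
    rows[[length(rows) + 1]] <<- if (nrow(m) >= 3 && ncol(m) >= 2) {
      ic <- icc_absolute_single(m)
      data.frame(condition = label, icc = ic$icc, ci_low = ic$ci_low,
                 ci_high = ic$ci_high, n = ic$n, category = ic$category)
    } else {
      data.frame(condition = label, icc = NA_real_, ci_low = NA_real_,
                 ci_high = NA_real_, n = nrow(m), category = NA_character_)
    }
  }
  tasks <- c("rest", "finger_to_nose", "speech")
  for (st in c("OFF", "ON")) {
    for (tk in tasks) add(paste0(st, "-", tk), cond(st, tk))
  }
  add("OFF rest_to_finger_to_nose",
      delta(cond("OFF", "finger_to_nose"), cond("OFF", "rest")))
  add("OFF rest_to_speech", delta(cond("OFF", "speech"), cond("OFF", "rest")))
  for (tk in tasks) {
    add(paste0("dOFF-ON ", tk), delta(cond("OFF", tk), cond("ON", tk)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Shapiro-Wilk normality gate on the two-way residuals (unit means and
# condition-cell means removed): the additive unit effects would otherwise
# reappear identically in every cell and trip the test.
normality_gate <- function(df, alpha = 0.05) {
  um <- stats::ave(df$value, df$unit)
  cm <- stats::ave(df$value, interaction(df$visit, df$stim_state, df$task))
  resid <- df$value - um - cm + mean(df$value)
  resid <- resid[is.finite(resid)]
  if (length(resid) < 3 || sd(resid) == 0) return(TRUE)
  shapiro.test(resid)$p.value > alpha
}

#' Consistency report for a cohort feature table
#'
#' Runs the reliability battery per feature, mirroring the analysis plan
#' for repeated-visit LFP physiomarkers:
#' \itemize{
#'   \item aperiodic features (`offset`, `exponent`): Shapiro-Wilk gate,
#'     then a Visit x Stimulation x Task repeated-measures ANOVA (normal
#'     branch) or per-condition Wilcoxon visit comparisons (non-normal
#'     branch), plus the 11-row ICC table;
#'   \item periodic features (`band_power`, `peak_width`): per-condition
#'     Wilcoxon signed-rank comparisons of visit 1 vs visit 2 and the ICC
#'     table (width: OFF-rest only).
#' }
#' A feature is flagged `consistent` when no Visit main effect or
#' Visit-involving interaction (ANOVA branch), or no per-condition visit
#' difference (Wilcoxon branch), is significant at `alpha`.
#'
#' @param features long-format feature table with columns
#'   `hemisphere_id`, `peak_id`, `visit`, `stim_state`, `task`,
#'   `feature`, `value`.
#' @param alpha significance level of the consistency verdict.
#' @return named list (per feature) of lists with elements `branch`
#'   (`"anova"` or `"wilcoxon"`), `tests` (data.frame), `icc`
#'   (data.frame), `consistent` (logical).
#' @export
consistency_report <- function(features, alpha = 0.05) {
  out <- list()
  for (feat in intersect(c("offset", "exponent", "band_power", "peak_width"),
                         unique(features$feature))) {
    df <- features[features$feature == feat, ]
    df$unit <- if (feat %in% c("offset", "exponent")) {
      df$hemisphere_id
    } else {
      paste(df$hemisphere_id, df$peak_id, sep = ":")
    }
    aperiodic <- feat %in% c("offset", "exponent")
    # units with incomplete condition sets (e.g. a recording without an
    # artifact-free segment) cannot enter the within-unit ANOVA
    n_cells <- length(unique(interaction(df$visit, df$stim_state, df$task)))
    per_unit <- table(df$unit)
    df <- df[df$unit %in% names(per_unit)[per_unit == n_cells], ]
    use_anova <- aperiodic && normality_gate(df)
    if (use_anova) {
      an <- rm_anova_ws(df, dv = "value", unit = "unit",
                        factors = c("visit", "stim_state", "task"))
      visit_rows <- grepl("visit", an$effect)
      consistent <- all(an$p_reported[visit_rows] > alpha)
      tests <- an
      branch <- "anova"
    } else {
      conds <- unique(df[df$task != "", c("stim_state", "task")])
      tests <- do.call(rbind, lapply(seq_len(nrow(conds)), function(i) {
        sub <- df[df$stim_state == conds$stim_state[i] &
                    df$task == conds$task[i], ]
        m <- tapply(sub$value, list(sub$unit, sub$visit), mean)
        m <- m[complete.cases(m), , drop = FALSE]
        if (nrow(m) < 2 || sd(m[, 2] - m[, 1]) == 0) return(NULL)
        w <- wilcoxon_signed_rank(m[, 2], m[, 1])
        data.frame(stim_state = conds$stim_state[i], task = conds$task[i],
                   z = w$statistic, p = w$p, effect = w$effect,
                   n = nrow(m))
      }))
      consistent <- if (is.null(tests)) NA else all(tests$p > alpha)
      branch <- "wilcoxon"
    }
    icc <- if (feat == "peak_width") {
      sub <- df[df$stim_state == "OFF" & df$task == "rest", ]
      m <- tapply(sub$value, list(sub$unit, sub$visit), mean)
      m <- m[complete.cases(m), , drop = FALSE]
      if (nrow(m) >= 3 && ncol(m) >= 2) {
        ic <- icc_absolute_single(m)
        data.frame(condition = "OFF-rest", icc = ic$icc, ci_low = ic$ci_low,
                   ci_high = ic$ci_high, n = ic$n, category = ic$category)
      } else {
        data.frame(condition = "OFF-rest", icc = NA_real_,
                   ci_low = NA_real_, ci_high = NA_real_, n = nrow(m),
                   category = NA_character_)
      }
    } else {
      icc_table(df)
    }
    out[[feat]] <- list(branch = branch, tests = tests, icc = icc,
                        consistent = consistent)
  }
  out
}
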