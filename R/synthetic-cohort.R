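#' Ground-truth spectral parameters for a simulated recording
#'
#' Bundles the parameters of the generative model for one recording: an
#' aperiodic (1/f-like) component described by an offset (log10 power at
#' 1 Hz) and an exponent (the magnitude of the log-log slope), plus up to a
#' handful of Gaussian peaks expressed in log10-power space.
#'
#' The model for the one-sided power spectral density is, in log10 space,
#' \deqn{L(f) = \mathrm{offset} - \chi \log_{10} f +
#'   \sum_i h_i \exp\{-(f - c_i)^2 / (2 s_i^2)\}}
#' so a peak's `height` is measured above the aperiodic curve and its
#' bandwidth is conventionally reported as `2 * sd`.
#'
#' @param offset log10(uV^2/Hz) of the aperiodic component at 1 Hz.
#' @param exponent spectral exponent chi >= 0 (1/f^chi).
#' @param peaks data.frame with columns `center_frequency` (Hz),
#'   `height` (log10 power above the aperiodic curve) and `sd` (Hz), or
#'   `NULL` for a peak-free spectrum.
#' @param fs sampling rate in Hz, used to validate peak positions.
#' @return an object of class `stn_truth`.
#' @export
ground_truth_spectrum <- function(offset, exponent, peaks = NULL, fs = 250) {
  if (!is.finite(offset)) stopf("offset must be finite")
  if (!is.finite(exponent) || exponent < 0) stopf("exponent must be >= 0")
  if (is.null(peaks)) {
    peaks <- data.frame(center_frequency = numeric(), height = numeric(),
                        sd = numeric())
  }
  peaks <- as.data.frame(peaks)
  stopifnot(all(c("center_frequency", "height", "sd") %in% names(peaks)))
  if (nrow(peaks)) {
    if (any(peaks$center_frequency <= 0 | peaks$center_frequency >= fs / 2)) {
      stopf("peak centers must lie within (0, fs/2)")
    }
    if (any(peaks$sd <= 0)) stopf("peak sd must be > 0")
  }
  structure(list(offset = offset, exponent = exponent, peaks = peaks, fs = fs),
            class = "stn_truth")
}

# log10 one-sided PSD of a ground-truth spectrum on frequency grid f.
# Frequencies below f_floor are clamped so the power law stays finite.
truth_log_psd <- function(truth, f, f_floor = 0.5) {
  lp <- truth$offset - truth$exponent * log10(pmax(f, f_floor))
  pk <- truth$peaks
  if (nrow(pk)) {
    for (i in seq_len(nrow(pk))) {
      lp <- lp + pk$height[i] *
        exp(-(f - pk$center_frequency[i])^2 / (2 * pk$sd[i]^2))
    }
  }
  lp
}

#' Generate a 1/f^chi background series by spectral shaping
#'
#' Draws Gaussian white noise in the frequency domain and scales its
#' amplitudes so that the expected one-sided PSD equals
#' `10^offset / f^exponent`, then inverse-transforms to a real time series.
#' Spectral shaping (rather than an autoregressive approximation) makes the
#' expected spectrum exact, which is what the downstream recovery tests
#' rely on.
#'
#' @param offset log10(uV^2/Hz) at 1 Hz.
#' @param exponent spectral exponent chi >= 0.
#' @param duration length of the series in seconds.
#' @param fs sampling rate in Hz.
#' @param seed integer seed; the same seed yields the identical series.
#' @return numeric vector of `round(duration * fs)` samples (uV).
#' @export
generate_aperiodic_background <- function(offset, exponent, duration, fs,
                                          seed = NULL) {
  if (duration <= 0 || fs <= 0) stopf("duration and fs must be positive")
  if (!is.finite(exponent)) stopf("exponent must be finite")
  n <- round(duration * fs)
  if (n < 2 * fs) stopf("need at least 2 s of samples (duration*fs >= 2*fs)")
  truth <- ground_truth_spectrum(offset, exponent, fs = fs)
  with_seed(seed, shape_noise(truth_log_psd(truth, rfft_freqs(n, fs)), n, fs))
}

rfft_freqs <- function(n, fs) (0:(floor(n / 2))) * fs / n

# Synthesize a real series whose expected one-sided PSD is 10^log_psd.
shape_noise <- function(log_psd, n, fs) {
  nf <- floor(n / 2) + 1
  psd <- 10^log_psd
  psd[1] <- 0                                   # no DC component
  amp <- sqrt(psd * fs * n / 2)
  z <- complex(real = rnorm(nf), imaginary = rnorm(nf)) / sqrt(2)
  z[1] <- 0
  if (n %% 2 == 0) {                            # Nyquist bin must be real
    z[nf] <- complex(real = Re(z[nf]) * sqrt(2), imaginary = 0)
    amp[nf] <- amp[nf] / sqrt(2)
  }
  half <- amp * z
  spec <- if (n %% 2 == 0) {
    c(half, Conj(rev(half[2:(nf - 1)])))
  } else {
    c(half, Conj(rev(half[2:nf])))
  }
  Re(fft(spec, inverse = TRUE)) / n
}

#' Superimpose a narrow-band oscillation on a series
#'
#' Adds a Gaussian bump (in log10-power space) to the spectrum of `x` by
#' rescaling its FFT magnitudes, i.e. the oscillation inherits the random
#' phases of the underlying series so the bump in the log-PSD is exactly
#' Gaussian in expectation. `height = 0` returns the input unchanged.
#'
#' @param x numeric series.
#' @param fs sampling rate (Hz).
#' @param center_frequency peak center (Hz), must be below Nyquist.
#' @param height log10-power of the bump at its center.
#' @param sd Gaussian width of the bump (Hz).
#' @return numeric series of the same length.
#' @export
add_oscillation <- function(x, fs, center_frequency, height, sd) {
  if (center_frequency <= 0 || center_frequency >= fs / 2) {
    stopf("center_frequency must lie within (0, fs/2)")
  }
  if (sd <= 0) stopf("sd must be > 0")
  if (height == 0) return(x)
  n <- length(x)
  f <- rfft_freqs(n, fs)
  gain <- 10^(height * exp(-(f - center_frequency)^2 / (2 * sd^2)) / 2)
  full_gain <- if (n %% 2 == 0) {
    c(gain, rev(gain[2:(length(gain) - 1)]))
  } else {
    c(gain, rev(gain[2:length(gain)]))
  }
  Re(fft(fft(x) * full_gain, inverse = TRUE)) / n
}

# Stylized biphasic QRS wavelet (~80 ms at fs): the first derivative of a
# Gaussian, normalized to unit peak amplitude. Fixed morphology; clinical
# realism is out of scope -- the point is to exercise beat-locked SVD
# suppression.
qrs_template <- function(fs, width_s = 0.08) {
  half <- round(width_s * fs / 2)
  t <- (-half:half) / fs
  s <- width_s / 5
  w <- -t / s * exp(-t^2 / (2 * s^2))
  w / max(abs(w))
}

#' Contaminate an LFP series with ECG, line-noise and FTG artifacts
#'
#' Adds (i) a QRS-shaped beat train coupled into the LFP, (ii) a 50 Hz
#' line-noise sinusoid, and (iii) optionally a narrow "finely-tuned gamma"
#' (FTG) tone at half the stimulation frequency. A clean copy of the beat
#' train (with small measurement noise) is returned as the simultaneous ECG
#' channel so that R-peak detection can be exercised downstream.
#'
#' Gains are expressed relative to the standard deviation of the input so
#' zero gains are exact no-ops.
#'
#' @param x LFP series (uV).
#' @param fs sampling rate (Hz).
#' @param heart_rate beats per minute, within `[40, 120]`.
#' @param ecg_coupling_gain amplitude of the coupled QRS train relative to
#'   `sd(x)`; 0 disables ECG contamination.
#' @param line_noise_amplitude amplitude of the 50 Hz sinusoid relative to
#'   `sd(x)`.
#' @param ftg logical; add a tone at `stim_frequency / 2`.
#' @param stim_frequency stimulation frequency in Hz (required when
#'   `ftg = TRUE`).
#' @param ftg_amplitude amplitude of the FTG tone relative to `sd(x)`.
#' @param seed integer seed for beat-time jitter and ECG noise.
#' @return list with elements `lfp` (contaminated series), `ecg` (the ECG
#'   channel, arbitrary mV units) and `beat_times` (ground-truth R-peak
#'   times in seconds).
#' @export
add_artifacts <- function(x, fs, heart_rate = 70, ecg_coupling_gain = 0,
                          line_noise_amplitude = 0, ftg = FALSE,
                          stim_frequency = NULL, ftg_amplitude = 0.4,
                          seed = NULL) {
  if (heart_rate < 40 || heart_rate > 120) {
    stopf("heart_rate must be within [40, 120] bpm")
  }
  if (ftg && is.null(stim_frequency)) {
    stopf("stim_frequency is required when ftg = TRUE")
  }
  n <- length(x)
  dur <- n / fs
  s <- sd(x)
  with_seed(seed, {
    rr <- 60 / heart_rate
    n_beats <- ceiling(dur / rr) + 2
    beat_times <- runif(1, 0, rr) + cumsum(c(0, rr * (1 + rnorm(n_beats - 1, 0, 0.02))))
    beat_times <- beat_times[beat_times < dur - 0.05]
    tmpl <- qrs_template(fs)
    half <- (length(tmpl) - 1) / 2
    train <- numeric(n)
    for (bt in beat_times) {
      j <- round(bt * fs) + 1
      idx <- (j - half):(j + half)
      ok <- idx >= 1 & idx <= n
      train[idx[ok]] <- train[idx[ok]] + tmpl[ok]
    }
    tt <- (seq_len(n) - 1) / fs
    lfp <- x + ecg_coupling_gain * s * train +
      line_noise_amplitude * s * sin(2 * pi * 50 * tt)
    if (ftg) {
      lfp <- lfp + ftg_amplitude * s *
        sin(2 * pi * (stim_frequency / 2) * tt)
    }
    ecg <- train + rnorm(n, 0, 0.02)
    list(lfp = lfp, ecg = ecg, beat_times = beat_times)
  })
}

#' Configuration for a simulated recording cohort
#'
#' Collects every tunable of the cohort generator. The defaults emulate the
#' reference study design: 12 subjects, two hemispheres, two visits at
#' least weeks apart, stimulation OFF/ON, and three tasks (about 60 s of
#' rest and 30 s each of finger-to-nose per hand and speech) sampled at
#' 250 Hz, with ECG, 50 Hz line noise and (in a subset of hemispheres)
#' stimulation-entrained finely-tuned gamma at half the stimulation
#' frequency.
#'
#' Effect sizes (`effects`) are signed deltas applied to the ground-truth
#' spectra and are free parameters of the simulation: the directions mirror
#' the reference findings (stimulation raises offset and exponent and
#' suppresses beta power; movement and speech suppress beta power with
#' stimulation OFF; speech raises the offset, more so with stimulation ON),
#' while the magnitudes are the package's own documented choices.
#'
#' @param n_subjects number of subjects (> 0).
#' @param visits number of visits (the analysis layer assumes 2).
#' @param fs sampling rate (Hz).
#' @param durations named list of task durations in seconds.
#' @param baseline named list: means/SDs of subject-level offset and
#'   exponent, beta-peak count probabilities and parameter ranges.
#' @param effects named list of signed condition deltas (see Details).
#' @param between_visit_jitter named list of between-visit SDs for offset,
#'   exponent, peak height (log10) and peak center frequency (Hz), plus
#'   `peak_dropout`, the probability that a non-primary peak is absent at a
#'   given visit.
#' @param heart_rate beats per minute.
#' @param ecg_coupling_gain,line_noise_amplitude,ftg_amplitude artifact
#'   gains relative to the clean-signal SD.
#' @param stim_frequency stimulation frequency (Hz), recycled per
#'   hemisphere.
#' @param ftg_probability probability that a hemisphere expresses
#'   finely-tuned gamma during stimulation ON.
#' @param seed integer seed controlling the whole cohort.
#' @return an object of class `stn_cohort_config` (a validated list).
#' @export
cohort_config <- function(n_subjects = 12,
                          visits = 2,
                          fs = 250,
                          durations = list(rest = 60, finger_to_nose = 30,
                                           speech = 30),
                          baseline = list(offset_mean = 1.0, offset_sd = 0.4,
                                          exponent_mean = 1.5, exponent_sd = 0.3,
                                          n_peak_prob = c(0.15, 0.45, 0.40),
                                          peak_cf_range = c(14, 32),
                                          peak_height_range = c(0.35, 0.8),
                                          peak_sd_range = c(1.0, 2.5)),
                          effects = list(stim_offset = 0.15,
                                         stim_exponent = 0.25,
                                         stim_beta = -0.25,
                                         task_beta = -0.18,
                                         task_beta_on_scale = 0.3,
                                         speech_offset = 0.10,
                                         task_stim_offset = 0.08,
                                         task_stim_exponent = 0.08),
                          between_visit_jitter = list(offset = 0.10,
                                                      exponent = 0.10,
                                                      peak_height = 0.08,
                                                      peak_cf = 0.8,
                                                      peak_dropout = 0.12),
                          heart_rate = 70,
                          ecg_coupling_gain = 1.0,
                          line_noise_amplitude = 0.15,
                          ftg_amplitude = 0.4,
                          stim_frequency = 130,
                          ftg_probability = 0.5,
                          seed = 1L) {
  if (n_subjects < 1) stopf("n_subjects must be >= 1")
  if (any(unlist(durations) <= 0)) stopf("all durations must be > 0")
  jt <- between_visit_jitter
  if (any(unlist(jt[c("offset", "exponent", "peak_height", "peak_cf")]) < 0)) {
    stopf("jitter SDs must be >= 0")
  }
  cfg <- list(n_subjects = as.integer(n_subjects), visits = as.integer(visits),
              fs = fs, durations = durations, baseline = baseline,
              effects = effects, between_visit_jitter = jt,
              heart_rate = heart_rate, ecg_coupling_gain = ecg_coupling_gain,
              line_noise_amplitude = line_noise_amplitude,
              ftg_amplitude = ftg_amplitude, stim_frequency = stim_frequency,
              ftg_probability = ftg_probability, seed = as.integer(seed))
  class(cfg) <- "stn_cohort_config"
  cfg
}

#' Construct a single LFP recording object
#'
#' The container used throughout the package for one channel-pair's time
#' series plus its cell metadata. Users with their own data can build
#' recordings directly (or via [read_recording()]) and feed them to
#' [clean_recording()] / [analyze_recording()].
#'
#' @param subject_id,hemisphere,visit,stim_state,task cell metadata
#'   (hemisphere `"L"`/`"R"`, stim_state `"OFF"`/`"ON"`).
#' @param fs sampling rate (Hz).
#' @param lfp LFP samples (uV), finite.
#' @param ecg optional simultaneous ECG channel at the same rate.
#' @param stim_frequency stimulation frequency (Hz) or `NA`.
#' @param events optional data.frame of (label, time) event markers.
#' @return an object of class `stn_recording`.
#' @export
new_recording <- function(subject_id, hemisphere, visit, stim_state, task,
                          fs, lfp, ecg = NULL, stim_frequency = NA,
                          events = NULL) {
  if (!all(is.finite(lfp))) stopf("lfp must be finite")
  structure(list(subject_id = subject_id, hemisphere = hemisphere,
                 visit = visit, stim_state = stim_state, task = task,
                 fs = fs, lfp = lfp, ecg = ecg,
                 stim_frequency = stim_frequency, events = events),
            class = "stn_recording")
}

#' @export
print.stn_recording <- function(x, ...) {
  cat(sprintf("<stn_recording> %s %s visit %s %s-%s: %.1f s @ %g Hz%s\n",
              x$subject_id, x$hemisphere, x$visit, x$stim_state, x$task,
              length(x$lfp) / x$fs, x$fs,
              if (!is.null(x$ecg)) " (+ECG)" else ""))
  invisible(x)
}

# Condition-specific ground truth for one recording cell, derived from the
# visit-level truth by applying the configured stimulation/task deltas.
condition_truth <- function(vt, stim_state, task, eff, fs) {
  offset <- vt$offset
  exponent <- vt$exponent
  peaks <- vt$peaks
  on <- stim_state == "ON"
  if (on) {
    offset <- offset + eff$stim_offset
    exponent <- exponent + eff$stim_exponent
    if (nrow(peaks)) {
      peaks$height <- peaks$height + eff$stim_beta * peaks$responsiveness
    }
  }
  if (task != "rest") {
    scale <- if (on) eff$task_beta_on_scale else 1
    if (nrow(peaks)) peaks$height <- peaks$height + eff$task_beta * scale
    if (task == "speech") {
      offset <- offset + eff$speech_offset + if (on) eff$task_stim_offset else 0
    } else if (on) {
      offset <- offset + eff$task_stim_offset
    }
    if (on) exponent <- exponent + eff$task_stim_exponent
  }
  if (nrow(peaks)) peaks$height <- pmax(peaks$height, 0.05)
  ground_truth_spectrum(offset, exponent,
                        peaks[peaks$present, c("center_frequency", "height", "sd")],
                        fs = fs)
}

#' Generate a full simulated cohort with ground-truth ledger
#'
#' Produces one recording per subject x hemisphere x visit x stimulation
#' state x task cell (the finger-to-nose task is recorded once per hand;
#' downstream analysis uses the hemisphere contralateral to the moving
#' hand). Every recording is built from a known ground-truth spectrum that
#' is stored in the returned ledger, so recovery by the analysis chain can
#' be scored exactly. The whole cohort is a deterministic function of the
#' configuration (including its seed).
#'
#' @param config a [cohort_config()].
#' @return an object of class `stn_cohort`: list with `recordings` (list of
#'   `stn_recording`), `ledger` (data.frame of per-cell ground truth;
#'   peak parameters nested in the `peaks` list-column), `manifest`
#'   (data.frame of cell metadata) and `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "stn_cohort_config"))
  fs <- config$fs
  eff <- config$effects
  jt <- config$between_visit_jitter
  bl <- config$baseline
  tasks <- c("rest", "finger_to_nose_left", "finger_to_nose_right", "speech")

  grid <- expand.grid(subject = seq_len(config$n_subjects),
                      hemisphere = c("L", "R"),
                      visit = seq_len(config$visits),
                      stim_state = c("OFF", "ON"),
                      task = tasks,
                      stringsAsFactors = FALSE)
  grid <- grid[order(grid$subject, grid$hemisphere, grid$visit,
                     grid$stim_state, grid$task), ]
  seeds <- derive_seeds(config$seed, nrow(grid) + 1L)

  # subject/hemisphere-level baselines and visit-level jitter, drawn from a
  # dedicated stream so recording synthesis seeds stay decoupled
  base <- with_seed(seeds[1], {
    lapply(seq_len(config$n_subjects), function(s) {
      lapply(c(L = "L", R = "R"), function(h) {
        n_pk <- sample.int(length(bl$n_peak_prob), 1, prob = bl$n_peak_prob)
        cf <- sort(runif(n_pk, bl$peak_cf_range[1], bl$peak_cf_range[2]))
        while (n_pk > 1 && min(diff(cf)) < 4) {
          cf <- sort(runif(n_pk, bl$peak_cf_range[1], bl$peak_cf_range[2]))
        }
        peaks <- data.frame(
          peak_id = seq_len(n_pk),
          center_frequency = cf,
          height = runif(n_pk, bl$peak_height_range[1], bl$peak_height_range[2]),
          sd = runif(n_pk, bl$peak_sd_range[1], bl$peak_sd_range[2]),
          responsiveness = runif(n_pk, 0.4, 1.6))
        o0 <- rnorm(1, bl$offset_mean, bl$offset_sd)
        e0 <- max(0.3, rnorm(1, bl$exponent_mean, bl$exponent_sd))
        visits <- lapply(seq_len(config$visits), function(v) {
          pk <- peaks
          pk$center_frequency <- pk$center_frequency + rnorm(n_pk, 0, jt$peak_cf)
          pk$height <- pmax(pk$height + rnorm(n_pk, 0, jt$peak_height), 0.1)
          pk$present <- c(TRUE, runif(n_pk - 1) > jt$peak_dropout)
          list(offset = o0 + rnorm(1, 0, jt$offset),
               exponent = max(0.3, e0 + rnorm(1, 0, jt$exponent)),
               peaks = pk)
        })
        list(visits = visits, ftg = runif(1) < config$ftg_probability)
      })
    })
  })

  recordings <- vector("list", nrow(grid))
  ledger <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    vt <- base[[g$subject]][[g$hemisphere]]$visits[[g$visit]]
    # movement affects the hemisphere contralateral to the moving hand
    eff_task <- switch(g$task,
                       rest = "rest",
                       speech = "speech",
                       finger_to_nose_left =
                         if (g$hemisphere == "R") "finger_to_nose" else "rest",
                       finger_to_nose_right =
                         if (g$hemisphere == "L") "finger_to_nose" else "rest")
    truth <- condition_truth(vt, g$stim_state, eff_task, eff, fs)
    dur <- if (g$task == "rest") config$durations$rest else {
      config$durations[[sub("_(left|right)$", "", g$task)]]
    }
    sd_rec <- seeds[i + 1L]
    x <- generate_aperiodic_background(truth$offset, truth$exponent, dur, fs,
                                       seed = sd_rec)
    if (nrow(truth$peaks)) {
      for (p in seq_len(nrow(truth$peaks))) {
        x <- add_oscillation(x, fs, truth$peaks$center_frequency[p],
                             truth$peaks$height[p], truth$peaks$sd[p])
      }
    }
    ftg_here <- base[[g$subject]][[g$hemisphere]]$ftg && g$stim_state == "ON"
    art <- add_artifacts(x, fs, heart_rate = config$heart_rate,
                         ecg_coupling_gain = config$ecg_coupling_gain,
                         line_noise_amplitude = config$line_noise_amplitude,
                         ftg = ftg_here, stim_frequency = config$stim_frequency,
                         ftg_amplitude = config$ftg_amplitude,
                         seed = sd_rec %% .Machine$integer.max)
    sid <- sprintf("S%02d", g$subject)
    recordings[[i]] <- new_recording(sid, g$hemisphere, g$visit, g$stim_state,
                                     g$task, fs, art$lfp, art$ecg,
                                     stim_frequency = config$stim_frequency,
                                     events = data.frame(label = "task_start",
                                                         time = 0))
    ledger[[i]] <- data.frame(subject_id = sid, hemisphere = g$hemisphere,
                              visit = g$visit, stim_state = g$stim_state,
                              task = g$task, offset = truth$offset,
                              exponent = truth$exponent,
                              ftg = ftg_here,
                              n_peaks = nrow(truth$peaks))
    ledger[[i]]$peaks <- list(truth$peaks)
  }
  ledger <- do.call(rbind, ledger)
  manifest <- data.frame(index = seq_len(nrow(grid)),
                         subject_id = sprintf("S%02d", grid$subject),
                         hemisphere = grid$hemisphere, visit = grid$visit,
                         stim_state = grid$stim_state, task = grid$task,
                         fs = fs, stim_frequency = config$stim_frequency,
                         stringsAsFactors = FALSE)
  structure(list(recordings = recordings, ledger = ledger,
                 manifest = manifest, config = config),
            class = "stn_cohort")
}

#' @export
print.stn_cohort <- function(x, ...) {
  cat(sprintf("<stn_cohort> %d recordings (%d subjects, %d visits), fs = %g Hz\n",
              length(x$recordings), x$config$n_subjects, x$config$visits,
              x$config$fs))
  invisible(x)
}

#' Write a cohort to delimited text files plus JSON manifest and ledger
#'
#' One tab-separated file per recording (columns `time_s`, `lfp_uV` and,
#' when present, `ecg_mV`), a JSON manifest with per-recording metadata and
#' file paths, and a JSON ground-truth ledger.
#'
#' @param cohort an `stn_cohort`.
#' @param dir output directory (created if needed).
#' @return invisibly, the manifest data.frame with a `file_path` column.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "stn_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- cohort$manifest
  man$file_path <- file.path(dir, sprintf(
    "%s_%s_v%d_%s_%s.tsv", man$subject_id, man$hemisphere, man$visit,
    man$stim_state, man$task))
  for (i in seq_along(cohort$recordings)) {
    r <- cohort$recordings[[i]]
    df <- data.frame(time_s = (seq_along(r$lfp) - 1) / r$fs, lfp_uV = r$lfp)
    if (!is.null(r$ecg)) df$ecg_mV <- r$ecg
    write.table(df, man$file_path[i], sep = "\t", row.names = FALSE,
                quote = FALSE)
  }
  jsonlite::write_json(man, file.path(dir, "manifest.json"), dataframe = "rows")
  led <- cohort$ledger
  led$peaks <- lapply(led$peaks, function(p) p)
  jsonlite::write_json(led, file.path(dir, "ledger.json"), dataframe = "rows")
  invisible(man)
}

#' Read one recording back from a delimited signal file
#'
#' @param path a file written by [write_cohort()] (or user data in the same
#'   format: columns `time_s`, `lfp_uV`, optional `ecg_mV`).
#' @param meta one manifest row (list or 1-row data.frame) with the cell
#'   metadata.
#' @return an `stn_recording`.
#' @export
read_recording <- function(path, meta) {
  if (!file.exists(path)) stopf("recording file missing: %s", path)
  df <- read.delim(path)
  fs <- round(1 / median(diff(df$time_s)))
  new_recording(meta$subject_id, meta$hemisphere, meta$visit, meta$stim_state,
                meta$task, fs, df$lfp_uV,
                ecg = if ("ecg_mV" %in% names(df)) df$ecg_mV else NULL,
                stim_frequency = meta$stim_frequency)
}
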