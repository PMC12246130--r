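#' Zero-phase 3 Hz high-pass filter
#'
#' Bidirectional (forward-backward) 4th-order Butterworth high-pass,
#' removing DC and slow drifts below the cutoff. Because the filter is
#' applied in both directions the magnitude response is squared: a tone at
#' the cutoff emerges with amplitude 1/2 rather than 1/sqrt(2).
#'
#' @param x numeric series.
#' @param fs sampling rate (Hz).
#' @param cutoff high-pass cutoff (Hz).
#' @param order filter order of the single pass.
#' @return filtered series of the same length.
#' @export
highpass_3hz <- function(x, fs, cutoff = 3, order = 4) {
  if (length(x) < 6 * fs / cutoff) {
    stopf("series too short for a %g Hz high-pass (need > %d samples)",
          cutoff, ceiling(6 * fs / cutoff))
  }
  bf <- signal::butter(order, cutoff / (fs / 2), type = "high")
  as.numeric(signal::filtfilt(bf, x))
}

#' Hampel filter on the magnitude spectrum
#'
#' Suppresses narrow-band spectral outliers within a frequency band. The
#' recording's FFT magnitude spectrum is compared bin-wise to its sliding
#' median `m` (window of `window_bins` bins); the local robust scale is
#' `1.4826` times the sliding median of the absolute deviations
#' `|mag - m|`. Bins inside the band whose deviation exceeds
#' `threshold` times that scale are replaced by the local median (phases
#' preserved) before inverse-transforming. This removes prominent
#' narrow-band peaks at recurrent frequencies while leaving the broadband
#' shape intact.
#'
#' @param x numeric series.
#' @param fs sampling rate (Hz).
#' @param band two-element numeric, frequency range to screen (Hz).
#' @param threshold outlier threshold in robust-SD units (study range
#'   2.6-3.5, default 3.0).
#' @param window_bins sliding window length in bins (odd).
#' @return list with `series` (filtered) and `flagged_frequencies` (Hz of
#'   suppressed bins).
#' @export
spectral_hampel <- function(x, fs, band, threshold = 3.0, window_bins = 11) {
  if (length(band) != 2 || band[1] >= band[2]) stopf("band must be [f_lo, f_hi]")
  if (band[1] <= 0 || band[2] > fs / 2) stopf("band must lie within (0, fs/2]")
  n <- length(x)
  X <- fft(x)
  nf <- floor(n / 2) + 1
  f <- rfft_freqs(n, fs)
  mag <- Mod(X[1:nf])
  m <- stats::runmed(mag, window_bins, endrule = "median")
  dev <- abs(mag - m)
  scale <- 1.4826 * stats::runmed(dev, window_bins, endrule = "median")
  # floor the robust scale so numerically constant neighbourhoods (MAD at
  # machine precision) are not all flagged
  scale <- pmax(scale, 1e-9 * m)
  in_band <- f >= band[1] & f <= band[2]
  # only bins whose whole deviation window is made of full-window medians
  # are eligible; bins near the spectrum edges are never flagged
  half <- (window_bins - 1) / 2
  full_win <- seq_along(mag) > 2 * half & seq_along(mag) <= nf - 2 * half
  flagged <- which(in_band & full_win & scale > 0 & dev > threshold * scale)
  med_repl <- m[flagged]
  if (length(flagged)) {
    scale <- med_repl / pmax(mag[flagged], .Machine$double.eps)
    X[flagged] <- X[flagged] * scale
    # mirror to the conjugate half so the output stays real
    conj_idx <- n - flagged + 2
    keep <- conj_idx >= 2 & conj_idx <= n
    X[conj_idx[keep]] <- Conj(X[flagged[keep]])
    x <- Re(fft(X, inverse = TRUE)) / n
  }
  list(series = x, flagged_frequencies = f[flagged])
}

# Second-order IIR notch (biquad) with unity gain away from f0 and a zero
# at f0; bandwidth is the -3 dB width.
design_notch <- function(f0, fs, bandwidth = 1) {
  w0 <- 2 * pi * f0 / fs
  dw <- 2 * pi * bandwidth / fs
  gb <- 1 / sqrt(2)
  beta <- (sqrt(1 - gb^2) / gb) * tan(dw / 2)
  gain <- 1 / (1 + beta)
  list(b = gain * c(1, -2 * cos(w0), 1),
       a = c(1, -2 * gain * cos(w0), 2 * gain - 1))
}

#' Zero-phase notch filters
#'
#' Applies a cascade of narrow (default 1 Hz bandwidth) second-order IIR
#' notches, each run forward and backward for zero phase. An empty
#' frequency list is the identity.
#'
#' @param x numeric series.
#' @param fs sampling rate (Hz).
#' @param frequencies numeric vector of notch center frequencies (Hz).
#' @param bandwidth -3 dB bandwidth of each notch (Hz).
#' @return filtered series.
#' @export
notch_filter <- function(x, fs, frequencies, bandwidth = 1) {
  for (f0 in frequencies) {
    if (f0 >= fs / 2) stopf("notch frequency %g Hz is at/above Nyquist", f0)
    nd <- design_notch(f0, fs, bandwidth)
    x <- as.numeric(signal::filtfilt(filt = nd$b, a = nd$a, x = x))
  }
  x
}

#' Detect R-peaks in an ECG channel
#'
#' A lightweight energy-based detector (differentiate, square, integrate,
#' adaptive threshold) with a 250 ms refractory period, standing in for the
#' manually reviewed detection of the original workflow; the returned
#' vector can be edited before being passed on to
#' [suppress_ecg_svd()].
#'
#' @param ecg ECG series sampled at the LFP rate.
#' @param fs sampling rate (Hz).
#' @return numeric vector of beat times (s), increasing; empty (with
#'   attribute `warning`) for flat input.
#' @export
detect_r_peaks <- function(ecg, fs) {
  if (sd(ecg) == 0) {
    return(structure(numeric(0), warning = "flat ECG, no beats detected"))
  }
  d <- c(0, diff(ecg))
  energy <- d^2
  win <- round(0.06 * fs)
  energy <- as.numeric(stats::filter(energy, rep(1 / win, win), sides = 2))
  energy[is.na(energy)] <- 0
  thr <- 0.3 * quantile(energy, 0.995)
  refractory <- round(0.25 * fs)
  above <- energy > thr
  peaks <- integer(0)
  i <- 1
  n <- length(ecg)
  while (i <= n) {
    if (above[i]) {
      j <- i
      while (j < n && above[j + 1]) j <- j + 1
      seg <- i:j
      cand <- seg[which.max(energy[seg])]
      # refine to the extremum of |ecg| within +/-40 ms
      lo <- max(1, cand - round(0.04 * fs))
      hi <- min(n, cand + round(0.04 * fs))
      cand <- (lo:hi)[which.max(abs(ecg[lo:hi]))]
      if (!length(peaks) || cand - peaks[length(peaks)] >= refractory) {
        peaks <- c(peaks, cand)
      }
      i <- j + max(1, refractory %/% 2)
    } else {
      i <- i + 1
    }
  }
  (peaks - 1) / fs
}

#' Suppress ECG artifacts by beat-locked SVD template subtraction
#'
#' Epochs the LFP from 250 ms before to 400 ms after each R-peak, stacks
#' the epochs into a matrix and takes its singular value decomposition.
#' Components whose temporal pattern correlates with the mean beat waveform
#' at `|r| >=` `r_threshold` (at most `max_components`) are taken as
#' cardiac, reconstructed per epoch and subtracted with cosine-tapered
#' epoch edges; samples outside epochs are untouched. With fewer than 8
#' beats no suppression is attempted. When consecutive beats are closer
#' than the epoch span, the subtraction window of each epoch is truncated
#' at the midpoint between beats so nothing is subtracted twice.
#'
#' @param x LFP series.
#' @param fs sampling rate (Hz).
#' @param beat_times R-peak times in seconds (see [detect_r_peaks()]).
#' @param r_threshold absolute correlation with the mean beat waveform
#'   required to call a component cardiac.
#' @param max_components cap on the number of subtracted components.
#' @param pre,post epoch extent around each R-peak (s).
#' @return list with `series`, `n_components_used` and `n_beats`.
#' @export
suppress_ecg_svd <- function(x, fs, beat_times, r_threshold = 0.8,
                             max_components = 3, pre = 0.25, post = 0.4) {
  n <- length(x)
  ipre <- round(pre * fs)
  ipost <- round(post * fs)
  len <- ipre + ipost + 1
  centers <- round(beat_times * fs) + 1
  centers <- centers[centers - ipre >= 1 & centers + ipost <= n]
  if (length(centers) < 8) {
    return(list(series = x, n_components_used = 0L,
                n_beats = length(centers)))
  }
  ep <- t(vapply(centers, function(c0) x[(c0 - ipre):(c0 + ipost)],
                 numeric(len)))
  mean_beat <- colMeans(ep)
  sv <- svd(ep)
  ncomp <- min(ncol(sv$v), 10)
  r <- vapply(seq_len(ncomp), function(k) {
    suppressWarnings(abs(cor(sv$v[, k], mean_beat)))
  }, numeric(1))
  r[is.na(r)] <- 0
  sel <- which(r >= r_threshold)
  sel <- head(sel[order(-sv$d[sel])], max_components)
  if (!length(sel)) {
    return(list(series = x, n_components_used = 0L,
                n_beats = length(centers)))
  }
  # Cardiac energy has to outweigh oscillations outside the QRS region:
  # restrict the selected components to the support of the mean-beat
  # envelope (cosine-tapered), which strips the background tilt that an
  # unrestricted singular vector picks up.
  env <- stats::filter(abs(mean_beat), rep(1 / 5, 5), sides = 2)
  env[is.na(env)] <- 0
  sup <- which(env > 0.15 * max(env))
  lo <- max(1, min(sup) - 4)
  hi <- min(len, max(sup) + 4)
  mask <- numeric(len)
  mask[lo:hi] <- tukey_window(hi - lo + 1, 0.3)
  V <- sv$v[, sel, drop = FALSE] * mask
  V <- qr.Q(qr(V))                             # re-orthonormalize
  # Per-epoch coefficients carry the epoch's own background projection on
  # top of the cardiac amplitude; shrink them towards the across-beat
  # mean, with the noise level estimated from non-cardiac components.
  # Stable coupling then subtracts a common template (no background
  # leakage) while genuinely varying coupling is still tracked.
  coef <- ep %*% V
  rest <- setdiff(seq_len(ncomp), sel)
  noise_var <- if (length(rest)) {
    median(apply(sweep(sv$u[, rest, drop = FALSE], 2, sv$d[rest], "*"),
                 2, var))
  } else {
    0
  }
  for (k in seq_len(ncol(coef))) {
    v <- var(coef[, k])
    lam <- if (v > 0) max(0, 1 - noise_var / v) else 0
    coef[, k] <- mean(coef[, k]) + lam * (coef[, k] - mean(coef[, k]))
  }
  recon <- coef %*% t(V)
  out <- x
  for (b in seq_along(centers)) {
    idx <- (centers[b] - ipre):(centers[b] + ipost)
    art <- recon[b, ]
    # truncate at midpoints to neighbouring beats
    lo_lim <- if (b > 1) ceiling((centers[b - 1] + centers[b]) / 2) else 1L
    hi_lim <- if (b < length(centers)) {
      floor((centers[b] + centers[b + 1]) / 2)
    } else {
      n
    }
    ok <- idx >= lo_lim & idx <= hi_lim
    out[idx[ok]] <- out[idx[ok]] - art[ok]
  }
  list(series = out, n_components_used = length(sel),
       n_beats = length(centers))
}

tukey_window <- function(n, alpha) {
  w <- rep(1, n)
  edge <- floor(alpha * (n - 1) / 2)
  if (edge > 0) {
    k <- 0:edge
    ramp <- 0.5 * (1 + cos(pi * (2 * k / (alpha * (n - 1)) - 1)))
    w[k + 1] <- ramp
    w[n - k] <- ramp
  }
  w
}

#' Select artifact-free 10-s segments
#'
#' Tiles the cleaned series into consecutive windows of `length_s` seconds
#' and selects, earliest first, the tiles in which every sample lies
#' within the recording's mean +/- 5 SD (mean and SD computed on the full
#' cleaned series). Returns up to `n_wanted` windows; finding none is an
#' error.
#'
#' @param x cleaned series.
#' @param fs sampling rate (Hz).
#' @param n_wanted maximum number of segments (study convention: 2).
#' @param length_s segment length in seconds.
#' @param n_sd admissible deviation from the mean, in SDs.
#' @return list with `segments` (list of numeric vectors) and
#'   `start_times` (s).
#' @export
select_segments <- function(x, fs, n_wanted = 2, length_s = 10, n_sd = 5) {
  n <- length(x)
  win <- round(length_s * fs)
  if (n < win) stopf("series shorter than one %g-s segment", length_s)
  mu <- mean(x)
  s <- sd(x)
  bad <- abs(x - mu) > n_sd * s
  segments <- list()
  starts <- integer(0)
  for (i in seq(1, n - win + 1, by = win)) {
    if (length(segments) >= n_wanted) break
    if (!any(bad[i:(i + win - 1)])) {
      segments[[length(segments) + 1]] <- x[i:(i + win - 1)]
      starts <- c(starts, i)
    }
  }
  if (!length(segments)) stopf("no artifact-free %g-s segment found", length_s)
  list(segments = segments, start_times = (starts - 1) / fs)
}

# Flag a candidate finely-tuned gamma tone: is the periodogram bin nearest
# stim_frequency/2 more than `ratio` times the local median?
propose_ftg_notch <- function(x, fs, stim_frequency, ratio = 10,
                              half_window = 20) {
  n <- length(x)
  f <- rfft_freqs(n, fs)
  p <- (Mod(fft(x)[seq_along(f)])^2) / (fs * n)
  target <- stim_frequency / 2
  j <- which.min(abs(f - target))
  lo <- max(2, j - half_window)
  hi <- min(length(f), j + half_window)
  local <- p[setdiff(lo:hi, (j - 1):(j + 1))]
  is.finite(p[j]) && p[j] > ratio * median(local)
}

#' Run the five-step artifact-suppression chain on one recording
#'
#' Applies, in order: (a) zero-phase 3 Hz high-pass; (b) spectral Hampel
#' filter over 30-125 Hz; (c) notch filters (50 Hz line noise, any extra
#' frequencies, and a notch at half the stimulation frequency when a
#' finely-tuned gamma tone is detected there); (d) SVD-based ECG
#' beat-template subtraction when an ECG channel is available; (e) spectral
#' Hampel filter over 3.8-40 Hz. Finally selects up to two artifact-free
#' 10-s segments.
#'
#' @param recording an `stn_recording`.
#' @param hampel_threshold_1 threshold of the 30-125 Hz Hampel step
#'   (admissible range 2.6-3.5).
#' @param hampel_threshold_2 threshold of the 3.8-40 Hz Hampel step
#'   (admissible range 2.6-3.3).
#' @param notch_frequencies base notch list (Hz).
#' @param beat_times optional externally reviewed R-peak times (s);
#'   detected from the ECG channel when `NULL`.
#' @param segment_length_s segment length for [select_segments()].
#' @return list with `series` (cleaned), `log` (an `stn_cleaning_log`) and
#'   `segments` (a segment pair, see [select_segments()]).
#' @export
clean_recording <- function(recording,
                            hampel_threshold_1 = 3.0,
                            hampel_threshold_2 = 3.0,
                            notch_frequencies = 50,
                            beat_times = NULL,
                            segment_length_s = 10) {
  stopifnot(inherits(recording, "stn_recording"))
  if (hampel_threshold_1 < 2.6 || hampel_threshold_1 > 3.5) {
    stopf("hampel_threshold_1 outside admissible range [2.6, 3.5]")
  }
  if (hampel_threshold_2 < 2.6 || hampel_threshold_2 > 3.3) {
    stopf("hampel_threshold_2 outside admissible range [2.6, 3.3]")
  }
  fs <- recording$fs
  x <- highpass_3hz(recording$lfp, fs)

  # decide the notch list on the high-passed series, before the broadband
  # Hampel step can swallow a narrow stimulation-entrained tone
  notches <- sort(unique(notch_frequencies))
  half_stim_applied <- FALSE
  if (!is.na(recording$stim_frequency)) {
    half_stim <- recording$stim_frequency / 2
    if (!any(abs(notches - half_stim) <= 0.5) &&
        propose_ftg_notch(x, fs, recording$stim_frequency)) {
      notches <- sort(c(notches, half_stim))
    }
    half_stim_applied <- any(abs(notches - half_stim) <= 0.5)
  }

  h1 <- spectral_hampel(x, fs, band = c(30, 125),
                        threshold = hampel_threshold_1)
  x <- h1$series

  x <- notch_filter(x, fs, notches)

  n_beats <- 0L
  n_comp <- 0L
  if (!is.null(recording$ecg)) {
    if (is.null(beat_times)) beat_times <- detect_r_peaks(recording$ecg, fs)
    n_beats <- length(beat_times)
    sv <- suppress_ecg_svd(x, fs, beat_times)
    x <- sv$series
    n_comp <- sv$n_components_used
  }

  h2 <- spectral_hampel(x, fs, band = c(3.8, 40),
                        threshold = hampel_threshold_2)
  x <- h2$series

  segments <- select_segments(x, fs, length_s = segment_length_s)

  log <- structure(list(
    steps_applied = c("highpass_3hz", "hampel_30_125", "notch", "ecg_svd",
                      "hampel_3.8_40"),
    hampel_threshold_1 = hampel_threshold_1,
    hampel_threshold_2 = hampel_threshold_2,
    notch_frequencies = notches,
    half_stim_notch_applied = half_stim_applied,
    n_beats_detected = n_beats,
    n_svd_components = n_comp,
    hampel_flagged_1 = h1$flagged_frequencies,
    hampel_flagged_2 = h2$flagged_frequencies,
    n_segments_found = length(segments$segments)),
    class = "stn_cleaning_log")
  list(series = x, log = log, segments = segments)
}
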