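#' Welch power spectral density of a segment pair
#'
#' Averages modified periodograms over 50%-overlapping Hamming-windowed
#' sections of 1.5 s (375 samples at 250 Hz, step 187 samples), then
#' averages across the 1-2 input segments. The one-sided density is
#' Parseval-consistent: `sum(power) * df` approximates the signal variance.
#' With the default window the frequency resolution is 250/375 = 0.67 Hz.
#'
#' @param segments a numeric vector, or list of 1-2 numeric vectors
#'   (e.g. `select_segments()$segments`).
#' @param fs sampling rate (Hz).
#' @param window_s window length (s).
#' @param overlap fractional window overlap; the step is rounded down.
#' @return object of class `stn_psd`: list with `frequencies` (Hz),
#'   `power` (uV^2/Hz) and `n_segments_averaged`.
#' @export
welch_psd <- function(segments, fs = 250, window_s = 1.5, overlap = 0.5) {
  if (is.numeric(segments)) segments <- list(segments)
  nwin <- round(window_s * fs)
  step <- floor(nwin * (1 - overlap))
  if (any(vapply(segments, length, 1L) < nwin)) {
    stopf("each segment must be at least one window (%d samples) long", nwin)
  }
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(nwin - 1)) / (nwin - 1))  # Hamming
  scale <- 1 / (fs * sum(w^2))
  nf <- floor(nwin / 2) + 1
  psd_one <- function(x) {
    starts <- seq(1, length(x) - nwin + 1, by = step)
    acc <- numeric(nf)
    for (s0 in starts) {
      seg <- x[s0:(s0 + nwin - 1)]
      X <- fft((seg - mean(seg)) * w)[1:nf]
      p <- Mod(X)^2 * scale
      # one-sided: double everything except DC (and Nyquist for even nwin)
      dbl <- 2:(if (nwin %% 2 == 0) nf - 1 else nf)
      p[dbl] <- 2 * p[dbl]
      acc <- acc + p
    }
    acc / length(starts)
  }
  pw <- Reduce(`+`, lapply(segments, psd_one)) / length(segments)
  structure(list(frequencies = (0:(nf - 1)) * fs / nwin, power = pw,
                 n_segments_averaged = length(segments), fs = fs),
            class = "stn_psd")
}

#' @export
print.stn_psd <- function(x, ...) {
  cat(sprintf("<stn_psd> %d bins, %.4g-%.4g Hz (df = %.4g Hz), %d segment(s)\n",
              length(x$frequencies), min(x$frequencies), max(x$frequencies),
              x$frequencies[2] - x$frequencies[1], x$n_segments_averaged))
  invisible(x)
}

as_psd <- function(frequencies, power, n_segments_averaged = 1L, fs = NA) {
  structure(list(frequencies = frequencies, power = power,
                 n_segments_averaged = n_segments_averaged, fs = fs),
            class = "stn_psd")
}

ols_line <- function(lf, ly) {
  co <- coef(lm(ly ~ lf))
  c(offset = unname(co[1]), exponent = -unname(co[2]))
}

#' Fit the aperiodic (1/f-like) component of a PSD
#'
#' Fits `L(f) = offset - exponent * log10(f)` to the log10 power over the
#' fit range with a robust two-pass procedure: an initial ordinary
#' least-squares fit, then a refit restricted to bins whose positive
#' residual ("flattened spectrum") does not exceed its 2.5th percentile --
#' which drops peak regions and anchors the line to the spectral floor.
#'
#' @param psd an `stn_psd`.
#' @param fit_range two-element numeric (Hz), default 3-49 Hz.
#' @param flatten_percentile percentile (in percent) of the flattened
#'   spectrum used as the peak-exclusion threshold.
#' @return list with `offset`, `exponent` and `fit_range`.
#' @export
fit_aperiodic <- function(psd, fit_range = c(3, 49), flatten_percentile = 2.5) {
  sel <- psd$frequencies >= fit_range[1] & psd$frequencies <= fit_range[2]
  if (!any(sel)) stopf("psd does not cover the fit range")
  f <- psd$frequencies[sel]
  p <- psd$power[sel]
  if (any(p <= 0)) stopf("non-positive power inside the fit range")
  lf <- log10(f)
  ly <- log10(p)
  fit1 <- ols_line(lf, ly)
  res <- ly - (fit1["offset"] - fit1["exponent"] * lf)
  res[res < 0] <- 0
  keep <- res <= quantile(res, flatten_percentile / 100)
  fit2 <- if (sum(keep) >= 3) ols_line(lf[keep], ly[keep]) else fit1
  list(offset = unname(fit2["offset"]), exponent = unname(fit2["exponent"]),
       fit_range = fit_range)
}

gaussian_bump <- function(f, cf, height, sd) {
  height * exp(-(f - cf)^2 / (2 * sd^2))
}

# Overlap pruning: when two Gaussians sit within one sd (of the wider) of
# each other, keep the taller; prevents a single broad bump from being
# fitted as a stack of narrow ones.
drop_overlapping <- function(peaks) {
  repeat {
    if (nrow(peaks) < 2) return(peaks)
    o <- order(peaks$center_frequency)
    peaks <- peaks[o, , drop = FALSE]
    dropped <- FALSE
    for (i in seq_len(nrow(peaks) - 1)) {
      gap <- peaks$center_frequency[i + 1] - peaks$center_frequency[i]
      if (gap < max(peaks$sd[i], peaks$sd[i + 1])) {
        loser <- if (peaks$height[i] >= peaks$height[i + 1]) i + 1 else i
        peaks <- peaks[-loser, , drop = FALSE]
        dropped <- TRUE
        break
      }
    }
    if (!dropped) return(peaks)
  }
}

peaks_curve <- function(f, peaks) {
  y <- numeric(length(f))
  if (!is.null(peaks) && nrow(peaks)) {
    for (i in seq_len(nrow(peaks))) {
      y <- y + gaussian_bump(f, peaks$center_frequency[i], peaks$height[i],
                             peaks$sd[i])
    }
  }
  y
}

#' Extract Gaussian peaks from the flattened spectrum
#'
#' Iteratively locates the maximum of the flattened spectrum (log10 PSD
#' minus the aperiodic fit); while it exceeds `rel_threshold` standard
#' deviations of the flattened spectrum, a Gaussian is seeded there (width
#' guessed from the half-height extent, bounded to `sd` in 1-6 Hz,
#' i.e. bandwidth 2-12 Hz), subtracted, and the search repeats up to
#' `max_peaks` times. All seeded Gaussians are then refit jointly by
#' bounded least squares, peaks centred within one `sd` of a fit-range
#' edge are dropped, and if more than `max_peaks` survive the tallest are
#' kept. Equal maxima are resolved towards the lower frequency.
#'
#' @param psd an `stn_psd`.
#' @param aperiodic a fit from [fit_aperiodic()].
#' @param max_peaks maximum number of Gaussians.
#' @param rel_threshold detection threshold in SDs of the flattened
#'   spectrum.
#' @param sd_limits bounds for the Gaussian `sd` (Hz).
#' @return data.frame with columns `center_frequency`, `height`, `sd`
#'   (zero rows when nothing exceeds threshold).
#' @export
extract_peaks <- function(psd, aperiodic, max_peaks = 4, rel_threshold = 2.0,
                          sd_limits = c(1, 6)) {
  rng <- aperiodic$fit_range
  sel <- psd$frequencies >= rng[1] & psd$frequencies <= rng[2]
  f <- psd$frequencies[sel]
  flat <- log10(psd$power[sel]) -
    (aperiodic$offset - aperiodic$exponent * log10(f))
  empty <- data.frame(center_frequency = numeric(), height = numeric(),
                      sd = numeric())
  work <- flat
  guesses <- NULL
  df <- f[2] - f[1]
  for (i in seq_len(max_peaks)) {
    j <- which.max(work)                       # ties: lowest frequency wins
    h <- work[j]
    if (h <= rel_threshold * sd(work)) break
    half <- h / 2
    ri <- j; while (ri < length(work) && work[ri] > half) ri <- ri + 1
    li <- j; while (li > 1 && work[li] > half) li <- li - 1
    fwhm <- 2 * min(f[ri] - f[j], f[j] - f[li])
    sd_guess <- min(max(fwhm / 2.355, sd_limits[1]), sd_limits[2])
    # refine the candidate by a bounded single-Gaussian fit to the current
    # residual spectrum before subtracting (a raw half-height width guess
    # is noisy and leaves side lobes that masquerade as further peaks)
    one <- optim(c(f[j], h, sd_guess), function(p) {
      sum((work - gaussian_bump(f, p[1], p[2], p[3]))^2)
    }, method = "L-BFGS-B",
    lower = c(f[j] - 2 * df, 0, sd_limits[1]),
    upper = c(f[j] + 2 * df, Inf, sd_limits[2]))
    guesses <- rbind(guesses,
                     data.frame(center_frequency = one$par[1],
                                height = one$par[2], sd = one$par[3]))
    work <- work - gaussian_bump(f, one$par[1], one$par[2], one$par[3])
  }
  if (is.null(guesses)) return(empty)
  guesses <- drop_overlapping(guesses)
  objective <- function(p) {
    m <- matrix(p, ncol = 3, byrow = TRUE)
    yhat <- numeric(length(f))
    for (i in seq_len(nrow(m))) {
      yhat <- yhat + m[i, 2] * exp(-(f - m[i, 1])^2 / (2 * m[i, 3]^2))
    }
    sum((flat - yhat)^2)
  }
  joint_fit <- function(g) {
    par0 <- as.numeric(t(as.matrix(g)))
    lower <- as.numeric(t(cbind(g$center_frequency - 2 * g$sd, 0,
                                sd_limits[1])))
    upper <- as.numeric(t(cbind(g$center_frequency + 2 * g$sd, Inf,
                                sd_limits[2])))
    opt <- optim(par0, objective, method = "L-BFGS-B", lower = lower,
                 upper = upper, control = list(maxit = 500))
    m <- matrix(opt$par, ncol = 3, byrow = TRUE)
    data.frame(center_frequency = m[, 1], height = m[, 2], sd = m[, 3])
  }
  peaks <- joint_fit(guesses)
  pruned <- drop_overlapping(peaks)
  if (nrow(pruned) < nrow(peaks)) peaks <- joint_fit(pruned)
  # drop edge-hugging and vanished peaks
  keep <- peaks$height > 0 &
    peaks$center_frequency - peaks$sd >= rng[1] &
    peaks$center_frequency + peaks$sd <= rng[2]
  peaks <- peaks[keep, , drop = FALSE]
  if (nrow(peaks) > max_peaks) {
    peaks <- peaks[order(-peaks$height), , drop = FALSE][seq_len(max_peaks), ]
  }
  peaks <- peaks[order(peaks$center_frequency), , drop = FALSE]
  rownames(peaks) <- NULL
  peaks
}

#' Decompose a PSD into periodic and aperiodic components
#'
#' Full parameterization in the spirit of spectral 1/f + Gaussian-peak
#' models: robust aperiodic fit, iterative peak extraction with joint
#' refit, then a final aperiodic refit on the peak-subtracted spectrum.
#' Goodness of fit (r-squared and RMSE, both in log10-power units) is
#' reported over the fit range.
#'
#' @inheritParams fit_aperiodic
#' @inheritParams extract_peaks
#' @return object of class `stn_spectral_model`: list with `aperiodic`
#'   (offset, exponent, fit_range), `peaks` (data.frame), `r_squared`,
#'   `rmse`.
#' @export
parameterize_spectrum <- function(psd, fit_range = c(3, 49), max_peaks = 4,
                                  rel_threshold = 2.0, sd_limits = c(1, 6),
                                  flatten_percentile = 2.5) {
  ap <- fit_aperiodic(psd, fit_range, flatten_percentile)
  peaks <- extract_peaks(psd, ap, max_peaks, rel_threshold, sd_limits)
  sel <- psd$frequencies >= fit_range[1] & psd$frequencies <= fit_range[2]
  f <- psd$frequencies[sel]
  ly <- log10(psd$power[sel])
  if (nrow(peaks)) {
    sub <- ly - peaks_curve(f, peaks)
    fit <- ols_line(log10(f), sub)
    ap <- list(offset = unname(fit["offset"]),
               exponent = unname(fit["exponent"]), fit_range = fit_range)
  }
  model <- structure(list(aperiodic = ap, peaks = peaks,
                          r_squared = NA_real_, rmse = NA_real_,
                          fit_range = fit_range),
                     class = "stn_spectral_model")
  yhat <- model_curve(model, f)
  model$rmse <- sqrt(mean((ly - yhat)^2))
  model$r_squared <- 1 - sum((ly - yhat)^2) / sum((ly - mean(ly))^2)
  model
}

#' Model curve of a fitted spectral decomposition
#'
#' The full model in log10-power space: aperiodic line plus the sum of the
#' Gaussian peaks (an exact reconstruction identity).
#'
#' @param model an `stn_spectral_model`.
#' @param f frequencies (Hz) at which to evaluate.
#' @return numeric vector of log10 power.
#' @export
model_curve <- function(model, f) {
  model$aperiodic$offset - model$aperiodic$exponent * log10(f) +
    peaks_curve(f, model$peaks)
}

#' @export
print.stn_spectral_model <- function(x, ...) {
  cat(sprintf("<stn_spectral_model> offset %.3f, exponent %.3f, %d peak(s), r2 = %.4f\n",
              x$aperiodic$offset, x$aperiodic$exponent, nrow(x$peaks),
              x$r_squared))
  if (nrow(x$peaks)) print(round(x$peaks, 3))
  invisible(x)
}
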