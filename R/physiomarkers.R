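#' Beta peaks of a fitted spectral model
#'
#' Filters the model's Gaussian peaks to the beta band. Bounds are
#' inclusive: a peak centred at exactly 13 or 35 Hz counts as beta.
#'
#' @param model an `stn_spectral_model`.
#' @param range beta band limits (Hz).
#' @return data.frame with `center_frequency`, `height`, `sd` and
#'   `width` (`= 2 * sd`), possibly with zero rows.
#' @export
beta_peaks <- function(model, range = c(13, 35)) {
  pk <- model$peaks
  pk <- pk[pk$center_frequency >= range[1] & pk$center_frequency <= range[2],
           , drop = FALSE]
  pk$width <- 2 * pk$sd
  rownames(pk) <- NULL
  pk
}

#' Match beta peaks across two visits
#'
#' One-to-one matching under the between-visit consistency criterion:
#' among all pairings that use only cross-visit pairs with frequency
#' difference at most `tolerance`, the pairing that matches the largest
#' number of peaks is chosen and, among those, the one with the smallest
#' total frequency difference. The optimum is computed exactly (peak lists
#' are small, at most a handful per visit, so exhaustive search is cheap
#' and deterministic); exact ties are resolved towards pairing the
#' visit-1 peak with the larger height, then the lower visit-1 frequency.
#' A 2.5 Hz tolerance is the study default; 0.67 Hz (one spectral bin) is
#' the strict variant.
#'
#' @param peaks_v1,peaks_v2 data.frames as returned by [beta_peaks()] for
#'   the OFF-stimulation rest recordings of the same hemisphere at visit 1
#'   and 2.
#' @param tolerance maximum |frequency difference| (Hz) for consistency.
#' @return data.frame with one row per matched (consistent) peak:
#'   `cf_visit1`, `cf_visit2`, `delta_f`, `width_visit1`, `width_visit2`,
#'   plus the row indices `idx_v1`, `idx_v2` of the inputs; ordered by
#'   `cf_visit1`.
#' @export
match_across_visits <- function(peaks_v1, peaks_v2, tolerance = 2.5) {
  out <- data.frame(cf_visit1 = numeric(), cf_visit2 = numeric(),
                    delta_f = numeric(), width_visit1 = numeric(),
                    width_visit2 = numeric(), idx_v1 = integer(),
                    idx_v2 = integer())
  n1 <- nrow(peaks_v1)
  n2 <- nrow(peaks_v2)
  if (!n1 || !n2) return(out)
  # visit-1 peaks explored tallest-first so that, on exact ties in
  # (count, total delta), the first optimum found honours the tie rule
  ord <- order(-peaks_v1$height, peaks_v1$center_frequency)
  dmat <- abs(outer(peaks_v1$center_frequency, peaks_v2$center_frequency, "-"))
  best <- list(count = -1L, total = Inf, assign = integer(0))
  recurse <- function(pos, assign, used2, count, total) {
    # bound: even matching every remaining visit-1 peak cannot beat best
    remaining <- n1 - pos + 1
    if (count + remaining < best$count) return(invisible())
    if (pos > n1) {
      if (count > best$count ||
          (count == best$count && total < best$total - 1e-12)) {
        best <<- list(count = count, total = total, assign = assign)
      }
      return(invisible())
    }
    i <- ord[pos]
    cand <- which(dmat[i, ] <= tolerance & !(seq_len(n2) %in% used2))
    for (j in cand[order(dmat[i, cand])]) {
      a <- assign
      a[i] <- j
      recurse(pos + 1, a, c(used2, j), count + 1L, total + dmat[i, j])
    }
    recurse(pos + 1, assign, used2, count, total)
  }
  recurse(1L, rep(NA_integer_, n1), integer(0), 0L, 0)
  matched1 <- which(!is.na(best$assign))
  if (!length(matched1)) return(out)
  matched1 <- matched1[order(peaks_v1$center_frequency[matched1])]
  matched2 <- best$assign[matched1]
  width_of <- function(pk, idx) {
    if ("width" %in% names(pk)) pk$width[idx] else 2 * pk$sd[idx]
  }
  out <- data.frame(
    cf_visit1 = peaks_v1$center_frequency[matched1],
    cf_visit2 = peaks_v2$center_frequency[matched2],
    delta_f = dmat[cbind(matched1, matched2)],
    width_visit1 = width_of(peaks_v1, matched1),
    width_visit2 = width_of(peaks_v2, matched2),
    idx_v1 = matched1, idx_v2 = matched2)
  rownames(out) <- NULL
  out
}

#' Beta band power over a 4 Hz band around a peak
#'
#' Trapezoidal integral of the raw PSD (aperiodic component included) over
#' the peak's center +/- 2 Hz. The center is snapped to the nearest bin of
#' the native 0.67 Hz grid and the band spans an equal number of bins
#' (default 3) on either side, so the integration width is exactly
#' `2 * half_width_bins * df` (= 4 Hz on the native grid).
#'
#' The center frequency is conventionally frozen per hemisphere from the
#' OFF-stimulation rest recording of the same visit and reused for all
#' conditions of that hemisphere/visit.
#'
#' @param psd an `stn_psd` (the original spectrum, not peak-subtracted).
#' @param center_frequency peak center (Hz).
#' @param half_width_bins bins on each side of the snapped center.
#' @return band power (uV^2/Hz * Hz).
#' @export
band_power <- function(psd, center_frequency, half_width_bins = 3) {
  f <- psd$frequencies
  df <- f[2] - f[1]
  if (center_frequency - half_width_bins * df < min(f) ||
      center_frequency + half_width_bins * df > max(f)) {
    stopf("band around %g Hz extends outside the PSD range", center_frequency)
  }
  j <- which.min(abs(f - center_frequency))
  idx <- (j - half_width_bins):(j + half_width_bins)
  pracma::trapz(f[idx], psd$power[idx])
}

#' Stimulation-responsiveness of a consistent beta peak
#'
#' Expresses stimulation-induced beta-power suppression as a percentage of
#' the "natural fluctuation" (NF), the absolute difference of
#' OFF-stimulation resting beta power between the two visits:
#' \deqn{\mathrm{suppression} = 100 \cdot
#'   \frac{(P^{off}_1 - P^{on}_1) + (P^{off}_2 - P^{on}_2)}{2\,\mathrm{NF}}}
#' 100% therefore corresponds to a suppression as large as the natural
#' between-visit fluctuation; positive values are suppressions. A zero NF
#' leaves the score undefined and is an error (the peak is unrankable).
#'
#' @param p_off_v1,p_on_v1,p_off_v2,p_on_v2 rest-condition band powers of
#'   one consistent peak: stimulation OFF/ON at visits 1 and 2.
#' @return list with `natural_fluctuation` and `suppression_percent`.
#' @export
responsiveness <- function(p_off_v1, p_on_v1, p_off_v2, p_on_v2) {
  pw <- c(p_off_v1, p_on_v1, p_off_v2, p_on_v2)
  if (any(pw < 0)) stopf("band powers must be non-negative")
  nf <- abs(p_off_v1 - p_off_v2)
  if (nf == 0) stopf("natural fluctuation is zero: responsiveness undefined")
  list(natural_fluctuation = nf,
       suppression_percent =
         100 * ((p_off_v1 - p_on_v1) + (p_off_v2 - p_on_v2)) / (2 * nf))
}

#' Select the most stimulation-responsive consistent peak
#'
#' Returns the row with the largest `suppression_percent`; a single
#' candidate is returned as-is. Exact ties go to the lower visit-1 center
#' frequency.
#'
#' @param matches data.frame of consistent peaks with at least
#'   `cf_visit1` and `suppression_percent` columns.
#' @return the chosen row (1-row data.frame).
#' @export
select_responsive_peak <- function(matches) {
  if (!nrow(matches)) stopf("no consistent peak to select from")
  if (nrow(matches) == 1) return(matches)
  sc <- matches$suppression_percent
  if (all(!is.finite(sc))) stopf("no scoreable peak (all scores undefined)")
  ord <- order(-sc, matches$cf_visit1)
  matches[ord[1], , drop = FALSE]
}

#' Presence of finely-tuned gamma for a recording
#'
#' The operational definition used throughout: finely-tuned gamma is
#' present if and only if the cleaning chain applied a notch at half the
#' stimulation frequency (within 0.5 Hz).
#'
#' @param cleaning_log an `stn_cleaning_log` from [clean_recording()].
#' @param stim_frequency stimulation frequency (Hz).
#' @return logical flag.
#' @export
detect_ftg <- function(cleaning_log, stim_frequency) {
  if (is.null(stim_frequency) || is.na(stim_frequency)) {
    stopf("stim_frequency is required")
  }
  any(abs(cleaning_log$notch_frequencies - stim_frequency / 2) <= 0.5)
}
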