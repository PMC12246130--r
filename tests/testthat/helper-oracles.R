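# Independent oracles used across the suite. These deliberately use
# different code paths from the package (plain loops, base-R model fits,
# exhaustive enumeration) so implementation and check stay decoupled.

# Brute-force one-to-one peak assignment: enumerate every injective
# pairing built from pairs within tolerance; maximize matched count, then
# minimize total |delta f|.
oracle_match <- function(p1, p2, tol = 2.5) {
  n1 <- nrow(p1)
  n2 <- nrow(p2)
  if (!n1 || !n2) return(data.frame(idx_v1 = integer(), idx_v2 = integer()))
  subsets <- function(v) {
    unlist(lapply(0:length(v), function(k) combn(v, k, simplify = FALSE)),
           recursive = FALSE)
  }
  perms <- function(v) {
    if (!length(v)) return(list(integer(0)))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  best <- NULL
  for (s1 in subsets(seq_len(n1))) {
    if (length(s1) > n2) next
    for (s2 in subsets(seq_len(n2))) {
      if (length(s2) != length(s1)) next
      for (pp in perms(s2)) {
        d <- abs(p1$center_frequency[s1] - p2$center_frequency[pp])
        if (any(d > tol)) next
        cand <- list(count = length(s1), total = sum(d), s1 = s1, s2 = pp)
        if (is.null(best) || cand$count > best$count ||
            (cand$count == best$count && cand$total < best$total - 1e-12)) {
          best <- cand
        }
      }
    }
  }
  if (is.null(best) || best$count == 0) {
    return(data.frame(idx_v1 = integer(), idx_v2 = integer()))
  }
  o <- order(best$s1)
  data.frame(idx_v1 = best$s1[o], idx_v2 = best$s2[o])
}

match_key <- function(i1, i2) paste(sort(paste(i1, i2)), collapse = ";")

# Per-bin spectral Hampel flags, recomputed with plain loops from the
# documented definition (sliding median m, scale = 1.4826 * sliding median
# of |mag - m|).
oracle_hampel_flags <- function(x, fs, band, threshold, window_bins = 11) {
  n <- length(x)
  nf <- floor(n / 2) + 1
  f <- (0:(nf - 1)) * fs / n
  mag <- Mod(fft(x)[1:nf])
  half <- (window_bins - 1) / 2
  win_med <- function(v, j) {
    if (j - half < 1 || j + half > length(v)) return(NA_real_)
    median(v[(j - half):(j + half)])
  }
  m <- vapply(seq_len(nf), function(j) win_med(mag, j), numeric(1))
  dev <- abs(mag - m)
  sc <- 1.4826 * vapply(seq_len(nf), function(j) win_med(dev, j), numeric(1))
  sc <- pmax(sc, 1e-9 * m)
  ok <- !is.na(dev) & !is.na(sc)
  which(f >= band[1] & f <= band[2] & ok & sc > 0 & dev > threshold * sc)
}

# periodogram-based band amplitude at a single frequency (projection)
tone_amplitude <- function(x, fs, f0) {
  t <- (seq_along(x) - 1) / fs
  2 * abs(mean(x * exp(-2i * pi * f0 * t)))
}

# quick synthetic ECG: unit-amplitude QRS train at given beat times
synth_ecg_train <- function(beat_times, n, fs) {
  half <- round(0.04 * fs)
  t0 <- (-half:half) / fs
  s <- 0.08 / 5
  tmpl <- -t0 / s * exp(-t0^2 / (2 * s^2))
  tmpl <- tmpl / max(abs(tmpl))
  train <- numeric(n)
  for (bt in beat_times) {
    j <- round(bt * fs) + 1
    idx <- (j - half):(j + half)
    ok <- idx >= 1 & idx <= n
    train[idx[ok]] <- train[idx[ok]] + tmpl[ok]
  }
  train
}

# Exact Wilcoxon two-sided p by explicit enumeration over all 2^n sign
# assignments (independent of the package's convolution).
oracle_wilcoxon_exact_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  wobs <- sum(r[d > 0])
  ws <- vapply(0:(2^n - 1), function(mask) {
    sum(r[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0])
  }, numeric(1))
  p_lo <- mean(ws <= wobs + 1e-9)
  p_hi <- mean(ws >= wobs - 1e-9)
  min(1, 2 * min(p_lo, p_hi))
}

# small deterministic peak-set generator mimicking the cohort generator's
# peak geometry (>= 4 Hz separation, per-visit jitter, dropout)
random_peak_pair <- function() {
  n <- sample(1:4, 1)
  repeat {
    cf <- sort(runif(n, 13, 35))
    if (n == 1 || min(diff(cf)) >= 4) break
  }
  mk <- function() {
    keep <- runif(n) > 0.12
    if (!any(keep)) keep[1] <- TRUE
    data.frame(center_frequency = cf[keep] + rnorm(sum(keep), 0, 0.8),
               height = runif(sum(keep), 0.1, 1),
               sd = runif(sum(keep), 1, 3))
  }
  list(v1 = mk(), v2 = mk())
}

# flat-PSD helper on the native Welch grid
flat_psd <- function(level = 1, fs = 250, nwin = 375) {
  f <- (0:(floor(nwin / 2))) * fs / nwin
  structure(list(frequencies = f, power = rep(level, length(f)),
                 n_segments_averaged = 1L, fs = fs), class = "stn_psd")
}

# PSD evaluated from an analytic log10 spectrum on the native grid
analytic_psd <- function(fun, fs = 250, nwin = 375) {
  f <- (0:(floor(nwin / 2))) * fs / nwin
  structure(list(frequencies = f, power = 10^fun(f),
                 n_segments_averaged = 1L, fs = fs), class = "stn_psd")
}
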