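#' Intraclass correlation, two-way model, absolute agreement, single rater
#'
#' ICC for an n x k matrix of ratings (rows = subjects/hemispheres/peaks,
#' columns = visits), following the two-way ANOVA decomposition with
#' absolute agreement and single-measurement definition:
#' \deqn{ICC(A,1) = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E +
#'   \frac{k}{n}(MS_C - MS_E)}}
#' The 95% confidence interval uses the standard F-based formula with a
#' Satterthwaite approximation for the denominator degrees of freedom
#' (McGraw-Wong convention; two-way mixed and random models share this
#' point estimate for absolute agreement). The point estimate is
#' categorized as poor (< 0.5), moderate (0.5-0.75), good (0.75-0.9) or
#' excellent (>= 0.9).
#'
#' @param m numeric matrix (or data.frame) with n >= 3 rows and k >= 2
#'   columns, no missing cells.
#' @param alpha 1 - confidence level.
#' @return object of class `stn_icc`: list with `icc`, `ci_low`,
#'   `ci_high`, `n`, `k`, `category` and the mean squares.
#' @export
icc_absolute_single <- function(m, alpha = 0.05) {
  m <- as.matrix(m)
  if (any(!is.finite(m))) stopf("missing or non-finite cells")
  n <- nrow(m)
  k <- ncol(m)
  if (n < 3) stopf("need at least 3 rows")
  if (k < 2) stopf("need at least 2 columns")
  g <- mean(m)
  if (sum((m - g)^2) == 0) stopf("zero total variance: ICC undefined")
  rm_ <- rowMeans(m)
  cm <- colMeans(m)
  ssr <- k * sum((rm_ - g)^2)
  ssc <- n * sum((cm - g)^2)
  sst <- sum((m - g)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  # Satterthwaite df for the CI
  a <- (k * icc) / (n * (1 - icc))
  b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  fl <- qf(1 - alpha / 2, n - 1, v)
  fu <- qf(1 - alpha / 2, v, n - 1)
  ci_low <- n * (msr - fl * mse) /
    (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
  ci_high <- n * (fu * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * fu * msr)
  structure(list(icc = icc, ci_low = ci_low, ci_high = ci_high, n = n, k = k,
                 category = icc_category(icc),
                 ms = c(msr = msr, msc = msc, mse = mse)),
            class = "stn_icc")
}

#' Interpretation category of an ICC point estimate
#'
#' @param icc numeric ICC value(s).
#' @return character: "poor" (< 0.5), "moderate" (0.5-0.75),
#'   "good" (0.75-0.9) or "excellent" (>= 0.9).
#' @export
icc_category <- function(icc) {
  cut(icc, breaks = c(-Inf, 0.5, 0.75, 0.9, Inf), right = FALSE,
      labels = c("poor", "moderate", "good", "excellent")) |> as.character()
}

#' @export
print.stn_icc <- function(x, ...) {
  cat(sprintf("ICC(A,1) = %.3f [%.3f %.3f] (n = %d, k = %d): %s\n",
              x$icc, x$ci_low, x$ci_high, x$n, x$k, x$category))
  invisible(x)
}

# orthonormal contrast matrix, (k-1) x k, rows orthonormal and orthogonal
# to the constant vector
orthonormal_contrasts <- function(k) {
  C <- stats::contr.helmert(k)
  C <- sweep(C, 2, sqrt(colSums(C^2)), "/")
  t(C)
}

#' Fully within-subject repeated-measures ANOVA
#'
#' Classical univariate repeated-measures ANOVA for a complete, balanced
#' design in which every factor varies within the experimental unit. Each
#' effect is tested against its own effect-by-unit interaction. For
#' effects with more than one numerator df, Mauchly's sphericity test and
#' the Greenhouse-Geisser epsilon are computed from the covariance of the
#' orthonormalized within-unit contrast scores; the reported p-value
#' (`p_reported`) uses Greenhouse-Geisser-corrected dfs when Mauchly's
#' test is significant at `sphericity_alpha`, and the uncorrected p
#' otherwise. Effect sizes are partial eta-squared and Cohen's f.
#'
#' @param data long-format data.frame.
#' @param dv name of the dependent-variable column.
#' @param unit name of the experimental-unit column.
#' @param factors character vector of within-unit factor columns.
#' @param sphericity_alpha alpha of the Mauchly gate.
#' @return data.frame with one row per effect (main effects and all
#'   interactions): F, dfs, p, Mauchly chi-squared/p, epsilon, corrected
#'   dfs/p, `p_reported`, partial eta-squared, Cohen's f.
#' @export
rm_anova_ws <- function(data, dv = "value", unit = "unit",
                        factors, sphericity_alpha = 0.05) {
  y <- data[[dv]]
  if (any(!is.finite(y))) stopf("non-finite values in dv")
  u <- factor(data[[unit]])
  fl <- lapply(factors, function(f) factor(data[[f]]))
  names(fl) <- factors
  n <- nlevels(u)
  nlev <- vapply(fl, nlevels, 1L)
  n_cells <- prod(nlev)
  cnt <- table(u, interaction(fl, drop = FALSE))
  if (any(cnt != 1)) stopf("design must be complete and balanced (one observation per unit x cell)")

  vars_all <- c(list(unit = u), fl)
  margin_sum <- function(vars) {
    if (!length(vars)) return(sum(y)^2 / length(y))
    g <- interaction(vars_all[vars], drop = FALSE)
    tt <- tapply(y, g, sum)
    nn <- tapply(y, g, length)
    sum(tt^2 / nn)
  }
  subsets <- function(v) {
    unlist(lapply(0:length(v), function(k) combn(v, k, simplify = FALSE)),
           recursive = FALSE)
  }
  effect_ss <- function(vars) {
    ss <- 0
    for (w in subsets(vars)) ss <- ss + (-1)^(length(vars) - length(w)) * margin_sum(w)
    ss
  }

  effects <- subsets(factors)
  effects <- effects[lengths(effects) > 0]
  rows <- lapply(effects, function(eff) {
    df1 <- prod(nlev[eff] - 1)
    df2 <- (n - 1) * df1
    ss_eff <- effect_ss(eff)
    ss_err <- effect_ss(c("unit", eff))
    F <- (ss_eff / df1) / (ss_err / df2)
    p <- pf(F, df1, df2, lower.tail = FALSE)
    eta_p <- ss_eff / (ss_eff + ss_err)
    # sphericity: contrast scores per unit on the marginal cell means
    mtab <- tapply(y, c(vars_all["unit"], vars_all[eff]), mean)
    M <- matrix(mtab, nrow = n)                 # n x prod(nlev[eff])
    C <- Reduce(kronecker, lapply(rev(eff), function(f2) {
      orthonormal_contrasts(nlev[[f2]])
    }))
    Z <- M %*% t(C)
    if (df1 >= 2) {
      S <- cov(Z)
      d <- df1
      eps <- sum(diag(S))^2 / (d * sum(S^2))
      W <- det(S) / (sum(diag(S)) / d)^d
      W <- max(W, .Machine$double.xmin)
      chi2 <- -(n - 1) * (1 - (2 * d^2 + d + 2) / (6 * d * (n - 1))) * log(W)
      mdf <- d * (d + 1) / 2 - 1
      mp <- stats::pchisq(chi2, mdf, lower.tail = FALSE)
    } else {
      eps <- 1
      chi2 <- NA_real_
      mp <- NA_real_
    }
    p_gg <- pf(F, df1 * eps, df2 * eps, lower.tail = FALSE)
    corrected <- df1 >= 2 && !is.na(mp) && mp < sphericity_alpha
    data.frame(effect = paste(eff, collapse = ":"),
               df_effect = df1, df_error = df2, F = F, p = p,
               mauchly_chi2 = chi2, mauchly_p = mp, epsilon_gg = eps,
               df_effect_gg = df1 * eps, df_error_gg = df2 * eps, p_gg = p_gg,
               gg_applied = corrected,
               p_reported = if (corrected) p_gg else p,
               partial_eta_sq = eta_p,
               cohens_f = sqrt(eta_p / (1 - eta_p)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' 2 x 2 x 3 repeated-measures ANOVA on a feature table
#'
#' Convenience wrapper for the Visit (2) x Stimulation (2) x Task (3)
#' within-hemisphere design: expects columns `hemisphere_id`, `visit`,
#' `stim_state`, `task` and `value` with one row per hemisphere and cell.
#'
#' @param feature_table long-format data.frame (24 hemispheres x 12 cells
#'   in the full design).
#' @return see [rm_anova_ws()].
#' @export
rm_anova_2x2x3 <- function(feature_table) {
  rm_anova_ws(feature_table, dv = "value", unit = "hemisphere_id",
              factors = c("visit", "stim_state", "task"))
}

#' Cohen's f from an F statistic
#'
#' Converts a repeated-measures ANOVA F statistic to Cohen's f via partial
#' eta-squared:
#' `eta_p^2 = F * df1 / (F * df1 + df2)`, `f = sqrt(eta_p^2/(1 - eta_p^2))`.
#'
#' @param F F statistic (>= 0).
#' @param df_effect,df_error numerator/denominator degrees of freedom.
#' @return Cohen's f.
#' @export
cohens_f_from_F <- function(F, df_effect, df_error) {
  stopifnot(F >= 0, df_effect >= 1, df_error >= 1)
  eta_p <- F * df_effect / (F * df_effect + df_error)
  sqrt(eta_p / (1 - eta_p))
}

#' Paired-samples t test with Cohen's d
#'
#' Tests the mean of the paired differences against zero and reports
#' Cohen's d for paired designs, `d = mean(diff)/sd(diff)` (equivalently
#' `t/sqrt(n)`).
#'
#' @param x,y equal-length paired samples.
#' @return list of class `stn_paired_test` with `kind = "t"`,
#'   `statistic`, `df`, `p`, `effect` (Cohen's d) and `n_pairs`.
#' @export
paired_t_test <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  d <- x - y
  sdd <- sd(d)
  if (sdd == 0) stopf("zero variance of differences: t undefined")
  n <- length(d)
  tval <- mean(d) / (sdd / sqrt(n))
  structure(list(kind = "t", statistic = tval, df = n - 1,
                 p = 2 * pt(-abs(tval), n - 1),
                 effect = mean(d) / sdd, effect_name = "cohens_d",
                 n_pairs = n),
            class = "stn_paired_test")
}

# Exact null distribution of W+ for signed ranks r (possibly tied,
# half-integer average ranks) via shift-and-add convolution over 2*r.
wplus_exact_p <- function(r, wpos) {
  ir <- round(2 * r)
  total <- sum(ir)
  dist <- numeric(total + 1)          # index = value of 2*W+ + 1
  dist[1] <- 1
  for (v in ir) {
    shifted <- c(numeric(v), dist[seq_len(length(dist) - v)])
    dist <- dist + shifted
  }
  dist <- dist / sum(dist)
  w2 <- round(2 * wpos)
  p_lo <- sum(dist[seq_len(w2 + 1)])
  p_hi <- sum(dist[(w2 + 1):length(dist)])
  min(1, 2 * min(p_lo, p_hi))
}

#' Wilcoxon signed-rank test with effect size
#'
#' Paired signed-rank test with the classic zero-handling (zero
#' differences dropped) and average ranks for ties. The standardized
#' statistic is the tie-corrected normal deviate
#' \deqn{Z = \frac{W^+ - n(n+1)/4}{\sqrt{n(n+1)(2n+1)/24 - \sum(t^3-t)/48}}}
#' (no continuity correction), signed so that `Z > 0` when `x` tends to
#' exceed `y`. For `n <= exact_max_n` non-zero pairs the p-value is exact
#' (full enumeration of the 2^n sign assignments via convolution over the
#' observed ranks, doubled one-sided tail); otherwise the normal
#' approximation is used. The default effect size is Rosenthal's
#' `r = Z / sqrt(n_pairs)` with `n_pairs` the number of supplied pairs;
#' the matched-pairs rank-biserial correlation
#' `(W+ - W-) / (W+ + W-)` is available as an alternative.
#'
#' @param x,y equal-length paired samples.
#' @param exact_max_n largest number of non-zero pairs for which the exact
#'   p-value is computed.
#' @param effect `"rosenthal"` (default) or `"rank_biserial"`.
#' @return list of class `stn_paired_test` with `kind = "wilcoxon"`,
#'   `statistic` (Z), `w_plus`, `p`, `exact`, `effect` and `n_pairs`.
#' @export
wilcoxon_signed_rank <- function(x, y, exact_max_n = 12,
                                 effect = c("rosenthal", "rank_biserial")) {
  effect <- match.arg(effect)
  stopifnot(length(x) == length(y))
  n_pairs <- length(x)
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (!n) stopf("all differences are zero: test undefined")
  r <- rank(abs(d))
  wpos <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sigma <- sqrt(n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48)
  z <- if (sigma > 0) (wpos - mu) / sigma else 0
  exact <- n <= exact_max_n
  p <- if (exact) wplus_exact_p(r, wpos) else 2 * pnorm(-abs(z))
  eff <- switch(effect,
                rosenthal = z / sqrt(n_pairs),
                rank_biserial = (wpos - (sum(r) - wpos)) / sum(r))
  structure(list(kind = "wilcoxon", statistic = z, w_plus = wpos, p = p,
                 exact = exact, effect = eff, effect_name = effect,
                 n_pairs = n_pairs, n_nonzero = n),
            class = "stn_paired_test")
}

#' @export
print.stn_paired_test <- function(x, ...) {
  cat(sprintf("%s test: statistic = %.3f, p = %.4g, %s = %.3f (n = %d)\n",
              x$kind, x$statistic, x$p, x$effect_name, x$effect, x$n_pairs))
  invisible(x)
}

#' Bonferroni correction
#'
#' @param p p-values in `[0, 1]`.
#' @param m number of comparisons (defaults to `length(p)`).
#' @return adjusted p-values `min(1, p * m)`.
#' @export
bonferroni <- function(p, m = length(p)) {
  stopifnot(all(p >= 0 & p <= 1))
  pmin(1, p * m)
}
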