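test_that("ICC is 1 for perfect agreement and matches hand-expanded mean squares", {
  m <- cbind(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5))
  ic <- icc_absolute_single(m)
  expect_equal(ic$icc, 1)

  # 6 x 2 toy matrix: expand the two-way decomposition by hand
  m2 <- cbind(c(9, 6, 8, 7, 10, 6), c(2, 1, 4, 1, 5, 2))
  n <- 6; k <- 2
  g <- mean(m2)
  msr <- k * sum((rowMeans(m2) - g)^2) / (n - 1)
  msc <- n * sum((colMeans(m2) - g)^2) / (k - 1)
  mse <- (sum((m2 - g)^2) - (n - 1) * msr - (k - 1) * msc) / ((n - 1) * (k - 1))
  want <- (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
  ic2 <- icc_absolute_single(m2)
  expect_equal(ic2$icc, want, tolerance = 1e-12)
  expect_lte(ic2$ci_low, ic2$icc)
  expect_gte(ic2$ci_high, ic2$icc)
  expect_true(abs(ic2$icc) <= 1)

  expect_error(icc_absolute_single(matrix(5, 4, 2)), "zero total variance")
  expect_error(icc_absolute_single(m2[1:2, ]), "at least 3")
})

test_that("ICC categories follow the fixed cut-offs", {
  expect_equal(icc_category(c(0.49, 0.5, 0.749, 0.75, 0.766, 0.899, 0.9)),
               c("poor", "moderate", "moderate", "good", "good", "good",
                 "excellent"))
})

test_that("ICC confidence interval covers the true value about 95% of the time", {
  # two-way model with true ICC(A,1) = 0.7 at n = 24, k = 2
  set.seed(61)
  n <- 24
  cover <- 0
  n_sim <- 500
  for (s in seq_len(n_sim)) {
    rows <- rnorm(n, 0, sqrt(0.7))
    cols <- rnorm(2, 0, sqrt(0.05))
    m <- outer(rows, c(1, 1)) + outer(rep(1, n), cols) +
      matrix(rnorm(2 * n, 0, sqrt(0.25)), n, 2)
    ic <- icc_absolute_single(m)
    if (ic$ci_low <= 0.7 && ic$ci_high >= 0.7) cover <- cover + 1
  }
  expect_gte(cover / n_sim, 0.92)
  expect_lte(cover / n_sim, 0.98)
})

make_ws_table <- function(n_units = 5, seed = 62, visit_effect = 0) {
  set.seed(seed)
  g <- expand.grid(unit = paste0("u", seq_len(n_units)),
                   visit = c("1", "2"), stim_state = c("OFF", "ON"),
                   task = c("rest", "ftn", "speech"),
                   stringsAsFactors = FALSE)
  g$value <- rnorm(nrow(g)) + 0.8 * (g$stim_state == "ON") +
    visit_effect * (g$visit == "2") +
    0.4 * (g$task == "speech") + rep(rnorm(n_units), length.out = nrow(g))
  g
}

test_that("within-subject ANOVA F statistics agree with base aov on a toy table", {
  g <- make_ws_table()
  got <- rm_anova_ws(g, dv = "value", unit = "unit",
                     factors = c("visit", "stim_state", "task"))
  g2 <- g
  g2[c("unit", "visit", "stim_state", "task")] <-
    lapply(g2[c("unit", "visit", "stim_state", "task")], factor)
  ref <- summary(aov(value ~ visit * stim_state * task +
                       Error(unit / (visit * stim_state * task)), data = g2))
  ref_F <- unlist(lapply(ref, function(s) {
    tab <- s[[1]]
    setNames(tab[["F value"]][!is.na(tab[["F value"]])],
             trimws(rownames(tab)[!is.na(tab[["F value"]])]))
  }))
  names(ref_F) <- sub("^Error.*\\.", "", names(ref_F))
  for (i in seq_len(nrow(got))) {
    eff <- got$effect[i]
    expect_equal(got$F[i], unname(ref_F[[eff]]), tolerance = 1e-8,
                 label = paste("F for", eff))
  }
  # seven effects for three factors
  expect_equal(nrow(got), 7)
})

test_that("ANOVA is invariant to adding a constant and epsilon is 1 for 2-level factors", {
  g <- make_ws_table(seed = 63)
  a1 <- rm_anova_ws(g, dv = "value", unit = "unit",
                    factors = c("visit", "stim_state", "task"))
  g$value <- g$value + 100
  a2 <- rm_anova_ws(g, dv = "value", unit = "unit",
                    factors = c("visit", "stim_state", "task"))
  expect_equal(a1$F, a2$F, tolerance = 1e-9)

  expect_equal(a1$epsilon_gg[a1$effect == "visit"], 1)
  expect_equal(a1$epsilon_gg[a1$effect == "stim_state"], 1)
  expect_true(is.na(a1$mauchly_p[a1$effect == "visit"]))
  # epsilon bounded within [1/(k-1), 1] for the 3-level factor
  eps_task <- a1$epsilon_gg[a1$effect == "task"]
  expect_gte(eps_task, 0.5)
  expect_lte(eps_task, 1)
})

test_that("GG epsilon equals 1 under compound symmetry", {
  # construct exact compound-symmetric within-unit data for a 3-level factor
  n <- 40
  set.seed(64)
  u <- rnorm(n)
  g <- expand.grid(unit = seq_len(n), task = c("a", "b", "c"),
                   stringsAsFactors = FALSE)
  # equal-variance, equal-covariance cells: unit effect + iid noise with
  # noise made exactly exchangeable by symmetrizing
  e <- matrix(rnorm(3 * n), n, 3)
  # force the sample covariance of contrasts to be spherical
  e <- e %*% solve(chol(cov(e)))
  g$value <- u[g$unit] + e[cbind(g$unit, as.integer(factor(g$task)))]
  an <- rm_anova_ws(g, dv = "value", unit = "unit", factors = "task")
  expect_equal(an$epsilon_gg, 1, tolerance = 1e-6)
})

test_that("ANOVA rejects unbalanced tables", {
  g <- make_ws_table()
  expect_error(rm_anova_ws(g[-1, ], dv = "value", unit = "unit",
                           factors = c("visit", "stim_state", "task")),
               "balanced")
})

test_that("Cohen's f reproduces the reference statistical identities", {
  expect_equal(round(cohens_f_from_F(55.198, 1, 23), 3), 1.549)
  expect_equal(round(cohens_f_from_F(5.763, 2, 46), 3), 0.501)
  expect_equal(round(cohens_f_from_F(26.447, 1, 23), 3), 1.072)
  expect_equal(round(cohens_f_from_F(0.015, 1, 23), 3), 0.026)
  expect_equal(round(cohens_f_from_F(4.181, 2, 46), 3), 0.426)
  expect_equal(round(cohens_f_from_F(0.281, 1, 23), 3), 0.111)
  expect_equal(cohens_f_from_F(0, 1, 23), 0)
})

test_that("paired t test matches the closed form and reference d = t/sqrt(n)", {
  # d = t / sqrt(n): t(23) = 2.449 with 24 pairs gives d = 0.500
  expect_equal(round(2.449 / sqrt(24), 3), 0.5)
  set.seed(65)
  x <- rnorm(24)
  y <- x + rnorm(24, 0.3, 0.6)
  r <- paired_t_test(y, x)
  d <- y - x
  t_manual <- mean(d) / (sd(d) / sqrt(24))
  expect_equal(r$statistic, t_manual, tolerance = 1e-12)
  expect_equal(r$p, 2 * pt(-abs(t_manual), 23), tolerance = 1e-12)
  expect_equal(r$effect, r$statistic / sqrt(24), tolerance = 1e-12)

  expect_error(paired_t_test(c(2, 3, 4), c(1, 2, 3)), "zero variance")
})

test_that("Wilcoxon reproduces the reference effect size and simple exact cases", {
  # Z / sqrt(n): Z = 2.828 with 45 pairs gives 0.422
  expect_equal(round(2.828 / sqrt(45), 3), 0.422)

  # all positive differences, n = 6: exact two-sided p = 2/64
  r <- wilcoxon_signed_rank(2:7, 1:6)
  expect_true(r$exact)
  expect_equal(r$p, 2 / 64)
  expect_equal(wilcoxon_signed_rank(2:7, 1:6,
                                    effect = "rank_biserial")$effect, 1)

  expect_error(wilcoxon_signed_rank(1:4, 1:4), "zero")
})

test_that("exact Wilcoxon p equals 2^n enumeration on random data", {
  set.seed(66)
  for (i in 1:25) {
    n <- sample(5:10, 1)
    x <- rnorm(n)
    y <- x + rnorm(n, 0.4)
    if (sample(2, 1) == 1) y <- round(y, 1)        # provoke ties sometimes
    if (all(x == y)) next
    r <- wilcoxon_signed_rank(x, y)
    expect_equal(r$p, oracle_wilcoxon_exact_p(x - y), tolerance = 1e-12)
  }
})

test_that("Wilcoxon agrees with wilcox.test in the tie-free exact regime", {
  set.seed(67)
  for (i in 1:10) {
    n <- sample(6:11, 1)
    x <- rnorm(n)
    y <- rnorm(n)
    r <- wilcoxon_signed_rank(x, y)
    ref <- wilcox.test(x, y, paired = TRUE, exact = TRUE)
    expect_equal(r$p, ref$p.value, tolerance = 1e-12)
  }
})

test_that("large-n Wilcoxon uses the tie-corrected normal deviate", {
  set.seed(68)
  x <- rnorm(45)
  y <- x + rnorm(45, 0.25)
  r <- wilcoxon_signed_rank(x, y)
  expect_false(r$exact)
  d <- y - x                                      # note the sign convention
  ref <- wilcox.test(x, y, paired = TRUE, exact = FALSE, correct = FALSE)
  expect_equal(r$p, ref$p.value, tolerance = 1e-9)
  expect_equal(sign(r$statistic), sign(sum(sign(x - y))))
})

test_that("Bonferroni caps at 1 and preserves ordering", {
  expect_equal(bonferroni(0.02, 3), 0.06)
  expect_equal(bonferroni(0.5, 3), 1)
  p <- c(0.001, 0.04, 0.2, 0.9)
  expect_equal(order(bonferroni(p)), order(p))
  expect_error(bonferroni(1.2), ">=")
})

sim_features <- function(seed, visit_shift_off = 0, n_units = 24) {
  set.seed(seed)
  g <- expand.grid(hemisphere_id = paste0("h", seq_len(n_units)),
                   peak_id = 1, visit = 1:2, stim_state = c("OFF", "ON"),
                   task = c("rest", "finger_to_nose", "speech"),
                   stringsAsFactors = FALSE)
  base <- rnorm(n_units, 10, 2)
  g$value <- base[match(g$hemisphere_id, paste0("h", seq_len(n_units)))] +
    rnorm(nrow(g), 0, 0.3) +
    visit_shift_off * (g$visit == 2 & g$stim_state == "OFF")
  g
}

test_that("the ICC table has the 11-row layout: 6 conditions plus 5 deltas", {
  f <- sim_features(70)
  f$unit <- f$hemisphere_id
  tab <- icc_table(f)
  expect_equal(nrow(tab), 11)
  expect_equal(sum(grepl("^OFF-|^ON-", tab$condition)), 6)
  expect_equal(sum(grepl("rest_to_|dOFF-ON", tab$condition)), 5)
  expect_true(all(tab$n == 24))
  expect_true(all(tab$icc >= -1 & tab$icc <= 1))
})

test_that("consistency report flags an injected OFF-only visit-2 shift in the Wilcoxon branch", {
  f0 <- sim_features(71)
  f0$feature <- "band_power"
  rep0 <- consistency_report(f0)
  expect_equal(rep0$band_power$branch, "wilcoxon")
  expect_equal(nrow(rep0$band_power$tests), 6)
  # the verdict is exactly "no per-condition visit difference at alpha"
  expect_identical(rep0$band_power$consistent,
                   all(rep0$band_power$tests$p > 0.05))

  f1 <- sim_features(72, visit_shift_off = 1.5)
  f1$feature <- "band_power"
  rep1 <- consistency_report(f1)
  tests <- rep1$band_power$tests
  expect_false(rep1$band_power$consistent)
  # the shift is huge relative to noise: every OFF condition flags it,
  # and the untouched ON conditions cannot all flag
  expect_true(all(tests$p[tests$stim_state == "OFF"] < 0.05))
  expect_false(all(tests$p[tests$stim_state == "ON"] < 0.05))
})

test_that("aperiodic features with Gaussian noise take the ANOVA branch and pass when visit-null", {
  f <- sim_features(73)
  f$feature <- "offset"
  f$peak_id <- NA
  rep_ <- consistency_report(f)
  expect_equal(rep_$offset$branch, "anova")
  expect_true(rep_$offset$consistent)
  expect_equal(nrow(rep_$offset$icc), 11)
})
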