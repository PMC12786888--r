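test_that("mean_cea averages rater grades without rounding", {
  expect_equal(mean_cea(c(3, 3, 3)), 3.0)
  expect_equal(mean_cea(c(3, 4, 3)), 10 / 3)
  expect_equal(mean_cea(c(0, 0, 0)), 0.0)
  expect_error(mean_cea(numeric(0)), "no CEA grades")
  expect_error(mean_cea(c(2, 5, 1)), "\\[0, 4\\]")
  expect_error(mean_cea(c(1.5, 2, 2)), "integers")
})

test_that("complete agreement matches a brute-force recount", {
  ref <- reference_cea_table()
  agr <- complete_agreement_fraction(ref)
  expect_equal(agr$agree, 39L)
  expect_equal(agr$total, 60L)
  expect_equal(agr$percent, 65)

  # independent loop oracle on random fixtures
  set.seed(9)
  for (rep in 1:10) {
    cea <- random_cea_frame(n_subjects = 12)
    agr <- complete_agreement_fraction(cea)
    brute <- 0L
    for (s in unique(cea$subject)) for (tp in c("T0", "T1", "T2")) {
      g <- cea$grade[cea$subject == s & cea$timepoint == tp]
      if (g[1] == g[2] && g[2] == g[3]) brute <- brute + 1L
    }
    expect_equal(agr$agree, brute)
    expect_equal(agr$percent, 100 * brute / 36)
  }

  # all unanimous
  uni <- random_cea_frame(4)
  uni$grade <- rep(2L, nrow(uni))
  expect_equal(complete_agreement_fraction(uni)$percent, 100)

  expect_error(complete_agreement_fraction(ref[-1, ]), "without all 3 raters")
})

test_that("energy_summary reproduces the packaged treatment table", {
  es <- energy_summary(treatment_energy_table())
  expect_equal(round(es$mean, 1), c(12.7, 14.5, 16.1))
  expect_equal(round(es$sd, 2), c(0.80, 0.76, 0.64))

  # identical energies: SD 0
  const <- data.frame(subject = 1:5, e1 = 13, e2 = 13, e3 = 13)
  expect_equal(energy_summary(const)$sd, rep(0, 3))

  expect_error(energy_summary(const[0, ]), "no treatment records")
  expect_error(energy_summary(data.frame(subject = 1, e1 = -2, e2 = 1, e3 = 1)),
               "positive")
})

test_that("percent_change follows the decrease/increase conventions", {
  expect_equal(round(percent_change(6.86, 5.92), 2), 13.70)
  expect_equal(percent_change(5, 5), 0)
  expect_equal(round(percent_change(0.490, 0.512, "increase"), 2), 4.49)
  expect_equal(percent_change(10, 8), -percent_change(10, 12))
  expect_error(percent_change(0, 1), "positive")
})

test_that("spearman_cor matches rank-based closed forms and cor()", {
  x <- c(1, 2, 5, 9, 12)
  expect_equal(spearman_cor(x, x^3)$rho, 1)       # monotone-invariant
  expect_equal(spearman_cor(x, -x)$rho, -1)
  expect_equal(spearman_cor(x, x)$p, 0)

  set.seed(11)
  for (rep in 1:20) {
    n <- sample(5:40, 1)
    a <- sample(0:8, n, replace = TRUE)  # ties on purpose
    b <- a + stats::rnorm(n, 0, 3)
    s <- spearman_cor(a, b)
    expect_equal(s$rho, stats::cor(a, b, method = "spearman"),
                 tolerance = 1e-12)
    expect_equal(sign(s$t_stat), sign(s$rho))
    expect_true(s$p >= 0 && s$p <= 1)
    # monotone transform of either variable leaves rho unchanged
    expect_equal(spearman_cor(exp(a / 4), b)$rho, s$rho, tolerance = 1e-12)
  }

  # t = R sqrt(n-2)/sqrt(1-R^2): the published-scale example
  r <- 0.943; n <- 20
  t_formula <- r * sqrt(n - 2) / sqrt(1 - r^2)
  expect_equal(t_formula, 12.02, tolerance = 5e-4)
  y <- stats::qnorm(seq(0.05, 0.95, length.out = 20))
  s <- spearman_cor(y, y + 0.001 * y^2)
  expect_equal(s$t_stat, s$rho * sqrt(18) / sqrt(1 - s$rho^2))

  expect_error(spearman_cor(rep(1, 5), 1:5), "constant")
  expect_error(spearman_cor(1:3, 1:4), "paired")
  expect_error(spearman_cor(1:2, 1:2), "at least 3")
})

test_that("friedman_with_dunn agrees with stats::friedman.test and hand arithmetic", {
  # identical values: statistic 0, everything non-significant
  m0 <- matrix(5, nrow = 4, ncol = 3, dimnames = list(NULL, c("T0", "T1", "T2")))
  f0 <- friedman_with_dunn(m0)
  expect_equal(f0$statistic, 0)
  expect_equal(f0$p, 1)
  expect_equal(f0$posthoc$p_adj, rep(1, 3))

  # 4 subjects, strict common ordering: 12/(nk(k+1)) sum(R^2) - 3n(k+1) = 8
  m1 <- matrix(c(1, 2, 3), nrow = 4, ncol = 3, byrow = TRUE) +
    matrix(stats::runif(12, 0, 0.1), 4, 3)
  m1 <- m1[, order(colMeans(m1))]
  colnames(m1) <- c("T0", "T1", "T2")
  expect_equal(friedman_with_dunn(m1)$statistic, 8.0)

  # oracle: stats::friedman.test, with and without ties
  set.seed(13)
  for (rep in 1:15) {
    n <- sample(4:12, 1)
    vals <- matrix(sample(0:6, n * 3, replace = TRUE), n, 3)  # heavy ties
    if (any(apply(vals, 1, function(r) length(unique(r))) == 1) &&
        all(apply(vals, 2, stats::sd) == 0)) next
    colnames(vals) <- c("T0", "T1", "T2")
    mine <- friedman_with_dunn(vals)
    ref <- stats::friedman.test(vals)
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
    expect_equal(mine$df, 2L)
    # Dunn: adjusted p never below unadjusted, all in [0,1]
    expect_true(all(mine$posthoc$p_adj >= mine$posthoc$p_unadj - 1e-15))
    expect_true(all(mine$posthoc$p_adj <= 1 & mine$posthoc$p_unadj >= 0))
    # within-subject monotone transform leaves the statistic unchanged
    mono <- friedman_with_dunn(exp(vals / 3))
    expect_equal(mono$statistic, mine$statistic, tolerance = 1e-12)
  }

  expect_error(friedman_with_dunn(matrix(1, 2, 3)), "at least 3 subjects")
  bad <- matrix(1:9, 3, 3); bad[2, 2] <- NA
  expect_error(friedman_with_dunn(bad), "missing cells")
})

test_that("chi-square p ordering agrees with a within-subject permutation null", {
  # three 6 x 3 tables with increasing treatment effect
  set.seed(17)
  base <- matrix(stats::rnorm(18), 6, 3)
  tables <- lapply(c(0, 0.8, 2.5), function(eff) {
    m <- base - outer(rep(1, 6), c(0, eff, eff))
    colnames(m) <- c("T0", "T1", "T2"); m
  })
  perm_p <- function(m, n_perm = 1500) {
    obs <- friedman_with_dunn(m)$statistic
    hits <- 0L
    for (b in seq_len(n_perm)) {
      mp <- t(apply(m, 1, sample))
      colnames(mp) <- colnames(m)
      if (friedman_with_dunn(mp)$statistic >= obs - 1e-12) hits <- hits + 1L
    }
    hits / n_perm
  }
  p_chi <- vapply(tables, function(m) friedman_with_dunn(m)$p, 0)
  p_perm <- vapply(tables, perm_p, 0)
  # the chi-square approximation tracks the permutation null closely and
  # makes the same significance calls at 0.05
  expect_true(all(abs(p_chi - p_perm) < 0.07))
  expect_equal(p_chi < 0.05, p_perm < 0.05)
})

test_that("study_analysis assembles medians, tests and correlations", {
  set.seed(19)
  # strong synthetic effect, 8 subjects, built directly at the feature level
  mk_vals <- function(base) {
    t(vapply(seq_len(8), function(i) {
      b <- base + stats::rnorm(1, 0, 0.5)
      c(b, b * 0.8, b * 0.8) + stats::rnorm(3, 0, 0.05)
    }, numeric(3)))
  }
  contrast_vals <- stats::setNames(
    lapply(c(7.5, 7.4, 6.9, 6.9, 7.3), mk_vals), c(FACE_ZONES, "face"))
  feats <- feature_frame(contrast_vals)
  cea <- random_cea_frame(8)
  res <- study_analysis(feats, cea)
  expect_s3_class(res, "glcmface_analysis")
  fc <- res$zones[["face.contrast"]]
  expect_equal(unname(fc$medians["T0"] > fc$medians["T1"]), TRUE)
  expect_lt(fc$friedman$p, 0.05)
  expect_gt(fc$pct_change_T0_T1, 0)
  # homogeneity derived as 1/(1+contrast) must move the other way
  fh <- res$zones[["face.homogeneity"]]
  expect_gt(fh$pct_change_T0_T1, 0)  # increase convention
  expect_equal(res$agreement$total, 24L)
  expect_equal(nrow(res$correlations), 6L)
  expect_true(all(abs(res$correlations$R) <= 1))

  # schema errors
  expect_error(study_analysis(feats[feats$timepoint == "T0", ]),
               "three timepoints")
  expect_error(study_analysis(feats[, -4]), "missing column")
  expect_error(study_analysis(feats, cea, alpha = 1.5), "alpha")
})
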