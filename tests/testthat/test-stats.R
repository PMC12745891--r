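# independent implementation of Welch's heteroscedastic F for cross-checks
welch_f_oracle <- function(groups) {
  k <- length(groups)
  n <- vapply(groups, length, numeric(1))
  m <- vapply(groups, mean, numeric(1))
  v <- vapply(groups, stats::var, numeric(1))
  w <- n / v
  mw <- sum(w * m) / sum(w)
  num <- sum(w * (m - mw)^2) / (k - 1)
  lam <- 3 * sum((1 - w / sum(w))^2 / (n - 1)) / (k^2 - 1)
  f <- num / (1 + 2 * lam * (k - 2) / 3)
  list(f = f, df1 = k - 1, df2 = 1 / lam)
}

test_that("Welch ANOVA matches the direct-formula oracle", {
  groups <- list(c(1, 2, 3), c(2, 3, 4), c(5, 6, 7))
  tab <- data.frame(displacement = unlist(groups),
                    g = rep(c("a", "b", "c"), lengths(groups)))
  w <- welch_anova(tab, "g")
  o <- welch_f_oracle(groups)
  expect_equal(w$statistic, o$f, tolerance = 1e-10)
  expect_equal(w$df1, o$df1)
  expect_equal(w$df2, o$df2, tolerance = 1e-10)
})

test_that("Welch ANOVA reduces to classical ANOVA under equal variances", {
  # for two groups with identical sample variances the Welch correction
  # term vanishes and the two F statistics coincide exactly, even with
  # unequal group sizes
  withr::with_seed(7, {
    x <- stats::rnorm(50)
    g <- rep(c("a", "b"), c(20, 30))
    for (lv in unique(g)) {
      idx <- g == lv
      x[idx] <- (x[idx] - mean(x[idx])) / stats::sd(x[idx])
    }
    x <- x + (g == "b") * 0.8
    tab <- data.frame(displacement = x, g = g)
    w <- welch_anova(tab, "g")
    f_classic <- summary(stats::aov(displacement ~ g, tab))[[1]]$`F value`[1]
    expect_equal(w$statistic, f_classic, tolerance = 1e-8)
  })
})

test_that("Welch ANOVA guards against degenerate inputs", {
  tab <- data.frame(displacement = c(2, 2, 2, 2, 3, 4), g = rep(c("a", "b"), each = 3))
  expect_error(welch_anova(tab, "g"), "degenerate variance")
  one <- data.frame(displacement = rnorm(5), g = "a")
  expect_error(welch_anova(one, "g"), "2 groups")

  # near-identical groups give F ~ 0
  tabj <- data.frame(
    displacement = c(2, 2 + 1e-9, 2 - 1e-9, 2, 2 + 1e-9, 2 - 1e-9),
    g = rep(c("a", "b"), each = 3))
  expect_lt(welch_anova(tabj, "g")$statistic, 1e-6)
})

test_that("null rejection rate of Welch ANOVA is calibrated", {
  # heteroscedastic null: identical means, different spreads and sizes
  rejections <- withr::with_seed(11, {
    mean(vapply(seq_len(2000), function(i) {
      tab <- data.frame(
        displacement = c(stats::rnorm(50), stats::rnorm(50, 0, 1)),
        g = rep(c("a", "b"), each = 50))
      welch_anova(tab, "g")$p.value < 0.05
    }, logical(1)))
  })
  expect_gte(rejections, 0.03)
  expect_lte(rejections, 0.07)
})

test_that("effect sizes follow the closed form", {
  es <- effect_sizes(0.2)
  expect_identical(es$cohens_f, 0.5)
  expect_identical(effect_sizes(0)$cohens_f, 0)
  # the published paired thresholds 0.14 / 0.4 are consistent
  expect_equal(effect_sizes(0.14)$cohens_f, 0.4034733, tolerance = 1e-6)
  expect_error(effect_sizes(1), "\\[0, 1\\)")
  expect_error(effect_sizes(-0.1), "\\[0, 1\\)")
  # invariant: f == sqrt(eta2 / (1 - eta2))
  for (e2 in c(0.05, 0.3, 0.7)) {
    es <- effect_sizes(e2)
    expect_equal(es$cohens_f, sqrt(e2 / (1 - e2)), tolerance = 1e-12)
  }
})

test_that("Games-Howell separates shifted groups and is antisymmetric", {
  withr::with_seed(3, {
    same <- data.frame(displacement = stats::rnorm(40),
                       g = rep(c("a", "b"), each = 20))
    gh <- games_howell(same, "g")
    expect_gt(gh$p_adj[1], 0.2)

    shifted <- data.frame(
      displacement = c(stats::rnorm(20), stats::rnorm(20, 5, 1)),
      g = rep(c("a", "b"), each = 20))
    gh2 <- games_howell(shifted, "g")
    expect_lt(gh2$p_adj[1], 0.001)
    expect_identical(gh2$stars[1], "***")
  })

  tab <- data.frame(displacement = c(1, 2, 3, 2, 3, 4, 5, 6, 7),
                    g = rep(c("a", "b", "c"), each = 3))
  gh3 <- games_howell(tab, "g")
  # diff(a, b) must be the negative of diff computed with swapped levels
  tab2 <- tab
  tab2$g <- factor(tab2$g, levels = c("c", "b", "a"))
  gh4 <- games_howell(tab2, "g")
  d_ab <- gh3$diff[gh3$group1 == "a" & gh3$group2 == "b"]
  d_ba <- gh4$diff[gh4$group1 == "b" & gh4$group2 == "a"]
  expect_equal(d_ab, -d_ba, tolerance = 1e-12)
})

test_that("the mixed model recovers injected protocol offsets", {
  tab <- make_lmm_table(seed = 1)
  fit <- lmm_compare(tab, "MR_coronal_10bin", include_waveform_mean = FALSE)
  truth <- c(CT = -0.88, MR_axial_5bin = -1.73)
  e <- fit$effects
  expect_setequal(e$protocol, names(truth))
  for (i in seq_len(nrow(e))) {
    expect_lt(abs(e$estimate[i] - truth[e$protocol[i]]), 2 * e$se[i])
  }
  # CI consistency by construction
  expect_equal(e$ci_low, e$estimate - 1.96 * e$se, tolerance = 1e-6)
  expect_equal(e$ci_high, e$estimate + 1.96 * e$se, tolerance = 1e-6)

  # with the pseudo-protocol the programmed-mean gap is recovered too
  fit2 <- lmm_compare(tab, "MR_coronal_10bin")
  wm <- fit2$effects[fit2$effects$protocol == "waveform_mean", ]
  expect_lt(abs(wm$estimate - 1.32), 3 * wm$se + 0.1)
})

test_that("zero offsets produce covering confidence intervals", {
  tab <- make_lmm_table(seed = 4,
                        offsets = c(MR_coronal_10bin = 0,
                                    MR_axial_5bin = 0, CT = 0))
  fit <- lmm_compare(tab, "MR_coronal_10bin", include_waveform_mean = FALSE)
  expect_true(all(fit$effects$ci_low < 0 & fit$effects$ci_high > 0))
})

test_that("protocol fixed effects are unbiased over repeated designs", {
  ests <- withr::with_seed(99, {
    t(vapply(seq_len(100), function(i) {
      tab <- make_lmm_table(seed = sample.int(1e6, 1))
      fit <- lmm_compare(tab, "MR_coronal_10bin",
                         include_waveform_mean = FALSE)
      e <- fit$effects
      c(CT = e$estimate[e$protocol == "CT"],
        ax = e$estimate[e$protocol == "MR_axial_5bin"])
    }, numeric(2)))
  })
  expect_lt(abs(mean(ests[, 1]) - (-0.88)), 0.1)
  expect_lt(abs(mean(ests[, 2]) - (-1.73)), 0.1)
})
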