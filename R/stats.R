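# Protocol comparison statistics: Welch's heteroscedastic ANOVA with
# eta-squared / Cohen's f effect sizes, Games-Howell post hoc pairwise
# tests, and a linear mixed-effects comparison across protocols.

check_groups <- function(x, g) {
  ok <- is.finite(x)
  x <- x[ok]
  g <- factor(g[ok])
  if (nlevels(g) < 2L) stop("need at least 2 groups", call. = FALSE)
  ns <- tapply(x, g, length)
  if (any(ns < 2L)) stop("every group needs >= 2 replicates", call. = FALSE)
  vs <- tapply(x, g, stats::var)
  if (any(vs == 0)) {
    stop("degenerate variance: a group has zero within-group variance",
         call. = FALSE)
  }
  list(x = x, g = g)
}

#' Welch's ANOVA with effect sizes
#'
#' Welch's heteroscedastic one-way ANOVA (base R's
#' [stats::oneway.test()] with `var.equal = FALSE`), augmented with
#' eta-squared computed from the classical between/total sums of squares --
#' the conventional effect size reported alongside Welch's F -- and the
#' derived Cohen's f.
#'
#' @param table Data frame of measurements.
#' @param group_by Name of the grouping column.
#' @param value Name of the response column (default `"displacement"`).
#' @return An object of class `welch_anova`: `statistic` (F), `df1`, `df2`
#'   (Satterthwaite), `p.value`, and `effect_sizes` (see [effect_sizes()]).
#' @export
welch_anova <- function(table, group_by, value = "displacement") {
  d <- check_groups(table[[value]], table[[group_by]])
  fit <- stats::oneway.test(d$x ~ d$g, var.equal = FALSE)
  grand <- mean(d$x)
  ss_between <- sum(tapply(d$x, d$g, function(v) {
    length(v) * (mean(v) - grand)^2
  }))
  ss_total <- sum((d$x - grand)^2)
  es <- effect_sizes(ss_between / ss_total)
  structure(list(statistic = unname(fit$statistic),
                 df1 = unname(fit$parameter[1L]),
                 df2 = unname(fit$parameter[2L]),
                 p.value = fit$p.value, effect_sizes = es,
                 group_by = group_by),
            class = "welch_anova")
}

#' @export
print.welch_anova <- function(x, ...) {
  cat(sprintf(
    "Welch's ANOVA on %s: F(%.4g, %.4g) = %.4g, p = %.4g\n",
    x$group_by, x$df1, x$df2, x$statistic, x$p.value))
  cat(sprintf("  eta^2 = %.4f, Cohen's f = %.4f\n",
              x$effect_sizes$eta_squared, x$effect_sizes$cohens_f))
  invisible(x)
}

#' ANOVA effect sizes from eta-squared
#'
#' Cohen's f is derived from eta-squared by
#' `f = sqrt(eta^2 / (1 - eta^2))`; the conventional large-effect
#' thresholds (eta^2 > 0.14, f > 0.4) are two views of the same quantity.
#'
#' @param eta_squared Proportion of variance explained, in `[0, 1)`.
#' @return An object of class `effect_sizes` with `eta_squared` and
#'   `cohens_f`.
#' @export
effect_sizes <- function(eta_squared) {
  if (!is.finite(eta_squared) || eta_squared < 0 || eta_squared >= 1) {
    stop("`eta_squared` must lie in [0, 1)", call. = FALSE)
  }
  structure(list(eta_squared = eta_squared,
                 cohens_f = sqrt(eta_squared / (1 - eta_squared))),
            class = "effect_sizes")
}

p_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
    ifelse(p < 0.05, "*", "")))
}

#' Games-Howell post hoc pairwise comparisons
#'
#' Pairwise comparisons under unequal variances: Welch-type standard
#' errors and degrees of freedom with studentized-range (Tukey) adjustment.
#' Significance stars follow the 0.05 / 0.01 / 0.001 convention.
#'
#' @inheritParams welch_anova
#' @param conf_level Confidence level for the adjusted intervals.
#' @return Data frame with one row per ordered pair: `group1`, `group2`,
#'   `diff` (mean of group1 minus group2), `se`, `t`, `df`, `p_adj`,
#'   `ci_low`, `ci_high`, `stars`.
#' @export
games_howell <- function(table, group_by, value = "displacement",
                         conf_level = 0.95) {
  d <- check_groups(table[[value]], table[[group_by]])
  lev <- levels(d$g)
  k <- length(lev)
  m <- tapply(d$x, d$g, mean)
  v <- tapply(d$x, d$g, stats::var)
  n <- tapply(d$x, d$g, length)
  pairs <- utils::combn(lev, 2L)
  res <- apply(pairs, 2L, function(pr) {
    i <- pr[1L]
    j <- pr[2L]
    se <- sqrt(v[i] / n[i] + v[j] / n[j])
    df <- se^4 / ((v[i] / n[i])^2 / (n[i] - 1) + (v[j] / n[j])^2 / (n[j] - 1))
    tstat <- (m[i] - m[j]) / se
    p <- stats::ptukey(abs(tstat) * sqrt(2), nmeans = k, df = df,
                       lower.tail = FALSE)
    qc <- stats::qtukey(conf_level, nmeans = k, df = df) / sqrt(2)
    c(diff = unname(m[i] - m[j]), se = unname(se), t = unname(tstat),
      df = unname(df), p_adj = unname(p),
      ci_low = unname(m[i] - m[j] - qc * se),
      ci_high = unname(m[i] - m[j] + qc * se))
  })
  out <- data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ],
                    t(res), row.names = NULL)
  out$stars <- p_stars(out$p_adj)
  out
}

#' Linear mixed-effects protocol comparison
#'
#' Fits `value ~ protocol + (1 | waveform)` by restricted maximum
#' likelihood, with the protocol factor releveled so every fixed effect is
#' a displacement difference relative to `reference`.  The random intercept
#' absorbs the between-waveform variability that comes with programming a
#' different mean amplitude per patient-derived waveform.  When the table
#' carries a `ground_truth_pp` column, a pseudo-protocol `"waveform_mean"`
#' (the programmed mean amplitude of each waveform) is added, so its fixed
#' effect reports how far the reference protocol sits from the programmed
#' motion.  Confidence intervals are Wald (`estimate +/- 1.96 SE`);
#' p-values use Satterthwaite degrees of freedom.
#'
#' A singular random-effects fit is flagged and the function falls back to
#' a per-waveform paired summary (mean over waveforms of the within-
#' waveform protocol difference) with a warning.
#'
#' @param table Data frame with the response, a protocol column and a
#'   waveform id column; optionally `ground_truth_pp` in mm.
#' @param reference Protocol level used as the reference.
#' @param value,protocol,waveform Column names.
#' @param include_waveform_mean Add the programmed-amplitude
#'   pseudo-protocol (default: when `ground_truth_pp` is available).
#' @return An object of class `lmm_result`: data frame `effects` with
#'   `protocol`, `estimate`, `se`, `ci_low`, `ci_high`, `p`, `stars`; plus
#'   `reference`, `random_sd` (waveform), `residual_sd`, `singular`.
#' @export
lmm_compare <- function(table, reference, value = "displacement",
                        protocol = "protocol", waveform = "waveform_id",
                        include_waveform_mean = NULL) {
  df <- data.frame(y = table[[value]],
                   protocol = as.character(table[[protocol]]),
                   waveform = as.character(table[[waveform]]))
  df <- df[is.finite(df$y), ]
  if (is.null(include_waveform_mean)) {
    include_waveform_mean <- "ground_truth_pp" %in% names(table) &&
      any(is.finite(table$ground_truth_pp))
  }
  if (include_waveform_mean) {
    gt <- table[is.finite(table$ground_truth_pp), ]
    extra <- data.frame(y = gt$ground_truth_pp,
                        protocol = "waveform_mean",
                        waveform = as.character(gt[[waveform]]))
    df <- rbind(df, extra)
  }
  if (!reference %in% df$protocol) {
    stop("reference protocol not present in the table", call. = FALSE)
  }
  df$protocol <- stats::relevel(factor(df$protocol), ref = reference)
  if (nlevels(df$protocol) < 2L || length(unique(df$waveform)) < 2L) {
    stop("need >= 2 protocols and >= 2 waveforms", call. = FALSE)
  }
  fit <- lmerTest::lmer(y ~ protocol + (1 | waveform), data = df,
                        REML = TRUE)
  singular <- lme4::isSingular(fit)
  cf <- stats::coef(summary(fit))
  rows <- grep("^protocol", rownames(cf))
  eff <- data.frame(
    protocol = sub("^protocol", "", rownames(cf)[rows]),
    estimate = cf[rows, "Estimate"], se = cf[rows, "Std. Error"],
    p = cf[rows, "Pr(>|t|)"], row.names = NULL)
  if (singular) {
    warning(paste("singular random-effects fit; reporting per-waveform",
                  "paired summary"), call. = FALSE)
    ref_mean <- tapply(df$y[df$protocol == reference],
                       df$waveform[df$protocol == reference], mean)
    eff <- do.call(rbind, lapply(setdiff(levels(df$protocol), reference),
      function(lv) {
        sub <- df[df$protocol == lv, ]
        pm <- tapply(sub$y, sub$waveform, mean)
        common <- intersect(names(pm), names(ref_mean))
        diffs <- pm[common] - ref_mean[common]
        se <- stats::sd(diffs) / sqrt(length(diffs))
        data.frame(protocol = lv, estimate = mean(diffs), se = se,
                   p = tryCatch(stats::t.test(diffs)$p.value,
                                error = function(e) NA_real_))
      }))
  }
  eff$ci_low <- eff$estimate - 1.96 * eff$se
  eff$ci_high <- eff$estimate + 1.96 * eff$se
  eff$stars <- p_stars(eff$p)
  eff <- eff[, c("protocol", "estimate", "se", "ci_low", "ci_high", "p",
                 "stars")]
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(effects = eff, reference = reference,
                 random_sd = vc$sdcor[vc$grp == "waveform"],
                 residual_sd = vc$sdcor[vc$grp == "Residual"],
                 singular = singular, fit = fit),
            class = "lmm_result")
}

#' @export
print.lmm_result <- function(x, ...) {
  cat(sprintf("Linear mixed model (reference: %s)%s\n", x$reference,
              if (x$singular) " [singular fit -> paired summary]" else ""))
  e <- x$effects
  for (i in seq_len(nrow(e))) {
    cat(sprintf("  %-18s %+.2f +/- %.2f mm (95%% CI [%.2f, %.2f]) p = %.3g %s\n",
                e$protocol[i], e$estimate[i], e$se[i], e$ci_low[i],
                e$ci_high[i], e$p[i], e$stars[i]))
  }
  cat(sprintf("  waveform SD %.3f mm, residual SD %.3f mm\n",
              x$random_sd, x$residual_sd))
  invisible(x)
}
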