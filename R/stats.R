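#' Percent change from pre to post
#'
#' `100 * (post - pre) / pre`.  Positive values mean the raw measure
#' increased; for measures where lower is better (logMAR acuity, stereo
#' thresholds in arcsec, interocular delay) improvement is a negative
#' percent change, and [summarize_study()] reports the signed raw
#' difference alongside.
#'
#' @param pre,post Numeric vectors (recycled); `pre` must be nonzero.
#' @return Numeric vector of percent changes.
#' @examples
#' percent_change(22.8, 26.7)   # ~17.1
#' @export
percent_change <- function(pre, post) {
  if (any(pre == 0)) stop("`pre` must be nonzero")
  100 * (post - pre) / pre
}

.stats_result <- function(statistic, df, p_value, test_name) {
  structure(
    list(statistic = unname(statistic), df = unname(df),
         p_value = unname(p_value), test_name = test_name, tails = 2L),
    class = "stats_result"
  )
}

#' @export
print.stats_result <- function(x, ...) {
  p <- if (x$p_value < 0.001) "p << 0.01" else sprintf("p = %.3g", x$p_value)
  cat(sprintf("%s: t(%s) = %.4g, %s (two-tailed)\n", x$test_name,
              format(x$df, digits = 4), x$statistic, p))
  invisible(x)
}

#' Paired two-tailed t-test
#'
#' Planned pre/post comparison within subjects:
#' \eqn{t = \bar d / (s_d / \sqrt n)} with \eqn{d = pre - post} and
#' \eqn{df = n - 1}.  A positive statistic means the measure decreased.
#'
#' @param pre,post Numeric vectors of equal length (n >= 2), pairwise by
#'   subject.
#' @return A `stats_result` with `statistic`, `df`, `p_value`.
#' @export
paired_t <- function(pre, post) {
  stopifnot(length(pre) == length(post), length(pre) >= 2)
  d <- pre - post
  if (stats::sd(d) <= 1e-12 * max(abs(mean(d)), 1)) {
    stop("zero-variance differences: the paired t statistic is undefined")
  }
  tt <- tryCatch(stats::t.test(pre, post, paired = TRUE),
                 error = function(e) {
                   stop("zero-variance differences: the paired t statistic ",
                        "is undefined", call. = FALSE)
                 })
  .stats_result(tt$statistic, tt$parameter, tt$p.value, "paired t-test")
}

#' Welch two-sample two-tailed t-test
#'
#' Between-group comparison without assuming equal variances
#' (Welch-Satterthwaite degrees of freedom).
#'
#' @param group_a,group_b Numeric vectors, each of length >= 2.
#' @return A `stats_result`.
#' @export
welch_t <- function(group_a, group_b) {
  stopifnot(length(group_a) >= 2, length(group_b) >= 2)
  tt <- stats::t.test(group_a, group_b, var.equal = FALSE)
  .stats_result(tt$statistic, tt$parameter, tt$p.value, "Welch t-test")
}

#' Two-factor within-subject ANOVA
#'
#' Repeated-measures ANOVA with two within-subject factors (by default
#' phase and eye condition), fitted with per-subject error strata.  Degenerate
#' tables are handled explicitly rather than returning NaN: an effect with
#' zero sum of squares reports F = 0, p = 1, and an effect with positive sum
#' of squares over a zero-residual stratum reports F = Inf, p = 0 with a
#' note.
#'
#' @param data Long-format data.frame.
#' @param dv Name of the response column.
#' @param subject Name of the subject identifier column.
#' @param within Character vector naming the two within-subject factor
#'   columns.
#' @return A data.frame with one row per effect: `effect`, `df1`, `df2`,
#'   `F`, `p_value`, `note`.
#' @export
rm_anova <- function(data, dv = "value", subject = "subject",
                     within = c("phase", "condition")) {
  stopifnot(is.data.frame(data), length(within) == 2,
            all(c(dv, subject, within) %in% names(data)))
  d <- data.frame(
    y = data[[dv]],
    subject = factor(data[[subject]]),
    f1 = factor(data[[within[1]]]),
    f2 = factor(data[[within[2]]])
  )
  tab <- table(d$subject, d$f1, d$f2)
  if (any(tab != 1)) {
    stop("design must be balanced and complete: one observation per ",
         "subject x ", within[1], " x ", within[2], " cell")
  }
  fit <- stats::aov(y ~ f1 * f2 + Error(subject / (f1 * f2)), data = d)
  sm <- summary(fit)
  tot_ss <- sum((d$y - mean(d$y))^2)
  scale <- max(tot_ss, 1e-12)
  out <- NULL
  for (stratum in sm) {
    ta <- stratum[[1]]
    rn <- trimws(rownames(ta))
    resid_row <- rn == "Residuals"
    if (!any(resid_row) || all(resid_row)) next
    ss_err <- ta[resid_row, "Sum Sq"]
    df_err <- ta[resid_row, "Df"]
    for (i in which(!resid_row)) {
      ss <- ta[i, "Sum Sq"]
      df1 <- ta[i, "Df"]
      if (ss / scale < 1e-9) {
        row <- data.frame(effect = rn[i], df1 = df1, df2 = df_err,
                          F = 0, p_value = 1, note = "zero effect SS")
      } else if (ss_err / scale < 1e-9) {
        row <- data.frame(effect = rn[i], df1 = df1, df2 = df_err,
                          F = Inf, p_value = 0,
                          note = "zero residual SS: F unbounded")
      } else {
        Fv <- (ss / df1) / (ss_err / df_err)
        row <- data.frame(effect = rn[i], df1 = df1, df2 = df_err, F = Fv,
                          p_value = stats::pf(Fv, df1, df_err,
                                              lower.tail = FALSE),
                          note = "")
      }
      out <- rbind(out, row)
    }
  }
  effect_names <- c(f1 = within[1], f2 = within[2],
                    `f1:f2` = paste(within, collapse = ":"))
  out$effect <- ifelse(out$effect %in% names(effect_names),
                       effect_names[out$effect], out$effect)
  rownames(out) <- NULL
  out
}

#' Reference group-level means
#'
#' Published group means for the study conditions the synthetic-data
#' generator emulates: pre- and post-training measures for six adult
#' amblyopes (amblyopic eye AE, fellow eye FE, binocular OU) and six
#' normally sighted controls (non-dominant NDE, dominant DE, OU).  These
#' serve as default ground-truth values for simulator fixtures and as the
#' input table for the printed-arithmetic checks in the report stage
#' (session-course CFF gain, acuity and stereo changes, interocular-delay
#' improvement).
#'
#' @return A data.frame with columns `group`, `measure`, `condition`,
#'   `unit`, `pre`, `post` (`NA` where no group mean was reported).
#' @export
reference_group_means <- function() {
  rbind(
    data.frame(group = "amblyopic", measure = "cff_training",
               condition = "AE", unit = "Hz", pre = 22.8, post = 26.7),
    data.frame(group = "normal", measure = "cff_training",
               condition = "NDE", unit = "Hz", pre = 30.34, post = 30.7),
    data.frame(group = "amblyopic", measure = "cff_staircase",
               condition = c("AE", "FE"), unit = "Hz",
               pre = c(27.3, 30.1), post = c(30.6, 31.7)),
    data.frame(group = "normal", measure = "cff_staircase",
               condition = "NDE", unit = "Hz", pre = 31.41, post = 33.02),
    data.frame(group = "amblyopic", measure = "va",
               condition = c("AE", "FE", "OU"), unit = "logMAR",
               pre = c(0.38, 0.02, -0.01), post = c(0.26, -0.03, -0.05)),
    data.frame(group = "normal", measure = "va",
               condition = c("NDE", "DE", "OU"), unit = "logMAR",
               pre = c(-0.07, -0.07, -0.10), post = c(-0.10, -0.08, -0.12)),
    data.frame(group = "amblyopic", measure = "stereo_flicker",
               condition = "OU", unit = "arcsec", pre = 618.4, post = 533.6),
    data.frame(group = "amblyopic", measure = "stereo_static",
               condition = "OU", unit = "arcsec", pre = 409.3, post = 348.04),
    data.frame(group = "amblyopic", measure = "stereo_randot",
               condition = "OU", unit = "arcsec", pre = 280, post = 137),
    data.frame(group = "amblyopic", measure = "vep_amplitude",
               condition = c("AE", "FE", "OU"), unit = "uV",
               pre = c(2.63, 3.4, 2.8), post = c(3.54, 3.8, 3.6)),
    data.frame(group = "normal", measure = "vep_amplitude",
               condition = c("NDE", "DE", "OU"), unit = "uV",
               pre = c(3.17, 3.12, 4.01), post = c(3.5, 3.45, 4.03)),
    data.frame(group = "amblyopic", measure = "vep_snr",
               condition = c("AE", "FE"), unit = "ratio",
               pre = c(14.5, 19.6), post = c(18.9, NA)),
    data.frame(group = "normal", measure = "vep_snr",
               condition = c("DE", "NDE", "OU"), unit = "ratio",
               pre = c(17.9, 19.5, 24.87), post = c(17.5, 19.44, 24.4)),
    data.frame(group = "amblyopic", measure = "vep_delay",
               condition = "interocular", unit = "ms", pre = 8.8, post = 3.0),
    data.frame(group = "normal", measure = "vep_delay",
               condition = "interocular", unit = "ms", pre = 2.6, post = NA)
  )
}

#' Summarize a study's measure table
#'
#' Aggregates a long-format measure table into the report tables of a
#' pre/post training study: per group, measure and eye condition it gives
#' group means, the signed raw change (pre - post for lower-is-better
#' measures is left to the reader; the column is post - pre), both
#' percent-change conventions (percent change of the group means, and the
#' mean of per-subject percent changes -- these differ, and only the latter
#' matches per-subject-normalized figures), dispersion as both SD and SE,
#' the planned paired comparison, and a Shapiro-Wilk normality diagnostic
#' of the paired differences backing the usual quantile-quantile check.
#'
#' @param measures Data.frame with columns `subject`, `group`, `measure`,
#'   `condition`, `phase` (`"pre"`/`"post"`), `value` (and optionally
#'   `unit`).
#' @param holm Apply a Holm adjustment across the planned comparisons
#'   (default FALSE: planned comparisons are reported uncorrected).
#' @return An object of class `study_summary`: a data.frame with one row
#'   per group x measure x condition.
#' @export
summarize_study <- function(measures, holm = FALSE) {
  req <- c("subject", "group", "measure", "condition", "phase", "value")
  stopifnot(is.data.frame(measures), all(req %in% names(measures)))
  stopifnot(all(measures$phase %in% c("pre", "post")))
  keys <- unique(measures[, c("group", "measure", "condition")])
  rows <- NULL
  for (i in seq_len(nrow(keys))) {
    sub <- measures[measures$group == keys$group[i] &
                    measures$measure == keys$measure[i] &
                    measures$condition == keys$condition[i], ]
    pre <- sub$value[sub$phase == "pre"][order(sub$subject[sub$phase == "pre"])]
    post <- sub$value[sub$phase == "post"][order(sub$subject[sub$phase == "post"])]
    if (!length(pre) || length(pre) != length(post)) next
    n <- length(pre)
    diffs <- post - pre
    tt <- if (n >= 2) tryCatch(paired_t(pre, post), error = function(e) NULL)
          else NULL
    sw <- if (n >= 3 && stats::sd(diffs) > 0) {
      stats::shapiro.test(diffs)$p.value
    } else NA_real_
    rows <- rbind(rows, data.frame(
      group = keys$group[i], measure = keys$measure[i],
      condition = keys$condition[i], n = n,
      pre_mean = mean(pre), post_mean = mean(post),
      change = mean(diffs),
      change_sd = stats::sd(diffs), change_se = stats::sd(diffs) / sqrt(n),
      pct_change_of_means = if (mean(pre) != 0)
        percent_change(mean(pre), mean(post)) else NA_real_,
      mean_subject_pct_change = if (all(pre != 0))
        mean(percent_change(pre, post)) else NA_real_,
      t = if (is.null(tt)) NA_real_ else tt$statistic,
      df = if (is.null(tt)) NA_real_ else tt$df,
      p_value = if (is.null(tt)) NA_real_ else tt$p_value,
      shapiro_p = sw))
  }
  if (holm && any(!is.na(rows$p_value))) {
    rows$p_holm <- stats::p.adjust(rows$p_value, method = "holm")
  }
  structure(rows, class = c("study_summary", "data.frame"))
}

#' @export
print.study_summary <- function(x, ...) {
  y <- as.data.frame(x)
  y$p_value <- ifelse(is.na(y$p_value), NA,
                      ifelse(y$p_value < 0.001, "<< 0.01",
                             sprintf("%.3g", y$p_value)))
  print(y, row.names = FALSE, digits = 4)
  invisible(x)
}
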