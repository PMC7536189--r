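#' @title Comparison result container
#' @description Uniform return type of the test battery: effect size
#'   (difference of means where meaningful), test statistic, (possibly
#'   corrected, real-valued) degrees of freedom, two-sided p-value, the
#'   correction applied and a test label.
#' @param effect numeric effect (difference of means) or `NA`.
#' @param statistic test statistic.
#' @param df degrees of freedom (scalar or length-2 for F tests).
#' @param p_value two-sided p-value.
#' @param correction `"none"`, `"greenhouse_geisser"` or `"bonferroni"`.
#' @param test_name label.
#' @param extra optional named list merged into the result.
#' @keywords internal
comparison_result <- function(effect, statistic, df, p_value,
                              correction = "none", test_name, extra = NULL) {
  out <- c(list(effect = effect, statistic = statistic, df = df,
                p_value = p_value, correction = correction,
                test_name = test_name), extra)
  class(out) <- "comparison_result"
  out
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<%s> statistic = %.4g, df = %s, p = %.4g%s\n",
              x$test_name, x$statistic,
              paste(signif(x$df, 4), collapse = ", "), x$p_value,
              if (x$correction != "none") paste0(" [", x$correction, "]")
              else ""))
  invisible(x)
}

#' Paired two-sided t-test
#'
#' Student's paired t-test, the comparison used for within-animal
#' baseline-versus-learning contrasts.
#'
#' @param x,y paired numeric vectors of equal length >= 2.
#' @return a `comparison_result`.
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2)
    stop("paired test needs equal lengths >= 2")
  d <- x - y
  if (stats::sd(d) == 0) {
    if (mean(d) == 0)
      return(comparison_result(0, 0, length(d) - 1, 1, "none", "paired t"))
    stop("degenerate test")
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  comparison_result(mean(d), unname(tt$statistic), unname(tt$parameter),
                    tt$p.value, "none", "paired t")
}

#' Unpaired two-sided t-test (equal variances)
#'
#' Student's two-sample t-test with pooled variance, used for group
#' comparisons.
#'
#' @param x,y numeric vectors, each of length >= 2.
#' @return a `comparison_result`.
#' @export
unpaired_t <- function(x, y) {
  if (length(x) < 2 || length(y) < 2)
    stop("unpaired test needs two samples of length >= 2")
  if (stats::sd(x) == 0 && stats::sd(y) == 0) stop("degenerate test")
  tt <- stats::t.test(x, y, var.equal = TRUE)
  comparison_result(mean(x) - mean(y), unname(tt$statistic),
                    unname(tt$parameter), tt$p.value, "none", "unpaired t")
}

#' One-way repeated-measures ANOVA with sphericity handling
#'
#' Fits the one-way within-subject ANOVA on a subjects-by-conditions
#' matrix. Mauchly's test of sphericity is computed (for 3 or more
#' conditions); when sphericity is rejected at `alpha`, the
#' Greenhouse-Geisser epsilon-corrected degrees of freedom and p-value
#' are reported instead of the uncorrected ones.
#'
#' @param data numeric matrix, rows = subjects, columns = conditions;
#'   no missing cells.
#' @param alpha significance level of the Mauchly test (default 0.05).
#' @return a `comparison_result` with extra fields `gg_epsilon`,
#'   `mauchly_w`, `mauchly_p`, `df_uncorrected`.
#' @export
rm_anova <- function(data, alpha = 0.05) {
  data <- as.matrix(data)
  if (anyNA(data)) stop("unbalanced design")
  n <- nrow(data); k <- ncol(data)
  if (n < 3 || k < 2) stop("need >= 3 subjects and >= 2 conditions")

  grand <- mean(data)
  ss_cond <- n * sum((colMeans(data) - grand)^2)
  ss_subj <- k * sum((rowMeans(data) - grand)^2)
  ss_err <- sum((data - outer(rowMeans(data), colMeans(data), "+") + grand)^2)
  if (ss_cond < 1e-12 * max(1, grand^2))
    return(comparison_result(NA_real_, 0, c(k - 1, (k - 1) * (n - 1)), 1,
                             "none", "rm ANOVA",
                             extra = list(gg_epsilon = NA_real_,
                                          mauchly_w = NA_real_,
                                          mauchly_p = NA_real_,
                                          df_uncorrected = c(k - 1, (k - 1) * (n - 1)))))

  mlm <- stats::lm(data ~ 1)
  idata <- data.frame(cond = factor(seq_len(k)))
  aov_res <- car::Anova(mlm, idata = idata, idesign = ~cond, type = 3)
  # car warns when the Huynh-Feldt epsilon exceeds 1; HF is not used here
  s <- suppressWarnings(summary(aov_res, multivariate = FALSE))
  uni <- s$univariate.tests
  fval <- uni["cond", "F value"]
  df1 <- uni["cond", "num Df"]; df2 <- uni["cond", "den Df"]
  pval <- uni["cond", "Pr(>F)"]

  mw <- NA_real_; mp <- NA_real_; eps <- NA_real_
  correction <- "none"; df <- c(df1, df2)
  if (k >= 3) {
    mw <- s$sphericity.tests["cond", "Test statistic"]
    mp <- s$sphericity.tests["cond", "p-value"]
    eps <- s$pval.adjustments["cond", "GG eps"]
    if (!is.na(mp) && mp < alpha) {
      correction <- "greenhouse_geisser"
      df <- c(df1 * eps, df2 * eps)
      pval <- s$pval.adjustments["cond", "Pr(>F[GG])"]
    }
  }
  comparison_result(NA_real_, unname(fval), unname(df), unname(pval),
                    correction, "rm ANOVA",
                    extra = list(gg_epsilon = unname(eps),
                                 mauchly_w = unname(mw),
                                 mauchly_p = unname(mp),
                                 df_uncorrected = c(df1, df2)))
}

#' Pearson correlation with two-sided test
#'
#' @param x,y numeric vectors of equal length >= 3 with nonzero variance.
#' @return list with `r` and `p` (two-sided, from the t transform),
#'   plus `n`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("correlation needs equal lengths >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("degenerate correlation")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Shapiro-Wilk normality test
#'
#' @param x numeric vector (3 <= n <= 5000, nonconstant).
#' @return list with `W` and `p`.
#' @export
shapiro_wilk <- function(x) {
  if (length(x) < 3) stop("degenerate sample")
  res <- tryCatch(stats::shapiro.test(x),
                  error = function(e) stop("degenerate sample"))
  list(W = unname(res$statistic), p = res$p.value)
}

#' Bonferroni adjustment
#'
#' `min(1, p * m)` for a family of `m` comparisons.
#'
#' @param p_values numeric vector of raw p-values in \[0,1\].
#' @param m family size (default `length(p_values)`); must be at least
#'   the number of p-values supplied.
#' @return adjusted p-values.
#' @export
bonferroni <- function(p_values, m = length(p_values)) {
  if (any(p_values < 0 | p_values > 1)) stop("p-values must lie in [0,1]")
  if (m < length(p_values)) stop("invalid family size")
  pmin(1, p_values * m)
}
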