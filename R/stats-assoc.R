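# Association stage: Bonferroni-gated Pearson correlations with a critical
# correlation threshold, normality-gated non-parametric subgroup tests, the
# interaction regression of recovery on network expression x lesion volume,
# and median/range descriptives.

#' Bonferroni-corrected per-comparison alpha
#'
#' @param alpha family-wise significance level.
#' @param m number of comparisons (>= 1).
#' @return list: \code{alpha} (full precision alpha/m) and \code{rounded}
#'   (three decimals, as conventionally printed).
#' @examples
#' bonferroniAlpha(0.05, 8)  # 0.00625, printed 0.006
#' @export
bonferroniAlpha <- function(alpha, m) {
  if (m < 1) stop("m must be >= 1")
  a <- alpha / m
  list(alpha = a, rounded = round(a, 3))
}

#' Critical Pearson correlation at a given alpha
#'
#' Inverts the t test of a correlation coefficient: r_crit =
#' t / sqrt(t^2 + n - 2) with t the Student quantile at the stated tail
#' probability on n - 2 degrees of freedom. Monotone decreasing in n.
#'
#' @param n sample size (>= 4).
#' @param alpha per-comparison significance level.
#' @param tails "two" (default) or "one".
#' @return critical |r|.
#' @export
criticalR <- function(n, alpha, tails = c("two", "one")) {
  tails <- match.arg(tails)
  if (n < 4) stop("n must be >= 4")
  p <- if (tails == "two") 1 - alpha / 2 else 1 - alpha
  t <- qt(p, df = n - 2)
  t / sqrt(t^2 + n - 2)
}

#' Pearson correlations against external variables, Bonferroni-gated
#'
#' @param coefficients per-scan values (e.g. component expression).
#' @param externals data.frame of per-scan variables.
#' @param alpha family-wise level (default 0.05).
#' @param m comparison count for the correction (default: number of
#'   externals).
#' @return data.frame: variable, n, r, alpha_per_comparison, critical_r,
#'   significant; r is NA (flagged non-significant) for zero-variance input.
#' @export
correlateWithExternals <- function(coefficients, externals, alpha = 0.05,
                                   m = ncol(externals)) {
  aPer <- bonferroniAlpha(alpha, m)$alpha
  rows <- lapply(names(externals), function(v) {
    x <- externals[[v]]
    ok <- complete.cases(coefficients, x)
    n <- sum(ok)
    if (n < 4 || sd(x[ok]) == 0 || sd(coefficients[ok]) == 0) {
      warning("correlation undefined for '", v, "'")
      r <- NA_real_; rc <- NA_real_
    } else {
      r <- cor(coefficients[ok], x[ok])
      rc <- criticalR(n, aPer)
    }
    data.frame(variable = v, n = n, r = r, alpha_per_comparison = aPer,
               critical_r = rc, significant = !is.na(r) && abs(r) > rc,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Subgroup comparisons with a normality gate
#'
#' Reports the Shapiro-Wilk normality test of the variable, the
#' Kruskal-Wallis rank test across the subgroups, and the two-tailed
#' Mann-Whitney U test of the impaired subgroup against the pooled
#' recovered (fast + slow) patients.
#'
#' @param values per-patient scalar variable.
#' @param classes subgroup labels ("fast"/"slow"/"impaired").
#' @param alpha significance level carried into the report (default 0.05).
#' @return list: shapiro_p, kruskal_p, mannwhitney_p (impaired vs pooled
#'   recovered; NA if no impaired group), alpha, degenerate flag.
#' @export
subgroupTests <- function(values, classes, alpha = 0.05) {
  classes <- as.character(classes)
  tabn <- table(classes)
  if (length(tabn) < 2L) stop("need at least 2 subgroups")
  if (any(tabn < 2L)) stop("every subgroup must have >= 2 patients")
  degenerate <- sd(values) == 0
  sw <- if (degenerate) NA_real_ else
    tryCatch(shapiro.test(values)$p.value, error = function(e) NA_real_)
  kw <- if (degenerate) 1 else
    tryCatch(kruskal.test(values, factor(classes))$p.value,
             error = function(e) 1)
  mw <- NA_real_
  if ("impaired" %in% classes) {
    imp <- values[classes == "impaired"]
    rec <- values[classes != "impaired"]
    mw <- if (degenerate) 1 else
      tryCatch(suppressWarnings(
        wilcox.test(imp, rec, alternative = "two.sided")$p.value),
        error = function(e) 1)
  }
  list(shapiro_p = sw, kruskal_p = kw, mannwhitney_p = mw, alpha = alpha,
       degenerate = degenerate, n = as.list(tabn))
}

#' Interaction regression of recovery on network expression and lesion volume
#'
#' Fits y = b0 + b1 x1 + b2 x2 + b3 (x1 x2) by ordinary least squares, or by
#' iteratively reweighted least squares with Huber weights (tuning constant
#' 1.345) when \code{robust = TRUE}. Reports per-term estimates, standard
#' errors and t statistics on n - 4 degrees of freedom, the overall R
#' squared and the F statistic on (3, n - 4).
#'
#' @param y response (e.g. behavioural recovery expression).
#' @param x1 network expression coefficients.
#' @param x2 lesion volume (cc).
#' @param robust use Huber IRLS instead of OLS.
#' @return list of class \code{"RegressionResult"}: coefficients table,
#'   df, r_squared, f_statistic, f_df, f_p.
#' @export
interactionRegression <- function(y, x1, x2, robust = FALSE) {
  n <- length(y)
  if (n <= 4) stop("need n > 4 observations")
  d <- data.frame(y = y, x1 = x1, x2 = x2, x1x2 = x1 * x2)
  X <- cbind(1, d$x1, d$x2, d$x1x2)
  kap <- kappa(crossprod(scale(X[, -1])), exact = TRUE)
  if (!is.finite(kap) || kap > 1e12) {
    stop("collinear design: x1, x2 and x1:x2 are not jointly identifiable")
  }
  fit <- if (robust) {
    MASS::rlm(y ~ x1 + x2 + x1x2, data = d, psi = MASS::psi.huber,
              k = 1.345, maxit = 100)
  } else {
    lm(y ~ x1 + x2 + x1x2, data = d)
  }
  est <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  tval <- est / se
  df <- n - 4L
  res <- residuals(fit)
  rsq <- 1 - sum(res^2) / sum((y - mean(y))^2)
  fstat <- (rsq / 3) / ((1 - rsq) / df)
  out <- list(
    coefficients = data.frame(
      term = c("(Intercept)", "x1", "x2", "x1:x2"),
      estimate = unname(est), se = unname(se), t = unname(tval),
      p = unname(2 * pt(abs(tval), df, lower.tail = FALSE)),
      stringsAsFactors = FALSE),
    df = df, r_squared = rsq, f_statistic = fstat, f_df = c(3L, df),
    f_p = pf(fstat, 3, df, lower.tail = FALSE),
    robust = robust)
  class(out) <- "RegressionResult"
  out
}

#' @export
print.RegressionResult <- function(x, ...) {
  cat(sprintf("Interaction regression (%s): R2 = %.3f, F(%d, %d) = %.2f, p = %.3g\n",
              if (x$robust) "Huber IRLS" else "OLS", x$r_squared,
              x$f_df[1], x$f_df[2], x$f_statistic, x$f_p))
  print(x$coefficients, row.names = FALSE)
  invisible(x)
}

#' Median and range descriptives
#'
#' Median (mean of the two middle values for even n) and (min, max) range.
#'
#' @param values nonempty numeric vector (NAs dropped).
#' @return list: median, range (length-2).
#' @export
descriptives <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0L) stop("empty input")
  list(median = median(values), range = range(values))
}
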