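# Response-feature analysis: impute missing z-scores, fit linear and
# exponential recovery models per patient, select by AIC, classify into
# fast / slow / impaired subgroups, and run the behavioural PCA with
# Kaiser-Guttmann component selection.

#' Column-mean imputation of a patients-by-visits matrix
#'
#' Each missing cell is replaced by the mean of the observed values at the
#' same visit (column); observed cells are untouched.
#'
#' @param m numeric matrix (patients x visits) with NA for missing cells.
#' @return completed matrix.
#' @export
imputeMissing <- function(m) {
  if (any(colSums(!is.na(m)) == 0)) {
    stop("a visit column has no observed values; cannot impute")
  }
  for (j in seq_len(ncol(m))) {
    miss <- is.na(m[, j])
    if (any(miss)) m[miss, j] <- mean(m[!miss, j])
  }
  m
}

# profiled exponential fit: for fixed tau the model
#   z(t) = zInf - (zInf - z0) exp(-t/tau) = c0 + c1 exp(-t/tau)
# is linear in (c0, c1); RSS(tau) is minimised over a tau grid and refined
# by 1-D optimisation around the best grid point
.fitExponential <- function(z, t, tauGrid = c(5, 15, 30, 60, 120, 240)) {
  rssAt <- function(tau) {
    b <- cbind(1, exp(-t / tau))
    fit <- .lm.fit(b, z)
    sum(fit$residuals^2)
  }
  rssGrid <- vapply(tauGrid, rssAt, numeric(1))
  best <- which.min(rssGrid)
  lo <- tauGrid[max(1L, best - 1L)] / 2
  hi <- tauGrid[min(length(tauGrid), best + 1L)] * 2
  opt <- tryCatch(optimize(rssAt, c(lo, hi)), error = function(e) NULL)
  tau <- if (!is.null(opt) && opt$objective <= min(rssGrid)) {
    opt$minimum
  } else tauGrid[best]
  b <- cbind(1, exp(-t / tau))
  fit <- .lm.fit(b, z)
  c0 <- fit$coefficients[1]; c1 <- fit$coefficients[2]
  list(zInf = c0, z0 = c0 + c1, tau = tau, rss = sum(fit$residuals^2))
}

.aic <- function(rss, n, k, aicc = FALSE) {
  a <- 2 * k + n * log(max(rss, 1e-24) / n)
  if (aicc) a <- a + 2 * k * (k + 1) / max(n - k - 1, 1)
  a
}

#' Fit recovery models to one patient's z-score series
#'
#' Fits a linear model z = a + b t (closed-form least squares) and an
#' exponential model z = zInf - (zInf - z0) exp(-t/tau) (profiled nonlinear
#' least squares over a tau grid with local refinement). The better model by
#' AIC = 2k + n ln(RSS/n) is selected; ties favour the linear model (fewer
#' parameters). The asymptote is zInf for the exponential family and the
#' fitted value at the last visit for the linear family.
#'
#' @param z numeric z-score series (>= 4 observations, no NA — impute first).
#' @param days visit days matching \code{z}.
#' @param aicc use the small-sample corrected criterion instead (default
#'   FALSE).
#' @param tauGrid multi-start grid of time constants (days).
#' @return list of class \code{"RecoveryFit"}: family, parameters, rss,
#'   aic for both families, asymptote, class label.
#' @export
fitRecoveryModels <- function(z, days, aicc = FALSE,
                              tauGrid = c(5, 15, 30, 60, 120, 240)) {
  ok <- is.finite(z) & is.finite(days)
  z <- z[ok]; t <- days[ok]
  n <- length(z)
  if (n < 4L) stop("need >= 4 observations to compare 2- and 3-parameter fits")
  linfit <- .lm.fit(cbind(1, t), z)
  linRss <- sum(linfit$residuals^2)
  expfit <- tryCatch(.fitExponential(z, t, tauGrid), error = function(e) NULL)
  aicLin <- .aic(linRss, n, 2L, aicc)
  if (is.null(expfit)) {
    warning("exponential fit failed from all starts; falling back to linear")
    aicExp <- Inf
  } else {
    aicExp <- .aic(expfit$rss, n, 3L, aicc)
  }
  useExp <- is.finite(aicExp) && aicExp < aicLin
  fit <- if (useExp) {
    list(family = "exponential",
         parameters = c(z0 = unname(expfit$z0), zInf = unname(expfit$zInf),
                        tau = unname(expfit$tau)),
         rss = expfit$rss,
         asymptote = unname(expfit$zInf))
  } else {
    a <- linfit$coefficients[1]; b <- linfit$coefficients[2]
    list(family = "linear",
         parameters = c(a = unname(a), b = unname(b)),
         rss = linRss,
         asymptote = unname(a + b * max(t)))
  }
  fit$aic <- c(linear = aicLin, exponential = aicExp)
  fit$n <- n
  fit$class <- classifyRecovery(fit)
  class(fit) <- "RecoveryFit"
  fit
}

#' Classify a fitted recovery trajectory
#'
#' Linear family maps to "fast"; exponential with asymptote >= -2.5 z units
#' to "slow"; exponential converging below -2.5 to "impaired". With
#' \code{strictFast = TRUE}, "fast" additionally requires a fitted baseline
#' within the normal band (z >= -2.5); linear fits failing it are labelled
#' "slow".
#'
#' @param fit a \code{RecoveryFit} (or compatible list with \code{family},
#'   \code{asymptote} and \code{parameters}).
#' @param strictFast require normal fitted baseline for the fast label.
#' @return "fast", "slow" or "impaired".
#' @export
classifyRecovery <- function(fit, strictFast = FALSE) {
  if (fit$family == "linear") {
    if (strictFast && fit$parameters[["a"]] < -2.5) return("slow")
    return("fast")
  }
  if (fit$asymptote >= -2.5) "slow" else "impaired"
}

#' Fit and classify every patient in a cohort
#'
#' z-transforms the chosen test, imputes missing cells by visit means, fits
#' both model families per patient and returns the per-patient report.
#'
#' @param cohort result of \code{\link{generateCohort}}.
#' @param test test id (default "pso").
#' @param ... passed to \code{\link{fitRecoveryModels}}.
#' @return data.frame: id, family, class, asymptote, aic_linear,
#'   aic_exponential, rss.
#' @export
classifyCohort <- function(cohort, test = "pso", ...) {
  zm <- imputeMissing(cohortZMatrix(cohort, test))
  days <- as.numeric(colnames(zm))
  rows <- lapply(rownames(zm), function(id) {
    f <- fitRecoveryModels(zm[id, ], days, ...)
    data.frame(id = id, family = f$family, class = f$class,
               asymptote = f$asymptote,
               aic_linear = f$aic[["linear"]],
               aic_exponential = f$aic[["exponential"]],
               rss = f$rss, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Behavioural PCA of a subjects-by-visits matrix
#'
#' Column-centred (covariance) PCA via SVD. Time courses are the right
#' singular vectors, subject expression coefficients the projections of the
#' centred rows onto them, and variance fractions the squared singular
#' values over their total. Components are retained by the Kaiser-Guttmann
#' criterion: eigenvalue above the mean eigenvalue.
#'
#' @param m complete numeric matrix (subjects x visits).
#' @return list: \code{timeCourses} (visits x components),
#'   \code{coefficients} (subjects x components), \code{varianceFractions},
#'   \code{eigenvalues}, \code{retained} (indices).
#' @export
behavioralPca <- function(m) {
  if (any(is.na(m))) stop("matrix must be complete; impute first")
  xc <- scale(m, center = TRUE, scale = FALSE)
  if (all(abs(xc) < 1e-12)) {
    return(list(timeCourses = matrix(0, ncol(m), 0),
                coefficients = matrix(0, nrow(m), 0),
                varianceFractions = numeric(0), eigenvalues = numeric(0),
                retained = integer(0)))
  }
  sv <- svd(xc)
  keep <- sv$d > sv$d[1] * 1e-12
  d <- sv$d[keep]
  scores <- sv$u[, keep, drop = FALSE] %*% diag(d, length(d))
  eig <- d^2 / (nrow(m) - 1)
  retained <- which(eig > mean(eig))
  list(timeCourses = sv$v[, keep, drop = FALSE],
       coefficients = scores,
       varianceFractions = d^2 / sum(d^2),
       eigenvalues = eig,
       retained = retained)
}
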