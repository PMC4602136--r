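# Synthetic cohort generation: patients with known recovery-subgroup
# membership, trajectory parameters and healthy-control statistics, so that
# the downstream response-feature analysis and covariance stages can be
# tested without any patient data.

# tests whose score is a completion time: larger raw value = worse, so the
# z-transform is sign-flipped relative to force/count tests
.TIMED_TESTS <- c("pso")
.KNOWN_TESTS <- c("pso", "hd", "tor")

# deterministic stream splitting: one user-facing seed, independent
# substreams per stage/patient
deriveSeed <- function(seed, index) {
  s <- (as.numeric(seed) * 48271 + as.numeric(index) * 8191) %% 2147483647
  as.integer(s)
}

withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Default healthy-control population parameters
#'
#' Per-test control means and SDs chosen so that the z-scores of typical
#' patient raw scores match the published descriptive conventions for these
#' tests (e.g. a picking-small-objects time of 11 s maps to z = -5 under a
#' control mean of 6 s and SD of 1 s).
#'
#' @return named list of c(mean, sd) pairs per test.
#' @export
defaultControlConfig <- function() {
  list(
    pso = c(mean = 6.0, sd = 1.0),    # seconds; timed, lower = better
    hd  = c(mean = 36,  sd = 12),     # kg grip force
    tor = c(mean = 28.5, sd = 2.5)    # objects recognised out of 30
  )
}

#' Generate healthy-control statistics
#'
#' Returns the configured population parameters together with a sampled
#' control table of \code{n} subjects, reproducible under \code{seed}.
#'
#' @param config named list of per-test c(mean, sd); see
#'   \code{\link{defaultControlConfig}}.
#' @param n number of control subjects (default 22).
#' @param seed integer RNG seed.
#' @return A \linkS4class{ControlStats}.
#' @examples
#' cs <- generateControlStats(seed = 1)
#' cs@mean[["pso"]]
#' @export
generateControlStats <- function(config = defaultControlConfig(), n = 22L,
                                 seed = 1L) {
  if (n < 2L) stop("need at least 2 control subjects")
  mu <- vapply(config, function(p) p[["mean"]], numeric(1))
  sg <- vapply(config, function(p) p[["sd"]], numeric(1))
  if (any(!is.finite(sg)) || any(sg <= 0)) {
    stop("invalid configuration: every control sd must be positive")
  }
  tab <- withSeed(seed, {
    as.data.frame(lapply(seq_along(mu), function(i) rnorm(n, mu[i], sg[i])),
                  col.names = names(mu))
  })
  names(tab) <- names(mu)
  new("ControlStats", mean = mu, sd = sg, nControls = as.integer(n),
      controls = tab)
}

#' z-transform raw scores against control statistics
#'
#' Timed tests (completion times, e.g. picking small objects) use
#' z = (control mean - value) / sd so that worse (slower) performance maps to
#' more negative z; force and count tests use z = (value - mean) / sd.
#' Normal performance is conventionally the band |z| <= 2.5.
#'
#' @param raw numeric vector of raw scores.
#' @param stats a \linkS4class{ControlStats}.
#' @param test test identifier (one of the tests in \code{stats}).
#' @return numeric vector of z-scores.
#' @export
zTransform <- function(raw, stats, test) {
  test <- tolower(test)
  if (!test %in% names(stats@mean)) {
    stop("unknown test id: ", test)
  }
  m <- stats@mean[[test]]; s <- stats@sd[[test]]
  if (s <= 0) stop("control sd must be positive")
  if (test %in% .TIMED_TESTS) (m - raw) / s else (raw - m) / s
}

#' Invert the z-transform back to raw score units
#' @inheritParams zTransform
#' @param z numeric vector of z-scores.
#' @return numeric vector of raw scores.
#' @export
invertZ <- function(z, stats, test) {
  test <- tolower(test)
  if (!test %in% names(stats@mean)) stop("unknown test id: ", test)
  m <- stats@mean[[test]]; s <- stats@sd[[test]]
  if (test %in% .TIMED_TESTS) m - z * s else m + z * s
}

#' Evaluate a recovery trajectory at given visit days
#'
#' Linear trajectories follow z(t) = a + b t; exponential trajectories follow
#' z(t) = zInf - (zInf - z0) exp(-t / tau), i.e. they start at z0 and
#' converge to the asymptote zInf with time constant tau (days). Gaussian
#' noise of the stated SD is added when \code{noiseSd > 0}.
#'
#' @param truth one-row data.frame (or list) with fields \code{family}
#'   ("linear" or "exponential") and parameters \code{a}, \code{b} or
#'   \code{z0}, \code{zInf}, \code{tau}, plus \code{noiseSd}.
#' @param visitDays numeric vector of days post-stroke (>= 3 visits).
#' @param seed optional seed for the noise draw.
#' @return numeric z-score series, one value per visit.
#' @examples
#' tr <- list(family = "exponential", z0 = -8, zInf = -4, tau = 60, noiseSd = 0)
#' generateTrajectory(tr, c(0, 60, 1e6))  # -8, -4 - 4*exp(-1), ~-4
#' @export
generateTrajectory <- function(truth, visitDays, seed = NULL) {
  if (length(visitDays) < 3L) stop("need at least 3 visits")
  fam <- as.character(truth$family)
  mu <- if (fam == "linear") {
    truth$a + truth$b * visitDays
  } else if (fam == "exponential") {
    if (!is.finite(truth$tau) || truth$tau <= 0) {
      stop("invalid parameter: tau must be positive")
    }
    truth$zInf - (truth$zInf - truth$z0) * exp(-visitDays / truth$tau)
  } else stop("unknown model family: ", fam)
  nsd <- if (is.null(truth$noiseSd)) 0 else truth$noiseSd
  if (nsd > 0) {
    eps <- if (is.null(seed)) rnorm(length(mu), 0, nsd) else {
      withSeed(seed, rnorm(length(mu), 0, nsd))
    }
    mu <- mu + eps
  }
  mu
}

# draw per-class trajectory parameters; ranges keep slow/impaired asymptotes
# clear of the -2.5 classification boundary so truth labels are well defined
.drawTruth <- function(class, noiseSd) {
  switch(class,
    fast = list(family = "linear",
                a = runif(1, -1, 0.5), b = runif(1, 0, 0.004),
                z0 = NA_real_, zInf = NA_real_, tau = NA_real_,
                noiseSd = noiseSd),
    slow = list(family = "exponential", a = NA_real_, b = NA_real_,
                z0 = runif(1, -8, -3), zInf = runif(1, -2, 0.5),
                tau = runif(1, 20, 90), noiseSd = noiseSd),
    impaired = list(family = "exponential", a = NA_real_, b = NA_real_,
                    z0 = runif(1, -15, -6), zInf = runif(1, -6, -3),
                    tau = runif(1, 30, 120), noiseSd = noiseSd),
    stop("unknown class: ", class)
  )
}

#' Default visit schedule: baseline plus monthly visits to month 9
#' @return numeric vector of 10 visit days.
#' @export
defaultVisitSchedule <- function() seq(0, 270, by = 30)

#' Generate a synthetic stroke cohort with known recovery classes
#'
#' Builds a cohort of patients partitioned into fast (linear trajectory),
#' slow (exponential, asymptote >= -2.5) and impaired (exponential, asymptote
#' < -2.5) recovery subgroups. Raw scores are obtained by inverting the
#' z-transform with the returned control statistics; a configurable fraction
#' of score cells is deleted to emulate missed visits.
#'
#' @param nPerClass named integer vector c(fast=, slow=, impaired=);
#'   default 8/12/8.
#' @param schedule visit days (>= 3), default baseline + monthly to month 9.
#' @param noiseSd trajectory noise SD in z units (default 0.5).
#' @param missingFraction fraction of patient-visit PSO cells set missing
#'   (default 10/280, the planned-visit miss rate this design emulates).
#' @param controlConfig per-test control parameters.
#' @param seed integer seed; all randomness derives from it.
#' @return list with elements \code{scores} (long data.frame: id, visit_day,
#'   test, value — raw units, NA where missing), \code{demographics},
#'   \code{truth} (one row per patient with class/family/parameters) and
#'   \code{controls} (a \linkS4class{ControlStats}).
#' @export
generateCohort <- function(nPerClass = c(fast = 8L, slow = 12L, impaired = 8L),
                           schedule = defaultVisitSchedule(),
                           noiseSd = 0.5,
                           missingFraction = 10 / 280,
                           controlConfig = defaultControlConfig(),
                           seed = 1L) {
  if (length(schedule) < 3L) stop("schedule must contain at least 3 visits")
  if (is.unsorted(schedule, strictly = TRUE)) {
    stop("visit days must be strictly increasing")
  }
  if (any(nPerClass < 1L)) stop("each class count must be >= 1")
  classes <- rep(names(nPerClass), times = nPerClass)
  n <- length(classes)
  controls <- generateControlStats(controlConfig, seed = deriveSeed(seed, 1))

  truth <- withSeed(deriveSeed(seed, 2), {
    rows <- lapply(seq_len(n), function(i) {
      tr <- .drawTruth(classes[i], noiseSd)
      data.frame(id = sprintf("s%02d", i), class = classes[i],
                 family = tr$family, a = tr$a, b = tr$b, z0 = tr$z0,
                 zInf = tr$zInf, tau = tr$tau, noiseSd = tr$noiseSd,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })

  demographics <- withSeed(deriveSeed(seed, 3), {
    data.frame(
      id = truth$id,
      age = round(runif(n, 41, 82)),
      gender = sample(c("M", "F"), n, replace = TRUE, prob = c(24, 4) / 28),
      side = sample(c("L", "R"), n, replace = TRUE, prob = c(13, 15) / 28),
      etiology = sample(c("LAD", "CE", "UN", "OC"), n, replace = TRUE,
                        prob = c(11, 10, 4, 3) / 28),
      class = truth$class,
      stringsAsFactors = FALSE
    )
  })

  # per-patient z trajectories for PSO (the classification target), with
  # simpler class-linked series for the secondary tests
  scores <- withSeed(deriveSeed(seed, 4), {
    out <- vector("list", n)
    for (i in seq_len(n)) {
      zpso <- generateTrajectory(truth[i, ], schedule)
      # grip force and tactile recognition share the class signal at reduced
      # gain: ordinal summaries correlated with class, not item-level models
      zhd <- pmax(pmin(0.25 * zpso + rnorm(length(schedule), 0, 0.4), 3), -3)
      ztor <- pmax(pmin(0.3 * zpso + rnorm(length(schedule), 0, 0.3), 0.6), -8)
      raw <- rbind(
        data.frame(id = truth$id[i], visit_day = schedule, test = "pso",
                   value = pmax(invertZ(zpso, controls, "pso"), 0)),
        data.frame(id = truth$id[i], visit_day = schedule, test = "hd",
                   value = pmax(invertZ(zhd, controls, "hd"), 0)),
        data.frame(id = truth$id[i], visit_day = schedule, test = "tor",
                   value = pmin(pmax(round(invertZ(ztor, controls, "tor")), 0),
                                30))
      )
      out[[i]] <- raw
    }
    do.call(rbind, out)
  })
  rownames(scores) <- NULL

  if (missingFraction > 0) {
    scores <- withSeed(deriveSeed(seed, 5), {
      idx <- which(scores$test == "pso" & scores$visit_day > 0)
      nmiss <- round(missingFraction * n * length(schedule))
      if (nmiss > 0 && length(idx) > 0) {
        scores$value[sample(idx, min(nmiss, length(idx)))] <- NA_real_
      }
      scores
    })
  }

  list(scores = scores, demographics = demographics, truth = truth,
       controls = controls)
}

#' Wide patient-by-visit z-score matrix for one test
#'
#' @param cohort result of \code{\link{generateCohort}} (or a compatible
#'   list with \code{scores} and \code{controls}).
#' @param test test id (default "pso").
#' @return numeric matrix, patients in rows (named by id), visits in columns
#'   (named by day); NA where missing.
#' @export
cohortZMatrix <- function(cohort, test = "pso") {
  sc <- cohort$scores[cohort$scores$test == test, ]
  ids <- unique(sc$id)
  days <- sort(unique(sc$visit_day))
  m <- matrix(NA_real_, length(ids), length(days),
              dimnames = list(ids, as.character(days)))
  z <- zTransform(sc$value, cohort$controls, test)
  m[cbind(match(sc$id, ids), match(sc$visit_day, days))] <- z
  m
}
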