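#' @importFrom stats aov TukeyHSD lm median sd rbinom rhyper rnorm runif
#'   setNames
NULL

#' Permutation subsampling of a statistic across sample sizes
#'
#' For every subsample size from \code{nMin} up to the population's full
#' size, draws \code{reps} subsamples without replacement, recomputes the
#' statistic on each, and summarises the replicate distribution (median,
#' mean, SD, CV = SD/mean). At the full size every replicate is the
#' complete sample, so SD and CV are exactly zero. Deterministic for a
#' given seed: each (subsample size, replicate) pair has its own derived
#' substream.
#'
#' @param x a \linkS4class{GenotypeMatrix}
#' @param samples character vector: the population's sample ids
#' @param statistic function(GenotypeMatrix) -> single numeric
#' @param nMin smallest subsample size (default 3)
#' @param reps replicates per subsample size (default 20)
#' @param seed integer seed
#' @param label population label carried into the output
#' @return list with \code{summary} (data.frame per subsample size) and
#'   \code{replicates} (long data.frame of all replicate values)
#' @export
permuteSubsample <- function(x, samples, statistic, nMin = 3L, reps = 20L,
                             seed = 1L, label = "pop") {
  stopifnot(is(x, "GenotypeMatrix"), is.function(statistic))
  N <- length(samples)
  if (N < nMin) {
    warning(sprintf("population '%s' has %d < %d samples; skipped",
                    label, N, nMin), call. = FALSE)
    return(list(summary = data.frame(), replicates = data.frame(),
                skipped = TRUE))
  }
  repRows <- list(); sumRows <- list()
  for (nSub in seq.int(nMin, N)) {
    vals <- vapply(seq_len(reps), function(r) {
      idx <- withSeed(subSeed(seed, label, nSub, r),
                      sample.int(N, nSub))
      statistic(x[, samples[idx]])
    }, numeric(1))
    m <- mean(vals)
    s <- sd(vals)
    sumRows[[length(sumRows) + 1L]] <- data.frame(
      population = label, n_sub = nSub, median = median(vals), mean = m,
      sd = s, cv = if (isTRUE(all.equal(m, 0))) NaN else s / abs(m))
    repRows[[length(repRows) + 1L]] <- data.frame(
      population = label, n_sub = nSub, rep = seq_len(reps), value = vals)
  }
  list(summary = do.call(rbind, sumRows),
       replicates = do.call(rbind, repRows), skipped = FALSE)
}

#' Flag departure from neutrality by mean Tajima's D
#'
#' TRUE iff the absolute mean D across permutation replicates exceeds 1.5
#' (strict), an approximate p < 0.05 criterion under neutrality.
#'
#' @param meanD mean Tajima's D across permutation replicates
#' @return logical
#' @export
neutralityTestD <- function(meanD) !is.na(meanD) & abs(meanD) > 1.5

#' Flag significant variability of Watterson's theta across replicates
#'
#' TRUE iff the coefficient of variation across permutation replicates
#' exceeds 1.0 (strict).
#'
#' @param cv coefficient of variation (SD / mean)
#' @return logical
#' @export
variabilityTestTheta <- function(cv) !is.na(cv) & cv > 1.0

#' One-way ANOVA across time periods with Tukey HSD
#'
#' Fixed-effects one-way ANOVA of a diversity statistic's replicate values
#' over time periods (within one species-by-site stratum), with Tukey
#' honest-significant-difference adjusted pairwise comparisons. Note the
#' inputs are permutation replicates, so the test inherits the
#' pseudo-replication of the resampling design.
#'
#' @param values numeric replicate values
#' @param groups factor/character of equal length: time period per value
#' @return list with \code{F}, \code{p}, \code{groupMeans}, \code{tukey}
#'   (data.frame pair, diff, p_adj), \code{degenerate} flag
#' @export
anovaTimePeriods <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need >= 2 groups")
  if (any(table(groups) < 2)) stop("need >= 2 values per group")
  df <- data.frame(y = values, g = groups)
  fit <- aov(y ~ g, data = df)
  an <- summary(fit)[[1]]
  Fv <- an[["F value"]][1]
  p <- an[["Pr(>F)"]][1]
  degenerate <- FALSE
  gm <- tapply(values, groups, mean)
  ssw <- sum((values - gm[groups])^2)
  ssb <- sum(tapply(values, groups, length) * (gm - mean(values))^2)
  if (ssw <= 1e-12 * max(ssb, .Machine$double.xmin)) {
    # zero within-group variance: either all groups identical (no signal)
    # or perfectly separated means (degenerate, p reported as 0)
    if (ssb <= 1e-12) { Fv <- 0; p <- 1 }
    else { Fv <- Inf; p <- 0; degenerate <- TRUE }
  } else if (!is.finite(Fv)) { Fv <- 0; p <- 1 }
  tk <- tryCatch({
    t0 <- TukeyHSD(fit)$g
    data.frame(pair = rownames(t0), diff = t0[, "diff"],
               p_adj = t0[, "p adj"], row.names = NULL)
  }, error = function(e) data.frame(pair = character(0), diff = numeric(0),
                                    p_adj = numeric(0)))
  list(F = Fv, p = p, groupMeans = tapply(values, groups, mean),
       tukey = tk, degenerate = degenerate)
}

#' Regress a per-population diversity summary on a covariate
#'
#' Ordinary least squares of (typically) median pi per population on a
#' covariate such as sample size, number of years sampled, or the range
#' between first and last collection year; slope tested by t-test.
#'
#' @param x covariate per population (>= 3 populations)
#' @param y response per population (e.g. median pi across permutations)
#' @return list with \code{slope}, \code{intercept}, \code{r2}, \code{p}
#' @export
regressDiversityVs <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::var(y) == 0)
    return(list(slope = 0, intercept = y[1], r2 = 0, p = 1))
  fit <- lm(y ~ x)
  sm <- summary(fit)
  co <- sm$coefficients
  slope <- unname(co["x", "Estimate"])
  p <- if ("x" %in% rownames(co) && nrow(co) >= 2 && ncol(co) >= 4)
    unname(co["x", 4]) else NA_real_
  if (sm$sigma == 0) p <- if (slope == 0) 1 else 0
  list(slope = slope, intercept = unname(co["(Intercept)", "Estimate"]),
       r2 = sm$r.squared, p = p)
}

#' Classify a demographic trend from diversity trajectories
#'
#' Applies a rule table to the direction of change of pi, Watterson's
#' theta and Tajima's D between the first and last time point:
#' rising pi and theta with falling D indicates expansion; falling pi with
#' rising D (theta either way) indicates contraction; all three flat is
#' stable; anything else is mixed. "Flat" uses a relative tolerance for pi
#' and theta (default 2\% of the earlier value) and an absolute tolerance
#' for D (default 0.1), since D is naturally centred near zero.
#'
#' @param pi,theta,d numeric vectors ordered by time point (>= 2 points)
#' @param relTol relative flatness tolerance for pi and theta
#' @param dTol absolute flatness tolerance for D
#' @return list with \code{classification}, per-statistic \code{direction}
#'   (-1, 0, 1), and the deltas
#' @export
classifyTrend <- function(pi, theta, d, relTol = 0.02, dTol = 0.1) {
  stopifnot(length(pi) >= 2, length(theta) == length(pi),
            length(d) == length(pi))
  relDir <- function(v) {
    delta <- v[length(v)] - v[1]
    if (is.na(delta) || abs(delta) <= relTol * abs(v[1])) 0L
    else sign(delta)
  }
  absDir <- function(v) {
    delta <- v[length(v)] - v[1]
    if (is.na(delta) || abs(delta) <= dTol) 0L else sign(delta)
  }
  dPi <- relDir(pi); dTh <- relDir(theta); dD <- absDir(d)
  cls <- if (dPi == 0 && dTh == 0 && dD == 0) "stable"
  else if (dPi > 0 && dTh > 0 && dD < 0) "expansion"
  else if (dPi < 0 && dD > 0) "contraction"
  else "mixed"
  list(classification = cls,
       direction = c(pi = dPi, theta = dTh, d = dD),
       delta = c(pi = pi[length(pi)] - pi[1],
                 theta = theta[length(theta)] - theta[1],
                 d = d[length(d)] - d[1]))
}
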