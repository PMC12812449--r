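#' Neutral Fst baseline from non-coding sites
#'
#' Per-site Weir-Cockerham Fst over a (non-coding) matrix, summarised as
#' mean and sample SD over sites with defined estimates. Fewer than two
#' informative sites is an error; fewer than 30 attaches a low-power
#' warning attribute.
#'
#' @param x non-coding \linkS4class{GenotypeMatrix}
#' @param populations named sample -> group assignment (>= 2 groups)
#' @return list with \code{mean}, \code{sd}, \code{nSites},
#'   \code{lowPower}, \code{perSite}
#' @export
neutralBaseline <- function(x, populations) {
  res <- weirCockerhamFst(x, populations)
  fst <- res$perSite$fst
  fst <- fst[!is.na(fst)]
  if (length(fst) < 2) stop("insufficient baseline: < 2 informative sites")
  lowPower <- length(fst) < 30
  if (lowPower)
    warning("baseline built from < 30 sites; outlier thresholds are weak",
            call. = FALSE)
  list(mean = mean(fst), sd = sd(fst), nSites = length(fst),
       lowPower = lowPower, perSite = res$perSite)
}

#' Flag Fst outliers against a neutral baseline
#'
#' A candidate site is an outlier iff its Fst strictly exceeds the baseline
#' mean plus two baseline SDs. The report also carries the candidate mean
#' and its percent elevation over the baseline mean,
#' \eqn{100 (\bar F_{cand} - \bar F_{base}) / \bar F_{base}}.
#'
#' @param candidateFst data.frame with at least columns \code{locus},
#'   \code{pos}, \code{fst} (e.g. \code{weirCockerhamFst(...)$perSite}), or
#'   a bare numeric vector of candidate Fst values.
#' @param baseline list from \code{\link{neutralBaseline}} (or any list
#'   with \code{mean} and \code{sd})
#' @return data.frame of candidates with \code{outlier} flags; attributes
#'   \code{threshold}, \code{baselineMean}, \code{baselineSd},
#'   \code{candidateMean}, \code{elevationPercent}
#' @export
fstOutliers <- function(candidateFst, baseline) {
  if (is.numeric(candidateFst))
    candidateFst <- data.frame(locus = NA_character_,
                               pos = seq_along(candidateFst),
                               fst = candidateFst)
  stopifnot("fst" %in% colnames(candidateFst),
            is.finite(baseline$mean), is.finite(baseline$sd))
  thr <- baseline$mean + 2 * baseline$sd
  out <- candidateFst
  out$outlier <- !is.na(out$fst) & out$fst > thr
  candMean <- mean(out$fst, na.rm = TRUE)
  attr(out, "threshold") <- thr
  attr(out, "baselineMean") <- baseline$mean
  attr(out, "baselineSd") <- baseline$sd
  attr(out, "candidateMean") <- candMean
  attr(out, "elevationPercent") <-
    100 * (candMean - baseline$mean) / baseline$mean
  out
}

#' Allele-frequency trajectories through time
#'
#' Alternate-allele frequency per group and time period for candidate
#' sites, from called alleles. Group-by-period cells with no called
#' genotype are marked absent (frequency NA with \code{absent = TRUE}),
#' which is distinct from a frequency of zero.
#'
#' @param x a \linkS4class{GenotypeMatrix}
#' @param groups named sample -> group assignment (e.g. species x site)
#' @param timePeriods named sample -> ordered time period labels
#' @param sites optional row indices/logical restricting to candidate sites
#' @return long data.frame: locus, pos, group, time_period, freq, n_called,
#'   absent
#' @export
alleleTrajectories <- function(x, groups, timePeriods, sites = NULL) {
  stopifnot(is(x, "GenotypeMatrix"))
  if (!is.null(sites)) x <- x[sites, ]
  groups <- as.character(groups[colnames(x)])
  timePeriods <- as.character(timePeriods[colnames(x)])
  si <- siteInfo(x)
  gt <- genotypes(x)
  rows <- list()
  for (g in unique(groups)) for (tp in unique(timePeriods)) {
    sel <- groups == g & timePeriods == tp
    if (!any(sel)) next
    sub <- gt[, sel, drop = FALSE]
    nCalled <- rowSums(calledChrom(sub))
    nAlt <- rowSums(altCopies(sub))
    rows[[length(rows) + 1L]] <- data.frame(
      locus = si$locus, pos = si$pos, group = g, time_period = tp,
      freq = ifelse(nCalled > 0, nAlt / nCalled, NA_real_),
      n_called = nCalled, absent = nCalled == 0)
  }
  do.call(rbind, rows)
}

#' Large allele-frequency shifts through time
#'
#' Descriptive reconstruction of "large" temporal shifts: per site and
#' group, the range of the allele frequency across time periods with data;
#' flagged when it exceeds \code{minShift}. The cutoff is configurable
#' because no canonical threshold exists.
#'
#' @param traj data.frame from \code{\link{alleleTrajectories}}
#' @param minShift minimum |delta frequency| to flag (default 0.25)
#' @return data.frame per locus, pos, group with \code{shift} and
#'   \code{large} flag
#' @export
largeFrequencyShifts <- function(traj, minShift = 0.25) {
  key <- interaction(traj$locus, traj$pos, traj$group, drop = TRUE)
  rows <- lapply(split(traj, key), function(d) {
    f <- d$freq[!is.na(d$freq)]
    shift <- if (length(f) >= 2) diff(range(f)) else NA_real_
    data.frame(locus = d$locus[1], pos = d$pos[1], group = d$group[1],
               shift = shift, large = !is.na(shift) && shift > minShift)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Polymorphism and allele-sharing summary per species
#'
#' For each species (samples pooled over time points and localities):
#' sample size; total SNPs (candidate sites with at least one called
#' genotype in the species); polymorphic SNPs (two alleles observed within
#' the species); percent polymorphic (rounded to 1 decimal); per-locus
#' polymorphic counts; fixed = total - polymorphic; percent heterozygosity
#' (mean per-site observed heterozygote fraction over the species'
#' polymorphic sites, x100); unique alleles (observed in this species and
#' no other); and alleles missing relative to the all-species union.
#'
#' @param x a \linkS4class{GenotypeMatrix} restricted to candidate SNPs
#' @param species named sample -> species assignment
#' @param locusOfSite optional per-site locus labels (defaults to the
#'   \code{locus} column of the site table)
#' @return data.frame, one row per species, with a \code{perLocus}
#'   attribute (species x locus polymorphic counts)
#' @export
polymorphismSummary <- function(x, species, locusOfSite = NULL) {
  stopifnot(is(x, "GenotypeMatrix"))
  species <- as.character(species[colnames(x)])
  if (is.null(locusOfSite)) locusOfSite <- siteInfo(x)$locus
  sps <- unique(species)
  gt <- genotypes(x)
  obs <- lapply(setNames(sps, sps), function(sp) {
    g <- gt[, species == sp, drop = FALSE]
    nCalled <- rowSums(calledChrom(g))
    nAlt <- rowSums(altCopies(g))
    dip <- !is.na(g) & g <= 2L
    nDip <- rowSums(dip)
    list(nCalled = nCalled, nAlt = nAlt,
         hasRef = nCalled - nAlt > 0, hasAlt = nAlt > 0,
         hetFrac = ifelse(nDip > 0, rowSums(isHet(g)) / nDip, NA_real_))
  })
  refAnywhere <- Reduce(`+`, lapply(obs, function(o) o$hasRef))
  altAnywhere <- Reduce(`+`, lapply(obs, function(o) o$hasAlt))
  perLocus <- NULL
  rows <- lapply(sps, function(sp) {
    o <- obs[[sp]]
    present <- o$nCalled > 0
    poly <- o$hasRef & o$hasAlt
    total <- sum(present)
    byLocus <- tapply(poly, locusOfSite, sum)
    perLocus <<- rbind(perLocus, byLocus)
    uniqueAlleles <- sum(o$hasRef & refAnywhere == 1L) +
      sum(o$hasAlt & altAnywhere == 1L)
    missingAlleles <- sum(refAnywhere > 0 & !o$hasRef) +
      sum(altAnywhere > 0 & !o$hasAlt)
    data.frame(species = sp, sample_size = sum(species == sp),
               total_snps = total, polymorphic = sum(poly),
               pct_polymorphic = round(100 * sum(poly) / max(total, 1), 1),
               fixed = total - sum(poly),
               pct_heterozygosity = if (any(poly))
                 100 * mean(o$hetFrac[poly], na.rm = TRUE) else NA_real_,
               unique_alleles = uniqueAlleles,
               missing_alleles = missingAlleles)
  })
  out <- do.call(rbind, rows)
  rownames(perLocus) <- sps
  attr(out, "perLocus") <- perLocus
  out
}
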