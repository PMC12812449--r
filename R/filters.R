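#' Filter configuration for the SNP filter chain
#'
#' Thresholds of the site/genotype filter chain. Boundary conventions:
#' QUAL >= \code{minQual} passes, DP >= \code{minDepth} passes, a
#' heterozygote passes allele balance only strictly inside
#' (\code{alleleBalanceLo}, \code{alleleBalanceHi}), sites with minor
#' allele frequency <= \code{maxMafExcluded} or minor allele count <
#' \code{minMac} are removed, and at least \code{minPresenceFraction} of
#' individuals must carry a called genotype.
#'
#' @param minQual minimum site QUAL (default 30)
#' @param biallelicOnly drop non-biallelic SNPs (default TRUE)
#' @param maxMafExcluded sites with MAF at or below this are removed (0.015)
#' @param minMac minimum minor allele count (3)
#' @param minDepth minimum per-genotype depth (5)
#' @param alleleBalanceLo,alleleBalanceHi open interval of acceptable
#'   heterozygote allele balance (0.25, 0.75)
#' @param minPresenceFraction minimum fraction of individuals called (0.5)
#' @param indelWindowBp SNPs within this many bp of an indel are pruned (3)
#' @param indelClusterGapBp indels this close together form a cluster (5)
#' @return a \code{filter_config} list
#' @export
filterConfig <- function(minQual = 30, biallelicOnly = TRUE,
                         maxMafExcluded = 0.015, minMac = 3, minDepth = 5,
                         alleleBalanceLo = 0.25, alleleBalanceHi = 0.75,
                         minPresenceFraction = 0.5,
                         indelWindowBp = 3, indelClusterGapBp = 5) {
  stopifnot(alleleBalanceLo >= 0, alleleBalanceLo < alleleBalanceHi,
            alleleBalanceHi <= 1, minQual >= 0, minMac >= 0, minDepth >= 0,
            maxMafExcluded >= 0, minPresenceFraction >= 0,
            minPresenceFraction <= 1, indelWindowBp >= 0,
            indelClusterGapBp >= 0)
  structure(as.list(environment()), class = "filter_config")
}

#' Prune SNPs near indels and indel clusters
#'
#' A SNP is removed when it lies within \code{indelWindowBp} (default 3 bp)
#' of any indel on the same locus. Indels whose nearest neighbouring indel
#' is at most \code{indelClusterGapBp} (default 5 bp) away form a cluster;
#' SNPs falling anywhere inside a cluster's span (or within the window of
#' any member) are removed as well.
#'
#' @param snpPos integer vector of SNP positions (one locus)
#' @param indelPos integer vector of indel positions on the same locus
#' @param config a \code{\link{filterConfig}}
#' @return logical vector: TRUE where the SNP is kept
#' @export
pruneIndelProximity <- function(snpPos, indelPos,
                                config = filterConfig()) {
  if (length(snpPos) == 0) return(logical(0))
  if (length(indelPos) == 0) return(rep(TRUE, length(snpPos)))
  w <- config$indelWindowBp
  nearIndel <- vapply(snpPos, function(p)
    any(abs(p - indelPos) <= w), logical(1))
  keep <- !nearIndel
  ip <- sort(unique(indelPos))
  if (length(ip) >= 2) {
    gaps <- diff(ip)
    inCluster <- c(FALSE, gaps <= config$indelClusterGapBp) |
                 c(gaps <= config$indelClusterGapBp, FALSE)
    if (any(inCluster)) {
      # contiguous runs of clustered indels; SNPs inside a run's span go too
      runs <- split(ip[inCluster], cumsum(!inCluster)[inCluster])
      for (r in runs) {
        if (length(r) < 2) next
        keep[snpPos >= min(r) - w & snpPos <= max(r) + w] <- FALSE
      }
    }
  }
  keep
}

#' Apply the site and genotype filter chain
#'
#' Filters are applied in a fixed order: (1) indel-proximity pruning (and
#' removal of the indel records themselves), (2) site QUAL, (3) biallelic
#' SNPs only, (4) genotype-level masking (depth below \code{minDepth}, or a
#' heterozygote whose allele balance falls outside the open interval),
#' (5) site-level minor-allele count/frequency and presence filters,
#' computed from called alleles \emph{after} genotype masking. When the
#' matrix carries no AD the allele-balance mask is a no-op and the report
#' flags it; likewise for DP and the depth mask.
#'
#' @param x a \linkS4class{GenotypeMatrix}
#' @param config a \code{\link{filterConfig}}
#' @return list with elements \code{matrix} (filtered
#'   \linkS4class{GenotypeMatrix}) and \code{report} (data.frame of
#'   per-filter removals, with attributes \code{genotypesMasked},
#'   \code{missingness}, \code{adAbsent}, \code{dpAbsent})
#' @export
applySiteFilters <- function(x, config = filterConfig()) {
  stopifnot(is(x, "GenotypeMatrix"), inherits(config, "filter_config"))
  steps <- character(0); removed <- integer(0); nIn <- nrow(x)

  tally <- function(name, n) {
    steps <<- c(steps, name); removed <<- c(removed, n)
  }

  si <- siteInfo(x)
  # (1) indel proximity: prune SNPs near indels, then drop indel records
  keep <- rep(TRUE, nrow(x))
  for (loc in unique(si$locus[si$isIndel])) {
    idx <- which(si$locus == loc & !si$isIndel)
    if (length(idx))
      keep[idx] <- pruneIndelProximity(si$pos[idx],
                                       si$pos[si$locus == loc & si$isIndel],
                                       config)
  }
  keep[si$isIndel] <- FALSE
  tally("indel_proximity", sum(!keep))
  x <- x[keep, ]; si <- siteInfo(x)

  # (2) QUAL (missing QUAL fails)
  keep <- !is.na(si$qual) & si$qual >= config$minQual
  tally("qual", sum(!keep))
  x <- x[keep, ]; si <- siteInfo(x)

  # (3) biallelic SNPs only
  if (config$biallelicOnly) {
    keep <- !grepl(",", si$alt) & nchar(si$ref) == 1L & nchar(si$alt) == 1L
  } else keep <- rep(TRUE, nrow(x))
  tally("biallelic_snp", sum(!keep))
  x <- x[keep, ]

  # (4) genotype-level masking
  gt <- genotypes(x); dp <- depths(x)
  adr <- refDepths(x); ada <- altDepths(x)
  dpAbsent <- all(is.na(dp)); adAbsent <- all(is.na(adr) & is.na(ada))
  mask <- matrix(FALSE, nrow(gt), ncol(gt))
  if (!dpAbsent)
    mask <- mask | (!is.na(gt) & !is.na(dp) & dp < config$minDepth)
  if (!adAbsent) {
    tot <- adr + ada
    ab <- ifelse(!is.na(tot) & tot > 0, adr / tot, NA_real_)
    badAB <- isHet(gt) & !is.na(ab) &
      (ab <= config$alleleBalanceLo | ab >= config$alleleBalanceHi)
    mask <- mask | badAB
  }
  nMasked <- sum(mask)
  if (nMasked > 0) {
    gt[mask] <- NA_integer_
    x <- GenotypeMatrix(gt, siteInfo(x), dp = dp, adRef = adr, adAlt = ada,
                        sampleData = sampleData(x))
  }

  # (5) site-level MAC / MAF / presence after masking
  gt <- genotypes(x)
  ac <- siteAlleleCounts(gt)
  mac <- pmin(ac$nAlt, ac$nCalled - ac$nAlt)
  maf <- ifelse(ac$nCalled > 0, mac / ac$nCalled, 0)
  presence <- rowMeans(calledChrom(gt) > 0)
  keepMac <- mac >= config$minMac
  tally("mac", sum(!keepMac))
  keepMaf <- maf > config$maxMafExcluded
  tally("maf", sum(keepMac & !keepMaf))
  keepPres <- presence >= config$minPresenceFraction
  tally("presence", sum(keepMac & keepMaf & !keepPres))
  x <- x[keepMac & keepMaf & keepPres, ]

  report <- data.frame(filter = steps, removed = removed)
  report$sites_out <- nIn - cumsum(removed)
  report$sites_in <- c(nIn, report$sites_out[-nrow(report)])
  report <- report[, c("filter", "sites_in", "removed", "sites_out")]
  attr(report, "genotypesMasked") <- nMasked
  attr(report, "adAbsent") <- adAbsent
  attr(report, "dpAbsent") <- dpAbsent
  attr(report, "missingness") <- if (nrow(x) > 0) computeMissingness(x)
                                 else NA_real_
  if (adAbsent)
    warning("AD absent: allele-balance filter is a no-op", call. = FALSE)
  if (dpAbsent)
    warning("DP absent: depth filter is a no-op", call. = FALSE)
  list(matrix = x, report = report)
}

#' Thin to one random SNP per locus
#'
#' Chooses exactly one site uniformly at random from each locus carrying at
#' least one site; deterministic for a given seed.
#'
#' @param x a \linkS4class{GenotypeMatrix}
#' @param seed integer seed for the thinning stream
#' @return thinned \linkS4class{GenotypeMatrix}
#' @export
thinOneSnpPerLocus <- function(x, seed = 1L) {
  stopifnot(is(x, "GenotypeMatrix"))
  if (nrow(x) == 0) stop("no sites to thin")
  loci <- siteInfo(x)$locus
  pick <- withSeed(seed, {
    vapply(split(seq_len(nrow(x)), loci), function(idx)
      if (length(idx) == 1L) idx else idx[sample.int(length(idx), 1L)],
      integer(1))
  })
  x[sort(unname(pick)), ]
}

#' Partition sites into coding and non-coding matrices
#'
#' A site with 1-based position p is coding iff p-1 lies inside one of the
#' locus's 0-based half-open coding intervals (the BED convention). The two
#' outputs partition the input sites exactly.
#'
#' @param x a \linkS4class{GenotypeMatrix}
#' @param locusMap data.frame with \code{locus}, \code{start0}, \code{end0}
#'   (e.g. from \code{\link{readLocusBed}}); loci absent from the map are an
#'   error, except that an empty map labels everything non-coding.
#' @return list with \code{coding} and \code{noncoding} matrices
#' @export
partitionCodingNoncoding <- function(x, locusMap) {
  stopifnot(is(x, "GenotypeMatrix"))
  si <- siteInfo(x)
  if (nrow(locusMap) > 0) {
    missingLoci <- setdiff(unique(si$locus), unique(locusMap$locus))
    if (length(missingLoci))
      stop("loci absent from locus map: ",
           paste(utils::head(missingLoci, 3), collapse = ", "))
  }
  coding <- rep(FALSE, nrow(x))
  for (i in seq_len(nrow(locusMap))) {
    hit <- si$locus == locusMap$locus[i] &
      (si$pos - 1L) >= locusMap$start0[i] & (si$pos - 1L) < locusMap$end0[i]
    coding <- coding | hit
  }
  list(coding = x[coding, ], noncoding = x[!coding, ])
}

#' Downsample per-genotype depth to a target mean
#'
#' For each sample whose mean depth exceeds \code{targetMeanDepth}, each
#' genotype's DP is replaced by a binomial draw with success probability
#' target/mean, and AD is re-split from the new depth hypergeometrically
#' (sampling reads without replacement). Samples at or below the target are
#' untouched; genotypes whose new depth falls below 1 become missing.
#'
#' @param x a \linkS4class{GenotypeMatrix} with DP present
#' @param targetMeanDepth positive target mean depth (the archival default
#'   of 24 mirrors typical downsampling of heterogeneous museum panels)
#' @param seed integer seed
#' @return a \linkS4class{GenotypeMatrix}
#' @export
downsampleDepth <- function(x, targetMeanDepth = 24, seed = 1L) {
  stopifnot(is(x, "GenotypeMatrix"))
  if (targetMeanDepth <= 0) stop("target depth must be positive")
  gt <- genotypes(x); dp <- depths(x)
  adr <- refDepths(x); ada <- altDepths(x)
  if (all(is.na(dp))) stop("DP absent: cannot downsample")
  withSeed(seed, {
    for (j in seq_len(ncol(x))) {
      m <- mean(dp[, j], na.rm = TRUE)
      if (!is.finite(m) || m <= targetMeanDepth) next
      ok <- which(!is.na(dp[, j]))
      newDp <- rbinom(length(ok), dp[ok, j], targetMeanDepth / m)
      haveAd <- !is.na(adr[ok, j]) & !is.na(ada[ok, j]) &
        (adr[ok, j] + ada[ok, j]) >= newDp
      newRef <- numeric(length(ok))
      newRef[haveAd] <- rhyper(sum(haveAd), adr[ok, j][haveAd],
                               ada[ok, j][haveAd], newDp[haveAd])
      if (any(!haveAd)) {
        tot <- adr[ok, j][!haveAd] + ada[ok, j][!haveAd]
        p <- ifelse(!is.na(tot) & tot > 0, adr[ok, j][!haveAd] / tot, NA)
        newRef[!haveAd] <- ifelse(is.na(p), NA,
                                  rbinom(sum(!haveAd), newDp[!haveAd],
                                         ifelse(is.na(p), 0, p)))
      }
      dp[ok, j] <- newDp
      adr[ok, j] <- newRef
      ada[ok, j] <- newDp - newRef
      gone <- ok[newDp < 1]
      gt[gone, j] <- NA_integer_
      dp[gone, j] <- NA_real_
      adr[gone, j] <- NA_real_; ada[gone, j] <- NA_real_
    }
    GenotypeMatrix(gt, siteInfo(x), dp = dp, adRef = adr, adAlt = ada,
                   sampleData = sampleData(x))
  })
}

#' Fraction of missing genotype cells
#'
#' Missing cells (uncalled genotypes) divided by the total cells of the
#' sample-by-site matrix.
#'
#' @param x a \linkS4class{GenotypeMatrix}
#' @return numeric in [0, 1]
#' @export
computeMissingness <- function(x) {
  stopifnot(is(x, "GenotypeMatrix"))
  if (nrow(x) == 0 || ncol(x) == 0) stop("empty matrix")
  mean(is.na(genotypes(x)))
}

#' Filter candidate capture targets by length and GC content
#'
#' Keeps candidates with length in [200, 400] bp and GC fraction in
#' [0.30, 0.70], both bounds inclusive.
#'
#' @param candidates data.frame with columns \code{length_bp} and
#'   \code{gc_fraction}
#' @param minLen,maxLen,minGc,maxGc inclusive bounds
#' @return the kept rows of \code{candidates}
#' @export
filterCandidateTargets <- function(candidates, minLen = 200, maxLen = 400,
                                   minGc = 0.30, maxGc = 0.70) {
  stopifnot(all(c("length_bp", "gc_fraction") %in% colnames(candidates)),
            all(candidates$length_bp > 0),
            all(candidates$gc_fraction >= 0 & candidates$gc_fraction <= 1))
  keep <- candidates$length_bp >= minLen & candidates$length_bp <= maxLen &
    candidates$gc_fraction >= minGc & candidates$gc_fraction <= maxGc
  candidates[keep, , drop = FALSE]
}
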