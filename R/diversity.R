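#' Per-site nucleotide diversity
#'
#' Unbiased per-site pi for a biallelic site: the proportion of
#' distinct-allele pairs among all C(n, 2) pairs of called chromosomes,
#' \eqn{\pi = \frac{n}{n-1} 2 p (1-p)}.
#'
#' @param nMinor minor (or either) allele count
#' @param nTotal total called chromosomes (>= 2 for a defined value)
#' @return numeric; \code{NaN} when fewer than 2 chromosomes are called
#' @examples
#' sitePi(3, 8)  # 15/28
#' @export
sitePi <- function(nMinor, nTotal) {
  out <- rep(NaN, length(nMinor))
  ok <- !is.na(nTotal) & nTotal >= 2
  p <- nMinor[ok] / nTotal[ok]
  out[ok] <- nTotal[ok] / (nTotal[ok] - 1) * 2 * p * (1 - p)
  out
}

#' Mean nucleotide diversity over sites
#'
#' Averages \code{\link{sitePi}} over sites with at least two called
#' chromosomes. By default the denominator is the number of such variant
#' sites (SNP-matrix pi); supplying \code{totalSites} (e.g. the panel's
#' total surveyed bp including invariant positions) yields per-bp pi.
#'
#' @param x a \linkS4class{GenotypeMatrix}
#' @param samples optional character/index vector restricting to a
#'   population
#' @param totalSites optional denominator including invariant sites
#' @return list with \code{pi}, \code{nSitesUsed}
#' @export
meanPi <- function(x, samples = NULL, totalSites = NULL) {
  stopifnot(is(x, "GenotypeMatrix"))
  if (!is.null(samples)) x <- x[, samples]
  ac <- siteAlleleCounts(genotypes(x))
  ok <- ac$nCalled >= 2
  if (!any(ok)) {
    warning("no site with >= 2 called chromosomes", call. = FALSE)
    return(list(pi = NaN, nSitesUsed = 0L))
  }
  pis <- sitePi(ac$nAlt[ok], ac$nCalled[ok])
  denom <- if (is.null(totalSites)) sum(ok) else totalSites
  list(pi = sum(pis) / denom, nSitesUsed = sum(ok))
}

#' Observed and expected heterozygosity
#'
#' \code{hObs} is the mean over sites of the fraction of called diploid
#' genotypes that are heterozygous; \code{hExp} is the mean over sites of
#' \eqn{2p(1-p)} from called allele frequencies.
#'
#' @inheritParams meanPi
#' @return list with \code{hObs}, \code{hExp}
#' @export
heterozygosity <- function(x, samples = NULL) {
  stopifnot(is(x, "GenotypeMatrix"))
  if (!is.null(samples)) x <- x[, samples]
  gt <- genotypes(x)
  dip <- !is.na(gt) & gt <= 2L
  nDip <- rowSums(dip)
  hetFrac <- ifelse(nDip > 0, rowSums(isHet(gt)) / nDip, NA_real_)
  ac <- siteAlleleCounts(gt)
  p <- ifelse(ac$nCalled > 0, ac$nAlt / ac$nCalled, NA_real_)
  list(hObs = mean(hetFrac, na.rm = TRUE),
       hExp = mean(2 * p * (1 - p), na.rm = TRUE))
}

#' Private alleles per population
#'
#' Counts, for each population, (site, allele) combinations observed in
#' that population and in no other.
#'
#' @param x a \linkS4class{GenotypeMatrix}
#' @param populations named factor/character vector assigning each sample
#'   (by column name) to a population
#' @return named integer vector of private-allele counts
#' @export
privateAlleles <- function(x, populations) {
  stopifnot(is(x, "GenotypeMatrix"))
  populations <- populations[colnames(x)]
  pops <- unique(as.character(populations))
  gt <- genotypes(x)
  # presence[site, pop, allele]
  hasRef <- sapply(pops, function(p) {
    g <- gt[, populations == p, drop = FALSE]
    rowSums(calledChrom(g) - altCopies(g)) > 0
  })
  hasAlt <- sapply(pops, function(p) {
    g <- gt[, populations == p, drop = FALSE]
    rowSums(altCopies(g)) > 0
  })
  hasRef <- matrix(hasRef, ncol = length(pops),
                   dimnames = list(NULL, pops))
  hasAlt <- matrix(hasAlt, ncol = length(pops),
                   dimnames = list(NULL, pops))
  privRef <- hasRef & rowSums(hasRef) == 1L
  privAlt <- hasAlt & rowSums(hasAlt) == 1L
  out <- colSums(privRef) + colSums(privAlt)
  setNames(as.integer(out), names(out))
}

#' Watterson's theta per site
#'
#' \eqn{\theta_W = S / (a_1 L)} with \eqn{a_1 = \sum_{i=1}^{n-1} 1/i}.
#'
#' @param S segregating sites in the window
#' @param nChrom called chromosomes (>= 2)
#' @param windowLength window length in bp
#' @return per-site Watterson's theta
#' @export
wattersonTheta <- function(S, nChrom, windowLength) {
  stopifnot(all(windowLength > 0))
  out <- rep(NaN, length(S))
  zero <- S == 0
  out[zero] <- 0
  ok <- !zero & nChrom >= 2
  a1 <- vapply(nChrom[ok], function(n) sum(1 / seq_len(n - 1)), numeric(1))
  out[ok] <- S[ok] / (a1 * rep_len(windowLength, length(S))[ok])
  out
}

# Tajima (1989) normalization constants
tajimaConstants <- function(n) {
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Tajima's D
#'
#' \eqn{D = (\pi_{total} - S/a_1) / \sqrt{e_1 S + e_2 S (S-1)}} with the
#' standard normalization constants; \eqn{\pi_{total}} is the window sum of
#' mean pairwise differences (not per-site). Undefined (NaN) when S = 0 or
#' fewer than 4 chromosomes are called.
#'
#' @param S segregating sites
#' @param piTotal window total pairwise-difference sum
#' @param nChrom called chromosomes
#' @return Tajima's D, or NaN where undefined
#' @export
tajimasD <- function(S, piTotal, nChrom) {
  out <- rep(NaN, length(S))
  ok <- !is.na(S) & !is.na(nChrom) & S >= 1 & nChrom >= 4
  for (k in which(ok)) {
    cst <- tajimaConstants(nChrom[k])
    denom <- sqrt(cst$e1 * S[k] + cst$e2 * S[k] * (S[k] - 1))
    out[k] <- if (denom > 0) (piTotal[k] - S[k] / cst$a1) / denom else NaN
  }
  out
}

#' Windowed segregating sites, Watterson's theta and Tajima's D
#'
#' Tiles each locus with windows of \code{size} bp (step defaults to the
#' size, i.e. non-overlapping; the final window of a locus is partial and
#' is used with its true length). Per window: S (segregating sites among
#' called alleles), nChrom (mean called chromosomes over the window's
#' sites, rounded to the nearest integer for the normalization constants),
#' per-site Watterson's theta, and Tajima's D from the window's summed
#' site pi.
#'
#' @param x a \linkS4class{GenotypeMatrix}
#' @param samples optional population restriction
#' @param size window size in bp (default 150)
#' @param step step between window starts (default \code{size})
#' @param locusLengths named vector of locus lengths; defaults to the
#'   largest observed position per locus
#' @return data.frame of per-window statistics
#' @export
slidingWindowStats <- function(x, samples = NULL, size = 150L, step = size,
                               locusLengths = NULL) {
  stopifnot(is(x, "GenotypeMatrix"), size >= 1, step >= 1)
  size <- as.integer(size); step <- as.integer(step)
  if (!is.null(samples)) x <- x[, samples]
  si <- siteInfo(x)
  gt <- genotypes(x)
  ac <- siteAlleleCounts(gt)
  seg <- ac$nCalled > 0 & ac$nAlt > 0 & ac$nAlt < ac$nCalled
  pis <- sitePi(ac$nAlt, ac$nCalled)
  loci <- unique(si$locus)
  if (is.null(locusLengths)) {
    locusLengths <- tapply(si$pos, si$locus, max)
  }
  res <- list()
  for (loc in loci) {
    L <- as.integer(locusLengths[[loc]])
    starts <- seq(1L, max(1L, L), by = step)
    starts <- starts[starts <= L]
    idxLoc <- which(si$locus == loc)
    for (s0 in starts) {
      e0 <- min(s0 + size - 1L, L)
      idx <- idxLoc[si$pos[idxLoc] >= s0 & si$pos[idxLoc] <= e0]
      S <- sum(seg[idx])
      nChrom <- if (length(idx)) round(mean(ac$nCalled[idx])) else 0
      piTot <- sum(pis[idx][ac$nCalled[idx] >= 2], na.rm = TRUE)
      wlen <- e0 - s0 + 1L
      res[[length(res) + 1L]] <- data.frame(
        locus = loc, start = s0, end = e0, length = wlen,
        n_sites = length(idx), S = S, n_chrom = nChrom,
        theta_w = wattersonTheta(S, nChrom, wlen),
        pi_total = piTot,
        tajimas_d = tajimasD(S, piTot, nChrom))
    }
  }
  do.call(rbind, res)
}

# Weir & Cockerham (1984) per-site variance components for one site.
# freqs p_i, het fractions h_i, sizes n_i (diploids) per population.
wcComponents <- function(n, p, h) {
  keep <- n >= 1
  n <- n[keep]; p <- p[keep]; h <- h[keep]
  r <- length(n)
  if (r < 2) return(c(a = NA_real_, b = NA_real_, c = NA_real_))
  nbar <- mean(n)
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n * p) / (r * nbar)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / (r * nbar)
  if (nbar <= 1 || nc <= 0) return(c(a = NA_real_, b = NA_real_, c = NA_real_))
  a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) /
                        (nbar - 1))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  c(a = a, b = b, c = cc)
}

#' Weir-Cockerham Fst
#'
#' Per-site Weir-Cockerham variance components (a: among populations,
#' b: among individuals within populations, c: within individuals) and the
#' per-site estimator \eqn{\hat\theta = a/(a+b+c)}, computed from called
#' diploid genotypes. Two summary means are returned: the ratio of averaged
#' components \eqn{\sum a / \sum (a+b+c)} and the mean of per-site ratios
#' (the default for baseline and outlier work); sites with a zero component
#' sum are excluded from both.
#'
#' @param x a \linkS4class{GenotypeMatrix}
#' @param populations named vector assigning samples to populations
#' @return list with \code{perSite} (data.frame locus, pos, a, b, c, fst),
#'   \code{meanRatioOfAverages}, \code{meanOfRatios}, \code{grouping}
#' @export
weirCockerhamFst <- function(x, populations) {
  stopifnot(is(x, "GenotypeMatrix"))
  populations <- as.character(populations[colnames(x)])
  pops <- unique(populations)
  if (length(pops) < 2) stop("need >= 2 populations")
  gt <- genotypes(x)
  nMat <- sapply(pops, function(pp) {
    g <- gt[, populations == pp, drop = FALSE]
    rowSums(!is.na(g) & g <= 2L)
  })
  pMat <- sapply(pops, function(pp) {
    g <- gt[, populations == pp, drop = FALSE]
    dip <- !is.na(g) & g <= 2L
    alt <- rowSums(altCopies(g) * dip)
    n2 <- 2 * rowSums(dip)
    ifelse(n2 > 0, alt / n2, NA_real_)
  })
  hMat <- sapply(pops, function(pp) {
    g <- gt[, populations == pp, drop = FALSE]
    dip <- !is.na(g) & g <= 2L
    nd <- rowSums(dip)
    ifelse(nd > 0, rowSums(isHet(g)) / nd, NA_real_)
  })
  nMat <- matrix(nMat, ncol = length(pops))
  pMat <- matrix(pMat, ncol = length(pops))
  hMat <- matrix(hMat, ncol = length(pops))
  comp <- t(vapply(seq_len(nrow(x)), function(i) {
    ok <- nMat[i, ] >= 1
    wcComponents(nMat[i, ok], pMat[i, ok], hMat[i, ok])
  }, numeric(3)))
  tot <- rowSums(comp)
  fst <- ifelse(!is.na(tot) & tot != 0, comp[, 1] / tot, NA_real_)
  si <- siteInfo(x)
  perSite <- data.frame(locus = si$locus, pos = si$pos,
                        a = comp[, 1], b = comp[, 2], c = comp[, 3],
                        fst = fst)
  def <- !is.na(tot) & tot != 0
  list(perSite = perSite,
       meanRatioOfAverages = if (any(def))
         sum(comp[def, 1]) / sum(tot[def]) else NaN,
       meanOfRatios = if (any(def)) mean(fst[def]) else NaN,
       grouping = pops)
}
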