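# Fixture builders and independent oracles used across the suite.

# Build a GenotypeMatrix from a plain genotype matrix (sites x samples).
makeGM <- function(gt, locus = NULL, pos = NULL, ref = "A", alt = "G",
                   qual = 60, dp = NULL, adRef = NULL, adAlt = NULL,
                   sampleData = NULL) {
  gt <- as.matrix(gt)
  n <- nrow(gt)
  si <- data.frame(
    locus = if (is.null(locus)) rep("L1", n) else rep_len(locus, n),
    pos = if (is.null(pos)) seq_len(n) else pos,
    ref = rep_len(ref, n), alt = rep_len(alt, n),
    qual = rep_len(qual, n))
  GenotypeMatrix(gt, si, dp = dp, adRef = adRef, adAlt = adAlt,
                 sampleData = sampleData)
}

# Brute-force per-site pi: mean pairwise difference over all chromosome
# pairs, by explicit enumeration.
bruteSitePi <- function(nMinor, nTotal) {
  alleles <- c(rep(1, nMinor), rep(0, nTotal - nMinor))
  pairs <- utils::combn(nTotal, 2)
  mean(alleles[pairs[1, ]] != alleles[pairs[2, ]])
}

# Independent Weir-Cockerham oracle via the explicit allele-indicator
# ANOVA table (sums of squares between populations, between individuals
# within populations, and within individuals), rather than the closed-form
# component expressions used by the implementation.
wcOracle <- function(doseList) {
  doseList <- doseList[vapply(doseList, length, integer(1)) >= 1]
  r <- length(doseList)
  if (r < 2) return(NA_real_)
  n <- vapply(doseList, length, numeric(1))
  N <- sum(n)
  p <- vapply(doseList, function(d) mean(d) / 2, numeric(1))
  pbar <- sum(n * p) / N
  SSP <- 2 * sum(n * (p - pbar)^2)
  SSI <- 2 * sum(unlist(mapply(function(d, pi) (d / 2 - pi)^2, doseList, p,
                               SIMPLIFY = FALSE)))
  nHet <- sum(unlist(doseList) == 1)
  SSG <- 0.5 * nHet
  nc <- (N - sum(n^2) / N) / (r - 1)
  MSP <- SSP / (r - 1)
  MSI <- if (N - r > 0) SSI / (N - r) else 0
  MSG <- SSG / N
  a <- (MSP - MSI) / (2 * nc)
  b <- (MSI - MSG) / 2
  cc <- MSG
  if (a + b + cc == 0) return(NA_real_)
  a / (a + b + cc)
}

# Hand sums-of-squares one-way ANOVA F.
handAnovaF <- function(values, groups) {
  groups <- factor(groups)
  gm <- tapply(values, groups, mean)
  ns <- tapply(values, groups, length)
  grand <- mean(values)
  ssb <- sum(ns * (gm - grand)^2)
  ssw <- sum((values - gm[groups])^2)
  k <- nlevels(groups)
  (ssb / (k - 1)) / (ssw / (length(values) - k))
}

# Independent Tajima's D oracle, written directly from the published
# normalization constants.
oracleTajimaD <- function(S, piTotal, n) {
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (piTotal - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# Random population dose fixture for Fst checks.
randomDoseFixture <- function(nPops = 2, nMin = 4, nMax = 10) {
  lapply(seq_len(nPops), function(i) {
    n <- sample(nMin:nMax, 1)
    p <- runif(1, 0.05, 0.95)
    rbinom(n, 2, p)
  })
}

# GenotypeMatrix from per-population dose vectors (one site).
gmFromDoses <- function(doseList) {
  doses <- unlist(doseList)
  gt <- matrix(as.integer(doses), nrow = 1)
  colnames(gt) <- sprintf("s%02d", seq_along(doses))
  pops <- rep(sprintf("pop%d", seq_along(doseList)),
              vapply(doseList, length, integer(1)))
  list(gm = makeGM(gt), pops = setNames(pops, colnames(gt)))
}

# Table-3-style candidate-SNP fixture: three species with prescribed
# per-locus polymorphic counts and per-species site availability.
# Locus sizes: CXCR4 13, ILF2 30, ILF3 6 sites (49 total).
table3Fixture <- function() {
  locus <- rep(c("CXCR4", "ILF2", "ILF3"), c(13, 30, 6))
  nSites <- length(locus)
  species <- rep(c("yonahlossee", "cinereus", "welleri"), each = 4)
  samples <- sprintf("%s_%d", species, rep(1:4, times = 3))
  gt <- matrix(0L, nSites, length(samples),
               dimnames = list(NULL, samples))
  polyIdx <- function(counts) {
    # first `counts[l]` sites of locus l
    unlist(lapply(seq_along(counts), function(l)
      which(locus == c("CXCR4", "ILF2", "ILF3")[l])[seq_len(counts[l])]))
  }
  setPoly <- function(gt, sp, counts) {
    idx <- polyIdx(counts)
    gt[idx, which(species == sp)[1]] <- 1L
    gt
  }
  gt <- setPoly(gt, "yonahlossee", c(9, 12, 3))   # 24/49 polymorphic
  gt <- setPoly(gt, "cinereus", c(2, 3, 1))       # 6 polymorphic
  gt <- setPoly(gt, "welleri", c(3, 2, 0))        # 5 polymorphic
  # site availability (chosen to avoid each species' polymorphic sites):
  # cinereus called at 37 sites (12 dropped), welleri at 32 (17 dropped)
  gt[c(36:43, 46:49), species == "cinereus"] <- NA_integer_
  gt[18:34, species == "welleri"] <- NA_integer_
  gm <- makeGM(gt, locus = locus,
               pos = unlist(lapply(table(factor(locus,
                 levels = c("CXCR4", "ILF2", "ILF3"))), seq_len)))
  list(gm = gm, species = setNames(species, samples), locus = locus)
}
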