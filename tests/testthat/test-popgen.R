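test_that("per-site pi matches brute-force pairwise enumeration", {
  expect_equal(sitePi(0, 10), 0)
  expect_equal(sitePi(1, 2), 1)
  expect_equal(sitePi(3, 8), 15 / 28)
  expect_true(is.nan(sitePi(1, 1)))
  set.seed(21)
  for (i in 1:60) {
    n <- sample(2:12, 1)
    k <- sample(0:n, 1)
    expect_equal(sitePi(k, n), bruteSitePi(k, n), tolerance = 1e-12)
  }
})

test_that("mean pi averages defined sites and flags empty populations", {
  gt <- rbind(c(1L, 1L, 0L, 0L),   # p = 0.25 -> site pi (8/7)*2*.25*.75
              c(0L, 0L, 0L, 0L))   # monomorphic -> 0
  gm <- makeGM(gt)
  expected <- (8 / 7) * 2 * 0.25 * 0.75
  expect_equal(meanPi(gm)$pi, (expected + 0) / 2)
  expect_equal(meanPi(gm, totalSites = 100)$pi, expected / 100)
  allNA <- makeGM(matrix(NA_integer_, 2, 3))
  expect_warning(res <- meanPi(allNA), "called")
  expect_true(is.nan(res$pi))
})

test_that("heterozygosities follow their definitions and HWE at scale", {
  gt <- rbind(rep(0L, 4), rep(2L, 4))
  h <- heterozygosity(makeGM(gt))
  expect_equal(h$hObs, 0)
  expect_equal(h$hExp, 0)
  gt2 <- matrix(1L, 1, 4)
  h2 <- heterozygosity(makeGM(gt2))
  expect_equal(h2$hObs, 1)
  expect_equal(h2$hExp, 0.5)
  set.seed(31)
  gt3 <- matrix(rbinom(500, 2, 0.3), 1, 500)
  h3 <- heterozygosity(makeGM(gt3))
  se <- sqrt(0.42 * 0.58 / 500)
  expect_lt(abs(h3$hObs - 0.42), 3 * se + 0.01)
  expect_lt(abs(h3$hExp - 0.42), 3 * se + 0.01)
})

test_that("private alleles match explicit membership sets", {
  # site 1: alt only in popA; site 2: alt in A and B; site 3: ref only in B
  gt <- rbind(c(1L, 0L, 0L, 0L),
              c(1L, 1L, 1L, 0L),
              c(2L, 2L, 1L, 2L))
  gm <- makeGM(gt)
  pops <- setNames(c("A", "A", "B", "B"), colnames(genotypes(gm)))
  pa <- privateAlleles(gm, pops)
  expect_identical(pa[["A"]], 1L + 0L + 0L)
  expect_identical(pa[["B"]], 0L + 0L + 1L)
  # brute-force oracle on random 3-population fixtures
  set.seed(77)
  for (rep in 1:20) {
    g <- matrix(sample(c(0L, 1L, 2L, NA), 30, replace = TRUE), 10, 3)
    colnames(g) <- c("x", "y", "z")
    gm2 <- makeGM(g)
    pops2 <- setNames(c("P1", "P2", "P3"), colnames(g))
    oracle <- c(P1 = 0L, P2 = 0L, P3 = 0L)
    for (s in 1:10) for (allele in c("ref", "alt")) {
      who <- vapply(colnames(g), function(sm) {
        gg <- g[s, sm]
        if (is.na(gg)) return(FALSE)
        if (allele == "ref") gg %in% c(0L, 1L) else gg %in% c(1L, 2L)
      }, logical(1))
      if (sum(who) == 1) {
        pop <- pops2[names(who)[who]]
        oracle[pop] <- oracle[pop] + 1L
      }
    }
    expect_identical(privateAlleles(gm2, pops2)[names(oracle)], oracle)
  }
})

test_that("Watterson's theta follows S over a1 L", {
  expect_equal(wattersonTheta(0, 8, 150), 0)
  expect_equal(wattersonTheta(1, 2, 1), 1)
  a1 <- sum(1 / 1:7)
  expect_equal(wattersonTheta(3, 8, 150), 3 / (a1 * 150), tolerance = 1e-12)
})

test_that("Tajima's D matches an independently coded constants oracle", {
  a1 <- sum(1 / 1:9)
  expect_equal(tajimasD(5, 5 / a1, 10), 0)
  expect_true(is.nan(tajimasD(0, 0, 10)))
  expect_true(is.nan(tajimasD(3, 1, 3)))
  expect_equal(tajimasD(5, 4.0, 10), oracleTajimaD(5, 4.0, 10),
               tolerance = 1e-12)
  set.seed(41)
  for (i in 1:30) {
    n <- sample(4:40, 1)
    S <- sample(1:25, 1)
    piT <- runif(1, 0, S)
    expect_equal(tajimasD(S, piT, n), oracleTajimaD(S, piT, n),
                 tolerance = 1e-12)
  }
})

test_that("windows tile loci with a true-length partial tail", {
  sc <- demographicScenario(nLoci = 3, locusLengthBp = 710,
    sitesPerLocus = 30,
    epochSizes = data.frame(start_gen = 0, N = 200),
    samplingEpochs = data.frame(generation = 0, label = "T1", n_samples = 8),
    mu = 0, seed = 8)
  gm <- applyArchivalArtifacts(simulateTemporalPopulation(sc),
                               cleanArtifactModel())
  lens <- setNames(rep(710L, 3), unique(siteInfo(gm)$locus))
  w <- slidingWindowStats(gm, size = 150, locusLengths = lens)
  expect_identical(nrow(w), 15L)                # ceiling(710/150) per locus
  expect_identical(unique(w$length[w$start == 601]), 110L)
  # per-window S adds up to the locus total at step = size
  ac <- rowSums(altCopies(genotypes(gm)))
  perLocus <- tapply(seq_len(nrow(gm)), siteInfo(gm)$locus, function(idx) {
    g <- genotypes(gm)[idx, , drop = FALSE]
    alt <- rowSums(altCopies(g)); tot <- rowSums(calledChrom(g))
    sum(alt > 0 & alt < tot)
  })
  agg <- tapply(w$S, w$locus, sum)
  expect_equal(unname(agg[names(perLocus)]), unname(perLocus))
  # an empty window has S = 0, theta 0, D undefined
  empty <- w[w$n_sites == 0, ]
  if (nrow(empty)) {
    expect_true(all(empty$S == 0))
    expect_true(all(empty$theta_w == 0))
    expect_true(all(is.nan(empty$tajimas_d)))
  }
})

test_that("Weir-Cockerham Fst spans no-differentiation to fixation", {
  fixed <- gmFromDoses(list(rep(0L, 10), rep(2L, 10)))
  res <- weirCockerhamFst(fixed$gm, fixed$pops)
  expect_equal(res$perSite$fst, 1)
  set.seed(51)
  vals <- replicate(40, {
    p <- runif(1, 0.2, 0.8)
    f <- gmFromDoses(list(rbinom(12, 2, p), rbinom(12, 2, p)))
    weirCockerhamFst(f$gm, f$pops)$perSite$fst
  })
  expect_lt(abs(mean(vals, na.rm = TRUE)), 0.05)
})

test_that("Fst matches the allele-indicator ANOVA oracle on random fixtures", {
  set.seed(61)
  checked <- 0
  while (checked < 100) {
    doses <- randomDoseFixture(nPops = sample(2:4, 1))
    oracle <- wcOracle(doses)
    if (is.na(oracle)) next
    f <- gmFromDoses(doses)
    impl <- weirCockerhamFst(f$gm, f$pops)$perSite$fst
    expect_equal(impl, oracle, tolerance = 1e-10)
    checked <- checked + 1
  }
  # the worked two-population case: n1 = n2 = 8, p1 = 0.25, p2 = 0.75
  doses <- list(c(rep(0L, 4), rep(1L, 4)), c(rep(2L, 4), rep(1L, 4)))
  f <- gmFromDoses(doses)
  expect_equal(weirCockerhamFst(f$gm, f$pops)$perSite$fst,
               wcOracle(doses), tolerance = 1e-10)
})
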