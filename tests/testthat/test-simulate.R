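test_that("scenario and artifact-model constructors enforce invariants", {
  expect_error(demographicScenario(nLoci = 1,
    epochSizes = data.frame(start_gen = 0, N = 1)), "sizes")
  expect_error(demographicScenario(nLoci = 1,
    epochSizes = data.frame(start_gen = c(0, 0), N = c(10, 10))),
    "strictly increasing")
  expect_error(demographicScenario(nLoci = 1,
    samplingEpochs = data.frame(generation = c(0, 5), label = c("T1", "T1"),
                                n_samples = 3)), "unique")
  expect_error(artifactModel(missingRate = 1.5), "rates")
  expect_error(simulateTemporalPopulation(
    demographicScenario(nLoci = 1, sitesPerLocus = 0)))
})

test_that("Hardy-Weinberg heterozygosity emerges with artifacts off", {
  sc <- demographicScenario(nLoci = 40, sitesPerLocus = 10,
    epochSizes = data.frame(start_gen = 0, N = 500),
    samplingEpochs = data.frame(generation = 0, label = "T1",
                                n_samples = 120),
    mu = 0, seed = 7)
  tr <- simulateTemporalPopulation(sc)
  gm <- applyArchivalArtifacts(tr, cleanArtifactModel())
  expect_identical(dim(genotypes(gm)), c(400L, 120L))
  p <- tr$freqByEpoch[, "T1"]
  gt <- genotypes(gm)
  hetObs <- rowMeans(gt == 1L)
  hetExp <- 2 * p * (1 - p)
  use <- p > 0.1 & p < 0.9
  # mean deviation over many sites shrinks as binomial error averages out
  dev <- hetObs[use] - hetExp[use]
  expect_lt(abs(mean(dev)), 4 * sd(dev) / sqrt(length(dev)) + 0.005)
})

test_that("with artifacts off observed genotypes equal truth exactly", {
  sc <- scenarioPreset("stable", nLoci = 20, sitesPerLocus = 5,
                       nSamples = 6, seed = 5)
  tr <- simulateTemporalPopulation(sc)
  gm <- applyArchivalArtifacts(tr, cleanArtifactModel())
  truthAll <- do.call(cbind, tr$genotypesByEpoch)
  expect_equal(unname(genotypes(gm)), unname(truthAll))
})

test_that("drift forces fixation or loss in a tiny population", {
  # brute-force Markov-chain oracle on the 5-state chain (2N = 4)
  P <- outer(0:4, 0:4, function(i, j)
    dbinom(j, 4, i / 4))
  v <- c(0, 1, 0, 0, 0)  # start from one derived copy
  for (g in 1:200) v <- as.vector(v %*% P)
  absorbedOracle <- v[1] + v[5]
  expect_gt(absorbedOracle, 0.99)
  hits <- vapply(1:60, function(s) {
    sc <- demographicScenario(nLoci = 1, sitesPerLocus = 1,
      epochSizes = data.frame(start_gen = 0, N = 2),
      samplingEpochs = data.frame(generation = 200, label = "T1",
                                  n_samples = 2),
      mu = 0, propSegregating = 1, seed = s)
    tr <- simulateTemporalPopulation(sc)
    f <- tr$freqByEpoch[1, 1]
    f == 0 || f == 1
  }, logical(1))
  expect_gte(mean(hits), 59 / 60)
})

test_that("a hundredfold crash lowers nucleotide diversity at later epochs", {
  lowerCount <- 0
  for (s in 1:50) {
    mk <- function(Ns) {
      sc <- demographicScenario(nLoci = 30, sitesPerLocus = 5,
        epochSizes = Ns,
        samplingEpochs = data.frame(generation = c(0, 40),
                                    label = c("T1", "T2"), n_samples = 10),
        mu = 0, propSegregating = 1, seed = s)
      tr <- simulateTemporalPopulation(sc)
      gm <- applyArchivalArtifacts(tr, cleanArtifactModel())
      md <- sampleData(gm)
      meanPi(gm, colnames(gm)[md$time_period == "T2"],
             totalSites = nrow(gm))$pi
    }
    piBott <- mk(data.frame(start_gen = c(0, 1), N = c(5000, 50)))
    piStab <- mk(data.frame(start_gen = 0, N = 5000))
    if (piBott < piStab) lowerCount <- lowerCount + 1
  }
  expect_gte(lowerCount / 50, 0.9)
})

test_that("neutral SFS initialisation follows the 1/i law", {
  sc <- demographicScenario(nLoci = 1000, sitesPerLocus = 100,
    epochSizes = data.frame(start_gen = 0, N = 10),
    samplingEpochs = data.frame(generation = 0, label = "T1", n_samples = 3),
    mu = 0, propSegregating = 1, seed = 42)
  tr <- simulateTemporalPopulation(sc)
  counts <- round(tr$initFreq * 20)
  obs <- tabulate(counts, nbins = 19)
  expTot <- sum(obs) * (1 / 1:19) / sum(1 / 1:19)
  chi <- sum((obs - expTot)^2 / expTot)
  # 18 df; well below the 0.001 tail cutoff under the correct law
  expect_lt(chi, qchisq(0.999, df = 18))
})

test_that("identical seeds replay to byte-identical VCFs", {
  mk <- function() {
    sc <- scenarioPreset("bottleneck", nLoci = 10, sitesPerLocus = 4,
                         nSamples = 4, seed = 9)
    gm <- applyArchivalArtifacts(simulateTemporalPopulation(sc))
    f <- tempfile(fileext = ".vcf")
    writeGenotypeVcf(gm, f)
    f
  }
  f1 <- mk(); f2 <- mk()
  expect_identical(readLines(f1), readLines(f2))
  unlink(c(f1, f2))
})

test_that("dropout converts heterozygotes to homozygotes at the set rate", {
  sc <- demographicScenario(nLoci = 20, sitesPerLocus = 10,
    epochSizes = data.frame(start_gen = 0, N = 100),
    samplingEpochs = data.frame(generation = 0, label = "T1", n_samples = 10),
    mu = 0, seed = 3)
  tr <- simulateTemporalPopulation(sc)
  tr$genotypesByEpoch$T1[] <- 1L  # force an all-heterozygote truth
  m <- artifactModel(depth = list(historic_liver = c(40, 0.1),
                                  frozen_blood = c(40, 0.1),
                                  modern_liver = c(40, 0.1)),
                     missingRate = 0, dropoutRate = 0.5,
                     damageRateCT = 0, damageRateGA = 0)
  gm <- applyArchivalArtifacts(tr, m)
  hObs <- mean(genotypes(gm) == 1L)
  se <- sqrt(0.5 * 0.5 / length(genotypes(gm)))
  expect_lt(abs(hObs - 0.5), 4 * se + 0.01)
})

test_that("observed heterozygosity is non-increasing in the dropout rate", {
  rates <- c(0, 0.1, 0.3, 0.5)
  hets <- sapply(1:20, function(s) {
    sc <- scenarioPreset("stable", nLoci = 30, sitesPerLocus = 5,
                         nSamples = 8, seed = s)
    tr <- simulateTemporalPopulation(sc)
    vapply(rates, function(r) {
      m <- artifactModel(depth = list(historic_liver = c(40, 0.1),
                                      frozen_blood = c(40, 0.1),
                                      modern_liver = c(40, 0.1)),
                         missingRate = 0, dropoutRate = r,
                         damageRateCT = 0, damageRateGA = 0)
      gm <- applyArchivalArtifacts(tr, m)
      mean(genotypes(gm) == 1L, na.rm = TRUE)
    }, numeric(1))
  })
  avg <- rowMeans(hets)
  expect_true(all(diff(avg) < 0))
})

test_that("unknown tissue classes are rejected", {
  sc <- scenarioPreset("stable", nLoci = 2, sitesPerLocus = 2,
                       nSamples = 3, seed = 1)
  tr <- simulateTemporalPopulation(sc)
  ta <- defaultTissueAssignment(tr)
  ta[1] <- "mystery_tissue"
  expect_error(applyArchivalArtifacts(tr, artifactModel(), ta),
               "unknown tissue")
})
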