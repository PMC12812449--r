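test_that("indel proximity pruning honours window and cluster rules", {
  cfg <- filterConfig()
  expect_false(pruneIndelProximity(100L, 103L, cfg))   # |delta| = 3 removed
  expect_true(pruneIndelProximity(100L, 104L, cfg))    # |delta| = 4 kept
  # indels at 50 and 54 (gap 4 <= 5) cluster; the SNP between them goes
  expect_false(pruneIndelProximity(52L, c(50L, 54L), cfg))
  expect_identical(pruneIndelProximity(integer(0), 10L, cfg), logical(0))
  expect_true(all(pruneIndelProximity(c(1L, 20L), integer(0), cfg)))
})

test_that("MAC and MAF thresholds act on called alleles", {
  # 50 diploids: 2 het carriers -> MAC 2 (< 3) but MAF 0.02 (> 0.015)
  gt <- matrix(0L, 1, 50)
  gt[1, 1:2] <- 1L
  res <- suppressWarnings(applySiteFilters(makeGM(gt)))
  expect_identical(nrow(res$matrix), 0L)
  rep <- res$report
  expect_identical(rep$removed[rep$filter == "mac"], 1L)
  # 100 diploids, 4 het carriers: MAC 4, MAF 0.02 -> retained
  gt2 <- matrix(0L, 1, 100)
  gt2[1, 1:4] <- 1L
  res2 <- suppressWarnings(applySiteFilters(makeGM(gt2)))
  expect_identical(nrow(res2$matrix), 1L)
  # MAC 4 but MAF 4/300 = 0.0133 <= 0.015 -> removed by the MAF filter
  gt3 <- matrix(0L, 1, 150)
  gt3[1, 1:4] <- 1L
  res3 <- suppressWarnings(applySiteFilters(makeGM(gt3)))
  rep3 <- res3$report
  expect_identical(rep3$removed[rep3$filter == "maf"], 1L)
})

test_that("allele-balance masking can push a site below presence", {
  # 4 samples; one het has AD 2,8 (balance 0.2 <= 0.25): masked missing.
  # With one other sample already missing, presence drops to 0.5 exactly,
  # which still passes; a third missing call removes the site.
  gt <- matrix(c(1L, 1L, NA, 0L), 1, 4)
  dp <- matrix(10, 1, 4)
  adr <- matrix(c(2, 5, NA, 10), 1, 4)
  ada <- matrix(c(8, 5, NA, 0), 1, 4)
  gm <- makeGM(gt, dp = dp, adRef = adr, adAlt = ada)
  cfg <- filterConfig(minMac = 0, maxMafExcluded = 0)
  res <- applySiteFilters(gm, cfg)
  expect_identical(attr(res$report, "genotypesMasked"), 1L)
  expect_identical(nrow(res$matrix), 1L)      # presence 2/4 = 0.5 passes
  gt2 <- matrix(c(1L, 1L, NA, NA), 1, 4)
  gm2 <- makeGM(gt2, dp = dp, adRef = adr, adAlt = ada)
  res2 <- applySiteFilters(gm2, cfg)
  expect_identical(nrow(res2$matrix), 0L)     # presence 1/4 after masking
  expect_identical(res2$report$removed[res2$report$filter == "presence"], 1L)
})

test_that("boundary conventions: QUAL, depth and balance edges", {
  gt <- matrix(c(1L, 1L), 2, 1)
  gm <- makeGM(gt, qual = c(30, 29.99))
  res <- suppressWarnings(applySiteFilters(gm,
    filterConfig(minMac = 0, maxMafExcluded = 0, minPresenceFraction = 0)))
  expect_identical(nrow(res$matrix), 1L)  # QUAL 30 passes, 29.99 fails
  # DP 5 passes, DP 4 masks; AB exactly 0.25 masks (open interval)
  gt2 <- matrix(c(1L, 1L, 1L), 1, 3)
  dp2 <- matrix(c(5, 4, 8), 1, 3)
  adr2 <- matrix(c(2, 2, 2), 1, 3)
  ada2 <- matrix(c(3, 2, 6), 1, 3)
  gm2 <- makeGM(gt2, dp = dp2, adRef = adr2, adAlt = ada2)
  res2 <- applySiteFilters(gm2,
    filterConfig(minMac = 0, maxMafExcluded = 0, minPresenceFraction = 0))
  kept <- genotypes(res2$matrix)
  expect_identical(unname(kept[1, ]), c(1L, NA_integer_, NA_integer_))
})

test_that("the filter chain is idempotent and its bookkeeping balances", {
  sc <- scenarioPreset("bottleneck", nLoci = 40, sitesPerLocus = 6,
                       nSamples = 8, seed = 11)
  gm <- applyArchivalArtifacts(simulateTemporalPopulation(sc),
                               artifactModel(qualErrorFraction = 0.1))
  res1 <- suppressWarnings(applySiteFilters(gm))
  res2 <- suppressWarnings(applySiteFilters(res1$matrix))
  expect_identical(genotypes(res2$matrix), genotypes(res1$matrix))
  rep <- res1$report
  expect_identical(rep$sites_in[1] - sum(rep$removed),
                   rep$sites_out[nrow(rep)])
  expect_true(all(rep$sites_in - rep$removed == rep$sites_out))
})

test_that("indel records prune nearby SNPs inside the chain", {
  si <- data.frame(locus = "L1", pos = c(100L, 103L, 110L),
                   ref = c("A", "AT", "C"), alt = c("G", "A", "T"),
                   qual = 60)
  gt <- matrix(1L, 3, 6)
  gm <- GenotypeMatrix(gt, si)
  res <- suppressWarnings(applySiteFilters(gm,
    filterConfig(minMac = 0, maxMafExcluded = 0)))
  # SNP at 100 is within 3 bp of the indel at 103; the indel itself goes too
  expect_identical(siteInfo(res$matrix)$pos, 110L)
})

test_that("one-SNP thinning is deterministic, uniform and seed-sensitive", {
  sc <- scenarioPreset("stable", nLoci = 100, sitesPerLocus = 5,
                       nSamples = 4, seed = 13)
  gm <- applyArchivalArtifacts(simulateTemporalPopulation(sc),
                               cleanArtifactModel())
  t1 <- thinOneSnpPerLocus(gm, seed = 1)
  t2 <- thinOneSnpPerLocus(gm, seed = 1)
  t3 <- thinOneSnpPerLocus(gm, seed = 2)
  expect_identical(nrow(t1), 100L)
  expect_identical(siteInfo(t1)$pos, siteInfo(t2)$pos)
  expect_false(identical(siteInfo(t1)$pos, siteInfo(t3)$pos))
  expect_identical(anyDuplicated(siteInfo(t1)$locus), 0L)
  # uniformity on a single 5-site locus across many seeds
  one <- gm[siteInfo(gm)$locus == siteInfo(gm)$locus[1], ]
  picks <- vapply(1:2000, function(s) siteInfo(thinOneSnpPerLocus(one, s))$pos,
                  integer(1))
  counts <- table(factor(picks, levels = sort(unique(siteInfo(one)$pos))))
  se <- sqrt(2000 * 0.2 * 0.8)
  expect_true(all(abs(counts - 400) <= 3 * se))
})

test_that("coding partition respects the BED off-by-one convention", {
  si <- data.frame(locus = "L1", pos = c(155L, 156L, 555L, 556L),
                   ref = "A", alt = "G", qual = 60)
  gm <- GenotypeMatrix(matrix(1L, 4, 2), si)
  map <- data.frame(locus = "L1", start0 = 155L, end0 = 555L)
  part <- partitionCodingNoncoding(gm, map)
  expect_identical(siteInfo(part$coding)$pos, c(156L, 555L))
  expect_identical(siteInfo(part$noncoding)$pos, c(155L, 556L))
  # partition property: the two halves reassemble the input site set
  expect_setequal(c(siteInfo(part$coding)$pos, siteInfo(part$noncoding)$pos),
                  siteInfo(gm)$pos)
  expect_error(partitionCodingNoncoding(gm,
    data.frame(locus = "L2", start0 = 0L, end0 = 10L)), "absent")
})

test_that("depth downsampling hits the target mean and spares shallow samples", {
  n <- 1000
  gt <- matrix(1L, n, 2)
  dp <- cbind(rep(48, n), rep(10, n))
  adr <- matrix(round(dp / 2), n, 2)
  ada <- dp - adr
  gm <- makeGM(gt, dp = dp, adRef = adr, adAlt = ada)
  out <- downsampleDepth(gm, 24, seed = 5)
  expect_lt(abs(mean(depths(out)[, 1]) - 24), 1)
  expect_identical(depths(out)[, 2], rep(10, n))
  # AD still sums to DP after the hypergeometric re-split
  expect_true(all(refDepths(out) + altDepths(out) == depths(out),
                  na.rm = TRUE))
  expect_error(downsampleDepth(gm, 0), "positive")
})

test_that("missingness is the missing-cell fraction of the matrix", {
  gt <- matrix(c(0L, 1L, NA, 2L), 2, 2)
  expect_equal(computeMissingness(makeGM(gt)), 0.25)
  # a 141 x 2229 matrix with cells masked at 15.7% recovers the rate
  set.seed(404)
  big <- matrix(0L, 2229, 141)
  mask <- runif(length(big)) < 0.157
  big[mask] <- NA_integer_
  est <- computeMissingness(makeGM(big))
  se <- sqrt(0.157 * 0.843 / length(big))
  expect_lt(abs(est - 0.157), 3 * se)
})

test_that("capture-target filtering uses inclusive length and GC bounds", {
  cand <- data.frame(length_bp = c(300, 150, 300, 200, 400, 401),
                     gc_fraction = c(0.5, 0.5, 0.8, 0.30, 0.70, 0.5))
  kept <- filterCandidateTargets(cand)
  expect_identical(rownames(kept), c("1", "4", "5"))
  expect_error(filterCandidateTargets(
    data.frame(length_bp = -5, gc_fraction = 0.5)))
})
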