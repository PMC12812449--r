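#' Forward Wright-Fisher simulation of a serially sampled population
#'
#' Simulates biallelic sites across independent loci under a
#' piecewise-constant diploid population size. Each tracked site is either
#' initialised as segregating, with its derived-allele count \eqn{i \in
#' \{1, ..., 2N-1\}} drawn from the neutral site-frequency spectrum
#' (probability proportional to \eqn{1/i}), or starts monomorphic. Allele
#' frequencies then evolve by binomial Wright-Fisher resampling with the
#' current epoch's \eqn{2N} chromosomes; monomorphic sites (including sites
#' that have fixed or been lost) gain a new derived allele with probability
#' \eqn{2N\mu} per generation, entering at frequency \eqn{1/2N}. At each
#' sampling epoch, diploid genotypes for that epoch's samples are drawn
#' binomially from the current frequency (Hardy-Weinberg); sites invariant
#' in a sample are retained.
#'
#' Sites within a locus are simulated independently (free recombination);
#' downstream one-SNP-per-locus thinning makes the statistics insensitive
#' to this simplification.
#'
#' @param scenario a \code{\link{demographicScenario}}.
#' @return a \code{truth_record} list with elements \code{siteTable}
#'   (locus, pos, ref, alt), \code{freqByEpoch} (sites x sampling epochs,
#'   population derived-allele frequency at sampling time),
#'   \code{initFreq}, \code{genotypesByEpoch} (list of sites x samples
#'   integer matrices of true alt-allele doses), \code{sampleTable}
#'   (sample, time_period, year, generation) and the scenario itself.
#' @export
simulateTemporalPopulation <- function(scenario) {
  stopifnot(inherits(scenario, "demographic_scenario"))
  sc <- scenario
  nSites <- sc$nLoci * sc$sitesPerLocus
  if (nSites < 1) stop("scenario must contain at least one site")

  siteTable <- withSeed(subSeed(sc$seed, "sites"), {
    pos <- as.vector(vapply(seq_len(sc$nLoci), function(l)
      sort(sample.int(sc$locusLengthBp, sc$sitesPerLocus)),
      integer(sc$sitesPerLocus)))
    # allele pairs: half the sites get deamination-prone pairs (C/T, G/A)
    pairs <- rbind(c("C", "T"), c("G", "A"), c("A", "C"), c("T", "G"))
    pick <- sample.int(4L, nSites, replace = TRUE)
    data.frame(locus = rep(sprintf("locus%04d", seq_len(sc$nLoci)),
                           each = sc$sitesPerLocus),
               pos = pos,
               ref = pairs[pick, 1], alt = pairs[pick, 2],
               stringsAsFactors = FALSE)
  })

  sizeAt <- function(gen) {
    idx <- findInterval(gen, sc$epochSizes$start_gen)
    as.integer(sc$epochSizes$N[idx])
  }

  freq <- withSeed(subSeed(sc$seed, "init"), {
    twoN <- 2L * sizeAt(0)
    f <- numeric(nSites)
    seg <- runif(nSites) < sc$propSegregating
    if (any(seg)) {
      i <- seq_len(twoN - 1L)
      f[seg] <- sample(i, sum(seg), replace = TRUE, prob = 1 / i) / twoN
    }
    f
  })
  initFreq <- freq

  epochs <- sc$samplingEpochs
  nEpoch <- nrow(epochs)
  freqByEpoch <- matrix(NA_real_, nSites, nEpoch,
                        dimnames = list(NULL, epochs$label))
  genotypesByEpoch <- vector("list", nEpoch)
  names(genotypesByEpoch) <- epochs$label

  sampleEpoch <- function(e, f) {
    n <- epochs$n_samples[e]
    ids <- sprintf("%s_s%02d", epochs$label[e], seq_len(n))
    withSeed(subSeed(sc$seed, "sample", e), {
      g <- matrix(rbinom(length(f) * n, 2L, rep(f, n)),
                  nrow = length(f), ncol = n, dimnames = list(NULL, ids))
      storage.mode(g) <- "integer"
      g
    })
  }

  gen <- 0L
  maxGen <- sc$nGenerations
  repeat {
    hit <- which(epochs$generation == gen)
    for (e in hit) {
      freqByEpoch[, e] <- freq
      genotypesByEpoch[[e]] <- sampleEpoch(e, freq)
    }
    if (gen >= maxGen) break
    gen <- gen + 1L
    twoN <- 2L * sizeAt(gen)
    withSeed(subSeed(sc$seed, "gen", gen), {
      seg <- freq > 0 & freq < 1
      if (any(seg))
        freq[seg] <- rbinom(sum(seg), twoN, freq[seg]) / twoN
      if (sc$mu > 0) {
        mono <- which(!seg)
        if (length(mono)) {
          hitMut <- mono[runif(length(mono)) < twoN * sc$mu]
          # a new derived allele replaces the fixed state at frequency 1/2N;
          # on sites fixed for the derived allele the mutation restores ref
          freq[hitMut] <- ifelse(freq[hitMut] >= 1, 1 - 1 / twoN, 1 / twoN)
        }
      }
    })
  }

  sampleTable <- do.call(rbind, lapply(seq_len(nEpoch), function(e) {
    n <- epochs$n_samples[e]
    data.frame(sample = colnames(genotypesByEpoch[[e]]),
               time_period = epochs$label[e],
               generation = epochs$generation[e],
               year = round(sc$baseYear +
                            epochs$generation[e] * sc$yearsPerGeneration),
               stringsAsFactors = FALSE)
  }))

  structure(list(siteTable = siteTable, freqByEpoch = freqByEpoch,
                 initFreq = initFreq, genotypesByEpoch = genotypesByEpoch,
                 sampleTable = sampleTable, scenario = sc),
            class = "truth_record")
}

#' Default tissue assignment: one preparation type per time period
#'
#' Mirrors the archival reality that the oldest specimens are formalin-fixed
#' liver, the middle period frozen blood, and the modern period frozen
#' liver.
#' @param truth a \code{truth_record}
#' @return named character vector sample -> tissue class
#' @export
defaultTissueAssignment <- function(truth) {
  map <- c(T1 = "historic_liver", T2 = "frozen_blood", T3 = "modern_liver")
  tp <- truth$sampleTable$time_period
  tissue <- unname(map[tp])
  tissue[is.na(tissue)] <- "modern_liver"
  stats::setNames(tissue, truth$sampleTable$sample)
}

#' Overlay archival-DNA artifacts on true genotypes
#'
#' Applies, per genotype: a tissue-specific depth draw (normal, truncated
#' at 1: draws below 1 become missing), outright missingness, allelic
#' dropout of heterozygotes (observed as a homozygote for one allele chosen
#' uniformly), and deamination-type miscalls: at sites whose REF/ALT pair
#' is C/T, each C allele copy is miscalled T with \code{damageRateCT};
#' at G/A sites each G copy is miscalled A with \code{damageRateGA}. Allele
#' depths are a binomial split of the depth by the observed genotype,
#' except that a heterozygote *created* by a damage flip is supported only
#' by damaged reads, so its minor-allele read fraction equals the per-read
#' miscall rate — downstream allele-balance filtering therefore removes
#' most damage-induced false heterozygotes, as it does in real pipelines.
#' QUAL is 60 for all sites unless \code{qualErrorFraction} > 0.
#'
#' @param truth a \code{truth_record} from
#'   \code{\link{simulateTemporalPopulation}}.
#' @param model an \code{\link{artifactModel}}.
#' @param tissueAssignment named vector sample -> tissue class covering all
#'   samples; defaults to \code{\link{defaultTissueAssignment}}.
#' @return a \linkS4class{GenotypeMatrix} with sample metadata columns
#'   \code{species}, \code{site}, \code{time_period}, \code{year},
#'   \code{tissue}.
#' @export
applyArchivalArtifacts <- function(truth, model = artifactModel(),
                                   tissueAssignment =
                                     defaultTissueAssignment(truth)) {
  stopifnot(inherits(truth, "truth_record"),
            inherits(model, "artifact_model"))
  st <- truth$sampleTable
  if (!all(st$sample %in% names(tissueAssignment)))
    stop("tissue assignment must cover all samples")
  tissues <- tissueAssignment[st$sample]
  unknown <- setdiff(unique(tissues), names(model$depth))
  if (length(unknown))
    stop("unknown tissue class: ", paste(unknown, collapse = ", "))

  gtTrue <- do.call(cbind, truth$genotypesByEpoch)
  nSites <- nrow(gtTrue); nSamp <- ncol(gtTrue)
  sc <- truth$scenario
  ref <- truth$siteTable$ref; alt <- truth$siteTable$alt

  withSeed(subSeed(sc$seed, "artifacts"), {
    mu <- vapply(model$depth[tissues], `[`, numeric(1), 1L)
    sdv <- vapply(model$depth[tissues], `[`, numeric(1), 2L)
    dp <- matrix(stats::rnorm(nSites * nSamp,
                              rep(mu, each = nSites),
                              rep(sdv, each = nSites)), nSites, nSamp)
    missing <- dp < 1 | matrix(runif(nSites * nSamp) < model$missingRate,
                               nSites, nSamp)
    dp <- round(pmax(dp, 1))

    gt <- gtTrue
    # allelic dropout: het -> homozygote for a uniformly chosen allele
    dropHit <- isHet(gt) & matrix(runif(nSites * nSamp) < model$dropoutRate,
                                  nSites, nSamp)
    gt[dropHit] <- 2L * rbinom(sum(dropHit), 1L, 0.5)

    # damage miscalls: flip vulnerable allele copies at C/T and G/A sites
    rateOf <- ifelse(ref == "C" & alt == "T" | ref == "T" & alt == "C",
                     model$damageRateCT,
              ifelse(ref == "G" & alt == "A" | ref == "A" & alt == "G",
                     model$damageRateGA, 0))
    # the damaged base is C (C>T) or G (G>A); +1 dose if it is REF, -1 if ALT
    dmgDir <- ifelse(ref %in% c("C", "G"), 1L, ifelse(alt %in% c("C", "G"),
                                                      -1L, 0L))
    vulnerable <- ifelse(dmgDir == 1L, 2L - gt, gt)  # copies of the C/G base
    gtBefore <- gt
    if (any(rateOf > 0)) {
      flips <- matrix(rbinom(nSites * nSamp, as.vector(vulnerable),
                             rep(rateOf, nSamp)), nSites, nSamp)
      gt <- gt + dmgDir * flips
      gt[gt < 0L] <- 0L; gt[gt > 2L] <- 2L
      storage.mode(gt) <- "integer"
    }

    gt[missing] <- NA_integer_
    dp[missing] <- NA_real_

    pHet <- matrix(0, nSites, nSamp)
    pHet[which(gt == 1L)] <- 0.5
    pHet[which(gt == 2L)] <- 1
    # a damage-created heterozygote is supported only by damaged reads, so
    # its allele-depth balance mirrors the per-read miscall rate rather
    # than 0.5 — this is what lets the allele-balance filter catch it
    rateMat <- matrix(rep(rateOf, nSamp), nSites, nSamp)
    fromHomRef <- which(gt == 1L & gtBefore == 0L)
    fromHomAlt <- which(gt == 1L & gtBefore == 2L)
    pHet[fromHomRef] <- pmax(rateMat[fromHomRef], 1e-6)
    pHet[fromHomAlt] <- 1 - pmax(rateMat[fromHomAlt], 1e-6)
    dpDraw <- dp; dpDraw[is.na(dpDraw)] <- 0
    adAlt <- matrix(rbinom(nSites * nSamp, as.vector(dpDraw), as.vector(pHet)),
                    nSites, nSamp)
    adAlt[which(gt == 0L)] <- 0
    adAlt[which(gt == 2L)] <- dp[which(gt == 2L)]
    adAlt[is.na(gt)] <- NA_real_
    adRef <- dp - adAlt

    qual <- rep(60, nSites)
    if (model$qualErrorFraction > 0) {
      bad <- runif(nSites) < model$qualErrorFraction
      qual[bad] <- 10
    }

    si <- data.frame(truth$siteTable, qual = qual)
    sampleMeta <- data.frame(species = "P_synthetica", site = "SiteA",
                             time_period = st$time_period, year = st$year,
                             tissue = unname(tissues),
                             row.names = st$sample)
    gm <- GenotypeMatrix(gt, si, dp = dp, adRef = adRef, adAlt = adAlt,
                         sampleData = sampleMeta)
    colnames(gm) <- st$sample
    gm
  })
}
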