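#' Describe a temporal sampling demography
#'
#' A demographic scenario drives the forward Wright-Fisher simulator: a set
#' of loci, piecewise-constant diploid population sizes, and labelled
#' sampling epochs mirroring serially collected specimens (three time
#' periods by default: 1960s-70s, 1980s-90s, 2010s).
#'
#' @param nLoci number of independent loci.
#' @param locusLengthBp locus length in bp (default 710, a typical captured
#'   exon-plus-flanks target length).
#' @param sitesPerLocus number of tracked positions per locus.
#' @param epochSizes data.frame with columns \code{start_gen} (strictly
#'   increasing, first must be 0) and \code{N} (diploid size, >= 2); each row
#'   holds from its start generation until the next row.
#' @param samplingEpochs data.frame with columns \code{generation},
#'   \code{label} (unique, e.g. T1/T2/T3) and \code{n_samples}.
#' @param mu per-site per-generation mutation rate. The default 5.97e-9 is
#'   a mean vertebrate (fish) pedigree rate often borrowed when the focal
#'   taxon has no direct estimate.
#' @param propSegregating fraction of tracked positions initialised as
#'   segregating from the neutral site-frequency spectrum; the rest start
#'   monomorphic and only gain variation by mutation.
#' @param yearsPerGeneration calendar years per generation used only to
#'   annotate metadata years (default 3; generation time is a configuration
#'   choice, not an observed quantity).
#' @param baseYear calendar year assigned to generation 0.
#' @param seed master seed; per-locus and per-sample substreams are derived
#'   deterministically from it.
#' @return a \code{demographic_scenario} list.
#' @export
demographicScenario <- function(nLoci,
                                locusLengthBp = 710L,
                                sitesPerLocus = 10L,
                                epochSizes = data.frame(start_gen = 0, N = 1000),
                                samplingEpochs = data.frame(
                                  generation = c(0, 8, 17),
                                  label = c("T1", "T2", "T3"),
                                  n_samples = 12),
                                mu = 5.97e-9,
                                propSegregating = 1,
                                yearsPerGeneration = 3,
                                baseYear = 1965,
                                seed = 1L) {
  epochSizes <- as.data.frame(epochSizes)
  samplingEpochs <- as.data.frame(samplingEpochs)
  stopifnot(nLoci >= 1, locusLengthBp >= 1,
            sitesPerLocus >= 1, sitesPerLocus <= locusLengthBp,
            mu >= 0, propSegregating >= 0, propSegregating <= 1)
  if (any(epochSizes$N < 2)) stop("all population sizes must be >= 2")
  if (is.unsorted(epochSizes$start_gen, strictly = TRUE))
    stop("epoch boundaries must be strictly increasing")
  if (epochSizes$start_gen[1] != 0) stop("first epoch must start at generation 0")
  if (anyDuplicated(samplingEpochs$label)) stop("sampling labels must be unique")
  span <- max(samplingEpochs$generation)
  if (any(samplingEpochs$generation < 0))
    stop("sampling generations must be non-negative")
  structure(list(nLoci = as.integer(nLoci),
                 locusLengthBp = as.integer(locusLengthBp),
                 sitesPerLocus = as.integer(sitesPerLocus),
                 epochSizes = epochSizes,
                 samplingEpochs = samplingEpochs[order(samplingEpochs$generation), ],
                 mu = mu, propSegregating = propSegregating,
                 yearsPerGeneration = yearsPerGeneration,
                 baseYear = baseYear,
                 nGenerations = span,
                 seed = as.integer(seed)),
            class = "demographic_scenario")
}

#' Archival-DNA artifact model
#'
#' Parameters of the error layer applied to true genotypes: per-tissue
#' sequencing depth distributions, genotype missingness, allelic dropout
#' (the "homozygous bias" of degraded specimens: a heterozygote observed as
#' a homozygote for one of its alleles), and deamination-type miscalls
#' (C>T and G>A) applied per allele copy at sites whose REF/ALT pair is C/T
#' or G/A.
#'
#' Defaults reflect quantities typical of formalin-fixed liver, historic
#' frozen blood and modern liver preparations: mean depths 19.2x (SD 16.7),
#' 37.7x (SD 25.8) and 54.0x (SD 33.6), and miscall rates 0.008 (C>T) and
#' 0.006 (G>A).
#'
#' @param depth named list mapping tissue class to \code{c(mean, sd)} of the
#'   per-genotype depth distribution (normal, truncated below 1: draws below
#'   1 become missing genotypes).
#' @param missingRate probability a genotype is uncalled outright.
#' @param dropoutRate probability a true heterozygote is observed as a
#'   homozygote for one of its alleles chosen uniformly.
#' @param damageRateCT,damageRateGA per-allele-copy miscall probabilities.
#' @param qualErrorFraction fraction of emitted sites given low QUAL (< 30)
#'   to exercise the quality filter; 0 by default (all sites QUAL 60).
#' @return an \code{artifact_model} list.
#' @export
artifactModel <- function(depth = list(historic_liver = c(19.2, 16.7),
                                       frozen_blood  = c(37.7, 25.8),
                                       modern_liver  = c(54.0, 33.6)),
                          missingRate = 0.15,
                          dropoutRate = 0.05,
                          damageRateCT = 0.008,
                          damageRateGA = 0.006,
                          qualErrorFraction = 0) {
  probs <- c(missingRate, dropoutRate, damageRateCT, damageRateGA,
             qualErrorFraction)
  if (any(probs < 0 | probs > 1)) stop("all rates must lie in [0, 1]")
  if (any(vapply(depth, function(d) d[1] <= 0 || d[2] < 0, logical(1))))
    stop("depth means must be positive and SDs non-negative")
  structure(list(depth = depth, missingRate = missingRate,
                 dropoutRate = dropoutRate, damageRateCT = damageRateCT,
                 damageRateGA = damageRateGA,
                 qualErrorFraction = qualErrorFraction),
            class = "artifact_model")
}

#' Null artifact model (no missingness, dropout or damage)
#' @export
cleanArtifactModel <- function() {
  artifactModel(depth = list(historic_liver = c(40, 0.1),
                             frozen_blood = c(40, 0.1),
                             modern_liver = c(40, 0.1)),
                missingRate = 0, dropoutRate = 0,
                damageRateCT = 0, damageRateGA = 0)
}

#' Built-in demographic scenario presets
#'
#' Three toy demographies whose drift and mutation signals are measurable
#' over a three-time-point sampling design: \code{"stable"} (large constant
#' population, negligible change over the sampled span), \code{"expansion"}
#' (a small long-standing population grows 20-fold shortly after the first
#' sampling epoch, so mutational influx adds rare variants: pi and
#' Watterson's theta rise, Tajima's D falls), and \code{"bottleneck"}
#' (a 20-fold crash after the first epoch: rare variants are lost and
#' heterozygosity decays, so pi and theta fall while D rises). Effective
#' sizes, the per-site mutation rate and epoch spacings are deliberately
#' exaggerated relative to wild populations so that the expected signatures
#' emerge over tens of generations at a few thousand sites; see the package
#' vignette.
#'
#' @param name one of \code{"stable"}, \code{"expansion"}, \code{"bottleneck"}.
#' @param nLoci,sitesPerLocus,nSamples dimensions of the simulated panel.
#' @param seed master seed.
#' @return a \code{demographic_scenario}
#' @export
scenarioPreset <- function(name = c("stable", "expansion", "bottleneck"),
                           nLoci = 300L, sitesPerLocus = 20L,
                           nSamples = 16L, seed = 1L) {
  name <- match.arg(name)
  se <- data.frame(generation = c(5, 40, 70), label = c("T1", "T2", "T3"),
                   n_samples = nSamples)
  cfg <- switch(name,
    stable = list(sizes = data.frame(start_gen = 0, N = 4000),
                  mu = 0, propSeg = 0.20),
    expansion = list(sizes = data.frame(start_gen = c(0, 10), N = c(30, 600)),
                     mu = 6e-5, propSeg = 0.05),
    bottleneck = list(sizes = data.frame(start_gen = c(0, 10), N = c(600, 30)),
                      mu = 1e-6, propSeg = 0.30))
  demographicScenario(nLoci = nLoci, sitesPerLocus = sitesPerLocus,
                      epochSizes = cfg$sizes, samplingEpochs = se,
                      mu = cfg$mu, propSegregating = cfg$propSeg,
                      seed = seed)
}
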