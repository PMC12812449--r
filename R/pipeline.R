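#' Per-time-period diversity summaries
#'
#' For each time period in the sample metadata: per-bp nucleotide
#' diversity (site pi summed over variant sites, divided by the total
#' surveyed positions), and windowed Watterson's theta and Tajima's D
#' (means over windows with defined values).
#'
#' @param x a \linkS4class{GenotypeMatrix} whose colData has
#'   \code{time_period}
#' @param totalSites denominator for per-bp pi (total surveyed positions,
#'   including invariant ones); defaults to the number of rows of \code{x}
#' @param windowSize window size for theta/D (default 150 bp)
#' @param locusLengths optional named locus lengths for windowing
#' @return data.frame: one row per time period with pi, theta_w, tajimas_d,
#'   n_windows
#' @export
periodDiversity <- function(x, totalSites = nrow(x), windowSize = 150L,
                            locusLengths = NULL) {
  md <- sampleData(x)
  stopifnot("time_period" %in% colnames(md))
  periods <- unique(md$time_period)
  rows <- lapply(periods, function(tp) {
    sel <- colnames(x)[md$time_period == tp]
    mp <- meanPi(x, sel, totalSites = totalSites)
    w <- slidingWindowStats(x, sel, size = windowSize,
                            locusLengths = locusLengths)
    data.frame(time_period = tp,
               pi = mp$pi,
               n_variant_sites = mp$nSitesUsed,
               theta_w = mean(w$theta_w, na.rm = TRUE),
               tajimas_d = mean(w$tajimas_d[is.finite(w$tajimas_d)]),
               n_windows = sum(is.finite(w$tajimas_d)))
  })
  do.call(rbind, rows)
}

# Filter configuration used for trend classification: quality masks only.
# The study-scale MAC >= 3 / MAF > 0.015 thresholds are not applied because
# at demonstration sample sizes they censor the rare tail of the frequency
# spectrum, which carries the S and Tajima's D signals.
trendFilterConfig <- function() {
  filterConfig(minMac = 0, maxMafExcluded = 0)
}

#' Simulate a scenario, apply artifacts, and classify the recovered trend
#'
#' End-to-end parameter-recovery run: forward-simulate a demographic
#' scenario, overlay archival artifacts, apply the quality filter chain
#' (depth and allele-balance masking, presence; minor-allele thresholds
#' off, see Details), compute per-period diversity, and classify the trend.
#'
#' @param scenario a \code{demographic_scenario} or a preset name
#'   ("stable", "expansion", "bottleneck")
#' @param model an \code{\link{artifactModel}}
#' @param seed master seed (overrides the scenario's)
#' @return list with \code{call} (the classification), \code{periods}
#'   (per-period diversity table), \code{truth}, \code{matrix}
#' @export
recoverScenario <- function(scenario, model = artifactModel(), seed = NULL) {
  if (is.character(scenario))
    scenario <- scenarioPreset(scenario,
                               seed = if (is.null(seed)) 1L else seed)
  else if (!is.null(seed)) scenario$seed <- as.integer(seed)
  truth <- simulateTemporalPopulation(scenario)
  gm <- applyArchivalArtifacts(truth, model)
  flt <- suppressWarnings(applySiteFilters(gm, trendFilterConfig()))
  totalSites <- nrow(gm)
  pd <- periodDiversity(flt$matrix, totalSites = totalSites,
                        locusLengths = setNames(
                          rep(scenario$locusLengthBp, scenario$nLoci),
                          sprintf("locus%04d", seq_len(scenario$nLoci))))
  ord <- match(scenario$samplingEpochs$label, pd$time_period)
  pd <- pd[ord[!is.na(ord)], ]
  cl <- classifyTrend(pd$pi, pd$theta_w, pd$tajimas_d)
  list(call = cl, periods = pd, truth = truth, matrix = flt$matrix)
}

#' Run the full analysis pipeline on a synthetic or supplied dataset
#'
#' Wires simulate -> filter -> diversity -> temporal inference -> scan.
#' Produces, for each of the six dataset tags ({all_reads, downsampled} x
#' {all_sites, coding, noncoding}), the filtered matrix and its filter
#' report; then per-period diversity, permutation subsampling with
#' ANOVA/Tukey across time periods, a trend call, and an Fst-outlier scan
#' of candidate (coding "immune-like") sites against the non-coding
#' baseline. A manifest records the seed, per-stage counts and tags;
#' re-running with the same configuration reproduces it exactly.
#'
#' @param scenario scenario preset name or \code{demographic_scenario}
#' @param model an \code{\link{artifactModel}}
#' @param config a \code{\link{filterConfig}} for the dataset products
#' @param seed master seed
#' @param reps,nMin permutation settings
#' @param downsampleTarget target mean depth for the downsampled tags
#' @param codingSpanBp centered coding span per locus
#' @param candidateLoci loci whose coding SNPs form the candidate set for
#'   the outlier scan (default: the first two loci)
#' @param outDir optional directory; when given, VCF/BED/metadata and all
#'   result tables are written there as plain text
#' @return list with \code{datasets}, \code{diversity}, \code{permutation},
#'   \code{anova}, \code{trend}, \code{scan}, \code{manifest}
#' @export
runPipeline <- function(scenario = "stable", model = artifactModel(),
                        config = filterConfig(), seed = 1L, reps = 20L,
                        nMin = 3L, downsampleTarget = 24,
                        codingSpanBp = 400L, candidateLoci = NULL,
                        outDir = NULL) {
  if (is.character(scenario)) scenario <- scenarioPreset(scenario, seed = seed)
  truth <- simulateTemporalPopulation(scenario)
  raw <- applyArchivalArtifacts(truth, model)
  locusMap <- centeredCodingMap(unique(siteInfo(raw)$locus),
                                scenario$locusLengthBp, codingSpanBp)

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    emitDataset(raw, file.path(outDir, "synthetic"),
                locusLengthBp = scenario$locusLengthBp,
                codingSpanBp = codingSpanBp)
  }

  buildTag <- function(m) {
    flt <- suppressWarnings(applySiteFilters(m, config))
    part <- partitionCodingNoncoding(flt$matrix, locusMap)
    list(all_sites = list(matrix = flt$matrix, report = flt$report),
         coding = list(matrix = part$coding, report = flt$report),
         noncoding = list(matrix = part$noncoding, report = flt$report))
  }
  datasets <- list()
  ar <- buildTag(raw)
  ds <- buildTag(downsampleDepth(raw, downsampleTarget,
                                 seed = subSeed(seed, "downsample")))
  for (nm in names(ar)) {
    datasets[[paste0("all_reads_", nm)]] <- ar[[nm]]
    datasets[[paste0("downsampled_", nm)]] <- ds[[nm]]
  }

  main <- datasets$all_reads_all_sites$matrix
  locusLengths <- setNames(rep(scenario$locusLengthBp, scenario$nLoci),
                           sprintf("locus%04d", seq_len(scenario$nLoci)))

  trendFlt <- suppressWarnings(applySiteFilters(raw, trendFilterConfig()))
  diversity <- periodDiversity(trendFlt$matrix, totalSites = nrow(raw),
                               locusLengths = locusLengths)
  ord <- match(scenario$samplingEpochs$label, diversity$time_period)
  diversity <- diversity[ord[!is.na(ord)], ]
  trend <- classifyTrend(diversity$pi, diversity$theta_w,
                         diversity$tajimas_d)

  md <- sampleData(main)
  perm <- list(); anv <- NULL
  if (nrow(main) > 0) {
    stat <- function(m) meanPi(m)$pi
    for (tp in unique(md$time_period)) {
      sel <- colnames(main)[md$time_period == tp]
      perm[[tp]] <- permuteSubsample(main, sel, stat, nMin = nMin,
                                     reps = reps,
                                     seed = subSeed(seed, "perm", tp),
                                     label = tp)
    }
    fullN <- vapply(perm, function(p) !p$skipped, logical(1))
    # ANOVA over the pooled permutation replicate values per period, as the
    # resampling design prescribes (pseudo-replication inherited knowingly)
    repAll <- do.call(rbind, lapply(names(perm)[fullN],
                                    function(tp) perm[[tp]]$replicates))
    if (length(unique(repAll$population)) >= 2)
      anv <- anovaTimePeriods(repAll$value, repAll$population)
  }

  scan <- NULL
  coding <- datasets$all_reads_coding$matrix
  noncoding <- datasets$all_reads_noncoding$matrix
  if (is.null(candidateLoci))
    candidateLoci <- utils::head(unique(siteInfo(raw)$locus), 2)
  pops <- setNames(md$time_period, colnames(main))
  candIdx <- siteInfo(coding)$locus %in% candidateLoci
  if (nrow(noncoding) >= 2 && any(candIdx) &&
      length(unique(pops)) >= 2) {
    base <- tryCatch(suppressWarnings(neutralBaseline(noncoding, pops)),
                     error = function(e) NULL)
    if (!is.null(base)) {
      candFst <- weirCockerhamFst(coding[candIdx, ], pops)$perSite
      scan <- fstOutliers(candFst, base)
    }
  }

  manifest <- list(
    seed = seed,
    scenario = list(nLoci = scenario$nLoci,
                    sitesPerLocus = scenario$sitesPerLocus,
                    epochs = scenario$samplingEpochs$label),
    tags = names(datasets),
    sites_raw = nrow(raw),
    sites_by_tag = vapply(datasets, function(d) nrow(d$matrix), integer(1)),
    samples = ncol(raw),
    missingness_raw = computeMissingness(raw),
    trend = trend$classification)

  if (!is.null(outDir)) {
    write.table(diversity, file.path(outDir, "diversity_by_period.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    for (tp in names(perm))
      if (!perm[[tp]]$skipped)
        write.table(perm[[tp]]$summary,
                    file.path(outDir, paste0("perm_", tp, ".tsv")),
                    sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(scan))
      write.table(scan, file.path(outDir, "fst_outliers.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(c(paste("seed:", seed),
                 paste("trend:", trend$classification),
                 paste("tags:", paste(names(datasets), collapse = ",")),
                 paste("sites_by_tag:",
                       paste(names(datasets),
                             vapply(datasets, function(d) nrow(d$matrix),
                                    integer(1)),
                             sep = "=", collapse = ","))),
               file.path(outDir, "manifest.txt"))
  }

  list(datasets = datasets, diversity = diversity, permutation = perm,
       anova = anv, trend = trend, scan = scan, manifest = manifest)
}
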