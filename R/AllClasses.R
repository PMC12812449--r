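#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData
#'   colData assayNames
NULL

#' GenotypeMatrix: samples x biallelic sites with depth and quality context
#'
#' The central container of the package: a
#' \linkS4class{SummarizedExperiment} whose rows are variant sites and whose
#' columns are samples. Assays:
#' \describe{
#'   \item{gt}{integer genotype codes: \code{NA} missing, 0/1/2 alt-allele
#'     dose of a diploid call, 4/5 half-calls carrying the REF/ALT allele.}
#'   \item{dp}{per-genotype read depth (DP), \code{NA} when absent.}
#'   \item{adRef, adAlt}{per-genotype allele depths (AD), \code{NA} when absent.}
#' }
#' \code{rowData} carries the site table (\code{locus}, 1-based \code{pos},
#' \code{ref}, \code{alt}, \code{qual}, \code{isIndel}); \code{colData}
#' carries sample metadata (typically \code{species}, \code{site},
#' \code{time_period}, \code{year}, \code{tissue}).
#'
#' @export
setClass("GenotypeMatrix", contains = "SummarizedExperiment")

setValidity("GenotypeMatrix", function(object) {
  msg <- character(0)
  an <- assayNames(object)
  if (!all(c("gt", "dp", "adRef", "adAlt") %in% an))
    msg <- c(msg, "assays 'gt', 'dp', 'adRef', 'adAlt' are required")
  rd <- rowData(object)
  need <- c("locus", "pos", "ref", "alt", "qual")
  if (!all(need %in% colnames(rd)))
    msg <- c(msg, sprintf("rowData must contain %s", paste(need, collapse = ", ")))
  if (length(msg)) return(msg)
  if (nrow(object) > 0) {
    key <- paste(rd$locus, rd$pos)
    if (anyDuplicated(key)) msg <- c(msg, "positions must be unique within a locus")
    same <- !is.na(rd$ref) & !is.na(rd$alt) & rd$ref == rd$alt
    if (any(same)) msg <- c(msg, "ref and alt alleles must differ")
    gt <- assay(object, "gt")
    ok <- is.na(gt) | gt %in% c(0L, 1L, 2L, GT_HALF_REF, GT_HALF_ALT)
    if (!all(ok)) msg <- c(msg, "gt codes must be NA, 0, 1, 2, 4 or 5")
    ad <- refDepths(object) + altDepths(object)
    dp <- depths(object)
    both <- !is.na(ad) & !is.na(dp)
    if (any(ad[both] > dp[both]))
      msg <- c(msg, "AD sums must not exceed DP where both are present")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypeMatrix
#'
#' @param gt integer matrix (sites x samples) of genotype codes; see
#'   \linkS4class{GenotypeMatrix} for the coding.
#' @param siteInfo data.frame with columns \code{locus}, \code{pos},
#'   \code{ref}, \code{alt}, \code{qual} and optionally \code{isIndel}.
#' @param dp,adRef,adAlt optional matrices of the same shape as \code{gt};
#'   missing values allowed. Defaults to all-\code{NA}.
#' @param sampleData optional data.frame of per-sample metadata; row order
#'   must match \code{colnames(gt)}.
#' @return a \linkS4class{GenotypeMatrix}
#' @examples
#' gt <- matrix(c(0L, 1L, 2L, 1L), nrow = 2,
#'              dimnames = list(NULL, c("s1", "s2")))
#' si <- data.frame(locus = "L1", pos = c(10L, 20L), ref = c("A", "C"),
#'                  alt = c("G", "T"), qual = 60)
#' GenotypeMatrix(gt, si)
#' @export
GenotypeMatrix <- function(gt, siteInfo, dp = NULL, adRef = NULL, adAlt = NULL,
                           sampleData = NULL) {
  gt <- as.matrix(gt)
  storage.mode(gt) <- "integer"
  if (is.null(colnames(gt)))
    colnames(gt) <- sprintf("sample%02d", seq_len(ncol(gt)))
  blank <- function(m) {
    if (is.null(m)) m <- matrix(NA_real_, nrow(gt), ncol(gt))
    m <- as.matrix(m); storage.mode(m) <- "double"
    dimnames(m) <- dimnames(gt); m
  }
  siteInfo <- as.data.frame(siteInfo)
  if (is.null(siteInfo$isIndel))
    siteInfo$isIndel <- nchar(siteInfo$ref) != 1L | nchar(siteInfo$alt) != 1L
  siteInfo$pos <- as.integer(siteInfo$pos)
  cd <- if (is.null(sampleData)) DataFrame(row.names = colnames(gt))
        else DataFrame(sampleData, row.names = colnames(gt))
  se <- SummarizedExperiment(
    assays = SimpleList(gt = gt, dp = blank(dp),
                        adRef = blank(adRef), adAlt = blank(adAlt)),
    rowData = DataFrame(siteInfo), colData = cd)
  new("GenotypeMatrix", se)
}

#' @describeIn GenotypeMatrix-accessors genotype code matrix (sites x samples)
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))
#' @describeIn GenotypeMatrix-accessors per-genotype depth matrix
#' @export
setGeneric("depths", function(x) standardGeneric("depths"))
#' @describeIn GenotypeMatrix-accessors reference-allele depth matrix
#' @export
setGeneric("refDepths", function(x) standardGeneric("refDepths"))
#' @describeIn GenotypeMatrix-accessors alternate-allele depth matrix
#' @export
setGeneric("altDepths", function(x) standardGeneric("altDepths"))
#' @describeIn GenotypeMatrix-accessors site table as a data.frame
#' @export
setGeneric("siteInfo", function(x) standardGeneric("siteInfo"))
#' @describeIn GenotypeMatrix-accessors sample metadata as a data.frame
#' @export
setGeneric("sampleData", function(x) standardGeneric("sampleData"))

#' Accessors for GenotypeMatrix
#'
#' @param x a \linkS4class{GenotypeMatrix}
#' @name GenotypeMatrix-accessors
NULL

#' @rdname GenotypeMatrix-accessors
#' @export
setMethod("genotypes", "GenotypeMatrix", function(x) assay(x, "gt"))
#' @rdname GenotypeMatrix-accessors
#' @export
setMethod("depths", "GenotypeMatrix", function(x) assay(x, "dp"))
#' @rdname GenotypeMatrix-accessors
#' @export
setMethod("refDepths", "GenotypeMatrix", function(x) assay(x, "adRef"))
#' @rdname GenotypeMatrix-accessors
#' @export
setMethod("altDepths", "GenotypeMatrix", function(x) assay(x, "adAlt"))
#' @rdname GenotypeMatrix-accessors
#' @export
setMethod("siteInfo", "GenotypeMatrix",
          function(x) as.data.frame(rowData(x)))
#' @rdname GenotypeMatrix-accessors
#' @export
setMethod("sampleData", "GenotypeMatrix",
          function(x) as.data.frame(colData(x)))

setMethod("show", "GenotypeMatrix", function(object) {
  cat(sprintf("GenotypeMatrix: %d sites x %d samples\n",
              nrow(object), ncol(object)))
  si <- siteInfo(object)
  if (nrow(object) > 0) {
    cat(sprintf("  loci: %d | indel records: %d | QUAL range: %s\n",
                length(unique(si$locus)), sum(si$isIndel),
                paste(signif(range(si$qual, na.rm = TRUE), 4), collapse = "-")))
    cat(sprintf("  missing genotype fraction: %.3f\n",
                computeMissingness(object)))
  }
  cd <- sampleData(object)
  if (ncol(cd) > 0)
    cat("  sample metadata:", paste(colnames(cd), collapse = ", "), "\n")
  invisible(object)
})
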