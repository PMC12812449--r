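#' @importFrom utils read.delim write.table
NULL

#' Write a GenotypeMatrix to a plain-text VCF 4.2 file
#'
#' Emits CHROM = locus id, 1-based POS, REF/ALT, QUAL and per-sample
#' GT:DP:AD. Half-calls are written as \code{./0}-style genotypes and
#' missing genotypes as \code{./.}. Writing then reading back reproduces the
#' matrix exactly.
#'
#' @param x a \linkS4class{GenotypeMatrix}
#' @param path output path (plain text)
#' @return \code{path}, invisibly
#' @export
writeGenotypeVcf <- function(x, path) {
  stopifnot(is(x, "GenotypeMatrix"))
  si <- siteInfo(x)
  gt <- genotypes(x); dp <- depths(x); adr <- refDepths(x); ada <- altDepths(x)
  gtStr <- matrix("./.", nrow(gt), ncol(gt))
  gtStr[which(gt == 0L)] <- "0/0"
  gtStr[which(gt == 1L)] <- "0/1"
  gtStr[which(gt == 2L)] <- "1/1"
  gtStr[which(gt == GT_HALF_REF)] <- "./0"
  gtStr[which(gt == GT_HALF_ALT)] <- "./1"
  fmt <- function(v) ifelse(is.na(v), ".", format(v, trim = TRUE,
                                                  scientific = FALSE))
  cells <- matrix(paste(gtStr, fmt(dp),
                        paste(fmt(adr), fmt(ada), sep = ","), sep = ":"),
                  nrow(gt), ncol(gt))
  header <- c("##fileformat=VCFv4.2",
    "##source=chronopop",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(x)), collapse = "\t"))
  body <- if (nrow(gt) > 0)
    paste(si$locus, si$pos, ".", si$ref, si$alt, fmt(si$qual), "PASS", ".",
          "GT:DP:AD",
          apply(cells, 1, paste, collapse = "\t"), sep = "\t")
  else character(0)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a VCF into a GenotypeMatrix
#'
#' Parses a VCF 4.x file (via \pkg{vcfR}) keeping GT, DP and AD. Records
#' lacking DP or AD get \code{NA} in those assays (downstream depth and
#' allele-balance filters then pass them with a warning flag in the filter
#' report). Half-calls and multiallelic records are preserved; for
#' multiallelic records any non-reference allele counts toward the alt dose
#' and the full comma-separated ALT string is retained so the biallelic
#' filter can act on it.
#'
#' @param path VCF path
#' @return a \linkS4class{GenotypeMatrix}
#' @export
readGenotypeVcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fixed <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fixed) == 0) stop("VCF contains no records: ", path)
  gtRaw <- vcfR::extract.gt(v, element = "GT")
  alleleDose <- function(a) {
    d <- rep(NA_integer_, length(a))
    d[a == "0"] <- 0L
    suppressWarnings(num <- as.integer(a))
    d[!is.na(num) & num >= 1L] <- 1L
    d
  }
  parseGT <- function(s) {
    s[s %in% c(".", "./.", ".|.", "")] <- NA_character_
    parts <- strsplit(s, "[/|]")
    a1 <- alleleDose(vapply(parts, function(p) if (length(p) >= 1) p[1] else
      NA_character_, character(1)))
    a2 <- alleleDose(vapply(parts, function(p) if (length(p) >= 2) p[2] else
      NA_character_, character(1)))
    out <- rep(NA_integer_, length(s))
    both <- !is.na(a1) & !is.na(a2)
    out[both] <- a1[both] + a2[both]
    half1 <- !is.na(a1) & !both & !is.na(s)
    out[half1] <- ifelse(a1[half1] == 0L, GT_HALF_REF, GT_HALF_ALT)
    half2 <- !is.na(a2) & is.na(a1)
    out[half2] <- ifelse(a2[half2] == 0L, GT_HALF_REF, GT_HALF_ALT)
    out
  }
  gt <- matrix(parseGT(as.vector(gtRaw)), nrow(gtRaw), ncol(gtRaw),
               dimnames = list(NULL, colnames(gtRaw)))
  hasDP <- "DP" %in% unlist(strsplit(unique(v@gt[, "FORMAT"]), ":"))
  hasAD <- "AD" %in% unlist(strsplit(unique(v@gt[, "FORMAT"]), ":"))
  dims <- dim(gt)
  dp <- if (hasDP)
    matrix(suppressWarnings(as.numeric(vcfR::extract.gt(v, "DP"))), dims[1])
  else NULL
  if (hasAD) {
    adStr <- vcfR::extract.gt(v, "AD")
    splitAD <- function(k) {
      out <- matrix(NA_real_, dims[1], dims[2])
      ok <- !is.na(adStr) & adStr != "."
      vals <- strsplit(adStr[ok], ",")
      out[ok] <- suppressWarnings(as.numeric(vapply(vals, function(p)
        if (length(p) >= k) p[k] else NA_character_, character(1))))
      out
    }
    adRef <- splitAD(1); adAlt <- splitAD(2)
  } else adRef <- adAlt <- NULL
  si <- data.frame(locus = fixed$CHROM, pos = as.integer(fixed$POS),
                   ref = fixed$REF, alt = fixed$ALT,
                   qual = suppressWarnings(as.numeric(fixed$QUAL)),
                   stringsAsFactors = FALSE)
  GenotypeMatrix(gt, si, dp = dp, adRef = adRef, adAlt = adAlt)
}

#' Write a locus coding map as BED3
#'
#' BED uses 0-based half-open intervals; a site with 1-based position p is
#' coding iff p-1 falls inside an interval.
#'
#' @param locusMap data.frame with columns \code{locus}, \code{start0},
#'   \code{end0} (0-based half-open) and optionally \code{length}.
#' @param path output path
#' @export
writeLocusBed <- function(locusMap, path) {
  stopifnot(all(c("locus", "start0", "end0") %in% colnames(locusMap)))
  keep <- locusMap$end0 > locusMap$start0
  write.table(locusMap[keep, c("locus", "start0", "end0")], path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED3 file into a locus coding map
#' @param path BED path
#' @return data.frame with \code{locus}, \code{start0}, \code{end0}
#' @export
readLocusBed <- function(path) {
  bed <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(bed) < 3) stop("malformed BED (need 3 columns): ", path)
  out <- data.frame(locus = as.character(bed[[1]]),
                    start0 = as.integer(bed[[2]]),
                    end0 = as.integer(bed[[3]]), stringsAsFactors = FALSE)
  if (any(out$end0 < out$start0)) stop("malformed BED interval in ", path)
  out
}

#' Centered coding span for each locus
#'
#' Places a coding interval of \code{codingSpanBp} centered within each
#' locus; the flanks are non-coding. For a 710 bp locus and a 400 bp span
#' the interval is [155, 555) in 0-based half-open coordinates.
#'
#' @param loci character vector of locus ids
#' @param locusLengthBp locus length
#' @param codingSpanBp width of the central coding interval (<= locus length)
#' @return data.frame usable as a locus map
#' @export
centeredCodingMap <- function(loci, locusLengthBp, codingSpanBp) {
  stopifnot(codingSpanBp >= 0, codingSpanBp <= locusLengthBp)
  s0 <- (locusLengthBp - codingSpanBp) %/% 2L
  data.frame(locus = loci, start0 = as.integer(s0),
             end0 = as.integer(s0 + codingSpanBp),
             length = as.integer(locusLengthBp), stringsAsFactors = FALSE)
}

#' Write sample metadata TSV
#' @param x a \linkS4class{GenotypeMatrix} whose colData carries metadata
#' @param path output path
#' @export
writeSampleMetadata <- function(x, path) {
  md <- sampleData(x)
  md <- data.frame(sample = colnames(x), md, stringsAsFactors = FALSE)
  write.table(md, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata TSV
#' @param path TSV with a \code{sample} column
#' @return data.frame keyed by sample id
#' @export
readSampleMetadata <- function(path) {
  md <- read.delim(path, stringsAsFactors = FALSE)
  if (!"sample" %in% colnames(md)) stop("metadata must have a 'sample' column")
  md
}

#' Emit a synthetic dataset as VCF + BED + metadata
#'
#' Writes the three files downstream stages consume:
#' \code{<prefix>.vcf} (GT:DP:AD), \code{<prefix>.bed} (a centered coding
#' span per locus, 0-based half-open) and \code{<prefix>_meta.tsv}. Reading
#' the VCF back reproduces the matrix exactly.
#'
#' @param x a \linkS4class{GenotypeMatrix}
#' @param outPrefix path prefix for the three files
#' @param locusLengthBp locus length used for the BED intervals
#' @param codingSpanBp centered coding span width (default 400)
#' @return named character vector of the written paths
#' @export
emitDataset <- function(x, outPrefix, locusLengthBp = 710L,
                        codingSpanBp = 400L) {
  if (nrow(x) == 0) stop("refusing to emit an empty matrix")
  loci <- unique(siteInfo(x)$locus)
  paths <- c(vcf = paste0(outPrefix, ".vcf"),
             bed = paste0(outPrefix, ".bed"),
             meta = paste0(outPrefix, "_meta.tsv"))
  writeGenotypeVcf(x, paths["vcf"])
  writeLocusBed(centeredCodingMap(loci, locusLengthBp, codingSpanBp),
                paths["bed"])
  writeSampleMetadata(x, paths["meta"])
  paths
}
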