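# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG state
#'
#' Runs \code{expr} with the RNG seeded at \code{seed} and restores the
#' caller's RNG state afterwards, so seeded operations do not perturb the
#' global stream.
#' @noRd
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

#' Derive a deterministic 31-bit substream seed from a master seed
#'
#' A small multiplicative hash keeps per-locus / per-sample / per-replicate
#' streams reproducible and independent of evaluation order.
#' @noRd
subSeed <- function(master, ...) {
  parts <- c(as.numeric(master), vapply(list(...), function(p) {
    if (is.character(p)) sum(utf8ToInt(p) * seq_along(utf8ToInt(p))) else as.numeric(p)
  }, numeric(1)))
  h <- 0
  for (p in parts) h <- (h * 69069 + (p %% 2147483647) + 1) %% 2147483647
  as.integer(h %% 2147483646L + 1L)
}

# Genotype codes: NA = missing, 0/1/2 = diploid alt-allele dose,
# 4 = haploid half-call carrying REF, 5 = haploid half-call carrying ALT.
GT_HALF_REF <- 4L
GT_HALF_ALT <- 5L

#' Called chromosomes per genotype code (2 diploid, 1 half-call, 0 missing)
#' @noRd
calledChrom <- function(gt) {
  out <- ifelse(is.na(gt), 0L, ifelse(gt >= 4L, 1L, 2L))
  storage.mode(out) <- "integer"
  out
}

#' Alt-allele copies per genotype code
#' @noRd
altCopies <- function(gt) {
  out <- ifelse(is.na(gt), 0L, ifelse(gt == GT_HALF_ALT, 1L,
                ifelse(gt == GT_HALF_REF, 0L, gt)))
  storage.mode(out) <- "integer"
  out
}

#' Is a genotype a called diploid heterozygote?
#' @noRd
isHet <- function(gt) !is.na(gt) & gt == 1L

#' Per-site called chromosome and alt-copy totals
#' @noRd
siteAlleleCounts <- function(gt) {
  list(nCalled = rowSums(calledChrom(gt)), nAlt = rowSums(altCopies(gt)))
}
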