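# Seeded synthetic-data generator emulating the shape of the two study
# datasets: case/control genotype tables over SNV sites, and pairs of
# VCF-subset files with partially overlapping positions.  Every dataset comes
# with ground truth computed by the independent plaintext oracles.

#' Synthetic case/control genotype data
#'
#' Genotypes are drawn per person and SNV as Binomial(2, p_j) counts of allele
#' A under Hardy-Weinberg equilibrium; the case group's allele frequency at
#' \code{assocIndex} is shifted by \code{delta} to plant an associated
#' variant.  Defaults mirror the study shape: 200 + 200 persons over 311 SNVs.
#'
#' @param nCase,nControl persons per group.
#' @param s number of SNV sites.
#' @param mafVector per-SNV allele-A frequency in (0, 1); default uniform on
#'   [0.05, 0.5].
#' @param assocIndex optional SNV index (1-based) carrying the association.
#' @param delta case-group frequency shift at \code{assocIndex}.
#' @param seed RNG seed (mandatory: generation is a reproducible protocol
#'   step).
#' @return list with \code{case} and \code{control}
#'   (\linkS4class{GenotypeMatrix}) and \code{truth} (exact per-SNV counts,
#'   MAFs and chi-square from the reference oracles).
#' @export
genCaseControl <- function(nCase = 200, nControl = 200, s = 311,
                           mafVector = NULL, assocIndex = NULL, delta = 0,
                           seed) {
  stopifnot(!missing(seed))
  set.seed(seed)
  p <- if (is.null(mafVector)) stats::runif(s, 0.05, 0.5) else mafVector
  stopifnot(length(p) == s, all(p > 0 & p < 1))
  pCase <- p
  if (!is.null(assocIndex)) {
    stopifnot(assocIndex >= 1, assocIndex <= s)
    pCase[assocIndex] <- p[assocIndex] + delta
    if (pCase[assocIndex] <= 0 || pCase[assocIndex] >= 1) {
      stop("spec error: shifted frequency outside (0, 1)")
    }
  }
  draw <- function(N, pv) {
    matrix(stats::rbinom(N * s, 2, rep(pv, each = N)), nrow = N)
  }
  case <- genotypeMatrix(draw(nCase, pCase), "case")
  control <- genotypeMatrix(draw(nControl, p), "control")
  nA <- colSums(case@codes)
  nAp <- colSums(control@codes)
  truth <- list(
    nA_case = nA, nA_control = nAp,
    maf_case = vapply(seq_len(s), function(j) mafRef(case@codes[, j]), 0),
    maf_control = vapply(seq_len(s), function(j) mafRef(control@codes[, j]), 0),
    chi2 = vapply(seq_len(s), function(j) {
      suppressWarnings(
        chi2TableRef(nA[j], 2 * nCase - nA[j], nAp[j], 2 * nControl - nAp[j])
      )
    }, 0)
  )
  list(case = case, control = control, truth = truth)
}

randAlt <- function(len) paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = "")

# one variant record given (or choosing) a reference string
randRecord <- function(svProbs, maxAltLen, ref = NULL) {
  if (is.null(ref)) {
    sv <- sample(names(svProbs), 1, prob = svProbs)
    ref <- switch(sv,
      SUB = randAlt(sample(seq_len(maxAltLen), 1)),
      INS = randAlt(1),
      DEL = randAlt(sample(2:maxAltLen, 1))
    )
  } else {
    ok <- if (nchar(ref) == 1) c("SUB", "INS") else c("SUB", "DEL")
    pr <- svProbs[ok]
    sv <- sample(ok, 1, prob = pr / sum(pr))
  }
  alt <- switch(sv,
    SUB = {
      a <- randAlt(nchar(ref))
      while (a == ref) a <- randAlt(nchar(ref))
      a
    },
    INS = paste0(ref, randAlt(sample(seq_len(maxAltLen - nchar(ref)), 1))),
    DEL = substr(ref, 1, 1)
  )
  list(sv = sv, ref = ref, alt = alt)
}

#' Synthetic pair of VCF-subset variant tables
#'
#' Generates \code{nSites} merged positions; each is shared by both
#' participants with probability \code{pShared} (both records drawn over a
#' common reference string, identical with probability \code{pIdentical}),
#' otherwise one-sided.  Alternate strings are capped at 7 bases so they fit
#' the 15-bit encoding.
#'
#' @param nSites number of merged positions.
#' @param pShared probability a position appears in both files.
#' @param pIdentical probability a shared position carries identical records.
#' @param svProbs named probabilities over c(SUB, INS, DEL).
#' @param maxAltLen maximal alternate length (<= 7).
#' @param chrom chromosome label.
#' @param seed RNG seed (mandatory).
#' @return list with \code{a}, \code{b} (GRanges), \code{merged}, and
#'   \code{truth} (hamming, edit, overlap, nSites) from the reference
#'   algorithms.
#' @export
genVcfPair <- function(nSites = 50, pShared = 0.5, pIdentical = 0.3,
                       svProbs = c(SUB = 0.6, INS = 0.2, DEL = 0.2),
                       maxAltLen = 7, chrom = "1", seed) {
  stopifnot(!missing(seed), maxAltLen <= 7, abs(sum(svProbs) - 1) < 1e-9)
  set.seed(seed)
  pos <- sort(sample.int(nSites * 100, nSites))
  rowsA <- list()
  rowsB <- list()
  overlap <- 0L
  for (i in seq_len(nSites)) {
    shared <- stats::runif(1) < pShared
    if (shared) {
      overlap <- overlap + 1L
      rx <- randRecord(svProbs, maxAltLen)
      ry <- if (stats::runif(1) < pIdentical) {
        rx
      } else {
        randRecord(svProbs, maxAltLen, ref = rx$ref)
      }
      rowsA[[length(rowsA) + 1]] <- c(pos = pos[i], rx)
      rowsB[[length(rowsB) + 1]] <- c(pos = pos[i], ry)
    } else {
      r <- randRecord(svProbs, maxAltLen)
      if (stats::runif(1) < 0.5) {
        rowsA[[length(rowsA) + 1]] <- c(pos = pos[i], r)
      } else {
        rowsB[[length(rowsB) + 1]] <- c(pos = pos[i], r)
      }
    }
  }
  toFrame <- function(rows) {
    data.frame(
      chrom = chrom,
      pos = vapply(rows, function(r) r$pos, 0),
      sv = vapply(rows, function(r) r$sv, ""),
      ref = vapply(rows, function(r) r$ref, ""),
      alt = vapply(rows, function(r) r$alt, ""),
      stringsAsFactors = FALSE
    )
  }
  dfA <- toFrame(rowsA)
  dfB <- toFrame(rowsB)
  merged <- mergeSites(dfA, dfB)
  list(
    a = variantGRanges(dfA), b = variantGRanges(dfB), merged = merged,
    truth = list(
      hamming = hammingRef(merged), edit = editRef(merged),
      overlap = overlap, nSites = nSites
    )
  )
}

variantGRanges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$pos, width = nchar(df$ref)),
    sv = df$sv, ref = df$ref, alt = df$alt
  )
}
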