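# Plaintext reference implementations (ground truth): the Hamming and
# approximate-edit-distance algorithms over merged variant lists, the allelic
# contingency-table chi-square, and the minor allele frequency.  These are
# pure, integer/rational-exact, and deliberately independent of the encodings
# and circuits they validate.

# A merged list is a data.frame with one row per (chrom, pos) in the union of
# the two variant sets and columns x_present, x_sv, x_ref, x_alt (and the y_
# counterparts); an absent side has present = FALSE and empty strings.

#' Reference Hamming distance over a merged variant list
#'
#' Per site: 0 when either present record is an insertion or deletion
#' (this branch is tested first and wins even when the other side is absent);
#' otherwise 1 when one side is absent or the records share the reference but
#' differ in the alternate; otherwise 0.
#'
#' @param merged a merged list from \code{\link{mergeSites}}.
#' @return integer total distance.
#' @export
hammingRef <- function(merged) {
  h <- 0L
  for (i in seq_len(nrow(merged))) {
    r <- merged[i, ]
    svs <- c(if (r$x_present) r$x_sv, if (r$y_present) r$y_sv)
    if (any(svs %in% c("INS", "DEL"))) {
      hi <- 0L
    } else if (!r$x_present || !r$y_present ||
      (r$x_ref == r$y_ref && r$x_alt != r$y_alt)) {
      hi <- 1L
    } else {
      hi <- 0L
    }
    h <- h + hi
  }
  h
}

# genotype length: 0 for an absent side, len(ref) for a deletion, len(alt)
# otherwise
refLengthD <- function(present, sv, ref, alt) {
  if (!present) return(0L)
  if (sv == "DEL") nchar(ref) else nchar(alt)
}

#' Reference approximate edit distance over a merged variant list
#'
#' Per site: 0 when both records exist and agree in ref and alt, else
#' max(D(x), D(y)) where D is 0 for an absent side, the reference length for a
#' deletion and the alternate length otherwise.
#'
#' @inheritParams hammingRef
#' @return integer total distance.
#' @export
editRef <- function(merged) {
  e <- 0L
  for (i in seq_len(nrow(merged))) {
    r <- merged[i, ]
    Dx <- refLengthD(r$x_present, r$x_sv, r$x_ref, r$x_alt)
    Dy <- refLengthD(r$y_present, r$y_sv, r$y_ref, r$y_alt)
    same <- r$x_present && r$y_present &&
      r$x_ref == r$y_ref && r$x_alt == r$y_alt
    e <- e + if (same) 0L else max(Dx, Dy)
  }
  e
}

#' Allelic chi-square statistic from the 2x2 contingency table
#'
#' T * (nA*nB' - nB*nA')^2 / (R*S*G*K) with margins R = S = 2N, G = nA + nA',
#' K = nB + nB', T = 4N.
#'
#' @param nA,nB case-group allele counts (nA + nB = 2N).
#' @param nAp,nBp control-group allele counts.
#' @param frac return the exact fraction c(numerator, denominator) instead of
#'   a double.
#' @return chi-square value (NaN with a warning when a column margin is zero).
#' @export
chi2TableRef <- function(nA, nB, nAp, nBp, frac = FALSE) {
  R <- nA + nB
  S <- nAp + nBp
  if (R != S) stop("groups must have equal allele totals")
  G <- nA + nAp
  K <- nB + nBp
  Tt <- R + S
  if (G == 0 || K == 0) {
    warning("undefined statistic: monomorphic site (zero column margin)")
    return(if (frac) c(NaN, NaN) else NaN)
  }
  num <- Tt * (nA * nBp - nB * nAp)^2
  den <- R * S * G * K
  if (frac) c(num, den) else num / den
}

#' Reference minor allele frequency of a genotype column
#'
#' nA = 2*nAA + nAB, nB = 2*nBB + nAB; MAF = min(nA, nB) / (nA + nB).
#'
#' @param column genotype strings in \{AA, AB, BB\} or integer codes in
#'   \{0, 1, 2\} (the A-allele count).
#' @return frequency in [0, 0.5].
#' @export
mafRef <- function(column) {
  codes <- if (is.character(column)) {
    vapply(column, encodeGenotype, 0)
  } else {
    stopifnot(all(column %in% 0:2))
    column
  }
  N <- length(codes)
  nA <- sum(codes)
  nB <- 2 * N - nA
  stopifnot(nA + nB == 2 * N)
  min(nA, nB) / (2 * N)
}
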