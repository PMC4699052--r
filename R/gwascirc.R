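# Task 1: homomorphic minor-allele-frequency and allelic chi-square pipelines,
# in the slot-packing (leveled scheme) and coefficient-packing (scale-invariant
# scheme) styles, plus the closed-form statistics.  Only additions are needed
# homomorphically; the divisions and minima of the statistics happen after
# decryption.

#' Pack one person's genotype codes into plaintext slots
#'
#' Slot j holds the person's code at SNV j; remaining slots are zero.
#'
#' @param personCodes integer vector of codes in \{0,1,2\}, length s <= ell.
#' @param layout a \linkS4class{SlotLayout}.
#' @return plaintext \linkS4class{RingElement} mod t.
#' @export
packSlots <- function(personCodes, layout) {
  if (length(personCodes) > layout@ell) {
    stop("capacity error: more SNVs than slots (block-partition the sites)")
  }
  crtPack(personCodes, layout)
}

#' Pack a genotype group into coefficient-packed plaintext polynomials
#'
#' Person i within a block of n' = floor(n/s) persons occupies coefficients
#' [i*s, (i+1)*s); ceiling(N/n') polynomials are produced.  Coefficient
#' packing supports homomorphic addition only, which is all the
#' case-control statistics need.
#'
#' @param group a \linkS4class{GenotypeMatrix} or codes matrix (persons x SNVs).
#' @param n ring degree.
#' @return list with \code{polys} (list of coefficient vectors of length n),
#'   \code{nPrime} (persons per polynomial) and \code{s}.
#' @export
packCoeffs <- function(group, n) {
  m <- if (is(group, "GenotypeMatrix")) group@codes else group
  s <- ncol(m)
  if (s > n) stop("error: more SNVs than ring coefficients")
  nPrime <- n %/% s
  N <- nrow(m)
  nPolys <- ceiling(N / nPrime)
  polys <- vector("list", nPolys)
  for (b in seq_len(nPolys)) {
    v <- numeric(n)
    persons <- ((b - 1) * nPrime + 1):min(b * nPrime, N)
    for (k in seq_along(persons)) {
      v[((k - 1) * s + 1):(k * s)] <- m[persons[k], ]
    }
    polys[[b]] <- v
  }
  list(polys = polys, nPrime = nPrime, s = s)
}

#' Homomorphic sum of a list of ciphertexts
#'
#' @param cts non-empty list of ciphertexts of one scheme.
#' @param params the scheme's parameters.
#' @return a ciphertext decrypting to the sum.
#' @export
heSum <- function(cts, params) {
  if (length(cts) == 0) stop("error: empty ciphertext list")
  cls <- class(cts[[1]])
  if (!all(vapply(cts, function(x) is(x, cls), TRUE))) {
    stop("error: mixed ciphertext types")
  }
  acc <- cts[[1]]
  addf <- if (is(acc, "BGVCiphertext")) bgvAdd else yasheAdd
  for (i in seq_along(cts)[-1]) acc <- addf(acc, cts[[i]], params)
  acc
}

#' Decode per-SNV counts from a decrypted plaintext
#'
#' Slots variant: the first s slot constants of the decrypted element.
#' Coefficients variant: m_j = sum_{i=0}^{n'-1} m_{j + i*s} (the identity when
#' n' = 1).
#'
#' @param msg decrypted plaintext (\linkS4class{RingElement} mod t).
#' @param layout slot layout used to pack.
#' @param s number of SNVs.
#' @return numeric vector of s counts (residues mod t; see
#'   \code{\link{decodeSigned}} for signed quantities).
#' @export
decodeCountsSlots <- function(msg, layout, s) {
  crtUnpack(msg, layout)[seq_len(s)]
}

#' @param nPrime persons per polynomial used when packing.
#' @rdname decodeCountsSlots
#' @export
decodeCountsCoeffs <- function(msg, s, nPrime) {
  v <- if (is(msg, "RingElement")) coeffs(msg) %% msgModulus(msg) else msg
  if (nPrime == 1) return(v[seq_len(s)])
  idx <- matrix(v[seq_len(s * nPrime)], nrow = s)
  rowSums(idx)
}

msgModulus <- function(msg) {
  t <- bigAsNumeric(msg@q)
  stopifnot(!is.na(t))
  t
}

#' Minor allele frequency from an aggregated count
#'
#' min(m_j, 2N - m_j) / (2N); the minimum is taken after decryption.
#'
#' @param mj allele-A count(s) at the SNV (0 <= mj <= 2N).
#' @param N persons in the group.
#' @return frequency in [0, 0.5].
#' @export
maf <- function(mj, N) {
  if (any(mj < 0 | mj > 2 * N)) stop("error: count out of range [0, 2N]")
  pmin(mj, 2 * N - mj) / (2 * N)
}

#' Sum and difference ciphertexts for the chi-square statistic
#'
#' ct+ = ct_case + ct_control, ct- = ct_case - ct_control.
#'
#' @param ctCase,ctCont group-aggregate ciphertexts of one scheme.
#' @param params scheme parameters.
#' @return list(plus, minus).
#' @export
chi2Pair <- function(ctCase, ctCont, params) {
  if (is(ctCase, "BGVCiphertext")) {
    list(
      plus = bgvAdd(ctCase, ctCont, params),
      minus = bgvSub(ctCase, ctCont, params)
    )
  } else {
    list(
      plus = yasheAdd(ctCase, ctCont, params),
      minus = yasheSub(ctCase, ctCont, params)
    )
  }
}

#' Signed decoding of a mod-t residue
#'
#' Values larger than t/2 represent negatives: v - t.  The boundary v = t/2
#' decodes to +t/2 (unreachable when the no-wraparound validation holds).
#'
#' @param v residue(s) in [0, t).
#' @param t plaintext modulus.
#' @return centered integer(s).
#' @examples
#' decodeSigned(1000, 1024) # -24
#' @export
decodeSigned <- function(v, t) {
  if (any(v < 0 | v >= t)) stop("residue out of [0, t)")
  ifelse(v > t / 2, v - t, v)
}

#' Allelic chi-square from the sum/difference form
#'
#' 4N * diff^2 / (sum * (4N - sum)), the simplified closed form of the
#' contingency-table statistic in terms of sum = nA + nA' and
#' diff = nA - nA'.  Monomorphic sites (sum 0 or 4N) yield NaN with a warning.
#'
#' @param sum,diff per-SNV aggregate sum and difference of A-allele counts.
#' @param N persons per group.
#' @param frac return exact c(numerator, denominator) instead (scalar input
#'   only).
#' @return chi-square value(s).
#' @export
chi2 <- function(sum, diff, N, frac = FALSE) {
  if (frac) {
    stopifnot(length(sum) == 1)
    if (sum <= 0 || sum >= 4 * N) {
      warning("undefined statistic: monomorphic site")
      return(c(NaN, NaN))
    }
    return(c(4 * N * diff^2, sum * (4 * N - sum)))
  }
  bad <- sum <= 0 | sum >= 4 * N
  if (any(bad)) warning("undefined statistic: monomorphic site(s) yield NaN")
  out <- rep(NaN, length(sum))
  ok <- !bad
  out[ok] <- 4 * N * diff[ok]^2 / (sum[ok] * (4 * N - sum[ok]))
  out
}

# ---- end-to-end pipelines ----

#' Secure case-control GWAS, end to end
#'
#' Encrypts each person's genotype vector (slot packing under the leveled
#' scheme; coefficient packing under the scale-invariant scheme), aggregates
#' homomorphically, forms the sum/difference ciphertexts, decrypts, decodes,
#' and computes MAFs and the allelic chi-square per SNV.  Refuses to run when
#' the aggregate bound 4N >= t could wrap the plaintext space.
#'
#' @param case,control \linkS4class{GenotypeMatrix} objects with equal SNV
#'   count and person count.
#' @param scheme "bgv" or "yashe".
#' @param params,keys,layout optional scheme objects; demonstration-scale
#'   defaults are generated when missing (layout only used by the bgv scheme).
#' @return data.frame: snv, nA_case, nA_control, maf_case, maf_control, chi2.
#' @export
secureGwas <- function(case, control, scheme = c("bgv", "yashe"),
                       params = NULL, keys = NULL, layout = NULL) {
  scheme <- match.arg(scheme)
  stopifnot(nSnvs(case) == nSnvs(control), nPersons(case) == nPersons(control))
  N <- nPersons(case)
  s <- nSnvs(case)
  if (is.null(params)) {
    if (scheme == "bgv") {
      params <- bgvParams(255, plaintextModulusFor(N, "chi2"), 3L)
    } else {
      params <- yasheParamsGen(20, 0, plaintextModulusFor(N, "chi2"),
        max(64, 2^ceiling(log2(s))),
        addBudget = 4 * N
      )
    }
  }
  t <- params@ring@t
  if (4 * N >= t) {
    stop(sprintf(
      "no-wraparound validation failed: 4N = %d must be < t = %s",
      4 * N, format(t)
    ))
  }
  if (is.null(keys)) {
    keys <- if (scheme == "bgv") bgvKeyGen(params) else yasheKeyGen(params)
  }
  if (scheme == "bgv") {
    if (is.null(layout)) layout <- slotLayout(params@ring@m, t)
    res <- gwasBgv(case, control, keys, params, layout, N, s)
  } else {
    res <- gwasYashe(case, control, keys, params, N, s)
  }
  data.frame(
    snv = seq_len(s),
    nA_case = res$nCase, nA_control = res$nCont,
    maf_case = maf(res$nCase, N), maf_control = maf(res$nCont, N),
    chi2 = suppressWarnings(chi2(res$nCase + res$nCont, res$nCase - res$nCont, N))
  )
}

gwasBgv <- function(case, control, keys, params, layout, N, s) {
  ell <- layout@ell
  blocks <- blockIndices(s, ell)
  nCase <- numeric(0)
  nCont <- numeric(0)
  t <- params@ring@t
  for (idx in blocks) {
    encGroup <- function(gm) {
      cts <- lapply(seq_len(N), function(i) {
        bgvEncrypt(packSlots(gm@codes[i, idx], layout), keys, params)
      })
      heSum(cts, params)
    }
    ctCase <- encGroup(case)
    ctCont <- encGroup(control)
    # one modulus switch after the aggregation (L = 1 + 2 chain accounting)
    ctCase <- bgvModSwitch(ctCase, params@L - 2L, params)
    ctCont <- bgvModSwitch(ctCont, params@L - 2L, params)
    pair <- chi2Pair(ctCase, ctCont, params)
    mCase <- decodeCountsSlots(bgvDecrypt(ctCase, keys, params), layout, length(idx))
    mCont <- decodeCountsSlots(bgvDecrypt(ctCont, keys, params), layout, length(idx))
    mPlus <- decodeCountsSlots(bgvDecrypt(pair$plus, keys, params), layout, length(idx))
    mMinus <- decodeSigned(
      decodeCountsSlots(bgvDecrypt(pair$minus, keys, params), layout, length(idx)), t
    )
    # consistency of the homomorphic sum/difference with the group decryptions
    stopifnot(all(mPlus == mCase + mCont), all(mMinus == mCase - mCont))
    nCase <- c(nCase, mCase)
    nCont <- c(nCont, mCont)
  }
  list(nCase = nCase, nCont = nCont)
}

gwasYashe <- function(case, control, keys, params, N, s) {
  n <- params@ring@n
  t <- params@ring@t
  encGroup <- function(gm) {
    pk <- packCoeffs(gm, n)
    cts <- lapply(pk$polys, function(v) yasheEncrypt(v, keys, params))
    list(ct = heSum(cts, params), nPrime = pk$nPrime)
  }
  gc1 <- encGroup(case)
  gc2 <- encGroup(control)
  pair <- chi2Pair(gc1$ct, gc2$ct, params)
  mCase <- decodeCountsCoeffs(yasheDecrypt(gc1$ct, keys, params), s, gc1$nPrime)
  mCont <- decodeCountsCoeffs(yasheDecrypt(gc2$ct, keys, params), s, gc2$nPrime)
  # the difference polynomial's coefficients are signed residues: decode each
  # before the block aggregation
  mv <- coeffs(yasheDecrypt(pair$minus, keys, params)) %% t
  mvs <- decodeSigned(mv, t)
  mMinus <- decodeCountsCoeffs(mvs, s, gc1$nPrime)
  pv <- coeffs(yasheDecrypt(pair$plus, keys, params)) %% t
  mPlus <- decodeCountsCoeffs(pv, s, gc1$nPrime)
  stopifnot(all(mPlus == mCase + mCont), all(mMinus == mCase - mCont))
  list(nCase = mCase, nCont = mCont)
}
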