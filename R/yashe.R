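# Scale-invariant scheme (YASHE style) over R_q = Z_q[x]/(x^n + 1), q prime.
#
# Ciphertexts are single ring elements; Dec(ct) = round(t/q * [f*ct]_q) mod t.
# Multiplication computes the integer product of the two ciphertexts, scales
# by t/q with rounding, and key-switches with a word-decomposition evaluation
# key (gamma_i = f*omega^i + e_i + hpub*s_i).

#' Required modulus size for M multiplicative levels
#'
#' The worst-case inherent-noise bound after M levels,
#' (n*t)^{2(M-1)} * 12 n^2 t sigma l_w w, must stay below q/t; this returns
#' the minimal log2(q).  l_w depends on q itself, so the estimate is iterated
#' to a fixpoint (two rounds suffice).  For M = 0 only the fresh noise and an
#' addition budget constrain q.
#'
#' @param M multiplicative levels.
#' @param n ring degree.
#' @param t plaintext modulus.
#' @param sigma error standard deviation.
#' @param omega decomposition word (number or decimal string).
#' @param addBudget additions of fresh ciphertexts to absorb (M = 0 case and
#'   slack otherwise).
#' @return minimal log2(q) (numeric).
#' @export
yasheLogqBound <- function(M, n, t, sigma = 8, omega = bigPow2(128),
                           addBudget = 64) {
  B <- 6 * sigma
  freshLog2 <- log2(n) + log2(t) + log2(t / 2 + 2 * B + 2)
  if (M == 0) {
    return(freshLog2 + log2(t) + log2(addBudget) + 2)
  }
  logw <- bigLog2(bigstr(omega))
  lq <- 2 * M * log2(n * t) # lower bound without the key-switch term
  for (iter in 1:2) {
    lw <- floor(lq / logw) + 1
    lq <- 2 * (M - 1) * log2(n * t) +
      log2(12 * sigma * lw) + 2 * log2(n) + log2(t) + logw + log2(t)
  }
  max(lq, 2 * M * log2(n * t))
}

#' Construct parameters for the scale-invariant scheme
#'
#' m = 2n is a power of two; q is the smallest prime with q = 1 (mod m) whose
#' size meets the noise bound for M levels (the maximal-q security side is not
#' modelled here, so the ring degree n is supplied by the caller).
#'
#' @param lambda nominal security parameter (recorded).
#' @param M multiplicative levels the parameters must support.
#' @param t plaintext modulus.
#' @param n ring degree (power of two).
#' @param sigma error standard deviation (B = 6*sigma).
#' @param omega decomposition word; default 2^128, but toy moduli need a
#'   smaller word so that l_w >= 2.
#' @param addBudget addition slack, see \code{\link{yasheLogqBound}}.
#' @param marginBits extra modulus bits beyond the bound.
#' @return a \linkS4class{YASHEParams}.
#' @export
yasheParamsGen <- function(lambda, M, t, n, sigma = 8, omega = NULL,
                           addBudget = 64, marginBits = 10) {
  if (!isPowerOfTwo(n)) stop("n must be a power of two")
  M <- as.integer(M)
  if (M < 0) stop("M must be >= 0")
  m <- 2L * as.integer(n)
  if (is.null(omega)) {
    lqGuess <- yasheLogqBound(M, n, t, sigma, bigPow2(128), addBudget)
    omega <- if (lqGuess > 160) bigPow2(128) else bigPow2(max(8, ceiling(lqGuess / 4)))
  }
  omega <- bigstr(omega)
  lq <- ceiling(yasheLogqBound(M, n, t, sigma, omega, addBudget)) + marginBits
  q <- gs_next_prime_cong(bigPow2(lq), m, 1)
  lw <- as.integer(floor(bigLog2(q) / bigLog2(omega)) + 1)
  ring <- ringParams(m, q, t)
  new("YASHEParams",
    ring = ring, sigma = sigma, B = 6 * sigma, omega = omega, lw = lw,
    M = M, lambda = as.numeric(lambda)
  )
}

setMethod("show", "YASHEParams", function(object) {
  cat(sprintf(
    "YASHEParams: n = %d, t = %s, log2(q) ~ %.1f (prime, q = 1 mod %d), M = %d, l_w = %d\n",
    object@ring@n, format(object@ring@t), bigLog2(object@ring@q),
    object@ring@m, object@M, object@lw
  ))
})

#' @rdname nSlots
#' @export
setMethod("nSlots", "YASHEParams", function(x) {
  p <- plaintextBase(x@ring@t)$p
  as.integer(x@ring@n / multOrderSmall(p %% x@ring@m, x@ring@m))
})

#' @rdname level
#' @export
setMethod("level", "YASHECiphertext", function(x) x@depth)

setMethod("show", "YASHECiphertext", function(object) {
  cat(sprintf(
    "YASHECiphertext: depth %d, log2(q) ~ %.1f, est. noise ~ 2^%.1f\n",
    object@depth, bigLog2(object@c@q), object@noiseLog2
  ))
})

setMethod("show", "YASHEKeys", function(object) {
  cat(sprintf(
    "YASHEKeys: f = t*f' + 1 (ternary f'), evk with %d words\n",
    length(object@evk)
  ))
})

yasheGaussian <- function(params) {
  prof <- noiseProfile(sigma = params@sigma, B = ceiling(params@B), h = 0L)
  sampleGaussian(params@ring@n, prof, params@ring@q, params@ring@m)
}

#' Key generation for the scale-invariant scheme
#'
#' f = [t*f' + 1]_q with dense ternary f'; if f is not invertible in R_q a new
#' f' is drawn (up to 32 attempts).  The public key is hpub = [t*g*f^{-1}]_q,
#' and for M >= 1 the evaluation key is gamma_i = [f*omega^i + e_i + hpub*s_i]_q
#' for i = 0..l_w - 1.
#'
#' @param params a \linkS4class{YASHEParams}.
#' @return a \linkS4class{YASHEKeys}.
#' @export
yasheKeyGen <- function(params) {
  ring <- params@ring
  q <- ring@q
  n <- ring@n
  f <- NULL
  for (attempt in 1:32) {
    fp <- sampleTernaryDense(n, q, ring@m)
    cand <- ringAdd(ringScalMul(fp, ring@t), ringElement(1, q = q, m = ring@m))
    iv <- gs_poly_inv_negacyclic(cand@coeffs, q)
    if (isTRUE(iv$ok)) {
      f <- cand
      finv <- new("RingElement", coeffs = as.character(iv$inv), q = q, m = ring@m)
      break
    }
  }
  if (is.null(f)) stop("keygen failure: f not invertible after 32 attempts")
  g <- sampleTernaryDense(n, q, ring@m)
  hpub <- ringScalMul(ringMul(g, finv, ring), ring@t)
  evk <- list()
  if (params@M >= 1) {
    wpow <- "1"
    for (i in seq_len(params@lw)) {
      e <- yasheGaussian(params)
      s <- yasheGaussian(params)
      gam <- ringAdd(
        ringAdd(ringScalMul(f, wpow), e),
        ringMul(hpub, s, ring)
      )
      evk[[i]] <- gam
      wpow <- gs_big_mul(wpow, params@omega)
    }
  }
  new("YASHEKeys", f = f, finv = finv, hpub = hpub, evk = evk)
}

#' Encrypt a plaintext ring element
#'
#' Enc(m) = [floor(q/t) * [m]_t + e + hpub*s]_q with Gaussian e, s.
#'
#' @param msg plaintext \linkS4class{RingElement} mod t or numeric vector.
#' @param pk public key element hpub (a YASHEKeys is also accepted).
#' @param params a \linkS4class{YASHEParams}.
#' @return a \linkS4class{YASHECiphertext}.
#' @export
yasheEncrypt <- function(msg, pk, params) {
  if (is(pk, "YASHEKeys")) pk <- pk@hpub
  ring <- params@ring
  delta <- gs_big_divmod(ring@q, bigstr(ring@t))$q
  mEl <- asPlaintext(msg, ring)
  e <- yasheGaussian(params)
  s <- yasheGaussian(params)
  c <- ringAdd(
    ringAdd(ringScalMul(ringLift(mEl, ring@q), delta), e),
    ringMul(pk, s, ring)
  )
  fresh <- log2(ring@n) + log2(ring@t) + log2(ring@t / 2 + 2 * params@B + 2)
  new("YASHECiphertext", c = c, depth = 0L, noiseLog2 = fresh)
}

#' Measured inherent noise
#'
#' The inherent noise is the v with f*ct = floor(q/t)*[m]_t + v (mod q); it is
#' measured here by decrypting and subtracting.  Decryption stays correct
#' while the infinity norm is below about q/(2t).
#'
#' @param ct a \linkS4class{YASHECiphertext}.
#' @param keys a \linkS4class{YASHEKeys}.
#' @param params a \linkS4class{YASHEParams}.
#' @return list(noise element, linf string, failed flag at the q/(4t) safety
#'   threshold).
#' @export
yasheNoise <- function(ct, keys, params) {
  ring <- params@ring
  q <- ring@q
  fc <- ringMul(keys@f, ct@c, ring)
  msgv <- gs_yashe_round_dec(fc@coeffs, q, ring@t)
  delta <- gs_big_divmod(q, bigstr(ring@t))$q
  mC <- ringElement(msgv, q = ring@t, m = ring@m) # centered [m]_t
  v <- ringSub(fc, ringScalMul(ringLift(mC, q), delta))
  linf <- ringLinf(v)
  thresh <- gs_big_divmod(q, bigstr(4 * ring@t))$q
  list(noise = v, linf = linf, failed = gs_big_cmp(linf, thresh) >= 0)
}

#' Decrypt a ciphertext
#'
#' Dec(ct, sk) = round(t/q * [f*ct]_q) mod t, coefficientwise, with rounding
#' half away from zero.  Signals a \code{genoSHE_decryption_failure} warning
#' when the measured inherent noise reaches q/(4t).
#'
#' @inheritParams yasheNoise
#' @param withNoise also return the measured noise.
#' @return plaintext \linkS4class{RingElement} mod t (or a list).
#' @export
yasheDecrypt <- function(ct, keys, params, withNoise = FALSE) {
  ring <- params@ring
  fc <- ringMul(keys@f, ct@c, ring)
  msgv <- gs_yashe_round_dec(fc@coeffs, ring@q, ring@t)
  msg <- ringElement(msgv, q = ring@t, m = ring@m)
  nz <- yasheNoise(ct, keys, params)
  if (nz$failed) {
    warning(warningCondition(
      "measured inherent noise reached q/(4t): result unreliable",
      class = "genoSHE_decryption_failure"
    ))
  }
  if (withNoise) list(msg = msg, linf = nz$linf, failed = nz$failed) else msg
}

#' Homomorphic addition / subtraction
#' @param ct,ct2 ciphertexts.
#' @param params a \linkS4class{YASHEParams}.
#' @export
yasheAdd <- function(ct, ct2, params) {
  new("YASHECiphertext",
    c = ringAdd(ct@c, ct2@c), depth = max(ct@depth, ct2@depth),
    noiseLog2 = max(ct@noiseLog2, ct2@noiseLog2) + 1
  )
}

#' @rdname yasheAdd
#' @export
yasheSub <- function(ct, ct2, params) {
  new("YASHECiphertext",
    c = ringSub(ct@c, ct2@c), depth = max(ct@depth, ct2@depth),
    noiseLog2 = max(ct@noiseLog2, ct2@noiseLog2) + 1
  )
}

yasheAddPlain <- function(ct, msg, params) {
  ring <- params@ring
  delta <- gs_big_divmod(ring@q, bigstr(ring@t))$q
  mEl <- asPlaintext(msg, ring)
  new("YASHECiphertext",
    c = ringAdd(ct@c, ringScalMul(ringLift(mEl, ring@q), delta)),
    depth = ct@depth, noiseLog2 = ct@noiseLog2 + 0.5
  )
}

yashePlainSub <- function(msg, ct, params) {
  ring <- params@ring
  delta <- gs_big_divmod(ring@q, bigstr(ring@t))$q
  mEl <- asPlaintext(msg, ring)
  new("YASHECiphertext",
    c = ringSub(ringScalMul(ringLift(mEl, ring@q), delta), ct@c),
    depth = ct@depth, noiseLog2 = ct@noiseLog2 + 0.5
  )
}

yasheScalMul <- function(ct, k, params) {
  new("YASHECiphertext",
    c = ringScalMul(ct@c, k), depth = ct@depth,
    noiseLog2 = ct@noiseLog2 + log2(abs(k) + 1)
  )
}

#' Balanced base-omega word decomposition, and its dual
#'
#' \code{wordDecompose} splits a ring element into l_w elements with
#' coefficients in (-omega/2, omega/2] such that
#' sum_i D_i(a) * omega^i = a (as centered integers);
#' \code{powersOf} returns ([a * omega^i]_q)_i.  Their inner product is a*b
#' mod q.
#'
#' @param a a \linkS4class{RingElement} mod q.
#' @param params a \linkS4class{YASHEParams}.
#' @return list of l_w ring elements.
#' @export
wordDecompose <- function(a, params) {
  D <- gs_word_decompose(a@coeffs, a@q, params@omega, params@lw)
  lapply(seq_len(params@lw), function(i) {
    new("RingElement", coeffs = as.character(D[i, ]), q = a@q, m = a@m)
  })
}

#' @rdname wordDecompose
#' @export
powersOf <- function(a, params) {
  out <- vector("list", params@lw)
  wpow <- "1"
  for (i in seq_len(params@lw)) {
    out[[i]] <- ringScalMul(a, wpow)
    wpow <- gs_big_mul(wpow, params@omega)
  }
  out
}

#' Homomorphic multiplication
#'
#' ct_mult = SwitchKey(round(t/q * ct*ct') mod q, evk): the integer
#' (negacyclic) product of the two ciphertexts is scaled by t/q with rounding,
#' then re-linearized to a ciphertext under f via the word-decomposition inner
#' product with the evaluation key.
#'
#' @param ct,ct2 ciphertexts.
#' @param keys a \linkS4class{YASHEKeys} with evk present.
#' @param params a \linkS4class{YASHEParams}.
#' @return a \linkS4class{YASHECiphertext} of depth max(depth) + 1.
#' @export
yasheMult <- function(ct, ct2, keys, params) {
  depth <- max(ct@depth, ct2@depth) + 1L
  if (depth > params@M) {
    stop("depth-budget error: parameters support M = ", params@M, " levels")
  }
  if (length(keys@evk) == 0) stop("no evaluation key (parameters had M = 0)")
  ring <- params@ring
  ctil <- gs_yashe_mult_core(ct@c@coeffs, ct2@c@coeffs, ring@q, ring@t)
  cEl <- new("RingElement", coeffs = as.character(ctil), q = ring@q, m = ring@m)
  D <- wordDecompose(cEl, params)
  acc <- ringZero(ring)
  for (i in seq_len(params@lw)) {
    acc <- ringAdd(acc, ringMul(D[[i]], keys@evk[[i]], ring))
  }
  new("YASHECiphertext",
    c = acc, depth = depth,
    noiseLog2 = ct@noiseLog2 + ct2@noiseLog2 + log2(ring@n * ring@t)
  )
}
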