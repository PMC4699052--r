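# Leveled modulus-switching scheme (BGV style).
#
# Ciphertexts are pairs (c0, c1) over R_{q_l} with Dec = [c0 - s*c1]_{q_l} mod t.
# Multiplication tensors to three components, switches back to two with an
# evaluation key over R_{P*q_{L-2}} that encrypts P*s^2 (modulus-raising
# gadget: scale the ciphertext up by P, add d2 * evk, then divide P back out
# with the same rescaling primitive used for modulus switching), and finally
# drops one chain prime to shrink the noise.

# heuristic noise constants (infinity-norm bounds, log2 domain)
bgvNoiseConsts <- function(ring, noise) {
  t <- ring@t
  B <- noise@B
  h <- noise@h
  nu0 <- t * (B * (2 * h + 1) + 1)         # fresh ciphertext
  msAdd <- 2 * t * (1 + h)                 # additive term of one modulus switch
  list(
    nu0Log2 = log2(nu0),
    msAddLog2 = log2(msAdd),
    multExpLog2 = log2(ring@n) + ring@expansionLog2
  )
}

#' Construct parameters for the leveled scheme directly
#'
#' Builds the modulus chain from L primes of \code{betaBits} bits, each
#' congruent to 1 mod t (so rescaling preserves the plaintext), and a
#' key-switching factor P = 2^K * t + 1 with enough headroom that the
#' switching noise is negligible.  When \code{betaBits} is NULL it is derived
#' from the noise heuristics (stability of the noise recursion under
#' multiply-then-switch, plus an addition budget).
#'
#' @param m odd cyclotomic index.
#' @param t plaintext modulus, 1 < t < q_0.
#' @param L chain length (L >= 2).
#' @param betaBits bit size of each chain prime.
#' @param sigma,h error width and secret Hamming weight.
#' @param lambda nominal security parameter recorded in the object.
#' @param addBudget number of fresh-noise additions the bottom modulus must
#'   absorb.
#' @return a \linkS4class{BGVParams}.
#' @export
bgvParams <- function(m, t, L, betaBits = NULL, sigma = 3.2, h = 64,
                      lambda = NA_real_, addBudget = 64) {
  L <- as.integer(L)
  if (L < 2) stop("need L >= 2")
  noise <- noiseProfile(sigma = sigma, h = min(h, eulerPhi(m)))
  ring0 <- ringParams(m, 4 * t, t) # placeholder modulus; replaced below
  nc <- bgvNoiseConsts(ring0, noise)
  if (is.null(betaBits)) {
    c0Log2 <- max(nc$nu0Log2, nc$msAddLog2) + 1
    betaBits <- ceiling(max(
      nc$multExpLog2 + c0Log2, # p >= expansion * stable noise
      log2(8 * addBudget) + c0Log2 # q_0 >= 8 * addition budget * noise
    )) + 4
  }
  if (betaBits <= log2(t) + 1) betaBits <- ceiling(log2(t)) + 2
  primes <- character(L)
  start <- 2^betaBits
  for (k in seq_len(L)) {
    primes[k] <- gs_next_prime_cong(bigstr(start), t, 1 %% t)
    start <- as.numeric(primes[k]) + 1
  }
  moduli <- character(L)
  moduli[1] <- primes[1]
  for (i in seq_len(L - 1)) moduli[i + 1] <- gs_big_mul(moduli[i], primes[i + 1])
  qstar <- moduli[L - 1] # q_{L-2}
  K <- ceiling(bigLog2(qstar) + log2(eulerPhi(m)) + log2(noise@B) + log2(t) + 8)
  P <- gs_big_add(gs_big_mul(bigPow2(K), bigstr(t)), "1")
  ring <- ringParams(m, moduli[L], t)
  new("BGVParams",
    ring = ring, primes = primes, moduli = moduli, L = L, P = P,
    noise = noise, lambda = as.numeric(lambda)
  )
}

#' Parameter generation from a security target
#'
#' Searches for the smallest odd m whose degree phi(m) meets the RLWE security
#' lower bound \code{bgvSecurityMinPhi(L, m, lambda)} and whose slot count
#' reaches \code{targetSlots}, then builds the modulus chain as in
#' \code{\link{bgvParams}}.
#'
#' @param lambda security parameter.
#' @param L chain length.
#' @param t plaintext modulus.
#' @param targetSlots minimum number of CRT slots (default 1).
#' @param sigma,h noise profile.
#' @param mMax search cap on m.
#' @return a \linkS4class{BGVParams}.
#' @export
bgvParamsGen <- function(lambda, L, t, targetSlots = 1, sigma = 3.2, h = 64,
                         mMax = 30000) {
  p <- plaintextBase(t)$p
  m <- 3
  while (m <= mMax) {
    if (m %% 2 == 1 && m %% p != 0) {
      phi <- eulerPhi(m)
      if (phi >= bgvSecurityMinPhi(L, m, lambda)) {
        d <- multOrderSmall(p %% m, m)
        if (phi / d >= targetSlots) {
          return(bgvParams(m, t, L, sigma = sigma, h = h, lambda = lambda))
        }
      }
    }
    m <- m + 2
  }
  stop("parameter-search failure: no admissible m below the search cap")
}

setMethod("show", "BGVParams", function(object) {
  cat(sprintf(
    "BGVParams: m = %d (n = %d), t = %s, L = %d, log2(q_{L-1}) ~ %.1f\n",
    object@ring@m, object@ring@n, format(object@ring@t), object@L,
    bigLog2(object@moduli[object@L])
  ))
})

#' @rdname nSlots
#' @export
setMethod("nSlots", "BGVParams", function(x) {
  p <- plaintextBase(x@ring@t)$p
  as.integer(x@ring@n / multOrderSmall(p %% x@ring@m, x@ring@m))
})

#' @rdname level
#' @export
setMethod("level", "BGVCiphertext", function(x) x@level)

setMethod("show", "BGVCiphertext", function(object) {
  cat(sprintf(
    "BGVCiphertext: level %d, log2(q_l) ~ %.1f, est. noise ~ 2^%.1f\n",
    object@level, bigLog2(object@c0@q), object@noiseLog2
  ))
})

setMethod("show", "BGVKeys", function(object) {
  cat(sprintf(
    "BGVKeys: sparse ternary secret (weight %d), pk + evk present\n",
    sum(coeffs(object@sk) != 0)
  ))
})

#' Key generation for the leveled scheme
#'
#' The secret s is sparse ternary of weight h; the public key is an RLWE pair
#' (a, b = a*s + t*e) over R_{q_{L-1}}; the evaluation key is the analogous
#' pair over R_{P*q_{L-2}} with P*s^2 folded into b.
#'
#' @param params a \linkS4class{BGVParams}.
#' @return a \linkS4class{BGVKeys}.
#' @export
bgvKeyGen <- function(params) {
  ring <- params@ring
  q <- params@moduli[params@L]
  s <- sampleTernarySparse(ring@n, params@noise@h, q, ring@m)
  a <- sampleUniform(ring@n, q, ring@m)
  e <- sampleGaussian(ring@n, params@noise, q, ring@m)
  b <- ringAdd(ringMul(a, s, ring), ringScalMul(e, ring@t))
  Pq <- gs_big_mul(params@P, params@moduli[params@L - 1])
  sP <- ringLift(s, Pq)
  aK <- sampleUniform(ring@n, Pq, ring@m)
  eK <- sampleGaussian(ring@n, params@noise, Pq, ring@m)
  s2P <- ringScalMul(ringMul(sP, sP, ring, q = Pq), params@P)
  bK <- ringAdd(ringAdd(ringMul(aK, sP, ring, q = Pq), ringScalMul(eK, ring@t)), s2P)
  new("BGVKeys",
    sk = s, pk = list(a = a, b = b), evk = list(a = aK, b = bK)
  )
}

#' Encrypt a plaintext ring element
#'
#' @param msg a \linkS4class{RingElement} with modulus t (e.g. from
#'   \code{\link{crtPack}}), or a numeric coefficient vector reduced mod t.
#' @param pk public key pair from \code{\link{bgvKeyGen}} (a BGVKeys object is
#'   also accepted).
#' @param params a \linkS4class{BGVParams}.
#' @return a fresh \linkS4class{BGVCiphertext} at level L-1.
#' @export
bgvEncrypt <- function(msg, pk, params) {
  if (is(pk, "BGVKeys")) pk <- pk@pk
  ring <- params@ring
  q <- params@moduli[params@L]
  mEl <- asPlaintext(msg, ring)
  v <- sampleTernarySparse(ring@n, params@noise@h, q, ring@m)
  e0 <- sampleGaussian(ring@n, params@noise, q, ring@m)
  e1 <- sampleGaussian(ring@n, params@noise, q, ring@m)
  c0 <- ringAdd(ringAdd(ringLift(mEl, q), ringMul(pk$b, v, ring)), ringScalMul(e0, ring@t))
  c1 <- ringAdd(ringMul(pk$a, v, ring), ringScalMul(e1, ring@t))
  nc <- bgvNoiseConsts(ring, params@noise)
  new("BGVCiphertext",
    c0 = c0, c1 = c1, level = params@L - 1L, noiseLog2 = nc$nu0Log2
  )
}

# coerce numeric vectors / mod-t elements into a centered plaintext element
asPlaintext <- function(msg, ring) {
  if (is(msg, "RingElement")) {
    stopifnot(msg@m == ring@m)
    return(ringReduce(msg, ring@t))
  }
  ringElement(msg, q = ring@t, m = ring@m)
}

#' Measured ciphertext noise
#'
#' The noise polynomial [c0 - s*c1]_{q_l}; its infinity norm is the exact
#' quantity the decryption bound constrains.  Requires the secret key, so this
#' is a testing/diagnostic facility.
#'
#' @param ct a \linkS4class{BGVCiphertext}.
#' @param keys a \linkS4class{BGVKeys} (or the secret \linkS4class{RingElement}).
#' @param params a \linkS4class{BGVParams}.
#' @return list with the noise element, its infinity norm (string), and
#'   \code{failed} (TRUE when the norm reaches q_l/4, the safety threshold).
#' @export
bgvNoise <- function(ct, keys, params) {
  s <- if (is(keys, "BGVKeys")) keys@sk else keys
  ql <- ct@c0@q
  sl <- ringLift(s, ql)
  e <- ringSub(ct@c0, ringMul(sl, ct@c1, params@ring, q = ql))
  linf <- ringLinf(e)
  failed <- gs_big_cmp(gs_big_mul(linf, "4"), ql) >= 0
  list(noise = e, linf = linf, failed = failed)
}

#' Decrypt a ciphertext
#'
#' Dec(ct, sk) = [c0 - s*c1]_{q_l} mod t.  A warning of class
#' \code{genoSHE_decryption_failure} is signalled when the measured noise
#' reaches a quarter of the level modulus (an honest pipeline never comes near
#' this; reaching it means the result cannot be trusted).
#'
#' @inheritParams bgvNoise
#' @param withNoise also return the measured noise.
#' @return plaintext \linkS4class{RingElement} modulo t, or a list when
#'   \code{withNoise}.
#' @export
bgvDecrypt <- function(ct, keys, params, withNoise = FALSE) {
  nz <- bgvNoise(ct, keys, params)
  if (nz$failed) {
    warning(warningCondition(
      "measured decryption noise reached q_l/4: result unreliable",
      class = "genoSHE_decryption_failure"
    ))
  }
  msgv <- gs_poly_mod_small(nz$noise@coeffs, params@ring@t)
  msg <- ringElement(msgv, q = params@ring@t, m = params@ring@m)
  if (withNoise) list(msg = msg, linf = nz$linf, failed = nz$failed) else msg
}

alignLevels <- function(ct, ct2, params) {
  l <- min(ct@level, ct2@level)
  list(
    a = bgvModSwitch(ct, l, params),
    b = bgvModSwitch(ct2, l, params)
  )
}

#' Homomorphic addition / subtraction
#'
#' Operands at different levels are first aligned by switching the higher one
#' down.
#'
#' @param ct,ct2 ciphertexts.
#' @param params a \linkS4class{BGVParams}.
#' @return a \linkS4class{BGVCiphertext}.
#' @export
bgvAdd <- function(ct, ct2, params) {
  p <- alignLevels(ct, ct2, params)
  new("BGVCiphertext",
    c0 = ringAdd(p$a@c0, p$b@c0), c1 = ringAdd(p$a@c1, p$b@c1),
    level = p$a@level, noiseLog2 = max(p$a@noiseLog2, p$b@noiseLog2) + 1
  )
}

#' @rdname bgvAdd
#' @export
bgvSub <- function(ct, ct2, params) {
  p <- alignLevels(ct, ct2, params)
  new("BGVCiphertext",
    c0 = ringSub(p$a@c0, p$b@c0), c1 = ringSub(p$a@c1, p$b@c1),
    level = p$a@level, noiseLog2 = max(p$a@noiseLog2, p$b@noiseLog2) + 1
  )
}

# add a plaintext (mod t) to a ciphertext without touching the noise much
bgvAddPlain <- function(ct, msg, params) {
  mEl <- asPlaintext(msg, params@ring)
  new("BGVCiphertext",
    c0 = ringAdd(ct@c0, ringLift(mEl, ct@c0@q)), c1 = ct@c1,
    level = ct@level, noiseLog2 = ct@noiseLog2 + 0.1
  )
}

# plaintext-minus-ciphertext (used by the arithmetic circuits' 1 - x)
bgvPlainSub <- function(msg, ct, params) {
  mEl <- asPlaintext(msg, params@ring)
  z <- ringZero(params@ring, q = ct@c0@q)
  new("BGVCiphertext",
    c0 = ringSub(ringLift(mEl, ct@c0@q), ct@c0), c1 = ringSub(z, ct@c1),
    level = ct@level, noiseLog2 = ct@noiseLog2 + 0.1
  )
}

#' Modulus switching
#'
#' Rescales a ciphertext from q_l to a lower chain modulus, dividing the noise
#' by the dropped primes (up to a small additive rounding term that depends on
#' t and the secret weight).  Switching to the current level is the identity.
#'
#' @param ct a ciphertext.
#' @param targetLevel desired level, 0 <= targetLevel <= level(ct).
#' @param params a \linkS4class{BGVParams}.
#' @return a \linkS4class{BGVCiphertext} at \code{targetLevel}.
#' @export
bgvModSwitch <- function(ct, targetLevel, params) {
  targetLevel <- as.integer(targetLevel)
  if (targetLevel < 0) stop("invalid target level")
  if (targetLevel > ct@level) stop("cannot switch upward")
  nc <- bgvNoiseConsts(params@ring, params@noise)
  while (ct@level > targetLevel) {
    l <- ct@level
    ql <- params@moduli[l + 1]
    p <- params@primes[l + 1]
    c0 <- gs_bgv_modswitch(ct@c0@coeffs, ql, p, params@ring@t)
    c1 <- gs_bgv_modswitch(ct@c1@coeffs, ql, p, params@ring@t)
    qlow <- params@moduli[l]
    ct <- new("BGVCiphertext",
      c0 = new("RingElement", coeffs = as.character(c0), q = qlow, m = params@ring@m),
      c1 = new("RingElement", coeffs = as.character(c1), q = qlow, m = params@ring@m),
      level = l - 1L,
      noiseLog2 = max(ct@noiseLog2 - bigLog2(p), nc$msAddLog2) + 1
    )
  }
  ct
}

#' Key switching of a three-component ciphertext
#'
#' Input decrypts as d0 - s*d1 + s^2*d2; output is a two-component ciphertext
#' under s at the same level.  Realized by scaling up to modulus P*q_l, adding
#' d2 times the evaluation key, and rescaling P back out.
#'
#' @param ct3 list with ring elements d0, d1, d2 and \code{level}.
#' @param keys a \linkS4class{BGVKeys} (evk is used).
#' @param params a \linkS4class{BGVParams}.
#' @return a \linkS4class{BGVCiphertext}.
#' @export
bgvSwitchKey <- function(ct3, keys, params) {
  evk <- if (is(keys, "BGVKeys")) keys@evk else keys
  ring <- params@ring
  l <- ct3$level
  ql <- params@moduli[l + 1]
  Pq <- gs_big_mul(params@P, ql)
  evb <- ringReduce(evk$b, Pq)
  eva <- ringReduce(evk$a, Pq)
  d2 <- ringLift(ct3$d2, Pq)
  u0 <- ringAdd(ringScalMul(ringLift(ct3$d0, Pq), params@P), ringMul(d2, evb, ring, q = Pq))
  u1 <- ringAdd(ringScalMul(ringLift(ct3$d1, Pq), params@P), ringMul(d2, eva, ring, q = Pq))
  c0 <- gs_bgv_modswitch(u0@coeffs, Pq, params@P, ring@t)
  c1 <- gs_bgv_modswitch(u1@coeffs, Pq, params@P, ring@t)
  nc <- bgvNoiseConsts(ring, params@noise)
  new("BGVCiphertext",
    c0 = new("RingElement", coeffs = as.character(c0), q = ql, m = ring@m),
    c1 = new("RingElement", coeffs = as.character(c1), q = ql, m = ring@m),
    level = as.integer(l),
    noiseLog2 = max(ct3$noiseLog2 %||% 0, nc$msAddLog2) + 1
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Homomorphic multiplication
#'
#' Tensors the two ciphertexts, switches the s^2 component away with the
#' evaluation key, and drops one chain prime.  Operands are first aligned to
#' min(level, L-2) (fresh ciphertexts therefore spend one switch before their
#' first product, matching the L = M + 2 chain accounting).  Each
#' multiplication consumes exactly one level; when the current level is 0 no
#' further multiplication is possible.
#'
#' @param ct,ct2 ciphertexts.
#' @param keys a \linkS4class{BGVKeys} (evk is used).
#' @param params a \linkS4class{BGVParams}.
#' @return a \linkS4class{BGVCiphertext} one level down.
#' @export
bgvMult <- function(ct, ct2, keys, params) {
  l <- min(ct@level, ct2@level, params@L - 2L)
  if (l < 1) stop("depth-budget error: modulus chain exhausted")
  ct <- bgvModSwitch(ct, l, params)
  ct2 <- bgvModSwitch(ct2, l, params)
  ring <- params@ring
  ql <- params@moduli[l + 1]
  d0 <- ringMul(ct@c0, ct2@c0, ring, q = ql)
  d1 <- ringAdd(
    ringMul(ct@c0, ct2@c1, ring, q = ql),
    ringMul(ct@c1, ct2@c0, ring, q = ql)
  )
  d2 <- ringMul(ct@c1, ct2@c1, ring, q = ql)
  nc <- bgvNoiseConsts(ring, params@noise)
  prodNoise <- ct@noiseLog2 + ct2@noiseLog2 + nc$multExpLog2
  out <- bgvSwitchKey(
    list(d0 = d0, d1 = d1, d2 = d2, level = l, noiseLog2 = prodNoise),
    keys, params
  )
  bgvModSwitch(out, l - 1L, params)
}
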