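# Cyclotomic ring arithmetic, CRT slot structure, and random samplers.

# cache of per-m ring structure (Phi_m and reduction rows)
.ringStructCache <- new.env(parent = emptyenv())

ringStructure <- function(m) {
  key <- as.character(m)
  if (!is.null(.ringStructCache[[key]])) return(.ringStructCache[[key]])
  phim <- cyclotomic(m)
  nega <- isPowerOfTwo(m)
  red <- if (nega) matrix(0L, 0, length(phim) - 1) else cycloReductionRows(phim, m)
  st <- list(phim = phim, redRows = red, negacyclic = nega, n = length(phim) - 1)
  .ringStructCache[[key]] <- st
  st
}

# product of two mod-t coefficient vectors in R_t = Z_t[x]/Phi_m, small
# arithmetic only (plaintext-side oracle / circuit evaluation)
ptRingMul <- function(a, b, m, t) {
  st <- ringStructure(m)
  n <- st$n
  a <- c(a %% t, numeric(n - length(a)))
  b <- c(b %% t, numeric(n - length(b)))
  conv <- numeric(2 * n - 1)
  for (i in seq_len(n)) {
    if (a[i] != 0) {
      idx <- i:(i + n - 1)
      conv[idx] <- conv[idx] + a[i] * b
    }
  }
  conv <- conv %% t
  if (st$negacyclic) {
    res <- conv[seq_len(n)]
    if (2 * n - 1 > n) {
      tailc <- conv[(n + 1):(2 * n - 1)]
      res[seq_along(tailc)] <- res[seq_along(tailc)] - tailc
    }
    return(res %% t)
  }
  fold <- numeric(m)
  for (k in seq_along(conv)) {
    idx <- (k - 1) %% m + 1
    fold[idx] <- fold[idx] + conv[k]
  }
  fold <- fold %% t
  res <- fold[seq_len(n)]
  if (m > n) {
    for (k in (n + 1):m) {
      if (fold[k] != 0) res <- res + fold[k] * st$redRows[k - n, ]
    }
  }
  res %% t
}

#' Coefficients of the m-th cyclotomic polynomial
#'
#' Computed over the integers by Moebius-style exact division: the radical
#' case recursively divides x^rad - 1 by the cyclotomics of the proper
#' divisors, and Phi_m(x) = Phi_rad(m)(x^{m/rad(m)}).
#'
#' @param m cyclotomic index, m >= 2.
#' @return numeric vector of integer coefficients, ascending powers, length
#'   phi(m) + 1 (monic).
#' @examples
#' cyclotomic(8)  # x^4 + 1
#' cyclotomic(3)  # x^2 + x + 1
#' @export
cyclotomic <- function(m) {
  if (!isWholeNumber(m) || m < 2) stop("invalid parameter: m must be an integer >= 2")
  rad <- prod(unique(primeFactors(m)))
  f <- cyclotomicSquarefree(rad)
  k <- m / rad
  if (k > 1) { # substitute x -> x^k
    out <- numeric((length(f) - 1) * k + 1)
    out[(seq_along(f) - 1) * k + 1] <- f
    f <- out
  }
  stopifnot(length(f) == eulerPhi(m) + 1, f[length(f)] == 1)
  f
}

cyclotomicSquarefree <- function(m) {
  if (m == 1) return(c(-1, 1))
  ps <- unique(primeFactors(m))
  if (length(ps) == 1) return(rep(1, m)) # prime
  f <- c(-1, numeric(m - 1), 1) # x^m - 1
  divs <- Filter(function(d) m %% d == 0, seq_len(m - 1))
  for (d in divs) f <- intPolyDivExact(f, cyclotomicSquarefree(d))
  f
}

# exact division of integer polynomials (remainder must vanish)
intPolyDivExact <- function(a, b) {
  da <- length(a) - 1
  db <- length(b) - 1
  q <- numeric(da - db + 1)
  r <- a
  for (k in (da - db):0) {
    coefv <- r[db + k + 1] / b[db + 1]
    q[k + 1] <- coefv
    idx <- (k + 1):(db + k + 1)
    r[idx] <- r[idx] - coefv * b
  }
  stopifnot(max(abs(r)) < 1e-9, max(abs(q)) < 2^50)
  round(q)
}

#' Construct ring parameters
#'
#' @param m cyclotomic index: odd for the modulus-switching profile, a power
#'   of two for the scale-invariant profile.
#' @param q coefficient modulus (number or decimal string).
#' @param t plaintext modulus.
#' @return a \linkS4class{RingParams}.
#' @export
ringParams <- function(m, q, t) {
  m <- as.integer(m)
  st <- ringStructure(m)
  phim <- st$phim
  n <- st$n
  nega <- st$negacyclic
  red <- st$redRows
  if (nega) {
    expLog2 <- 0
  } else {
    colAbs <- if (nrow(red) > 0) max(colSums(abs(red))) else 0
    expLog2 <- log2(2 * (1 + colAbs))
  }
  new("RingParams",
    m = m, n = as.integer(n), q = bigstr(q), t = t, phim = phim,
    redRows = red, negacyclic = nega, expansionLog2 = expLog2
  )
}

# rows of x^k mod Phi_m for k = n .. m-1 (odd m); small integer entries
cycloReductionRows <- function(phim, m) {
  n <- length(phim) - 1
  if (m - 1 < n) return(matrix(0L, 0, n))
  rows <- matrix(0L, m - n, n)
  cur <- -phim[seq_len(n)] # x^n mod Phi
  rows[1, ] <- cur
  if (m - 1 > n) {
    for (k in (n + 1):(m - 1)) {
      top <- cur[n]
      cur <- c(0, cur[-n])
      if (top != 0) cur <- cur - top * phim[seq_len(n)]
      stopifnot(max(abs(cur)) < 2^40)
      rows[k - n + 1, ] <- cur
    }
  }
  storage.mode(rows) <- "integer"
  rows
}

#' Construct a ring element
#'
#' @param coeffs numeric or character coefficient vector (ascending powers,
#'   length at most n; padded with zeros).  Values are centered mod q.
#' @param params a \linkS4class{RingParams}, or supply \code{q} and \code{m}.
#' @param q,m modulus and cyclotomic index when \code{params} is missing.
#' @return a \linkS4class{RingElement}.
#' @export
ringElement <- function(coeffs, params = NULL, q = params@q, m = params@m) {
  n <- eulerPhi(m)
  if (length(coeffs) > n) stop("too many coefficients")
  co <- vapply(coeffs, bigstr, "")
  co <- c(co, rep("0", n - length(co)))
  co <- gs_poly_center(co, bigstr(q))
  new("RingElement", coeffs = unname(co), q = bigstr(q), m = as.integer(m))
}

ringZero <- function(params, q = params@q) ringElement(numeric(0), q = q, m = params@m)

#' @rdname modulus
#' @export
setMethod("modulus", "RingElement", function(x) x@q)

#' @rdname coeffs
#' @export
setMethod("coeffs", "RingElement", function(x, strings = FALSE) {
  if (strings) return(x@coeffs)
  v <- bigAsNumeric(x@coeffs)
  if (anyNA(v)) x@coeffs else v
})

setMethod("show", "RingElement", function(object) {
  cat(sprintf(
    "RingElement in Z_q[x]/Phi_%d(x): n = %d, log2(q) ~ %.1f\n",
    object@m, length(object@coeffs), bigLog2(object@q)
  ))
  head <- paste(utils::head(object@coeffs, 8), collapse = ", ")
  cat("  coeffs: [", head, if (length(object@coeffs) > 8) ", ..." else "", "]\n", sep = "")
})

setMethod("show", "RingParams", function(object) {
  cat(sprintf(
    "RingParams: m = %d (n = %d, %s), log2(q) ~ %.1f, t = %s\n",
    object@m, object@n,
    if (object@negacyclic) "x^n + 1" else "odd index",
    bigLog2(object@q), format(object@t)
  ))
})

checkCompatible <- function(a, b) {
  if (a@m != b@m || a@q != b@q)
    stop("invalid input: ring elements have mismatched modulus or index")
}

#' Ring addition / subtraction / negation
#' @param a,b ring elements over the same ring and modulus.
#' @return a \linkS4class{RingElement}.
#' @export
ringAdd <- function(a, b) {
  checkCompatible(a, b)
  new("RingElement", coeffs = as.character(gs_poly_add(a@coeffs, b@coeffs, a@q)), q = a@q, m = a@m)
}

#' @rdname ringAdd
#' @export
ringSub <- function(a, b) {
  checkCompatible(a, b)
  new("RingElement", coeffs = as.character(gs_poly_sub(a@coeffs, b@coeffs, a@q)), q = a@q, m = a@m)
}

#' @rdname ringAdd
#' @export
ringNeg <- function(a) {
  z <- ringElement(numeric(0), q = a@q, m = a@m)
  ringSub(z, a)
}

#' Ring multiplication a * b mod (Phi_m, q)
#'
#' Exact schoolbook convolution with cyclotomic reduction (negacyclic wrap for
#' power-of-two m; fold mod x^m - 1 plus precomputed reduction rows for odd m).
#'
#' @param a,b ring elements.
#' @param params the \linkS4class{RingParams} carrying the reduction data.
#' @param q optional modulus override (must match the elements).
#' @return a \linkS4class{RingElement}.
#' @export
ringMul <- function(a, b, params, q = a@q) {
  checkCompatible(a, b)
  if (a@m != params@m) stop("invalid input: params do not match elements")
  out <- gs_poly_mul(
    a@coeffs, b@coeffs, bigstr(q),
    params@negacyclic, params@m, params@redRows
  )
  new("RingElement", coeffs = as.character(out), q = bigstr(q), m = a@m)
}

# multiply by an integer scalar
ringScalMul <- function(a, c) {
  new("RingElement",
    coeffs = as.character(gs_poly_scalmul(a@coeffs, bigstr(c), a@q)),
    q = a@q, m = a@m
  )
}

# reinterpret the (small) coefficients of x under a new modulus
ringLift <- function(x, q, m = x@m) ringElement(x@coeffs, q = q, m = m)

# centered reduction of x to a smaller modulus dividing (or independent of) q
ringReduce <- function(x, q) {
  new("RingElement",
    coeffs = as.character(gs_poly_center(x@coeffs, bigstr(q))),
    q = bigstr(q), m = x@m
  )
}

ringLinf <- function(x) gs_poly_linf(x@coeffs)

# ---- samplers ----

#' Sparse ternary sample
#'
#' A ring element with exactly h nonzero coefficients, each plus or minus one
#' with equal probability.  Uses R's global RNG stream.
#'
#' @param n ring degree.
#' @param h number of nonzero coefficients, 0 <= h <= n.
#' @param q modulus to attach to the element.
#' @param m cyclotomic index.
#' @export
sampleTernarySparse <- function(n, h, q, m) {
  if (h > n || h < 0) stop("invalid parameter: need 0 <= h <= n")
  v <- numeric(n)
  if (h > 0) {
    pos <- sample.int(n, h)
    v[pos] <- sample(c(-1, 1), h, replace = TRUE)
  }
  ringElement(v, q = q, m = m)
}

# dense uniform ternary (used by the scale-invariant scheme's keygen)
sampleTernaryDense <- function(n, q, m) {
  ringElement(sample(c(-1, 0, 1), n, replace = TRUE), q = q, m = m)
}

#' Truncated discrete Gaussian sample
#'
#' Coefficients are rounded normal draws, resampled until they fall in
#' [-B, B].
#'
#' @param n ring degree.
#' @param profile a \linkS4class{NoiseProfile} (sigma and B are used).
#' @param q,m modulus and cyclotomic index for the element.
#' @export
sampleGaussian <- function(n, profile, q, m) {
  v <- round(stats::rnorm(n, 0, profile@sigma))
  bad <- which(abs(v) > profile@B)
  while (length(bad) > 0) {
    v[bad] <- round(stats::rnorm(length(bad), 0, profile@sigma))
    bad <- bad[abs(v[bad]) > profile@B]
  }
  ringElement(v, q = q, m = m)
}

sampleUniform <- function(n, q, m) {
  new("RingElement",
    coeffs = as.character(gs_sample_uniform(as.integer(n), bigstr(q))),
    q = bigstr(q), m = as.integer(m)
  )
}

# ---- slot structure ----

#' CRT plaintext-slot layout of R_t
#'
#' Phi_m factors modulo t into ell = phi(m)/d irreducible polynomials of
#' common degree d, where d is the multiplicative order modulo m of the prime
#' base of t.  For prime t the factors are found by equal-degree splitting;
#' for t = 2^r (odd m) the mod-2 factors are Hensel-lifted.  Integer slot
#' values live in the constant terms of the factor residues.
#'
#' @param m cyclotomic index; must be coprime to the prime base of t.
#' @param t plaintext modulus: 2, 2^r, or an odd prime.
#' @param computeFactors factor Phi_m explicitly (required for packing);
#'   set FALSE for an order-only layout (slot counting at large m).
#' @return a \linkS4class{SlotLayout}.
#' @examples
#' slotLayout(7, 2)       # ell = 2 slots of degree 3
#' slotLayout(8191, 2, computeFactors = FALSE)  # ell = 630
#' @export
slotLayout <- function(m, t, computeFactors = NULL) {
  m <- as.integer(m)
  base <- plaintextBase(t)
  p <- base$p
  r <- base$r
  if (m %% p == 0) {
    stop(sprintf(
      "no batching: gcd(t, m) > 1 (Phi_m mod %d is a repeated-factor power)", p
    ))
  }
  phi <- eulerPhi(m)
  d <- multOrderSmall(p, m)
  ell <- phi / d
  if (is.null(computeFactors)) computeFactors <- phi <= 2048
  factors <- list()
  basis <- matrix(0, 0, 0)
  if (computeFactors) {
    phim <- cyclotomic(m)
    f2 <- withLocalSeed(
      20240601 + m + p,
      ptEqualDegreeFactors(phim %% p, d, p)
    )
    stopifnot(length(f2) == ell)
    if (r > 1) {
      factors <- ptHenselLift2(f2, phim, r)
    } else {
      factors <- f2
    }
    basis <- crtBasis(factors, phim, t, p, r, phi)
  }
  new("SlotLayout",
    m = m, t = t, ell = as.integer(ell), d = as.integer(d),
    factors = factors, basis = basis
  )
}

plaintextBase <- function(t) {
  if (!isWholeNumber(t) || t < 2) stop("t must be an integer >= 2")
  if (isPowerOfTwo(t)) return(list(p = 2, r = as.integer(log2(t))))
  if (gs_is_prime(bigstr(t))) return(list(p = t, r = 1L))
  stop("plaintext modulus must be a power of two or a prime")
}

# idempotent basis C_i = (Phi/f_i) * ((Phi/f_i)^{-1} mod f_i)  (mod Phi, t)
crtBasis <- function(factors, phim, t, p, r, n) {
  ell <- length(factors)
  basis <- matrix(0, ell, n)
  phiModT <- phim %% t
  for (i in seq_len(ell)) {
    G <- ptDivmod(phiModT, factors[[i]], t)$q
    w <- if (r > 1) ptInvmod2r(G, factors[[i]], r) else ptInvmod(G, factors[[i]], t)
    Ci <- ptMod(ptMul(G, w, t), phiModT, t)
    Ci <- c(Ci, numeric(n - length(Ci)))
    basis[i, ] <- Ci[seq_len(n)]
  }
  basis
}

#' @rdname nSlots
#' @export
setMethod("nSlots", "SlotLayout", function(x) x@ell)

setMethod("show", "SlotLayout", function(object) {
  cat(sprintf(
    "SlotLayout: m = %d, t = %s -> %d slots of degree %d%s\n",
    object@m, format(object@t), object@ell, object@d,
    if (length(object@factors)) "" else " (order-only)"
  ))
})

#' Pack integer slot values into a plaintext ring element
#'
#' The values vector (length <= ell, entries mod t) is carried to the element
#' of R_t congruent to value_i modulo the i-th factor; packing is a ring
#' isomorphism onto the integer slot subring, so sums and products of packed
#' elements act slotwise.
#'
#' @param values numeric vector of integers (reduced mod t).
#' @param layout a \linkS4class{SlotLayout} with factors computed.
#' @return a \linkS4class{RingElement} with modulus t.
#' @export
crtPack <- function(values, layout) {
  if (length(layout@factors) == 0) stop("layout was computed order-only")
  if (length(values) > layout@ell) stop("capacity error: more values than slots")
  t <- layout@t
  v <- c(values %% t, numeric(layout@ell - length(values)))
  poly <- as.vector(v %*% layout@basis) %% t
  ringElement(poly, q = t, m = layout@m)
}

#' Unpack slot values from a plaintext ring element
#'
#' @param x a \linkS4class{RingElement} modulo t (or a numeric coefficient
#'   vector).
#' @param layout the \linkS4class{SlotLayout} used to pack.
#' @param full return the full residue polynomials (ell x d matrix) instead of
#'   the constant terms.
#' @return numeric vector of length ell (or a matrix when \code{full}).
#' @export
crtUnpack <- function(x, layout, full = FALSE) {
  if (length(layout@factors) == 0) stop("layout was computed order-only")
  t <- layout@t
  poly <- if (is(x, "RingElement")) {
    v <- bigAsNumeric(x@coeffs)
    stopifnot(!anyNA(v))
    v %% t
  } else {
    x %% t
  }
  res <- matrix(0, layout@ell, layout@d)
  for (i in seq_len(layout@ell)) {
    ri <- ptMod(poly, layout@factors[[i]], t)
    ri <- c(ri, numeric(layout@d - length(ri)))
    res[i, ] <- ri[seq_len(layout@d)]
  }
  if (full) res else res[, 1]
}
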