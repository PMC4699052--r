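#' @import methods
NULL

#' Noise distribution profile
#'
#' Parameters of the truncated discrete Gaussian error distribution and the
#' sparse ternary secret-key distribution shared by both encryption schemes.
#'
#' @slot sigma standard deviation of the discrete Gaussian error.
#' @slot B truncation bound for error coefficients; defaults to \code{6*sigma}.
#' @slot h Hamming weight (number of nonzero coefficients) of sparse ternary
#'   secrets.
#' @export
setClass("NoiseProfile",
  representation(sigma = "numeric", B = "numeric", h = "integer"),
  validity = function(object) {
    if (object@sigma <= 0) return("sigma must be positive")
    if (object@B < 1) return("B must be >= 1")
    if (object@h < 0) return("h must be >= 0")
    TRUE
  }
)

#' @param sigma Gaussian standard deviation.
#' @param B truncation bound; default \code{ceiling(6 * sigma)}.
#' @param h secret Hamming weight.
#' @rdname NoiseProfile-class
#' @export
noiseProfile <- function(sigma = 3.2, B = ceiling(6 * sigma), h = 64L) {
  new("NoiseProfile", sigma = sigma, B = B, h = as.integer(h))
}

#' Cyclotomic ring parameters
#'
#' The ring R = Z[x]/(Phi_m(x)) together with a coefficient modulus q and a
#' plaintext modulus t.  Reduction data (rows of x^k mod Phi_m for
#' n <= k < m) is precomputed so products can be reduced exactly; for
#' power-of-two m the ring is negacyclic (Phi_m = x^n + 1) and no rows are
#' needed.
#'
#' @slot m cyclotomic index.
#' @slot n ring degree, phi(m).
#' @slot q coefficient modulus as a decimal string (arbitrary precision).
#' @slot t plaintext modulus (small integer).
#' @slot phim integer coefficients of Phi_m, ascending powers.
#' @slot redRows integer matrix, row k-n holds x^k mod Phi_m.
#' @slot negacyclic TRUE when Phi_m = x^n + 1.
#' @slot expansionLog2 log2 multiplicative expansion bound of one ring product,
#'   used by the noise heuristics.
#' @export
setClass("RingParams",
  representation(
    m = "integer", n = "integer", q = "character", t = "numeric",
    phim = "numeric", redRows = "matrix", negacyclic = "logical",
    expansionLog2 = "numeric"
  ),
  validity = function(object) {
    if (object@n != eulerPhi(object@m)) return("n must equal phi(m)")
    if (object@t < 2) return("t must be > 1")
    if (bigCmp(object@q, bigstr(object@t)) <= 0) return("need t < q")
    TRUE
  }
)

#' Element of R_q
#'
#' A ring element with coefficients stored as decimal strings in the centered
#' representation (-q/2, q/2].
#'
#' @slot coeffs length-n character vector of centered coefficients.
#' @slot q modulus (decimal string).
#' @slot m cyclotomic index of the carrier ring.
#' @export
setClass("RingElement",
  representation(coeffs = "character", q = "character", m = "integer"),
  validity = function(object) {
    if (length(object@coeffs) != eulerPhi(object@m))
      return("coefficient vector must have length phi(m)")
    linf <- gs_poly_linf(object@coeffs)
    if (gs_big_cmp(gs_big_mul(linf, "2"), object@q) > 0)
      return("coefficients not reduced into (-q/2, q/2]")
    TRUE
  }
)

#' CRT plaintext-slot structure
#'
#' Factorization of Phi_m modulo t into ell irreducible factors of common
#' degree d, with the CRT interpolation basis used to pack integer values into
#' slot constant terms.  Factor (and hence slot) order is fixed by sorting the
#' factors lexicographically on their coefficient vectors.
#'
#' @slot m cyclotomic index.
#' @slot t plaintext modulus.
#' @slot ell number of slots.
#' @slot d common degree of the irreducible factors.
#' @slot factors list of factor coefficient vectors (mod t), or empty when the
#'   layout was computed order-only.
#' @slot basis ell x n matrix; row i is the CRT idempotent C_i (1 mod f_i, 0
#'   mod f_j).
#' @export
setClass("SlotLayout",
  representation(
    m = "integer", t = "numeric", ell = "integer", d = "integer",
    factors = "list", basis = "matrix"
  ),
  validity = function(object) {
    if (object@ell * object@d != eulerPhi(object@m))
      return("ell * d must equal phi(m)")
    TRUE
  }
)

# ---- BGV-style scheme ----

#' Parameters of the leveled modulus-switching scheme
#'
#' @slot ring carrier \linkS4class{RingParams} at the top modulus q_{L-1}.
#' @slot primes chain primes p_0..p_{L-1} (decimal strings).
#' @slot moduli cumulative moduli q_i = p_0...p_i (decimal strings).
#' @slot L chain length.
#' @slot P key-switching modulus factor (decimal string), P = 1 mod t.
#' @slot noise error/secret profile.
#' @slot lambda nominal security parameter used during generation.
#' @export
setClass("BGVParams",
  representation(
    ring = "RingParams", primes = "character", moduli = "character",
    L = "integer", P = "character", noise = "NoiseProfile", lambda = "numeric"
  ),
  validity = function(object) {
    if (length(object@primes) != object@L) return("need L chain primes")
    if (length(object@moduli) != object@L) return("need L cumulative moduli")
    if (bigCmp(bigstr(object@ring@t), object@moduli[1]) >= 0)
      return("need t < q_0")
    for (i in seq_len(object@L - 1)) {
      dm <- gs_big_divmod(object@moduli[i + 1], object@moduli[i])
      if (dm$r != "0") return("moduli must form a divisibility chain")
    }
    if (gs_big_mod_small(object@P, object@ring@t) != 1)
      return("P must be 1 mod t")
    TRUE
  }
)

#' Key material of the leveled scheme
#'
#' @slot sk sparse ternary secret s.
#' @slot pk public RLWE pair (a, b) with b = a*s + t*e over R_{q_{L-1}}.
#' @slot evk key-switching pair over R_{P*q_{L-2}} encrypting P*s^2.
#' @export
setClass("BGVKeys",
  representation(sk = "RingElement", pk = "list", evk = "list")
)

#' Ciphertext of the leveled scheme
#'
#' @slot c0,c1 ring elements modulo the level modulus.
#' @slot level index into the modulus chain (0-based).
#' @slot noiseLog2 heuristic log2 bound on the noise infinity norm.
#' @export
setClass("BGVCiphertext",
  representation(
    c0 = "RingElement", c1 = "RingElement", level = "integer",
    noiseLog2 = "numeric"
  ),
  validity = function(object) {
    if (object@c0@q != object@c1@q) return("components must share a modulus")
    if (object@level < 0) return("level must be >= 0")
    TRUE
  }
)

# ---- YASHE-style scheme ----

#' Parameters of the scale-invariant scheme
#'
#' @slot ring carrier \linkS4class{RingParams}; m is a power of two and q a
#'   prime with q = 1 mod m.
#' @slot sigma,B error distribution parameters (B = 6*sigma).
#' @slot omega decomposition word (decimal string).
#' @slot lw number of base-omega digits, floor(log_omega q) + 1.
#' @slot M multiplicative levels supported.
#' @slot lambda nominal security parameter.
#' @export
setClass("YASHEParams",
  representation(
    ring = "RingParams", sigma = "numeric", B = "numeric",
    omega = "character", lw = "integer", M = "integer", lambda = "numeric"
  ),
  validity = function(object) {
    if (!isPowerOfTwo(object@ring@m)) return("m must be a power of two")
    if (object@M < 0) return("M must be >= 0")
    TRUE
  }
)

#' Key material of the scale-invariant scheme
#'
#' The public key is written h in the original scheme; it is named hpub here
#' to avoid the clash with the secret-key Hamming weight h.
#'
#' @slot f secret key, t*f' + 1 with ternary f'.
#' @slot finv inverse of f in R_q.
#' @slot hpub public key t*g*f^{-1}.
#' @slot evk list of lw ring elements gamma_i = f*omega^i + e_i + hpub*s_i
#'   (empty when M = 0; no multiplications are then supported).
#' @export
setClass("YASHEKeys",
  representation(
    f = "RingElement", finv = "RingElement", hpub = "RingElement",
    evk = "list"
  )
)

#' Ciphertext of the scale-invariant scheme (a single ring element)
#'
#' @slot c ring element modulo q.
#' @slot depth multiplicative depth consumed so far.
#' @slot noiseLog2 heuristic log2 bound on the inherent noise.
#' @export
setClass("YASHECiphertext",
  representation(c = "RingElement", depth = "integer", noiseLog2 = "numeric")
)

# ---- genomic data ----

#' Genotype code matrix for one study group
#'
#' Persons x SNV sites, entries in {0, 1, 2}: the count of the major allele A
#' in the genotype (AA -> 2, AB -> 1, BB -> 0).
#'
#' @slot codes integer matrix (persons in rows, SNVs in columns).
#' @slot group group label (e.g. "case", "control").
#' @export
setClass("GenotypeMatrix",
  representation(codes = "matrix", group = "character"),
  validity = function(object) {
    v <- as.vector(object@codes)
    if (!all(v %in% c(0L, 1L, 2L))) return("codes must be in {0, 1, 2}")
    TRUE
  }
)
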