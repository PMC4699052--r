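# Parameter-estimation calculator: multiplication depth, modulus sizes,
# ciphertext sizes, security lower bound, and task planning.

#' Per-multiplication modulus-switch count of the leveled scheme
#'
#' d_{n,t} ~ log2(h * n * t^4) / 36, the number of ~18-bit chain primes one
#' classical multiplication consumes.  Fractional values are rounded up when
#' integer chains are built (\code{ceiling = TRUE}).
#'
#' @param n ring degree.
#' @param t plaintext modulus.
#' @param h secret Hamming weight.
#' @param ceiling round up to a whole number of switches.
#' @return numeric depth (or integer when \code{ceiling}).
#' @examples
#' bgvDepth(2^14, 2, 64)            # 24/36
#' bgvDepth(2^14, 2, 64, ceiling = TRUE) # 1
#' @export
bgvDepth <- function(n, t, h, ceiling = FALSE) {
  d <- log2(h * n * t^4) / 36
  if (ceiling) max(1, base::ceiling(d)) else d
}

#' Modulus size of the leveled scheme
#'
#' log2(q) ~ 24 + 1.5*log2(n) + (L - 2) * (11 + 0.5*log2(n)).
#' \code{bgvLogqConstant} and \code{bgvLogqPerLevel} give the displayed
#' integer base term (rounded to nearest) and per-level increment (rounded up
#' — a whole-bit budget per level is the conservative choice when sizing chain
#' primes).
#'
#' @param n ring degree.
#' @param L chain length (L >= 2).
#' @return numeric log2(q).
#' @export
bgvLogq <- function(n, L) {
  stopifnot(L >= 2)
  24 + 1.5 * log2(n) + (L - 2) * (11 + 0.5 * log2(n))
}

#' @rdname bgvLogq
#' @export
bgvLogqConstant <- function(n) floor(24 + 1.5 * log2(n) + 0.5)

#' @rdname bgvLogq
#' @export
bgvLogqPerLevel <- function(n) ceiling(11 + 0.5 * log2(n))

#' Ciphertext sizes
#'
#' A leveled-scheme ciphertext is two ring elements (2 * n * log2(q) bits); a
#' scale-invariant ciphertext is one (n * log2(q) bits).  \code{ctKb} converts
#' to kB (1 kB = 1024 bytes, nearest integer).
#'
#' @param n ring degree.
#' @param log2q modulus size in bits.
#' @return size in bytes.
#' @examples
#' ctKb(bgvCtBytes(8190, 132)) # 264
#' ctKb(yasheCtBytes(1024, 48)) # 6
#' @export
bgvCtBytes <- function(n, log2q) ceiling(2 * n * log2q / 8)

#' @rdname bgvCtBytes
#' @export
yasheCtBytes <- function(n, log2q) ceiling(n * log2q / 8)

#' @param bytes a size in bytes.
#' @rdname bgvCtBytes
#' @export
ctKb <- function(bytes) round(bytes / 1024)

#' Per-level modulus bits of the scale-invariant scheme
#'
#' The dominant per-level term of the noise bound: 2 * log2(n * t) bits of
#' modulus per multiplicative level (displayed rounded to nearest).
#'
#' @param n ring degree.
#' @param t plaintext modulus.
#' @param display round to nearest integer.
#' @export
yashePerLevelBits <- function(n, t, display = TRUE) {
  v <- 2 * log2(n * t)
  if (display) floor(v + 0.5) else v
}

#' RLWE security lower bound on the ring degree
#'
#' phi(m) >= (L * (log2(m) + 23) - 8.5) * (lambda + 110) / 7.2, the
#' Lindner-Peikert-style bound used to size the leveled scheme's ring.  (The
#' printed inequality is ambiguous about grouping; this reading is consistent
#' with the accepted deployments at lambda = 80 and is guarded by consistency
#' checks rather than equalities.)
#'
#' @param L chain length.
#' @param m cyclotomic index.
#' @param lambda security parameter.
#' @return lower bound on phi(m).
#' @export
bgvSecurityMinPhi <- function(L, m, lambda) {
  (L * (log2(m) + 23) - 8.5) * (lambda + 110) / 7.2
}

#' Number of CRT plaintext slots
#'
#' ell = phi(m) / d where d is the multiplicative order modulo m of the prime
#' base of t — the number of irreducible factors of Phi_m modulo t.
#'
#' @param m cyclotomic index.
#' @param t plaintext modulus (power of two or prime), coprime to m.
#' @return integer slot count.
#' @examples
#' slotCount(8191, 2)     # 630
#' slotCount(16384, 8191) # 4096
#' @export
slotCount <- function(m, t) {
  p <- plaintextBase(t)$p
  if (m %% p == 0) stop("no batching: gcd(t, m) > 1")
  as.integer(eulerPhi(m) / multOrderSmall(p %% m, m))
}

#' Smallest power-of-two plaintext modulus for aggregate counts
#'
#' Group aggregates must not wrap modulo t: allele counts reach 2N per group
#' (bound for MAF) and 4N for the case+control sum in the chi-square pipeline.
#'
#' @param N persons per group.
#' @param task "maf" or "chi2".
#' @return the modulus t (e.g. 512 for MAF at N = 200, 1024 for chi2).
#' @export
plaintextModulusFor <- function(N, task = c("maf", "chi2")) {
  task <- match.arg(task)
  bound <- if (task == "maf") 2 * N else 4 * N
  2^ceiling(log2(bound + 1))
}

#' Parameter plan for a task
#'
#' Emits the derivable parameter columns (t, log2 q, n, ell, levels, |ct|) for
#' the requested task under both schemes, using the reference deployment rings
#' (odd m = 5461 or 8191 for the leveled scheme, power-of-two n for the
#' scale-invariant one) unless overridden.
#'
#' @param task one of "maf", "chi2", "hamming", "edit".
#' @param N persons per group (GWAS tasks).
#' @param s number of SNV sites (GWAS tasks; selects the ring by slot count).
#' @param scheme "bgv", "yashe" or "both".
#' @param mBgv,nYashe optional ring overrides.
#' @return data.frame, one row per scheme.
#' @export
planTable <- function(task = c("maf", "chi2", "hamming", "edit"),
                      N = 200, s = 311, scheme = c("both", "bgv", "yashe"),
                      mBgv = NULL, nYashe = NULL) {
  task <- match.arg(task)
  scheme <- match.arg(scheme)
  rows <- list()
  gwas <- task %in% c("maf", "chi2")
  if (scheme %in% c("both", "bgv")) {
    if (gwas) {
      t <- plaintextModulusFor(N, task)
      m <- mBgv
      if (is.null(m)) {
        # reference rings: m = 5461 (phi = 5292, 378 slots) when it fits,
        # else m = 8191 (phi = 8190, 630 slots)
        m <- if (slotCount(5461, t) >= s) 5461 else 8191
        if (slotCount(m, t) < s) stop("planning error: no reference ring with enough slots")
      }
      L <- 3L
    } else {
      t <- 2
      m <- if (is.null(mBgv)) 8191 else mBgv
      L <- if (task == "hamming") 7L else 8L
    }
    n <- eulerPhi(m)
    lq <- bgvLogqConstant(n) + (L - 2) * bgvLogqPerLevel(n)
    rows[[length(rows) + 1]] <- data.frame(
      scheme = "bgv", task = task, t = t, n = n, ell = slotCount(m, t),
      levels = L, log2q = lq, ct_kB = ctKb(bgvCtBytes(n, lq))
    )
  }
  if (scheme %in% c("both", "yashe")) {
    if (gwas) {
      t <- plaintextModulusFor(N, "chi2") # 2^10 covers both statistics
      n <- if (is.null(nYashe)) { if (s <= 1024) 1024 else 4096 } else nYashe
      M <- 0L
      lq <- ceiling(yasheLogqBound(0, n, t, addBudget = 2 * N))
    } else {
      n <- if (is.null(nYashe)) 8192 else nYashe
      t <- 8191 # odd prime splitting x^n + 1 into degree-2 factors
      M <- if (task == "hamming") 6L else 6L
      lq <- ceiling(M * yashePerLevelBits(n, t, display = FALSE))
    }
    # coefficient packing (GWAS tasks) fills all n coefficients: "slots" = n
    ell <- if (gwas) n else slotCount(2 * n, t)
    rows[[length(rows) + 1]] <- data.frame(
      scheme = "yashe", task = task, t = t, n = n, ell = ell,
      levels = M, log2q = lq, ct_kB = ctKb(yasheCtBytes(n, lq))
    )
  }
  do.call(rbind, rows)
}
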