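# internal helpers shared across modules

# canonical decimal-string form for exact integers handed to the C++ layer
bigstr <- function(x) {
  if (is.character(x)) return(x)
  stopifnot(is.numeric(x), all(x == floor(x)), all(abs(x) < 2^53))
  sprintf("%.0f", x)
}

bigAdd <- function(a, b) gs_big_add(bigstr(a), bigstr(b))
bigSub <- function(a, b) gs_big_sub(bigstr(a), bigstr(b))
bigMul <- function(a, b) gs_big_mul(bigstr(a), bigstr(b))
bigMod <- function(a, q) gs_big_mod(bigstr(a), bigstr(q))
bigCmp <- function(a, b) gs_big_cmp(bigstr(a), bigstr(b))
bigDiv <- function(a, b) gs_big_divmod(bigstr(a), bigstr(b))$q
bigLog2 <- function(a) gs_big_log2(bigstr(a))

# 2^k as a decimal string (k may exceed 53-bit-safe range of doubles)
bigPow2 <- function(k) {
  stopifnot(k >= 0)
  x <- "1"
  two <- "2"
  while (k >= 30) {
    x <- gs_big_mul(x, bigstr(2^30))
    k <- k - 30
  }
  if (k > 0) x <- gs_big_mul(x, bigstr(2^k))
  x
}

bigProd <- function(xs) {
  out <- "1"
  for (x in xs) out <- gs_big_mul(out, bigstr(x))
  out
}

# numeric value when it fits exactly in a double, else NA
bigAsNumeric <- function(x) {
  v <- suppressWarnings(as.numeric(x))
  ifelse(!is.na(v) & abs(v) < 2^53, v, NA_real_)
}

isWholeNumber <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) && x == floor(x)

# multiplicative order of a modulo m (a, m small integers, gcd(a, m) = 1)
multOrderSmall <- function(a, m) {
  a <- a %% m
  if (gcdSmall(a, m) != 1) stop("multiplicative order undefined: gcd(a, m) != 1")
  cur <- a %% m
  for (k in seq_len(m)) {
    if (cur == 1) return(k)
    cur <- (cur * a) %% m
  }
  stop("order not found") # unreachable for valid input
}

gcdSmall <- function(a, b) {
  while (b != 0) {
    tmp <- a %% b
    a <- b
    b <- tmp
  }
  a
}

# modular inverse of small integers
modinvSmall <- function(a, m) {
  a <- a %% m
  g <- c(m, a)
  x <- c(0, 1)
  while (g[2] != 0) {
    q <- g[1] %/% g[2]
    g <- c(g[2], g[1] - q * g[2])
    x <- c(x[2], x[1] - q * x[2])
  }
  if (g[1] != 1) stop("not invertible")
  x[1] %% m
}

# prime factorization by trial division (small m)
primeFactors <- function(m) {
  stopifnot(isWholeNumber(m), m >= 1)
  out <- integer(0)
  d <- 2
  while (d * d <= m) {
    while (m %% d == 0) {
      out <- c(out, d)
      m <- m / d
    }
    d <- d + 1
  }
  if (m > 1) out <- c(out, m)
  out
}

eulerPhi <- function(m) {
  if (m == 1) return(1)
  p <- unique(primeFactors(m))
  phi <- m
  for (pp in p) phi <- phi / pp * (pp - 1)
  phi
}

isPowerOfTwo <- function(m) m >= 1 && bitwAnd(as.integer(m), as.integer(m - 1)) == 0

# preserve / restore the global RNG so internal randomized algorithms
# (factor splitting) do not perturb user-visible reproducibility
withLocalSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
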