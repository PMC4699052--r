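# Dense polynomial arithmetic over Z_t for small t (<= a few thousand).
# Vectors are coefficient sequences in ascending powers, values in [0, t).
# Used for the plaintext ring R_t: slot-structure factorization, CRT batching
# bases, and plaintext reference arithmetic.  Coefficient magnitudes during a
# product are bounded by deg * t^2, far inside the exact double range for the
# sizes this package touches.

ptTrim <- function(a) {
  nz <- which(a != 0)
  if (length(nz) == 0) return(0)
  a[seq_len(max(nz))]
}

ptDeg <- function(a) {
  nz <- which(a != 0)
  if (length(nz) == 0) -1L else max(nz) - 1L
}

ptMul <- function(a, b, t) {
  a <- ptTrim(a %% t)
  b <- ptTrim(b %% t)
  if (ptDeg(a) < 0 || ptDeg(b) < 0) return(0)
  la <- length(a)
  lb <- length(b)
  guard <- (t - 1)^2 * min(la, lb)
  stopifnot(guard < 2^52)
  if (la * lb <= 4096) {
    out <- numeric(la + lb - 1)
    for (i in seq_len(la)) {
      if (a[i] != 0) {
        idx <- i:(i + lb - 1)
        out[idx] <- out[idx] + a[i] * b
      }
    }
  } else {
    out <- round(stats::convolve(a, rev(b), type = "open"))
  }
  out %% t
}

ptAdd <- function(a, b, t) {
  n <- max(length(a), length(b))
  (c(a, numeric(n - length(a))) + c(b, numeric(n - length(b)))) %% t
}

ptSub <- function(a, b, t) {
  n <- max(length(a), length(b))
  (c(a, numeric(n - length(a))) - c(b, numeric(n - length(b)))) %% t
}

# long division; leading coefficient of b must be invertible mod t
ptDivmod <- function(a, b, t) {
  a <- ptTrim(a %% t)
  b <- ptTrim(b %% t)
  db <- ptDeg(b)
  if (db < 0) stop("polynomial division by zero")
  linv <- modinvSmall(b[db + 1], t)
  r <- a
  da <- ptDeg(r)
  if (da < db) return(list(q = 0, r = a))
  q <- numeric(da - db + 1)
  while (da >= db) {
    coefv <- (r[da + 1] * linv) %% t
    q[da - db + 1] <- coefv
    idx <- (da - db + 1):(da + 1)
    r[idx] <- (r[idx] - coefv * b) %% t
    da <- ptDeg(r)
  }
  list(q = q, r = ptTrim(r))
}

ptMod <- function(a, b, t) ptDivmod(a, b, t)$r

ptGcd <- function(a, b, t) {
  # t prime
  a <- ptTrim(a %% t)
  b <- ptTrim(b %% t)
  while (ptDeg(b) >= 0) {
    r <- ptMod(a, b, t)
    a <- b
    b <- r
  }
  d <- ptDeg(a)
  if (d < 0) return(0)
  ptMul(a, modinvSmall(a[d + 1], t), t) # monic
}

ptPowmod <- function(h, e, f, t) {
  result <- 1
  base <- ptMod(h, f, t)
  while (e > 0) {
    if (e %% 2 == 1) result <- ptMod(ptMul(result, base, t), f, t)
    base <- ptMod(ptMul(base, base, t), f, t)
    e <- e %/% 2
  }
  result
}

# inverse of a modulo (f, t), t prime
ptInvmod <- function(a, f, t) {
  r0 <- ptTrim(f %% t)
  r1 <- ptMod(a, f, t)
  t0 <- 0
  t1 <- 1
  while (ptDeg(r1) > 0) {
    dm <- ptDivmod(r0, r1, t)
    t2 <- ptSub(t0, ptMul(dm$q, t1, t), t)
    r0 <- r1
    r1 <- dm$r
    t0 <- t1
    t1 <- t2
  }
  if (ptDeg(r1) < 0) stop("element not invertible modulo f")
  ptMod(ptMul(t1, modinvSmall(r1[1], t), t), f, t)
}

# equal-degree factorization of a squarefree F mod prime p whose irreducible
# factors all have degree d (the situation for cyclotomics with gcd(p, m) = 1)
ptEqualDegreeFactors <- function(F, d, p) {
  out <- list()
  stack <- list(ptTrim(F %% p))
  while (length(stack) > 0) {
    f <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    df <- ptDeg(f)
    if (df == d) {
      linv <- modinvSmall(f[df + 1], p)
      out[[length(out) + 1]] <- ptMul(f, linv, p)
      next
    }
    repeat {
      h <- floor(stats::runif(df) * p)
      if (p == 2) {
        # trace map sum_{i=0}^{d-1} h^(2^i) mod f
        g <- ptMod(h, f, 2)
        cur <- g
        for (i in seq_len(d - 1)) {
          cur <- ptMod(ptMul(cur, cur, 2), f, 2)
          g <- ptAdd(g, cur, 2)
        }
      } else {
        g <- ptPowmod(h, (p^d - 1) / 2, f, p)
        g <- ptSub(g, 1, p)
      }
      s <- ptGcd(g, f, p)
      ds <- ptDeg(s)
      if (ds > 0 && ds < df) {
        stack[[length(stack) + 1]] <- s
        stack[[length(stack) + 1]] <- ptDivmod(f, s, p)$q
        break
      }
    }
  }
  # canonical deterministic order: lexicographic on coefficient vectors
  key <- vapply(out, function(f) paste(sprintf("%04d", f), collapse = ""), "")
  out[order(key)]
}

# lift a coprime factorization of Phi mod 2 to mod 2^r (linear Hensel steps)
ptHenselLift2 <- function(factors2, phi, r) {
  if (r == 1) return(factors2)
  ell <- length(factors2)
  # fixed mod-2 data: G_i = prod_{j != i} f_j, u_i = G_i^{-1} mod (f_i, 2)
  u <- vector("list", ell)
  for (i in seq_len(ell)) {
    G <- 1
    for (j in seq_len(ell)) if (j != i) G <- ptMul(G, factors2[[j]], 2)
    u[[i]] <- ptInvmod(G, factors2[[i]], 2)
  }
  cur <- factors2
  for (k in seq_len(r - 1)) {
    mod <- 2^(k + 1)
    P <- 1
    for (i in seq_len(ell)) P <- ptMul(P, cur[[i]], mod)
    diff <- ptSub(phi, P, mod)
    stopifnot(all(diff %% 2^k == 0))
    E <- ptTrim((diff / 2^k) %% 2)
    if (ptDeg(E) < 0) next
    for (i in seq_len(ell)) {
      delta <- ptMod(ptMul(E, u[[i]], 2), factors2[[i]], 2)
      delta <- c(delta, numeric(length(cur[[i]]) - length(delta)))
      cur[[i]] <- (cur[[i]] + 2^k * delta[seq_along(cur[[i]])]) %% mod
    }
  }
  cur
}

# inverse of g modulo (f, 2^r) by Newton lifting from the mod-2 inverse
ptInvmod2r <- function(g, f, r) {
  w <- ptInvmod(g, f, 2)
  k <- 1
  while (k < r) {
    k <- min(2 * k, r)
    mod <- 2^k
    gw <- ptMod(ptMul(g, w, mod), f, mod)
    two <- ptSub(2, gw, mod)
    w <- ptMod(ptMul(w, two, mod), f, mod)
  }
  w
}
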