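# Equality, Hamming, comparison, max and approximate-edit-distance circuits.
#
# Every circuit exists in two message-space forms: the binary form over R_2
# (XOR is addition, AND is multiplication) and the arithmetic form over a
# prime plaintext modulus, obtained from the identities
# x XOR y = (x - y)^2 and x AND y = x * y on {0, 1} inputs.
#
# Circuits are written once against a tiny evaluator interface (add, sub, mul,
# addc, csub) so the same code runs on plaintext slot vectors, on ciphertexts
# of either scheme, and on a depth-counting evaluator used for static depth
# accounting.  Multiplications are arranged in balanced trees: the Hamming
# term folds its 15 equality factors and the presence term into one
# 16-leaf product, giving multiplicative depth 5 (binary form).

# ---- evaluators ----

evalPlain <- function(t) {
  list(
    form = if (t == 2) "binary" else "arithmetic",
    add = function(a, b) (a + b) %% t,
    sub = function(a, b) (a - b) %% t,
    mul = function(a, b) (a * b) %% t,
    addc = function(a, cst) (a + cst) %% t,
    csub = function(cst, a) (cst - a) %% t
  )
}

evalDepth <- function(form) {
  list(
    form = form,
    add = function(a, b) max(a, b),
    sub = function(a, b) max(a, b),
    mul = function(a, b) max(a, b) + 1,
    addc = function(a, cst) a,
    csub = function(cst, a) a
  )
}

evalBGV <- function(keys, params, layout) {
  const <- function(cst) crtPack(rep(cst, layout@ell), layout)
  list(
    form = if (params@ring@t == 2) "binary" else "arithmetic",
    add = function(a, b) bgvAdd(a, b, params),
    sub = function(a, b) bgvSub(a, b, params),
    mul = function(a, b) bgvMult(a, b, keys, params),
    addc = function(a, cst) bgvAddPlain(a, const(cst), params),
    csub = function(cst, a) bgvPlainSub(const(cst), a, params)
  )
}

evalYASHE <- function(keys, params, layout) {
  const <- function(cst) crtPack(rep(cst, layout@ell), layout)
  list(
    form = if (params@ring@t == 2) "binary" else "arithmetic",
    add = function(a, b) yasheAdd(a, b, params),
    sub = function(a, b) yasheSub(a, b, params),
    mul = function(a, b) yasheMult(a, b, keys, params),
    addc = function(a, cst) yasheAddPlain(a, const(cst), params),
    csub = function(cst, a) yashePlainSub(const(cst), a, params)
  )
}

# balanced product tree (minimizes multiplicative depth)
prodTree <- function(ev, xs) {
  while (length(xs) > 1) {
    nxt <- list()
    i <- 1
    while (i + 1 <= length(xs)) {
      nxt[[length(nxt) + 1]] <- ev$mul(xs[[i]], xs[[i + 1]])
      i <- i + 2
    }
    if (i == length(xs)) nxt[[length(nxt) + 1]] <- xs[[i]]
    xs <- nxt
  }
  xs[[1]]
}

# XNOR factor per bit: binary s + s' + 1; arithmetic 1 - (s - s')^2
eqFactors <- function(ev, sx, sy) {
  lapply(seq_along(sx), function(j) {
    if (ev$form == "binary") {
      ev$addc(ev$add(sx[[j]], sy[[j]]), 1)
    } else {
      d <- ev$sub(sx[[j]], sy[[j]])
      ev$csub(1, ev$mul(d, d))
    }
  })
}

circEq <- function(ev, sx, sy) prodTree(ev, eqFactors(ev, sx, sy))

# Hamming term h_i: binary (E(s,s') AND (e+e'+1) + 1) AND f AND f';
# arithmetic (E*((e-e')^2 - 1) + 1)*f*f', evaluated distributed as
# E * eterm * (f*f') + f*f' so the whole product is one balanced tree.
circHammingTerm <- function(ev, ex, fx, sx, ey, fy, sy) {
  if (ev$form == "binary") {
    inner <- prodTree(ev, c(eqFactors(ev, sx, sy), list(ev$addc(ev$add(ex, ey), 1))))
    ev$mul(ev$addc(inner, 1), ev$mul(fx, fy))
  } else {
    d <- ev$sub(ex, ey)
    eterm <- ev$addc(ev$mul(d, d), -1) # (e - e')^2 - 1
    ff <- ev$mul(fx, fy)
    P <- prodTree(ev, c(eqFactors(ev, sx, sy), list(eterm, ff)))
    ev$add(P, ff)
  }
}

# comparison C(x, y) = 1 iff x < y on mu-bit LSB-first words:
# c_1 = (1 - x1) * y1;  c_j = (1 - x_j) y_j + (1 - (x_j - y_j)^2) c_{j-1}
# (binary: c_j = ((x_j + 1) AND y_j) + ((x_j + y_j + 1) AND c_{j-1}))
circCmp <- function(ev, xbits, ybits) {
  mu <- length(xbits)
  notx <- if (ev$form == "binary") ev$addc(xbits[[1]], 1) else ev$csub(1, xbits[[1]])
  c_prev <- ev$mul(notx, ybits[[1]])
  if (mu >= 2) {
    for (j in 2:mu) {
      notx <- if (ev$form == "binary") ev$addc(xbits[[j]], 1) else ev$csub(1, xbits[[j]])
      A <- ev$mul(notx, ybits[[j]])
      B <- if (ev$form == "binary") {
        ev$addc(ev$add(xbits[[j]], ybits[[j]]), 1)
      } else {
        d <- ev$sub(xbits[[j]], ybits[[j]])
        ev$csub(1, ev$mul(d, d))
      }
      c_prev <- ev$add(A, ev$mul(B, c_prev))
    }
  }
  c_prev
}

# j-th bit of max(x, y): x_j + C(x,y) * (x_j + y_j)   (binary; XOR = add)
#                        x_j + C(x,y) * (y_j - x_j)   (arithmetic)
circMaxBits <- function(ev, xbits, ybits, C = NULL) {
  if (is.null(C)) C <- circCmp(ev, xbits, ybits)
  lapply(seq_along(xbits), function(j) {
    dj <- if (ev$form == "binary") {
      ev$add(xbits[[j]], ybits[[j]])
    } else {
      ev$sub(ybits[[j]], xbits[[j]])
    }
    ev$add(xbits[[j]], ev$mul(C, dj))
  })
}

# per-bit approximate-edit term: binary (E AND (f+f'+1) + 1) AND max[j];
# arithmetic max[j] + (E * ((f-f')^2 - 1)) * max[j]
circEditTermBits <- function(ev, fx, sx, fy, sy, xbits, ybits) {
  maxb <- circMaxBits(ev, xbits, ybits)
  if (ev$form == "binary") {
    inner <- prodTree(ev, c(eqFactors(ev, sx, sy), list(ev$addc(ev$add(fx, fy), 1))))
    flip <- ev$addc(inner, 1)
    lapply(maxb, function(mb) ev$mul(flip, mb))
  } else {
    d <- ev$sub(fx, fy)
    fterm <- ev$addc(ev$mul(d, d), -1)
    X <- prodTree(ev, c(eqFactors(ev, sx, sy), list(fterm)))
    lapply(maxb, function(mb) ev$add(mb, ev$mul(X, mb)))
  }
}

# ---- exported plaintext circuit surface ----

asForm <- function(form, t) {
  form <- match.arg(form, c("binary", "arithmetic"))
  if (form == "binary" && t != 2) stop("binary form requires t = 2")
  if (form == "arithmetic" && t == 2) stop("arithmetic form requires t > 2")
  evalPlain(t)
}

toList <- function(m) lapply(seq_len(nrow(m)), function(i) m[i, ])

#' String-equality circuit
#'
#' 1 iff the two bit strings are equal, evaluated as a balanced product of
#' per-bit XNOR terms: binary form AND_j (s_j + s'_j + 1), arithmetic form
#' prod_j (1 - (s_j - s'_j)^2).  Inputs may be vectors of slot values per bit
#' position (matrices: bits in rows, slots in columns).
#'
#' @param s,sp 0/1 vectors of equal length (or matrices of slot columns).
#' @param form "binary" or "arithmetic".
#' @param t plaintext modulus (2 for binary).
#' @param nbits required input length (15 for the SNP-string instance; use a
#'   smaller value for reduced-width checks, or NA to skip the check).
#' @return 0/1 value (or slot vector).
#' @export
eqBits <- function(s, sp, form = c("binary", "arithmetic"), t = if (match.arg(form) == "binary") 2 else 8191,
                   nbits = 15) {
  ev <- asForm(match.arg(form), t)
  if (is.matrix(s)) s <- toList(s) else s <- as.list(s)
  if (is.matrix(sp)) sp <- toList(sp) else sp <- as.list(sp)
  if (length(s) != length(sp)) stop("length mismatch")
  if (!is.na(nbits) && length(s) != nbits) {
    stop(sprintf("expected %d bits per string", nbits))
  }
  circEq(ev, s, sp)
}

#' Hamming-distance term of one merged site
#'
#' Reproduces the per-site value of the reference Hamming algorithm from the
#' encoded inputs (presence flags e, type flags f, 15-bit strings s).
#'
#' @param ex,fx,ey,fy flag values (0/1 scalars or slot vectors).
#' @param sx,sy 15-bit strings: vectors of 15 bits or 15 x slots matrices.
#' @inheritParams eqBits
#' @return per-site 0/1 value.
#' @export
hammingTerm <- function(ex, fx, sx, ey, fy, sy,
                        form = c("binary", "arithmetic"),
                        t = if (match.arg(form) == "binary") 2 else 8191) {
  ev <- asForm(match.arg(form), t)
  sx <- if (is.matrix(sx)) toList(sx) else as.list(sx)
  sy <- if (is.matrix(sy)) toList(sy) else as.list(sy)
  circHammingTerm(ev, ex, fx, sx, ey, fy, sy)
}

#' Less-than comparison circuit on mu-bit words
#'
#' C(x, y) = 1 iff x < y, via the bit-serial recursion
#' c_j = (1 - x_j) y_j + (1 - (x_j - y_j)^2) c_{j-1} (LSB first).
#'
#' @param xbits,ybits LSB-first bit vectors (or bit x slot matrices).
#' @inheritParams eqBits
#' @export
cmpBits <- function(xbits, ybits, form = c("binary", "arithmetic"),
                    t = if (match.arg(form) == "binary") 2 else 8191) {
  ev <- asForm(match.arg(form), t)
  xb <- if (is.matrix(xbits)) toList(xbits) else as.list(xbits)
  yb <- if (is.matrix(ybits)) toList(ybits) else as.list(ybits)
  if (length(xb) != length(yb)) stop("width mismatch")
  circCmp(ev, xb, yb)
}

#' Bitwise maximum circuit
#'
#' max(x, y)[j] = x_j XOR (C(x, y) AND (x_j XOR y_j)); ties return x.
#'
#' @inheritParams cmpBits
#' @return list of mu bit values (LSB first).
#' @export
maxBits <- function(xbits, ybits, form = c("binary", "arithmetic"),
                    t = if (match.arg(form) == "binary") 2 else 8191) {
  ev <- asForm(match.arg(form), t)
  xb <- if (is.matrix(xbits)) toList(xbits) else as.list(xbits)
  yb <- if (is.matrix(ybits)) toList(ybits) else as.list(ybits)
  if (length(xb) != length(yb)) stop("width mismatch")
  circMaxBits(ev, xb, yb)
}

#' Approximate-edit-distance term of one merged site (bit-sliced)
#'
#' Per bit j of the site's edit value:
#' (E(s, s') AND (f + f' + 1) + 1) AND max(D, D')[j].
#'
#' @param fx,fy type flags.
#' @param sx,sy 15-bit strings.
#' @param DxBits,DyBits LSB-first length bits.
#' @inheritParams eqBits
#' @return list of mu bit values (LSB first) whose radix-2 recombination is
#'   the per-site edit value.
#' @export
editTerm <- function(fx, sx, DxBits, fy, sy, DyBits,
                     form = c("binary", "arithmetic"),
                     t = if (match.arg(form) == "binary") 2 else 8191) {
  ev <- asForm(match.arg(form), t)
  sx <- if (is.matrix(sx)) toList(sx) else as.list(sx)
  sy <- if (is.matrix(sy)) toList(sy) else as.list(sy)
  xb <- if (is.matrix(DxBits)) toList(DxBits) else as.list(DxBits)
  yb <- if (is.matrix(DyBits)) toList(DyBits) else as.list(DyBits)
  circEditTermBits(ev, fx, sx, fy, sy, xb, yb)
}

#' Aggregate decrypted per-site circuit outputs
#'
#' \code{aggregateHamming} sums per-site 0/1 terms; \code{aggregateEdit}
#' recombines bit-sliced per-site values as sum_j l_{i,j} * 2^{j-1} and sums
#' over sites.
#'
#' @param values numeric vector of per-site Hamming terms.
#' @export
aggregateHamming <- function(values) sum(values)

#' @param bitmat mu x sites matrix of decrypted bits (LSB-first rows).
#' @param mu bit width.
#' @rdname aggregateHamming
#' @export
aggregateEdit <- function(bitmat, mu = nrow(bitmat)) {
  stopifnot(nrow(bitmat) == mu)
  sum(as.vector(2^(0:(mu - 1)) %*% bitmat))
}

#' Static multiplicative-depth accounting
#'
#' Runs the requested circuit on a depth-counting evaluator (inputs at depth
#' 0) and returns the multiplicative depth it consumes.
#'
#' @param circuit one of "eq", "hamming", "cmp", "max", "edit".
#' @param form "binary" or "arithmetic".
#' @param mu bit width for cmp/max/edit.
#' @return integer depth.
#' @export
circuitDepth <- function(circuit = c("eq", "hamming", "cmp", "max", "edit"),
                         form = c("binary", "arithmetic"), mu = 4) {
  circuit <- match.arg(circuit)
  ev <- evalDepth(match.arg(form))
  z15 <- as.list(numeric(15))
  zmu <- as.list(numeric(mu))
  out <- switch(circuit,
    eq = circEq(ev, z15, z15),
    hamming = circHammingTerm(ev, 0, 0, z15, 0, 0, z15),
    cmp = circCmp(ev, zmu, zmu),
    max = max(unlist(circMaxBits(ev, zmu, zmu))),
    edit = max(unlist(circEditTermBits(ev, 0, z15, 0, z15, zmu, zmu)))
  )
  as.integer(max(unlist(out)))
}

# ---- homomorphic orchestrators ----

blockIndices <- function(nSites, ell) {
  split(seq_len(nSites), ceiling(seq_len(nSites) / ell))
}

encryptSlotVector <- function(v, scheme, keys, params, layout) {
  pt <- crtPack(v, layout)
  if (scheme == "bgv") bgvEncrypt(pt, keys, params) else yasheEncrypt(pt, keys, params)
}

decryptSlots <- function(ct, scheme, keys, params, layout) {
  pt <- if (scheme == "bgv") {
    bgvDecrypt(ct, keys, params)
  } else {
    yasheDecrypt(ct, keys, params)
  }
  crtUnpack(pt, layout)
}

checkDepthBudget <- function(circuit, form, mu, scheme, params) {
  need <- circuitDepth(circuit, form, mu)
  have <- if (is(params, "BGVParams")) params@L - 2L else params@M
  if (need > have) {
    stop(sprintf(
      "pipeline error: circuit needs depth %d but parameters support %d",
      need, have
    ))
  }
  invisible(need)
}

#' Homomorphic Hamming distance over encoded variant sites
#'
#' Encrypts the encoded inputs bitwise with CRT slot batching (sites across
#' slots, block-partitioned when there are more sites than slots), evaluates
#' the Hamming-term circuit, and decrypts and aggregates.  Static depth
#' accounting rejects parameter sets that cannot absorb the circuit before any
#' homomorphic work happens.
#'
#' @param enc encoded sites from \code{\link{encodeSites}}.
#' @param scheme "bgv" (binary form, t = 2) or "yashe" (arithmetic form,
#'   prime t).
#' @param keys,params scheme keys and parameters.
#' @param layout \linkS4class{SlotLayout} matching the scheme's plaintext
#'   modulus.
#' @return list with \code{total}, per-site \code{terms}, and the number of
#'   ciphertext blocks used.
#' @export
heHamming <- function(enc, scheme = c("bgv", "yashe"), keys, params, layout) {
  scheme <- match.arg(scheme)
  form <- if (params@ring@t == 2) "binary" else "arithmetic"
  checkDepthBudget("hamming", form, enc$mu, scheme, params)
  ev <- if (scheme == "bgv") {
    evalBGV(keys, params, layout)
  } else {
    evalYASHE(keys, params, layout)
  }
  blocks <- blockIndices(enc$nSites, layout@ell)
  terms <- numeric(0)
  for (idx in blocks) {
    encv <- function(v) encryptSlotVector(v[idx], scheme, keys, params, layout)
    ctEx <- encv(enc$ex)
    ctEy <- encv(enc$ey)
    ctFx <- encv(enc$fx)
    ctFy <- encv(enc$fy)
    ctSx <- lapply(1:15, function(j) encv(enc$sx[j, ]))
    ctSy <- lapply(1:15, function(j) encv(enc$sy[j, ]))
    out <- circHammingTerm(ev, ctEx, ctFx, ctSx, ctEy, ctFy, ctSy)
    vals <- decryptSlots(out, scheme, keys, params, layout)
    terms <- c(terms, vals[seq_along(idx)])
  }
  list(total = aggregateHamming(terms), terms = terms, blocks = length(blocks))
}

#' Homomorphic approximate edit distance over encoded variant sites
#'
#' As \code{\link{heHamming}}, with the bit-sliced edit-term circuit: one
#' output ciphertext per length bit, recombined after decryption.
#'
#' @inheritParams heHamming
#' @return list with \code{total}, per-site \code{terms}, per-site bit matrix,
#'   and the block count.
#' @export
heEdit <- function(enc, scheme = c("bgv", "yashe"), keys, params, layout) {
  scheme <- match.arg(scheme)
  form <- if (params@ring@t == 2) "binary" else "arithmetic"
  checkDepthBudget("edit", form, enc$mu, scheme, params)
  ev <- if (scheme == "bgv") {
    evalBGV(keys, params, layout)
  } else {
    evalYASHE(keys, params, layout)
  }
  blocks <- blockIndices(enc$nSites, layout@ell)
  bits <- matrix(0, enc$mu, 0)
  for (idx in blocks) {
    encv <- function(v) encryptSlotVector(v[idx], scheme, keys, params, layout)
    ctFx <- encv(enc$fx)
    ctFy <- encv(enc$fy)
    ctSx <- lapply(1:15, function(j) encv(enc$sx[j, ]))
    ctSy <- lapply(1:15, function(j) encv(enc$sy[j, ]))
    ctDx <- lapply(seq_len(enc$mu), function(j) encv(enc$DxBits[j, ]))
    ctDy <- lapply(seq_len(enc$mu), function(j) encv(enc$DyBits[j, ]))
    outBits <- circEditTermBits(ev, ctFx, ctSx, ctFy, ctSy, ctDx, ctDy)
    blockBits <- vapply(outBits, function(ct) {
      decryptSlots(ct, scheme, keys, params, layout)[seq_along(idx)]
    }, numeric(length(idx)))
    bits <- cbind(bits, if (is.matrix(blockBits)) t(blockBits) else matrix(blockBits, enc$mu, length(idx)))
  }
  terms <- as.vector(2^(0:(enc$mu - 1)) %*% bits)
  list(
    total = aggregateEdit(bits, enc$mu), terms = terms, bits = bits,
    blocks = length(blocks)
  )
}

#' Secure sequence comparison, end to end
#'
#' Merges two variant tables, encodes them, and runs the homomorphic Hamming
#' and/or approximate-edit-distance pipelines.
#'
#' @param a,b variant tables (GRanges or data.frames).
#' @param which distances to compute.
#' @param scheme "bgv" or "yashe".
#' @param params,keys,layout optional precomputed scheme objects; generated at
#'   demonstration scale when missing.
#' @param mu length bit width (default from the data).
#' @return list with the merged list, the requested distance results, and the
#'   plaintext reference values.
#' @export
secureDistance <- function(a, b, which = c("hamming", "edit"),
                           scheme = c("bgv", "yashe"), params = NULL,
                           keys = NULL, layout = NULL, mu = NULL) {
  scheme <- match.arg(scheme)
  which <- match.arg(which, several.ok = TRUE)
  merged <- mergeSites(a, b)
  enc <- encodeSites(merged, mu = mu)
  if (is.null(params)) {
    if (scheme == "bgv") {
      params <- bgvParams(1023, 2, 8L, h = 64)
    } else {
      params <- yasheParamsGen(20, 6, 127, 128, omega = 2^24)
    }
  }
  if (is.null(keys)) {
    keys <- if (scheme == "bgv") bgvKeyGen(params) else yasheKeyGen(params)
  }
  if (is.null(layout)) layout <- slotLayout(params@ring@m, params@ring@t)
  out <- list(merged = merged, scheme = scheme)
  if ("hamming" %in% which) {
    out$hamming <- heHamming(enc, scheme, keys, params, layout)
    out$hammingRef <- hammingRef(merged)
  }
  if ("edit" %in% which) {
    out$edit <- heEdit(enc, scheme, keys, params, layout)
    out$editRef <- editRef(merged)
  }
  out
}
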