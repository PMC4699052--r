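# comparison circuits: exhaustive equivalence with integer oracles,
# binary/arithmetic form agreement, depth accounting, homomorphic evaluation

test_that("reduced-width equality circuit matches string equality exhaustively", {
  for (x in 0:15) {
    for (y in 0:15) {
      xb <- bitsOf(x, 4)
      yb <- bitsOf(y, 4)
      want <- as.integer(x == y)
      expect_equal(eqBits(xb, yb, "binary", nbits = 4), want)
      expect_equal(eqBits(xb, yb, "arithmetic", t = 127, nbits = 4), want)
    }
  }
  s <- as.integer(strsplit(encodeSnpBits("GTC"), "")[[1]])
  expect_equal(eqBits(s, s, "binary"), 1)
  s2 <- s
  s2[4] <- 1 - s2[4]
  expect_equal(eqBits(s, s2, "binary"), 0)
  expect_error(eqBits(s[1:10], s[1:10], "binary"), "15 bits")
})

test_that("comparison and max circuits match integer oracles exhaustively (mu = 4)", {
  for (x in 0:15) {
    for (y in 0:15) {
      xb <- bitsOf(x, 4)
      yb <- bitsOf(y, 4)
      cb <- cmpBits(xb, yb, "binary")
      ca <- cmpBits(xb, yb, "arithmetic", t = 127)
      expect_equal(cb, as.integer(x < y))
      expect_equal(ca, cb) # forms agree
      mb <- sum(unlist(maxBits(xb, yb, "binary")) * 2^(0:3))
      ma <- sum(unlist(maxBits(xb, yb, "arithmetic", t = 127)) * 2^(0:3))
      expect_equal(mb, max(x, y))
      expect_equal(ma, max(x, y))
      # C(x,y) + C(y,x) + [x == y] = 1
      expect_equal(cb + cmpBits(yb, xb, "binary") + as.integer(x == y), 1)
    }
  }
  expect_error(cmpBits(bitsOf(3, 4), bitsOf(3, 3), "binary"), "width")
})

test_that("binary and arithmetic forms agree on random full-width inputs", {
  set.seed(81)
  K <- 10000 # slot-vectorized: one call evaluates all K instances
  sx <- matrix(rbinom(15 * K, 1, 0.5), 15, K)
  sy <- matrix(rbinom(15 * K, 1, 0.5), 15, K)
  ex <- rbinom(K, 1, 0.5); ey <- rbinom(K, 1, 0.5)
  fx <- rbinom(K, 1, 0.5); fy <- rbinom(K, 1, 0.5)
  hb <- hammingTerm(ex, fx, sx, ey, fy, sy, "binary")
  ha <- hammingTerm(ex, fx, sx, ey, fy, sy, "arithmetic", t = 8191)
  expect_equal(ha, hb)
  eb <- eqBits(sx, sy, "binary")
  ea <- eqBits(sx, sy, "arithmetic", t = 8191)
  expect_equal(ea, eb)
  mu <- 4
  Dx <- matrix(rbinom(mu * K, 1, 0.5), mu, K)
  Dy <- matrix(rbinom(mu * K, 1, 0.5), mu, K)
  tb <- editTerm(fx, sx, Dx, fy, sy, Dy, "binary")
  ta <- editTerm(fx, sx, Dx, fy, sy, Dy, "arithmetic", t = 8191)
  expect_equal(do.call(rbind, ta), do.call(rbind, tb))
})

test_that("aggregation: zeros, radix recombination, oracle totals", {
  expect_equal(aggregateHamming(numeric(10)), 0)
  expect_equal(aggregateEdit(matrix(0, 3, 5)), 0)
  expect_equal(aggregateEdit(matrix(c(1, 0, 1), 3, 1)), 5) # LSB-first 101 -> 5
  set.seed(82)
  for (i in 1:20) {
    g <- genVcfPair(nSites = 20, seed = 8200 + i)
    enc <- encodeSites(g$merged)
    ht <- hammingTerm(enc$ex, enc$fx, enc$sx, enc$ey, enc$fy, enc$sy, "binary")
    expect_equal(aggregateHamming(ht), g$truth$hamming)
    et <- editTerm(enc$fx, enc$sx, enc$DxBits, enc$fy, enc$sy, enc$DyBits, "binary")
    expect_equal(aggregateEdit(do.call(rbind, et), enc$mu), g$truth$edit)
  }
})

test_that("static depth accounting stays within the published budgets", {
  expect_equal(circuitDepth("eq", "binary"), 4) # ceil(log2 15)
  expect_lte(circuitDepth("hamming", "binary"), 6)
  expect_lte(circuitDepth("hamming", "arithmetic"), 6)
  expect_lte(circuitDepth("edit", "binary", mu = 4), 4 + ceiling(log2(4)) + 2)
  expect_lte(circuitDepth("edit", "arithmetic", mu = 4), 4 + ceiling(log2(4)) + 2)
  # consistent with the published chains: L = depth + 2 gives 7 and 8
  expect_lte(circuitDepth("hamming", "binary") + 2, 7)
  expect_lte(circuitDepth("edit", "binary", mu = 4) + 2, 8)
})

test_that("depth budget is enforced before any homomorphic work", {
  g <- genVcfPair(nSites = 4, seed = 83)
  enc <- encodeSites(g$merged, mu = 4)
  shallow <- yasheParamsGen(20, 1, 127, 128, omega = 2^24) # M = 1 < needed
  lay <- slotLayout(256, 127)
  set.seed(84)
  keys <- yasheKeyGen(shallow)
  expect_error(heHamming(enc, "yashe", keys, shallow, lay), "pipeline error")
  expect_error(heEdit(enc, "yashe", keys, shallow, lay), "pipeline error")
})

test_that("homomorphic evaluation equals circuit equals record-level oracle", {
  g <- genVcfPair(nSites = 12, seed = 85)
  enc <- encodeSites(g$merged, mu = 4)
  set.seed(86)
  pr <- yasheParamsGen(20, 6, 127, 128, omega = 2^24)
  keys <- yasheKeyGen(pr)
  lay <- slotLayout(256, 127)
  hh <- heHamming(enc, "yashe", keys, pr, lay)
  plainTerms <- hammingTerm(enc$ex, enc$fx, enc$sx, enc$ey, enc$fy, enc$sy,
    "arithmetic", t = 127)
  expect_equal(hh$terms, plainTerms) # homomorphic == plaintext circuit
  expect_equal(hh$total, g$truth$hamming) # == record-level algorithm
  he <- heEdit(enc, "yashe", keys, pr, lay)
  expect_equal(he$total, g$truth$edit)
  # identical inputs give zero distance
  g0 <- mergeSites(g$a, g$a)
  enc0 <- encodeSites(g0, mu = 4)
  hh0 <- heHamming(enc0, "yashe", keys, pr, lay)
  expect_equal(hh0$total, 0)
})
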