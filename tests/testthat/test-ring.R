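# cyclotomic ring arithmetic, slot structure, samplers

test_that("cyclotomic polynomials match known forms", {
  expect_equal(cyclotomic(8), c(1, 0, 0, 0, 1)) # x^4 + 1
  expect_equal(cyclotomic(3), c(1, 1, 1))
  expect_equal(cyclotomic(12), c(1, 0, -1, 0, 1)) # x^4 - x^2 + 1
  phi <- cyclotomic(8191) # prime index: 1 + x + ... + x^8190
  expect_length(phi, 8191)
  expect_true(all(phi == 1))
  expect_error(cyclotomic(1.5), "invalid")
  expect_error(cyclotomic(1), "invalid")
})

test_that("ring multiplication: negacyclic wrap, identity, schoolbook oracle", {
  rp <- ringParams(8, 97, 2)
  a <- ringElement(c(0, 0, 0, 1), rp) # x^3
  b <- ringElement(c(0, 1), rp) # x
  expect_equal(coeffs(ringMul(a, b, rp)), c(-1, 0, 0, 0))
  set.seed(21)
  for (m in c(8, 15, 31, 63, 64)) {
    q <- 12289
    rp <- ringParams(m, q, 2)
    n <- rp@n
    one <- ringElement(1, rp)
    for (i in 1:100) {
      av <- sample(-(q %/% 2):(q %/% 2), n, TRUE)
      bv <- sample(-(q %/% 2):(q %/% 2), n, TRUE)
      ra <- ringElement(av, rp)
      expect_equal(coeffs(ringMul(ra, one, rp)), coeffs(ra)) # identity
      got <- coeffs(ringMul(ra, ringElement(bv, rp), rp))
      expect_equal(got, schoolbookRingMul(av, bv, m, q))
    }
  }
  rp31 <- ringParams(31, 97, 2)
  expect_error(
    ringMul(ringElement(1, rp31), ringElement(1, q = 101, m = 31L), rp31),
    "mismatch"
  )
})

test_that("every emitted coefficient is centered in (-q/2, q/2]", {
  set.seed(22)
  rp <- ringParams(15, 101, 2)
  for (i in 1:50) {
    x <- ringMul(
      genoSHE:::sampleUniform(8, 101, 15), genoSHE:::sampleUniform(8, 101, 15), rp
    )
    v <- coeffs(x)
    expect_true(all(v > -101 / 2 & v <= 101 / 2))
  }
})

test_that("slot layouts: ell * d = phi(m), known counts, degenerate case", {
  l7 <- slotLayout(7, 2)
  expect_equal(l7@ell, 2L)
  expect_equal(l7@d, 3L) # ord_7(2) = 3
  for (spec in list(c(7, 2), c(31, 2), c(255, 512), c(256, 127), c(31, 64))) {
    l <- slotLayout(spec[1], spec[2])
    expect_equal(l@ell * l@d, genoSHE:::eulerPhi(spec[1]))
    # product of the factors recovers Phi_m mod the prime base
    p <- if (spec[2] %% 2 == 0) 2 else spec[2]
    prod <- 1
    for (f in l@factors) prod <- genoSHE:::ptMul(prod, f %% p, p)
    expect_equal(
      genoSHE:::ptTrim(prod),
      genoSHE:::ptTrim(cyclotomic(spec[1]) %% p)
    )
  }
  expect_equal(slotCount(8191, 2), 630L)
  expect_equal(slotCount(16384, 8191), 4096L)
  ly <- slotLayout(8191, 2, computeFactors = FALSE)
  expect_equal(ly@ell, 630L)
  expect_equal(ly@d, 13L)
  expect_error(slotLayout(16, 2), "no batching") # (x+1)^n mod 2
})

test_that("CRT packing is a slotwise ring isomorphism (roundtrip, add, mult)", {
  set.seed(23)
  cases <- list(
    list(m = 255, t = 512), # Hensel-lifted power-of-two modulus
    list(m = 31, t = 2), # binary slots
    list(m = 256, t = 127) # prime t over a power-of-two ring
  )
  for (cs in cases) {
    lay <- slotLayout(cs$m, cs$t)
    for (i in 1:40) {
      u <- sample(0:(cs$t - 1), lay@ell, TRUE)
      v <- sample(0:(cs$t - 1), lay@ell, TRUE)
      pu <- crtPack(u, lay)
      pv <- crtPack(v, lay)
      expect_equal(crtUnpack(pu, lay), u)
      expect_equal(crtUnpack(ringAdd(pu, pv), lay), (u + v) %% cs$t)
      prod <- genoSHE:::ptRingMul(
        coeffs(pu) %% cs$t, coeffs(pv) %% cs$t, cs$m, cs$t
      )
      expect_equal(crtUnpack(prod, lay), (u * v) %% cs$t)
    }
    # constants pack to the constant polynomial
    cc <- sample(0:(cs$t - 1), 1)
    pc <- coeffs(crtPack(rep(cc, lay@ell), lay)) %% cs$t
    expect_equal(pc, c(cc, numeric(lay@ell * lay@d - 1)))
    expect_error(crtPack(numeric(lay@ell + 1), lay), "capacity")
  }
})

test_that("sparse ternary sampler has exact weight and balanced signs", {
  set.seed(24)
  for (h in c(0, 1, 16, 64)) {
    s <- sampleTernarySparse(64, h, 12289, 128)
    v <- coeffs(s)
    expect_equal(sum(v != 0), h)
    expect_true(all(v %in% c(-1, 0, 1)))
  }
  expect_error(sampleTernarySparse(16, 17, 97, 32), "invalid parameter")
  # sign balance: over many draws the positive count behaves binomial(h, 1/2)
  h <- 32
  npos <- sum(replicate(300, sum(coeffs(sampleTernarySparse(64, h, 12289, 128)) > 0)))
  total <- 300 * h
  expect_lt(abs(npos - total / 2), 3 * sqrt(total / 4))
})

test_that("truncated Gaussian sampler: support and empirical spread", {
  set.seed(25)
  prof <- noiseProfile(sigma = 8, h = 0)
  draws <- unlist(lapply(1:800, function(i) coeffs(sampleGaussian(128, prof, 12289, 256))))
  expect_true(all(abs(draws) <= prof@B))
  expect_lt(abs(stats::sd(draws) - 8) / 8, 0.1) # within 10% at ~1e5 samples
  prof2 <- noiseProfile() # leveled-scheme default
  expect_equal(prof2@sigma, 3.2)
  expect_equal(noiseProfile(sigma = 8)@B, 48) # B = 6*sigma
})
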