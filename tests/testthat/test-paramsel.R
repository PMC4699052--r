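# parameter-estimation formulas

test_that("multiplication depth d_{n,t}", {
  expect_equal(bgvDepth(2^14, 2, 64), 24 / 36)
  expect_equal(bgvDepth(2^14, 2, 64, ceiling = TRUE), 1)
  expect_equal(bgvDepth(2^14, 2^10, 64), (6 + 14 + 40) / 36)
  # monotone nondecreasing in each argument
  expect_true(bgvDepth(2^15, 2, 64) > bgvDepth(2^14, 2, 64))
  expect_true(bgvDepth(2^14, 4, 64) > bgvDepth(2^14, 2, 64))
  expect_true(bgvDepth(2^14, 2, 128) > bgvDepth(2^14, 2, 64))
})

test_that("leveled-scheme modulus size: displayed constants at n = 8190", {
  expect_equal(bgvLogqConstant(8190), 43)
  expect_equal(bgvLogqPerLevel(8190), 18)
  # the L = 3 minus L = 2 difference is exactly 11 + log2(n)/2
  expect_equal(bgvLogq(8190, 3) - bgvLogq(8190, 2), 11 + 0.5 * log2(8190))
  expect_equal(round(bgvLogq(8190, 2)), 43)
})

test_that("ciphertext sizes reproduce the published cells", {
  expect_equal(ctKb(bgvCtBytes(8190, 132)), 264) # leveled, Hamming ring
  expect_equal(yasheCtBytes(1024, 48), 6144) # exactly 6 kB
  expect_equal(ctKb(yasheCtBytes(1024, 48)), 6)
  expect_equal(ctKb(yasheCtBytes(8192, 384)), 384)
})

test_that("scale-invariant modulus bound: per-level bits and M = 1 form", {
  expect_equal(yashePerLevelBits(8192, 8191), 52)
  # M = 1 reduces to log2(12 n^2 t sigma l_w w) + log2(t)
  n <- 128; t <- 127; sigma <- 8; w <- 2^24
  b1 <- yasheLogqBound(1, n, t, sigma, w)
  lw <- floor(b1 / 24) + 1
  expect_equal(b1, log2(12 * n^2 * t * sigma * lw * w) + log2(t), tolerance = 1e-6)
})

test_that("security lower bound is monotone and consistent with deployments", {
  expect_true(bgvSecurityMinPhi(8, 8191, 80) > bgvSecurityMinPhi(7, 8191, 80))
  expect_true(bgvSecurityMinPhi(7, 8191, 128) > bgvSecurityMinPhi(7, 8191, 80))
  expect_lte(bgvSecurityMinPhi(7, 8191, 80), 8190) # Hamming ring accepted
  expect_lte(bgvSecurityMinPhi(8, 8191, 80), 8190) # edit ring accepted
  expect_lte(bgvSecurityMinPhi(3, 5461, 80), 5292) # GWAS ring accepted
})

test_that("task planning reproduces plaintext moduli and slot counts", {
  expect_equal(plaintextModulusFor(200, "maf"), 512) # 400 < t
  expect_equal(plaintextModulusFor(200, "chi2"), 1024) # 800 < t
  tab <- planTable("maf", N = 200, s = 311)
  expect_equal(tab$t[tab$scheme == "bgv"], 512)
  expect_equal(tab$ell[tab$scheme == "bgv"], 378L) # phi(5461)/ord(2) = 5292/14
  expect_equal(tab$n[tab$scheme == "bgv"], 5292)
  tab2 <- planTable("chi2", N = 200, s = 311)
  expect_equal(tab2$t[tab2$scheme == "bgv"], 1024)
  th <- planTable("hamming")
  expect_equal(th$t[th$scheme == "bgv"], 2)
  expect_equal(th$ell[th$scheme == "bgv"], 630)
  expect_equal(th$levels[th$scheme == "bgv"], 7)
  expect_equal(th$ell[th$scheme == "yashe"], 4096)
  expect_equal(planTable("edit")$levels[1], 8)
})

test_that("size relations between the schemes match the regime analysis", {
  # around log2(n) ~ 14, h = 64, M >= 4: the scale-invariant scheme needs the
  # larger modulus, but its single-element ciphertexts stay smaller than the
  # two-element ones at matched parameters
  n <- 2^14
  t <- 8191
  for (M in 4:8) {
    L <- M * bgvDepth(n, t, 64, ceiling = TRUE) + 2
    lqB <- bgvLogq(n, L)
    lqY <- 2 * M * log2(n * t)
    expect_gt(lqY, lqB)
    expect_gt(bgvCtBytes(n, lqB), yasheCtBytes(n, lqY))
  }
})
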