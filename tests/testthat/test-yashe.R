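# scale-invariant scheme

test_that("key generation: f invertible, f = t*f' + 1, public-key identity", {
  pr <- toyYasheParams()
  ring <- pr@ring
  set.seed(41)
  for (i in 1:20) {
    keys <- yasheKeyGen(pr)
    one <- coeffs(ringMul(keys@f, keys@finv, ring))
    expect_equal(one, c(1, numeric(ring@n - 1)))
    # f == 1 mod t by construction
    expect_equal(genoSHE:::gs_poly_mod_small(keys@f@coeffs, ring@t),
      c(1, numeric(ring@n - 1)))
    # [f * hpub]_q = t*g: small (ternary g scaled by t)
    fh <- ringMul(keys@f, keys@hpub, ring)
    expect_lte(as.numeric(genoSHE:::ringLinf(fh)), ring@t)
    v <- coeffs(fh)
    expect_true(all(v %% ring@t == 0))
  }
})

test_that("encryption round-trips; inherent noise is small and measurable", {
  pr <- toyYasheParams()
  keys <- toyYasheKeys()
  t <- pr@ring@t
  set.seed(42)
  for (i in 1:200) {
    msg <- sample(0:(t - 1), pr@ring@n, TRUE)
    ct <- yasheEncrypt(msg, keys, pr)
    expect_equal(coeffs(yasheDecrypt(ct, keys, pr)) %% t, msg)
  }
  z <- numeric(pr@ring@n)
  expect_equal(coeffs(yasheDecrypt(yasheEncrypt(z, keys, pr), keys, pr)), z)
  ct <- yasheEncrypt(z, keys, pr)
  nz <- yasheNoise(ct, keys, pr)
  expect_false(nz$failed)
  # fresh inherent noise far below the correctness bound q/(2t)
  bound <- genoSHE:::bigLog2(pr@ring@q) - log2(2 * t)
  expect_lt(genoSHE:::bigLog2(nz$linf), bound - 4)
})

test_that("homomorphic add and mult agree with the plaintext ring", {
  pr <- toyYasheParams()
  keys <- toyYasheKeys()
  t <- pr@ring@t
  m <- pr@ring@m
  set.seed(43)
  for (i in 1:50) {
    u <- sample(0:(t - 1), pr@ring@n, TRUE)
    v <- sample(0:(t - 1), pr@ring@n, TRUE)
    ca <- yasheEncrypt(u, keys, pr)
    cb <- yasheEncrypt(v, keys, pr)
    expect_equal(coeffs(yasheDecrypt(yasheAdd(ca, cb, pr), keys, pr)) %% t, (u + v) %% t)
    got <- coeffs(yasheDecrypt(yasheMult(ca, cb, keys, pr), keys, pr)) %% t
    expect_equal(got, genoSHE:::ptRingMul(u, v, m, t))
  }
  u <- sample(0:(t - 1), pr@ring@n, TRUE)
  ca <- yasheEncrypt(u, keys, pr)
  co <- yasheEncrypt(c(1, numeric(pr@ring@n - 1)), keys, pr)
  expect_equal(coeffs(yasheDecrypt(yasheMult(ca, co, keys, pr), keys, pr)) %% t, u)
})

test_that("M sequential squarings succeed at parameters generated for M", {
  pr <- toyYasheParams() # M = 3
  keys <- toyYasheKeys()
  t <- pr@ring@t
  ct <- yasheEncrypt(c(3, numeric(pr@ring@n - 1)), keys, pr)
  val <- 3
  for (k in seq_len(pr@M)) {
    ct <- yasheMult(ct, ct, keys, pr)
    val <- (val^2) %% t
    expect_equal(level(ct), k)
  }
  expect_equal(coeffs(yasheDecrypt(ct, keys, pr))[1] %% t, val)
  expect_error(yasheMult(ct, ct, keys, pr), "depth-budget")
})

test_that("word decomposition: reconstruction, zero, inner-product identity", {
  pr <- toyYasheParams()
  ring <- pr@ring
  set.seed(44)
  for (i in 1:50) {
    a <- genoSHE:::sampleUniform(ring@n, ring@q, ring@m)
    D <- wordDecompose(a, pr)
    expect_length(D, pr@lw)
    # digits centered in (-w/2, w/2]
    for (d in D) {
      dv <- coeffs(d)
      w <- as.numeric(pr@omega)
      expect_true(all(dv > -w / 2 & dv <= w / 2))
    }
    rec <- genoSHE:::ringZero(ring)
    wp <- "1"
    for (j in seq_along(D)) {
      rec <- ringAdd(rec, genoSHE:::ringScalMul(D[[j]], wp))
      wp <- genoSHE:::bigMul(wp, pr@omega)
    }
    expect_identical(rec@coeffs, a@coeffs)
    b <- genoSHE:::sampleUniform(ring@n, ring@q, ring@m)
    P <- powersOf(b, pr)
    ip <- genoSHE:::ringZero(ring)
    for (j in seq_along(D)) ip <- ringAdd(ip, ringMul(D[[j]], P[[j]], ring))
    expect_identical(ip@coeffs, ringMul(a, b, ring)@coeffs)
  }
  z <- ringElement(numeric(0), q = ring@q, m = ring@m)
  expect_true(all(vapply(wordDecompose(z, pr), function(d) all(coeffs(d) == 0), TRUE)))
})

test_that("decryption rounding survives noise just below q/(2t)", {
  pr <- toyYasheParams()
  keys <- toyYasheKeys()
  ring <- pr@ring
  t <- ring@t
  set.seed(45)
  delta <- genoSHE:::bigDiv(ring@q, t)
  vb <- genoSHE:::bigSub(genoSHE:::bigDiv(ring@q, 2 * t), sprintf("%d", t + 2))
  msg <- sample(0:(t - 1), ring@n, TRUE)
  mC <- ringElement(msg, q = t, m = ring@m)
  target <- ringAdd(
    genoSHE:::ringScalMul(genoSHE:::ringLift(mC, ring@q), delta),
    ringElement(rep(vb, ring@n), q = ring@q, m = ring@m)
  )
  ct <- new("YASHECiphertext", c = ringMul(keys@finv, target, ring),
    depth = 0L, noiseLog2 = 0)
  expect_equal(suppressWarnings(coeffs(yasheDecrypt(ct, keys, pr)) %% t), msg)
})

test_that("parameter generation: prime q = 1 mod m above the noise bound", {
  pr <- yasheParamsGen(20, 0, 1024, 64, addBudget = 100)
  expect_true(genoSHE:::gs_is_prime(pr@ring@q))
  expect_equal(genoSHE:::gs_big_mod_small(pr@ring@q, 128), 1)
  expect_gte(genoSHE:::bigLog2(pr@ring@q), yasheLogqBound(0, 64, 1024, addBudget = 100))
  # published deployment: the 2M log2(nt) lower bound at M = 6, n = 8192,
  # t = 8191 is ~312 bits; the 384-bit modulus clears it
  expect_gte(384, 2 * 6 * log2(8192 * 8191))
  expect_equal(ceiling(2 * 6 * log2(8192 * 8191)), 312)
  # the bound is increasing in M
  bs <- vapply(1:6, function(M) yasheLogqBound(M, 128, 127, omega = 2^24), 0)
  expect_true(all(diff(bs) > 0))
  # ciphertext size bookkeeping: one ring element of n ceil(log2 q)-bit words
  bits <- 64 * ceiling(genoSHE:::bigLog2(pr@ring@q))
  expect_equal(yasheCtBytes(64, ceiling(genoSHE:::bigLog2(pr@ring@q))), ceiling(bits / 8))
})
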