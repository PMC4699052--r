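# leveled modulus-switching scheme

test_that("key generation satisfies the RLWE construction identities", {
  pr <- toyBgvParams()
  set.seed(31)
  for (i in 1:20) {
    keys <- bgvKeyGen(pr)
    # [b - a*s]_q is t times a small error
    e <- ringSub(keys@pk$b, ringMul(keys@pk$a, keys@sk, pr@ring))
    expect_true(all(genoSHE:::gs_poly_mod_small(e@coeffs, pr@ring@t) == 0))
    expect_equal(sum(coeffs(keys@sk) != 0), pr@noise@h) # exact weight
  }
  # chain structure: q_i | q_{i+1}
  for (i in seq_len(pr@L - 1)) {
    dm <- genoSHE:::gs_big_divmod(pr@moduli[i + 1], pr@moduli[i])
    expect_identical(dm$r, "0")
  }
})

test_that("encryption round-trips and is randomized", {
  pr <- toyBgvParams()
  keys <- toyBgvKeys()
  t <- pr@ring@t
  set.seed(32)
  for (i in 1:200) {
    msg <- sample(0:(t - 1), pr@ring@n, TRUE)
    ct <- bgvEncrypt(msg, keys, pr)
    expect_equal(coeffs(bgvDecrypt(ct, keys, pr)) %% t, msg)
  }
  z <- numeric(pr@ring@n)
  expect_equal(coeffs(bgvDecrypt(bgvEncrypt(z, keys, pr), keys, pr)), z)
  c1 <- bgvEncrypt(z, keys, pr)
  c2 <- bgvEncrypt(z, keys, pr)
  expect_false(identical(c1@c0@coeffs, c2@c0@coeffs))
})

test_that("homomorphic add and mult agree with the plaintext ring, slotwise", {
  pr <- toyBgvParams()
  keys <- toyBgvKeys()
  t <- pr@ring@t
  lay <- slotLayout(pr@ring@m, t) # 6 slots of degree 5
  set.seed(33)
  for (i in 1:40) {
    u <- sample(0:(t - 1), lay@ell, TRUE)
    v <- sample(0:(t - 1), lay@ell, TRUE)
    ca <- bgvEncrypt(crtPack(u, lay), keys, pr)
    cb <- bgvEncrypt(crtPack(v, lay), keys, pr)
    expect_equal(crtUnpack(bgvDecrypt(bgvAdd(ca, cb, pr), keys, pr), lay), (u + v) %% t)
    expect_equal(crtUnpack(bgvDecrypt(bgvSub(ca, cb, pr), keys, pr), lay), (u - v) %% t)
    expect_equal(crtUnpack(bgvDecrypt(bgvMult(ca, cb, keys, pr), keys, pr), lay), (u * v) %% t)
  }
  # ct + Enc(0) preserves the plaintext; Enc(a) * Enc(1) = a
  u <- sample(0:(t - 1), lay@ell, TRUE)
  ca <- bgvEncrypt(crtPack(u, lay), keys, pr)
  cz <- bgvEncrypt(crtPack(numeric(lay@ell), lay), keys, pr)
  co <- bgvEncrypt(crtPack(rep(1, lay@ell), lay), keys, pr)
  expect_equal(crtUnpack(bgvDecrypt(bgvAdd(ca, cz, pr), keys, pr), lay), u)
  expect_equal(crtUnpack(bgvDecrypt(bgvMult(ca, co, keys, pr), keys, pr), lay), u)
})

test_that("each multiplication consumes one level; the chain bottoms out", {
  pr <- toyBgvParams() # L = 4
  keys <- toyBgvKeys()
  lay <- slotLayout(pr@ring@m, pr@ring@t)
  ct <- bgvEncrypt(crtPack(rep(1, lay@ell), lay), keys, pr)
  expect_equal(level(ct), pr@L - 1L)
  ct <- bgvMult(ct, ct, keys, pr) # aligned to L-2, result one lower
  expect_equal(level(ct), pr@L - 3L)
  ct <- bgvMult(ct, ct, keys, pr)
  expect_equal(level(ct), 0L)
  expect_error(bgvMult(ct, ct, keys, pr), "depth-budget")
  expect_equal(crtUnpack(bgvDecrypt(ct, keys, pr), lay), rep(1, lay@ell))
})

test_that("modulus switching preserves plaintexts and rescales noise", {
  pr <- toyBgvParams()
  keys <- toyBgvKeys()
  t <- pr@ring@t
  set.seed(34)
  nc <- genoSHE:::bgvNoiseConsts(pr@ring, pr@noise)
  for (i in 1:100) {
    msg <- sample(0:(t - 1), pr@ring@n, TRUE)
    ct <- bgvEncrypt(msg, keys, pr)
    sw <- bgvModSwitch(ct, 1, pr)
    expect_equal(level(sw), 1L)
    expect_equal(coeffs(bgvDecrypt(sw, keys, pr)) %% t, msg)
    # measured noise after the switch is within 2x of old * q'/q plus the
    # additive rounding bound
    old <- as.numeric(bgvNoise(ct, keys, pr)$linf)
    newN <- as.numeric(bgvNoise(sw, keys, pr)$linf)
    ratio <- 2^(genoSHE:::bigLog2(pr@moduli[2]) - genoSHE:::bigLog2(pr@moduli[4]))
    expect_lt(newN, 2 * (old * ratio + 2^nc$msAddLog2))
  }
  ct <- bgvEncrypt(numeric(pr@ring@n), keys, pr)
  same <- bgvModSwitch(ct, level(ct), pr) # switching to own level is identity
  expect_identical(same@c0@coeffs, ct@c0@coeffs)
  expect_error(bgvModSwitch(ct, -1, pr), "invalid")
})

test_that("key switching collapses s^2 ciphertexts without changing plaintexts", {
  pr <- toyBgvParams()
  keys <- toyBgvKeys()
  t <- pr@ring@t
  ring <- pr@ring
  set.seed(35)
  for (i in 1:30) {
    u <- sample(0:(t - 1), ring@n, TRUE)
    v <- sample(0:(t - 1), ring@n, TRUE)
    l <- pr@L - 2L
    ca <- bgvModSwitch(bgvEncrypt(u, keys, pr), l, pr)
    cb <- bgvModSwitch(bgvEncrypt(v, keys, pr), l, pr)
    ql <- pr@moduli[l + 1]
    d0 <- ringMul(ca@c0, cb@c0, ring, q = ql)
    d1 <- ringAdd(ringMul(ca@c0, cb@c1, ring, q = ql), ringMul(ca@c1, cb@c0, ring, q = ql))
    d2 <- ringMul(ca@c1, cb@c1, ring, q = ql)
    # three-component decryption oracle: [d0 - s*d1 + s^2*d2]_q mod t
    s <- genoSHE:::ringLift(keys@sk, ql)
    s2 <- ringMul(s, s, ring, q = ql)
    raw <- ringAdd(ringSub(d0, ringMul(s, d1, ring, q = ql)), ringMul(s2, d2, ring, q = ql))
    want <- genoSHE:::gs_poly_mod_small(raw@coeffs, t)
    sw <- bgvSwitchKey(list(d0 = d0, d1 = d1, d2 = d2, level = l, noiseLog2 = 30), keys, pr)
    expect_equal(coeffs(bgvDecrypt(sw, keys, pr)) %% t, want)
  }
  # switching (c0, c1, 0) is plaintext-neutral
  ct <- bgvModSwitch(bgvEncrypt(sample(0:(t - 1), ring@n, TRUE), keys, pr), pr@L - 2L, pr)
  z <- genoSHE:::ringZero(ring, ct@c0@q)
  sw <- bgvSwitchKey(list(d0 = ct@c0, d1 = ct@c1, d2 = z, level = level(ct), noiseLog2 = 10), keys, pr)
  expect_equal(coeffs(bgvDecrypt(sw, keys, pr)), coeffs(bgvDecrypt(ct, keys, pr)))
})

test_that("decryption failure is detected, never silent", {
  pr <- toyBgvParams()
  keys <- toyBgvKeys()
  set.seed(36)
  ct <- bgvEncrypt(numeric(pr@ring@n), keys, pr)
  expect_false(bgvNoise(ct, keys, pr)$failed)
  # noise of a fresh ciphertext is below noise after one multiplication
  ct2 <- bgvMult(ct, ct, keys, pr)
  fresh <- bgvNoise(bgvModSwitch(ct, level(ct2), pr), keys, pr)
  expect_true(genoSHE:::bigCmp(bgvNoise(ct2, keys, pr)$linf, fresh$linf) >= 0 ||
    as.numeric(fresh$linf) < 4) # both tiny is acceptable
  # shifting c0 by ~q/2 flips the failure signal
  half <- genoSHE:::gs_big_divmod(ct@c0@q, "2")$q
  bad <- ct
  bad@c0 <- ringAdd(ct@c0, ringElement(rep(half, pr@ring@n), q = ct@c0@q, m = pr@ring@m))
  expect_warning(bgvDecrypt(bad, keys, pr), class = "genoSHE_decryption_failure")
})

test_that("parameter generation meets its postconditions", {
  pr <- bgvParamsGen(20, 3, 512)
  expect_s4_class(pr, "BGVParams")
  expect_gte(pr@ring@n, bgvSecurityMinPhi(3, pr@ring@m, 20))
  expect_true(genoSHE:::bigCmp(pr@moduli[1], "512") > 0) # q_0 > t
  # the published lambda = 80 deployments satisfy the bound
  expect_lte(bgvSecurityMinPhi(7, 8191, 80), 8190)
  expect_lte(bgvSecurityMinPhi(3, 8191, 80), 8190)
  expect_error(bgvParamsGen(80, 7, 2, mMax = 99), "parameter-search failure")
})
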