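# Task-1 packing, decoding and statistics

test_that("slot packing places codes at slot positions", {
  lay <- slotLayout(31, 64)
  pt <- packSlots(c(2, 1, 0), lay)
  expect_equal(crtUnpack(pt, lay), c(2, 1, 0, 0, 0, 0))
  expect_equal(coeffs(packSlots(numeric(3), lay)), numeric(30))
  expect_error(packSlots(numeric(7), lay), "capacity")
  # sum of packed persons = per-SNV column sums
  set.seed(71)
  gm <- matrix(sample(0:2, 5 * 6, TRUE), 5, 6)
  acc <- packSlots(gm[1, ], lay)
  for (i in 2:5) acc <- ringAdd(acc, packSlots(gm[i, ], lay))
  expect_equal(crtUnpack(acc, lay), colSums(gm))
})

test_that("coefficient packing: layout, polynomial count, column-sum recovery", {
  gm <- matrix(c(2, 1, 0, 1, 0, 2, 1, 1), 2, 4, byrow = TRUE)
  pk <- packCoeffs(gm, 8)
  expect_length(pk$polys, 1) # n' = 2 persons fit one polynomial
  expect_equal(pk$polys[[1]], c(2, 1, 0, 1, 0, 2, 1, 1))
  gm5 <- matrix(sample(0:2, 5 * 4, TRUE), 5, 4)
  pk5 <- packCoeffs(gm5, 8)
  expect_length(pk5$polys, 3) # ceiling(5 / 2)
  total <- Reduce(`+`, pk5$polys)
  expect_equal(decodeCountsCoeffs(total, 4, 2), colSums(gm5))
  expect_error(packCoeffs(gm, 2), "more SNVs")
})

test_that("count decoding: coefficient formula and the n' = 1 identity", {
  expect_equal(decodeCountsCoeffs(c(1, 2, 3, 4), 2, 2), c(4, 6))
  expect_equal(decodeCountsCoeffs(c(5, 6, 7, 8), 4, 1), c(5, 6, 7, 8))
})

test_that("MAF closed form", {
  expect_equal(maf(300, 200), 0.25) # min(300, 100)/400
  expect_equal(maf(0, 200), 0)
  expect_equal(maf(400, 200), 0)
  expect_error(maf(401, 200), "out of range")
  set.seed(72)
  for (i in 1:100) {
    col <- sample(0:2, 30, TRUE)
    expect_equal(maf(sum(col), 30), mafRef(col))
  }
})

test_that("signed decoding, exhaustively at t = 64", {
  expect_equal(decodeSigned(1000, 1024), -24)
  expect_equal(decodeSigned(100, 1024), 100)
  expect_equal(decodeSigned(32, 64), 32) # boundary maps to +t/2
  for (x in -31:31) expect_equal(decodeSigned(x %% 64, 64), x)
  expect_error(decodeSigned(64, 64), "out of")
})

test_that("chi-square closed form and monomorphic handling", {
  expect_equal(chi2(500, 100, 200), 160 / 3)
  expect_equal(chi2(500, 0, 200), 0)
  expect_warning(v <- chi2(0, 0, 200), "monomorphic")
  expect_true(is.nan(v))
  expect_warning(chi2(800, 0, 200), "monomorphic")
})

test_that("the pipeline refuses plaintext-space wraparound", {
  g <- genCaseControl(nCase = 20, nControl = 20, s = 4, seed = 73)
  small <- yasheParamsGen(20, 0, 64, 16, addBudget = 200) # t = 64 < 4N = 80
  expect_error(
    secureGwas(g$case, g$control, "yashe", params = small),
    "no-wraparound"
  )
})

test_that("homomorphic aggregation equals plaintext sums under both packings", {
  g <- genCaseControl(nCase = 8, nControl = 8, s = 6, seed = 74)
  set.seed(75)
  # leveled scheme, slot packing
  prB <- toyBgvParams() # t = 64 > 4*8
  keysB <- toyBgvKeys()
  lay <- slotLayout(31, 64)
  cts <- lapply(1:8, function(i) bgvEncrypt(packSlots(codes(g$case)[i, ], lay), keysB, prB))
  agg <- heSum(cts, prB)
  expect_equal(
    decodeCountsSlots(bgvDecrypt(agg, keysB, prB), lay, 6),
    unname(g$truth$nA_case)
  )
  expect_error(heSum(list(), prB), "empty")
  # scale-invariant scheme, coefficient packing
  prY <- yasheParamsGen(20, 0, 512, 16, addBudget = 64)
  keysY <- yasheKeyGen(prY)
  pk <- packCoeffs(g$case, 16)
  ctsY <- lapply(pk$polys, function(v) yasheEncrypt(v, keysY, prY))
  aggY <- heSum(ctsY, prY)
  expect_equal(
    unname(decodeCountsCoeffs(yasheDecrypt(aggY, keysY, prY), 6, pk$nPrime)),
    unname(g$truth$nA_case)
  )
})

test_that("sum/difference ciphertext pair decodes to sums and signed differences", {
  g <- genCaseControl(nCase = 8, nControl = 8, s = 6, seed = 76)
  set.seed(77)
  prB <- toyBgvParams()
  keysB <- toyBgvKeys()
  lay <- slotLayout(31, 64)
  encAgg <- function(gm) {
    heSum(lapply(1:8, function(i) {
      bgvEncrypt(packSlots(codes(gm)[i, ], lay), keysB, prB)
    }), prB)
  }
  ctCase <- encAgg(g$case)
  ctCont <- encAgg(g$control)
  pair <- chi2Pair(ctCase, ctCont, prB)
  sums <- decodeCountsSlots(bgvDecrypt(pair$plus, keysB, prB), lay, 6)
  diffs <- decodeSigned(decodeCountsSlots(bgvDecrypt(pair$minus, keysB, prB), lay, 6), 64)
  expect_equal(sums, unname(g$truth$nA_case + g$truth$nA_control))
  expect_equal(diffs, unname(g$truth$nA_case - g$truth$nA_control))
  # conservation: total of the sum slots equals case + control totals
  expect_equal(sum(sums), sum(g$truth$nA_case) + sum(g$truth$nA_control))
  # identical groups give all-zero differences
  pairSame <- chi2Pair(ctCase, ctCase, prB)
  expect_equal(
    decodeCountsSlots(bgvDecrypt(pairSame$minus, keysB, prB), lay, 6),
    numeric(6)
  )
})
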