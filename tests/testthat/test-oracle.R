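# plaintext reference algorithms

mkMerged <- function(a, b) mergeSites(a, b)

test_that("Hamming reference follows the printed branch order", {
  a <- data.frame(chrom = "1", pos = 1, sv = "SUB", ref = "A", alt = "G")
  b <- data.frame(chrom = "1", pos = 1, sv = "SUB", ref = "A", alt = "T")
  expect_equal(hammingRef(mkMerged(a, b)), 1) # same ref, different alt
  expect_equal(hammingRef(mkMerged(a, a)), 0) # identical lists
  # INS/DEL branch wins even against a mismatching partner or absence
  ai <- data.frame(chrom = "1", pos = 1, sv = "INS", ref = "A", alt = "ACG")
  expect_equal(hammingRef(mkMerged(ai, b)), 0)
  b2 <- data.frame(chrom = "1", pos = 2, sv = "SUB", ref = "C", alt = "T")
  expect_equal(hammingRef(mkMerged(ai, b2)), 1) # INS site 0, one-sided site 1
  # one-sided SUB counts 1
  expect_equal(hammingRef(mkMerged(a, b2)), 2)
})

test_that("edit-distance reference: identity, absence, length rule", {
  a <- data.frame(chrom = "1", pos = 1, sv = "DEL", ref = "ACGT", alt = "A")
  b0 <- a[0, ]
  b0 <- data.frame(chrom = "1", pos = 2, sv = "SUB", ref = "C", alt = "G")
  expect_equal(editRef(mkMerged(a, a)), 0)
  # DEL(ref ACGT) vs absent -> 4; one-sided SUB -> 1
  expect_equal(editRef(mkMerged(a, b0)), 5)
  a2 <- data.frame(chrom = "1", pos = 1, sv = "SUB", ref = "AC", alt = "GG")
  b2 <- data.frame(chrom = "1", pos = 1, sv = "SUB", ref = "AC", alt = "GGT")
  expect_error(mergeSites(a2, b2), NA)
  # same ref, alts of lengths 2 and 3 -> max = 3
  suppressWarnings(expect_equal(editRef(mkMerged(a2, b2)), 3))
})

test_that("contingency-table chi-square: zero difference, worked value, margins", {
  expect_equal(chi2TableRef(300, 100, 300, 100), 0)
  expect_equal(chi2TableRef(300, 100, 200, 200), 160 / 3)
  fr <- chi2TableRef(300, 100, 200, 200, frac = TRUE)
  expect_equal(fr[1] / fr[2], 160 / 3)
  expect_warning(res <- chi2TableRef(400, 0, 400, 0), "monomorphic")
  expect_true(is.nan(res))
})

test_that("simplified chi-square equals the contingency form for ALL tables, N <= 10", {
  for (N in c(2, 5, 10)) {
    for (nA in 0:(2 * N)) {
      for (nAp in 0:(2 * N)) {
        sum <- nA + nAp
        if (sum == 0 || sum == 4 * N) next
        a <- chi2TableRef(nA, 2 * N - nA, nAp, 2 * N - nAp, frac = TRUE)
        b <- chi2(sum, nA - nAp, N, frac = TRUE)
        # exact rational equality via cross-multiplication
        expect_identical(a[1] * b[2], a[2] * b[1])
      }
    }
  }
})

test_that("MAF reference counts alleles exactly", {
  expect_equal(mafRef(c("AA", "AA")), 0) # all AA: nA = 2N
  expect_equal(mafRef(c("AA", "AB")), 0.25) # nA = 3, nB = 1
  expect_equal(mafRef(c(2, 1)), 0.25) # code input
  set.seed(61)
  for (i in 1:100) {
    col <- sample(0:2, 20, TRUE)
    nA <- sum(col)
    expect_equal(mafRef(col), min(nA, 40 - nA) / 40)
  }
})
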