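# genomic encodings

test_that("genotype codes follow AA -> 2, AB -> 1, BB -> 0", {
  expect_equal(encodeGenotype("AA"), 2)
  expect_equal(encodeGenotype("AB"), 1)
  expect_equal(encodeGenotype("BB"), 0)
  expect_error(encodeGenotype("AC"), "encoding error")
  expect_true(is.na(encodeGenotype("AC", strict = FALSE)))
})

test_that("site merging: union size, absent sides, deterministic order, errors", {
  a <- data.frame(
    chrom = "1", pos = c(10, 20, 30), sv = "SUB",
    ref = "A", alt = c("C", "G", "T"), stringsAsFactors = FALSE
  )
  b <- data.frame(
    chrom = "1", pos = c(40, 50), sv = "SUB",
    ref = "A", alt = c("C", "G"), stringsAsFactors = FALSE
  )
  m <- mergeSites(a, b)
  expect_equal(nrow(m), 5) # disjoint: |A| + |B|
  expect_true(all(xor(m$x_present, m$y_present)))
  expect_equal(m$pos, c(10, 20, 30, 40, 50))
  m2 <- mergeSites(a, a)
  expect_equal(nrow(m2), 3) # identical files: no absent side
  expect_true(all(m2$x_present & m2$y_present))
  dup <- rbind(a, a[1, ])
  expect_error(mergeSites(dup, b), "duplicate position")
  # randomized union-size law |A| + |B| - overlap
  set.seed(51)
  for (i in 1:20) {
    pa <- sample(1:200, 30)
    pb <- sample(1:200, 25)
    fa <- data.frame(chrom = "2", pos = pa, sv = "SUB", ref = "A", alt = "C")
    fb <- data.frame(chrom = "2", pos = pb, sv = "SUB", ref = "A", alt = "G")
    expect_equal(nrow(mergeSites(fa, fb)), length(union(pa, pb)))
  }
  # shared positions with different REF strings are flagged loudly
  aa <- data.frame(chrom = "1", pos = 5, sv = "SUB", ref = "AC", alt = "GT")
  bb <- data.frame(chrom = "1", pos = 5, sv = "SUB", ref = "TG", alt = "CA")
  expect_warning(mergeSites(aa, bb), "different REF")
})

test_that("flags: presence e, INS/DEL flag f, absent side gets (0, 1)", {
  a <- data.frame(chrom = "1", pos = c(1, 2, 3), sv = c("SUB", "INS", "DEL"),
    ref = c("A", "A", "AC"), alt = c("C", "AG", "A"), stringsAsFactors = FALSE)
  b <- data.frame(chrom = "1", pos = c(1, 9), sv = "SUB", ref = c("A", "G"),
    alt = c("C", "T"), stringsAsFactors = FALSE)
  m <- mergeSites(a, b)
  f1 <- encodeFlags(m[m$pos == 1, ]) # both SUB
  expect_equal(unname(f1), c(1, 1, 1, 1))
  f2 <- encodeFlags(m[m$pos == 2, ]) # x INS, y absent
  expect_equal(unname(f2), c(1, 0, 0, 1))
  f3 <- encodeFlags(m[m$pos == 3, ]) # x DEL, y absent
  expect_equal(unname(f3), c(1, 0, 0, 1))
  f4 <- encodeFlags(m[m$pos == 9, ]) # x absent, y SUB
  expect_equal(unname(f4), c(0, 1, 1, 1))
})

test_that("15-bit SNP strings: worked example, padding, absence, capacity", {
  expect_equal(encodeSnpBits("GTC"), "011110100000000")
  expect_equal(encodeSnpBits("A"), "001000000000000")
  expect_equal(encodeSnpBits("x", present = FALSE), "000000000000000")
  expect_equal(nchar(encodeSnpBits("ACGTACG")), 15) # 7 bases fill the string
  expect_error(encodeSnpBits("ACGTACGT"), "capacity")
  expect_error(encodeSnpBits("AXG"), "A,C,G,T")
})

test_that("the trailing-1 padding makes the encoding injective (lengths <= 3)", {
  alph <- c("A", "C", "G", "T")
  strs <- c(
    "", alph,
    apply(expand.grid(alph, alph), 1, paste, collapse = ""),
    apply(expand.grid(alph, alph, alph), 1, paste, collapse = "")
  )
  encs <- vapply(strs, encodeSnpBits, "")
  expect_equal(anyDuplicated(encs), 0)
  expect_false(encodeSnpBits("", present = FALSE) %in% encs) # absent distinct
})

test_that("genotype lengths: absent 0, DEL uses ref, otherwise alt", {
  expect_equal(genotypeLength("SUB", "A", "C", present = FALSE), 0)
  expect_equal(genotypeLength("DEL", "ACGT", "A"), 4)
  expect_equal(genotypeLength("INS", "A", "AAG"), 3)
  expect_equal(genotypeLength("SUB", "AC", "GT"), 2)
})

test_that("encoding is semantics-preserving: circuits equal the record-level algorithms", {
  set.seed(52)
  for (rep in 1:10) {
    g <- genVcfPair(nSites = 25, seed = 5200 + rep)
    enc <- encodeSites(g$merged)
    ht <- hammingTerm(enc$ex, enc$fx, enc$sx, enc$ey, enc$fy, enc$sy, "binary")
    expect_equal(aggregateHamming(ht), hammingRef(g$merged))
    et <- editTerm(enc$fx, enc$sx, enc$DxBits, enc$fy, enc$sy, enc$DyBits, "binary")
    expect_equal(aggregateEdit(do.call(rbind, et), enc$mu), editRef(g$merged))
  }
})
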