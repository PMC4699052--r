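# Genomic encodings: genotype codes, merged variant lists, presence and
# variant-type flags, 15-bit SNP strings, and genotype lengths.

#' Encode a genotype as an integer
#'
#' AA -> 2, AB -> 1, BB -> 0 (the count of allele A).  The mapping is
#' allele-symbol agnostic: homozygous major / heterozygous / homozygous minor.
#'
#' @param gt genotype string.
#' @param strict error on anything else; when FALSE, return
#'   \code{missingCode}.
#' @param missingCode value for unknown genotypes in non-strict mode.
#' @return integer code.
#' @examples
#' encodeGenotype("AA") # 2
#' encodeGenotype("AB") # 1
#' @export
encodeGenotype <- function(gt, strict = TRUE, missingCode = NA_real_) {
  code <- c(AA = 2, AB = 1, BB = 0)[gt]
  if (is.na(code)) {
    if (strict) stop(sprintf("encoding error: unknown genotype '%s'", gt))
    return(missingCode)
  }
  unname(code)
}

#' Construct a GenotypeMatrix
#'
#' @param codes integer matrix persons x SNVs with entries in \{0,1,2\}, or a
#'   character matrix of genotypes AA/AB/BB.
#' @param group group label.
#' @return a \linkS4class{GenotypeMatrix}.
#' @export
genotypeMatrix <- function(codes, group = "group") {
  if (is.character(codes)) {
    codes <- matrix(vapply(codes, encodeGenotype, 0),
      nrow = nrow(codes), dimnames = dimnames(codes)
    )
  }
  storage.mode(codes) <- "integer"
  new("GenotypeMatrix", codes = codes, group = group)
}

#' @rdname nPersons
#' @export
setMethod("nPersons", "GenotypeMatrix", function(x) nrow(x@codes))

#' @rdname nSnvs
#' @export
setMethod("nSnvs", "GenotypeMatrix", function(x) ncol(x@codes))

#' @rdname codes
#' @export
setMethod("codes", "GenotypeMatrix", function(x) x@codes)

setMethod("show", "GenotypeMatrix", function(object) {
  cat(sprintf(
    "GenotypeMatrix '%s': %d persons x %d SNVs\n",
    object@group, nrow(object@codes), ncol(object@codes)
  ))
})

# normalize variant input (GRanges from readVcfSubset, or a data.frame with
# chrom/pos/sv/ref/alt) to a plain data.frame
asVariantFrame <- function(x) {
  if (is(x, "GRanges")) {
    df <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(x)),
      pos = GenomicRanges::start(x),
      sv = as.character(S4Vectors::mcols(x)$sv),
      ref = as.character(S4Vectors::mcols(x)$ref),
      alt = as.character(S4Vectors::mcols(x)$alt),
      stringsAsFactors = FALSE
    )
    return(df)
  }
  stopifnot(all(c("chrom", "pos", "sv", "ref", "alt") %in% names(x)))
  as.data.frame(x)[, c("chrom", "pos", "sv", "ref", "alt")]
}

validateVariants <- function(df, label) {
  if (!all(df$sv %in% c("SUB", "INS", "DEL"))) {
    stop(sprintf("%s: structural-variant type must be SUB, INS or DEL", label))
  }
  if (!all(grepl("^[ACGT]+$", df$ref)) || !all(grepl("^[ACGT]*$", df$alt))) {
    stop(sprintf("%s: ref/alt must be over {A,C,G,T}", label))
  }
  if (any(df$pos < 1)) stop(sprintf("%s: positions must be >= 1", label))
  key <- paste(df$chrom, df$pos)
  if (anyDuplicated(key)) {
    stop(sprintf("%s: duplicate position within one file", label))
  }
  df
}

#' Merge two variant lists by position
#'
#' One row per (chrom, pos) in the union of the two lists, in deterministic
#' (chrom, pos) order; a side with no record at a position is marked absent.
#' Two records at the same position with different REF strings are legal input
#' but the distance algorithms then take their literal fall-through branches;
#' such sites are reported loudly.
#'
#' @param a,b variant tables (GRanges from \code{\link{readVcfSubset}} or
#'   data.frames with chrom, pos, sv, ref, alt).
#' @return the merged list: a data.frame with chrom, pos, x_present, x_sv,
#'   x_ref, x_alt, y_present, y_sv, y_ref, y_alt.
#' @export
mergeSites <- function(a, b) {
  da <- validateVariants(asVariantFrame(a), "first variant list")
  db <- validateVariants(asVariantFrame(b), "second variant list")
  keyA <- paste(da$chrom, da$pos)
  keyB <- paste(db$chrom, db$pos)
  keys <- union(keyA, keyB)
  chrom <- sub(" .*$", "", keys)
  pos <- as.numeric(sub("^.* ", "", keys))
  ord <- order(chrom, pos)
  keys <- keys[ord]
  ia <- match(keys, keyA)
  ib <- match(keys, keyB)
  merged <- data.frame(
    chrom = chrom[ord], pos = pos[ord],
    x_present = !is.na(ia),
    x_sv = ifelse(is.na(ia), "", da$sv[ia]),
    x_ref = ifelse(is.na(ia), "", da$ref[ia]),
    x_alt = ifelse(is.na(ia), "", da$alt[ia]),
    y_present = !is.na(ib),
    y_sv = ifelse(is.na(ib), "", db$sv[ib]),
    y_ref = ifelse(is.na(ib), "", db$ref[ib]),
    y_alt = ifelse(is.na(ib), "", db$alt[ib]),
    stringsAsFactors = FALSE
  )
  both <- merged$x_present & merged$y_present
  mismat <- both & merged$x_ref != merged$y_ref
  if (any(mismat)) {
    warning(sprintf(
      "%d shared position(s) carry different REF strings; the distance circuits compare ALT strings only and may disagree with the record-level algorithms there (positions: %s)",
      sum(mismat), paste(utils::head(merged$pos[mismat], 5), collapse = ", ")
    ))
  }
  merged
}

#' Presence and variant-type flags of a merged site
#'
#' e = 1 iff the participant has a record at the site; f = 0 iff that record's
#' type is INS or DEL.  An absent side gets (e, f) = (0, 1): f must stay 1 so
#' the f*f' factor of the Hamming circuit does not cancel the
#' one-side-missing case.
#'
#' @param site one row of a merged list.
#' @return named vector c(e_x, f_x, e_y, f_y).
#' @export
encodeFlags <- function(site) {
  fx <- if (site$x_present && site$x_sv %in% c("INS", "DEL")) 0L else 1L
  fy <- if (site$y_present && site$y_sv %in% c("INS", "DEL")) 0L else 1L
  c(
    e_x = as.integer(site$x_present), f_x = fx,
    e_y = as.integer(site$y_present), f_y = fy
  )
}

#' 15-bit encoding of an alternate-allele string
#'
#' Each base is two bits (A -> 00, G -> 01, C -> 10, T -> 11), concatenated,
#' then a single 1 is appended (so that e.g. "A" and "AA" stay distinct and no
#' encoding collides with the absent-site all-zero string), then zero-padded
#' to 15 bits.  At most 7 bases fit.
#'
#' @param alt base string over \{A,C,G,T\} (may be empty: pad-only encoding).
#' @param present encode as the all-zero string when FALSE (missing site).
#' @return character string of 15 bits.
#' @examples
#' encodeSnpBits("GTC") # "011110100000000"
#' @export
encodeSnpBits <- function(alt, present = TRUE) {
  if (!present) return(strrep("0", 15))
  if (nchar(alt) > 7) stop("capacity error: alternate string longer than 7 bases")
  if (nchar(alt) > 0 && !grepl("^[ACGT]+$", alt)) stop("alt must be over {A,C,G,T}")
  map <- c(A = "00", G = "01", C = "10", T = "11")
  bits <- paste0(paste(map[strsplit(alt, "")[[1]]], collapse = ""), "1")
  paste0(bits, strrep("0", 15 - nchar(bits)))
}

#' Genotype length of a record
#'
#' 0 for an absent side; the reference length for a deletion; the alternate
#' length otherwise.
#'
#' @param sv "SUB", "INS" or "DEL" (ignored when \code{present} is FALSE).
#' @param ref,alt base strings.
#' @param present FALSE for an absent side.
#' @return non-negative integer length.
#' @export
genotypeLength <- function(sv, ref, alt, present = TRUE) {
  refLengthD(present, sv, ref, alt)
}

bitsLsbFirst <- function(x, mu) {
  stopifnot(x < 2^mu)
  (x %/% 2^(0:(mu - 1))) %% 2
}

#' Bit-level encoding of a merged list
#'
#' Produces the inputs of the distance circuits: presence/type flag vectors,
#' 15 x n bit matrices of the two sides' SNP strings, genotype lengths and
#' their mu-bit LSB-first bit matrices.  A deletion contributes its reference
#' length to D but its alternate string to s (both files share the reference,
#' so only alternate strings are compared).
#'
#' @param merged a merged list from \code{\link{mergeSites}}.
#' @param mu length bit width; default the smallest width covering max(D)
#'   (at most 4, since alternate strings are capped at 7 bases).
#' @return list with ex, fx, ey, fy (integer vectors), sx, sy (15 x n 0/1
#'   matrices), Dx, Dy (integer vectors), DxBits, DyBits (mu x n matrices),
#'   mu, and nSites.
#' @export
encodeSites <- function(merged, mu = NULL) {
  n <- nrow(merged)
  fl <- t(vapply(seq_len(n), function(i) encodeFlags(merged[i, ]), integer(4)))
  sxStr <- vapply(seq_len(n), function(i) {
    encodeSnpBits(merged$x_alt[i], merged$x_present[i])
  }, "")
  syStr <- vapply(seq_len(n), function(i) {
    encodeSnpBits(merged$y_alt[i], merged$y_present[i])
  }, "")
  toBits <- function(s) as.integer(strsplit(s, "")[[1]])
  sx <- vapply(sxStr, toBits, integer(15))
  sy <- vapply(syStr, toBits, integer(15))
  Dx <- vapply(seq_len(n), function(i) {
    as.integer(refLengthD(merged$x_present[i], merged$x_sv[i], merged$x_ref[i], merged$x_alt[i]))
  }, 0L)
  Dy <- vapply(seq_len(n), function(i) {
    as.integer(refLengthD(merged$y_present[i], merged$y_sv[i], merged$y_ref[i], merged$y_alt[i]))
  }, 0L)
  if (is.null(mu)) {
    mu <- max(1, ceiling(log2(max(Dx, Dy, 1) + 1)))
  }
  list(
    ex = fl[, "e_x"], fx = fl[, "f_x"], ey = fl[, "e_y"], fy = fl[, "f_y"],
    sx = unname(sx), sy = unname(sy), Dx = Dx, Dy = Dy,
    DxBits = vapply(Dx, bitsLsbFirst, numeric(mu), mu = mu),
    DyBits = vapply(Dy, bitsLsbFirst, numeric(mu), mu = mu),
    mu = mu, nSites = n
  )
}
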