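# File formats: VCF subsets (via vcfR), genotype CSVs, results TSVs, and the
# JSON cipher container used to stage keys/ciphertexts between pipeline
# invocations.  The container is plain text with exact decimal coefficient
# strings and an md5 checksum; roundtrips are bit-exact.

#' Read a VCF-subset file
#'
#' Expects the standard eight columns; the structural-variant type is taken
#' from the INFO key SVTYPE when present, otherwise inferred from the ref/alt
#' lengths (longer ref: DEL; longer alt: INS; equal: SUB).  Multi-allelic ALT
#' fields are rejected.
#'
#' @param path VCF file (uncompressed or gzipped).
#' @return a GRanges with metadata columns sv, ref, alt.
#' @examples
#' vcf <- system.file("extdata", "synthetic_participant_a.vcf", package = "genoSHE")
#' readVcfSubset(vcf)
#' @export
readVcfSubset <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  if (any(grepl(",", alt))) {
    stop("multi-allelic ALT fields are not supported")
  }
  info <- vcfR::getINFO(v)
  sv <- sub("^.*SVTYPE=([A-Z]+).*$", "\\1", info)
  noKey <- !grepl("SVTYPE=", info)
  ref <- fix[, "REF"]
  sv[noKey] <- ifelse(nchar(ref[noKey]) > nchar(alt[noKey]), "DEL",
    ifelse(nchar(ref[noKey]) < nchar(alt[noKey]), "INS", "SUB")
  )
  df <- data.frame(
    chrom = fix[, "CHROM"], pos = as.numeric(fix[, "POS"]),
    sv = sv, ref = ref, alt = alt, stringsAsFactors = FALSE
  )
  bad <- which(!df$sv %in% c("SUB", "INS", "DEL"))
  if (length(bad)) {
    stop(sprintf("malformed row %d: SVTYPE '%s'", bad[1], df$sv[bad[1]]))
  }
  variantGRanges(validateVariants(df, path))
}

#' Write a VCF-subset file
#'
#' @param gr GRanges with sv, ref, alt metadata (or an equivalent data.frame).
#' @param path output file.
#' @export
writeVcfSubset <- function(gr, path) {
  df <- asVariantFrame(gr)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.1",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Type of structural variant\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  ), con)
  writeLines(sprintf(
    "%s\t%d\t.\t%s\t%s\t.\t.\tSVTYPE=%s",
    df$chrom, as.integer(df$pos), df$ref, df$alt, df$sv
  ), con)
  invisible(path)
}

#' Read / write a genotype CSV (persons x SNVs, values AA/AB/BB)
#'
#' @param path CSV file; first column holds person identifiers.
#' @param group group label for the resulting object.
#' @return a \linkS4class{GenotypeMatrix}.
#' @export
readGenotypeCsv <- function(path, group = basename(path)) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE,
    colClasses = "character")
  m <- as.matrix(df)
  genotypeMatrix(m, group)
}

#' @param gm a \linkS4class{GenotypeMatrix}.
#' @rdname readGenotypeCsv
#' @export
writeGenotypeCsv <- function(gm, path) {
  lab <- c(`2` = "AA", `1` = "AB", `0` = "BB")
  m <- matrix(lab[as.character(gm@codes)], nrow = nrow(gm@codes))
  rownames(m) <- sprintf("person%d", seq_len(nrow(m)))
  colnames(m) <- sprintf("snv%d", seq_len(ncol(m)))
  utils::write.csv(m, path)
  invisible(path)
}

#' Write a results table as TSV
#' @param df data.frame of results.
#' @param path output file.
#' @export
writeResultsTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- JSON cipher container ----

containerClasses <- c(
  "NoiseProfile", "RingParams", "RingElement", "SlotLayout",
  "BGVParams", "BGVKeys", "BGVCiphertext",
  "YASHEParams", "YASHEKeys", "YASHECiphertext", "GenotypeMatrix"
)

encodeObj <- function(x) {
  if (isS4(x) && class(x)[1] %in% containerClasses) {
    out <- list(`.class` = class(x)[1])
    for (sn in methods::slotNames(class(x))) {
      out[[sn]] <- encodeObj(methods::slot(x, sn))
    }
    return(out)
  }
  if (is.matrix(x)) {
    return(list(
      `.matrix` = TRUE, dim = dim(x), mode = storage.mode(x),
      data = as.vector(x)
    ))
  }
  if (is.list(x)) {
    return(list(`.list` = TRUE, names = names(x) %||% character(0),
      items = lapply(x, encodeObj)))
  }
  list(`.atomic` = TRUE, mode = storage.mode(x), data = x)
}

decodeObj <- function(x) {
  if (!is.list(x)) return(x)
  if (!is.null(x$.class)) {
    cls <- x$.class
    args <- list(Class = cls)
    for (sn in setdiff(names(x), ".class")) args[[sn]] <- decodeObj(x[[sn]])
    return(do.call(methods::new, args))
  }
  if (isTRUE(x$.matrix)) {
    d <- unlist(x$data)
    if (length(d) == 0) d <- vector(x$mode, 0)
    storage.mode(d) <- x$mode
    dims <- unlist(x$dim)
    return(matrix(d, nrow = dims[1], ncol = dims[2]))
  }
  if (isTRUE(x$.list)) {
    items <- lapply(x$items, decodeObj)
    nm <- unlist(x$names)
    if (length(nm)) names(items) <- nm
    return(items)
  }
  if (isTRUE(x$.atomic)) {
    d <- unlist(x$data)
    if (is.null(d)) d <- vector(x$mode, 0)
    storage.mode(d) <- x$mode
    return(d)
  }
  lapply(x, decodeObj)
}

#' Write / read the cipher container
#'
#' A versioned JSON document carrying any of this package's key, parameter,
#' ciphertext or data objects (coefficients as exact decimal strings) plus an
#' md5 checksum of the payload.  \code{readCipherContainer} verifies the
#' checksum before decoding.
#'
#' @param obj object (or named list of objects) to store.
#' @param path file path.
#' @param meta optional named list of plain metadata.
#' @export
writeCipherContainer <- function(obj, path, meta = list()) {
  payload <- jsonlite::toJSON(encodeObj(obj), auto_unbox = TRUE, digits = NA)
  tmp <- tempfile()
  writeLines(payload, tmp)
  doc <- list(
    magic = "genoSHE-container", version = 1L,
    checksum = unname(tools::md5sum(tmp)),
    meta = meta,
    payload = jsonlite::fromJSON(payload, simplifyVector = FALSE)
  )
  unlink(tmp)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = FALSE)
  invisible(path)
}

#' @rdname writeCipherContainer
#' @export
readCipherContainer <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(doc$magic, "genoSHE-container")) {
    stop("not a genoSHE container")
  }
  payload <- jsonlite::toJSON(doc$payload, auto_unbox = TRUE, digits = NA)
  tmp <- tempfile()
  writeLines(payload, tmp)
  ok <- identical(unname(tools::md5sum(tmp)), doc$checksum)
  unlink(tmp)
  if (!ok) stop("container checksum mismatch")
  list(obj = decodeObj(doc$payload), meta = doc$meta)
}
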