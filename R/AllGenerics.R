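#' Coefficient modulus of an object
#' @param x object carrying a modulus.
#' @return decimal string.
#' @export
setGeneric("modulus", function(x) standardGeneric("modulus"))

#' Coefficients of a ring element
#'
#' Centered coefficients in (-q/2, q/2].  Returned as numerics when every
#' coefficient is exactly representable in a double, otherwise as decimal
#' strings.
#' @param x a \linkS4class{RingElement}.
#' @param strings force character output.
#' @return numeric or character vector of length n.
#' @export
setGeneric("coeffs", function(x, strings = FALSE) standardGeneric("coeffs"))

#' Number of plaintext slots
#' @param x a \linkS4class{SlotLayout} or scheme parameter object.
#' @export
setGeneric("nSlots", function(x) standardGeneric("nSlots"))

#' Ciphertext level (position in the modulus chain)
#' @param x a ciphertext.
#' @export
setGeneric("level", function(x) standardGeneric("level"))

#' Number of persons in a genotype matrix
#' @param x a \linkS4class{GenotypeMatrix}.
#' @export
setGeneric("nPersons", function(x) standardGeneric("nPersons"))

#' Number of SNV sites in a genotype matrix
#' @param x a \linkS4class{GenotypeMatrix}.
#' @export
setGeneric("nSnvs", function(x) standardGeneric("nSnvs"))

#' Genotype codes
#' @param x a \linkS4class{GenotypeMatrix}.
#' @return integer matrix, persons x SNVs, entries in {0,1,2}.
#' @export
setGeneric("codes", function(x) standardGeneric("codes"))
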