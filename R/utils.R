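#' Amino-acid alphabet used throughout the package
#'
#' The 20 standard residues plus \code{X} for any unknown or non-standard
#' residue.  \code{X} scores zero against every residue.
#' @return Character vector of length 21.
#' @export
aa_alphabet <- function() {
  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
    "M", "F", "P", "S", "T", "W", "Y", "V", "X")
}

# integer-encode a sequence against the package alphabet (X = 21)
encode_seq <- function(s) {
  idx <- match(strsplit(toupper(s), "")[[1]], aa_alphabet())
  idx[is.na(idx)] <- 21L
  idx
}

decode_seq <- function(idx) paste(aa_alphabet()[idx], collapse = "")

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
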