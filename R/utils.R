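#' @keywords internal
"_PACKAGE"

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of nucleotide strings
#'
#' Vectorised reverse complement over the \{A,C,G,T,N\} alphabet.
#'
#' @param x Character vector of uppercase nucleotide strings.
#' @return Character vector of the same length.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# seq string -> integer codes 1..5 for A,C,G,T,N
encode_seq <- function(seq) {
  codes <- match(strsplit(seq, "", fixed = TRUE)[[1]], c(DNA_BASES, "N"))
  if (anyNA(codes)) {
    stop("sequence contains characters outside {A,C,G,T,N}")
  }
  codes
}

validate_seq <- function(seq, strict, what = "sequence") {
  seq <- toupper(seq)
  bad <- grepl("[^ACGTN]", seq)
  if (any(bad)) {
    if (strict) {
      stop(sprintf("%s contains characters outside {A,C,G,T,N}", what))
    }
    seq[bad] <- gsub("[^ACGTN]", "N", seq[bad])
  }
  seq
}

`%||%` <- function(a, b) if (is.null(a)) b else a
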