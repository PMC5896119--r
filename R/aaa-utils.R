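# Shared low-level sequence helpers.

DNA_ALPHABET <- c("A", "C", "G", "T", "N")

#' Reverse-complement a nucleotide string
#'
#' @param x character vector of DNA strings (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x))
  out <- vapply(x, function(s) {
    if (nchar(s) == 0L) return("")
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1), USE.NAMES = FALSE)
  out
}

#' Translate a nucleotide string with the standard genetic code
#'
#' Codons containing `N` translate to `X` and never count as stop codons.
#'
#' @param nt nucleotide string; length must be divisible by 3.
#' @return character vector of single-letter amino acids (`*` for stop).
#' @keywords internal
codon_translate <- function(nt) {
  n <- nchar(nt)
  if (n %% 3L != 0L) {
    stop("sequence length ", n, " is not divisible by 3")
  }
  if (n == 0L) return(character(0))
  starts <- seq.int(1L, n, by = 3L)
  codons <- substring(nt, starts, starts + 2L)
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"
  aa
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

norm_dna <- function(x, what = "sequence") {
  x <- toupper(x)
  bad <- grepl(sprintf("[^%s]", paste(DNA_ALPHABET, collapse = "")), x)
  if (any(bad)) {
    stop("invalid characters in ", what,
         " (allowed: ", paste(DNA_ALPHABET, collapse = ","), ")")
  }
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a
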