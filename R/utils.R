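# Small shared helpers.

#' Reverse-complement nucleotide sequences
#'
#' Strings may contain IUPAC ambiguity codes; complementation follows the
#' IUPAC table (e.g. `R` <-> `Y`).
#'
#' @param x character vector of nucleotide sequences.
#' @return character vector of reverse complements.
#' @export
#' @examples
#' revcomp("ATGAAA")  # "TTTCAT"
revcomp <- function(x) {
  stopifnot(is.character(x))
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  unname(out)
}

# split a sequence string into single characters
seq_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

# split a CDS into codon strings; length must be divisible by 3
codon_split <- function(cds) {
  n <- nchar(cds)
  if (n %% 3L != 0L) {
    stop("CDS length (", n, ") is not divisible by 3")
  }
  substring(cds, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
}

# deterministic integer sub-seeds derived from one master seed
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
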