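#' @useDynLib caprimir, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import Biostrings
#' @importFrom GenomicRanges GRanges findOverlaps seqnames start end strand
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits mcols
#' @importFrom stats pnbinom rpois rbinom rlnorm runif setNames sd
#' @importFrom utils write.table read.table
NULL

# normalise a nucleotide string to uppercase RNA (T -> U); errors on other
# characters
normalize_rna <- function(x) {
  y <- chartr("acgut", "ACGUU", x)
  y <- chartr("T", "U", y)
  if (grepl("[^ACGU]", y)) stop("sequence contains a non-ACGU/T character")
  y
}

# normalise to uppercase DNA (U -> T); N allowed if allow_n
normalize_dna <- function(x, allow_n = FALSE) {
  y <- chartr("acgtun", "ACGTTN", x)
  y <- chartr("U", "T", y)
  pat <- if (allow_n) "[^ACGTN]" else "[^ACGT]"
  if (any(grepl(pat, y))) stop("sequence contains an invalid character")
  y
}

# reverse complement of DNA strings (character in, character out)
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# percentage of A+U (A+T) bases in a sequence
au_percent <- function(x) {
  x <- normalize_dna(x)
  n <- nchar(x)
  at <- vapply(strsplit(x, ""), function(ch) sum(ch %in% c("A", "T")), 1L)
  100 * at / n
}

# random DNA of given lengths from a uniform base distribution
random_dna <- function(n_len) {
  vapply(n_len, function(l)
    paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = ""),
    character(1))
}
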