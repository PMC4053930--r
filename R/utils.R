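#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over `A`/`C`/`G`/`T`/`N` strings.
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of the same length.
#' @export
#' @examples
#' revcomp(c("ACGT", "AAAC"))
revcomp <- function(x) {
  stopifnot(is.character(x))
  cpp_revcomp(x)
}

#' Generate random DNA
#'
#' Uniform i.i.d. ACGT sequence, used by the simulator and in tests.
#'
#' @param n Sequence length in bases.
#' @return A single DNA string.
#' @export
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' N50 of a set of sequence lengths
#'
#' The length L such that sequences of length >= L together contain at least
#' half of the total bases.
#'
#' @param lengths Integer vector of sequence lengths.
#' @return The N50 length.
#' @export
#' @examples
#' n50(c(2, 2, 2, 3, 3, 4)) # total 16, need >= 8
n50 <- function(lengths) {
  if (length(lengths) == 0) return(0L)
  ls <- sort(as.numeric(lengths), decreasing = TRUE)
  cum <- cumsum(ls)
  as.integer(ls[which(cum >= sum(ls) / 2)[1]])
}

# split a string into its k-mers (R-side helper for small inputs and tests)
seq_kmers <- function(seq, k) {
  L <- nchar(seq)
  if (L < k) return(character(0))
  substring(seq, seq_len(L - k + 1), k:L)
}

# canonical form: lexicographic min of a k-mer and its reverse complement
canonical_kmer <- function(x) {
  rc <- revcomp(x)
  ifelse(x <= rc, x, rc)
}

# non-N length of sequences
non_n_length <- function(seqs) {
  nchar(seqs) - stringr::str_count(seqs, "N")
}
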