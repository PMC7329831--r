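#' Reverse complement of DNA strings
#'
#' Vectorized reverse complement over plain character vectors; `N` maps to
#' `N`.
#'
#' @param x character vector of DNA sequences over `{A,C,G,T,N}`.
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Decode a Phred+33 quality string to integer scores
#' @param qual quality string (one read).
#' @return integer vector of per-base Phred scores.
#' @export
phred_scores <- function(qual) {
  if (is.na(qual) || nchar(qual) == 0) return(integer(0))
  utf8ToInt(qual) - 33L
}

#' Encode integer Phred scores as a Phred+33 string
#' @param scores integer vector of Phred scores (0..93).
#' @return single quality string.
#' @export
phred_string <- function(scores) {
  if (length(scores) == 0) return("")
  intToUtf8(pmin(93L, pmax(0L, as.integer(scores))) + 33L)
}

# all k-length windows of one sequence (character vector of substrings)
seq_windows <- function(seq, k) {
  L <- nchar(seq)
  if (L < k) return(character(0))
  starts <- seq_len(L - k + 1L)
  substring(seq, starts, starts + k - 1L)
}

# maximal N-free stretches of a sequence: data.frame(start, end) 1-based
# inclusive
n_free_stretches <- function(seq) {
  bad <- gregexpr("[^ACGT]", seq)[[1]]
  L <- nchar(seq)
  if (bad[1] == -1) return(data.frame(start = 1L, end = L))
  cuts <- c(0L, as.integer(bad), L + 1L)
  starts <- head(cuts, -1) + 1L
  ends <- tail(cuts, -1) - 1L
  keep <- ends >= starts
  data.frame(start = starts[keep], end = ends[keep])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
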