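#' Canonicalize k-mers
#'
#' The canonical form of a k-mer is the lexicographic minimum of the k-mer
#' and its reverse complement. Odd `k` guarantees the two differ.
#'
#' @param x character vector of k-mers over `{A,C,G,T}` (odd length).
#' @return character vector of canonical k-mers.
#' @export
canonicalize <- function(x) {
  if (length(x) == 0) return(character(0))
  if (nchar(x[1]) %% 2L == 0L)
    stop("k must be odd to avoid palindromic canonical ambiguity",
         call. = FALSE)
  if (any(grepl("[^ACGT]", x)))
    stop("k-mers must not contain N; split reads at N first", call. = FALSE)
  rc <- revcomp(x)
  ifelse(x <= rc, x, rc)
}

#' Enumerate the k-mer windows of a read
#'
#' One entry per k-window within each maximal N-free stretch of the read,
#' reported in canonical orientation together with the flanking bases
#' (swapped between sides and complemented when the window was
#' reverse-complemented) and their Phred scores, so a counter can apply
#' the extension quality gate.
#'
#' @param seq read sequence.
#' @param qual Phred+33 quality string (`NULL` for maximal quality).
#' @param k odd window size.
#' @return `data.frame` with columns `kmer` (canonical), `left_base`,
#'   `right_base` (`NA` at stretch boundaries), `left_qual`, `right_qual`.
#' @export
extract_kmers <- function(seq, qual = NULL, k) {
  empty <- data.frame(kmer = character(0), left_base = character(0),
                      right_base = character(0), left_qual = integer(0),
                      right_qual = integer(0), stringsAsFactors = FALSE)
  if (nchar(seq) < k) return(empty)
  q <- if (is.null(qual)) rep(93L, nchar(seq)) else phred_scores(qual)
  stretches <- n_free_stretches(seq)
  out <- list()
  for (i in seq_len(nrow(stretches))) {
    a <- stretches$start[i]; b <- stretches$end[i]
    if (b - a + 1L < k) next
    starts <- seq.int(a, b - k + 1L)
    win <- substring(seq, starts, starts + k - 1L)
    lb <- ifelse(starts > a, substring(seq, starts - 1L, starts - 1L),
                 NA_character_)
    rb <- ifelse(starts + k - 1L < b, substring(seq, starts + k, starts + k),
                 NA_character_)
    lq <- ifelse(starts > a, q[pmax(starts - 1L, 1L)], NA_integer_)
    rq <- ifelse(starts + k - 1L < b, q[pmin(starts + k, length(q))],
                 NA_integer_)
    canon <- canonicalize(win)
    flip <- canon != win
    comp <- function(z) chartr("ACGT", "TGCA", z)
    out[[length(out) + 1L]] <- data.frame(
      kmer = canon,
      left_base = ifelse(flip, comp(rb), lb),
      right_base = ifelse(flip, comp(lb), rb),
      left_qual = ifelse(flip, rq, lq),
      right_qual = ifelse(flip, lq, rq),
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0) return(empty)
  do.call(rbind, out)
}

#' Count k-mers with the two-pass Bloom-filtered scheme
#'
#' Pass one inserts every canonical k-mer into a Bloom filter and promotes
#' to the exact table only those already present; pass two recounts the
#' promoted k-mers exactly, accumulating per-side extension counts for
#' flanking bases at or above `qual_floor`. Finalization drops records
#' below `min_count`, so counts for every retained k-mer exactly equal a
#' naive full-dictionary count (Bloom false positives can only promote
#' singletons, which finalization removes).
#'
#' @param reads read table from [read_fastq()], or any data.frame with
#'   `seq` and optionally `qual` columns.
#' @param k odd k-mer size in 15..63.
#' @param qual_floor Phred gate for extension counting.
#' @param min_count minimum retained count (>= 2).
#' @return a `kmer_table`: data.frame with columns `kmer`, `count`,
#'   `lA,lC,lG,lT,rA,rC,rG,rT`, plus attributes `k` and `stats`.
#' @export
count_kmers <- function(reads, k, qual_floor = 20L, min_count = 2L) {
  quals <- if (!is.null(reads$qual)) reads$qual else character(0)
  res <- .count_kmers_cpp(reads$seq, quals, as.integer(k),
                          as.integer(qual_floor), as.integer(min_count))
  new_kmer_table(res$kmer, res$count, res$ext, k, res$stats)
}

ext_cols <- c("lA", "lC", "lG", "lT", "rA", "rC", "rG", "rT")

new_kmer_table <- function(kmer, count, ext, k, stats = NULL) {
  ext <- matrix(as.integer(ext), ncol = 8,
                dimnames = list(NULL, ext_cols))
  tab <- data.frame(kmer = kmer, count = as.integer(count),
                    stringsAsFactors = FALSE)
  tab <- cbind(tab, as.data.frame(ext))
  attr(tab, "k") <- as.integer(k)
  attr(tab, "stats") <- stats
  class(tab) <- c("kmer_table", "data.frame")
  tab
}

#' @export
print.kmer_table <- function(x, ...) {
  cat(sprintf("kmer_table: %d k-mers (k=%d)\n", nrow(x), attr(x, "k")))
  if (nrow(x) > 0) print(utils::head(as.data.frame(x), 5))
  invisible(x)
}

#' High-quality extension call for one k-mer side
#'
#' If exactly one base's extension count reaches `threshold` it is chosen;
#' two or more qualifying bases are a fork; none is a deadend.
#'
#' @param record one-row slice of a `kmer_table` (or any list with the
#'   extension count fields).
#' @param side `"left"` or `"right"`.
#' @param threshold extension count threshold (>= 1).
#' @return single string: `"A"/"C"/"G"/"T"`, `"FORK"` or `"DEADEND"`.
#' @export
hq_extension <- function(record, side = c("right", "left"), threshold) {
  side <- match.arg(side)
  stopifnot(threshold >= 1)
  cols <- if (side == "left") c("lA", "lC", "lG", "lT")
          else c("rA", "rC", "rG", "rT")
  counts <- vapply(cols, function(cl) as.integer(record[[cl]]), integer(1))
  qual <- which(counts >= threshold)
  if (length(qual) == 0) return("DEADEND")
  if (length(qual) >= 2) return("FORK")
  c("A", "C", "G", "T")[qual]
}

#' Dump a k-mer table as TSV
#' @param table a `kmer_table`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_kmer_table <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
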