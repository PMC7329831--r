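#' Adaptive extension threshold policy
#'
#' The count threshold an extension must reach scales with the frequency of
#' the k-mer being extended: `t_hq(c) = max(floor, ceiling(alpha * c))`.
#' The linear-in-coverage form with a floor is the simplest monotone rule
#' that lets both high- and low-coverage genomes assemble without a single
#' static threshold fragmenting one of them.
#'
#' @param alpha slope of the threshold in the k-mer count.
#' @param floor minimum threshold (the "seen at least twice" evidence
#'   floor when 2).
#' @return object of class `threshold_policy`.
#' @export
threshold_policy <- function(alpha = 0.1, floor = 2L) {
  stopifnot(alpha > 0, floor >= 1)
  structure(list(alpha = as.numeric(alpha), floor = as.integer(floor)),
            class = "threshold_policy")
}

#' Adaptive threshold for a k-mer count
#' @param count count of the k-mer being extended (>= 1).
#' @param policy a [threshold_policy()].
#' @return integer threshold, monotone nondecreasing in `count`.
#' @export
adaptive_threshold <- function(count, policy = threshold_policy()) {
  pmax(policy$floor, as.integer(ceiling(policy$alpha * count)))
}

#' Traverse the k-mer table into contigs
#'
#' Seeds a bidirectional walk from every unused k-mer in lexicographic
#' order; each step applies [hq_extension()] with the adaptive threshold of
#' the current k-mer's count, stopping at forks, deadends, or k-mers
#' already claimed. Every table k-mer ends up in exactly one contig.
#' Output contigs are in canonical orientation (lexicographic minimum of
#' the sequence and its reverse complement) and sorted by sequence, so the
#' result is independent of strand and seed order.
#'
#' @param table a finalized `kmer_table`.
#' @param policy a [threshold_policy()].
#' @return `data.frame` of class `contig_set`: columns `id`, `seq`,
#'   `depth` (mean constituent k-mer count), `nkmer`, `left_state`,
#'   `right_state` (`"fork"/"deadend"/"used"`), `left_fork`, `right_fork`
#'   (qualifying outward bases at fork ends). Attribute `k`.
#' @export
walk_contigs <- function(table, policy = threshold_policy()) {
  k <- attr(table, "k")
  ext <- as.matrix(as.data.frame(table)[, ext_cols, drop = FALSE])
  res <- .walk_contigs_cpp(table$kmer, table$count, ext,
                           policy$alpha, policy$floor)
  contigs <- data.frame(id = seq_len(nrow(res)), seq = res$seq,
                        depth = res$depth, nkmer = res$nkmer,
                        left_state = res$left_state,
                        right_state = res$right_state,
                        left_fork = res$left_fork,
                        right_fork = res$right_fork,
                        stringsAsFactors = FALSE)
  attr(contigs, "k") <- k
  class(contigs) <- c("contig_set", "data.frame")
  contigs
}

#' @export
print.contig_set <- function(x, ...) {
  cat(sprintf("contig_set: %d contigs, %d bp total (k=%s)\n",
              nrow(x), sum(nchar(x$seq)),
              paste(attr(x, "k"), collapse = ",")))
  invisible(x)
}

as_contig_set <- function(seq, depth, k = NA_integer_) {
  df <- data.frame(id = seq_along(seq), seq = seq, depth = depth,
                   nkmer = pmax(1L, nchar(seq) - as.integer(k) + 1L),
                   left_state = "deadend", right_state = "deadend",
                   left_fork = "", right_fork = "",
                   stringsAsFactors = FALSE)
  if (is.na(k)) df$nkmer <- nchar(seq)
  attr(df, "k") <- k
  class(df) <- c("contig_set", "data.frame")
  df
}

#' Write contigs to FASTA with depth-annotated headers
#' @param contigs a `contig_set`.
#' @param path output FASTA.
#' @param prefix header prefix (`"contig"` or `"scaffold"`).
#' @return `path`, invisibly.
#' @export
write_contigs <- function(contigs, path, prefix = "contig") {
  ids <- sprintf("%s_%d len=%d depth=%.2f", prefix, contigs$id,
                 nchar(contigs$seq), contigs$depth)
  write_fasta(ids, contigs$seq, path)
}
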