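#' Recruit reads to contig ends
#'
#' Reads sharing an exact `seed_len`-mer with the terminal `window` bases
#' of a contig are anchored and verified by ungapped extension allowing at
#' most two mismatches in the overlap. Each read is assigned to at most one
#' contig end (longest overlap; ties are discarded), and only reads whose
#' alignment reaches the contig terminus and overhangs past it are kept --
#' those are the reads that can vote on new bases.
#'
#' @param contigs a `contig_set`.
#' @param reads read table from [read_fastq()].
#' @param seed_len exact seed length.
#' @param window terminal window size in which the seed must fall
#'   (default `2 * read length`).
#' @return `data.frame` with one row per recruited read: `contig`, `end`
#'   (`"left"`/`"right"`), `read_row`, `overlap`, `overhang` (bases past
#'   the end, already oriented away from the contig), `overhang_qual`.
#' @export
recruit_end_reads <- function(contigs, reads, seed_len = 21L,
                              window = NULL) {
  if (nrow(contigs) == 0 || nrow(reads) == 0)
    return(data.frame(contig = integer(0), end = character(0),
                      read_row = integer(0), overlap = integer(0),
                      overhang = character(0), overhang_qual = character(0),
                      stringsAsFactors = FALSE))
  if (is.null(window)) window <- 2L * max(nchar(reads$seq))
  aln <- .align_reads_cpp(contigs$seq, reads$seq, as.integer(seed_len),
                          2L, 1L)
  aln <- as.data.frame(aln)
  aln <- aln[aln$rank == 1L & aln$tied == 0L, , drop = FALSE]
  if (nrow(aln) == 0)
    return(recruit_end_reads(contigs[0, ], reads[0, ], seed_len))
  clen <- nchar(contigs$seq)[aln$ref]
  rlen <- nchar(reads$seq)[aln$read]

  # full-overlap verification: an alignment trimmed inside both the read
  # and the contig hit a third mismatch in the overlap and is rejected.
  # In the aligned frame the non-overhang flank must reach either the
  # read boundary or the contig boundary.
  qstart <- ifelse(aln$orient == 0L, aln$rstart, rlen - aln$rend)
  qend <- ifelse(aln$orient == 0L, aln$rend, rlen - aln$rstart)

  rev_str <- function(x) {
    if (length(x) == 0) return(character(0))
    vapply(x, function(s) paste(rev(strsplit(s, "")[[1]]), collapse = ""),
           character(1), USE.NAMES = FALSE)
  }
  # right end: overhang is the read tail (fwd) or reverse-complemented
  # head (rc); left end mirrors this, oriented away from the contig
  reach_right <- aln$cend == clen & aln$cstart >= pmax(0L, clen - window) &
    (qstart == 0L | aln$cstart == 0L) &
    ifelse(aln$orient == 0L, aln$rend < rlen, aln$rstart > 0L)
  reach_left <- aln$cstart == 0L & aln$cend <= window &
    (qend == rlen | aln$cend == clen) &
    ifelse(aln$orient == 0L, aln$rstart > 0L, aln$rend < rlen)
  pick <- function(sel, end_name) {
    a <- aln[sel, , drop = FALSE]
    if (nrow(a) == 0) return(NULL)
    rseq <- reads$seq[a$read]; rqual <- reads$qual[a$read]
    # overhang beyond the terminus, read past-the-end (right/fwd,
    # left/rc) or before-the-start (reversed and complemented)
    tailward <- if (end_name == "right") a$orient == 0L else a$orient == 1L
    oh <- oq <- character(nrow(a))
    oh[tailward] <- substring(rseq[tailward], a$rend[tailward] + 1L)
    oq[tailward] <- substring(rqual[tailward], a$rend[tailward] + 1L)
    oh[!tailward] <- revcomp(substring(rseq[!tailward], 1L,
                                       a$rstart[!tailward]))
    oq[!tailward] <- rev_str(substring(rqual[!tailward], 1L,
                                       a$rstart[!tailward]))
    data.frame(contig = a$ref, end = end_name, read_row = a$read,
               overlap = a$cend - a$cstart, overhang = oh,
               overhang_qual = oq, stringsAsFactors = FALSE)
  }
  res <- rbind(pick(reach_right, "right"), pick(reach_left, "left"))
  if (is.null(res) || nrow(res) == 0)
    return(data.frame(contig = integer(0), end = character(0),
                      read_row = integer(0), overlap = integer(0),
                      overhang = character(0), overhang_qual = character(0),
                      stringsAsFactors = FALSE))
  # a read votes at one end only: keep its longest overlap, drop ties
  res <- res[order(res$read_row, -res$overlap), , drop = FALSE]
  first <- !duplicated(res$read_row)
  nxt_same <- c(res$read_row[-1] == res$read_row[-nrow(res)], FALSE)
  nxt_tie <- c(res$overlap[-1] == res$overlap[-nrow(res)], FALSE)
  res <- res[first & !(nxt_same & nxt_tie), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# vote-walk over a set of overhang strings: returns the extension string
walk_votes <- function(overhangs, quals, qual_floor, min_votes,
                       max_len = Inf) {
  ext <- character(0)
  pos <- 1L
  while (pos <= max_len) {
    votes <- c(A = 0L, C = 0L, G = 0L, T = 0L)
    for (i in seq_along(overhangs)) {
      if (nchar(overhangs[i]) < pos) next
      b <- substring(overhangs[i], pos, pos)
      q <- phred_scores(substring(quals[i], pos, pos))
      if (b %in% names(votes) && length(q) == 1 && q >= qual_floor)
        votes[b] <- votes[b] + 1L
    }
    qualifying <- names(votes)[votes >= min_votes]
    if (length(qualifying) != 1L) break  # local fork or no support
    ext <- c(ext, qualifying)
    pos <- pos + 1L
  }
  paste(ext, collapse = "")
}

#' Extend one contig past an end by local consensus
#'
#' Walks one base at a time beyond the contig terminus. A base is accepted
#' only when at least `min_votes` recruited reads support it at Phred >=
#' `qual_floor` and no competing base reaches `min_votes` (a local fork
#' stops the walk). The input contig is preserved verbatim as a prefix or
#' suffix of the output.
#'
#' @param contig one-row slice of a `contig_set`.
#' @param end_alignments rows of [recruit_end_reads()] output for this
#'   contig.
#' @param qual_floor Phred gate for votes.
#' @param min_votes minimum supporting reads per base (>= 2).
#' @return the contig row with `seq` possibly extended on either side.
#' @export
extend_contig <- function(contig, end_alignments, qual_floor = 20L,
                          min_votes = 2L) {
  stopifnot(min_votes >= 2L)
  for (side in c("left", "right")) {
    ea <- end_alignments[end_alignments$end == side, , drop = FALSE]
    if (nrow(ea) < min_votes) next
    ext <- walk_votes(ea$overhang, ea$overhang_qual, qual_floor, min_votes)
    if (nchar(ext) == 0) next
    contig$seq <- if (side == "right") paste0(contig$seq, ext)
                  else paste0(revcomp(ext), contig$seq)
  }
  contig
}

#' Run one round of local extension over all contigs
#'
#' @param contigs a `contig_set`.
#' @param reads read table.
#' @param seed_len seed length for end recruitment.
#' @param qual_floor Phred gate for votes.
#' @param min_votes minimum votes per extended base.
#' @return the extended `contig_set` (depths unchanged: they refer to the
#'   original k-mer support).
#' @export
extend_all_contigs <- function(contigs, reads, seed_len = 21L,
                               qual_floor = 20L, min_votes = 2L) {
  if (nrow(contigs) == 0) return(contigs)
  rec <- recruit_end_reads(contigs, reads, seed_len)
  if (nrow(rec) == 0) return(contigs)
  for (i in seq_len(nrow(contigs))) {
    ea <- rec[rec$contig == i, , drop = FALSE]
    if (nrow(ea) == 0) next
    contigs[i, ] <- extend_contig(contigs[i, ], ea, qual_floor, min_votes)
  }
  contigs
}
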