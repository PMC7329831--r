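#' Convert contigs into k-mers for the next iteration
#'
#' Contigs from one iteration are treated as long error-free reads for the
#' next, larger k: every `k_next`-mer of every contig is emitted with count
#' `max(min_count, round(depth))` and the single extension implied by the
#' contig context, at maximal quality. Contigs shorter than `k_next`
#' contribute nothing.
#'
#' @param contigs a `contig_set` from the previous iteration.
#' @param k_next the next (larger) odd k.
#' @param min_count count floor carried into the synthetic records.
#' @return a `kmer_table` fragment (counts and extensions in canonical
#'   orientation), mergeable with a read-derived table via
#'   [merge_kmer_tables()].
#' @export
contigs_to_kmers <- function(contigs, k_next, min_count = 2L) {
  keep <- nchar(contigs$seq) >= k_next
  co <- contigs[keep, , drop = FALSE]
  if (nrow(co) == 0)
    return(new_kmer_table(character(0), integer(0),
                          matrix(integer(0), ncol = 8), k_next))
  cnt <- pmax(as.integer(min_count), as.integer(round(co$depth)))
  parts <- lapply(seq_len(nrow(co)), function(i) {
    df <- extract_kmers(co$seq[i], qual = NULL, k = k_next)
    df$count <- cnt[i]
    df
  })
  dt <- data.table::rbindlist(parts)
  # per-occurrence extension counts at the occurrence's own count, then
  # aggregate per canonical k-mer
  for (b in c("A", "C", "G", "T")) {
    data.table::set(dt, j = paste0("l", b),
                    value = ifelse(!is.na(dt$left_base) & dt$left_base == b,
                                   dt$count, 0L))
    data.table::set(dt, j = paste0("r", b),
                    value = ifelse(!is.na(dt$right_base) & dt$right_base == b,
                                   dt$count, 0L))
  }
  agg <- dt[, c(list(count = sum(count)),
                lapply(.SD, sum)),
            by = kmer, .SDcols = ext_cols]
  data.table::setorder(agg, kmer)
  new_kmer_table(agg$kmer, agg$count,
                 as.matrix(agg[, ext_cols, with = FALSE]), k_next)
}

#' Merge k-mer tables additively
#'
#' Counts and extension counts for shared canonical k-mers are summed;
#' used to combine read-derived and contig-derived evidence at the same k.
#'
#' @param a,b `kmer_table`s at the same k.
#' @return merged `kmer_table`, lexicographically ordered.
#' @export
merge_kmer_tables <- function(a, b) {
  if (attr(a, "k") != attr(b, "k"))
    stop("cannot merge k-mer tables with different k", call. = FALSE)
  if (nrow(a) == 0) return(b)
  if (nrow(b) == 0) return(a)
  dt <- data.table::rbindlist(list(
    as.data.frame(a)[, c("kmer", "count", ext_cols)],
    as.data.frame(b)[, c("kmer", "count", ext_cols)]))
  agg <- dt[, lapply(.SD, sum), by = kmer,
            .SDcols = c("count", ext_cols)]
  data.table::setorder(agg, kmer)
  new_kmer_table(agg$kmer, agg$count,
                 as.matrix(agg[, ext_cols, with = FALSE]), attr(a, "k"))
}

#' Run one contig-generation iteration at a single k
#'
#' Read k-mer counting (merged with k-mers from the previous iteration's
#' contigs), adaptive-threshold traversal, bubble merging, hair removal,
#' fork pruning, and one round of read-based local extension.
#'
#' @param reads read table.
#' @param prev_contigs `contig_set` from the previous (smaller-k)
#'   iteration, or `NULL` for the first.
#' @param k this iteration's odd k.
#' @param config an [assembly_config()].
#' @return a `contig_set`.
#' @export
run_iteration <- function(reads, prev_contigs, k, config = assembly_config()) {
  tab <- count_kmers(reads, k, config$qual_floor, config$min_count)
  if (!is.null(prev_contigs) && nrow(prev_contigs) > 0) {
    ctab <- contigs_to_kmers(prev_contigs, k, config$min_count)
    tab <- merge_kmer_tables(tab, ctab)
  }
  policy <- threshold_policy(config$alpha, config$thq_floor)
  contigs <- walk_contigs(tab, policy)
  if (nrow(contigs) > 0) {
    g <- build_unitig_graph(contigs, tab, policy)
    g <- merge_bubbles(g, config$bubble_len_factor)
    g <- remove_hairs(g, config$hair_len_factor)
    g <- prune_forks(g, config$prune_ratio, config$prune_max_iters)
    contigs <- graph_contigs(g)
    contigs <- extend_all_contigs(contigs, reads, config$seed_len,
                                  config$qual_floor, min_votes = 2L)
  }
  # contigs too short to be re-expressed as k-mers at this k cannot be
  # re-walked; pass them through so the multi-k union never loses the
  # shallow genomes assembled at smaller k (dropping copies already
  # contained in a walked contig)
  if (!is.null(prev_contigs) && nrow(prev_contigs) > 0) {
    shorts <- prev_contigs[nchar(prev_contigs$seq) < k, , drop = FALSE]
    if (nrow(shorts) > 0 && nrow(contigs) > 0) {
      hay <- paste(contigs$seq, collapse = "#")
      contained <- vapply(shorts$seq, function(s)
        grepl(s, hay, fixed = TRUE) || grepl(revcomp(s), hay, fixed = TRUE),
        logical(1), USE.NAMES = FALSE)
      shorts <- shorts[!contained, , drop = FALSE]
    }
    if (nrow(shorts) > 0) {
      merged <- rbind(as.data.frame(contigs)[, c("seq", "depth")],
                      as.data.frame(shorts)[, c("seq", "depth")])
      merged <- merged[order(merged$seq), , drop = FALSE]
      contigs <- as_contig_set(merged$seq, merged$depth, k)
    }
  }
  contigs
}

#' Run the full iterative multi-k contig generation
#'
#' Folds [run_iteration()] over `config$k_list`: each iteration's contigs
#' are re-ingested as long error-free reads at the next, larger k, so low
#' abundance genomes assembled early survive while later iterations
#' resolve longer repeats.
#'
#' @param reads read table.
#' @param config an [assembly_config()].
#' @param out_dir optional directory for per-k intermediate FASTA files
#'   (`contigs_k<k>.fasta`).
#' @param verbose emit one log line per iteration.
#' @return final iteration's `contig_set` with stable ids; pieces shorter
#'   than `config$min_contig_len` (isolated error islands, mostly) are
#'   dropped from the final output only, never between iterations.
#' @export
run_all <- function(reads, config = assembly_config(), out_dir = NULL,
                    verbose = FALSE) {
  contigs <- NULL
  for (k in config$k_list) {
    contigs <- run_iteration(reads, contigs, k, config)
    if (verbose)
      message(sprintf("iter k=%d contigs=%d total_bp=%d", k,
                      nrow(contigs), sum(nchar(contigs$seq))))
    if (!is.null(out_dir))
      write_contigs(contigs, file.path(out_dir,
                                       sprintf("contigs_k%d.fasta", k)))
  }
  keep <- nchar(contigs$seq) >= config$min_contig_len
  contigs <- contigs[keep, , drop = FALSE]
  contigs$id <- seq_len(nrow(contigs))
  rownames(contigs) <- NULL
  attr(contigs, "k") <- max(config$k_list)
  class(contigs) <- c("contig_set", "data.frame")
  contigs
}
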