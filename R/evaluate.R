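#' Align assembly contigs to reference genomes
#'
#' Shared `anchor_len`-mers between contig and reference are chained per
#' (contig, reference, strand, diagonal) into maximal ungapped blocks
#' (split where consecutive anchors are more than `max_anchor_gap` apart),
#' identity is computed over each block by direct comparison, and blocks
#' below `min_identity` are dropped. Substitution-style divergence stays
#' within one block; indels start a new diagonal.
#'
#' @param contigs a `contig_set` or named character vector of sequences.
#' @param refs named character vector of reference sequences.
#' @param anchor_len exact anchor length.
#' @param min_identity minimum block identity retained.
#' @param max_anchor_gap anchor spacing above which a block is split.
#' @return `data.frame`: `contig`, `ref`, `contig_start`, `contig_end`,
#'   `ref_start`, `ref_end` (0-based half-open, contig coords on the
#'   original strand), `orient`, `identity`.
#' @export
align_contigs_to_refs <- function(contigs, refs, anchor_len = 31L,
                                  min_identity = 0.95,
                                  max_anchor_gap = 100L) {
  cseqs <- if (is.data.frame(contigs)) contigs$seq else unname(contigs)
  cids <- if (is.data.frame(contigs)) as.character(contigs$id)
          else (names(contigs) %||% as.character(seq_along(contigs)))
  empty <- data.frame(contig = character(0), ref = character(0),
                      contig_start = integer(0), contig_end = integer(0),
                      ref_start = integer(0), ref_end = integer(0),
                      orient = character(0), identity = numeric(0),
                      stringsAsFactors = FALSE)
  if (length(cseqs) == 0 || length(refs) == 0) return(empty)

  anchor_dt <- function(seqs, ids) {
    parts <- lapply(seq_along(seqs), function(i) {
      w <- seq_windows(seqs[i], anchor_len)
      if (length(w) == 0) return(NULL)
      data.table::data.table(kmer = w, id = ids[i],
                             pos = seq_along(w) - 1L)
    })
    data.table::rbindlist(parts)
  }
  ref_anchors <- anchor_dt(unname(refs), names(refs))
  if (nrow(ref_anchors) == 0) return(empty)
  data.table::setnames(ref_anchors, c("id", "pos"), c("rid", "rpos"))
  data.table::setkey(ref_anchors, kmer)

  out <- list()
  for (strand in c("+", "-")) {
    qseqs <- if (strand == "+") cseqs else revcomp(cseqs)
    q_anchors <- anchor_dt(qseqs, cids)
    if (nrow(q_anchors) == 0) next
    data.table::setnames(q_anchors, c("id", "pos"), c("qid", "qpos"))
    hits <- ref_anchors[q_anchors, on = "kmer", nomatch = NULL,
                        allow.cartesian = TRUE]
    if (nrow(hits) == 0) next
    hits[, diag_id := rpos - qpos]
    data.table::setorder(hits, qid, rid, diag_id, qpos)
    hits[, block := cumsum(c(1L, (diff(qpos) > max_anchor_gap) |
                                  (diff(qpos) <= 0L))),
         by = .(qid, rid, diag_id)]
    blocks <- hits[, .(qs = min(qpos), qe = max(qpos) + anchor_len,
                       rs = min(rpos), re = max(rpos) + anchor_len),
                   by = .(qid, rid, diag_id, block)]
    qlen <- setNames(nchar(cseqs), cids)
    for (i in seq_len(nrow(blocks))) {
      b <- blocks[i]
      qseq <- qseqs[match(b$qid, cids)]
      s1 <- substring(qseq, b$qs + 1L, b$qe)
      s2 <- substring(refs[[b$rid]], b$rs + 1L, b$re)
      mm <- sum(utf8ToInt(s1) != utf8ToInt(s2))
      idy <- 1 - mm / nchar(s1)
      if (idy < min_identity) next
      L <- qlen[[b$qid]]
      cs <- if (strand == "+") b$qs else L - b$qe
      ce <- if (strand == "+") b$qe else L - b$qs
      out[[length(out) + 1L]] <- data.frame(
        contig = b$qid, ref = b$rid, contig_start = cs, contig_end = ce,
        ref_start = b$rs, ref_end = b$re, orient = strand,
        identity = idy, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Genome fraction of a reference
#'
#' Percentage of the reference covered by the union of alignment blocks.
#'
#' @param alignments output of [align_contigs_to_refs()].
#' @param ref_id reference id.
#' @param ref_len reference length in bases.
#' @return percent in `[0, 100]`.
#' @export
genome_fraction <- function(alignments, ref_id, ref_len) {
  a <- alignments[alignments$ref == ref_id, , drop = FALSE]
  if (nrow(a) == 0) return(0)
  ir <- IRanges::reduce(IRanges::IRanges(start = a$ref_start + 1L,
                                         end = a$ref_end))
  100 * sum(IRanges::width(ir)) / ref_len
}

#' Duplication ratio against a reference
#'
#' Total assembly bases aligned to the reference divided by the reference
#' length; overlapping alignments count multiply, so a reference present
#' n times in the assembly scores n.
#'
#' @inheritParams genome_fraction
#' @return nonnegative float.
#' @export
duplication_ratio <- function(alignments, ref_id, ref_len) {
  a <- alignments[alignments$ref == ref_id, , drop = FALSE]
  if (nrow(a) == 0) return(0)
  sum(a$ref_end - a$ref_start) / ref_len
}

#' Chimericity of a read-provenance profile
#'
#' Shannon entropy (natural log) of the proportions `p_i` of reads from
#' each source genome composing a contig: 0 for a pure contig, `ln(2)` for
#' a balanced two-genome chimera.
#'
#' @param p numeric vector of proportions (positive entries sum to 1), or
#'   raw counts (normalized internally).
#' @return nonnegative entropy.
#' @export
chimericity <- function(p) {
  p <- p[!is.na(p) & p > 0]
  if (length(p) == 0) stop("empty provenance profile", call. = FALSE)
  p <- p / sum(p)
  -sum(p * log(p))
}

#' Assign reads to contigs and accumulate provenance profiles
#'
#' Each read goes to its single best-aligning contig (ties discarded);
#' per-contig counts of source genomes (from read provenance) become the
#' proportions `p_i` used by [chimericity()].
#'
#' @param reads read table with a `provenance` column.
#' @param contigs a `contig_set`.
#' @param seed_len seed length for alignment.
#' @return `data.frame`: `contig`, `genome`, `count`, `p`.
#' @export
assign_reads_to_contigs <- function(reads, contigs, seed_len = 21L) {
  empty <- data.frame(contig = integer(0), genome = character(0),
                      count = integer(0), p = numeric(0),
                      stringsAsFactors = FALSE)
  if (nrow(reads) == 0 || nrow(contigs) == 0) return(empty)
  aln <- as.data.frame(.align_reads_cpp(contigs$seq, reads$seq,
                                        as.integer(seed_len), 2L, 1L))
  aln <- aln[aln$rank == 1L & aln$tied == 0L, , drop = FALSE]
  if (nrow(aln) == 0) return(empty)
  prov <- reads$provenance[aln$read]
  keep <- !is.na(prov)
  dt <- data.table::data.table(contig = aln$ref[keep], genome = prov[keep])
  agg <- dt[, .(count = .N), by = .(contig, genome)]
  agg[, p := count / sum(count), by = contig]
  data.table::setorder(agg, contig, genome)
  as.data.frame(agg)
}

#' Per-contig chimericity summary
#'
#' @param profiles output of [assign_reads_to_contigs()].
#' @return list: `per_contig` (contig, n_genomes, chimericity),
#'   `mean_all`, `fraction_chimeric`, `mean_chimeric` (the three
#'   headline numbers: mean over all profiled contigs, fraction with
#'   reads from two or more genomes, and mean over those).
#' @export
chimericity_summary <- function(profiles) {
  if (nrow(profiles) == 0)
    return(list(per_contig = data.frame(contig = integer(0),
                                        n_genomes = integer(0),
                                        chimericity = numeric(0)),
                mean_all = NA_real_, fraction_chimeric = NA_real_,
                mean_chimeric = NA_real_))
  per <- do.call(rbind, lapply(split(profiles, profiles$contig),
    function(d) data.frame(contig = d$contig[1],
                           n_genomes = sum(d$count > 0),
                           chimericity = chimericity(d$p))))
  rownames(per) <- NULL
  chim <- per$n_genomes >= 2L
  list(per_contig = per,
       mean_all = mean(per$chimericity),
       fraction_chimeric = mean(chim),
       mean_chimeric = if (any(chim)) mean(per$chimericity[chim])
                       else 0)
}

#' Concatenate per-sample assemblies into a multiassembly
#'
#' @param per_sample_assemblies named list of `contig_set`s (names become
#'   id prefixes).
#' @return a `contig_set` with sample-prefixed ids preserved in
#'   `source_id`.
#' @export
multiassembly <- function(per_sample_assemblies) {
  nm <- names(per_sample_assemblies) %||%
    paste0("s", seq_along(per_sample_assemblies))
  seqs <- unlist(lapply(per_sample_assemblies, function(a) a$seq),
                 use.names = FALSE)
  depths <- unlist(lapply(per_sample_assemblies, function(a) a$depth),
                   use.names = FALSE)
  src <- unlist(lapply(seq_along(per_sample_assemblies), function(i)
    sprintf("%s_%d", nm[i], per_sample_assemblies[[i]]$id)),
    use.names = FALSE)
  out <- as_contig_set(seqs, depths)
  out$source_id <- src
  out
}

#' Naive containment deduplication of an assembly
#'
#' Processes contigs longest-first; a contig is removed when its sequence
#' (or reverse complement) is contained in an already retained, longer (or
#' equal) contig. `containment_identity < 1` relaxes exact containment to
#' anchor-block coverage: the contig must be covered over at least that
#' fraction of its length at at least that identity by one retained
#' contig. Idempotent; never removes the last copy of a distinct
#' sequence.
#'
#' @param assembly a `contig_set`.
#' @param containment_identity containment stringency in (0, 1].
#' @return the deduplicated `contig_set`.
#' @export
dedupe <- function(assembly, containment_identity = 1.0) {
  n <- nrow(assembly)
  if (n <= 1) return(assembly)
  ord <- order(-nchar(assembly$seq), assembly$seq)
  kept <- integer(0)
  for (i in ord) {
    s <- assembly$seq[i]
    contained <- FALSE
    if (length(kept) > 0) {
      if (containment_identity >= 1) {
        rc <- revcomp(s)
        hits <- vapply(assembly$seq[kept], function(ks)
          grepl(s, ks, fixed = TRUE) || grepl(rc, ks, fixed = TRUE),
          logical(1))
        contained <- any(hits)
      } else {
        aln <- align_contigs_to_refs(
          setNames(assembly$seq[kept], as.character(kept)),
          setNames(s, "q"), min_identity = containment_identity)
        # blocks are contig(kept)-vs-ref(candidate); coverage on candidate
        if (nrow(aln) > 0) {
          for (kc in unique(aln$contig)) {
            a <- aln[aln$contig == kc, ]
            cov <- IRanges::reduce(IRanges::IRanges(a$ref_start + 1L,
                                                    a$ref_end))
            if (sum(IRanges::width(cov)) >=
                containment_identity * nchar(s)) {
              contained <- TRUE
              break
            }
          }
        }
      }
    }
    if (!contained) kept <- c(kept, i)
  }
  out <- assembly[sort(kept), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(assembly)
  attr(out, "k") <- attr(assembly, "k")
  out
}

#' Full evaluation report against a simulation truth manifest
#'
#' Per-reference genome fraction and duplication ratio, the per-depth
#' genome-fraction table (keyed by realized simulated depth), the
#' cumulative aligned-length curve (contigs ordered longest to shortest),
#' and the chimericity summary when reads are supplied.
#'
#' @param assembly a `contig_set`.
#' @param truth truth list from [simulate_reads()] (`genomes`,
#'   `abundances`, `reads`).
#' @param reads optional read table with provenance, for chimericity.
#' @param read_len read length used in simulation.
#' @param min_identity alignment identity gate.
#' @return list: `per_ref` data.frame (`ref`, `ref_len`, `depth`,
#'   `genome_fraction`, `duplication_ratio`), `cumulative` data.frame
#'   (`rank`, `aligned_len`, `cumulative_bp`), `chimericity` (summary or
#'   `NULL`), `alignments`.
#' @export
eval_report <- function(assembly, truth, reads = NULL, read_len = 150L,
                        min_identity = 0.95) {
  refs <- truth$genomes
  aln <- align_contigs_to_refs(assembly, refs, min_identity = min_identity)
  depth_m <- realized_depth(list(truth = truth), read_len)
  per_ref <- do.call(rbind, lapply(names(refs), function(r) {
    data.frame(ref = r, ref_len = nchar(refs[[r]]),
               depth = sum(depth_m[r, ]),
               genome_fraction = genome_fraction(aln, r, nchar(refs[[r]])),
               duplication_ratio = duplication_ratio(aln, r,
                                                     nchar(refs[[r]])),
               stringsAsFactors = FALSE)
  }))
  cum <- data.frame(rank = integer(0), aligned_len = numeric(0),
                    cumulative_bp = numeric(0))
  if (nrow(aln) > 0) {
    per_contig <- tapply(aln$contig_end - aln$contig_start, aln$contig, sum)
    al <- sort(pmin(unname(per_contig),
                    nchar(assembly$seq)[match(names(per_contig),
                                              as.character(assembly$id))]),
               decreasing = TRUE)
    cum <- data.frame(rank = seq_along(al), aligned_len = al,
                      cumulative_bp = cumsum(al))
  }
  chim <- NULL
  if (!is.null(reads))
    chim <- chimericity_summary(assign_reads_to_contigs(reads, assembly))
  list(per_ref = per_ref, cumulative = cum, chimericity = chim,
       alignments = aln)
}

#' Write an evaluation report to TSV files
#' @param report list from [eval_report()].
#' @param out_dir output directory.
#' @return `out_dir`, invisibly.
#' @export
write_eval_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(report$per_ref, file.path(out_dir, "report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$cumulative,
                     file.path(out_dir, "cumulative.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report$chimericity)) {
    utils::write.table(report$chimericity$per_contig,
                       file.path(out_dir, "chimericity.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    summ <- report$chimericity[c("mean_all", "fraction_chimeric",
                                 "mean_chimeric")]
    jsonlite::write_json(summ, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(out_dir)
}

#' Fraction of strain-diagnostic sites recovered with the strain allele
#'
#' For a strain derived from a parent by substitutions only (equal
#' lengths), the diagnostic sites are the positions where the two differ.
#' The assembly is aligned to the strain reference and a site counts as
#' recovered when some alignment block covers it with the strain's base.
#'
#' @param assembly a `contig_set`.
#' @param strain_ref,parent_ref equal-length reference sequences.
#' @param min_identity alignment identity gate.
#' @return fraction in `[0, 1]` of diagnostic sites recovered.
#' @export
strain_specific_fraction <- function(assembly, strain_ref, parent_ref,
                                     min_identity = 0.95) {
  stopifnot(nchar(strain_ref) == nchar(parent_ref))
  sv <- utf8ToInt(strain_ref)
  pv <- utf8ToInt(parent_ref)
  diag_pos <- which(sv != pv)  # 1-based
  if (length(diag_pos) == 0) return(NA_real_)
  aln <- align_contigs_to_refs(assembly, c(strain = strain_ref),
                               min_identity = min_identity)
  if (nrow(aln) == 0) return(0)
  recovered <- logical(length(diag_pos))
  for (i in seq_len(nrow(aln))) {
    a <- aln[i, ]
    inb <- which(diag_pos > a$ref_start & diag_pos <= a$ref_end)
    if (length(inb) == 0) next
    cseq <- assembly$seq[match(a$contig, as.character(assembly$id))]
    if (a$orient == "-") cseq <- revcomp(cseq)
    # oriented contig coords: ref pos r maps to qs + (r - rs)
    qs <- if (a$orient == "+") a$contig_start
          else nchar(cseq) - a$contig_end
    off <- diag_pos[inb] - a$ref_start          # 1-based within block
    bases <- utf8ToInt(cseq)[qs + off]
    recovered[inb] <- recovered[inb] | (bases == sv[diag_pos[inb]])
  }
  mean(recovered)
}
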