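#' Align reads to contigs for scaffolding
#'
#' Seed-and-extend, ungapped, at most two mismatches. A read may receive up
#' to two alignments on barely-overlapping read intervals (so a single read
#' can splint two contigs). Ties for the best placement are flagged and
#' excluded from best-hit uses.
#'
#' @param reads read table from [read_fastq()].
#' @param contigs a `contig_set`.
#' @param seed_len exact seed length.
#' @return `data.frame`: `read_row`, `contig`, `cstart`, `cend`, `rstart`,
#'   `rend` (0-based half-open; read coords on the original read),
#'   `orient` (`"fwd"`/`"rc"`), `matches`, `mm`, `rank`, `tied`.
#' @export
align_reads_to_contigs <- function(reads, contigs, seed_len = 21L) {
  if (nrow(reads) == 0 || nrow(contigs) == 0)
    return(data.frame(read_row = integer(0), contig = integer(0),
                      cstart = integer(0), cend = integer(0),
                      rstart = integer(0), rend = integer(0),
                      orient = character(0), matches = integer(0),
                      mm = integer(0), rank = integer(0),
                      tied = logical(0), stringsAsFactors = FALSE))
  aln <- as.data.frame(.align_reads_cpp(contigs$seq, reads$seq,
                                        as.integer(seed_len), 2L, 2L))
  data.frame(read_row = aln$read, contig = aln$ref,
             cstart = aln$cstart, cend = aln$cend,
             rstart = aln$rstart, rend = aln$rend,
             orient = ifelse(aln$orient == 0L, "fwd", "rc"),
             matches = aln$matches, mm = aln$mm, rank = aln$rank,
             tied = aln$tied == 1L, stringsAsFactors = FALSE)
}

end_key <- function(contig, side) sprintf("%d:%s", contig, side)

#' Build contig-graph edges from splints and spans
#'
#' A *splint* is a single read whose two alignments bridge two contig
#' ends; a *span* is a read pair whose mates align to two different
#' contigs. Each piece of evidence implies a pair of oriented contig ends
#' and a gap estimate: for splints, the distance between the two contig
#' ends projected onto the read; for spans, `insert_mu - tail_a - tail_b`
#' where each tail is the distance from the mate's projected fragment end
#' to its contig's linking end. Evidence is aggregated per unordered end
#' pair; under-supported edges and span pairs that could not fit the
#' insert distribution (`tail_a + tail_b > insert_mu + 3 insert_sigma`)
#' are dropped.
#'
#' @param alignments output of [align_reads_to_contigs()].
#' @param contigs a `contig_set`.
#' @param reads the read table (for pairing).
#' @param insert_mu,insert_sigma insert size model.
#' @param min_edge_support minimum distinct reads/pairs per kept edge.
#' @return `data.frame` of class `contig_edges`: `end_a`, `end_b`
#'   (`"<contig>:<L|R>"`), `kind` (`"splint"/"span"/"both"`), `support`,
#'   `gap`, `gap_sd`, `max_aln`, and a list-column `read_rows` of
#'   supporting read rows.
#' @export
build_edges <- function(alignments, contigs, reads,
                        insert_mu = 270, insert_sigma = 30,
                        min_edge_support = 2L) {
  empty <- data.frame(end_a = character(0), end_b = character(0),
                      kind = character(0), support = integer(0),
                      gap = numeric(0), gap_sd = numeric(0),
                      max_aln = integer(0), stringsAsFactors = FALSE)
  empty$read_rows <- list()
  class(empty) <- c("contig_edges", "data.frame")
  if (nrow(alignments) == 0) return(empty)
  clen <- nchar(contigs$seq)
  aln <- alignments[!alignments$tied | alignments$rank > 1L, , drop = FALSE]

  ev <- list()  # evidence records: end_a, end_b, gap, key, aln_len, kind, rows
  add_ev <- function(ea, eb, gap, key, aln_len, kind, rows) {
    if (ea > eb) { tmp <- ea; ea <- eb; eb <- tmp }
    ev[[length(ev) + 1L]] <<- data.frame(
      end_a = ea, end_b = eb, gap = gap, key = key,
      aln_len = aln_len, kind = kind, rows = I(list(rows)),
      stringsAsFactors = FALSE)
  }

  # --- splints ---------------------------------------------------------
  two <- aln[aln$read_row %in% aln$read_row[aln$rank == 2L], , drop = FALSE]
  if (nrow(two) > 0) {
    for (rr in unique(two$read_row)) {
      h <- two[two$read_row == rr, , drop = FALSE]
      if (nrow(h) != 2L) next
      h <- h[order(h$rstart), ]
      if (h$contig[1] == h$contig[2]) next
      a1 <- h[1, ]; a2 <- h[2, ]
      if (a1$orient == "fwd") {
        e1 <- end_key(a1$contig, "R")
        p1 <- a1$rend + (clen[a1$contig] - a1$cend)
      } else {
        e1 <- end_key(a1$contig, "L")
        p1 <- a1$rend + a1$cstart
      }
      if (a2$orient == "fwd") {
        e2 <- end_key(a2$contig, "L")
        p2 <- a2$rstart - a2$cstart
      } else {
        e2 <- end_key(a2$contig, "R")
        p2 <- a2$rstart - (clen[a2$contig] - a2$cend)
      }
      add_ev(e1, e2, p2 - p1, paste0("s", rr),
             min(a1$rend - a1$rstart, a2$rend - a2$rstart), "splint", rr)
    }
  }

  # --- spans -----------------------------------------------------------
  best <- aln[aln$rank == 1L & !aln$tied, , drop = FALSE]
  pid <- reads$pair_id[best$read_row]
  mate <- reads$mate[best$read_row]
  paired <- pid[duplicated(pid)]
  for (p in unique(paired)) {
    idx <- which(pid == p)
    if (length(idx) != 2L) next
    if (mate[idx[1]] == mate[idx[2]]) next
    a1 <- best[idx[1], ]; a2 <- best[idx[2], ]
    if (a1$contig == a2$contig) next
    tail_of <- function(a) {
      if (a$orient == "fwd")
        list(end = end_key(a$contig, "R"),
             tail = clen[a$contig] - (a$cstart - a$rstart))
      else
        list(end = end_key(a$contig, "L"), tail = a$cend + a$rstart)
    }
    t1 <- tail_of(a1); t2 <- tail_of(a2)
    if (t1$tail + t2$tail > insert_mu + 3 * insert_sigma) next
    add_ev(t1$end, t2$end, insert_mu - t1$tail - t2$tail, paste0("p", p),
           min(a1$cend - a1$cstart, a2$cend - a2$cstart), "span",
           c(a1$read_row, a2$read_row))
  }

  if (length(ev) == 0) return(empty)
  evd <- do.call(rbind, ev)
  evd <- evd[!duplicated(paste(evd$end_a, evd$end_b, evd$key)), ,
             drop = FALSE]
  keyed <- paste(evd$end_a, evd$end_b)
  out <- lapply(split(seq_len(nrow(evd)), keyed), function(ii) {
    e <- evd[ii, , drop = FALSE]
    kinds <- unique(e$kind)
    data.frame(end_a = e$end_a[1], end_b = e$end_b[1],
               kind = if (length(kinds) == 2) "both" else kinds,
               support = length(unique(e$key)),
               gap = mean(e$gap),
               gap_sd = if (nrow(e) > 1) stats::sd(e$gap) else NA_real_,
               max_aln = max(e$aln_len),
               rows = I(list(sort(unique(unlist(e$rows))))),
               stringsAsFactors = FALSE)
  })
  edges <- do.call(rbind, out)
  edges <- edges[edges$support >= min_edge_support, , drop = FALSE]
  edges <- edges[order(edges$end_a, edges$end_b), , drop = FALSE]
  rownames(edges) <- NULL
  names(edges)[names(edges) == "rows"] <- "read_rows"
  class(edges) <- c("contig_edges", "data.frame")
  edges
}

edge_touches <- function(edges, ekey) {
  which(edges$end_a == ekey | edges$end_b == ekey)
}

edge_other_end <- function(edges, i, ekey) {
  if (edges$end_a[i] == ekey) edges$end_b[i] else edges$end_a[i]
}

parse_end2 <- function(x) {
  sp <- strsplit(x, ":", fixed = TRUE)[[1]]
  list(contig = as.integer(sp[1]), side = sp[2])
}

# opposite end of a contig entered at `ekey`
opposite_end <- function(ekey) {
  p <- parse_end2(ekey)
  end_key(p$contig, if (p$side == "L") "R" else "L")
}

#' Resolve a fork during contig-graph traversal
#'
#' Bounded depth-first search (at most `fork_search_depth` edges) down each
#' candidate edge, looking for a vertex whose depth is within a factor
#' `depth_similarity_ratio` of the walk depth. A candidate wins if it
#' alone reaches such a vertex; failing that, an edge whose longest
#' supporting alignment is at least twice every rival's, then an edge
#' whose support is at least twice every rival's. Otherwise the walk
#' terminates.
#'
#' @param contigs a `contig_set`.
#' @param edges a `contig_edges` table.
#' @param cand_idx candidate edge indices out of the fork end.
#' @param fork_end the oriented end (`"<contig>:<side>"`) being left.
#' @param walk_depth running length-weighted mean depth of the walk.
#' @param fork_search_depth DFS edge budget.
#' @param depth_similarity_ratio similarity ratio bound (> 1).
#' @param exclude contig ids the search may not enter (e.g. path members).
#' @return the chosen edge index, or `NA` if the fork is unresolvable.
#' @export
resolve_fork <- function(contigs, edges, cand_idx, fork_end, walk_depth,
                         fork_search_depth = 5L,
                         depth_similarity_ratio = 2.0,
                         exclude = integer(0)) {
  similar <- function(d) {
    max(d, walk_depth) / min(d, walk_depth) <= depth_similarity_ratio
  }
  reach_similar <- function(first_edge) {
    hits <- integer(0)
    walk <- function(ekey, depth_left, seen) {
      v <- parse_end2(ekey)$contig
      if (v %in% exclude) return(invisible())
      if (similar(contigs$depth[v])) hits <<- c(hits, v)
      if (depth_left <= 0L) return(invisible())
      out_end <- opposite_end(ekey)
      for (j in edge_touches(edges, out_end)) {
        if (j %in% seen) next
        walk(edge_other_end(edges, j, out_end), depth_left - 1L,
             c(seen, j))
      }
    }
    entered <- edge_other_end(edges, first_edge, fork_end)
    walk(entered, fork_search_depth - 1L, first_edge)
    unique(hits)
  }
  sim_sets <- lapply(cand_idx, reach_similar)
  n_sim <- vapply(sim_sets, length, integer(1))
  if (sum(n_sim > 0) == 1L) return(cand_idx[n_sim > 0])
  # refinement 1: much longer supporting alignments
  ml <- edges$max_aln[cand_idx]
  for (i in seq_along(cand_idx))
    if (all(ml[i] >= 2 * ml[-i])) return(cand_idx[i])
  # refinement 2: much better supported
  sp <- edges$support[cand_idx]
  for (i in seq_along(cand_idx))
    if (all(sp[i] >= 2 * sp[-i])) return(cand_idx[i])
  NA_integer_
}

# walk a path out of `seed`, never entering `excluded` contigs
walk_path <- function(contigs, edges, seed, excluded,
                      fork_search_depth, depth_similarity_ratio) {
  path <- data.frame(contig = seed, orient = "+", gap_after = NA_real_,
                     edge_after = NA_integer_, stringsAsFactors = FALSE)
  clen <- nchar(contigs$seq)
  extend <- function(path, forward) {
    repeat {
      if (forward) {
        last <- path[nrow(path), ]
        cur_end <- end_key(last$contig, if (last$orient == "+") "R" else "L")
      } else {
        first <- path[1, ]
        cur_end <- end_key(first$contig, if (first$orient == "+") "L" else "R")
      }
      cand <- edge_touches(edges, cur_end)
      cand <- cand[!vapply(cand, function(j)
        parse_end2(edge_other_end(edges, j, cur_end))$contig %in%
          c(path$contig, excluded), logical(1))]
      if (length(cand) == 0) return(path)
      wd <- sum(contigs$depth[path$contig] * clen[path$contig]) /
        sum(clen[path$contig])
      j <- if (length(cand) == 1L) cand else
        resolve_fork(contigs, edges, cand, cur_end, wd,
                     fork_search_depth, depth_similarity_ratio,
                     exclude = c(path$contig, excluded))
      if (is.na(j)) return(path)
      peer <- parse_end2(edge_other_end(edges, j, cur_end))
      if (forward) {
        ori <- if (peer$side == "L") "+" else "-"
        path$gap_after[nrow(path)] <- edges$gap[j]
        path$edge_after[nrow(path)] <- j
        path <- rbind(path, data.frame(contig = peer$contig, orient = ori,
                                       gap_after = NA_real_,
                                       edge_after = NA_integer_,
                                       stringsAsFactors = FALSE))
      } else {
        ori <- if (peer$side == "R") "+" else "-"
        path <- rbind(data.frame(contig = peer$contig, orient = ori,
                                 gap_after = edges$gap[j],
                                 edge_after = j,
                                 stringsAsFactors = FALSE), path)
      }
    }
  }
  path <- extend(path, forward = TRUE)
  path <- extend(path, forward = FALSE)
  path
}

#' Traverse the contig graph into vertex-disjoint scaffold paths
#'
#' Walks are seeded from every contig in decreasing length order (longer
#' contigs carry more reliable depth). Walks are speculative: all
#' candidate paths of a round are generated against the same assigned
#' set, then accepted longest-first (total bases; ties to the lower seed
#' id), discarding any path that shares a vertex with an already accepted
#' one; orphaned vertices are re-walked in the next round until every
#' contig lies in exactly one path.
#'
#' @param contigs a `contig_set`.
#' @param edges a `contig_edges` table.
#' @param config an [assembly_config()].
#' @return list of path data.frames (`contig`, `orient`, `gap_after`,
#'   `edge_after`).
#' @export
traverse_contig_graph <- function(contigs, edges,
                                  config = assembly_config()) {
  n <- nrow(contigs)
  assigned <- rep(FALSE, n)
  paths <- list()
  ord <- order(-nchar(contigs$seq), contigs$id)
  while (!all(assigned)) {
    seeds <- contigs$id[ord][!assigned[contigs$id[ord]]]
    cands <- lapply(seeds, function(s)
      walk_path(contigs, edges, s, which(assigned),
                config$fork_search_depth, config$depth_similarity_ratio))
    bp <- vapply(cands, function(p) sum(nchar(contigs$seq[p$contig])),
                 numeric(1))
    acc_order <- order(-bp, seeds)
    progressed <- FALSE
    for (i in acc_order) {
      p <- cands[[i]]
      if (any(assigned[p$contig])) next
      paths[[length(paths) + 1L]] <- p
      assigned[p$contig] <- TRUE
      progressed <- TRUE
    }
    if (!progressed) break  # cannot happen: the best candidate is disjoint
  }
  paths
}

# vote-walk gap filling between two oriented sequences
fill_gap <- function(left_seq, right_seq, gap, fill_reads, seed_len,
                     qual_floor, insert_sigma, k) {
  n_fallback <- function() {
    paste0(left_seq, strrep("N", max(1L, round(gap))), right_seq)
  }
  if (gap < 0) {
    # try exact-overlap merge near the estimated overlap; overlaps of at
    # least k-1 are always trusted, shorter ones only down to the
    # estimate itself (floor 10) since the gap estimate vouches for them
    min_ov <- max(10L, min(k - 1L, as.integer(floor(-gap))))
    ovs <- seq.int(min_ov,
                   min(nchar(left_seq), nchar(right_seq),
                       ceiling(-gap + 3 * insert_sigma)))
    if (length(ovs) > 0) {
      ovs <- ovs[order(abs(ovs + gap))]
      for (ov in ovs) {
        a <- substring(left_seq, nchar(left_seq) - ov + 1L)
        b <- substring(right_seq, 1L, ov)
        if (sum(utf8ToInt(a) != utf8ToInt(b)) <= 1L)
          return(paste0(left_seq, substring(right_seq, ov + 1L)))
      }
    }
    return(paste0(left_seq, "N", right_seq))
  }
  if (nrow(fill_reads) == 0) return(n_fallback())
  target_window <- substring(right_seq, 1L,
                             min(nchar(right_seq),
                                 ceiling(gap + 3 * insert_sigma) +
                                   2L * seed_len))
  reads_fwd <- fill_reads$seq
  reads_rc <- revcomp(reads_fwd)
  quals_fwd <- fill_reads$qual
  quals_rc <- vapply(quals_fwd, function(q)
    paste(rev(strsplit(q, "")[[1]]), collapse = ""), character(1),
    USE.NAMES = FALSE)
  grown <- ""
  max_steps <- ceiling(gap + 3 * insert_sigma) + 2L * seed_len
  for (step in seq_len(max_steps)) {
    tip <- paste0(substring(left_seq,
                            max(1L, nchar(left_seq) - seed_len + 1L + nchar(grown)),
                            nchar(left_seq)), grown)
    tip <- substring(tip, max(1L, nchar(tip) - seed_len + 1L))
    if (nchar(tip) < seed_len) return(n_fallback())
    # reached the right contig?
    hit <- regexpr(tip, target_window, fixed = TRUE)
    if (hit > 0) {
      return(paste0(left_seq, grown,
                    substring(right_seq, hit + seed_len)))
    }
    votes <- c(A = 0L, C = 0L, G = 0L, T = 0L)
    vote_scan <- function(rs, qs) {
      for (i in seq_along(rs)) {
        p <- regexpr(tip, rs[i], fixed = TRUE)
        if (p > 0 && p + seed_len <= nchar(rs[i])) {
          b <- substring(rs[i], p + seed_len, p + seed_len)
          q <- phred_scores(substring(qs[i], p + seed_len, p + seed_len))
          if (b %in% names(votes) && length(q) == 1 && q >= qual_floor)
            votes[b] <<- votes[b] + 1L
        }
      }
    }
    vote_scan(reads_fwd, quals_fwd)
    vote_scan(reads_rc, quals_rc)
    qual <- names(votes)[votes >= 2L]
    if (length(qual) != 1L) return(n_fallback())
    grown <- paste0(grown, qual)
  }
  n_fallback()
}

#' Render one scaffold path to sequence
#'
#' Gaps are filled by a local vote-walk over the reads that supported the
#' junction's edge (plus their mates), requiring two concordant votes per
#' base and an exact `seed_len`-mer landing on the next contig; on failure
#' the estimated gap is padded with `N`s. Negative gaps attempt an exact
#' overlap merge (at least k-1 bases, at most one mismatch), else a single
#' `N`.
#'
#' @param path one path from [traverse_contig_graph()].
#' @param contigs a `contig_set`.
#' @param edges the `contig_edges` used to build the path.
#' @param reads the read table.
#' @param config an [assembly_config()].
#' @param k assembler k (for the minimum overlap; the largest of
#'   `config$k_list` when called inside the pipeline).
#' @return list with `seq` and `depth` (length-weighted mean).
#' @export
close_gaps <- function(path, contigs, edges, reads,
                       config = assembly_config(),
                       k = max(config$k_list)) {
  oriented <- function(i) {
    s <- contigs$seq[path$contig[i]]
    if (path$orient[i] == "+") s else revcomp(s)
  }
  seqs <- vapply(seq_len(nrow(path)), oriented, character(1))
  out <- seqs[1]
  if (nrow(path) > 1) {
    pair_map <- split(seq_len(nrow(reads)), reads$pair_id)
    for (i in seq_len(nrow(path) - 1L)) {
      gap <- path$gap_after[i]
      ej <- path$edge_after[i]
      rows <- if (!is.na(ej)) edges$read_rows[[ej]] else integer(0)
      if (length(rows) > 0) {
        mates <- unlist(pair_map[reads$pair_id[rows]], use.names = FALSE)
        rows <- sort(unique(c(rows, mates)))
      }
      out <- fill_gap(out, seqs[i + 1L], gap,
                      reads[rows, , drop = FALSE],
                      config$seed_len, config$qual_floor,
                      config$insert_sigma, k)
    }
  }
  w <- nchar(contigs$seq[path$contig])
  list(seq = out,
       depth = sum(contigs$depth[path$contig] * w) / sum(w))
}

#' Scaffold contigs with paired-end evidence, over repeated rounds
#'
#' Each round aligns the reads to the current contigs, builds the splint /
#' span contig graph, traverses it into vertex-disjoint paths, and renders
#' gap-filled scaffolds, which become the contigs of the next round.
#' Repeats tend to increase contiguity at some cost in error; the round
#' count is the user's trade-off knob.
#'
#' @param contigs a `contig_set` (e.g. from [run_all()]).
#' @param reads the read table.
#' @param config an [assembly_config()]; `config$scaffold_rounds` rounds
#'   are run.
#' @return a `contig_set` of scaffolds, ids stable (sorted by sequence).
#' @export
scaffold_rounds <- function(contigs, reads, config = assembly_config()) {
  k <- max(config$k_list)
  cur <- contigs
  for (round in seq_len(config$scaffold_rounds)) {
    if (nrow(cur) <= 1) break
    aln <- align_reads_to_contigs(reads, cur, config$seed_len)
    edges <- build_edges(aln, cur, reads, config$insert_mu,
                         config$insert_sigma, config$min_edge_support)
    paths <- traverse_contig_graph(cur, edges, config)
    rendered <- lapply(paths, close_gaps, contigs = cur, edges = edges,
                       reads = reads, config = config, k = k)
    seqs <- vapply(rendered, `[[`, "", "seq")
    depths <- vapply(rendered, `[[`, 0, "depth")
    ord <- order(seqs)
    cur <- as_contig_set(seqs[ord], depths[ord], k)
  }
  cur
}

#' Write a contig-graph edge table to TSV
#' @param edges a `contig_edges` table from [build_edges()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_edges <- function(edges, path) {
  utils::write.table(
    as.data.frame(edges)[, c("end_a", "end_b", "kind", "support",
                             "gap", "gap_sd")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
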