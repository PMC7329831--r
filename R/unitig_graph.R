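#' Build the unitig graph over walked contigs
#'
#' Contig ends that terminated at a fork (or ran into an already-claimed
#' k-mer) are linked to the contigs whose terminal k-mer is the qualifying
#' neighbor, one node-overlap (k-1 bases) apart. Links are only made to
#' *terminal* k-mers of other contigs; a qualifying extension landing in a
#' contig interior is left unlinked. The graph is strand-symmetric: every
#' edge is stored once per unordered pair of oriented ends.
#'
#' @param contigs a `contig_set` from [walk_contigs()].
#' @param table the `kmer_table` the contigs were walked from.
#' @param policy the [threshold_policy()] used during the walk.
#' @return object of class `unitig_graph`: list with `contigs`, `edges`
#'   (`id_a`, `side_a`, `id_b`, `side_b`), and `k`.
#' @export
build_unitig_graph <- function(contigs, table, policy = threshold_policy()) {
  k <- attr(table, "k")
  if (!is.null(attr(contigs, "k")) && !is.na(attr(contigs, "k")) &&
      attr(contigs, "k") != k)
    stop("contigs and table disagree on k", call. = FALSE)
  n <- nrow(contigs)
  edges <- data.frame(id_a = integer(0), side_a = character(0),
                      id_b = integer(0), side_b = character(0),
                      stringsAsFactors = FALSE)
  g <- structure(list(contigs = contigs, edges = edges, k = k),
                 class = "unitig_graph")
  if (n == 0) return(g)
  if (any(nchar(contigs$seq) < k))
    stop("contig shorter than k: inconsistent contig/table pair",
         call. = FALSE)

  ext <- as.matrix(as.data.frame(table)[, ext_cols, drop = FALSE])

  L <- nchar(contigs$seq)
  left_k <- substring(contigs$seq, 1L, k)
  right_k <- substring(contigs$seq, L - k + 1L, L)

  # all 2n ends at once: outward extension counts in end orientation
  end_contig <- rep(seq_len(n), 2L)
  end_side <- rep(c("L", "R"), each = n)
  okmer <- c(left_k, right_k)
  canon_ok <- canonicalize(okmer)
  rec_i <- match(canon_ok, table$kmer)
  is_can <- canon_ok == okmer
  # column selection: outward side in canonical storage, complemented and
  # mirrored when the end k-mer is stored reverse-complemented
  colsel <- matrix(NA_integer_, length(okmer), 4)
  sel <- end_side == "R" & is_can;  colsel[sel, ] <- rep(5:8, each = sum(sel))
  sel <- end_side == "R" & !is_can; colsel[sel, ] <- rep(4:1, each = sum(sel))
  sel <- end_side == "L" & is_can;  colsel[sel, ] <- rep(1:4, each = sum(sel))
  sel <- end_side == "L" & !is_can; colsel[sel, ] <- rep(8:5, each = sum(sel))
  counts <- matrix(0L, length(okmer), 4)
  okrows <- which(!is.na(rec_i))
  for (j in 1:4)
    counts[okrows, j] <- ext[cbind(rec_i[okrows], colsel[okrows, j])]
  thr <- rep(.Machine$integer.max, length(okmer))
  thr[okrows] <- adaptive_threshold(table$count[rec_i[okrows]], policy)
  qual <- counts >= thr

  # neighbor k-mers for every qualifying (end, base), in bulk
  hits <- which(qual, arr.ind = TRUE)
  ea <- integer(0); sa <- character(0); eb <- integer(0); sb <- character(0)
  if (nrow(hits) > 0) {
    e_i <- hits[, 1]
    base <- c("A", "C", "G", "T")[hits[, 2]]
    is_R <- end_side[e_i] == "R"
    nb <- ifelse(is_R, paste0(substring(okmer[e_i], 2L), base),
                 paste0(base, substring(okmer[e_i], 1L, k - 1L)))
    # neighbor as it would read *leaving* this end
    leaving <- nb
    leaving[!is_R] <- revcomp(nb[!is_R])
    hit_L <- match(leaving, left_k)
    hit_R <- match(revcomp(leaving), right_k)
    cj <- ifelse(!is.na(hit_L), hit_L, hit_R)
    side_j <- ifelse(!is.na(hit_L), "L", "R")
    keep <- !is.na(cj)
    ea <- end_contig[e_i[keep]]; sa <- end_side[e_i[keep]]
    eb <- cj[keep]; sb <- side_j[keep]
  }
  if (length(ea) > 0) {
    # dedupe unordered end pairs
    a_end <- paste0(ea, ":", sa); b_end <- paste0(eb, ":", sb)
    lo <- pmin(a_end, b_end); hi <- pmax(a_end, b_end)
    keep <- !duplicated(paste(lo, hi)) & a_end != b_end
    parse_end <- function(x) {
      sp <- strsplit(x, ":", fixed = TRUE)
      list(id = as.integer(vapply(sp, `[`, "", 1L)),
           side = vapply(sp, `[`, "", 2L))
    }
    pa <- parse_end(lo[keep]); pb <- parse_end(hi[keep])
    g$edges <- data.frame(id_a = pa$id, side_a = pa$side,
                          id_b = pb$id, side_b = pb$side,
                          stringsAsFactors = FALSE)
  }
  g$attach <- implicit_attachments(g, table)
  g
}

# Ends whose adjacent table k-mer lies in the *interior* of another contig
# never get a junction edge: the deeper walk passed straight through the
# branching k-mer because the shallow branch fell below the adaptive
# threshold. These implicit attachments mark error tips and error bubbles
# hanging off a trunk, and feed hair removal and bubble merging.
implicit_attachments <- function(g, table) {
  co <- g$contigs
  k <- g$k
  empty <- data.frame(id = integer(0), side = character(0),
                      host = integer(0), host_depth = numeric(0),
                      stringsAsFactors = FALSE)
  if (nrow(co) < 2) return(empty)
  # constituent-k-mer -> deepest host contig, one batch
  windows <- lapply(co$seq, seq_windows, k = k)
  kmap <- data.table::data.table(
    kmer = canonicalize(unlist(windows, use.names = FALSE)),
    host = rep(co$id, lengths(windows)))
  depth_by_id <- setNames(co$depth, co$id)
  kmap[, host_depth := depth_by_id[as.character(host)]]
  data.table::setorder(kmap, kmer, -host_depth)
  kmap <- kmap[!duplicated(kmer)]

  # edge-free ends, their four possible neighbor k-mers, in bulk
  L <- nchar(co$seq)
  end_id <- rep(co$id, 2L)
  end_side <- rep(c("L", "R"), each = nrow(co))
  okmer <- c(substring(co$seq, 1L, k), substring(co$seq, L - k + 1L, L))
  has_edge <- paste(end_id, end_side) %in%
    c(paste(g$edges$id_a, g$edges$side_a),
      paste(g$edges$id_b, g$edges$side_b))
  free <- which(!has_edge)
  if (length(free) == 0) return(empty)
  e_i <- rep(free, each = 4L)
  base <- rep(c("A", "C", "G", "T"), length(free))
  is_R <- end_side[e_i] == "R"
  nb <- ifelse(is_R, paste0(substring(okmer[e_i], 2L), base),
               paste0(base, substring(okmer[e_i], 1L, k - 1L)))
  cn <- canonicalize(nb)
  in_table <- !is.na(match(cn, table$kmer))
  hit <- match(cn, kmap$kmer)
  valid <- in_table & !is.na(hit) & kmap$host[hit] != end_id[e_i]
  if (!any(valid)) return(empty)
  cand <- data.table::data.table(
    id = end_id[e_i[valid]], side = end_side[e_i[valid]],
    host = kmap$host[hit[valid]], host_depth = kmap$host_depth[hit[valid]])
  data.table::setorder(cand, id, side, -host_depth)
  as.data.frame(cand[!duplicated(paste(id, side))])
}

#' @export
print.unitig_graph <- function(x, ...) {
  cat(sprintf("unitig_graph: %d contigs, %d edges (k=%d)\n",
              nrow(x$contigs), nrow(x$edges), x$k))
  invisible(x)
}

# edges incident to end (id, side); returns row indices into g$edges
incident <- function(g, id, side) {
  which((g$edges$id_a == id & g$edges$side_a == side) |
        (g$edges$id_b == id & g$edges$side_b == side))
}

# peer (id, side) across edge row i from the perspective of contig `id`
edge_peer <- function(g, i, id, side) {
  e <- g$edges[i, ]
  if (e$id_a == id && e$side_a == side) list(id = e$id_b, side = e$side_b)
  else list(id = e$id_a, side = e$side_a)
}

drop_contigs <- function(g, ids) {
  if (length(ids) == 0) return(g)
  g$edges <- g$edges[!(g$edges$id_a %in% ids | g$edges$id_b %in% ids), ,
                     drop = FALSE]
  g$contigs <- g$contigs[!(g$contigs$id %in% ids), , drop = FALSE]
  if (!is.null(g$attach) && nrow(g$attach) > 0)
    g$attach <- g$attach[!(g$attach$id %in% ids | g$attach$host %in% ids), ,
                         drop = FALSE]
  g
}

attach_at <- function(g, id, side) {
  if (is.null(g$attach) || nrow(g$attach) == 0) return(NULL)
  a <- g$attach[g$attach$id == id & g$attach$side == side, , drop = FALSE]
  if (nrow(a) == 0) NULL else a[1, ]
}

#' Merge bubbles in the unitig graph
#'
#' Two parallel contigs joining the same pair of junction ends, each no
#' longer than `bubble_len_factor * k`, are collapsed: the lower-depth
#' branch is deleted and its depth added to the survivor (preserving
#' coverage mass). Ties keep the lexicographically smaller sequence.
#' Repeats to fixpoint.
#'
#' @param g a `unitig_graph`.
#' @param bubble_len_factor length gate in units of k.
#' @return the modified graph.
#' @export
merge_bubbles <- function(g, bubble_len_factor = 3L) {
  gate <- bubble_len_factor * g$k
  repeat {
    changed <- FALSE
    co <- g$contigs
    # candidate branches: exactly one edge on each side
    sig <- vapply(seq_len(nrow(co)), function(i) {
      id <- co$id[i]
      el <- incident(g, id, "L"); er <- incident(g, id, "R")
      if (length(el) != 1L || length(er) != 1L) return(NA_character_)
      pl <- edge_peer(g, el, id, "L"); pr <- edge_peer(g, er, id, "R")
      if (pl$id == id || pr$id == id) return(NA_character_)  # self loop
      ends <- sort(c(paste0(pl$id, ":", pl$side),
                     paste0(pr$id, ":", pr$side)))
      if (ends[1] == ends[2]) return(NA_character_)
      paste(ends, collapse = "|")
    }, character(1))
    ok <- !is.na(sig) & nchar(co$seq) <= gate
    groups <- split(which(ok), sig[ok])
    losers_all <- integer(0)
    for (grp in groups) {
      if (length(grp) < 2) next
      d <- co$depth[grp]; s <- co$seq[grp]
      best <- grp[order(-d, s)][1]
      losers <- setdiff(grp, best)
      g$contigs$depth[g$contigs$id == co$id[best]] <-
        co$depth[best] + sum(co$depth[losers])
      losers_all <- c(losers_all, losers)
      changed <- TRUE
    }
    if (length(losers_all) > 0) g <- drop_contigs(g, co$id[losers_all])
    if (!changed) break
  }
  # implicit bubbles: an edge-free branch whose two ends both rejoin the
  # same deeper trunk contig (the parallel path an error carves through a
  # well-covered region); the branch is absorbed into the trunk,
  # conserving coverage mass
  repeat {
    changed <- FALSE
    co <- g$contigs
    att <- g$attach
    if (is.null(att) || nrow(att) == 0) break
    edged <- unique(c(paste(g$edges$id_a, g$edges$side_a),
                      paste(g$edges$id_b, g$edges$side_b)))
    aL <- att[att$side == "L", , drop = FALSE]
    aR <- att[att$side == "R", , drop = FALSE]
    iL <- match(co$id, aL$id); iR <- match(co$id, aR$id)
    cand <- which(nchar(co$seq) <= gate &
                    !is.na(iL) & !is.na(iR) &
                    aL$host[iL] == aR$host[iR] &
                    co$depth <= aL$host_depth[iL] &
                    !(paste(co$id, "L") %in% edged) &
                    !(paste(co$id, "R") %in% edged))
    # never absorb a branch into a host deleted in the same sweep
    cand <- cand[!(aL$host[iL[cand]] %in% co$id[cand])]
    if (length(cand) > 0) {
      hosts <- aL$host[iL[cand]]
      mass <- tapply(co$depth[cand] * co$nkmer[cand], hosts, sum)
      hi <- match(as.integer(names(mass)), g$contigs$id)
      g$contigs$depth[hi] <- g$contigs$depth[hi] +
        as.numeric(mass) / g$contigs$nkmer[hi]
      g <- drop_contigs(g, co$id[cand])
      changed <- TRUE
    }
    if (!changed) break
  }
  g
}

#' Remove hairs (short dead-end branches)
#'
#' A contig with exactly one junction-attached end and one free end, at
#' most `hair_len_factor * k` long, and shallower than the deepest branch
#' at its junction is deleted. Repeats to fixpoint, then unbranched chains
#' are re-concatenated.
#'
#' @param g a `unitig_graph`.
#' @param hair_len_factor length gate in units of k.
#' @return the modified graph.
#' @export
remove_hairs <- function(g, hair_len_factor = 2L) {
  gate <- hair_len_factor * g$k
  repeat {
    co <- g$contigs
    to_drop <- integer(0)
    short <- which(nchar(co$seq) <= gate)
    for (i in short) {
      id <- co$id[i]
      el <- incident(g, id, "L"); er <- incident(g, id, "R")
      aL <- attach_at(g, id, "L"); aR <- attach_at(g, id, "R")
      # an end counts as junction-attached via an explicit fork edge or an
      # implicit attachment into a trunk interior
      l_att <- length(el) > 0 || !is.null(aL)
      r_att <- length(er) > 0 || !is.null(aR)
      if (l_att == r_att) next                 # isolated or both attached
      att <- if (l_att) el else er
      side <- if (l_att) "L" else "R"
      impl <- if (l_att) aL else aR
      # junction = the peer end(s); branch depths = all contigs hanging off
      # those ends plus the junction contigs themselves
      peer_depths <- if (is.null(impl)) numeric(0) else impl$host_depth
      for (e in att) {
        p <- edge_peer(g, e, id, side)
        peer_depths <- c(peer_depths,
                         co$depth[co$id == p$id])
        for (e2 in incident(g, p$id, p$side)) {
          q <- edge_peer(g, e2, p$id, p$side)
          peer_depths <- c(peer_depths, co$depth[co$id == q$id])
        }
      }
      if (co$depth[i] < max(peer_depths)) to_drop <- c(to_drop, id)
    }
    if (length(to_drop) == 0) break
    g <- drop_contigs(g, to_drop)
  }
  condense_graph(g)
}

#' Prune depth-discordant fork branches
#'
#' At every junction end with two or more outgoing links, links to branches
#' whose depth falls below `prune_ratio` times the deepest branch there are
#' severed (the branch contig is kept, only the connection is cut).
#' Iterates until no change or `prune_max_iters`, then re-concatenates
#' unbranched chains with length-weighted mean depth.
#'
#' @param g a `unitig_graph`.
#' @param prune_ratio ratio gate in (0, 1).
#' @param prune_max_iters iteration cap.
#' @return the modified graph.
#' @export
prune_forks <- function(g, prune_ratio = 0.1, prune_max_iters = 10L) {
  stopifnot(prune_ratio > 0, prune_ratio < 1)
  for (iter in seq_len(prune_max_iters)) {
    changed <- FALSE
    co <- g$contigs
    depth_of <- function(id) co$depth[co$id == id]
    to_drop <- integer(0)
    for (i in seq_len(nrow(co))) {
      for (side in c("L", "R")) {
        inc <- incident(g, co$id[i], side)
        if (length(inc) < 2) next
        d <- vapply(inc, function(e)
          depth_of(edge_peer(g, e, co$id[i], side)$id), numeric(1))
        cut <- inc[d < prune_ratio * max(d)]
        to_drop <- c(to_drop, cut)
      }
    }
    to_drop <- unique(to_drop)
    if (length(to_drop) > 0) {
      g$edges <- g$edges[-to_drop, , drop = FALSE]
      changed <- TRUE
    }
    if (!changed) break
  }
  condense_graph(g)
}

#' Re-concatenate unbranched chains of the unitig graph
#'
#' Wherever an edge joins two ends that each carry exactly one link, the
#' two contigs are merged across their k-1 base node overlap; depth becomes
#' the k-mer-count-weighted mean. Repeats until no such edge remains.
#'
#' @param g a `unitig_graph`.
#' @return the condensed graph.
#' @export
condense_graph <- function(g) {
  k <- g$k
  repeat {
    merged <- FALSE
    if (nrow(g$edges) == 0) break
    for (e in seq_len(nrow(g$edges))) {
      ed <- g$edges[e, ]
      if (ed$id_a == ed$id_b) next                      # circular
      if (length(incident(g, ed$id_a, ed$side_a)) != 1L) next
      if (length(incident(g, ed$id_b, ed$side_b)) != 1L) next
      g <- merge_edge(g, e)
      merged <- TRUE
      break
    }
    if (!merged) break
  }
  g
}

# flip a contig in place: reverse-complement sequence, swap edge sides
flip_contig <- function(g, id) {
  i <- which(g$contigs$id == id)
  g$contigs$seq[i] <- revcomp(g$contigs$seq[i])
  swap <- function(s) ifelse(s == "L", "R", "L")
  sel_a <- g$edges$id_a == id
  sel_b <- g$edges$id_b == id
  g$edges$side_a[sel_a] <- swap(g$edges$side_a[sel_a])
  g$edges$side_b[sel_b] <- swap(g$edges$side_b[sel_b])
  st <- g$contigs[i, c("left_state", "right_state")]
  g$contigs$left_state[i] <- st[[2]]; g$contigs$right_state[i] <- st[[1]]
  fk <- g$contigs[i, c("left_fork", "right_fork")]
  comp_sort <- function(z) {
    if (nchar(z) == 0) return(z)
    paste(sort(strsplit(chartr("ACGT", "TGCA", z), "")[[1]]), collapse = "")
  }
  g$contigs$left_fork[i] <- comp_sort(fk[[2]])
  g$contigs$right_fork[i] <- comp_sort(fk[[1]])
  if (!is.null(g$attach) && nrow(g$attach) > 0) {
    sel <- g$attach$id == id
    g$attach$side[sel] <- swap(g$attach$side[sel])
  }
  g
}

# merge the two contigs joined by edge row e (both ends must be simple)
merge_edge <- function(g, e) {
  ed <- g$edges[e, ]
  k <- g$k
  # orient A so the joining side is R, B so it is L
  if (ed$side_a == "L") { g <- flip_contig(g, ed$id_a); ed$side_a <- "R" }
  if (ed$side_b == "R") { g <- flip_contig(g, ed$id_b); ed$side_b <- "L" }
  ia <- which(g$contigs$id == ed$id_a)
  ib <- which(g$contigs$id == ed$id_b)
  A <- g$contigs[ia, ]; B <- g$contigs[ib, ]
  if (substring(A$seq, nchar(A$seq) - k + 2L) !=
      substring(B$seq, 1L, k - 1L)) {
    # overlap does not verify; sever the link instead of corrupting
    g$edges <- g$edges[-e, , drop = FALSE]
    return(g)
  }
  newseq <- paste0(A$seq, substring(B$seq, k))
  nk <- A$nkmer + B$nkmer
  g$contigs$seq[ia] <- newseq
  g$contigs$depth[ia] <- (A$depth * A$nkmer + B$depth * B$nkmer) / nk
  g$contigs$nkmer[ia] <- nk
  g$contigs$right_state[ia] <- B$right_state
  g$contigs$right_fork[ia] <- B$right_fork
  # re-point B's remaining (right-side) edges at A's new right end
  g$edges <- g$edges[-e, , drop = FALSE]
  sel_a <- g$edges$id_a == ed$id_b
  sel_b <- g$edges$id_b == ed$id_b
  g$edges$id_a[sel_a] <- ed$id_a
  g$edges$id_b[sel_b] <- ed$id_a
  g$contigs <- g$contigs[-ib, , drop = FALSE]
  if (!is.null(g$attach) && nrow(g$attach) > 0) {
    keep <- !(g$attach$id == ed$id_b & g$attach$side == "L")
    g$attach <- g$attach[keep, , drop = FALSE]
    g$attach$id[g$attach$id == ed$id_b] <- ed$id_a
    g$attach$host[g$attach$host == ed$id_b] <- ed$id_a
  }
  g
}

#' Extract the contig set of a unitig graph
#' @param g a `unitig_graph`.
#' @return a `contig_set` with stable, renumbered ids (sorted by sequence).
#' @export
graph_contigs <- function(g) {
  co <- g$contigs[order(g$contigs$seq), , drop = FALSE]
  co$id <- seq_len(nrow(co))
  rownames(co) <- NULL
  attr(co, "k") <- g$k
  class(co) <- c("contig_set", "data.frame")
  co
}
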