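rand_seq <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
}

# hand-built unitig graph for refinement unit tests
make_graph <- function(seqs, depths, edges, k = 21L) {
  co <- data.frame(id = seq_along(seqs), seq = seqs, depth = depths,
                   nkmer = nchar(seqs) - k + 1L,
                   left_state = "deadend", right_state = "deadend",
                   left_fork = "", right_fork = "",
                   stringsAsFactors = FALSE)
  ed <- if (is.null(edges))
    data.frame(id_a = integer(0), side_a = character(0),
               id_b = integer(0), side_b = character(0),
               stringsAsFactors = FALSE)
  else data.frame(id_a = edges[, 1], side_a = edges[, 2],
                  id_b = edges[, 3], side_b = edges[, 4],
                  stringsAsFactors = FALSE)
  ed$id_a <- as.integer(ed$id_a); ed$id_b <- as.integer(ed$id_b)
  structure(list(contigs = co, edges = ed, k = k),
            class = "unitig_graph")
}

test_that("a low-depth SNP branch forms a fork and bubble merging keeps
           coverage mass", {
  k <- 21L
  g0 <- generate_genomes(600, seed = 17)[[1]]
  snp <- g0
  old <- substr(snp, 300, 300)
  substr(snp, 300, 300) <- if (old == "A") "C" else "A"
  tile <- function(s, cov) {
    starts <- unlist(lapply(seq_len(cov), function(o)
      seq(1 + (o * 17) %% 120, nchar(s) - 149, by = 150)))
    substring(s, starts, starts + 149)
  }
  rd <- reads_from_seqs(c(tile(g0, 10), tile(snp, 3)))
  tab <- count_kmers(rd, k)
  pol <- threshold_policy()
  contigs <- walk_contigs(tab, pol)
  gr <- build_unitig_graph(contigs, tab, pol)
  expect_true(nrow(gr$contigs) >= 4)   # trunk pieces + two branches
  total_before <- sum(gr$contigs$depth * gr$contigs$nkmer)
  gr2 <- merge_bubbles(gr, 3L)
  # one of the two parallel branches is gone
  expect_lt(nrow(gr2$contigs), nrow(gr$contigs))
  # the survivor absorbed the loser's depth (mass conserved at the bubble)
  expect_equal(sum(gr2$contigs$depth * gr2$contigs$nkmer), total_before,
               tolerance = 0.02)
  # after condensing, the sequence set contains the major allele path
  co <- graph_contigs(condense_graph(gr2))
  main <- co$seq[which.max(nchar(co$seq))]
  expect_true(grepl(main, g0, fixed = TRUE) ||
                grepl(rc_naive(main), g0, fixed = TRUE))
})

test_that("bubble merging respects the length gate and identity cases", {
  k <- 21L
  x <- rand_seq(100, 18); y <- rand_seq(100, 19)
  mk_branch <- function(mid_seed, mid_len) {
    paste0(substr(x, 100 - k + 2, 100), rand_seq(mid_len, mid_seed),
           substr(y, 1, k - 1))
  }
  p <- mk_branch(20, 10); q <- mk_branch(21, 12)
  ed <- rbind(c(1, "R", 3, "L"), c(1, "R", 4, "L"),
              c(3, "R", 2, "L"), c(4, "R", 2, "L"))
  g <- make_graph(c(x, y, p, q), c(30, 30, 10, 2), ed, k)
  g2 <- merge_bubbles(g, 3L)
  expect_equal(nrow(g2$contigs), 3)
  expect_false(q %in% g2$contigs$seq)   # lower depth branch deleted
  expect_equal(g2$contigs$depth[g2$contigs$seq == p], 12)

  # branches longer than the gate are untouched
  p2 <- mk_branch(22, 200); q2 <- mk_branch(23, 210)
  g3 <- make_graph(c(x, y, p2, q2), c(30, 30, 10, 2), ed, k)
  expect_equal(nrow(merge_bubbles(g3, 3L)$contigs), 4)

  # no parallel paths -> identity
  g4 <- make_graph(c(x, y), c(30, 30), NULL, k)
  expect_identical(merge_bubbles(g4, 3L)$contigs$seq, c(x, y))
})

test_that("hairs are clipped and the trunk re-concatenates", {
  k <- 21L
  a <- rand_seq(120, 24)
  b <- paste0(substr(a, 120 - k + 2, 120), rand_seq(120, 25))
  tip <- paste0(substr(a, 120 - k + 2, 120), rand_seq(5, 26))  # 25 bp
  ed <- rbind(c(1, "R", 2, "L"), c(1, "R", 3, "L"))
  g <- make_graph(c(a, b, tip), c(10, 10, 2), ed, k)
  g2 <- remove_hairs(g, 2L)
  expect_equal(nrow(g2$contigs), 1)    # tip gone, a+b condensed
  expect_equal(nchar(g2$contigs$seq), 120 + nchar(b) - (k - 1))

  # isolated contigs are never hairs
  g3 <- make_graph(tip, 2, NULL, k)
  expect_equal(nrow(remove_hairs(g3, 2L)$contigs), 1)

  # long dead ends are retained
  long_tip <- paste0(substr(a, 120 - k + 2, 120), rand_seq(80, 27))
  g4 <- make_graph(c(a, b, long_tip), c(10, 10, 2),
                   rbind(c(1, "R", 2, "L"), c(1, "R", 3, "L")), k)
  expect_equal(nrow(remove_hairs(g4, 2L)$contigs), 3)
})

test_that("fork pruning severs depth-discordant links and is idempotent", {
  k <- 21L
  a <- rand_seq(150, 28)
  b <- paste0(substr(a, 150 - k + 2, 150), rand_seq(150, 29))
  c_ <- paste0(substr(a, 150 - k + 2, 150), rand_seq(150, 30))
  ed <- rbind(c(1, "R", 2, "L"), c(1, "R", 3, "L"))
  g <- make_graph(c(a, b, c_), c(50, 50, 3), ed, k)
  g2 <- prune_forks(g, 0.1, 10L)
  # depth-3 link severed, a and b condensed into one chain
  expect_equal(nrow(g2$contigs), 2)
  expect_equal(nrow(g2$edges), 0)
  expect_true(any(nchar(g2$contigs$seq) == 150 + nchar(b) - (k - 1)))
  # fixpoint: pruning again changes nothing
  g3 <- prune_forks(g2, 0.1, 10L)
  expect_identical(g3$contigs$seq, g2$contigs$seq)

  # similar depths are both kept (no severing, fork intact, no condense)
  g4 <- make_graph(c(a, b, c_), c(50, 40, 45), ed, k)
  expect_equal(nrow(prune_forks(g4, 0.1, 10L)$edges), 2)
})

test_that("an X-shaped shared k-mer run yields arm and core contigs with
           two junctions", {
  k <- 21L
  core <- rand_seq(k, 31)
  # distinct flanking bases on both sides so the shared run is exactly core
  s1 <- paste0(rand_seq(149, 32), "A", core, "C", rand_seq(149, 33))
  s2 <- paste0(rand_seq(149, 34), "G", core, "T", rand_seq(149, 35))
  rd <- reads_from_seqs(rep(c(s1, s2), each = 3))
  tab <- count_kmers(rd, k)
  pol <- threshold_policy()
  contigs <- walk_contigs(tab, pol)
  gr <- build_unitig_graph(contigs, tab, pol)
  # 4 arms + shared core
  expect_equal(nrow(gr$contigs), 5)
  core_id <- gr$contigs$id[gr$contigs$seq == canonicalize(core)]
  expect_length(core_id, 1)
  # the core's two ends are the two junctions, two edges each
  expect_equal(length(metadbg:::incident(gr, core_id, "L")), 2)
  expect_equal(length(metadbg:::incident(gr, core_id, "R")), 2)
})

test_that("refinement never invents sequence or grows total length", {
  g <- generate_genomes(4000, seed = 36)
  rd <- sim_reads(g, depth = 15, error = 0.01, seed = 36)
  tab <- count_kmers(rd, 21)
  pol <- threshold_policy()
  contigs <- walk_contigs(tab, pol)
  gr <- build_unitig_graph(contigs, tab, pol)
  len0 <- sum(nchar(gr$contigs$seq))
  gr <- merge_bubbles(gr, 3L)
  gr <- remove_hairs(gr, 2L)
  gr <- prune_forks(gr, 0.1, 10L)
  co <- graph_contigs(gr)
  expect_lte(sum(nchar(co$seq)), len0)
  # every constituent k-mer of every refined contig is in the table
  tab_env <- new.env()
  for (km in tab$kmer) assign(km, TRUE, envir = tab_env)
  for (s in co$seq) {
    kms <- canonicalize(substring(s, 1:(nchar(s) - 20), 21:nchar(s)))
    expect_true(all(vapply(kms, exists, logical(1), envir = tab_env)))
  }
})
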