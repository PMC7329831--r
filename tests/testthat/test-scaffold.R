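# two-contig fixture with simulated pairs across a known gap
junction_fixture <- function(gap, seed, glen = 3000, depth = 30) {
  g <- generate_genomes(glen, seed = seed)[[1]]
  cut <- glen %/% 2
  co <- metadbg:::as_contig_set(
    c(substr(g, 1, cut), substr(g, cut + gap + 1, glen)),
    rep(depth, 2), 55)
  rd <- sim_reads(setNames(g, "g1"), depth = depth, seed = seed)
  list(genome = g, contigs = co, reads = rd, gap = gap)
}

test_that("read alignment finds full hits, splints and nothing for
           foreign reads", {
  g <- generate_genomes(2000, seed = 60)[[1]]
  co <- metadbg:::as_contig_set(c(substr(g, 1, 1000),
                                  substr(g, 1001, 2000)), c(10, 10), 55)
  inside <- reads_from_seqs(substr(g, 301, 450))
  a1 <- align_reads_to_contigs(inside, co)
  expect_equal(nrow(a1), 1)
  expect_equal(a1$rend - a1$rstart, 150)
  straddle <- reads_from_seqs(substr(g, 926, 1075))
  a2 <- align_reads_to_contigs(straddle, co)
  expect_equal(nrow(a2), 2)
  expect_setequal(a2$contig, 1:2)
  expect_equal(sum(a2$rend - a2$rstart), 150)
  foreign <- reads_from_seqs(generate_genomes(150, seed = 61)[[1]])
  expect_equal(nrow(align_reads_to_contigs(foreign, co)), 0)
})

test_that("span evidence estimates gaps within the insert spread", {
  fx <- junction_fixture(gap = 100, seed = 62)
  aln <- align_reads_to_contigs(fx$reads, fx$contigs)
  ed <- build_edges(aln, fx$contigs, fx$reads)
  expect_equal(nrow(ed), 1)
  expect_setequal(c(ed$end_a, ed$end_b), c("1:R", "2:L"))
  expect_gte(ed$support, 10)
  expect_lte(abs(ed$gap - fx$gap), 30)
})

test_that("an under-supported link never becomes an edge", {
  fx <- junction_fixture(gap = 50, seed = 63)
  aln <- align_reads_to_contigs(fx$reads, fx$contigs)
  keep <- aln$read_row %in% sample(unique(aln$read_row), 40)
  ed <- build_edges(aln, fx$contigs, fx$reads, min_edge_support = 1e6L)
  expect_equal(nrow(ed), 0)
})

test_that("splints link abutting contigs with a near-zero gap", {
  g <- generate_genomes(2000, seed = 64)[[1]]
  co <- metadbg:::as_contig_set(c(substr(g, 1, 1000),
                                  substr(g, 1001, 2000)), c(30, 30), 55)
  straddles <- reads_from_seqs(vapply(seq(905, 995, by = 10), function(s)
    substr(g, s, s + 149), character(1)))
  aln <- align_reads_to_contigs(straddles, co)
  ed <- build_edges(aln, co, straddles)
  expect_equal(nrow(ed), 1)
  expect_true(ed$kind %in% c("splint", "both"))
  expect_lte(abs(ed$gap), 2)
})

test_that("fork resolution prefers the depth-consistent branch and the
           support refinement otherwise", {
  co <- metadbg:::as_contig_set(
    unname(generate_genomes(c(900, 400, 800, 700), seed = 65)),
    c(10, 100, 10, 50), 55)
  # path depth 10 forking into repeat (depth 100) that re-emerges into a
  # depth-10 contig, versus a depth-50 branch
  ed <- data.frame(end_a = c("1:R", "2:R", "1:R"),
                   end_b = c("2:L", "3:L", "4:L"),
                   kind = "span", support = c(10L, 10L, 10L),
                   gap = 20, gap_sd = 5, max_aln = c(100L, 100L, 100L),
                   stringsAsFactors = FALSE)
  ed$read_rows <- list(integer(0), integer(0), integer(0))
  cand <- metadbg:::edge_touches(ed, "1:R")
  pick <- resolve_fork(co, ed, cand, "1:R", walk_depth = 10,
                       fork_search_depth = 5L,
                       depth_similarity_ratio = 2.0)
  expect_equal(ed$end_b[pick], "2:L")   # through the repeat to depth 10

  # no depth-similar target anywhere: support refinement decides
  co2 <- metadbg:::as_contig_set(generate_genomes(c(900, 400, 800),
                                                  seed = 66),
                                 c(10, 100, 95), 55)
  ed2 <- data.frame(end_a = c("1:R", "1:R"), end_b = c("2:L", "3:L"),
                    kind = "span", support = c(20L, 2L), gap = 20,
                    gap_sd = 5, max_aln = c(100L, 100L),
                    stringsAsFactors = FALSE)
  ed2$read_rows <- list(integer(0), integer(0))
  pick2 <- resolve_fork(co2, ed2, 1:2, "1:R", walk_depth = 10,
                        fork_search_depth = 5L,
                        depth_similarity_ratio = 2.0)
  expect_equal(ed2$end_b[pick2], "2:L")

  # two equally plausible branches: unresolved
  co3 <- metadbg:::as_contig_set(generate_genomes(c(900, 400, 800),
                                                  seed = 67),
                                 c(10, 10, 10), 55)
  ed3 <- ed2
  ed3$support <- c(5L, 5L)
  pick3 <- resolve_fork(co3, ed3, 1:2, "1:R", walk_depth = 10,
                        fork_search_depth = 5L,
                        depth_similarity_ratio = 2.0)
  expect_true(is.na(pick3))
})

test_that("traversal chains unambiguous edges and isolates the rest", {
  co <- metadbg:::as_contig_set(generate_genomes(rep(600, 5), seed = 68),
                                rep(20, 5), 55)
  chain <- data.frame(end_a = c("1:R", "2:R", "3:R", "4:R"),
                      end_b = c("2:L", "3:L", "4:L", "5:L"),
                      kind = "span", support = 10L, gap = 10, gap_sd = 3,
                      max_aln = 100L, stringsAsFactors = FALSE)
  chain$read_rows <- replicate(4, integer(0), simplify = FALSE)
  paths <- traverse_contig_graph(co, chain, assembly_config())
  expect_length(paths, 1)
  expect_equal(sort(paths[[1]]$contig), 1:5)

  no_edges <- chain[0, ]
  paths2 <- traverse_contig_graph(co, no_edges, assembly_config())
  expect_length(paths2, 5)
  expect_true(all(vapply(paths2, nrow, integer(1)) == 1L))
})

test_that("gap filling restores the exact junction sequence, pads when
           starved, and merges true overlaps", {
  fx <- junction_fixture(gap = 50, seed = 69)
  cfg <- assembly_config()
  sc <- scaffold_rounds(fx$contigs, fx$reads, cfg)
  expect_equal(nrow(sc), 1)
  expect_false(grepl("N", sc$seq, fixed = TRUE))
  expect_true(sc$seq == fx$genome || rc_naive(sc$seq) == fx$genome)

  # starved of reads: N padding near the estimated gap size
  ed <- data.frame(end_a = "1:R", end_b = "2:L", kind = "span",
                   support = 10L, gap = 47.2, gap_sd = 8, max_aln = 100L,
                   stringsAsFactors = FALSE)
  ed$read_rows <- list(integer(0))
  path <- data.frame(contig = 1:2, orient = "+",
                     gap_after = c(47.2, NA), edge_after = c(1L, NA),
                     stringsAsFactors = FALSE)
  out <- close_gaps(path, fx$contigs, ed, fx$reads[0, ], cfg, k = 55)
  expect_equal(nchar(out$seq), sum(nchar(fx$contigs$seq)) + 47)
  expect_true(grepl(strrep("N", 47), out$seq, fixed = TRUE))

  # negative gap with a true 15 bp end overlap: exact merge, no Ns
  g <- generate_genomes(2000, seed = 70)[[1]]
  co <- metadbg:::as_contig_set(c(substr(g, 1, 1015), substr(g, 1001, 2000)),
                                c(30, 30), 21)
  ed2 <- ed
  ed2$gap <- -15
  path2 <- data.frame(contig = 1:2, orient = "+",
                      gap_after = c(-15, NA), edge_after = c(1L, NA),
                      stringsAsFactors = FALSE)
  out2 <- close_gaps(path2, co, ed2, fx$reads[0, ], cfg, k = 21)
  expect_equal(out2$seq, g)
})

test_that("scaffolding a shattered genome reassembles one scaffold and
           rounds never increase the scaffold count", {
  g <- generate_genomes(10000, seed = 71)[[1]]
  cuts <- list(c(1, 2500), c(2561, 5000), c(5081, 7500), c(7551, 10000))
  co <- metadbg:::as_contig_set(
    vapply(cuts, function(x) substr(g, x[1], x[2]), character(1)),
    rep(30, 4), 55)
  rd <- sim_reads(setNames(g, "g1"), depth = 30, seed = 71)
  cfg1 <- assembly_config(scaffold_rounds = 1L)
  sc1 <- scaffold_rounds(co, rd, cfg1)
  cfg2 <- assembly_config(scaffold_rounds = 2L)
  sc2 <- scaffold_rounds(co, rd, cfg2)
  expect_lte(nrow(sc2), nrow(sc1))
  expect_equal(nrow(sc2), 1)
  aln <- align_contigs_to_refs(sc2, c(g1 = g))
  expect_gte(genome_fraction(aln, "g1", 10000), 99)
  expect_gte(min(aln$identity), 0.99)

  # sequence conservation: each input contig appears verbatim
  for (s in co$seq)
    expect_true(grepl(s, sc2$seq, fixed = TRUE) ||
                  grepl(rc_naive(s), sc2$seq, fixed = TRUE))

  # rounds on an edge-free graph are a no-op
  lone <- metadbg:::as_contig_set(generate_genomes(c(800, 900), seed = 72),
                                  c(5, 5), 55)
  sc3 <- scaffold_rounds(lone, rd[0, ], assembly_config())
  expect_setequal(sc3$seq, lone$seq)
})
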