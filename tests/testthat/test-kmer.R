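test_that("canonicalization picks the lexicographic minimum strand", {
  expect_equal(canonicalize("AAT"), "AAT")
  expect_equal(canonicalize("TTT"), "AAA")
  set.seed(4)
  x <- vapply(1:1000, function(i)
    paste(sample(c("A", "C", "G", "T"), 21, TRUE), collapse = ""),
    character(1))
  expect_equal(canonicalize(x), canonicalize(rc_naive(x)))
  expect_equal(canonicalize(canonicalize(x)), canonicalize(x))
  expect_error(canonicalize("ACGT"), "odd")
  expect_error(canonicalize("ACNGTCA"), "N")
})

test_that("k-mer window enumeration reports canonical flanks", {
  w <- extract_kmers("ACGTA", k = 3)
  # windows ACG(canon ACG), CGT(canon ACG), GTA(canon GTA... TAC) before
  # canonical flipping; check count and flank bookkeeping
  expect_equal(nrow(w), 3)
  expect_equal(w$kmer, canonicalize(c("ACG", "CGT", "GTA")))
  # first window: no left flank, right flank T
  expect_true(is.na(w$left_base[1]) || is.na(w$right_base[1]))
  # N splits below k leave nothing
  expect_equal(nrow(extract_kmers("ACNGT", k = 3)), 0)
  # L - k + 1 windows on a clean read
  rd <- sim_reads(generate_genomes(1000, seed = 3), 1, seed = 3)
  expect_equal(nrow(extract_kmers(rd$seq[1], rd$qual[1], 21)), 130)
})

test_that("two-pass Bloom counting equals the naive dictionary counter", {
  rd <- reads_from_seqs(rep("ACGTACGT", 2))
  tab <- count_kmers(rd, 5, min_count = 2)
  # the four windows collapse to two canonical 5-mers (ACGTA/TACGT and
  # CGTAC/GTACG are reverse-complement pairs), each seen twice per read
  expect_equal(nrow(tab), 2)
  expect_true(all(tab$count == 4))
  expect_same_kmer_table(tab, naive_count_kmers(rd, 5))

  # realistic reads with errors and Ns
  g <- generate_genomes(2000, seed = 5)
  rd2 <- sim_reads(g, depth = 8, error = 0.01, seed = 5)
  rd2$seq[3] <- paste0(substr(rd2$seq[3], 1, 70), "N",
                       substr(rd2$seq[3], 72, 150))
  tab2 <- count_kmers(rd2, 21)
  expect_same_kmer_table(tab2, naive_count_kmers(rd2, 21))
})

test_that("count table is strand invariant", {
  g <- generate_genomes(1500, seed = 6)
  rd <- sim_reads(g, depth = 6, seed = 6)
  fwd <- count_kmers(rd, 21)
  rev <- rd
  rev$seq <- rc_naive(rev$seq)
  rev$qual <- vapply(rev$qual, function(q)
    paste(rev(strsplit(q, "")[[1]]), collapse = ""), character(1),
    USE.NAMES = FALSE)
  expect_same_kmer_table(count_kmers(rev, 21), as.data.frame(fwd))
})

test_that("singletons are dropped and an injected error never survives", {
  # unique random reads -> nothing retained
  set.seed(7)
  rd <- reads_from_seqs(vapply(1:30, function(i)
    paste(sample(c("A", "C", "G", "T"), 21, TRUE), collapse = ""),
    character(1)))
  expect_equal(nrow(count_kmers(rd, 21)), 0)

  # 50 clean copies of a sequence + 1 erroneous copy
  g <- generate_genomes(1000, seed = 8)[[1]]
  clean <- reads_from_seqs(rep(substr(g, 1, 500), 50))
  bad <- substr(g, 1, 500)
  substr(bad, 250, 250) <- if (substr(bad, 250, 250) == "A") "C" else "A"
  rd2 <- rbind(clean, reads_from_seqs(bad))
  tab <- count_kmers(rd2, 21)
  clean_tab <- count_kmers(clean, 21)
  expect_setequal(tab$kmer, clean_tab$kmer)
})

test_that("extension counts respect the quality gate and count bound", {
  set.seed(11)
  s <- paste(sample(c("A", "C", "G", "T"), 40, TRUE), collapse = "")
  rd <- reads_from_seqs(rep(s, 3))
  rd$qual[2] <- strrep("5", nchar(s))  # Phred 20 exactly: passes the gate
  rd$qual[3] <- strrep("#", nchar(s))  # Phred 2: below the gate
  tab <- count_kmers(rd, 15, qual_floor = 20)
  for (cl in c("lA", "lC", "lG", "lT", "rA", "rC", "rG", "rT"))
    expect_true(all(tab[[cl]] <= tab$count))
  # the low-quality copy contributes to counts but not to extensions
  expect_true(all(tab$count == 3))
  inner <- rowSums(tab[, c("rA", "rC", "rG", "rT")])
  expect_true(all(inner <= 2))
  expect_same_kmer_table(tab, naive_count_kmers(rd, 15))
})

test_that("hq_extension distinguishes unique, fork and deadend", {
  rec <- list(lA = 0L, lC = 0L, lG = 0L, lT = 0L,
              rA = 5L, rC = 0L, rG = 0L, rT = 0L)
  expect_equal(hq_extension(rec, "right", 2), "A")
  rec$rC <- 3L
  expect_equal(hq_extension(rec, "right", 2), "FORK")
  expect_equal(hq_extension(list(lA = 0L, lC = 0L, lG = 0L, lT = 0L,
                                 rA = 1L, rC = 0L, rG = 0L, rT = 0L),
                            "right", 2), "DEADEND")
})
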