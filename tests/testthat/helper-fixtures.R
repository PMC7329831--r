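# Shared fixtures and independent oracles for the suite. Everything is
# generated in code; no data files.

# independent reverse complement (no package code)
rc_naive <- function(x) {
  vapply(x, function(s)
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]),
          collapse = ""), character(1), USE.NAMES = FALSE)
}

# Brute-force dictionary k-mer counter: the oracle for the Bloom two-pass
# scheme. Enumerates windows by hand, canonicalizes by direct comparison,
# applies the same extension quality gate, drops sub-min_count records.
naive_count_kmers <- function(reads, k, qual_floor = 20L, min_count = 2L) {
  counts <- new.env(hash = TRUE)
  bump <- function(key, field, by = 1L) {
    rec <- get0(key, envir = counts, inherits = FALSE)
    if (is.null(rec)) rec <- c(count = 0L, lA = 0L, lC = 0L, lG = 0L,
                               lT = 0L, rA = 0L, rC = 0L, rG = 0L, rT = 0L)
    rec[field] <- rec[field] + by
    assign(key, rec, envir = counts)
  }
  for (i in seq_len(nrow(reads))) {
    s <- reads$seq[i]
    q <- utf8ToInt(reads$qual[i]) - 33L
    # maximal N-free stretches
    runs <- gregexpr("[ACGT]+", s)[[1]]
    if (runs[1] == -1) next
    lens <- attr(runs, "match.length")
    for (j in seq_along(runs)) {
      a <- runs[j]; b <- runs[j] + lens[j] - 1L
      if (b - a + 1L < k) next
      for (st in a:(b - k + 1L)) {
        w <- substr(s, st, st + k - 1L)
        wrc <- rc_naive(w)
        canon <- if (w <= wrc) w else wrc
        flip <- w > wrc
        lb <- if (st > a) substr(s, st - 1L, st - 1L) else NA
        rb <- if (st + k - 1L < b) substr(s, st + k, st + k) else NA
        lq <- if (st > a) q[st - 1L] else NA
        rq <- if (st + k - 1L < b) q[st + k] else NA
        if (flip) {
          tmp <- lb; lb <- if (is.na(rb)) NA else chartr("ACGT", "TGCA", rb)
          rb <- if (is.na(tmp)) NA else chartr("ACGT", "TGCA", tmp)
          tmp <- lq; lq <- rq; rq <- tmp
        }
        bump(canon, "count")
        if (!is.na(lb) && lq >= qual_floor) bump(canon, paste0("l", lb))
        if (!is.na(rb) && rq >= qual_floor) bump(canon, paste0("r", rb))
      }
    }
  }
  keys <- sort(ls(envir = counts))
  rows <- lapply(keys, function(key) get(key, envir = counts))
  df <- as.data.frame(do.call(rbind, rows))
  df <- cbind(data.frame(kmer = keys, stringsAsFactors = FALSE), df)
  df[df$count >= min_count, , drop = FALSE]
}

# quick single-genome read set at a given depth
sim_reads <- function(genome, depth, error = 0, seed = 1L,
                      read_len = 150L) {
  if (is.null(names(genome))) names(genome) <- paste0("g", seq_along(genome))
  ab <- setNames(rep(1 / length(genome), length(genome)), names(genome))
  sim <- simulate_reads(genome, ab,
                        read_sim_params(read_len = read_len,
                                        sub_error_rate = error,
                                        total_bases_per_sample =
                                          sum(nchar(genome)) * depth),
                        seed = seed)
  sim$samples[[1]]
}

# reads as a plain table from explicit sequences (uniform high quality)
reads_from_seqs <- function(seqs, qual_char = "I") {
  data.frame(id = paste0("r", seq_along(seqs)), seq = seqs,
             qual = vapply(nchar(seqs), function(n)
               strrep(qual_char, n), character(1)),
             mate = "unpaired", pair_id = paste0("r", seq_along(seqs)),
             provenance = NA_character_, stringsAsFactors = FALSE)
}

expect_same_kmer_table <- function(tab, oracle) {
  df <- as.data.frame(tab)
  rownames(df) <- NULL; rownames(oracle) <- NULL
  expect_equal(df$kmer, oracle$kmer)
  expect_equal(df$count, oracle$count)
  for (cl in c("lA", "lC", "lG", "lT", "rA", "rC", "rG", "rT"))
    expect_equal(df[[cl]], oracle[[cl]], label = cl)
}
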