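test_that("genome generation is deterministic with controlled GC and
           planted features", {
  g1 <- generate_genomes(10000, gc = 0.5, seed = 1)
  g2 <- generate_genomes(10000, gc = 0.5, seed = 1)
  expect_identical(g1, g2)
  gc <- sum(strsplit(g1[[1]], "")[[1]] %in% c("G", "C")) / 10000
  expect_lt(abs(gc - 0.5), 0.02)
  gh <- generate_genomes(10000, gc = 0.65, seed = 2)
  gch <- sum(strsplit(gh[[1]], "")[[1]] %in% c("G", "C")) / 10000
  expect_lt(abs(gch - 0.65), 0.02)

  # planted repeat appears exactly twice
  gr <- generate_genomes(8000, repeat_len = 300, repeat_copies = 2,
                         seed = 3)[[1]]
  starts <- seq_len(8000 - 299)
  wins <- substring(gr, starts, starts + 299)
  expect_equal(max(table(wins)), 2)

  # strain divergence within the requested band
  strain <- derive_strain(gr, divergence = 0.01, seed = 4)
  d <- sum(utf8ToInt(strain) != utf8ToInt(gr)) / nchar(gr)
  expect_gte(d, 0.008); expect_lte(d, 0.012)
})

test_that("lognormal abundances normalize, degenerate and match the
           distribution's CV", {
  a <- draw_abundances(25, seed = 5)
  expect_length(a, 25)
  expect_true(all(a > 0))
  expect_equal(sum(a), 1, tolerance = 1e-12)
  a0 <- draw_abundances(10, sigma = 1e-9, seed = 6)
  expect_equal(a0, rep(0.1, 10), tolerance = 1e-6)
  set.seed(7)
  x <- rlnorm(1e4, 1, 0.8)
  cv_emp <- sd(x) / mean(x)
  cv_th <- sqrt(exp(0.8^2) - 1)
  expect_lt(abs(cv_emp - cv_th) / cv_th, 0.1)
})

test_that("replicate samples share structure and renormalize", {
  base <- setNames(draw_abundances(20, seed = 8), paste0("g", 1:20))
  m0 <- replicate_samples(base, 4, replicate_sigma = 0, seed = 8)
  expect_true(all(abs(m0 - base) < 1e-12))
  m <- replicate_samples(base, 12, replicate_sigma = 0.3, seed = 8)
  expect_equal(unname(colSums(m)), rep(1, 12), tolerance = 1e-12)
  cors <- combn(12, 2, function(ij)
    suppressWarnings(cor(m[, ij[1]], m[, ij[2]], method = "spearman")))
  expect_gt(mean(cors), 0.5)
})

test_that("simulated reads hit requested depth, match their source, and
           respect abundances", {
  g <- generate_genomes(10000, seed = 9)
  sim <- simulate_reads(g, setNames(1, names(g)),
                        read_sim_params(sub_error_rate = 0,
                                        total_bases_per_sample = 10000 * 30),
                        seed = 9)
  depth <- realized_depth(sim)
  expect_lt(abs(depth[1, 1] - 30), 2)
  rd <- sim$samples[[1]]
  # error-free reads substring-match the genome (R2 via revcomp)
  idx <- sample.int(nrow(rd), 50)
  expect_true(all(vapply(idx, function(i)
    grepl(rd$seq[i], g[[1]], fixed = TRUE) ||
      grepl(rc_naive(rd$seq[i]), g[[1]], fixed = TRUE), logical(1))))

  # 9:1 mixture: provenance counts within 3 sigma of binomial
  g2 <- generate_genomes(c(5000, 5000), seed = 10)
  sim2 <- simulate_reads(g2, setNames(c(0.9, 0.1), names(g2)),
                         read_sim_params(total_bases_per_sample = 3e6),
                         seed = 10)
  n_pairs <- nrow(sim2$truth$reads)
  n1 <- sum(sim2$truth$reads$genome == "g1")
  expect_lt(abs(n1 - 0.9 * n_pairs), 3 * sqrt(n_pairs * 0.9 * 0.1) + 1)
})

test_that("simulation is deterministic per seed and samples get distinct
           sub-seeds", {
  g <- generate_genomes(c(4000, 4000), seed = 11)
  ab <- replicate_samples(setNames(c(0.5, 0.5), names(g)), 2, 0.3, 11)
  s1 <- simulate_reads(g, ab, read_sim_params(total_bases_per_sample = 1e5),
                       seed = 11)
  s2 <- simulate_reads(g, ab, read_sim_params(total_bases_per_sample = 1e5),
                       seed = 11)
  expect_identical(s1$samples, s2$samples)
  expect_false(identical(s1$samples[[1]]$seq, s1$samples[[2]]$seq))
})

test_that("written simulations round-trip through the FASTQ reader with
           provenance intact", {
  g <- generate_genomes(3000, seed = 12)
  sim <- simulate_reads(g, setNames(1, names(g)),
                        read_sim_params(total_bases_per_sample = 6e4),
                        seed = 12)
  d <- tempfile(); dir.create(d)
  write_simulation(sim, d)
  expect_true(file.exists(file.path(d, "truth", "genomes.fasta")))
  expect_true(file.exists(file.path(d, "truth", "reads.tsv")))
  back <- read_fastq(file.path(d, "sample_1_R1.fastq.gz"),
                     file.path(d, "sample_1_R2.fastq.gz"))
  expect_equal(nrow(back), nrow(sim$samples[[1]]))
  expect_true(all(back$provenance == "g1"))
  expect_equal(length(unique(back$pair_id)), nrow(back) / 2)
})
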