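test_that("reference alignment finds exact slices, rejects foreign
           sequence, and scores SNPs", {
  refs <- generate_genomes(c(5000, 5000), seed = 80)
  slice <- substr(refs[[1]], 1001, 2000)
  co <- metadbg:::as_contig_set(slice, 10)
  aln <- align_contigs_to_refs(co, refs)
  expect_equal(nrow(aln), 1)
  expect_equal(aln$ref, "g1")
  expect_equal(aln$ref_start, 1000)
  expect_equal(aln$ref_end, 2000)
  expect_equal(aln$identity, 1)

  foreign <- generate_genomes(1000, seed = 81)[[1]]
  expect_equal(nrow(align_contigs_to_refs(
    metadbg:::as_contig_set(foreign, 10), refs)), 0)

  snp <- slice
  substr(snp, 500, 500) <- chartr("ACGT", "TGCA", substr(snp, 500, 500))
  aln2 <- align_contigs_to_refs(metadbg:::as_contig_set(snp, 10), refs)
  expect_equal(nrow(aln2), 1)
  expect_equal(aln2$identity, (1000 - 1) / 1000)

  # reverse-complement contigs align with "-" orientation, same interval
  rcc <- metadbg:::as_contig_set(rc_naive(slice), 10)
  aln3 <- align_contigs_to_refs(rcc, refs)
  expect_equal(aln3$orient, "-")
  expect_equal(aln3$ref_start, 1000)
  expect_equal(aln3$ref_end, 2000)
})

test_that("genome fraction is a coverage union and duplication ratio
           counts multiplicity", {
  ref_len <- 1000
  mk <- function(rs, re) data.frame(contig = "c", ref = "r",
                                    contig_start = 0, contig_end = re - rs,
                                    ref_start = rs, ref_end = re,
                                    orient = "+", identity = 1,
                                    stringsAsFactors = FALSE)
  expect_equal(genome_fraction(mk(0, 0)[0, ], "r", ref_len), 0)
  two <- rbind(mk(0, 500), mk(250, 1000))
  expect_equal(genome_fraction(two, "r", ref_len), 100)
  expect_equal(duplication_ratio(two, "r", ref_len), 1.25)
  gaps <- rbind(mk(0, 400), mk(600, 1000))
  expect_equal(genome_fraction(gaps, "r", ref_len), 80)

  # four copies of a full-length match: dup ratio 4, fraction 100
  four <- do.call(rbind, replicate(4, mk(0, 1000), simplify = FALSE))
  expect_equal(duplication_ratio(four, "r", ref_len), 4)
  expect_equal(genome_fraction(four, "r", ref_len), 100)
})

test_that("chimericity is the entropy of provenance proportions", {
  expect_equal(chimericity(1), 0)
  expect_equal(chimericity(c(0.5, 0.5)), log(2), tolerance = 1e-9)
  expect_equal(chimericity(c(0.9, 0.1)),
               -(0.9 * log(0.9) + 0.1 * log(0.1)), tolerance = 1e-12)
  expect_equal(chimericity(c(5, 5)), log(2))  # counts normalize
  expect_error(chimericity(numeric(0)), "empty")
  # bounded by ln(n), zero iff pure
  set.seed(82)
  for (i in 1:20) {
    p <- runif(4); p <- p / sum(p)
    expect_lte(chimericity(p), log(4) + 1e-12)
    expect_gte(chimericity(p), 0)
  }
})

test_that("read assignment produces pure profiles for pure contigs and
           balanced ones for constructed chimeras", {
  g <- generate_genomes(c(4000, 4000), seed = 83)
  co <- metadbg:::as_contig_set(c(g[[1]], g[[2]]), c(10, 10))
  sim <- simulate_reads(g, setNames(c(0.5, 0.5), names(g)),
                        read_sim_params(total_bases_per_sample = 2e5,
                                        sub_error_rate = 0),
                        seed = 83)
  rd <- sim$samples[[1]]
  prof <- assign_reads_to_contigs(rd, co)
  summ <- chimericity_summary(prof)
  expect_equal(summ$fraction_chimeric, 0)
  expect_equal(summ$mean_all, 0)

  # a deliberate half-and-half chimera
  chim <- metadbg:::as_contig_set(
    paste0(substr(g[[1]], 1, 2000), substr(g[[2]], 2001, 4000)), 10)
  prof2 <- assign_reads_to_contigs(rd, chim)
  h <- chimericity_summary(prof2)
  expect_equal(h$fraction_chimeric, 1)
  expect_gt(h$mean_all, 0.5)   # close to ln 2
})

test_that("multiassembly concatenates and containment dedupe removes
           exact duplicates only", {
  g <- generate_genomes(3000, seed = 84)[[1]]
  one <- metadbg:::as_contig_set(g, 10)
  multi <- multiassembly(list(s1 = one, s2 = one, s3 = one))
  expect_equal(nrow(multi), 3)
  dd <- dedupe(multi)
  expect_equal(nrow(dd), 1)

  # half-overlapping contigs: neither contains the other, both retained
  a <- substr(g, 1, 2000); b <- substr(g, 1001, 3000)
  ab <- metadbg:::as_contig_set(c(a, b), c(5, 5))
  expect_equal(nrow(dedupe(ab)), 2)

  # reverse-complement copies are containments too; idempotence
  rcset <- metadbg:::as_contig_set(c(g, rc_naive(substr(g, 101, 900))),
                                   c(5, 5))
  dd2 <- dedupe(rcset)
  expect_equal(nrow(dd2), 1)
  expect_identical(dedupe(dd2)$seq, dd2$seq)
})

test_that("the evaluation report ties per-reference metrics to the truth
           manifest", {
  g <- generate_genomes(c(6000, 6000), seed = 85)
  sim <- simulate_reads(g, setNames(c(0.7, 0.3), names(g)),
                        read_sim_params(total_bases_per_sample = 4e5,
                                        sub_error_rate = 0),
                        seed = 85)
  # perfect assembly of g1 only
  asm <- metadbg:::as_contig_set(g[[1]], 20)
  rep <- eval_report(asm, sim$truth, reads = sim$samples[[1]])
  pr <- rep$per_ref
  expect_equal(pr$genome_fraction[pr$ref == "g1"], 100)
  expect_equal(pr$duplication_ratio[pr$ref == "g1"], 1)
  expect_equal(pr$genome_fraction[pr$ref == "g2"], 0)
  expect_equal(rep$chimericity$mean_all, 0)
  expect_gt(pr$depth[pr$ref == "g1"], pr$depth[pr$ref == "g2"])
  expect_equal(nrow(rep$cumulative), 1)
  expect_equal(rep$cumulative$cumulative_bp, 6000)

  d <- tempfile(); dir.create(d)
  write_eval_report(rep, d)
  expect_true(all(file.exists(file.path(d, c("report.tsv",
                                             "cumulative.tsv",
                                             "chimericity.tsv",
                                             "summary.json")))))
})

test_that("strain-diagnostic sites are scored by allele, not just
           coverage", {
  parent <- generate_genomes(5000, seed = 86)[[1]]
  strain <- derive_strain(parent, 0.01, seed = 87)
  # assembly = the parent only: covers the strain ref but recovers no
  # strain alleles
  asm_p <- metadbg:::as_contig_set(parent, 20)
  expect_equal(strain_specific_fraction(asm_p, strain, parent), 0)
  # assembly = the strain: recovers all diagnostic sites
  asm_s <- metadbg:::as_contig_set(strain, 5)
  expect_equal(strain_specific_fraction(asm_s, strain, parent), 1)
  # reverse complement of the strain still counts
  asm_rc <- metadbg:::as_contig_set(rc_naive(strain), 5)
  expect_equal(strain_specific_fraction(asm_rc, strain, parent), 1)
})
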