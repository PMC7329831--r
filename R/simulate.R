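#' Generate synthetic genomes
#'
#' I.i.d. bases at a requested GC content, with optional planted exact
#' repeats (for repeat-resolution fixtures) and optional strain
#' derivation: a copy of a parent genome with a given per-base
#' substitution divergence (for strain-variation experiments).
#'
#' @param lengths integer vector of genome lengths.
#' @param gc GC content in (0, 1), recycled over genomes.
#' @param ids genome ids (default `g1..gn`).
#' @param repeat_len,repeat_copies plant an exact repeat of this length at
#'   `repeat_copies` random positions within each genome (0 = none).
#' @param seed RNG seed.
#' @return named character vector of genome sequences.
#' @export
generate_genomes <- function(lengths, gc = 0.5, ids = NULL,
                             repeat_len = 0L, repeat_copies = 2L,
                             seed = 1L) {
  set.seed(seed)
  n <- length(lengths)
  gc <- rep_len(gc, n)
  if (is.null(ids)) ids <- paste0("g", seq_len(n))
  stopifnot(length(ids) == n, !anyDuplicated(ids))
  out <- character(n)
  for (i in seq_len(n)) {
    p <- c(A = (1 - gc[i]) / 2, C = gc[i] / 2, G = gc[i] / 2,
           T = (1 - gc[i]) / 2)
    s <- sample(names(p), lengths[i], replace = TRUE, prob = p)
    if (repeat_len > 0L && lengths[i] > (repeat_len + 2L) * repeat_copies) {
      unit <- sample(names(p), repeat_len, replace = TRUE, prob = p)
      starts <- sort(sample.int(lengths[i] - repeat_len, repeat_copies))
      # keep copies non-overlapping; drop colliding starts
      keep <- c(TRUE, diff(starts) >= repeat_len)
      for (st in starts[keep]) s[st:(st + repeat_len - 1L)] <- unit
    }
    out[i] <- paste(s, collapse = "")
  }
  names(out) <- ids
  out
}

#' Derive a diverged strain from a parent genome
#'
#' @param parent parent genome sequence.
#' @param divergence per-base substitution probability.
#' @param seed RNG seed.
#' @return strain sequence of equal length.
#' @export
derive_strain <- function(parent, divergence = 0.01, seed = 1L) {
  set.seed(seed)
  s <- strsplit(parent, "")[[1]]
  hit <- which(stats::runif(length(s)) < divergence)
  for (i in hit) {
    s[i] <- sample(setdiff(c("A", "C", "G", "T"), s[i]), 1L)
  }
  paste(s, collapse = "")
}

#' Draw base community abundances from a lognormal profile
#'
#' @param n_genomes number of genomes.
#' @param mu,sigma lognormal parameters (log scale).
#' @param seed RNG seed.
#' @return numeric vector of positive abundances summing to 1.
#' @export
draw_abundances <- function(n_genomes, mu = 1, sigma = 2, seed = 1L) {
  stopifnot(sigma > 0)
  set.seed(seed)
  x <- stats::rlnorm(n_genomes, meanlog = mu, sdlog = sigma)
  x / sum(x)
}

#' Replicate-model per-sample abundances
#'
#' Each sample's profile is the base profile perturbed by multiplicative
#' lognormal noise and renormalized, so samples share community structure
#' (positive rank correlation) while varying in composition.
#'
#' @param base_abundance base profile (positive, sums to 1).
#' @param n_samples number of samples.
#' @param replicate_sigma SD of the lognormal perturbation (0 = identical
#'   samples).
#' @param seed RNG seed.
#' @return matrix `n_genomes x n_samples`, columns summing to 1.
#' @export
replicate_samples <- function(base_abundance, n_samples,
                              replicate_sigma = 0.3, seed = 1L) {
  set.seed(seed)
  n <- length(base_abundance)
  out <- matrix(NA_real_, n, n_samples)
  for (s in seq_len(n_samples)) {
    noise <- if (replicate_sigma > 0)
      stats::rlnorm(n, 0, replicate_sigma) else rep(1, n)
    a <- base_abundance * noise
    out[, s] <- a / sum(a)
  }
  dimnames(out) <- list(names(base_abundance),
                        paste0("sample_", seq_len(n_samples)))
  out
}

#' Read simulation parameters
#'
#' @param read_len read length (bases).
#' @param insert_mu,insert_sigma Normal insert-size model; inserts are
#'   truncated below at `read_len` (overlapping pairs allowed).
#' @param sub_error_rate per-base substitution probability, in `[0, 0.1]`.
#' @param qual_mean,qual_sd Phred model for correct bases.
#' @param err_qual_mean,err_qual_sd Phred model for erroneous bases
#'   (drawn low, but overlapping the correct-base range).
#' @param total_bases_per_sample total sequenced bases per sample.
#' @return list of validated parameters.
#' @export
read_sim_params <- function(read_len = 150L, insert_mu = 270,
                            insert_sigma = 30, sub_error_rate = 0.005,
                            qual_mean = 37, qual_sd = 3,
                            err_qual_mean = 12, err_qual_sd = 4,
                            total_bases_per_sample = 3e6) {
  stopifnot(sub_error_rate >= 0, sub_error_rate <= 0.1, read_len > 0)
  list(read_len = as.integer(read_len), insert_mu = insert_mu,
       insert_sigma = insert_sigma, sub_error_rate = sub_error_rate,
       qual_mean = qual_mean, qual_sd = qual_sd,
       err_qual_mean = err_qual_mean, err_qual_sd = err_qual_sd,
       total_bases_per_sample = total_bases_per_sample)
}

# derive a deterministic 31-bit sub-seed from (seed, index); double
# arithmetic keeps the products exact and the result below 2^31
sub_seed <- function(seed, index) {
  m <- 2147483587
  as.integer((as.numeric(seed) %% m * 48271 + as.numeric(index) * 16807) %% m)
}

#' Simulate paired-end reads for one or more samples
#'
#' Per pair: genome chosen proportionally to abundance times genome
#' length, fragment start uniform, insert Normal(mu, sigma) truncated at
#' the read length; R1 is the fragment prefix and R2 the reverse
#' complement of the fragment suffix. Substitutions are i.i.d. at
#' `sub_error_rate` with erroneous bases given low (but not disqualifying)
#' Phred scores. Headers carry `genome=<id> pos=<start>` provenance.
#'
#' @param genomes named character vector of genome sequences.
#' @param sample_abundances matrix from [replicate_samples()] (or a single
#'   column for one sample).
#' @param params from [read_sim_params()].
#' @param seed master seed; per-sample sub-seeds derive from it.
#' @return list with `samples` (list of read tables, one per sample) and
#'   `truth` (list: `genomes`, `abundances`, `reads` manifest with
#'   `read_id`, `sample`, `genome`, `pos`, `insert`).
#' @export
simulate_reads <- function(genomes, sample_abundances,
                           params = read_sim_params(), seed = 1L) {
  if (is.null(dim(sample_abundances)))
    sample_abundances <- matrix(sample_abundances,
                                ncol = 1,
                                dimnames = list(names(sample_abundances),
                                                "sample_1"))
  stopifnot(nrow(sample_abundances) == length(genomes))
  glen <- nchar(genomes)
  rl <- params$read_len
  if (any(glen < rl)) stop("genomes must be at least read_len long",
                           call. = FALSE)
  n_samples <- ncol(sample_abundances)
  samples <- vector("list", n_samples)
  manifests <- vector("list", n_samples)
  for (s in seq_len(n_samples)) {
    set.seed(sub_seed(seed, s))
    ab <- sample_abundances[, s]
    n_pairs <- max(1L, round(params$total_bases_per_sample / (2 * rl)))
    gsel <- sample.int(length(genomes), n_pairs, replace = TRUE,
                       prob = ab * glen)
    insert <- pmax(rl, round(stats::rnorm(n_pairs, params$insert_mu,
                                          params$insert_sigma)))
    insert <- pmin(insert, glen[gsel])  # resample-equivalent clamp
    start <- vapply(seq_len(n_pairs), function(i)
      sample.int(glen[gsel[i]] - insert[i] + 1L, 1L), integer(1))
    frag <- substring(genomes[gsel], start, start + insert - 1L)
    r1 <- substring(frag, 1L, rl)
    r2 <- revcomp(substring(frag, insert - rl + 1L, insert))
    seqs <- c(rbind(r1, r2))  # interleave R1/R2 per pair
    n_reads <- length(seqs)
    # substitution errors + qualities, vectorized over the whole sample
    total_b <- n_reads * rl
    qual <- round(stats::rnorm(total_b, params$qual_mean, params$qual_sd))
    err <- which(stats::runif(total_b) < params$sub_error_rate)
    if (length(err) > 0) {
      qual[err] <- round(stats::rnorm(length(err), params$err_qual_mean,
                                      params$err_qual_sd))
      mat <- matrix(utf8ToInt(paste(seqs, collapse = "")), nrow = rl)
      stopifnot(length(mat) == total_b)
      shift <- sample.int(3L, length(err), replace = TRUE)
      bases <- utf8ToInt("ACGT")
      cur <- match(mat[err], bases)
      mat[err] <- bases[((cur - 1L + shift) %% 4L) + 1L]
      seqs <- vapply(seq_len(n_reads), function(i)
        intToUtf8(mat[, i]), character(1))
    }
    qual <- pmin(40L, pmax(2L, as.integer(qual)))
    qmat <- matrix(qual, nrow = rl)
    quals <- vapply(seq_len(n_reads), function(i)
      phred_string(qmat[, i]), character(1))
    pair_ids <- sprintf("s%d_p%d", s, seq_len(n_pairs))
    ids <- rep(pair_ids, each = 2L)
    headers <- sprintf("%s genome=%s pos=%d", ids,
                       rep(names(genomes)[gsel], each = 2L),
                       rep(start, each = 2L))
    samples[[s]] <- data.frame(
      id = ids, header = headers, seq = seqs, qual = quals,
      mate = rep(c("R1", "R2"), n_pairs), pair_id = ids,
      provenance = rep(names(genomes)[gsel], each = 2L),
      stringsAsFactors = FALSE)
    manifests[[s]] <- data.frame(
      read_id = pair_ids, sample = colnames(sample_abundances)[s],
      genome = names(genomes)[gsel], pos = start, insert = insert,
      stringsAsFactors = FALSE)
  }
  names(samples) <- colnames(sample_abundances)
  list(samples = samples,
       truth = list(genomes = genomes,
                    abundances = sample_abundances,
                    reads = do.call(rbind, manifests)))
}

#' Realized per-genome sequencing depth of a simulation
#' @param sim result of [simulate_reads()].
#' @param read_len read length used.
#' @return matrix genome x sample of realized mean depths.
#' @export
realized_depth <- function(sim, read_len = 150L) {
  tr <- sim$truth$reads
  glen <- nchar(sim$truth$genomes)
  gn <- names(sim$truth$genomes)
  sn <- colnames(sim$truth$abundances)
  out <- matrix(0, length(gn), length(sn), dimnames = list(gn, sn))
  agg <- stats::aggregate(rep(2L * read_len, nrow(tr)),
                          by = list(genome = tr$genome, sample = tr$sample),
                          FUN = sum)
  for (i in seq_len(nrow(agg)))
    out[agg$genome[i], agg$sample[i]] <- agg$x[i] / glen[agg$genome[i]]
  out
}

#' Write a simulation to FASTQ plus a ground-truth manifest
#'
#' Produces `sample_<s>_R1.fastq.gz` / `sample_<s>_R2.fastq.gz`,
#' `truth/genomes.fasta`, `truth/abundances.tsv` and `truth/reads.tsv`.
#'
#' @param sim result of [simulate_reads()].
#' @param out_dir output directory (created).
#' @param gzip compress FASTQ output.
#' @return `out_dir`, invisibly.
#' @export
write_simulation <- function(sim, out_dir, gzip = TRUE) {
  dir.create(file.path(out_dir, "truth"), recursive = TRUE,
             showWarnings = FALSE)
  ext <- if (gzip) ".fastq.gz" else ".fastq"
  for (s in seq_along(sim$samples)) {
    rd <- sim$samples[[s]]
    for (m in c("R1", "R2")) {
      sel <- rd$mate == m
      write_fastq_one(rd$header[sel], rd$seq[sel], rd$qual[sel],
                      file.path(out_dir,
                                sprintf("sample_%d_%s%s", s, m, ext)))
    }
  }
  write_fasta(names(sim$truth$genomes), unname(sim$truth$genomes),
              file.path(out_dir, "truth", "genomes.fasta"))
  ab <- data.frame(genome = rownames(sim$truth$abundances),
                   sim$truth$abundances, check.names = FALSE)
  utils::write.table(ab, file.path(out_dir, "truth", "abundances.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$reads,
                     file.path(out_dir, "truth", "reads.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out_dir)
}
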