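#' Read paired or unpaired FASTQ files
#'
#' Reads Phred+33 FASTQ (gzipped transparently by extension) into a flat
#' read table. Pairing is positional between two files, or by alternating
#' records with `interleaved = TRUE`. A `genome=<id>` token in the header
#' comment (as written by [simulate_reads()]) is parsed into the
#' `provenance` column.
#'
#' @param path1 FASTQ file (R1 when `path2` given).
#' @param path2 optional mate file (R2).
#' @param interleaved treat `path1` as interleaved R1/R2 records.
#' @return `data.frame` with columns `id`, `seq`, `qual` (Phred+33 string),
#'   `mate` (`"R1"`, `"R2"` or `"unpaired"`), `pair_id`, `provenance`
#'   (`NA` when no token present).
#' @export
read_fastq <- function(path1, path2 = NULL, interleaved = FALSE) {
  if (!is.null(path2) && interleaved)
    stop("give either two files or interleaved = TRUE, not both",
         call. = FALSE)
  r1 <- read_fastq_one(path1)
  if (!is.null(path2)) {
    r2 <- read_fastq_one(path2)
    if (nrow(r1) != nrow(r2))
      stop(sprintf("mate-count mismatch: %d records in %s, %d in %s",
                   nrow(r1), path1, nrow(r2), path2), call. = FALSE)
    r1$mate <- rep("R1", nrow(r1))
    r2$mate <- rep("R2", nrow(r2))
    pid <- sub("/[12]$", "", r1$id)
    r1$pair_id <- pid
    r2$pair_id <- pid
    out <- rbind(r1, r2)
    rownames(out) <- NULL
    return(out)
  }
  if (interleaved) {
    n <- nrow(r1)
    if (n %% 2L != 0L)
      stop(sprintf("interleaved file %s has an odd record count (%d)",
                   path1, n), call. = FALSE)
    r1$mate <- rep(c("R1", "R2"), n / 2L)
    pid <- sub("/[12]$", "", r1$id[seq(1L, n, by = 2L)])
    r1$pair_id <- rep(pid, each = 2L)
    return(r1)
  }
  r1$mate <- rep("unpaired", nrow(r1))
  r1$pair_id <- r1$id
  r1
}

read_fastq_one <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path, call. = FALSE)
  x <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fastq",
                                 with.qualities = TRUE),
    error = function(e) diagnose_fastq(path, conditionMessage(e)))
  if (length(x) > 0) {
    quals <- S4Vectors::mcols(x)$qualities
    bad <- which(Biostrings::width(quals) != Biostrings::width(x))
    if (length(bad) > 0)
      stop(sprintf(
        "truncated FASTQ record %d in %s: sequence/quality length mismatch",
        bad[1], path), call. = FALSE)
    # a final record missing its quality line is silently absorbed by the
    # parser; a line count not divisible by 4 betrays it
    nl <- count_lines(path)
    if (nl %% 4L != 0L)
      stop(sprintf("truncated FASTQ record %d in %s", nl %/% 4L + 1L, path),
           call. = FALSE)
  }
  headers <- names(x)
  ids <- sub("\\s.*$", "", headers)
  prov <- rep(NA_character_, length(headers))
  hit <- regmatches(headers, regexpr("genome=\\S+", headers))
  has <- grepl("genome=\\S+", headers)
  prov[has] <- sub("^genome=", "", hit)
  data.frame(id = ids, seq = as.character(x),
             qual = as.character(S4Vectors::mcols(x)$qualities),
             mate = rep("unpaired", length(x)),
             pair_id = ids, provenance = prov,
             stringsAsFactors = FALSE, row.names = NULL)
}

diagnose_fastq <- function(path, msg) {
  nl <- count_lines(path)
  if (nl %% 4L != 0L)
    stop(sprintf("truncated FASTQ record %d in %s", nl %/% 4L + 1L, path),
         call. = FALSE)
  stop(sprintf("failed to parse FASTQ %s: %s", path, msg), call. = FALSE)
}

count_lines <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "r") else file(path, "r")
  on.exit(close(con))
  n <- 0L
  repeat {
    chunk <- readLines(con, n = 65536L)
    if (length(chunk) == 0L) break
    n <- n + length(chunk)
  }
  n
}

#' Write sequences to FASTA
#'
#' @param ids unique sequence ids (full header lines allowed).
#' @param seqs character vector of sequences (may contain `N`).
#' @param path output file; `.gz` suffix compresses.
#' @param wrap line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(ids, seqs, path, wrap = 80L) {
  if (anyDuplicated(ids))
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  if (length(ids) != length(seqs))
    stop("ids and seqs lengths differ", call. = FALSE)
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- ids
  Biostrings::writeXStringSet(x, path, width = as.integer(wrap),
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Read a FASTA file into a named character vector
#' @param path FASTA file (gzip ok).
#' @return named character vector of sequences; names are the first
#'   whitespace-delimited token of each header.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

write_fastq_one <- function(ids, seqs, quals, path) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- ids
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(quals),
                              compress = grepl("\\.gz$", path))
  invisible(path)
}
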