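#' Assembly run configuration
#'
#' Builds and validates the full parameter set for an assembly run. Values
#' not supplied fall back to built-in defaults; [load_config()] layers a
#' YAML/flat-key file between the two.
#'
#' @param k_list ascending odd k-mer sizes for the iterative schedule
#'   (each in 15..63).
#' @param qual_floor Phred score a flanking base must reach to contribute
#'   to extension counts (and to local-extension votes).
#' @param min_count minimum k-mer count retained after counting
#'   (singleton filter when 2).
#' @param alpha adaptive-threshold coefficient: the extension threshold for
#'   a k-mer of count `c` is `max(thq_floor, ceiling(alpha * c))`.
#' @param thq_floor floor of the adaptive extension threshold.
#' @param hair_len_factor hairs (short dead-end branches) up to
#'   `hair_len_factor * k` bases may be removed.
#' @param bubble_len_factor parallel branches up to `bubble_len_factor * k`
#'   bases may be merged as bubbles.
#' @param prune_ratio fork branches below `prune_ratio` times the deepest
#'   branch at a junction are disconnected.
#' @param prune_max_iters iteration cap for fork pruning.
#' @param seed_len exact-seed length for read/contig alignment.
#' @param min_edge_support minimum distinct reads/pairs supporting a
#'   contig-graph edge.
#' @param fork_search_depth bounded search depth (in edges) when resolving
#'   scaffold-graph forks.
#' @param depth_similarity_ratio two depths are "similar" when
#'   `max(a,b)/min(a,b)` is at most this ratio.
#' @param scaffold_rounds number of align/link/traverse/gap-fill rounds.
#' @param insert_mu,insert_sigma mean and SD of the paired-end insert size
#'   (bases).
#' @param min_contig_len shortest contig reported by the pipeline;
#'   shorter pieces (mostly isolated error islands) are dropped at output
#'   time, never mid-iteration.
#' @param rng_seed integer seed from which all randomness flows.
#' @return object of class `assembly_config` (a validated named list).
#' @export
assembly_config <- function(k_list = c(21L, 33L, 55L),
                            qual_floor = 20L,
                            min_count = 2L,
                            alpha = 0.1,
                            thq_floor = 2L,
                            hair_len_factor = 2L,
                            bubble_len_factor = 3L,
                            prune_ratio = 0.1,
                            prune_max_iters = 10L,
                            seed_len = 21L,
                            min_edge_support = 2L,
                            fork_search_depth = 5L,
                            depth_similarity_ratio = 2.0,
                            scaffold_rounds = 2L,
                            insert_mu = 270,
                            insert_sigma = 30,
                            min_contig_len = 200L,
                            rng_seed = 1L) {
  cfg <- list(
    k_list = as.integer(k_list), qual_floor = as.integer(qual_floor),
    min_count = as.integer(min_count), alpha = as.numeric(alpha),
    thq_floor = as.integer(thq_floor),
    hair_len_factor = as.integer(hair_len_factor),
    bubble_len_factor = as.integer(bubble_len_factor),
    prune_ratio = as.numeric(prune_ratio),
    prune_max_iters = as.integer(prune_max_iters),
    seed_len = as.integer(seed_len),
    min_edge_support = as.integer(min_edge_support),
    fork_search_depth = as.integer(fork_search_depth),
    depth_similarity_ratio = as.numeric(depth_similarity_ratio),
    scaffold_rounds = as.integer(scaffold_rounds),
    insert_mu = as.numeric(insert_mu),
    insert_sigma = as.numeric(insert_sigma),
    min_contig_len = as.integer(min_contig_len),
    rng_seed = as.integer(rng_seed))
  class(cfg) <- "assembly_config"
  validate_config(cfg)
}

validate_config <- function(cfg) {
  k <- cfg$k_list
  if (length(k) == 0 || any(is.na(k)))
    stop("k_list must be a non-empty vector of integers", call. = FALSE)
  if (any(k %% 2L == 0L))
    stop("k_list values must be odd (even k: ",
         paste(k[k %% 2L == 0L], collapse = ","), ")", call. = FALSE)
  if (any(k < 15L) || any(k > 63L))
    stop("k_list values must lie in [15, 63]", call. = FALSE)
  if (is.unsorted(k, strictly = TRUE))
    stop("k_list must be strictly increasing", call. = FALSE)
  if (cfg$min_count < 2L) stop("min_count must be >= 2", call. = FALSE)
  if (cfg$prune_ratio <= 0 || cfg$prune_ratio >= 1)
    stop("prune_ratio must be in (0, 1)", call. = FALSE)
  if (cfg$scaffold_rounds < 1L)
    stop("scaffold_rounds must be >= 1", call. = FALSE)
  if (cfg$depth_similarity_ratio <= 1)
    stop("depth_similarity_ratio must be > 1", call. = FALSE)
  if (cfg$alpha <= 0) stop("alpha must be > 0", call. = FALSE)
  if (cfg$min_contig_len < 0) stop("min_contig_len must be >= 0", call. = FALSE)
  cfg
}

#' Load an assembly configuration from a YAML file
#'
#' Precedence: explicit `overrides` (e.g. CLI flags) > file values >
#' built-in defaults.
#'
#' @param path YAML (or flat `key: value`) file; `NULL` for defaults only.
#' @param overrides named list overriding file values.
#' @return validated `assembly_config`.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  vals <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    # numeric scalars come back as strings (identity handlers) so that a
    # flat "k_list: 21,33" is splittable; assembly_config() re-coerces
    vals <- yaml::read_yaml(path, handlers = list(
      int = identity, float = identity))
    if (!is.null(vals$k_list))
      vals$k_list <- as.integer(unlist(strsplit(as.character(vals$k_list),
                                                ",")))
  }
  vals[names(overrides)] <- overrides
  known <- names(formals(assembly_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0)
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(assembly_config, vals)
}

#' @export
print.assembly_config <- function(x, ...) {
  cat("assembly_config\n")
  for (nm in names(x)) cat(sprintf("  %-22s %s\n", nm,
                                   paste(x[[nm]], collapse = ",")))
  invisible(x)
}
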