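#' Assembly parameters (hash length k and coverage cutoff C)
#'
#' @param k odd de Bruijn hash length (k-mer size), 15 <= k < read length.
#' @param C non-negative coverage cutoff: after graph construction every
#'   node with multiplicity <= C is removed (survival requires
#'   multiplicity > C; C = 0 keeps everything).
#' @param min_contig_len minimum emitted contig length in nt (>= k).
#' @param tip_clip_len dead-end paths shorter than this (nt) whose mean
#'   multiplicity is below the graph median are clipped; default 2k.
#' @return a validated list of class `assembly_params`.
#' @export
assembly_params <- function(k = 31L, C = 6, min_contig_len = 100L,
                            tip_clip_len = 2L * k) {
  check_that(is_count(k) && k >= 15 && k %% 2 == 1, "k",
             "must be an odd integer >= 15")
  check_that(is.numeric(C) && length(C) == 1 && C >= 0, "C",
             "must be a non-negative real")
  check_that(is_count(min_contig_len) && min_contig_len >= k,
             "min_contig_len", "must be a count >= k")
  check_that(is.numeric(tip_clip_len) && tip_clip_len >= 0, "tip_clip_len",
             "must be non-negative")
  structure(list(k = as.integer(k), C = as.numeric(C),
                 min_contig_len = as.integer(min_contig_len),
                 tip_clip_len = as.numeric(tip_clip_len)),
            class = "assembly_params")
}

#' Build the canonical k-mer graph of a read set
#'
#' Nodes are canonical k-mers (lexicographic minimum of a k-mer and its
#' reverse complement) with integer multiplicity equal to the number of
#' read k-mers mapping to them; strand-aware edges record every
#' (k-1)-overlap adjacency observed between consecutive read k-mers.
#'
#' @param reads a `read_set` or character vector of read sequences, all of
#'   length >= k.
#' @param k odd hash length; must not exceed the shortest read.
#' @return a list of class `kmer_graph` with elements `k`, `nodes` (a
#'   data.frame `kmer`, `count`) and `edges` (a data.frame `from`, `to`,
#'   `from_fwd`, `to_fwd`, indices into `nodes`, logical flags telling
#'   whether the canonical string is traversed in forward orientation).
#' @export
build_graph <- function(reads, k) {
  seqs <- seqs_of(reads)
  check_that(is_count(k) && k %% 2 == 1 && k <= 63, "k",
             "must be an odd integer <= 63")
  if (length(seqs) > 0 && k > min(nchar(seqs)))
    check_that(FALSE, "k", "must not exceed the read length")
  g <- cpp_build_graph(seqs, as.integer(k))
  structure(list(
    k = as.integer(k),
    nodes = data.frame(kmer = g$kmer, count = g$count,
                       stringsAsFactors = FALSE),
    edges = data.frame(from = g$edge_from, to = g$edge_to,
                       from_fwd = g$edge_from_fwd, to_fwd = g$edge_to_fwd)
  ), class = "kmer_graph")
}

#' Remove low-multiplicity nodes from a k-mer graph
#'
#' Deletes every node with multiplicity <= C together with its incident
#' edges (Velvet-style coverage cutoff: survival requires multiplicity
#' strictly above C, so C = 0 is the identity on any real graph).
#'
#' @param graph a `kmer_graph`.
#' @param C non-negative cutoff.
#' @return the filtered `kmer_graph`.
#' @export
apply_coverage_cutoff <- function(graph, C) {
  stopifnot(inherits(graph, "kmer_graph"))
  check_that(is.numeric(C) && length(C) == 1 && C >= 0, "C",
             "must be a non-negative real")
  keep <- graph$nodes$count > C
  remap <- cumsum(keep)
  nodes <- graph$nodes[keep, , drop = FALSE]
  rownames(nodes) <- NULL
  e <- graph$edges
  ekeep <- keep[e$from] & keep[e$to]
  e <- e[ekeep, , drop = FALSE]
  e$from <- remap[e$from]
  e$to <- remap[e$to]
  rownames(e) <- NULL
  structure(list(k = graph$k, nodes = nodes, edges = e),
            class = "kmer_graph")
}

#' Assemble reads into contigs at one (k, C) setting
#'
#' Pipeline: [build_graph()] -> [apply_coverage_cutoff()] -> clip dead-end
#' tips shorter than `tip_clip_len` whose mean multiplicity is below the
#' graph median -> compress maximal unambiguous paths (unitigs) -> emit
#' contigs of at least `min_contig_len` nt. Output is deterministic:
#' contigs are reported in their lexicographically smaller orientation,
#' ordered by decreasing length then sequence, and ids encode provenance as
#' `{sample}_k{k}_C{C}_{serial}`.
#'
#' @param reads a `read_set` or character vector (non-empty).
#' @param params an [assembly_params()] object.
#' @param sample sample label recorded in contig ids and provenance.
#' @return a `contig_set` data.frame with columns `id`, `sequence`,
#'   `length`, `sample`, `k_used`, `C_used`, `mean_kmer_coverage`,
#'   `n_reads_assembled` (NA until filled by the mapping stage).
#' @export
assemble <- function(reads, params, sample = "S1") {
  stopifnot(inherits(params, "assembly_params"))
  seqs <- seqs_of(reads)
  if (length(seqs) == 0) stop("reads must be non-empty", call. = FALSE)
  g <- build_graph(seqs, params$k)
  g <- apply_coverage_cutoff(g, params$C)
  if (nrow(g$nodes) == 0)
    return(empty_contig_set())
  u <- cpp_unitigs(g$nodes$kmer, g$nodes$count,
                   g$edges$from, g$edges$to,
                   g$edges$from_fwd, g$edges$to_fwd,
                   params$k, params$tip_clip_len, params$min_contig_len)
  n <- length(u$sequence)
  if (n == 0) return(empty_contig_set())
  contig_set(
    id = sprintf("%s_k%d_C%g_%05d", sample, params$k, params$C, seq_len(n)),
    sequence = u$sequence,
    sample = sample, k_used = params$k, C_used = params$C,
    mean_kmer_coverage = u$mean_kmer_coverage
  )
}

#' Construct a contig set
#'
#' @param id,sequence,sample,k_used,C_used,mean_kmer_coverage,n_reads_assembled
#'   column values (recycled where scalar).
#' @return a `contig_set` data.frame.
#' @export
contig_set <- function(id, sequence, sample = "S1", k_used = NA_integer_,
                       C_used = NA_real_, mean_kmer_coverage = NA_real_,
                       n_reads_assembled = NA_integer_) {
  if (anyDuplicated(id)) stop("contig ids must be unique within a set")
  n <- length(id)
  x <- data.frame(id = id, sequence = sequence, length = nchar(sequence),
                  sample = rep_len(sample, n),
                  k_used = rep_len(k_used, n),
                  C_used = rep_len(C_used, n),
                  mean_kmer_coverage = rep_len(mean_kmer_coverage, n),
                  n_reads_assembled = rep_len(n_reads_assembled, n),
                  stringsAsFactors = FALSE)
  class(x) <- c("contig_set", "data.frame")
  x
}

empty_contig_set <- function() {
  contig_set(id = character(0), sequence = character(0),
             sample = character(0), k_used = integer(0), C_used = numeric(0),
             mean_kmer_coverage = numeric(0), n_reads_assembled = integer(0))
}

#' Write a contig set as FASTA
#'
#' @param contigs a `contig_set`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_contigs_fasta <- function(contigs, path) {
  x <- Biostrings::DNAStringSet(contigs$sequence)
  names(x) <- contigs$id
  Biostrings::writeXStringSet(x, path, width = 80L)
  invisible(path)
}
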