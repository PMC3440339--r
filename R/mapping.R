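#' Read-mapping parameters
#'
#' @param max_mismatches maximum substitutions allowed in a placement
#'   (0-5; default 3, the bounded-mismatch regime of short-read mappers of
#'   the MAQ generation).
#' @param seed_length exact-seed length for the seed-and-verify index. To
#'   guarantee that no placement within the mismatch limit is missed, the
#'   effective seed is shortened to `floor(read_length /
#'   (max_mismatches + 1))` when that is smaller (pigeonhole guarantee).
#' @param report_policy placement accounting; only `"best"` (single best
#'   placement per read) is implemented.
#' @return a validated list of class `mapping_params`.
#' @export
mapping_params <- function(max_mismatches = 3L, seed_length = 20L,
                           report_policy = "best") {
  check_that(is_count(max_mismatches) && max_mismatches <= 5,
             "max_mismatches", "must be an integer in [0, 5]")
  check_that(is_count(seed_length) && seed_length >= 4, "seed_length",
             "must be a count >= 4")
  check_that(identical(report_policy, "best"), "report_policy",
             'only "best" is supported')
  structure(list(max_mismatches = as.integer(max_mismatches),
                 seed_length = as.integer(seed_length),
                 report_policy = report_policy),
            class = "mapping_params")
}

#' Map reads back to contigs under a bounded-mismatch rule
#'
#' Each read counts toward exactly one contig: its minimum-mismatch
#' placement within `max_mismatches`, searched on both strands. Ties are
#' broken by (fewest mismatches, lexicographically smallest contig id,
#' smallest start position, forward strand first). Reads with no placement
#' within the limit are counted separately as unmapped.
#'
#' @param reads a `read_set` or character vector.
#' @param contigs a non-empty `contig_set`.
#' @param params a [mapping_params()].
#' @return a list of class `read_mapping`: `assignments` (per-read
#'   data.frame `read_id`, `contig_id`, `position`, `strand`,
#'   `mismatches`; NA for unmapped reads), `counts` (per-contig
#'   data.frame `contig_id`, `n_reads_assembled`, every contig present),
#'   `n_unmapped`, `n_total`.
#' @export
map_reads <- function(reads, contigs, params = mapping_params()) {
  stopifnot(inherits(params, "mapping_params"))
  if (nrow(contigs) == 0) stop("contigs must be non-empty", call. = FALSE)
  seqs <- seqs_of(reads)
  ids <- if (is.data.frame(reads)) reads$id else
    sprintf("read_%07d", seq_along(seqs))
  ord <- c_order(contigs$id) # contig rank encodes the id tie-break
  ctg <- contigs[ord, , drop = FALSE]
  m <- cpp_map_reads(seqs, ctg$sequence, params$max_mismatches,
                     params$seed_length)
  mapped <- m[, 1] > 0
  assignments <- data.frame(
    read_id = ids,
    contig_id = ifelse(mapped, ctg$id[ifelse(mapped, m[, 1], 1L)],
                       NA_character_),
    position = ifelse(mapped, m[, 2], NA_integer_),
    strand = ifelse(mapped, c("+", "-")[ifelse(mapped, m[, 3], 1L)],
                    NA_character_),
    mismatches = ifelse(mapped, m[, 4], NA_integer_),
    stringsAsFactors = FALSE)
  tab <- table(factor(assignments$contig_id[mapped], levels = contigs$id))
  counts <- data.frame(contig_id = contigs$id,
                       n_reads_assembled = as.integer(tab),
                       stringsAsFactors = FALSE)
  structure(list(assignments = assignments, counts = counts,
                 n_unmapped = sum(!mapped), n_total = length(seqs)),
            class = "read_mapping")
}

#' Per-nucleotide depth of coverage
#'
#' The relative-abundance statistic: `n_reads * read_length / contig_len`,
#' rounded half-even to 2 decimals.
#'
#' @param n_reads number of reads assembled to the contig (vectorised).
#' @param read_length read length in nt.
#' @param contig_len contig length in nt (> 0).
#' @return depth (coverage per nt), 2 decimals.
#' @export
compute_depth <- function(n_reads, read_length, contig_len) {
  if (any(contig_len <= 0))
    stop("contig_len must be positive", call. = FALSE)
  round(n_reads * read_length / contig_len, 2)
}

#' Per-contig abundance records from a read mapping
#'
#' @param mapping a `read_mapping` from [map_reads()].
#' @param contigs the `contig_set` that was mapped against.
#' @param read_length read length used for the depth formula.
#' @return a data.frame of class `abundance_records`: `contig_id`,
#'   `n_reads_assembled`, `contig_len`, `depth`, `rank` (dense rank over
#'   descending read counts).
#' @export
abundance_table <- function(mapping, contigs, read_length = 75L) {
  stopifnot(inherits(mapping, "read_mapping"))
  cnt <- mapping$counts
  len <- contigs$length[match(cnt$contig_id, contigs$id)]
  x <- data.frame(contig_id = cnt$contig_id,
                  n_reads_assembled = cnt$n_reads_assembled,
                  contig_len = len,
                  depth = compute_depth(cnt$n_reads_assembled, read_length,
                                        len),
                  stringsAsFactors = FALSE)
  x$rank <- match(-x$n_reads_assembled,
                  sort(unique(-x$n_reads_assembled)))
  x <- x[c_order(x$rank, x$contig_id), , drop = FALSE]
  rownames(x) <- NULL
  class(x) <- c("abundance_records", "data.frame")
  x
}

#' Top-N most abundant contigs
#'
#' Selects the `n` records with the highest read counts (ties by contig
#' id) and reports the fold range of the listed counts (max/min, one
#' decimal) in `attr(, "fold_range")`. When fewer than `n` records exist,
#' all are returned and `attr(, "truncated")` is TRUE.
#'
#' @param records an `abundance_records` data.frame (or any data.frame
#'   with `contig_id` and `n_reads_assembled`).
#' @param n number of rows requested (>= 1).
#' @return the ranked table with attributes `fold_range` and `truncated`.
#' @export
top_n_table <- function(records, n = 10L) {
  check_that(is_count(n) && n >= 1, "n", "must be a positive count")
  ord <- c_order(-records$n_reads_assembled, records$contig_id)
  out <- records[ord, , drop = FALSE][seq_len(min(n, nrow(records))), ,
                                      drop = FALSE]
  rownames(out) <- NULL
  mn <- min(out$n_reads_assembled)
  attr(out, "fold_range") <- if (nrow(out) == 0 || mn == 0) NA_real_
                             else round(max(out$n_reads_assembled) / mn, 1)
  attr(out, "truncated") <- nrow(records) < n
  out
}
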