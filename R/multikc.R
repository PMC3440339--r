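#' Grid of (k, C) assembly settings
#'
#' The default grid brackets the single best-performing cell reported for
#' this kind of data (k = 31, C = 6) and spans under- and over-pruning
#' regimes in both directions.
#'
#' @param k_values odd hash lengths.
#' @param C_values non-negative coverage cutoffs.
#' @return a validated list of class `grid_spec`.
#' @export
grid_spec <- function(k_values = c(21L, 25L, 31L, 41L), C_values = c(2, 6)) {
  check_that(length(k_values) > 0 && all(k_values %% 2 == 1) &&
               all(k_values >= 15), "k_values",
             "must be a non-empty vector of odd integers >= 15")
  check_that(length(C_values) > 0 && all(C_values >= 0), "C_values",
             "must be a non-empty vector of non-negative reals")
  structure(list(k_values = as.integer(k_values),
                 C_values = as.numeric(C_values)),
            class = "grid_spec")
}

#' Run the Multiple-k/Multiple-C assembly procedure
#'
#' For every cell (k, C) of the grid the reads are assembled and the
#' resulting contig set depleted of redundancy; the per-cell survivors are
#' then pooled and depleted again, and length-filtered at
#' `min_contig_len`. Cells are processed in row-major order (k outer, C
#' inner); the whole procedure is deterministic.
#'
#' @param reads a `read_set` or character vector of read sequences.
#' @param grid a [grid_spec()].
#' @param cluster a [cluster_params()].
#' @param asm_defaults an [assembly_params()] whose `min_contig_len` and
#'   `tip_clip_len` policy apply to every cell (`tip_clip_len` is re-derived
#'   as 2k per cell when it equals 2k of the default cell).
#' @param sample sample label.
#' @return the merged `contig_set`; per-cell depleted sets are attached as
#'   `attr(, "per_cell")` (a named list, names `k{k}_C{C}`).
#' @export
run_multikc <- function(reads, grid = grid_spec(),
                        cluster = cluster_params(),
                        asm_defaults = assembly_params(),
                        sample = "S1") {
  stopifnot(inherits(grid, "grid_spec"))
  per_cell <- list()
  auto_tip <- isTRUE(all.equal(asm_defaults$tip_clip_len,
                               2 * asm_defaults$k))
  for (k in grid$k_values) {
    for (C in grid$C_values) {
      p <- assembly_params(k = k, C = C,
                           min_contig_len = asm_defaults$min_contig_len,
                           tip_clip_len = if (auto_tip) 2L * k
                                          else asm_defaults$tip_clip_len)
      cell <- assemble(reads, p, sample = sample)
      per_cell[[sprintf("k%d_C%g", k, C)]] <- deplete(cell, cluster)
    }
  }
  nonempty <- Filter(nrow, per_cell)
  merged <- if (length(nonempty) == 0) empty_contig_set()
            else pool_and_deplete(nonempty, cluster)
  merged <- merged[merged$length >= asm_defaults$min_contig_len, ,
                   drop = FALSE]
  rownames(merged) <- NULL
  class(merged) <- c("contig_set", "data.frame")
  attr(merged, "per_cell") <- per_cell
  merged
}

#' Assembly summary statistics (contig counts, N50, read coverage)
#'
#' N50 is the largest contig length L such that contigs of length >= L
#' contain at least half of the total assembled nucleotides.
#' `reads_covered_frac` is the fraction of reads with at least one
#' placement within the mapping mismatch limit (NA when `reads` is NULL).
#'
#' @param contigs a `contig_set`.
#' @param reads optional `read_set` used for the read-coverage fraction.
#' @param len_threshold length threshold for `frac_ge_threshold` (nt).
#' @param mapping a [mapping_params()] used for read-back mapping.
#' @return a list of class `assembly_stats`: `n_contigs`, `mean_len`,
#'   `longest`, `n50`, `frac_ge_threshold`, `reads_covered_frac`.
#' @export
compute_stats <- function(contigs, reads = NULL, len_threshold = 500L,
                          mapping = mapping_params()) {
  if (nrow(contigs) == 0) {
    return(structure(list(n_contigs = 0L, mean_len = 0, longest = 0L,
                          n50 = 0L, frac_ge_threshold = 0,
                          reads_covered_frac = 0),
                     class = "assembly_stats"))
  }
  len <- sort(contigs$length, decreasing = TRUE)
  total <- sum(as.numeric(len))
  n50 <- len[which(cumsum(as.numeric(len)) >= total / 2)[1]]
  covered <- NA_real_
  if (!is.null(reads) && length(seqs_of(reads)) > 0) {
    m <- map_reads(reads, contigs, mapping)
    covered <- 1 - m$n_unmapped / m$n_total
  }
  structure(list(n_contigs = nrow(contigs),
                 mean_len = mean(contigs$length),
                 longest = max(contigs$length),
                 n50 = n50,
                 frac_ge_threshold = mean(contigs$length >= len_threshold),
                 reads_covered_frac = covered),
            class = "assembly_stats")
}

#' @export
print.assembly_stats <- function(x, ...) {
  cat(sprintf(paste0("assembly stats: %d contigs, mean %.1f nt, ",
                     "longest %d nt, N50 %d nt, %.1f%% >= threshold"),
              x$n_contigs, x$mean_len, x$longest, x$n50,
              100 * x$frac_ge_threshold))
  if (!is.na(x$reads_covered_frac))
    cat(sprintf(", %.1f%% of reads covered", 100 * x$reads_covered_frac))
  cat("\n")
  invisible(x)
}

#' Distinct reference transcripts recovered by a contig set
#'
#' A transcript counts as recovered when at least one contig's top
#' annotation hit is that transcript. This is the quantity the
#' multiple-k/multiple-C merge is designed to increase relative to any
#' single (k, C) cell.
#'
#' @param contigs a `contig_set`.
#' @param reference the `transcript_set` to annotate against.
#' @param params an [annotation_params()].
#' @return character vector of recovered transcript ids.
#' @export
recovered_transcripts <- function(contigs, reference,
                                  params = annotation_params()) {
  if (nrow(contigs) == 0) return(character(0))
  hits <- annotate_contigs(contigs, reference, params)
  c_sort(unique(hits$hit_id[hits$tier != "none" & !is.na(hits$hit_id)]))
}
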