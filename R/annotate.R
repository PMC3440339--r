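#' Annotation parameters for the cascade homology search
#'
#' The cascade searches a translated tier first (six-frame translation of
#' the contig against frame-0 reference peptides, BLOSUM62, ungapped
#' X-drop extension) and falls back to a nucleotide tier (+2/-3) for
#' contigs without a translated hit. E-values follow the Karlin-Altschul
#' form E = K m n exp(-lambda S) with m the query length, n the total
#' database length, and published ungapped defaults for the constants.
#'
#' @param evalue_cutoff maximum e-value of a reported hit (> 0).
#' @param min_hsp_len minimum aligned length (residues for the translated
#'   tier, nt for the nucleotide tier).
#' @param top_hits hits reported per contig; fixed at 1 (top hit only).
#' @param seed_word_aa,seed_word_nt exact-seed word sizes of the two tiers.
#' @param xdrop score drop-off at which ungapped extension stops.
#' @param karlin_protein,karlin_K named pairs `c(lambda=, K=)` for the two
#'   tiers (`karlin_K` holds the nucleotide pair).
#' @return a validated list of class `annotation_params`.
#' @export
annotation_params <- function(evalue_cutoff = 1e-3, min_hsp_len = 33L,
                              top_hits = 1L,
                              seed_word_aa = 4L, seed_word_nt = 11L,
                              xdrop = 20L,
                              karlin_protein = c(lambda = 0.3176, K = 0.134),
                              karlin_K = c(lambda = 1.28, K = 0.46)) {
  check_that(is.numeric(evalue_cutoff) && evalue_cutoff > 0, "evalue_cutoff",
             "must be positive")
  check_that(is_count(min_hsp_len) && min_hsp_len >= 1, "min_hsp_len",
             "must be a positive count")
  check_that(identical(as.integer(top_hits), 1L), "top_hits",
             "only top-hit-only annotation (top_hits = 1) is supported")
  check_that(is_count(seed_word_aa) && seed_word_aa >= 2, "seed_word_aa",
             "must be a count >= 2")
  check_that(is_count(seed_word_nt) && seed_word_nt >= 4, "seed_word_nt",
             "must be a count >= 4")
  check_that(is.numeric(xdrop) && xdrop > 0, "xdrop", "must be positive")
  structure(list(evalue_cutoff = evalue_cutoff,
                 min_hsp_len = as.integer(min_hsp_len),
                 top_hits = 1L,
                 seed_word_aa = as.integer(seed_word_aa),
                 seed_word_nt = as.integer(seed_word_nt),
                 xdrop = as.numeric(xdrop),
                 karlin_protein = karlin_protein,
                 karlin_nucleotide = karlin_K),
            class = "annotation_params")
}

blosum62_matrix <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      m <- e$BLOSUM62
      storage.mode(m) <- "integer"
      cache <<- m
    }
    cache
  }
})

nucleotide_matrix <- function(match = 2L, mismatch = -3L) {
  m <- matrix(mismatch, 4, 4, dimnames = list(c("A", "C", "G", "T"),
                                              c("A", "C", "G", "T")))
  diag(m) <- match
  storage.mode(m) <- "integer"
  m
}

# frame-0 peptide of each sequence (trailing partial codon trimmed)
frame0_peptides <- function(seqs) {
  L <- (nchar(seqs) %/% 3L) * 3L
  trimmed <- substring(seqs, 1L, L)
  as.character(Biostrings::translate(Biostrings::DNAStringSet(trimmed),
                                     no.init.codon = TRUE))
}

# six-frame translations; returns data.frame(contig = index, pep)
six_frame_peptides <- function(seqs) {
  n <- length(seqs)
  rc <- revcomp(seqs)
  qs <- character(0)
  qc <- integer(0)
  for (src in list(seqs, rc)) {
    for (f in 0:2) {
      sub <- substring(src, 1L + f)
      qs <- c(qs, sub)
      qc <- c(qc, seq_len(n))
    }
  }
  data.frame(contig = qc, pep = frame0_peptides(qs),
             stringsAsFactors = FALSE)
}

empty_hits <- function() {
  h <- data.frame(contig_id = character(0), hit_id = character(0),
                  taxon = character(0), tier = character(0),
                  score = numeric(0), evalue = numeric(0),
                  identity = numeric(0), align_len = integer(0),
                  s_start = integer(0), s_end = integer(0),
                  stringsAsFactors = FALSE)
  class(h) <- c("homology_hits", "data.frame")
  h
}

# one search tier; returns the best passing hit per contig
tier_best_hits <- function(queries, query_contig, contig_ids, subjects,
                           subject_ids, subject_taxa, matrix, seed, params,
                           karlin, tier_label) {
  res <- cpp_seed_extend(queries, subjects, matrix, rownames(matrix),
                         seed, params$xdrop)
  if (nrow(res) == 0) return(empty_hits())
  qlen <- nchar(queries)[res$query]
  db_len <- sum(as.numeric(nchar(subjects)))
  res$evalue <- unname(karlin["K"]) * qlen * db_len *
    exp(-unname(karlin["lambda"]) * res$score)
  res <- res[res$evalue <= params$evalue_cutoff &
               res$align_len >= params$min_hsp_len, , drop = FALSE]
  if (nrow(res) == 0) return(empty_hits())
  res$contig <- query_contig[res$query]
  res$hit_id <- subject_ids[res$subject]
  res <- res[c_order(res$contig, res$evalue, -res$score, res$hit_id), ,
             drop = FALSE]
  res <- res[!duplicated(res$contig), , drop = FALSE]
  h <- data.frame(contig_id = contig_ids[res$contig],
                  hit_id = res$hit_id,
                  taxon = subject_taxa[res$subject],
                  tier = tier_label,
                  score = as.numeric(res$score),
                  evalue = res$evalue,
                  identity = res$matches / res$align_len,
                  align_len = res$align_len,
                  s_start = res$s_start, s_end = res$s_end,
                  stringsAsFactors = FALSE)
  class(h) <- c("homology_hits", "data.frame")
  h
}

#' Cascade top-hit annotation of contigs against a labelled reference
#'
#' Tier 1 aligns the six-frame translation of each contig against the
#' frame-0 peptides of the reference (BLOSUM62, exact-word seeds, ungapped
#' X-drop extension); if the best hit passes the e-value and HSP-length
#' cutoffs the contig is annotated and the cascade stops. Contigs without
#' a translated hit proceed to tier 2, a nucleotide search of both strands
#' (+2/-3). Contigs failing both tiers are reported with tier `"none"`.
#' The best hit is the lowest e-value, ties broken by higher score then
#' lexicographic hit id; exactly one row per contig is returned.
#'
#' Subject coordinates (`s_start`, `s_end`, 1-based closed) are in the
#' subject's native units: peptide residues for the translated tier,
#' nucleotides for the nucleotide tier.
#'
#' @param contigs a `contig_set`.
#' @param reference a non-empty `transcript_set` with taxon labels.
#' @param params an [annotation_params()].
#' @return a `homology_hits` data.frame, one row per contig.
#' @export
annotate_contigs <- function(contigs, reference,
                             params = annotation_params()) {
  stopifnot(inherits(params, "annotation_params"))
  if (nrow(reference) == 0)
    stop("reference must be non-empty", call. = FALSE)
  if (nrow(contigs) == 0) return(empty_hits())

  # tier 1: translated
  ref_pep <- frame0_peptides(reference$sequence)
  fr <- six_frame_peptides(contigs$sequence)
  t1 <- tier_best_hits(fr$pep, fr$contig, contigs$id, ref_pep,
                       reference$id, reference$taxon, blosum62_matrix(),
                       params$seed_word_aa, params, params$karlin_protein,
                       "translated")

  # tier 2: nucleotide, only for contigs without a translated hit
  remaining <- setdiff(contigs$id, t1$contig_id)
  t2 <- empty_hits()
  if (length(remaining) > 0) {
    sub2 <- contigs[match(remaining, contigs$id), , drop = FALSE]
    queries <- c(sub2$sequence, revcomp(sub2$sequence))
    qcontig <- rep(seq_len(nrow(sub2)), 2)
    t2 <- tier_best_hits(queries, qcontig, sub2$id, reference$sequence,
                         reference$id, reference$taxon, nucleotide_matrix(),
                         params$seed_word_nt, params,
                         params$karlin_nucleotide, "nucleotide")
  }

  none_ids <- setdiff(contigs$id, c(t1$contig_id, t2$contig_id))
  t3 <- empty_hits()
  if (length(none_ids) > 0) {
    t3 <- data.frame(contig_id = none_ids, hit_id = NA_character_,
                     taxon = NA_character_, tier = "none",
                     score = NA_real_, evalue = NA_real_,
                     identity = NA_real_, align_len = NA_integer_,
                     s_start = NA_integer_, s_end = NA_integer_,
                     stringsAsFactors = FALSE)
  }
  out <- rbind(as.data.frame(t1), as.data.frame(t2), as.data.frame(t3))
  out <- out[match(contigs$id, out$contig_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("homology_hits", "data.frame")
  out
}

#' Non-redundant top hits
#'
#' Distinct reference identifiers appearing as top hits, with the number
#' of contigs annotating to each.
#'
#' @param hits a `homology_hits` data.frame.
#' @return a data.frame `hit_id`, `n_contigs`, sorted by id.
#' @export
nonredundant_top_hits <- function(hits) {
  h <- hits$hit_id[!is.na(hits$hit_id) & hits$tier != "none"]
  if (length(h) == 0)
    return(data.frame(hit_id = character(0), n_contigs = integer(0),
                      stringsAsFactors = FALSE))
  tab <- table(h)
  out <- data.frame(hit_id = names(tab), n_contigs = as.integer(tab),
                    stringsAsFactors = FALSE)
  out[c_order(out$hit_id), , drop = FALSE]
}

#' Overlap summary of two non-redundant hit sets
#'
#' @param set_a,set_b character vectors of hit ids (duplicates ignored).
#' @return a data.frame with one row per category (`shared`, `a_only`,
#'   `b_only`, `union`): count and percentage of the union (1 decimal).
#' @export
overlap_summary <- function(set_a, set_b) {
  a <- unique(set_a)
  b <- unique(set_b)
  shared <- length(intersect(a, b))
  a_only <- length(setdiff(a, b))
  b_only <- length(setdiff(b, a))
  un <- shared + a_only + b_only
  counts <- c(shared = shared, a_only = a_only, b_only = b_only, union = un)
  data.frame(category = names(counts), count = as.integer(counts),
             pct_of_union = if (un > 0) round(100 * counts / un, 1)
                            else rep(NA_real_, 4),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Species/taxon distribution of non-redundant top hits
#'
#' Non-redundant hits are grouped by the taxon label of the reference they
#' hit; percentages of the total non-redundant hits are reported to 2
#' decimals.
#'
#' @param hits a `homology_hits` data.frame.
#' @return a data.frame `taxon`, `n_hits`, `pct`, sorted by decreasing
#'   count then taxon.
#' @export
taxon_distribution <- function(hits) {
  h <- hits[!is.na(hits$hit_id) & hits$tier != "none", , drop = FALSE]
  nr <- h[!duplicated(h$hit_id), , drop = FALSE]
  if (nrow(nr) == 0)
    return(data.frame(taxon = character(0), n_hits = integer(0),
                      pct = numeric(0), stringsAsFactors = FALSE))
  tab <- table(nr$taxon)
  out <- data.frame(taxon = names(tab), n_hits = as.integer(tab),
                    stringsAsFactors = FALSE)
  out$pct <- round(100 * out$n_hits / sum(out$n_hits), 2)
  out <- out[c_order(-out$n_hits, out$taxon), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Gene-set recovery: homologs found per annotated gene group
#'
#' For each gene group, counts the distinct group members with at least
#' one top hit and expresses it as a percentage of the group size (2
#' decimals). Hits to ids absent from `groups` are tallied under
#' `"ungrouped"`; a totals row (over the grouped genes) is appended.
#'
#' @param hits a `homology_hits` data.frame.
#' @param groups mapping from reference id to gene group: a named
#'   character vector (names = ids) or a data.frame with columns `hit_id`
#'   and `gene_group`.
#' @return a data.frame `gene_group`, `group_size`, `n_recovered`,
#'   `pct_recovered`.
#' @export
gene_set_recovery <- function(hits, groups) {
  if (is.data.frame(groups)) {
    groups <- setNames(groups$gene_group, groups$hit_id)
  }
  if (length(groups) == 0) stop("groups must be non-empty", call. = FALSE)
  hit_ids <- unique(hits$hit_id[!is.na(hits$hit_id) & hits$tier != "none"])
  glevels <- c_sort(unique(unname(groups)))
  size <- vapply(glevels, function(g) sum(groups == g), integer(1))
  rec <- vapply(glevels, function(g)
    length(intersect(hit_ids, names(groups)[groups == g])), integer(1))
  out <- data.frame(gene_group = glevels, group_size = size,
                    n_recovered = rec,
                    pct_recovered = round(100 * rec / size, 2),
                    stringsAsFactors = FALSE, row.names = NULL)
  ungrouped <- setdiff(hit_ids, names(groups))
  if (length(ungrouped) > 0) {
    out <- rbind(out, data.frame(gene_group = "ungrouped",
                                 group_size = NA_integer_,
                                 n_recovered = length(ungrouped),
                                 pct_recovered = NA_real_))
  }
  total <- data.frame(gene_group = "total", group_size = sum(size),
                      n_recovered = sum(rec),
                      pct_recovered = round(100 * sum(rec) / sum(size), 2))
  rbind(out, total)
}

#' Covered length and percentage of a reference molecule
#'
#' Merges the aligned reference intervals of a set of hits (1-based closed
#' coordinates) and reports the union length in nt and its percentage of
#' the reference length, rounded to the nearest integer. Used for
#' rRNA-style reference-coverage arithmetic.
#'
#' @param intervals a data.frame with columns `s_start`, `s_end` (e.g.
#'   nucleotide-tier `homology_hits` rows).
#' @param ref_len reference length in nt (> 0).
#' @return a list: `covered_nt`, `pct` (integer percentage).
#' @export
reference_coverage <- function(intervals, ref_len) {
  check_that(is.numeric(ref_len) && ref_len > 0, "ref_len",
             "must be positive")
  s <- intervals$s_start
  e <- intervals$s_end
  if (length(s) == 0) return(list(covered_nt = 0L, pct = 0L))
  if (any(is.na(s) | is.na(e)) || any(s < 1) || any(e > ref_len) ||
      any(s > e))
    stop("intervals must lie within [1, ref_len]", call. = FALSE)
  ir <- IRanges::reduce(IRanges::IRanges(start = s, end = e))
  covered <- sum(IRanges::width(ir))
  list(covered_nt = as.integer(covered),
       pct = as.integer(round(100 * covered / ref_len)))
}
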