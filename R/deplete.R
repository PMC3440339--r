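#' Clustering parameters for redundancy depletion
#'
#' @param identity_threshold minimum identity (matches / length of the
#'   shorter sequence) for a contig to join a cluster, in (0.5, 1].
#' @param word_size exact-seed length used to pre-filter candidate
#'   representatives (<= 12). A query is only aligned against
#'   representatives sharing `word_size`-mers with it (either strand).
#' @param min_shared_words number of distinct shared words required before
#'   a representative is aligned (capped at the number of words either
#'   sequence can contain, so short sequences are never filtered out by
#'   the cap alone). Any alignment at >= 95 percent identity over >= 100 nt
#'   shares far more words than this unless it is gap-dominated; raising
#'   the value speeds clustering up, lowering it towards 1 approaches the
#'   pure shares-a-seed rule.
#' @param coverage_mode rule defining the identity denominator; only
#'   `"shorter"` (full length of the shorter sequence, the CD-HIT
#'   global-identity convention) is implemented.
#' @return a validated list of class `cluster_params`.
#' @export
cluster_params <- function(identity_threshold = 0.95, word_size = 8L,
                           min_shared_words = 8L,
                           coverage_mode = "shorter") {
  check_that(is.numeric(identity_threshold) &&
               identity_threshold > 0.5 && identity_threshold <= 1,
             "identity_threshold", "must be in (0.5, 1]")
  check_that(is_count(word_size) && word_size >= 4 && word_size <= 12,
             "word_size", "must be a count in [4, 12]")
  check_that(is_count(min_shared_words) && min_shared_words >= 1,
             "min_shared_words", "must be a positive count")
  check_that(identical(coverage_mode, "shorter"), "coverage_mode",
             'only "shorter" is supported')
  structure(list(identity_threshold = identity_threshold,
                 word_size = as.integer(word_size),
                 min_shared_words = as.integer(min_shared_words),
                 coverage_mode = coverage_mode),
            class = "cluster_params")
}

# global identity of a against b over both strands: matches of the best
# end-free alignment divided by the full length of the shorter sequence
# (the CD-HIT convention; containment scores 1, partial overlap is
# penalised by the unaligned remainder). When `stop_at` is given, the
# reverse strand is skipped if the forward strand already reaches it
# (membership decisions are unaffected).
pair_identity <- function(a, b, stop_at = NULL) {
  denom <- min(nchar(a), nchar(b))
  if (denom == 0) return(0)
  best <- 0
  for (q in c(a, revcomp(a))) {
    al <- cpp_overlap_align(q, b)
    best <- max(best, al[2] / denom)
    if (!is.null(stop_at) && best >= stop_at) break
  }
  best
}

all_words <- function(seq, w) {
  n <- nchar(seq)
  if (n < w) return(character(0))
  unique(substring(seq, 1:(n - w + 1), w:n))
}

#' Deplete a contig set of redundancy by greedy identity clustering
#'
#' Greedy incremental clustering in the style of CD-HIT: contigs are
#' processed in decreasing length order (ties by lexicographic id); each
#' contig joins the first existing cluster whose representative shares
#' exact `word_size` seeds (either strand) and aligns at identity >=
#' `identity_threshold`, otherwise it founds a new cluster. Identity is
#' matches of the best end-free alignment (+1 match, -1 mismatch, -2 gap,
#' both strands tested) divided by the full length of the shorter
#' sequence, so a contained contig scores 1 and collapses into its
#' superstring's cluster.
#'
#' @param contigs a `contig_set` (may be empty).
#' @param params a [cluster_params()] object.
#' @return the representatives as a `contig_set`, in decreasing length
#'   order, with provenance columns preserved. Cluster membership is
#'   attached as `attr(, "clusters")`: a data.frame `member_id`,
#'   `representative_id`, `identity`.
#' @export
deplete <- function(contigs, params = cluster_params()) {
  stopifnot(inherits(params, "cluster_params"))
  n <- nrow(contigs)
  clusters <- data.frame(member_id = character(0),
                         representative_id = character(0),
                         identity = numeric(0), stringsAsFactors = FALSE)
  if (n == 0) {
    out <- contigs
    attr(out, "clusters") <- clusters
    return(out)
  }
  ord <- c_order(-contigs$length, contigs$id)
  x <- contigs[ord, , drop = FALSE]
  w <- params$word_size

  rep_idx <- integer(0)              # row indices (into x) of representatives
  rep_nwords <- integer(0)           # distinct words per representative
  word_env <- new.env(hash = TRUE, parent = emptyenv())
  member_rep <- integer(n)           # cluster (index into rep_idx) per row
  member_ident <- numeric(n)

  for (i in seq_len(n)) {
    seq_i <- x$sequence[i]
    cand <- integer(0)
    if (length(rep_idx) > 0) {
      qwords <- unique(c(all_words(seq_i, w), all_words(revcomp(seq_i), w)))
      hits <- unlist(lapply(qwords, function(qw) word_env[[qw]]),
                     use.names = FALSE)
      if (length(hits) > 0) {
        tab <- tabulate(hits, nbins = length(rep_idx))
        # a candidate must share min_shared_words words, capped at what
        # either sequence could possibly contain
        need <- pmin(params$min_shared_words, length(qwords), rep_nwords)
        cand <- which(tab >= pmax(1L, need))
      }
    }
    assigned <- FALSE
    for (ci in cand) { # ascending = cluster founding order
      idn <- pair_identity(seq_i, x$sequence[rep_idx[ci]],
                           stop_at = params$identity_threshold)
      if (idn >= params$identity_threshold) {
        member_rep[i] <- ci
        member_ident[i] <- idn
        assigned <- TRUE
        break
      }
    }
    if (!assigned) {
      rwords <- all_words(seq_i, w)
      rep_idx <- c(rep_idx, i)
      rep_nwords <- c(rep_nwords, length(rwords))
      ci <- length(rep_idx)
      member_rep[i] <- ci
      member_ident[i] <- 1
      for (qw in rwords) {
        word_env[[qw]] <- c(word_env[[qw]], ci)
      }
    }
  }
  out <- x[rep_idx, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("contig_set", "data.frame")
  clusters <- data.frame(member_id = x$id,
                         representative_id = x$id[rep_idx[member_rep]],
                         identity = member_ident, stringsAsFactors = FALSE)
  attr(out, "clusters") <- clusters
  out
}

#' Pool contig sets from one sample and deplete the union
#'
#' Concatenates the per-(k, C) contig sets of a sample and runs
#' [deplete()] on the pooled set; per-cell provenance (`k_used`, `C_used`)
#' of each surviving representative is preserved.
#'
#' @param sets a list of `contig_set` objects from the same sample.
#' @param params a [cluster_params()] object.
#' @return the depleted pooled `contig_set`.
#' @export
pool_and_deplete <- function(sets, params = cluster_params()) {
  stopifnot(is.list(sets), length(sets) > 0)
  pooled <- do.call(rbind, lapply(sets, as.data.frame))
  samples <- unique(pooled$sample)
  if (length(samples) > 1)
    stop("cannot pool contig sets from different samples: ",
         paste(samples, collapse = ", "), call. = FALSE)
  pooled <- pooled[!duplicated(pooled$id), , drop = FALSE]
  rownames(pooled) <- NULL
  class(pooled) <- c("contig_set", "data.frame")
  deplete(pooled, params)
}

#' Write a CD-HIT-style cluster report
#'
#' One block per cluster: the representative line followed by member lines
#' with their identity to the representative.
#'
#' @param depleted output of [deplete()] (must carry the `clusters`
#'   attribute).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_clstr <- function(depleted, path) {
  cl <- attr(depleted, "clusters")
  if (is.null(cl)) stop("no cluster attribute; pass the output of deplete()")
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(depleted))) {
    rid <- depleted$id[i]
    writeLines(sprintf(">Cluster %d", i - 1L), con)
    members <- cl[cl$representative_id == rid, , drop = FALSE]
    writeLines(sprintf("%d\t%s\t%s\t%.4f",
                       seq_len(nrow(members)) - 1L, members$member_id,
                       ifelse(members$member_id == rid, "*", "member"),
                       members$identity), con)
  }
  invisible(path)
}
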