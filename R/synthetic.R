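#' Simulation parameters for the synthetic transcriptome generator
#'
#' Bundles and validates every knob of the synthetic data module. The
#' generator emulates the statistical structure the assembly/annotation
#' pipeline assumes: a eukaryote host transcriptome with log-normally
#' distributed expression, a high-abundance AT-rich primary-endosymbiont
#' fraction whose transcripts carry no polyA tail (and are therefore
#' depleted by each round of polyA selection), and a rare secondary
#' endosymbiont contributing only short rRNA-like fragments.
#'
#' @param n_host_transcripts,n_primary_endo_transcripts,n_secondary_endo_fragments
#'   counts of reference transcripts per class.
#' @param read_length read length in nt (fixed-length single-end reads).
#' @param n_reads number of reads to simulate.
#' @param error_rate per-base substitution probability in \[0, 0.1\].
#' @param abundance_sigma log-normal shape parameter of the expression
#'   distribution (meanlog 0).
#' @param polyA_rounds number of polyA-selection rounds applied to the
#'   library (0 = no selection).
#' @param nonpolyA_retention_per_round fraction of non-polyadenylated
#'   molecules surviving one selection round, in (0, 1].
#' @param seed integer seed; mandatory, recorded in all outputs.
#' @param n_gene_groups number of gene-group labels cycled over the host
#'   transcripts (used by gene-set recovery reporting).
#' @param host_gc,endo_gc GC fraction of host and endosymbiont sequences.
#' @param primary_abundance_factor,secondary_abundance_factor multipliers
#'   applied to the raw log-normal weight of endosymbiont transcripts; the
#'   primary endosymbiont is abundant before polyA selection, the secondary
#'   one rare.
#' @param host_len_range,primary_len_range,secondary_len_range inclusive
#'   transcript length ranges (nt) per class.
#' @return a validated list of class `simulation_params`.
#' @export
simulation_params <- function(n_host_transcripts = 60L,
                              n_primary_endo_transcripts = 15L,
                              n_secondary_endo_fragments = 5L,
                              read_length = 75L,
                              n_reads = 50000L,
                              error_rate = 0.005,
                              abundance_sigma = 1.5,
                              polyA_rounds = 2L,
                              nonpolyA_retention_per_round = 0.46,
                              seed = 1L,
                              n_gene_groups = 4L,
                              host_gc = 0.5,
                              endo_gc = 0.30,
                              primary_abundance_factor = 6,
                              secondary_abundance_factor = 0.05,
                              host_len_range = c(400L, 2500L),
                              primary_len_range = c(300L, 1500L),
                              secondary_len_range = c(150L, 800L)) {
  check_that(is_count(n_host_transcripts), "n_host_transcripts",
             "must be a non-negative count")
  check_that(is_count(n_primary_endo_transcripts),
             "n_primary_endo_transcripts", "must be a non-negative count")
  check_that(is_count(n_secondary_endo_fragments),
             "n_secondary_endo_fragments", "must be a non-negative count")
  check_that(is_count(read_length) && read_length >= 20, "read_length",
             "must be a count >= 20")
  check_that(is_count(n_reads), "n_reads", "must be a non-negative count")
  check_that(is.numeric(error_rate) && length(error_rate) == 1 &&
               error_rate >= 0 && error_rate <= 0.1, "error_rate",
             "must be in [0, 0.1]")
  check_that(is.numeric(abundance_sigma) && abundance_sigma >= 0,
             "abundance_sigma", "must be non-negative")
  check_that(is_count(polyA_rounds), "polyA_rounds",
             "must be an integer >= 0")
  check_that(is.numeric(nonpolyA_retention_per_round) &&
               nonpolyA_retention_per_round > 0 &&
               nonpolyA_retention_per_round <= 1,
             "nonpolyA_retention_per_round", "must be in (0, 1]")
  check_that(is_count(abs(seed)) || (is.numeric(seed) && seed == floor(seed)),
             "seed", "must be an integer")
  check_that(is_count(n_gene_groups) && n_gene_groups >= 1, "n_gene_groups",
             "must be a positive count")
  for (nm in c("host_gc", "endo_gc")) {
    v <- get(nm)
    check_that(is.numeric(v) && v > 0 && v < 1, nm, "must be in (0, 1)")
  }
  for (nm in c("host_len_range", "primary_len_range", "secondary_len_range")) {
    v <- get(nm)
    check_that(length(v) == 2 && all(v >= 150) && v[1] <= v[2], nm,
               "must be an increasing pair of lengths >= 150")
  }
  p <- list(n_host_transcripts = as.integer(n_host_transcripts),
            n_primary_endo_transcripts = as.integer(n_primary_endo_transcripts),
            n_secondary_endo_fragments = as.integer(n_secondary_endo_fragments),
            read_length = as.integer(read_length),
            n_reads = as.integer(n_reads),
            error_rate = error_rate,
            abundance_sigma = abundance_sigma,
            polyA_rounds = as.integer(polyA_rounds),
            nonpolyA_retention_per_round = nonpolyA_retention_per_round,
            seed = as.integer(seed),
            n_gene_groups = as.integer(n_gene_groups),
            host_gc = host_gc, endo_gc = endo_gc,
            primary_abundance_factor = primary_abundance_factor,
            secondary_abundance_factor = secondary_abundance_factor,
            host_len_range = as.integer(host_len_range),
            primary_len_range = as.integer(primary_len_range),
            secondary_len_range = as.integer(secondary_len_range))
  structure(p, class = "simulation_params")
}

random_seq <- function(len, gc) {
  prob <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(prob), len, replace = TRUE, prob = prob), collapse = "")
}

#' Generate a labelled reference transcriptome
#'
#' Draws a reference set of host, primary-endosymbiont and
#' secondary-endosymbiont transcripts. The RNG consumption order is part of
#' the contract (so the stream can be re-drawn independently for
#' verification): after `set.seed(seed)`, (1) one `rlnorm(n_total, 0,
#' abundance_sigma)` call draws the raw abundance weights for all
#' transcripts in the order host, primary, secondary; (2) one `sample()`
#' call per class (in that order) draws transcript lengths uniformly over
#' the class length range; (3) sequences are drawn transcript by
#' transcript, in the same order, as i.i.d. bases at the class GC fraction.
#' Class abundance factors are applied to the raw weights after step (1):
#' `abundance_weight = raw_lognormal * class_factor`.
#'
#' Host transcripts are polyadenylated and carry a cycling gene-group
#' label; endosymbiont transcripts are not polyadenylated; the secondary
#' endosymbiont contributes only short rRNA-like fragments (group "rRNA").
#'
#' @param params a [simulation_params()] object.
#' @return a `data.frame` of class `transcript_set` with columns `id`,
#'   `taxon`, `gene_group`, `sequence`, `length`, `abundance_weight`,
#'   `polyadenylated`.
#' @export
generate_reference <- function(params) {
  stopifnot(inherits(params, "simulation_params"))
  nh <- params$n_host_transcripts
  np <- params$n_primary_endo_transcripts
  ns <- params$n_secondary_endo_fragments
  n <- nh + np + ns
  if (n == 0) return(empty_transcript_set())
  set.seed(params$seed)
  raw_w <- rlnorm(n, 0, params$abundance_sigma)
  len <- integer(n)
  ranges <- list(params$host_len_range, params$primary_len_range,
                 params$secondary_len_range)
  counts <- c(nh, np, ns)
  pos <- 1L
  for (i in 1:3) {
    if (counts[i] > 0) {
      rg <- ranges[[i]]
      len[pos:(pos + counts[i] - 1L)] <-
        sample(seq.int(rg[1], rg[2]), counts[i], replace = TRUE)
      pos <- pos + counts[i]
    }
  }
  gc <- c(rep(params$host_gc, nh), rep(params$endo_gc, np + ns))
  seqs <- character(n)
  for (i in seq_len(n)) seqs[i] <- random_seq(len[i], gc[i])

  taxon <- c(rep("host", nh), rep("primary_endosymbiont", np),
             rep("secondary_endosymbiont", ns))
  id <- c(sprintf("host_%04d", seq_len(nh)),
          sprintf("primary_%04d", seq_len(np)),
          sprintf("secondary_%04d", seq_len(ns)))
  grp <- c(if (nh > 0) sprintf("group_%02d",
                               ((seq_len(nh) - 1L) %% params$n_gene_groups) + 1L),
           rep(NA_character_, np),
           rep("rRNA", ns))
  factor_by_class <- c(rep(1, nh),
                       rep(params$primary_abundance_factor, np),
                       rep(params$secondary_abundance_factor, ns))
  ref <- data.frame(id = id, taxon = taxon, gene_group = grp,
                    sequence = seqs, length = len,
                    abundance_weight = raw_w * factor_by_class,
                    polyadenylated = c(rep(TRUE, nh), rep(FALSE, np + ns)),
                    stringsAsFactors = FALSE)
  class(ref) <- c("transcript_set", "data.frame")
  ref
}

empty_transcript_set <- function() {
  ref <- data.frame(id = character(0), taxon = character(0),
                    gene_group = character(0), sequence = character(0),
                    length = integer(0), abundance_weight = numeric(0),
                    polyadenylated = logical(0), stringsAsFactors = FALSE)
  class(ref) <- c("transcript_set", "data.frame")
  ref
}

# expected per-read sampling weight of each transcript: molar abundance x
# transcript length x polyA retention (fragment sampling: a transcript
# contributes reads in proportion to how much of it is present in the
# library, i.e. molecules x nucleotides)
effective_weights <- function(reference, params) {
  retention <- ifelse(reference$polyadenylated, 1,
                      params$nonpolyA_retention_per_round ^ params$polyA_rounds)
  reference$abundance_weight * reference$length * retention
}

#' Simulate fixed-length single-end reads from a reference
#'
#' Each read is drawn by (1) selecting a transcript with probability
#' proportional to `abundance_weight * length * retention` — fragment
#' sampling under the standard RNA-seq model, where `abundance_weight` is
#' molar relative expression, a transcript contributes sequence in
#' proportion to molecules x nucleotides, and retention is 1 for
#' polyadenylated transcripts and `nonpolyA_retention_per_round ^
#' polyA_rounds` otherwise; (2) a uniform start position; (3) independent
#' per-base substitution at `error_rate` (substituted base uniform over the
#' three alternatives). Reads carry the identity of their source transcript
#' as a truth label. Under this model the expected per-nucleotide depth of
#' a fully assembled transcript is proportional to its `abundance_weight`,
#' which is what makes depth a usable relative-abundance statistic.
#'
#' The simulator seeds its own stream at `seed + 1` so that reference
#' generation and read simulation consume independent, individually
#' re-drawable streams. RNG consumption order: (1) one `sample()` call for
#' all transcript indices; (2) one `runif(n_reads)` call for start
#' positions; (3) one `rbinom(n_reads, read_length, error_rate)` call for
#' per-read substitution counts; (4) for each read with at least one
#' substitution, in read order, one `sample()` of positions then one
#' `sample()` of replacement bases.
#'
#' @param reference a `transcript_set` (every transcript must be at least
#'   `read_length` nt).
#' @param params a [simulation_params()] object.
#' @return a `data.frame` of class `read_set` with columns `id`,
#'   `sequence`, `truth_id`; the read length is stored in
#'   `attr(, "read_length")`.
#' @export
simulate_reads <- function(reference, params) {
  stopifnot(inherits(params, "simulation_params"))
  rl <- params$read_length
  n <- params$n_reads
  if (n > 0 && nrow(reference) == 0)
    stop("cannot simulate reads from an empty reference", call. = FALSE)
  if (nrow(reference) > 0 && any(reference$length < rl))
    stop("every reference transcript must be at least read_length nt",
         call. = FALSE)
  if (n == 0) return(empty_read_set(rl))

  set.seed(params$seed + 1L)
  w <- effective_weights(reference, params)
  idx <- sample.int(nrow(reference), n, replace = TRUE, prob = w)
  maxstart <- reference$length[idx] - rl + 1L
  start <- 1L + as.integer(floor(runif(n) * maxstart))
  start <- pmin(start, maxstart) # guard against runif returning exactly 1
  seqs <- substring(reference$sequence[idx], start, start + rl - 1L)

  if (params$error_rate > 0) {
    nmut <- rbinom(n, rl, params$error_rate)
    bases <- c("A", "C", "G", "T")
    for (i in which(nmut > 0)) {
      chars <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
      pos <- sample.int(rl, nmut[i])
      for (p in pos) {
        chars[p] <- sample(setdiff(bases, chars[p]), 1)
      }
      seqs[i] <- paste(chars, collapse = "")
    }
  }
  reads <- data.frame(id = sprintf("read_%07d", seq_len(n)),
                      sequence = seqs,
                      truth_id = reference$id[idx],
                      stringsAsFactors = FALSE)
  attr(reads, "read_length") <- rl
  class(reads) <- c("read_set", "data.frame")
  reads
}

empty_read_set <- function(read_length = 75L) {
  reads <- data.frame(id = character(0), sequence = character(0),
                      truth_id = character(0), stringsAsFactors = FALSE)
  attr(reads, "read_length") <- as.integer(read_length)
  class(reads) <- c("read_set", "data.frame")
  reads
}

#' Solve the per-round polyA retention for a target non-polyA read fraction
#'
#' Given a realised reference, returns the per-round retention r such that
#' the expected fraction of reads drawn from non-polyadenylated transcripts
#' equals `target_fraction` after `polyA_rounds` rounds of selection:
#' solves target = r^R W_np / (W_p + r^R W_np) for r, where W_p and W_np
#' are the summed read-sampling weights (abundance x length) of
#' polyadenylated and non-polyadenylated transcripts.
#'
#' @param reference a `transcript_set` containing both classes.
#' @param target_fraction desired expected non-polyA read fraction in (0, 1).
#' @param polyA_rounds number of selection rounds (>= 1).
#' @return per-round retention in (0, 1]; errors if the target needs r > 1.
#' @export
calibrate_retention <- function(reference, target_fraction, polyA_rounds = 1L) {
  stopifnot(polyA_rounds >= 1)
  w <- reference$abundance_weight * reference$length
  w_p <- sum(w[reference$polyadenylated])
  w_np <- sum(w[!reference$polyadenylated])
  if (w_np == 0 || w_p == 0)
    stop("reference must contain both polyadenylated and non-polyadenylated transcripts")
  rR <- target_fraction * w_p / ((1 - target_fraction) * w_np)
  r <- rR ^ (1 / polyA_rounds)
  if (r > 1)
    stop("target fraction unreachable: non-polyA weight share too small")
  r
}

#' Fraction of reads drawn from non-polyadenylated transcripts
#'
#' @param reads a `read_set` with truth labels.
#' @param reference the `transcript_set` the reads were simulated from.
#' @return empirical non-polyA read fraction.
#' @export
nonpolya_read_fraction <- function(reads, reference) {
  polya <- reference$polyadenylated[match(reads$truth_id, reference$id)]
  if (anyNA(polya)) stop("reads carry truth ids absent from the reference")
  mean(!polya)
}

# ---- FASTA / FASTQ interchange ---------------------------------------------

#' Write a reference transcriptome as FASTA with structured headers
#'
#' Headers carry the taxon/group/polyA/weight metadata:
#' `>id taxon=<label> group=<label> polyA=<0|1> weight=<float>`.
#'
#' @param reference a `transcript_set`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(reference, path) {
  x <- Biostrings::DNAStringSet(reference$sequence)
  names(x) <- sprintf("%s taxon=%s group=%s polyA=%d weight=%.10g",
                      reference$id, reference$taxon,
                      ifelse(is.na(reference$gene_group), "NA",
                             reference$gene_group),
                      as.integer(reference$polyadenylated),
                      reference$abundance_weight)
  Biostrings::writeXStringSet(x, path, width = 80L)
  invisible(path)
}

#' Read a reference transcriptome written by [write_reference_fasta()]
#'
#' @param path FASTA file path.
#' @return a `transcript_set`.
#' @export
read_reference_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  hdr <- names(x)
  field <- function(key) sub(sprintf(".*%s=([^ ]+).*", key), "\\1", hdr)
  grp <- field("group")
  ref <- data.frame(id = sub(" .*", "", hdr),
                    taxon = field("taxon"),
                    gene_group = ifelse(grp == "NA", NA_character_, grp),
                    sequence = as.character(x),
                    length = Biostrings::width(x),
                    abundance_weight = as.numeric(field("weight")),
                    polyadenylated = field("polyA") == "1",
                    stringsAsFactors = FALSE)
  class(ref) <- c("transcript_set", "data.frame")
  ref
}

#' Write simulated reads as Sanger FASTQ with truth labels
#'
#' The truth transcript id is stored in the description after a `truth=`
#' key; qualities are a constant placeholder (no stage consumes them).
#'
#' @param reads a `read_set`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_reads_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$sequence)
  names(x) <- sprintf("%s truth=%s", reads$id, reads$truth_id)
  qual <- Biostrings::BStringSet(strrep("I", nchar(reads$sequence)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = qual)
  invisible(path)
}

#' Read a FASTQ file (optionally carrying `truth=` labels)
#'
#' @param path FASTQ file path.
#' @return a `read_set`; `truth_id` is `NA` when no label is present.
#' @export
read_reads_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  hdr <- names(x)
  truth <- ifelse(grepl("truth=", hdr, fixed = TRUE),
                  sub(".*truth=([^ ]+).*", "\\1", hdr), NA_character_)
  reads <- data.frame(id = sub(" .*", "", hdr),
                      sequence = as.character(x),
                      truth_id = truth, stringsAsFactors = FALSE)
  attr(reads, "read_length") <- if (nrow(reads)) max(nchar(reads$sequence)) else NA_integer_
  class(reads) <- c("read_set", "data.frame")
  reads
}
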