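#' Full pipeline configuration
#'
#' Bundles the parameters of every stage plus seed and output directory.
#' When several samples are named they share one reference transcriptome
#' (generated at `seed`) but differ in sampled reads: each sample
#' re-jitters the transcript abundances (log-normal factor with sdlog
#' `sample_abundance_sigma`) and draws its reads from a sample-specific
#' stream (`seed + 1000 * sample_index`), emulating tissue-level
#' expression differences over a common gene complement.
#'
#' @param sample_names character vector of sample labels.
#' @param simulation a [simulation_params()].
#' @param grid a [grid_spec()].
#' @param cluster a [cluster_params()].
#' @param mapping a [mapping_params()].
#' @param annotation an [annotation_params()].
#' @param output_dir directory the report bundle is written to.
#' @param seed master seed (also used for the shared reference).
#' @param sample_abundance_sigma sdlog of the per-sample abundance jitter.
#' @return a validated list of class `run_config`.
#' @export
run_config <- function(sample_names = "demo",
                       simulation = simulation_params(seed = seed),
                       grid = grid_spec(),
                       cluster = cluster_params(),
                       mapping = mapping_params(),
                       annotation = annotation_params(),
                       output_dir = tempfile("multikc_run_"),
                       seed = 1L,
                       sample_abundance_sigma = 0.5) {
  check_that(is.character(sample_names) && length(sample_names) >= 1 &&
               !anyDuplicated(sample_names), "sample_names",
             "must be distinct labels")
  stopifnot(inherits(simulation, "simulation_params"),
            inherits(grid, "grid_spec"),
            inherits(cluster, "cluster_params"),
            inherits(mapping, "mapping_params"),
            inherits(annotation, "annotation_params"))
  check_that(is.numeric(seed) && length(seed) == 1 && seed == floor(seed),
             "seed", "must be an integer")
  structure(list(sample_names = sample_names, simulation = simulation,
                 grid = grid, cluster = cluster, mapping = mapping,
                 annotation = annotation, output_dir = output_dir,
                 seed = as.integer(seed),
                 sample_abundance_sigma = sample_abundance_sigma),
            class = "run_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [run_config()]; nested maps
#' (`simulation`, `grid`, `cluster`, `mapping`, `annotation`) override the
#' defaults of the corresponding parameter constructors.
#'
#' @param path YAML file path.
#' @param ... overrides applied after the file (e.g. `output_dir`, `seed`).
#' @return a `run_config`.
#' @export
load_run_config <- function(path, ...) {
  y <- yaml::read_yaml(path)
  dots <- list(...)
  y[names(dots)] <- dots
  seed <- if (!is.null(y$seed)) as.integer(y$seed) else 1L
  sim_args <- y$simulation %||% list()
  if (is.null(sim_args$seed)) sim_args$seed <- seed
  args <- list(
    sample_names = y$sample_names %||% "demo",
    simulation = do.call(simulation_params, sim_args),
    grid = do.call(grid_spec, y$grid %||% list()),
    cluster = do.call(cluster_params, y$cluster %||% list()),
    mapping = do.call(mapping_params, y$mapping %||% list()),
    annotation = do.call(annotation_params, y$annotation %||% list()),
    seed = seed)
  if (!is.null(y$output_dir)) args$output_dir <- y$output_dir
  if (!is.null(y$sample_abundance_sigma))
    args$sample_abundance_sigma <- y$sample_abundance_sigma
  do.call(run_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full pipeline and emit the report bundle
#'
#' For every sample: simulate reads from the shared reference, run the
#' Multiple-k/Multiple-C assembly, map the reads back, build abundance
#' tables, annotate the merged contigs, and write the per-sample report
#' tables (assembly/annotation summary, taxon distribution, gene-set
#' recovery, top-10 and full abundance tables, contig FASTA, per-contig
#' hits). With two or more samples, pairwise overlap summaries of the
#' non-redundant hit sets are added. A JSON manifest records parameters,
#' seed and MD5 checksums of every emitted file. All outputs are
#' deterministic functions of the configuration, so two runs with the same
#' config produce byte-identical bundles.
#'
#' @param config a [run_config()].
#' @param quiet suppress progress messages.
#' @return invisibly, a list with the reference, per-sample results and
#'   the manifest.
#' @export
run_full <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)

  ref <- generate_reference(config$simulation)
  if (nrow(ref) == 0)
    stop("stage reference-generation: empty reference (all transcript counts are 0)",
         call. = FALSE)
  write_reference_fasta(ref, file.path(config$output_dir, "reference.fasta"))

  groups <- setNames(ref$gene_group[!is.na(ref$gene_group)],
                     ref$id[!is.na(ref$gene_group)])
  results <- list()
  hit_sets <- list()
  for (si in seq_along(config$sample_names)) {
    sname <- config$sample_names[si]
    say("sample %s: simulating reads", sname)
    sref <- ref
    set.seed(config$seed + 1000L * si)
    sref$abundance_weight <- sref$abundance_weight *
      rlnorm(nrow(sref), 0, config$sample_abundance_sigma)
    sp <- config$simulation
    sp$seed <- config$seed + 1000L * si
    reads <- simulate_reads(sref, sp)

    say("sample %s: multiple-k/multiple-C assembly (%d cells)", sname,
        length(config$grid$k_values) * length(config$grid$C_values))
    merged <- run_multikc(reads, config$grid, config$cluster,
                          assembly_params(min_contig_len = 100L),
                          sample = sname)
    if (nrow(merged) == 0)
      stop(sprintf("stage assembly: no contigs for sample %s", sname),
           call. = FALSE)

    say("sample %s: mapping %d reads back to %d contigs", sname,
        nrow(reads), nrow(merged))
    mp <- map_reads(reads, merged, config$mapping)
    merged$n_reads_assembled <-
      mp$counts$n_reads_assembled[match(merged$id, mp$counts$contig_id)]
    ab <- abundance_table(mp, merged, sp$read_length)
    top10 <- top_n_table(ab, 10L)

    say("sample %s: cascade annotation", sname)
    hits <- annotate_contigs(merged, ref, config$annotation)
    nr <- nonredundant_top_hits(hits)
    tiers <- table(factor(hits$tier,
                          levels = c("translated", "nucleotide", "none")))
    stats <- compute_stats(merged, reads, 500L, config$mapping)
    summary_tab <- data.frame(
      statistic = c("total_contigs", "mean_len", "longest", "n50",
                    "frac_ge_500nt", "reads_covered_frac",
                    "translated_hits", "nucleotide_hits", "no_hits",
                    "nonredundant_top_hits"),
      value = c(stats$n_contigs, round(stats$mean_len, 1), stats$longest,
                stats$n50, round(stats$frac_ge_threshold, 4),
                round(stats$reads_covered_frac, 4),
                as.integer(tiers["translated"]),
                as.integer(tiers["nucleotide"]), as.integer(tiers["none"]),
                nrow(nr)),
      stringsAsFactors = FALSE)

    pdir <- file.path(config$output_dir, sname)
    dir.create(pdir, showWarnings = FALSE)
    write_contigs_fasta(merged, file.path(pdir, "contigs.fasta"))
    write_tsv(summary_tab, file.path(pdir, "assembly_summary.tsv"))
    write_tsv(taxon_distribution(hits),
              file.path(pdir, "taxon_distribution.tsv"))
    write_tsv(gene_set_recovery(hits, groups),
              file.path(pdir, "gene_set_recovery.tsv"))
    ab10 <- top10
    ab10$fold_range <- attr(top10, "fold_range")
    write_tsv(ab10, file.path(pdir, "abundance_top10.tsv"))
    write_tsv(ab, file.path(pdir, "abundance_full.tsv"))
    write_tsv(as.data.frame(hits), file.path(pdir, "hits.tsv"))

    hit_sets[[sname]] <- nr$hit_id
    results[[sname]] <- list(reads = reads, contigs = merged, mapping = mp,
                             abundance = ab, top10 = top10, hits = hits,
                             stats = stats, summary = summary_tab)
  }

  if (length(hit_sets) >= 2) {
    pairs <- utils::combn(names(hit_sets), 2, simplify = FALSE)
    for (pr in pairs) {
      ov <- overlap_summary(hit_sets[[pr[1]]], hit_sets[[pr[2]]])
      write_tsv(ov, file.path(config$output_dir,
                              sprintf("overlap_%s_vs_%s.tsv", pr[1], pr[2])))
    }
  }

  files <- list.files(config$output_dir, recursive = TRUE,
                      full.names = FALSE)
  files <- setdiff(files, "manifest.json")
  sums <- tools::md5sum(file.path(config$output_dir, files))
  manifest <- list(
    package = "multikc",
    version = as.character(utils::packageVersion("multikc")),
    seed = config$seed,
    sample_names = config$sample_names,
    parameters = list(
      simulation = unclass(config$simulation),
      grid = unclass(config$grid),
      cluster = unclass(config$cluster),
      mapping = unclass(config$mapping),
      annotation = lapply(unclass(config$annotation), unname)),
    checksums = as.list(setNames(unname(sums), files)))
  jsonlite::write_json(manifest,
                       file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(reference = ref, samples = results, manifest = manifest))
}
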