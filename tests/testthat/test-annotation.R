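ann_reference <- function(seed, n = 12, gc = 0.5, len = 360:900) {
  set.seed(seed)
  manual_reference(vapply(sample(len, n, replace = TRUE), random_dna,
                          character(1), gc = gc),
                   taxon = rep(c("host", "primary_endosymbiont"),
                               length.out = n),
                   ids = sprintf("ref_%03d", seq_len(n)))
}

test_that("a contig identical to a reference transcript is a translated-tier hit", {
  ref <- ann_reference(501)
  cs <- manual_contigs(ref$sequence[3], ids = "q1")
  h <- annotate_contigs(cs, ref)
  expect_identical(h$tier, "translated")
  expect_identical(h$hit_id, "ref_003")
  expect_identical(h$taxon, ref$taxon[3])
  expect_equal(h$identity, 1.0)
  expect_lte(h$evalue, 1e-3)
})

test_that("an unrelated short contig gets no hit under strict cutoffs", {
  ref <- ann_reference(502)
  set.seed(5021)
  h <- annotate_contigs(manual_contigs(random_dna(150)), ref)
  expect_identical(h$tier, "none")
  expect_true(is.na(h$hit_id))
  expect_error(annotate_contigs(manual_contigs(random_dna(150)),
                                multikc:::empty_transcript_set()),
               "non-empty")
})

test_that("top hits equal the truth and the exhaustive local-alignment oracle", {
  ref <- ann_reference(503, n = 15)
  set.seed(5031)
  truth <- sample(nrow(ref), 30, replace = TRUE)
  contigs <- manual_contigs(vapply(truth, function(i) {
    s <- ref$sequence[i]
    start <- sample(nchar(s) - 299, 1)
    frag <- substr(s, start, start + sample(299:320, 1))
    frag <- mutate_seq(frag, rbinom(1, nchar(frag), 0.01))
    if (runif(1) < 0.5) rc_oracle(frag) else frag
  }, character(1)), ids = sprintf("q%03d", 1:30))
  h <- annotate_contigs(contigs, ref)
  expect_true(all(h$tier == "translated"))
  expect_identical(h$hit_id, ref$id[truth])

  # independent oracle: full Smith-Waterman over all pairs and frames
  pep_db <- Biostrings::AAStringSet(multikc:::frame0_peptides(ref$sequence))
  data(BLOSUM62, package = "Biostrings", envir = environment())
  for (q in sample(30, 6)) { # spot-check a subset (oracle is expensive)
    frames <- multikc:::six_frame_peptides(contigs$sequence[q])$pep
    best <- -Inf; best_ref <- NA
    for (r in seq_len(nrow(ref))) {
      sc <- max(Biostrings::pairwiseAlignment(
        Biostrings::AAStringSet(frames), pep_db[[r]],
        substitutionMatrix = BLOSUM62, type = "local",
        gapOpening = 100, gapExtension = 100, scoreOnly = TRUE))
      if (sc > best) { best <- sc; best_ref <- ref$id[r] }
    }
    expect_identical(h$hit_id[q], best_ref)
  }
})

test_that("annotation precision is at least 0.95 for 300+ nt contigs", {
  correct <- 0L; total <- 0L
  for (rep in 1:10) {
    ref <- ann_reference(510 + rep, n = 10)
    truth <- sample(nrow(ref), 12, replace = TRUE)
    contigs <- manual_contigs(vapply(truth, function(i) {
      s <- ref$sequence[i]
      start <- sample(nchar(s) - 299, 1)
      mutate_seq(substr(s, start, start + 299), rbinom(1, 300, 0.01))
    }, character(1)), ids = sprintf("q%03d", seq_along(truth)))
    h <- annotate_contigs(contigs, ref)
    ok <- h$tier != "none"
    correct <- correct + sum(h$hit_id[ok] == ref$id[truth][ok])
    total <- total + sum(ok)
  }
  expect_gt(total, 100)
  expect_gte(correct / total, 0.95)
})

test_that("the cascade is exclusive and tiers partition the contig set", {
  ref <- ann_reference(520, n = 8)
  set.seed(5201)
  protein_hit <- substr(ref$sequence[1], 10, 320)          # translated tier
  nt_only <- paste0(substr(ref$sequence[2], 1, 60),
                    random_dna(90))                        # 60 nt overlap:
                                                           # < 33 aa, >= 33 nt
  nothing <- random_dna(150)
  cs <- manual_contigs(c(protein_hit, nt_only, nothing),
                       ids = c("prot", "nt", "none"))
  h <- annotate_contigs(cs, ref)
  expect_identical(h$tier[h$contig_id == "prot"], "translated")
  expect_identical(h$tier[h$contig_id == "nt"], "nucleotide")
  expect_identical(h$tier[h$contig_id == "none"], "none")
  expect_identical(nrow(h), nrow(cs))           # exactly one row per contig
  expect_identical(sort(h$contig_id), sort(cs$id))
  expect_identical(h$hit_id[h$contig_id == "nt"], "ref_002")
})

test_that("non-redundant hit counting equals direct set construction", {
  ref <- ann_reference(530, n = 4)
  cs <- manual_contigs(rep(substr(ref$sequence[2], 1, 300), 5),
                       ids = sprintf("q%d", 1:5))
  nr <- nonredundant_top_hits(annotate_contigs(cs, ref))
  expect_identical(nrow(nr), 1L)
  expect_identical(nr$n_contigs, 5L)
  expect_identical(nrow(nonredundant_top_hits(multikc:::empty_hits())), 0L)

  # brute-force distinct-count on a synthetic hit table
  set.seed(5301)
  tab <- data.frame(contig_id = sprintf("c%02d", 1:20),
                    hit_id = sample(sprintf("h%02d", 1:7), 20, replace = TRUE),
                    tier = "translated", stringsAsFactors = FALSE)
  nr2 <- nonredundant_top_hits(tab)
  expect_identical(nr2$hit_id, sort(unique(tab$hit_id)))
  expect_identical(nr2$n_contigs, as.integer(table(tab$hit_id)[nr2$hit_id]))
})

test_that("overlap summaries reproduce printed percentages and set algebra", {
  a <- sprintf("s%05d", 1:(9244 + 1396))          # shared + a-only
  b <- c(sprintf("s%05d", 1:9244), sprintf("b%05d", 1:5617))
  ov <- overlap_summary(a, b)
  expect_identical(ov$count[ov$category == "union"], 16257L)
  expect_equal(ov$pct_of_union[ov$category == "shared"], 56.9)
  expect_equal(ov$pct_of_union[ov$category == "a_only"], 8.6)
  expect_equal(ov$pct_of_union[ov$category == "b_only"], 34.6)

  same <- overlap_summary(letters, letters)
  expect_equal(same$pct_of_union[same$category == "shared"], 100.0)

  set.seed(540)
  x <- sample(letters, 12); y <- sample(letters, 15)
  ov2 <- overlap_summary(x, y)
  expect_identical(ov2$count[1], length(intersect(x, y)))
  expect_identical(ov2$count[2], length(setdiff(x, y)))
  expect_identical(ov2$count[3], length(setdiff(y, x)))
  expect_identical(ov2$count[4], length(union(x, y)))
})

test_that("taxon distribution percentages follow plain arithmetic", {
  mk_hits <- function(taxa) {
    data.frame(contig_id = sprintf("c%05d", seq_along(taxa)),
               hit_id = sprintf("h%05d", seq_along(taxa)),
               taxon = taxa, tier = "translated", stringsAsFactors = FALSE)
  }
  td <- taxon_distribution(mk_hits(rep(c("Acyrthosiphon pisum", "other"),
                                       c(8730, 1910))))
  expect_equal(td$pct[td$taxon == "Acyrthosiphon pisum"], 82.05)
  expect_identical(sum(td$n_hits), 10640L)

  td1 <- taxon_distribution(mk_hits(rep("only", 7)))
  expect_equal(td1$pct, 100.00)

  set.seed(550)
  td2 <- taxon_distribution(mk_hits(sample(LETTERS[1:5], 137, replace = TRUE)))
  expect_lt(abs(sum(td2$pct) - 100), 0.05)
  expect_equal(td2$pct, round(100 * td2$n_hits / 137, 2))
})

test_that("gene-set recovery percentages match the printed arithmetic", {
  groups <- setNames(rep("Amino acid transporters", 47),
                     sprintf("aat%02d", 1:47))
  hits <- data.frame(contig_id = sprintf("c%02d", 1:45),
                     hit_id = sprintf("aat%02d", 1:45),
                     tier = "translated", stringsAsFactors = FALSE)
  out <- gene_set_recovery(hits, groups)
  expect_equal(out$pct_recovered[out$gene_group == "Amino acid transporters"],
               95.74)

  # totals row over the full published gene-set table
  gs <- read.delim(system.file("extdata", "reported_gene_sets.tsv",
                               package = "multikc"), comment.char = "#")
  groups2 <- unlist(lapply(seq_len(nrow(gs)), function(i)
    setNames(rep(gs$gene_group[i], gs$n_pea_aphid_genes[i]),
             sprintf("%02d_%04d", i, seq_len(gs$n_pea_aphid_genes[i])))))
  rec_ids <- unlist(lapply(seq_len(nrow(gs)), function(i)
    sprintf("%02d_%04d", i, seq_len(gs$total_recovered[i]))))
  hits2 <- data.frame(contig_id = seq_along(rec_ids), hit_id = rec_ids,
                      tier = "translated", stringsAsFactors = FALSE)
  out2 <- gene_set_recovery(hits2, groups2)
  expect_identical(out2$group_size[out2$gene_group == "total"], 1430L)
  expect_identical(out2$n_recovered[out2$gene_group == "total"], 1145L)
  expect_equal(out2$pct_recovered[out2$gene_group == "total"], 80.07)

  # no hits -> 0% everywhere
  out3 <- gene_set_recovery(multikc:::empty_hits(), groups)
  expect_true(all(out3$n_recovered == 0))
  expect_true(all(out3$pct_recovered[!is.na(out3$pct_recovered)] == 0))
})

test_that("reference coverage merges intervals like a per-base mask", {
  cov <- reference_coverage(data.frame(s_start = 101, s_end = 1170), 1505)
  expect_identical(cov$covered_nt, 1070L)
  expect_identical(cov$pct, 71L)

  full <- reference_coverage(data.frame(s_start = 1, s_end = 980), 980)
  expect_identical(full$pct, 100L)

  set.seed(560)
  for (i in 1:10) {
    n <- sample(1:8, 1); L <- 500
    s <- sample(L - 50, n); e <- pmin(L, s + sample(10:80, n, replace = TRUE))
    got <- reference_coverage(data.frame(s_start = s, s_end = e), L)
    mask <- logical(L)
    for (j in seq_len(n)) mask[s[j]:e[j]] <- TRUE
    expect_identical(got$covered_nt, sum(mask))
    expect_identical(got$pct, as.integer(round(100 * sum(mask) / L)))
  }
  expect_error(reference_coverage(data.frame(s_start = 0, s_end = 10), 100),
               "within")
  expect_error(reference_coverage(data.frame(s_start = 5, s_end = 101), 100),
               "within")
})
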