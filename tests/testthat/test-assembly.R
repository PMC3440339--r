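test_that("graph of single reads has the expected nodes and edges", {
  set.seed(101)
  km <- repeat_free_transcript(21, 21)
  g <- build_graph(km, 21)
  expect_identical(nrow(g$nodes), 1L)
  expect_identical(nrow(g$edges), 0L)
  expect_identical(g$nodes$count, 1L)

  s <- repeat_free_transcript(22, 21) # two distinct k-mers
  g2 <- build_graph(s, 21)
  expect_identical(nrow(g2$nodes), 2L)
  expect_identical(nrow(g2$edges), 1L)
})

test_that("graph construction rejects bad k", {
  expect_error(build_graph("ACGTACGTACGTACGTACGTACGT", 20), "k")
  expect_error(build_graph("ACGT", 21), "k")
})

test_that("node multiset equals brute-force canonical k-mer counting", {
  set.seed(102)
  tx <- repeat_free_transcript(40, 21)
  reads <- tiling_reads(tx, 30, 1) # > 10 overlapping reads
  g <- build_graph(reads, 21)
  oracle <- oracle_kmer_counts(reads, 21)
  expect_identical(g$nodes$kmer, oracle$kmer)
  expect_identical(g$nodes$count, oracle$count)

  # and on messier input: random reads, some reverse-complemented
  reads2 <- c(replicate(15, random_dna(40)), rc_oracle(reads[1:3]))
  g2 <- build_graph(reads2, 15)
  oracle2 <- oracle_kmer_counts(reads2, 15)
  expect_identical(g2$nodes$kmer, oracle2$kmer)
  expect_identical(g2$nodes$count, oracle2$count)
})

test_that("coverage cutoff removes exactly the nodes at or below C", {
  set.seed(103)
  reads <- c(replicate(10, random_dna(60)),
             tiling_reads(random_dna(120), 60, 10))
  g <- build_graph(reads, 21)
  expect_identical(apply_coverage_cutoff(g, 0), g) # identity at C = 0
  # brute-force filter oracle
  flt <- apply_coverage_cutoff(g, 3)
  keep <- g$nodes$count > 3
  expect_identical(flt$nodes$kmer, g$nodes$kmer[keep])
  old_ids <- which(keep)
  expect_identical(flt$nodes$count, g$nodes$count[keep])
  e_keep <- g$edges[g$edges$from %in% old_ids & g$edges$to %in% old_ids, ]
  expect_identical(flt$nodes$kmer[flt$edges$from], g$nodes$kmer[e_keep$from])
  expect_identical(flt$nodes$kmer[flt$edges$to], g$nodes$kmer[e_keep$to])
  # single node of multiplicity 1 vanishes at C = 2
  g1 <- build_graph(repeat_free_transcript(21, 21), 21)
  expect_identical(nrow(apply_coverage_cutoff(g1, 2)$nodes), 0L)
  expect_error(apply_coverage_cutoff(g, -1), "C")
})

test_that("error-free tiling reads reconstruct the transcript losslessly", {
  set.seed(104)
  for (i in 1:10) {
    len <- sample(150:400, 1)
    tx <- repeat_free_transcript(len, 21)
    reads <- tiling_reads(tx, 75, 5)
    cs <- assemble(reads, assembly_params(k = 21, C = 0))
    expect_identical(nrow(cs), 1L)
    expect_true(cs$sequence %in% c(tx, rc_oracle(tx)))
  }
})

test_that("assembly is empty when total coverage never exceeds C", {
  set.seed(105)
  tx <- repeat_free_transcript(300, 21)
  reads <- tiling_reads(tx, 75, 40) # every k-mer covered at most 2x
  cs <- assemble(reads, assembly_params(k = 21, C = 6))
  expect_identical(nrow(cs), 0L)
})

test_that("contigs equal the brute-force unitig decomposition at a shared k-mer", {
  set.seed(106)
  k <- 21
  repeat { # two transcripts sharing exactly one internal canonical k-mer
    shared <- random_dna(k)
    a <- paste0(random_dna(60), shared, random_dna(60))
    b <- paste0(random_dna(60), shared, random_dna(60))
    kc <- oracle_kmer_counts(c(a, b), k)
    if (sum(kc$count >= 2) == 1) break
  }
  reads <- c(tiling_reads(a, 75, 3), tiling_reads(b, 75, 3))
  g <- apply_coverage_cutoff(build_graph(reads, k), 0)
  expected <- oracle_unitigs(g, min_len = k)
  cs <- assemble(reads, assembly_params(k = k, C = 0, min_contig_len = k,
                                        tip_clip_len = 0))
  expect_identical(sort(cs$sequence, method = "radix"), expected)
  expect_gt(nrow(cs), 1) # the shared k-mer forces a branch
})

test_that("unitig decomposition matches the oracle on random read sets", {
  set.seed(107)
  for (i in 1:5) {
    reads <- c(tiling_reads(random_dna(150), 60, 7),
               tiling_reads(random_dna(120), 60, 11),
               replicate(3, random_dna(60)))
    g <- apply_coverage_cutoff(build_graph(reads, 19), 0)
    expected <- oracle_unitigs(g, min_len = 19)
    cs <- assemble(reads, assembly_params(k = 19, C = 0, min_contig_len = 19,
                                          tip_clip_len = 0))
    expect_identical(sort(cs$sequence, method = "radix"), expected)
  }
})

test_that("total assembled nucleotides are non-increasing in C", {
  set.seed(108)
  tx1 <- random_dna(500); tx2 <- random_dna(300)
  reads <- c(tiling_reads(tx1, 75, 2), tiling_reads(tx2, 75, 4),
             replicate(20, random_dna(75)))
  nt <- vapply(c(0, 1, 2, 4, 8, 16), function(C) {
    sum(assemble(reads, assembly_params(k = 21, C = C))$length)
  }, numeric(1))
  expect_true(all(diff(nt) <= 0))
})

test_that("every contig spells a walk of sound k-mers and ids encode provenance", {
  set.seed(109)
  tx <- random_dna(600)
  reads <- c(tiling_reads(tx, 75, 3), replicate(10, random_dna(75)))
  prm <- assembly_params(k = 23, C = 1)
  cs <- assemble(reads, prm, sample = "gut")
  expect_true(all(grepl("^gut_k23_C1_\\d{5}$", cs$id)))
  expect_true(all(cs$length >= prm$min_contig_len))
  g <- apply_coverage_cutoff(build_graph(reads, 23), 1)
  for (s in cs$sequence) { # all contig k-mers are surviving graph nodes
    kms <- substring(s, 1:(nchar(s) - 22), 23:nchar(s))
    can <- ifelse(kms <= rc_oracle(kms), kms, rc_oracle(kms))
    expect_true(all(can %in% g$nodes$kmer))
  }
})
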