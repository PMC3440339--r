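test_that("parameter validation names the offending field", {
  expect_error(simulation_params(error_rate = 0.5, seed = 1), "error_rate")
  expect_error(simulation_params(read_length = 10, seed = 1), "read_length")
  expect_error(simulation_params(n_reads = -1, seed = 1), "n_reads")
  expect_error(simulation_params(nonpolyA_retention_per_round = 0, seed = 1),
               "nonpolyA_retention_per_round")
})

test_that("all-zero transcript counts give an empty reference", {
  p <- simulation_params(n_host_transcripts = 0,
                         n_primary_endo_transcripts = 0,
                         n_secondary_endo_fragments = 0, seed = 3)
  expect_identical(nrow(generate_reference(p)), 0L)
})

test_that("generation is deterministic down to the FASTA bytes", {
  p <- simulation_params(n_host_transcripts = 5,
                         n_primary_endo_transcripts = 2,
                         n_secondary_endo_fragments = 1,
                         n_reads = 200, seed = 11)
  r1 <- generate_reference(p)
  r2 <- generate_reference(p)
  expect_identical(r1, r2)
  f1 <- tempfile(fileext = ".fasta"); f2 <- tempfile(fileext = ".fasta")
  write_reference_fasta(r1, f1); write_reference_fasta(r2, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(simulate_reads(r1, p), simulate_reads(r2, p))
})

test_that("abundance weights match an independent re-draw of the documented stream", {
  p <- simulation_params(n_host_transcripts = 50,
                         n_primary_endo_transcripts = 0,
                         n_secondary_endo_fragments = 0,
                         abundance_sigma = 1.5, seed = 7)
  ref <- generate_reference(p)
  set.seed(7)
  expect_equal(ref$abundance_weight, rlnorm(50, 0, 1.5))
  # endosymbiont class factors multiply the same stream
  p2 <- simulation_params(n_host_transcripts = 4,
                          n_primary_endo_transcripts = 3,
                          n_secondary_endo_fragments = 2,
                          abundance_sigma = 1.2, seed = 19)
  ref2 <- generate_reference(p2)
  set.seed(19)
  raw <- rlnorm(9, 0, 1.2)
  expect_equal(ref2$abundance_weight,
               raw * c(rep(1, 4), rep(p2$primary_abundance_factor, 3),
                       rep(p2$secondary_abundance_factor, 2)))
})

test_that("reference structure matches the class contract", {
  p <- simulation_params(n_host_transcripts = 8,
                         n_primary_endo_transcripts = 4,
                         n_secondary_endo_fragments = 3, seed = 5)
  ref <- generate_reference(p)
  expect_false(anyDuplicated(ref$id) > 0)
  expect_true(all(ref$length >= 150))
  expect_true(all(ref$abundance_weight > 0))
  expect_true(all(ref$polyadenylated[ref$taxon == "host"]))
  expect_false(any(ref$polyadenylated[ref$taxon != "host"]))
  sec <- ref[ref$taxon == "secondary_endosymbiont", ]
  expect_true(all(sec$length >= 150 & sec$length <= 800))
  expect_true(all(nchar(ref$sequence) == ref$length))
  # endosymbiont sequences are AT-rich relative to host
  gc_of <- function(s) {
    v <- strsplit(paste(s, collapse = ""), "")[[1]]
    mean(v %in% c("G", "C"))
  }
  expect_lt(gc_of(ref$sequence[ref$taxon != "host"]),
            gc_of(ref$sequence[ref$taxon == "host"]) - 0.1)
})

test_that("error-free reads are exact substrings and truth labels are valid", {
  p <- simulation_params(n_host_transcripts = 1,
                         n_primary_endo_transcripts = 0,
                         n_secondary_endo_fragments = 0,
                         error_rate = 0, n_reads = 150, seed = 2)
  ref <- generate_reference(p)
  reads <- simulate_reads(ref, p)
  expect_identical(nrow(reads), 150L)
  expect_true(all(nchar(reads$sequence) == p$read_length))
  expect_true(all(reads$truth_id %in% ref$id))
  expect_true(all(vapply(reads$sequence, grepl, logical(1),
                         x = ref$sequence, fixed = TRUE)))
})

test_that("simulating from an empty reference is an error", {
  p <- simulation_params(n_host_transcripts = 0,
                         n_primary_endo_transcripts = 0,
                         n_secondary_endo_fragments = 0,
                         n_reads = 10, seed = 4)
  expect_error(simulate_reads(generate_reference(p), p), "empty reference")
})

test_that("read counts split 1:3 for weights 1 and 3 within binomial bounds", {
  set.seed(31)
  ref <- manual_reference(c(random_dna(500), random_dna(500)), weight = c(1, 3))
  p <- simulation_params(n_host_transcripts = 2,
                         n_primary_endo_transcripts = 0,
                         n_secondary_endo_fragments = 0,
                         error_rate = 0, n_reads = 4000, seed = 31)
  reads <- simulate_reads(ref, p)
  n2 <- sum(reads$truth_id == "ref_002")
  bounds <- qbinom(c(0.005, 0.995), 4000, 0.75) # exact binomial 99% interval
  expect_gte(n2, bounds[1])
  expect_lte(n2, bounds[2])
})

test_that("per-transcript read fractions follow weight x retention (chi-square GOF)", {
  set.seed(77)
  seqs <- replicate(8, random_dna(600))
  ref <- manual_reference(seqs, weight = rlnorm(8, 0, 1),
                          polyA = c(rep(TRUE, 5), rep(FALSE, 3)))
  p <- simulation_params(n_host_transcripts = 5,
                         n_primary_endo_transcripts = 3,
                         n_secondary_endo_fragments = 0,
                         error_rate = 0.005, n_reads = 100000,
                         polyA_rounds = 1,
                         nonpolyA_retention_per_round = 0.4, seed = 77)
  reads <- simulate_reads(ref, p)
  counts <- table(factor(reads$truth_id, levels = ref$id))
  w <- ref$abundance_weight * ifelse(ref$polyadenylated, 1, 0.4)
  gof <- suppressWarnings(chisq.test(counts, p = w / sum(w)))
  expect_gt(gof$p.value, 0.01)
})

test_that("retention calibration hits the target non-polyA read fraction", {
  # moderate abundance spread so the realised non-polyA weight share
  # cannot collapse below the target by chance
  p0 <- simulation_params(n_host_transcripts = 30,
                          n_primary_endo_transcripts = 10,
                          n_secondary_endo_fragments = 3,
                          abundance_sigma = 1.0, seed = 13)
  ref <- generate_reference(p0)
  r <- calibrate_retention(ref, target_fraction = 0.30, polyA_rounds = 1)
  p <- simulation_params(n_host_transcripts = 30,
                         n_primary_endo_transcripts = 10,
                         n_secondary_endo_fragments = 3,
                         abundance_sigma = 1.0,
                         n_reads = 100000, error_rate = 0,
                         polyA_rounds = 1,
                         nonpolyA_retention_per_round = r, seed = 13)
  frac <- nonpolya_read_fraction(simulate_reads(ref, p), ref)
  expect_lt(abs(frac - 0.30), 0.03)
})

test_that("FASTA and FASTQ round trips preserve records and metadata", {
  p <- simulation_params(n_host_transcripts = 4,
                         n_primary_endo_transcripts = 2,
                         n_secondary_endo_fragments = 1,
                         n_reads = 50, seed = 21)
  ref <- generate_reference(p)
  fa <- tempfile(fileext = ".fasta")
  write_reference_fasta(ref, fa)
  back <- read_reference_fasta(fa)
  expect_identical(back$id, ref$id)
  expect_identical(back$sequence, ref$sequence)
  expect_identical(back$taxon, ref$taxon)
  expect_identical(back$polyadenylated, ref$polyadenylated)
  expect_equal(back$abundance_weight, ref$abundance_weight, tolerance = 1e-8)

  reads <- simulate_reads(ref, p)
  fq <- tempfile(fileext = ".fastq")
  write_reads_fastq(reads, fq)
  back2 <- read_reads_fastq(fq)
  expect_identical(back2$id, reads$id)
  expect_identical(back2$sequence, reads$sequence)
  expect_identical(back2$truth_id, reads$truth_id)
})
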