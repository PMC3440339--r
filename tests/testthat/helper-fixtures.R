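# fixture builders: everything is generated in code under local seeds

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# a transcript with no repeated canonical k-mer (resampled until true)
repeat_free_transcript <- function(len, k) {
  repeat {
    s <- random_dna(len)
    kms <- substring(s, 1:(len - k + 1), k:len)
    rcs <- rc_oracle(kms)
    can <- ifelse(kms <= rcs, kms, rcs)
    if (!anyDuplicated(can)) return(s)
  }
}

# error-free reads tiling a sequence end to end
tiling_reads <- function(seq, read_len, step) {
  n <- nchar(seq)
  starts <- unique(c(seq(1, n - read_len + 1, by = step), n - read_len + 1))
  substring(seq, starts, starts + read_len - 1)
}

# mutate a sequence with n random substitutions
mutate_seq <- function(s, n_subs) {
  chars <- strsplit(s, "")[[1]]
  pos <- sample(length(chars), n_subs)
  for (p in pos) chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  paste(chars, collapse = "")
}

# a transcript_set built by hand
manual_reference <- function(seqs, taxon = "host", polyA = TRUE,
                             weight = 1, group = NA_character_,
                             ids = sprintf("ref_%03d", seq_along(seqs))) {
  ref <- data.frame(id = ids, taxon = taxon, gene_group = group,
                    sequence = seqs, length = nchar(seqs),
                    abundance_weight = weight, polyadenylated = polyA,
                    stringsAsFactors = FALSE)
  class(ref) <- c("transcript_set", "data.frame")
  ref
}

# a contig_set from bare sequences
manual_contigs <- function(seqs, ids = sprintf("ctg_%03d", seq_along(seqs)),
                           sample = "S1") {
  contig_set(id = ids, sequence = seqs, sample = sample)
}
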