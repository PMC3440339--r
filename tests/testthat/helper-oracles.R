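# Independent brute-force oracles used to validate the optimised
# implementations on small instances. Each oracle is written as directly
# as possible from the definition it checks.

rc_oracle <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# canonical k-mer multiset of a read set, by direct dictionary counting
oracle_kmer_counts <- function(reads, k) {
  tab <- new.env(parent = emptyenv())
  for (r in reads) {
    n <- nchar(r)
    if (n < k) next
    for (i in 1:(n - k + 1)) {
      km <- substr(r, i, i + k - 1)
      rc <- rc_oracle(km)
      can <- if (km <= rc) km else rc
      tab[[can]] <- (tab[[can]] %||% 0L) + 1L
    }
  }
  keys <- sort(ls(tab), method = "radix")
  data.frame(kmer = keys,
             count = vapply(keys, function(x) tab[[x]], integer(1),
                            USE.NAMES = FALSE),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force unitig finder: walk the maximal unambiguous path through
# every oriented node, spell it, deduplicate by canonical sequence
oracle_unitigs <- function(graph, min_len = 0) {
  n <- nrow(graph$nodes)
  if (n == 0) return(character(0))
  succ <- vector("list", 2 * n) # [[2*u - o]] with o in {1 (fwd), 0 (rev)}
  key <- function(u, o) 2L * u - o
  add <- function(u, uo, v, vo) {
    k <- key(u, uo)
    succ[[k]] <<- unique(rbind(succ[[k]], c(v, vo)))
  }
  e <- graph$edges
  for (i in seq_len(nrow(e))) {
    add(e$from[i], as.integer(e$from_fwd[i]), e$to[i], as.integer(e$to_fwd[i]))
    add(e$to[i], 1L - as.integer(e$to_fwd[i]),
        e$from[i], 1L - as.integer(e$from_fwd[i]))
  }
  one_succ <- function(u, o) {
    s <- succ[[key(u, o)]]
    if (is.null(s) || nrow(s) != 1) NULL else s[1, ]
  }
  spell <- function(path) { # rows (node, orient)
    k <- graph$k
    s <- ""
    for (i in seq_len(nrow(path))) {
      km <- graph$nodes$kmer[path[i, 1]]
      if (path[i, 2] == 0) km <- rc_oracle(km)
      s <- if (i == 1) km else paste0(s, substr(km, k, k))
    }
    rc <- rc_oracle(s)
    if (s <= rc) s else rc
  }
  seqs <- character(0)
  for (u in seq_len(n)) {
    for (o in c(1L, 0L)) {
      path <- matrix(c(u, o), ncol = 2)
      repeat { # extend forward while unambiguous both ways
        nx <- one_succ(path[nrow(path), 1], path[nrow(path), 2])
        if (is.null(nx)) break
        if (is.null(one_succ(nx[1], 1L - nx[2]))) break
        if (nx[1] %in% path[, 1]) break
        path <- rbind(path, nx)
      }
      repeat { # extend backward
        pv <- one_succ(path[1, 1], 1L - path[1, 2])
        if (is.null(pv)) break
        if (is.null(one_succ(pv[1], 1L - pv[2]))) break
        if (pv[1] %in% path[, 1]) break
        path <- rbind(c(pv[1], 1L - pv[2]), path)
      }
      seqs <- c(seqs, spell(path))
    }
  }
  seqs <- unique(seqs)
  sort(seqs[nchar(seqs) >= min_len], method = "radix")
}

# O(n^2) greedy clustering without the word filter, same order and
# identity rule as deplete()
oracle_cluster <- function(contigs, threshold = 0.95) {
  ord <- order(-contigs$length, contigs$id, method = "radix")
  x <- contigs[ord, , drop = FALSE]
  reps <- integer(0)
  assign_to <- integer(nrow(x))
  for (i in seq_len(nrow(x))) {
    assigned <- FALSE
    for (ci in seq_along(reps)) {
      idn <- multikc:::pair_identity(x$sequence[i], x$sequence[reps[ci]])
      if (idn >= threshold) { assign_to[i] <- ci; assigned <- TRUE; break }
    }
    if (!assigned) { reps <- c(reps, i); assign_to[i] <- length(reps) }
  }
  list(representatives = x$id[reps],
       membership = data.frame(member_id = x$id,
                               representative_id = x$id[reps[assign_to]],
                               stringsAsFactors = FALSE))
}

# exhaustive best-placement scan: every contig, position, strand
oracle_map <- function(read_seqs, contigs, max_mm) {
  ctg <- contigs[order(contigs$id, method = "radix"), , drop = FALSE]
  char_rows <- lapply(ctg$sequence, function(s) strsplit(s, "")[[1]])
  out <- data.frame(contig_id = NA_character_, position = NA_integer_,
                    strand = NA_character_, mismatches = NA_integer_,
                    stringsAsFactors = FALSE)[rep(1, length(read_seqs)), ]
  rownames(out) <- NULL
  for (r in seq_along(read_seqs)) {
    best <- NULL
    for (strand in c("+", "-")) {
      s <- if (strand == "+") read_seqs[r] else rc_oracle(read_seqs[r])
      sc <- strsplit(s, "")[[1]]
      L <- length(sc)
      for (c in seq_len(nrow(ctg))) {
        cc <- char_rows[[c]]
        if (length(cc) < L) next
        for (start in 1:(length(cc) - L + 1)) {
          mm <- sum(sc != cc[start:(start + L - 1)])
          if (mm > max_mm) next
          cand <- list(mm = mm, c = c, pos = start, strand = strand)
          if (is.null(best) ||
              mm < best$mm ||
              (mm == best$mm && (c < best$c ||
                (c == best$c && (start < best$pos ||
                  (start == best$pos && strand == "+" &&
                   best$strand == "-")))))) {
            best <- cand
          }
        }
      }
    }
    if (!is.null(best)) {
      out$contig_id[r] <- ctg$id[best$c]
      out$position[r] <- best$pos
      out$strand[r] <- best$strand
      out$mismatches[r] <- best$mm
    }
  }
  out
}

oracle_n50 <- function(lengths) {
  ls <- sort(lengths, decreasing = TRUE)
  tot <- sum(ls)
  for (L in ls) {
    if (sum(ls[ls >= L]) >= tot / 2) return(L)
  }
  ls[length(ls)]
}
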