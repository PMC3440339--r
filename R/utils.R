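# small shared helpers; exported where users plausibly need them

#' Reverse complement of nucleotide strings
#'
#' @param x character vector of sequences over A/C/G/T (other characters are
#'   complemented to N).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  vapply(x, function(s) {
    chartr("ACGTacgt", "TGCAtgca",
           paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

# lexicographically canonical orientation (used for k-mers and contigs)
canonical_seq <- function(x) {
  rc <- revcomp(x)
  ifelse(x <= rc, x, rc)
}

# parameter validation helper: all errors name the offending field
check_that <- function(ok, field, msg) {
  if (!isTRUE(ok)) stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

is_count <- function(x) length(x) == 1 && is.numeric(x) && !is.na(x) &&
  x >= 0 && x == floor(x)

# byte-wise (C locale) string ordering, independent of the session locale,
# so greedy tie-breaks and contig ids sort identically everywhere
c_order <- function(...) order(..., method = "radix")
c_sort <- function(x, decreasing = FALSE) sort(x, decreasing = decreasing,
                                               method = "radix")

# sequences of a read set / contig set / transcript set as character vector
seqs_of <- function(x) {
  if (is.character(x)) return(x)
  if (is.data.frame(x) && "sequence" %in% names(x)) return(x$sequence)
  stop("cannot extract sequences from object of class ",
       paste(class(x), collapse = "/"))
}
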