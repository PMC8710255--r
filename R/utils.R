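# shared internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

# all k-length windows of a character scalar, in position order
seq_kmers <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  starts <- seq_len(n - k + 1L)
  substring(s, starts, starts + k - 1L)
}

# vectorised reverse complement on plain character (IUPAC codes handled)
revcomp_chr <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

as_seq_string <- function(x) {
  if (inherits(x, "XString") || inherits(x, "XStringSet")) {
    x <- as.character(x)
  }
  toupper(unname(x))
}

is_count1 <- function(x) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x >= 1 && x == as.integer(x)
}
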