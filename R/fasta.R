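# FASTA readers/writers and the ***-separated multi-reference protein format

# IUPAC nucleotide codes (ambiguity allowed); protein letters incl. ambiguity
# codes, selenocysteine/pyrrolysine and '*' as stop
.NUC_RE <- "^[ACGTURYSWKMBDHVN]+$"
.PROT_RE <- "^[ACDEFGHIKLMNPQRSTVWYBJZXUO*]+$"

#' Read a (multi-)FASTA file
#'
#' Reads nucleotide or protein FASTA into a [Biostrings::DNAStringSet] /
#' [Biostrings::AAStringSet]. Record ids are the first whitespace-delimited
#' token of each header; the full header is kept in `mcols(x)$description`.
#' Sequences are uppercased. Duplicate ids are rejected because ids key all
#' downstream joins.
#'
#' @param path Path to a FASTA file.
#' @param alphabet `"nucleotide"` or `"protein"`; records are validated
#'   against the corresponding IUPAC letter set (ambiguity codes allowed,
#'   `*` permitted as a protein stop).
#' @return A `DNAStringSet` (nucleotide) or `AAStringSet` (protein), named
#'   by record id, in file order.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">c1 a contig", "ACGT"), fa)
#' read_fasta(fa)
read_fasta <- function(path, alphabet = c("nucleotide", "protein")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path, call. = FALSE)
  }
  raw <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) {
      stop("not FASTA-formatted: ", path, " (", conditionMessage(e), ")",
           call. = FALSE)
    }
  )
  if (length(raw) == 0L) {
    stop("no FASTA records ('>' headers) found in ", path, call. = FALSE)
  }
  seqs <- toupper(as.character(raw))
  headers <- names(raw)
  ids <- sub("\\s.*$", "", headers)
  if (any(!nzchar(ids))) {
    stop("empty record id (header line ", which(!nzchar(ids))[1L],
         ") in ", path, call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop("duplicate record id '", ids[duplicated(ids)][1L], "' in ", path,
         call. = FALSE)
  }
  if (any(!nzchar(seqs))) {
    stop("record '", ids[!nzchar(seqs)][1L], "' has an empty sequence",
         call. = FALSE)
  }
  re <- if (alphabet == "nucleotide") .NUC_RE else .PROT_RE
  bad <- !grepl(re, seqs)
  if (any(bad)) {
    stop("record '", ids[bad][1L], "' contains characters illegal for the ",
         alphabet, " alphabet", call. = FALSE)
  }
  out <- if (alphabet == "nucleotide") {
    Biostrings::DNAStringSet(chartr("U", "T", seqs))
  } else {
    Biostrings::AAStringSet(seqs)
  }
  names(out) <- ids
  S4Vectors::mcols(out)$description <- headers
  out
}

#' Write sequences to FASTA
#'
#' @param x A named `XStringSet` (or named character vector of sequences).
#' @param path Output path.
#' @param width Line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70L) {
  if (is.character(x)) x <- Biostrings::BStringSet(x)
  Biostrings::writeXStringSet(x, filepath = path, width = width)
  invisible(path)
}

#' Read ***-separated multi-reference protein CDS sets
#'
#' One amino-acid FASTA file can carry the CDS sets of several references,
#' with consecutive references separated by a line of three or more
#' asterisks (`***`) and nothing else. Records between separators belong to
#' one reference, in file order.
#'
#' @param path Path to the protein FASTA file.
#' @param n_expected Expected number of reference sets; a mismatch is an
#'   error reporting both counts.
#' @return A list of `AAStringSet`, one per reference, in file order.
#' @export
read_protein_reference_sets <- function(path, n_expected) {
  stopifnot(is_count1(n_expected))
  if (!file.exists(path)) {
    stop("protein FASTA file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  is_sep <- grepl("^\\*{3,}$", trimws(lines))
  chunk <- cumsum(is_sep) + 1L
  n_sets <- max(chunk)
  if (n_sets != n_expected) {
    stop("protein reference set count mismatch: file has ", n_sets,
         " set(s) but ", n_expected, " reference(s) were provided",
         call. = FALSE)
  }
  sets <- vector("list", n_sets)
  for (i in seq_len(n_sets)) {
    body <- lines[chunk == i & !is_sep]
    body <- body[nzchar(trimws(body))]
    if (length(body) == 0L || !any(startsWith(body, ">"))) {
      stop("empty protein set between separators (set ", i, ") in ", path,
           call. = FALSE)
    }
    tmp <- tempfile(fileext = ".faa")
    on.exit(unlink(tmp), add = TRUE)
    writeLines(body, tmp)
    sets[[i]] <- read_fasta(tmp, alphabet = "protein")
  }
  all_ids <- unlist(lapply(sets, names), use.names = FALSE)
  if (anyDuplicated(all_ids)) {
    stop("CDS id '", all_ids[duplicated(all_ids)][1L],
         "' appears in more than one reference set; ids must be unique ",
         "across the run", call. = FALSE)
  }
  sets
}
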