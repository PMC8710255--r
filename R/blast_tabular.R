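# BLAST tabular HSP I/O and the HSP table container

.HSP_COLS <- c("contig_id", "ref_id", "gene_id", "pident", "align_len",
               "q_start", "q_end", "s_start", "s_end", "evalue", "bitscore",
               "frame", "qseq_aa", "sseq_aa")

#' Construct/validate an HSP table
#'
#' HSPs (BLASTx high-scoring segment pairs) are carried as a data frame with
#' columns `contig_id`, `ref_id`, `gene_id`, `pident`, `align_len`,
#' `q_start`, `q_end` (1-based inclusive nucleotide positions on the contig,
#' `q_start <= q_end` regardless of strand), `s_start`, `s_end` (positions
#' on the subject protein), `evalue`, `bitscore`, `frame` (in
#' -3..-1, 1..3) and the aligned strings `qseq_aa`/`sseq_aa` (may be empty).
#'
#' @param df A data frame with (at least) the columns above; `ref_id`,
#'   `qseq_aa`, `sseq_aa` default to `NA`/`""` when missing.
#' @return The validated data frame with columns in canonical order.
#' @export
hsp_table <- function(df) {
  stopifnot(is.data.frame(df))
  if (is.null(df$ref_id)) df$ref_id <- rep(NA_character_, nrow(df))
  if (is.null(df$qseq_aa)) df$qseq_aa <- rep("", nrow(df))
  if (is.null(df$sseq_aa)) df$sseq_aa <- rep("", nrow(df))
  missing <- setdiff(.HSP_COLS, names(df))
  if (length(missing)) {
    stop("HSP table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df <- df[, .HSP_COLS]
  if (nrow(df)) {
    if (any(df$q_start > df$q_end)) {
      stop("HSP table has q_start > q_end", call. = FALSE)
    }
    if (any(df$align_len < 1L)) stop("align_len must be >= 1", call. = FALSE)
    if (any(!df$frame %in% c(-3:-1, 1:3))) {
      stop("frame must be in -3..-1, 1..3", call. = FALSE)
    }
    has_both <- nzchar(df$qseq_aa) & nzchar(df$sseq_aa)
    if (any(nchar(df$qseq_aa[has_both]) != nchar(df$sseq_aa[has_both]))) {
      stop("qseq_aa and sseq_aa must have equal length when both present",
           call. = FALSE)
    }
  }
  rownames(df) <- NULL
  df
}

#' Read BLAST tabular output into an HSP table
#'
#' Parses the tab-separated dialect
#' `qseqid sseqid pident length qstart qend sstart send evalue bitscore
#' qframe [qseq sseq]` (11 or 13 columns); `#`-prefixed comment lines are
#' tolerated as in BLAST outfmt 7. When a raw line has `qstart > qend`
#' (the BLASTx minus-strand convention) the two are swapped — orientation is
#' carried by the sign of the frame.
#'
#' `ref_id` is left `NA`: the tabular format names only the subject CDS, and
#' the owning reference is assigned later from the protein reference sets
#' (see [assign_references()]).
#'
#' @param path Path to the tabular file.
#' @return An HSP table (see [hsp_table()]) in file order.
#' @export
read_blast_tabular <- function(path) {
  if (!file.exists(path)) {
    stop("BLAST tabular file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  lineno <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  ncols <- lengths(fields)
  bad <- which(!(ncols %in% c(11L, 13L)))
  if (length(bad)) {
    stop("line ", lineno[bad[1L]], ": expected 11 or 13 tab-separated ",
         "columns, found ", ncols[bad[1L]], call. = FALSE)
  }
  n <- length(fields)
  if (n == 0L) {
    return(hsp_table(data.frame(contig_id = character(), gene_id = character(),
                                pident = numeric(), align_len = integer(),
                                q_start = integer(), q_end = integer(),
                                s_start = integer(), s_end = integer(),
                                evalue = numeric(), bitscore = numeric(),
                                frame = integer())))
  }
  num <- function(col, what, integer = FALSE) {
    x <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", col)))
    if (anyNA(x)) {
      stop("line ", lineno[which(is.na(x))[1L]], ": non-numeric ", what,
           " field", call. = FALSE)
    }
    if (integer) as.integer(x) else x
  }
  qstart <- num(5L, "qstart", integer = TRUE)
  qend <- num(6L, "qend", integer = TRUE)
  flip <- qstart > qend
  df <- data.frame(
    contig_id = vapply(fields, `[[`, "", 1L),
    ref_id = NA_character_,
    gene_id = vapply(fields, `[[`, "", 2L),
    pident = num(3L, "pident"),
    align_len = num(4L, "length", integer = TRUE),
    q_start = ifelse(flip, qend, qstart),
    q_end = ifelse(flip, qstart, qend),
    s_start = num(7L, "sstart", integer = TRUE),
    s_end = num(8L, "send", integer = TRUE),
    evalue = num(9L, "evalue"),
    bitscore = num(10L, "bitscore"),
    frame = num(11L, "qframe", integer = TRUE),
    qseq_aa = if (all(ncols == 13L)) vapply(fields, `[[`, "", 12L) else "",
    sseq_aa = if (all(ncols == 13L)) vapply(fields, `[[`, "", 13L) else "",
    stringsAsFactors = FALSE
  )
  hsp_table(df)
}

#' Write an HSP table as BLAST tabular
#'
#' Inverse of [read_blast_tabular()]: minus-frame rows are written with
#' `qstart > qend`, mimicking BLASTx.
#'
#' @param hsps An HSP table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_blast_tabular <- function(hsps, path) {
  hsps <- hsp_table(hsps)
  qs <- ifelse(hsps$frame < 0, hsps$q_end, hsps$q_start)
  qe <- ifelse(hsps$frame < 0, hsps$q_start, hsps$q_end)
  with_seqs <- any(nzchar(hsps$qseq_aa) | nzchar(hsps$sseq_aa))
  cols <- list(hsps$contig_id, hsps$gene_id, formatC(hsps$pident, format = "fg"),
               hsps$align_len, qs, qe, hsps$s_start, hsps$s_end,
               format(hsps$evalue, scientific = TRUE, digits = 3, trim = TRUE),
               formatC(hsps$bitscore, format = "fg"), hsps$frame)
  if (with_seqs) cols <- c(cols, list(hsps$qseq_aa, hsps$sseq_aa))
  writeLines(do.call(paste, c(cols, sep = "\t")), path)
  invisible(path)
}

#' Assign each HSP to the reference owning its subject CDS
#'
#' @param hsps An HSP table (typically with `ref_id` still `NA`).
#' @param protein_sets Named list of `AAStringSet`, one per reference, as
#'   returned by [read_protein_reference_sets()] (names = reference ids).
#' @return The HSP table with `ref_id` filled in.
#' @export
assign_references <- function(hsps, protein_sets) {
  hsps <- hsp_table(hsps)
  stopifnot(is.list(protein_sets), !is.null(names(protein_sets)))
  map <- rep(names(protein_sets), vapply(protein_sets, length, 0L))
  names(map) <- unlist(lapply(protein_sets, names), use.names = FALSE)
  unknown <- setdiff(unique(hsps$gene_id), names(map))
  if (length(unknown)) {
    stop("subject CDS id(s) not found in any protein reference set: ",
         paste(head(unknown, 3L), collapse = ", "), call. = FALSE)
  }
  hsps$ref_id <- unname(map[hsps$gene_id])
  hsps
}
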