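# Plain-text gene reports: .sorted (pre-M, all pairs) and .regsp (post-M,
# valid pairs only). The block layout is frozen by golden-file tests:
#   header comments, then per (contig, reference) block:
#     "## contig: <id> | reference: <id> | gene_count: <n>"   (a, b)
#     per gene, best score first:
#       "> gene: <id>"                                        (c)
#       "  query_nt: <plus-strand slice or .>"                (d)
#       "  hit: q_start=.. q_end=.. align_len=.. bitscore=.. evalue=.. frame=.." (e)
#       "  query_aa: <aligned query or .>"                    (f)
#       "  sbjct_aa: <aligned subject or .>"

#' Write a gene-search report file
#'
#' Stage `"sorted"` includes every reported contig/reference pair (the
#' state before the minimum-count filter `M`); stage `"regsp"` keeps only
#' pairs valid under `M`. Within a block genes appear in descending
#' bit-score order; blocks follow the report order (references in input
#' order).
#'
#' @param reports List of `contig_report` objects from [run_gene_search()].
#' @param stage `"sorted"` or `"regsp"`.
#' @param path Output path.
#' @param queries Optional named `DNAStringSet`/character vector of contig
#'   sequences; when given, the matched query nucleotide subsequence
#'   (plus-strand slice) is printed for each gene, otherwise `"."`.
#' @param params Optional [search_params()] echoed in the header.
#' @param source Optional string naming the HSP provenance, echoed in the
#'   header.
#' @return `path`, invisibly.
#' @export
write_report <- function(reports, stage = c("sorted", "regsp"), path,
                         queries = NULL, params = NULL, source = NULL) {
  stage <- match.arg(stage)
  if (stage == "regsp") {
    reports <- Filter(function(r) isTRUE(r$valid), reports)
  }
  qseqs <- if (!is.null(queries)) {
    vapply(as.list(queries), as_seq_string, "")
  }
  lines <- c(
    "# gene search report",
    sprintf("# stage: %s (%s)", stage,
            if (stage == "sorted") "pre-M filter; all contig/reference pairs"
            else "post-M filter; valid pairs only"),
    if (!is.null(params)) sprintf("# parameters: N=%d M=%d", params$N, params$M),
    if (!is.null(source)) sprintf("# hsp source: %s", source),
    sprintf("# blocks: %d", length(reports))
  )
  for (r in reports) {
    lines <- c(lines, "",
               sprintf("## contig: %s | reference: %s | gene_count: %d",
                       r$contig_id, r$ref_id, r$subgene_count))
    s <- r$surviving
    for (i in seq_len(nrow(s))) {
      nt <- "."
      if (!is.null(qseqs) && r$contig_id %in% names(qseqs)) {
        nt <- substr(qseqs[[r$contig_id]], s$q_start[i], s$q_end[i])
      }
      lines <- c(lines,
        sprintf("> gene: %s", s$gene_id[i]),
        sprintf("  query_nt: %s", nt),
        sprintf("  hit: q_start=%d q_end=%d align_len=%d bitscore=%s evalue=%s frame=%+d",
                s$q_start[i], s$q_end[i], s$align_len[i],
                formatC(s$bitscore[i], format = "fg"),
                format(s$evalue[i], scientific = TRUE, digits = 3, trim = TRUE),
                s$frame[i]),
        sprintf("  query_aa: %s",
                if (nzchar(s$qseq_aa[i])) s$qseq_aa[i] else "."),
        sprintf("  sbjct_aa: %s",
                if (nzchar(s$sseq_aa[i])) s$sseq_aa[i] else "."))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Count report blocks in a written report file
#'
#' @param path Path to a `.sorted`/`.regsp` file.
#' @return Data frame `contig_id`, `ref_id`, `gene_count`, one row per
#'   block, in file order.
#' @export
read_report_blocks <- function(path) {
  lines <- grep("^## contig: ", readLines(path, warn = FALSE), value = TRUE)
  m <- regmatches(lines,
    regexec("^## contig: (\\S+) \\| reference: (\\S+) \\| gene_count: (\\d+)$",
            lines))
  data.frame(contig_id = vapply(m, `[`, "", 2L),
             ref_id = vapply(m, `[`, "", 3L),
             gene_count = as.integer(vapply(m, `[`, "", 4L)),
             stringsAsFactors = FALSE)
}
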