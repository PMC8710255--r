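# Gene-search core: overlap grouping, per-group N-1 cap, M validation.
# BLAST 1-based inclusive query coordinates come in from the formats layer;
# interval arithmetic here treats [q_start, q_end] as closed, so two hits
# overlap iff they share at least one base.

#' Gene-search parameters N and M
#'
#' @param N Maximum number of matched BLAST hits per group; a group keeps at
#'   most `N - 1` hits. Natural number >= 1.
#' @param M Minimum sub-gene count per contig: a contig/reference pair is
#'   valid only when at least `M` hits survive the group cap. Natural
#'   number >= 1.
#' @return An object of class `search_params`.
#' @export
search_params <- function(N, M) {
  if (!is_count1(N) || !is_count1(M)) {
    stop("N and M must be natural numbers (>= 1)", call. = FALSE)
  }
  if (N == 1L) {
    warning("N = 1 allows 0 hits per group (N - 1): every group is emptied ",
            "and no contig can be valid", call. = FALSE)
  }
  structure(list(N = as.integer(N), M = as.integer(M)),
            class = "search_params")
}

#' @export
print.search_params <- function(x, ...) {
  cat("gene-search parameters: N =", x$N, "(max", x$N - 1L,
      "hits/group), M =", x$M, "(min sub-gene count)\n")
  invisible(x)
}

# rank of HSP rows inside a group or report: descending bitscore, ties by
# ascending E-value, then descending align_len, then input order (.row)
.hsp_rank_order <- function(df) {
  order(-df$bitscore, df$evalue, -df$align_len, df$.row)
}

.with_row_index <- function(hsps) {
  if (is.null(hsps$.row)) hsps$.row <- seq_len(nrow(hsps))
  hsps
}

#' Form overlap groups of HSPs on one contig/reference pair
#'
#' A group is a maximal set of HSPs whose query nucleotide intervals are
#' connected by pairwise overlap (shared length >= 1 base): the connected
#' components of the interval-overlap graph. Every HSP lands in exactly one
#' group; the query spans of different groups are pairwise disjoint.
#'
#' @param hsps An HSP table whose rows all share one `contig_id` and one
#'   `ref_id`.
#' @return A list of groups, each a list with `contig_id`, `ref_id`,
#'   `members` (HSP rows in input order) and `q_span` (`c(start, end)`).
#' @export
find_groups <- function(hsps) {
  rows <- .with_row_index(hsps)$.row
  hsps <- hsp_table(hsps)
  hsps$.row <- rows
  if (nrow(hsps) == 0L) return(list())
  if (length(unique(hsps$contig_id)) > 1L ||
      length(unique(as.character(hsps$ref_id))) > 1L) {
    stop("find_groups expects HSPs of a single (contig, reference) pair",
         call. = FALSE)
  }
  ord <- order(hsps$q_start, hsps$q_end)
  starts <- hsps$q_start[ord]
  ends <- hsps$q_end[ord]
  # sweep: a new component starts where an interval begins past the running
  # max end (closed intervals: touching positions still overlap)
  prev_max <- cummax(ends)
  comp <- cumsum(c(TRUE, starts[-1L] > prev_max[-length(prev_max)]))
  group_of <- integer(nrow(hsps))
  group_of[ord] <- comp
  lapply(seq_len(max(comp)), function(g) {
    members <- hsps[group_of == g, , drop = FALSE]
    members <- members[order(members$.row), , drop = FALSE]
    rownames(members) <- NULL
    list(contig_id = members$contig_id[1L],
         ref_id = members$ref_id[1L],
         members = members,
         q_span = c(min(members$q_start), max(members$q_end)))
  })
}

#' Cap a group at N - 1 hits
#'
#' When a group holds more than `N - 1` HSPs, only the top `N - 1` by rank
#' survive (descending bitscore; ties broken by ascending E-value, then
#' descending alignment length, then input order). `N = 1` legally yields an
#' empty survivor set.
#'
#' @param group A group as returned by [find_groups()].
#' @param N The group-cap parameter.
#' @return Surviving HSP rows, sorted by rank.
#' @export
cap_group <- function(group, N) {
  stopifnot(is_count1(N))
  m <- group$members
  keep <- min(nrow(m), as.integer(N) - 1L)
  out <- m[.hsp_rank_order(m), , drop = FALSE][seq_len(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Evaluate one contig against one reference
#'
#' Groups the pair's HSPs, applies the per-group `N - 1` cap, counts the
#' survivors (the sub-gene count) and checks validity against `M`.
#'
#' @param hsps HSP table rows of a single (contig, reference) pair.
#' @param params A [search_params()] object.
#' @return A `contig_report`: list with `contig_id`, `ref_id`, `surviving`
#'   (HSP rows sorted by descending bitscore), `subgene_count` and `valid`.
#' @export
evaluate_contig <- function(hsps, params) {
  stopifnot(inherits(params, "search_params"))
  groups <- find_groups(hsps)
  if (length(groups) == 0L) {
    stop("evaluate_contig needs at least one HSP", call. = FALSE)
  }
  caps <- lapply(groups, cap_group, N = params$N)
  surviving <- do.call(rbind, c(caps, list(make.row.names = FALSE)))
  surviving <- surviving[.hsp_rank_order(surviving), , drop = FALSE]
  rownames(surviving) <- NULL
  n <- nrow(surviving)
  structure(list(contig_id = groups[[1L]]$contig_id %||% NA_character_,
                 ref_id = groups[[1L]]$ref_id %||% NA_character_,
                 surviving = surviving,
                 subgene_count = n,
                 valid = n >= params$M),
            class = "contig_report")
}

#' Run the gene search over all contig/reference pairs
#'
#' Splits an HSP table by (reference, contig) and evaluates each pair with
#' [evaluate_contig()]. Pairs with no HSP yield no report. Reports are
#' ordered by reference, then contig (given orders, or order of first
#' appearance in `hsps`).
#'
#' @param hsps An HSP table spanning any number of contigs and references
#'   (with `ref_id` assigned).
#' @param params A [search_params()] object.
#' @param contig_order,ref_order Optional id vectors fixing the block order
#'   of the reports (e.g. FASTA input order).
#' @return A list of `contig_report` objects.
#' @export
run_gene_search <- function(hsps, params, contig_order = NULL,
                            ref_order = NULL) {
  hsps <- hsp_table(hsps)
  hsps$.row <- seq_len(nrow(hsps))
  stopifnot(inherits(params, "search_params"))
  if (nrow(hsps) == 0L) return(list())
  if (anyNA(hsps$ref_id)) {
    stop("HSPs must have ref_id assigned (see assign_references())",
         call. = FALSE)
  }
  contigs <- contig_order %||% unique(hsps$contig_id)
  refs <- ref_order %||% unique(hsps$ref_id)
  reports <- list()
  for (r in refs) {
    for (ct in contigs) {
      rows <- hsps[hsps$ref_id == r & hsps$contig_id == ct, , drop = FALSE]
      if (nrow(rows) == 0L) next
      reports[[length(reports) + 1L]] <- evaluate_contig(rows, params)
    }
  }
  reports
}

#' Summarise gene-search reports as a data frame
#'
#' @param reports A list of `contig_report` objects from
#'   [run_gene_search()].
#' @return A data frame with `contig_id`, `ref_id`, `subgene_count`,
#'   `valid`, one row per reported pair.
#' @export
report_summary <- function(reports) {
  data.frame(
    contig_id = vapply(reports, `[[`, "", "contig_id"),
    ref_id = vapply(reports, `[[`, "", "ref_id"),
    subgene_count = vapply(reports, `[[`, 0L, "subgene_count"),
    valid = vapply(reports, `[[`, NA, "valid"),
    stringsAsFactors = FALSE
  )
}

#' @export
print.contig_report <- function(x, ...) {
  cat(sprintf("contig %s vs reference %s: %d sub-gene hit(s), %s\n",
              x$contig_id, x$ref_id, x$subgene_count,
              if (x$valid) "valid" else "invalid"))
  invisible(x)
}
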