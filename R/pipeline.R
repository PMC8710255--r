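# Pipeline driver: input validation, HSP acquisition (tabular file,
# built-in translated search, or external blastx), gene search, report
# writing, dot-plot rendering, logging.

#' Pipeline run configuration
#'
#' @param query Path to the query contig/scaffold multi-FASTA (nucleotide).
#'   May be `NULL` when running from a precomputed HSP table without the
#'   dot-plot branch.
#' @param ref_nt Path to the reference nucleotide FASTA / multi-FASTA (one
#'   record per reference). May be `NULL` in HSP-table-only runs.
#' @param ref_aa Path to the reference protein CDS FASTA, consecutive
#'   references separated by a `***` line. Required for the
#'   `minisearch`/`external-blastx` sources.
#' @param N,M Gene-search parameters (see [search_params()]).
#' @param k k-mer size for the dot plot, 10-30 (default 13).
#' @param hsp_source One of `"minisearch"` (built-in translated search),
#'   `"tabular-file"` (precomputed BLAST tabular), `"external-blastx"`
#'   (invoke a `blastx` executable on the PATH).
#' @param hsp_table Path to the BLAST tabular file
#'   (`hsp_source = "tabular-file"`).
#' @param out_dir Output directory (created if needed).
#' @param prefix Basename for output files (default `"run"`).
#' @param evalue_cutoff E-value cutoff passed to external blastx
#'   (default 1e-5).
#' @param show_all_matches Draw all merged dot-plot segments instead of the
#'   resolved (non-overlapping) selection.
#' @param plot_only Skip the gene search and only produce the dot plot.
#' @param minisearch Parameters for the built-in search
#'   (see [minisearch_params()]).
#' @return An object of class `run_config`.
#' @export
run_config <- function(query = NULL, ref_nt = NULL, ref_aa = NULL,
                       N = 4L, M = 4L, k = 13L,
                       hsp_source = c("minisearch", "tabular-file",
                                      "external-blastx"),
                       hsp_table = NULL, out_dir, prefix = "run",
                       evalue_cutoff = 1e-5, show_all_matches = FALSE,
                       plot_only = FALSE,
                       minisearch = minisearch_params()) {
  hsp_source <- match.arg(hsp_source)
  kp <- kmer_params(k)  # validates the 10-30 range
  sp <- if (!plot_only) search_params(N, M)
  if (plot_only && (is.null(query) || is.null(ref_nt))) {
    stop("plot-only mode needs both query and ref_nt FASTA files",
         call. = FALSE)
  }
  if (!plot_only && hsp_source == "tabular-file" && is.null(hsp_table)) {
    stop("hsp_source = 'tabular-file' needs hsp_table", call. = FALSE)
  }
  if (!plot_only && hsp_source %in% c("minisearch", "external-blastx") &&
      (is.null(query) || is.null(ref_aa))) {
    stop("hsp_source = '", hsp_source,
         "' needs query and ref_aa FASTA files", call. = FALSE)
  }
  structure(list(query = query, ref_nt = ref_nt, ref_aa = ref_aa,
                 params = sp, kmer = kp, hsp_source = hsp_source,
                 hsp_table = hsp_table, out_dir = out_dir, prefix = prefix,
                 evalue_cutoff = evalue_cutoff,
                 show_all_matches = isTRUE(show_all_matches),
                 plot_only = isTRUE(plot_only),
                 minisearch = minisearch),
            class = "run_config")
}

#' Warn about input scales beyond the recommended limits
#'
#' The pipeline stays usable, but plots get crowded past roughly 30 query
#' entries or with 10 or more references; both conditions raise warnings,
#' never errors.
#'
#' @param n_queries Number of query contig records.
#' @param n_references Number of reference sequences.
#' @return Character vector of warning messages (also raised as warnings);
#'   empty when within limits.
#' @export
validate_scale <- function(n_queries, n_references) {
  msgs <- character(0)
  if (n_queries > 30) {
    msgs <- c(msgs, sprintf(
      "%d query entries exceed the recommended maximum of 30; the dot plot may be crowded",
      n_queries))
  }
  if (n_references >= 10) {
    msgs <- c(msgs, sprintf(
      "%d references reach the recommended limit (fewer than 10); consider splitting the run",
      n_references))
  }
  for (m in msgs) warning(m, call. = FALSE)
  invisible(msgs)
}

.blastx_hsps <- function(query_path, protein_sets, evalue_cutoff, workdir) {
  blastx <- Sys.which("blastx")
  makedb <- Sys.which("makeblastdb")
  if (!nzchar(blastx) || !nzchar(makedb)) {
    stop("no blastx/makeblastdb executable found on the PATH; rerun with ",
         "hsp_source = 'tabular-file' (precomputed hits) or 'minisearch' ",
         "(built-in search)", call. = FALSE)
  }
  faa <- file.path(workdir, "refdb.faa")
  all_prot <- do.call(c, unname(protein_sets))
  Biostrings::writeXStringSet(all_prot, faa)
  db <- file.path(workdir, "refdb")
  st <- system2(makedb, c("-in", faa, "-dbtype", "prot", "-out", db),
                stdout = FALSE, stderr = FALSE)
  if (st != 0L) stop("makeblastdb failed", call. = FALSE)
  out <- file.path(workdir, "blastx.tsv")
  st <- system2(blastx,
    c("-query", query_path, "-db", db, "-evalue",
      format(evalue_cutoff, scientific = TRUE),
      "-outfmt",
      shQuote("6 qseqid sseqid pident length qstart qend sstart send evalue bitscore qframe qseq sseq"),
      "-out", out),
    stdout = FALSE, stderr = FALSE)
  if (st != 0L) stop("blastx run failed", call. = FALSE)
  read_blast_tabular(out)
}

#' Run the whole pipeline
#'
#' Reproduces the workflow end to end: read inputs, obtain HSPs per
#' contig/reference pair, apply the two-stage N/M gene search, write the
#' `.sorted` (pre-M) and `.regsp` (post-M) reports, build and render the
#' k-mer dot plot, and log a machine-readable per-pair summary.
#'
#' @param config A [run_config()] object.
#' @return Invisibly, a list with `out_dir`, `files` (named paths),
#'   `reports`, `summary` (data frame) and `layout` (or `NULL`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(config$out_dir)) {
    stop("cannot create output directory ", config$out_dir, call. = FALSE)
  }
  log_lines <- character(0)
  note <- function(...) {
    msg <- sprintf(...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }
  note("k-mer size: %d%s", config$kmer$k,
       if (config$kmer$k == 13L) " (default)" else "")
  queries <- if (!is.null(config$query)) {
    read_fasta(config$query, "nucleotide")
  }
  refs_nt <- if (!is.null(config$ref_nt)) {
    read_fasta(config$ref_nt, "nucleotide")
  }
  ref_ids <- if (!is.null(refs_nt)) names(refs_nt)
  protein_sets <- NULL
  if (!is.null(config$ref_aa)) {
    if (is.null(ref_ids)) {
      stop("ref_aa given without ref_nt: the nucleotide references define ",
           "the reference ids and count", call. = FALSE)
    }
    protein_sets <- tryCatch(
      read_protein_reference_sets(config$ref_aa, length(ref_ids)),
      error = function(e) {
        stop(conditionMessage(e), " [protein file: ", config$ref_aa,
             "; nucleotide file: ", config$ref_nt, "]", call. = FALSE)
      })
    names(protein_sets) <- ref_ids
  }
  if (!is.null(queries)) {
    validate_scale(length(queries), length(ref_ids %||% character(0)))
  }

  files <- list()
  reports <- NULL
  summary_df <- NULL
  if (!config$plot_only) {
    note("gene search parameters: N=%d M=%d", config$params$N,
         config$params$M)
    hsps <- switch(config$hsp_source,
      "tabular-file" = {
        h <- read_blast_tabular(config$hsp_table)
        if (!is.null(protein_sets)) {
          h <- assign_references(h, protein_sets)
        } else if (anyNA(h$ref_id)) {
          if (!is.null(ref_ids) && length(ref_ids) == 1L) {
            h$ref_id <- ref_ids
          } else {
            stop("cannot assign HSPs to references: provide ref_aa (CDS ",
                 "sets) or a single-reference run", call. = FALSE)
          }
        }
        h
      },
      "minisearch" = {
        note("HSP source: built-in translated search (word_size=%d, min_score=%d)",
             config$minisearch$word_size, config$minisearch$min_score)
        per_pair <- list()
        for (r in ref_ids) {
          for (ct in names(queries)) {
            per_pair[[length(per_pair) + 1L]] <-
              minisearch(queries[[ct]], protein_sets[[r]],
                         config$minisearch, contig_id = ct, ref_id = r)
          }
        }
        do.call(rbind, c(per_pair, list(make.row.names = FALSE)))
      },
      "external-blastx" = {
        note("HSP source: external blastx (evalue cutoff %g)",
             config$evalue_cutoff)
        h <- .blastx_hsps(config$query, protein_sets, config$evalue_cutoff,
                          config$out_dir)
        assign_references(h, protein_sets)
      })
    hsps <- hsp_table(hsps)
    note("HSPs obtained: %d", nrow(hsps))
    reports <- run_gene_search(hsps, config$params,
                               contig_order = if (!is.null(queries)) names(queries),
                               ref_order = ref_ids)
    summary_df <- report_summary(reports)
    note("contig/reference pairs reported: %d (%d valid under M)",
         nrow(summary_df), sum(summary_df$valid))
    src_label <- switch(config$hsp_source,
                        "tabular-file" = paste0("tabular file ", config$hsp_table),
                        "minisearch" = "built-in translated search (raw scores, not NCBI bitscores)",
                        "external-blastx" = "external blastx")
    files$sorted <- file.path(config$out_dir,
                              paste0(config$prefix, ".sorted"))
    files$regsp <- file.path(config$out_dir, paste0(config$prefix, ".regsp"))
    write_report(reports, "sorted", files$sorted, queries = queries,
                 params = config$params, source = src_label)
    write_report(reports, "regsp", files$regsp, queries = queries,
                 params = config$params, source = src_label)
    files$summary <- file.path(config$out_dir,
                               paste0(config$prefix, "_summary.json"))
    writeLines(vapply(seq_len(nrow(summary_df)), function(i) {
      jsonlite::toJSON(as.list(summary_df[i, ]), auto_unbox = TRUE)
    }, ""), files$summary)
  }

  layout <- NULL
  if (!is.null(queries) && !is.null(refs_nt)) {
    layout <- build_layout(queries, refs_nt, config$kmer,
                           resolve = !config$show_all_matches)
    files$cplot <- file.path(config$out_dir,
                             paste0(config$prefix, "_cplot.pdf"))
    render_pdf(layout, plot_style(), files$cplot)
    note("dot plot: %d panel(s) rendered to %s", length(layout$panels),
         files$cplot)
  } else if (!config$plot_only) {
    note("dot plot skipped: query and/or reference nucleotide FASTA not provided")
  }

  files$log <- file.path(config$out_dir, paste0(config$prefix, ".log"))
  writeLines(log_lines, files$log)
  invisible(list(out_dir = config$out_dir, files = files, reports = reports,
                 summary = summary_df, layout = layout))
}
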