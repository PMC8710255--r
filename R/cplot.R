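# cPlot engine: exact k-mer matching on both strands, diagonal-run merging,
# overlap resolution, contig ordering, and layout assembly.
# Coordinates in this module are 0-based half-open.

#' k-mer parameters for the dot plot
#'
#' @param k Word length for exact matching, between 10 and 30; default 13.
#' @return An object of class `kmer_params`.
#' @export
kmer_params <- function(k = 13L) {
  if (!(length(k) == 1L && is.numeric(k) && !is.na(k) && k == as.integer(k))) {
    stop("k-mer size must be a single integer", call. = FALSE)
  }
  if (k < 10 || k > 30) {
    stop("k-mer size must be between 10 and 30 (got ", k, ")", call. = FALSE)
  }
  structure(list(k = as.integer(k)), class = "kmer_params")
}

# 0-based start positions of ACGT-only k-mers, plus the k-mer strings
.clean_kmers <- function(s, k) {
  km <- seq_kmers(s, k)
  ok <- grepl("^[ACGT]+$", km)
  list(pos = which(ok) - 1L, kmer = km[ok])
}

#' Find exact shared k-mers between a contig and a reference
#'
#' Reports every pair of 0-based positions `(q_pos, r_pos)` where the
#' k-length query window equals the reference window (forward) or equals
#' the reverse complement of the reference window, i.e. matches the
#' reference read on the minus strand (reverse). The reference is indexed
#' once; windows containing ambiguity codes (N etc.) never match.
#'
#' @param query,reference Nucleotide sequences (character scalar or
#'   `DNAString`/length-1 `DNAStringSet`).
#' @param params A [kmer_params()] object.
#' @return A data frame with columns `q_pos`, `r_pos`, `orientation`
#'   (`"forward"`/`"reverse"`). Sequences shorter than k give an empty
#'   result with a warning.
#' @export
find_kmer_matches <- function(query, reference, params = kmer_params()) {
  stopifnot(inherits(params, "kmer_params"))
  k <- params$k
  q <- as_seq_string(query)
  r <- as_seq_string(reference)
  empty <- data.frame(q_pos = integer(), r_pos = integer(),
                      orientation = character(), stringsAsFactors = FALSE)
  if (nchar(q) < k || nchar(r) < k) {
    warning("sequence shorter than k = ", k, "; no k-mer matches possible",
            call. = FALSE)
    return(empty)
  }
  rk <- .clean_kmers(r, k)
  qk <- .clean_kmers(q, k)
  if (length(rk$pos) == 0L || length(qk$pos) == 0L) return(empty)
  index <- split(rk$pos, rk$kmer)

  expand <- function(keys, q_pos, orientation) {
    hits <- index[keys]
    n <- lengths(hits)
    n[is.na(names(hits))] <- 0L
    if (sum(n) == 0L) return(empty)
    data.frame(q_pos = rep(q_pos, n),
               r_pos = unlist(hits[n > 0L], use.names = FALSE),
               orientation = orientation, stringsAsFactors = FALSE)
  }
  fwd <- expand(qk$kmer, qk$pos, "forward")
  rev <- expand(revcomp_chr(qk$kmer), qk$pos, "reverse")
  out <- rbind(fwd, rev)
  out <- out[order(match(out$orientation, c("forward", "reverse")),
                   out$q_pos, out$r_pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge consecutive k-mer matches into diagonal segments
#'
#' Maximal runs of matches on one diagonal become one segment: forward runs
#' keep `r_pos - q_pos` constant while `q_pos` steps by +1; reverse
#' (anti-diagonal) runs keep `r_pos + q_pos` constant. A run of `L` matches
#' spans `L - 1 + k` bases.
#'
#' @param matches Match data frame from [find_kmer_matches()] (one
#'   contig/reference pair).
#' @param k The k-mer size used to find the matches.
#' @param contig_id,ref_id Ids stamped onto the segments.
#' @return A data frame of segments: `contig_id`, `ref_id`, `q_start`,
#'   `q_end`, `r_start`, `r_end` (0-based half-open), `orientation`,
#'   `length`.
#' @export
merge_matches <- function(matches, k, contig_id = NA_character_,
                          ref_id = NA_character_) {
  empty <- data.frame(contig_id = character(), ref_id = character(),
                      q_start = integer(), q_end = integer(),
                      r_start = integer(), r_end = integer(),
                      orientation = character(), length = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(matches) == 0L) return(empty)
  one_strand <- function(m, orientation) {
    if (nrow(m) == 0L) return(empty)
    diag <- if (orientation == "forward") m$r_pos - m$q_pos else m$r_pos + m$q_pos
    ord <- order(diag, m$q_pos)
    d <- diag[ord]; q <- m$q_pos[ord]; r <- m$r_pos[ord]
    new_run <- c(TRUE, d[-1L] != d[-length(d)] | q[-1L] != q[-length(q)] + 1L)
    run <- cumsum(new_run)
    qs <- tapply(q, run, min); qe <- tapply(q, run, max) + k
    rs <- tapply(r, run, min); re <- tapply(r, run, max) + k
    data.frame(contig_id = contig_id, ref_id = ref_id,
               q_start = as.integer(qs), q_end = as.integer(qe),
               r_start = as.integer(rs), r_end = as.integer(re),
               orientation = orientation,
               length = as.integer(qe - qs), stringsAsFactors = FALSE)
  }
  out <- rbind(one_strand(matches[matches$orientation == "forward", ], "forward"),
               one_strand(matches[matches$orientation == "reverse", ], "reverse"))
  out <- out[order(out$q_start, out$r_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Resolve overlapping candidate segments
#'
#' Candidate segments whose query intervals overlap form clusters (connected
#' components of query-interval overlap); within each cluster the longest
#' segment is kept, ties broken by smallest `r_start`, then forward before
#' reverse. Kept segments therefore have pairwise non-overlapping query
#' intervals. Scanning proceeds from the start of the reference, so the
#' result is returned in ascending `r_start` order.
#'
#' @param segments Segment data frame from [merge_matches()] (one
#'   contig/reference pair).
#' @return The kept segments, sorted by `r_start`.
#' @export
resolve_overlaps <- function(segments) {
  if (nrow(segments) <= 1L) return(segments)
  ord <- order(segments$q_start, segments$q_end)
  qs <- segments$q_start[ord]; qe <- segments$q_end[ord]
  # half-open intervals: overlap iff next start < running max end
  prev_max <- cummax(qe)
  comp <- cumsum(c(TRUE, qs[-1L] >= prev_max[-length(prev_max)]))
  cluster <- integer(nrow(segments))
  cluster[ord] <- comp
  pick <- vapply(seq_len(max(comp)), function(cl) {
    idx <- which(cluster == cl)
    s <- segments[idx, , drop = FALSE]
    best <- order(-s$length, s$r_start,
                  match(s$orientation, c("forward", "reverse")))[1L]
    idx[best]
  }, 0L)
  out <- segments[pick[order(segments$r_start[pick], segments$q_start[pick])], ,
                  drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Order contigs along the references
#'
#' Contigs are sorted by (index of the first reference in which they have
#' any segment, then `r_start` of their longest segment in that reference,
#' then input order); contigs with no segment anywhere are appended last in
#' input order.
#'
#' @param segments Data frame of (resolved) segments across all contigs and
#'   references.
#' @param contig_ids All contig ids in input order.
#' @param ref_ids Reference ids in input order.
#' @return Character vector: contig ids in display order.
#' @export
order_contigs <- function(segments, contig_ids, ref_ids) {
  key <- t(vapply(contig_ids, function(ct) {
    s <- segments[segments$contig_id == ct, , drop = FALSE]
    if (nrow(s) == 0L) return(c(Inf, Inf))
    ri <- min(match(s$ref_id, ref_ids))
    s1 <- s[s$ref_id == ref_ids[ri], , drop = FALSE]
    longest <- s1[order(-s1$length, s1$r_start)[1L], ]
    c(ri, longest$r_start)
  }, numeric(2)))
  contig_ids[order(key[, 1L], key[, 2L], seq_along(contig_ids))]
}

#' Build a multi-panel dot-plot layout
#'
#' Runs find -> merge -> resolve for every (contig, reference) pair and
#' assembles one panel per reference, with a single global contig order
#' applied to the query axis (cumulative offsets concatenate the contigs).
#'
#' @param queries Named `DNAStringSet` (or named character vector) of query
#'   contigs.
#' @param references Named `DNAStringSet` (or named character vector) of
#'   reference sequences.
#' @param params A [kmer_params()] object.
#' @param resolve Keep only resolved (non-overlapping) segments (default);
#'   `FALSE` keeps all merged segments.
#' @return A `dotplot_layout`: list with `panels` (per reference: `ref_id`,
#'   `ref_len`, `segments`), `contig_order`, `offsets` (0-based, named by
#'   contig), `query_lengths` and `k`.
#' @export
build_layout <- function(queries, references, params = kmer_params(),
                         resolve = TRUE) {
  stopifnot(inherits(params, "kmer_params"))
  qs <- vapply(as.list(queries), as_seq_string, "")
  rs <- vapply(as.list(references), as_seq_string, "")
  if (is.null(names(qs)) || is.null(names(rs))) {
    stop("queries and references must be named", call. = FALSE)
  }
  if (all(nchar(qs) < params$k) && all(nchar(rs) < params$k)) {
    warning("all sequences are shorter than k = ", params$k,
            "; the layout has empty panels", call. = FALSE)
  }
  all_segments <- list()
  panels <- vector("list", length(rs))
  names(panels) <- names(rs)
  for (r in names(rs)) {
    seg_r <- list()
    for (ct in names(qs)) {
      if (nchar(qs[[ct]]) < params$k || nchar(rs[[r]]) < params$k) next
      m <- find_kmer_matches(qs[[ct]], rs[[r]], params)
      seg <- merge_matches(m, params$k, contig_id = ct, ref_id = r)
      if (resolve) seg <- resolve_overlaps(seg)
      seg_r[[ct]] <- seg
    }
    segs <- if (length(seg_r)) {
      do.call(rbind, c(seg_r, list(make.row.names = FALSE)))
    } else {
      merge_matches(data.frame(q_pos = integer(), r_pos = integer(),
                               orientation = character()), params$k)
    }
    panels[[r]] <- list(ref_id = r, ref_len = nchar(rs[[r]]), segments = segs)
    all_segments[[r]] <- segs
  }
  segs_all <- do.call(rbind, c(all_segments, list(make.row.names = FALSE)))
  contig_order <- order_contigs(segs_all, names(qs), names(rs))
  lens <- nchar(qs)[contig_order]
  offsets <- c(0L, cumsum(as.integer(lens)))[seq_along(lens)]
  names(offsets) <- contig_order
  structure(list(panels = panels, contig_order = contig_order,
                 offsets = offsets, query_lengths = nchar(qs),
                 k = params$k),
            class = "dotplot_layout")
}

#' @export
print.dotplot_layout <- function(x, ...) {
  nseg <- sum(vapply(x$panels, function(p) nrow(p$segments), 0L))
  cat(sprintf("dot-plot layout: %d panel(s), %d contig(s), %d segment(s), k = %d\n",
              length(x$panels), length(x$contig_order), nseg, x$k))
  invisible(x)
}
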