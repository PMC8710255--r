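# Independent oracles and fixture generators used across the suite.
# These deliberately avoid the package's own algorithms: grouping is done by
# repeated pairwise merging, k-mer matching by exhaustive per-diagonal
# character comparison, translation by direct codon-table lookup.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_dna <- function(s, rate) {
  chars <- strsplit(s, "")[[1]]
  hit <- which(runif(length(chars)) < rate)
  for (i in hit) chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1)
  paste(chars, collapse = "")
}

revcomp_oracle <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

# translation by direct lookup in the standard codon table
oracle_translate <- function(s) {
  codons <- substring(s, seq(1, nchar(s) - 2, by = 3),
                      seq(3, nchar(s), by = 3))
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

# random HSP instance spanning 1-2 contigs and 1-2 references
random_hsp_instance <- function(n_max = 20L) {
  n <- sample.int(n_max, 1L)
  qs <- sample.int(600L, n, replace = TRUE)
  len <- sample(30:250, n, replace = TRUE)
  data.frame(
    contig_id = sample(c("c1", "c2"), n, replace = TRUE),
    ref_id = sample(c("r1", "r2"), n, replace = TRUE),
    gene_id = paste0("g", seq_len(n)),
    pident = round(runif(n, 40, 100), 1),
    align_len = as.integer(round(len / 3)),
    q_start = qs,
    q_end = qs + len,
    s_start = 1L,
    s_end = as.integer(round(len / 3)),
    evalue = 10^-round(runif(n, 1, 40)),
    # rounding makes score ties frequent, exercising the tie-break
    bitscore = round(runif(n, 5, 30)) * 10,
    frame = sample(c(-3:-1, 1:3), n, replace = TRUE),
    qseq_aa = "", sseq_aa = "",
    stringsAsFactors = FALSE
  )
}

# gene search by exhaustive pairwise merging (transitive closure)
oracle_gene_search <- function(hsps, N, M) {
  hsps$.row <- seq_len(nrow(hsps))
  out <- list()
  for (r in unique(hsps$ref_id)) {
    for (ct in unique(hsps$contig_id)) {
      h <- hsps[hsps$ref_id == r & hsps$contig_id == ct, , drop = FALSE]
      if (nrow(h) == 0L) next
      comp <- seq_len(nrow(h))
      repeat {
        changed <- FALSE
        for (i in seq_len(nrow(h))) {
          for (j in seq_len(nrow(h))) {
            if (comp[i] != comp[j] &&
                h$q_start[i] <= h$q_end[j] && h$q_start[j] <= h$q_end[i]) {
              comp[comp == comp[j]] <- comp[i]
              changed <- TRUE
            }
          }
        }
        if (!changed) break
      }
      surv <- do.call(rbind, lapply(unique(comp), function(g) {
        mm <- h[comp == g, , drop = FALSE]
        mm <- mm[order(-mm$bitscore, mm$evalue, -mm$align_len, mm$.row), ,
                 drop = FALSE]
        utils::head(mm, max(0L, N - 1L))
      }))
      cnt <- if (is.null(surv)) 0L else nrow(surv)
      out[[paste(ct, r, sep = "|")]] <- list(
        contig_id = ct, ref_id = r,
        genes = sort(if (is.null(surv)) character(0) else surv$gene_id),
        group_sizes = sort(as.integer(table(comp))),
        count = cnt, valid = cnt >= M)
    }
  }
  out
}

# exhaustive per-diagonal window comparison (naive quadratic k-mer oracle)
oracle_kmer_matches <- function(q, r, k) {
  qc <- strsplit(q, "")[[1]]
  rc <- strsplit(r, "")[[1]]
  n <- length(qc); m <- length(rc)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  okq <- qc %in% names(comp)
  okr <- rc %in% names(comp)
  rows <- list()
  record_runs <- function(eq, q0, pos_fun, orientation) {
    eq[is.na(eq)] <- FALSE
    rl <- rle(eq)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1L
    for (j in which(rl$values & rl$lengths >= k)) {
      for (st in starts[j]:(ends[j] - k + 1L)) {
        p <- q0 + st - 1L  # 0-based query window start
        rows[[length(rows) + 1L]] <<- data.frame(
          q_pos = p, r_pos = pos_fun(p), orientation = orientation,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (n >= k && m >= k) {
    for (d in (-(n - k)):(m - k)) {  # forward diagonal: r_pos - q_pos
      qi <- max(0L, -d):min(n - 1L, m - 1L - d)
      if (length(qi) < k) next
      eq <- qc[qi + 1L] == rc[qi + d + 1L] & okq[qi + 1L] & okr[qi + d + 1L]
      record_runs(eq, qi[1L], function(p) p + d, "forward")
    }
    for (cc in (k - 1L):(n + m - k - 1L)) {  # anti-diagonal: q_pos + r_pos + k - 1
      qi <- max(0L, cc - m + 1L):min(n - 1L, cc)
      if (length(qi) < k) next
      eq <- qc[qi + 1L] == unname(comp[rc[cc - qi + 1L]]) &
        okq[qi + 1L] & okr[cc - qi + 1L]
      record_runs(eq, qi[1L], function(p) cc - p - k + 1L, "reverse")
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(q_pos = integer(), r_pos = integer(),
                      orientation = character(), stringsAsFactors = FALSE)
  }
  out[out$r_pos >= 0L & out$r_pos <= m - k, , drop = FALSE]
}

sort_matches <- function(m) {
  m <- m[order(m$orientation, m$q_pos, m$r_pos), , drop = FALSE]
  rownames(m) <- NULL
  m
}

sort_segments <- function(s) {
  s <- s[order(s$orientation, s$q_start, s$r_start),
         c("q_start", "q_end", "r_start", "r_end", "orientation", "length")]
  rownames(s) <- NULL
  s
}

# per-cluster exhaustive overlap resolution (pairwise-merge clusters)
oracle_resolve <- function(segments) {
  n <- nrow(segments)
  if (n <= 1L) return(segments)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (comp[i] != comp[j] &&
            segments$q_start[i] < segments$q_end[j] &&
            segments$q_start[j] < segments$q_end[i]) {
          comp[comp == comp[j]] <- comp[i]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  keep <- vapply(unique(comp), function(g) {
    idx <- which(comp == g)
    s <- segments[idx, , drop = FALSE]
    idx[order(-s$length, s$r_start,
              match(s$orientation, c("forward", "reverse")))[1L]]
  }, 0L)
  out <- segments[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# query-axis bases covered by any matched k-mer window
match_coverage <- function(q, r, k) {
  m <- find_kmer_matches(q, r, kmer_params(k))
  if (nrow(m) == 0L) return(0L)
  length(unique(unlist(mapply(seq, m$q_pos, m$q_pos + k - 1L,
                              SIMPLIFY = FALSE))))
}
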