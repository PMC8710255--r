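# Built-in translated homology search: six-frame translation, exact peptide
# word seeding, ungapped x-drop extension under BLOSUM62. This is the
# package's dependency-free HSP source; its raw scores are not NCBI
# bitscores and reports label their provenance.

#' Parameters of the built-in translated search
#'
#' @param word_size Length of the exact peptide seed words (>= 3, default 5).
#' @param x_drop Extension stops once the running score falls this far
#'   below the best score seen (default 20).
#' @param min_score Minimum raw alignment score for an HSP to be reported
#'   (default 50).
#' @return An object of class `minisearch_params`.
#' @export
minisearch_params <- function(word_size = 5L, x_drop = 20L, min_score = 50L) {
  stopifnot(is_count1(word_size), word_size >= 3,
            is_count1(x_drop), is_count1(min_score))
  structure(list(word_size = as.integer(word_size),
                 x_drop = as.integer(x_drop),
                 min_score = as.integer(min_score)),
            class = "minisearch_params")
}

#' Six-frame translation
#'
#' Translates a nucleotide sequence in all six reading frames under the
#' standard genetic code: frames `+1..+3` from the sequence, `-1..-3` from
#' its reverse complement. Stops appear as `*`; codons containing ambiguity
#' codes translate to `X`.
#'
#' @param seq Nucleotide sequence (character scalar or `DNAString`).
#' @return Named character vector of the six peptides (`"+1"` .. `"-3"`);
#'   empty for sequences shorter than 3.
#' @export
six_frame_translate <- function(seq) {
  s <- as_seq_string(seq)
  n <- nchar(s)
  if (n < 3L) return(character(0))
  rc <- revcomp_chr(chartr("U", "T", s))
  one <- function(src, f) {
    len <- 3L * ((nchar(src) - f + 1L) %/% 3L)
    if (len < 3L) return("")
    sub <- substr(src, f, f + len - 1L)
    as.character(Biostrings::translate(Biostrings::DNAString(sub),
                                       if.fuzzy.codon = "X",
                                       no.init.codon = TRUE))
  }
  s_clean <- chartr("U", "T", s)
  out <- c(`+1` = one(s_clean, 1L), `+2` = one(s_clean, 2L),
           `+3` = one(s_clean, 3L),
           `-1` = one(rc, 1L), `-2` = one(rc, 2L), `-3` = one(rc, 3L))
  out
}

# word index of a peptide: positions (1-based) keyed by word string;
# words containing '*' or 'X' are not seedable
.word_index <- function(chars, w) {
  n <- length(chars)
  if (n < w) return(list(pos = integer(), word = character()))
  word <- vapply(seq_len(n - w + 1L),
                 function(i) paste(chars[i:(i + w - 1L)], collapse = ""), "")
  ok <- !grepl("[*X]", word, fixed = FALSE)
  list(pos = which(ok), word = word[ok])
}

# ungapped x-drop extension of a seed [qa, qa+w-1] along diagonal d
# (subject pos = query pos + d); returns c(a, b, score)
.extend_seed <- function(qv, sv, qa, d, w, x_drop) {
  La <- length(qv); Ls <- length(sv)
  lo <- max(1L, 1L - d)
  hi <- min(La, Ls - d)
  seed_score <- sum(.blosum62_pair_scores(qv[qa:(qa + w - 1L)],
                                          sv[(qa + d):(qa + d + w - 1L)]))
  # rightwards
  best_r <- qa + w - 1L; gain_r <- 0L; run <- 0L
  i <- qa + w
  while (i <= hi) {
    run <- run + .blosum62_pair_scores(qv[i], sv[i + d])
    if (run > gain_r) { gain_r <- run; best_r <- i }
    if (run < gain_r - x_drop) break
    i <- i + 1L
  }
  # leftwards
  best_l <- qa; gain_l <- 0L; run <- 0L
  i <- qa - 1L
  while (i >= lo) {
    run <- run + .blosum62_pair_scores(qv[i], sv[i + d])
    if (run > gain_l) { gain_l <- run; best_l <- i }
    if (run < gain_l - x_drop) break
    i <- i - 1L
  }
  c(best_l, best_r, seed_score + gain_r + gain_l)
}

# aa interval [a, b] in frame `f` (signed) of a contig of length L ->
# 1-based inclusive nucleotide interval on the contig plus strand
.aa_to_nt <- function(a, b, f, L) {
  off <- abs(f)
  p_start <- off + 3L * (a - 1L)
  p_end <- off + 3L * b - 1L
  if (f > 0) c(p_start, p_end) else c(L - p_end + 1L, L - p_start + 1L)
}

#' Translated homology search of one contig against protein CDSs
#'
#' For every exact `word_size` peptide word shared between a six-frame
#' translation of the contig and a protein, the seed is extended ungapped
#' in both directions under BLOSUM62 with x-drop termination; extensions
#' scoring at least `min_score` are reported as HSPs with nucleotide
#' contig coordinates. The raw score is stored in the `bitscore` column and
#' the E-value column carries a monotone transform of the score
#' (`10^(-score/10)`), usable for ranking only.
#'
#' @param contig A nucleotide sequence (character scalar, `DNAString`, or
#'   length-1 named `DNAStringSet`).
#' @param proteins An `AAStringSet` (or named character vector) of subject
#'   CDSs.
#' @param params A [minisearch_params()] object.
#' @param contig_id,ref_id Ids stamped onto the HSPs (default: the contig
#'   name, `NA` reference).
#' @return An HSP table, sorted by descending score.
#' @export
minisearch <- function(contig, proteins, params = minisearch_params(),
                       contig_id = NULL, ref_id = NA_character_) {
  stopifnot(inherits(params, "minisearch_params"))
  if (is.null(contig_id)) {
    contig_id <- names(contig) %||% "query"
    contig_id <- contig_id[1L]
  }
  if (inherits(contig, "XStringSet")) contig <- contig[[1L]]
  s <- as_seq_string(contig)
  L <- nchar(s)
  w <- params$word_size
  prot <- vapply(as.list(proteins), as_seq_string, "")
  if (is.null(names(prot))) names(prot) <- paste0("protein", seq_along(prot))
  frames <- six_frame_translate(s)
  empty <- hsp_table(data.frame(contig_id = character(), gene_id = character(),
                                pident = numeric(), align_len = integer(),
                                q_start = integer(), q_end = integer(),
                                s_start = integer(), s_end = integer(),
                                evalue = numeric(), bitscore = numeric(),
                                frame = integer()))
  if (length(frames) == 0L) return(empty)

  prot_chars <- lapply(prot, function(p) strsplit(p, "")[[1]])
  prot_idx <- lapply(prot_chars, .word_index, w = w)
  hits <- list()
  for (fl in names(frames)) {
    pep <- frames[[fl]]
    if (!nzchar(pep)) next
    f <- as.integer(fl)
    qv <- strsplit(pep, "")[[1]]
    q_idx <- .word_index(qv, w)
    if (length(q_idx$pos) == 0L) next
    for (g in names(prot)) {
      sv <- prot_chars[[g]]
      pidx <- prot_idx[[g]]
      if (length(pidx$pos) == 0L) next
      lookup <- split(pidx$pos, pidx$word)
      shared <- lookup[q_idx$word]
      nhit <- lengths(shared)
      if (sum(nhit) == 0L) next
      qa_all <- rep(q_idx$pos, nhit)
      sa_all <- unlist(shared[nhit > 0L], use.names = FALSE)
      d_all <- sa_all - qa_all
      done <- list()  # per-diagonal extended intervals already reported
      seen <- character(0)
      ord <- order(d_all, qa_all)
      for (ii in ord) {
        qa <- qa_all[ii]; d <- d_all[ii]
        dk <- as.character(d)
        iv <- done[[dk]]
        if (!is.null(iv) && any(qa >= iv[, 1L] & qa <= iv[, 2L])) next
        ext <- .extend_seed(qv, sv, qa, d, w, params$x_drop)
        a <- ext[1L]; b <- ext[2L]; score <- ext[3L]
        done[[dk]] <- rbind(iv, c(a, b))
        if (score < params$min_score) next
        key <- paste(g, fl, a, b, sep = ":")
        if (key %in% seen) next
        seen <- c(seen, key)
        qnt <- .aa_to_nt(a, b, f, L)
        qaa <- qv[a:b]; saa <- sv[(a + d):(b + d)]
        hits[[length(hits) + 1L]] <- data.frame(
          contig_id = contig_id, ref_id = ref_id, gene_id = g,
          pident = 100 * mean(qaa == saa),
          align_len = b - a + 1L,
          q_start = qnt[1L], q_end = qnt[2L],
          s_start = a + d, s_end = b + d,
          evalue = 10^(-score / 10),
          bitscore = score,
          frame = f,
          qseq_aa = paste(qaa, collapse = ""),
          sseq_aa = paste(saa, collapse = ""),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(hits) == 0L) return(empty)
  out <- do.call(rbind, c(hits, list(make.row.names = FALSE)))
  out <- out[order(-out$bitscore, out$evalue, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  hsp_table(out)
}
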