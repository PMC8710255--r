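# Synthetic data: the frozen two-contig/three-reference worked-example HSP
# configuration, and a mutable genome/contig simulator for end-to-end tests.

#' The frozen two-contig, three-reference worked example
#'
#' A deterministic HSP configuration exercising both filter parameters:
#'
#' * Contig_1 vs Ref_1: hits a,b overlapping plus c,d,e disjoint (5 hits);
#' * Contig_2 vs Ref_1: hits 1-4 disjoint plus 5,6,7,8 mutually
#'   overlapping with distinct scores, hit 8 scoring lowest (8 hits; at
#'   N = 4 the cap discards hit 8, leaving 7);
#' * Contig_1 vs Ref_2: no hits;
#' * Contig_2 vs Ref_2: 3 disjoint hits (invalid at M = 4);
#' * Contig_1 vs Ref_3: 4 disjoint hits (valid at M = 4);
#' * Contig_2 vs Ref_3: a single hit (invalid at M = 4).
#'
#' Coordinates and scores are fixed, arbitrary realisations of that
#' topology. E-values decrease with score, so score order and E-value order
#' agree.
#'
#' @return A list with `hsps` (HSP table, `ref_id` assigned),
#'   `gene_to_ref` (named character), `expected` (the evaluation at
#'   N = 4, M = 4: `contig_id`, `ref_id`, `subgene_count`, `valid`),
#'   `contig_ids` and `ref_ids` (input orders).
#' @export
fig2_fixture <- function() {
  row <- function(contig, ref, gene, qs, qe, score, frame = 1L) {
    data.frame(contig_id = contig, ref_id = ref, gene_id = gene,
               pident = round(50 + score / 6, 1),
               align_len = as.integer((qe - qs + 1L) / 3L),
               q_start = as.integer(qs), q_end = as.integer(qe),
               s_start = 1L, s_end = as.integer((qe - qs + 1L) / 3L),
               evalue = 10^(-score / 10), bitscore = score,
               frame = as.integer(frame), qseq_aa = "", sseq_aa = "",
               stringsAsFactors = FALSE)
  }
  hsps <- rbind(
    # Contig_1 vs Ref_1: a,b overlap; c,d,e disjoint
    row("Contig_1", "Ref_1", "R1_ga", 100, 399, 210),
    row("Contig_1", "Ref_1", "R1_gb", 350, 649, 190, frame = 2L),
    row("Contig_1", "Ref_1", "R1_gc", 800, 1099, 230),
    row("Contig_1", "Ref_1", "R1_gd", 1200, 1499, 180, frame = -1L),
    row("Contig_1", "Ref_1", "R1_ge", 1600, 1899, 205),
    # Contig_2 vs Ref_1: 1-4 disjoint; 5,6,7,8 mutually overlapping
    row("Contig_2", "Ref_1", "R1_g1", 100, 399, 260),
    row("Contig_2", "Ref_1", "R1_g2", 500, 799, 240),
    row("Contig_2", "Ref_1", "R1_g3", 900, 1199, 225, frame = 3L),
    row("Contig_2", "Ref_1", "R1_g4", 1300, 1599, 215),
    row("Contig_2", "Ref_1", "R1_g5", 1700, 1999, 200),
    row("Contig_2", "Ref_1", "R1_g6", 1750, 2049, 185, frame = -2L),
    row("Contig_2", "Ref_1", "R1_g7", 1800, 2099, 170),
    row("Contig_2", "Ref_1", "R1_g8", 1850, 2149, 150),
    # Contig_2 vs Ref_2: 3 disjoint
    row("Contig_2", "Ref_2", "R2_g1", 200, 499, 190),
    row("Contig_2", "Ref_2", "R2_g2", 600, 899, 175),
    row("Contig_2", "Ref_2", "R2_g3", 1000, 1299, 160, frame = -3L),
    # Contig_1 vs Ref_3: 4 disjoint
    row("Contig_1", "Ref_3", "R3_g1", 100, 399, 220),
    row("Contig_1", "Ref_3", "R3_g2", 500, 799, 205),
    row("Contig_1", "Ref_3", "R3_g3", 900, 1199, 195),
    row("Contig_1", "Ref_3", "R3_g4", 1300, 1599, 185),
    # Contig_2 vs Ref_3: single hit
    row("Contig_2", "Ref_3", "R3_g5", 300, 599, 170)
  )
  hsps <- hsp_table(hsps)
  gene_to_ref <- structure(hsps$ref_id, names = hsps$gene_id)
  expected <- data.frame(
    contig_id = c("Contig_1", "Contig_2", "Contig_2", "Contig_1", "Contig_2"),
    ref_id = c("Ref_1", "Ref_1", "Ref_2", "Ref_3", "Ref_3"),
    subgene_count = c(5L, 7L, 3L, 4L, 1L),
    valid = c(TRUE, TRUE, FALSE, TRUE, FALSE),
    stringsAsFactors = FALSE
  )
  list(hsps = hsps, gene_to_ref = gene_to_ref, expected = expected,
       contig_ids = c("Contig_1", "Contig_2"),
       ref_ids = c("Ref_1", "Ref_2", "Ref_3"))
}

#' Configuration of the synthetic genome/contig simulator
#'
#' @param seed RNG seed; all randomness of the generator flows through it.
#' @param n_genes Number of non-overlapping ORFs placed on the reference.
#' @param gene_len_range ORF length range in bp (rounded to codons;
#'   includes start and stop codons).
#' @param intergenic_len_range Intergenic spacer length range in bp.
#' @param contig_count Number of contigs the mutated genome copy is cut
#'   into.
#' @param substitution_rate Per-base substitution probability applied to
#'   the genome copy before cutting.
#' @param revcomp_fraction Probability that a contig is reverse-complemented.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(seed = 1L, n_genes = 8L,
                         gene_len_range = c(300L, 900L),
                         intergenic_len_range = c(100L, 300L),
                         contig_count = 3L, substitution_rate = 0.02,
                         revcomp_fraction = 0.25) {
  ok_range <- function(r) length(r) == 2L && all(r >= 1) && r[1L] <= r[2L]
  if (!is_count1(n_genes) || !is_count1(contig_count) ||
      !ok_range(gene_len_range) || !ok_range(intergenic_len_range) ||
      substitution_rate < 0 || substitution_rate > 1 ||
      revcomp_fraction < 0 || revcomp_fraction > 1) {
    stop("invalid simulator configuration: counts must be >= 1, ranges ",
         "positive and ordered, rates in [0, 1]", call. = FALSE)
  }
  structure(list(seed = as.integer(seed), n_genes = as.integer(n_genes),
                 gene_len_range = as.integer(gene_len_range),
                 intergenic_len_range = as.integer(intergenic_len_range),
                 contig_count = as.integer(contig_count),
                 substitution_rate = substitution_rate,
                 revcomp_fraction = revcomp_fraction),
            class = "synth_config")
}

.BASES <- c("A", "C", "G", "T")
.STOPS <- c("TAA", "TAG", "TGA")
.SENSE_CODONS <- setdiff(
  apply(expand.grid(.BASES, .BASES, .BASES), 1L, paste, collapse = ""),
  .STOPS)

# uniform integer in [a, b], safe when a == b (sample() would misread it)
.rint <- function(a, b) a + sample.int(b - a + 1L, 1L) - 1L

.random_orf <- function(len_range) {
  len <- .rint(len_range[1L], len_range[2L])
  n_cod <- max(3L, round(len / 3))
  codons <- character(n_cod)
  codons[1L] <- "ATG"
  codons[2:(n_cod - 1L)] <- sample(.SENSE_CODONS, n_cod - 2L, replace = TRUE)
  codons[n_cod] <- sample(.STOPS, 1L)
  paste(codons, collapse = "")
}

.mutate_seq <- function(s, rate) {
  if (rate <= 0) return(s)
  chars <- strsplit(s, "")[[1]]
  hit <- which(runif(length(chars)) < rate)
  for (i in hit) chars[i] <- sample(setdiff(.BASES, chars[i]), 1L)
  paste(chars, collapse = "")
}

#' Simulate a reference genome, its CDS set, and mutated query contigs
#'
#' Builds a reference nucleotide sequence carrying `n_genes` non-overlapping
#' ORFs (ATG start, single terminal stop, no internal stops) separated by
#' random intergenic spacers; its protein CDS set (translations without the
#' stop); and query contigs cut from a substitution-mutated copy of the
#' genome, each contig optionally reverse-complemented. The truth table
#' records which genes each contig fully contains and where.
#'
#' @param config A [synth_config()] object.
#' @return A list: `reference` (list with `ref_id`, `nucleotide`
#'   (`DNAStringSet`), `proteins` (`AAStringSet` named by gene)), `contigs`
#'   (`DNAStringSet`), `genes` (data frame of genome intervals), `truth`
#'   (data frame `contig_id`, `gene_id`, `start`, `end`, `strand` —
#'   contig-local coordinates), and `config`.
#' @export
make_genome_and_contigs <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  genes <- vapply(seq_len(config$n_genes), function(i)
    .random_orf(config$gene_len_range), "")
  gene_ids <- sprintf("gene%02d", seq_len(config$n_genes))
  spacer <- function() paste(sample(.BASES,
    .rint(config$intergenic_len_range[1L], config$intergenic_len_range[2L]),
    replace = TRUE), collapse = "")
  parts <- character(0)
  starts <- integer(config$n_genes)
  pos <- 0L
  for (i in seq_len(config$n_genes)) {
    sp <- spacer()
    parts <- c(parts, sp, genes[i])
    pos <- pos + nchar(sp)
    starts[i] <- pos + 1L
    pos <- pos + nchar(genes[i])
  }
  parts <- c(parts, spacer())
  genome <- paste(parts, collapse = "")
  gene_tab <- data.frame(gene_id = gene_ids, start = starts,
                         end = starts + nchar(genes) - 1L,
                         stringsAsFactors = FALSE)
  proteins <- vapply(genes, function(g) {
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(g)))
    sub("\\*$", "", aa)
  }, "", USE.NAMES = FALSE)
  prot_set <- Biostrings::AAStringSet(proteins)
  names(prot_set) <- gene_ids

  mutated <- .mutate_seq(genome, config$substitution_rate)
  L <- nchar(genome)
  n_ct <- config$contig_count
  cuts <- if (n_ct > 1L) sort(sample(seq(2L, L - 1L), n_ct - 1L)) else integer(0)
  ct_start <- c(1L, cuts)
  ct_end <- c(cuts - 1L, L)
  flip <- runif(n_ct) < config$revcomp_fraction
  contig_ids <- sprintf("contig%02d", seq_len(n_ct))
  contigs <- vapply(seq_len(n_ct), function(i) {
    s <- substr(mutated, ct_start[i], ct_end[i])
    if (flip[i]) revcomp_chr(s) else s
  }, "")
  contig_set <- Biostrings::DNAStringSet(contigs)
  names(contig_set) <- contig_ids

  truth <- do.call(rbind, lapply(seq_len(n_ct), function(i) {
    inside <- gene_tab$start >= ct_start[i] & gene_tab$end <= ct_end[i]
    if (!any(inside)) return(NULL)
    g <- gene_tab[inside, , drop = FALSE]
    local_start <- g$start - ct_start[i] + 1L
    local_end <- g$end - ct_start[i] + 1L
    clen <- ct_end[i] - ct_start[i] + 1L
    if (flip[i]) {
      tmp <- local_start
      local_start <- clen - local_end + 1L
      local_end <- clen - tmp + 1L
    }
    data.frame(contig_id = contig_ids[i], gene_id = g$gene_id,
               start = local_start, end = local_end,
               strand = if (flip[i]) "-" else "+",
               stringsAsFactors = FALSE)
  }))
  if (is.null(truth)) {
    truth <- data.frame(contig_id = character(), gene_id = character(),
                        start = integer(), end = integer(),
                        strand = character(), stringsAsFactors = FALSE)
  }
  ref_nt <- Biostrings::DNAStringSet(genome)
  names(ref_nt) <- "ref01"
  list(reference = list(ref_id = "ref01", nucleotide = ref_nt,
                        proteins = prot_set),
       contigs = contig_set, genes = gene_tab, truth = truth,
       config = config)
}
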