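test_that("read_fasta parses single and multi-record files with uppercasing", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">c1 first contig", "acgt", ">c2", "TTGG", "CCAA"), fa)
  x <- read_fasta(fa, "nucleotide")
  expect_identical(names(x), c("c1", "c2"))
  expect_identical(as.character(x[["c1"]]), "ACGT")
  expect_identical(as.character(x[["c2"]]), "TTGGCCAA")
  expect_identical(S4Vectors::mcols(x)$description[1], "c1 first contig")
})

test_that("read_fasta accepts protein records with a stop and rejects bad input", {
  fa <- withr::local_tempfile(fileext = ".faa")
  writeLines(c(">p1", "MKV*"), fa)
  p <- read_fasta(fa, "protein")
  expect_identical(as.character(p[["p1"]]), "MKV*")

  writeLines(c(">c1", "MKV*"), fa)
  expect_error(read_fasta(fa, "nucleotide"), "illegal.*nucleotide")
  writeLines(c(">a", "ACGT", ">a", "GGCC"), fa)
  expect_error(read_fasta(fa, "nucleotide"), "duplicate record id 'a'")
  writeLines(character(0), fa)
  expect_error(read_fasta(fa, "nucleotide"), "FASTA")
})

test_that("FASTA write/read round trip preserves ids and sequences", {
  set.seed(11)
  x <- Biostrings::DNAStringSet(vapply(1:4, function(i) random_dna(120), ""))
  names(x) <- paste0("seq", 1:4)
  fa <- withr::local_tempfile(fileext = ".fa")
  write_fasta(x, fa)
  y <- read_fasta(fa, "nucleotide")
  expect_identical(names(y), names(x))
  expect_identical(as.character(y), as.character(x))
})

test_that("protein reference sets split on lines of three or more asterisks", {
  faa <- withr::local_tempfile(fileext = ".faa")
  writeLines(c(">a1", "MKL", ">a2", "MVV", "***", ">b1", "MA", ">b2", "MC",
               ">b3", "MD"), faa)
  sets <- read_protein_reference_sets(faa, 2)
  expect_length(sets, 2)
  expect_identical(lengths(sets), c(2L, 3L))
  expect_identical(names(sets[[2]]), c("b1", "b2", "b3"))

  # a five-asterisk separator still splits (minimum-of-three rule)
  writeLines(c(">a1", "MKL", "*****", ">b1", "MA"), faa)
  expect_length(read_protein_reference_sets(faa, 2), 2)

  # no separator: everything is one set
  writeLines(c(">a1", "MKL", ">a2", "MVV"), faa)
  expect_length(read_protein_reference_sets(faa, 1)[[1]], 2)
})

test_that("protein reference sets report count mismatches and empty sets", {
  faa <- withr::local_tempfile(fileext = ".faa")
  writeLines(c(">a1", "MKL", "***", ">b1", "MA"), faa)
  expect_error(read_protein_reference_sets(faa, 3), "2 set.*3 reference")
  writeLines(c(">a1", "MKL", "***", "***", ">b1", "MA"), faa)
  expect_error(read_protein_reference_sets(faa, 3), "empty protein set")
})

test_that("read_blast_tabular parses the 11/13-column dialect", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "# blastx comment",
    "c1\tgeneA\t98.0\t120\t10\t369\t1\t120\t1e-50\t250\t1",
    "c1\tgeneB\t90.0\t120\t369\t10\t1\t120\t1e-30\t180\t-2"
  ), tsv)
  h <- read_blast_tabular(tsv)
  expect_equal(nrow(h), 2)
  expect_equal(h$q_start, c(10L, 10L))
  expect_equal(h$q_end, c(369L, 369L))
  expect_equal(h$frame, c(1L, -2L))
  expect_equal(h$bitscore, c(250, 180))
  expect_true(all(h$q_start <= h$q_end))
})

test_that("read_blast_tabular preserves line order and flags malformed lines", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  lines <- sprintf("ctg\tg%d\t90\t100\t%d\t%d\t1\t100\t1e-10\t%d\t1",
                   1:8, (1:8) * 400, (1:8) * 400 + 299, 100 + 1:8)
  writeLines(lines, tsv)
  h <- read_blast_tabular(tsv)
  expect_equal(h$gene_id, paste0("g", 1:8))

  writeLines(c(lines[1], "ctg\tonly\tthree"), tsv)
  expect_error(read_blast_tabular(tsv), "line 2")
  writeLines("ctg\tg1\tnotanumber\t100\t1\t300\t1\t100\t1e-10\t100\t1", tsv)
  expect_error(read_blast_tabular(tsv), "non-numeric")
})

test_that("BLAST tabular write/read round trip (incl. minus-frame swap)", {
  fx <- fig2_fixture()
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_blast_tabular(fx$hsps, tsv)
  back <- read_blast_tabular(tsv)
  expect_equal(nrow(back), nrow(fx$hsps))
  expect_true(all(back$q_start <= back$q_end))
  for (col in c("contig_id", "gene_id", "q_start", "q_end", "frame",
                "align_len", "bitscore")) {
    expect_equal(back[[col]], fx$hsps[[col]], info = col)
  }
  # minus-frame rows were written with qstart > qend
  raw <- read.table(tsv, sep = "\t")
  neg <- raw$V11 < 0
  expect_true(all(raw$V5[neg] > raw$V6[neg]))
})

test_that("assign_references maps subject CDS ids to owning references", {
  fx <- fig2_fixture()
  h <- fx$hsps
  h$ref_id <- NA_character_
  sets <- lapply(split(names(fx$gene_to_ref), fx$gene_to_ref), function(ids) {
    s <- Biostrings::AAStringSet(rep("MKL", length(ids)))
    names(s) <- ids
    s
  })
  h2 <- assign_references(h, sets)
  expect_identical(h2$ref_id, fx$hsps$ref_id)
  h$gene_id[1] <- "unknown_gene"
  expect_error(assign_references(h, sets), "unknown_gene")
})

test_that("report files: regsp blocks are the valid subset, scores sorted", {
  fx <- fig2_fixture()
  params <- suppressWarnings(search_params(4, 4))
  reports <- run_gene_search(fx$hsps, params, fx$contig_ids, fx$ref_ids)
  sorted_f <- withr::local_tempfile(fileext = ".sorted")
  regsp_f <- withr::local_tempfile(fileext = ".regsp")
  write_report(reports, "sorted", sorted_f, params = params)
  write_report(reports, "regsp", regsp_f, params = params)

  bs <- read_report_blocks(sorted_f)
  br <- read_report_blocks(regsp_f)
  expect_equal(nrow(bs), 5)
  expect_equal(nrow(br), 3)
  # the pre-M file records 3 hits for Contig_2 vs Ref_2 ...
  expect_equal(bs$gene_count[bs$contig_id == "Contig_2" & bs$ref_id == "Ref_2"], 3L)
  # ... and that pair is absent after the M filter
  expect_false(any(br$contig_id == "Contig_2" & br$ref_id == "Ref_2"))
  # regsp blocks are a subset of sorted blocks
  expect_true(all(paste(br$contig_id, br$ref_id) %in%
                    paste(bs$contig_id, bs$ref_id)))
  # within each block, bitscores are non-increasing
  lines <- readLines(sorted_f)
  scores <- as.numeric(sub(".*bitscore=([0-9.e+-]+) .*", "\\1",
                           grep("bitscore=", lines, value = TRUE)))
  blocks <- cumsum(grepl("^## contig:", lines))[grepl("bitscore=", lines)]
  for (b in unique(blocks)) {
    expect_true(all(diff(scores[blocks == b]) <= 0))
  }
})

test_that("an empty report collection writes a header-only file", {
  f <- withr::local_tempfile()
  write_report(list(), "sorted", f)
  lines <- readLines(f)
  expect_true(all(startsWith(lines, "#")))
  expect_equal(nrow(read_report_blocks(f)), 0)
})

test_that("report includes the matched query subsequence when sequences are given", {
  hsps <- hsp_table(data.frame(
    contig_id = "c1", ref_id = "r1", gene_id = "g1", pident = 100,
    align_len = 4L, q_start = 3L, q_end = 14L, s_start = 1L, s_end = 4L,
    evalue = 1e-10, bitscore = 80, frame = 3L,
    qseq_aa = "MKVL", sseq_aa = "MKVL"))
  reports <- run_gene_search(hsps, suppressWarnings(search_params(2, 1)))
  f <- withr::local_tempfile()
  q <- Biostrings::DNAStringSet(c(c1 = "AAATGAAAGTACTTGGG"))
  write_report(reports, "sorted", f, queries = q)
  lines <- readLines(f)
  expect_true(any(grepl("query_nt: ATGAAAGTACTT", lines)))
  expect_true(any(grepl("query_aa: MKVL", lines)))
})
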