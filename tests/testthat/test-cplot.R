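test_that("kmer_params enforces the 10-30 range with default 13", {
  expect_equal(kmer_params()$k, 13L)
  expect_equal(kmer_params(10)$k, 10L)
  expect_equal(kmer_params(30)$k, 30L)
  expect_error(kmer_params(9), "between 10 and 30")
  expect_error(kmer_params(31), "between 10 and 30")
  expect_error(kmer_params(13.5), "integer")
})

test_that("identical sequences give the identity diagonal", {
  m <- find_kmer_matches("ACGTACGTACGTAC", "ACGTACGTACGTAC", kmer_params(13))
  expect_equal(m$q_pos, c(0L, 1L))
  expect_equal(m$r_pos, c(0L, 1L))
  expect_true(all(m$orientation == "forward"))
})

test_that("a reverse-complemented query yields reverse matches only", {
  set.seed(5)
  s <- random_dna(20)
  m <- find_kmer_matches(revcomp_oracle(s), s, kmer_params(13))
  expect_equal(sum(m$orientation == "reverse"), 8)
  expect_equal(sum(m$orientation == "forward"), 0)
  # anti-diagonal constant r_pos + q_pos is fixed across the run
  expect_equal(length(unique(m$r_pos + m$q_pos)), 1L)
})

test_that("sequences shorter than k warn and return no matches", {
  expect_warning(m <- find_kmer_matches("ACGT", "ACGTACGTACGTAC",
                                        kmer_params(13)), "shorter than k")
  expect_equal(nrow(m), 0)
})

test_that("ambiguity codes never match", {
  s <- paste0(strrep("N", 20), "ACGTACGTACGTACGTACGT")
  m <- find_kmer_matches(s, s, kmer_params(13))
  expect_true(all(m$q_pos >= 20))
})

test_that("find_kmer_matches is transpose-symmetric for forward matches", {
  set.seed(12)
  a <- random_dna(300)
  b <- paste0(substr(a, 50, 180), random_dna(100))
  m1 <- find_kmer_matches(a, b, kmer_params(12))
  m2 <- find_kmer_matches(b, a, kmer_params(12))
  f1 <- sort_matches(m1[m1$orientation == "forward", ])
  f2 <- sort_matches(data.frame(q_pos = m2$r_pos[m2$orientation == "forward"],
                                r_pos = m2$q_pos[m2$orientation == "forward"],
                                orientation = "forward"))
  expect_equal(f1, f2)
})

test_that("merge_matches fuses diagonal runs into maximal segments", {
  m <- find_kmer_matches("ACGTACGTACGTAC", "ACGTACGTACGTAC", kmer_params(13))
  seg <- merge_matches(m, 13)
  expect_equal(nrow(seg), 1)
  expect_equal(seg$q_start, 0L)
  expect_equal(seg$q_end, 14L)
  expect_equal(seg$length, 14L)
  expect_equal(seg$q_end - seg$q_start, seg$r_end - seg$r_start)

  expect_equal(nrow(merge_matches(m[0, ], 13)), 0)
})

test_that("a single mismatched base splits shared blocks into two segments", {
  set.seed(31)
  b1 <- random_dna(30)
  b2 <- random_dna(30)
  ref <- paste0(b1, "A", b2)
  qry <- paste0(b1, "C", b2)  # differs at the junction base only
  seg <- merge_matches(find_kmer_matches(qry, ref, kmer_params(10)), 10)
  fwd <- seg[seg$orientation == "forward" & seg$length == 30, ]
  expect_equal(nrow(fwd), 2)
  expect_equal(sort(fwd$q_start), c(0L, 31L))
})

test_that("resolve_overlaps keeps the longest candidate per overlap cluster", {
  seg <- data.frame(contig_id = "c", ref_id = "r",
                    q_start = c(0L, 10L), q_end = c(40L, 35L),
                    r_start = c(100L, 500L), r_end = c(140L, 525L),
                    orientation = "forward", length = c(40L, 25L),
                    stringsAsFactors = FALSE)
  kept <- resolve_overlaps(seg)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$length, 40L)

  disjoint <- seg
  disjoint$q_start <- c(0L, 50L); disjoint$q_end <- c(40L, 75L)
  expect_equal(nrow(resolve_overlaps(disjoint)), 2)
})

test_that("resolve_overlaps equals the exhaustive cluster scan on random inputs", {
  set.seed(77)
  for (rep in 1:30) {
    n <- sample(1:12, 1)
    qs <- sample(0:200, n)
    len <- sample(10:80, n, replace = TRUE)
    seg <- data.frame(contig_id = "c", ref_id = "r",
                      q_start = qs, q_end = qs + len,
                      r_start = sample(0:500, n), orientation =
                        sample(c("forward", "reverse"), n, replace = TRUE),
                      length = len, stringsAsFactors = FALSE)
    seg$r_end <- seg$r_start + len
    got <- resolve_overlaps(seg)
    want <- oracle_resolve(seg)
    expect_equal(sort_segments(got), sort_segments(want))
    # kept query intervals are pairwise non-overlapping
    o <- order(got$q_start)
    if (nrow(got) > 1) {
      expect_true(all(got$q_start[o][-1] >= got$q_end[o][-nrow(got)]))
    }
  }
})

test_that("contigs are ordered by first reference, then position, no-hit last", {
  seg <- data.frame(
    contig_id = c("cA", "cB"), ref_id = "r1",
    q_start = 0L, q_end = 50L,
    r_start = c(5000L, 100L), r_end = c(5050L, 150L),
    orientation = "forward", length = 50L, stringsAsFactors = FALSE)
  expect_equal(order_contigs(seg, c("cA", "cB", "cC"), "r1"),
               c("cB", "cA", "cC"))
  expect_equal(order_contigs(seg[0, ], "solo", "r1"), "solo")
})

test_that("build_layout assembles one panel per reference in input order", {
  set.seed(3)
  s <- random_dna(300)
  refs <- setNames(vapply(1:5, function(i) random_dna(250), ""),
                   paste0("ref", 1:5))
  refs[["ref3"]] <- s
  lay <- build_layout(c(q1 = s), refs, kmer_params(13))
  expect_s3_class(lay, "dotplot_layout")
  expect_equal(names(lay$panels), paste0("ref", 1:5))
  seg3 <- lay$panels$ref3$segments
  expect_equal(nrow(seg3), 1)
  expect_equal(seg3$q_start, 0L)
  expect_equal(seg3$q_end, 300L)
})

test_that("identity layout is a single full diagonal for any valid k", {
  set.seed(8)
  s <- random_dna(400)
  for (k in c(10, 13, 30)) {
    lay <- build_layout(c(q = s), c(r = s), kmer_params(k))
    seg <- lay$panels$r$segments
    expect_equal(nrow(seg), 1, info = paste("k =", k))
    expect_equal(seg$length, 400L, info = paste("k =", k))
    expect_equal(seg$orientation, "forward")
  }
})

test_that("matched coverage is non-increasing in k (plots fade out)", {
  set.seed(21)
  ref <- random_dna(1500)
  qry <- mutate_dna(ref, 0.03)
  cov <- vapply(c(10, 13, 20, 30), function(k) match_coverage(qry, ref, k), 0L)
  expect_true(all(diff(cov) <= 0))
  expect_gt(cov[1], 0)
})

test_that("find+merge equals the naive per-diagonal window oracle", {
  set.seed(14)
  for (rep in 1:6) {
    n <- sample(200:500, 1)
    ref <- random_dna(n)
    qry <- if (rep %% 2) mutate_dna(ref, 0.05) else
      paste0(substr(ref, 1, n %/% 3), random_dna(n %/% 3),
             revcomp_oracle(substr(ref, 2 * (n %/% 3), n)))
    k <- sample(c(10, 13, 16), 1)
    got <- sort_matches(find_kmer_matches(qry, ref, kmer_params(k)))
    want <- sort_matches(oracle_kmer_matches(qry, ref, k))
    expect_equal(got, want, info = paste("rep", rep))
    # merged segments re-expand to the same match set
    seg <- merge_matches(got, k)
    expect_equal(sum(seg$length - k + 1L), nrow(got))
  }
})
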