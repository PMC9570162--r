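test_that("build_kmer_index records every N-free k-mer with all positions", {
  suppressWarnings(idx <- build_kmer_index(seq_record("r", "ACGTACGT"), 4))
  expect_equal(idx$table,
               list(ACGT = c(0L, 4L), CGTA = 1L, GTAC = 2L, TACG = 3L))
  expect_equal(idx$ref_length, 8L)

  suppressWarnings(idx2 <- build_kmer_index(seq_record("r", "ACNGT"), 2))
  expect_equal(idx2$table, list(AC = 0L, GT = 3L))

  ref <- random_sequence(300, seed = 1)
  idx3 <- build_kmer_index(ref, 15)
  if (length(idx3$table) == 300 - 15 + 1) {
    expect_equal(sort(unlist(idx3$table, use.names = FALSE)), 0:(300 - 15))
  }
  expect_true(all(vapply(idx3$table, function(p) all(diff(p) > 0), TRUE)))
})

test_that("build_kmer_index validates k", {
  r <- seq_record("r", "ACGTACGT")
  expect_error(build_kmer_index(r, 0), class = "contigdot_parameter_error")
  expect_error(build_kmer_index(r, 9), class = "contigdot_parameter_error")
  expect_warning(build_kmer_index(r, 4), "range")
})

test_that("scan_anchors reports every (query position, reference position) pair", {
  suppressWarnings(idx <- build_kmer_index(seq_record("r", "ACGTACGT"), 4))
  a <- scan_anchors(idx, "ACGT", "forward")
  expect_equal(a$query_pos, c(0L, 0L))
  expect_equal(a$ref_pos, c(0L, 4L))

  expect_equal(nrow(scan_anchors(idx, "NNNNNN", "forward")), 0L)
  expect_equal(nrow(scan_anchors(idx, "ACG", "forward")), 0L)

  ref <- random_sequence(200, seed = 2)
  idx2 <- build_kmer_index(ref, 15)
  a2 <- scan_anchors(idx2, ref$seq, "forward")
  expect_equal(nrow(a2), 200 - 15 + 1)
  expect_true(all(a2$ref_pos == a2$query_pos))
})

test_that("merge_anchors fuses consecutive co-diagonal anchors into maximal segments", {
  anchors <- data.frame(query_pos = 0:6, ref_pos = 0:6, strand = "forward")
  segs <- merge_anchors(anchors, 4, 20L, "forward", "q")
  expect_equal(nrow(segs), 1L)
  expect_equal(segs$ref_start, 0L)
  expect_equal(segs$ref_end, 10L)
  expect_equal(segs$query_start, 0L)
  expect_equal(segs$query_end, 10L)
  expect_equal(segs$length, 10L)

  gapped <- data.frame(query_pos = c(0:2, 5:6), ref_pos = c(0:2, 5:6),
                       strand = "forward")
  segs2 <- merge_anchors(gapped, 4, 20L, "forward", "q")
  expect_equal(nrow(segs2), 2L)
  expect_equal(segs2$length, c(6L, 5L))  # 3-anchor and 2-anchor runs

  expect_equal(nrow(merge_anchors(empty <- data.frame(query_pos = integer(),
                                                      ref_pos = integer()),
                                  4, 10L, "forward", "q")), 0L)
})

test_that("merged segments equal the brute-force maximal-exact-match set", {
  withr::with_seed(42, {
    for (case in 1:60) {
      ref <- random_sequence(sample(60:250, 1), seed = sample.int(1e6, 1))
      qseq <- mosaic_query(ref$seq, n_pieces = sample(2:4, 1),
                           piece = sample(25:50, 1))
      query <- seq_record("q", qseq)
      k <- sample(c(10L, 12L), 1)
      idx <- build_kmer_index(ref, k)
      canon <- function(d) {
        d <- d[order(d$ref_start, d$ref_end, d$strand, d$query_start), ]
        rownames(d) <- NULL
        d[c("ref_start", "ref_end", "query_start", "query_end", "strand")]
      }
      got <- align_query(idx, query, k)
      want <- oracle_mems(ref$seq, query$seq, k)
      expect_equal(canon(as.data.frame(got)), canon(want))
    }
  })
})

test_that("segment invariants hold: exact match content on both strands", {
  withr::with_seed(7, {
    ref <- random_sequence(400, seed = 99)
    query <- seq_record("q", mosaic_query(ref$seq, 5, 60))
    idx <- build_kmer_index(ref, 12)
    segs <- align_query(idx, query, 12)
    expect_gt(nrow(segs), 0)
    for (i in seq_len(nrow(segs))) {
      rsub <- substring(ref$seq, segs$ref_start[i] + 1, segs$ref_end[i])
      qsub <- substring(query$seq, segs$query_start[i] + 1, segs$query_end[i])
      if (segs$strand[i] == "forward") expect_equal(rsub, qsub)
      else expect_equal(rsub, reverse_complement(qsub))
    }
  })
})

test_that("self-alignment and reverse-complement alignment give one full-cover segment", {
  ref <- random_sequence(800, seed = 5)
  idx <- build_kmer_index(ref, 15)
  fwd <- align_query(idx, ref, 15)
  expect_equal(nrow(fwd), 1L)
  expect_equal(fwd$strand, "forward")
  expect_equal(c(fwd$ref_start, fwd$ref_end), c(0L, 800L))

  rc <- seq_record("rc", reverse_complement(ref$seq))
  rev <- align_query(idx, rc, 15)
  expect_equal(nrow(rev), 1L)
  expect_equal(rev$strand, "reverse")
  expect_equal(c(rev$ref_start, rev$ref_end), c(0L, 800L))
  expect_equal(c(rev$query_start, rev$query_end), c(0L, 800L))
})

test_that("strand symmetry: reverse complementing the query swaps strands and mirrors intervals", {
  withr::with_seed(21, {
    ref <- random_sequence(300, seed = 31)
    query <- seq_record("q", mosaic_query(ref$seq, 4, 40))
    idx <- build_kmer_index(ref, 11)
    a <- align_query(idx, query, 11)
    b <- align_query(idx, seq_record("q", reverse_complement(query$seq)), 11)
    expect_equal(nrow(a), nrow(b))
    flip <- data.frame(
      ref_start = b$ref_start, ref_end = b$ref_end,
      query_start = query$length - b$query_end,
      query_end = query$length - b$query_start,
      strand = ifelse(b$strand == "forward", "reverse", "forward"))
    flip <- flip[order(flip$ref_start, flip$ref_end, flip$strand), ]
    expect_equal(a$ref_start, flip$ref_start)
    expect_equal(a$query_start, flip$query_start)
    expect_equal(a$query_end, flip$query_end)
    expect_equal(a$strand, flip$strand)
  })
})

test_that("threshold filters segments and must be >= k", {
  ref <- random_sequence(500, seed = 8)
  idx <- build_kmer_index(ref, 15)
  expect_error(align_query(idx, ref, 10), class = "contigdot_parameter_error")
  expect_equal(nrow(align_query(idx, ref, 501)), 0L)

  # raising the threshold never adds segments
  query <- seq_record("q", withr::with_seed(1, mosaic_query(ref$seq, 5, 30)))
  n_prev <- Inf
  for (thr in c(15, 20, 30, 45)) {
    n <- nrow(align_query(idx, query, thr))
    expect_lte(n, n_prev)
    n_prev <- n
  }
})
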