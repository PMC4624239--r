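params <- scan_params()

test_that("score_motif and noise_threshold follow the length-amplified scheme", {
  expect_equal(score_motif(12, 0, params), 144)
  expect_equal(score_motif(13, 2, params), 165)
  expect_equal(score_motif(8, 0, params), 64)
  expect_equal(noise_threshold(params), 144)
  expect_equal(noise_threshold(scan_params(noise_word_len = 8)), 64)
  expect_equal(noise_threshold(scan_params(s_p = 2, s_q = -1)), 288)
  # converting one match to a mismatch at fixed length drops the score by
  # (s_p - s_q) * length
  set.seed(5)
  for (i in 1:25) {
    p <- sample(2:40, 1); q <- sample(0:10, 1)
    drop <- score_motif(p, q, params) - score_motif(p - 1, q + 1, params)
    expect_equal(drop, (params$s_p - params$s_q) * (p + q))
  }
})

test_that("find_seeds enumerates shared k-mers, honouring N and mask", {
  q <- dna_seq("q", "ACGTACGTTT")
  t <- dna_seq("t", "GGACGTACGTGG")
  s <- find_seeds(q, t, params)
  expect_equal(nrow(s), 1L)
  expect_equal(c(s$q_start, s$t_start), c(0L, 2L))

  expect_equal(nrow(find_seeds(dna_seq("q", "AAAAAAAAAA"),
                               dna_seq("t", "CCCCCCCCCC"), params)), 0L)
  # query shorter than k: empty, not an error
  expect_equal(nrow(find_seeds(dna_seq("q", "ACGT"), t, params)), 0L)

  # masked or N positions are excluded from seeding
  qm <- dna_seq("q", "acgtacgtTT")  # first 8 soft-masked
  expect_equal(nrow(find_seeds(qm, t, params)), 0L)
  qn <- dna_seq("q", "ACGNACGTTT")
  expect_equal(nrow(find_seeds(qn, t, params)), 0L)
})

test_that("find_seeds equals brute-force enumeration on random pairs", {
  set.seed(101)
  for (i in 1:30) {
    q <- rand_seq(sample(60:200, 1), id = "q",
                  seed = NULL)
    t <- rand_seq(sample(60:200, 1), id = "t")
    q$mask <- stats::runif(seq_length(q)) < 0.05
    t$mask <- stats::runif(seq_length(t)) < 0.05
    got <- find_seeds(q, t, params)
    ref <- oracle_seeds(q, t, params$k)
    expect_equal(got[c("q_start", "t_start")], ref,
                 ignore_attr = TRUE)
  }
})

test_that("extend_seed: identity, tie truncation, boundary cases", {
  # identical 10 nt sequences: motif covers all 10 nt
  s10 <- rand_seq(10, seed = 1)
  m <- extend_seed(s10, s10, list(q_start = 0L, t_start = 0L, length = 8L,
                                  orientation = "+"), params)
  expect_equal(c(m$q_start, m$q_end, m$p, m$q, m$score), c(0, 10, 10, 0, 100))

  # mismatch then match: running score ties at 8; shorter region wins
  m <- extend_seed(dna_seq("q", "ACGTACGTAG"), dna_seq("t", "ACGTACGTTG"),
                   list(q_start = 0L, t_start = 0L, length = 8L,
                        orientation = "+"), params)
  expect_equal(c(m$q_end - m$q_start, m$p, m$q, m$score), c(8, 8, 0, 64))

  # seed abutting the sequence start: upstream extension empty, no error
  q <- dna_seq("q", "ACGTACGTCC")
  t <- dna_seq("t", "ACGTACGTCC")
  m <- extend_seed(q, t, list(q_start = 0L, t_start = 0L, length = 8L,
                              orientation = "+"), params)
  expect_equal(m$q_start, 0)
})

test_that("extension equals the exhaustive-prefix oracle on random seeds", {
  set.seed(202)
  n_checked <- 0L
  for (i in 1:40) {
    q <- rand_seq(sample(80:300, 1), id = "q")
    t <- rand_seq(sample(80:300, 1), id = "t")
    seeds <- find_seeds(q, t, params)
    if (nrow(seeds) == 0L) next
    for (j in seq_len(min(5L, nrow(seeds)))) {
      got <- extend_seed(q, t, seeds[j, ], params)
      ref <- oracle_extend(q, t, seeds[j, ], params)
      expect_equal(got$q_start, ref$q_start)
      expect_equal(got$q_end, ref$q_end)
      expect_equal(got$t_start, ref$t_start)
      expect_equal(got$t_end, ref$t_end)
      expect_equal(got$score, ref$score)
      n_checked <- n_checked + 1L
    }
  }
  expect_gte(n_checked, 20L)
})

test_that("build_raw_profile merges strands and maps reverse coordinates", {
  # target = reverse complement of query: one full-length reverse motif
  q <- rand_seq(40, seed = 7, id = "q")
  t <- reverse_complement(q)
  t$id <- "t"
  prof <- build_raw_profile(q, t, params)
  expect_equal(nrow(prof$motifs), 1L)
  expect_equal(prof$motifs$orientation, "-")
  expect_equal(c(prof$motifs$t_start, prof$motifs$t_end), c(0, 40))
  expect_equal(prof$motifs$p, 40)

  # no shared k-mers on either strand: empty profile
  q2 <- dna_seq("q", strrep("A", 30))
  t2 <- dna_seq("t", strrep("C", 30))
  expect_equal(nrow(build_raw_profile(q2, t2, params)$motifs), 0L)
})

test_that("strand antisymmetry: profiles mirror under target revcomp", {
  set.seed(303)
  for (i in 1:5) {
    q <- rand_seq(100, id = "q")
    t <- rand_seq(300, id = "t")
    L <- seq_length(t)
    pf <- build_raw_profile(q, t, params)$motifs
    pr <- build_raw_profile(q, reverse_complement(t), params)$motifs
    if (nrow(pr) > 0L) {
      ts <- L - pr$t_end; te <- L - pr$t_start
      pr$t_start <- ts; pr$t_end <- te
      pr$orientation <- ifelse(pr$orientation == "+", "-", "+")
    }
    expect_equal(motif_key(pf), motif_key(pr))
  }
})

test_that("filter_overlaps: disjoint kept, equal scores may overlap", {
  m1 <- mk_motif(0, 0, rep(TRUE, 12))
  m2 <- mk_motif(30, 30, rep(TRUE, 12))
  out <- filter_overlaps(rbind(m1, m2), axis = "target", params = params,
                         axis_len = 100)
  expect_equal(nrow(out), 2L)
  expect_equal(motif_key(out), motif_key(rbind(m1, m2)))

  # equal-score overlap: both kept unmodified
  m3 <- mk_motif(0, 0, rep(TRUE, 12))
  m4 <- mk_motif(50, 6, rep(TRUE, 12))   # overlaps m3 on target, same score
  out <- filter_overlaps(rbind(m3, m4), axis = "target", params = params,
                         axis_len = 100)
  expect_equal(nrow(out), 2L)
  expect_equal(sort(out$t_start), c(0, 6))
  expect_equal(out$length, c(12L, 12L))

  # unequal scores: smaller truncated away from the overlap, rescored
  big <- mk_motif(0, 0, rep(TRUE, 20))             # t [0,20), score 400
  small <- mk_motif(40, 12, rep(TRUE, 16))         # t [12,28), score 256
  out <- filter_overlaps(rbind(big, small), axis = "target",
                         params = params, axis_len = 100)
  expect_equal(nrow(out), 2L)
  sm <- out[out$q_start >= 40, ]
  expect_equal(c(sm$t_start, sm$t_end), c(20, 28))
  expect_equal(c(sm$q_start, sm$q_end), c(48, 56))
  expect_equal(sm$score, score_motif(8, 0, params))
  # remaining perfect core shorter than k: motif discarded outright
  out_drop <- filter_overlaps(rbind(big, mk_motif(40, 15, rep(TRUE, 12))),
                              axis = "target", params = params,
                              axis_len = 100)
  expect_equal(nrow(out_drop), 1L)
})

test_that("filter_overlaps equals the brute-force reference and is idempotent", {
  set.seed(404)
  for (i in 1:40) {
    ms <- rand_motif_set(sample(5:20, 1), qlen = 300, tlen = 300, params)
    for (axis in c("target", "query")) {
      got <- filter_overlaps(ms, axis = axis, params = params,
                             axis_len = 300)
      ref <- oracle_filter(ms, axis, params)
      expect_equal(motif_key(got), motif_key(ref))
      again <- filter_overlaps(got, axis = axis, params = params,
                               axis_len = 300)
      expect_equal(motif_key(again), motif_key(got))
      # surviving overlapping motifs on the filtered axis have equal scores
      st <- if (axis == "target") got$t_start else got$q_start
      en <- if (axis == "target") got$t_end else got$q_end
      if (nrow(got) > 1L) {
        for (a in 1:(nrow(got) - 1L)) {
          for (b in (a + 1L):nrow(got)) {
            if (st[a] < en[b] && st[b] < en[a]) {
              expect_equal(got$score[a], got$score[b])
            }
          }
        }
      }
    }
  }
})
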