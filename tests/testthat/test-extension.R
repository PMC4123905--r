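m62 <- load_score_matrix()

test_that("identity seeds extend to the full identity run", {
  ct <- concat_sequences(c(s = "LKMNPWWWQRSTA"))
  idx <- build_suffix_array(ct)
  seeds <- data.frame(q_pos = 6L, db_pos = 6L, length = 3L, score = 33L)
  h <- ungapped_extend(seeds, idx, idx, m62, x_drop = 20L)
  expect_equal(h$q_start, 1L)
  expect_equal(h$q_end, 13L)
  expect_equal(h$score, exact_match_score("LKMNPWWWQRSTA", m62))
})

test_that("extension never crosses delimiters", {
  ct <- concat_sequences(c(a = "WWW", b = "WWW"))
  idx <- build_suffix_array(ct)
  seeds <- data.frame(q_pos = 5L, db_pos = 5L, length = 3L, score = 33L)
  h <- ungapped_extend(seeds, idx, idx, m62, x_drop = 100L)
  expect_equal(c(h$q_start, h$q_end, h$db_start, h$db_end),
               c(5L, 7L, 5L, 7L))
})

test_that("ungapped extension equals the exhaustive dropoff-reachable search", {
  set.seed(201)
  for (i in 1:200) {
    qc <- rand_concat(2, c(20, 60))
    dbc <- rand_concat(2, c(20, 60))
    q_pos <- sample(which(strsplit(qc$text, "")[[1]] != "#"), 1)
    db_pos <- sample(which(strsplit(dbc$text, "")[[1]] != "#"), 1)
    len <- sample(1:3, 1)
    if (grepl("#", substring(qc$text, q_pos, q_pos + len - 1)) ||
        q_pos + len - 1 > nchar(qc$text) ||
        grepl("#", substring(dbc$text, db_pos, db_pos + len - 1)) ||
        db_pos + len - 1 > nchar(dbc$text)) next
    x_drop <- sample(c(5L, 20L, 40L), 1)
    seeds <- data.frame(q_pos = q_pos, db_pos = db_pos, length = len,
                        score = 0L)
    got <- ungapped_extend(seeds, build_suffix_array(qc),
                           build_suffix_array(dbc), m62, x_drop)
    want <- naive_ungapped(qc$text, dbc$text, q_pos, db_pos, len,
                           m62$scores, x_drop)
    expect_equal(unlist(got[1, 1:5]), want[1:5],
                 ignore_attr = TRUE)
  }
})

test_that("chain filter merges by the two conditions only", {
  q <- concat_sequences(c(q = "WWWWAAAAWWWW"))
  d <- concat_sequences(c(s = "WWWWAAAAWWWW"))
  qi <- build_suffix_array(q)
  di <- build_suffix_array(d)
  # identical extents collapse
  two <- data.frame(q_start = c(1L, 1L), q_end = c(4L, 4L),
                    db_start = c(1L, 1L), db_end = c(4L, 4L),
                    score = c(44L, 44L), diagonal = c(0L, 0L))
  expect_equal(nrow(chain_filter(two, qi, di, m62, 20L)), 1L)
  # different diagonals untouched
  offdiag <- data.frame(q_start = c(1L, 2L), q_end = c(4L, 5L),
                        db_start = c(1L, 4L), db_end = c(4L, 7L),
                        score = c(44L, 20L), diagonal = c(0L, 2L))
  expect_equal(nrow(chain_filter(offdiag, qi, di, m62, 20L)), 2L)
  # same diagonal, cheap one-residue gap: merged and rescored
  near <- data.frame(q_start = c(1L, 6L), q_end = c(4L, 12L),
                     db_start = c(1L, 6L), db_end = c(4L, 12L),
                     score = c(44L, 0L), diagonal = c(0L, 0L))
  merged <- chain_filter(near, qi, di, m62, 20L)
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$q_start, 1L)
  expect_equal(merged$q_end, 12L)
  expect_equal(merged$score,
               pair_score("WWWWAAAAWWWW", "WWWWAAAAWWWW", m62))
  # same diagonal but an expensive intervening segment: kept apart
  qg <- concat_sequences(c(q = paste0("WWWW", strrep("W", 8), "WWWW")))
  dg <- concat_sequences(c(s = paste0("WWWW", strrep("P", 8), "WWWW")))
  far <- data.frame(q_start = c(1L, 13L), q_end = c(4L, 16L),
                    db_start = c(1L, 13L), db_end = c(4L, 16L),
                    score = c(44L, 44L), diagonal = c(0L, 0L))
  # intervening W-vs-P segment scores 8 * (-4) = -32 < -20
  kept <- chain_filter(far, build_suffix_array(qg),
                       build_suffix_array(dg), m62, 20L)
  expect_equal(nrow(kept), 2L)
})

test_that("chain filter is idempotent and leaves no mergeable pair", {
  set.seed(211)
  for (i in 1:100) {
    qc <- rand_concat(2, c(40, 80))
    dbc <- rand_concat(2, c(40, 80))
    qi <- build_suffix_array(qc)
    di <- build_suffix_array(dbc)
    p <- search_params(t_seed = 20L, d = 7L)
    seeds <- seed_search(qi, di, m62, p)
    if (nrow(seeds) == 0L) next
    hsps <- ungapped_extend(seeds, qi, di, m62, 20L)
    f1 <- chain_filter(hsps, qi, di, m62, 20L)
    f2 <- chain_filter(f1, qi, di, m62, 20L)
    expect_equal(f1, f2)
    # post-condition: no same-diagonal pair overlaps or chains cheaply
    by_diag <- split(f1, f1$diagonal)
    for (g in by_diag) {
      if (nrow(g) < 2) next
      g <- g[order(g$q_start), ]
      for (k in seq_len(nrow(g) - 1)) {
        expect_gt(g$q_start[k + 1], g$q_end[k] + 1L)
        gap_q <- substring(qc$text, g$q_end[k] + 1L, g$q_start[k + 1] - 1L)
        gap_d <- substring(dbc$text, g$db_end[k] + 1L,
                           g$db_start[k + 1] - 1L)
        if (!grepl("#", gap_q) && !grepl("#", gap_d))
          expect_lt(pair_score(gap_q, gap_d, m62), -20L)
      }
    }
  }
})

test_that("gapped extension with infinite dropoff equals anchored local DP", {
  set.seed(221)
  for (i in 1:50) {
    n <- sample(40:150, 1)
    m <- sample(40:150, 1)
    qs <- rand_protein(n)
    ss <- rand_protein(m)
    # plant a shared segment so the anchor sits on signal
    seg <- rand_protein(sample(8:15, 1))
    qa <- sample(seq_len(n - nchar(seg)), 1)
    sa <- sample(seq_len(m - nchar(seg)), 1)
    qs <- paste0(substring(qs, 1, qa - 1), seg,
                 substring(qs, qa + nchar(seg), n))
    ss <- paste0(substring(ss, 1, sa - 1), seg,
                 substring(ss, sa + nchar(seg), m))
    anchor_off <- sample(seq_len(nchar(seg)), 1) - 1L
    hsp <- data.frame(q_start = qa + anchor_off, q_end = qa + anchor_off,
                      db_start = sa + anchor_off, db_end = sa + anchor_off,
                      score = 10L, diagonal = 0L)
    got <- gapped_extend(hsp, build_suffix_array(qs),
                         build_suffix_array(ss), m62,
                         search_params(), x_drop = Inf)
    want <- anchored_sw_score(qs, ss, qa + anchor_off, sa + anchor_off,
                              m62$scores, 11, 1)
    expect_equal(got$score, want)
    # statistics are mutually consistent
    expect_equal(got$n_ident + got$n_mismatch +
                   (got$align_len - got$n_ident - got$n_mismatch),
                 got$align_len)
  }
})

test_that("gapped score is monotone in the dropoff and exact on identity", {
  set.seed(231)
  qs <- rand_protein(80)
  hsp <- data.frame(q_start = 30L, q_end = 40L, db_start = 30L,
                    db_end = 40L, score = 50L, diagonal = 0L)
  qi <- build_suffix_array(qs)
  ident <- gapped_extend(hsp, qi, qi, m62, search_params(), x_drop = Inf)
  expect_equal(ident$score, exact_match_score(qs, m62))
  expect_equal(ident$n_gapopen, 0L)
  expect_equal(ident$n_ident, 80L)
  ss <- rand_protein(80)
  s_inf <- gapped_extend(hsp, qi, build_suffix_array(ss), m62,
                         search_params(), x_drop = Inf)$score
  for (xd in c(0L, 10L, 38L)) {
    s_fin <- gapped_extend(hsp, qi, build_suffix_array(ss), m62,
                           search_params(), x_drop = xd)$score
    expect_lte(s_fin, s_inf)
  }
})

test_that("a planted two-residue insertion yields exactly one gap of length 2", {
  set.seed(241)
  base <- rand_protein(60)
  ins <- paste0(substring(base, 1, 30), "KR", substring(base, 31, 60))
  hsp <- data.frame(q_start = 10L, q_end = 20L, db_start = 10L,
                    db_end = 20L, score = 40L, diagonal = 0L)
  g <- gapped_extend(hsp, build_suffix_array(ins),
                     build_suffix_array(base), m62, search_params(),
                     x_drop = Inf)
  expect_equal(g$n_gapopen, 1L)
  expect_equal(g$align_len - g$n_ident - g$n_mismatch, 2L)
  expect_equal(g$score, exact_match_score(base, m62) - 11L - 2L)
})
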