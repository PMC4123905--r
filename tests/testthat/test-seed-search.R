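m62 <- load_score_matrix()

test_that("worked tripeptide pairs behave as the thresholds dictate", {
  p <- search_params()  # T_seed = 30, D = 4
  db <- build_suffix_array(concat_sequences(c(s = "WWW")))
  q <- build_suffix_array(concat_sequences(c(q = "WWW")))
  s <- seed_search(q, db, m62, p)
  expect_equal(nrow(s), 1L)
  expect_equal(s$length, 3L)
  expect_equal(s$score, 33L)  # prefixes score 11, 22: survive both prunes
  # AAA vs AAA: prefix scores 4, 8, 12 never reach 30
  dbA <- build_suffix_array(concat_sequences(c(s = "AAA")))
  qA <- build_suffix_array(concat_sequences(c(q = "AAA")))
  expect_equal(nrow(seed_search(qA, dbA, m62, p)), 0L)
})

test_that("pruning rules fire exactly as specified on two-residue states", {
  # {AA, AR}: score_max 8, score 3 <= 8 - 4 -> pruned under D = 4
  p <- search_params(t_seed = 100L, d = 4L)
  q <- build_suffix_array(concat_sequences(c(q = "AAW")))
  db <- build_suffix_array(concat_sequences(c(s = "ARW")))
  s <- seed_search(q, db, m62, p)
  o <- seed_search_oracle(q$text, db$text, m62, p)
  expect_same_seeds(s, o)
  expect_equal(nrow(s), 0L)
  # with D = 7 the state survives: 3 > 8 - 7
  p7 <- search_params(t_seed = 14L, d = 7L, length_max = 3L)
  s7 <- seed_search(q, db, m62, p7)
  o7 <- seed_search_oracle(q$text, db$text, m62, p7)
  expect_same_seeds(s7, o7)
  # {A, R} scores -1 <= 0: never extended
  pAR <- search_params(t_seed = 5L, d = 100L)
  qA <- build_suffix_array(concat_sequences(c(q = "AR")))
  dbR <- build_suffix_array(concat_sequences(c(s = "RA")))
  sAR <- seed_search(qA, dbR, m62, pAR)
  expect_true(!any(sAR$q_pos == 1L & sAR$db_pos == 1L & sAR$length > 1L))
})

test_that("search equals the per-pair walk on random concatenated texts", {
  set.seed(101)
  grid <- expand.grid(t_seed = c(22L, 26L, 30L), d = c(1L, 4L, 7L))
  for (i in 1:30) {
    g <- grid[(i - 1) %% nrow(grid) + 1, ]
    p <- search_params(t_seed = g$t_seed, d = g$d)
    dbc <- rand_concat(sample(2:4, 1), c(30, 120))
    qc <- rand_concat(sample(1:3, 1), c(20, 80))
    db <- build_suffix_array(dbc)
    if (i %% 3 == 0) db <- build_prefix_table(db)
    q <- build_suffix_array(qc)
    expect_same_seeds(seed_search(q, db, m62, p),
                      seed_search_oracle(qc, dbc, m62, p))
  }
})

test_that("adversarial low-complexity texts agree with the walk", {
  p <- search_params(t_seed = 22L, d = 4L)
  cases <- list(
    list(q = strrep("W", 40), db = strrep("W", 60)),
    list(q = strrep("A", 50), db = strrep("A", 50)),
    list(q = strrep("LK", 25), db = strrep("LK", 30)),
    list(q = paste0(strrep("W", 20), strrep("A", 20)),
         db = paste0(strrep("A", 20), strrep("W", 20))))
  for (cs in cases) {
    q <- build_suffix_array(concat_sequences(c(q = cs$q)))
    db <- build_suffix_array(concat_sequences(c(s = cs$db)))
    expect_same_seeds(seed_search(q, db, m62, p),
                      seed_search_oracle(cs$q, cs$db, m62, p))
  }
})

test_that("every emitted seed re-walks cleanly under the rules", {
  set.seed(111)
  p <- search_params(t_seed = 24L, d = 4L)
  shared <- rand_protein(8)  # planted so at least one seed exists
  qc <- concat_sequences(c(q1 = paste0(rand_protein(40), shared,
                                       rand_protein(40)),
                           q2 = rand_protein(60)))
  dbc <- concat_sequences(c(s1 = rand_protein(70),
                            s2 = paste0(rand_protein(30), shared,
                                        rand_protein(50)),
                            s3 = rand_protein(80)))
  seeds <- seed_search(build_suffix_array(qc), build_suffix_array(dbc),
                       m62, p)
  expect_gt(nrow(seeds), 0L)
  S <- m62$scores
  for (i in seq_len(nrow(seeds))) {
    sd <- seeds[i, ]
    qs <- strsplit(substring(qc$text, sd$q_pos,
                             sd$q_pos + sd$length - 1), "")[[1]]
    ds <- strsplit(substring(dbc$text, sd$db_pos,
                             sd$db_pos + sd$length - 1), "")[[1]]
    expect_false(any(qs == "#") || any(ds == "#"))
    expect_lte(sd$length, p$length_max)
    run <- cumsum(S[cbind(qs, ds)])
    run_max <- cumsum(S[cbind(qs, qs)])
    expect_equal(run[sd$length], sd$score)
    expect_gte(sd$score, p$t_seed)
    if (sd$length > 1) {
      pref <- seq_len(sd$length - 1)
      expect_true(all(run[pref] > 0))
      expect_true(all(run[pref] > run_max[pref] - p$d))
      expect_true(all(run[pref] < p$t_seed))
    }
  }
})

test_that("seed sets shrink with T_seed and grow with D", {
  set.seed(121)
  qc <- rand_concat(2, c(60, 100))
  dbc <- rand_concat(3, c(80, 160))
  q <- build_suffix_array(qc)
  db <- build_suffix_array(dbc)
  prev <- NULL
  for (ts in c(22L, 24L, 26L, 28L, 30L, 32L)) {
    cur <- seed_key(seed_search(q, db, m62,
                                search_params(t_seed = ts, d = 4L)))
    if (!is.null(prev)) expect_true(all(cur %in% prev))
    prev <- cur
  }
  prev <- NULL
  for (d in c(1L, 4L, 7L)) {
    cur <- seed_key(seed_search(q, db, m62,
                                search_params(t_seed = 22L, d = d)))
    if (!is.null(prev)) expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("expand_state enumerates the rank cross product with a cap", {
  set.seed(131)
  ct <- concat_sequences(c(a = "WWAWW", b = "WWA"))
  idx <- build_suffix_array(ct)
  ivq <- sa_interval(2L, 4L, 1L)
  ivdb <- sa_interval(1L, 4L, 1L)
  got <- expand_state(idx, idx, ivq, ivdb, score = 11L)
  expect_equal(nrow(got), 6L)
  capped <- expand_state(idx, idx, ivq, ivdb, score = 11L, max_pairs = 4)
  expect_equal(nrow(capped), 4L)
  expect_equal(capped, got[1:4, ])
  # a state's seeds re-read to the same database substring
  p <- search_params(t_seed = 22L, d = 4L)
  qc <- rand_concat(1, c(60, 60))
  dbc <- rand_concat(2, c(60, 60))
  seeds <- seed_search(build_suffix_array(qc), build_suffix_array(dbc),
                       m62, p)
  for (i in seq_len(min(nrow(seeds), 20))) {
    expect_equal(
      pair_score(substring(qc$text, seeds$q_pos[i],
                           seeds$q_pos[i] + seeds$length[i] - 1),
                 substring(dbc$text, seeds$db_pos[i],
                           seeds$db_pos[i] + seeds$length[i] - 1), m62),
      seeds$score[i])
  }
})

test_that("the per-state cap bounds emission deterministically", {
  p <- search_params(t_seed = 22L, d = 4L, max_interval_product = 3)
  q <- build_suffix_array(concat_sequences(c(q = strrep("W", 10))))
  db <- build_suffix_array(concat_sequences(c(s = strrep("W", 10))))
  s_cap <- seed_search(q, db, m62, p)
  s_all <- seed_search(q, db, m62,
                       search_params(t_seed = 22L, d = 4L))
  expect_lt(nrow(s_cap), nrow(s_all))
  expect_true(all(seed_key(s_cap) %in% seed_key(s_all)))
})
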