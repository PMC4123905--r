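# Independent reference implementations used across the suite. All are
# deliberately naive (quadratic sorts, full scans, plain-loop DP) and share
# no code with the package's C++ kernels.

RES20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

rand_protein <- function(len) paste(sample(RES20, len, TRUE), collapse = "")

rand_concat <- function(n_seqs, len_range) {
  lens <- sample(len_range[1]:len_range[2], n_seqs, TRUE)
  concat_sequences(setNames(vapply(lens, rand_protein, ""),
                            paste0("s", seq_len(n_seqs))))
}

# naive suffix sort; byte order coincides with the package collation
# ('#' 0x23 < '*' 0x2A < letters)
naive_suffix_array <- function(text) {
  n <- nchar(text)
  order(substring(text, seq_len(n), n), method = "radix")
}

# linear-scan interval narrowing; symbol comparisons by byte code so the
# reference is locale-independent (the package collation is byte order for
# its ASCII alphabet)
naive_narrow <- function(text, positions, sp, ep, depth, ch) {
  if (sp >= ep) return(c(sp, sp))
  ranks <- sp:(ep - 1)
  codes <- utf8ToInt(text)[positions[ranks] + depth]  # NA past the end
  target <- utf8ToInt(ch)
  hit <- !is.na(codes) & codes == target
  if (!any(hit))
    return(rep(sp + sum(is.na(codes) | codes < target), 2))
  c(sp + which(hit)[1] - 1, sp + max(which(hit)))
}

seed_key <- function(df) paste(df$q_pos, df$db_pos, df$length, df$score)

expect_same_seeds <- function(a, b) {
  expect_equal(anyDuplicated(seed_key(a)), 0L)
  expect_equal(anyDuplicated(seed_key(b)), 0L)
  expect_setequal(seed_key(a), seed_key(b))
}

# exhaustive ungapped best-extent search restricted to dropoff-reachable
# extensions, replicated per direction with plain loops
naive_ungapped <- function(q_text, db_text, q_pos, db_pos, len, S, x_drop) {
  score_at <- function(qi, di)
    S[substring(q_text, qi, qi), substring(db_text, di, di)]
  seed_score <- sum(vapply(seq_len(len) - 1L, function(k)
    score_at(q_pos + k, db_pos + k), 0L))
  reach <- function(step_q, step_d, from_q, from_d) {
    run <- seed_score
    best <- seed_score
    ext <- 0L
    t <- 1L
    repeat {
      qi <- from_q + step_q * t
      di <- from_d + step_d * t
      if (qi < 1L || di < 1L || qi > nchar(q_text) || di > nchar(db_text))
        break
      cq <- substring(q_text, qi, qi)
      cd <- substring(db_text, di, di)
      if (cq == "#" || cd == "#") break
      run <- run + S[cq, cd]
      if (run > best) {
        best <- run
        ext <- t
      } else if (run < best - x_drop) break
      t <- t + 1L
    }
    list(best = best, ext = ext)
  }
  r <- reach(1L, 1L, q_pos + len - 1L, db_pos + len - 1L)
  l <- reach(-1L, -1L, q_pos, db_pos)
  c(q_start = q_pos - l$ext, q_end = q_pos + len - 1L + r$ext,
    db_start = db_pos - l$ext, db_end = db_pos + len - 1L + r$ext,
    score = l$best + r$best - seed_score)
}

# plain-loop affine extension DP from a corner (no dropoff); returns the
# best score over all consumed prefix pairs, optionally forcing at least
# one residue of each side (so the corner pair itself is aligned)
naive_half_best <- function(q, s, S, go, ge, force) {
  n <- nchar(q)
  m <- nchar(s)
  NEG <- -1e9
  H <- matrix(NEG, n + 1, m + 1)
  E <- matrix(NEG, n + 1, m + 1)
  F_ <- matrix(NEG, n + 1, m + 1)
  H[1, 1] <- 0
  qs <- strsplit(q, "")[[1]]
  ss <- strsplit(s, "")[[1]]
  for (i in 0:n) for (j in 0:m) {
    if (i == 0 && j == 0) next
    e <- f <- h <- NEG
    if (j > 0) e <- max(H[i + 1, j] - go - ge, E[i + 1, j] - ge)
    if (i > 0) f <- max(H[i, j + 1] - go - ge, F_[i, j + 1] - ge)
    if (i > 0 && j > 0 && H[i, j] > NEG / 2)
      h <- H[i, j] + S[qs[i], ss[j]]
    E[i + 1, j + 1] <- e
    F_[i + 1, j + 1] <- f
    H[i + 1, j + 1] <- max(h, e, f)
  }
  if (force) {
    if (n == 0 || m == 0) return(NEG)
    max(H[2:(n + 1), 2:(m + 1)])
  } else {
    max(H)
  }
}

# optimal local alignment score through the anchor cell (qa, sa aligned)
anchored_sw_score <- function(q, s, qa, sa, S, go, ge) {
  revstr <- function(x) paste(rev(strsplit(x, "")[[1]]), collapse = "")
  left <- naive_half_best(revstr(substring(q, 1, qa)),
                          revstr(substring(s, 1, sa)), S, go, ge, TRUE)
  right <- naive_half_best(substring(q, qa + 1, nchar(q)),
                           substring(s, sa + 1, nchar(s)), S, go, ge, FALSE)
  left + right
}
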