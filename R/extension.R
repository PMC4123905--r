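#' X-drop ungapped extension of seeds
#'
#' Extends each seed left from its start and right from its end one residue
#' at a time, tracking running and best scores per direction; a direction
#' stops at a text boundary, at a delimiter, or once the running score falls
#' below `best - x_drop`. Returns the best-scoring gap-free extent
#' containing the seed (a high-scoring segment pair).
#'
#' @param seeds data.frame from [seed_search()] (`q_pos`, `db_pos`,
#'   `length`, `score`).
#' @param q_index,db_index the two [sa_index][build_suffix_array] objects
#'   (or texts).
#' @param m a [score_matrix][load_score_matrix].
#' @param x_drop raw-score dropoff.
#' @param dedup drop duplicate extents (distinct seeds often extend to the
#'   same HSP).
#' @return data.frame with `q_start`, `q_end`, `db_start`, `db_end`
#'   (1-based inclusive), `score`, `diagonal` (`db_start - q_start`).
#' @export
ungapped_extend <- function(seeds, q_index, db_index,
                            m = load_score_matrix(), x_drop = 20L,
                            dedup = TRUE) {
  q_index <- as_sa_index(q_index)
  db_index <- as_sa_index(db_index)
  if (nrow(seeds) == 0L)
    return(data.frame(q_start = integer(), q_end = integer(),
                      db_start = integer(), db_end = integer(),
                      score = integer(), diagonal = integer()))
  res <- cpp_ungapped_extend(q_index$text$text, db_index$text$text,
                             as.matrix(seeds[, c("q_pos", "db_pos",
                                                 "length", "score")]),
                             score_table256(m), as.integer(x_drop), SAX_DELIM)
  out <- as.data.frame(res)
  out$diagonal <- out$db_start - out$q_start
  if (dedup) out <- unique(out)
  rownames(out) <- NULL
  out
}

#' Merge redundant same-diagonal HSPs
#'
#' Chain filtering over gap-free extents from one query/subject context.
#' Within each diagonal, extents sorted by start are merged in two cases:
#' overlapping extents are combined into their coordinate union, and
#' non-overlapping extents are combined when the ungapped score of the
#' intervening diagonal segment stays above `-x_drop` (the dropoff used for
#' ungapped extension). Merged extents are rescored over the union and
#' merging repeats to a fixed point. Extents on different diagonals, or in
#' different subject sequences, are never merged.
#'
#' @param hsps data.frame from [ungapped_extend()].
#' @param q_index,db_index the two [sa_index][build_suffix_array] objects
#'   (or texts).
#' @param m a [score_matrix][load_score_matrix].
#' @param x_drop the ungapped dropoff.
#' @return data.frame of the same shape; idempotent.
#' @export
chain_filter <- function(hsps, q_index, db_index, m = load_score_matrix(),
                         x_drop = 20L) {
  q_index <- as_sa_index(q_index)
  db_index <- as_sa_index(db_index)
  if (nrow(hsps) == 0L) return(hsps)
  q_text <- q_index$text$text
  db_text <- db_index$text$text
  subject_of <- findInterval(hsps$db_start, db_index$text$boundaries)
  query_of <- findInterval(hsps$q_start, q_index$text$boundaries)
  groups <- split(hsps, list(hsps$diagonal, subject_of, query_of),
                  drop = TRUE)
  merged <- lapply(groups, function(g) {
    g <- g[order(g$q_start, g$q_end), , drop = FALSE]
    repeat {
      changed <- FALSE
      i <- 1L
      while (i < nrow(g)) {
        a <- g[i, ]
        b <- g[i + 1L, ]
        overlap <- b$q_start <= a$q_end + 1L
        join <- overlap
        if (!overlap) {
          gap_q <- substring(q_text, a$q_end + 1L, b$q_start - 1L)
          gap_db <- substring(db_text, a$db_end + 1L, b$db_start - 1L)
          join <- !grepl(SAX_DELIM, gap_db, fixed = TRUE) &&
            pair_score(gap_q, gap_db, m) >= -x_drop
        }
        if (join) {
          u <- a
          u$q_end <- max(a$q_end, b$q_end)
          u$db_end <- max(a$db_end, b$db_end)
          u$score <- pair_score(substring(q_text, u$q_start, u$q_end),
                                substring(db_text, u$db_start, u$db_end), m)
          g <- rbind(g[seq_len(i - 1L), , drop = FALSE], u,
                     g[-seq_len(i + 1L), , drop = FALSE])
          changed <- TRUE
        } else {
          i <- i + 1L
        }
      }
      if (!changed) break
    }
    g
  })
  out <- do.call(rbind, merged)
  out <- out[order(out$diagonal, out$q_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# anchor for gapped extension: midpoint of the maximal-scoring gap-free
# sub-segment of the HSP (max-subarray over per-position scores)
hsp_anchor <- function(hsp, q_text, db_text, m) {
  qs <- strsplit(substring(q_text, hsp$q_start, hsp$q_end), "")[[1L]]
  ds <- strsplit(substring(db_text, hsp$db_start, hsp$db_end), "")[[1L]]
  s <- m$scores[cbind(qs, ds)]
  best <- 0L
  run <- 0L
  start <- 1L
  b_start <- 1L
  b_end <- 1L
  for (i in seq_along(s)) {
    if (run <= 0L) {
      run <- s[i]
      start <- i
    } else {
      run <- run + s[i]
    }
    if (run > best) {
      best <- run
      b_start <- start
      b_end <- i
    }
  }
  (b_start + b_end) %/% 2L
}

#' X-drop gapped extension of a chained HSP
#'
#' Affine-gap dynamic programming outward from an anchor cell — the
#' midpoint of the HSP's maximal-scoring segment — in both directions,
#' dropping cells that fall more than `x_drop_gapped` below the running
#' best. With an infinite dropoff this yields the optimal local alignment
#' through the anchor. The DP runs on the full query-side sequence and the
#' subject sequence containing the HSP, never across delimiters.
#'
#' @param hsp one row from [chain_filter()].
#' @param q_index,db_index the two [sa_index][build_suffix_array] objects.
#' @param m a [score_matrix][load_score_matrix].
#' @param params a [search_params()] (gap penalties and `x_drop_gapped`).
#' @param x_drop override for the gapped dropoff (`Inf` allowed).
#' @return One-row data.frame: `q_start`, `q_end`, `db_start`, `db_end`
#'   (concatenated-text coordinates), `score`, `n_ident`, `n_mismatch`,
#'   `n_gapopen`, `align_len`, `q_seq_index`, `db_seq_index`.
#' @export
gapped_extend <- function(hsp, q_index, db_index, m = load_score_matrix(),
                          params = search_params(),
                          x_drop = params$x_drop_gapped) {
  q_index <- as_sa_index(q_index)
  db_index <- as_sa_index(db_index)
  qct <- q_index$text
  dct <- db_index$text
  qi <- findInterval(hsp$q_start, qct$boundaries)
  di <- findInterval(hsp$db_start, dct$boundaries)
  q_seq <- substring(qct$text, qct$boundaries[qi],
                     qct$boundaries[qi] + qct$lengths[qi] - 1L)
  d_seq <- substring(dct$text, dct$boundaries[di],
                     dct$boundaries[di] + dct$lengths[di] - 1L)
  off <- hsp_anchor(hsp, qct$text, dct$text, m) - 1L
  qa <- hsp$q_start - qct$boundaries[qi] + 1L + off
  da <- hsp$db_start - dct$boundaries[di] + 1L + off
  r <- cpp_gapped_extend(q_seq, d_seq, qa, da, score_table256(m),
                         params$gap_open, params$gap_extend, x_drop)
  data.frame(q_start = r$q_start + qct$boundaries[qi] - 1L,
             q_end = r$q_end + qct$boundaries[qi] - 1L,
             db_start = r$s_start + dct$boundaries[di] - 1L,
             db_end = r$s_end + dct$boundaries[di] - 1L,
             score = r$score, n_ident = r$n_ident,
             n_mismatch = r$n_mismatch, n_gapopen = r$n_gapopen,
             align_len = r$length, q_seq_index = qi, db_seq_index = di)
}
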