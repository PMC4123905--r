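#' Search parameters
#'
#' Bundles every tunable of the pipeline. `t_seed` and `d` are the two
#' seed-search controls: seeds are emitted once their substitution score
#' reaches `t_seed` (default 30), and a substring pair is abandoned when its
#' score lags the query substring's exact-match score by `d` or more
#' (default 4), or falls to zero or below. `length_max` bounds seed length;
#' with a BLOSUM62 diagonal of at least 4 and `d = 4`, any pair surviving
#' the score-gap rule to depth 13 would already have been emitted, so 13 is
#' a non-binding default.
#'
#' @param t_seed integer seed score threshold (> 0).
#' @param d score-gap pruning bound (>= 1).
#' @param length_max maximum seed length in residues.
#' @param x_drop_ungapped raw-score dropoff for ungapped extension.
#' @param x_drop_gapped raw-score dropoff for gapped extension.
#' @param gap_open,gap_extend affine gap penalties (positive; a gap of
#'   length L costs `gap_open + gap_extend * L`).
#' @param l_db database chunk budget in residues.
#' @param max_interval_product cap on seeds emitted per interval pair
#'   (`Inf` = no cap).
#' @param max_targets subjects reported per query.
#' @param evalue_max report threshold on E-value.
#' @param block_size query frames per search block (output-neutral knob).
#' @param threads worker processes; never changes the output.
#' @return An object of class `search_params`.
#' @export
search_params <- function(t_seed = 30L, d = 4L, length_max = 13L,
                          x_drop_ungapped = 20L, x_drop_gapped = 38L,
                          gap_open = 11L, gap_extend = 1L,
                          l_db = 2^31 - 1, max_interval_product = Inf,
                          max_targets = 10L, evalue_max = 10,
                          block_size = 2000L, threads = 1L) {
  if (t_seed <= 0) stop("t_seed must be > 0")
  if (d < 1) stop("d must be >= 1")
  if (length_max < 1) stop("length_max must be >= 1")
  if (gap_open <= 0 || gap_extend <= 0) stop("gap penalties must be > 0")
  if (x_drop_ungapped < 0 || x_drop_gapped < 0) stop("dropoffs must be >= 0")
  structure(list(t_seed = as.integer(t_seed), d = as.integer(d),
                 length_max = as.integer(length_max),
                 x_drop_ungapped = as.integer(x_drop_ungapped),
                 x_drop_gapped = as.integer(x_drop_gapped),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 l_db = l_db, max_interval_product = max_interval_product,
                 max_targets = as.integer(max_targets),
                 evalue_max = evalue_max, block_size = as.integer(block_size),
                 threads = as.integer(threads)),
            class = "search_params")
}

as_sa_index <- function(x) {
  if (inherits(x, "sa_index")) return(x)
  if (is.character(x) || inherits(x, "concat_text"))
    return(build_suffix_array(x))
  stop("expected a sa_index, concat_text or string")
}

#' Find score-thresholded variable-length seeds
#'
#' Simultaneous depth-first traversal of the query and database suffix
#' arrays. Each state is a pair of SA intervals sharing a matched length;
#' descending extends both sides by one symbol (at most `|alphabet|^2` child
#' pairs). A state whose pair score reaches `t_seed` is emitted — the cross
#' product of its two intervals becomes coordinate seeds — and is not
#' extended further; states are pruned when the score falls to zero or
#' below, lags the query substring's exact-match score by `d` or more, or
#' reaches `length_max`. Delimiters are never crossed on either side.
#'
#' @param q_index query [sa_index][build_suffix_array] (or text).
#' @param db_index database `sa_index` (or text); uses its prefix table for
#'   database-side narrowing when one is built.
#' @param m a [score_matrix][load_score_matrix].
#' @param params a [search_params()].
#' @return data.frame with `q_pos`, `db_pos` (1-based offsets into the
#'   respective concatenated texts), `length`, `score`; every row has
#'   `score >= t_seed`.
#' @export
seed_search <- function(q_index, db_index, m = load_score_matrix(),
                        params = search_params()) {
  q_index <- as_sa_index(q_index)
  db_index <- as_sa_index(db_index)
  res <- cpp_seed_search(q_index$text$text, q_index$positions,
                         db_index$text$text, db_index$positions,
                         score_table256(m), rank_table256(q_index$alphabet),
                         paste(q_index$alphabet, collapse = ""),
                         params$t_seed, params$d, params$length_max,
                         if (is.finite(params$max_interval_product))
                           params$max_interval_product else -1,
                         SAX_DELIM, db_index$ptable, residue_index256())
  as.data.frame(res)
}

#' Brute-force per-pair seed reference
#'
#' Independent reference for [seed_search()]: for every coordinate pair of
#' non-delimiter positions, walks forward one residue at a time
#' accumulating the pair score and the query exact-match score, emitting at
#' the first length whose score reaches `t_seed` and abandoning the pair at
#' the first length whose score is non-positive or lags the exact-match
#' score by `d` or more. Quadratic in text size; for validation only.
#'
#' @inheritParams seed_search
#' @param q_text,db_text concatenated texts (strings or `concat_text`).
#' @return data.frame as from [seed_search()].
#' @export
seed_search_oracle <- function(q_text, db_text, m = load_score_matrix(),
                               params = search_params()) {
  if (inherits(q_text, "concat_text")) q_text <- q_text$text
  if (inherits(db_text, "concat_text")) db_text <- db_text$text
  res <- cpp_seed_oracle(q_text, db_text, score_table256(m), params$t_seed,
                         params$d, params$length_max, SAX_DELIM)
  as.data.frame(res)
}

#' Expand an emitted search state into coordinate seeds
#'
#' Cross product of the query and database interval ranks, translated to
#' text offsets, in ascending (query rank, database rank) order, truncated
#' at `max_pairs`.
#'
#' @param q_index,db_index the two [sa_index][build_suffix_array] objects.
#' @param iv_q,iv_db the state's [sa_interval]s (equal depth).
#' @param score the state's pair score.
#' @param max_pairs cap on emitted seeds (`Inf` = no cap).
#' @return data.frame with `q_pos`, `db_pos`, `length`, `score`.
#' @export
expand_state <- function(q_index, db_index, iv_q, iv_db, score,
                         max_pairs = Inf) {
  stopifnot(iv_q$depth == iv_db$depth)
  n_q <- interval_size(iv_q)
  n_db <- interval_size(iv_db)
  if (n_q == 0L || n_db == 0L)
    return(data.frame(q_pos = integer(), db_pos = integer(),
                      length = integer(), score = integer()))
  rq <- rep(seq(iv_q$sp, iv_q$ep - 1L), each = n_db)
  rdb <- rep(seq(iv_db$sp, iv_db$ep - 1L), times = n_q)
  keep <- seq_len(min(length(rq), max_pairs))
  data.frame(q_pos = q_index$positions[rq[keep]],
             db_pos = db_index$positions[rdb[keep]],
             length = iv_q$depth, score = as.integer(score))
}
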