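#' Read a FASTA file
#'
#' Multi-line records, CRLF tolerated. Protein sequences are uppercased and
#' symbols outside the 20 residues, `X` and `*` are mapped to `X`; DNA is
#' returned as-is for [translate_six_frames()] to sanitize.
#'
#' @param path FASTA file.
#' @param type `"protein"` or `"dna"`.
#' @return Named character vector (names are the first whitespace-separated
#'   token of each header).
#' @export
read_fasta <- function(path, type = c("protein", "dna")) {
  type <- match.arg(type)
  set <- if (type == "protein") Biostrings::readAAStringSet(path)
         else Biostrings::readDNAStringSet(path)
  if (length(set) == 0L)
    return(setNames(character(), character()))
  widths <- Biostrings::width(set)
  if (any(widths == 0L))
    stop("malformed FASTA record (no sequence body): '",
         names(set)[widths == 0L][1L], "'")
  seqs <- as.character(set)
  names(seqs) <- vapply(strsplit(names(set), "\\s+"), `[`, "", 1L)
  if (type == "protein") {
    seqs <- toupper(seqs)
    seqs <- vapply(seqs, function(s)
      gsub(sprintf("[^%s]", paste(c(SAX_RESIDUES, "X", "\\*"), collapse = "")),
           "X", s), "", USE.NAMES = TRUE)
  }
  seqs
}

# translated (or native) frames for a set of queries
query_frames <- function(queries, query_type) {
  if (query_type == "protein") {
    frames <- data.frame(query_id = names(queries), frame = 0L,
                         protein = unname(queries),
                         dna_length = nchar(unname(queries)),
                         stringsAsFactors = FALSE)
    return(frames)
  }
  do.call(rbind, lapply(names(queries), function(id)
    translate_six_frames(queries[[id]], id)))
}

# frames whose protein is long enough to hold any seed at all
viable_frames <- function(frames) frames[nchar(frames$protein) >= 1L, ,
                                         drop = FALSE]

empty_result <- function() {
  data.frame(query_id = character(), subject_id = character(),
             pident = numeric(), length = integer(), mismatch = integer(),
             gapopen = integer(), q_start = integer(), q_end = integer(),
             s_start = integer(), s_end = integer(), evalue = numeric(),
             bit_score = numeric(), stringsAsFactors = FALSE)
}

# one block of query frames against one database chunk:
# seeds -> ungapped HSPs -> chain filter -> gapped hits -> rows
search_block_chunk <- function(q_index, frames, chunk, m, params, ka,
                               total_db_residues) {
  db_index <- chunk$index
  seeds <- seed_search(q_index, db_index, m, params)
  if (nrow(seeds) == 0L) return(empty_result())
  hsps <- ungapped_extend(seeds, q_index, db_index, m,
                          params$x_drop_ungapped)
  hsps <- hsps[hsps$score > 0L, , drop = FALSE]
  if (nrow(hsps) == 0L) return(empty_result())
  hsps <- chain_filter(hsps, q_index, db_index, m, params$x_drop_ungapped)
  rows <- lapply(seq_len(nrow(hsps)), function(i) {
    g <- gapped_extend(hsps[i, ], q_index, db_index, m, params)
    if (is.na(g$score[1L]) || g$score <= 0L) return(NULL)
    g
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows) || nrow(rows) == 0L) return(empty_result())
  qct <- q_index$text
  dct <- db_index$text
  # frame-local / subject-local coordinates
  rows$frame_row <- rows$q_seq_index
  rows$q_local_start <- rows$q_start - qct$boundaries[rows$q_seq_index] + 1L
  rows$q_local_end <- rows$q_end - qct$boundaries[rows$q_seq_index] + 1L
  rows$s_local_start <- rows$db_start - dct$boundaries[rows$db_seq_index] + 1L
  rows$s_local_end <- rows$db_end - dct$boundaries[rows$db_seq_index] + 1L
  rows$subject_id <- dct$ids[rows$db_seq_index]
  rows$query_id <- frames$query_id[rows$frame_row]
  rows$frame <- frames$frame[rows$frame_row]
  rows$q_frame_len <- nchar(frames$protein[rows$frame_row])
  rows$dna_length <- frames$dna_length[rows$frame_row]
  rows <- unique(rows)
  # cull containment-redundant hits per (query frame, subject)
  keys <- paste(rows$query_id, rows$frame, rows$subject_id)
  kept <- lapply(split(rows, keys), function(g) {
    g <- g[order(-g$score, g$q_local_start, g$s_local_start), , drop = FALSE]
    keep <- rep(TRUE, nrow(g))
    for (i in seq_len(nrow(g))[-1L]) {
      for (j in seq_len(i - 1L)) {
        if (!keep[j]) next
        if (g$q_local_start[i] >= g$q_local_start[j] &&
            g$q_local_end[i] <= g$q_local_end[j] &&
            g$s_local_start[i] >= g$s_local_start[j] &&
            g$s_local_end[i] <= g$s_local_end[j]) {
          keep[i] <- FALSE
          break
        }
      }
    }
    g[keep, , drop = FALSE]
  })
  rows <- do.call(rbind, kept)
  qc <- mapply(function(f, s, e, n) unlist(map_frame_to_dna(f, s, e, n)),
               rows$frame, rows$q_local_start, rows$q_local_end,
               rows$dna_length)
  data.frame(query_id = rows$query_id, subject_id = rows$subject_id,
             pident = round(100 * rows$n_ident / rows$align_len, 2L),
             length = rows$align_len, mismatch = rows$n_mismatch,
             gapopen = rows$n_gapopen,
             q_start = as.integer(qc[1L, ]), q_end = as.integer(qc[2L, ]),
             s_start = rows$s_local_start, s_end = rows$s_local_end,
             evalue = evalue(rows$score, rows$q_frame_len,
                             total_db_residues, ka),
             bit_score = round(bit_score(rows$score, ka), 1L),
             stringsAsFactors = FALSE)
}

#' Search queries against an indexed protein database
#'
#' The full pipeline: queries are translated (DNA) or taken as-is
#' (protein), batched into blocks, and each block is searched against every
#' database chunk through seed search, X-drop ungapped extension, chain
#' filtering and gapped extension. Rows are merged across chunks and
#' frames, deduplicated, sorted per query by bit score (ties: E-value, then
#' subject id) and truncated to `max_targets` subjects per query. The
#' result is invariant under the chunking of the database, the block size
#' and the thread count.
#'
#' @param queries named character vector of sequences, or a FASTA path.
#' @param db a [sax_db][build_index], or an index prefix saved with
#'   [save_index()].
#' @param m a [score_matrix][load_score_matrix].
#' @param params a [search_params()].
#' @param query_type `"dna"` (six-frame translated) or `"protein"`.
#' @param ka [Karlin-Altschul constants][karlin_altschul_params] for
#'   E-values and bit scores.
#' @param verbose log per-stage counts to stderr.
#' @return data.frame of BLAST tabular rows: `query_id`, `subject_id`,
#'   `pident`, `length`, `mismatch`, `gapopen`, `q_start`, `q_end`,
#'   `s_start`, `s_end`, `evalue`, `bit_score`. Query coordinates are on
#'   the DNA read for DNA queries (reverse strand: start > end).
#' @export
sax_search <- function(queries, db, m = load_score_matrix(),
                       params = search_params(),
                       query_type = c("dna", "protein"),
                       ka = karlin_altschul_params(), verbose = FALSE) {
  query_type <- match.arg(query_type)
  if (is.character(queries) && length(queries) == 1L &&
      is.null(names(queries)) && file.exists(queries))
    queries <- read_fasta(queries, type = query_type)
  if (is.character(db) && length(db) == 1L) db <- load_index(db)
  stopifnot(inherits(db, "sax_db"))
  if (length(queries) == 0L) return(empty_result())
  frames <- viable_frames(query_frames(queries, query_type))
  if (nrow(frames) == 0L) return(empty_result())
  # blocks never split one query's frames (parallel partition is by query)
  qids <- unique(frames$query_id)
  frames_per_query <- table(frames$query_id)[qids]
  block_of_query <- cumsum(frames_per_query)
  block_id <- setNames((block_of_query - 1L) %/% max(params$block_size, 1L),
                       qids)
  blocks <- split(qids, block_id[qids])
  run_block <- function(block_qids) {
    bf <- frames[frames$query_id %in% block_qids, , drop = FALSE]
    q_index <- build_suffix_array(concat_sequences(
      setNames(bf$protein, paste0("f", seq_len(nrow(bf))))))
    out <- lapply(db$chunks, function(chunk)
      search_block_chunk(q_index, bf, chunk, m, params, ka,
                         db$total_residues))
    do.call(rbind, out)
  }
  results <- if (params$threads > 1L) {
    parallel::mclapply(blocks, run_block, mc.cores = params$threads)
  } else {
    lapply(blocks, run_block)
  }
  rows <- unique(do.call(rbind, results))
  if (is.null(rows) || nrow(rows) == 0L) return(empty_result())
  if (verbose)
    message(nrow(rows), " candidate rows for ", length(qids), " queries")
  rows <- rows[rows$evalue <= params$evalue_max, , drop = FALSE]
  rows <- rows[order(match(rows$query_id, qids), -rows$bit_score,
                     rows$evalue, rows$subject_id, rows$q_start,
                     rows$s_start), ,
               drop = FALSE]
  kept <- lapply(split(rows, match(rows$query_id, qids)), function(g) {
    top <- unique(g$subject_id)[seq_len(min(length(unique(g$subject_id)),
                                            params$max_targets))]
    g[g$subject_id %in% top, , drop = FALSE]
  })
  out <- do.call(rbind, kept)
  rownames(out) <- NULL
  out
}

format_evalue <- function(e) {
  vapply(e, function(x) {
    if (x < 1e-2) {
      s <- sprintf("%.1e", x)
      sub("e([+-])0(\\d\\d)$", "e\\1\\2", s)
    } else if (x < 10) {
      sprintf("%.3f", x)
    } else {
      sprintf("%.1f", x)
    }
  }, "")
}

#' Write results in BLAST tabular format
#'
#' Twelve tab-separated columns, no header, one row per hit; E-values in
#' BLAST-style scientific notation below 1e-2.
#'
#' @param rows data.frame from [sax_search()].
#' @param path output file or `""` for stdout.
#' @return Invisibly, `path`.
#' @export
write_tabular <- function(rows, path) {
  out <- rows
  out$pident <- sprintf("%.2f", out$pident)
  out$evalue <- format_evalue(out$evalue)
  out$bit_score <- sprintf("%.1f", out$bit_score)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read rows written by [write_tabular()]
#' @param path tabular file.
#' @return data.frame with the twelve standard columns.
#' @export
read_tabular <- function(path) {
  rows <- read.table(path, sep = "\t", stringsAsFactors = FALSE,
                     col.names = c("query_id", "subject_id", "pident",
                                   "length", "mismatch", "gapopen",
                                   "q_start", "q_end", "s_start", "s_end",
                                   "evalue", "bit_score"))
  rows
}
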