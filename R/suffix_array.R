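#' Build a suffix index over a (concatenated) text
#'
#' Constructs the suffix array of the text: the permutation of all suffix
#' start positions in lexicographic order under the package collation
#' (`#` < `*` < residues alphabetically). Construction is by prefix doubling
#' in O(n log^2 n).
#'
#' @param x a [concat_text][concat_sequences] or a single character string.
#' @param alphabet symbols in collation order; defaults to the package
#'   alphabet. Toy alphabets are allowed for arbitrary texts.
#' @return An object of class `sa_index`: list with `text` (a
#'   `concat_text`), `positions` (1-based suffix starts, sorted), `alphabet`,
#'   and `ptable` (`NULL` until [build_prefix_table()] is applied).
#' @examples
#' idx <- build_suffix_array("ABAB#", alphabet = c("#", "A", "B"))
#' idx$positions # 5 3 1 4 2
#' @export
build_suffix_array <- function(x, alphabet = SAX_ALPHABET) {
  if (is.character(x) && length(x) == 1L) {
    ct <- structure(list(text = x, boundaries = 1L, ids = "text",
                         lengths = nchar(x)), class = "concat_text")
  } else if (inherits(x, "concat_text")) {
    ct <- x
  } else {
    stop("`x` must be a concat_text or a single string")
  }
  rank256 <- rank_table256(alphabet)
  positions <- cpp_build_sa(ct$text, rank256)
  structure(list(text = ct, positions = positions, alphabet = alphabet,
                 ptable = NULL),
            class = "sa_index")
}

#' @export
print.sa_index <- function(x, ...) {
  cat("<sa_index>", length(x$positions), "suffixes",
      if (!is.null(x$ptable)) "(prefix table built)" else "", "\n")
  invisible(x)
}

#' Construct a suffix-array interval
#'
#' Half-open range `[sp, ep)` of suffix-array ranks whose suffixes share a
#' matched prefix of length `depth`.
#'
#' @param sp inclusive start rank (1-based); `ep` exclusive end rank.
#' @param ep see `sp`.
#' @param depth number of characters matched so far.
#' @return An object of class `sa_interval`.
#' @export
sa_interval <- function(sp, ep, depth = 0L) {
  if (sp > ep) stop("sa_interval: sp > ep")
  structure(list(sp = as.integer(sp), ep = as.integer(ep),
                 depth = as.integer(depth)),
            class = "sa_interval")
}

#' @export
print.sa_interval <- function(x, ...) {
  cat("<sa_interval> [", x$sp, ",", x$ep, ") depth", x$depth, "\n")
  invisible(x)
}

#' Interval covering all suffixes of an index
#' @param index a [sa_index][build_suffix_array].
#' @return `sa_interval` spanning every rank at depth 0.
#' @export
full_interval <- function(index)
  sa_interval(1L, length(index$positions) + 1L, 0L)

#' Number of suffixes in an interval
#' @param iv a [sa_interval].
#' @return Integer size; 0 for the empty interval.
#' @export
interval_size <- function(iv) iv$ep - iv$sp

#' Narrow an interval by one character
#'
#' Binary search (O(log n)) for the maximal sub-interval of `iv` whose
#' suffixes carry symbol `ch` at offset `iv$depth`; the result's depth is one
#' greater. The empty interval maps to itself.
#'
#' @param index a [sa_index][build_suffix_array].
#' @param iv a [sa_interval].
#' @param ch single character.
#' @return A `sa_interval`.
#' @export
narrow_interval <- function(index, iv, ch) {
  stopifnot(inherits(index, "sa_index"), inherits(iv, "sa_interval"))
  r <- cpp_narrow(index$text$text, index$positions, iv$sp, iv$ep, iv$depth,
                  ch, rank_table256(index$alphabet))
  sa_interval(r[1L], r[2L], iv$depth + 1L)
}

#' Precompute intervals for all short residue strings
#'
#' Tabulates the suffix-array interval of every string of length 1 to 5 over
#' the 20-residue alphabet, so the seed search can skip binary searches for
#' the first five characters of a descent. Keys containing `#`, `*` or `X`
#' are excluded and fall back to on-demand narrowing.
#'
#' @param index a [sa_index][build_suffix_array] over the package alphabet.
#' @param max_depth key length tabulated; fixed default 5.
#' @return The index with its `ptable` slot filled.
#' @export
build_prefix_table <- function(index, max_depth = 5L) {
  stopifnot(inherits(index, "sa_index"))
  tab <- cpp_build_ptable(index$text$text, index$positions,
                          rank_table256(index$alphabet),
                          paste(SAX_RESIDUES, collapse = ""), max_depth)
  index$ptable <- list(sp = tab$sp, ep = tab$ep, max_depth = max_depth,
                       residues = SAX_RESIDUES)
  index
}

#' Interval of an arbitrary substring, via table or descent
#'
#' For all-residue keys of length up to the table depth the precomputed
#' interval is returned directly; longer keys start from the deepest table
#' hit and continue by [narrow_interval()]; keys containing symbols outside
#' the 20 residues (or when no table is built) are resolved by pure
#' narrowing. The result is identical to narrowing from the full interval in
#' every case.
#'
#' @param index a [sa_index][build_suffix_array].
#' @param w residue string, `nchar(w) >= 1`.
#' @return A `sa_interval` at depth `nchar(w)` (possibly empty).
#' @export
lookup_interval <- function(index, w) {
  stopifnot(inherits(index, "sa_index"), nchar(w) >= 1L)
  chars <- strsplit(w, "")[[1L]]
  iv <- full_interval(index)
  start <- 1L
  pt <- index$ptable
  if (!is.null(pt)) {
    ridx <- match(chars, pt$residues) - 1L
    k <- 0L
    while (k < length(chars) && k < pt$max_depth && !is.na(ridx[k + 1L]))
      k <- k + 1L
    if (k > 0L) {
      key <- 0
      for (i in seq_len(k)) key <- key * 20 + ridx[i]
      iv <- sa_interval(pt$sp[[k]][key + 1L], pt$ep[[k]][key + 1L], k)
      start <- k + 1L
    }
  }
  for (i in seq(from = start, length.out = length(chars) - start + 1L))
    iv <- narrow_interval(index, iv, chars[i])
  iv
}

#' Pack database sequences into bounded-size chunks
#'
#' Greedy packing in input order: sequences are appended to the current
#' chunk until adding the next one would exceed the residue budget `l_db`;
#' no sequence is split across chunks, so the chunks' union is exactly the
#' input database.
#'
#' @param seqs named character vector of protein sequences.
#' @param l_db residue budget per chunk; must be at least the longest single
#'   sequence and at most 2^31 - 1 (positions are 32-bit).
#' @return List of named character vectors, one per chunk.
#' @export
chunk_sequences <- function(seqs, l_db) {
  if (l_db > 2^31 - 1) stop("l_db exceeds the 32-bit position limit")
  lens <- nchar(seqs)
  too_big <- lens > l_db
  if (any(too_big))
    stop("sequence '", names(seqs)[too_big][1L],
         "' is longer than the chunk budget l_db")
  chunk_of <- integer(length(seqs))
  acc <- 0L
  k <- 1L
  for (i in seq_along(seqs)) {
    if (acc + lens[i] > l_db && acc > 0L) {
      k <- k + 1L
      acc <- 0L
    }
    chunk_of[i] <- k
    acc <- acc + lens[i]
  }
  unname(split(seqs, chunk_of))
}

#' Build a chunked, searchable database index
#'
#' Splits the database into chunks of at most `l_db` residues
#' ([chunk_sequences()]), concatenates each chunk with delimiters, builds
#' its suffix array and (optionally) its short-substring prefix table.
#'
#' @param seqs named character vector of protein sequences, or the path to a
#'   protein FASTA file.
#' @param l_db residue budget per chunk (default: everything in one chunk).
#' @param ptable build the length-<=5 prefix lookup table per chunk.
#' @return An object of class `sax_db`: list with `chunks` (each a list of
#'   `chunk_index`, `index`, `residue_count`), `total_residues`,
#'   `n_sequences`.
#' @export
build_index <- function(seqs, l_db = Inf, ptable = TRUE) {
  if (is.character(seqs) && length(seqs) == 1L && is.null(names(seqs)) &&
      file.exists(seqs))
    seqs <- read_fasta(seqs, type = "protein")
  parts <- chunk_sequences(seqs, min(l_db, 2^31 - 1))
  chunks <- lapply(seq_along(parts), function(k) {
    idx <- build_suffix_array(concat_sequences(parts[[k]]))
    if (ptable) idx <- build_prefix_table(idx)
    list(chunk_index = k, index = idx,
         residue_count = sum(nchar(parts[[k]])))
  })
  structure(list(chunks = chunks,
                 total_residues = sum(nchar(seqs)),
                 n_sequences = length(seqs)),
            class = "sax_db")
}

#' @export
print.sax_db <- function(x, ...) {
  cat("<sax_db>", x$n_sequences, "sequences,", x$total_residues,
      "residues in", length(x$chunks), "chunk(s)\n")
  invisible(x)
}
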