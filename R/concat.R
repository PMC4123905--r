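#' Concatenate sequences into a single delimited text
#'
#' Joins sequences with the `#` delimiter into one long text
#' `S_0#S_1#...#S_{N-1}`, the form over which suffix arrays are built. The
#' mapping from text positions back to (sequence, offset) is total and
#' invertible on non-delimiter positions.
#'
#' @param seqs named character vector of residue strings (unique, non-empty
#'   names; non-empty sequences over the residues plus `X`/`*`).
#' @return An object of class `concat_text`: list with `text` (single
#'   string), `boundaries` (1-based start of each sequence in `text`),
#'   `ids`, `lengths`.
#' @examples
#' ct <- concat_sequences(c(a = "MK", b = "W"))
#' ct$text # "MK#W"
#' @export
concat_sequences <- function(seqs) {
  if (length(seqs) == 0L) stop("empty sequence list")
  if (is.list(seqs)) seqs <- unlist(seqs)
  ids <- names(seqs)
  if (is.null(ids) || any(!nzchar(ids))) stop("all sequences must be named")
  if (anyDuplicated(ids))
    stop("duplicate sequence id: ", ids[duplicated(ids)][1L])
  if (any(!nzchar(seqs)))
    stop("empty sequence: ", ids[!nzchar(seqs)][1L])
  ok <- grepl(paste0("^[", paste(c(SAX_RESIDUES, "X", "\\*"), collapse = ""),
                     "]+$"), seqs)
  if (!all(ok))
    stop("sequence '", ids[!ok][1L], "' contains symbols outside the alphabet")
  lens <- nchar(seqs)
  boundaries <- cumsum(c(1L, head(lens, -1L) + 1L))
  structure(list(text = paste(seqs, collapse = SAX_DELIM),
                 boundaries = as.integer(boundaries),
                 ids = ids, lengths = as.integer(lens)),
            class = "concat_text")
}

#' Recover the original sequences from a concatenated text
#'
#' Inverse of [concat_sequences()].
#'
#' @param ct a `concat_text`.
#' @return Named character vector of sequences.
#' @export
split_concat <- function(ct) {
  stopifnot(inherits(ct, "concat_text"))
  setNames(substring(ct$text, ct$boundaries, ct$boundaries + ct$lengths - 1L),
           ct$ids)
}

#' Map concatenated-text positions to source sequences
#'
#' @param ct a `concat_text`.
#' @param pos integer vector of 1-based positions into `ct$text`.
#' @return data.frame with `pos`, `seq_index`, `id`, `offset` (1-based
#'   offset within the source sequence); `NA`s for delimiter positions.
#' @export
locate_position <- function(ct, pos) {
  stopifnot(inherits(ct, "concat_text"))
  idx <- findInterval(pos, ct$boundaries)
  off <- pos - ct$boundaries[idx] + 1L
  is_delim <- idx < 1L | off > ct$lengths[idx]
  data.frame(pos = pos,
             seq_index = ifelse(is_delim, NA_integer_, idx),
             id = ifelse(is_delim, NA_character_, ct$ids[idx]),
             offset = ifelse(is_delim, NA_integer_, off),
             stringsAsFactors = FALSE)
}

#' @export
print.concat_text <- function(x, ...) {
  cat("<concat_text>", length(x$ids), "sequences,", nchar(x$text),
      "symbols\n")
  invisible(x)
}
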