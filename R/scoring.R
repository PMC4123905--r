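#' Load a substitution score matrix
#'
#' Loads the bundled BLOSUM62 matrix, or any NCBI-format matrix file
#' (whitespace-separated, a header row of symbols, one labelled row per
#' symbol). The returned matrix is defined over the package alphabet: the 20
#' amino acids, `X` (ambiguous), `*` (stop) and `#` (sequence delimiter).
#' Every pair involving `#` or `*` is fixed at one below the smallest
#' residue entry of the source matrix, so extension across a stop or a
#' sequence boundary always loses score; `X` keeps the source matrix's own
#' `X` row.
#'
#' @param name_or_path `"BLOSUM62"` for the bundled matrix, or a path to an
#'   NCBI-format matrix file.
#' @return An object of class `score_matrix`: a list with `alphabet`
#'   (symbols in collation order), `scores` (integer matrix with symbol
#'   dimnames) and `name`.
#' @examples
#' m <- load_score_matrix()
#' m$scores["A", "A"]
#' @export
load_score_matrix <- function(name_or_path = "BLOSUM62") {
  if (!is.character(name_or_path) || length(name_or_path) != 1L)
    stop("`name_or_path` must be a single string")
  if (identical(name_or_path, "BLOSUM62")) {
    path <- system.file("extdata", "BLOSUM62", package = "saxsearch")
    name <- "BLOSUM62"
  } else if (file.exists(name_or_path)) {
    path <- name_or_path
    name <- basename(name_or_path)
  } else {
    stop("unknown score matrix '", name_or_path,
         "': not a bundled name and not a readable file")
  }
  raw <- parse_ncbi_matrix(path)
  needed <- c(SAX_RESIDUES, "X")
  missing <- setdiff(needed, rownames(raw))
  if (length(missing))
    stop("matrix file '", path, "' lacks rows for: ",
         paste(missing, collapse = ", "))
  core <- raw[needed, needed]
  if (!all(core == t(core)))
    stop("matrix file '", path, "' is not symmetric over the residues")
  sentinel <- min(core) - 1L
  n <- length(SAX_ALPHABET)
  scores <- matrix(sentinel, n, n, dimnames = list(SAX_ALPHABET, SAX_ALPHABET))
  scores[needed, needed] <- core
  scores[SAX_DELIM, ] <- sentinel
  scores[, SAX_DELIM] <- sentinel
  scores[SAX_STOP, ] <- sentinel
  scores[, SAX_STOP] <- sentinel
  storage.mode(scores) <- "integer"
  structure(list(alphabet = SAX_ALPHABET, scores = scores, name = name),
            class = "score_matrix")
}

parse_ncbi_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2L)
    stop("matrix file '", path, "' has no header/data lines")
  header <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  if (any(nchar(header) != 1L))
    stop("malformed matrix header in '", path, "': token '",
         header[which(nchar(header) != 1L)[1L]], "'")
  rows <- strsplit(trimws(lines[-1L]), "\\s+")
  labels <- vapply(rows, `[`, "", 1L)
  vals <- lapply(rows, function(f) suppressWarnings(as.integer(f[-1L])))
  bad <- which(lengths(vals) != length(header) |
                 vapply(vals, anyNA, logical(1L)))
  if (length(bad))
    stop("malformed matrix row for symbol '", labels[bad[1L]], "' in '",
         path, "'")
  m <- do.call(rbind, vals)
  dimnames(m) <- list(labels, header)
  m
}

#' @export
print.score_matrix <- function(x, ...) {
  cat("<score_matrix>", x$name, "-", length(x$alphabet), "symbols\n")
  invisible(x)
}

# byte-indexed 256x256 score table for the C++ kernels
score_table256 <- function(m) {
  stopifnot(inherits(m, "score_matrix"))
  tab <- matrix(-32000L, 256L, 256L)
  codes <- utf8ToInt(paste(m$alphabet, collapse = "")) + 1L
  tab[codes, codes] <- m$scores
  tab
}

encode_check <- function(s, m, what = "string") {
  bad <- setdiff(strsplit(s, "")[[1L]], m$alphabet)
  if (length(bad))
    stop(what, " contains symbols outside the matrix alphabet: ",
         paste(unique(bad), collapse = ", "))
  invisible(s)
}

#' Score an ungapped pair of equal-length strings
#'
#' Sums the substitution score position by position. The two strings must
#' have the same length; the empty pair scores 0.
#'
#' @param a,b residue strings of equal length.
#' @param m a [score_matrix][load_score_matrix].
#' @return Integer raw score.
#' @examples
#' m <- load_score_matrix()
#' pair_score("WWW", "WWW", m) # 33
#' @export
pair_score <- function(a, b, m) {
  stopifnot(inherits(m, "score_matrix"))
  if (nchar(a) != nchar(b))
    stop("pair_score: strings differ in length (", nchar(a), " vs ",
         nchar(b), ")")
  if (nchar(a) == 0L) return(0L)
  encode_check(a, m, "a")
  encode_check(b, m, "b")
  sum(m$scores[cbind(strsplit(a, "")[[1L]], strsplit(b, "")[[1L]])])
}

#' Exact-match (self-alignment) score of a string
#'
#' The sum of the diagonal matrix entries of the string's symbols: the best
#' score any equal-length database substring could reach against it. This is
#' the `score_max` quantity that drives the seed-search score-gap pruning
#' rule.
#'
#' @inheritParams pair_score
#' @return Integer raw score; equals `pair_score(a, a, m)`.
#' @export
exact_match_score <- function(a, m) pair_score(a, a, m)

#' Karlin-Altschul statistical parameters
#'
#' Constants for converting raw alignment scores to E-values and bit scores.
#' Defaults are the standard published gapped constants for BLOSUM62 with
#' gap open 11 / extend 1.
#'
#' @param lambda scale per raw-score unit (> 0).
#' @param K search-space constant (> 0).
#' @param gapped flag recording which regime the constants describe.
#' @return An object of class `ka_params`.
#' @export
karlin_altschul_params <- function(lambda = 0.267, K = 0.041, gapped = TRUE) {
  if (!is.numeric(lambda) || lambda <= 0) stop("lambda must be > 0")
  if (!is.numeric(K) || K <= 0) stop("K must be > 0")
  structure(list(lambda = lambda, K = K, gapped = isTRUE(gapped)),
            class = "ka_params")
}

#' Expected number of chance alignments at or above a raw score
#'
#' `E = K * m * n * exp(-lambda * S)` with `m` the query length and `n` the
#' database length in residues. No BLAST-style effective-length correction
#' is applied.
#'
#' @param raw_score non-negative integer raw score (vectorised).
#' @param query_len,db_len lengths in residues (> 0).
#' @param p [ka_params][karlin_altschul_params].
#' @return Positive numeric E-value(s); strictly decreasing in `raw_score`.
#' @export
evalue <- function(raw_score, query_len, db_len,
                   p = karlin_altschul_params()) {
  stopifnot(inherits(p, "ka_params"))
  if (any(query_len <= 0) || any(db_len <= 0))
    stop("sequence lengths must be positive")
  if (any(raw_score < 0)) stop("raw_score must be >= 0")
  p$K * as.numeric(query_len) * as.numeric(db_len) *
    exp(-p$lambda * raw_score)
}

#' Bit score of a raw alignment score
#'
#' `S' = (lambda * S - ln K) / ln 2`.
#'
#' @inheritParams evalue
#' @return Numeric bit score(s).
#' @export
bit_score <- function(raw_score, p = karlin_altschul_params()) {
  stopifnot(inherits(p, "ka_params"))
  (p$lambda * raw_score - log(p$K)) / log(2)
}
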