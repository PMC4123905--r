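# On-disk index format: <prefix>.manifest.json plus, per chunk,
# <prefix>.<k>.text and <prefix>.<k>.sa. Binary files open with the magic
# bytes "SAXI" and a version byte; the positions array is little-endian
# 32-bit (the 2^31-symbol chunk limit makes 32 bits sufficient). The prefix
# table is a derived structure and is rebuilt on load rather than stored.

SAX_MAGIC <- charToRaw("SAXI")
SAX_FORMAT_VERSION <- 1L

#' Serialize a database index to disk
#'
#' @param db a [sax_db][build_index].
#' @param prefix path prefix for the output files.
#' @return Invisibly, the manifest path.
#' @export
save_index <- function(db, prefix) {
  stopifnot(inherits(db, "sax_db"))
  chunk_meta <- lapply(db$chunks, function(ch) {
    k <- ch$chunk_index
    text_path <- sprintf("%s.%d.text", prefix, k)
    sa_path <- sprintf("%s.%d.sa", prefix, k)
    con <- file(text_path, "wb")
    writeBin(SAX_MAGIC, con)
    writeBin(as.raw(SAX_FORMAT_VERSION), con)
    writeBin(charToRaw(ch$index$text$text), con)
    close(con)
    con <- file(sa_path, "wb")
    writeBin(SAX_MAGIC, con)
    writeBin(as.raw(SAX_FORMAT_VERSION), con)
    writeBin(length(ch$index$positions), con, size = 4L, endian = "little")
    writeBin(ch$index$positions, con, size = 4L, endian = "little")
    close(con)
    list(chunk_index = k, ids = ch$index$text$ids,
         lengths = ch$index$text$lengths,
         residue_count = ch$residue_count,
         ptable = !is.null(ch$index$ptable))
  })
  manifest <- list(format = "saxsearch-index", version = SAX_FORMAT_VERSION,
                   n_sequences = db$n_sequences,
                   total_residues = db$total_residues,
                   chunks = chunk_meta)
  path <- paste0(prefix, ".manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

read_magic <- function(con, path) {
  magic <- readBin(con, "raw", 4L)
  if (length(magic) < 4L || !identical(magic, SAX_MAGIC))
    stop("'", path, "': bad magic bytes, not a saxsearch index file")
  ver <- as.integer(readBin(con, "raw", 1L))
  if (length(ver) != 1L || ver != SAX_FORMAT_VERSION)
    stop("'", path, "': unsupported index format version ", ver)
}

#' Load a database index from disk
#'
#' @param prefix the path prefix used with [save_index()].
#' @return A [sax_db][build_index]; identical to the saved one (prefix
#'   tables are rebuilt when the manifest records them).
#' @export
load_index <- function(prefix) {
  mpath <- paste0(prefix, ".manifest.json")
  if (!file.exists(mpath)) stop("no index manifest at '", mpath, "'")
  manifest <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  if (!identical(manifest$format, "saxsearch-index"))
    stop("'", mpath, "' is not a saxsearch index manifest")
  meta <- manifest$chunks
  chunks <- lapply(seq_len(nrow(meta)), function(i) {
    k <- meta$chunk_index[i]
    text_path <- sprintf("%s.%d.text", prefix, k)
    sa_path <- sprintf("%s.%d.sa", prefix, k)
    con <- file(text_path, "rb")
    read_magic(con, text_path)
    text <- rawToChar(readBin(con, "raw", file.size(text_path)))
    close(con)
    con <- file(sa_path, "rb")
    read_magic(con, sa_path)
    n <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    positions <- readBin(con, "integer", n, size = 4L, endian = "little")
    close(con)
    if (length(positions) != n || n != nchar(text))
      stop("'", sa_path, "': truncated positions array")
    lengths <- as.integer(meta$lengths[[i]])
    ct <- structure(list(text = text,
                         boundaries = cumsum(c(1L, head(lengths, -1L) + 1L)),
                         ids = unlist(meta$ids[[i]]), lengths = lengths),
                    class = "concat_text")
    idx <- structure(list(text = ct, positions = positions,
                          alphabet = SAX_ALPHABET, ptable = NULL),
                     class = "sa_index")
    if (isTRUE(meta$ptable[i])) idx <- build_prefix_table(idx)
    list(chunk_index = k, index = idx,
         residue_count = meta$residue_count[i])
  })
  structure(list(chunks = chunks,
                 total_residues = manifest$total_residues,
                 n_sequences = manifest$n_sequences),
            class = "sax_db")
}
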