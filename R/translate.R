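#' Six-frame translation of a DNA read
#'
#' Translates a read in all three codon phases on both strands with the
#' standard genetic code. Ambiguous codons become `X`, stop codons stay
#' in-frame as `*`, trailing partial codons are dropped. `U` is read as `T`
#' and lowercase input is accepted.
#'
#' @param dna a nucleotide string.
#' @param id query identifier attached to every frame.
#' @return data.frame with `query_id`, `frame` (+1, +2, +3, -1, -2, -3),
#'   `protein`, `dna_length`; zero rows for input shorter than one codon.
#'   Frame `f > 0` starts at base `f` of the read; frame `f < 0` starts at
#'   base `|f|` of the reverse complement. [map_frame_to_dna()] converts
#'   residue coordinates back to read coordinates.
#' @examples
#' translate_six_frames("ATGAAA")$protein[1] # "MK"
#' @export
translate_six_frames <- function(dna, id = "query") {
  dna <- chartr("u", "t", tolower(dna))
  dna <- gsub("[^acgt]", "n", dna)
  n <- nchar(dna)
  if (n < 3L)
    return(data.frame(query_id = character(), frame = integer(),
                      protein = character(), dna_length = integer(),
                      stringsAsFactors = FALSE))
  fwd <- Biostrings::DNAString(toupper(dna))
  rev <- Biostrings::reverseComplement(fwd)
  frames <- c(1L, 2L, 3L, -1L, -2L, -3L)
  protein <- vapply(frames, function(f) {
    s <- if (f > 0L) fwd else rev
    start <- abs(f)
    len <- ((n - start + 1L) %/% 3L) * 3L
    if (len < 3L) return(NA_character_)
    # no.init.codon: frames are not ORFs, the first codon gets no
    # initiator-methionine treatment
    aa <- Biostrings::translate(Biostrings::subseq(s, start, start + len - 1L),
                                if.fuzzy.codon = "X", no.init.codon = TRUE)
    as.character(aa)
  }, character(1L))
  out <- data.frame(query_id = id, frame = frames, protein = protein,
                    dna_length = n, stringsAsFactors = FALSE)
  out[!is.na(out$protein) & nzchar(out$protein), , drop = FALSE]
}

#' Map residue coordinates of a frame back to the DNA read
#'
#' BLASTX convention: coordinates are reported on the read, 1-based
#' inclusive, with reverse-strand frames giving `start > end`.
#'
#' @param frame one of +1, +2, +3, -1, -2, -3 (0 = native protein query,
#'   returned unchanged).
#' @param aa_start,aa_end 1-based residue positions within the frame.
#' @param dna_len read length in bases.
#' @return list with `start` and `end` in read coordinates.
#' @export
map_frame_to_dna <- function(frame, aa_start, aa_end, dna_len) {
  if (frame == 0L) return(list(start = aa_start, end = aa_end))
  f <- abs(frame)
  s <- 3L * (aa_start - 1L) + f
  e <- 3L * (aa_end - 1L) + f + 2L
  if (frame > 0L) list(start = s, end = e)
  else list(start = dna_len - s + 1L, end = dna_len - e + 1L)
}
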