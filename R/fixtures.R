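# Robinson-Robinson amino-acid background frequencies (the standard set
# used for protein null models), indexed by residue.
ROBINSON_FREQS <- c(
  A = 0.07805, R = 0.05129, N = 0.04487, D = 0.05364, C = 0.01925,
  Q = 0.04264, E = 0.06295, G = 0.07377, H = 0.02199, I = 0.05142,
  L = 0.09019, K = 0.05744, M = 0.02243, F = 0.03856, P = 0.05203,
  S = 0.07120, T = 0.05841, W = 0.01330, Y = 0.03216, V = 0.06441)

with_fixture_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic protein database
#'
#' Sequences of i.i.d. residues drawn from Robinson-Robinson background
#' frequencies; byte-identical regeneration from the same seed.
#'
#' @param n number of sequences (>= 1).
#' @param len residue length, a single value or one per sequence.
#' @param seed RNG seed.
#' @return Named character vector (`dbseq0001`, ...).
#' @export
make_protein_db <- function(n, len = 300L, seed = 1L) {
  if (n < 1L) stop("n must be >= 1")
  len <- rep_len(as.integer(len), n)
  with_fixture_seed(seed, {
    seqs <- vapply(len, function(l)
      paste(sample(names(ROBINSON_FREQS), l, replace = TRUE,
                   prob = ROBINSON_FREQS), collapse = ""), "")
    setNames(seqs, sprintf("dbseq%04d", seq_len(n)))
  })
}

# inverted standard genetic code: residue -> codons
codons_by_residue <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
}

#' Reverse-translate a protein with uniform synonymous codons
#'
#' @param protein residue string (20 amino acids only).
#' @param seed RNG seed.
#' @return DNA string of length `3 * nchar(protein)`.
#' @export
reverse_translate <- function(protein, seed = 1L) {
  tab <- codons_by_residue()
  chars <- strsplit(protein, "")[[1L]]
  with_fixture_seed(seed, {
    paste(vapply(chars, function(a) {
      cods <- tab[[a]]
      if (is.null(cods)) stop("no codon for symbol '", a, "'")
      cods[sample.int(length(cods), 1L)]
    }, ""), collapse = "")
  })
}

#' Plant homologous DNA queries into a synthetic database
#'
#' Samples database segments, applies point substitutions down to the
#' requested identity and single-residue indels at the stated rate, then
#' reverse-translates through uniformly chosen synonymous codons onto a
#' random strand. The truth table records every edit, so the emitted
#' queries are exactly reproducible from it.
#'
#' @param db named character vector (e.g. from [make_protein_db()]).
#' @param n_queries number of reads to plant.
#' @param identity target residue identity in (0, 1].
#' @param indel_rate per-position probability of a single-residue indel.
#' @param read_len_nt read length in bases (a multiple of 3 is used).
#' @param seed RNG seed.
#' @return List with `queries` (named DNA vector), `truth` (data.frame:
#'   `query_id`, `source_id`, `src_start`, `src_end`, `identity`,
#'   `n_subst`, `n_indel`, `strand`, `mutated_protein`).
#' @export
plant_queries <- function(db, n_queries, identity = 0.8, indel_rate = 0,
                          read_len_nt = 150L, seed = 1L) {
  if (identity <= 0 || identity > 1) stop("identity must be in (0, 1]")
  n_aa <- read_len_nt %/% 3L
  if (any(nchar(db) < n_aa))
    stop("read longer than source sequence '",
         names(db)[nchar(db) < n_aa][1L], "'")
  residues <- names(ROBINSON_FREQS)
  with_fixture_seed(seed, {
    rows <- vector("list", n_queries)
    queries <- character(n_queries)
    for (i in seq_len(n_queries)) {
      src <- sample.int(length(db), 1L)
      src_seq <- db[[src]]
      start <- sample.int(nchar(src_seq) - n_aa + 1L, 1L)
      seg <- strsplit(substring(src_seq, start, start + n_aa - 1L), "")[[1L]]
      # exact substitution count so every read realizes the target identity
      mutate <- rep(FALSE, n_aa)
      mutate[sample.int(n_aa, round((1 - identity) * n_aa))] <- TRUE
      seg[mutate] <- vapply(seg[mutate], function(a)
        sample(setdiff(residues, a), 1L), "")
      n_indel <- 0L
      if (indel_rate > 0) {
        j <- 1L
        while (j <= length(seg)) {
          if (runif(1L) < indel_rate) {
            if (runif(1L) < 0.5 && length(seg) > 1L) {
              seg <- seg[-j]          # deletion
            } else {
              seg <- append(seg, sample(residues, 1L, prob = ROBINSON_FREQS),
                            after = j)  # insertion
              j <- j + 1L
            }
            n_indel <- n_indel + 1L
          }
          j <- j + 1L
        }
      }
      prot <- paste(seg, collapse = "")
      dna <- reverse_translate(prot, seed = sample.int(2^31 - 1L, 1L))
      strand <- sample(c("+", "-"), 1L)
      if (strand == "-")
        dna <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(dna)))
      qid <- sprintf("read%04d", i)
      queries[i] <- dna
      rows[[i]] <- data.frame(query_id = qid, source_id = names(db)[src],
                              src_start = start, src_end = start + n_aa - 1L,
                              identity = 1 - mean(mutate), n_subst = sum(mutate),
                              n_indel = n_indel, strand = strand,
                              mutated_protein = prot,
                              stringsAsFactors = FALSE)
    }
    truth <- do.call(rbind, rows)
    list(queries = setNames(queries, truth$query_id), truth = truth)
  })
}
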