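#' Global pairwise identity
#'
#' Needleman-Wunsch global alignment with affine gap penalties, used for
#' DNA-level and protein-level identity between paired transcripts and for
#' paralog clustering. Identity is the fraction of alignment columns (terminal
#' gaps included) that match; `net_indel` is the signed length difference
#' `nchar(b) - nchar(a)`.
#'
#' Scoring defaults: DNA match +2 / mismatch -3, gap open 5 / extend 2;
#' protein BLOSUM62, gap open 11 / extend 1. A gap of length L costs
#' `open + L * extend`.
#'
#' @param a,b Sequences to align (non-empty strings).
#' @param alphabet `"dna"` or `"protein"`.
#' @param gap_open,gap_extend Affine gap penalties (positive costs); defaults
#'   depend on `alphabet`.
#' @return A one-row tibble: `identity` (fraction in `[0, 1]`),
#'   `aligned_length` (alignment columns), `net_indel` (signed bases),
#'   `coverage_a`, `coverage_b` (fraction of each sequence in both-aligned
#'   columns, used by clustering).
#' @export
#' @examples
#' global_identity("ACGTACGT", "ACGTACGT", "dna")
#' global_identity("MKL", "ML", "protein")
global_identity <- function(a, b, alphabet = c("dna", "protein"),
                            gap_open = NULL, gap_extend = NULL) {
  alphabet <- match.arg(alphabet)
  if (!nzchar(a) || !nzchar(b)) abort("global_identity: empty input sequence")
  aln <- align_global(a, b, alphabet, gap_open, gap_extend, strings = FALSE)
  matches <- Biostrings::nmatch(aln$aln)
  both <- matches + Biostrings::nmismatch(aln$aln)  # both-aligned columns
  cols <- nchar(a) + nchar(b) - both                # total alignment columns
  tibble(
    identity = matches / cols,
    aligned_length = cols,
    net_indel = nchar(b) - nchar(a),
    coverage_a = both / nchar(a),
    coverage_b = both / nchar(b)
  )
}

# Global alignment of a pair of sequences; with strings = TRUE the
# full-column aligned strings (terminal gaps included) are materialised,
# which is comparatively slow and only needed for gap-run inspection.
align_global <- function(a, b, alphabet, gap_open = NULL, gap_extend = NULL,
                         strings = TRUE) {
  if (alphabet == "dna") {
    gap_open <- gap_open %||% 5
    gap_extend <- gap_extend %||% 2
    mat <- dna_score_matrix()
    pa <- Biostrings::DNAString(toupper(a))
    sb <- Biostrings::DNAString(toupper(b))
  } else {
    gap_open <- gap_open %||% 11
    gap_extend <- gap_extend %||% 1
    mat <- "BLOSUM62"
    pa <- Biostrings::AAString(a)
    sb <- Biostrings::AAString(b)
  }
  aln <- Biostrings::pairwiseAlignment(
    pa, sb, type = "global", substitutionMatrix = mat,
    gapOpening = gap_open, gapExtension = gap_extend
  )
  out <- list(aln = aln, score = Biostrings::score(aln))
  if (strings) {
    out$pattern <- as.character(Biostrings::alignedPattern(aln))
    out$subject <- as.character(Biostrings::alignedSubject(aln))
  }
  out
}

.align_cache <- new.env(parent = emptyenv())

dna_score_matrix <- function(match = 2, mismatch = -3) {
  key <- paste0("dna_", match, "_", mismatch)
  if (is.null(.align_cache[[key]])) {
    .align_cache[[key]] <- Biostrings::nucleotideSubstitutionMatrix(
      match = match, mismatch = mismatch, baseOnly = FALSE
    )
  }
  .align_cache[[key]]
}

#' Translate a coding sequence
#'
#' Standard genetic code. Translation stops at the first stop codon; a
#' trailing incomplete codon is ignored; codons containing ambiguity codes
#' translate to `X`.
#'
#' @param cds A nucleotide string of length >= 3.
#' @return A list with `protein` (amino-acid string, stop excluded) and
#'   `premature_stop` (`TRUE` when a stop codon occurs before the final
#'   complete codon).
#' @export
#' @examples
#' translate_cds("ATGAAATAA")
#' translate_cds("ATGTAAAAA")
translate_cds <- function(cds) {
  if (nchar(cds) < 3) abort("translate_cds: sequence shorter than one codon")
  up <- toupper(cds)
  if (str_detect(up, "[^ACGTUMRWSYKVHDBN]")) {
    abort("translate_cds: non-IUPAC character in sequence")
  }
  up <- gsub("U", "T", up, fixed = TRUE)
  n_codon <- nchar(up) %/% 3
  codons <- substring(up, 3 * seq_len(n_codon) - 2, 3 * seq_len(n_codon))
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"
  stop_at <- which(aa == "*")
  if (length(stop_at) == 0) {
    return(list(protein = paste(aa, collapse = ""), premature_stop = FALSE))
  }
  s <- stop_at[1]
  list(
    protein = if (s == 1) "" else paste(aa[seq_len(s - 1)], collapse = ""),
    premature_stop = s < n_codon
  )
}

#' Reverse complement
#'
#' @param x A nucleotide string (IUPAC codes allowed; case folded to upper).
#' @return The reverse complement string.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(toupper(x))))
}
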