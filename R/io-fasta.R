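#' Read and write FASTA with case preserved
#'
#' `read_fasta()` returns a genome tibble with one row per sequence. Case is
#' preserved verbatim because lowercase marks donor-filled (reference-patched)
#' bases and drives the provenance report. `write_fasta()` is its inverse;
#' writing then re-reading reproduces the tibble exactly.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `seq_name` (first word of the header),
#'   `residues` (the sequence, case preserved) and `length` (bases).
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", "ACgtN"), fa)
#' read_fasta(fa)
read_fasta <- function(path) {
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) abort(paste0("malformed FASTA at '", path, "': ", conditionMessage(e)))
  )
  genome <- tibble(
    seq_name = vapply(strsplit(names(set), "[ \t]"), `[`, "", 1L),
    residues = unname(as.character(set))
  )
  genome$length <- nchar(genome$residues)
  validate_genome(genome)
  genome
}

#' @param genome A genome tibble as returned by `read_fasta()`.
#' @param width Line width for sequence wrapping.
#' @rdname read_fasta
#' @export
write_fasta <- function(genome, path, width = 70L) {
  validate_genome(genome)
  set <- Biostrings::BStringSet(genome$residues)
  names(set) <- genome$seq_name
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

validate_genome <- function(genome) {
  stopifnot(is.data.frame(genome), all(c("seq_name", "residues") %in% names(genome)))
  # nucleotide or amino-acid IUPAC letters (case preserved), '*' for stops
  bad <- str_detect(genome$residues, "[^A-Za-z*]")
  if (any(bad)) {
    abort(paste0(
      "non-IUPAC characters in sequence(s): ",
      paste(genome$seq_name[bad], collapse = ", ")
    ))
  }
  if ("length" %in% names(genome) &&
      !identical(unname(as.integer(genome$length)), unname(nchar(genome$residues)))) {
    abort("genome 'length' column disagrees with residue count")
  }
  invisible(genome)
}

#' Replace intervals of a sequence with Ns
#'
#' Hard-masks the given half-open intervals (for example candidate rDNA array
#' loci before a second annotation pass). Bases outside the intervals,
#' including their case, are untouched; sequence length never changes, and
#' masking is idempotent. Overlapping intervals mask their union.
#'
#' @param genome A genome tibble (`seq_name`, `residues`).
#' @param intervals A tibble with columns `seq_name`, `start`, `end`
#'   (0-based half-open).
#' @return The genome tibble with masked residues.
#' @export
#' @examples
#' g <- tibble::tibble(seq_name = "s", residues = "ACGTAC", length = 6L)
#' mask_intervals(g, tibble::tibble(seq_name = "s", start = 1, end = 3))
mask_intervals <- function(genome, intervals) {
  validate_genome(genome)
  if (nrow(intervals) == 0) return(genome)
  stopifnot(all(c("seq_name", "start", "end") %in% names(intervals)))
  unknown <- setdiff(intervals$seq_name, genome$seq_name)
  if (length(unknown) > 0) {
    abort(paste0("intervals name unknown sequence(s): ", paste(unknown, collapse = ", ")))
  }
  for (i in seq_len(nrow(genome))) {
    iv <- intervals[intervals$seq_name == genome$seq_name[i], , drop = FALSE]
    if (nrow(iv) == 0) next
    len <- nchar(genome$residues[i])
    if (any(iv$start < 0) || any(iv$end > len) || any(iv$end <= iv$start)) {
      abort(paste0("interval out of bounds on '", genome$seq_name[i], "'"))
    }
    res <- strsplit(genome$residues[i], "", fixed = TRUE)[[1]]
    for (j in seq_len(nrow(iv))) {
      res[(iv$start[j] + 1L):iv$end[j]] <- "N"
    }
    genome$residues[i] <- paste(res, collapse = "")
  }
  genome$length <- nchar(genome$residues)
  genome
}

#' Fetch one sequence from a genome tibble
#'
#' @param genome A genome tibble.
#' @param seq_name Sequence identifier.
#' @return The residue string.
#' @keywords internal
genome_seq <- function(genome, seq_name) {
  i <- match(seq_name, genome$seq_name)
  if (is.na(i)) abort(paste0("sequence '", seq_name, "' not found in genome"))
  genome$residues[i]
}
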