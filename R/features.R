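#' Donor-sequence provenance report
#'
#' In a reference-guided assembly, bases filled in from the donor (guide)
#' genome are written in lowercase and bases supported by the sample's own
#' reads are upper case. This report counts lowercase residues per sequence
#' and computes the source ratio `(total - donor) / total` — the fraction of
#' each sequence derived from the sample itself — rounded half-even to four
#' decimals. A `total` row sums bases before taking the ratio. Uppercase `N`
#' counts as non-donor; provenance is purely case-driven.
#'
#' @param genome A case-preserved genome tibble ([read_fasta()]).
#' @return A tibble with columns `seq_name`, `total_bp`, `donor_bp`, `ratio`,
#'   ending with a `total` row.
#' @export
#' @examples
#' g <- tibble::tibble(seq_name = "s", residues = "ACgtAC", length = 6L)
#' provenance_report(g)
provenance_report <- function(genome) {
  validate_genome(genome)
  per <- tibble(
    seq_name = genome$seq_name,
    total_bp = nchar(genome$residues),
    donor_bp = str_count(genome$residues, "[a-z]")
  )
  total <- tibble(
    seq_name = "total",
    total_bp = sum(per$total_bp),
    donor_bp = sum(per$donor_bp)
  )
  out <- bind_rows(per, total)
  out$ratio <- source_ratio(out$total_bp, out$donor_bp)
  out
}

#' Source ratio of an assembled sequence
#'
#' Fraction of a sequence derived from the sample itself rather than filled
#' in from the donor genome: `(total_bp - donor_bp) / total_bp`, rounded
#' half-even to four decimals.
#'
#' @param total_bp Total bases.
#' @param donor_bp Donor-derived (lowercase) bases.
#' @return The ratio rounded to 4 decimals.
#' @export
#' @examples
#' source_ratio(148018047, 35504706)
source_ratio <- function(total_bp, donor_bp) {
  stopifnot(all(donor_bp >= 0), all(donor_bp <= total_bp))
  round((total_bp - donor_bp) / total_bp, 4)
}

#' Length of a half-open interval
#'
#' The coordinate convention used throughout: an interval printed as
#' `start`-`end` spans `end - start` bases.
#'
#' @param start,end Interval bounds, `end > start`.
#' @return `end - start`.
#' @export
#' @examples
#' interval_length(21541750, 21555531)
interval_length <- function(start, end) {
  if (any(end <= start)) abort("interval_length: end must exceed start")
  end - start
}

#' Validate a NUMT (or any insertion) by spanning read alignments
#'
#' Counts primary long-read alignments that contain the entire candidate
#' insertion and extend at least `flank_bp` beyond it on both ends
#' (inclusive: an alignment reaching exactly `flank_bp` past each end
#' counts). Secondary alignments are excluded, as when reads are mapped with
#' secondary output disabled.
#'
#' @param seq_name Sequence carrying the insertion.
#' @param start,end Half-open insertion interval.
#' @param alignments An alignment tibble ([read_paf()]).
#' @param flank_bp Required flank on each side (default 500).
#' @return The supporting read count (integer).
#' @export
validate_numt <- function(seq_name, start, end, alignments, flank_bp = 500L) {
  stopifnot(end > start, flank_bp >= 0)
  hit <- alignments$target_name == seq_name &
    alignments$is_primary &
    alignments$target_start <= start - flank_bp &
    alignments$target_end >= end + flank_bp
  sum(hit)
}
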