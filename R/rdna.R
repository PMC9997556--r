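#' Filter candidate rDNA alignments
#'
#' First pass of the two-pass rDNA procedure: from alignments of a reference
#' rDNA unit against the genome, retain records longer than `min_len` bases
#' and more than `min_identity` percent identical (both strictly), the loci
#' that will be hard-masked before lifting over the rest of the annotation.
#'
#' @param alignments An alignment tibble ([read_paf()]).
#' @param min_len Minimum alignment block length (strict, default 1000).
#' @param min_identity Minimum percent identity (strict, default 98.5).
#' @return The surviving rows.
#' @export
filter_rdna_candidates <- function(alignments, min_len = 1000, min_identity = 98.5) {
  filter(alignments, .data$aln_len > min_len, .data$identity > min_identity)
}

#' Merge candidate loci into approximate array intervals
#'
#' Collapses overlapping (or within `gap_tolerance` bases) target intervals
#' into maximal intervals, per sequence — the approximate rDNA array
#' locations handed to masking.
#'
#' @param kept Filtered alignment tibble.
#' @param gap_tolerance Merge records separated by at most this many bases
#'   (default 0 = only touching/overlapping).
#' @return A tibble of merged intervals: `seq_name`, `start`, `end`.
#' @export
merge_candidate_loci <- function(kept, gap_tolerance = 0L) {
  if (nrow(kept) == 0) {
    return(tibble(seq_name = character(), start = integer(), end = integer()))
  }
  out <- map(sort(unique(kept$target_name)), function(sn) {
    k <- kept[kept$target_name == sn, , drop = FALSE]
    r <- IRanges::reduce(
      IRanges::IRanges(start = k$target_start + 1L, end = k$target_end),
      min.gapwidth = gap_tolerance + 1L
    )
    tibble(seq_name = sn, start = IRanges::start(r) - 1L, end = IRanges::end(r))
  })
  bind_rows(out)
}

#' Group labeled subunit placements into valid rDNA units
#'
#' A valid rDNA unit requires the three rRNA subunits to map at one locus in
#' transcription order — 18S, 5.8S, 28S — on one strand (mirrored to
#' 28S, 5.8S, 18S in genomic coordinates on the minus strand). Placements are
#' scanned greedily left to right per sequence and strand; three consecutive
#' placements with the expected labels whose overall span is at most
#' `max_unit_span` form a unit, each placement used at most once. Everything
#' else is rejected with a reason.
#'
#' @param placements An alignment tibble whose `query_name` carries the
#'   subunit label (`18S`, `5.8S` or `28S`, e.g. as the query sequence name).
#' @param max_unit_span Maximum bases from the start of the first subunit to
#'   the end of the third (default 45000, about one tandem-repeat unit).
#' @return A list with `units` (tibble: `unit_id`, `seq_name`, `strand`,
#'   `start`, `end`, `subunits` list-column of the three placements in
#'   transcription order) and `rejected` (tibble of unused placements with a
#'   `reason` column: `order`, `span` or `incomplete`).
#' @export
group_valid_units <- function(placements, max_unit_span = 45000L) {
  pl <- mutate(placements, subunit = subunit_label(.data$query_name))
  bad <- is.na(pl$subunit)
  if (any(bad)) {
    abort(paste0("placement(s) without an 18S/5.8S/28S label: ",
                 paste(unique(pl$query_name[bad]), collapse = ", ")))
  }
  units <- list(); rejected <- list()
  keys <- distinct(pl, .data$target_name, .data$strand)
  keys <- arrange(keys, .data$target_name, .data$strand)
  for (k in seq_len(nrow(keys))) {
    p <- filter(pl, .data$target_name == keys$target_name[k],
                .data$strand == keys$strand[k])
    p <- arrange(p, .data$target_start, .data$target_end)
    expected <- if (keys$strand[k] == "-") c("28S", "5.8S", "18S") else c("18S", "5.8S", "28S")
    leftover <- integer(0)
    i <- 1L
    while (i <= nrow(p)) {
      trio_ok <- FALSE
      if (i + 2L <= nrow(p)) {
        trio <- p[i:(i + 2L), , drop = FALSE]
        span <- max(trio$target_end) - min(trio$target_start)
        trio_ok <- identical(trio$subunit, expected) && span <= max_unit_span
      }
      if (trio_ok) {
        # store subunits in transcription order
        tr <- if (keys$strand[k] == "-") trio[3:1, , drop = FALSE] else trio
        units[[length(units) + 1]] <- tibble(
          seq_name = keys$target_name[k], strand = keys$strand[k],
          start = min(trio$target_start), end = max(trio$target_end),
          subunits = list(tr)
        )
        i <- i + 3L
      } else {
        leftover <- c(leftover, i)
        i <- i + 1L
      }
    }
    if (length(leftover) > 0) {
      lo <- p[leftover, , drop = FALSE]
      reason <- if (nrow(lo) < 3) {
        "incomplete"
      } else {
        # a correctly ordered triple among the leftovers can only have failed
        # on span; anything else failed on label order
        spans_ok <- vapply(seq_len(nrow(lo) - 2L), function(j) {
          identical(lo$subunit[j:(j + 2L)], expected)
        }, NA)
        if (any(spans_ok)) "span" else "order"
      }
      rejected[[length(rejected) + 1]] <- mutate(lo, reason = reason)
    }
  }
  units <- if (length(units) == 0) {
    tibble(unit_id = character(), seq_name = character(), strand = character(),
           start = integer(), end = integer(), subunits = list())
  } else {
    u <- bind_rows(units)
    u <- arrange(u, .data$seq_name, .data$start)
    mutate(u, unit_id = sprintf("rdna_unit_%04d", row_number()),
           .before = 1)
  }
  rejected <- if (length(rejected) == 0) {
    mutate(pl[0, , drop = FALSE], reason = character())
  } else {
    bind_rows(rejected)
  }
  stopifnot(3L * nrow(units) + nrow(rejected) == nrow(pl))  # each record used once
  list(units = units, rejected = rejected)
}

subunit_label <- function(query_name) {
  lab <- dplyr::case_when(
    str_detect(query_name, "(^|[^0-9.])18S") ~ "18S",
    str_detect(query_name, "5\\.8S") ~ "5.8S",
    str_detect(query_name, "(^|[^0-9.])28S") ~ "28S",
    TRUE ~ NA_character_
  )
  lab
}

#' Audit rDNA units against the rest of the annotation
#'
#' Reports every (unit, gene) pair whose genomic intervals intersect on the
#' same sequence; an empty result means no rDNA unit was placed on top of
#' another mapped gene (a clean second-pass lift-over).
#'
#' @param units The `units` tibble from [group_valid_units()].
#' @param other_genes A transcript tibble of the non-rDNA annotation.
#' @return A tibble of overlapping pairs: `unit_id`, `gene_id`,
#'   `transcript_id`, `seq_name`.
#' @export
audit_overlaps <- function(units, other_genes) {
  if (nrow(units) == 0 || nrow(other_genes) == 0) {
    return(tibble(unit_id = character(), gene_id = character(),
                  transcript_id = character(), seq_name = character()))
  }
  spans <- tibble(
    transcript_id = other_genes$transcript_id,
    gene_id = other_genes$gene_id,
    seq_name = other_genes$seq_name,
    start = map_int(other_genes$exons, ~ min(.x$start)),
    end = map_int(other_genes$exons, ~ max(.x$end))
  )
  out <- list()
  for (i in seq_len(nrow(units))) {
    hit <- spans$seq_name == units$seq_name[i] &
      spans$start < units$end[i] & units$start[i] < spans$end
    if (any(hit)) {
      out[[length(out) + 1]] <- tibble(
        unit_id = units$unit_id[i],
        gene_id = spans$gene_id[hit],
        transcript_id = spans$transcript_id[hit],
        seq_name = units$seq_name[i]
      )
    }
  }
  if (length(out) == 0) {
    return(tibble(unit_id = character(), gene_id = character(),
                  transcript_id = character(), seq_name = character()))
  }
  bind_rows(out)
}
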