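#' Read and write PAF alignment records
#'
#' PAF is the single alignment-evidence format the pipeline consumes (long
#' reads for NUMT validation, rDNA subunit placements). Identity is percent
#' matching bases over alignment block length (columns 10/11); primary status
#' comes from the `tp:A` tag and defaults to primary when the tag is absent.
#'
#' @param path Path to a PAF file (12+ tab-separated columns).
#' @return A tibble with columns `query_name`, `query_len`, `query_start`,
#'   `query_end`, `strand`, `target_name`, `target_len`, `target_start`,
#'   `target_end`, `n_matches`, `aln_len`, `mapq`, `is_primary`, `identity`
#'   (percent). Coordinates are 0-based half-open as in PAF itself.
#' @export
read_paf <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(empty_paf())
  fields <- str_split(lines, "\t")
  if (any(lengths(fields) < 12)) {
    abort(paste0("PAF line ", which(lengths(fields) < 12)[1], " has fewer than 12 columns"))
  }
  core <- do.call(rbind, map(fields, ~ .x[1:12]))
  tags <- map_chr(fields, function(x) {
    tp <- x[str_starts(x, "tp:A:")]
    if (length(tp) > 0) sub("tp:A:", "", tp[1]) else "P"
  })
  out <- tibble(
    query_name = core[, 1],
    query_len = as.integer(core[, 2]),
    query_start = as.integer(core[, 3]),
    query_end = as.integer(core[, 4]),
    strand = core[, 5],
    target_name = core[, 6],
    target_len = as.integer(core[, 7]),
    target_start = as.integer(core[, 8]),
    target_end = as.integer(core[, 9]),
    n_matches = as.integer(core[, 10]),
    aln_len = as.integer(core[, 11]),
    mapq = as.integer(core[, 12]),
    is_primary = tags %in% c("P", "I")
  )
  if (any(out$query_end <= out$query_start) || any(out$target_end <= out$target_start)) {
    abort("PAF record with end <= start")
  }
  out$identity <- 100 * out$n_matches / out$aln_len
  out
}

empty_paf <- function() {
  tibble(
    query_name = character(), query_len = integer(),
    query_start = integer(), query_end = integer(), strand = character(),
    target_name = character(), target_len = integer(),
    target_start = integer(), target_end = integer(),
    n_matches = integer(), aln_len = integer(), mapq = integer(),
    is_primary = logical(), identity = double()
  )
}

#' @param alignments An alignment tibble as returned by `read_paf()`.
#' @rdname read_paf
#' @export
write_paf <- function(alignments, path) {
  a <- alignments
  body <- if (nrow(a) == 0) character(0) else paste(
    a$query_name, a$query_len, a$query_start, a$query_end, a$strand,
    a$target_name, a$target_len, a$target_start, a$target_end,
    a$n_matches, a$aln_len, a$mapq,
    paste0("tp:A:", ifelse(a$is_primary, "P", "S")),
    sep = "\t"
  )
  writeLines(body, path)
  invisible(path)
}

#' Read and write BED intervals
#'
#' BED is emitted natively in the package's 0-based half-open convention.
#'
#' @param path Path to a 3+ column BED file.
#' @return A tibble with `seq_name`, `start`, `end` (plus `name` if present).
#' @export
read_bed <- function(path) {
  x <- suppressMessages(readr::read_tsv(path, col_names = FALSE,
                                        show_col_types = FALSE, progress = FALSE))
  if (nrow(x) == 0) return(tibble(seq_name = character(), start = integer(), end = integer()))
  out <- tibble(
    seq_name = as.character(x[[1]]),
    start = as.integer(x[[2]]),
    end = as.integer(x[[3]])
  )
  if (ncol(x) >= 4) out$name <- as.character(x[[4]])
  out
}

#' @param intervals A tibble with `seq_name`, `start`, `end` (and optional `name`).
#' @rdname read_bed
#' @export
write_bed <- function(intervals, path) {
  iv <- arrange(intervals, .data$seq_name, .data$start, .data$end)
  cols <- list(iv$seq_name, iv$start, iv$end)
  if ("name" %in% names(iv)) cols <- c(cols, list(iv$name))
  body <- if (nrow(iv) == 0) character(0) else do.call(paste, c(cols, sep = "\t"))
  writeLines(body, path)
  invisible(path)
}
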