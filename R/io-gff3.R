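#' Read and write paired-annotation GFF3
#'
#' Parses a GFF3 file with the gene -> transcript -> exon/CDS hierarchy
#' (linked through `Parent` attributes) into a transcript-model tibble.
#' External 1-based inclusive coordinates are converted to the package's
#' 0-based half-open convention at this boundary; CDS phase is retained.
#' Exon and CDS segments are stored in ascending coordinate order regardless
#' of strand.
#'
#' @param path Path to a GFF3 file.
#' @return A tibble with one row per transcript: `gene_id`, `gene_name`,
#'   `transcript_id`, `biotype`, `seq_name`, `strand`, and list-columns
#'   `exons` (tibbles of `start`, `end`) and `cds` (tibbles of `start`,
#'   `end`, `phase`; zero rows for non-coding transcripts).
#' @export
read_gff3 <- function(path) {
  lines <- readLines(path)
  lines <- lines[!str_starts(lines, "#") & nzchar(lines)]
  if (length(lines) == 0) return(empty_transcripts())
  fields <- str_split(lines, "\t")
  nf <- lengths(fields)
  if (any(nf != 9)) {
    abort(paste0("GFF3 line ", which(nf != 9)[1], " does not have 9 columns"))
  }
  m <- do.call(rbind, fields)
  feat <- tibble(
    seq_name = m[, 1], type = m[, 3],
    start = as.integer(m[, 4]) - 1L,      # to 0-based half-open
    end = as.integer(m[, 5]),
    strand = m[, 7], phase = m[, 8], attr = m[, 9]
  )
  feat$id <- gff3_attr(feat$attr, "ID")
  feat$parent <- gff3_attr(feat$attr, "Parent")

  genes <- feat[feat$type == "gene", , drop = FALSE]
  tx_types <- setdiff(unique(feat$type), c("gene", "exon", "CDS"))
  txs <- feat[feat$type %in% tx_types, , drop = FALSE]
  exons <- feat[feat$type == "exon", , drop = FALSE]
  cds <- feat[feat$type == "CDS", , drop = FALSE]

  orphan <- setdiff(cds$parent, txs$id)
  if (length(orphan) > 0) {
    abort(paste0("CDS feature(s) without a parent transcript: ",
                 paste(orphan, collapse = ", ")))
  }
  orphan_ex <- setdiff(exons$parent, txs$id)
  if (length(orphan_ex) > 0) {
    abort(paste0("exon feature(s) without a parent transcript: ",
                 paste(orphan_ex, collapse = ", ")))
  }

  gene_name <- stats::setNames(gff3_attr(genes$attr, "gene_name"), genes$id)
  biotype <- stats::setNames(gff3_attr(genes$attr, "biotype"), genes$id)

  out <- tibble(
    gene_id = txs$parent,
    transcript_id = txs$id,
    seq_name = txs$seq_name,
    strand = txs$strand
  )
  out$gene_name <- unname(gene_name[out$gene_id])
  out$gene_name <- ifelse(is.na(out$gene_name), out$gene_id, out$gene_name)
  out$biotype <- unname(biotype[out$gene_id])
  out$biotype <- ifelse(is.na(out$biotype), "protein_coding", out$biotype)
  out$exons <- map(out$transcript_id, function(id) {
    e <- exons[exons$parent == id, c("start", "end")]
    arrange(as_tibble(e), .data$start)
  })
  out$cds <- map(out$transcript_id, function(id) {
    cc <- cds[cds$parent == id, c("start", "end", "phase")]
    cc$phase <- suppressWarnings(as.integer(cc$phase))
    arrange(as_tibble(cc), .data$start)
  })
  out <- out[order(out$seq_name, map_int(out$exons, ~ min(c(.x$start, .Machine$integer.max))),
                   out$gene_id, out$transcript_id), ]
  validate_transcripts(out)
  select(out, "gene_id", "gene_name", "transcript_id", "biotype",
         "seq_name", "strand", "exons", "cds")
}

#' @param transcripts A transcript tibble as returned by `read_gff3()`.
#' @param source Value for the GFF3 source column.
#' @rdname read_gff3
#' @export
write_gff3 <- function(transcripts, path, source = "genomepair") {
  validate_transcripts(transcripts)
  tx <- arrange(transcripts, .data$seq_name,
                map_int(.data$exons, ~ min(c(.x$start, .Machine$integer.max))),
                .data$gene_id, .data$transcript_id)
  lines <- character(0)
  row9 <- function(seq, type, start, end, strand, phase, attr) {
    paste(seq, source, type, start + 1L, end, ".", strand, phase, attr, sep = "\t")
  }
  for (gid in unique(tx$gene_id)) {
    g <- tx[tx$gene_id == gid, , drop = FALSE]
    g_start <- min(map_int(g$exons, ~ min(.x$start)))
    g_end <- max(map_int(g$exons, ~ max(.x$end)))
    lines <- c(lines, row9(
      g$seq_name[1], "gene", g_start, g_end, g$strand[1], ".",
      paste0("ID=", gid, ";gene_name=", g$gene_name[1], ";biotype=", g$biotype[1])
    ))
    for (i in seq_len(nrow(g))) {
      tx_type <- if (nrow(g$cds[[i]]) > 0) "mRNA" else "transcript"
      t_start <- min(g$exons[[i]]$start)
      t_end <- max(g$exons[[i]]$end)
      lines <- c(lines, row9(
        g$seq_name[i], tx_type, t_start, t_end, g$strand[i], ".",
        paste0("ID=", g$transcript_id[i], ";Parent=", gid)
      ))
      e <- g$exons[[i]]
      for (j in seq_len(nrow(e))) {
        lines <- c(lines, row9(
          g$seq_name[i], "exon", e$start[j], e$end[j], g$strand[i], ".",
          paste0("Parent=", g$transcript_id[i])
        ))
      }
      cc <- g$cds[[i]]
      for (j in seq_len(nrow(cc))) {
        lines <- c(lines, row9(
          g$seq_name[i], "CDS", cc$start[j], cc$end[j], g$strand[i],
          cc$phase[j], paste0("Parent=", g$transcript_id[i])
        ))
      }
    }
  }
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

gff3_attr <- function(attr, key) {
  vapply(regmatches(attr, gregexpr(paste0("(^|;)", key, "=[^;]*"), attr)),
         function(x) if (length(x) > 0) sub(paste0("^;?", key, "="), "", x[1]) else NA_character_,
         "")
}

empty_transcripts <- function() {
  tibble(
    gene_id = character(), gene_name = character(),
    transcript_id = character(), biotype = character(),
    seq_name = character(), strand = character(),
    exons = list(), cds = list()
  )
}

validate_transcripts <- function(tx) {
  stopifnot(is.data.frame(tx),
            all(c("gene_id", "transcript_id", "seq_name", "strand",
                  "exons", "cds") %in% names(tx)))
  for (i in seq_len(nrow(tx))) {
    e <- tx$exons[[i]]; cc <- tx$cds[[i]]
    if (nrow(e) == 0) abort(paste0("transcript ", tx$transcript_id[i], " has no exons"))
    if (is.unsorted(e$start) || any(e$end <= e$start)) {
      abort(paste0("exons of ", tx$transcript_id[i], " not sorted non-overlapping"))
    }
    if (nrow(e) > 1 && any(e$start[-1] < e$end[-nrow(e)])) {
      abort(paste0("exons of ", tx$transcript_id[i], " overlap"))
    }
    if (nrow(cc) > 0) {
      # every CDS segment must lie inside some exon
      inside <- vapply(seq_len(nrow(cc)), function(j) {
        any(e$start <= cc$start[j] & cc$end[j] <= e$end)
      }, NA)
      if (!all(inside)) {
        abort(paste0("CDS of ", tx$transcript_id[i], " not contained in exons"))
      }
    }
  }
  invisible(tx)
}
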