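#' Roll transcript verdicts up to genes
#'
#' Per gene, the representative transcript is the isoform with the highest
#' protein identity to its counterpart (ties broken by lexicographically
#' smallest `transcript_id`), and the gene inherits that transcript's effect
#' category — so a gene with one intact isoform is called by the intact one.
#' Non-coding verdicts (category `NA`) are ignored. The result is independent
#' of the input row order.
#'
#' @param verdicts A verdict tibble from [classify_transcripts()].
#' @param tx2gene Optional tibble (`transcript_id`, `gene_id`) overriding the
#'   gene assignment carried in `verdicts`.
#' @return A gene-verdict tibble: `gene_id`, `gene_name`, `representative_tx`,
#'   `category`, `aa_identity`, `deleterious`.
#' @export
rollup_genes <- function(verdicts, tx2gene = NULL) {
  v <- verdicts
  if (!is.null(tx2gene)) {
    v <- select(v, -dplyr::any_of("gene_id"))
    v <- left_join(v, tx2gene, by = "transcript_id")
  }
  if (anyNA(v$gene_id)) {
    abort(paste0("transcript(s) without a gene: ",
                 paste(v$transcript_id[is.na(v$gene_id)], collapse = ", ")))
  }
  v <- filter(v, !is.na(.data$category))
  if (!"gene_name" %in% names(v)) v$gene_name <- v$gene_id
  v <- arrange(v, .data$gene_id, dplyr::desc(.data$aa_identity), .data$transcript_id)
  rep_rows <- v[!duplicated(v$gene_id), , drop = FALSE]
  tibble(
    gene_id = rep_rows$gene_id,
    gene_name = rep_rows$gene_name,
    representative_tx = rep_rows$transcript_id,
    category = rep_rows$category,
    aa_identity = rep_rows$aa_identity,
    deleterious = rep_rows$category %in% DELETERIOUS_CATEGORIES
  )
}

#' Summarise gene categories
#'
#' `category_summary()` computes the conserved/altered accounting from
#' per-category gene counts: conserved genes are `identical` + `synonymous`,
#' the conserved fraction is rounded half-up to a whole percent, and the
#' deleterious total sums start-loss, stop-gain, 5'/3' truncation and
#' frameshift. `summarize_genes()` tallies a gene-verdict tibble first.
#'
#' @param counts A named numeric vector or a tibble (`category`, `n`) of gene
#'   counts per effect category.
#' @return An object of class `category_summary`; see [tidy()] and
#'   [glance()] methods.
#' @export
#' @examples
#' s <- category_summary(c(identical = 8, synonymous = 1, frameshift = 1))
#' glance(s)
category_summary <- function(counts) {
  if (is.data.frame(counts)) {
    counts <- stats::setNames(counts$n, counts$category)
  }
  bad <- setdiff(names(counts), EFFECT_CATEGORIES)
  if (length(bad) > 0) {
    abort(paste0("unknown category label(s): ", paste(bad, collapse = ", ")))
  }
  full <- stats::setNames(numeric(length(EFFECT_CATEGORIES)), EFFECT_CATEGORIES)
  full[names(counts)] <- counts
  total <- sum(full)
  if (total == 0) abort("category_summary: no genes")
  conserved <- sum(full[c("identical", "synonymous")])
  out <- list(
    counts = tibble(category = names(full), n = as.numeric(full)),
    total = total,
    conserved_count = conserved,
    altered_count = total - conserved,
    conserved_fraction = conserved / total,
    conserved_pct = floor(100 * conserved / total + 0.5),  # half-up
    deleterious_total = sum(full[DELETERIOUS_CATEGORIES])
  )
  class(out) <- "category_summary"
  out
}

#' @param gene_verdicts A gene-verdict tibble from [rollup_genes()].
#' @rdname category_summary
#' @export
summarize_genes <- function(gene_verdicts) {
  category_summary(count(gene_verdicts, category = .data$category))
}

#' @export
print.category_summary <- function(x, ...) {
  cat("Gene category summary:", x$total, "genes\n")
  cat("  conserved:", x$conserved_count, paste0("(", x$conserved_pct, "%)"),
      " altered:", x$altered_count, "\n")
  cat("  deleterious (start_lost + stop_gained + truncations + frameshift):",
      x$deleterious_total, "\n")
  print(x$counts, n = Inf)
  invisible(x)
}

#' @export
tidy.category_summary <- function(x, ...) {
  mutate(x$counts, fraction = .data$n / x$total,
         conserved = .data$category %in% c("identical", "synonymous"),
         deleterious = .data$category %in% DELETERIOUS_CATEGORIES)
}

#' @export
glance.category_summary <- function(x, ...) {
  tibble(
    total = x$total, conserved_count = x$conserved_count,
    altered_count = x$altered_count, conserved_pct = x$conserved_pct,
    deleterious_total = x$deleterious_total
  )
}

#' Zygosity rescue of candidate deleterious genes
#'
#' Keeps only candidate genes whose damage is supported by at least one
#' homozygous, non-SNP variant inside a coding exon: heterozygous candidates
#' are dropped because the alternative haplotype retains an intact copy.
#' Variants are filtered to `hom` and `!is_snp`, intersected with the union
#' of CDS exon intervals over all transcripts of each candidate gene (in the
#' coordinate system the variants were called in), and deduplicated by
#' (sequence, position, ref, alt) within each gene so isoform exon sharing
#' does not inflate site counts.
#'
#' @param deleterious A gene-verdict tibble (typically
#'   `filter(rollup_genes(...), deleterious)`).
#' @param variants A variant tibble ([read_vcf()]).
#' @param annotation The transcript tibble of the genome the variants are
#'   called against.
#' @return The surviving subset of `deleterious` with `n_sites` and a `sites`
#'   list-column; attribute `n_distinct_sites` counts distinct sites across
#'   all surviving genes.
#' @export
zygosity_rescue <- function(deleterious, variants, annotation) {
  hom_nonsnp <- filter(variants, .data$zygosity == "hom", !.data$is_snp)
  survivors <- list()
  all_sites <- list()
  for (i in seq_len(nrow(deleterious))) {
    gid <- deleterious$gene_id[i]
    tx <- annotation[annotation$gene_id == gid, , drop = FALSE]
    if (nrow(tx) == 0) next
    cds_iv <- bind_rows(map2(tx$cds, tx$seq_name, function(cc, sn) {
      if (nrow(cc) == 0) return(NULL)
      tibble(seq_name = sn, start = cc$start, end = cc$end)
    }))
    if (is.null(cds_iv) || nrow(cds_iv) == 0) next
    hits <- list()
    for (sn in unique(cds_iv$seq_name)) {
      iv <- cds_iv[cds_iv$seq_name == sn, , drop = FALSE]
      merged <- IRanges::reduce(IRanges::IRanges(start = iv$start + 1L, end = iv$end))
      vv <- hom_nonsnp[hom_nonsnp$seq_name == sn, , drop = FALSE]
      if (nrow(vv) == 0) next
      vr <- IRanges::IRanges(start = vv$pos + 1L,
                             end = vv$pos + nchar(vv$ref_allele))
      ov <- IRanges::findOverlaps(vr, merged)
      if (length(ov) > 0) hits[[sn]] <- vv[unique(S4Vectors::queryHits(ov)), , drop = FALSE]
    }
    if (length(hits) == 0) next
    sites <- distinct(bind_rows(hits), .data$seq_name, .data$pos,
                      .data$ref_allele, .data$alt_allele)
    row <- deleterious[i, , drop = FALSE]
    row$n_sites <- nrow(sites)
    row$sites <- list(sites)
    survivors[[length(survivors) + 1]] <- row
    all_sites[[length(all_sites) + 1]] <- sites
  }
  out <- if (length(survivors) == 0) {
    mutate(deleterious[0, , drop = FALSE], n_sites = integer(), sites = list())
  } else {
    bind_rows(survivors)
  }
  distinct_sites <- if (length(all_sites) == 0) 0L else {
    nrow(distinct(bind_rows(all_sites)))
  }
  attr(out, "n_distinct_sites") <- distinct_sites
  out
}

#' Protein-level report against a reference protein set
#'
#' For each gene, compares the proteins translated from both assemblies to an
#' external reference protein (e.g. RefSeq): protein lengths, length ratio
#' (assembly / reference, 3 decimals) and global amino-acid identity
#' (3 decimals). A gene whose reference protein is missing is flagged, not
#' dropped.
#'
#' @param gene_ids Character vector of gene identifiers to report.
#' @param ref_proteins,subj_proteins,refseq_proteins Protein tibbles
#'   (`seq_name` = gene id, `residues` = amino-acid sequence), e.g. from
#'   [read_fasta()].
#' @return A tibble with one row per gene: lengths, `ref_length_ratio`,
#'   `subj_length_ratio`, `ref_identity`, `subj_identity`, `missing_refseq`.
#' @export
protein_report <- function(gene_ids, ref_proteins, subj_proteins, refseq_proteins) {
  rows <- map(gene_ids, function(g) {
    rs <- refseq_proteins$residues[match(g, refseq_proteins$seq_name)]
    rp <- ref_proteins$residues[match(g, ref_proteins$seq_name)]
    sp <- subj_proteins$residues[match(g, subj_proteins$seq_name)]
    base <- tibble(
      gene_id = g,
      refseq_len = nchar(rs) %||% NA_integer_,
      ref_len = nchar(rp) %||% NA_integer_,
      subj_len = nchar(sp) %||% NA_integer_,
      missing_refseq = is.na(rs)
    )
    if (is.na(rs)) {
      return(mutate(base, ref_length_ratio = NA_real_, subj_length_ratio = NA_real_,
                    ref_identity = NA_real_, subj_identity = NA_real_))
    }
    mutate(base,
      ref_length_ratio = length_ratio(base$ref_len, base$refseq_len),
      subj_length_ratio = length_ratio(base$subj_len, base$refseq_len),
      ref_identity = if (is.na(rp)) NA_real_ else
        round(global_identity(rs, rp, "protein")$identity, 3),
      subj_identity = if (is.na(sp)) NA_real_ else
        round(global_identity(rs, sp, "protein")$identity, 3)
    )
  })
  bind_rows(rows)
}

#' Protein length ratio
#'
#' Assembly protein length over reference protein length, rounded to three
#' decimals — the worked arithmetic of the protein-level comparison table.
#'
#' @param len Assembly protein length (aa).
#' @param refseq_len Reference protein length (aa).
#' @return The ratio rounded to 3 decimals.
#' @export
#' @examples
#' length_ratio(1241, 6985)
length_ratio <- function(len, refseq_len) {
  if (any(refseq_len <= 0)) abort("reference protein length must be positive")
  round(len / refseq_len, 3)
}
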