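#' Extract the coding (or spliced) sequence of a transcript
#'
#' Concatenates the CDS segments of one transcript in transcription order and
#' reverse-complements minus-strand models; output is upper case regardless of
#' the genome's soft-masking. With `what = "exons"` the spliced exon sequence
#' is returned instead (used for DNA-only comparison of non-coding
#' transcripts).
#'
#' @param genome A genome tibble (`seq_name`, `residues`).
#' @param tx A one-row transcript tibble (see [read_gff3()]).
#' @param what `"cds"` or `"exons"`.
#' @return A nucleotide string.
#' @export
extract_cds <- function(genome, tx, what = c("cds", "exons")) {
  what <- match.arg(what)
  stopifnot(nrow(tx) == 1)
  segs <- tx[[what]][[1]]
  if (nrow(segs) == 0) {
    abort(paste0("transcript ", tx$transcript_id, " has no ", toupper(what), " segments"))
  }
  res <- genome_seq(genome, tx$seq_name)
  if (max(segs$end) > nchar(res)) {
    abort(paste0("transcript ", tx$transcript_id, " extends past end of ", tx$seq_name))
  }
  pieces <- substring(res, segs$start + 1L, segs$end)
  s <- toupper(paste(pieces, collapse = ""))
  if (tx$strand == "-") revcomp(s) else s
}

#' Classify one pair of coding sequences
#'
#' The heart of the annotation comparison: given the reference and subject CDS
#' of the same transcript, assigns one of the ten effect categories. The
#' decision sequence is (1) byte-identical CDS is `identical`; (2) identical
#' proteins are `synonymous`; (3) otherwise features are detected on a global
#' DNA alignment and the most severe one (per `severity`) wins:
#'
#' * a terminal alignment gap removing the reference 5'/3' terminus including
#'   the whole start/stop codon -> `truncation_5p` / `truncation_3p`;
#' * any other single indel whose length is not a multiple of 3 ->
#'   `frameshift`;
#' * a premature stop codon in the subject translation -> `stop_gained`;
#' * a substituted (not truncated-away) start codon -> `start_lost`;
#' * indels all multiples of 3 -> `inframe_insertion` / `inframe_deletion` by
#'   the sign of the net length difference;
#' * pure substitutions at equal length -> `nonsynonymous`.
#'
#' @param ref_cds,subj_cds Coding sequences (strings).
#' @param severity Character vector ordering feature labels from most to
#'   least severe; the default is
#'   frameshift > stop_gained > start_lost > truncation_5p > truncation_3p >
#'   inframe > nonsynonymous.
#' @return A list: `category`, `dna_identity`, `aa_identity` (fractions),
#'   `ref_protein_len`, `subj_protein_len`.
#' @export
#' @examples
#' classify_cds("ATGAAATTTTAA", "ATGAAATTCTAA")$category  # synonymous
#' classify_cds("ATGAAATTTTAA", "ATGAATTTTAA")$category   # frameshift
classify_cds <- function(ref_cds, subj_cds, severity = DEFAULT_SEVERITY) {
  ref_cds <- toupper(ref_cds)
  subj_cds <- toupper(subj_cds)
  tr_ref <- translate_cds(ref_cds)
  tr_subj <- translate_cds(subj_cds)
  out <- list(
    category = NA_character_,
    dna_identity = NA_real_, aa_identity = NA_real_,
    ref_protein_len = nchar(tr_ref$protein),
    subj_protein_len = nchar(tr_subj$protein)
  )
  if (identical(ref_cds, subj_cds)) {
    out$category <- "identical"
    out$dna_identity <- 1
    out$aa_identity <- 1
    return(out)
  }
  out$dna_identity <- global_identity(ref_cds, subj_cds, "dna")$identity
  if (identical(tr_ref$protein, tr_subj$protein) && nzchar(tr_ref$protein) &&
      tr_ref$premature_stop == tr_subj$premature_stop) {
    out$category <- "synonymous"
    out$aa_identity <- 1
    return(out)
  }
  out$aa_identity <- protein_identity(tr_ref$protein, tr_subj$protein)

  feats <- cds_alignment_features(ref_cds, subj_cds)
  features <- character(0)
  if (feats$trunc5) features <- c(features, "truncation_5p")
  if (feats$trunc3) features <- c(features, "truncation_3p")
  if (feats$frameshift) features <- c(features, "frameshift")
  if (tr_subj$premature_stop) features <- c(features, "stop_gained")
  if (!feats$trunc5 && substr(subj_cds, 1, 3) != "ATG" &&
      substr(ref_cds, 1, 3) == "ATG") {
    features <- c(features, "start_lost")
  }
  if (feats$inframe != "none") features <- c(features, feats$inframe)
  if (feats$has_substitution) features <- c(features, "nonsynonymous")

  hit <- severity[severity %in% features]
  out$category <- if (length(hit) > 0) hit[1] else "nonsynonymous"
  out
}

protein_identity <- function(p1, p2) {
  if (!nzchar(p1) || !nzchar(p2)) return(0)
  global_identity(p1, p2, "protein")$identity
}

# Detect truncation / frameshift / in-frame indel evidence from the global
# DNA alignment of a CDS pair. Gap placement inside repeats is ambiguous, so
# a deletion run counts as a terminal (truncation) gap when it is *shiftable*
# to the sequence terminus, not only when the aligner happened to put it
# there.
cds_alignment_features <- function(ref_cds, subj_cds) {
  aln <- align_global(ref_cds, subj_cds, "dna")
  pa <- aln$pattern   # reference with gaps
  sb <- aln$subject   # subject with gaps
  runs <- function(s) {
    m <- gregexpr("-+", s)[[1]]
    if (m[1] == -1) return(tibble(start = integer(), len = integer()))
    tibble(start = as.integer(m), len = attr(m, "match.length"))
  }
  del <- runs(sb)  # gaps in subject = reference bases missing from subject
  ins <- runs(pa)  # gaps in reference = extra subject bases

  # ref coordinates (1-based) covered by each deletion run
  pa_chars <- strsplit(pa, "", fixed = TRUE)[[1]]
  nongap_before <- cumsum(pa_chars != "-")
  n_ref <- nchar(ref_cds)
  del$ref_start <- ifelse(del$start == 1, 1L, nongap_before[del$start - 1] + 1L)
  del$ref_end <- del$ref_start + del$len - 1L

  # a deletion of ref[i..j] equals a 5'-terminal deletion iff
  # ref[1..i-1] == ref[j-i+2..j]; symmetric at the 3' end
  can5 <- vapply(seq_len(nrow(del)), function(k) {
    i <- del$ref_start[k]; j <- del$ref_end[k]
    substr(ref_cds, 1, i - 1) == substr(ref_cds, j - i + 2, j)
  }, NA)
  can3 <- vapply(seq_len(nrow(del)), function(k) {
    i <- del$ref_start[k]; j <- del$ref_end[k]
    substr(ref_cds, j + 1, n_ref) == substr(ref_cds, i, i + (n_ref - j) - 1)
  }, NA)
  is_t5 <- can5 & del$len >= 3   # must remove at least the whole start codon
  is_t3 <- !is_t5 & can3 & del$len >= 3
  trunc5 <- any(is_t5)
  trunc3 <- any(is_t3)
  del_keep <- del[!is_t5 & !is_t3, , drop = FALSE]

  indel_lens <- c(del_keep$len, ins$len)
  frameshift <- any(indel_lens %% 3 != 0)
  net <- sum(ins$len) - sum(del_keep$len)
  inframe <- "none"
  if (!frameshift && length(indel_lens) > 0) {
    if (net > 0) inframe <- "inframe_insertion"
    if (net < 0) inframe <- "inframe_deletion"
  }
  sb_chars <- strsplit(sb, "", fixed = TRUE)[[1]]
  both <- pa_chars != "-" & sb_chars != "-"
  list(trunc5 = trunc5, trunc3 = trunc3, frameshift = frameshift,
       inframe = inframe, net_indel = net,
       has_substitution = any(both & pa_chars != sb_chars))
}

#' Classify all paired transcripts between two annotated genomes
#'
#' Joins the two annotations on `transcript_id` and classifies every pair.
#' Coding pairs get a category, DNA identity and protein identity; pairs
#' without CDS in either annotation get DNA identity of the spliced exon
#' sequence only (category `NA`). A transcript coding in one annotation but
#' not the other raises an error (a structural annotation defect, distinct
#' from an unmapped transcript, which is simply absent from the join and
#' counted in the `n_unmapped` attribute).
#'
#' @param ref_transcripts,subj_transcripts Transcript tibbles ([read_gff3()]).
#' @param ref_genome,subj_genome Genome tibbles ([read_fasta()]).
#' @param severity Severity precedence passed to [classify_cds()].
#' @return A verdict tibble: `transcript_id`, `gene_id`, `gene_name`,
#'   `biotype`, `category`, `dna_identity`, `aa_identity`,
#'   `ref_protein_len`, `subj_protein_len`; attribute `n_unmapped` counts
#'   reference transcripts with no subject counterpart.
#' @export
classify_transcripts <- function(ref_transcripts, subj_transcripts,
                                 ref_genome, subj_genome,
                                 severity = DEFAULT_SEVERITY) {
  shared <- intersect(ref_transcripts$transcript_id, subj_transcripts$transcript_id)
  n_unmapped <- sum(!ref_transcripts$transcript_id %in% shared)
  ref_t <- ref_transcripts[match(shared, ref_transcripts$transcript_id), , drop = FALSE]
  subj_t <- subj_transcripts[match(shared, subj_transcripts$transcript_id), , drop = FALSE]

  rows <- map(seq_along(shared), function(i) {
    rtx <- ref_t[i, ]; stx <- subj_t[i, ]
    ref_coding <- nrow(rtx$cds[[1]]) > 0
    subj_coding <- nrow(stx$cds[[1]]) > 0
    if (xor(ref_coding, subj_coding)) {
      abort(paste0("transcript ", shared[i],
                   " has CDS in only one annotation (structural defect)"))
    }
    if (!ref_coding) {
      a <- extract_cds(ref_genome, rtx, "exons")
      b <- extract_cds(subj_genome, stx, "exons")
      dna <- if (identical(a, b)) 1 else global_identity(a, b, "dna")$identity
      return(tibble(
        transcript_id = shared[i], gene_id = rtx$gene_id,
        gene_name = rtx$gene_name, biotype = rtx$biotype,
        category = NA_character_, dna_identity = dna, aa_identity = NA_real_,
        ref_protein_len = NA_integer_, subj_protein_len = NA_integer_
      ))
    }
    v <- classify_cds(extract_cds(ref_genome, rtx), extract_cds(subj_genome, stx),
                      severity = severity)
    tibble(
      transcript_id = shared[i], gene_id = rtx$gene_id,
      gene_name = rtx$gene_name, biotype = rtx$biotype,
      category = v$category, dna_identity = v$dna_identity,
      aa_identity = v$aa_identity,
      ref_protein_len = v$ref_protein_len, subj_protein_len = v$subj_protein_len
    )
  })
  out <- bind_rows(rows)
  attr(out, "n_unmapped") <- n_unmapped
  out
}
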