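#' Simulation configuration
#'
#' Parameters of the synthetic genome-pair generator. Defaults describe the
#' desk-scale study conditions the package is tested under: ~50 multi-exon
#' protein-coding genes covering all ten effect categories, heterozygous and
#' homozygous planted variants, one NUMT with 26 spanning reads, five tandem
#' rDNA units with decoy placements, and lowercase donor patches.
#'
#' @param seed Integer seed; every simulation draw derives from it.
#' @param n_genes Number of genes on the gene chromosome.
#' @param category_counts Named integer vector of planted genes per effect
#'   category; `NULL` scales a default mix (all ten categories represented)
#'   to `n_genes`.
#' @param exons_per_gene Inclusive range of exon counts per gene.
#' @param cds_len Inclusive range of CDS lengths (bases; forced to multiples
#'   of 3, minimum 90).
#' @param intron_len,intergenic_len Inclusive ranges (bases).
#' @param het_fraction_deleterious Probability that a deleterious planted
#'   variant is heterozygous (rescued later).
#' @param het_fraction_benign Same for benign (non-deleterious) edits.
#' @param het_intact_fraction Fraction of heterozygous planted genes whose
#'   subject sequence keeps the intact haplotype (the assembly picked the
#'   undamaged copy); those genes classify as identical.
#' @param rdna_units Number of planted valid rDNA units.
#' @param rdna_decoys Add decoy subunit placements (wrong order, incomplete)
#'   and decoy array candidates (short, low identity).
#' @param rdna_divergence Percent divergence of planted rDNA copies from the
#'   reference unit (identity = 100 - divergence).
#' @param numt_len NUMT insertion length (bases).
#' @param numt_spanning,numt_nonspanning Spanning read count and decoy count.
#' @param numt_flank Required flank the planted spanning reads satisfy.
#' @param donor_patch_len Bases lowercased at the start of each subject
#'   sequence (donor provenance marking).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed,
                       n_genes = 50L,
                       category_counts = NULL,
                       exons_per_gene = c(2L, 4L),
                       cds_len = c(150L, 300L),
                       intron_len = c(60L, 150L),
                       intergenic_len = c(150L, 400L),
                       het_fraction_deleterious = 0.4,
                       het_fraction_benign = 0.5,
                       het_intact_fraction = 0,
                       rdna_units = 5L,
                       rdna_decoys = TRUE,
                       rdna_divergence = 1,
                       numt_len = 13781L,
                       numt_spanning = 26L,
                       numt_nonspanning = 10L,
                       numt_flank = 500L,
                       donor_patch_len = 500L) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  if (is.null(category_counts)) {
    category_counts <- default_category_counts(n_genes)
  }
  stopifnot(all(names(category_counts) %in% EFFECT_CATEGORIES),
            sum(category_counts) == n_genes,
            all(category_counts >= 0))
  cds_len <- pmax(90L, as.integer(cds_len))
  cfg <- list(
    seed = as.integer(seed), n_genes = as.integer(n_genes),
    category_counts = category_counts,
    exons_per_gene = as.integer(exons_per_gene),
    cds_len = cds_len, intron_len = as.integer(intron_len),
    intergenic_len = as.integer(intergenic_len),
    het_fraction_deleterious = het_fraction_deleterious,
    het_fraction_benign = het_fraction_benign,
    het_intact_fraction = het_intact_fraction,
    rdna_units = as.integer(rdna_units), rdna_decoys = isTRUE(rdna_decoys),
    rdna_divergence = rdna_divergence,
    rdna_lens = c(`18S` = 1800L, `5.8S` = 160L, `28S` = 4000L),
    rdna_spacers = c(ets5 = 700L, its1 = 300L, its2 = 250L, ets3 = 500L),
    rdna_gap = 2000L,
    numt_len = as.integer(numt_len),
    numt_spanning = as.integer(numt_spanning),
    numt_nonspanning = as.integer(numt_nonspanning),
    numt_flank = as.integer(numt_flank),
    donor_patch_len = as.integer(donor_patch_len)
  )
  class(cfg) <- "sim_config"
  cfg
}

default_category_counts <- function(n_genes) {
  props <- c(
    identical = 0.28, synonymous = 0.10, nonsynonymous = 0.12,
    inframe_insertion = 0.08, inframe_deletion = 0.08,
    start_lost = 0.06, stop_gained = 0.06,
    truncation_5p = 0.06, truncation_3p = 0.06, frameshift = 0.10
  )
  if (n_genes < 10) abort("need at least 10 genes to plant all ten categories")
  counts <- stats::setNames(pmax(1L, as.integer(floor(props * n_genes))), names(props))
  # pad/trim the identical class to hit n_genes exactly
  counts["identical"] <- counts["identical"] + (n_genes - sum(counts))
  if (counts["identical"] < 1) abort("category counts exceed n_genes")
  counts
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

random_cds <- function(cds_len) {
  n_codon <- cds_len %/% 3
  non_stop <- setdiff(names(Biostrings::GENETIC_CODE), STOP_CODONS)
  internal <- sample(non_stop, n_codon - 2L, replace = TRUE)
  paste0("ATG", paste(internal, collapse = ""), sample(STOP_CODONS, 1))
}

rint <- function(range) {
  if (range[1] == range[2]) return(range[1])
  sample(seq(range[1], range[2]), 1)
}

#' Generate a reference genome and annotation
#'
#' Builds the gene chromosome of the synthetic pair: `n_genes` multi-exon
#' protein-coding genes on alternating strands, each with an ATG start, an
#' in-frame terminal stop codon and no internal stop, separated by random
#' intergenic sequence. Deterministic under the config seed (the caller is
#' expected to have seeded the RNG; [simulate_genome_pair()] does).
#'
#' @param config A [sim_config()].
#' @return A list with `genome` (tibble, one sequence `sim1`) and
#'   `transcripts` (one transcript per gene).
#' @export
generate_reference <- function(config) {
  n <- config$n_genes
  pieces <- character(0)
  tx_rows <- list()
  cursor <- 0L
  for (g in seq_len(n)) {
    inter <- rint(config$intergenic_len)
    pieces <- c(pieces, random_dna(inter))
    cursor <- cursor + inter
    cds_len <- 3L * (rint(config$cds_len) %/% 3L)
    n_exons <- rint(config$exons_per_gene)
    strand <- if (g %% 2 == 0) "-" else "+"
    gene <- build_gene_region(cds_len, n_exons, config$intron_len, strand)
    gid <- sprintf("g%03d", g)
    segs <- mutate(gene$segments, start = .data$start + cursor, end = .data$end + cursor)
    tx_rows[[g]] <- tibble(
      gene_id = gid, gene_name = toupper(gid),
      transcript_id = paste0(gid, ".t1"), biotype = "protein_coding",
      seq_name = "sim1", strand = strand,
      exons = list(select(segs, "start", "end")),
      cds = list(select(segs, "start", "end", "phase"))
    )
    pieces <- c(pieces, gene$region)
    cursor <- cursor + nchar(gene$region)
  }
  tail_len <- rint(config$intergenic_len)
  pieces <- c(pieces, random_dna(tail_len))
  residues <- paste(pieces, collapse = "")
  genome <- tibble(seq_name = "sim1", residues = residues, length = nchar(residues))
  list(genome = genome, transcripts = bind_rows(tx_rows))
}

# One gene region: CDS split over n_exons segments with introns; returns the
# (strand-applied) genomic region string and ascending-coordinate segments
# with phase, in region-local coordinates.
build_gene_region <- function(cds_len, n_exons, intron_len, strand) {
  cds <- random_cds(cds_len)
  base <- cds_len %/% n_exons
  cuts <- if (n_exons == 1) integer(0) else {
    base * seq_len(n_exons - 1L) + sample(-3:3, n_exons - 1L, replace = TRUE)
  }
  bounds <- c(0L, as.integer(cuts), cds_len)
  seg_lens <- diff(bounds)
  stopifnot(all(seg_lens >= 9))
  exon_seqs <- substring(cds, bounds[-length(bounds)] + 1L, bounds[-1])
  introns <- vapply(seq_len(n_exons - 1L), function(i) random_dna(rint(intron_len)), "")
  # sense layout: e1 i1 e2 i2 ... ek
  region_sense <- paste0(paste0(exon_seqs, c(introns, "")), collapse = "")
  pos <- 0L
  seg <- list()
  cum <- 0L
  for (j in seq_len(n_exons)) {
    seg[[j]] <- tibble(start = pos, end = pos + seg_lens[j],
                       phase = (3L - cum %% 3L) %% 3L)
    cum <- cum + seg_lens[j]
    pos <- pos + seg_lens[j] + if (j < n_exons) nchar(introns[j]) else 0L
  }
  segs <- bind_rows(seg)
  if (strand == "-") {
    L <- nchar(region_sense)
    segs <- tibble(start = L - segs$end, end = L - segs$start, phase = segs$phase)
    segs <- arrange(segs, .data$start)
    region <- revcomp(region_sense)
  } else {
    region <- region_sense
  }
  list(region = region, segments = segs, cds = cds)
}

#' Plant one effect category into a coding sequence
#'
#' Mutates a valid CDS so that [classify_cds()] assigns exactly the requested
#' category, and returns the edit in CDS coordinates so it can be mapped onto
#' the genome. Edits are always placed wholly inside one CDS segment (so a
#' lifted annotation stays consistent) and are chosen so deleterious edits
#' are non-SNP variants: frameshifts are 2-bp deletions, start losses and
#' stop gains are whole-codon replacements, truncations delete a
#' multiple-of-3 terminus including the start/stop codon.
#'
#' @param ref_cds A valid CDS string (ATG start, terminal stop, no internal
#'   stop).
#' @param category One of [effect_categories()].
#' @param seg_lens CDS segment lengths in transcription order (defaults to a
#'   single segment).
#' @return A list: `cds` (mutated sequence), `edit` (`NULL` or a list with
#'   0-based `pos`, `ref`, `alt` in CDS coordinates), `detail`.
#' @export
plant_effect <- function(ref_cds, category, seg_lens = nchar(ref_cds)) {
  category <- match.arg(category, EFFECT_CATEGORIES)
  n_codon <- nchar(ref_cds) %/% 3L
  codons <- substring(ref_cds, 3L * seq_len(n_codon) - 2L, 3L * seq_len(n_codon))
  seg_bounds <- cumsum(seg_lens)
  codon_in_one_segment <- function(i) {
    # bases [3(i-1), 3i) must not straddle a segment boundary
    a <- 3L * (i - 1L)
    seg_a <- findInterval(a, seg_bounds) # 0-based segment index of first base
    seg_b <- findInterval(3L * i - 1L, seg_bounds)
    seg_a == seg_b
  }
  internal <- setdiff(seq_len(n_codon - 1L), 1L)
  internal <- internal[vapply(internal, codon_in_one_segment, NA)]
  if (length(internal) == 0 && !category %in% c("identical", "truncation_5p", "truncation_3p")) {
    abort("no internal codon lies wholly inside one CDS segment")
  }
  apply_edit <- function(pos, ref, alt) {
    stopifnot(substr(ref_cds, pos + 1L, pos + nchar(ref)) == ref)
    mutated <- paste0(substr(ref_cds, 1, pos), alt,
                      substr(ref_cds, pos + nchar(ref) + 1L, nchar(ref_cds)))
    list(cds = mutated, edit = list(pos = pos, ref = ref, alt = alt))
  }
  out <- switch(category,
    identical = list(cds = ref_cds, edit = NULL),
    synonymous = {
      found <- NULL
      for (i in sample(internal)) {
        c0 <- codons[i]
        aa <- Biostrings::GENETIC_CODE[[c0]]
        syn <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE == aa]
        one_off <- syn[vapply(syn, function(s) {
          sum(strsplit(s, "")[[1]] != strsplit(c0, "")[[1]]) == 1
        }, NA)]
        if (length(one_off) > 0) {
          s <- sample(one_off, 1)
          d <- which(strsplit(s, "")[[1]] != strsplit(c0, "")[[1]])
          found <- apply_edit(3L * (i - 1L) + d - 1L,
                              substr(c0, d, d), substr(s, d, d))
          break
        }
      }
      if (is.null(found)) abort("no synonymous single-base site available")
      found
    },
    nonsynonymous = {
      found <- NULL
      for (i in sample(internal)) {
        c0 <- strsplit(codons[i], "")[[1]]
        for (p in sample(1:3)) {
          for (b in sample(setdiff(c("A", "C", "G", "T"), c0[p]))) {
            cn <- c0; cn[p] <- b
            aa_new <- Biostrings::GENETIC_CODE[[paste(cn, collapse = "")]]
            if (aa_new != "*" && aa_new != Biostrings::GENETIC_CODE[[codons[i]]]) {
              found <- apply_edit(3L * (i - 1L) + p - 1L, c0[p], b)
              break
            }
          }
          if (!is.null(found)) break
        }
        if (!is.null(found)) break
      }
      if (is.null(found)) abort("no nonsynonymous site available")
      found
    },
    inframe_insertion = {
      # insert one codon at a boundary strictly inside a segment
      ok <- internal[vapply(internal, function(i) {
        p <- 3L * (i - 1L)
        p > 0 && !p %in% seg_bounds
      }, NA)]
      if (length(ok) == 0) abort("no in-segment codon boundary for insertion")
      p <- 3L * (sample(ok, 1) - 1L)
      apply_edit(p, "", "GCT")
    },
    inframe_deletion = {
      i <- sample(internal, 1)
      apply_edit(3L * (i - 1L), codons[i], "")
    },
    start_lost = apply_edit(0L, "ATG", "CTT"),
    stop_gained = {
      ok <- internal[vapply(internal, function(i) {
        sum(strsplit(codons[i], "")[[1]] != c("T", "A", "A")) >= 2
      }, NA)]
      if (length(ok) == 0) abort("no codon two substitutions from TAA available")
      i <- sample(ok, 1)
      apply_edit(3L * (i - 1L), codons[i], "TAA")
    },
    frameshift = {
      i <- sample(internal, 1)
      p <- 3L * (i - 1L)
      apply_edit(p, substr(ref_cds, p + 1L, p + 2L), "")
    },
    truncation_5p = {
      if (seg_lens[1] < 6L) abort("first CDS segment too short to truncate")
      apply_edit(0L, substr(ref_cds, 1, 6), "")
    },
    truncation_3p = {
      L <- nchar(ref_cds)
      if (seg_lens[length(seg_lens)] < 6L) abort("last CDS segment too short to truncate")
      apply_edit(L - 6L, substr(ref_cds, L - 5L, L), "")
    }
  )
  out$detail <- if (is.null(out$edit)) "no edit" else {
    sprintf("cds_pos=%d ref=%s alt=%s", out$edit$pos,
            ifelse(nzchar(out$edit$ref), out$edit$ref, "-"),
            ifelse(nzchar(out$edit$alt), out$edit$alt, "-"))
  }
  out
}

# Map an edit in CDS coordinates onto the genome. The edit must sit wholly
# inside one CDS segment. Returns gstart (0-based), ref/alt on the genomic
# plus strand.
cds_edit_to_genomic <- function(edit, tx) {
  cc <- tx$cds[[1]]
  segs <- if (tx$strand == "-") cc[rev(seq_len(nrow(cc))), , drop = FALSE] else cc
  lens <- segs$end - segs$start
  cum <- cumsum(c(0L, lens))
  len_ref <- nchar(edit$ref)
  probe <- if (len_ref > 0) edit$pos else max(edit$pos - 1L, 0L)
  j <- findInterval(probe, cum, rightmost.closed = FALSE)
  off <- edit$pos - cum[j]
  if (tx$strand == "+") {
    gstart <- segs$start[j] + off
    list(gstart = gstart, ref = edit$ref, alt = edit$alt)
  } else {
    gend <- segs$end[j] - off
    list(gstart = gend - len_ref, ref = revcomp_allow_empty(edit$ref),
         alt = revcomp_allow_empty(edit$alt))
  }
}

revcomp_allow_empty <- function(x) if (nzchar(x)) revcomp(x) else x

# Shift a boundary coordinate through a set of applied edits (ascending by
# gstart). Positions inside a deleted interval clamp to its start.
map_boundary <- function(x, edits) {
  shift <- 0L
  for (e in edits) {
    len_ref <- nchar(e$ref); len_alt <- nchar(e$alt)
    if (x <= e$gstart) break
    if (x >= e$gstart + len_ref) {
      shift <- shift + len_alt - len_ref
    } else {
      return(e$gstart + shift)
    }
  }
  x + shift
}

#' Build the subject genome from a planted-effect plan
#'
#' Applies one planted edit per gene to the reference sequence, shifts the
#' annotation coordinates accordingly (the lifted subject annotation), and
#' emits the matching variant records against the reference coordinates with
#' the planted zygosity. Heterozygous genes drawn into the intact-haplotype
#' fraction keep the reference sequence (the variant is still reported het in
#' the VCF) and therefore classify as identical.
#'
#' @param reference The list from [generate_reference()].
#' @param plan A tibble `gene_id`, `category`, `zygosity`
#'   (`"het"`/`"hom"`/`"none"`), `keep_intact` (logical).
#' @param config A [sim_config()].
#' @return A list: `genome` (subject), `transcripts` (lifted), `variants`,
#'   `truth`.
#' @export
build_subject <- function(reference, plan, config) {
  ref_genome <- reference$genome
  ref_tx <- reference$transcripts
  stopifnot(!anyDuplicated(plan$gene_id))
  edits_applied <- list()
  variants <- list()
  truth <- list()
  res <- genome_seq(ref_genome, "sim1")
  for (i in seq_len(nrow(plan))) {
    gid <- plan$gene_id[i]
    tx <- ref_tx[ref_tx$gene_id == gid, , drop = FALSE]
    stopifnot(nrow(tx) == 1)
    cds <- extract_cds(ref_genome, tx)
    cc <- tx$cds[[1]]
    seg_lens <- if (tx$strand == "-") rev(cc$end - cc$start) else cc$end - cc$start
    planted <- plant_effect(cds, plan$category[i], seg_lens)
    truth[[i]] <- tibble(
      gene_id = gid, planted_category = plan$category[i],
      planted_zygosity = plan$zygosity[i],
      applied = !isTRUE(plan$keep_intact[i]) && !is.null(planted$edit),
      detail = planted$detail,
      planted_cds = planted$cds
    )
    if (is.null(planted$edit)) next
    ge <- cds_edit_to_genomic(planted$edit, tx)
    stopifnot(substr(res, ge$gstart + 1L, ge$gstart + nchar(ge$ref)) == ge$ref ||
              nchar(ge$ref) == 0)
    variants[[length(variants) + 1]] <- anchored_variant(res, ge, plan$zygosity[i])
    if (!isTRUE(plan$keep_intact[i])) {
      edits_applied[[length(edits_applied) + 1]] <- ge
    }
  }
  # apply edits right to left
  subj_res <- res
  if (length(edits_applied) > 0) {
    ord <- order(vapply(edits_applied, `[[`, 0L, "gstart"), decreasing = TRUE)
    for (e in edits_applied[ord]) {
      subj_res <- paste0(
        substr(subj_res, 1, e$gstart), e$alt,
        substr(subj_res, e$gstart + nchar(e$ref) + 1L, nchar(subj_res))
      )
    }
    edits_applied <- edits_applied[rev(ord)]  # ascending for boundary mapping
  }
  subj_tx <- ref_tx
  for (i in seq_len(nrow(subj_tx))) {
    subj_tx$exons[[i]] <- remap_segments(subj_tx$exons[[i]], edits_applied)
    cds_new <- remap_segments(subj_tx$cds[[i]], edits_applied)
    subj_tx$cds[[i]] <- recompute_phase(cds_new, subj_tx$strand[i])
  }
  genome <- tibble(seq_name = "sim1", residues = subj_res, length = nchar(subj_res))
  list(
    genome = genome, transcripts = subj_tx,
    variants = if (length(variants) > 0) bind_rows(variants) else empty_variants(),
    truth = bind_rows(truth)
  )
}

remap_segments <- function(segs, edits) {
  if (length(edits) == 0 || nrow(segs) == 0) return(segs)
  segs$start <- vapply(segs$start, map_boundary, 0L, edits = edits)
  segs$end <- vapply(segs$end, map_boundary, 0L, edits = edits)
  segs[segs$end > segs$start, , drop = FALSE]
}

recompute_phase <- function(cds_segs, strand) {
  if (nrow(cds_segs) == 0 || !"phase" %in% names(cds_segs)) return(cds_segs)
  ord <- if (strand == "-") rev(seq_len(nrow(cds_segs))) else seq_len(nrow(cds_segs))
  cum <- 0L
  for (j in ord) {
    cds_segs$phase[j] <- (3L - cum %% 3L) %% 3L
    cum <- cum + cds_segs$end[j] - cds_segs$start[j]
  }
  cds_segs
}

# VCF-style left-anchored variant for a genomic edit.
anchored_variant <- function(res, ge, zygosity) {
  len_ref <- nchar(ge$ref); len_alt <- nchar(ge$alt)
  if (len_ref > 0 && len_alt > 0) {
    pos <- ge$gstart; ref <- ge$ref; alt <- ge$alt
  } else {
    stopifnot(ge$gstart >= 1)
    anchor <- substr(res, ge$gstart, ge$gstart)
    pos <- ge$gstart - 1L
    ref <- paste0(anchor, ge$ref)
    alt <- paste0(anchor, ge$alt)
  }
  tibble(
    seq_name = "sim1", pos = as.integer(pos), ref_allele = ref, alt_allele = alt,
    zygosity = zygosity, is_snp = nchar(ref) == 1L & nchar(alt) == 1L
  )
}

#' Simulate rDNA arrays and a NUMT with alignment evidence
#'
#' Lays out `rdna_units` tandem rDNA units (scaled 18S/5.8S/28S subunits with
#' spacers) on a dedicated sequence and emits (a) labeled subunit placements
#' in PAF for the valid-unit grouping, with wrong-order and incomplete decoys
#' when `rdna_decoys`, and (b) array-level candidate alignments for the
#' filter/mask pass, with short and low-identity decoys. Also plants one NUMT
#' interval on a second sequence with `numt_spanning` primary reads spanning
#' it by at least `numt_flank` on both sides, plus non-spanning, short-flank
#' and secondary decoy reads.
#'
#' @param config A [sim_config()].
#' @return A list: `genome` (sequences `simR`, `simN`), `rdna_subunits`,
#'   `rdna_candidates`, `reads` (PAF tibbles), `numt`
#'   (`seq_name`, `start`, `end`), `truth` (unit count, spanning count).
#' @export
simulate_rdna_and_numt <- function(config) {
  id_pct <- 100 - config$rdna_divergence
  lens <- config$rdna_lens
  sp <- config$rdna_spacers
  paf_row <- function(qname, qlen, tname, tlen, tstart, tend, strand = "+",
                      identity = id_pct, primary = TRUE) {
    alen <- tend - tstart
    tibble(
      query_name = qname, query_len = as.integer(qlen),
      query_start = 0L, query_end = as.integer(qlen), strand = strand,
      target_name = tname, target_len = as.integer(tlen),
      target_start = as.integer(tstart), target_end = as.integer(tend),
      n_matches = as.integer(round(alen * identity / 100)),
      aln_len = as.integer(alen), mapq = 60L,
      is_primary = primary,
      identity = 100 * round(alen * identity / 100) / alen
    )
  }
  # --- rDNA layout on simR
  sub_rows <- list(); cand_rows <- list()
  cursor <- 1000L
  unit_strands <- rep(c("+", "-"), length.out = config$rdna_units)
  for (u in seq_len(config$rdna_units)) {
    strand <- unit_strands[u]
    unit_start <- cursor
    labels_genomic <- if (strand == "-") c("28S", "5.8S", "18S") else c("18S", "5.8S", "28S")
    lens_genomic <- lens[labels_genomic]
    starts_genomic <- unit_start + sp["ets5"] +
      c(0L, cumsum(lens_genomic[-3] + c(sp["its1"], sp["its2"])))
    for (s in 1:3) {
      lab <- labels_genomic[s]
      sub_rows[[length(sub_rows) + 1]] <- paf_row(
        lab, lens[lab], "simR", 0L,
        starts_genomic[s], starts_genomic[s] + lens[lab], strand
      )
    }
    unit_end <- unit_start + sp["ets5"] + sum(lens) + sp["its1"] + sp["its2"] + sp["ets3"]
    cand_rows[[length(cand_rows) + 1]] <- paf_row(
      "rDNA_ref_unit", unit_end - unit_start, "simR", 0L, unit_start, unit_end, strand
    )
    cursor <- unit_end + config$rdna_gap
  }
  if (config$rdna_decoys) {
    # wrong-order triple: 18S, 28S, 5.8S in genomic order on +
    d0 <- cursor + 5000L
    p <- d0
    for (lab in c("18S", "28S", "5.8S")) {
      sub_rows[[length(sub_rows) + 1]] <- paf_row(lab, lens[lab], "simR", 0L,
                                                  p, p + lens[lab], "+")
      p <- p + lens[lab] + 300L
    }
    # incomplete pair far away
    q <- p + 20000L
    for (lab in c("18S", "5.8S")) {
      sub_rows[[length(sub_rows) + 1]] <- paf_row(lab, lens[lab], "simR", 0L,
                                                  q, q + lens[lab], "+")
      q <- q + lens[lab] + 300L
    }
    cursor <- q + 1000L
    # candidate decoys: too short, too divergent
    cand_rows[[length(cand_rows) + 1]] <- paf_row("rDNA_ref_unit", 800L, "simR", 0L,
                                                  cursor, cursor + 800L, "+")
    cand_rows[[length(cand_rows) + 1]] <- paf_row("rDNA_ref_unit", 5000L, "simR", 0L,
                                                  cursor + 2000L, cursor + 7000L, "+",
                                                  identity = 95)
    cursor <- cursor + 8000L
  }
  simR_len <- cursor + 1000L
  # --- NUMT on simN
  flank_region <- 5000L
  numt_start <- flank_region
  numt_end <- numt_start + config$numt_len
  simN_len <- numt_end + flank_region
  reads <- list()
  for (r in seq_len(config$numt_spanning)) {
    js <- sample(0:1000, 1); je <- sample(0:1000, 1)
    ts <- max(0L, numt_start - config$numt_flank - js)
    te <- min(simN_len, numt_end + config$numt_flank + je)
    reads[[length(reads) + 1]] <- paf_row(
      sprintf("read_span_%03d", r), te - ts, "simN", simN_len, ts, te,
      sample(c("+", "-"), 1), identity = 94
    )
  }
  n_dec <- config$numt_nonspanning
  if (n_dec > 0) {
    kinds <- rep(c("short_flank", "partial", "secondary"), length.out = n_dec)
    for (r in seq_len(n_dec)) {
      nm <- sprintf("read_decoy_%03d", r)
      reads[[length(reads) + 1]] <- switch(kinds[r],
        short_flank = paf_row(nm, config$numt_len + 999L, "simN", simN_len,
                              numt_start - (config$numt_flank - 1L),
                              numt_end + config$numt_flank, "+", identity = 94),
        partial = paf_row(nm, 4000L, "simN", simN_len,
                          numt_start + 100L, numt_start + 4100L, "+", identity = 94),
        secondary = paf_row(nm, config$numt_len + 2400L, "simN", simN_len,
                            numt_start - 1200L, numt_end + 1200L, "+",
                            identity = 94, primary = FALSE)
      )
    }
  }
  genome <- tibble(
    seq_name = c("simR", "simN"),
    residues = c(random_dna(simR_len), random_dna(simN_len))
  )
  genome$length <- nchar(genome$residues)
  rdna_subunits <- mutate(bind_rows(sub_rows), target_len = as.integer(simR_len))
  rdna_candidates <- mutate(bind_rows(cand_rows), target_len = as.integer(simR_len))
  list(
    genome = genome,
    rdna_subunits = rdna_subunits,
    rdna_candidates = rdna_candidates,
    reads = bind_rows(reads),
    numt = list(seq_name = "simN", start = numt_start, end = numt_end),
    truth = list(rdna_units = config$rdna_units,
                 numt_support = config$numt_spanning)
  )
}

#' Simulate a full annotated genome pair with ground truth
#'
#' The top-level generator: seeds the RNG from the config, builds the
#' reference genome and annotation, draws the planted-effect plan (category
#' per gene, zygosity per edit), builds the subject genome, lifted
#' annotation and variants, simulates the rDNA and NUMT evidence, and
#' lowercases the donor patches on the subject. Identical seeds give byte
#' identical results.
#'
#' @param config A [sim_config()].
#' @return A list with `config`, `ref_genome`, `subj_genome`,
#'   `ref_transcripts`, `subj_transcripts`, `variants`, `truth`,
#'   `rdna_subunits`, `rdna_candidates`, `reads`, `numt`, `rdna_truth`.
#' @export
simulate_genome_pair <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  reference <- generate_reference(config)
  # planted-effect plan
  cats <- rep(names(config$category_counts), config$category_counts)
  plan <- tibble(
    gene_id = sort(unique(reference$transcripts$gene_id)),
    category = sample(cats)
  )
  is_del <- plan$category %in% DELETERIOUS_CATEGORIES
  has_edit <- plan$category != "identical"
  p_het <- ifelse(is_del, config$het_fraction_deleterious, config$het_fraction_benign)
  draw <- stats::runif(nrow(plan))
  plan$zygosity <- ifelse(!has_edit, "none", ifelse(draw < p_het, "het", "hom"))
  plan$keep_intact <- plan$zygosity == "het" &
    stats::runif(nrow(plan)) < config$het_intact_fraction
  subject <- build_subject(reference, plan, config)
  extra <- simulate_rdna_and_numt(config)
  # donor patches: lowercase the first donor_patch_len bases of each subject seq
  subj_genome <- bind_rows(subject$genome, extra$genome)
  if (config$donor_patch_len > 0) {
    subj_genome$residues <- vapply(subj_genome$residues, function(r) {
      k <- min(config$donor_patch_len, nchar(r))
      paste0(tolower(substr(r, 1, k)), substr(r, k + 1L, nchar(r)))
    }, "", USE.NAMES = FALSE)
  }
  truth <- subject$truth
  truth$effective_category <- ifelse(
    truth$applied | truth$planted_category == "identical",
    truth$planted_category, "identical"
  )
  list(
    config = config,
    ref_genome = reference$genome,
    subj_genome = subj_genome,
    ref_transcripts = reference$transcripts,
    subj_transcripts = subject$transcripts,
    variants = subject$variants,
    truth = truth,
    rdna_subunits = extra$rdna_subunits,
    rdna_candidates = extra$rdna_candidates,
    reads = extra$reads,
    numt = extra$numt,
    rdna_truth = extra$truth
  )
}

#' Write a simulation to disk
#'
#' Emits the fixture files every pipeline stage reads: `ref.fa`, `subj.fa`,
#' `ref.gff3`, `subj.gff3`, `subj.vcf`, `reads.paf`, `rdna_subunits.paf`,
#' `rdna_candidates.paf`, `truth.tsv` and `config.tsv` (flat key-value).
#'
#' @param sim A list from [simulate_genome_pair()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(x) file.path(dir, x)
  write_fasta(sim$ref_genome, fp("ref.fa"))
  write_fasta(sim$subj_genome, fp("subj.fa"))
  write_gff3(sim$ref_transcripts, fp("ref.gff3"))
  write_gff3(sim$subj_transcripts, fp("subj.gff3"))
  write_vcf(sim$variants, fp("subj.vcf"), sample = "subject")
  write_paf(sim$reads, fp("reads.paf"))
  write_paf(sim$rdna_subunits, fp("rdna_subunits.paf"))
  write_paf(sim$rdna_candidates, fp("rdna_candidates.paf"))
  readr::write_tsv(sim$truth, fp("truth.tsv"), progress = FALSE)
  cfg <- sim$config
  flat <- unlist(cfg[!names(cfg) %in% c("rdna_lens", "rdna_spacers", "category_counts")])
  keyvals <- c(
    paste0(names(flat), "\t", flat),
    paste0("category_counts.", names(cfg$category_counts), "\t", cfg$category_counts),
    paste0("rdna_lens.", names(cfg$rdna_lens), "\t", cfg$rdna_lens),
    paste0("rdna_spacers.", names(cfg$rdna_spacers), "\t", cfg$rdna_spacers)
  )
  writeLines(keyvals, fp("config.tsv"))
  numt_bed <- tibble(seq_name = sim$numt$seq_name, start = sim$numt$start,
                     end = sim$numt$end, name = "numt")
  write_bed(numt_bed, fp("numt.bed"))
  invisible(dir)
}
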