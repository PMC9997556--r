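#' Pipeline run configuration
#'
#' Collects the input paths, stage toggles and thresholds for
#' [run_pipeline()]. Stage dependencies: `triage` needs `classify`;
#' `rescue` and `proteins` need `triage`; `clusters` and `classify` need the
#' genomes and annotations.
#'
#' @param ref_fasta,subj_fasta,ref_gff3,subj_gff3 Paths to the paired genomes
#'   and annotations (shared gene/transcript ids).
#' @param vcf Subject-vs-reference variant calls (for `rescue`).
#' @param reads_paf Long-read alignments to the subject (for `numt`).
#' @param numt_bed BED of candidate insertion intervals (for `numt`).
#' @param rdna_subunits_paf Labeled 18S/5.8S/28S placements (for `rdna`).
#' @param rdna_candidates_paf Array-level rDNA candidate alignments (for
#'   `rdna`).
#' @param refseq_proteins External reference protein FASTA keyed by gene id
#'   (for `proteins`).
#' @param out_dir Output directory for the report bundle.
#' @param stages Character vector of stages to run, a subset of
#'   `c("classify", "triage", "rescue", "proteins", "provenance", "numt",
#'   "rdna", "clusters")`.
#' @param flank_bp NUMT flank requirement.
#' @param rdna_min_len,rdna_min_identity,rdna_max_unit_span rDNA thresholds.
#' @param cluster_identity,cluster_coverage Paralog-cluster thresholds.
#' @param severity Effect severity precedence (see [classify_cds()]).
#' @return A list of class `run_config`.
#' @export
run_config <- function(ref_fasta, subj_fasta, ref_gff3, subj_gff3,
                       vcf = NULL, reads_paf = NULL, numt_bed = NULL,
                       rdna_subunits_paf = NULL, rdna_candidates_paf = NULL,
                       refseq_proteins = NULL,
                       out_dir = tempfile("genomepair_run_"),
                       stages = c("classify", "triage", "rescue",
                                  "provenance", "numt", "rdna", "clusters"),
                       flank_bp = 500L,
                       rdna_min_len = 1000, rdna_min_identity = 98.5,
                       rdna_max_unit_span = 45000L,
                       cluster_identity = 0.9, cluster_coverage = 0.9,
                       severity = DEFAULT_SEVERITY) {
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

ALL_STAGES <- c("classify", "triage", "rescue", "proteins", "provenance",
                "numt", "rdna", "clusters")

validate_run_config <- function(cfg) {
  problems <- character(0)
  need <- function(path, label, stage) {
    if (is.null(path)) {
      problems <<- c(problems, paste0("stage '", stage, "' needs ", label))
    } else if (!file.exists(path)) {
      problems <<- c(problems, paste0(label, " not found: ", path))
    }
  }
  bad <- setdiff(cfg$stages, ALL_STAGES)
  if (length(bad) > 0) problems <- c(problems, paste0("unknown stage(s): ", paste(bad, collapse = ", ")))
  core <- c("classify", "triage", "rescue", "proteins", "clusters")
  if (any(core %in% cfg$stages)) {
    need(cfg$ref_fasta, "ref_fasta", "classify")
    need(cfg$subj_fasta, "subj_fasta", "classify")
    need(cfg$ref_gff3, "ref_gff3", "classify")
    need(cfg$subj_gff3, "subj_gff3", "classify")
  }
  if ("provenance" %in% cfg$stages) need(cfg$subj_fasta, "subj_fasta", "provenance")
  if ("triage" %in% cfg$stages && !"classify" %in% cfg$stages) {
    problems <- c(problems, "stage 'triage' needs stage 'classify'")
  }
  if ("rescue" %in% cfg$stages) {
    need(cfg$vcf, "vcf", "rescue")
    if (!"triage" %in% cfg$stages) problems <- c(problems, "stage 'rescue' needs stage 'triage'")
  }
  if ("proteins" %in% cfg$stages) {
    need(cfg$refseq_proteins, "refseq_proteins", "proteins")
    if (!"triage" %in% cfg$stages) problems <- c(problems, "stage 'proteins' needs stage 'triage'")
  }
  if ("numt" %in% cfg$stages) {
    need(cfg$reads_paf, "reads_paf", "numt")
    need(cfg$numt_bed, "numt_bed", "numt")
  }
  if ("rdna" %in% cfg$stages) need(cfg$rdna_subunits_paf, "rdna_subunits_paf", "rdna")
  if (length(problems) > 0) {
    abort(paste0("invalid run configuration:\n  ",
                 paste(problems, collapse = "\n  ")))
  }
  invisible(cfg)
}

stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

#' Run the annotated-genome-pair comparison pipeline
#'
#' Orchestrates the stages in analysis order — classify, gene rollup and
#' summary, zygosity rescue, protein report, donor provenance, NUMT
#' validation, rDNA unit validation, paralog copy-number comparison — as
#' toggled in the config. Each stage writes one TSV to the output directory,
#' plus a machine-readable `summary.json`; progress goes to the message
#' stream, results only to disk and the returned object. The pipeline is
#' deterministic: same inputs and config give byte-identical outputs.
#'
#' @param cfg A [run_config()].
#' @return An object of class `genomepair_report`: the per-stage result
#'   tibbles, the summary list, and `out_dir`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  validate_run_config(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list(out_dir = cfg$out_dir)
  summary <- list(stages = cfg$stages)
  fp <- function(x) file.path(cfg$out_dir, x)
  t0 <- Sys.time()

  genomes_needed <- any(c("classify", "provenance", "clusters") %in% cfg$stages)
  if (genomes_needed) {
    ref_genome <- read_fasta(cfg$ref_fasta)
    subj_genome <- read_fasta(cfg$subj_fasta)
  }
  if (any(c("classify", "clusters") %in% cfg$stages)) {
    ref_tx <- read_gff3(cfg$ref_gff3)
    subj_tx <- read_gff3(cfg$subj_gff3)
  }

  if ("classify" %in% cfg$stages) {
    verdicts <- classify_transcripts(ref_tx, subj_tx, ref_genome, subj_genome,
                                     severity = cfg$severity)
    res$verdicts <- verdicts
    out <- mutate(verdicts,
                  dna_identity = sprintf("%.4f", .data$dna_identity),
                  aa_identity = ifelse(is.na(.data$aa_identity), "NA",
                                       sprintf("%.4f", .data$aa_identity)))
    readr::write_tsv(out, fp("verdicts.tsv"), progress = FALSE)
    summary$n_transcripts <- nrow(verdicts)
    summary$n_unmapped <- attr(verdicts, "n_unmapped")
    stage_log("classify", nrow(verdicts), " transcript pairs classified")
  }

  if ("triage" %in% cfg$stages) {
    genes <- rollup_genes(res$verdicts)
    res$gene_verdicts <- genes
    cs <- summarize_genes(genes)
    res$category_summary <- cs
    readr::write_tsv(genes[setdiff(names(genes), "sites")], fp("gene_verdicts.tsv"),
                     progress = FALSE)
    readr::write_tsv(tidy(cs), fp("category_summary.tsv"), progress = FALSE)
    summary$n_genes <- cs$total
    summary$conserved_pct <- cs$conserved_pct
    summary$deleterious_total <- cs$deleterious_total
    summary$category_counts <- stats::setNames(as.list(cs$counts$n), cs$counts$category)
    stage_log("triage", cs$total, " genes; ", cs$deleterious_total, " deleterious")
  }

  if ("rescue" %in% cfg$stages) {
    variants <- read_vcf(cfg$vcf)
    ref_annot <- read_gff3(cfg$ref_gff3)
    dels <- filter(res$gene_verdicts, .data$deleterious)
    rescued <- zygosity_rescue(dels, variants, ref_annot)
    res$rescued <- rescued
    out <- select(rescued, -"sites")
    readr::write_tsv(out, fp("rescue.tsv"), progress = FALSE)
    summary$n_deleterious_candidates <- nrow(dels)
    summary$n_hom_deleterious <- nrow(rescued)
    summary$n_distinct_sites <- attr(rescued, "n_distinct_sites")
    summary$hom_deleterious_genes <- rescued$gene_id
    stage_log("rescue", nrow(rescued), " of ", nrow(dels),
              " candidate genes kept after zygosity rescue")
  }

  if ("proteins" %in% cfg$stages) {
    refseq <- read_fasta(cfg$refseq_proteins)
    target <- if (!is.null(res$rescued)) res$rescued else
      filter(res$gene_verdicts, .data$deleterious)
    prot <- function(genome, tx_tbl, gid) {
      tx <- tx_tbl[tx_tbl$gene_id == gid, ][1, ]
      translate_cds(extract_cds(genome, tx))$protein
    }
    ref_prot <- tibble(seq_name = target$gene_id,
                       residues = map_chr(target$gene_id, ~ prot(ref_genome, ref_tx, .x)))
    subj_prot <- tibble(seq_name = target$gene_id,
                        residues = map_chr(target$gene_id, ~ prot(subj_genome, subj_tx, .x)))
    report <- protein_report(target$gene_id, ref_prot, subj_prot, refseq)
    res$protein_report <- report
    readr::write_tsv(report, fp("protein_report.tsv"), progress = FALSE)
    stage_log("proteins", nrow(report), " genes in protein report")
  }

  if ("provenance" %in% cfg$stages) {
    if (!genomes_needed) subj_genome <- read_fasta(cfg$subj_fasta)
    prov <- provenance_report(read_fasta(cfg$subj_fasta))
    res$provenance <- prov
    out <- mutate(prov, ratio = sprintf("%.4f", .data$ratio))
    readr::write_tsv(out, fp("provenance.tsv"), progress = FALSE)
    summary$donor_bp <- prov$donor_bp[prov$seq_name == "total"]
    summary$genome_ratio <- prov$ratio[prov$seq_name == "total"]
    stage_log("provenance", nrow(prov) - 1, " sequences")
  }

  if ("numt" %in% cfg$stages) {
    reads <- read_paf(cfg$reads_paf)
    calls <- read_bed(cfg$numt_bed)
    calls$length <- interval_length(calls$start, calls$end)
    calls$support_count <- map_int(seq_len(nrow(calls)), function(i) {
      as.integer(validate_numt(calls$seq_name[i], calls$start[i], calls$end[i],
                               reads, flank_bp = cfg$flank_bp))
    })
    res$numt <- calls
    readr::write_tsv(calls, fp("numt_report.tsv"), progress = FALSE)
    summary$numt_support <- stats::setNames(as.list(calls$support_count),
                                            paste0(calls$seq_name, ":", calls$start, "-", calls$end))
    stage_log("numt", nrow(calls), " candidate insertion(s) checked")
  }

  if ("rdna" %in% cfg$stages) {
    if (!is.null(cfg$rdna_candidates_paf)) {
      cand <- read_paf(cfg$rdna_candidates_paf)
      kept <- filter_rdna_candidates(cand, cfg$rdna_min_len, cfg$rdna_min_identity)
      loci <- merge_candidate_loci(kept)
      res$rdna_loci <- loci
      write_bed(loci, fp("rdna_loci.bed"))
      summary$n_rdna_loci <- nrow(loci)
    }
    subs <- read_paf(cfg$rdna_subunits_paf)
    grouped <- group_valid_units(subs, max_unit_span = cfg$rdna_max_unit_span)
    res$rdna_units <- grouped$units
    res$rdna_rejected <- grouped$rejected
    readr::write_tsv(select(grouped$units, -"subunits"), fp("rdna_units.tsv"),
                     progress = FALSE)
    readr::write_tsv(grouped$rejected, fp("rdna_rejected.tsv"), progress = FALSE)
    if (!is.null(res$verdicts)) {
      overlaps <- audit_overlaps(grouped$units,
                                 read_gff3(cfg$subj_gff3))
      res$rdna_overlaps <- overlaps
      readr::write_tsv(overlaps, fp("rdna_overlaps.tsv"), progress = FALSE)
      summary$n_rdna_gene_overlaps <- nrow(overlaps)
    }
    summary$n_rdna_units <- nrow(grouped$units)
    summary$n_rdna_subunits <- 3L * nrow(grouped$units)
    stage_log("rdna", nrow(grouped$units), " valid units (",
              3L * nrow(grouped$units), " subunits)")
  }

  if ("clusters" %in% cfg$stages) {
    seqs <- bind_rows(
      cluster_input(ref_genome, ref_tx, "ref"),
      cluster_input(subj_genome, subj_tx, "subj")
    )
    clusters <- cluster_sequences(seqs, cfg$cluster_identity, cfg$cluster_coverage,
                                  alphabet = "protein")
    cns <- compare_copy_numbers(clusters)
    res$clusters <- clusters
    res$copy_numbers <- cns
    flat <- mutate(clusters,
                   members_ref = map_chr(.data$members_ref, paste, collapse = ","),
                   members_subj = map_chr(.data$members_subj, paste, collapse = ","))
    readr::write_tsv(flat, fp("clusters.tsv"), progress = FALSE)
    readr::write_tsv(tidy(cns), fp("copy_numbers.tsv"), progress = FALSE)
    summary$n_clusters <- cns$n_clusters
    summary$n_clusters_changed <- cns$n_changed
    stage_log("clusters", cns$n_clusters, " clusters, ", cns$n_changed, " changed")
  }

  summary$elapsed_sec <- round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 2)
  res$summary <- summary
  json <- summary
  json$elapsed_sec <- NULL  # keep the bundle byte-deterministic
  jsonlite::write_json(json, fp("summary.json"), auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  class(res) <- "genomepair_report"
  res
}

# Per-gene representative protein sequences for clustering.
cluster_input <- function(genome, transcripts, label) {
  coding <- transcripts[map_int(transcripts$cds, nrow) > 0, , drop = FALSE]
  first_tx <- coding[!duplicated(coding$gene_id), , drop = FALSE]
  prot <- map_chr(seq_len(nrow(first_tx)), function(i) {
    translate_cds(extract_cds(genome, first_tx[i, ]))$protein
  })
  keep <- nzchar(prot)
  tibble(id = paste0(label, ":", first_tx$gene_id[keep]),
         genome = label, residues = prot[keep])
}

#' @export
print.genomepair_report <- function(x, ...) {
  cat("genomepair report bundle:", x$out_dir, "\n")
  for (nm in setdiff(names(x$summary), "stages")) {
    val <- x$summary[[nm]]
    if (length(val) == 1 && !is.list(val)) cat("  ", nm, ": ", val, "\n", sep = "")
  }
  invisible(x)
}

#' @export
tidy.genomepair_report <- function(x, ...) {
  if (is.null(x$category_summary)) abort("report has no triage stage")
  tidy(x$category_summary)
}

#' @export
glance.genomepair_report <- function(x, ...) {
  s <- x$summary
  as_tibble(s[vapply(s, function(v) length(v) == 1 && !is.list(v), NA)])
}
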