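mk_verdicts <- function(...) {
  rows <- list(...)
  tibble::tibble(
    transcript_id = purrr::map_chr(rows, 1),
    gene_id = purrr::map_chr(rows, 2),
    gene_name = toupper(purrr::map_chr(rows, 2)),
    biotype = "protein_coding",
    category = purrr::map_chr(rows, 3),
    dna_identity = 0.99,
    aa_identity = purrr::map_dbl(rows, 4),
    ref_protein_len = 100L, subj_protein_len = 100L
  )
}

test_that("the representative transcript carries the gene category", {
  v <- mk_verdicts(
    list("t1", "gA", "frameshift", 0.95),
    list("t2", "gA", "identical", 1.0),
    list("t3", "gB", "stop_gained", 0.7)
  )
  g <- rollup_genes(v)
  # intact isoform rescues the gene at the isoform level
  expect_equal(g$category[g$gene_id == "gA"], "identical")
  expect_equal(g$representative_tx[g$gene_id == "gA"], "t2")
  expect_false(g$deleterious[g$gene_id == "gA"])
  # single-transcript gene keeps its transcript's category
  expect_equal(g$category[g$gene_id == "gB"], "stop_gained")
  expect_true(g$deleterious[g$gene_id == "gB"])
})

test_that("aa-identity ties break to the smallest transcript id", {
  v <- mk_verdicts(
    list("t9", "g", "synonymous", 1.0),
    list("t2", "g", "identical", 1.0)
  )
  expect_equal(rollup_genes(v)$representative_tx, "t2")
  expect_equal(rollup_genes(v)$category, "identical")
})

test_that("rollup is idempotent and order-independent", {
  set.seed(31)
  v <- mk_verdicts(
    list("t1", "gA", "frameshift", 0.95), list("t2", "gA", "identical", 1.0),
    list("t3", "gB", "stop_gained", 0.7), list("t4", "gB", "nonsynonymous", 0.99),
    list("t5", "gC", "synonymous", 1.0)
  )
  base <- rollup_genes(v)
  for (rep in 1:5) {
    shuf <- v[sample(nrow(v)), ]
    expect_equal(rollup_genes(shuf), base)
  }
})

test_that("transcripts without a gene are an error listing the ids", {
  v <- mk_verdicts(list("t1", "gA", "identical", 1.0))
  v$gene_id <- NA_character_
  expect_error(rollup_genes(v), "t1")
})

test_that("category summary computes the conserved/deleterious accounting", {
  s <- category_summary(c(identical = 8, synonymous = 1, nonsynonymous = 0,
                          frameshift = 1))
  expect_equal(s$total, 10)
  expect_equal(s$conserved_count, 9)
  expect_equal(s$conserved_pct, 90)
  expect_equal(s$deleterious_total, 1)
  # all-identical set
  s2 <- category_summary(c(identical = 5))
  expect_equal(s2$conserved_pct, 100)
  expect_equal(s2$deleterious_total, 0)
  # glance/tidy expose the same numbers
  expect_equal(glance(s)$deleterious_total, 1)
  expect_equal(sum(tidy(s)$n), 10)
  expect_equal(sum(tidy(s)$fraction), 1)
  expect_error(category_summary(c(bogus = 3)), "unknown category")
})

test_that("conserved percent rounds half-up", {
  # 165/200 = 82.5% -> 83 under half-up
  s <- category_summary(c(identical = 165, frameshift = 35))
  expect_equal(s$conserved_pct, 83)
})

test_that("zygosity rescue keeps only genes with a hom non-SNP coding variant", {
  sim <- simulate_genome_pair(sim_config(seed = 23, n_genes = 20))
  annot <- sim$ref_transcripts
  genes <- tibble::tibble(
    gene_id = c("g001", "g002"), gene_name = c("G001", "G002"),
    representative_tx = c("g001.t1", "g002.t1"),
    category = "frameshift", aa_identity = 0.5, deleterious = TRUE
  )
  cds1 <- annot$cds[[1]]
  pos_in_cds <- cds1$start[1] + 2L
  mkvar <- function(pos, zyg, ref, alt) tibble::tibble(
    seq_name = "sim1", pos = as.integer(pos), ref_allele = ref, alt_allele = alt,
    zygosity = zyg, is_snp = nchar(ref) == 1 & nchar(alt) == 1
  )
  # empty VCF: nothing survives
  out <- zygosity_rescue(genes, mkvar(integer(0), character(0), character(0), character(0)),
                         annot)
  expect_equal(nrow(out), 0)
  expect_equal(attr(out, "n_distinct_sites"), 0)
  # het-only 2-bp deletion: dropped
  out <- zygosity_rescue(genes, mkvar(pos_in_cds, "het", "ATT", "A"), annot)
  expect_equal(nrow(out), 0)
  # hom SNP: dropped (SNPs cannot frameshift)
  out <- zygosity_rescue(genes, mkvar(pos_in_cds, "hom", "A", "T"), annot)
  expect_equal(nrow(out), 0)
  # hom non-SNP inside CDS: kept, with the site reported once
  out <- zygosity_rescue(genes, mkvar(pos_in_cds, "hom", "ATT", "A"), annot)
  expect_equal(out$gene_id, "g001")
  expect_equal(out$n_sites, 1)
  expect_equal(attr(out, "n_distinct_sites"), 1)
})

test_that("exon sharing between isoforms does not inflate site counts", {
  # two isoforms of one gene sharing a coding exon
  annot <- tibble::tibble(
    gene_id = "g", gene_name = "G",
    transcript_id = c("g.t1", "g.t2"), biotype = "protein_coding",
    seq_name = "s", strand = "+",
    exons = list(tibble::tibble(start = 10L, end = 40L),
                 tibble::tibble(start = 10L, end = 55L)),
    cds = list(tibble::tibble(start = 10L, end = 40L, phase = 0L),
               tibble::tibble(start = 10L, end = 55L, phase = 0L))
  )
  genes <- tibble::tibble(gene_id = "g", gene_name = "G",
                          representative_tx = "g.t1", category = "frameshift",
                          aa_identity = 0.5, deleterious = TRUE)
  v <- tibble::tibble(seq_name = "s", pos = 20L, ref_allele = "GTT",
                      alt_allele = "G", zygosity = "hom", is_snp = FALSE)
  out <- zygosity_rescue(genes, v, annot)
  expect_equal(out$n_sites, 1)
  expect_equal(attr(out, "n_distinct_sites"), 1)
})

test_that("removing variants never adds rescued genes (monotonicity)", {
  sim <- simulate_genome_pair(sim_config(seed = 37))
  verd <- classify_transcripts(sim$ref_transcripts, sim$subj_transcripts,
                               sim$ref_genome, sim$subj_genome)
  dels <- dplyr::filter(rollup_genes(verd), deleterious)
  full <- zygosity_rescue(dels, sim$variants, sim$ref_transcripts)
  set.seed(1)
  for (rep in 1:3) {
    sub <- sim$variants[sample(nrow(sim$variants), nrow(sim$variants) %/% 2), ]
    part <- zygosity_rescue(dels, sub, sim$ref_transcripts)
    expect_true(all(part$gene_id %in% full$gene_id))
  }
  # het-only variant set rescues nothing
  het_only <- dplyr::filter(sim$variants, zygosity == "het", is_snp == FALSE)
  het_out <- zygosity_rescue(dels, dplyr::mutate(het_only), sim$ref_transcripts)
  expect_equal(nrow(het_out), 0)
})

test_that("protein report flags missing reference entries and rounds to 3 decimals", {
  ref_p <- tibble::tibble(seq_name = c("gA", "gB"), residues = c("MKLV", "MAAA"))
  subj_p <- tibble::tibble(seq_name = c("gA", "gB"), residues = c("MKLV", "MA"))
  refseq <- tibble::tibble(seq_name = "gA", residues = "MKLV")
  rep <- protein_report(c("gA", "gB"), ref_p, subj_p, refseq)
  expect_equal(rep$ref_length_ratio[rep$gene_id == "gA"], 1.000)
  expect_equal(rep$ref_identity[rep$gene_id == "gA"], 1.000)
  expect_false(rep$missing_refseq[rep$gene_id == "gA"])
  expect_true(rep$missing_refseq[rep$gene_id == "gB"])
  expect_true(is.na(rep$subj_length_ratio[rep$gene_id == "gB"]))
  expect_equal(nrow(rep), 2)  # flagged, not dropped
})
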