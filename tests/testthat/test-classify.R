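one_tx <- function(seq_name, strand, cds, exons = cds, genome_res) {
  list(
    genome = tibble::tibble(seq_name = seq_name, residues = genome_res,
                            length = nchar(genome_res)),
    tx = tibble::tibble(
      gene_id = "g", gene_name = "G", transcript_id = "t",
      biotype = "protein_coding", seq_name = seq_name, strand = strand,
      exons = list(exons), cds = list(cds)
    )
  )
}

test_that("extract_cds splices, strand-orients and upper-cases", {
  cds <- tibble::tibble(start = 2L, end = 5L, phase = 0L)
  w <- one_tx("s", "+", cds, genome_res = "ttATGtt")
  expect_equal(extract_cds(w$genome, w$tx), "ATG")
  w <- one_tx("s", "-", cds, genome_res = "ttCATtt")
  expect_equal(extract_cds(w$genome, w$tx), "ATG")
})

test_that("multi-exon minus-strand extraction equals splice-then-revcomp", {
  set.seed(21)
  for (rep in 1:25) {
    res <- random_dna_str(120)
    s1 <- sample(0:20, 1); e1 <- s1 + sample(6:18, 1)
    s2 <- e1 + sample(5:20, 1); e2 <- s2 + sample(6:18, 1)
    cds <- tibble::tibble(start = c(s1, s2), end = c(e1, e2), phase = 0L)
    w <- one_tx("s", "-", cds, genome_res = res)
    manual <- revcomp(paste0(substr(res, s1 + 1, e1), substr(res, s2 + 1, e2)))
    expect_equal(extract_cds(w$genome, w$tx), manual)
  }
})

test_that("classification assigns each category from its defining feature", {
  ref <- "ATGGCTAAATTCCCAGGTTGGTACGAAGATTAA"  # MAKFPGWYED*
  # single 2-bp deletion: length not a multiple of 3 -> frameshift
  fs <- paste0(substr(ref, 1, 9), substr(ref, 12, nchar(ref)))
  expect_equal(classify_cds(ref, fs)$category, "frameshift")
  # GCT -> GCC (Ala -> Ala): synonymous, proteins identical
  syn <- sub("GCT", "GCC", ref)
  v <- classify_cds(ref, syn)
  expect_equal(v$category, "synonymous")
  expect_equal(v$aa_identity, 1)
  expect_lt(v$dna_identity, 1)
  # internal AAA -> TAA: premature stop, shorter protein
  sg <- sub("AAA", "TAA", ref)
  v <- classify_cds(ref, sg)
  expect_equal(v$category, "stop_gained")
  expect_lt(v$subj_protein_len, v$ref_protein_len)
  # start codon substituted away
  sl <- sub("^ATG", "CTT", ref)
  expect_equal(classify_cds(ref, sl)$category, "start_lost")
  # whole-codon deletion: in-frame deletion
  del <- paste0(substr(ref, 1, 12), substr(ref, 16, nchar(ref)))
  expect_equal(classify_cds(ref, del)$category, "inframe_deletion")
  # codon insertion
  ins <- paste0(substr(ref, 1, 12), "GAA", substr(ref, 13, nchar(ref)))
  expect_equal(classify_cds(ref, ins)$category, "inframe_insertion")
  # 5' terminus (incl. ATG) missing
  t5 <- substr(ref, 7, nchar(ref))
  expect_equal(classify_cds(ref, t5)$category, "truncation_5p")
  # 3' terminus (incl. stop) missing
  t3 <- substr(ref, 1, nchar(ref) - 6)
  expect_equal(classify_cds(ref, t3)$category, "truncation_3p")
  # substitution that changes the amino acid
  ns <- sub("TTC", "TTA", ref)  # F -> L
  expect_equal(classify_cds(ref, ns)$category, "nonsynonymous")
  # identical
  v <- classify_cds(ref, ref)
  expect_equal(v$category, "identical")
  expect_equal(v$dna_identity, 1)
  expect_equal(v$aa_identity, 1)
})

test_that("planted effects are recovered exactly by the classifier", {
  set.seed(7)
  for (category in effect_categories()) {
    for (rep in 1:20) {
      cds <- random_cds_str(sample(40:90, 1))
      planted <- plant_effect(cds, category)
      got <- classify_cds(cds, planted$cds)$category
      expect_equal(got, category, info = paste(category, "rep", rep))
    }
  }
})

test_that("swapping the pair inverts directional categories and keeps symmetric ones", {
  set.seed(9)
  for (rep in 1:5) {
    cds <- random_cds_str(50)
    for (cat in c("identical", "synonymous", "nonsynonymous")) {
      mut <- plant_effect(cds, cat)$cds
      expect_equal(classify_cds(mut, cds)$category, cat)
    }
    ins <- plant_effect(cds, "inframe_insertion")$cds
    expect_equal(classify_cds(ins, cds)$category, "inframe_deletion")
    del <- plant_effect(cds, "inframe_deletion")$cds
    expect_equal(classify_cds(del, cds)$category, "inframe_insertion")
  }
})

test_that("severity precedence picks the most disruptive co-occurring feature", {
  ref <- "ATGGCTAAATTCCCAGGTTGGTACGAAGATTAA"
  # frameshift plus a nonsynonymous substitution: frameshift wins
  both <- sub("TGG", "TGT", paste0(substr(ref, 1, 9), substr(ref, 12, nchar(ref))))
  expect_equal(classify_cds(ref, both)$category, "frameshift")
  # a custom severity order can depose the default winner
  v <- classify_cds(ref, both,
                    severity = c("nonsynonymous", "frameshift", "stop_gained",
                                 "start_lost", "truncation_5p", "truncation_3p",
                                 "inframe_insertion", "inframe_deletion"))
  expect_equal(v$category, "nonsynonymous")
})

test_that("coding/non-coding disagreement errors; non-coding pairs get DNA identity only", {
  sim <- simulate_genome_pair(sim_config(seed = 15, n_genes = 10))
  ref_tx <- sim$ref_transcripts
  subj_tx <- sim$subj_transcripts
  # make one transcript non-coding in both annotations
  nc <- 1L
  ref_nc <- ref_tx; ref_nc$cds[[nc]] <- ref_nc$cds[[nc]][0, ]
  subj_nc <- subj_tx; subj_nc$cds[[nc]] <- subj_nc$cds[[nc]][0, ]
  v <- classify_transcripts(ref_nc, subj_nc, sim$ref_genome, sim$subj_genome)
  row <- v[v$transcript_id == ref_tx$transcript_id[nc], ]
  expect_true(is.na(row$category))
  expect_false(is.na(row$dna_identity))
  # CDS present on only one side is a structural defect
  expect_error(
    classify_transcripts(ref_nc, subj_tx, sim$ref_genome, sim$subj_genome),
    "only one annotation"
  )
})
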