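small_cfg <- function(seed, ...) {
  sim_config(seed = seed, n_genes = 12, rdna_units = 2,
             numt_len = 3000L, numt_spanning = 6L, numt_nonspanning = 3L, ...)
}

test_that("the same seed reproduces every emitted file byte for byte", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_simulation(simulate_genome_pair(small_cfg(77)), d1)
  write_simulation(simulate_genome_pair(small_cfg(77)), d2)
  files <- list.files(d1)
  expect_gt(length(files), 5)
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  # a different seed changes the sequence content
  d3 <- withr::local_tempdir()
  write_simulation(simulate_genome_pair(small_cfg(78)), d3)
  expect_false(identical(readLines(file.path(d1, "ref.fa")),
                         readLines(file.path(d3, "ref.fa"))))
})

test_that("generated genes are well-formed coding models", {
  sim <- simulate_genome_pair(sim_config(seed = 79, n_genes = 15))
  expect_equal(nrow(sim$ref_transcripts), 15)
  for (i in seq_len(nrow(sim$ref_transcripts))) {
    cds <- extract_cds(sim$ref_genome, sim$ref_transcripts[i, ])
    expect_equal(nchar(cds) %% 3, 0)
    expect_equal(substr(cds, 1, 3), "ATG")
    tr <- translate_cds(cds)
    expect_false(tr$premature_stop)
    expect_equal(nchar(tr$protein), nchar(cds) / 3 - 1)  # terminal stop present
  }
})

test_that("a plan with no effects leaves subject identical to reference", {
  cfg <- sim_config(seed = 81, n_genes = 10,
                    category_counts = c(identical = 10))
  sim <- simulate_genome_pair(cfg)
  expect_identical(sim$subj_genome$residues[1],
                   paste0(tolower(substr(sim$ref_genome$residues[1], 1, 500)),
                          substr(sim$ref_genome$residues[1], 501,
                                 nchar(sim$ref_genome$residues[1]))))
  expect_equal(nrow(sim$variants), 0)
  expect_true(all(sim$truth$planted_zygosity == "none"))
})

test_that("a targeted hom frameshift plants exactly one non-SNP record in its CDS", {
  cfg <- small_cfg(83)
  set.seed(cfg$seed)
  ref <- generate_reference(cfg)
  plan <- tibble::tibble(
    gene_id = sort(unique(ref$transcripts$gene_id)),
    category = "identical", zygosity = "none", keep_intact = FALSE
  )
  plan$category[5] <- "frameshift"
  plan$zygosity[5] <- "hom"
  subj <- build_subject(ref, plan, cfg)
  expect_equal(nrow(subj$variants), 1)
  v <- subj$variants
  expect_equal(v$zygosity, "hom")
  expect_false(v$is_snp)
  g5 <- ref$transcripts[ref$transcripts$gene_id == plan$gene_id[5], ]
  cds <- g5$cds[[1]]
  covered <- any(v$pos + nchar(v$ref_allele) > cds$start & v$pos < cds$end)
  expect_true(covered)
})

test_that("lifted subject models reproduce the planted CDS (round-trip oracle)", {
  sim <- simulate_genome_pair(sim_config(seed = 85))
  for (i in seq_len(nrow(sim$truth))) {
    gid <- sim$truth$gene_id[i]
    stx <- sim$subj_transcripts[sim$subj_transcripts$gene_id == gid, ]
    got <- extract_cds(sim$subj_genome, stx)
    want <- if (sim$truth$applied[i] || sim$truth$planted_category[i] == "identical") {
      sim$truth$planted_cds[i]
    } else {
      rtx <- sim$ref_transcripts[sim$ref_transcripts$gene_id == gid, ]
      extract_cds(sim$ref_genome, rtx)
    }
    expect_equal(got, want, info = gid)
  }
})

test_that("planting requests that cannot be satisfied are errors", {
  expect_error(plant_effect("ATGTAA", "inframe_deletion"), "")   # no internal codon
  expect_error(sim_config(seed = 1, n_genes = 5), "at least 10")
  expect_error(sim_config(seed = 1, n_genes = 20,
                          category_counts = c(identical = 3)), "")
})

test_that("simulated rDNA arrays and NUMT reads mirror their configuration", {
  cfg <- sim_config(seed = 87, n_genes = 10, rdna_units = 5,
                    numt_spanning = 26L, numt_nonspanning = 10L)
  set.seed(cfg$seed)
  extra <- simulate_rdna_and_numt(cfg)
  # without decoys: exactly the planted units
  cfg0 <- sim_config(seed = 88, n_genes = 10, rdna_units = 5, rdna_decoys = FALSE)
  set.seed(cfg0$seed)
  clean <- simulate_rdna_and_numt(cfg0)
  out <- group_valid_units(clean$rdna_subunits)
  expect_equal(nrow(out$units), 5)
  expect_equal(nrow(out$rejected), 0)
  # with decoys the planted units still come out, decoys are rejected
  out2 <- group_valid_units(extra$rdna_subunits)
  expect_equal(nrow(out2$units), 5)
  expect_gt(nrow(out2$rejected), 0)
  # spanning-read truth is recovered
  expect_equal(validate_numt(extra$numt$seq_name, extra$numt$start,
                             extra$numt$end, extra$reads), 26)
  # candidate decoys fail the identity/length filter
  kept <- filter_rdna_candidates(extra$rdna_candidates)
  expect_equal(nrow(kept), 5)
})

test_that("divergent rDNA copies fail the identity filter by construction", {
  cfg <- sim_config(seed = 89, n_genes = 10, rdna_units = 3,
                    rdna_divergence = 5, rdna_decoys = FALSE)
  set.seed(cfg$seed)
  extra <- simulate_rdna_and_numt(cfg)
  expect_equal(nrow(filter_rdna_candidates(extra$rdna_subunits)), 0)
  expect_equal(nrow(filter_rdna_candidates(extra$rdna_candidates)), 0)
})

test_that("het-planted genes can keep the intact haplotype in the assembly", {
  cfg <- sim_config(seed = 91, n_genes = 20, het_intact_fraction = 1,
                    het_fraction_deleterious = 1, het_fraction_benign = 1)
  sim <- simulate_genome_pair(cfg)
  # every edited gene is het and kept intact: subject classifies identical
  expect_true(all(sim$truth$planted_zygosity %in% c("none", "het")))
  expect_true(all(!sim$truth$applied | sim$truth$planted_category == "identical"))
  v <- classify_transcripts(sim$ref_transcripts, sim$subj_transcripts,
                            sim$ref_genome, sim$subj_genome)
  expect_true(all(v$category == "identical"))
  # the variants are still reported (het) for the rescue stage
  expect_gt(nrow(sim$variants), 0)
  expect_true(all(sim$variants$zygosity == "het"))
})
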