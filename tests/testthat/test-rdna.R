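mk_paf <- function(qname, tstart, tend, strand = "+", identity = 99.5,
                   target = "chr13", primary = TRUE) {
  alen <- tend - tstart
  tibble::tibble(
    query_name = qname, query_len = alen, query_start = 0L, query_end = alen,
    strand = strand, target_name = target, target_len = 10000000L,
    target_start = as.integer(tstart), target_end = as.integer(tend),
    n_matches = as.integer(round(alen * identity / 100)), aln_len = alen,
    mapq = 60L, is_primary = primary,
    identity = 100 * round(alen * identity / 100) / alen
  )
}

test_that("candidate filter applies strict length and identity cutoffs", {
  recs <- dplyr::bind_rows(
    mk_paf("u", 0, 1000, identity = 99.0),    # length exactly at cutoff: rejected
    mk_paf("u", 0, 1500, identity = 98.4),    # identity below cutoff: rejected
    mk_paf("u", 0, 1500, identity = 99.2),    # passes
    mk_paf("u", 0, 999, identity = 99.9)      # too short
  )
  kept <- filter_rdna_candidates(recs)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$aln_len, 1500L)
})

test_that("a constructed candidate set keeps exactly its passing records", {
  set.seed(47)
  pass <- purrr::map(1:7, ~ mk_paf("u", .x * 5000, .x * 5000 + sample(1100:4000, 1),
                                   identity = runif(1, 98.6, 99.9)))
  fail <- purrr::map(1:5, ~ mk_paf("u", 100000 + .x * 5000,
                                   100000 + .x * 5000 + sample(300:900, 1),
                                   identity = runif(1, 99, 100)))
  recs <- dplyr::bind_rows(c(pass, fail))
  expect_equal(nrow(filter_rdna_candidates(recs)), 7)
})

test_that("candidate loci merge like a quadratic merge oracle", {
  a <- dplyr::bind_rows(mk_paf("u", 0, 100), mk_paf("u", 50, 200))
  expect_equal(merge_candidate_loci(a),
               tibble::tibble(seq_name = "chr13", start = 0L, end = 200L))
  b <- dplyr::bind_rows(mk_paf("u", 0, 100), mk_paf("u", 500, 700))
  expect_equal(nrow(merge_candidate_loci(b)), 2)
  set.seed(49)
  for (rep in 1:10) {
    n <- sample(5:15, 1)
    starts <- sample(0:2000, n)
    recs <- dplyr::bind_rows(purrr::map(starts, ~ mk_paf("u", .x, .x + sample(50:400, 1))))
    got <- merge_candidate_loci(recs, gap_tolerance = 10L)
    want <- oracle_merge(tibble::tibble(start = recs$target_start, end = recs$target_end),
                         gap = 10L)
    expect_equal(got$start, as.integer(want$start))
    expect_equal(got$end, as.integer(want$end))
  }
})

test_that("three subunits in transcription order form one valid unit", {
  trio <- dplyr::bind_rows(
    mk_paf("18S", 1000, 2800),
    mk_paf("5.8S", 3100, 3260),
    mk_paf("28S", 3500, 7500)
  )
  out <- group_valid_units(trio)
  expect_equal(nrow(out$units), 1)
  expect_equal(nrow(out$rejected), 0)
  expect_equal(out$units$start, 1000L)
  expect_equal(out$units$end, 7500L)
  expect_equal(out$units$subunits[[1]]$query_name, c("18S", "5.8S", "28S"))
})

test_that("out-of-order subunits yield no units and order rejects", {
  wrong <- dplyr::bind_rows(
    mk_paf("18S", 1000, 2800),
    mk_paf("28S", 3100, 7100),
    mk_paf("5.8S", 7500, 7660)
  )
  out <- group_valid_units(wrong)
  expect_equal(nrow(out$units), 0)
  expect_equal(nrow(out$rejected), 3)
  expect_equal(unique(out$rejected$reason), "order")
})

test_that("minus-strand units are recognised in mirrored genomic order", {
  minus <- dplyr::bind_rows(
    mk_paf("28S", 1000, 5000, strand = "-"),
    mk_paf("5.8S", 5300, 5460, strand = "-"),
    mk_paf("18S", 5800, 7600, strand = "-")
  )
  out <- group_valid_units(minus)
  expect_equal(nrow(out$units), 1)
  # subunits reported in transcription order
  expect_equal(out$units$subunits[[1]]$query_name, c("18S", "5.8S", "28S"))
})

test_that("a triple wider than the unit span is rejected for span", {
  wide <- dplyr::bind_rows(
    mk_paf("18S", 0, 1800),
    mk_paf("5.8S", 30000, 30160),
    mk_paf("28S", 60000, 64000)
  )
  out <- group_valid_units(wide)
  expect_equal(nrow(out$units), 0)
  expect_equal(unique(out$rejected$reason), "span")
  # and a generous span limit accepts it
  expect_equal(nrow(group_valid_units(wide, max_unit_span = 100000L)$units), 1)
})

test_that("grouping is invariant under input shuffling and never reuses a record", {
  set.seed(53)
  sim <- simulate_genome_pair(sim_config(seed = 53, n_genes = 10, rdna_units = 6))
  base <- group_valid_units(sim$rdna_subunits)
  expect_equal(3 * nrow(base$units) + nrow(base$rejected), nrow(sim$rdna_subunits))
  expect_equal(nrow(base$units) %% 1, 0)
  for (rep in 1:3) {
    shuf <- sim$rdna_subunits[sample(nrow(sim$rdna_subunits)), ]
    out <- group_valid_units(shuf)
    expect_equal(out$units$start, base$units$start)
    expect_equal(out$units$unit_id, base$units$unit_id)
  }
})

test_that("filtering before grouping equals grouping the filtered subset", {
  sim <- simulate_genome_pair(sim_config(seed = 59, n_genes = 10, rdna_units = 4))
  subs <- sim$rdna_subunits
  # mix in low-identity records so the filter bites
  lowid <- dplyr::mutate(subs[1:3, ], target_start = target_start + 500000L,
                         target_end = target_end + 500000L,
                         n_matches = as.integer(0.9 * n_matches),
                         identity = 90)
  mixed <- dplyr::bind_rows(subs, lowid)
  keep <- filter_rdna_candidates(mixed, min_len = 100, min_identity = 98.5)
  a <- group_valid_units(keep)
  b <- group_valid_units(mixed[mixed$aln_len > 100 & mixed$identity > 98.5, ])
  expect_equal(a$units$start, b$units$start)
})

test_that("unlabeled placements are rejected up front", {
  expect_error(group_valid_units(mk_paf("oddball", 0, 1000)), "label")
})

test_that("overlap audit reports unit-gene intersections and clean layouts", {
  units <- tibble::tibble(unit_id = "u1", seq_name = "chr13", strand = "+",
                          start = 1000L, end = 8000L, subunits = list(NULL))
  genes <- tibble::tibble(
    gene_id = "g1", gene_name = "G1", transcript_id = "t1",
    biotype = "protein_coding", seq_name = "chr13", strand = "+",
    exons = list(tibble::tibble(start = 2000L, end = 2500L)),
    cds = list(tibble::tibble(start = 2000L, end = 2500L, phase = 0L))
  )
  hits <- audit_overlaps(units, genes)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$gene_id, "g1")
  # disjoint gene: clean audit
  genes$exons[[1]] <- tibble::tibble(start = 9000L, end = 9500L)
  expect_equal(nrow(audit_overlaps(units, genes)), 0)
  expect_equal(nrow(audit_overlaps(units, genes[0, ])), 0)
})
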