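#' Cluster near-identical genes across two genomes
#'
#' Single-linkage clustering over the pairwise relation "globally at least
#' `min_identity` identical and aligned over at least `min_coverage` of both
#' sequences' lengths" — a gene belongs to a cluster when it satisfies the
#' criterion with at least one other member. Protein-coding genes are
#' clustered on amino-acid sequences, non-coding genes on nucleotide
#' sequences (`alphabet`). Cluster ids are deterministic: clusters are
#' numbered by their lexicographically smallest member id.
#'
#' @param seqs A tibble with `id` (unique gene label), `genome` (`"ref"` or
#'   `"subj"`), `residues` (sequence).
#' @param min_identity Identity threshold on alignment columns (default 0.9).
#' @param min_coverage Coverage threshold required of *both* sequences
#'   (default 0.9).
#' @param alphabet `"protein"` or `"dna"`.
#' @return A cluster tibble: `cluster_id`, `members_ref`, `members_subj`
#'   (list-columns of ids), `n_ref`, `n_subj`, `delta = n_subj - n_ref`,
#'   `loss_class` in
#'   none / absent_in_subject / lost_one / lost_multiple / gained.
#' @export
cluster_sequences <- function(seqs, min_identity = 0.9, min_coverage = 0.9,
                              alphabet = c("protein", "dna")) {
  alphabet <- match.arg(alphabet)
  stopifnot(all(c("id", "genome", "residues") %in% names(seqs)),
            !anyDuplicated(seqs$id),
            all(seqs$genome %in% c("ref", "subj")))
  n <- nrow(seqs)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (n > 1) {
    lens <- nchar(seqs$residues)
    edges <- integer(0)
    # identity and coverage are both bounded by min(len)/max(len), so pairs
    # failing that bound cannot be edges and are never aligned; surviving
    # pairs are aligned in one batched call per subject sequence
    bound_needed <- max(min_identity, min_coverage)
    for (j in 2:n) {
      is <- seq_len(j - 1L)
      bound <- pmin(lens[is], lens[j]) / pmax(lens[is], lens[j])
      is <- is[bound >= bound_needed]
      if (length(is) == 0) next
      hit <- batch_edge_check(seqs$residues[is], seqs$residues[j], alphabet,
                              min_identity, min_coverage)
      if (any(hit)) edges <- c(edges, rbind(is[hit], j))
    }
    if (length(edges) > 0) g <- igraph::add_edges(g, edges)
  }
  comp <- igraph::components(g)$membership
  split_ids <- split(seq_len(n), comp)
  # deterministic ordering by smallest member id
  ord <- order(vapply(split_ids, function(ix) min(seqs$id[ix]), ""))
  rows <- map(seq_along(ord), function(r) {
    ix <- split_ids[[ord[r]]]
    mr <- sort(seqs$id[ix][seqs$genome[ix] == "ref"])
    ms <- sort(seqs$id[ix][seqs$genome[ix] == "subj"])
    tibble(
      cluster_id = sprintf("cluster_%04d", r),
      members_ref = list(mr), members_subj = list(ms),
      n_ref = length(mr), n_subj = length(ms)
    )
  })
  out <- bind_rows(rows)
  out$delta <- out$n_subj - out$n_ref
  out$loss_class <- dplyr::case_when(
    out$delta == 0 ~ "none",
    out$n_subj == 0 ~ "absent_in_subject",
    out$delta == -1 ~ "lost_one",
    out$delta < -1 ~ "lost_multiple",
    TRUE ~ "gained"
  )
  out
}

# Batched identity/coverage test of many candidate partners against one
# sequence; alignment parameters identical to global_identity().
batch_edge_check <- function(a_vec, b, alphabet, min_identity, min_coverage) {
  if (alphabet == "dna") {
    pats <- Biostrings::DNAStringSet(toupper(a_vec))
    subj <- Biostrings::DNAString(toupper(b))
    mat <- dna_score_matrix(); go <- 5; ge <- 2
  } else {
    pats <- Biostrings::AAStringSet(a_vec)
    subj <- Biostrings::AAString(b)
    mat <- "BLOSUM62"; go <- 11; ge <- 1
  }
  aln <- Biostrings::pairwiseAlignment(pats, subj, type = "global",
                                       substitutionMatrix = mat,
                                       gapOpening = go, gapExtension = ge)
  nm <- Biostrings::nmatch(aln)
  both <- nm + Biostrings::nmismatch(aln)   # both-aligned columns
  la <- nchar(a_vec); lb <- nchar(b)
  cols <- la + lb - both                    # total alignment columns
  nm / cols >= min_identity & both / la >= min_coverage & both / lb >= min_coverage
}

#' Summarise copy-number differences between genomes
#'
#' Tallies clusters by loss class, counts clusters with copy-number change,
#' and lists clusters with at least `k` reference members (the gene families
#' of interest).
#'
#' @param clusters A cluster tibble ([cluster_sequences()]).
#' @param k Reference-member threshold for the family list (default 3).
#' @return An object of class `copy_number_summary` with `by_class` counts,
#'   `n_clusters`, `n_changed`, and `families` (clusters with `n_ref >= k`);
#'   see the [tidy()] and [glance()] methods.
#' @export
compare_copy_numbers <- function(clusters, k = 3L) {
  classes <- c("none", "absent_in_subject", "lost_one", "lost_multiple", "gained")
  by_class <- count(clusters, loss_class = factor(.data$loss_class, levels = classes),
                    .drop = FALSE)
  by_class$loss_class <- as.character(by_class$loss_class)
  out <- list(
    by_class = as_tibble(by_class),
    n_clusters = nrow(clusters),
    n_changed = sum(clusters$loss_class != "none"),
    families = filter(clusters, .data$n_ref >= k),
    k = k
  )
  class(out) <- "copy_number_summary"
  out
}

#' @export
print.copy_number_summary <- function(x, ...) {
  cat("Copy-number comparison:", x$n_clusters, "clusters,",
      x$n_changed, "with copy-number change\n")
  print(x$by_class)
  cat("Families with >=", x$k, "reference members:", nrow(x$families), "\n")
  invisible(x)
}

#' @export
tidy.copy_number_summary <- function(x, ...) x$by_class

#' @export
glance.copy_number_summary <- function(x, ...) {
  wide <- stats::setNames(as.list(x$by_class$n), x$by_class$loss_class)
  bind_cols(tibble(n_clusters = x$n_clusters, n_changed = x$n_changed),
            as_tibble(wide))
}
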