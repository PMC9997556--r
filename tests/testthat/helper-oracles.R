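# Independent oracles used by the tests. These deliberately re-derive results
# by brute force and stay out of the package's own code paths.

# Gotoh global alignment with affine gaps (gap of length L costs
# open + L * extend), returning the optimal score and the identity of the
# traceback alignment (matches / total columns, terminal gaps included).
oracle_global_align <- function(a, b, alphabet = c("dna", "protein")) {
  alphabet <- match.arg(alphabet)
  if (alphabet == "dna") {
    open <- 5; extend <- 2
    score_pair <- function(x, y) if (x == y) 2 else -3
  } else {
    open <- 11; extend <- 1
    data("BLOSUM62", package = "Biostrings", envir = environment())
    B <- get("BLOSUM62", envir = environment())
    score_pair <- function(x, y) B[x, y]
  }
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)  # a[i] aligned to b[j]
  X <- matrix(NEG, n + 1, m + 1)  # gap in b (a[i] unmatched)
  Y <- matrix(NEG, n + 1, m + 1)  # gap in a
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- -(open + i * extend)
  for (j in seq_len(m)) Y[1, j + 1] <- -(open + j * extend)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- score_pair(av[i], bv[j])
      M[i + 1, j + 1] <- s + max(M[i, j], X[i, j], Y[i, j])
      X[i + 1, j + 1] <- max(M[i, j + 1] - open - extend,
                             X[i, j + 1] - extend,
                             Y[i, j + 1] - open - extend)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - open - extend,
                             Y[i + 1, j] - extend,
                             X[i + 1, j] - open - extend)
    }
  }
  best <- max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
  # traceback (prefer M, then X, then Y on ties)
  state <- c("M", "X", "Y")[which.max(c(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1]))]
  i <- n; j <- m
  matches <- 0L; cols <- 0L
  while (i > 0 || j > 0) {
    cols <- cols + 1L
    if (state == "M") {
      s <- score_pair(av[i], bv[j])
      if (av[i] == bv[j]) matches <- matches + 1L
      prev <- c(M[i, j], X[i, j], Y[i, j])
      target <- M[i + 1, j + 1] - s
      state <- c("M", "X", "Y")[which(abs(prev - target) < 1e-9)[1]]
      i <- i - 1; j <- j - 1
    } else if (state == "X") {
      cur <- X[i + 1, j + 1]
      opts <- c(M[i, j + 1] - open - extend, X[i, j + 1] - extend,
                Y[i, j + 1] - open - extend)
      state <- c("M", "X", "Y")[which(abs(opts - cur) < 1e-9)[1]]
      i <- i - 1
    } else {
      cur <- Y[i + 1, j + 1]
      opts <- c(M[i + 1, j] - open - extend, Y[i + 1, j] - extend,
                X[i + 1, j] - open - extend)
      state <- c("M", "Y", "X")[which(abs(opts - cur) < 1e-9)[1]]
      j <- j - 1
    }
    if (i == 0 && j > 0) { cols <- cols + j; break }
    if (j == 0 && i > 0) { cols <- cols + i; break }
  }
  list(score = best, identity = matches / cols, matches = matches, cols = cols)
}

# All identities achievable by *optimal* global alignments of a and b:
# when several alignments tie on score they can differ in match and column
# counts, so the implementation's identity is checked for membership in this
# set. Forward Gotoh DP, then memoized enumeration over all optimal
# predecessor transitions.
oracle_identity_set <- function(a, b, alphabet = c("dna", "protein")) {
  alphabet <- match.arg(alphabet)
  if (alphabet == "dna") {
    open <- 5; extend <- 2
    score_pair <- function(x, y) if (x == y) 2 else -3
  } else {
    open <- 11; extend <- 1
    data("BLOSUM62", package = "Biostrings", envir = environment())
    B <- get("BLOSUM62", envir = environment())
    score_pair <- function(x, y) B[x, y]
  }
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(av); m <- length(bv); NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1); X <- matrix(NEG, n + 1, m + 1)
  Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- -(open + i * extend)
  for (j in seq_len(m)) Y[1, j + 1] <- -(open + j * extend)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    sc <- score_pair(av[i], bv[j])
    M[i + 1, j + 1] <- sc + max(M[i, j], X[i, j], Y[i, j])
    X[i + 1, j + 1] <- max(M[i, j + 1] - open - extend, X[i, j + 1] - extend,
                           Y[i, j + 1] - open - extend)
    Y[i + 1, j + 1] <- max(M[i + 1, j] - open - extend, Y[i + 1, j] - extend,
                           X[i + 1, j] - open - extend)
  }
  mats <- list(M, X, Y)
  memo <- new.env(parent = emptyenv())
  eps <- 1e-9
  # set of (matches, cols) pairs over optimal paths from origin to (i,j,state)
  collect <- function(i, j, s) {
    key <- paste(i, j, s)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    val <- mats[[s]][i + 1, j + 1]
    out <- NULL
    if (val < -1e8) {
      out <- matrix(numeric(0), ncol = 2)
    } else if (i == 0 && j == 0) {
      out <- if (s == 1) matrix(c(0, 0), ncol = 2) else matrix(numeric(0), ncol = 2)
    } else if (s == 1) {
      sc <- score_pair(av[i], bv[j])
      add_match <- as.numeric(av[i] == bv[j])
      parts <- list()
      for (p in 1:3) {
        if (abs(mats[[p]][i, j] - (val - sc)) < eps) {
          prev <- collect(i - 1, j - 1, p)
          if (nrow(prev) > 0) parts[[length(parts) + 1]] <-
            cbind(prev[, 1] + add_match, prev[, 2] + 1)
        }
      }
      out <- if (length(parts)) unique(do.call(rbind, parts)) else matrix(numeric(0), ncol = 2)
    } else if (s == 2) {
      costs <- c(open + extend, extend, open + extend)
      parts <- list()
      for (p in 1:3) {
        if (i >= 1 && abs(mats[[p]][i, j + 1] - costs[p] - val) < eps) {
          prev <- collect(i - 1, j, p)
          if (nrow(prev) > 0) parts[[length(parts) + 1]] <-
            cbind(prev[, 1], prev[, 2] + 1)
        }
      }
      out <- if (length(parts)) unique(do.call(rbind, parts)) else matrix(numeric(0), ncol = 2)
    } else {
      costs <- c(open + extend, open + extend, extend)  # from M, X, Y
      parts <- list()
      for (p in 1:3) {
        if (j >= 1 && abs(mats[[p]][i + 1, j] - costs[p] - val) < eps) {
          prev <- collect(i, j - 1, p)
          if (nrow(prev) > 0) parts[[length(parts) + 1]] <-
            cbind(prev[, 1], prev[, 2] + 1)
        }
      }
      out <- if (length(parts)) unique(do.call(rbind, parts)) else matrix(numeric(0), ncol = 2)
    }
    memo[[key]] <- out
    out
  }
  finals <- c(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
  best <- max(finals)
  pairs <- do.call(rbind, lapply(which(abs(finals - best) < eps),
                                 function(s) collect(n, m, s)))
  unique(pairs[, 1] / pairs[, 2])
}

# Quadratic interval merge: repeatedly fuse any two intervals that overlap or
# are within `gap` of each other.
oracle_merge <- function(iv, gap = 0L) {
  iv <- iv[order(iv$start), , drop = FALSE]
  repeat {
    fused <- FALSE
    if (nrow(iv) >= 2) {
      for (i in seq_len(nrow(iv) - 1)) {
        for (j in seq((i + 1), nrow(iv))) {
          if (iv$start[j] <= iv$end[i] + gap && iv$start[i] <= iv$end[j] + gap) {
            iv$start[i] <- min(iv$start[i], iv$start[j])
            iv$end[i] <- max(iv$end[i], iv$end[j])
            iv <- iv[-j, , drop = FALSE]
            fused <- TRUE
            break
          }
        }
        if (fused) break
      }
    }
    if (!fused) break
  }
  iv[order(iv$start), , drop = FALSE]
}

# Exhaustive all-pairs single-linkage clustering via union-find, with the
# same edge criterion as cluster_sequences().
oracle_cluster <- function(seqs, min_identity = 0.9, min_coverage = 0.9,
                           alphabet = "protein") {
  n <- nrow(seqs)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        gi <- global_identity(seqs$residues[i], seqs$residues[j], alphabet)
        if (gi$identity >= min_identity && gi$coverage_a >= min_coverage &&
            gi$coverage_b >= min_coverage) {
          parent[find(i)] <- find(j)
        }
      }
    }
  }
  comp <- vapply(seq_len(n), find, 0L)
  unname(split(seqs$id, comp))
}

random_dna_str <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

random_protein_str <- function(n) {
  paste(sample(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]], n, TRUE), collapse = "")
}

# Random valid CDS: ATG + non-stop codons + stop.
random_cds_str <- function(n_codon) {
  stops <- c("TAA", "TAG", "TGA")
  all_codons <- names(Biostrings::GENETIC_CODE)
  internal <- sample(setdiff(all_codons, stops), n_codon - 2L, replace = TRUE)
  paste0("ATG", paste(internal, collapse = ""), sample(stops, 1))
}
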