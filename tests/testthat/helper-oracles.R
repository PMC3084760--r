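# Independent oracles used by the tests: a plain-R affine-gap dynamic
# programming aligner (Gotoh), a naive window scan for the NOR motifs, and
# small random-sequence helpers. These deliberately share no code with the
# package's alignment path.

.oracle_matrix <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

# optimal Smith-Waterman score; a gap of length k costs open + k * extend
oracle_local_score <- function(a, b, open = 11, extend = 1) {
  sm <- .oracle_matrix()
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  M <- matrix(0, n + 1, m + 1)
  Ix <- matrix(NEG, n + 1, m + 1)  # gap in b (vertical)
  Iy <- matrix(NEG, n + 1, m + 1)  # gap in a (horizontal)
  best <- 0
  for (i in 1:n) {
    for (j in 1:m) {
      Ix[i + 1, j + 1] <- max(M[i, j + 1] - open - extend, Ix[i, j + 1] - extend)
      Iy[i + 1, j + 1] <- max(M[i + 1, j] - open - extend, Iy[i + 1, j] - extend)
      M[i + 1, j + 1] <- max(0, max(M[i, j], Ix[i, j], Iy[i, j]) + sm[av[i], bv[j]])
      best <- max(best, M[i + 1, j + 1], Ix[i + 1, j + 1], Iy[i + 1, j + 1])
    }
  }
  best
}

# optimal global (end-to-end) score under the same gap convention
oracle_global_score <- function(a, b, open = 11, extend = 1) {
  sm <- .oracle_matrix()
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  Ix <- matrix(NEG, n + 1, m + 1)
  Iy <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in 1:n) Ix[i + 1, 1] <- -open - i * extend
  for (j in 1:m) Iy[1, j + 1] <- -open - j * extend
  for (i in 1:n) {
    for (j in 1:m) {
      Ix[i + 1, j + 1] <- max(M[i, j + 1] - open - extend, Ix[i, j + 1] - extend)
      Iy[i + 1, j + 1] <- max(M[i + 1, j] - open - extend, Iy[i + 1, j] - extend)
      M[i + 1, j + 1] <- max(M[i, j], Ix[i, j], Iy[i, j]) + sm[av[i], bv[j]]
    }
  }
  max(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1])
}

# brute-force window scan for the two NOR motifs
oracle_nor_motifs <- function(s) {
  ch <- strsplit(s, "")[[1]]
  arom <- c("F", "Y", "W")
  L <- length(ch)
  m1 <- FALSE
  if (L >= 5) {
    for (i in 1:(L - 4)) {
      if (ch[i] == "H" && ch[i + 2] %in% arom && ch[i + 4] == "E") { m1 <- TRUE; break }
    }
  }
  m2 <- FALSE
  if (L >= 23) {
    for (i in 1:(L - 22)) {
      if (ch[i] == "H" && ch[i + 1] == "H" && ch[i + 3] %in% arom &&
          ch[i + 4] %in% arom && ch[i + 22] == "E") { m2 <- TRUE; break }
    }
  }
  c(m1, m2)
}

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

random_aa <- function(n, alphabet = AA20) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# tiny labeled reference set built from explicit sequences
tiny_refset <- function(seqs, types) {
  recs <- protein_records(id = names(seqs), residues = unname(seqs))
  build_reference_set(recs, stats::setNames(types, names(seqs)))
}

# random additive distance matrix from a random topology with positive
# branch lengths; returns list(dist, tree)
random_additive_matrix <- function(n_leaves) {
  tree <- ape::rtree(n_leaves, rooted = FALSE,
                     br = function(k) stats::runif(k, 0.1, 1))
  d <- ape::cophenetic.phylo(tree)
  ord <- sort(rownames(d))
  list(d = d[ord, ord], tree = tree)
}
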