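make_sim <- function(m, ids = NULL) {
  if (is.null(ids)) ids <- letters[seq_len(nrow(m))]
  dimnames(m) <- list(ids, ids)
  diag(m) <- 100
  structure(list(ids = ids, sim = m), class = "similarity_matrix")
}

test_that("network building respects the edge threshold and drops self-pairs", {
  sm <- make_sim(matrix(c(100, 40, 40, 100), 2))
  net <- build_network(sm, min_edge = 0)
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$weight, 40)
  net50 <- build_network(sm, min_edge = 50)
  expect_equal(nrow(net50$edges), 0)
  expect_equal(nrow(net50$nodes), 2)
})

test_that("edge set equals brute-force pair enumeration; complete when all positive", {
  set.seed(61)
  n <- 7
  m <- matrix(runif(n * n, 1, 99), n, n)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  sm <- make_sim(m)
  thr <- 30
  net <- build_network(sm, min_edge = thr)
  brute <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (sm$sim[i, j] >= thr && sm$sim[i, j] > 0) brute <- brute + 1
  }
  expect_equal(nrow(net$edges), brute)
  # all-positive similarities with no threshold: complete graph C(n,2)
  expect_equal(nrow(build_network(sm, min_edge = 0)$edges), choose(n, 2))
})

test_that("cluster mean similarities match hand computation and NA singletons", {
  m <- matrix(c(100, 50, 10, 20,
                50, 100, 12, 22,
                10, 12, 100, 60,
                20, 22, 60, 100), 4, byrow = TRUE)
  sm <- make_sim(m, c("p1", "p2", "q1", "q2"))
  labels <- c(p1 = "A1", p2 = "A1", q1 = "B", q2 = "B")
  cm <- cluster_mean_similarity(sm, labels)
  get <- function(a, b) cm$mean_similarity[cm$type_a == a & cm$type_b == b]
  expect_equal(get("A1", "A1"), 50)
  expect_equal(get("B", "B"), 60)
  expect_equal(get("A1", "B"), mean(c(10, 20, 12, 22)))

  labels2 <- c(p1 = "A1", p2 = "A1", q1 = "B", q2 = "NOR")
  cm2 <- cluster_mean_similarity(sm, labels2)
  expect_true(is.na(cm2$mean_similarity[cm2$type_a == "B" & cm2$type_b == "B"]))

  # permutation invariance to id order
  perm <- c(3, 1, 4, 2)
  smp <- make_sim(m[perm, perm], c("q1", "p1", "q2", "p2"))
  cmp <- cluster_mean_similarity(smp, labels)
  expect_equal(cmp, cm)
})

test_that("similarity-to-distance transform is the documented linear map", {
  m <- matrix(c(100, 0, 0, 100), 2)
  dm <- to_distances(make_sim(m))
  expect_equal(dm$d[1, 2], 1)
  expect_equal(unname(diag(dm$d)), c(0, 0))
  set.seed(62)
  n <- 5
  r <- matrix(runif(n * n, 0, 100), n, n)
  r[lower.tri(r)] <- t(r)[lower.tri(r)]
  sm <- make_sim(r)
  dm2 <- to_distances(sm)
  expect_equal(dm2$d, (100 - sm$sim) / 100,
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("three-taxon NJ solves the three-point closed form", {
  d <- matrix(c(0, 0.4, 0.6,
                0.4, 0, 0.8,
                0.6, 0.8, 0), 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tree <- neighbor_joining(structure(list(ids = rownames(d), d = d),
                                     class = "distance_matrix"))
  expect_s3_class(tree, "phylo")
  expect_setequal(tree$tip.label, c("a", "b", "c"))
  # closed form: x = (dab + dac - dbc)/2 etc.
  lens <- stats::setNames(tree$edge.length[match(1:3, tree$edge[, 2])],
                          tree$tip.label)
  expect_equal(lens[["a"]], (0.4 + 0.6 - 0.8) / 2)
  expect_equal(lens[["b"]], (0.4 + 0.8 - 0.6) / 2)
  expect_equal(lens[["c"]], (0.6 + 0.8 - 0.4) / 2)
  expect_error(neighbor_joining(d[1:2, 1:2]), "3 taxa")
})

test_that("four-taxon additive matrix recovers the generating quartet", {
  # tree ((a,b),(c,d)) with internal branch 0.3
  d <- matrix(0, 4, 4, dimnames = list(c("a", "b", "c", "d"), c("a", "b", "c", "d")))
  bl <- c(a = 0.2, b = 0.3, c = 0.25, d = 0.15); int <- 0.3
  d["a", "b"] <- d["b", "a"] <- bl["a"] + bl["b"]
  d["c", "d"] <- d["d", "c"] <- bl["c"] + bl["d"]
  for (x in c("a", "b")) for (y in c("c", "d")) {
    d[x, y] <- d[y, x] <- bl[x] + int + bl[y]
  }
  tree <- neighbor_joining(d)
  # four-point condition oracle: the true split pairs a with b
  splits <- ape::prop.part(tree)
  pairs <- sapply(splits, function(s) paste(sort(attr(splits, "labels")[s]), collapse = ""))
  expect_true("ab" %in% pairs || "cd" %in% pairs)
  expect_equal(ape::cophenetic.phylo(tree)[rownames(d), colnames(d)], d,
               tolerance = 1e-9)
})

test_that("NJ reconstructs topology and path lengths on random additive matrices", {
  set.seed(63)
  for (t in 1:10) {
    gen <- random_additive_matrix(sample(5:12, 1))
    tree <- neighbor_joining(gen$d)
    expect_equal(ape::dist.topo(ape::unroot(gen$tree), tree), 0,
                 ignore_attr = TRUE)
    expect_equal(ape::cophenetic.phylo(tree)[rownames(gen$d), colnames(gen$d)],
                 gen$d, tolerance = 1e-9)
  }
})

test_that("negative branch clamping preserves sibling path length", {
  tree <- ape::read.tree(text = "((a:0.5,b:-0.2):0.1,c:0.3,d:0.4);")
  fixed <- clamp_negative_branches(tree)
  expect_true(all(fixed$edge.length >= 0))
  ab_before <- 0.5 + (-0.2)
  cp <- ape::cophenetic.phylo(fixed)
  expect_equal(cp["a", "b"], ab_before)
})

test_that("bootstrap support is well-behaved on degenerate inputs", {
  aln <- c(a = "AAAAAAAAGGGG", b = "AAAAAAAAGGGC", c = "TTTTTTTTGGGG",
           d = "TTTTTTTTGGCC")
  t1 <- bootstrap_support(aln, n_reps = 1, seed = 5)
  expect_true(all(t1$node.label %in% c(0, 1)))
  # resampling-invariant alignment (every column is the same pattern):
  # each replicate sees the identical distance matrix, so every split of
  # the no-resampling tree keeps full support
  uni <- c(a = strrep("A", 12), b = strrep("A", 12), c = strrep("C", 12),
           d = strrep("C", 12))
  tu <- bootstrap_support(uni, n_reps = 20, seed = 5)
  expect_true(all(tu$node.label == 1))
  expect_error(bootstrap_support(NULL), "alignment")
})

test_that("bootstrap split frequencies equal an independent resampling loop", {
  set.seed(64)
  bases <- c("A", "C", "G", "T")
  aln <- vapply(1:5, function(i) paste(sample(bases, 40, TRUE), collapse = ""), "")
  names(aln) <- paste0("t", 1:5)
  n_reps <- 50; seed <- 17
  tree <- bootstrap_support(aln, n_reps = n_reps, seed = seed)

  # independent loop with the same seed protocol
  mat <- do.call(rbind, strsplit(aln, ""))
  rownames(mat) <- names(aln)
  pdist <- function(m) {
    n <- nrow(m); d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- mean(m[i, ] != m[j, ])
    }
    d
  }
  main <- ape::nj(stats::as.dist(pdist(mat)))
  boots <- lapply(seq_len(n_reps), function(r) {
    set.seed(seed + r)
    cols <- sample.int(ncol(mat), ncol(mat), replace = TRUE)
    ape::nj(stats::as.dist(pdist(mat[, cols, drop = FALSE])))
  })
  want <- ape::prop.clades(main, boots, rooted = FALSE)
  want[is.na(want)] <- 0
  expect_equal(unname(tree$node.label), unname(want / n_reps))
})

test_that("network exports are written and parse back", {
  set.seed(65)
  m <- matrix(runif(16, 10, 90), 4)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  sm <- make_sim(m)
  labels <- stats::setNames(c("A1", "A1", "B", "B"), sm$ids)
  net <- build_network(sm, labels)
  edge_path <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(net, edge_path)
  tab <- utils::read.delim(edge_path)
  expect_equal(nrow(tab), nrow(net$edges))
  gml_path <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(net, gml_path)
  g <- igraph::read_graph(gml_path, format = "graphml")
  expect_equal(igraph::gorder(g), 4)
  expect_equal(igraph::gsize(g), nrow(net$edges))
  nwk <- withr::local_tempfile(fileext = ".nwk")
  write_newick(neighbor_joining(to_distances(sm)), nwk)
  expect_s3_class(ape::read.tree(nwk), "phylo")
})
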