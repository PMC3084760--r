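# Similarity-network export, per-cluster mean similarities, and
# neighbor-joining trees from similarity-derived distances. The network is
# exported (edge list / GraphML), never laid out here; NJ uses the
# classical Saitou-Nei agglomeration (via ape) on d = (100 - sim) / 100,
# with negative branch lengths clamped to zero and the deficit moved onto
# the sibling edge.

#' Build a similarity network
#'
#' One node per sequence (annotated with its type label when available)
#' and one weighted edge per unordered pair whose percent similarity is
#' at least `min_edge` and strictly positive; self-pairs are excluded.
#' The default `min_edge = 0` keeps every positive-similarity pair, so all
#' pairwise relationships enter the network.
#'
#' @param simmatrix a `similarity_matrix` from [all_vs_all()].
#' @param labels optional named character vector (id -> type).
#' @param min_edge minimum similarity for an edge (default 0).
#' @return a `similarity_network`: list with `nodes` (id, type) and
#'   `edges` (id1, id2, weight).
#' @export
build_network <- function(simmatrix, labels = NULL, min_edge = 0) {
  validate_similarity_matrix(simmatrix)
  ids <- simmatrix$ids
  nodes <- data.frame(id = ids,
                      type = if (is.null(labels)) NA_character_ else unname(labels[ids]),
                      stringsAsFactors = FALSE)
  pr <- which(upper.tri(simmatrix$sim), arr.ind = TRUE)
  w <- simmatrix$sim[pr]
  keep <- w > 0 & w >= min_edge
  edges <- data.frame(id1 = ids[pr[keep, 1]], id2 = ids[pr[keep, 2]],
                      weight = w[keep], stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges), class = "similarity_network")
}

#' @export
print.similarity_network <- function(x, ...) {
  cat("similarity_network: ", nrow(x$nodes), " nodes, ", nrow(x$edges),
      " edges\n", sep = "")
  invisible(x)
}

#' Export a network as a tab-separated edge list
#'
#' @param network a `similarity_network`.
#' @param path output path (columns id1, id2, weight).
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(network, path) {
  utils::write.table(network$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Export a network as GraphML
#'
#' Node type labels are carried as a node attribute, edge similarities as
#' the edge weight, for import into Cytoscape or similar viewers.
#'
#' @param network a `similarity_network`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(network, path) {
  g <- igraph::graph_from_data_frame(network$edges, directed = FALSE,
                                     vertices = network$nodes)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Mean within- and between-type similarities
#'
#' For a pair of identical types the mean is taken over unordered distinct
#' within-type pairs; for two different types over all cross pairs. A type
#' with fewer than two members has an undefined within-type mean (NA).
#'
#' @param simmatrix a `similarity_matrix`.
#' @param labels named character vector (id -> type) covering all ids.
#' @return data frame: type_a, type_b, mean_similarity, n_pairs, with one
#'   row per unordered type pair (including within-type rows).
#' @export
cluster_mean_similarity <- function(simmatrix, labels) {
  validate_similarity_matrix(simmatrix)
  ids <- simmatrix$ids
  if (!all(ids %in% names(labels))) {
    stop("labels must cover every id in the similarity matrix")
  }
  lab <- unname(labels[ids])
  types <- sort(unique(lab))
  out <- list()
  for (a in seq_along(types)) for (b in a:length(types)) {
    ta <- types[a]; tb <- types[b]
    ia <- which(lab == ta); ib <- which(lab == tb)
    if (ta == tb) {
      if (length(ia) < 2) {
        vals <- numeric(0)
      } else {
        sub <- simmatrix$sim[ia, ia, drop = FALSE]
        vals <- sub[upper.tri(sub)]
      }
    } else {
      vals <- as.vector(simmatrix$sim[ia, ib, drop = FALSE])
    }
    out[[length(out) + 1]] <- data.frame(
      type_a = ta, type_b = tb,
      mean_similarity = if (length(vals)) mean(vals) else NA_real_,
      n_pairs = length(vals), stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Convert percent similarities to distances
#'
#' d = (100 - similarity) / 100, with the diagonal forced to zero.
#'
#' @param simmatrix a `similarity_matrix`.
#' @return a `distance_matrix`: list with `ids` and symmetric matrix `d`.
#' @export
to_distances <- function(simmatrix) {
  validate_similarity_matrix(simmatrix)
  d <- (100 - simmatrix$sim) / 100
  diag(d) <- 0
  structure(list(ids = simmatrix$ids, d = d), class = "distance_matrix")
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classical Saitou-Nei neighbor joining (Q-criterion agglomeration, as
#' implemented in ape). Negative branch lengths, which NJ can produce on
#' non-additive input, are clamped to zero with the (negative) deficit
#' added to the sibling edge so that the path length between the two
#' siblings is preserved.
#'
#' @param dist a `distance_matrix` (or plain symmetric matrix with
#'   dimnames) over >= 3 taxa.
#' @return an unrooted `ape::phylo` tree with the input ids as tip labels.
#' @export
neighbor_joining <- function(dist) {
  d <- if (inherits(dist, "distance_matrix")) dist$d else as.matrix(dist)
  if (nrow(d) < 3) stop("neighbor joining needs at least 3 taxa")
  if (any(abs(d - t(d)) > 1e-9) || any(diag(d) != 0)) {
    stop("distance matrix must be symmetric with zero diagonal")
  }
  tree <- ape::nj(stats::as.dist(d))
  clamp_negative_branches(tree)
}

#' Clamp negative branch lengths
#'
#' Sets each negative branch length to zero and adds the deficit to the
#' sibling edge (the other edge sharing the same parent node), preserving
#' the path length between the two siblings.
#'
#' @param tree an `ape::phylo` tree.
#' @return the adjusted tree.
#' @export
clamp_negative_branches <- function(tree) {
  el <- tree$edge.length
  if (is.null(el) || all(el >= 0)) return(tree)
  for (e in order(el)) {
    if (tree$edge.length[e] >= 0) next
    parent <- tree$edge[e, 1]
    sibs <- setdiff(which(tree$edge[, 1] == parent), e)
    deficit <- tree$edge.length[e]
    tree$edge.length[e] <- 0
    if (length(sibs) > 0) {
      s <- sibs[1]
      tree$edge.length[s] <- max(0, tree$edge.length[s] + deficit)
    }
  }
  tree
}

#' Neighbor-joining tree with bootstrap support from an alignment
#'
#' Bootstraps operate on a user-supplied fixed multiple alignment (a
#' character matrix or a list of equal-length gapped strings): alignment
#' columns are resampled with replacement, a pairwise p-distance matrix
#' (fraction of mismatching compared columns; columns with a gap in either
#' sequence are skipped) is computed per replicate, an NJ tree is built,
#' and split frequencies are recorded on the tree computed from the
#' original alignment.
#'
#' @param alignment character matrix (rows = sequences, one residue or
#'   "-" per cell, rownames = ids) or named character vector of
#'   equal-length gapped strings.
#' @param n_reps number of bootstrap replicates (default 100).
#' @param seed integer seed for the resampling protocol: replicate r draws
#'   its columns after `set.seed(seed + r)`.
#' @return an `ape::phylo` tree for the full alignment, with
#'   `node.label` holding split support as a fraction of replicates.
#' @export
bootstrap_support <- function(alignment, n_reps = 100, seed = 1) {
  if (is.null(alignment)) {
    stop("bootstrap requires a fixed multiple alignment; supply one ",
         "(character matrix or equal-length gapped strings)")
  }
  aln <- .as_alignment_matrix(alignment)
  if (nrow(aln) < 3) stop("bootstrap needs at least 3 aligned sequences")
  if (n_reps < 1) stop("n_reps must be >= 1")
  main <- neighbor_joining(.p_distance(aln))
  boots <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    set.seed(seed + r)
    cols <- sample.int(ncol(aln), ncol(aln), replace = TRUE)
    boots[[r]] <- neighbor_joining(.p_distance(aln[, cols, drop = FALSE]))
  }
  counts <- ape::prop.clades(main, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0
  main$node.label <- counts / n_reps
  main
}

.as_alignment_matrix <- function(alignment) {
  if (is.matrix(alignment)) return(alignment)
  lens <- nchar(alignment)
  if (length(unique(lens)) != 1) stop("aligned sequences must have equal length")
  m <- do.call(rbind, strsplit(alignment, "", fixed = TRUE))
  rownames(m) <- names(alignment)
  m
}

# pairwise p-distance on an alignment matrix: mismatches / compared
# columns, gap-containing columns skipped per pair; no comparable columns
# gives the maximal distance 1
.p_distance <- function(aln) {
  n <- nrow(aln)
  d <- matrix(0, n, n, dimnames = list(rownames(aln), rownames(aln)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- aln[i, ] != "-" & aln[j, ] != "-"
    d[i, j] <- d[j, i] <- if (any(ok)) mean(aln[i, ok] != aln[j, ok]) else 1
  }
  structure(list(ids = rownames(aln), d = d), class = "distance_matrix")
}

#' Write a tree in Newick format
#'
#' @param tree an `ape::phylo`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
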