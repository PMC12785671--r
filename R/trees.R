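#' Tree building from a distance matrix
#'
#' `neighbor_joining()` runs the Saitou-Nei agglomeration (via
#' \code{ape::\link[ape]{nj}}) and post-processes negative branch lengths:
#' each negative edge is clamped to zero and its deficit transferred to the
#' sister edge so that path lengths around the node are preserved as far as
#' possible. `upgma()` and `ward_cluster()` are average-linkage and Ward
#' minimum-variance agglomerations (via \code{\link[stats]{hclust}} methods
#' `"average"` and `"ward.D2"`), returned as rooted `phylo` dendrograms.
#' Ties in the merge criterion resolve to the lowest-index pair, following
#' `hclust`.
#'
#' @param dm Symmetric distance matrix with ids as dimnames.
#' @return An \code{ape} `phylo` tree; NJ trees are unrooted, UPGMA and Ward
#'   trees rooted. UPGMA trees are ultrametric (equal leaf depths).
#' @export
neighbor_joining <- function(dm) {
  dm <- validate_dist(dm)
  if (nrow(dm) < 3) stop("neighbour-joining needs at least 3 samples")
  tr <- ape::nj(stats::as.dist(dm))
  clamp_negative_edges(tr)
}

# Clamp negative branch lengths to zero, moving the deficit onto the sister
# edge (the other edge sharing the same parent node).
clamp_negative_edges <- function(tr) {
  el <- tr$edge.length
  neg <- which(el < 0)
  for (e in neg) {
    parent <- tr$edge[e, 1]
    sibs <- which(tr$edge[, 1] == parent & seq_along(el) != e)
    if (length(sibs)) {
      s <- sibs[1]
      el[s] <- max(0, el[s] + el[e])
    }
    el[e] <- 0
  }
  tr$edge.length <- el
  tr
}

#' @rdname neighbor_joining
#' @export
upgma <- function(dm) {
  dm <- validate_dist(dm)
  if (nrow(dm) < 2) stop("need at least 2 samples")
  hc <- stats::hclust(stats::as.dist(dm), method = "average")
  ape::as.phylo(hc)
}

#' @rdname neighbor_joining
#' @export
ward_cluster <- function(dm) {
  dm <- validate_dist(dm)
  if (nrow(dm) < 2) stop("need at least 2 samples")
  hc <- stats::hclust(stats::as.dist(dm), method = "ward.D2")
  ape::as.phylo(hc)
}

#' Locus-bootstrap support for a genotype-based tree
#'
#' Resamples loci with replacement, rebuilds the tree for each replicate
#' from the resampled genotype table, and annotates each internal
#' bipartition of the full-data tree with the percentage of replicates in
#' which it occurs. Loci (not individuals) are the resampling unit, the
#' standard choice for multilocus distance trees.
#'
#' @param table A [genotype_table] with at least two loci.
#' @param builder `"nj"`, `"upgma"` or `"ward"`.
#' @param reps Number of bootstrap replicates (>= 1).
#' @param seed Integer seed for the resampling stream.
#' @param rescale_missing Passed to [codominant_distance()].
#' @return The full-data `phylo` tree with `node.label` set to percentage
#'   support values in `[0, 100]` (root label 100).
#' @export
bootstrap_support <- function(table, builder = c("nj", "upgma", "ward"),
                              reps = 100, seed = 1, rescale_missing = FALSE) {
  builder <- match.arg(builder)
  L <- n_loci(table)
  if (L < 2) stop("locus bootstrap needs at least 2 loci")
  if (reps < 1) stop("reps must be >= 1")
  build <- function(tab) {
    dm <- codominant_distance(tab, rescale_missing)
    switch(builder, nj = neighbor_joining(dm), upgma = upgma(dm),
           ward = ward_cluster(dm))
  }
  full <- build(table)
  boots <- with_stream(seed, "tree_bootstrap", {
    lapply(seq_len(reps), function(r) build(subset_table(table, loci = sample.int(L, L, replace = TRUE))))
  })
  rooted <- builder != "nj"
  counts <- ape::prop.clades(full, boots, rooted = rooted)
  supp <- 100 * counts / reps
  supp[is.na(supp)] <- 0
  # the root bipartition (all leaves) is present in every replicate
  supp[1] <- 100
  full$node.label <- supp
  full
}

#' Write / read a tree in Newick format
#'
#' `write_newick()` serialises a `phylo` tree with branch lengths and (when
#' present) internal-node support labels; leaf labels containing spaces,
#' quotes or Newick syntax characters are single-quoted, which the stock
#' \code{ape} writer does not support. `read_newick()` parses with
#' \code{ape::\link[ape]{read.tree}} and strips such quoting so the pair
#' round-trips.
#'
#' @param tree A `phylo` object.
#' @param path Output (input) file path.
#' @return `write_newick()` returns `path` invisibly; `read_newick()` a
#'   `phylo` tree.
#' @export
write_newick <- function(tree, path) {
  txt <- newick_string(tree)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(txt, con)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  tr <- ape::read.tree(path)
  unq <- function(x) {
    q <- grepl("^'.*'$", x)
    x[q] <- gsub("''", "'", substr(x[q], 2, nchar(x[q]) - 1))
    x
  }
  tr$tip.label <- unq(tr$tip.label)
  if (!is.null(tr$node.label)) tr$node.label <- unq(tr$node.label)
  tr
}

quote_label <- function(x) {
  need <- grepl("[][ \t,;:()']", x)
  x[need] <- paste0("'", gsub("'", "''", x[need]), "'")
  x
}

newick_string <- function(tree) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1
  labels <- quote_label(tree$tip.label)
  nlab <- tree$node.label %||% rep("", tree$Nnode)
  nlab <- as.character(nlab)
  nlab[is.na(nlab)] <- ""
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  fmt_len <- function(e) {
    if (is.null(tree$edge.length)) "" else paste0(":", format(tree$edge.length[e], digits = 10))
  }
  rec <- function(node) {
    es <- kids[[as.character(node)]]
    parts <- vapply(es, function(e) {
      child <- tree$edge[e, 2]
      if (child <= ntip) paste0(labels[child], fmt_len(e))
      else paste0(rec(child), nlab[child - ntip], fmt_len(e))
    }, character(1))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  paste0(rec(root), nlab[1], ";")
}
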