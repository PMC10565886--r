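#' Read a rooted phylogeny from a Newick string
#'
#' Thin, validating wrapper around [ape::read.tree()]. Trees are the covariance
#' scaffold for every model in the package, so the reader enforces the
#' invariants those models rely on: a single root, unique tip labels and a
#' branch length on every edge. Zero-length branches are allowed (they occur in
#' published trees); negative lengths are not.
#'
#' @param text a Newick string, e.g. `"((A:1,B:1):1,C:2);"`.
#' @return an object of class `"phylo"` (the \pkg{ape} container used
#'   throughout).
#' @examples
#' tr <- read_newick("((A:1,B:1):1,C:2);")
#' @export
read_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tr) || !inherits(tr, "phylo"))
    stop("malformed Newick string: ", substr(text, 1, 60))
  validate_phylo(tr)
  tr
}

#' Read a sample of trees over an identical tip set
#'
#' One tree per line. All trees must share the same tip label set; this is the
#' container used when analyses are repeated over a posterior sample of trees.
#'
#' @param path file with one Newick string per line (blank lines skipped).
#' @return a `"multiPhylo"` list of validated trees.
#' @export
read_newick_trees <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("no trees in ", path)
  trees <- lapply(lines, read_newick)
  tips <- sort(trees[[1L]]$tip.label)
  for (i in seq_along(trees)) {
    if (!identical(sort(trees[[i]]$tip.label), tips))
      stop("tree ", i, " has a different tip set from tree 1")
  }
  class(trees) <- "multiPhylo"
  trees
}

#' Write a phylogeny as Newick
#' @param tree a `"phylo"` object.
#' @param path optional file; if `NULL` the string is returned.
#' @export
write_newick <- function(tree, path = NULL) {
  txt <- ape::write.tree(tree)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

# Invariant checks shared by every entry point that accepts a tree.
validate_phylo <- function(tree) {
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths; branch lengths are mandatory")
  if (anyNA(tree$edge.length) || length(tree$edge.length) != nrow(tree$edge))
    stop("missing branch length on at least one edge")
  if (any(tree$edge.length < 0))
    stop("negative branch length")
  dup <- tree$tip.label[duplicated(tree$tip.label)]
  if (length(dup))
    stop("duplicate tip label(s): ", paste(unique(dup), collapse = ", "))
  invisible(tree)
}

# Depth of every node (tips and internal) from the root, following edges.
node_depths <- function(tree) {
  n <- length(tree$tip.label)
  root <- n + 1L
  nn <- n + tree$Nnode
  depth <- rep(NA_real_, nn)
  depth[root] <- 0
  # edges in preorder
  ord <- ape::reorder.phylo(tree, "postorder")
  e <- ord$edge[rev(seq_len(nrow(ord$edge))), , drop = FALSE]
  el <- ord$edge.length[rev(seq_len(nrow(ord$edge)))]
  for (i in seq_len(nrow(e))) depth[e[i, 2L]] <- depth[e[i, 1L]] + el[i]
  depth
}

#' Phylogenetic covariance matrix under Brownian motion
#'
#' Entry (i, j) is the shared root-to-MRCA path length of tips i and j, the
#' Brownian-motion trait covariance implied by the tree; the diagonal holds
#' root-to-tip depths.
#'
#' @param tree a `"phylo"` object.
#' @param taxa ordered tip labels to include; defaults to all tips in tree
#'   order. Pruning a tree and then computing the covariance gives exactly the
#'   corresponding submatrix.
#' @return a symmetric positive-semidefinite matrix with `taxa` as dimnames.
#' @export
phylo_covariance <- function(tree, taxa = tree$tip.label) {
  validate_phylo(tree)
  unknown <- setdiff(taxa, tree$tip.label)
  if (length(unknown))
    stop("unknown taxa: ", paste(unknown, collapse = ", "))
  V <- ape::vcv.phylo(tree)
  V[taxa, taxa, drop = FALSE]
}

# Covariance among ALL nodes (tips + internal): depth of the MRCA of each
# pair. Used by the simulator (node ground truth) and ancestral prediction.
phylo_covariance_full <- function(tree) {
  d <- node_depths(tree)
  D <- ape::dist.nodes(tree)
  C <- (outer(d, d, "+") - D) / 2
  # guard tiny negative round-off
  C[C < 0 & C > -1e-12] <- 0
  C
}

#' Prune a phylogeny to a subset of taxa
#'
#' Retained tips keep their root-to-tip depths; internal nodes left with a
#' single child are collapsed with branch lengths summed, so pairwise MRCA
#' depths (and hence the phylogenetic covariance) are unchanged.
#'
#' @param tree a `"phylo"` object.
#' @param taxa tip labels to keep.
#' @export
prune_to_taxa <- function(tree, taxa) {
  keep <- intersect(tree$tip.label, taxa)
  if (length(keep) == 0L) stop("no taxa to keep: empty intersection with tips")
  if (length(keep) == length(tree$tip.label)) return(tree)
  ape::keep.tip(tree, keep)
}

#' Bipartition keys for internal nodes
#'
#' A node's identity across a sample of trees is its set of descendant tip
#' labels. The key is the sorted tip set collapsed with `"|"`, which is stable
#' under node rotations and renumbering.
#'
#' @param tree a `"phylo"` object.
#' @return character vector of keys named by internal node number.
#' @export
node_keys <- function(tree) {
  n <- length(tree$tip.label)
  internal <- n + seq_len(tree$Nnode)
  desc <- descendant_tips(tree)
  keys <- vapply(internal, function(nd)
    paste(sort(tree$tip.label[desc[[nd]]]), collapse = "|"), character(1L))
  names(keys) <- internal
  keys
}

# list: node number -> integer vector of descendant tip indices
descendant_tips <- function(tree) {
  n <- length(tree$tip.label)
  nn <- n + tree$Nnode
  out <- vector("list", nn)
  for (i in seq_len(n)) out[[i]] <- i
  e <- ape::reorder.phylo(tree, "postorder")$edge
  for (i in seq_len(nrow(e))) {
    p <- e[i, 1L]; ch <- e[i, 2L]
    out[[p]] <- c(out[[p]], out[[ch]])
  }
  out
}

#' Match internal nodes across a tree sample by bipartition
#'
#' @param trees a `"multiPhylo"` over one tip set.
#' @return data frame with one row per distinct bipartition key: `key`,
#'   `n_trees` (how many trees contain it) and a list-column `node` giving the
#'   per-tree node number (`NA` where absent).
#' @export
node_correspondence <- function(trees) {
  stopifnot(length(trees) >= 1L)
  keysets <- lapply(trees, node_keys)
  all_keys <- unique(unlist(keysets, use.names = FALSE))
  node <- matrix(NA_integer_, nrow = length(all_keys), ncol = length(trees),
                 dimnames = list(all_keys, NULL))
  for (j in seq_along(keysets)) {
    ks <- keysets[[j]]
    node[match(ks, all_keys), j] <- as.integer(names(ks))
  }
  data.frame(key = all_keys,
             n_trees = rowSums(!is.na(node)),
             node = I(lapply(seq_along(all_keys), function(i) node[i, ])),
             stringsAsFactors = FALSE)
}
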