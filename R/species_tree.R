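#' Species tree with stable branch identifiers
#'
#' Wraps a rooted binary [ape::phylo] tree and attaches a stable integer id to
#' every branch, including the root stem (the edge above the root node, held
#' in `phylo$root.edge`). Branch ids are the reporting unit for birth/death
#' event ledgers: an event "on branch b" happened on the edge leading into
#' the node that `b` identifies.
#'
#' Every branch is identified by the node it leads into, so the root stem is
#' identified by the root node itself. If `branch_ids` is not supplied, ids
#' are assigned in preorder starting from the root stem (id 1).
#'
#' @param phy A rooted `phylo` object with unique tip labels and non-negative
#'   branch lengths. A `root.edge` is optional but required for placing
#'   events above the crown node (outgroup polarity).
#' @param branch_ids Optional data frame with columns `node` (node number in
#'   `phy`) and `branch_id` (unique integers). Must cover every node,
#'   including the root.
#' @return An object of class `species_tree`: a list with elements `phy`
#'   (the tree) and `branch_ids` (node to id map).
#' @examples
#' tr <- species_tree(ape::read.tree(text = "((A:1,B:1):1,C:2):1;"))
#' tr$branch_ids
#' @export
species_tree <- function(phy, branch_ids = NULL) {
  if (!inherits(phy, "phylo")) stop("'phy' must be an ape 'phylo' object")
  if (!ape::is.rooted(phy)) stop("species tree must be rooted")
  if (anyDuplicated(phy$tip.label)) stop("tip labels must be unique")
  if (is.null(phy$edge.length)) stop("species tree must have branch lengths")
  if (any(phy$edge.length < 0)) stop("branch lengths must be >= 0")

  ntip <- length(phy$tip.label)
  root <- ntip + 1L
  nodes <- c(root, preorder_nodes(phy))

  if (is.null(branch_ids)) {
    branch_ids <- data.frame(node = nodes, branch_id = seq_along(nodes))
  } else {
    if (!all(c("node", "branch_id") %in% names(branch_ids)))
      stop("'branch_ids' needs columns 'node' and 'branch_id'")
    if (anyDuplicated(branch_ids$branch_id))
      stop("branch ids must be unique")
    if (!setequal(branch_ids$node, nodes))
      stop("'branch_ids' must cover every node of the tree exactly once")
  }
  structure(list(phy = phy, branch_ids = branch_ids), class = "species_tree")
}

#' @export
print.species_tree <- function(x, ...) {
  cat("Species tree with", length(x$phy$tip.label), "tips and",
      nrow(x$branch_ids), "identified branches\n")
  invisible(x)
}

# child nodes of all edges in preorder (root stem excluded)
preorder_nodes <- function(phy) {
  phy <- ape::reorder.phylo(phy, "cladewise")
  phy$edge[, 2]
}

#' Map between nodes and branch ids
#'
#' @param tree A [species_tree()].
#' @param node Node number(s).
#' @return `branch_of_node()` gives the branch id of the edge leading into
#'   `node`; `node_of_branch()` inverts it.
#' @export
branch_of_node <- function(tree, node) {
  idx <- match(node, tree$branch_ids$node)
  if (anyNA(idx)) stop("unknown node: ", paste(node[is.na(idx)], collapse = ", "))
  tree$branch_ids$branch_id[idx]
}

#' @rdname branch_of_node
#' @param branch_id Branch id(s).
#' @export
node_of_branch <- function(tree, branch_id) {
  idx <- match(branch_id, tree$branch_ids$branch_id)
  if (anyNA(idx))
    stop("unknown branch id: ", paste(branch_id[is.na(idx)], collapse = ", "))
  tree$branch_ids$node[idx]
}

#' Most recent common ancestor node of a set of tips
#'
#' @param tree A [species_tree()].
#' @param tips Character vector of tip labels (length >= 1).
#' @return Node number; for a single tip, the tip node itself.
#' @export
mrca_node <- function(tree, tips) {
  phy <- tree$phy
  idx <- match(tips, phy$tip.label)
  if (anyNA(idx)) stop("unknown tips: ", paste(tips[is.na(idx)], collapse = ", "))
  if (length(idx) == 1L) return(idx)
  ape::getMRCA(phy, idx)
}

#' Tips descending from a node
#'
#' @inheritParams branch_of_node
#' @return Character vector of tip labels below `node` (the node itself if a
#'   tip).
#' @export
tips_below <- function(tree, node) {
  phy <- tree$phy
  ntip <- length(phy$tip.label)
  if (node <= ntip) return(phy$tip.label[node])
  kids <- phy$edge[phy$edge[, 1] == node, 2]
  unlist(lapply(kids, function(k) tips_below(tree, k)), use.names = FALSE)
}

# children of a node (numeric(0) for tips)
node_children <- function(tree, node) {
  tree$phy$edge[tree$phy$edge[, 1] == node, 2]
}

# length of the branch leading into a node (root stem -> root.edge)
branch_length_into <- function(tree, node) {
  phy <- tree$phy
  root <- length(phy$tip.label) + 1L
  if (node == root) {
    if (is.null(phy$root.edge)) return(0)
    return(phy$root.edge)
  }
  phy$edge.length[match(node, phy$edge[, 2])]
}
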