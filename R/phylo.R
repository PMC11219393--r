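#' Tamura-Nei (1993) distance between two aligned sequences
#'
#' Closed-form TN93 estimate of substitutions per site, computed from the
#' two transition proportions (A/G and C/T), the transversion proportion,
#' and base frequencies estimated empirically from the pair's retained
#' sites. Sites where either sequence carries a gap or any non-A/C/G/T
#' code are excluded for this pair only (pairwise deletion; ambiguity codes
#' are excluded along with gaps).
#'
#' Saturated pairs (any logarithm argument at or below zero) and degenerate
#' pairs (a base class with zero frequency) yield `NaN`, which downstream
#' tree building refuses unless the caller substitutes a ceiling.
#'
#' @param a,b Aligned sequences of equal length (strings or base vectors).
#' @return Estimated substitutions per site (`NaN` when undefined).
#' @export
tn93_distance <- function(a, b) {
  x <- as_base_vector(a)
  y <- as_base_vector(b)
  if (length(x) != length(y)) stop("sequences must be aligned (equal length)")
  ok <- x %in% c("A", "C", "G", "T") & y %in% c("A", "C", "G", "T")
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n == 0) return(NaN)
  freq <- (table(factor(x, levels = c("A", "C", "G", "T"))) +
           table(factor(y, levels = c("A", "C", "G", "T")))) / (2 * n)
  gA <- freq[["A"]]; gC <- freq[["C"]]; gG <- freq[["G"]]; gT <- freq[["T"]]
  gR <- gA + gG
  gY <- gC + gT
  P1 <- sum((x == "A" & y == "G") | (x == "G" & y == "A")) / n
  P2 <- sum((x == "C" & y == "T") | (x == "T" & y == "C")) / n
  Q <- sum(x != y) / n - P1 - P2
  if (gR == 0 || gY == 0 || gA * gG == 0 || gC * gT == 0) return(NaN)
  w1 <- 1 - gR / (2 * gA * gG) * P1 - Q / (2 * gR)
  w2 <- 1 - gY / (2 * gC * gT) * P2 - Q / (2 * gY)
  w3 <- 1 - Q / (2 * gR * gY)
  if (w1 <= 0 || w2 <= 0 || w3 <= 0) return(NaN)
  -2 * gA * gG / gR * log(w1) -
    2 * gC * gT / gY * log(w2) -
    2 * (gR * gY - gA * gG * gY / gR - gC * gT * gR / gY) * log(w3)
}

#' Pairwise TN93 distance matrix of an alignment
#'
#' @param aln Named list/vector of aligned sequences (equal length).
#' @return Symmetric numeric matrix with zero diagonal; saturated pairs are
#'   `NaN` and reported via the `"n_saturated"` attribute.
#' @export
tn93_matrix <- function(aln) {
  aln <- lapply(aln, as_base_vector)
  n <- length(aln)
  labels <- names(aln)
  if (is.null(labels)) labels <- paste0("seq", seq_len(n))
  D <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    D[i, j] <- D[j, i] <- tn93_distance(aln[[i]], aln[[j]])
  attr(D, "n_saturated") <- sum(!is.finite(D[upper.tri(D)]))
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Canonical Saitou-Nei agglomeration: at each step the pair minimizing the
#' Q-criterion is joined, with ties broken by the lowest label-index pair
#' (row-major). Negative branch-length estimates are clamped to zero.
#'
#' @param D Square symmetric matrix of finite distances (labels as
#'   dimnames), n >= 3.
#' @return An unrooted [ape::phylo] tree.
#' @export
nj_tree <- function(D) {
  if (!is.matrix(D) || nrow(D) != ncol(D)) stop("'D' must be square")
  if (any(!is.finite(D))) stop("non-finite distances; resolve saturation first")
  n <- nrow(D)
  if (n < 3) stop("need at least 3 taxa")
  labels <- rownames(D)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))

  # node bookkeeping: tips 1..n, internal nodes appended
  active <- seq_len(n)            # current cluster -> node id
  node_count <- n
  edges <- matrix(0L, 0, 2)
  lens <- numeric(0)
  Dm <- D

  while (length(active) > 3) {
    m <- nrow(Dm)
    R <- rowSums(Dm)
    Qc <- (m - 2) * Dm - outer(R, R, "+")
    diag(Qc) <- Inf
    best <- which(Qc == min(Qc), arr.ind = TRUE)
    best <- best[best[, 1] < best[, 2], , drop = FALSE]
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
    i <- best[1]; j <- best[2]
    li <- Dm[i, j] / 2 + (R[i] - R[j]) / (2 * (m - 2))
    lj <- Dm[i, j] - li
    node_count <- node_count + 1L
    u <- node_count
    edges <- rbind(edges, c(u, active[i]), c(u, active[j]))
    lens <- c(lens, max(li, 0), max(lj, 0))
    du <- (Dm[i, ] + Dm[j, ] - Dm[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    Dm2 <- rbind(cbind(Dm[keep, keep, drop = FALSE], du[keep]),
                 c(du[keep], 0))
    Dm <- Dm2
    active <- c(active[keep], u)
  }
  # final three clusters join at one internal node
  node_count <- node_count + 1L
  u <- node_count
  l1 <- (Dm[1, 2] + Dm[1, 3] - Dm[2, 3]) / 2
  l2 <- (Dm[1, 2] + Dm[2, 3] - Dm[1, 3]) / 2
  l3 <- (Dm[1, 3] + Dm[2, 3] - Dm[1, 2]) / 2
  edges <- rbind(edges, c(u, active[1]), c(u, active[2]), c(u, active[3]))
  lens <- c(lens, max(l1, 0), max(l2, 0), max(l3, 0))

  # renumber internal nodes to ape convention (root = ntip + 1, here the
  # last-created node, then the others in reverse creation order)
  internal <- sort(unique(edges[edges > n]))
  remap <- integer(max(internal))
  remap[u] <- n + 1L
  others <- setdiff(internal, u)
  remap[others] <- n + 1L + seq_along(others)
  e2 <- edges
  e2[e2 > n] <- remap[e2[e2 > n]]
  phy <- list(edge = e2, edge.length = lens, tip.label = labels,
              Nnode = length(internal))
  class(phy) <- "phylo"
  ape::reorder.phylo(phy, "cladewise")
}

# leaf bipartition keys of the internal edges of an unrooted tree
split_keys <- function(phy) {
  ntip <- length(phy$tip.label)
  keys <- character(0)
  nodes <- integer(0)
  for (k in seq_len(nrow(phy$edge))) {
    child <- phy$edge[k, 2]
    if (child <= ntip) next
    tips <- phy$tip.label[clade_tips(phy, child)]
    other <- setdiff(phy$tip.label, tips)
    if (length(tips) < 2 || length(other) < 2) next  # trivial split
    side <- if (phy$tip.label[1] %in% tips) other else tips
    keys <- c(keys, paste(sort(side), collapse = "|"))
    nodes <- c(nodes, child)
  }
  data.frame(node = nodes, key = keys, stringsAsFactors = FALSE)
}

clade_tips <- function(phy, node) {
  ntip <- length(phy$tip.label)
  if (node <= ntip) return(node)
  kids <- phy$edge[phy$edge[, 1] == node, 2]
  unlist(lapply(kids, clade_tips, phy = phy))
}

#' Nonparametric bootstrap support for a neighbor-joining gene tree
#'
#' Resamples alignment columns with replacement, rebuilds the TN93 + NJ
#' tree for each replicate, and reports for every internal bipartition of
#' the full-data tree the fraction of replicates containing it. Support is
#' mapped onto the full-data tree (no consensus topology is formed).
#' Replicates in which any pairwise distance is saturated are dropped and
#' counted.
#'
#' @param aln Named list of aligned sequences (>= 4 taxa).
#' @param replicates Number of bootstrap replicates.
#' @param seed Integer seed (mandatory).
#' @return The full-data [ape::phylo] tree with `node.label` holding
#'   integer percent support; attributes `"support"` (named fractions) and
#'   `"dropped_replicates"`.
#' @export
bootstrap_support <- function(aln, replicates = 1000, seed) {
  if (missing(seed)) stop("'seed' is mandatory")
  aln <- lapply(aln, as_base_vector)
  D <- tn93_matrix(aln)
  if (any(!is.finite(D))) stop("saturated distances in the full alignment")
  tree <- nj_tree(D)
  base <- split_keys(tree)
  if (replicates == 0) return(tree)

  set.seed(as.integer(seed))
  L <- length(aln[[1]])
  counts <- stats::setNames(rep(0L, nrow(base)), base$key)
  dropped <- 0L
  for (r in seq_len(replicates)) {
    idx <- sample.int(L, L, replace = TRUE)
    rs <- lapply(aln, function(s) s[idx])
    Dr <- tn93_matrix(rs)
    if (any(!is.finite(Dr))) {
      dropped <- dropped + 1L
      next
    }
    rk <- split_keys(nj_tree(Dr))$key
    hit <- base$key %in% rk
    counts[hit] <- counts[hit] + 1L
  }
  valid <- replicates - dropped
  support <- if (valid > 0) counts / valid else counts * NA_real_
  ntip <- length(tree$tip.label)
  labs <- rep("", tree$Nnode)
  labs[base$node - ntip] <- as.character(round(100 * support))
  tree$node.label <- labs
  attr(tree, "support") <- support
  attr(tree, "dropped_replicates") <- dropped
  tree
}

#' Proportion of differing sites (p-distance), pairwise deletion
#'
#' @inheritParams tn93_distance
#' @return Proportion in `[0, 1]`.
#' @export
p_distance <- function(a, b) {
  x <- as_base_vector(a)
  y <- as_base_vector(b)
  ok <- x %in% c("A", "C", "G", "T") & y %in% c("A", "C", "G", "T")
  mean(x[ok] != y[ok])
}
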