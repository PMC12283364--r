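#' Rooted colony tree with per-branch mutation annotation
#'
#' `colony_tree` is the package's central container: a rooted tree whose
#' tips are single-cell-derived colonies and whose root is the zygote
#' (ancestral all-absent genotype). Every node except the root identifies
#' the branch above it, so branches are indexed by their child node.
#' Branch lengths are carried in up to four channels: `raw_length`
#' (assigned mutation count), `corrected_length` (sensitivity-corrected),
#' `ultrametric_length` (after root-to-tip normalisation) and `time_span`
#' (years, after molecular-clock scaling).
#'
#' Internally the topology is a parent-pointer vector: tips are nodes
#' `1..n_tips`, internal nodes follow, and `parent[root] == 0`.
#'
#' @param parent Integer vector of parent node ids (0 for the root).
#' @param n_tips Number of tip nodes (nodes `1..n_tips`).
#' @param tip_labels Character vector of colony ids for tips.
#' @param node_age Optional numeric vector of node ages in years
#'   (root at the earliest age, tips at the sampling age).
#'
#' @return An object of class `colony_tree`.
#' @export
colony_tree <- function(parent, n_tips, tip_labels = as.character(seq_len(n_tips)),
                        node_age = NULL) {
  parent <- as.integer(parent)
  n_nodes <- length(parent)
  root <- which(parent == 0L)
  if (length(root) != 1L) stop("tree must have exactly one root")
  if (length(tip_labels) != n_tips) stop("tip_labels length must equal n_tips")
  # connectivity/acyclicity: every node must reach the root
  for (v in seq_len(n_nodes)) {
    u <- v
    steps <- 0L
    while (u != root) {
      u <- parent[u]
      steps <- steps + 1L
      if (steps > n_nodes) stop("cycle detected in parent vector")
    }
  }
  branch_nodes <- setdiff(seq_len(n_nodes), root)
  branch <- data.frame(
    node = branch_nodes,
    parent = parent[branch_nodes],
    raw_length = NA_real_,
    corrected_length = NA_real_,
    ultrametric_length = NA_real_,
    time_span = NA_real_,
    t_start = NA_real_,
    t_end = NA_real_
  )
  structure(
    list(
      parent = parent, n_tips = as.integer(n_tips), root = root,
      tip_labels = tip_labels, node_age = node_age,
      branch = branch,
      mutations = stats::setNames(
        replicate(length(branch_nodes), character(0), simplify = FALSE),
        as.character(branch_nodes)
      )
    ),
    class = "colony_tree"
  )
}

#' @export
print.colony_tree <- function(x, ...) {
  cat("colony_tree:", x$n_tips, "tips,", length(x$parent), "nodes\n")
  chans <- c("raw_length", "corrected_length", "ultrametric_length", "time_span")
  have <- chans[vapply(chans, function(ch) any(!is.na(x$branch[[ch]])), logical(1))]
  cat("  length channels set:", if (length(have)) paste(have, collapse = ", ") else "none", "\n")
  invisible(x)
}

#' Children lists for every node
#' @keywords internal
tree_children <- function(tree) {
  ch <- vector("list", length(tree$parent))
  for (v in seq_along(tree$parent)) {
    p <- tree$parent[v]
    if (p != 0L) ch[[p]] <- c(ch[[p]], v)
  }
  ch
}

#' Postorder traversal (children before parents)
#' @keywords internal
tree_postorder <- function(tree) {
  n <- length(tree$parent)
  order <- integer(0)
  stack <- tree$root
  ch <- tree_children(tree)
  # iterative reverse-preorder gives postorder when reversed
  pre <- integer(0)
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    pre <- c(pre, v)
    stack <- c(stack, ch[[v]])
  }
  rev(pre)
}

#' Tip sets subtended by every node
#'
#' @return List indexed by node id of integer tip-id vectors.
#' @keywords internal
tree_tip_sets <- function(tree) {
  sets <- vector("list", length(tree$parent))
  ch <- tree_children(tree)
  for (v in tree_postorder(tree)) {
    if (v <= tree$n_tips) {
      sets[[v]] <- v
    } else {
      sets[[v]] <- sort(unlist(lapply(ch[[v]], function(c) sets[[c]])))
    }
  }
  sets
}

#' Depth of every node (edges from the root)
#' @keywords internal
tree_depths <- function(tree) {
  d <- integer(length(tree$parent))
  for (v in rev(tree_postorder(tree))) { # preorder
    d[v] <- if (v == tree$root) 0L else d[tree$parent[v]] + 1L
  }
  d
}

#' Convert a colony_tree to an ape "phylo" object
#'
#' @param tree A `colony_tree`.
#' @param length_channel Which branch-length channel to export, one of
#'   `"raw_length"`, `"corrected_length"`, `"ultrametric_length"`,
#'   `"time_span"`.
#' @return An [ape::as.phylo] compatible `phylo` object with internal node
#'   labels `"node<k>"` keyed by the colony_tree node ids.
#' @export
as_phylo <- function(tree, length_channel = "raw_length") {
  stopifnot(inherits(tree, "colony_tree"))
  n <- tree$n_tips
  internal <- setdiff(seq_along(tree$parent), seq_len(n))
  # ape wants root = n+1; build a relabelling
  relab <- integer(length(tree$parent))
  relab[seq_len(n)] <- seq_len(n)
  relab[tree$root] <- n + 1L
  rest <- setdiff(internal, tree$root)
  relab[rest] <- n + 1L + seq_along(rest)
  edge_child <- tree$branch$node
  edge <- cbind(relab[tree$branch$parent], relab[edge_child])
  lens <- tree$branch[[length_channel]]
  phy <- list(
    edge = edge,
    edge.length = if (all(is.na(lens))) NULL else lens,
    Nnode = length(internal),
    tip.label = tree$tip_labels,
    node.label = paste0("node", c(tree$root, rest))
  )
  class(phy) <- "phylo"
  phy <- ape::reorder.phylo(phy, "cladewise")
  phy
}

#' Write a colony_tree to a Newick file
#'
#' @inheritParams as_phylo
#' @param path Output file path.
#' @export
write_colony_tree <- function(tree, path, length_channel = "raw_length") {
  ape::write.tree(as_phylo(tree, length_channel), file = path)
  invisible(path)
}

#' Root-to-node distance for a given length channel
#' @keywords internal
tree_node_distances <- function(tree, channel = "corrected_length") {
  d <- numeric(length(tree$parent))
  lens <- stats::setNames(tree$branch[[channel]], tree$branch$node)
  for (v in rev(tree_postorder(tree))) {
    if (v == tree$root) d[v] <- 0 else d[v] <- d[tree$parent[v]] + lens[[as.character(v)]]
  }
  d
}
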