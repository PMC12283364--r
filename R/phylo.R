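## Maximum-parsimony reconstruction of colony phylogenies from binary
## somatic genotype matrices. Trees are rooted at the zygote (ancestral
## all-absent state), so no outgroup is needed; unknown genotypes are
## uninformative in both scoring and assignment.

# State masks: 1 = {absent}, 2 = {present}, 3 = {absent, present} (unknown).
calls_to_masks <- function(calls) {
  m <- matrix(3L, nrow(calls), ncol(calls))
  m[calls == 0L] <- 1L
  m[calls == 1L] <- 2L
  m # variants x tips
}

postorder_parent <- function(parent, root) {
  n <- length(parent)
  kids <- vector("list", n)
  for (v in seq_len(n)) {
    p <- parent[v]
    if (p != 0L) kids[[p]] <- c(kids[[p]], v)
  }
  pre <- integer(0)
  stack <- root
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    pre <- c(pre, v)
    stack <- c(stack, kids[[v]])
  }
  list(order = rev(pre), children = kids)
}

# Vectorised exact small-parsimony score across all characters at once,
# with the root constrained to the absent state. Two-state Sankoff
# dynamic programming is used rather than the set-based Fitch pass: the
# classic "unions + 1 if the root set lacks the root state" adjustment is
# only a lower bound on a zygote-rooted tree (it implicitly allows a free
# change on a stem branch above the MRCA, which this tree has no room
# for), whereas the DP is exact for any topology including
# multifurcations and ambiguous tips.
# tip_masks: tips x variants matrix of state masks.
fitch_score_masks <- function(parent, root, n_tips, tip_masks) {
  po <- postorder_parent(parent, root)
  n_nodes <- length(parent)
  n_var <- ncol(tip_masks)
  big <- 1e9
  c0 <- matrix(0, n_nodes, n_var) # min changes in subtree given node = 0
  c1 <- matrix(0, n_nodes, n_var)
  c0[seq_len(n_tips), ] <- ifelse(bitwAnd(tip_masks, 1L) > 0L, 0, big)
  c1[seq_len(n_tips), ] <- ifelse(bitwAnd(tip_masks, 2L) > 0L, 0, big)
  for (v in po$order) {
    kids <- po$children[[v]]
    if (!length(kids)) next
    s0 <- numeric(n_var)
    s1 <- numeric(n_var)
    for (k in kids) {
      s0 <- s0 + pmin(c0[k, ], c1[k, ] + 1)
      s1 <- s1 + pmin(c1[k, ], c0[k, ] + 1)
    }
    c0[v, ] <- pmin(s0, big)
    c1[v, ] <- pmin(s1, big)
  }
  c0[root, ]
}

#' Small-parsimony score of one character on a zygote-rooted tree
#'
#' Minimum number of 0<->1 changes needed to explain per-tip states on the
#' given topology, with the root fixed at the ancestral absent state
#' (exact two-state dynamic programme; see the note on
#' [fitch_score_masks] internals for why the set-based Fitch shortcut is
#' not used). Unknown tips impose no constraint.
#'
#' @param tree A [colony_tree] (topology only is used).
#' @param tip_states Integer/logical vector over tips in tip order:
#'   1 = present, 0 = absent, NA = unknown.
#' @return Integer change count.
#' @export
fitch_score <- function(tree, tip_states) {
  stopifnot(inherits(tree, "colony_tree"), length(tip_states) == tree$n_tips)
  if (all(is.na(tip_states))) {
    warning("character is all-unknown; score 0")
    return(0L)
  }
  tm <- calls_to_masks(matrix(as.integer(tip_states), nrow = 1L))
  as.integer(fitch_score_masks(tree$parent, tree$root, tree$n_tips, t(tm)))
}

#' Total parsimony score of a genotype matrix on a topology
#'
#' @param tree A [colony_tree].
#' @param gm A [genotype_matrix()] (columns must match tip order).
#' @return Integer: summed Fitch score over all variant rows.
#' @export
parsimony_score <- function(tree, gm) {
  tm <- calls_to_masks(gm$calls)
  sum(fitch_score_masks(tree$parent, tree$root, tree$n_tips, t(tm)))
}

# Enumerate all rooted binary topologies on n labelled tips as
# (parent vector, root) pairs: tips 1..n, internal node for the k-th added
# tip is n + k - 1. There are (2n-3)!! such trees.
all_rooted_topologies <- function(n) {
  stopifnot(n >= 2)
  res <- list()
  recurse <- function(parent, root, next_tip) {
    if (next_tip > n) {
      res[[length(res) + 1L]] <<- list(parent = parent, root = root)
      return(invisible(NULL))
    }
    m <- n + next_tip - 1L # new internal node id
    present <- c(seq_len(next_tip - 1L), (n + 1L):(n + next_tip - 2L))
    for (c_node in present) {
      p2 <- parent
      if (c_node == root) {
        p2[m] <- 0L
        p2[root] <- m
        p2[next_tip] <- m
        recurse(p2, m, next_tip + 1L)
      } else {
        p2[m] <- p2[c_node]
        p2[c_node] <- m
        p2[next_tip] <- m
        recurse(p2, root, next_tip + 1L)
      }
    }
  }
  parent0 <- integer(2L * n - 1L)
  parent0[1L] <- parent0[2L] <- n + 1L
  recurse(parent0, n + 1L, 3L)
  res
}

# Canonical string form of a topology (sorted nested tip labels); used as
# the deterministic tie-break between equally parsimonious trees.
canonical_topology <- function(parent, root, n_tips, labels = as.character(seq_len(n_tips))) {
  po <- postorder_parent(parent, root)
  rep_of <- character(length(parent))
  for (v in po$order) {
    kids <- po$children[[v]]
    if (!length(kids)) {
      rep_of[v] <- labels[v]
    } else {
      rep_of[v] <- paste0("(", paste(sort(rep_of[kids]), collapse = ","), ")")
    }
  }
  rep_of[root]
}

# Subtree-prune-and-regraft neighbours of a rooted binary tree: detach the
# subtree above node v (its parent p is suppressed) and reinsert p on every
# edge outside the subtree, or above the root. Includes all NNI moves.
spr_moves <- function(parent, root, n_tips) {
  moves <- list()
  n_nodes <- length(parent)
  subtree_of <- function(v) {
    out <- v
    repeat {
      kids <- which(parent %in% out & !(seq_len(n_nodes) %in% out))
      if (!length(kids)) break
      out <- c(out, kids)
    }
    out
  }
  for (v in seq_len(n_nodes)) {
    p <- parent[v]
    if (p == 0L) next # cannot prune at the root
    sib <- setdiff(which(parent == p), v)
    if (length(sib) != 1L) next # only binary nodes are suppressed
    s <- sib
    gp <- parent[p]
    sub <- subtree_of(v)
    # prune the subtree at v, suppressing its parent p
    base <- parent
    base[s] <- gp
    base[p] <- 0L
    new_root <- if (gp == 0L) s else root
    # regraft p on any edge outside the subtree (c_node == s recreates
    # the current tree, so it is skipped)
    cand <- setdiff(seq_len(n_nodes), c(sub, p, s))
    for (c_node in cand) {
      p2 <- base
      r2 <- new_root
      if (c_node == r2) {
        p2[p] <- 0L
        p2[c_node] <- p
        p2[v] <- p
        r2 <- p
      } else {
        p2[p] <- p2[c_node]
        p2[c_node] <- p
        p2[v] <- p
      }
      moves[[length(moves) + 1L]] <- list(parent = p2, root = r2)
    }
  }
  moves
}

# Nearest-neighbour interchange neighbours of a rooted binary tree around
# internal edge (p -> v): swap one child of v with v's sibling.
nni_moves <- function(parent, root, n_tips) {
  moves <- list()
  internal <- setdiff(seq_along(parent), seq_len(n_tips))
  for (v in internal) {
    p <- parent[v]
    if (p == 0L) next # v is root
    sib <- setdiff(which(parent == p), v)
    kids <- which(parent == v)
    for (a in kids) {
      for (s in sib) {
        p2 <- parent
        p2[a] <- p
        p2[s] <- v
        moves[[length(moves) + 1L]] <- p2
      }
    }
  }
  moves
}

#' Reconstruct a rooted maximum-parsimony colony phylogeny
#'
#' Minimises the total Fitch score of the somatic genotype matrix over
#' rooted binary topologies. For `n_tips <= max_exhaustive_tips` every
#' rooted topology is scored (the global optimum is returned); for larger
#' trees a deterministic heuristic is used: stepwise addition with
#' colonies ordered by somatic burden (descending, ties by label),
#' nearest-neighbour-interchange and subtree-prune-regraft hill climbing,
#' then a parsimony ratchet (`ratchet_iterations` rounds of character
#' reweighting with SPR descent, seeded by `search_seed`) to escape local
#' optima on homoplasy-rich data. Ties in the exhaustive search resolve
#' to the lexicographically smallest canonical topology, so results are
#' reproducible.
#'
#' @param gm A [genotype_matrix()] of somatic calls (provenance "kept"
#'   rows are used).
#' @param max_exhaustive_tips Exhaustive-search cut-over (default 8).
#' @param ratchet_iterations Reweighting rounds in the heuristic search
#'   (default 10; 0 disables the ratchet).
#' @param search_seed Integer seed for the ratchet perturbations; the
#'   caller's random-number state is left untouched.
#' @return A [colony_tree] with mutations assigned to branches via
#'   [assign_mutations()] and `parsimony_score` attribute set.
#' @export
reconstruct_tree <- function(gm, max_exhaustive_tips = 8L,
                             ratchet_iterations = 10L, search_seed = 1L) {
  stopifnot(inherits(gm, "genotype_matrix"))
  gm <- somatic_genotypes(gm)
  labels <- colnames(gm$calls)
  n <- length(labels)
  if (n < 3) {
    warning("fewer than 3 colonies; returning degenerate star tree")
    parent <- c(rep(n + 1L, n), 0L)
    tree <- colony_tree(parent, n, labels)
    return(assign_mutations(tree, gm))
  }
  tip_masks <- t(calls_to_masks(gm$calls)) # tips x variants
  # collapse identical genotype patterns: parsimony is additive over
  # characters, so score unique patterns once and weight by multiplicity
  pat_key <- apply(tip_masks, 2L, paste, collapse = "")
  uniq <- !duplicated(pat_key)
  pat_w <- as.numeric(table(factor(pat_key, levels = pat_key[uniq])))
  pat_masks <- tip_masks[, uniq, drop = FALSE]
  score_of <- function(parent, root) {
    sum(pat_w * fitch_score_masks(parent, root, n, pat_masks))
  }

  if (n <= max_exhaustive_tips) {
    topos <- all_rooted_topologies(n)
    best <- NULL
    best_score <- Inf
    best_canon <- NULL
    for (tp in topos) {
      s <- score_of(tp$parent, tp$root)
      if (s < best_score) {
        best <- tp
        best_score <- s
        best_canon <- canonical_topology(tp$parent, tp$root, n, labels)
      } else if (s == best_score) {
        cn <- canonical_topology(tp$parent, tp$root, n, labels)
        if (cn < best_canon) {
          best <- tp
          best_canon <- cn
        }
      }
    }
    parent <- best$parent
    root <- best$root
  } else {
    burden <- colSums(gm$calls == 1L, na.rm = TRUE)
    ord <- order(-burden, labels)
    # stepwise addition over tips in burden order
    parent <- integer(2L * n - 1L)
    root <- n + 1L
    parent[ord[1L]] <- parent[ord[2L]] <- root
    added <- ord[1:2]
    for (k in 3:n) {
      tip <- ord[k]
      m <- n + k - 1L
      cand_nodes <- c(added, (n + 1L):(n + k - 2L))
      best_p <- NULL
      best_root <- root
      best_s <- Inf
      for (c_node in cand_nodes) {
        p2 <- parent
        r2 <- root
        if (c_node == root) {
          p2[m] <- 0L
          p2[root] <- m
          p2[tip] <- m
          r2 <- m
        } else {
          p2[m] <- p2[c_node]
          p2[c_node] <- m
          p2[tip] <- m
        }
        s <- score_of(p2, r2)
        if (s < best_s) {
          best_p <- p2
          best_root <- r2
          best_s <- s
        }
      }
      parent <- best_p
      root <- best_root
      added <- c(added, tip)
    }
    # NNI hill climbing (cheap), SPR refinement, then a parsimony ratchet
    weighted_score <- function(p, r, w) {
      sum(w * fitch_score_masks(p, r, n, pat_masks))
    }
    nni_descend <- function(parent, root, w) {
      cur <- weighted_score(parent, root, w)
      repeat {
        improved <- FALSE
        for (p2 in nni_moves(parent, root, n)) {
          s <- weighted_score(p2, root, w)
          if (s < cur) {
            parent <- p2
            cur <- s
            improved <- TRUE
            break
          }
        }
        if (!improved) break
      }
      list(parent = parent, root = root, score = cur)
    }
    spr_descend <- function(parent, root, w) {
      cur <- weighted_score(parent, root, w)
      repeat {
        improved <- FALSE
        for (mv in spr_moves(parent, root, n)) {
          s <- weighted_score(mv$parent, mv$root, w)
          if (s < cur) {
            parent <- mv$parent
            root <- mv$root
            cur <- s
            improved <- TRUE
            break
          }
        }
        if (!improved) break
      }
      list(parent = parent, root = root, score = cur)
    }
    cur <- nni_descend(parent, root, pat_w)
    cur <- spr_descend(cur$parent, cur$root, pat_w)
    if (ratchet_iterations > 0) {
      old_seed <- if (exists(".Random.seed", envir = globalenv())) {
        get(".Random.seed", envir = globalenv())
      }
      set.seed(as.integer(search_seed))
      for (it in seq_len(ratchet_iterations)) {
        # upweight a random ~30% of the character mass, descend under the
        # perturbed weights, then re-descend under the true weights
        extra <- stats::rmultinom(
          1, max(1, round(0.3 * sum(pat_w))), pat_w / sum(pat_w)
        )[, 1]
        pert <- spr_descend(cur$parent, cur$root, pat_w + extra)
        re <- spr_descend(pert$parent, pert$root, pat_w)
        if (re$score < cur$score) cur <- re
      }
      if (!is.null(old_seed)) {
        assign(".Random.seed", old_seed, envir = globalenv())
      }
    }
    parent <- cur$parent
    root <- cur$root
  }
  tree <- colony_tree(parent, n, labels)
  tree <- assign_mutations(tree, gm)
  attr(tree, "parsimony_score") <- score_of(parent, root)
  tree
}

#' Assign every somatic mutation to one branch
#'
#' Each variant is placed on the branch whose subtended tip set minimises
#' the symmetric difference with the variant's present-set (unknown tips
#' are excluded from the comparison). Ties break toward the most rootward
#' branch, then the smallest branch id. The per-variant mismatch count
#' (the number of tips whose genotype disagrees with a single-origin
#' placement, i.e. homoplasy or genotyping error) is recorded.
#'
#' @param tree A [colony_tree] topology over the genotype matrix colonies.
#' @param gm A [genotype_matrix()] of somatic calls.
#' @return The tree with `mutations`, `branch$raw_length` and an
#'   `assignment` data frame (`variant_id`, `branch_id`, `mismatches`)
#'   attached as `tree$assignment`.
#' @export
assign_mutations <- function(tree, gm) {
  stopifnot(inherits(tree, "colony_tree"), inherits(gm, "genotype_matrix"))
  gm <- somatic_genotypes(gm)
  if (!identical(colnames(gm$calls), tree$tip_labels)) {
    gm$calls <- gm$calls[, tree$tip_labels, drop = FALSE]
  }
  n_tips <- tree$n_tips
  tip_sets <- tree_tip_sets(tree)
  depths <- tree_depths(tree)
  branch_nodes <- tree$branch$node
  ord <- order(depths[branch_nodes], branch_nodes)
  branch_nodes <- branch_nodes[ord] # rootward first
  B <- matrix(0L, length(branch_nodes), n_tips)
  for (i in seq_along(branch_nodes)) {
    B[i, tip_sets[[branch_nodes[i]]]] <- 1L
  }
  calls <- gm$calls
  present_n <- rowSums(calls == 1L, na.rm = TRUE)
  drop <- present_n == 0L
  if (any(drop)) {
    warning(sum(drop), " variant(s) present in no colony; dropped from assignment")
  }
  keep_idx <- which(!drop)
  n_var <- length(keep_idx)
  assignment <- data.frame(
    variant_id = gm$variants$variant_id[keep_idx],
    branch_id = integer(n_var), mismatches = integer(n_var),
    stringsAsFactors = FALSE
  )
  has_na <- rowSums(is.na(calls)) > 0L
  # complete rows: vectorised symmetric-difference via matrix product
  full <- keep_idx[!has_na[keep_idx]]
  if (length(full)) {
    P <- t(calls[full, , drop = FALSE]) # tips x variants
    mism <- outer(rowSums(B), colSums(P), "+") - 2L * (B %*% P)
    pick <- apply(mism, 2L, which.min) # first minimum = most rootward
    rows <- match(full, keep_idx)
    assignment$branch_id[rows] <- branch_nodes[pick]
    assignment$mismatches[rows] <- mism[cbind(pick, seq_along(full))]
  }
  partial <- keep_idx[has_na[keep_idx]]
  for (i in partial) {
    p <- calls[i, ]
    known <- which(!is.na(p))
    mism <- as.integer(B[, known, drop = FALSE] %*% rep(1L, length(known))) +
      sum(p[known]) - 2L * as.integer(B[, known, drop = FALSE] %*% p[known])
    j <- which.min(mism)
    row <- match(i, keep_idx)
    assignment$branch_id[row] <- branch_nodes[j]
    assignment$mismatches[row] <- mism[j]
  }
  tree$mutations <- split(
    assignment$variant_id,
    factor(assignment$branch_id, levels = tree$branch$node)
  )
  tree$branch$raw_length <- as.numeric(lengths(tree$mutations))
  tree$assignment <- assignment
  tree
}

#' Per-colony unknown-genotype fraction at mutated sites
#'
#' The fraction of unknown entries for each colony, among variant rows
#' genotyped present in at least one colony. High-coverage colony data
#' keep this in the low percent range; larger values indicate a colony
#' whose genotypes (and terminal branch) are unreliable.
#'
#' @param gm A [genotype_matrix()].
#' @return Data frame with `colony` and `unknown_fraction`.
#' @export
missingness_report <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  mutated <- rowSums(gm$calls == 1L, na.rm = TRUE) >= 1L
  calls <- gm$calls[mutated, , drop = FALSE]
  frac <- if (nrow(calls)) colMeans(is.na(calls)) else rep(0, ncol(gm$calls))
  data.frame(
    colony = colnames(gm$calls), unknown_fraction = as.numeric(frac),
    stringsAsFactors = FALSE
  )
}
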