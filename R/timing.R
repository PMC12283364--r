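## Conversion of raw mutation-count branch lengths into
## sensitivity-corrected, ultrametric and age-scaled (time) trees.

#' Estimate per-colony mutation-detection sensitivity
#'
#' Terminal branches carry mutations unique to one colony, so variable
#' sequencing depth deflates them. Two estimators are offered:
#' `germline_recall` — the fraction of the individual's germline
#' heterozygous variants called present in the colony under the standard
#' genotyping thresholds (germline hets are a built-in truth set at VAF
#' 0.5, exactly like clonal somatic variants); `depth_model` — a closed
#' Poisson-depth/binomial-sampling computation,
#' sum over d of P(D = d) * P(Alt >= max(min_alt, ceil(vaf_thr * d)) | d),
#' with D ~ Poisson(mean_depth) and Alt ~ Binomial(d, 0.5).
#'
#' @param counts A [read_counts] (needed for `germline_recall`).
#' @param germline_ids Variant ids of germline heterozygous variants
#'   (`germline_recall` method).
#' @param mean_depth Per-colony mean depth (`depth_model` method); may be
#'   a named vector over colonies.
#' @param cfg A [filter_config()] supplying the genotyping thresholds.
#' @param method `"germline_recall"` or `"depth_model"`.
#' @return Data frame with `colony`, `sensitivity`, `method`, `support`.
#' @export
estimate_sensitivity <- function(counts = NULL, germline_ids = NULL,
                                 mean_depth = NULL, cfg = filter_config(),
                                 method = c("germline_recall", "depth_model")) {
  method <- match.arg(method)
  if (method == "germline_recall") {
    stopifnot(inherits(counts, "read_counts"), length(germline_ids) > 0)
    idx <- match(germline_ids, counts$variants$variant_id)
    if (anyNA(idx)) stop("unknown germline variant ids")
    sub <- read_counts(
      counts$variants[idx, , drop = FALSE], counts$colonies,
      counts$alt[idx, , drop = FALSE], counts$depth[idx, , drop = FALSE]
    )
    gm <- genotype_calls(sub, cfg)
    sens <- colMeans(gm$calls == 1L, na.rm = FALSE)
    sens[is.na(sens)] <- colMeans(gm$calls == 1L, na.rm = TRUE)[is.na(sens)]
    out <- data.frame(
      colony = counts$colonies, sensitivity = as.numeric(sens),
      method = "germline_recall", support = length(germline_ids),
      stringsAsFactors = FALSE
    )
  } else {
    stopifnot(!is.null(mean_depth))
    colony <- if (!is.null(names(mean_depth))) names(mean_depth) else as.character(seq_along(mean_depth))
    sens <- vapply(mean_depth, function(lambda) {
      detection_probability(lambda, cfg$min_alt_reads, cfg$vaf_autosome)
    }, numeric(1))
    out <- data.frame(
      colony = colony, sensitivity = as.numeric(sens),
      method = "depth_model", support = as.numeric(mean_depth),
      stringsAsFactors = FALSE
    )
  }
  if (any(out$sensitivity <= 0)) {
    stop(
      "sensitivity of 0 for colony ",
      paste(out$colony[out$sensitivity <= 0], collapse = ", "),
      "; colony cannot be corrected"
    )
  }
  out
}

# P(calling a clonal het) under Poisson depth and binomial allele sampling;
# the depth sum is truncated where the Poisson tail mass drops below 1e-12.
detection_probability <- function(mean_depth, min_alt, vaf_threshold) {
  d_max <- max(20, stats::qpois(1 - 1e-12, mean_depth))
  d <- 0:d_max
  need <- pmax(min_alt, ceiling(vaf_threshold * d))
  p_call <- stats::pbinom(need - 1, d, 0.5, lower.tail = FALSE)
  sum(stats::dpois(d, mean_depth) * p_call)
}

#' Correct terminal branch lengths for detection sensitivity
#'
#' Terminal branches are divided by the colony's sensitivity; internal
#' branches (whose mutations are supported by several colonies) are
#' copied unchanged into the corrected channel.
#'
#' @param tree A [colony_tree] with `raw_length` set.
#' @param sens Data frame from [estimate_sensitivity()] covering all tips.
#' @return The tree with `branch$corrected_length` filled.
#' @export
correct_terminal_branches <- function(tree, sens) {
  stopifnot(inherits(tree, "colony_tree"))
  s <- stats::setNames(sens$sensitivity, sens$colony)
  missing <- setdiff(tree$tip_labels, names(s))
  if (length(missing)) {
    stop("missing sensitivity for colony: ", paste(missing, collapse = ", "))
  }
  tree$branch$corrected_length <- tree$branch$raw_length
  is_tip <- tree$branch$node <= tree$n_tips
  tip_sens <- s[tree$tip_labels[tree$branch$node[is_tip]]]
  tree$branch$corrected_length[is_tip] <-
    tree$branch$raw_length[is_tip] / as.numeric(tip_sens)
  tree
}

#' Normalise a tree to equal root-to-tip distances
#'
#' All colonies were sampled at one time point, so after sensitivity
#' correction the only root-to-tip variation left should be Poisson noise;
#' the tree can therefore be made ultrametric. An iteratively reweighted
#' means scheme is used: each internal node's height above the tips is set
#' bottom-up to the weighted mean of (child height + child corrected
#' branch length), with weights equal to subtree tip counts in the first
#' iteration and subtree corrected-mutation totals in later iterations;
#' a top-down pass then resets each branch to the parent-child height
#' difference, clamping at zero (which redistributes the deficit along the
#' descendant path). Iteration stops when no node height moves by more
#' than `tol`. Finally all branches are scaled so the tree height equals
#' the mean corrected root-to-tip distance.
#'
#' @param tree A [colony_tree] with `corrected_length` set.
#' @param tol Convergence tolerance on node heights (default 1e-6).
#' @param max_iter Maximum iterations (default 100).
#' @param weighting `"auto"` (tip counts then mutation totals, the
#'   default), `"tips"` or `"mutations"` throughout.
#' @return The tree with `branch$ultrametric_length` filled; attribute
#'   `"converged"` is FALSE if `max_iter` was hit.
#' @export
make_ultrametric <- function(tree, tol = 1e-6, max_iter = 100,
                             weighting = c("auto", "tips", "mutations")) {
  stopifnot(inherits(tree, "colony_tree"))
  weighting <- match.arg(weighting)
  if (any(is.na(tree$branch$corrected_length))) {
    stop("corrected_length must be set; run correct_terminal_branches() first")
  }
  po <- postorder_parent(tree$parent, tree$root)
  n_nodes <- length(tree$parent)
  lens <- numeric(n_nodes) # corrected length of branch above each node
  lens[tree$branch$node] <- tree$branch$corrected_length
  # subtree weights
  tip_counts <- numeric(n_nodes)
  mut_totals <- numeric(n_nodes)
  for (v in po$order) {
    kids <- po$children[[v]]
    if (!length(kids)) {
      tip_counts[v] <- 1
      mut_totals[v] <- lens[v]
    } else {
      tip_counts[v] <- sum(tip_counts[kids])
      mut_totals[v] <- sum(mut_totals[kids]) + lens[v]
    }
  }
  target_h <- mean(tree_node_distances(tree, "corrected_length")[seq_len(tree$n_tips)])
  h <- numeric(n_nodes)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    w <- switch(weighting,
      auto = if (iter == 1L) tip_counts else pmax(mut_totals, 1e-9),
      tips = tip_counts,
      mutations = pmax(mut_totals, 1e-9)
    )
    h_new <- numeric(n_nodes)
    for (v in po$order) {
      kids <- po$children[[v]]
      if (length(kids)) {
        h_new[v] <- sum(w[kids] * (h_new[kids] + lens[kids])) / sum(w[kids])
      }
    }
    if (iter > 1L && max(abs(h_new - h)) < tol) {
      h <- h_new
      converged <- TRUE
      break
    }
    h <- h_new
  }
  if (!converged && max_iter > 1L) {
    warning("make_ultrametric did not converge in ", max_iter, " iterations")
  }
  # top-down clamp: child height may not exceed its parent's
  h_final <- h
  for (v in rev(po$order)) { # preorder
    if (v == tree$root) next
    if (v > tree$n_tips) {
      h_final[v] <- min(h_final[tree$parent[v]], h[v])
    } else {
      h_final[v] <- 0
    }
  }
  ultra <- h_final[tree$branch$parent] - h_final[tree$branch$node]
  # scale to the target height
  scale <- if (h_final[tree$root] > 0) target_h / h_final[tree$root] else 1
  tree$branch$ultrametric_length <- ultra * scale
  attr(tree, "ultrametric_converged") <- converged
  tree
}

#' Scale an ultrametric tree to chronological age
#'
#' The near-constant somatic mutation rate acts as a molecular clock: the
#' ultrametric tree is scaled linearly so every root-to-tip distance
#' equals the age at sampling (plus an optional gestation offset).
#'
#' @param tree A [colony_tree] with `ultrametric_length` set.
#' @param age_at_sampling Age in years.
#' @param gestation_offset Added years of prenatal time (default 0).
#' @return The tree with `branch$time_span`, `branch$t_start`,
#'   `branch$t_end` filled (ages in years from conception of the branch's
#'   parent and child nodes).
#' @export
scale_to_age <- function(tree, age_at_sampling, gestation_offset = 0) {
  stopifnot(inherits(tree, "colony_tree"))
  if (any(is.na(tree$branch$ultrametric_length))) {
    stop("ultrametric_length must be set; run make_ultrametric() first")
  }
  lens <- stats::setNames(tree$branch$ultrametric_length, tree$branch$node)
  d <- numeric(length(tree$parent))
  for (v in rev(tree_postorder(tree))) {
    if (v != tree$root) d[v] <- d[tree$parent[v]] + lens[[as.character(v)]]
  }
  height <- max(d[seq_len(tree$n_tips)])
  if (height <= 0) stop("tree height is zero; cannot scale to age")
  total_time <- age_at_sampling + gestation_offset
  scale <- total_time / height
  tree$branch$time_span <- tree$branch$ultrametric_length * scale
  tree$branch$t_start <- d[tree$branch$parent] * scale
  tree$branch$t_end <- d[tree$branch$node] * scale
  tree
}

#' Fraction of a mutation set timed within an exposure window
#'
#' For a time-scaled tree and a set of mutations with branch assignments,
#' the fraction whose branch time interval intersects the window
#' `[start_age, end_age]`. Used to check phylogenetic timings against
#' known periods of mutagen exposure.
#'
#' @param tree A time-scaled [colony_tree] (see [scale_to_age()]).
#' @param mutation_ids Character vector of variant ids.
#' @param window Numeric length-2 vector `(start_age, end_age)` in years.
#' @return Fraction in `[0, 1]`.
#' @export
exposure_window_overlap <- function(tree, mutation_ids, window) {
  stopifnot(inherits(tree, "colony_tree"), length(window) == 2)
  if (!length(mutation_ids)) stop("empty mutation set")
  if (any(is.na(tree$branch$t_start))) stop("tree is not time-scaled")
  branch_of <- rep(tree$branch$node, lengths(tree$mutations))
  names(branch_of) <- unlist(tree$mutations, use.names = FALSE)
  b <- branch_of[mutation_ids]
  if (anyNA(b)) {
    warning(sum(is.na(b)), " mutation(s) not assigned to any branch; counted as non-overlapping")
  }
  idx <- match(b, tree$branch$node)
  overlaps <- !is.na(idx) &
    tree$branch$t_start[idx] <= window[2] &
    tree$branch$t_end[idx] >= window[1]
  mean(overlaps)
}
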