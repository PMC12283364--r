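# Shared fixtures: small constructed trees, read-count tables and
# brute-force oracles used across the suite.

# balanced 4-tip tree ((A,B),(C,D)); nodes: 1..4 tips, 5 root, 6 = AB, 7 = CD
quartet_tree <- function(labels = c("A", "B", "C", "D")) {
  colony_tree(c(6L, 6L, 7L, 7L, 0L, 5L, 5L), 4L, labels)
}

# random rooted binary tree by sequential pair joins, with raw/corrected
# branch lengths suitable for ultrametric tests
random_colony_tree <- function(n, mean_len = 30) {
  parent <- integer(2L * n - 1L)
  active <- seq_len(n)
  next_id <- n + 1L
  while (length(active) > 1L) {
    pair <- sample.int(length(active), 2L)
    parent[active[pair]] <- next_id
    active <- c(active[-pair], next_id)
    next_id <- next_id + 1L
  }
  tree <- colony_tree(parent, n, paste0("c", seq_len(n)))
  tree$branch$raw_length <- stats::rpois(nrow(tree$branch), mean_len)
  tree$branch$corrected_length <- tree$branch$raw_length
  tree
}

# read_counts with explicitly constructed alt/depth for threshold tests
make_counts <- function(alt, depth, sex = rep(FALSE, nrow(alt)),
                        colonies = paste0("c", seq_len(ncol(alt)))) {
  variants <- data.frame(
    variant_id = paste0("v", seq_len(nrow(alt))),
    chrom = ifelse(sex, "X", "1"),
    pos = seq_len(nrow(alt)),
    ref = "C", alt = "T", channel_96 = 0L,
    stringsAsFactors = FALSE
  )
  read_counts(variants, colonies, alt, depth)
}

# brute-force small-parsimony oracle: enumerate all internal 0/1 labelings
# (root fixed at 0) and all completions of unknown tips; count changed edges
fitch_oracle <- function(tree, tip_states) {
  n_nodes <- length(tree$parent)
  internal <- setdiff(seq_len(n_nodes), seq_len(tree$n_tips))
  free_internal <- setdiff(internal, tree$root)
  unknown_tips <- which(is.na(tip_states))
  free <- c(free_internal, unknown_tips)
  best <- Inf
  n_free <- length(free)
  for (mask in 0:(2^n_free - 1)) {
    states <- integer(n_nodes)
    states[seq_len(tree$n_tips)] <- tip_states
    states[tree$root] <- 0L
    bits <- as.integer(intToBits(mask))[seq_len(max(n_free, 1))]
    states[free] <- bits[seq_len(n_free)]
    changes <- 0L
    for (v in seq_len(n_nodes)) {
      p <- tree$parent[v]
      if (p != 0L) changes <- changes + (states[v] != states[p])
    }
    best <- min(best, changes)
  }
  best
}

# per-colony true somatic burdens from a simulated cohort's truth channel
true_burden_table <- function(cohort) {
  rows <- lapply(cohort$individuals, function(ind) {
    b <- true_colony_burdens(ind)
    data.frame(
      colony = b$colony,
      individual = ind$metadata$individual,
      age_years = ind$metadata$age_years,
      exposed = ind$metadata$exposed,
      sbs_burden = b$sbs_burden,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

# random binary genotype matrix (no missing data unless asked)
random_genotype_matrix <- function(n_tips, n_var, p_present = 0.4, na_frac = 0) {
  calls <- matrix(
    as.integer(stats::runif(n_tips * n_var) < p_present),
    n_var, n_tips
  )
  if (na_frac > 0) {
    calls[stats::runif(length(calls)) < na_frac] <- NA_integer_
  }
  colnames(calls) <- paste0("c", seq_len(n_tips))
  variants <- data.frame(
    variant_id = paste0("v", seq_len(n_var)),
    chrom = "1", pos = seq_len(n_var), ref = "C", alt = "T",
    channel_96 = 0L, stringsAsFactors = FALSE
  )
  genotype_matrix(calls, variants)
}

# exhaustive optimum parsimony score over all rooted topologies
exhaustive_optimum <- function(gm) {
  n <- ncol(gm$calls)
  masks <- t(cloneclock:::calls_to_masks(gm$calls))
  topos <- cloneclock:::all_rooted_topologies(n)
  min(vapply(topos, function(tp) {
    sum(cloneclock:::fitch_score_masks(tp$parent, tp$root, n, masks))
  }, numeric(1)))
}
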