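#' Configuration for the synthetic-cohort generator
#'
#' Defines the statistical structure of a simulated cohort of individuals,
#' each contributing a set of single-cell-derived colonies. Somatic
#' single-base substitutions accrue along a coalescent genealogy under a
#' linear molecular clock (`burden_intercept` mutations present at birth
#' plus `burden_slope` per year of life); chemotherapy exposure is modelled
#' as mutation "pulses" hitting every lineage alive at the exposure age,
#' with channels drawn from a pulse-specific 96-channel signature.
#'
#' @param ages_years Numeric vector of sampling ages, one individual each.
#' @param colonies_per_individual Colonies sampled per individual (>= 2).
#' @param burden_intercept Expected somatic SBS present at birth
#'   (default 54.57).
#' @param burden_slope Expected somatic SBS acquired per year
#'   (default 16.832).
#' @param chemo_pulses List of pulses, each a list with `age_years`,
#'   `expected_extra_sbs` (per surviving lineage) and `signature_id`
#'   naming an entry of `signature_defs`.
#' @param exposed_individuals Integer indices of the individuals that
#'   receive the pulses (default: all when pulses are given, none
#'   otherwise).
#' @param signature_defs Named list of 96-channel probability vectors;
#'   defaults to [example_signatures()].
#' @param clock_signature Name of the signature used for clock-like and
#'   birth mutations (default `"sig_clock"`).
#' @param n_germline_het Number of germline heterozygous variants carried
#'   by every colony at VAF 0.5 (default 400).
#' @param artifact_rate Expected number of in-vitro (culture) subclonal
#'   artifact variants per colony; VAF drawn from Beta(2, 6) so most fall
#'   below the 0.2 genotyping threshold (default 5).
#' @param mean_depth Expected sequencing depth per site per colony
#'   (default 25, matching colony WGS in the low-20s to low-30s range).
#' @param driver_rate Expected driver acquisitions per lineage per year
#'   (default 0).
#' @param driver_advantage Relative sampling weight of a driver clade
#'   against the background population (default 1 = neutral).
#' @param pulse_overdispersion Gamma-distributed per-lineage variability
#'   of pulse dose (variance of the unit-mean multiplier; 0 = none).
#' @param seed Integer master seed; per-individual substreams are derived
#'   from it.
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(ages_years,
                       colonies_per_individual = 8,
                       burden_intercept = 54.57,
                       burden_slope = 16.832,
                       chemo_pulses = list(),
                       exposed_individuals = NULL,
                       signature_defs = example_signatures(),
                       clock_signature = "sig_clock",
                       n_germline_het = 400,
                       artifact_rate = 5,
                       mean_depth = 25,
                       driver_rate = 0,
                       driver_advantage = 1,
                       pulse_overdispersion = 0,
                       seed = 1L) {
  if (length(ages_years) < 1 || any(ages_years < 0)) {
    stop("ages_years must be non-negative and non-empty")
  }
  if (colonies_per_individual < 2) stop("colonies_per_individual must be >= 2")
  if (burden_intercept < 0 || burden_slope < 0) {
    stop("burden parameters must be non-negative")
  }
  if (mean_depth <= 0) stop("mean_depth must be positive")
  for (nm in names(signature_defs)) {
    check_signature_vector(signature_defs[[nm]], nm)
  }
  if (!clock_signature %in% names(signature_defs)) {
    stop("clock_signature not found in signature_defs")
  }
  for (p in chemo_pulses) {
    stopifnot(all(c("age_years", "expected_extra_sbs", "signature_id") %in% names(p)))
    if (p$expected_extra_sbs < 0) stop("pulse expected_extra_sbs must be >= 0")
    if (!p$signature_id %in% names(signature_defs)) {
      stop("pulse signature_id not found in signature_defs")
    }
  }
  if (is.null(exposed_individuals)) {
    exposed_individuals <- if (length(chemo_pulses)) seq_along(ages_years) else integer(0)
  }
  structure(list(
    ages_years = ages_years,
    colonies_per_individual = as.integer(colonies_per_individual),
    burden_intercept = burden_intercept,
    burden_slope = burden_slope,
    chemo_pulses = chemo_pulses,
    exposed_individuals = as.integer(exposed_individuals),
    signature_defs = signature_defs,
    clock_signature = clock_signature,
    n_germline_het = as.integer(n_germline_het),
    artifact_rate = artifact_rate,
    mean_depth = mean_depth,
    driver_rate = driver_rate,
    driver_advantage = driver_advantage,
    pulse_overdispersion = pulse_overdispersion,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# Derive a reproducible 32-bit substream seed for one individual.
substream_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 7919 + 104729 * index) %% 2147483647)
}

# Kingman coalescent merge structure over a set of existing node ids.
# Merge ages are squashed so that tips sit at their own ages and the final
# merge lands exactly at t_lo; every merge is strictly younger than t_hi.
# `env` carries parent/age vectors by reference.
coalesce_units <- function(unit_ids, t_lo, t_hi, env) {
  m <- length(unit_ids)
  if (m == 1L) {
    return(unit_ids)
  }
  k <- m:2
  waits <- stats::rexp(length(k), rate = choose(k, 2))
  tau <- cumsum(waits)
  ages <- t_hi - (t_hi - t_lo) * tau / tau[length(tau)]
  active <- unit_ids
  for (j in seq_along(ages)) {
    pair <- sample.int(length(active), 2L)
    new_id <- length(env$parent) + 1L
    env$parent[new_id] <- 0L
    env$age[new_id] <- ages[j]
    env$parent[active[pair]] <- new_id
    active <- c(active[-pair], new_id)
  }
  active
}

#' Simulate one individual: genealogy, mutations and read counts
#'
#' Draws a coalescent-shaped genealogy over the individual's colonies
#' (all lineages coalescing by birth), places clock-like somatic SBS on
#' branches in proportion to their time span, adds the birth burden to the
#' earliest branches, applies chemotherapy pulses to every lineage alive at
#' each exposure age, inserts driver-clade expansions, germline
#' heterozygous variants and in-vitro subclonal artifacts, and finally
#' samples reads (depth Poisson, alt binomial at the true VAF).
#'
#' @param cfg A [sim_config()].
#' @param individual_index Which entry of `cfg$ages_years` to simulate.
#'
#' @return List with elements `truth` (class `truth_set`: `tree` with true
#'   branch mutation assignments and node ages, `catalog` of all simulated
#'   variants with class and signature of origin, `driver_events`,
#'   `clone_fractions`), `counts` (a [read_counts]) and `metadata`
#'   (one-row data frame).
#' @export
simulate_individual <- function(cfg, individual_index = 1L) {
  stopifnot(inherits(cfg, "sim_config"))
  if (individual_index < 1 || individual_index > length(cfg$ages_years)) {
    stop("individual_index out of range")
  }
  age <- cfg$ages_years[individual_index]
  n_col <- cfg$colonies_per_individual
  exposed <- individual_index %in% cfg$exposed_individuals
  pulses <- if (exposed) cfg$chemo_pulses else list()
  for (p in pulses) {
    if (p$age_years > age) {
      stop("pulse age ", p$age_years, " exceeds sampling age ", age)
    }
  }
  ind_id <- sprintf("ind%d", individual_index)
  set.seed(substream_seed(cfg$seed, individual_index))

  ## ---- driver clade structure -------------------------------------------
  n_events <- if (cfg$driver_rate > 0 && age > 0) {
    stats::rpois(1, cfg$driver_rate * age * n_col)
  } else {
    0L
  }
  driver_ages <- if (n_events > 0) stats::runif(n_events, 0, age) else numeric(0)
  # colony -> clade assignment: clade weight grows with clade age and
  # driver_advantage, competing against a background pool of weight n_col
  clade_w <- cfg$driver_advantage * (age - driver_ages) / max(age, 1e-9)
  assign_prob <- c(clade_w, n_col)
  clade_of <- sample.int(n_events + 1L, n_col, replace = TRUE, prob = assign_prob)
  clade_of[clade_of == n_events + 1L] <- 0L # background
  realized <- sort(unique(clade_of[clade_of > 0L]))

  ## ---- genealogy ---------------------------------------------------------
  env <- new.env()
  env$parent <- integer(n_col)
  env$age <- rep(age, n_col)
  clade_roots <- integer(0)
  clade_stem_node <- stats::setNames(integer(length(realized)), realized)
  for (k in realized) {
    members <- which(clade_of == k)
    r <- coalesce_units(members, t_lo = driver_ages[k], t_hi = age, env)
    clade_roots <- c(clade_roots, r)
    clade_stem_node[as.character(k)] <- r
  }
  outer_units <- c(which(clade_of == 0L), clade_roots)
  u_bound <- min(c(age, driver_ages[realized]))
  root <- coalesce_units(outer_units, t_lo = 0, t_hi = u_bound, env)
  if (env$age[root] > 0) { # single clade swallowed everything: add zygote
    new_id <- length(env$parent) + 1L
    env$parent[new_id] <- 0L
    env$age[new_id] <- 0
    env$parent[root] <- new_id
    root <- new_id
  }
  tip_labels <- sprintf("%s_c%d", ind_id, seq_len(n_col))
  tree <- colony_tree(env$parent, n_col, tip_labels, node_age = env$age)
  stopifnot(tree$root == root)

  ## ---- mutations ---------------------------------------------------------
  sigs <- cfg$signature_defs
  clock_sig <- cfg$clock_signature
  ct <- channel_table()
  branch_nodes <- tree$branch$node
  parent_of <- tree$parent
  root_children <- which(parent_of == root)

  new_variant <- function(n, class, signature, branch, colony = NA_character_,
                          gene = NA_character_, consequence = NA_character_,
                          channel_probs = sigs[[signature]]) {
    if (n == 0L) {
      return(NULL)
    }
    chan <- sample.int(96L, n, replace = TRUE, prob = channel_probs) - 1L
    data.frame(
      chrom = as.character(sample.int(22L, n, replace = TRUE)),
      pos = sample.int(2e8, n, replace = TRUE),
      ref = ct$ref[chan + 1L],
      alt = ct$alt[chan + 1L],
      channel_96 = chan,
      class = class,
      true_signature = signature,
      branch_id = branch,
      colony = colony,
      gene = gene,
      consequence = consequence,
      stringsAsFactors = FALSE
    )
  }

  parts <- list()
  # clock mutations per branch, plus birth burden on the earliest branches
  for (v in branch_nodes) {
    span <- env$age[v] - env$age[parent_of[v]]
    n_clock <- stats::rpois(1, cfg$burden_slope * span)
    if (v %in% root_children) {
      n_clock <- n_clock + stats::rpois(1, cfg$burden_intercept)
    }
    parts[[length(parts) + 1L]] <- new_variant(n_clock, "somatic", clock_sig, v)
  }
  # chemotherapy pulses: every lineage alive at the pulse age
  for (p in pulses) {
    live <- branch_nodes[env$age[parent_of[branch_nodes]] < p$age_years &
      env$age[branch_nodes] >= p$age_years]
    for (v in live) {
      mult <- if (cfg$pulse_overdispersion > 0) {
        stats::rgamma(1,
          shape = 1 / cfg$pulse_overdispersion,
          rate = 1 / cfg$pulse_overdispersion
        )
      } else {
        1
      }
      n_p <- stats::rpois(1, p$expected_extra_sbs * mult)
      parts[[length(parts) + 1L]] <-
        new_variant(n_p, "somatic", p$signature_id, v)
    }
  }
  # driver events on clade stem branches
  driver_events <- NULL
  if (length(realized)) {
    genes <- sample(default_driver_genes(), length(realized), replace = TRUE)
    for (i in seq_along(realized)) {
      v <- clade_stem_node[[as.character(realized[i])]]
      parts[[length(parts) + 1L]] <- new_variant(
        1L, "somatic", clock_sig, v,
        gene = genes[i], consequence = "truncating"
      )
      driver_events <- rbind(driver_events, data.frame(
        branch_id = v, gene = genes[i],
        event_age = driver_ages[realized[i]], stringsAsFactors = FALSE
      ))
    }
  }
  # germline heterozygous variants (flat channel usage)
  parts[[length(parts) + 1L]] <-
    new_variant(cfg$n_germline_het, "germline", "sig_flat", NA_integer_,
      channel_probs = rep(1 / 96, 96)
    )
  # in-vitro subclonal artifacts, private to one colony
  for (ci in seq_len(n_col)) {
    n_art <- stats::rpois(1, cfg$artifact_rate)
    parts[[length(parts) + 1L]] <-
      new_variant(n_art, "artifact", "sig_flat", NA_integer_,
        colony = tip_labels[ci], channel_probs = rep(1 / 96, 96)
      )
  }
  catalog <- do.call(rbind, parts)
  if (is.null(catalog)) stop("simulation produced no variants")
  catalog$variant_id <- sprintf("%s_v%06d", ind_id, seq_len(nrow(catalog)))
  catalog <- catalog[, c(
    "variant_id", "chrom", "pos", "ref", "alt", "channel_96",
    "class", "true_signature", "branch_id", "colony", "gene", "consequence"
  )]

  ## ---- truth tree annotation ---------------------------------------------
  tip_sets <- tree_tip_sets(tree)
  som <- catalog[catalog$class == "somatic", ]
  muts_by_branch <- split(som$variant_id, factor(som$branch_id, levels = branch_nodes))
  tree$mutations <- stats::setNames(muts_by_branch, as.character(branch_nodes))
  tree$branch$raw_length <- vapply(tree$mutations, length, integer(1))
  clone_fractions <- data.frame(
    node = branch_nodes,
    n_colonies = vapply(branch_nodes, function(v) length(tip_sets[[v]]), integer(1)),
    fraction = vapply(branch_nodes, function(v) length(tip_sets[[v]]) / n_col, numeric(1))
  )

  ## ---- read sampling -----------------------------------------------------
  n_var <- nrow(catalog)
  vaf <- matrix(0, n_var, n_col)
  vaf[catalog$class == "germline", ] <- 0.5
  som_idx <- which(catalog$class == "somatic")
  for (i in som_idx) {
    v <- catalog$branch_id[i]
    vaf[i, tip_sets[[v]]] <- 0.5
  }
  art_idx <- which(catalog$class == "artifact")
  if (length(art_idx)) {
    art_vaf <- stats::rbeta(length(art_idx), 2, 6)
    art_col <- match(catalog$colony[art_idx], tip_labels)
    vaf[cbind(art_idx, art_col)] <- art_vaf
  }
  depth <- matrix(stats::rpois(n_var * n_col, cfg$mean_depth), n_var, n_col)
  alt <- matrix(stats::rbinom(n_var * n_col, as.vector(depth), as.vector(vaf)),
    n_var, n_col
  )
  counts <- read_counts(catalog, tip_labels, alt, depth)

  metadata <- data.frame(
    individual = ind_id, age_years = age, exposed = exposed,
    n_colonies = n_col, mean_depth = cfg$mean_depth, stringsAsFactors = FALSE
  )
  truth <- structure(
    list(
      tree = tree, catalog = catalog, driver_events = driver_events,
      clone_fractions = clone_fractions
    ),
    class = "truth_set"
  )
  list(truth = truth, counts = counts, metadata = metadata)
}

#' Simulate a full cohort
#'
#' One independent individual per entry of `cfg$ages_years`, each with its
#' own derived random substream, so cohorts are reproducible and
#' individuals can be regenerated in isolation.
#'
#' @param cfg A [sim_config()].
#' @return List with `individuals` (list of [simulate_individual()]
#'   results) and `metadata` (one row per individual).
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  individuals <- lapply(
    seq_along(cfg$ages_years),
    function(i) simulate_individual(cfg, i)
  )
  metadata <- do.call(rbind, lapply(individuals, `[[`, "metadata"))
  list(individuals = individuals, metadata = metadata)
}

#' Simulate a duplex-sequencing 96-channel spectrum
#'
#' Draws a multinomial mutation spectrum from a weighted mixture of the
#' configured signatures, as produced by error-corrected duplex sequencing
#' of a polyclonal cell population. Optionally distorts the spectrum by a
#' sample-specific trinucleotide-context abundance (so that
#' [abundance_correct()] has something to undo) and always emits the
#' abundance vectors needed for that correction.
#'
#' @param cfg A [sim_config()].
#' @param cell_type_mix Named non-negative weights over
#'   `cfg$signature_defs` entries.
#' @param n Total number of mutations to draw.
#' @param distort_abundance If TRUE, draw a random context abundance and
#'   bias the spectrum accordingly (default FALSE).
#' @return List with `counts` (96-channel integer vector),
#'   `observed_abundance` and `target_abundance` (32-context frequencies).
#' @export
simulate_duplex_spectrum <- function(cfg, cell_type_mix, n = 10000,
                                     distort_abundance = FALSE) {
  stopifnot(inherits(cfg, "sim_config"))
  if (any(cell_type_mix < 0)) stop("mixture weights must be non-negative")
  if (sum(cell_type_mix) <= 0) stop("mixture weights must not all be zero")
  bad <- setdiff(names(cell_type_mix), names(cfg$signature_defs))
  if (length(bad)) stop("unknown signatures in mix: ", paste(bad, collapse = ", "))
  w <- cell_type_mix / sum(cell_type_mix)
  p <- Reduce(`+`, Map(function(nm, wi) wi * cfg$signature_defs[[nm]],
    names(w), as.numeric(w)
  ))
  target <- rep(1 / 32, 32)
  observed <- target
  if (distort_abundance) {
    observed <- stats::runif(32, 0.5, 1.5)
    observed <- observed / sum(observed)
  }
  ctx <- channel_to_context()
  q <- p * observed[ctx] / target[ctx]
  q <- q / sum(q)
  counts <- if (n > 0) as.integer(stats::rmultinom(1, n, q)) else integer(96)
  list(
    counts = stats::setNames(counts, sbs96_channels()),
    observed_abundance = stats::setNames(observed, trinuc32_contexts()),
    target_abundance = stats::setNames(target, trinuc32_contexts())
  )
}

#' Write the simulated truth and observation tables of one individual
#'
#' Emits the mutation catalog TSV, the read-count TSV pair, the true tree
#' as Newick (branch lengths = true SBS counts) and the metadata TSV.
#'
#' @param sim Result of [simulate_individual()].
#' @param outdir Output directory (created if missing).
#' @return Character vector of the files written.
#' @export
write_simulated_individual <- function(sim, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  id <- sim$metadata$individual
  cat_path <- file.path(outdir, paste0(id, "_mutations.tsv"))
  utils::write.table(sim$truth$catalog, cat_path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  write_read_counts(sim$counts, file.path(outdir, id))
  tree_path <- file.path(outdir, paste0(id, "_truth_tree.nwk"))
  write_colony_tree(sim$truth$tree, tree_path, "raw_length")
  meta_path <- file.path(outdir, paste0(id, "_metadata.tsv"))
  utils::write.table(sim$metadata, meta_path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  c(
    cat_path, paste0(file.path(outdir, id), c("_alt.tsv", "_depth.tsv", "_variants.tsv")),
    tree_path, meta_path
  )
}

#' Write / read a simulation configuration as JSON
#'
#' @param cfg A [sim_config()].
#' @param path JSON file path.
#' @export
write_sim_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "sim_config"))
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$signature_defs <- lapply(raw$signature_defs, as.numeric)
  raw$chemo_pulses <- if (length(raw$chemo_pulses)) {
    lapply(seq_len(nrow(raw$chemo_pulses)), function(i) as.list(raw$chemo_pulses[i, ]))
  } else {
    list()
  }
  do.call(sim_config, raw)
}

#' True per-colony somatic burdens from a simulated truth set
#'
#' Counts, for every colony, the somatic mutations on its root-to-tip
#' path in the true genealogy — the burden an error-free assay would
#' measure. Marginally each colony burden is Poisson with mean
#' `burden_intercept + burden_slope * age` (plus any pulse exposure),
#' with within-individual correlation through shared branches.
#'
#' @param sim Result of [simulate_individual()], or its `truth` element.
#' @return Data frame with `colony`, `sbs_burden`.
#' @export
true_colony_burdens <- function(sim) {
  truth <- if (!is.null(sim$truth)) sim$truth else sim
  tree <- truth$tree
  sets <- tree_tip_sets(tree)
  som <- truth$catalog[truth$catalog$class == "somatic", ]
  burden <- integer(tree$n_tips)
  for (i in seq_len(nrow(som))) {
    tips <- sets[[som$branch_id[i]]]
    burden[tips] <- burden[tips] + 1L
  }
  data.frame(
    colony = tree$tip_labels, sbs_burden = burden,
    stringsAsFactors = FALSE
  )
}
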