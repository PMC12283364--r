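## Clonal-architecture metrics from timed colony trees: clade clonal
## fractions, expanded clades, driver-gene overlays and clone growth
## between time points.

#' Default clonal-hematopoiesis driver gene catalog
#'
#' A synthetic default list of 18 genes recurrently under positive
#' selection in aging or chemotherapy-exposed blood (the DNA damage
#' response genes PPM1D, TP53 and CHEK2 among them). It is a stand-in
#' configuration, not a curated resource: supply your own catalog for
#' real analyses.
#'
#' @return Character vector of 18 gene symbols.
#' @export
default_driver_genes <- function() {
  c(
    "DNMT3A", "TET2", "ASXL1", "PPM1D", "TP53", "CHEK2", "JAK2", "SF3B1",
    "SRSF2", "U2AF1", "CBL", "GNB1", "GNAS", "IDH1", "IDH2", "KRAS",
    "NRAS", "BRCC3"
  )
}

#' Driver catalog with a variant-class rule
#'
#' @param genes Unique gene symbols (default [default_driver_genes()]).
#' @param missense_whitelist Optional character vector of
#'   `"GENE:PROTEINCHANGE"` entries; truncating variants in catalog genes
#'   always count as drivers, missense variants only if whitelisted.
#' @return List of class `driver_catalog`.
#' @export
driver_catalog <- function(genes = default_driver_genes(),
                           missense_whitelist = character(0)) {
  if (anyDuplicated(genes)) stop("driver gene symbols must be unique")
  structure(list(genes = genes, missense_whitelist = missense_whitelist),
    class = "driver_catalog"
  )
}

#' Clonal fraction of every clade
#'
#' Each branch defines the clade of colonies descending through it; the
#' clonal fraction is that colony count over the total, treating sampled
#' colonies as a random draw from the HSPC population. The root row
#' carries fraction 1 by construction.
#'
#' @param tree A [colony_tree] with at least 2 tips.
#' @return Data frame of class `clade_report`: `branch_id`, `parent`,
#'   `n_colonies`, `fraction`, `t_start`, `t_end` (branch time interval
#'   when the tree is time-scaled, else NA).
#' @export
clade_fractions <- function(tree) {
  stopifnot(inherits(tree, "colony_tree"))
  if (tree$n_tips < 2) stop("need at least two tips")
  tip_sets <- tree_tip_sets(tree)
  n <- tree$n_tips
  counts <- vapply(tree$branch$node, function(v) length(tip_sets[[v]]), integer(1))
  out <- data.frame(
    branch_id = c(tree$root, tree$branch$node),
    parent = c(NA_integer_, tree$branch$parent),
    n_colonies = c(n, counts),
    fraction = c(1, counts / n),
    t_start = c(NA_real_, tree$branch$t_start),
    t_end = c(NA_real_, tree$branch$t_end),
    stringsAsFactors = FALSE
  )
  class(out) <- c("clade_report", "data.frame")
  out
}

#' Flag expanded clades
#'
#' A clade is expanded when its clonal fraction strictly exceeds
#' `threshold` (default 1%) and it contains at least `min_colonies`
#' colonies (default 2, guarding against single-colony noise in trees of
#' under ~100 colonies). The maximal (non-nested) expanded clades are
#' additionally marked: an expanded clade none of whose ancestors is
#' itself an expanded non-root clade.
#'
#' @param report A [clade_fractions()] report.
#' @param tree The [colony_tree] the report came from.
#' @param threshold Clonal-fraction threshold (default 0.01, strict).
#' @param min_colonies Minimum colony count (default 2).
#' @return The report with logical columns `expanded` and
#'   `maximal_expanded`; the root is never flagged.
#' @export
expanded_clades <- function(report, tree, threshold = 0.01, min_colonies = 2) {
  stopifnot(inherits(report, "clade_report"), inherits(tree, "colony_tree"))
  is_root <- is.na(report$parent)
  report$expanded <- !is_root & report$fraction > threshold &
    report$n_colonies >= min_colonies
  expanded_set <- report$branch_id[report$expanded]
  maximal <- logical(nrow(report))
  for (i in which(report$expanded)) {
    v <- report$branch_id[i]
    anc_expanded <- FALSE
    u <- tree$parent[v]
    while (u != 0L && u != tree$root) {
      if (u %in% expanded_set) {
        anc_expanded <- TRUE
        break
      }
      u <- tree$parent[u]
    }
    maximal[i] <- !anc_expanded
  }
  report$maximal_expanded <- maximal
  report
}

# is a mutation row a driver under the catalog's variant-class rule?
is_driver_mutation <- function(annotations, catalog) {
  gene_ok <- annotations$gene %in% catalog$genes
  cons <- annotations$consequence
  trunc <- !is.na(cons) & cons %in% c("truncating", "nonsense", "frameshift", "splice")
  missense_key <- paste0(annotations$gene, ":", annotations$protein_change %||% "")
  missense_ok <- !is.na(cons) & cons == "missense" &
    missense_key %in% catalog$missense_whitelist
  gene_ok & (trunc | missense_ok)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Overlay driver-gene labels on clades
#'
#' A clade is labelled with every catalog gene carrying a
#' protein-altering (driver-class) mutation on its stem branch or any
#' ancestral branch, in root-to-tip branch order, so nested drivers
#' accumulate on the inner clade.
#'
#' @param tree A [colony_tree] with branch mutation assignments.
#' @param catalog A [driver_catalog()].
#' @param annotations Data frame with `variant_id`, `gene`,
#'   `consequence` (and optionally `protein_change`) for assigned
#'   mutations.
#' @param report Optional existing [clade_fractions()] report to extend.
#' @return The clade report with a `drivers` character column
#'   (comma-separated gene labels, "" if none).
#' @export
annotate_drivers <- function(tree, catalog, annotations, report = NULL) {
  stopifnot(inherits(tree, "colony_tree"), inherits(catalog, "driver_catalog"))
  if (is.null(report)) report <- clade_fractions(tree)
  known <- annotations[!is.na(annotations$gene), , drop = FALSE]
  unknown <- unique(setdiff(known$gene, catalog$genes))
  if (length(unknown)) {
    warning(
      "gene symbols not in catalog ignored: ",
      paste(utils::head(unknown, 5), collapse = ", "),
      if (length(unknown) > 5) ", ..."
    )
  }
  drv <- known[is_driver_mutation(known, catalog), , drop = FALSE]
  branch_genes <- lapply(tree$branch$node, function(v) {
    ids <- tree$mutations[[as.character(v)]]
    unique(drv$gene[drv$variant_id %in% ids])
  })
  names(branch_genes) <- as.character(tree$branch$node)
  labels <- character(nrow(report))
  for (i in seq_len(nrow(report))) {
    v <- report$branch_id[i]
    if (v == tree$root) {
      labels[i] <- ""
      next
    }
    path <- integer(0)
    u <- v
    while (u != tree$root) {
      path <- c(u, path) # root-to-tip order
      u <- tree$parent[u]
    }
    genes <- unlist(lapply(as.character(path), function(b) branch_genes[[b]]))
    labels[i] <- paste(unique(genes), collapse = ",")
  }
  report$drivers <- labels
  report
}

#' Clone-size change between two time points
#'
#' Fold change of a clone's colony fraction between two samplings, with
#' exact (Clopper-Pearson) 95% confidence intervals on each fraction. A
#' clone absent at the first time point but present at the second is
#' flagged as a new clone (fold change undefined).
#'
#' @param count_t1,count_t2 Length-2 vectors `(clone colonies, total
#'   colonies)` at each time point.
#' @param conf_level Confidence level for the per-time-point intervals.
#' @return List: `fraction_t1`, `fraction_t2`, `ci_t1`, `ci_t2`, `fold`,
#'   `new_clone`.
#' @export
clone_growth <- function(count_t1, count_t2, conf_level = 0.95) {
  stopifnot(length(count_t1) == 2, length(count_t2) == 2)
  if (count_t1[2] <= 0 || count_t2[2] <= 0) stop("totals must be positive")
  if (count_t1[1] == 0 && count_t2[1] == 0) {
    stop("clone absent at both time points")
  }
  f1 <- count_t1[1] / count_t1[2]
  f2 <- count_t2[1] / count_t2[2]
  ci1 <- stats::binom.test(count_t1[1], count_t1[2], conf.level = conf_level)$conf.int
  ci2 <- stats::binom.test(count_t2[1], count_t2[2], conf.level = conf_level)$conf.int
  new_clone <- count_t1[1] == 0 && count_t2[1] > 0
  list(
    fraction_t1 = unname(f1), fraction_t2 = unname(f2),
    ci_t1 = as.numeric(ci1), ci_t2 = as.numeric(ci2),
    fold = if (new_clone) NA_real_ else unname(f2 / f1),
    new_clone = new_clone
  )
}

#' Summarise the clonal architecture of one individual
#'
#' Aggregates a timed, driver-annotated tree into the quantities used to
#' compare exposed and unexposed individuals: the number of maximal
#' expanded clades, the number carrying each driver gene, and the
#' earliest origin time among expanded clades.
#'
#' @param tree A timed [colony_tree].
#' @param catalog A [driver_catalog()].
#' @param annotations Mutation annotation data frame (see
#'   [annotate_drivers()]).
#' @param threshold,min_colonies Passed to [expanded_clades()].
#' @return List: `n_expanded` (maximal expanded clades),
#'   `n_expanded_with_driver`, `driver_gene_counts` (named vector),
#'   `oldest_expansion_origin` (years; NA if none), `report` (the full
#'   clade report).
#' @export
architecture_summary <- function(tree, catalog = driver_catalog(),
                                 annotations = NULL,
                                 threshold = 0.01, min_colonies = 2) {
  report <- clade_fractions(tree)
  report <- expanded_clades(report, tree, threshold, min_colonies)
  if (!is.null(annotations)) {
    report <- annotate_drivers(tree, catalog, annotations, report)
  } else {
    report$drivers <- ""
  }
  maximal <- report[report$maximal_expanded %in% TRUE, , drop = FALSE]
  gene_counts <- table(unlist(strsplit(maximal$drivers[maximal$drivers != ""], ",")))
  list(
    n_expanded = nrow(maximal),
    n_expanded_with_driver = sum(maximal$drivers != ""),
    driver_gene_counts = if (length(gene_counts)) {
      stats::setNames(as.integer(gene_counts), names(gene_counts))
    } else {
      integer(0)
    },
    oldest_expansion_origin = if (nrow(maximal) && !all(is.na(maximal$t_start))) {
      min(maximal$t_start, na.rm = TRUE)
    } else {
      NA_real_
    },
    report = report
  )
}
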