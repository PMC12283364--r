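## End-to-end orchestration: simulate (optional) -> filter -> tree ->
## time -> signatures -> burden -> architecture, with a checksum manifest
## so identical configurations and seeds yield identical outputs.

#' Assemble a pipeline configuration
#'
#' @param outdir Run directory; all outputs are written beneath it.
#' @param sim A [sim_config()] (simulated-cohort mode), or NULL to read
#'   counts written by [write_read_counts()] from `counts_dir`.
#' @param counts_dir Directory holding `<individual>` count TSV prefixes
#'   and a `metadata.tsv` (real-data mode).
#' @param filter A [filter_config()].
#' @param filter_mode `"simple"` or `"cohort"` (see [filter_variants()]).
#' @param signatures Named list of reference signature probability
#'   vectors for branch attribution (default [example_signatures()]).
#' @param stages Character vector of stages to run, a subset of
#'   `c("filter", "tree", "time", "signatures", "burden", "architecture")`;
#'   later stages require earlier ones.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir,
                            sim = NULL,
                            counts_dir = NULL,
                            filter = filter_config(),
                            filter_mode = c("simple", "cohort"),
                            signatures = example_signatures(),
                            stages = c(
                              "filter", "tree", "time", "signatures",
                              "burden", "architecture"
                            )) {
  filter_mode <- match.arg(filter_mode)
  if (is.null(sim) && is.null(counts_dir)) {
    stop("either a sim_config or a counts_dir is required")
  }
  if (!is.null(counts_dir) && !dir.exists(counts_dir)) {
    stop("counts_dir does not exist: ", counts_dir)
  }
  structure(
    list(
      outdir = outdir, sim = sim, counts_dir = counts_dir, filter = filter,
      filter_mode = filter_mode, signatures = signatures, stages = stages
    ),
    class = "pipeline_config"
  )
}

log_stage <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

#' Run the full colony-genomics pipeline
#'
#' Executes the configured stages for every individual and writes all
#' outputs (genotype matrices, filter and QC reports, Newick trees in
#' each branch-length channel, branch assignments, per-branch signature
#' exposures, the cohort burden table and model fit, clade reports) under
#' `cfg$outdir`, together with a `manifest.json` listing every file with
#' its MD5 checksum.
#'
#' @param cfg A [pipeline_config()].
#' @return Invisibly, a list with `manifest` (data frame of file, md5)
#'   and the in-memory per-individual results.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  emit <- function(path) files <<- c(files, path)

  ## ---- inputs ------------------------------------------------------------
  if (!is.null(cfg$sim)) {
    log_stage("simulate", length(cfg$sim$ages_years), " individual(s), seed ", cfg$sim$seed)
    cohort <- simulate_cohort(cfg$sim)
    for (sim_i in cohort$individuals) {
      for (f in write_simulated_individual(sim_i, file.path(cfg$outdir, "sim"))) emit(f)
    }
  } else {
    meta_path <- file.path(cfg$counts_dir, "metadata.tsv")
    if (!file.exists(meta_path)) stop("missing metadata file: ", meta_path)
    meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
    cohort <- list(
      individuals = lapply(seq_len(nrow(meta)), function(i) {
        prefix <- file.path(cfg$counts_dir, meta$individual[i])
        if (!file.exists(paste0(prefix, "_alt.tsv"))) {
          stop("missing counts for individual at: ", paste0(prefix, "_alt.tsv"))
        }
        list(counts = read_read_counts(prefix), metadata = meta[i, , drop = FALSE], truth = NULL)
      }),
      metadata = meta
    )
  }

  results <- list()
  burden_rows <- list()
  for (ind in cohort$individuals) {
    id <- ind$metadata$individual
    counts <- ind$counts
    res <- list(metadata = ind$metadata)
    prefix <- file.path(cfg$outdir, id)

    if ("filter" %in% cfg$stages) {
      log_stage("filter", id, ": ", nrow(counts$variants), " candidate variants")
      gm <- filter_variants(counts, cfg$filter, cfg$filter_mode)
      qc <- colony_qc(counts, gm, cfg$filter)
      write_genotype_matrix(gm, prefix)
      emit(paste0(prefix, "_genotypes.tsv"))
      emit(paste0(prefix, "_filter_report.tsv"))
      utils::write.table(qc, paste0(prefix, "_colony_qc.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE
      )
      emit(paste0(prefix, "_colony_qc.tsv"))
      res$genotypes <- gm
      res$qc <- qc
    }

    if ("tree" %in% cfg$stages) {
      som <- somatic_genotypes(res$genotypes)
      log_stage("tree", id, ": ", nrow(som$calls), " somatic variants")
      tree <- reconstruct_tree(res$genotypes)
      write_colony_tree(tree, paste0(prefix, "_tree_raw.nwk"), "raw_length")
      emit(paste0(prefix, "_tree_raw.nwk"))
      utils::write.table(tree$assignment, paste0(prefix, "_branch_assignment.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE
      )
      emit(paste0(prefix, "_branch_assignment.tsv"))
      res$tree <- tree
    }

    if ("time" %in% cfg$stages) {
      log_stage("time", id, ": scaling to age ", ind$metadata$age_years)
      sens <- estimate_sensitivity(
        mean_depth = stats::setNames(colMeans(counts$depth), counts$colonies),
        cfg = cfg$filter, method = "depth_model"
      )
      tree <- correct_terminal_branches(res$tree, sens)
      tree <- make_ultrametric(tree)
      tree <- scale_to_age(tree, ind$metadata$age_years)
      for (chan in c("corrected", "ultrametric", "time")) {
        col <- if (chan == "time") "time_span" else paste0(chan, "_length")
        write_colony_tree(tree, paste0(prefix, "_tree_", chan, ".nwk"), col)
        emit(paste0(prefix, "_tree_", chan, ".nwk"))
      }
      res$tree <- tree
    }

    if ("signatures" %in% cfg$stages) {
      log_stage("signatures", id, ": per-branch exposure fitting")
      ann <- res$genotypes$variants
      fits <- assign_branch_signatures(res$tree, ann, cfg$signatures)
      expo_tab <- do.call(rbind, lapply(names(fits), function(b) {
        f <- fits[[b]]
        if (!length(f$exposures)) {
          return(NULL)
        }
        data.frame(
          branch_id = b, signature = names(f$exposures),
          mutations = as.numeric(f$exposures),
          fraction = as.numeric(f$fractions),
          unassigned = f$unassigned, stringsAsFactors = FALSE
        )
      }))
      if (is.null(expo_tab)) {
        expo_tab <- data.frame(
          branch_id = character(0), signature = character(0),
          mutations = numeric(0), fraction = numeric(0), unassigned = numeric(0)
        )
      }
      utils::write.table(expo_tab, paste0(prefix, "_branch_exposures.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE
      )
      emit(paste0(prefix, "_branch_exposures.tsv"))
      res$branch_exposures <- fits
    }

    if ("burden" %in% cfg$stages) {
      col_meta <- data.frame(
        colony = counts$colonies,
        individual = id,
        age_years = ind$metadata$age_years,
        exposed = isTRUE(ind$metadata$exposed),
        stringsAsFactors = FALSE
      )
      res$burden <- count_burdens(res$genotypes, col_meta, qc = res$qc)
      burden_rows[[id]] <- res$burden
    }

    if ("architecture" %in% cfg$stages) {
      log_stage("architecture", id)
      res$architecture <- architecture_summary(
        res$tree,
        annotations = res$genotypes$variants
      )
      utils::write.table(res$architecture$report, paste0(prefix, "_clades.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE
      )
      emit(paste0(prefix, "_clades.tsv"))
    }
    results[[id]] <- res
  }

  if ("burden" %in% cfg$stages && length(burden_rows)) {
    tbl <- do.call(rbind, burden_rows)
    bt_path <- file.path(cfg$outdir, "burden_table.tsv")
    utils::write.table(tbl, bt_path, sep = "\t", quote = FALSE, row.names = FALSE)
    emit(bt_path)
    if (length(unique(tbl$individual)) >= 2 && all(table(tbl$individual) >= 2)) {
      log_stage("burden", "fitting mixed model on ", nrow(tbl), " colonies")
      fit <- fit_burden_model(tbl)
      fit_path <- file.path(cfg$outdir, "burden_fit.json")
      jsonlite::write_json(unclass(fit), fit_path, auto_unbox = TRUE, digits = NA)
      emit(fit_path)
      results$burden_fit <- fit
    }
  }

  manifest <- data.frame(
    file = sub(paste0("^", cfg$outdir, "/?"), "", files),
    md5 = unname(tools::md5sum(files)),
    stringsAsFactors = FALSE
  )
  manifest <- manifest[order(manifest$file), , drop = FALSE]
  jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"))
  log_stage("done", nrow(manifest), " files written")
  invisible(list(manifest = manifest, results = results))
}
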