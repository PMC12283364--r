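#' Variant- and colony-level filter thresholds
#'
#' All thresholds used to turn raw per-colony read counts into a
#' high-confidence somatic genotype matrix. Defaults follow the
#' high-depth colony WGS conventions for this assay class: a call needs
#' two or more supporting reads at VAF >= 0.2 (autosomes) or >= 0.4 (sex
#' chromosomes); sites with mean depth > 50 or < 8 across an individual's
#' colonies are unreliable and removed; variants present in strictly more
#' than half the colonies are treated as germline; colonies whose somatic
#' VAF distribution peaks below 0.4 are flagged as nonclonal.
#'
#' @param min_alt_reads Minimum alt reads to call a variant present (2).
#' @param vaf_autosome Minimum VAF on autosomes (0.2).
#' @param vaf_sex Minimum VAF on sex chromosomes (0.4).
#' @param germline_fraction Present-fraction above which (strictly) a
#'   variant is classed germline (0.5).
#' @param mean_depth_max,mean_depth_min Per-site mean-depth bounds (50, 8).
#' @param genotyping_min_depth Depth below which, with no alt support, a
#'   genotype is unknown rather than absent (6).
#' @param clonal_peak_vaf Peak-VAF threshold under which a colony is
#'   flagged nonclonal (0.4).
#' @param dup_share_threshold Jaccard overlap of somatic variant sets
#'   above which two colonies are technical duplicates (0.8).
#' @param low_cov_colony_mean Mean-depth threshold under which a colony is
#'   flagged low-coverage (8).
#' @param binom_germline_alpha Significance level of the aggregated exact
#'   binomial germline test in cohort mode (1e-5).
#' @param overdispersion_rho_min Beta-binomial dispersion below which a
#'   non-germline variant shared across colonies is a systematic artifact
#'   (0.1).
#' @return A validated list of class `filter_config`.
#' @export
filter_config <- function(min_alt_reads = 2,
                          vaf_autosome = 0.2,
                          vaf_sex = 0.4,
                          germline_fraction = 0.5,
                          mean_depth_max = 50,
                          mean_depth_min = 8,
                          genotyping_min_depth = 6,
                          clonal_peak_vaf = 0.4,
                          dup_share_threshold = 0.8,
                          low_cov_colony_mean = 8,
                          binom_germline_alpha = 1e-5,
                          overdispersion_rho_min = 0.1) {
  fracs <- c(vaf_autosome, vaf_sex, germline_fraction, clonal_peak_vaf, dup_share_threshold)
  if (any(fracs < 0 | fracs > 1)) stop("fractions must lie in [0, 1]")
  if (mean_depth_min > mean_depth_max) stop("depth bounds out of order")
  structure(as.list(environment()), class = "filter_config")
}

#' Genotype matrix of present/absent/unknown calls
#'
#' @param calls Integer matrix (variants x colonies): 1 = present,
#'   0 = absent, NA = unknown.
#' @param variants Variant annotation data frame (as in [read_counts]).
#' @param provenance Per-variant character verdict
#'   (kept / germline / depth_fail / artifact).
#' @return Object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, variants, provenance = rep("kept", nrow(calls))) {
  stopifnot(nrow(calls) == nrow(variants), length(provenance) == nrow(calls))
  rownames(calls) <- variants$variant_id
  structure(
    list(calls = calls, variants = variants, provenance = provenance),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(
    "genotype_matrix:", nrow(x$calls), "variants x", ncol(x$calls), "colonies;",
    sum(x$provenance == "kept"), "kept\n"
  )
  invisible(x)
}

#' Call genotypes from read counts
#'
#' A variant is present in a colony if it has at least `min_alt_reads`
#' supporting reads and a VAF at or above the chromosome-class threshold;
#' unknown if the site is too shallow to exclude it (depth below
#' `genotyping_min_depth` with fewer than `min_alt_reads` alt reads);
#' absent otherwise.
#'
#' @param counts A [read_counts].
#' @param cfg A [filter_config()].
#' @return A [genotype_matrix()] (calls only; no germline or depth
#'   filtering applied).
#' @export
genotype_calls <- function(counts, cfg = filter_config()) {
  stopifnot(inherits(counts, "read_counts"), inherits(cfg, "filter_config"))
  vaf_thresh <- ifelse(counts$variants$is_sex_chrom, cfg$vaf_sex, cfg$vaf_autosome)
  vaf <- counts$alt / pmax(counts$depth, 1L)
  present <- counts$alt >= cfg$min_alt_reads & vaf >= vaf_thresh
  unknown <- counts$depth < cfg$genotyping_min_depth & counts$alt < cfg$min_alt_reads
  calls <- matrix(0L, nrow(counts$alt), ncol(counts$alt),
    dimnames = dimnames(counts$alt)
  )
  calls[present] <- 1L
  calls[!present & unknown] <- NA_integer_
  genotype_matrix(calls, counts$variants)
}

#' Remove likely germline variants by the majority rule
#'
#' Variants called present in strictly more than `germline_fraction` of an
#' individual's colonies are removed as germline; variants present in
#' exactly half the colonies are retained (strict inequality).
#'
#' @param gm A [genotype_matrix()].
#' @param cfg A [filter_config()].
#' @return The genotype matrix restricted to retained variants; removed
#'   rows are reported in `attr(, "removed")` with provenance "germline".
#' @export
filter_germline_majority <- function(gm, cfg = filter_config()) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (ncol(gm$calls) < 2) stop("need at least two colonies")
  frac <- rowSums(gm$calls == 1L, na.rm = TRUE) / ncol(gm$calls)
  is_germ <- frac > cfg$germline_fraction
  out <- genotype_matrix(
    gm$calls[!is_germ, , drop = FALSE],
    gm$variants[!is_germ, , drop = FALSE],
    gm$provenance[!is_germ]
  )
  attr(out, "removed") <- data.frame(
    variant_id = gm$variants$variant_id[is_germ],
    reason = "germline", stringsAsFactors = FALSE
  )
  out
}

#' Retain variants at sites with reliable mean depth
#'
#' Sites with mean depth across the individual's colonies above
#' `mean_depth_max` (collapsed repeats) or below `mean_depth_min`
#' (uncallable) are removed.
#'
#' @param counts A [read_counts].
#' @param cfg A [filter_config()].
#' @return Data frame with `variant_id`, `mean_depth`, `retained`.
#' @export
filter_depth_sites <- function(counts, cfg = filter_config()) {
  stopifnot(inherits(counts, "read_counts"))
  md <- rowMeans(counts$depth)
  data.frame(
    variant_id = counts$variants$variant_id,
    mean_depth = md,
    retained = md >= cfg$mean_depth_min & md <= cfg$mean_depth_max,
    stringsAsFactors = FALSE
  )
}

# Beta-binomial log-likelihood and ML dispersion at fixed mean.
# rho is the standard overdispersion parameter: alpha = mu (1 - rho) / rho.
betabinom_loglik <- function(rho, alt, depth, mu) {
  a <- mu * (1 - rho) / rho
  b <- (1 - mu) * (1 - rho) / rho
  sum(lchoose(depth, alt) + lbeta(alt + a, depth - alt + b) - lbeta(a, b))
}

estimate_rho <- function(alt, depth, mu) {
  mu <- min(max(mu, 1e-4), 1 - 1e-4)
  keep <- depth > 0
  alt <- alt[keep]
  depth <- depth[keep]
  if (!length(alt)) {
    return(NA_real_)
  }
  opt <- stats::optimize(function(r) -betabinom_loglik(r, alt, depth, mu),
    interval = c(1e-6, 0.999)
  )
  opt$minimum
}

#' Cohort-scale binomial filtering of germline and systematic artifacts
#'
#' For large phylogenies (tens of colonies per individual), aggregate
#' read counts across colonies discriminate variant classes: a germline
#' heterozygous variant keeps an aggregated VAF indistinguishable from 0.5
#' (two-sided exact binomial test not rejected at `binom_germline_alpha`,
#' aggregated VAF within 0.4-0.6); a systematic artifact shows a similar
#' low VAF in every colony (beta-binomial dispersion across colonies below
#' `overdispersion_rho_min`); a true somatic variant is present at ~0.5 in
#' the colonies that carry it and absent elsewhere, which is strongly
#' overdispersed. Somatic variants are then genotyped with
#' [genotype_calls()].
#'
#' @param counts A [read_counts].
#' @param cfg A [filter_config()].
#' @return A [genotype_matrix()] over all input variants with provenance
#'   "kept" (somatic), "germline" or "artifact"; calls for non-kept rows
#'   are set absent.
#' @export
filter_binomial_cohort <- function(counts, cfg = filter_config()) {
  stopifnot(inherits(counts, "read_counts"))
  n_col <- length(counts$colonies)
  if (n_col < 40) {
    warning("binomial cohort filtering is designed for >= 40 colonies; got ", n_col)
  }
  A <- rowSums(counts$alt)
  D <- rowSums(counts$depth)
  n_var <- nrow(counts$alt)
  provenance <- character(n_var)
  for (i in seq_len(n_var)) {
    if (D[i] == 0) {
      warning("variant ", counts$variants$variant_id[i], " has zero aggregate depth; dropped")
      provenance[i] <- "depth_fail"
      next
    }
    agg_vaf <- A[i] / D[i]
    p_germ <- stats::binom.test(A[i], D[i], p = 0.5)$p.value
    if (p_germ >= cfg$binom_germline_alpha && agg_vaf >= 0.4 && agg_vaf <= 0.6) {
      provenance[i] <- "germline"
      next
    }
    if (A[i] > 0) {
      rho <- estimate_rho(counts$alt[i, ], counts$depth[i, ], agg_vaf)
      if (!is.na(rho) && rho < cfg$overdispersion_rho_min) {
        provenance[i] <- "artifact"
        next
      }
    }
    provenance[i] <- "kept"
  }
  gm <- genotype_calls(counts, cfg)
  calls <- gm$calls
  calls[provenance != "kept", ] <- 0L
  genotype_matrix(calls, counts$variants, provenance)
}

# Histogram-mode peak VAF with fixed 0.05 bins; deterministic surrogate for
# visual inspection of the VAF distribution. Ties resolve to the higher bin.
peak_vaf <- function(vafs, bin = 0.05) {
  if (!length(vafs)) {
    return(NA_real_)
  }
  breaks <- seq(0, 1, by = bin)
  idx <- pmin(findInterval(vafs, breaks, rightmost.closed = TRUE), length(breaks) - 1L)
  tab <- tabulate(idx, nbins = length(breaks) - 1L)
  best <- max(which(tab == max(tab)))
  (breaks[best] + breaks[best + 1L]) / 2
}

#' Per-colony quality control
#'
#' Classifies every colony as `pass`, `duplicate` (somatic variant set
#' Jaccard overlap with another colony above `dup_share_threshold`; the
#' lower-coverage member of the pair is flagged), `nonclonal` (the mode of
#' the somatic VAF histogram, 0.05 bins over sufficiently covered
#' supported sites, falls below `clonal_peak_vaf` -- the signature of a
#' colony founded by more than one cell or contaminated), or
#' `low_coverage`. Colonies with fewer than 20 somatic variants get
#' verdict `indeterminate` and are reported rather than dropped.
#'
#' @param counts A [read_counts].
#' @param gm A [genotype_matrix()] after germline removal.
#' @param cfg A [filter_config()].
#' @return Data frame with `colony`, `verdict`, `peak_vaf`, `mean_depth`,
#'   `n_somatic`.
#' @export
colony_qc <- function(counts, gm, cfg = filter_config()) {
  stopifnot(inherits(counts, "read_counts"), inherits(gm, "genotype_matrix"))
  colonies <- counts$colonies
  keep <- gm$provenance == "kept"
  calls <- gm$calls[keep, , drop = FALSE]
  kept_ids <- gm$variants$variant_id[keep]
  alt <- counts$alt[match(kept_ids, counts$variants$variant_id), , drop = FALSE]
  depth <- counts$depth[match(kept_ids, counts$variants$variant_id), , drop = FALSE]

  mean_depth <- colMeans(counts$depth)
  som_sets <- lapply(seq_along(colonies), function(j) which(calls[, j] == 1L))
  n_som <- lengths(som_sets)
  peak <- vapply(seq_along(colonies), function(j) {
    ok <- alt[, j] >= cfg$min_alt_reads & depth[, j] >= cfg$genotyping_min_depth
    peak_vaf(alt[ok, j] / depth[ok, j])
  }, numeric(1))

  verdict <- rep("pass", length(colonies))
  # duplicates: flag the lower-coverage member of each overlapping pair
  # (ties flag the later colony, so exactly one member survives)
  n_col <- length(colonies)
  if (n_col >= 2) {
    for (a in seq_len(n_col - 1L)) {
      for (b in (a + 1L):n_col) {
        u <- length(union(som_sets[[a]], som_sets[[b]]))
        if (u == 0) next
        jac <- length(intersect(som_sets[[a]], som_sets[[b]])) / u
        if (jac > cfg$dup_share_threshold) {
          worse <- if (mean_depth[a] < mean_depth[b]) a else b
          verdict[worse] <- "duplicate"
        }
      }
    }
  }
  nc <- verdict == "pass" & !is.na(peak) & peak < cfg$clonal_peak_vaf
  verdict[nc] <- "nonclonal"
  lc <- verdict == "pass" & mean_depth < cfg$low_cov_colony_mean
  verdict[lc] <- "low_coverage"
  verdict[n_som < 20 & verdict == "pass"] <- "indeterminate"

  data.frame(
    colony = colonies, verdict = verdict, peak_vaf = peak,
    mean_depth = mean_depth, n_somatic = n_som, stringsAsFactors = FALSE
  )
}

#' Run the high-depth ("simple") filter chain
#'
#' Genotype calling, strict-majority germline removal and mean-depth site
#' filtering, in that order, returning the somatic genotype matrix used
#' for burden counting and phylogeny reconstruction.
#'
#' @param counts A [read_counts].
#' @param cfg A [filter_config()].
#' @param mode `"simple"` (high-depth filter set) or `"cohort"` (aggregate
#'   binomial strategy for large phylogenies).
#' @return A [genotype_matrix()] whose provenance records every removal
#'   reason; rows are never invented, only dropped or relabelled.
#' @export
filter_variants <- function(counts, cfg = filter_config(),
                            mode = c("simple", "cohort")) {
  mode <- match.arg(mode)
  depth_rep <- filter_depth_sites(counts, cfg)
  if (mode == "cohort") {
    gm <- filter_binomial_cohort(counts, cfg)
    prov <- gm$provenance
    prov[!depth_rep$retained & prov == "kept"] <- "depth_fail"
    calls <- gm$calls
    calls[prov != "kept", ] <- 0L
    return(genotype_matrix(calls, gm$variants, prov))
  }
  gm <- genotype_calls(counts, cfg)
  frac <- rowSums(gm$calls == 1L, na.rm = TRUE) / ncol(gm$calls)
  prov <- rep("kept", nrow(gm$calls))
  prov[frac > cfg$germline_fraction] <- "germline"
  prov[!depth_rep$retained & prov == "kept"] <- "depth_fail"
  calls <- gm$calls
  calls[prov != "kept", ] <- 0L
  genotype_matrix(calls, gm$variants, prov)
}

#' Keep only rows classified somatic
#'
#' @param gm A [genotype_matrix()] with provenance.
#' @return The genotype matrix restricted to provenance "kept" rows.
#' @export
somatic_genotypes <- function(gm) {
  keep <- gm$provenance == "kept"
  genotype_matrix(
    gm$calls[keep, , drop = FALSE],
    gm$variants[keep, , drop = FALSE],
    gm$provenance[keep]
  )
}

#' Write a genotype matrix as TSV (1/0/NA calls plus a filter report)
#'
#' @param gm A [genotype_matrix()].
#' @param prefix Path prefix; writes `<prefix>_genotypes.tsv` and
#'   `<prefix>_filter_report.tsv`.
#' @export
write_genotype_matrix <- function(gm, prefix) {
  utils::write.table(gm$calls, paste0(prefix, "_genotypes.tsv"),
    sep = "\t", quote = FALSE, col.names = NA
  )
  utils::write.table(
    data.frame(
      variant_id = gm$variants$variant_id, verdict = gm$provenance,
      stringsAsFactors = FALSE
    ),
    paste0(prefix, "_filter_report.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(prefix)
}
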