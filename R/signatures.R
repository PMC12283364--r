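## 96-channel spectra, context-abundance correction, signature exposure
## fitting (non-negative least squares with the >5% contribution rule),
## de novo extraction by restarted KL-NMF, per-branch attribution and
## group comparison of exposures.

#' Build a 96-channel spectrum from mutation records
#'
#' @param mutations Data frame with a `channel_96` column (0-95; NA for
#'   unknown context).
#' @return Named integer vector of 96 channel counts; mutations with
#'   unknown channel are counted in `attr(, "unknown_channel")`.
#' @export
build_spectrum <- function(mutations) {
  ch <- mutations$channel_96
  unknown <- sum(is.na(ch))
  counts <- tabulate(ch[!is.na(ch)] + 1L, nbins = 96L)
  out <- stats::setNames(as.integer(counts), sbs96_channels())
  attr(out, "unknown_channel") <- unknown
  out
}

#' Correct a spectrum for trinucleotide context abundance
#'
#' Duplex-sequenced samples interrogate different amounts of each
#' trinucleotide context, so raw channel counts must be rescaled by
#' target/observed context frequency (then renormalised to the original
#' total) before spectra from different samples are comparable. Swapping
#' the two abundance arguments inverts the correction.
#'
#' @param spec 96-channel count (or probability) vector.
#' @param observed_abundance 32-context frequencies of the sample.
#' @param target_abundance 32-context frequencies of the reference scale.
#' @return Corrected 96-channel vector with the same total as `spec`.
#' @export
abundance_correct <- function(spec, observed_abundance, target_abundance) {
  stopifnot(length(spec) == 96, length(observed_abundance) == 32, length(target_abundance) == 32)
  ctx <- channel_to_context()
  if (any(observed_abundance[ctx] <= 0 & spec > 0)) {
    stop("zero observed context abundance for a channel with nonzero count")
  }
  total <- sum(spec)
  if (total == 0) {
    return(spec)
  }
  scaled <- spec * target_abundance[ctx] / observed_abundance[ctx]
  scaled * total / sum(scaled)
}

#' Cosine similarity between two 96-channel spectra
#'
#' The standard inner-product cosine; values above ~0.95 indicate that two
#' spectra likely reflect the same underlying process.
#'
#' @param u,v Non-negative numeric vectors of equal length.
#' @return Numeric in `[0, 1]`.
#' @export
cosine_similarity <- function(u, v) {
  if (sum(u) == 0 || sum(v) == 0) stop("cosine similarity undefined for zero vector")
  sum(u * v) / sqrt(sum(u^2) * sum(v^2))
}

#' Fit known-signature exposures to a spectrum
#'
#' Non-negative least squares of the spectrum on the signature
#' probability profiles, scaled to the spectrum total, followed by the
#' parsimony rule used for reporting: signatures contributing at most
#' `min_contribution` of the sample's mutation burden are removed
#' (smallest first) and the fit repeated until every retained signature
#' exceeds the threshold. The non-negative residual is reported as the
#' unassigned mutation count, so attributions plus unassigned always
#' equal the spectrum total.
#'
#' @param spec 96-channel count vector.
#' @param sigs Named list (or 96 x k matrix) of signature probability
#'   vectors.
#' @param min_contribution Minimum reported contribution as a fraction of
#'   the total burden (default 0.05).
#' @return List of class `exposure_fit`: `exposures` (named mutation
#'   counts over retained signatures), `unassigned`, `total`,
#'   `fractions`.
#' @export
fit_exposures <- function(spec, sigs, min_contribution = 0.05) {
  S <- if (is.matrix(sigs)) sigs else do.call(cbind, sigs)
  stopifnot(nrow(S) == 96, length(spec) == 96)
  total <- sum(spec)
  if (total <= 0) stop("spectrum total must be positive")
  active <- colnames(S)
  if (is.null(active)) active <- colnames(S) <- paste0("sig", seq_len(ncol(S)))
  p <- spec / total
  coef_for <- function(cols) {
    fit <- pracma::lsqnonneg(S[, cols, drop = FALSE], as.numeric(p))
    stats::setNames(fit$x, cols)
  }
  e <- coef_for(active)
  repeat {
    if (!length(e)) break
    small <- which(e <= min_contribution + 1e-12)
    if (!length(small)) break
    drop_sig <- names(small)[which.min(e[small])]
    active <- setdiff(active, drop_sig)
    if (!length(active)) {
      e <- numeric(0)
      break
    }
    e <- coef_for(active)
  }
  if (!length(e)) {
    warning("no signature retained; all mutations unassigned")
    return(structure(
      list(
        exposures = numeric(0), unassigned = total, total = total,
        fractions = numeric(0)
      ),
      class = "exposure_fit"
    ))
  }
  if (sum(e) > 1) e <- e / sum(e) # NNLS can slightly overshoot the simplex
  counts <- e * total
  structure(
    list(
      exposures = counts, unassigned = total - sum(counts), total = total,
      fractions = e
    ),
    class = "exposure_fit"
  )
}

#' @export
print.exposure_fit <- function(x, ...) {
  cat("exposure_fit over", x$total, "mutations\n")
  if (length(x$exposures)) {
    print(round(rbind(count = x$exposures, fraction = x$fractions), 3))
  }
  cat("unassigned:", round(x$unassigned, 1), "\n")
  invisible(x)
}

# KL-divergence NMF by multiplicative updates: X (96 x samples) ~ S %*% E.
kl_nmf <- function(X, k, max_iter = 400, tol = 1e-6) {
  m <- nrow(X)
  n <- ncol(X)
  S <- matrix(stats::runif(m * k, 0.1, 1), m, k)
  E <- matrix(stats::runif(k * n, 0.1, 1), k, n)
  eps <- 1e-12
  obj_old <- Inf
  for (it in seq_len(max_iter)) {
    R <- S %*% E + eps
    S <- S * ((X / R) %*% t(E)) / pmax(matrix(rowSums(E), m, k, byrow = TRUE), eps)
    R <- S %*% E + eps
    E <- E * (t(S) %*% (X / R)) / pmax(matrix(colSums(S), k, n), eps)
    if (it %% 20 == 0) {
      R <- S %*% E + eps
      obj <- sum(X * log((X + eps) / R) - X + R)
      if (abs(obj_old - obj) < tol * abs(obj_old + 1)) break
      obj_old <- obj
    }
  }
  R <- S %*% E + eps
  obj <- sum(X * log((X + eps) / R) - X + R)
  # normalise signatures to probability vectors, push scale into exposures
  sc <- colSums(S)
  S <- sweep(S, 2, pmax(sc, eps), "/")
  E <- sweep(E, 1, sc, "*")
  list(S = S, E = E, objective = obj)
}

#' De novo extraction of mutational signatures
#'
#' Non-negative matrix factorisation of the sample-by-channel count
#' matrix under the generalised Kullback-Leibler objective, with
#' `n_restarts` random restarts per candidate rank. The rank is selected
#' by requiring both a stable factorisation (mean silhouette of the
#' restart signatures clustered at that rank of at least `sil_threshold`)
#' and a material drop in reconstruction error over the previous rank
#' (relative improvement of at least `gain_threshold`) — the elbow rule.
#' The best-objective restart at the chosen rank is returned.
#'
#' @param spectra Sample x 96 count matrix.
#' @param k_range Candidate numbers of signatures (default 1:5).
#' @param seed Integer seed (restarts are reproducible).
#' @param n_restarts Restarts per rank (default 20).
#' @param sil_threshold,gain_threshold Model-selection thresholds
#'   (defaults 0.85 and 0.05).
#' @return List: `signatures` (named list of 96-channel probability
#'   vectors), `exposures` (samples x k counts), `k`, `selection` (per-k
#'   diagnostics).
#' @export
extract_denovo <- function(spectra, k_range = 1:5, seed = 1L, n_restarts = 20,
                           sil_threshold = 0.85, gain_threshold = 0.05) {
  X <- t(as.matrix(spectra)) # 96 x samples
  stopifnot(nrow(X) == 96)
  if (max(k_range) >= ncol(X)) stop("k must be smaller than the number of samples")
  set.seed(as.integer(seed))
  diag_rows <- list()
  best_by_k <- list()
  for (k in sort(k_range)) {
    runs <- lapply(seq_len(n_restarts), function(i) kl_nmf(X, k))
    objs <- vapply(runs, `[[`, numeric(1), "objective")
    best <- runs[[which.min(objs)]]
    # silhouette of restart signatures clustered into k groups (cosine)
    sil <- 1
    if (k > 1) {
      sig_mat <- do.call(cbind, lapply(runs, `[[`, "S")) # 96 x (k*restarts)
      sig_norm <- sweep(sig_mat, 2, sqrt(colSums(sig_mat^2)), "/")
      km <- stats::kmeans(t(sig_norm), centers = k, nstart = 10)
      dmat <- 1 - crossprod(sig_norm) # cosine distance
      sil <- mean(cluster::silhouette(km$cluster, dmatrix = dmat)[, "sil_width"])
    }
    diag_rows[[length(diag_rows) + 1L]] <- data.frame(
      k = k, error = best$objective, silhouette = sil
    )
    best_by_k[[as.character(k)]] <- best
  }
  selection <- do.call(rbind, diag_rows)
  selection$gain <- c(
    NA,
    -diff(selection$error) / pmax(utils::head(selection$error, -1), 1e-12)
  )
  ok <- selection$silhouette >= sil_threshold &
    (is.na(selection$gain) | selection$gain >= gain_threshold)
  # largest k whose own gain and all previous gains pass the elbow rule
  chosen <- selection$k[1]
  for (i in seq_len(nrow(selection))) {
    if (all(ok[seq_len(i)])) chosen <- selection$k[i] else break
  }
  best <- best_by_k[[as.character(chosen)]]
  sig_list <- lapply(seq_len(chosen), function(j) {
    stats::setNames(best$S[, j], sbs96_channels())
  })
  names(sig_list) <- paste0("denovo", seq_len(chosen))
  expo <- t(best$E)
  colnames(expo) <- names(sig_list)
  rownames(expo) <- rownames(spectra)
  list(signatures = sig_list, exposures = expo, k = chosen, selection = selection)
}

#' Attribute signatures to every branch of a colony tree
#'
#' Fits known-signature exposures to the spectrum of each branch's
#' assigned mutations. Branches with fewer than `min_mutations` mutations
#' give unstable non-negative fits, so they inherit the exposure
#' fractions of the pooled fit over their parent's whole clade (all
#' mutations assigned within the subtree rooted at the parent node),
#' scaled to the branch's own mutation count.
#'
#' @param tree A [colony_tree] with branch mutation assignments.
#' @param mutations Data frame with `variant_id` and `channel_96` for all
#'   assigned mutations.
#' @param sigs Named list of signature probability vectors.
#' @param min_contribution Reporting threshold (default 0.05).
#' @param min_mutations Minimum branch size for a standalone fit
#'   (default 20).
#' @return Named list over branch ids of `exposure_fit` objects (empty
#'   branches yield a zero-total placeholder).
#' @export
assign_branch_signatures <- function(tree, mutations, sigs,
                                     min_contribution = 0.05,
                                     min_mutations = 20) {
  stopifnot(inherits(tree, "colony_tree"))
  chan <- stats::setNames(mutations$channel_96, mutations$variant_id)
  branch_ids <- tree$branch$node
  # pooled clade mutation lists (subtree of each node, branch included)
  po <- postorder_parent(tree$parent, tree$root)
  clade_muts <- vector("list", length(tree$parent))
  for (v in po$order) {
    own <- if (v == tree$root) character(0) else tree$mutations[[as.character(v)]]
    clade_muts[[v]] <- c(own, unlist(lapply(po$children[[v]], function(c) clade_muts[[c]])))
  }
  out <- list()
  for (v in branch_ids) {
    ids <- tree$mutations[[as.character(v)]]
    n_b <- length(ids)
    if (n_b == 0) {
      out[[as.character(v)]] <- structure(
        list(exposures = numeric(0), unassigned = 0, total = 0, fractions = numeric(0)),
        class = "exposure_fit"
      )
      next
    }
    if (n_b >= min_mutations) {
      spec <- build_spectrum(data.frame(channel_96 = unname(chan[ids])))
      out[[as.character(v)]] <- fit_exposures(spec, sigs, min_contribution)
    } else {
      pool_ids <- clade_muts[[tree$parent[v]]]
      spec <- build_spectrum(data.frame(channel_96 = unname(chan[pool_ids])))
      pooled <- fit_exposures(spec, sigs, min_contribution)
      frac <- pooled$fractions
      out[[as.character(v)]] <- structure(
        list(
          exposures = frac * n_b, unassigned = n_b * max(0, 1 - sum(frac)),
          total = n_b, fractions = frac
        ),
        class = "exposure_fit"
      )
    }
  }
  out
}

#' Compare signature exposures between two groups
#'
#' Per-signature two-sided pooled-variance (equal-variance) t tests of
#' exposure fractions in exposed versus unexposed samples, with
#' Benjamini-Hochberg and Bonferroni multiple-testing adjustments across
#' signatures.
#'
#' @param group_a,group_b Matrices or data frames (samples x signatures)
#'   of exposure fractions with matching columns.
#' @return Data frame: `signature`, `mean_a`, `mean_b`, `t`, `df`, `p`,
#'   `p_fdr`, `p_bonferroni`, `degenerate`.
#' @export
compare_exposures <- function(group_a, group_b) {
  A <- as.matrix(group_a)
  B <- as.matrix(group_b)
  stopifnot(ncol(A) == ncol(B), nrow(A) >= 2, nrow(B) >= 2)
  sig_names <- colnames(A)
  if (is.null(sig_names)) sig_names <- paste0("sig", seq_len(ncol(A)))
  res <- lapply(seq_len(ncol(A)), function(j) {
    a <- A[, j]
    b <- B[, j]
    na <- length(a)
    nb <- length(b)
    df <- na + nb - 2
    sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / df
    degenerate <- FALSE
    if (sp2 <= 0) {
      if (mean(a) == mean(b)) {
        t_stat <- 0
        p <- 1
      } else {
        t_stat <- sign(mean(a) - mean(b)) * Inf
        p <- 0
        degenerate <- TRUE
      }
    } else {
      t_stat <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
      p <- 2 * stats::pt(-abs(t_stat), df)
    }
    data.frame(
      signature = sig_names[j], mean_a = mean(a), mean_b = mean(b),
      t = t_stat, df = df, p = p, degenerate = degenerate,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, res)
  out$p_fdr <- stats::p.adjust(out$p, method = "BH")
  out$p_bonferroni <- stats::p.adjust(out$p, method = "bonferroni")
  out[, c(
    "signature", "mean_a", "mean_b", "t", "df", "p", "p_fdr",
    "p_bonferroni", "degenerate"
  )]
}

#' Write a signature set as TSV (96 fixed-order rows x named columns)
#' @param sigs Named list of 96-channel probability vectors.
#' @param path Output path.
#' @export
write_signatures <- function(sigs, path) {
  m <- do.call(cbind, sigs)
  rownames(m) <- sbs96_channels()
  utils::write.table(m, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}

#' Read a signature set written by [write_signatures()]
#' @param path Input path.
#' @return Named list of 96-channel probability vectors.
#' @export
read_signatures <- function(path) {
  m <- as.matrix(utils::read.delim(path, row.names = 1, check.names = FALSE))
  sigs <- lapply(seq_len(ncol(m)), function(j) stats::setNames(m[, j], rownames(m)))
  names(sigs) <- colnames(m)
  sigs
}
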