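## Per-colony mutation burden counting and the Poisson identity-link
## mixed-effects model of burden against age and mutagen exposure.
##
## The model for colony j of individual i is
##   y_ij ~ Poisson(mu_ij),  mu_ij = b0 + b1 * age_i + b2 * exposed_i + u_i,
##   u_i ~ Normal(0, sigma^2),
## i.e. an identity link (burdens are additive in years and in exposure
## effects, not multiplicative) with a per-individual random intercept.
## The marginal likelihood integrates u_i by adaptive Gauss-Hermite
## quadrature; the identity link can push the mean non-positive during
## optimisation, so the mean is clamped at 1e-6 inside the likelihood.

#' Count per-colony somatic mutation burdens
#'
#' @param gm A filtered [genotype_matrix()]; burden is the number of
#'   somatic variants called present in the colony.
#' @param metadata Data frame with columns `colony`, `individual`,
#'   `age_years`, `exposed` (one row per colony), or per-individual rows
#'   plus a `colony`-to-individual mapping embedded in colony names.
#' @param qc Optional result of [colony_qc()]; colonies with a verdict
#'   other than "pass" are excluded.
#' @return Data frame of class `burden_table`: `colony`, `individual`,
#'   `age_years`, `exposed`, `sbs_burden`, `mean_depth` (if available).
#' @export
count_burdens <- function(gm, metadata, qc = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  gm <- somatic_genotypes(gm)
  colonies <- colnames(gm$calls)
  idx <- match(colonies, metadata$colony)
  if (anyNA(idx)) {
    stop("colony missing from metadata: ", paste(colonies[is.na(idx)], collapse = ", "))
  }
  out <- data.frame(
    colony = colonies,
    individual = metadata$individual[idx],
    age_years = metadata$age_years[idx],
    exposed = metadata$exposed[idx],
    sbs_burden = as.integer(colSums(gm$calls == 1L, na.rm = TRUE)),
    stringsAsFactors = FALSE
  )
  if (!is.null(metadata$mean_depth)) out$mean_depth <- metadata$mean_depth[idx]
  if (!is.null(qc)) {
    keep <- qc$verdict[match(out$colony, qc$colony)] == "pass"
    out <- out[keep, , drop = FALSE]
  }
  class(out) <- c("burden_table", "data.frame")
  out
}

# Gauss-Hermite nodes/weights for int f(x) exp(-x^2) dx (Golub-Welsch).
gauss_hermite <- function(n) {
  if (n == 1) {
    return(list(x = 0, w = sqrt(pi)))
  }
  off <- sqrt(seq_len(n - 1) / 2)
  J <- matrix(0, n, n)
  J[cbind(seq_len(n - 1), 2:n)] <- off
  J[cbind(2:n, seq_len(n - 1))] <- off
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(x = e$values[ord], w = sqrt(pi) * e$vectors[1, ord]^2)
}

# Per-individual integrand: g(u) = sum_j log Pois(y_j; eta_j + u) - u^2/(2s^2)
# (Poisson log-density up to the y! constant, which cancels nowhere and is
# added once outside). Returns the log marginal via adaptive GH.
agh_log_marginal <- function(y, eta, sigma, gh) {
  clamp <- 1e-6
  g <- function(u) {
    mu <- pmax(eta + u, clamp)
    sum(y * log(mu) - mu) - u^2 / (2 * sigma^2)
  }
  # Newton search for the mode
  u_hat <- 0
  for (it in 1:50) {
    mu <- pmax(eta + u_hat, clamp)
    live <- eta + u_hat > clamp
    g1 <- sum((y / mu - 1) * live) - u_hat / sigma^2
    g2 <- -sum((y / mu^2) * live) - 1 / sigma^2
    step <- g1 / g2
    u_new <- u_hat - step
    # backtrack if the step overshoots into a lower g
    tries <- 0
    while (g(u_new) < g(u_hat) - 1e-12 && tries < 30) {
      u_new <- (u_new + u_hat) / 2
      tries <- tries + 1
    }
    if (abs(u_new - u_hat) < 1e-10) {
      u_hat <- u_new
      break
    }
    u_hat <- u_new
  }
  mu <- pmax(eta + u_hat, clamp)
  g2 <- -sum(y / mu^2) - 1 / sigma^2
  s_hat <- 1 / sqrt(-g2)
  nodes <- u_hat + sqrt(2) * s_hat * gh$x
  gv <- vapply(nodes, g, numeric(1))
  m <- max(gv + gh$x^2)
  # log integral of exp(g(u)) du
  log_int <- log(sqrt(2) * s_hat) + m + log(sum(gh$w / sqrt(pi) * exp(gv + gh$x^2 - m))) +
    0.5 * log(pi)
  log_int - log(sqrt(2 * pi) * sigma)
}

#' Fit the Poisson identity-link mixed-effects burden model
#'
#' Maximum-likelihood fit of
#' `sbs_burden ~ age + exposure + (1 | individual)` with a Poisson
#' response and identity link, the per-individual Gaussian random
#' intercept integrated by adaptive Gauss-Hermite quadrature. The
#' optimiser starts deterministically at method-of-moments values (OLS
#' coefficients; residual spread of individual means). A likelihood-ratio
#' p-value for the exposure term is reported when both exposure groups
#' are present.
#'
#' @param tbl A [count_burdens()] table (or any data frame with
#'   `individual`, `age_years`, `exposed`, `sbs_burden`).
#' @param n_quad Number of quadrature nodes (default 21).
#' @return List of class `burden_fit`: `intercept`, `slope`,
#'   `exposure_effect` (NA if inestimable), `random_intercept_sd`,
#'   `loglik`, `converged`, `exposure_p`, `n_individuals`, `n_colonies`.
#' @export
fit_burden_model <- function(tbl, n_quad = 21) {
  stopifnot(all(c("individual", "age_years", "exposed", "sbs_burden") %in% names(tbl)))
  ind <- factor(tbl$individual)
  if (nlevels(ind) < 2) stop("need at least two individuals")
  if (any(table(ind) < 2)) stop("need at least two colonies per individual")
  y <- round(tbl$sbs_burden)
  age <- tbl$age_years
  expo <- as.numeric(tbl$exposed)
  use_expo <- length(unique(expo)) > 1
  gh <- gauss_hermite(n_quad)
  lgamma_const <- sum(lgamma(y + 1))

  nll <- function(par, with_expo) {
    b0 <- par[1]
    b1 <- par[2]
    b2 <- if (with_expo) par[3] else 0
    sigma <- par[length(par)]
    if (sigma <= 0) {
      return(1e10)
    }
    eta <- b0 + b1 * age + b2 * expo
    ll <- 0
    for (lev in levels(ind)) {
      sel <- ind == lev
      ll <- ll + agh_log_marginal(y[sel], eta[sel], sigma, gh)
    }
    -(ll - lgamma_const)
  }

  # method-of-moments start
  ols <- if (use_expo) {
    stats::lm(y ~ age + expo)
  } else {
    stats::lm(y ~ age)
  }
  cf <- stats::coef(ols)
  ind_resid <- tapply(stats::resid(ols), ind, mean)
  sd0 <- max(stats::sd(ind_resid), 1)
  start <- if (use_expo) c(cf[1], cf[2], cf[3], sd0) else c(cf[1], cf[2], sd0)
  lower <- c(rep(-Inf, length(start) - 1), 1e-4)

  opt <- stats::optim(start, nll,
    with_expo = use_expo, method = "L-BFGS-B",
    lower = lower, control = list(maxit = 500)
  )
  converged <- opt$convergence == 0
  if (!converged) warning("burden model optimiser did not converge (code ", opt$convergence, ")")

  exposure_p <- NA_real_
  if (use_expo) {
    opt0 <- stats::optim(c(start[1], start[2], start[length(start)]), nll,
      with_expo = FALSE, method = "L-BFGS-B",
      lower = c(-Inf, -Inf, 1e-4), control = list(maxit = 500)
    )
    lr <- 2 * (opt0$value - opt$value)
    exposure_p <- stats::pchisq(max(lr, 0), df = 1, lower.tail = FALSE)
  }

  structure(list(
    intercept = unname(opt$par[1]),
    slope = unname(opt$par[2]),
    exposure_effect = if (use_expo) unname(opt$par[3]) else NA_real_,
    random_intercept_sd = unname(opt$par[length(opt$par)]),
    loglik = -opt$value,
    converged = converged,
    exposure_p = exposure_p,
    n_individuals = nlevels(ind),
    n_colonies = nrow(tbl)
  ), class = "burden_fit")
}

#' @export
print.burden_fit <- function(x, ...) {
  cat("Poisson identity-link mixed-model fit\n")
  cat(sprintf(
    "  intercept (SBS at birth): %.2f\n  slope (SBS/year): %.3f\n",
    x$intercept, x$slope
  ))
  if (!is.na(x$exposure_effect)) {
    cat(sprintf(
      "  exposure effect (SBS): %.1f  (LRT p = %.3g)\n",
      x$exposure_effect, x$exposure_p
    ))
  }
  cat(sprintf(
    "  random intercept SD: %.2f   loglik: %.2f   converged: %s\n",
    x$random_intercept_sd, x$loglik, x$converged
  ))
  invisible(x)
}

#' Expected mutation burden at a given age
#'
#' Linear clock prediction `intercept + slope * age`. With the reference
#' coefficients (intercept 54.57 SBS at birth, slope 16.832 SBS/year)
#' this gives e.g. 273.4 expected SBS at age 13.
#'
#' @param fit A `burden_fit`, or NULL to use `intercept`/`slope` directly.
#' @param age_years Age (>= 0).
#' @param intercept,slope Coefficients used when `fit` is NULL.
#' @return Expected SBS count (unrounded).
#' @export
predict_burden <- function(fit = NULL, age_years,
                           intercept = 54.57, slope = 16.832) {
  if (any(age_years < 0)) stop("age must be non-negative")
  if (!is.null(fit)) {
    intercept <- fit$intercept
    slope <- fit$slope
  }
  intercept + slope * age_years
}

#' Poisson prediction interval for a mutation burden
#'
#' Central interval of a Poisson count at the given mean: the lower bound
#' is the smallest k with CDF >= (1-level)/2 and the upper bound the
#' smallest k with CDF >= 1-(1-level)/2.
#'
#' @param mean Expected count (> 0).
#' @param level Coverage level in (0, 1), default 0.95.
#' @return Integer vector `c(lower, upper)`.
#' @export
poisson_prediction_interval <- function(mean, level = 0.95) {
  if (mean <= 0) stop("mean must be positive")
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  alpha <- (1 - level) / 2
  c(
    lower = stats::qpois(alpha, mean),
    upper = stats::qpois(1 - alpha, mean)
  )
}

#' Fold increase of the average mutation rate over a period
#'
#' Expresses an additional mutation load acquired over a period as a
#' multiple of the baseline accrual rate: `(extra_sbs / years) /
#' baseline_rate`. An extra 1,000 SBS in one year against the ~18
#' SBS/year baseline of adult HSPCs is a >50-fold rate increase.
#'
#' @param extra_sbs Additional mutations acquired.
#' @param years Duration of the period (> 0).
#' @param baseline_rate Baseline SBS per year (default 18).
#' @return Fold change (0 when `extra_sbs` is 0).
#' @export
fold_rate_increase <- function(extra_sbs, years, baseline_rate = 18) {
  if (years <= 0) stop("years must be positive")
  if (baseline_rate <= 0) stop("baseline_rate must be positive")
  (extra_sbs / years) / baseline_rate
}
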