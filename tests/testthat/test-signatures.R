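test_that("spectra are channel histograms", {
  m <- data.frame(channel_96 = rep(2L, 100)) # A[C>A]G
  spec <- build_spectrum(m)
  expect_equal(unname(spec[3]), 100L)
  expect_equal(sum(spec), 100L)
  empty <- build_spectrum(data.frame(channel_96 = integer(0)))
  expect_true(all(empty == 0L))
  with_na <- build_spectrum(data.frame(channel_96 = c(0L, NA, 5L)))
  expect_equal(sum(with_na), 2L)
  expect_equal(attr(with_na, "unknown_channel"), 1L)
})

test_that("abundance correction rescales by context and round-trips", {
  spec <- build_spectrum(data.frame(channel_96 = rep(c(0L, 40L), c(60, 40))))
  target <- rep(1 / 32, 32)
  expect_equal(abundance_correct(spec, target, target), spec) # identity
  observed <- target
  ctx0 <- channel_to_context()[1] # context of channel 0
  observed[ctx0] <- 2 * observed[ctx0]
  observed <- observed / sum(observed)
  corr <- abundance_correct(spec, observed, target)
  # channel observed at twice its target context frequency halves in
  # relative weight before renormalisation
  ratio_before <- spec[1] / spec[41]
  ratio_after <- corr[1] / corr[41]
  expect_equal(unname(ratio_after / ratio_before), 0.5, tolerance = 1e-9)
  expect_equal(sum(corr), sum(spec)) # total preserved
  # swapping arguments inverts
  back <- abundance_correct(corr, target, observed)
  expect_equal(unname(as.numeric(back)), unname(as.numeric(spec)),
    tolerance = 1e-9, ignore_attr = TRUE
  )
  zero <- rep(0L, 96)
  expect_equal(abundance_correct(zero, observed, target), zero)
})

test_that("cosine similarity handles the standard cases", {
  v <- runif(96)
  expect_equal(cosine_similarity(v, v), 1)
  a <- c(rep(1, 48), rep(0, 48))
  b <- c(rep(0, 48), rep(1, 48))
  expect_equal(cosine_similarity(a, b), 0)
  u <- c(1, 1, rep(0, 94))
  w <- c(1, 0, 1, rep(0, 93))
  expect_equal(cosine_similarity(u, w), 0.5)
  expect_error(cosine_similarity(u, rep(0, 96)), "zero")
})

test_that("exact mixtures are recovered and conservation holds", {
  sigs <- example_signatures()
  spec <- 1000 * (0.7 * sigs$sig_alkyl + 0.3 * sigs$sig_platinum)
  fit <- fit_exposures(spec, sigs[c("sig_alkyl", "sig_platinum")])
  expect_equal(unname(fit$exposures["sig_alkyl"]), 700, tolerance = 1)
  expect_equal(unname(fit$exposures["sig_platinum"]), 300, tolerance = 1)
  expect_lt(fit$unassigned, 1)
  expect_equal(sum(fit$exposures) + fit$unassigned, fit$total, tolerance = 0.5)
})

test_that("the >5% contribution rule prunes minor components", {
  sigs <- example_signatures()
  spec <- 5000 * (0.56 * sigs$sig_clock + 0.4 * sigs$sig_alkyl +
    0.04 * sigs$sig_platinum)
  fit <- fit_exposures(spec, sigs[c("sig_clock", "sig_alkyl", "sig_platinum")])
  expect_false("sig_platinum" %in% names(fit$exposures))
  expect_true(all(fit$fractions > 0.05))
  # lowering the threshold keeps the minor component
  fit2 <- fit_exposures(spec, sigs[c("sig_clock", "sig_alkyl", "sig_platinum")],
    min_contribution = 0.01
  )
  expect_true("sig_platinum" %in% names(fit2$exposures))
  expect_gte(length(fit2$exposures), length(fit$exposures))
})

test_that("multinomial samples recover mixture fractions within L1 0.05", {
  sigs <- example_signatures()
  truth <- c(sig_clock = 0.5, sig_alkyl = 0.3, sig_platinum = 0.2)
  p <- truth[1] * sigs$sig_clock + truth[2] * sigs$sig_alkyl +
    truth[3] * sigs$sig_platinum
  set.seed(77)
  spec <- as.integer(rmultinom(1, 5000, p))
  fit <- fit_exposures(spec, sigs[names(truth)])
  l1 <- sum(abs(fit$fractions[names(truth)] - truth), na.rm = TRUE)
  expect_lt(l1, 0.05)
})

test_that("de novo extraction recovers planted signatures and is seeded", {
  sigs <- example_signatures()
  set.seed(5)
  n_samp <- 30
  mix <- cbind(runif(n_samp, 0.2, 0.8))
  spectra <- t(vapply(seq_len(n_samp), function(i) {
    p <- mix[i] * sigs$sig_clock + (1 - mix[i]) * sigs$sig_alkyl
    as.numeric(rmultinom(1, 3000, p))
  }, numeric(96)))
  res <- extract_denovo(spectra, k_range = 1:3, seed = 11, n_restarts = 8)
  expect_equal(res$k, 2)
  best_cos <- vapply(
    list(sigs$sig_clock, sigs$sig_alkyl),
    function(s) max(vapply(res$signatures, cosine_similarity, numeric(1), u = s)),
    numeric(1)
  )
  expect_true(all(best_cos >= 0.95))
  res2 <- extract_denovo(spectra, k_range = 1:3, seed = 11, n_restarts = 8)
  expect_identical(res$signatures, res2$signatures)
})

test_that("rank-1 data select a single signature", {
  sigs <- example_signatures()
  set.seed(6)
  spectra <- t(vapply(1:12, function(i) {
    as.numeric(rmultinom(1, 4000, sigs$sig_clock))
  }, numeric(96)))
  res <- extract_denovo(spectra, k_range = 1:3, seed = 2, n_restarts = 6)
  expect_equal(res$k, 1)
  expect_gte(cosine_similarity(res$signatures[[1]], sigs$sig_clock), 0.99)
})

test_that("branch attribution identifies pulse-signature branches", {
  sigs <- example_signatures()
  tree <- quartet_tree()
  set.seed(13)
  chan_clock <- sample.int(96, 120, replace = TRUE, prob = sigs$sig_clock) - 1L
  chan_alkyl <- sample.int(96, 80, replace = TRUE, prob = sigs$sig_alkyl) - 1L
  ids <- paste0("m", seq_len(200))
  ann <- data.frame(
    variant_id = ids,
    channel_96 = c(chan_clock, chan_alkyl), stringsAsFactors = FALSE
  )
  tree$mutations[["6"]] <- ids[1:120] # clock branch
  tree$mutations[["7"]] <- ids[121:200] # pure chemo branch
  tree$branch$raw_length <- vapply(
    tree$mutations[as.character(tree$branch$node)], length, integer(1)
  )
  fits <- assign_branch_signatures(tree, ann, sigs[c("sig_clock", "sig_alkyl")])
  chemo <- fits[["7"]]
  expect_gte(unname(chemo$fractions["sig_alkyl"]), 0.9)
  # empty branch yields an empty exposure
  expect_equal(fits[["1"]]$total, 0)
  # small branches inherit the parent-clade pooled fractions
  tree$mutations[["1"]] <- ids[1:5]
  tree$branch$raw_length[tree$branch$node == 1L] <- 5
  fits2 <- assign_branch_signatures(tree, ann, sigs[c("sig_clock", "sig_alkyl")])
  expect_equal(fits2[["1"]]$total, 5)
  expect_equal(sum(fits2[["1"]]$exposures) + fits2[["1"]]$unassigned, 5,
    tolerance = 0.5
  )
})

test_that("group comparison reproduces the pooled t test and adjustments", {
  a <- matrix(c(1, 2, 3), ncol = 1, dimnames = list(NULL, "s1"))
  b <- matrix(c(4, 5, 6), ncol = 1, dimnames = list(NULL, "s1"))
  res <- compare_exposures(a, b)
  expect_equal(res$t, -3.674235, tolerance = 1e-6)
  expect_equal(res$df, 4)
  expect_equal(res$p, 0.02131164, tolerance = 1e-6)
  # identical groups
  same <- compare_exposures(a, a)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  # BH and Bonferroni columns match hand-written step-up / scaling oracles
  set.seed(99)
  A <- matrix(rnorm(5 * 4), 5, 4, dimnames = list(NULL, paste0("s", 1:4)))
  B <- matrix(rnorm(5 * 4, mean = c(0, 0.5, 1, 2)), 5, 4, byrow = TRUE,
    dimnames = list(NULL, paste0("s", 1:4))
  )
  res2 <- compare_exposures(A, B)
  bh_oracle <- function(p) {
    m <- length(p)
    o <- order(p, decreasing = TRUE)
    adj <- pmin(1, cummin(m / seq(m, 1) * p[o]))
    adj[order(o)]
  }
  expect_equal(res2$p_fdr, bh_oracle(res2$p))
  expect_equal(res2$p_bonferroni, pmin(1, res2$p * 4))
  # degenerate zero-variance unequal means
  za <- matrix(c(1, 1), ncol = 1, dimnames = list(NULL, "s1"))
  zb <- matrix(c(2, 2), ncol = 1, dimnames = list(NULL, "s1"))
  deg <- compare_exposures(za, zb)
  expect_true(deg$degenerate)
  expect_equal(deg$p, 0)
})
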