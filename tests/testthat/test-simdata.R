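test_that("simulation is deterministic under a fixed seed", {
  cfg <- sim_config(ages_years = 30, colonies_per_individual = 6, seed = 5)
  a <- simulate_individual(cfg, 1)
  b <- simulate_individual(cfg, 1)
  expect_identical(a$counts$alt, b$counts$alt)
  expect_identical(a$counts$depth, b$counts$depth)
  expect_identical(a$truth$catalog, b$truth$catalog)
  expect_identical(a$truth$tree$parent, b$truth$tree$parent)
})

test_that("mean true burden matches the clock closed form at age 40", {
  # five independent individuals of 60 colonies give 300 colonies; the
  # colony-mean within an individual is correlated through shared branches,
  # so the tolerance reflects between-individual spread, not Poisson error
  cfg <- sim_config(
    ages_years = rep(40, 5), colonies_per_individual = 60,
    n_germline_het = 0, artifact_rate = 0, mean_depth = 25, seed = 91
  )
  coh <- simulate_cohort(cfg)
  tbl <- true_burden_table(coh)
  expect_gt(nrow(tbl), 200)
  expected <- 54.57 + 16.832 * 40
  expect_lt(abs(mean(tbl$sbs_burden) - expected), 40)
})

test_that("genealogy is anchored at birth and tips at the sampling age", {
  cfg <- sim_config(ages_years = 55, colonies_per_individual = 12, seed = 2)
  sim <- simulate_individual(cfg, 1)
  tree <- sim$truth$tree
  expect_equal(tree$node_age[tree$root], 0)
  expect_equal(unname(tree$node_age[seq_len(tree$n_tips)]), rep(55, 12))
  # parent always older than child
  for (i in seq_len(nrow(tree$branch))) {
    expect_lt(
      tree$node_age[tree$branch$parent[i]],
      tree$node_age[tree$branch$node[i]] + 1e-12
    )
  }
})

test_that("variant classes partition the read-count rows", {
  cfg <- sim_config(ages_years = 20, colonies_per_individual = 5, seed = 3)
  sim <- simulate_individual(cfg, 1)
  cat_ <- sim$truth$catalog
  expect_setequal(unique(cat_$class), c("somatic", "germline", "artifact"))
  expect_identical(cat_$variant_id, sim$counts$variants$variant_id)
  expect_false(anyDuplicated(cat_$variant_id) > 0)
  # every somatic mutation sits on exactly one branch
  som <- cat_[cat_$class == "somatic", ]
  expect_true(all(som$branch_id %in% sim$truth$tree$branch$node))
  expect_equal(
    sum(sim$truth$tree$branch$raw_length), nrow(som)
  )
})

test_that("a zero-rate pulse contributes no mutations", {
  cfg <- sim_config(
    ages_years = 30, colonies_per_individual = 5,
    chemo_pulses = list(list(
      age_years = 10, expected_extra_sbs = 0,
      signature_id = "sig_alkyl"
    )), seed = 4
  )
  sim <- simulate_individual(cfg, 1)
  expect_equal(sum(sim$truth$catalog$true_signature == "sig_alkyl"), 0)
})

test_that("pulse mutations lie on branches spanning the pulse age", {
  cfg <- sim_config(
    ages_years = 40, colonies_per_individual = 10,
    chemo_pulses = list(list(
      age_years = 12, expected_extra_sbs = 200,
      signature_id = "sig_alkyl"
    )), seed = 8
  )
  sim <- simulate_individual(cfg, 1)
  tree <- sim$truth$tree
  pulse <- sim$truth$catalog[sim$truth$catalog$true_signature == "sig_alkyl", ]
  expect_gt(nrow(pulse), 0)
  for (v in unique(pulse$branch_id)) {
    expect_lt(tree$node_age[tree$parent[v]], 12)
    expect_gte(tree$node_age[v], 12)
  }
})

test_that("cohort metadata carries exposure flags and burdens regress on age", {
  ages <- c(1, 10, 20, 30, 40, 50, 60, 70, 80)
  cfg <- sim_config(
    ages_years = ages, colonies_per_individual = 8,
    n_germline_het = 0, artifact_rate = 0, seed = 12
  )
  coh <- simulate_cohort(cfg)
  expect_false(any(coh$metadata$exposed))
  tbl <- true_burden_table(coh)
  means <- tapply(tbl$sbs_burden, tbl$individual, mean)
  ind_age <- coh$metadata$age_years[match(names(means), coh$metadata$individual)]
  fit <- stats::lm(means ~ ind_age)
  expect_lt(abs(unname(stats::coef(fit)[2]) - 16.832) / 16.832, 0.15)
})

test_that("duplex spectra reproduce their generating mixture", {
  cfg <- sim_config(ages_years = 40, seed = 21)
  set.seed(1)
  one <- simulate_duplex_spectrum(cfg, c(sig_alkyl = 1), n = 10000)
  expect_equal(sum(one$counts), 10000)
  expect_gte(
    cosine_similarity(one$counts, cfg$signature_defs$sig_alkyl), 0.99
  )
  zero <- simulate_duplex_spectrum(cfg, c(sig_alkyl = 1), n = 0)
  expect_true(all(zero$counts == 0))
  expect_error(
    simulate_duplex_spectrum(cfg, c(sig_alkyl = 0, sig_flat = 0)),
    "zero"
  )
})

test_that("driver advantage produces expanded clades with catalog genes", {
  cfg <- sim_config(
    ages_years = 60, colonies_per_individual = 40,
    driver_rate = 0.002, driver_advantage = 30, seed = 17
  )
  sim <- simulate_individual(cfg, 1)
  expect_false(is.null(sim$truth$driver_events))
  expect_true(all(sim$truth$driver_events$gene %in% default_driver_genes()))
  # driver branches subtend the clades recorded in the truth fractions
  cf <- sim$truth$clone_fractions
  drv <- merge(sim$truth$driver_events, cf, by.x = "branch_id", by.y = "node")
  expect_true(all(drv$fraction > 0))
})

test_that("sim_config validates inputs and round-trips through JSON", {
  expect_error(sim_config(ages_years = 30, colonies_per_individual = 1), ">= 2")
  expect_error(sim_config(ages_years = 30, burden_slope = -1), "non-negative")
  bad_sig <- list(bad = rep(1 / 95, 95))
  expect_error(sim_config(ages_years = 30, signature_defs = bad_sig), "length 96")
  cfg <- sim_config(
    ages_years = c(10, 20), colonies_per_individual = 4,
    chemo_pulses = list(list(
      age_years = 5, expected_extra_sbs = 50,
      signature_id = "sig_alkyl"
    )), seed = 33
  )
  path <- withr::local_tempfile(fileext = ".json")
  write_sim_config(cfg, path)
  cfg2 <- read_sim_config(path)
  expect_equal(cfg2$ages_years, cfg$ages_years)
  expect_equal(cfg2$chemo_pulses[[1]]$age_years, 5)
  a <- simulate_individual(cfg, 1)
  b <- simulate_individual(cfg2, 1)
  expect_identical(a$counts$alt, b$counts$alt)
  # pulse beyond the sampling age is rejected at simulation time
  cfg_bad <- sim_config(
    ages_years = 3, colonies_per_individual = 4,
    chemo_pulses = list(list(
      age_years = 5, expected_extra_sbs = 50,
      signature_id = "sig_alkyl"
    )), seed = 1
  )
  expect_error(simulate_individual(cfg_bad, 1), "exceeds sampling age")
})
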