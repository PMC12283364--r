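test_that("germline recall sensitivity is the called fraction", {
  set.seed(9)
  n_g <- 500
  depth <- matrix(rpois(n_g * 2, 30), n_g, 2)
  alt <- matrix(rbinom(n_g * 2, as.vector(depth), 0.5), n_g, 2)
  # degrade colony 2: drop half its alt reads so some calls fail
  alt[, 2] <- rbinom(n_g, as.vector(depth[, 2]), 0.2)
  counts <- make_counts(alt, depth)
  sens <- estimate_sensitivity(counts,
    germline_ids = counts$variants$variant_id,
    method = "germline_recall"
  )
  gm <- genotype_calls(counts)
  expect_equal(sens$sensitivity, unname(colMeans(gm$calls == 1L)))
  expect_gt(sens$sensitivity[1], 0.99)
  expect_lt(sens$sensitivity[2], 0.8)
})

test_that("depth-model sensitivity matches a brute-force summation", {
  cfg <- filter_config()
  oracle <- function(lambda) {
    s <- 0
    for (d in 0:300) {
      need <- max(cfg$min_alt_reads, ceiling(cfg$vaf_autosome * d))
      p_alt <- sum(dbinom(need:max(need, d), d, 0.5))
      if (need > d) p_alt <- 0
      s <- s + dpois(d, lambda) * p_alt
    }
    s
  }
  for (lambda in c(5, 15, 25)) {
    sens <- estimate_sensitivity(
      mean_depth = c(col = lambda),
      method = "depth_model"
    )
    expect_equal(sens$sensitivity, oracle(lambda), tolerance = 1e-9)
  }
  # deep sequencing detects everything
  deep <- estimate_sensitivity(mean_depth = c(col = 500), method = "depth_model")
  expect_gt(deep$sensitivity, 0.9999)
})

test_that("terminal branch correction divides by sensitivity", {
  tree <- quartet_tree()
  raw <- c("1" = 40, "2" = 10, "3" = 0, "4" = 20, "6" = 30, "7" = 15)
  tree$branch$raw_length <- unname(raw[as.character(tree$branch$node)])
  sens <- data.frame(
    colony = c("A", "B", "C", "D"),
    sensitivity = c(0.8, 1, 0.5, 0.9)
  )
  out <- correct_terminal_branches(tree, sens)
  corr <- stats::setNames(out$branch$corrected_length, out$branch$node)
  expect_equal(unname(corr["1"]), 40 / 0.8) # raw 40, sens 0.8 -> 50
  expect_equal(unname(corr["2"]), 10) # sens 1 -> unchanged
  expect_equal(unname(corr["3"]), 0) # raw 0 stays 0
  expect_equal(unname(corr["6"]), 30) # internal unchanged
  expect_error(
    correct_terminal_branches(tree, sens[-2, ]),
    "missing sensitivity for colony: B"
  )
})

test_that("ultrametric normalisation equalises root-to-tip distances", {
  set.seed(300)
  for (rep in 1:25) {
    tree <- random_colony_tree(sample(4:12, 1))
    out <- make_ultrametric(tree)
    d <- cloneclock:::tree_node_distances(out, "ultrametric_length")
    tips <- d[seq_len(out$n_tips)]
    expect_lt(max(tips) - min(tips), 1e-6)
    expect_true(all(out$branch$ultrametric_length >= -1e-12))
  }
})

test_that("an already-ultrametric tree is a fixed point", {
  tree <- quartet_tree()
  # heights: AB at 60+40, CD at 30+70, root children chosen ultrametric
  lens <- c("1" = 40, "2" = 40, "3" = 70, "4" = 70, "6" = 60, "7" = 30)
  tree$branch$raw_length <- unname(lens[as.character(tree$branch$node)])
  tree$branch$corrected_length <- tree$branch$raw_length
  out <- make_ultrametric(tree)
  expect_equal(out$branch$ultrametric_length, out$branch$corrected_length,
    tolerance = 1e-9
  )
})

test_that("a two-tip tree balances to the mean tip distance", {
  parent <- c(3L, 3L, 0L)
  tree <- colony_tree(parent, 2L, c("A", "B"))
  tree$branch$raw_length <- c(90, 110)
  tree$branch$corrected_length <- c(90, 110)
  out <- make_ultrametric(tree)
  expect_equal(sort(out$branch$ultrametric_length), c(100, 100))
})

test_that("total length is approximately preserved on clock-like trees", {
  cfg <- sim_config(
    ages_years = 45, colonies_per_individual = 20,
    n_germline_het = 0, artifact_rate = 0, seed = 88
  )
  sim <- simulate_individual(cfg, 1)
  tree <- sim$truth$tree
  tree$branch$corrected_length <- tree$branch$raw_length
  out <- make_ultrametric(tree)
  expect_lt(
    abs(sum(out$branch$ultrametric_length) - sum(tree$branch$corrected_length)) /
      sum(tree$branch$corrected_length),
    0.05
  )
})

test_that("age scaling sets every tip time to the sampling age", {
  tree <- quartet_tree()
  lens <- c("1" = 40, "2" = 40, "3" = 70, "4" = 70, "6" = 60, "7" = 30)
  tree$branch$corrected_length <- unname(lens[as.character(tree$branch$node)])
  tree$branch$raw_length <- tree$branch$corrected_length
  tree <- make_ultrametric(tree)
  out <- scale_to_age(tree, 50)
  d <- cloneclock:::tree_node_distances(out, "time_span")
  expect_equal(unname(d[1:4]), rep(50, 4))
  # height 100 units at age 50 -> 0.5 yr per mutation unit
  expect_equal(out$branch$time_span, out$branch$ultrametric_length * 0.5)
  # gestation offset shifts the clock for cord blood
  cb <- scale_to_age(tree, 0, gestation_offset = 0.75)
  dcb <- cloneclock:::tree_node_distances(cb, "time_span")
  expect_equal(unname(dcb[1:4]), rep(0.75, 4))
})

test_that("window overlap fractions follow branch time intervals", {
  tree <- quartet_tree()
  lens <- c("1" = 40, "2" = 40, "3" = 70, "4" = 70, "6" = 60, "7" = 30)
  tree$branch$corrected_length <- unname(lens[as.character(tree$branch$node)])
  tree$branch$raw_length <- tree$branch$corrected_length
  tree <- scale_to_age(make_ultrametric(tree), 100)
  # branch 6 spans 0-60 yr; branch 1 spans 60-100 yr
  tree$mutations[["1"]] <- c("m1", "m2")
  tree$mutations[["6"]] <- "m3"
  expect_equal(exposure_window_overlap(tree, c("m1", "m2"), c(70, 80)), 1)
  expect_equal(exposure_window_overlap(tree, c("m1", "m2"), c(10, 20)), 0)
  expect_equal(exposure_window_overlap(tree, c("m1", "m2", "m3"), c(10, 20)), 1 / 3)
  expect_error(exposure_window_overlap(tree, character(0), c(1, 2)), "empty")
})

test_that("increasing a terminal raw length never shrinks its correction", {
  sens <- data.frame(colony = c("A", "B", "C", "D"), sensitivity = rep(0.7, 4))
  tree <- quartet_tree()
  lens <- c("1" = 40, "2" = 40, "3" = 70, "4" = 70, "6" = 60, "7" = 30)
  tree$branch$raw_length <- unname(lens[as.character(tree$branch$node)])
  base <- correct_terminal_branches(tree, sens)
  tree2 <- tree
  i <- which(tree2$branch$node == 1L)
  tree2$branch$raw_length[i] <- tree2$branch$raw_length[i] + 25
  more <- correct_terminal_branches(tree2, sens)
  expect_gt(more$branch$corrected_length[i], base$branch$corrected_length[i])
})
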