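test_that("a degenerate sweep reproduces a single run of the base", {
  base <- coevo_params(max_iterations = 600)
  single <- run_coevo(base, keep_proportions = FALSE)
  sw <- run_sweep(tibble::tibble(max_area = base$max_area), base)
  expect_equal(nrow(sw), 1)
  expect_equal(sw$end_state_class, single$end_state_class)
  expect_equal(sw$humans, single$final_state$humans)
  expect_equal(sw$time_end, single$time_end)
})

test_that("sweeps are deterministic and reject unknown parameters", {
  pts <- grid_points(
    utility_per_capita_type_n_plants_to_humans = c(0.5, 1.5),
    max_area = c(200, 1000))
  expect_equal(nrow(pts), 4)
  base <- coevo_params(max_iterations = 400)
  a <- run_sweep(pts, base)
  b <- run_sweep(pts, base)
  expect_identical(a, b)
  expect_equal(nrow(a), 4)
  expect_error(run_sweep(tibble::tibble(no_such_param = 1), base),
               "no_such_param")
  expect_error(grid_points(not_a_param = 1:2), "not_a_param")
})

test_that("a facilitator axis shows a single monotone class boundary", {
  # decreasing the plants' type-n utility from a full-coevolution base
  # flips the class to no_coevolution exactly once along the axis
  base <- update_params(coevo_params(),
    utility_per_capita_type_1_plants_to_humans = 0.05)
  axis <- c(1, 2, 3, 4.5, 6, 8)
  sw <- run_sweep(tibble::tibble(
    utility_per_capita_type_n_plants_to_humans = axis), base)
  is_full <- sw$end_state_class == "full_coevolution"
  expect_equal(sw$end_state_class[!is_full],
               rep("no_coevolution", sum(!is_full)))
  expect_true(any(is_full) && any(!is_full))
  expect_equal(sum(diff(is_full) != 0), 1)  # one boundary
  expect_true(all(diff(is_full) >= 0))      # monotone facilitation
})

test_that("Latin hypercube samples are stratified and space-filling", {
  ranges <- list(
    intrinsic_growth_rate_humans = c(0.01, 0.21),
    utility_per_capita_type_n_plants_to_humans = c(0, 2),
    max_area = c(100, 600))
  n <- 10
  pts <- sample_lhs(ranges, n_samples = n, seed = 4)
  expect_equal(nrow(pts), n)
  # Latin property: exactly one sample per marginal bin
  for (nm in names(ranges)) {
    lo <- ranges[[nm]][1]
    hi <- ranges[[nm]][2]
    bins <- findInterval(pts[[nm]], seq(lo, hi, length.out = n + 1),
                         rightmost.closed = TRUE)
    expect_setequal(bins, seq_len(n))
  }
  # determinism
  expect_identical(pts, sample_lhs(ranges, n_samples = n, seed = 4))
  # n = 1 stays inside all ranges
  p1 <- sample_lhs(ranges, n_samples = 1, seed = 9)
  expect_true(p1$max_area >= 100 && p1$max_area <= 600)
  # infinite range is a design error
  expect_error(sample_lhs(list(max_area = c(1, Inf)), 5), "finite")
  expect_error(sample_lhs(list(bogus = c(0, 1)), 5), "bogus")
})

test_that("the maximin winner beats every losing candidate hypercube", {
  # brute-force re-draw of the candidate set under the same seed
  ranges <- list(intrinsic_growth_rate_humans = c(0, 1),
                 undirected_variation_humans = c(0, 1))
  n <- 8
  seed <- 21
  pts <- sample_lhs(ranges, n_samples = n, seed = seed, candidates = 20)
  unit <- as.matrix(pts)
  unit[, 1] <- unit[, 1]  # ranges are already [0, 1]
  winner_score <- min(stats::dist(unit))
  set.seed(seed)
  scores <- replicate(20, min(stats::dist(lhs::randomLHS(n, 2))))
  expect_equal(winner_score, max(scores), tolerance = 1e-12)
})

test_that("importance ranking identifies an informative predictor", {
  set.seed(8)
  n <- 120
  fake <- tibble::tibble(
    undirected_variation_humans = runif(n),
    intrinsic_growth_rate_humans = runif(n),
    max_area = runif(n, 100, 1000),
    coevolution_coefficient_humans = NA_real_)
  # noiseless function of exactly one varied parameter
  fake$coevolution_coefficient_humans <-
    sin(2 * pi * fake$undirected_variation_humans)
  imp <- rank_importance(fake, "coevolution_coefficient_humans",
                         seed = 8, ntree_grid = 100)
  expect_equal(imp$parameter[1], "undirected_variation_humans")
  expect_equal(nrow(imp), 3)
  expect_true(all(c("permutation_importance", "impurity_importance")
                  %in% names(imp)))
})

test_that("pure-noise targets yield importances centred on zero", {
  # sign test: across repeats, positive and negative permutation
  # importances of uninformative predictors are about equally frequent
  set.seed(31)
  signs <- replicate(5, {
    n <- 80
    fake <- tibble::tibble(
      undirected_variation_humans = runif(n),
      intrinsic_growth_rate_humans = runif(n),
      coevolution_coefficient_humans = rnorm(n))
    imp <- rank_importance(fake, "coevolution_coefficient_humans",
                           seed = sample.int(1e6, 1), ntree_grid = 100)
    sign(imp$permutation_importance)
  })
  pos <- sum(signs > 0)
  total <- length(signs)
  expect_gt(stats::binom.test(pos, total)$p.value, 0.01)
})

test_that("importance ranking rejects degenerate inputs", {
  n <- 60
  fake <- tibble::tibble(undirected_variation_humans = runif(n),
                         coevolution_coefficient_humans = 1)
  expect_error(rank_importance(fake, "coevolution_coefficient_humans"),
               "degenerate target")
  fake$coevolution_coefficient_humans <- runif(n)
  expect_error(rank_importance(fake[1:10, ], "coevolution_coefficient_humans"),
               "at least 50")
})

test_that("tipping-point bisection brackets a class change consistently", {
  base <- update_params(coevo_params(),
    utility_per_capita_type_1_plants_to_humans = 0.05)
  axis <- "utility_per_capita_type_n_plants_to_humans"
  expect_error(
    find_tipping_point(base, axis, c(0.1, 0.2)),
    "no-bracket")
  expect_error(find_tipping_point(base, "nope", c(0, 1)), "unknown")
  coarse <- find_tipping_point(base, axis, c(3, 5), tol = 2e-2)
  expect_equal(coarse$class_below, "no_coevolution")
  expect_equal(coarse$class_above, "full_coevolution")
  # a tighter re-run lands inside the coarse bracket
  fine <- find_tipping_point(base, axis, coarse$bracket, tol = 1e-1)
  expect_gte(fine$tipping_point, coarse$bracket[1])
  expect_lte(fine$tipping_point, coarse$bracket[2])
  # the class flips across the returned point
  width <- diff(coarse$bracket)
  below <- run_coevo(do.call(update_params, stats::setNames(
    list(base, coarse$tipping_point - 2 * width), c("", axis))),
    keep_proportions = FALSE)
  above <- run_coevo(do.call(update_params, stats::setNames(
    list(base, coarse$tipping_point + 2 * width), c("", axis))),
    keep_proportions = FALSE)
  expect_equal(below$end_state_class, "no_coevolution")
  expect_equal(above$end_state_class, "full_coevolution")
})
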