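test_that("type values interpolate linearly between the endpoints", {
  # with 10 types and endpoints 1 and 10, type 5 has value 5
  v <- type_values(1, 10, 10)
  expect_equal(v[5], 5)
  expect_identical(v[1], 1)
  expect_identical(v[10], 10)
  expect_equal(type_values(3, 1.5, 4), c(3, 2.5, 2, 1.5))
  expect_equal(type_values(2.7, 2.7, 6), rep(2.7, 6))
  expect_error(type_values(0, 1, 1), "n must be")
})

test_that("aggregate utilities weight per-type values by shares and size", {
  prm <- coevo_params(
    number_types_humans = 2, number_types_plants = 2,
    utility_per_capita_type_1_humans_to_plants = 0,
    utility_per_capita_type_n_humans_to_plants = 2)
  st <- coevo_state(10, 0, c(0.5, 0.5), c(1, 0))
  u <- aggregate_utilities(st, prm)
  expect_equal(u$utility_humans_to_plants, 10)  # 10 * (0.5*0 + 0.5*2)
  expect_equal(u$utility_plants_to_humans, 0)   # empty plant population

  # degenerate distribution picks out the type-1 baseline exactly
  st1 <- coevo_state(4, 7, c(1, 0), c(1, 0))
  u1 <- aggregate_utilities(st1, prm)
  expect_equal(u1$utility_other_to_humans, prm$utility_other_to_type_1_humans)
  expect_equal(u1$utility_other_to_plants, prm$utility_other_to_type_1_plants)
})

test_that("plant carrying capacity is capped by max_area", {
  k <- carrying_capacities(5, 10, 7, 100, 50)
  expect_equal(k$carrying_capacity_humans, 15)
  expect_equal(k$carrying_capacity_plants, 50)
  k0 <- carrying_capacities(0, 0, 0, 0, 99)
  expect_equal(unlist(k0, use.names = FALSE), c(0, 0))
  kinf <- carrying_capacities(5, 10, 7, 100, Inf)
  expect_equal(kinf$carrying_capacity_plants, 107)
})

test_that("logistic update matches the map and its degenerate rules", {
  expect_equal(logistic_update(50, 0.1, 100), 52.5)
  expect_equal(logistic_update(100, 0.3, 100), 100)  # fixed point at K
  expect_equal(logistic_update(42, 0, 77), 42)       # zero growth rate
  expect_equal(logistic_update(10, 0.2, 0), 8)       # K = 0: decay
  expect_equal(logistic_update(10, 1, 0), 0)
  expect_error(logistic_update(-1, 0.1, 10), "invalid argument")
})

test_that("undirected variation relaxes towards uniform and conserves mass", {
  expect_equal(undirected_variation(c(1, 0), 0.5), c(0.75, 0.25))
  expect_equal(undirected_variation(c(0.3, 0.7), 0), c(0.3, 0.7))
  u <- rep(1 / 4, 4)
  expect_equal(undirected_variation(u, 0.63), u)  # uniform is a fixed point
  expect_equal(undirected_variation(c(0.1, 0.2, 0.7), 1), rep(1 / 3, 3))
  expect_error(undirected_variation(c(1, 0), 1.5), "invalid parameter")
  for (v in c(0.1, 0.5, 0.9)) {
    expect_equal(sum(undirected_variation(c(0.2, 0.5, 0.3), v)), 1)
  }
})

test_that("fitness scores reproduce the algebraic limits", {
  n <- 5
  expect_equal(fitness_scores(n, 1, 0), n - seq_len(n))  # favours type 1
  expect_equal(fitness_scores(n, 0, 1), seq_len(n))      # favours type n
  expect_equal(fitness_scores(2, 1, 1), c(1, 1))         # balance: neutral
  expect_equal(fitness_scores(3, 0, 0), rep(1, 3))       # no selection at all
  expect_error(fitness_scores(3, -1, 0), "invalid argument")
  # affine in the type index for any mix
  f <- fitness_scores(6, 2.5, 7.5)
  expect_equal(diff(f, differences = 2), rep(0, 4))
})

test_that("replicator update reweights by relative fitness", {
  expect_equal(replicator_update(c(0.5, 0.5), c(1, 3)), c(0.25, 0.75))
  expect_equal(replicator_update(c(0.2, 0.3, 0.5), c(2, 2, 2)),
               c(0.2, 0.3, 0.5))                 # neutral selection
  expect_equal(replicator_update(c(1, 0), c(2, 5)), c(1, 0))  # vertex fixed
  stag <- replicator_update(c(0, 1), c(1, 0))
  expect_equal(as.numeric(stag), c(0, 1))
  expect_true(attr(stag, "stagnant"))
  expect_error(replicator_update(c(0.5, 0.5), c(-1, 1)), "invalid argument")
})

test_that("one step matches the independent transcription oracle", {
  set.seed(42)
  for (k in 1:100) {
    inst <- random_instance()
    got <- coevo_step(inst$state, inst$params)
    want <- oracle_step(inst$state$humans, inst$state$plants,
                        inst$state$type_proportions_humans,
                        inst$state$type_proportions_plants, inst$params)
    expect_equal(got$state$humans, want$H, tolerance = 1e-10)
    expect_equal(got$state$plants, want$P, tolerance = 1e-10)
    expect_equal(got$state$type_proportions_humans, want$pop_H,
                 tolerance = 1e-10)
    expect_equal(got$state$type_proportions_plants, want$pop_P,
                 tolerance = 1e-10)
    expect_equal(got$diagnostics$carrying_capacity_humans, want$K_H,
                 tolerance = 1e-10)
    expect_equal(got$diagnostics$carrying_capacity_plants, want$K_P,
                 tolerance = 1e-10)
    expect_equal(got$diagnostics$fitness_humans, want$fit_H,
                 tolerance = 1e-10)
    expect_equal(got$diagnostics$fitness_plants, want$fit_P,
                 tolerance = 1e-10)
  }
})

test_that("multi-step runs conserve proportions, signs and the plant cap", {
  set.seed(7)
  for (k in 1:10) {
    inst <- random_instance()
    prm <- update_params(inst$params, max_iterations = 80)
    run <- suppressWarnings(run_coevo(prm))
    tr <- run$trajectory
    h_cols <- grep("type_proportions_humans_", names(tr))
    p_cols <- grep("type_proportions_plants_", names(tr))
    expect_true(all(abs(rowSums(tr[h_cols]) - 1) < 1e-12))
    expect_true(all(abs(rowSums(tr[p_cols]) - 1) < 1e-12))
    expect_true(all(tr[h_cols] >= 0) && all(tr[p_cols] >= 0))
    expect_true(all(tr$humans >= 0) && all(tr$plants >= 0))
    expect_true(all(tr$carrying_capacity_plants <= prm$max_area + 1e-12))
  }
})

test_that("swapping the population blocks mirrors the trajectory", {
  set.seed(99)
  for (k in 1:5) {
    inst <- random_instance()
    prm <- update_params(inst$params, max_area = Inf, max_iterations = 60)
    mirrored <- swap_populations(prm)
    a <- suppressWarnings(run_coevo(prm))
    b <- suppressWarnings(run_coevo(mirrored))
    expect_equal(a$time_end, b$time_end)
    expect_equal(a$trajectory$humans, b$trajectory$plants, tolerance = 1e-10)
    expect_equal(a$trajectory$plants, b$trajectory$humans, tolerance = 1e-10)
    expect_equal(a$coevolution_coefficient_humans,
                 b$coevolution_coefficient_plants, tolerance = 1e-10)
  }
})

test_that("with constant capacity the logistic converges to the baseline", {
  # cross-utilities zero, no variation, all mass on type 1: K is constant
  # and equals the type-1 baseline
  prm <- coevo_params(
    initial_population_humans = 3,
    initial_population_plants = 30,
    utility_per_capita_type_1_plants_to_humans = 0,
    utility_per_capita_type_n_plants_to_humans = 0,
    utility_per_capita_type_1_humans_to_plants = 0,
    utility_per_capita_type_n_humans_to_plants = 0,
    undirected_variation_humans = 0,
    undirected_variation_plants = 0,
    reltol_exponential = 9)
  run <- run_coevo(prm)
  expect_true(run$converged)
  expect_equal(run$final_state$humans, prm$utility_other_to_type_1_humans,
               tolerance = 1e-6)
  expect_equal(run$final_state$plants, prm$utility_other_to_type_1_plants,
               tolerance = 1e-6)
  # proportions never moved
  expect_equal(run$final_state$type_proportions_humans,
               c(1, rep(0, prm$number_types_humans - 1)))
})
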