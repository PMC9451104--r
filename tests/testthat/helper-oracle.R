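# Independent straight-line transcription of one synchronous model step,
# written directly from the update rules with no shared code with the
# package internals. Used as the oracle for step equivalence.
oracle_step <- function(H, P, pop_H, pop_P, prm) {
  n_H <- prm$number_types_humans
  n_P <- prm$number_types_plants

  # per-type values: straight lines between the two endpoints
  u_HiP <- seq(prm$utility_per_capita_type_1_humans_to_plants,
               prm$utility_per_capita_type_n_humans_to_plants,
               length.out = n_H)
  u_PiH <- seq(prm$utility_per_capita_type_1_plants_to_humans,
               prm$utility_per_capita_type_n_plants_to_humans,
               length.out = n_P)
  u_bHi <- seq(prm$utility_other_to_type_1_humans,
               prm$utility_other_to_type_n_humans, length.out = n_H)
  u_bPi <- seq(prm$utility_other_to_type_1_plants,
               prm$utility_other_to_type_n_plants, length.out = n_P)

  U_HP <- 0; for (i in 1:n_H) U_HP <- U_HP + pop_H[i] * u_HiP[i]
  U_HP <- H * U_HP
  U_PH <- 0; for (i in 1:n_P) U_PH <- U_PH + pop_P[i] * u_PiH[i]
  U_PH <- P * U_PH
  U_bH <- 0; for (i in 1:n_H) U_bH <- U_bH + pop_H[i] * u_bHi[i]
  U_bP <- 0; for (i in 1:n_P) U_bP <- U_bP + pop_P[i] * u_bPi[i]

  K_H <- U_PH + U_bH
  K_P <- min(U_HP + U_bP, prm$max_area)

  r_H <- prm$intrinsic_growth_rate_humans
  r_P <- prm$intrinsic_growth_rate_plants
  H_next <- if (K_H == 0) max(H * (1 - r_H), 0) else
    max(H + r_H * H - r_H * H^2 / K_H, 0)
  P_next <- if (K_P == 0) max(P * (1 - r_P), 0) else
    max(P + r_P * P - r_P * P^2 / K_P, 0)

  fit_H <- numeric(n_H)
  for (i in 1:n_H) {
    fit_H[i] <- if (U_bH + U_PH == 0) 1 else
      ((n_H - i) * U_bH + i * U_PH) / (U_bH + U_PH)
  }
  fit_P <- numeric(n_P)
  for (i in 1:n_P) {
    fit_P[i] <- if (U_bP + U_HP == 0) 1 else
      ((n_P - i) * U_bP + i * U_HP) / (U_bP + U_HP)
  }

  pop_H1 <- pop_H + prm$undirected_variation_humans * (1 / n_H - pop_H)
  pop_P1 <- pop_P + prm$undirected_variation_plants * (1 / n_P - pop_P)
  mf_H <- sum(fit_H * pop_H1)
  pop_H2 <- if (mf_H == 0) pop_H1 else fit_H * pop_H1 / mf_H
  mf_P <- sum(fit_P * pop_P1)
  pop_P2 <- if (mf_P == 0) pop_P1 else fit_P * pop_P1 / mf_P

  list(H = H_next, P = P_next, pop_H = pop_H2, pop_P = pop_P2,
       K_H = K_H, K_P = K_P, fit_H = fit_H, fit_P = fit_P,
       U_HP = U_HP, U_PH = U_PH, U_bH = U_bH, U_bP = U_bP)
}

# random valid parameter set and state for property tests
random_instance <- function() {
  n_H <- sample(2:6, 1)
  n_P <- sample(2:6, 1)
  prm <- coevo_params(
    initial_population_humans = runif(1, 0, 50),
    initial_population_plants = runif(1, 0, 200),
    number_types_humans = n_H,
    number_types_plants = n_P,
    undirected_variation_humans = runif(1),
    undirected_variation_plants = runif(1),
    intrinsic_growth_rate_humans = runif(1, 0, 0.5),
    intrinsic_growth_rate_plants = runif(1, 0, 0.5),
    utility_per_capita_type_n_plants_to_humans = runif(1, 0, 3),
    utility_per_capita_type_1_plants_to_humans = runif(1, 0, 3),
    utility_per_capita_type_n_humans_to_plants = runif(1, 0, 3),
    utility_per_capita_type_1_humans_to_plants = runif(1, 0, 3),
    utility_other_to_type_n_plants = runif(1, 0.1, 100),
    utility_other_to_type_1_plants = runif(1, 0.1, 100),
    utility_other_to_type_n_humans = runif(1, 0.1, 100),
    utility_other_to_type_1_humans = runif(1, 0.1, 100),
    max_area = runif(1, 50, 500))
  rand_props <- function(n) {
    x <- runif(n)
    x / sum(x)
  }
  state <- coevo_state(runif(1, 0, 100), runif(1, 0, 300),
                       rand_props(n_H), rand_props(n_P))
  list(params = prm, state = state)
}

# swap the human and plant parameter blocks (for the mirror-symmetry test)
swap_populations <- function(prm) {
  coevo_params(
    initial_population_humans = prm$initial_population_plants,
    initial_population_plants = prm$initial_population_humans,
    number_types_humans = prm$number_types_plants,
    number_types_plants = prm$number_types_humans,
    undirected_variation_humans = prm$undirected_variation_plants,
    undirected_variation_plants = prm$undirected_variation_humans,
    intrinsic_growth_rate_humans = prm$intrinsic_growth_rate_plants,
    intrinsic_growth_rate_plants = prm$intrinsic_growth_rate_humans,
    utility_per_capita_type_n_plants_to_humans =
      prm$utility_per_capita_type_n_humans_to_plants,
    utility_per_capita_type_1_plants_to_humans =
      prm$utility_per_capita_type_1_humans_to_plants,
    utility_per_capita_type_n_humans_to_plants =
      prm$utility_per_capita_type_n_plants_to_humans,
    utility_per_capita_type_1_humans_to_plants =
      prm$utility_per_capita_type_1_plants_to_humans,
    utility_other_to_type_n_plants = prm$utility_other_to_type_n_humans,
    utility_other_to_type_1_plants = prm$utility_other_to_type_1_humans,
    utility_other_to_type_n_humans = prm$utility_other_to_type_n_plants,
    utility_other_to_type_1_humans = prm$utility_other_to_type_1_plants,
    max_area = prm$max_area,
    max_iterations = prm$max_iterations,
    reltol_exponential = prm$reltol_exponential,
    coevolution_threshold = prm$coevolution_threshold)
}
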