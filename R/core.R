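#' Per-type values by linear interpolation between endpoints
#'
#' Types are ordered from least (1) to most (n) mutualistic; any per-type
#' quantity (utility per capita, baseline utility) is defined by its
#' type-1 and type-n endpoints, with intermediate types linearly
#' interpolated. For example, with n = 10 and endpoints 1 and 10, type 5
#' has value 5.
#'
#' @param value_type_1 Value attached to type 1.
#' @param value_type_n Value attached to type n.
#' @param n Number of types (integer, at least 2).
#' @return Numeric vector of length `n`; entries 1 and `n` equal the two
#'   endpoints exactly.
#' @examples
#' type_values(1, 10, 10)
#' @export
type_values <- function(value_type_1, value_type_n, n) {
  if (length(n) != 1 || is.na(n) || n < 2 || n != round(n)) {
    stop("invalid parameter: n must be an integer >= 2", call. = FALSE)
  }
  value_type_1 + (seq_len(n) - 1) * (value_type_n - value_type_1) / (n - 1)
}

#' Aggregate utilities of one population to the other and to itself
#'
#' The utility of population A to population B is the sum over A's types
#' of utility per capita weighted by the type share, times A's size. The
#' baseline utilities are the type-share-weighted means of the per-type
#' baseline ("other resources") utilities.
#'
#' @param state A [coevo_state()] (or any list with `humans`, `plants`,
#'   `type_proportions_humans`, `type_proportions_plants`).
#' @param params A [coevo_params()] object.
#' @return Named list with `utility_humans_to_plants`,
#'   `utility_plants_to_humans`, `utility_other_to_humans`,
#'   `utility_other_to_plants`.
#' @export
aggregate_utilities <- function(state, params) {
  u <- precompute_type_values(params)
  list(
    utility_humans_to_plants =
      state$humans * sum(state$type_proportions_humans * u$u_humans_to_plants),
    utility_plants_to_humans =
      state$plants * sum(state$type_proportions_plants * u$u_plants_to_humans),
    utility_other_to_humans =
      sum(state$type_proportions_humans * u$u_other_to_humans),
    utility_other_to_plants =
      sum(state$type_proportions_plants * u$u_other_to_plants)
  )
}

# Interpolated per-type utility vectors; constant within a run.
precompute_type_values <- function(params) {
  list(
    u_plants_to_humans = type_values(
      params$utility_per_capita_type_1_plants_to_humans,
      params$utility_per_capita_type_n_plants_to_humans,
      params$number_types_plants),
    u_humans_to_plants = type_values(
      params$utility_per_capita_type_1_humans_to_plants,
      params$utility_per_capita_type_n_humans_to_plants,
      params$number_types_humans),
    u_other_to_humans = type_values(
      params$utility_other_to_type_1_humans,
      params$utility_other_to_type_n_humans,
      params$number_types_humans),
    u_other_to_plants = type_values(
      params$utility_other_to_type_1_plants,
      params$utility_other_to_type_n_plants,
      params$number_types_plants)
  )
}

#' Carrying capacities from aggregate utilities
#'
#' The human carrying capacity is the plant contribution plus the human
#' baseline. The plant carrying capacity is the human contribution plus
#' the plant baseline, capped at `max_area` (the contiguous area
#' constraint that breaks the model's human/plant symmetry).
#'
#' @param utility_plants_to_humans,utility_other_to_humans Contributions
#'   to the human carrying capacity (nonnegative).
#' @param utility_humans_to_plants,utility_other_to_plants Contributions
#'   to the plant carrying capacity (nonnegative).
#' @param max_area Plant-side cap (positive, may be `Inf`).
#' @return Named list with `carrying_capacity_humans`,
#'   `carrying_capacity_plants`.
#' @export
carrying_capacities <- function(utility_plants_to_humans,
                                utility_other_to_humans,
                                utility_humans_to_plants,
                                utility_other_to_plants,
                                max_area) {
  list(
    carrying_capacity_humans =
      utility_plants_to_humans + utility_other_to_humans,
    carrying_capacity_plants =
      min(utility_humans_to_plants + utility_other_to_plants, max_area)
  )
}

#' Discrete-time Verhulst-Pearl logistic update
#'
#' One step of the logistic map, `pop + r*pop - r*pop^2/K`. When the
#' carrying capacity is zero the density term is undefined; the update is
#' then defined as geometric decay `pop*(1 - r)` clipped at 0, so that a
#' collapsed capacity drives extinction rather than a division error.
#'
#' @param pop Current population (nonnegative).
#' @param r Intrinsic growth rate (nonnegative).
#' @param K Carrying capacity (nonnegative).
#' @return Updated population.
#' @examples
#' logistic_update(50, 0.1, 100) # 52.5
#' @export
logistic_update <- function(pop, r, K) {
  if (pop < 0 || r < 0 || K < 0) {
    stop("invalid argument: pop, r and K must be >= 0", call. = FALSE)
  }
  if (K == 0) return(max(pop * (1 - r), 0))
  max(pop + r * pop - r * pop^2 / K, 0)
}

#' Undirected variation of a type distribution
#'
#' Deterministic relaxation of the type-proportion vector towards the
#' uniform distribution: `pop + v*(1/n - pop)`. Represents mutation in
#' genetic transmission, or innovation and error in cultural
#' transmission. `v = 0` leaves the distribution unchanged; `v = 1` maps
#' any distribution to uniform.
#'
#' @param pop Type-proportion vector (nonnegative, summing to 1).
#' @param v Variation level in \[0, 1\].
#' @return Proportion vector of the same length, summing to 1.
#' @export
undirected_variation <- function(pop, v) {
  if (length(v) != 1 || is.na(v) || v < 0 || v > 1) {
    stop("invalid parameter: v must lie in [0, 1]", call. = FALSE)
  }
  pop + v * (1 / length(pop) - pop)
}

#' Fitness scores of the mutualism types
#'
#' The fitness of type i mixes the baseline utility (favouring the
#' non-mutualistic end) and the partner population's contribution
#' (favouring the mutualistic end):
#' `((n - i)*U_b + i*U_partner) / (U_b + U_partner)`.
#' When both utilities are zero the environment exerts no selection and a
#' vector of ones is returned.
#'
#' @param n Number of types.
#' @param utility_other Baseline ("other resources") aggregate utility.
#' @param utility_partner Aggregate utility contributed by the partner
#'   population.
#' @return Numeric fitness vector of length `n`, affine in the type
#'   index.
#' @examples
#' fitness_scores(4, utility_other = 1, utility_partner = 0) # favours type 1
#' fitness_scores(4, utility_other = 0, utility_partner = 1) # favours type n
#' @export
fitness_scores <- function(n, utility_other, utility_partner) {
  if (utility_other < 0 || utility_partner < 0) {
    stop("invalid argument: utilities must be >= 0", call. = FALSE)
  }
  total <- utility_other + utility_partner
  i <- seq_len(n)
  if (total == 0) return(rep(1, n))
  ((n - i) * utility_other + i * utility_partner) / total
}

#' Replicator update of a type distribution
#'
#' Each type's share is reweighted by its fitness relative to the
#' population-mean fitness: `pop_i * f_i / sum_j pop_j * f_j`. Types with
#' zero share stay at zero (inertia: only represented types are
#' transmitted). If the mean fitness is zero the update is undefined; the
#' input is returned unchanged with attribute `stagnant = TRUE`.
#'
#' @param pop Type-proportion vector (nonnegative, summing to 1).
#' @param fitness Nonnegative fitness vector of the same length.
#' @return Proportion vector summing to 1.
#' @examples
#' replicator_update(c(0.5, 0.5), c(1, 3)) # c(0.25, 0.75)
#' @export
replicator_update <- function(pop, fitness) {
  if (length(fitness) != length(pop)) {
    stop("invalid argument: pop and fitness must have equal length",
         call. = FALSE)
  }
  if (any(fitness < 0)) {
    stop("invalid argument: fitness must be >= 0", call. = FALSE)
  }
  mean_fitness <- sum(fitness * pop)
  if (mean_fitness == 0) {
    return(structure(pop, stagnant = TRUE))
  }
  fitness * pop / mean_fitness
}

#' Model state at one time step
#'
#' @param humans,plants Population sizes (nonnegative).
#' @param type_proportions_humans,type_proportions_plants Type-proportion
#'   vectors (nonnegative, each summing to 1 within 1e-12).
#' @param time Time index (integer, >= 0).
#' @return An object of class `coevo_state`.
#' @export
coevo_state <- function(humans, plants,
                        type_proportions_humans, type_proportions_plants,
                        time = 0L) {
  s <- list(
    humans = as.numeric(humans),
    plants = as.numeric(plants),
    type_proportions_humans = as.numeric(type_proportions_humans),
    type_proportions_plants = as.numeric(type_proportions_plants),
    time = as.integer(time)
  )
  validate_coevo_state(s)
  structure(s, class = "coevo_state")
}

validate_coevo_state <- function(s) {
  if (s$humans < 0 || s$plants < 0) {
    stop("invalid state: populations must be >= 0", call. = FALSE)
  }
  for (nm in c("type_proportions_humans", "type_proportions_plants")) {
    pop <- s[[nm]]
    if (length(pop) < 2 || any(pop < 0) || abs(sum(pop) - 1) > 1e-12) {
      stop("invalid state: ", nm,
           " must be nonnegative, length >= 2, and sum to 1", call. = FALSE)
    }
  }
  if (s$time < 0) stop("invalid state: time must be >= 0", call. = FALSE)
  invisible(s)
}

initial_state <- function(params) {
  pop_h <- params$initial_type_proportions_humans
  if (is.null(pop_h)) {
    pop_h <- c(1, rep(0, params$number_types_humans - 1))
  }
  pop_p <- params$initial_type_proportions_plants
  if (is.null(pop_p)) {
    pop_p <- c(1, rep(0, params$number_types_plants - 1))
  }
  coevo_state(params$initial_population_humans,
              params$initial_population_plants,
              pop_h, pop_p, time = 0L)
}

#' One synchronous step of the coupled dynamics
#'
#' Computes all diagnostics (aggregate utilities, carrying capacities,
#' fitness vectors, coevolution and dependency coefficients) from the
#' time-t state, then advances populations by the logistic map and type
#' distributions by undirected variation followed by the replicator
#' update, every rate and fitness frozen at time t (a synchronous,
#' fully deterministic map).
#'
#' @param state A [coevo_state()] at time t.
#' @param params A [coevo_params()] object.
#' @return List with `state` (the `coevo_state` at t + 1) and
#'   `diagnostics` (named list of the time-t quantities:
#'   utilities, carrying capacities, fitness vectors, coevolution and
#'   dependency coefficients).
#' @export
coevo_step <- function(state, params) {
  validate_coevo_state(state)
  u <- precompute_type_values(params)
  stepped <- step_kernel(
    humans = state$humans, plants = state$plants,
    pop_h = state$type_proportions_humans,
    pop_p = state$type_proportions_plants,
    params = params, type_u = u)
  new_state <- coevo_state(
    stepped$humans, stepped$plants,
    normalize_props(stepped$pop_h), normalize_props(stepped$pop_p),
    time = state$time + 1L)
  list(state = new_state, diagnostics = stepped$diagnostics)
}

# Raw step on plain numerics; the hot path shared by coevo_step() and the
# run loop. Arithmetic is inlined (identical to the exported primitives,
# which the test suite cross-checks) to keep long sweeps fast.
step_kernel <- function(humans, plants, pop_h, pop_p, params, type_u) {
  n_h <- params$number_types_humans
  n_p <- params$number_types_plants

  u_hp <- humans * sum(pop_h * type_u$u_humans_to_plants)
  u_ph <- plants * sum(pop_p * type_u$u_plants_to_humans)
  u_bh <- sum(pop_h * type_u$u_other_to_humans)
  u_bp <- sum(pop_p * type_u$u_other_to_plants)

  k_h <- u_ph + u_bh
  k_p <- min(u_hp + u_bp, params$max_area)

  # fitness_scores(), inlined
  tot_h <- u_bh + u_ph
  i_h <- seq_len(n_h)
  fit_h <- if (tot_h == 0) rep(1, n_h) else
    ((n_h - i_h) * u_bh + i_h * u_ph) / tot_h
  tot_p <- u_bp + u_hp
  i_p <- seq_len(n_p)
  fit_p <- if (tot_p == 0) rep(1, n_p) else
    ((n_p - i_p) * u_bp + i_p * u_hp) / tot_p

  # logistic_update(), inlined
  r_h <- params$intrinsic_growth_rate_humans
  r_p <- params$intrinsic_growth_rate_plants
  humans_next <- if (k_h == 0) max(humans * (1 - r_h), 0) else
    max(humans + r_h * humans - r_h * humans * humans / k_h, 0)
  plants_next <- if (k_p == 0) max(plants * (1 - r_p), 0) else
    max(plants + r_p * plants - r_p * plants * plants / k_p, 0)

  # undirected_variation() then replicator_update(), inlined
  pop_h_var <- pop_h + params$undirected_variation_humans *
    (1 / n_h - pop_h)
  pop_p_var <- pop_p + params$undirected_variation_plants *
    (1 / n_p - pop_p)
  mf_h <- sum(fit_h * pop_h_var)
  pop_h_next <- if (mf_h == 0) structure(pop_h_var, stagnant = TRUE) else
    fit_h * pop_h_var / mf_h
  mf_p <- sum(fit_p * pop_p_var)
  pop_p_next <- if (mf_p == 0) structure(pop_p_var, stagnant = TRUE) else
    fit_p * pop_p_var / mf_p

  diagnostics <- list(
    utility_humans_to_plants = u_hp,
    utility_plants_to_humans = u_ph,
    utility_other_to_humans = u_bh,
    utility_other_to_plants = u_bp,
    carrying_capacity_humans = k_h,
    carrying_capacity_plants = k_p,
    fitness_humans = fit_h,
    fitness_plants = fit_p,
    coevolution_coefficient_humans = coevolution_coefficient(pop_h),
    coevolution_coefficient_plants = coevolution_coefficient(pop_p),
    dependency_coefficient_humans = dependency_coefficient(fit_h),
    dependency_coefficient_plants = dependency_coefficient(fit_p)
  )
  list(humans = humans_next, plants = plants_next,
       pop_h = pop_h_next, pop_p = pop_p_next,
       diagnostics = diagnostics)
}

# Guard against drift of the unit-sum invariant over long runs.
normalize_props <- function(pop) {
  s <- sum(pop)
  if (s > 0 && abs(s - 1) > 1e-15) pop / s else pop
}
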