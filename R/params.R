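#' Model parameters for a human-plant coevolution run
#'
#' Constructs and validates the full parameter set of the coupled
#' logistic/replicator model. Each population (humans, plants) is described
#' by an initial size, a number of mutualism types, a level of undirected
#' variation, an intrinsic growth rate, and per-type utilities defined by
#' their type-1 and type-n endpoints (intermediate types are linear
#' interpolations, see [type_values()]). Plants are additionally capped by
#' `max_area`, the maximum number of plant units fitting the contiguous
#' area available.
#'
#' Parameter names follow the model's standard R notation so that
#' configuration files, trajectory tables and sweep results are
#' self-documenting.
#'
#' The defaults are a reference setting under which both populations fully
#' transit to the most mutualistic types (see [coevo_presets()],
#' `full_coevolution`).
#'
#' @param initial_population_humans,initial_population_plants Initial
#'   population sizes (nonnegative; population units are organisms or any
#'   explicit proxy).
#' @param number_types_humans,number_types_plants Number of discrete
#'   mutualism types per population, ordered from least (1) to most (n)
#'   mutualistic. Integers, at least 2.
#' @param undirected_variation_humans,undirected_variation_plants Per-step
#'   relaxation fraction of the type distribution towards uniformity, in
#'   \[0, 1\]. Stands in for mutation/innovation.
#' @param intrinsic_growth_rate_humans,intrinsic_growth_rate_plants
#'   Intrinsic logistic growth rates per time step (nonnegative).
#' @param utility_per_capita_type_n_plants_to_humans,utility_per_capita_type_1_plants_to_humans
#'   Carrying-capacity contribution of one plant of type n (resp. type 1)
#'   to the human population.
#' @param utility_per_capita_type_n_humans_to_plants,utility_per_capita_type_1_humans_to_plants
#'   Carrying-capacity contribution of one human of type n (resp. type 1)
#'   to the plant population.
#' @param utility_other_to_type_n_plants,utility_other_to_type_1_plants
#'   Baseline carrying capacity available to plants of type n (resp. 1)
#'   from resources other than humans.
#' @param utility_other_to_type_n_humans,utility_other_to_type_1_humans
#'   Baseline carrying capacity available to humans of type n (resp. 1)
#'   from resources other than this plant.
#' @param max_area Hard cap on the plant carrying capacity (positive, may
#'   be `Inf`).
#' @param max_iterations Maximum number of time steps before a run is
#'   interrupted (integer, at least 1).
#' @param reltol_exponential Positive exponent \eqn{\epsilon}; a run has
#'   converged when every population level and type proportion changes by
#'   less than \eqn{10^{-\epsilon}} in one step.
#' @param coevolution_threshold Threshold in (-1, 1) against which the
#'   coevolution coefficients are compared to decide whether a qualitative
#'   type shift has happened (used for end-state classification and
#'   timing).
#' @param initial_type_proportions_humans,initial_type_proportions_plants
#'   Optional initial type-proportion vectors (nonnegative, summing to 1).
#'   Default `NULL` places all mass on type 1, the non-mutualistic
#'   ("wild") start; undirected variation then seeds the other types.
#'
#' @return An object of class `coevo_params`: a validated named list.
#' @examples
#' p <- coevo_params(number_types_humans = 5, number_types_plants = 5)
#' p$number_types_humans
#' @export
coevo_params <- function(initial_population_humans = 10,
                         initial_population_plants = 100,
                         number_types_humans = 10,
                         number_types_plants = 10,
                         undirected_variation_humans = 0.01,
                         undirected_variation_plants = 0.01,
                         intrinsic_growth_rate_humans = 0.05,
                         intrinsic_growth_rate_plants = 0.1,
                         utility_per_capita_type_n_plants_to_humans = 1.5,
                         utility_per_capita_type_1_plants_to_humans = 0.15,
                         utility_per_capita_type_n_humans_to_plants = 5,
                         utility_per_capita_type_1_humans_to_plants = 0.5,
                         utility_other_to_type_n_plants = 20,
                         utility_other_to_type_1_plants = 100,
                         utility_other_to_type_n_humans = 2,
                         utility_other_to_type_1_humans = 10,
                         max_area = 1000,
                         max_iterations = 5000,
                         reltol_exponential = 6,
                         coevolution_threshold = 0.5,
                         initial_type_proportions_humans = NULL,
                         initial_type_proportions_plants = NULL) {
  p <- list(
    initial_population_humans = as.numeric(initial_population_humans),
    initial_population_plants = as.numeric(initial_population_plants),
    number_types_humans = as.integer(round(number_types_humans)),
    number_types_plants = as.integer(round(number_types_plants)),
    undirected_variation_humans = as.numeric(undirected_variation_humans),
    undirected_variation_plants = as.numeric(undirected_variation_plants),
    intrinsic_growth_rate_humans = as.numeric(intrinsic_growth_rate_humans),
    intrinsic_growth_rate_plants = as.numeric(intrinsic_growth_rate_plants),
    utility_per_capita_type_n_plants_to_humans =
      as.numeric(utility_per_capita_type_n_plants_to_humans),
    utility_per_capita_type_1_plants_to_humans =
      as.numeric(utility_per_capita_type_1_plants_to_humans),
    utility_per_capita_type_n_humans_to_plants =
      as.numeric(utility_per_capita_type_n_humans_to_plants),
    utility_per_capita_type_1_humans_to_plants =
      as.numeric(utility_per_capita_type_1_humans_to_plants),
    utility_other_to_type_n_plants = as.numeric(utility_other_to_type_n_plants),
    utility_other_to_type_1_plants = as.numeric(utility_other_to_type_1_plants),
    utility_other_to_type_n_humans = as.numeric(utility_other_to_type_n_humans),
    utility_other_to_type_1_humans = as.numeric(utility_other_to_type_1_humans),
    max_area = as.numeric(max_area),
    max_iterations = as.integer(round(max_iterations)),
    reltol_exponential = as.numeric(reltol_exponential),
    coevolution_threshold = as.numeric(coevolution_threshold),
    initial_type_proportions_humans =
      if (is.null(initial_type_proportions_humans)) NULL else
        as.numeric(initial_type_proportions_humans),
    initial_type_proportions_plants =
      if (is.null(initial_type_proportions_plants)) NULL else
        as.numeric(initial_type_proportions_plants)
  )
  validate_coevo_params(p)
  structure(p, class = "coevo_params")
}

#' Names of the scalar model parameters
#'
#' @param include_initial Include the two initial population sizes?
#' @param include_controls Include the run-control settings
#'   (`max_iterations`, `reltol_exponential`, `coevolution_threshold`)?
#' @return Character vector of parameter names in standard order.
#' @export
coevo_param_names <- function(include_initial = TRUE, include_controls = TRUE) {
  nm <- c(
    "initial_population_humans", "initial_population_plants",
    "number_types_humans", "number_types_plants",
    "undirected_variation_humans", "undirected_variation_plants",
    "intrinsic_growth_rate_humans", "intrinsic_growth_rate_plants",
    "utility_per_capita_type_n_plants_to_humans",
    "utility_per_capita_type_1_plants_to_humans",
    "utility_per_capita_type_n_humans_to_plants",
    "utility_per_capita_type_1_humans_to_plants",
    "utility_other_to_type_n_plants", "utility_other_to_type_1_plants",
    "utility_other_to_type_n_humans", "utility_other_to_type_1_humans",
    "max_area",
    "max_iterations", "reltol_exponential", "coevolution_threshold"
  )
  if (!include_initial) {
    nm <- setdiff(nm, c("initial_population_humans",
                        "initial_population_plants"))
  }
  if (!include_controls) {
    nm <- setdiff(nm, c("max_iterations", "reltol_exponential",
                        "coevolution_threshold"))
  }
  nm
}

check_scalar <- function(x, name) {
  if (length(x) != 1 || !is.numeric(x) || is.na(x)) {
    stop("parameter `", name, "` must be a single non-missing number",
         call. = FALSE)
  }
  invisible(x)
}

validate_coevo_params <- function(p) {
  scalars <- setdiff(names(p), c("initial_type_proportions_humans",
                                 "initial_type_proportions_plants"))
  for (nm in scalars) check_scalar(p[[nm]], nm)

  stopifnot_param(p$initial_population_humans >= 0,
                  "initial_population_humans must be >= 0")
  stopifnot_param(p$initial_population_plants >= 0,
                  "initial_population_plants must be >= 0")
  stopifnot_param(p$number_types_humans >= 2,
                  "number_types_humans must be an integer >= 2")
  stopifnot_param(p$number_types_plants >= 2,
                  "number_types_plants must be an integer >= 2")
  for (nm in c("undirected_variation_humans", "undirected_variation_plants")) {
    stopifnot_param(p[[nm]] >= 0 && p[[nm]] <= 1,
                    paste(nm, "must lie in [0, 1]"))
  }
  for (nm in c("intrinsic_growth_rate_humans", "intrinsic_growth_rate_plants",
               grep("^utility_", names(p), value = TRUE))) {
    stopifnot_param(p[[nm]] >= 0, paste(nm, "must be >= 0"))
  }
  stopifnot_param(p$max_area > 0, "max_area must be positive (may be Inf)")
  stopifnot_param(p$max_iterations >= 1,
                  "max_iterations must be an integer >= 1")
  stopifnot_param(p$reltol_exponential > 0,
                  "reltol_exponential must be positive")
  stopifnot_param(p$coevolution_threshold > -1 && p$coevolution_threshold < 1,
                  "coevolution_threshold must lie in (-1, 1)")

  check_init_props(p$initial_type_proportions_humans,
                   p$number_types_humans, "humans")
  check_init_props(p$initial_type_proportions_plants,
                   p$number_types_plants, "plants")
  invisible(p)
}

stopifnot_param <- function(cond, msg) {
  if (!isTRUE(cond)) stop("invalid parameter: ", msg, call. = FALSE)
}

check_init_props <- function(pop, n, who) {
  if (is.null(pop)) return(invisible(NULL))
  if (length(pop) != n) {
    stop("invalid parameter: initial_type_proportions_", who,
         " must have length number_types_", who, " (", n, ")", call. = FALSE)
  }
  if (any(pop < 0) || abs(sum(pop) - 1) > 1e-12) {
    stop("invalid parameter: initial_type_proportions_", who,
         " must be nonnegative and sum to 1", call. = FALSE)
  }
  invisible(NULL)
}

#' Update a parameter set with new values
#'
#' @param params A [coevo_params()] object.
#' @param ... Named parameter values to override.
#' @return A validated `coevo_params` object.
#' @export
update_params <- function(params, ...) {
  stopifnot(inherits(params, "coevo_params"))
  dots <- list(...)
  if (length(dots) == 0) return(params)
  bad <- setdiff(names(dots), names(params))
  if (length(bad) > 0) {
    stop("unknown parameter(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  do.call(coevo_params, utils::modifyList(unclass(params), dots))
}

#' @export
print.coevo_params <- function(x, ...) {
  cat("<coevo_params>\n")
  for (nm in coevo_param_names()) {
    cat(sprintf("  %-45s %s\n", nm, format(x[[nm]])))
  }
  if (!is.null(x$initial_type_proportions_humans)) {
    cat("  initial_type_proportions_humans: custom\n")
  }
  if (!is.null(x$initial_type_proportions_plants)) {
    cat("  initial_type_proportions_plants: custom\n")
  }
  invisible(x)
}
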