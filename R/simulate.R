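#' Coevolution coefficient of a type distribution
#'
#' Summarises where a type-proportion vector sits between the
#' non-mutualistic and mutualistic ends of the type spectrum:
#' `sum_i pop_i * (i - 1)/(n - 1) * 2 - 1`. It equals -1 when the entire
#' population is of type 1, +1 when it is entirely of type n, and 0 for
#' the uniform distribution.
#'
#' @param pop Type-proportion vector (length >= 2, summing to 1).
#' @return A number in \[-1, 1\].
#' @examples
#' coevolution_coefficient(c(0, 0, 1)) # 1
#' coevolution_coefficient(c(1, 0, 0)) # -1
#' @export
coevolution_coefficient <- function(pop) {
  n <- length(pop)
  if (n < 2) stop("invalid argument: pop must have length >= 2",
                  call. = FALSE)
  sum(pop * (seq_len(n) - 1) / (n - 1)) * 2 - 1
}

#' Dependency coefficient of a fitness vector
#'
#' The ordinary least-squares slope of the fitness scores against the
#' type index 1..n. Its sign indicates which end of the type spectrum
#' selection currently favours: positive values mean the partner
#' population's contribution dominates the baseline and selection pushes
#' towards stronger mutualism.
#'
#' @param fitness Numeric fitness vector (length >= 2).
#' @return The OLS slope (a real number).
#' @examples
#' dependency_coefficient(c(1, 2, 3)) # 1
#' @export
dependency_coefficient <- function(fitness) {
  n <- length(fitness)
  if (n < 2) stop("invalid argument: fitness must have length >= 2",
                  call. = FALSE)
  i <- seq_len(n)
  di <- i - mean(i)
  sum(di * (fitness - mean(fitness))) / sum(di * di)
}

#' Convergence test between consecutive states
#'
#' A run has converged when both population levels and both type
#' distributions are stable: every absolute change is strictly below
#' `10^-reltol_exponential`.
#'
#' @param prev,curr States at t - 1 and t (lists with `humans`, `plants`
#'   and the two type-proportion vectors).
#' @param reltol_exponential Positive exponent \eqn{\epsilon}.
#' @return `TRUE` if all changes are below the tolerance.
#' @export
has_converged <- function(prev, curr, reltol_exponential) {
  tol <- 10^(-reltol_exponential)
  abs(curr$humans - prev$humans) < tol &&
    abs(curr$plants - prev$plants) < tol &&
    max(abs(curr$type_proportions_humans -
              prev$type_proportions_humans)) < tol &&
    max(abs(curr$type_proportions_plants -
              prev$type_proportions_plants)) < tol
}

#' Timing of a persistent coevolutionary shift
#'
#' Returns the first time index at which a coevolution-coefficient series
#' exceeds the threshold and never falls back to or below it for the rest
#' of the series — i.e. the start of the final sojourn above the
#' threshold. Oscillating series that end below the threshold have no
#' such index and return `NA`.
#'
#' @param series Numeric series of coevolution coefficients, indexed from
#'   time 0.
#' @param threshold Coevolution threshold in (-1, 1).
#' @return Integer time index (0-based), or `NA_integer_` if the shift
#'   never completes.
#' @export
register_timing <- function(series, threshold) {
  if (length(series) == 0) stop("invalid argument: empty series",
                                call. = FALSE)
  above <- series > threshold
  if (!above[length(above)]) return(NA_integer_)
  below_idx <- which(!above)
  start <- if (length(below_idx) == 0) 1L else max(below_idx) + 1L
  as.integer(start - 1L)
}

#' Classify the end-state of a run
#'
#' Converged runs are classified by how many coevolution coefficients
#' exceed the threshold: both (`full_coevolution`), exactly one
#' (`partial_stationary`), or neither (`no_coevolution`). Runs
#' interrupted at the iteration cap with sustained population variance
#' over the late window are `oscillatory`; interrupted runs without such
#' variance (extremely slow drift) fall back to the stationary rules with
#' a warning.
#'
#' @param converged Did the run meet the tolerance before the cap?
#' @param coevolution_coefficient_humans,coevolution_coefficient_plants
#'   Final coevolution coefficients.
#' @param coevolution_threshold Threshold in (-1, 1).
#' @param oscillating For non-converged runs, the result of the
#'   late-window variance rule (see [run_coevo()]).
#' @return One of `"no_coevolution"`, `"full_coevolution"`,
#'   `"partial_stationary"`, `"oscillatory"`.
#' @export
classify_end_state <- function(converged,
                               coevolution_coefficient_humans,
                               coevolution_coefficient_plants,
                               coevolution_threshold,
                               oscillating = FALSE) {
  if (!converged && oscillating) return("oscillatory")
  if (!converged) {
    warning("run interrupted at max_iterations without oscillation; ",
            "classified by the stationary rules", call. = FALSE)
  }
  n_above <- (coevolution_coefficient_humans > coevolution_threshold) +
    (coevolution_coefficient_plants > coevolution_threshold)
  c("no_coevolution", "partial_stationary", "full_coevolution")[n_above + 1]
}

# Late-window oscillation rule: over the last 10% of recorded steps, a
# population is oscillating if its variance exceeds 1% of its squared
# mean (with a 1e-6 floor on the squared mean to avoid zero division).
detect_oscillation <- function(humans_series, plants_series) {
  len <- length(humans_series)
  window <- max(2L, ceiling(0.1 * len))
  idx <- (len - window + 1L):len
  osc_one <- function(x) {
    stats::var(x[idx]) > 1e-2 * max(mean(x[idx])^2, 1e-6)
  }
  osc_one(humans_series) || osc_one(plants_series)
}

#' Run the coupled human-plant dynamics to its end-state
#'
#' Iterates the synchronous step ([coevo_step()]) from the initial
#' populations and type distributions until both population levels and
#' type distributions are stable (see [has_converged()]) or
#' `max_iterations` is reached. Collects the full trajectory, final
#' coefficients, timing of type shifts, and the end-state class.
#'
#' @param params A [coevo_params()] object.
#' @param keep_proportions Record the per-step type-proportion vectors in
#'   the trajectory? Set `FALSE` in large sweeps to save memory.
#' @return An object of class `coevo_run` with elements
#'   `params`, `trajectory` (a tibble, one row per time step; see
#'   [tidy.coevo_run()]), `final_state` (a [coevo_state()]),
#'   `end_state_class`, `coevolution_coefficient_humans/_plants`,
#'   `dependency_coefficient_humans/_plants`, `timing_humans`,
#'   `timing_plants`, `time_end`, `converged`, `stagnant`.
#' @examples
#' run <- run_coevo(coevo_params(max_iterations = 200))
#' run$end_state_class
#' @export
run_coevo <- function(params, keep_proportions = TRUE) {
  stopifnot(inherits(params, "coevo_params"))
  state0 <- initial_state(params)
  type_u <- precompute_type_values(params)
  t_max <- params$max_iterations
  n_h <- params$number_types_humans
  n_p <- params$number_types_plants

  scalar_names <- c(
    "humans", "plants",
    "carrying_capacity_humans", "carrying_capacity_plants",
    "utility_humans_to_plants", "utility_plants_to_humans",
    "utility_other_to_humans", "utility_other_to_plants",
    "coevolution_coefficient_humans", "coevolution_coefficient_plants",
    "dependency_coefficient_humans", "dependency_coefficient_plants")
  series <- matrix(NA_real_, nrow = t_max + 1L, ncol = length(scalar_names),
                   dimnames = list(NULL, scalar_names))
  if (keep_proportions) {
    props_h <- matrix(NA_real_, nrow = t_max + 1L, ncol = n_h)
    props_p <- matrix(NA_real_, nrow = t_max + 1L, ncol = n_p)
  }

  humans <- state0$humans
  plants <- state0$plants
  pop_h <- state0$type_proportions_humans
  pop_p <- state0$type_proportions_plants
  converged <- FALSE
  stagnant <- FALSE
  t_end <- t_max

  diag_row <- function(diag) {
    c(diag$carrying_capacity_humans, diag$carrying_capacity_plants,
      diag$utility_humans_to_plants, diag$utility_plants_to_humans,
      diag$utility_other_to_humans, diag$utility_other_to_plants,
      diag$coevolution_coefficient_humans,
      diag$coevolution_coefficient_plants,
      diag$dependency_coefficient_humans,
      diag$dependency_coefficient_plants)
  }

  for (t in seq_len(t_max)) {
    stepped <- step_kernel(humans, plants, pop_h, pop_p, params, type_u)
    series[t, 1] <- humans
    series[t, 2] <- plants
    series[t, 3:12] <- diag_row(stepped$diagnostics)
    if (keep_proportions) {
      props_h[t, ] <- pop_h
      props_p[t, ] <- pop_p
    }
    if (isTRUE(attr(stepped$pop_h, "stagnant")) ||
        isTRUE(attr(stepped$pop_p, "stagnant"))) {
      stagnant <- TRUE
    }
    prev <- list(humans = humans, plants = plants,
                 type_proportions_humans = pop_h,
                 type_proportions_plants = pop_p)
    humans <- stepped$humans
    plants <- stepped$plants
    pop_h <- normalize_props(as.numeric(stepped$pop_h))
    pop_p <- normalize_props(as.numeric(stepped$pop_p))
    curr <- list(humans = humans, plants = plants,
                 type_proportions_humans = pop_h,
                 type_proportions_plants = pop_p)
    if (has_converged(prev, curr, params$reltol_exponential)) {
      converged <- TRUE
      t_end <- t
      break
    }
  }

  # diagnostics of the final state itself (row t_end + 1)
  final_diag <- step_kernel(humans, plants, pop_h, pop_p, params,
                            type_u)$diagnostics
  series[t_end + 1L, 1] <- humans
  series[t_end + 1L, 2] <- plants
  series[t_end + 1L, 3:12] <- diag_row(final_diag)
  if (keep_proportions) {
    props_h[t_end + 1L, ] <- pop_h
    props_p[t_end + 1L, ] <- pop_p
  }

  rows <- seq_len(t_end + 1L)
  trajectory <- tibble::as_tibble(as.data.frame(series[rows, , drop = FALSE]))
  trajectory <- tibble::add_column(trajectory, time = rows - 1L,
                                   .before = 1)
  if (keep_proportions) {
    colnames(props_h) <- paste0("type_proportions_humans_", seq_len(n_h))
    colnames(props_p) <- paste0("type_proportions_plants_", seq_len(n_p))
    trajectory <- dplyr::bind_cols(
      trajectory,
      tibble::as_tibble(as.data.frame(props_h[rows, , drop = FALSE])),
      tibble::as_tibble(as.data.frame(props_p[rows, , drop = FALSE])))
  }

  oscillating <- if (converged) FALSE else
    detect_oscillation(series[rows, "humans"], series[rows, "plants"])
  coevo_h <- final_diag$coevolution_coefficient_humans
  coevo_p <- final_diag$coevolution_coefficient_plants
  class_label <- classify_end_state(
    converged, coevo_h, coevo_p, params$coevolution_threshold,
    oscillating = oscillating)

  result <- list(
    params = params,
    trajectory = trajectory,
    final_state = coevo_state(humans, plants, pop_h, pop_p,
                              time = t_end),
    end_state_class = class_label,
    coevolution_coefficient_humans = coevo_h,
    coevolution_coefficient_plants = coevo_p,
    dependency_coefficient_humans = final_diag$dependency_coefficient_humans,
    dependency_coefficient_plants = final_diag$dependency_coefficient_plants,
    timing_humans = register_timing(
      trajectory$coevolution_coefficient_humans,
      params$coevolution_threshold),
    timing_plants = register_timing(
      trajectory$coevolution_coefficient_plants,
      params$coevolution_threshold),
    time_end = as.integer(t_end),
    converged = converged,
    stagnant = stagnant
  )
  structure(result, class = "coevo_run")
}

#' @export
print.coevo_run <- function(x, ...) {
  cat("<coevo_run>\n")
  cat("  end-state:      ", x$end_state_class,
      if (x$converged) "(converged)" else "(interrupted)", "\n")
  cat(sprintf("  time_end:        %d\n", x$time_end))
  cat(sprintf("  humans, plants:  %.4g, %.4g\n",
              x$final_state$humans, x$final_state$plants))
  cat(sprintf("  coevolution:     humans %.3f, plants %.3f (threshold %.2f)\n",
              x$coevolution_coefficient_humans,
              x$coevolution_coefficient_plants,
              x$params$coevolution_threshold))
  cat(sprintf("  dependency:      humans %.3f, plants %.3f\n",
              x$dependency_coefficient_humans,
              x$dependency_coefficient_plants))
  cat("  timing:          humans", format(x$timing_humans),
      "| plants", format(x$timing_plants), "\n")
  invisible(x)
}

#' Tidy the trajectory of a fitted run
#'
#' @param x A `coevo_run` object.
#' @param ... Unused.
#' @return The trajectory tibble: one row per time step with populations,
#'   carrying capacities, utilities, coefficients and (if recorded) type
#'   proportions.
#' @importFrom generics tidy
#' @export
tidy.coevo_run <- function(x, ...) {
  x$trajectory
}

#' One-row summary of a fitted run
#'
#' @param x A `coevo_run` object.
#' @param ... Unused.
#' @return A one-row tibble with the end-state class, final populations,
#'   coefficients, timings, `time_end` and the convergence flag.
#' @importFrom generics glance
#' @export
glance.coevo_run <- function(x, ...) {
  tibble::tibble(
    end_state_class = x$end_state_class,
    humans = x$final_state$humans,
    plants = x$final_state$plants,
    coevolution_coefficient_humans = x$coevolution_coefficient_humans,
    coevolution_coefficient_plants = x$coevolution_coefficient_plants,
    dependency_coefficient_humans = x$dependency_coefficient_humans,
    dependency_coefficient_plants = x$dependency_coefficient_plants,
    timing_humans = x$timing_humans,
    timing_plants = x$timing_plants,
    time_end = x$time_end,
    converged = x$converged
  )
}
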