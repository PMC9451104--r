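#' Run a parameter sweep
#'
#' Executes one full simulation per row of `points`, overriding the base
#' parameter set with that row's values, and collects the run-level
#' outputs. The sweep is fully deterministic given its input table.
#'
#' @param points A data frame (e.g. from [sample_lhs()], [grid_points()]
#'   or [tidyr::expand_grid()]) whose columns are model parameter names
#'   and whose rows are the settings to run.
#' @param base A [coevo_params()] object supplying every parameter not
#'   varied in `points`.
#' @return A tibble with one row per run: the full parameter vector
#'   actually used (after validation), then `end_state_class`, final
#'   `humans` and `plants`, the coevolution and dependency coefficients,
#'   `timing_humans`, `timing_plants`, `time_end` and `converged`.
#' @examples
#' pts <- tidyr::expand_grid(
#'   utility_per_capita_type_n_plants_to_humans = c(0.5, 1.5))
#' run_sweep(pts, coevo_params(max_iterations = 500))
#' @export
run_sweep <- function(points, base = coevo_params()) {
  stopifnot(is.data.frame(points), inherits(base, "coevo_params"))
  if (nrow(points) < 1) stop("design error: empty design", call. = FALSE)
  bad <- setdiff(names(points), coevo_param_names())
  if (length(bad) > 0) {
    stop("design error: unknown parameter(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  purrr::map_dfr(seq_len(nrow(points)), function(i) {
    params <- do.call(update_params,
                      c(list(base), as.list(points[i, , drop = FALSE])))
    run <- suppressWarnings(run_coevo(params, keep_proportions = FALSE))
    vals <- unclass(params)[coevo_param_names()]
    dplyr::bind_cols(tibble::as_tibble(vals), glance(run))
  })
}

#' Regular grid of parameter settings
#'
#' Convenience wrapper around [tidyr::expand_grid()]: builds the full
#' factorial crossing of the supplied per-parameter value vectors, ready
#' for [run_sweep()].
#'
#' @param ... Named vectors of parameter values (names must be model
#'   parameter names).
#' @return A tibble with one row per combination.
#' @export
grid_points <- function(...) {
  values <- list(...)
  bad <- setdiff(names(values), coevo_param_names())
  if (length(values) == 0 || is.null(names(values)) || any(names(values) == "")
      || length(bad) > 0) {
    stop("design error: arguments must be named after model parameters",
         if (length(bad) > 0) paste0(" (unknown: ",
                                     paste(bad, collapse = ", "), ")"),
         call. = FALSE)
  }
  tidyr::expand_grid(!!!values)
}

#' Latin hypercube sample of the parameter space
#'
#' Draws a space-filling Latin hypercube: each parameter's range is
#' stratified into `n_samples` equal bins with exactly one sample per
#' bin. Among `candidates` independently drawn hypercubes, the one
#' maximizing the minimum pairwise distance between points (in
#' normalized coordinates) is kept — a best-of-k maximin criterion.
#'
#' @param ranges Parameter ranges: either a named list of `c(lower,
#'   upper)` pairs or a data frame with columns `parameter`, `lower`,
#'   `upper`. All ranges must be finite; names must be model parameters.
#' @param n_samples Number of design points (at least 1).
#' @param seed Integer RNG seed; the design is reproducible from
#'   (`ranges`, `n_samples`, `seed`).
#' @param candidates Number of candidate hypercubes scored by the
#'   maximin criterion.
#' @return A tibble with `n_samples` rows and one column per parameter.
#' @examples
#' sample_lhs(list(intrinsic_growth_rate_humans = c(0.01, 0.2)),
#'            n_samples = 5, seed = 1)
#' @export
sample_lhs <- function(ranges, n_samples, seed = 1L, candidates = 20L) {
  ranges <- normalize_ranges(ranges)
  if (n_samples < 1) stop("design error: n_samples must be >= 1",
                          call. = FALSE)
  d <- nrow(ranges)
  old_seed <- .Random.seed_save()
  on.exit(.Random.seed_restore(old_seed), add = TRUE)
  set.seed(as.integer(seed))
  best <- NULL
  best_score <- -Inf
  for (k in seq_len(max(1L, candidates))) {
    cand <- lhs::randomLHS(n_samples, d)
    score <- if (n_samples == 1) 0 else min(stats::dist(cand))
    if (score > best_score) {
      best_score <- score
      best <- cand
    }
  }
  scaled <- sweep(best, 2, ranges$upper - ranges$lower, "*")
  scaled <- sweep(scaled, 2, ranges$lower, "+")
  colnames(scaled) <- ranges$parameter
  out <- tibble::as_tibble(as.data.frame(scaled))
  # integer-valued parameters are snapped to whole numbers
  for (nm in intersect(c("number_types_humans", "number_types_plants",
                         "max_iterations"), names(out))) {
    out[[nm]] <- round(out[[nm]])
  }
  out
}

normalize_ranges <- function(ranges) {
  if (is.data.frame(ranges)) {
    stopifnot(all(c("parameter", "lower", "upper") %in% names(ranges)))
    out <- tibble::tibble(parameter = as.character(ranges$parameter),
                          lower = as.numeric(ranges$lower),
                          upper = as.numeric(ranges$upper))
  } else if (is.list(ranges) && !is.null(names(ranges))) {
    out <- tibble::tibble(parameter = names(ranges),
                          lower = purrr::map_dbl(ranges, 1),
                          upper = purrr::map_dbl(ranges, 2))
  } else {
    stop("design error: ranges must be a named list or a data frame",
         call. = FALSE)
  }
  bad <- setdiff(out$parameter, coevo_param_names())
  if (length(bad) > 0) {
    stop("design error: unknown parameter(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(out$lower)) || any(!is.finite(out$upper))) {
    stop("design error: all ranges must be finite", call. = FALSE)
  }
  if (any(out$lower > out$upper)) {
    stop("design error: lower bounds must not exceed upper bounds",
         call. = FALSE)
  }
  out
}

# save/restore the global RNG state so design sampling does not disturb
# the caller's random stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(seed) {
  if (is.null(seed)) return(invisible(NULL))
  assign(".Random.seed", seed, envir = globalenv())
  invisible(NULL)
}

#' Rank parameter importance with a random-forest emulator
#'
#' Fits a random-forest regression of a run-level output on the sweep's
#' parameter columns, tuning the number of trees and the number of
#' predictors sampled per split by 10-fold cross-validation, and reports
#' two importance measures: the permutation measure (%IncMSE, computed on
#' out-of-bag samples) used for the ranking, and the total impurity
#' decrease (IncNodePurity) reported alongside.
#'
#' @param sweep A sweep result tibble from [run_sweep()] (at least 50
#'   rows).
#' @param target One of `coevolution_coefficient_humans/_plants`,
#'   `dependency_coefficient_humans/_plants`, `timing_humans`,
#'   `timing_plants`.
#' @param parameters Predictor columns; default: every model parameter
#'   varied in the sweep, excluding the initial populations (which have
#'   virtually no effect on end-states).
#' @param include_initial Include the initial populations among the
#'   default predictors?
#' @param seed Integer seed for the forest's bootstrap.
#' @param ntree_grid,mtry_grid Candidate values tuned by
#'   cross-validation; `NULL` picks a small default grid.
#' @return A tibble (`parameter`, `permutation_importance`,
#'   `impurity_importance`), sorted by decreasing permutation importance.
#' @export
rank_importance <- function(sweep, target,
                            parameters = NULL,
                            include_initial = FALSE,
                            seed = 1L,
                            ntree_grid = NULL,
                            mtry_grid = NULL) {
  stopifnot(is.data.frame(sweep))
  targets <- c("coevolution_coefficient_humans",
               "coevolution_coefficient_plants",
               "dependency_coefficient_humans",
               "dependency_coefficient_plants",
               "timing_humans", "timing_plants")
  target <- match.arg(target, targets)
  if (is.null(parameters)) {
    cand <- intersect(coevo_param_names(include_initial = include_initial,
                                        include_controls = FALSE),
                      names(sweep))
    parameters <- cand[purrr::map_int(sweep[cand], dplyr::n_distinct) > 1]
  }
  if (length(parameters) < 1) {
    stop("no varied parameter columns found in the sweep", call. = FALSE)
  }
  data <- sweep[stats::complete.cases(sweep[c(parameters, target)]),
                c(parameters, target)]
  if (nrow(data) < 50) {
    stop("sweep must provide at least 50 complete records", call. = FALSE)
  }
  y <- data[[target]]
  if (dplyr::n_distinct(y) < 2) {
    stop("degenerate target: `", target, "` is constant", call. = FALSE)
  }
  x <- as.data.frame(data[parameters])

  p <- length(parameters)
  if (is.null(mtry_grid)) {
    mtry_grid <- unique(pmax(1, c(floor(p / 3), floor(2 * p / 3), p)))
  }
  if (is.null(ntree_grid)) ntree_grid <- c(250, 500)

  old_seed <- .Random.seed_save()
  on.exit(.Random.seed_restore(old_seed), add = TRUE)
  set.seed(as.integer(seed))

  grid <- expand.grid(ntree = ntree_grid, mtry = mtry_grid)
  folds <- sample(rep(seq_len(10), length.out = nrow(data)))
  cv_mse <- purrr::map_dbl(seq_len(nrow(grid)), function(g) {
    errs <- purrr::map_dbl(seq_len(10), function(f) {
      test <- folds == f
      fit <- randomForest::randomForest(
        x = x[!test, , drop = FALSE], y = y[!test],
        ntree = grid$ntree[g], mtry = grid$mtry[g])
      mean((stats::predict(fit, x[test, , drop = FALSE]) - y[test])^2)
    })
    mean(errs)
  })
  best <- grid[which.min(cv_mse), ]

  fit <- randomForest::randomForest(
    x = x, y = y, ntree = best$ntree, mtry = best$mtry,
    importance = TRUE)
  imp <- randomForest::importance(fit)
  tibble::tibble(
    parameter = rownames(imp),
    permutation_importance = imp[, "%IncMSE"],
    impurity_importance = imp[, "IncNodePurity"]
  ) |>
    dplyr::arrange(dplyr::desc(.data$permutation_importance))
}

#' Locate a tipping point along one parameter axis
#'
#' End-state classes change discontinuously at threshold values of most
#' model parameters. Given a bracket whose two ends classify
#' differently, bisects the axis until the bracket is narrower than
#' `tol` times its initial width and returns the midpoint.
#'
#' @param base A [coevo_params()] object (all parameters except the
#'   scanned one).
#' @param parameter Name of the parameter to scan.
#' @param bracket Length-2 numeric `c(lo, hi)` with differing end-state
#'   classes.
#' @param tol Relative bracket-width tolerance.
#' @return A list with `tipping_point` (the final midpoint),
#'   `class_below`, `class_above`, and the final `bracket`.
#' @export
find_tipping_point <- function(base, parameter, bracket, tol = 1e-3) {
  stopifnot(inherits(base, "coevo_params"), length(bracket) == 2)
  if (!parameter %in% coevo_param_names()) {
    stop("design error: unknown parameter: ", parameter, call. = FALSE)
  }
  lo <- min(bracket)
  hi <- max(bracket)
  class_at <- function(value) {
    params <- do.call(update_params,
                      stats::setNames(list(base, value), c("", parameter)))
    suppressWarnings(run_coevo(params, keep_proportions = FALSE))$end_state_class
  }
  class_lo <- class_at(lo)
  class_hi <- class_at(hi)
  if (identical(class_lo, class_hi)) {
    stop("no-bracket error: end-state class is `", class_lo,
         "` at both ends of the bracket", call. = FALSE)
  }
  width0 <- hi - lo
  while (hi - lo >= tol * width0) {
    mid <- (lo + hi) / 2
    if (identical(class_at(mid), class_lo)) lo <- mid else hi <- mid
  }
  list(tipping_point = (lo + hi) / 2,
       class_below = class_lo,
       class_above = class_hi,
       bracket = c(lo, hi))
}
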