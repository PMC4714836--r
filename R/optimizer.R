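# The outer optimization loop: design vector -> porosity law -> two-phase
# mesh -> poroelastic solve -> stimulus/phenotype -> bone occupancy ->
# Omega, iterated under box-constrained SQP, plus the factorial study driver.

#' Evaluation context for the porosity optimization
#'
#' Bundles everything an objective evaluation needs besides the design
#' vector: the scaffold geometry spec, the law kind, the materials by
#' region, the load case and the mechano-regulation constants.
#'
#' @param spec A [scaffold_spec()].
#' @param law_kind One of `"constant"`, `"linear"`, `"bilinear"`,
#'   `"trilinear"`.
#' @param scaffold_E Scaffold Young's modulus, MPa (study values 500, 1000,
#'   1500).
#' @param load A [load_case()].
#' @param materials Optional named list of [material_properties()] per
#'   region; by default [scaffold_properties()] with `scaffold_E` and
#'   [granulation_properties()].
#' @param mechanoreg A [mechanoreg_params()].
#' @return An object of class `design_context`.
#' @export
design_context <- function(spec, law_kind, scaffold_E = 1000,
                           load = load_case("compression"),
                           materials = NULL,
                           mechanoreg = mechanoreg_params()) {
  stopifnot(inherits(spec, "scaffold_spec"))
  law_kind <- match.arg(law_kind, LAW_KINDS)
  if (is.null(materials)) {
    materials <- list(scaffold = scaffold_properties(E = scaffold_E),
                      granulation = granulation_properties())
  }
  structure(
    list(spec = spec, law_kind = law_kind, scaffold_E = scaffold_E,
         load = load, materials = materials, mechanoreg = mechanoreg),
    class = "design_context"
  )
}

#' Evaluate one porosity design
#'
#' Runs the full pipeline for a design vector: coefficients to law, mesh
#' build, poroelastic solve, stimulus and phenotype classification, bone
#' occupancy. Deterministic: the same vector always yields the same mesh
#' and objective. An infeasible geometry (overlapping pores) is returned as
#' a large penalized objective instead of an error, so line searches can
#' recover.
#'
#' @param x Design vector of law coefficients (um), length matching the
#'   context's law kind.
#' @param context A [design_context()].
#' @param penalty Objective value assigned to infeasible geometries.
#' @return A list: `Omega`, `BO_percent`, `law`, `feasible`.
#' @export
evaluate_design <- function(x, context, penalty = 1e6) {
  stopifnot(inherits(context, "design_context"))
  law <- tryCatch(
    vector_to_law(context$law_kind, x, y_min = 0, y_max = context$spec$h),
    error = function(e) e
  )
  if (inherits(law, "error")) {
    return(list(Omega = penalty, BO_percent = NA_real_, law = NULL,
                feasible = FALSE))
  }
  res <- tryCatch({
    mesh <- build_scaffold_mesh(context$spec, law)
    sol <- solve_poroelastic(mesh, context$materials, context$load)
    objective_metrics(sol, mesh, context$mechanoreg)
  }, fgsopt_geometry_error = function(e) e)
  if (inherits(res, "error")) {
    warning(sprintf("infeasible geometry at [%s]: penalized",
                    paste(signif(x, 4), collapse = ", ")), call. = FALSE)
    return(list(Omega = penalty, BO_percent = NA_real_, law = law,
                feasible = FALSE))
  }
  list(Omega = res$Omega, BO_percent = res$BO_percent, law = law,
       feasible = TRUE)
}

#' Optimizer configuration
#'
#' @param initial Initial coefficient value(s), um; a scalar is recycled to
#'   the law's length (default 150, the centre of the admissible interval).
#' @param lower,upper Coefficient bounds, um (defaults 5 and 300).
#' @param fd_step Finite-difference step for the SQP gradient, um.
#' @param ftol Objective (BO% points) improvement tolerance.
#' @param steptol Step-length tolerance, um.
#' @param maxit Maximum SQP iterations per start.
#' @param starts Numeric vector of additional uniform multistart values
#'   (each spawns a start with all coefficients equal to it); the `initial`
#'   start is always included.
#' @param polish After the SQP starts finish, refine the best iterate with a
#'   coordinate pattern search at the `fd_step` scale (default `TRUE`);
#'   useful because remeshing makes the objective piecewise constant in the
#'   coefficients.
#' @param seed Integer seed recorded with the run (the pipeline is
#'   deterministic; the seed governs any optional jitter and is stored for
#'   provenance).
#' @return An object of class `optimization_config`.
#' @export
optimization_config <- function(initial = 150, lower = A_LOWER,
                                upper = A_UPPER, fd_step = 5,
                                ftol = 1e-2, steptol = 1, maxit = 50,
                                starts = c(50, 250), polish = TRUE,
                                seed = 1L) {
  stopifnot(ftol > 0, steptol > 0, maxit >= 1, fd_step > 0,
            all(initial >= lower), all(initial <= upper))
  structure(
    list(initial = initial, lower = lower, upper = upper,
         fd_step = fd_step, ftol = ftol, steptol = steptol,
         maxit = maxit, starts = starts, polish = isTRUE(polish),
         seed = as.integer(seed)),
    class = "optimization_config"
  )
}

#' Optimize the porosity distribution law
#'
#' Minimizes `Omega = -BO%` over the law coefficients within
#' `[5, 300]` um using the box-constrained SQP iteration, from the
#' configured start(s); the best iterate over all starts is returned.
#'
#' @param context A [design_context()].
#' @param config An [optimization_config()].
#' @param extra_starts Optional list of full-length coefficient vectors to
#'   use as additional starts (e.g. the optimum of a poorer law expanded to
#'   this law's breakpoints).
#' @return An object of class `optimization_record`: `best_law`,
#'   `best_BO_percent`, `best_Omega`, `history` (a tibble of accepted
#'   iterates across starts), `termination`, `n_evals`.
#' @export
optimize_porosity <- function(context, config = optimization_config(),
                              extra_starts = NULL) {
  stopifnot(inherits(context, "design_context"))
  n <- n_coefficients(context$law_kind)
  lower <- rep(config$lower, n)
  upper <- rep(config$upper, n)
  cache <- new.env(parent = emptyenv())
  n_evals <- 0L
  fn <- function(x) {
    key <- paste(sprintf("%.9g", x), collapse = "|")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    n_evals <<- n_evals + 1L
    val <- evaluate_design(x, context)$Omega
    cache[[key]] <- val
    val
  }
  start_list <- c(
    list(rep_len(config$initial, n)),
    lapply(config$starts, function(s) rep(s, n)),
    extra_starts %||% list()
  )
  runs <- vector("list", length(start_list))
  for (k in seq_along(start_list)) {
    runs[[k]] <- sqp_box(fn, start_list[[k]], lower, upper,
                         fd_step = config$fd_step, ftol = config$ftol,
                         steptol = config$steptol, maxit = config$maxit)
    runs[[k]]$history$start <- k
  }
  fs <- vapply(runs, function(r) r$f, numeric(1))
  best <- runs[[which.min(fs)]]
  if (isTRUE(config$polish)) {
    pol <- polish_coordinates(fn, best$x, best$f, lower, upper,
                              h = config$fd_step)
    best$x <- pol$x
    best$f <- pol$f
  }
  best_eval <- evaluate_design(best$x, context)
  history <- dplyr::bind_rows(lapply(runs, function(r) r$history))
  history$BO_percent <- -history$f
  structure(
    list(context = context,
         best_x = best$x,
         best_law = best_eval$law,
         best_BO_percent = best_eval$BO_percent,
         best_Omega = best_eval$Omega,
         history = as_tibble(history),
         termination = best$termination,
         n_starts = length(start_list),
         n_evals = n_evals),
    class = "optimization_record"
  )
}

#' @export
print.optimization_record <- function(x, ...) {
  cat(sprintf("<optimization_record: %s law, E = %g MPa, %s load>\n",
              x$context$law_kind, x$context$scaffold_E, x$context$load$kind))
  cat(sprintf("  best BO%% = %.3f at A = [%s] um (%d evaluations, %s)\n",
              x$best_BO_percent,
              paste(signif(x$best_x, 4), collapse = ", "),
              x$n_evals, x$termination))
  invisible(x)
}

#' Tidy the iterate history of an optimization
#'
#' @param x An `optimization_record`.
#' @param ... Unused.
#' @return A tibble of accepted iterates (`start`, `iteration`, objective,
#'   coefficients, `BO_percent`).
#' @exportS3Method generics::tidy
tidy.optimization_record <- function(x, ...) x$history

#' One-row summary of an optimization
#'
#' @param x An `optimization_record`.
#' @param ... Unused.
#' @return A one-row tibble: factors, best coefficients, best BO%, PVPD,
#'   evaluation count and termination reason.
#' @exportS3Method generics::glance
glance.optimization_record <- function(x, ...) {
  tibble(
    law = x$context$law_kind,
    E_MPa = x$context$scaffold_E,
    load = x$context$load$kind,
    BO_percent = x$best_BO_percent,
    Omega = x$best_Omega,
    PVPD = pvpd(x$best_law),
    coefficients = paste(signif(x$best_x, 5), collapse = ";"),
    n_evals = x$n_evals,
    termination = x$termination
  )
}

#' Plot the optimization history
#'
#' @param object An `optimization_record`.
#' @param ... Unused.
#' @return A ggplot of BO% versus iteration per start.
#' @exportS3Method ggplot2::autoplot
autoplot.optimization_record <- function(object, ...) {
  ggplot2::ggplot(object$history,
                  ggplot2::aes(x = .data$iteration, y = .data$BO_percent,
                               colour = factor(.data$start))) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "SQP iteration", y = "BO%", colour = "start")
}
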