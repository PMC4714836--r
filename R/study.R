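# Full-factorial design study: scaffold Young's moduli x loading conditions
# x porosity-law kinds, with each cell solved by the porosity optimizer.

#' Enumerate the factorial study design
#'
#' The reference study crosses 3 scaffold Young's moduli, 3 loading
#' conditions and 4 porosity-law kinds: 36 optimization analyses.
#'
#' @param E Scaffold Young's moduli, MPa.
#' @param loads Load-case kinds.
#' @param laws Porosity-law kinds.
#' @return A tibble with one row per optimization run (`run`, `E_MPa`,
#'   `load`, `law`).
#' @export
study_plan <- function(E = c(500, 1000, 1500),
                       loads = c("compression", "shear", "mixed"),
                       laws = LAW_KINDS) {
  stopifnot(length(E) > 0, length(loads) > 0, length(laws) > 0)
  loads <- match.arg(loads, c("compression", "shear", "mixed"),
                     several.ok = TRUE)
  laws <- match.arg(laws, LAW_KINDS, several.ok = TRUE)
  grid <- expand.grid(law = laws, load = loads, E_MPa = E,
                      stringsAsFactors = FALSE)
  # run the laws in increasing richness within each (E, load) cell so a
  # richer law can be warm-started from the poorer optimum
  grid$law <- factor(grid$law, levels = LAW_KINDS)
  grid <- grid[order(grid$E_MPa, grid$load, grid$law), ]
  tibble(run = seq_len(nrow(grid)), E_MPa = grid$E_MPa,
         load = as.character(grid$load), law = as.character(grid$law))
}

# express a poorer law's optimum in a richer law's coefficients by sampling
# the optimal radius profile at the richer law's breakpoints (exact whenever
# the poorer profile is linear across the richer partition)
expand_law_to <- function(law, kind, h) {
  target <- porosity_law(kind, rep(150, n_coefficients(kind)),
                         y_min = 0, y_max = h)
  pmax(A_LOWER, pmin(A_UPPER, evaluate_radius(law, target$breaks[
    if (kind == "constant") 1L else seq_len(n_coefficients(kind))])))
}

#' Run the factorial porosity-optimization study
#'
#' Executes one porosity optimization per (Young's modulus, load, law)
#' combination. Within each (E, load) cell the law kinds run from poorest
#' (constant) to richest (trilinear) and every richer law receives the
#' poorer optima as warm starts, which makes the optimal BO% non-decreasing
#' along the nesting chain. Per-cell iBO% (trilinear minus constant bone
#' occupancy) is summarised when both laws are present. Individual run
#' failures are recorded and the study continues.
#'
#' @param spec A [scaffold_spec()] shared by all runs.
#' @param E,loads,laws Factor levels (see [study_plan()]).
#' @param config An [optimization_config()].
#' @param load_args Named list of extra arguments for [load_case()]
#'   (tractions, ramp, steps).
#' @param mechanoreg A [mechanoreg_params()].
#' @param verbose Print a line per run.
#' @return An object of class `study_result`: `runs` (a tibble with one row
#'   per optimization: factors, best coefficients, BO%, Omega, PVPD),
#'   `ibo` (per-(E, load) iBO%), and `records` (the underlying
#'   `optimization_record`s).
#' @export
run_study <- function(spec = scaffold_spec(),
                      E = c(500, 1000, 1500),
                      loads = c("compression", "shear", "mixed"),
                      laws = LAW_KINDS,
                      config = optimization_config(),
                      load_args = list(),
                      mechanoreg = mechanoreg_params(),
                      verbose = FALSE) {
  plan <- study_plan(E, loads, laws)
  records <- vector("list", nrow(plan))
  rows <- vector("list", nrow(plan))
  warm <- list()  # per (E, load): list of optimal laws found so far
  for (i in seq_len(nrow(plan))) {
    cell <- paste(plan$E_MPa[i], plan$load[i], sep = "|")
    lc <- do.call(load_case, c(list(kind = plan$load[i]), load_args))
    ctx <- design_context(spec, plan$law[i], scaffold_E = plan$E_MPa[i],
                          load = lc, mechanoreg = mechanoreg)
    extra <- lapply(warm[[cell]] %||% list(), expand_law_to,
                    kind = plan$law[i], h = spec$h)
    rec <- tryCatch(
      optimize_porosity(ctx, config, extra_starts = extra),
      error = function(e) e
    )
    if (inherits(rec, "error")) {
      rows[[i]] <- tibble(run = plan$run[i], E_MPa = plan$E_MPa[i],
                          load = plan$load[i], law = plan$law[i],
                          BO_percent = NA_real_, Omega = NA_real_,
                          PVPD = NA_real_, coefficients = NA_character_,
                          n_evals = NA_integer_,
                          termination = paste("error:",
                                              conditionMessage(rec)))
      next
    }
    records[[i]] <- rec
    warm[[cell]] <- c(warm[[cell]] %||% list(), list(rec$best_law))
    g <- glance(rec)
    rows[[i]] <- dplyr::bind_cols(tibble(run = plan$run[i]),
                                  g[, c("E_MPa", "load", "law",
                                        "BO_percent", "Omega", "PVPD",
                                        "coefficients", "n_evals",
                                        "termination")])
    if (verbose) {
      message(sprintf("run %d/%d: E=%g %s %s -> BO%% = %.3f",
                      i, nrow(plan), plan$E_MPa[i], plan$load[i],
                      plan$law[i], rec$best_BO_percent))
    }
  }
  runs <- dplyr::bind_rows(rows)
  ibo_tbl <- runs |>
    dplyr::filter(.data$law %in% c("constant", "trilinear"),
                  !is.na(.data$BO_percent)) |>
    dplyr::select("E_MPa", "load", "law", "BO_percent") |>
    tidyr::pivot_wider(names_from = "law", values_from = "BO_percent")
  if (all(c("constant", "trilinear") %in% names(ibo_tbl))) {
    ibo_tbl <- ibo_tbl |>
      dplyr::filter(!is.na(.data$constant), !is.na(.data$trilinear)) |>
      dplyr::mutate(iBO_percent = ibo(.data$trilinear, .data$constant))
  } else {
    ibo_tbl <- ibo_tbl[0, ]
  }
  structure(list(plan = plan, runs = runs, ibo = ibo_tbl,
                 records = records, spec = spec, config = config),
            class = "study_result")
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("<study_result: %d runs>\n", nrow(x$runs)))
  print(x$runs, n = Inf)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.study_result <- function(x, ...) x$runs

#' @exportS3Method generics::glance
glance.study_result <- function(x, ...) {
  tibble(
    n_runs = nrow(x$runs),
    n_failed = sum(is.na(x$runs$BO_percent)),
    best_BO_percent = max(x$runs$BO_percent, na.rm = TRUE),
    mean_iBO_percent = if (nrow(x$ibo)) mean(x$ibo$iBO_percent) else NA_real_
  )
}

#' Plot study bone occupancies
#'
#' @param object A `study_result`.
#' @param ... Unused.
#' @return A ggplot of optimal BO% by law, facetted by load and Young's
#'   modulus.
#' @exportS3Method ggplot2::autoplot
autoplot.study_result <- function(object, ...) {
  dat <- dplyr::mutate(object$runs,
                       law = factor(.data$law, levels = LAW_KINDS))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$law, y = .data$BO_percent)) +
    ggplot2::geom_col() +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$load),
                        cols = ggplot2::vars(.data$E_MPa)) +
    ggplot2::labs(x = "porosity law", y = "optimal BO%")
}
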