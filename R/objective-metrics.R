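# Objective and summary metrics: mature-bone volume, bone occupancy BO%,
# objective Omega = -BO%, percent variation of pore dimension (PVPD) and the
# graded-vs-homogeneous gain iBO%.

#' Predicted mature-bone volume
#'
#' Sum of element measures over the granulation elements classified as
#' mature bone (`n_resorb < S < n_mature`).
#'
#' @param field A tibble from [stimulus_field()] (columns `phenotype` and
#'   `measure`).
#' @return Total mature-bone measure, in the mesh's measure units.
#' @export
bone_volume <- function(field) {
  stopifnot(all(c("phenotype", "measure") %in% names(field)))
  sum(field$measure[field$phenotype == "mature_bone"])
}

#' Bone occupancy percentage and objective value
#'
#' `BO% = 100 * V_BONE / V_TOT`, the percentage of the full scaffold domain
#' (scaffold solid plus pores) predicted to be occupied by mature bone. The
#' optimization minimizes `Omega = -BO%`.
#'
#' @param V_BONE Mature-bone measure.
#' @param V_TOT Total domain measure (the full prism `t * t * h`, including
#'   the scaffold solid), same units as `V_BONE`.
#' @return `bone_occupancy()`: BO% in `[0, 100]`.
#' @export
bone_occupancy <- function(V_BONE, V_TOT) {
  stopifnot(V_TOT > 0)
  if (V_BONE < 0 || V_BONE > V_TOT * (1 + 1e-12)) {
    abort("V_BONE must lie in [0, V_TOT]", class = "fgsopt_validation_error")
  }
  100 * V_BONE / V_TOT
}

#' @rdname bone_occupancy
#' @param BO_percent Bone occupancy percentage.
#' @return `objective_value()`: `Omega = -BO_percent`.
#' @export
objective_value <- function(BO_percent) -BO_percent

#' Percent variation of the pore dimension (PVPD)
#'
#' `PVPD = 100 * (A_H - A_L) / A_L` where `A_H` and `A_L` are the highest
#' and lowest pore radius attained anywhere along the scaffold height. For a
#' piecewise-linear law the extremes sit at breakpoints, so they are taken
#' from the law's breakpoint radii exactly; a sampled numeric profile is
#' accepted too.
#'
#' @param profile A [porosity_law()], or a numeric vector of radii, or a
#'   tibble with an `A_um` column (as from [radius_profile()]).
#' @return PVPD in percent (>= 0; 0 iff the profile is constant).
#' @export
pvpd <- function(profile) {
  A <- if (inherits(profile, "porosity_law")) {
    profile$coefficients
  } else if (is.data.frame(profile)) {
    profile$A_um
  } else {
    as.numeric(profile)
  }
  if (length(A) == 0 || any(!is.finite(A)) || min(A) <= 0) {
    abort("profile radii must be positive", class = "fgsopt_validation_error")
  }
  100 * (max(A) - min(A)) / min(A)
}

#' Bone-occupancy gain of the graded over the homogeneous scaffold (iBO%)
#'
#' `iBO% = BO%_trilinear - BO%_constant`: the increment in bone occupancy
#' obtained by moving from the optimal constant (homogeneous) porosity law
#' to the optimal tri-linear law. Zero means grading brings no benefit.
#'
#' @param BO_trilinear,BO_constant Bone occupancies in `[0, 100]`.
#' @return iBO% (may be negative for non-optimal inputs).
#' @export
ibo <- function(BO_trilinear, BO_constant) {
  stopifnot(BO_trilinear >= 0, BO_trilinear <= 100,
            BO_constant >= 0, BO_constant <= 100)
  BO_trilinear - BO_constant
}

# full-prism reference measure matching the mesh dimensionality:
# t*t*h in 3D, t*h*(unit depth) in 2D (the ratio BO% is depth-free)
total_domain_measure <- function(mesh) {
  spec <- mesh$spec
  if (is.null(spec)) return(sum(mesh$measure))
  d <- ncol(mesh$nodes)
  if (d == 2L) spec$t * spec$h else spec$t * spec$h * spec$t
}

#' Objective metrics of a solved design
#'
#' Convenience wrapper composing [stimulus_field()], [bone_volume()] and
#' [bone_occupancy()] for a solved scaffold design.
#'
#' @param solution A `poroelastic_solution`.
#' @param mesh The `scaffold_mesh` it was computed on.
#' @param params A [mechanoreg_params()].
#' @return A one-row tibble: `V_BONE`, `V_TOT`, `BO_percent`, `Omega`.
#' @export
objective_metrics <- function(solution, mesh, params = mechanoreg_params()) {
  field <- stimulus_field(solution, mesh, params)
  V_BONE <- bone_volume(field)
  V_TOT <- total_domain_measure(mesh)
  BO <- bone_occupancy(V_BONE, V_TOT)
  tibble(V_BONE = V_BONE, V_TOT = V_TOT,
         BO_percent = BO, Omega = objective_value(BO))
}
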