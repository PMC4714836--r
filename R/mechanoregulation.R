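# Prendergast-type mechano-regulation: biophysical stimulus from octahedral
# shear strain and interstitial fluid flow, and phenotype classification.

PHENOTYPES <- c("resorption", "mature_bone", "immature_bone",
                "cartilage", "fibrous")

#' Mechano-regulation constants
#'
#' Empirical constants of the stimulus and the boundaries of the
#' mechano-regulation diagram: `a` (strain constant, stored as the fraction
#' 0.0375, i.e. 3.75%), `b` (fluid-flow constant, 3 um/s), and the band
#' limits `n_resorb = 0.01`, `n_mature = 0.53`, `c = 3`.
#'
#' @param a Strain constant (dimensionless fraction).
#' @param b Flow constant, um/s.
#' @param n_resorb,n_mature,c Band boundaries, with
#'   `0 < n_resorb < n_mature < 1 < c`.
#' @return An object of class `mechanoreg_params`.
#' @export
mechanoreg_params <- function(a = 0.0375, b = 3,
                              n_resorb = 0.01, n_mature = 0.53, c = 3) {
  stopifnot(a > 0, b > 0,
            n_resorb > 0, n_resorb < n_mature, n_mature < 1, c > 1)
  structure(list(a = a, b = b, n_resorb = n_resorb,
                 n_mature = n_mature, c = c),
            class = "mechanoreg_params")
}

#' Octahedral shear strain
#'
#' `gamma = (2/3) * sqrt((eI - eII)^2 + (eII - eIII)^2 + (eIII - eI)^2)`,
#' a non-negative deviatoric invariant of the principal strains. Vectorized
#' over its arguments.
#'
#' @param eps_I,eps_II,eps_III Principal strains (dimensionless).
#' @return Octahedral shear strain, >= 0.
#' @export
octahedral_shear_strain <- function(eps_I, eps_II, eps_III) {
  if (any(!is.finite(c(eps_I, eps_II, eps_III)))) {
    abort("principal strains must be finite", class = "fgsopt_validation_error")
  }
  (2 / 3) * sqrt((eps_I - eps_II)^2 + (eps_II - eps_III)^2 +
                   (eps_III - eps_I)^2)
}

#' Biophysical stimulus
#'
#' `S = gamma / a + v / b`: the scalar stimulus that drives tissue
#' differentiation, linear and monotone in both the octahedral shear strain
#' and the interstitial fluid flow.
#'
#' @param gamma Octahedral shear strain (>= 0).
#' @param v Interstitial fluid flow magnitude, um/s (>= 0).
#' @param params A [mechanoreg_params()].
#' @return Stimulus values `S >= 0`, vectorized.
#' @export
biophysical_stimulus <- function(gamma, v, params = mechanoreg_params()) {
  if (any(gamma < 0) || any(v < 0)) {
    abort("gamma and v must be non-negative", class = "fgsopt_validation_error")
  }
  gamma / params$a + v / params$b
}

#' Classify the tissue phenotype from the stimulus
#'
#' The mechano-regulation diagram partitions the stimulus axis into five
#' bands: resorption (`S < n_resorb`), mature bone
#' (`n_resorb < S < n_mature`), immature bone (`n_mature < S < 1`),
#' cartilage (`1 < S < c`) and fibrous tissue (`S > c`). Band boundaries are
#' closed on the lower edge (e.g. `S = n_mature` classifies as immature
#' bone) and `S = 0` classifies as resorption, a deterministic convention
#' for the measure-zero boundary cases.
#'
#' @param S Stimulus values (>= 0), vectorized.
#' @param params A [mechanoreg_params()].
#' @return A factor with levels `resorption`, `mature_bone`,
#'   `immature_bone`, `cartilage`, `fibrous`.
#' @export
classify_stimulus <- function(S, params = mechanoreg_params()) {
  if (any(!is.finite(S)) || any(S < 0)) {
    abort("S must be finite and non-negative", class = "fgsopt_validation_error")
  }
  idx <- findInterval(S, c(params$n_resorb, params$n_mature, 1, params$c)) + 1L
  factor(PHENOTYPES[idx], levels = PHENOTYPES)
}

#' Stimulus and phenotype field over the granulation elements
#'
#' Computes, for every element occupying the scaffold pores, the octahedral
#' shear strain, the stimulus `S` and the predicted phenotype. Scaffold
#' elements are excluded: differentiation happens only in the granulation
#' tissue.
#'
#' @param solution A `poroelastic_solution` on `mesh`.
#' @param mesh The `scaffold_mesh` the solution was computed on.
#' @param params A [mechanoreg_params()].
#' @return A tibble with one row per granulation element: `element`,
#'   `gamma`, `v_um_s`, `S`, `phenotype`, `measure`, and centroid
#'   coordinates.
#' @export
stimulus_field <- function(solution, mesh, params = mechanoreg_params()) {
  stopifnot(inherits(solution, "poroelastic_solution"),
            inherits(mesh, "scaffold_mesh"))
  if (solution$n_elements != nrow(mesh$elements)) {
    abort("solution and mesh element counts differ",
          class = "fgsopt_validation_error")
  }
  gran <- which(mesh$region == "granulation")
  if (length(gran) == 0) {
    abort("mesh has no granulation elements", class = "fgsopt_validation_error")
  }
  gamma <- octahedral_shear_strain(solution$principal[gran, 1],
                                   solution$principal[gran, 2],
                                   solution$principal[gran, 3])
  v <- solution$v_um_s[gran]
  S <- biophysical_stimulus(gamma, v, params)
  tibble(
    element = gran,
    x_um = mesh$centroids[gran, 1],
    y_um = mesh$centroids[gran, 2],
    gamma = gamma,
    v_um_s = v,
    S = S,
    phenotype = classify_stimulus(S, params),
    measure = mesh$measure[gran]
  )
}

#' Plot a stimulus/phenotype field
#'
#' @param field A tibble from [stimulus_field()].
#' @return A ggplot of the granulation element centroids coloured by
#'   phenotype.
#' @export
plot_phenotype_field <- function(field) {
  ggplot2::ggplot(field, ggplot2::aes(x = .data$x_um, y = .data$y_um,
                                      colour = .data$phenotype)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm, loaded face at 0)",
                  colour = "phenotype")
}
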