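# Shared fixtures and independent analytical oracles.

# Small two-phase scaffold for pipeline tests: 2 x 2 pores, coarse mesh,
# solves in well under a second.
tiny_spec <- function(elem_size = 60) {
  scaffold_spec(t = 800, h = 1200, pore_rows = 2, pore_cols = 2,
                elem_size = elem_size)
}

tiny_materials <- function(E_scaffold = 1000) {
  list(scaffold = scaffold_properties(E = E_scaffold),
       granulation = granulation_properties())
}

# --- Terzaghi 1D consolidation oracle (independent of the solver) ---------
# Classical series for the excess pore pressure ratio p/p0 at depth ratio
# Z = z/L (z from the drained face) and time factor Tv = cv t / L^2.
terzaghi_pressure_ratio <- function(Z, Tv, n_terms = 200) {
  m <- 0:n_terms
  M <- (pi / 2) * (2 * m + 1)
  vapply(Z, function(z) sum(2 / M * sin(M * z) * exp(-M^2 * Tv)), numeric(1))
}

# d(p/p0)/dZ of the series (for the Darcy-flux oracle)
terzaghi_pressure_gradient <- function(Z, Tv, n_terms = 200) {
  m <- 0:n_terms
  M <- (pi / 2) * (2 * m + 1)
  vapply(Z, function(z) sum(2 * cos(M * z) * exp(-M^2 * Tv)), numeric(1))
}

# Standard poroelastic consolidation constants for an oedometric column of
# the given material under traction sigma (MPa): consolidation coefficient
# cv (m^2/s), initial pressure p0 (MPa) after undrained loading.
consolidation_constants <- function(mat, sigma = 1) {
  E <- mat$E * 1e6
  nu <- mat$nu
  Kc <- E * (1 - nu) / ((1 + nu) * (1 - 2 * nu))   # drained oedometric modulus
  alpha <- mat$alpha
  M <- mat$M_Pa
  cv <- mat$permeability * M * Kc / (Kc + alpha^2 * M)
  p0 <- alpha * M / (Kc + alpha^2 * M) * sigma
  list(cv = cv, p0_MPa = p0, Kc = Kc)
}

expect_no_na <- function(x) expect_false(anyNA(x))
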