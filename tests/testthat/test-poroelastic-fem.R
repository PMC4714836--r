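test_that("principal strains sort eigenvalues and are rotation invariant", {
  expect_equal(principal_strains(diag(c(0.02, 0.01, -0.01))),
               c(0.02, 0.01, -0.01))
  # pure shear in 2D: closed-form eigenvalues (+gamma/2, -gamma/2)
  t2 <- matrix(c(0, 0.01, 0.01, 0), 2, 2)
  expect_equal(principal_strains(t2), c(0.01, 0, -0.01), tolerance = 1e-12)
  # invariance under a 45 degree rotation
  th <- pi / 4
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  t3 <- diag(c(0.02, 0.005, -0.01))
  expect_equal(principal_strains(R %*% t3 %*% t(R)), principal_strains(t3),
               tolerance = 1e-12)
  expect_error(principal_strains(matrix(c(0, 1, 0, 0), 2, 2)),
               class = "fgsopt_validation_error")
})

test_that("material constructors derive Biot constants correctly", {
  gr <- granulation_properties()
  expect_equal(gr$E, 0.2)
  expect_equal(gr$nu, 0.167)
  expect_equal(gr$permeability, 1e-14)
  expect_equal(gr$porosity, 0.8)
  # nearly incompressible constituents: alpha close to 1, M close to K_f/n
  expect_gt(gr$alpha, 0.999)
  expect_equal(gr$M_Pa, 2300e6 / (gr$alpha - 0.8 + 0.8), tolerance = 1e-3)
  expect_error(material_properties(-1, 0.3, 1e-14, 0.5))
  expect_error(material_properties(100, 0.6, 1e-14, 0.5))
})

test_that("drained patch test matches closed-form uniaxial elasticity", {
  blk <- build_patch_block(t = 1000, h = 1000, nx = 3, ny = 3)
  mat <- material_properties(E = 1000, nu = 0, permeability = 1e-12,
                             porosity = 0.5)
  sol <- solve_poroelastic(blk, mat,
                           load_case("compression", compression = 1,
                                     ramp = 1e4, steps = 5))
  # sigma / E = 1 / 1000: uniform axial strain, zero flux
  expect_equal(max(abs(sol$strains[, 2] + 1e-3)) / 1e-3, 0,
               tolerance = 1e-6)
  expect_lt(max(abs(sol$strains[, 1])), 1e-9)
  expect_lt(max(sol$v_um_s) * 1e-6 / 1e-3, 1e-3)  # m/s vs strain scale
})

test_that("zero load produces identically zero response", {
  blk <- build_patch_block(t = 1000, h = 1000, nx = 2, ny = 2)
  mat <- tiny_materials()$granulation
  sol <- solve_poroelastic(blk, mat,
                           load_case("compression", compression = 0))
  expect_equal(max(abs(sol$strains)), 0)
  expect_equal(max(sol$v_um_s), 0)
  expect_equal(max(abs(sol$p_nodal_MPa)), 0)
})

test_that("consolidation isochrones match the Terzaghi series within 2%", {
  mat <- granulation_properties()
  cc <- consolidation_constants(mat, sigma = 1)
  L_um <- 1000
  tc <- (L_um * 1e-6)^2 / cc$cv
  col <- build_consolidation_column(n_elements = 60, length = L_um)
  sol <- solve_poroelastic(
    col, mat,
    load_case("compression", compression = 1, ramp = tc * 1e-4, steps = 3),
    hold_until = tc, hold_steps = 400, keep_history = TRUE
  )
  Z <- col$nodes[, 2] / L_um
  for (Tv in c(0.1, 0.5, 1.0)) {
    idx <- which.min(abs(sol$times - Tv * tc))
    p_fe <- sol$p_history_MPa[, idx] / cc$p0_MPa
    p_ref <- terzaghi_pressure_ratio(Z, sol$times[idx] / tc)
    expect_lt(max(abs(p_fe - p_ref)), 0.02)
  }
})

test_that("Darcy flux agrees with the analytical consolidation gradient", {
  mat <- granulation_properties()
  cc <- consolidation_constants(mat, sigma = 1)
  L_um <- 1000
  tc <- (L_um * 1e-6)^2 / cc$cv
  col <- build_consolidation_column(n_elements = 80, length = L_um)
  sol <- solve_poroelastic(
    col, mat,
    load_case("compression", compression = 1, ramp = tc * 1e-4, steps = 3),
    hold_until = 0.5 * tc, hold_steps = 200
  )
  # element centroids at mid depth: v = k * |dp/dz|, independent series
  Tv <- sol$time / tc
  zc <- col$centroids[, 2] / L_um
  mid <- which(abs(zc - 0.5) < 0.1)
  dpdZ <- terzaghi_pressure_gradient(zc[mid], Tv)          # d(p/p0)/dZ
  grad_Pa_m <- abs(dpdZ) * (cc$p0_MPa * 1e6) / (L_um * 1e-6) # dp/dz in Pa/m
  v_ref_um <- mat$permeability * grad_Pa_m * 1e6            # m/s -> um/s
  expect_equal(sol$v_um_s[mid], v_ref_um, tolerance = 0.05)
})

test_that("response is linear in the load and superposes across cases", {
  spec <- tiny_spec()
  mesh <- build_scaffold_mesh(spec, porosity_law("constant", 120,
                                                 y_max = spec$h))
  mats <- tiny_materials()
  s1 <- solve_poroelastic(mesh, mats, load_case("compression",
                                                compression = 1))
  s2 <- solve_poroelastic(mesh, mats, load_case("compression",
                                                compression = 2))
  expect_equal(s2$strains, 2 * s1$strains, tolerance = 1e-8)
  expect_equal(s2$p_nodal_MPa, 2 * s1$p_nodal_MPa, tolerance = 1e-8)

  sh <- solve_poroelastic(mesh, mats, load_case("shear", shear = 0.5))
  mx <- solve_poroelastic(mesh, mats, load_case("mixed", compression = 1,
                                                shear = 0.5))
  expect_equal(mx$strains, s1$strains + sh$strains, tolerance = 1e-8)
  expect_equal(mx$displacement_um, s1$displacement_um + sh$displacement_um,
               tolerance = 1e-8)
})

test_that("pore pressure vanishes on drained boundary nodes", {
  spec <- tiny_spec()
  mesh <- build_scaffold_mesh(spec, porosity_law("constant", 120,
                                                 y_max = spec$h),
                              drainage = "pore_wall")
  sol <- solve_poroelastic(mesh, tiny_materials(), load_case("compression"))
  expect_equal(max(abs(sol$p_nodal_MPa[mesh$boundary$outer_drained])), 0)
  expect_true(all(sol$v_um_s >= 0))
  # principal strains sorted
  expect_true(all(sol$principal[, 1] >= sol$principal[, 2]))
  expect_true(all(sol$principal[, 2] >= sol$principal[, 3]))
})

test_that("solver validates inputs", {
  spec <- tiny_spec()
  mesh <- build_scaffold_mesh(spec, porosity_law("constant", 120,
                                                 y_max = spec$h))
  expect_error(
    solve_poroelastic(mesh, list(scaffold = scaffold_properties()),
                      load_case("compression")),
    class = "fgsopt_validation_error"
  )
})

test_that("coarse 3D solve produces a physically sensible field", {
  spec <- scaffold_spec(t = 1200, h = 1800, pore_rows = 2, pore_cols = 1,
                        dimensionality = "coarse_3d", elem_size = 200)
  mesh <- build_scaffold_mesh(spec, porosity_law("constant", 200,
                                                 y_max = spec$h))
  sol <- solve_poroelastic(mesh, tiny_materials(), load_case("compression"))
  expect_equal(sol$time, 1)
  expect_true(all(is.finite(sol$principal)))
  # compression: the dominant principal strain is compressive somewhere
  expect_lt(min(sol$principal[, 3]), -1e-5)
  # drained channel ends carry zero pressure
  expect_equal(max(abs(sol$p_nodal_MPa[mesh$boundary$outer_drained])), 0)
})
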