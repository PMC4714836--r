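test_that("octahedral shear strain matches closed forms", {
  # hydrostatic state has no deviatoric part
  expect_equal(octahedral_shear_strain(0.01, 0.01, 0.01), 0)
  # (2/3) * sqrt(2) * 0.01
  expect_equal(octahedral_shear_strain(0.01, 0, 0), 0.00942809,
               tolerance = 1e-6)
  # (delta, 0, -delta): (2/3) * sqrt(6) * delta
  expect_equal(octahedral_shear_strain(0.01, 0, -0.01), 0.01632993,
               tolerance = 1e-6)
})

test_that("gamma is permutation invariant and scale equivariant", {
  set.seed(11)
  for (rep in 1:25) {
    e <- rnorm(3, sd = 0.01)
    g0 <- octahedral_shear_strain(e[1], e[2], e[3])
    perms <- list(c(1, 3, 2), c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))
    for (p in perms) {
      expect_equal(octahedral_shear_strain(e[p[1]], e[p[2]], e[p[3]]), g0)
    }
    lam <- runif(1, 0, 5)
    expect_equal(octahedral_shear_strain(lam * e[1], lam * e[2], lam * e[3]),
                 lam * g0, tolerance = 1e-12)
  }
})

test_that("stimulus is linear with the printed constants", {
  p <- mechanoreg_params()
  expect_equal(p$a, 0.0375)
  expect_equal(p$b, 3)
  expect_equal(biophysical_stimulus(0.0375, 0, p), 1)  # gamma = a
  expect_equal(biophysical_stimulus(0, 3, p), 1)       # v = b
  expect_equal(biophysical_stimulus(0, 0, p), 0)
  expect_equal(biophysical_stimulus(0.0375, 3, p), 2)
  expect_error(biophysical_stimulus(-0.1, 0), class = "fgsopt_validation_error")
})

test_that("phenotype bands match the mechano-regulation diagram", {
  expect_equal(as.character(classify_stimulus(0.3)), "mature_bone")
  expect_equal(as.character(classify_stimulus(2)), "cartilage")
  expect_equal(as.character(classify_stimulus(0.005)), "resorption")
  expect_equal(as.character(classify_stimulus(0.7)), "immature_bone")
  expect_equal(as.character(classify_stimulus(5)), "fibrous")
})

test_that("the five bands partition the stimulus axis", {
  p <- mechanoreg_params()
  edges <- c(p$n_resorb, p$n_mature, 1, p$c)
  S <- sort(c(seq(0, 6, length.out = 4001),
              edges, edges - 1e-12, edges + 1e-12))
  ph <- classify_stimulus(S, p)
  expect_no_na(ph)
  expect_equal(length(ph), length(S))
  # monotone: larger S never maps to a lower-S band
  expect_true(all(diff(as.integer(ph)) >= 0))
  # boundary convention: closed on the lower edge
  expect_equal(as.character(classify_stimulus(p$n_mature)), "immature_bone")
  expect_equal(as.character(classify_stimulus(p$n_resorb)), "mature_bone")
  expect_equal(as.character(classify_stimulus(1)), "cartilage")
  expect_equal(as.character(classify_stimulus(p$c)), "fibrous")
  expect_equal(as.character(classify_stimulus(0)), "resorption")
})

test_that("parameter invariants are enforced", {
  expect_error(mechanoreg_params(n_resorb = 0.6))   # above n_mature
  expect_error(mechanoreg_params(c = 0.5))          # below 1
  expect_error(mechanoreg_params(a = -1))
})

test_that("stimulus fields cover exactly the granulation elements", {
  spec <- tiny_spec()
  mesh <- build_scaffold_mesh(spec, porosity_law("constant", 120,
                                                 y_max = spec$h))
  sol <- solve_poroelastic(mesh, tiny_materials(), load_case("compression"))
  field <- stimulus_field(sol, mesh)
  expect_equal(nrow(field), sum(mesh$region == "granulation"))
  expect_true(all(field$S >= 0))
  expect_equal(field$S, field$gamma / 0.0375 + field$v_um_s / 3,
               tolerance = 1e-12)
  # zero load: all S zero, resorption by the S = 0 convention
  sol0 <- solve_poroelastic(mesh, tiny_materials(),
                            load_case("compression", compression = 0))
  f0 <- stimulus_field(sol0, mesh)
  expect_equal(max(f0$S), 0)
  expect_true(all(f0$phenotype == "resorption"))
})
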