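test_that("mesh measures sum exactly to the domain measure", {
  spec <- tiny_spec()
  mesh <- build_scaffold_mesh(spec, porosity_law("constant", 120,
                                                 y_max = spec$h))
  expect_equal(sum(mesh$measure), spec$t * spec$h, tolerance = 1e-10)
  expect_setequal(unique(mesh$region), c("scaffold", "granulation"))
  # region labels partition the elements
  expect_equal(sum(mesh$region == "scaffold") +
                 sum(mesh$region == "granulation"), nrow(mesh$elements))
})

test_that("granulation measure approaches the analytic disc area", {
  spec4 <- scaffold_spec(t = 1200, h = 1800, pore_rows = 3, pore_cols = 2,
                         elem_size = 30)
  A <- 120
  mesh <- build_scaffold_mesh(spec4, porosity_law("constant", A,
                                                  y_max = spec4$h))
  analytic <- 6 * pi * A^2
  meshed <- sum(mesh$measure[mesh$region == "granulation"])
  expect_equal(meshed, analytic, tolerance = 0.05)
})

test_that("granulation measure converges with refinement", {
  A <- 120
  analytic <- 6 * pi * A^2
  errs <- vapply(c(120, 60, 30), function(hsz) {
    spec <- scaffold_spec(t = 1200, h = 1800, pore_rows = 3, pore_cols = 2,
                          elem_size = hsz)
    mesh <- build_scaffold_mesh(spec, porosity_law("constant", A,
                                                   y_max = spec$h))
    abs(sum(mesh$measure[mesh$region == "granulation"]) - analytic) / analytic
  }, numeric(1))
  expect_lt(errs[3], errs[1])
  expect_lt(errs[3], 0.05)
})

test_that("meshing is deterministic and monotone in the radii", {
  spec <- tiny_spec()
  law <- porosity_law("linear", c(100, 150), y_max = spec$h)
  m1 <- build_scaffold_mesh(spec, law)
  m2 <- build_scaffold_mesh(spec, law)
  expect_identical(m1$nodes, m2$nodes)
  expect_identical(m1$elements, m2$elements)
  expect_identical(m1$region, m2$region)

  gran <- function(A) {
    m <- build_scaffold_mesh(spec, porosity_law("constant", A,
                                                y_max = spec$h))
    sum(m$measure[m$region == "granulation"])
  }
  g <- vapply(c(80, 110, 140, 170), gran, numeric(1))
  expect_true(all(diff(g) > 0))
})

test_that("infeasible pore geometries raise a geometry error naming the row", {
  spec <- tiny_spec()  # dx = 400 um: radius 200 reaches the next pore
  expect_error(
    build_scaffold_mesh(spec, porosity_law("constant", 250, y_max = spec$h)),
    regexp = "row", class = "fgsopt_geometry_error"
  )
})

test_that("the reference 3D prism volume is t * t * h", {
  spec <- scaffold_spec(dimensionality = "coarse_3d", elem_size = 400)
  mesh <- build_scaffold_mesh(spec, porosity_law("constant", 150,
                                                 y_max = spec$h))
  expect_equal(sum(mesh$measure), 2548 * 2548 * 3822, tolerance = 1e-9)
  expect_equal(domain_measure_mm(mesh), 24.814, tolerance = 5e-5)
})

test_that("boundary tags are present and consistent", {
  spec <- tiny_spec()
  mesh <- build_scaffold_mesh(spec, porosity_law("constant", 120,
                                                 y_max = spec$h))
  expect_gt(length(mesh$boundary$top_loaded), 1)
  expect_gt(length(mesh$boundary$bottom_clamped), 1)
  expect_true(all(mesh$nodes[mesh$boundary$top_loaded, 2] == 0))
  expect_true(all(mesh$nodes[mesh$boundary$bottom_clamped, 2] == spec$h))
  # default 2D drainage: pores do not touch the outer boundary
  expect_length(mesh$boundary$outer_drained, 0)
  # pore-wall drainage: drained nodes lie on the scaffold/granulation rim
  mesh2 <- build_scaffold_mesh(spec, porosity_law("constant", 120,
                                                  y_max = spec$h),
                               drainage = "pore_wall")
  expect_gt(length(mesh2$boundary$outer_drained), 0)
})

test_that("consolidation column fixture has the benchmark layout", {
  col <- build_consolidation_column(10, 1000)
  expect_equal(nrow(col$elements), 20)  # 10 rows x 2 triangles
  expect_equal(sum(col$measure), 1000 * (1000 / 10), tolerance = 1e-10)
  expect_identical(col$boundary$outer_drained, col$boundary$top_loaded)
  expect_true(all(col$region == "granulation"))
  expect_error(build_consolidation_column(1, 1000),
               class = "fgsopt_validation_error")
  expect_error(build_consolidation_column(10, -5),
               class = "fgsopt_validation_error")
})

test_that("patch block fixture is homogeneous with fully drained boundary", {
  blk <- build_patch_block(t = 1000, h = 1500, nx = 2, ny = 3)
  expect_true(all(blk$region == "scaffold"))
  expect_equal(sum(blk$measure), 1000 * 1500, tolerance = 1e-10)
  blk3 <- build_patch_block(t = 2548, h = 3822, nx = 2, ny = 3,
                            dimensionality = "coarse_3d")
  expect_equal(sum(blk3$measure) / 1e9, 24.814, tolerance = 5e-5)
})

test_that("mesh tibble view matches the mesh", {
  spec <- tiny_spec()
  mesh <- build_scaffold_mesh(spec, porosity_law("constant", 120,
                                                 y_max = spec$h))
  tb <- as_tibble(mesh)
  expect_equal(nrow(tb), nrow(mesh$elements))
  expect_equal(sum(tb$measure), sum(mesh$measure))
})
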