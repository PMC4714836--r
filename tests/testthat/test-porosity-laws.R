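test_that("the four law kinds evaluate per their piecewise-linear equations", {
  # constant: A_1 everywhere
  law <- porosity_law("constant", 100)
  expect_equal(evaluate_radius(law, c(0, 1000, 3822)), rep(100, 3))

  # linear: midpoint of the interpolation between the end radii
  law <- porosity_law("linear", c(100, 200), y_min = 0, y_max = 3822)
  expect_equal(evaluate_radius(law, 1911), 150)
  expect_equal(evaluate_radius(law, 0), 100)
  expect_equal(evaluate_radius(law, 3822), 200)

  # degenerate linear with equal radii is the constant law
  law <- porosity_law("linear", c(150, 150))
  expect_equal(evaluate_radius(law, seq(0, 3822, length.out = 7)), rep(150, 7))
  expect_equal(law_gradient(law, 1000), 0)

  # bilinear and trilinear hit their breakpoint radii exactly
  law <- porosity_law("bilinear", c(100, 250, 150))
  expect_equal(evaluate_radius(law, law$breaks), c(100, 250, 150))
  law <- porosity_law("trilinear", c(120, 140, 160, 180))
  expect_equal(evaluate_radius(law, law$breaks), c(120, 140, 160, 180))
})

test_that("gradients match the slope of the active segment", {
  law <- porosity_law("linear", c(100, 200), y_min = 0, y_max = 3822)
  expect_equal(law_gradient(law, 1000), 100 / 3822, tolerance = 1e-12)
  expect_equal(law_gradient(porosity_law("constant", 80), 500), 0)
  # flat piecewise law: zero slope on every segment
  law <- porosity_law("trilinear", rep(150, 4))
  expect_equal(law_gradient(law, c(100, 1500, 2800, 3822)), rep(0, 4))
  # at an interior breakpoint the left segment's slope is returned
  law <- porosity_law("bilinear", c(100, 200, 200))
  m1 <- (200 - 100) / (law$breaks[2] - law$breaks[1])
  expect_equal(law_gradient(law, law$breaks[2]), m1)
})

test_that("laws are continuous at interior breakpoints for random draws", {
  set.seed(42)
  for (kind in c("bilinear", "trilinear")) {
    for (rep in 1:20) {
      A <- runif(match(kind, c("", "", "bilinear", "trilinear")),
                 min = 5, max = 300)
      law <- porosity_law(kind, A)
      for (yb in law$breaks[-c(1, length(law$breaks))]) {
        delta <- 1e-7 * 3822
        gap <- abs(evaluate_radius(law, yb - delta) -
                     evaluate_radius(law, yb + delta))
        expect_lt(gap, 1e-4)
      }
    }
  }
})

test_that("richer laws reproduce any constant law exactly (nesting)", {
  y <- seq(0, 3822, length.out = 41)
  base <- evaluate_radius(porosity_law("constant", 175), y)
  for (kind in c("linear", "bilinear", "trilinear")) {
    n <- match(kind, c("constant", "linear", "bilinear", "trilinear"))
    expect_equal(evaluate_radius(porosity_law(kind, rep(175, n)), y), base)
  }
})

test_that("evaluated radii stay within the coefficient extremes", {
  set.seed(7)
  for (rep in 1:20) {
    A <- runif(4, 5, 300)
    law <- porosity_law("trilinear", A)
    r <- evaluate_radius(law, seq(0, 3822, length.out = 101))
    expect_gte(min(r), min(A) - 1e-9)
    expect_lte(max(r), max(A) + 1e-9)
  }
})

test_that("domain and validation errors are raised", {
  law <- porosity_law("linear", c(100, 200))
  expect_error(evaluate_radius(law, -1), class = "fgsopt_domain_error")
  expect_error(evaluate_radius(law, 4000), class = "fgsopt_domain_error")
  expect_error(porosity_law("linear", 100), class = "fgsopt_validation_error")
  expect_error(porosity_law("constant", 400), class = "fgsopt_bound_error")
  expect_error(porosity_law("constant", 2), class = "fgsopt_bound_error")
  expect_error(porosity_law("bilinear", c(100, 100, 100), y_int = 5000),
               class = "fgsopt_validation_error")
})

test_that("design-vector adapters round-trip and enforce bounds", {
  law <- porosity_law("trilinear", c(120, 140, 160, 180))
  expect_equal(law_to_vector(law), c(120, 140, 160, 180))
  back <- vector_to_law("trilinear", law_to_vector(law))
  expect_equal(evaluate_radius(back, back$breaks), c(120, 140, 160, 180))
  expect_equal(law_to_vector(vector_to_law("constant", 100)), 100)
  expect_error(vector_to_law("constant", 400), class = "fgsopt_bound_error")
  expect_error(vector_to_law("trilinear", c(100, 100)),
               class = "fgsopt_validation_error")
})

test_that("radius profiles include breakpoints and export cleanly", {
  law <- porosity_law("bilinear", c(100, 200, 150))
  prof <- radius_profile(law, n = 21)
  expect_true(all(law$breaks %in% prof$y_um))
  expect_equal(prof$A_um, evaluate_radius(law, prof$y_um))
  expect_s3_class(prof, "tbl_df")
})
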