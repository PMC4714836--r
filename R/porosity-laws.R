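# Admissible pore-radius interval for every law coefficient, in micrometres.
A_LOWER <- 5
A_UPPER <- 300

LAW_KINDS <- c("constant", "linear", "bilinear", "trilinear")

n_coefficients <- function(kind) match(kind, LAW_KINDS)

#' Pore-radius bounds
#'
#' The admissible interval for every porosity-law coefficient, in micrometres.
#' All design variables of the optimizer live in this box.
#'
#' @return Named numeric vector with elements `lower` (5) and `upper` (300).
#' @export
pore_radius_bounds <- function() c(lower = A_LOWER, upper = A_UPPER)

#' Piecewise-linear porosity distribution law
#'
#' Constructs a law describing how the pore radius `A` (um) varies with the
#' height coordinate `y` (um) of a functionally graded scaffold. Four kinds
#' are supported: `constant` (one coefficient), `linear` (two), `bilinear`
#' (three) and `trilinear` (four). The coefficients are the radii attained at
#' the breakpoints of the law, ordered from `y_min` to `y_max`; between
#' breakpoints the radius interpolates linearly, so the evaluated law is
#' continuous on `[y_min, y_max]`.
#'
#' The coordinate convention places `y = 0` at the loaded face and
#' `y = y_max` at the clamped face. Interior breakpoints default to an equal
#' partition of `[y_min, y_max]` (the midpoint for `bilinear`, thirds for
#' `trilinear`) and may be overridden.
#'
#' @param kind One of `"constant"`, `"linear"`, `"bilinear"`, `"trilinear"`.
#' @param coefficients Numeric vector of radii `A_i` in um; length 1, 2, 3 or
#'   4 according to `kind`. Every coefficient must lie in
#'   `[pore_radius_bounds()["lower"], pore_radius_bounds()["upper"]]`.
#' @param y_min,y_max Domain of the law in um (defaults 0 and 3822).
#' @param y_int Interior breakpoint for the bilinear law (um).
#' @param y_int1,y_int2 Interior breakpoints for the trilinear law (um).
#' @return An object of class `porosity_law` with fields `kind`,
#'   `coefficients` and `breaks` (the breakpoint heights).
#' @examples
#' law <- porosity_law("linear", c(100, 200))
#' evaluate_radius(law, 1911)
#' @export
porosity_law <- function(kind = LAW_KINDS, coefficients,
                         y_min = 0, y_max = 3822,
                         y_int = NULL, y_int1 = NULL, y_int2 = NULL) {
  kind <- match.arg(kind)
  coefficients <- as.numeric(coefficients)
  nc <- n_coefficients(kind)
  if (length(coefficients) != nc) {
    abort(sprintf("a %s law needs %d coefficients, got %d",
                  kind, nc, length(coefficients)),
          class = "fgsopt_validation_error")
  }
  if (any(!is.finite(coefficients)) ||
      any(coefficients < A_LOWER) || any(coefficients > A_UPPER)) {
    abort(sprintf("all coefficients must lie in [%g, %g] um", A_LOWER, A_UPPER),
          class = "fgsopt_bound_error")
  }
  if (!is.finite(y_min) || !is.finite(y_max) || y_min >= y_max) {
    abort("y_min must be smaller than y_max", class = "fgsopt_validation_error")
  }
  breaks <- switch(kind,
    constant  = c(y_min, y_max),
    linear    = c(y_min, y_max),
    bilinear  = c(y_min, y_int %||% mean(c(y_min, y_max)), y_max),
    trilinear = c(y_min,
                  y_int1 %||% (y_min + (y_max - y_min) / 3),
                  y_int2 %||% (y_min + 2 * (y_max - y_min) / 3),
                  y_max)
  )
  if (any(diff(breaks) <= 0)) {
    abort("breakpoints must be strictly increasing",
          class = "fgsopt_validation_error")
  }
  structure(
    list(kind = kind, coefficients = coefficients, breaks = breaks),
    class = "porosity_law"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Radii at the breakpoints: the constant law holds A_1 at both ends.
break_values <- function(law) {
  if (law$kind == "constant") rep(law$coefficients, 2L) else law$coefficients
}

#' Evaluate the pore radius of a porosity law
#'
#' @param law A [porosity_law()].
#' @param y Height coordinate(s) in um; must lie within the law's domain.
#' @return Pore radius (um), vectorized over `y`.
#' @export
evaluate_radius <- function(law, y) {
  stopifnot(inherits(law, "porosity_law"))
  rng <- range(law$breaks)
  if (any(!is.finite(y)) || any(y < rng[1]) || any(y > rng[2])) {
    abort(sprintf("y must lie in [%g, %g] um", rng[1], rng[2]),
          class = "fgsopt_domain_error")
  }
  stats::approx(law$breaks, break_values(law), xout = y, ties = "ordered")$y
}

#' Gradient of a porosity law
#'
#' Slope `m` (um/um) of the active linear segment at height `y`. At an
#' interior breakpoint the left segment's slope is returned (a deterministic
#' convention; the gradient is diagnostic only).
#'
#' @inheritParams evaluate_radius
#' @return Slope(s) `m`, 0 for the constant law.
#' @export
law_gradient <- function(law, y) {
  stopifnot(inherits(law, "porosity_law"))
  rng <- range(law$breaks)
  if (any(!is.finite(y)) || any(y < rng[1]) || any(y > rng[2])) {
    abort(sprintf("y must lie in [%g, %g] um", rng[1], rng[2]),
          class = "fgsopt_domain_error")
  }
  vals <- break_values(law)
  slopes <- diff(vals) / diff(law$breaks)
  # segment index: left-continuous so y == break -> left segment
  idx <- findInterval(y, law$breaks, left.open = TRUE)
  idx[idx < 1L] <- 1L
  idx[idx > length(slopes)] <- length(slopes)
  slopes[idx]
}

#' Convert between a porosity law and the optimizer's design vector
#'
#' The design variables of the porosity optimization are the law coefficients
#' `A_i` in breakpoint order. These two adapters round-trip exactly.
#'
#' @param law A [porosity_law()].
#' @return `law_to_vector()`: numeric vector of coefficients.
#' @export
law_to_vector <- function(law) {
  stopifnot(inherits(law, "porosity_law"))
  law$coefficients
}

#' @rdname law_to_vector
#' @param kind Law kind (see [porosity_law()]).
#' @param x Numeric design vector whose length matches `kind`.
#' @param ... Passed on to [porosity_law()] (domain and breakpoints).
#' @return `vector_to_law()`: a `porosity_law`.
#' @export
vector_to_law <- function(kind, x, ...) {
  porosity_law(kind = kind, coefficients = x, ...)
}

#' Sampled radius profile of a law
#'
#' @param law A [porosity_law()].
#' @param n Number of equally spaced sample heights.
#' @return A tibble with columns `y_um` and `A_um` (breakpoints are always
#'   included so piecewise-linear extremes are exact).
#' @export
radius_profile <- function(law, n = 101) {
  y <- sort(unique(c(seq(law$breaks[1], law$breaks[length(law$breaks)],
                         length.out = n), law$breaks)))
  tibble(y_um = y, A_um = evaluate_radius(law, y))
}

#' @export
print.porosity_law <- function(x, ...) {
  cat(sprintf("<porosity_law: %s>\n", x$kind))
  cat("  A (um):", paste(signif(x$coefficients, 5), collapse = ", "), "\n")
  cat("  breakpoints y (um):", paste(signif(x$breaks, 6), collapse = ", "), "\n")
  invisible(x)
}

#' @export
format.porosity_law <- function(x, ...) {
  sprintf("%s[%s]", x$kind, paste(signif(x$coefficients, 5), collapse = ","))
}

#' Plot a porosity law's radius profile
#'
#' @param object A [porosity_law()].
#' @param ... Unused.
#' @return A ggplot of pore radius versus height.
#' @exportS3Method ggplot2::autoplot
autoplot.porosity_law <- function(object, ...) {
  prof <- radius_profile(object)
  ggplot2::ggplot(prof, ggplot2::aes(x = .data$y_um, y = .data$A_um)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_point(data = tibble(y_um = object$breaks,
                                      A_um = break_values(object))) +
    ggplot2::labs(x = "height y (µm)", y = "pore radius A (µm)",
                  title = sprintf("%s porosity law", object$kind)) +
    ggplot2::ylim(0, NA)
}
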