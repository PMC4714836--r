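#' Scaffold geometry specification
#'
#' Describes the prismatic scaffold domain and its pore lattice. The default
#' dimensions are the reference design: a square base of edge
#' `t = 2548` um and height `h = 3822` um. Circular pores (radius given by a
#' porosity law evaluated at each pore row's centre height) are arranged on a
#' regular lattice of `pore_rows` rows along `y` and `pore_cols` columns
#' along `x`; in `coarse_3d` mode the pores are channels running through the
#' depth (`z`) of the prism, so the radius varies only with `y`.
#'
#' The lattice centres sit at the cell centres of an even subdivision of the
#' domain, which leaves walls of at least
#' `min(t/pore_cols, h/pore_rows)/2 - 300` um at the maximum admissible
#' radius; the defaults (5 x 3) keep that margin positive.
#'
#' @param t Base edge in um (default 2548).
#' @param h Height in um (default 3822).
#' @param pore_rows,pore_cols Pore lattice dimensions (default 5 x 3).
#' @param dimensionality `"plane_strain_2d"` (default) or `"coarse_3d"`.
#' @param elem_size Target element size in um. The reference discretization
#'   uses 40 um; desk-scale studies use coarser values.
#' @return An object of class `scaffold_spec`.
#' @export
scaffold_spec <- function(t = 2548, h = 3822,
                          pore_rows = 5, pore_cols = 3,
                          dimensionality = c("plane_strain_2d", "coarse_3d"),
                          elem_size = 40) {
  dimensionality <- match.arg(dimensionality)
  stopifnot(t > 0, h > 0, pore_rows >= 1, pore_cols >= 1, elem_size > 0)
  dx <- t / pore_cols
  dy <- h / pore_rows
  centers <- expand.grid(
    x = dx * (seq_len(pore_cols) - 0.5),
    y = dy * (seq_len(pore_rows) - 0.5)
  )
  structure(
    list(t = t, h = h,
         pore_rows = pore_rows, pore_cols = pore_cols,
         spacing = c(x = dx, y = dy),
         centers = as.matrix(centers),
         dimensionality = dimensionality,
         elem_size = elem_size),
    class = "scaffold_spec"
  )
}

#' @export
print.scaffold_spec <- function(x, ...) {
  cat(sprintf("<scaffold_spec: %g x %g um, %s, %d x %d pores, elem %g um>\n",
              x$t, x$h, x$dimensionality, x$pore_rows, x$pore_cols,
              x$elem_size))
  invisible(x)
}

# Structured simplex grid on [0,Lx] x [0,Ly] (x [0,Lz]).
# 2D: each cell split into 2 triangles; 3D: each cube cell into 6 tetrahedra
# (Kuhn subdivision, conforming across cells).
structured_simplex_mesh <- function(L, n) {
  d <- length(L)
  stopifnot(d %in% c(2L, 3L), all(n >= 1))
  gx <- seq(0, L[1], length.out = n[1] + 1)
  gy <- seq(0, L[2], length.out = n[2] + 1)
  if (d == 2L) {
    nodes <- as.matrix(expand.grid(x = gx, y = gy))
    nid <- function(i, j) (j - 1L) * (n[1] + 1L) + i
    cells <- expand.grid(i = seq_len(n[1]), j = seq_len(n[2]))
    a <- nid(cells$i,      cells$j)
    b <- nid(cells$i + 1L, cells$j)
    c_ <- nid(cells$i + 1L, cells$j + 1L)
    dd <- nid(cells$i,     cells$j + 1L)
    elements <- rbind(cbind(a, b, c_), cbind(a, c_, dd))
  } else {
    gz <- seq(0, L[3], length.out = n[3] + 1)
    nodes <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
    nid <- function(i, j, k)
      ((k - 1L) * (n[2] + 1L) + (j - 1L)) * (n[1] + 1L) + i
    cells <- expand.grid(i = seq_len(n[1]), j = seq_len(n[2]),
                         k = seq_len(n[3]))
    v <- list(
      nid(cells$i,      cells$j,      cells$k),
      nid(cells$i + 1L, cells$j,      cells$k),
      nid(cells$i,      cells$j + 1L, cells$k),
      nid(cells$i + 1L, cells$j + 1L, cells$k),
      nid(cells$i,      cells$j,      cells$k + 1L),
      nid(cells$i + 1L, cells$j,      cells$k + 1L),
      nid(cells$i,      cells$j + 1L, cells$k + 1L),
      nid(cells$i + 1L, cells$j + 1L, cells$k + 1L)
    )
    # six tetrahedra sharing the main diagonal v1-v8
    tets <- list(c(1, 2, 4, 8), c(1, 4, 3, 8), c(1, 3, 7, 8),
                 c(1, 7, 5, 8), c(1, 5, 6, 8), c(1, 6, 2, 8))
    elements <- do.call(rbind, lapply(tets, function(tt)
      cbind(v[[tt[1]]], v[[tt[2]]], v[[tt[3]]], v[[tt[4]]])))
  }
  dimnames(elements) <- NULL
  list(nodes = nodes, elements = elements)
}

simplex_measures <- function(nodes, elements) {
  d <- ncol(nodes)
  p1 <- nodes[elements[, 1], , drop = FALSE]
  if (d == 2L) {
    u <- nodes[elements[, 2], , drop = FALSE] - p1
    v <- nodes[elements[, 3], , drop = FALSE] - p1
    abs(u[, 1] * v[, 2] - u[, 2] * v[, 1]) / 2
  } else {
    u <- nodes[elements[, 2], , drop = FALSE] - p1
    v <- nodes[elements[, 3], , drop = FALSE] - p1
    w <- nodes[elements[, 4], , drop = FALSE] - p1
    abs(u[, 1] * (v[, 2] * w[, 3] - v[, 3] * w[, 2]) -
        u[, 2] * (v[, 1] * w[, 3] - v[, 3] * w[, 1]) +
        u[, 3] * (v[, 1] * w[, 2] - v[, 2] * w[, 1])) / 6
  }
}

element_centroids <- function(nodes, elements) {
  d <- ncol(nodes)
  acc <- 0
  for (k in seq_len(ncol(elements)))
    acc <- acc + nodes[elements[, k], , drop = FALSE]
  acc / ncol(elements)
}

new_scaffold_mesh <- function(nodes, elements, region, boundary, spec = NULL,
                              law = NULL, fixed_components = NULL) {
  structure(
    list(nodes = nodes, elements = elements, region = region,
         measure = simplex_measures(nodes, elements),
         centroids = element_centroids(nodes, elements),
         boundary = boundary, spec = spec, law = law,
         fixed_components = fixed_components),
    class = "scaffold_mesh"
  )
}

#' Build the two-phase scaffold + granulation mesh
#'
#' Discretizes the scaffold prism on a structured simplex grid (triangles in
#' 2D plane strain, tetrahedra in coarse 3D) and labels each element
#' `"granulation"` when its centroid falls inside a pore disc, `"scaffold"`
#' otherwise. Pore radii are taken from the porosity law evaluated at each
#' lattice row's centre height, so the radius is constant within a row and
#' varies across rows.
#'
#' Boundary node sets are tagged: `top_loaded` (the loaded face `y = 0`,
#' tied to a rigid plate by the solver), `bottom_clamped` (`y = h`), and
#' `outer_drained` (free-exudation surface where pore pressure is fixed to
#' zero). In 3D the drained set is the granulation nodes on the front/back
#' faces where the pore channels open. In the plane-strain section the pores
#' do not touch the outer boundary, so with the default
#' `drainage = "outer_surface"` the drained set is empty: the channels drain
#' out of plane, which the section cannot represent over a short ramp, and
#' the in-plane response is effectively undrained. `drainage = "pore_wall"`
#' instead fixes `p = 0` on the pore rims (fully drained pores).
#'
#' @param spec A [scaffold_spec()].
#' @param law A [porosity_law()] defined on `[0, spec$h]`.
#' @param drainage Drained-boundary convention for the 2D section (see
#'   Details).
#' @return An object of class `scaffold_mesh` with node coordinates (um),
#'   simplex connectivity, per-element region labels and measures (um^2 per
#'   unit depth in 2D, um^3 in 3D), and boundary tag node sets.
#' @export
build_scaffold_mesh <- function(spec, law,
                                drainage = c("outer_surface", "pore_wall")) {
  stopifnot(inherits(spec, "scaffold_spec"), inherits(law, "porosity_law"))
  drainage <- match.arg(drainage)
  rng <- range(law$breaks)
  if (rng[1] > 0 || rng[2] < spec$h) {
    abort("porosity law domain must cover [0, h]",
          class = "fgsopt_validation_error")
  }
  row_y <- unique(spec$centers[, "y"])
  row_A <- evaluate_radius(law, row_y)
  check_pore_feasibility(spec, row_y, row_A)

  d <- if (spec$dimensionality == "plane_strain_2d") 2L else 3L
  L <- if (d == 2L) c(spec$t, spec$h) else c(spec$t, spec$h, spec$t)
  n <- pmax(1L, as.integer(round(L / spec$elem_size)))
  g <- structured_simplex_mesh(L, n)
  cen <- element_centroids(g$nodes, g$elements)

  region <- rep("scaffold", nrow(g$elements))
  A_of_row <- stats::setNames(row_A, as.character(row_y))
  for (r in seq_len(nrow(spec$centers))) {
    cx <- spec$centers[r, "x"]; cy <- spec$centers[r, "y"]
    A <- A_of_row[[as.character(cy)]]
    inside <- (cen[, 1] - cx)^2 + (cen[, 2] - cy)^2 < A^2
    region[inside] <- "granulation"
  }

  tol <- 1e-9 * max(L)
  top <- which(abs(g$nodes[, 2]) < tol)
  bottom <- which(abs(g$nodes[, 2] - spec$h) < tol)

  gran_nodes <- unique(as.vector(g$elements[region == "granulation", ]))
  if (d == 2L) {
    if (drainage == "pore_wall") {
      scaf_nodes <- unique(as.vector(g$elements[region == "scaffold", ]))
      drained <- intersect(gran_nodes, scaf_nodes) # pore rim
    } else {
      # outer granulation surface: the pores do not touch the section
      # boundary, so the set is empty -- the channels drain out of plane,
      # which the plane-strain section cannot see during a 1 s ramp
      on_bnd <- which(abs(g$nodes[, 1]) < tol | abs(g$nodes[, 1] - L[1]) < tol |
                        abs(g$nodes[, 2]) < tol | abs(g$nodes[, 2] - L[2]) < tol)
      drained <- intersect(gran_nodes, on_bnd)
    }
  } else {
    face <- which(abs(g$nodes[, 3]) < tol | abs(g$nodes[, 3] - L[3]) < tol)
    drained <- intersect(gran_nodes, face)
  }

  new_scaffold_mesh(
    g$nodes, g$elements, region,
    boundary = list(top_loaded = top, bottom_clamped = bottom,
                    outer_drained = drained),
    spec = spec, law = law
  )
}

check_pore_feasibility <- function(spec, row_y, row_A) {
  dx <- spec$spacing["x"]; dy <- spec$spacing["y"]
  for (r in seq_along(row_y)) {
    A <- row_A[r]
    problems <- character(0)
    if (spec$pore_cols > 1 && 2 * A >= dx)
      problems <- c(problems, "adjacent pores in the row overlap")
    # nearest lattice centre sits dx/2 from the lateral walls
    if (A >= dx / 2)
      problems <- c(problems, "pore breaches the lateral boundary")
    if (r < length(row_y) && row_A[r] + row_A[r + 1] >= dy)
      problems <- c(problems, "pore overlaps the next row")
    if (row_y[r] - A <= 0 || row_y[r] + A >= spec$h)
      problems <- c(problems, "pore breaches the top/bottom face")
    if (length(problems)) {
      abort(sprintf("infeasible pore geometry in row %d (y = %g um, A = %g um): %s",
                    r, row_y[r], A, paste(unique(problems), collapse = "; ")),
            class = "fgsopt_geometry_error")
    }
  }
  invisible(TRUE)
}

#' Total and per-region measures of a mesh
#'
#' @param mesh A `scaffold_mesh`.
#' @return A tibble with one row per region plus a `total` row; `measure` is
#'   um^2 x unit depth in 2D, um^3 in 3D.
#' @export
mesh_measures <- function(mesh) {
  stopifnot(inherits(mesh, "scaffold_mesh"))
  by_region <- tapply(mesh$measure, mesh$region, sum)
  tibble(
    region = c(names(by_region), "total"),
    measure = c(as.numeric(by_region), sum(mesh$measure))
  )
}

#' Total domain measure of the reference scaffold prism
#'
#' Bookkeeping helper: the volume of the full prism `t x t x h` in mm^3
#' computed from a mesh in `coarse_3d` mode (or `t x h x` unit depth in 2D,
#' returned in mm^2).
#'
#' @param mesh A `scaffold_mesh`.
#' @return Total measure in mm^3 (3D) or mm^2 (2D).
#' @export
domain_measure_mm <- function(mesh) {
  stopifnot(inherits(mesh, "scaffold_mesh"))
  d <- ncol(mesh$nodes)
  sum(mesh$measure) / 1000^d
}

#' @export
print.scaffold_mesh <- function(x, ...) {
  d <- ncol(x$nodes)
  cat(sprintf("<scaffold_mesh: %dD, %d nodes, %d elements (%d granulation)>\n",
              d, nrow(x$nodes), nrow(x$elements),
              sum(x$region == "granulation")))
  invisible(x)
}

#' @exportS3Method tibble::as_tibble
as_tibble.scaffold_mesh <- function(x, ...) {
  cen <- x$centroids
  out <- tibble(element = seq_len(nrow(x$elements)),
                x_um = cen[, 1], y_um = cen[, 2])
  if (ncol(cen) == 3L) out$z_um <- cen[, 3]
  out$region <- x$region
  out$measure <- x$measure
  out
}

#' Terzaghi consolidation column fixture
#'
#' A one-dimensional consolidation benchmark realised as a thin 2D strip:
#' `n_elements` element rows along `y`, lateral displacement fixed everywhere
#' (oedometric conditions), drained and loaded at `y = 0`, clamped and
#' impermeable at `y = length`. Used to validate the poroelastic solver
#' against the classical analytical series.
#'
#' @param n_elements Number of element rows along the column (>= 2).
#' @param length Column length in um.
#' @return A single-region (`granulation`) `scaffold_mesh` with lateral
#'   displacement constrained (oedometric column).
#' @export
build_consolidation_column <- function(n_elements = 40, length = 1000) {
  if (n_elements < 2) {
    abort("n_elements must be at least 2", class = "fgsopt_validation_error")
  }
  if (length <= 0) {
    abort("length must be positive", class = "fgsopt_validation_error")
  }
  width <- length / n_elements
  g <- structured_simplex_mesh(c(width, length), c(1L, as.integer(n_elements)))
  tol <- 1e-9 * length
  top <- which(abs(g$nodes[, 2]) < tol)
  bottom <- which(abs(g$nodes[, 2] - length) < tol)
  new_scaffold_mesh(
    g$nodes, g$elements, rep("granulation", nrow(g$elements)),
    boundary = list(top_loaded = top, bottom_clamped = bottom,
                    outer_drained = top),
    fixed_components = list(x = seq_len(nrow(g$nodes)))
  )
}

#' Homogeneous patch-test block fixture
#'
#' A pore-free block with the same boundary tags as the scaffold, used for
#' drained-limit patch tests against closed-form uniaxial elasticity. All
#' outer boundary nodes are drained so the steady response is purely elastic.
#'
#' @param t,h Block dimensions in um.
#' @param nx,ny Element grid.
#' @param dimensionality `"plane_strain_2d"` or `"coarse_3d"`.
#' @return A single-region (`scaffold`) `scaffold_mesh`.
#' @export
build_patch_block <- function(t = 2548, h = 3822, nx = 4, ny = 6,
                              dimensionality = c("plane_strain_2d",
                                                 "coarse_3d")) {
  dimensionality <- match.arg(dimensionality)
  d <- if (dimensionality == "plane_strain_2d") 2L else 3L
  L <- if (d == 2L) c(t, h) else c(t, h, t)
  n <- if (d == 2L) c(nx, ny) else c(nx, ny, nx)
  g <- structured_simplex_mesh(L, as.integer(n))
  tol <- 1e-9 * max(L)
  top <- which(abs(g$nodes[, 2]) < tol)
  bottom <- which(abs(g$nodes[, 2] - h) < tol)
  on_bnd <- abs(g$nodes[, 1]) < tol | abs(g$nodes[, 1] - t) < tol |
    abs(g$nodes[, 2]) < tol | abs(g$nodes[, 2] - h) < tol
  if (d == 3L) {
    on_bnd <- on_bnd | abs(g$nodes[, 3]) < tol | abs(g$nodes[, 3] - t) < tol
  }
  new_scaffold_mesh(
    g$nodes, g$elements, rep("scaffold", nrow(g$elements)),
    boundary = list(top_loaded = top, bottom_clamped = bottom,
                    outer_drained = which(on_bnd))
  )
}
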