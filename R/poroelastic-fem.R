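# Quasi-static Biot poroelasticity on simplex meshes (linear u-p elements,
# backward-Euler time stepping). Geometry enters in micrometres and MPa at the
# API; assembly is done in SI (m, Pa, s).

UM <- 1e-6   # metres per micrometre
MPA <- 1e6   # pascal per megapascal

#' Poroelastic material properties
#'
#' Biphasic (solid skeleton + pore fluid) linear poroelastic material.
#' The Biot coefficient and storage modulus are derived from the grain and
#' fluid bulk moduli by the standard relations
#' `alpha = 1 - K_drained / K_grain` and
#' `1/M = (alpha - n) / K_grain + n / K_fluid`,
#' with `K_drained = E / (3 (1 - 2 nu))`.
#'
#' @param E Young's modulus of the drained skeleton, MPa.
#' @param nu Poisson's ratio of the drained skeleton.
#' @param permeability Darcy permeability (already divided by fluid
#'   viscosity), m^4/(N s) = m^2/(Pa s).
#' @param porosity Fluid volume fraction `n` in (0, 1).
#' @param K_grain,K_fluid Bulk moduli of the solid grains and the pore
#'   fluid, MPa (default 2300 each).
#' @return An object of class `material_properties` carrying the inputs and
#'   the derived SI quantities `alpha` and `M_Pa`.
#' @export
material_properties <- function(E, nu, permeability, porosity,
                                K_grain = 2300, K_fluid = 2300) {
  stopifnot(E > 0, nu >= 0, nu < 0.5, permeability > 0,
            porosity > 0, porosity < 1, K_grain > 0, K_fluid > 0)
  K_drained <- E / (3 * (1 - 2 * nu))
  alpha <- max(0, min(1, 1 - K_drained / K_grain))
  inv_M <- (alpha - porosity) / (K_grain * MPA) + porosity / (K_fluid * MPA)
  structure(
    list(E = E, nu = nu, permeability = permeability, porosity = porosity,
         K_grain = K_grain, K_fluid = K_fluid,
         alpha = alpha, M_Pa = 1 / inv_M),
    class = "material_properties"
  )
}

#' Granulation tissue reference properties
#'
#' The early-repair soft tissue assumed to fill the scaffold pores:
#' `E = 0.2` MPa, `nu = 0.167`, permeability `1e-14` m^4/(N s), porosity
#' 0.8, grain and fluid bulk moduli 2300 MPa.
#'
#' @return A [material_properties()] object.
#' @export
granulation_properties <- function() {
  material_properties(E = 0.2, nu = 0.167, permeability = 1e-14,
                      porosity = 0.8, K_grain = 2300, K_fluid = 2300)
}

#' Scaffold biomaterial properties
#'
#' The scaffold solid with a selectable Young's modulus (the study values
#' are 500, 1000 and 1500 MPa). The remaining poroelastic constants are not
#' design variables; the defaults (`nu = 0.3`, permeability `1e-14`
#' m^4/(N s), porosity 0.5, bulk moduli 2300 MPa) follow the established
#' biphasic scaffold models this line of work builds on and can be
#' overridden.
#'
#' @param E Young's modulus, MPa.
#' @inheritParams material_properties
#' @return A [material_properties()] object.
#' @export
scaffold_properties <- function(E = 1000, nu = 0.3, permeability = 1e-14,
                                porosity = 0.5, K_grain = 2300,
                                K_fluid = 2300) {
  material_properties(E = E, nu = nu, permeability = permeability,
                      porosity = porosity, K_grain = K_grain,
                      K_fluid = K_fluid)
}

#' Loading case for the scaffold model
#'
#' Tractions applied to the rigid plate tied to the loaded face: a vertical
#' compressive traction (`compression` kind), a horizontal shear traction
#' (`shear`), or their vector sum (`mixed`). The load is ramped linearly
#' over `ramp` seconds and the solution is evaluated at the end of the ramp.
#'
#' @param kind `"compression"`, `"shear"` or `"mixed"`.
#' @param compression Compressive traction magnitude, MPa (default 1).
#' @param shear Shear traction magnitude, MPa (default 0.5).
#' @param ramp Ramp duration, s (default 1).
#' @param steps Number of implicit time steps across the ramp (default 10).
#' @return An object of class `load_case`.
#' @export
load_case <- function(kind = c("compression", "shear", "mixed"),
                      compression = 1, shear = 0.5, ramp = 1, steps = 10) {
  kind <- match.arg(kind)
  stopifnot(compression >= 0, shear >= 0, ramp > 0, steps >= 1)
  structure(
    list(kind = kind, compression = compression, shear = shear,
         ramp = ramp, steps = as.integer(steps)),
    class = "load_case"
  )
}

# traction vector (Pa) on the plate for a load case, by spatial dimension
plate_traction <- function(load, d) {
  tv <- numeric(d)
  if (load$kind %in% c("compression", "mixed"))
    tv[2] <- load$compression * MPA   # presses along +y (into the body)
  if (load$kind %in% c("shear", "mixed"))
    tv[1] <- load$shear * MPA
  tv
}

# plane-strain / 3D elasticity matrix (engineering shear strains), Pa
elastic_matrix <- function(E_Pa, nu, d) {
  lam <- E_Pa * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E_Pa / (2 * (1 + nu))
  if (d == 2L) {
    matrix(c(lam + 2 * mu, lam, 0,
             lam, lam + 2 * mu, 0,
             0, 0, mu), 3, 3, byrow = TRUE)
  } else {
    C <- matrix(0, 6, 6)
    C[1:3, 1:3] <- lam
    diag(C)[1:3] <- lam + 2 * mu
    diag(C)[4:6] <- mu
    C
  }
}

# shape-function gradients (rows = local nodes, cols = dims) and measure, SI
simplex_grads <- function(X) {
  d <- ncol(X)
  Jm <- t(X[-1, , drop = FALSE]) - X[1, ]      # d x d
  detJ <- det(Jm)
  grads_rest <- solve(Jm)                       # rows: nodes 2..d+1
  G <- rbind(-colSums(grads_rest), grads_rest)
  list(G = G, vol = abs(detJ) / factorial(d))
}

strain_B <- function(G) {
  d <- ncol(G); nn <- nrow(G)
  if (d == 2L) {
    B <- matrix(0, 3, 2 * nn)
    for (i in seq_len(nn)) {
      B[1, 2 * i - 1] <- G[i, 1]
      B[2, 2 * i] <- G[i, 2]
      B[3, 2 * i - 1] <- G[i, 2]
      B[3, 2 * i] <- G[i, 1]
    }
  } else {
    B <- matrix(0, 6, 3 * nn)
    for (i in seq_len(nn)) {
      ix <- 3 * i - 2; iy <- 3 * i - 1; iz <- 3 * i
      B[1, ix] <- G[i, 1]; B[2, iy] <- G[i, 2]; B[3, iz] <- G[i, 3]
      B[4, ix] <- G[i, 2]; B[4, iy] <- G[i, 1]
      B[5, iy] <- G[i, 3]; B[5, iz] <- G[i, 2]
      B[6, ix] <- G[i, 3]; B[6, iz] <- G[i, 1]
    }
  }
  B
}

# Vectorized assembly for linear (constant-strain) triangles: closed-form
# shape-function gradients b_i = dN_i/dx, c_i = dN_i/dy and 2x2 nodal
# stiffness blocks expressed directly in (lambda, mu), evaluated across all
# elements at once.
assemble_tri2d <- function(nodes_m, elements, region, materials, n_u) {
  ne <- nrow(elements)
  n1 <- elements[, 1]; n2 <- elements[, 2]; n3 <- elements[, 3]
  x1 <- nodes_m[n1, 1]; y1 <- nodes_m[n1, 2]
  x2 <- nodes_m[n2, 1]; y2 <- nodes_m[n2, 2]
  x3 <- nodes_m[n3, 1]; y3 <- nodes_m[n3, 2]
  det <- (x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1)
  vol <- abs(det) / 2
  b <- cbind((y2 - y3) / det, (y3 - y1) / det, (y1 - y2) / det)
  cc <- cbind((x3 - x2) / det, (x1 - x3) / det, (x2 - x1) / det)

  prop <- function(f) {
    out <- numeric(ne)
    for (rg in unique(region)) out[region == rg] <- f(materials[[rg]])
    out
  }
  E <- prop(function(m) m$E * MPA)
  nu <- prop(function(m) m$nu)
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  alpha <- prop(function(m) m$alpha)
  perm <- prop(function(m) m$permeability)
  invM <- prop(function(m) 1 / m$M_Pa)

  ux <- cbind(2L * n1 - 1L, 2L * n2 - 1L, 2L * n3 - 1L)
  uy <- ux + 1L
  pd <- n_u + cbind(n1, n2, n3)

  nblk <- 9L * ne
  ki <- integer(4L * nblk); kj <- integer(4L * nblk); kv <- numeric(4L * nblk)
  hi <- integer(nblk); hj <- integer(nblk); hv <- numeric(nblk)
  qi <- integer(2L * nblk); qj <- integer(2L * nblk); qv <- numeric(2L * nblk)
  pos_k <- 0L; pos_h <- 0L; pos_q <- 0L
  idx <- seq_len(ne)
  for (i in 1:3) {
    for (j in 1:3) {
      bi <- b[, i]; ci <- cc[, i]; bj <- b[, j]; cj <- cc[, j]
      # displacement stiffness, 2x2 nodal block
      ki[pos_k + idx] <- ux[, i]; kj[pos_k + idx] <- ux[, j]
      kv[pos_k + idx] <- ((lam + 2 * mu) * bi * bj + mu * ci * cj) * vol
      pos_k <- pos_k + ne
      ki[pos_k + idx] <- ux[, i]; kj[pos_k + idx] <- uy[, j]
      kv[pos_k + idx] <- (lam * bi * cj + mu * ci * bj) * vol
      pos_k <- pos_k + ne
      ki[pos_k + idx] <- uy[, i]; kj[pos_k + idx] <- ux[, j]
      kv[pos_k + idx] <- (lam * ci * bj + mu * bi * cj) * vol
      pos_k <- pos_k + ne
      ki[pos_k + idx] <- uy[, i]; kj[pos_k + idx] <- uy[, j]
      kv[pos_k + idx] <- ((lam + 2 * mu) * ci * cj + mu * bi * bj) * vol
      pos_k <- pos_k + ne
      # pressure conductivity
      hi[pos_h + idx] <- pd[, i]; hj[pos_h + idx] <- pd[, j]
      hv[pos_h + idx] <- perm * (bi * bj + ci * cj) * vol
      pos_h <- pos_h + ne
      # coupling (value independent of the pressure node j)
      qi[pos_q + idx] <- ux[, i]; qj[pos_q + idx] <- pd[, j]
      qv[pos_q + idx] <- alpha * bi * vol / 3
      pos_q <- pos_q + ne
      qi[pos_q + idx] <- uy[, i]; qj[pos_q + idx] <- pd[, j]
      qv[pos_q + idx] <- alpha * ci * vol / 3
      pos_q <- pos_q + ne
    }
  }
  si <- as.vector(pd)
  sv <- rep(invM * vol / 3, 3L)
  list(ki = ki, kj = kj, kv = kv, hi = hi, hj = hj, hv = hv,
       qi = qi, qj = qj, qv = qv, si = si, sv = sv,
       b = b, cc = cc, vol = vol, perm = perm,
       porosity = prop(function(m) m$porosity))
}

# Constraint handling: the reduced unknowns are the rigid-plate masters
# (translations and, optionally, rotations about the plate centroid), the
# free interior displacement dofs and the free pressure dofs. A sparse
# transformation T maps reduced unknowns to the full nodal dof vector
# (u node-major x,y(,z), then p), with clamped/fixed/drained dofs dropped
# (their value is zero).
build_transformation <- function(mesh, nodes_m, plate_rotation = TRUE) {
  d <- ncol(mesh$nodes)
  nn <- nrow(mesh$nodes)
  n_u <- nn * d
  Nfull <- n_u + nn
  u_id <- function(node, comp) (node - 1L) * d + comp

  fixed <- logical(Nfull)
  for (comp in seq_len(d))
    fixed[u_id(mesh$boundary$bottom_clamped, comp)] <- TRUE
  if (!is.null(mesh$fixed_components)) {
    comp_idx <- c(x = 1L, y = 2L, z = 3L)
    for (nm in names(mesh$fixed_components))
      fixed[u_id(mesh$fixed_components[[nm]], comp_idx[[nm]])] <- TRUE
  }
  fixed[n_u + mesh$boundary$outer_drained] <- TRUE

  plate <- mesh$boundary$top_loaded
  r <- sweep(nodes_m[plate, , drop = FALSE], 2, colMeans(nodes_m[plate, , drop = FALSE]))
  n_rot <- if (!plate_rotation || length(plate) < 2) 0L else if (d == 2L) 1L else 3L

  ncol_max <- d + n_rot + Nfull
  col <- 0L
  trans_col <- integer(d)
  for (comp in seq_len(d)) {
    if (any(!fixed[u_id(plate, comp)])) {
      col <- col + 1L
      trans_col[comp] <- col
    }
  }
  rot_col <- if (n_rot > 0) col + seq_len(n_rot) else integer(0)
  col <- col + n_rot

  ti <- integer(0); tj <- integer(0); tv <- numeric(0)
  add <- function(i, j, v) {
    ti <<- c(ti, i); tj <<- c(tj, j); tv <<- c(tv, v)
  }
  # plate dofs: translation + rotation weights (u = U + theta x r)
  for (kk in seq_along(plate)) {
    node <- plate[kk]
    for (comp in seq_len(d)) {
      id <- u_id(node, comp)
      if (fixed[id]) next
      if (trans_col[comp] > 0L) add(id, trans_col[comp], 1)
      if (n_rot == 1L) {
        # 2D: u_x = Ux - theta*ry ; u_y = Uy + theta*rx
        w <- if (comp == 1L) -r[kk, 2] else r[kk, 1]
        if (abs(w) > 0) add(id, rot_col[1], w)
      } else if (n_rot == 3L) {
        w <- switch(comp,
                    c(0, r[kk, 3], -r[kk, 2]),    # u_x: th_y*rz - th_z*ry
                    c(-r[kk, 3], 0, r[kk, 1]),    # u_y: th_z*rx - th_x*rz
                    c(r[kk, 2], -r[kk, 1], 0))    # u_z: th_x*ry - th_y*rx
        for (k2 in 1:3) if (abs(w[k2]) > 0) add(id, rot_col[k2], w[k2])
      }
    }
  }
  # ordinary free dofs
  plate_u <- rep(FALSE, Nfull)
  for (comp in seq_len(d)) plate_u[u_id(plate, comp)] <- TRUE
  ordinary <- which(!fixed & !plate_u)
  own <- col + seq_along(ordinary)
  col <- col + length(ordinary)
  ti <- c(ti, ordinary); tj <- c(tj, own); tv <- c(tv, rep(1, length(ordinary)))

  Tm <- Matrix::sparseMatrix(i = ti, j = tj, x = tv, dims = c(Nfull, col))
  # drop structurally empty columns (e.g. a rotation with all-zero arms)
  used <- Matrix::colSums(abs(Tm)) > 0
  if (!all(used)) {
    remap <- cumsum(used)
    Tm <- Tm[, used, drop = FALSE]
    trans_col <- ifelse(trans_col > 0L & used[pmax(trans_col, 1L)],
                        remap[pmax(trans_col, 1L)], 0L)
  }
  list(Tm = Tm, trans_col = trans_col, n_u = n_u, Nfull = Nfull)
}

#' Solve quasi-static Biot poroelasticity on a scaffold mesh
#'
#' Displacement-pressure coupled solution with linear simplex elements and
#' implicit backward-Euler time stepping through the load ramp. The loaded
#' face is tied to a rigid plate (its nodes move rigidly with the plate's
#' translations and, by default, free rotations about the plate centroid —
#' see `plate_rotation`), the clamped face is fixed, and pore pressure is
#' zero on the drained boundary set. Element-centroid principal strains,
#' Darcy flux magnitudes and pore pressures are reported at the evaluation
#' time (the final step).
#'
#' @param mesh A `scaffold_mesh` (from [build_scaffold_mesh()],
#'   [build_consolidation_column()] or [build_patch_block()]).
#' @param materials Either a single [material_properties()] object or a
#'   named list with one entry per mesh region (e.g. `scaffold`,
#'   `granulation`).
#' @param load A [load_case()].
#' @param hold_until Optionally continue time stepping (at constant load)
#'   until this time, s.
#' @param hold_steps Number of equal steps in the hold phase.
#' @param keep_history Keep nodal pressure at every step (for consolidation
#'   benchmarks).
#' @param intrinsic If `TRUE`, report the intrinsic fluid velocity
#'   (Darcy flux divided by porosity) instead of the Darcy flux.
#' @param plate_rotation If `TRUE` (default) the rigid plate carries free
#'   rotation degrees of freedom about its centroid, so only the force
#'   resultant (no moment) is imposed — the behaviour of a rigid-body tie
#'   loaded at its reference point. With `FALSE` the plate translates
#'   without rotating.
#' @return A `poroelastic_solution`: per-element principal strains
#'   `eps_I >= eps_II >= eps_III`, fluid flow magnitude `v_um_s` (um/s),
#'   element and nodal pore pressure (MPa), and the evaluation time.
#' @export
solve_poroelastic <- function(mesh, materials, load,
                              hold_until = NULL, hold_steps = 0,
                              keep_history = FALSE, intrinsic = FALSE,
                              plate_rotation = TRUE) {
  stopifnot(inherits(mesh, "scaffold_mesh"), inherits(load, "load_case"))
  d <- ncol(mesh$nodes)
  regions <- unique(mesh$region)
  if (inherits(materials, "material_properties")) {
    materials <- stats::setNames(rep(list(materials), length(regions)),
                                 regions)
  }
  if (!all(regions %in% names(materials))) {
    abort(sprintf("materials missing for region(s): %s",
                  paste(setdiff(regions, names(materials)), collapse = ", ")),
          class = "fgsopt_validation_error")
  }
  if (length(mesh$boundary$top_loaded) == 0 ||
      length(mesh$boundary$bottom_clamped) == 0) {
    abort("mesh must carry top_loaded and bottom_clamped boundary tags",
          class = "fgsopt_validation_error")
  }

  nodes_m <- mesh$nodes * UM
  ne <- nrow(mesh$elements)
  nn <- nrow(mesh$nodes)
  nn_el <- ncol(mesh$elements)
  cons <- build_transformation(mesh, nodes_m, plate_rotation)
  Tm <- cons$Tm
  Tt <- Matrix::t(Tm)
  n_u <- cons$n_u
  Nfull <- cons$Nfull
  u_id0 <- function(node) (node - 1L) * d   # + comp

  asm2d <- NULL
  if (d == 2L) {
    asm2d <- assemble_tri2d(nodes_m, mesh$elements, mesh$region, materials,
                            n_u)
    Kmat <- Matrix::sparseMatrix(i = asm2d$ki, j = asm2d$kj, x = asm2d$kv,
                                 dims = c(Nfull, Nfull))
    Qmat <- Matrix::sparseMatrix(i = asm2d$qi, j = asm2d$qj, x = asm2d$qv,
                                 dims = c(Nfull, Nfull))
    Hmat <- Matrix::sparseMatrix(i = asm2d$hi, j = asm2d$hj, x = asm2d$hv,
                                 dims = c(Nfull, Nfull))
    Smat <- Matrix::sparseMatrix(i = asm2d$si, j = asm2d$si, x = asm2d$sv,
                                 dims = c(Nfull, Nfull))
  } else {
  Cmats <- lapply(materials, function(m) elastic_matrix(m$E * MPA, m$nu, d))

  # element loop over full (unconstrained) dofs; constraints enter through T
  nK <- ne * (nn_el * d)^2
  nQ <- ne * nn_el * d * nn_el
  nH <- ne * nn_el^2
  ki <- integer(nK); kj <- integer(nK); kv <- numeric(nK)
  qi <- integer(nQ); qj <- integer(nQ); qv <- numeric(nQ)
  hi <- integer(nH); hj <- integer(nH); hv <- numeric(nH)
  si <- integer(ne * nn_el); sv <- numeric(ne * nn_el)
  n_k <- 0L; n_q <- 0L; n_h <- 0L; n_s <- 0L
  Blist <- vector("list", ne)
  Glist <- vector("list", ne)

  for (e in seq_len(ne)) {
    en <- mesh$elements[e, ]
    sg <- simplex_grads(nodes_m[en, , drop = FALSE])
    G <- sg$G; vol <- sg$vol
    Blist[[e]] <- B <- strain_B(G)
    Glist[[e]] <- G
    m <- materials[[mesh$region[e]]]
    Ke <- crossprod(B, Cmats[[mesh$region[e]]] %*% B) * vol
    udof <- rep(u_id0(en), each = d) + seq_len(d)   # node-major x,y(,z)
    pdof <- n_u + en

    nu_l <- length(udof)
    idx <- n_k + seq_len(nu_l * nu_l)
    ki[idx] <- rep(udof, times = nu_l)
    kj[idx] <- rep(udof, each = nu_l)
    kv[idx] <- Ke
    n_k <- n_k + nu_l * nu_l

    # coupling Q[(i,comp), j] = alpha * G[i,comp] * vol / nn_el
    Qe <- matrix(m$alpha * as.vector(t(G)) * vol / nn_el, nu_l, nn_el)
    idx <- n_q + seq_len(nu_l * nn_el)
    qi[idx] <- rep(udof, times = nn_el)
    qj[idx] <- rep(pdof, each = nu_l)
    qv[idx] <- Qe
    n_q <- n_q + nu_l * nn_el

    He <- m$permeability * (G %*% t(G)) * vol
    idx <- n_h + seq_len(nn_el * nn_el)
    hi[idx] <- rep(pdof, times = nn_el)
    hj[idx] <- rep(pdof, each = nn_el)
    hv[idx] <- He
    n_h <- n_h + nn_el * nn_el

    idx <- n_s + seq_len(nn_el)
    si[idx] <- pdof
    sv[idx] <- vol / (nn_el * m$M_Pa)
    n_s <- n_s + nn_el
  }

  Kmat <- Matrix::sparseMatrix(i = ki, j = kj, x = kv, dims = c(Nfull, Nfull))
  Qmat <- Matrix::sparseMatrix(i = qi, j = qj, x = qv, dims = c(Nfull, Nfull))
  Hmat <- Matrix::sparseMatrix(i = hi, j = hj, x = hv, dims = c(Nfull, Nfull))
  Smat <- Matrix::sparseMatrix(i = si[seq_len(n_s)], j = si[seq_len(n_s)],
                               x = sv[seq_len(n_s)], dims = c(Nfull, Nfull))
  }
  Rmat <- Matrix::t(Qmat) + Smat    # rhs recurrence operator

  # time grid: ramp phase + optional constant-load hold phase
  t_ramp <- seq(0, load$ramp, length.out = load$steps + 1)[-1]
  t_hold <- numeric(0)
  if (!is.null(hold_until) && hold_until > load$ramp && hold_steps > 0) {
    t_hold <- seq(load$ramp, hold_until, length.out = hold_steps + 1)[-1]
  }
  times <- c(t_ramp, t_hold)

  # plate force: traction * loaded-face area (unit depth in 2D); the
  # resultant acts through the plate centroid, so rotations carry no moment
  width_m <- diff(range(nodes_m[mesh$boundary$top_loaded, 1]))
  area_m <- if (d == 2L) width_m else {
    width_m * diff(range(nodes_m[mesh$boundary$top_loaded, 3]))
  }
  f_plate <- plate_traction(load, d) * area_m

  xfull <- numeric(Nfull)
  lu_cache <- list()
  p_hist <- if (keep_history) matrix(0, nn, length(times))
  t_prev <- 0
  for (s in seq_along(times)) {
    t_now <- times[s]
    dt <- t_now - t_prev
    key <- sprintf("%.15g", dt)
    if (is.null(lu_cache[[key]])) {
      A <- Tt %*% (Kmat - Qmat + Matrix::t(Qmat) + Smat + dt * Hmat) %*% Tm
      # stiffness (~E/L^2) and storage (~vol/M) entries differ by many
      # orders of magnitude: equilibrate symmetrically before factorizing
      dsc <- 1 / sqrt(pmax(abs(Matrix::diag(A)), .Machine$double.xmin))
      Dm <- Matrix::Diagonal(x = dsc)
      lu_cache[[key]] <- list(lu = Matrix::lu(Dm %*% A %*% Dm), dsc = dsc)
    }
    fac <- min(t_now / load$ramp, 1)
    b <- as.numeric(Tt %*% (Rmat %*% xfull))
    act <- cons$trans_col > 0L
    b[cons$trans_col[act]] <- b[cons$trans_col[act]] + fac * f_plate[act]
    fct <- lu_cache[[key]]
    q <- fct$dsc * as.numeric(Matrix::solve(fct$lu, fct$dsc * b))
    xfull <- as.numeric(Tm %*% q)
    if (keep_history) p_hist[, s] <- xfull[n_u + seq_len(nn)] / MPA
    t_prev <- t_now
  }

  ufull <- matrix(xfull[seq_len(n_u)], nn, d, byrow = TRUE)
  pfull <- xfull[n_u + seq_len(nn)]

  if (d == 2L) {
    el <- mesh$elements
    b <- asm2d$b; cc <- asm2d$cc
    ux <- cbind(ufull[el[, 1], 1], ufull[el[, 2], 1], ufull[el[, 3], 1])
    uy <- cbind(ufull[el[, 1], 2], ufull[el[, 2], 2], ufull[el[, 3], 2])
    pe <- cbind(pfull[el[, 1]], pfull[el[, 2]], pfull[el[, 3]])
    exx <- rowSums(b * ux)
    eyy <- rowSums(cc * uy)
    gxy <- rowSums(cc * ux) + rowSums(b * uy)
    strains <- cbind(exx, eyy, gxy, deparse.level = 0)
    # closed-form in-plane eigenvalues; out-of-plane principal strain is 0
    ctr <- (exx + eyy) / 2
    rad <- sqrt(((exx - eyy) / 2)^2 + (gxy / 2)^2)
    e1 <- ctr + rad
    e2 <- ctr - rad
    pr <- cbind(pmax(e1, 0), e1 + e2 - pmax(e1, 0) - pmin(e2, 0),
                pmin(e2, 0), deparse.level = 0)
    gpx <- rowSums(b * pe)
    gpy <- rowSums(cc * pe)
    flux <- asm2d$perm * sqrt(gpx^2 + gpy^2)
    if (intrinsic) flux <- flux / asm2d$porosity
    v <- flux / UM
    p_el <- rowMeans(pe) / MPA
  } else {
  nstrain <- 6L
  strains <- matrix(0, ne, nstrain)
  pr <- matrix(0, ne, 3)
  v <- numeric(ne)
  p_el <- numeric(ne)
  for (e in seq_len(ne)) {
    en <- mesh$elements[e, ]
    ue <- as.vector(t(ufull[en, , drop = FALSE]))
    eps <- as.numeric(Blist[[e]] %*% ue)
    strains[e, ] <- eps
    pr[e, ] <- principal_strains(strain_vector_to_tensor(eps, d))
    gp <- as.numeric(t(Glist[[e]]) %*% pfull[en])   # Pa/m
    m <- materials[[mesh$region[e]]]
    flux <- m$permeability * sqrt(sum(gp^2))         # m/s
    if (intrinsic) flux <- flux / m$porosity
    v[e] <- flux / UM                                # um/s
    p_el[e] <- mean(pfull[en]) / MPA
  }
  }

  structure(
    list(principal = pr, strains = strains, v_um_s = v,
         p_element_MPa = p_el, p_nodal_MPa = pfull / MPA,
         displacement_um = ufull / UM,
         time = times[length(times)], times = times,
         p_history_MPa = p_hist,
         mesh_dim = d, n_elements = ne),
    class = "poroelastic_solution"
  )
}

strain_vector_to_tensor <- function(eps, d) {
  if (d == 2L) {
    # plane strain: out-of-plane principal strain is identically zero
    matrix(c(eps[1], eps[3] / 2, 0,
             eps[3] / 2, eps[2], 0,
             0, 0, 0), 3, 3)
  } else {
    matrix(c(eps[1], eps[4] / 2, eps[6] / 2,
             eps[4] / 2, eps[2], eps[5] / 2,
             eps[6] / 2, eps[5] / 2, eps[3]), 3, 3)
  }
}

#' Principal strains of a symmetric small-strain tensor
#'
#' @param tensor A symmetric 2x2 or 3x3 strain matrix (tensorial shear
#'   components, not engineering).
#' @return Numeric vector `c(eps_I, eps_II, eps_III)` in descending order;
#'   for a 2x2 input the out-of-plane strain is taken as zero (plane
#'   strain).
#' @export
principal_strains <- function(tensor) {
  stopifnot(is.matrix(tensor), nrow(tensor) == ncol(tensor),
            nrow(tensor) %in% c(2L, 3L))
  if (max(abs(tensor - t(tensor))) > 1e-8 * max(1, max(abs(tensor)))) {
    abort("strain tensor must be symmetric", class = "fgsopt_validation_error")
  }
  ev <- eigen((tensor + t(tensor)) / 2, symmetric = TRUE,
              only.values = TRUE)$values
  if (nrow(tensor) == 2L) ev <- c(ev, 0)
  sort(ev, decreasing = TRUE)
}

#' @export
print.poroelastic_solution <- function(x, ...) {
  cat(sprintf("<poroelastic_solution: %d elements, t = %g s>\n",
              x$n_elements, x$time))
  cat(sprintf("  |eps_I| max %.3e, v max %.3g um/s, p max %.3g MPa\n",
              max(abs(x$principal[, 1])), max(x$v_um_s),
              max(abs(x$p_nodal_MPa))))
  invisible(x)
}

#' Per-element view of a poroelastic solution
#'
#' @param x A `poroelastic_solution`.
#' @param mesh Optionally the mesh it was computed on, to attach region and
#'   measure columns.
#' @param ... Unused.
#' @return A tibble with one row per element.
#' @exportS3Method generics::tidy
tidy.poroelastic_solution <- function(x, mesh = NULL, ...) {
  out <- tibble(
    element = seq_len(x$n_elements),
    eps_I = x$principal[, 1], eps_II = x$principal[, 2],
    eps_III = x$principal[, 3],
    v_um_s = x$v_um_s, p_MPa = x$p_element_MPa
  )
  if (!is.null(mesh)) {
    out$region <- mesh$region
    out$measure <- mesh$measure
  }
  out
}
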