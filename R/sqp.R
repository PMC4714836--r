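# Bound-constrained sequential quadratic programming for small (n <= ~6)
# black-box problems. Damped-BFGS model Hessian, finite-difference gradients,
# and an exact active-set solution of the box-constrained QP subproblem
# (feasible because the active-set patterns {free, lower, upper}^n are
# enumerable at this dimensionality).

# Exact solution of  min  g'd + 0.5 d'B d  s.t.  lo <= d <= hi
# by enumerating bound-activity patterns and checking the KKT conditions.
solve_box_qp <- function(g, B, lo, hi) {
  n <- length(g)
  best <- NULL
  best_val <- Inf
  patterns <- as.matrix(expand.grid(rep(list(c(0L, -1L, 1L)), n)))
  for (r in seq_len(nrow(patterns))) {
    pat <- patterns[r, ]
    d <- numeric(n)
    d[pat == -1L] <- lo[pat == -1L]
    d[pat == 1L] <- hi[pat == 1L]
    free <- which(pat == 0L)
    if (length(free)) {
      rhs <- -(g[free] + B[free, -free, drop = FALSE] %*% d[-free])
      sol <- tryCatch(solve(B[free, free, drop = FALSE], rhs),
                      error = function(e) NULL)
      if (is.null(sol)) next
      d[free] <- as.numeric(sol)
      if (any(d[free] < lo[free] - 1e-12) || any(d[free] > hi[free] + 1e-12))
        next
    }
    # dual feasibility at active bounds: multiplier = -(g + B d) component
    grad_q <- as.numeric(g + B %*% d)
    if (any(pat == -1L & grad_q < -1e-10)) next
    if (any(pat == 1L & grad_q > 1e-10)) next
    val <- sum(g * d) + 0.5 * sum(d * (B %*% d))
    if (val < best_val) {
      best_val <- val
      best <- d
    }
  }
  if (is.null(best)) {
    # fall back to a projected steepest-descent step
    d <- pmax(lo, pmin(hi, -g))
    best <- d
  }
  best
}

# central differences (one-sided at the box edge): the O(h^2) bias keeps
# quadratic model optima where they belong even at large probe steps
fd_gradient <- function(fn, x, f0, lower, upper, h) {
  n <- length(x)
  g <- numeric(n)
  evals <- 0L
  for (i in seq_len(n)) {
    up <- min(h, upper[i] - x[i])
    dn <- min(h, x[i] - lower[i])
    if (up + dn <= 0) {
      g[i] <- 0
      next
    }
    fp <- if (up > 0) {
      xp <- x; xp[i] <- x[i] + up
      evals <- evals + 1L
      fn(xp)
    } else f0
    fm <- if (dn > 0) {
      xm <- x; xm[i] <- x[i] - dn
      evals <- evals + 1L
      fn(xm)
    } else f0
    g[i] <- (fp - fm) / (up + dn)
  }
  list(g = g, evals = evals)
}

#' Box-constrained SQP minimizer
#'
#' Minimizes a black-box function over a box using a sequential quadratic
#' programming iteration: finite-difference gradients, a damped BFGS
#' approximation of the Hessian, an exactly solved box-constrained QP
#' subproblem, and a backtracking line search. Designed for the small,
#' possibly noisy objectives that arise when each evaluation runs a meshed
#' finite element analysis.
#'
#' @param fn Objective function of a numeric vector.
#' @param x0 Start point (projected into the box if necessary).
#' @param lower,upper Bound vectors.
#' @param fd_step Finite-difference step for gradients (same units as `x`).
#' @param ftol Stop when the objective improves by less than this between
#'   accepted iterates.
#' @param steptol Stop when the accepted step is shorter than this
#'   (infinity norm).
#' @param maxit Maximum SQP iterations.
#' @return A list: `x`, `f`, `termination` (one of `"ftol"`, `"steptol"`,
#'   `"maxit"`, `"stalled"`), `iterations`, `n_evals`, and `history` (a
#'   tibble of accepted iterates).
#' @export
sqp_box <- function(fn, x0, lower, upper, fd_step = 5,
                    ftol = 1e-2, steptol = 1, maxit = 50) {
  n <- length(x0)
  stopifnot(length(lower) == n, length(upper) == n, all(lower < upper))
  lower <- unname(lower); upper <- unname(upper)
  x <- unname(pmax(lower, pmin(upper, as.numeric(x0))))
  n_evals <- 1L
  f <- fn(x)
  B <- diag(n)
  scaled <- FALSE
  prev <- NULL   # previous iterate and gradient, for the BFGS secant pair
  hist <- vector("list", maxit + 1L)
  hist[[1]] <- c(iteration = 0, f = f, x)
  termination <- "maxit"
  it <- 0L
  while (it < maxit) {
    it <- it + 1L
    fg <- fd_gradient(fn, x, f, lower, upper, fd_step)
    n_evals <- n_evals + fg$evals
    g <- fg$g
    if (!scaled && sqrt(sum(g^2)) > 0) {
      # scale the initial model so the first step is ~ one fd_step long
      B <- diag(n) * max(sqrt(sum(g^2)) / max(fd_step, 1e-8), 1e-12)
      scaled <- TRUE
    }
    # damped-BFGS update from the secant pair of the last accepted step
    if (!is.null(prev)) {
      sk <- x - prev$x
      yk <- g - prev$g
      Bs <- as.numeric(B %*% sk)
      sBs <- sum(sk * Bs)
      sy <- sum(sk * yk)
      if (is.finite(sy) && sBs > 0 && sum(sk^2) > 0) {
        theta <- if (sy >= 0.2 * sBs) 1 else 0.8 * sBs / (sBs - sy)
        yk <- theta * yk + (1 - theta) * Bs
        sy <- sum(sk * yk)
        if (sy > 1e-12 * sqrt(sum(sk^2)) * sqrt(sum(yk^2))) {
          B <- B - tcrossprod(Bs) / sBs + tcrossprod(yk) / sy
        }
      }
    }
    prev <- list(x = x, g = g)
    # projected-gradient stationarity check
    pg <- pmax(lower, pmin(upper, x - g)) - x
    if (max(abs(pg)) < 1e-12) {
      termination <- "stalled"
      break
    }
    d <- solve_box_qp(g, B, lower - x, upper - x)
    if (max(abs(d)) < .Machine$double.eps) {
      termination <- "stalled"
      break
    }
    # backtracking line search (simple decrease; the objective may be
    # piecewise constant, so Armijo with a slope test would be too strict)
    alpha <- 1
    accepted <- FALSE
    for (ls in 1:6) {
      xt <- pmax(lower, pmin(upper, x + alpha * d))
      ft <- fn(xt)
      n_evals <- n_evals + 1L
      if (ft < f - 1e-14) {
        accepted <- TRUE
        break
      }
      alpha <- alpha / 2
    }
    if (!accepted) {
      termination <- "stalled"
      break
    }
    s <- xt - x
    df <- f - ft
    x <- xt
    f <- ft
    hist[[it + 1L]] <- c(iteration = it, f = f, x)
    if (df < ftol) {
      termination <- "ftol"
      break
    }
    if (max(abs(s)) < steptol) {
      termination <- "steptol"
      break
    }
  }
  hist <- hist[!vapply(hist, is.null, logical(1))]
  hm <- do.call(rbind, hist)
  colnames(hm) <- c("iteration", "f", paste0("x", seq_len(n)))
  list(x = x, f = f, termination = termination, iterations = it,
       n_evals = n_evals, history = as_tibble(as.data.frame(hm)))
}

# Coordinate pattern-search polish for piecewise-constant objectives: cycle
# over coordinates trying +/- h and +/- h/2 moves, keeping improvements,
# with h halved once when a full cycle brings nothing. Complements the SQP
# iteration when the objective is stepwise in the design variables (region
# labels flip at discrete radii on a fixed grid).
polish_coordinates <- function(fn, x, f, lower, upper, h, rounds = 4) {
  n <- length(x)
  n_evals <- 0L
  h_cur <- h
  for (r in seq_len(rounds)) {
    improved <- FALSE
    for (i in seq_len(n)) {
      for (st in c(h_cur, -h_cur, h_cur / 2, -h_cur / 2)) {
        xt <- x
        xt[i] <- min(upper[i], max(lower[i], x[i] + st))
        if (xt[i] == x[i]) next
        ft <- fn(xt)
        n_evals <- n_evals + 1L
        if (ft < f - 1e-12) {
          x <- xt
          f <- ft
          improved <- TRUE
        }
      }
    }
    if (!improved) {
      if (h_cur <= h / 2) break
      h_cur <- h_cur / 2
    }
  }
  list(x = x, f = f, n_evals = n_evals)
}
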