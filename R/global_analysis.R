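#' Dulac expression for limit-cycle exclusion
#'
#' With the Dulac multiplier \eqn{\phi(y,z) = 1/(yz)}, the divergence of
#' the scaled vector field reduces to
#' \deqn{F(y,z) = -\tau - \xi\,\frac{f_{cr}(y)}{y z^2},}
#' which is strictly negative on the open square for every admissible
#' response pair. By the Bendixson-Dulac criterion the model therefore
#' admits no non-trivial periodic orbit: epidemic waves cannot arise from
#' this adaptation mechanism alone.
#'
#' @inheritParams vector_field
#' @return The value of \eqn{F} at the state (vectorised over states given
#'   as a 2-column matrix).
#' @export
dulac_expression <- function(state, params, pair) {
  if (is.matrix(state)) { y <- state[, 1]; z <- state[, 2] }
  else { y <- state[[1]]; z <- state[[2]] }
  if (any(y <= 0 | z <= 0 | y >= 1 | z >= 1))
    stop("Dulac expression is defined on the open square (0,1)^2",
         call. = FALSE)
  -params$tau - params$xi * pair$f_cr(y) / (y * z^2)
}

#' Verify absence of limit cycles on a grid
#'
#' Evaluates the Dulac expression on an interior lattice and reports the
#' maximum. A strictly negative maximum certifies (at grid resolution)
#' that the single-sign condition of the Bendixson-Dulac criterion holds.
#'
#' @inheritParams vector_field
#' @param grid integer vector \code{c(ny, nz)}: interior lattice size
#'   (default 201 x 201).
#' @return A list with \code{pass} (logical), \code{max_value}, and
#'   \code{argmax} (the state where the maximum is attained).
#' @export
verify_no_limit_cycles <- function(params, pair, grid = c(201L, 201L)) {
  yg <- seq_len(grid[1]) / (grid[1] + 1)
  zg <- seq_len(grid[2]) / (grid[2] + 1)
  # F is separable: max over z of -xi*c/ (y z^2) is at z max for c >= 0
  vals <- outer(yg, zg, function(y, z)
    -params$tau - params$xi * pair$f_cr(y) / (y * z^2))
  k <- arrayInd(which.max(vals), dim(vals))
  list(pass = max(vals) < 0, max_value = max(vals),
       argmax = c(y = yg[k[1]], z = zg[k[2]]))
}

#' Solve the 2x2 Lyapunov equation
#'
#' For a Hurwitz matrix \eqn{J}, returns the unique symmetric positive
#' definite \eqn{P} with \eqn{PJ + J^T P = -I}. The quadratic form
#' \eqn{\hat V(x) = x^T P x} is then a local Lyapunov function for the
#' linearised flow and is used to estimate regions of attraction.
#'
#' @param J a real 2x2 matrix with both eigenvalue real parts negative.
#' @return Symmetric positive definite 2x2 matrix \eqn{P}.
#' @export
lyapunov_matrix <- function(J) {
  stopifnot(is.matrix(J), all(dim(J) == 2L))
  ev <- eigen(J, only.values = TRUE)$values
  if (any(Re(ev) >= 0))
    stop("Lyapunov equation requires a stable equilibrium (Hurwitz Jacobian)",
         call. = FALSE)
  A <- kronecker(t(J), diag(2)) + kronecker(diag(2), t(J))
  p <- solve(A, -as.vector(diag(2)))
  P <- matrix(p, 2, 2)
  P <- (P + t(P)) / 2
  P
}

#' Estimate a region of attraction from a quadratic Lyapunov function
#'
#' Builds \eqn{\hat V(x) = (x - x_E)^T P (x - x_E)} from the Lyapunov
#' matrix of the equilibrium's Jacobian, evaluates its orbital derivative
#' \eqn{d\hat V/dt = 2 (x - x_E)^T P f(x)} with the full nonlinear vector
#' field on a lattice over \eqn{[0,1]^2}, and finds by bisection the
#' largest level \eqn{c^*} whose sublevel set
#' \eqn{\Omega_{c} = \{\hat V \le c\} \cap [0,1]^2} contains no lattice
#' point with \eqn{d\hat V/dt \ge 0} other than the equilibrium itself.
#' \eqn{\Omega_{c^*}} is an inner estimate of the basin: often
#' conservative, but every point in it is guaranteed (at lattice
#' resolution) to flow to the equilibrium.
#'
#' @param eq a stable \code{animfa_equilibrium}.
#' @inheritParams vector_field
#' @param grid integer vector \code{c(ny, nz)} lattice size (default
#'   401 x 401 over \eqn{[0,1]^2}).
#' @param c_rel_tol relative tolerance of the bisection on \eqn{c}.
#' @return An object of class \code{animfa_roa}: list with
#'   \code{equilibrium}, \code{P}, \code{c_star}, \code{grid} (list of
#'   \code{y}, \code{z} lattice vectors), \code{omega_set} (logical
#'   matrix, \code{TRUE} inside \eqn{\Omega_{c^*}}), \code{V} and
#'   \code{dVdt} matrices, and \code{diagnostic}.
#' @export
estimate_region_of_attraction <- function(eq, params, pair,
                                          grid = c(401L, 401L),
                                          c_rel_tol = 1e-6) {
  stopifnot(inherits(eq, "animfa_equilibrium"))
  P <- lyapunov_matrix(eq$jacobian)  # errors if not Hurwitz
  yg <- seq(0, 1, length.out = grid[1])
  zg <- seq(0, 1, length.out = grid[2])
  Y <- matrix(yg, grid[1], grid[2])
  Z <- matrix(zg, grid[1], grid[2], byrow = TRUE)
  dy <- Y - eq$y; dz <- Z - eq$z
  V <- P[1, 1] * dy^2 + 2 * P[1, 2] * dy * dz + P[2, 2] * dz^2
  f <- .vf_matrix(as.vector(Y), as.vector(Z), params, pair)
  # dV/dt = 2 (x - xE)' P f(x), exact gradient of the quadratic form
  dV <- 2 * ((P[1, 1] * dy + P[1, 2] * dz) * matrix(f[, 1], grid[1], grid[2]) +
             (P[1, 2] * dy + P[2, 2] * dz) * matrix(f[, 2], grid[1], grid[2]))
  at_eq <- abs(dy) < 1e-12 & abs(dz) < 1e-12
  bad <- (dV >= 0) & !at_eq
  diagnostic <- NULL
  if (!any(bad)) {
    c_star <- max(V)
  } else {
    admissible <- function(c) !any(bad & (V <= c))
    lo <- 0; hi <- min(V[bad])
    if (!admissible(hi)) {
      # hi itself contains a bad point (V == hi there); shrink below it
      while (hi - lo > c_rel_tol * max(hi, 1e-300)) {
        mid <- (lo + hi) / 2
        if (admissible(mid)) lo <- mid else hi <- mid
      }
      c_star <- lo
    } else c_star <- hi * (1 - c_rel_tol)
    if (c_star <= 0)
      diagnostic <- "no positive level admissible at this grid resolution"
  }
  structure(
    list(equilibrium = eq, P = P, c_star = c_star,
         grid = list(y = yg, z = zg),
         omega_set = V <= c_star, V = V, dVdt = dV,
         diagnostic = diagnostic),
    class = "animfa_roa")
}

#' @export
print.animfa_roa <- function(x, ...) {
  cat(sprintf("<animfa_roa> around (%.6g, %.6g): c* = %.6g, |Omega| = %d grid points\n",
              x$equilibrium$y, x$equilibrium$z, x$c_star, sum(x$omega_set)))
  if (!is.null(x$diagnostic)) cat("  note:", x$diagnostic, "\n")
  invisible(x)
}

#' Separatrix between basins of attraction
#'
#' Computes the invariant curve dividing two basins. For an interior
#' saddle the curve is its stable manifold, obtained by backward-time
#' integration from the saddle displaced by \code{h} along each side of
#' the stable eigendirection, clipped to \eqn{[0,1]^2}. When the interior
#' equilibrium is not a saddle (no real stable eigendirection), the
#' dividing curve is instead located by bisection on initial conditions
#' along grid columns (attractor-boundary bisection). The method actually
#' used is recorded in the result.
#'
#' @param saddle an interior \code{animfa_equilibrium}.
#' @inheritParams vector_field
#' @param t_back backward-time horizon for eigenvector shooting.
#' @param h displacement along the stable eigenvector.
#' @param method \code{"auto"} (shooting for a saddle, otherwise
#'   bisection), \code{"shooting"} or \code{"bisection"}.
#' @param n_columns number of grid columns for the bisection method.
#' @param horizon forward-simulation horizon used by the bisection method.
#' @return An object of class \code{animfa_separatrix}: list with
#'   \code{points} (ordered two-column matrix of states), \code{method},
#'   and \code{equilibrium}.
#' @export
separatrix <- function(saddle, params, pair, t_back = 60,
                       h = 1e-6, method = c("auto", "shooting", "bisection"),
                       n_columns = 201L, horizon = 500) {
  stopifnot(inherits(saddle, "animfa_equilibrium"))
  method <- match.arg(method)
  ev <- eigen(saddle$jacobian)
  re <- Re(ev$values)
  is_saddle <- any(re < 0) && any(re > 0) && all(abs(Im(ev$values)) < 1e-10)
  if (method == "auto") method <- if (is_saddle) "shooting" else "bisection"
  if (method == "shooting") {
    if (!is_saddle || !any(re < 0))
      stop("separatrix undefined for this equilibrium type: ",
           "no real stable eigendirection", call. = FALSE)
    vs <- Re(ev$vectors[, which.min(re)])
    vs <- vs / sqrt(sum(vs^2))
    branch <- function(sgn) {
      x0 <- c(saddle$y, saddle$z) + sgn * h * vs
      rhs <- function(t, state, parms) list(-vector_field(state, params, pair))
      rootfun <- function(t, state, parms)
        min(state[1], state[2], 1 - state[1], 1 - state[2]) - 1e-9
      sol <- deSolve::lsodar(y = x0, times = seq(0, t_back, length.out = 2001),
                             func = rhs, parms = NULL, rootfunc = rootfun,
                             rtol = 1e-10, atol = 1e-12)
      unname(unclass(sol)[, 2:3, drop = FALSE])
    }
    b_minus <- branch(-1)
    b_plus <- branch(+1)
    pts <- rbind(b_minus[rev(seq_len(nrow(b_minus))), , drop = FALSE],
                 c(saddle$y, saddle$z), b_plus)
    pts <- pmin(pmax(pts, 0), 1)
  } else {
    # attractor-boundary bisection along z for each y-column
    dfe <- disease_free_equilibrium(params, pair)
    ees <- endemic_equilibria(params, pair)
    attractors <- Filter(function(e) startsWith(e$stability, "stable"),
                         c(list(dfe), ees))
    if (length(attractors) < 2)
      stop("bisection separatrix requires two attractors", call. = FALSE)
    label_of <- function(y0, z0) {
      term <- .simulate_batch(params, pair, matrix(c(y0, z0), 1), horizon)
      d <- vapply(attractors, function(a)
        sqrt((a$y - term[1])^2 + (a$z - term[2])^2), numeric(1))
      which.min(d)
    }
    ys <- seq(1e-3, 1 - 1e-3, length.out = n_columns)
    pts <- matrix(NA_real_, 0, 2)
    for (y0 in ys) {
      lo <- 0; hi <- 1
      l_lo <- label_of(y0, lo); l_hi <- label_of(y0, hi)
      if (l_lo == l_hi) next
      while (hi - lo > 1e-6) {
        mid <- (lo + hi) / 2
        if (label_of(y0, mid) == l_lo) lo <- mid else hi <- mid
      }
      pts <- rbind(pts, c(y0, (lo + hi) / 2))
    }
  }
  structure(list(points = pts, method = method, equilibrium = saddle),
            class = "animfa_separatrix")
}

#' @export
print.animfa_separatrix <- function(x, ...) {
  cat(sprintf("<animfa_separatrix> %d points (method: %s)\n",
              nrow(x$points), x$method))
  invisible(x)
}

# Signed side of each point relative to an ordered polyline: sign of the
# cross product with the tangent of the nearest segment. Used to check
# basin labels against the separatrix.
.polyline_side <- function(poly, pts) {
  a <- poly[-nrow(poly), , drop = FALSE]
  b <- poly[-1, , drop = FALSE]
  ab <- b - a
  len2 <- pmax(rowSums(ab^2), 1e-300)
  side <- numeric(nrow(pts))
  for (i in seq_len(nrow(pts))) {
    p <- pts[i, ]
    tt <- pmin(pmax(((p[1] - a[, 1]) * ab[, 1] +
                     (p[2] - a[, 2]) * ab[, 2]) / len2, 0), 1)
    qx <- a[, 1] + tt * ab[, 1]; qy <- a[, 2] + tt * ab[, 2]
    d2 <- (p[1] - qx)^2 + (p[2] - qy)^2
    k <- which.min(d2)
    side[i] <- sign(ab[k, 1] * (p[2] - a[k, 2]) - ab[k, 2] * (p[1] - a[k, 1]))
  }
  side
}

#' Map basins of attraction
#'
#' Forward-simulates a lattice of initial conditions and labels each by
#' the equilibrium its orbit terminates at (within \code{label_tol}).
#' Points that have not settled by the horizon are labelled
#' \code{"unresolved"}, never forced.
#'
#' @inheritParams vector_field
#' @param grid integer vector \code{c(ny, nz)} lattice size.
#' @param horizon forward-simulation horizon (rescaled time).
#' @param label_tol distance to an equilibrium at which an orbit is
#'   considered settled.
#' @return An object of class \code{animfa_basin_map}: list with
#'   \code{grid} (data.frame \code{y0, z0}), \code{labels} (character:
#'   \code{"dfe"}, \code{"ee_1"}, ..., \code{"unresolved"}),
#'   \code{attractors} (named list of equilibria), \code{horizon},
#'   \code{terminal} (matrix of terminal states).
#' @export
basin_map <- function(params, pair, grid = c(101L, 101L), horizon = 500,
                      label_tol = 1e-6) {
  dfe <- disease_free_equilibrium(params, pair)
  ees <- endemic_equilibria(params, pair)
  eqs <- c(list(dfe), ees)
  names(eqs) <- c("dfe", if (length(ees))
    paste0("ee_", seq_along(ees)) else character(0))
  yg <- seq(0, 1, length.out = grid[1])
  zg <- seq(0, 1, length.out = grid[2])
  pts <- as.matrix(expand.grid(y0 = yg, z0 = zg))
  term <- .simulate_batch(params, pair, pts, horizon,
                          rtol = 1e-8, atol = 1e-10)
  eq_y <- vapply(eqs, function(e) e$y, numeric(1))
  eq_z <- vapply(eqs, function(e) if (is.na(e$z)) 0 else e$z, numeric(1))
  labels <- rep("unresolved", nrow(pts))
  d_all <- sapply(seq_along(eqs), function(k)
    sqrt((term[, 1] - eq_y[k])^2 + (term[, 2] - eq_z[k])^2))
  d_all <- matrix(d_all, nrow = nrow(pts))
  if (any(vapply(eqs, function(e) e$kind == "dfe_family", logical(1)))) {
    # distance to the degenerate segment {y=0} is just the terminal y
    k_fam <- which(vapply(eqs, function(e) e$kind == "dfe_family", logical(1)))
    d_all[, k_fam] <- term[, 1]
  }
  k_min <- max.col(-d_all, ties.method = "first")
  settled <- d_all[cbind(seq_len(nrow(pts)), k_min)] <= label_tol
  labels[settled] <- names(eqs)[k_min[settled]]
  structure(
    list(grid = as.data.frame(pts), labels = labels, attractors = eqs,
         horizon = horizon, terminal = term),
    class = "animfa_basin_map")
}

#' @export
print.animfa_basin_map <- function(x, ...) {
  cat(sprintf("<animfa_basin_map> %d initial conditions, horizon %g\n",
              nrow(x$grid), x$horizon))
  print(table(x$labels))
  invisible(x)
}
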