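#' Critical manifold of the slow-network limit
#'
#' When the network adapts slowly relative to disease transmission, the
#' prevalence is the fast variable and the set of layer-equation
#' equilibria organises the dynamics. That critical manifold is the union
#' of the disease-free branch \eqn{\{y = 0\}} and, for \eqn{\tau > 1}, the
#' curve \deqn{y = \frac{\tau z - 1}{\tau z}, \qquad z \in [1/\tau, 1].}
#' The two branches exchange stability at the non-hyperbolic point
#' \eqn{(0, 1/\tau)}.
#'
#' @param params a \code{model_parameters} object.
#' @param n number of sample points per branch.
#' @return An object of class \code{animfa_critical_manifold}: list with
#'   \code{branch1} (data.frame \code{z, y, lambda}),
#'   \code{branch2} (same columns; zero rows when \eqn{\tau \le 1}), and
#'   \code{nonhyperbolic_point} \code{c(y, z)}.
#' @export
critical_manifold <- function(params, n = 201L) {
  tau <- params$tau
  z1 <- seq(0, 1, length.out = n)
  branch1 <- data.frame(z = z1, y = 0, lambda = tau * z1 - 1)
  if (tau > 1) {
    z2 <- seq(1 / tau, 1, length.out = n)
    branch2 <- data.frame(z = z2, y = (tau * z2 - 1) / (tau * z2),
                          lambda = 1 - tau * z2)
  } else {
    branch2 <- data.frame(z = numeric(0), y = numeric(0),
                          lambda = numeric(0))
  }
  structure(list(branch1 = branch1, branch2 = branch2,
                 nonhyperbolic_point = c(y = 0, z = 1 / tau),
                 tau = tau),
            class = "animfa_critical_manifold")
}

#' @export
print.animfa_critical_manifold <- function(x, ...) {
  cat(sprintf("<animfa_critical_manifold> tau=%g\n", x$tau))
  cat(sprintf("  branch 1: {y=0}, attracting for z < 1/tau = %.6g\n",
              1 / x$tau))
  if (nrow(x$branch2))
    cat(sprintf("  branch 2: y=(tau z-1)/(tau z), z in [%.6g, 1], attracting\n",
                1 / x$tau))
  else cat("  branch 2: empty (tau <= 1)\n")
  invisible(x)
}

#' Layer-problem stability along the critical manifold
#'
#' Eigenvalue of the fast (layer) equation linearised at a point of the
#' critical manifold: \eqn{\lambda = \tau z - 1} on the disease-free
#' branch and \eqn{\lambda = 1 - \tau z} on the endemic branch. Negative
#' values mark normally attracting parts of the manifold.
#'
#' @param z link density in \eqn{[0,1]}.
#' @param params a \code{model_parameters} object.
#' @param branch 1 (disease-free, \eqn{y=0}) or 2 (endemic curve).
#' @return The eigenvalue (vectorised over \code{z}).
#' @export
layer_stability <- function(z, params, branch = 1L) {
  stopifnot(all(z >= 0 & z <= 1), branch %in% c(1L, 2L))
  if (branch == 2L && any(z < 1 / params$tau - 1e-12))
    stop("branch 2 requires z >= 1/tau", call. = FALSE)
  if (branch == 1L) params$tau * z - 1 else 1 - params$tau * z
}

#' Reduced (slow) flow on the critical manifold
#'
#' The slow dynamics of the link density constrained to a branch of the
#' critical manifold:
#' \deqn{\frac{dz}{ds} = -\zeta z f_{br}(y^*(z)) + \xi (1-z) f_{cr}(y^*(z)),}
#' with \eqn{y^*(z) = 0} on branch 1 and \eqn{y^*(z) = (\tau z - 1)/(\tau z)}
#' on branch 2. Time is the slow time \eqn{s = \varepsilon t}.
#'
#' @inheritParams layer_stability
#' @param pair a \code{response_pair}.
#' @return \eqn{dz/ds} (vectorised over \code{z}).
#' @export
reduced_flow <- function(z, params, pair, branch = 1L) {
  stopifnot(all(z >= 0 & z <= 1), branch %in% c(1L, 2L))
  if (branch == 1L) {
    y <- rep_len(0, length(z))
  } else {
    if (any(params$tau * z < 1 - 1e-12))
      stop("branch 2 requires tau * z >= 1", call. = FALSE)
    y <- (params$tau * z - 1) / (params$tau * z)
  }
  -params$zeta * z * pair$f_br(y) + params$xi * (1 - z) * pair$f_cr(y)
}

#' Entry-exit map along the disease-free slow branch
#'
#' An orbit of the slow-fast system entering a neighbourhood of the
#' disease-free branch at \eqn{z_{in} < 1/\tau} drifts along it (the
#' prevalence stays exponentially small) past the non-hyperbolic point
#' \eqn{z = 1/\tau} — a delayed loss of stability — and erupts at the exit
#' density \eqn{z_{out} > 1/\tau} solving
#' \deqn{\int_{z_{in}}^{z_{out}} \frac{\tau z - 1}{g_0(z)}\, dz = 0,}
#' where \eqn{g_0(z) = -\zeta z f_{br}(0) + \xi (1-z) f_{cr}(0)} is the
#' reduced flow on the branch. (The accumulated fast-contraction balance
#' is measured along slow time; for constant link creation with
#' \eqn{f_{br}(0)=0} and \eqn{\xi = f_{cr}(0) = 1} the integrand reduces to
#' \eqn{(\tau z - 1)/(1 - z)}.) When \eqn{f_{br}(0) = 0} and
#' \eqn{f_{cr}(0) > 0} the antiderivative
#' \eqn{(-\tau z - (\tau - 1)\log(1-z))/(\xi f_{cr}(0))}
#' is used in closed form; otherwise adaptive quadrature. Since the
#' integrand diverges as \eqn{z \to 1}, the exit point is always strictly
#' below 1. The general-response integrand extends the constant-creation
#' case following the entry-exit literature and is flagged in the result.
#'
#' @param z_in entry link density in \eqn{[0, 1/\tau)}.
#' @param params a \code{model_parameters} object with \eqn{\tau > 1}.
#' @param pair a \code{response_pair} whose branch-1 reduced flow is
#'   strictly positive on \eqn{[z_{in}, 1)}.
#' @param tol tolerance of the bisection on the cumulative integral.
#' @param method \code{"auto"} uses the closed-form antiderivative when
#'   \eqn{f_{br}(0) = 0} and quadrature otherwise; \code{"quadrature"}
#'   forces adaptive quadrature (useful as a cross-check of the closed
#'   form).
#' @return A list with \code{z_in}, \code{z_out}, \code{integral_residual}
#'   (value of the defining integral at \code{z_out}), and \code{method}
#'   (\code{"closed_form"} or \code{"quadrature"}).
#' @export
entry_exit_map <- function(z_in, params, pair, tol = 1e-10,
                           method = c("auto", "closed_form", "quadrature")) {
  method <- match.arg(method)
  tau <- params$tau
  stopifnot(tau > 1, z_in >= 0, z_in <= 1 / tau)
  br0 <- pair$f_br(0); cr0 <- pair$f_cr(0)
  g0 <- function(z) -params$zeta * z * br0 + params$xi * (1 - z) * cr0
  zchk <- seq(z_in, 1 - 1e-6, length.out = 201)
  if (any(g0(zchk) <= 0))
    stop("entry-exit undefined: slow flow not transporting past 1/tau",
         call. = FALSE)
  if (z_in == 1 / tau)  # degenerate: zero-length interval
    return(list(z_in = z_in, z_out = z_in, integral_residual = 0,
                method = "closed_form"))
  if (method == "closed_form" && abs(br0) >= 1e-300)
    stop("closed-form antiderivative requires f_br(0) = 0", call. = FALSE)
  if (method != "quadrature" && abs(br0) < 1e-300) {
    # g0(z) = xi*cr0*(1-z): antiderivative of (tau z - 1)/g0 is
    # (-tau z - (tau-1) log(1-z)) / (xi*cr0)
    G <- function(z) (-tau * z - (tau - 1) * log1p(-z)) / (params$xi * cr0)
    Phi <- function(z) G(z) - G(z_in)
    method <- "closed_form"
  } else {
    integrand <- function(z) (tau * z - 1) / g0(z)
    Phi <- function(z)
      stats::integrate(integrand, z_in, z, rel.tol = 1e-11,
                       abs.tol = 1e-12, subdivisions = 1000L,
                       stop.on.error = FALSE)$value
    method <- "quadrature"
  }
  # Phi < 0 just past 1/tau (net contraction accumulated) and increases to
  # +Inf as z -> 1; grow the bracket geometrically towards the singularity
  lo <- 1 / tau
  hi <- NA_real_
  for (k in 1:30) {
    cand <- 1 - (1 - 1 / tau) / 2^k
    if (Phi(cand) > 0) { hi <- cand; break }
    lo <- cand
  }
  if (is.na(hi))
    stop("entry-exit undefined: cumulative integral does not change sign ",
         "below z = 1", call. = FALSE)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (Phi(mid) < 0) lo <- mid else hi <- mid
  }
  z_out <- (lo + hi) / 2
  list(z_in = z_in, z_out = z_out, integral_residual = Phi(z_out),
       method = method)
}

#' Simulate the slow-network (stiff) system
#'
#' Integrates the slow-fast form of the model, in which the link dynamics
#' is scaled by \eqn{0 < \varepsilon \ll 1} (substitutions
#' \eqn{\zeta \mapsto \zeta\varepsilon}, \eqn{\xi \mapsto \varepsilon};
#' note the link-creation rate is absorbed into \eqn{\varepsilon}, leaving
#' \eqn{\zeta} as the only free slow rate):
#' \deqn{dy/dt = -y + \tau y (1-y) z, \qquad
#'   dz/dt = \varepsilon\,[-\zeta z f_{br}(y) + (1-z) f_{cr}(y)].}
#' Uses the stiffness-switching \code{lsoda} integrator; the prevalence
#' collapses to an exponentially small boundary layer near \eqn{y = 0}
#' and re-erupts per the entry-exit mechanism (see [entry_exit_map()]).
#'
#' @inheritParams simulate_animfa
#' @param epsilon slow-fast scale in (0, 1); defaults to
#'   \code{params$epsilon}.
#' @return An \code{animfa_trajectory} (times are fast time).
#' @export
simulate_slowfast <- function(params, pair, initial, horizon,
                              epsilon = params$epsilon, n_out = 4001L,
                              rtol = 1e-10, atol = 1e-12) {
  if (is.null(epsilon) || epsilon <= 0 || epsilon >= 1)
    stop("epsilon must lie in (0, 1)", call. = FALSE)
  stopifnot(all(initial >= 0 & initial <= 1), horizon > 0)
  rhs <- function(t, state, parms) {
    y <- min(max(state[[1]], 0), 1); z <- min(max(state[[2]], 0), 1)
    list(c(-y + params$tau * y * (1 - y) * z,
           epsilon * (-params$zeta * z * pair$f_br(y) +
                        (1 - z) * pair$f_cr(y))))
  }
  times <- seq(0, horizon, length.out = max(2L, n_out))
  sol <- deSolve::ode(y = c(y = initial[[1]], z = initial[[2]]),
                      times = times, func = rhs, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol,
                      maxsteps = 100000L)
  if (attr(sol, "istate")[1] < 0)
    stop(sprintf("solver failure at t=%.6g (last state y=%.6g z=%.6g)",
                 sol[nrow(sol), 1], sol[nrow(sol), 2], sol[nrow(sol), 3]),
         call. = FALSE)
  st <- pmin(pmax(unclass(sol)[, c("y", "z"), drop = FALSE], 0), 1)
  structure(
    list(times = sol[, "time"], states = st,
         terminal_event = "horizon_reached",
         solver_stats = list(rtol = rtol, atol = atol, epsilon = epsilon)),
    class = "animfa_trajectory")
}

# Detect the re-eruption of a slow-fast orbit: the entry z (last downward
# crossing of y = thresh before the dormant phase) and the exit z (next
# upward crossing). Linear interpolation in t between stored points; z
# moves at O(epsilon), so output-grid resolution is ample.
.entry_exit_from_trajectory <- function(traj, thresh = 0.01) {
  y <- traj$states[, 1]; z <- traj$states[, 2]
  below <- y < thresh
  d <- diff(below)
  enter <- which(d == 1)   # index i: crossing between i and i+1 downward
  exit <- which(d == -1)
  if (!length(enter) || !length(exit))
    return(NULL)
  i <- enter[1]
  j <- exit[exit > i][1]
  if (is.na(j)) return(NULL)
  interp_z <- function(k) {
    w <- (thresh - y[k]) / (y[k + 1] - y[k])
    z[k] + w * (z[k + 1] - z[k])
  }
  list(z_entry = interp_z(i), z_exit = interp_z(j))
}
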