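#' Model parameters
#'
#' Parameter container for the rescaled planar model. Time is measured in
#' units of the mean infectious period (rescaled time \eqn{\tilde t =
#' \delta t}), so the model is governed by the effective infection rate
#' \eqn{\tau = \beta/\delta}, the link-breaking rate \eqn{\zeta} and the
#' link-creation rate \eqn{\xi} (both per rescaled time unit). The
#' effective link-breaking rate \eqn{\omega = \zeta/\xi} is always derived,
#' never stored independently.
#'
#' @param tau effective infection rate (> 0).
#' @param zeta link-breaking rate (> 0).
#' @param xi link-creation rate (> 0).
#' @param epsilon optional slow-fast scale in (0, 1); used by
#'   [simulate_slowfast()].
#' @param delta_raw,beta_raw optional pre-rescaling curing and infection
#'   rates, recorded for provenance by [rescale_parameters()].
#' @return An object of class \code{model_parameters}.
#' @examples
#' model_parameters(tau = 3, zeta = 1, xi = 1)
#' @export
model_parameters <- function(tau, zeta = 1, xi = 1, epsilon = NULL,
                             delta_raw = NULL, beta_raw = NULL) {
  for (nm in c("tau", "zeta", "xi")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("parameter '", nm, "' must be a single positive number",
           call. = FALSE)
  }
  if (!is.null(epsilon) &&
      (!is.numeric(epsilon) || length(epsilon) != 1L ||
       epsilon <= 0 || epsilon >= 1))
    stop("parameter 'epsilon' must lie in (0, 1)", call. = FALSE)
  structure(
    list(tau = tau, zeta = zeta, xi = xi, omega = zeta / xi,
         epsilon = epsilon, delta_raw = delta_raw, beta_raw = beta_raw),
    class = "model_parameters")
}

#' @export
print.model_parameters <- function(x, ...) {
  cat(sprintf("<model_parameters> tau=%g zeta=%g xi=%g (omega=%g)",
              x$tau, x$zeta, x$xi, x$omega))
  if (!is.null(x$epsilon)) cat(sprintf(" epsilon=%g", x$epsilon))
  cat("\n")
  invisible(x)
}

#' Rescale raw rates to the dimensionless parameterisation
#'
#' Divides all rates by the curing rate \eqn{\delta}, which sets the time
#' unit: \eqn{\tau = \beta/\delta}, \eqn{\tilde\zeta = \zeta/\delta},
#' \eqn{\tilde\xi = \xi/\delta}. The ratio \eqn{\omega = \zeta/\xi} is
#' invariant under this rescaling.
#'
#' @param delta curing rate (> 0, per original time unit).
#' @param beta infection rate (> 0).
#' @param zeta_raw link-breaking rate (> 0).
#' @param xi_raw link-creation rate (> 0).
#' @return A \code{model_parameters} object.
#' @export
rescale_parameters <- function(delta, beta, zeta_raw, xi_raw) {
  for (nm in c("delta", "beta", "zeta_raw", "xi_raw")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("parameter '", nm, "' must be a single positive number",
           call. = FALSE)
  }
  model_parameters(tau = beta / delta, zeta = zeta_raw / delta,
                   xi = xi_raw / delta,
                   delta_raw = delta, beta_raw = beta)
}

#' The planar vector field
#'
#' Evaluates the right-hand side of the rescaled model
#' \deqn{dy/dt = -y + \tau y (1-y) z,}
#' \deqn{dz/dt = -\zeta z f_{br}(y) + \xi (1-z) f_{cr}(y).}
#'
#' @param state numeric vector \code{c(y, z)} in \eqn{[0,1]^2}.
#' @param params a \code{model_parameters} object.
#' @param pair a \code{response_pair}.
#' @return Named numeric vector \code{c(dy, dz)}.
#' @examples
#' vector_field(c(0.5, 0.5), model_parameters(3), builtin_pair("linear_breaking"))
#' @export
vector_field <- function(state, params, pair) {
  y <- state[[1]]; z <- state[[2]]
  c(dy = -y + params$tau * y * (1 - y) * z,
    dz = -params$zeta * z * pair$f_br(y) +
      params$xi * (1 - z) * pair$f_cr(y))
}

# Vectorised field over matrices of states (columns y, z); used by the
# batch simulator behind basin maps and region-of-attraction soundness.
.vf_matrix <- function(y, z, params, pair) {
  cbind(-y + params$tau * y * (1 - y) * z,
        -params$zeta * z * pair$f_br(y) + params$xi * (1 - z) * pair$f_cr(y))
}

#' Simulate a trajectory
#'
#' Integrates the model with a stiffness-capable adaptive solver
#' (\code{deSolve::lsodar}). Integration stops early when the vector-field
#' norm drops below \code{vf_tol} or the state comes within \code{eq_tol}
#' of one of the supplied equilibria. The square \eqn{[0,1]^2} is forward
#' invariant for the exact flow; numerical states are clamped back to the
#' square post-step and the largest excursion is recorded. Excursions
#' beyond \code{clamp_tol} indicate solver failure and raise an error.
#'
#' @param params a \code{model_parameters} object.
#' @param pair a \code{response_pair}.
#' @param initial numeric \code{c(y0, z0)} in \eqn{[0,1]^2}.
#' @param horizon final rescaled time (> 0).
#' @param equilibria optional list of equilibrium objects (from
#'   [disease_free_equilibrium()] / [endemic_equilibria()]) used for
#'   convergence detection and labelling.
#' @param n_out number of output time points.
#' @param rtol,atol solver tolerances.
#' @param vf_tol vector-field norm below which the orbit is declared
#'   converged.
#' @param eq_tol distance to a known equilibrium below which the orbit is
#'   declared converged to it.
#' @param clamp_tol largest tolerated excursion outside \eqn{[0,1]^2}.
#' @return An object of class \code{animfa_trajectory}: list with
#'   \code{times}, \code{states} (matrix with columns \code{y}, \code{z}),
#'   \code{terminal_event} (\code{"horizon_reached"},
#'   \code{"converged:<label>"} or \code{"converged"}), and
#'   \code{solver_stats}.
#' @export
simulate_animfa <- function(params, pair, initial, horizon,
                            equilibria = NULL, n_out = 401L,
                            rtol = 1e-8, atol = 1e-10,
                            vf_tol = 1e-9, eq_tol = 1e-6,
                            clamp_tol = 1e-9) {
  stopifnot(inherits(params, "model_parameters"),
            inherits(pair, "response_pair"),
            length(initial) == 2L, horizon > 0)
  if (any(initial < 0 | initial > 1))
    stop("initial state must lie in [0,1]^2", call. = FALSE)
  eq_pts <- NULL
  if (!is.null(equilibria)) {
    if (inherits(equilibria, "animfa_equilibrium"))
      equilibria <- list(equilibria)
    eq_pts <- do.call(rbind, lapply(equilibria, function(e) c(e$y, e$z)))
  }
  rhs <- function(t, state, parms) {
    list(vector_field(state, params, pair))
  }
  rootfun <- function(t, state, parms) {
    f <- vector_field(state, params, pair)
    r <- sqrt(sum(f^2)) - vf_tol
    if (!is.null(eq_pts)) {
      d <- sqrt((eq_pts[, 1] - state[1])^2 + (eq_pts[, 2] - state[2])^2)
      r <- c(r, min(d) - eq_tol)
    }
    r
  }
  times <- seq(0, horizon, length.out = max(2L, n_out))
  sol <- deSolve::lsodar(y = c(y = initial[[1]], z = initial[[2]]),
                         times = times, func = rhs, parms = NULL,
                         rootfunc = rootfun,
                         rtol = rtol, atol = atol)
  st <- unclass(sol)[, c("y", "z"), drop = FALSE]
  excursion <- max(0, max(-st), max(st - 1))
  if (excursion > clamp_tol)
    stop(sprintf(paste0("solver failure: state left [0,1]^2 by %.3g ",
                        "(last state y=%.6g z=%.6g at t=%.6g)"),
                 excursion, st[nrow(st), 1], st[nrow(st), 2],
                 sol[nrow(sol), "time"]),
         call. = FALSE)
  st <- pmin(pmax(st, 0), 1)
  tt <- sol[, "time"]
  rooted <- !is.null(attr(sol, "troot")) && length(attr(sol, "troot")) > 0
  terminal <- "horizon_reached"
  if (rooted) {
    terminal <- "converged"
    if (!is.null(eq_pts)) {
      last <- st[nrow(st), ]
      d <- sqrt((eq_pts[, 1] - last[1])^2 + (eq_pts[, 2] - last[2])^2)
      k <- which.min(d)
      lab <- equilibria[[k]]$kind
      terminal <- paste0("converged:", lab, sprintf("(%.6g,%.6g)",
                                                    eq_pts[k, 1], eq_pts[k, 2]))
    }
  }
  structure(
    list(times = tt, states = st, terminal_event = terminal,
         solver_stats = list(rtol = rtol, atol = atol,
                             n_steps = nrow(st),
                             max_boundary_excursion = excursion)),
    class = "animfa_trajectory")
}

#' @export
print.animfa_trajectory <- function(x, ...) {
  n <- length(x$times)
  cat(sprintf("<animfa_trajectory> %d points, t in [%g, %g]\n",
              n, x$times[1], x$times[n]))
  cat(sprintf("  terminal: %s at (y=%.6g, z=%.6g)\n", x$terminal_event,
              x$states[n, 1], x$states[n, 2]))
  invisible(x)
}

#' @export
as.data.frame.animfa_trajectory <- function(x, ...) {
  data.frame(t = x$times, y = x$states[, 1], z = x$states[, 2])
}

# Batch terminal-state computation: integrates many initial conditions as
# one stacked ODE system (non-stiff solver, vectorised RHS). Returns the
# matrix of terminal states. Used by basin_map() and the ROA soundness
# check, where per-point lsodar calls would be prohibitively slow.
.simulate_batch <- function(params, pair, initials, horizon,
                            rtol = 1e-8, atol = 1e-10,
                            chunk = 2000L, times = NULL) {
  n <- nrow(initials)
  out <- matrix(NA_real_, n, 2)
  if (is.null(times)) times <- c(0, horizon)
  idx <- split(seq_len(n), ceiling(seq_len(n) / chunk))
  for (ii in idx) {
    m <- length(ii)
    state0 <- c(initials[ii, 1], initials[ii, 2])
    rhs <- function(t, state, parms) {
      y <- state[1:m]; z <- state[(m + 1):(2 * m)]
      # clamp inside the RHS so responses are never evaluated outside [0,1]
      y <- pmin(pmax(y, 0), 1); z <- pmin(pmax(z, 0), 1)
      d <- .vf_matrix(y, z, params, pair)
      list(c(d[, 1], d[, 2]))
    }
    sol <- deSolve::ode(y = state0, times = times, func = rhs, parms = NULL,
                        method = "ode45", rtol = rtol, atol = atol)
    last <- sol[nrow(sol), -1]
    out[ii, 1] <- pmin(pmax(last[1:m], 0), 1)
    out[ii, 2] <- pmin(pmax(last[(m + 1):(2 * m)], 0), 1)
  }
  colnames(out) <- c("y", "z")
  out
}
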