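#' Jacobian of the planar model
#'
#' Evaluates the Jacobian matrix of the vector field at an arbitrary state,
#' \deqn{J = \begin{pmatrix} -1+\tau(1-2y)z & \tau y(1-y) \\
#'   -\zeta z f_{br}'(y) + \xi(1-z) f_{cr}'(y) &
#'   -\zeta f_{br}(y) - \xi f_{cr}(y) \end{pmatrix}.}
#' At any disease-free state (\eqn{y = 0}) the matrix is lower-triangular,
#' so its eigenvalues are the diagonal entries and are always real there.
#'
#' @inheritParams vector_field
#' @return A 2x2 numeric matrix.
#' @export
model_jacobian <- function(state, params, pair) {
  y <- state[[1]]; z <- state[[2]]
  dbr <- response_derivative(pair, "br", y)
  dcr <- response_derivative(pair, "cr", y)
  matrix(c(-1 + params$tau * (1 - 2 * y) * z,
           -params$zeta * z * dbr + params$xi * (1 - z) * dcr,
           params$tau * y * (1 - y),
           -params$zeta * pair$f_br(y) - params$xi * pair$f_cr(y)),
         2, 2)
}

#' Classify linear stability from eigenvalues
#'
#' Labels a planar equilibrium from the eigenvalues of its Jacobian. Real
#' parts within \code{tol} of zero make the classification
#' \code{"undetermined"}: linearisation is inconclusive there and the label
#' is surfaced rather than silently resolved.
#'
#' @param eigenvalues complex (or numeric) vector of length 2.
#' @param tol tolerance on real parts (default 1e-8).
#' @return One of \code{"stable_node"}, \code{"unstable_node"},
#'   \code{"saddle"}, \code{"stable_spiral"}, \code{"unstable_spiral"},
#'   \code{"undetermined"}.
#' @export
classify_stability <- function(eigenvalues, tol = 1e-8) {
  stopifnot(length(eigenvalues) == 2L, tol > 0)
  re <- Re(eigenvalues)
  im <- Im(as.complex(eigenvalues))
  if (any(abs(re) <= tol)) return("undetermined")
  complex_pair <- any(abs(im) > tol)
  if (all(re < 0)) return(if (complex_pair) "stable_spiral" else "stable_node")
  if (all(re > 0)) return(if (complex_pair) "unstable_spiral" else "unstable_node")
  "saddle"
}

# Assemble a classified equilibrium object; residual is re-evaluated from
# the vector field, independently of however (y, z) was obtained.
.make_equilibrium <- function(y, z, kind, params, pair) {
  J <- model_jacobian(c(y, z), params, pair)
  ev <- eigen(J, only.values = TRUE)$values
  f <- vector_field(c(y, z), params, pair)
  structure(
    list(y = y, z = z, kind = kind, jacobian = J,
         eigenvalues = as.complex(ev),
         stability = classify_stability(ev),
         residual = max(abs(f))),
    class = "animfa_equilibrium")
}

#' @export
print.animfa_equilibrium <- function(x, ...) {
  cat(sprintf("<animfa_equilibrium> %s (y=%.8g, z=%s) %s\n",
              x$kind, x$y,
              if (is.na(x$z)) "family: z in [0,1]" else sprintf("%.8g", x$z),
              x$stability))
  if (!is.null(x$eigenvalues))
    cat("  eigenvalues:", format(x$eigenvalues, digits = 6), "\n")
  invisible(x)
}

#' Disease-free equilibrium
#'
#' The model always admits the disease-free steady state \eqn{y = 0} with
#' link density \deqn{z_0 = \frac{f_{cr}(0)}{\omega f_{br}(0) + f_{cr}(0)}}
#' when at least one response is non-zero at \eqn{y = 0}. When both vanish
#' there, every point of the segment \eqn{\{y = 0,\ z \in [0,1]\}} is an
#' equilibrium (a degenerate family); linear analysis is inconclusive for
#' the family (one eigenvalue is exactly 0), so no definite stability label
#' is assigned.
#'
#' @inheritParams vector_field
#' @param z_family for the degenerate family only: a representative
#'   \eqn{z}-value at which to evaluate the Jacobian. Ignored otherwise.
#' @return An \code{animfa_equilibrium} of kind \code{"dfe"} or
#'   \code{"dfe_family"} (the latter carries \code{family = c(0, 1)} and,
#'   unless \code{z_family} is given, no Jacobian).
#' @export
disease_free_equilibrium <- function(params, pair, z_family = NULL) {
  stopifnot(inherits(params, "model_parameters"),
            inherits(pair, "response_pair"))
  br0 <- pair$f_br(0); cr0 <- pair$f_cr(0)
  denom <- params$omega * br0 + cr0
  if (denom > 0) {
    eq <- .make_equilibrium(0, cr0 / denom, "dfe", params, pair)
    return(eq)
  }
  # degenerate family: both responses vanish at y = 0
  if (!is.null(z_family)) {
    stopifnot(z_family >= 0, z_family <= 1)
    eq <- .make_equilibrium(0, z_family, "dfe_family", params, pair)
    eq$stability <- "undetermined"  # lambda_2 = 0 exactly on the family
    eq$family <- c(0, 1)
    return(eq)
  }
  structure(
    list(y = 0, z = NA_real_, kind = "dfe_family", jacobian = NULL,
         eigenvalues = NULL, stability = "undetermined", residual = 0,
         family = c(0, 1)),
    class = "animfa_equilibrium")
}

# Left-hand side of the endemic equilibrium equation
# omega f_br(y) - (tau - 1) f_cr(y) + tau y f_cr(y) = 0.
.ee_equation <- function(y, params, pair) {
  params$omega * pair$f_br(y) -
    (params$tau - 1) * pair$f_cr(y) + params$tau * y * pair$f_cr(y)
}

#' Endemic equilibria
#'
#' Finds all endemic steady states: the roots \eqn{y_E \in (0,1)} of the
#' balance equation \deqn{\omega f_{br}(y) = (\tau - 1) f_{cr}(y) -
#' \tau y f_{cr}(y),} each paired with the steady-state link density
#' \eqn{z_E = 1/(\tau(1-y_E))}. Roots whose link density falls outside
#' \eqn{(0,1]} are infeasible and discarded; \eqn{y_E = 1} is never a
#' valid equilibrium. Roots are located by a dense sign scan (2001 points)
#' with bracketed refinement; tangential (double) roots, as at a
#' saddle-node, are additionally sought as local minima of the absolute
#' residual and flagged with \code{multiplicity = 2}.
#'
#' @inheritParams vector_field
#' @param scan_points number of scan points on \eqn{(0,1)}.
#' @return A list of \code{animfa_equilibrium} objects of kind
#'   \code{"endemic"} (possibly empty), ordered by \eqn{y}.
#' @export
endemic_equilibria <- function(params, pair, scan_points = 2001L) {
  stopifnot(inherits(params, "model_parameters"),
            inherits(pair, "response_pair"))
  yg <- seq(1e-9, 1 - 1e-9, length.out = scan_points)
  vals <- .ee_equation(yg, params, pair)
  roots <- numeric(0)
  mult <- integer(0)
  sgn <- sign(vals)
  # exact zeros at scan points
  hit <- which(vals == 0)
  roots <- c(roots, yg[hit]); mult <- c(mult, rep(1L, length(hit)))
  flip <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  for (i in flip) {
    r <- stats::uniroot(function(y) .ee_equation(y, params, pair),
                        c(yg[i], yg[i + 1]), tol = 1e-14)
    roots <- c(roots, r$root); mult <- c(mult, 1L)
  }
  # tangency search: interior local minima of |E| that dip to ~0 without a
  # sign change (double roots at a fold)
  av <- abs(vals)
  loc_min <- which(diff(sign(diff(av))) > 0) + 1L
  for (i in loc_min) {
    if (length(roots) && min(abs(yg[i] - roots)) < 5e-3) next
    opt <- stats::optimize(function(y) abs(.ee_equation(y, params, pair)),
                           c(yg[max(1L, i - 1L)], yg[min(scan_points, i + 1L)]),
                           tol = 1e-12)
    if (opt$objective < 1e-10) {
      roots <- c(roots, opt$minimum); mult <- c(mult, 2L)
    }
  }
  if (!length(roots)) return(list())
  o <- order(roots)
  roots <- roots[o]; mult <- mult[o]
  # merge duplicates within 1e-8
  keep <- c(TRUE, diff(roots) > 1e-8)
  roots <- roots[keep]; mult <- mult[keep]
  out <- list()
  for (k in seq_along(roots)) {
    yE <- roots[k]
    if (yE <= 0 || yE >= 1) next
    zE <- 1 / (params$tau * (1 - yE))
    if (zE <= 0 || zE > 1 + 1e-12) next
    zE <- min(zE, 1)
    eq <- .make_equilibrium(yE, zE, "endemic", params, pair)
    eq$multiplicity <- mult[k]
    out[[length(out) + 1L]] <- eq
  }
  out
}

#' Basic reproduction number
#'
#' The next-generation splitting of the prevalence equation at the
#' disease-free equilibrium gives
#' \deqn{R_0 = \tau\,\frac{f_{cr}(0)}{\omega f_{br}(0) + f_{cr}(0)}.}
#' The splitting requires \eqn{f_{cr}(0) > 0}; when link creation vanishes
#' in the disease-free state the method does not apply (the disease-free
#' equilibrium never loses stability) and a threshold-based definition via
#' [critical_threshold()] should be used instead.
#'
#' @inheritParams vector_field
#' @return A single number \eqn{R_0}.
#' @export
basic_reproduction_number <- function(params, pair) {
  stopifnot(inherits(params, "model_parameters"),
            inherits(pair, "response_pair"))
  cr0 <- pair$f_cr(0)
  if (cr0 <= 0)
    stop("next-generation method not applicable: f_cr(0) = 0", call. = FALSE)
  params$tau * cr0 / (params$omega * pair$f_br(0) + cr0)
}

#' Critical infection-rate threshold
#'
#' Locates, by bisection over \eqn{\tau}, the point where the number of
#' endemic equilibria changes — the transcritical threshold \eqn{R_0 = 1}
#' in the regular cases, or the saddle-node fold where a pair of endemic
#' equilibria is born when the next-generation number is undefined.
#'
#' @param params_template a \code{model_parameters} object supplying
#'   \eqn{\zeta} and \eqn{\xi}; its \eqn{\tau} is overridden.
#' @param pair a \code{response_pair}.
#' @param tau_range numeric length-2 interval to search.
#' @param tol bracket width at which bisection stops.
#' @return A list with \code{tau_star} (midpoint of the final bracket),
#'   \code{ee_count_below}, \code{ee_count_above}, \code{bracket_width}.
#' @export
critical_threshold <- function(params_template, pair,
                               tau_range, tol = 1e-6) {
  stopifnot(length(tau_range) == 2L, tau_range[1] < tau_range[2], tol > 0)
  count_at <- function(tau) {
    p <- model_parameters(tau = tau, zeta = params_template$zeta,
                          xi = params_template$xi)
    length(endemic_equilibria(p, pair))
  }
  lo <- tau_range[1]; hi <- tau_range[2]
  n_lo <- count_at(lo); n_hi <- count_at(hi)
  if (n_lo == n_hi)
    stop("no threshold in range: equal endemic-equilibrium counts (",
         n_lo, ") at both ends", call. = FALSE)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (count_at(mid) == n_lo) lo <- mid else hi <- mid
  }
  list(tau_star = (lo + hi) / 2, ee_count_below = n_lo,
       ee_count_above = n_hi, bracket_width = hi - lo)
}
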