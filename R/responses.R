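#' Functional response pairs
#'
#' A response pair holds the two prevalence-dependent multipliers of the
#' link dynamics: the link-breaking response \code{f_br(y)} and the
#' link-creation response \code{f_cr(y)}, both defined on the prevalence
#' interval \eqn{[0,1]} and required to be non-negative there. The pair is
#' the behavioural core of the adaptive-network model: it encodes how
#' individuals rewire their contacts in response to the current prevalence.
#'
#' Responses may be given as R functions or as expression strings in a
#' restricted arithmetic grammar (symbol \code{y}, the operators
#' \code{+ - * / ^}, parentheses, and the functions \code{exp} and
#' \code{log}). Expression input enables symbolic differentiation; function
#' input falls back to central differences unless analytic derivatives are
#' supplied.
#'
#' @param f_br link-breaking response: function of \code{y} or expression string.
#' @param f_cr link-creation response: function of \code{y} or expression string.
#' @param dfbr,dfcr optional analytic derivatives (functions of \code{y}).
#' @param name label attached to the pair.
#' @return An object of class \code{response_pair} with elements
#'   \code{name}, \code{f_br}, \code{f_cr}, \code{dfbr}, \code{dfcr}
#'   (the derivatives may be \code{NULL}), and \code{smoothness_hint}
#'   (\code{"analytic"} or \code{"numeric"}).
#' @seealso [builtin_pair()] for the four named example pairs,
#'   [validate_pair()] for the admissibility checks.
#' @examples
#' p <- response_pair("y^2", "1 - y", name = "quadratic breaking")
#' p$f_br(0.5)
#' response_derivative(p, "br", 0.5)
#' @export
response_pair <- function(f_br, f_cr, dfbr = NULL, dfcr = NULL,
                          name = "custom") {
  br <- .as_response(f_br, "f_br")
  cr <- .as_response(f_cr, "f_cr")
  if (is.null(dfbr)) dfbr <- br$deriv
  if (is.null(dfcr)) dfcr <- cr$deriv
  structure(
    list(name = name, f_br = br$fn, f_cr = cr$fn,
         dfbr = dfbr, dfcr = dfcr,
         smoothness_hint = if (!is.null(dfbr) && !is.null(dfcr))
           "analytic" else "numeric",
         expr_br = br$expr, expr_cr = cr$expr),
    class = "response_pair")
}

# Accepts a function or a restricted expression string; returns the callable,
# a symbolic derivative when the expression path allows it, and the source text.
.as_response <- function(f, what) {
  if (is.function(f)) {
    return(list(fn = f, deriv = NULL, expr = NULL))
  }
  if (is.character(f) && length(f) == 1L) {
    e <- .parse_response_expr(f, what)
    fn <- function(y) eval(e, list(y = y))
    deriv <- tryCatch({
      de <- stats::D(e, "y")
      function(y) {
        v <- eval(de, list(y = y))
        # D() collapses constants; recycle to the input length
        rep_len(v, length(y))
      }
    }, error = function(err) NULL)
    return(list(fn = fn, deriv = deriv, expr = f))
  }
  stop(what, " must be a function or a single expression string", call. = FALSE)
}

# Restricted grammar: y, numeric literals, + - * / ^, parentheses, exp, log.
.parse_response_expr <- function(txt, what) {
  e <- tryCatch(parse(text = txt)[[1]],
                error = function(err)
                  stop("cannot parse ", what, ": ", conditionMessage(err),
                       call. = FALSE))
  allowed_calls <- c("+", "-", "*", "/", "^", "(", "exp", "log")
  check <- function(x) {
    if (is.numeric(x)) return(invisible(TRUE))
    if (is.name(x)) {
      if (!identical(as.character(x), "y"))
        stop("symbol '", as.character(x), "' not allowed in ", what,
             " (only 'y')", call. = FALSE)
      return(invisible(TRUE))
    }
    if (is.call(x)) {
      op <- as.character(x[[1]])
      if (!op %in% allowed_calls)
        stop("operator/function '", op, "' not allowed in ", what,
             call. = FALSE)
      for (i in seq_along(x)[-1]) check(x[[i]])
      return(invisible(TRUE))
    }
    stop("unsupported construct in ", what, call. = FALSE)
  }
  check(e)
  e
}

#' Built-in functional response pairs
#'
#' The four named pairs used throughout the examples:
#' \describe{
#'   \item{\code{rlad}}{Random Link-Activation Deactivation,
#'     \eqn{f_{br}(y)=f_{cr}(y)=1}: link dynamics independent of prevalence.}
#'   \item{\code{linear_breaking}}{\eqn{f_{br}(y)=y}, \eqn{f_{cr}(y)=1}:
#'     breaking proportional to prevalence, creation constant.}
#'   \item{\code{asis}}{Adaptive SIS, \eqn{f_{br}(y)=2y(1-y)},
#'     \eqn{f_{cr}(y)=(1-y)^2}: breaking requires susceptible-infected
#'     contact, creation between susceptibles. The factor 2 is the
#'     conversion factor from the underlying Markovian model and is kept
#'     verbatim.}
#'   \item{\code{aid}}{Adaptive Information Diffusion,
#'     \eqn{f_{br}(y)=(1-y)^2}, \eqn{f_{cr}(y)=2y(1-y)}: links are created
#'     when the spreading item (e.g. a rumour) is prevalent.}
#' }
#' All built-ins carry analytic derivatives.
#'
#' @param name one of \code{"rlad"}, \code{"linear_breaking"},
#'   \code{"asis"}, \code{"aid"}.
#' @return A \code{response_pair}.
#' @examples
#' builtin_pair("asis")$f_br(0.5)
#' @export
builtin_pair <- function(name) {
  valid <- c("rlad", "linear_breaking", "asis", "aid")
  if (!is.character(name) || length(name) != 1L || !name %in% valid)
    stop("unknown builtin response pair; valid names are: ",
         paste(valid, collapse = ", "), call. = FALSE)
  switch(name,
    rlad = response_pair(
      function(y) rep_len(1, length(y)), function(y) rep_len(1, length(y)),
      dfbr = function(y) rep_len(0, length(y)),
      dfcr = function(y) rep_len(0, length(y)),
      name = "rlad"),
    linear_breaking = response_pair(
      function(y) y, function(y) rep_len(1, length(y)),
      dfbr = function(y) rep_len(1, length(y)),
      dfcr = function(y) rep_len(0, length(y)),
      name = "linear_breaking"),
    asis = response_pair(
      function(y) 2 * y * (1 - y), function(y) (1 - y)^2,
      dfbr = function(y) 2 - 4 * y,
      dfcr = function(y) -2 * (1 - y),
      name = "asis"),
    aid = response_pair(
      function(y) (1 - y)^2, function(y) 2 * y * (1 - y),
      dfbr = function(y) -2 * (1 - y),
      dfcr = function(y) 2 - 4 * y,
      name = "aid"))
}

#' @export
print.response_pair <- function(x, ...) {
  cat("<response_pair> ", x$name, "\n", sep = "")
  if (!is.null(x$expr_br)) cat("  f_br(y) = ", x$expr_br, "\n", sep = "")
  if (!is.null(x$expr_cr)) cat("  f_cr(y) = ", x$expr_cr, "\n", sep = "")
  cat("  derivatives: ", x$smoothness_hint, "\n", sep = "")
  invisible(x)
}

#' Validate a functional response pair
#'
#' Checks the admissibility conditions on a uniform grid over \eqn{[0,1]}:
#' both responses must be non-negative and finite, they must not both be
#' identically zero, and any supplied analytic derivatives must agree with
#' a central difference to 1e-6. Negativity below 1e-12 in magnitude is
#' absorbed as roundoff.
#'
#' @param pair a \code{response_pair}.
#' @param grid_size number of grid points (default 10001).
#' @return A list with \code{valid} (logical) and \code{violations}
#'   (character vector of human-readable findings, empty when valid).
#' @export
validate_pair <- function(pair, grid_size = 10001L) {
  stopifnot(inherits(pair, "response_pair"), grid_size >= 2L)
  yg <- seq(0, 1, length.out = grid_size)
  violations <- character(0)
  vals <- list(f_br = pair$f_br(yg), f_cr = pair$f_cr(yg))
  for (nm in names(vals)) {
    v <- vals[[nm]]
    bad <- !is.finite(v)
    if (any(bad))
      violations <- c(violations, sprintf(
        "%s non-finite at %d grid point(s), first at y=%.6g",
        nm, sum(bad), yg[which(bad)[1]]))
    neg <- is.finite(v) & v < -1e-12
    if (any(neg))
      violations <- c(violations, sprintf(
        "%s negative at %d grid point(s), first at y=%.6g (value %.3g)",
        nm, sum(neg), yg[which(neg)[1]], v[which(neg)[1]]))
  }
  if (all(abs(vals$f_br) <= 1e-12, na.rm = TRUE) &&
      all(abs(vals$f_cr) <= 1e-12, na.rm = TRUE))
    violations <- c(violations, "both responses identically zero on [0,1]")
  # derivative cross-check on a coarser grid to keep the check cheap
  if (identical(pair$smoothness_hint, "analytic")) {
    yd <- seq(0, 1, length.out = min(grid_size, 1001L))
    for (which in c("br", "cr")) {
      ana <- .resp_deriv_analytic(pair, which, yd)
      num <- .resp_deriv_numeric(pair, which, yd)
      dev <- max(abs(ana - num))
      if (!is.finite(dev) || dev > 1e-6)
        violations <- c(violations, sprintf(
          "analytic f_%s' deviates from central difference by %.3g", which, dev))
    }
  }
  list(valid = length(violations) == 0L, violations = violations)
}

.resp_deriv_analytic <- function(pair, which, y) {
  d <- if (which == "br") pair$dfbr else pair$dfcr
  rep_len(d(y), length(y))
}

# Central difference, h = 1e-6; second-order one-sided stencils where the
# central one would leave [0,1].
.resp_deriv_numeric <- function(pair, which, y, h = 1e-6) {
  f <- if (which == "br") pair$f_br else pair$f_cr
  out <- numeric(length(y))
  interior <- y - h >= 0 & y + h <= 1
  if (any(interior)) {
    yi <- y[interior]
    out[interior] <- (f(yi + h) - f(yi - h)) / (2 * h)
  }
  low <- y - h < 0
  if (any(low)) {
    yl <- y[low]
    out[low] <- (-3 * f(yl) + 4 * f(yl + h) - f(yl + 2 * h)) / (2 * h)
  }
  high <- y + h > 1
  if (any(high)) {
    yh <- y[high]
    out[high] <- (3 * f(yh) - 4 * f(yh - h) + f(yh - 2 * h)) / (2 * h)
  }
  out
}

#' Differentiate a functional response
#'
#' Returns the derivative of the selected response at \code{y}: the
#' analytic derivative when the pair carries one, otherwise a central
#' difference with step 1e-6 (one-sided at the interval ends). The
#' derivative enters the Jacobian of the model, so non-differentiable
#' user-supplied responses degrade the stability classification; they are
#' flagged by [validate_pair()] but not forbidden.
#'
#' @param pair a \code{response_pair}.
#' @param which \code{"br"} or \code{"cr"}.
#' @param y prevalence value(s) in \eqn{[0,1]}.
#' @return Numeric vector of derivative values.
#' @export
response_derivative <- function(pair, which = c("br", "cr"), y) {
  which <- match.arg(which)
  stopifnot(all(y >= 0 & y <= 1))
  d <- if (which == "br") pair$dfbr else pair$dfcr
  if (!is.null(d)) rep_len(d(y), length(y)) else
    .resp_deriv_numeric(pair, which, y)
}

#' Closed-form solution for the prevalence-independent (RLAD) model
#'
#' When both responses are constant, the link density decouples and decays
#' exponentially to \eqn{1/(1+\omega)}; with \eqn{z} held at that limit the
#' prevalence follows a logistic curve. This function evaluates that
#' closed form: \deqn{z(t) = \frac{1}{1+\omega} +
#'   \Big(z_0 - \frac{1}{1+\omega}\Big) e^{-(\xi+\zeta)t},}
#' and \eqn{y(t)} the logistic solution of
#' \eqn{dy/dt = -y + \tau y (1-y)/(1+\omega)}, with steady state
#' \eqn{y_E = 1 - (1+\omega)/\tau} and growth rate
#' \eqn{K = \tau/(1+\omega) - 1} (the rate the fixed-link-density ODE
#' actually carries; it reduces to \eqn{\tau - 1} on a complete static
#' graph, \eqn{\omega \to 0}).
#'
#' @param params a \code{model_parameters} object with \eqn{\tau > 1+\omega}.
#' @param y0,z0 initial prevalence and link density.
#' @param t rescaled time(s) at which to evaluate.
#' @return A list with vectors \code{y} and \code{z}, and the closed-form
#'   constants \code{yE}, \code{K}, \code{t0} (inflection time, finite only
#'   when \eqn{0 < y_0 < y_E}), and \code{zLimit}.
#' @export
rlad_closed_form <- function(params, y0, z0, t) {
  stopifnot(inherits(params, "model_parameters"))
  omega <- params$omega
  tau <- params$tau
  if (tau <= 1 + omega)
    stop("no endemic logistic branch: requires tau > 1 + omega", call. = FALSE)
  stopifnot(y0 >= 0, y0 < 1, z0 >= 0, z0 <= 1, all(t >= 0))
  zLimit <- 1 / (1 + omega)
  z <- zLimit + (z0 - zLimit) * exp(-(params$xi + params$zeta) * t)
  yE <- 1 - (1 + omega) / tau
  K <- tau / (1 + omega) - 1
  t0 <- if (y0 > 0 && y0 < yE) log(yE / y0 - 1) / K else NA_real_
  y <- if (y0 == 0) {
    rep_len(0, length(t))
  } else if (y0 == yE) {
    rep_len(y0, length(t))
  } else {
    # algebraically identical to yE / (1 + exp(-K (t - t0))) but valid
    # for y0 > yE as well, where t0 is not real
    yE / (1 + (yE / y0 - 1) * exp(-K * t))
  }
  list(y = y, z = z, yE = yE, K = K, t0 = t0, zLimit = zLimit)
}
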