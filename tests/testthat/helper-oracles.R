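# Independent oracles shared across test files.

# 1-D integration of the fixed-link-density prevalence ODE
# dy/dt = -y + tau y (1-y) z_fix  -- used to check the logistic closed form.
integrate_fixed_z <- function(tau, z_fix, y0, times) {
  sol <- deSolve::lsoda(c(y = y0), times,
                        function(t, s, p) list(-s + tau * s * (1 - s) * z_fix),
                        NULL, rtol = 1e-12, atol = 1e-14)
  unname(sol[, "y"])
}

# Closed-form endemic y-coordinates printed for the four example pairs
# (NULL when none exists in the feasible region).
closed_form_ee_y <- function(name, tau, omega) {
  switch(name,
    rlad = if (tau > 1 + omega) 1 - (1 + omega) / tau,
    linear_breaking = if (tau > 1) (tau - 1) / (tau + omega),
    asis = if (tau > 1)
      1 - (1 - 2 * omega) / (2 * tau) -
        sqrt(((1 - 2 * omega) / (2 * tau))^2 + 2 * omega / tau),
    aid = {
      disc <- (2 * tau + omega - 2)^2 - 8 * tau * omega
      if (disc > 0) {
        y12 <- (2 * tau + omega - 2 + c(-1, 1) * sqrt(disc)) / (4 * tau)
        y12[y12 > 0 & y12 < 1 & y12 <= 1 - 1 / tau]
      }
    })
}

# Random polynomial response (non-negative on [0,1] by construction).
random_poly_response <- function() {
  a <- stats::runif(3, 0, 2)
  function(y) a[1] + a[2] * y + a[3] * y^2
}

# Antiderivative root for the entry-exit relation of the constant-creation
# model (f_br(0)=0, f_cr(0)=c0): independent of the package path.
entry_exit_oracle <- function(z_in, tau, xi = 1, c0 = 1) {
  G <- function(z) (-tau * z - (tau - 1) * log1p(-z)) / (xi * c0)
  stats::uniroot(function(z) G(z) - G(z_in), c(1 / tau + 1e-12, 1 - 1e-12),
                 tol = 1e-13)$root
}
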