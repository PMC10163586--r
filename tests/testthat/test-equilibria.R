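test_that("disease-free equilibrium follows the general link-density formula", {
  p3 <- model_parameters(3, 1, 1)
  expect_equal(disease_free_equilibrium(p3, builtin_pair("linear_breaking"))$z, 1)
  expect_equal(disease_free_equilibrium(p3, builtin_pair("aid"))$z, 0)
  expect_equal(disease_free_equilibrium(p3, builtin_pair("rlad"))$z, 0.5)
  # omega-dependence: z0 = f_cr(0) / (omega f_br(0) + f_cr(0))
  p_w <- model_parameters(2, zeta = 3, xi = 1)  # omega = 3
  expect_equal(disease_free_equilibrium(p_w, builtin_pair("rlad"))$z, 0.25)
  # degenerate family when both responses vanish at 0
  fam_pair <- response_pair("y", "y")
  fam <- disease_free_equilibrium(p3, fam_pair)
  expect_identical(fam$kind, "dfe_family")
  expect_identical(fam$stability, "undetermined")
  expect_equal(fam$family, c(0, 1))
  fam_pt <- disease_free_equilibrium(p3, fam_pair, z_family = 0.5)
  expect_equal(fam_pt$z, 0.5)
  expect_identical(fam_pt$stability, "undetermined")
})

test_that("endemic equilibria match the printed closed forms", {
  p3 <- model_parameters(3, 1, 1)
  ee_lb <- endemic_equilibria(p3, builtin_pair("linear_breaking"))
  expect_length(ee_lb, 1)
  expect_equal(ee_lb[[1]]$y, 0.5, tolerance = 1e-10)
  expect_equal(ee_lb[[1]]$z, 2 / 3, tolerance = 1e-10)
  ee_as <- endemic_equilibria(p3, builtin_pair("asis"))
  expect_length(ee_as, 1)
  expect_equal(ee_as[[1]]$y, 1 / 3, tolerance = 1e-8)
  expect_equal(ee_as[[1]]$z, 1 / 2, tolerance = 1e-8)
  ee_aid <- endemic_equilibria(p3, builtin_pair("aid"))
  expect_length(ee_aid, 2)
  expect_equal(sapply(ee_aid, `[[`, "y"), c(1 / 3, 1 / 2), tolerance = 1e-8)
  expect_length(endemic_equilibria(model_parameters(0.8, 1, 1),
                                   builtin_pair("linear_breaking")), 0)
})

test_that("equilibrium invariants: residual and link-density relation", {
  set.seed(5)
  for (b in c("rlad", "linear_breaking", "asis", "aid")) {
    pair <- builtin_pair(b)
    for (i in 1:8) {
      params <- model_parameters(stats::runif(1, 0.5, 6),
                                 stats::runif(1, 0.3, 3),
                                 stats::runif(1, 0.3, 3))
      for (e in endemic_equilibria(params, pair)) {
        expect_lte(e$residual, 1e-10)
        expect_gt(e$y, 0); expect_lt(e$y, 1)
        expect_lt(abs(e$z - 1 / (params$tau * (1 - e$y))), 1e-10)
        # both steady-state relations hold simultaneously
        expect_lt(abs(animfa:::.ee_equation(e$y, params, pair)), 1e-10)
      }
      dfe <- disease_free_equilibrium(params, pair)
      expect_lte(dfe$residual, 1e-10)
    }
  }
})

test_that("closed-form and numerical equilibria agree on a parameter grid", {
  for (b in c("rlad", "linear_breaking", "asis", "aid")) {
    pair <- builtin_pair(b)
    for (tau in c(1.5, 3, 5)) {
      for (omega in c(0.25, 1, 4)) {
        params <- model_parameters(tau, zeta = omega, xi = 1)
        y_exp <- sort(closed_form_ee_y(b, tau, omega))
        y_num <- sort(vapply(endemic_equilibria(params, pair), `[[`,
                             numeric(1), "y"))
        expect_equal(length(y_num), length(y_exp),
                     info = sprintf("%s tau=%g omega=%g", b, tau, omega))
        if (length(y_exp))
          expect_lt(max(abs(y_num - y_exp)), 1e-8)
      }
    }
  }
})

test_that("the endemic state merges with the disease-free state at threshold", {
  # transcritical cases: at R0 = 1 the endemic root coincides with y = 0
  p_rlad <- model_parameters(2 + 1e-9, zeta = 1, xi = 1)  # R0 = tau/2
  ee <- endemic_equilibria(p_rlad, builtin_pair("rlad"))
  expect_true(all(vapply(ee, `[[`, numeric(1), "y") < 1e-6))
  p_lb <- model_parameters(1 + 1e-9, 1, 1)
  ee2 <- endemic_equilibria(p_lb, builtin_pair("linear_breaking"))
  expect_true(all(vapply(ee2, `[[`, numeric(1), "y") < 1e-6))
  # just above threshold the endemic root sits close to the disease-free one
  p_up <- model_parameters(2.001, 1, 1)
  ee3 <- endemic_equilibria(p_up, builtin_pair("rlad"))
  expect_length(ee3, 1)
  expect_lt(abs(ee3[[1]]$y - (1 - 2 / 2.001)), 1e-10)
})

test_that("the Jacobian matches the analytic matrix", {
  p3 <- model_parameters(3, 1, 1)
  # lower-triangular at any disease-free state
  for (b in c("rlad", "linear_breaking", "asis", "aid")) {
    J <- model_jacobian(c(0, 0.7), p3, builtin_pair(b))
    expect_equal(J[1, 2], 0)
  }
  J_aid <- model_jacobian(c(0, 0), p3, builtin_pair("aid"))
  expect_equal(J_aid, matrix(c(-1, 2, 0, -1), 2, 2))
  ee <- endemic_equilibria(p3, builtin_pair("rlad"))[[1]]
  expect_equal(sort(Re(ee$eigenvalues)), c(-2, -0.5), tolerance = 1e-10)
})

test_that("stability classification covers all planar cases", {
  expect_identical(classify_stability(c(-0.5, -2)), "stable_node")
  expect_identical(classify_stability(complex(real = c(-0.1, -0.1),
                                              imaginary = c(0.5, -0.5))),
                   "stable_spiral")
  expect_identical(classify_stability(c(0.3, 1)), "unstable_node")
  expect_identical(classify_stability(complex(real = c(0.2, 0.2),
                                              imaginary = c(1, -1))),
                   "unstable_spiral")
  expect_identical(classify_stability(c(-1, 2)), "saddle")
  expect_identical(classify_stability(c(-1, 0)), "undetermined")
  expect_identical(classify_stability(c(-1, 5e-9), tol = 1e-8), "undetermined")
})

test_that("next-generation reproduction number and its failure mode", {
  p3 <- model_parameters(3, 1, 1)
  expect_equal(basic_reproduction_number(p3, builtin_pair("rlad")), 1.5)
  expect_equal(basic_reproduction_number(p3, builtin_pair("linear_breaking")), 3)
  expect_equal(basic_reproduction_number(p3, builtin_pair("asis")), 3)
  expect_error(basic_reproduction_number(p3, builtin_pair("aid")),
               "not applicable")
})

test_that("threshold detection recovers the bifurcation point in tau", {
  tmpl <- model_parameters(1, 1, 1)
  thr_aid <- critical_threshold(tmpl, builtin_pair("aid"), c(1, 5))
  expect_equal(thr_aid$tau_star, (3 + 2 * sqrt(2)) / 2, tolerance = 1e-6)
  expect_equal(c(thr_aid$ee_count_below, thr_aid$ee_count_above), c(0, 2))
  thr_lb <- critical_threshold(tmpl, builtin_pair("linear_breaking"),
                               c(0.5, 2))
  expect_equal(thr_lb$tau_star, 1, tolerance = 1e-5)
  thr_rlad <- critical_threshold(tmpl, builtin_pair("rlad"), c(1, 3))
  expect_equal(thr_rlad$tau_star, 2, tolerance = 1e-5)
  expect_error(critical_threshold(tmpl, builtin_pair("linear_breaking"),
                                  c(2, 4)), "no threshold")
})

test_that("an endemic state exists whenever the reproduction number exceeds one", {
  set.seed(31)
  for (b in c("rlad", "linear_breaking", "asis")) {
    pair <- builtin_pair(b)
    found <- 0L
    while (found < 10L) {
      params <- model_parameters(stats::runif(1, 0.5, 8),
                                 stats::runif(1, 0.2, 4),
                                 stats::runif(1, 0.2, 4))
      r0 <- basic_reproduction_number(params, pair)
      if (r0 <= 1 + 1e-6) next
      found <- found + 1L
      expect_gt(length(endemic_equilibria(params, pair)), 0)
    }
  }
})
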