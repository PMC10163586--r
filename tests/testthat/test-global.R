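test_that("Dulac expression: point values and boundary domain", {
  p3 <- model_parameters(3, 1, 1)
  lb <- builtin_pair("linear_breaking")
  expect_equal(dulac_expression(c(0.5, 0.5), p3, lb), -11)
  # second term vanishes where link creation vanishes: aid at any y with
  # f_cr(y) = 0 only at the ends, so use a pair with interior zero
  pz <- response_pair("y", "(y - 0.5)^2 * 0")  # f_cr identically 0
  expect_equal(dulac_expression(c(0.3, 0.7), p3, pz), -3)
  expect_error(dulac_expression(c(0, 0.5), p3, lb), "open square")
})

test_that("the Dulac expression is negative throughout the open square", {
  set.seed(13)
  p <- model_parameters(2.3, 0.8, 1.7)
  for (b in c("rlad", "linear_breaking", "asis", "aid")) {
    rep <- verify_no_limit_cycles(p, builtin_pair(b), grid = c(101L, 101L))
    expect_true(rep$pass, info = b)
    expect_lte(rep$max_value, -p$tau)
  }
  for (i in 1:5) {
    pair <- response_pair(random_poly_response(), random_poly_response())
    expect_true(validate_pair(pair, 101L)$valid)
    rep <- verify_no_limit_cycles(p, pair, grid = c(101L, 101L))
    expect_true(rep$pass)
  }
})

test_that("the 2x2 Lyapunov equation is solved exactly", {
  expect_equal(lyapunov_matrix(-diag(2)), diag(2) / 2)
  P_aid <- lyapunov_matrix(matrix(c(-1, 2, 0, -1), 2, 2))
  expect_equal(P_aid, matrix(c(1.5, 0.5, 0.5, 0.5), 2, 2),
               tolerance = 1e-12)
  set.seed(99)
  for (i in 1:25) {
    A <- matrix(stats::rnorm(4), 2, 2)
    A <- A - (max(Re(eigen(A)$values)) + stats::runif(1, 0.2, 2)) * diag(2)
    P <- lyapunov_matrix(A)
    expect_lte(max(abs(P %*% A + t(A) %*% P + diag(2))), 1e-12)
    expect_gt(P[1, 1], 0)
    expect_gt(det(P), 0)
  }
  expect_error(lyapunov_matrix(matrix(c(1, 0, 0, -1), 2, 2)),
               "stable equilibrium")
})

test_that("the Lyapunov sublevel set is a sound inner basin estimate", {
  params <- model_parameters(3, 1, 1)
  aid <- builtin_pair("aid")
  dfe <- disease_free_equilibrium(params, aid)
  roa <- estimate_region_of_attraction(dfe, params, aid,
                                       grid = c(101L, 101L))
  expect_gt(roa$c_star, 0)
  expect_gt(sum(roa$omega_set), 1)
  expect_lte(max(abs(roa$P %*% dfe$jacobian +
                     t(dfe$jacobian) %*% roa$P + diag(2))), 1e-10)
  # dV/dt < 0 on Omega away from the equilibrium
  at_eq <- outer(abs(roa$grid$y - dfe$y) < 1e-12,
                 abs(roa$grid$z - dfe$z) < 1e-12, `&`)
  expect_true(all(roa$dVdt[roa$omega_set & !at_eq] < 0))
  # soundness: every Omega point flows to the equilibrium
  idx <- which(roa$omega_set, arr.ind = TRUE)
  pts <- cbind(roa$grid$y[idx[, 1]], roa$grid$z[idx[, 2]])
  term <- animfa:::.simulate_batch(params, aid, pts, horizon = 400)
  d <- sqrt((term[, 1] - dfe$y)^2 + (term[, 2] - dfe$z)^2)
  expect_lt(max(d), 1e-6)
})

test_that("the separatrix passes through the interior saddle and divides basins", {
  params <- model_parameters(3, 1, 1)
  aid <- builtin_pair("aid")
  ees <- endemic_equilibria(params, aid)
  saddle <- ees[[which(sapply(ees, `[[`, "stability") == "saddle")]]
  sep <- separatrix(saddle, params, aid)
  expect_identical(sep$method, "shooting")
  d_saddle <- sqrt((sep$points[, 1] - 1 / 3)^2 + (sep$points[, 2] - 1 / 2)^2)
  expect_lt(min(d_saddle), 1e-5)
  # points displaced to either side converge to different attractors
  mid <- sep$points[which.min(abs(sep$points[, 1] - 0.4)), ]
  probe <- rbind(mid + c(0, 1e-3), mid - c(0, 1e-3))
  term <- animfa:::.simulate_batch(params, aid, probe, horizon = 600)
  dfe <- disease_free_equilibrium(params, aid)
  stable_ee <- ees[[which(sapply(ees, `[[`, "stability") == "stable_node")]]
  d_dfe <- sqrt((term[, 1] - dfe$y)^2 + (term[, 2] - dfe$z)^2)
  d_ee <- sqrt((term[, 1] - stable_ee$y)^2 + (term[, 2] - stable_ee$z)^2)
  expect_true(xor(d_dfe[1] < d_ee[1], d_dfe[2] < d_ee[2]))
  # a globally stable endemic state has no separatrix
  lb <- builtin_pair("linear_breaking")
  ee_lb <- endemic_equilibria(params, lb)[[1]]
  expect_error(separatrix(ee_lb, params, lb, method = "shooting"),
               "separatrix undefined")
})

test_that("basin labels identify both attractors of the bistable regime", {
  params <- model_parameters(3, 1, 1)
  aid <- builtin_pair("aid")
  bm <- basin_map(params, aid, grid = c(41L, 41L), horizon = 400)
  lab_at <- function(y0, z0)
    bm$labels[which.min((bm$grid$y0 - y0)^2 + (bm$grid$z0 - z0)^2)]
  expect_identical(lab_at(0.05, 0.10), "dfe")
  lab_up <- lab_at(0.50, 0.90)
  expect_match(lab_up, "^ee_")
  expect_equal(bm$attractors[[lab_up]]$y, 0.5, tolerance = 1e-8)
  expect_gt(sum(bm$labels == "dfe"), 0)
  expect_gt(sum(bm$labels == lab_up), 0)
})

test_that("a unique globally stable state attracts the whole interior", {
  params <- model_parameters(3, 1, 1)
  lb <- builtin_pair("linear_breaking")
  bm <- basin_map(params, lb, grid = c(21L, 21L), horizon = 400)
  interior <- bm$grid$y0 > 0 & bm$grid$y0 < 1
  expect_true(all(bm$labels[interior] == "ee_1"))
})
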