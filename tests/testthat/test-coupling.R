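test_that("under-relaxation blends and converges geometrically", {
  expect_equal(underrelax(2000, 1000, 1), 2000)
  expect_equal(underrelax(2000, 1000, 0.5), 1500)
  expect_error(underrelax(1, 0, 0), "lambda")
  expect_error(underrelax(1, 0, 1.5), "lambda")

  # repeated application approaches a fixed target at rate (1 - lambda)
  lam <- 0.3; x <- 0; target <- 100
  errs <- numeric(20)
  for (k in 1:20) { x <- underrelax(target, x, lam); errs[k] <- abs(target - x) }
  expect_equal(errs[-1] / errs[-20], rep(1 - lam, 19), tolerance = 1e-10)
})

test_that("coupling error reproduces the sum-of-squares convergence check", {
  expect_equal(coupling_error(c(1, 2), c(1, 2)), 0)
  expect_equal(coupling_error(c(10.2, 20.1), c(10, 20)), 0.05)   # converged at 0.1
  expect_equal(coupling_error(7.4, 7.0), 0.16)                   # not converged
  expect_equal(coupling_error(c(3, 4), c(0, 0), metric = "rms"), sqrt(12.5))
  expect_equal(coupling_error(c(3, -4), c(0, 0), metric = "max_abs"), 4)
  expect_error(coupling_error(c(1, 2), 1), "mismatched")
  expect_error(coupling_error(c(a = 1, b = 2), c(a = 1, c = 2)), "mismatched")
})

test_that("coupled linear toy matches the monolithic sparse solve", {
  R_left <- 2e6; R_right <- 1.5e6; R_out <- 5e5
  net <- make_linear_toy(R_left, R_right, R_out)
  R_macro <- c(LPA = 5e7, RPA = 4e7)
  macro <- linear_macro(R_macro)
  Q <- 6e-5
  bcs <- boundary_conditions(0, outlet_pressure = 400)
  cr <- run_coupled(macro, net, Q, posture("zero_g"),
                    config = coupling_config(lambda = 0.5, epsilon = 1e-18,
                                             max_iterations = 200),
                    bcs_template = bcs, law = rigid_law())
  expect_true(cr$converged)

  # monolithic: junction(5) -> macro resistors -> interfaces(1,2) -> lung
  # resistors -> node 3 -> outlet 4; cardiac output injected at the junction
  src <- numeric(5); src[5] <- Q
  P_ref <- dense_network_solve(5, c(5L, 5L, 1L, 2L, 3L), c(1L, 2L, 3L, 3L, 4L),
                               1 / c(R_macro[["LPA"]], R_macro[["RPA"]],
                                     R_left, R_right, R_out),
                               src = src, dirichlet_node = 4L, dirichlet_val = 400)
  expect_equal(unname(cr$interface_pressures[["left"]]), P_ref[1], tolerance = 1e-8)
  expect_equal(unname(cr$interface_pressures[["right"]]), P_ref[2], tolerance = 1e-8)
  expect_equal(unname(cr$interface_flows[["left"]]),
               (P_ref[5] - P_ref[1]) / R_macro[["LPA"]], tolerance = 1e-10)
  # flows across the interface sum to the cardiac output exactly
  expect_equal(sum(cr$interface_flows), Q, tolerance = 1e-14 * Q)
})

test_that("lambda = 1 converges in a few iterations when the macro dominates", {
  net <- make_linear_toy()
  macro <- linear_macro(c(LPA = 1e9, RPA = 1e9))  # loop gain << 1
  cr <- run_coupled(macro, net, 6e-5, posture("zero_g"),
                    config = coupling_config(lambda = 1, epsilon = 0.1),
                    bcs_template = boundary_conditions(0, outlet_pressure = 400),
                    law = rigid_law())
  expect_true(cr$converged)
  expect_lte(cr$iterations, 3)
})

test_that("the converged solution does not depend on lambda", {
  net <- make_linear_toy()
  macro <- linear_macro(c(LPA = 6e7, RPA = 6e7))
  bcs <- boundary_conditions(0, outlet_pressure = 400)
  cr1 <- run_coupled(macro, net, 6e-5, posture("zero_g"),
                     config = coupling_config(lambda = 0.3, epsilon = 1e-8),
                     bcs_template = bcs, law = rigid_law())
  cr2 <- run_coupled(macro, net, 6e-5, posture("zero_g"),
                     config = coupling_config(lambda = 0.7, epsilon = 1e-8),
                     bcs_template = bcs, law = rigid_law())
  expect_true(cr1$converged && cr2$converged)
  expect_lt(max(abs(cr1$interface_pressures - cr2$interface_pressures)), 1e-3)
})

test_that("the interface error trace settles monotonically after a transient", {
  net <- make_linear_toy()
  macro <- linear_macro(c(LPA = 6e7, RPA = 5e7))
  cr <- run_coupled(macro, net, 6e-5, posture("zero_g"),
                    config = coupling_config(lambda = 0.4, epsilon = 1e-12,
                                             max_iterations = 60),
                    bcs_template = boundary_conditions(0, outlet_pressure = 400),
                    law = rigid_law())
  err <- cr$log$error
  if (length(err) > 10) {
    for (k in 6:(length(err) - 5)) {
      expect_lte(min(err[k:(k + 5)]), err[k] * (1 + 1e-9))
    }
  }
  expect_lte(utils::tail(err, 1), 1e-12)
})

test_that("coupling on an anatomic network conserves flow and meets the threshold", {
  net <- small_net()
  macro <- calibrate_macro()
  cr <- run_coupled(macro, net, 4.8 / 6e4, posture("supine"),
                    config = coupling_config(lambda = 0.1),
                    bcs_template = boundary_conditions(0))
  expect_true(cr$converged)
  expect_lte(utils::tail(cr$log$error, 1), 0.1)
  expect_equal(sum(cr$state$acini$flow), 4.8 / 6e4, tolerance = 1e-8)
})
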