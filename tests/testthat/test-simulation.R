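test_that("stiff integrator reproduces analytic solutions", {
  sys <- decay_system(k = 1, x0 = 1)
  traj <- simulate_system(sys, t_end = 1, n_points = 11)
  expect_lt(abs(traj$states[11, 1] - exp(-1)), 1e-6)

  # 2-state linear system against the matrix-exponential oracle
  A <- matrix(c(-2, 1, 0.5, -3), 2, 2)
  sys2 <- linear_system(A, x0 = c(1, -1))
  times <- c(0, 0.3, 0.7, 1.2, 2, 3.5)
  traj2 <- simulate_system(sys2, times = times)
  for (i in seq_along(times)) {
    oracle <- as.numeric(Matrix::expm(A * times[i]) %*% c(1, -1))
    expect_lt(max(abs(traj2$states[i, ] - oracle)) / max(abs(oracle)), 1e-6)
  }
})

test_that("conserved totals drift below integrator tolerance", {
  net <- make_conserved_network(seed = 2, n_species = 6, n_moieties = 2)
  sys <- build_state_space(net, io_spec(
    inputs = list(), output = str2lang(names(net$species)[1])))
  gamma <- left_null_space(stoichiometry_matrix(net))
  traj <- simulate_system(sys, t_end = 10)
  tot <- traj$states %*% t(gamma)
  drift <- apply(tot, 2, function(col) diff(range(col)) / max(abs(col)))
  expect_lt(max(drift), 1e-8)
})

test_that("integration failure is signalled as a blow-up condition", {
  sys <- controlled_system(
    f = function(x) x^2,               # finite-time escape
    h = function(x) x,
    jac = function(x, u = numeric(0)) matrix(2 * x, 1, 1),
    x0 = 1
  )
  expect_error(suppressWarnings(simulate_system(sys, t_end = 10)),
               class = "netreduce_blowup")
})

test_that("steady states are located and polished", {
  # dx/dt = 1 - x
  sys <- controlled_system(
    f = function(x) 1 - x, h = function(x) x,
    jac = function(x, u = numeric(0)) matrix(-1, 1, 1), x0 = 0.2)
  expect_close(find_steady_state(sys), 1, 1e-7)

  net <- ab_network(k1 = 1, k2 = 1, a0 = 2, b0 = 0)
  sysab <- build_state_space(net, io_spec(inputs = list(), output = quote(A)))
  expect_close(find_steady_state(sysab), c(1, 1), 1e-7)
})

test_that("a limit-cycle system reports non-convergence", {
  vdp <- controlled_system(
    f = function(x) c(x[2], (1 - x[1]^2) * x[2] - x[1]),
    h = function(x) x[1],
    jac = function(x, u = numeric(0))
      matrix(c(0, -2 * x[1] * x[2] - 1, 1, 1 - x[1]^2), 2, 2),
    x0 = c(2, 0))
  expect_error(find_steady_state(vdp, t_max = 100),
               class = "netreduce_no_steady_state")
})

test_that("maximal relative error matches hand-computed cases", {
  mk <- function(y) trajectory(times = 0:10, states = matrix(y, 11, 1),
                               outputs = matrix(y, 11, 1))
  expect_equal(max_relative_error(mk(rep(2, 11)), mk(rep(2, 11)))$E, 0)
  expect_equal(max_relative_error(mk(rep(2, 11)), mk(rep(1.9, 11)))$E, 0.05)

  # an output crossing zero has that instant masked, E stays finite
  tt <- seq(-1, 1, length.out = 21)
  ref <- trajectory(times = tt + 2, states = matrix(tt, 21, 1),
                    outputs = matrix(tt, 21, 1))
  cand <- trajectory(times = tt + 2, states = matrix(tt * 1.01, 21, 1),
                     outputs = matrix(tt * 1.01, 21, 1))
  rep <- max_relative_error(ref, cand)
  expect_true(any(rep$guard_mask))
  expect_true(is.finite(rep$E))
  expect_lt(rep$E, 0.011)

  zero <- mk(rep(0, 11))
  expect_error(max_relative_error(zero, zero),
               class = "netreduce_degenerate_output")
})

test_that("E is invariant under common positive output rescaling", {
  set.seed(1)
  y <- runif(11, 0.5, 2); yb <- y * runif(11, 0.9, 1.1)
  mk <- function(v) trajectory(times = 0:10, states = matrix(v, 11, 1),
                               outputs = matrix(v, 11, 1))
  E1 <- max_relative_error(mk(y), mk(yb))$E
  E2 <- max_relative_error(mk(7 * y), mk(7 * yb))$E
  expect_equal(E1, E2, tolerance = 1e-12)
})

test_that("stiffness coefficient uses eigenvalue moduli with zero-mode exclusion", {
  sysd <- linear_system(diag(c(-1, -100)), x0 = c(1, 1))
  expect_equal(stiffness_coefficient(sysd), 100)
  sysi <- linear_system(diag(c(-1, -1, -1)), x0 = c(1, 1, 1))
  expect_equal(stiffness_coefficient(sysi), 1)
  # exact conservation contributes a zero eigenvalue, excluded
  A <- matrix(c(-1, 1, 1, -1), 2, 2)
  expect_equal(stiffness_coefficient(linear_system(A, c(1, 0))), 1)
  zero <- linear_system(matrix(0, 2, 2), c(1, 1))
  expect_error(stiffness_coefficient(zero),
               class = "netreduce_undefined_stiffness")
})

test_that("chi is invariant under diagonal state and uniform time rescaling", {
  set.seed(9)
  for (i in 1:5) {
    A <- matrix(rnorm(16), 4, 4) - diag(4, 4)
    sys <- linear_system(A, x0 = runif(4, 0.5, 1.5))
    chi <- stiffness_coefficient(sys)
    s <- runif(4, 0.2, 5); ts <- runif(1, 0.1, 10)
    scaled <- apply_scaling(sys, list(state_scales = s, time_scale = ts))
    expect_equal(stiffness_coefficient(scaled), chi, tolerance = 1e-8)
  }
})

test_that("simulation is deterministic and exports tidily", {
  sys <- decay_system()
  t1 <- simulate_system(sys, u = 0.3, t_end = 2)
  t2 <- simulate_system(sys, u = 0.3, t_end = 2)
  expect_identical(t1$states, t2$states)
  td <- as_tidy(t1)
  expect_named(td, c("time", "variable", "value"))
  expect_equal(nrow(td), length(t1$times))
})
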