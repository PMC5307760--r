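test_that("scalar empirical Gramians match the Lyapunov closed form", {
  # x' = -x + u, y = x : P = Q = 0.5
  sys <- decay_system(k = 1, x0 = 0)
  des <- perturbation_design(n_sims = 6, n_points = 801, horizon = 12, seed = 2)
  P <- empirical_controllability_gramian(sys, des, x_star = 0)
  Q <- empirical_observability_gramian(sys, des, x_star = 0)
  expect_lt(abs(P[1, 1] / 0.5 - 1), 0.05)
  expect_lt(abs(Q[1, 1] / 0.5 - 1), 0.05)
})

test_that("degenerate channels give zero Gramians", {
  # input disconnected -> P = 0
  sys0 <- controlled_system(
    f = function(x) -x, g = function(x) matrix(0, 1, 1),
    h = function(x) x, jac = function(x, u = 0) matrix(-1, 1, 1),
    x0 = 0, u0 = 0)
  des <- perturbation_design(n_sims = 3, n_points = 101, horizon = 5, seed = 1)
  expect_equal(empirical_controllability_gramian(sys0, des, x_star = 0),
               matrix(0, 1, 1))
  # blind output -> Q = 0
  sysh <- controlled_system(
    f = function(x) -x, g = function(x) matrix(1, 1, 1),
    h = function(x) 0, jac = function(x, u = 0) matrix(-1, 1, 1),
    x0 = 0, u0 = 0)
  expect_close(empirical_observability_gramian(sysh, des, x_star = 0),
               matrix(0, 1, 1), 1e-12)
})

test_that("decoupled subsystems give a diagonal controllability Gramian", {
  A <- diag(c(-1, -2))
  sys <- controlled_system(
    f = function(x) as.numeric(A %*% x),
    g = function(x) matrix(c(1, 0, 0, 1), 2, 2),
    h = function(x) x,
    jac = function(x, u = numeric(2)) A,
    x0 = c(0, 0), u0 = c(0, 0))
  des <- perturbation_design(n_sims = 4, n_points = 401, horizon = 12, seed = 5)
  P <- empirical_controllability_gramian(sys, des, x_star = c(0, 0))
  expect_lt(abs(P[1, 2]), 1e-8 * sum(diag(P)))
})

test_that("Gramian perturbations respect conservation through totals update", {
  fx <- make_phosphorelay(stiff_ratio = 10)
  sys <- build_state_space(fx$network, fx$spec)
  gamma <- left_null_space(stoichiometry_matrix(fx$network))
  cons <- conservation_set(gamma, sys$x0)
  xs <- find_steady_state(sys)
  rr <- eliminate_states(sys, cons, speed_rank(sys, xs))
  red <- rr$system
  xsr <- find_steady_state(red)
  # perturb each reduced coordinate; the rebuilt system's totals must match
  # the perturbed full-state initial condition, and stay conserved along the
  # perturbed trajectory
  for (j in seq_len(red$n)) {
    delta <- 0.4 * netreduce:::unit_vec(red$n, j)
    pert <- netreduce:::perturbed_initial(red, xsr, delta)
    x_full0 <- red$lift(xsr + delta)
    traj <- simulate_system(pert$system, x0 = pert$x0, t_end = 3, n_points = 31)
    fulls <- t(apply(traj$states, 1, function(z) pert$system$lift(z)))
    tots <- fulls %*% t(gamma)
    expect_close(tots[1, ], as.numeric(gamma %*% x_full0), 1e-9)
    expect_lt(max(apply(tots, 2, function(cl) diff(range(cl)))), 1e-7)
  }
})

test_that("balancing transform equalises and diagonalises the Gramians", {
  # scalar: single Hankel value sqrt(PQ)
  bt1 <- balancing_transform(matrix(2), matrix(8))
  expect_equal(bt1$hankel, 4)
  # already balanced: T1, S1 are identity up to sign
  S <- diag(c(3, 2, 1))
  bt2 <- balancing_transform(S, S)
  expect_close(abs(bt2$T1), diag(1, 3), 1e-10)
  expect_close(bt2$T1 %*% S %*% t(bt2$T1), S, 1e-10)
  # random SPD pair: both transformed Gramians equal diag(hankel)
  set.seed(12)
  M1 <- crossprod(matrix(rnorm(16), 4)); M2 <- crossprod(matrix(rnorm(16), 4))
  bt3 <- balancing_transform(M1, M2)
  D <- diag(bt3$hankel, 4)
  expect_close(bt3$T1 %*% M1 %*% t(bt3$T1), D, 1e-6 * max(bt3$hankel))
  expect_close(t(bt3$S1) %*% M2 %*% bt3$S1, D, 1e-6 * max(bt3$hankel))
  expect_close(bt3$T1 %*% bt3$S1, diag(1, 4), 1e-8)
  expect_true(all(diff(bt3$hankel) <= 1e-12))
})

test_that("rank-deficient requests name the feasible dimension", {
  P <- diag(c(1, 1, 0))   # rank 2 against full-rank Q
  err <- expect_error(balancing_transform(P, diag(1, 3), n_red = 3),
                      class = "netreduce_rank_error")
  expect_match(conditionMessage(err), "2")
})

test_that("full-rank truncation is the identity reduction", {
  fx <- make_lti(seed = 21, n = 3)
  des <- perturbation_design(n_sims = 5, n_points = 401, seed = 9)
  P <- empirical_controllability_gramian(fx$system, des, x_star = numeric(3))
  Q <- empirical_observability_gramian(fx$system, des, x_star = numeric(3))
  bt <- balancing_transform(P, Q)
  tsys <- truncate_balanced(fx$system, bt)
  proto <- error_protocol(u = 1, t_end = 10, n_points = 101,
                          from_steady_state = FALSE)
  t1 <- netreduce:::simulate_protocol(fx$system, proto)
  t2 <- netreduce:::simulate_protocol(tsys, proto)
  expect_lt(max(abs(t1$outputs - t2$outputs)), 1e-8)
})

test_that("Hankel spectrum is invariant under diagonal state rescaling", {
  fx <- make_lti(seed = 31, n = 3)
  des <- perturbation_design(n_sims = 5, n_points = 601, horizon = 15, seed = 4)
  P1 <- empirical_controllability_gramian(fx$system, des, x_star = numeric(3))
  Q1 <- empirical_observability_gramian(fx$system, des, x_star = numeric(3))
  h1 <- balancing_transform(P1, Q1)$hankel
  scaled <- apply_scaling(fx$system,
                          list(state_scales = c(0.5, 2, 3), time_scale = 1))
  P2 <- empirical_controllability_gramian(scaled, des, x_star = numeric(3))
  Q2 <- empirical_observability_gramian(scaled, des, x_star = numeric(3))
  h2 <- balancing_transform(P2, Q2)$hankel
  expect_close(h2 / h1, rep(1, 3), 1e-4)
})

test_that("importance indices rescale Gramian diagonals to a unit maximum", {
  idx <- importance_indices(diag(c(1, 1)), diag(c(4, 1)))
  expect_equal(idx$observability, c(1, 0.5))
  expect_equal(max(idx$controllability), 1)
  expect_equal(max(idx$input_output), 1)
  # a state dead in both Gramians scores zero everywhere
  idx2 <- importance_indices(diag(c(1, 0)), diag(c(1, 0)),
                             labels = c("a", "b"))
  expect_equal(unlist(idx2[2, -1], use.names = FALSE), c(0, 0, 0))
  expect_error(importance_indices(matrix(0, 2, 2), matrix(0, 2, 2)),
               class = "netreduce_undefined_index")
})
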