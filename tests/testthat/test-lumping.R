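test_that("identity projection reproduces the dynamics", {
  fx <- make_phosphorelay(stiff_ratio = 10)
  sys <- build_state_space(fx$network, fx$spec)
  idsys <- galerkin_reduce(sys, diag(1, 6), diag(1, 6))
  t1 <- simulate_system(sys, t_end = 3, n_points = 31)
  t2 <- simulate_system(idsys, t_end = 3, n_points = 31)
  expect_lt(max(abs(t1$states - t2$states)), 1e-10)
})

test_that("an exchange-symmetric linear block lumps with zero output error", {
  # columns of the (1,2) block sum to the same value, so s = x1 + x2 obeys
  # a closed scalar equation and the lump is exact
  A <- matrix(c(-2, 1, 0,
                1, -2, 0.5,
                0.5, 0.5, -1.5), 3, 3, byrow = TRUE)
  sys <- linear_system(A, x0 = c(1, 0.2, 0.4), C = matrix(c(1, 1, 1), 1, 3))
  L <- pair_lump_matrix(3, 1, 2)
  red <- galerkin_reduce(sys, L, moore_penrose_inverse(L))
  proto <- error_protocol(u = 0, t_end = 4, n_points = 101,
                          from_steady_state = FALSE)
  E <- max_relative_error(simulate_protocol(sys, proto),
                          simulate_protocol(red, proto))$E
  expect_lt(E, 1e-6)
})

test_that("generalised inverses evaluate to their closed forms", {
  L <- matrix(c(1, 1), 1, 2)
  expect_equal(moore_penrose_inverse(L), matrix(c(0.5, 0.5), 2, 1))
  expect_equal(moore_penrose_inverse(diag(1, 3)), diag(1, 3))
  L4 <- matrix(1, 1, 4)
  expect_true(all(moore_penrose_inverse(L4) == 0.25))

  expect_equal(steady_state_inverse(L, c(1, 3)), matrix(c(0.25, 0.75), 2, 1))
  expect_error(steady_state_inverse(L, c(0, 0)),
               class = "netreduce_singular_inverse")
  # an unlumped species keeps weight exactly 1
  L2 <- pair_lump_matrix(3, 1, 2)
  Lb <- steady_state_inverse(L2, c(1, 3, 5))
  expect_equal(Lb[3, 2], 1)
  expect_equal(Lb[1:2, 1], c(0.25, 0.75))
})

test_that("averaged inverse integrates the pair proportions", {
  tt <- seq(0, 4, length.out = 201)
  mk <- function(x1, x2) trajectory(times = tt, states = cbind(x1, x2),
                                    outputs = matrix(x1 + x2, ncol = 1))
  # x_h = 2 x_k at all times -> weights (2/3, 1/3)
  tr <- mk(2 * exp(-tt), exp(-tt))
  Lb <- averaged_inverse(matrix(c(1, 1), 1, 2), tr)
  expect_close(Lb[, 1], c(2 / 3, 1 / 3), 1e-9)
  # symmetric pair -> (1/2, 1/2)
  Lb2 <- averaged_inverse(matrix(c(1, 1), 1, 2), mk(exp(-tt), exp(-tt)))
  expect_close(Lb2[, 1], c(0.5, 0.5), 1e-12)
  # identically-zero pair total is degenerate
  expect_error(averaged_inverse(matrix(c(1, 1), 1, 2), mk(0 * tt, 0 * tt)),
               class = "netreduce_degenerate_pair")
})

test_that("averaged inverse approaches the steady-state inverse as T grows", {
  # linear relaxation to a nonzero steady state (2, 6)
  A <- diag(c(-3, -3))
  xs <- c(2, 6)
  sys <- controlled_system(
    f = function(x) A %*% (x - xs), h = function(x) sum(x),
    jac = function(x, u = numeric(0)) A, x0 = c(5, 1))
  tr <- simulate_system(sys, t_end = 40, n_points = 801)
  Lb_avg <- averaged_inverse(matrix(c(1, 1), 1, 2), tr, T_end = 40)
  Lb_ss <- steady_state_inverse(matrix(c(1, 1), 1, 2), xs)
  expect_lt(max(abs(Lb_avg - Lb_ss)), 0.05)
  # and closer still with a longer averaging window
  tr2 <- simulate_system(sys, t_end = 400, n_points = 4001)
  Lb_avg2 <- averaged_inverse(matrix(c(1, 1), 1, 2), tr2, T_end = 400)
  expect_lt(max(abs(Lb_avg2 - Lb_ss)), max(abs(Lb_avg - Lb_ss)))
})

test_that("pairwise lumps compose into larger lumps", {
  outer <- lumping_scheme(matrix(c(1, 1, 0, 0, 0, 1), 2, 3, byrow = TRUE),
                          moore_penrose_inverse(matrix(c(1, 1, 0, 0, 0, 1),
                                                       2, 3, byrow = TRUE)))
  inner_L <- matrix(c(1, 1, 0, 0,
                      0, 0, 1, 0,
                      0, 0, 0, 1), 3, 4, byrow = TRUE)
  inner <- lumping_scheme(inner_L, moore_penrose_inverse(inner_L))
  comp <- compose_lumpings(outer, inner)
  expect_equal(unname(comp$L),
               matrix(c(1, 1, 1, 0, 0, 0, 0, 1), 2, 4, byrow = TRUE))
  expect_close(comp$L %*% comp$L_bar, diag(1, 2), 1e-12)
  # composing with identity leaves the scheme unchanged
  id <- lumping_scheme(diag(1, 3), diag(1, 3))
  expect_equal(compose_lumpings(id, inner)$L, inner$L)
})

test_that("proper-lumping structure is enforced and preserved", {
  expect_error(lumping_scheme(matrix(c(1, 1, 1, 0), 2, 2), diag(1, 2)),
               class = "netreduce_invalid_argument")
  # column orthogonality after composition
  L1 <- pair_lump_matrix(4, 1, 2)
  s1 <- lumping_scheme(L1, moore_penrose_inverse(L1))
  L2 <- pair_lump_matrix(3, 1, 3)
  s2 <- compose_lumpings(lumping_scheme(L2, moore_penrose_inverse(L2)), s1)
  expect_true(all(colSums(s2$L) <= 1))
  expect_true(all(s2$L %in% c(0, 1)))
})

phospho_reduced <- function(stiff_ratio = 1000) {
  fx <- make_phosphorelay(stiff_ratio = stiff_ratio)
  sys <- build_state_space(fx$network, fx$spec)
  gamma <- left_null_space(stoichiometry_matrix(fx$network))
  cons <- conservation_set(gamma, sys$x0)
  xs <- find_steady_state(sys)
  rr <- eliminate_states(sys, cons, speed_rank(sys, xs))
  list(fx = fx, sys = sys, rr = rr, xs = xs)
}

test_that("forward selection with a zero error budget returns the identity", {
  pr <- phospho_reduced(100)
  scheme <- forward_selection_lump(pr$rr$system, pr$fx$protocol,
                                   max_error = 1e-12, chi_c = 2)
  expect_equal(scheme$n_red, scheme$n)
  expect_equal(length(scheme$history), 0L)
})

test_that("the greedy step picks the brute-force (pair, inverse) minimiser", {
  pr <- phospho_reduced(1000)
  red <- pr$rr$system
  xsr <- pr$xs[pr$rr$retained]
  proto <- pr$fx$protocol
  reference <- netreduce:::simulate_protocol(pr$sys, proto)

  # independent brute force over all pairs and both inverses
  nn <- red$n
  unpert <- simulate_system(red, t_end = proto$t_end, n_points = 200)
  best <- NULL
  for (h in seq_len(nn - 1)) for (k in (h + 1):nn) {
    Lp <- pair_lump_matrix(nn, h, k)
    for (inv in c("steady-state", "averaged")) {
      Lb <- tryCatch(
        if (inv == "steady-state") steady_state_inverse(Lp, xsr)
        else averaged_inverse(Lp, unpert),
        error = function(e) NULL)
      if (is.null(Lb)) next
      E <- tryCatch({
        cand <- galerkin_reduce(red, Lp, Lb)
        max_relative_error(reference,
                           netreduce:::simulate_protocol(cand, proto))$E
      }, error = function(e) Inf)
      if (is.null(best) || E < best$E) best <- list(h = h, k = k, inv = inv, E = E)
    }
  }

  scheme <- forward_selection_lump(red, proto, max_error = 0.05, chi_c = 250,
                                   reference = reference, x_star = xsr)
  expect_gte(length(scheme$history), 1L)
  step1 <- scheme$history[[1]]
  expect_equal(c(step1$h, step1$k), c(best$h, best$k))
  expect_equal(step1$E, best$E, tolerance = 1e-6)
  # the designated fast-equilibrating pair is the minimiser
  expect_setequal(red$state_names[c(best$h, best$k)], pr$fx$fast_pair)
  expect_lt(best$E, 0.01)
})

test_that("lumping strips stiffness on the phosphorelay fixture", {
  pr <- phospho_reduced(1000)
  chi0 <- stiffness_coefficient(pr$rr$system)
  scheme <- forward_selection_lump(
    pr$rr$system, pr$fx$protocol, max_error = 0.05, chi_c = 250,
    reference = netreduce:::simulate_protocol(pr$sys, pr$fx$protocol),
    x_star = pr$xs[pr$rr$retained])
  steps <- attr(scheme, "per_step")
  expect_gte(nrow(steps), 1L)
  # chi non-increasing across the accepted lumping steps (observed tendency
  # on this fixture, not a theorem)
  expect_true(all(diff(c(chi0, steps$chi)) <= 1e-6))
  expect_lt(steps$chi[nrow(steps)], 250)
})

test_that("the Moore-Penrose inverse is never better than the best of the others", {
  pr <- phospho_reduced(1000)
  red <- pr$rr$system
  xsr <- pr$xs[pr$rr$retained]
  proto <- pr$fx$protocol
  reference <- netreduce:::simulate_protocol(pr$sys, proto)
  unpert <- simulate_system(red, t_end = proto$t_end, n_points = 200)
  nn <- red$n
  for (h in seq_len(nn - 1)) for (k in (h + 1):nn) {
    Lp <- pair_lump_matrix(nn, h, k)
    score <- function(Lb) tryCatch({
      cand <- galerkin_reduce(red, Lp, Lb)
      max_relative_error(reference, netreduce:::simulate_protocol(cand, proto))$E
    }, error = function(e) Inf)
    E_mp <- score(moore_penrose_inverse(Lp))
    E_ss <- tryCatch(score(steady_state_inverse(Lp, xsr)), error = function(e) Inf)
    E_av <- score(averaged_inverse(Lp, unpert))
    expect_gte(E_mp + 1e-9, min(E_ss, E_av))
  }
})
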