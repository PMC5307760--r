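minimal_sbml <- function() {
  net <- reaction_network(
    species = c(A = 1, B = 0),
    reactions = list(reaction(c(A = 1L), c(B = 1L), quote(k * A))),
    parameters = c(k = 2)
  )
  write_sbml(net)
}

test_that("minimal SBML ingests as an identity mapping", {
  net <- read_sbml(minimal_sbml())
  expect_length(net$species, 2L)
  expect_length(net$reactions, 1L)
  expect_length(net$parameters, 1L)
  expect_identical(names(net$species), c("A", "B"))
  expect_equal(unname(net$species), c(1, 0))
  expect_equal(unname(net$parameters[["k"]]), 2)
})

test_that("malformed and unsupported SBML raise classed errors", {
  expect_error(read_sbml("<sbml><model"), class = "netreduce_parse_error")
  txt <- paste(minimal_sbml())
  # reaction without a kinetic law
  txt_nokl <- gsub("(?s)<kineticLaw>.*?</kineticLaw>", "", txt, perl = TRUE)
  expect_error(read_sbml(txt_nokl), class = "netreduce_unsupported_feature")
  # events are outside the ODE core
  txt_ev <- sub("<listOfReactions>",
                "<listOfEvents><event id=\"e\"/></listOfEvents><listOfReactions>",
                txt)
  err <- expect_error(read_sbml(txt_ev), class = "netreduce_unsupported_feature")
  expect_match(conditionMessage(err), "event")
})

test_that("stoichiometry matrix has net-production columns in reaction order", {
  net <- reaction_network(
    species = c(A = 1, B = 0),
    reactions = list(reaction(c(A = 1L), c(B = 1L), quote(k * A))),
    parameters = c(k = 1)
  )
  expect_equal(unname(stoichiometry_matrix(net)), matrix(c(-1L, 1L), 2, 1))

  # reversible binding as one net column, product release as the second
  enz <- reaction_network(
    species = c(E = 1, S = 2, C = 0, P = 0),
    reactions = list(
      reaction(c(E = 1L, S = 1L), c(C = 1L), quote(kon * E * S - koff * C)),
      reaction(c(C = 1L), c(E = 1L, P = 1L), quote(kcat * C))
    ),
    parameters = c(kon = 1, koff = 1, kcat = 1)
  )
  N <- stoichiometry_matrix(enz)
  expect_equal(unname(N), cbind(c(-1L, -1L, 1L, 0L), c(1L, 0L, -1L, 1L)))

  empty <- reaction_network(species = c(A = 1), reactions = list())
  expect_equal(dim(stoichiometry_matrix(empty)), c(1L, 0L))
})

test_that("build_state_space splits dynamics and input channels", {
  # dx/dt = -k x + u, h = x
  net <- reaction_network(
    species = c(x = 1),
    reactions = list(reaction(c(x = 1L), stats::setNames(integer(0), character(0)),
                              quote(k * x))),
    parameters = c(k = 3)
  )
  sys <- build_state_space(net, io_spec(
    inputs = list(list(id = "x", mode = "additive-rate")), output = quote(x)))
  expect_equal(sys$f(2), -6)
  expect_equal(as.numeric(sys$g(2)), 1)
  expect_equal(sys$h(5), 5)
  expect_equal(sys$u0, 0)

  # parameter-scale input: u = 1 reproduces the original model
  fx <- make_phosphorelay(stiff_ratio = 10)
  sysp <- build_state_space(fx$network, fx$spec)
  expect_equal(sysp$u0, 1)
  x <- fx$network$species * 1.1
  rhs_full <- sysp$f(x) + as.numeric(sysp$g(x))
  # direct evaluation of the network fluxes
  N <- stoichiometry_matrix(fx$network)
  env <- as.list(c(fx$network$parameters, x))
  v <- vapply(fx$network$reactions, function(rx) eval(rx$rate, env), numeric(1))
  expect_close(rhs_full, as.numeric(N %*% v), 1e-12)

  expect_error(
    build_state_space(fx$network, io_spec(inputs = "nosuch", output = quote(Yp))),
    class = "netreduce_invalid_iospec")
})

test_that("nonlinear dependence on an input parameter is rejected", {
  net <- reaction_network(
    species = c(A = 1, B = 0),
    reactions = list(reaction(c(A = 1L), c(B = 1L), quote(k^2 * A))),
    parameters = c(k = 2)
  )
  expect_error(
    build_state_space(net, io_spec(
      inputs = list(list(id = "k", mode = "parameter-scale")),
      output = quote(B))),
    class = "netreduce_affine_error")
})

test_that("symbolic Jacobian agrees with finite differences at random states", {
  fx <- make_phosphorelay(stiff_ratio = 10)
  sys <- build_state_space(fx$network, fx$spec)
  set.seed(42)
  for (i in seq_len(20)) {
    x <- stats::runif(sys$n, 0.05, 2)
    J <- sys$jac(x, sys$u0)
    Jfd <- netreduce:::num_jacobian(function(z) {
      sys$f(z) + as.numeric(sys$g(z)) * sys$u0
    }, x)
    expect_lt(max(abs(J - Jfd)) / max(abs(Jfd)), 1e-4)
  }
})

test_that("closed mass-action dynamics annihilate the conserved weights", {
  net <- make_conserved_network(seed = 5, n_species = 6, n_moieties = 2)
  sys <- build_state_space(net, io_spec(
    inputs = list(), output = str2lang(names(net$species)[1])))
  gamma <- left_null_space(stoichiometry_matrix(net))
  set.seed(7)
  for (i in 1:5) {
    x <- stats::runif(sys$n, 0.1, 2)
    expect_close(as.numeric(gamma %*% sys$f(x)), 0, 1e-10)
  }
})
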