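#' Score a nondimensionalised parameter set
#'
#' The order-of-magnitude spread \eqn{\sigma =
#' \log_{10}(\max \tilde p / \min \tilde p)} of a positive dimensionless
#' parameter set; 0 iff all entries are equal. Candidate
#' nondimensionalisations are ranked by this score and the minimiser is
#' applied, which narrows the numeric range the integrator has to handle.
#'
#' @param scaled_parameters positive numeric vector of dimensionless
#'   parameters.
#' @return sigma >= 0.
#' @export
score_scaling <- function(scaled_parameters) {
  p <- as.numeric(scaled_parameters)
  assert_that(length(p) > 0 && all(is.finite(p)) && all(p > 0),
              "netreduce_domain_error",
              "scaled parameters must be positive and finite")
  log10(max(p) / min(p))
}

#' Propose candidate nondimensionalisations
#'
#' Samples `n_candidates` scalings of a reaction network. Each candidate
#' draws its time scale as the reciprocal of one sampled rate constant
#' (first-order, or pseudo-first-order by combining with a reference
#' concentration for higher-order mass-action constants) and one global
#' concentration scale from the pool of positive initial concentrations,
#' conserved totals and the maximum initial value. The concentration
#' scale is shared by all species: a species-specific scale would turn a
#' downstream proper lumping (a plain sum of concentrations) into a
#' weighted sum and so change which states are accurately lumpable,
#' whereas a common unit leaves every downstream reduction step
#' invariant and only affects floating-point conditioning.
#' Dimensionless parameters are formed as
#' \eqn{\tilde p = p\,t_s\,c^{m-1}} where m is the reactant order of the
#' reaction the parameter appears in (parameters not attached to a
#' single mass-action reaction are treated as first-order rates).
#'
#' @param network a [reaction_network()].
#' @param n_candidates number of candidates (default 50).
#' @param seed integer seed; the candidate list is reproducible.
#' @return list of `scaling` objects, each with `state_scales` (named,
#'   positive), `time_scale` (positive), `scaled_parameters` and `sigma`.
#' @export
propose_scalings <- function(network, n_candidates = 50L, seed = 1L) {
  set.seed(seed)
  x0 <- network$species
  pars <- network$parameters
  n <- length(x0)
  # parameter -> reactant order of the reactions it appears in
  orders <- parameter_orders(network)
  gamma <- left_null_space(stoichiometry_matrix(network))
  totals <- if (nrow(gamma)) as.numeric(gamma %*% x0) else numeric(0)
  glob <- max(x0, 0)
  have_conc <- glob > 0
  if (!have_conc) {
    warnf("no positive concentration scale available; falling back to unit scales")
  }
  lapply(seq_len(n_candidates), function(i) {
    # time scale from one sampled (pseudo-)first-order rate
    if (length(pars)) {
      k_idx <- sample.int(length(pars), 1L)
      k <- pars[[k_idx]]
      m <- orders[[names(pars)[k_idx]]] %||% 1
      cref <- if (have_conc) glob else 1
      rate1 <- k * cref^(m - 1)      # pseudo-first-order composite
      ts <- 1 / max(rate1, .Machine$double.eps)
    } else ts <- 1
    cpool <- c(x0[x0 > 0], totals[totals > 0], glob)
    cscale <- if (have_conc) cpool[[sample.int(length(cpool), 1L)]] else 1
    ss <- stats::setNames(rep(cscale, n), names(x0))
    ptilde <- scaled_parameter_set(pars, orders, ts, cscale)
    sc <- structure(list(state_scales = ss, time_scale = ts,
                         scaled_parameters = ptilde),
                    class = "scaling")
    sc$sigma <- if (length(ptilde)) score_scaling(ptilde) else 0
    sc
  })
}

parameter_orders <- function(network) {
  orders <- list()
  for (rx in network$reactions) {
    m <- sum(rx$reactants)
    for (p in intersect(all_symbols(rx$rate), names(network$parameters))) {
      orders[[p]] <- max(orders[[p]] %||% 0, m)
    }
  }
  orders
}

scaled_parameter_set <- function(pars, orders, ts, cscale) {
  if (!length(pars)) return(numeric(0))
  vapply(names(pars), function(p) {
    m <- orders[[p]] %||% 1
    pars[[p]] * ts * cscale^(m - 1)
  }, numeric(1))
}

#' Select the best of the proposed scalings
#'
#' @param candidates list from [propose_scalings()].
#' @return the candidate with the smallest sigma (first on ties).
#' @export
best_scaling <- function(candidates) {
  sigmas <- vapply(candidates, `[[`, numeric(1), "sigma")
  candidates[[which.min(sigmas)]]
}

#' Apply a nondimensionalisation to a system
#'
#' Rescales states by `state_scales` and time by `time_scale`:
#' \eqn{\tilde x = x / s}, \eqn{\tau = t / t_s}, giving \eqn{d\tilde
#' x/d\tau = t_s\,D^{-1} f(D \tilde x)} (D = diag(s)) and likewise for
#' each input channel. The output map is left in original concentration
#' units (`h(D x~)`), so output trajectories mapped back to original time
#' reproduce the unscaled simulation exactly; only the numerical
#' conditioning changes.
#'
#' @param system a [controlled_system()].
#' @param scaling a `scaling` (from [propose_scalings()]), or a list with
#'   `state_scales` and `time_scale`.
#' @return a [controlled_system()] in dimensionless variables, with the
#'   scaling stored in attribute `"scaling"`.
#' @export
apply_scaling <- function(system, scaling) {
  s <- as.numeric(scaling$state_scales)
  ts <- scaling$time_scale
  assert_that(length(s) == system$n && all(s > 0) && ts > 0,
              "netreduce_invalid_argument", "invalid scaling for this system")
  n <- system$n
  f_s <- function(z) ts * system$f(s * z) / s
  g_s <- function(z) ts * as_matrix(system$g(s * z), n) / s
  h_s <- function(z) system$h(s * z)
  jac_s <- function(z, u = system$u0)
    ts * (system$jac(s * z, u) * rep(1 / s, times = n)) * rep(s, each = n)
  out <- controlled_system(
    f = f_s, g = g_s, h = h_s, jac = jac_s,
    x0 = system$x0 / s, u0 = system$u0,
    state_names = system$state_names, output_names = system$output_names,
    lift = function(z) system$lift(s * z),
    from_full = function(x_full) apply_scaling(system$from_full(x_full), scaling)
  )
  attr(out, "scaling") <- scaling
  out
}

#' Map a trajectory of a scaled system back to original units
#'
#' @param traj a `trajectory` simulated from [apply_scaling()] output.
#' @param scaling the scaling that produced the system.
#' @return a `trajectory` in original time/concentration units.
#' @export
unscale_trajectory <- function(traj, scaling) {
  s <- as.numeric(scaling$state_scales)
  trajectory(times = traj$times * scaling$time_scale,
             states = sweep(traj$states, 2L, s, `*`),
             outputs = traj$outputs,
             state_names = traj$state_names,
             output_names = traj$output_names)
}
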