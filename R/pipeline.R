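#' Error-scoring protocol
#'
#' Defines the perturbation experiment under which original and reduced
#' models are compared: an input signal (constant vector or function of
#' time, e.g. a step introduced at t = 0), a simulation horizon and the
#' comparison grid. The same protocol is used to score lumping candidates
#' and to validate final reductions.
#'
#' @param u input: numeric vector (held constant) or function(t).
#' @param t_end horizon; `NULL` lets callers substitute a settle time.
#' @param n_points comparison grid size (default 200).
#' @param grid `"linear"` or `"log"` spacing.
#' @param from_steady_state if `TRUE` (default) each system is started at
#'   its own unperturbed steady state, so the protocol measures the
#'   response to the input perturbation alone (the adapted-state
#'   experiment); `FALSE` starts from the declared initial condition.
#' @return object of class `error_protocol`.
#' @export
error_protocol <- function(u, t_end = NULL, n_points = 200L, grid = "linear",
                           from_steady_state = TRUE) {
  structure(list(u = u, t_end = t_end, n_points = as.integer(n_points),
                 grid = match.arg(grid, c("linear", "log")),
                 from_steady_state = isTRUE(from_steady_state)),
            class = "error_protocol")
}

protocol_times <- function(protocol) {
  t_end <- protocol$t_end
  if (protocol$grid == "log") {
    c(0, exp(seq(log(t_end / 1e3), log(t_end), length.out = protocol$n_points - 1L)))
  } else {
    seq(0, t_end, length.out = protocol$n_points)
  }
}

simulate_protocol <- function(system, protocol, x0 = NULL) {
  if (is.null(x0) && isTRUE(protocol$from_steady_state)) {
    x0 <- find_steady_state(system)
  }
  simulate_system(system, u = protocol$u, x0 = x0,
                  times = protocol_times(protocol))
}

# Rescale a protocol's horizon into a scaled system's time unit.
scale_protocol <- function(protocol, time_scale) {
  protocol$t_end <- protocol$t_end / time_scale
  protocol
}

#' Reduction configuration
#'
#' @param max_error maximum tolerated maximal relative error (fraction,
#'   default 0.05 i.e. 5%).
#' @param chi_c critical stiffness coefficient ending the lumping stage
#'   (default 250).
#' @param n_nondim_candidates candidate nondimensionalisations sampled
#'   (default 50); 0 disables the nondimensionalisation stage.
#' @param design a [perturbation_design()] for the Gramian stage.
#' @param seed integer seed for all sampling.
#' @param rtol,atol solver tolerances.
#' @return object of class `reduction_config`.
#' @export
reduction_config <- function(max_error = 0.05, chi_c = 250,
                             n_nondim_candidates = 50L,
                             design = NULL, seed = 1L,
                             rtol = 1e-8, atol = 1e-10) {
  assert_that(max_error > 0 && max_error < 1, "netreduce_invalid_argument",
              "max_error must be a fraction in (0, 1)")
  assert_that(chi_c > 1, "netreduce_invalid_argument", "chi_c must exceed 1")
  structure(list(max_error = max_error, chi_c = chi_c,
                 n_nondim_candidates = as.integer(n_nondim_candidates),
                 design = design, seed = as.integer(seed),
                 rtol = rtol, atol = atol),
            class = "reduction_config")
}

#' Run the combined model reduction algorithm
#'
#' Orchestrates the full reduction of a controlled reaction network:
#' \enumerate{
#'   \item build the control-affine state space from the network and the
#'     input/output declaration;
#'   \item sample candidate nondimensionalisations, apply the one with the
#'     smallest order-of-magnitude spread;
#'   \item find conserved moieties (Householder QR of the stoichiometry
#'     matrix), speed-rank states at the unperturbed steady state and
#'     eliminate the slowest species per relation;
#'   \item forward-selection proper lumping - trialling the steady-state
#'     and averaged inverses per pair - until the error budget would be
#'     violated, the stiffness coefficient falls below `chi_c`, or one
#'     state remains;
#'   \item empirical Gramians for the lumped system, Laub balancing, and
#'     truncation scanning every reduced dimension downward, keeping the
#'     smallest that meets the error budget (Hankel ordering does not
#'     guarantee monotone error for nonlinear systems).
#' }
#' If the Gramian stage fails (the stiffness failure mode balanced
#' truncation is sensitive to), the best lumped model is returned with a
#' diagnostic - graceful degradation, not an error.
#'
#' @param network a [reaction_network()].
#' @param spec an [io_spec()].
#' @param protocol an [error_protocol()]; its `u` is the validation
#'   perturbation and `t_end` the comparison horizon (in the network's
#'   original time unit).
#' @param config a [reduction_config()].
#' @return object of class `reduction_report`; see Details.
#' @export
run_combined_reduction <- function(network, spec, protocol,
                                   config = reduction_config()) {
  t_start <- proc.time()[["elapsed"]]
  stages <- list()
  push_stage <- function(stage, dim, E = NA_real_, chi = NA_real_) {
    stages[[length(stages) + 1L]] <<-
      data.frame(stage = stage, dim = dim, E = E, chi = chi,
                 elapsed = proc.time()[["elapsed"]] - t_start)
  }

  system0 <- build_state_space(network, spec)
  push_stage("import", system0$n)

  # -- nondimensionalisation ------------------------------------------------
  scaling <- NULL
  system <- system0
  proto <- protocol
  if (config$n_nondim_candidates > 0L && length(network$parameters)) {
    cands <- propose_scalings(network, config$n_nondim_candidates,
                              seed = config$seed)
    scaling <- best_scaling(cands)
    system <- apply_scaling(system0, scaling)
    proto <- scale_protocol(protocol, scaling$time_scale)
    push_stage("nondimensionalise", system$n)
  }

  # -- conservation analysis ------------------------------------------------
  gamma <- left_null_space(stoichiometry_matrix(network))
  if (!is.null(scaling)) {
    # relation gamma.x = const becomes (gamma D).x~ = const in scaled states
    gamma_s <- gamma %*% diag(as.numeric(scaling$state_scales), system$n)
  } else gamma_s <- gamma
  cons <- conservation_set(gamma_s, system$x0)
  x_star <- find_steady_state(system)
  ranking <- speed_rank(system, x_star)
  realisation <- eliminate_states(system, cons, ranking)
  red <- realisation$system
  chi0 <- tryCatch(stiffness_coefficient(red),
                   netreduce_undefined_stiffness = function(e) NA_real_)
  push_stage("conservation", red$n, E = 0, chi = chi0)

  # reference: the full (scaled) model under the protocol
  reference <- simulate_protocol(system, proto)
  x_star_red <- x_star[realisation$retained]

  # -- forward-selection lumping -------------------------------------------
  scheme <- forward_selection_lump(red, proto,
                                   max_error = config$max_error,
                                   chi_c = config$chi_c,
                                   reference = reference,
                                   x_star = x_star_red)
  lumped <- if (scheme$n_red < scheme$n) {
    galerkin_reduce(red, scheme$L, scheme$L_bar)
  } else red
  per_step <- attr(scheme, "per_step")
  if (!is.null(per_step) && nrow(per_step)) {
    for (i in seq_len(nrow(per_step))) {
      push_stage("lump", per_step$dim[i], E = per_step$E[i],
                 chi = per_step$chi[i])
    }
  }
  lump_E <- if (!is.null(per_step) && nrow(per_step))
    per_step$E[nrow(per_step)] else 0
  chi_lumped <- tryCatch(stiffness_coefficient(lumped),
                         netreduce_undefined_stiffness = function(e) NA_real_)

  # -- empirical balanced truncation ---------------------------------------
  design <- config$design %||% perturbation_design(seed = config$seed)
  best <- list(system = lumped, dim = lumped$n, E = lump_E,
               method = if (scheme$n_red < scheme$n) "lump" else "conservation")
  gram <- tryCatch({
    xs_l <- find_steady_state(lumped, x_guess = as.numeric(scheme$L %*% x_star_red))
    P <- empirical_controllability_gramian(lumped, design, x_star = xs_l)
    Q <- empirical_observability_gramian(lumped, design, x_star = xs_l)
    list(P = P, Q = Q, x_star = xs_l)
  }, netreduce_gramian_failure = function(e) e,
     netreduce_no_steady_state = function(e) e)
  transform <- NULL
  indices <- NULL
  truncation_log <- NULL
  if (!inherits(gram, "error")) {
    indices <- tryCatch(
      importance_indices(gram$P, gram$Q, labels = lumped$state_names),
      netreduce_undefined_index = function(e) NULL)
    transform <- tryCatch(balancing_transform(gram$P, gram$Q),
                          netreduce_error = function(e) NULL)
  }
  if (!is.null(transform)) {
    # try every reduced dimension; keep the smallest meeting the budget
    for (nr in rev(seq_len(max(transform$n_red - 1L, 0L)))) {
      res <- tryCatch({
        trunc_sys <- truncate_balanced(lumped, transform, n_red = nr,
                                       x_center = gram$x_star)
        traj <- simulate_protocol(trunc_sys, proto)
        list(E = max_relative_error(reference, traj)$E, system = trunc_sys)
      }, netreduce_blowup = function(e) list(E = Inf, system = NULL),
         netreduce_no_steady_state = function(e) list(E = Inf, system = NULL),
         netreduce_degenerate_output = function(e) list(E = Inf, system = NULL),
         netreduce_invalid_system = function(e) list(E = Inf, system = NULL))
      push_stage("truncate", nr, E = res$E)
      truncation_log <- rbind(truncation_log,
                              data.frame(dim = nr, E = res$E))
      if (is.finite(res$E) && res$E <= config$max_error && nr < best$dim) {
        best <- list(system = res$system, dim = nr, E = res$E,
                     method = "truncate")
      }
    }
  }

  structure(list(
    stages = do.call(rbind, stages),
    final = best,
    scaling = scaling,
    conservation = list(gamma = gamma, set = cons,
                        eliminated = realisation$eliminated,
                        retained = realisation$retained,
                        chi = chi0),
    lumping = list(scheme = scheme, per_step = per_step,
                   chi = chi_lumped, system = lumped),
    gramians = if (!inherits(gram, "error")) gram else NULL,
    gramian_failure = if (inherits(gram, "error")) conditionMessage(gram) else NULL,
    balancing = transform,
    truncation = truncation_log,
    indices = indices,
    config = config,
    protocol = protocol,
    reference = reference,
    network = network,
    system_scaled = system,
    realisation = realisation
  ), class = "reduction_report")
}

#' @export
print.reduction_report <- function(x, ...) {
  cat("<reduction_report>\n")
  cat(sprintf("  final model: %d states via %s, E = %.3g%% (budget %.3g%%)\n",
              x$final$dim, x$final$method, 100 * x$final$E,
              100 * x$config$max_error))
  if (!is.null(x$gramian_failure)) {
    cat("  truncation stage degraded:", x$gramian_failure, "\n")
  }
  cat(sprintf("  stages: %s\n",
              paste(sprintf("%s(%d)", x$stages$stage, x$stages$dim),
                    collapse = " -> ")))
  invisible(x)
}

#' Validate a reduction against the original model
#'
#' Simulates both systems under a shared protocol and returns the
#' maximal-relative-error report. A blow-up of the candidate is reported
#' as an infeasible reduction (`E = Inf`, `feasible = FALSE`), not an
#' error.
#'
#' @param original,reduced [controlled_system()] objects sharing the
#'   output dimension.
#' @param protocol an [error_protocol()] with a set horizon.
#' @return an `error_report` with an extra `feasible` flag.
#' @export
validate_reduction <- function(original, reduced, protocol) {
  reference <- simulate_protocol(original, protocol)
  res <- tryCatch({
    traj <- simulate_protocol(reduced, protocol)
    max_relative_error(reference, traj)
  }, netreduce_blowup = function(e) {
    structure(list(E = Inf, pointwise = NULL,
                   guard_mask = NULL, delta = NA_real_,
                   failure = conditionMessage(e)),
              class = "error_report")
  }, netreduce_no_steady_state = function(e) {
    structure(list(E = Inf, pointwise = NULL,
                   guard_mask = NULL, delta = NA_real_,
                   failure = conditionMessage(e)),
              class = "error_report")
  })
  res$feasible <- is.finite(res$E)
  res
}
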