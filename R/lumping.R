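#' Galerkin projection of a controlled system
#'
#' Builds the reduced dynamics for a projection pair (L, L_bar) with
#' `L %*% L_bar = I`: \eqn{\tilde f(\tilde x) = L f(\bar L \tilde x)},
#' \eqn{\tilde g_i = L g_i(\bar L \tilde x)}, \eqn{\tilde h = h(\bar L
#' \tilde x)}, \eqn{\tilde x_0 = L x_0}. The same construction serves
#' proper lumping (0/1 L with a generalised lumping inverse) and balanced
#' truncation (real T1, S1); the Jacobian follows by the chain rule, so the
#' reduced system keeps an analytic Jacobian.
#'
#' @param system a [controlled_system()] of dimension n.
#' @param L projection matrix (n_red x n).
#' @param L_bar right inverse (n x n_red), `L %*% L_bar = I`.
#' @param state_names optional names for the reduced states.
#' @param center optional projection centre c: the reduction is applied to
#'   deviation variables, \eqn{\tilde x = L (x - c)}, lifted as \eqn{x
#'   \approx c + \bar L \tilde x}. Lumping uses c = 0 (lumped states stay
#'   sums of concentrations); balanced truncation centres on the
#'   unperturbed steady state, which keeps it an exact fixed point of the
#'   reduced dynamics.
#' @return a [controlled_system()] of dimension `nrow(L)`.
#' @export
galerkin_reduce <- function(system, L, L_bar, state_names = NULL,
                            center = NULL) {
  L <- as.matrix(L); L_bar <- as.matrix(L_bar)
  n <- system$n
  cen <- if (is.null(center)) numeric(n) else as.numeric(center)
  assert_that(length(cen) == n, "netreduce_invalid_argument",
              "center must have the system's dimension")
  assert_that(ncol(L) == n && nrow(L_bar) == n && nrow(L) == ncol(L_bar),
              "netreduce_invalid_argument", "projection dimensions mismatch")
  assert_that(max(abs(L %*% L_bar - diag(nrow(L)))) < 1e-8,
              "netreduce_invalid_argument", "L %%*%% L_bar must equal identity")
  state_names <- state_names %||% lump_names(L, system$state_names)
  up <- function(z) cen + as.numeric(L_bar %*% z)
  f_r <- function(z) as.numeric(L %*% system$f(up(z)))
  g_r <- function(z) L %*% as_matrix(system$g(up(z)), n)
  h_r <- function(z) system$h(up(z))
  jac_r <- function(z, u = system$u0) L %*% system$jac(up(z), u) %*% L_bar
  controlled_system(
    f = f_r, g = g_r, h = h_r, jac = jac_r,
    x0 = as.numeric(L %*% (system$x0 - cen)), u0 = system$u0,
    state_names = state_names, output_names = system$output_names,
    lift = function(z) system$lift(up(z)),
    from_full = function(x_full)
      galerkin_reduce(system$from_full(x_full), L, L_bar, state_names,
                      center = center)
  )
}

lump_names <- function(L, names_in) {
  if (is.null(names_in)) return(NULL)
  vapply(seq_len(nrow(L)), function(i) {
    members <- names_in[abs(L[i, ] - 1) < 1e-12 & abs(L[i, ]) > 0.5]
    if (length(members) && length(members) == sum(L[i, ] != 0)) {
      paste(members, collapse = "+")
    } else sprintf("z%d", i)
  }, character(1))
}

#' Pairwise proper-lumping matrix
#'
#' The (n-1) x n 0/1 matrix that sums states h and k (h < k) into one
#' lumped variable (placed at row h) and keeps all other states.
#'
#' @param n current dimension.
#' @param h,k indices of the pair to lump (`h < k`).
#' @return 0/1 matrix of dimension (n-1) x n.
#' @export
pair_lump_matrix <- function(n, h, k) {
  assert_that(h < k && k <= n, "netreduce_invalid_argument",
              "need h < k <= n")
  L <- matrix(0, n - 1L, n)
  keep <- setdiff(seq_len(n), k)
  L[cbind(seq_len(n - 1L), keep)] <- 1
  L[h, k] <- 1
  L
}

#' Generalised lumping inverses
#'
#' Three right inverses of a proper lumping matrix L, trading accuracy
#' against singularity risk:
#' \describe{
#'   \item{Moore-Penrose}{`L^+ = t(L) solve(L t(L))`; equal weights
#'     1/(block size) within each lumped block.}
#'   \item{steady-state}{`X t(L) solve(L X t(L))` with `X = diag(x_star)`;
#'     within-block weights proportional to the unperturbed steady state,
#'     so the lifted reduced steady state reproduces the full one. Fails
#'     with a singularity when a whole block has zero steady state.}
#'   \item{averaged}{for a pairwise lump, weights are the time-averaged
#'     proportions \eqn{w_h = (1/T)\int_0^T x_h/(x_h+x_k)\,dt} over an
#'     unperturbed trajectory approaching equilibrium; reduces to the
#'     steady-state inverse as T grows when the pair's steady state is
#'     nonzero, while avoiding its singularity when it is zero.}
#' }
#'
#' @param L proper lumping matrix.
#' @return n x n_red right-inverse matrix.
#' @export
moore_penrose_inverse <- function(L) {
  L <- as.matrix(L)
  t(L) %*% solve(L %*% t(L))
}

#' @rdname moore_penrose_inverse
#' @param x_star unperturbed steady state of the unlumped system.
#' @export
steady_state_inverse <- function(L, x_star) {
  L <- as.matrix(L)
  block_mass <- as.numeric(L %*% x_star)
  if (any(abs(block_mass) < 1e-12 * max(abs(x_star), 1))) {
    stopf("netreduce_singular_inverse",
          "a lumped block has zero steady-state mass; the steady-state inverse is singular (use the averaged or Moore-Penrose inverse)")
  }
  X <- diag(as.numeric(x_star), length(x_star))
  X %*% t(L) %*% solve(L %*% X %*% t(L))
}

#' @rdname moore_penrose_inverse
#' @param L_pair pairwise lumping matrix from [pair_lump_matrix()].
#' @param traj an unperturbed `trajectory` of the unlumped system
#'   reaching (near) steady state.
#' @param T_end upper quadrature limit (defaults to the trajectory end).
#' @param guard relative floor on the pair sum below which time points are
#'   excluded from the quadrature.
#' @export
averaged_inverse <- function(L_pair, traj, T_end = NULL, guard = 1e-9) {
  L_pair <- as.matrix(L_pair)
  n <- ncol(L_pair)
  pair_row <- which(rowSums(L_pair != 0) == 2L)
  assert_that(length(pair_row) == 1L, "netreduce_invalid_argument",
              "L_pair must lump exactly one pair of states")
  hk <- which(L_pair[pair_row, ] != 0)
  h <- hk[1]; k <- hk[2]
  T_end <- T_end %||% max(traj$times)
  sel <- traj$times <= T_end + 1e-12
  tt <- traj$times[sel]
  xh <- traj$states[sel, h]; xk <- traj$states[sel, k]
  s <- xh + xk
  ok <- abs(s) > guard * max(abs(s), .Machine$double.eps)
  if (!any(ok)) {
    stopf("netreduce_degenerate_pair",
          "lumped pair has identically zero total on [0, T]; averaged inverse undefined")
  }
  # quadrature over the included points only, normalised by the included span
  w_h <- trapz(tt[ok], (xh / s)[ok]) / max(diff(range(tt[ok])), .Machine$double.eps)
  if (sum(ok) == 1L) w_h <- (xh / s)[ok]
  w_h <- min(max(w_h, 0), 1)
  L_bar <- moore_penrose_inverse(L_pair)
  L_bar[h, pair_row] <- w_h
  L_bar[k, pair_row] <- 1 - w_h
  L_bar
}

#' Compose sequential lumpings
#'
#' Any proper lumping can be expressed as a chain of pairwise lumps; this
#' composes an outer (pairwise) scheme applied on top of an inner scheme:
#' `L = L_outer %*% L_inner`, `L_bar = L_bar_inner %*% L_bar_outer`, which
#' preserves `L %*% L_bar = I`.
#'
#' @param outer,inner `lumping_scheme` objects (outer operates on the
#'   inner's reduced coordinates).
#' @return a `lumping_scheme`.
#' @export
compose_lumpings <- function(outer, inner) {
  assert_that(ncol(outer$L) == nrow(inner$L), "netreduce_invalid_argument",
              "lumping dimensions do not chain")
  lumping_scheme(L = outer$L %*% inner$L,
                 L_bar = inner$L_bar %*% outer$L_bar,
                 history = c(inner$history, outer$history))
}

#' @rdname compose_lumpings
#' @param L,L_bar projection and right inverse.
#' @param history list of per-step records.
#' @export
lumping_scheme <- function(L, L_bar, history = list()) {
  L <- as.matrix(L); L_bar <- as.matrix(L_bar)
  assert_that(max(abs(L %*% L_bar - diag(nrow(L)))) < 1e-8,
              "netreduce_invalid_argument", "L %%*%% L_bar must equal identity")
  assert_that(all(L %in% c(0, 1)) && all(colSums(L) <= 1) && all(rowSums(L) >= 1),
              "netreduce_invalid_argument",
              "L is not a proper lumping matrix (0/1, orthogonal columns)")
  structure(list(L = L, L_bar = L_bar, n = ncol(L), n_red = nrow(L),
                 history = history),
            class = "lumping_scheme")
}

#' @export
print.lumping_scheme <- function(x, ...) {
  cat(sprintf("<lumping_scheme> %d -> %d states, %d pairwise steps\n",
              x$n, x$n_red, length(x$history)))
  invisible(x)
}

identity_scheme <- function(n) lumping_scheme(diag(1, n), diag(1, n))

#' Forward-selection proper lumping
#'
#' Greedy pairwise lumping: at each step every unordered pair of current
#' states is tried with both the steady-state and the averaged lumping
#' inverse; each candidate reduced model is simulated under the error
#' protocol and scored by the maximal relative output error E against the
#' reference trajectory; the minimising (pair, inverse) is applied. Ties
#' prefer the candidate with lower resulting stiffness, then lexicographic
#' pair order. The loop exits when the best candidate would exceed
#' `max_error`, when the stiffness coefficient falls below `chi_c`, or at
#' one remaining state. Candidates whose simulation blows up score E =
#' infinity (infeasible), not an error.
#'
#' @param system a [controlled_system()] (typically the
#'   conservation-eliminated realisation).
#' @param protocol an [error_protocol()] defining the perturbation input
#'   and horizon used for scoring.
#' @param max_error maximum tolerated maximal relative error (fraction;
#'   default 0.05).
#' @param chi_c critical stiffness coefficient below which lumping stops
#'   (default 250).
#' @param reference optional reference `trajectory` (defaults to the
#'   protocol simulation of `system` itself).
#' @param x_star unperturbed steady state (located if omitted).
#' @param inverses which generalised inverses to trial per candidate.
#' @return a `lumping_scheme` whose `history` records, per accepted step,
#'   the pair, the inverse chosen, E and the stiffness coefficient; the
#'   attribute `per_step` carries the same as a data.frame.
#' @export
forward_selection_lump <- function(system, protocol,
                                   max_error = 0.05, chi_c = 250,
                                   reference = NULL, x_star = NULL,
                                   inverses = c("steady-state", "averaged")) {
  n <- system$n
  scheme <- identity_scheme(n)
  if (max_error <= 0 || n == 1L) return(scheme)
  reference <- reference %||% simulate_protocol(system, protocol)
  x_star <- x_star %||% tryCatch(find_steady_state(system),
                                 netreduce_no_steady_state = function(e) system$x0)
  current <- system
  cur_xstar <- x_star
  per_step <- list()
  repeat {
    nn <- current$n
    if (nn == 1L) break
    chi_now <- tryCatch(stiffness_coefficient(current),
                        netreduce_undefined_stiffness = function(e) Inf)
    if (chi_now < chi_c) break
    cand <- best_pair_candidate(system, current, scheme, protocol, reference,
                                cur_xstar, inverses)
    if (is.null(cand) || cand$E > max_error) break
    scheme <- cand$scheme
    current <- cand$system
    guess <- as.numeric(cand$pair_L %*% cur_xstar)
    cur_xstar <- tryCatch(find_steady_state(current, x_guess = guess),
                          netreduce_error = function(e) guess)
    chi <- tryCatch(stiffness_coefficient(current),
                    netreduce_undefined_stiffness = function(e) NA_real_)
    per_step[[length(per_step) + 1L]] <-
      data.frame(dim = current$n, pair_h = cand$h, pair_k = cand$k,
                 inverse = cand$inverse, E = cand$E, chi = chi)
    scheme$history[[length(scheme$history) + 1L]] <-
      list(h = cand$h, k = cand$k, inverse = cand$inverse,
           E = cand$E, chi = chi)
    if (!is.na(chi) && chi < chi_c) break
  }
  attr(scheme, "per_step") <- if (length(per_step)) do.call(rbind, per_step) else
    data.frame(dim = integer(0), pair_h = integer(0), pair_k = integer(0),
               inverse = character(0), E = numeric(0), chi = numeric(0))
  scheme
}

# Evaluate all (pair, inverse) candidates for one greedy step; returns the
# minimiser or NULL if all blew up.
best_pair_candidate <- function(base_system, current, scheme, protocol,
                                reference, cur_xstar, inverses) {
  nn <- current$n
  unpert <- tryCatch(
    simulate_system(current, t_end = protocol$t_end,
                    n_points = protocol$n_points),
    netreduce_blowup = function(e) NULL
  )
  best <- NULL
  for (h in seq_len(nn - 1L)) {
    for (k in (h + 1L):nn) {
      Lp <- pair_lump_matrix(nn, h, k)
      for (inv in inverses) {
        L_bar_p <- tryCatch(switch(
          inv,
          "steady-state" = steady_state_inverse(Lp, cur_xstar),
          "averaged" = if (is.null(unpert)) NULL else
            averaged_inverse(Lp, unpert),
          "moore-penrose" = moore_penrose_inverse(Lp)
        ), netreduce_error = function(e) NULL)
        if (is.null(L_bar_p)) next
        cand_scheme <- tryCatch(
          compose_lumpings(lumping_scheme(Lp, L_bar_p), scheme),
          netreduce_error = function(e) NULL)
        if (is.null(cand_scheme)) next
        red <- tryCatch(
          galerkin_reduce(base_system, cand_scheme$L, cand_scheme$L_bar),
          netreduce_error = function(e) NULL)
        if (is.null(red)) next
        E <- tryCatch({
          traj <- simulate_protocol(red, protocol)
          max_relative_error(reference, traj)$E
        }, netreduce_blowup = function(e) Inf,
           netreduce_no_steady_state = function(e) Inf,
           netreduce_degenerate_output = function(e) Inf)
        if (!is.finite(E)) next
        chi <- tryCatch(stiffness_coefficient(red),
                        error = function(e) Inf)
        better <- is.null(best) || E < best$E - 1e-15 ||
          (abs(E - best$E) <= 1e-15 && chi < best$chi)
        if (better) {
          best <- list(E = E, chi = chi, h = h, k = k, inverse = inv,
                       scheme = cand_scheme, system = red, pair_L = Lp)
        }
      }
    }
  }
  best
}
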