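#' Left null space of a stoichiometry matrix
#'
#' Computes an integer basis of the left null space of the stoichiometry
#' matrix N, i.e. the conserved-moiety relations \eqn{\Gamma N = 0}. The
#' rank decision uses a Householder QR factorisation (base R's LAPACK QR)
#' of N: rows of Q beyond the numerical rank annihilate N. The raw
#' orthonormal basis is brought to row-reduced form and rescaled to
#' smallest-integer coefficients when the entries are rational to within
#' 1e-9, so relations read as moiety totals (e.g. E + C, S + C + P).
#'
#' @param N stoichiometry matrix (n species x r reactions).
#' @param rank_tol relative tolerance on the QR diagonal for the rank
#'   decision.
#' @return a c x n matrix `gamma` (possibly 0 rows) with
#'   `rownames` NULL and `colnames` from N.
#' @export
left_null_space <- function(N, rank_tol = 1e-9) {
  N <- as.matrix(N)
  n <- nrow(N)
  if (ncol(N) == 0L) {
    gamma <- diag(1, n)
    colnames(gamma) <- rownames(N)
    return(gamma)
  }
  qrN <- qr(N)
  d <- abs(diag(qr.R(qrN)))
  rank <- if (!length(d) || max(d) == 0) 0L else sum(d > rank_tol * max(d))
  c_dim <- n - rank
  if (c_dim == 0L) {
    gamma <- matrix(0, 0, n, dimnames = list(NULL, rownames(N)))
    return(gamma)
  }
  Q <- qr.Q(qrN, complete = TRUE)
  gamma <- t(Q[, (rank + 1L):n, drop = FALSE])
  gamma <- rref_rows(gamma, tol = 1e-10)
  gamma <- t(apply(gamma, 1L, integerise))
  if (c_dim == 1L) gamma <- matrix(gamma, nrow = 1L)
  # sanity: must annihilate N
  assert_that(max(abs(gamma %*% N)) < 1e-8 * max(1, max(abs(N))),
              "netreduce_internal", "left null space residual too large")
  colnames(gamma) <- rownames(N)
  unname_rows(gamma)
}

# Gauss-Jordan row reduction (partial pivoting) of a full-row-rank matrix;
# yields rational entries for rational subspaces.
rref_rows <- function(M, tol = 1e-10) {
  M <- as.matrix(M)
  r <- nrow(M); n <- ncol(M)
  lead <- 1L
  for (i in seq_len(r)) {
    while (lead <= n) {
      piv <- which.max(abs(M[i:r, lead])) + i - 1L
      if (abs(M[piv, lead]) > tol) break
      lead <- lead + 1L
    }
    if (lead > n) break
    if (piv != i) M[c(i, piv), ] <- M[c(piv, i), ]
    M[i, ] <- M[i, ] / M[i, lead]
    for (k in seq_len(r)) {
      if (k != i && abs(M[k, lead]) > tol) M[k, ] <- M[k, ] - M[k, lead] * M[i, ]
    }
    lead <- lead + 1L
  }
  M
}

unname_rows <- function(M) { rownames(M) <- NULL; M }

#' Conservation set of a network realisation
#'
#' Bundles the conserved-moiety matrix with the totals implied by an
#' initial condition. Totals are recorded as the map `gamma %*% x0` rather
#' than frozen numbers, so downstream perturbations of the initial
#' condition (as in the empirical observability Gramian) update them
#' consistently.
#'
#' @param gamma c x n left-null matrix from [left_null_space()].
#' @param x0 initial condition of the full realisation.
#' @return object of class `conservation_set`.
#' @export
conservation_set <- function(gamma, x0) {
  gamma <- as.matrix(gamma)
  structure(list(gamma = gamma, totals = as.numeric(gamma %*% x0), x0 = x0),
            class = "conservation_set")
}

#' @export
print.conservation_set <- function(x, ...) {
  cat(sprintf("<conservation_set> %d relations over %d species\n",
              nrow(x$gamma), ncol(x$gamma)))
  invisible(x)
}

#' Speed-rank state variables
#'
#' Orders state variables from slow to fast using the absolute diagonal
#' entries of the Jacobian at the unperturbed steady state - the outgoing
#' rate of concentration from each state, a cheap proxy for each
#' variable's intrinsic time scale. Slow variables are the preferred
#' targets for algebraic elimination via conservation relations, keeping
#' the fast (readily lumpable) variables available for lumping.
#'
#' @param system a [controlled_system()].
#' @param x_star unperturbed steady state; if `NULL`, an attempt is made to
#'   locate it, falling back to `x0` with a warning when that fails.
#' @return integer permutation of `1:n`, slowest first; ties keep
#'   declaration order.
#' @export
speed_rank <- function(system, x_star = NULL) {
  if (is.null(x_star)) {
    x_star <- tryCatch(find_steady_state(system),
                       netreduce_no_steady_state = function(e) {
                         warnf("steady state unavailable; speed-ranking at x0")
                         system$x0
                       })
  }
  dj <- abs(diag(system$jac(x_star, system$u0)))
  order(dj, seq_along(dj))   # ascending |J_ii|, ties by declaration order
}

#' Eliminate conserved state variables
#'
#' Produces the simplified realisation of the system in which one species
#' per conservation relation is replaced by its algebraic expression in
#' the conserved total and the retained species. Relations are processed
#' most-constrained first (fewest candidate species), and each is
#' assigned the slowest not-yet-eliminated species with a nonzero
#' coefficient such that the c x c submatrix of gamma on the eliminated
#' set stays invertible. The reduced system reproduces the full
#' trajectory exactly (up to integration tolerance) and carries a
#' `from_full` hook that recomputes totals from any perturbed full
#' initial condition.
#'
#' @param system a [controlled_system()] of dimension n.
#' @param conservation a [conservation_set()] valid for `system`'s
#'   coordinates.
#' @param ranking slow-to-fast ordering from [speed_rank()]; defaults to
#'   declaration order (naive elimination).
#' @return object of class `reduced_realisation`: list with `system` (the
#'   (n-c)-dimensional [controlled_system()]), `eliminated`, `retained`
#'   (index vectors), `reconstruct(x_r)` (affine lift to full
#'   coordinates), and `conservation`.
#' @export
eliminate_states <- function(system, conservation, ranking = NULL) {
  gamma <- conservation$gamma
  c_dim <- nrow(gamma)
  n <- system$n
  assert_that(ncol(gamma) == n, "netreduce_invalid_argument",
              "conservation set does not match system dimension")
  if (c_dim == 0L) {
    return(structure(list(system = system, eliminated = integer(0),
                          retained = seq_len(n),
                          reconstruct = function(x_r) x_r,
                          conservation = conservation),
                     class = "reduced_realisation"))
  }
  ranking <- ranking %||% seq_len(n)
  slowness <- match(seq_len(n), ranking)   # position in slow->fast order

  # most-constrained relation first; greedy slowest feasible species
  rel_order <- order(rowSums(gamma != 0))
  eliminated <- integer(0)
  for (rel in rel_order) {
    cand <- setdiff(which(gamma[rel, ] != 0), eliminated)
    cand <- cand[order(slowness[cand])]
    chosen <- NA_integer_
    for (s in cand) {
      trial <- c(eliminated, s)
      # the growing eliminated submatrix (relations processed so far) must
      # stay invertible for the algebraic substitution to be well-posed
      sub <- gamma[rel_order[seq_along(trial)], trial, drop = FALSE]
      if (qr(sub)$rank == length(trial)) { chosen <- s; break }
    }
    if (is.na(chosen)) {
      stopf("netreduce_elimination_infeasible",
            "no admissible species to eliminate for conservation relation %d", rel)
    }
    eliminated <- c(eliminated, chosen)
  }
  retained <- setdiff(seq_len(n), eliminated)
  Ge <- gamma[, eliminated, drop = FALSE]
  assert_that(qr(Ge)$rank == c_dim, "netreduce_elimination_infeasible",
              "eliminated submatrix of gamma is singular")
  Gr <- gamma[, retained, drop = FALSE]
  Ge_inv <- solve(Ge)
  build_reduced(system, conservation, eliminated, retained, Ge_inv, Gr)
}

build_reduced <- function(system, conservation, eliminated, retained,
                          Ge_inv, Gr) {
  n <- system$n
  totals <- conservation$totals
  lift_full <- function(x_r) {
    x <- numeric(n)
    x[retained] <- x_r
    x[eliminated] <- as.numeric(Ge_inv %*% (totals - Gr %*% x_r))
    x
  }
  # d(full)/d(x_r): identity on retained rows, -Ge^{-1} Gr on eliminated rows
  M <- matrix(0, n, length(retained))
  M[cbind(retained, seq_along(retained))] <- 1
  M[eliminated, ] <- -Ge_inv %*% Gr
  f_r <- function(x_r) system$f(lift_full(x_r))[retained]
  g_r <- function(x_r) as_matrix(system$g(lift_full(x_r)), n)[retained, , drop = FALSE]
  h_r <- function(x_r) system$h(lift_full(x_r))
  jac_r <- function(x_r, u = system$u0) {
    (system$jac(lift_full(x_r), u)[retained, , drop = FALSE]) %*% M
  }
  red_sys <- controlled_system(
    f = f_r, g = g_r, h = h_r, jac = jac_r,
    x0 = system$x0[retained], u0 = system$u0,
    state_names = system$state_names[retained],
    output_names = system$output_names,
    lift = function(x_r) system$lift(lift_full(x_r)),
    from_full = function(x_full) {
      parent2 <- system$from_full(x_full)
      cons2 <- conservation_set(conservation$gamma, parent2$x0)
      rr <- build_reduced(parent2, cons2, eliminated, retained, Ge_inv, Gr)
      rr$system
    }
  )
  structure(list(system = red_sys, eliminated = eliminated,
                 retained = retained, reconstruct = lift_full,
                 conservation = conservation),
            class = "reduced_realisation")
}

#' @export
print.reduced_realisation <- function(x, ...) {
  cat(sprintf("<reduced_realisation> %d -> %d states (eliminated: %s)\n",
              length(x$retained) + length(x$eliminated), length(x$retained),
              paste(x$eliminated, collapse = ", ")))
  invisible(x)
}

#' Conservation relations as a table
#'
#' @param conservation a [conservation_set()].
#' @param species optional species names.
#' @return data.frame with one row per (relation, species) nonzero
#'   coefficient plus the conserved total.
#' @export
conservation_table <- function(conservation, species = NULL) {
  gamma <- conservation$gamma
  species <- species %||% colnames(gamma) %||% paste0("x", seq_len(ncol(gamma)))
  out <- do.call(rbind, lapply(seq_len(nrow(gamma)), function(i) {
    nz <- which(gamma[i, ] != 0)
    data.frame(relation = i, species = species[nz],
               coefficient = gamma[i, nz],
               total = conservation$totals[i])
  }))
  out %||% data.frame(relation = integer(0), species = character(0),
                      coefficient = numeric(0), total = numeric(0))
}
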