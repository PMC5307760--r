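#' Random stable LTI fixture with analytic Gramians
#'
#' Generates a stable linear time-invariant system \eqn{\dot x = Ax + Bu},
#' \eqn{y = Cx} with all eigenvalues of A shifted left of
#' `-stability_margin`, and attaches the analytic controllability and
#' observability Gramians (solutions of \eqn{AP + PA' + BB' = 0} and
#' \eqn{A'Q + QA + C'C = 0}, solved exactly by a Kronecker-product linear
#' solve) plus the Hankel singular values \eqn{\sqrt{eig(PQ)}}. These are
#' the independent oracles for the empirical-Gramian and
#' balanced-truncation stages.
#'
#' @param seed integer seed (fixture is seed-deterministic).
#' @param n state dimension.
#' @param stability_margin minimum decay rate of the slowest mode.
#' @param n_inputs,n_outputs channel counts.
#' @return list with `A`, `B`, `C`, `system` (a [controlled_system()]),
#'   `analytic_P`, `analytic_Q`, `hankel`.
#' @export
make_lti <- function(seed = 1L, n = 4L, stability_margin = 0.5,
                     n_inputs = 1L, n_outputs = 1L) {
  set.seed(seed)
  A <- matrix(stats::rnorm(n * n), n, n)
  shift <- max(Re(eigen(A, only.values = TRUE)$values)) + stability_margin
  A <- A - diag(shift, n)
  B <- matrix(stats::rnorm(n * n_inputs), n, n_inputs)
  C <- matrix(stats::rnorm(n_outputs * n), n_outputs, n)
  P <- solve_lyapunov(A, B %*% t(B))
  Q <- solve_lyapunov(t(A), t(C) %*% C)
  hankel <- sort(sqrt(pmax(Re(eigen(P %*% Q, only.values = TRUE)$values), 0)),
                 decreasing = TRUE)
  sys <- controlled_system(
    f = function(x) as.numeric(A %*% x),
    g = function(x) B,
    h = function(x) as.numeric(C %*% x),
    jac = function(x, u = numeric(n_inputs)) A,
    x0 = numeric(n), u0 = numeric(n_inputs)
  )
  list(A = A, B = B, C = C, system = sys,
       analytic_P = P, analytic_Q = Q, hankel = hankel)
}

#' Solve the continuous Lyapunov equation A X + X A' + W = 0
#'
#' Direct Kronecker-product solve; exact up to linear-solve round-off,
#' intended for small oracle systems.
#'
#' @param A stable square matrix.
#' @param W symmetric right-hand side.
#' @return symmetric solution X.
#' @export
solve_lyapunov <- function(A, W) {
  n <- nrow(A)
  M <- kronecker(diag(1, n), A) + kronecker(A, diag(1, n))
  X <- matrix(solve(M, -as.vector(W)), n, n)
  (X + t(X)) / 2
}

#' Random closed mass-action network with known conserved moieties
#'
#' Assembles a closed network from modification motifs: species are
#' partitioned into `n_moieties` groups, each group forming a reversible
#' conversion chain (so each group's total is conserved), with
#' enzyme-style cross-group catalysis coupling the dynamics without
#' adding or removing mass. The left null space of the stoichiometry
#' matrix has dimension exactly `n_moieties` by construction, which is
#' verified internally (the network is resampled under fresh sub-seeds
#' if round-off ever breaks the rank condition).
#'
#' @param seed integer seed.
#' @param n_species total species count.
#' @param n_moieties number of conserved groups (< n_species).
#' @return a [reaction_network()] with attribute `"moieties"` (the list
#'   of species index groups).
#' @export
make_conserved_network <- function(seed = 1L, n_species = 6L, n_moieties = 2L) {
  assert_that(n_moieties < n_species && n_moieties >= 1L,
              "netreduce_generation_error",
              "need n_moieties < n_species")
  for (attempt in seq_len(20L)) {
    set.seed(seed + 1000L * (attempt - 1L))
    sizes <- rep(n_species %/% n_moieties, n_moieties)
    extra <- n_species %% n_moieties
    if (extra) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    groups <- split(seq_len(n_species), rep(seq_len(n_moieties), sizes))
    sp_names <- unlist(lapply(seq_len(n_moieties), function(g)
      paste0("S", g, "_", seq_len(sizes[g]))))
    x0 <- stats::runif(n_species, 0.5, 2)
    names(x0) <- sp_names
    reactions <- list()
    pars <- numeric(0)
    add_par <- function(name) {
      val <- exp(stats::runif(1, log(0.1), log(10)))
      pars[[name]] <<- val
      name
    }
    for (g in seq_len(n_moieties)) {
      ids <- groups[[g]]
      if (length(ids) < 2L) next
      for (i in seq_len(length(ids) - 1L)) {
        a <- sp_names[ids[i]]; b <- sp_names[ids[i + 1L]]
        kf <- add_par(sprintf("kf%d_%d", g, i))
        kr <- add_par(sprintf("kr%d_%d", g, i))
        reactions <- c(reactions, list(
          reaction(stats::setNames(1L, a), stats::setNames(1L, b),
                   str2lang(sprintf("%s * %s", kf, a))),
          reaction(stats::setNames(1L, b), stats::setNames(1L, a),
                   str2lang(sprintf("%s * %s", kr, b)))
        ))
      }
      if (g >= 2L && length(ids) >= 2L) {
        # first species of the previous group catalyses this group's first
        # conversion: mass-conserving in both groups
        enz <- sp_names[groups[[g - 1L]][1L]]
        a <- sp_names[ids[1L]]; b <- sp_names[ids[2L]]
        kc <- add_par(sprintf("kc%d", g))
        reactions <- c(reactions, list(
          reaction(stats::setNames(1L, a), stats::setNames(1L, b),
                   str2lang(sprintf("%s * %s * %s", kc, enz, a)))
        ))
      }
    }
    net <- reaction_network(species = x0, reactions = reactions,
                            parameters = pars)
    gamma <- left_null_space(stoichiometry_matrix(net))
    if (nrow(gamma) == n_moieties) {
      attr(net, "moieties") <- groups
      return(net)
    }
  }
  stopf("netreduce_generation_error",
        "could not generate a network with the requested moiety count")
}

#' Stiff ligand-controlled phosphorelay fixture
#'
#' A minimal kinase/phosphotransfer/phosphatase chain emulating the
#' structure of two-component chemotactic signalling: a kinase A
#' autophosphorylates at a ligand-controlled rate (the input scales
#' `k_auto`), transfers its phosphoryl group to the response regulator Y
#' through the transient complex C (= Ap.Y), and the phosphorylated
#' regulator exchanges rapidly between two conformations Yp and Yq before
#' dephosphorylation. The conformational exchange runs `stiff_ratio`
#' times faster than the slow block, so the model's stiffness coefficient
#' at the initial condition grows with `stiff_ratio`, and (Yp, Yq) - held
#' in proportional equilibrium by the fast exchange - is an accurately
#' lumpable pair. Both protein moieties are conserved (A + Ap + C and
#' Y + Yp + Yq + C). The output is total phosphorylated response
#' regulator, Yp + Yq + C.
#'
#' @param rates named list of base rates `k_auto`, `k_bind`, `k_unbind`,
#'   `k_tr`, `k_conf`, `k_deph` (1/time or 1/(conc time)); defaults span
#'   the 0.3-10 range typical of signalling steps, with the exchange
#'   `k_conf` the one multiplied by `stiff_ratio`.
#' @param stiff_ratio factor (>= 1) by which the conformational exchange
#'   is faster than the base scale.
#' @return list with `network`, `spec` (input: parameter-scale on
#'   `k_auto`; output `Yp + Yq + C`), `protocol` (a halving step of the
#'   autophosphorylation rate at t = 0) and `fast_pair` (names of the
#'   designated fast-equilibrating pair).
#' @export
make_phosphorelay <- function(rates = list(), stiff_ratio = 1000) {
  assert_that(stiff_ratio >= 1, "netreduce_invalid_argument",
              "stiff_ratio must be >= 1")
  r <- utils::modifyList(
    list(k_auto = 0.5, k_bind = 10, k_unbind = 10, k_tr = 10,
         k_conf = 0.8, k_deph = 0.3),
    rates)
  pars <- c(k_auto = r$k_auto, k_bind = r$k_bind, k_unbind = r$k_unbind,
            k_tr = r$k_tr, k_conf = r$k_conf * stiff_ratio,
            k_deph = r$k_deph)
  species <- c(A = 0.8, Ap = 0.1, Y = 0.6, Yp = 0.1, Yq = 0.1, C = 0.1)
  reactions <- list(
    reaction(c(A = 1L), c(Ap = 1L), quote(k_auto * A), id = "autophos"),
    reaction(c(Ap = 1L, Y = 1L), c(C = 1L), quote(k_bind * Ap * Y), id = "bind"),
    reaction(c(C = 1L), c(Ap = 1L, Y = 1L), quote(k_unbind * C), id = "unbind"),
    reaction(c(C = 1L), c(A = 1L, Yp = 1L), quote(k_tr * C), id = "transfer"),
    reaction(c(Yp = 1L), c(Yq = 1L), quote(k_conf * Yp), id = "conf_fwd"),
    reaction(c(Yq = 1L), c(Yp = 1L), quote(k_conf * Yq), id = "conf_rev"),
    reaction(c(Yp = 1L), c(Y = 1L), quote(k_deph * Yp), id = "dephos")
  )
  network <- reaction_network(species = species, reactions = reactions,
                              parameters = pars)
  spec <- io_spec(inputs = list(list(id = "k_auto", mode = "parameter-scale")),
                  output = quote(Yp + Yq + C))
  protocol <- error_protocol(u = 0.5, t_end = 30)
  list(network = network, spec = spec, protocol = protocol,
       fast_pair = c("Yp", "Yq"), stiff_ratio = stiff_ratio)
}
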