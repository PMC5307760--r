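#' Control-affine state-space systems
#'
#' A `controlled_system` is the evaluable realisation
#' \deqn{\dot x = f(x) + \sum_i g_i(x)\,u_i(t), \qquad y = h(x),}
#' i.e. a set of autonomous dynamics `f`, one additive input channel `g_i`
#' per declared input, and an output map `h`, together with an analytic
#' Jacobian of the full right-hand side. All reduction stages (conservation
#' elimination, lumping, balanced truncation, nondimensionalisation) consume
#' and produce objects of this class, so reductions compose.
#'
#' Two optional hooks support conservation-aware perturbation of initial
#' conditions: `lift(x)` maps a state of this (possibly reduced) system back
#' to the coordinates of the original full model, and `from_full(x_full)`
#' rebuilds the system for a new full-model initial condition - recomputing
#' any conserved totals on the way, so that perturbing initial conditions
#' can never violate conservation.
#'
#' @param f function(x) -> numeric(n), autonomous dynamics.
#' @param g function(x) -> n x l matrix of input channels (columns), or NULL
#'   for an autonomous system.
#' @param h function(x) -> numeric(p), output map.
#' @param jac function(x, u) -> n x n Jacobian of f(x) + g(x) u.
#' @param x0 initial state (length n).
#' @param u0 unperturbed input (length l).
#' @param state_names,output_names identifier vectors.
#' @param lift,from_full optional hooks described above.
#' @return object of class `controlled_system`.
#' @export
controlled_system <- function(f, g = NULL, h = NULL, jac = NULL, x0, u0 = numeric(0),
                              state_names = NULL, output_names = NULL,
                              lift = NULL, from_full = NULL) {
  n <- length(x0)
  state_names <- state_names %||% paste0("x", seq_len(n))
  if (is.null(g)) g <- function(x) matrix(0, n, max(1L, length(u0)))
  if (is.null(h)) h <- function(x) x
  if (is.null(jac)) jac <- function(x, u = u0) num_jacobian(function(z) {
    f(z) + as_matrix(g(z), n) %*% (if (length(u)) u else 0)
  }, x)
  p <- length(h(x0))
  output_names <- output_names %||% paste0("y", seq_len(p))
  sys <- structure(
    list(n = n, l = length(u0), p = p, f = f, g = g, h = h, jac = jac,
         x0 = as.numeric(x0), u0 = as.numeric(u0),
         state_names = state_names, output_names = output_names),
    class = "controlled_system"
  )
  sys$lift <- lift %||% function(x) x
  sys$from_full <- from_full %||% function(x_full) { sys$x0 <- as.numeric(x_full); sys }
  # eager sanity check: f, g, h must evaluate at x0
  fx <- sys$f(sys$x0)
  assert_that(length(fx) == n && all(is.finite(fx)), "netreduce_invalid_system",
              "f does not evaluate to a finite length-%d vector at x0", n)
  assert_that(all(is.finite(sys$h(sys$x0))), "netreduce_invalid_system",
              "h does not evaluate to a finite vector at x0")
  sys
}

#' @export
print.controlled_system <- function(x, ...) {
  cat(sprintf("<controlled_system> n = %d states, l = %d inputs, p = %d outputs\n",
              x$n, x$l, x$p))
  invisible(x)
}

# Full right-hand side at constant input u.
rhs_at <- function(system, u = system$u0) {
  n <- system$n
  function(x) {
    v <- system$f(x)
    if (length(u)) v <- v + as_matrix(system$g(x), n) %*% u
    as.numeric(v)
  }
}

# Central finite-difference Jacobian.
num_jacobian <- function(fn, x, eps = NULL) {
  n <- length(x)
  f0 <- fn(x)
  J <- matrix(0, length(f0), n)
  for (i in seq_len(n)) {
    hstep <- eps %||% (1e-6 * max(abs(x[i]), 1))
    xp <- x; xm <- x
    xp[i] <- xp[i] + hstep; xm[i] <- xm[i] - hstep
    J[, i] <- (fn(xp) - fn(xm)) / (2 * hstep)
  }
  J
}

#' Input/output declaration for a reaction network
#'
#' Declares which quantity acts as the control input and which combination
#' of species is observed. Two input modes are supported: `"additive-rate"`
#' adds the input directly to the rate of change of a named species (e.g. an
#' extracellular ligand supplied at a controlled rate), while
#' `"parameter-scale"` multiplies a named rate constant by the input (e.g.
#' an agonist scaling a receptor-binding rate), requiring every rate law to
#' be affine in that parameter.
#'
#' @param inputs list of `list(id =, mode =)` entries, or a character vector
#'   of identifiers (mode then defaults by identifier kind: species ->
#'   additive-rate, parameter -> parameter-scale).
#' @param output an R expression (or character string) over species
#'   identifiers giving the observed output y = h(x).
#' @return object of class `io_spec`.
#' @examples
#' io_spec(inputs = "k_auto", output = "Yp + C")
#' @export
io_spec <- function(inputs, output) {
  if (is.character(inputs)) inputs <- lapply(inputs, function(id) list(id = id))
  inputs <- lapply(inputs, function(inp) {
    assert_that(!is.null(inp$id), "netreduce_invalid_iospec",
                "each input needs an 'id' field")
    inp
  })
  if (is.character(output)) output <- str2lang(output)
  if (inherits(output, "formula")) output <- output[[length(output)]]
  structure(list(inputs = inputs, output = output), class = "io_spec")
}

#' Build a control-affine state-space system from a reaction network
#'
#' Collects all reaction fluxes into the autonomous dynamics f, isolates the
#' contribution of each declared input into its own channel g_i, compiles
#' the output expression into h, and differentiates the rate laws
#' symbolically to obtain the analytic Jacobian. For a `"parameter-scale"`
#' input on parameter k, each rate law must be affine in k (v = a(x) + k
#' b(x)); the k-proportional part moves into g with unperturbed input u0 =
#' 1, so that u = 1 reproduces the original model and u rescales the rate
#' constant. Nonlinear dependence on an input parameter breaks control
#' affinity and is rejected.
#'
#' @param network a [reaction_network()].
#' @param spec an [io_spec()].
#' @return a [controlled_system()].
#' @export
build_state_space <- function(network, spec) {
  sp_names <- names(network$species)
  n <- length(sp_names)
  pars <- network$parameters
  N <- stoichiometry_matrix(network)
  rates <- lapply(network$reactions, `[[`, "rate")
  r <- length(rates)

  # classify inputs
  modes <- character(0); ids <- character(0)
  for (inp in spec$inputs) {
    id <- inp$id
    mode <- inp$mode %||% if (id %in% sp_names) "additive-rate" else "parameter-scale"
    assert_that(mode %in% c("additive-rate", "parameter-scale"),
                "netreduce_invalid_iospec", "unknown input mode '%s'", mode)
    if (mode == "additive-rate") {
      assert_that(id %in% sp_names, "netreduce_invalid_iospec",
                  "additive-rate input '%s' is not a declared species", id)
    } else {
      assert_that(id %in% names(pars), "netreduce_invalid_iospec",
                  "parameter-scale input '%s' is not a declared parameter", id)
    }
    ids <- c(ids, id); modes <- c(modes, mode)
  }
  l <- length(ids)

  out_syms <- all_symbols(spec$output)
  assert_that(all(out_syms %in% c(sp_names, names(pars))),
              "netreduce_invalid_iospec",
              "output expression references unknown identifier '%s'",
              if (length(setdiff(out_syms, c(sp_names, names(pars)))))
                setdiff(out_syms, c(sp_names, names(pars)))[1] else "")

  # split each rate law: base part (into f) and per-input parameter-scale parts
  # (into g). For input parameter q: v = a(x) + q*b(x); dv/dq = b must be
  # q-free (affinity check, done numerically at random states).
  base_rates <- rates
  g_rate <- vector("list", l)          # per input: list of r exprs (or 0)
  for (ii in seq_len(l)) {
    if (modes[ii] != "parameter-scale") next
    q <- ids[ii]
    gexprs <- vector("list", r)
    for (j in seq_len(r)) {
      if (!(q %in% all_symbols(rates[[j]]))) { gexprs[[j]] <- 0; next }
      dv <- stats::D(rates[[j]], q)
      assert_that(!(q %in% all_symbols(dv)), "netreduce_affine_error",
        "rate law of reaction %s is nonlinear in input parameter '%s'; the model is not control-affine in this input",
        network$reactions[[j]]$id, q)
      # q-part of the flux: q * dv ; base part: v - q*dv
      gexprs[[j]] <- call("*", as.name(q), dv)
      base_rates[[j]] <- call("-", base_rates[[j]], gexprs[[j]])
    }
    g_rate[[ii]] <- gexprs
  }

  eval_exprs <- function(exprs, x) {
    e <- list2env(as.list(pars), parent = baseenv())
    for (i in seq_len(n)) assign(sp_names[i], x[i], e)
    vapply(exprs, function(ex) eval(ex, e), numeric(1))
  }

  f <- function(x) as.numeric(N %*% eval_exprs(base_rates, x))
  g <- function(x) {
    G <- matrix(0, n, max(1L, l))
    for (ii in seq_len(l)) {
      if (modes[ii] == "additive-rate") {
        G[match(ids[ii], sp_names), ii] <- 1
      } else {
        G[, ii] <- as.numeric(N %*% eval_exprs(g_rate[[ii]], x))
      }
    }
    G
  }
  h_fun <- {
    hexpr <- spec$output
    function(x) {
      e <- list2env(as.list(pars), parent = baseenv())
      for (i in seq_len(n)) assign(sp_names[i], x[i], e)
      as.numeric(eval(hexpr, e))
    }
  }

  # symbolic flux Jacobian dv_j/dx_i for base and input parts
  d_base <- lapply(base_rates, function(ex) lapply(sp_names, function(s) stats::D(ex, s)))
  d_g <- lapply(seq_len(l), function(ii) {
    if (modes[ii] != "parameter-scale") return(NULL)
    lapply(g_rate[[ii]], function(ex)
      if (is.numeric(ex)) NULL else lapply(sp_names, function(s) stats::D(ex, s)))
  })
  eval_dmat <- function(dlist, x) {
    e <- list2env(as.list(pars), parent = baseenv())
    for (i in seq_len(n)) assign(sp_names[i], x[i], e)
    Dv <- matrix(0, length(dlist), n)
    for (j in seq_along(dlist)) {
      if (is.null(dlist[[j]])) next
      Dv[j, ] <- vapply(dlist[[j]], function(ex) eval(ex, e), numeric(1))
    }
    Dv
  }
  u0 <- ifelse(modes == "parameter-scale", 1, 0)
  jac <- function(x, u = u0) {
    J <- N %*% eval_dmat(d_base, x)
    for (ii in seq_len(l)) {
      if (modes[ii] == "parameter-scale" && length(u) && u[ii] != 0) {
        J <- J + u[ii] * (N %*% eval_dmat(d_g[[ii]], x))
      }
      # additive-rate channels are state-independent: no Jacobian term
    }
    unname(as.matrix(J))
  }

  controlled_system(
    f = f, g = g, h = h_fun, jac = jac,
    x0 = unname(network$species), u0 = u0,
    state_names = sp_names,
    output_names = deparse1(spec$output)
  )
}
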