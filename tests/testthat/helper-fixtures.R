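# Shared builders for small analytic systems used across test files.

# dx/dt = -k x + u, y = x : the minimal controlled system.
decay_system <- function(k = 1, x0 = 1) {
  controlled_system(
    f = function(x) -k * x,
    g = function(x) matrix(1, 1, 1),
    h = function(x) x,
    jac = function(x, u = 0) matrix(-k, 1, 1),
    x0 = x0, u0 = 0
  )
}

# A <-> B mass-action network with conserved total.
ab_network <- function(k1 = 1, k2 = 1, a0 = 2, b0 = 0) {
  reaction_network(
    species = c(A = a0, B = b0),
    reactions = list(
      reaction(c(A = 1L), c(B = 1L), quote(k1 * A)),
      reaction(c(B = 1L), c(A = 1L), quote(k2 * B))
    ),
    parameters = c(k1 = k1, k2 = k2)
  )
}

# E + S <-> C -> E + P (irreversible product step): two moieties.
enzyme_network <- function() {
  reaction_network(
    species = c(E = 1, S = 2, C = 0, P = 0),
    reactions = list(
      reaction(c(E = 1L, S = 1L), c(C = 1L), quote(kon * E * S)),
      reaction(c(C = 1L), c(E = 1L, S = 1L), quote(koff * C)),
      reaction(c(C = 1L), c(E = 1L, P = 1L), quote(kcat * C))
    ),
    parameters = c(kon = 2, koff = 1, kcat = 0.5)
  )
}

# Linear system x' = A x as a controlled_system (no input).
linear_system <- function(A, x0, C = NULL) {
  n <- nrow(A)
  C <- C %||% diag(1, n)
  controlled_system(
    f = function(x) as.numeric(A %*% x),
    g = function(x) matrix(0, n, 1),
    h = function(x) as.numeric(C %*% x),
    jac = function(x, u = 0) A,
    x0 = x0, u0 = 0
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

expect_close <- function(object, expected, tol = 1e-8) {
  expect_lt(max(abs(object - expected)), tol)
}
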