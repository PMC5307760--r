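# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(class, fmt, ...) {
  stop(structure(
    class = c(class, "netreduce_error", "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' @noRd
assert_that <- function(ok, class, fmt, ...) {
  if (!isTRUE(ok)) stopf(class, fmt, ...)
  invisible(TRUE)
}

# Trapezoidal quadrature on an arbitrary grid.
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

# Smallest-integer rescaling of a (near-)rational vector. Entries are
# approximated by rationals with bounded denominator; if all entries are
# rational to within `tol` the vector is scaled so entries become coprime
# integers, otherwise it is returned unchanged.
integerise <- function(v, tol = 1e-9, max_den = 1000L) {
  nz <- v[abs(v) > tol]
  if (!length(nz)) return(v)
  ref <- nz[which.max(abs(nz))]
  w <- v / ref
  dens <- vapply(w, function(z) {
    for (d in seq_len(max_den)) {
      if (abs(z * d - round(z * d)) < tol * d) return(d)
    }
    NA_integer_
  }, integer(1))
  if (anyNA(dens)) return(v)
  den <- Reduce(lcm_int, dens)
  ints <- round(w * den)
  g <- Reduce(gcd_int, abs(ints[ints != 0]))
  ints <- ints / max(g, 1L)
  # fix overall sign: make the first nonzero entry positive
  first <- ints[ints != 0][1L]
  if (!is.na(first) && first < 0) ints <- -ints
  ints
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)
lcm_int <- function(a, b) a / gcd_int(a, b) * b

# Monotone-cubic interpolation of a trajectory column onto new times.
interp_col <- function(t_old, y_old, t_new) {
  if (length(t_old) < 3L) {
    return(stats::approx(t_old, y_old, xout = t_new, rule = 2)$y)
  }
  f <- stats::splinefun(t_old, y_old, method = "monoH.FC")
  f(t_new)
}

as_matrix <- function(x, nrow = NULL) {
  if (is.matrix(x)) return(x)
  m <- matrix(x, nrow = nrow %||% length(x))
  m
}

# Substitute symbols in an R expression (a call/name/number) using a named
# list of replacement language objects.
subst_expr <- function(expr, env_list) {
  do.call(substitute, list(expr, env_list))
}

# All symbols appearing in an expression.
all_symbols <- function(expr) {
  if (is.name(expr)) return(as.character(expr))
  if (is.call(expr)) {
    return(unique(unlist(lapply(as.list(expr)[-1L], all_symbols))))
  }
  character(0)
}
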