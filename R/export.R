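#' Symbolically lump a reaction network
#'
#' Constructs the reaction network whose species are the lumped variables:
#' the lumped stoichiometry is `L %*% N` and every rate law has each
#' original species replaced by its reconstruction through the lumping
#' inverse (a weighted combination of lumped variables). Because lumped
#' states are plain sums of species concentrations, the result is again a
#' well-formed reaction network and can be serialised as SBML.
#'
#' @param network original [reaction_network()].
#' @param L,L_bar lumping matrix and generalised inverse.
#' @return a [reaction_network()] with attribute `"lump_map"` (membership
#'   of each lumped species).
#' @export
lumped_network <- function(network, L, L_bar) {
  L <- as.matrix(L); L_bar <- as.matrix(L_bar)
  sp <- names(network$species)
  n_red <- nrow(L)
  lump_ids <- vapply(seq_len(n_red), function(i) {
    members <- sp[L[i, ] != 0]
    if (length(members) == 1L) members else paste0("lump_", i)
  }, character(1))
  # reconstruction expressions x_j = sum_k L_bar[j,k] * z_k
  recon <- lapply(seq_along(sp), function(j) {
    terms <- which(abs(L_bar[j, ]) > 1e-14)
    if (!length(terms)) return(0)
    exprs <- lapply(terms, function(k) {
      w <- L_bar[j, k]
      if (abs(w - 1) < 1e-12) as.name(lump_ids[k]) else
        call("*", w, as.name(lump_ids[k]))
    })
    Reduce(function(a, b) call("+", a, b), exprs)
  })
  names(recon) <- sp
  NL <- L %*% stoichiometry_matrix(network)
  reactions <- lapply(seq_along(network$reactions), function(j) {
    rx <- network$reactions[[j]]
    col <- NL[, j]
    reaction(
      reactants = stats::setNames(as.integer(-col[col < 0]), lump_ids[col < 0]),
      products = stats::setNames(as.integer(col[col > 0]), lump_ids[col > 0]),
      rate = subst_expr(rx$rate, recon),
      id = rx$id
    )
  })
  # drop reactions whose lumped stoichiometry vanished entirely (internal
  # conversions inside one lump)
  keep <- vapply(seq_along(reactions), function(j) any(NL[, j] != 0), logical(1))
  out <- reaction_network(
    species = stats::setNames(as.numeric(L %*% network$species), lump_ids),
    reactions = reactions[keep],
    parameters = network$parameters,
    compartments = network$compartments
  )
  attr(out, "lump_map") <- stats::setNames(
    lapply(seq_len(n_red), function(i) sp[L[i, ] != 0]), lump_ids)
  out
}

#' Export a model or reduction
#'
#' Lumped models (reduced states are sums of original species) export as
#' SBML with an annotation listing lump membership and the inverse
#' weights; balanced-truncated models - whose transformed states are no
#' longer species concentrations - export as a JSON-serialised ODE
#' definition: deparsed symbolic right-hand sides together with the
#' projection matrices T1, S1 and the Hankel singular values (from which
#' the retained \eqn{\Sigma_1} diagonal can be recomputed).
#'
#' @param x what to export: a [reaction_network()] (format `"sbml"`), a
#'   list with `network`, `L`, `L_bar` (lumped export), or a
#'   `reduction_report`.
#' @param format `"sbml"` or `"json"`.
#' @param file output path; `NULL` returns the text.
#' @return invisibly, the serialised text.
#' @export
export_model <- function(x, format = c("sbml", "json"), file = NULL) {
  format <- match.arg(format)
  if (inherits(x, "reaction_network")) {
    assert_that(format == "sbml", "netreduce_unsupported_format",
                "reaction networks export as SBML")
    return(write_sbml(x, file))
  }
  if (inherits(x, "reduction_report")) {
    return(export_report(x, format, file))
  }
  if (is.list(x) && !is.null(x$network) && !is.null(x$L)) {
    assert_that(format == "sbml", "netreduce_unsupported_format",
                "lumped models export as SBML")
    ln <- lumped_network(x$network, x$L, x$L_bar)
    ann <- list(lump_map = attr(ln, "lump_map"),
                L_bar = round(as.matrix(x$L_bar), 12))
    return(write_sbml(ln, file, annotation = ann))
  }
  stopf("netreduce_unsupported_format",
        "cannot export object of class %s as %s", class(x)[1], format)
}

export_report <- function(report, format, file) {
  if (format == "sbml") {
    assert_that(report$final$method %in% c("lump", "conservation"),
                "netreduce_unsupported_format",
                "balanced-truncated models cannot be expressed as SBML species; use format = 'json'")
    scheme <- report$lumping$scheme
    return(export_model(list(network = report$network, L = scheme$L,
                             L_bar = scheme$L_bar),
                        format = "sbml", file = file))
  }
  payload <- list(
    final_dim = report$final$dim,
    method = report$final$method,
    max_relative_error = report$final$E,
    scaling = if (!is.null(report$scaling)) list(
      state_scales = as.list(report$scaling$state_scales),
      time_scale = report$scaling$time_scale,
      sigma = report$scaling$sigma),
    conservation = list(
      gamma = as.matrix(report$conservation$gamma),
      eliminated = report$conservation$eliminated,
      retained = report$conservation$retained),
    lumping = list(L = as.matrix(report$lumping$scheme$L),
                   L_bar = as.matrix(report$lumping$scheme$L_bar)),
    balancing = if (!is.null(report$balancing)) list(
      T1 = as.matrix(report$balancing$T1),
      S1 = as.matrix(report$balancing$S1),
      hankel = report$balancing$hankel),
    gramians = if (!is.null(report$gramians)) list(
      P = as.matrix(report$gramians$P),
      Q = as.matrix(report$gramians$Q)),
    rhs = deparse_rhs(report),
    indices = report$indices,
    stages = report$stages
  )
  txt <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                          null = "null", pretty = TRUE)
  if (!is.null(file)) writeLines(txt, file)
  invisible(txt)
}

# Human-readable symbolic right-hand sides of the original network in
# terms of its rate laws (the reduced dynamics follow by projecting these
# through the exported matrices).
deparse_rhs <- function(report) {
  net <- report$network
  N <- stoichiometry_matrix(net)
  rates <- vapply(net$reactions, function(rx) deparse1(rx$rate), character(1))
  list(species = names(net$species),
       stoichiometry = as.matrix(N),
       rate_laws = rates)
}
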