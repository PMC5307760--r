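#' Reaction network objects
#'
#' A `reaction_network` is the internal representation of a biochemical
#' reaction network: an ordered set of species with initial concentrations,
#' a set of reactions (reactant/product stoichiometries plus a kinetic rate
#' law given as an R expression over species and parameter identifiers), a
#' parameter set, and compartment volumes. Species order is fixed at
#' construction and every matrix produced downstream (stoichiometry,
#' Jacobians, lumping and truncation projections) uses that order.
#'
#' @param species named numeric vector of initial concentrations; names are
#'   the species identifiers (declaration order is preserved).
#' @param reactions list of reactions. Each reaction is a list with fields
#'   `reactants` (named integer vector of stoichiometries), `products`
#'   (named integer vector), `rate` (an R expression or one-sided formula in
#'   species and parameter identifiers) and optionally `id`.
#' @param parameters named numeric vector of rate parameters (positive).
#' @param compartments named numeric vector of compartment volumes
#'   (defaults to a single unit compartment).
#'
#' @return An object of class `reaction_network`.
#' @examples
#' net <- reaction_network(
#'   species = c(A = 1, B = 0),
#'   reactions = list(reaction(c(A = 1), c(B = 1), quote(k * A))),
#'   parameters = c(k = 2)
#' )
#' stoichiometry_matrix(net)
#' @export
reaction_network <- function(species, reactions, parameters = numeric(0),
                             compartments = c(default = 1)) {
  assert_that(is.numeric(species) && !is.null(names(species)) &&
                !anyDuplicated(names(species)),
              "netreduce_invalid_network",
              "species must be a named numeric vector with unique names")
  assert_that(all(species >= 0), "netreduce_invalid_network",
              "initial concentrations must be non-negative")
  assert_that(all(parameters > 0) || !length(parameters),
              "netreduce_invalid_network", "parameters must be positive")
  reactions <- lapply(seq_along(reactions), function(j) {
    rx <- reactions[[j]]
    rx$id <- rx$id %||% paste0("r", j)
    rx$rate <- as_rate_expr(rx$rate)
    for (side in c("reactants", "products")) {
      s <- rx[[side]]
      if (length(s)) {
        assert_that(all(names(s) %in% names(species)),
                    "netreduce_invalid_network",
                    "reaction %s references undeclared species '%s'",
                    rx$id, setdiff(names(s), names(species))[1])
        assert_that(all(s >= 0) && all(abs(s - round(s)) < 1e-9),
                    "netreduce_invalid_network",
                    "stoichiometries in reaction %s must be non-negative integers",
                    rx$id)
      }
    }
    refs <- all_symbols(rx$rate)
    unknown <- setdiff(refs, c(names(species), names(parameters)))
    assert_that(!length(unknown), "netreduce_invalid_network",
                "rate law of reaction %s references unknown identifier '%s'",
                rx$id, if (length(unknown)) unknown[1] else "")
    rx
  })
  structure(
    list(species = species, reactions = reactions, parameters = parameters,
         compartments = compartments),
    class = "reaction_network"
  )
}

#' @rdname reaction_network
#' @param reactants,products named integer vectors of stoichiometries.
#' @param rate rate-law expression (quoted call, e.g. `quote(k * A)`).
#' @param id optional reaction identifier.
#' @export
reaction <- function(reactants, products, rate, id = NULL) {
  list(reactants = reactants, products = products, rate = rate, id = id)
}

as_rate_expr <- function(rate) {
  if (inherits(rate, "formula")) rate <- rate[[length(rate)]]
  if (is.character(rate)) rate <- str2lang(rate)
  assert_that(is.language(rate) || is.numeric(rate),
              "netreduce_invalid_network", "rate law must be an expression")
  rate
}

#' @export
print.reaction_network <- function(x, ...) {
  cat(sprintf("<reaction_network> %d species, %d reactions, %d parameters\n",
              length(x$species), length(x$reactions), length(x$parameters)))
  invisible(x)
}

#' Stoichiometry matrix of a reaction network
#'
#' Entry (i, j) is the net production of species i in reaction j
#' (products minus reactants); the column order matches reaction order.
#'
#' @param network a [reaction_network()].
#' @return integer matrix of dimension n_species x n_reactions.
#' @export
stoichiometry_matrix <- function(network) {
  sp <- names(network$species)
  N <- matrix(0L, length(sp), length(network$reactions),
              dimnames = list(sp, vapply(network$reactions, `[[`, "", "id")))
  for (j in seq_along(network$reactions)) {
    rx <- network$reactions[[j]]
    for (s in names(rx$reactants)) N[s, j] <- N[s, j] - rx$reactants[[s]]
    for (s in names(rx$products)) N[s, j] <- N[s, j] + rx$products[[s]]
  }
  N
}

# Evaluate all reaction fluxes at a state (named) with parameters in scope.
flux_env <- function(network) {
  e <- new.env(parent = baseenv())
  for (p in names(network$parameters)) assign(p, network$parameters[[p]], e)
  e
}
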