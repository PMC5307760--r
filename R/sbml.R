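#' Read an SBML model into a reaction network
#'
#' Parses SBML Level 2 or Level 3 (the subset describing plain reaction
#' networks: compartments, species, global and reaction-local parameters,
#' reactions with MathML kinetic laws, and initial assignments that
#' evaluate to constants). Amount-valued initial conditions are converted
#' to concentrations by the compartment size so all species share one
#' concentration unit; species flagged `constant`/`boundaryCondition` are
#' folded into the parameter set. Constructs outside the ODE core -
#' events, algebraic/assignment/rate rules, function definitions, delays -
#' raise an unsupported-feature error naming the construct; a reaction
#' without a kinetic law is likewise rejected.
#'
#' @param source path to an SBML file, or a single string of SBML XML.
#' @return a [reaction_network()].
#' @export
read_sbml <- function(source) {
  doc <- tryCatch(xml2::read_xml(source),
                  error = function(e)
                    stopf("netreduce_parse_error", "malformed SBML XML: %s",
                          conditionMessage(e)))
  xml2::xml_ns_strip(doc)
  model <- xml2::xml_find_first(doc, ".//model")
  assert_that(!inherits(model, "xml_missing"), "netreduce_parse_error",
              "document has no <model> element")

  for (bad in c("event" = ".//listOfEvents/event",
                "algebraicRule" = ".//algebraicRule",
                "assignmentRule" = ".//assignmentRule",
                "rateRule" = ".//rateRule",
                "functionDefinition" = ".//functionDefinition",
                "delay" = ".//delay",
                "constraint" = ".//listOfConstraints/constraint")) {
    if (length(xml2::xml_find_all(model, bad))) {
      stopf("netreduce_unsupported_feature",
            "SBML construct <%s> is outside the supported ODE core",
            names(which(c("event" = ".//listOfEvents/event",
                          "algebraicRule" = ".//algebraicRule",
                          "assignmentRule" = ".//assignmentRule",
                          "rateRule" = ".//rateRule",
                          "functionDefinition" = ".//functionDefinition",
                          "delay" = ".//delay",
                          "constraint" = ".//listOfConstraints/constraint") == bad)))
    }
  }

  xattr <- function(node, name, default = NA_character_) {
    v <- xml2::xml_attr(node, name)
    if (is.na(v)) default else v
  }
  num_attr <- function(node, name, default = NA_real_) {
    v <- xattr(node, name)
    if (is.na(v)) default else as.numeric(v)
  }

  comp_nodes <- xml2::xml_find_all(model, ".//listOfCompartments/compartment")
  compartments <- stats::setNames(
    vapply(comp_nodes, function(nd)
      num_attr(nd, "size", num_attr(nd, "volume", 1)), numeric(1)),
    vapply(comp_nodes, function(nd) xattr(nd, "id"), character(1)))
  if (!length(compartments)) compartments <- c(default = 1)
  compartments[is.na(compartments)] <- 1

  sp_nodes <- xml2::xml_find_all(model, ".//listOfSpecies/species")
  assert_that(length(sp_nodes) > 0, "netreduce_parse_error",
              "model declares no species")
  sp_ids <- vapply(sp_nodes, function(nd) xattr(nd, "id"), character(1))
  sp_conc <- vapply(sp_nodes, function(nd) {
    conc <- num_attr(nd, "initialConcentration")
    if (!is.na(conc)) return(conc)
    amt <- num_attr(nd, "initialAmount")
    vol <- compartments[[xattr(nd, "compartment", names(compartments)[1])]] %||% 1
    if (!is.na(amt)) amt / vol else 0
  }, numeric(1))
  is_fixed <- vapply(sp_nodes, function(nd) {
    identical(xattr(nd, "constant"), "true") ||
      identical(xattr(nd, "boundaryCondition"), "true")
  }, logical(1))

  # model-level parameters only; reaction-local ones are handled per reaction
  par_nodes <- xml2::xml_find_all(model, "./listOfParameters/parameter")
  parameters <- stats::setNames(
    vapply(par_nodes, function(nd) num_attr(nd, "value", 1), numeric(1)),
    vapply(par_nodes, function(nd) xattr(nd, "id"), character(1)))

  # initial assignments: constant-evaluable expressions only
  ia_nodes <- xml2::xml_find_all(model, ".//listOfInitialAssignments/initialAssignment")
  if (length(ia_nodes)) {
    env <- list2env(c(as.list(parameters),
                      stats::setNames(as.list(sp_conc), sp_ids),
                      as.list(compartments)), parent = baseenv())
    for (nd in ia_nodes) {
      sym <- xattr(nd, "symbol")
      ex <- mathml_to_expr(xml2::xml_find_first(nd, ".//math"))
      val <- tryCatch(eval(ex, env), error = function(e)
        stopf("netreduce_unsupported_feature",
              "initialAssignment for '%s' is not constant-evaluable", sym))
      if (sym %in% sp_ids) sp_conc[match(sym, sp_ids)] <- val
      else if (sym %in% names(parameters)) parameters[[sym]] <- val
      assign(sym, val, env)
    }
  }

  # fixed species become parameters
  fixed_pars <- stats::setNames(sp_conc[is_fixed], sp_ids[is_fixed])
  fixed_pars <- fixed_pars[fixed_pars > 0]   # zero-valued fixed species stay as 0 constants
  species <- stats::setNames(sp_conc[!is_fixed], sp_ids[!is_fixed])
  parameters <- c(parameters, fixed_pars)

  rx_nodes <- xml2::xml_find_all(model, ".//listOfReactions/reaction")
  reactions <- lapply(rx_nodes, function(nd) {
    rid <- xattr(nd, "id", "reaction")
    kl <- xml2::xml_find_first(nd, ".//kineticLaw")
    assert_that(!inherits(kl, "xml_missing"), "netreduce_unsupported_feature",
                "reaction '%s' has no kineticLaw", rid)
    math <- xml2::xml_find_first(kl, ".//math")
    assert_that(!inherits(math, "xml_missing"), "netreduce_unsupported_feature",
                "kineticLaw of reaction '%s' has no <math>", rid)
    rate <- mathml_to_expr(math)
    # local parameters: prefix with the reaction id to keep them unique
    loc_nodes <- c(xml2::xml_find_all(kl, ".//listOfParameters/parameter"),
                   xml2::xml_find_all(kl, ".//listOfLocalParameters/localParameter"))
    if (length(loc_nodes)) {
      loc <- stats::setNames(
        vapply(loc_nodes, function(x) num_attr(x, "value", 1), numeric(1)),
        vapply(loc_nodes, function(x) xattr(x, "id"), character(1)))
      ren <- stats::setNames(paste0(rid, "_", names(loc)), names(loc))
      rate <- subst_expr(rate, stats::setNames(lapply(ren, as.name), names(ren)))
      parameters <<- c(parameters, stats::setNames(loc, ren))
    }
    side <- function(path) {
      refs <- xml2::xml_find_all(nd, path)
      refs <- refs[vapply(refs, function(x) xattr(x, "species") %in% names(species),
                          logical(1))]
      if (!length(refs)) return(stats::setNames(integer(0), character(0)))
      st <- vapply(refs, function(x) num_attr(x, "stoichiometry", 1), numeric(1))
      sp <- vapply(refs, function(x) xattr(x, "species"), character(1))
      tapply_sum <- tapply(st, sp, sum)
      stats::setNames(as.integer(tapply_sum), names(tapply_sum))
    }
    reaction(reactants = side(".//listOfReactants/speciesReference"),
             products = side(".//listOfProducts/speciesReference"),
             rate = rate, id = rid)
  })

  # substitute compartment symbols by their sizes in rate laws
  comp_sub <- lapply(compartments, function(v) v)
  reactions <- lapply(reactions, function(rx) {
    rx$rate <- subst_expr(rx$rate, comp_sub)
    rx
  })
  # drop parameters valued <= 0 that are never referenced (reaction_network
  # requires positive parameters)
  used <- unique(unlist(lapply(reactions, function(rx) all_symbols(rx$rate))))
  parameters <- parameters[names(parameters) %in% used | parameters > 0]
  zero_pars <- parameters[parameters <= 0]
  if (length(zero_pars)) {
    # inline non-positive constants directly into the rate laws
    reactions <- lapply(reactions, function(rx) {
      rx$rate <- subst_expr(rx$rate, as.list(zero_pars))
      rx
    })
    parameters <- parameters[parameters > 0]
  }
  reaction_network(species = species, reactions = reactions,
                   parameters = parameters, compartments = compartments)
}

# ---- MathML <-> R expressions ----------------------------------------------

mathml_to_expr <- function(math_node) {
  kids <- xml2::xml_children(math_node)
  assert_that(length(kids) == 1L, "netreduce_parse_error",
              "<math> must contain exactly one expression")
  mathml_node_to_expr(kids[[1L]])
}

mathml_node_to_expr <- function(node) {
  name <- xml2::xml_name(node)
  switch(
    name,
    "ci" = as.name(trimws(xml2::xml_text(node))),
    "cn" = mathml_number(node),
    "pi" = pi,
    "exponentiale" = exp(1),
    "apply" = {
      kids <- xml2::xml_children(node)
      op <- xml2::xml_name(kids[[1L]])
      args <- lapply(kids[-1L], mathml_node_to_expr)
      mathml_apply(op, args, kids[[1L]])
    },
    stopf("netreduce_unsupported_feature",
          "unsupported MathML element <%s>", name)
  )
}

mathml_number <- function(node) {
  type <- xml2::xml_attr(node, "type")
  txt <- xml2::xml_text(node)
  if (identical(type, "e-notation") || identical(type, "rational")) {
    parts <- as.numeric(strsplit(trimws(txt), "\\s+")[[1]])
    if (identical(type, "e-notation")) return(parts[1] * 10^parts[2])
    return(parts[1] / parts[2])
  }
  as.numeric(trimws(txt))
}

mathml_apply <- function(op, args, op_node) {
  nary <- function(fun, args) Reduce(function(a, b) call(fun, a, b), args)
  switch(
    op,
    "plus" = if (length(args)) nary("+", args) else 0,
    "times" = if (length(args)) nary("*", args) else 1,
    "minus" = if (length(args) == 1L) call("-", args[[1L]]) else nary("-", args),
    "divide" = nary("/", args),
    "power" = call("^", args[[1L]], args[[2L]]),
    "exp" = call("exp", args[[1L]]),
    "ln" = call("log", args[[1L]]),
    "log" = if (length(args) == 1L) call("log", args[[1L]], 10) else
      call("log", args[[2L]], args[[1L]]),
    "root" = call("sqrt", args[[length(args)]]),
    "abs" = call("abs", args[[1L]]),
    "floor" = call("floor", args[[1L]]),
    "ceiling" = call("ceiling", args[[1L]]),
    stopf("netreduce_unsupported_feature",
          "unsupported MathML operator <%s>", op)
  )
}

expr_to_mathml <- function(expr) {
  if (is.numeric(expr)) return(sprintf("<cn> %.17g </cn>", expr))
  if (is.name(expr)) return(sprintf("<ci> %s </ci>", as.character(expr)))
  assert_that(is.call(expr), "netreduce_unsupported_feature",
              "cannot serialise expression of class %s", class(expr)[1])
  op <- as.character(expr[[1L]])
  args <- lapply(as.list(expr)[-1L], expr_to_mathml)
  tag <- switch(op,
                "+" = "plus", "-" = "minus", "*" = "times", "/" = "divide",
                "^" = "power", "exp" = "exp", "log" = "ln", "sqrt" = "root",
                "abs" = "abs", "(" = NA_character_,
                stopf("netreduce_unsupported_feature",
                      "operator '%s' has no MathML serialisation", op))
  if (is.na(tag)) return(args[[1L]])
  paste0("<apply> <", tag, "/> ", paste(unlist(args), collapse = " "),
         " </apply>")
}

#' Write a reaction network as SBML Level 3
#'
#' @param network a [reaction_network()].
#' @param file output path; if `NULL` the XML is returned as a string.
#' @param annotation optional list serialised (as JSON) into the model's
#'   `<annotation>` element - used to record lump membership for lumped
#'   models.
#' @return invisibly, the SBML text.
#' @export
write_sbml <- function(network, file = NULL, annotation = NULL) {
  esc <- function(x) gsub("&", "&amp;", gsub("<", "&lt;", x))
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">',
    '  <model id="model" substanceUnits="mole" timeUnits="second">',
    '    <listOfCompartments>',
    sprintf('      <compartment id="%s" size="%.17g" constant="true"/>',
            names(network$compartments), network$compartments),
    '    </listOfCompartments>',
    '    <listOfSpecies>',
    sprintf(paste0('      <species id="%s" compartment="%s" ',
                   'initialConcentration="%.17g" hasOnlySubstanceUnits="false" ',
                   'boundaryCondition="false" constant="false"/>'),
            names(network$species), names(network$compartments)[1],
            network$species),
    '    </listOfSpecies>')
  if (length(network$parameters)) {
    lines <- c(lines,
               '    <listOfParameters>',
               sprintf('      <parameter id="%s" value="%.17g" constant="true"/>',
                       names(network$parameters), network$parameters),
               '    </listOfParameters>')
  }
  lines <- c(lines, '    <listOfReactions>')
  for (rx in network$reactions) {
    lines <- c(lines, sprintf('      <reaction id="%s" reversible="false" fast="false">', rx$id))
    side_block <- function(tag, s) {
      if (!length(s)) return(character(0))
      c(sprintf('        <%s>', tag),
        sprintf('          <speciesReference species="%s" stoichiometry="%d" constant="true"/>',
                names(s), as.integer(s)),
        sprintf('        </%s>', tag))
    }
    lines <- c(lines,
               side_block("listOfReactants", rx$reactants),
               side_block("listOfProducts", rx$products),
               '        <kineticLaw>',
               '          <math xmlns="http://www.w3.org/1998/Math/MathML">',
               paste0('            ', expr_to_mathml(rx$rate)),
               '          </math>',
               '        </kineticLaw>',
               '      </reaction>')
  }
  lines <- c(lines, '    </listOfReactions>')
  if (!is.null(annotation)) {
    lines <- c(lines,
               '    <annotation>',
               paste0('      <netreduce:metadata xmlns:netreduce="https://netreduce.invalid/ns">',
                      esc(jsonlite::toJSON(annotation, auto_unbox = TRUE)),
                      '</netreduce:metadata>'),
               '    </annotation>')
  }
  lines <- c(lines, '  </model>', '</sbml>')
  txt <- paste(lines, collapse = "\n")
  if (!is.null(file)) writeLines(txt, file)
  invisible(txt)
}
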