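# Best-effort SBML Level 2/3 subset import: species, global and
# reaction-local parameters, reactions with MathML kinetic laws, and
# initialAssignment elements with constant right-hand sides. Events,
# algebraic rules, (rate/assignment) rules, delays and functionDefinitions
# are outside the subset and rejected with an explicit message.

#' Load a reaction network from a model file
#'
#' Dispatches on file extension: `.xml`/`.sbml` files are parsed as an SBML
#' Level 2/3 subset, anything else as the native YAML schema (see
#' [read_network_yaml()]).
#'
#' @param source Path to the model file.
#' @return A validated `reaction_network`.
#' @export
load_network <- function(source) {
  if (grepl("\\.(xml|sbml)$", source, ignore.case = TRUE)) read_sbml(source)
  else read_network_yaml(source)
}

#' Read an SBML model (supported subset)
#'
#' Parses species (initialConcentration or initialAmount), global constant
#' parameters, reactions with reactant/product stoichiometries and MathML
#' kinetic laws, and initialAssignments whose right-hand sides are constant
#' expressions. Reaction-local parameters are hoisted to global scope under
#' `<reaction id>.<parameter id>`. All parameters referenced by at least one
#' kinetic law are flagged as rate constants; refine the flags afterwards if
#' only a subset represents structure-dependent reaction rates.
#'
#' @param path Path to the SBML file.
#' @return A validated `reaction_network`.
#' @export
read_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  model <- xml2::xml_find_first(doc, ".//model")
  if (inherits(model, "xml_missing")) stop("SBML parse failure: no <model>")
  for (bad in c("listOfEvents", "listOfRules", "listOfFunctionDefinitions",
                "listOfConstraints")) {
    node <- xml2::xml_find_first(model, paste0("./", bad))
    if (!inherits(node, "xml_missing") && length(xml2::xml_children(node)))
      stop("unsupported SBML construct: ", bad,
           " (events, rules, function definitions and constraints are",
           " outside the supported subset)")
  }
  model_id <- xml2::xml_attr(model, "id")
  if (is.na(model_id)) model_id <- basename(path)

  sp_nodes <- xml2::xml_find_all(model, ".//listOfSpecies/species")
  if (!length(sp_nodes)) stop("SBML model declares no species")
  species <- data.frame(
    id = xml2::xml_attr(sp_nodes, "id"),
    initial = vapply(sp_nodes, function(n) {
      v <- xml2::xml_attr(n, "initialConcentration")
      if (is.na(v)) v <- xml2::xml_attr(n, "initialAmount")
      if (is.na(v)) 0 else as.numeric(v)
    }, numeric(1)),
    protein = NA_character_,
    stringsAsFactors = FALSE
  )

  par_nodes <- xml2::xml_find_all(model, "./listOfParameters/parameter")
  parameters <- data.frame(
    id = xml2::xml_attr(par_nodes, "id"),
    value = vapply(par_nodes, function(n) {
      v <- xml2::xml_attr(n, "value")
      if (is.na(v)) NA_real_ else as.numeric(v)
    }, numeric(1)),
    rate_constant = FALSE,
    stringsAsFactors = FALSE
  )

  # compartments referenced in kinetic laws behave as constant parameters
  comp_nodes <- xml2::xml_find_all(model, ".//listOfCompartments/compartment")
  if (length(comp_nodes)) {
    comp <- data.frame(
      id = xml2::xml_attr(comp_nodes, "id"),
      value = vapply(comp_nodes, function(n) {
        v <- xml2::xml_attr(n, "size")
        if (is.na(v)) v <- xml2::xml_attr(n, "volume")
        if (is.na(v)) 1 else as.numeric(v)
      }, numeric(1)),
      rate_constant = FALSE,
      stringsAsFactors = FALSE
    )
    parameters <- rbind(parameters, comp)
  }

  rx_nodes <- xml2::xml_find_all(model, ".//listOfReactions/reaction")
  reactions <- list()
  for (rn in rx_nodes) {
    rid <- xml2::xml_attr(rn, "id")
    stoich <- numeric(0)
    add_refs <- function(xpath, sign) {
      for (ref in xml2::xml_find_all(rn, xpath)) {
        sid <- xml2::xml_attr(ref, "species")
        s <- xml2::xml_attr(ref, "stoichiometry")
        s <- if (is.na(s)) 1 else as.numeric(s)
        stoich[sid] <<- (if (sid %in% names(stoich)) stoich[[sid]] else 0) +
          sign * s
      }
    }
    add_refs("./listOfReactants/speciesReference", -1)
    add_refs("./listOfProducts/speciesReference", +1)
    kl <- xml2::xml_find_first(rn, "./kineticLaw")
    if (inherits(kl, "xml_missing"))
      stop("reaction '", rid, "' has no kineticLaw")
    local_map <- character(0)
    for (lp in xml2::xml_find_all(
      kl, "./listOfParameters/parameter | ./listOfLocalParameters/localParameter")) {
      lid <- xml2::xml_attr(lp, "id")
      gid <- paste0(rid, ".", lid)
      parameters <- rbind(parameters, data.frame(
        id = gid, value = as.numeric(xml2::xml_attr(lp, "value")),
        rate_constant = FALSE, stringsAsFactors = FALSE))
      local_map[lid] <- gid
    }
    math <- xml2::xml_find_first(kl, "./math")
    if (inherits(math, "xml_missing"))
      stop("reaction '", rid, "' kineticLaw has no <math>")
    rate <- mathml_to_r(xml2::xml_child(math), rename = local_map)
    reactions[[length(reactions) + 1L]] <-
      list(id = rid, stoich = stoich, rate = rate)
  }

  # initialAssignment with constant RHS overrides the declared initial value
  for (ia in xml2::xml_find_all(model, ".//listOfInitialAssignments/initialAssignment")) {
    sym <- xml2::xml_attr(ia, "symbol")
    expr_chr <- mathml_to_r(xml2::xml_child(xml2::xml_find_first(ia, "./math")))
    expr <- parse(text = expr_chr)[[1]]
    const_env <- new.env(parent = baseenv())
    for (i in seq_len(nrow(parameters)))
      if (!is.na(parameters$value[i]))
        assign(parameters$id[i], parameters$value[i], envir = const_env)
    val <- tryCatch(eval(expr, const_env), error = function(e)
      stop("unsupported SBML construct: non-constant initialAssignment for '",
           sym, "'"))
    if (sym %in% species$id) species$initial[species$id == sym] <- val
    else if (sym %in% parameters$id) parameters$value[parameters$id == sym] <- val
    else stop("initialAssignment for unknown symbol '", sym, "'")
  }
  if (anyNA(parameters$value))
    stop("parameter(s) without value: ",
         paste(parameters$id[is.na(parameters$value)], collapse = ", "))

  used <- unique(unlist(lapply(reactions, function(rx)
    all.vars(parse(text = rx$rate)[[1]]))))
  parameters$rate_constant <- parameters$id %in% setdiff(used, species$id) &
    !(parameters$id %in% if (length(comp_nodes)) xml2::xml_attr(comp_nodes, "id") else character(0))
  reaction_network(model_id, species, parameters, reactions)
}

# MathML (content markup) subset -> R expression text. `rename` maps local
# parameter ids to their hoisted global ids.
mathml_to_r <- function(node, rename = character(0)) {
  name <- xml2::xml_name(node)
  if (name == "ci") {
    sym <- trimws(xml2::xml_text(node))
    if (sym %in% names(rename)) sym <- rename[[sym]]
    return(sym)
  }
  if (name == "cn") {
    type <- xml2::xml_attr(node, "type")
    if (!is.na(type) && type == "e-notation") {
      parts <- strsplit(trimws(xml2::xml_text(node)), "\\s+")[[1]]
      return(sprintf("%se%s", parts[1], parts[length(parts)]))
    }
    return(trimws(xml2::xml_text(node)))
  }
  if (name %in% c("pi", "exponentiale"))
    return(if (name == "pi") "pi" else "exp(1)")
  if (name != "apply")
    stop("unsupported MathML element: <", name, ">")
  kids <- xml2::xml_children(node)
  op <- xml2::xml_name(kids[[1]])
  args <- vapply(kids[-1], mathml_to_r, character(1), rename = rename)
  paren <- function(a) paste0("(", a, ")")
  switch(op,
    plus = if (length(args) == 0) "0" else paren(paste(args, collapse = " + ")),
    minus = if (length(args) == 1) paren(paste0("-", args))
            else paren(paste(args, collapse = " - ")),
    times = if (length(args) == 0) "1" else paren(paste(args, collapse = " * ")),
    divide = paren(paste(args, collapse = " / ")),
    power = paren(paste0(args[1], "^", args[2])),
    root = paren(paste0("sqrt(", args[length(args)], ")")),
    exp = paste0("exp(", args[1], ")"),
    ln = paste0("log(", args[1], ")"),
    log = paste0("log10(", args[length(args)], ")"),
    abs = paste0("abs(", args[1], ")"),
    stop("unsupported MathML operator: <", op, ">")
  )
}
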