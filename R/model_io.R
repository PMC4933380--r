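# Reaction-network containers, the native plain-text model format, and
# validation of cross-references between networks, stimulation conditions,
# and domain annotations.

# Functions a rate law is allowed to call, beyond arithmetic operators.
.rate_law_functions <- c(
  "+", "-", "*", "/", "^", "(", "exp", "log", "log10", "sqrt", "abs",
  "sin", "cos", "tan", "pmax", "pmin", "max", "min"
)

#' Construct a reaction network
#'
#' A `reaction_network` is the simulable object of the package: a set of
#' molecular species with initial concentrations, a set of constant
#' parameters (those flagged as rate constants carry the reference values
#' `k*` at which dynamical influence is evaluated), and a set of reactions,
#' each combining an integer stoichiometry with an arbitrary arithmetic
#' rate-law expression over species and parameters. Mass-action kinetics is
#' not assumed.
#'
#' @param model_id Character scalar naming the model.
#' @param species Data frame with columns `id` (character, unique),
#'   `initial` (numeric, >= 0) and `protein` (character or `NA`; complexes
#'   list every member protein separated by `";"`).
#' @param parameters Data frame with columns `id` (character, unique),
#'   `value` (numeric, >= 0 reference value `k*`) and `rate_constant`
#'   (logical; only flagged parameters are scored for influence).
#' @param reactions List of lists, each with `id` (character), `stoich`
#'   (named numeric vector of signed integer coefficients over species ids)
#'   and `rate` (character scalar, the rate-law expression).
#'
#' @return An object of class `reaction_network`.
#' @examples
#' net <- reaction_network(
#'   "decay",
#'   species = data.frame(id = "A", initial = 1, protein = "P"),
#'   parameters = data.frame(id = "k", value = 1, rate_constant = TRUE),
#'   reactions = list(list(id = "r1", stoich = c(A = -1), rate = "k * A"))
#' )
#' @export
reaction_network <- function(model_id, species, parameters, reactions) {
  stopifnot(is.character(model_id), length(model_id) == 1L)
  species <- as.data.frame(species, stringsAsFactors = FALSE)
  parameters <- as.data.frame(parameters, stringsAsFactors = FALSE)
  if (is.null(species$protein)) species$protein <- NA_character_
  species$protein <- as.character(species$protein)
  species <- species[, c("id", "initial", "protein")]
  if (is.null(parameters$rate_constant)) parameters$rate_constant <- TRUE
  parameters <- parameters[, c("id", "value", "rate_constant")]
  net <- structure(
    list(model_id = model_id, species = species, parameters = parameters,
         reactions = reactions),
    class = "reaction_network"
  )
  validate_network(net)
  net
}

#' Validate a reaction network
#'
#' Checks the structural invariants: unique species and parameter ids,
#' non-negative initial concentrations and parameter values, every symbol in
#' every rate law declared as a species or parameter, only whitelisted
#' mathematical functions used, and every rate law evaluating to a finite
#' value at the initial state.
#'
#' @param net A `reaction_network`.
#' @return `net`, invisibly, if valid; otherwise an error is signalled.
#' @export
validate_network <- function(net) {
  sp <- net$species
  pp <- net$parameters
  if (anyDuplicated(sp$id)) stop("duplicate species ids: ",
                                 paste(sp$id[duplicated(sp$id)], collapse = ", "))
  if (anyDuplicated(pp$id)) stop("duplicate parameter ids: ",
                                 paste(pp$id[duplicated(pp$id)], collapse = ", "))
  if (any(!is.finite(sp$initial)) || any(sp$initial < 0))
    stop("initial concentrations must be finite and >= 0")
  if (any(!is.finite(pp$value)) || any(pp$value < 0))
    stop("parameter values must be finite and >= 0")
  declared <- c(sp$id, pp$id)
  env <- initial_state_env(net)
  for (rx in net$reactions) {
    if (is.null(rx$id) || is.null(rx$stoich) || is.null(rx$rate))
      stop("each reaction needs id, stoich and rate")
    unknown_sp <- setdiff(names(rx$stoich), sp$id)
    if (length(unknown_sp))
      stop("reaction '", rx$id, "' stoichiometry references undeclared species: ",
           paste(unknown_sp, collapse = ", "))
    expr <- parse_rate_law(rx$rate, rx$id)
    dangling <- setdiff(all.vars(expr), declared)
    if (length(dangling))
      stop("reaction '", rx$id, "' rate law references undeclared symbol(s): ",
           paste(dangling, collapse = ", "))
    bad_fun <- setdiff(setdiff(all.names(expr), all.vars(expr)),
                       .rate_law_functions)
    if (length(bad_fun))
      stop("reaction '", rx$id, "' rate law uses unsupported function(s): ",
           paste(bad_fun, collapse = ", "))
    v <- eval(expr, env)
    if (!is.finite(v))
      stop("reaction '", rx$id, "' rate law is non-finite at the initial state")
  }
  invisible(net)
}

parse_rate_law <- function(rate, reaction_id) {
  out <- tryCatch(parse(text = rate)[[1]],
                  error = function(e) stop("cannot parse rate law of reaction '",
                                           reaction_id, "': ", conditionMessage(e)))
  out
}

initial_state_env <- function(net) {
  env <- new.env(parent = baseenv())
  for (i in seq_len(nrow(net$species)))
    assign(net$species$id[i], net$species$initial[i], envir = env)
  for (i in seq_len(nrow(net$parameters)))
    assign(net$parameters$id[i], net$parameters$value[i], envir = env)
  env
}

#' @export
print.reaction_network <- function(x, ...) {
  cat("<reaction_network> ", x$model_id, ": ",
      nrow(x$species), " species, ",
      nrow(x$parameters), " parameters (",
      sum(x$parameters$rate_constant), " rate constants), ",
      length(x$reactions), " reactions\n", sep = "")
  invisible(x)
}

#' Construct a stimulation condition
#'
#' A stimulation condition is the unit over which dynamical influence sums:
#' a named set of overrides of initial concentrations and/or parameter values
#' applied at t = 0 (typically a ligand addition), together with the
#' simulation horizon over which dynamics are followed.
#'
#' @param condition_id Character scalar.
#' @param overrides Named list or numeric vector mapping species or parameter
#'   ids to replacement values; may be empty.
#' @param horizon Positive simulation horizon `T_c`.
#' @return An object of class `stimulation_condition`.
#' @export
stimulation_condition <- function(condition_id, overrides = list(), horizon) {
  stopifnot(is.character(condition_id), length(condition_id) == 1L)
  overrides <- as.list(overrides)
  if (length(overrides) && is.null(names(overrides)))
    stop("overrides must be named")
  if (!is.numeric(horizon) || length(horizon) != 1L || !is.finite(horizon) ||
      horizon <= 0)
    stop("horizon T must be a positive number")
  structure(list(condition_id = condition_id, overrides = overrides,
                 horizon = as.numeric(horizon)),
            class = "stimulation_condition")
}

#' @export
print.stimulation_condition <- function(x, ...) {
  cat("<stimulation_condition> ", x$condition_id, ": ",
      length(x$overrides), " override(s), horizon ", x$horizon, "\n", sep = "")
  invisible(x)
}

#' Apply a stimulation condition to a network
#'
#' Returns a copy of the network with the condition's t = 0 overrides applied
#' to initial concentrations and/or parameter values. The input network is
#' unchanged; an empty override map yields an identical copy.
#'
#' @param net A `reaction_network`.
#' @param cond A `stimulation_condition`.
#' @return A new `reaction_network`.
#' @export
apply_condition <- function(net, cond) {
  stopifnot(inherits(net, "reaction_network"),
            inherits(cond, "stimulation_condition"))
  out <- net
  for (id in names(cond$overrides)) {
    val <- as.numeric(cond$overrides[[id]])
    if (id %in% out$species$id) {
      out$species$initial[out$species$id == id] <- val
    } else if (id %in% out$parameters$id) {
      out$parameters$value[out$parameters$id == id] <- val
    } else {
      stop("condition '", cond$condition_id,
           "' overrides unknown id: ", id)
    }
  }
  out
}

# 17 significant digits round-trips an IEEE double exactly through decimal.
.num_chr <- function(x) vapply(x, function(v) sprintf("%.17g", v), character(1))

#' Write a reaction network to the native YAML format
#'
#' The native format is a plain-text YAML document mirroring the
#' `reaction_network` fields. Numeric values are serialized with 17
#' significant digits so that a write/read round-trip reproduces every field
#' bit-for-bit.
#'
#' @param net A `reaction_network`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_network_yaml <- function(net, path) {
  stopifnot(inherits(net, "reaction_network"))
  doc <- list(
    model_id = net$model_id,
    species = lapply(seq_len(nrow(net$species)), function(i) {
      s <- list(id = net$species$id[i],
                initial = .num_chr(net$species$initial[i]))
      if (!is.na(net$species$protein[i])) s$protein <- net$species$protein[i]
      s
    }),
    parameters = lapply(seq_len(nrow(net$parameters)), function(i) {
      list(id = net$parameters$id[i],
           value = .num_chr(net$parameters$value[i]),
           rate_constant = net$parameters$rate_constant[i])
    }),
    reactions = lapply(net$reactions, function(rx) {
      st <- as.list(.num_chr(rx$stoich))
      names(st) <- names(rx$stoich)
      list(id = rx$id, stoich = st, rate = rx$rate)
    })
  )
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Read a reaction network from the native YAML format
#'
#' @param path Path to a YAML model file written by [write_network_yaml()]
#'   or hand-authored in the same schema.
#' @return A validated `reaction_network`.
#' @export
read_network_yaml <- function(path) {
  doc <- yaml::read_yaml(path)
  for (field in c("model_id", "species", "parameters", "reactions"))
    if (is.null(doc[[field]])) stop("model file missing field: ", field)
  species <- data.frame(
    id = vapply(doc$species, function(s) as.character(s$id), character(1)),
    initial = vapply(doc$species, function(s) as.numeric(s$initial), numeric(1)),
    protein = vapply(doc$species, function(s)
      if (is.null(s$protein)) NA_character_ else as.character(s$protein),
      character(1)),
    stringsAsFactors = FALSE
  )
  parameters <- data.frame(
    id = vapply(doc$parameters, function(p) as.character(p$id), character(1)),
    value = vapply(doc$parameters, function(p) as.numeric(p$value), numeric(1)),
    rate_constant = vapply(doc$parameters, function(p)
      isTRUE(as.logical(p$rate_constant)), logical(1)),
    stringsAsFactors = FALSE
  )
  reactions <- lapply(doc$reactions, function(rx) {
    st <- vapply(rx$stoich, as.numeric, numeric(1))
    names(st) <- names(rx$stoich)
    list(id = as.character(rx$id), stoich = st, rate = as.character(rx$rate))
  })
  reaction_network(as.character(doc$model_id), species, parameters, reactions)
}

#' Write stimulation conditions to YAML
#'
#' @param conds List of `stimulation_condition` objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_conditions_yaml <- function(conds, path) {
  doc <- lapply(conds, function(cd) {
    ov <- lapply(cd$overrides, function(v) .num_chr(as.numeric(v)))
    list(condition_id = cd$condition_id, overrides = ov,
         horizon = .num_chr(cd$horizon))
  })
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Read stimulation conditions from YAML
#'
#' @param path Path to a conditions YAML file.
#' @return List of `stimulation_condition` objects.
#' @export
read_conditions_yaml <- function(path) {
  doc <- yaml::read_yaml(path)
  lapply(doc, function(cd) {
    ov <- lapply(cd$overrides, as.numeric)
    stimulation_condition(as.character(cd$condition_id), ov,
                          as.numeric(cd$horizon))
  })
}

#' Load a protein-domain annotation table
#'
#' Reads the many-to-many mapping from reaction rate constants to the protein
#' domains at which their reactions occur. One parameter may map to several
#' domains (a reaction at a domain interface) and one domain typically
#' collects several parameters; `N_d`, the count of parameters annotated to a
#' domain, is the divisor of the geometric mean in [domain_influence()].
#'
#' @param source Path to a TSV with columns `protein_id`, `domain_id`,
#'   `param_id`, or a data frame with those columns.
#' @param net Optional `reaction_network` to validate `param_id`s against.
#' @return A `domain_annotation`: a data frame of the three columns, with
#'   exact duplicate rows removed (a warning is raised when any are found).
#' @export
load_domain_annotation <- function(source, net = NULL) {
  ann <- if (is.data.frame(source)) source
  else utils::read.delim(source, stringsAsFactors = FALSE)
  need <- c("protein_id", "domain_id", "param_id")
  if (!all(need %in% names(ann)))
    stop("annotation must have columns: ", paste(need, collapse = ", "))
  ann <- ann[, need]
  dup <- duplicated(ann)
  if (any(dup)) {
    warning("removed ", sum(dup), " duplicate (protein, domain, param) row(s)")
    ann <- ann[!dup, , drop = FALSE]
  }
  if (any(!nzchar(ann$domain_id)) || anyNA(ann$domain_id))
    stop("empty domain_id in annotation")
  if (!is.null(net)) {
    stopifnot(inherits(net, "reaction_network"))
    unknown <- setdiff(unique(ann$param_id), net$parameters$id)
    if (length(unknown))
      stop("annotation references unknown param_id(s): ",
           paste(unknown, collapse = ", "))
  }
  rownames(ann) <- NULL
  class(ann) <- c("domain_annotation", "data.frame")
  ann
}

#' Load a per-domain covariate table
#'
#' Reads the row type of all downstream statistics: one row per protein
#' domain carrying the evolutionary rate dN/dS (`omega`), dynamical influence
#' `D`, and protein-level covariates expression breadth `B`, expression level
#' `X`, interaction degree `d`, betweenness centrality `C`, knockout
#' essentiality `E` (binary) and knockout growth rate `Gr`. Any covariate may
#' be missing (`NA`); protein-level covariates must be identical across
#' domains of the same protein.
#'
#' @param source Path to a TSV or a data frame with at least `domain_id` and
#'   `protein_id`.
#' @return A data frame with the standard column set (missing covariate
#'   columns are added as `NA`).
#' @export
load_covariate_table <- function(source) {
  tab <- if (is.data.frame(source)) source
  else utils::read.delim(source, stringsAsFactors = FALSE)
  if (!all(c("domain_id", "protein_id") %in% names(tab)))
    stop("covariate table must have domain_id and protein_id columns")
  for (v in c("omega", "D", "B", "X", "d", "C", "E", "Gr"))
    if (is.null(tab[[v]])) tab[[v]] <- NA_real_
  if (any(tab$omega < 0, na.rm = TRUE)) stop("omega (dN/dS) must be >= 0")
  for (v in c("B", "X", "d", "C", "E", "Gr")) {
    rng <- tapply(tab[[v]], tab$protein_id, function(z) {
      z <- z[!is.na(z)]
      if (!length(z)) 0 else max(z) - min(z)
    })
    if (any(rng > 0, na.rm = TRUE))
      stop("protein-level covariate '", v,
           "' differs across domains of one protein")
  }
  tab[, c("domain_id", "protein_id", "omega", "D", "B", "X", "d", "C", "E", "Gr")]
}
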