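# Model-derived covariates: protein abundance from initial conditions, the
# domain co-reaction graph, and degree / betweenness centrality for both
# model-derived and external interaction graphs.

#' Model-derived protein abundance
#'
#' Abundance of a protein is the sum of initial concentrations of all
#' molecular species corresponding to it, including modified forms and
#' complexes; a complex contributes its concentration once to each member
#' protein. Species membership is read from the network's `protein` field,
#' with complex members separated by `";"`. Species without a protein
#' mapping are ignored with a warning.
#'
#' @param net A `reaction_network`.
#' @return Named numeric vector of abundances, one entry per protein.
#' @export
model_abundance <- function(net) {
  stopifnot(inherits(net, "reaction_network"))
  sp <- net$species
  unmapped <- sp$id[is.na(sp$protein) | !nzchar(sp$protein)]
  if (length(unmapped))
    warning("species without protein mapping ignored: ",
            paste(unmapped, collapse = ", "))
  ab <- list()
  for (i in seq_len(nrow(sp))) {
    if (is.na(sp$protein[i]) || !nzchar(sp$protein[i])) next
    for (p in strsplit(sp$protein[i], ";", fixed = TRUE)[[1]]) {
      p <- trimws(p)
      ab[[p]] <- (if (is.null(ab[[p]])) 0 else ab[[p]]) + sp$initial[i]
    }
  }
  unlist(ab)
}

# Parameters entering a reaction's rate law, in declaration order.
reaction_params <- function(net) {
  lapply(net$reactions, function(rx)
    intersect(all.vars(parse_rate_law(rx$rate, rx$id)), net$parameters$id))
}

#' Build the domain co-reaction graph
#'
#' Constructs an undirected simple graph with one node per annotated domain
#' and an edge between any two domains that participate in a reaction
#' together — i.e., some reaction's rate law uses parameters annotated to
#' both. Domains never co-occurring in a reaction remain isolated nodes.
#'
#' @param ann A `domain_annotation`.
#' @param net The `reaction_network` (supplies the parameter -> reaction
#'   mapping through the rate laws).
#' @return An `igraph` undirected simple graph over the domain ids.
#' @export
build_domain_graph <- function(ann, net) {
  stopifnot(inherits(net, "reaction_network"))
  doms <- unique(ann$domain_id)
  edges <- character(0)
  for (pars in reaction_params(net)) {
    dset <- sort(unique(ann$domain_id[ann$param_id %in% pars]))
    if (length(dset) >= 2) {
      cmb <- utils::combn(dset, 2)
      edges <- c(edges, as.vector(cmb))
    }
  }
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(doms), name = doms)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Read an external protein interaction graph from edge-list files
#'
#' Reads one or more 2-column TSV edge lists (protein_id pairs, with or
#' without a header line named `a`/`b`), takes their union, removes
#' self-loops and duplicate edges irrespective of orientation, and returns
#' an undirected simple graph.
#'
#' @param paths Character vector of file paths.
#' @return An `igraph` undirected simple graph.
#' @export
read_interaction_edges <- function(paths) {
  all_edges <- NULL
  for (p in paths) {
    tab <- utils::read.delim(p, header = FALSE, stringsAsFactors = FALSE)
    if (identical(tolower(as.character(tab[1, 1])), "a")) tab <- tab[-1, ]
    all_edges <- rbind(all_edges, tab[, 1:2])
  }
  a <- as.character(all_edges[[1]]); b <- as.character(all_edges[[2]])
  keep <- a != b
  a <- a[keep]; b <- b[keep]
  key <- paste(pmin(a, b), pmax(a, b), sep = "\r")
  dedup <- !duplicated(key)
  igraph::graph_from_edgelist(cbind(a[dedup], b[dedup]), directed = FALSE)
}

#' Degree and betweenness centrality
#'
#' Computes each node's simple degree and its normalized betweenness
#' centrality: the fraction of all shortest paths between node pairs that
#' pass through the node, with equal-length shortest paths splitting credit
#' fractionally, normalized by `(n - 1)(n - 2) / 2` (the undirected
#' convention), so `C` lies in `[0, 1]`. Disconnected pairs contribute
#' nothing.
#'
#' @param g An `igraph` undirected graph.
#' @return Data frame with columns `node_id`, `degree`, `betweenness`.
#' @export
degree_and_betweenness <- function(g) {
  stopifnot(igraph::vcount(g) >= 1)
  n <- igraph::vcount(g)
  btw <- igraph::betweenness(g, directed = FALSE, normalized = n >= 3)
  nm <- igraph::V(g)$name
  if (is.null(nm)) nm <- as.character(seq_len(n))
  data.frame(node_id = nm,
             degree = as.integer(igraph::degree(g)),
             betweenness = as.numeric(btw),
             stringsAsFactors = FALSE, row.names = NULL)
}
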