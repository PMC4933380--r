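# Aggregation of rate-constant influences to protein domains, and
# comparison of domain influences across rate-constant ensembles.

#' Domain dynamical influence
#'
#' Aggregates rate-constant influences to the domain level: the influence
#' `D_d` of a domain is the geometric mean of the influences `kappa` of the
#' `N_d` rate constants annotated to it. The geometric mean is used because
#' rate-constant sensitivities range over orders of magnitude. A zero
#' `kappa` propagates: a domain containing a dynamically inert parameter has
#' `D = 0` (flooring would invent information); such domains are reported
#' via a message. Parameters annotated to several domains contribute their
#' `kappa` to each domain independently.
#'
#' @param infl An `influence_table` (columns `param_id`, `kappa`).
#' @param ann A `domain_annotation` (columns `protein_id`, `domain_id`,
#'   `param_id`).
#' @return A `domain_influence` data frame with columns `domain_id`,
#'   `protein_id`, `D`, `N_d`, carrying the influence table's `model_id`,
#'   `species_used` and `method` attributes.
#' @export
domain_influence <- function(infl, ann) {
  stopifnot(is.data.frame(infl), all(c("param_id", "kappa") %in% names(infl)))
  need <- c("protein_id", "domain_id", "param_id")
  stopifnot(is.data.frame(ann), all(need %in% names(ann)))
  missing_k <- setdiff(unique(ann$param_id), infl$param_id)
  if (length(missing_k))
    stop("annotation references unscored parameter(s): ",
         paste(missing_k, collapse = ", "))
  kappa <- stats::setNames(infl$kappa, infl$param_id)
  doms <- unique(ann[, c("domain_id", "protein_id")])
  if (anyDuplicated(doms$domain_id))
    stop("domain_id mapped to more than one protein_id: ",
         paste(doms$domain_id[duplicated(doms$domain_id)], collapse = ", "))
  D <- numeric(nrow(doms))
  N_d <- integer(nrow(doms))
  for (i in seq_len(nrow(doms))) {
    kk <- kappa[ann$param_id[ann$domain_id == doms$domain_id[i]]]
    N_d[i] <- length(kk)
    D[i] <- if (any(kk == 0)) 0 else exp(mean(log(kk)))
  }
  if (any(D == 0))
    message("domain(s) with a zero-influence parameter scored D = 0: ",
            paste(doms$domain_id[D == 0], collapse = ", "))
  out <- data.frame(domain_id = doms$domain_id, protein_id = doms$protein_id,
                    D = D, N_d = N_d, stringsAsFactors = FALSE,
                    row.names = NULL)
  structure(out,
            model_id = attr(infl, "model_id"),
            species_used = attr(infl, "species_used"),
            method = attr(infl, "method"),
            class = c("domain_influence", "data.frame"))
}

#' Domain influences over an ensemble of rate-constant sets
#'
#' Re-scores every parameter set of a rate-constant ensemble: for each set
#' the network's rate constants are replaced, all stimulation conditions are
#' re-simulated with sensitivities, and per-parameter and per-domain
#' influences recomputed.
#'
#' @param net A `reaction_network`.
#' @param conds List of `stimulation_condition` objects.
#' @param ann A `domain_annotation`.
#' @param param_sets Data frame with a `set_id` column plus one column per
#'   rate constant (the ensemble TSV layout of [read_ensemble_tsv()]).
#' @param n_grid Grid intervals per condition.
#' @return An `ensemble_influence`: list with `D` (domains x sets matrix of
#'   domain influences), `kappa` (parameters x sets matrix) and `set_ids`.
#' @export
ensemble_domain_influence <- function(net, conds, ann, param_sets,
                                      n_grid = 128) {
  stopifnot(is.data.frame(param_sets), "set_id" %in% names(param_sets),
            nrow(param_sets) >= 1)
  k_ids <- setdiff(names(param_sets), "set_id")
  unknown <- setdiff(k_ids, net$parameters$id)
  if (length(unknown))
    stop("ensemble references unknown parameter(s): ",
         paste(unknown, collapse = ", "))
  D_mat <- NULL; K_mat <- NULL
  for (i in seq_len(nrow(param_sets))) {
    nn <- net
    for (ki in k_ids)
      nn$parameters$value[nn$parameters$id == ki] <- param_sets[[ki]][i]
    trajs <- simulate_conditions(nn, conds, n_grid = n_grid)
    infl <- parameter_influence(trajs, nn)
    dom <- domain_influence(infl, ann)
    if (is.null(D_mat)) {
      D_mat <- matrix(NA_real_, nrow(dom), nrow(param_sets),
                      dimnames = list(dom$domain_id, param_sets$set_id))
      K_mat <- matrix(NA_real_, nrow(infl), nrow(param_sets),
                      dimnames = list(infl$param_id, param_sets$set_id))
    }
    D_mat[dom$domain_id, i] <- dom$D
    K_mat[infl$param_id, i] <- infl$kappa
  }
  structure(list(D = D_mat, kappa = K_mat, set_ids = param_sets$set_id),
            class = "ensemble_influence")
}

#' Compare domain influences across an ensemble of rate-constant sets
#'
#' Samples pairs of parameter sets and computes the Spearman rank
#' correlation of their domain-influence vectors, summarizing robustness of
#' relative influence to rate-constant uncertainty. When the number of
#' distinct unordered pairs does not exceed `n_pairs`, every pair is used
#' exactly once; otherwise `n_pairs` pairs are drawn uniformly. When a
#' per-domain `omega` (dN/dS) vector is supplied, the per-set Spearman
#' correlation between influence and `omega` is also returned together with
#' the fraction of sets in which it is negative.
#'
#' @param ens An `ensemble_influence`, or a domains x sets numeric matrix of
#'   domain influences with domain ids as row names.
#' @param n_pairs Number of pairs to sample (default 10000).
#' @param seed Integer seed for pair sampling.
#' @param omega Optional named numeric vector of dN/dS values over (a subset
#'   of) the domains.
#' @return List with `pair_correlations`, `median_pair_correlation`, `pairs`
#'   (2-column matrix of set indices) and, when `omega` is given,
#'   `omega_correlations` and `fraction_negative`.
#' @export
compare_influence_ensembles <- function(ens, n_pairs = 10000, seed = NULL,
                                        omega = NULL) {
  D <- if (inherits(ens, "ensemble_influence")) ens$D else as.matrix(ens)
  m <- ncol(D)
  if (m < 2) stop("ensemble must contain at least 2 parameter sets")
  if (!is.null(seed)) set.seed(seed)
  n_distinct <- choose(m, 2)
  if (n_distinct <= n_pairs) {
    pairs <- t(utils::combn(m, 2))
  } else {
    i <- sample.int(m, n_pairs, replace = TRUE)
    j <- sample.int(m - 1, n_pairs, replace = TRUE)
    j <- ifelse(j >= i, j + 1L, j)
    pairs <- cbind(pmin(i, j), pmax(i, j))
  }
  rho <- vapply(seq_len(nrow(pairs)), function(p)
    stats::cor(D[, pairs[p, 1]], D[, pairs[p, 2]], method = "spearman"),
    numeric(1))
  out <- list(pair_correlations = rho,
              median_pair_correlation = stats::median(rho),
              pairs = pairs)
  if (!is.null(omega)) {
    common <- intersect(rownames(D), names(omega))
    if (length(common) < 3)
      stop("fewer than 3 domains shared between ensemble and omega")
    oc <- apply(D[common, , drop = FALSE], 2, function(d)
      stats::cor(d, omega[common], method = "spearman"))
    out$omega_correlations <- oc
    out$fraction_negative <- mean(oc < 0)
  }
  out
}
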