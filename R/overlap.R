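# Between-model agreement of domain influences, and the randomization that
# removes overlapping domains to check whether domains shared between
# models inflate the meta-analytic statistics.

#' Between-model correlation of domain influences
#'
#' For every pair of models sharing at least `min_overlap` domains, computes
#' the Spearman rank correlation of the shared domains' influence values,
#' then combines the pair correlations by sample-size weighting (weight =
#' overlap count), the same weighting used by the meta-analysis mean.
#'
#' @param doms Named list of `domain_influence` data frames (or any data
#'   frames with `domain_id` and `D` columns), one per model.
#' @param min_overlap Minimum number of shared domains for a pair to
#'   qualify (default 4).
#' @return List with `pairs` (data frame `model_a`, `model_b`, `r`, `n`)
#'   and `mean_correlation` (the weighted mean across qualifying pairs).
#' @export
between_model_influence_correlation <- function(doms, min_overlap = 4) {
  stopifnot(length(doms) >= 2)
  ids <- names(doms)
  if (is.null(ids)) ids <- as.character(seq_along(doms))
  pairs <- NULL
  for (i in seq_len(length(doms) - 1)) {
    for (j in seq(i + 1, length(doms))) {
      a <- doms[[i]]; b <- doms[[j]]
      shared <- intersect(a$domain_id, b$domain_id)
      if (length(shared) < min_overlap) next
      r <- spearman_cor(a$D[match(shared, a$domain_id)],
                        b$D[match(shared, b$domain_id)])
      pairs <- rbind(pairs, data.frame(
        model_a = ids[i], model_b = ids[j], r = r, n = length(shared),
        stringsAsFactors = FALSE))
    }
  }
  if (is.null(pairs))
    stop("no model pair with at least ", min_overlap, " overlapping domains")
  list(pairs = pairs,
       mean_correlation = sum(pairs$n * pairs$r) / sum(pairs$n))
}

#' Overlapping-domain removal randomization
#'
#' Domains appearing in more than one model could inflate significance in
#' the across-model analyses. Per replicate, every such domain is retained
#' in exactly one uniformly chosen model and deleted from the others; the
#' meta-analysis (and, optionally, the permutation test) is then rerun on
#' the thinned data. With no shared domains every replicate equals the
#' unrandomized analysis.
#'
#' @param records List of per-model covariate tables (or
#'   `list(cov =, ...)` entries); domains are matched across models by
#'   `domain_id`.
#' @param pair Character vector of the two variable names.
#' @param n_rep Number of randomization replicates (default 1000).
#' @param seed Optional integer seed.
#' @param n_perm Permutations for the per-replicate permutation test; `0`
#'   (default) skips the test and returns only the mean correlations.
#' @param scheme Permutation scheme passed to [permutation_test()] when
#'   `n_perm > 0`.
#' @return List with `replicates` (data frame with `rho0` and, when
#'   computed, `p_value` per replicate), `quantiles` (50th, 5th and 95th
#'   quantiles of each column), and `retention` (domain x model matrix
#'   counting how often each shared domain was retained in each model).
#' @export
overlap_randomization <- function(records, pair = c("omega", "D"),
                                  n_rep = 1000, seed = NULL, n_perm = 0,
                                  scheme = "domain_level") {
  if (!is.null(seed)) set.seed(seed)
  records <- normalize_records(records)
  ids <- names(records)
  if (is.null(ids)) ids <- as.character(seq_along(records))
  dom_models <- list() # domain_id -> integer vector of model indices
  for (i in seq_along(records))
    for (d in unique(records[[i]]$cov$domain_id))
      dom_models[[d]] <- c(dom_models[[d]], i)
  shared <- names(dom_models)[vapply(dom_models, length, integer(1)) > 1]
  retention <- matrix(0L, length(shared), length(records),
                      dimnames = list(shared, ids))
  rho0 <- numeric(n_rep)
  pval <- if (n_perm > 0) numeric(n_rep) else NULL
  for (b in seq_len(n_rep)) {
    keep_in <- vapply(shared, function(d) {
      ms <- dom_models[[d]]
      ms[sample.int(length(ms), 1)]
    }, integer(1))
    if (length(shared))
      retention[cbind(shared, ids[keep_in])] <-
        retention[cbind(shared, ids[keep_in])] + 1L
    thinned <- lapply(seq_along(records), function(i) {
      m <- records[[i]]
      drop_doms <- shared[keep_in != i]
      m$cov <- m$cov[!(m$cov$domain_id %in% drop_doms), , drop = FALSE]
      m
    })
    rho0[b] <- suppressWarnings(meta_correlation(thinned, pair))$rho0
    if (n_perm > 0)
      pval[b] <- suppressWarnings(
        permutation_test(thinned, pair, scheme = scheme,
                         n_perm = n_perm))$p_value
  }
  reps <- data.frame(rho0 = rho0)
  if (!is.null(pval)) reps$p_value <- pval
  qs <- vapply(reps, stats::quantile, numeric(3), probs = c(0.5, 0.05, 0.95))
  rownames(qs) <- c("q50", "q05", "q95")
  list(replicates = reps, quantiles = qs, retention = retention)
}
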