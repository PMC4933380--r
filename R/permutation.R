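# Structured permutation tests of the null hypothesis that two domain
# variables are independent within each network. Three schemes match the
# level at which each variable is defined:
#   param_influence — domain influences are not independent (domains share
#       reactions), so the rate-parameter influences kappa, the most basic
#       unit, are permuted within each model and the domain influence D is
#       recomputed from the permuted kappa;
#   domain_level    — domain-level variables (evolutionary rate omega) are
#       permuted directly within each model;
#   protein_level   — protein-level covariates (B, X, d, C, E, Gr) are
#       permuted at the protein level, so domains of one protein always
#       keep identical covariate values.
# The test statistic is the sample-size-weighted mean correlation across
# models; permutations are carried out independently within each model.

# One permuted copy of a model's covariate table under a scheme.
permute_model_cov <- function(cov, scheme, pair,
                              kappa = NULL, annotation = NULL,
                              joint = TRUE) {
  out <- cov
  if (scheme == "param_influence") {
    if (!"D" %in% pair)
      stop("param_influence scheme requires 'D' in the variable pair")
    if (is.null(kappa) || is.null(annotation))
      stop("param_influence scheme needs per-model kappa and annotation")
    perm_kappa <- kappa
    perm_kappa$kappa <- sample(kappa$kappa)
    dom <- suppressMessages(domain_influence(perm_kappa, annotation))
    idx <- match(out$domain_id, dom$domain_id)
    if (anyNA(idx))
      stop("covariate table has domain(s) absent from the annotation")
    out$D <- dom$D[idx]
  } else if (scheme == "domain_level") {
    target <- intersect(pair, .domain_level_vars)
    if (!length(target)) stop("no domain-level variable in the pair")
    target <- if ("omega" %in% target) "omega" else target[1]
    out[[target]] <- sample(out[[target]])
  } else if (scheme == "protein_level") {
    target <- intersect(pair, .protein_level_vars)
    if (!length(target)) stop("no protein-level variable in the pair")
    prot <- unique(out$protein_id)
    perm <- sample(length(prot))
    vars <- if (joint) .protein_level_vars else target
    pidx <- match(out$protein_id, prot)
    for (v in vars) {
      pv <- out[[v]][match(prot, out$protein_id)] # one value per protein
      out[[v]] <- pv[perm][pidx]
    }
  } else stop("unknown permutation scheme: ", scheme)
  out
}

# Weighted mean correlation (the meta-analytic statistic) over prepared
# per-model complete-case tables.
weighted_mean_cor <- function(models, pair) {
  r <- vapply(models, function(m) cor_pair(m$cov, pair), numeric(1))
  n <- vapply(models, function(m) nrow(m$cov), numeric(1))
  sum(n * r) / sum(n)
}

#' Permutation test for independence of two domain variables
#'
#' Tests the null hypothesis that the two variables are independent within
#' networks, by comparing the observed sample-size-weighted mean correlation
#' across models against its distribution under within-model permutation.
#' The permutation scheme respects the level at which the permuted variable
#' is defined (see the scheme descriptions in the Details of this file's
#' functions): `"param_influence"` permutes rate-constant influences and
#' recomputes domain influence, `"domain_level"` permutes the domain-level
#' variable, `"protein_level"` permutes protein-level covariate tuples among
#' proteins. The two-sided p-value is the fraction of permuted absolute mean
#' correlations at least as large as the observed absolute mean correlation;
#' when no permuted value is as extreme the p-value is reported as
#' `< 1/N_perm`.
#'
#' @param records List of per-model records: covariate data frames, or
#'   `list(cov =, kappa =, annotation =)` (the latter two required for the
#'   `param_influence` scheme).
#' @param pair Character vector of the two variable names.
#' @param scheme One of `"param_influence"`, `"domain_level"`,
#'   `"protein_level"`.
#' @param n_perm Number of permutations (default 10000; fewer than 100 is
#'   warned against).
#' @param seed Optional integer seed.
#' @param joint For `protein_level`: permute all protein-level covariates as
#'   one tuple per protein (`TRUE`, default) or only the tested covariate
#'   (`FALSE`).
#' @return A `permutation_result`: list with `observed`, `null` (length
#'   `n_perm`), `p_value` (in `(0, 1]`), `n_exceed`, `below_resolution`,
#'   `p_label`, `n_perm`, `scheme`, `seed`.
#' @export
permutation_test <- function(records, pair, scheme = "domain_level",
                             n_perm = 10000, seed = NULL, joint = TRUE) {
  if (n_perm < 100)
    warning("n_perm < 100 gives a very coarse p-value resolution")
  if (!is.null(seed)) set.seed(seed)
  records <- normalize_records(records)
  # listwise deletion once; permutations act within the complete-case set
  models <- lapply(records, function(m) {
    cc <- stats::complete.cases(m$cov[, pair, drop = FALSE])
    cov <- m$cov[cc, , drop = FALSE]
    if (nrow(cov) < 3) return(NULL)
    list(cov = cov, kappa = m$kappa, annotation = m$annotation)
  })
  models <- models[!vapply(models, is.null, logical(1))]
  if (!length(models)) stop("no model with enough complete domains")
  observed <- weighted_mean_cor(models, pair)
  if (scheme == "domain_level" && !any(pair %in% .binary_vars)) {
    # permuting y then ranking equals permuting the ranks of y, so the
    # Spearman null can be computed as Pearson on precomputed ranks,
    # vectorized over permutations within each model
    target <- if ("omega" %in% pair) "omega" else
      intersect(pair, .domain_level_vars)[1]
    other <- setdiff(pair, target)[1]
    n_tot <- sum(vapply(models, function(m) nrow(m$cov), numeric(1)))
    null <- numeric(n_perm)
    for (m in models) {
      n <- nrow(m$cov)
      rx <- rank(m$cov[[other]])
      ry <- rank(m$cov[[target]])
      P <- vapply(seq_len(n_perm), function(b) sample.int(n), integer(n))
      r_m <- as.vector(stats::cor(rx, matrix(ry[P], n, n_perm)))
      null <- null + n * r_m / n_tot
    }
    return(permutation_result(observed, null, n_perm, scheme, seed))
  }
  null <- vapply(seq_len(n_perm), function(b) {
    perm <- lapply(models, function(m) {
      m$cov <- permute_model_cov(m$cov, scheme, pair,
                                 kappa = m$kappa, annotation = m$annotation,
                                 joint = joint)
      m
    })
    weighted_mean_cor(perm, pair)
  }, numeric(1))
  permutation_result(observed, null, n_perm, scheme, seed)
}

permutation_result <- function(observed, null, n_perm, scheme, seed) {
  n_exceed <- sum(abs(null) >= abs(observed))
  below <- n_exceed == 0
  p <- if (below) 1 / n_perm else n_exceed / n_perm
  structure(list(observed = observed, null = null,
                 p_value = p, n_exceed = n_exceed,
                 below_resolution = below,
                 p_label = if (below) sprintf("<%g", 1 / n_perm)
                           else sprintf("%g", p),
                 n_perm = n_perm, scheme = scheme, seed = seed),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "<permutation_result> scheme %s: observed mean r = %+.4f, two-sided p %s (N_perm = %d)\n",
    x$scheme, x$observed, x$p_label, x$n_perm))
  invisible(x)
}

#' Residual permutation test for a partial correlation
#'
#' Tests independence of two target variables after controlling for other
#' covariates. Within each model, the residuals from the ordinary
#' least-squares fits of the targets on the controls are computed once; each
#' permutation then shuffles one residual vector against the other within
#' each model, recomputes the product-moment correlation, and combines
#' across models by sample-size weighting. This disrupts any relationship
#' between the targets while preserving every relationship with the
#' controls. With no controls it reduces to a plain correlation permutation
#' test. P-value convention as in [permutation_test()].
#'
#' @param records List of per-model covariate tables.
#' @param pair Character vector of the two target variable names.
#' @param controls Character vector of control variable names.
#' @param n_perm Number of permutations.
#' @param seed Optional integer seed.
#' @return A `permutation_result`.
#' @export
residual_permutation_test <- function(records, pair, controls,
                                      n_perm = 10000, seed = NULL) {
  if (n_perm < 100)
    warning("n_perm < 100 gives a very coarse p-value resolution")
  if (!is.null(seed)) set.seed(seed)
  records <- normalize_records(records)
  fits <- lapply(records, function(m)
    partial_correlation(m$cov, pair, controls))
  r <- vapply(fits, `[[`, numeric(1), "r")
  n <- vapply(fits, `[[`, numeric(1), "n")
  observed <- sum(n * r) / sum(n)
  null <- vapply(seq_len(n_perm), function(b) {
    rp <- vapply(fits, function(f) {
      e1 <- f$residuals[, 1][sample(f$n)]
      stats::cor(e1, f$residuals[, 2])
    }, numeric(1))
    sum(n * rp) / sum(n)
  }, numeric(1))
  permutation_result(observed, null, n_perm, "residual", seed)
}
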