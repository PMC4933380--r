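# Per-network correlation statistics and the Hunter-Schmidt random-effects
# meta-analysis of correlations across networks.

# Variables measured per domain vs. per protein; protein-level covariates
# are constant across the domains of one protein.
.domain_level_vars <- c("omega", "D")
.protein_level_vars <- c("B", "X", "d", "C", "E", "Gr")
.binary_vars <- "E"

#' Spearman rank correlation
#'
#' Product-moment correlation of the average-ranked (mid-rank) vectors.
#' A constant vector makes the correlation undefined and is signalled as an
#' error rather than returned as `NA`.
#'
#' @param x,y Numeric vectors of equal length >= 3; ties allowed.
#' @return The rank correlation in `[-1, 1]`.
#' @export
spearman_cor <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need at least 3 observations")
  if (anyNA(x) || anyNA(y)) stop("missing values; apply listwise deletion first")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("rank correlation undefined for a constant vector")
  stats::cor(x, y, method = "spearman")
}

#' Rank-biserial correlation
#'
#' Association between a continuous variable and a binary grouping, in
#' Cliff's-delta form: `rb = 2 U1 / (n1 n0) - 1`, where `U1` counts the
#' pairs in which the group-1 (essential / affected) value exceeds the
#' group-0 value, with half credit for ties. `+1` means complete separation
#' with group 1 larger; identical distributions give 0.
#'
#' @param x Numeric vector.
#' @param group Binary vector (logical, or 0/1) of the same length; `1` /
#'   `TRUE` marks the affected group.
#' @return The rank-biserial correlation in `[-1, 1]`.
#' @export
rank_biserial <- function(x, group) {
  stopifnot(length(x) == length(group))
  if (anyNA(x) || anyNA(group)) stop("missing values; apply listwise deletion first")
  g <- as.logical(group)
  n1 <- sum(g); n0 <- sum(!g)
  if (n1 == 0 || n0 == 0) stop("both groups must be nonempty")
  # U1 from the rank sum with mid-ranks: equals #(x1 > x0) + 0.5 #(ties)
  U1 <- sum(rank(x)[g]) - n1 * (n1 + 1) / 2
  2 * U1 / (n1 * n0) - 1
}

# Correlation of one variable pair within one model's covariate table,
# after listwise deletion on the pair. Binary variables (essentiality) pair
# through the rank-biserial coefficient, all others through Spearman.
cor_pair <- function(cov, pair) {
  x <- cov[[pair[1]]]; y <- cov[[pair[2]]]
  if (pair[2] %in% .binary_vars) rank_biserial(x, y)
  else if (pair[1] %in% .binary_vars) rank_biserial(y, x)
  else spearman_cor(x, y)
}

#' Per-model correlation for one variable pair
#'
#' Applies listwise deletion on the two variables and computes the Spearman
#' rank correlation, or the rank-biserial correlation when one variable is
#' binary essentiality.
#'
#' @param cov A covariate table (see [load_covariate_table()]).
#' @param pair Character vector of two variable names among
#'   `omega, D, B, X, d, C, E, Gr`.
#' @return List with `r` (the correlation) and `n` (domains with complete
#'   data for the pair), or `NULL` when fewer than 3 complete domains
#'   remain.
#' @export
model_correlation <- function(cov, pair) {
  stopifnot(length(pair) == 2, all(pair %in% names(cov)))
  cc <- stats::complete.cases(cov[, pair])
  sub <- cov[cc, , drop = FALSE]
  if (nrow(sub) < 3) return(NULL)
  list(r = cor_pair(sub, pair), n = nrow(sub))
}

#' Partial correlation controlling for covariates
#'
#' Fits ordinary least-squares linear models of each target variable on the
#' control variables (binary controls entered as 0/1), and returns the
#' product-moment correlation between the two residual vectors. Domains are
#' included only when every target and control variable is measured
#' (listwise deletion across all variables).
#'
#' @param cov A covariate table.
#' @param pair Character vector of the two target variable names.
#' @param controls Character vector of control variable names (possibly
#'   empty, in which case the plain product-moment correlation of the
#'   targets is returned).
#' @return List with `r`, `n`, and `residuals` (an `n x 2` matrix of the
#'   two residual vectors).
#' @export
partial_correlation <- function(cov, pair, controls = character(0)) {
  stopifnot(length(pair) == 2, all(c(pair, controls) %in% names(cov)))
  vars <- c(pair, controls)
  cc <- stats::complete.cases(cov[, vars, drop = FALSE])
  sub <- cov[cc, vars, drop = FALSE]
  n <- nrow(sub)
  if (n < length(controls) + 3)
    stop("only ", n, " complete domains; need at least ",
         length(controls) + 3)
  X <- if (length(controls))
    as.matrix(as.data.frame(lapply(sub[, controls, drop = FALSE], as.numeric)))
  else matrix(numeric(0), n, 0)
  X <- cbind(`(Intercept)` = 1, X)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("rank-deficient control design matrix")
  res <- vapply(pair, function(v) qr.resid(qrX, as.numeric(sub[[v]])),
                numeric(n))
  if (any(apply(res, 2, stats::sd) < 1e-12 * max(1, apply(abs(res), 2, max), na.rm = TRUE)) ||
      any(apply(res, 2, stats::sd) == 0))
    stop("zero-variance residuals: a target is an exact linear function of the controls")
  list(r = stats::cor(res[, 1], res[, 2]), n = n, residuals = res)
}

#' Hunter-Schmidt random-effects meta-analysis of correlations
#'
#' Combines per-model correlations `r_i` with domain sample sizes `n_i`
#' under the random-effects model in which each network has its own true
#' correlation drawn from a population with mean `rho_0` and standard
#' deviation `sigma_rho`. The estimators are: mean correlation
#' `rho_0 = sum(n_i r_i) / sum(n_i)`; observed cross-sample variance
#' `sigma_r^2 = sum(n_i (r_i - rho_0)^2) / sum(n_i)`; sampling-error
#' variance `sigma_e^2 = [sum(n_i (1 - r_i^2)^2 / (n_i - 1))] / sum(n_i)`;
#' population variance `sigma_rho^2 = max(0, sigma_r^2 - sigma_e^2)`
#' (truncated at zero); standard error `SE = sigma_r / sqrt(K)` with `K` the
#' number of models; 95% CI `rho_0 +/- 1.96 SE`.
#'
#' @param r Numeric vector of per-model correlations, or a list of
#'   `list(r =, n =)` pairs as returned by [model_correlation()].
#' @param n Integer vector of per-model sample sizes (ignored when `r` is a
#'   list).
#' @return A `meta_analysis_result`: list with `rho0`, `var_r`, `var_e`,
#'   `sd_rho`, `se`, `ci` (length-2), `K`, `r`, `n`.
#' @export
hunter_schmidt_meta <- function(r, n = NULL) {
  if (is.list(r)) {
    n <- vapply(r, `[[`, numeric(1), "n")
    r <- vapply(r, `[[`, numeric(1), "r")
  }
  stopifnot(length(r) == length(n), length(r) >= 1)
  if (any(!is.finite(r)) || any(abs(r) > 1)) stop("correlations must lie in [-1, 1]")
  if (any(n <= 1)) stop("every study needs n > 1")
  rho0 <- sum(n * r) / sum(n)
  var_r <- sum(n * (r - rho0)^2) / sum(n)
  var_e <- sum(n * (1 - r^2)^2 / (n - 1)) / sum(n)
  sd_rho <- sqrt(max(0, var_r - var_e))
  K <- length(r)
  se <- sqrt(var_r) / sqrt(K)
  structure(list(rho0 = rho0, var_r = var_r, var_e = var_e, sd_rho = sd_rho,
                 se = se, ci = rho0 + c(-1.96, 1.96) * se, K = K,
                 r = r, n = n),
            class = "meta_analysis_result")
}

#' @export
print.meta_analysis_result <- function(x, ...) {
  cat(sprintf(
    "<meta_analysis_result> rho0 = %+.3f (95%% CI %+.3f, %+.3f), sigma_rho = %.3f, K = %d\n",
    x$rho0, x$ci[1], x$ci[2], x$sd_rho, x$K))
  invisible(x)
}

# Normalize the per-model records argument used by the meta-analytic and
# permutation machinery: each element is either a covariate data frame or a
# list(cov =, kappa =, annotation =).
normalize_records <- function(records) {
  lapply(records, function(m) {
    if (is.data.frame(m)) list(cov = m, kappa = NULL, annotation = NULL)
    else {
      stopifnot(is.list(m), is.data.frame(m$cov))
      list(cov = m$cov,
           kappa = m$kappa,
           annotation = m$annotation)
    }
  })
}

#' Meta-analytic correlation for one variable pair across models
#'
#' Computes the per-model correlation (with listwise deletion) for each
#' network and combines them with [hunter_schmidt_meta()]. Models with
#' fewer than 3 complete domains are dropped with a warning.
#'
#' @param records List of per-model covariate tables (or
#'   `list(cov =, ...)` entries).
#' @param pair Character vector of two variable names.
#' @return A `meta_analysis_result`.
#' @export
meta_correlation <- function(records, pair) {
  records <- normalize_records(records)
  rs <- lapply(records, function(m) model_correlation(m$cov, pair))
  drop <- vapply(rs, is.null, logical(1))
  if (any(drop))
    warning(sum(drop), " model(s) dropped: fewer than 3 complete domains")
  rs <- rs[!drop]
  if (!length(rs)) stop("no model with enough complete domains for ",
                        paste(pair, collapse = " vs "))
  hunter_schmidt_meta(rs)
}

#' Meta-analytic partial correlation across models
#'
#' Per-model partial correlations via [partial_correlation()], combined
#' with [hunter_schmidt_meta()].
#'
#' @param records List of per-model covariate tables.
#' @param pair Character vector of the two target variables.
#' @param controls Character vector of control variables.
#' @return A `meta_analysis_result`.
#' @export
meta_partial_correlation <- function(records, pair, controls) {
  records <- normalize_records(records)
  rs <- lapply(records, function(m)
    partial_correlation(m$cov, pair, controls)[c("r", "n")])
  hunter_schmidt_meta(rs)
}
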