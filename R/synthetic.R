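# Download-free synthetic fixtures: mass-action signaling cascades with a
# ligand stimulus, rate-constant ensembles, and multi-network domain
# populations with a planted random-effects correlation structure.

#' Synthetic mass-action signaling cascade
#'
#' Builds a ligand -> receptor -> kinase cascade in mass-action kinetics:
#' the ligand `L` binds receptor `R0` reversibly to form the active complex
#' `LR`; each tier's activator then reversibly binds the next kinase
#' (binding `kb`, unbinding `ku`), phosphorylates it (`kc`), and a
#' first-order dephosphorylation (`kd`) closes the cycle. Rate constants
#' are drawn log-normally around 1 (sdlog 0.5), so each seed gives a
#' distinct but dynamically well-behaved network. Total protein mass
#' (free + bound + phosphorylated forms) is conserved along trajectories.
#'
#' Domains partition each protein's rate constants: the receptor carries a
#' ligand-binding domain (`k1p`, `k1m`); with a single tier the kinase
#' carries one binding domain holding its four-parameter motif
#' (phosphorylation, dephosphorylation, kinase-binding, kinase-unbinding);
#' deeper cascades split each kinase into a kinase-binding domain
#' (`kb`, `ku`) and a phospho-site domain (`kc`, `kd`), and additionally
#' map each tier's catalytic constant to the upstream kinase's catalytic
#' domain, exercising the many-to-many annotation contract.
#'
#' Stimulation conditions add ligand at t = 0 (`L` overridden from 0 to
#' each dose) and simulate over a horizon long enough for the cascade to
#' respond through all tiers.
#'
#' @param n_tiers Number of kinase tiers (>= 1).
#' @param seed Optional integer seed; the same seed reproduces the network
#'   exactly.
#' @param doses Ligand doses, one stimulation condition per dose.
#' @param horizon Simulation horizon `T_c` per condition; default
#'   `10 + 5 * n_tiers`.
#' @return List with `network` (a `reaction_network`), `annotation` (a
#'   `domain_annotation`) and `conditions` (list of
#'   `stimulation_condition`).
#' @export
make_cascade_network <- function(n_tiers = 3, seed = NULL,
                                 doses = c(0.5, 2),
                                 horizon = 10 + 5 * n_tiers) {
  stopifnot(n_tiers >= 1, length(doses) >= 1, all(doses > 0))
  if (!is.null(seed)) set.seed(seed)
  draw <- function(n) exp(stats::rnorm(n, 0, 0.5))

  species <- data.frame(
    id = c("L", "R", "LR"),
    initial = c(0, 1, 0),
    protein = c("L", "R0", "L;R0"),
    stringsAsFactors = FALSE)
  parameters <- data.frame(
    id = c("k1p", "k1m"), value = draw(2), rate_constant = TRUE,
    stringsAsFactors = FALSE)
  reactions <- list(
    list(id = "lig_bind", stoich = c(L = -1, R = -1, LR = 1),
         rate = "k1p * L * R"),
    list(id = "lig_unbind", stoich = c(L = 1, R = 1, LR = -1),
         rate = "k1m * LR"))
  ann <- data.frame(protein_id = "R0", domain_id = "R0-LB",
                    param_id = c("k1p", "k1m"), stringsAsFactors = FALSE)

  act <- "LR"          # activator species feeding the next tier
  act_prot <- "L;R0"   # its protein membership
  act_name <- "R0"     # protein owning the catalytic function upstream
  for (i in seq_len(n_tiers)) {
    kin <- paste0("K", i)
    E <- paste0("E", i); Cx <- paste0("C", i); Ep <- paste0("Ep", i)
    kb <- paste0("kb", i); ku <- paste0("ku", i)
    kc <- paste0("kc", i); kd <- paste0("kd", i)
    species <- rbind(species, data.frame(
      id = c(E, Cx, Ep),
      initial = c(1, 0, 0),
      protein = c(kin, paste(act_prot, kin, sep = ";"), kin),
      stringsAsFactors = FALSE))
    parameters <- rbind(parameters, data.frame(
      id = c(kb, ku, kc, kd), value = draw(4), rate_constant = TRUE,
      stringsAsFactors = FALSE))
    st_bind <- c(-1, -1, 1); names(st_bind) <- c(act, E, Cx)
    st_unbind <- -st_bind
    st_cat <- c(1, -1, 1); names(st_cat) <- c(act, Cx, Ep)
    st_deph <- c(1, -1); names(st_deph) <- c(E, Ep)
    reactions <- c(reactions, list(
      list(id = paste0("bind", i), stoich = st_bind,
           rate = sprintf("%s * %s * %s", kb, act, E)),
      list(id = paste0("unbind", i), stoich = st_unbind,
           rate = sprintf("%s * %s", ku, Cx)),
      list(id = paste0("cat", i), stoich = st_cat,
           rate = sprintf("%s * %s", kc, Cx)),
      list(id = paste0("dephos", i), stoich = st_deph,
           rate = sprintf("%s * %s", kd, Ep))))
    if (n_tiers == 1) {
      ann <- rbind(ann, data.frame(
        protein_id = kin, domain_id = paste0(kin, "-KB"),
        param_id = c(kb, ku, kc, kd), stringsAsFactors = FALSE))
    } else {
      ann <- rbind(ann, data.frame(
        protein_id = kin,
        domain_id = paste0(kin, c("-KB", "-KB", "-PS", "-PS")),
        param_id = c(kb, ku, kc, kd), stringsAsFactors = FALSE))
      if (i >= 2) # catalysis also occurs at the upstream kinase's catalytic domain
        ann <- rbind(ann, data.frame(
          protein_id = act_name, domain_id = paste0(act_name, "-CAT"),
          param_id = kc, stringsAsFactors = FALSE))
    }
    act <- Ep; act_prot <- kin; act_name <- kin
  }

  net <- reaction_network(paste0("cascade", n_tiers), species, parameters,
                          reactions)
  conds <- lapply(seq_along(doses), function(ci)
    stimulation_condition(paste0("ligand_dose_", doses[ci]),
                          list(L = doses[ci]), horizon))
  list(network = net,
       annotation = load_domain_annotation(ann, net),
       conditions = conds)
}

#' Synthetic multi-network domain population
#'
#' Emulates the random-effects model behind the meta-analysis: each of `K`
#' networks has its own true influence/evolutionary-rate correlation
#' `rho_i ~ Normal(rho0, sigma_rho^2)`, truncated to (-0.999, 0.999), and
#' its domains' `(omega, D)` pairs are drawn from a Gaussian copula whose
#' latent Pearson correlation `2 sin(pi rho_i / 6)` targets a Spearman
#' correlation of `rho_i`. `omega` is mapped to a positive dN/dS-like
#' log-normal scale (median 0.1) and `D` to a positive log-normal scale
#' spanning orders of magnitude; only ranks enter the downstream
#' statistics. Protein-level covariates (`B`, `X`, `d`, `C`, `E`, `Gr`)
#' are drawn per protein from a latent Gaussian with a common pairwise
#' cross-correlation, mapped to their natural scales (tissue counts,
#' log-normal expression, count-like degree, a [0, 1] centrality, binary
#' essentiality at a set prevalence, a relative growth rate), and repeated
#' identically across each protein's domains. By default they are
#' independent of `(omega, D)`, so the planted signal is exactly the
#' `omega`-`D` population correlation.
#'
#' @param K Number of networks (default 18).
#' @param rho0 Population mean Spearman correlation between `omega` and `D`.
#' @param sigma_rho Population standard deviation of the per-network
#'   correlation (>= 0).
#' @param n_range Integer range of per-network domain counts.
#' @param cov_cor Common pairwise correlation among the latent protein-level
#'   covariates (must give a positive semi-definite latent matrix).
#' @param essential_prev Prevalence of essentiality (fraction of proteins).
#' @param shared_frac Fraction of each network's domains drawn from a
#'   global shared pool, so the same `domain_id` (and `protein_id`) recurs
#'   across networks; 0 (default) makes all domains network-private.
#' @param seed Optional integer seed.
#' @return Named list of `K` covariate tables (see
#'   [load_covariate_table()] for the column contract).
#' @export
make_meta_population <- function(K = 18, rho0 = -0.25, sigma_rho = 0.15,
                                 n_range = c(8, 40), cov_cor = 0.25,
                                 essential_prev = 0.5, shared_frac = 0,
                                 seed = NULL) {
  stopifnot(K >= 1, abs(rho0) <= 1, sigma_rho >= 0,
            shared_frac >= 0, shared_frac < 1)
  if (!is.null(seed)) set.seed(seed)
  p <- length(.protein_level_vars)
  Sig <- matrix(cov_cor, p, p); diag(Sig) <- 1
  Lchol <- tryCatch(chol(Sig), error = function(e)
    stop("infeasible covariate correlation matrix (not positive definite)"))
  pool_size <- if (shared_frac > 0)
    max(4L, ceiling(shared_frac * max(n_range))) else 0L
  out <- vector("list", K)
  names(out) <- paste0("M", seq_len(K))
  for (i in seq_len(K)) {
    rho_i <- max(-0.999, min(0.999, stats::rnorm(1, rho0, sigma_rho)))
    n_i <- sample(seq(n_range[1], n_range[2]), 1)
    n_shared <- if (pool_size > 0) min(pool_size, round(shared_frac * n_i)) else 0L
    shared_ids <- if (n_shared > 0)
      sample(paste0("SD", seq_len(pool_size)), n_shared) else character(0)
    # domains -> proteins: shared domains sit on their own shared protein,
    # private domains are grouped 1-3 per private protein
    n_priv <- n_i - n_shared
    priv_prot <- integer(0)
    while (length(priv_prot) < n_priv)
      priv_prot <- c(priv_prot,
                     rep(length(unique(priv_prot)) + 1L,
                         sample(1:3, 1)))
    priv_prot <- priv_prot[seq_len(n_priv)]
    domain_id <- c(shared_ids,
                   if (n_priv > 0) paste0(names(out)[i], "_D", seq_len(n_priv)))
    protein_id <- c(sub("^SD", "SP", shared_ids),
                    if (n_priv > 0) paste0(names(out)[i], "_P", priv_prot))
    # latent bivariate Gaussian targeting Spearman rho_i at the domain level
    r_lat <- 2 * sin(pi * rho_i / 6)
    z1 <- stats::rnorm(n_i)
    z2 <- r_lat * z1 + sqrt(1 - r_lat^2) * stats::rnorm(n_i)
    omega <- stats::qlnorm(stats::pnorm(z1), meanlog = log(0.1), sdlog = 0.8)
    D <- stats::qlnorm(stats::pnorm(z2), meanlog = 0, sdlog = 1.5)
    # protein-level covariates: one latent Gaussian row per protein
    prots <- unique(protein_id)
    Z <- matrix(stats::rnorm(length(prots) * p), length(prots), p) %*% Lchol
    U <- stats::pnorm(Z)
    ptab <- data.frame(
      protein_id = prots,
      B = ceiling(U[, 1] * 45),
      X = stats::qlnorm(U[, 2], meanlog = log(100), sdlog = 1),
      d = stats::qpois(U[, 3], lambda = 8),
      C = stats::qbeta(U[, 4], 1, 8),
      E = as.integer(U[, 5] < essential_prev),
      Gr = stats::qbeta(U[, 6], 8, 2),
      stringsAsFactors = FALSE)
    idx <- match(protein_id, ptab$protein_id)
    out[[i]] <- data.frame(
      domain_id = domain_id, protein_id = protein_id,
      omega = omega, D = D,
      B = ptab$B[idx], X = ptab$X[idx], d = ptab$d[idx],
      C = ptab$C[idx], E = ptab$E[idx], Gr = ptab$Gr[idx],
      stringsAsFactors = FALSE)
  }
  out
}

#' Synthetic rate-constant ensemble
#'
#' Stands in for an ensemble of parameter sets consistent with experimental
#' data: each set multiplies every reference rate constant `k*` by an
#' independent log-normal factor `exp(N(0, log_jitter_sd^2))`. With
#' `log_jitter_sd = 0` every set equals `k*`.
#'
#' @param net A `reaction_network`; only parameters flagged as rate
#'   constants are jittered.
#' @param n_sets Ensemble size (>= 2).
#' @param log_jitter_sd Standard deviation of the log-factors.
#' @param seed Optional integer seed.
#' @return Data frame with `set_id` plus one column per rate constant (the
#'   layout written/read by [write_ensemble_tsv()] /
#'   [read_ensemble_tsv()]).
#' @export
make_parameter_ensemble <- function(net, n_sets, log_jitter_sd = 0.1,
                                    seed = NULL) {
  stopifnot(inherits(net, "reaction_network"), n_sets >= 2,
            log_jitter_sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  sel <- net$parameters$rate_constant
  k_ids <- net$parameters$id[sel]
  kstar <- net$parameters$value[sel]
  sets <- as.data.frame(t(vapply(seq_len(n_sets), function(s)
    kstar * exp(stats::rnorm(length(kstar), 0, log_jitter_sd)),
    numeric(length(kstar)))))
  names(sets) <- k_ids
  cbind(data.frame(set_id = paste0("set", seq_len(n_sets)),
                   stringsAsFactors = FALSE), sets)
}

#' Write a rate-constant ensemble to TSV
#'
#' Values are serialized with 17 significant digits so a round-trip through
#' the file reproduces them exactly.
#'
#' @param sets Data frame from [make_parameter_ensemble()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ensemble_tsv <- function(sets, path) {
  out <- sets
  for (v in setdiff(names(out), "set_id")) out[[v]] <- .num_chr(out[[v]])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a rate-constant ensemble from TSV
#'
#' @param path Path to a TSV written by [write_ensemble_tsv()].
#' @return Data frame with `set_id` plus one numeric column per parameter.
#' @export
read_ensemble_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"set_id" %in% names(tab)) stop("ensemble TSV needs a set_id column")
  for (v in setdiff(names(tab), "set_id")) tab[[v]] <- as.numeric(tab[[v]])
  tab
}
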