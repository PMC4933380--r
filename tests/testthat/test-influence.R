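# Domain aggregation (geometric mean), key-species restriction, and
# ensemble comparison.

test_that("domain influence is the geometric mean of its parameters' kappa", {
  infl <- structure(
    data.frame(param_id = c("p1", "p2", "p3", "p4", "p5"),
               kappa = c(4, 9, 7, 1e-2, 1e-6)),
    class = c("influence_table", "data.frame"))
  ann <- data.frame(
    protein_id = c("P", "P", "P", "Q", "Q"),
    domain_id = c("d_two", "d_two", "d_one", "d_log", "d_log"),
    param_id = c("p1", "p2", "p3", "p4", "p5"))
  dom <- domain_influence(infl, ann)
  expect_equal(dom$D[dom$domain_id == "d_two"], 6)         # sqrt(4 * 9)
  expect_equal(dom$D[dom$domain_id == "d_one"], 7)         # identity
  expect_equal(dom$D[dom$domain_id == "d_log"], 1e-4)      # log-scale mean
  expect_equal(dom$N_d, c(2L, 1L, 2L))
  # bounds: min kappa <= D <= max kappa within each domain
  for (i in seq_len(nrow(dom))) {
    kk <- infl$kappa[infl$param_id %in% ann$param_id[ann$domain_id == dom$domain_id[i]]]
    expect_gte(dom$D[i], min(kk) * (1 - 1e-12))
    expect_lte(dom$D[i], max(kk) * (1 + 1e-12))
  }
})

test_that("a zero-kappa parameter propagates D = 0 and is reported", {
  infl <- structure(data.frame(param_id = c("p1", "p2"), kappa = c(0, 5)),
                    class = c("influence_table", "data.frame"))
  ann <- data.frame(protein_id = "P", domain_id = "d", param_id = c("p1", "p2"))
  expect_message(dom <- domain_influence(infl, ann), "D = 0")
  expect_equal(dom$D, 0)
})

test_that("domain influence is permutation-invariant and homogeneous", {
  set.seed(77)
  for (rep in 1:5) {
    kk <- exp(rnorm(6))
    infl <- structure(data.frame(param_id = paste0("p", 1:6), kappa = kk),
                      class = c("influence_table", "data.frame"))
    ann <- data.frame(protein_id = "P", domain_id = "d", param_id = paste0("p", 1:6))
    d0 <- domain_influence(infl, ann)$D
    perm <- infl; perm$kappa <- sample(kk)
    expect_equal(domain_influence(perm, ann)$D, d0)
    scl <- infl; scl$kappa <- 3 * kk
    expect_equal(domain_influence(scl, ann)$D, 3 * d0)
  }
})

test_that("annotation referencing an unscored parameter errors", {
  infl <- structure(data.frame(param_id = "p1", kappa = 1),
                    class = c("influence_table", "data.frame"))
  ann <- data.frame(protein_id = "P", domain_id = "d", param_id = c("p1", "p9"))
  expect_error(domain_influence(infl, ann), "unscored")
})

test_that("key-species restriction with the full set is the full computation", {
  cas <- make_cascade_network(n_tiers = 2, seed = 21)
  trajs <- simulate_conditions(cas$network, cas$conditions, 64)
  full <- parameter_influence(trajs, cas$network)
  key_all <- restrict_to_key_species(trajs, cas$network,
                                     cas$network$species$id)
  expect_identical(key_all$kappa, full$kappa)
  expect_identical(attr(key_all, "species_used"), "key")
})

test_that("excluding the only affected species zeroes kappa", {
  # two uncoupled decays: restricting to A removes all influence of kB
  net <- reaction_network(
    "two_decays",
    species = data.frame(id = c("A", "B"), initial = c(1, 1), protein = NA),
    parameters = data.frame(id = c("kA", "kB"), value = c(1, 2),
                            rate_constant = TRUE),
    reactions = list(
      list(id = "dA", stoich = c(A = -1), rate = "kA * A"),
      list(id = "dB", stoich = c(B = -1), rate = "kB * B"))
  )
  trajs <- list(simulate_with_sensitivities(net, decay_condition(1), 64))
  key <- restrict_to_key_species(trajs, net, "A")
  expect_equal(key$kappa[key$param_id == "kB"], 0)
  expect_gt(key$kappa[key$param_id == "kA"], 0)
  expect_error(restrict_to_key_species(trajs, net, "nope"), "unknown species")
  expect_error(restrict_to_key_species(trajs, net, character(0)), "nonempty")
})

test_that("full and key domain influences are positively rank-correlated", {
  cas <- make_cascade_network(n_tiers = 3, seed = 31)
  trajs <- simulate_conditions(cas$network, cas$conditions, 64)
  full <- domain_influence(parameter_influence(trajs, cas$network),
                           cas$annotation)
  key <- domain_influence(
    restrict_to_key_species(trajs, cas$network, c("Ep1", "Ep2", "Ep3")),
    cas$annotation)
  expect_gt(cor(full$D, key$D[match(full$domain_id, key$domain_id)],
                method = "spearman"), 0)
})

test_that("identical parameter sets give all pairwise correlations = 1", {
  D <- matrix(rep(c(3, 1, 2, 5), 4), ncol = 4,
              dimnames = list(paste0("d", 1:4), paste0("s", 1:4)))
  cmp <- compare_influence_ensembles(D, n_pairs = 100, seed = 1)
  expect_true(all(cmp$pair_correlations == 1))
  expect_equal(cmp$median_pair_correlation, 1)
})

test_that("a two-set ensemble yields exactly one distinct pair", {
  D <- cbind(s1 = c(1, 2, 3, 4), s2 = c(2, 1, 4, 3))
  rownames(D) <- paste0("d", 1:4)
  cmp <- compare_influence_ensembles(D, n_pairs = 10000, seed = 1)
  expect_equal(length(cmp$pair_correlations), 1)
  expect_error(compare_influence_ensembles(D[, 1, drop = FALSE]),
               "at least 2")
})

test_that("pairwise agreement decreases with log-parameter jitter", {
  cas <- make_cascade_network(n_tiers = 2, seed = 41, doses = 1)
  med <- sapply(c(0.1, 1.2), function(sd) {
    sets <- make_parameter_ensemble(cas$network, n_sets = 4,
                                    log_jitter_sd = sd, seed = 5)
    ens <- ensemble_domain_influence(cas$network, cas$conditions,
                                    cas$annotation, sets, n_grid = 48)
    compare_influence_ensembles(ens, seed = 2)$median_pair_correlation
  })
  expect_gt(med[1], 0.8)       # small jitter: close to 1
  expect_gt(med[1], med[2])    # monotone in jitter
})

test_that("ensemble comparison reports the influence-omega correlation sign", {
  D <- cbind(s1 = c(4, 3, 2, 1), s2 = c(4, 2, 3, 1), s3 = c(3, 4, 2, 1))
  rownames(D) <- paste0("d", 1:4)
  omega <- c(d1 = 0.1, d2 = 0.2, d3 = 0.3, d4 = 0.4) # opposite ranks
  cmp <- compare_influence_ensembles(D, n_pairs = 10, seed = 3, omega = omega)
  expect_equal(cmp$fraction_negative, 1)
})
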