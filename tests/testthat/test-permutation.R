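# Structured permutation schemes and p-value conventions.

test_that("param_influence scheme preserves the kappa multiset and recomputes D", {
  cas <- make_cascade_network(n_tiers = 2, seed = 61)
  trajs <- simulate_conditions(cas$network, cas$conditions, 48)
  infl <- parameter_influence(trajs, cas$network)
  dom <- domain_influence(infl, cas$annotation)
  cov <- data.frame(domain_id = dom$domain_id, protein_id = dom$protein_id,
                    omega = exp(rnorm(nrow(dom))), D = dom$D,
                    B = NA, X = NA, d = NA, C = NA, E = NA, Gr = NA)
  set.seed(1)
  for (rep in 1:5) {
    perm <- netinflux:::permute_model_cov(cov, "param_influence",
                                          c("omega", "D"),
                                          kappa = infl,
                                          annotation = cas$annotation)
    # D values come from SOME assignment of the same kappa multiset
    expect_false(identical(perm$omega, NULL))
    expect_equal(sort(unique(perm$domain_id)), sort(unique(cov$domain_id)))
    # single-parameter domains must take kappa values from the multiset
    single <- dom$domain_id[dom$N_d == 1]
    expect_true(all(perm$D[perm$domain_id %in% single] %in% infl$kappa))
    # omega untouched
    expect_identical(perm$omega, cov$omega)
  }
  expect_error(netinflux:::permute_model_cov(cov, "param_influence",
                                             c("omega", "B"),
                                             kappa = infl,
                                             annotation = cas$annotation),
               "requires 'D'")
})

test_that("protein_level scheme keeps domains of one protein identical", {
  recs <- make_meta_population(K = 3, seed = 71)
  set.seed(2)
  for (cov in recs) {
    perm <- netinflux:::permute_model_cov(cov, "protein_level",
                                          c("omega", "X"), joint = TRUE)
    for (v in c("B", "X", "d", "C", "E", "Gr")) {
      spread <- tapply(perm[[v]], perm$protein_id, function(z) max(z) - min(z))
      expect_true(all(spread == 0))
    }
    # the multiset of per-protein tuples is preserved
    expect_setequal(unique(perm$X), unique(cov$X))
    # joint permutation keeps covariate tuples together
    key0 <- paste(cov$B, cov$X, cov$d, cov$C, cov$E, cov$Gr)[!duplicated(cov$protein_id)]
    key1 <- paste(perm$B, perm$X, perm$d, perm$C, perm$E, perm$Gr)[!duplicated(perm$protein_id)]
    expect_setequal(key0, key1)
  }
})

test_that("domain_level scheme permutes omega within the model", {
  cov <- toy_records()$A
  set.seed(3)
  perm <- netinflux:::permute_model_cov(cov, "domain_level", c("omega", "D"))
  expect_setequal(perm$omega, cov$omega)
  expect_identical(perm$D, cov$D)
  expect_error(netinflux:::permute_model_cov(cov, "nonsense", c("omega", "D")),
               "unknown permutation scheme")
})

test_that("permutation p-values follow the two-sided convention", {
  recs <- toy_records()
  pt <- permutation_test(recs, c("omega", "D"), scheme = "domain_level",
                         n_perm = 200, seed = 5)
  expect_true(pt$p_value > 0 && pt$p_value <= 1)
  expect_equal(pt$p_value,
               if (pt$n_exceed == 0) 1 / 200 else pt$n_exceed / 200)
  if (pt$below_resolution) expect_match(pt$p_label, "^<")
  expect_length(pt$null, 200)
  expect_warning(
    permutation_test(recs, c("omega", "D"), n_perm = 50, seed = 5),
    "coarse")
})

test_that("a strong planted signal is detected; a null is not", {
  pop_alt <- make_meta_population(K = 8, rho0 = -0.7, sigma_rho = 0.05,
                                  n_range = c(25, 35), seed = 81)
  pt_alt <- permutation_test(pop_alt, c("omega", "D"),
                             scheme = "domain_level", n_perm = 400, seed = 6)
  expect_true(pt_alt$below_resolution)  # nothing as extreme in 400 draws
  pop_null <- make_meta_population(K = 8, rho0 = 0, sigma_rho = 0,
                                   n_range = c(25, 35), seed = 82)
  pt_null <- permutation_test(pop_null, c("omega", "D"),
                              scheme = "domain_level", n_perm = 400, seed = 7)
  expect_gt(pt_null$p_value, 0.01)
})

test_that("the observed statistic is seed-independent; only the null varies", {
  recs <- toy_records()
  p1 <- permutation_test(recs, c("omega", "D"), n_perm = 150, seed = 1)
  p2 <- permutation_test(recs, c("omega", "D"), n_perm = 150, seed = 2)
  expect_identical(p1$observed, p2$observed)
  expect_false(identical(p1$null, p2$null))
})

test_that("residual permutation reduces to a plain test with no controls", {
  recs <- toy_records()
  rp <- residual_permutation_test(recs, c("omega", "D"), character(0),
                                  n_perm = 200, seed = 9)
  # with no controls the residuals are centered raw values, so the observed
  # statistic is the weighted mean Pearson correlation
  r1 <- cor(recs$A$omega, recs$A$D); r2 <- cor(recs$B$omega, recs$B$D)
  expect_equal(rp$observed, (6 * r1 + 5 * r2) / 11, tolerance = 1e-12)
  expect_true(rp$p_value > 0 && rp$p_value <= 1)
})

test_that("residual permutation rejects at ~alpha under a mediated null", {
  # both targets are linear in the control plus independent noise, so the
  # partial association is null although the marginal one is strong
  set.seed(91)
  pvals <- replicate(25, {
    recs <- lapply(1:4, function(i) {
      n <- 30
      z <- rnorm(n)
      data.frame(domain_id = paste0("m", i, "_d", 1:n),
                 protein_id = paste0("m", i, "_p", 1:n),
                 omega = z + rnorm(n, sd = 0.5),
                 D = z + rnorm(n, sd = 0.5),
                 B = z, X = NA, d = NA, C = NA, E = NA, Gr = NA)
    })
    residual_permutation_test(recs, c("omega", "D"), "B",
                              n_perm = 150)$p_value
  })
  expect_lt(mean(pvals <= 0.05), 0.25)
  expect_gt(mean(pvals > 0.2), 0.3)
})

test_that("permutation p-values are approximately uniform under the null", {
  # distribution of p over independent null datasets at reduced N_perm
  set.seed(101)
  pvals <- replicate(40, {
    pop <- make_meta_population(K = 4, rho0 = 0, sigma_rho = 0,
                                n_range = c(12, 18))
    permutation_test(pop, c("omega", "D"), scheme = "domain_level",
                     n_perm = 120)$p_value
  })
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.001)
})
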