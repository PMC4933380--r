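test_that("a minimal decay model builds and validates", {
  net <- decay_network()
  expect_s3_class(net, "reaction_network")
  expect_equal(nrow(net$species), 1)
  expect_equal(nrow(net$parameters), 1)
})

test_that("validation rejects dangling references and bad rate laws", {
  expect_error(reaction_network(
    "bad",
    species = data.frame(id = "A", initial = 1, protein = NA),
    parameters = data.frame(id = "k", value = 1, rate_constant = TRUE),
    reactions = list(list(id = "r", stoich = c(A = -1), rate = "k * Z"))
  ), "undeclared symbol")
  expect_error(reaction_network(
    "bad2",
    species = data.frame(id = "A", initial = 1, protein = NA),
    parameters = data.frame(id = "k", value = 1, rate_constant = TRUE),
    reactions = list(list(id = "r", stoich = c(A = -1, Q = 1), rate = "k * A"))
  ), "undeclared species")
  expect_error(reaction_network(
    "bad3",
    species = data.frame(id = c("A", "A"), initial = c(1, 2), protein = NA),
    parameters = data.frame(id = "k", value = 1, rate_constant = TRUE),
    reactions = list()
  ), "duplicate species")
  # division by a zero initial concentration -> non-finite at initial state
  expect_error(reaction_network(
    "bad4",
    species = data.frame(id = c("A", "B"), initial = c(1, 0), protein = NA),
    parameters = data.frame(id = "k", value = 1, rate_constant = TRUE),
    reactions = list(list(id = "r", stoich = c(A = -1), rate = "k * A / B"))
  ), "non-finite")
})

test_that("validation rejects randomly corrupted rate laws", {
  set.seed(202)
  for (rep in 1:10) {
    cas <- make_cascade_network(n_tiers = 2, seed = rep)
    net <- cas$network
    j <- sample(length(net$reactions), 1)
    bad_sym <- paste0("ghost", rep)
    net$reactions[[j]]$rate <- paste(net$reactions[[j]]$rate, "*", bad_sym)
    expect_error(validate_network(net), "undeclared symbol")
  }
})

test_that("native YAML round-trip preserves every field bit-for-bit", {
  cas <- make_cascade_network(n_tiers = 3, seed = 99)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_network_yaml(cas$network, path)
  back <- read_network_yaml(path)
  expect_identical(back$model_id, cas$network$model_id)
  expect_identical(back$species, cas$network$species)
  expect_identical(back$parameters, cas$network$parameters)
  expect_identical(back$reactions, cas$network$reactions)

  cpath <- withr::local_tempfile(fileext = ".yaml")
  write_conditions_yaml(cas$conditions, cpath)
  back_c <- read_conditions_yaml(cpath)
  expect_equal(back_c, cas$conditions, ignore_attr = TRUE)
})

test_that("apply_condition overrides a copy and leaves the original intact", {
  cas <- make_cascade_network(n_tiers = 1, seed = 3)
  net <- cas$network
  out <- apply_condition(net, stimulation_condition("stim", list(L = 1), 5))
  expect_equal(out$species$initial[out$species$id == "L"], 1)
  expect_equal(net$species$initial[net$species$id == "L"], 0)
  expect_equal(out$species$initial[out$species$id != "L"],
               net$species$initial[net$species$id != "L"])
  # empty override map is the identity
  same <- apply_condition(net, stimulation_condition("null", list(), 5))
  expect_identical(same$species, net$species)
  expect_identical(same$parameters, net$parameters)
  expect_error(
    apply_condition(net, stimulation_condition("bad", list(nope = 1), 5)),
    "unknown id")
})

test_that("overriding a rate constant changes the simulated dynamics", {
  cas <- make_cascade_network(n_tiers = 1, seed = 3)
  base <- stimulation_condition("b", list(L = 1), 5)
  slow <- stimulation_condition("s", list(L = 1, kc1 = cas$network$parameters$value[
    cas$network$parameters$id == "kc1"] / 10), 5)
  y1 <- simulate_with_sensitivities(cas$network, base, 64, sensitivities = FALSE)$y
  y2 <- simulate_with_sensitivities(cas$network, slow, 64, sensitivities = FALSE)$y
  expect_gt(max(abs(y1[, "Ep1"] - y2[, "Ep1"])), 1e-3)
})

test_that("domain annotation loads, deduplicates and validates", {
  cas <- make_cascade_network(n_tiers = 1, seed = 1)
  # Fig 1A-style motif: four rate constants on one kinase-binding domain
  motif <- cas$annotation[cas$annotation$domain_id == "K1-KB", ]
  expect_equal(nrow(motif), 4)
  expect_setequal(motif$param_id, c("kb1", "ku1", "kc1", "kd1"))

  dup <- rbind(cas$annotation, cas$annotation[1, ])
  expect_warning(ann <- load_domain_annotation(dup, cas$network), "duplicate")
  expect_equal(nrow(ann), nrow(cas$annotation))

  bad <- rbind(cas$annotation,
               data.frame(protein_id = "X", domain_id = "XD", param_id = "kzz"))
  expect_error(load_domain_annotation(bad, cas$network), "unknown param_id")

  # many-to-many: one parameter annotated to two domains appears in both
  mm <- rbind(cas$annotation,
              data.frame(protein_id = "R0", domain_id = "R0-TM", param_id = "k1p"))
  ann2 <- load_domain_annotation(mm, cas$network)
  expect_equal(sum(ann2$param_id == "k1p"), 2)
})

test_that("TSV round-trip of annotation and covariates works", {
  cas <- make_cascade_network(n_tiers = 2, seed = 4)
  path <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(cas$annotation, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  ann <- load_domain_annotation(path, cas$network)
  expect_equal(as.data.frame(ann), as.data.frame(cas$annotation))

  cov <- make_meta_population(K = 1, seed = 5)[[1]]
  cpath <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(cov, cpath, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- load_covariate_table(cpath)
  expect_equal(back$domain_id, cov$domain_id)
  expect_equal(back$omega, cov$omega, tolerance = 1e-6)
})

test_that("covariate table rejects protein-level inconsistency", {
  cov <- make_meta_population(K = 1, seed = 6)[[1]]
  multi <- names(which(table(cov$protein_id) > 1))[1]
  cov$X[which(cov$protein_id == multi)[1]] <- -999
  expect_error(load_covariate_table(cov), "differs across domains")
})

test_that("SBML subset import reads species, parameters and kinetics", {
  path <- system.file("extdata", "two_species_decay.xml", package = "netinflux")
  net <- read_sbml(path)
  expect_equal(sort(net$species$id), c("A", "B"))
  expect_true("k1" %in% net$parameters$id)
  expect_true(net$parameters$rate_constant[net$parameters$id == "k1"])
  expect_false(net$parameters$rate_constant[net$parameters$id == "cell"])
  tr <- simulate_with_sensitivities(net, stimulation_condition("c", list(), 2),
                                    64, sensitivities = FALSE)
  expect_equal(unname(tr$y[65, "A"]), exp(-1), tolerance = 1e-6)
  # load_network dispatches on extension
  net2 <- load_network(path)
  expect_identical(net2$species, net$species)
})

test_that("SBML reader rejects unsupported constructs", {
  bad <- withr::local_tempfile(fileext = ".xml")
  writeLines(c(
    '<?xml version="1.0"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">',
    '<model id="m"><listOfEvents><event id="e"/></listOfEvents>',
    '<listOfSpecies><species id="A" initialConcentration="1"/></listOfSpecies>',
    '</model></sbml>'), bad)
  expect_error(read_sbml(bad), "unsupported SBML construct")
})
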