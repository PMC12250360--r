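# Network assembly: reaction/species bookkeeping, stoichiometry,
# propensities and conservation structure.

test_that("pathway blocks assemble the expected reactions and species", {
  full <- build_network(default_rates(), default_drugs()$Morphine)
  expect_length(full$reactions, 25)
  expect_equal(nrow(full$species), 20)
  expect_setequal(unique(full$species$pathway_tag),
                  c("serotonin", "shared", "opioid", "messenger"))

  serot <- build_network(pathways = "serotonin")
  expect_length(serot$reactions, 12)
  expect_true(all(grepl("^S", vapply(serot$reactions, `[[`, "", "id"))))
  expect_false(any(c("MOR", "OL", "cAMP") %in% serot$species$name))

  # exactly one Hill-type reaction, and only in the cAMP block
  laws <- vapply(full$reactions, `[[`, "", "rate_law")
  expect_identical(sum(laws == "hill_production"), 1L)
  ids <- vapply(full$reactions, `[[`, "", "id")
  expect_identical(ids[laws == "hill_production"], "C1")
})

test_that("configuration errors are caught at build time", {
  expect_error(build_network(default_rates(),
                             pathways = c("serotonin", "opioid", "competing")),
               "drug_spec")
  bad_rates <- default_rates()
  bad_rates$kbind5HT <- NULL
  expect_error(build_network(bad_rates, pathways = "serotonin"),
               "unknown rate constant")
  expect_error(default_rates(list(kdeg_typo = 1)), "kdeg_typo")
  expect_error(default_initial_state(c(NOPE = 1)), "NOPE")
})

test_that("drug_spec derives kon from koff and Kd", {
  d <- drug_spec("x", Kd = 76.08, dose = 1)
  expect_equal(d$kon, 5e-8 / (76.08e-3))
  expect_equal(d$kon * d$Kd_uM, d$koff)
  expect_error(drug_spec("x", Kd = -1, dose = 1), "positive")
})

test_that("stoichiometric matrix has the expected columns", {
  net <- build_network(default_rates(), default_drugs()$Morphine)
  S <- stoichiometric_matrix(net)
  expect_identical(dim(S), c(20L, 25L))

  # binding reaction: ligand and receptor consumed, complex formed
  s6 <- S[, "S6"]
  expect_identical(s6[["5HT"]], -1L)
  expect_identical(s6[["5HTR4"]], -1L)
  expect_identical(s6[["5HTR4:5HT"]], 1L)
  expect_identical(sum(s6 != 0), 3L)

  # catalytic G-activation: the receptor complex cancels
  s8 <- S[, "S8"]
  expect_identical(s8[["5HTR4:5HT"]], 0L)
  expect_identical(s8[["aS_GDP:bgS"]], -1L)
  expect_identical(s8[["aS_GTP"]], 1L)
  expect_identical(s8[["bgS"]], 1L)

  # a single A -> B reaction gives the column (-1, +1)
  toy <- oicsim:::.network_from_parts(
    data.frame(name = c("A", "B"), initial = c(1, 0), pathway_tag = "custom"),
    list(list(id = "R1", block = "custom", reactants = c(A = 1),
              products = c(B = 1), rate_constant_name = "k",
              rate_law = "mass_action", k = 1)))
  expect_identical(unname(stoichiometric_matrix(toy)[, 1]), c(-1L, 1L))
})

test_that("moiety indicator vectors lie in the left null space of S", {
  net <- build_network(default_rates(), default_drugs()$Morphine)
  S <- stoichiometric_matrix(net)
  M <- oicsim:::.moiety_matrix(net)
  expect_identical(nrow(M), 7L)
  expect_equal(max(abs(M %*% S)), 0)
})

test_that("propensities follow mass action, with the Hill law on C1", {
  net <- build_network(default_rates(), default_drugs()$Morphine)
  x <- setNames(net$species$initial, net$species$name)
  x["5HT"] <- 1
  flux <- propensities(net, x)
  # hand value: kbind5HT * [5HT] * [5HTR4] = 4.46e-3 * 1 * 5e-6
  expect_equal(flux[["S6"]], 2.23e-8, tolerance = 1e-12)
  expect_equal(flux[["S1"]], 0.05)          # zeroth-order synthesis
  expect_equal(flux[["C1"]], 0)             # no activated AC yet
  expect_equal(flux[["O1"]], 0)             # no ligand yet

  # Hill production at a known activation level
  x2 <- x
  x2["AC"] <- 0; x2["AC:aS_GTP"] <- 2e-3
  h <- (1 / 135)^2.44
  expect_equal(propensities(net, x2)[["C1"]], 141.3 * h / (1 + h))

  # well-posedness at the resting state: all net rates finite
  dx <- net$stoich %*% propensities(net, setNames(net$species$initial,
                                                  net$species$name))
  expect_true(all(is.finite(dx)))

  x_bad <- x; x_bad["5HT"] <- -1
  expect_error(propensities(net, x_bad), "negative")
})

test_that("conserved totals reproduce the configured pools at rest", {
  net <- build_network(default_rates(), default_drugs()$Morphine)
  x0 <- setNames(net$species$initial, net$species$name)
  tot <- conserved_totals(net, x0)
  expect_equal(tot[["MOR_total"]], 5e-6)
  expect_equal(tot[["AC_total"]], 2e-3)
  expect_equal(tot[["5HTR4_total"]], 5e-6)
  expect_equal(tot[["aS_total"]], 0.05)
})

test_that("ligand-releasing unbinding variant changes only S7/O2 products", {
  net <- build_network(default_rates(), default_drugs()$Morphine,
                       release_ligand_on_unbind = TRUE)
  S <- stoichiometric_matrix(net)
  expect_identical(S[["5HT", "S7"]], 1L)
  expect_identical(S[["OL", "O2"]], 1L)
  # literal variant destroys the ligand
  lit <- build_network(default_rates(), default_drugs()$Morphine)
  expect_identical(stoichiometric_matrix(lit)[["5HT", "S7"]], 0L)
})

test_that("pulsed serotonin release gates the S2 flux by phase", {
  net <- build_network(pathways = "serotonin",
                       pulse_release = list(amplitude = 10, period_ms = 1000,
                                            duty = 0.1))
  x <- setNames(net$species$initial, net$species$name)
  in_burst <- propensities(net, x, t = 50)[["S2"]]
  off_burst <- propensities(net, x, t = 500)[["S2"]]
  expect_equal(in_burst, 10 * 0.001 * x[["5HT_IN"]])
  expect_equal(off_burst, 0)
})
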