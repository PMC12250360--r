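# Acute-treatment experiments, recovery/depletion readouts and the
# degradation sweep machinery.

test_that("recovery time of a constructed dip-and-recovery curve matches
           the analytic crossing", {
  # baseline 1 until t = 10 h, instantaneous dip to 0.2, exponential
  # return 1 - 0.8 exp(-(t - 10)/20); crosses 0.8 * max at
  # t = 10 + 20 log(4)
  tt_h <- seq(0, 120, by = 0.5)
  y <- ifelse(tt_h < 10, 1, 1 - 0.8 * exp(-(tt_h - 10) / 20))
  t_rec <- oicsim:::.recovery_from_series(tt_h * 3.6e6, y,
                                          threshold_fraction = 0.8,
                                          dose_time = 10 * 3.6e6)
  expect_equal(t_rec / 3.6e6, 20 * log(4), tolerance = 2e-3)

  # constant-at-max observable: nothing to recover from
  expect_equal(oicsim:::.recovery_from_series(tt_h, rep(2, length(tt_h)),
                                              0.8, 0), 0)
  # never recovers within the horizon: censored, not an error
  y2 <- ifelse(tt_h < 10, 1, 0.1)
  out <- oicsim:::.recovery_from_series(tt_h, y2, 0.8, 10)
  expect_true(is.na(out))
  expect_equal(attr(out, "censored_at"), 110)
})

test_that("depletion time follows the first-order closed form on a pure
           decay path", {
  k <- 1e-7
  net <- make_decay_network(k = k, A0 = 1)
  # rename the species to the tissue-ligand slot for the readout
  net$species$name <- "OL"
  dimnames(net$stoich)[[1]] <- "OL"
  net$reactions[[1]]$reactants <- c(OL = 1)
  tt <- seq(0, 1e8, length.out = 400)
  tr <- integrate_network(net, c(OL = 1), t_end = max(tt), times = tt)
  ic50 <- 0.05
  expect_equal(depletion_time(tr, ic50) * 3.6e6, log(1 / ic50) / k,
               tolerance = 1e-3)
  # starting below the IC50 means zero depletion time
  expect_equal(depletion_time(tr, 2), 0)
})

test_that("zero dose gives nothing to recover from and no occupancy", {
  res <- run_acute_treatment(default_drugs()$Morphine, dose = 0,
                             horizon = 3.6e6 * 12)
  expect_equal(res$report$recovery_time_hours, 0)
  expect_equal(res$report$peak_occupancy_pct, 0)
})

test_that("acute treatment readouts are internally consistent", {
  base <- drug_free_baseline()
  dr <- default_drugs()$Morphine
  res <- run_acute_treatment(dr, baseline_state = base, ic50 = 5e-3)
  rep <- res$report
  expect_gt(rep$recovery_time_days, 1)
  expect_false(is.na(rep$depletion_time_hours))

  # peak occupancy agrees with the equilibrium isotherm at the peak
  # tissue concentration (binding is fast relative to the tissue
  # kinetics at this dose)
  traj <- res$trajectory
  ol_peak <- max(species_path(traj, "OL"))
  iso <- 100 * ol_peak / (ol_peak + dr$Kd_uM)
  expect_equal(rep$peak_occupancy_pct, iso, tolerance = 0.01)

  # late-time tissue depletion is first order with rate kdegOL
  tt <- traj$times
  sel <- tt > oicsim:::days_to_ms(8) & tt < oicsim:::days_to_ms(13)
  lf <- stats::lm(log(species_path(traj, "OL")[sel]) ~ tt[sel])
  expect_equal(-unname(coef(lf)[2]), dr$kdegOL, tolerance = 0.02)

  # endogenous-peptide kinetics: near-total occupancy but fast recovery
  em2 <- run_acute_treatment(default_drugs()$`Endomorphin-2`,
                             baseline_state = base)
  expect_gt(em2$report$peak_occupancy_pct, 99)
  expect_lt(em2$report$recovery_time_days,
            rep$recovery_time_days / 4)
})

test_that("opioid dosing leaves the serotonin arm untouched, and the
           detector notices an artificial cross-reaction", {
  chk <- pathway_independence_check(default_drugs()$Morphine,
                                    horizon = oicsim:::days_to_ms(1))
  expect_true(chk$pass)
  expect_lt(max(chk$max_rel_diff), 1e-6)

  chk2 <- pathway_independence_check(default_drugs()$`Endomorphin-2`,
                                     horizon = oicsim:::days_to_ms(1))
  expect_true(chk2$pass)

  # counterexample: a reaction where the bound opioid receptor consumes
  # serotonin must trip the detector
  net <- build_network(default_rates(), default_drugs()$Morphine)
  cross <- list(id = "X1", block = "custom",
                reactants = c(`MOR:OL` = 1, `5HT` = 1),
                products = c(`MOR:OL` = 1),
                rate_constant_name = "kx", rate_law = "mass_action",
                k = 1)
  net_x <- oicsim:::.network_from_parts(net$species,
                                        c(net$reactions, list(cross)),
                                        net$rates, drug = net$drug)
  chk3 <- pathway_independence_check(default_drugs()$Morphine,
                                     network = net_x,
                                     horizon = oicsim:::days_to_ms(1))
  expect_false(chk3$pass)
})

test_that("recovery shortens with faster degradation and the dose
           dependence flattens", {
  kd <- 0.57
  doses <- c(0.01, 1)
  kdegs <- c(1e-8, 1e-7, 1e-6)
  sw <- degradation_sweep(kdegs, kd, doses)
  m <- vapply(sw$results, function(r) r$recovery_days, matrix(0, 1, 2))
  rec <- matrix(m, nrow = length(doses))  # doses x kdegs
  # monotone non-increasing in kdeg at fixed dose
  expect_true(all(diff(rec[1, ]) < 0))
  expect_true(all(diff(rec[2, ]) < 0))
  # non-decreasing in dose within each kdeg slice
  expect_true(all(rec[2, ] >= rec[1, ] - 1e-6))
  expect_true(all(vapply(sw$results, `[[`, 0, "dose_monotone_fraction") == 1))
  # dose-dependence range shrinks monotonically with kdeg
  spread <- rec[2, ] - rec[1, ]
  expect_true(all(diff(spread) < 0))
})

test_that("the G-alpha-i displacement rate k3 shifts potency and recovery
           but leaves receptor occupancy untouched", {
  # k3 (reaction C3) is not independently measured; it defaults to the
  # AC association rate.  A factor-10 change in either direction moves
  # the simulated pIC50 by under one log unit and the recovery time by
  # under 50%, and cannot move occupancy, which is set upstream of AC.
  d <- default_drugs()$Morphine
  out <- lapply(c(3.5e-4, 3.5e-3, 3.5e-2), function(k3) {
    rates <- default_rates(list(k3 = k3))
    cur <- simulate_inhibition_curve(d, dose_grid(d$Kd_uM, 10, 6),
                                     rates = rates)
    acute <- run_acute_treatment(d, rates = rates)
    c(pic50 = pic50(fit_hill(cur$dose, cur$response, "fall")),
      recovery = acute$report$recovery_time_days,
      occ = acute$report$peak_occupancy_pct)
  })
  m <- do.call(rbind, out)
  expect_true(all(diff(m[, "pic50"]) > 0))
  expect_lt(max(abs(m[, "pic50"] - m[2, "pic50"])), 1)
  expect_true(all(diff(m[, "recovery"]) > 0))
  expect_lt(max(abs(m[, "recovery"] / m[2, "recovery"] - 1)), 0.5)
  expect_lt(diff(range(m[, "occ"])), 1e-6)
})

test_that("recovery ordering across the default drugs reflects their
           degradation kinetics", {
  base <- drug_free_baseline()
  rec <- vapply(default_drugs(), function(d) {
    run_acute_treatment(d, baseline_state = base)$report$recovery_time_days
  }, numeric(1))
  # Morphine (highest dose, slow degradation) is slowest; the rapidly
  # degraded Endomorphin-2 is by far the fastest despite its huge dose
  expect_identical(names(which.max(rec)), "Morphine")
  expect_identical(names(which.min(rec)), "Endomorphin-2")
  expect_lt(rec[["Endomorphin-2"]], min(rec[c("Morphine", "Fentanyl")]) / 3)
})
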