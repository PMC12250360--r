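# Steady-state cAMP law: closed form, synthetic-data generator, and
# parameter inference (round trips, identifiability structure).

test_that("steady-state cAMP closed form and monotonicity", {
  p <- camp_params()  # k1 6.1e-3, k2 141.3, EC50 135, n 2.44
  expect_equal(steady_state_camp(0, p), 0)
  expect_equal(steady_state_camp(135, p), 141.3 / (2 * 6.1e-3))
  expect_equal(steady_state_camp(135, p), 11581.97, tolerance = 1e-6)

  a <- seq(0, 300, length.out = 50)
  expect_true(all(diff(steady_state_camp(a, p)) > 0))
  p_hi_k2 <- camp_params(k2 = 2 * p$k2)
  expect_true(all(steady_state_camp(a[-1], p_hi_k2) >
                  steady_state_camp(a[-1], p)))
  p_hi_k1 <- camp_params(k1 = 2 * p$k1)
  expect_true(all(steady_state_camp(a[-1], p_hi_k1) <
                  steady_state_camp(a[-1], p)))
  # only the ratio k2/k1 matters: joint scaling leaves the law unchanged
  p_scaled <- camp_params(k1 = 3 * p$k1, k2 = 3 * p$k2)
  expect_equal(steady_state_camp(a, p_scaled), steady_state_camp(a, p))
  expect_error(steady_state_camp(-0.1, p), ">= 0")
})

# surrogate activation model (saturating in dose, scaled by density) used
# where the test does not need the full pathway simulation
surrogate_ac <- function(doses, density) {
  (density / 5e-5) * 0.9 * doses / (doses + 0.5)
}

test_that("generator is deterministic, exact at zero noise, and ordered
           by receptor density", {
  tp <- camp_params()
  grid <- dose_grid(0.5, 6, 3)
  pts0 <- generate_synthetic_calibration(tp, c(5e-6, 5e-5), grid,
                                         noise_cv = 0, seed = 7,
                                         ac_on_model = surrogate_ac)
  expect_equal(pts0$camp_accumulation,
               steady_state_camp(pts0$ac_on, tp))
  # higher density -> higher plateau
  plateau <- tapply(pts0$camp_accumulation, pts0$receptor_density_uM, max)
  expect_true(plateau[["5e-05"]] > plateau[["5e-06"]])

  a <- generate_synthetic_calibration(tp, 5e-6, grid, noise_cv = 0.05,
                                      seed = 11, ac_on_model = surrogate_ac)
  b <- generate_synthetic_calibration(tp, 5e-6, grid, noise_cv = 0.05,
                                      seed = 11, ac_on_model = surrogate_ac)
  c2 <- generate_synthetic_calibration(tp, 5e-6, grid, noise_cv = 0.05,
                                       seed = 12, ac_on_model = surrogate_ac)
  expect_identical(a, b)
  expect_false(identical(a, c2))
})

test_that("noiseless round trip recovers the parameters exactly in the
           identifiable regime", {
  truth <- camp_params(k1 = 6.1e-3, k2 = 10, EC50_hill = 0.2, n_hill = 2)
  pts <- generate_synthetic_calibration(truth, c(5e-6, 5e-5),
                                        dose_grid(0.5, 8, 4), noise_cv = 0,
                                        ac_on_model = surrogate_ac)
  fit <- infer_camp_params(pts, k1 = 6.1e-3)
  expect_equal(fit$params$k2 / fit$params$k1, truth$k2 / truth$k1,
               tolerance = 1e-4)
  expect_equal(fit$params$EC50_hill, truth$EC50_hill, tolerance = 1e-4)
  expect_equal(fit$params$n_hill, truth$n_hill, tolerance = 1e-4)
})

test_that("far below the Hill midpoint only the amplitude and exponent
           are identifiable, and they are recovered", {
  truth <- camp_params()  # EC50 135 >> any AC_on fraction: power-law ridge
  pts <- generate_synthetic_calibration(truth, c(5e-6, 5e-5),
                                        dose_grid(0.5, 8, 4), noise_cv = 0,
                                        ac_on_model = surrogate_ac)
  fit <- infer_camp_params(pts, k1 = truth$k1)
  amp_truth <- truth$k2 / (truth$k1 * truth$EC50_hill^truth$n_hill)
  expect_equal(fit$amplitude, amp_truth, tolerance = 1e-3)
  expect_equal(fit$params$n_hill, truth$n_hill, tolerance = 1e-3)
  # the fitted curve matches the truth everywhere it was observed
  expect_equal(predict(fit, pts$ac_on),
               steady_state_camp(pts$ac_on, truth), tolerance = 1e-3)
})

test_that("round trip through the simulated serotonin pathway is unbiased
           at 5% noise", {
  # activation computed once from the pathway model, then reused across
  # noise replicates through a lookup closure
  densities <- c(5e-6, 1.6e-5, 5e-5)
  grid <- dose_grid(0.33, 6, 4)
  tab <- lapply(densities, function(dd)
    simulate_agonist_curve(grid, receptor_density = dd)$response)
  names(tab) <- as.character(densities)
  lookup <- function(doses, density) tab[[as.character(density)]]

  truth <- camp_params(k1 = 6.1e-3, k2 = 5, EC50_hill = 0.3, n_hill = 2.44)
  fits <- lapply(1:40, function(s) {
    pts <- generate_synthetic_calibration(truth, densities, grid,
                                          noise_cv = 0.05, seed = s,
                                          ac_on_model = lookup)
    infer_camp_params(pts, k1 = truth$k1, seed = s)
  })
  ec50s <- vapply(fits, function(f) f$params$EC50_hill, numeric(1))
  lbias <- mean(log(ec50s)) - log(truth$EC50_hill)
  expect_lt(abs(lbias), 2 * sd(log(ec50s)) / sqrt(length(ec50s)) + 0.02)
  # typical recovery within 10% of truth
  expect_lt(median(abs(ec50s - truth$EC50_hill) / truth$EC50_hill), 0.1)
})

test_that("degenerate designs raise identifiability errors", {
  tp <- camp_params()
  pts <- data.frame(serotonin_uM = 1:8, receptor_density_uM = 5e-6,
                    ac_on = rep(0.4, 8),
                    camp_accumulation = steady_state_camp(rep(0.4, 8), tp))
  expect_error(infer_camp_params(pts), "identifiable")
  expect_error(infer_camp_params(pts[1:3, ]), "at least 6")
  expect_error(infer_camp_params(pts[, -3]), "ac_on")
})

test_that("calibration datasets round-trip through CSV", {
  tp <- camp_params()
  pts <- generate_synthetic_calibration(tp, 5e-6, dose_grid(0.5, 6, 3),
                                        noise_cv = 0, ac_on_model = surrogate_ac)
  f <- tempfile(fileext = ".csv")
  write_calibration_csv(pts, f)
  back <- read_calibration_csv(f)
  expect_equal(back$camp_accumulation, pts$camp_accumulation)
  writeLines("a,b\n1,2", f)
  expect_error(read_calibration_csv(f), "lacks columns")
  unlink(f)
})
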