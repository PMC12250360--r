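# Dose-response generation and four-parameter logistic (Hill) fitting.
#
# Agonist protocol: a serotonin bolus is the sole stimulus (the EC-cell
# source is silenced so the applied dose, not the endogenous baseline,
# sets the exposure); the response is the peak activated-AC fraction,
# i.e. the level of the slow quasi-plateau that follows the fast binding
# transient.
#
# Inhibition protocol (forskolin-like): the opioid is pre-equilibrated
# with the receptor at a fixed bath concentration, then all AC is switched
# to its activated form and cyclic AMP is read out after a fixed interval,
# normalised to the drug-free control.

#' Log-spaced dose grid
#'
#' @param center grid centre, uM (typically the drug Kd).
#' @param n_points number of doses (default 24).
#' @param span_decades total width in decades (default 6).
#' @return increasing numeric vector of doses (uM).
#' @export
dose_grid <- function(center, n_points = 24, span_decades = 6) {
  stopifnot(center > 0, n_points >= 2, span_decades > 0)
  10^seq(log10(center) - span_decades / 2,
         log10(center) + span_decades / 2, length.out = n_points)
}

#' Agonist dose-response of AC activation vs serotonin
#'
#' For each serotonin dose, integrates the serotonin pathway (S4-S12; the
#' enterochromaffin-cell source reactions are silenced so the bolus is the
#' only stimulus) from an initial state with `[5HT](0) = dose` and records
#' the peak activated-AC fraction reached along the trajectory.  Because
#' receptor unbinding and AC dissociation are orders of magnitude slower
#' than binding and G-protein cycling, this peak is a well-defined
#' quasi-steady plateau.
#'
#' @param doses serotonin doses, uM (increasing).
#' @param receptor_density initial 5HTR4 concentration, uM.
#' @param rates rate table from [default_rates()].
#' @param readout `"ac_on"` (activated-AC fraction) or `"camp"` (the
#'   steady-state cyclic AMP level implied by the calibrated Hill law,
#'   [steady_state_camp()], evaluated at the AC readout).
#' @param t_end integration horizon per dose, ms (default 24 h).
#' @param options solver options.
#' @return data.frame with columns `dose` and `response`.
#' @export
#' @examples
#' \donttest{
#' cur <- simulate_agonist_curve(dose_grid(0.3, n_points = 8, span_decades = 4))
#' fit_hill(cur$dose, cur$response, direction = "rise")
#' }
simulate_agonist_curve <- function(doses, receptor_density = 5e-6,
                                   rates = default_rates(),
                                   readout = c("ac_on", "camp"),
                                   t_end = hours_to_ms(24),
                                   options = solver_options()) {
  readout <- match.arg(readout)
  stopifnot(all(doses >= 0))
  rates_silent <- rates
  rates_silent$ksynthesis5HTIN <- 0
  net <- build_network(rates_silent, pathways = "serotonin",
                       initial_overrides = c("5HTR4" = receptor_density,
                                             "5HT_IN" = 0, "5HT" = 0))
  resp <- vapply(doses, function(d) {
    x0 <- setNames(net$species$initial, net$species$name)
    x0["5HT"] <- d
    tr <- integrate_network(net, x0, t_end = t_end, options = options)
    max(ac_on_fraction(tr))
  }, numeric(1))
  if (readout == "camp") {
    resp <- steady_state_camp(resp, as_camp_params(rates))
  }
  data.frame(dose = doses, response = resp)
}

# state after pre-incubating the receptor + G-alpha-i machinery with the
# ligand clamped at `dose`; AC pools withheld (added at assay start)
.preincubate_opioid <- function(drug, dose, rates, options) {
  net <- build_network(rates, drug, pathways = "opioid",
                       initial_overrides = c("AC" = 0))
  x0 <- setNames(net$species$initial, net$species$name)
  x0["OL"] <- dose
  if (dose == 0) return(list(state = x0, network = net))
  st <- steady_state(net, x0, tol = 1e-9, options = options, clamp = "OL")
  list(state = st, network = net)
}

#' Inhibition dose-response of cAMP accumulation vs opioid
#'
#' Forskolin-like assay.  For each dose the opioid is first equilibrated
#' with the mu-opioid receptor and its G-alpha-i cycle at a clamped bath
#' concentration; then all adenylyl cyclase is switched to the activated
#' `AC:aS_GTP` form (with the corresponding G-alpha-s supplied in bound
#' form and the free G-protein pools at their resting values), the system
#' is integrated for `readout_time`, and cyclic AMP at the end of the
#' interval is recorded.  Responses are normalised to the drug-free
#' control (100%).  The serotonin drive is off throughout, as in a
#' cell-assay setting.
#'
#' @param drug a [drug_spec()].
#' @param doses opioid bath concentrations, uM.
#' @param readout_time cAMP readout interval, ms (default 30 min).
#' @param rates rate table.
#' @param options solver options.
#' @return data.frame with columns `dose`, `camp` (uM at readout) and
#'   `response` (percent of drug-free control).
#' @export
simulate_inhibition_curve <- function(drug, doses,
                                      readout_time = 1.8e6,
                                      rates = default_rates(),
                                      options = solver_options()) {
  stopifnot(all(doses >= 0), readout_time > 0)
  rates_silent <- rates
  rates_silent$ksynthesis5HTIN <- 0
  one <- function(dose) {
    pre <- .preincubate_opioid(drug, dose, rates, options)
    net <- build_network(rates_silent, drug,
                         pathways = c("serotonin", "opioid", "competing"),
                         initial_overrides = c("5HT" = 0, "5HT_IN" = 0,
                                               "5HTR4" = 0))
    x0 <- setNames(net$species$initial, net$species$name)
    # carry over the pre-incubated opioid arm
    for (nm in names(pre$state)) if (nm %in% names(x0)) x0[nm] <- pre$state[[nm]]
    # forskolin-like initialisation: the whole AC pool activated, with its
    # G-alpha-s partner bound; free G-protein pools at resting values
    ac_total <- 2e-3
    x0["AC:aS_GTP"] <- ac_total
    x0["AC"] <- 0
    x0["AC:aI_GTP"] <- 0
    x0["cAMP"] <- 0
    tr <- integrate_network(net, x0, t_end = readout_time, options = options,
                            clamp = "OL",
                            times = c(0, readout_time / 2, readout_time))
    species_path(tr, "cAMP")[3]
  }
  camp <- vapply(doses, one, numeric(1))
  control <- one(0)
  data.frame(dose = doses, camp = camp, response = 100 * camp / control)
}

#' Four-parameter logistic (Hill) fit
#'
#' Least-squares fit of the 4PL model in log10-dose space,
#' `y = bottom + (top - bottom) / (1 + 10^(s (log10(mid) - log10(d))))`
#' for a rising curve (sign of `s` flipped for `direction = "fall"`), via
#' Levenberg-Marquardt.  The midpoint is the EC50 (rise) or IC50 (fall).
#'
#' @param doses dose vector (uM, all > 0, at least 5 points).
#' @param responses response vector.
#' @param direction `"rise"` (agonist) or `"fall"` (inhibition).
#' @return object of class `hill_fit` with fields `bottom`, `top`,
#'   `midpoint`, `hill_slope`, `se` (per-parameter standard errors),
#'   `residual_norm`, `direction` and the data.
#' @export
#' @examples
#' d <- dose_grid(0.33, n_points = 12, span_decades = 4)
#' y <- 1 / (1 + (0.33 / d)^1.13)
#' fit <- fit_hill(d, y, "rise")
#' coef(fit)
fit_hill <- function(doses, responses, direction = c("rise", "fall")) {
  direction <- match.arg(direction)
  if (length(doses) < 5) stop("need at least 5 dose points", call. = FALSE)
  if (any(doses <= 0)) stop("doses must be > 0", call. = FALSE)
  if (length(doses) != length(responses)) stop("length mismatch", call. = FALSE)
  ld <- log10(doses)
  rng <- diff(range(responses))
  if (rng <= 0) stop("responses are constant; nothing to fit", call. = FALSE)
  rho <- suppressWarnings(stats::cor(ld, responses, method = "spearman"))
  want <- if (direction == "rise") 1 else -1
  if (is.finite(rho) && sign(rho) != want && abs(rho) > 0.3) {
    stop("responses are not monotone in the requested direction", call. = FALSE)
  }

  sgn <- if (direction == "rise") 1 else -1
  model <- function(p, x) {
    p["bottom"] + (p["top"] - p["bottom"]) /
      (1 + 10^(sgn * p["h"] * (p["lmid"] - x)))
  }
  # start values: asymptotes from data, midpoint where the half-range is
  # crossed
  lo <- min(responses); hi <- max(responses)
  half <- (lo + hi) / 2
  lmid0 <- ld[which.min(abs(responses - half))]
  start <- c(bottom = lo, top = hi, lmid = lmid0, h = 1)
  fit <- minpack.lm::nls.lm(
    par = start,
    fn = function(p) responses - model(p, ld),
    lower = c(bottom = lo - 2 * rng, top = lo - 2 * rng,
              lmid = min(ld) - 2, h = 1e-3),
    upper = c(bottom = hi + 2 * rng, top = hi + 2 * rng,
              lmid = max(ld) + 2, h = 1e3),
    control = minpack.lm::nls.lm.control(maxiter = 500)
  )
  p <- fit$par
  dof <- length(doses) - 4L
  se <- rep(NA_real_, 4)
  cov <- tryCatch({
    s2 <- fit$deviance / max(dof, 1)
    s2 * solve(fit$hessian / 2)
  }, error = function(e) NULL)
  if (!is.null(cov)) se <- sqrt(pmax(diag(cov), 0))
  names(se) <- names(p)
  # midpoint SE on the uM scale via the delta method
  mid <- 10^p[["lmid"]]
  se_mid <- se[["lmid"]] * log(10) * mid
  structure(list(
    bottom = unname(p["bottom"]), top = unname(p["top"]),
    midpoint = mid, hill_slope = unname(p["h"]),
    se = c(bottom = unname(se["bottom"]), top = unname(se["top"]),
           midpoint = unname(se_mid), hill_slope = unname(se["h"])),
    residual_norm = sqrt(fit$deviance),
    direction = direction,
    doses = doses, responses = responses
  ), class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  lab <- if (x$direction == "rise") "EC50" else "IC50"
  cat(sprintf("<hill_fit> %s curve, %d points\n", x$direction,
              length(x$doses)))
  cat(sprintf("  %s        %.4g uM (se %.3g)\n", lab, x$midpoint,
              x$se[["midpoint"]]))
  cat(sprintf("  Hill slope  %.4g (se %.3g)\n", x$hill_slope,
              x$se[["hill_slope"]]))
  cat(sprintf("  bottom/top  %.4g / %.4g\n", x$bottom, x$top))
  if (x$direction == "fall") {
    cat(sprintf("  pIC50       %.4g\n", pic50(x)))
  }
  cat(sprintf("  residual norm %.3g\n", x$residual_norm))
  invisible(x)
}

#' @export
summary.hill_fit <- function(object, ...) {
  est <- coef(object)
  out <- data.frame(estimate = est,
                    std_error = object$se[names(est)])
  cat(sprintf("4PL fit (%s), residual norm %.3g\n", object$direction,
              object$residual_norm))
  print(out)
  invisible(out)
}

#' @export
coef.hill_fit <- function(object, ...) {
  c(bottom = object$bottom, top = object$top,
    midpoint = object$midpoint, hill_slope = object$hill_slope)
}

#' @export
predict.hill_fit <- function(object, newdata = NULL, ...) {
  d <- if (is.null(newdata)) object$doses else newdata
  sgn <- if (object$direction == "rise") 1 else -1
  object$bottom + (object$top - object$bottom) /
    (1 + 10^(sgn * object$hill_slope * (log10(object$midpoint) - log10(d))))
}

#' @export
residuals.hill_fit <- function(object, ...) {
  object$responses - predict(object)
}

#' @export
plot.hill_fit <- function(x, ...) {
  plot(x$doses, x$responses, log = "x", xlab = "dose (uM)",
       ylab = "response", ...)
  dd <- 10^seq(log10(min(x$doses)), log10(max(x$doses)), length.out = 200)
  lines(dd, predict(x, dd), col = "steelblue")
  abline(v = x$midpoint, lty = 2, col = "grey50")
  invisible(x)
}

#' pIC50 of an inhibition fit
#'
#' `-log10(IC50)` with the IC50 expressed in molar (doses are uM).
#'
#' @param fit a `hill_fit` with `direction = "fall"`, or a numeric IC50
#'   in uM.
#' @return numeric pIC50.
#' @export
#' @examples
#' pic50(1)     # 6
#' pic50(0.01)  # 8
pic50 <- function(fit) {
  ic50 <- if (inherits(fit, "hill_fit")) {
    if (fit$direction != "fall") stop("pIC50 requires an inhibition fit",
                                      call. = FALSE)
    fit$midpoint
  } else fit
  -log10(ic50 * 1e-6)
}

#' Agonist dose-response across receptor densities
#'
#' Repeats [simulate_agonist_curve()] + [fit_hill()] for a set of 5HTR4
#' densities and summarises how the EC50 and the maximal response (Emax)
#' depend on receptor density.
#'
#' @param densities receptor densities, uM.
#' @param doses serotonin dose grid, uM.
#' @param rates rate table.
#' @param t_end per-dose horizon, ms.
#' @param options solver options.
#' @return object of class `oic_density_sweep`: per-density fits plus a
#'   summary data.frame (`density`, `ec50`, `hill_slope`, `emax`).
#' @export
receptor_density_sweep <- function(densities, doses,
                                   rates = default_rates(),
                                   t_end = hours_to_ms(24),
                                   options = solver_options()) {
  stopifnot(all(densities > 0))
  fits <- vector("list", length(densities))
  rows <- vector("list", length(densities))
  for (i in seq_along(densities)) {
    cur <- simulate_agonist_curve(doses, receptor_density = densities[i],
                                  rates = rates, t_end = t_end,
                                  options = options)
    f <- tryCatch(fit_hill(cur$dose, cur$response, "rise"),
                  error = function(e) e)
    fits[[i]] <- f
    rows[[i]] <- if (inherits(f, "error")) {
      data.frame(density = densities[i], ec50 = NA_real_,
                 hill_slope = NA_real_, emax = max(cur$response))
    } else {
      data.frame(density = densities[i], ec50 = f$midpoint,
                 hill_slope = f$hill_slope, emax = f$top)
    }
  }
  summary <- do.call(rbind, rows)
  structure(list(fits = fits, summary = summary,
                 ec50_mean = mean(summary$ec50, na.rm = TRUE),
                 ec50_sd = stats::sd(summary$ec50, na.rm = TRUE),
                 slope_mean = mean(summary$hill_slope, na.rm = TRUE),
                 emax_range = range(summary$emax)),
            class = "oic_density_sweep")
}

#' @export
print.oic_density_sweep <- function(x, ...) {
  cat(sprintf("<oic_density_sweep> %d densities\n", nrow(x$summary)))
  cat(sprintf("  EC50  %.4g +/- %.3g uM\n", x$ec50_mean, x$ec50_sd))
  cat(sprintf("  slope %.4g\n", x$slope_mean))
  cat(sprintf("  Emax  %.4g .. %.4g\n", x$emax_range[1], x$emax_range[2]))
  invisible(x)
}
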