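# In-silico treatment experiments on the full 25-reaction network:
# acute equianalgesic dosing with recovery/depletion/occupancy readouts,
# pathway-independence verification, and degradation-rate sweeps.

# first crossing of y >= frac * max(y) after the post-dose nadir;
# linear interpolation between grid points; NA (attr censored) if the
# threshold is never reached again
.recovery_from_series <- function(times, y, threshold_fraction = 0.8,
                                  dose_time = 0) {
  stopifnot(length(times) == length(y), threshold_fraction > 0,
            threshold_fraction <= 1)
  target <- threshold_fraction * max(y)
  post <- which(times >= dose_time)
  if (!length(post)) stop("no samples after the dose time", call. = FALSE)
  yp <- y[post]; tp <- times[post]
  if (min(yp) >= target) return(0)  # never dropped below threshold
  nadir <- which.min(yp)
  above <- which(yp[nadir:length(yp)] >= target)
  if (!length(above)) {
    out <- NA_real_
    attr(out, "censored_at") <- max(tp) - dose_time
    return(out)
  }
  i2 <- nadir + above[1] - 1L
  i1 <- i2 - 1L
  t_cross <- if (i1 < 1 || yp[i2] == yp[i1]) tp[i2] else {
    tp[i1] + (target - yp[i1]) / (yp[i2] - yp[i1]) * (tp[i2] - tp[i1])
  }
  t_cross - dose_time
}

#' Recovery time of an observable after dosing
#'
#' Time (in hours, from the dose) at which the observable first returns to
#' `threshold_fraction` of its maximal observed value over the whole
#' trajectory (pre-dose baseline included), after the post-dose nadir.
#' Linear interpolation between output grid points.  If the threshold is
#' never re-crossed within the horizon the result is `NA` with attribute
#' `censored_at` (the horizon, hours).
#'
#' @param traj an `oic_trajectory`, typically from [run_acute_treatment()].
#' @param observable `"ac_on"` (activated-AC fraction; equivalently the
#'   `AC:aS_GTP` concentration since the AC total is conserved) or
#'   `"camp"` (the cAMP concentration path).
#' @param threshold_fraction recovery threshold (default 0.8).
#' @param dose_time_ms time of dosing on the trajectory clock; defaults to
#'   the trajectory's recorded dose time (0 if none).
#' @return recovery time in hours (0 when nothing to recover from).
#' @export
recovery_time <- function(traj, observable = c("ac_on", "camp"),
                          threshold_fraction = 0.8, dose_time_ms = NULL) {
  observable <- match.arg(observable)
  y <- switch(observable,
              ac_on = ac_on_fraction(traj),
              camp = species_path(traj, "cAMP"))
  if (is.null(dose_time_ms)) {
    dose_time_ms <- attr(traj, "dose_time_ms")
    if (is.null(dose_time_ms)) dose_time_ms <- 0
  }
  out <- .recovery_from_series(traj$times, y, threshold_fraction, dose_time_ms)
  if (is.na(out)) {
    cen <- attr(out, "censored_at")
    out_h <- NA_real_
    attr(out_h, "censored_at") <- ms_to_hours(cen)
    return(out_h)
  }
  ms_to_hours(out)
}

#' Time for the tissue drug concentration to deplete to the IC50
#'
#' First time (hours from the dose) at which the tissue opioid
#' concentration falls below `ic50` and stays below it for the rest of the
#' trajectory.  Returns 0 if the concentration never reaches the IC50.
#'
#' @param traj an `oic_trajectory` with a tissue opioid (`OL`) path.
#' @param ic50 IC50 in uM (from the drug's fitted inhibition curve).
#' @param dose_time_ms dose time on the trajectory clock (default: recorded
#'   attribute, else 0).
#' @return hours from dose.
#' @export
depletion_time <- function(traj, ic50, dose_time_ms = NULL) {
  stopifnot(ic50 > 0)
  ol <- species_path(traj, "OL")
  if (is.null(dose_time_ms)) {
    dose_time_ms <- attr(traj, "dose_time_ms")
    if (is.null(dose_time_ms)) dose_time_ms <- 0
  }
  post <- which(traj$times >= dose_time_ms)
  tp <- traj$times[post]; yp <- ol[post]
  below <- yp < ic50
  if (all(below)) return(0)
  if (below[length(below)] == FALSE) {
    out <- NA_real_
    attr(out, "censored_at") <- ms_to_hours(max(tp) - dose_time_ms)
    return(out)
  }
  # last index still at/above ic50
  i1 <- max(which(!below))
  i2 <- i1 + 1L
  t_cross <- tp[i1] + (ic50 - yp[i1]) / (yp[i2] - yp[i1]) * (tp[i2] - tp[i1])
  ms_to_hours(t_cross - dose_time_ms)
}

#' Acute opioid treatment on the full network
#'
#' Pre-equilibrates the drug-free system (serotonin drive running, no
#' opioid), adds the dose to the drug's compartment (blood by default),
#' and integrates the combined 25-reaction network over the horizon.
#' Returns the trajectory (pre-dose segment included; the dose time is
#' recorded in attribute `dose_time_ms`) together with a recovery report.
#'
#' @param drug a [drug_spec()].
#' @param dose dose in uM (default: the drug's equianalgesic dose).
#' @param rates rate table.
#' @param pre_equilibration drug-free equilibration before dosing, ms
#'   (default 24 h).
#' @param horizon post-dose horizon, ms (default 14 days).
#' @param threshold_fraction recovery threshold (default 0.8).
#' @param ic50 optional IC50 (uM) for the depletion readout.
#' @param baseline_state optional pre-equilibrated drug-free state (named
#'   vector), reused across calls to skip the equilibration integration.
#' @param options solver options.
#' @return list of class `oic_acute` with elements `trajectory` and
#'   `report` (class `recovery_report`).
#' @export
#' @examples
#' \donttest{
#' res <- run_acute_treatment(default_drugs()$Fentanyl)
#' res$report
#' }
run_acute_treatment <- function(drug, dose = drug$dose,
                                rates = default_rates(),
                                pre_equilibration = hours_to_ms(24),
                                horizon = days_to_ms(14),
                                threshold_fraction = 0.8,
                                ic50 = NULL, baseline_state = NULL,
                                options = solver_options()) {
  stopifnot(dose >= 0, horizon > 0, pre_equilibration >= 0)
  net <- build_network(rates, drug)
  sp <- net$species$name
  if (is.null(baseline_state)) {
    baseline_state <- drug_free_baseline(rates, pre_equilibration,
                                         options = options, drug = drug)
  }
  # short pre-dose segment at baseline so the trajectory shows the plateau
  pre_ms <- min(pre_equilibration, hours_to_ms(24))
  pre_tr <- if (pre_ms > 0) {
    integrate_network(net, baseline_state, t_end = pre_ms, options = options,
                      times = seq(0, pre_ms, length.out = 25))
  } else NULL
  x_dose <- if (is.null(pre_tr)) baseline_state[sp] else
    pre_tr$conc[nrow(pre_tr$conc), ]
  target <- if (drug$dose_compartment == "blood") "OL_Blood" else "OL"
  x_dose[target] <- x_dose[target] + dose
  post_tr <- integrate_network(net, x_dose, t_end = horizon, options = options)

  times <- c(if (!is.null(pre_tr)) pre_tr$times,
             post_tr$times + pre_ms)
  conc <- rbind(if (!is.null(pre_tr)) pre_tr$conc, post_tr$conc)
  dup <- duplicated(times)
  traj <- structure(list(times = times[!dup], conc = conc[!dup, , drop = FALSE],
                         network = net, options = options, clamp = character()),
                    class = "oic_trajectory")
  attr(traj, "dose_time_ms") <- pre_ms

  occ <- receptor_occupancy(traj, "MOR")
  post_idx <- traj$times >= pre_ms
  rec <- recovery_time(traj, "ac_on", threshold_fraction)
  rep <- structure(list(
    drug = drug$name, dose = dose,
    recovery_time_hours = rec,
    recovery_time_days = rec / 24,
    depletion_time_hours = if (!is.null(ic50))
      depletion_time(traj, ic50) else NA_real_,
    ic50 = if (is.null(ic50)) NA_real_ else ic50,
    peak_occupancy_pct = if (dose > 0) max(occ[post_idx]) else 0,
    threshold_fraction = threshold_fraction
  ), class = "recovery_report")
  structure(list(trajectory = traj, report = rep), class = "oic_acute")
}

#' Drug-free baseline state of the full network
#'
#' Integrates the full network without any opioid for the given duration
#' and returns the final state (the healthy-gut baseline used as the
#' pre-dose reference).
#'
#' @param rates rate table.
#' @param duration equilibration time, ms.
#' @param options solver options.
#' @param drug drug spec used to assemble the network (its reactions carry
#'   zero flux while the opioid concentrations are zero).
#' @return named state vector.
#' @export
drug_free_baseline <- function(rates = default_rates(),
                               duration = hours_to_ms(24),
                               options = solver_options(),
                               drug = default_drugs()$Morphine) {
  net <- build_network(rates, drug)
  tr <- integrate_network(net, t_end = duration, options = options)
  tr$conc[nrow(tr$conc), ]
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("<recovery_report> %s, dose %.4g uM\n", x$drug, x$dose))
  if (is.na(x$recovery_time_hours)) {
    cat(sprintf("  recovery:  censored at %.3g h\n",
                attr(x$recovery_time_hours, "censored_at")))
  } else {
    cat(sprintf("  recovery to %.0f%% of max: %.3g h (%.3g days)\n",
                100 * x$threshold_fraction, x$recovery_time_hours,
                x$recovery_time_days))
  }
  if (!is.na(x$depletion_time_hours)) {
    cat(sprintf("  depletion to IC50 (%.3g uM): %.3g h (%.3g days)\n",
                x$ic50, x$depletion_time_hours, x$depletion_time_hours / 24))
  }
  cat(sprintf("  peak MOR occupancy: %.3g%%\n", x$peak_occupancy_pct))
  invisible(x)
}

#' @export
print.oic_acute <- function(x, ...) {
  print(x$report)
  invisible(x)
}

#' Verify that opioid dosing leaves the serotonin arm untouched
#'
#' Runs the network twice from the same pre-equilibrated state -- once
#' with the dose, once without -- and reports the maximum relative
#' difference of the serotonin species paths.  Because the two pathways
#' only interact downstream at AC, the difference should be at the
#' integration-tolerance level.
#'
#' @param drug a [drug_spec()].
#' @param dose dose in uM.
#' @param rates rate table.
#' @param horizon comparison horizon, ms (default 2 days).
#' @param species serotonin-arm species to compare.
#' @param network optional pre-built network (overrides `drug`/`rates`),
#'   e.g. one with an artificial cross-pathway reaction for testing the
#'   detector.
#' @param tol pass threshold on the max relative difference.
#' @param options solver options.
#' @return list with `max_rel_diff` (per species), `pass`.
#' @export
pathway_independence_check <- function(drug, dose = drug$dose,
                                       rates = default_rates(),
                                       horizon = days_to_ms(2),
                                       species = c("5HT", "5HTR4:5HT"),
                                       network = NULL, tol = 1e-6,
                                       options = solver_options()) {
  net <- if (is.null(network)) build_network(rates, drug) else network
  base <- drug_free_baseline(rates, hours_to_ms(24), options,
                             drug = if (is.null(net$drug)) drug else net$drug)
  base <- base[net$species$name]
  base[is.na(base)] <- 0
  names(base) <- net$species$name
  x1 <- base
  x1[if (!is.null(net$drug) && net$drug$dose_compartment == "tissue") "OL"
     else "OL_Blood"] <- dose
  grid <- .output_grid(horizon)
  tr0 <- integrate_network(net, base, t_end = horizon, times = grid,
                           options = options)
  tr1 <- integrate_network(net, x1, t_end = horizon, times = grid,
                           options = options)
  mrd <- vapply(species, function(nm) {
    a <- species_path(tr0, nm); b <- species_path(tr1, nm)
    scale <- max(abs(a), 1e-300)
    max(abs(a - b)) / scale
  }, numeric(1))
  list(max_rel_diff = mrd, pass = all(mrd < tol))
}

#' Recovery-time sweep over affinity, dose and degradation rate
#'
#' For each opioid degradation rate `kdeg`, simulates the acute-treatment
#' protocol on a grid of receptor affinities (Kd, with
#' `kon = koff / Kd` at fixed `koff`) and doses, and records the cAMP
#' recovery time in each cell.  Cells whose cAMP has not re-crossed the
#' threshold within the horizon are `NA` (censored).
#'
#' @param kdeg_values tissue degradation rates, ms^-1.
#' @param kd_grid receptor affinities, nM (log-spaced recommended).
#' @param dose_grid doses, uM (log-spaced recommended).
#' @param koff fixed unbinding rate, ms^-1.
#' @param rates rate table.
#' @param horizon post-dose horizon per cell, ms (default 14 days).
#' @param threshold_fraction recovery threshold (default 0.8).
#' @param observable `"camp"` (default) or `"ac_on"`.
#' @param options solver options.
#' @return object of class `oic_sweep`: list of per-kdeg results, each
#'   with `kdeg`, `recovery_days` (matrix Kd x dose, in days),
#'   `contour_2day` (iso-lines at 2 days in log10 coordinates) and
#'   `dose_monotone_fraction` (fraction of adjacent dose pairs with
#'   non-decreasing recovery).
#' @export
degradation_sweep <- function(kdeg_values, kd_grid, dose_grid, koff = 5e-8,
                              rates = default_rates(),
                              horizon = days_to_ms(14),
                              threshold_fraction = 0.8,
                              observable = c("camp", "ac_on"),
                              options = solver_options()) {
  observable <- match.arg(observable)
  baseline <- drug_free_baseline(rates, hours_to_ms(24), options)
  per_kdeg <- lapply(kdeg_values, function(kdeg) {
    m <- matrix(NA_real_, nrow = length(kd_grid), ncol = length(dose_grid),
                dimnames = list(paste0("Kd_", signif(kd_grid, 3), "nM"),
                                paste0("dose_", signif(dose_grid, 3), "uM")))
    for (i in seq_along(kd_grid)) {
      for (j in seq_along(dose_grid)) {
        dr <- drug_spec("sweep", Kd = kd_grid[i], dose = dose_grid[j],
                        kdegOL = kdeg, koff = koff)
        cell <- tryCatch({
          res <- run_acute_treatment(dr, rates = rates, horizon = horizon,
                                     threshold_fraction = threshold_fraction,
                                     baseline_state = baseline,
                                     options = options)
          rt <- recovery_time(res$trajectory, observable, threshold_fraction)
          if (is.na(rt)) NA_real_ else rt / 24
        }, error = function(e) NA_real_)
        m[i, j] <- cell
      }
    }
    contour <- if (length(kd_grid) > 1 && length(dose_grid) > 1 &&
                   !anyNA(m)) {
      grDevices::contourLines(x = log10(kd_grid), y = log10(dose_grid),
                              z = m, levels = 2)
    } else list()
    diffs <- t(apply(m, 1, diff))
    mono <- mean(diffs >= -1e-6, na.rm = TRUE)
    list(kdeg = kdeg, recovery_days = m, contour_2day = contour,
         dose_monotone_fraction = mono)
  })
  structure(list(results = per_kdeg, kd_grid = kd_grid,
                 dose_grid = dose_grid, koff = koff,
                 observable = observable,
                 threshold_fraction = threshold_fraction),
            class = "oic_sweep")
}

#' @export
print.oic_sweep <- function(x, ...) {
  cat(sprintf("<oic_sweep> %d degradation rates, %d x %d (Kd x dose) grid\n",
              length(x$results), length(x$kd_grid), length(x$dose_grid)))
  for (r in x$results) {
    cat(sprintf("  kdeg %.3g ms^-1: recovery %.3g .. %.3g days (%d censored)\n",
                r$kdeg, suppressWarnings(min(r$recovery_days, na.rm = TRUE)),
                suppressWarnings(max(r$recovery_days, na.rm = TRUE)),
                sum(is.na(r$recovery_days))))
  }
  invisible(x)
}

#' @export
plot.oic_sweep <- function(x, which = 1, ...) {
  r <- x$results[[which]]
  lx <- log10(x$kd_grid); ly <- log10(x$dose_grid)
  image(lx, ly, r$recovery_days, col = hcl.colors(64, "viridis"),
        xlab = "log10 Kd (nM)", ylab = "log10 dose (uM)",
        main = sprintf("cAMP recovery (days), kdeg = %.0e ms^-1", r$kdeg), ...)
  contour(lx, ly, r$recovery_days, levels = 2, add = TRUE, col = "yellow",
          lwd = 2)
  invisible(x)
}

#' Write a sweep matrix to CSV
#'
#' Rows are Kd values, columns doses; entries in days.
#'
#' @param sweep an `oic_sweep`.
#' @param path output file.
#' @param which index of the degradation rate to write.
#' @return `path`, invisibly.
#' @export
write_sweep_csv <- function(sweep, path, which = 1) {
  write.csv(sweep$results[[which]]$recovery_days, path)
  invisible(path)
}
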