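# Deterministic integration of the reaction-rate equations
#   dx/dt = S %*% pi(x, t)
# with LSODA (via deSolve), plus derived observables and steady-state
# detection.

#' Solver options
#'
#' @param rel_tol relative tolerance (default `1e-8`).
#' @param abs_tol absolute tolerance (default `1e-14` uM; species span
#'   about eight orders of magnitude, from 5e-6 uM receptors to
#'   millimolar-range doses).
#' @param max_step maximum internal step in ms (default unlimited).
#' @param method_hint `"auto"` (LSODA switches stiff/non-stiff itself) or
#'   `"stiff"` (BDF).
#' @return list of class `solver_options`.
#' @export
solver_options <- function(rel_tol = 1e-8, abs_tol = 1e-14,
                           max_step = Inf, method_hint = c("auto", "stiff")) {
  method_hint <- match.arg(method_hint)
  if (rel_tol <= 0 || abs_tol <= 0) stop("tolerances must be > 0", call. = FALSE)
  structure(list(rel_tol = rel_tol, abs_tol = abs_tol, max_step = max_step,
                 method_hint = method_hint), class = "solver_options")
}

# output grid: log-dense over the first hour (binding transients live on
# ms-minute scales), then hourly out to t_end
.output_grid <- function(t_end, points_per_hour = 1) {
  early_end <- min(t_end, 3.6e6)
  early <- unique(c(0, 10^seq(0, log10(early_end), length.out = 60)))
  if (t_end <= 3.6e6) return(sort(unique(c(early, t_end))))
  step <- 3.6e6 / points_per_hour
  late <- seq(3.6e6, t_end, by = step)
  sort(unique(c(early, late, t_end)))
}

# rhs closure for deSolve; clamps tiny negatives produced by the solver
.make_rhs <- function(network, clamp = character()) {
  S <- network$stoich
  clamp_idx <- match(clamp, rownames(S))
  if (any(is.na(clamp_idx))) stop("clamped species not in network", call. = FALSE)
  function(t, y, parms) {
    neg <- y < 0
    if (any(neg)) {
      if (any(y < -1e-9)) {
        stop("solver produced a large negative concentration (",
             paste(rownames(S)[y < -1e-9], collapse = ", "), ")", call. = FALSE)
      }
      y[neg] <- 0
    }
    names(y) <- rownames(S)
    flux <- .propensities_fast(network, y, t)
    dx <- as.numeric(S %*% flux)
    if (length(clamp_idx)) dx[clamp_idx] <- 0
    list(dx)
  }
}

#' Integrate the network ODEs
#'
#' Solves `dx/dt = S pi(x, t)` with LSODA from `t = 0` to `t_end` ms on an
#' output grid that is log-dense over the first hour and hourly (by
#' default) afterwards, dense enough that linearly interpolated event
#' times (recovery, depletion) are accurate to well under a minute.
#'
#' @param network an `oic_network`.
#' @param initial_state named concentration vector; defaults to the
#'   network's built-in initial concentrations.
#' @param t_end horizon in ms (> 0).
#' @param options a [solver_options()] object.
#' @param clamp character vector of species held constant (their time
#'   derivative is forced to zero), e.g. a ligand fixed at an assay
#'   concentration.
#' @param times optional explicit output grid (ms, increasing, starting
#'   at 0); overrides the default grid.
#' @param points_per_hour density of the uniform part of the default grid.
#' @return an object of class `oic_trajectory` with elements `times` (ms)
#'   and `conc` (matrix, time x species).
#' @export
#' @examples
#' net <- build_network(pathways = "serotonin")
#' tr <- integrate_network(net, t_end = 3.6e6)
#' tr
integrate_network <- function(network, initial_state = NULL, t_end,
                              options = solver_options(), clamp = character(),
                              times = NULL, points_per_hour = 1) {
  stopifnot(t_end > 0)
  sp <- network$species$name
  if (is.null(initial_state)) {
    initial_state <- setNames(network$species$initial, sp)
  } else {
    if (is.null(names(initial_state))) names(initial_state) <- sp
    missing <- setdiff(sp, names(initial_state))
    if (length(missing)) initial_state[missing] <- 0
    initial_state <- initial_state[sp]
  }
  if (any(initial_state < 0)) stop("negative initial concentration", call. = FALSE)
  if (is.null(times)) times <- .output_grid(t_end, points_per_hour)
  rhs <- .make_rhs(network, clamp)
  method <- if (options$method_hint == "stiff") "bdf" else "lsoda"
  sol <- deSolve::ode(y = initial_state, times = times, func = rhs,
                      parms = NULL, method = method,
                      rtol = options$rel_tol, atol = options$abs_tol,
                      maxsteps = 5e5,
                      hmax = if (is.finite(options$max_step)) options$max_step else NULL)
  istate <- attr(sol, "istate")
  if (!is.null(istate) && istate[1] < 0) {
    stop("integration failed (istate ", istate[1],
         "); last time reached ", max(sol[, 1]), " ms", call. = FALSE)
  }
  if (nrow(sol) < length(times)) {
    stop("integration stopped early at t = ", max(sol[, 1]), " ms",
         call. = FALSE)
  }
  conc <- sol[, -1, drop = FALSE]
  conc[conc < 0 & conc > -1e-9] <- 0
  structure(list(times = sol[, 1], conc = conc, network = network,
                 options = options, clamp = clamp),
            class = "oic_trajectory")
}

#' @export
print.oic_trajectory <- function(x, ...) {
  cat(sprintf("<oic_trajectory> %d time points over %.3g h, %d species\n",
              length(x$times), ms_to_hours(max(x$times)), ncol(x$conc)))
  invisible(x)
}

#' @export
as.data.frame.oic_trajectory <- function(x, ...) {
  data.frame(time_ms = rep(x$times, ncol(x$conc)),
             species = rep(colnames(x$conc), each = length(x$times)),
             concentration_uM = as.vector(x$conc),
             stringsAsFactors = FALSE)
}

#' @export
plot.oic_trajectory <- function(x, species = NULL, time_unit = c("hours", "days", "ms"),
                                log = "", ...) {
  time_unit <- match.arg(time_unit)
  tt <- switch(time_unit, hours = ms_to_hours(x$times),
               days = ms_to_days(x$times), ms = x$times)
  if (is.null(species)) species <- colnames(x$conc)
  y <- x$conc[, species, drop = FALSE]
  matplot(tt, y, type = "l", lty = 1, xlab = paste0("time (", time_unit, ")"),
          ylab = "concentration (uM)", log = log, ...)
  legend("topright", legend = species, col = seq_along(species), lty = 1,
         cex = 0.7, bty = "n")
  invisible(x)
}

#' Extract one species path
#' @param traj an `oic_trajectory`.
#' @param species species name.
#' @return numeric vector over `traj$times`.
#' @export
species_path <- function(traj, species) {
  if (!species %in% colnames(traj$conc)) {
    stop("species not in trajectory: ", species, call. = FALSE)
  }
  traj$conc[, species]
}

#' Activated-AC fraction along a trajectory
#'
#' `AC_on(t) = [AC:aS_GTP] / ([AC:aS_GTP] + [AC:aI_GTP] + [AC])`, the
#' fraction of adenylyl cyclase engaged by activated stimulatory G-alpha.
#' Missing pools (e.g. no inhibitory arm in a serotonin-only network)
#' contribute zero.
#'
#' @param traj an `oic_trajectory` (or a state matrix with named columns).
#' @return numeric vector in `[0, 1]`.
#' @export
ac_on_fraction <- function(traj) {
  conc <- if (inherits(traj, "oic_trajectory")) traj$conc else traj
  g <- function(nm) if (nm %in% colnames(conc)) conc[, nm] else 0
  on <- g("AC:aS_GTP"); off <- g("AC:aI_GTP"); free <- g("AC")
  tot <- on + off + free
  if (all(tot <= 0)) stop("AC total is zero; AC_on undefined", call. = FALSE)
  ifelse(tot > 0, on / tot, 0)
}

#' Receptor occupancy along a trajectory
#'
#' Percentage of receptor bound: `100 * bound / (bound + free)`.
#'
#' @param traj an `oic_trajectory`.
#' @param receptor `"MOR"` or `"5HTR4"`.
#' @return percent time series.
#' @export
receptor_occupancy <- function(traj, receptor = c("MOR", "5HTR4")) {
  receptor <- match.arg(receptor)
  bound_nm <- if (receptor == "MOR") "MOR:OL" else "5HTR4:5HT"
  free <- species_path(traj, receptor)
  bound <- species_path(traj, bound_nm)
  tot <- free + bound
  ifelse(tot > 0, 100 * bound / tot, 0)
}

#' Steady state by long-horizon integration
#'
#' Integrates in geometrically growing chunks until the per-hour relative
#' change of every species falls below `tol`, then verifies that the
#' residual `max |S pi(x)|` is small relative to the flux scale.
#'
#' @param network an `oic_network` (autonomous: pulsed release not allowed).
#' @param initial_state optional named start state.
#' @param tol relative change per simulated hour below which the state is
#'   declared stationary (default `1e-9`).
#' @param max_horizon maximum horizon in ms (default 60 days).
#' @param options solver options.
#' @param clamp species held constant (excluded from the convergence test).
#' @return named steady-state concentration vector with attribute
#'   `"residual"` (max absolute net rate, uM/ms).
#' @export
steady_state <- function(network, initial_state = NULL, tol = 1e-9,
                         max_horizon = days_to_ms(60),
                         options = solver_options(), clamp = character()) {
  if (!is.null(network$pulse_release)) {
    stop("steady_state requires an autonomous network (pulsed release off)",
         call. = FALSE)
  }
  sp <- network$species$name
  state <- if (is.null(initial_state)) {
    setNames(network$species$initial, sp)
  } else {
    s <- initial_state
    if (is.null(names(s))) names(s) <- sp
    miss <- setdiff(sp, names(s)); s[miss] <- 0
    s[sp]
  }
  chunk <- 3.6e6  # 1 h
  elapsed <- 0
  floor_conc <- 1e-12
  repeat {
    tr <- integrate_network(network, state, t_end = chunk, options = options,
                            clamp = clamp, times = c(0, chunk / 2, chunk))
    new <- tr$conc[nrow(tr$conc), ]
    test_sp <- setdiff(sp, clamp)
    rel <- abs(new[test_sp] - state[test_sp]) /
      pmax(abs(new[test_sp]), floor_conc)
    rel_per_hour <- rel / (chunk / 3.6e6)
    elapsed <- elapsed + chunk
    state <- new
    if (max(rel_per_hour) < tol) break
    if (elapsed >= max_horizon) {
      worst <- test_sp[which.max(rel_per_hour)]
      stop("no steady state within ", signif(ms_to_days(max_horizon), 3),
           " days; slowest species: ", worst,
           " (relative change ", signif(max(rel_per_hour), 3), " per hour)",
           call. = FALSE)
    }
    chunk <- min(chunk * 2, max_horizon - elapsed + 3.6e6)
  }
  flux <- .propensities_fast(network, pmax(state, 0), elapsed)
  resid <- max(abs(network$stoich %*% flux))
  attr(state, "residual") <- resid
  state
}

#' Write a trajectory to tidy CSV
#'
#' Columns `time_ms`, `species`, `concentration_uM`.
#'
#' @param traj an `oic_trajectory`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}
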