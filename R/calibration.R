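# Cyclic AMP production law: closed-form steady state, synthetic
# calibration-data generation, and inference of the Hill-law parameters
# from steady-state dose-response data.
#
# The cAMP balance  d[cAMP]/dt = -k1 cAMP + k2 H(AC_on)  with
# H(a) = (a/EC50)^n / (1 + (a/EC50)^n)  has the steady state
# cAMP* = (k2/k1) H(AC_on).  Steady-state data therefore constrain only
# the ratio k2/k1 (k1 is held fixed during inference) and, when the
# observed AC_on range stays far below EC50, only the combination
# k2 / (k1 EC50^n) together with n (the Hill law degenerates to a power
# law).  The fitter works in log space where the constant-CV noise of
# cAMP assays is homoscedastic.

#' cAMP production-law parameters
#'
#' @param k1 cAMP degradation rate, ms^-1.
#' @param k2 cAMP production scale.
#' @param EC50_hill Hill midpoint in activated-AC-fraction units.
#' @param n_hill Hill coefficient (> 0).
#' @return object of class `camp_params`.
#' @export
#' @examples
#' camp_params()
camp_params <- function(k1 = 6.1e-3, k2 = 141.3, EC50_hill = 135,
                        n_hill = 2.44) {
  if (any(c(k1, k2, EC50_hill, n_hill) <= 0)) {
    stop("all cAMP parameters must be > 0", call. = FALSE)
  }
  structure(list(k1 = k1, k2 = k2, EC50_hill = EC50_hill, n_hill = n_hill),
            class = "camp_params")
}

#' @export
print.camp_params <- function(x, ...) {
  cat(sprintf("<camp_params> k1 %.4g ms^-1, k2 %.4g, EC50 %.4g, n %.4g (k2/k1 %.4g)\n",
              x$k1, x$k2, x$EC50_hill, x$n_hill, x$k2 / x$k1))
  invisible(x)
}

# extract the cAMP parameters embedded in a rate table
as_camp_params <- function(rates) {
  camp_params(k1 = rates$k1, k2 = rates$k2,
              EC50_hill = rates$EC50_hill, n_hill = rates$n_hill)
}

#' Steady-state cAMP level for a given AC activation
#'
#' Closed form `cAMP* = (k2/k1) (a/EC50)^n / (1 + (a/EC50)^n)` where `a`
#' is the activated-AC fraction.  Vectorised over `ac_on`.
#'
#' @param ac_on activated-AC fraction(s), >= 0.
#' @param params a [camp_params()] object.
#' @return steady-state cAMP level(s).
#' @export
#' @examples
#' steady_state_camp(0, camp_params())          # 0
#' steady_state_camp(135, camp_params())        # k2/(2 k1)
steady_state_camp <- function(ac_on, params = camp_params()) {
  if (any(ac_on < 0)) stop("ac_on must be >= 0", call. = FALSE)
  h <- (ac_on / params$EC50_hill)^params$n_hill
  (params$k2 / params$k1) * h / (1 + h)
}

# run fn with a deterministic, locally scoped RNG state
.with_seed <- function(seed, fn) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  fn()
}

#' Generate synthetic cAMP calibration data
#'
#' Emulates a cAMP-accumulation-versus-serotonin calibration experiment at
#' one or more receptor densities: for each (density, serotonin) pair the
#' activated-AC fraction is computed from the serotonin-pathway simulation
#' (see [simulate_agonist_curve()]), mapped through the steady-state Hill
#' law, and multiplied by lognormal noise with the given coefficient of
#' variation.
#'
#' @param true_params a [camp_params()] object (the ground truth).
#' @param receptor_densities 5HTR4 densities, uM.
#' @param serotonin_grid serotonin doses, uM.
#' @param noise_cv coefficient of variation of the multiplicative
#'   lognormal noise (0 = noiseless).
#' @param seed integer seed; output is reproducible given the seed.
#' @param ac_on_model optional function `f(doses, density)` returning the
#'   activated-AC fraction for a dose vector, replacing the built-in
#'   simulation (used to avoid re-simulating in Monte-Carlo loops).
#' @param rates rate table used by the built-in AC model.
#' @return data.frame with columns `serotonin_uM`, `receptor_density_uM`,
#'   `ac_on` and `camp_accumulation`.
#' @export
generate_synthetic_calibration <- function(true_params,
                                           receptor_densities = c(5e-6, 1.6e-5, 5e-5),
                                           serotonin_grid = dose_grid(0.33, 8, 4),
                                           noise_cv = 0.05, seed = 1,
                                           ac_on_model = NULL,
                                           rates = default_rates()) {
  stopifnot(noise_cv >= 0)
  if (is.null(ac_on_model)) {
    ac_on_model <- function(doses, density) {
      simulate_agonist_curve(doses, receptor_density = density,
                             rates = rates)$response
    }
  }
  blocks <- lapply(receptor_densities, function(dens) {
    ac <- ac_on_model(serotonin_grid, dens)
    data.frame(serotonin_uM = serotonin_grid,
               receptor_density_uM = dens,
               ac_on = ac,
               camp_accumulation = steady_state_camp(ac, true_params))
  })
  out <- do.call(rbind, blocks)
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    noise <- .with_seed(seed, function()
      rlnorm(nrow(out), meanlog = -sdlog^2 / 2, sdlog = sdlog))
    out$camp_accumulation <- out$camp_accumulation * noise
  }
  rownames(out) <- NULL
  out
}

#' Infer cAMP production-law parameters from steady-state data
#'
#' Least-squares fit of the steady-state Hill law to calibration points,
#' performed on the log scale (constant-CV noise is homoscedastic there),
#' with `k1` held fixed: steady-state data only constrain the ratio
#' `k2/k1`, so `k2`, `EC50_hill` and `n_hill` are free.  A bounded
#' multi-start L-BFGS-B search (5 log-uniform starts) guards against local
#' minima; approximate per-parameter confidence intervals come from the
#' numerical Hessian at the optimum.
#'
#' When the observed AC activations never approach `EC50_hill` the law is
#' a power law and only `n_hill` and the amplitude `k2/(k1 EC50^n)` are
#' identifiable; `EC50_hill` and `k2` then trade off along a flat ridge.
#' The fitted curve (and the reported `amplitude`) is well determined
#' either way.
#'
#' @param points data.frame from [generate_synthetic_calibration()] (or
#'   read via [read_calibration_csv()]); must contain
#'   `camp_accumulation` and either an `ac_on` column or enough
#'   information for `ac_on_model`.
#' @param ac_on_model optional function `f(doses, density)` supplying the
#'   activated-AC fraction when `points` has no `ac_on` column.
#' @param k1 fixed cAMP degradation rate, ms^-1.
#' @param seed seed for the multi-start draws.
#' @param n_starts number of starts (default 5).
#' @return object of class `camp_fit`: `params` ([camp_params()]),
#'   `amplitude` (`k2/(k1 EC50^n)`), `se`, `ci` (95%), `residuals`
#'   (log-scale), `points`.
#' @export
infer_camp_params <- function(points, ac_on_model = NULL, k1 = 6.1e-3,
                              seed = 1, n_starts = 5) {
  if (nrow(points) < 6) stop("need at least 6 calibration points", call. = FALSE)
  if (!"ac_on" %in% names(points)) {
    if (is.null(ac_on_model)) {
      stop("points lack an ac_on column and no ac_on_model was supplied",
           call. = FALSE)
    }
    points$ac_on <- NA_real_
    for (dens in unique(points$receptor_density_uM)) {
      idx <- which(points$receptor_density_uM == dens)
      points$ac_on[idx] <- ac_on_model(points$serotonin_uM[idx], dens)
    }
  }
  ac <- points$ac_on
  y <- points$camp_accumulation
  keep <- ac > 0 & y > 0
  ac <- ac[keep]; y <- y[keep]
  if (length(ac) < 6) stop("need at least 6 points with positive ac_on and cAMP",
                           call. = FALSE)
  if (diff(range(ac)) / max(ac) < 1e-6) {
    stop("all activations are (nearly) equal: parameters not identifiable",
         call. = FALSE)
  }
  ly <- log(y)
  # theta = log(k2, EC50, n)
  obj <- function(theta) {
    p <- exp(theta)
    h <- (ac / p[2])^p[3]
    pred <- log(p[1] / k1) + log(h) - log1p(h)
    sum((ly - pred)^2)
  }
  lower <- log(c(1e-6, 1e-4, 0.2))
  upper <- log(c(1e8, 1e6, 10))
  starts <- .with_seed(seed, function() {
    s <- matrix(runif(3 * (n_starts - 1)), ncol = 3)
    rbind(log(c(141.3, 135, 2.44)),
          t(lower + t(s) * (upper - lower)))
  })
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    res <- tryCatch(
      optim(starts[i, ], obj, method = "L-BFGS-B", lower = lower,
            upper = upper, control = list(maxit = 500)),
      error = function(e) NULL)
    if (!is.null(res) && (is.null(best) || res$value < best$value)) best <- res
  }
  if (is.null(best)) stop("calibration fit failed from all starts", call. = FALSE)
  # polish + numerical hessian
  polished <- optim(best$par, obj, method = "L-BFGS-B", lower = lower,
                    upper = upper, hessian = TRUE,
                    control = list(maxit = 500, factr = 1e4))
  theta <- polished$par
  p <- exp(theta)
  params <- camp_params(k1 = k1, k2 = p[1], EC50_hill = p[2], n_hill = p[3])
  resid <- ly - log(steady_state_camp(ac, params))
  dof <- max(length(ac) - 3L, 1L)
  s2 <- sum(resid^2) / dof
  se_theta <- rep(NA_real_, 3)
  cov <- tryCatch(s2 * solve(polished$hessian / 2), error = function(e) NULL)
  if (!is.null(cov)) se_theta <- sqrt(pmax(diag(cov), 0))
  q <- qt(0.975, dof)
  ci <- exp(cbind(lower = theta - q * se_theta,
                  upper = theta + q * se_theta))
  rownames(ci) <- c("k2", "EC50_hill", "n_hill")
  structure(list(
    params = params,
    amplitude = p[1] / (k1 * p[2]^p[3]),
    se = setNames(se_theta * p, c("k2", "EC50_hill", "n_hill")),  # delta method
    ci = ci,
    residuals = resid,
    rss_log = sum(resid^2),
    points = points
  ), class = "camp_fit")
}

#' @export
print.camp_fit <- function(x, ...) {
  p <- x$params
  cat("<camp_fit> steady-state cAMP law\n")
  cat(sprintf("  k1 (fixed)  %.4g ms^-1\n", p$k1))
  cat(sprintf("  k2          %.4g    (k2/k1 %.4g)\n", p$k2, p$k2 / p$k1))
  cat(sprintf("  EC50_hill   %.4g\n", p$EC50_hill))
  cat(sprintf("  n_hill      %.4g\n", p$n_hill))
  cat(sprintf("  amplitude k2/(k1 EC50^n)  %.4g\n", x$amplitude))
  cat(sprintf("  log-scale RSS %.4g over %d points\n", x$rss_log,
              length(x$residuals)))
  invisible(x)
}

#' @export
coef.camp_fit <- function(object, ...) {
  p <- object$params
  c(k1 = p$k1, k2 = p$k2, EC50_hill = p$EC50_hill, n_hill = p$n_hill)
}

#' @export
predict.camp_fit <- function(object, ac_on, ...) {
  steady_state_camp(ac_on, object$params)
}

#' Write / read calibration datasets as CSV
#'
#' Columns `serotonin_uM`, `receptor_density_uM`, `camp_accumulation`
#' (plus `ac_on` when present).
#'
#' @param points calibration data.frame.
#' @param path file path.
#' @return `path` (write) or the data.frame (read).
#' @export
write_calibration_csv <- function(points, path) {
  write.csv(points, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_calibration_csv
#' @export
read_calibration_csv <- function(path) {
  out <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("serotonin_uM", "receptor_density_uM", "camp_accumulation")
  miss <- setdiff(need, names(out))
  if (length(miss)) stop("calibration file lacks columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  out
}
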