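# Canonical parameter tables: rate constants, initial concentrations and
# drug definitions.  Units are micromolar (uM) for concentrations and
# milliseconds (ms) for time throughout; binding constants are uM^-1 ms^-1.

#' Default rate constants of the signalling network
#'
#' Returns the full named list of rate constants used by the reaction
#' network: serotonin synthesis/release/degradation in the enterochromaffin
#' (EC) cell, serotonin receptor binding, G-protein cycling, adenylyl
#' cyclase (AC) association/dissociation, opioid transfer/elimination, the
#' AC-competition rate `k3`, and the cyclic AMP production/degradation
#' parameters (`k1`, `k2`, `EC50_hill`, `n_hill`).
#'
#' Two constants deserve comment.  `k3` (the rate at which free activated
#' G-alpha-i displaces G-alpha-s from AC) is not independently measured;
#' it defaults to the AC association rate, the same class of molecular
#' event.  The cAMP Hill parameters are the calibrated values
#' `k1 = 6.1e-3 ms^-1`, `k2 = 141.3`, `EC50_hill = 135`, `n_hill = 2.44`.
#'
#' @param overrides named list of rate constants replacing defaults.
#'   Unknown names are an error.
#' @return named list of rate constants (time unit ms, concentration uM).
#' @export
#' @examples
#' r <- default_rates()
#' r$kbind5HT
default_rates <- function(overrides = list()) {
  rates <- list(
    ksynthesis5HTIN  = 0.05,     # uM ms^-1, zeroth-order EC-cell synthesis
    krelease5HTIN    = 0.001,    # ms^-1
    kdegrade5HTIN    = 0.01,     # ms^-1
    kdegrade5HT      = 0.01,     # ms^-1
    kreuptake5HT     = 2.38e-8,  # ms^-1
    kbind5HT         = 4.46e-3,  # uM^-1 ms^-1
    kunbind5HT       = 5e-8,     # ms^-1
    ktransfer        = 1.38e-7,  # ms^-1, blood -> tissue
    kelimination     = 1e-8,     # ms^-1, blood clearance
    kactivation      = 0.2,      # uM^-1 ms^-1, G-alpha GDP->GTP exchange
    kassembly        = 0.033,    # uM^-1 ms^-1, G-protein reassembly
    khydrolization   = 6.7e-5,   # ms^-1, GTP hydrolysis
    kACassociation_s = 3.5e-3,   # uM^-1 ms^-1
    kACassociation_i = 3.5e-3,   # uM^-1 ms^-1
    kACdissociation_s = 3.3e-6,  # ms^-1
    kACdissociation_i = 3.3e-6,  # ms^-1
    k3               = 3.5e-3,   # uM^-1 ms^-1, G-alpha-i displacing G-alpha-s
    k1               = 6.1e-3,   # ms^-1, cAMP degradation
    k2               = 141.3,    # uM ms^-1 scale of cAMP production
    EC50_hill        = 135,      # AC_on units, midpoint of the cAMP Hill law
    n_hill           = 2.44      # Hill coefficient of cAMP production
  )
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(rates))
    if (length(bad)) {
      stop("unknown rate constant(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    rates[names(overrides)] <- overrides
  }
  stopifnot(all(vapply(rates, is.numeric, logical(1))))
  if (any(unlist(rates) < 0)) stop("rate constants must be >= 0", call. = FALSE)
  if (rates$n_hill <= 0 || rates$EC50_hill <= 0) {
    stop("n_hill and EC50_hill must be > 0", call. = FALSE)
  }
  rates
}

# species table; tags group species by pathway membership
.species_table <- function() {
  data.frame(
    name = c("5HT_IN", "5HT", "5HTR4", "5HTR4:5HT",
             "aS_GDP:bgS", "aS_GTP", "aS_GDP", "bgS",
             "AC", "AC:aS_GTP", "AC:aI_GTP",
             "MOR", "MOR:OL", "OL", "OL_Blood",
             "aI_GDP:bgI", "aI_GTP", "aI_GDP", "bgI",
             "cAMP"),
    initial = c(1.8e-4, 1e-7, 5e-6, 0,
                0.05, 0, 0, 0,
                2e-3, 0, 0,
                5e-6, 0, 0, 0,
                0.05, 0, 0, 0,
                0),
    pathway_tag = c(rep("serotonin", 8),
                    rep("shared", 3),
                    rep("opioid", 8),
                    "messenger"),
    stringsAsFactors = FALSE
  )
}

#' Default initial concentrations
#'
#' Named vector of initial concentrations (uM) for all 20 model species.
#' The free AC concentration defaults to `2e-3` uM (the total AC pool; all
#' AC starts free), which can be overridden.  All complexes start at zero.
#'
#' @param overrides named numeric vector/list replacing defaults; unknown
#'   species names are an error.
#' @return named numeric vector of length 20.
#' @export
default_initial_state <- function(overrides = NULL) {
  tab <- .species_table()
  x0 <- setNames(tab$initial, tab$name)
  if (!is.null(overrides) && length(overrides)) {
    ov <- unlist(overrides)
    bad <- setdiff(names(ov), names(x0))
    if (length(bad)) {
      stop("unknown species: ", paste(bad, collapse = ", "), call. = FALSE)
    }
    x0[names(ov)] <- ov
  }
  if (any(x0 < 0)) stop("initial concentrations must be >= 0", call. = FALSE)
  x0
}

#' Define an opioid ligand
#'
#' A `drug_spec` bundles the receptor affinity and pharmacokinetic
#' constants of one mu-opioid-receptor ligand.  The binding on-rate is
#' derived from the dissociation constant as `kon = koff / Kd` (after
#' converting Kd from nM to uM), with `koff` fixed at `5e-8 ms^-1` for all
#' ligands by default so that affinity differences are carried entirely by
#' `kon`.
#'
#' @param name drug label.
#' @param Kd equilibrium dissociation constant at MOR, in nM.
#' @param dose default administered dose, uM.
#' @param kdegOL first-order tissue degradation rate of the ligand, ms^-1.
#'   Pharmaceutical opioids default to `1e-8`; rapidly cleaved endogenous
#'   peptides are orders of magnitude faster.
#' @param koff receptor unbinding rate, ms^-1.
#' @param kon receptor binding rate, uM^-1 ms^-1; computed from `koff / Kd`
#'   when not supplied.
#' @param dose_compartment `"blood"` (dose enters the blood species and
#'   reaches the tissue by first-order transfer) or `"tissue"` (dose placed
#'   directly in the tissue compartment).
#' @return an object of class `drug_spec`.
#' @export
#' @examples
#' drug_spec("Morphine", Kd = 76.08, dose = 4.7)
drug_spec <- function(name, Kd, dose, kdegOL = 1e-8,
                      koff = 5e-8, kon = NULL,
                      dose_compartment = c("blood", "tissue")) {
  dose_compartment <- match.arg(dose_compartment)
  Kd_uM <- Kd * 1e-3
  if (is.null(kon)) kon <- koff / Kd_uM
  if (any(c(Kd, koff, kon) <= 0) || kdegOL < 0 || dose < 0) {
    stop("drug constants must be positive (kdegOL, dose >= 0)", call. = FALSE)
  }
  structure(list(name = name, Kd = Kd, Kd_uM = Kd_uM,
                 koff = koff, kon = kon, kdegOL = kdegOL,
                 dose = dose, dose_compartment = dose_compartment),
            class = "drug_spec")
}

#' @export
print.drug_spec <- function(x, ...) {
  cat(sprintf("<drug_spec> %s\n", x$name))
  cat(sprintf("  Kd     %.4g nM   (kon %.4g uM^-1 ms^-1, koff %.3g ms^-1)\n",
              x$Kd, x$kon, x$koff))
  cat(sprintf("  kdegOL %.3g ms^-1\n", x$kdegOL))
  cat(sprintf("  dose   %.4g uM into %s\n", x$dose, x$dose_compartment))
  invisible(x)
}

#' The four reference opioids
#'
#' Morphine, Methadone, Fentanyl (pharmaceutical, slow tissue degradation)
#' and Endomorphin-2 (endogenous tetrapeptide, fast degradation), with
#' literature affinities and equianalgesic doses: 10 mg Morphine (4.7 uM),
#' 1 mg Methadone (0.2 uM), 0.1 mg Fentanyl (0.01 uM) and 1425.51 uM
#' Endomorphin-2.
#'
#' @return named list of [drug_spec()] objects.
#' @export
#' @examples
#' default_drugs()$Fentanyl
default_drugs <- function() {
  list(
    Morphine       = drug_spec("Morphine",       Kd = 76.08, dose = 4.7),
    Methadone      = drug_spec("Methadone",      Kd = 41.92, dose = 0.2),
    Fentanyl       = drug_spec("Fentanyl",       Kd = 0.57,  dose = 0.01),
    `Endomorphin-2` = drug_spec("Endomorphin-2", Kd = 2.33,  dose = 1425.51,
                                kdegOL = 1.02e-4)
  )
}

# unit helpers
ms_to_hours <- function(ms) ms / 3.6e6
ms_to_days  <- function(ms) ms / 8.64e7
hours_to_ms <- function(h) h * 3.6e6
days_to_ms  <- function(d) d * 8.64e7
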