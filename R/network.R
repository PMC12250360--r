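# Reaction network assembly: species, reactions, stoichiometry and
# propensity (flux) functions.
#
# The full network has 25 reactions in three blocks:
#   S1-S12  serotonin pathway (EC-cell synthesis/release, 5HTR4 binding,
#           G-alpha-s cycle, AC activation)
#   O1-O10  opioid pathway (two-compartment drug kinetics, MOR binding,
#           G-alpha-i cycle, AC inhibition)
#   C1-C3   cyclic AMP production (Hill law in the activated-AC fraction),
#           cAMP degradation, and G-alpha-i displacing G-alpha-s from AC.
# All reactions are mass action except C1 (Hill-type production).

# full reaction table; each entry: reactants/products as named multisets
.reaction_table <- function() {
  r <- function(id, block, reactants, products, rate, law = "mass_action") {
    list(id = id, block = block, reactants = reactants, products = products,
         rate_constant_name = rate, rate_law = law)
  }
  list(
    r("S1",  "serotonin", c(),                       c("5HT_IN" = 1),  "ksynthesis5HTIN"),
    r("S2",  "serotonin", c("5HT_IN" = 1),           c("5HT" = 1),     "krelease5HTIN"),
    r("S3",  "serotonin", c("5HT_IN" = 1),           c(),              "kdegrade5HTIN"),
    r("S4",  "serotonin", c("5HT" = 1),              c(),              "kdegrade5HT"),
    r("S5",  "serotonin", c("5HT" = 1),              c("5HT_IN" = 1),  "kreuptake5HT"),
    r("S6",  "serotonin", c("5HT" = 1, "5HTR4" = 1), c("5HTR4:5HT" = 1), "kbind5HT"),
    r("S7",  "serotonin", c("5HTR4:5HT" = 1),        c("5HTR4" = 1),   "kunbind5HT"),
    r("S8",  "serotonin", c("5HTR4:5HT" = 1, "aS_GDP:bgS" = 1),
                          c("5HTR4:5HT" = 1, "aS_GTP" = 1, "bgS" = 1), "kactivation"),
    r("S9",  "serotonin", c("aS_GTP" = 1),           c("aS_GDP" = 1),  "khydrolization"),
    r("S10", "serotonin", c("aS_GDP" = 1, "bgS" = 1), c("aS_GDP:bgS" = 1), "kassembly"),
    r("S11", "serotonin", c("aS_GTP" = 1, "AC" = 1), c("AC:aS_GTP" = 1), "kACassociation_s"),
    r("S12", "serotonin", c("AC:aS_GTP" = 1),        c("aS_GTP" = 1, "AC" = 1), "kACdissociation_s"),

    r("O1",  "opioid", c("OL" = 1, "MOR" = 1),       c("MOR:OL" = 1),  "kbindOL"),
    r("O2",  "opioid", c("MOR:OL" = 1),              c("MOR" = 1),     "kunbindOL"),
    r("O3",  "opioid", c("OL_Blood" = 1),            c("OL" = 1),      "ktransfer"),
    r("O4",  "opioid", c("OL_Blood" = 1),            c(),              "kelimination"),
    r("O5",  "opioid", c("OL" = 1),                  c(),              "kdegOL"),
    r("O6",  "opioid", c("MOR:OL" = 1, "aI_GDP:bgI" = 1),
                       c("MOR:OL" = 1, "aI_GTP" = 1, "bgI" = 1), "kactivation"),
    r("O7",  "opioid", c("aI_GTP" = 1),              c("aI_GDP" = 1),  "khydrolization"),
    r("O8",  "opioid", c("aI_GDP" = 1, "bgI" = 1),   c("aI_GDP:bgI" = 1), "kassembly"),
    r("O9",  "opioid", c("aI_GTP" = 1, "AC" = 1),    c("AC:aI_GTP" = 1), "kACassociation_i"),
    r("O10", "opioid", c("AC:aI_GTP" = 1),           c("aI_GTP" = 1, "AC" = 1), "kACdissociation_i"),

    r("C1",  "competing", c(),                       c("cAMP" = 1),    "k2", "hill_production"),
    r("C2",  "competing", c("cAMP" = 1),             c(),              "k1"),
    r("C3",  "competing", c("aI_GTP" = 1, "AC:aS_GTP" = 1),
                          c("AC:aI_GTP" = 1, "aS_GTP" = 1), "k3")
  )
}

#' Build the signalling reaction network
#'
#' Assembles the requested blocks of the 25-reaction serotonin/opioid/cAMP
#' network together with the species they reference.  The species set is
#' the union of species appearing in the selected reactions (plus the AC
#' pools needed to evaluate the activated-AC fraction when the cAMP block
#' is included), so a serotonin-only network carries no opioid species.
#'
#' @param rates named list from [default_rates()] (possibly with overrides).
#' @param drug a [drug_spec()] or `NULL`.  Required when the opioid block
#'   is requested; supplies `kbindOL`, `kunbindOL` and `kdegOL`.
#' @param pathways character subset of
#'   `c("serotonin", "opioid", "competing")`.  `"competing"` adds the cAMP
#'   production/degradation reactions C1-C2 and, when the opioid block is
#'   also present, the AC-competition reaction C3.
#' @param initial_overrides named vector of initial-concentration
#'   overrides, passed to [default_initial_state()].
#' @param release_ligand_on_unbind logical; the printed unbinding reactions
#'   consume the ligand (`receptor:ligand -> receptor`).  Set `TRUE` to
#'   return the free ligand instead.  Default `FALSE` (literal reading).
#' @param pulse_release optional list `list(amplitude=, period_ms=, duty=)`
#'   switching the EC-cell serotonin release (S2) to a periodic burst
#'   train: during a fraction `duty` of each period the release rate is
#'   `krelease5HTIN * amplitude`, otherwise zero.  Default `NULL`
#'   (continuous release).
#' @return an object of class `oic_network`.
#' @export
#' @examples
#' net <- build_network(default_rates(), default_drugs()$Morphine)
#' net
#' serot <- build_network(default_rates(), pathways = "serotonin")
#' length(serot$reactions)  # 12
build_network <- function(rates = default_rates(), drug = NULL,
                          pathways = c("serotonin", "opioid", "competing"),
                          initial_overrides = NULL,
                          release_ligand_on_unbind = FALSE,
                          pulse_release = NULL) {
  pathways <- match.arg(pathways, several.ok = TRUE)
  if ("opioid" %in% pathways && is.null(drug)) {
    stop("the opioid pathway requires a drug_spec", call. = FALSE)
  }
  if (identical(pathways, "competing") || !length(setdiff(pathways, "competing"))) {
    stop("the competing block requires at least one upstream pathway",
         call. = FALSE)
  }
  all_rx <- .reaction_table()
  keep <- vapply(all_rx, function(rx) {
    if (rx$block == "competing") {
      if (rx$id == "C3") return("opioid" %in% pathways && "competing" %in% pathways)
      return("competing" %in% pathways)
    }
    rx$block %in% pathways
  }, logical(1))
  rx <- all_rx[keep]

  if (release_ligand_on_unbind) {
    rx <- lapply(rx, function(r) {
      if (r$id == "S7") r$products <- c("5HTR4" = 1, "5HT" = 1)
      if (r$id == "O2") r$products <- c("MOR" = 1, "OL" = 1)
      r
    })
  }

  # resolve rate constants (drug-level names come from the drug spec)
  drug_rates <- if (!is.null(drug)) {
    list(kbindOL = drug$kon, kunbindOL = drug$koff, kdegOL = drug$kdegOL)
  } else list()
  rx <- lapply(rx, function(r) {
    nm <- r$rate_constant_name
    k <- if (nm %in% names(drug_rates)) drug_rates[[nm]] else rates[[nm]]
    if (is.null(k)) stop("unknown rate constant: ", nm, call. = FALSE)
    r$k <- k
    r
  })

  # species = union referenced; AC pools are needed by the C1 propensity
  referenced <- unique(unlist(lapply(rx, function(r)
    c(names(r$reactants), names(r$products)))))
  if ("competing" %in% pathways) {
    referenced <- union(referenced, "AC")
  }
  tab <- .species_table()
  tab <- tab[tab$name %in% referenced, , drop = FALSE]
  x0 <- default_initial_state(initial_overrides)
  tab$initial <- unname(x0[tab$name])

  net <- structure(list(
    species = tab,
    reactions = rx,
    rates = rates,
    drug = drug,
    pathways = pathways,
    release_ligand_on_unbind = release_ligand_on_unbind,
    pulse_release = pulse_release
  ), class = "oic_network")
  net$stoich <- stoichiometric_matrix(net)
  net
}

#' @export
print.oic_network <- function(x, ...) {
  cat(sprintf("<oic_network> %d species, %d reactions [%s]\n",
              nrow(x$species), length(x$reactions),
              paste(x$pathways, collapse = " + ")))
  if (!is.null(x$drug)) cat(sprintf("  drug: %s (Kd %.4g nM, dose %.4g uM)\n",
                                    x$drug$name, x$drug$Kd, x$drug$dose))
  invisible(x)
}

#' Species names of a network
#' @param network an `oic_network`.
#' @return character vector in canonical order.
#' @export
species_names <- function(network) network$species$name

#' Stoichiometric matrix
#'
#' Net-change matrix `S` with one row per species and one column per
#' reaction: `S[i, j]` is the net number of molecules of species `i`
#' produced by one firing of reaction `j`.  Catalytic species (appearing
#' identically on both sides) have net zero.
#'
#' @param network an `oic_network`.
#' @return integer matrix, `dimnames` = species x reaction ids.
#' @export
#' @examples
#' net <- build_network(pathways = "serotonin")
#' stoichiometric_matrix(net)[, "S6"]
stoichiometric_matrix <- function(network) {
  sp <- network$species$name
  S <- matrix(0L, nrow = length(sp), ncol = length(network$reactions),
              dimnames = list(sp, vapply(network$reactions, `[[`, "", "id")))
  for (j in seq_along(network$reactions)) {
    rx <- network$reactions[[j]]
    for (nm in names(rx$reactants)) S[nm, j] <- S[nm, j] - as.integer(rx$reactants[[nm]])
    for (nm in names(rx$products))  S[nm, j] <- S[nm, j] + as.integer(rx$products[[nm]])
  }
  S
}

# activated-AC fraction from a named state vector (0 when no AC present)
.ac_on_state <- function(state) {
  on  <- if ("AC:aS_GTP" %in% names(state)) state[["AC:aS_GTP"]] else 0
  off <- if ("AC:aI_GTP" %in% names(state)) state[["AC:aI_GTP"]] else 0
  ac  <- if ("AC" %in% names(state)) state[["AC"]] else 0
  tot <- on + off + ac
  if (tot <= 0) return(0)
  on / tot
}

#' Reaction propensities (fluxes)
#'
#' Evaluates the flux vector of all reactions at a given state.  Mass
#' action reactions return `k * prod(reactant concentrations)`; the
#' zeroth-order synthesis reaction returns its rate constant; the cAMP
#' production reaction C1 returns
#' `k2 * (AC_on/EC50)^n / (1 + (AC_on/EC50)^n)` evaluated at the
#' activated-AC fraction of the state.
#'
#' @param network an `oic_network`.
#' @param state named non-negative concentration vector (uM) matching
#'   `species_names(network)`.
#' @param t time in ms (only relevant in pulsed-release mode).
#' @return named flux vector (uM/ms), one entry per reaction.
#' @export
#' @examples
#' net <- build_network(pathways = "serotonin")
#' x <- setNames(net$species$initial, net$species$name)
#' propensities(net, x)
propensities <- function(network, state, t = 0) {
  sp <- network$species$name
  if (is.null(names(state))) names(state) <- sp
  state <- state[sp]
  if (any(is.na(state))) stop("state does not match network species", call. = FALSE)
  if (any(state < 0)) stop("negative concentration in state", call. = FALSE)
  flux <- .propensities_fast(network, state, t)
  setNames(flux, vapply(network$reactions, `[[`, "", "id"))
}

# internal fast path: assumes state ordered, non-negative enforced upstream
.propensities_fast <- function(network, state, t) {
  rates <- network$rates
  pulse <- network$pulse_release
  n <- length(network$reactions)
  flux <- numeric(n)
  for (j in seq_len(n)) {
    rx <- network$reactions[[j]]
    if (rx$rate_law == "hill_production") {
      ac_on <- .ac_on_state(state)
      h <- (ac_on / rates$EC50_hill)^rates$n_hill
      flux[j] <- rx$k * h / (1 + h)
    } else {
      k <- rx$k
      if (!is.null(pulse) && rx$id == "S2") {
        phase <- (t %% pulse$period_ms) / pulse$period_ms
        k <- if (phase < pulse$duty) k * pulse$amplitude else 0
      }
      f <- k
      for (nm in names(rx$reactants)) {
        m <- rx$reactants[[nm]]
        f <- f * if (m == 1) state[[nm]] else state[[nm]]^m
      }
      flux[j] <- f
    }
  }
  flux
}

#' Conserved moiety totals
#'
#' The closed binding/cycling structure of the network conserves seven
#' totals along any trajectory: the two receptor pools (free + bound), the
#' AC pool (free + stimulated + inhibited), and the four G-protein subunit
#' pools (alpha-s, beta-gamma-s, alpha-i, beta-gamma-i, each summed over
#' free, complexed and AC-bound forms).  Moieties whose species are absent
#' from the network are omitted.
#'
#' @param network an `oic_network`.
#' @param state named concentration vector.
#' @return named numeric vector of moiety totals (uM).
#' @export
conserved_totals <- function(network, state) {
  if (is.null(names(state))) names(state) <- network$species$name
  g <- function(nms) {
    nms <- intersect(nms, names(state))
    if (!length(nms)) return(NA_real_)
    sum(state[nms])
  }
  tot <- c(
    `5HTR4_total` = g(c("5HTR4", "5HTR4:5HT")),
    MOR_total     = g(c("MOR", "MOR:OL")),
    AC_total      = g(c("AC", "AC:aS_GTP", "AC:aI_GTP")),
    aS_total      = g(c("aS_GDP:bgS", "aS_GTP", "aS_GDP", "AC:aS_GTP")),
    bgS_total     = g(c("aS_GDP:bgS", "bgS")),
    aI_total      = g(c("aI_GDP:bgI", "aI_GTP", "aI_GDP", "AC:aI_GTP")),
    bgI_total     = g(c("aI_GDP:bgI", "bgI"))
  )
  tot[!is.na(tot)]
}

# indicator vectors of the moieties, as rows over network species; used in
# tests to verify they lie in the left null space of S
.moiety_matrix <- function(network) {
  sp <- network$species$name
  defs <- list(
    `5HTR4_total` = c("5HTR4", "5HTR4:5HT"),
    MOR_total     = c("MOR", "MOR:OL"),
    AC_total      = c("AC", "AC:aS_GTP", "AC:aI_GTP"),
    aS_total      = c("aS_GDP:bgS", "aS_GTP", "aS_GDP", "AC:aS_GTP"),
    bgS_total     = c("aS_GDP:bgS", "bgS"),
    aI_total      = c("aI_GDP:bgI", "aI_GTP", "aI_GDP", "AC:aI_GTP"),
    bgI_total     = c("aI_GDP:bgI", "bgI")
  )
  defs <- defs[vapply(defs, function(d) all(d %in% sp), logical(1))]
  m <- matrix(0, nrow = length(defs), ncol = length(sp),
              dimnames = list(names(defs), sp))
  for (i in seq_along(defs)) m[i, defs[[i]]] <- 1
  m
}
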