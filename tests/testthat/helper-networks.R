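# Shared fixtures: toy networks built in code and a fixed-step RK4
# integrator used as an independent oracle for the LSODA engine.

# single-species first-order decay network A -> 0 at rate k
make_decay_network <- function(k = 0.01, A0 = 1) {
  species <- data.frame(name = "A", initial = A0, pathway_tag = "custom",
                        stringsAsFactors = FALSE)
  reactions <- list(list(id = "D1", block = "custom",
                         reactants = c(A = 1), products = setNames(numeric(0), character(0)),
                         rate_constant_name = "k", rate_law = "mass_action",
                         k = k))
  oicsim:::.network_from_parts(species, reactions, rates = list(k = k))
}

# opioid binding-only subnetwork OL + MOR <-> MOR:OL (ligand consumed on
# unbind, as in the full model)
make_binding_network <- function(kon, koff, MOR0 = 5e-6) {
  species <- data.frame(name = c("OL", "MOR", "MOR:OL"),
                        initial = c(0, MOR0, 0), pathway_tag = "custom",
                        stringsAsFactors = FALSE)
  reactions <- list(
    list(id = "B1", block = "custom", reactants = c(OL = 1, MOR = 1),
         products = c(`MOR:OL` = 1), rate_constant_name = "kon",
         rate_law = "mass_action", k = kon),
    list(id = "B2", block = "custom", reactants = c(`MOR:OL` = 1),
         products = c(MOR = 1), rate_constant_name = "koff",
         rate_law = "mass_action", k = koff)
  )
  oicsim:::.network_from_parts(species, reactions,
                               rates = list(kon = kon, koff = koff))
}

# classical fixed-step RK4 on dx/dt = S pi(x), independent of deSolve
rk4_integrate <- function(net, x0, t_end, h) {
  S <- net$stoich
  f <- function(x, t) {
    as.numeric(S %*% oicsim:::.propensities_fast(net, pmax(x, 0), t))
  }
  x <- x0
  t <- 0
  steps <- ceiling(t_end / h)
  for (i in seq_len(steps)) {
    k1 <- f(x, t)
    k2 <- f(x + h / 2 * k1, t + h / 2)
    k3 <- f(x + h / 2 * k2, t + h / 2)
    k4 <- f(x + h * k3, t + h)
    x <- x + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- t + h
  }
  x
}

# full-network initial state with the Morphine dose in the blood pool
dosed_state <- function(net, dose = 4.7) {
  x <- setNames(net$species$initial, net$species$name)
  x["OL_Blood"] <- dose
  x
}
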