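# Small purpose-built networks used across the simulation tests.

# One reversible non-enzymatic reaction A <-> B in a single compartment,
# with A starting at `a0` mM. With k_f = k_r = k the solution is
# A(t) = A_inf + (a0 - A_inf) * exp(-2 k t).
make_ab_network <- function(a0 = 1) {
  compartments <- data.frame(id = "cell", volume_l = 1e-12,
                             stringsAsFactors = FALSE)
  species <- data.frame(id = c("A", "B"), name = c("species A", "species B"),
                        compartment = "cell", role = "metabolite",
                        initial_conc_mM = c(a0, 0), stringsAsFactors = FALSE)
  rx <- list(reaction_spec(1L, "non_enzymatic",
                           substrates = c("A@cell" = 1),
                           products = c("B@cell" = 1),
                           parameters = c("kf_r1", "kr_r1", "Keq_r1")))
  new_network(compartments, species, rx)
}

ab_variant <- function(kf = 1, kr = 1) {
  v <- c(kf_r1 = kf, kr_r1 = kr, Keq_r1 = kf / kr)
  attr(v, "index") <- 1L
  v
}

# Closed two-compartment subnetwork: A is shuttled out by a transporter
# and interconverts with B in both compartments; no sources, no
# degradation, so total amount is conserved.
make_transport_network <- function(a0 = 1) {
  compartments <- data.frame(id = c("intracellular", "extracellular"),
                             volume_l = c(1e-12, 1e-9),
                             stringsAsFactors = FALSE)
  species <- rbind(
    data.frame(id = c("A", "B"), name = c("A", "B"),
               compartment = "intracellular", role = "metabolite",
               initial_conc_mM = c(a0, 0), stringsAsFactors = FALSE),
    data.frame(id = c("A", "B"), name = c("A", "B"),
               compartment = "extracellular", role = "metabolite",
               initial_conc_mM = 0, stringsAsFactors = FALSE),
    data.frame(id = "TR", name = "transporter", compartment = "intracellular",
               role = "transporter", initial_conc_mM = 0,
               stringsAsFactors = FALSE))
  rx <- list(
    reaction_spec(1L, "non_enzymatic",
                  substrates = c("A@intracellular" = 1),
                  products = c("B@intracellular" = 1),
                  parameters = c("kf_r1", "kr_r1", "Keq_r1")),
    reaction_spec(2L, "transport",
                  substrates = c("A@intracellular" = 1),
                  products = c("A@extracellular" = 1),
                  catalyst = "TR@intracellular",
                  parameters = c("Km_r2", "kcat_TR")),
    reaction_spec(3L, "non_enzymatic",
                  substrates = c("A@extracellular" = 1),
                  products = c("B@extracellular" = 1),
                  parameters = c("kf_r3", "kr_r3", "Keq_r3")))
  new_network(compartments, species, rx)
}

transport_variant <- function() {
  v <- c(kf_r1 = 2e-3, kr_r1 = 1e-3, Keq_r1 = 2,
         Km_r2 = 0.01, kcat_TR = 10, conc_TR = 1e-5,
         kf_r3 = 1e-3, kr_r3 = 5e-4, Keq_r3 = 2)
  attr(v, "index") <- 1L
  v
}

# Minimal two-compartment network with a programmed release feeding A,
# export of A, and first-order loss; used where many fast simulations of
# an "observable" extracellular species are needed.
make_release_network <- function() {
  compartments <- data.frame(id = c("intracellular", "extracellular"),
                             volume_l = c(1e-12, 1e-9),
                             stringsAsFactors = FALSE)
  species <- rbind(
    data.frame(id = "A", name = "A", compartment = "intracellular",
               role = "metabolite", initial_conc_mM = 1e-28,
               stringsAsFactors = FALSE),
    data.frame(id = "A", name = "A", compartment = "extracellular",
               role = "metabolite", initial_conc_mM = 1e-28,
               stringsAsFactors = FALSE),
    data.frame(id = "SRC", name = "source pool", compartment = "intracellular",
               role = "source", initial_conc_mM = 0, stringsAsFactors = FALSE),
    data.frame(id = "TR", name = "transporter", compartment = "intracellular",
               role = "transporter", initial_conc_mM = 0,
               stringsAsFactors = FALSE))
  rx <- list(
    reaction_spec(1L, "substrate_release",
                  substrates = c("SRC@intracellular" = 1),
                  products = c("A@intracellular" = 1)),
    reaction_spec(2L, "transport",
                  substrates = c("A@intracellular" = 1),
                  products = c("A@extracellular" = 1),
                  catalyst = "TR@intracellular",
                  parameters = c("Km_r2", "kcat_TR")),
    reaction_spec(3L, "degradation",
                  substrates = c("A@extracellular" = 1),
                  parameters = "kdeg_r3"))
  new_network(compartments, species, rx)
}

release_net_variant <- function() {
  v <- c(Km_r2 = 0.01, kcat_TR = 10, conc_TR = 1e-5, kdeg_r3 = 1e-5)
  attr(v, "index") <- 1L
  v
}

# score table built directly from numbers (no simulation)
fake_score_table <- function(points) {
  structure(c(cumulative_scores(points),
              list(sigma = 1, n_below_loq = 0L)),
            class = "aa_scoretable")
}

# trajectory object built directly from a matrix (no simulation)
fake_trajectory <- function(times_h, conc, variant = 1L, status = "ok") {
  structure(list(times_h = times_h, conc = conc, status = status,
                 message = NA_character_, variant = variant),
            class = "aa_trajectory")
}
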