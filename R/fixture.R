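# Packaged AA-cascade network.
#
# The catalogue covers the canonical eicosanoid biosynthesis map: COX-1/COX-2
# oxygenation of arachidonic acid (AA) to PGH2, the five prostanoid synthase
# arms (PGE2, PGF2a, PGD2/PGJ2, PGI2, TXA2) with 15-PGDH/PTGR2 catabolism,
# the 5-/12-/15-LOX arms (HPETEs reduced to HETEs by PHGPx, 5-HETE oxidised
# to 5-oxo-ETE, LTA4 converted to LTB4/LTC4), non-enzymatic hydrolysis and
# dehydration reactions in both compartments, ABC- and PGT-mediated export,
# and first-order degradation of every metabolite. AA enters via three
# alternative routes: reaction 1 (enzymatic, phospholipase-mediated,
# disabled by default), reaction 95 (time-programmed release from an
# unspecified source, enabled by default) and reaction 113 (non-enzymatic
# release from a membrane-bound pool, disabled by default).

INTRACELLULAR_VOL_L <- 1e-12  # 1 pL
EXTRACELLULAR_VOL_L <- 1e-9   # 1 nL
METABOLITE_INIT_MM <- 1e-28

# metabolite id -> display name; order fixed (drives state-vector layout)
AA_METABOLITES <- c(
  AA            = "arachidonic acid",
  PGH2          = "prostaglandin H2",
  PGE2          = "prostaglandin E2",
  PGF2a         = "prostaglandin F2alpha",
  PGD2          = "prostaglandin D2",
  PGJ2          = "prostaglandin J2",
  PGJ2_15d      = "15-deoxy-prostaglandin J2",
  PGI2          = "prostaglandin I2",
  PGF1a_6keto   = "6-keto-prostaglandin F1alpha",
  TXA2          = "thromboxane A2",
  TXB2          = "thromboxane B2",
  PGE2_15keto   = "15-keto-prostaglandin E2",
  PGE2_dhk      = "13,14-dihydro-15-keto-prostaglandin E2",
  PGF2a_15keto  = "15-keto-prostaglandin F2alpha",
  PGF2a_dhk     = "13,14-dihydro-15-keto-prostaglandin F2alpha",
  HPETE5        = "5-hydroperoxy-eicosatetraenoic acid",
  HETE5         = "5-hydroxy-eicosatetraenoic acid",
  oxoETE5       = "5-oxo-eicosatetraenoic acid",
  HPETE12       = "12-hydroperoxy-eicosatetraenoic acid",
  HETE12        = "12-hydroxy-eicosatetraenoic acid",
  HPETE15       = "15-hydroperoxy-eicosatetraenoic acid",
  HETE15        = "15-hydroxy-eicosatetraenoic acid",
  LTA4          = "leukotriene A4",
  LTB4          = "leukotriene B4",
  LTC4          = "leukotriene C4")

# 15-keto-PGF2a is turned over intracellularly before it can be exported,
# so it has no extracellular counterpart: 25 + 24 = 49 metabolites.
AA_EXPORTED <- setdiff(names(AA_METABOLITES), "PGF2a_15keto")

AA_ENZYMES <- c(
  PLA2      = "phospholipase A2",
  COX1      = "cyclooxygenase-1",
  COX2      = "cyclooxygenase-2",
  PGES      = "prostaglandin E synthase",
  PGFS      = "prostaglandin F synthase",
  PGDS      = "prostaglandin D synthase",
  PGIS      = "prostaglandin I synthase",
  TXAS      = "thromboxane A synthase",
  PGDH15    = "15-prostaglandin dehydrogenase",
  PTGR2     = "prostaglandin reductase 2",
  LOX5_FLAP = "5-lipoxygenase/FLAP complex",
  LOX5      = "5-lipoxygenase",
  LOX12     = "12-lipoxygenase",
  LOX15     = "15-lipoxygenase",
  PHGPx     = "phospholipid hydroperoxide glutathione peroxidase",
  HEDH5     = "5-hydroxyeicosanoid dehydrogenase",
  LTA4H     = "leukotriene A4 hydrolase",
  LTC4S     = "leukotriene C4 synthase")

AA_TRANSPORTERS <- c(
  PGT = "prostaglandin transporter",
  ABC = "ATP-binding cassette transporter")

# species carried by each transporter (intracellular -> extracellular)
PGT_CARGO <- c("PGE2", "PGF2a", "PGD2", "PGE2_15keto", "PGE2_dhk", "PGH2",
               "PGF1a_6keto", "PGJ2", "PGJ2_15d", "PGF2a_dhk", "PGI2",
               "TXA2", "TXB2")
ABC_CARGO <- c("AA", "HPETE5", "HETE5", "oxoETE5", "HPETE12", "HETE12",
               "HPETE15", "HETE15", "LTA4", "LTB4", "LTC4")
# prostanoids additionally exported by ABC (dual-route species)
ABC_DUAL <- c("PGE2", "PGF2a", "PGD2", "PGE2_15keto", "PGE2_dhk")

# enzymatic conversions (reactions 2-22): substrate, product, catalyst
AA_ENZYMATIC <- list(
  list("AA", "PGH2", "COX1"),
  list("AA", "PGH2", "COX2"),
  list("PGH2", "PGE2", "PGES"),
  list("PGH2", "PGF2a", "PGFS"),
  list("PGH2", "PGD2", "PGDS"),
  list("PGH2", "PGI2", "PGIS"),
  list("PGH2", "TXA2", "TXAS"),
  list("PGE2", "PGE2_15keto", "PGDH15"),
  list("PGE2_15keto", "PGE2_dhk", "PTGR2"),
  list("PGF2a", "PGF2a_15keto", "PGDH15"),
  list("PGF2a_15keto", "PGF2a_dhk", "PTGR2"),
  list("AA", "HPETE5", "LOX5_FLAP"),
  list("AA", "HPETE12", "LOX12"),
  list("AA", "HPETE15", "LOX15"),
  list("HPETE5", "HETE5", "PHGPx"),
  list("HPETE12", "HETE12", "PHGPx"),
  list("HPETE15", "HETE15", "PHGPx"),
  list("HETE5", "oxoETE5", "HEDH5"),
  list("HPETE5", "LTA4", "LOX5"),
  list("LTA4", "LTB4", "LTA4H"),
  list("LTA4", "LTC4", "LTC4S"))

# non-enzymatic conversions (reactions 23-33): substrate, product, compartment
AA_NONENZ <- list(
  list("PGD2", "PGJ2", "intracellular"),
  list("PGJ2", "PGJ2_15d", "intracellular"),
  list("PGI2", "PGF1a_6keto", "intracellular"),
  list("TXA2", "TXB2", "intracellular"),
  list("PGD2", "PGJ2", "extracellular"),
  list("PGJ2", "PGJ2_15d", "extracellular"),
  list("PGI2", "PGF1a_6keto", "extracellular"),
  list("TXA2", "TXB2", "extracellular"),
  list("HPETE5", "HETE5", "extracellular"),
  list("HPETE12", "HETE12", "extracellular"),
  list("HPETE15", "HETE15", "extracellular"))

enz_params <- function(n) sprintf(c("kcat_r%d", "Kms_r%d", "Kmp_r%d", "Keq_r%d"), n)
nonenz_params <- function(n) sprintf(c("kf_r%d", "kr_r%d", "Keq_r%d"), n)

#' Build the packaged AA-cascade network
#'
#' Constructs the shipped arachidonic-acid cascade fixture: 113 reactions
#' over 49 metabolites (25 intracellular, 24 extracellular), 18 enzymes,
#' 2 transporters and 2 source pools, in an intracellular (1 pL) and an
#' extracellular (1 nL) compartment. All metabolites start at 1e-28 mM.
#' AA-release reaction 95 is enabled; the alternative release reactions 1
#' and 113 are disabled.
#'
#' @return a validated `aa_network`
#' @export
build_aa_cascade <- function() {
  compartments <- data.frame(
    id = c("intracellular", "extracellular"),
    volume_l = c(INTRACELLULAR_VOL_L, EXTRACELLULAR_VOL_L),
    stringsAsFactors = FALSE)

  ic <- function(id) species_key(id, "intracellular")
  ec <- function(id) species_key(id, "extracellular")

  species <- rbind(
    data.frame(id = names(AA_METABOLITES), name = unname(AA_METABOLITES),
               compartment = "intracellular", role = "metabolite",
               initial_conc_mM = METABOLITE_INIT_MM, stringsAsFactors = FALSE),
    data.frame(id = AA_EXPORTED, name = paste("extracellular",
                                              unname(AA_METABOLITES[AA_EXPORTED])),
               compartment = "extracellular", role = "metabolite",
               initial_conc_mM = METABOLITE_INIT_MM, stringsAsFactors = FALSE),
    data.frame(id = names(AA_ENZYMES), name = unname(AA_ENZYMES),
               compartment = "intracellular", role = "enzyme",
               initial_conc_mM = 0, stringsAsFactors = FALSE),
    data.frame(id = names(AA_TRANSPORTERS), name = unname(AA_TRANSPORTERS),
               compartment = "intracellular", role = "transporter",
               initial_conc_mM = 0, stringsAsFactors = FALSE),
    data.frame(id = c("AA_src", "memAA"),
               name = c("unspecified arachidonic acid source",
                        "membrane-bound arachidonic acid pool"),
               compartment = "intracellular", role = "source",
               initial_conc_mM = c(0, 1), stringsAsFactors = FALSE))

  rx <- list()

  # reaction 1: enzymatic release of AA from the membrane pool (off)
  rx[[1]] <- reaction_spec(1L, "enzymatic",
                           substrates = stats::setNames(1, ic("memAA")),
                           products = stats::setNames(1, ic("AA")),
                           catalyst = ic("PLA2"),
                           parameters = enz_params(1L), enabled = FALSE)

  # reactions 2-22: enzymatic conversions
  num <- 2L
  for (e in AA_ENZYMATIC) {
    rx[[num]] <- reaction_spec(num, "enzymatic",
                               substrates = stats::setNames(1, ic(e[[1]])),
                               products = stats::setNames(1, ic(e[[2]])),
                               catalyst = ic(e[[3]]),
                               parameters = enz_params(num))
    num <- num + 1L
  }

  # reactions 23-33: non-enzymatic conversions
  for (ne in AA_NONENZ) {
    key <- function(id) species_key(id, ne[[3]])
    rx[[num]] <- reaction_spec(num, "non_enzymatic",
                               substrates = stats::setNames(1, key(ne[[1]])),
                               products = stats::setNames(1, key(ne[[2]])),
                               parameters = nonenz_params(num))
    num <- num + 1L
  }

  # reactions 34-62: transport (PGT then ABC then ABC dual routes)
  transport_plan <- rbind(
    data.frame(id = PGT_CARGO, transporter = "PGT", stringsAsFactors = FALSE),
    data.frame(id = ABC_CARGO, transporter = "ABC", stringsAsFactors = FALSE),
    data.frame(id = ABC_DUAL, transporter = "ABC", stringsAsFactors = FALSE))
  for (i in seq_len(nrow(transport_plan))) {
    id <- transport_plan$id[i]; tr <- transport_plan$transporter[i]
    cargo <- if (tr == "PGT") PGT_CARGO else unique(c(ABC_CARGO, ABC_DUAL))
    rx[[num]] <- reaction_spec(num, "transport",
                               substrates = stats::setNames(1, ic(id)),
                               products = stats::setNames(1, ec(id)),
                               catalyst = ic(tr),
                               competitors = ic(setdiff(cargo, id)),
                               parameters = c(sprintf("Km_r%d", num),
                                              sprintf("kcat_%s", tr)))
    num <- num + 1L
  }
  stopifnot(num == 63L)

  # reactions 63-94 and 96-112: first-order degradation of every metabolite
  deg_keys <- c(ic(names(AA_METABOLITES)), ec(AA_EXPORTED))
  deg_numbers <- c(63:94, 96:112)
  for (i in seq_along(deg_keys)) {
    n <- deg_numbers[i]
    rx[[n]] <- reaction_spec(n, "degradation",
                             substrates = stats::setNames(1, deg_keys[i]),
                             parameters = sprintf("kdeg_r%d", n))
  }

  # reaction 95: programmed release of AA from the unspecified source (on)
  rx[[95]] <- reaction_spec(95L, "substrate_release",
                            substrates = stats::setNames(1, ic("AA_src")),
                            products = stats::setNames(1, ic("AA")),
                            enabled = TRUE)

  # reaction 113: non-enzymatic release from the membrane pool (off)
  rx[[113]] <- reaction_spec(113L, "non_enzymatic",
                             substrates = stats::setNames(1, ic("memAA")),
                             products = stats::setNames(1, ic("AA")),
                             parameters = nonenz_params(113L),
                             enabled = FALSE)

  # substrates sharing an enzyme compete for it (e.g. PGE2 and PGF2a for
  # 15-PGDH, the three HPETEs for PHGPx)
  enz_idx <- which(vapply(rx, function(r) r$rtype == "enzymatic", TRUE))
  by_cat <- split(enz_idx, vapply(rx[enz_idx], function(r) r$catalyst, ""))
  for (idx in by_cat) {
    subs <- unique(unlist(lapply(rx[idx], function(r) names(r$substrates))))
    for (i in idx)
      rx[[i]]$competitors <- setdiff(subs, names(rx[[i]]$substrates))
  }

  net <- new_network(compartments, species, rx)
  report <- validate_network(net)
  if (nrow(report))
    stop("internal error: fixture fails validation:\n",
         paste(report$problem, collapse = "\n"))
  net
}
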