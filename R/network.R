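# Reaction types understood by the simulator.
REACTION_TYPES <- c("substrate_release", "protein_induction", "enzymatic",
                    "non_enzymatic", "transport", "degradation")

SPECIES_ROLES <- c("metabolite", "enzyme", "transporter", "source")

# Parameter kinds a reaction may reference.
PARAM_KINDS <- c("k_cat", "K_ms", "K_mp", "K_eq", "k_f", "k_r", "k_deg",
                 "enzyme_conc_0")

#' Species key
#'
#' Species identifiers are unique within a compartment only (the same
#' chemical species may exist intracellularly and extracellularly), so a
#' species is addressed everywhere as `"id@compartment"`.
#'
#' @param id species identifier
#' @param compartment compartment identifier
#' @return character key `"id@compartment"`
#' @export
species_key <- function(id, compartment) paste0(id, "@", compartment)

split_species_key <- function(key) {
  parts <- strsplit(key, "@", fixed = TRUE)
  data.frame(id = vapply(parts, `[`, "", 1L),
             compartment = vapply(parts, `[`, "", 2L),
             stringsAsFactors = FALSE)
}

#' Construct a reaction network
#'
#' A network holds compartments (id, volume in litres), species (id, name,
#' compartment, role, initial concentration in mM) and a list of typed
#' reaction specifications. Reactions keep their catalogue numbering in all
#' messages so that problems can be traced back to the source tables.
#'
#' @param compartments data.frame with columns `id`, `volume_l`
#' @param species data.frame with columns `id`, `name`, `compartment`,
#'   `role`, `initial_conc_mM`
#' @param reactions list of reaction specs as built by [reaction_spec()]
#' @return object of class `aa_network`
#' @export
new_network <- function(compartments, species, reactions) {
  net <- structure(list(compartments = compartments,
                        species = species,
                        reactions = reactions),
                   class = "aa_network")
  net
}

#' Construct a reaction specification
#'
#' @param number integer catalogue number (unique within a network)
#' @param rtype one of `r toString(REACTION_TYPES)`
#' @param substrates named numeric vector of stoichiometries keyed by
#'   species key (`"id@compartment"`)
#' @param products named numeric vector of stoichiometries
#' @param catalyst species key of the enzyme/transporter, or `NA`
#' @param competitors character vector of species keys sharing the catalyst
#' @param parameters character vector of parameter-prior names this
#'   reaction draws (kinetic parameters only; the catalyst concentration
#'   prior is implied by the catalyst)
#' @param enabled logical; disabled reactions contribute zero flux
#' @return object of class `aa_reaction`
#' @export
reaction_spec <- function(number, rtype, substrates = numeric(),
                          products = numeric(), catalyst = NA_character_,
                          competitors = character(),
                          parameters = character(), enabled = TRUE) {
  stopifnot(rtype %in% REACTION_TYPES)
  structure(list(number = as.integer(number), rtype = rtype,
                 substrates = substrates, products = products,
                 catalyst = catalyst, competitors = competitors,
                 parameters = parameters, enabled = isTRUE(enabled)),
            class = "aa_reaction")
}

#' @export
print.aa_network <- function(x, ...) {
  n_met <- sum(x$species$role == "metabolite")
  cat("AA-cascade reaction network\n")
  cat("  compartments:", nrow(x$compartments), "\n")
  cat("  species:     ", nrow(x$species),
      sprintf("(%d metabolites, %d enzymes, %d transporters, %d sources)\n",
              n_met, sum(x$species$role == "enzyme"),
              sum(x$species$role == "transporter"),
              sum(x$species$role == "source")))
  cat("  reactions:   ", length(x$reactions),
      sprintf("(%d enabled)\n", sum(vapply(x$reactions, function(r) r$enabled, TRUE))))
  invisible(x)
}

#' Count reactions in a network
#' @param net an `aa_network`
#' @param enabled_only count only enabled reactions?
#' @return integer count
#' @export
n_reactions <- function(net, enabled_only = FALSE) {
  if (!enabled_only) return(length(net$reactions))
  sum(vapply(net$reactions, function(r) r$enabled, TRUE))
}

#' Count metabolite species in a network
#'
#' Counts species with role `"metabolite"`; enzymes, transporters and
#' source pools are excluded.
#' @param net an `aa_network`
#' @return integer count
#' @export
n_metabolites <- function(net) sum(net$species$role == "metabolite")

all_species_keys <- function(net) {
  species_key(net$species$id, net$species$compartment)
}

reaction_species_keys <- function(r) {
  unique(c(names(r$substrates), names(r$products),
           if (!is.na(r$catalyst)) r$catalyst, r$competitors))
}

#' Validate a reaction network
#'
#' Checks every structural invariant of the network data model and returns
#' a report of violations instead of raising, so that a whole catalogue can
#' be audited in one pass. An empty report means the network is valid.
#'
#' Checked invariants: positive compartment volumes; non-negative initial
#' concentrations; species ids unique within each compartment; all species
#' referenced by reactions exist; unique reaction numbers; enzymatic
#' reactions carry a catalyst and the (k_cat, K_ms, K_mp, K_eq) quadruplet;
#' non-enzymatic reactions carry the (k_f, k_r, K_eq) triplet; transport
#' reactions connect the same chemical species identity across two distinct
#' compartments via a transporter; competitors share the reaction's
#' catalyst (each appears as substrate of another reaction with that
#' catalyst).
#'
#' @param net an `aa_network`
#' @return data.frame with columns `reaction` (NA for network-level
#'   problems) and `problem`; zero rows iff valid
#' @export
validate_network <- function(net) {
  problems <- list()
  add <- function(reaction, problem)
    problems[[length(problems) + 1L]] <<- data.frame(
      reaction = reaction, problem = problem, stringsAsFactors = FALSE)

  if (any(net$compartments$volume_l <= 0))
    add(NA_integer_, "compartment with non-positive volume")
  if (any(net$species$initial_conc_mM < 0))
    add(NA_integer_, "species with negative initial concentration")
  dup <- duplicated(species_key(net$species$id, net$species$compartment))
  if (any(dup))
    add(NA_integer_, paste("duplicated species id within compartment:",
                           paste(net$species$id[dup], collapse = ", ")))
  if (!all(net$species$compartment %in% net$compartments$id))
    add(NA_integer_, "species in unknown compartment")
  if (!all(net$species$role %in% SPECIES_ROLES))
    add(NA_integer_, "species with unknown role")

  keys <- all_species_keys(net)
  numbers <- vapply(net$reactions, function(r) r$number, 1L)
  if (anyDuplicated(numbers))
    add(NA_integer_, "duplicated reaction numbers")

  # which species are substrates of which catalyst (for competitor checks)
  cat_subs <- list()
  for (r in net$reactions) {
    if (!is.na(r$catalyst))
      cat_subs[[r$catalyst]] <- c(cat_subs[[r$catalyst]], names(r$substrates))
  }

  for (r in net$reactions) {
    missing <- setdiff(reaction_species_keys(r), keys)
    if (length(missing))
      add(r$number, paste("reaction", r$number, "references unknown species:",
                          paste(missing, collapse = ", ")))
    kinds <- prior_kind(r$parameters)
    if (r$rtype == "enzymatic") {
      if (is.na(r$catalyst))
        add(r$number, paste("enzymatic reaction", r$number, "has no catalyst"))
      need <- c("k_cat", "K_ms", "K_mp", "K_eq")
      if (!setequal(intersect(kinds, need), need))
        add(r$number, paste("enzymatic reaction", r$number,
                            "must reference the quadruplet k_cat/K_ms/K_mp/K_eq"))
    } else if (r$rtype == "non_enzymatic") {
      need <- c("k_f", "k_r", "K_eq")
      if (!setequal(intersect(kinds, need), need))
        add(r$number, paste("non-enzymatic reaction", r$number,
                            "must reference the triplet k_f/k_r/K_eq"))
    } else if (r$rtype == "transport") {
      if (is.na(r$catalyst))
        add(r$number, paste("transport reaction", r$number, "has no transporter"))
      sk <- split_species_key(names(r$substrates))
      pk <- split_species_key(names(r$products))
      if (nrow(sk) != 1L || nrow(pk) != 1L || sk$id != pk$id ||
          sk$compartment == pk$compartment)
        add(r$number, paste("transport reaction", r$number,
                            "must move one species between two compartments"))
    } else if (r$rtype == "degradation") {
      if (length(r$substrates) != 1L)
        add(r$number, paste("degradation reaction", r$number,
                            "must have exactly one substrate"))
    }
    if (length(r$competitors) && !is.na(r$catalyst)) {
      shared <- cat_subs[[r$catalyst]]
      bad <- setdiff(r$competitors, shared)
      if (length(bad))
        add(r$number, paste("reaction", r$number, "lists competitors not",
                            "sharing its catalyst:", paste(bad, collapse = ", ")))
    }
  }
  if (!length(problems))
    return(data.frame(reaction = integer(), problem = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, problems)
}

# --- catalogue (TSV) serialisation ------------------------------------------

encode_stoich <- function(x) {
  if (!length(x)) return("")
  paste(sprintf("%s:%s", names(x), format(unname(x), digits = 17)),
        collapse = ";")
}

decode_stoich <- function(s) {
  if (is.na(s) || !nzchar(s)) return(numeric())
  parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
  bad <- vapply(parts, length, 1L) != 2L
  if (any(bad)) stop("malformed stoichiometry field: ", s, call. = FALSE)
  out <- as.numeric(vapply(parts, `[`, "", 2L))
  names(out) <- vapply(parts, `[`, "", 1L)
  if (anyNA(out)) stop("malformed stoichiometry field: ", s, call. = FALSE)
  out
}

encode_list <- function(x) paste(x, collapse = ";")
decode_list <- function(s) {
  if (is.na(s) || !nzchar(s)) return(character())
  strsplit(s, ";", fixed = TRUE)[[1]]
}

#' Save a network catalogue
#'
#' Writes the network as three hand-editable text files in `dir`:
#' `species.tsv`, `reactions.tsv` and `manifest.json` (compartments and
#' format version). [load_network()] on the directory restores the network
#' losslessly.
#'
#' @param net an `aa_network`
#' @param dir output directory (created if missing)
#' @return `dir`, invisibly
#' @export
save_network <- function(net, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(format = "aa-cascade-catalogue", version = 1L,
                   compartments = net$compartments)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  sp <- net$species
  sp$initial_conc_mM <- format(sp$initial_conc_mM, digits = 17)
  utils::write.table(sp, file.path(dir, "species.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  rx <- data.frame(
    number = vapply(net$reactions, function(r) r$number, 1L),
    rtype = vapply(net$reactions, function(r) r$rtype, ""),
    substrates = vapply(net$reactions, function(r) encode_stoich(r$substrates), ""),
    products = vapply(net$reactions, function(r) encode_stoich(r$products), ""),
    catalyst = vapply(net$reactions, function(r) r$catalyst, ""),
    competitors = vapply(net$reactions, function(r) encode_list(r$competitors), ""),
    parameters = vapply(net$reactions, function(r) encode_list(r$parameters), ""),
    enabled = vapply(net$reactions, function(r) r$enabled, TRUE),
    stringsAsFactors = FALSE)
  utils::write.table(rx, file.path(dir, "reactions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  invisible(dir)
}

#' Load a network catalogue
#'
#' Reads a catalogue directory written by [save_network()] (or edited by
#' hand), validates it, and returns the network. Validation failures are
#' raised as an error naming the offending reaction numbers.
#'
#' @param dir catalogue directory containing `species.tsv`, `reactions.tsv`
#'   and `manifest.json`
#' @return a validated `aa_network`
#' @export
load_network <- function(dir) {
  man_path <- file.path(dir, "manifest.json")
  if (!file.exists(man_path)) stop("no manifest.json in ", dir, call. = FALSE)
  manifest <- jsonlite::read_json(man_path, simplifyVector = TRUE)
  if (!identical(manifest$format, "aa-cascade-catalogue"))
    stop("not an aa-cascade catalogue: ", dir, call. = FALSE)
  comp <- as.data.frame(manifest$compartments, stringsAsFactors = FALSE)
  comp$volume_l <- as.numeric(comp$volume_l)

  sp <- utils::read.delim(file.path(dir, "species.tsv"), sep = "\t",
                          colClasses = "character")
  need <- c("id", "name", "compartment", "role", "initial_conc_mM")
  if (!all(need %in% names(sp)))
    stop("species.tsv missing columns: ",
         paste(setdiff(need, names(sp)), collapse = ", "), call. = FALSE)
  sp$initial_conc_mM <- as.numeric(sp$initial_conc_mM)
  if (anyNA(sp$initial_conc_mM))
    stop("species.tsv: unparseable initial_conc_mM", call. = FALSE)

  rx <- utils::read.delim(file.path(dir, "reactions.tsv"), sep = "\t",
                          colClasses = "character")
  need <- c("number", "rtype", "substrates", "products", "catalyst",
            "competitors", "parameters", "enabled")
  if (!all(need %in% names(rx)))
    stop("reactions.tsv missing columns: ",
         paste(setdiff(need, names(rx)), collapse = ", "), call. = FALSE)
  reactions <- lapply(seq_len(nrow(rx)), function(i) {
    num <- suppressWarnings(as.integer(rx$number[i]))
    if (is.na(num)) stop("reactions.tsv row ", i, ": bad reaction number ",
                         rx$number[i], call. = FALSE)
    reaction_spec(
      number = num,
      rtype = rx$rtype[i],
      substrates = decode_stoich(rx$substrates[i]),
      products = decode_stoich(rx$products[i]),
      catalyst = if (is.na(rx$catalyst[i]) || !nzchar(rx$catalyst[i]))
        NA_character_ else rx$catalyst[i],
      competitors = decode_list(rx$competitors[i]),
      parameters = decode_list(rx$parameters[i]),
      enabled = as.logical(rx$enabled[i]))
  })
  net <- new_network(comp, sp, reactions)
  report <- validate_network(net)
  if (nrow(report))
    stop("invalid network catalogue:\n  ",
         paste(report$problem, collapse = "\n  "), call. = FALSE)
  net
}
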