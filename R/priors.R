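# Weighted log-normal parameter priors and thermodynamically consistent
# ensemble sampling.

# Floor on the ln-space width of a prior; a single literature value would
# otherwise collapse the prior to a point.
SIGMA_MIN_DEFAULT <- 0.25

#' Parameter kind from a prior name
#'
#' Prior names follow the catalogue convention `kcat_r7`, `Kms_r7`,
#' `Kmp_r7`, `Keq_r7`, `kf_r23`, `kr_r23`, `Km_r34` (transport affinity),
#' `kdeg_r63`, `kcat_PGT`/`kcat_ABC` (transporter turnover) and
#' `conc_COX1` (initial enzyme/transporter concentration).
#'
#' @param name character vector of prior names
#' @return character vector of kinds (one of `r toString(PARAM_KINDS)`)
#' @export
prior_kind <- function(name) {
  kind <- rep(NA_character_, length(name))
  kind[startsWith(name, "kcat_")] <- "k_cat"
  kind[startsWith(name, "Kms_")]  <- "K_ms"
  kind[startsWith(name, "Kmp_")]  <- "K_mp"
  kind[startsWith(name, "Keq_")]  <- "K_eq"
  kind[startsWith(name, "kf_")]   <- "k_f"
  kind[startsWith(name, "kr_")]   <- "k_r"
  kind[startsWith(name, "kdeg_")] <- "k_deg"
  kind[startsWith(name, "Km_")]   <- "K_ms"
  kind[startsWith(name, "conc_")] <- "enzyme_conc_0"
  kind
}

#' Construct a parameter prior
#'
#' @param name prior name (see [prior_kind()])
#' @param mu mean of ln(value); `NA` for dependent priors
#' @param sigma standard deviation of ln(value); `NA` for dependent priors
#' @param dependent is this value derived thermodynamically (K_mp, k_r)
#'   rather than sampled?
#' @param sources optional data.frame of weighted literature values with
#'   columns `value`, `weight`, `source`
#' @return object of class `aa_prior`
#' @export
parameter_prior <- function(name, mu = NA_real_, sigma = NA_real_,
                            dependent = FALSE, sources = NULL) {
  if (!dependent) {
    stopifnot(is.finite(mu), is.finite(sigma), sigma > 0)
  }
  structure(list(name = name, kind = prior_kind(name), mu = mu,
                 sigma = sigma, dependent = dependent, sources = sources),
            class = "aa_prior")
}

#' Fit a log-normal prior to weighted literature values
#'
#' Computes the weighted mean and standard deviation of `ln(value)` with
#' internally normalised weights; the standard deviation is floored at
#' `sigma_min` so that a single reported value still yields a usable
#' (non-degenerate) prior.
#'
#' @param values positive numeric vector of literature values
#' @param weights positive likelihood weights (default: equal)
#' @param name prior name
#' @param sources optional character vector of citation tags
#' @param sigma_min ln-space floor on sigma
#' @return an `aa_prior`
#' @export
fit_weighted_lognormal <- function(values, weights = rep(1, length(values)),
                                   name = "prior",
                                   sources = rep(NA_character_, length(values)),
                                   sigma_min = SIGMA_MIN_DEFAULT) {
  if (!length(values)) stop("no values to fit", call. = FALSE)
  if (any(values <= 0)) stop("values must be positive", call. = FALSE)
  if (any(weights <= 0) || length(weights) != length(values))
    stop("weights must be positive and match values", call. = FALSE)
  w <- weights / sum(weights)
  lv <- log(values)
  mu <- sum(w * lv)
  sigma <- max(sqrt(sum(w * (lv - mu)^2)), sigma_min)
  parameter_prior(name, mu, sigma,
                  sources = data.frame(value = values, weight = weights,
                                       source = sources,
                                       stringsAsFactors = FALSE))
}

#' Derive a thermodynamically dependent parameter
#'
#' For a non-enzymatic triplet the reverse rate constant is fixed by the
#' equilibrium constant, `k_r = k_f / K_eq`. For an enzymatic quadruplet
#' the product Michaelis constant follows from the Haldane relation of the
#' reversible rate law with a single turnover number,
#' `K_mp = K_eq * K_ms`.
#'
#' @param rate `k_f` (non-enzymatic) or `k_cat` (enzymatic), s^-1
#' @param K_ms substrate Michaelis constant, mM (enzymatic only)
#' @param K_eq equilibrium constant (dimensionless)
#' @param type `"non_enzymatic"` (returns k_r) or `"enzymatic"`
#'   (returns K_mp)
#' @return the dependent parameter value (positive)
#' @export
derive_dependent <- function(rate, K_ms = NULL, K_eq, type = c("non_enzymatic", "enzymatic")) {
  type <- match.arg(type)
  if (any(rate <= 0) || any(K_eq <= 0) ||
      (type == "enzymatic" && any(K_ms <= 0)))
    stop("all inputs must be positive", call. = FALSE)
  if (type == "non_enzymatic") rate / K_eq else K_eq * K_ms
}

#' Prior sets
#'
#' A prior set is a named list of [parameter_prior()] objects covering
#' every parameter a network draws.
#'
#' @param priors list of `aa_prior`
#' @return object of class `aa_priorset`
#' @export
prior_set <- function(priors) {
  names(priors) <- vapply(priors, function(p) p$name, "")
  structure(priors, class = "aa_priorset")
}

#' @export
print.aa_priorset <- function(x, ...) {
  dep <- vapply(x, function(p) p$dependent, TRUE)
  cat("Parameter prior set:", length(x), "priors (",
      sum(!dep), "sampled,", sum(dep), "dependent )\n")
  invisible(x)
}

#' Serialise a prior set to JSON
#' @param priors an `aa_priorset`
#' @param path output file
#' @return `path`, invisibly
#' @export
save_priors <- function(priors, path) {
  out <- lapply(unname(priors), function(p) {
    rec <- list(name = p$name, kind = p$kind, mu = p$mu, sigma = p$sigma,
                dependent = p$dependent)
    if (!is.null(p$sources)) rec$sources <- p$sources
    rec
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Read a prior set from JSON
#' @param path JSON file written by [save_priors()]
#' @return an `aa_priorset`
#' @export
load_priors <- function(path) {
  recs <- jsonlite::read_json(path, simplifyVector = FALSE)
  prior_set(lapply(recs, function(r) {
    parameter_prior(r$name,
                    mu = if (is.null(r$mu)) NA_real_ else r$mu,
                    sigma = if (is.null(r$sigma)) NA_real_ else r$sigma,
                    dependent = isTRUE(r$dependent),
                    sources = if (!is.null(r$sources))
                      do.call(rbind, lapply(r$sources, as.data.frame)))
  }))
}

# --- default priors for the shipped network ---------------------------------

# ln-space (mu, sigma) baselines per parameter kind; concentrations and the
# COX/LOX abundances are overridden below.
PRIOR_BASELINES <- list(
  k_cat = c(log(5), 0.8),       # turnover number, s^-1
  K_ms  = c(log(5e-3), 1.0),    # Michaelis/affinity constant, mM
  K_eq  = c(log(1e6), 1.0),     # strongly exergonic oxygenations
  k_f   = c(log(2e-3), 1.0),    # non-enzymatic hydrolysis/dehydration, s^-1
  k_deg = c(log(1e-5), 1.0),    # first-order loss, s^-1
  enzyme_conc_0 = c(log(1e-5), 1.7))  # proteomics-derived abundance, mM

# enzyme-specific abundance overrides (ln mM): COX isoforms sit around
# 1e-4..1e-2 mM, the LOX isoforms around 1e-7..1e-4 mM
PRIOR_CONC_OVERRIDES <- list(
  conc_COX1  = c(log(1e-3), 1.15),
  conc_COX2  = c(log(1e-3), 1.15),
  conc_LOX12 = c(log(10^-5.5), 1.7),
  conc_LOX15 = c(log(10^-5.5), 1.7))

catalyst_conc_name <- function(catalyst) {
  paste0("conc_", split_species_key(catalyst)$id)
}

# all prior names a network requires: per-reaction kinetic parameters plus
# one concentration prior per catalyst
required_prior_names <- function(net, enabled_only = FALSE) {
  names <- character()
  for (r in net$reactions) {
    if (enabled_only && !r$enabled) next
    names <- c(names, r$parameters,
               if (!is.na(r$catalyst)) catalyst_conc_name(r$catalyst))
  }
  unique(names)
}

#' Default prior set for a network
#'
#' Builds a complete prior set for every parameter the network references,
#' using literature-scale baselines per parameter kind (turnover numbers a
#' few per second, Michaelis constants in the low micromolar range,
#' strongly product-favouring equilibrium constants, slow first-order
#' degradation) and wide proteomics-derived abundance priors, with
#' narrower/shifted overrides for the COX and LOX isoform concentrations.
#' `K_mp` and `k_r` priors are created as dependent (never sampled; derived
#' via [derive_dependent()] at sampling time).
#'
#' @param net an `aa_network`
#' @return an `aa_priorset`
#' @export
default_priors <- function(net) {
  nm <- required_prior_names(net)
  prior_set(lapply(nm, function(n) {
    kind <- prior_kind(n)
    if (kind %in% c("K_mp", "k_r"))
      return(parameter_prior(n, dependent = TRUE))
    base <- PRIOR_BASELINES[[kind]]
    if (!is.null(PRIOR_CONC_OVERRIDES[[n]]))
      base <- PRIOR_CONC_OVERRIDES[[n]]
    parameter_prior(n, base[1], base[2])
  }))
}

# --- ensemble sampling ------------------------------------------------------

# deterministic order of independently sampled parameter names for a
# network: kinetic parameters by ascending reaction number, then catalyst
# concentrations in order of first appearance
sampled_parameter_names <- function(net, priors) {
  nm <- character(); conc <- character()
  ord <- order(vapply(net$reactions, function(r) r$number, 1L))
  for (r in net$reactions[ord]) {
    if (!r$enabled) next
    for (p in r$parameters) {
      if (is.null(priors[[p]]))
        stop("reaction ", r$number, ": no prior for parameter ", p,
             call. = FALSE)
      if (!priors[[p]]$dependent) nm <- c(nm, p)
    }
    if (!is.na(r$catalyst)) {
      cn <- catalyst_conc_name(r$catalyst)
      if (is.null(priors[[cn]]))
        stop("reaction ", r$number, ": no prior for parameter ", cn,
             call. = FALSE)
      conc <- c(conc, cn)
    }
  }
  unique(c(nm, conc))
}

#' Count independently sampled parameters
#'
#' The number of parameters that are drawn marginally from their priors
#' for the enabled part of the network (dependent K_mp/k_r values and
#' parameters of disabled reactions are excluded). This is also the number
#' of hypotheses used for Bonferroni correction during adaptation.
#'
#' @param net an `aa_network`
#' @param priors an `aa_priorset` (default: [default_priors()])
#' @return integer count
#' @export
n_sampled_parameters <- function(net, priors = default_priors(net)) {
  length(sampled_parameter_names(net, priors))
}

#' Sample an ensemble of model variants
#'
#' Draws `n` complete parameter assignments. Independent parameters are
#' sampled marginally from their log-normal priors; the dependent members
#' of each enzymatic quadruplet (K_mp) and non-enzymatic triplet (k_r) are
#' then derived per variant via [derive_dependent()], so every variant is
#' thermodynamically consistent by construction. Sampling is reproducible:
#' the same seed yields identical assignments.
#'
#' @param net an `aa_network`
#' @param priors an `aa_priorset`
#' @param n number of variants
#' @param seed integer RNG seed
#' @return object of class `aa_ensemble` with fields `values` (n x p
#'   matrix, one full assignment per row), `n`, `seed`, `priors` and
#'   `sampled_names`
#' @export
sample_ensemble <- function(net, priors = default_priors(net), n = 1000L,
                            seed = 1L) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  nm <- sampled_parameter_names(net, priors)
  mu <- vapply(priors[nm], function(p) p$mu, 1)
  sigma <- vapply(priors[nm], function(p) p$sigma, 1)

  set.seed(seed)
  z <- matrix(stats::rnorm(n * length(nm)), nrow = n)
  values <- exp(sweep(sweep(z, 2L, sigma, `*`), 2L, mu, `+`))
  colnames(values) <- nm

  # derive dependent parameters per enabled reaction
  dep <- list()
  for (r in net$reactions) {
    if (!r$enabled) next
    if (r$rtype == "enzymatic") {
      num <- r$number
      dep[[sprintf("Kmp_r%d", num)]] <-
        derive_dependent(values[, sprintf("kcat_r%d", num)],
                         values[, sprintf("Kms_r%d", num)],
                         values[, sprintf("Keq_r%d", num)], "enzymatic")
    } else if (r$rtype == "non_enzymatic") {
      num <- r$number
      dep[[sprintf("kr_r%d", num)]] <-
        derive_dependent(values[, sprintf("kf_r%d", num)],
                         K_eq = values[, sprintf("Keq_r%d", num)],
                         type = "non_enzymatic")
    }
  }
  if (length(dep)) {
    depm <- do.call(cbind, dep)
    values <- cbind(values, depm)
  }

  structure(list(values = values, n = as.integer(n), seed = as.integer(seed),
                 priors = priors, sampled_names = nm,
                 network_signature = network_signature(net)),
            class = "aa_ensemble")
}

network_signature <- function(net) {
  paste(vapply(net$reactions, function(r)
    paste0(r$number, ":", r$rtype, ":", r$enabled), ""), collapse = "|")
}

#' @export
print.aa_ensemble <- function(x, ...) {
  cat("Model-variant ensemble:", x$n, "variants,",
      length(x$sampled_names), "sampled +",
      ncol(x$values) - length(x$sampled_names), "dependent parameters",
      "(seed", paste0(x$seed, ")"), "\n")
  invisible(x)
}

#' Extract one model variant
#' @param ens an `aa_ensemble`
#' @param i variant index
#' @return named numeric vector of the full parameter assignment, with
#'   attribute `index`
#' @export
get_variant <- function(ens, i) {
  stopifnot(i >= 1, i <= ens$n)
  v <- ens$values[i, ]
  attr(v, "index") <- as.integer(i)
  v
}

#' Thermodynamic-consistency residuals of an ensemble
#'
#' Relative residuals of the Haldane constraints across all variants:
#' `|K_mp/(K_eq*K_ms) - 1|` for enzymatic quadruplets and
#' `|k_f/(k_r*K_eq) - 1|` for non-enzymatic triplets.
#'
#' @param net an `aa_network`
#' @param ens an `aa_ensemble`
#' @return numeric vector of residuals (one per variant x constraint)
#' @export
thermo_residuals <- function(net, ens) {
  res <- list()
  v <- ens$values
  for (r in net$reactions) {
    if (!r$enabled) next
    num <- r$number
    if (r$rtype == "enzymatic") {
      res[[length(res) + 1L]] <-
        abs(v[, sprintf("Kmp_r%d", num)] /
              (v[, sprintf("Keq_r%d", num)] * v[, sprintf("Kms_r%d", num)]) - 1)
    } else if (r$rtype == "non_enzymatic") {
      res[[length(res) + 1L]] <-
        abs(v[, sprintf("kf_r%d", num)] /
              (v[, sprintf("kr_r%d", num)] * v[, sprintf("Keq_r%d", num)]) - 1)
    }
  }
  unlist(res, use.names = FALSE)
}
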