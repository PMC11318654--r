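# Assembly and integration of the ODE system for one model variant.
#
# The state vector holds every metabolite concentration (mM), keyed by
# "id@compartment". Enzymes, transporters and source pools are not state:
# enzyme levels are variant parameters (piecewise-constant under
# induction), and source pools are treated as non-depleting constants.
# Internal time is seconds; all interfaces use hours relative to the
# stimulus (the equilibration phase runs over negative hours).

#' Simulation protocol
#'
#' The equilibration-then-stimulus protocol: the system relaxes for
#' `equilibration` hours with substrate release off, the release profile
#' activates at t = 0, and the response is recorded for `post_stimulus`
#' hours.
#'
#' @param equilibration equilibration length, hours
#' @param post_stimulus post-stimulus length, hours
#' @param release an [release_profile()] activated at the stimulus, or
#'   `NULL` for no release
#' @param inductions list of [induction_schedule()]s
#' @param report_times hours post-stimulus at which predictions are read
#'   out (must lie in `(0, post_stimulus]`)
#' @param rtol,atol solver tolerances (atol in mM; the default resolves
#'   the 1e-28 mM initial floor)
#' @param output_dt output grid spacing, hours
#' @return object of class `aa_protocol`
#' @export
simulation_protocol <- function(equilibration = 1, post_stimulus = 6,
                                release = NULL, inductions = list(),
                                report_times = c(0.5, 1, 3, 6),
                                rtol = 1e-8, atol = 1e-30,
                                output_dt = 0.1) {
  stopifnot(equilibration >= 0, post_stimulus > 0)
  if (any(report_times <= 0 | report_times > post_stimulus))
    stop("report times must lie in (0, post_stimulus]", call. = FALSE)
  structure(list(equilibration = equilibration,
                 post_stimulus = post_stimulus, release = release,
                 inductions = inductions, report_times = report_times,
                 rtol = rtol, atol = atol, output_dt = output_dt),
            class = "aa_protocol")
}

variant_value <- function(variant, name, reaction = NULL) {
  if (!name %in% names(variant))
    stop("variant is missing parameter ", name,
         if (!is.null(reaction)) paste0(" (reaction ", reaction, ")"),
         call. = FALSE)
  unname(variant[[name]])
}

# Km of `key` for catalyst `cat`: the substrate affinity of the (unique)
# reaction with that catalyst in which `key` is the substrate.
competitor_km <- function(net, cat, key) {
  for (r in net$reactions) {
    if (!identical(r$catalyst, cat)) next
    if (key %in% names(r$substrates)) {
      nm <- r$parameters[prior_kind(r$parameters) == "K_ms"]
      if (length(nm) == 1L) return(nm)
    }
  }
  stop("no reaction defines the affinity of ", key, " for ", cat,
       call. = FALSE)
}

# Precompute index structures for fast right-hand-side evaluation.
compile_model <- function(net, variant) {
  sp <- net$species
  state_keys <- species_key(sp$id, sp$compartment)[sp$role == "metabolite"]
  const_keys <- species_key(sp$id, sp$compartment)[sp$role == "source"]
  const_vals <- sp$initial_conc_mM[sp$role == "source"]
  ext_keys <- c(state_keys, const_keys)
  n_state <- length(state_keys)
  n_ext <- length(ext_keys)
  key_idx <- stats::setNames(seq_len(n_ext), ext_keys)
  vol <- stats::setNames(net$compartments$volume_l, net$compartments$id)
  comp_of <- stats::setNames(sp$compartment, species_key(sp$id, sp$compartment))

  enabled <- Filter(function(r) r$enabled, net$reactions)
  nr <- length(enabled)
  Nmat <- matrix(0, n_state, nr)

  types <- vapply(enabled, function(r) r$rtype, "")
  groups <- list(enz = which(types == "enzymatic"),
                 non = which(types == "non_enzymatic"),
                 trn = which(types == "transport"),
                 deg = which(types == "degradation"),
                 rel = which(types == "substrate_release"))

  get1 <- function(x) key_idx[[names(x)[1]]]

  # stoichiometry with cross-compartment volume scaling for transport so
  # that amount (conc x volume) is conserved by the transport term
  for (j in seq_len(nr)) {
    r <- enabled[[j]]
    for (k in seq_along(r$substrates)) {
      idx <- key_idx[[names(r$substrates)[k]]]
      if (idx <= n_state) Nmat[idx, j] <- Nmat[idx, j] - r$substrates[k]
    }
    scale <- 1
    if (r$rtype == "transport") {
      vd <- vol[[comp_of[[names(r$substrates)[1]]]]]
      va <- vol[[comp_of[[names(r$products)[1]]]]]
      scale <- vd / va
    }
    for (k in seq_along(r$products)) {
      idx <- key_idx[[names(r$products)[k]]]
      if (idx <= n_state) Nmat[idx, j] <- Nmat[idx, j] + scale * r$products[k]
    }
  }

  pull <- function(idx, sym) {
    vapply(enabled[idx], function(r) {
      nm <- r$parameters[prior_kind(r$parameters) == sym]
      variant_value(variant, nm[1], r$number)
    }, 1)
  }

  enz <- NULL
  if (length(groups$enz)) {
    idx <- groups$enz
    compM <- matrix(0, length(idx), n_ext)
    for (k in seq_along(idx)) {
      r <- enabled[[idx[k]]]
      for (cmp in r$competitors) {
        km_name <- competitor_km(net, r$catalyst, cmp)
        compM[k, key_idx[[cmp]]] <- 1 / variant_value(variant, km_name, r$number)
      }
    }
    enz <- list(j = idx,
                si = vapply(enabled[idx], function(r) get1(r$substrates), 1L),
                pi = vapply(enabled[idx], function(r) get1(r$products), 1L),
                kcat = pull(idx, "k_cat"), Kms = pull(idx, "K_ms"),
                Kmp = pull(idx, "K_mp"), Keq = pull(idx, "K_eq"),
                cat = vapply(enabled[idx], function(r) r$catalyst, ""),
                Ebase = vapply(enabled[idx], function(r)
                  variant_value(variant, catalyst_conc_name(r$catalyst),
                                r$number), 1),
                compM = compM)
  }

  non <- NULL
  if (length(groups$non)) {
    idx <- groups$non
    non <- list(j = idx,
                si = vapply(enabled[idx], function(r) get1(r$substrates), 1L),
                pi = vapply(enabled[idx], function(r) get1(r$products), 1L),
                kf = pull(idx, "k_f"), kr = pull(idx, "k_r"))
  }

  trn <- NULL
  if (length(groups$trn)) {
    idx <- groups$trn
    compM <- matrix(0, length(idx), n_ext)
    Km <- pull(idx, "K_ms")
    for (k in seq_along(idx)) {
      r <- enabled[[idx[k]]]
      compM[k, get1(r$substrates)] <- 1 / Km[k]   # self-occupancy term
      for (cmp in r$competitors) {
        km_name <- competitor_km(net, r$catalyst, cmp)
        compM[k, key_idx[[cmp]]] <- 1 / variant_value(variant, km_name, r$number)
      }
    }
    trn <- list(j = idx,
                si = vapply(enabled[idx], function(r) get1(r$substrates), 1L),
                Km = Km, kcat = pull(idx, "k_cat"),
                cat = vapply(enabled[idx], function(r) r$catalyst, ""),
                Tbase = vapply(enabled[idx], function(r)
                  variant_value(variant, catalyst_conc_name(r$catalyst),
                                r$number), 1),
                compM = compM)
  }

  deg <- NULL
  if (length(groups$deg)) {
    idx <- groups$deg
    deg <- list(j = idx,
                si = vapply(enabled[idx], function(r) get1(r$substrates), 1L),
                kdeg = pull(idx, "k_deg"))
  }

  rel <- NULL
  if (length(groups$rel)) {
    idx <- groups$rel
    rel <- list(j = idx,
                pi = vapply(enabled[idx], function(r) get1(r$products), 1L))
  }

  list(state_keys = state_keys, const_vals = const_vals, n_state = n_state,
       nr = nr, Nmat = Nmat, enz = enz, non = non, trn = trn, deg = deg,
       rel = rel,
       init = stats::setNames(sp$initial_conc_mM[sp$role == "metabolite"],
                              state_keys))
}

# Right-hand side closure for one protocol segment: constant enzyme levels
# (possibly induction-overridden) and a smooth release-rate function.
rhs_factory <- function(cm, release_rate = NULL, enzyme_levels = NULL) {
  Evec <- if (!is.null(cm$enz)) cm$enz$Ebase
  Tvec <- if (!is.null(cm$trn)) cm$trn$Tbase
  if (!is.null(enzyme_levels)) {
    if (!is.null(cm$enz)) {
      hit <- match(cm$enz$cat, names(enzyme_levels))
      Evec[!is.na(hit)] <- enzyme_levels[hit[!is.na(hit)]]
    }
    if (!is.null(cm$trn)) {
      hit <- match(cm$trn$cat, names(enzyme_levels))
      Tvec[!is.na(hit)] <- enzyme_levels[hit[!is.na(hit)]]
    }
  }
  # occupancy (competition) matrices of the enzymatic and transport
  # groups stacked so one matrix product serves both
  ne <- if (is.null(cm$enz)) 0L else length(cm$enz$j)
  nt <- if (is.null(cm$trn)) 0L else length(cm$trn$j)
  occM <- rbind(if (ne) cm$enz$compM, if (nt) cm$trn$compM)
  yext <- c(rep(0, cm$n_state), cm$const_vals)
  sidx <- seq_len(cm$n_state)
  function(t, y, parms) {
    y[y < 0] <- 0
    yext[sidx] <- y
    v <- numeric(cm$nr)
    occ <- if (!is.null(occM)) occM %*% yext
    if (ne) {
      e <- cm$enz
      S <- yext[e$si]; P <- yext[e$pi]
      den <- 1 + S / e$Kms + P / e$Kmp + occ[seq_len(ne)]
      v[e$j] <- e$kcat * Evec * (S / e$Kms - P / (e$Kms * e$Keq)) / den
    }
    if (!is.null(cm$non)) {
      nn <- cm$non
      v[nn$j] <- nn$kf * yext[nn$si] - nn$kr * yext[nn$pi]
    }
    if (nt) {
      tr <- cm$trn
      S <- yext[tr$si]
      den <- 1 + occ[ne + seq_len(nt)]
      v[tr$j] <- tr$kcat * Tvec * (S / tr$Km) / den
    }
    if (!is.null(cm$deg)) v[cm$deg$j] <- cm$deg$kdeg * yext[cm$deg$si]
    if (!is.null(cm$rel) && !is.null(release_rate))
      v[cm$rel$j] <- release_rate(t)
    list(cm$Nmat %*% v)
  }
}

#' Assemble the ODE right-hand side for one variant
#'
#' Returns `dC/dt` as a function of time (seconds relative to the
#' stimulus) and the named state vector of metabolite concentrations.
#' Each species' derivative is the stoichiometry-weighted sum of the rates
#' of its incident enabled reactions; cross-compartment transport scales
#' the acceptor-side flux by the donor/acceptor volume ratio so the
#' transported amount is conserved. Disabled reactions contribute nothing.
#'
#' @param net an `aa_network`
#' @param variant a model-variant assignment from [get_variant()]
#' @param release optional [release_profile()] driving the
#'   substrate-release reactions (active for t >= 0)
#' @return function `(t, state)` returning the named derivative vector
#'   (mM/s); the initial state is attached as attribute `init`
#' @export
assemble_odes <- function(net, variant, release = NULL) {
  cm <- compile_model(net, variant)
  rate <- if (!is.null(release)) {
    segs <- release_segments(release, 1e6)
    function(t_sec) release_rate_at(segs, t_sec / HOUR_S)
  }
  rhs <- rhs_factory(cm, release_rate = rate)
  f <- function(t, state) {
    d <- rhs(t, state[cm$state_keys], NULL)[[1]]
    stats::setNames(as.vector(d), cm$state_keys)
  }
  attr(f, "init") <- cm$init
  f
}

# instantaneous release rate (mM/s) at hour h from precomputed segments
release_rate_at <- function(segs, h) {
  if (h < 0) return(0)
  i <- max(which(segs$t0 <= h + 1e-12))
  s <- segs[i, ]
  if (s$mode != "rise") return(0)
  (s$M - s$A0) * log(2) / s$Td * 2^(-(min(h, s$t1) - s$t0) / s$Td) / HOUR_S
}

#' Simulate one model variant through the protocol
#'
#' Integrates the variant's ODE system with a stiff-capable solver
#' (`deSolve::lsoda`) over the equilibration phase, activates the release
#' profile at the stimulus, and continues over the post-stimulus window.
#' Release-schedule events, the decay switch-on and induction steps are
#' implemented by stopping and restarting the integration at the event
#' times, so the right-hand side is smooth within each segment. A failed
#' integration returns a trajectory flagged `status = "failed"` rather
#' than raising, so ensembles survive pathological parameter draws.
#'
#' @param net an `aa_network`
#' @param variant a variant assignment ([get_variant()])
#' @param protocol a [simulation_protocol()]
#' @return object of class `aa_trajectory`: `times_h` (hours relative to
#'   the stimulus), `conc` (time x species matrix, mM), `status`,
#'   `variant` (index)
#' @export
run_variant <- function(net, variant, protocol = simulation_protocol()) {
  cm <- tryCatch(compile_model(net, variant), error = function(e) e)
  if (inherits(cm, "error")) stop(cm)

  post <- protocol$post_stimulus
  rel_segs <- if (!is.null(protocol$release))
    release_segments(protocol$release, post)

  # event times (hours post-stimulus) where integration restarts
  events <- c(0, post)
  if (!is.null(rel_segs)) events <- c(events, rel_segs$t0, rel_segs$t1)
  for (ind in protocol$inductions)
    events <- c(events, vapply(ind$steps, function(s) s$time, 1))
  events <- sort(unique(pmin(pmax(events, 0), post)))

  grid <- sort(unique(c(seq(-protocol$equilibration, post,
                            by = protocol$output_dt),
                        protocol$report_times, events,
                        -protocol$equilibration)))

  y <- cm$init
  out_t <- numeric(); out_c <- NULL
  status <- "ok"; msg <- NA_character_

  segment_bounds <- unique(c(-protocol$equilibration, events))
  for (si in seq_len(length(segment_bounds) - 1L)) {
    h0 <- segment_bounds[si]; h1 <- segment_bounds[si + 1L]
    tt <- sort(unique(c(h0, grid[grid > h0 & grid <= h1], h1))) * HOUR_S

    # the segment bounds include every release-segment boundary, so one
    # release segment (scalar parameters) covers this whole interval
    rate <- NULL
    if (h0 >= 0 && !is.null(rel_segs)) {
      j <- findInterval(h0 + 1e-12, rel_segs$t0)
      if (j >= 1L && rel_segs$mode[j] == "rise") {
        amp <- (rel_segs$M[j] - rel_segs$A0[j]) * log(2) / rel_segs$Td[j] /
          HOUR_S
        st0 <- rel_segs$t0[j]; Td <- rel_segs$Td[j]
        rate <- function(t_sec) amp * 2^(-(t_sec / HOUR_S - st0) / Td)
      }
    }

    levels <- NULL
    if (length(protocol$inductions) && h0 >= 0) {
      levels <- vapply(protocol$inductions, function(ind) {
        base <- variant_value(variant, catalyst_conc_name(ind$enzyme))
        induction_level(h0, ind, base)
      }, 1)
      names(levels) <- vapply(protocol$inductions,
                              function(ind) ind$enzyme, "")
    }

    rhs <- rhs_factory(cm, release_rate = rate, enzyme_levels = levels)
    sol <- tryCatch(
      suppressWarnings(
        deSolve::ode(y = y, times = tt, func = rhs, parms = NULL,
                     method = "lsoda", rtol = protocol$rtol,
                     atol = protocol$atol, maxsteps = 50000)),
      error = function(e) e)
    if (inherits(sol, "error") || anyNA(sol) || any(!is.finite(sol)) ||
        nrow(sol) < length(tt)) {
      status <- "failed"
      msg <- if (inherits(sol, "error")) conditionMessage(sol)
             else "integration did not reach the end of the window"
      break
    }
    keep <- if (si == 1L) seq_len(nrow(sol)) else -1L
    out_t <- c(out_t, sol[keep, 1] / HOUR_S)
    out_c <- rbind(out_c, sol[keep, -1, drop = FALSE])
    y <- sol[nrow(sol), -1]
  }

  if (is.null(out_c))
    out_c <- matrix(numeric(), 0, cm$n_state)
  # solver-level undershoot within a few atol of zero is numerical zero
  out_c[out_c < 0 & out_c > -1e3 * protocol$atol] <- 0
  colnames(out_c) <- cm$state_keys
  structure(list(times_h = out_t, conc = out_c, status = status,
                 message = msg, variant = attr(variant, "index")),
            class = "aa_trajectory")
}

#' @export
print.aa_trajectory <- function(x, ...) {
  cat("Trajectory (variant", x$variant, "):", length(x$times_h),
      "time points over", sprintf("[%.2f, %.2f] h,", min(x$times_h),
                                  max(x$times_h)),
      "status:", x$status, "\n")
  invisible(x)
}

#' Concentrations at given times
#'
#' Linear interpolation of a trajectory at requested times.
#'
#' @param traj an `aa_trajectory`
#' @param species species key(s) `"id@compartment"`
#' @param times_h hours relative to the stimulus
#' @return matrix times x species, mM
#' @export
trajectory_at <- function(traj, species, times_h) {
  if (traj$status != "ok") stop("trajectory is flagged as failed", call. = FALSE)
  out <- vapply(species, function(sp) {
    if (!sp %in% colnames(traj$conc))
      stop("unknown species in trajectory: ", sp, call. = FALSE)
    if (length(traj$times_h) < 2L)
      return(rep(traj$conc[1L, sp], length(times_h)))
    stats::approx(traj$times_h, traj$conc[, sp], xout = times_h,
                  rule = 2)$y
  }, numeric(length(times_h)))
  matrix(out, nrow = length(times_h), ncol = length(species),
         dimnames = list(NULL, species))
}

#' Total amount of a set of species
#'
#' Sum of concentration x compartment volume over the given species at
#' every time point; useful for conservation checks on closed
#' subnetworks.
#'
#' @param net the network (for compartment volumes)
#' @param traj an `aa_trajectory`
#' @param species species keys to include (default: all state species)
#' @return numeric vector of amounts (mmol) per time point
#' @export
total_amount <- function(net, traj, species = colnames(traj$conc)) {
  vol <- stats::setNames(net$compartments$volume_l, net$compartments$id)
  comp <- split_species_key(species)$compartment
  as.vector(traj$conc[, species, drop = FALSE] %*% vol[comp])
}
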