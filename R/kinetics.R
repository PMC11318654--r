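# Rate-law family of the simulator and the stimulus-driven substrate
# release and protein induction inputs. All rate constants are in s^-1 and
# concentrations in mM; user-facing times are in hours.

HOUR_S <- 3600

#' Substrate-release profile
#'
#' Describes the time course of arachidonic acid made available to the
#' cascade after a stimulus. Within a segment the available concentration
#' rises from its current level `A0` toward the target maximum `M` as
#' `A(t) = M - (M - A0) * 2^(-t/doubling_time)`; if the decay switch is on,
#' the level instead halves every `half_life` hours from `peak_time`
#' onward. Scheduled re-assignments change the parameters at set times;
#' the available concentration is continuous across every event.
#'
#' @param max_conc_6h maximum 6 h concentration of AA, mM
#' @param doubling_time rise half-time, hours
#' @param half_life decay half-life, hours
#' @param decay_switch does the available AA decay after its peak?
#' @param peak_time hours post-stimulus at which decay begins (only used
#'   when `decay_switch` is `TRUE`)
#' @param schedule list of re-assignment events, each a list with a `time`
#'   (hours post-stimulus) and any of the other profile fields
#' @return object of class `aa_release_profile`
#' @export
release_profile <- function(max_conc_6h, doubling_time = 0.25,
                            half_life = 1, decay_switch = FALSE,
                            peak_time = 0.5, schedule = list()) {
  stopifnot(max_conc_6h >= 0, doubling_time > 0, half_life > 0,
            peak_time >= 0)
  times <- vapply(schedule, function(ev) ev$time, 1)
  if (length(times) && any(diff(times) <= 0))
    stop("schedule times must be strictly increasing", call. = FALSE)
  structure(list(max_conc_6h = max_conc_6h, doubling_time = doubling_time,
                 half_life = half_life, decay_switch = isTRUE(decay_switch),
                 peak_time = peak_time, schedule = schedule),
            class = "aa_release_profile")
}

# Piecewise segmentation of a release profile over [0, t_end] hours.
# Returns a data.frame with one row per segment: start/end times, the
# parameters in force, the mode ("rise", "decay" or "hold") and the
# carried-over level A0 and cumulative released amount R0 at segment start.
release_segments <- function(profile, t_end) {
  pars <- profile[c("max_conc_6h", "doubling_time", "half_life",
                    "decay_switch", "peak_time")]
  events <- vapply(profile$schedule, function(ev) ev$time, 1)
  breaks <- sort(unique(c(0, events[events < t_end],
                          if (profile$decay_switch) pars$peak_time,
                          t_end)))
  breaks <- breaks[breaks <= t_end & breaks >= 0]
  segs <- NULL
  A0 <- 0; R0 <- 0
  for (i in seq_len(length(breaks) - 1L)) {
    t0 <- breaks[i]; t1 <- breaks[i + 1L]
    for (ev in profile$schedule) {
      if (ev$time == t0)
        for (f in setdiff(names(ev), "time")) pars[[f]] <- ev[[f]]
    }
    # once the decay switch engages (at peak_time) decay takes precedence;
    # a schedule event can resume the rise by switching decay off or
    # moving peak_time later
    decay_active <- isTRUE(pars$decay_switch) && t0 >= pars$peak_time
    mode <- if (decay_active && A0 > 0) "decay"
            else if (pars$max_conc_6h > A0) "rise" else "hold"
    seg <- data.frame(t0 = t0, t1 = t1, M = pars$max_conc_6h,
                      Td = pars$doubling_time, Th = pars$half_life,
                      mode = mode, A0 = A0, R0 = R0,
                      stringsAsFactors = FALSE)
    A1 <- switch(mode,
                 rise = seg$M - (seg$M - A0) * 2^(-(t1 - t0) / seg$Td),
                 decay = A0 * 2^(-(t1 - t0) / seg$Th),
                 hold = A0)
    if (mode == "rise") R0 <- R0 + (A1 - A0)
    A0 <- A1
    segs <- rbind(segs, seg)
  }
  segs
}

eval_segment <- function(seg, t) {
  dt <- t - seg$t0
  switch(seg$mode,
         rise = seg$M - (seg$M - seg$A0) * 2^(-dt / seg$Td),
         decay = seg$A0 * 2^(-dt / seg$Th),
         hold = seg$A0)
}

#' Available AA concentration at a time post-stimulus
#'
#' @param t hours since the stimulus (vectorised, `t >= 0`)
#' @param profile an [release_profile()]
#' @return available AA concentration, mM
#' @export
release_concentration <- function(t, profile) {
  if (any(t < 0)) stop("t must be non-negative", call. = FALSE)
  if (!length(t)) return(numeric())
  segs <- release_segments(profile, max(t, max(vapply(profile$schedule,
                                                      function(e) e$time, 1),
                                               0)) + 1e-9)
  vapply(t, function(ti) {
    i <- max(which(segs$t0 <= ti + 1e-12))
    eval_segment(segs[i, ], min(ti, segs$t1[i]))
  }, 1)
}

#' Cumulative AA released by a time post-stimulus
#'
#' Total amount of AA injected into the cascade by time `t`: the sum of
#' all increases of the available-AA curve (decay phases release nothing).
#'
#' @inheritParams release_concentration
#' @return cumulative released concentration, mM
#' @export
release_cumulative <- function(t, profile) {
  if (any(t < 0)) stop("t must be non-negative", call. = FALSE)
  segs <- release_segments(profile, max(t, max(vapply(profile$schedule,
                                                      function(e) e$time, 1),
                                               0)) + 1e-9)
  vapply(t, function(ti) {
    i <- max(which(segs$t0 <= ti + 1e-12))
    s <- segs[i, ]
    s$R0 + if (s$mode == "rise")
      eval_segment(s, min(ti, s$t1)) - s$A0 else 0
  }, 1)
}

#' Protein-induction schedule
#'
#' Piecewise-constant (right-continuous) enzyme concentration: the
#' baseline before the first step, then the most recent step target.
#'
#' @param enzyme species key of the induced enzyme/transporter
#' @param steps list of `list(time = <hours post-stimulus>, conc = <mM>)`
#' @return object of class `aa_induction`
#' @export
induction_schedule <- function(enzyme, steps = list()) {
  times <- vapply(steps, function(s) s$time, 1)
  concs <- vapply(steps, function(s) s$conc, 1)
  if (length(times) && any(diff(times) <= 0))
    stop("step times must be strictly increasing", call. = FALSE)
  if (any(concs < 0)) stop("target concentrations must be >= 0", call. = FALSE)
  structure(list(enzyme = enzyme, steps = steps), class = "aa_induction")
}

#' Enzyme level under an induction schedule
#'
#' @param t hours post-stimulus (vectorised)
#' @param schedule an [induction_schedule()]
#' @param baseline enzyme concentration before the first step, mM
#' @return enzyme concentration at `t`, mM
#' @export
induction_level <- function(t, schedule, baseline) {
  if (!length(schedule$steps)) return(rep(baseline, length(t)))
  times <- vapply(schedule$steps, function(s) s$time, 1)
  concs <- vapply(schedule$steps, function(s) s$conc, 1)
  vapply(t, function(ti) {
    i <- which(times <= ti)
    if (!length(i)) baseline else concs[max(i)]
  }, 1)
}

# --- rate laws --------------------------------------------------------------

#' Reversible Michaelis-Menten rate with competitive inhibition
#'
#' The uni-uni reversible rate law used for every enzymatic reaction:
#' `v = k_cat * E * (S/K_ms - P/(K_ms*K_eq)) /
#'      (1 + S/K_ms + P/K_mp + sum_j C_j/K_mj)`.
#' The numerator vanishes exactly at chemical equilibrium (`P = S*K_eq`),
#' so the velocity always carries the thermodynamic sign of
#' `S - P/K_eq`. Competing substrates of the same enzyme add occupancy
#' terms to the denominator and can only shrink the magnitude of `v`.
#'
#' @param S substrate concentration, mM
#' @param P product concentration, mM
#' @param E enzyme concentration, mM
#' @param k_cat turnover number, s^-1
#' @param K_ms substrate Michaelis constant, mM
#' @param K_mp product Michaelis constant, mM
#' @param K_eq equilibrium constant
#' @param competitors optional list of `c(conc, K_m)` pairs (or a 2-column
#'   matrix) of species competing for the enzyme
#' @return reaction velocity, mM s^-1
#' @export
enzymatic_rate <- function(S, P, E, k_cat, K_ms, K_mp, K_eq,
                           competitors = NULL) {
  check_rate_args(c(S, P, E), c(k_cat, K_ms, K_mp, K_eq))
  comp <- competitor_term(competitors)
  num <- k_cat * E * (S / K_ms - P / (K_ms * K_eq))
  num / (1 + S / K_ms + P / K_mp + comp)
}

#' Reversible mass-action rate
#'
#' `v = k_f * S - k_r * P` for non-enzymatic conversions.
#'
#' @param S substrate concentration, mM
#' @param P product concentration, mM
#' @param k_f forward rate constant, s^-1
#' @param k_r reverse rate constant, s^-1
#' @return velocity, mM s^-1
#' @export
non_enzymatic_rate <- function(S, P, k_f, k_r) {
  check_rate_args(c(S, P), c(k_f, k_r))
  k_f * S - k_r * P
}

#' Facilitated transport rate with transporter competition
#'
#' `v = k_cat * T * (S/K_m) / (1 + S/K_m + sum_j S_j/K_mj)`, in donor-
#' compartment concentration units. Species sharing a transporter compete
#' through their individual affinities; with no competitors the law
#' reduces to Michaelis-Menten.
#'
#' @param S donor-compartment substrate concentration, mM
#' @param K_m substrate affinity for the transporter, mM
#' @param T_conc transporter concentration, mM
#' @param k_cat transporter turnover number, s^-1
#' @param competitors optional list of `c(conc, K_m)` pairs of
#'   co-transported species
#' @return velocity on the donor-compartment basis, mM s^-1
#' @export
transport_rate <- function(S, K_m, T_conc, k_cat, competitors = NULL) {
  check_rate_args(c(S, T_conc), c(K_m, k_cat))
  comp <- competitor_term(competitors)
  k_cat * T_conc * (S / K_m) / (1 + S / K_m + comp)
}

#' First-order degradation rate
#'
#' @param S species concentration, mM
#' @param k_deg degradation rate constant, s^-1 (may be zero)
#' @return velocity, mM s^-1
#' @export
degradation_rate <- function(S, k_deg) {
  if (any(S < 0) || any(k_deg < 0))
    stop("negative concentration or rate constant", call. = FALSE)
  k_deg * S
}

competitor_term <- function(competitors) {
  if (is.null(competitors) || !length(competitors)) return(0)
  if (is.matrix(competitors))
    return(sum(competitors[, 1] / competitors[, 2]))
  sum(vapply(competitors, function(cj) {
    if (cj[1] < 0 || cj[2] <= 0)
      stop("competitor concentrations must be >= 0 and K_m > 0",
           call. = FALSE)
    cj[1] / cj[2]
  }, 1))
}

check_rate_args <- function(concs, params) {
  if (any(concs < 0)) stop("negative concentration", call. = FALSE)
  if (any(params <= 0)) stop("non-positive rate parameter", call. = FALSE)
  invisible(TRUE)
}
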