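# Ensemble execution and prediction-band summaries.

#' Simulate every variant of an ensemble
#'
#' Runs [run_variant()] for each variant in order. Failed integrations
#' are kept in place with their status flag (and counted in a message)
#' so downstream stages can exclude them; the result is order-stable and
#' fully determined by the ensemble seed.
#'
#' @param net the `aa_network` the ensemble was sampled against
#' @param ens an `aa_ensemble` from [sample_ensemble()]
#' @param protocol a [simulation_protocol()]
#' @param quiet suppress the failed-variant count message?
#' @return list of `aa_trajectory`, one per variant
#' @export
run_ensemble <- function(net, ens, protocol = simulation_protocol(),
                         quiet = FALSE) {
  if (!identical(ens$network_signature, network_signature(net)))
    stop("ensemble was sampled against a different network ",
         "(reaction inventory mismatch)", call. = FALSE)
  trajs <- lapply(seq_len(ens$n), function(i)
    run_variant(net, get_variant(ens, i), protocol))
  n_failed <- sum(vapply(trajs, function(tr) tr$status != "ok", TRUE))
  if (!quiet && n_failed > 0)
    message(n_failed, " of ", ens$n, " variants failed to integrate")
  trajs
}

#' Median and interquartile band of ensemble predictions
#'
#' @param trajs list of trajectories from [run_ensemble()]
#' @param species species key `"id@compartment"`
#' @param times_h readout times (hours post-stimulus)
#' @return data.frame with `time_h`, `median`, `q25`, `q75` and `n_ok`
#'   (successful variants used)
#' @export
summarize_ensemble <- function(trajs, species,
                               times_h = c(0.5, 1, 3, 6)) {
  ok <- Filter(function(tr) tr$status == "ok", trajs)
  if (!length(ok)) stop("no successful trajectories", call. = FALSE)
  mat <- vapply(ok, function(tr)
    trajectory_at(tr, species, times_h)[, 1], numeric(length(times_h)))
  mat <- matrix(mat, nrow = length(times_h))
  qs <- apply(mat, 1L, stats::quantile, probs = c(0.25, 0.5, 0.75),
              names = FALSE)
  data.frame(species = species, time_h = times_h,
             median = qs[2, ], q25 = qs[1, ], q75 = qs[3, ],
             n_ok = length(ok), stringsAsFactors = FALSE)
}

#' Write trajectories as tidy CSV
#'
#' Long format: `variant, species, compartment, time_h, conc_mM`.
#'
#' @param trajs list of trajectories
#' @param path output CSV
#' @param times_h times to export (default: each trajectory's own grid)
#' @return `path`, invisibly
#' @export
write_trajectories <- function(trajs, path, times_h = NULL) {
  rows <- lapply(trajs, function(tr) {
    if (tr$status != "ok") return(NULL)
    tt <- if (is.null(times_h)) tr$times_h else times_h
    cc <- trajectory_at(tr, colnames(tr$conc), tt)
    sk <- split_species_key(colnames(tr$conc))
    data.frame(variant = tr$variant,
               species = rep(sk$id, each = length(tt)),
               compartment = rep(sk$compartment, each = length(tt)),
               time_h = rep(tt, times = ncol(cc)),
               conc_mM = as.vector(cc), stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
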