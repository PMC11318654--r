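# Quality scoring of variant predictions against experimental eicosanoid
# time courses, and the three ensemble-level Psi scores.

# Simulated values are floored here before taking logs so that a variant
# predicting (numerical) zero gets a finite, very poor score instead of
# -Inf dominating every cumulative sum.
SIM_FLOOR_MM <- 1e-30

# Default pass thresholds for the Psi scores: per-point, per-metabolite
# cumulative (4 time points) and total cumulative (all data points).
PSI_THRESHOLDS <- c(timepoint = -10, metabolite = -40, total = -500)

#' Experimental dataset constructor
#'
#' @param metabolite species id of the measured metabolite (matched in
#'   the extracellular compartment by the scoring helpers)
#' @param time_h measurement times, hours post-stimulus
#' @param conc_mM concentrations in model units (mM)
#' @param below_loq logical; measurements under the limit of
#'   quantification are kept in the table but excluded from scoring
#' @param label free-text cell-type/stimulus label
#' @return data.frame of class `aa_dataset`
#' @export
experimental_dataset <- function(metabolite, time_h, conc_mM,
                                 below_loq = FALSE, label = "") {
  d <- data.frame(metabolite = metabolite, time_h = time_h,
                  conc_mM = conc_mM,
                  below_loq = rep_len(below_loq, length(metabolite)),
                  stringsAsFactors = FALSE)
  if (any(d$conc_mM[!d$below_loq] <= 0))
    stop("non-positive concentration without below-LOQ flag", call. = FALSE)
  attr(d, "label") <- label
  class(d) <- c("aa_dataset", class(d))
  d
}

#' Read an experimental dataset CSV
#'
#' Columns: `metabolite, time_h, conc, below_loq, unit, conversion_factor`.
#' Concentrations are converted to mM as `conc * conversion_factor`; the
#' factor must be supplied explicitly (no silent default), because
#' converting assay units such as pg per million cells to mM requires
#' cell counts and volumes the model does not know.
#'
#' @param path CSV file
#' @return an `aa_dataset`
#' @export
read_dataset <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("metabolite", "time_h", "conc", "below_loq", "unit",
            "conversion_factor")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("dataset missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyNA(d$conversion_factor))
    stop("conversion_factor must be given for every row", call. = FALSE)
  experimental_dataset(d$metabolite, d$time_h,
                       d$conc * d$conversion_factor,
                       as.logical(d$below_loq))
}

#' Write an experimental dataset CSV
#' @param dataset an `aa_dataset` (concentrations already in mM)
#' @param path output CSV
#' @return `path`, invisibly
#' @export
write_dataset <- function(dataset, path) {
  out <- data.frame(metabolite = dataset$metabolite,
                    time_h = dataset$time_h, conc = dataset$conc_mM,
                    below_loq = dataset$below_loq, unit = "mM",
                    conversion_factor = 1)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Point quality score
#'
#' The log-density of a Gaussian evaluated at the log experimental value
#' with the log simulated value as its mean:
#' `score = ln N(E; S, sigma)` with `E = ln(experimental)` and
#' `S = ln(simulated)`. The score is maximal (`-ln(sigma*sqrt(2*pi))`)
#' when prediction and measurement agree, symmetric, and strictly
#' decreasing in `|E - S|`; less negative scores indicate a more accurate
#' variant.
#'
#' @param experimental measured concentration, mM (> 0)
#' @param simulated predicted concentration, mM (floored at 1e-30 before
#'   the log)
#' @param sigma ln-space width of the score kernel
#' @return log-density score (vectorised)
#' @export
point_quality_score <- function(experimental, simulated, sigma = 1) {
  if (any(experimental <= 0))
    stop("experimental concentrations must be positive", call. = FALSE)
  stats::dnorm(log(experimental), mean = log(pmax(simulated, SIM_FLOOR_MM)),
               sd = sigma, log = TRUE)
}

#' Score an ensemble against a dataset
#'
#' Computes the per-point quality score for every successful variant and
#' every quantifiable data point (below-LOQ points are excluded), plus the
#' per-metabolite and total cumulative sums.
#'
#' @param trajs trajectories from [run_ensemble()]
#' @param dataset an `aa_dataset`; metabolite ids are matched to the
#'   extracellular species of the network
#' @param sigma score kernel width (ln-space)
#' @param compartment compartment in which measured metabolites live
#' @return object of class `aa_scoretable`: data.frames `points`
#'   (variant, metabolite, time_h, score), `metabolites` (variant,
#'   metabolite, cumulative) and `totals` (variant, total)
#' @export
score_ensemble <- function(trajs, dataset, sigma = 1,
                           compartment = "extracellular") {
  scored <- dataset[!dataset$below_loq, , drop = FALSE]
  n_excluded <- sum(dataset$below_loq)
  if (!nrow(scored)) stop("no quantifiable data points", call. = FALSE)
  ok <- Filter(function(tr) tr$status == "ok", trajs)
  if (!length(ok)) stop("no successful trajectories to score", call. = FALSE)
  keys <- species_key(unique(scored$metabolite), compartment)
  missing <- setdiff(keys, colnames(ok[[1]]$conc))
  if (length(missing))
    stop("dataset metabolites not in the model: ",
         paste(split_species_key(missing)$id, collapse = ", "),
         call. = FALSE)
  points <- do.call(rbind, lapply(ok, function(tr) {
    sim <- trajectory_at(tr, species_key(scored$metabolite, compartment),
                         scored$time_h)
    # trajectory_at returns a times x species matrix; we need the
    # row-wise pairing (point i with its own metabolite)
    simv <- sim[cbind(seq_len(nrow(scored)), seq_len(nrow(scored)))]
    data.frame(variant = tr$variant, metabolite = scored$metabolite,
               time_h = scored$time_h,
               score = point_quality_score(scored$conc_mM, simv, sigma),
               stringsAsFactors = FALSE)
  }))
  structure(c(cumulative_scores(points),
              list(sigma = sigma, n_below_loq = n_excluded)),
            class = "aa_scoretable")
}

#' Cumulative scores from point scores
#'
#' @param points data.frame with columns `variant`, `metabolite`,
#'   `time_h`, `score`
#' @return list with `points`, `metabolites` (per-variant-per-metabolite
#'   sums) and `totals` (per-variant sums)
#' @export
cumulative_scores <- function(points) {
  if (!nrow(points))
    return(list(points = points,
                metabolites = data.frame(variant = integer(),
                                         metabolite = character(),
                                         cumulative = numeric()),
                totals = data.frame(variant = integer(),
                                    total = numeric())))
  met <- stats::aggregate(score ~ variant + metabolite, data = points, FUN = sum)
  names(met)[names(met) == "score"] <- "cumulative"
  tot <- stats::aggregate(score ~ variant, data = points, FUN = sum)
  names(tot)[names(tot) == "score"] <- "total"
  list(points = points, metabolites = met[order(met$variant, met$metabolite), ],
       totals = tot[order(tot$variant), ])
}

#' @export
print.aa_scoretable <- function(x, ...) {
  cat("Quality-score table:", nrow(x$totals), "variants x",
      nrow(x$points) / nrow(x$totals), "data points",
      sprintf("(sigma = %g; %d below-LOQ points excluded)\n",
              x$sigma, x$n_below_loq))
  invisible(x)
}

#' Ensemble Psi scores
#'
#' The percentage of scored variants whose quality scores clear the pass
#' thresholds: per (metabolite, time point) using the point score
#' (default > -10), per metabolite using the metabolite cumulative score
#' (default > -40), and in total using the total cumulative score
#' (default > -500).
#'
#' @param table an `aa_scoretable` (or the list from
#'   [cumulative_scores()])
#' @param thresholds named vector with elements `timepoint`, `metabolite`
#'   and `total`
#' @return list with data.frames `psi_timepoint` (metabolite, time_h,
#'   psi), `psi_metabolite` (metabolite, psi) and scalar `psi_total`,
#'   all percentages in [0, 100]
#' @export
psi_scores <- function(table, thresholds = PSI_THRESHOLDS) {
  if (!nrow(table$points)) stop("empty score table", call. = FALSE)
  pct <- function(x) 100 * mean(x)
  tp <- stats::aggregate(score ~ metabolite + time_h, data = table$points,
                         FUN = function(s) pct(s > thresholds[["timepoint"]]))
  names(tp)[names(tp) == "score"] <- "psi"
  met <- stats::aggregate(cumulative ~ metabolite, data = table$metabolites,
                          FUN = function(s) pct(s > thresholds[["metabolite"]]))
  names(met)[names(met) == "cumulative"] <- "psi"
  list(psi_timepoint = tp[order(tp$metabolite, tp$time_h), ],
       psi_metabolite = met,
       psi_total = pct(table$totals$total > thresholds[["total"]]))
}
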