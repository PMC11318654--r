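# Cell-type adaptation: Kolmogorov-Smirnov comparison of the parameter
# distributions of the best-fitting variants against their sampling
# priors, with Bonferroni control of the family-wise error rate, and
# refitting of significantly shifted priors.

#' Select the best-fitting variants
#'
#' The `ceiling(fraction * n)` variants with the highest (least negative)
#' total cumulative quality score; ties are broken by variant index so
#' the selection is deterministic.
#'
#' @param table an `aa_scoretable` (or list with a `totals` data.frame)
#' @param fraction proportion of variants to keep (default: top decile)
#' @return integer vector of variant indices
#' @export
select_top_models <- function(table, fraction = 0.1) {
  tot <- table$totals
  if (!nrow(tot)) stop("empty score table", call. = FALSE)
  stopifnot(fraction > 0, fraction <= 1)
  k <- ceiling(fraction * nrow(tot))
  ord <- order(-tot$total, tot$variant)
  sort(tot$variant[ord[seq_len(k)]])
}

#' KS-test adaptation of one prior
#'
#' One-sample, two-sided Kolmogorov-Smirnov test of the ln-transformed
#' parameter values of the selected variants against the prior's
#' Normal(mu, sigma) in ln space. The result is significant when the raw
#' p-value clears the Bonferroni-corrected level `alpha / n_hypotheses`;
#' a significant prior is refitted (maximum-likelihood log-normal on the
#' top values, sigma floored at `sigma_min`), otherwise returned
#' unchanged.
#'
#' @param top_values parameter values of the selected variants (> 0)
#' @param prior the `aa_prior` the values were sampled from (must be
#'   independently sampled, not a dependent K_mp/k_r prior)
#' @param alpha family-wise error rate
#' @param n_hypotheses number of tested hypotheses (use
#'   [n_sampled_parameters()] for a whole-network adaptation)
#' @param sigma_min ln-space floor for the refitted sigma
#' @return list of class `aa_adaptation`: `parameter`, `statistic`,
#'   `p_value`, `significant`, `n_hypotheses`, `adjusted` (an `aa_prior`,
#'   refitted iff significant)
#' @export
ks_adapt <- function(top_values, prior, alpha = 0.01, n_hypotheses = 1L,
                     sigma_min = SIGMA_MIN_DEFAULT) {
  if (prior$dependent)
    stop("dependent priors are derived, not sampled; only sampled ",
         "parameters can be KS-tested", call. = FALSE)
  if (length(top_values) < 5)
    stop("need at least 5 values for the KS test", call. = FALSE)
  lv <- log(top_values)
  ks <- stats::ks.test(lv, "pnorm", mean = prior$mu, sd = prior$sigma)
  significant <- ks$p.value < alpha / n_hypotheses
  adjusted <- prior
  if (significant) {
    adjusted <- parameter_prior(prior$name, mean(lv),
                                max(stats::sd(lv), sigma_min))
  }
  structure(list(parameter = prior$name,
                 statistic = unname(ks$statistic),
                 p_value = ks$p.value, significant = significant,
                 n_hypotheses = as.integer(n_hypotheses),
                 adjusted = adjusted),
            class = "aa_adaptation")
}

#' Enrichment profile of the top-variant values against the prior
#'
#' Bins ln-space parameter values over the prior's central 99.9% mass and
#' reports, per bin, the log-ratio of the observed count among the
#' selected variants to the count expected under the prior, with a
#' pseudocount keeping empty bins finite.
#'
#' @param top_values parameter values of the selected variants
#' @param prior the sampling `aa_prior`
#' @param bins number of bins (>= 2)
#' @param pseudocount added to observed and expected counts
#' @return data.frame with `lower`, `upper` (natural-scale bin edges),
#'   `observed`, `expected` and `log_ratio`
#' @export
enrichment_profile <- function(top_values, prior, bins = 20,
                               pseudocount = 0.5) {
  stopifnot(bins >= 2)
  if (prior$dependent || !is.finite(prior$sigma))
    stop("degenerate prior", call. = FALSE)
  half <- stats::qnorm(1 - 5e-4)
  edges <- seq(prior$mu - half * prior$sigma, prior$mu + half * prior$sigma,
               length.out = bins + 1L)
  lv <- log(top_values)
  observed <- vapply(seq_len(bins), function(i)
    sum(lv >= edges[i] & lv < edges[i + 1L]), 1)
  observed[bins] <- observed[bins] + sum(lv == edges[bins + 1L])
  p <- stats::pnorm(edges, prior$mu, prior$sigma)
  expected <- length(top_values) * diff(p)
  data.frame(lower = exp(edges[-(bins + 1L)]), upper = exp(edges[-1L]),
             observed = observed, expected = expected,
             log_ratio = log((observed + pseudocount) /
                               (expected + pseudocount)))
}

#' Adapt a whole prior set to a scored ensemble
#'
#' Applies [select_top_models()] and then [ks_adapt()] to every
#' independently sampled parameter, using the network's sampled-parameter
#' count as the Bonferroni hypothesis count (184 for the shipped
#' network).
#'
#' @param net the `aa_network`
#' @param ens the scored `aa_ensemble`
#' @param table the `aa_scoretable` for `ens`
#' @param fraction top fraction of variants to use
#' @param alpha family-wise error rate
#' @param parameters parameter names to test (default: all sampled)
#' @return list with `results` (data.frame: parameter, statistic,
#'   p_value, significant), `priors` (the adapted `aa_priorset`),
#'   `top_variants` and `n_hypotheses`
#' @export
adapt_priors <- function(net, ens, table, fraction = 0.1, alpha = 0.01,
                         parameters = ens$sampled_names) {
  n_hyp <- length(ens$sampled_names)
  top <- select_top_models(table, fraction)
  rows <- match(top, seq_len(ens$n))
  adapted <- ens$priors
  results <- do.call(rbind, lapply(parameters, function(p) {
    res <- ks_adapt(ens$values[rows, p], ens$priors[[p]],
                    alpha = alpha, n_hypotheses = n_hyp)
    adapted[[p]] <<- res$adjusted
    data.frame(parameter = p, statistic = res$statistic,
               p_value = res$p_value, significant = res$significant,
               stringsAsFactors = FALSE)
  }))
  list(results = results, priors = adapted, top_variants = top,
       n_hypotheses = n_hyp)
}
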