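test_that("the point score is the Gaussian log-density in log space", {
  # perfect prediction: the Gaussian mode
  expect_equal(point_quality_score(1e-6, 1e-6, sigma = 1),
               -log(sqrt(2 * pi)))
  expect_equal(point_quality_score(1e-6, 1e-6, sigma = 0.5),
               -log(0.5 * sqrt(2 * pi)))

  # four ln-units off at sigma 1: -ln sqrt(2 pi) - 8, inside the -10 band
  s <- point_quality_score(exp(0), exp(4), sigma = 1)
  expect_equal(s, -log(sqrt(2 * pi)) - 8)
  expect_gt(s, -10)

  # oracle equivalence against direct Gaussian log-pdf arithmetic on a grid
  set.seed(1)
  E <- exp(runif(200, -8, 2)); S <- exp(runif(200, -8, 2))
  sigma <- 0.8
  oracle <- -0.5 * ((log(E) - log(S)) / sigma)^2 - log(sigma * sqrt(2 * pi))
  expect_equal(point_quality_score(E, S, sigma), oracle)

  # symmetric and strictly decreasing in |E - S|
  expect_equal(point_quality_score(exp(1), exp(3)),
               point_quality_score(exp(3), exp(1)))
  d <- point_quality_score(1e-5, 1e-5 * exp(seq(0, 5, by = 0.5)))
  expect_true(all(diff(d) < 0))

  expect_error(point_quality_score(-1, 1), "positive")
})

test_that("scores are invariant to a common unit rescaling", {
  expect_equal(point_quality_score(3e-6, 8e-6),
               point_quality_score(3e-6 * 1e3, 8e-6 * 1e3))
})

test_that("very small simulated values are floored, not -Inf", {
  s <- point_quality_score(1e-6, 0)
  expect_true(is.finite(s))
  expect_lt(s, -100)
})

test_that("cumulative scores are exact sums of their point scores", {
  pts <- data.frame(variant = 1L, metabolite = "PGE2",
                    time_h = c(0.5, 1, 3, 6), score = rep(-5, 4))
  cs <- cumulative_scores(pts)
  expect_equal(cs$metabolites$cumulative, -20)
  expect_equal(cs$totals$total, -20)

  # random table against a brute-force loop oracle
  set.seed(7)
  pts <- expand.grid(variant = 1:6, metabolite = c("a", "b", "c"),
                     time_h = c(0.5, 1, 3, 6), stringsAsFactors = FALSE)
  pts$score <- -rexp(nrow(pts), 0.1)
  cs <- cumulative_scores(pts)
  for (v in 1:6) {
    for (m in c("a", "b", "c")) {
      acc <- 0
      for (i in seq_len(nrow(pts)))
        if (pts$variant[i] == v && pts$metabolite[i] == m)
          acc <- acc + pts$score[i]
      expect_equal(cs$metabolites$cumulative[cs$metabolites$variant == v &
                                               cs$metabolites$metabolite == m],
                   acc)
    }
    expect_equal(cs$totals$total[cs$totals$variant == v],
                 sum(pts$score[pts$variant == v]))
  }
})

test_that("Psi scores equal hand-counted pass percentages", {
  # 1000 variants, one metabolite/time: 380 pass the total threshold
  pts <- data.frame(variant = 1:1000, metabolite = "PGE2", time_h = 0.5,
                    score = c(rep(-400, 380), rep(-600, 620)))
  psi <- psi_scores(fake_score_table(pts))
  expect_equal(psi$psi_total, 38)

  # all variants at the maximum: every Psi is 100
  best <- -log(sqrt(2 * pi))
  pts <- expand.grid(variant = 1:20, metabolite = c("a", "b"),
                     time_h = c(0.5, 1), stringsAsFactors = FALSE)
  pts$score <- best
  psi <- psi_scores(fake_score_table(pts))
  expect_true(all(psi$psi_timepoint$psi == 100))
  expect_true(all(psi$psi_metabolite$psi == 100))
  expect_equal(psi$psi_total, 100)

  # mixed synthetic table: 2 metabolites x 2 times, 4 points per variant.
  # variants 1-3 score -3 everywhere: pass every threshold; variants 4-7
  # score -25: fail the point (-25 < -10) and metabolite (-50 < -40)
  # thresholds but pass the total (-100 > -500); variants 8-10 score
  # -150: fail everything (total -600)
  pts <- expand.grid(variant = 1:10, metabolite = c("a", "b"),
                     time_h = c(0.5, 1), stringsAsFactors = FALSE)
  pts$score <- rep(c(rep(-3, 3), rep(-25, 4), rep(-150, 3)), 4)
  psi <- psi_scores(fake_score_table(pts))
  expect_true(all(psi$psi_timepoint$psi == 30))
  expect_true(all(psi$psi_metabolite$psi == 30))
  expect_equal(psi$psi_total, 70)

  # the -10 band: -9 counts as close, -11 does not
  pts <- data.frame(variant = 1:2, metabolite = "m", time_h = 1,
                    score = c(-9, -11))
  psi <- psi_scores(fake_score_table(pts))
  expect_equal(psi$psi_timepoint$psi, 50)
})

test_that("psi from totals equals psi re-derived from points", {
  set.seed(3)
  pts <- expand.grid(variant = 1:50, metabolite = c("a", "b", "c"),
                     time_h = c(0.5, 1, 3, 6), stringsAsFactors = FALSE)
  pts$score <- -rexp(nrow(pts), 1 / 60)
  tab <- fake_score_table(pts)
  psi <- psi_scores(tab)
  totals <- tapply(pts$score, pts$variant, sum)
  expect_equal(psi$psi_total, 100 * mean(totals > -500))
})

test_that("datasets round-trip through CSV with explicit unit conversion", {
  ds <- experimental_dataset(c("PGE2", "HETE12"), c(0.5, 1),
                             c(2e-6, 3e-7), below_loq = c(FALSE, FALSE),
                             label = "demo")
  path <- withr::local_tempfile(fileext = ".csv")
  write_dataset(ds, path)
  back <- read_dataset(path)
  expect_equal(back$conc_mM, ds$conc_mM)

  # conversion factor applied on read
  raw <- read.csv(path)
  raw$unit <- "pg_per_1e6cells"; raw$conc <- raw$conc * 2
  raw$conversion_factor <- 0.5
  write.csv(raw, path, row.names = FALSE)
  back2 <- read_dataset(path)
  expect_equal(back2$conc_mM, ds$conc_mM)

  raw$conversion_factor <- NA
  write.csv(raw, path, row.names = FALSE)
  expect_error(read_dataset(path), "conversion_factor")

  expect_error(experimental_dataset("x", 1, -1), "below-LOQ")
})

test_that("scoring an ensemble excludes below-LOQ points and names unknowns", {
  tt <- c(0.5, 1, 3, 6)
  mk <- function(i, level)
    fake_trajectory(tt, matrix(level, 4, 1,
                               dimnames = list(NULL, "PGE2@extracellular")),
                    variant = i)
  trajs <- list(mk(1, 1e-6), mk(2, 1e-5))
  ds <- experimental_dataset(rep("PGE2", 4), tt,
                             c(1e-6, 1e-6, 1e-6, 1e-9),
                             below_loq = c(FALSE, FALSE, FALSE, TRUE))
  tab <- score_ensemble(trajs, ds)
  expect_equal(nrow(tab$points), 2 * 3)   # the LOQ point is dropped
  expect_equal(tab$n_below_loq, 1L)
  # variant 1 predicts exactly: all points at the mode
  expect_equal(tab$totals$total[1], 3 * -log(sqrt(2 * pi)))

  bad <- experimental_dataset("NOTINMODEL", 1, 1e-6)
  expect_error(score_ensemble(trajs, bad), "NOTINMODEL")
})
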