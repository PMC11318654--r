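test_that("weighted log-normal fits match direct moment computations", {
  # single value: mu forced, sigma floored
  p <- fit_weighted_lognormal(2.0)
  expect_equal(p$mu, log(2))
  expect_equal(p$sigma, 0.25)

  # symmetric pair in log space
  p <- fit_weighted_lognormal(c(1, exp(2)))
  expect_equal(p$mu, 1.0)

  # equal-weight geometric ladder against an independent arithmetic oracle
  vals <- c(0.5, 1, 2, 4, 8)
  lv <- log(vals)
  oracle_mu <- mean(lv)
  oracle_sigma <- sqrt(mean((lv - mean(lv))^2))
  p <- fit_weighted_lognormal(vals)
  expect_equal(p$mu, oracle_mu)
  expect_equal(p$sigma, oracle_sigma)

  # uneven weights: weighting one value heavily pulls mu toward it
  p <- fit_weighted_lognormal(c(1, 100), weights = c(9, 1))
  expect_equal(p$mu, 0.1 * log(100))

  expect_error(fit_weighted_lognormal(numeric()), "no values")
  expect_error(fit_weighted_lognormal(c(1, -2)), "positive")
  expect_error(fit_weighted_lognormal(1, weights = 0), "weights")
})

test_that("dependent parameters satisfy their thermodynamic identities", {
  expect_equal(derive_dependent(2, K_eq = 4, type = "non_enzymatic"), 0.5)
  expect_equal(derive_dependent(5, K_eq = 1, type = "non_enzymatic"), 5)
  expect_equal(derive_dependent(3, K_ms = 0.2, K_eq = 10,
                                type = "enzymatic"), 2)
  expect_error(derive_dependent(-1, K_eq = 1), "positive")
  expect_error(derive_dependent(1, K_eq = 0), "positive")
})

test_that("sampled ensembles are thermodynamically consistent", {
  net <- build_aa_cascade()
  priors <- default_priors(net)
  # 21 quadruplets + 11 triplets per variant; 320 variants > 1e4 residuals
  ens <- sample_ensemble(net, priors, n = 320, seed = 42)
  res <- thermo_residuals(net, ens)
  expect_gte(length(res), 1e4)
  expect_lt(max(res), 1e-9)
  expect_true(all(ens$values > 0))
})

test_that("sampling is deterministic in the seed", {
  net <- build_aa_cascade()
  priors <- default_priors(net)
  e1 <- sample_ensemble(net, priors, n = 5, seed = 7)
  e2 <- sample_ensemble(net, priors, n = 5, seed = 7)
  e3 <- sample_ensemble(net, priors, n = 5, seed = 8)
  expect_identical(e1$values, e2$values)
  expect_true(any(e1$values != e3$values))
})

test_that("degenerate-width priors concentrate at their mode", {
  net <- make_ab_network()
  priors <- prior_set(list(
    parameter_prior("kf_r1", log(2), 0.25),
    parameter_prior("kr_r1", dependent = TRUE),
    parameter_prior("Keq_r1", log(4), 0.25)))
  ens <- sample_ensemble(net, priors, n = 1, seed = 3)
  expect_lt(abs(log(ens$values[1, "kf_r1"]) - log(2)), 4 * 0.25)
  expect_lt(abs(log(ens$values[1, "Keq_r1"]) - log(4)), 4 * 0.25)
})

test_that("marginal ln-samples match their prior moments", {
  net <- make_ab_network()
  priors <- prior_set(list(
    parameter_prior("kf_r1", -2, 0.7),
    parameter_prior("kr_r1", dependent = TRUE),
    parameter_prior("Keq_r1", 1, 0.3)))
  n <- 1e5
  ens <- sample_ensemble(net, priors, n = n, seed = 11)
  for (nm in c("kf_r1", "Keq_r1")) {
    lv <- log(ens$values[, nm])
    mu <- priors[[nm]]$mu; sigma <- priors[[nm]]$sigma
    expect_lt(abs(mean(lv) - mu), 3 * sigma / sqrt(n))
    expect_lt(abs(sd(lv) - sigma), 3 * sigma / sqrt(2 * n))
  }
})

test_that("missing priors are reported with reaction and symbol", {
  net <- make_ab_network()
  priors <- prior_set(list(parameter_prior("kf_r1", 0, 1)))
  expect_error(sample_ensemble(net, priors, n = 2, seed = 1),
               "reaction 1.*kr_r1")
  expect_error(sample_ensemble(build_aa_cascade(),
                               default_priors(build_aa_cascade()),
                               n = 0, seed = 1), "n must be")
})

test_that("the sampled-parameter census counts only enabled, independent parameters", {
  net <- build_aa_cascade()
  expect_equal(n_sampled_parameters(net), 184L)

  # disabling a degradation reaction removes exactly its one parameter
  net2 <- net
  i <- which(vapply(net2$reactions, function(r) r$number, 1L) == 63L)
  net2$reactions[[i]]$enabled <- FALSE
  expect_equal(n_sampled_parameters(net2, default_priors(net2)), 183L)
})

test_that("prior sets round-trip through JSON", {
  p1 <- fit_weighted_lognormal(c(1, 2, 4), name = "kcat_r2",
                               sources = c("a", "b", "c"))
  p2 <- parameter_prior("Kmp_r2", dependent = TRUE)
  path <- withr::local_tempfile(fileext = ".json")
  save_priors(prior_set(list(p1, p2)), path)
  back <- load_priors(path)
  expect_equal(back[["kcat_r2"]]$mu, p1$mu)
  expect_equal(back[["kcat_r2"]]$sigma, p1$sigma)
  expect_equal(back[["kcat_r2"]]$kind, "k_cat")
  expect_true(back[["Kmp_r2"]]$dependent)
})
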