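test_that("release rises toward the maximum and stays monotone without decay", {
  prof <- release_profile(10, doubling_time = 0.5)
  tt <- seq(0, 24, by = 0.1)
  a <- release_concentration(tt, prof)
  expect_true(all(diff(a) >= 0))
  expect_lt(abs(a[length(a)] - 10), 1e-6)
  # rise half-time: half the asymptote after one doubling time
  expect_equal(release_concentration(0.5, prof), 5)
  expect_error(release_concentration(-1, prof), "non-negative")
})

test_that("the decay phase halves the level every half-life", {
  prof <- release_profile(8, doubling_time = 0.05, decay_switch = TRUE,
                          peak_time = 1, half_life = 1.5)
  peak <- release_concentration(1, prof)
  expect_equal(release_concentration(1 + 1.5, prof), peak / 2)
  expect_equal(release_concentration(1 + 3, prof), peak / 4)
  # continuous at the switch
  expect_lt(abs(release_concentration(1 - 1e-9, prof) - peak), 1e-6)
})

test_that("the minimal + delayed schedule splits release 10% / 90% at 3 h", {
  prof <- make_release_scenarios(10)$minimal_delayed
  frac <- release_cumulative(3, prof) / release_cumulative(6, prof)
  expect_equal(frac, 0.10, tolerance = 1e-6)
  # and the schedule re-assignment keeps the level continuous
  expect_lt(abs(release_concentration(3 + 1e-9, prof) -
                  release_concentration(3 - 1e-9, prof)), 1e-6)
})

test_that("release scenarios have their defining shapes", {
  sc <- make_release_scenarios(10)
  # constant: time-invariant once risen
  expect_equal(release_concentration(c(1, 3, 6), sc$constant),
               rep(10, 3), tolerance = 1e-4)
  # decaying: strictly decreasing after the peak with the set half-life
  tt <- seq(0.5, 6, by = 0.25)
  a <- release_concentration(tt, sc$decaying)
  expect_true(all(diff(a) < 0))
  p <- release_concentration(0.25, sc$decaying)
  expect_equal(release_concentration(0.25 + sc$decaying$half_life,
                                     sc$decaying), p / 2)
  # delayed: nothing before 3 h, full release after
  expect_equal(release_concentration(2.9, sc$delayed), 0)
  expect_gt(release_concentration(4, sc$delayed), 9)
  # single pulse: up fast, mostly gone by 6 h
  expect_gt(release_concentration(0.25, sc$single_pulse), 9)
  expect_lt(release_concentration(6, sc$single_pulse),
            0.01 * release_concentration(0.25, sc$single_pulse))
})

test_that("the enzymatic rate law honours its limiting behaviours", {
  expect_equal(enzymatic_rate(1, 0.1, 0, 5, 0.01, 0.02, 10), 0)
  # chemical equilibrium: P = S * K_eq
  expect_equal(enzymatic_rate(2, 2 * 10, 1e-3, 5, 0.01, 0.1, 10), 0)
  # saturation: P = 0, S = 100 K_ms approaches k_cat * E within 1%
  v <- enzymatic_rate(100 * 0.01, 0, 1e-3, 5, 0.01, 0.1, 1e6)
  expect_lt(abs(v - 5 * 1e-3) / (5 * 1e-3), 0.01)
  expect_error(enzymatic_rate(-1, 0, 1, 1, 1, 1, 1), "negative")
  expect_error(enzymatic_rate(1, 0, 1, 0, 1, 1, 1), "non-positive")
})

test_that("reversible rates share the sign of the thermodynamic driving force", {
  set.seed(5)
  for (i in 1:200) {
    S <- runif(1, 0, 2); P <- runif(1, 0, 2)
    Keq <- exp(runif(1, -3, 3))
    v <- enzymatic_rate(S, P, 1e-3, 5, exp(runif(1, -5, 0)),
                        exp(runif(1, -5, 0)), Keq)
    expect_equal(sign(v), sign(S - P / Keq))
    vn <- non_enzymatic_rate(S, P, 2, 2 / Keq)
    expect_equal(sign(vn), sign(S - P / Keq))
  }
})

test_that("competitors shrink the magnitude but never flip the sign", {
  base <- enzymatic_rate(0.5, 0.01, 1e-3, 5, 0.01, 0.1, 100)
  with1 <- enzymatic_rate(0.5, 0.01, 1e-3, 5, 0.01, 0.1, 100,
                          competitors = list(c(0.3, 0.05)))
  with2 <- enzymatic_rate(0.5, 0.01, 1e-3, 5, 0.01, 0.1, 100,
                          competitors = list(c(0.3, 0.05), c(0.1, 0.01)))
  expect_true(abs(with1) < abs(base))
  expect_true(abs(with2) < abs(with1))
  expect_equal(sign(base), sign(with1))
})

test_that("non-enzymatic mass action is exact", {
  expect_equal(non_enzymatic_rate(0, 0, 1, 1), 0)
  expect_equal(non_enzymatic_rate(1, 4, 2, 0.5), 0)  # P/S = kf/kr
  expect_equal(non_enzymatic_rate(3, 1, 2, 0.5), 5.5)
})

test_that("the transport law reduces to Michaelis-Menten and competes", {
  expect_equal(transport_rate(1, 1, 2, 3), 3 * 2 / 2)  # half saturation
  expect_equal(transport_rate(1, 1, 1, 1, competitors = list(c(2, 0.5))),
               1 / 6)
  no_comp <- transport_rate(0.3, 0.1, 1e-5, 10)
  zero_comp <- transport_rate(0.3, 0.1, 1e-5, 10,
                              competitors = list(c(0, 0.5)))
  expect_equal(no_comp, zero_comp)
  expect_lt(transport_rate(0.3, 0.1, 1e-5, 10,
                           competitors = list(c(0.5, 0.5))), no_comp)
})

test_that("degradation is first order", {
  expect_equal(degradation_rate(0, 1), 0)
  expect_equal(degradation_rate(2, 0), 0)
  expect_equal(degradation_rate(2, 0.1), 0.2)
  expect_error(degradation_rate(-1, 1), "negative")
})

test_that("induction is piecewise constant and right-continuous", {
  empty <- induction_schedule("COX2@intracellular")
  expect_equal(induction_level(c(0, 3, 6), empty, 1e-4), rep(1e-4, 3))

  sched <- induction_schedule("COX2@intracellular",
                              steps = list(list(time = 3, conc = 2e-4)))
  expect_equal(induction_level(2.9, sched, 1e-4), 1e-4)
  expect_equal(induction_level(3.0, sched, 1e-4), 2e-4)
  expect_equal(induction_level(5.0, sched, 1e-4), 2e-4)

  # a rise-then-fall schedule reproduces an induction peak
  updown <- induction_schedule("COX2@intracellular",
                               steps = list(list(time = 1, conc = 3e-4),
                                            list(time = 3, conc = 5e-4),
                                            list(time = 4, conc = 2e-4)))
  lev <- induction_level(c(0.5, 2, 3.5, 5), updown, 1e-4)
  expect_equal(which.max(lev), 3L)
  expect_true(lev[4] < lev[3] && lev[1] < lev[2])

  expect_error(induction_schedule("x", steps = list(list(time = 2, conc = -1))),
               ">= 0")
})
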