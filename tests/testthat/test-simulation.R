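test_that("the assembled RHS matches the symbolic form for A <-> B", {
  net <- make_ab_network()
  f <- assemble_odes(net, ab_variant(kf = 2, kr = 0.5))
  state <- c("A@cell" = 3, "B@cell" = 1)
  d <- f(0, state)
  v <- 2 * 3 - 0.5 * 1
  expect_equal(unname(d), c(-v, v))
})

test_that("a network with all reactions disabled has a zero RHS", {
  net <- make_ab_network()
  net$reactions[[1]]$enabled <- FALSE
  f <- assemble_odes(net, ab_variant())
  d <- f(0, c("A@cell" = 3, "B@cell" = 1))
  expect_equal(unname(d), c(0, 0))
})

test_that("the integrated A <-> B system matches its closed form", {
  net <- make_ab_network(a0 = 1)
  # k_f = k_r = 1 s^-1: A(t) = 0.5 + 0.5 exp(-2 t), t in seconds
  report_h <- c(0.2, 0.5, 1, 2) / 3600
  protocol <- simulation_protocol(equilibration = 0,
                                  post_stimulus = 4 / 3600,
                                  report_times = report_h,
                                  output_dt = 0.1 / 3600)
  traj <- run_variant(net, ab_variant(1, 1), protocol)
  expect_equal(traj$status, "ok")
  a <- trajectory_at(traj, "A@cell", report_h)[, 1]
  closed <- 0.5 + 0.5 * exp(-2 * report_h * 3600)
  expect_lt(max(abs(a - closed)), 1e-6)
})

test_that("transport conserves amount on a closed subnetwork over 7 h", {
  net <- make_transport_network(a0 = 1)
  protocol <- simulation_protocol(equilibration = 1, post_stimulus = 6)
  traj <- run_variant(net, transport_variant(), protocol)
  expect_equal(traj$status, "ok")
  amount <- total_amount(net, traj)
  expect_lt(max(abs(amount - amount[1])) / amount[1], 1e-8)

  # single transport step: donor loss equals acceptor gain in amount
  f <- assemble_odes(net, transport_variant())
  d <- f(0, c("A@intracellular" = 0.5, "B@intracellular" = 0,
              "A@extracellular" = 0, "B@extracellular" = 0))
  expect_equal(d[["A@intracellular"]] * 1e-12 +
                 d[["A@extracellular"]] * 1e-9,
               -d[["B@intracellular"]] * 1e-12, tolerance = 1e-12)
})

test_that("without a stimulus the cascade stays at its initial floor", {
  net <- build_aa_cascade()
  ens <- sample_ensemble(net, default_priors(net), n = 1, seed = 2)
  protocol <- simulation_protocol(release = NULL)
  traj <- run_variant(net, get_variant(ens, 1), protocol)
  expect_equal(traj$status, "ok")
  expect_true(all(traj$conc <= 10 * 1e-28))
  expect_true(all(traj$conc >= -protocol$atol))
})

test_that("the stimulus drives AA and downstream extracellular mediators", {
  net <- build_aa_cascade()
  ens <- sample_ensemble(net, default_priors(net), n = 1, seed = 2)
  protocol <- simulation_protocol(release = release_profile(10, 0.25))
  traj <- run_variant(net, get_variant(ens, 1), protocol)
  expect_equal(traj$status, "ok")
  at6 <- trajectory_at(traj, c("AA@intracellular", "PGE2@extracellular",
                               "HETE12@extracellular"), 6)
  expect_true(all(at6 > 1e-12))
  # pre-stimulus the system is still at the floor
  at0 <- trajectory_at(traj, "PGE2@extracellular", -0.1)
  expect_lt(at0[1, 1], 1e-20)
  expect_true(all(traj$conc >= -protocol$atol))
})

test_that("solutions are converged with respect to the solver tolerances", {
  net <- build_aa_cascade()
  ens <- sample_ensemble(net, default_priors(net), n = 1, seed = 4)
  sp <- c("PGE2@extracellular", "HETE12@extracellular",
          "HETE15@extracellular")
  p1 <- simulation_protocol(release = release_profile(10, 0.25))
  p2 <- simulation_protocol(release = release_profile(10, 0.25),
                            rtol = p1$rtol / 10, atol = p1$atol / 10)
  t1 <- run_variant(net, get_variant(ens, 1), p1)
  t2 <- run_variant(net, get_variant(ens, 1), p2)
  c1 <- trajectory_at(t1, sp, c(0.5, 1, 3, 6))
  c2 <- trajectory_at(t2, sp, c(0.5, 1, 3, 6))
  expect_lt(max(abs(c1 - c2) / pmax(abs(c2), 1e-30)), 1e-3)
})

test_that("induction schedules raise the targeted enzyme's products", {
  net <- build_aa_cascade()
  ens <- sample_ensemble(net, default_priors(net), n = 1, seed = 2)
  v <- get_variant(ens, 1)
  release <- release_profile(10, 0.25)
  base <- run_variant(net, v, simulation_protocol(release = release))
  induced <- run_variant(net, v, simulation_protocol(
    release = release,
    inductions = list(induction_schedule(
      "COX2@intracellular",
      steps = list(list(time = 1, conc = 50 * v[["conc_COX2"]]))))))
  expect_equal(induced$status, "ok")
  pge2_base <- trajectory_at(base, "PGE2@extracellular", 6)[1, 1]
  pge2_ind <- trajectory_at(induced, "PGE2@extracellular", 6)[1, 1]
  expect_gt(pge2_ind, pge2_base)
  # before the induction step the two runs agree
  expect_equal(trajectory_at(induced, "PGE2@extracellular", 0.5)[1, 1],
               trajectory_at(base, "PGE2@extracellular", 0.5)[1, 1],
               tolerance = 1e-6)
})

test_that("invalid protocols and missing parameters are rejected", {
  expect_error(simulation_protocol(report_times = c(0.5, 8)),
               "report times")
  net <- make_ab_network()
  v <- c(kf_r1 = 1)
  expect_error(run_variant(net, v, simulation_protocol(
    equilibration = 0, post_stimulus = 1, report_times = 0.5)),
    "missing parameter")
})
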