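test_that("compile_odes evaluates rate laws and stoichiometry correctly", {
  # A -> B, v = k A: at k = 0.1, A = 10 the flux is 1 nM/min
  net <- reaction_network(
    rbind(species("A", initial_concentration = 10), species("B")),
    list(reaction("r1", c(A = 1), c(B = 1), kinetic_law = quote(k * A))),
    c(k = 0.1))
  ode <- compile_odes(net)
  expect_equal(ode$rates(0, c(A = 10, B = 0), c(k = 0.1)), 1)
  expect_equal(ode$deriv(0, c(A = 10, B = 0), c(k = 0.1)), c(-1, 1))

  # 2A -> B, v = k A^2: at k = 0.5, A = 2: v = 2, dA/dt = -4, dB/dt = +2
  net2 <- reaction_network(
    rbind(species("A", initial_concentration = 2), species("B")),
    list(reaction("r1", c(A = 2), c(B = 1), kinetic_law = quote(k * A^2))),
    c(k = 0.5))
  ode2 <- compile_odes(net2)
  expect_equal(ode2$rates(0, c(A = 2, B = 0), c(k = 0.5)), 2)
  expect_equal(ode2$deriv(0, c(A = 2, B = 0), c(k = 0.5)), c(-4, 2))

  # all rate constants zero -> zero derivative everywhere
  expect_equal(ode$deriv(3, c(A = 7, B = 1), c(k = 0)), c(0, 0))

  # unresolvable symbol is a compile error naming it
  net$reactions[[1]]$kinetic_law <- quote(kmiss * A)
  expect_error(compile_odes(net), "kmiss")
})

test_that("boundary species are held at zero derivative", {
  net <- reaction_network(
    rbind(species("S", initial_concentration = 5, boundary = TRUE),
          species("Pd")),
    list(reaction("r1", c(S = 1), c(Pd = 1), kinetic_law = quote(k * S))),
    c(k = 0.2))
  tr <- simulate_network(net, t_end = 5, n_points = 51)
  expect_equal(unname(tr$conc["S", ]), rep(5, 51))
  # product accumulates at the constant boundary-driven rate
  expect_equal(unname(tr$conc["Pd", 51]), 5 * 0.2 * 5, tolerance = 1e-6)
})

test_that("decay fixture matches its exponential closed form on the grid", {
  net <- make_fixture("decay")$network
  tr <- simulate_network(net, t_end = 10, n_points = 601)
  expect_equal(tr$time, seq(0, 10, length.out = 601))
  ref <- 10 * exp(-0.1 * tr$time)
  expect_lt(max(abs(tr$conc["A", ] - ref) / ref), 1e-6)
  expect_equal(unname(tr$conc["A", 601]), 10 * exp(-1), tolerance = 1e-6)
})

test_that("conservative fixtures conserve mass along the trajectory", {
  for (m in c("reversible_pair", "receptor_inhibitor")) {
    fix <- make_fixture(m)
    tr <- simulate_network(fix$network, t_end = 10, n_points = 201)
    for (w in fix$conserved) {
      tot <- colSums(tr$conc[names(w), , drop = FALSE] * w)
      if (max(tot) == 0) next
      expect_lt(diff(range(tot)) / max(tot), 1e-6)
    }
  }
})

test_that("a timed dose leaves the pre-event segment bit-identical and jumps exactly", {
  net <- make_fixture("receptor_inhibitor")$network
  t0 <- simulate_network(net, regime(), t_end = 10, n_points = 101)
  rg <- regime("E", list(intervention("dose", "I", 30, 5)))
  t1 <- simulate_network(net, rg, t_end = 10, n_points = 101)
  pre <- which(t0$time < 5)
  expect_identical(t1$conc[, pre], t0$conc[, pre])
  expect_identical(t1$vel[, pre], t0$vel[, pre])
  j <- which(t0$time == 5)
  expect_equal(unname(t1$conc["I", j] - t0$conc["I", j]), 30)
  others <- setdiff(rownames(t0$conc), "I")
  expect_equal(t1$conc[others, j], t0$conc[others, j], tolerance = 1e-9)
})

test_that("off-grid intervention times are honored as discontinuities", {
  net <- make_fixture("decay")$network
  rg <- regime("E", list(intervention("set_concentration", "A", 20, 3.21)))
  tr <- simulate_network(net, rg, t_end = 10, n_points = 101)
  after <- tr$time > 3.21
  ref <- 20 * exp(-0.1 * (tr$time[after] - 3.21))
  expect_lt(max(abs(tr$conc["A", after] - ref) / ref), 1e-6)
})

test_that("doubling the output grid does not change the solution", {
  net <- make_fixture("receptor_inhibitor")$network
  t1 <- simulate_network(net, t_end = 10, n_points = 301)
  t2 <- simulate_network(net, t_end = 10, n_points = 601)
  idx <- match(round(t1$time, 9), round(t2$time, 9))
  scale <- pmax(apply(t1$conc, 1, max), 1e-12)
  expect_lt(max(abs(t1$conc - t2$conc[, idx]) / scale), 1e-6)
})

test_that("adaptive solver agrees with the independent RK4 oracle", {
  for (m in c("decay", "reversible_pair")) {
    net <- make_fixture(m)$network
    ref <- rk4_oracle(net, t_end = 2, h = 1e-3)
    tr <- simulate_network(net, t_end = 2, n_points = 201)
    expect_lt(oracle_rel_err(tr, ref), 1e-5)
  }
})

test_that("velocities are the kinetic laws evaluated at the reported states", {
  fix <- make_fixture("reversible_pair")
  tr <- simulate_network(fix$network, t_end = 5, n_points = 51)
  expect_equal(unname(tr$vel["fwd", ]), unname(0.3 * tr$conc["A", ]),
               tolerance = 1e-9)
  expect_equal(unname(tr$vel["rev", ]), unname(0.2 * tr$conc["B", ]),
               tolerance = 1e-9)
})

test_that("integrated_signal implements the trapezoidal window integral", {
  net <- reaction_network(rbind(species("C", initial_concentration = 2)),
                          list(), numeric())
  tr <- simulate_network(net, t_end = 10, n_points = 101)
  expect_equal(integrated_signal(tr, "C", c(0, 10)), 20)
  # zero concentration integrates to zero
  net0 <- reaction_network(rbind(species("Z", initial_concentration = 0)),
                           list(), numeric())
  expect_equal(integrated_signal(simulate_network(net0, t_end = 10,
                                                  n_points = 11), "Z"), 0)
  # exponential decay: integral of 10 e^{-0.1 t} over [0,10] = 100 (1 - e^{-1})
  trd <- simulate_network(make_fixture("decay")$network, t_end = 10,
                          n_points = 601)
  expect_equal(integrated_signal(trd, "A", c(0, 10)), 100 * (1 - exp(-1)),
               tolerance = 1e-4)
  expect_error(integrated_signal(trd, "nope"), "unknown species")
  expect_error(integrated_signal(trd, "A", c(-1, 5)), "within")
})

test_that("trajectories round-trip through CSV within formatting precision", {
  fix <- make_fixture("linear_cascade", n = 2)
  rg <- regime("Experiment", list(intervention("dose", "X1", 5, 1)))
  tr <- simulate_network(fix$network, rg, t_end = 5, n_points = 51)
  prefix <- file.path(withr::local_tempdir(), "traj")
  write_trajectory(tr, prefix)
  tr2 <- read_trajectory(prefix)
  expect_equal(tr2$time, tr$time, tolerance = 1e-12)
  expect_equal(tr2$conc, tr$conc, tolerance = 1e-12)
  expect_equal(tr2$vel, tr$vel, tolerance = 1e-12)
  expect_equal(tr2$regime_label, "Experiment")
  expect_equal(tr2$settings$rtol, tr$settings$rtol)
})

test_that("simulation inputs are validated", {
  net <- make_fixture("decay")$network
  expect_error(simulate_network(net, t_end = 0), "t_end")
  expect_error(simulate_network(net, n_points = 1), "n_points")
  expect_error(simulate_network(net, regime("E", list(
    intervention("dose", "nope", 1, 0)))), "unknown species")
})
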