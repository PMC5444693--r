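test_that("doses resolve through the catalogue with paper-patterned values", {
  fix <- make_fixture("receptor_inhibitor")
  ctl <- fixture_catalogue(fix, name = "pertuzumab", dosage = 30)
  d30 <- make_dose(ctl, "pertuzumab", 30, time = 0)
  expect_equal(d30$kind, "dose")
  expect_equal(d30$target, "I")
  expect_equal(d30$value, 30)
  expect_equal(d30$time, 0)
  d100 <- make_dose(ctl, "pertuzumab", 100, time = 0)
  expect_equal(d100$value, 100)
  # omitted dosage falls back to the catalogue default
  expect_equal(make_dose(ctl, "pertuzumab")$value, 30)
  expect_error(make_dose(ctl, "nosuchdrug"), "unknown drug")
  expect_error(make_dose(ctl, "pertuzumab", -1), "non-negative")
})

test_that("apply_intervention implements dose/set/scale semantics", {
  conc <- c(PTEN = 8, drug = 0, AKT = 3)
  params <- c(k1 = 0.5, k2 = 2)
  st <- apply_intervention(conc, params,
                           intervention("scale_concentration", "PTEN", 0.5))
  expect_equal(st$conc[["PTEN"]], 4)            # 50% reduction pattern
  st <- apply_intervention(conc, params, intervention("dose", "drug", 30))
  expect_equal(st$conc[["drug"]], 30)
  expect_equal(st$conc[c("PTEN", "AKT")], conc[c("PTEN", "AKT")])
  st <- apply_intervention(conc, params,
                           intervention("set_concentration", "AKT", 1.5))
  expect_equal(st$conc[["AKT"]], 1.5)
  st <- apply_intervention(conc, params, intervention("set_parameter", "k1", 9))
  expect_equal(st$params[["k1"]], 9)
  st <- apply_intervention(conc, params,
                           intervention("scale_parameter", "k2", 0.25))
  expect_equal(st$params[["k2"]], 0.5)
  # identity factor leaves the state untouched
  st <- apply_intervention(conc, params,
                           intervention("scale_parameter", "k1", 1.0))
  expect_identical(st$conc, conc)
  expect_identical(st$params, params)
})

test_that("apply_intervention touches exactly one entry (locality property)", {
  set.seed(42)
  for (i in 1:25) {
    conc <- stats::setNames(runif(6, 0, 10), paste0("s", 1:6))
    params <- stats::setNames(runif(4, 0.1, 2), paste0("k", 1:4))
    kind <- sample(c("dose", "set_concentration", "scale_concentration",
                     "set_parameter", "scale_parameter"), 1)
    conc_kind <- kind %in% c("dose", "set_concentration", "scale_concentration")
    target <- if (conc_kind) sample(names(conc), 1) else sample(names(params), 1)
    iv <- intervention(kind, target, runif(1, 0, 3), runif(1, 0, 10))
    st <- apply_intervention(conc, params, iv)
    dc <- which(st$conc != conc)
    dp <- which(st$params != params)
    expect_lte(length(dc) + length(dp), 1L)
    if (length(dc)) expect_equal(names(conc)[dc], target)
    if (length(dp)) expect_equal(names(params)[dp], target)
  }
})

test_that("scale factors compose multiplicatively at the same instant", {
  conc <- c(A = 7); params <- numeric()
  a <- 0.6; b <- 0.3
  st1 <- apply_intervention(conc, params,
                            intervention("scale_concentration", "A", a))
  st1 <- apply_intervention(st1$conc, st1$params,
                            intervention("scale_concentration", "A", b))
  st2 <- apply_intervention(conc, params,
                            intervention("scale_concentration", "A", a * b))
  expect_equal(st1$conc, st2$conc)
})

test_that("validate_regime sorts, checks targets and rejects out-of-range times", {
  net <- make_fixture("receptor_inhibitor")$network
  ivs <- list(intervention("dose", "I", 10, 5),
              intervention("scale_concentration", "R3", 0.5, 0),
              intervention("dose", "I", 20, 5))
  rg <- validate_regime(regime("E", ivs), net, t_end = 10)
  expect_equal(vapply(rg$interventions, `[[`, 0, "time"), c(0, 5, 5))
  # stable tie order: the 10 nM dose declared first stays first
  expect_equal(vapply(rg$interventions, `[[`, 0, "value")[2:3], c(10, 20))

  expect_silent(validate_regime(regime("Control"), net, 10))
  expect_error(validate_regime(
    regime("E", list(intervention("dose", "ghost", 1, 0))), net, 10),
    "unknown species")
  expect_error(validate_regime(
    regime("E", list(intervention("set_parameter", "nok", 1, 0))), net, 10),
    "unknown parameter")
  expect_error(validate_regime(
    regime("E", list(intervention("dose", "I", 1, 20))), net, 10),
    "beyond t_end")
})

test_that("identity-only regimes reproduce the untreated trajectory", {
  net <- make_fixture("reversible_pair")$network
  rg <- regime("E", list(intervention("scale_concentration", "A", 1, 2),
                         intervention("scale_parameter", "kf", 1, 4)))
  t0 <- simulate_network(net, regime(), t_end = 8, n_points = 81)
  t1 <- simulate_network(net, rg, t_end = 8, n_points = 81)
  # restarting the integrator at the no-op discontinuities perturbs the step
  # sequence, so agreement is at the global-error level, not bitwise
  expect_equal(t1$conc, t0$conc, tolerance = 1e-6)
})

test_that("regimes round-trip through the YAML specification format", {
  rg <- regime("Experiment",
               list(intervention("dose", "I", 30, 0),
                    intervention("scale_concentration", "P", 0.5, 0),
                    intervention("dose", "I", 100, 5)))
  p <- withr::local_tempfile(fileext = ".yaml")
  write_regime(rg, p)
  rg2 <- read_regime(p)
  expect_equal(rg2$label, rg$label)
  expect_equal(length(rg2$interventions), 3L)
  for (i in 1:3)
    expect_equal(unclass(rg2$interventions[[i]]), unclass(rg$interventions[[i]]))
})

test_that("regime files can name catalogue drugs", {
  fix <- make_fixture("receptor_inhibitor")
  ctl <- fixture_catalogue(fix, name = "pertuzumab", dosage = 30)
  p <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("label: Experiment",
               "interventions:",
               "- drug: pertuzumab",
               "  time: 0"), p)
  rg <- read_regime(p, ctl)
  expect_equal(rg$interventions[[1]]$target, "I")
  expect_equal(rg$interventions[[1]]$value, 30)
  expect_error(read_regime(p), "no catalogue")
})
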