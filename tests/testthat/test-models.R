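test_that("demo models are at rest without stimulus", {
  for (m in list(demo_steady, demo_osc)) {
    expect_lt(max(abs(kin_rhs(m, m$initial_state, u = 0))), 1e-9)
    tr <- simulate_model(m, sampling_spec(m$default_horizon_h, 6),
                         stimulus = 0, outputs = "all")
    init <- m$initial_state
    pos <- init > 0
    drift <- abs(sweep(tr$values[, pos, drop = FALSE], 2, init[pos]))
    expect_lt(max(sweep(drift, 2, init[pos], "/")), 1e-6)
    expect_lt(max(abs(tr$values[, !pos, drop = FALSE])), 1e-8)
  }
})

test_that("transcription-factor moiety is conserved along both demo models", {
  tr <- simulate_model(demo_steady, sampling_spec(10, 6), outputs = "all")
  tot <- stat_moiety(tr$values)
  expect_lt(max(abs(tot - tot[1]) / tot[1]), 1e-6)

  tr <- simulate_model(demo_osc, sampling_spec(15, 6), outputs = "all")
  tot <- nfkb_moiety(tr$values)
  expect_lt(max(abs(tot - tot[1]) / tot[1]), 1e-6)
})

test_that("steady demo outputs have the designed qualitative shape", {
  tr <- simulate_model(demo_steady, sampling_spec(10, 60))
  dimn <- tr$values[, "DimN"]
  # exactly one interior maximum, relaxing to a nonzero steady state
  expect_identical(sum(diff(sign(diff(dimn))) == -2), 1L)
  expect_gt(dimn[length(dimn)], 1)
  expect_gt(max(dimn), dimn[length(dimn)])
  # inhibitor rises monotonically to a plateau
  socs <- tr$values[, "SOCS"]
  expect_true(all(diff(socs) > -1e-9))
  n <- length(socs)
  expect_lt(abs(socs[n] - socs[n - 60]) / socs[n], 1e-3)
})

test_that("oscillator demo sustains at least three complete peak-pairs in 15 h", {
  tr <- simulate_model(demo_osc, sampling_spec(15, 60))
  f <- profile_oscillation(tr)
  expect_true(f$defined)
  expect_gte(f$N, 3L)
  # detected peak types alternate
  pk <- detect_peaks(tr)
  expect_true(all(pk$type[-1] != pk$type[-nrow(pk)]))
})

test_that("apply_perturbation changes exactly one number", {
  m <- demo_steady
  p10 <- apply_perturbation(m, perturbation("rate_up", "r_dim", 10))
  expect_identical(p10$rate_constants[["r_dim"]],
                   10 * m$rate_constants[["r_dim"]])
  others <- setdiff(m$rate_constant_names, "r_dim")
  expect_identical(p10$rate_constants[others], m$rate_constants[others])
  expect_identical(p10$initial_state, m$initial_state)

  ident <- apply_perturbation(m, perturbation("rate_up", "r_dim", 1))
  expect_identical(ident$rate_constants, m$rate_constants)

  pd <- apply_perturbation(m, perturbation("molecule_down", "PP", 0.01))
  expect_identical(pd$initial_state[["PP"]], 0.01 * m$initial_state[["PP"]])
  expect_identical(pd$rate_constants, m$rate_constants)
})

test_that("perturbations compose multiplicatively on the same target", {
  m <- demo_osc
  for (case in list(c("rate_up", "r_lib"), c("molecule_up", "NIc"))) {
    two <- apply_perturbation(
      apply_perturbation(m, perturbation(case[1], case[2], 5)),
      perturbation(case[1], case[2], 4))
    one <- apply_perturbation(m, perturbation(case[1], case[2], 20))
    expect_identical(two$rate_constants, one$rate_constants)
    expect_identical(two$initial_state, one$initial_state)
  }
})

test_that("invalid perturbations are rejected with informative errors", {
  expect_error(apply_perturbation(demo_steady,
                                  perturbation("rate_up", "nope", 2)),
               "unknown rate constant.*nope")
  # SOCS starts at zero: not preexisting
  expect_error(apply_perturbation(demo_steady,
                                  perturbation("molecule_up", "SOCS", 2)),
               "preexisting")
  expect_error(perturbation("rate_up", "r_dim", 0.5), "fold must be > 1")
  expect_error(perturbation("molecule_down", "PP", 2), "fold must be < 1")
  expect_error(perturbation("rate_up", "r_dim", -1), "positive")
})

test_that("preexisting set is exactly the nonzero-initial species", {
  expect_setequal(preexisting_molecules(demo_steady),
                  c("Rec", "STAT3c", "PP"))
  expect_setequal(preexisting_molecules(demo_osc),
                  c("TNFR", "IKKn", "NIc"))
  # and it is the universe used by molecule scans
  expect_setequal(candidate_universe(demo_osc, "molecule_down"),
                  preexisting_molecules(demo_osc))
})

test_that("compiled kernel matches an R-level integration of the same RHS", {
  for (m in list(demo_steady, toy_model())) {
    t_s <- seq(0, 3600, by = 600)
    ref <- deSolve::lsoda(
      unname(m$initial_state), t_s,
      func = function(t, y, parms) list(unname(kin_rhs(m, y))),
      rtol = 1e-10, atol = 1e-12)
    fast <- deSolve::lsoda(
      unname(m$initial_state), t_s,
      func = "kin_derivs", dllname = "kinfault", initfunc = "kin_init",
      parms = kinfault:::pack_network(m), rtol = 1e-10, atol = 1e-12)
    expect_lt(max(abs(ref[, -1] - fast[, -1])),
              1e-6 * max(1, max(abs(ref[, -1]))))
  }
})

test_that("model JSON summary lists states, rates and the preexisting set", {
  js <- jsonlite::fromJSON(model_summary_json(demo_steady))
  expect_identical(names(js$states), demo_steady$state_names)
  expect_identical(names(js$rate_constants), demo_steady$rate_constant_names)
  expect_setequal(js$preexisting, c("Rec", "STAT3c", "PP"))
  expect_false(js$oscillatory)
})
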