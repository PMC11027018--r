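test_that("reference parameters hit the healthy-human baseline targets", {
  b <- test_init$baseline
  expect_gt(b[["MAP"]], 90); expect_lt(b[["MAP"]], 96)
  expect_equal(b[["GFR"]], 120, tolerance = 0.05)
  expect_equal(b[["RBF"]], 1.1, tolerance = 0.05)
  expect_gt(b[["FENa"]], 0.3); expect_lt(b[["FENa"]], 1.0)
  ## exact equilibrium at initialization
  a <- etsim:::model_algebra(0, test_init$state0, test_init$parms)
  expect_lt(max(abs(a$dy[1:15])), 1e-8)
})

test_that("steady-state initialization balances sodium excretion to intake", {
  for (na in c(100, 200, 300)) {
    init <- steady_state_initialize(test_cfg, Na_intake = na)
    expect_equal(init$baseline[["UNaV"]], na / 1440, tolerance = 1e-10)
  }
  ## an open-loop steady state (no TGF/RAAS/ANP feedback) also exists
  cfg0 <- et_config(overrides = list(feedback = list(
    G_tgf = 0, G_myo = 0, G_raas = 0, G_anp = 0)))
  init0 <- steady_state_initialize(cfg0)
  expect_lt(max(abs(etsim:::model_algebra(
    0, init0$state0, init0$parms)$dy[1:15])), 1e-8)
})

test_that("baseline drifts less than 1e-6 over 24 simulated hours", {
  prot <- protocol(events = list(), horizon = 1440, Na_diet = 150)
  tr <- simulate_protocol(prot, list(), test_cfg, times = c(0, 1440))
  for (v in c("MAP", "RBF", "GFR", "FENa", "plasma_Na", "ECF")) {
    expect_lt(abs(tr[[v]][2] / tr[[v]][1] - 1), 1e-6)
  }
})

test_that("sodium is conserved along a perturbed 24-h trajectory", {
  prot <- protocol(events = list(dose_event("ET1", 0.5, "pmol/kg/min",
                                            60, 360)),
                   horizon = 1440, Na_diet = 150)
  tr <- simulate_protocol(prot, refined_truth, test_cfg,
                          times = seq(0, 1440, by = 60))
  n <- nrow(tr)
  na_in <- test_init$parms[etsim:::PIDX[["Na_in"]]] * 1440
  balance <- (tr$Na_amount[n] - tr$Na_amount[1]) -
    (na_in - (tr$cum_UNaV[n] - tr$cum_UNaV[1]))
  expect_lt(abs(balance) / tr$Na_amount[1], 1e-6)
})

test_that("instantaneous resistance and reabsorption perturbations act as expected", {
  st <- test_init$state0
  base <- cardiorenal_derivatives(st, test_init)$outputs
  ## afferent constriction: RBF, GFR and filtration fraction all fall
  r <- cardiorenal_derivatives(st, test_init,
                               multipliers = c(afferent_R = 1.5))$outputs
  expect_lt(r[["RBF"]], base[["RBF"]])
  expect_lt(r[["GFR"]], base[["GFR"]])
  expect_lt(r[["FF"]], base[["FF"]])
  ## raising proximal reabsorption lowers FELi and sodium excretion
  pt <- cardiorenal_derivatives(st, test_init,
                                multipliers = c(PT_Na_reabsorption = 1.02))
  expect_lt(pt$outputs[["FELi"]], base[["FELi"]])
  expect_lt(pt$outputs[["UNaV"]], base[["UNaV"]])
  expect_equal(pt$outputs[["RBF"]], base[["RBF"]], tolerance = 1e-12)
  ## monotonicity: preglomerular constriction strictly decreases RBF
  rbf <- vapply(c(1, 1.2, 1.5, 2, 3), function(f)
    cardiorenal_derivatives(st, test_init,
                            multipliers = c(preafferent_R = f))$outputs[["RBF"]],
    0)
  expect_true(all(diff(rbf) < 0))
  ## all-ones multipliers leave the model at its exact baseline
  same <- cardiorenal_derivatives(
    st, test_init, multipliers = setNames(rep(1, 8), ET_TARGETS))
  expect_identical(same$outputs, base)
  expect_error(cardiorenal_derivatives(st, test_init,
                                       multipliers = c(foo = 2)),
               "unknown effect target")
})

test_that("derived outputs match hand arithmetic and their identities", {
  ## FENa = UNaV / (GFR * plasma_Na): 0.1 / (0.120 * 140) = 0.595 %
  expect_equal(100 * 0.1 / (120 / 1000 * 140), 0.595, tolerance = 1e-3)
  b <- test_init$baseline
  expect_equal(b[["FELi"]], 30, tolerance = 1e-9)       # 1 - 0.70
  expect_equal(b[["RVR"]], b[["MAP"]] / b[["RBF"]], tolerance = 1e-12)
  expect_equal(93 / 1.1, 84.5, tolerance = 1e-3)
  ## along a dosed trajectory: RVR = MAP/RBF, RBF = RPF/(1 - hct),
  ## 0 <= FENa <= FELi <= 100
  prot <- build_bohm_protocol("BQ788")
  tr <- simulate_protocol(prot, refined_truth, test_cfg,
                          times = seq(0, 60, by = 5))
  expect_equal(tr$RVR, tr$MAP / tr$RBF, tolerance = 1e-9)
  expect_equal(tr$RBF, tr$RPF / (1 - test_cfg$subject$hematocrit),
               tolerance = 1e-12)
  expect_true(all(tr$FENa >= 0 & tr$FENa <= 100))
  expect_true(all(tr$FELi >= 0 & tr$FELi <= 100))
  expect_true(all(tr$FELi >= tr$FENa))
  ## compute_derived reproduces the stored outputs from raw states
  cd <- compute_derived(tr)
  expect_equal(cd$GFR, tr$GFR, tolerance = 1e-12)
  expect_equal(cd$FENa, tr$FENa, tolerance = 1e-12)
})

test_that("autoregulation buffers GFR against a pressure step only when enabled", {
  step_gfr <- function(cfg) {
    init <- steady_state_initialize(cfg)
    p <- init$parms
    p[etsim:::PIDX[["CO0"]]] <- p[etsim:::PIDX[["CO0"]]] *
      (init$baseline[["MAP"]] + 10) / init$baseline[["MAP"]]
    y <- deSolve::ode(y = init$state0, times = c(0, 120), func = "derivs",
                      parms = p, dllname = "etsim", initfunc = "initmod",
                      nout = 16, outnames = etsim:::OUTPUT_NAMES)
    unname(y[2, "GFR"] / init$baseline[["GFR"]] - 1)
  }
  with_fb <- step_gfr(test_cfg)
  without <- step_gfr(et_config(overrides = list(feedback = list(
    G_tgf = 0, G_myo = 0))))
  expect_lt(abs(with_fb), 0.10)
  expect_gt(abs(without), abs(with_fb))
})

test_that("plasma sodium stays in the physiological band under water loading", {
  tr <- simulate_protocol(build_rabelink_protocol(), refined_truth, test_cfg)
  expect_true(all(tr$plasma_Na > 120 & tr$plasma_Na < 160))
  expect_true(all(tr$ECF > 0 & tr$blood_volume > 0))
})
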