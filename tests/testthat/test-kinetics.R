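test_that("baseline occupancy satisfies the internalization-equilibrium balance", {
  k <- test_cfg$kinetics
  occ <- baseline_occupancy(test_cfg)
  ## algebraic root-check: kon * free * (R_tot - bound) = (koff + k_int) * bound
  chk <- function(free, bound, R, kon, koff, kint)
    expect_equal(kon * free * (R - bound), (koff + kint) * bound,
                 tolerance = 1e-8)
  chk(occ[["ET1_tissue"]], occ[["bound_A_tissue"]], k$R_A_tissue,
      k$kon_A, k$koff_A, k$k_int_A)
  chk(occ[["ET1_tissue"]], occ[["bound_B_tissue"]], k$R_B_tissue,
      k$kon_B, k$koff_B, k$k_int_B)
  chk(occ[["ET1_plasma"]], occ[["bound_A_plasma"]], k$R_A_plasma,
      k$kon_A, k$koff_A, k$k_int_A)
  chk(occ[["ET1_plasma"]], occ[["bound_B_plasma"]], k$R_B_plasma,
      k$kon_B, k$koff_B, k$k_int_B)
  ## physiological anchor of the reference kinetics
  expect_equal(occ[["ET1_plasma"]], 2, tolerance = 1e-3)
})

test_that("zero production gives zero occupancy; ET_B occupancy dominates in tissue", {
  cfg0 <- et_config(overrides = list(kinetics = list(
    bigET1_production_rate = 1e-12)))  # validator requires > 0
  cfg0$kinetics$bigET1_production_rate <- 0
  occ0 <- baseline_occupancy(cfg0)
  expect_identical(unname(occ0), rep(0, 7))
  ## monotonicity of the binding isotherm: R_B_total > R_A_total and
  ## Kd_B <= Kd_A in tissue imply higher ET_B occupancy
  k <- test_cfg$kinetics
  expect_gt(k$R_B_tissue, k$R_A_tissue)
  expect_lte(k$koff_B / k$kon_B, k$koff_A / k$kon_A)
  occ <- baseline_occupancy(test_cfg)
  expect_gt(occ[["bound_B_tissue"]], occ[["bound_A_tissue"]])
})

test_that("derivatives vanish at the steady state and reject invalid input", {
  st <- test_init$state0[1:8]
  d <- et1_derivatives(st, test_cfg)
  expect_lt(max(abs(d)), 1e-8)
  bad <- st; bad[["ET1_plasma"]] <- -1
  expect_error(et1_derivatives(bad, test_cfg), "negative")
  expect_error(et1_derivatives(st, test_cfg,
                               infusion_rates = list(insulin = 5)),
               "unknown infused agent")
  expect_error(et1_derivatives(st, test_cfg,
                               infusion_rates = list(ET1 = -3)),
               ">= 0")
  over <- st; over[["bound_A_tissue"]] <- test_cfg$kinetics$R_A_tissue + 1
  expect_error(et1_derivatives(over, test_cfg), "exceeds total receptor")
})

test_that("kinetic derivatives conserve ET-1 mass", {
  k <- test_cfg$kinetics
  st <- test_init$state0[1:8] * c(1.3, 0.8, 1.5, 0.9, 1.1, 0.7, 1.2, 0)
  inf <- list(ET1 = 12, bigET1 = 5)
  d <- et1_derivatives(st, test_cfg, infusion_rates = inf)
  Vt <- k$V_tissue; Vp <- k$V_plasma
  dtotal <- (d[["bigET1_tissue"]] + d[["ET1_tissue"]] +
             d[["bound_A_tissue"]] + d[["bound_B_tissue"]]) * Vt +
    (d[["ET1_plasma"]] + d[["bound_A_plasma"]] + d[["bound_B_plasma"]]) * Vp
  production <- k$bigET1_production_rate + inf$ET1 + inf$bigET1
  losses <- (k$k_int_A * st[["bound_A_tissue"]] +
             k$k_int_B * st[["bound_B_tissue"]]) * Vt +
    (k$k_int_A * st[["bound_A_plasma"]] +
     k$k_int_B * st[["bound_B_plasma"]]) * Vp +
    k$k_cl_plasma * st[["ET1_plasma"]] * Vp
  expect_equal(dtotal, production - losses, tolerance = 1e-10)
})

test_that("near-irreversible ET_B binding rises monotonically toward its cap", {
  cfg <- et_config(overrides = list(kinetics = list(koff_B = 1e-9)))
  prot <- protocol(events = list(dose_event("ET1", 4, "pmol/kg/min", 0, 120)),
                   horizon = 120)
  tr <- simulate_et1(cfg, prot, t_grid = seq(0, 120, by = 2))
  bb <- tr$bound_B_plasma
  expect_true(all(diff(bb) > -1e-6 * max(bb)))
  expect_true(all(bb <= cfg$kinetics$R_B_plasma + 1e-6))
})

test_that("ET_B blockade raises free plasma ET-1 above baseline", {
  prot <- protocol(events = list(dose_event("BQ788", 4, "nmol/kg/min",
                                            0, 180)),
                   horizon = 180)
  tr <- simulate_et1(test_cfg, prot, t_grid = seq(0, 180, by = 5))
  expect_gt(tr$ET1_plasma[tr$time == 180], 2 * tr$ET1_plasma[1])
})

test_that("doubling plasma volume halves the early concentration increment", {
  prot <- protocol(events = list(dose_event("ET1", 4, "pmol/kg/min", 0, 10)),
                   horizon = 10)
  early <- c(0.25, 0.5)
  tr1 <- simulate_et1(test_cfg, prot, t_grid = early)
  cfg2 <- et_config(overrides = list(kinetics = list(
    V_plasma = 2 * test_cfg$kinetics$V_plasma)))
  tr2 <- simulate_et1(cfg2, prot, t_grid = early)
  d1 <- tr1$ET1_plasma[tr1$time == 0.5] - tr1$ET1_plasma[1]
  d2 <- tr2$ET1_plasma[tr2$time == 0.5] - tr2$ET1_plasma[1]
  expect_equal(d2 / d1, 0.5, tolerance = 0.05)
})
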