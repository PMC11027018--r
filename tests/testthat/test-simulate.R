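test_that("an empty protocol yields a flat trajectory at baseline", {
  prot <- protocol(events = list(), horizon = 240)
  tr <- simulate_protocol(prot, refined_truth, test_cfg,
                          times = seq(0, 240, by = 30))
  for (v in c("plasma_ET1", "MAP", "RBF", "GFR", "urine_flow"))
    expect_lt(diff(range(tr[[v]])) / tr[[v]][1], 1e-7)
})

test_that("plasma ET-1 rises under infusion and decays back after stop", {
  prot <- protocol(events = list(dose_event("ET1", 0.2, "pmol/kg/min",
                                            0, 60)),
                   horizon = 240)
  tr <- simulate_protocol(prot, list(), test_cfg,
                          times = c(0, 30, 60, 90, 240))
  et1 <- tr$plasma_ET1
  expect_gt(et1[tr$time == 60], et1[1] * 1.1)
  expect_lt(et1[tr$time == 90], et1[tr$time == 60])
  expect_equal(et1[tr$time == 240], et1[1], tolerance = 1e-3)
})

test_that("compiled and R reference solvers agree on a three-dose protocol", {
  tt <- seq(0, 225, by = 15)
  tc <- simulate_protocol(build_rabelink_protocol(), refined_truth,
                          test_cfg, times = tt)
  tr <- simulate_protocol(build_rabelink_protocol(), refined_truth,
                          test_cfg, times = tt, solver = "R",
                          rtol = 1e-9, atol = 1e-12)
  for (v in c("plasma_ET1", "bound_A_tissue", "MAP", "RBF", "GFR",
              "UNaV", "FELi")) {
    expect_lt(max(abs(tc[[v]] / tr[[v]] - 1)), 1e-4)
  }
})

test_that("cumulative trackers close the ET-1 mass balance over 6 h", {
  prot <- protocol(events = list(
    dose_event("ET1", 0.4, "pmol/kg/min", 30, 120),
    dose_event("ET1", 0.8, "pmol/kg/min", 180, 240)),
    horizon = 360)
  tr <- simulate_protocol(prot, refined_truth, test_cfg,
                          times = seq(0, 360, by = 10))
  k <- test_cfg$kinetics
  pools <- function(r)
    (r$bigET1_tissue + r$ET1_tissue + r$bound_A_tissue +
     r$bound_B_tissue) * k$V_tissue +
    (r$ET1_plasma + r$bound_A_plasma + r$bound_B_plasma) * k$V_plasma
  n <- nrow(tr)
  lhs <- pools(tr[n, ]) - pools(tr[1, ]) + tr$cum_et1_out[n]
  rhs <- tr$cum_et1_in[n]
  expect_lt(abs(lhs / rhs - 1), 1e-6)
})

test_that("trajectories are non-negative and continuous across dose switches", {
  tr <- simulate_protocol(build_bohm_protocol("BQ788"), refined_truth,
                          test_cfg, times = seq(0, 60, by = 0.5))
  conc <- as.matrix(tr[, etsim:::STATE_NAMES[1:8]])
  expect_true(min(conc) >= 0)
  ## states stay continuous across the dose on/off boundaries (15, 30,
  ## 50 min): per half-minute changes bounded well below the full range
  ## even while the 4 pmol/kg/min ET-1 infusion drives fast kinetics
  for (v in c("plasma_ET1", "bound_B_plasma", "MAP")) {
    steps <- abs(diff(tr[[v]]))
    expect_lt(max(steps) / diff(range(tr[[v]])), 0.5)
    expect_true(all(is.finite(tr[[v]])))
  }
  expect_error(simulate_protocol(build_bohm_protocol("saline"),
                                 refined_truth, test_cfg, times = 100),
               "exceed the protocol horizon")
})

test_that("the ET_B-antagonist paradox chain holds directionally", {
  ## ET_B blockade raises free ET-1, raises ET_A-bound complex (tissue and
  ## plasma), lowers ET_B-bound complex, and raises SVR and MAP
  prot <- protocol(events = list(dose_event("BQ788", 4, "nmol/kg/min",
                                            0, 60)),
                   horizon = 120)
  tr <- simulate_protocol(prot, refined_truth, test_cfg,
                          times = c(0, 60, 120))
  late <- nrow(tr)
  expect_gt(tr$plasma_ET1[late], tr$plasma_ET1[1])
  expect_gt(tr$bound_A_plasma[late], tr$bound_A_plasma[1])
  expect_gt(tr$bound_A_tissue[late], tr$bound_A_tissue[1])
  expect_lt(tr$bound_B_plasma[late], tr$bound_B_plasma[1])
  expect_gt(tr$SVR[late], tr$SVR[1])
  expect_gt(tr$MAP[late], tr$MAP[1])
  expect_gt(tr$RVR[late], tr$RVR[1])
})
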