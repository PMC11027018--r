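MM_ET1 <- 2491.9

test_that("dose conversions reproduce the printed clinical equivalences", {
  ## 0.5 ng/kg/min ET-1 is 0.2 pmol/kg/min (to one decimal place)
  expect_equal(round(convert_dose(0.5, "ng/kg/min", "pmol/kg/min",
                                  molar_mass = MM_ET1), 1), 0.2)
  expect_equal(round(convert_dose(1.0, "ng/kg/min", "pmol/kg/min",
                                  molar_mass = MM_ET1), 1), 0.4)
  expect_equal(round(convert_dose(2.0, "ng/kg/min", "pmol/kg/min",
                                  molar_mass = MM_ET1), 1), 0.8)
  ## 4 pmol/kg/min ET-1 is 10 ng/kg/min (to the nearest integer)
  expect_equal(round(convert_dose(4, "pmol/kg/min", "ng/kg/min",
                                  molar_mass = MM_ET1)), 10)
})

test_that("dose conversion is exact, identical on identity, and round-trips", {
  expect_identical(convert_dose(3.7, "nmol/kg/min", "nmol/kg/min"), 3.7)
  x <- convert_dose(0.2, "mg/kg/hr", "pmol/kg/min", molar_mass = 500)
  expect_equal(x, 0.2e-3 / 500 * 1e12 / 60, tolerance = 1e-12)
  back <- convert_dose(x, "pmol/kg/min", "mg/kg/hr", molar_mass = 500)
  expect_equal(back, 0.2, tolerance = 1e-12)
  expect_equal(convert_dose(6, "nmol/kg/min", "umol/kg/hr"), 0.36)
  expect_error(convert_dose(1, "ng/kg/min", "mL/kg/min"), "incompatible")
  expect_error(convert_dose(1, "ng/kg/min", "pmol/kg/min"), "molar mass")
  expect_error(convert_dose(1, "smoots/kg/min", "pmol/kg/min"),
               "unsupported")
})

test_that("study protocol builders encode the published designs", {
  rab <- build_rabelink_protocol()
  et1_ev <- Filter(function(e) e$agent == "ET1", rab$events)
  expect_length(et1_ev, 3)
  expect_equal(sum(vapply(et1_ev, function(e) e$t_end - e$t_start, 0)), 180)
  expect_equal(vapply(et1_ev, `[[`, 0, "rate"), c(0.2, 0.4, 0.8))
  expect_equal(rab$Na_diet, 200)
  expect_equal(rab$sample_times$ET1, c(0, 75, 125, 225))
  expect_true(rab$match_urine)

  expect_length(build_bohm_protocol("saline")$events, 1)  # ET-1 only
  bq <- build_bohm_protocol("BQ788")
  expect_identical(bq$antagonist, "BQ788")
  ab <- Filter(function(e) e$agent == "BQ788", bq$events)[[1]]
  expect_equal(c(ab$t_start, ab$t_end, ab$rate), c(0, 15, 4))

  v0 <- build_vml588_protocol(0)
  v2 <- build_vml588_protocol(0.2)
  expect_null(v0$antagonist)
  expect_identical(v2$antagonist, "VML588")
  ## placebo arm shares the full measurement structure
  expect_identical(v0$sample_times, v2$sample_times)
  expect_identical(v0$bins, v2$bins)
  expect_error(build_vml588_protocol(0.3), "must be one of")
})

test_that("protocols serialize losslessly", {
  path <- withr::local_tempfile(fileext = ".yaml")
  for (prot in list(build_rabelink_protocol(), build_bohm_protocol("BQ123"),
                    build_vml588_protocol(0.4))) {
    write_protocol(prot, path)
    back <- read_protocol(path)
    expect_equal(back, prot, tolerance = 1e-12)
  }
})

test_that("protocol construction validates events and schedules", {
  expect_error(dose_event("ET1", -1, "ng/kg/min", 0, 10), ">= 0")
  expect_error(dose_event("ET1", 1, "ng/kg/min", 10, 10), "exceed")
  expect_error(protocol(events = list(dose_event("ET1", 1, "ng/kg/min",
                                                 0, 100)),
                        horizon = 50), "outside")
  expect_error(protocol(horizon = 60,
                        sample_times = list(MAP = c(0, 90))),
               "outside simulation horizon")
  expect_error(protocol(events = list(
    dose_event("BQ123", 1, "nmol/kg/min", 0, 10),
    dose_event("BQ788", 1, "nmol/kg/min", 0, 10)), horizon = 20),
    "at most one antagonist")
})
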