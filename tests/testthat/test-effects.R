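test_that("both link forms return exactly 1 at the baseline occupancy", {
  for (form in c("linear", "sigmoidal")) {
    for (occ0 in c(0.3, 1.6, 5)) {
      m <- mechanism("ET_A", "afferent_R", form, m = 0.7, b = 0.8,
                     ET1R_i0 = occ0)
      expect_identical(effect_value(m, occ0), 1)
    }
  }
})

test_that("linear link evaluates the slope and clamps at zero", {
  m <- mechanism("ET_A", "preafferent_R", "linear", m = 0.288, ET1R_i0 = 1)
  expect_equal(effect_value(m, 3), 1.576)          # 1 + 0.288 * 2
  m1 <- mechanism("ET_A", "preafferent_R", "linear", m = 1, ET1R_i0 = 2.5)
  expect_identical(effect_value(m1, 0.5), 0)       # 1 + 1 * (-2), clamped
  ## piecewise linear with a single kink at the clamp
  occ <- seq(0, 6, by = 0.25)
  e <- effect_value(m1, occ)
  expect_true(all(diff(e, differences = 2)[occ[-(1:2)] > 2] < 1e-12))
  expect_true(all(e >= 0))
})

test_that("sigmoidal link is bounded by 1 -/+ m/2 and needs b > 0", {
  m <- mechanism("ET_B", "efferent_R", "sigmoidal", m = 0.4, b = 0.6,
                 ET1R_i0 = 2)
  expect_equal(effect_value(m, 1e6), 1 - 0.2, tolerance = 1e-12)
  expect_equal(effect_value(m, 0), 1 + 0.4 / (1 + exp(-2 / 0.6)) - 0.2)
  lim0 <- 1 + 0.4 - 0.2   # occupancy -> -Inf limit
  expect_lt(abs(effect_value(m, 0) - lim0), 0.02)
  expect_error(mechanism("ET_B", "efferent_R", "sigmoidal", m = 1, b = 0),
               "b > 0")
  bad <- mechanism("ET_B", "efferent_R", "sigmoidal", m = 1, b = 1,
                   ET1R_i0 = 1)
  bad$b <- -1
  expect_error(effect_value(bad, 2), "b > 0")
})

test_that("link direction follows the sign convention", {
  occ <- c(0.5, 1, 2, 4)
  lin_up <- mechanism("ET_A", "systemic_R", "linear", m = 0.3, ET1R_i0 = 1)
  expect_true(all(diff(effect_value(lin_up, occ)) > 0))
  lin_dn <- mechanism("ET_A", "systemic_R", "linear", m = -0.3, ET1R_i0 = 1)
  expect_true(all(diff(effect_value(lin_dn, occ)) < 0))
  ## as implemented, the sigmoid decreases with occupancy for m > 0; the
  ## sign of m carries direction
  sig <- mechanism("ET_A", "systemic_R", "sigmoidal", m = 0.3, b = 1,
                   ET1R_i0 = 1)
  expect_true(all(diff(effect_value(sig, occ)) < 0))
  sig$m <- -0.3
  expect_true(all(diff(effect_value(sig, occ)) > 0))
})

test_that("apply_effects composes multiplicatively and order-independently", {
  occ <- c(bound_A_tissue = 2, bound_B_tissue = 6, bound_A_plasma = 1,
           bound_B_plasma = 3)
  ea <- mechanism("ET_A", "efferent_R", "linear", m = 0.2, ET1R_i0 = 1)
  eb <- mechanism("ET_B", "efferent_R", "linear", m = -0.05, ET1R_i0 = 4)
  single_a <- apply_effects(list(ea), occ)[["efferent_R"]]
  single_b <- apply_effects(list(eb), occ)[["efferent_R"]]
  both <- apply_effects(list(ea, eb), occ)[["efferent_R"]]
  expect_equal(both, single_a * single_b)
  expect_gt(both, min(single_a, single_b))
  expect_lt(both, max(single_a, single_b))
  ## permutation invariance over a larger set
  mechs <- mechanism_preset("refined")
  mechs <- anchor_mechanisms(mechs, test_init$occ0)
  for (perm in list(7:1, c(3, 1, 7, 5, 2, 6, 4))) {
    expect_identical(apply_effects(mechs, occ), apply_effects(mechs[perm], occ))
  }
  ## untargeted parameters stay at 1; empty list is all-ones
  e0 <- apply_effects(list(), occ)
  expect_identical(unname(e0), rep(1, 8))
  expect_identical(names(e0), ET_TARGETS)
})

test_that("duplicate (receptor, target) pairs are rejected", {
  occ <- c(bound_A_tissue = 2, bound_B_tissue = 6, bound_A_plasma = 1,
           bound_B_plasma = 3)
  dup <- list(mechanism("ET_A", "efferent_R", m = 0.1, ET1R_i0 = 1),
              mechanism("ET_A", "efferent_R", m = 0.2, ET1R_i0 = 1))
  expect_error(apply_effects(dup, occ), "duplicate")
})

test_that("candidate set covers both receptors on all eight targets", {
  cands <- candidate_set()
  keys <- vapply(cands, function(m) paste(m$receptor, m$target), "")
  expect_length(keys, 16)
  expect_false(anyDuplicated(keys) > 0)
  for (tg in c("PT_Na_reabsorption", "CD_Na_reabsorption",
               "venous_capacitance", "venous_compliance"))
    expect_true(paste("ET_B", tg) %in% keys)
  expect_setequal(attr(cands, "forms"), c("linear", "sigmoidal"))
})

test_that("calibrated presets anchor to baseline occupancies with E = 1", {
  mechs <- anchor_mechanisms(mechanism_preset("refined"), test_init$occ0)
  e <- apply_effects(mechs, test_init$occ0)
  expect_equal(unname(e), rep(1, 8), tolerance = 1e-12)
  expect_length(mechs, 7)
  expect_true(all(vapply(mechs, `[[`, "", "form") == "linear"))
})
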