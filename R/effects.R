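## Receptor-occupancy -> effect link functions and mechanism bookkeeping.

#' @rdname mechanism
#' @export
ET_TARGETS <- c("preafferent_R", "afferent_R", "efferent_R", "systemic_R",
                "PT_Na_reabsorption", "CD_Na_reabsorption",
                "venous_capacitance", "venous_compliance")

#' @rdname mechanism
#' @export
ET_RECEPTORS <- c("ET_A", "ET_B")

## Targets read their occupancy from the tissue compartment (renal and
## tubular effects) or the plasma compartment (systemic vascular and venous
## effects).
TARGET_COMPARTMENT <- c(preafferent_R = "tissue", afferent_R = "tissue",
                        efferent_R = "tissue", systemic_R = "plasma",
                        PT_Na_reabsorption = "tissue",
                        CD_Na_reabsorption = "tissue",
                        venous_capacitance = "plasma",
                        venous_compliance = "plasma")

#' Define a candidate ET-1 effect mechanism
#'
#' A mechanism is one arm linking the concentration of ET-1 bound to one
#' receptor (its occupancy, pM) to a multiplicative effect on one
#' physiological target parameter. The effect is 1 at the baseline occupancy
#' `ET1R_i0` and scales with the slope `m`; the sigmoidal form additionally
#' has a steepness `b` (pM).
#'
#' @param receptor `"ET_A"` or `"ET_B"`.
#' @param target One of the eight target parameters in `ET_TARGETS`.
#' @param form `"linear"` or `"sigmoidal"`.
#' @param m Slope (per pM of occupancy change; sign carries direction).
#' @param b Steepness (pM); required positive for the sigmoidal form.
#' @param ET1R_i0 Baseline bound concentration (pM). `NA` means "fill from
#'   the model's no-dose steady state" when the mechanism is used in a
#'   simulation.
#' @return A list of class `et_mechanism`.
#' @examples
#' mechanism("ET_A", "preafferent_R", m = 0.288)
#' @export
mechanism <- function(receptor, target, form = c("linear", "sigmoidal"),
                      m = 0, b = 1, ET1R_i0 = NA_real_) {
  receptor <- match.arg(receptor, ET_RECEPTORS)
  target <- match.arg(target, ET_TARGETS)
  form <- match.arg(form)
  if (form == "sigmoidal" && (!is.finite(b) || b <= 0))
    stop("sigmoidal form requires steepness b > 0")
  if (!is.na(ET1R_i0) && ET1R_i0 < 0) stop("ET1R_i0 must be >= 0")
  structure(list(receptor = receptor, target = target, form = form,
                 m = m, b = b, ET1R_i0 = ET1R_i0),
            class = "et_mechanism")
}

#' @export
print.et_mechanism <- function(x, ...) {
  cat(sprintf("%s -> %s [%s] m = %g%s (ET1R_i0 = %s pM)\n",
              x$receptor, x$target, x$form, x$m,
              if (x$form == "sigmoidal") sprintf(", b = %g", x$b) else "",
              if (is.na(x$ET1R_i0)) "baseline" else format(x$ET1R_i0)))
  invisible(x)
}

check_mechanisms <- function(mechanisms) {
  if (length(mechanisms) == 0) return(invisible(mechanisms))
  keys <- vapply(mechanisms, function(m) paste(m$receptor, m$target), "")
  if (anyDuplicated(keys))
    stop("duplicate (receptor, target) pair: ", keys[duplicated(keys)][1])
  invisible(mechanisms)
}

#' Occupancy-to-effect link function
#'
#' Evaluates the dimensionless effect multiplier `E` for a mechanism at a
#' given receptor occupancy. Linear form:
#' `E = max(1 + m * (occ - ET1R_i0), 0)` (clamped at zero). Sigmoidal form:
#' `E = 1 + m / (1 + exp((occ - ET1R_i0)/b)) - m/2`, which is bounded in
#' `1 -/+ m/2` and decreases with occupancy for positive `m` (the sign of
#' `m` carries the direction). Both forms return exactly 1 at
#' `occ = ET1R_i0`.
#'
#' @param mech An `et_mechanism` (its `ET1R_i0` must be set).
#' @param occupancy Bound receptor concentration(s), pM, `>= 0`.
#' @return Numeric multiplier(s) `E >= 0`.
#' @examples
#' m <- mechanism("ET_A", "preafferent_R", m = 0.288, ET1R_i0 = 1)
#' effect_value(m, 3)   # 1 + 0.288 * 2 = 1.576
#' @export
effect_value <- function(mech, occupancy) {
  if (any(occupancy < 0)) stop("occupancy must be >= 0")
  occ0 <- mech$ET1R_i0
  if (is.na(occ0)) stop("mechanism has no baseline occupancy (ET1R_i0)")
  if (mech$form == "linear") {
    pmax(1 + mech$m * (occupancy - occ0), 0)
  } else {
    if (mech$b <= 0) stop("sigmoidal form requires b > 0")
    1 + mech$m / (1 + exp((occupancy - occ0) / mech$b)) - mech$m / 2
  }
}

#' Compose mechanisms into per-target effect multipliers
#'
#' Evaluates every mechanism at the occupancy of its receptor in the
#' compartment its target reads from (tissue for renal vascular and tubular
#' targets, plasma for systemic vascular and venous targets) and composes
#' mechanisms sharing a target multiplicatively. Targets with no mechanism
#' get multiplier 1.
#'
#' @param mechanisms List of `et_mechanism` objects (unique
#'   (receptor, target) pairs).
#' @param occupancies Named numeric vector with elements `bound_A_tissue`,
#'   `bound_B_tissue`, `bound_A_plasma`, `bound_B_plasma` (pM).
#' @return Named numeric vector of multipliers over `ET_TARGETS`.
#' @export
apply_effects <- function(mechanisms, occupancies) {
  check_mechanisms(mechanisms)
  mult <- setNames(rep(1, length(ET_TARGETS)), ET_TARGETS)
  for (mech in mechanisms) {
    comp <- TARGET_COMPARTMENT[[mech$target]]
    key <- paste0("bound_", if (mech$receptor == "ET_A") "A" else "B",
                  "_", comp)
    occ <- occupancies[[key]]
    if (is.null(occ) || is.na(occ))
      stop("occupancy ", key, " not available for target ", mech$target)
    mult[mech$target] <- mult[mech$target] * effect_value(mech, occ)
  }
  mult
}

#' Full candidate set of postulated ET-1 mechanisms
#'
#' All combinations of receptor (ET_A, ET_B), the eight target parameters
#' (pre-afferent, afferent, efferent and systemic arterial resistance,
#' proximal-tubule and collecting-duct sodium reabsorption, venous
#' capacitance and compliance) and functional form (linear, sigmoidal),
#' as templates with slope 0.
#'
#' @param forms Functional forms to include.
#' @return List of `et_mechanism` templates (one per receptor/target; the
#'   forms to try are attached as the `forms` attribute consumed by
#'   [forward_select()]).
#' @export
candidate_set <- function(forms = c("linear", "sigmoidal")) {
  cands <- list()
  for (tg in ET_TARGETS) {
    for (rc in ET_RECEPTORS) {
      cands[[length(cands) + 1L]] <- mechanism(rc, tg, "linear", m = 0)
    }
  }
  attr(cands, "forms") <- forms
  cands
}

#' Calibrated mechanism presets
#'
#' The seven-mechanism set identified by the selection procedure, with the
#' slopes of either the initial calibration (fit to the ET-1 ramp and the
#' BQ123/BQ788 antagonist studies) or the refined calibration (the same fit
#' with the VML588 validation study appended to the objective). All arms are
#' linear.
#'
#' @param which `"refined"` (default) or `"initial"`.
#' @return List of `et_mechanism` objects with `ET1R_i0 = NA` (anchored to
#'   the model baseline when simulated).
#' @examples
#' vapply(mechanism_preset("refined"), `[[`, 0, "m")
#' @export
mechanism_preset <- function(which = c("refined", "initial")) {
  which <- match.arg(which)
  slopes <- if (which == "refined") {
    list(c("ET_A", "preafferent_R",      0.288),
         c("ET_A", "PT_Na_reabsorption", 0.0311),
         c("ET_A", "afferent_R",         1.66),
         c("ET_A", "systemic_R",         0.060),
         c("ET_A", "efferent_R",         0.0635),
         c("ET_B", "efferent_R",        -0.0059),
         c("ET_B", "systemic_R",         0.0135))
  } else {
    list(c("ET_A", "preafferent_R",      0.344),
         c("ET_A", "PT_Na_reabsorption", 0.041),
         c("ET_A", "afferent_R",         1.79),
         c("ET_A", "systemic_R",         0.068),
         c("ET_A", "efferent_R",         0.086),
         c("ET_B", "efferent_R",        -0.008),
         c("ET_B", "systemic_R",         0.013))
  }
  lapply(slopes, function(s)
    mechanism(s[[1]], s[[2]], "linear", m = as.numeric(s[[3]])))
}

## Fill ET1R_i0 for mechanisms that have not been anchored yet, from the
## model's baseline occupancies (named as in apply_effects()).
anchor_mechanisms <- function(mechanisms, occ0) {
  lapply(mechanisms, function(mech) {
    if (is.na(mech$ET1R_i0)) {
      comp <- TARGET_COMPARTMENT[[mech$target]]
      key <- paste0("bound_", if (mech$receptor == "ET_A") "A" else "B",
                    "_", comp)
      mech$ET1R_i0 <- occ0[[key]]
    }
    mech
  })
}
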