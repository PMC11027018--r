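## Reduced cardiorenal model: initialization, derivative interface and
## derived outputs. The renal vasculature is a preafferent resistance in
## series with lumped afferent, efferent and peritubular resistances;
## glomerular filtration follows Starling forces with a single-point oncotic
## average; sodium passes four sequential reabsorbing segments; volume and
## pressure close the loop through a linearized venous-return relation.

#' Initialize the coupled model at its no-dose steady state
#'
#' Solves the endothelin kinetics steady state, anchors the feedback
#' setpoints (macula densa sodium delivery, preafferent inlet pressure) at
#' the baseline operating point, and back-solves the collecting-duct sodium
#' reabsorption fraction and the distal water reabsorption fraction so that
#' urinary excretion exactly balances intake. The returned state is an exact
#' equilibrium of the model equations.
#'
#' @param config An `et_config`.
#' @param Na_intake Sodium intake (mmol/day); default from the
#'   configuration.
#' @param water_intake Water intake (mL/min); default from the
#'   configuration.
#' @return A list of class `et_init`: `state0` (named state vector),
#'   `parms` (packed parameter vector with setpoints filled), `baseline`
#'   (named vector of derived outputs at baseline), `occ0` (baseline
#'   receptor occupancies) and `config`.
#' @export
steady_state_initialize <- function(config, Na_intake = NULL,
                                    water_intake = NULL) {
  cr <- config$cardiorenal
  if (is.null(Na_intake)) Na_intake <- cr$Na_intake
  if (is.null(water_intake)) water_intake <- cr$water_intake
  kin0 <- baseline_occupancy(config)
  p <- pack_parms(config)
  i <- PIDX
  p[i["Na_in"]] <- Na_intake / 1440
  p[i["water_in"]] <- water_intake

  ## Baseline hemodynamics at nominal parameters (all multipliers and
  ## feedback states = 1).
  MAP0 <- p[i["CO0"]] * p[i["SVR0"]]
  Rtot0 <- p[i["Rpre0"]] + p[i["Raff0"]] + p[i["Reff0"]] + p[i["Rptc"]]
  RBF0 <- (MAP0 - p[i["Prv"]]) / Rtot0
  Pglom0 <- p[i["Prv"]] + RBF0 * (p[i["Reff0"]] + p[i["Rptc"]])
  RPF0_mL <- 1000 * RBF0 * (1 - p[i["hct"]])
  GFR0 <- p[i["Kf"]] * (Pglom0 - p[i["Pbow"]] - p[i["pi_in"]]) /
    (1 + p[i["Kf"]] * p[i["pi_in"]] / RPF0_mL)
  if (GFR0 <= 0) stop("failed to initialize: non-positive baseline GFR ",
                      "(worst residual: glomerular filtration balance)")
  phiNa0 <- GFR0 / 1000 * p[i["CNa0"]]
  phiMD0 <- phiNa0 * (1 - p[i["etaPT0"]]) * (1 - p[i["etaLoH"]])
  cd_delivery <- phiMD0 * (1 - p[i["etaDCT"]])
  etaCD0 <- 1 - p[i["Na_in"]] / cd_delivery
  if (etaCD0 <= 0 || etaCD0 >= 1)
    stop("failed to initialize: sodium intake incompatible with segmental ",
         "reabsorption (worst residual: collecting-duct sodium balance)")
  distw0 <- GFR0 * (1 - p[i["etaPT0"]]) * p[i["fw_dist"]]
  etaW0 <- 1 - water_intake / distw0
  if (etaW0 <= 0 || etaW0 >= 1)
    stop("failed to initialize: water intake incompatible with distal ",
         "delivery (worst residual: water balance)")
  p[i["etaCD0"]] <- etaCD0
  p[i["etaW0"]] <- etaW0
  p[i["PhiMD0"]] <- phiMD0
  p[i["Paffin0"]] <- MAP0 - RBF0 * p[i["Rpre0"]]

  state0 <- setNames(numeric(N_STATES), STATE_NAMES)
  state0[KINETIC_STATES[1:7]] <- kin0
  state0["ECF"] <- p[i["ECF0"]]
  state0["Na_amount"] <- p[i["CNa0"]] * p[i["ECF0"]]
  state0[c("A_tgf", "A_myo", "A_raas", "A_anp", "A_adh")] <- 1

  a <- model_algebra(0, state0, p)
  resid <- abs(a$dy[1:15])
  if (max(resid) > 1e-6) {
    worst <- STATE_NAMES[which.max(resid)]
    stop("failed to converge to steady state; worst-residual equation: ",
         worst, " (", format(max(resid)), ")")
  }
  structure(list(state0 = state0,
                 parms = p,
                 baseline = setNames(a$out, OUTPUT_NAMES),
                 occ0 = kin0[4:7],
                 config = config),
            class = "et_init")
}

#' Time-derivatives of the cardiorenal state under given effect multipliers
#'
#' Evaluates the reduced cardiorenal model at one state with an explicit
#' set of ET-1 effect multipliers (bypassing the kinetics coupling), as used
#' for resistance-network and segmental-cascade analyses.
#'
#' @param state Named state vector (see [steady_state_initialize()]).
#' @param init An `et_init` object (carries parameters and setpoints).
#' @param multipliers Named numeric vector over [ET_TARGETS] (values `>= 0`,
#'   1 = no effect); missing targets default to 1.
#' @return List with `derivatives` (named, cardiorenal states only) and
#'   `outputs` (named derived outputs).
#' @export
cardiorenal_derivatives <- function(state, init, multipliers = NULL) {
  mult <- setNames(rep(1, length(ET_TARGETS)), ET_TARGETS)
  if (!is.null(multipliers)) {
    bad <- setdiff(names(multipliers), ET_TARGETS)
    if (length(bad)) stop("unknown effect target: ",
                          paste(bad, collapse = ", "))
    if (any(multipliers < 0)) stop("multipliers must be >= 0")
    mult[names(multipliers)] <- multipliers
  }
  p <- init$parms
  ## Encode the multipliers as linear mechanisms acting on a unit occupancy
  ## signal: occ0 = 0, occupancy fixed by the state's bound concentrations
  ## is bypassed by writing E directly through slope m at occupancy 1.
  p <- set_mechanism_block(p, list())
  for (t_i in seq_along(ET_TARGETS)) {
    if (mult[t_i] != 1) {
      base <- MECH_BASE + ((t_i - 1L) * 2L) * 4L
      p[base] <- 1                 # linear form on the ET_A slot
      p[base + 1L] <- mult[t_i] - 1  # E = 1 + m*(occ - occ0)
      p[base + 2L] <- 1
      ## occupancy - occ0 = 1 exactly: anchor one pM below current bound
      comp <- TARGET_COMPARTMENT[[ET_TARGETS[t_i]]]
      occ <- if (comp == "tissue") state[["bound_A_tissue"]]
             else state[["bound_A_plasma"]]
      p[base + 3L] <- occ - 1
    }
  }
  a <- model_algebra(0, state[STATE_NAMES], p)
  list(derivatives = setNames(a$dy[9:15], STATE_NAMES[9:15]),
       outputs = setNames(a$out, OUTPUT_NAMES))
}

#' Derived physiological outputs along a trajectory
#'
#' Recomputes the model outputs (MAP, RBF, RPF, GFR, RVR, SVR, urine flow,
#' sodium excretion, FENa, FELi, ...) from a matrix/data frame of raw state
#' trajectories. `RVR = MAP/RBF` and `RBF = RPF/(1 - hematocrit)` hold as
#' identities; `FELi` equals 100 times one minus the effective proximal
#' fractional reabsorption (lithium as a pure proximal marker). Where GFR is
#' zero, FENa is reported as missing rather than infinite.
#'
#' @param traj A trajectory from [simulate_protocol()], or any data frame
#'   containing `time` and the state columns.
#' @param parms Packed parameter vector; defaults to the one stored on the
#'   trajectory.
#' @return Data frame: `time`, derived outputs, and `plasma_ET1` (pM).
#' @export
compute_derived <- function(traj, parms = attr(traj, "parms")) {
  if (is.null(parms)) stop("no parameter vector available")
  n <- nrow(traj)
  out <- matrix(NA_real_, n, N_OUT, dimnames = list(NULL, OUTPUT_NAMES))
  for (r in seq_len(n)) {
    y <- as.numeric(traj[r, STATE_NAMES])
    out[r, ] <- model_algebra(traj$time[r], y, parms)$out
  }
  res <- data.frame(time = traj$time, out, check.names = FALSE)
  res$FENa[res$GFR <= 0] <- NA_real_
  res$plasma_ET1 <- traj$ET1_plasma
  res
}
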