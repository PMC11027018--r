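## Endothelin-1 kinetics: production, conversion, two-compartment
## distribution, receptor binding with internalization, competitive
## antagonism.

KINETIC_STATES <- STATE_NAMES[1:8]

## Minimal packed-parameter vector for the kinetics subsystem alone.
kinetics_parms <- function(config, antagonist = NULL,
                           infusion_rates = NULL) {
  p <- pack_parms(config, antagonist)
  if (!is.null(infusion_rates)) {
    known <- c("ET1", "bigET1", "antagonist")
    extra <- setdiff(names(infusion_rates), known)
    if (length(extra)) stop("unknown infused agent: ",
                            paste(extra, collapse = ", "))
    if (any(unlist(infusion_rates) < 0)) stop("infusion rates must be >= 0")
    if (!is.null(infusion_rates$ET1))
      p[PIDX["inf_ET1"]] <- infusion_rates$ET1
    if (!is.null(infusion_rates$bigET1))
      p[PIDX["inf_big"]] <- infusion_rates$bigET1
    if (!is.null(infusion_rates$antagonist)) {
      if (is.null(antagonist))
        stop("antagonist infusion given but no antagonist specified")
      p[PIDX["inf_ant"]] <- infusion_rates$antagonist
    }
  }
  p
}

#' Time-derivatives of the ET-1 kinetic state
#'
#' Mass-action kinetics of Big ET-1 production and conversion by ECE,
#' tissue/plasma ET-1 exchange, binding to ET_A and ET_B receptors with
#' internalization of the bound complexes, first-order antagonist
#' pharmacokinetics, and optional non-receptor plasma clearance. Antagonist
#' receptor occupancy is treated as a rapid equilibrium that scales the free
#' receptor available to ET-1 by `1/(1 + C_ant/Kd)`.
#'
#' @param state Named numeric vector with elements `bigET1_tissue`,
#'   `ET1_tissue`, `ET1_plasma`, `bound_A_tissue`, `bound_B_tissue`,
#'   `bound_A_plasma`, `bound_B_plasma`, `antagonist` (all pM, `>= 0`).
#' @param config An `et_config`.
#' @param infusion_rates Named list with any of `ET1`, `bigET1` (pmol/min)
#'   and `antagonist` (pmol/min); unknown agents are rejected.
#' @param antagonist Antagonist specification from [antagonist_spec()], if
#'   one is present.
#' @return Named numeric vector of time-derivatives (pM/min) over the same
#'   eight elements.
#' @export
et1_derivatives <- function(state, config, infusion_rates = NULL,
                            antagonist = NULL) {
  state <- state[KINETIC_STATES]
  if (any(is.na(state))) stop("state must contain all kinetic state fields")
  if (any(state < 0)) stop("negative concentration in input state")
  if (state[["bound_A_tissue"]] > config$kinetics$R_A_tissue ||
      state[["bound_B_tissue"]] > config$kinetics$R_B_tissue ||
      state[["bound_A_plasma"]] > config$kinetics$R_A_plasma ||
      state[["bound_B_plasma"]] > config$kinetics$R_B_plasma)
    stop("bound complex exceeds total receptor density")
  p <- kinetics_parms(config, antagonist, infusion_rates)
  y <- numeric(N_STATES)
  y[1:8] <- as.numeric(state)
  setNames(kinetics_rates(y, p)$dy, KINETIC_STATES)
}

#' Baseline receptor occupancies at the no-dose steady state
#'
#' Solves the kinetics subsystem for its steady state with no infusions by
#' damped Newton iteration on the free tissue and plasma ET-1
#' concentrations (bound complexes satisfy the equilibrium-with-
#' internalization balance `kon*ET1_free*(R_tot - bound) =
#' (koff + k_int)*bound` at that point).
#'
#' @param config An `et_config`.
#' @param tol Convergence tolerance on the amount-balance residuals
#'   (pmol/min).
#' @param max_iter Iteration budget.
#' @return Named numeric vector: `bigET1_tissue`, `ET1_tissue`,
#'   `ET1_plasma`, `bound_A_tissue`, `bound_B_tissue`, `bound_A_plasma`,
#'   `bound_B_plasma` (pM).
#' @export
baseline_occupancy <- function(config, tol = 1e-10, max_iter = 200) {
  k <- config$kinetics
  P <- k$bigET1_production_rate
  if (P == 0) {
    return(setNames(numeric(7), KINETIC_STATES[1:7]))
  }
  Vt <- k$V_tissue; Vp <- k$V_plasma
  KdpA <- (k$koff_A + k$k_int_A) / k$kon_A
  KdpB <- (k$koff_B + k$k_int_B) / k$kon_B
  bnd <- function(R, E, Kd) R * E / (Kd + E)
  dbnd <- function(R, E, Kd) R * Kd / (Kd + E)^2
  resid <- function(x, y) {
    Ft <- P - k$k_tp * Vt * x + k$k_pt * Vp * y -
      (k$k_int_A * bnd(k$R_A_tissue, x, KdpA) +
       k$k_int_B * bnd(k$R_B_tissue, x, KdpB)) * Vt
    Fp <- k$k_tp * Vt * x - k$k_pt * Vp * y -
      (k$k_int_A * bnd(k$R_A_plasma, y, KdpA) +
       k$k_int_B * bnd(k$R_B_plasma, y, KdpB)) * Vp -
      k$k_cl_plasma * y * Vp
    c(Ft, Fp)
  }
  x <- 1; y <- 1
  for (it in seq_len(max_iter)) {
    f <- resid(x, y)
    if (max(abs(f)) < tol) break
    j11 <- -k$k_tp * Vt - (k$k_int_A * dbnd(k$R_A_tissue, x, KdpA) +
                           k$k_int_B * dbnd(k$R_B_tissue, x, KdpB)) * Vt
    j12 <- k$k_pt * Vp
    j21 <- k$k_tp * Vt
    j22 <- -k$k_pt * Vp - (k$k_int_A * dbnd(k$R_A_plasma, y, KdpA) +
                           k$k_int_B * dbnd(k$R_B_plasma, y, KdpB)) * Vp -
      k$k_cl_plasma * Vp
    det <- j11 * j22 - j12 * j21
    dx <- (-f[1] * j22 + f[2] * j12) / det
    dy <- (-f[2] * j11 + f[1] * j21) / det
    step <- 1
    repeat {  # damp to keep concentrations positive
      xn <- x + step * dx; yn <- y + step * dy
      if (xn > 0 && yn > 0) break
      step <- step / 2
      if (step < 1e-12) stop("baseline occupancy: step collapsed")
    }
    x <- xn; y <- yn
    if (it == max_iter)
      stop("no steady state found within iteration budget (residual ",
           format(max(abs(resid(x, y)))), ")")
  }
  c(bigET1_tissue = P / (k$k_ECE * Vt),
    ET1_tissue = x, ET1_plasma = y,
    bound_A_tissue = bnd(k$R_A_tissue, x, KdpA),
    bound_B_tissue = bnd(k$R_B_tissue, x, KdpB),
    bound_A_plasma = bnd(k$R_A_plasma, y, KdpA),
    bound_B_plasma = bnd(k$R_B_plasma, y, KdpB))
}

#' Simulate the ET-1 kinetics subsystem alone
#'
#' Integrates the kinetics states under a dosing protocol, with the
#' cardiorenal model inactive (the coupling is one-way, so the kinetic
#' trajectory is identical to its trajectory in the full model).
#'
#' @param config An `et_config` (its `kinetics` block defines the model).
#' @param protocol An [protocol()] object; dose events outside the
#'   simulation horizon are rejected.
#' @param t_grid Output times (min), starting at 0.
#' @param rtol,atol Solver tolerances.
#' @return Data frame: `time` plus the eight kinetic states (pM).
#' @export
simulate_et1 <- function(config, protocol, t_grid = NULL,
                         rtol = config$solver$rtol,
                         atol = config$solver$atol) {
  traj <- simulate_protocol(protocol, mechanisms = list(), config = config,
                            times = t_grid, rtol = rtol, atol = atol)
  traj[, c("time", KINETIC_STATES)]
}
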