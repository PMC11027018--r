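## Trajectory simulation: piecewise integration across dose on/off times
## with the compiled right-hand side (default) or the R reference RHS.

VAR_COLUMN <- c(ET1 = "plasma_ET1", MAP = "MAP", RBF = "RBF", RPF = "RPF",
                GFR = "GFR", RVR = "RVR", SVR = "SVR",
                urine_flow = "urine_flow", UNaV = "UNaV", FENa = "FENa",
                FELi = "FELi")

## Absolute infusion rate (pmol/min; mL/min for water) for one dose event.
event_rate_abs <- function(ev, config) {
  bw <- config$subject$body_weight_kg
  if (ev$agent == "water") {
    return(convert_dose(ev$rate, ev$units, "mL/kg/min") * bw)
  }
  mm <- if (ev$agent %in% c("ET1", "bigET1")) config$kinetics$molar_mass_ET1
        else config$antagonists[[ev$agent]]$molar_mass
  convert_dose(ev$rate, ev$units, "pmol/kg/min", molar_mass = mm) * bw
}

#' Simulate a dosing protocol with the coupled model
#'
#' Initializes the coupled ET-1 kinetics / cardiorenal model at the
#' protocol's dietary steady state, applies the protocol's infusions and
#' water loading, and integrates piecewise across dose on/off times so the
#' trajectory is piecewise-smooth at those times. Mechanisms with
#' `ET1R_i0 = NA` are anchored at the baseline occupancies, which makes all
#' effect multipliers exactly 1 before dosing.
#'
#' @param protocol An [protocol()] object.
#' @param mechanisms List of [mechanism()] objects (may be empty).
#' @param config An `et_config`.
#' @param init Optional precomputed [steady_state_initialize()] result for
#'   this configuration and the protocol's sodium diet (reused across calls
#'   in fitting loops).
#' @param times Output times (min); `NULL` for the protocol's measurement
#'   times plus a 2-min grid.
#' @param solver `"compiled"` (C right-hand side) or `"R"` (reference
#'   implementation).
#' @param rtol,atol Solver tolerances.
#' @return Data frame of class `et_trajectory`: `time`, the 21 state
#'   columns, the derived outputs and `plasma_ET1`; the packed parameter
#'   vector is attached as attribute `parms`.
#' @export
simulate_protocol <- function(protocol, mechanisms = list(),
                              config = et_config(), init = NULL,
                              times = NULL, solver = c("compiled", "R"),
                              rtol = config$solver$rtol,
                              atol = config$solver$atol) {
  solver <- match.arg(solver)
  if (is.null(init))
    init <- steady_state_initialize(config, Na_intake = protocol$Na_diet)
  mechanisms <- anchor_mechanisms(mechanisms, init$occ0)
  ant <- if (!is.null(protocol$antagonist))
    antagonist_spec(config, protocol$antagonist) else NULL
  p <- init$parms
  if (!is.null(ant)) {
    p[PIDX["ant_KdA"]] <- ant$Kd_A
    p[PIDX["ant_KdB"]] <- ant$Kd_B
    p[PIDX["ant_kel"]] <- log(2) / ant$plasma_halflife
    p[PIDX["ant_Vd"]] <- ant$V_distribution
    p[PIDX["ant_F"]] <- ant$bioavailable_fraction
  }
  p <- set_mechanism_block(p, mechanisms)
  p[PIDX["match_urine"]] <- as.numeric(isTRUE(protocol$match_urine))

  events <- protocol$events
  if (protocol$water_load > 0) {
    dur <- config$protocol_defaults$water_load_duration
    dur <- min(dur, protocol$horizon)
    events <- c(events, list(dose_event(
      "water", protocol$water_load / dur, "mL/kg/min", 0, dur)))
  }
  sched <- unlist(c(protocol$sample_times,
                    lapply(protocol$bins, as.numeric)), use.names = FALSE)
  if (is.null(times)) {
    times <- sort(unique(c(seq(0, protocol$horizon, by = 2),
                           protocol$horizon, sched)))
  } else {
    times <- sort(unique(c(0, times, sched)))
    if (max(times) > protocol$horizon)
      stop("requested times exceed the protocol horizon")
  }
  bounds <- sort(unique(c(0, protocol$horizon,
                          vapply(events, `[[`, 0, "t_start"),
                          vapply(events, `[[`, 0, "t_end"))))
  bounds <- bounds[bounds <= protocol$horizon]
  ## summed absolute infusion rate per dose segment and agent class
  slot_of <- function(a) switch(a, ET1 = 1L, bigET1 = 2L, water = 4L, 3L)
  n_seg <- length(bounds) - 1L
  seg_rates <- matrix(0, n_seg, 4L)
  for (ev in events) {
    j <- slot_of(ev$agent)
    act <- which(bounds[-length(bounds)] >= ev$t_start &
                   bounds[-1] <= ev$t_end)
    seg_rates[act, j] <- seg_rates[act, j] + event_rate_abs(ev, config)
  }

  check_sol <- function(sol, nt) {
    ds <- attr(sol, "istate")
    if ((!is.null(ds) && ds[1] < 0) || nrow(sol) < nt ||
        anyNA(sol[nrow(sol), ]))
      stop("ODE solver failed in protocol '", protocol$label, "'")
  }
  if (solver == "compiled") {
    ## one integrator call per simulation: infusion rates enter as
    ## step-function forcings
    forc <- lapply(1:4, function(j)
      cbind(bounds, c(seg_rates[, j], 0)))
    sol <- deSolve::ode(y = init$state0, times = times, func = "derivs",
                        parms = p, dllname = "etsim", initfunc = "initmod",
                        initforc = "initforc", forcings = forc,
                        fcontrol = list(method = "constant", rule = 2,
                                        f = 0),
                        nout = N_OUT, outnames = OUTPUT_NAMES,
                        rtol = rtol, atol = atol, maxsteps = 2000)
    check_sol(sol, length(times))
    m <- sol
  } else {
    y <- init$state0
    rows <- vector("list", n_seg)
    for (s in seq_len(n_seg)) {
      t0 <- bounds[s]; t1 <- bounds[s + 1L]
      ps <- p
      ps[PIDX[c("inf_ET1", "inf_big", "inf_ant", "inf_water")]] <-
        seg_rates[s, ]
      tt <- sort(unique(c(t0, times[times > t0 & times < t1], t1)))
      sol <- deSolve::ode(y = y, times = tt, func = model_rhs_R,
                          parms = ps, rtol = rtol, atol = atol,
                          maxsteps = 10000)
      check_sol(sol, length(tt))
      y <- sol[nrow(sol), 1L + seq_len(N_STATES)]
      rows[[s]] <- sol[if (s == 1) seq_len(nrow(sol)) else -1, ,
                       drop = FALSE]
    }
    m <- do.call(rbind, rows)
    m <- m[m[, "time"] %in% times, , drop = FALSE]
  }
  colnames(m) <- c("time", STATE_NAMES, OUTPUT_NAMES)
  conc <- m[, STATE_NAMES[1:8], drop = FALSE]
  if (min(conc) < -1e-6)
    stop("negative concentration in simulated trajectory (min ",
         format(min(conc)), ")")
  m[, STATE_NAMES[1:8]] <- pmax(conc, 0)
  traj <- as.data.frame(m)
  traj$FENa[traj$GFR <= 0] <- NA_real_
  traj$plasma_ET1 <- traj$ET1_plasma
  attr(traj, "parms") <- p
  attr(traj, "protocol") <- protocol
  class(traj) <- c("et_trajectory", "data.frame")
  traj
}

## Instantaneous value of an output variable at given times.
sim_value <- function(traj, var, time) {
  col <- VAR_COLUMN[[var]]
  if (is.null(col)) stop("unknown observation variable: ", var)
  idx <- match(time, traj$time)
  if (anyNA(idx))
    return(approx(traj$time, traj[[col]], xout = time)$y)
  traj[[col]][idx]
}

## Interval average of a urine variable over [t0, t1] from the cumulative
## trackers.
bin_average <- function(traj, var, t0, t1) {
  cum <- function(col, at) approx(traj$time, traj[[col]], xout = at)$y
  dt <- t1 - t0
  switch(var,
         urine_flow = (cum("cum_urine", t1) - cum("cum_urine", t0)) / dt,
         UNaV = (cum("cum_UNaV", t1) - cum("cum_UNaV", t0)) / dt,
         FENa = 100 * (cum("cum_UNaV", t1) - cum("cum_UNaV", t0)) /
           (cum("cum_filt_Na", t1) - cum("cum_filt_Na", t0)),
         FELi = 100 * (cum("cum_fePT", t1) - cum("cum_fePT", t0)) / dt,
         stop("no interval average defined for variable: ", var))
}

## Model predictions for every row of an observation table. Simulates each
## (study, arm) once at the required times.
predict_observations <- function(observations, mechanisms = list(),
                                 config = et_config(), inits = NULL,
                                 solver = "compiled", rtol = NULL,
                                 atol = NULL) {
  obs <- observations
  obs$pred <- NA_real_
  groups <- unique(obs[, c("study", "arm")])
  for (g in seq_len(nrow(groups))) {
    study <- groups$study[g]; arm <- groups$arm[g]
    sel <- obs$study == study & obs$arm == arm
    prot <- protocol_for(study, arm)
    init <- if (!is.null(inits)) inits[[as.character(prot$Na_diet)]]
    tr <- simulate_protocol(
      prot, mechanisms, config, init = init,
      times = unique(c(obs$time[sel], obs$t_start[sel])),
      solver = solver,
      rtol = if (is.null(rtol)) config$solver$rtol else rtol,
      atol = if (is.null(atol)) config$solver$atol else atol)
    for (r in which(sel)) {
      obs$pred[r] <- if (is.na(obs$t_start[r]))
        sim_value(tr, obs$variable[r], obs$time[r])
      else bin_average(tr, obs$variable[r], obs$t_start[r], obs$time[r])
    }
  }
  obs
}
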