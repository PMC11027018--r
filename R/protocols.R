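## Clinical dosing protocols and dose-unit conversion.

DOSE_AGENTS <- c("ET1", "bigET1", "BQ123", "BQ788", "VML588", "water")

#' Timed infusion event
#'
#' @param agent One of `"ET1"`, `"bigET1"`, `"BQ123"`, `"BQ788"`,
#'   `"VML588"`, `"water"`.
#' @param rate Infusion rate in `units` (must be `>= 0`).
#' @param units Rate units, e.g. `"ng/kg/min"`, `"pmol/kg/min"`,
#'   `"nmol/kg/min"`, `"mg/kg/hr"`; `"mL/kg/min"` for water.
#' @param t_start,t_end Start/stop times (min), `t_end > t_start`.
#' @return A list of class `et_dose_event`.
#' @export
dose_event <- function(agent, rate, units, t_start, t_end) {
  agent <- match.arg(agent, DOSE_AGENTS)
  if (!is.finite(rate) || rate < 0) stop("rate must be >= 0")
  if (!(t_end > t_start)) stop("t_end must exceed t_start")
  structure(list(agent = agent, rate = rate, units = units,
                 t_start = t_start, t_end = t_end),
            class = "et_dose_event")
}

#' Study protocol
#'
#' A dosing/measurement schedule: infusion events, dietary sodium, an
#' optional oral water load (absorbed at constant rate over
#' `water_load_duration` minutes from t = 0) with an optional
#' drink-to-match-urine-output flag, and per-variable measurement times
#' (instantaneous samples) and collection bins (interval averages, used for
#' urine variables).
#'
#' @param events List of [dose_event()] objects.
#' @param horizon Simulation horizon (min).
#' @param Na_diet Dietary sodium (mmol/day).
#' @param water_load Oral water load (mL/kg) given at t = 0.
#' @param match_urine If `TRUE`, water intake tracks urine output
#'   (maintained water loading).
#' @param sample_times Named list: variable -> instantaneous measurement
#'   times (min).
#' @param bins Named list: variable -> two-column matrix of collection
#'   interval start/end times (min).
#' @param label Protocol label.
#' @return A list of class `et_protocol`.
#' @export
protocol <- function(events = list(), horizon, Na_diet = 150,
                     water_load = 0, match_urine = FALSE,
                     sample_times = list(), bins = list(), label = "") {
  for (ev in events) {
    if (!inherits(ev, "et_dose_event")) stop("events must be dose_event()s")
    if (ev$t_end > horizon || ev$t_start < 0)
      stop("dose event outside [0, horizon]")
  }
  for (v in names(sample_times))
    if (any(sample_times[[v]] < 0 | sample_times[[v]] > horizon))
      stop("measurement times outside simulation horizon")
  for (v in names(bins))
    if (any(bins[[v]] < 0 | bins[[v]] > horizon))
      stop("collection bins outside simulation horizon")
  ants <- unique(vapply(events, `[[`, "", "agent"))
  ants <- intersect(ants, c("BQ123", "BQ788", "VML588"))
  if (length(ants) > 1) stop("at most one antagonist per protocol")
  structure(list(events = events, horizon = horizon, Na_diet = Na_diet,
                 water_load = water_load, match_urine = match_urine,
                 sample_times = sample_times, bins = bins,
                 antagonist = if (length(ants)) ants else NULL,
                 label = label),
            class = "et_protocol")
}

#' @export
print.et_protocol <- function(x, ...) {
  cat(sprintf("Protocol '%s': horizon %g min, Na diet %g mmol/day%s\n",
              x$label, x$horizon, x$Na_diet,
              if (x$water_load > 0)
                sprintf(", water load %g mL/kg%s", x$water_load,
                        if (x$match_urine) " (matched)" else "") else ""))
  for (ev in x$events)
    cat(sprintf("  %s %g %s, t = %g-%g min\n", ev$agent, ev$rate, ev$units,
                ev$t_start, ev$t_end))
  invisible(x)
}

DOSE_MASS_G <- c(g = 1, mg = 1e-3, ug = 1e-6, ng = 1e-9, pg = 1e-12)
DOSE_MOL_PMOL <- c(mol = 1e12, mmol = 1e9, umol = 1e6, nmol = 1e3, pmol = 1)
DOSE_TIME_MIN <- c(min = 1, hr = 60, h = 60, s = 1 / 60)

parse_dose_units <- function(units) {
  parts <- strsplit(units, "/", fixed = TRUE)[[1]]
  if (length(parts) != 3 || parts[2] != "kg")
    stop("unsupported dose units: ", units)
  amount <- parts[1]; tm <- parts[3]
  if (!tm %in% names(DOSE_TIME_MIN)) stop("unsupported time unit: ", tm)
  if (amount %in% names(DOSE_MASS_G)) {
    list(kind = "mass", to_base = DOSE_MASS_G[[amount]],
         per_min = DOSE_TIME_MIN[[tm]])
  } else if (amount %in% names(DOSE_MOL_PMOL)) {
    list(kind = "molar", to_base = DOSE_MOL_PMOL[[amount]],
         per_min = DOSE_TIME_MIN[[tm]])
  } else if (amount == "mL") {
    list(kind = "volume", to_base = 1, per_min = DOSE_TIME_MIN[[tm]])
  } else stop("unsupported amount unit: ", amount)
}

#' Convert an infusion rate between units
#'
#' Exact linear conversion between per-kilogram infusion-rate units
#' (mass-based such as `ng/kg/min` or `mg/kg/hr`, and molar such as
#' `pmol/kg/min` or `nmol/kg/min`). Mass/molar cross-conversion requires the
#' agent's molar mass.
#'
#' @param rate Numeric rate in `from` units.
#' @param from,to Unit strings of the form `"<amount>/kg/<time>"`.
#' @param molar_mass Molar mass (g/mol); needed only across the mass/molar
#'   boundary.
#' @return Rate in `to` units.
#' @examples
#' convert_dose(0.5, "ng/kg/min", "pmol/kg/min", molar_mass = 2491.9)
#' @export
convert_dose <- function(rate, from, to, molar_mass = NULL) {
  uf <- parse_dose_units(from); ut <- parse_dose_units(to)
  if (identical(from, to)) return(rate)
  if (uf$kind == "volume" || ut$kind == "volume") {
    if (uf$kind != ut$kind) stop("incompatible unit pair: ", from, " -> ", to)
    return(rate * uf$to_base / uf$per_min * ut$per_min / ut$to_base)
  }
  ## normalize to pmol/kg/min
  if (uf$kind == "mass") {
    if (is.null(molar_mass)) stop("molar mass required for ", from)
    base <- rate * uf$to_base / molar_mass * 1e12 / uf$per_min
  } else {
    base <- rate * uf$to_base / uf$per_min
  }
  if (ut$kind == "mass") {
    if (is.null(molar_mass)) stop("molar mass required for ", to)
    base * ut$per_min * molar_mass / 1e12 / ut$to_base
  } else {
    base * ut$per_min / ut$to_base
  }
}

#' Clinical study protocols
#'
#' Builders for the three infusion studies the model is calibrated and
#' validated against.
#'
#' `build_rabelink_protocol()`: after equilibration on a 200 mmol/day sodium
#' diet (the model is initialized at that diet's steady state), ET-1 is
#' infused at 0.2, 0.4 and 0.8 pmol/kg/min in consecutive 60-min blocks with
#' a maintained 25 mL/kg oral water load; plasma ET-1 sampled at 0, 75, 125
#' and 225 min, hemodynamics hourly, urine collected in the three infusion
#' hours plus the 180-225 min recovery period.
#'
#' `build_bohm_protocol(arm)`: saline, BQ123 (5 nmol/kg/min, 0-50 min) or
#' BQ788 (4 nmol/kg/min, 0-15 min), each with ET-1 4 pmol/kg/min from 30 to
#' 50 min; plasma ET-1, MAP, RBF and RVR sampled at 0, 15, 30, 40, 50 min.
#'
#' `build_vml588_protocol(dose)`: VML588 at 0 (placebo), 0.05, 0.2 or 0.4
#' mg/kg/hr for the whole study, ET-1 1 pmol/kg/min from 90 to 110 min,
#' maintained diuresis; hemodynamics at 0, 90, 120, 210 min, sodium
#' excretion in 30-min urine bins.
#'
#' @param arm For the antagonist study: `"saline"`, `"BQ123"` or `"BQ788"`.
#' @param dose For the VML588 study: 0, 0.05, 0.2 or 0.4 (mg/kg/hr).
#' @param bq123_rate BQ123 infusion rate (nmol/kg/min); the study used
#'   2.5-5, the upper bound is the default.
#' @return An `et_protocol`.
#' @export
build_rabelink_protocol <- function() {
  hemo <- c(0, 60, 120, 180, 225)
  ubins <- cbind(c(0, 60, 120, 180), c(60, 120, 180, 225))
  protocol(
    events = list(
      dose_event("ET1", 0.2, "pmol/kg/min", 0, 60),
      dose_event("ET1", 0.4, "pmol/kg/min", 60, 120),
      dose_event("ET1", 0.8, "pmol/kg/min", 120, 180)),
    horizon = 225, Na_diet = 200, water_load = 25, match_urine = TRUE,
    sample_times = list(ET1 = c(0, 75, 125, 225), MAP = hemo, RBF = hemo,
                        GFR = hemo, RVR = hemo),
    bins = list(urine_flow = ubins, UNaV = ubins, FENa = ubins,
                FELi = ubins),
    label = "rabelink")
}

#' @rdname build_rabelink_protocol
#' @export
build_bohm_protocol <- function(arm = c("saline", "BQ123", "BQ788"),
                                bq123_rate = 5) {
  arm <- match.arg(arm)
  events <- list(dose_event("ET1", 4, "pmol/kg/min", 30, 50))
  if (arm == "BQ123")
    events <- c(events, list(dose_event("BQ123", bq123_rate,
                                        "nmol/kg/min", 0, 50)))
  if (arm == "BQ788")
    events <- c(events, list(dose_event("BQ788", 4, "nmol/kg/min", 0, 15)))
  tt <- c(0, 15, 30, 40, 50)
  protocol(events = events, horizon = 60, Na_diet = 150,
           sample_times = list(ET1 = tt, MAP = tt, RBF = tt, RVR = tt),
           label = paste0("bohm:", arm))
}

#' @rdname build_rabelink_protocol
#' @export
build_vml588_protocol <- function(dose = c(0, 0.05, 0.2, 0.4)) {
  dose <- dose[1]
  if (!dose %in% c(0, 0.05, 0.2, 0.4))
    stop("VML588 dose must be one of 0, 0.05, 0.2, 0.4 mg/kg/hr")
  events <- list(dose_event("ET1", 1, "pmol/kg/min", 90, 110))
  if (dose > 0)
    events <- c(events, list(dose_event("VML588", dose, "mg/kg/hr", 0, 240)))
  hemo <- c(0, 90, 120, 210)
  ubins <- cbind(seq(0, 210, by = 30), seq(30, 240, by = 30))
  protocol(events = events, horizon = 240, Na_diet = 150, water_load = 10,
           match_urine = TRUE,
           sample_times = list(MAP = hemo, RBF = hemo, GFR = hemo,
                               RVR = hemo),
           bins = list(UNaV = ubins),
           label = paste0("vml588:", dose))
}

## Registry: protocol for a (study, arm) pair as used in observation tables.
protocol_for <- function(study, arm = "") {
  switch(study,
         rabelink = build_rabelink_protocol(),
         bohm = build_bohm_protocol(arm),
         vml588 = build_vml588_protocol(as.numeric(arm)),
         stop("unknown study: ", study))
}

## All arms of a study.
study_arms <- function(study) {
  switch(study,
         rabelink = "",
         bohm = c("saline", "BQ123", "BQ788"),
         vml588 = c("0", "0.05", "0.2", "0.4"),
         stop("unknown study: ", study))
}

#' Serialize / deserialize a protocol
#'
#' Protocols round-trip losslessly through a YAML representation.
#'
#' @param x An `et_protocol`.
#' @param path File path.
#' @return `write_protocol` returns `path` invisibly; `read_protocol`
#'   returns the protocol.
#' @export
write_protocol <- function(x, path) {
  lst <- unclass(x)
  lst$events <- lapply(lst$events, unclass)
  lst$bins <- lapply(lst$bins, function(b)
    list(start = as.numeric(b[, 1]), end = as.numeric(b[, 2])))
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_protocol
#' @export
read_protocol <- function(path) {
  lst <- yaml::read_yaml(path)
  events <- lapply(lst$events, function(e)
    dose_event(e$agent, e$rate, e$units, e$t_start, e$t_end))
  bins <- lapply(lst$bins, function(b) cbind(b$start, b$end))
  protocol(events = events, horizon = lst$horizon, Na_diet = lst$Na_diet,
           water_load = lst$water_load, match_urine = lst$match_urine,
           sample_times = lapply(lst$sample_times, as.numeric),
           bins = bins, label = lst$label)
}
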