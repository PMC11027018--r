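## Packed parameter vector and the R reference implementation of the model
## right-hand side. The compiled C version in src/etsim.c mirrors this file
## index-for-index; a test asserts trajectory equivalence between the two.

N_PARMS <- 135L
N_STATES <- 21L
N_OUT <- 16L

PIDX <- c(
  P_big = 1, kECE = 2, ktp = 3, kpt = 4, Vt = 5, Vp = 6,
  konA = 7, koffA = 8, kintA = 9, konB = 10, koffB = 11, kintB = 12,
  RAt = 13, RBt = 14, RAp = 15, RBp = 16, kclp = 17,
  ant_KdA = 18, ant_KdB = 19, ant_kel = 20, ant_Vd = 21, ant_F = 22,
  Rpre0 = 23, Raff0 = 24, Reff0 = 25, Rptc = 26, Kf = 27, Pbow = 28,
  pi_in = 29, Prv = 30, hct = 31, SVR0 = 32, CO0 = 33, s_co = 34,
  fb = 35, c_cap = 36, c_comp = 37, ECF0 = 38, BV0 = 39, CNa0 = 40,
  etaPT0 = 41, etaLoH = 42, etaDCT = 43, etaCD0 = 44, fw_dist = 45,
  etaW0 = 46, Na_in = 47, water_in = 48,
  Gtgf = 49, tau_tgf = 50, Gmyo = 51, tau_myo = 52, Graas = 53,
  tau_raas = 54, graas_svr = 55, graas_pt = 56, graas_cd = 57,
  Ganp = 58, tau_anp = 59, ganp_cd = 60, GadhNa = 61, GadhV = 62,
  tau_adh = 63, gadh_w = 64, PhiMD0 = 65, Paffin0 = 66,
  inf_ET1 = 67, inf_big = 68, inf_ant = 69, inf_water = 70,
  match_urine = 71)
MECH_BASE <- 72L  # 16 slots x (form, m, b, occ0); slot = (target-1)*2 + receptor

STATE_NAMES <- c("bigET1_tissue", "ET1_tissue", "ET1_plasma",
                 "bound_A_tissue", "bound_B_tissue", "bound_A_plasma",
                 "bound_B_plasma", "antagonist",
                 "ECF", "Na_amount", "A_tgf", "A_myo", "A_raas", "A_anp",
                 "A_adh", "cum_et1_in", "cum_et1_out", "cum_UNaV",
                 "cum_urine", "cum_filt_Na", "cum_fePT")

OUTPUT_NAMES <- c("MAP", "RBF", "RPF", "GFR", "RVR", "SVR", "urine_flow",
                  "UNaV", "FENa", "FELi", "CO", "P_glom", "FF", "plasma_Na",
                  "blood_volume", "eta_PT_eff")

clampv <- function(x, lo, hi) pmin(pmax(x, lo), hi)

## Fill the 16-slot mechanism block of a packed parameter vector.
## Mechanisms must already be anchored (finite ET1R_i0).
set_mechanism_block <- function(p, mechanisms) {
  check_mechanisms(mechanisms)
  p[MECH_BASE:(MECH_BASE + 63L)] <- rep(c(0, 0, 1, 0), 16)
  for (mech in mechanisms) {
    t_i <- match(mech$target, ET_TARGETS)
    r_i <- match(mech$receptor, ET_RECEPTORS)
    if (is.na(mech$ET1R_i0))
      stop("mechanism ", mech$receptor, "->", mech$target,
           " has no baseline occupancy; anchor it first")
    base <- MECH_BASE + ((t_i - 1L) * 2L + (r_i - 1L)) * 4L
    p[base] <- if (mech$form == "linear") 1 else 2
    p[base + 1L] <- mech$m
    p[base + 2L] <- mech$b
    p[base + 3L] <- mech$ET1R_i0
  }
  p
}

## Effect multipliers for all 8 targets from the packed mechanism block.
effects_from_parms <- function(p, BAt, BBt, BAp, BBp) {
  occ_A <- c(BAt, BAt, BAt, BAp, BAt, BAt, BAp, BAp)
  occ_B <- c(BBt, BBt, BBt, BBp, BBt, BBt, BBp, BBp)
  E <- rep(1, 8)
  for (t_i in 1:8) {
    for (r_i in 1:2) {
      base <- MECH_BASE + ((t_i - 1L) * 2L + (r_i - 1L)) * 4L
      form <- p[base]
      if (form == 0) next
      m <- p[base + 1L]; b <- p[base + 2L]; occ0 <- p[base + 3L]
      occ <- if (r_i == 1L) occ_A[t_i] else occ_B[t_i]
      e <- if (form == 1) max(1 + m * (occ - occ0), 0)
           else 1 + m / (1 + exp((occ - occ0) / b)) - m / 2
      E[t_i] <- E[t_i] * e
    }
  }
  E
}

## Endothelin kinetics rates on packed parameters. Returns derivatives of
## the 8 kinetic states plus the total ET-1 input and elimination rates
## (pmol/min) for the conservation trackers.
kinetics_rates <- function(y, p) {
  i <- PIDX
  BigT <- y[1]; ET1t <- y[2]; ET1p <- y[3]
  BAt <- y[4]; BBt <- y[5]; BAp <- y[6]; BBp <- y[7]; Cant <- y[8]
  fA <- 1 + Cant / p[i["ant_KdA"]]
  fB <- 1 + Cant / p[i["ant_KdB"]]
  RfAt <- max(p[i["RAt"]] - BAt, 0) / fA
  RfBt <- max(p[i["RBt"]] - BBt, 0) / fB
  RfAp <- max(p[i["RAp"]] - BAp, 0) / fA
  RfBp <- max(p[i["RBp"]] - BBp, 0) / fB
  bAt <- p[i["konA"]] * ET1t * RfAt - p[i["koffA"]] * BAt
  bBt <- p[i["konB"]] * ET1t * RfBt - p[i["koffB"]] * BBt
  bAp <- p[i["konA"]] * ET1p * RfAp - p[i["koffA"]] * BAp
  bBp <- p[i["konB"]] * ET1p * RfBp - p[i["koffB"]] * BBp
  Vt <- p[i["Vt"]]; Vp <- p[i["Vp"]]
  dBig <- (p[i["P_big"]] + p[i["inf_big"]]) / Vt - p[i["kECE"]] * BigT
  dET1t <- p[i["kECE"]] * BigT - p[i["ktp"]] * ET1t +
    p[i["kpt"]] * ET1p * Vp / Vt - bAt - bBt
  dET1p <- p[i["inf_ET1"]] / Vp + p[i["ktp"]] * ET1t * Vt / Vp -
    p[i["kpt"]] * ET1p - bAp - bBp - p[i["kclp"]] * ET1p
  dCant <- p[i["inf_ant"]] * p[i["ant_F"]] / p[i["ant_Vd"]] -
    p[i["ant_kel"]] * Cant
  rate_in <- p[i["P_big"]] + p[i["inf_big"]] + p[i["inf_ET1"]]
  rate_out <- (p[i["kintA"]] * BAt + p[i["kintB"]] * BBt) * Vt +
    (p[i["kintA"]] * BAp + p[i["kintB"]] * BBp) * Vp +
    p[i["kclp"]] * ET1p * Vp
  list(dy = c(dBig, dET1t, dET1p,
              bAt - p[i["kintA"]] * BAt, bBt - p[i["kintB"]] * BBt,
              bAp - p[i["kintA"]] * BAp, bBp - p[i["kintB"]] * BBp,
              dCant),
       rate_in = rate_in, rate_out = rate_out)
}

## Full model right-hand side (R reference implementation).
## Returns list(dy, out) with out the 16 derived outputs.
model_algebra <- function(t, y, p) {
  i <- PIDX
  kin <- kinetics_rates(y, p)
  ECF <- y[9]; MNa <- y[10]
  Atgf <- y[11]; Amyo <- y[12]; Araas <- y[13]; Aanp <- y[14]; Aadh <- y[15]
  CNa <- MNa / ECF
  BV <- p[i["BV0"]] + p[i["fb"]] * (ECF - p[i["ECF0"]])
  E <- effects_from_parms(p, y[4], y[5], y[6], y[7])
  ## E targets: 1 preafferent_R, 2 afferent_R, 3 efferent_R, 4 systemic_R,
  ## 5 PT_Na, 6 CD_Na, 7 venous_capacitance, 8 venous_compliance
  ## Venous effects have authority only over the volume-coupled component
  ## of cardiac output: capacitance diverts part of an ECF excess away from
  ## the stressed compartment, compliance flattens the venous-return slope.
  ## Both are inert at baseline volume (modest-gain venous arms).
  vol_term <- p[i["fb"]] * (ECF - p[i["ECF0"]]) /
    (1 + p[i["c_cap"]] * (E[7] - 1))
  CO <- p[i["CO0"]] * (1 + p[i["s_co"]] * vol_term /
                         (p[i["BV0"]] * (1 + p[i["c_comp"]] * (E[8] - 1))))
  CO <- max(CO, 0.5)
  SVR <- p[i["SVR0"]] * E[4] * (1 + p[i["graas_svr"]] * (Araas - 1))
  MAP <- CO * SVR
  Rpre <- p[i["Rpre0"]] * E[1] * Amyo
  Raff <- p[i["Raff0"]] * E[2] * Atgf
  Reff <- p[i["Reff0"]] * E[3]
  Rtot <- Rpre + Raff + Reff + p[i["Rptc"]]
  RBF <- max((MAP - p[i["Prv"]]) / Rtot, 1e-6)
  Paffin <- MAP - RBF * Rpre
  Pglom <- p[i["Prv"]] + RBF * (Reff + p[i["Rptc"]])
  RPF <- RBF * (1 - p[i["hct"]])
  RPF_mL <- 1000 * RPF
  GFR <- p[i["Kf"]] * (Pglom - p[i["Pbow"]] - p[i["pi_in"]]) /
    (1 + p[i["Kf"]] * p[i["pi_in"]] / RPF_mL)
  GFR <- max(GFR, 0)
  FF <- GFR / RPF_mL
  phiNa <- GFR / 1000 * CNa
  etaPT <- clampv(p[i["etaPT0"]] * E[5] *
                    (1 + p[i["graas_pt"]] * (Araas - 1)), 0.01, 0.99)
  phiMD <- phiNa * (1 - etaPT) * (1 - p[i["etaLoH"]])
  etaCD <- clampv(p[i["etaCD0"]] * E[6] *
                    (1 + p[i["graas_cd"]] * (Araas - 1)) *
                    (1 - p[i["ganp_cd"]] * (Aanp - 1)), 0.01, 0.999)
  UNaV <- phiMD * (1 - p[i["etaDCT"]]) * (1 - etaCD)
  FENa <- 100 * UNaV / max(phiNa, 1e-9)
  FELi <- 100 * (1 - etaPT)
  distw <- GFR * (1 - etaPT) * p[i["fw_dist"]]
  etaW <- clampv(p[i["etaW0"]] * (1 + p[i["gadh_w"]] * (Aadh - 1)), 0, 0.999)
  urine <- max(distw * (1 - etaW), 0.02)
  RVR <- MAP / RBF
  PhiMD0 <- p[i["PhiMD0"]]
  S_tgf <- clampv(1 + p[i["Gtgf"]] * (phiMD - PhiMD0) / PhiMD0, 0.05, 5)
  S_myo <- clampv(1 + p[i["Gmyo"]] * (Paffin - p[i["Paffin0"]]) /
                    p[i["Paffin0"]], 0.05, 5)
  S_raas <- clampv(1 - p[i["Graas"]] * (phiMD - PhiMD0) / PhiMD0, 0.05, 5)
  S_anp <- clampv(1 + p[i["Ganp"]] * (ECF - p[i["ECF0"]]) / p[i["ECF0"]],
                  0.05, 5)
  S_adh <- clampv(1 + p[i["GadhNa"]] * (CNa - p[i["CNa0"]]) / p[i["CNa0"]] -
                    p[i["GadhV"]] * (ECF - p[i["ECF0"]]) / p[i["ECF0"]],
                  0.05, 5)
  water_total <- p[i["inf_water"]] +
    if (p[i["match_urine"]] > 0.5) urine else p[i["water_in"]]
  dy <- numeric(N_STATES)
  dy[1:8] <- kin$dy
  dy[9] <- (water_total - urine) / 1000
  dy[10] <- p[i["Na_in"]] - UNaV
  dy[11] <- (S_tgf - Atgf) / p[i["tau_tgf"]]
  dy[12] <- (S_myo - Amyo) / p[i["tau_myo"]]
  dy[13] <- (S_raas - Araas) / p[i["tau_raas"]]
  dy[14] <- (S_anp - Aanp) / p[i["tau_anp"]]
  dy[15] <- (S_adh - Aadh) / p[i["tau_adh"]]
  dy[16] <- kin$rate_in
  dy[17] <- kin$rate_out
  dy[18] <- UNaV
  dy[19] <- urine
  dy[20] <- phiNa
  dy[21] <- 1 - etaPT
  out <- c(MAP, RBF, RPF, GFR, RVR, SVR, urine, UNaV, FENa, FELi, CO,
           Pglom, FF, CNa, BV, etaPT)
  list(dy = dy, out = out)
}

## deSolve-compatible wrapper for the R reference RHS.
model_rhs_R <- function(t, y, p) {
  a <- model_algebra(t, y, p)
  list(a$dy, a$out)
}

## Pack configuration (without mechanisms, setpoints or infusions) into the
## numeric parameter vector consumed by both RHS implementations.
pack_parms <- function(config, antagonist = NULL) {
  k <- config$kinetics; cr <- config$cardiorenal; fb <- config$feedback
  p <- numeric(N_PARMS)
  i <- PIDX
  p[i["P_big"]] <- k$bigET1_production_rate
  p[i["kECE"]] <- k$k_ECE; p[i["ktp"]] <- k$k_tp; p[i["kpt"]] <- k$k_pt
  p[i["Vt"]] <- k$V_tissue; p[i["Vp"]] <- k$V_plasma
  p[i["konA"]] <- k$kon_A; p[i["koffA"]] <- k$koff_A
  p[i["kintA"]] <- k$k_int_A
  p[i["konB"]] <- k$kon_B; p[i["koffB"]] <- k$koff_B
  p[i["kintB"]] <- k$k_int_B
  p[i["RAt"]] <- k$R_A_tissue; p[i["RBt"]] <- k$R_B_tissue
  p[i["RAp"]] <- k$R_A_plasma; p[i["RBp"]] <- k$R_B_plasma
  p[i["kclp"]] <- k$k_cl_plasma
  if (is.null(antagonist)) {
    p[i["ant_KdA"]] <- 1e30; p[i["ant_KdB"]] <- 1e30
    p[i["ant_kel"]] <- 1; p[i["ant_Vd"]] <- 1; p[i["ant_F"]] <- 0
  } else {
    p[i["ant_KdA"]] <- antagonist$Kd_A
    p[i["ant_KdB"]] <- antagonist$Kd_B
    p[i["ant_kel"]] <- log(2) / antagonist$plasma_halflife
    p[i["ant_Vd"]] <- antagonist$V_distribution
    p[i["ant_F"]] <- antagonist$bioavailable_fraction
  }
  p[i["Rpre0"]] <- cr$R_preafferent; p[i["Raff0"]] <- cr$R_afferent
  p[i["Reff0"]] <- cr$R_efferent; p[i["Rptc"]] <- cr$R_peritubular
  p[i["Kf"]] <- cr$K_f; p[i["Pbow"]] <- cr$P_bowman
  p[i["pi_in"]] <- cr$pi_in; p[i["Prv"]] <- cr$P_renal_vein
  p[i["hct"]] <- config$subject$hematocrit
  p[i["SVR0"]] <- cr$SVR_nominal; p[i["CO0"]] <- cr$CO_nominal
  p[i["s_co"]] <- cr$co_volume_gain
  p[i["fb"]] <- cr$blood_fraction_of_ecf_change
  p[i["c_cap"]] <- cr$venous_capacitance_gain
  p[i["c_comp"]] <- cr$venous_compliance_gain
  p[i["ECF0"]] <- cr$ECF0; p[i["BV0"]] <- cr$blood_volume0
  p[i["CNa0"]] <- cr$plasma_Na0
  p[i["etaPT0"]] <- cr$eta_PT; p[i["etaLoH"]] <- cr$eta_LoH
  p[i["etaDCT"]] <- cr$eta_DCT; p[i["etaCD0"]] <- cr$eta_CD
  p[i["fw_dist"]] <- cr$fw_dist
  p[i["etaW0"]] <- 0.97                     # re-solved at initialization
  p[i["Na_in"]] <- cr$Na_intake / 1440      # mmol/day -> mmol/min
  p[i["water_in"]] <- cr$water_intake
  p[i["Gtgf"]] <- fb$G_tgf; p[i["tau_tgf"]] <- fb$tau_tgf
  p[i["Gmyo"]] <- fb$G_myo; p[i["tau_myo"]] <- fb$tau_myo
  p[i["Graas"]] <- fb$G_raas; p[i["tau_raas"]] <- fb$tau_raas
  p[i["graas_svr"]] <- fb$g_raas_svr; p[i["graas_pt"]] <- fb$g_raas_pt
  p[i["graas_cd"]] <- fb$g_raas_cd
  p[i["Ganp"]] <- fb$G_anp; p[i["tau_anp"]] <- fb$tau_anp
  p[i["ganp_cd"]] <- fb$g_anp_cd
  p[i["GadhNa"]] <- fb$G_adh_na; p[i["GadhV"]] <- fb$G_adh_v
  p[i["tau_adh"]] <- fb$tau_adh; p[i["gadh_w"]] <- fb$g_adh_w
  p[i["PhiMD0"]] <- 1; p[i["Paffin0"]] <- 1  # re-solved at initialization
  p <- set_mechanism_block(p, list())
  p
}
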