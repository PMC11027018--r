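# Reference parameterization: healthy 70-kg male subject.
# Concentrations in pM, time in minutes, volumes in L unless noted.
subject:
  body_weight_kg: 70.0
  hematocrit: 0.45

kinetics:
  # Big ET-1 production (pmol/min, whole body); chosen together with the
  # rate constants below so that the no-dose steady state has plasma
  # ET-1 = 2.000 pM (see vignette, "Reference kinetics").
  bigET1_production_rate: 114.694346
  k_ECE: 0.1            # 1/min, Big ET-1 -> ET-1 conversion (tissue)
  k_tp: 3.1             # 1/min, tissue -> plasma transfer
  k_pt: 8.0             # 1/min, plasma -> tissue transfer
  V_tissue: 15.0        # L
  V_plasma: 4.0         # L
  kon_A: 0.05           # 1/pM/min
  koff_A: 0.5           # 1/min   (Kd_A = 10 pM)
  k_int_A: 0.6          # 1/min, internalization of ET1-ET_A complex
  kon_B: 0.05
  koff_B: 0.3           # (Kd_B = 6 pM)
  k_int_B: 0.9          # ET_B is the dominant clearance receptor
  R_A_tissue: 20.0      # pM total ET_A density, renal/tissue compartment
  R_B_tissue: 80.0      # pM; ET_B expression much higher renally
  R_A_plasma: 6.0       # pM; resistance vessels are mainly ET_A
  R_B_plasma: 20.0
  k_cl_plasma: 2.0      # 1/min, non-receptor plasma clearance
  molar_mass_ET1: 2491.9  # g/mol, for ng <-> pmol dose conversion

antagonists:
  BQ123:                # ET_A-selective
    Kd_A: 1.0e+04         # pM (10 nM)
    Kd_B: 1.0e+07
    plasma_halflife: 20.0   # min
    V_distribution: 15.0    # L
    bioavailable_fraction: 1.0
    molar_mass: 611.0
  BQ788:                # ET_B-selective
    Kd_A: 2.0e+06
    Kd_B: 2.0e+03         # pM (2 nM)
    plasma_halflife: 20.0
    V_distribution: 15.0
    bioavailable_fraction: 1.0
    molar_mass: 664.0
  VML588:               # ET_A-selective; in-vivo potency chosen so the
    Kd_A: 3.0e+05         # 0.05/0.2/0.4 mg/kg/hr arms span partial to
    Kd_B: 3.0e+08         # near-complete ET_A blockade
    plasma_halflife: 30.0
    V_distribution: 15.0
    bioavailable_fraction: 1.0
    molar_mass: 500.0   # synthetic stand-in value

cardiorenal:
  N_nephrons: 2.0e+06
  # Resistances are totals across the kidney (mmHg.min/L)
  R_preafferent: 14.0
  R_afferent: 16.0
  R_efferent: 44.0
  R_peritubular: 6.9
  K_f: 6.65             # mL/min/mmHg, whole-kidney ultrafiltration coeff.
  P_bowman: 12.0        # mmHg
  pi_in: 25.0           # mmHg, afferent plasma oncotic pressure
  P_renal_vein: 4.0     # mmHg
  SVR_nominal: 18.6     # mmHg.min/L
  CO_nominal: 5.0       # L/min
  co_volume_gain: 0.8   # fractional CO change per fractional blood-volume change
  blood_fraction_of_ecf_change: 0.25
  venous_capacitance_gain: 0.5   # venous arms modulate only the
  venous_compliance_gain: 0.5    # volume-coupled part of cardiac output
  ECF0: 15.0            # L
  blood_volume0: 5.0    # L
  plasma_Na0: 140.0     # mmol/L
  eta_PT: 0.70          # baseline fractional Na reabsorption, proximal tubule
  eta_LoH: 0.75
  eta_DCT: 0.60
  eta_CD: 0.80          # re-solved at initialization from Na intake
  fw_dist: 1.0          # fraction of post-PT fluid reaching the diluting segment
  Na_intake: 150.0      # mmol/day (protocols may override)
  water_intake: 1.0     # mL/min (balances baseline urine flow)

feedback:
  G_tgf: 2.0            # afferent response to macula densa Na delivery
  tau_tgf: 5.0          # min
  G_myo: 2.0            # preafferent myogenic response to local pressure
  tau_myo: 3.0
  G_raas: 0.5           # renin/AngII response to MD delivery
  tau_raas: 30.0
  g_raas_svr: 0.3
  g_raas_pt: 0.15
  g_raas_cd: 0.3
  G_anp: 1.5            # ANP response to ECF excess
  tau_anp: 30.0
  g_anp_cd: 0.3
  G_adh_na: 10.0        # vasopressin response to plasma Na (osmolality proxy)
  G_adh_v: 2.0
  tau_adh: 20.0
  g_adh_w: 0.4

solver:
  rtol: 1.0e-6
  atol: 1.0e-9

protocol_defaults:
  water_load_duration: 45.0   # min over which an oral water load is absorbed
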