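/* Compiled right-hand side of the coupled endothelin-1 kinetics /
 * cardiorenal model. Mirrors the R reference implementation in R/model.R
 * index-for-index; the testthat suite asserts trajectory equivalence.
 */
#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <math.h>

#define NP 135
static double p[NP];

/* 0-based parameter indices (R PIDX minus one) */
#define P_BIG    0
#define K_ECE    1
#define K_TP     2
#define K_PT     3
#define V_T      4
#define V_P      5
#define KON_A    6
#define KOFF_A   7
#define KINT_A   8
#define KON_B    9
#define KOFF_B  10
#define KINT_B  11
#define R_A_T   12
#define R_B_T   13
#define R_A_P   14
#define R_B_P   15
#define K_CLP   16
#define ANT_KDA 17
#define ANT_KDB 18
#define ANT_KEL 19
#define ANT_VD  20
#define ANT_F   21
#define RPRE0   22
#define RAFF0   23
#define REFF0   24
#define RPTC    25
#define KF      26
#define PBOW    27
#define PI_IN   28
#define PRV     29
#define HCT     30
#define SVR0    31
#define CO0     32
#define S_CO    33
#define FB      34
#define C_CAP   35
#define C_COMP  36
#define ECF0    37
#define BV0     38
#define CNA0    39
#define ETAPT0  40
#define ETALOH  41
#define ETADCT  42
#define ETACD0  43
#define FW_DIST 44
#define ETAW0   45
#define NA_IN   46
#define WATER_IN 47
#define GTGF    48
#define TAU_TGF 49
#define GMYO    50
#define TAU_MYO 51
#define GRAAS   52
#define TAU_RAAS 53
#define GRAAS_SVR 54
#define GRAAS_PT 55
#define GRAAS_CD 56
#define GANP    57
#define TAU_ANP 58
#define GANP_CD 59
#define GADH_NA 60
#define GADH_V  61
#define TAU_ADH 62
#define GADH_W  63
#define PHIMD0  64
#define PAFFIN0 65
#define INF_ET1 66
#define INF_BIG 67
#define INF_ANT 68
#define INF_WATER 69
#define MATCH_URINE 70
#define MECH0   71   /* 16 slots x (form, m, b, occ0) */

static double clampd(double x, double lo, double hi)
{
    return x < lo ? lo : (x > hi ? hi : x);
}

void initmod(void (*odeparms)(int *, double *))
{
    int n = NP;
    odeparms(&n, p);
}

/* Infusion rates (ET-1, Big ET-1, antagonist, water) can be supplied as
 * step-function forcings; they are written straight into the contiguous
 * infusion slots of the parameter vector, so a call without forcings
 * simply uses the constant rates passed in parms. */
void initforc(void (*odeforcs)(int *, double *))
{
    int n = 4;
    odeforcs(&n, p + INF_ET1);
}

/* effect multiplier for target t (0..7) given the four occupancies */
static double eff(int t, double BAt, double BBt, double BAp, double BBp)
{
    /* plasma-read targets: systemic_R (3), venous capacitance (6),
     * venous compliance (7); all others read tissue occupancy */
    int plasma = (t == 3 || t == 6 || t == 7);
    double occA = plasma ? BAp : BAt;
    double occB = plasma ? BBp : BBt;
    double E = 1.0;
    int r;
    for (r = 0; r < 2; r++) {
        const double *s = p + MECH0 + (t * 2 + r) * 4;
        double form = s[0];
        if (form == 0.0) continue;
        double m = s[1], b = s[2], occ0 = s[3];
        double occ = r == 0 ? occA : occB;
        double e;
        if (form == 1.0) {
            e = 1.0 + m * (occ - occ0);
            if (e < 0.0) e = 0.0;
        } else {
            e = 1.0 + m / (1.0 + exp((occ - occ0) / b)) - m / 2.0;
        }
        E *= e;
    }
    return E;
}

void derivs(int *neq, double *t, double *y, double *ydot,
            double *yout, int *ip)
{
    if (ip[0] < 16) error("nout should be at least 16");

    double BigT = y[0], ET1t = y[1], ET1p = y[2];
    double BAt = y[3], BBt = y[4], BAp = y[5], BBp = y[6], Cant = y[7];
    double ECF = y[8], MNa = y[9];
    double Atgf = y[10], Amyo = y[11], Araas = y[12], Aanp = y[13],
           Aadh = y[14];

    /* --- endothelin kinetics --- */
    double fA = 1.0 + Cant / p[ANT_KDA];
    double fB = 1.0 + Cant / p[ANT_KDB];
    double RfAt = fmax(p[R_A_T] - BAt, 0.0) / fA;
    double RfBt = fmax(p[R_B_T] - BBt, 0.0) / fB;
    double RfAp = fmax(p[R_A_P] - BAp, 0.0) / fA;
    double RfBp = fmax(p[R_B_P] - BBp, 0.0) / fB;
    double bAt = p[KON_A] * ET1t * RfAt - p[KOFF_A] * BAt;
    double bBt = p[KON_B] * ET1t * RfBt - p[KOFF_B] * BBt;
    double bAp = p[KON_A] * ET1p * RfAp - p[KOFF_A] * BAp;
    double bBp = p[KON_B] * ET1p * RfBp - p[KOFF_B] * BBp;
    double Vt = p[V_T], Vp = p[V_P];

    ydot[0] = (p[P_BIG] + p[INF_BIG]) / Vt - p[K_ECE] * BigT;
    ydot[1] = p[K_ECE] * BigT - p[K_TP] * ET1t +
        p[K_PT] * ET1p * Vp / Vt - bAt - bBt;
    ydot[2] = p[INF_ET1] / Vp + p[K_TP] * ET1t * Vt / Vp -
        p[K_PT] * ET1p - bAp - bBp - p[K_CLP] * ET1p;
    ydot[3] = bAt - p[KINT_A] * BAt;
    ydot[4] = bBt - p[KINT_B] * BBt;
    ydot[5] = bAp - p[KINT_A] * BAp;
    ydot[6] = bBp - p[KINT_B] * BBp;
    ydot[7] = p[INF_ANT] * p[ANT_F] / p[ANT_VD] - p[ANT_KEL] * Cant;

    double rate_in = p[P_BIG] + p[INF_BIG] + p[INF_ET1];
    double rate_out = (p[KINT_A] * BAt + p[KINT_B] * BBt) * Vt +
        (p[KINT_A] * BAp + p[KINT_B] * BBp) * Vp + p[K_CLP] * ET1p * Vp;

    /* --- cardiorenal algebra --- */
    double CNa = MNa / ECF;
    double BV = p[BV0] + p[FB] * (ECF - p[ECF0]);
    double E_pre = eff(0, BAt, BBt, BAp, BBp);
    double E_aff = eff(1, BAt, BBt, BAp, BBp);
    double E_eff = eff(2, BAt, BBt, BAp, BBp);
    double E_svr = eff(3, BAt, BBt, BAp, BBp);
    double E_pt  = eff(4, BAt, BBt, BAp, BBp);
    double E_cd  = eff(5, BAt, BBt, BAp, BBp);
    double E_vcap = eff(6, BAt, BBt, BAp, BBp);
    double E_vcomp = eff(7, BAt, BBt, BAp, BBp);

    /* venous arms act only on the volume-coupled CO component */
    double vol_term = p[FB] * (ECF - p[ECF0]) /
        (1.0 + p[C_CAP] * (E_vcap - 1.0));
    double CO = p[CO0] * (1.0 + p[S_CO] * vol_term /
                          (p[BV0] * (1.0 + p[C_COMP] * (E_vcomp - 1.0))));
    if (CO < 0.5) CO = 0.5;
    double SVR = p[SVR0] * E_svr * (1.0 + p[GRAAS_SVR] * (Araas - 1.0));
    double MAP = CO * SVR;
    double Rpre = p[RPRE0] * E_pre * Amyo;
    double Raff = p[RAFF0] * E_aff * Atgf;
    double Reff = p[REFF0] * E_eff;
    double Rtot = Rpre + Raff + Reff + p[RPTC];
    double RBF = fmax((MAP - p[PRV]) / Rtot, 1e-6);
    double Paffin = MAP - RBF * Rpre;
    double Pglom = p[PRV] + RBF * (Reff + p[RPTC]);
    double RPF = RBF * (1.0 - p[HCT]);
    double RPF_mL = 1000.0 * RPF;
    double GFR = p[KF] * (Pglom - p[PBOW] - p[PI_IN]) /
        (1.0 + p[KF] * p[PI_IN] / RPF_mL);
    if (GFR < 0.0) GFR = 0.0;
    double FF = GFR / RPF_mL;
    double phiNa = GFR / 1000.0 * CNa;
    double etaPT = clampd(p[ETAPT0] * E_pt *
                          (1.0 + p[GRAAS_PT] * (Araas - 1.0)), 0.01, 0.99);
    double phiMD = phiNa * (1.0 - etaPT) * (1.0 - p[ETALOH]);
    double etaCD = clampd(p[ETACD0] * E_cd *
                          (1.0 + p[GRAAS_CD] * (Araas - 1.0)) *
                          (1.0 - p[GANP_CD] * (Aanp - 1.0)), 0.01, 0.999);
    double UNaV = phiMD * (1.0 - p[ETADCT]) * (1.0 - etaCD);
    double FENa = 100.0 * UNaV / fmax(phiNa, 1e-9);
    double FELi = 100.0 * (1.0 - etaPT);
    double distw = GFR * (1.0 - etaPT) * p[FW_DIST];
    double etaW = clampd(p[ETAW0] * (1.0 + p[GADH_W] * (Aadh - 1.0)),
                         0.0, 0.999);
    double urine = fmax(distw * (1.0 - etaW), 0.02);
    double RVR = MAP / RBF;

    double S_tgf = clampd(1.0 + p[GTGF] * (phiMD - p[PHIMD0]) / p[PHIMD0],
                          0.05, 5.0);
    double S_myo = clampd(1.0 + p[GMYO] * (Paffin - p[PAFFIN0]) / p[PAFFIN0],
                          0.05, 5.0);
    double S_raas = clampd(1.0 - p[GRAAS] * (phiMD - p[PHIMD0]) / p[PHIMD0],
                           0.05, 5.0);
    double S_anp = clampd(1.0 + p[GANP] * (ECF - p[ECF0]) / p[ECF0],
                          0.05, 5.0);
    double S_adh = clampd(1.0 + p[GADH_NA] * (CNa - p[CNA0]) / p[CNA0] -
                          p[GADH_V] * (ECF - p[ECF0]) / p[ECF0], 0.05, 5.0);
    double water_total = p[INF_WATER] +
        (p[MATCH_URINE] > 0.5 ? urine : p[WATER_IN]);

    ydot[8] = (water_total - urine) / 1000.0;
    ydot[9] = p[NA_IN] - UNaV;
    ydot[10] = (S_tgf - Atgf) / p[TAU_TGF];
    ydot[11] = (S_myo - Amyo) / p[TAU_MYO];
    ydot[12] = (S_raas - Araas) / p[TAU_RAAS];
    ydot[13] = (S_anp - Aanp) / p[TAU_ANP];
    ydot[14] = (S_adh - Aadh) / p[TAU_ADH];
    ydot[15] = rate_in;
    ydot[16] = rate_out;
    ydot[17] = UNaV;
    ydot[18] = urine;
    ydot[19] = phiNa;
    ydot[20] = 1.0 - etaPT;

    yout[0] = MAP;   yout[1] = RBF;   yout[2] = RPF;   yout[3] = GFR;
    yout[4] = RVR;   yout[5] = SVR;   yout[6] = urine; yout[7] = UNaV;
    yout[8] = FENa;  yout[9] = FELi;  yout[10] = CO;   yout[11] = Pglom;
    yout[12] = FF;   yout[13] = CNa;  yout[14] = BV;   yout[15] = etaPT;
}

static const R_CMethodDef cMethods[] = {
    {"initmod", (DL_FUNC) &initmod, 1},
    {"initforc", (DL_FUNC) &initforc, 1},
    {"derivs", (DL_FUNC) &derivs, 6},
    {NULL, NULL, 0}
};

void R_init_etsim(DllInfo *dll)
{
    R_registerRoutines(dll, cMethods, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);
}
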