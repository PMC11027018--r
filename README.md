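# etsim

Quantitative systems pharmacology of endothelin-1 (ET-1) in healthy
humans: a coupled model of ET-1 kinetics and cardiorenal physiology, with
machinery to identify *which* receptor-mediated mechanisms explain
observed hemodynamic and excretory responses and to estimate *how strong*
they are.

## Who this is for

Modelers and pharmacologists studying the endothelin system — ET-1
infusion responses, ET_A/ET_B receptor antagonists and their renal
consequences (vasoconstriction, sodium retention, the fluid-retention
liability of ET_A antagonists) — who want a tested, reproducible pipeline
for simulating clinical infusion protocols, generating study-shaped
synthetic data, and running structure-identification and calibration
experiments.

## The model in brief

**Kinetics.** Big ET-1 is produced at a constant rate and converted by ECE
to ET-1 in a tissue compartment; ET-1 exchanges with plasma and binds
ET_A and ET_B receptors by mass action; bound complexes are cleared by
internalization (ET_B carries most of the clearance, which is why ET_B
blockade raises circulating ET-1). Competitive antagonists (BQ123, BQ788,
VML588) follow one-compartment PK and scale the free receptor pool.

**Physiology.** A reduced cardiorenal ODE model: preafferent/afferent/
efferent/peritubular renal resistances, Starling-force glomerular
filtration (GFR = K_f(P_glom − P_Bowman − π)), four-segment fractional
sodium reabsorption, vasopressin-controlled water handling, volume–
pressure closure (MAP = CO × SVR), and first-order feedback for
tubuloglomerular feedback, myogenic tone, RAAS, ANP and vasopressin.

**Linkage.** Each candidate mechanism maps one receptor occupancy ET1R_i
(pM) to a multiplier on one target parameter, equal to 1 at the baseline
occupancy ET1R_i0:

    E_linear = max(1 + m (ET1R_i − ET1R_i0), 0)
    E_sig    = 1 + m / (1 + exp((ET1R_i − ET1R_i0)/b)) − m/2

**Identification.** A weighted least-squares objective over per-study
observation tables; bounded Levenberg–Marquardt + L-BFGS-B estimation;
greedy forward selection over {ET_A, ET_B} × 8 targets × 2 forms with a
confirmatory backward-elimination pass. A calibrated seven-mechanism
preset (`mechanism_preset("refined")`) ships with the package, and the
synthetic-data generator uses it as ground truth for recovery
experiments.

## Worked example

```r
library(etsim)
cfg <- et_config()                      # reference healthy-subject parameters

## simulate the ET-1 ramp study under the calibrated mechanism set
tr <- simulate_protocol(build_rabelink_protocol(),
                        mechanism_preset("refined"), cfg)
round(subset(tr, time %in% c(0, 60, 120, 180),
             c(time, plasma_ET1, MAP, RBF, GFR, FENa)), 3)
#>     time plasma_ET1     MAP   RBF     GFR  FENa
#> 1      0      2.000  93.000 1.100 119.964 0.827
#> 31    60      2.521 101.217 1.133 131.018 0.880
#> 62   120      3.047 102.959 1.117 127.788 0.884
#> 93   180      4.113 106.111 1.092 123.251 0.843
```

Reading the numbers: plasma ET-1 roughly doubles over the three
hour-blocks of increasing infusion (0.2/0.4/0.8 pmol/kg/min); mean
arterial pressure rises ~13 mmHg (systemic ET_A/ET_B vasoconstriction
plus the maintained water load); renal blood flow falls below its 1.100
L/min baseline despite the higher perfusion pressure — the preafferent
and afferent ET_A constriction at work; the fall in fractional sodium
excretion toward the end of the ramp reflects the proximal-tubule ET_A
sodium-retention arm.

A recovery experiment in three lines:

```r
obs <- generate_observations(synthetic_spec(seed = 1), cfg)  # 196 rows, 8 arms
start <- lapply(mechanism_preset("refined"), function(m) { m$m <- 0; m })
fit <- fit_parameters(start, obs, cfg, n_starts = 2)
print(fit)   # slopes with SEs as % of estimate
```

Command-line use (thin wrapper over the same functions):

```sh
Rscript inst/cli/etsim.R synth --seed 1 --out runs/synth
Rscript inst/cli/etsim.R select --obs runs/synth/observations.csv --out runs/sel
```

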