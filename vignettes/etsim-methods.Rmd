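---
title: "Modeling endothelin-1 effects on cardiorenal function: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling endothelin-1 effects on cardiorenal function: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific problem

Endothelin-1 (ET-1) is a potent vasoconstrictor with anti-natriuretic and
anti-diuretic actions, exerted through two receptors: ET~A~, dominant on
resistance vessels, and ET~B~, which besides signaling is the main
clearance route for circulating ET-1 (bound complexes are internalized and
degraded). Because the two receptors pull physiology in different
directions — and because blocking ET~B~ raises ET-1 itself — the net effect
of ET-1 or of receptor antagonists on blood pressure, renal blood flow
(RBF), glomerular filtration (GFR) and sodium excretion is hard to predict
qualitatively. `etsim` couples a kinetic model of ET-1 production,
distribution, receptor binding and antagonism to a reduced
ordinary-differential-equation model of cardiorenal physiology, links
receptor occupancy to physiological targets through simple effect
functions, and provides machinery to *identify which links are needed* to
explain clinical infusion studies and to *estimate their magnitudes* by
bounded least squares.

# Model structure

## ET-1 kinetics

Big ET-1 is produced at a constant rate and converted to ET-1 by
endothelin-converting enzyme in a tissue compartment; ET-1 exchanges with a
plasma compartment by first-order transfer. In each compartment ET-1 binds
ET~A~ and ET~B~ by mass action,

$$\frac{d[ET1R_i]}{dt} = k_{on,i}\,[ET1]\,(R_{i,tot}-[ET1R_i]) -
  k_{off,i}\,[ET1R_i] - k_{int,i}\,[ET1R_i],$$

with internalization $k_{int}$ clearing the bound complex. Competitive
antagonists (BQ123, BQ788, VML588) follow one-compartment pharmacokinetics
with first-order elimination; their receptor occupancy is treated as a
rapid equilibrium, so the receptor pool available to ET-1 is scaled by
$1/(1 + C_{ant}/K_d)$. This avoids four bound-antagonist state variables
while preserving the ET-1 mass balance exactly; it is accurate whenever
antagonist binding equilibrates fast relative to the minutes-scale
dynamics of interest, which holds at the micromolar concentrations these
protocols reach. A first-order non-receptor plasma clearance term
represents pulmonary and proteolytic elimination.

All concentrations are in pM, time in minutes; per-kg doses are converted
with a configurable 70-kg body weight and an ET-1 molar mass of 2491.9
g/mol.

## Reference kinetics

The rate constants are not identifiable from the fitted studies alone, so
the package ships one frozen "reference kinetics" configuration
(`inst/extdata/reference_config.yaml`), chosen once to satisfy:

* baseline plasma ET-1 of 2.000 pM (the production rate is back-solved
  analytically so the no-dose steady state lands there exactly);
* a roughly two-fold rise in plasma ET-1 over the 0.2/0.4/0.8 pmol/kg/min
  infusion ramp, staying inside the 1–50 pM range spanned by the clinical
  studies (peak ~34 pM under ET~B~ blockade plus ET-1 infusion);
* ET~B~ carrying the majority (~73%) of total ET-1 clearance, so ET~B~
  blockade raises ET-1 markedly while ET~A~ blockade raises it mildly;
* renal tissue expressing more ET~B~ than ET~A~ (80 vs 20 pM), plasma-facing
  resistance vessels more ET~A~ (6 vs 20 pM — the plasma ET~B~ pool also
  serves clearance);
* receptor-occupancy excursions of a magnitude commensurate with the
  calibrated slopes, so that every mechanism in the calibrated set produces
  a measurable response in at least one study arm (without this the
  selection and recovery machinery would be exercising unidentifiable
  parameters).

A consequence worth stating plainly: baseline receptor occupancies are an
appreciable fraction of the dosing-induced excursions, so *antagonist-alone*
arms produce stronger renal vasodilation in this reference world than the
clinical reports show (where antagonists alone had minimal hemodynamic
effect). In particular, full ET~A~ blockade drives the afferent-resistance
effect multiplier to its zero clamp. Synthetic-data experiments are
self-consistent and unaffected, but absolute antagonist-alone responses
should not be read as clinical predictions.

## Cardiorenal physiology

The cardiorenal side is a deliberate reduction of a full
nephron-and-hormone model to what ≤4-h acute infusion protocols can
constrain:

* **Renal vasculature.** A preafferent resistance in series with lumped
  afferent, efferent and peritubular resistances;
  $RBF = (MAP - P_{vein})/R_{tot}$, glomerular pressure from the downstream
  drop.
* **Filtration.** $GFR = K_f(P_{glom} - P_{Bowman} - \pi)$ with a
  single-point oncotic average $\pi = \pi_{in}(1 + FF)$; substituting
  $FF = GFR/RPF$ makes this a closed-form linear solve. The error relative
  to integrating the oncotic profile along the capillary is absorbed into
  the calibration of $K_f$.
* **Tubule.** Sequential fractional Na⁺ reabsorption in four segments
  (baseline 0.70 / 0.75 / 0.60 / back-solved ≈0.72–0.79). Fractional
  lithium excretion is implemented as $FELi = 1 - \eta_{PT,eff}$, lithium
  being a pure proximal marker. Distal water handling is a single
  vasopressin-controlled reabsorption fraction.
* **Volume and pressure.** Extracellular fluid volume integrates intake
  minus urine; blood volume takes a fixed fraction (0.25) of ECF changes
  (an algebraic stand-in for Starling exchange); cardiac output is linear
  in the volume excess with a modest gain (0.8), and
  $MAP = CO \times SVR$. Venous capacitance and compliance are targetable,
  but act only on the volume-coupled component of cardiac output
  (capacitance diverts part of an ECF excess away from the stressed
  compartment, compliance flattens the venous-return slope), so they are
  inert at baseline volume. This deliberate modest-gain design keeps the
  venous arms testable without letting them impersonate the systemic
  resistance arms, to which a direct multiplicative CO modifier would be
  observationally equivalent (MAP is the product CO × SVR and neither CO
  nor SVR is measured in these protocols).
* **Feedback.** First-order states for tubuloglomerular feedback (macula
  densa Na delivery → afferent resistance, gain 2, τ = 5 min), a myogenic
  preafferent response (local perfusion pressure, gain 2, τ = 3 min), a
  lumped renin–angiotensin activity (τ = 30 min) acting on SVR and
  reabsorption, ANP (volume, τ = 30 min) and vasopressin (osmolality and
  volume, τ = 20 min). The TGF/myogenic gains satisfy the autoregulation
  check (a +10 mmHg pressure step moves steady-state GFR by <10% with
  feedback on, much more with it off). They also break the otherwise
  near-perfect collinearity of the preafferent and afferent resistance
  arms: both are upstream in series, so only their closed-loop dynamics
  (myogenic state multiplying one, TGF state the other) let least squares
  apportion constriction between them.

Initialization is exact by construction: the kinetic steady state is
solved by damped Newton iteration, the collecting-duct sodium fraction and
distal water fraction are back-solved from dietary intake, and all
feedback setpoints are anchored at the resulting operating point. A 24-h
simulation drifts by less than 10⁻⁶ relative.

## Occupancy → effect links

Each candidate mechanism links the bound concentration of one receptor
(tissue occupancy for renal vascular and tubular targets, plasma occupancy
for systemic vascular and venous targets) to one target parameter through
a multiplier that is exactly 1 at baseline occupancy:

* linear: $E = \max(1 + m\,(ET1R_i - ET1R_{i0}),\ 0)$ — clamped at zero;
* sigmoidal: $E = 1 + m/(1 + e^{(ET1R_i - ET1R_{i0})/b}) - m/2$ — bounded
  in $1 \mp m/2$.

The sigmoidal form as written *decreases* with occupancy for positive
$m$; the sign of $m$ carries direction (the calibrated sets indeed report
a negative efferent ET~B~ slope). Mechanisms sharing a target compose
multiplicatively, which preserves the baseline identity, positivity, and
order independence. Effects enter only as multipliers on nominal
parameters, never additively.

Two calibrated seven-mechanism presets ship with the package
(`mechanism_preset("initial")` and `"refined"`, the latter including the
VML588 validation study in the objective): ET~A~ constriction of the
preafferent (m = 0.288), afferent (1.66) and efferent (0.0635)
arterioles and the systemic vasculature (0.060), ET~A~ enhancement of
proximal Na⁺ reabsorption (0.0311), ET~B~ efferent dilation (−0.0059) and
ET~B~ systemic constriction (0.0135); all linear.

# Estimation and mechanism selection

## Objective

$OBJ = \sum_k \left((y_k^{sim} - y_k^{obs})/w_k\right)^2$ over every
observation row, simulating each study arm once per evaluation. Weights
are the reported standard errors where available, else 5% of the
variable's baseline value — this puts mmHg-, L/min- and percent-scale
variables on comparable footing, which joint fitting of several studies
requires. Urine variables are compared as collection-bin averages
(computed from cumulative-excretion model states), not instantaneous
values. Simulation failures yield an infinite objective (a large finite
penalty inside optimizers) rather than an error.

## Optimizer

The slopes span three orders of magnitude (1.66 to 0.0059) and the two
preglomerular arms are nearly collinear, which defeats single-method
optimizers started all-at-once from neutral values: both quasi-Newton and
trust-region least squares commit early to a wrong apportioning of the
preglomerular constriction and then cannot traverse the resulting
curved valley (they converge to "swap basins" with, e.g., the preafferent
slope absorbing the afferent signal). Difference steps matter too:
Levenberg–Marquardt with machine-epsilon forward differences cannot see
small-slope gradients above ODE-solver noise, so all finite-difference
steps are set to ~1% of each parameter. The `"staged"` method runs
bounded L-BFGS-B under per-parameter scaling and polishes with bounded
Levenberg–Marquardt; for joint fits of several mechanisms from a neutral
start the `"sequential"` method is the robust choice: mechanisms are
introduced one at a time in greedy best-first order (a coarse grid scan
over the incoming slope, then a warm-started joint refit of everything
introduced), ending with a staged polish of all parameters. Introducing
the dominant arms first keeps the warm-started fits on the correct side
of the collinearity valley; on synthetic recovery experiments this
pipeline reaches the global basin where all-at-once starts do not.
Multi-start with seeded jitter guards against remaining local minima.
Standard errors come from the finite-difference Jacobian of the weighted
residuals at the optimum and are reported as percent of the estimate.

## Forward selection / backward elimination

Selection starts from the NULL model (no ET-1 effects). Each round fits
every remaining (receptor × target × form) candidate, keeps the single
best objective reducer, and jointly refits all kept parameters; rounds
stop when the best relative reduction falls below 1% or within the
multistart spread of the refit. A backward pass then drops each kept
mechanism, refits the rest, and flags any whose removal does not worsen
the objective. Two deliberate choices:

* **Screening cost.** Each candidate's slope is first grid-scanned to
  pick a robust optimizer start (the linear clamp makes zero starts
  fragile), then fitted cheaply with the previously kept slopes frozen;
  the few best candidates are re-screened by a warm-started *joint* refit
  with everything kept, which corrects the rank distortions that
  frozen-parameter screening produces among collinear candidates (without
  it, a collecting-duct arm can outrank the proximal-tubule arm whose
  signal it partially mimics). The round's winner is then refit jointly
  with a multi-start polish, so every accepted round's objective comes
  from a full joint refit and the final parameter vector is coherent.
  Screening every candidate by joint refit (`screen = "refit"`) or by the
  frozen screen alone (`"fixed"`) remains available.
* **Tie-breaking.** When linear and sigmoidal fits of the same candidate
  attain the same objective (within a relative tolerance of 10⁻³), the
  linear form wins — fewer parameters. With linear ground truth the
  sigmoid can approach but not beat the linear fit, so this rule keeps
  selection from decorating the model with unneeded steepness parameters.

## Synthetic data

The clinical observations behind the calibrated presets exist only as
published figures, so the generator stands in for them: it simulates the
three study designs —

* the ET-1 ramp (0.2/0.4/0.8 pmol/kg/min hour-blocks, 200 mmol/day sodium
  diet, maintained 25 mL/kg water load),
* the antagonist study (saline / BQ123 5 nmol/kg/min / BQ788 4
  nmol/kg/min, each followed by ET-1 4 pmol/kg/min from 30–50 min), and
* the VML588 dose-ranging study (0 / 0.05 / 0.2 / 0.4 mg/kg/hr with ET-1 1
  pmol/kg/min at 90–110 min, 30-min urine bins)

— under a known mechanism set and samples the model outputs at each
protocol's measurement times. Each reported value is the mean of `n`
subject replicates carrying multiplicative Gaussian noise of the given CV
(default 3%, with n = 6/6/9 subjects as in the source studies), so the
emitted standard error CV·value/√n is the actual sampling error of the
value — keeping the fitting weights statistically consistent with the
noise. Generation is deterministic given the seed and restores the
caller's RNG state.

What passing recovery tests on these data do and do not show: they
demonstrate that the estimation and selection machinery can recover the
generating mechanisms and magnitudes from study-shaped, noise-corrupted
data of realistic information content — not that the reference model is a
validated description of any individual patient, and not robustness to
model misspecification (the generator and the fitted model share
structure, deliberately). Between-subject variability, crossover
correlation and figure-digitization error are not emulated.

# Numerical choices

* Solver: `deSolve::lsoda` on a compiled C right-hand side, rtol 10⁻⁶ /
  atol 10⁻⁹; integration is segmented at dose on/off times so trajectories
  are piecewise smooth. An R implementation of the same right-hand side is
  kept as a reference; a test pins the two to within 10⁻⁴ relative on a
  three-dose protocol.
* Oral water loads are absorbed at a constant rate over 45 min rather than
  as an instantaneous bolus, keeping plasma sodium inside its
  physiological band.
* Degenerate situations are clamped, not fatal: negative net filtration
  pressure clamps GFR (and FENa is reported missing where GFR is zero),
  segmental reabsorption fractions are clamped to (0.01, 0.99/0.999),
  feedback signals to [0.05, 5], urine flow to ≥0.02 mL/min.
* Slope bounds for fitting are [−20, 20] (steepness [0.01, 100] pM);
  estimates at a bound are flagged.
* Problem sizes used in the shipped experiments: 196 observations across
  eight study arms; recovery fits use 1–2 optimizer starts and the
  selection run one screening start with a three-start joint refit per
  round. These were chosen as the smallest designs that exercise the full
  machinery; all are configurable upward.

## The stop rule at the noise floor

The selection stop rule accepts a round only when the objective falls by
at least 1% (configurable) and by more than the multistart spread of the
refit. With SE-based weights the objective at the generating model sits
near the chi-square floor (roughly the number of observations), so 1% of
the objective is about two units — the scale of a one-degree-of-freedom
chi-square fluctuation. Greedy selection that has already absorbed all
real structure is then still offered many residual candidates, and the
chance that some near-zero-slope arm clears the threshold on noise alone
is appreciable. In the packaged synthetic experiment the procedure
recovers all seven generating arms first and may then admit one such
spurious low-contribution arm (fitted slope of order 10^-3) that the
backward pass, using the same tolerance, retains. Users who want a
conservative final set should raise `min_rel_reduction` or inspect the
trace's per-round reductions; the default is kept at the permissive value
so that weak real mechanisms (the efferent ET_B arm contributes only a
few percent) are not silently discarded.

# Known limitations

* The reference kinetics are one self-consistent parameterization
  satisfying the constraints above, not a fit to kinetic data; absolute
  occupancies (hence slope magnitudes in per-pM units) are only meaningful
  relative to it.
* Antagonist-alone renal responses are exaggerated relative to clinical
  reports (see above).
* The linear clamp at zero creates flat objective regions for arms under
  full receptor blockade; the staged optimizer and multi-start mitigate
  but do not remove the resulting local-minimum risk.
* Female physiology, disease states, glucose handling/SGLT2 interactions,
  non-osmotic sodium storage and detailed RAAS pharmacology are out of
  scope.
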