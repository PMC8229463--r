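---
title: "A whole-body PBPK model for oral fexuprazan: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A whole-body PBPK model for oral fexuprazan: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fexupbpk)
```

Fexuprazan is a potassium-competitive acid blocker (P-CAB) given orally
for acid-related disorders. No intravenous clinical data exist for it, so
its absolute bioavailability and tissue exposure in humans cannot be
measured directly; they have to be reconstructed by a mechanistic model
fed with in vitro, preclinical and clinical oral data. `fexupbpk`
implements that reconstruction end to end: interspecies scaling of
distribution and clearance, a 13-compartment perfusion-limited whole-body
model, non-compartmental analysis, per-subject estimation of the two
parameters the mechanistic chain cannot supply, and a synthetic cohort
generator so that every stage can be verified without the original trial
data.

## Model structure

The body is represented by 11 tissue compartments (adipose, adrenal
gland, brain, heart, kidney, large intestine, liver, lung, small
intestine, spleen, stomach) plus venous and arterial blood pools, with an
absorption compartment feeding the liver via the portal vein. All
tissues are perfusion-limited, justified by fexuprazan's high Caco-2
permeability (comparable to propranolol). Amounts are in ng, volumes in
mL, flows in mL/min and time in min throughout.

For a non-eliminating tissue `T`,

$$V_T \frac{dC_T}{dt} = Q_T \left(C_{art} - \frac{C_T\,R}{K_{p,T}}\right),$$

where `R` is the blood-to-plasma concentration ratio and `Kp` the
equilibrium tissue-to-plasma partition coefficient; the term
`C_T R / Kp` is the emergent venous blood concentration of the tissue.
Stomach, spleen and both intestines drain into the liver (portal
circulation); adipose, adrenal gland, brain, heart, kidney and liver
drain into the venous pool. The liver additionally receives the
hepatic-arterial flow (total hepatic flow minus the portal sum), the
first-order absorption input `Ka · Xa`, and loses drug at rate
`CLu,int · fup · C_LI / Kp,LI` — clearance acting on the unbound liver
water concentration. The lung sits in series between the venous and
arterial pools at full cardiac output. The residual cardiac output
(`Q_RE = Q_CO − Σ` systemic tissue flows `≈ 1877 mL/min` for the default
physiology) is a pure arteriovenous shunt with no tissue mass behind it.

Reported "plasma concentration" is the venous amount divided by venous
volume and by `R`: the vascular pools propagate blood concentrations,
observations are plasma.

## Parameter provenance

* **Absorption.** `Ka` comes from the Caco-2 apparent permeability
  (165 nm/s) through the published log-linear Caco-2-to-jejunal
  correlation and the cylindrical-gut relation `Ka = 2 Peff / r` with
  `r = 1.75` cm, giving 0.0607 min⁻¹. The fraction absorbed `Fa` is not
  predictable from first principles for this compound and is an estimated
  parameter (pooled reference value 0.761). Oral doses enter the
  absorption compartment already multiplied by `Fa`; gut-wall extraction
  is assumed absent (`Fg = 1`).
* **Distribution.** Rat steady-state Kp values (AUC ratios in 11
  tissues) are scaled to humans by a single scalar chosen so that the
  Øie–Tozer volume
  `V_SS = V_p + V_{rbc} EP + Σ V_T Kp` matches the allometric
  human prediction; `EP = 1 + (R−1)/Hct`. The allometric law is an
  unweighted log–log least-squares fit to rat/monkey/dog V_SS
  (20.2, 9.17 and 12.6 L/kg at 0.25, 4 and 10 kg), which gives
  `V_SS(L) = 15.0·BW^0.8356` and 7.48 L/kg at 70 kg. Because the liver
  eliminates the drug, its AUC-ratio Kp understates the equilibrium
  partition coefficient by the availability factor, so the scaled liver
  Kp is divided by `1 − ER`. The plasma/erythrocyte split of blood volume
  uses the hematocrit (0.45).
* **Elimination.** Renal excretion is negligible (0.29–2.02% of dose),
  so elimination is hepatic. Recombinant-CYP3A4 kinetics of the two
  identified metabolites (M14, M11) are scaled to the whole liver with an
  inter-system extrapolation factor
  (`ISEF = 6100/(200·79) ≈ 0.39`, reported as 0.4), the microsomal
  CYP3A4 abundance (79 pmol/mg), MPPGL 39.79 mg/g and the 1800 g liver.
  The unbound intrinsic clearance is
  `CLu,int = Σ Vmax/(Km·fu,mic) + CLu,add`, with Km in µM numerically
  equal to nmol/mL so the ratio is a clearance in mL/min without any
  molecular-weight conversion. `CLu,add` — biliary plus unidentified
  pathways — is the second estimated parameter (pooled reference
  12.9 L/min). With the reference values the pathway fractions are
  18.5% (M14), 0.35% (M11) and 81.1% (CLu,add). Hepatic availability
  follows the well-stirred model on the blood scale,
  `Fh = Q_{LI} R / (Q_{LI} R + f_{up}\,CLu_{int})`, and
  `F = Fa · Fg · Fh ≈ 0.387` analytically.

Two deliberate interpretive choices are worth stating. First, the
intrinsic-clearance sum carries no separate biliary term beyond
`CLu,add`: the published pathway fractions are reproduced exactly by the
two enzymatic terms plus `CLu,add` alone, so any residual liver-water
clearance term is set to zero while `fu,liver = fup/Kp,liver` is still
computed and reported. Second, the well-stirred expression is evaluated
with the hepatic flow on the blood-concentration scale (`Q·R`); this is
the only reading that simultaneously reproduces the reference
bioavailability (≈38.5%) and the extraction-corrected liver Kp (≈303).

### Known tensions in the parameter chain

Solving the Øie–Tozer equation exactly with the default physiology and
rat Kp table gives a Kp scalar of 0.339 for the 7.48 L/kg target, not the
reference 0.371 (the reference analysis likely used an extended form with
protein-binding terms). Both are available: `solve_kp_scalar()` returns
the exact solver value, and the scaling chain (`derive_human_kp()`) can
be driven with either; the built-in human Kp map uses the reference
values as printed. Similarly, the small-intestine entry of the reference
human Kp table (124) does not equal scalar-times-rat (236); the printed
value is used as-is in the default parameter set, and the discrepancy is
asserted, not hidden, in the test suite.

## Numerics

The system is linear and time-invariant, so the classical fixed-step
fourth-order Runge–Kutta update is a constant one-step matrix
`P = I + hA + (hA)²/2 + (hA)³/6 + (hA)⁴/24`; `pbpk_simulate()` applies it
per step, which is bit-identical to naive RK4 stepping (asserted in the
tests) and fast enough that no compiled code is needed. A second path,
`pbpk_plasma_at()`, advances between dose events and sampling times with
binary powers of `P`, making per-subject fitting and cohort generation
essentially free of integration cost.

The default step is `dt = 0.5` min. The fastest process in the system is
the arterial pool turnover `Q_CO/V_art ≈ 3.0 min⁻¹`, which puts the RK4
stability boundary near 0.9 min: 0.5 min is comfortably inside, and
`convergence_check()` (which re-runs at `dt/2` and compares plasma
curves, flagging deviations above 0.1% of the peak) confirms step
adequacy at ≈3·10⁻⁵ for the default scenarios. The simulator floors
negative amounts at zero (warning if the undershoot exceeds 10⁻⁹ of the
dose) and warns explicitly when a too-large step produces non-finite
amounts. Dose events are instantaneous state increments snapped to the
integration grid (tolerance `dt/2`); the intravenous route is a bolus
into the venous pool. Mass balance — cumulative input equals system
content plus cumulative elimination — holds to ~10⁻¹⁴ relative because
the eliminated amount is carried as a state.

## Non-compartmental analysis

AUC uses the linear trapezoidal rule throughout, with linear
interpolation at window edges so the rule is exact for piecewise-linear
curves and additive over adjacent windows; on the dense simulation grid
the choice of linear versus log-linear trapezoids is immaterial. Moment
analysis regresses the last three positive-concentration points (more on
dense grids, user-adjustable) log-linearly for `λ_z` and extrapolates
AUC and AUMC to infinity; `V_SS = Dose·AUMC/AUC²` for IV profiles.

One caveat the tests document: for this model the plasma-moment `V_SS`
(≈316 L, computed exactly from the system matrix as
`AUC = −A^{-1}x_0`, `AUMC = A^{-2}x_0`) is far below the anatomical sum
`V_{blood}R + Σ V_T Kp ≈ 781 L`. This is not an integration artifact:
the liver is both the dominant volume term (Kp 303) and the eliminating
organ, and elimination outside the sampling compartment makes
moment-based volumes understate equilibrium volumes — the same
phenomenon the Kp extraction-ratio correction compensates for at the
parameterisation stage. The NCA is therefore validated against the exact
matrix oracle and against closed-form exponential curves, not against
the anatomical sum.

### Reference windows for the clinical summary metrics

The clinical studies report `AUC_last` without printing their sampling
schedules, so the analysis fixes windows once and records them in every
output: day-1 rows of the multiple-ascending-dose study use the 24-h
dosing interval; day-7 rows use the seventh interval (144–168 h); the
multi-ethnic study rows use 48-h windows after the first and after the
eighth once-daily dose. `AUC` is reported in ng·min/mL, the unit under
which the reference AUC and Cmax values are mutually consistent with a
linear model.

## Parameter estimation

`fit_subject()` estimates `Fa` and `CLu,add` per subject by least
squares (uniform weights by default; `1/y` and `1/y²` options) against
the subject's day-1 profile, with `Ka` fixed at its
permeability-predicted value. The model is linear in `Fa`, so for any
candidate `CLu,add` the optimal `Fa` is a closed-form (clamped) linear
least-squares coefficient; the remaining one-dimensional profile
objective over `CLu,add` is minimised by bounded derivative-free
golden-section search, started on three subintervals of the log-scale
range `[0, 100]` L/min to guard against local minima — on noiseless data
it is unimodal (asserted). Bounds: `Fa ∈ (0, 3]` (apparent fractions
above 1 are legitimate fit outputs and flagged), `CLu,add ∈ [0, 100]`
L/min. Degenerate inputs (all-zero profiles) return a flagged
non-converged result rather than an error. Estimates are invariant to a
joint rescaling of dose and concentrations, and noiseless synthetic
subjects are recovered to well under 1%.

`pool_and_test()` runs a one-way ANOVA of each parameter across dose
groups (α = 0.05) and recommends pooling to the grand mean when neither
differs — the statistical premise for treating the kinetics as linear
over 20–80 mg. Tukey's post-hoc comparisons are outside this package's
scope.

## Synthetic cohorts

`generate_cohort()` emulates the clinical designs: by default 8 subjects
per dose at 20/40/80 mg once daily, a rich Phase-1 schedule (0.25, 0.5,
1, 1.5, 2, 3, 4, 6, 8, 12, 24 h post dose), lognormal inter-individual
variability on `Fa` (CV 35%) and `CLu,add` (CV 50%) — magnitudes chosen
once to echo the dispersion of the reported per-subject estimates —
proportional residual error (CV 10%, plus an optional additive SD), and
an LLOQ of 0.1 ng/mL below which samples are dropped (never imputed, so
no negative concentration survives). A 24-subject-per-arm two-dose
variant of the second study design is a one-line change of the spec.
Draws are lognormal because PK parameters are positive and right-skewed;
the generator is deterministic under a seed and restores the caller's
RNG state.

What the generator deliberately does not emulate: food effects, dropout,
ethnic covariates, within-subject (inter-occasion) variability, and any
misspecification of the structural model itself. Recovery tests on these
cohorts therefore demonstrate estimator correctness under the model's
own assumptions — they cannot detect structural model error against real
data.

## Problem sizes used in the shipped checks

The packaged tests and the acceptance script simulate single doses over
24–48 h and repeated regimens over 7 days at `dt = 0.5` min, run the
oral/IV bioavailability comparison over 168 h, and repeat the
noisy-cohort recovery (24 subjects, 3 dose groups) over 20 seeds —
roughly a minute of compute in total, chosen so the whole verification
story stays interactive.

## Limitations

* `Fa` and `CLu,add` are top-down estimates; the model cannot explain
  *why* bioavailability is ≈38%, only decompose it consistently.
* Elimination is linearised (`Vmax/Km`); saturation above the studied
  dose range is not represented, and M14 formation (Km 0.093 µM) would
  saturate first.
* Perfusion-limited distribution and `Fg = 1` are assumptions inherited
  from the compound's permeability profile, not tested by the data.
* The mechanistic absorption cascade (dissolution, transit, gut
  metabolism) is collapsed into `Fa` and `Ka`.
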