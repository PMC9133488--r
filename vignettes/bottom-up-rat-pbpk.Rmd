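---
title: "Bottom-up rat PBPK from in vitro data: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bottom-up rat PBPK from in vitro data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rpbpk)
```

## The problem

Early pharmacokinetic characterisation consumes large numbers of laboratory
animals. A bottom-up physiologically based pharmacokinetic (PBPK) model
replaces the first in vivo rat study with a simulation built entirely from
in vitro measurements: physicochemistry (MW, logP, compound type, pKa),
blood binding (B/P, fu), absorption descriptors (PSA, HBD, or a measured
Papp) and metabolic stability (microsomal or hepatocyte CLint, or a Vmax/Km
pair). `rpbpk` implements that workflow for single oral doses in the rat,
together with the machinery used to judge it: two-fold fold-error scoring
against observed studies, R²/MAE/RMSE performance metrics, and fu × CLint
sensitivity grids. The packaged worked examples are seven classical CYP/UGT
probe substrates (phenacetin, tolbutamide, omeprazole, metoprolol,
chlorzoxazone, nifedipine, baicalein).

## Model structure

The simulated system has four drug-containing compartments plus bookkeeping
states, all in mg:

* **Gut lumen.** The oral dose starts here and leaves by first-order
  absorption (`ka`) into the enterocyte, competing with lumenal transit loss
  (`kt = 1 / transit time`). The fraction absorbed is `fa = ka / (ka + kt)`.
* **Enterocyte.** A single well-mixed cell compartment (volume
  `enterocyte_volume`). Drug leaves by perfusion-limited exit into portal
  blood at the villous blood flow `Qvilli`, and by gut-wall metabolism —
  linear (`CLint,gut`, scaled by total gut microsomal protein) or saturable
  Michaelis–Menten (`Vmax` scaled the same way and converted to mg/h via MW;
  `Km` converted to µg/ml via MW). Metabolism acts on the unbound enterocyte
  concentration with `fu,gut = 1` (no gut binding data exist for these
  compounds).
* **Liver.** A venous-equilibrium (perfusion-limited) compartment of
  plasma-referenced volume `Vliver × Kp,liver`. It receives the enterocyte
  outflow plus systemic blood at the hepatic blood flow `Qh` and eliminates
  at the scaled unbound intrinsic clearance. At quasi-steady state this
  wiring reproduces exactly the well-stirred liver model; when the
  parallel-tube or dispersion model is selected, the elimination coefficient
  is replaced by the effective intrinsic clearance that reproduces that
  model's extraction ratio, so the steady-state extraction matches the
  chosen model while the transient wiring stays compartmental.
* **Systemic.** A lumped compartment of volume `Vss − Vliver × Kp,liver`;
  its concentration is the reported plasma concentration. Blood flows carry
  `Q × B/P × Cplasma`.

Hepatic and gut first pass and the oral bioavailability identity
`F = fa × Fg × Fh` emerge from the structure rather than being imposed. The
intentionally minimal structure is the smallest one that produces both
first-pass sites and the dose-dependent gut extraction needed for
omeprazole's supra-proportional exposure.

### Absorption

Human effective jejunal permeability comes from either of two log-linear
models, both with coefficients in the physiology configuration rather than
code:

* descriptors: `log10 Peff(cm/s) = -2.546 - 0.011 PSA - 0.278 HBD`;
* monolayer assay: `log10 Peff(1e-4 cm/s) = 0.4926 log10 Papp(1e-6 cm/s) - 0.1454`.

Rat permeability follows by inverting the inter-species line
`Peff,human = 3.6 Peff,rat + 0.03` (10⁻⁴ cm/s), and the lumen is treated as
a cylinder of radius `r`, giving `ka = 2 Peff,rat / r`. A single gut
compartment with competing absorption and transit was chosen over a
multi-segment transit model; it reproduces the observed Tmax window
(0.2–2 h) for all seven probes and keeps `fa` an explicit closed form.
Absorption is assumed permeability-limited and transporter-free, which
restricts the model to BCS class II-like, passively absorbed compounds.

### Distribution

Tissue:plasma partition coefficients are predicted with the
tissue-composition framework of Rodgers & Rowland (the packaged
`tissue_composition_rat.csv` carries the source citation): ionisation-
weighted water terms, a neutral-lipid/phospholipid term driven by
`P = 10^logP` (with the vegetable-oil:water correction
`log Pvo:w = 1.115 logP - 1.35` in adipose, where octanol overstates
triglyceride affinity), an acidic-phospholipid binding term for
moderate-to-strong bases (pKa,base ≥ 7) whose association constant is
inferred from B/P and hematocrit, and an albumin-ratio term for acids,
neutrals and weak bases scaled by `(1/fu − 1)` after removing the plasma
lipid contribution. Negative inferred binding residuals are floored at zero
with a warning.

`Vss` sums `Kp × Vtissue` over the 11 packaged tissues, plus plasma, an
erythrocyte term from B/P, and a rest-of-body closure. The closure uses the
volume-weighted mean of the predicted tissue Kp values: a fixed Kp of 1
would add ~0.14 L/kg to every compound regardless of its binding, which is
physically inconsistent for highly bound acids whose predicted Kp is ~0.1 in
every explicit tissue. A global `kp_scalar` (default 1) multiplies all
tissue partition coefficients.

### Elimination

IVIVE scaling is conventional: microsomal CLint × MPPGL × liver weight,
hepatocyte CLint × HPGL × liver weight, divided by the incubation unbound
fraction; gut CLint (or Vmax) scales by the total gut microsomal protein.
Three liver models are available — well-stirred (default), parallel-tube,
and the two-parameter dispersion closed form with dispersion number 0.17 —
ordered `CLws ≤ CLdisp ≤ CLpt` for any clearance. Elimination is
metabolism-only: renal and biliary routes are deliberately absent, matching
the probe substrates' disposition.

## System parameters and their defaults

All physiology lives in `physiology.yaml` (units in the file):

| parameter | default | basis |
|---|---|---|
| body weight | 0.25 kg | standard male SD rat |
| liver weight | 9.15 g | 3.66% of body weight |
| hepatic blood flow | 0.828 L/h | 13.8 ml/min |
| MPPGL | 40 mg/g | published range ~30–60 |
| HPGL | 99 ×10⁶/g | published range ~96–135 |
| intestine radius | 0.18 cm | rat small intestine |
| SI transit time | 1.5 h | rat small-intestinal transit |
| plasma volume | 7.8 ml | 31.2 ml/kg |
| hematocrit | 0.46 | rat default |
| villous blood flow | 0.50 L/h | calibrated, see below |
| gut microsomal protein | 600 mg | calibrated, see below |

MPPGL and HPGL were fixed once, globally, within their published ranges so
that the liver-only probes track their reference predictions; they are never
adjusted per compound. The two gut first-pass scaling factors have no rat
literature consensus; they were calibrated once against the omeprazole dose
series (the only packaged compound whose gut extraction is saturable and
dose-resolved) and then frozen for every compound — metoprolol, nifedipine
and baicalein inherit them unchanged. pH values: plasma 7.4, intracellular
water 7.0, erythrocyte 7.22.

## Numerical choices

* Stiff-capable integration (`deSolve::lsoda`), rtol 1e-8, atol 1e-10 mg;
  output on a fixed 0.01 h grid over 24 h by default. Runs are
  deterministic: repeated simulations are byte-identical.
* Mass balance (all compartments + eliminated + unabsorbed = dose) is
  checked at every output point; the worst relative imbalance ships with the
  profile and stays far below 1e-6 of the dose.
* Cmax/Tmax are read from the grid maximum with local quadratic refinement
  through the three surrounding points (skipped at grid boundaries);
  AUC(0–t) is the linear trapezoid, truncatable at a study's last sampling
  time.
* Observed Tmax ranges ("0.33–0.50 h") are scored against the nearer bound
  with both bounds retained, matching how fold-error ranges are reported in
  validation tables; a prediction inside the range scores fold error 1.
* Sensitivity grids default to 21 × 21; for all-linear compounds the
  extremes provably sit at the grid corners (AUC ∝ 1/(fu × CLint)), so the
  resolution affects only the interior map, not the reported fold ranges.
* An analytic Bateman profile is packaged as the reduction-limit oracle: as
  villous flow → ∞, liver volume → 0 and gut metabolism → 0, the four-
  compartment system collapses to a one-compartment first-order oral model
  with absorption rate `ka + kt` and availability `fa × Fh`; the ODE matches
  the closed form to < 1e-6 µg/ml there.

## The synthetic-data generator

The validation layer needs observed studies; the generator emulates the
statistical structure of sparse literature PK studies so that layer is
testable without animal data. Per replicate study it applies multiplicative
log-normal jitter (default geometric CV 30%) to fu and hepatic CLint — the
two inputs whose literature spreads dominate the sensitivity analysis —
simulates, samples a sparse schedule (default 0.083–24 h, 9 points), adds
proportional log-normal residual noise (default CV 20%), and derives
Tmax/Cmax/AUC from the sampled points exactly as a literature study would
(no refinement, trapezoid over the schedule). The un-jittered model
evaluated on the same schedule is returned as truth, so with both CVs at 0
the pipeline returns fold errors of exactly 1 and R² = 1, MAE = RMSE = 0.
What the generator does **not** emulate: rat strain and formulation effects,
correlated fu–CLint errors, assay-specific bias, and below-limit-of-
quantification censoring — so green synthetic-pipeline tests demonstrate
the correctness of the machinery, not real-data accuracy.

`recover_clint_from_auc()` closes the loop: one-dimensional root finding on
the simulator recovers the generating CLint from a noiseless synthetic AUC
to well under 1%, and to ~10% median error under 20% residual noise.

## Known limitations

* Liver models beyond well-stirred alter only the steady-state extraction;
  intra-organ concentration gradients are not resolved in the transient.
* No active transport, efflux, enterohepatic recycling, stomach compartment,
  multiple dosing or IV route.
* Nifedipine's concentration-tiered hepatic CLint is collapsed to its single
  median linear value, as in the workflow this package reproduces.
* The enterocyte exit is perfusion-limited; a permeability-limited
  basolateral membrane would slow gut transit of low-permeability compounds
  and is not modelled.
* Predictions inherit the full uncertainty of the in vitro inputs — the
  packaged sensitivity ranges translate literature fu/CLint spreads into
  up to ~13-fold AUC uncertainty for phenacetin and more for nifedipine or
  chlorzoxazone. The sensitivity grid, not the point prediction, is the
  honest output of a bottom-up model.

## Problem sizes used in the shipped checks

The packaged tests and the acceptance script run entirely at desk scale:
24 h simulations on a 0.01 h grid (2 401 points), sensitivity grids up to
21 × 21 with corner-determined summaries computed on coarser grids, 100–500
draw property sweeps for the virtual-compound and noise models, and a few
hundred Monte-Carlo replicates for the noise-expectation checks.
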