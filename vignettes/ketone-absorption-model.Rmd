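---
title: "A systems model of ketone monoester absorption and its in silico knockouts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A systems model of ketone monoester absorption and its in silico knockouts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Oral ingestion of the ketone monoester (R)-3-hydroxybutyl
(R)-3-hydroxybutyrate raises blood d-beta-hydroxybutyrate (BHB) far above
the normal endogenous range (< 0.5 mM), which is of therapeutic interest
for neurological disease. The kinetics are awkward: the ester hydrolyses
along the whole gut, BHB is carried by saturable monocarboxylate
transporters (MCTs) whose expression varies down the gut, disposition is
nonlinear, and circulating ketones feed back on their own endogenous
production. `ketoabsorb` implements a whole-body compartmental model of
this system whose purpose is *mechanism probing*: any transport or
reaction process can be knocked out in silico, and the knockout's
influence on blood BHB exposure is quantified.

## Model structure

The model tracks amounts (mmol) in 37 states across five physiological
components:

* **Gut** — four sequential lumen segments (upper/lower proximal,
  upper/lower distal), each holding ester, butanediol and BHB, chained
  by first-order transit that ends in a faeces sink. Ester hydrolyses in
  every segment into butanediol + BHB (1:1:1). All three species can be
  absorbed passively into the portal compartment. In the three
  transporter-expressing segments an enterocyte BHB state mediates active
  absorption: apical uptake by MCT1 (low affinity, high capacity) and
  SMCT1 (high affinity, low capacity) in parallel, then basolateral
  export by MCT4. Carrier capacity (`vmax`) increases from proximal to
  distal segments, mirroring reported expression gradients; the builder
  asserts this monotonicity.
* **Portal** — first-order transfer of absorbed material to the liver.
* **Liver** — ester hydrolysis, butanediol conversion to BHB,
  reversible BHB/AcAc interconversion, irreversible AcAc decarboxylation
  to acetone, and zero-order endogenous AcAc production under saturable
  negative feedback. BHB and AcAc exchange with blood through a shared
  MCT1 carrier; other species move passively.
* **Blood** — ester and butanediol metabolism, AcAc decarboxylation,
  and a lumped "other" state (glucose, insulin, ...) that contributes to
  the feedback signal. BHB/AcAc exchange with tissues through MCT1 and
  MCT2 in parallel.
* **Tissues** — lumped consumers: BHB and AcAc are converted to
  acetyl-CoA (a consumption sink, standing for the Krebs cycle) and a
  small fraction leaves through renal excretion; acetone is exhaled
  (excretion sink).

Every process is one of four rate laws (amount-based; compartment
volumes never enter the kinetics, exactly as the Michaelis constant is
defined as the *amount* at half-maximal velocity):

* first order: \(J = k A\);
* saturable: \(J = V_{max} A / (k_m + A)\);
* saturable with competitive inhibition by the partner ketone sharing
  the carrier: \(J = V_{max} A_i / (k_m^i (1 + A_i/k_m^i + A_j/k_m^j))\),
  implemented in the algebraically identical form
  \(V_{max} A_i/(k_m^i + A_i + (k_m^i/k_m^j) A_j)\) so that it reduces
  *exactly* to the saturable law at \(A_j = 0\);
* zero order with saturable feedback:
  \(J = R_0 (1 - I_{max} S/(IC_{50} + S))\), where
  \(S = \sum_k w_k A_k\) over blood BHB, blood AcAc and the lumped
  "other" state.

The feedback form deserves a note: the requirement is only that
inhibition of endogenous production is *saturable*. We adopt the
simplest such law (an Imax model on the weighted sum of circulating
inhibitor amounts, weights defaulting to 1 and zeroable per state) and
isolate it behind `feedback_law()` so an alternative functional form can
be swapped in without touching the network code.

Mass bookkeeping is stoichiometric: each process carries a product map
with integer coefficients (hydrolysis of 1 mmol ester credits 1 mmol
butanediol *and* 1 mmol BHB), and the ester counts two mole-equivalents.
Processes entering sink states deposit mole-equivalents, so with
endogenous production disabled the weighted total is conserved exactly —
this is a tested invariant, not an aspiration.

## The knockout machinery

Every process carries an `indicator` gate (1 = operational, 0 = not).
Knockouts flip indicators; they never delete processes, so a gated model
is structurally identical to the full model and gating is exactly
equivalent to deletion (also a tested invariant). Ten gut variants are
catalogued: passive-diffusion knockouts in each of the four segments
(affecting ester, butanediol and BHB absorption into portal — not
transit, not hydrolysis, which are not absorption processes) and
apical/basolateral active-transport knockouts in each of the three
transporter-expressing segments (affecting BHB only). Fifteen
combination sets group these variants into process- and region-level
experiments, up to whole-gut passive, whole-gut active, whole proximal
and whole distal knockouts.

Influence is quantified from the blood BHB concentration \(C(t)\) on the
dense simulation grid over the 6 h observation window:

* \(AUC\) by the linear trapezoid, **without** baseline subtraction.
  Total exposure is the right basis here: the fractional statistic
  \(AUC_{fraction} = 1 - AUC_{knockout}/AUC_{full}\) then has the
  published interpretation (1 = knockout removed all absorption; 0 = no
  contribution; negative values are possible and meaningful — removing a
  proximal pathway can push material to distal segments that absorb it),
  and the endogenous floor keeps \(AUC_{fraction} < 1\) whenever
  production is positive.
* \(T_{max}\) on the dense grid (ties broken to the earliest time, a
  boundary maximum is flagged), and the shift
  \(T_{max,knockout} - T_{max,full}\).

## Parameters

The fixture ships 101 named parameters with units and a provenance tag
(`literature`, `scaled`, `estimated`, `fixture-default`). The choices
that matter most:

* Transit constants 2.5, 1.5, 1.0, 0.35 /h down the four segments
  (fasted gastric emptying through colonic transit on a coarse scale).
* Gut carrier affinities: MCT1/MCT4 are parameterised low-affinity,
  high-capacity (`km` 300 mmol) and SMCT1 high-affinity, low-capacity
  (`km` 1 mmol); capacities rise distally (e.g. apical MCT1 `vmax` 20,
  200, 240 mmol/h). With these values gut uptake stays near-linear over
  the studied dose range, while systemic disposition (tissue MCT1 `km`
  20 mmol) is the saturable step. This combination — together with the
  dilution of the fractional statistic by the endogenous baseline at low
  dose — is what produces the dose-dependent absorption pattern: distal
  and active contributions to exposure grow with dose.
* Endogenous production 6 mmol/h AcAc with `imax` 0.8 and `ic50` 8 mmol,
  giving a baseline blood BHB of ~0.046 mM (normal range, above the
  0.02 mM assay LLOQ).
* Body weight 70 kg, blood volume 5 L; doses are given in mg/kg of the
  monoester (molar mass 176.212 g/mol), so 192 and 573 mg/kg convert to
  76.27 and 227.6 mmol deposited in the upper proximal lumen.

The same fixture schema accepts an externally supplied full parameter
table (e.g. a published supplementary listing) via `load_fixture()`, for
exact-reproduction runs; the packaged values are a calibrated default,
not a re-derivation of any published table. The canonical 37-state
decomposition is this package's own; a source model enumerating more
states can be loaded through the same schema-shaped interface.

## Calibration

Free parameters are estimated by extended least squares against
mean concentration-time data at the two dose levels:
\(\sum_{d,t} (y - \hat y)^2/g + \ln g\) with the combined-error variance
model \(g = (a + b\,\hat y)^2\). Observations below the LLOQ are
excluded. Optimisation is bound-constrained (L-BFGS-B) with seeded
log-uniform multistart (default 5 starts) guarding against local
minima; a failed simulation inside the objective returns a large finite
penalty so the optimiser can retreat. For noise-free recovery
experiments the additive-only weighting (\(b = 0\)) is used: the
log-variance term of ELS is informative only when there is residual
noise to model, and with \(b > 0\) it introduces a small finite-sample
shrinkage that has nothing to estimate on noise-free data.

Local sensitivity uses normalised central differences (1% step,
root-mean-square elasticity over the curve); it ranks candidates for the
free set. The blood-volume elasticity is exactly -1 (a pure output
scaling), which doubles as a self-check of the machinery.

## The synthetic study generator

No clinical dataset is shipped; `generate_dataset()` stands in for it.
It emulates a balanced repeated-measures design: per dose, `n_subjects`
individuals are each sampled at every time point. Noise has three
components: a subject-level proportional effect (CV 15%) shared across a
subject's samples — this is what a repeated-measures design implies and
what makes the mean curve deviate *coherently* from the truth — plus an
observation-level proportional component (CV 10%) and an additive assay
term (SD 0.02 mM). Individual draws below the LLOQ are censored before
the per-time mean and SEM are formed; fully censored time points are
dropped with a warning. Default sampling: 0, 0.25, 0.5, 0.75, 1, 1.5, 2,
3, 4, 6 h — dense early to resolve the peak of an oral dose.

What passing tests on these data do and do not show: the generator
reproduces the *structural* features of the reference data (non-zero
sub-0.5 mM baseline, single early peak, dose-monotone and supra-linear
peaks, LLOQ behaviour), so calibration and assessment code paths are
exercised realistically. It does not emulate real between-occasion
variability, non-normal assay error, dropout, or the four intermediate
dose levels of the source clinical study, so quantitative agreement with
any real dataset is out of reach by design.

## Numerical choices

* Solver: `deSolve::lsoda`, `rtol` 1e-8, `atol` 1e-10 mmol; saturable
  terms make the system moderately stiff near carrier saturation.
  Amounts are clamped at zero inside the right-hand side so transient
  solver undershoot cannot feed negative amounts into the rate laws.
* Baseline by pre-integration of the undosed system in 100 h blocks
  until the largest non-sink derivative falls below 1e-9 mmol/h (cap
  1000 h), rather than an algebraic solve — robust to the feedback
  nonlinearity, and verified to be start-point independent. Sinks grow
  linearly at steady state and are excluded from the residual.
* Output grid 0-6 h at 0.01 h; AUC and Tmax are computed on this grid
  (Tmax tie-break: earliest).
* Validation is strict at assembly: dangling references, non-absorbing
  sinks and fate partitions whose fractions do not sum to 1 are all
  build errors; simulation never sees an invalid model.
* Problem sizes used in the shipped tests: 37-state simulations over
  0-6 h; recovery fits with 20 observations (2 doses x 10 times), 1-3
  free parameters, multistart up to 5; the replicate bias study uses 20
  seeded single-parameter refits.

## Known limitations

* The gut is a chain of well-mixed segments, not a spatially continuous
  tube; segment boundaries are nominal, not anatomical.
* One mean individual: no inter-individual variability or mixed-effects
  layer; body weight enters only through the dose conversion.
* The model's parameters are globally non-identifiable from blood BHB
  alone; the calibration machinery estimates small free subsets against
  rich synthetic data and makes no uncertainty claims.
* Acetone leaves by a lumped first-order exhalation step; no breath
  kinetics. AcAc first appears in the liver; the gut handles only
  ester, butanediol and BHB.
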