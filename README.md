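# ketoabsorb

Systems-pharmacology model of the gastrointestinal absorption and
catabolism of the ketone monoester (R)-3-hydroxybutyl
(R)-3-hydroxybutyrate, with *in silico* knockout machinery for probing
where and how d-beta-hydroxybutyrate (BHB) is absorbed.

## The problem and who this is for

Oral ketone esters raise blood BHB to therapeutically interesting levels
(> 1 mM against a normal endogenous background of < 0.5 mM), but the
absorption process is mechanistically tangled: the ester hydrolyses along
the whole gut, BHB is carried by saturable monocarboxylate transporters
(MCT1, SMCT1 apically; MCT4 basolaterally) whose capacity increases from
proximal to distal gut, disposition is nonlinear, and circulating ketones
feed back on endogenous ketogenesis. Separating passive from
carrier-mediated absorption, or proximal from distal gut, is difficult or
impossible experimentally. This package is for modellers who want to do
it *in silico*: every transport or reaction process in the model carries
an indicator gate, and "knocking out" a process or a gut region is a
one-call clone of the model.

## The model in brief

Amounts `A_i` (mmol) evolve as `dA_i/dt = f_i,a * J_i(A) * A_i` summed
over processes, where the flux law `J` is first order (`k`), saturable
(`Vmax * A/(km + A)`, with `km` an amount), competitive between BHB and
AcAc sharing a carrier
(`Vmax * A_i / (km_i * (1 + A_i/km_i + A_j/km_j))`), or zero order under
saturable feedback inhibition (`R0 * (1 - Imax * S/(IC50 + S))`). The
network has 37 states in 5 components — four gut lumen segments (ester,
butanediol, BHB) with enterocyte BHB states in the three
transporter-expressing segments, portal, liver, blood (including a
lumped feedback state for glucose/insulin-like factors), tissues, and
faeces/consumption/excretion sinks.

Knockout influence is quantified by the fractional area under the blood
BHB curve, `AUC_fraction = 1 - AUC_knockout / AUC_full` (1 = the
knocked-out pathway carried all absorption, 0 = none, negative values =
removal rerouted material to more productive sites), and by the shift in
the time of peak concentration, `Tmax_knockout - Tmax_full`.

The packaged parameter fixture (101 parameters, each tagged
`literature` / `scaled` / `estimated` / `fixture-default`) is calibrated
so that the model reproduces the qualitative reference behaviour: a
single early post-dose peak, dose-dependent nonlinearity between
192 and 573 mg/kg, an endogenous baseline below 0.5 mM, and distal/active
contributions to exposure that grow with dose. Extended-least-squares
calibration, local sensitivity analysis and a synthetic clinical-study
generator (mean +/- SEM, balanced design, LLOQ censoring) round out the
pipeline.

## Worked example

```r
library(ketoabsorb)

model <- build_ketone_model(default_fixture())
model
#> keto_model: 37 states, 80 processes, 5 components (gut, portal, liver, blood, tissues)

baseline <- equilibrate(model)          # endogenous steady state
sim <- run_dose(model, 192, baseline = baseline)   # 192 mg/kg oral dose
sim
#> keto_sim: 601 time points over [0, 6] h, 37 states
#>   blood BHB: baseline 0.046 mM, peak 2.216 mM at t = 1.72 h

rep3 <- assess_knockouts(model, sets = c(12, 13, 15))
rep3[c("set", "dose_mg_per_kg", "auc_full", "auc_knockout",
       "auc_fraction", "tmax_shift")]
#>  set dose_mg_per_kg auc_full auc_knockout auc_fraction tmax_shift
#>   12            192      7.1         3.46        0.513       1.47
#>   12            573     35.3        10.99        0.688       0.67
#>   13            192      7.1         5.76        0.189      -0.25
#>   13            573     35.3        26.49        0.249      -0.58
#>   15            192      7.1         4.69        0.339      -0.36
#>   15            573     35.3        20.04        0.432      -0.92
```

Reading the table: set 12 knocks out passive diffusion along the whole
gut — half to two thirds of exposure vanishes and the peak arrives later
(positive Tmax shift), so passive diffusion dominates early absorption.
Set 13 (all active transport) and set 15 (whole distal gut) matter more
at 573 than at 192 mg/kg — low doses are absorbed mostly proximally and
passively, high doses recruit distal carrier-mediated uptake — and their
knockouts pull the peak *earlier* (negative shift) because the late,
distal portion of the input is what they remove.

A command-line surface wraps the same functions
(`inst/cli/keto.R simulate|knockout|assess|fit|synth|sensitivity`); each
run writes a `manifest.json` with the package version, seed and full
configuration, from which the output directory is reproducible.

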