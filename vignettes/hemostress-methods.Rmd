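---
title: "Noninvasive hemodynamics at rest and stress: models and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Noninvasive hemodynamics at rest and stress: models and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemostress)
```

## The problem

A stress echocardiogram usually reports wall motion and ejection fraction,
yet the measurements already on the worksheet — heart rate, cuff blood
pressure, left ventricular end-diastolic and end-systolic volumes, a handful
of Doppler velocities and a diastolic-time estimate — determine a far richer
hemodynamic description: cardiac output and systemic vascular resistance,
ventricular and arterial elastance and their ratio (ventricular-arterial
coupling), pulmonary pressures and resistances from regurgitant jets, and
diastolic function through E/e′ and the diastolic mean filling rate.
`hemostress` is the calculation engine for that panel: it takes per-stage
measurement records (rest, optional intermediates, peak), derives every
parameter it can, pairs rest and peak into a calculated-results sheet with
absolute and percent changes, and classifies the response to stress.

## The model, block by block

**Systemic block.** With weight $W$ (kg), height $H$ (cm), volumes in mL and
pressures in mmHg:

- $\mathrm{BSA} = \sqrt{WH/3600}$ (Mosteller; the Haycock power form
  $0.024265\,W^{0.5378}H^{0.3964}$ is available via
  `hemo_config(bsa_method = "power")`),
- $\mathrm{SV} = \mathrm{EDV} - \mathrm{ESV}$, $\mathrm{SVi} = \mathrm{SV}/\mathrm{BSA}$,
- $\mathrm{CO} = \mathrm{HR}\cdot\mathrm{SV}/1000$, $\mathrm{CI} = \mathrm{CO}/\mathrm{BSA}$,
- $\mathrm{MAP} = (\mathrm{SBP}-\mathrm{DBP})/3 + \mathrm{DBP}$, $\mathrm{PP} = \mathrm{SBP}-\mathrm{DBP}$,
- $\mathrm{ESP} = 0.9\,\mathrm{SBP}$ — the cuff surrogate for left
  ventricular end-systolic pressure,
- $E_{es}\mathrm{i} = \mathrm{ESP}/(\mathrm{ESV}/\mathrm{BSA})$,
  $E_{a}\mathrm{i} = \mathrm{ESP}/(\mathrm{SV}/\mathrm{BSA})$,
- $\mathrm{VAC} = E_{es}\mathrm{i}/E_{a}\mathrm{i} = \mathrm{SV}/\mathrm{ESV}$
  (the pressure cancels, so coupling is independent of the cuff reading),
- $\mathrm{SVR} = 80(\mathrm{MAP}-5)/\mathrm{CO}$ (5 mmHg approximates right
  atrial pressure), and arterial compliance $\mathrm{SV}/\mathrm{PP}$.

**Right-heart block.** Right atrial pressure comes from a categorical lookup
on inferior vena cava diameter and sniff collapse (3, 8 or 15 mmHg); the
simplified Bernoulli relation $\Delta P = 4v^2$ converts the tricuspid and
pulmonary regurgitant jet velocities into systolic and diastolic pulmonary
pressures; mean pulmonary pressure is estimated two ways (the
$\tfrac13\mathrm{SPAP}+\tfrac23\mathrm{PADP}$ weighting and the
peak-early-regurgitation jet) so their agreement can be checked; pulmonary
vascular resistance is estimated both by the catheterization formula
$80(\mathrm{mPAP}-\mathrm{PCWP})/\mathrm{CO}$ (with the E/e′-derived wedge
estimate when no measured value exists) and by the Doppler ratio
$10\,\mathrm{TRV}/\mathrm{TVI}_{RVOT}$ in Wood units; capacitance is
$\mathrm{SV}/\mathrm{PAPP}$.

**Diastolic block.** Septal E/e′ classifies filling pressure (normal < 8,
elevated > 15), the wedge pressure estimate is $1.24\,(E/e') + 1.9$ mmHg, and
the diastolic mean filling rate is
$\mathrm{SVi}/t_{dias}\times 1000$ (mL·m⁻²·s⁻¹) with the *cardiological*
diastolic time (second-to-first heart sound interval, sensor- or
M-mode-derived).

**Cross-stage analysis.** The force-frequency relation plots raw systolic
cuff pressure over end-systolic volume index against heart rate; its maximum
defines the critical heart rate. The rest-to-peak change in stroke volume is
decomposed into an end-diastolic (Frank-Starling) and an end-systolic
(inotropic) contribution that sum to 100%.

## Conventions and open choices

Several printed conventions are ambiguous or conflicting; the package's
resolutions are:

- **Elastance indexing.** "Indexed" elastance is sometimes written as the
  raw ratio divided by BSA and sometimes as pressure over the volume
  *index*. Only the latter reproduces the standard normal averages
  ($E_{es}\mathrm{i}$ about 4.5 rising to 14.5, $E_{a}\mathrm{i}$ 2.3 rising
  to 3.2 mmHg·mL⁻¹·m⁻²), so pressure/(volume/BSA) is the default;
  `hemo_config(elastance_indexing = "divide_bsa")` exposes the other
  reading. VAC is always computed as SV/ESV.
- **Elastance pressure.** Default ESP $= 0.9\,$SBP; raw SBP via
  `hemo_config(ees_pressure = "sbp")` (the convention used for the
  force-frequency series, which always uses raw SBP).
- **Doppler mean pulmonary pressure.** The two printed variants differ by
  the RAP term; the default adds RAP
  (`hemo_config(mpap_doppler_add_rap = FALSE)` to omit), and the report
  notes which form was used.
- **RAP lookup boundaries.** The published table leaves diameter exactly
  2.1 cm and collapse exactly 50% unassigned; the package assigns
  $\le 2.1$ cm to the small-diameter branch and $\ge 50\%$ to the collapsing
  branch, making the lookup total with values in {3, 8, 15} mmHg.
- **Resistance units.** 1 Wood unit = 80 dyne·s·cm⁻⁵ = 8 MPa·s/m³; hence
  dyn→MPa·s/m³ divides by 10 (the dimensionally consistent factor, matching
  the usual printed ranges 900–1300 dyn = 90–130 MPa·s/m³, although a
  divide-by-8 rule is sometimes misprinted). Conversions route through Wood
  units so round trips are exact.
- **Cycle length rounding.** $60000/\mathrm{HR}$ rounded half-away-from-zero
  to whole ms. Published tables occasionally print 666 ms at 90 bpm and
  463 ms at 130 bpm; these are treated as typos (the rule gives 667 and
  462).
- **Indeterminate bands.** E/e′ between 8 and 15 has no published class and
  is labelled indeterminate, as is a tricuspid E/A in [0.8, 2.1] with
  E/E′ ≤ 6 and no hepatic-vein data (the rule gives no positive grade
  there). E/A band edges 0.8 and 2.1 belong to the middle band; the E/E′
  criterion is strict (> 6).
- **Force-frequency taxonomy.** Only two shapes are classically defined
  (up-sloping; flat-or-negative). A peak value above baseline but at or
  below an intermediate maximum is labelled *biphasic*, with the critical
  heart rate at the interior maximum; ties take the earliest stage.
- **Resting reference bands.** Normal ranges for SV, CO, CI, MAP, SVR and
  PVR are resting ranges; the engine applies them as flags on the rest stage
  only (a cardiac output of 13 L/min at peak exercise is physiology, not an
  alarm). Stress-specific cutoffs (exercise SPAP ≥ 43 mmHg, or > 60 mmHg for
  athletes/over-55; RVSP > 40 mmHg; TR velocity > 2.9 m/s; reversed D/S
  ratio) always apply. All flags are advisory; the engine never refuses
  out-of-range physiology.
- **mPAP consistency tolerance.** 5 mmHg by default (not a published value;
  configurable via `hemo_config(mpap_tolerance = )`).
- **Input redundancy.** Only the TR jet *velocity* is accepted; the gradient
  is always derived as $4v^2$, avoiding inconsistent duplicate inputs.

Missing optional inputs never abort a case: each dependent parameter is
retained on the sheet with an explicit `n/c (missing <field>)` reason, so
every panel row appears exactly once, valued or explained.

## The synthetic training cases

`make_fixture(profile, seed)` builds three-stage cases *backwards*: target
elastance indices and coupling are drawn with ±5% seeded jitter around the
published normal averages (4.5→14.5 and 2.3→3.2 mmHg·mL⁻¹·m⁻², coupling
about 1.9→4.5) or the dilated-cardiomyopathy pattern (coupling 0.38–0.43 at
rest rising only to 0.44–0.49 against a raised arterial elastance), and the
raw volumes are solved algebraically from cuff pressure and BSA. Diastolic
times are solved from a target rest-to-peak filling-rate ratio (about 3 for
normal, 1.5–1.8 for DCM); jet velocities, IVC geometry and RVOT integrals
are drawn from profile-typical ranges. The DCM intermediate stage is given a
contractility value 12% above peak, producing a biphasic force-frequency
relation with an interior critical heart rate.

By construction the qualitative contracts hold for every seed — that is the
point of a training phantom, and the contract tests sweep 50 consecutive
seeds per profile to guard the construction. What the fixtures do *not*
emulate: measurement noise and inter-observer variability, E/A fusion at
tachycardia, arrhythmia, valvular disease, and any correlation structure of
real populations. Passing fixture contracts therefore demonstrates the
engine's arithmetic and classification logic, not clinical performance on
real data. One consequence of building from the published averages is that
the normal stroke volume index is nearly flat from rest to peak (47 vs 45
mL/m²), so the stroke-volume decomposition — a ratio of small differences —
is ill-conditioned on normal fixtures; it is well behaved whenever the
stroke volume actually changes.

## Numerical notes

All derived values are kept at full double precision internally; only report
rendering rounds (pressures 0–1 decimals, elastances and ratios 2, percent
changes 1). Percent change with a zero rest value yields a not-computable
marker rather than an error. Degenerate inputs are rejected at the algebra's
own boundaries: EDV ≤ ESV, SBP ≤ DBP, zero denominators, negative
velocities, and a PA pulse pressure that would come out negative
(inconsistent jets) are domain errors in the scalar functions and
not-computable rows in the panel. Unit-conversion factors are rational and
applied via Wood units, making round trips bit-exact. Reports are
byte-deterministic for identical inputs.

## Limitations

The engine computes from, and is only as good as, noninvasive surrogates:
the 0.9·SBP end-systolic pressure applies to central rather than brachial
recordings; the cardiological diastolic time overestimates the filling time
(the bias largely cancels in rest-to-peak comparisons); the Doppler PVR
estimator is unreliable above 8 Wood units and is flagged as such; and no
Doppler-trace digitization, image segmentation or workload-protocol modeling
is attempted — measurements enter the engine as numbers on the worksheet.
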