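# hemostress

Noninvasive hemodynamic panels for the rest/stress echocardiography lab.

A stress echo worksheet already contains everything needed for a complete
hemodynamic characterization — heart rate, cuff blood pressure, 3D- or
2D-derived left ventricular volumes, a few Doppler jet velocities, and a
diastolic-time estimate — but the thirty-odd derived parameters are tedious
and error-prone to calculate by hand, twice (rest and peak), plus their
changes. `hemostress` is the calculation engine for that panel, aimed at
echocardiographers, physiology trainees, and anyone building or auditing
stress-hemodynamics worksheets.

## What it computes

For each stage it derives the systemic block

- BSA = √(weight·height/3600), SV = EDV − ESV (+ index), CO = HR·SV (+ index)
- MAP = (SBP − DBP)/3 + DBP, PP, ESP = 0.9·SBP
- LV elastance index *E*es·i = ESP/(ESV/BSA), arterial elastance index
  *E*a·i = ESP/(SV/BSA), ventricular-arterial coupling
  VAC = *E*es·i/*E*a·i = SV/ESV
- SVR = 80·(MAP − 5)/CO, arterial compliance SV/PP

the right-heart block (right atrial pressure from IVC diameter/collapse;
simplified-Bernoulli SPAP, PADP and both mean-PA-pressure estimates; PA
pulse pressure; pulmonary vascular resistance by both the catheterization
formula and the Doppler TRV/TVI ratio in Wood units; capacitance SV/PAPP),
and the diastolic block (septal and averaged E/e′, the wedge-pressure
estimate 1.24·E/e′ + 1.9, the diastolic mean filling rate SVi/t·1000, D/S
time ratio, right ventricular diastolic grading).

Across stages it builds the calculated-results sheet with absolute and
percent rest→peak changes, classifies the force-frequency relation
(SP/ESVi vs heart rate: up-sloping / biphasic / flat-or-negative) with its
critical heart rate, decomposes the stroke-volume response into
end-diastolic vs end-systolic contributions, and cross-checks the two mean
pulmonary pressure estimates.

## Worked example

```r
library(hemostress)

case <- make_fixture("normal", seed = 1)   # seeded synthetic training case
comp <- stress_comparison(case)

glance(comp)[, c("vac_rest", "vac_peak", "svr_pct_change",
                 "filling_rate_ratio", "ffr_shape")]
#> # A tibble: 1 × 5
#>   vac_rest vac_peak svr_pct_change filling_rate_ratio ffr_shape
#>      <dbl>    <dbl>          <dbl>              <dbl> <chr>
#> 1     2.04     4.47          -47.5               3.05 up_sloping
```

Coupling rises from 2.04 to 4.47 (contractility outpacing arterial load),
systemic resistance falls 47.5% with exercise vasodilation, the diastolic
mean filling rate triples, and the force-frequency relation is up-sloping —
the healthy stress response. The full sheet (excerpt):

```r
cat(render_report(comp, "text"))
#> parameter   algorithm                     rest   peak   unit          % change
#> bsa         sqrt(weight * height / 3600)  1.84   1.84   m^2           0.0
#> sv          EDV - ESV                     89.1   89.9   mL            0.9
#> co          HR * SV / 1000                6.50   14.83  L/min         128.1
#> map         (SBP - DBP)/3 + DBP           89.3   106.0  mmHg          18.7
#> esp         0.9 * SBP                     108.0  151.2  mmHg          40.0
#> ees_index   ESP / (ESV / BSA)             4.56   13.85  mmHg/mL/m^2   203.7
#> ea_index    ESP / (SV / BSA)              2.23   3.10   mmHg/mL/m^2   38.8
#> vac         Ees/Ea = SV / ESV             2.04   4.47   ratio         118.9
#> svr         80 * (MAP - 5) / CO           1037   545    dyne.s.cm^-5  -47.5
#> ...
```

Cases load from JSON or CSV (`read_case()`), validate with report-only
plausibility checks (`validate_case()`), and render to text/CSV/JSON
(`render_report()`) or per-parameter heart-rate trend figures
(`plot_trends()`, `autoplot()`). A `"dcm"` fixture profile generates the
dilated-cardiomyopathy contrast (blunted coupling below 0.5, modest
resistance response, biphasic force-frequency relation). A thin command-line
launcher ships in `inst/cli/`:

```sh
Rscript inst/cli/hemostress fixture --profile normal --seed 1 --out case.json
Rscript inst/cli/hemostress calc --input case.json --format text
```

See `vignette` source `vignettes/hemostress-methods.Rmd` for the model
details, conventions (elastance indexing, RAP lookup boundaries, unit
conversions) and the fixture construction.

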