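# fsvpet — forward stroke volume from dynamic cardiac PET

`fsvpet` measures **forward stroke volume (FSV)** — the net blood volume
ejected through the aortic valve per heartbeat — directly from a dynamic
cardiac PET series, using data every quantitative PET study already
acquires: the dynamic frames, the injected dose, and the heart rate. It is
aimed at researchers in quantitative cardiac PET who want hemodynamics as a
by-product of routine kinetic imaging, without manual region drawing.

The core is the indicator dilution principle,

```
FSV = I / ( ∫ C_A(t) dt × HR )
```

with `I` the injected dose (Bq), `C_A(t)` the whole-blood arterial
time-activity curve restricted to the bolus **first pass** (Bq/mL), and
`HR` the heart rate (s⁻¹): Bq / (Bq·s·mL⁻¹ × s⁻¹) = mL. The package
automates the full chain:

1. **Blood-pool segmentation** — k-means clustering of voxel time-activity
   curves (5 clusters for ¹¹C-acetate, 6 for ¹⁵O-water), automatic or
   manual selection of the arterial and venous clusters, and erosion of
   each cluster's outer voxel layer to limit partial-volume contamination.
2. **First-pass isolation** — the last successive frame pair whose
   downslope exceeds 0.75 × the maximum downslope anchors a two-point
   exponential that replaces the recirculation-contaminated tail.
3. **FSV computation** — for arterial and venous pools independently, plus
   their average, with anchors and AUCs recorded for audit.
4. **Agreement statistics** — OLS regression, paired t-test, Bland–Altman
   with proportional-error detection, repeatability coefficient.
5. **Synthetic phantom** — a dynamic series generator with known
   ground-truth FSV (gamma-variate bolus, recirculation, myocardial
   uptake, partial-volume blur, seeded noise) so the entire chain is
   testable without patient data.

I/O is 4D NIfTI-1 plus a frame-schedule CSV sidecar
(`frame_start_s,frame_duration_s`); TACs and cluster summaries are CSV,
reports are JSON.

## Worked example

```r
library(fsvpet)

# hand arithmetic: 400 MBq, first-pass AUC 5e6 Bq·s/mL, HR 60 → 80 mL
compute_fsv(4e8, 5e6, 60)
#> [1] 80

# phantom with known truth (80 mL), recirculation fraction 0.3
cfg <- phantom_config(fsv_true = 80, heart_rate = 60,
                      recirculation_fraction = 0.3)
sim <- simulate_dynamic_series(cfg)
res <- compute_fsv_report(sim$series, acquisition_context(400, 60))
res
#> fsv_result: arterial 76.6 mL, venous 71.6 mL, average 74.1 mL
#>   dose 400.0 MBq, HR 60 /min; anchors t1/t2: arterial 5/6, venous 3/4
```

The arterial estimate lands 4 % below truth (the quantified
tail-extrapolation bias of the stated bolus model); without first-pass
isolation, integrating the raw curve returns ≈ 56 mL (−29 %) — the
isolation step is what makes the measurement possible under recirculation.

Command-line use mirrors the API:

```sh
Rscript inst/cli/fsvpet simulate --fsv 80 --hr 60 --out-dir ph
Rscript inst/cli/fsvpet compute --image ph/series.nii --schedule ph/schedule.csv \
        --dose-mbq 400 --hr 60 --tracer acetate --out-dir out
Rscript inst/cli/fsvpet agree --input pairs.csv --out-dir ag
```

`compute` writes `fsv_result.json`, cluster labels (NIfTI), raw and
composite TAC CSVs, a cluster summary, and a config echo sufficient to
reproduce the run.

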