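# spheroMDR

Profiling the multidrug-resistance (MDR) status of cancer cell lines
from multicellular tumor spheroid (MCS) assays.

Cancer cells acquire resistance to chemotherapy largely through
ATP-binding-cassette efflux transporters (P-gp/MDR1, MRP1, BCRP) that
pump drugs out of the cell.  Spheroid cultures expose this phenotype
far more clearly than monolayers, and a practical screen combines four
readouts per cell line:

1. **Calcein-AM uptake imaging** — time-lapse fluorescence of spheroids
   loaded with calcein-AM; efflux-competent lines retain little dye and
   only at the rim.  Mean fluorescence over the segmented spheroid
   follows saturating kinetics `C(t) = (u/e)(1 − e^{−et})`, and the
   summary statistic is the trapezoidal time-integral of the series
   ("total accumulated calcein", a.u.·h).
2. **MTS dose–response screening** — per-well `A490 − A650` absorbances
   converted to viability and fit with a four-parameter logistic
   `V(c) = bottom + (top − bottom)/(1 + (c/IC50)^hill)`; IC50s (with
   profile-likelihood CIs) rank lines from sensitive to resistant.
3. **DCFDA/ROS imaging** — a 60-minute series whose decaying green
   signal (negative fitted slope, p < 0.05) marks the
   treatment-sensitive phenotype.
4. **Flow cytometry under transporter inhibitors** — PI-negative gating,
   median fluorescence intensity (MFI) per tube, and retention ratios
   MFI(inhibitor)/MFI(control) for verapamil (MDR1), MK-571 (MRP1) and
   novobiocin (BCRP); ratios near 1 everywhere indicate strong
   constitutive efflux.

The package implements every stage — including a dilated fully
convolutional segmentation network (13 3×3 conv layers in 5 blocks,
dilations 1/2/4/8/16, weighted cross-entropy 1:10, ADAM at 1e-4,
trained with flip/rotation augmentation; forward/backward passes in
RcppArmadillo) plus a classical Otsu-threshold baseline — and combines
the four evidence streams into a per-line call: `sensitive`,
`moderately_resistant` or `highly_resistant`.  A seeded synthetic-data
generator produces image stacks, plates and flow-event tables with
known ground truth, so every stage is validated by recovery
experiments.

## Worked example

Run the whole pipeline on the default simulated three-line cohort:

```r
library(spheroMDR)
report <- run_pipeline(default_cohort_config(seed = 1))
print(report)
#> CohortReport (seed 1 )
#>   line_sensitive: sensitive (score 0.000)
#>   line_moderate: moderately_resistant (score 0.597)
#>   line_resistant: highly_resistant (score 1.000)
report$profiles$line_moderate$rationale
#> score 0.597 -> moderately_resistant. Evidence: accumulated calcein
#> norm 0.531 (uptake term 0.469); IC50 rank norm 0.500; ROS decay FALSE;
#> retention norm 0.412 (mean ratio 1.579). Missing streams were skipped
#> and weights renormalized.
```

The score is a weighted combination (weights 0.4/0.3/0.2/0.1, logged in
every report) of cohort-normalized accumulated calcein, IC50 mean rank,
the ROS decay flag and mean inhibitor retention; classes cut at 1/3 and
2/3.  Individual stages are just as usable on their own, e.g. the flow
arm:

```r
fs <- flow_spec(retention_ratio = c(MDR1 = 1.5, MRP1 = 2, BCRP = 3,
                                    control = 1))
analyze_flow(make_flow_events(fs, seed = 2))
#> TransporterReport: live fraction 0.901 (PI gate 808)
#>   MDR1: retention ratio 1.505 +/- 0.020
#>   MRP1: retention ratio 2.000 +/- 0.015
#>   BCRP: retention ratio 2.984 +/- 0.013
#>   ranking: BCRP > MRP1 > MDR1
#>   Inhibition of BCRP raises dye retention most (ratio 2.98),
#>   consistent with BCRP-dominant efflux.
```

The numbered scripts under `analysis/` walk through the study step by
step (simulation, segmentation benchmark, kinetics, dose–response,
flow, integrated profiling) and write tidy tables under `results/`.

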