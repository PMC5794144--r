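# thermovine

Estimating grapevine midday stem water potential (Ψ_stem, MPa) from
vehicle-mounted ("on-the-go") thermal imaging of the canopy.

Ψ_stem measured with a pressure chamber is the reference for vineyard
irrigation decisions, but it is destructive and slow. Because water-stressed
vines close their stomata and stop cooling themselves, canopy temperature —
normalised by the wet/dry reference temperatures of an evaposensor — carries
the same information. `thermovine` implements the full workflow as a tested,
reusable R package:

* **synthetic campaigns** — weather, reference temperatures T_wet/T_dry,
  ground-truth Ψ_stem (7 dates × 3 irrigation regimes × 4 blocks × 2 canopy
  sides × 3 vines = 252 samples/side; marginal mean −1.23 MPa, SD ≈ 0.30
  MPa) and 320 × 256 thermal frames with sky/canopy/soil structure;
* **acquisition geometry** — scene coverage `2 d tan(FOV/2)`, frame counts,
  the non-overlap subsampling stride, centred middle-frame selection;
* **feature extraction** — ROI cropping, segmentation to the closed interval
  [T_wet, T_dry], per-frame mean/median/SD, and the indices

  CWSI = (T_canopy − T_wet) / (T_dry − T_wet),
  I_g = (T_dry − T_canopy) / (T_canopy − T_wet) = 1/CWSI − 1;

* **learner** — a from-scratch rotation forest (per-tree random feature
  groups, per-group principal-axis rotations estimated on 75% bootstrap
  samples, 10 trees) over reduced-error-pruning regression trees (variance
  reduction, 3 internal folds, bottom-up pruning with backfitting);
* **evaluation** — the calibration / 10-fold cross-validation / external
  prediction protocol with a range-and-date-stratified 80/20 split
  (252 → 200 train / 50 test), side-specific and balanced global datasets,
  R² (squared Pearson correlation; coefficient of determination also
  reported) and RMSE in MPa, plus a t-test for equality of the east/west
  calibration slopes.

See `vignettes/thermovine-methods.Rmd` for the model, its assumptions, and
what the synthetic world does and does not establish.

## Worked example

```r
library(thermovine)

# the acquisition arithmetic for the default camera/traverse
explain_run(run_config())
#> quantity                      value
#> scene_width_m                  1.07
#> scene_height_m                 0.85
#> frames_per_replication         1080
#> nonoverlap_stride                46
#> subsampled_frames                23
#> retained_frames                  14
#> measurements_per_day             36
#> samples_per_side                252

# full synthetic pipeline: 3 datasets (east, west, global) x 2 feature sets
res <- run_end_to_end(run_config(seed = 17))
subset(res$report_table, dataset == "east" & feature_set == "with_refs")
#>   dataset feature_set       stage        r2    r2_cod      rmse n_train n_test
#> 1    east   with_refs calibration 0.8370265 0.8327098 0.1187077     200     50
#> 2    east   with_refs          cv 0.6776265 0.6773361 0.1648614     200     50
#> 3    east   with_refs  prediction 0.5783832 0.5742283 0.1872591     200     50
```

Scene coverage 1.07 m × 0.85 m follows from the 48° × 39° fields of view at
1.2 m; 1080 frames cover a 25 m replication at 5 km/h and 60 FPS; one frame
in 46 is laterally disjoint, giving 23 frames of which the centred 14 span
the monitored middle 15 plants. In the report table, `r2`/`rmse` compare
observed and predicted Ψ_stem (MPa) for a model fit on 200 training rows:
`calibration` evaluates on the training rows themselves, `cv` pools 10-fold
held-out predictions within the training set, and `prediction` evaluates the
trained model on the 50 held-out test rows. At the default generator noise
(residual SD 0.16 MPa around the Ψ_stem–CWSI link) the cross-validated R²
lands near 0.7; with low noise (SD 0.1 MPa) it exceeds 0.8.

Command-line use (the same stages as subcommands):

```sh
Rscript inst/cli/thermovine.R geometry --explain
Rscript inst/cli/thermovine.R run --out out/ --seed 17
Rscript inst/cli/thermovine.R synth --out camp/ --seed 1 --frames
```

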