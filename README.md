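# oarseg

Strategies for improving deep-learning segmentation of low-contrast
organs-at-risk on CT, packaged as a tested R toolkit — with the salivary
glands (submandibular, SMG; parotid, PG) as the paradigm organ.

Automated organ-at-risk delineation for radiotherapy planning works, but
rarely better than a Sørensen–Dice coefficient (SDC) of ~0.9, and the
practical question is which strategies *around* a given model improve its
performance and reliability. `oarseg` implements that strategy toolbox:

* **Preprocessing** — organ-centred ROI cropping (64×64×32 / 96×64×64
  voxels for SMG/PG), Hounsfield-unit windowing ((−75, 175) / (−190, 310)
  HU), and zero-centred [0, 1] normalisation; laterality flipping to pool
  left/right glands under a symmetry assumption.
* **Traditional augmentation** — flips, rotations in all angles, Gaussian
  HU noise (σ = 15).
* **Domain-specific CT augmentation** — elastic deformation with affine
  jitter (α = 38/58, σ = 3.8/5.8, affine α = 3.8/5.8 for SMG/PG) plus body
  (σ = 100 HU) and organ (σ = 30 HU) density shifts.
* **Cost functions** — soft Dice; true-positive-weighted Dice,
  `SDC(w) = 2w·tp/(2w·tp + fp + fn)` with w = 0.5 or 0.05; and the
  combined cost `(1 − softSDC) + HD/(0.33·x)` where x is the ROI diagonal
  (96 voxels for the SMG crop, normaliser 31.68).
* **Patient-specific HU windowing** — a 969-window grid search (centres
  −100…400 step 10, widths 100…1000 step 50) keeping the window with the
  highest SDC.
* **Ensembling** — voxel-wise voting over models that differ only in their
  random initialisation, with cut-off sweeps and the majority cut-off
  (≥ 6 of 11) as the default.
* **Metrics** — SDC, 3D Hausdorff distance (verified against a brute-force
  oracle), and a contour-complexity score (mean perimeter/area per axial
  slice).
* **A training backend** — a compact 3D U-net-style fully-convolutional
  network written in R/Rcpp (im2col convolutions, hand-derived backprop
  checked against finite differences), with dropout, Adam and early
  stopping (improvement < 0.001 for 4 epochs on a 10% validation split).
* **A phantom generator and experiment runner** — synthetic CT phantoms
  with exact ground-truth masks, and six-fold cross-validated experiment
  designs (set-size, augmentation, cost-function, windowing, ensemble, and
  combined-strategy comparisons) that run in minutes on one CPU.

## Worked example

```r
library(oarseg)

cfg <- desk_scale_config()                       # fixed desk-scale conditions

# a synthetic cohort with exact ground truth
cohort <- generate_cohort(18, cfg$phantom, seed = 1)

# train one model per fold and ensemble 5 initialisations
ens <- run_ensemble_experiment(cohort, n_models = 5, cfg, seed = 1)
ens$cutoff_summary
#> # A tibble: 5 × 5
#>   cutoff sdc_mean sdc_sd hd_mean hd_sd
#>    <int>    <dbl>  <dbl>   <dbl> <dbl>
#> 1      1    0.793 0.0815    1.83 0.409
#> 2      2    0.834 0.0597    1.57 0.396
#> 3      3    0.849 0.0373    1.49 0.357
#> 4      4    0.843 0.0443    1.55 0.329
#> 5      5    0.804 0.0536    1.73 0.554
ens$standalone_summary
#> # A tibble: 2 × 3
#>   metric  mean     sd
#>   <chr>  <dbl>  <dbl>
#> 1 sdc    0.824 0.0528
#> 2 hd     1.70  0.391
```

Read: each of the 18 phantoms was segmented by 5 independently initialised
models of its fold; the majority vote (cut-off 3 of 5) averages SDC 0.849
against 0.824 for the mean stand-alone model, with a smaller SD — the
ensemble is both better and more reliable, and the best cut-off sits at
the majority, mirroring the qualitative behaviour expected of
initialisation-diversity ensembles. (Numbers are from this exact call;
your platform's BLAS may change trailing digits.)

Other entry points follow the same pattern: `run_set_size_experiment()`,
`run_augmentation_experiment()`, `run_cost_function_experiment()`,
`run_combined_experiment()`, `search_best_window()`,
`compare_set_vs_patient_window()`. `autoplot()` methods cover training
logs, window-search surfaces and cut-off sweeps. A thin command-line
front end for phantom generation, augmentation, evaluation and ensembling
is installed at `inst/cli/oarseg`.

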