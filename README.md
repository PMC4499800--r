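# plstraj

Systematic optimization of PLS calibration models for near-infrared (NIR)
spectra by **processing trajectory**: instead of tuning spectral
pretreatment, the number of latent factors, and variable selection one at a
time, `plstraj` enumerates *every* path through the three-way grid

> pretreatment × latent factors (1..A) × variable selection (full / VIP)

fits a PLS1 model for each path, scores it with the full chemometric panel
(RMSEC, R²cal, RMSECV, RMSEP, R²pre, RPD), and selects the best path by RPD.
The conventional one-parameter-at-a-time optimizer is included as a
comparator; because the exhaustive search covers every path the comparator
can reach, its chosen model is never better.

The package is aimed at chemometricians building quantitative NIR
calibrations for pharmaceutical and food quality control — moisture in
grain, marker compounds in herbal granules, API content in tablets — where
spectra suffer from overlapping absorption bands, baseline drift, and
multiplicative scatter.

## What is in the box

| Stage | Functions |
|---|---|
| Data I/O | `read_spectra`, `write_spectra`, `read_matlab_container` (MAT v5) |
| Pretreatment | `snv`, `savgol_coefficients`, `apply_savgol`, `pretreatment`, `apply_pretreatment` |
| Sample selection | `kennard_stone`, `split_dataset` (2:1 Kennard–Stone split) |
| PLS core | `fit_pls` (NIPALS PLS1), `predict`, `cross_validate` (10-fold, venetian blind), `vip_scores`, `select_variables` |
| Metrics | `rmse`, `r_squared`, `rpd`, `categorize_rpd`, `model_metrics` |
| Trajectory | `enumerate_grid`, `evaluate_path`, `run_trajectory`, `stepwise_optimize`, `write_report` |
| Synthetic data | `synthetic_spec`, `generate_spectra` |
| CLI | `parse_and_run`, installed script `exec/plstraj` |

Key formulas, using mean-centered calibration spectra X and reference
values y (%, w/w):

- NIPALS factor a: w_a ∝ X_aᵀy_a (unit norm), t_a = X_a w_a,
  p_a = X_aᵀt_a / t_aᵀt_a, q_a = y_aᵀt_a / t_aᵀt_a, then deflate.
- VIP_j = sqrt( p · Σ_a SS_a (w_aj)² / Σ_a SS_a ), SS_a = q_a²·t_aᵀt_a;
  channels with VIP > 1 are retained.
- RMSE = sqrt( Σ(ŷ−y)²/n ); R² = 1 − SSres/SStot; RPD = SD(y_val)/RMSEP,
  banded as fair [2.5, 3], good (3, 4], excellent (> 4).

## Worked example

```r
library(plstraj)

spec <- synthetic_spec(seed = 1)      # NIR-like: overlap + drift + scatter
ds   <- generate_spectra(spec, 60)
print(ds)
#> spectra_dataset: 60 samples x 700 channels (nm)
#>   axis: 1100 .. 2498 (spacing 2)
#>   reference: 9.40142 .. 10.967 %, mean 10.1993

result <- run_trajectory(ds)          # 120 paths: 6 pretreatments x 10 x 2
print(result)
#> trajectory_result: 120 paths (120 ok)
#> best path: 1D+SG(9)+SNV, A = 3, varsel = full, RPD = 5.6013 (excellent),
#>   RMSEP = 0.0774, R2pre = 0.9664
```

The winning path first takes a 9-point Savitzky–Golay first derivative
(removing the per-sample baseline offset and tilt exactly), then applies
SNV (removing the multiplicative scatter), and needs only 3 latent
factors. RMSEP = 0.0774% means the external-validation predictions of the
water content deviate by under a tenth of a percentage point; RPD = 5.6
(validation-set SD over RMSEP) puts the model in the "excellent" band.
The comparator chooses the same pretreatment here but a worse factor
count:

```r
sw <- stepwise_optimize(result$cal, result$val)
sw$metrics$rpd
#> [1] 5.318243
```

The same run from the shell:

```sh
plstraj synth -n 60 --seed 1 -o synth.csv
plstraj run --spectra synth.csv --report report.csv --model best.json
plstraj predict --model best.json --spectra synth.csv -o predictions.csv
```

## Limitations

- PLS1 only (single response); no PLS2, OPLS, or kernel variants.
- Variable selection is single-pass VIP thresholding; no UVE/CARS/GA.
- Pretreatment menu covers SNV and Savitzky–Golay smoothing/derivatives;
  MSC, detrending, OSC and wavelets are out of scope.
- The MAT v5 reader handles plain numeric arrays (enough for the public
  corn/tablet benchmark containers), not cells, structs, or sparse data.

See `vignettes/processing-trajectory.Rmd` for the methods discussion.
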