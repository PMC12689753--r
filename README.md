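# qdcnn

Accelerated quantitative T2/S0 mapping from undersampled multi-echo
spin-echo MRI, for people building or benchmarking model-based
reconstruction methods on simulated data.

Quantitative T2 mapping acquires one image per echo time TE and fits the
mono-exponential model

    S(TE) = S0 · exp(−TE / T2),      S0 = PD · (1 − exp(−TR / T1))

per pixel (complex amplitude S0, T2 in ms). Because the acquisition is
slow, k-space is undersampled per echo and the maps must be recovered from
incomplete data. This package implements an end-to-end framework, qDC-CNN,
that couples

* an **unrolled reconstruction network** — cascades of residual
  convolutional denoisers, each followed by a closed-form k-space
  data-consistency step against the measured lines, operating on all P
  echoes jointly as 2P real channels — with
* a **pixel-wise fully connected mapping network** producing
  (T2, Re S0, Im S0) per pixel,

trained jointly under three losses: an image loss, a map loss, and a
physics-informed data-consistency loss ‖y_Ω − E_Ω S(p)‖² that pushes the
k-space predicted from the estimated maps toward the measurements
(weights λ_r = 1, λ_p = 1e-2, λ_dc = 1e-6). Around the networks the
package provides the full study apparatus: a seeded digital-phantom
simulator (tissue-labelled head phantoms, calibrated 40 dB complex
Gaussian k-space noise, variable-density Cartesian undersampling),
classical variable-projection least-squares fitting as the non-learned
baseline, NRMSE/PSNR evaluation over a foreground region, and experiment
orchestration across acceleration factors and echo counts. The network
machinery (convolutions, backpropagation, Adam) is self-contained compiled
and R code.

## Worked example

Simulate a small case, undersample it 3×, and map it with the classical
zero-fill + least-squares pipeline:

```r
library(qdcnn)

cfg <- dataset_config(n_cases = 1, split = c(0, 0, 1), n_slices = 1,
                      h = 64, w = 64, af = 3, seed = 42)
ds <- build_dataset(cfg)
rec <- qdcnn:::dataset_slices(ds, "test")[[1]]

# zero-filled reconstruction of the undersampled k-space, then LSF mapping
maps_zf <- lsf_fit_image(zero_fill(rec$us_kspace, cfg$schedule))
map_errors(maps_zf, rec$gt)
#> # A tibble: 2 × 2
#>   parameter nrmse_pct
#>   <chr>         <dbl>
#> 1 T2             64.7
#> 2 S0             15.0

# the same slice fully sampled: only the acquisition noise remains
maps_fs <- lsf_fit_image(adjoint_encode(rec$fs_kspace, cfg$schedule))
map_errors(maps_fs, rec$gt)
#> # A tibble: 2 × 2
#>   parameter nrmse_pct
#>   <chr>         <dbl>
#> 1 T2            9.97
#> 2 S0            0.746
```

The first table says 3× undersampling corrupts the maps badly (T2 NRMSE
65% of the ground-truth norm over the brain region). The second isolates
the undersampling from the fit: with full k-space the S0 map is recovered
to under 1%, while T2 keeps a ~10% floor — that residual is concentrated
in CSF, whose 2000 ms T2 decays by only 8% across the 160 ms echo train
and is therefore intrinsically hard to estimate pixel-by-pixel at 40 dB.
The trained end-to-end pipeline reaches comparable map accuracy while
using only a fifth of the k-space lines (see the next section).

Training the learned pipeline uses the same objects:

```r
ds_desk <- build_dataset(dataset_config(scale = "desk"))  # train/val/test
pre  <- pretrain_fmap(map_net_config(), cfg$schedule)     # dictionary fit
fit  <- train_variant("A", ds_desk, recon_net_config(preset = "desk"),
                      map_net_config(), train_config(), pretrained = pre)
maps <- predict_maps(fit, rec$us_kspace, rec$mask_set)$p_rec
```

`autoplot()` methods display parameter maps, sampling masks and training
histories; `tidy()`/`glance()` return training histories and fit summaries
as tibbles.

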