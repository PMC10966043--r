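# specfuse

Spectral-spatial classification of laboratory hyperspectral image cubes,
built for grading plant material by growth year — e.g. ginseng roots,
where years 1-5 are traded as food and years 6-7 as medicine. The package
implements the full pipeline from raw digital-number (DN) cubes to a
trained classifier:

1. **Cube I/O** — ENVI-style header + flat-binary reader/writer (BSQ, BIL,
   BIP), band axis always in ascending wavelength order in memory.
2. **Segmentation** — Otsu binarization of a reference band (622 nm VNIR /
   1597 nm SWIR) splits each scene into sample region, white-reference
   region (flare-eroded), and background.
3. **Radiometric calibration** — column-wise white-reference
   normalization: `rho(i,j) = DN_sample(i,j) / mean(DN_whiteboard(:,j))`
   per band, which cancels the column illumination profile and any global
   gain exactly.
4. **Reflectance curves** — per-sample mean reflectance over the sample
   region, band by band: 288 VNIR + 108 SWIR = 396 values.
5. **Band selection** — random-forest impurity importance over 10
   repeated stratified splits; top-5 bands per spectral range.
6. **FC-CNN** — a dual-branch fusion network: a fully-connected spectral
   branch (396 → 512 → 1024 → 512 → 128) and a convolutional image branch
   (five 3x3 conv / batch-norm / ReLU / 2x2 max-pool blocks with filters
   64/128/128/64/32 on 256 x 1024 x C stacks, then dense 512),
   concatenated (640) into a dropout + dense softmax head. Trained with a
   mean-absolute-error loss on the softmax output against one-hot
   targets; evaluated by confusion-matrix accuracy over repeated random
   validation rounds. The network engine (im2col convolution, batch-norm,
   pooling, Adam, backprop) is implemented in the package with C++
   kernels under `src/`.
7. **Synthetic scenes** — a seeded generator that emulates the
   acquisition: whiteboard strip with edge flare, column illumination
   gradient, per-year reflectance signatures (800 nm peak, VNIR-SWIR gap
   shrinking with age, planted discriminative bands), spatial texture and
   sensor noise — so the whole pipeline is testable without instrument
   data.

## Worked example

```r
library(specfuse)

# a small synthetic study: 84 samples, years 1-7
cfg <- generator_config(seed = 1, scene_rows = 48, scene_cols = 144,
                        n_vnir = 60, n_swir = 24, snr = 100)
prep <- prepare_synthetic_dataset(cfg)          # segment + calibrate + curves
prep$curves
#> <spectral_dataset> 84 samples x 84 bands; years: 1:17 2:11 3:12 4:12 5:8 6:12 7:12

tbl <- rank_bands(prep$curves, n_splits = 10, seed = 7)
round(attr(tbl, "range_share"), 3)
#>  VNIR  SWIR
#> 0.228 0.772
sel <- select_top(tbl, k_vnir = 5, k_swir = 0)
round(sel$wavelength)                            # the five selected VNIR bands
#> [1] 522 563 654 766 898

# stack the selected band images and train the fusion model
prep2 <- prepare_synthetic_dataset(cfg, bands = sel,
                                   out_rows = 64, out_cols = 256)
plan <- experiment_plan(task = "food_medicinal", channels = "five-VNIR",
                        rounds = 5, iterations = 100, test_size = 17,
                        batch_size = 4, seed = 2)
fit <- run_experiment(plan, list(x_spec = prep2$curves$x,
                                 x_img = prep2$x_img, year = prep2$year))
fit
#> <fit_result> task=food_medicinal channels=five-VNIR (5 rounds x 100 iterations)
#> Round  Accuracy/%
#>     1        76.5
#>     2        88.2
#>     3        88.2
#>     4        88.2
#>     5        88.2
#> Mean accuracy: 85.9%
```

The mean accuracy is the average over the seeded validation rounds; each
round's accuracy is `100 * trace / total` of its confusion matrix on the
17 held-out samples (`fit$rounds[[1]]$cm`). The default generator
produces moderately overlapping year signatures; with stronger planted
contrasts (see the acceptance script's high-effect configuration) the
same protocol reaches 95%+. The architecture's parameter audit is
deterministic:

```r
count_parameters(build_fccnn(fccnn_spec()))
#> ...
#> Total parameters: 5,837,223
```

A thin command-line wrapper over these functions is installed at
`inst/cli/specfuse` (subcommands `simulate`, `curves`, `select-bands`,
`train`).

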