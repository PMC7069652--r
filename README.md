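# hsibg — retrieved-background illumination correction for hyperspectral imaging

Hyperspectral imaging (HSI) turns raw counts into reflectance and absorbance
by dividing by a background ("white") measurement:

    R(x,y,λ) = (I(x,y,λ) − I_dark) / (I₀(x,y,λ) − I_dark)
    A(x,y,λ) = −log₁₀ R(x,y,λ)

Those formulas assume the illumination at the sample equals the illumination
during the white measurement. In endoscopy and other in-vivo settings it does
not, and the error is exactly computable: a background wrong by a power
factor ω rescales reflectance by 1/ω and offsets absorbance by +log₁₀ω,
corrupting any statistic computed across pixels (PCA, spectral angle maps,
pixel classification).

`hsibg` implements the **retrieved background (RB)** correction: the
illumination spectrum at each pixel is estimated from the data themselves as

    RM(x,y,λ) = (C_s(x,y) / C_b) · NS(λ)

where `NS(λ)` is the min-max normalised source profile, `C_s` is the measured
intensity at a reference wavelength of negligible sample absorption (default
800 nm — inside the NIR tissue optical window, at a haemoglobin isosbestic
point), and `C_b = NS(800)`. Dividing by `RM` recovers the spectral *shape*
exactly under separable illumination — `A_RB(λ) = A_GT(λ) − A_GT(λ_ref)` —
independent of the spatial power distribution.

The package is a toolkit for the whole workflow, aimed at researchers
processing line-scan (pushbroom) HSI data and at anyone who wants to quantify
what an incorrect background does to downstream analysis:

* hypercube data model, pushbroom reconstruction, dark correction,
  synthetic-RGB rendering (Rayleigh colour filters), HDF5 / multi-band TIFF /
  CSV I/O;
* GT / SB / RB reflectance and absorbance normalisation
  (`reflectance_cube()`, `absorbance_cube()`, `retrieve_background()`,
  `rb_correct()`);
* a synthetic hypercube generator (Gaussian illumination fields, four-class
  circle phantoms, stand-in halogen/tissue/dye spectra, bounded uncorrelated
  noise) that feeds the RB code path bit-for-bit (`synth_dataset()`);
* pixel-wise PCA and spectral angle mapping (`pixelwise_pca()`, `sam_map()`);
* a pixel-wise classification harness — mini-batch k-means, incremental
  hinge-loss SVM, six-layer 1D CNN — scoring every train/test background
  combination (`classification_experiment()`, `run_full_experiment()`).

## Worked example

Build a small synthetic scene (four spectral classes under a random Gaussian
illumination field), apply all three background corrections, and look at what
each one does:

```r
library(hsibg)

lib     <- spectrum_library(n_channels = 100)          # 450-900 nm stand-ins
profile <- source_profile(lib$source, lib$wavelengths, ref_wavelength = 800)
ill     <- sample_illumination(c(16, 24), seed = 2)
layout  <- phantom_layout(c(16, 24), radius = 3)
gt      <- synth_gt_cube(layout, lib, alpha_max = 0.1, seed = 2)
tri     <- synth_triplet(gt, ill, lib, profile, layout = layout)

print(tri$rb)
#> <hypercube> 16 x 24 spatial, 100 channels (450.0-900.0 nm), kind=reflectance

range(ill$m)                                  # illumination power varies 20x
#> [1] 0.05 1.00

range(tri$rb$data[, , profile$ref_index])     # RB anchors R(800nm) = 1
#> [1] 1 1

abs_tri <- absorbance_triplet(tri)
k550 <- nearest_channel(lib$wavelengths, 550)
round(c(gt = mean(abs_tri$gt$data[, , k550]),
        sb = mean(abs_tri$sb$data[, , k550]),
        rb = mean(abs_tri$rb$data[, , k550])), 3)
#>    gt    sb    rb
#> 0.624 1.226 0.599

p <- pixelwise_pca(abs_tri$gt)
round(100 * sum(p$explained_variance_ratio[1:2]), 2)
#> [1] 99.69
```

The single-background absorbance at 550 nm is wrong by a factor two (the
per-pixel offset −log₁₀M leaks into the mean), while the retrieved background
tracks the ground truth, slightly lower because the samples retain a small
finite absorption at the 800 nm anchor. The four-class scene concentrates
99.7 % of its spectral variance in two principal components.

The full evaluation bundle (classification grid, PCA and SAM summaries, JSON
reports plus a provenance manifest) is one call, or one shell command via the
bundled CLI:

```r
run_full_experiment("hsibg-report", seed = 1)
```

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/hsibg.R", package="hsibg"))')" \
    full-experiment --out hsibg-report --seed 1
```

The CLI also exposes `synth`, `correct`, `analyze`, `classify` and `render`
subcommands for working with cubes on disk.

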