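## Synthetic hypercube generator: Gaussian illumination fields, a stand-in
## spectral library (halogen-like source, four sample classes, smooth
## colour-chart noise spectra), four-class circle phantoms, and the GT/SB/RB
## triplet construction used to study background-correction quality.

#' Sample a Gaussian illumination power field
#'
#' Emulates the spatial optical-power distribution `M(x, y)` of a tilted or
#' uneven illumination: an isotropic bivariate Gaussian density with a
#' uniformly random centre, rescaled to `[floor, 1]`. The positive floor keeps
#' every subsequent division by the background well-posed (real illuminations
#' are never exactly zero).
#'
#' @param shape Integer `(x, y)` image size.
#' @param sigma Gaussian width in pixels; default `0.35 * min(shape)`.
#' @param floor Minimum power after rescaling (default 0.05).
#' @param seed Optional RNG seed (the centre is the only random draw).
#' @param centre Optional fixed `(x, y)` centre, overriding the random draw.
#' @return Object of class `illumination_field`: list with `m` (matrix in
#'   `[floor, 1]`, max exactly 1), `density` (unscaled Gaussian), `centre`,
#'   `sigma`, `floor`.
#' @export
sample_illumination <- function(shape, sigma = 0.35 * min(shape),
                                floor = 0.05, seed = NULL, centre = NULL) {
  stopifnot(length(shape) == 2L, all(shape >= 1), sigma > 0,
            floor > 0, floor < 1)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(centre)) centre <- c(stats::runif(1, 1, shape[1]),
                                   stats::runif(1, 1, shape[2]))
  dx2 <- (seq_len(shape[1]) - centre[1])^2
  dy2 <- (seq_len(shape[2]) - centre[2])^2
  density <- exp(-outer(dx2, dy2, "+") / (2 * sigma^2)) / (2 * pi * sigma^2)
  rng <- range(density)
  m <- if (diff(rng) < .Machine$double.eps * max(rng)) {
    matrix(1, shape[1], shape[2])            # flat (sigma -> Inf) limit
  } else {
    floor + (1 - floor) * (density - rng[1]) / (rng[2] - rng[1])
  }
  structure(list(m = m, density = density, centre = centre, sigma = sigma,
                 floor = floor),
            class = "illumination_field")
}

#' Separable ground-truth background cube
#'
#' `BG(x, y, lambda) = M(x, y) * S_light(lambda)`: the illumination power
#' field times the source spectrum.
#'
#' @param ill An `illumination_field`.
#' @param source Source spectrum `S_light(lambda)` (non-negative).
#' @return A `background_field` of kind `"GT"`.
#' @export
make_background_cube <- function(ill, source) {
  stopifnot(inherits(ill, "illumination_field"))
  if (any(source < 0)) stop("source spectrum must be non-negative", call. = FALSE)
  background_field(outer(ill$m, as.numeric(source)), "GT")
}

# Planck blackbody spectral radiance (arbitrary units) at temperature T (K).
planck_spectrum <- function(wavelengths, temperature = 3200) {
  c2 <- 1.4387769e7                          # hc/k in nm*K
  wavelengths^-5 / (exp(c2 / (wavelengths * temperature)) - 1)
}

# Smooth band-edge envelope: cosine tapers to zero at both grid ends,
# emulating the roll-off of the spectrograph/camera response.
.band_envelope <- function(wl, lo_width = 60, hi_width = 50) {
  lo <- pmin(1, (wl - min(wl)) / lo_width)
  hi <- pmin(1, (max(wl) - wl) / hi_width)
  (0.5 - 0.5 * cos(pi * lo)) * (0.5 - 0.5 * cos(pi * hi))
}

.gauss <- function(wl, centre, width) exp(-((wl - centre) / width)^2)

#' Stand-in spectral library for the synthetic generator
#'
#' Builds, on a shared wavelength grid (default 300 channels over
#' 450-900 nm), a halogen-like source spectrum (3200 K Planck curve shaped by
#' a smooth band-edge response, anchored so its grid minimum is exactly zero)
#' and smooth stand-in spectra for the four phantom classes, constructed as
#' sums of Gaussian absorption bands converted to reflectance via
#' `10^(-A)`:
#'
#' * `muscle` - broad visible absorption, weak at 800 nm;
#' * `blood_oxy` - oxygenated blood, twin absorption peaks at 540 and 560 nm
#'   and a small finite NIR absorption;
#' * `methylene_blue` - strong 664 nm band, negligible absorption near 800 nm;
#' * `nigrosin` - broad absorber with small but finite 800 nm absorption.
#'
#' A fifth spectrum, deoxygenated blood (single 550 nm peak plus the 760 nm
#' band), is included for retrieval/noise studies, and a pool of six smooth
#' "colour-chart" spectra provides the uncorrelated per-pixel noise term.
#'
#' @param n_channels Number of spectral channels (default 300).
#' @param range Wavelength range in nm (default `c(450, 900)`).
#' @return Object of class `spectrum_library`: list with `wavelengths`,
#'   `source`, `samples` (named list of reflectance spectra, the class order
#'   used by phantom labels 0-3), `sample_absorbance`, `blood_deoxy` (list
#'   with `reflectance`, `absorbance`), `noise_pool` (list), `class_names`.
#' @export
spectrum_library <- function(n_channels = 300, range = c(450, 900)) {
  wl <- seq(range[1], range[2], length.out = n_channels)
  src <- planck_spectrum(wl) * .band_envelope(wl)
  src <- src - min(src)                      # band edge below detection
  src <- src / max(src)
  # All classes share a broad visible absorption hump (scattering baseline and
  # base chromophores common to tissue-mimicking phantoms); class-specific
  # bands ride on top. The shared structure mirrors measured spectra, where
  # most spectral variance lives in very few principal directions.
  hump <- 0.60 * .gauss(wl, 520, 110)
  A <- list(
    muscle         = hump + 0.06 * .gauss(wl, 555, 30) + 0.03,
    blood_oxy      = hump + 0.27 * .gauss(wl, 540, 8) + 0.27 * .gauss(wl, 560, 8) +
                     0.06 * .gauss(wl, 550, 70) + 0.02 + 0.03 * .gauss(wl, 820, 200),
    methylene_blue = hump + 0.54 * .gauss(wl, 664, 22) + 0.21 * .gauss(wl, 610, 25),
    nigrosin       = hump + 0.33 * .gauss(wl, 600, 120) + 0.02
  )
  A_deoxy <- hump + 0.33 * .gauss(wl, 550, 14) + 0.035 * .gauss(wl, 760, 30) +
             0.02 + 0.03 * .gauss(wl, 820, 200)
  noise_pool <- list(
    red    = 0.15 + 0.40 * .gauss(wl, 620, 90),
    green  = 0.15 + 0.40 * .gauss(wl, 530, 70),
    blue   = 0.15 + 0.35 * .gauss(wl, 470, 60) + 0.15 * .gauss(wl, 850, 150),
    warm   = 0.12 + 0.0006 * (wl - range[1]),
    grey   = 0.50 - 0.0005 * (wl - range[1]),
    nir    = 0.20 + 0.25 * .gauss(wl, 700, 120)
  )
  structure(list(wavelengths = wl, source = src,
                 samples = lapply(A, function(a) 10^(-a)),
                 sample_absorbance = A,
                 blood_deoxy = list(reflectance = 10^(-A_deoxy),
                                    absorbance = A_deoxy),
                 noise_pool = noise_pool,
                 class_names = names(A)),
            class = "spectrum_library")
}

#' Four-class circle phantom layout
#'
#' A label image with four spectral classes: class `i` (0-3) is a horizontal
#' row of three disjoint circles, all carrying the same spectrum, on a
#' background assigned class 0 (muscle), so exactly four classes are present.
#'
#' @param shape Integer `(x, y)` image size (default `c(256, 512)`).
#' @param radius Circle radius in pixels; default scales the reference
#'   28 px radius (on a 256 x 512 canvas) to `shape`.
#' @return Object of class `phantom_layout`: list with `labels` (integer
#'   matrix, values 0-3), `radius`, `class_names`.
#' @export
phantom_layout <- function(shape = c(256, 512), radius = NULL) {
  stopifnot(length(shape) == 2L, all(shape >= 16))
  if (is.null(radius))
    radius <- max(2L, round(28 * min(shape[1] / 256, shape[2] / 512)))
  radius <- min(radius, floor(shape[1] / 8) - 1L, floor(shape[2] / 6) - 1L)
  labels <- matrix(0L, shape[1], shape[2])
  xs <- (seq_len(4) - 0.5) * shape[1] / 4
  ys <- (seq_len(3) - 0.5) * shape[2] / 3
  xg <- matrix(seq_len(shape[1]), shape[1], shape[2])
  yg <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  for (i in seq_len(4)) {
    for (j in seq_len(3)) {
      inside <- (xg - xs[i])^2 + (yg - ys[j])^2 <= radius^2
      labels[inside] <- i - 1L
    }
  }
  structure(list(labels = labels, radius = radius,
                 class_names = c("muscle", "blood_oxy", "methylene_blue",
                                 "nigrosin")),
            class = "phantom_layout")
}

#' Ground-truth reflectance hypercube from a phantom layout
#'
#' Each pixel receives its class reflectance spectrum plus an uncorrelated
#' smooth noise term: `GT(x, y, lambda) = S_class(lambda) + alpha * N(lambda)`
#' with `alpha ~ Uniform(0, alpha_max)` and `N` drawn per pixel from the
#' colour-chart noise pool.
#'
#' @param layout A `phantom_layout`.
#' @param library A `spectrum_library`.
#' @param alpha_max Upper bound of the noise weight (default 0.1).
#' @param seed Optional RNG seed.
#' @return A reflectance `hypercube`; the per-pixel draws are attached as the
#'   `"draws"` attribute (list with `alpha` and `noise_index`) for replay.
#' @export
synth_gt_cube <- function(layout, library, alpha_max = 0.1, seed = NULL) {
  stopifnot(inherits(layout, "phantom_layout"),
            inherits(library, "spectrum_library"),
            alpha_max >= 0, alpha_max < 1)
  if (!is.null(seed)) set.seed(seed)
  cls <- as.integer(layout$labels)
  if (any(cls < 0L | cls > length(library$samples) - 1L))
    stop("layout labels index classes missing from the library", call. = FALSE)
  np <- length(cls)
  S <- do.call(rbind, library$samples)       # classes x channels
  N <- do.call(rbind, library$noise_pool)
  alpha <- stats::runif(np, 0, alpha_max)
  nidx <- sample.int(nrow(N), np, replace = TRUE)
  m <- S[cls + 1L, , drop = FALSE] + alpha * N[nidx, , drop = FALSE]
  m[m < 0] <- 0
  cube <- unvectorize_cube(m, dim(layout$labels), library$wavelengths,
                           "reflectance")
  attr(cube$data, "draws") <- list(alpha = alpha, noise_index = nidx)
  cube
}

#' GT/SB/RB reflectance triplet under a common illumination field
#'
#' Emulates the measurement chain: the raw signal is
#' `I = BG(x, y, lambda) * GT(x, y, lambda)` with the separable background
#' `BG = M * S_light`. The single-background cube divides by the source
#' spectrum alone, `SB = BG * GT / S_light = M * GT`, and the
#' retrieved-background cube divides by the field retrieved from the raw
#' signal itself via [rb_correct()] (the identical code path used for real
#' data).
#'
#' @param gt GT reflectance `hypercube` (from [synth_gt_cube()]).
#' @param ill An `illumination_field` of matching spatial shape.
#' @param library A `spectrum_library` on the same grid.
#' @param profile Optional `source_profile`; defaults to the library source
#'   at `ref_wavelength`.
#' @param ref_wavelength Reference wavelength for retrieval (nm, default 800).
#' @return Object of class `hypercube_triplet`: list with reflectance cubes
#'   `gt`, `sb`, `rb`, plus `illumination` and (if supplied) `layout`.
#' @param layout Optional `phantom_layout` carried along for evaluation.
#' @export
synth_triplet <- function(gt, ill, library, profile = NULL,
                          ref_wavelength = 800, layout = NULL) {
  stopifnot(inherits(gt, "hypercube"), gt$kind == "reflectance",
            inherits(ill, "illumination_field"),
            inherits(library, "spectrum_library"))
  if (!all(dim(gt$data)[1:2] == dim(ill$m)))
    stop("illumination field shape does not match the cube", call. = FALSE)
  if (is.null(profile))
    profile <- source_profile(library$source, library$wavelengths,
                              ref_wavelength)
  bg <- make_background_cube(ill, library$source)
  raw <- hypercube(bg$field * gt$data, gt$wavelengths, "counts")
  sb <- hypercube(gt$data * as.vector(ill$m), gt$wavelengths, "reflectance")
  rb <- rb_correct(raw, profile, mode = "reflectance")
  structure(list(gt = gt, sb = sb, rb = rb, illumination = ill,
                 layout = layout, profile = profile),
            class = "hypercube_triplet")
}

#' Convert a reflectance triplet to absorbance
#'
#' Elementwise `-log10` with the usual floor for non-positive values (the
#' retrieved cube is exactly zero on channels where the source profile rolls
#' to zero, so flooring is expected there).
#'
#' @param triplet A `hypercube_triplet` of reflectance cubes.
#' @param floor Floor for non-positive reflectance (default `1e-6`).
#' @return A `hypercube_triplet` of absorbance cubes.
#' @export
absorbance_triplet <- function(triplet, floor = 1e-6) {
  stopifnot(inherits(triplet, "hypercube_triplet"))
  out <- triplet
  for (nm in c("gt", "sb", "rb"))
    out[[nm]] <- suppressWarnings(
      reflectance_to_absorbance(triplet[[nm]], floor = floor))
  out
}

#' Noise robustness of the retrieved-background correction
#'
#' Monte-Carlo version of the single-spectrum experiment: channel-wise
#' multiplicative Gaussian noise of the stated relative level is added to the
#' raw (source times sample) spectrum, the RB absorbance is recomputed, and
#' the percent error against the noiseless RB absorbance is reported, averaged
#' over channels where the normalised source profile is above its retrieval
#' floor. Because the retrieval anchors on a single reference channel, the
#' error is expected to grow with the noise level.
#'
#' @param library A `spectrum_library` (the oxygenated-blood sample is used by
#'   default).
#' @param sample Reflectance spectrum of the sample; default
#'   `library$samples$blood_oxy`.
#' @param noise_levels Relative noise standard deviations
#'   (default `c(0.01, 0.05, 0.10, 0.20)`).
#' @param n_reps Replicates per level (default 100).
#' @param seed Optional RNG seed.
#' @param ref_wavelength Reference wavelength (nm).
#' @return `data.frame` with columns `noise_level`, `mean_error_pct`,
#'   `sd_error_pct`.
#' @export
noise_robustness_sim <- function(library, sample = library$samples$blood_oxy,
                                 noise_levels = c(0.01, 0.05, 0.10, 0.20),
                                 n_reps = 100, seed = NULL,
                                 ref_wavelength = 800) {
  stopifnot(inherits(library, "spectrum_library"), all(noise_levels >= 0),
            n_reps >= 1)
  if (!is.null(seed)) set.seed(seed)
  wl <- library$wavelengths
  profile <- source_profile(library$source, wl, ref_wavelength)
  keep <- profile$ns >= 1e-3                 # channels above the retrieval floor
  raw <- library$source * sample
  as_cube <- function(v) hypercube(array(pmax(v, 0), c(1, 1, length(v))), wl,
                                   "counts")
  rb_abs <- function(v) as.vector(suppressWarnings(
    rb_correct(as_cube(v), profile, mode = "absorbance"))$data)
  a_clean <- rb_abs(raw)
  res <- lapply(noise_levels, function(lvl) {
    errs <- vapply(seq_len(n_reps), function(r) {
      noisy <- raw * (1 + lvl * stats::rnorm(length(raw)))
      a <- rb_abs(noisy)
      100 * mean(abs(a[keep] - a_clean[keep])) / mean(abs(a_clean[keep]))
    }, numeric(1))
    data.frame(noise_level = lvl, mean_error_pct = mean(errs),
               sd_error_pct = stats::sd(errs))
  })
  do.call(rbind, res)
}

#' Generate a full synthetic train/test dataset
#'
#' Draws independent illumination fields and noise realisations for
#' `n_train` training and `n_test` test triplets over one shared phantom
#' layout and spectral library. Per-cube seeds are derived deterministically
#' from `seed`, so identical seeds reproduce the dataset exactly and train and
#' test draws never overlap.
#'
#' @param n_train,n_test Number of training / test triplets (defaults 50 / 3).
#' @param shape Spatial size (default `c(256, 512)`).
#' @param n_channels Spectral channels (default 300).
#' @param alpha_max Noise weight bound (default 0.1).
#' @param seed Base RNG seed (default 1).
#' @param range Wavelength range (nm).
#' @return List with `library`, `profile`, `layout`, `train`, `test` (lists of
#'   `hypercube_triplet`), and `seed`.
#' @export
synth_dataset <- function(n_train = 50, n_test = 3, shape = c(256, 512),
                          n_channels = 300, alpha_max = 0.1, seed = 1,
                          range = c(450, 900)) {
  stopifnot(n_train >= 1, n_test >= 1)
  library <- spectrum_library(n_channels, range)
  profile <- source_profile(library$source, library$wavelengths, 800)
  layout <- phantom_layout(shape)
  gen <- function(cube_seed) {
    ill <- sample_illumination(shape, seed = cube_seed)
    gt <- synth_gt_cube(layout, library, alpha_max, seed = cube_seed + 1L)
    synth_triplet(gt, ill, library, profile, layout = layout)
  }
  train <- lapply(seq_len(n_train), function(i) gen(seed + 13L * i))
  test <- lapply(seq_len(n_test), function(j) gen(seed + 1000003L + 13L * j))
  list(library = library, profile = profile, layout = layout,
       train = train, test = test, seed = seed)
}
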