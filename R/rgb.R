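## Synthetic RGB rendering: Rayleigh-shaped colour filters applied to a cube.

# Half-width constants of the unit Rayleigh density f(x) = x exp(-x^2/2):
# mode at x = 1, FWHM solved numerically once at load time.
.rayleigh_consts <- local({
  f <- function(x) x * exp(-x^2 / 2)
  half <- f(1) / 2
  lo <- stats::uniroot(function(x) f(x) - half, c(1e-9, 1))$root
  hi <- stats::uniroot(function(x) f(x) - half, c(1, 6))$root
  list(fwhm_per_sigma = hi - lo)
})

#' Build a bank of Rayleigh-shaped RGB colour filters
#'
#' Each filter response is a shifted Rayleigh probability density on the
#' wavelength grid, with its mode placed at the requested centre wavelength
#' (shift = centre - scale) and zero response below the shift origin. The
#' scale parameter is chosen to give the requested full width at half maximum.
#'
#' @param wavelengths Wavelength grid (nm).
#' @param centres Three centre wavelengths (nm), default the blue/green/orange
#'   set 442, 518, 579 nm; each must lie within the grid range.
#' @param amplitudes Three non-negative amplitudes multiplying the densities.
#' @param fwhm Full width at half maximum of each response (nm).
#' @return Object of class `rgb_filter_bank`: list with `responses`
#'   (n_channels x 3 matrix), `centres`, `amplitudes`, `wavelengths`.
#' @export
make_rgb_filters <- function(wavelengths, centres = c(442, 518, 579),
                             amplitudes = c(1, 1, 1), fwhm = 40) {
  wavelengths <- wavelength_grid(wavelengths)
  stopifnot(length(centres) == 3L, length(amplitudes) == 3L)
  if (any(amplitudes < 0)) stop("amplitudes must be non-negative", call. = FALSE)
  sigma <- fwhm / .rayleigh_consts$fwhm_per_sigma
  resp <- sapply(seq_len(3L), function(i) {
    nearest_channel(wavelengths, centres[i])  # errors if centre off-grid
    shift <- centres[i] - sigma
    x <- wavelengths - shift
    r <- ifelse(x > 0, (x / sigma^2) * exp(-x^2 / (2 * sigma^2)), 0)
    amplitudes[i] * r
  })
  structure(list(responses = resp, centres = centres, amplitudes = amplitudes,
                 wavelengths = wavelengths),
            class = "rgb_filter_bank")
}

# Trapezoidal quadrature weights for a (possibly non-uniform) grid.
trapezoid_weights <- function(x) {
  n <- length(x)
  w <- numeric(n)
  dx <- diff(x)
  w[1] <- dx[1] / 2
  w[n] <- dx[n - 1] / 2
  if (n > 2) w[2:(n - 1)] <- (dx[-(n - 1)] + dx[-1]) / 2
  w
}

#' Render a synthetic RGB image from a hypercube
#'
#' Each colour channel is the trapezoidal area under the pixel spectrum
#' multiplied by the corresponding filter response. All three channels are
#' then divided by the global maximum channel value so that no channel
#' saturates, and clipped to `[0, 1]`.
#'
#' @param cube A `hypercube` (any kind; typically reflectance).
#' @param filters An `rgb_filter_bank` on the same wavelength grid.
#' @return Numeric array `(x, y, 3)` with values in `[0, 1]`.
#' @export
render_rgb <- function(cube, filters) {
  stopifnot(inherits(cube, "hypercube"), inherits(filters, "rgb_filter_bank"))
  if (!isTRUE(all.equal(cube$wavelengths, filters$wavelengths)))
    stop("cube and filter bank wavelength grids differ", call. = FALSE)
  w <- trapezoid_weights(cube$wavelengths)
  m <- vectorize_cube(cube)                    # pixels x channels
  img <- m %*% (filters$responses * w)         # pixels x 3 (quadrature)
  mx <- max(img)
  if (mx > 0) img <- img / mx
  img[img < 0] <- 0
  img[img > 1] <- 1
  array(img, dim = c(dim(cube$data)[1:2], 3L))
}
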