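#' Validate a wavelength grid
#'
#' A wavelength grid is a strictly increasing vector of at least two positive
#' wavelengths in nanometres. All hypercubes and line-scan frames carry one.
#'
#' @param values Numeric vector of wavelengths (nm).
#' @return The validated numeric vector, invisibly classed for printing.
#' @export
wavelength_grid <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L)
    stop("a wavelength grid needs at least two channels", call. = FALSE)
  if (any(!is.finite(values)) || any(values <= 0))
    stop("wavelengths must be finite and positive", call. = FALSE)
  if (any(diff(values) <= 0))
    stop("wavelengths must be strictly increasing", call. = FALSE)
  values
}

#' Index of the grid channel nearest a wavelength
#'
#' @param wavelengths Wavelength grid (nm).
#' @param nm Target wavelength (nm); must lie within the grid range.
#' @return Integer channel index.
#' @export
nearest_channel <- function(wavelengths, nm) {
  wavelengths <- wavelength_grid(wavelengths)
  if (nm < min(wavelengths) || nm > max(wavelengths))
    stop(sprintf("wavelength %g nm is outside the grid range [%g, %g]",
                 nm, min(wavelengths), max(wavelengths)), call. = FALSE)
  which.min(abs(wavelengths - nm))
}

#' Construct a hypercube
#'
#' A hypercube is a 3D array `(x, y, lambda)` with an attached wavelength grid
#' and a `kind` describing the physical quantity stored: raw camera `counts`,
#' normalised `reflectance`, or `absorbance` (base-10; may be negative where
#' reflectance exceeds 1). The scan axis is the first spatial axis.
#'
#' @param data 3D numeric array, lambda extent matching `wavelengths`.
#' @param wavelengths Wavelength grid (nm).
#' @param kind One of `"counts"`, `"reflectance"`, `"absorbance"`.
#' @return An object of class `hypercube`: a list with elements `data`,
#'   `wavelengths`, `kind`.
#' @export
hypercube <- function(data, wavelengths,
                      kind = c("counts", "reflectance", "absorbance")) {
  kind <- match.arg(kind)
  wavelengths <- wavelength_grid(wavelengths)
  data <- as.array(data)
  if (length(dim(data)) != 3L)
    stop("hypercube data must be a 3D array (x, y, lambda)", call. = FALSE)
  if (dim(data)[3L] != length(wavelengths))
    stop("third array extent must equal the number of wavelength channels",
         call. = FALSE)
  if (any(!is.finite(data)))
    stop("hypercube values must be finite", call. = FALSE)
  if (kind != "absorbance" && any(data < 0))
    stop(sprintf("%s hypercubes cannot hold negative values", kind),
         call. = FALSE)
  structure(list(data = data, wavelengths = wavelengths, kind = kind),
            class = "hypercube")
}

#' @export
print.hypercube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<hypercube> %d x %d spatial, %d channels (%.1f-%.1f nm), kind=%s\n",
              d[1], d[2], d[3], min(x$wavelengths), max(x$wavelengths), x$kind))
  invisible(x)
}

#' @export
dim.hypercube <- function(x) dim(x$data)

#' Flatten a hypercube to a spectra matrix
#'
#' Vectorises the cube to an `(n_pixels x n_channels)` matrix, one pixel
#' spectrum per row (pixel order runs down the scan axis first). The spatial
#' dimensions are kept in the `"spatial_dim"` attribute so that
#' [unvectorize_cube()] restores the cube exactly.
#'
#' @param cube A `hypercube`.
#' @return Numeric matrix with attribute `spatial_dim`.
#' @export
vectorize_cube <- function(cube) {
  stopifnot(inherits(cube, "hypercube"))
  d <- dim(cube$data)
  m <- cube$data
  dim(m) <- c(d[1L] * d[2L], d[3L])
  attr(m, "spatial_dim") <- d[1:2]
  m
}

#' Restore a hypercube from a spectra matrix
#'
#' Inverse of [vectorize_cube()].
#'
#' @param m Spectra matrix (pixels x channels).
#' @param spatial_dim Length-2 integer vector `(x, y)`; defaults to the
#'   matrix's `spatial_dim` attribute.
#' @param wavelengths Wavelength grid (nm).
#' @param kind Cube kind.
#' @return A `hypercube`.
#' @export
unvectorize_cube <- function(m, spatial_dim = attr(m, "spatial_dim"),
                             wavelengths, kind = "counts") {
  if (is.null(spatial_dim))
    stop("spatial_dim is required when the matrix carries no spatial_dim attribute",
         call. = FALSE)
  if (prod(spatial_dim) != nrow(m))
    stop("spatial_dim does not match the number of rows", call. = FALSE)
  a <- as.numeric(m)
  dim(a) <- c(spatial_dim[1L], spatial_dim[2L], ncol(m))
  hypercube(a, wavelengths, kind)
}

#' Construct a line-scan (pushbroom) frame
#'
#' One acquisition of a pushbroom spectrograph: a 2D array of camera counts
#' with one spatial coordinate (the entrance-slit line) along rows and the
#' spectral coordinate along columns.
#'
#' @param data Non-negative numeric matrix (line pixel x wavelength channel).
#' @param wavelengths Wavelength grid (nm); length must equal `ncol(data)`.
#' @return Object of class `linescan_frame` (a matrix with a `wavelengths`
#'   attribute).
#' @export
linescan_frame <- function(data, wavelengths) {
  data <- as.matrix(data)
  wavelengths <- wavelength_grid(wavelengths)
  if (ncol(data) != length(wavelengths))
    stop("frame column count must equal the number of wavelength channels",
         call. = FALSE)
  if (any(!is.finite(data)) || any(data < 0))
    stop("frame counts must be finite and non-negative", call. = FALSE)
  structure(data, wavelengths = wavelengths, class = c("linescan_frame", "matrix"))
}

#' Dark-frame subtraction
#'
#' Subtracts the dark signal (recorded with the shutter closed) from a frame,
#' clamping at zero: under-dark pixels would otherwise poison downstream
#' ratios and logarithms.
#'
#' @param frame A `linescan_frame` or plain matrix of counts.
#' @param dark Scalar, per-line-pixel vector (length `nrow(frame)`), or a
#'   matrix of the same shape as `frame`. Values must be non-negative.
#' @return Corrected frame of the same class/shape.
#' @export
subtract_dark <- function(frame, dark) {
  if (any(!is.finite(dark)) || any(dark < 0))
    stop("dark values must be finite and non-negative", call. = FALSE)
  if (is.matrix(dark)) {
    if (!all(dim(dark) == dim(frame)))
      stop("dark frame shape does not match the frame", call. = FALSE)
    out <- unclass(frame) - dark
  } else if (length(dark) == 1L) {
    out <- unclass(frame) - dark
  } else if (length(dark) == nrow(frame)) {
    out <- unclass(frame) - dark          # recycles down columns: per line pixel
  } else {
    stop("dark must be a scalar, a length-nrow vector, or a same-shape matrix",
         call. = FALSE)
  }
  out[out < 0] <- 0
  attributes(out) <- attributes(frame)
  out
}

#' Pushbroom hypercube reconstruction
#'
#' Assembles an ordered sequence of line-scan frames into a counts hypercube.
#' Frame `i` (1-based) occupies scan rows `(i-1)*step_pixels + 1 ..
#' i*step_pixels`; its single spatial line is duplicated `step_pixels` times to
#' fill the physical slit width, so per-wavelength slices tile the scan axis
#' without gaps and the scan extent is exactly `length(frames) * step_pixels`.
#'
#' @param frames List of `linescan_frame`s (or matrices) sharing shape and
#'   wavelength grid.
#' @param step_pixels Scan step between consecutive frames, in pixels (>= 1).
#' @param wavelengths Wavelength grid; taken from the first frame when omitted.
#' @return A `hypercube` of kind `"counts"` with dimensions
#'   `(n_frames * step_pixels, line_pixels, n_channels)`.
#' @export
reconstruct_hypercube <- function(frames, step_pixels, wavelengths = NULL) {
  if (!is.list(frames) || length(frames) == 0L)
    stop("frames must be a non-empty list", call. = FALSE)
  step_pixels <- as.integer(step_pixels)
  if (is.na(step_pixels) || step_pixels < 1L)
    stop("step_pixels must be a positive integer", call. = FALSE)
  d1 <- dim(frames[[1L]])
  if (!all(vapply(frames, function(f) identical(dim(f), d1), logical(1))))
    stop("all frames must share the same shape", call. = FALSE)
  if (is.null(wavelengths)) wavelengths <- attr(frames[[1L]], "wavelengths")
  if (is.null(wavelengths))
    stop("wavelengths must be supplied when frames carry no grid", call. = FALSE)
  n <- length(frames)
  out <- array(0, dim = c(n * step_pixels, d1[1L], d1[2L]))
  for (i in seq_len(n)) {
    f <- unclass(frames[[i]])
    rows <- (i - 1L) * step_pixels + seq_len(step_pixels)
    for (r in rows) out[r, , ] <- f
  }
  hypercube(out, wavelengths, "counts")
}
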