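## Background correction: reflectance/absorbance normalisation under ground-truth
## (GT), single (SB) and retrieved (RB) backgrounds.
##
## The RB method estimates the per-pixel illumination spectrum as
##   RM(x, y, lambda) = (C_s(x, y) / C_b) * NS(lambda)
## where NS is the min-max normalised source profile, C_b = NS(lambda_ref) and
## C_s(x, y) is the measured (dark-subtracted) intensity at the grid channel
## nearest the reference wavelength, chosen where the sample absorbs little
## (default 800 nm, the haemoglobin isosbestic point inside the NIR tissue
## optical window). Dividing the raw cube by RM then gives reflectance whose
## value at the reference channel is 1 by construction.

#' Min-max normalise a spectrum
#'
#' Affine map sending the spectrum minimum to 0 and maximum to 1.
#'
#' @param x Numeric vector with at least two distinct values.
#' @return Normalised vector in `[0, 1]`.
#' @export
minmax_normalize <- function(x) {
  x <- as.numeric(x)
  r <- range(x, finite = TRUE)
  if (!all(is.finite(r)) || r[1] == r[2])
    stop("cannot min-max normalise a constant spectrum (degenerate range)",
         call. = FALSE)
  (x - r[1]) / (r[2] - r[1])
}

#' Normalised source profile for background retrieval
#'
#' Wraps a measured light-source spectrum into the object the RB correction
#' needs: its min-max normalised profile `NS(lambda)`, the reference channel
#' (nearest grid channel to `ref_wavelength`), and `C_b = NS(lambda_ref)`.
#'
#' @param intensity Non-negative source spectrum on `wavelengths`.
#' @param wavelengths Wavelength grid (nm).
#' @param ref_wavelength Reference wavelength (nm), default 800.
#' @return Object of class `source_profile`: list with `ns`, `wavelengths`,
#'   `ref_wavelength`, `ref_index`, `cb`.
#' @export
source_profile <- function(intensity, wavelengths, ref_wavelength = 800) {
  wavelengths <- wavelength_grid(wavelengths)
  stopifnot(length(intensity) == length(wavelengths))
  if (any(intensity < 0)) stop("source intensity must be non-negative", call. = FALSE)
  ns <- minmax_normalize(intensity)
  ref_index <- nearest_channel(wavelengths, ref_wavelength)
  cb <- ns[ref_index]
  if (cb <= 0)
    stop("the normalised source profile vanishes at the reference wavelength; choose another reference",
         call. = FALSE)
  structure(list(ns = ns, wavelengths = wavelengths,
                 ref_wavelength = ref_wavelength, ref_index = ref_index,
                 cb = cb),
            class = "source_profile")
}

#' Construct a background field
#'
#' A per-pixel, per-wavelength illumination estimate `B(x, y, lambda)` in
#' counts, tagged with its provenance: `GT` (white reference measured under
#' the sample's exact conditions), `SB` (one white reference reused
#' everywhere), or `RB` (retrieved from the sample cube itself).
#'
#' @param field 3D non-negative array, or a `hypercube` of counts.
#' @param kind `"GT"`, `"SB"` or `"RB"`.
#' @return Object of class `background_field`: list with `field` (3D array)
#'   and `kind`.
#' @export
background_field <- function(field, kind = c("GT", "SB", "RB")) {
  kind <- match.arg(kind)
  if (inherits(field, "hypercube")) field <- field$data
  field <- as.array(field)
  if (length(dim(field)) != 3L)
    stop("background field must be a 3D array", call. = FALSE)
  if (any(!is.finite(field)) || any(field < 0))
    stop("background field must be finite and non-negative", call. = FALSE)
  structure(list(field = field, kind = kind), class = "background_field")
}

# Resolve dark argument to something subtractable from a 3D array.
.dark_array <- function(dark, dims) {
  if (is.null(dark)) return(0)
  if (length(dark) == 1L) return(as.numeric(dark))
  dark <- as.array(dark)
  if (length(dim(dark)) == 2L && all(dim(dark) == dims[1:2]))
    return(array(dark, dim = dims))          # recycled along lambda
  if (length(dim(dark)) == 3L && all(dim(dark) == dims)) return(dark)
  stop("dark must be a scalar, an (x, y) matrix, or a full (x, y, lambda) array",
       call. = FALSE)
}

.field_of <- function(I0) {
  if (inherits(I0, "background_field")) I0$field
  else if (inherits(I0, "hypercube")) I0$data
  else as.array(I0)
}

#' Reflectance normalisation
#'
#' `R = (I - I_dark) / (I_0 - I_dark)`, elementwise, where `I_0` is the
#' background (white) signal.
#'
#' @param I Counts `hypercube` of the sample.
#' @param I0 Background: a `background_field`, counts `hypercube`, or 3D array
#'   of the same shape.
#' @param dark Dark signal: scalar, `(x, y)` matrix or full array; default 0.
#' @return Reflectance `hypercube`.
#' @export
reflectance_cube <- function(I, I0, dark = 0) {
  stopifnot(inherits(I, "hypercube"))
  if (I$kind != "counts")
    stop("reflectance normalisation expects a counts hypercube", call. = FALSE)
  dims <- dim(I$data)
  B <- .field_of(I0)
  if (!all(dim(B) == dims))
    stop("background shape does not match the sample cube", call. = FALSE)
  dk <- .dark_array(dark, dims)
  denom <- B - dk
  if (any(denom <= 0))
    stop("background minus dark must be strictly positive everywhere",
         call. = FALSE)
  num <- I$data - dk
  num[num < 0] <- 0
  hypercube(num / denom, I$wavelengths, "reflectance")
}

#' Absorbance normalisation
#'
#' `A = -log10((I - I_dark) / (I_0 - I_dark))`. Non-positive ratios (shadowed
#' or under-dark pixels) are floored at `floor` instead of aborting the whole
#' cube; the affected positions are returned in the `"floored"` attribute and
#' reported with a warning.
#'
#' @inheritParams reflectance_cube
#' @param floor Replacement for non-positive ratios (default `1e-6`).
#' @return Absorbance `hypercube` (values may be negative where R > 1), with a
#'   logical `"floored"` attribute on `$data` when any ratio was floored.
#' @export
absorbance_cube <- function(I, I0, dark = 0, floor = 1e-6) {
  R <- reflectance_cube(I, I0, dark)
  reflectance_to_absorbance(R, floor = floor)
}

#' Convert a reflectance hypercube to absorbance
#'
#' @param R Reflectance `hypercube`.
#' @param floor Replacement for non-positive reflectance values.
#' @return Absorbance `hypercube`.
#' @export
reflectance_to_absorbance <- function(R, floor = 1e-6) {
  stopifnot(inherits(R, "hypercube"), R$kind == "reflectance")
  r <- R$data
  bad <- r <= 0
  if (any(bad)) {
    warning(sprintf("%d non-positive reflectance values floored at %g",
                    sum(bad), floor), call. = FALSE)
    r[bad] <- floor
  }
  A <- hypercube(-log10(r), R$wavelengths, "absorbance")
  if (any(bad)) attr(A$data, "floored") <- bad
  A
}

#' Retrieve the per-pixel illumination field from a sample cube
#'
#' For each pixel, the measured intensity at the reference channel,
#' `C_s(x, y)`, is divided by `C_b = NS(lambda_ref)` and the ratio multiplied
#' onto the normalised source profile:
#' `RM(x, y, lambda) = (C_s / C_b) * NS(lambda)`. Optionally `C_s` is averaged
#' over `band_halfwidth` channels either side of the reference channel to damp
#' noise (off by default; the single channel value is the reference method).
#'
#' `NS` is floored at `ns_floor` before use so the retrieved field stays
#' strictly positive at the profile's min-max zero channel; floored channels
#' are recorded in the `"ns_floored"` attribute.
#'
#' @param I Dark-subtracted counts `hypercube` of the sample.
#' @param profile A `source_profile` on the same wavelength grid.
#' @param band_halfwidth Integer half-width (channels) for band-averaging
#'   `C_s`; 0 disables it.
#' @param ns_floor Floor applied to the normalised profile (default `1e-3`).
#' @return A `background_field` of kind `"RB"`; pixels with `C_s <= 0` are
#'   flagged in its `"invalid_pixels"` attribute (their field is set to the
#'   smallest positive retrieved value so corrections remain finite).
#' @export
retrieve_background <- function(I, profile, band_halfwidth = 0, ns_floor = 1e-3) {
  stopifnot(inherits(I, "hypercube"), inherits(profile, "source_profile"))
  if (!isTRUE(all.equal(I$wavelengths, profile$wavelengths)))
    stop("cube and source profile are on different wavelength grids", call. = FALSE)
  d <- dim(I$data)
  ri <- profile$ref_index
  if (band_halfwidth > 0) {
    idx <- max(1L, ri - band_halfwidth):min(d[3L], ri + band_halfwidth)
    cs <- apply(I$data[, , idx, drop = FALSE], c(1, 2), mean)
  } else {
    cs <- I$data[, , ri]
  }
  invalid <- cs <= 0
  ns <- pmax(profile$ns, ns_floor)
  ratio <- cs / profile$cb
  if (any(invalid)) {
    pos <- ratio[!invalid]
    ratio[invalid] <- if (length(pos)) min(pos) else 1
    warning(sprintf("%d pixels have non-positive intensity at the reference channel",
                    sum(invalid)), call. = FALSE)
  }
  rm_field <- outer(ratio, ns)               # (x*y) outer lambda, dims ok below
  dim(rm_field) <- d
  bg <- background_field(rm_field, "RB")
  attr(bg$field, "ns_floored") <- profile$ns < ns_floor
  if (any(invalid)) attr(bg$field, "invalid_pixels") <- invalid
  bg
}

#' Retrieved-background correction
#'
#' One-step RB normalisation: retrieves the illumination field from the cube
#' itself ([retrieve_background()]) and divides by it. With no band-averaging
#' the resulting reflectance equals 1 at the reference channel for every
#' pixel, by construction.
#'
#' Channels where the normalised source profile lies below `ns_floor` (at
#' least the profile's min-max zero channel) carry no retrievable illumination
#' information; their corrected reflectance is set to the neutral value 1
#' (absorbance 0) and the channels are flagged in the `"ns_floored"`
#' attribute of the result's `$data`.
#'
#' @inheritParams retrieve_background
#' @param mode `"reflectance"` or `"absorbance"`.
#' @param dark Dark signal subtracted from `I` before retrieval and
#'   normalisation (default 0: cube already dark-subtracted).
#' @param floor Absorbance floor (see [absorbance_cube()]).
#' @return A `hypercube` of the requested kind.
#' @export
rb_correct <- function(I, profile, mode = c("reflectance", "absorbance"),
                       dark = 0, band_halfwidth = 0, ns_floor = 1e-3,
                       floor = 1e-6) {
  mode <- match.arg(mode)
  stopifnot(inherits(I, "hypercube"))
  if (!identical(dark, 0)) {
    dk <- .dark_array(dark, dim(I$data))
    d <- I$data - dk
    d[d < 0] <- 0
    I <- hypercube(d, I$wavelengths, "counts")
  }
  bg <- retrieve_background(I, profile, band_halfwidth = band_halfwidth,
                            ns_floor = ns_floor)
  flo <- attr(bg$field, "ns_floored")
  R <- reflectance_cube(I, bg)
  if (any(flo)) {
    # no retrievable illumination where the normalised profile is below the
    # floor: return neutral reflectance there rather than a floored ratio
    R$data[, , flo] <- 1
  }
  out <- if (mode == "reflectance") R
         else reflectance_to_absorbance(R, floor = floor)
  if (any(flo)) attr(out$data, "ns_floored") <- flo
  out
}
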