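## Pixel-wise PCA and spectral angle mapping for comparing background
## corrections. PCA centres each pixel spectrum by its own mean (so per-pixel
## additive offsets, e.g. the absorbance offset caused by a wrong background
## scale, drop out by construction), then takes the SVD of the channel
## cross-product matrix. SAM is scale-invariant, so per-pixel multiplicative
## illumination errors drop out of reflectance angle maps instead.

#' Pixel-wise principal component analysis of a hypercube
#'
#' The cube is vectorised to a (pixels x channels) matrix; each pixel spectrum
#' is centred by its own mean (`center = "pixel"`, the reference behaviour) or
#' alternatively each channel by its mean over pixels (`center = "channel"`,
#' the textbook convention); the channel cross-product matrix with `1/(n-1)`
#' normalisation is then decomposed by SVD.
#'
#' @param cube A `hypercube` with at least two pixels.
#' @param center `"pixel"` (default) or `"channel"`.
#' @param n_components Number of loadings/score maps to return (default all).
#' @return Object of class `hsi_pca`: list with `loadings` (channels x k,
#'   orthonormal, largest-magnitude element of each made positive),
#'   `explained_variance_ratio` (non-increasing, sums to 1 over all
#'   components), `scores` (pixels x k, `spatial_dim` attribute attached),
#'   and `center`.
#' @export
pixelwise_pca <- function(cube, center = c("pixel", "channel"),
                          n_components = NULL) {
  center <- match.arg(center)
  stopifnot(inherits(cube, "hypercube"))
  m <- vectorize_cube(cube)
  if (nrow(m) < 2L)
    stop("pixel-wise PCA needs at least two pixels", call. = FALSE)
  xc <- if (center == "pixel") m - rowMeans(m) else sweep(m, 2L, colMeans(m))
  cov <- crossprod(xc) / (nrow(xc) - 1)
  s <- svd(cov)
  ev <- pmax(s$d, 0)
  total <- sum(ev)
  ratio <- if (total > 0) ev / total else rep(0, length(ev))
  k <- if (is.null(n_components)) ncol(cov) else min(n_components, ncol(cov))
  loadings <- s$u[, seq_len(k), drop = FALSE]
  # sign convention: largest-magnitude element of each loading positive
  for (j in seq_len(k)) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) loadings[, j] <- -loadings[, j]
  }
  scores <- xc %*% loadings
  attr(scores, "spatial_dim") <- attr(m, "spatial_dim")
  structure(list(loadings = loadings, explained_variance_ratio = ratio,
                 scores = scores, center = center),
            class = "hsi_pca")
}

#' Spectral angle between two spectra
#'
#' `acos` of the cosine similarity, with the argument clamped to `[-1, 1]`
#' against floating-point overshoot. Zero iff the spectra are proportional;
#' invariant to positive scaling of either argument.
#'
#' @param t,r Target and reference spectra (non-zero vectors, equal length).
#' @return Angle in radians (in `[0, pi/2]` for non-negative spectra).
#' @export
sam_angle <- function(t, r) {
  stopifnot(length(t) == length(r))
  nt <- sqrt(sum(t^2)); nr <- sqrt(sum(r^2))
  if (nt == 0 || nr == 0)
    stop("spectral angle is undefined for a zero spectrum", call. = FALSE)
  acos(max(-1, min(1, sum(t * r) / (nt * nr))))
}

#' Spectral angle map of a hypercube against a reference spectrum
#'
#' @param cube A `hypercube`.
#' @param reference Reference spectrum on the cube's grid (e.g. a cluster mean
#'   from [cluster_references()]).
#' @return Object of class `sam_result`: list with `angles` (matrix, radians)
#'   and `reference`.
#' @export
sam_map <- function(cube, reference) {
  stopifnot(inherits(cube, "hypercube"),
            length(reference) == length(cube$wavelengths))
  nr <- sqrt(sum(reference^2))
  if (nr == 0) stop("reference spectrum is zero", call. = FALSE)
  m <- vectorize_cube(cube)
  norms <- sqrt(rowSums(m^2))
  cosang <- as.vector(m %*% reference) / (norms * nr)
  cosang[norms == 0] <- NA_real_
  angles <- acos(pmax(-1, pmin(1, cosang)))
  structure(list(angles = matrix(angles, dim(cube$data)[1L], dim(cube$data)[2L]),
                 reference = reference),
            class = "sam_result")
}

#' Per-class mean spectra of a labelled hypercube
#'
#' Averages the pixel spectra of each phantom class, giving the reference
#' spectra used for SAM analysis of that same cube.
#'
#' @param cube A `hypercube`.
#' @param layout A `phantom_layout` (or integer label matrix) matching the
#'   cube's spatial shape.
#' @return Matrix (classes x channels), rows named by class label.
#' @export
cluster_references <- function(cube, layout) {
  stopifnot(inherits(cube, "hypercube"))
  labels <- if (inherits(layout, "phantom_layout")) layout$labels else layout
  if (!all(dim(labels) == dim(cube$data)[1:2]))
    stop("label image shape does not match the cube", call. = FALSE)
  m <- vectorize_cube(cube)
  cls <- sort(unique(as.integer(labels)))
  refs <- t(vapply(cls, function(k) colMeans(m[as.integer(labels) == k, ,
                                               drop = FALSE]),
                   numeric(ncol(m))))
  rownames(refs) <- cls
  refs
}
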