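## Cube and spectrum I/O: HDF5 container, multi-band TIFF interchange, CSV spectra.

#' Write a hypercube to an HDF5 file
#'
#' Layout: dataset `/data` (float32, x by y by lambda), dataset `/wavelengths`
#' (float64, nm) and a root attribute `kind`.
#'
#' @param cube A `hypercube`.
#' @param path Output `.h5` path (overwritten if present).
#' @return `path`, invisibly.
#' @export
write_cube_h5 <- function(cube, path) {
  stopifnot(inherits(cube, "hypercube"))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5createDataset(path, "data", dims = dim(cube$data),
                         H5type = "H5T_IEEE_F32LE")
  rhdf5::h5write(cube$data, path, "data")
  rhdf5::h5write(as.double(cube$wavelengths), path, "wavelengths")
  fid <- rhdf5::H5Fopen(path)
  rhdf5::h5writeAttribute(cube$kind, fid, "kind")
  rhdf5::H5Fclose(fid)
  rhdf5::h5closeAll()
  invisible(path)
}

#' Read a hypercube from an HDF5 file
#'
#' @param path `.h5` file written by [write_cube_h5()] (or any file exposing
#'   `/data`, `/wavelengths` and a root `kind` attribute).
#' @return A `hypercube`. Values are float32 on disk, so round-tripping is
#'   exact only to single precision.
#' @export
read_cube_h5 <- function(path) {
  data <- rhdf5::h5read(path, "data")
  wl <- as.numeric(rhdf5::h5read(path, "wavelengths"))
  fid <- rhdf5::H5Fopen(path)
  kind <- tryCatch(as.character(rhdf5::h5readAttributes(fid, "/")$kind),
                   error = function(e) "counts")
  rhdf5::H5Fclose(fid)
  rhdf5::h5closeAll()
  if (length(kind) == 0L || is.na(kind)) kind <- "counts"
  hypercube(data, wl, kind)
}

#' Write a hypercube as a multi-band TIFF
#'
#' One 32-bit float TIFF directory per wavelength channel. The TIFF writer
#' stores values in `[0, 1]`, so the cube is divided by its maximum and the
#' scale recorded in a JSON sidecar `<path>.json` together with the wavelength
#' grid and the cube kind; [read_cube_tiff()] undoes the scaling using the
#' sidecar.
#'
#' @param cube A `hypercube`.
#' @param path Output `.tif` path.
#' @return `path`, invisibly.
#' @export
write_cube_tiff <- function(cube, path) {
  stopifnot(inherits(cube, "hypercube"))
  mx <- max(cube$data)
  scale <- if (mx > 0) mx else 1
  slices <- lapply(seq_along(cube$wavelengths),
                   function(k) cube$data[, , k] / scale)
  tiff::writeTIFF(slices, path, bits.per.sample = 32L, reduce = FALSE,
                  compression = "none")
  jsonlite::write_json(list(wavelengths = cube$wavelengths, kind = cube$kind,
                            scale = scale),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a multi-band TIFF hypercube
#'
#' @param path `.tif` path; one directory per wavelength.
#' @param wavelengths Wavelength grid; defaults to the `<path>.json` sidecar.
#' @param kind Cube kind; defaults to the sidecar, else `"counts"`.
#' @return A `hypercube` (single-precision values).
#' @export
read_cube_tiff <- function(path, wavelengths = NULL, kind = NULL) {
  side <- paste0(path, ".json")
  scale <- 1
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    if (is.null(wavelengths)) wavelengths <- as.numeric(meta$wavelengths)
    if (is.null(kind)) kind <- meta$kind
    if (!is.null(meta$scale)) scale <- as.numeric(meta$scale)
  }
  if (is.null(kind)) kind <- "counts"
  if (is.null(wavelengths))
    stop("no wavelength sidecar found; pass `wavelengths`", call. = FALSE)
  slices <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(slices)) slices <- list(slices)
  if (length(slices) != length(wavelengths))
    stop("band count does not match the wavelength grid", call. = FALSE)
  a <- array(0, dim = c(dim(slices[[1]])[1:2], length(slices)))
  for (k in seq_along(slices)) a[, , k] <- slices[[k]][, , drop = TRUE]
  hypercube(a * scale, wavelengths, kind)
}

#' Read a two-column spectrum CSV
#'
#' Expects columns `wavelength_nm` and `intensity` (header required).
#'
#' @param path CSV path.
#' @return List with numeric `wavelengths` and `intensity`.
#' @export
read_spectrum_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("wavelength_nm", "intensity") %in% names(df)))
    stop("spectrum CSV needs columns wavelength_nm and intensity", call. = FALSE)
  list(wavelengths = wavelength_grid(df$wavelength_nm),
       intensity = as.numeric(df$intensity))
}

#' Write a two-column spectrum CSV
#'
#' @param wavelengths Wavelength grid (nm).
#' @param intensity Spectrum values.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_spectrum_csv <- function(wavelengths, intensity, path) {
  stopifnot(length(wavelengths) == length(intensity))
  utils::write.csv(data.frame(wavelength_nm = wavelengths,
                              intensity = intensity),
                   path, row.names = FALSE)
  invisible(path)
}
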