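#' Acquisition geometry of a camera-based fluorescence microscope
#'
#' Bundles the optical parameters that convert between camera pixels and
#' object-plane distances. The object-plane pixel size is always recomputed as
#' `camera_pixel_size_um * 1000 / magnification` (in nm) so it can never be
#' stored inconsistently with its inputs.
#'
#' @param camera_pixel_size_um Physical camera pixel pitch in micrometres
#'   (e.g. 24 for a typical EMCCD, 11 for an sCMOS).
#' @param magnification Total magnification onto the camera (dimensionless).
#' @param psf_e2_radius_nm 1/e^2 radius of the Gaussian point spread function
#'   in nm, as calibrated for the emission channel. May be `NA` before
#'   calibration (see [calibrate_psf()]).
#' @param emission_wavelength_nm Emission wavelength in nm.
#' @param numerical_aperture Objective numerical aperture.
#' @param binning Spatial binning factor currently applied (integer >= 1).
#'
#' @return An object of class `acquisition_geometry`: a list with the above
#'   fields plus `object_pixel_size_nm`, the back-projected pixel size in the
#'   object plane (after `binning`).
#' @export
#' @examples
#' g <- acquisition_geometry(24, 100, psf_e2_radius_nm = 364)
#' g$object_pixel_size_nm  # 240 nm
acquisition_geometry <- function(camera_pixel_size_um, magnification,
                                 psf_e2_radius_nm = NA_real_,
                                 emission_wavelength_nm = 565,
                                 numerical_aperture = 1.49,
                                 binning = 1L) {
  stopifnot(camera_pixel_size_um > 0, magnification > 0, binning >= 1)
  if (!is.na(psf_e2_radius_nm) && psf_e2_radius_nm <= 0)
    stop("psf_e2_radius_nm must be positive")
  g <- list(
    camera_pixel_size_um = camera_pixel_size_um,
    magnification = magnification,
    psf_e2_radius_nm = psf_e2_radius_nm,
    emission_wavelength_nm = emission_wavelength_nm,
    numerical_aperture = numerical_aperture,
    binning = as.integer(binning),
    object_pixel_size_nm = camera_pixel_size_um * 1000 / magnification * binning
  )
  class(g) <- "acquisition_geometry"
  g
}

#' @export
print.acquisition_geometry <- function(x, ...) {
  cat("<acquisition_geometry>\n")
  cat(sprintf("  camera pixel : %g um, magnification x%g, binning %d\n",
              x$camera_pixel_size_um, x$magnification, x$binning))
  cat(sprintf("  object pixel : %g nm\n", x$object_pixel_size_nm))
  cat(sprintf("  PSF 1/e2     : %s nm   (lambda = %g nm, NA = %g)\n",
              format(x$psf_e2_radius_nm), x$emission_wavelength_nm,
              x$numerical_aperture))
  invisible(x)
}

#' Update the binning factor of a geometry
#'
#' Returns a copy of `geometry` whose `binning` (and hence effective
#' object-plane pixel size) reflects `binning` additional spatial binning.
#'
#' @param geometry An [acquisition_geometry()].
#' @param binning New binning factor (replaces, does not multiply, the old one).
#' @return A new `acquisition_geometry`.
#' @export
with_binning <- function(geometry, binning) {
  acquisition_geometry(geometry$camera_pixel_size_um, geometry$magnification,
                       geometry$psf_e2_radius_nm,
                       geometry$emission_wavelength_nm,
                       geometry$numerical_aperture, binning)
}

#' Time-ordered image stack
#'
#' The universal input of all analysis stages: a `H x W x T` array of
#' non-negative intensity counts plus the acquisition frame time and,
#' optionally, the acquisition geometry.
#'
#' @param data Numeric array of dimension `c(H, W, T)` (rows, columns, frames),
#'   or a `H x W` matrix for a single frame. All values must be finite and
#'   >= 0.
#' @param frame_time Time per frame in seconds (> 0).
#' @param geometry Optional [acquisition_geometry()].
#' @param bit_depth Nominal camera bit depth (metadata only).
#' @return An object of class `image_stack` with elements `data`, `frame_time`,
#'   `geometry`, `bit_depth`.
#' @export
image_stack <- function(data, frame_time, geometry = NULL, bit_depth = 16L) {
  if (is.matrix(data)) dim(data) <- c(dim(data), 1L)
  if (length(dim(data)) != 3L) stop("data must be a H x W x T array")
  if (any(dim(data) < 1L)) stop("empty image stack")
  if (!all(is.finite(data))) stop("intensities must be finite")
  if (min(data) < 0) stop("intensities must be non-negative")
  if (!is.numeric(frame_time) || frame_time <= 0) stop("frame_time must be > 0")
  s <- list(data = data, frame_time = frame_time, geometry = geometry,
            bit_depth = as.integer(bit_depth))
  class(s) <- "image_stack"
  s
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_stack> %d x %d px, %d frames @ %g s/frame (%s s total)\n",
              d[1], d[2], d[3], x$frame_time, format(d[3] * x$frame_time)))
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$data)

n_frames <- function(stack) dim(stack$data)[3]

#' Read a multi-page grayscale TIFF as an image stack
#'
#' @param path Path to a multi-page grayscale TIFF (8/16/32 bit).
#' @param frame_time Seconds per frame.
#' @param geometry Optional [acquisition_geometry()] to attach.
#' @return An [image_stack()] with frames in file order.
#' @export
read_stack <- function(path, frame_time, geometry = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) == 0L) stop("TIFF contains no frames")
  if (any(!vapply(pages, is.matrix, logical(1))))
    stop("not a single-channel grayscale TIFF")
  dims <- vapply(pages, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("ragged page sizes in TIFF")
  arr <- array(unlist(pages, use.names = FALSE),
               dim = c(dims[1, 1], dims[2, 1], length(pages)))
  # readTIFF returns matrices filled row-major relative to the image; unlist of
  # matrices keeps R column-major layout, which is what we defined above.
  image_stack(arr, frame_time, geometry)
}

#' Write an image stack as a multi-page TIFF
#'
#' Integer stacks are written at 16 bit (values must fit in 0..65535); use
#' [write_map()] for floating-point parameter maps.
#'
#' @param stack An [image_stack()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  d <- stack$data
  if (max(d) > 65535) stop("values exceed 16-bit range")
  pages <- lapply(seq_len(dim(d)[3]), function(t) d[, , t] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Bin an image stack in time
#'
#' Groups of `n` consecutive frames are combined (sum or mean); leftover
#' frames that do not fill a complete group are dropped. The frame time of the
#' result is `n * frame_time`.
#'
#' @param stack An [image_stack()].
#' @param n Frames per group (integer >= 1).
#' @param mode `"sum"` or `"mean"`.
#' @return A binned [image_stack()].
#' @export
#' @examples
#' # 50,000 x 2 ms frames -> 5,000 x 20 ms frames by sum binning of 10
bin_temporal <- function(stack, n, mode = c("sum", "mean")) {
  mode <- match.arg(mode)
  n <- as.integer(n)
  stopifnot(n >= 1)
  d <- dim(stack$data)
  Tn <- d[3] %/% n
  if (Tn < 1L) stop("n exceeds the number of frames: empty output")
  if (n == 1L) return(stack)
  x <- stack$data[, , seq_len(Tn * n), drop = FALSE]
  # reshape so the grouping axis is first, then collapse it
  dim(x) <- c(d[1] * d[2], n, Tn)
  out <- colSums(aperm(x, c(2, 1, 3)))    # (H*W) x Tn sums over groups
  if (mode == "mean") out <- out / n
  dim(out) <- c(d[1], d[2], Tn)
  image_stack(out, stack$frame_time * n, stack$geometry, stack$bit_depth)
}

#' Bin an image stack in space
#'
#' Non-overlapping `n x n` pixel blocks anchored at pixel (0, 0) (top-left);
#' trailing partial rows/columns are dropped. The attached geometry (if any)
#' has its binning updated so the object-plane pixel size scales by `n`.
#'
#' @param stack An [image_stack()].
#' @param n Block side in pixels (integer >= 1).
#' @param mode `"sum"` or `"mean"`.
#' @return A spatially binned [image_stack()].
#' @export
bin_spatial <- function(stack, n, mode = c("sum", "mean")) {
  mode <- match.arg(mode)
  n <- as.integer(n)
  stopifnot(n >= 1)
  d <- dim(stack$data)
  Hn <- d[1] %/% n; Wn <- d[2] %/% n
  if (Hn < 1L || Wn < 1L) stop("n exceeds the image size: empty output")
  if (n == 1L) return(stack)
  x <- stack$data[seq_len(Hn * n), seq_len(Wn * n), , drop = FALSE]
  dim(x) <- c(n, Hn, n, Wn, d[3])
  out <- colSums(aperm(x, c(1, 3, 2, 4, 5)), dims = 2)  # sums n x n blocks
  if (mode == "mean") out <- out / (n * n)
  geom <- if (!is.null(stack$geometry))
    with_binning(stack$geometry, stack$geometry$binning * n) else NULL
  image_stack(out, stack$frame_time, geom, stack$bit_depth)
}

#' Crop an image stack
#'
#' Margins are given in pixels from each edge (0-based raster convention,
#' row/column, y increasing downward). Used e.g. to remove the dark border
#' that radiality super-resolution introduces, keeping the same field of view
#' in all co-registered maps.
#'
#' @param stack An [image_stack()].
#' @param top,bottom,left,right Number of pixels to remove from each edge.
#' @return A cropped [image_stack()].
#' @export
crop_stack <- function(stack, top = 0L, bottom = 0L, left = 0L, right = 0L) {
  d <- dim(stack$data)
  if (top + bottom >= d[1] || left + right >= d[2])
    stop("crop removes everything")
  rows <- seq.int(top + 1L, d[1] - bottom)
  cols <- seq.int(left + 1L, d[2] - right)
  image_stack(stack$data[rows, cols, , drop = FALSE], stack$frame_time,
              stack$geometry, stack$bit_depth)
}

#' Per-pixel parameter map
#'
#' A real-valued grid (e.g. a diffusion map) plus a validity mask. Values are
#' only meaningful where `validity` is `TRUE`; invalid entries are stored as
#' `NA`.
#'
#' @param values Numeric matrix.
#' @param validity Logical matrix of the same size (default: finite values).
#' @param name,units Labels for reporting.
#' @param binning Spatial binning at which the map was computed, relative to
#'   the parent stack.
#' @param origin 0-based (row, col) offset of the map's (0,0) pixel in the
#'   parent stack.
#' @return An object of class `parameter_map`.
#' @export
parameter_map <- function(values, validity = NULL, name = "value", units = "",
                          binning = 1L, origin = c(0L, 0L)) {
  values <- as.matrix(values)
  if (is.null(validity)) validity <- is.finite(values)
  validity <- as.matrix(validity)
  stopifnot(identical(dim(values), dim(validity)))
  validity[!is.finite(values)] <- FALSE
  values[!validity] <- NA_real_
  m <- list(values = values, validity = validity, name = name, units = units,
            binning = as.integer(binning), origin = as.integer(origin))
  class(m) <- "parameter_map"
  m
}

#' @export
print.parameter_map <- function(x, ...) {
  v <- x$values[x$validity]
  cat(sprintf("<parameter_map> %s [%s] %d x %d, %d/%d valid",
              x$name, x$units, nrow(x$values), ncol(x$values),
              sum(x$validity), length(x$validity)))
  if (length(v))
    cat(sprintf("; mean %.4g, sd %.4g", mean(v), stats::sd(v)))
  cat("\n")
  invisible(x)
}

#' Write a parameter map as 32-bit TIFF plus CSV
#'
#' The CSV is the canonical output and holds one row per pixel: 0-based
#' `row`, `col`, `value`, `valid`. The TIFF is a rendering for image viewers:
#' values are min-max scaled to [0, 1] (invalid pixels at 0); the scaling is
#' recorded in the CSV, not the TIFF.
#'
#' @param map A [parameter_map()].
#' @param path Output path without extension; `.tif` and `.csv` are appended.
#' @return The two paths, invisibly.
#' @export
write_map <- function(map, path) {
  v <- map$values
  v[!map$validity] <- NA
  rng <- range(v, na.rm = TRUE, finite = TRUE)
  if (!all(is.finite(rng)) || diff(rng) == 0) rng <- c(0, 1)
  scaled <- (v - rng[1]) / diff(rng)
  scaled[!is.finite(scaled)] <- 0
  tif <- paste0(path, ".tif"); csv <- paste0(path, ".csv")
  tiff::writeTIFF(scaled, tif, bits.per.sample = 32L, compression = "none")
  df <- data.frame(row = rep(seq_len(nrow(v)) - 1L, times = ncol(v)),
                   col = rep(seq_len(ncol(v)) - 1L, each = nrow(v)),
                   value = as.vector(map$values),
                   valid = as.vector(map$validity))
  utils::write.csv(df, csv, row.names = FALSE)
  invisible(c(tif, csv))
}
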