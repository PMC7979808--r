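#' Parameters for radiality super-resolution
#'
#' @param ring_radius Sampling-ring radius in original pixels. Default 0.5.
#' @param magnification Sub-pixel magnification M (integer >= 1). Default 5.
#' @param axes Axes in the ring; `2 * axes` points are sampled. Default 6.
#' @param temporal_mode `"TRAC2"` (lag-1 temporal auto-cumulant of the
#'   radiality series, default) or `"mean"`.
#' @param temporal_bin Frames averaged per radiality frame. Default 100.
#' @param intensity_weighting Weight radiality by the interpolated frame
#'   intensity? Default `TRUE`.
#' @return An `srrf_params` list.
#' @export
srrf_params <- function(ring_radius = 0.5, magnification = 5L, axes = 6L,
                        temporal_mode = c("TRAC2", "mean"),
                        temporal_bin = 100L, intensity_weighting = TRUE) {
  temporal_mode <- match.arg(temporal_mode)
  stopifnot(ring_radius > 0, magnification >= 1, axes >= 2, temporal_bin >= 1)
  structure(list(ring_radius = ring_radius,
                 magnification = as.integer(magnification),
                 axes = as.integer(axes), temporal_mode = temporal_mode,
                 temporal_bin = as.integer(temporal_bin),
                 intensity_weighting = isTRUE(intensity_weighting)),
            class = "srrf_params")
}

#' Super-resolution image container
#'
#' @param image Non-negative matrix on the magnified (radiality) or original
#'   (cumulant) grid.
#' @param magnification Sub-pixels per original pixel.
#' @param method Label (`"SRRF-TRAC2"`, `"SOFI-2"`, ...).
#' @param params The generating parameter object.
#' @param border Width (in original pixels) of the zeroed border.
#' @return A `superres_image`.
#' @export
superres_image <- function(image, magnification, method, params = NULL,
                           border = 0L) {
  stopifnot(is.matrix(image), min(image) >= 0)
  structure(list(image = image, magnification = as.integer(magnification),
                 method = method, params = params, border = as.integer(border)),
            class = "superres_image")
}

#' @export
print.superres_image <- function(x, ...) {
  cat(sprintf("<superres_image> %s, %d x %d (M = %d, border %d px)\n",
              x$method, nrow(x$image), ncol(x$image), x$magnification,
              x$border))
  invisible(x)
}

#' Radiality transform of a single frame
#'
#' Measures gradient convergence on an M-times finer grid: around every
#' sub-pixel centre, points on a ring of `ring_radius` are sampled; at each
#' point the (bicubically interpolated) intensity-gradient direction defines
#' a line, and the line's perpendicular distance from the centre scores how
#' precisely gradients converge there. Peaks of the radiality localise
#' emitters below the diffraction limit; uniform gradients (ramps) score ~0.
#'
#' @param frame Numeric matrix (>= 5 x 5).
#' @param params An [srrf_params()].
#' @return A [superres_image()] of size `M * dim(frame)` with a zeroed border
#'   of `ceiling(ring_radius) + 1` original pixels.
#' @export
radiality_frame <- function(frame, params = srrf_params()) {
  stopifnot(is.matrix(frame), nrow(frame) >= 5, ncol(frame) >= 5)
  r <- radiality_cpp(frame, params$magnification, params$ring_radius,
                     params$axes, params$intensity_weighting)
  b <- as.integer(ceiling(params$ring_radius) + 1)
  r <- zero_border(r, b * params$magnification)
  superres_image(r, params$magnification, "radiality", params, border = b)
}

zero_border <- function(m, w) {
  if (w <= 0) return(m)
  H <- nrow(m); W <- ncol(m)
  m[c(seq_len(min(w, H)), seq.int(max(1, H - w + 1), H)), ] <- 0
  m[, c(seq_len(min(w, W)), seq.int(max(1, W - w + 1), W))] <- 0
  m
}

#' SRRF-style super-resolution of an image stack
#'
#' The stack is average-binned to radiality frames (`temporal_bin` raw frames
#' each), the radiality transform is applied per frame, and the radiality
#' time series is compressed per sub-pixel: in `TRAC2` mode to the absolute
#' lag-1 temporal auto-correlation of fluctuations
#' `|<dR_t dR_{t+1}>|` (second-order auto-cumulant, which favours
#' fluctuating, i.e. genuinely blinking/exchanging, structures), in `mean`
#' mode to the plain temporal mean.
#'
#' With `normalize = TRUE` the result is divided by the squared (TRAC2) or
#' plain (mean) spatial-mean intensity of the input stack, making the output
#' invariant to global intensity rescaling.
#'
#' @param stack An [image_stack()].
#' @param params An [srrf_params()].
#' @param normalize Divide out the global intensity scale? Default `TRUE`.
#' @return A [superres_image()] on the `M * H x M * W` grid.
#' @export
srrf <- function(stack, params = srrf_params(), normalize = TRUE) {
  binned <- bin_temporal(stack, params$temporal_bin, "mean")
  Tn <- dim(binned$data)[3]
  if (params$temporal_mode == "TRAC2" && Tn < 2L)
    stop("TRAC2 needs at least 2 radiality frames after temporal binning")
  M <- params$magnification
  d <- dim(binned$data)
  rad <- array(0, c(d[1] * M, d[2] * M, Tn))
  for (t in seq_len(Tn))
    rad[, , t] <- radiality_cpp(binned$data[, , t], M, params$ring_radius,
                                params$axes, params$intensity_weighting)
  if (params$temporal_mode == "mean") {
    img <- apply(rad, c(1, 2), mean)
    if (normalize) img <- img / mean(stack$data)
  } else {
    mu <- apply(rad, c(1, 2), mean)
    dx <- sweep(rad, c(1, 2), mu)
    img <- abs(apply(dx[, , -Tn, drop = FALSE] * dx[, , -1, drop = FALSE],
                     c(1, 2), mean))
    if (normalize) img <- img / mean(stack$data)^2
  }
  b <- as.integer(ceiling(params$ring_radius) + 1)
  img <- zero_border(img, b * M)
  superres_image(img, M,
                 paste0("SRRF-", params$temporal_mode), params, border = b)
}

#' SOFI cumulant super-resolution
#'
#' Per-pixel temporal cumulants of the bleach-corrected intensity trace:
#' order 2 is the central second moment (variance), order 4 the fourth
#' cumulant `m4 - 3 m2^2`. Absolute values are returned. Because cumulants of
#' independent (e.g. Gaussian read) noise above order 2 vanish and
#' fluctuation amplitudes enter nonlinearly, higher orders sharpen emitter
#' images at the cost of dynamic range. Output stays on the original pixel
#' grid (no cross-cumulants).
#'
#' @param stack An [image_stack()].
#' @param order 2 or 4.
#' @param bleach_order Polynomial bleach-correction order (0 disables).
#' @return A [superres_image()] with `magnification = 1`.
#' @export
sofi <- function(stack, order = 2L, bleach_order = 8L) {
  order <- as.integer(order)
  if (!order %in% c(2L, 4L)) stop("order must be 2 or 4")
  d <- dim(stack$data)
  traces <- t(matrix(stack$data, d[1] * d[2], d[3]))
  traces <- bleach_correct_matrix(traces, bleach_order)$traces
  dx <- sweep(traces, 2, colMeans(traces))
  m2 <- colMeans(dx^2)
  k <- if (order == 2L) m2 else colMeans(dx^4) - 3 * m2^2
  superres_image(matrix(abs(k), d[1], d[2]), 1L, paste0("SOFI-", order))
}
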