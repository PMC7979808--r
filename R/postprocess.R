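#' Intensity mask from a mean (TIRF) image
#'
#' @param mean_image Numeric matrix (e.g. temporal mean of a stack).
#' @param threshold Numeric intensity threshold, or `"otsu"` to choose it by
#'   Otsu's method on the image histogram.
#' @return Logical matrix, `TRUE` where `mean_image >= threshold`, with the
#'   chosen threshold attached as attribute `"threshold"`. Warns when the
#'   mask comes out empty.
#' @export
tirf_mask <- function(mean_image, threshold = "otsu") {
  stopifnot(is.matrix(mean_image), all(is.finite(mean_image)))
  if (identical(threshold, "otsu"))
    threshold <- EBImage::otsu(mean_image, range = range(mean_image),
                               levels = 4096L)
  mask <- mean_image >= threshold
  if (!any(mask)) warning("threshold above image maximum: empty mask")
  attr(mask, "threshold") <- threshold
  mask
}

#' Diffusion threshold from a bimodal D histogram
#'
#' Histograms `log10(D)` over the valid masked pixels (40 bins over the data
#' range, smoothed by a 3-bin moving average). When at least two peaks are
#' found, the D at the minimum between the two largest peaks is returned —
#' the value separating a slow (aggregate/artefact) pool from the mobile
#' pool. Otherwise the configured fallback is returned with a warning.
#'
#' @param d_map A [parameter_map()] of D in um^2/s.
#' @param mask Optional logical matrix restricting the pixels.
#' @param bins Histogram bins. Default 40.
#' @param fallback Threshold used when the histogram is unimodal. Default
#'   0.2 um^2/s.
#' @return Threshold in um^2/s, with attributes `"fallback_used"` (logical)
#'   and `"histogram"`.
#' @export
d_histogram_threshold <- function(d_map, mask = NULL, bins = 40L,
                                  fallback = 0.2) {
  sel <- d_map$validity & d_map$values > 0
  if (!is.null(mask)) sel <- sel & mask
  v <- log10(d_map$values[sel])
  if (length(v) < 100) stop("fewer than 100 valid masked pixels")
  h <- graphics::hist(v, breaks = seq(min(v), max(v), length.out = bins + 1),
                      plot = FALSE)
  cnt <- as.numeric(stats::filter(h$counts, rep(1 / 3, 3), sides = 2))
  cnt[is.na(cnt)] <- h$counts[is.na(cnt)]
  n <- length(cnt)
  # candidate peaks: local maxima with at least 25% of the modal count
  is_peak <- which(cnt > c(-Inf, cnt[-n]) & cnt >= c(cnt[-1], -Inf) &
                     cnt >= 0.25 * max(cnt))
  bimodal <- FALSE
  if (length(is_peak) >= 2) {
    top2 <- sort(is_peak[order(cnt[is_peak], decreasing = TRUE)][1:2])
    between <- seq.int(top2[1], top2[2])
    vmin <- min(cnt[between])
    # a genuine valley must dip well below the smaller of the two peaks
    bimodal <- vmin < 0.6 * min(cnt[top2])
    # centre of the flat minimum region between the peaks
    minima <- between[cnt[between] <= vmin + 1e-9]
    valley <- minima[ceiling(length(minima) / 2)]
  }
  if (bimodal) {
    structure(10^h$mids[valley], fallback_used = FALSE, histogram = h)
  } else {
    warning("unimodal D histogram: using fallback threshold")
    structure(fallback, fallback_used = TRUE, histogram = h)
  }
}

#' Replicate a pixel-grid mask onto a finer super-resolution grid
#'
#' Nearest-neighbour block replication: a map pixel governs its `M x M`
#' sub-pixel block (masks are categorical, so no interpolation).
#'
#' @param mask Logical matrix.
#' @param M Integer sub-pixels per pixel.
#' @return Logical matrix of size `M * dim(mask)`.
#' @export
upsample_mask <- function(mask, M) {
  M <- as.integer(M)
  mask[rep(seq_len(nrow(mask)), each = M), rep(seq_len(ncol(mask)), each = M)]
}

#' Mutual artifact correction of a super-resolution image by dynamics
#'
#' The correction pipeline: (1) the super-resolution image is masked by the
#' intensity-derived TIRF mask (removes off-structure artefacts); (2) the D
#' map is thresholded at `d_threshold` inside the TIRF mask, keeping only
#' pixels whose valid diffusion coefficient is consistent with dynamics on
#' the structure (removes slow aggregates); (3) the super-resolution image is
#' masked again by the up-sampled D-filtered mask. On/off-structure D
#' summaries before and after D filtering quantify the precision gain.
#'
#' @param superres A [superres_image()].
#' @param tirf_mask Logical matrix on the map grid.
#' @param d_map A [parameter_map()] of D, co-registered with `tirf_mask`.
#' @param d_threshold Threshold in um^2/s (e.g. from
#'   [d_histogram_threshold()]). Pixels with `D >= d_threshold` are kept.
#' @return A `mask_pipeline_result`: list with `tirf_mask`,
#'   `d_filtered_mask`, `corrected_superres`, `d_threshold`, and `summary`
#'   (data.frame of on-mask D mean/SD/COV/n before and after filtering).
#' @export
correct_superres <- function(superres, tirf_mask, d_map, d_threshold = 0.2) {
  if (!identical(dim(tirf_mask), dim(d_map$values)))
    stop("tirf_mask and d_map are not co-registered")
  M <- nrow(superres$image) / nrow(tirf_mask)
  if (M != round(M) || ncol(superres$image) / ncol(tirf_mask) != M)
    stop("super-resolution grid is not an integer multiple of the map grid")
  tm <- tirf_mask & !is.na(tirf_mask)
  dmask <- tm & d_map$validity & !is.na(d_map$values) &
    d_map$values >= d_threshold
  img1 <- superres$image * upsample_mask(tm, M)
  img2 <- img1 * upsample_mask(dmask, M)
  stat <- function(v) c(mean = mean(v), sd = stats::sd(v),
                        cov = stats::sd(v) / mean(v), n = length(v))
  d_on <- d_map$values[tm & d_map$validity]
  d_flt <- d_map$values[dmask]
  summary <- rbind(on_mask = stat(d_on), d_filtered = stat(d_flt))
  structure(list(
    tirf_mask = tm, d_filtered_mask = dmask, d_threshold = d_threshold,
    corrected_superres = superres_image(img2, superres$magnification,
                                        paste0(superres$method, "+Dfilter"),
                                        superres$params, superres$border),
    tirf_masked_superres = superres_image(img1, superres$magnification,
                                          paste0(superres$method, "+TIRF"),
                                          superres$params, superres$border),
    summary = as.data.frame(summary)),
    class = "mask_pipeline_result")
}

#' @export
print.mask_pipeline_result <- function(x, ...) {
  cat(sprintf("<mask_pipeline_result> D threshold %.3g um^2/s\n",
              x$d_threshold))
  print(round(x$summary, 4))
  invisible(x)
}

#' Pearson correlation between two parameter maps
#'
#' Pixels must be valid in both maps to enter; with `log_transform` the
#' correlation is computed on `log10` values and non-positive pixels are
#' additionally excluded (their count is reported).
#'
#' @param map1,map2 [parameter_map()]s of identical dimensions (spatially bin
#'   the finer map first if needed).
#' @param log_transform Correlate `log10` values? Default `TRUE`.
#' @param breaks Bins per axis of the returned 2-D frequency table.
#' @return List: `R` (Pearson), `n`, `excluded_nonpositive`, `table` (2-D
#'   histogram counts with axis break points).
#' @export
map_correlation <- function(map1, map2, log_transform = TRUE, breaks = 50L) {
  if (!identical(dim(map1$values), dim(map2$values)))
    stop("maps must be co-registered to identical dimensions")
  sel <- map1$validity & map2$validity
  x <- map1$values[sel]; y <- map2$values[sel]
  excluded <- 0L
  if (log_transform) {
    pos <- x > 0 & y > 0
    excluded <- sum(!pos)
    x <- log10(x[pos]); y <- log10(y[pos])
  }
  if (length(x) < 10) stop("fewer than 10 valid pixel pairs")
  bx <- seq(min(x), max(x), length.out = breaks + 1)
  by <- seq(min(y), max(y), length.out = breaks + 1)
  tab <- table(cut(x, bx, include.lowest = TRUE),
               cut(y, by, include.lowest = TRUE))
  list(R = stats::cor(x, y), n = length(x),
       excluded_nonpositive = excluded,
       table = list(counts = unclass(tab), xbreaks = bx, ybreaks = by))
}

#' Signal-to-noise ratio between two pixel regions
#'
#' `SNR = (<I_signal> - <I_background>) / sd(signal)`, where the means and
#' the SD run over the pixels and frames of each region. The same expression
#' serves the cell/background and the on/off-fibre variants. A warning is
#' issued below SNR 3, the regime where dynamics-based filtering of
#' super-resolution images becomes unreliable.
#'
#' @param stack An [image_stack()].
#' @param signal_mask,background_mask Disjoint non-empty logical matrices on
#'   the pixel grid.
#' @return An `snr_result` list: `signal_mean`, `background_mean`,
#'   `signal_sd`, `snr`.
#' @export
snr <- function(stack, signal_mask, background_mask) {
  if (!any(signal_mask) || !any(background_mask)) stop("empty region")
  if (any(signal_mask & background_mask)) stop("regions are not disjoint")
  d <- dim(stack$data)
  px <- matrix(stack$data, d[1] * d[2], d[3])
  sig <- px[as.vector(signal_mask), , drop = FALSE]
  bgr <- px[as.vector(background_mask), , drop = FALSE]
  s <- stats::sd(as.vector(sig))     # SD over the region's pixels and frames
  if (s == 0) stop("zero signal variance: SNR undefined")
  out <- list(signal_mean = mean(sig), background_mean = mean(bgr),
              signal_sd = s, snr = (mean(sig) - mean(bgr)) / s)
  if (out$snr < 3)
    warning(sprintf("SNR %.2f < 3: dynamics-based filtering may be unreliable",
                    out$snr))
  structure(out, class = "snr_result")
}

#' @export
print.snr_result <- function(x, ...) {
  cat(sprintf("<snr_result> SNR = %.3g (signal %.4g, background %.4g, sd %.4g)\n",
              x$snr, x$signal_mean, x$background_mean, x$signal_sd))
  invisible(x)
}

#' Gaussian profile fit across a line, with FWHM
#'
#' Samples intensities along a line segment (linear interpolation), fits
#' `y = a + (b - a) exp(-(x - c)^2 / (2 d^2))` by least squares, and reports
#' the full width at half maximum `FWHM = 2 sqrt(2 ln 2) d` in physical units.
#'
#' @param image Numeric matrix.
#' @param from,to Endpoints `c(row, col)` in (possibly fractional) 0-based
#'   pixel coordinates.
#' @param pixel_size_nm Physical size of one pixel of `image` in nm.
#' @param n_samples Samples along the line (>= 5; default one per pixel of
#'   length).
#' @return A `gaussian_profile_fit` list: `a`, `b`, `c_nm`, `d_nm`,
#'   `fwhm_nm`, `profile` (data.frame x_nm, intensity, fitted).
#' @export
profile_fwhm <- function(image, from, to, pixel_size_nm = 1,
                         n_samples = NULL) {
  len_px <- sqrt(sum((to - from)^2))
  if (is.null(n_samples)) n_samples <- max(5L, ceiling(len_px) + 1L)
  if (n_samples < 5) stop("line must provide at least 5 samples")
  t <- seq(0, 1, length.out = n_samples)
  rows <- from[1] + t * (to[1] - from[1])
  cols <- from[2] + t * (to[2] - from[2])
  y <- bilinear_at(image, rows, cols)
  x <- t * len_px * pixel_size_nm
  if (stats::sd(y) == 0) stop("flat profile: Gaussian fit degenerate")
  a0 <- min(y); b0 <- max(y); c0 <- x[which.max(y)]
  d0 <- max(diff(range(x)) / 6, pixel_size_nm / 2)
  fit <- minpack.lm::nls.lm(
    par = c(a = a0, b = b0, cc = c0, d = d0),
    lower = c(-Inf, -Inf, min(x), 1e-6),
    fn = function(p) p[1] + (p[2] - p[1]) * exp(-(x - p[3])^2 / (2 * p[4]^2)) - y,
    control = minpack.lm::nls.lm.control(maxiter = 200))
  if (!(fit$info %in% 1:3))
    stop("Gaussian profile fit did not converge; residual SS = ",
         format(fit$deviance))
  p <- fit$par
  fitted <- p[1] + (p[2] - p[1]) * exp(-(x - p[3])^2 / (2 * p[4]^2))
  structure(list(a = unname(p[1]), b = unname(p[2]), c_nm = unname(p[3]),
                 d_nm = unname(abs(p[4])),
                 fwhm_nm = 2 * sqrt(2 * log(2)) * unname(abs(p[4])),
                 profile = data.frame(x_nm = x, intensity = y,
                                      fitted = fitted)),
            class = "gaussian_profile_fit")
}

bilinear_at <- function(image, rows, cols) {
  H <- nrow(image); W <- ncol(image)
  r0 <- pmin(pmax(floor(rows), 0), H - 1); c0 <- pmin(pmax(floor(cols), 0), W - 1)
  r1 <- pmin(r0 + 1, H - 1); c1 <- pmin(c0 + 1, W - 1)
  fr <- rows - r0; fc <- cols - c0
  fr <- pmin(pmax(fr, 0), 1); fc <- pmin(pmax(fc, 0), 1)
  idx <- function(r, c) image[cbind(r + 1, c + 1)]
  (1 - fr) * (1 - fc) * idx(r0, c0) + (1 - fr) * fc * idx(r0, c1) +
    fr * (1 - fc) * idx(r1, c0) + fr * fc * idx(r1, c1)
}

#' @export
print.gaussian_profile_fit <- function(x, ...) {
  cat(sprintf("<gaussian_profile_fit> FWHM = %.4g nm (d = %.4g nm, centre %.4g nm)\n",
              x$fwhm_nm, x$d_nm, x$c_nm))
  invisible(x)
}

#' Fourier ring correlation resolution
#'
#' Correlates two independent reconstructions of the same field in Fourier
#' rings: `FRC(q) = Re sum(F1 conj(F2)) / sqrt(sum|F1|^2 sum|F2|^2)` per
#' ring. The resolution is the inverse spatial frequency of the first
#' crossing below the fixed 1/7 threshold. If the curve never crosses from
#' above, the resolution is reported as `"below support"` (`NA` nm).
#'
#' @param image1,image2 Two matrices of identical size (e.g. reconstructions
#'   from odd and even frames; see [split_frames()]).
#' @param pixel_size_nm Pixel size of the images in nm.
#' @return An `frc_result`: `curve` (data.frame freq_per_nm, frc),
#'   `resolution_nm` (`NA` if below support), `threshold` (1/7).
#' @export
frc_resolution <- function(image1, image2, pixel_size_nm = 1) {
  stopifnot(identical(dim(image1), dim(image2)))
  H <- nrow(image1); W <- ncol(image1)
  F1 <- stats::fft(image1 - mean(image1))
  F2 <- stats::fft(image2 - mean(image2))
  fy <- c(seq_len(ceiling(H / 2)) - 1, -rev(seq_len(floor(H / 2)))) / H
  fx <- c(seq_len(ceiling(W / 2)) - 1, -rev(seq_len(floor(W / 2)))) / W
  fr <- sqrt(outer(fy^2, fx^2, "+"))
  nr <- floor(min(H, W) / 2)
  ring <- pmin(nr, 1L + as.integer(round(fr * min(H, W))))
  num <- Re(tapply(F1 * Conj(F2), ring, sum))
  d1 <- tapply(abs(F1)^2, ring, sum); d2 <- tapply(abs(F2)^2, ring, sum)
  frc <- as.numeric(num / sqrt(d1 * d2))
  freq <- (as.integer(names(num)) - 1L) / (min(H, W) * pixel_size_nm)
  keep <- freq > 0
  frc <- frc[keep]; freq <- freq[keep]
  thr <- 1 / 7
  below <- which(frc < thr)
  res <- NA_real_
  if (length(below) && below[1] > 1) {
    i <- below[1]
    # linear interpolation of the crossing
    f_cross <- freq[i - 1] + (thr - frc[i - 1]) * (freq[i] - freq[i - 1]) /
      (frc[i] - frc[i - 1])
    res <- 1 / f_cross
  } else if (!length(below)) {
    res <- 1 / max(freq)    # never drops below threshold: pixel-limited
  }
  structure(list(curve = data.frame(freq_per_nm = freq, frc = frc),
                 resolution_nm = res, threshold = thr,
                 below_support = length(below) > 0 && below[1] == 1),
            class = "frc_result")
}

#' @export
print.frc_result <- function(x, ...) {
  if (is.na(x$resolution_nm)) cat("<frc_result> below support\n")
  else cat(sprintf("<frc_result> resolution = %.4g nm (1/7 threshold)\n",
                   x$resolution_nm))
  invisible(x)
}

#' Split a stack into odd and even frames
#'
#' Two statistically independent half-stacks for [frc_resolution()].
#'
#' @param stack An [image_stack()].
#' @return List of two [image_stack()]s (`odd`, `even`).
#' @export
split_frames <- function(stack) {
  Tn <- dim(stack$data)[3]
  odd <- seq(1, Tn, by = 2); even <- seq(2, Tn, by = 2)
  list(odd = image_stack(stack$data[, , odd, drop = FALSE],
                         stack$frame_time * 2, stack$geometry),
       even = image_stack(stack$data[, , even, drop = FALSE],
                          stack$frame_time * 2, stack$geometry))
}
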