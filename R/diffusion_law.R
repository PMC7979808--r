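#' Straight-line fit of transit time versus observation area
#'
#' The FCS diffusion law: for free diffusion the average transit time grows
#' linearly with the observation area through the origin; domain trapping
#' bends the relation to a positive y-intercept, meshwork corralling to a
#' negative one. This helper fits the line given precomputed
#' `(A_eff, tau_d)` points and classifies the intercept.
#'
#' @param areas Effective areas in um^2 (one per binning, increasing).
#' @param taus Mean transit times in seconds.
#' @param sds Optional SDs of `taus`; used as 1/sd^2 weights when
#'   `weighted = TRUE`.
#' @param n_pixels Optional pixel counts per point (reported only).
#' @param binnings Optional binning factors (reported only).
#' @param weighted Weighted least squares? Default `FALSE` (unweighted).
#' @param z Classification threshold in multiples of the intercept SE.
#' @return A `diffusion_law_result`: list with `binnings`, `areas`, `taus`,
#'   `sds`, `n_pixels`, `slope`, `intercept`, `intercept_se`, `slope_se`,
#'   `classification`.
#' @export
diffusion_law_fit <- function(areas, taus, sds = NULL, n_pixels = NULL,
                              binnings = seq_along(areas), weighted = FALSE,
                              z = 2) {
  stopifnot(length(areas) == length(taus), length(areas) >= 3)
  if (is.unsorted(areas, strictly = TRUE))
    stop("areas must be strictly increasing")
  wts <- if (weighted && !is.null(sds)) 1 / sds^2 else NULL
  fit <- stats::lm(taus ~ areas, weights = wts)
  # exact synthetic inputs fit perfectly; the "perfect fit" warning is noise
  cf <- withCallingHandlers(
    summary(fit)$coefficients,
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  res <- structure(list(
    binnings = binnings, areas = areas, taus = taus, sds = sds,
    n_pixels = n_pixels,
    slope = unname(cf["areas", 1]), slope_se = unname(cf["areas", 2]),
    intercept = unname(cf["(Intercept)", 1]),
    intercept_se = unname(cf["(Intercept)", 2])),
    class = "diffusion_law_result")
  res$classification <- classify_intercept(res, z)
  res
}

#' FCS diffusion law of an image stack
#'
#' For every square binning, the stack is binned, each pixel's ACF fitted,
#' and the region-mean transit time `tau_d = A_eff / (4 D)` computed over
#' valid pixels (inside `region_mask` if given, taken at full resolution: a
#' binned pixel enters when the majority of its block is inside the mask).
#' The diffusion-law line is then fitted through the per-binning means.
#'
#' @param stack An [image_stack()].
#' @param geometry An [acquisition_geometry()] with calibrated PSF.
#' @param binnings Square binnings (default 1:5).
#' @param region_mask Optional full-resolution logical matrix.
#' @param scheme,bleach_order,lag_range Passed to [acf_map()].
#' @param weighted,z Passed to [diffusion_law_fit()].
#' @return A `diffusion_law_result` (see [diffusion_law_fit()]).
#' @export
diffusion_law <- function(stack, geometry = NULL, binnings = 1:5,
                          region_mask = NULL, scheme = correlator_scheme(),
                          bleach_order = 8L, lag_range = NULL,
                          weighted = FALSE, z = 2) {
  if (is.null(geometry)) geometry <- stack$geometry
  if (is.null(geometry)) stop("no acquisition geometry available")
  areas <- taus <- sds <- numeric(0); npix <- integer(0); used <- integer(0)
  for (b in binnings) {
    am <- acf_map(stack, scheme, binning = b, bleach_order = bleach_order,
                  lag_range = lag_range)
    fr <- fit_acf_map(am, geometry)
    sel <- fr$valid
    if (!is.null(region_mask)) {
      frac <- bin_spatial(image_stack(region_mask * 1, 1), b, "mean")$data[, , 1]
      sel <- sel & frac > 0.5
    }
    dv <- fr$D$values[sel]
    if (length(dv) < 1) next
    A <- effective_area(geometry, b)
    td <- A / (4 * dv)                     # per-pixel transit times
    areas <- c(areas, A); taus <- c(taus, mean(td))
    sds <- c(sds, stats::sd(td)); npix <- c(npix, length(dv))
    used <- c(used, b)
  }
  if (length(areas) < 3)
    stop("fewer than 3 binnings with valid pixels: insufficient data")
  diffusion_law_fit(areas, taus, sds, npix, used, weighted = weighted, z = z)
}

#' Classify a diffusion-law intercept
#'
#' `free` when the intercept is within `z` standard errors of zero; otherwise
#' `confined/domain` for a positive and `meshwork` for a negative intercept.
#'
#' @param result A `diffusion_law_result`.
#' @param z Threshold in multiples of the intercept SE. Default 2.
#' @return One of `"free"`, `"confined/domain"`, `"meshwork"`.
#' @export
classify_intercept <- function(result, z = 2) {
  t0 <- result$intercept; se <- result$intercept_se
  # the 1e-12 s floor keeps numerically exact fits (se = 0) classified free
  if (!is.finite(se) || abs(t0) <= z * se + 1e-12) "free"
  else if (t0 > 0) "confined/domain"
  else "meshwork"
}

#' @export
print.diffusion_law_result <- function(x, ...) {
  cat(sprintf(
    "<diffusion_law> intercept = %.4g +/- %.4g s (%s), slope = %.4g s/um^2\n",
    x$intercept, x$intercept_se, x$classification, x$slope))
  invisible(x)
}
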