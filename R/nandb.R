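#' Dark-frame detector calibration
#'
#' Offset and read-noise variance for number-and-brightness analysis, either
#' from a dark stack (camera shutter closed, same detector settings) or as a
#' stated global pair.
#'
#' @param dark Either an [image_stack()] of dark frames or `NULL`.
#' @param offset,sigma0_sq Global values used when no dark stack is given.
#' @param per_pixel If `TRUE` (and a dark stack is given), keep per-pixel
#'   offset/variance maps; otherwise global means are used.
#' @return A `dark_calibration` list with `offset` and `sigma0_sq` (scalars or
#'   matrices).
#' @export
dark_calibration <- function(dark = NULL, offset = 0, sigma0_sq = 0,
                             per_pixel = TRUE) {
  if (!is.null(dark)) {
    if (!inherits(dark, "image_stack")) stop("dark must be an image_stack")
    mu <- apply(dark$data, c(1, 2), mean)
    v <- apply(dark$data, c(1, 2), stats::var)
    if (!per_pixel) { mu <- mean(mu); v <- mean(v) }
    offset <- mu; sigma0_sq <- v
  }
  if (any(sigma0_sq < 0)) stop("sigma0_sq must be >= 0")
  structure(list(offset = offset, sigma0_sq = sigma0_sq),
            class = "dark_calibration")
}

#' Number and brightness maps
#'
#' Moment analysis of per-pixel intensity fluctuations:
#' `N = (<I> - offset)^2 / (sigma^2 - sigma0^2)` and
#' `B = (sigma^2 - sigma0^2) / (<I> - offset)`. In `"variance"` mode
#' `sigma^2` is the trace variance (shot noise contributes to B); in `"G1"`
#' mode the lag-1 covariance `<dF(t) dF(t+dt)>` replaces
#' `sigma^2 - sigma0^2`, which rejects shot and read noise because both are
#' uncorrelated between frames (the `sigma0^2` term is therefore omitted).
#' G1 mode requires molecules to remain correlated across one frame: the
#' transit time must be much longer than the (binned) frame time. A warning
#' is issued if a supplied `fitted_D` implies otherwise.
#'
#' Frames should represent 10-20 ms exposures; use `temporal_bin` to sum-bin
#' faster acquisitions (e.g. 10 x 2 ms frames per 20 ms sample).
#'
#' @param stack An [image_stack()].
#' @param dark A [dark_calibration()].
#' @param mode `"G1"` (default, as used for EMCCD data) or `"variance"`.
#' @param bleach_order Polynomial bleach-correction order (0 disables).
#' @param intensity_filter `"otsu"` (threshold the mean image by Otsu's
#'   method, keep the bright class), a numeric `c(lo, hi)` range on the mean
#'   intensity, or `NULL` to keep everything.
#' @param temporal_bin Sum-bin this many frames before analysis. Default 1.
#' @param fitted_D Optional D estimate (um^2/s) used only to warn when the
#'   G1 validity condition is violated.
#' @return An `nb_result`: list of [parameter_map()]s `N`, `B`,
#'   `mean_intensity`, plus `mode` and the filter range used.
#' @export
nb_maps <- function(stack, dark = dark_calibration(), mode = c("G1", "variance"),
                    bleach_order = 8L, intensity_filter = NULL,
                    temporal_bin = 1L, fitted_D = NULL) {
  mode <- match.arg(mode)
  if (temporal_bin > 1L) stack <- bin_temporal(stack, temporal_bin, "sum")
  d <- dim(stack$data)
  H <- d[1]; W <- d[2]; Tn <- d[3]
  if (!is.null(fitted_D) && !is.null(stack$geometry)) {
    td <- effective_area(stack$geometry) / (4 * fitted_D)
    if (td < 5 * stack$frame_time)
      warning(sprintf(paste0(
        "G1 validity: transit time (%.3g s) is not much longer than the ",
        "frame time (%.3g s)"), td, stack$frame_time))
  }
  off <- dark$offset; s0 <- dark$sigma0_sq
  if (is.matrix(off) && !identical(dim(off), c(H, W)))
    stop("dark calibration shape does not match the stack")
  traces <- t(matrix(stack$data, H * W, Tn))
  bc <- bleach_correct_matrix(traces, bleach_order)
  traces <- bc$traces
  mu <- colMeans(traces)
  dx <- sweep(traces, 2, mu)
  num <- if (mode == "variance")
    colSums(dx^2) / (Tn - 1) - as.vector(if (is.matrix(s0)) s0 else matrix(s0, H, W))
  else
    colSums(dx[-Tn, , drop = FALSE] * dx[-1, , drop = FALSE]) / (Tn - 2)
  offv <- as.vector(if (is.matrix(off)) off else matrix(off, H, W))
  signal <- mu - offv
  valid <- bc$ok & signal > 0
  mum <- matrix(mu, H, W)
  if (identical(intensity_filter, "otsu")) {
    thr <- EBImage::otsu(mum, range = range(mum), levels = 4096L)
    intensity_filter <- c(thr, Inf)
  }
  if (!is.null(intensity_filter))
    valid <- valid & mu >= intensity_filter[1] & mu <= intensity_filter[2]
  B <- num / signal
  N <- signal^2 / num
  N[!valid | num <= 0] <- NA_real_
  vm <- matrix(valid, H, W)
  binning <- if (!is.null(stack$geometry)) stack$geometry$binning else 1L
  structure(list(
    N = parameter_map(matrix(N, H, W), vm & matrix(num > 0, H, W), "N",
                      "particles", binning),
    B = parameter_map(matrix(B, H, W), vm, "B", "counts/molecule/frame",
                      binning),
    mean_intensity = parameter_map(mum, matrix(TRUE, H, W), "mean intensity",
                                   "counts/frame", binning),
    mode = mode, intensity_filter = intensity_filter),
    class = "nb_result")
}

#' @export
print.nb_result <- function(x, ...) {
  cat(sprintf("<nb_result> mode %s\n  ", x$mode)); print(x$B)
  invisible(x)
}

#' Fluorescent fraction from a tandem-dimer brightness ratio
#'
#' Under the binomial maturation model each subunit of a tandem dimer is
#' fluorescent independently with probability `p`, so the dimer/monomer
#' apparent-brightness ratio is `<q^2>/<q>` with `q ~ Binomial(2, p)`, i.e.
#' `1 + p`. A measured ratio r therefore gives `p = r - 1`.
#'
#' @param r_dimer_monomer Brightness ratio (tandem dimer over monomer), in
#'   `[1, 2]`.
#' @return Fluorescent probability p in `[0, 1]`.
#' @export
#' @examples
#' fluorescent_fraction(1.55)   # 0.55
fluorescent_fraction <- function(r_dimer_monomer) {
  if (r_dimer_monomer < 1 || r_dimer_monomer > 2)
    stop("ratio outside [1, 2]: violates the tandem-dimer binomial model")
  r_dimer_monomer - 1
}

#' Fraction of molecules in dimers
#'
#' For a monomer-dimer mixture with measured brightness ratio `r` (sample
#' over pure monomer) and fluorescent probability `p`, the fraction of
#' molecules (subunits) residing in dimers is `m_e = (r - 1)/p`. The
#' first-order propagated standard error from `se_r` and `se_p` is returned
#' alongside.
#'
#' @param r Brightness ratio (>= 1).
#' @param p Fluorescent probability in (0, 1].
#' @param se_r,se_p Standard errors of `r` and `p` (default 0).
#' @return List with `m_e` and `se`.
#' @export
#' @examples
#' dimer_fraction(1.35, 0.55)$m_e   # 0.636 -> 63%
dimer_fraction <- function(r, p, se_r = 0, se_p = 0) {
  stopifnot(p > 0, p <= 1, r >= 1)
  m <- (r - 1) / p
  if (m > 1)
    stop("(r-1)/p > 1: signal infeasible as pure monomer-dimer; use mixture_solve")
  se <- sqrt((se_r / p)^2 + ((r - 1) * se_p / p^2)^2)
  list(m_e = m, se = se)
}

#' Apparent brightness ratio of a pure k-mer to a monomer
#'
#' `<q^2>/<q>` for `q ~ Binomial(k, p)`, relative to the monomer value:
#' `1 + (k - 1) p`.
#'
#' @param k Oligomer order (>= 1).
#' @param p Fluorescent probability.
#' @return Brightness ratio.
#' @export
oligomer_brightness_ratio <- function(k, p) {
  stopifnot(k >= 1, p >= 0, p <= 1)
  1 + (k - 1) * p
}

#' Solve a two-species oligomer mixture from a brightness ratio
#'
#' For number fractions `f1 + f2 = 1` of `k1`-mers and `k2`-mers with
#' binomially fluorescent subunits, the apparent brightness ratio to pure
#' monomer is
#' `r = sum(f_i (k_i p (1-p) + k_i^2 p^2)) / sum(f_i k_i p)`.
#' Given `r`, `p` and the two orders, this solves for the number fractions.
#'
#' @param r Measured brightness ratio.
#' @param p Fluorescent probability in (0, 1].
#' @param orders Integer pair `c(k1, k2)` with `k1 < k2`.
#' @return List with `fractions` (named f1, f2), `orders`, and the attainable
#'   ratio `bounds`. Errors when `r` lies outside the pure-species bounds.
#' @export
#' @examples
#' mixture_solve(1.6, 0.55, c(1, 3))$fractions   # 0.71 / 0.29
#' mixture_solve(1.6, 0.55, c(2, 3))$fractions   # 0.94 / 0.06
mixture_solve <- function(r, p, orders) {
  stopifnot(length(orders) == 2, orders[1] < orders[2], p > 0, p <= 1)
  k1 <- orders[1]; k2 <- orders[2]
  num <- function(k) k * p * (1 - p) + k^2 * p^2
  den <- function(k) k * p
  r1 <- num(k1) / den(k1); r2 <- num(k2) / den(k2)
  if (r < min(r1, r2) - 1e-12 || r > max(r1, r2) + 1e-12)
    stop(sprintf("r = %g not attainable between pure %d-mer (%.4g) and pure %d-mer (%.4g)",
                 r, k1, r1, k2, r2))
  # r (f1 d1 + f2 d2) = f1 n1 + f2 n2 with f1 = 1 - f2
  f2 <- (r * den(k1) - num(k1)) /
    ((num(k2) - num(k1)) - r * (den(k2) - den(k1)))
  f2 <- min(1, max(0, f2))
  list(fractions = stats::setNames(c(1 - f2, f2),
                                   paste0("f", c(k1, k2))),
       orders = orders, bounds = c(r1, r2))
}
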