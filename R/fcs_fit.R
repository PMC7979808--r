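#' Spatial amplitude factor of the camera FCS model
#'
#' The correlation decay of free 2-D diffusion observed through a square
#' pixel of side `a_eff_nm` convolved with a Gaussian PSF of 1/e^2 radius
#' `omega_nm`:
#'
#' `g(tau) = ( sqrt(4 D tau + w^2) / (a sqrt(pi)) * (exp(-a^2/(4 D tau + w^2)) - 1)
#'            + erf(a / sqrt(4 D tau + w^2)) )^2`
#'
#' `g` is monotone decreasing in `tau`; `g(0)` lies in (0, 1) and tends to 1
#' when the pixel dwarfs the PSF. The full ACF model is
#' `G(tau) = (1/N) g(tau)/g(0) + G_inf`.
#'
#' @param tau Lag time(s) in seconds (>= 0).
#' @param D Diffusion coefficient in um^2/s.
#' @param a_eff_nm Binned pixel side in the object plane, nm.
#' @param omega_nm PSF 1/e^2 radius, nm.
#' @return g values (same length as `tau`).
#' @export
#' @examples
#' model_g(0, D = 2, a_eff_nm = 240, omega_nm = 364)   # 0.1204
model_g <- function(tau, D, a_eff_nm, omega_nm) {
  stopifnot(all(tau >= 0), D >= 0, a_eff_nm > 0, omega_nm >= 0)
  w2 <- 4 * D * tau * 1e6 + omega_nm^2     # nm^2
  s <- sqrt(w2)
  erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1
  (s / (a_eff_nm * sqrt(pi)) * (exp(-a_eff_nm^2 / w2) - 1) +
      erf(a_eff_nm / s))^2
}

# Full ACF model; two-component when F2 > 0 (shared geometry, normalised so
# G(0) - Ginf = 1/N).
model_acf <- function(tau, N, D, Ginf, a_eff_nm, omega_nm,
                      D2 = NA_real_, F2 = 0) {
  gn <- model_g(tau, D, a_eff_nm, omega_nm) / model_g(0, D, a_eff_nm, omega_nm)
  if (F2 > 0) {
    gn2 <- model_g(tau, D2, a_eff_nm, omega_nm) /
      model_g(0, D2, a_eff_nm, omega_nm)
    gn <- (1 - F2) * gn + F2 * gn2
  }
  gn / N + Ginf
}

#' Effective observation area
#'
#' The observation area of a (binned) camera pixel is the pixel area enlarged
#' by the PSF: `A_eff = (binning * a)^2 / g(0)` with `g` from [model_g()].
#' Always larger than the bare pixel area; for `omega -> 0` it reduces to it.
#'
#' @param geometry An [acquisition_geometry()] with calibrated PSF.
#' @param binning Additional spatial binning factor (>= 1).
#' @return Effective area in um^2.
#' @export
#' @examples
#' g <- acquisition_geometry(24, 100, 364)
#' effective_area(g, 1)   # 0.48 um^2
#' effective_area(g, 5)   # 2.10 um^2
effective_area <- function(geometry, binning = 1L) {
  a <- geometry$object_pixel_size_nm * binning
  g0 <- model_g(0, 1, a, geometry$psf_e2_radius_nm)
  (a / 1000)^2 / g0
}

#' Average transit time through an observation area
#'
#' `tau_d = A_eff / (4 D)` for free 2-D diffusion, the convention under which
#' a 0.48 um^2 area and D = 2 um^2/s give 60 ms.
#'
#' @param area_um2 Observation area in um^2.
#' @param D Diffusion coefficient in um^2/s.
#' @return Transit time in seconds.
#' @export
transit_time <- function(area_um2, D) {
  stopifnot(area_um2 > 0, D > 0)
  area_um2 / (4 * D)
}

#' Fit the camera FCS diffusion model to one ACF
#'
#' Weighted (1/sd) Levenberg-Marquardt least squares of
#' `G(tau) = (1/N) g(tau)/g(0) + G_inf`, one- or two-component. The first lag
#' channel is excluded (shot-noise dominated). Initial values come from the
#' amplitude (`N ~ 1/(G(tau1) - Ginf)`) and the half-decay lag unless `init`
#' is supplied; on non-convergence two further starts at 0.1x and 10x the
#' initial D are tried. A fit is valid only if it converged with
#' `0.01 < D < 10` um^2/s and a positive amplitude.
#'
#' @param acf A [pixel_acf()] with >= 8 usable lags.
#' @param geometry An [acquisition_geometry()].
#' @param binning Spatial binning of the pixel relative to
#'   `geometry$object_pixel_size_nm`.
#' @param mode `"one_component"` or `"two_component"`.
#' @param init Optional named list with elements `N`, `D`, `Ginf` (and `D2`,
#'   `F2` in two-component mode).
#' @param d_window Acceptance window for D in um^2/s.
#' @return A list: `params` (N, D, Ginf, and D2, F2 if requested), `chi2`
#'   (reduced), `valid`, `reason`, `fitted` (model values on the lag grid).
#' @export
fit_acf <- function(acf, geometry, binning = 1L,
                    mode = c("one_component", "two_component"), init = NULL,
                    d_window = c(0.01, 10)) {
  mode <- match.arg(mode)
  a_eff <- geometry$object_pixel_size_nm * binning
  omega <- geometry$psf_e2_radius_nm
  use <- which(is.finite(acf$G))[-1]           # drop lag-0-adjacent channel
  if (length(which(is.finite(acf$G))) < 8L)
    return(invalid_fit("fewer than 8 usable lags", mode))
  tau <- acf$lags[use]; G <- acf$G[use]
  w <- acf$sd[use]
  w <- if (all(is.finite(w)) && all(w > 0)) 1 / w else rep(1, length(G))
  two <- mode == "two_component"
  lower <- c(N = 1e-3, D = 1e-3, Ginf = -0.5)
  upper <- c(N = 1e6, D = 1e2, Ginf = 0.5)
  if (two) {
    lower <- c(lower, D2 = 1e-4, F2 = 0)
    upper <- c(upper, D2 = 1e2, F2 = 1)
  }
  # initialisation from amplitude and half-decay
  Ginf0 <- mean(G[tau >= stats::quantile(tau, 0.8)])
  amp0 <- max(G[1] - Ginf0, 1e-4)
  half <- tau[which(G - Ginf0 <= amp0 / 2)[1]]
  if (is.na(half)) half <- tau[length(tau) %/% 2]
  A_eff <- effective_area(geometry, binning)
  D0 <- min(max(A_eff / (4 * half), 1e-2), 50)
  start0 <- list(N = 1 / amp0, D = D0, Ginf = max(min(Ginf0, 0.4), -0.4))
  if (two) start0 <- c(start0, list(D2 = D0 / 10, F2 = 0.3))
  if (!is.null(init)) start0[names(init)] <- init
  resid_fn <- function(par) {
    m <- model_acf(tau, par[["N"]], par[["D"]], par[["Ginf"]], a_eff, omega,
                   D2 = if (two) par[["D2"]] else NA_real_,
                   F2 = if (two) par[["F2"]] else 0)
    (m - G) * w
  }
  best <- NULL
  for (fac in c(1, 0.1, 10)) {
    st <- start0; st$D <- min(max(st$D * fac, lower[["D"]]), upper[["D"]])
    fit <- tryCatch(
      minpack.lm::nls.lm(unlist(st), lower = lower, upper = upper,
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    conv <- fit$info %in% 1:3
    if (is.null(best) || (conv && fit$deviance < best$deviance)) best <- fit
    if (conv && fac == 1) break
  }
  if (is.null(best) || !(best$info %in% 1:3))
    return(invalid_fit("non-convergence", mode))
  par <- as.list(best$par)
  if (two && par$F2 > 0 && !is.na(par$D2) && par$D2 > par$D) {
    # enforce slow-component-second labelling
    tmp <- par$D; par$D <- par$D2; par$D2 <- tmp; par$F2 <- 1 - par$F2
  }
  chi2 <- best$deviance / max(1, length(G) - length(par))
  fitted <- model_acf(acf$lags, par$N, par$D, par$Ginf, a_eff, omega,
                      D2 = if (two) par$D2 else NA_real_,
                      F2 = if (two) par$F2 else 0)
  valid <- par$D > d_window[1] && par$D < d_window[2] && par$N > 0
  reason <- if (valid) "" else "D outside acceptance window"
  list(params = par, chi2 = chi2, valid = valid, reason = reason,
       fitted = fitted)
}

invalid_fit <- function(reason, mode) {
  par <- list(N = NA_real_, D = NA_real_, Ginf = NA_real_)
  if (mode == "two_component") par <- c(par, list(D2 = NA_real_, F2 = NA_real_))
  list(params = par, chi2 = NA_real_, valid = FALSE, reason = reason,
       fitted = NULL)
}

#' Fit every pixel of an ACF map
#'
#' One-component fits per pixel; optionally a two-component refit is
#' attempted wherever the one-component reduced chi-squared exceeds
#' `chi2_refit` (the heterogeneous off-fibre case).
#'
#' @param map An [acf_map()].
#' @param geometry An [acquisition_geometry()]; defaults to the stack's.
#' @param chi2_refit Threshold for the two-component refit (`Inf` disables;
#'   default 2).
#' @param d_window Acceptance window for D.
#' @return A `fit_result_map`: list of [parameter_map()]s `D`, `N`, `Ginf`,
#'   `chi2`, plus the overall `valid` matrix and the binned geometry.
#' @export
fit_acf_map <- function(map, geometry = NULL, chi2_refit = Inf,
                        d_window = c(0.01, 10)) {
  if (is.null(geometry)) geometry <- map$geometry
  if (is.null(geometry)) stop("no acquisition geometry available")
  d <- dim(map$G)
  H <- d[2]; W <- d[3]
  Dm <- Nm <- Gm <- Cm <- matrix(NA_real_, H, W)
  valid <- matrix(FALSE, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    if (!map$valid[i, j]) next
    f <- fit_acf(acf_at(map, i, j), geometry, binning = map$binning,
                 d_window = d_window)
    if (is.finite(chi2_refit) && isTRUE(f$chi2 > chi2_refit)) {
      f2 <- fit_acf(acf_at(map, i, j), geometry, binning = map$binning,
                    mode = "two_component", d_window = d_window)
      if (isTRUE(f2$valid) && isTRUE(f2$chi2 < f$chi2)) f <- f2
    }
    Dm[i, j] <- f$params$D; Nm[i, j] <- f$params$N
    Gm[i, j] <- f$params$Ginf; Cm[i, j] <- f$chi2
    valid[i, j] <- f$valid
  }
  structure(list(
    D = parameter_map(Dm, valid, "D", "um^2/s", map$binning),
    N = parameter_map(Nm, valid, "N", "particles", map$binning),
    Ginf = parameter_map(Gm, valid, "Ginf", "", map$binning),
    chi2 = parameter_map(Cm, valid, "chi2", "", map$binning),
    valid = valid, binning = map$binning, geometry = geometry),
    class = "fit_result_map")
}

#' @export
print.fit_result_map <- function(x, ...) {
  cat("<fit_result_map>\n  ")
  print(x$D)
  invisible(x)
}

#' Calibrate the PSF by binning invariance of D
#'
#' For a freely diffusing calibration sample the fitted D must not depend on
#' spatial binning — but the fitted value does depend on the PSF radius
#' assumed in the model. The calibration scans `omega_grid`, fits the mean D
#' at every binning for each candidate, and returns the radius minimising the
#' coefficient of variation of D across binnings.
#'
#' @param stack Calibration [image_stack()] (free diffusion).
#' @param geometry [acquisition_geometry()] (its PSF field is ignored).
#' @param binnings Integer binnings (>= 3 values).
#' @param omega_grid Candidate 1/e^2 radii in nm (>= 5 values).
#' @param scheme,bleach_order,lag_range Passed to [acf_map()].
#' @return List: `omega_star` (nm), `table` (data.frame omega, binning,
#'   mean D, n), `cv` (named by omega). Errors if the CV minimum sits on the
#'   grid boundary (calibration inconclusive).
#' @export
calibrate_psf <- function(stack, geometry, binnings = 1:5,
                          omega_grid = seq(264, 464, by = 25),
                          scheme = correlator_scheme(), bleach_order = 8L,
                          lag_range = NULL) {
  if (length(binnings) < 3L) stop("need at least 3 binnings")
  if (length(omega_grid) < 5L) stop("need at least 5 PSF candidates")
  maps <- lapply(binnings, function(b)
    acf_map(stack, scheme, binning = b, bleach_order = bleach_order,
            lag_range = lag_range))
  rows <- list()
  for (om in omega_grid) {
    gom <- acquisition_geometry(geometry$camera_pixel_size_um,
                                geometry$magnification, om,
                                geometry$emission_wavelength_nm,
                                geometry$numerical_aperture)
    for (bi in seq_along(binnings)) {
      fr <- fit_acf_map(maps[[bi]], gom)
      dv <- fr$D$values[fr$D$validity]
      rows[[length(rows) + 1L]] <- data.frame(
        omega = om, binning = binnings[bi],
        D = if (length(dv)) mean(dv) else NA_real_, n = length(dv))
    }
  }
  tab <- do.call(rbind, rows)
  cv <- vapply(omega_grid, function(om) {
    d <- tab$D[tab$omega == om]
    stats::sd(d) / mean(d)
  }, 0)
  names(cv) <- omega_grid
  imin <- which.min(cv)
  if (imin == 1L || imin == length(omega_grid))
    stop("no interior CV minimum on the PSF grid: calibration inconclusive")
  list(omega_star = omega_grid[imin], table = tab, cv = cv)
}
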