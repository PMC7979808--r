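# Synthetic frame helpers: Gaussian spots on a quiet background.
gauss_frame <- function(H, W, centres, sigma = 1, amp = 1000, bg = 10) {
  f <- matrix(bg, H, W)
  for (c0 in centres) {
    dx2 <- outer((seq_len(H) - 1 - c0[1])^2, (seq_len(W) - 1 - c0[2])^2, "+")
    f <- f + amp * exp(-dx2 / (2 * sigma^2))
  }
  f
}

test_that("radiality peaks within one sub-pixel of a symmetric spot centre", {
  p <- srrf_params()
  for (centre in list(c(9, 9), c(8.6, 10.3))) {
    f <- gauss_frame(19, 19, list(centre))
    r <- radiality_frame(f, p)
    peak <- which(r$image == max(r$image), arr.ind = TRUE)[1, ]
    # sub-pixel grid coordinate of the true centre
    truth <- (centre + 0.5) * p$magnification + 0.5
    expect_lt(max(abs(peak - truth)), 1 + 1e-9)
  }
})

test_that("a uniform intensity ramp has (near-)zero radiality", {
  f <- outer(seq_len(15), seq_len(15), function(i, j) 5 * i + 3 * j)
  r <- radiality_frame(f, srrf_params(intensity_weighting = FALSE))
  expect_lt(max(r$image), 0.05)     # parallel gradients never converge
  z <- radiality_frame(matrix(0, 10, 10), srrf_params())
  expect_true(all(z$image == 0))
})

test_that("two spots 0.8 px apart are resolved in radiality but not intensity", {
  c1 <- c(9, 8.6); c2 <- c(9, 9.4)
  f <- gauss_frame(19, 19, list(c1, c2), sigma = 0.6)
  p <- srrf_params(intensity_weighting = FALSE)
  r <- radiality_frame(f, p)$image
  # the raw image has a single maximum along the joining row profile
  row_raw <- f[10, ]
  expect_equal(sum(diff(sign(diff(row_raw))) == -2), 1)
  # the radiality profile along the magnified row shows two local maxima
  row_rad <- r[round((9 + 0.5) * 5 + 0.5), 30:70]
  n_peaks <- sum(diff(sign(diff(row_rad))) == -2)
  expect_gte(n_peaks, 2)
})

test_that("radiality is rotation-equivariant within interpolation error", {
  f <- gauss_frame(21, 21, list(c(7, 12)), sigma = 1.2)
  p <- srrf_params(intensity_weighting = FALSE)
  r1 <- radiality_frame(f, p)$image
  # rotate frame by 90 deg (counter-clockwise), rotate result back
  rot90 <- function(m) t(m)[ncol(m):1, ]
  r2 <- radiality_frame(rot90(f), p)$image
  unrot <- t(r2[nrow(r2):1, ])
  expect_lt(max(abs(r1 - unrot)), 0.05 * max(r1))
})

test_that("TRAC2 of a static noiseless structure is zero; mean mode returns it", {
  f <- gauss_frame(16, 16, list(c(7, 7)))
  arr <- array(rep(f, 6), c(16, 16, 6))
  s <- image_stack(arr, 0.2)
  p <- srrf_params(temporal_bin = 1)
  tr <- srrf(s, p)
  expect_equal(max(tr$image), 0, tolerance = 1e-20)
  mn <- srrf(s, srrf_params(temporal_bin = 1, temporal_mode = "mean"),
             normalize = FALSE)
  expect_equal(mn$image, radiality_frame(f, p)$image, tolerance = 1e-12)
  expect_error(srrf(image_stack(f, 0.2), p), "at least 2")
})

test_that("TRAC2 output is invariant to global intensity rescaling", {
  set.seed(80)
  arr <- array(rpois(14 * 14 * 20, 60), c(14, 14, 20))
  s1 <- image_stack(arr, 0.2)
  s2 <- image_stack(arr * 11, 0.2)
  p <- srrf_params(temporal_bin = 1)
  expect_equal(srrf(s1, p)$image, srrf(s2, p)$image, tolerance = 1e-9)
})

test_that("SOFI order 2 equals the N&B variance map and order 4 vanishes for Gaussian noise", {
  set.seed(81)
  arr <- array(rnorm(12 * 12 * 6000, 500, 20), c(12, 12, 6000))
  arr[arr < 0] <- 0
  s <- image_stack(arr, 0.02)
  k2 <- sofi(s, 2, bleach_order = 0)
  # shared oracle: per-pixel variance (to the 1/T vs 1/(T-1) convention)
  v <- apply(s$data, c(1, 2), function(x) mean((x - mean(x))^2))
  expect_equal(k2$image, v, tolerance = 1e-12)
  k4 <- sofi(s, 4, bleach_order = 0)
  # Gaussian cumulants above order 2 vanish; k4/k2^2 is standardised excess
  expect_lt(max(k4$image / k2$image^2), 0.3)
  expect_error(sofi(s, 3), "order")
})

test_that("SOFI order 2 of a two-state blinking emitter matches p(1-p) A^2", {
  set.seed(82)
  p_on <- 0.3; A <- 50
  Tn <- 20000
  on <- rbinom(Tn, 1, p_on)
  arr <- array(0, c(5, 5, Tn))
  arr[3, 3, ] <- A * on
  k2 <- sofi(image_stack(arr, 0.02), 2, bleach_order = 0)
  expect_equal(k2$image[3, 3], p_on * (1 - p_on) * A^2,
               tolerance = 0.05 * p_on * (1 - p_on) * A^2)
  expect_equal(max(k2$image[-3, ]), 0)
})

test_that("blinking fibres show higher TRAC2 contrast than mean radiality", {
  cfg <- sim_config(width = 24, height = 24, frames = 3000, seed = 83,
                    offset = 100, read_noise_sd = 2,
                    species = list(sim_species(D = 3, density = 2, epsilon = 600,
                                               binds_fibres = TRUE)),
                    fibres = list(sim_fibre(1.2, 2.9, 4.6, 2.9, k_on = 1000,
                                            k_off = 20)))
  sim <- simulate_stack(cfg)
  p <- srrf_params(temporal_bin = 100)
  tr <- srrf(sim$stack, p)
  mn <- srrf(sim$stack, srrf_params(temporal_bin = 100,
                                    temporal_mode = "mean"))
  fm <- upsample_mask(sim$truth$fibre_mask, 5)
  inner <- upsample_mask(imfluct:::zero_border(matrix(TRUE, 24, 24), 3) > 0, 5)
  contrast <- function(img) mean(img[fm & inner]) / mean(img[!fm & inner])
  expect_gt(contrast(tr$image), contrast(mn$image))
  expect_gt(contrast(tr$image), 2)
})

test_that("SRRF narrows a simulated fibre profile at least two-fold", {
  cfg <- sim_config(width = 24, height = 24, frames = 4000, seed = 84,
                    offset = 100, read_noise_sd = 2,
                    species = list(sim_species(D = 3, density = 2.5,
                                               epsilon = 600,
                                               binds_fibres = TRUE)),
                    fibres = list(sim_fibre(1.2, 2.88, 4.6, 2.88, k_on = 2000,
                                            k_off = 20,
                                            capture_radius_um = 0.05)))
  sim <- simulate_stack(cfg)
  g <- sim$stack$geometry
  mean_img <- apply(sim$stack$data, c(1, 2), mean)
  # profile across the fibre (fibre runs along a row at y = 2.88 um -> row 12)
  tirf_fit <- profile_fwhm(mean_img, from = c(5, 11.5), to = c(18, 11.5),
                           pixel_size_nm = g$object_pixel_size_nm)
  sr <- srrf(sim$stack, srrf_params(temporal_bin = 100))
  prof_col <- (11.5 + 0.5) * 5 + 0.5
  srrf_fit <- profile_fwhm(sr$image, from = c(35, prof_col - 1),
                           to = c(85, prof_col - 1),
                           pixel_size_nm = g$object_pixel_size_nm / 5)
  expect_lt(srrf_fit$fwhm_nm, tirf_fit$fwhm_nm / 2)
  # TIRF width is of the order of the diffraction-limited PSF
  expect_gt(tirf_fit$fwhm_nm, 300)
})

test_that("SOFI order 4 profiles are narrower than order 2 on a blinking ridge", {
  set.seed(85)
  Tn <- 3000; H <- 15; W <- 21
  arr <- array(rpois(H * W * Tn, 20), c(H, W, Tn))
  ridge <- exp(-((seq_len(H)) - 8)^2 / (2 * 1.6^2))
  for (t in seq_len(Tn)) {
    on <- rbinom(W, 1, 0.4)
    arr[, , t] <- arr[, , t] + 400 * ridge %o% on
  }
  s <- image_stack(arr, 0.02)
  f2 <- profile_fwhm(sofi(s, 2, bleach_order = 0)$image,
                     from = c(1, 10), to = c(14, 10), pixel_size_nm = 100)
  f4 <- profile_fwhm(sofi(s, 4, bleach_order = 0)$image,
                     from = c(1, 10), to = c(14, 10), pixel_size_nm = 100)
  expect_lt(f4$fwhm_nm, f2$fwhm_nm)
})
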