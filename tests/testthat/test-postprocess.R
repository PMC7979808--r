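test_that("intensity masks threshold correctly, including Otsu on bimodal images", {
  img <- matrix(10, 12, 12); img[4:9, 4:9] <- 200
  m <- tirf_mask(img, threshold = 50)
  expect_equal(sum(m), 36)
  expect_true(all(tirf_mask(img, threshold = min(img))))
  expect_warning(tirf_mask(img, threshold = 1e6), "empty")
  set.seed(90)
  noisy <- img + matrix(rnorm(144, 0, 5), 12)
  mo <- tirf_mask(noisy, "otsu")
  thr <- attr(mo, "threshold")
  expect_gt(thr, 30); expect_lt(thr, 180)     # between the modes
  expect_equal(as.vector(mo), as.vector(img == 200))
})

test_that("the D histogram threshold finds the valley between two pools", {
  set.seed(91)
  vals <- c(10^rnorm(300, log10(0.05), 0.12), 10^rnorm(300, log10(0.8), 0.12))
  dm <- parameter_map(matrix(vals, 30, 20), name = "D")
  thr <- d_histogram_threshold(dm)
  expect_false(attr(thr, "fallback_used"))
  expect_gt(as.numeric(thr), 0.05)
  expect_lt(as.numeric(thr), 0.8)
  # two delta-like modes: threshold strictly between them
  vals2 <- c(rep(0.05, 200) * exp(rnorm(200, 0, 0.01)),
             rep(0.8, 200) * exp(rnorm(200, 0, 0.01)))
  thr2 <- d_histogram_threshold(parameter_map(matrix(vals2, 20, 20)))
  expect_gt(as.numeric(thr2), 0.06); expect_lt(as.numeric(thr2), 0.7)
  # unimodal map falls back to the configured default with a warning
  uni <- parameter_map(matrix(10^rnorm(400, 0, 0.1), 20, 20))
  expect_warning(thr3 <- d_histogram_threshold(uni), "unimodal")
  expect_equal(as.numeric(thr3), 0.2)
  expect_true(attr(thr3, "fallback_used"))
  expect_error(d_histogram_threshold(parameter_map(matrix(1, 5, 5))), "100")
})

test_that("mask upsampling replicates blocks and preserves counts", {
  m <- matrix(c(TRUE, FALSE, FALSE, TRUE), 2)
  u <- upsample_mask(m, 3)
  expect_equal(dim(u), c(6L, 6L))
  expect_equal(sum(u), sum(m) * 9)
  expect_true(all(u[1:3, 1:3]))
  expect_false(any(u[1:3, 4:6]))
})

test_that("the correction pipeline preserves mask inclusion and is idempotent", {
  set.seed(92)
  H <- 10; W <- 10
  sr <- superres_image(matrix(runif(H * 5 * W * 5), H * 5), 5, "test")
  tm <- matrix(runif(H * W) > 0.3, H)
  dv <- matrix(10^runif(H * W, -2, 1), H)
  dmap <- parameter_map(dv, matrix(runif(H * W) > 0.1, H), "D")
  res <- correct_superres(sr, tm, dmap, 0.2)
  expect_true(all(res$d_filtered_mask <= res$tirf_mask))   # set inclusion
  expect_true(all(res$corrected_superres$image[!upsample_mask(res$d_filtered_mask, 5)] == 0))
  expect_lte(sum(res$d_filtered_mask), sum(res$tirf_mask))
  # idempotence
  res2 <- correct_superres(res$corrected_superres, tm, dmap, 0.2)
  expect_equal(res2$corrected_superres$image, res$corrected_superres$image)
  # all-true masks with permissive threshold leave the image unchanged
  allt <- matrix(TRUE, H, W)
  dall <- parameter_map(matrix(1, H, W), allt, "D")
  resid <- correct_superres(sr, allt, dall, 0.2)
  expect_equal(resid$corrected_superres$image, sr$image)
  expect_error(correct_superres(sr, allt[1:5, ], dall, 0.2), "co-registered")
})

test_that("map correlation is exact for identical and scaled maps and null for noise", {
  set.seed(93)
  v <- matrix(10^rnorm(40 * 40, 0, 0.4), 40)
  m1 <- parameter_map(v); m2 <- parameter_map(2 * v)
  expect_equal(map_correlation(m1, m1, log_transform = FALSE)$R, 1)
  expect_equal(map_correlation(m1, m2, log_transform = FALSE)$R, 1,
               tolerance = 1e-12)
  # affine invariance without log; power-law invariance with log
  m3 <- parameter_map(3 * v + 5)
  expect_equal(map_correlation(m1, m3, log_transform = FALSE)$R, 1,
               tolerance = 1e-12)
  m4 <- parameter_map(v^1.7)
  expect_equal(map_correlation(m1, m4, log_transform = TRUE)$R, 1,
               tolerance = 1e-12)
  n1 <- parameter_map(matrix(10^rnorm(1e4, 0, 0.3), 100))
  n2 <- parameter_map(matrix(10^rnorm(1e4, 0, 0.3), 100))
  expect_lt(abs(map_correlation(n1, n2)$R), 0.05)
  expect_error(map_correlation(parameter_map(matrix(1:4, 2)),
                               parameter_map(matrix(1:4, 2))), "10")
})

test_that("brightness elevated in slow-D domains anticorrelates B with D", {
  set.seed(94)
  H <- 40; W <- 40
  slow <- matrix(FALSE, H, W); slow[10:25, 8:30] <- TRUE
  D <- matrix(10^rnorm(H * W, log10(0.5), 0.15), H)
  D[slow] <- 10^rnorm(sum(slow), log10(0.05), 0.15)
  B <- matrix(10^rnorm(H * W, log10(4), 0.1), H)
  B[slow] <- 10^rnorm(sum(slow), log10(8), 0.1)
  res <- map_correlation(parameter_map(D), parameter_map(B))
  expect_lt(res$R, -0.3)
})

test_that("SNR arithmetic follows (signal - background)/sd", {
  arr <- array(0, c(6, 6, 100))
  set.seed(95)
  arr[1:3, , ] <- rnorm(3 * 6 * 100, 110, 5)
  arr[4:6, , ] <- rnorm(3 * 6 * 100, 100, 1)
  arr[arr < 0] <- 0
  s <- image_stack(arr, 0.002)
  sig <- matrix(FALSE, 6, 6); sig[1:3, ] <- TRUE
  res <- suppressWarnings(snr(s, sig, !sig))
  expect_equal(res$snr, (res$signal_mean - res$background_mean) / res$signal_sd)
  expect_equal(res$snr, 2, tolerance = 0.2)
  expect_warning(snr(s, !sig, sig), "< 3")      # inverted regions: negative SNR
  expect_error(snr(s, sig, sig), "disjoint")
  expect_error(snr(s, sig & FALSE, !sig), "empty")
  cst <- image_stack(array(5, c(4, 4, 10)), 0.002)
  half <- matrix(rep(c(TRUE, FALSE), each = 8), 4)
  expect_error(snr(cst, half, !half), "undefined")
})

test_that("higher-gain detection yields higher SNR at matched photon flux", {
  # a dim immobile structure ("cell") against read-noise-dominated background
  cell <- as.matrix(expand.grid(x = seq(1.2, 2.9, by = 0.12),
                                y = seq(1.2, 2.9, by = 0.12)))
  base <- list(width = 16, height = 16, frames = 400, offset = 100,
               species = list(sim_species(D = 0, n_molecules = nrow(cell),
                                          positions = cell, epsilon = 3)))
  em <- simulate_stack(do.call(sim_config, c(base, seed = 96, em_gain = 100,
                                             use_em_gamma = TRUE,
                                             read_noise_sd = 20)))$stack
  lo <- simulate_stack(do.call(sim_config, c(base, seed = 96,
                                             read_noise_sd = 20)))$stack
  sig <- matrix(FALSE, 16, 16); sig[6:11, 6:11] <- TRUE
  bg <- matrix(FALSE, 16, 16); bg[1:3, 1:3] <- TRUE
  snr_em <- suppressWarnings(snr(em, sig, bg)$snr)
  snr_lo <- suppressWarnings(snr(lo, sig, bg)$snr)
  expect_gt(snr_em, snr_lo)       # EM gain lifts weak signal above read noise
  expect_gt(snr_em, 0); expect_gt(snr_lo, 0)
})

test_that("Gaussian ridge profiles report FWHM = 2 sqrt(2 ln 2) d", {
  x <- seq(0, 2000, by = 50)       # nm positions across a 100-nm-sd ridge
  img <- matrix(rep(20 + 500 * exp(-(x - 1000)^2 / (2 * 100^2)), 5),
                ncol = 5)
  fit <- profile_fwhm(img, from = c(0, 2), to = c(length(x) - 1, 2),
                      pixel_size_nm = 50)
  expect_equal(fit$fwhm_nm, 235.5, tolerance = 0.2)
  expect_equal(fit$d_nm, 100, tolerance = 0.1)
  expect_equal(fit$a, 20, tolerance = 0.5)
  expect_error(profile_fwhm(matrix(7, 20, 5), from = c(0, 2), to = c(19, 2)),
               "flat")
})

test_that("FRC of identical images is ~1 and of independent noise has no support", {
  set.seed(97)
  img <- matrix(rpois(64 * 64, 50) + as.vector(outer(
    exp(-(1:64 - 32)^2 / 18), exp(-(1:64 - 30)^2 / 18))) * 500, 64)
  res <- frc_resolution(img, img, pixel_size_nm = 48)
  expect_true(all(res$curve$frc > 0.99))
  expect_false(res$below_support)
  expect_equal(res$resolution_nm, 1 / max(res$curve$freq_per_nm),
               tolerance = 1e-9)                       # pixel-limited bound
  n1 <- matrix(rnorm(64 * 64), 64); n2 <- matrix(rnorm(64 * 64), 64)
  res2 <- frc_resolution(n1, n2, pixel_size_nm = 48)
  expect_true(res2$below_support || res2$curve$frc[1] < 1 / 7)
  expect_true(is.na(res2$resolution_nm))
})

test_that("odd/even SRRF reconstructions give a finite sub-diffraction FRC resolution", {
  cfg <- sim_config(width = 24, height = 24, frames = 3000, seed = 98,
                    offset = 100, read_noise_sd = 2,
                    species = list(sim_species(D = 3, density = 2.5,
                                               epsilon = 600,
                                               binds_fibres = TRUE)),
                    fibres = list(sim_fibre(1.2, 2.88, 4.6, 2.88, k_on = 2000,
                                            k_off = 20,
                                            capture_radius_um = 0.05),
                                  sim_fibre(2.88, 1.2, 2.88, 4.6, k_on = 2000,
                                            k_off = 20,
                                            capture_radius_um = 0.05)))
  sim <- simulate_stack(cfg)
  halves <- split_frames(sim$stack)
  p <- srrf_params(temporal_bin = 50)
  r1 <- srrf(halves$odd, p); r2 <- srrf(halves$even, p)
  px <- sim$stack$geometry$object_pixel_size_nm / p$magnification
  res <- frc_resolution(r1$image, r2$image, px)
  expect_false(is.na(res$resolution_nm))
  # beats the diffraction-limited PSF of the simulation (~364 nm 1/e2 radius)
  expect_lt(res$resolution_nm, 364)
})
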