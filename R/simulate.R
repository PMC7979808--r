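#' Define a diffusing species for the TIRF simulator
#'
#' Each molecule of a species is a `k`-mer whose subunits are independently
#' fluorescent with probability `p_fluorescent` (binomial maturation model);
#' a fluorescent subunit contributes `epsilon` expected counts per frame,
#' spread over the PSF. Molecules perform free 2-D Brownian motion with
#' coefficient `D`; species flagged with `binds_fibres = TRUE` additionally
#' undergo two-state binding kinetics near fibre segments (see [sim_fibre()]).
#'
#' @param D Diffusion coefficient in um^2/s (free state).
#' @param density Surface density in molecules/um^2 (ignored if `n_molecules`
#'   is given).
#' @param k Oligomer order (subunits per molecule, integer >= 1).
#' @param p_fluorescent Probability that a subunit is fluorescent.
#' @param epsilon Expected counts per fluorescent subunit per frame.
#' @param binds_fibres Whether this species binds the configured fibres.
#' @param n_molecules Optional exact molecule count, overriding `density`.
#' @param positions Optional 2-column matrix of initial (x, y) positions in
#'   um (rows recycled to the molecule count); default uniform random.
#' @return A `sim_species` list.
#' @export
sim_species <- function(D, density = 1, k = 1L, p_fluorescent = 1,
                        epsilon = 300, binds_fibres = FALSE,
                        n_molecules = NULL, positions = NULL) {
  stopifnot(D >= 0, density >= 0, k >= 1,
            p_fluorescent >= 0, p_fluorescent <= 1, epsilon >= 0)
  structure(list(D = D, density = density, k = as.integer(k),
                 p_fluorescent = p_fluorescent, epsilon = epsilon,
                 binds_fibres = isTRUE(binds_fibres),
                 n_molecules = n_molecules, positions = positions),
            class = "sim_species")
}

#' Define a fibre segment with binding kinetics
#'
#' Binding is modelled as capture: a free molecule of a fibre-binding species
#' that comes within `capture_radius_um` of the segment binds with rate
#' `k_on` (per second); a bound molecule diffuses with `bound_D` and releases
#' with rate `k_off`. Exponential waiting times are discretised on the frame
#' grid.
#'
#' @param x0,y0,x1,y1 Segment endpoints in um (x along columns, y along rows).
#' @param k_on,k_off Binding/unbinding rates in 1/s.
#' @param bound_D Diffusion coefficient while bound, um^2/s.
#' @param capture_radius_um Capture distance from the segment, um (default one
#'   240-nm object pixel).
#' @return A `sim_fibre` list.
#' @export
sim_fibre <- function(x0, y0, x1, y1, k_on = 100, k_off = 10, bound_D = 0,
                      capture_radius_um = 0.24) {
  stopifnot(k_on >= 0, k_off >= 0, bound_D >= 0, capture_radius_um > 0)
  structure(list(x0 = x0, y0 = y0, x1 = x1, y1 = y1, k_on = k_on,
                 k_off = k_off, bound_D = bound_D,
                 capture_radius_um = capture_radius_um),
            class = "sim_fibre")
}

#' Simulation configuration for synthetic TIRF stacks
#'
#' Defaults follow the acquisition geometry of the measurements the package
#' targets: 2 ms frames, 50,000 frames, 128 x 128 pixels of 240 nm in the
#' object plane, and a 364-nm 1/e^2 PSF radius (561-nm excitation channel).
#' The simulated region is exactly the imaged pixel grid with periodic
#' boundaries, which keeps the molecule concentration stationary.
#'
#' @param width,height Image size in pixels.
#' @param frames Number of frames.
#' @param frame_time Seconds per frame.
#' @param geometry An [acquisition_geometry()]; its `object_pixel_size_nm` and
#'   `psf_e2_radius_nm` drive the optics.
#' @param species List of [sim_species()].
#' @param fibres List of [sim_fibre()] (may be empty).
#' @param offset Detector offset in counts.
#' @param read_noise_sd Gaussian read noise SD in counts.
#' @param em_gain Electron-multiplying gain (1 = no EM register).
#' @param use_em_gamma If `TRUE`, the EM register output for n photoelectrons
#'   is drawn from Gamma(n, scale = em_gain) (excess noise factor ~ 2);
#'   otherwise counts are multiplied by `em_gain` deterministically.
#' @param bleach_rate Per-fluorophore photobleaching rate, 1/s (irreversible).
#' @param seed Optional integer seed (`set.seed`) for reproducible stacks.
#' @return A `sim_config` list.
#' @export
sim_config <- function(width = 128L, height = 128L, frames = 50000L,
                       frame_time = 0.002,
                       geometry = acquisition_geometry(24, 100, 364),
                       species = list(sim_species(D = 2)),
                       fibres = list(),
                       offset = 100, read_noise_sd = 2, em_gain = 1,
                       use_em_gamma = FALSE, bleach_rate = 0, seed = NULL) {
  stopifnot(width >= 1, height >= 1, frames >= 1, frame_time > 0,
            bleach_rate >= 0, em_gain >= 1, read_noise_sd >= 0, offset >= 0)
  if (is.na(geometry$psf_e2_radius_nm)) stop("geometry needs a calibrated PSF")
  structure(list(width = as.integer(width), height = as.integer(height),
                 frames = as.integer(frames), frame_time = frame_time,
                 geometry = geometry, species = species, fibres = fibres,
                 offset = offset, read_noise_sd = read_noise_sd,
                 em_gain = em_gain, use_em_gamma = isTRUE(use_em_gamma),
                 bleach_rate = bleach_rate, seed = seed),
            class = "sim_config")
}

point_segment_dist <- function(x, y, f) {
  vx <- f$x1 - f$x0; vy <- f$y1 - f$y0
  L2 <- vx * vx + vy * vy
  t <- if (L2 == 0) 0 else pmin(1, pmax(0, ((x - f$x0) * vx + (y - f$y0) * vy) / L2))
  sqrt((x - (f$x0 + t * vx))^2 + (y - (f$y0 + t * vy))^2)
}

# Trajectories for one species: returns list(x, y, bound) of T x M matrices
# (um; bound is logical, all-FALSE for non-binding species).
simulate_trajectories <- function(sp, M, Tn, dt, Lx, Ly, fibres) {
  if (M == 0L) return(list(x = matrix(0, Tn, 0), y = matrix(0, Tn, 0),
                           bound = matrix(FALSE, Tn, 0)))
  if (!is.null(sp$positions)) {
    p0 <- sp$positions[rep_len(seq_len(nrow(sp$positions)), M), , drop = FALSE]
    x0 <- p0[, 1]; y0 <- p0[, 2]
  } else {
    x0 <- stats::runif(M, 0, Lx); y0 <- stats::runif(M, 0, Ly)
  }
  binding <- sp$binds_fibres && length(fibres) > 0
  if (!binding) {
    sd_step <- sqrt(2 * sp$D * dt)
    x <- apply(rbind(x0, matrix(stats::rnorm((Tn - 1) * M, 0, sd_step),
                                Tn - 1, M)), 2, cumsum)
    y <- apply(rbind(y0, matrix(stats::rnorm((Tn - 1) * M, 0, sd_step),
                                Tn - 1, M)), 2, cumsum)
    dim(x) <- dim(y) <- c(Tn, M)
    return(list(x = x %% Lx, y = y %% Ly, bound = matrix(FALSE, Tn, M)))
  }
  # state-dependent stepping, vectorised over molecules frame by frame
  x <- matrix(0, Tn, M); y <- matrix(0, Tn, M); bnd <- matrix(FALSE, Tn, M)
  xc <- x0; yc <- y0; bc <- rep(FALSE, M)
  sd_free <- sqrt(2 * sp$D * dt)
  for (t in seq_len(Tn)) {
    x[t, ] <- xc; y[t, ] <- yc; bnd[t, ] <- bc
    dmin <- rep(Inf, M); near_f <- rep(0L, M)
    for (fi in seq_along(fibres)) {
      dd <- point_segment_dist(xc, yc, fibres[[fi]])
      upd <- dd < dmin
      dmin[upd] <- dd[upd]; near_f[upd] <- fi
    }
    # release and capture act on the state at the start of the frame, so a
    # molecule released now diffuses freely for at least one step
    bc0 <- bc
    for (fi in seq_along(fibres)) {
      f <- fibres[[fi]]
      rel <- bc0 & near_f == fi & stats::runif(M) < (1 - exp(-f$k_off * dt))
      bc[rel] <- FALSE
      cap <- !bc0 & near_f == fi & dmin < f$capture_radius_um &
        stats::runif(M) < (1 - exp(-f$k_on * dt))
      bc[cap] <- TRUE
    }
    sdv <- ifelse(bc,
                  sqrt(2 * vapply(near_f, function(i)
                    if (i > 0) fibres[[i]]$bound_D else sp$D, 0) * dt),
                  sd_free)
    xc <- (xc + stats::rnorm(M, 0, sdv)) %% Lx
    yc <- (yc + stats::rnorm(M, 0, sdv)) %% Ly
  }
  list(x = x, y = y, bound = bnd)
}

#' Simulate a TIRF image stack with known ground truth
#'
#' Per frame, every fluorescent subunit deposits a 2-D Gaussian of 1/e^2
#' radius `psf_e2_radius_nm`, integrated over the pixel grid (periodic
#' boundaries). Expected counts are Poisson-sampled, passed through an
#' optional EM register (Gamma per-photoelectron gain), and Gaussian read
#' noise and the detector offset are added. Photobleaching switches
#' fluorophores off permanently with the configured rate. Positions are
#' sampled once per frame (no intra-frame motion blur).
#'
#' @param cfg A [sim_config()].
#' @return A list with elements `stack` (an [image_stack()]) and `truth`
#'   (per-species trajectories, bound states, fluorescent-subunit counts, and
#'   the fibre mask on the pixel grid).
#' @export
simulate_stack <- function(cfg) {
  if (!inherits(cfg, "sim_config")) stop("cfg must be a sim_config")
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  a_um <- cfg$geometry$object_pixel_size_nm / 1000
  sigma_um <- cfg$geometry$psf_e2_radius_nm / 2000   # 1/e^2 radius / 2, in um
  H <- cfg$height; W <- cfg$width; Tn <- cfg$frames; dt <- cfg$frame_time
  Lx <- W * a_um; Ly <- H * a_um
  area <- Lx * Ly
  expected <- array(0, dim = c(H, W, Tn))
  truth <- list(species = list(), fibre_mask = fibre_mask_grid(cfg))
  for (si in seq_along(cfg$species)) {
    sp <- cfg$species[[si]]
    M <- if (!is.null(sp$n_molecules)) as.integer(sp$n_molecules)
         else as.integer(round(sp$density * area))
    q <- if (M > 0) stats::rbinom(M, sp$k, sp$p_fluorescent) else integer(0)
    tr <- simulate_trajectories(sp, M, Tn, dt, Lx, Ly, cfg$fibres)
    amp <- matrix(rep(sp$epsilon * q, each = Tn), Tn, M)
    if (cfg$bleach_rate > 0 && M > 0) {
      # independent exponential lifetime per fluorescent subunit
      alive <- matrix(0, Tn, M)
      tgrid <- (seq_len(Tn) - 1) * dt
      for (m in seq_len(M)) {
        if (q[m] == 0) next
        bt <- stats::rexp(q[m], cfg$bleach_rate)
        alive[, m] <- colSums(outer(bt, tgrid, ">"))
      }
      amp <- sp$epsilon * alive
    }
    if (M > 0)
      expected <- expected + deposit_frames_cpp(tr$x, tr$y, amp, H, W,
                                                a_um, sigma_um)
    truth$species[[si]] <- list(x = tr$x, y = tr$y, bound = tr$bound, q = q,
                                D = sp$D, k = sp$k,
                                p_fluorescent = sp$p_fluorescent)
  }
  counts <- array(stats::rpois(length(expected), expected), dim = dim(expected))
  if (cfg$em_gain > 1) {
    if (cfg$use_em_gamma) {
      out <- numeric(length(counts))
      nz <- counts > 0
      out[nz] <- stats::rgamma(sum(nz), shape = counts[nz],
                               scale = cfg$em_gain)
      counts <- array(out, dim = dim(counts))
    } else counts <- counts * cfg$em_gain
  }
  if (cfg$read_noise_sd > 0)
    counts <- counts + stats::rnorm(length(counts), 0, cfg$read_noise_sd)
  counts <- counts + cfg$offset
  counts[counts < 0] <- 0
  stack <- image_stack(counts, dt, cfg$geometry)
  list(stack = stack, truth = truth)
}

# Boolean fibre mask on the pixel grid (pixel centre within capture radius).
fibre_mask_grid <- function(cfg) {
  a_um <- cfg$geometry$object_pixel_size_nm / 1000
  H <- cfg$height; W <- cfg$width
  mask <- matrix(FALSE, H, W)
  if (length(cfg$fibres) == 0) return(mask)
  xc <- ((col(mask) - 0.5) * a_um); yc <- ((row(mask) - 0.5) * a_um)
  for (f in cfg$fibres)
    mask <- mask | (point_segment_dist(as.vector(xc), as.vector(yc), f) <
                      f$capture_radius_um)
  matrix(mask, H, W)
}

#' Expected photobleaching decay trace
#'
#' Deterministic expected intensity of an ensemble bleaching with first-order
#' rate `rate`: `F0 * exp(-rate * t)` on the frame grid. With
#' `shot_noise = TRUE` each point is Poisson-sampled.
#'
#' @param rate Bleaching rate in 1/s (>= 0).
#' @param frames Number of frames.
#' @param frame_time Seconds per frame.
#' @param F0 Initial expected intensity (counts/frame).
#' @param shot_noise Add Poisson sampling?
#' @return Numeric vector of length `frames`.
#' @export
simulate_bleach_trace <- function(rate, frames, frame_time, F0 = 1000,
                                  shot_noise = FALSE) {
  stopifnot(rate >= 0, frames >= 1, frame_time > 0)
  mu <- F0 * exp(-rate * (seq_len(frames) - 1) * frame_time)
  if (shot_noise) stats::rpois(frames, mu) else mu
}
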