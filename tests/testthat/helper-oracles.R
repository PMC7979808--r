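# Independent oracles used across test files. These deliberately use naive
# O(T * tau) loops and literal formulas, not the package's vectorised paths.

# Direct-sum symmetric-normalisation correlation estimator at integer lag k.
direct_acf <- function(trace, k) {
  n <- length(trace)
  stopifnot(k >= 1, n - k >= 2)
  s <- 0
  for (i in seq_len(n - k)) s <- s + trace[i] * trace[i + k]
  num <- s / (n - k)
  ml <- mean(trace[seq_len(n - k)])
  mr <- mean(trace[seq.int(k + 1, n)])
  num / (ml * mr) - 1
}

# Bin-average a trace over non-overlapping windows of w samples (floor).
bin_average <- function(trace, w) {
  n <- length(trace) %/% w
  colMeans(matrix(trace[seq_len(n * w)], w, n))
}

# Progressive pair-halving as the multi-tau correlator performs it:
# floor(floor(T/2)/2)... differs from floor(T/4) never, but keep the exact
# sample path for bit-level comparisons.
progressive_bin <- function(trace, w) {
  while (w > 1) {
    n2 <- length(trace) %/% 2
    trace <- (trace[seq_len(n2) * 2 - 1] + trace[seq_len(n2) * 2]) / 2
    w <- w / 2
  }
  trace
}

# Default test geometry: EMCCD at x100, 240 nm object pixels, 364 nm PSF.
test_geometry <- function(psf = 364) acquisition_geometry(24, 100, psf)

# Small free-diffusion stack shared by several tests (cached per session).
shared_free_stack <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(width = 16, height = 16, frames = 10000, seed = 101,
                        species = list(sim_species(D = 2, density = 1.5,
                                                   epsilon = 300)))
      cache <<- simulate_stack(cfg)
    }
    cache
  }
})
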