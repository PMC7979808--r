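#' Multi-tau correlator scheme
#'
#' The correlator uses `q` blocks of progressively doubled bin width: block
#' `b` (0-based) averages `2^b` frames per sample. Block 0 carries `p` lag
#' channels at 1..p frames; every later block carries `p/2` channels at
#' `(p/2+1..p) * 2^b` frames, so lag times grow quasi-logarithmically while
#' remaining strictly increasing.
#'
#' @param p Channels in the first block (even, >= 4). Default 16.
#' @param q Number of blocks (>= 1). Default 12 (2-ms cell data); 9 is typical
#'   for 1-ms bilayer calibration data.
#' @return A `correlator_scheme` list.
#' @export
correlator_scheme <- function(p = 16L, q = 12L) {
  p <- as.integer(p); q <- as.integer(q)
  if (p < 4L || p %% 2L != 0L) stop("p must be even and >= 4")
  if (q < 1L) stop("q must be >= 1")
  structure(list(p = p, q = q), class = "correlator_scheme")
}

# Lag table: data.frame(block, width (frames/sample), k (lag in samples),
# lag_frames). Strictly increasing lag_frames; first lag = 1 frame.
scheme_lags <- function(scheme) {
  p <- scheme$p; q <- scheme$q
  blocks <- lapply(seq_len(q) - 1L, function(b) {
    k <- if (b == 0L) seq_len(p) else seq.int(p %/% 2L + 1L, p)
    data.frame(block = b, width = 2L^b, k = k, lag_frames = k * 2L^b)
  })
  do.call(rbind, blocks)
}

#' Photobleaching correction of an intensity trace
#'
#' Fits a polynomial trend `f(t)` of the given order by least squares and
#' returns `F(t)/sqrt(f(t)/f(0)) + f(0) * (1 - sqrt(f(t)/f(0)))`, which
#' restores the initial mean while suppressing the slow decay and preserving
#' the local fluctuation-to-mean relation of shot-noise-limited data.
#'
#' @param trace Numeric intensity series (counts/frame).
#' @param order Polynomial order (>= 0; 0 returns the trace unchanged since
#'   the fitted trend is constant). Default 8.
#' @return Corrected trace of the same length.
#' @export
bleach_correct <- function(trace, order = 8L) {
  order <- as.integer(order)
  stopifnot(order >= 0, length(trace) > order + 1)
  if (order == 0L) return(trace)
  f <- bleach_trend(matrix(trace, ncol = 1), order)[, 1]
  if (any(f <= 0)) stop("fitted bleach trend is non-positive: trace unusable")
  s <- sqrt(f / f[1])
  trace / s + f[1] * (1 - s)
}

# Polynomial trends for all columns of a T x P trace matrix at once
# (orthogonal design matrix shared across pixels).
bleach_trend <- function(traces, order) {
  Tn <- nrow(traces)
  X <- cbind(1, stats::poly(seq_len(Tn), degree = order))
  X %*% qr.solve(X, traces)
}

# Bleach-correct a T x P matrix; returns list(traces, ok) where ok flags
# columns with a positive fitted trend.
bleach_correct_matrix <- function(traces, order) {
  if (order == 0L) return(list(traces = traces, ok = rep(TRUE, ncol(traces))))
  f <- bleach_trend(traces, order)
  ok <- apply(f > 0, 2, all)
  # non-positive trends only occur on columns already flagged invalid
  s <- suppressWarnings(sqrt(sweep(f, 2, f[1, ], "/")))
  out <- traces / s + rep(f[1, ], each = nrow(traces)) * (1 - s)
  out[, !ok] <- traces[, !ok]   # left untouched, flagged invalid downstream
  list(traces = out, ok = ok)
}

# Core multi-tau estimator on a T x P matrix of traces.
#
# Symmetric normalisation: for lag k on the (possibly bin-averaged) trace B of
# length n, G = mean(B[i] * B[i+k]) / (mean(B[1..n-k]) * mean(B[k+1..n])) - 1.
# Returns G matrix (nlags x P); attributes carry the lag table.
multitau_matrix <- function(traces, scheme) {
  lt <- scheme_lags(scheme)
  Tn <- nrow(traces); P <- ncol(traces)
  G <- matrix(NA_real_, nrow(lt), P)
  cur <- traces; width <- 1L
  for (b in unique(lt$block)) {
    w <- 2L^b
    if (w > width) {          # halve: average consecutive pairs of samples
      n2 <- nrow(cur) %/% 2L
      if (n2 < 2L) break
      cur <- (cur[seq_len(n2) * 2L - 1L, , drop = FALSE] +
              cur[seq_len(n2) * 2L, , drop = FALSE]) / 2
      width <- w
    }
    n <- nrow(cur)
    for (r in which(lt$block == b)) {
      k <- lt$k[r]
      if (n - k < 2L) next
      head_ <- cur[seq_len(n - k), , drop = FALSE]
      tail_ <- cur[seq.int(k + 1L, n), , drop = FALSE]
      num <- colMeans(head_ * tail_)
      ml <- colMeans(head_); mr <- colMeans(tail_)
      G[r, ] <- num / (ml * mr) - 1
    }
  }
  structure(G, lags = lt)
}

#' Per-pixel autocorrelation function
#'
#' Container for one pixel's normalised intensity autocorrelation
#' `G(tau) = <dF(t) dF(t+tau)> / <F>^2` on the multi-tau lag grid, with a
#' per-lag standard-deviation estimate from segment splitting.
#'
#' @param lags Lag times in seconds (strictly increasing, first = frame time).
#' @param G Correlation amplitudes.
#' @param sd Per-lag SD estimates (may be `NA`).
#' @param mean_intensity Mean counts/frame of the (corrected) trace.
#' @param frame_time Seconds per frame.
#' @return A `pixel_acf` list.
#' @export
pixel_acf <- function(lags, G, sd = rep(NA_real_, length(lags)),
                      mean_intensity = NA_real_, frame_time = lags[1]) {
  stopifnot(length(lags) == length(G), length(sd) == length(G))
  structure(list(lags = lags, G = G, sd = sd,
                 mean_intensity = mean_intensity, frame_time = frame_time),
            class = "pixel_acf")
}

#' @export
print.pixel_acf <- function(x, ...) {
  cat(sprintf("<pixel_acf> %d lags, %g s .. %g s; G(tau1) = %.4g\n",
              length(x$lags), min(x$lags), max(x$lags), x$G[1]))
  invisible(x)
}

#' Multi-tau autocorrelation of an intensity trace
#'
#' Computes `G(tau) = <dF(t) dF(t+tau)> / <F>^2` on the quasi-logarithmic
#' multi-tau lag grid of `scheme`, with symmetric normalisation (the means in
#' numerator and denominator are taken over the two overlapping trace
#' segments, which reduces bias from residual drift). At block `b` the trace
#' is bin-averaged over `2^b` frames before correlation, so G at a binned lag
#' equals the direct estimator applied to the bin-averaged trace.
#'
#' The per-lag SD is estimated by splitting the trace into `n_segments` equal
#' parts, correlating each, and taking the across-segment SD divided by
#' `sqrt(n_segments)`.
#'
#' @param trace Intensity series (length >= 2 p).
#' @param scheme A [correlator_scheme()].
#' @param frame_time Seconds per frame.
#' @param n_segments Segments for the SD estimate (0 disables). Default 8.
#' @return A [pixel_acf()]. A zero-variance trace yields all-`NA` G (flagged
#'   degenerate rather than raising, so map-level batch runs continue).
#' @export
multitau_acf <- function(trace, scheme = correlator_scheme(),
                         frame_time, n_segments = 8L) {
  stopifnot(length(trace) >= 2L * scheme$p)
  tm <- matrix(trace, ncol = 1)
  G <- multitau_matrix(tm, scheme)
  lt <- attr(G, "lags")
  sdv <- rep(NA_real_, nrow(lt))
  if (n_segments > 1L) {
    seg_len <- length(trace) %/% n_segments
    if (seg_len >= 2L * scheme$p) {
      segs <- matrix(trace[seq_len(seg_len * n_segments)], seg_len, n_segments)
      Gs <- multitau_matrix(segs, scheme)
      sdv <- apply(Gs, 1, stats::sd) / sqrt(n_segments)
    }
  }
  if (stats::sd(trace) == 0) G[] <- NA_real_
  pixel_acf(lags = lt$lag_frames * frame_time, G = G[, 1], sd = sdv,
            mean_intensity = mean(trace), frame_time = frame_time)
}

#' Autocorrelation map of an image stack
#'
#' Bleach-corrects every (optionally spatially binned) pixel trace with a
#' polynomial of order `bleach_order`, then computes the multi-tau ACF per
#' pixel. Pixels with a degenerate trace (zero variance or a non-positive
#' bleach trend) are flagged invalid, not dropped.
#'
#' @param stack An [image_stack()].
#' @param scheme A [correlator_scheme()].
#' @param binning Spatial binning (sum mode) applied before correlation.
#' @param bleach_order Polynomial order for bleach correction (0 disables).
#' @param lag_range Optional `c(tau_min, tau_max)` in seconds restricting the
#'   returned lags (e.g. `c(0.002, 0.5)` to fit only short lag times).
#' @param n_segments Segments for SD estimation.
#' @return An `acf_map` object: list with `lags` (shared grid), `G` and `sd`
#'   (`nlags x H' x W'` arrays), `mean_intensity` (matrix), `valid` (matrix),
#'   `frame_time`, `binning`.
#' @export
acf_map <- function(stack, scheme = correlator_scheme(), binning = 1L,
                    bleach_order = 8L, lag_range = NULL, n_segments = 8L) {
  if (binning > 1L) stack <- bin_spatial(stack, binning, "sum")
  d <- dim(stack$data)
  H <- d[1]; W <- d[2]; Tn <- d[3]
  traces <- t(matrix(stack$data, H * W, Tn))   # T x P
  bc <- bleach_correct_matrix(traces, bleach_order)
  traces <- bc$traces
  G <- multitau_matrix(traces, scheme)
  lt <- attr(G, "lags")
  lags <- lt$lag_frames * stack$frame_time
  sdm <- matrix(NA_real_, nrow(lt), H * W)
  if (n_segments > 1L) {
    seg_len <- Tn %/% n_segments
    if (seg_len >= 2L * scheme$p) {
      Gs <- array(NA_real_, c(nrow(lt), n_segments, H * W))
      for (s in seq_len(n_segments)) {
        idx <- seq.int((s - 1L) * seg_len + 1L, s * seg_len)
        Gs[, s, ] <- multitau_matrix(traces[idx, , drop = FALSE], scheme)
      }
      sdm <- apply(Gs, c(1, 3), stats::sd) / sqrt(n_segments)
    }
  }
  varz <- apply(traces, 2, stats::sd) == 0
  valid <- bc$ok & !varz
  G[, !valid] <- NA_real_
  if (!is.null(lag_range)) {
    if (lag_range[1] > max(lags) || lag_range[2] < min(lags))
      stop("lag_range outside available lags")
    keep <- lags >= lag_range[1] & lags <= lag_range[2]
  } else keep <- rep(TRUE, length(lags))
  # drop lags unreachable for this trace length (NA even on valid pixels)
  if (any(valid)) keep <- keep & !is.na(G[, which(valid)[1]])
  structure(list(lags = lags[keep],
                 G = array(G[keep, , drop = FALSE], c(sum(keep), H, W)),
                 sd = array(sdm[keep, , drop = FALSE], c(sum(keep), H, W)),
                 mean_intensity = matrix(colMeans(traces), H, W),
                 valid = matrix(valid, H, W),
                 frame_time = stack$frame_time, binning = binning,
                 geometry = stack$geometry),
            class = "acf_map")
}

#' Extract one pixel's ACF from an ACF map
#'
#' @param map An [acf_map()].
#' @param row,col 1-based pixel indices in the binned grid.
#' @return A [pixel_acf()].
#' @export
acf_at <- function(map, row, col) {
  pixel_acf(map$lags, map$G[, row, col], map$sd[, row, col],
            map$mean_intensity[row, col], map$frame_time)
}
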