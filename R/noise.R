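#' Specification of the stochastic extracortical drive
#'
#' Describes the spatiotemporally filtered Gaussian noise imposed on the
#' ee extracortical input rate: per-point mean `mean`, standard deviation
#' `rel_sd * mean`, a radially symmetric Gaussian spatial low-pass with
#' power transfer -3 dB at `k3db` (cycles/mm), and temporal low-pass by
#' Catmull-Rom spline interpolation over independent Gaussian knot fields
#' with the knot interval calibrated so the interpolation kernel's power
#' transfer is -3 dB at `f3db` (Hz).
#'
#' @param mean mean drive rate (1/ms); defaults to the Table-level `p_ee`.
#' @param rel_sd relative standard deviation (default 0.10).
#' @param f3db temporal -3 dB point (Hz).
#' @param k3db spatial -3 dB point (cycles/mm; 0.2/mm = 2/cm).
#' @param temporal_filter if `FALSE`, draw an independent knot every step
#'   (white-in-time driving).
#' @param spatial_filter if `FALSE`, knots are spatially white.
#' @return A list of class `noise_spec`.
#' @export
noise_spec <- function(mean = default_parameters()$p_ext["ee"], rel_sd = 0.10,
                       f3db = 75, k3db = 0.2, temporal_filter = TRUE,
                       spatial_filter = TRUE) {
  stopifnot(mean > 0, rel_sd >= 0, f3db > 0, k3db > 0)
  structure(list(mean = unname(mean), rel_sd = rel_sd, f3db = f3db,
                 k3db = k3db, temporal_filter = temporal_filter,
                 spatial_filter = spatial_filter),
            class = "noise_spec")
}

# -3 dB point (in cycles per knot interval) of the power transfer of
# Catmull-Rom (Keys, a = -1/2) cardinal interpolation of an i.i.d. knot
# sequence. Computed once from the kernel's Fourier transform and cached.
.keys_cutoff <- function() {
  if (!is.null(.bf_cache$keys_cutoff)) return(.bf_cache$keys_cutoff)
  du <- 1 / 512
  u <- seq(-2, 2 - du, by = du)
  au <- abs(u)
  k <- ifelse(au <= 1, 1.5 * au^3 - 2.5 * au^2 + 1,
              ifelse(au <= 2, -0.5 * au^3 + 2.5 * au^2 - 4 * au + 2, 0))
  # zero-padded FFT -> kernel transform on a fine frequency grid
  nz <- 2^16
  kk <- c(k, rep(0, nz - length(k)))
  H2 <- Mod(stats::fft(kk))^2
  H2 <- H2 / H2[1]
  fr <- seq(0, length.out = nz, by = 1 / (nz * du))
  ix <- which(H2[seq_len(nz %/% 2)] < 0.5)[1]
  # linear interpolation to the half-power crossing
  x0 <- fr[ix - 1]; x1 <- fr[ix]
  y0 <- H2[ix - 1]; y1 <- H2[ix]
  .bf_cache$keys_cutoff <- x0 + (0.5 - y0) * (x1 - x0) / (y1 - y0)
  .bf_cache$keys_cutoff
}

#' Knot interval implied by a temporal -3 dB point
#'
#' @param f3db temporal cutoff (Hz).
#' @return knot interval (ms).
#' @export
knot_interval_ms <- function(f3db) 1000 * .keys_cutoff() / f3db

# Catmull-Rom weights for fractional positions u in [0,1), rows normalized
# to unit sum of squares so the interpolated field has exactly the knot
# variance at every instant.
.catmull_rom_weights <- function(u, normalize = TRUE) {
  w <- cbind(0.5 * (-u^3 + 2 * u^2 - u),
             0.5 * (3 * u^3 - 5 * u^2 + 2),
             0.5 * (-3 * u^3 + 4 * u^2 + u),
             0.5 * (u^3 - u^2))
  if (normalize) w <- w / sqrt(rowSums(w^2))
  w
}

# Spatial Gaussian power-transfer filter on the discrete Fourier grid,
# |T(k3db)|^2 = 1/2, plus the deterministic variance-renormalization factor.
.spatial_filter <- function(grid, k3db) {
  fx <- (seq_len(grid$nx) - 1) / (grid$nx * grid$dx)
  fx <- ifelse(fx > 1 / (2 * grid$dx), fx - 1 / grid$dx, fx)
  fy <- (seq_len(grid$ny) - 1) / (grid$ny * grid$dx)
  fy <- ifelse(fy > 1 / (2 * grid$dx), fy - 1 / grid$dx, fy)
  f2 <- outer(fy^2, fx^2, "+")
  alpha <- log(2) / (2 * k3db^2)
  Tf <- exp(-alpha * f2)
  list(T = Tf, renorm = sqrt(mean(Tf^2)))
}

#' Create a stateful generator of the extracortical noise stream
#'
#' The generator holds the four knot fields spanning the current knot
#' interval and draws a new spatially filtered, variance-renormalized,
#' standardized Gaussian knot field on each `advance()`. The stream is fully
#' determined by the R random number generator state, so a fixed seed gives
#' an identical stream. `sample_at(u)` evaluates the standardized field at
#' fractional position `u` of the current interval; the drive field is
#' `mean * (1 + rel_sd * z)`.
#'
#' @param spec a `noise_spec`.
#' @param grid a `grid_spec`.
#' @param dt integration time step (ms); the knot interval is rounded to a
#'   whole number of steps.
#' @return An environment with fields `knots` (npts x 4), `nsub` (steps per
#'   knot interval), `crw` (nsub x 4 normalized interpolation weights), and
#'   functions `advance()` and `sample_at(u)`.
#' @export
noise_generator <- function(spec, grid, dt = 0.05) {
  n <- grid$nx * grid$ny
  if (spec$spatial_filter &&
      1 / (2 * grid$dx) < spec$k3db)
    warning("grid too coarse to resolve the spatial cutoff")
  nsub <- if (spec$temporal_filter)
    max(2L, as.integer(round(knot_interval_ms(spec$f3db) / dt))) else 1L
  filt <- if (spec$spatial_filter) .spatial_filter(grid, spec$k3db) else NULL
  gen <- new.env(parent = emptyenv())
  gen$spec <- spec; gen$grid <- grid; gen$nsub <- nsub
  gen$crw <- .catmull_rom_weights((seq_len(nsub) - 1) / nsub,
                                  normalize = spec$temporal_filter)
  draw <- function() {
    z <- matrix(stats::rnorm(n), grid$ny, grid$nx)
    if (!is.null(filt)) {
      z <- Re(stats::fft(stats::fft(z) * filt$T, inverse = TRUE)) / n
      z <- z / filt$renorm
    }
    as.numeric(z)
  }
  gen$knots <- vapply(1:4, function(i) draw(), numeric(n))
  gen$advance <- function() {
    gen$knots <- cbind(gen$knots[, 2:4, drop = FALSE], draw())
    invisible(NULL)
  }
  gen$sample_at <- function(u) {
    w <- .catmull_rom_weights(u, normalize = spec$temporal_filter)
    as.numeric(gen$knots %*% t(w))
  }
  gen
}

#' Temporal power spectral density of the noise stream at one grid point
#'
#' Diagnostic: generates `duration` seconds of the standardized stream at
#' the integration cadence, decimated to `fs`, and returns its Welch PSD.
#' Used to verify the calibrated -3 dB point.
#'
#' @param gen a generator from [noise_generator()].
#' @param duration seconds of stream to generate.
#' @param dt integration step (ms).
#' @param fs analysis sampling rate (Hz).
#' @param point grid point index.
#' @return A `psd_result` (see [welch_psd()]).
#' @export
psd_of_stream <- function(gen, duration = 40, dt = 0.05, fs = 500,
                          point = 1L) {
  stride <- max(1L, as.integer(round(1000 / (fs * dt))))
  fs <- 1000 / (dt * stride)
  nstep <- as.integer(round(duration * 1000 / dt))
  out <- numeric(0)
  g <- 0L
  while (g < nstep) {
    take <- min(gen$nsub, nstep - g)
    u <- (seq_len(take) - 1) / gen$nsub
    sel <- which((g + seq_len(take) - 1L) %% stride == 0L)
    if (length(sel) > 0) {
      w <- .catmull_rom_weights(u[sel], normalize = gen$spec$temporal_filter)
      out <- c(out, as.numeric(w %*% gen$knots[point, ]))
    }
    gen$advance()
    g <- g + take
  }
  welch_psd(out, fs = fs)
}
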