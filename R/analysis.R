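#' Welch power spectral density of a single series
#'
#' Standard Welch estimate: the series is split into `window_s`-second
#' segments with fractional `overlap`, each segment is mean-removed,
#' Hann-windowed and periodogram-transformed, and the one-sided densities
#' are averaged. The density scaling satisfies Parseval: the integral of the
#' PSD over frequency approximates the variance of the (detrended) series.
#'
#' @param x numeric series.
#' @param fs sampling rate (Hz).
#' @param window_s segment length (s), default 2.5.
#' @param overlap fractional overlap, default 0.5.
#' @return A list of class `psd_result`: `freq` (Hz), `power` (x^2/Hz),
#'   `df`, `n_segments`, `fs`, `window_s`, `overlap`.
#' @export
welch_psd <- function(x, fs, window_s = 2.5, overlap = 0.5) {
  L <- as.integer(round(window_s * fs))
  if (length(x) < L) stop("series shorter than one Welch window")
  res <- .welch_matrix(matrix(x, nrow = 1), fs, window_s, overlap)
  structure(list(freq = res$freq, power = res$power, df = res$df,
                 n_segments = res$n_segments, fs = fs, window_s = window_s,
                 overlap = overlap),
            class = "psd_result")
}

# Welch PSD averaged over the rows of X (npts x nt): per-point PSDs are
# computed for every row and every segment, then averaged.
.welch_matrix <- function(X, fs, window_s = 2.5, overlap = 0.5) {
  nt <- ncol(X)
  L <- as.integer(round(window_s * fs))
  if (nt < L) stop("series shorter than one Welch window")
  hop <- max(1L, as.integer(round(L * (1 - overlap))))
  starts <- seq(1L, nt - L + 1L, by = hop)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(L) - 1) / L)
  U <- sum(w^2)
  nb <- L %/% 2 + 1L
  acc <- numeric(nb)
  for (s0 in starts) {
    seg <- X[, s0:(s0 + L - 1L), drop = FALSE]
    seg <- seg - rowMeans(seg)
    Z <- stats::mvfft(t(seg) * w)
    P <- rowMeans(Mod(Z[seq_len(nb), , drop = FALSE])^2)
    acc <- acc + P
  }
  power <- acc / length(starts) * (2 / (fs * U))
  power[1] <- power[1] / 2
  if (L %% 2 == 0) power[nb] <- power[nb] / 2
  list(freq = (seq_len(nb) - 1) * fs / L, power = power, df = fs / L,
       n_segments = length(starts))
}

.plateau_window <- function(rec, plateau) {
  w <- rec$protocol$plateaus[[plateau]]
  if (is.null(w)) stop("no plateau labelled '", plateau, "' in the protocol")
  w
}

.plateau_columns <- function(rec, field, plateau) {
  tm <- rec$times[[field]]
  if (is.null(tm)) stop("field '", field, "' was not recorded")
  w <- .plateau_window(rec, plateau)
  sel <- which(tm >= w[1] - 1e-9 & tm < w[2] - 1e-9)
  if (length(sel) == 0) stop("plateau window outside the recording")
  sel
}

#' Grid-averaged Welch PSD over a protocol plateau
#'
#' Computes the Welch PSD for every grid point over the plateau window and
#' averages them; both the raw average and the unit-area normalized variant
#' (total power one) are returned.
#'
#' @param rec a `recording`.
#' @param plateau plateau label (e.g. `"C"`).
#' @param field recorded field name (default `"h_e"`).
#' @param window_s,overlap Welch parameters.
#' @return A `psd_result` with elements `power` (raw average) and
#'   `power_norm` (unit area), plus the plateau label.
#' @export
grid_average_psd <- function(rec, plateau, field = "h_e", window_s = 2.5,
                             overlap = 0.5) {
  sel <- .plateau_columns(rec, field, plateau)
  res <- .welch_matrix(rec$fields[[field]][, sel, drop = FALSE], rec$fs,
                       window_s, overlap)
  tot <- sum(res$power) * res$df
  structure(list(freq = res$freq, power = res$power,
                 power_norm = res$power / tot, df = res$df,
                 n_segments = res$n_segments, fs = rec$fs,
                 window_s = window_s, overlap = overlap, plateau = plateau),
            class = "psd_result")
}

#' Ratio of frequency-integrated grid-averaged power between two plateaus
#'
#' Integrates the raw (un-normalized) grid-averaged Welch PSD over
#' frequency (excluding the 0 Hz bin; segments are mean-removed) on both
#' plateaus and returns plateau `b` over plateau `a`.
#'
#' @param rec a `recording`.
#' @param plateau_a,plateau_b plateau labels.
#' @inheritParams grid_average_psd
#' @export
total_power_ratio <- function(rec, plateau_a, plateau_b, field = "h_e",
                              window_s = 2.5, overlap = 0.5) {
  pa <- grid_average_psd(rec, plateau_a, field, window_s, overlap)
  pb <- grid_average_psd(rec, plateau_b, field, window_s, overlap)
  sum(pb$power[-1]) * pb$df / (sum(pa$power[-1]) * pa$df)
}

#' Detect burst peaks on a depletion trace
#'
#' Segments the maximal runs where the trace lies at or below `threshold`
#' ("burst peak regions"), takes the time of the deepest minimum in each
#' run (earliest on ties) as the burst peak time, and then censors short
#' inter-burst intervals: while any consecutive pair of peaks is closer
#' than `min_ibi_s`, the shallower of the two is dropped (removing
#' "double-dipping" by subsequent activity spikes within one burst).
#'
#' @param x trace (typically the effective ee PSP amplitude, mV).
#' @param times sample times (s), uniform.
#' @param threshold burst-region threshold (same units as `x`).
#' @param min_ibi_s censoring window (s).
#' @return numeric vector of retained burst peak times (s); empty if the
#'   trace never crosses the threshold.
#' @export
detect_burst_peaks <- function(x, times, threshold = 0.05, min_ibi_s = 1.0) {
  below <- x <= threshold
  if (!any(below)) return(numeric(0))
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  pk_t <- pk_v <- numeric(0)
  for (j in which(r$values)) {
    idx <- starts[j]:ends[j]
    m <- idx[which.min(x[idx])]
    pk_t <- c(pk_t, times[m]); pk_v <- c(pk_v, x[m])
  }
  while (length(pk_t) > 1) {
    gaps <- diff(pk_t)
    k <- which(gaps < min_ibi_s)[1]
    if (is.na(k)) break
    drop <- if (pk_v[k] >= pk_v[k + 1]) k else k + 1L
    pk_t <- pk_t[-drop]; pk_v <- pk_v[-drop]
  }
  pk_t
}

#' Effective ee PSP amplitude trace from a recorded efficacy field
#'
#' `Gamma_ee(x, t, c) = Gamma0_ee * C_e(x, t) * H_e(c(t))` (mV), the
#' quantity whose deep minima mark burst peaks. With
#' `mode = "normalized"` the Hill- and amplitude-scaling is omitted and the
#' bare `C_e * H_e` is returned (threshold then interpreted on that scale).
#'
#' @param rec a `recording` containing `C_e`.
#' @param cols column selection (defaults to all samples).
#' @param mode `"absolute"` (mV, default) or `"normalized"`.
#' @return matrix npts x length(cols).
#' @export
gamma_ee_trace <- function(rec, cols = NULL, mode = c("absolute",
                                                      "normalized")) {
  mode <- match.arg(mode)
  if (is.null(rec$fields$C_e)) stop("recording lacks the C_e field")
  if (is.null(cols)) cols <- seq_len(ncol(rec$fields$C_e))
  tm <- rec$times$C_e[cols]
  He <- hill_excitatory_amplitude(protocol_concentration(rec$protocol, tm))
  X <- rec$fields$C_e[, cols, drop = FALSE]
  X <- sweep(X, 2, He, "*")
  if (mode == "absolute") X <- X * unname(rec$params$Gamma0["ee"])
  X
}

#' Grid inter-burst-interval statistics
#'
#' Runs burst-peak detection on the effective ee amplitude trace of every
#' grid point over a time window and pools the retained inter-burst
#' intervals into grid statistics.
#'
#' @param rec a `recording` containing `C_e`.
#' @param window `c(from, to)` window (s); default the whole recording.
#' @param threshold burst threshold; with `mode = "absolute"` in mV
#'   (default 0.05).
#' @param min_ibi_s censoring window (s).
#' @param mode see [gamma_ee_trace()].
#' @return A list of class `burst_stats`: `mean`, `sd`, `n_ibi`, `n_bursts`,
#'   `points_bursting` (fraction of grid points with at least one detected
#'   peak), `threshold`, `min_ibi_s`, and the pooled `ibis`.
#' @export
ibi_statistics <- function(rec, window = NULL, threshold = 0.05,
                           min_ibi_s = 1.0,
                           mode = c("absolute", "normalized")) {
  mode <- match.arg(mode)
  tm <- rec$times$C_e
  if (is.null(tm)) stop("recording lacks the C_e field")
  cols <- if (is.null(window)) seq_along(tm)
          else which(tm >= window[1] - 1e-9 & tm < window[2] - 1e-9)
  X <- gamma_ee_trace(rec, cols, mode)
  tt <- tm[cols]
  ibis <- numeric(0); n_bursts <- 0L; n_pts <- 0L
  for (i in seq_len(nrow(X))) {
    pk <- detect_burst_peaks(X[i, ], tt, threshold, min_ibi_s)
    if (length(pk) > 0) n_pts <- n_pts + 1L
    n_bursts <- n_bursts + length(pk)
    if (length(pk) > 1) ibis <- c(ibis, diff(pk))
  }
  structure(list(mean = if (length(ibis)) mean(ibis) else NA_real_,
                 sd = if (length(ibis) > 1) stats::sd(ibis) else NA_real_,
                 n_ibi = length(ibis), n_bursts = n_bursts,
                 points_bursting = n_pts / nrow(X),
                 threshold = threshold, min_ibi_s = min_ibi_s,
                 ibis = ibis),
            class = "burst_stats")
}

#' Spatial autocorrelation length of a field snapshot
#'
#' Radially averaged spatial autocorrelation of a (mean-removed) snapshot on
#' the torus, computed via FFT; returns the first lag (mm) at which the
#' correlation falls below `1/e` — a characteristic pattern-size
#' diagnostic.
#'
#' @param field per-point vector.
#' @param grid a `grid_spec`.
#' @return correlation length (mm).
#' @export
correlation_length <- function(field, grid) {
  m <- matrix(field - mean(field), grid$ny, grid$nx)
  F2 <- Mod(stats::fft(m))^2
  ac <- Re(stats::fft(F2, inverse = TRUE))
  ac <- ac / ac[1, 1]
  nlag <- min(grid$nx, grid$ny) %/% 2
  prof <- numeric(nlag)
  for (l in seq_len(nlag)) # average over the two axes, both directions
    prof[l] <- mean(c(ac[1, l + 1], ac[1, grid$nx + 1 - l],
                      ac[l + 1, 1], ac[grid$ny + 1 - l, 1]))
  ix <- which(prof < exp(-1))[1]
  if (is.na(ix)) return(nlag * grid$dx)
  ix * grid$dx
}
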