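#' Circular patch override map on the torus
#'
#' Builds a per-grid-point map holding `inside` within the closed disk of
#' the given center and radius (toroidal distance) and `outside` elsewhere.
#'
#' @param grid a `grid_spec`.
#' @param center_cm patch center `c(x, y)` (cm).
#' @param radius_cm patch radius (cm).
#' @param inside,outside values of the overridden parameter.
#' @return per-point numeric vector (column-major, ny fastest).
#' @export
patch_mask <- function(grid, center_cm = c(20, 20), radius_cm = 9.6,
                       inside = 1.25, outside = 0.175) {
  stopifnot(radius_cm > 0)
  Lx <- grid$nx * grid$dx; Ly <- grid$ny * grid$dx
  if (2 * radius_cm * 10 > min(Lx, Ly))
    stop("patch does not fit the torus")
  xs <- (seq_len(grid$nx) - 1) * grid$dx
  ys <- (seq_len(grid$ny) - 1) * grid$dx
  dxv <- abs(xs - center_cm[1] * 10); dxv <- pmin(dxv, Lx - dxv)
  dyv <- abs(ys - center_cm[2] * 10); dyv <- pmin(dyv, Ly - dyv)
  d2 <- outer(dyv^2, dxv^2, "+")
  ifelse(as.numeric(d2) <= (radius_cm * 10)^2, inside, outside)
}

.point_index <- function(grid, x_mm, y_mm) {
  ix <- (as.integer(round(x_mm / grid$dx)) %% grid$nx)
  iy <- (as.integer(round(y_mm / grid$dx)) %% grid$ny)
  ix * grid$ny + iy + 1L
}

#' Patch-heterogeneity experiment
#'
#' Runs the model at fixed 0.25 mM isoflurane with the inhibitory depletion
#' factor raised inside a circular patch, and reports burst detection at
#' three probes: the patch center, a rim point one propagation scale inside
#' the patch boundary, and a point outside the patch. Raised inhibitory
#' resting amplitudes inside the patch abolish local bursting; activity from
#' the surrounding bursting tissue decays over the propagation scale, so the
#' rim sees damped "quasi-bursts" (spill-in) and the center essentially
#' nothing.
#'
#' @param grid a `grid_spec`.
#' @param p model parameters.
#' @param center_cm,radius_cm patch geometry (cm).
#' @param f_inside raised inhibitory depletion factor inside the patch.
#' @param conc isoflurane concentration (mM).
#' @param duration run length (s).
#' @param discard transient excluded from analysis (s).
#' @param seed noise seed.
#' @param threshold,min_ibi_s burst detection settings.
#' @param fs recording rate for the efficacy field (Hz).
#' @param grid_stats if `FALSE`, skip the (costly) whole-grid IBI
#'   statistics and return `NULL` in `stats`.
#' @return list with the `recording`, the probe indices, per-probe burst
#'   peak times, per-probe fluctuation amplitudes of the effective ee
#'   amplitude, and whole-grid `burst_stats`.
#' @export
run_patch_experiment <- function(grid, p = default_parameters(),
                                 center_cm = NULL, radius_cm = NULL,
                                 f_inside = 1.25, conc = 0.25,
                                 duration = 20, discard = 5, seed = 1,
                                 threshold = 0.05, min_ibi_s = 1.0,
                                 fs = 250, grid_stats = TRUE) {
  lam_mm <- unname(p$lambda["ee"])
  if (is.null(radius_cm)) radius_cm <- 4 * lam_mm / 10
  if (is.null(center_cm))
    center_cm <- c(grid$nx, grid$ny) * grid$dx / 2 / 10
  fmap <- patch_mask(grid, center_cm, radius_cm, inside = f_inside,
                     outside = unname(p$f["i"]))
  proto <- constant_protocol(conc, duration, label = "P", discard = discard)
  rec <- run_simulation(p, grid, proto,
                        record = record_spec("C_e", 0, duration, fs = fs),
                        seed = seed, f_map = list(i = fmap))
  cx <- center_cm[1] * 10; cy <- center_cm[2] * 10
  probes <- c(
    center = .point_index(grid, cx, cy),
    rim = .point_index(grid, cx + radius_cm * 10 - lam_mm, cy),
    outside = .point_index(grid, cx + min(2 * radius_cm * 10,
                                          grid$nx * grid$dx / 2 - grid$dx),
                           cy))
  tm <- rec$times$C_e
  cols <- which(tm >= discard)
  X <- gamma_ee_trace(rec, cols)
  tt <- tm[cols]
  peaks <- lapply(probes, function(i)
    detect_burst_peaks(X[i, ], tt, threshold, min_ibi_s))
  amp <- vapply(probes, function(i) diff(range(X[i, ])), numeric(1))
  outside_pts <- which(fmap == unname(p$f["i"]))
  stats_out <- if (grid_stats)
    ibi_statistics(rec, window = c(discard, duration),
                   threshold = threshold, min_ibi_s = min_ibi_s)
  list(recording = rec, probes = probes, peaks = peaks,
       fluctuation = amp, fmap = fmap, outside_points = outside_pts,
       stats = stats_out)
}

#' Connectivity-scale sweep
#'
#' Runs the model at fixed 0.25 mM for several cortico-cortical decay
#' scales `lambda` with identical noise seeds, and reports grid IBI
#' statistics and the burst-pattern correlation length per scale. Shorter
#' connectivity gives smaller, more numerous burst patterns: the mean
#' inter-burst interval decreases and its spread grows.
#'
#' @param grid a `grid_spec`.
#' @param lambdas_cm decay scales to simulate (cm).
#' @param p model parameters.
#' @param conc concentration (mM).
#' @param duration,discard run length and transient (s).
#' @param seed shared noise seed.
#' @param threshold,min_ibi_s burst detection settings.
#' @param fs recording rate (Hz).
#' @return list per lambda: `lambda_cm`, `stats` (`burst_stats`),
#'   `pattern_mm` (median snapshot correlation length).
#' @export
run_lambda_sweep <- function(grid, lambdas_cm = c(2.7, 2.4, 2.1),
                             p = default_parameters(), conc = 0.25,
                             duration = 30, discard = 5, seed = 1,
                             threshold = 0.05, min_ibi_s = 1.0, fs = 250) {
  out <- lapply(lambdas_cm, function(lam) {
    pl <- p
    pl$lambda[] <- lam * 10
    proto <- constant_protocol(conc, duration, discard = discard)
    rec <- run_simulation(pl, grid, proto,
                          record = record_spec("C_e", 0, duration, fs = fs),
                          seed = seed)
    st <- ibi_statistics(rec, window = c(discard, duration),
                         threshold = threshold, min_ibi_s = min_ibi_s)
    # pattern size from the slow efficacy field, which carries the burst
    # pattern (fast h_e snapshots are dominated by noise-scale structure)
    tm <- rec$times$C_e
    snap_cols <- which(tm >= discard)
    snap_cols <- snap_cols[seq(1, length(snap_cols), length.out = 8)]
    patt <- stats::median(vapply(snap_cols, function(j)
      correlation_length(rec$fields$C_e[, j], grid), numeric(1)))
    list(lambda_cm = lam, stats = st, pattern_mm = patt)
  })
  names(out) <- sprintf("lambda_%g", lambdas_cm)
  out
}

#' Induction-protocol experiment
#'
#' Runs the staged induction protocol, computes grid-averaged PSDs on each
#' plateau, total-power ratios relative to the resting plateau C, and burst
#' statistics per plateau.
#'
#' @param grid a `grid_spec`.
#' @param p model parameters.
#' @param seed noise seed.
#' @param through protocol truncation (see [figure2_protocol()]).
#' @param plateau_s,ramp_s protocol durations (s).
#' @param threshold,min_ibi_s burst detection settings.
#' @param fields which fields to record on the plateaus (`C_e` enables the
#'   burst statistics).
#' @param plateaus optional subset of plateau labels to record and analyze
#'   (must include `"C"`, the reference); `NULL` for all.
#' @return list with the `recording`, `psds` (per plateau), `power_ratios`
#'   (per plateau, relative to C) and `bursts` (per plateau `burst_stats`).
#' @export
run_figure2 <- function(grid, p = default_parameters(), seed = 1,
                        through = "end", plateau_s = c(10, 10, 40, 10),
                        ramp_s = c(10, 10, 10, 20), threshold = 0.05,
                        min_ibi_s = 1.0, fields = c("h_e", "C_e"),
                        plateaus = NULL) {
  proto <- figure2_protocol(through = through, plateau_s = plateau_s,
                            ramp_s = ramp_s)
  labs <- names(proto$plateaus)
  if (!is.null(plateaus)) {
    stopifnot("C" %in% plateaus)
    labs <- intersect(labs, plateaus)
    proto$plateaus <- proto$plateaus[labs]
  }
  nl <- length(labs)
  rec <- run_simulation(p, grid, proto,
                        record = record_spec(
                          rep(fields, each = nl),
                          rep(vapply(proto$plateaus, `[`, numeric(1), 1),
                              length(fields)),
                          rep(vapply(proto$plateaus, `[`, numeric(1), 2),
                              length(fields))),
                        seed = seed)
  rec <- .merge_windows(rec)
  psds <- lapply(labs, function(l) grid_average_psd(rec, l))
  names(psds) <- labs
  ratios <- vapply(labs, function(l)
    total_power_ratio(rec, "C", l), numeric(1))
  bursts <- NULL
  if ("C_e" %in% fields) {
    bursts <- lapply(labs, function(l)
      ibi_statistics(rec, window = proto$plateaus[[l]],
                     threshold = threshold, min_ibi_s = min_ibi_s))
    names(bursts) <- labs
  }
  list(recording = rec, psds = psds, power_ratios = ratios, bursts = bursts)
}

# Concatenate same-field recording windows into one matrix per field (the
# analysis functions select plateau columns by time).
.merge_windows <- function(rec) {
  base <- sub("\\.[0-9]+$", "", names(rec$fields))
  merged <- list(); times <- list()
  for (f in unique(base)) {
    ix <- which(base == f)
    ord <- order(vapply(ix, function(i) rec$times[[i]][1], numeric(1)))
    merged[[f]] <- do.call(cbind, rec$fields[ix[ord]])
    times[[f]] <- do.call(c, rec$times[ix[ord]])
  }
  rec$fields <- merged
  rec$times <- times
  rec
}
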