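#' Toroidal grid specification
#'
#' @param nx,ny numbers of grid points (>= 8).
#' @param dx grid spacing (mm).
#' @return A list of class `grid_spec`.
#' @export
grid_spec <- function(nx, ny = nx, dx = 1) {
  stopifnot(nx >= 8, ny >= 8, dx > 0)
  structure(list(nx = as.integer(nx), ny = as.integer(ny), dx = dx,
                 area_cm2 = nx * ny * dx^2 / 100),
            class = "grid_spec")
}

#' Piecewise-linear concentration protocol
#'
#' @param t0,t1 segment start/end times (s).
#' @param c0,c1 segment start/end concentrations (mM).
#' @param plateaus named list of `c(from, to)` windows (s) labelling the
#'   constant-concentration plateaus used by the analysis chain.
#' @return A list of class `protocol`.
#' @export
protocol <- function(t0, t1, c0, c1, plateaus = list()) {
  stopifnot(length(t0) == length(t1), length(c0) == length(c1),
            all(t1 > t0), all(c0 >= 0), all(c1 >= 0))
  if (length(t0) > 1)
    stopifnot(all(abs(t0[-1] - t1[-length(t1)]) < 1e-9))
  structure(list(t0 = t0, t1 = t1, c0 = c0, c1 = c1,
                 duration = t1[length(t1)], plateaus = plateaus),
            class = "protocol")
}

#' Constant-concentration protocol
#'
#' @param conc concentration (mM).
#' @param duration run length (s).
#' @param label plateau label for the analysis window (defaults to the whole
#'   run after `discard` seconds of transient).
#' @param discard transient length excluded from the labelled window (s).
#' @export
constant_protocol <- function(conc, duration, label = "P", discard = 0) {
  pl <- list()
  pl[[label]] <- c(discard, duration)
  protocol(0, duration, conc, conc, plateaus = pl)
}

#' Concentration at given times
#'
#' @param proto a `protocol`.
#' @param t_s times (s), vectorized.
#' @return concentrations (mM).
#' @export
protocol_concentration <- function(proto, t_s) {
  out <- numeric(length(t_s))
  last <- length(proto$t1)
  for (j in seq_along(proto$t0)) {
    sel <- t_s >= proto$t0[j] & (t_s < proto$t1[j] | (j == last))
    if (!any(sel)) next
    u <- (t_s[sel] - proto$t0[j]) / (proto$t1[j] - proto$t0[j])
    out[sel] <- proto$c0[j] + pmin(u, 1) * (proto$c1[j] - proto$c0[j])
  }
  out
}

#' The anesthesia induction protocol
#'
#' The staged isoflurane induction: 10 s at 0 MAC (plateau C), a 10 s ramp
#' to 0.5 MAC and 10 s there (plateau D), a 10 s ramp to 1.0 MAC and 40 s
#' there (plateau E, burst suppression), a 10 s ramp to 1.5 MAC and 10 s
#' there (plateau F, bursting abolished), then a 20 s ramp to 2.5 MAC.
#' MAC levels are converted to mM with [concentration_from_mac()].
#'
#' @param through if `"F"`, truncate after plateau F (100 s); if `"D"`,
#'   after plateau D (30 s); `"end"` runs the full 120 s.
#' @param plateau_s,ramp_s plateau and ramp durations (s); the defaults are
#'   the standard protocol.
#' @return A `protocol` with plateaus labelled C, D, E, F.
#' @export
figure2_protocol <- function(through = c("end", "F", "D"),
                             plateau_s = c(10, 10, 40, 10),
                             ramp_s = c(10, 10, 10, 20)) {
  through <- match.arg(through)
  mac <- c(0, 0.5, 1.0, 1.5, 2.5)
  cc <- concentration_from_mac(mac)
  t <- 0
  t0 <- t1 <- c0 <- c1 <- numeric(0)
  pl <- list()
  labs <- c("C", "D", "E", "F")
  for (j in 1:4) {
    t0 <- c(t0, t); t1 <- c(t1, t + plateau_s[j])
    c0 <- c(c0, cc[j]); c1 <- c(c1, cc[j])
    pl[[labs[j]]] <- c(t, t + plateau_s[j])
    t <- t + plateau_s[j]
    if (j == 2 && through == "D") break
    t0 <- c(t0, t); t1 <- c(t1, t + ramp_s[j])
    c0 <- c(c0, cc[j]); c1 <- c(c1, cc[j + 1])
    t <- t + ramp_s[j]
    if (j == 4 && through == "F") {
      t0 <- t0[-length(t0)]; t1 <- t1[-length(t1)]
      c0 <- c0[-length(c0)]; c1 <- c1[-length(c1)]
      break
    }
  }
  protocol(t0, t1, c0, c1, plateaus = pl)
}

#' Recording plan
#'
#' @param field field name (`"h_e"`, `"h_i"`, `"C_e"`, `"C_i"`, `"phi"`,
#'   `"I_ee"`), vectorized.
#' @param from,to window (s), recycled against `field`.
#' @param fs sampling rate (Hz); must divide the integration rate evenly.
#' @export
record_spec <- function(field, from, to, fs = 250) {
  data.frame(field = field, from = from, to = to, fs = fs)
}

.field_codes <- c(h_e = 0L, h_i = 1L, C_e = 2L, C_i = 3L, phi = 4L,
                  I_ee = 5L)

# per-step anesthetic scalar matrix: gamma(4), gtilde(4), gain(4)
.anesthetic_scalars <- function(p, conc) {
  nsub <- length(conc)
  He <- hill_excitatory_amplitude(conc)
  Hi <- hill_inhibitory_amplitude(conc)
  eps_i <- epsilon_from_kappa(inhibitory_decay_factor(conc))
  out <- matrix(0, nsub, 12)
  H <- list(ee = He, ei = He, ie = Hi, ii = Hi)
  epsl <- list(ee = 0, ei = 0, ie = eps_i, ii = eps_i)
  for (j in seq_along(.class_names)) {
    cl <- .class_names[j]
    rc <- rate_constants(p$delta[cl], epsl[[cl]])
    out[, j] <- rc$gamma
    out[, 4 + j] <- rc$gtilde
    out[, 8 + j] <- exp(rc$gamma * p$delta[cl]) * p$Gamma0[cl] * H[[cl]] /
      rc$gamma
  }
  out
}

.class_names <- c("ee", "ei", "ie", "ii")

#' Run a simulation under a concentration protocol
#'
#' Constructs the stationary initial state at zero anesthesia (unless a
#' state is supplied), then advances the full coupled system with the
#' forward-Euler / three-level scheme at time step `dt`, driving `p_ee` with
#' the filtered noise stream and recording the requested fields at the
#' recording rate. Fully deterministic for a fixed `seed`.
#'
#' @param p a `liley_params` object.
#' @param grid a `grid_spec`.
#' @param proto a `protocol`.
#' @param record a [record_spec()] data frame (may be empty).
#' @param noise a `noise_spec`; defaults to the standard drive built from
#'   `p`.
#' @param dt time step (ms), default 0.05.
#' @param seed RNG seed for the noise stream.
#' @param state0 optional initial `field_state` (e.g. to continue a run).
#' @param freeze_C if `TRUE`, hold the synaptic efficacies at 1, recovering
#'   the extended (non-bursting) model.
#' @param f_map optional list with per-point vectors `e` and/or `i`
#'   overriding the depletion factors pointwise (heterogeneous tissue).
#' @param progress print progress every simulated second.
#' @return A list of class `recording`: `fields` (per name, npts x nsamples
#'   matrix), `times` (s), `fs`, plus grid/protocol/params/seed metadata and
#'   the final `state`.
#' @export
run_simulation <- function(p, grid, proto, record = record_spec("h_e", 0,
                             proto$duration),
                           noise = noise_spec(mean = p$p_ext["ee"]),
                           dt = 0.05, seed = 1, state0 = NULL,
                           freeze_C = FALSE, f_map = NULL,
                           progress = FALSE) {
  stopifnot(inherits(p, "liley_params"), inherits(grid, "grid_spec"),
            inherits(proto, "protocol"))
  viol <- validate_parameters(p)
  if (length(viol) > 0)
    stop("invalid parameters: ", paste(viol, collapse = "; "))
  n <- grid$nx * grid$ny
  set.seed(seed)
  if (is.null(state0)) state0 <- construct_initial_state(p, grid)
  st <- state0
  # mutable copies (C++ updates in place)
  fields <- c("h_e", "h_i", "I_ee", "J_ee", "I_ei", "J_ei", "I_ie", "J_ie",
              "I_ii", "J_ii", "phi", "phi_prev", "C_e", "C_i")
  S <- lapply(st[fields], function(x) x + 0)
  shared_phi <- (p$lambda["ee"] == p$lambda["ei"] &&
                 p$v["ee"] == p$v["ei"])
  phi2 <- if (shared_phi) numeric(0) else S$phi + 0
  phi2_prev <- if (shared_phi) numeric(0) else S$phi_prev + 0

  gen <- noise_generator(noise, grid, dt)
  nsub <- gen$nsub
  dt_s <- dt / 1000
  nstep <- as.integer(round(proto$duration / dt_s))
  fs <- if (nrow(record) > 0) record$fs[1] else 250
  stride <- as.integer(round(1 / (fs * dt_s)))
  if (abs(stride * fs * dt_s - 1) > 1e-9)
    stop("recording rate must divide the integration rate evenly")

  recs <- list()
  if (nrow(record) > 0) for (r in seq_len(nrow(record))) {
    code <- .field_codes[record$field[r]]
    if (is.na(code)) stop("unknown recorded field: ", record$field[r])
    s0 <- as.integer(ceiling(record$from[r] / (dt_s * stride))) * stride
    s1 <- min(as.integer(round(record$to[r] / dt_s)), nstep)
    ncols <- length(seq(s0, s1 - 1, by = stride))
    recs[[r]] <- list(code = unname(code), start = s0, end = s1,
                      buf = matrix(0, n, ncols), counter = integer(1),
                      field = record$field[r])
  }

  est_mb <- sum(vapply(recs, function(r) ncol(r$buf), numeric(1))) * n *
    8 / 2^20
  if (est_mb > 500)
    message(sprintf("recording buffers: ~%.1f GB", est_mb / 1024))

  consts <- list(
    nx = grid$nx, ny = grid$ny, dt = dt, dx = grid$dx,
    tau_e = unname(p$tau["e"]), tau_i = unname(p$tau["i"]),
    hre = unname(p$h_r["e"]), hri = unname(p$h_r["i"]),
    heq = unname(p$h_eq),
    psiden = unname(abs(p$h_eq - p$h_r[c("e", "i", "e", "i")])),
    Nb = unname(p$N_beta), Na = unname(p$N_alpha),
    Smax_e = unname(p$S_max["e"]), Smax_i = unname(p$S_max["i"]),
    mu_e = unname(p$mu["e"]), mu_i = unname(p$mu["i"]),
    sigma_e = unname(p$sigma["e"]), sigma_i = unname(p$sigma["i"]),
    sig_scale = p$sigmoid_scale,
    lambda = unname(p$lambda), v = unname(p$v),
    pei = unname(p$p_ext["ei"]), pee_mean = noise$mean,
    rel_sd = noise$rel_sd,
    S0e = unname(st$S0["e"]), S0i = unname(st$S0["i"]),
    fe = if (!is.null(f_map$e)) f_map$e else unname(p$f["e"]),
    fi = if (!is.null(f_map$i)) f_map$i else unname(p$f["i"]),
    tau_rec_e = unname(p$tau_rec["e"]), tau_rec_i = unname(p$tau_rec["i"]),
    freezeC = freeze_C, record_stride = stride)

  step0 <- 0L
  next_report <- 1
  while (step0 < nstep) {
    take <- min(nsub, nstep - step0)
    t_ms <- (step0 + seq_len(take) - 1) * dt
    conc <- protocol_concentration(proto, t_ms / 1000)
    scal <- if (all(conc == conc[1]))
      matrix(.anesthetic_scalars(p, conc[1]), take, 12, byrow = TRUE)
    else .anesthetic_scalars(p, conc)
    crw <- gen$crw[seq_len(take), , drop = FALSE]
    bf_step_chunk(S$h_e, S$h_i, S$I_ee, S$J_ee, S$I_ei, S$J_ei,
                  S$I_ie, S$J_ie, S$I_ii, S$J_ii, S$phi, S$phi_prev,
                  phi2, phi2_prev, S$C_e, S$C_i,
                  gen$knots, crw, scal, consts, step0, recs)
    if (noise$rel_sd > 0) gen$advance()
    step0 <- step0 + take
    if (progress && step0 * dt_s >= next_report) {
      message(sprintf("t = %.1f s / %.1f s", step0 * dt_s, proto$duration))
      next_report <- next_report + 1
    }
  }

  out_fields <- list(); out_times <- list()
  for (r in recs) {
    nmf <- r$field
    key <- nmf
    i <- 1
    while (!is.null(out_fields[[key]])) { i <- i + 1; key <- paste0(nmf, ".", i) }
    out_fields[[key]] <- r$buf
    out_times[[key]] <- (seq(r$start, r$end - 1, by = stride)) * dt_s
  }
  final <- st
  for (nm in fields) final[[nm]] <- S[[nm]]
  structure(list(fields = out_fields, times = out_times, fs = fs,
                 grid = grid, protocol = proto, params = p, seed = seed,
                 noise = noise, dt = dt, state = final),
            class = "recording")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Tile-average downsampling of field frames
#'
#' Averages non-overlapping `tile x tile` squares of grid points, e.g.
#' 512 x 512 -> 128 x 128 for compact visualization output.
#'
#' @param field a per-point vector or npts x nframes matrix.
#' @param grid a `grid_spec` whose dimensions are divisible by `tile`.
#' @param tile tile edge length (grid points).
#' @return reduced vector or matrix.
#' @export
downsample_tiles <- function(field, grid, tile = 4) {
  if (is.matrix(field))
    return(apply(field, 2, bf_tile_average, nx = grid$nx, ny = grid$ny,
                 tile = tile))
  bf_tile_average(field, grid$nx, grid$ny, tile)
}
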