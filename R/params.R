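#' Default model parameter set
#'
#' Returns the mean-population parameter set used to obtain bursting in the
#' extended Liley field model under isoflurane, together with the slow
#' synaptic depletion/recovery parameters. All quantities are in the
#' package's internal unit system: ms, mm, mV, mM; rates in 1/ms.
#'
#' Synapse classes are indexed `lk` with `l` the pre-synaptic source and `k`
#' the post-synaptic target, ordered `ee, ei, ie, ii` throughout the package.
#'
#' @param sigmoid_scale numeric scale in the firing-rate sigmoid exponent
#'   `exp(-scale * (h - mu)/sigma)`. Default `sqrt(2)`; the literal reading
#'   `2` is available for comparison.
#' @return An object of class `liley_params`: a named list of parameters.
#' @export
default_parameters <- function(sigmoid_scale = sqrt(2)) {
  cls <- c("ee", "ei", "ie", "ii")
  p <- list(
    tau     = c(e = 65.815, i = 130.13),          # membrane decay times (ms)
    h_r     = c(e = -78.422, i = -72.959),        # resting potentials (mV)
    S_max   = c(e = 0.39535, i = 0.15439),        # max firing rates (1/ms)
    mu      = c(e = -51.656, i = -47.267),        # firing thresholds (mV)
    sigma   = c(e = 2.8669,  i = 4.3250),         # threshold spreads (mV)
    h_eq    = c(ee = -5.7891, ei = -1.6566,       # reversal potentials (mV)
                ie = -86.675, ii = -84.596),
    Gamma0  = c(ee = 0.18424, ei = 1.8771,        # PSP peak amplitudes (mV)
                ie = 1.5969,  ii = 1.0838),
    delta   = c(ee = 9.1059, ei = 1.2103,         # PSP rise times (ms)
                ie = 2.5985, ii = 9.6946),
    N_beta  = c(ee = 3410.8, ei = 2738.9,         # intracortical synapse counts
                ie = 863.89, ii = 267.92),
    N_alpha = c(ee = 3616.3, ei = 2905.1),        # cortico-cortical synapse counts
    lambda  = c(ee = 24.000, ei = 24.000),        # cortico-cortical decay scales (mm)
    v       = c(ee = 2.1042, ei = 2.1042),        # conduction velocities (mm/ms)
    p_ext   = c(ee = 9.3193, ei = 3.1563),        # extracortical input rates (1/ms)
    tau_rec = c(e = 800.00, i = 600.00),          # synaptic recovery times (ms)
    f       = c(e = 1.2500, i = 0.17500),         # synaptic depletion factors
    sigmoid_scale = sigmoid_scale
  )
  stopifnot(identical(names(p$h_eq), cls))
  class(p) <- "liley_params"
  p
}

#' Validate a model parameter set
#'
#' Checks positivity of all time constants, rates, velocities, length scales,
#' synapse counts, PSP amplitudes and rise times, positivity of the depletion
#' factors, and the ordering of reversal potentials around the resting
#' potentials (excitatory reversal above rest, inhibitory below).
#'
#' @param p a `liley_params` object.
#' @return A character vector of violation descriptions; empty if valid.
#' @export
validate_parameters <- function(p) {
  bad <- character(0)
  note <- function(msg) bad <<- c(bad, msg)
  pos_fields <- c("tau", "S_max", "sigma", "Gamma0", "delta", "N_beta",
                  "N_alpha", "lambda", "v", "p_ext", "tau_rec", "f")
  for (fld in pos_fields) {
    v <- p[[fld]]
    if (any(!is.finite(v)) || any(v <= 0)) {
      idx <- names(v)[!is.finite(v) | v <= 0]
      note(sprintf("%s[%s]: must be strictly positive",
                   fld, paste(idx, collapse = ",")))
    }
  }
  for (k in c("e", "i")) {
    if (is.finite(p$h_eq[paste0("e", k)]) && is.finite(p$h_r[k]) &&
        p$h_eq[paste0("e", k)] <= p$h_r[k])
      note(sprintf("h_eq[e%s]: excitatory reversal must exceed h_r[%s]", k, k))
    if (is.finite(p$h_eq[paste0("i", k)]) && is.finite(p$h_r[k]) &&
        p$h_eq[paste0("i", k)] >= p$h_r[k])
      note(sprintf("h_eq[i%s]: inhibitory reversal must lie below h_r[%s]", k, k))
  }
  bad
}

# Flatten a parameter set into scalar key/value pairs for the config format.
.params_flatten <- function(p) {
  out <- list()
  for (fld in setdiff(names(p), "sigmoid_scale")) {
    v <- p[[fld]]
    for (nm in names(v)) out[[paste0(fld, "_", nm)]] <- unname(v[nm])
  }
  out$sigmoid_scale <- p$sigmoid_scale
  out
}

#' Write a parameter set to a YAML config file
#'
#' The config holds one scalar key per parameter (e.g. `Gamma0_ee`), written
#' with enough digits to round-trip bit-exactly.
#'
#' @param p a `liley_params` object.
#' @param path output file path.
#' @export
write_parameters <- function(p, path) {
  flat <- .params_flatten(p)
  txt <- vapply(names(flat), function(nm)
    sprintf("%s: %s", nm, formatC(flat[[nm]], format = "g", digits = 17)),
    character(1))
  writeLines(txt, path)
  invisible(path)
}

#' Read a parameter set from a YAML config file
#'
#' Unknown keys are an error; missing keys fall back to the defaults.
#'
#' @param path config file path.
#' @return A `liley_params` object.
#' @export
read_parameters <- function(path) {
  vals <- yaml::read_yaml(path)
  p <- default_parameters()
  known <- names(.params_flatten(p))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0)
    stop("unknown parameter keys: ", paste(unknown, collapse = ", "))
  for (nm in names(vals)) {
    if (nm == "sigmoid_scale") { p$sigmoid_scale <- vals[[nm]]; next }
    parts <- regmatches(nm, regexpr("_[a-z]+$", nm))
    fld <- sub("_[a-z]+$", "", nm)
    key <- sub("^_", "", parts)
    p[[fld]][key] <- vals[[nm]]
  }
  p
}
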