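#' Default configuration for the PPS network
#'
#' Returns the full parameter set of the visuo-tactile peri-personal space
#' (PPS) network as a nested list. The shipped default (registered as
#' `"pps-default"`) was calibrated so that, with looming visual stimuli at
#' 75 cm/s, the network produces a sigmoidal dependence of decoded tactile
#' reaction time on visuo-tactile distance with a central point inside the
#' simulated range, distance-independent unisensory tactile RTs, and a
#' positive history-dependent shift of the central point at a forgetting
#' time constant of 4 s. Every value can be overridden via `...` (using
#' nested names, e.g. `hebb = list(tau_h_s = 2)`) or by editing a YAML copy
#' (see [read_pps_config()]).
#'
#' Main blocks:
#' \describe{
#'   \item{grid}{`n` neurons per side (41); tactile receptive-field spacing
#'     0.5 cm (20 x 20 cm face sheet); visual spacing 10 cm (400 x 400 cm
#'     planar space, one axis depth from the face, one lateral).}
#'   \item{neurons}{membrane time constant `tau_ms` per population,
#'     activation saturations `f_min`/`f_max`, sigmoid centre `theta` and
#'     slope `r` for tactile (t), visual (v) and multisensory (m) units.}
#'   \item{lateral}{Mexican-hat lateral kernel: excitatory/inhibitory
#'     amplitudes and Gaussian widths (in neuron-index units).}
#'   \item{feedforward}{basal feedforward weights: uniform tactile `w0_t`;
#'     visual maximum `w0_v` on the face decaying as `exp(-depth/lambda_v)`.
#'     Maxima equal the basal on-face values.}
#'   \item{feedback}{fixed feedback amplitudes `b_t`, `b_v`; the spatial
#'     pattern follows the basal feedforward maps.}
#'   \item{hebb}{learning-rate scales `rho0_t`, `rho0_v`; post-synaptic gate
#'     `gate_theta` (fraction of maximal multisensory activation, 0.05);
#'     forgetting time constant `tau_h_s` (s); update step `update_dt_ms`.}
#'   \item{stimulus}{Gaussian stimulus amplitudes and spatial spreads,
#'     tactile stimulus duration, looming start distance and velocity.}
#'   \item{sim}{integration step `dt_ms` (1 ms), decode horizon after
#'     tactile onset, inter-trial gap `iti_ms`, decode threshold `p_th`.}
#' }
#'
#' @param ... named overrides merged into the default (nested lists are
#'   merged element-wise).
#' @return A nested list of class `pps_config`.
#' @export
#' @examples
#' cfg <- pps_config(hebb = list(tau_h_s = 2))
#' cfg$hebb$tau_h_s
pps_config <- function(...) {
  cfg <- list(
    name = "pps-default",
    grid = list(
      n = 41L,
      tactile_spacing = 0.5, tactile_extent = 20,
      visual_spacing = 10,  visual_extent = 400
    ),
    neurons = list(
      tau_ms = c(t = 20, v = 20, m = 20),
      f_min  = c(t = 0,  v = 0,  m = 0),
      f_max  = c(t = 1,  v = 1,  m = 1),
      theta  = c(t = 12, v = 12, m = 12),
      r      = c(t = 1.2, v = 1.2, m = 0.35)
    ),
    lateral = list(exc_amp = 0.15, exc_sigma = 1, inh_amp = 0.05, inh_sigma = 4),
    feedforward = list(w0_t = 2, w0_v = 20, lambda_v = 60),
    feedback = list(b_t = 6, b_v = 2),
    hebb = list(rho0_t = 1.125e-3, rho0_v = 1.125e-3, gate_theta = 0.05,
                tau_h_s = 4, update_dt_ms = 1),
    stimulus = list(
      tact_amp = 20, tact_sigma = 1, tact_dur_ms = 50,
      vis_amp = 30, vis_sigma = 6,
      start_distance = 200, velocity = 75
    ),
    sim = list(dt_ms = 1, horizon_ms = 500, iti_ms = 2000, p_th = 4)
  )
  cfg <- merge_config(cfg, list(...))
  validate_config(cfg)
  structure(cfg, class = "pps_config")
}

merge_config <- function(base, overrides) {
  for (nm in names(overrides)) {
    if (is.list(base[[nm]]) && is.list(overrides[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], overrides[[nm]])
    } else if (is.numeric(base[[nm]]) && length(base[[nm]]) > 1 &&
               !is.null(names(base[[nm]])) && is.numeric(overrides[[nm]]) &&
               !is.null(names(overrides[[nm]]))) {
      base[[nm]][names(overrides[[nm]])] <- overrides[[nm]]
    } else {
      base[[nm]] <- overrides[[nm]]
    }
  }
  base
}

validate_config <- function(cfg) {
  g <- cfg$grid
  if (g$n < 3) abort("grid$n must be >= 3")
  if (g$tactile_spacing <= 0 || g$visual_spacing <= 0) {
    abort("grid spacings must be positive")
  }
  for (ext in c("tactile", "visual")) {
    got <- g[[paste0(ext, "_extent")]]
    want <- (g$n - 1) * g[[paste0(ext, "_spacing")]]
    if (abs(got - want) > 1e-8) {
      abort(sprintf("%s extent (%g) inconsistent with (n - 1) * spacing = %g",
                    ext, got, want))
    }
  }
  nr <- cfg$neurons
  if (any(nr$f_min >= nr$f_max)) abort("f_min must be < f_max")
  if (any(nr$tau_ms < 2 * cfg$sim$dt_ms)) {
    abort("membrane tau must be at least twice the Euler step for stability")
  }
  if (any(nr$r <= 0)) abort("activation slopes must be positive")
  lt <- cfg$lateral
  if (lt$exc_amp - lt$inh_amp <= 0) {
    abort("lateral kernel must be net excitatory at zero distance")
  }
  hb <- cfg$hebb
  if (hb$rho0_t < 0 || hb$rho0_v < 0) abort("rho0 must be non-negative")
  if (hb$gate_theta <= 0 || hb$gate_theta >= 1) abort("gate_theta must be in (0, 1)")
  if (hb$tau_h_s <= 0) abort("tau_h_s must be positive")
  if (cfg$stimulus$tact_sigma <= 0 || cfg$stimulus$vis_sigma <= 0) {
    abort("stimulus sigmas must be positive")
  }
  invisible(cfg)
}

#' Read or write a network configuration as YAML
#'
#' A configuration round-trips through a plain-text YAML file so that every
#' parameter of the simulator is overridable without touching code. The
#' shipped default is installed at
#' `system.file("extdata", "pps-default.yaml", package = "ppsrecal")`.
#'
#' @param path file path.
#' @return `read_pps_config()` returns a `pps_config`; `write_pps_config()`
#'   returns `path` invisibly.
#' @export
read_pps_config <- function(path) {
  raw <- yaml::read_yaml(path)
  for (blk in c("neurons")) {
    for (nm in names(raw[[blk]])) raw[[blk]][[nm]] <- unlist(raw[[blk]][[nm]])
  }
  do.call(pps_config, raw[setdiff(names(raw), "name")])
}

#' @rdname read_pps_config
#' @param cfg a `pps_config`.
#' @export
write_pps_config <- function(cfg, path) {
  # named numeric vectors must be emitted as YAML maps, not sequences
  listify <- function(x) {
    if (is.list(x)) {
      lapply(x, listify)
    } else if (is.numeric(x) && length(x) > 1 && !is.null(names(x))) {
      as.list(x)
    } else x
  }
  yaml::write_yaml(listify(unclass(cfg)), path)
  invisible(path)
}
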