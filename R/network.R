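#' Build a PPS network at rest
#'
#' Assembles the visuo-tactile network: two `n x n` unisensory sheets
#' (tactile receptive fields tiling the face at 0.5 cm; visual receptive
#' fields tiling a 400 x 400 cm planar space at 10 cm, one axis being depth
#' from the face), Mexican-hat lateral coupling within each sheet, plastic
#' feedforward weights onto a single multisensory unit, and fixed feedback
#' weights with the basal feedforward pattern. State variables start at
#' rest (`q = 0`) and the plastic weights at their basal maps.
#'
#' @param config a [pps_config()].
#' @return An object of class `pps_network`: the configuration, precomputed
#'   constant structures, and the mutable state (`q` maps, weights, clock).
#' @export
#' @examples
#' net <- build_network(pps_config())
#' range(net$state$W_v)
build_network <- function(config = pps_config()) {
  stopifnot(inherits(config, "pps_config"))
  g <- config$grid
  n <- g$n

  # tactile sheet coordinates (cm on the face), stimulus lands at the centre
  tx <- seq(0, g$tactile_extent, by = g$tactile_spacing)
  X_t <- matrix(tx, n, n)                # varies along rows
  Y_t <- matrix(tx, n, n, byrow = TRUE)

  # visual sheet: rows = depth from the face (0..extent cm), cols = lateral
  dv <- seq(0, g$visual_extent, by = g$visual_spacing)
  lv <- seq(-g$visual_extent / 2, g$visual_extent / 2, by = g$visual_spacing)
  D_v <- matrix(dv, n, n)
  L_v <- matrix(lv, n, n, byrow = TRUE)

  # separable 1-D factors of the lateral difference-of-Gaussians (index units)
  idx <- seq_len(n)
  d2 <- outer(idx, idx, function(i, j) (i - j)^2)
  Gex <- exp(-d2 / (2 * config$lateral$exc_sigma^2))
  Gin <- exp(-d2 / (2 * config$lateral$inh_sigma^2))

  ff <- config$feedforward
  W0_t <- matrix(ff$w0_t, n, n)
  W0_v <- ff$w0_v * exp(-D_v / ff$lambda_v)
  fb <- config$feedback
  B_t <- matrix(fb$b_t, n, n)
  B_v <- fb$b_v * exp(-D_v / ff$lambda_v)

  nr <- config$neurons
  hb <- config$hebb
  par <- list(
    dt = config$sim$dt_ms,
    tau_t = nr$tau_ms[["t"]], tau_v = nr$tau_ms[["v"]], tau_m = nr$tau_ms[["m"]],
    f_min = unname(nr$f_min[c("t", "v", "m")]),
    f_max = unname(nr$f_max[c("t", "v", "m")]),
    theta = unname(nr$theta[c("t", "v", "m")]),
    r     = unname(nr$r[c("t", "v", "m")]),
    Gex = Gex, Gin = Gin,
    lex = config$lateral$exc_amp, lin = config$lateral$inh_amp,
    B_t = B_t, B_v = B_v,
    W0_t = W0_t, W0_v = W0_v,
    Wmax_t = ff$w0_t, Wmax_v = ff$w0_v,
    rho0_t = hb$rho0_t, rho0_v = hb$rho0_v,
    gate_abs = hb$gate_theta * nr$f_max[["m"]],
    k_h = config$sim$dt_ms / (hb$tau_h_s * 1000),
    learn = TRUE,
    X_t = X_t, Y_t = Y_t, D_v = D_v, L_v = L_v
  )

  state <- list(
    q_t = matrix(0, n, n), q_v = matrix(0, n, n), q_m = 0,
    W_t = W0_t, W_v = W0_v, t_now = 0
  )

  structure(list(config = config, par = par, state = state),
            class = "pps_network")
}

#' @export
print.pps_network <- function(x, ...) {
  g <- x$config$grid
  cat(sprintf(
    "<pps_network> %d x %d unisensory sheets (tactile %g cm, visual %g cm spacing)\n",
    g$n, g$n, g$tactile_spacing, g$visual_spacing))
  cat(sprintf("  tau_H = %g s, t = %g ms, config '%s'\n",
              x$config$hebb$tau_h_s, x$state$t_now, x$config$name))
  invisible(x)
}

no_stim <- function() {
  list(tact_on = -1L, tact_off = -1L, tact_amp = 0, tact_sigma = 1,
       tact_x = 0, tact_y = 0,
       vis_on = -1L, vis_off = -1L, vis_amp = 0, vis_sigma = 1,
       vis_depth0 = 0, vis_vel = 0, vis_lat = 0,
       e_t_ext = NULL, e_v_ext = NULL)
}

run_block <- function(net, stim, n_steps, learn = TRUE) {
  par <- net$par
  par$learn <- learn
  out <- cpp_run_block(net$state[c("q_t", "q_v", "q_m", "W_t", "W_v")],
                       par, stim, as.integer(n_steps))
  net$state$q_t <- out$q_t
  net$state$q_v <- out$q_v
  net$state$q_m <- out$q_m
  net$state$W_t <- out$W_t
  net$state$W_v <- out$W_v
  net$state$t_now <- net$state$t_now + n_steps * net$par$dt
  list(net = net, sum_zt = as.numeric(out$sum_zt), zm = as.numeric(out$zm))
}

#' External input map of a Gaussian stimulus
#'
#' Evaluates the receptive-field-filtered input of a localized Gaussian
#' stimulus on a unisensory sheet at time `t`. A looming stimulus moves
#' along the depth axis of the visual sheet at constant velocity; a static
#' stimulus stays put. Before onset/after offset, or after a looming
#' stimulus reaches the face (contact), the map is zero. A stimulus centred
#' outside the represented space yields an all-zero map with a warning.
#'
#' @param net a `pps_network`.
#' @param modality `"tactile"` or `"visual"`.
#' @param t_ms time since stimulus schedule start, ms.
#' @param amplitude,sigma Gaussian amplitude and spatial SD (cm).
#' @param position for tactile: `c(x, y)` cm on the face (default centre).
#'   For visual: depth (cm) at `onset`, or start of the looming trajectory.
#' @param velocity looming approach speed, cm/s (0 = static).
#' @param onset,offset stimulus window, ms.
#' @return An `n x n` input map (matrix).
#' @export
external_input <- function(net, modality = c("tactile", "visual"), t_ms,
                           amplitude = NULL, sigma = NULL, position = NULL,
                           velocity = 0, onset = 0, offset = Inf) {
  modality <- match.arg(modality)
  st <- net$config$stimulus
  n <- net$config$grid$n
  if (t_ms < onset || t_ms >= offset) return(matrix(0, n, n))
  if (modality == "tactile") {
    amplitude <- amplitude %||% st$tact_amp
    sigma <- sigma %||% st$tact_sigma
    centre <- position %||% rep(net$config$grid$tactile_extent / 2, 2)
    if (centre[1] < 0 || centre[1] > net$config$grid$tactile_extent ||
        centre[2] < 0 || centre[2] > net$config$grid$tactile_extent) {
      warn("tactile stimulus outside the represented surface; zero input")
      return(matrix(0, n, n))
    }
    amplitude * exp(-((net$par$X_t - centre[1])^2 + (net$par$Y_t - centre[2])^2) /
                      (2 * sigma^2))
  } else {
    amplitude <- amplitude %||% st$vis_amp
    sigma <- sigma %||% st$vis_sigma
    depth0 <- position %||% st$start_distance
    pos <- depth0 - velocity * (t_ms - onset) / 1000
    if (pos < 0) return(matrix(0, n, n))   # contact: stimulus gone
    if (pos > net$config$grid$visual_extent) {
      warn("visual stimulus outside the represented space; zero input")
      return(matrix(0, n, n))
    }
    amplitude * exp(-((net$par$D_v - pos)^2 + net$par$L_v^2) / (2 * sigma^2))
  }
}

#' Advance the network by Euler steps under fixed input maps
#'
#' Integrates the membrane equations (explicit Euler, `dt` = 1 ms) for
#' `n_steps` steps while the given external input maps are held constant,
#' applying the Hebbian update every step unless `learn = FALSE`. Useful
#' for probing fixed points and the closed-form forgetting decay; trial
#' simulations use [run_trial()].
#'
#' @param net a `pps_network`.
#' @param e_t,e_v external input maps (matrices) added to the tactile and
#'   visual sheets; `NULL` for none.
#' @param n_steps number of 1-ms steps.
#' @param learn apply the Hebbian weight update each step?
#' @return A list: the advanced `net`, plus `sum_zt` (summed tactile
#'   activity per step) and `zm` (multisensory activity per step).
#' @export
pps_step <- function(net, e_t = NULL, e_v = NULL, n_steps = 1, learn = TRUE) {
  if (!all(is.finite(net$state$q_t)) || !all(is.finite(net$state$q_v)) ||
      !is.finite(net$state$q_m)) {
    abort("non-finite network state")
  }
  stim <- no_stim()
  if (!is.null(e_t)) stim$e_t_ext <- e_t
  if (!is.null(e_v)) stim$e_v_ext <- e_v
  out <- run_block(net, stim, n_steps, learn = learn)
  if (!all(is.finite(out$net$state$q_t)) || !is.finite(out$net$state$q_m)) {
    abort("network state became non-finite during integration")
  }
  out
}

#' One Hebbian weight update (reference form)
#'
#' The plain-R form of the plasticity rule applied each update step to the
#' feedforward weights: a reinforcement term active when both the
#' pre-synaptic unisensory neuron and the post-synaptic multisensory neuron
#' fire (the latter above a small gate), with a learning factor that
#' vanishes as weights approach their maximum, plus a forgetting term that
#' decays weights toward their basal map regardless of activity:
#' \deqn{\Delta W = \rho_0 (W_{max} - W)\, z\, (z^m - \theta)^+ - k_H (W - W(0))}
#' The C++ simulation loop applies the identical update; this function is
#' the independent reference used in tests and for closed-form reasoning.
#'
#' @param W current weight map (matrix or numeric).
#' @param W0 basal map \eqn{W(0)}.
#' @param Wmax saturation value.
#' @param z_pre pre-synaptic activity map.
#' @param z_m post-synaptic (multisensory) activity, scalar.
#' @param rho0 learning-rate scale.
#' @param gate post-synaptic gate threshold (absolute activity units).
#' @param k_h forgetting rate per update step.
#' @return Updated weights, clamped to `[0, Wmax]`.
#' @export
hebbian_step <- function(W, W0, Wmax, z_pre, z_m, rho0, gate, k_h) {
  g <- max(z_m - gate, 0)
  W <- W + rho0 * (Wmax - W) * z_pre * g - k_h * (W - W0)
  pmin(pmax(W, 0), Wmax)
}

# logistic activation, evaluated exactly as the compiled core does
# (saturations are exact outside |r (q - theta)| < 30)
act_r <- function(q, neurons, pop) {
  fmin <- neurons$f_min[[pop]]; fmax <- neurons$f_max[[pop]]
  x <- neurons$r[[pop]] * (q - neurons$theta[[pop]])
  z <- ifelse(x > 30, fmax,
              ifelse(x < -13.8, fmin, fmin + (fmax - fmin) / (1 + exp(-x))))
  if (is.matrix(q)) matrix(z, nrow(q), ncol(q)) else z
}

# plain-R replica of one Euler + Hebbian step, used as the independent
# reference the compiled loop is tested against
step_reference <- function(net, e_t = NULL, e_v = NULL) {
  p <- net$par
  nr <- net$config$neurons
  z_t <- act_r(net$state$q_t, nr, "t")
  z_v <- act_r(net$state$q_v, nr, "v")
  z_m <- act_r(net$state$q_m, nr, "m")
  lat <- function(z) {
    p$lex * (p$Gex %*% z %*% p$Gex) - p$lin * (p$Gin %*% z %*% p$Gin)
  }
  u_t <- lat(z_t) + p$B_t * z_m + if (is.null(e_t)) 0 else e_t
  u_v <- lat(z_v) + p$B_v * z_m + if (is.null(e_v)) 0 else e_v
  u_m <- sum(net$state$W_t * z_t) + sum(net$state$W_v * z_v)
  q_t <- net$state$q_t + p$dt / p$tau_t * (u_t - net$state$q_t)
  q_v <- net$state$q_v + p$dt / p$tau_v * (u_v - net$state$q_v)
  q_m <- net$state$q_m + p$dt / p$tau_m * (u_m - net$state$q_m)
  z_t <- act_r(q_t, nr, "t"); z_v <- act_r(q_v, nr, "v")
  z_m <- act_r(q_m, nr, "m")
  hb <- net$config$hebb
  W_t <- hebbian_step(net$state$W_t, p$W0_t, p$Wmax_t, z_t, z_m,
                      p$rho0_t, p$gate_abs, p$k_h)
  W_v <- hebbian_step(net$state$W_v, p$W0_v, p$Wmax_v, z_v, z_m,
                      p$rho0_v, p$gate_abs, p$k_h)
  list(q_t = q_t, q_v = q_v, q_m = q_m, W_t = W_t, W_v = W_v)
}

#' Decode a network reaction time from a tactile activity trace
#'
#' The network RT is the first time, counted from tactile stimulus onset,
#' at which the summed activity of the tactile sheet reaches the decode
#' threshold. Because single-neuron activity lies in \[0, 1\], the default
#' threshold of 4 requires an ensemble of a few tactile neurons to be
#' active. A trace that never crosses returns `NA` (timeout).
#'
#' @param trace numeric vector of summed tactile activity, one value per
#'   integration step, starting at tactile onset.
#' @param p_th decode threshold (default 4).
#' @param dt_ms step size, ms.
#' @return RT in ms, or `NA_real_` on timeout.
#' @export
#' @examples
#' decode_rt(seq(0, 10, length.out = 301), p_th = 4)
decode_rt <- function(trace, p_th = 4, dt_ms = 1) {
  if (length(trace) == 0) abort("empty activity trace")
  hit <- which(trace >= p_th)
  if (length(hit) == 0) return(NA_real_)
  hit[1] * dt_ms
}

#' Simulate one trial, carrying plastic weights
#'
#' Runs a single visuo-tactile (or unisensory tactile) trial: a looming
#' visual stimulus starts at `start_distance` and approaches at `velocity`;
#' the tactile Gaussian is delivered on the face when the visual stimulus
#' is `distance_cm` away (for unisensory trials, at the onset the same
#' disparity would imply). Integration continues for the decode horizon
#' after tactile onset and then through a stimulus-free inter-trial gap;
#' the Hebbian update (including forgetting) acts throughout, so plasticity
#' persists across consecutive calls on the same network.
#'
#' @param net a `pps_network` (state is carried in and out).
#' @param distance_cm visuo-tactile distance at tactile onset (cm), or `NA`
#'   for a unisensory tactile trial.
#' @param velocity looming speed, cm/s (default from the config).
#' @param learn apply Hebbian plasticity?
#' @param iti_ms stimulus-free gap appended after the trial, ms. The
#'   default (`NULL`) follows the behavioural timeline: the remaining
#'   time-to-contact of the looming stimulus plus the configured gap
#'   between contact and the next approach onset (`sim$iti_ms`).
#' @return A list: `rt_ms` (NA on timeout), `timeout` flag, and the
#'   advanced `net`.
#' @export
run_trial <- function(net, distance_cm, velocity = NULL, learn = TRUE,
                      iti_ms = NULL) {
  cfg <- net$config
  st <- cfg$stimulus
  sim <- cfg$sim
  velocity <- velocity %||% st$velocity
  dt <- sim$dt_ms

  unisensory <- is.na(distance_cm)
  # tactile onset: time for the looming stimulus to reach distance_cm
  ref_d <- if (unisensory) mean(c(55.25, 175.25)) else distance_cm
  tact_on_ms <- (st$start_distance - ref_d) / velocity * 1000
  if (tact_on_ms < 0) abort("distance exceeds the looming start distance")
  n_trial <- ceiling((tact_on_ms + sim$horizon_ms) / dt)
  tact_on <- as.integer(round(tact_on_ms / dt))

  stim <- no_stim()
  stim$tact_on <- tact_on
  stim$tact_off <- as.integer(tact_on + round(st$tact_dur_ms / dt))
  stim$tact_amp <- st$tact_amp
  stim$tact_sigma <- st$tact_sigma
  stim$tact_x <- cfg$grid$tactile_extent / 2
  stim$tact_y <- cfg$grid$tactile_extent / 2
  if (!unisensory) {
    stim$vis_on <- 0L
    stim$vis_off <- as.integer(n_trial)
    stim$vis_amp <- st$vis_amp
    stim$vis_sigma <- st$vis_sigma
    stim$vis_depth0 <- st$start_distance
    stim$vis_vel <- velocity
  }

  out <- run_block(net, stim, n_trial, learn = learn)
  trace <- out$sum_zt[(tact_on + 1):n_trial]
  rt <- decode_rt(trace, p_th = sim$p_th, dt_ms = dt)

  # forgetting follows the experiment's clock: after the decode horizon the
  # looming stimulus would still need (time-to-contact - horizon) to reach
  # the face, and the configured inter-trial gap runs from contact to the
  # next approach onset
  ttc_ms <- ref_d / velocity * 1000
  if (is.null(iti_ms)) {
    iti_ms <- sim$iti_ms + max(0, ttc_ms - sim$horizon_ms)
  }

  net <- out$net
  if (iti_ms > 0) {
    # integrate the first part of the gap dynamically (activity decays to
    # numerical rest within ~15 membrane time constants), then apply the
    # remaining forgetting in closed form: with no supra-threshold activity
    # the discrete update is exactly (W - W0) <- (1 - k_H)^n (W - W0)
    dyn_ms <- min(iti_ms, 300)
    net <- run_block(net, no_stim(), ceiling(dyn_ms / dt), learn = learn)$net
    rest <- round((iti_ms - dyn_ms) / dt)
    if (rest > 0) {
      if (learn && net$par$k_h > 0) {
        f <- (1 - net$par$k_h)^rest
        net$state$W_t <- net$par$W0_t + (net$state$W_t - net$par$W0_t) * f
        net$state$W_v <- net$par$W0_v + (net$state$W_v - net$par$W0_v) * f
      }
      net$state$q_t <- net$state$q_t * (1 - dt / net$par$tau_t)^rest
      net$state$q_v <- net$state$q_v * (1 - dt / net$par$tau_v)^rest
      net$state$q_m <- net$state$q_m * (1 - dt / net$par$tau_m)^rest
      net$state$t_now <- net$state$t_now + rest * dt
    }
  }
  list(rt_ms = rt, timeout = is.na(rt), net = net)
}

#' Permuted session schedule for network simulations
#'
#' Builds the per-trial condition order for a simulated session: `n_reps`
#' repetitions of each multisensory disparity plus (optionally) `n_reps`
#' unisensory tactile trials, permuted with the given seed so that
#' parameter sweeps can reuse one identical order. The default is blocked
#' randomisation (each condition once per shuffled block, `n_reps` blocks),
#' the standard psychophysical scheme; it balances how often each
#' disparity is preceded by each other disparity, which matters because
#' the serial-dependence analysis conditions on exactly those transitions.
#' `method = "full"` draws one unconstrained permutation instead.
#'
#' @param distances_cm visuo-tactile distances at tactile onset (cm);
#'   default: the six disparities of the looming psychophysics design.
#' @param n_reps trials per condition (default 20).
#' @param unisensory include a unisensory tactile condition?
#' @param seed integer seed fixing the permutation.
#' @param method `"blocked"` (default) or `"full"` randomisation.
#' @return A tibble with `trial_index`, `modality` (`"VT"`/`"T"`),
#'   `distance_cm` (`NA` for unisensory).
#' @export
session_schedule <- function(distances_cm = exp1_distances(), n_reps = 20,
                             unisensory = TRUE, seed = 1,
                             method = c("blocked", "full")) {
  method <- match.arg(method)
  conds <- c(distances_cm, if (unisensory) NA_real_)
  old <- .Random.seed_save()
  set.seed(seed)
  trials <- if (method == "blocked") {
    unlist(lapply(seq_len(n_reps), function(b) sample(conds)))
  } else {
    sample(rep(conds, each = n_reps))
  }
  .Random.seed_restore(old)
  tibble(
    trial_index = seq_along(trials),
    modality = ifelse(is.na(trials), "T", "VT"),
    distance_cm = trials
  )
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    # no prior state: put the generator kind back to the session default
    # (set.seed(kind = ) changes it globally) and drop the seed
    suppressWarnings(RNGkind("default", "default", "default"))
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

#' Run a simulated session with plasticity carried across trials
#'
#' Iterates [run_trial()] over a permuted schedule, carrying the plastic
#' feedforward weights (and the forgetting clock) continuously across
#' trials and inter-trial gaps. Each trial is labelled by the disparity of
#' the immediately preceding trial (`smaller` / `larger` / `excluded`,
#' following the serial-dependence splitting rules; see
#' [split_by_history()]).
#'
#' @param config a [pps_config()]; `tau_h_s` and the stimulus block control
#'   the forgetting time constant and looming parameters.
#' @param schedule a schedule from [session_schedule()], or `NULL` to build
#'   one from `seed`.
#' @param seed permutation seed (used only when `schedule` is `NULL`).
#' @param velocity looming speed override, cm/s.
#' @param n_reps trials per condition when building the default schedule.
#' @return A tibble of simulated trials: `trial_index`, `modality`,
#'   `distance_cm`, `rt_ms`, `timeout`, `history`, plus `tau_h_s`,
#'   `velocity` and `seed` as metadata columns.
#' @export
run_session <- function(config = pps_config(), schedule = NULL, seed = 1,
                        velocity = NULL, n_reps = 20) {
  velocity <- velocity %||% config$stimulus$velocity
  if (is.null(schedule)) {
    schedule <- session_schedule(n_reps = n_reps, seed = seed)
  }
  net <- build_network(config)
  rts <- numeric(nrow(schedule))
  tmo <- logical(nrow(schedule))
  for (i in seq_len(nrow(schedule))) {
    res <- run_trial(net, schedule$distance_cm[i], velocity = velocity)
    rts[i] <- res$rt_ms
    tmo[i] <- res$timeout
    net <- res$net
  }
  out <- schedule
  out$rt_ms <- rts
  out$timeout <- tmo
  out$history <- history_labels(out$distance_cm)
  out$tau_h_s <- config$hebb$tau_h_s
  out$velocity <- velocity
  out$seed <- seed
  out
}

# history labels for a numeric disparity sequence (NA = no-disparity trial)
history_labels <- function(d) {
  k <- length(d)
  lab <- rep("excluded", k)
  if (k < 2) return(lab)
  prev <- c(NA, d[-k])
  lv <- sort(unique(d[!is.na(d)]))
  interior <- !is.na(d) & d > lv[1] & d < lv[length(lv)]
  ok <- interior & !is.na(prev) & prev != d
  lab[ok & prev < d] <- "smaller"
  lab[ok & prev > d] <- "larger"
  lab[1] <- "excluded"
  lab
}

#' Fit history-split sigmoids to a simulated (or behavioural) RT session
#'
#' Averages multisensory RTs by distance within each history split and fits
#' the four-parameter sigmoid, returning the fitted central points and the
#' rapid-recalibration index (central point after larger-disparity trials
#' minus after smaller-disparity trials).
#'
#' @param session a trial tibble with `modality`, `distance_cm`, `rt_ms`,
#'   `history` columns (e.g. from [run_session()]).
#' @return A list: `fit_pooled`, `fit_smaller`, `fit_larger`
#'   ([fit_pps_sigmoid()] objects), `dxc` (the recalibration index, cm),
#'   `timeouts` (count of timed-out trials).
#' @export
session_recalibration <- function(session) {
  vt <- dplyr::filter(session, .data$modality == "VT", !is.na(.data$rt_ms))
  fit1 <- function(df) {
    m <- df |>
      group_by(.data$distance_cm) |>
      summarise(rt = mean(.data$rt_ms), .groups = "drop")
    if (nrow(m) < 4) {
      # a split can miss a level entirely (permutation luck, timeouts);
      # return a flagged fit, as for non-convergence
      return(structure(
        list(coefficients = c(y_min = NA_real_, y_max = NA_real_,
                              x_c = NA_real_, b = NA_real_),
             r2 = -Inf, converged = FALSE, n = nrow(m),
             data = tibble(x = m$distance_cm, y = m$rt, fitted = NA_real_)),
        class = "pps_sigmoid_fit"))
    }
    fit_sigmoid_xy(m$distance_cm, m$rt)
  }
  fp <- fit1(vt)
  fs <- fit1(dplyr::filter(vt, .data$history == "smaller"))
  fl <- fit1(dplyr::filter(vt, .data$history == "larger"))
  list(
    fit_pooled = fp, fit_smaller = fs, fit_larger = fl,
    dxc = recalibration_index(fl, fs),
    timeouts = sum(session$timeout)
  )
}

#' Sensitivity of rapid recalibration to the forgetting time constant
#'
#' Re-runs one fixed permuted session at each forgetting time constant and
#' summarises, per value: the recalibration index (central point shift,
#' cm), the pooled central point, and the distance effect (range of mean
#' multisensory RT across disparities, ms) together with a flat-PPS flag
#' (distance effect below `flat_tol_ms`).
#'
#' @param tau_values forgetting time constants, s.
#' @param config base configuration.
#' @param seed permutation seed; the identical schedule is reused across
#'   `tau_values` so runs are comparable.
#' @param n_reps trials per condition.
#' @param flat_tol_ms distance-effect tolerance below which PPS is flagged
#'   flat (default 5 ms of network time).
#' @return A tibble: `tau_h_s`, `dxc_cm`, `xc_pooled`, `distance_effect_ms`,
#'   `flat_pps`, `timeouts`.
#' @export
sweep_tau <- function(tau_values = c(1, 2, 4, 6, 8, 10),
                      config = pps_config(), seed = 1, n_reps = 20,
                      flat_tol_ms = 5) {
  schedule <- session_schedule(n_reps = n_reps, seed = seed)
  purrr::map_dfr(tau_values, function(th) {
    cfg <- merge_config(config, list(hebb = list(tau_h_s = th)))
    class(cfg) <- "pps_config"
    ses <- run_session(cfg, schedule = schedule, seed = seed)
    summarise_session(ses, flat_tol_ms = flat_tol_ms)
  })
}

summarise_session <- function(ses, flat_tol_ms = 5) {
  rec <- session_recalibration(ses)
  # distance effect over the second half of the session, once plasticity
  # has reached its steady state (the first half carries the burn-in of
  # the weight dynamics, which matters for slow forgetting time constants)
  vt <- dplyr::filter(ses, .data$modality == "VT", !is.na(.data$rt_ms),
                      .data$trial_index > max(ses$trial_index) / 2)
  mm <- vt |>
    group_by(.data$distance_cm) |>
    summarise(rt = mean(.data$rt_ms), .groups = "drop")
  de <- diff(range(mm$rt))
  tibble(
    tau_h_s = ses$tau_h_s[1], velocity = ses$velocity[1], seed = ses$seed[1],
    dxc_cm = rec$dxc,
    xc_pooled = unname(coef(rec$fit_pooled)["x_c"]),
    xc_smaller = unname(coef(rec$fit_smaller)["x_c"]),
    xc_larger = unname(coef(rec$fit_larger)["x_c"]),
    distance_effect_ms = de,
    flat_pps = de < flat_tol_ms,
    timeouts = rec$timeouts
  )
}

#' Rapid recalibration across looming velocities
#'
#' Runs one session per approach velocity at a fixed forgetting time
#' constant and summarises the pooled central point and the recalibration
#' index per velocity.
#'
#' @param velocities looming speeds, cm/s.
#' @param config base configuration (its `tau_h_s` is kept; default 4 s).
#' @param seed permutation seed shared across velocities.
#' @param n_reps trials per condition.
#' @return A tibble as in [sweep_tau()] with a `velocity` column.
#' @export
sweep_velocity <- function(velocities = c(25, 50, 75, 100),
                           config = pps_config(), seed = 1, n_reps = 20) {
  schedule <- session_schedule(n_reps = n_reps, seed = seed)
  purrr::map_dfr(velocities, function(v) {
    ses <- run_session(config, schedule = schedule, seed = seed, velocity = v)
    summarise_session(ses)
  })
}

#' Write a simulated RT table as delimited text
#'
#' @param session tibble from [run_session()].
#' @param path output path (tab-separated, with header).
#' @export
write_session <- function(session, path) {
  utils::write.table(session, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
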