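#' Visuo-tactile distances of the looming design
#'
#' The six disparities probed by the looming psychophysics design, in cm
#' at tactile onset (nearest to farthest).
#'
#' @return Numeric vector of six distances, cm.
#' @export
exp1_distances <- function() {
  sch <- exp1_timing()
  sort(sch$distance_cm)
}

# offsets -> distances for the looming design
exp1_timing <- function(start_distance = 200, velocity = 75,
                        fixation_s = 1.2, motion_delay_s = 0.3) {
  offsets <- c(1.83, 2.15, 2.47, 2.79, 3.11, 3.43)
  motion_onset <- fixation_s + motion_delay_s
  if (any(offsets <= motion_onset)) {
    abort("tactile offset earlier than visual motion onset")
  }
  travel <- offsets - motion_onset
  distance <- start_distance - velocity * travel
  tibble(
    offset_s = offsets,
    # nearest distance = longest offset: D1 is the latest tactile onset
    distance_index = rev(seq_along(offsets)),
    distance_cm = distance,
    ttc_ms = distance / velocity * 1000
  )
}

#' Trial schedule of the looming (augmented-reality) session
#'
#' Builds one session of the looming visuo-tactile design: 36 multisensory
#' trials at each of six disparities, 36 visual catch trials, and 8
#' unisensory tactile trials at each of the six equivalent temporal
#' offsets (300 trials in total), in seeded random order with a fixed
#' 500 ms inter-trial interval. Tactile onsets are staggered relative to
#' trial start; because the visual stimulus looms at constant velocity
#' from 200 cm (motion starting 0.3 s after a 1.2 s fixation), the
#' temporal offsets map linearly and negatively onto visuo-tactile
#' distance, and each experimental trial also carries its time-to-contact.
#'
#' @param seed integer seed fixing the trial order.
#' @return A tibble: `trial_index`, `modality` (`VT`/`T`/`V`),
#'   `distance_index` (`NA` for catch), `offset_s`, `distance_cm`,
#'   `ttc_ms`, `rt` (`NA`, to be filled by a generator), `iti_ms`.
#' @export
#' @examples
#' sch <- exp1_schedule(seed = 1)
#' nrow(sch)      # 300
exp1_schedule <- function(seed = 1) {
  tim <- exp1_timing()
  vt <- tim[rep(seq_len(nrow(tim)), each = 36), ]
  vt$modality <- "VT"
  tac <- tim[rep(seq_len(nrow(tim)), each = 8), ]
  tac$modality <- "T"
  catch <- tibble(offset_s = NA_real_, distance_index = NA_integer_,
                  distance_cm = NA_real_, ttc_ms = NA_real_,
                  modality = rep("V", 36))
  trials <- bind_rows(vt, tac, catch)
  old <- .Random.seed_save()
  set.seed(seed)
  trials <- trials[sample(nrow(trials)), ]
  .Random.seed_restore(old)
  trials$trial_index <- seq_len(nrow(trials))
  trials$rt <- NA_real_
  trials$iti_ms <- 500
  dplyr::relocate(as_tibble(trials), "trial_index", "modality",
                  "distance_index")
}

#' Trial schedule of the static-LED session
#'
#' Builds the static visuo-tactile design used for EEG: per block, 40
#' multisensory (VT) trials at each of seven distances, 10 visual-only
#' trials at each of the five interior distances, and 30 tactile-only
#' trials (360 trials/block), randomised within block, with inter-trial
#' intervals drawn uniformly between 1250 and 2250 ms.
#'
#' @param blocks number of blocks (0 gives an empty schedule).
#' @param seed integer seed.
#' @return A tibble: `block`, `trial_index`, `modality`,
#'   `distance_index`, `distance_cm`, `rt`, `iti_ms`.
#' @export
#' @examples
#' nrow(exp2_schedule(blocks = 1))   # 360
exp2_schedule <- function(blocks = 10, seed = 1) {
  dist_cm <- c(3.3, 13.2, 23.1, 33.0, 42.9, 52.8, 62.9)
  empty <- tibble(block = integer(), trial_index = integer(),
                  modality = character(), distance_index = integer(),
                  distance_cm = numeric(), rt = numeric(), iti_ms = numeric())
  if (blocks < 1) return(empty)
  one_block <- bind_rows(
    tibble(modality = "VT",
           distance_index = rep(1:7, each = 40)),
    tibble(modality = "V",
           distance_index = rep(2:6, each = 10)),
    tibble(modality = "T",
           distance_index = rep(NA_integer_, 30))
  )
  old <- .Random.seed_save()
  set.seed(seed)
  out <- purrr::map_dfr(seq_len(blocks), function(b) {
    blk <- one_block[sample(nrow(one_block)), ]
    blk$block <- b
    blk$iti_ms <- runif(nrow(blk), 1250, 2250)
    blk
  })
  .Random.seed_restore(old)
  out$trial_index <- seq_len(nrow(out))
  out$distance_cm <- dist_cm[out$distance_index]
  out$rt <- NA_real_
  dplyr::relocate(out, "block", "trial_index", "modality", "distance_index",
                  "distance_cm")
}

#' Generate reaction times with a history-dependent sigmoid
#'
#' Fills a schedule with synthetic RTs whose structure matches what the
#' sigmoid/history analyses assume: multisensory RTs follow
#' [pps_sigmoid()] in distance index, with the central point displaced by
#' `+delta/2` when the previous trial probed a larger disparity and
#' `-delta/2` when smaller (so the pooled sigmoid sits between the two
#' splits); unisensory tactile RTs are distance-independent with a slower
#' mean; visual catch trials draw no response. Noise is multiplicative
#' around the condition mean — gamma by default (shape `1/cv^2`, so the
#' coefficient of variation is `cv`), lognormal or none as alternatives.
#'
#' @param schedule a schedule from [exp1_schedule()] or [exp2_schedule()]
#'   (any tibble with `trial_index`, `modality`, `distance_index`).
#' @param y_min,y_max,x_c,b generating sigmoid (ms; `x` in distance-index
#'   units).
#' @param delta history shift of the central point, in distance levels.
#' @param t_mean mean unisensory tactile RT, ms.
#' @param noise `"gamma"`, `"lognormal"` or `"none"`.
#' @param cv coefficient of variation of the RT noise (default 0.2).
#' @param seed integer seed; generation is bit-reproducible given the seed.
#' @return The schedule with its `rt` column filled (ms; `NA` for catch
#'   trials) and a `history` column (labels from [split_by_history()]).
#' @export
generate_rts <- function(schedule, y_min = 260, y_max = 320, x_c = 3.5,
                         b = 0.8, delta = 0, t_mean = 330,
                         noise = c("gamma", "lognormal", "none"), cv = 0.2,
                         seed = 1) {
  noise <- match.arg(noise)
  if (nrow(schedule) == 0) abort("empty schedule")
  trials <- split_by_history(schedule)
  shift <- dplyr::case_when(
    trials$history == "larger" ~ delta / 2,
    trials$history == "smaller" ~ -delta / 2,
    TRUE ~ 0
  )
  mu <- dplyr::case_when(
    trials$modality == "VT" ~ pps_sigmoid(trials$distance_index, y_min, y_max,
                                          x_c + shift, b),
    trials$modality == "T" ~ t_mean,
    TRUE ~ NA_real_
  )
  old <- .Random.seed_save()
  # generators draw from an L'Ecuyer stream so that a seed shared with a
  # schedule permutation (Mersenne-Twister) never yields correlated draws
  set.seed(seed, kind = "L'Ecuyer-CMRG")
  mu_draw <- ifelse(is.na(mu), 1, mu)   # one draw per trial, NA'd below
  rt <- switch(noise,
    none = mu,
    gamma = {
      shape <- 1 / cv^2
      rgamma(length(mu_draw), shape = shape, scale = mu_draw / shape)
    },
    lognormal = {
      sdl <- sqrt(log(1 + cv^2))
      rlnorm(length(mu_draw), meanlog = log(mu_draw) - sdl^2 / 2, sdlog = sdl)
    })
  rt[is.na(mu)] <- NA_real_
  .Random.seed_restore(old)
  trials$rt <- rt
  trials
}

# quasi-uniform channel positions on the upper unit hemisphere
fibonacci_montage <- function(n_channels) {
  i <- seq_len(n_channels) - 0.5
  z <- i / n_channels            # upper hemisphere
  phi <- pi * (1 + sqrt(5)) * i
  r <- sqrt(1 - z^2)
  tibble(channel = seq_len(n_channels),
         x = r * cos(phi), y = r * sin(phi), z = z)
}

# canonical evoked waveform: early sensory deflection + main component
evoked_waveform <- function(times, peak_ms = 141, width_ms = 22) {
  0.5 * exp(-(times - 85)^2 / (2 * 12^2)) +
    exp(-(times - peak_ms)^2 / (2 * width_ms^2)) -
    0.4 * exp(-(times - 250)^2 / (2 * 40^2))
}

# unisensory channel topographies on a montage (zero-mean across channels)
eeg_topographies <- function(chanlocs) {
  v <- chanlocs$y * (1 - chanlocs$z)          # posterior-positive dipole
  t <- exp(-((chanlocs$x)^2 + (chanlocs$y - 0.2)^2 +
               (chanlocs$z - 1)^2) / 0.5)     # centro-parietal bump
  list(v = v - mean(v), t = t - mean(t))
}

#' Multisensory gain profile of the EEG generator
#'
#' The generating gain applied to the visuo-tactile response inside the
#' gain window: it decreases linearly from `gain_near` at the nearest
#' interior distance to 1 at the farthest, and is raised by `hist_boost`
#' after larger-disparity trials at the middle distances (3 and 4), where
#' the recalibration effect is expressed.
#'
#' @param distance_index distance level(s).
#' @param history `"smaller"` or `"larger"`.
#' @param gain_near gain at the nearest interior distance (default 1.4).
#' @param hist_boost additive gain after larger-disparity history at the
#'   middle distances (default 0.15).
#' @param middle distance levels carrying the history effect.
#' @return Numeric gain(s), all `>= 0`.
#' @export
eeg_gain <- function(distance_index, history = "smaller", gain_near = 1.4,
                     hist_boost = 0.15, middle = c(3, 4)) {
  g <- 1 + (gain_near - 1) * (6 - distance_index) / 4
  g <- g + ifelse(history == "larger" & distance_index %in% middle,
                  hist_boost, 0)
  if (any(g < 0)) abort("negative multisensory gain")
  g
}

#' Generate epoched multichannel evoked responses
#'
#' Synthesises one subject's epochs with the structure the GFP analyses
#' assume: unisensory visual and tactile responses are fixed channel
#' topographies carrying a canonical evoked waveform plus white sensor
#' noise; paired visuo-tactile responses are the sum of the two
#' unisensory patterns, multiplied inside the gain window (default
#' 124-158 ms) by a distance- and history-graded gain (see [eeg_gain()])
#' and exactly additive outside it. With `gain_near = 1` and
#' `hist_boost = 0` the paired response reduces to the additive model.
#' The generator does not attempt realistic EEG spectra or artifacts;
#' noise is white across samples and channels.
#'
#' @param n_channels montage size (default 128).
#' @param n_trials trials per condition cell.
#' @param distances distance levels of the VT conditions.
#' @param histories history labels crossed with distance for VT trials.
#' @param times epoch time axis, ms (default -200..800 at 1000 Hz).
#' @param gain_window ms window carrying the multisensory gain.
#' @param gain_near,hist_boost see [eeg_gain()].
#' @param amp_uV peak amplitude of the unisensory components, microvolts.
#' @param noise_uV white-noise SD per sample, microvolts.
#' @param seed integer seed.
#' @return An [eeg_epochs()] with `modality`, `distance_index`, `history`
#'   labels and a Fibonacci-hemisphere montage.
#' @export
generate_eeg <- function(n_channels = 128, n_trials = 20, distances = 2:6,
                         histories = c("smaller", "larger"),
                         times = seq(-200, 800), gain_window = c(124, 158),
                         gain_near = 1.4, hist_boost = 0.15, amp_uV = 3,
                         noise_uV = 2, seed = 1) {
  chanlocs <- fibonacci_montage(n_channels)
  topo <- eeg_topographies(chanlocs)
  w <- evoked_waveform(times) * (times > 0)
  resp_v <- amp_uV * outer(topo$v, w)
  resp_t <- amp_uV * outer(topo$t, w)
  in_win <- times >= gain_window[1] & times <= gain_window[2]

  conds <- bind_rows(
    tibble(modality = "V", distance_index = NA_integer_,
           history = NA_character_),
    tibble(modality = "T", distance_index = NA_integer_,
           history = NA_character_),
    tidyr::expand_grid(modality = "VT", distance_index = as.integer(distances),
                       history = histories)
  )
  labels <- conds[rep(seq_len(nrow(conds)), each = n_trials), ]

  clean <- function(row) {
    if (row$modality == "V") return(resp_v)
    if (row$modality == "T") return(resp_t)
    g <- eeg_gain(row$distance_index, row$history, gain_near, hist_boost)
    s <- resp_v + resp_t
    s[, in_win] <- s[, in_win] * g
    s
  }

  old <- .Random.seed_save()
  set.seed(seed, kind = "L'Ecuyer-CMRG")
  v <- array(0, c(n_channels, length(times), nrow(labels)))
  for (i in seq_len(nrow(labels))) {
    v[, , i] <- clean(labels[i, ]) +
      matrix(rnorm(n_channels * length(times), sd = noise_uV),
             n_channels, length(times))
  }
  .Random.seed_restore(old)
  eeg_epochs(v, times, labels, chanlocs = chanlocs)
}

#' Per-subject condition-average evoked responses (fast path)
#'
#' Generates, for a whole group of subjects, the *trial-averaged* evoked
#' response per condition directly (noise SD scaled by
#' `1/sqrt(n_trials)`), which is what the group-level GFP statistics
#' consume. Statistically equivalent to averaging [generate_eeg()] epochs
#' but orders of magnitude cheaper, so null calibrations with hundreds of
#' replicates stay tractable.
#'
#' @inheritParams generate_eeg
#' @param n_subjects number of subjects.
#' @param subject_sd between-subject SD of the component amplitude scale.
#' @return A tibble with one row per subject x condition, holding list
#'   columns `avg` (`channels x time` matrices); plus attributes `times`,
#'   `chanlocs`.
#' @export
generate_evoked_study <- function(n_subjects = 20, n_channels = 64,
                                  n_trials = 40, distances = 2:6,
                                  histories = c("smaller", "larger"),
                                  times = seq(-200, 800),
                                  gain_window = c(124, 158), gain_near = 1.4,
                                  hist_boost = 0.15, amp_uV = 3,
                                  noise_uV = 2, subject_sd = 0.1, seed = 1) {
  chanlocs <- fibonacci_montage(n_channels)
  topo <- eeg_topographies(chanlocs)
  w <- evoked_waveform(times) * (times > 0)
  in_win <- times >= gain_window[1] & times <= gain_window[2]
  conds <- bind_rows(
    tibble(modality = "V", distance_index = NA_integer_,
           history = NA_character_),
    tibble(modality = "T", distance_index = NA_integer_,
           history = NA_character_),
    tidyr::expand_grid(modality = "VT", distance_index = as.integer(distances),
                       history = histories)
  )
  sd_avg <- noise_uV / sqrt(n_trials)
  old <- .Random.seed_save()
  set.seed(seed, kind = "L'Ecuyer-CMRG")
  out <- purrr::map_dfr(seq_len(n_subjects), function(subj) {
    scale_s <- 1 + rnorm(1, sd = subject_sd)
    resp_v <- scale_s * amp_uV * outer(topo$v, w)
    resp_t <- scale_s * amp_uV * outer(topo$t, w)
    rows <- conds
    rows$subject <- subj
    rows$avg <- purrr::pmap(conds, function(modality, distance_index, history) {
      base <- switch(modality, V = resp_v, T = resp_t, VT = {
        g <- eeg_gain(distance_index, history, gain_near, hist_boost)
        s <- resp_v + resp_t
        s[, in_win] <- s[, in_win] * g
        s
      })
      base + matrix(rnorm(n_channels * length(times), sd = sd_avg),
                    n_channels, length(times))
    })
    rows
  })
  .Random.seed_restore(old)
  attr(out, "times") <- times
  attr(out, "chanlocs") <- chanlocs
  out
}
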