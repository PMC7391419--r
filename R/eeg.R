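#' Epoched multichannel EEG container
#'
#' A light container for epoched EEG: a `channels x time x trials` voltage
#' array (microvolts), the time axis in ms relative to stimulus onset, a
#' per-trial label table, optional unit-sphere channel positions, and a
#' list of bad channels to be reconstructed.
#'
#' @param voltages numeric array, `channels x time x trials` (microvolts).
#' @param times numeric vector of sample times, ms (length = `dim[2]`);
#'   must include a prestimulus baseline (negative times).
#' @param labels tibble with one row per trial (columns such as `modality`,
#'   `distance_index`, `history`); row count must equal `dim[3]`.
#' @param chanlocs optional tibble of channel positions with columns
#'   `channel`, `x`, `y`, `z` (unit sphere).
#' @param sfreq sampling rate, Hz.
#' @param bad_channels integer indices of channels to reconstruct.
#' @return An object of class `eeg_epochs`.
#' @export
eeg_epochs <- function(voltages, times, labels, chanlocs = NULL,
                       sfreq = 1000, bad_channels = integer()) {
  stopifnot(is.array(voltages), length(dim(voltages)) == 3)
  if (length(times) != dim(voltages)[2]) {
    abort("times must match the second dimension of voltages")
  }
  if (nrow(labels) != dim(voltages)[3]) {
    abort("labels must have one row per trial")
  }
  if (min(times) >= 0) abort("time axis must include a prestimulus baseline")
  structure(list(voltages = voltages, times = times,
                 labels = as_tibble(labels), chanlocs = chanlocs,
                 sfreq = sfreq, bad_channels = as.integer(bad_channels)),
            class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$voltages)
  cat(sprintf("<eeg_epochs> %d channels x %d samples x %d trials (%g Hz, %g..%g ms)\n",
              d[1], d[2], d[3], x$sfreq, min(x$times), max(x$times)))
  if (length(x$bad_channels)) {
    cat("  bad channels:", paste(x$bad_channels, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Read/write an epoch container
#'
#' Run-time serialisation helpers for `eeg_epochs` objects (RDS).
#'
#' @param x an `eeg_epochs`.
#' @param path file path.
#' @export
write_epochs <- function(x, path) {
  stopifnot(inherits(x, "eeg_epochs"))
  saveRDS(x, path)
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  x <- readRDS(path)
  if (!inherits(x, "eeg_epochs")) abort("file does not hold an eeg_epochs object")
  x
}

#' Preprocess epoched EEG
#'
#' The standard chain applied before GFP analysis, assuming the continuous
#' recording was already band-pass/notch filtered: (1) reject every trial
#' in which any good channel exceeds `reject_uv` microvolts in absolute
#' value; (2) reconstruct bad channels by inverse-distance-weighted
#' interpolation from the `k` nearest good channels on the unit sphere
#' (spherical-spline interpolation would be the exact alternative); (3)
#' subtract each channel's mean over the baseline window; (4) re-reference
#' to the average of all channels. After step 4 the instantaneous mean
#' across channels is zero at every sample.
#'
#' @param epochs an [eeg_epochs()].
#' @param reject_uv amplitude rejection threshold, microvolts (default 100).
#' @param baseline window in ms over which per-channel means are removed.
#' @param interpolate reconstruct `bad_channels`? Requires `chanlocs`.
#' @param k neighbours used for the interpolation.
#' @return A preprocessed `eeg_epochs` (rejected trials dropped; attribute
#'   `n_rejected` records the count).
#' @export
preprocess_epochs <- function(epochs, reject_uv = 100, baseline = c(-200, 0),
                              interpolate = TRUE, k = 4) {
  v <- epochs$voltages
  good <- setdiff(seq_len(dim(v)[1]), epochs$bad_channels)

  # 1. amplitude-based trial rejection (on channels we will keep as-is)
  peak <- apply(abs(v[good, , , drop = FALSE]), 3, max)
  keep <- peak <= reject_uv
  if (!any(keep)) abort("all trials rejected by the amplitude criterion")
  v <- v[, , keep, drop = FALSE]
  labels <- epochs$labels[keep, , drop = FALSE]

  # 2. bad-channel reconstruction
  if (interpolate && length(epochs$bad_channels)) {
    if (is.null(epochs$chanlocs)) {
      abort("bad-channel interpolation requires channel positions (chanlocs)")
    }
    pos <- as.matrix(epochs$chanlocs[, c("x", "y", "z")])
    for (bc in epochs$bad_channels) {
      dists <- sqrt(colSums((t(pos[good, , drop = FALSE]) - pos[bc, ])^2))
      nn <- good[order(dists)][seq_len(min(k, length(good)))]
      w <- 1 / pmax(sort(dists)[seq_along(nn)], 1e-6)
      w <- w / sum(w)
      v[bc, , ] <- apply(v[nn, , , drop = FALSE], c(2, 3),
                         function(col) sum(w * col))
    }
  }

  # 3. baseline correction
  bl <- epochs$times >= baseline[1] & epochs$times <= baseline[2]
  blm <- apply(v[, bl, , drop = FALSE], c(1, 3), mean)   # channels x trials
  v <- v - aperm(array(blm, c(dim(blm), dim(v)[2])), c(1, 3, 2))

  # 4. average reference
  cm <- apply(v, c(2, 3), mean)
  v <- v - aperm(array(cm, c(dim(cm), dim(v)[1])), c(3, 1, 2))

  out <- eeg_epochs(v, epochs$times, labels, chanlocs = epochs$chanlocs,
                    sfreq = epochs$sfreq, bad_channels = integer())
  attr(out, "n_rejected") <- sum(!keep)
  out
}

#' Global field power
#'
#' The standard deviation, across the whole electrode montage, of the
#' (trial-averaged) voltages at each time point, using the population form
#' of the SD (denominator = number of channels). GFP is non-negative,
#' reference-independent (adding any common signal to all channels leaves
#' it unchanged), and reduces the montage to a single time series.
#'
#' @param x a `channels x time` matrix of trial-averaged voltages.
#' @return A numeric vector of GFP values (microvolts), one per time point.
#' @export
#' @examples
#' gfp(rbind(c(1, 2), c(1, -2), c(-1, 0), c(-1, 0)))
gfp <- function(x) {
  if (!is.matrix(x) || nrow(x) < 2) {
    abort("gfp() needs a channels x time matrix with at least 2 channels")
  }
  mu <- colMeans(x)
  sqrt(colMeans(x^2) - mu^2)
}

#' Condition-average voltages and GFP traces
#'
#' Averages trials per condition (any combination of label columns) and
#' returns the GFP of each condition average as a tidy trace table.
#'
#' @param epochs an [eeg_epochs()].
#' @param ... label columns (tidy-eval) defining the conditions, e.g.
#'   `modality` or `modality, distance_index`.
#' @return A tibble: condition columns, `time_ms`, `gfp`, `n_trials`.
#' @export
condition_gfp <- function(epochs, ...) {
  lab <- mutate(epochs$labels, .trial = row_number())
  g <- dplyr::group_by(lab, ...)
  keys <- dplyr::group_keys(g)
  idx <- dplyr::group_rows(g)
  purrr::map_dfr(seq_along(idx), function(i) {
    avg <- trial_average(epochs, lab$.trial[idx[[i]]])
    nt <- length(epochs$times)
    dplyr::bind_cols(
      keys[rep(i, nt), , drop = FALSE],
      tibble(time_ms = epochs$times, gfp = gfp(avg),
             n_trials = length(idx[[i]])))
  })
}

#' Trial-averaged voltage matrix
#'
#' @param epochs an [eeg_epochs()].
#' @param trials integer indices of the trials to average (default all).
#' @return A `channels x time` matrix.
#' @export
trial_average <- function(epochs, trials = seq_len(dim(epochs$voltages)[3])) {
  if (length(trials) == 0) abort("no trials to average")
  rowMeans(epochs$voltages[, , trials, drop = FALSE], dims = 2)
}

#' Summed unisensory response
#'
#' Channel-wise, time-wise sum of the subject-level average visual and
#' tactile responses — the additive prediction against which the paired
#' visuo-tactile response is contrasted. Note that GFP is computed *after*
#' summation: `gfp(v + t)` generally differs from `gfp(v) + gfp(t)`.
#'
#' @param avg_v,avg_t `channels x time` trial-averaged responses.
#' @return Their sum, `channels x time`.
#' @export
summed_response <- function(avg_v, avg_t) {
  stopifnot(all(dim(avg_v) == dim(avg_t)))
  avg_v + avg_t
}

# vectorised one-sample t-tests: X is subjects x time, H0: mean = 0
onesample_t <- function(X) {
  n <- nrow(X)
  m <- colMeans(X)
  s <- sqrt((colSums(X^2) - n * m^2) / (n - 1))
  t <- m / (s / sqrt(n))
  p <- 2 * pt(abs(t), df = n - 1, lower.tail = FALSE)
  list(t = t, p = p, df = n - 1)
}

#' Time-resolved t-tests with a consecutive-significance criterion
#'
#' Performs a t-test at every time point — one-sample against zero
#' (`mode = "vs-zero"`) or paired between two matrices
#' (`mode = "paired"`) — and reports only runs of at least
#' `min_consecutive` consecutive points with `p < alpha` as significant
#' windows. The run criterion guards against the autocorrelation of EEG
#' time series inflating isolated false positives. Tests are two-sided by
#' default.
#'
#' @param x `subjects x time` matrix of values.
#' @param y optional second matrix for the paired mode.
#' @param times time axis, ms (default: sample indices).
#' @param mode `"vs-zero"` or `"paired"`.
#' @param alpha per-point significance level (default 0.01).
#' @param min_consecutive minimum run length in samples (default 10).
#' @param sided `"two"` or `"one"` (one-sided tests the positive
#'   direction).
#' @return A list: `t`, `p` (per time point), and `windows`, a tibble with
#'   `start_ms`, `end_ms`, `sign` (sign of the mean effect in the run).
#' @export
timewise_test <- function(x, y = NULL, times = NULL,
                          mode = c("vs-zero", "paired"), alpha = 0.01,
                          min_consecutive = 10, sided = c("two", "one")) {
  mode <- match.arg(mode)
  sided <- match.arg(sided)
  if (mode == "paired") {
    stopifnot(!is.null(y), all(dim(x) == dim(y)))
    x <- x - y
  }
  if (nrow(x) < 3) abort("need at least 3 subjects")
  if (is.null(times)) times <- seq_len(ncol(x))
  tt <- onesample_t(x)
  p <- if (sided == "two") tt$p else pt(tt$t, df = tt$df, lower.tail = FALSE)
  sig <- is.finite(p) & p < alpha
  windows <- runs_to_windows(sig, times, min_consecutive,
                             sign(colMeans(x)))
  list(t = tt$t, p = p, windows = windows)
}

runs_to_windows <- function(sig, times, min_run, signs) {
  r <- rle(sig)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & r$lengths >= min_run
  if (!any(keep)) {
    return(tibble(start_ms = numeric(), end_ms = numeric(), sign = numeric()))
  }
  tibble(
    start_ms = times[starts[keep]],
    end_ms = times[ends[keep]],
    sign = vapply(which(keep), function(i) {
      sign(mean(signs[starts[i]:ends[i]]))
    }, numeric(1))
  )
}

#' Paired-versus-summed supra-additivity contrast
#'
#' For each subject, takes the GFP of the paired visuo-tactile average and
#' the GFP of the summed unisensory (V + T) average, forms their
#' difference over time, and runs the time-resolved paired test. Positive
#' windows indicate supra-additivity (the multisensory response exceeds
#' the additive prediction), negative windows sub-additivity.
#'
#' @param gfp_paired,gfp_summed `subjects x time` GFP matrices.
#' @param times time axis, ms.
#' @inheritParams timewise_test
#' @return A list: `difference` (group-mean difference trace, a tibble),
#'   `per_subject` (matrix), `windows`.
#' @export
supraadditivity_contrast <- function(gfp_paired, gfp_summed, times = NULL,
                                     alpha = 0.01, min_consecutive = 10) {
  stopifnot(all(dim(gfp_paired) == dim(gfp_summed)))
  if (is.null(times)) times <- seq_len(ncol(gfp_paired))
  diffs <- gfp_paired - gfp_summed
  tw <- timewise_test(gfp_paired, gfp_summed, times = times, mode = "paired",
                      alpha = alpha, min_consecutive = min_consecutive)
  list(
    difference = tibble(time_ms = times, diff_gfp = colMeans(diffs)),
    per_subject = diffs,
    windows = tw$windows
  )
}

#' Per-subject paired and summed GFP traces from epochs
#'
#' Convenience pipeline for one subject's preprocessed epochs: averages
#' paired visuo-tactile trials (restricted to the interior distance
#' levels, where both smaller and larger disparities exist), averages the
#' unisensory visual and tactile trials, sums those averages, and returns
#' the GFP of each.
#'
#' @param epochs an [eeg_epochs()] with `modality` and `distance_index`
#'   labels.
#' @param distances distance levels entering the paired average (default:
#'   interior levels 2..6).
#' @param match_counts subsample paired trials (seeded) to the summed
#'   condition's trial count, mirroring the count-matching control for
#'   unequal signal-to-noise?
#' @param seed seed for the subsampling.
#' @return A list: `gfp_paired`, `gfp_summed` (vectors over time),
#'   `times`.
#' @export
subject_gfp_pair <- function(epochs, distances = 2:6, match_counts = FALSE,
                             seed = 1) {
  lab <- mutate(epochs$labels, .trial = row_number())
  vt <- filter(lab, .data$modality == "VT",
               .data$distance_index %in% distances)$.trial
  vv <- filter(lab, .data$modality == "V")$.trial
  tt <- filter(lab, .data$modality == "T")$.trial
  if (match_counts) {
    n_uni <- min(length(vv), length(tt))
    if (length(vt) > n_uni) {
      old <- .Random.seed_save()
      set.seed(seed)
      vt <- sample(vt, n_uni)
      .Random.seed_restore(old)
    }
  }
  avg_vt <- trial_average(epochs, vt)
  sum_uni <- summed_response(trial_average(epochs, vv),
                             trial_average(epochs, tt))
  list(gfp_paired = gfp(avg_vt), gfp_summed = gfp(sum_uni),
       times = epochs$times)
}

#' Window-averaged GFP statistics across conditions
#'
#' Averages each subject's condition GFP inside a fixed poststimulus
#' window (default 130-150 ms) and, when requested, runs repeated-measures
#' ANOVAs (delegated to [stats::aov()] with a subject error stratum) for a
#' distance factor and a history x distance design, plus all pairwise
#' paired t-tests between distances.
#'
#' @param gfp_df tidy GFP traces with columns `subject`, `time_ms`, `gfp`
#'   and condition columns (`distance_index`, optionally `history`).
#' @param window poststimulus window, ms.
#' @param anova run the delegated ANOVAs?
#' @return A list: `means` (subject x condition window means),
#'   `condition_means` (group means per condition), `anova_distance`,
#'   `anova_history` (when applicable), `pairwise` (tibble of paired
#'   t-tests between distances).
#' @export
window_stats <- function(gfp_df, window = c(130, 150), anova = TRUE) {
  cond_cols <- intersect(c("distance_index", "history"), names(gfp_df))
  means <- gfp_df |>
    filter(.data$time_ms >= window[1], .data$time_ms <= window[2]) |>
    group_by(across(all_of(c("subject", cond_cols)))) |>
    summarise(gfp = mean(.data$gfp), .groups = "drop")
  cmeans <- means |>
    group_by(across(all_of(cond_cols))) |>
    summarise(mean_gfp = mean(.data$gfp), sd_gfp = sd(.data$gfp),
              n = dplyr::n(), .groups = "drop")
  out <- list(means = means, condition_means = cmeans)
  if (anova && "distance_index" %in% cond_cols) {
    df <- means
    df$subject <- factor(df$subject)
    df$distance_index <- factor(df$distance_index)
    if ("history" %in% cond_cols) {
      df$history <- factor(df$history)
      out$anova_history <- summary(aov(
        gfp ~ distance_index * history +
          Error(subject / (distance_index * history)), data = df))
      dist_means <- df |>
        group_by(.data$subject, .data$distance_index) |>
        summarise(gfp = mean(.data$gfp), .groups = "drop")
    } else {
      dist_means <- df
    }
    out$anova_distance <- summary(aov(
      gfp ~ distance_index + Error(subject / distance_index),
      data = dist_means))
    lv <- levels(dist_means$distance_index)
    pairs <- utils::combn(lv, 2, simplify = FALSE)
    out$pairwise <- purrr::map_dfr(pairs, function(pr) {
      a <- dist_means$gfp[dist_means$distance_index == pr[1]]
      b <- dist_means$gfp[dist_means$distance_index == pr[2]]
      tt <- t.test(a, b, paired = TRUE)
      tibble(d1 = pr[1], d2 = pr[2], t = unname(tt$statistic),
             p.value = tt$p.value)
    })
  }
  out
}

#' Per-channel statistic map inside a window
#'
#' Localises which channels drive a window effect: for every channel, the
#' subject-wise window-mean voltages are tested across the factor levels
#' (paired t-test for 2 levels, repeated-measures ANOVA F for more) and
#' returned as a channel-indexed table for external plotting.
#'
#' @param window_means a `subjects x channels x levels` array of
#'   window-averaged voltages.
#' @return A tibble: `channel`, `statistic`, `p.value`.
#' @export
contribution_map <- function(window_means) {
  stopifnot(length(dim(window_means)) == 3)
  n_ch <- dim(window_means)[2]
  if (n_ch < 2) abort("a single-channel montage cannot localise an effect")
  n_lv <- dim(window_means)[3]
  purrr::map_dfr(seq_len(n_ch), function(ch) {
    m <- window_means[, ch, ]
    if (n_lv == 2) {
      tt <- t.test(m[, 1], m[, 2], paired = TRUE)
      tibble(channel = ch, statistic = unname(tt$statistic),
             p.value = tt$p.value)
    } else {
      df <- data.frame(
        y = as.vector(m),
        subj = factor(rep(seq_len(nrow(m)), n_lv)),
        lvl = factor(rep(seq_len(n_lv), each = nrow(m)))
      )
      sm <- summary(aov(y ~ lvl + Error(subj / lvl), data = df))
      tab <- sm[["Error: subj:lvl"]][[1]]
      tibble(channel = ch, statistic = tab["lvl", "F value"],
             p.value = tab["lvl", "Pr(>F)"])
    }
  })
}
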