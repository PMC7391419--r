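test_that("GFP is the population SD across channels", {
  # identical channels carry no field
  expect_equal(gfp(matrix(5, nrow = 8, ncol = 10)), rep(0, 10))
  # {+1, +1, -1, -1} has population SD 1
  expect_equal(gfp(matrix(c(1, 1, -1, -1), ncol = 1)), 1)
  # explicit population (divide-by-N) convention
  x <- matrix(rnorm(32 * 7), 32, 7)
  expect_equal(gfp(x),
               apply(x, 2, function(col) sqrt(mean((col - mean(col))^2))))
  expect_error(gfp(matrix(1, 1, 10)), "at least 2 channels")
})

test_that("GFP is invariant to common-mode (reference) signals", {
  set.seed(21)
  x <- matrix(rnorm(64 * 100), 64, 100)
  common <- sin(seq_len(100) / 5) * 40
  shifted <- x + matrix(common, 64, 100, byrow = TRUE)
  expect_equal(gfp(shifted), gfp(x), tolerance = 1e-12)
  expect_true(all(gfp(x) >= 0))
})

test_that("summed responses add channel-wise, with GFP computed afterwards", {
  set.seed(22)
  v <- matrix(rnorm(16 * 50), 16, 50)
  t0 <- matrix(0, 16, 50)
  expect_equal(summed_response(v, t0), v)
  expect_equal(gfp(summed_response(v, t0)), gfp(v))
  # exact cancellation
  expect_equal(gfp(summed_response(v, -v)), rep(0, 50))
  # orthogonal zero-mean topographies satisfy the Pythagorean identity
  u <- c(1, -1, 1, -1); w <- c(1, 1, -1, -1)
  a <- outer(u, rnorm(30)); b <- outer(w, rnorm(30))
  expect_equal(gfp(a + b)^2, gfp(a)^2 + gfp(b)^2, tolerance = 1e-12)
})

test_that("timewise tests mirror stats::t.test and enforce the run criterion", {
  set.seed(23)
  x <- matrix(rnorm(15 * 40), 15, 40)
  tw <- timewise_test(x, alpha = 0.05, min_consecutive = 1)
  ref <- apply(x, 2, function(col) t.test(col)$p.value)
  expect_equal(tw$p, ref, tolerance = 1e-12)

  y <- matrix(rnorm(15 * 40), 15, 40)
  twp <- timewise_test(x, y, mode = "paired", alpha = 0.05,
                       min_consecutive = 1)
  refp <- vapply(1:40, function(j) t.test(x[, j], y[, j], paired = TRUE)$p.value,
                 numeric(1))
  expect_equal(twp$p, refp, tolerance = 1e-12)
  expect_error(timewise_test(x[1:2, , drop = FALSE]), "at least 3 subjects")
})

test_that("a run of exactly 9 significant points reports no window", {
  n_sub <- 12
  x <- matrix(rnorm(n_sub * 30, sd = 0.1), n_sub, 30)
  x[, 11:19] <- x[, 11:19] + 5      # 9 consecutive strong points
  tw <- timewise_test(x, min_consecutive = 10)
  expect_equal(nrow(tw$windows), 0)
  # one more point and the window appears
  x[, 20] <- x[, 20] + 5
  tw2 <- timewise_test(x, min_consecutive = 10)
  expect_equal(nrow(tw2$windows), 1)
  expect_equal(tw2$windows$start_ms, 11)
  expect_equal(tw2$windows$end_ms, 20)
  expect_equal(tw2$windows$sign, 1)
})

test_that("an injected offset window is localised where it was placed", {
  set.seed(24)
  times <- seq(-200, 800)
  x <- matrix(rnorm(20 * length(times), sd = 1), 20, length(times))
  inj <- times >= 300 & times <= 350
  x[, inj] <- x[, inj] + 3          # SNR 3
  tw <- timewise_test(x, times = times)
  expect_gte(nrow(tw$windows), 1)
  w <- tw$windows[which.max(tw$windows$end_ms - tw$windows$start_ms), ]
  expect_lt(abs(w$start_ms - 300), 10)
  expect_lt(abs(w$end_ms - 350), 10)
})

test_that("white-noise nulls produce calibrated point-wise rates and no windows", {
  set.seed(25)
  reps <- 200
  n_sub <- 20; n_time <- 500
  frac_sig <- numeric(reps)
  n_windows <- integer(reps)
  for (i in seq_len(reps)) {
    x <- matrix(rnorm(n_sub * n_time), n_sub, n_time)
    tw <- timewise_test(x, alpha = 0.01, min_consecutive = 10)
    frac_sig[i] <- mean(tw$p < 0.01)
    n_windows[i] <- nrow(tw$windows)
  }
  expect_equal(mean(frac_sig), 0.01, tolerance = 0.35)
  # with independent samples, 10 consecutive hits at alpha = .01 are
  # essentially impossible: the family-wise false-window rate is ~0
  expect_equal(sum(n_windows), 0)
})

test_that("the additive null yields a null supra-additivity contrast", {
  set.seed(26)
  n_sub <- 10; n_time <- 200
  gfp_vt <- matrix(0, n_sub, n_time)
  gfp_sum <- matrix(0, n_sub, n_time)
  for (s in seq_len(n_sub)) {
    v <- matrix(rnorm(16 * n_time), 16, n_time)
    t0 <- matrix(rnorm(16 * n_time), 16, n_time)
    vt <- v + t0                      # exactly additive
    gfp_vt[s, ] <- gfp(vt)
    gfp_sum[s, ] <- gfp(summed_response(v, t0))
  }
  out <- supraadditivity_contrast(gfp_vt, gfp_sum)
  expect_equal(max(abs(out$difference$diff_gfp)), 0, tolerance = 1e-12)
  expect_equal(nrow(out$windows), 0)
})

test_that("an injected multisensory gain window is recovered within 10 ms", {
  study <- generate_evoked_study(n_subjects = 16, n_channels = 48,
                                 gain_near = 1.4, noise_uV = 1, seed = 31)
  times <- attr(study, "times")
  subs <- split(study, study$subject)
  gfp_vt <- t(vapply(subs, function(df) {
    avgs <- df$avg[df$modality == "VT"]
    gfp(Reduce(`+`, avgs) / length(avgs))
  }, numeric(length(times))))
  gfp_sum <- t(vapply(subs, function(df) {
    gfp(summed_response(df$avg[df$modality == "V"][[1]],
                        df$avg[df$modality == "T"][[1]]))
  }, numeric(length(times))))
  out <- supraadditivity_contrast(gfp_vt, gfp_sum, times = times)
  pos <- out$windows[out$windows$sign > 0, ]
  expect_gte(nrow(pos), 1)
  w <- pos[which.max(pos$end_ms - pos$start_ms), ]
  expect_lt(abs(w$start_ms - 124), 10)
  expect_lt(abs(w$end_ms - 158), 10)
})

test_that("preprocessing rejects, interpolates, baselines and re-references", {
  set.seed(27)
  n_ch <- 16; times <- seq(-200, 300); n_tr <- 12
  v <- array(rnorm(n_ch * length(times) * n_tr, sd = 5),
             c(n_ch, length(times), n_tr))
  v[3, 100, 2] <- 150                       # one excursion beyond 100 uV
  v <- v + 20                               # constant offset on every channel
  chanlocs <- ppsrecal:::fibonacci_montage(n_ch)
  ep <- eeg_epochs(v, times, tibble::tibble(modality = rep("T", n_tr)),
                   chanlocs = chanlocs, bad_channels = 5L)
  pp <- preprocess_epochs(ep, reject_uv = 100)
  expect_equal(dim(pp$voltages)[3], n_tr - 1)
  expect_equal(attr(pp, "n_rejected"), 1)
  # offsets removed and average reference: channel means over baseline ~ 0,
  # instantaneous channel mean exactly 0
  bl <- pp$times <= 0
  expect_lt(max(abs(apply(pp$voltages[, bl, , drop = FALSE], c(1, 3), mean))),
            1e-9)
  expect_lt(max(abs(apply(pp$voltages, c(2, 3), mean))), 1e-9)
  # everything rejected -> error
  expect_error(preprocess_epochs(ep, reject_uv = 1e-6), "all trials rejected")
})

test_that("bad channels are reconstructed from their sphere neighbours", {
  n_ch <- 32; times <- seq(-50, 50); n_tr <- 4
  chanlocs <- ppsrecal:::fibonacci_montage(n_ch)
  # smooth spatial field switched on at stimulus onset (so the baseline
  # window is clean): voltage is a linear function of sensor position
  field <- chanlocs$x * 2 + chanlocs$z
  step_w <- as.numeric(times > 0)
  v <- array(rep(outer(field, step_w), n_tr),
             c(n_ch, length(times), n_tr))
  v[10, , ] <- 999                          # corrupted channel
  ep <- eeg_epochs(v, times, tibble::tibble(i = seq_len(n_tr)),
                   chanlocs = chanlocs, bad_channels = 10L)
  pp <- preprocess_epochs(ep, reject_uv = Inf, baseline = c(-50, -10))
  # reconstructed value interpolates the smooth field, not the corruption;
  # inverse-distance weighting carries an O(inter-channel spacing) error
  post <- which(times > 0)[10]
  recon <- mean(pp$voltages[10, post, ])
  truth <- field[10] - mean(field)
  expect_lt(abs(recon - truth), 0.5)
})

test_that("window statistics recover a monotone distance gradient", {
  study <- generate_evoked_study(n_subjects = 14, n_channels = 32,
                                 gain_near = 1.5, hist_boost = 0,
                                 noise_uV = 0.5, seed = 32)
  times <- attr(study, "times")
  gfp_df <- dplyr::bind_rows(lapply(split(study, seq_len(nrow(study))),
    function(row) {
      if (row$modality != "VT") return(NULL)
      tibble::tibble(subject = row$subject,
                     distance_index = row$distance_index,
                     history = row$history, time_ms = times,
                     gfp = gfp(row$avg[[1]]))
    }))
  ws <- window_stats(gfp_df, window = c(130, 150))
  cm <- ws$condition_means |>
    dplyr::group_by(distance_index) |>
    dplyr::summarise(m = mean(mean_gfp)) |>
    dplyr::arrange(distance_index)
  expect_true(all(diff(cm$m) < 0))          # nearest = largest
  expect_s3_class(ws$pairwise, "tbl_df")
  expect_equal(nrow(ws$pairwise), choose(5, 2))
})

test_that("the contribution map ranks truly driven channels first", {
  set.seed(29)
  n_sub <- 14; n_ch <- 30
  wm <- array(rnorm(n_sub * n_ch * 2, sd = 1), c(n_sub, n_ch, 2))
  wm[, 10:20, 2] <- wm[, 10:20, 2] + 2      # effect on channels 10..20
  cm <- contribution_map(wm)
  top <- cm$channel[order(cm$p.value)][1:11]
  expect_gte(length(intersect(top, 10:20)), 9)
  expect_error(contribution_map(wm[, 1, , drop = FALSE]), "single-channel")
})

test_that("null contribution maps are calibrated", {
  set.seed(30)
  hits <- vapply(1:40, function(i) {
    wm <- array(rnorm(12 * 20 * 2), c(12, 20, 2))
    mean(contribution_map(wm)$p.value < 0.05)
  }, numeric(1))
  expect_equal(mean(hits), 0.05, tolerance = 0.5)
})
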