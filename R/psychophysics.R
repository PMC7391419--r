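#' Four-parameter RT sigmoid
#'
#' The function relating tactile reaction time to visuo-tactile distance:
#' \deqn{y(x) = \frac{y_{min} + y_{max} e^{(x - x_c)/b}}{1 + e^{(x - x_c)/b}}}
#' It rises from `y_min` (fast RTs near the body) to `y_max` (far), with
#' central point `x_c` — the operational boundary of peri-personal space —
#' and scale parameter `b` (larger `b`, shallower transition). Distances
#' must therefore be coded so that a larger `x` means a larger disparity
#' and a slower RT; `x` may be a distance index or centimetres, and `x_c`
#' and `b` inherit its units.
#'
#' @param x distance (index or cm).
#' @param y_min,y_max lower/upper RT asymptotes, ms.
#' @param x_c central point (same units as `x`).
#' @param b scale parameter, positive.
#' @return `y(x)`.
#' @export
#' @examples
#' pps_sigmoid(3.5, 260, 320, x_c = 3.5, b = 1)   # midpoint: 290
pps_sigmoid <- function(x, y_min, y_max, x_c, b) {
  e <- exp((x - x_c) / b)
  ifelse(is.infinite(e), y_max, (y_min + y_max * e) / (1 + e))
}

# internal: fit on plain vectors (x = distance, y = mean RT, w = weights)
fit_sigmoid_xy <- function(x, y, w = NULL) {
  if (is.null(w)) w <- rep(1, length(x))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]; w <- w[ok]
  if (length(x) < 4) abort("need at least 4 distance levels with finite mean RT")
  rng <- range(x)
  span <- diff(rng)
  # asymptotes are bounded to within one data range of the observed values:
  # with few sampled levels an unbounded fit can run its plateaus to
  # absurd values while interpolating the points
  yr <- max(diff(range(y)), 1e-6)
  lower <- c(y_min = min(y) - yr, y_max = min(y) - yr,
             x_c = rng[1] - 2 * span / (length(x) - 1), b = 1e-3)
  upper <- c(y_min = max(y) + yr, y_max = max(y) + yr,
             x_c = rng[2] + 2 * span / (length(x) - 1),
             b = 100 * max(1, span / 5))
  starts <- list(
    c(y_min = min(y), y_max = max(y), x_c = mean(rng), b = 1),
    c(y_min = min(y), y_max = max(y), x_c = mean(rng), b = span / 6),
    c(y_min = min(y), y_max = max(y), x_c = mean(rng), b = span / 2)
  )
  sw <- sqrt(w / mean(w))
  resid_fn <- function(p) {
    r <- sw * (y - pps_sigmoid(x, p[1], p[2], p[3], p[4]))
    r[!is.finite(r)] <- 1e6
    r
  }
  best <- NULL
  best_dev <- Inf
  for (s0 in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = s0, lower = lower, upper = upper,
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (!is.null(fit) && fit$info %in% 1:3) {
      dev <- sum(fit$fvec^2)
      if (dev < best_dev) { best <- fit; best_dev <- dev }
    }
  }
  if (is.null(best)) {
    return(structure(
      list(coefficients = c(y_min = NA_real_, y_max = NA_real_,
                            x_c = NA_real_, b = NA_real_),
           r2 = -Inf, converged = FALSE, n = length(x),
           data = tibble(x = x, y = y, fitted = NA_real_)),
      class = "pps_sigmoid_fit"))
  }
  cf <- coef(best)
  names(cf) <- c("y_min", "y_max", "x_c", "b")
  fitted <- pps_sigmoid(x, cf["y_min"], cf["y_max"], cf["x_c"], cf["b"])
  ss_res <- sum(w * (y - fitted)^2)
  ss_tot <- sum(w * (y - sum(w * y) / sum(w))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else as.numeric(ss_res < 1e-12)
  structure(
    list(coefficients = cf, r2 = r2, converged = TRUE, n = length(x),
         data = tibble(x = x, y = y, fitted = fitted)),
    class = "pps_sigmoid_fit")
}

#' Fit the RT-by-distance sigmoid
#'
#' Nonlinear least-squares fit (trust-region Levenberg-Marquardt) of
#' [pps_sigmoid()] to reaction times against distance. By default RTs are
#' averaged per distance level before fitting (the conventional procedure
#' for these designs); set `average = FALSE` to fit per-trial values.
#' Initialisation takes `y_min`/`y_max` from the extremes of the condition
#' means, `x_c` from the midpoint of the distance range, and `b = 1`; `b`
#' is bounded away from zero and `x_c` to within two levels outside the
#' sampled range. A fit that fails to converge is returned flagged, with
#' an `r2` of `-Inf`, rather than raising an error.
#'
#' @param data a data frame of trials or condition means.
#' @param x,y column names (tidy-eval) of distance and RT.
#' @param average average `y` per level of `x` before fitting?
#' @param weights `"equal"` (the classical procedure: every condition mean
#'   counts the same) or `"count"` (means weighted by their trial counts —
#'   the efficient choice when history splitting leaves cells of very
#'   different sizes; only meaningful with `average = TRUE`).
#' @return An object of class `pps_sigmoid_fit` with `coefficients`
#'   (`y_min`, `y_max`, `x_c`, `b`), `r2` (computed on the values that were
#'   fit), `converged`, and the fitted data. Supports [coef()], [tidy()],
#'   [glance()], [predict()] and [autoplot()].
#' @export
#' @examples
#' d <- tibble::tibble(dist = 1:6,
#'                     rt = pps_sigmoid(1:6, 260, 320, 3.5, 0.8))
#' coef(fit_pps_sigmoid(d, dist, rt))
fit_pps_sigmoid <- function(data, x, y, average = TRUE,
                            weights = c("equal", "count")) {
  weights <- match.arg(weights)
  xv <- dplyr::pull(data, {{ x }})
  yv <- dplyr::pull(data, {{ y }})
  if (average) {
    m <- tibble(x = xv, y = yv) |>
      filter(is.finite(.data$y)) |>
      group_by(.data$x) |>
      summarise(y = mean(.data$y), n = dplyr::n(), .groups = "drop")
    fit_sigmoid_xy(m$x, m$y, w = if (weights == "count") m$n else NULL)
  } else {
    fit_sigmoid_xy(xv, yv)
  }
}

#' @export
coef.pps_sigmoid_fit <- function(object, ...) object$coefficients

#' @export
print.pps_sigmoid_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<pps_sigmoid_fit> NON-CONVERGED (flagged; r2 = -Inf)\n")
  } else {
    cf <- x$coefficients
    cat(sprintf(
      "<pps_sigmoid_fit> y_min = %.1f, y_max = %.1f, x_c = %.3f, b = %.3f (R2 = %.3f, n = %d)\n",
      cf["y_min"], cf["y_max"], cf["x_c"], cf["b"], x$r2, x$n))
  }
  invisible(x)
}

#' @export
predict.pps_sigmoid_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$x else newdata
  cf <- object$coefficients
  unname(pps_sigmoid(x, cf[["y_min"]], cf[["y_max"]], cf[["x_c"]], cf[["b"]]))
}

#' @rdname fit_pps_sigmoid
#' @param x a `pps_sigmoid_fit`.
#' @param ... unused.
#' @method tidy pps_sigmoid_fit
#' @export
tidy.pps_sigmoid_fit <- function(x, ...) {
  tibble(term = names(x$coefficients),
         estimate = unname(x$coefficients))
}

#' @rdname fit_pps_sigmoid
#' @method glance pps_sigmoid_fit
#' @export
glance.pps_sigmoid_fit <- function(x, ...) {
  tibble(r.squared = x$r2, converged = x$converged, nobs = x$n)
}

#' Label trials by the disparity of the immediately preceding trial
#'
#' Serial-dependence splitting: each trial is labelled `"smaller"` if the
#' previous trial probed a smaller visuo-tactile disparity than the current
#' one, `"larger"` if a larger one, and `"excluded"` when the previous
#' trial probed the same distance, was a catch (visual-only) trial or
#' carried no distance, or when the current trial sits at an extreme
#' distance level (no smaller/larger condition exists for it). Trials must
#' be supplied in session order (strictly increasing `trial_index`).
#'
#' @param trials a trial tibble with `trial_index`, `modality`
#'   (`"VT"`/`"T"`/`"V"`) and `distance_index` (or `distance_cm`) columns.
#' @param distance column (tidy-eval) holding the disparity; default
#'   `distance_index`.
#' @param levels the design's full set of distance levels, used to decide
#'   which trials sit at the extremes; defaults to the levels observed in
#'   the table.
#' @return `trials` with a `history` column
#'   (`"smaller"`/`"larger"`/`"excluded"`).
#' @export
split_by_history <- function(trials, distance = distance_index,
                             levels = NULL) {
  ti <- trials$trial_index
  if (is.unsorted(ti, strictly = TRUE)) {
    abort("trials must be in session order (strictly increasing trial_index)")
  }
  d <- dplyr::pull(trials, {{ distance }})
  k <- nrow(trials)
  prev_d <- c(NA, d[-k])
  prev_catch <- c(TRUE, trials$modality[-k] == "V")
  lv <- levels %||%
    sort(unique(d[trials$modality %in% c("VT", "V") & !is.na(d)]))
  lab <- rep("excluded", k)
  cur_ok <- !is.na(d) & d > lv[1] & d < lv[length(lv)]
  ok <- cur_ok & !prev_catch & !is.na(prev_d) & prev_d != d
  lab[ok & prev_d < d] <- "smaller"
  lab[ok & prev_d > d] <- "larger"
  trials$history <- lab
  trials
}

#' Goodness-of-fit screening of per-subject sigmoid fits
#'
#' A subject is kept only if every one of their fits (pooled and both
#' history splits) reaches the a-priori goodness-of-fit bound; flagged
#' (non-converged) fits carry `r2 = -Inf` and therefore always fail.
#'
#' @param fits a tibble with one row per subject x fit, containing a
#'   `subject` column and an `r2` column (e.g. stacked [glance()] output).
#' @param r2_min minimum acceptable coefficient of determination
#'   (default 0.50).
#' @return A tibble with `subject` and `keep` (logical).
#' @export
#' @examples
#' f <- tibble::tibble(subject = c(1, 1, 1, 2, 2, 2),
#'                     r2 = c(.9, .8, .49, .51, .51, .51))
#' qc_filter(f)
qc_filter <- function(fits, r2_min = 0.5) {
  fits |>
    group_by(.data$subject) |>
    summarise(keep = all(is.finite(.data$r2) & .data$r2 >= r2_min),
              .groups = "drop")
}

#' Rapid-recalibration index
#'
#' The difference between the fitted central points of the two history
#' splits, `x_c(larger) - x_c(smaller)`. Positive values mean the PPS
#' boundary sits farther from the body after trials that probed a larger
#' visuo-tactile disparity. The index is antisymmetric under swapping the
#' two fits.
#'
#' @param fit_larger,fit_smaller `pps_sigmoid_fit` objects (or numeric
#'   central points).
#' @return The central-point difference (units of the fitted `x`).
#' @export
recalibration_index <- function(fit_larger, fit_smaller) {
  xc <- function(f) {
    if (inherits(f, "pps_sigmoid_fit")) unname(coef(f)["x_c"]) else as.numeric(f)
  }
  xc(fit_larger) - xc(fit_smaller)
}

#' n-back design matrix for the history GLM
#'
#' Builds the lagged design for modelling RT at trial *t* from the
#' disparities at lags 0..`n_back - 1`: one predictor column per lag, one
#' usable row per trial whose full lag window is available (rows with any
#' missing lag — catch trials, absent RTs — are dropped).
#'
#' @param trials a trial tibble in session order with `distance_index` and
#'   `rt` columns.
#' @param n_back number of trials in the window (default 10: lags 0..9).
#' @return A tibble with `rt` and `dist_lag0` .. `dist_lag{n_back-1}`.
#' @export
nback_design <- function(trials, n_back = 10) {
  if (n_back > nrow(trials)) {
    abort("n_back exceeds the session length")
  }
  d <- trials$distance_index
  out <- tibble(rt = trials$rt)
  for (k in seq_len(n_back) - 1) {
    out[[paste0("dist_lag", k)]] <- dplyr::lag(d, k)
  }
  out <- out[stats::complete.cases(out), , drop = FALSE]
  out
}

#' Gamma GLM of RT on trial history
#'
#' Fits the n-back design with a gamma-family GLM under the canonical
#' (inverse) link, delegating to [stats::glm()], and reports each lag's
#' coefficient together with its magnitude relative to the lag-0
#' (current-trial) coefficient. A rank-deficient design (e.g. a constant
#' distance column) yields `NA` coefficients for the aliased terms, which
#' are reported as such.
#'
#' @inheritParams nback_design
#' @return A list with `fit` (the `glm` object) and `effects`, a tibble
#'   with `lag`, `estimate`, `p.value` and `ratio`
#'   (`|estimate| / |estimate at lag 0|`).
#' @export
nback_glm <- function(trials, n_back = 10) {
  des <- nback_design(trials, n_back)
  fit <- glm(rt ~ ., data = des, family = Gamma(link = "inverse"))
  cf <- summary(fit)$coefficients
  terms <- paste0("dist_lag", seq_len(n_back) - 1)
  est <- setNames(rep(NA_real_, n_back), terms)
  pv <- est
  present <- intersect(terms, rownames(cf))
  est[present] <- cf[present, "Estimate"]
  pv[present] <- cf[present, "Pr(>|t|)"]
  if (anyNA(est)) {
    warn("rank-deficient n-back design: some lag coefficients are aliased")
  }
  list(
    fit = fit,
    effects = tibble(
      lag = seq_len(n_back) - 1,
      estimate = unname(est),
      p.value = unname(pv),
      ratio = abs(unname(est)) / abs(est[["dist_lag0"]])
    )
  )
}

#' Correlation between recalibration magnitude and sigmoid shallowness
#'
#' Pearson correlation, across subjects, between the rapid-recalibration
#' index (central-point shift) and the pooled sigmoid scale parameter `b`
#' (larger `b` = shallower PPS gradient). In designs where shallower
#' sigmoids recalibrate more, the expected sign is positive.
#'
#' @param data a tibble with one row per subject.
#' @param dxc,b columns (tidy-eval) holding the recalibration index and the
#'   pooled `b` value.
#' @return A tibble: `r`, `r.squared`, `p.value`, `n`.
#' @export
recal_slope_correlation <- function(data, dxc = dxc, b = b) {
  x <- dplyr::pull(data, {{ dxc }})
  y <- dplyr::pull(data, {{ b }})
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3) abort("need at least 3 subjects for the correlation")
  ct <- cor.test(x[ok], y[ok], method = "pearson")
  tibble(r = unname(ct$estimate), r.squared = unname(ct$estimate)^2,
         p.value = ct$p.value, n = sum(ok))
}

#' Write sigmoid fits as delimited text
#'
#' @param fits named list of `pps_sigmoid_fit` objects (names = split
#'   labels), or a tibble already in output form.
#' @param path output path (tab-separated).
#' @param subject subject identifier recycled over rows.
#' @export
write_fits <- function(fits, path, subject = 1) {
  if (is.list(fits) && !is.data.frame(fits)) {
    fits <- purrr::imap_dfr(fits, function(f, nm) {
      cf <- coef(f)
      tibble(subject = subject, split = nm,
             y_min = cf[["y_min"]], y_max = cf[["y_max"]],
             x_c = cf[["x_c"]], b = cf[["b"]], r2 = f$r2)
    })
  }
  utils::write.table(fits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
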