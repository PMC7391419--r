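#' @method autoplot pps_sigmoid_fit
#' @export
autoplot.pps_sigmoid_fit <- function(object, n = 200, ...) {
  d <- object$data
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "visuo-tactile distance", y = "RT (ms)")
  if (object$converged) {
    grid <- tibble(x = seq(min(d$x), max(d$x), length.out = n))
    grid$y <- predict(object, grid$x)
    xc <- unname(coef(object)["x_c"])
    p <- p +
      ggplot2::geom_line(data = grid, colour = "steelblue") +
      ggplot2::geom_vline(xintercept = xc, linetype = "dashed",
                          colour = "grey40")
  }
  p + ggplot2::theme_minimal()
}

#' Plot a simulated session split by sensory history
#'
#' Mean multisensory network RT against distance, one curve per history
#' split, with the unisensory level as a horizontal reference when
#' present.
#'
#' @param session tibble from [run_session()].
#' @return A ggplot object.
#' @export
plot_session_history <- function(session) {
  vt <- session |>
    filter(.data$modality == "VT", !is.na(.data$rt_ms),
           .data$history != "excluded") |>
    group_by(.data$distance_cm, .data$history) |>
    summarise(rt = mean(.data$rt_ms), .groups = "drop")
  p <- ggplot2::ggplot(vt, ggplot2::aes(x = .data$distance_cm, y = .data$rt,
                                        colour = .data$history)) +
    ggplot2::geom_point() + ggplot2::geom_line() +
    ggplot2::scale_colour_manual(
      values = c(smaller = "#c0392b", larger = "#2e6da4")) +
    ggplot2::labs(x = "visuo-tactile distance at tactile onset (cm)",
                  y = "network RT (ms)", colour = "previous trial") +
    ggplot2::theme_minimal()
  uni <- session$rt_ms[session$modality == "T" & !is.na(session$rt_ms)]
  if (length(uni)) {
    p <- p + ggplot2::geom_hline(yintercept = mean(uni), linetype = "dotted")
  }
  p
}

#' Plot GFP traces by condition
#'
#' @param gfp_df tidy trace table (e.g. from [condition_gfp()]) with
#'   columns `time_ms`, `gfp` and one grouping column.
#' @param colour column (tidy-eval) mapped to colour.
#' @param windows optional window tibble (`start_ms`, `end_ms`) shaded.
#' @return A ggplot object.
#' @export
plot_gfp <- function(gfp_df, colour = NULL, windows = NULL) {
  p <- ggplot2::ggplot(gfp_df,
                       ggplot2::aes(x = .data$time_ms, y = .data$gfp,
                                    colour = {{ colour }})) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time from stimulus onset (ms)",
                  y = expression(GFP ~ (mu * V))) +
    ggplot2::theme_minimal()
  if (!is.null(windows) && nrow(windows)) {
    p <- p + ggplot2::geom_rect(
      data = windows, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$start_ms, xmax = .data$end_ms,
                   ymin = -Inf, ymax = Inf),
      alpha = 0.15, fill = "grey50")
  }
  p
}

#' Plot a forgetting-time-constant sweep
#'
#' Recalibration index (top) and distance effect (bottom) against the
#' forgetting time constant, marking the flat-PPS regime.
#'
#' @param sweep tibble from [sweep_tau()].
#' @return A ggplot object.
#' @export
plot_sweep_tau <- function(sweep) {
  long <- tidyr::pivot_longer(
    sweep, c("dxc_cm", "distance_effect_ms"),
    names_to = "measure", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$tau_h_s, y = .data$value)) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$flat_pps)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~measure, scales = "free_y", ncol = 1,
                        labeller = ggplot2::as_labeller(c(
                          dxc_cm = "central-point shift (cm)",
                          distance_effect_ms = "distance effect (ms)"))) +
    ggplot2::labs(x = expression(tau[H] ~ (s)), y = NULL,
                  shape = "flat PPS") +
    ggplot2::theme_minimal()
}
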