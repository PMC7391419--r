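# shared fixtures built in code

# a small network configuration (21 x 21 sheets) for mechanical tests where
# the full 41 x 41 default would only cost time
small_config <- function(...) {
  pps_config(
    grid = list(n = 21L, tactile_spacing = 0.5, tactile_extent = 10,
                visual_spacing = 10, visual_extent = 200),
    ...
  )
}

# noiseless sigmoid condition means
sigmoid_means <- function(y_min = 260, y_max = 320, x_c = 3.5, b = 0.8,
                          x = 1:6) {
  tibble::tibble(distance_index = x,
                 rt = pps_sigmoid(x, y_min, y_max, x_c, b))
}

# a minimal ordered trial table from vectors
trial_table <- function(distance, modality = rep("VT", length(distance)),
                        rt = rep(300, length(distance))) {
  tibble::tibble(trial_index = seq_along(distance), modality = modality,
                 distance_index = distance, rt = rt)
}
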