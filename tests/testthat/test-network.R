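test_that("the default architecture covers the stated receptive-field grids", {
  net <- build_network(pps_config())
  g <- net$config$grid
  expect_equal(g$n, 41)
  # tactile sheet: 20 x 20 cm at 0.5 cm spacing
  expect_equal(range(net$par$X_t), c(0, 20))
  expect_equal(diff(sort(unique(net$par$X_t[, 1]))), rep(0.5, 40))
  # visual sheet: 400 x 400 cm at 10 cm spacing
  expect_equal(range(net$par$D_v), c(0, 400))
  expect_equal(range(net$par$L_v), c(-200, 200))
  expect_equal(diff(sort(unique(net$par$D_v[, 1]))), rep(10, 40))
  # rest state, weights at basal maps, feedback mirrors the basal pattern
  expect_true(all(net$state$q_t == 0) && net$state$q_m == 0)
  expect_identical(net$state$W_v, net$par$W0_v)
  expect_equal(net$par$B_v / net$par$B_v[1, 1],
               net$par$W0_v / net$par$W0_v[1, 1])
  # visual basal weights decay exponentially with depth, uniform laterally
  expect_equal(net$par$W0_v[1, 1], net$config$feedforward$w0_v)
  expect_true(all(diff(net$par$W0_v[, 1]) < 0))
  expect_equal(net$par$W0_v[, 1],
               net$config$feedforward$w0_v *
                 exp(-net$par$D_v[, 1] / net$config$feedforward$lambda_v))
})

test_that("configuration invariants are enforced", {
  expect_error(pps_config(grid = list(n = 2L, tactile_extent = 0.5)), "n must be")
  expect_error(pps_config(grid = list(tactile_extent = 21)), "inconsistent")
  expect_error(pps_config(neurons = list(f_min = c(t = 2))), "f_min")
  expect_error(pps_config(neurons = list(tau_ms = c(t = 1))), "Euler step")
  expect_error(pps_config(lateral = list(exc_amp = 0.01)), "net excitatory")
  expect_error(pps_config(hebb = list(tau_h_s = -1)), "tau_h_s")
  expect_error(pps_config(hebb = list(gate_theta = 1.5)), "gate_theta")
})

test_that("configurations round-trip through YAML", {
  cfg <- pps_config(hebb = list(tau_h_s = 2.5),
                    stimulus = list(velocity = 50))
  path <- withr::local_tempfile(fileext = ".yaml")
  write_pps_config(cfg, path)
  back <- read_pps_config(path)
  expect_equal(back$hebb$tau_h_s, 2.5)
  expect_equal(back$stimulus$velocity, 50)
  expect_equal(back$neurons$tau_ms, cfg$neurons$tau_ms)
  # shipped default parses to the in-code default
  shipped <- read_pps_config(system.file("extdata", "pps-default.yaml",
                                         package = "ppsrecal"))
  expect_equal(unclass(shipped)[-1], unclass(pps_config())[-1])
})

test_that("stimulus input maps peak on the nearest receptive field", {
  net <- build_network(small_config())
  # tactile stimulus exactly on a receptive-field centre
  m <- external_input(net, "tactile", t_ms = 10, position = c(5, 5))
  peak <- which(m == max(m), arr.ind = TRUE)
  expect_equal(net$par$X_t[peak], 5)
  expect_equal(net$par$Y_t[peak], 5)
  # before onset the map is zero
  expect_equal(external_input(net, "tactile", t_ms = 10, onset = 50),
               matrix(0, 21, 21))
  # looming stimulus: after 1000 ms at 75 cm/s from 200 cm it sits at 125 cm
  m2 <- external_input(net, "visual", t_ms = 1000, position = 200,
                       velocity = 75)
  peak2 <- which(m2 == max(m2), arr.ind = TRUE)
  expect_lte(abs(net$par$D_v[peak2[1, 1], peak2[1, 2]] - 125), 5)
  expect_equal(net$par$L_v[peak2[1, 1], peak2[1, 2]], 0)
  # outside the represented space: zero map plus a warning
  expect_warning(m3 <- external_input(net, "tactile", t_ms = 0,
                                      position = c(50, 50)), "outside")
  expect_equal(max(m3), 0)
})

test_that("membrane dynamics relax to the fixed point of the input", {
  # isolate a sheet: no lateral coupling, no feedback
  cfg <- small_config(lateral = list(exc_amp = 1e-9, inh_amp = 1e-12),
                      feedback = list(b_t = 0, b_v = 0))
  net <- build_network(cfg)
  e <- matrix(0, 21, 21); e[11, 11] <- 5    # sub-threshold constant input
  out <- pps_step(net, e_t = e, n_steps = 400, learn = FALSE)
  expect_equal(out$net$state$q_t[11, 11], 5, tolerance = 1e-6)
  # at u = theta the steady-state activation is the sigmoid midpoint
  e2 <- matrix(0, 21, 21); e2[11, 11] <- cfg$neurons$theta[["t"]]
  out2 <- pps_step(build_network(cfg), e_t = e2, n_steps = 600, learn = FALSE)
  z <- ppsrecal:::act_r(out2$net$state$q_t[11, 11], cfg$neurons, "t")
  expect_equal(z, (cfg$neurons$f_min[["t"]] + cfg$neurons$f_max[["t"]]) / 2,
               tolerance = 1e-4)
})

test_that("one integration step matches an independent R implementation", {
  cfg <- small_config()
  net <- build_network(cfg)
  # put the network in a structured non-trivial state
  set.seed(99)
  net$state$q_t <- matrix(runif(441, 0, 18), 21, 21)
  net$state$q_v <- matrix(runif(441, 0, 18), 21, 21)
  net$state$q_m <- 12
  e_t <- external_input(net, "tactile", 0, position = c(5, 5))
  e_v <- external_input(net, "visual", 0, position = 40, velocity = 0)

  ref <- ppsrecal:::step_reference(net, e_t, e_v)
  out <- pps_step(net, e_t = e_t, e_v = e_v, n_steps = 1, learn = TRUE)
  expect_equal(out$net$state$q_t, ref$q_t, tolerance = 1e-12)
  expect_equal(out$net$state$q_v, ref$q_v, tolerance = 1e-12)
  expect_equal(out$net$state$q_m, ref$q_m, tolerance = 1e-12)
  expect_equal(out$net$state$W_t, ref$W_t, tolerance = 1e-12)
  expect_equal(out$net$state$W_v, ref$W_v, tolerance = 1e-12)
})

test_that("the Hebbian rule has its closed-form special cases", {
  W0 <- matrix(2, 3, 3)
  # no post-synaptic drive and weights at basal: nothing moves
  expect_equal(hebbian_step(W0, W0, 2, matrix(1, 3, 3), z_m = 0.01,
                            rho0 = 1e-3, gate = 0.05, k_h = 1e-3), W0)
  # saturated weights: reinforcement is silenced, only forgetting acts
  Wmax <- 2
  out <- hebbian_step(W0, matrix(1, 3, 3), Wmax, matrix(1, 3, 3), z_m = 1,
                      rho0 = 1e-3, gate = 0.05, k_h = 1e-3)
  expect_true(all(out < W0))                 # decays toward the lower basal
  expect_equal(out, W0 - 1e-3 * (W0 - 1), tolerance = 1e-15)
  # weights never exceed the saturation bound or drop below zero
  big <- hebbian_step(matrix(1.999, 3, 3), matrix(0, 3, 3), 2,
                      matrix(1, 3, 3), z_m = 1, rho0 = 10, gate = 0.05,
                      k_h = 0)
  expect_true(all(big <= 2))
})

test_that("forgetting follows the discrete exponential decay exactly", {
  cfg <- small_config(hebb = list(tau_h_s = 2))
  net <- build_network(cfg)
  # potentiate some visual weights, then let the network idle
  dW <- matrix(0, 21, 21); dW[5:8, 9:12] <- 3
  net$state$W_v <- net$par$W0_v + dW
  n <- 4000
  out <- pps_step(net, n_steps = n, learn = TRUE)
  expected <- dW * (1 - net$par$k_h)^n
  got <- out$net$state$W_v - net$par$W0_v
  expect_lt(max(abs(got - expected)) / max(expected), 1e-10)
  # no stimulation: multisensory activity never crossed the learning gate
  expect_lt(max(out$zm), cfg$hebb$gate_theta)
})

test_that("network reaction times decode by threshold crossing", {
  expect_true(is.na(decode_rt(rep(0, 500))))
  ramp <- seq(0, 10, length.out = 301)      # crosses 4 at step 120
  expect_equal(decode_rt(ramp, p_th = 4), 121)
  expect_equal(decode_rt(c(0, 0, 5), p_th = 4), 3)
  expect_error(decode_rt(numeric(0)), "empty")
})

test_that("with frozen weights, RT is monotone in proximity and unisensory RT flat", {
  net <- build_network(pps_config())
  rts <- vapply(exp1_distances(), function(d) {
    run_trial(net, d, iti_ms = 0, learn = FALSE)$rt_ms
  }, numeric(1))
  expect_true(all(diff(rts) >= 0))          # nearer = faster
  expect_gt(rts[6] - rts[1], 5)             # a real distance effect
  uni <- run_trial(net, NA, iti_ms = 0, learn = FALSE)$rt_ms
  # far multisensory converges on the unisensory level; near is faster
  expect_lt(abs(rts[6] - uni), 2)
  expect_lt(rts[1], uni)
  # multisensory trial with the visual stimulus still very far at touch
  far <- run_trial(net, 195, iti_ms = 0, learn = FALSE)$rt_ms
  expect_equal(far, uni, tolerance = 1)
})

test_that("activities and weights respect their bounds during stimulation", {
  cfg <- pps_config()
  net <- build_network(cfg)
  res <- run_trial(net, 55.25, iti_ms = 100)
  n2 <- cfg$grid$n^2
  expect_true(all(res$net$state$W_t >= 0 &
                    res$net$state$W_t <= cfg$feedforward$w0_t))
  expect_true(all(res$net$state$W_v >= 0 &
                    res$net$state$W_v <= cfg$feedforward$w0_v))
  out <- pps_step(res$net, n_steps = 5)
  expect_true(all(out$sum_zt >= 0 & out$sum_zt <= n2))
  expect_true(all(out$zm >= 0 & out$zm <= 1))
})

test_that("without forgetting, repeated identical trials only speed up", {
  cfg <- pps_config(hebb = list(tau_h_s = 1e9))   # k_H ~ 0
  net <- build_network(cfg)
  r1 <- run_trial(net, 103.25, iti_ms = 500)
  r2 <- run_trial(r1$net, 103.25, iti_ms = 500)
  expect_lte(r2$rt_ms, r1$rt_ms)
  # weights only grew
  expect_true(all(r2$net$state$W_v - net$par$W0_v >= -1e-12))
})

test_that("tactile-only sessions leave the visual far field at basal weights", {
  cfg <- pps_config()
  net <- build_network(cfg)
  for (i in 1:3) net <- run_trial(net, NA, iti_ms = 500)$net
  dW <- net$state$W_v - net$par$W0_v
  far <- net$par$D_v > 100
  expect_lt(max(abs(dW[far])), 1e-6)
})

test_that("identical seeds reproduce identical sessions (determinism)", {
  sch <- session_schedule(distances_cm = c(40, 70, 100), n_reps = 2, seed = 5)
  cfg <- small_config(stimulus = list(start_distance = 150))
  a <- run_session(cfg, schedule = sch)
  b <- run_session(cfg, schedule = sch)
  expect_identical(a, b)
  # schedules permute reproducibly and reuse across sweeps
  expect_identical(session_schedule(seed = 2), session_schedule(seed = 2))
  expect_false(identical(session_schedule(seed = 2),
                         session_schedule(seed = 3)))
})

test_that("history labelling of simulated sessions follows the split rules", {
  d <- c(100, 40, 70, 70, NA, 70, 100, 40, 70)
  lab <- ppsrecal:::history_labels(d)
  expect_equal(lab, c("excluded",            # first trial
                      "excluded",            # extreme (smallest level)
                      "smaller",             # 40 -> 70
                      "excluded",            # same distance
                      "excluded",            # unisensory trial itself
                      "excluded",            # preceded by unisensory
                      "excluded",            # extreme (largest level)
                      "excluded",            # extreme
                      "smaller"))            # 40 -> 70 again
})
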