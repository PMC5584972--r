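test_that("zero initial condition stays zero and CFL violations are rejected", {
  p <- rd_params(D = 1, alpha_IL = 1, alpha_LI = 1, k = 1)
  x <- seq(0, 20, by = 0.5)
  init <- rd_state(x, rep(0, length(x)), rep(0, length(x)))
  run <- simulate_rd(p, init, t_end = 2, dt_out = 1)
  expect_true(all(vapply(run$states, function(s) all(s$I == 0 & s$L == 0),
                         TRUE)))
  expect_error(simulate_rd(p, init, t_end = 1, dt = 0.5), "CFL")
})

test_that("spatially uniform states reproduce the well-mixed kinetics", {
  p <- rd_params(D = 1, mu_I = 0, mu_L = 0, alpha_IL = 2, alpha_LI = 2,
                 k = 1)
  x <- seq(0, 5, by = 0.25)
  init <- rd_state(x, rep(0.1, length(x)), rep(0.1, length(x)))
  run <- simulate_rd(p, init, t_end = 3, dt = 0.005, dt_out = 1)
  hp <- hypercycle_params(alpha_12 = 2, alpha_21 = 2, K = 1)
  traj <- simulate_hypercycle(hp, c(0.1, 0.1), t_end = 3, dt_out = 1,
                              atol = 1e-12, rtol = 1e-10)
  for (m in seq_along(run$times)) {
    ode_val <- traj$Phi1[abs(traj$time - run$times[m]) < 1e-9]
    rel <- abs(run$states[[m]]$I - ode_val) / ode_val
    expect_lt(max(rel), 1e-6)
  }
})

test_that("diffusion alone conserves mass under no-flux boundaries", {
  p <- rd_params(D = 1, mu_I = 0, mu_L = 0, alpha_IL = 1, alpha_LI = 1,
                 k = 1)
  x <- seq(0, 30, by = 0.25)
  I0 <- exp(-(x - 10)^2)
  init <- rd_state(x, I0, rep(0, length(x)))   # L = 0: no reaction at all
  run <- simulate_rd(p, init, t_end = 5, dt_out = 1)
  mass <- vapply(run$states, function(s) sum(s$I), 0)
  expect_lt(max(abs(mass - mass[1]) / mass[1]), 1e-8)
  expect_true(all(vapply(run$states, function(s) all(s$L == 0), TRUE)))
})

test_that("a single Malthusian species advances at the Fisher speed", {
  p <- rd_params(D = 1, mu_I = 1, mu_L = 0, alpha_IL = 0, alpha_LI = 0,
                 k = 1)
  init <- rd_step_init(p, length_domain = 250, dx = 0.2, r0 = 10,
                       composition = c(1, 0))
  run <- simulate_rd(p, init, t_end = 100)
  tr <- measure_front_speed(run, threshold = 0.5)
  expect_lt(abs(tr$speed_I - fisher_speed(1, 1)) / 2, 0.05)
})

test_that("the obligate mutualistic front is pushed: speed and bulk match the closed forms", {
  p <- rd_params(D = 1, mu_I = 0, mu_L = 0, alpha_IL = 1, alpha_LI = 1,
                 k = 1)
  init <- rd_step_init(p, length_domain = 120, dx = 0.25, r0 = 10)
  run <- simulate_rd(p, init, t_end = 80)
  tr <- measure_front_speed(run, threshold = 0.25)
  v_th <- mutualistic_front_speed(1, 1, 1, 1)
  expect_lt(abs(tr$speed_I - v_th) / v_th, 0.03)
  expect_lt(abs(tr$speed_L - v_th) / v_th, 0.03)
  # identical parameters and identical initial profiles: identical traces
  expect_equal(tr$pos_I, tr$pos_L)
  # bulk composition behind the front matches the analytic fractions
  s_end <- run$states[[length(run$states)]]
  i_bulk <- which(s_end$x <= 5)
  expect_lt(max(abs(s_end$I[i_bulk] - 0.5)) / 0.5, 0.01)
  expect_lt(max(abs(s_end$L[i_bulk] - 0.5)) / 0.5, 0.01)
})

test_that("asymmetric cross terms set the bulk composition", {
  p <- rd_params(D = 1, alpha_IL = 1, alpha_LI = 3, k = 1)
  init <- rd_step_init(p, length_domain = 100, dx = 0.25, r0 = 10)
  run <- simulate_rd(p, init, t_end = 50)
  eps <- bulk_fractions(3)
  s_end <- run$states[[length(run$states)]]
  i_bulk <- which(s_end$x <= 5)
  expect_lt(max(abs(s_end$I[i_bulk] - eps["eps_I"])) / eps["eps_I"], 0.01)
  expect_lt(max(abs(s_end$L[i_bulk] - eps["eps_L"])) / eps["eps_L"], 0.01)
})

test_that("halving dx changes the measured pushed-front speed by under one percent", {
  speeds <- vapply(c(0.5, 0.25), function(dx) {
    p <- rd_params(D = 1, alpha_IL = 1, alpha_LI = 1, k = 1)
    init <- rd_step_init(p, length_domain = 80, dx = dx, r0 = 8)
    run <- simulate_rd(p, init, t_end = 50)
    measure_front_speed(run, threshold = 0.25)$speed_I
  }, 0)
  expect_lt(abs(diff(speeds)) / speeds[2], 0.01)
})

test_that("front measurement demands domain clearance and enough states", {
  p <- rd_params(D = 1, alpha_IL = 1, alpha_LI = 1, k = 1)
  init <- rd_step_init(p, length_domain = 25, dx = 0.25, r0 = 10)
  run <- simulate_rd(p, init, t_end = 40)
  expect_error(measure_front_speed(run, threshold = 0.25), "boundary")
  short <- simulate_rd(p, rd_step_init(p, 60, 0.25, 10), t_end = 2,
                       dt_out = 0.5)
  expect_error(measure_front_speed(short, threshold = 0.25))
})

test_that("profiles: coupled fronts at mu = 0, lag and exclusion as mu approaches the caps", {
  caps <- c(9.13e-2, 2.18e-1)
  run_profile <- function(f) {
    p <- rd_params(D = 1, mu_I = f * caps[1], mu_L = f * caps[2],
                   alpha_IL = 1, alpha_LI = 1, k = 1)
    init <- rd_step_init(p, length_domain = 120, dx = 0.25, r0 = 10)
    simulate_rd(p, init, t_end = 70)
  }
  front_gap <- function(run, tt) {
    s <- run$states[[which.min(abs(run$times - tt))]]
    fI <- max(s$x[s$I >= 0.25])
    fL <- max(s$x[s$L >= 0.25])
    fL - fI
  }
  r0 <- run_profile(0)
  expect_lt(abs(front_gap(r0, 70)), 2 * 0.25)
  r1 <- run_profile(1)
  gaps <- vapply(c(30, 50, 70), function(tt) front_gap(r1, tt), 0)
  expect_true(all(diff(gaps) > 0))   # the slower mutualist falls behind
  prof <- export_profiles(r0, c(0, 35, 70))
  expect_equal(sort(unique(prof$time)), c(0, 35, 70))
  expect_error(export_profiles(r0, 1000))
})

test_that("radial geometry relaxes to the planar behaviour at large radius", {
  p <- rd_params(D = 1, alpha_IL = 1, alpha_LI = 1, k = 1,
                 geometry = "radial")
  init <- rd_step_init(p, length_domain = 120, dx = 0.25, r0 = 15)
  run <- simulate_rd(p, init, t_end = 70)
  tr <- measure_front_speed(run, threshold = 0.25)
  v_th <- mutualistic_front_speed(1, 1, 1, 1)
  # curvature slows a radial front by about D / r
  expect_lt(tr$speed_I, v_th)
  in_window <- tr$times >= tr$fit_window[1]
  r_mean <- mean(tr$pos_I[in_window])
  v_curv <- v_th - 1 / r_mean
  expect_lt(abs(tr$speed_I - v_curv) / v_th, 0.02)
})

test_that("the mu sweep interpolates between pushed and pulled invasion", {
  base <- rd_params(D = 1, alpha_IL = 1, alpha_LI = 1, k = 1)
  caps <- c(9.13e-2, 2.18e-1)
  sweep <- speed_vs_mu_sweep(base, fractions = c(0, 0.5, 1), caps = caps,
                             length_domain = 250, dx = 0.25, r0 = 10,
                             t_end = 120, threshold = 0.25)
  v_push <- mutualistic_front_speed(1, 1, 1, 1)
  # obligate point: both species at the pushed speed
  expect_lt(abs(sweep$speed_I[1] - v_push) / v_push, 0.03)
  expect_lt(abs(sweep$speed_L[1] - v_push) / v_push, 0.03)
  # faster species accelerates monotonically with the Malthusian fraction
  expect_true(all(diff(sweep$speed_L) > 0))
  # obligate point is the sweep's minimum overall speed
  expect_equal(which.min(pmax(sweep$speed_I, sweep$speed_L)), 1L)
})
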