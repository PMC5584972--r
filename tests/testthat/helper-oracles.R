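# Independent oracles used across the suite. These deliberately avoid the
# package's own solvers: the ODE oracle is a plain fixed-step RK4 loop, and
# the edge/area summaries are computed directly from raw matrices.

# fixed-step classical RK4 for a generic RHS f(t, y) -> dy
rk4_oracle <- function(f, y0, t_end, dt = 1e-4, sample_times = NULL) {
  n_steps <- ceiling(t_end / dt)
  dt <- t_end / n_steps
  y <- y0
  t <- 0
  out_t <- numeric(0)
  out_y <- NULL
  maybe_store <- function(t, y) {
    if (is.null(sample_times) ||
        any(abs(sample_times - t) < dt / 2)) {
      out_t <<- c(out_t, t)
      out_y <<- rbind(out_y, y)
    }
  }
  maybe_store(t, y)
  for (i in seq_len(n_steps)) {
    k1 <- f(t, y)
    k2 <- f(t + dt / 2, y + dt / 2 * k1)
    k3 <- f(t + dt / 2, y + dt / 2 * k2)
    k4 <- f(t + dt, y + dt * k3)
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- i * dt
    maybe_store(t, y)
  }
  list(t = out_t, y = out_y)
}

hypercycle_rhs <- function(p) {
  function(t, y) {
    sat <- 1 - (y[1] + y[2]) / p$K
    c(p$alpha_12 * y[1] * y[2] * sat - p$delta_1 * y[1],
      p$alpha_21 * y[1] * y[2] * sat - p$delta_2 * y[2])
  }
}

# area-equivalent colony radius trace and its trailing-window OLS slope
area_expansion_speed <- function(run, frac = 0.3) {
  lg <- run$log
  ra <- sqrt((lg$N_I + lg$N_L + lg$N_P) / pi)
  n <- nrow(lg)
  idx <- seq.int(floor(n * (1 - frac)) + 1L, n)
  unname(stats::coef(stats::lm(ra[idx] ~ lg$step[idx]))[2])
}

# growth-permitted fraction among cells in the outermost per-ray band
edge_gated_fraction <- function(state, shell = 6) {
  occ <- which(state$strain > 0, arr.ind = TRUE)
  dy <- occ[, 1] - state$centre[1]
  dx <- occ[, 2] - state$centre[2]
  r <- sqrt(dx^2 + dy^2)
  th <- atan2(dy, dx) %% (2 * pi)
  nb <- max(8, ceiling(pi * max(r)))
  b <- pmin(floor(th / (2 * pi) * nb) + 1, nb)
  rmax <- tapply(r, b, max)
  edge <- r >= rmax[as.character(b)] - shell
  mean(state$permitted[occ][edge])
}

# P-strain frequency among edge sites restricted to a row subset
edge_p_frequency_rows <- function(state, rows, shell = 3) {
  occ <- which(state$strain > 0, arr.ind = TRUE)
  dy <- occ[, 1] - state$centre[1]
  dx <- occ[, 2] - state$centre[2]
  r <- sqrt(dx^2 + dy^2)
  th <- atan2(dy, dx) %% (2 * pi)
  nb <- max(8, ceiling(pi * max(r)))
  b <- pmin(floor(th / (2 * pi) * nb) + 1, nb)
  rmax <- tapply(r, b, max)
  edge <- r >= rmax[as.character(b)] - shell
  keep <- edge & occ[, 1] %in% rows
  mean(state$strain[occ][keep] == 3L)
}
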