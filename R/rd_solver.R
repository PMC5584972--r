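#' Parameters of the two-species mutualistic reaction-diffusion system
#'
#' The system
#' `dI/dt = D d2I/dr2 + (mu_I I + alpha_IL I L)(1 - (I+L)/k)` (and the L
#' counterpart) combines Malthusian growth (set by supplemented amino
#' acids) with cross-catalytic mutualistic growth confined to low densities
#' by the shared logistic term.
#'
#' @param D Shared diffusion coefficient (length^2/time), `> 0`.
#' @param mu_I,mu_L Malthusian rates (1/time), `>= 0`.
#' @param alpha_IL,alpha_LI Cross terms (1/(density * time)), `>= 0`.
#' @param k Carrying capacity (density), `> 0`.
#' @param geometry `"planar"` (default; the asymptotic-front limit where
#'   curvature is negligible) or `"radial"` (cylindrical Laplacian
#'   `(1/r) d/dr (r dU/dr)` for finite-radius studies).
#' @return Object of class `rd_params`.
#' @export
rd_params <- function(D = 1, mu_I = 0, mu_L = 0, alpha_IL = 1, alpha_LI = 1,
                      k = 1, geometry = c("planar", "radial")) {
  geometry <- match.arg(geometry)
  stopifnot(D > 0, mu_I >= 0, mu_L >= 0, alpha_IL >= 0, alpha_LI >= 0, k > 0)
  structure(list(D = D, mu_I = mu_I, mu_L = mu_L,
                 alpha_IL = alpha_IL, alpha_LI = alpha_LI, k = k,
                 geometry = geometry),
            class = "rd_params")
}

#' Discretised state of the RD system
#'
#' @param x Uniform grid coordinates (length units), strictly increasing.
#' @param I,L Density arrays on the grid (non-negative).
#' @param time Time stamp (default 0).
#' @return Object of class `rd_state`.
#' @export
rd_state <- function(x, I, L, time = 0) {
  stopifnot(length(x) == length(I), length(x) == length(L),
            all(I >= 0), all(L >= 0))
  dx <- diff(x)
  stopifnot(all(abs(dx - dx[1]) < 1e-9 * dx[1]))
  structure(list(x = x, I = I, L = L, time = time, dx = dx[1]),
            class = "rd_state")
}

#' Step initial condition seeded at the bulk front composition
#'
#' Builds an `rd_state` with both species at their asymptotic bulk
#' composition `k * bulk_fractions(alpha_star)` on `r in [0, r0]` and zero
#' elsewhere, which seeds the pushed front close to its travelling shape.
#'
#' @param params An [rd_params()] object.
#' @param length_domain Domain length.
#' @param dx Grid spacing.
#' @param r0 Width of the occupied step.
#' @param composition Optional length-2 densities `(I, L)` of the step;
#'   default is the bulk-fraction split of `k` (equal split if either cross
#'   term is zero).
#' @return An `rd_state`.
#' @export
rd_step_init <- function(params, length_domain, dx, r0,
                         composition = NULL) {
  stopifnot(inherits(params, "rd_params"), length_domain > r0, r0 > 0, dx > 0)
  x <- seq(0, length_domain, by = dx)
  if (is.null(composition)) {
    if (params$alpha_IL > 0 && params$alpha_LI > 0) {
      eps <- bulk_fractions(params$alpha_LI / params$alpha_IL)
      composition <- params$k * as.numeric(eps)
    } else {
      composition <- rep(params$k / 2, 2)
    }
  }
  step <- as.numeric(x <= r0)
  rd_state(x, composition[1] * step, composition[2] * step)
}

# semi-discrete RHS: central-difference Laplacian with no-flux (zero
# gradient) boundaries, written in flux form so diffusion conserves mass
.rd_rhs <- function(I, L, params, dx, rgrid = NULL) {
  lap <- function(y) {
    n <- length(y)
    if (is.null(rgrid)) {
      (c(y[1], y[-n]) - 2 * y + c(y[-1], y[n])) / dx^2
    } else {
      # radial flux form: (1/r) d/dr (r dU/dr) on faces, zero-flux ends
      rf <- (rgrid[-1] + rgrid[-n]) / 2
      flux <- rf * diff(y) / dx            # r * dU/dr at interior faces
      (c(flux, 0) - c(0, flux)) / (rgrid * dx)
    }
  }
  sat <- 1 - (I + L) / params$k
  list(I = params$D * lap(I) + (params$mu_I * I + params$alpha_IL * I * L) * sat,
       L = params$D * lap(L) + (params$mu_L * L + params$alpha_LI * I * L) * sat)
}

#' Integrate the reaction-diffusion system
#'
#' Explicit method-of-lines integration: central differences in space
#' (no-flux boundaries, flux form) and classical fourth-order Runge-Kutta
#' in time, guarded by the diffusive CFL condition `D dt / dx^2 <= 0.25`.
#'
#' @param params An [rd_params()] object.
#' @param init An `rd_state` initial condition (see [rd_step_init()]).
#' @param t_end Final time.
#' @param dt Time step; default `0.2 * dx^2 / D` (CFL-compliant).
#' @param dt_out Interval at which states are stored; default `t_end/100`.
#' @return Object of class `rd_run`: list with `times`, `states` (list of
#'   `rd_state`), and `params`.
#' @export
simulate_rd <- function(params, init, t_end, dt = NULL, dt_out = t_end / 100) {
  stopifnot(inherits(params, "rd_params"), inherits(init, "rd_state"),
            t_end > 0)
  dx <- init$dx
  if (is.null(dt)) dt <- 0.2 * dx^2 / params$D
  cfl <- params$D * dt / dx^2
  if (cfl > 0.25) {
    stop(sprintf("CFL violation: D*dt/dx^2 = %.3g > 0.25; use dt <= %.3g",
                 cfl, 0.25 * dx^2 / params$D))
  }
  rgrid <- if (params$geometry == "radial") pmax(init$x, dx / 2) else NULL
  n_out <- max(1L, round(t_end / dt_out))
  steps_per_out <- max(1L, ceiling(dt_out / dt))
  dt <- dt_out / steps_per_out   # land exactly on output times
  I <- init$I; L <- init$L
  states <- vector("list", n_out + 1)
  states[[1]] <- rd_state(init$x, I, L, init$time)
  times <- init$time + dt_out * (0:n_out)
  cap <- params$k * (1 + 1e-9)
  for (m in seq_len(n_out)) {
    for (s in seq_len(steps_per_out)) {
      k1 <- .rd_rhs(I, L, params, dx, rgrid)
      k2 <- .rd_rhs(I + dt / 2 * k1$I, L + dt / 2 * k1$L, params, dx, rgrid)
      k3 <- .rd_rhs(I + dt / 2 * k2$I, L + dt / 2 * k2$L, params, dx, rgrid)
      k4 <- .rd_rhs(I + dt * k3$I, L + dt * k3$L, params, dx, rgrid)
      I <- I + dt / 6 * (k1$I + 2 * k2$I + 2 * k3$I + k4$I)
      L <- L + dt / 6 * (k1$L + 2 * k2$L + 2 * k3$L + k4$L)
    }
    if (anyNA(I) || anyNA(L) || any(!is.finite(I)) || any(!is.finite(L))) {
      stop("NaN/Inf detected at t = ", times[m + 1],
           "; reduce dt or check parameters")
    }
    I <- pmin(pmax(I, 0), cap)
    L <- pmin(pmax(L, 0), cap)
    states[[m + 1]] <- rd_state(init$x, I, L, times[m + 1])
  }
  structure(list(times = times, states = states, params = params,
                 dt = dt, dx = dx),
            class = "rd_run")
}

# outermost position where a density profile crosses `level` (linear
# sub-grid interpolation); NA if never above the level
.front_position <- function(x, y, level) {
  above <- y >= level
  if (!any(above)) return(NA_real_)
  i <- max(which(above))
  if (i == length(x)) return(x[i])
  x[i] + (level - y[i]) / (y[i + 1] - y[i]) * (x[i + 1] - x[i])
}

#' Track front positions and fit the front speed
#'
#' The front position of each species is the outermost grid location where
#' its density crosses `threshold * k` (linear sub-grid interpolation); the
#' speed is the OLS slope of position versus time over the trailing
#' `fit_fraction` of the trace.
#'
#' @param run An `rd_run` from [simulate_rd()].
#' @param threshold Front threshold as a fraction of `k` (default 0.5).
#' @param fit_fraction Trailing fraction of the trace used in the speed fit
#'   (default 0.5).
#' @param boundary_margin Minimum clearance (in grid spacings) between the
#'   front and the domain end during the fit window (default 5); violation
#'   means the domain was too small and is an error.
#' @return Object of class `front_trace`: list with `times`, `pos_I`,
#'   `pos_L`, and per-species `speed`, `se`, plus the fit window.
#' @export
measure_front_speed <- function(run, threshold = 0.5, fit_fraction = 0.5,
                                boundary_margin = 5) {
  stopifnot(inherits(run, "rd_run"), length(run$states) >= 10,
            threshold > 0, threshold < 1,
            fit_fraction > 0, fit_fraction <= 1)
  level <- threshold * run$params$k
  x <- run$states[[1]]$x
  pos_I <- vapply(run$states, function(s) .front_position(x, s$I, level), 0)
  pos_L <- vapply(run$states, function(s) .front_position(x, s$L, level), 0)
  n <- length(run$times)
  fit_idx <- seq.int(ceiling(n * (1 - fit_fraction)) + 1L, n)
  lim <- max(x) - boundary_margin * run$dx
  fit_one <- function(pos) {
    p <- pos[fit_idx]; t <- run$times[fit_idx]
    ok <- !is.na(p)
    if (sum(ok) < 3) return(list(speed = NA_real_, se = NA_real_))
    if (any(p[ok] > lim)) {
      stop("front reached the domain boundary inside the fit window; ",
           "enlarge the domain")
    }
    fit <- stats::lm(p[ok] ~ t[ok])
    list(speed = unname(stats::coef(fit)[2]),
         se = summary(fit)$coefficients[2, 2])
  }
  fI <- fit_one(pos_I); fL <- fit_one(pos_L)
  structure(list(times = run$times, pos_I = pos_I, pos_L = pos_L,
                 speed_I = fI$speed, se_I = fI$se,
                 speed_L = fL$speed, se_L = fL$se,
                 threshold = threshold,
                 fit_window = range(run$times[fit_idx])),
            class = "front_trace")
}

#' @export
print.front_trace <- function(x, ...) {
  cat(sprintf("front_trace: speed_I = %.5g (se %.2g), speed_L = %.5g (se %.2g)\n",
              x$speed_I, x$se_I, x$speed_L, x$se_L))
  invisible(x)
}

#' Front-speed sweep from obligate mutualism to competition
#'
#' Scans the fraction `f` of the maximal Malthusian rates
#' `(mu_CI, mu_CL)` applied on top of fixed cross terms, running
#' [simulate_rd()] + [measure_front_speed()] at each point. At `f = 0` both
#' species travel together at the pushed mutualistic speed (the minimum of
#' the sweep); at large `f` the faster Malthusian species pulls ahead
#' toward its Fisher speed and the slower one is left behind.
#'
#' @param base An [rd_params()] object providing `D`, cross terms and `k`
#'   (its `mu` fields are overridden).
#' @param fractions Numeric vector of fractions in `[0, 1]`, or a 2-column
#'   matrix of per-species fractions `(f_I, f_L)`.
#' @param caps Length-2 maximal Malthusian rates `(mu_CI, mu_CL)` (1/time).
#' @param length_domain,dx,r0,t_end Simulation geometry and duration passed
#'   to [rd_step_init()]/[simulate_rd()].
#' @param ... Further arguments to [measure_front_speed()].
#' @return Data frame with columns `f_I`, `f_L`, `mu_I`, `mu_L`, `speed_I`,
#'   `speed_L`.
#' @export
speed_vs_mu_sweep <- function(base, fractions, caps,
                              length_domain = 300, dx = 0.25, r0 = 10,
                              t_end = 150, ...) {
  stopifnot(inherits(base, "rd_params"), length(caps) == 2, all(caps >= 0))
  fr <- if (is.matrix(fractions)) fractions else cbind(fractions, fractions)
  stopifnot(all(fr >= 0), all(fr <= 1))
  rows <- lapply(seq_len(nrow(fr)), function(i) {
    p <- rd_params(D = base$D, mu_I = fr[i, 1] * caps[1],
                   mu_L = fr[i, 2] * caps[2],
                   alpha_IL = base$alpha_IL, alpha_LI = base$alpha_LI,
                   k = base$k, geometry = base$geometry)
    init <- rd_step_init(p, length_domain, dx, r0)
    run <- simulate_rd(p, init, t_end)
    tr <- measure_front_speed(run, ...)
    data.frame(f_I = fr[i, 1], f_L = fr[i, 2],
               mu_I = p$mu_I, mu_L = p$mu_L,
               speed_I = tr$speed_I, speed_L = tr$speed_L)
  })
  do.call(rbind, rows)
}

#' Export density profiles at requested times
#'
#' @param run An `rd_run`.
#' @param times_requested Times at which profiles are wanted; the nearest
#'   stored states are used.
#' @return Long data frame with columns `time`, `r`, `I`, `L`.
#' @export
export_profiles <- function(run, times_requested) {
  stopifnot(inherits(run, "rd_run"),
            all(times_requested >= min(run$times)),
            all(times_requested <= max(run$times)))
  rows <- lapply(times_requested, function(tt) {
    s <- run$states[[which.min(abs(run$times - tt))]]
    data.frame(time = s$time, r = s$x, I = s$I, L = s$L)
  })
  do.call(rbind, rows)
}
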