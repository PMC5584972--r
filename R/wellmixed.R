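#' Parameters of the two-member hypercycle
#'
#' Cross-catalytic replication rates, death rates and shared carrying
#' capacity of the two-member hypercycle
#' `dPhi1/dt = alpha_12 Phi1 Phi2 (1 - (Phi1+Phi2)/K) - delta_1 Phi1`
#' (and symmetrically for Phi2). Second-order kinetics mean neither member
#' can proliferate without the other.
#'
#' @param alpha_12,alpha_21 Cross-catalytic replication rates
#'   (1/(density * time)), `>= 0`.
#' @param delta_1,delta_2 Death rates (1/time), `>= 0`. Default 0: the
#'   logistic term is taken to capture growth inhibition.
#' @param K Carrying capacity (density), `> 0`.
#' @return Object of class `hypercycle_params`.
#' @export
hypercycle_params <- function(alpha_12, alpha_21, delta_1 = 0, delta_2 = 0, K) {
  stopifnot(alpha_12 >= 0, alpha_21 >= 0, delta_1 >= 0, delta_2 >= 0, K > 0)
  structure(list(alpha_12 = alpha_12, alpha_21 = alpha_21,
                 delta_1 = delta_1, delta_2 = delta_2, K = K),
            class = "hypercycle_params")
}

#' Parameters of the three-member community (mutualists plus parasite)
#'
#' Extends the hypercycle to a third strain P that consumes one of the
#' cross-fed amino acids without reciprocating. The minimal form keeps the
#' shared logistic saturation and gives P a single cross term with its
#' donor mutualist:
#' `dP/dt = (mu_P P + alpha_P P * donor)(1 - N/k)`, `N = I + L + P`.
#'
#' @param mu_I,mu_L,mu_P Malthusian rates (1/time), `>= 0`; zero in the
#'   obligate scenario.
#' @param alpha_IL,alpha_LI Mutualist cross terms (1/(density * time)).
#' @param alpha_P Parasite coupling to its donor (1/(density * time)).
#' @param donor Which mutualist feeds P: `"I"` (P consumes the amino acid
#'   secreted by I, the default, matching the lattice model's sensing
#'   assignment where P cells sense leucine) or `"L"`.
#' @param k Shared carrying capacity (density), `> 0`.
#' @return Object of class `community_params`.
#' @export
community_params <- function(mu_I = 0, mu_L = 0, mu_P = 0,
                             alpha_IL, alpha_LI, alpha_P,
                             donor = c("I", "L"), k) {
  donor <- match.arg(donor)
  stopifnot(mu_I >= 0, mu_L >= 0, mu_P >= 0,
            alpha_IL >= 0, alpha_LI >= 0, alpha_P >= 0, k > 0)
  structure(list(mu_I = mu_I, mu_L = mu_L, mu_P = mu_P,
                 alpha_IL = alpha_IL, alpha_LI = alpha_LI,
                 alpha_P = alpha_P, donor = donor, k = k),
            class = "community_params")
}

.as_trajectory <- function(out, names, params, atol, rtol) {
  df <- as.data.frame(out)
  colnames(df) <- c("time", names)
  # clamp tiny negative solver undershoot without hiding real negativity
  for (nm in names) df[[nm]] <- ifelse(df[[nm]] < 0 & df[[nm]] > -10 * atol,
                                       0, df[[nm]])
  structure(df, params = params, atol = atol, rtol = rtol,
            class = c("wellmixed_trajectory", "data.frame"))
}

#' Integrate the two-member hypercycle
#'
#' Adaptive integration (lsoda) of the hypercycle ODEs from a non-negative
#' initial density pair.
#'
#' @param params A [hypercycle_params()] object.
#' @param y0 Initial densities, length-2 non-negative numeric `(Phi1, Phi2)`.
#' @param t_end Final time (`> 0`).
#' @param dt_out Output sampling interval; default `t_end/200`.
#' @param atol,rtol Solver tolerances.
#' @return A `wellmixed_trajectory` data frame with columns `time`, `Phi1`,
#'   `Phi2`; solver settings and parameters kept as attributes.
#' @export
simulate_hypercycle <- function(params, y0, t_end, dt_out = t_end / 200,
                                atol = 1e-9, rtol = 1e-7) {
  stopifnot(inherits(params, "hypercycle_params"),
            length(y0) == 2, all(y0 >= 0), t_end > 0, dt_out > 0)
  rhs <- function(t, y, p) {
    sat <- 1 - (y[1] + y[2]) / p$K
    list(c(p$alpha_12 * y[1] * y[2] * sat - p$delta_1 * y[1],
           p$alpha_21 * y[1] * y[2] * sat - p$delta_2 * y[2]))
  }
  times <- seq(0, t_end, by = dt_out)
  out <- deSolve::ode(unname(y0), times, rhs, params, atol = atol, rtol = rtol)
  if (attr(out, "istate")[1] < 0) {
    stop("hypercycle integration failed: ", paste(attr(out, "istate"), collapse = " "))
  }
  .as_trajectory(out, c("Phi1", "Phi2"), params, atol, rtol)
}

#' Integrate the three-member community
#'
#' Adaptive integration of the mutualist pair plus parasite. With
#' `alpha_P = 0` and `P(0) = 0` the system reduces exactly to the
#' death-free hypercycle.
#'
#' @param params A [community_params()] object.
#' @param y0 Initial densities, length-3 non-negative numeric `(I, L, P)`.
#' @inheritParams simulate_hypercycle
#' @return A `wellmixed_trajectory` data frame with columns `time`, `I`,
#'   `L`, `P`.
#' @export
simulate_community <- function(params, y0, t_end, dt_out = t_end / 200,
                               atol = 1e-9, rtol = 1e-7) {
  stopifnot(inherits(params, "community_params"),
            length(y0) == 3, all(y0 >= 0), t_end > 0, dt_out > 0)
  rhs <- function(t, y, p) {
    sat <- 1 - sum(y) / p$k
    donor_dens <- if (p$donor == "I") y[1] else y[2]
    list(c((p$mu_I * y[1] + p$alpha_IL * y[1] * y[2]) * sat,
           (p$mu_L * y[2] + p$alpha_LI * y[1] * y[2]) * sat,
           (p$mu_P * y[3] + p$alpha_P * y[3] * donor_dens) * sat))
  }
  times <- seq(0, t_end, by = dt_out)
  out <- deSolve::ode(unname(y0), times, rhs, params, atol = atol, rtol = rtol)
  if (attr(out, "istate")[1] < 0) {
    stop("community integration failed: ", paste(attr(out, "istate"), collapse = " "))
  }
  .as_trajectory(out, c("I", "L", "P"), params, atol, rtol)
}

.check_window <- function(times, window) {
  stopifnot(length(window) == 2, window[1] < window[2])
  idx <- which(times >= window[1] & times <= window[2])
  if (length(idx) < 4) stop("need at least 4 points inside the fit window")
  idx
}

#' Malthusian growth rate from a log-linear fit
#'
#' Estimates the exponential growth rate as the ordinary-least-squares slope
#' of `log(signal - background)` against time over a user-chosen window
#' (the exponential regime of a plate-reader time course).
#'
#' @param times,signal Numeric vectors (time, fluorescence or density).
#' @param window Length-2 numeric, fit window `(t0, t1)`.
#' @param background Signal background to subtract (same units as
#'   `signal`); default 0.
#' @return Object of class `growth_fit`: list with `rate` (1/time), `se`,
#'   `r_squared`, `window`, `n`.
#' @export
fit_malthusian_rate <- function(times, signal, window, background = 0) {
  stopifnot(length(times) == length(signal))
  idx <- .check_window(times, window)
  y <- signal[idx] - background
  if (any(y <= 0)) {
    stop("non-positive background-subtracted signal inside window at point(s) ",
         paste(idx[y <= 0], collapse = ", "))
  }
  fit <- stats::lm(log(y) ~ times[idx])
  sm <- suppressWarnings(summary(fit))  # noiseless fixtures fit perfectly
  structure(list(rate = unname(stats::coef(fit)[2]),
                 se = sm$coefficients[2, 2],
                 r_squared = sm$r.squared,
                 window = window, n = length(idx)),
            class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("growth_fit: rate = %.6g (se %.3g, R^2 %.4f, n = %d, window [%g, %g])\n",
              x$rate, x$se, x$r_squared, x$n, x$window[1], x$window[2]))
  invisible(x)
}

#' Hyperbolic (cross-catalytic) growth rates from a coculture time series
#'
#' At low total density the hypercycle kinetics reduce to
#' `dI/dt ~ alpha_IL * I * L` (and symmetrically), so each cross term is
#' estimated as the no-intercept OLS slope of the finite-difference
#' derivative against the density product over the window. Central
#' differences are used at interior points.
#'
#' @param times Sampling times.
#' @param I,L Density time series of the two strains.
#' @param window Length-2 fit window (applied to the interior points where
#'   central differences exist).
#' @param k Carrying capacity used only for the low-density guard.
#' @param guard Maximum allowed `max(I + L)/k` inside the window
#'   (default 0.1): beyond this the low-density approximation is refused.
#' @return List with `alpha_IL` and `alpha_LI`, each a `growth_fit` (rate in
#'   1/(density * time)).
#' @export
fit_hyperbolic_rates <- function(times, I, L, window, k, guard = 0.1) {
  stopifnot(length(times) == length(I), length(times) == length(L), k > 0)
  n <- length(times)
  stopifnot(n >= 6)
  interior <- 2:(n - 1)
  ti <- times[interior]
  idx <- .check_window(ti, window)
  sel <- interior[idx]
  if (max(I[sel] + L[sel]) / k >= guard) {
    stop("window violates the low-density guard: max(I+L)/k = ",
         signif(max(I[sel] + L[sel]) / k, 3), " >= ", guard)
  }
  prod_sel <- I[sel] * L[sel]
  if (all(prod_sel == 0)) stop("degenerate regressor: I*L is zero throughout the window")
  cd <- function(y) (y[sel + 1] - y[sel - 1]) / (times[sel + 1] - times[sel - 1])
  one_fit <- function(dy) {
    fit <- stats::lm(dy ~ 0 + prod_sel)
    sm <- suppressWarnings(summary(fit))  # noiseless fixtures fit perfectly
    structure(list(rate = unname(stats::coef(fit)[1]),
                   se = sm$coefficients[1, 2],
                   r_squared = sm$r.squared,
                   window = window, n = length(sel)),
              class = "growth_fit")
  }
  list(alpha_IL = one_fit(cd(I)), alpha_LI = one_fit(cd(L)))
}

#' Convert a fluorescence signal to cell density
#'
#' Cell concentration scales linearly with fluorescence; densities are
#' recovered as `slope * max(signal - background, 0)`.
#'
#' @param signal Fluorescence reading(s).
#' @param slope Calibration slope (1/ml per fluorescence unit), `> 0`.
#' @param background Fluorescence background; default 0.
#' @return Density (cells/ml), same length as `signal`.
#' @export
fluorescence_to_density <- function(signal, slope, background = 0) {
  stopifnot(slope > 0)
  slope * pmax(signal - background, 0)
}
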