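#' Fisher invasion speed of a single Malthusian species
#'
#' Asymptotic front speed of the one-species Fisher reaction-diffusion
#' equation, `2 * sqrt(mu * D)`. This is the invasion speed of either strain
#' when its mutualistic partner is absent and growth is purely Malthusian,
#' and the asymptotic speed of the two-species system when Malthusian rates
#' dominate the cross terms.
#'
#' @param mu Malthusian growth rate (1/time), `mu >= 0`.
#' @param D Diffusion coefficient (length^2/time), `D > 0`.
#' @return Front speed (length/time).
#' @export
#' @examples
#' fisher_speed(1, 1) # 2
fisher_speed <- function(mu, D) {
  stopifnot(is.numeric(mu), is.numeric(D), all(mu >= 0), all(D > 0))
  2 * sqrt(mu * D)
}

#' Pushed-front speed of the obligate two-species mutualistic loop
#'
#' Closed-form invasion speed of the two-species cross-feeding
#' reaction-diffusion system with zero Malthusian rates:
#' `sqrt(D * k * alpha_IL * alpha_LI / (2 * (alpha_IL + alpha_LI)))`.
#' Unlike the Fisher speed it depends on the carrying capacity `k`, the
#' hallmark of a pushed front driven by the bulk kinetics. Both mutualists
#' travel at this common speed.
#'
#' @param D Diffusion coefficient (length^2/time).
#' @param k Carrying capacity (density).
#' @param alpha_IL,alpha_LI Cross-catalytic growth rates
#'   (1/(density * time)). All arguments must be positive.
#' @return Front speed (length/time).
#' @export
#' @examples
#' mutualistic_front_speed(1, 1, 1, 1) # 0.5
mutualistic_front_speed <- function(D, k, alpha_IL, alpha_LI) {
  stopifnot(D > 0, k > 0, alpha_IL > 0, alpha_LI > 0)
  sqrt(D * k * alpha_IL * alpha_LI / (2 * (alpha_IL + alpha_LI)))
}

#' Dimensionless pushed-front speed
#'
#' Front speed of the obligate mutualistic loop in dimensionless variables,
#' `c = sqrt(alpha_star / (2 * (1 + alpha_star)))`, where
#' `alpha_star = alpha_LI / alpha_IL` is the ratio of the two cross terms.
#' Strictly increasing in `alpha_star` with supremum `1/sqrt(2)`.
#'
#' @param alpha_star Ratio of cross-catalytic rates, `> 0`.
#' @return Dimensionless speed.
#' @export
dimensionless_speed <- function(alpha_star) {
  stopifnot(is.numeric(alpha_star), all(alpha_star > 0))
  sqrt(alpha_star / (2 * (1 + alpha_star)))
}

#' Bulk strain fractions behind the mutualistic front
#'
#' Equilibrium composition of the population behind the travelling front:
#' `eps_I = 1/(1 + alpha_star)`, `eps_L = alpha_star/(1 + alpha_star)`.
#' The species receiving the stronger catalytic boost dominates the bulk;
#' the fractions always sum to one.
#'
#' @inheritParams dimensionless_speed
#' @return Named numeric vector `c(eps_I, eps_L)`.
#' @export
bulk_fractions <- function(alpha_star) {
  stopifnot(is.numeric(alpha_star), all(alpha_star > 0))
  c(eps_I = 1 / (1 + alpha_star), eps_L = alpha_star / (1 + alpha_star))
}

#' Dimensionless transformation of the mutualistic RD system
#'
#' Rescales the two-species reaction-diffusion system to dimensionless
#' densities `I* = I/k`, `L* = L/k`, time `t* = alpha_IL * k * t` and space
#' `r* = sqrt(alpha_IL * k / D) * r`, leaving the single dimensionless
#' parameter `alpha_star = alpha_LI / alpha_IL`. Dimensional front speeds
#' are recovered as `dimensionless_speed(alpha_star) * speed_scale`.
#'
#' @inheritParams mutualistic_front_speed
#' @return Object of class `dimensionless_params`: list with `alpha_star`,
#'   `time_scale` (1/time), `length_scale` (1/length), `speed_scale`
#'   (length/time).
#' @export
nondimensionalize <- function(D, k, alpha_IL, alpha_LI) {
  stopifnot(D > 0, k > 0, alpha_IL > 0, alpha_LI > 0)
  structure(list(
    alpha_star   = alpha_LI / alpha_IL,
    time_scale   = alpha_IL * k,
    length_scale = sqrt(alpha_IL * k / D),
    speed_scale  = sqrt(D * alpha_IL * k)
  ), class = "dimensionless_params")
}

#' Analytic travelling-wave solution of the dimensionless mutualistic front
#'
#' Solves the reciprocal-power wave ansatz
#' `U_i(z) = xi_i / (1 + a * exp(b * z))^s` for the dimensionless two-species
#' mutualistic system. Requiring every coefficient group of the
#' characteristic equation to vanish forces `s = 1`, `b = c`,
#' `(xi_I, xi_L) = bulk_fractions(alpha_star)` and
#' `c = dimensionless_speed(alpha_star)`. The offset `a` is a translation
#' freedom and is passed through unchanged.
#'
#' @inheritParams dimensionless_speed
#' @param a Profile offset (`> 0`); shifts the wave along `z` only.
#' @return Object of class `travelling_wave`: list with fields `xi_I`,
#'   `xi_L`, `a`, `b`, `s`, `c`, `alpha_star`.
#' @seealso [characteristic_residuals()] to verify a candidate solution,
#'   [wave_profile()] to evaluate the profile.
#' @export
solve_travelling_wave <- function(alpha_star, a = 1) {
  stopifnot(alpha_star > 0, a > 0)
  eps <- bulk_fractions(alpha_star)
  cc <- dimensionless_speed(alpha_star)
  structure(list(
    xi_I = unname(eps["eps_I"]), xi_L = unname(eps["eps_L"]),
    a = a, b = cc, s = 1, c = cc, alpha_star = alpha_star
  ), class = "travelling_wave")
}

#' @export
print.travelling_wave <- function(x, ...) {
  cat("Travelling-wave solution (alpha* =", format(x$alpha_star), ")\n")
  cat("  s =", x$s, " b = c =", format(x$c), "\n")
  cat("  bulk fractions xi_I =", format(x$xi_I), ", xi_L =", format(x$xi_L), "\n")
  invisible(x)
}

#' Evaluate the travelling-wave density profiles
#'
#' @param z Dimensionless comoving coordinate `z = r* - c t*` (vectorised).
#' @param sol A `travelling_wave` object (see [solve_travelling_wave()]).
#' @return Matrix with columns `I` and `L`: dimensionless densities, each
#'   decreasing from its bulk fraction at `z -> -Inf` to 0 at `z -> +Inf`.
#' @export
wave_profile <- function(z, sol) {
  stopifnot(inherits(sol, "travelling_wave"))
  shape <- (1 + sol$a * exp(sol$b * z))^(-sol$s)
  cbind(I = sol$xi_I * shape, L = sol$xi_L * shape)
}

# Coefficient groups of one travelling-wave equation under the ansatz.
#
# Substituting U_i = xi_i * eta^{-s}, eta = 1 + a e^{bz}, into
#   U'' + c U' + gamma * U_I U_L (1 - U_I - U_L) = 0
# and multiplying by eta^{s+2}/xi_self gives
#   s(s+1) a^2 b^2 E^2  -  s a b (b + c) E eta
#   + C eta^{2-s}  -  C (xi_I + xi_L) eta^{2-2s},    E = e^{bz},
# with C = gamma * xi_I * xi_L / xi_self. Powers eta^p with non-negative
# integer p expand binomially into powers of E; any other power is an
# independent function of z and forms its own group. A true solution must
# zero every group simultaneously.
.wave_equation_groups <- function(xi_I, xi_L, a, b, s, cc, gamma, xi_self) {
  poly <- c(E0 = 0, E1 = 0, E2 = 0)
  extra <- numeric(0)
  add_poly <- function(poly, coef, p) {
    # coef * eta^p as polynomial in E (p a non-negative integer <= 2 here)
    for (j in 0:p) {
      poly[j + 1] <- poly[j + 1] + coef * choose(p, j) * a^j
    }
    poly
  }
  poly["E2"] <- s * (s + 1) * a^2 * b^2
  # -s a b (b + c) * E * (1 + a E)
  poly["E1"] <- poly["E1"] - s * a * b * (b + cc)
  poly["E2"] <- poly["E2"] - s * a^2 * b * (b + cc)
  C <- gamma * xi_I * xi_L / xi_self
  for (term in list(c(C, 2 - s), c(-C * (xi_I + xi_L), 2 - 2 * s))) {
    coef <- term[1]; p <- term[2]
    if (p >= 0 && abs(p - round(p)) < 1e-12) {
      poly <- add_poly(poly, coef, round(p))
    } else {
      nm <- paste0("eta^", format(p))
      extra[nm] <- if (nm %in% names(extra)) extra[[nm]] + coef else coef
    }
  }
  c(poly, extra)
}

#' Residual coefficient groups of the travelling-wave ansatz
#'
#' Substitutes a candidate reciprocal-power wave
#' `U_i(z) = xi_i / (1 + a e^{bz})^s` into the two dimensionless
#' travelling-wave ODEs and returns, for each equation, the coefficient
#' attached to every distinct power of `e^{bz}` (after clearing the shared
#' `eta^{-(s+2)}` factor). Powers `eta^{2-s}` and `eta^{2-2s}` that are not
#' polynomial in `e^{bz}` appear as their own named groups. A genuine
#' solution makes every coefficient vanish; this is how the exponent
#' `s = 1` is singled out.
#'
#' @inheritParams dimensionless_speed
#' @param candidate Named list or vector with components `xi_I`, `xi_L`,
#'   `a`, `b`, `s`, `c` (all positive), e.g. a [solve_travelling_wave()]
#'   result.
#' @return List with elements `eq_I` and `eq_L`, each a named numeric vector
#'   of coefficient groups, plus `max_abs`, the largest absolute coefficient.
#' @export
characteristic_residuals <- function(alpha_star, candidate) {
  stopifnot(alpha_star > 0)
  cand <- as.list(candidate)
  need <- c("xi_I", "xi_L", "a", "b", "s", "c")
  stopifnot(all(need %in% names(cand)))
  v <- vapply(cand[need], as.numeric, numeric(1))
  stopifnot(all(v > 0))
  eq_I <- .wave_equation_groups(v["xi_I"], v["xi_L"], v["a"], v["b"], v["s"],
                                v["c"], gamma = 1, xi_self = v["xi_I"])
  eq_L <- .wave_equation_groups(v["xi_I"], v["xi_L"], v["a"], v["b"], v["s"],
                                v["c"], gamma = alpha_star, xi_self = v["xi_L"])
  list(eq_I = eq_I, eq_L = eq_L, max_abs = max(abs(c(eq_I, eq_L))))
}

#' Numeric residual of the travelling-wave ODEs at sampled positions
#'
#' Direct numerical check, independent of the coefficient grouping: evaluates
#' `U'' + c U' + f(U_I, U_L)` for both equations at the supplied `z` values
#' using exact derivatives of the ansatz.
#'
#' @inheritParams characteristic_residuals
#' @param z Positions at which to evaluate the residuals.
#' @return Matrix with columns `res_I`, `res_L` (one row per `z`).
#' @export
wave_residual_at <- function(alpha_star, candidate, z) {
  cand <- as.list(candidate)
  xi <- c(cand$xi_I, cand$xi_L)
  a <- cand$a; b <- cand$b; s <- cand$s; cc <- cand$c
  E <- exp(b * z)
  eta <- 1 + a * E
  res <- matrix(0, length(z), 2, dimnames = list(NULL, c("res_I", "res_L")))
  U <- cbind(xi[1] * eta^(-s), xi[2] * eta^(-s))
  growth <- U[, 1] * U[, 2] * (1 - U[, 1] - U[, 2])
  for (i in 1:2) {
    U1 <- -s * xi[i] * eta^(-s - 1) * a * b * E
    U2 <- s * (s + 1) * xi[i] * eta^(-s - 2) * (a * b * E)^2 -
      s * xi[i] * eta^(-s - 1) * a * b^2 * E
    gamma <- if (i == 1) 1 else alpha_star
    res[, i] <- U2 + cc * U1 + gamma * growth
  }
  res
}

#' Identify the admissible travelling-wave exponent
#'
#' Scans candidate ansatz exponents `s` and, for each, searches for positive
#' `(xi_L, b, c)` (with `xi_I = 1 - xi_L` forced by the bulk fixed point and
#' the gauge choice `a = 1`) that zero all residual coefficient groups of
#' [characteristic_residuals()] simultaneously. Exponents whose groups
#' include a non-polynomial `eta` power with a necessarily positive
#' coefficient cannot be zeroed; numerically this shows up as a residual
#' floor far above `tol`. The unique admissible exponent is `s = 1`.
#'
#' @inheritParams dimensionless_speed
#' @param candidates Exponents to scan.
#' @param tol Largest absolute coefficient group accepted as "vanishing".
#' @return List: `table` (data.frame of `s`, achieved `residual`,
#'   `consistent`), and `s_admitted` (numeric, the consistent exponents).
#' @export
find_wave_exponent <- function(alpha_star = 1,
                               candidates = c(0.5, 1, 1.5, 2),
                               tol = 1e-10) {
  stopifnot(alpha_star > 0, length(candidates) >= 1)
  group_vec <- function(par, s) {
    xi_L <- stats::plogis(par[1])
    b <- exp(par[2]); cc <- exp(par[3])
    cand <- list(xi_I = 1 - xi_L, xi_L = xi_L, a = 1, b = b, s = s, c = cc)
    r <- characteristic_residuals(alpha_star, cand)
    c(r$eq_I, r$eq_L)
  }
  objective <- function(par, s) sum(group_vec(par, s)^2)
  gauss_newton <- function(par, s, iters = 30) {
    for (i in seq_len(iters)) {
      g <- group_vec(par, s)
      J <- vapply(seq_along(par), function(j) {
        h <- 1e-7 * max(1, abs(par[j]))
        pj <- par; pj[j] <- pj[j] + h
        (group_vec(pj, s) - g) / h
      }, numeric(length(g)))
      step <- tryCatch(qr.solve(J, -g), error = function(e) rep(0, length(par)))
      if (!all(is.finite(step)) || sqrt(sum(step^2)) < 1e-15) break
      par <- par + step
    }
    par
  }
  # deterministic multi-start grid over (logit xi_L, log b, log c)
  starts <- expand.grid(q = c(-1, 0, 1), lb = c(-1.5, -0.5, 0.5),
                        lc = c(-1.5, -0.5, 0.5))
  res <- vapply(candidates, function(s) {
    vals <- apply(starts, 1, function(st) {
      fit <- stats::optim(as.numeric(st), objective, s = s,
                          method = "Nelder-Mead",
                          control = list(maxit = 4000, reltol = 1e-16))
      par <- gauss_newton(fit$par, s)
      max(abs(group_vec(par, s)))
    })
    min(vals)
  }, numeric(1))
  tab <- data.frame(s = candidates, residual = res, consistent = res < tol)
  list(table = tab, s_admitted = candidates[tab$consistent])
}
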