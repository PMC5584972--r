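#' Synthetic growth time series with known rates
#'
#' Emulates plate-reader growth curves: either a pure exponential
#' (Malthusian) curve or a death-free hypercycle coculture (hyperbolic
#' kinetics, via [simulate_hypercycle()]), with multiplicative lognormal
#' noise of a stated coefficient of variation. The generating parameters
#' are recorded as ground truth.
#'
#' @param kind `"malthusian"` or `"hyperbolic"`.
#' @param mu Malthusian rate (1/time), used when `kind = "malthusian"`.
#' @param alpha_IL,alpha_LI Cross terms, used when `kind = "hyperbolic"`.
#' @param y0 Initial density (scalar for malthusian, length-2 for
#'   hyperbolic).
#' @param K Carrying capacity (hyperbolic only).
#' @param t_end Final time; `n_points >= 10` samples are taken uniformly.
#' @param n_points Number of samples.
#' @param noise_cv Coefficient of variation of multiplicative lognormal
#'   noise (0 = noiseless).
#' @param seed Integer seed; the series is reproducible given the seed.
#' @return List with `data` (data frame: `time` plus one density column per
#'   strain) and `truth` (generating parameters).
#' @export
generate_growth_timeseries <- function(kind = c("malthusian", "hyperbolic"),
                                       mu = 0.2, alpha_IL = 1, alpha_LI = 1,
                                       y0 = NULL, K = 1, t_end = 10,
                                       n_points = 30, noise_cv = 0,
                                       seed = 1) {
  kind <- match.arg(kind)
  stopifnot(n_points >= 10, noise_cv >= 0, t_end > 0)
  times <- seq(0, t_end, length.out = n_points)
  noisy <- function(x) {
    if (noise_cv == 0) return(x)
    sdlog <- sqrt(log(1 + noise_cv^2))
    x * stats::rlnorm(length(x), meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }
  set.seed(seed)
  if (kind == "malthusian") {
    if (is.null(y0)) y0 <- 1e-3
    data <- data.frame(time = times, density = noisy(y0 * exp(mu * times)))
    truth <- list(kind = kind, mu = mu, y0 = y0, noise_cv = noise_cv,
                  seed = seed)
  } else {
    if (is.null(y0)) y0 <- c(1e-3, 1e-3) * K
    par <- hypercycle_params(alpha_12 = alpha_IL, alpha_21 = alpha_LI, K = K)
    traj <- simulate_hypercycle(par, y0, t_end,
                                dt_out = t_end / (n_points - 1))
    data <- data.frame(time = traj$time, I = noisy(traj$Phi1),
                       L = noisy(traj$Phi2))
    truth <- list(kind = kind, alpha_IL = alpha_IL, alpha_LI = alpha_LI,
                  K = K, y0 = y0, noise_cv = noise_cv, seed = seed)
  }
  list(data = data, truth = truth)
}

#' Synthetic sectored colony with known geometry
#'
#' Builds a disk-shaped label grid divided into `n_sectors` radial sectors
#' of equal angle, cycling through the given strain labels, optionally with
#' angular jitter of the boundaries. Ground truth (sector count, boundary
#' angles) is recorded, so any sector metric run on the fixture can be
#' scored exactly.
#'
#' @param n_sectors Number of radial sectors (`>= 1`).
#' @param radius Disk radius in lattice units.
#' @param strains Labels cycled over sectors (default `c(1, 2)`).
#' @param jitter Standard deviation of Gaussian angular jitter (radians)
#'   applied to sector boundaries (0 = exact equal sectors).
#' @param seed Integer seed (used only when `jitter > 0`).
#' @param size Lattice side length; default `2 * radius + 5`.
#' @return List with `grid` (a [label_grid()]) and `truth` (list:
#'   `n_sectors`, `boundaries`, `strains`, `radius`).
#' @export
generate_sector_colony <- function(n_sectors, radius, strains = c(1, 2),
                                   jitter = 0, seed = 1, size = NULL) {
  stopifnot(n_sectors >= 1, radius >= 3, jitter >= 0)
  if (is.null(size)) size <- 2 * ceiling(radius) + 5
  centre <- c((size + 1) / 2, (size + 1) / 2)
  bnd <- 2 * pi * (seq_len(n_sectors) - 1) / n_sectors
  if (jitter > 0) {
    set.seed(seed)
    bnd <- sort((bnd + stats::rnorm(n_sectors, 0, jitter)) %% (2 * pi))
  }
  lab_of <- function(theta) {
    # sector index: count of boundaries <= theta (boundaries sorted)
    i <- findInterval(theta, bnd)
    i[i == 0] <- n_sectors   # angles before the first boundary wrap around
    strains[(i - 1) %% length(strains) + 1]
  }
  mat <- matrix(0L, size, size)
  idx <- which(mat == 0, arr.ind = TRUE)
  dy <- idx[, 1] - centre[1]; dx <- idx[, 2] - centre[2]
  r <- sqrt(dx^2 + dy^2)
  inside <- r <= radius
  theta <- atan2(dy[inside], dx[inside]) %% (2 * pi)
  mat[idx[inside, , drop = FALSE]] <- as.integer(lab_of(theta))
  list(grid = label_grid(mat, centre = centre),
       truth = list(n_sectors = n_sectors, boundaries = bnd,
                    strains = strains, radius = radius))
}

# one Koch-snowflake-side refinement of a polyline
.koch_refine <- function(pts) {
  out <- matrix(0, (nrow(pts) - 1) * 4 + 1, 2)
  k <- 1
  rot60 <- matrix(c(cos(-pi / 3), sin(-pi / 3),
                    -sin(-pi / 3), cos(-pi / 3)), 2, 2)
  for (i in seq_len(nrow(pts) - 1)) {
    a <- pts[i, ]; b <- pts[i + 1, ]
    v <- (b - a) / 3
    p1 <- a + v
    p2 <- a + 2 * v
    peak <- p1 + as.numeric(rot60 %*% v)
    out[k:(k + 3), ] <- rbind(a, p1, peak, p2)
    k <- k + 4
  }
  out[nrow(out), ] <- pts[nrow(pts), ]
  out
}

#' Synthetic boundary point sets with known fractal dimension
#'
#' Generates rasterised curves with a closed-form Hausdorff dimension,
#' serving as oracles for [box_counting_dimension()]: a straight line
#' (dimension 1) or a Koch curve (dimension `log(4)/log(3)`). Points are
#' sampled densely along each segment (at least one point per unit step)
#' so every smallest-scale box along the curve is hit.
#'
#' @param kind `"line"` or `"koch"`.
#' @param iterations Koch refinement depth (`<= 6`).
#' @param scale Total curve extent in raster units (default `3^5`).
#' @return List with `points` (two-column matrix) and `truth` (list:
#'   `dimension`, plus `box_sizes` and `scaling_range`, the box ladder
#'   aligned with the curve's construction scales over which the
#'   box-counting estimate is unbiased).
#' @export
generate_fractal_boundary <- function(kind = c("line", "koch"),
                                      iterations = 4, scale = 3^5) {
  kind <- match.arg(kind)
  stopifnot(iterations >= 1, iterations <= 6, scale > 1)
  if (kind == "line") {
    t <- seq(0, scale, by = 0.5)
    pts <- cbind(t, 0.37 * t)   # irrational-ish slope, not axis-aligned
    sizes <- 2^(0:floor(log2(scale / 2)))
    truth <- list(dimension = 1, box_sizes = sizes,
                  scaling_range = range(sizes))
  } else {
    poly <- matrix(c(0, 0, scale, 0), 2, 2, byrow = TRUE)
    for (i in seq_len(iterations)) poly <- .koch_refine(poly)
    # sample along segments at spacing <= 0.5 raster units
    seg <- lapply(seq_len(nrow(poly) - 1), function(i) {
      a <- poly[i, ]; b <- poly[i + 1, ]
      len <- sqrt(sum((b - a)^2))
      tt <- seq(0, 1, length.out = max(2, ceiling(len / 0.5) + 1))
      cbind(a[1] + tt * (b[1] - a[1]), a[2] + tt * (b[2] - a[2]))
    })
    pts <- do.call(rbind, seg)
    feature <- scale / 3^iterations   # smallest segment length
    sizes <- feature * 3^(0:(iterations - 1))
    truth <- list(dimension = log(4) / log(3), box_sizes = sizes,
                  scaling_range = range(sizes))
  }
  list(points = pts, truth = truth)
}
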