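#' Integer-labelled colony snapshot
#'
#' The common currency of all colony metrics: an integer lattice with 0 for
#' empty sites and `1..S` for strain identities, plus the colony centre and
#' the lattice spacing.
#'
#' @param mat Integer matrix (rows = y, columns = x); values `>= 0`.
#' @param centre Length-2 centre coordinates in lattice units
#'   (row, column); default the matrix centre.
#' @param spacing Physical length per lattice site (default 1).
#' @return Object of class `label_grid`.
#' @export
label_grid <- function(mat, centre = NULL, spacing = 1) {
  mat <- as.matrix(mat)
  stopifnot(all(mat >= 0), all(mat == round(mat)), spacing > 0)
  if (is.null(centre)) centre <- (dim(mat) + 1) / 2
  stopifnot(length(centre) == 2,
            centre[1] >= 1, centre[1] <= nrow(mat),
            centre[2] >= 1, centre[2] <= ncol(mat))
  structure(list(mat = mat, centre = centre, spacing = spacing),
            class = "label_grid")
}

# polar coordinates of all occupied sites (lattice units)
.occupied_polar <- function(grid) {
  idx <- which(grid$mat > 0, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    return(data.frame(row = integer(), col = integer(), r = numeric(),
                      theta = numeric(), label = integer()))
  }
  dy <- idx[, 1] - grid$centre[1]
  dx <- idx[, 2] - grid$centre[2]
  data.frame(row = idx[, 1], col = idx[, 2],
             r = sqrt(dx^2 + dy^2),
             theta = atan2(dy, dx) %% (2 * pi),
             label = grid$mat[idx])
}

#' Single-strain sector widths along a circle
#'
#' Samples the strain label along the circle of the given radius
#' (nearest-site sampling, angular step at most one site arc). Maximal runs
#' of identical non-empty labels are sectors; runs wrapping through 0 are
#' merged. The width of a sector is its angular extent times the radius
#' (arc length).
#'
#' @param grid A [label_grid()].
#' @param radius Circle radius in physical units (`>= 3` lattice spacings).
#' @return Object of class `sector_stats`: list with `radius`, `sectors`
#'   (data frame: `strain`, `angle`, `width`), `mean_width` (named by
#'   strain), `n_sectors`, `occupied_angle`.
#' @export
sector_widths <- function(grid, radius) {
  stopifnot(inherits(grid, "label_grid"), radius >= 3 * grid$spacing)
  r_lat <- radius / grid$spacing
  n <- max(8L, ceiling(2 * pi * r_lat))
  theta <- 2 * pi * (seq_len(n) - 1) / n
  row <- round(grid$centre[1] + r_lat * sin(theta))
  col <- round(grid$centre[2] + r_lat * cos(theta))
  ok <- row >= 1 & row <= nrow(grid$mat) & col >= 1 & col <= ncol(grid$mat)
  lab <- integer(n)
  lab[ok] <- grid$mat[cbind(row[ok], col[ok])]
  if (all(lab == 0)) {
    return(structure(list(radius = radius,
                          sectors = data.frame(strain = integer(),
                                               angle = numeric(),
                                               width = numeric()),
                          mean_width = numeric(0), n_sectors = 0L,
                          occupied_angle = 0),
                     class = "sector_stats"))
  }
  runs <- rle(lab)
  # merge wrap-around: same non-empty label at both ends of the scan
  wrapped <- FALSE
  if (length(runs$values) > 1 &&
      runs$values[1] == runs$values[length(runs$values)] &&
      runs$values[1] != 0) {
    runs$lengths[1] <- runs$lengths[1] + runs$lengths[length(runs$lengths)]
    runs$lengths <- runs$lengths[-length(runs$lengths)]
    runs$values <- runs$values[-length(runs$values)]
    wrapped <- TRUE
  }
  keep <- runs$values != 0
  dtheta <- 2 * pi / n
  sectors <- data.frame(strain = runs$values[keep],
                        angle = runs$lengths[keep] * dtheta)
  sectors$width <- sectors$angle * radius
  mw <- tapply(sectors$width, sectors$strain, mean)
  structure(list(radius = radius, sectors = sectors,
                 mean_width = mw, n_sectors = nrow(sectors),
                 occupied_angle = sum(sectors$angle)),
            class = "sector_stats")
}

#' Mean sector width as a function of radius
#'
#' Evaluates [sector_widths()] on an increasing grid of radii and exposes
#' the ordinary-least-squares slope of mean width versus radius — the
#' mutualism-versus-drift diagnostic: straight interleaved sectors keep an
#' approximately constant width (slope near zero only if sectors keep
#' splitting; with a fixed sector count the width grows with the
#' circumference), while drift-driven coarsening raises the width faster
#' through sector loss.
#'
#' @param grid A [label_grid()].
#' @param radii Increasing radii at which to measure.
#' @return Data frame with columns `radius`, `mean_width`, `n_sectors`
#'   (rows with no occupied sites are dropped); the OLS slope of
#'   `mean_width` on `radius` is attached as attribute `slope` (NA when
#'   fewer than 3 usable radii).
#' @export
patch_width_curve <- function(grid, radii) {
  stopifnot(inherits(grid, "label_grid"), all(diff(radii) > 0))
  rows <- lapply(radii, function(r) {
    st <- sector_widths(grid, r)
    if (st$n_sectors == 0) return(NULL)
    data.frame(radius = r, mean_width = mean(st$sectors$width),
               n_sectors = st$n_sectors)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(radius = numeric(),
                                      mean_width = numeric(),
                                      n_sectors = integer())
  slope <- if (nrow(out) >= 3) {
    unname(stats::coef(stats::lm(mean_width ~ radius, data = out))[2])
  } else NA_real_
  attr(out, "slope") <- slope
  out
}

# per-angular-bin outermost occupied radius; returns for each occupied site
# whether it belongs to the front edge band
.edge_mask <- function(pol, shell_lat) {
  rmax <- max(pol$r)
  nbins <- max(8L, ceiling(pi * rmax))
  bin <- pmin(floor(pol$theta / (2 * pi) * nbins) + 1L, nbins)
  ray_max <- tapply(pol$r, bin, max)
  pol$r >= ray_max[as.character(bin)] - shell_lat
}

#' Strain frequency at the edge of the colony front
#'
#' The front edge is the set of occupied sites whose radial distance lies
#' within `shell_thickness` of the outermost occupied distance along their
#' angular ray (per-ray outermost band, robust to front roughness). Returns
#' the fraction of edge sites carrying the given strain.
#'
#' @param grid A [label_grid()] with at least one occupied site.
#' @param strain Strain label of interest.
#' @param shell_thickness Band depth in physical units (default 3 sites).
#' @return Fraction in `[0, 1]`.
#' @export
front_edge_frequency <- function(grid, strain, shell_thickness = 3) {
  stopifnot(inherits(grid, "label_grid"), shell_thickness > 0)
  pol <- .occupied_polar(grid)
  if (nrow(pol) == 0) stop("empty colony")
  edge <- .edge_mask(pol, shell_thickness / grid$spacing)
  mean(pol$label[edge] == strain)
}

#' Fraction of active cells
#'
#' @param activity Logical (or 0/1) matrix marking active cells.
#' @param labels Optional label matrix of the same shape restricting the
#'   census to occupied sites; if omitted, any `TRUE` entry counts as an
#'   active cell and any non-`NA` entry of `activity` as a cell.
#' @return `active cells / all cells`; 0 for an empty colony.
#' @export
active_fraction <- function(activity, labels = NULL) {
  act <- as.matrix(activity)
  if (!is.null(labels)) {
    labels <- if (inherits(labels, "label_grid")) labels$mat else as.matrix(labels)
    stopifnot(all(dim(act) == dim(labels)))
    occ <- labels > 0
    if (!any(occ)) return(0)
    return(sum(act[occ] != 0) / sum(occ))
  }
  if (length(act) == 0) return(0)
  sum(act != 0) / length(act)
}

#' Colony radius of a labelled snapshot
#'
#' Mean over angular rays of the outermost occupied distance from the
#' centre (physical units).
#'
#' @param grid A [label_grid()].
#' @return Radius (0 for an empty grid).
#' @export
colony_radius <- function(grid) {
  stopifnot(inherits(grid, "label_grid"))
  pol <- .occupied_polar(grid)
  if (nrow(pol) == 0) return(0)
  nbins <- max(8L, ceiling(pi * max(pol$r)))
  bin <- pmin(floor(pol$theta / (2 * pi) * nbins) + 1L, nbins)
  mean(tapply(pol$r, bin, max)) * grid$spacing
}

#' Colony radius trace and expansion speed
#'
#' @param grids List of [label_grid()] snapshots (chronological).
#' @param times Times of the snapshots; default `0, 1, 2, ...`.
#' @return List with `table` (data frame `time`, `radius`), `speed` (OLS
#'   slope over the trailing half), `se`, and `shrinking` (TRUE, with a
#'   warning, if the radius ever decreases).
#' @export
colony_radius_and_speed <- function(grids, times = seq_along(grids) - 1) {
  stopifnot(length(grids) >= 5, length(times) == length(grids))
  radius <- vapply(grids, colony_radius, 0)
  tab <- data.frame(time = times, radius = radius)
  shrinking <- any(diff(radius) < 0)
  if (shrinking) warning("colony radius decreases along the trace")
  n <- length(times)
  idx <- seq.int(floor(n / 2) + 1L, n)
  fit <- stats::lm(radius ~ time, data = tab[idx, ])
  list(table = tab,
       speed = unname(stats::coef(fit)[2]),
       se = suppressWarnings(summary(fit))$coefficients[2, 2],
       shrinking = shrinking)
}

#' Boundary sites between different strains
#'
#' Occupied sites having at least one 4-neighbour carrying a different
#' non-empty strain label.
#'
#' @param grid A [label_grid()].
#' @return Two-column matrix of (row, col) lattice coordinates (possibly
#'   empty if fewer than two strains touch).
#' @export
boundary_points <- function(grid) {
  stopifnot(inherits(grid, "label_grid"))
  m <- grid$mat
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(0L, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- m
  ctr <- pad[2:(nr + 1), 2:(nc + 1)]
  is_bnd <- matrix(FALSE, nr, nc)
  for (sh in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
    nb <- pad[2:(nr + 1) + sh[1], 2:(nc + 1) + sh[2]]
    is_bnd <- is_bnd | (ctr > 0 & nb > 0 & nb != ctr)
  }
  which(is_bnd, arr.ind = TRUE)
}

#' Box-counting fractal dimension of a point set
#'
#' Covers the point set with square boxes of decreasing size, counts
#' occupied boxes `N(l)` and estimates the dimension as minus the OLS slope
#' of `log N` versus `log l` over a scaling range. By default the fit
#' excludes both cutoffs that plague box counting on finite sets: sizes so
#' large that fewer than 8 boxes are occupied (set-scale cutoff) and sizes
#' so small that the occupied-box count approaches the number of points
#' (sampling-scale saturation, `N > n_points/4`).
#'
#' @param points Two-column matrix of point coordinates (any units).
#' @param box_sizes Decreasing geometric sequence of box sizes; default a
#'   factor `sqrt(2)` ladder from half the set extent down to roughly the
#'   sampling resolution.
#' @param scaling_range Optional length-2 numeric giving the box-size range
#'   used in the fit, overriding the default cutoff rule.
#' @return List with `dimension`, its OLS standard error `se`, `r_squared`,
#'   and `table` (data frame `box_size`, `n_boxes`).
#' @export
box_counting_dimension <- function(points, box_sizes = NULL,
                                   scaling_range = NULL) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 2, nrow(points) >= 100)
  ext <- max(apply(points, 2, function(v) diff(range(v))))
  stopifnot(ext > 0)
  if (is.null(box_sizes)) {
    n_sizes <- max(8L, 2L * (floor(log2(ext)) + 1L))
    box_sizes <- (ext / 2) / sqrt(2)^(seq_len(n_sizes) - 1)
  }
  box_sizes <- sort(box_sizes, decreasing = TRUE)
  origin <- apply(points, 2, min)
  counts <- vapply(box_sizes, function(l) {
    ix <- floor((points[, 1] - origin[1]) / l)
    iy <- floor((points[, 2] - origin[2]) / l)
    length(unique(ix * (max(iy) + 2) + iy))
  }, 0)
  tab <- data.frame(box_size = box_sizes, n_boxes = counts)
  if (is.null(scaling_range)) {
    keep <- which(counts >= 8 & counts <= max(nrow(points) / 4, 16))
  } else {
    keep <- which(box_sizes >= min(scaling_range) &
                    box_sizes <= max(scaling_range))
  }
  stopifnot(length(keep) >= 3)
  fit <- stats::lm(log(n_boxes) ~ log(box_size), data = tab[keep, ])
  sm <- suppressWarnings(summary(fit))
  list(dimension = -unname(stats::coef(fit)[2]),
       se = sm$coefficients[2, 2],
       r_squared = sm$r.squared,
       table = tab)
}
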