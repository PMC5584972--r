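#' Configuration of the lattice agent-based colony simulator
#'
#' One cell per lattice site; five diffusing extracellular fields (food,
#' the two cross-fed amino acids iso and leu, antibiotic, beta-lactamase
#' enzyme). Cell behaviour is a set of Heaviside (threshold) rules: a cell
#' grows only while local food exceeds `g_f`, its required amino acid
#' exceeds `g_am` (strain I- senses iso; L- and P sense leu) and the
#' antibiotic is strictly below `g_at`. Cells with food above `g_f` absorb
#' food and secrete at constant rates: I- releases leu, L- releases iso,
#' and the parasite P releases the antibiotic-degrading enzyme. P grows
#' faster than the mutualists by the factor `p_advantage` (default 1.10).
#'
#' Time step and lattice spacing are both 1. Field diffusion coefficients
#' above the explicit single-pass stability bound 0.25 are integrated with
#' internal substeps, so fast molecular diffusion can be represented.
#'
#' @param lattice_size Side length of the square lattice (sites).
#' @param neighbourhood 4 or 8 (default) neighbour sites for division.
#' @param g_f,g_am,g_at Food, amino-acid and antibiotic thresholds
#'   (concentration units). Growth needs food `> g_f`, amino acid `> g_am`
#'   and antibiotic `< g_at` (strict, matching "exceeds"/"below").
#' @param food_uptake,aa_uptake,aa_secretion,enz_secretion Exchange rates
#'   (concentration per site per step).
#' @param div_rate Base division-accumulator advance per step (1/step);
#'   a cell divides when its accumulator reaches 1.
#' @param p_advantage Multiplier on `div_rate` for strain P.
#' @param D_food,D_aa,D_ab,D_enz Field diffusion coefficients
#'   (site^2/step).
#' @param ab_decay Mass-action degradation rate of antibiotic by enzyme
#'   (per concentration per step).
#' @param F0,I0,L0,Ampi0 Initial uniform field levels: food, iso, leu and
#'   antibiotic. `Ampi0` may also be a full matrix (see
#'   [antibiotic_profile()]).
#' @return Object of class `abm_config`.
#' @export
abm_config <- function(lattice_size = 200, neighbourhood = 8,
                       g_f = 1, g_am = 0.05, g_at = 1,
                       food_uptake = 1, aa_uptake = 0.3,
                       aa_secretion = 0.3, enz_secretion = 0.1,
                       div_rate = 0.25, p_advantage = 1.10,
                       D_food = 0.2, D_aa = 0.5, D_ab = 0.05, D_enz = 0.2,
                       ab_decay = 0.5,
                       F0 = 90, I0 = 0, L0 = 0, Ampi0 = 0) {
  stopifnot(lattice_size >= 10, neighbourhood %in% c(4, 8),
            g_f >= 0, g_am >= 0, g_at >= 0,
            food_uptake >= 0, aa_uptake >= 0, aa_secretion >= 0,
            enz_secretion >= 0, div_rate > 0, p_advantage > 0,
            ab_decay >= 0, F0 >= 0, I0 >= 0, L0 >= 0, all(Ampi0 >= 0))
  stopifnot(D_food >= 0, D_aa >= 0, D_ab >= 0, D_enz >= 0)
  structure(as.list(environment()), class = "abm_config")
}

.neigh_offsets <- function(neighbourhood) {
  if (neighbourhood == 4) {
    list(r = c(-1L, 1L, 0L, 0L), c = c(0L, 0L, -1L, 1L))
  } else {
    list(r = c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L),
         c = c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L))
  }
}

#' Inoculate a colony
#'
#' Places `n_cells` cells uniformly at random on distinct sites within a
#' central disk, with strains drawn independently from `fractions`
#' (I-, L-, P). Fields start at the configured uniform levels (or the
#' supplied `Ampi0` profile).
#'
#' @param config An [abm_config()].
#' @param radius Inoculum disk radius (sites).
#' @param fractions Length-3 strain mix, summing to 1.
#' @param n_cells Number of cells to place (at most the number of disk
#'   sites).
#' @param seed Integer seed; identical seeds give identical snapshots.
#' @return Object of class `abm_state`: list with `step`, `strain` (integer
#'   matrix, 0 empty / 1 I- / 2 L- / 3 P), `acc`, `active`, `fields`
#'   (list food/iso/leu/ab/enz), `centre`, `config`.
#' @export
init_colony <- function(config, radius = 12, fractions = c(0.5, 0.5, 0),
                        n_cells = 150, seed = 1) {
  stopifnot(inherits(config, "abm_config"), length(fractions) == 3,
            abs(sum(fractions) - 1) < 1e-9, all(fractions >= 0),
            radius > 0, radius < config$lattice_size / 2)
  set.seed(seed)
  n <- config$lattice_size
  centre <- c((n + 1) / 2, (n + 1) / 2)
  idx <- which(matrix(TRUE, n, n), arr.ind = TRUE)
  r <- sqrt((idx[, 1] - centre[1])^2 + (idx[, 2] - centre[2])^2)
  disk <- idx[r <= radius, , drop = FALSE]
  if (n_cells > nrow(disk)) {
    stop("overfull inoculum disk: ", n_cells, " cells for ",
         nrow(disk), " sites")
  }
  sites <- disk[sample.int(nrow(disk), n_cells), , drop = FALSE]
  strain <- matrix(0L, n, n)
  strain[sites] <- sample.int(3L, n_cells, replace = TRUE, prob = fractions)
  uni <- function(v) if (is.matrix(v)) {
    stopifnot(all(dim(v) == c(n, n))); v + 0
  } else matrix(v, n, n)
  structure(list(step = 0L, strain = strain,
                 acc = matrix(0, n, n),
                 active = strain > 0,
                 fields = list(food = uni(config$F0), iso = uni(config$I0),
                               leu = uni(config$L0), ab = uni(config$Ampi0),
                               enz = matrix(0, n, n)),
                 centre = centre, config = config),
            class = "abm_state")
}

#' Heaviside growth gate
#'
#' Evaluates, for every cell, the conjunction of the three threshold
#' conditions (food `> g_f`, strain-specific amino acid `> g_am`,
#' antibiotic `< g_at`) and tags the first violated condition.
#'
#' @param state An `abm_state`.
#' @return List with `permitted` (logical matrix, FALSE off-colony) and
#'   `tag` (character matrix: `"food"`, `"aa"`, `"antibiotic"`, `"none"`
#'   for permitted cells, `NA` for empty sites).
#' @export
sense_and_gate <- function(state) {
  cfg <- state$config
  s <- state$strain
  occ <- s > 0
  food_ok <- state$fields$food > cfg$g_f
  # I- senses iso; L- and P sense leu
  aa <- state$fields$leu
  aa[s == 1L] <- state$fields$iso[s == 1L]
  aa_ok <- aa > cfg$g_am
  ab_ok <- state$fields$ab < cfg$g_at
  permitted <- occ & food_ok & aa_ok & ab_ok
  tag <- matrix(NA_character_, nrow(s), ncol(s))
  tag[occ] <- "none"
  tag[occ & food_ok & aa_ok & !ab_ok] <- "antibiotic"
  tag[occ & food_ok & !aa_ok] <- "aa"
  tag[occ & !food_ok] <- "food"
  list(permitted = permitted, tag = tag)
}

#' Constant-rate exchange between cells and fields
#'
#' Cells whose local food exceeds `g_f` absorb food and secrete their
#' strain product (I- releases leu, L- releases iso, P releases enzyme);
#' growth-permitted cells additionally absorb their required amino acid.
#' All fields are floored at zero.
#'
#' @param state An `abm_state`.
#' @param permitted Logical matrix from [sense_and_gate()]; computed if
#'   missing.
#' @return The state with updated fields.
#' @export
exchange_step <- function(state, permitted = NULL) {
  cfg <- state$config
  if (is.null(permitted)) permitted <- sense_and_gate(state)$permitted
  s <- state$strain
  fed <- s > 0 & state$fields$food > cfg$g_f
  f <- state$fields
  f$food[fed] <- pmax(f$food[fed] - cfg$food_uptake, 0)
  f$leu[fed & s == 1L] <- f$leu[fed & s == 1L] + cfg$aa_secretion
  f$iso[fed & s == 2L] <- f$iso[fed & s == 2L] + cfg$aa_secretion
  f$enz[fed & s == 3L] <- f$enz[fed & s == 3L] + cfg$enz_secretion
  take_iso <- permitted & s == 1L
  take_leu <- permitted & s != 1L & s > 0L
  f$iso[take_iso] <- pmax(f$iso[take_iso] - cfg$aa_uptake, 0)
  f$leu[take_leu] <- pmax(f$leu[take_leu] - cfg$aa_uptake, 0)
  state$fields <- f
  state
}

# explicit no-flux diffusion over one unit time step (dt = dx = 1).
# Coefficients above the single-pass stability bound 0.25 are handled by
# substepping, so fast molecular diffusion (small molecules spread much
# faster than the colony grows) remains stable.
.diffuse <- function(M, D) {
  if (D == 0) return(M)
  n_sub <- ceiling(D / 0.25)
  d <- D / n_sub
  n <- nrow(M)
  iu <- c(1, seq_len(n - 1)); id <- c(seq_len(n - 1) + 1, n)
  for (s in seq_len(n_sub)) {
    M <- M + d * (M[iu, , drop = FALSE] + M[id, , drop = FALSE] +
                    M[, iu, drop = FALSE] + M[, id, drop = FALSE] - 4 * M)
  }
  M
}

#' Field transport and antibiotic degradation
#'
#' Diffuses every field one explicit step (no-flux boundaries) and then
#' removes antibiotic by mass action with the enzyme field,
#' `ab <- ab - ab_decay * enz * ab`, floored at zero.
#'
#' @inheritParams exchange_step
#' @return The state with updated fields.
#' @export
field_step <- function(state) {
  cfg <- state$config
  f <- state$fields
  f$food <- .diffuse(f$food, cfg$D_food)
  f$iso <- .diffuse(f$iso, cfg$D_aa)
  f$leu <- .diffuse(f$leu, cfg$D_aa)
  f$ab <- .diffuse(f$ab, cfg$D_ab)
  f$enz <- .diffuse(f$enz, cfg$D_enz)
  f$ab <- pmax(f$ab - cfg$ab_decay * f$enz * f$ab, 0)
  state$fields <- f
  state
}

#' Advance division accumulators and divide ready cells
#'
#' Growth-permitted cells advance their accumulator by the strain rate
#' (P: `p_advantage` times faster). Cells reaching 1 divide, in seeded
#' random order, into a uniformly chosen empty neighbour site (the
#' remainder above 1 is carried over so the mean rate is preserved); fully
#' enclosed cells defer with the accumulator capped at 1.
#'
#' @inheritParams exchange_step
#' @return The state with updated `strain`, `acc` and `active` (a cell is
#'   active when growth-permitted and not fully enclosed).
#' @export
division_step <- function(state, permitted = NULL) {
  cfg <- state$config
  if (is.null(permitted)) permitted <- sense_and_gate(state)$permitted
  s <- state$strain
  rate <- matrix(0, nrow(s), ncol(s))
  rate[permitted] <- cfg$div_rate
  rate[permitted & s == 3L] <- cfg$div_rate * cfg$p_advantage
  acc <- state$acc + rate
  ready <- which(acc >= 1 & permitted, arr.ind = TRUE)
  strain <- s + 0L   # force copies: the C++ kernel updates in place
  acc <- acc + 0
  if (nrow(ready) > 0) {
    ord <- sample.int(nrow(ready))
    ofs <- .neigh_offsets(cfg$neighbourhood)
    divide_ready_cpp(strain, acc, ready[ord, 1], ready[ord, 2], ofs$r, ofs$c)
  }
  state$strain <- strain
  state$acc <- acc
  # active = growth-permitted and adjacent to free space (8-neighbourhood)
  n <- nrow(strain)
  empty <- strain == 0L
  nb_empty <- matrix(FALSE, n, n)
  ofs <- .neigh_offsets(8)
  for (j in seq_along(ofs$r)) {
    rs <- pmin(pmax(seq_len(n) + ofs$r[j], 1), n)
    cs <- pmin(pmax(seq_len(n) + ofs$c[j], 1), n)
    nb_empty <- nb_empty | empty[rs, cs]
  }
  state$active <- permitted & nb_empty
  state
}

#' Run the agent-based colony simulation
#'
#' Iterates sense -> exchange -> field -> division with a single seeded
#' generator, logging per step the population per strain, the active-cell
#' fraction and the colony radius (outermost occupied distance from the
#' centre).
#'
#' @param config An [abm_config()].
#' @param n_steps Number of update sweeps.
#' @param inoculum List with `radius`, `fractions`, `n_cells` passed to
#'   [init_colony()]; ignored when `init_state` is given.
#' @param snapshot_every Store a snapshot every this many steps (default:
#'   only the final state).
#' @param seed Integer seed controlling all randomness of the run.
#' @param init_state Optional prebuilt `abm_state` (its `config` is used).
#' @return Object of class `abm_run`: list with `log` (data frame: `step`,
#'   `N_I`, `N_L`, `N_P`, `active_fraction`, `radius`), `snapshots` (list
#'   of `abm_state`), `final` (final `abm_state`), `config`, `seed`.
#' @export
run_abm <- function(config, n_steps,
                    inoculum = list(radius = 12, fractions = c(0.5, 0.5, 0),
                                    n_cells = 150),
                    snapshot_every = NULL, seed = 1, init_state = NULL) {
  if (is.null(init_state)) {
    state <- init_colony(config, inoculum$radius, inoculum$fractions,
                         inoculum$n_cells, seed = seed)
  } else {
    state <- init_state
    config <- state$config
    set.seed(seed)
  }
  n <- config$lattice_size
  centre <- state$centre
  dist2 <- outer((seq_len(n) - centre[1])^2, (seq_len(n) - centre[2])^2, "+")
  log_rows <- vector("list", n_steps + 1)
  snapshots <- list()
  log_state <- function(st, step) {
    occ <- st$strain > 0
    data.frame(step = step,
               N_I = sum(st$strain == 1L), N_L = sum(st$strain == 2L),
               N_P = sum(st$strain == 3L),
               active_fraction = if (any(occ)) sum(st$active & occ) / sum(occ) else 0,
               radius = if (any(occ)) sqrt(max(dist2[occ])) else 0)
  }
  log_rows[[1]] <- log_state(state, 0L)
  for (step in seq_len(n_steps)) {
    gate <- sense_and_gate(state)
    state <- exchange_step(state, gate$permitted)
    state <- field_step(state)
    state <- division_step(state, gate$permitted)
    state$permitted <- gate$permitted   # threshold gate alone, no crowding
    state$step <- step
    log_rows[[step + 1]] <- log_state(state, step)
    if (!is.null(snapshot_every) && step %% snapshot_every == 0) {
      snapshots[[length(snapshots) + 1]] <- state
    }
  }
  structure(list(log = do.call(rbind, log_rows), snapshots = snapshots,
                 final = state, config = config, seed = seed),
            class = "abm_run")
}

#' Initial antibiotic concentration profiles
#'
#' @param kind `"uniform"`, `"linear-gradient"` (rows interpolate from
#'   `c_lo` at the bottom row to `c_hi` at the top row) or `"half-plane"`
#'   (`c_hi` on rows above `y0`, `c_lo` elsewhere).
#' @param lattice_size Side length of the lattice.
#' @param c_lo,c_hi Concentrations; `uniform` uses only `c_hi`.
#' @param y0 Dividing row for `half-plane` (default: the middle).
#' @return Numeric matrix suitable as `Ampi0` in [abm_config()].
#' @export
antibiotic_profile <- function(kind = c("uniform", "linear-gradient",
                                        "half-plane"),
                               lattice_size, c_lo = 0, c_hi = 0,
                               y0 = NULL) {
  kind <- match.arg(kind)
  n <- lattice_size
  stopifnot(c_lo >= 0, c_hi >= 0)
  switch(kind,
    "uniform" = matrix(c_hi, n, n),
    "linear-gradient" = matrix(rep(seq(c_lo, c_hi, length.out = n), n),
                               n, n),
    "half-plane" = {
      if (is.null(y0)) y0 <- (n + 1) / 2
      matrix(rep(ifelse(seq_len(n) > y0, c_hi, c_lo), n), n, n)
    })
}

#' Extract the label grid of an ABM state
#'
#' @param state An `abm_state` or `abm_run` (final state used).
#' @return A [label_grid()] of the strain lattice.
#' @export
abm_label_grid <- function(state) {
  if (inherits(state, "abm_run")) state <- state$final
  stopifnot(inherits(state, "abm_state"))
  label_grid(state$strain, centre = state$centre)
}
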