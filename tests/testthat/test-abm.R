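small_cfg <- function(...) abm_config(lattice_size = 60, ...)

rich_state <- function(cfg = small_cfg(I0 = 50, L0 = 50), n_cells = 30,
                       fractions = c(0.5, 0.5, 0), seed = 1, radius = 8) {
  init_colony(cfg, radius = radius, fractions = fractions,
              n_cells = n_cells, seed = seed)
}

test_that("inoculation: monoculture disks, determinism and binomial strain mixing", {
  cfg <- small_cfg()
  st <- init_colony(cfg, radius = 8, fractions = c(1, 0, 0), n_cells = 50,
                    seed = 2)
  expect_true(all(st$strain[st$strain > 0] == 1L))
  ctr <- st$centre
  occ <- which(st$strain > 0, arr.ind = TRUE)
  expect_true(all((occ[, 1] - ctr[1])^2 + (occ[, 2] - ctr[2])^2 <= 8^2))
  a <- init_colony(cfg, 8, c(0.3, 0.3, 0.4), 60, seed = 9)
  b <- init_colony(cfg, 8, c(0.3, 0.3, 0.4), 60, seed = 9)
  expect_identical(a$strain, b$strain)
  expect_error(init_colony(cfg, radius = 3, fractions = c(1, 0, 0),
                           n_cells = 1000), "overfull")
  # strain counts across seeds stay within the 99% binomial band
  lo <- qbinom(0.005, 200, 0.5)
  hi <- qbinom(0.995, 200, 0.5)
  big <- abm_config(lattice_size = 100)
  hits <- sum(vapply(1:100, function(s) {
    st <- init_colony(big, radius = 15, fractions = c(0.5, 0.5, 0),
                      n_cells = 200, seed = s)
    n1 <- sum(st$strain == 1L)
    n1 >= lo && n1 <= hi
  }, TRUE))
  expect_gte(hits, 96)
})

test_that("the growth gate applies the three thresholds strictly and tags the first violation", {
  cfg <- small_cfg(I0 = 10, L0 = 10)
  st <- rich_state(cfg)
  g <- sense_and_gate(st)
  occ <- st$strain > 0
  expect_true(all(g$permitted[occ]))
  expect_true(all(g$tag[occ] == "none"))
  # antibiotic exactly at threshold blocks (strict inequality)
  st$fields$ab[] <- cfg$g_at
  expect_false(any(sense_and_gate(st)$permitted))
  expect_true(all(sense_and_gate(st)$tag[occ] == "antibiotic"))
  # an I- cell starves for iso no matter how much leu is around
  st2 <- rich_state(small_cfg(I0 = 0, L0 = 1e6))
  g2 <- sense_and_gate(st2)
  isI <- st2$strain == 1L
  expect_false(any(g2$permitted[isI]))
  expect_true(all(g2$tag[isI] == "aa"))
  # food at threshold blocks with tag food
  st3 <- rich_state(small_cfg(I0 = 10, L0 = 10, F0 = 1))
  g3 <- sense_and_gate(st3)
  expect_false(any(g3$permitted))
  expect_true(all(g3$tag[st3$strain > 0] == "food"))
})

test_that("exchange accounting: single-cell secretion, food proviso, and the aa ledger", {
  cfg <- small_cfg(I0 = 10, L0 = 10)
  st <- init_colony(cfg, radius = 3, fractions = c(1, 0, 0), n_cells = 1,
                    seed = 1)
  site <- which(st$strain == 1L)
  before <- st$fields
  st2 <- exchange_step(st)
  expect_equal(st2$fields$leu[site], before$leu[site] + cfg$aa_secretion)
  expect_equal(st2$fields$food[site], before$food[site] - cfg$food_uptake)
  expect_equal(st2$fields$iso[site], before$iso[site] - cfg$aa_uptake)
  expect_equal(sum(st2$fields$enz), 0)
  # no cells: nothing moves
  empty <- init_colony(cfg, 3, c(1, 0, 0), 0, seed = 1)
  expect_equal(exchange_step(empty)$fields, empty$fields)
  # food everywhere below the threshold freezes all exchange
  starved <- rich_state(small_cfg(I0 = 10, L0 = 10, F0 = 0.5))
  expect_equal(exchange_step(starved)$fields, starved$fields)
  # ledger: aa change = secretion by fed donors - uptake by permitted takers
  mixed <- rich_state(cfg, n_cells = 40, fractions = c(0.5, 0.5, 0))
  g <- sense_and_gate(mixed)
  out <- exchange_step(mixed, g$permitted)
  n_I <- sum(mixed$strain == 1L)
  n_L <- sum(mixed$strain == 2L)
  d_leu <- sum(out$fields$leu) - sum(mixed$fields$leu)
  d_iso <- sum(out$fields$iso) - sum(mixed$fields$iso)
  expect_equal(d_leu, n_I * cfg$aa_secretion - n_L * cfg$aa_uptake,
               tolerance = 1e-8)
  expect_equal(d_iso, n_L * cfg$aa_secretion - n_I * cfg$aa_uptake,
               tolerance = 1e-8)
})

test_that("field transport conserves mass, leaves uniform fields alone, and degrades antibiotic only with enzyme", {
  cfg <- small_cfg(Ampi0 = 2)
  st <- rich_state(cfg)
  st$fields$food <- matrix(runif(60 * 60, 50, 100), 60, 60)
  tot <- sum(st$fields$food)
  st2 <- field_step(st)
  expect_lt(abs(sum(st2$fields$food) - tot) / tot, 1e-8)
  expect_equal(st2$fields$ab, st$fields$ab)   # enz = 0: no degradation
  uni <- rich_state(cfg)
  expect_equal(field_step(uni)$fields$food, uni$fields$food)
  uni$fields$enz[] <- 1
  after <- field_step(uni)
  expect_equal(after$fields$ab,
               uni$fields$ab * (1 - cfg$ab_decay), tolerance = 1e-12)
})

test_that("division accumulator: first division at step 4 for rate 0.25, crowding defers", {
  cfg <- small_cfg(I0 = 1e6, L0 = 1e6, F0 = 1e6, div_rate = 0.25)
  st <- init_colony(cfg, 3, c(1, 0, 0), 1, seed = 1)
  for (step in 1:8) {
    st <- division_step(st)
    n <- sum(st$strain > 0)
    if (step < 4) expect_equal(n, 1L)
    if (step == 4) expect_equal(n, 2L)
  }
  # fully surrounded cell never divides while enclosed: its accumulator
  # pegs at 1 (an unobstructed cell would have cycled below 1 twice by now)
  st2 <- init_colony(cfg, 3, c(1, 0, 0), 1, seed = 1)
  ctr <- which(st2$strain == 1L, arr.ind = TRUE)
  for (dr in -1:1) for (dc in -1:1) {
    st2$strain[ctr[1] + dr, ctr[2] + dc] <- 1L
  }
  for (step in 1:10) st2 <- division_step(st2)
  expect_equal(st2$acc[ctr[1], ctr[2]], 1)
  # enclosure persists: parents stay in place when they divide
  ring <- st2$strain[ctr[1] + (-1:1), ctr[2] + (-1:1)]
  expect_true(all(ring > 0))
})

test_that("the parasite's 10% division-rate advantage shows up in generation counts", {
  # free-growth harness: daughters are pruned so the focal cell never crowds
  generations <- function(strain_id, T) {
    cfg <- small_cfg(I0 = 1e6, L0 = 1e6, F0 = 1e6, div_rate = 0.25)
    st <- init_colony(cfg, 3, c(0, 0, 0) + (1:3 == strain_id), 1, seed = 1)
    site <- which(st$strain > 0)
    divisions <- 0
    for (step in seq_len(T)) {
      st <- division_step(st)
      extra <- setdiff(which(st$strain > 0), site)
      divisions <- divisions + length(extra)
      st$strain[extra] <- 0L
      st$acc[extra] <- 0
    }
    divisions
  }
  g_I <- generations(1, 40)
  g_P <- generations(3, 40)
  expect_equal(g_I, 10)   # rate 0.25: one division every 4 steps
  expect_equal(g_P, 11)   # rate 0.275 over 40 steps
  # implied population ratio matches the continuous-rate oracle 2^(0.025*40)
  expect_equal(2^(g_P - g_I), 2^(0.25 * 0.10 * 40), tolerance = 1e-12)
})

test_that("runs are bit-reproducible and keep fields non-negative, food non-increasing", {
  cfg <- small_cfg()
  r1 <- run_abm(cfg, 40, inoculum = list(radius = 6, fractions = c(.5, .5, 0),
                                         n_cells = 40), seed = 5)
  r2 <- run_abm(cfg, 40, inoculum = list(radius = 6, fractions = c(.5, .5, 0),
                                         n_cells = 40), seed = 5)
  expect_identical(r1$final$strain, r2$final$strain)
  expect_identical(r1$log, r2$log)
  r3 <- run_abm(cfg, 40, inoculum = list(radius = 6, fractions = c(.5, .5, 0),
                                         n_cells = 40), seed = 6)
  expect_false(identical(r1$final$strain, r3$final$strain))
  for (f in r1$final$fields) expect_true(all(f >= 0))
  # food is only consumed
  expect_lte(sum(r1$final$fields$food), cfg$F0 * 60 * 60)
})

test_that("obligate gate: monocultures and partnerless mixes cannot grow", {
  cfg <- small_cfg()   # I0 = L0 = 0: no supplemented amino acids
  for (mix in list(c(1, 0, 0), c(0, 1, 0), c(0, 0.5, 0.5))) {
    run <- run_abm(cfg, 50, inoculum = list(radius = 6, fractions = mix,
                                            n_cells = 40), seed = 3)
    expect_equal(tail(run$log$radius, 1), run$log$radius[1])
    expect_lte(sum(run$final$strain > 0), 40)
  }
  # both mutualists present: the colony does grow
  run2 <- run_abm(cfg, 80, inoculum = list(radius = 6,
                                           fractions = c(0.5, 0.5, 0),
                                           n_cells = 40), seed = 3)
  expect_gt(tail(run2$log$radius, 1), run2$log$radius[1] + 3)
})

test_that("antibiotic profiles have the requested geometry", {
  u <- antibiotic_profile("uniform", lattice_size = 30, c_hi = 1.5)
  expect_true(all(u == 1.5))
  g <- antibiotic_profile("linear-gradient", lattice_size = 30, c_lo = 0,
                          c_hi = 3)
  expect_equal(g[1, 1], 0)
  expect_equal(g[30, 1], 3)
  expect_true(all(diff(g[, 5]) > 0))
  h <- antibiotic_profile("half-plane", lattice_size = 30, c_lo = 0.2,
                          c_hi = 2)
  expect_true(all(h[16:30, ] == 2))
  expect_true(all(h[1:15, ] == 0.2))
  expect_error(antibiotic_profile("blob", 30))
})

test_that("edge versus interior: late-run activity concentrates at the front", {
  cfg <- abm_config(lattice_size = 120)
  run <- run_abm(cfg, 120, inoculum = list(radius = 10,
                                           fractions = c(.5, .5, 0),
                                           n_cells = 100), seed = 2)
  st <- run$final
  occ <- which(st$strain > 0, arr.ind = TRUE)
  r <- sqrt((occ[, 1] - st$centre[1])^2 + (occ[, 2] - st$centre[2])^2)
  rmax <- max(r)
  edge <- r >= rmax - 6
  interior <- r < rmax / 2
  expect_gte(mean(st$active[occ][edge]), mean(st$active[occ][interior]))
})

test_that("supplemented amino acids widen sectors, starve the facultative front band, and speed tracks activity", {
  levels <- c(0, 0.5, 30)
  seeds <- 1:10
  res <- lapply(seeds, function(s) {
    one <- lapply(levels, function(lev) {
      cfg <- abm_config(lattice_size = 160, I0 = lev, L0 = lev)
      run <- run_abm(cfg, 170,
                     inoculum = list(radius = 10, fractions = c(.5, .5, 0),
                                     n_cells = 120), seed = s)
      wd <- sector_widths(abm_label_grid(run), 40)
      list(gated = edge_gated_fraction(run$final),
           speed = area_expansion_speed(run),
           width = mean(wd$sectors$width))
    })
    list(gated = vapply(one, `[[`, 0, "gated"),
         speed = vapply(one, `[[`, 0, "speed"),
         width = vapply(one, `[[`, 0, "width"))
  })
  # (i) facultative mid level lowers the front-band growth-permitted share
  dip <- vapply(res, function(r) r$gated[2] < r$gated[1], TRUE)
  expect_gte(mean(dip), 0.8)
  # (ii) activity and expansion rate move together across levels
  cors <- vapply(res, function(r) cor(r$gated, r$speed), 0)
  expect_gte(mean(cors > 0), 0.8)
  # (iii) sector width at fixed radius increases with supplementation
  wid <- t(vapply(res, `[[`, numeric(3), "width"))
  expect_gt(mean(wid[, 2] > wid[, 1]), 0.8)
  expect_gt(mean(wid[, 3] > wid[, 1]), 0.8)
})
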