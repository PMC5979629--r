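test_that("a still field leaves every particle at its source cell", {
  g <- open_grid(20, 20)
  g$habitat_extant[5:8, 5:8] <- TRUE
  f <- uniform_field(g, 0, 0, days = 35)
  ep <- track_particles(g, f, release_schedule(particles_per_cell = 3),
                        seed = 1, dt_minutes = 180, diffusion_m2s = 0)
  expect_false(any(ep$lost))
  expect_equal(ep$end_cell, ep$source_cell)
})

test_that("uniform eastward flow displaces by u * t within one cell", {
  g <- open_grid(40, 20)                    # 160 km x 80 km, 4 km cells
  g$habitat_extant[3, 10] <- TRUE
  f <- uniform_field(g, u = 0.1, v = 0, days = 40)
  # 5-day drift at 0.1 m/s = 43.2 km east
  sched <- release_schedule(month_weights = c(jul = 1, aug = 0, sep = 0),
                            duration_days = 5, duration_weights = 1,
                            particles_per_cell = 6)
  ep <- track_particles(g, f, sched, seed = 2, dt_minutes = 15,
                        diffusion_m2s = 0)
  start_x <- (3 - 0.5) * g$cell_size
  expect_false(any(ep$lost))
  expect_equal(ep$end_x_km - start_x, rep(43.2, 6), tolerance = 1e-6)
  expect_lt(max(abs(ep$end_y_km - 9.5 * g$cell_size)), g$cell_size)
})

test_that("tracking is deterministic for a seed", {
  g <- open_grid(25, 25)
  g$habitat_extant[6:9, 6:9] <- TRUE
  f <- make_velocity_field(g, flow_config(years = 1995, season_days = 35,
                                          snapshot_interval_hours = 24,
                                          seed = 4))
  sched <- release_schedule(particles_per_cell = 3)
  ep1 <- track_particles(g, f, sched, seed = 11, dt_minutes = 120)
  ep2 <- track_particles(g, f, sched, seed = 11, dt_minutes = 120)
  expect_identical(ep1, ep2)
  ep3 <- track_particles(g, f, sched, seed = 12, dt_minutes = 120)
  expect_false(identical(ep1$end_x_km, ep3$end_x_km))
})

test_that("particles starting on land are rejected", {
  g <- make_seascape(seascape_config(nx = 30, ny = 30))
  f <- uniform_field(open_grid(30, 30), 0, 0, days = 35)
  land <- which(!g$sea)[1]
  expect_error(track_particles(g, f, release_schedule(),
                               source_cells = land), "on land")
})

test_that("dispersal matrix matches a hand count with loss on bare coast", {
  g <- open_grid(10, 10)
  # habitat: cells A (2,2) and B (5,2); coast elsewhere is bare sea
  g$habitat_extant[] <- FALSE
  A <- 2 + 1 * 10; B <- 5 + 1 * 10
  g$habitat_extant[c(A, B)] <- TRUE
  ep <- data.frame(
    source_cell = rep(A, 10),
    end_cell = c(rep(B, 4), rep(A, 2), rep(77L, 4)),   # 4 on bare coast
    lost = rep(FALSE, 10), year = 2000, release_hours = 0,
    duration_days = 5, end_x_km = 0, end_y_km = 0)
  expect_warning(P <- build_dispersal_matrix(ep, g, "cell", "extant"),
                 "zero released")   # row B had no releases
  expect_equal(P[paste0("c", A), paste0("c", B)], 0.4)
  expect_equal(P[paste0("c", A), paste0("c", A)], 0.2)
  expect_equal(sum(P[paste0("c", A), ]), 0.6)
  expect_true(all(is.na(P[paste0("c", B), ])))
})

test_that("row sum plus loss fraction is exactly one", {
  g <- open_grid(25, 25)
  g$habitat_extant[5:10, 5:10] <- TRUE
  f <- make_velocity_field(g, flow_config(years = 1995, season_days = 35,
                                          snapshot_interval_hours = 24,
                                          boundary_speed = 0.1, seed = 2))
  ep <- track_particles(g, f, release_schedule(particles_per_cell = 4),
                        seed = 3, dt_minutes = 120)
  P <- build_dispersal_matrix(ep, g, "cell", "extant")
  rel <- attr(P, "released")
  for (lab in rownames(P)) {
    cells <- as.integer(sub("c", "", lab))
    hits <- sum(!ep$lost & ep$source_cell == cells & !is.na(ep$end_cell) &
                  g$habitat_extant[pmax(ep$end_cell, 1)])
    expect_equal(sum(P[lab, ]) + (rel[[lab]] - hits) / rel[[lab]], 1)
  }
})

test_that("site-level aggregation equals direct site-level counting", {
  g <- open_grid(30, 30)
  g$habitat_extant[4:9, 4:7] <- TRUE
  g$habitat_extant[15:20, 20:23] <- TRUE
  hab <- which(g$habitat_extant)
  ys <- (hab - 1L) %/% g$nx + 1L
  g$sites <- list(S1 = hab[ys <= 10], S2 = hab[ys > 10])
  f <- make_velocity_field(g, flow_config(years = 1995, season_days = 35,
                                          snapshot_interval_hours = 24,
                                          boundary_speed = 0.08, seed = 5))
  ep <- track_particles(g, f, release_schedule(particles_per_cell = 5),
                        seed = 6, dt_minutes = 120)
  P_cell <- build_dispersal_matrix(ep, g, "cell", "extant")
  S_direct <- build_dispersal_matrix(ep, g, "site", "extant")
  S_agg <- aggregate_to_sites(P_cell, g)
  expect_equal(unclass(S_agg), unclass(S_direct), ignore_attr = TRUE,
               tolerance = 1e-12)
})

test_that("Monte-Carlo error of P shrinks like 1/sqrt(n)", {
  g <- open_grid(20, 20)
  g$habitat_extant[5:8, 5:8] <- TRUE
  f <- make_velocity_field(g, flow_config(years = 1995, season_days = 35,
                                          snapshot_interval_hours = 24,
                                          boundary_speed = 0.05,
                                          noise_speed = 0.05, seed = 7))
  est <- function(ppc, seeds) vapply(seeds, function(s) {
    ep <- track_particles(g, f, release_schedule(particles_per_cell = ppc),
                          seed = s, dt_minutes = 240)
    as.vector(unclass(build_dispersal_matrix(ep, g, "cell", "extant")))
  }, numeric(16 * 16))
  # per-entry Monte-Carlo variance across replicate seeds, averaged over
  # all matrix entries; quadrupling the particle count should cut it ~4x
  v_small <- mean(apply(est(2, 1:8), 1, stats::var))
  v_large <- mean(apply(est(8, 1:8), 1, stats::var))
  expect_lt(v_large, v_small / 2)
  expect_gt(v_large, v_small / 8)
})
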