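test_that("seascape generation is deterministic and honours its invariants", {
  cfg <- seascape_config(nx = 50, ny = 40, seed = 9)
  g1 <- make_seascape(cfg)
  g2 <- make_seascape(cfg)
  expect_identical(g1$sea, g2$sea)
  expect_identical(g1$habitat_extant, g2$habitat_extant)
  expect_identical(g1$sites, g2$sites)
  # habitat within sea; sites within habitat
  expect_true(all(g1$sea[g1$habitat_extant]))
  expect_true(all(g1$sea[g1$habitat_historic]))
  hab <- g1$habitat_extant | g1$habitat_historic
  for (s in names(g1$sites)) expect_true(all(hab[g1$sites[[s]]]))
  # the sea region is a single connected component (4-neighbour flood fill)
  comp <- local({
    lab <- matrix(0L, g1$nx, g1$ny)
    start <- which(g1$sea)[1]
    stack <- start; lab[start] <- 1L
    while (length(stack)) {
      c0 <- stack[length(stack)]; stack <- stack[-length(stack)]
      x <- (c0 - 1L) %% g1$nx + 1L; y <- (c0 - 1L) %/% g1$nx + 1L
      for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
        xn <- x + d[1]; yn <- y + d[2]
        if (xn < 1 || xn > g1$nx || yn < 1 || yn > g1$ny) next
        cn <- xn + (yn - 1L) * g1$nx
        if (g1$sea[cn] && lab[cn] == 0L) { lab[cn] <- 1L; stack <- c(stack, cn) }
      }
    }
    sum(lab == 1L)
  })
  expect_equal(comp, sum(g1$sea))
})

test_that("historic_fraction = 0 collapses historic habitat onto extant", {
  g <- make_seascape(seascape_config(nx = 40, ny = 40,
                                     historic_fraction = 0))
  expect_identical(g$habitat_historic, g$habitat_extant)
  g1 <- make_seascape(seascape_config(nx = 40, ny = 40,
                                      historic_fraction = 1))
  expect_gt(sum(g1$habitat_historic), sum(g1$habitat_extant))
})

test_that("extant habitat forms at least two disjoint archipelagos", {
  g <- make_seascape(seascape_config(nx = 60, ny = 48, n_archipelagos = 3))
  # count 8-connected components of the extant habitat
  lab <- matrix(0L, g$nx, g$ny); ncomp <- 0L
  for (c0 in which(g$habitat_extant)) {
    if (lab[c0] > 0L) next
    ncomp <- ncomp + 1L
    stack <- c0; lab[c0] <- ncomp
    while (length(stack)) {
      cc <- stack[length(stack)]; stack <- stack[-length(stack)]
      x <- (cc - 1L) %% g$nx + 1L; y <- (cc - 1L) %/% g$nx + 1L
      for (dx in -1:1) for (dy in -1:1) {
        xn <- x + dx; yn <- y + dy
        if (xn < 1 || xn > g$nx || yn < 1 || yn > g$ny) next
        cn <- xn + (yn - 1L) * g$nx
        if (g$habitat_extant[cn] && lab[cn] == 0L) {
          lab[cn] <- ncomp; stack <- c(stack, cn)
        }
      }
    }
  }
  expect_gte(ncomp, 2)
})

test_that("velocity fields are zero on land, finite, and seasonal snapshots align", {
  g <- make_seascape(seascape_config(nx = 40, ny = 30))
  f <- make_velocity_field(g, flow_config(years = 1995, season_days = 20,
                                          snapshot_interval_hours = 12))
  expect_equal(length(f$times), 20 * 2 + 1)
  for (yr in f$years) {
    expect_true(all(is.finite(yr$u)), all(is.finite(yr$v)))
    land <- which(!g$sea)
    for (t in c(1, dim(yr$u)[3])) {
      expect_true(all(yr$u[, , t][land] == 0))
      expect_true(all(yr$v[, , t][land] == 0))
    }
  }
  expect_error(flow_config(season_days = 10, snapshot_interval_hours = 7),
               "divide")
})

test_that("interior divergence of the analytic flow is small", {
  g <- open_grid(40, 40)
  f <- make_velocity_field(g, flow_config(years = 1995, season_days = 10,
                                          snapshot_interval_hours = 24,
                                          boundary_speed = 0.1,
                                          gyre_speed = 0.05,
                                          noise_speed = 0.05))
  u <- f$years[[1]]$u[, , 1]; v <- f$years[[1]]$v[, , 1]
  h <- g$cell_size * 1000
  div <- (u[3:40, 2:39] - u[1:38, 2:39]) / (2 * h) +
    (v[2:39, 3:40] - v[2:39, 1:38]) / (2 * h)
  speed <- sqrt(u^2 + v^2)
  # centred-difference divergence much smaller than speed / cell
  expect_lt(max(abs(div)), 0.2 * max(speed) / h)
})

test_that("interannual variability separates years", {
  g <- open_grid(30, 30)
  f <- make_velocity_field(g, flow_config(years = 1995:1998,
                                          season_days = 10,
                                          snapshot_interval_hours = 24,
                                          noise_speed = 0.08))
  # same snapshot, different years -> different fields
  d <- vapply(2:4, function(y)
    mean(abs(f$years[[y]]$u[, , 1] - f$years[[1]]$u[, , 1])), numeric(1))
  expect_true(all(d > 0))
  # and the per-year multipliers propagate
  expect_equal(vapply(f$years, `[[`, numeric(1), "nao"),
               c(1.2, 0.7, 1.0, 1.35))
})
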