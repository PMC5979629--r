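#' Configuration for a synthetic seascape
#'
#' Describes a coastline-bounded grid that emulates the structure of a
#' coastal shelf sea: land along the western edge with a wavy coast,
#' near-shore extant habitat grouped into disjoint archipelagos, an offshore
#' annulus of historic (lost) habitat, and named sampling-site polygons.
#' Defaults echo a ~400 x 320 km domain at 4 km resolution.
#'
#' @param nx,ny grid cell counts (>= 20 each).
#' @param cell_size_km cell edge length in km (default 4).
#' @param coast_width,coast_amp mean width and amplitude (cells) of the land
#'   band along the western edge.
#' @param n_archipelagos number of disjoint alongshore habitat groups.
#' @param habitat_fringe habitat extends this many cells offshore from the
#'   coast (default 3).
#' @param historic_fraction fraction of the offshore historic annulus
#'   retained as historic habitat (0 = no lost habitat, historic == extant).
#' @param sites_per_archipelago sampling sites per habitat group (default 2).
#' @param lon_range,lat_range mapped geographic extent (decimal degrees).
#' @param seed integer seed controlling the coastline jitter.
#' @return list of class `seascape_config`.
#' @export
seascape_config <- function(nx = 100L, ny = 80L, cell_size_km = 4,
                            coast_width = 8L, coast_amp = 4L,
                            n_archipelagos = 4L, habitat_fringe = 3L,
                            historic_fraction = 1, sites_per_archipelago = 2L,
                            lon_range = c(8, 13), lat_range = c(54, 59),
                            seed = 1L) {
  if (nx < 20L || ny < 20L) stop("grid must be at least 20 x 20 cells")
  stopifnot(historic_fraction >= 0, historic_fraction <= 1,
            n_archipelagos >= 2L, habitat_fringe >= 1L)
  structure(as.list(environment()), class = "seascape_config")
}

#' Build a synthetic seascape grid
#'
#' Deterministic for a given config (including its seed). The sea region is
#' connected by construction (land is a single western band); extant habitat
#' forms `n_archipelagos` disjoint near-shore patches; historic habitat adds
#' an offshore annulus absent from the extant map, emulating a lost offshore
#' bank.
#'
#' @param config a [seascape_config()].
#' @return list of class `seascape_grid` with logical `nx x ny` matrices
#'   `sea`, `habitat_extant`, `habitat_historic`, named `sites` (lists of
#'   linear cell indices), per-cell `lon`/`lat` matrices and the config.
#' @export
make_seascape <- function(config = seascape_config()) {
  c_ <- config
  nx <- c_$nx; ny <- c_$ny
  jitter <- withr_seed(c_$seed, round(stats::rnorm(ny, 0, 0.8)))
  edge <- pmax(1L, pmin(nx - 10L, round(
    c_$coast_width + c_$coast_amp * sin(2 * pi * 2 * seq_len(ny) / ny) +
      jitter)))
  sea <- matrix(TRUE, nx, ny)
  for (y in seq_len(ny)) sea[seq_len(edge[y]), y] <- FALSE
  # extant habitat: near-shore fringe inside alongshore archipelago bands
  extant <- matrix(FALSE, nx, ny)
  band_h <- floor(ny / (2 * c_$n_archipelagos))
  band_starts <- round(seq(2, ny - band_h - 1, length.out = c_$n_archipelagos))
  for (b in band_starts) {
    ys <- b:(b + band_h - 1L)
    for (y in ys) {
      xs <- (edge[y] + 1L):min(nx, edge[y] + c_$habitat_fringe)
      extant[xs, y] <- TRUE
    }
  }
  extant <- extant & sea
  if (!any(extant)) stop("config yields zero habitat cells")
  # historic annulus on an offshore bank, absent from the extant map
  historic <- extant
  if (c_$historic_fraction > 0) {
    cx <- min(nx - 4, max(edge) + c_$habitat_fringe + 12)
    cy <- round(ny * 0.55)
    ring <- which(outer(seq_len(nx), seq_len(ny), function(x, y) {
      r <- sqrt((x - cx)^2 + (y - cy)^2); r >= 3 & r <= 6
    }) & sea & !extant)
    ang <- atan2((ring - 1L) %/% nx + 1L - cy, (ring - 1L) %% nx + 1L - cx)
    keep <- ring[order(ang)][seq_len(ceiling(length(ring) *
                                               c_$historic_fraction))]
    historic[keep] <- TRUE
  }
  # site polygons: 2x2 habitat blocks at the ends of each archipelago
  sites <- list()
  for (bi in seq_along(band_starts)) {
    b <- band_starts[bi]
    anchors <- round(seq(b + 1, b + band_h - 2,
                         length.out = c_$sites_per_archipelago))
    for (si in seq_along(anchors)) {
      y0 <- anchors[si]
      cells <- integer(0)
      for (y in y0:(y0 + 1L)) {
        hx <- which(extant[, y])
        cells <- c(cells, hx[seq_len(min(2L, length(hx)))] + (y - 1L) * nx)
      }
      sites[[sprintf("S%02d", (bi - 1L) * c_$sites_per_archipelago + si)]] <-
        cells[extant[cells]]
    }
  }
  lon <- matrix(rep(c_$lon_range[1] + (seq_len(nx) - 0.5) / nx *
                      diff(c_$lon_range), ny), nx, ny)
  lat <- matrix(rep(c_$lat_range[1] + (seq_len(ny) - 0.5) / ny *
                      diff(c_$lat_range), each = nx), nx, ny)
  grid <- structure(list(nx = nx, ny = ny, cell_size = c_$cell_size_km,
                         sea = sea, habitat_extant = extant,
                         habitat_historic = historic, sites = sites,
                         lon = lon, lat = lat, coast_edge = edge,
                         config = c_),
                    class = "seascape_grid")
  validate_seascape(grid)
  grid
}

validate_seascape <- function(grid) {
  stopifnot(all(grid$habitat_extant[!grid$sea] == FALSE),
            all(grid$habitat_historic[!grid$sea] == FALSE),
            all(grid$habitat_extant[grid$habitat_extant] %in% TRUE))
  hab_all <- grid$habitat_extant | grid$habitat_historic
  for (s in names(grid$sites))
    if (!all(hab_all[grid$sites[[s]]]))
      stop("site ", s, " extends outside habitat")
  invisible(grid)
}

#' @export
print.seascape_grid <- function(x, ...) {
  cat(sprintf(
    "<seascape_grid> %d x %d cells (%g km), %d sea, %d extant / %d historic habitat, %d sites\n",
    x$nx, x$ny, x$cell_size, sum(x$sea), sum(x$habitat_extant),
    sum(x$habitat_historic), length(x$sites)))
  invisible(x)
}

#' Site centroid coordinates of a seascape grid
#' @param grid a `seascape_grid`
#' @return data.frame `site`, `lon`, `lat`
#' @export
site_coords <- function(grid) {
  do.call(rbind, lapply(names(grid$sites), function(s) {
    cells <- grid$sites[[s]]
    data.frame(site = s, lon = mean(grid$lon[cells]),
               lat = mean(grid$lat[cells]))
  }))
}

#' Configuration for synthetic surface currents
#'
#' The analytic flow is a poleward coastal boundary current (exponential
#' decay offshore), a basin-scale double gyre derived from a streamfunction,
#' and seeded streamfunction noise whose amplitude is scaled per year by an
#' NAO-like circulation multiplier — giving interannual variability without
#' a hydrodynamic model. All components are divergence-free in the interior
#' before land masking.
#'
#' @param boundary_speed alongshore current peak speed (m/s, default 0.15).
#' @param boundary_width e-folding width of the boundary current (cells).
#' @param direction +1 for northward (poleward) alongshore flow, -1 reversed.
#' @param gyre_speed double-gyre velocity scale (m/s).
#' @param noise_speed stochastic streamfunction velocity scale (m/s).
#' @param years simulated years (default 1995:2002).
#' @param nao_multipliers per-year circulation multipliers, recycled to
#'   `length(years)`; defaults emulate NAO swings around 1.
#' @param season_days simulated days per year (July 1 origin; default 122 =
#'   July-October, covering the release window plus the longest drift).
#' @param snapshot_interval_hours velocity snapshot spacing (default 24; the
#'   analytic field varies slowly, so linear interpolation between daily
#'   snapshots is accurate at desk scale).
#' @param seed integer seed for the noise modes.
#' @return list of class `flow_config`.
#' @export
flow_config <- function(boundary_speed = 0.15, boundary_width = 6,
                        direction = 1, gyre_speed = 0.05,
                        noise_speed = 0.05, years = 1995:2002,
                        nao_multipliers = c(1.2, 0.7, 1.0, 1.35, 0.8,
                                            1.1, 0.9, 1.05),
                        season_days = 122, snapshot_interval_hours = 24,
                        seed = 1L) {
  stopifnot(direction %in% c(-1, 1), season_days > 0)
  if ((season_days * 24) %% snapshot_interval_hours != 0)
    stop("snapshot interval must divide the simulated period")
  nao_multipliers <- rep_len(nao_multipliers, length(years))
  structure(as.list(environment()), class = "flow_config")
}

#' Build a time-varying velocity field on a seascape grid
#'
#' @param grid a `seascape_grid`.
#' @param config a [flow_config()].
#' @return list of class `velocity_field`: per-year `u`/`v` arrays
#'   (`nx x ny x n_snapshots`, m/s, zero on land), snapshot times in hours,
#'   years and multipliers.
#' @export
make_velocity_field <- function(grid, config = flow_config()) {
  c_ <- config
  nx <- grid$nx; ny <- grid$ny
  times <- seq(0, c_$season_days * 24, by = c_$snapshot_interval_hours)
  xs <- matrix(rep(seq_len(nx), ny), nx, ny)
  ys <- matrix(rep(seq_len(ny), each = nx), nx, ny)
  dist_off <- xs - matrix(rep(grid$coast_edge, each = nx), nx, ny)
  bnd_v <- c_$direction * c_$boundary_speed *
    exp(-pmax(dist_off, 0) / c_$boundary_width)
  bnd_v[!grid$sea] <- 0
  # double gyre from psi = A sin(pi X) sin(2 pi Y), X, Y in [0, 1]
  Lx_km <- nx * grid$cell_size; Ly_km <- ny * grid$cell_size
  X <- xs / nx; Y <- ys / ny
  A <- c_$gyre_speed * Ly_km * 1000 / (2 * pi)   # psi scale, m^2/s per unit
  gy_u <- -(A * 2 * pi / (Ly_km * 1000)) * sin(pi * X) * cos(2 * pi * Y)
  gy_v <- (A * pi / (Lx_km * 1000)) * cos(pi * X) * sin(2 * pi * Y)
  n_modes <- 6L
  years <- vector("list", length(c_$years))
  for (yi in seq_along(c_$years)) {
    modes <- withr_seed(c_$seed + 1000L * yi, list(
      kx = sample(1:4, n_modes, replace = TRUE),
      ky = sample(1:4, n_modes, replace = TRUE),
      phase = stats::runif(n_modes, 0, 2 * pi),
      omega = stats::runif(n_modes, 0.2, 1.5) * 2 * pi / (24 * 10),
      amp = stats::rnorm(n_modes, 1, 0.3)))
    amp_scale <- c_$noise_speed * c_$nao_multipliers[yi]
    u <- v <- array(0, dim = c(nx, ny, length(times)))
    for (ti in seq_along(times)) {
      t <- times[ti]
      mod_gyre <- 1 + 0.3 * sin(2 * pi * t / (24 * c_$season_days))
      uu <- gy_u * mod_gyre
      vv <- bnd_v + gy_v * mod_gyre
      if (amp_scale > 0) {
        for (k in seq_len(n_modes)) {
          ph <- 2 * pi * (modes$kx[k] * X + modes$ky[k] * Y) +
            modes$phase[k] + modes$omega[k] * t
          # streamfunction psi_k = B cos(ph): u = -dpsi/dy, v = dpsi/dx
          B <- amp_scale * modes$amp[k] * Ly_km * 1000 /
            (2 * pi * max(modes$kx[k], modes$ky[k])) / 2
          uu <- uu + B * 2 * pi * modes$ky[k] / (Ly_km * 1000) * sin(ph)
          vv <- vv - B * 2 * pi * modes$kx[k] / (Lx_km * 1000) * sin(ph)
        }
      }
      uu[!grid$sea] <- 0; vv[!grid$sea] <- 0
      u[, , ti] <- uu; v[, , ti] <- vv
    }
    years[[yi]] <- list(year = c_$years[yi], nao = c_$nao_multipliers[yi],
                        u = u, v = v)
  }
  structure(list(years = years, times = times,
                 snapshot_interval_hours = c_$snapshot_interval_hours,
                 season_days = c_$season_days, config = c_),
            class = "velocity_field")
}

#' @export
print.velocity_field <- function(x, ...) {
  cat(sprintf("<velocity_field> %d year(s), %d snapshots every %g h\n",
              length(x$years), length(x$times), x$snapshot_interval_hours))
  invisible(x)
}

# bilinear-in-space, linear-in-time velocity lookup (m/s), vectorized over
# particle positions given in km
field_velocity <- function(field, grid, x_km, y_km, t_hours, year_idx) {
  yr <- field$years[[year_idx]]
  nt <- length(field$times)
  ti <- findInterval(t_hours, field$times, rightmost.closed = TRUE)
  ti <- pmin(pmax(ti, 1L), nt - 1L)
  w_t <- (t_hours - field$times[ti]) / field$snapshot_interval_hours
  w_t <- pmin(pmax(w_t, 0), 1)
  cs <- grid$cell_size
  fx <- pmin(pmax(x_km / cs - 0.5, 0), grid$nx - 1.000001)
  fy <- pmin(pmax(y_km / cs - 0.5, 0), grid$ny - 1.000001)
  x0 <- floor(fx); y0 <- floor(fy)
  wx <- fx - x0; wy <- fy - y0
  i0 <- as.integer(x0) + 1L; j0 <- as.integer(y0) + 1L
  i1 <- pmin(i0 + 1L, grid$nx); j1 <- pmin(j0 + 1L, grid$ny)
  interp_one <- function(arr, tslice) {
    base <- (tslice - 1L) * grid$nx * grid$ny
    g <- function(i, j) arr[base + (j - 1L) * grid$nx + i]
    (1 - wx) * (1 - wy) * g(i0, j0) + wx * (1 - wy) * g(i1, j0) +
      (1 - wx) * wy * g(i0, j1) + wx * wy * g(i1, j1)
  }
  u <- (1 - w_t) * interp_one(yr$u, ti) + w_t * interp_one(yr$u, ti + 1L)
  v <- (1 - w_t) * interp_one(yr$v, ti) + w_t * interp_one(yr$v, ti + 1L)
  list(u = u, v = v)
}
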