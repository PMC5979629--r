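#' Release schedule for drifting shoots
#'
#' Releases span July-September with monthly proportions 20/50/30% and drift
#' durations mixed over 5/10/20/30 days with weights 5/10/20/65%, matching
#' field observations of flowering-shoot detachment and buoyancy. Release
#' day within a month is uniform.
#'
#' @param month_weights named weights for July/August/September (sum to 1).
#' @param duration_days candidate drift durations (days).
#' @param duration_weights mixture weights (sum to 1).
#' @param particles_per_cell particles released per source cell per year.
#' @param years subset of field years to simulate (default: all).
#' @return list of class `release_schedule`.
#' @export
release_schedule <- function(month_weights = c(jul = 0.20, aug = 0.50,
                                               sep = 0.30),
                             duration_days = c(5, 10, 20, 30),
                             duration_weights = c(0.05, 0.10, 0.20, 0.65),
                             particles_per_cell = 10L, years = NULL) {
  stopifnot(abs(sum(month_weights) - 1) < 1e-8,
            abs(sum(duration_weights) - 1) < 1e-8,
            all(duration_days > 0), particles_per_cell >= 1)
  structure(list(month_weights = month_weights,
                 duration_days = duration_days,
                 duration_weights = duration_weights,
                 particles_per_cell = as.integer(particles_per_cell),
                 years = years),
            class = "release_schedule")
}

# month start day offsets from July 1 and month lengths
.month_offsets <- c(jul = 0, aug = 31, sep = 62)
.month_lengths <- c(jul = 31, aug = 31, sep = 30)

#' Track buoyant particles through a velocity field
#'
#' Fourth-order Runge-Kutta advection of surface-drifting particles with
#' bilinear spatial and linear temporal velocity interpolation, optional
#' seeded sub-grid diffusion, and a beaching rule: a particle whose next
#' position falls on land stops where it is (its end cell is that last sea
#' cell); a particle leaving the domain is flagged lost. Deterministic for a
#' seed.
#'
#' @param grid a `seascape_grid`.
#' @param field a `velocity_field` built on `grid`.
#' @param schedule a [release_schedule()].
#' @param seed integer seed.
#' @param source_cells linear indices of release cells (default: extant
#'   habitat). All must be sea cells.
#' @param dt_minutes advection time step (default 15).
#' @param diffusion_m2s horizontal sub-grid diffusivity; 0 disables the
#'   random walk (default 10).
#' @return data.frame of class `trajectory_endpoints`: `source_cell`,
#'   `end_cell` (`NA` when lost), `lost`, `year`, `release_hours`,
#'   `duration_days`, `end_x_km`, `end_y_km`.
#' @export
track_particles <- function(grid, field, schedule = release_schedule(),
                            seed = 1L,
                            source_cells = which(grid$habitat_extant),
                            dt_minutes = 15, diffusion_m2s = 10) {
  if (!length(source_cells)) stop("no source cells")
  if (any(!grid$sea[source_cells]))
    stop("source cell(s) on land: ",
         paste(source_cells[!grid$sea[source_cells]], collapse = ", "))
  if (max(schedule$duration_days) > field$season_days)
    stop("drift durations exceed the simulated season")
  years <- schedule$years
  if (is.null(years)) years <- vapply(field$years, `[[`, numeric(1), "year")
  year_idx <- match(years, vapply(field$years, `[[`, numeric(1), "year"))
  if (anyNA(year_idx)) stop("schedule years not present in the field")
  dt_h <- dt_minutes / 60
  cs <- grid$cell_size
  out <- vector("list", length(year_idx))
  withr_seed(seed, for (k in seq_along(year_idx)) {
    yi <- year_idx[k]
    n <- length(source_cells) * schedule$particles_per_cell
    src <- rep(source_cells, each = schedule$particles_per_cell)
    mo <- names(schedule$month_weights)[
      sample.int(length(schedule$month_weights), n, replace = TRUE,
                 prob = schedule$month_weights)]
    rel_h <- (.month_offsets[mo] + stats::runif(n) * .month_lengths[mo]) * 24
    dur_d <- schedule$duration_days[
      sample.int(length(schedule$duration_days), n, replace = TRUE,
                 prob = schedule$duration_weights)]
    end_h <- pmin(rel_h + dur_d * 24, field$season_days * 24)
    # start at cell centres
    px <- ((src - 1L) %% grid$nx + 0.5) * cs
    py <- ((src - 1L) %/% grid$nx + 0.5) * cs
    done <- rep(FALSE, n); lost <- rep(FALSE, n)
    sigma_km <- if (diffusion_m2s > 0)
      sqrt(2 * diffusion_m2s * dt_minutes * 60) / 1000 else 0
    t <- 0
    t_end <- max(end_h)
    while (t < t_end && !all(done)) {
      act <- which(!done & rel_h <= t & end_h > t)
      if (length(act)) {
        x <- px[act]; y <- py[act]
        vel <- function(xx, yy, tt) {
          vv <- field_velocity(field, grid, xx, yy, tt, yi)
          list(u = vv$u * 3.6, v = vv$v * 3.6)      # m/s -> km/h
        }
        k1 <- vel(x, y, t)
        k2 <- vel(x + dt_h / 2 * k1$u, y + dt_h / 2 * k1$v, t + dt_h / 2)
        k3 <- vel(x + dt_h / 2 * k2$u, y + dt_h / 2 * k2$v, t + dt_h / 2)
        k4 <- vel(x + dt_h * k3$u, y + dt_h * k3$v, t + dt_h)
        nx_km <- x + dt_h / 6 * (k1$u + 2 * k2$u + 2 * k3$u + k4$u)
        ny_km <- y + dt_h / 6 * (k1$v + 2 * k2$v + 2 * k3$v + k4$v)
        if (sigma_km > 0) {
          nx_km <- nx_km + stats::rnorm(length(act), 0, sigma_km)
          ny_km <- ny_km + stats::rnorm(length(act), 0, sigma_km)
        }
        off <- nx_km < 0 | nx_km >= grid$nx * cs |
          ny_km < 0 | ny_km >= grid$ny * cs
        ci <- pmin(pmax(floor(nx_km / cs) + 1L, 1L), grid$nx)
        cj <- pmin(pmax(floor(ny_km / cs) + 1L, 1L), grid$ny)
        beached <- !off & !grid$sea[cbind(ci, cj)]
        move <- !off & !beached
        px[act[move]] <- nx_km[move]
        py[act[move]] <- ny_km[move]
        done[act[off]] <- TRUE; lost[act[off]] <- TRUE
        done[act[beached]] <- TRUE          # stays at last sea position
      }
      t <- t + dt_h
      done[!done & end_h <= t] <- TRUE      # drift time over
    }
    ei <- pmin(pmax(floor(px / cs) + 1L, 1L), grid$nx)
    ej <- pmin(pmax(floor(py / cs) + 1L, 1L), grid$ny)
    end_cell <- ifelse(lost, NA_integer_, ei + (ej - 1L) * grid$nx)
    out[[k]] <- data.frame(source_cell = src, end_cell = end_cell,
                           lost = lost, year = years[k],
                           release_hours = as.numeric(rel_h),
                           duration_days = dur_d,
                           end_x_km = px, end_y_km = py)
  })
  ep <- do.call(rbind, out)
  class(ep) <- c("trajectory_endpoints", class(ep))
  ep
}

#' Build a single-generation dispersal matrix from endpoints
#'
#' `P[i, j]` is the number of trajectories released in `i` that ended inside
#' `j`, divided by the total released from `i`. Destinations are restricted
#' to habitat cells (or site polygons); trajectories ending elsewhere, or
#' lost, count as loss, so row sums can fall below 1 (row sum + loss
#' fraction = 1 exactly).
#'
#' @param endpoints a `trajectory_endpoints` data.frame.
#' @param grid a `seascape_grid`.
#' @param level `"cell"` (labels = habitat cells) or `"site"` (labels =
#'   site polygons; sources restricted to cells inside sites).
#' @param habitat `"extant"` or `"historic"` habitat mask for the label set.
#' @return a labelled square matrix of class `dispersal_matrix` with
#'   attributes `generation = "single"`, `released` (per-row totals) and
#'   `level`. Rows with zero releases are `NA` (with a warning).
#' @export
build_dispersal_matrix <- function(endpoints, grid,
                                   level = c("cell", "site"),
                                   habitat = c("extant", "historic")) {
  level <- match.arg(level)
  habitat <- match.arg(habitat)
  if (!nrow(endpoints)) stop("no endpoints")
  mask <- if (habitat == "extant") grid$habitat_extant else
    grid$habitat_historic
  if (level == "cell") {
    cells <- which(mask)
    labels <- paste0("c", cells)
    n <- length(cells)
    P <- matrix(0, n, n, dimnames = list(labels, labels))
    rel <- stats::setNames(numeric(n), labels)
    src_lab <- paste0("c", endpoints$source_cell)
    tab_rel <- table(src_lab)
    rel[names(tab_rel)] <- as.numeric(tab_rel)
    ok <- !endpoints$lost & !is.na(endpoints$end_cell) &
      mask[pmax(endpoints$end_cell, 1L)]
    hits <- endpoints[ok, , drop = FALSE]
    if (nrow(hits)) {
      tt <- table(factor(paste0("c", hits$source_cell), levels = labels),
                  factor(paste0("c", hits$end_cell), levels = labels))
      P <- P + as.matrix(tt)
    }
  } else {
    labels <- names(grid$sites)
    n <- length(labels)
    cell2site <- rep(NA_character_, grid$nx * grid$ny)
    for (s in labels) cell2site[grid$sites[[s]]] <- s
    P <- matrix(0, n, n, dimnames = list(labels, labels))
    src_site <- cell2site[endpoints$source_cell]
    keep <- !is.na(src_site)
    rel <- stats::setNames(numeric(n), labels)
    tab_rel <- table(src_site[keep])
    rel[names(tab_rel)] <- as.numeric(tab_rel)
    end_site <- rep(NA_character_, nrow(endpoints))
    has_end <- !endpoints$lost & !is.na(endpoints$end_cell)
    end_site[has_end] <- cell2site[endpoints$end_cell[has_end]]
    ok <- keep & !is.na(end_site)
    if (any(ok)) {
      tt <- table(factor(src_site[ok], levels = labels),
                  factor(end_site[ok], levels = labels))
      P <- P + as.matrix(tt)
    }
  }
  zero <- rel == 0
  P <- sweep(P, 1, pmax(rel, 1), "/")
  if (any(zero)) {
    warning("source row(s) with zero released particles set to NA: ",
            paste(names(rel)[zero], collapse = ", "))
    P[zero, ] <- NA_real_
  }
  structure(P, generation = "single", released = rel, level = level,
            class = c("dispersal_matrix", "matrix", "array"))
}

#' Aggregate a cell-level dispersal matrix to site level
#'
#' Per-propagule semantics: the site-to-site probability is the
#' released-weighted mean over source cells of the summed probability of
#' ending in any destination-site cell. With equal releases per cell this
#' equals direct site-level counting of the same trajectories.
#'
#' @param P cell-level `dispersal_matrix` (labels `c<index>`).
#' @param grid a `seascape_grid`.
#' @param released per-source-cell release counts; defaults to the matrix's
#'   `released` attribute, else equal weights.
#' @return site-level matrix with the same `generation` tag.
#' @export
aggregate_to_sites <- function(P, grid, released = attr(P, "released")) {
  labels <- names(grid$sites)
  cells <- as.integer(sub("^c", "", rownames(P)))
  if (is.null(released)) released <- stats::setNames(rep(1, nrow(P)),
                                                     rownames(P))
  S <- matrix(0, length(labels), length(labels),
              dimnames = list(labels, labels))
  for (a in labels) {
    ra <- which(cells %in% grid$sites[[a]])
    if (!length(ra)) next
    w <- released[ra]
    if (sum(w) == 0) w <- rep(1, length(ra))
    for (b in labels) {
      cb <- which(cells %in% grid$sites[[b]])
      if (!length(cb)) next
      per_src <- rowSums(P[ra, cb, drop = FALSE])
      S[a, b] <- sum(w * per_src) / sum(w)
    }
  }
  structure(S, generation = attr(P, "generation"), level = "site",
            class = c("dispersal_matrix", "matrix", "array"))
}

#' @export
print.dispersal_matrix <- function(x, ...) {
  cat(sprintf("<dispersal_matrix> %d x %d (%s, %s level)\n",
              nrow(x), ncol(x), attr(x, "generation") %||% "untagged",
              attr(x, "level") %||% "?"))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
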