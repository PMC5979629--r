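# Programmatic fixtures shared across the suite. Everything is generated in
# code under fixed seeds; no data files.

# small deterministic two-site, two-locus table
toy_table <- function() {
  al <- rbind(c(101, 103, 201, 201),
              c(101, 101, 201, 203),
              c(103, 103, 203, 203),
              c(101, 103, 201, 203))
  genotype_table(al, paste0("r", 1:4), c("A", "A", "B", "B"),
                 c("L1", "L2"))
}

# draw n diploid genotypes per site under Hardy-Weinberg from given
# per-locus allele frequency lists (one list per site)
hw_table <- function(site_freqs, n, seed = 1) {
  withr::with_seed(seed, {
    rows <- list(); sites <- character(); ids <- character()
    k <- 0L
    for (s in names(site_freqs)) {
      fr <- site_freqs[[s]]
      for (i in seq_len(n)) {
        g <- unlist(lapply(fr, function(p)
          sample(as.integer(names(p)), 2, replace = TRUE, prob = p)))
        rows[[length(rows) + 1L]] <- g
        k <- k + 1L
        sites <- c(sites, s); ids <- c(ids, paste0(s, "_", i))
      }
    }
    genotype_table(do.call(rbind, rows), ids, sites,
                   paste0("L", seq_along(site_freqs[[1]])))
  })
}

# uniform-frequency biallelic loci, same freqs at every site
flat_freqs <- function(n_loci, alleles = c(10, 11), p = NULL) {
  if (is.null(p)) p <- rep(1 / length(alleles), length(alleles))
  lapply(seq_len(n_loci), function(l)
    stats::setNames(p, alleles))
}

# tiny all-sea grid for lagrangian/ibo tests (built directly so arbitrary
# small sizes are allowed)
open_grid <- function(nx = 30, ny = 30, cell = 4) {
  lon <- matrix(rep(8 + (seq_len(nx) - 0.5) / nx * 5, ny), nx, ny)
  lat <- matrix(rep(54 + (seq_len(ny) - 0.5) / ny * 5, each = nx), nx, ny)
  structure(list(nx = nx, ny = ny, cell_size = cell,
                 sea = matrix(TRUE, nx, ny),
                 habitat_extant = matrix(FALSE, nx, ny),
                 habitat_historic = matrix(FALSE, nx, ny),
                 sites = list(), lon = lon, lat = lat,
                 coast_edge = rep(0L, ny),
                 config = list(seed = 1)),
            class = "seascape_grid")
}

# constant-velocity field over an open grid (u, v in m/s)
uniform_field <- function(grid, u = 0, v = 0, days = 10) {
  f <- make_velocity_field(grid, flow_config(
    boundary_speed = 0, gyre_speed = 0, noise_speed = 0, years = 2000,
    nao_multipliers = 1, season_days = days,
    snapshot_interval_hours = 24, seed = 1))
  for (y in seq_along(f$years)) {
    f$years[[y]]$u[] <- u
    f$years[[y]]$v[] <- v
  }
  f
}

# independent Bellman-Ford relaxation over an 8-connected sea lattice,
# oracle route for sea_distance (no igraph)
bf_sea_distance <- function(sea, cell, from, to) {
  nx <- nrow(sea); ny <- ncol(sea)
  dist <- matrix(Inf, nx, ny)
  dist[from[1], from[2]] <- 0
  moves <- rbind(c(1, 0, 1), c(-1, 0, 1), c(0, 1, 1), c(0, -1, 1),
                 c(1, 1, sqrt(2)), c(1, -1, sqrt(2)),
                 c(-1, 1, sqrt(2)), c(-1, -1, sqrt(2)))
  repeat {
    changed <- FALSE
    for (x in seq_len(nx)) for (y in seq_len(ny)) {
      if (!sea[x, y] || !is.finite(dist[x, y])) next
      for (m in seq_len(nrow(moves))) {
        xn <- x + moves[m, 1]; yn <- y + moves[m, 2]
        if (xn < 1 || xn > nx || yn < 1 || yn > ny || !sea[xn, yn]) next
        nd <- dist[x, y] + moves[m, 3] * cell
        if (nd < dist[xn, yn] - 1e-12) { dist[xn, yn] <- nd; changed <- TRUE }
      }
    }
    if (!changed) break
  }
  dist[to[1], to[2]]
}

# all set partitions of 1..n (restricted growth strings)
all_partitions <- function(n) {
  out <- list()
  rec <- function(assign, maxc) {
    i <- length(assign) + 1L
    if (i > n) { out[[length(out) + 1L]] <<- assign; return(invisible()) }
    for (c in seq_len(maxc + 1L))
      rec(c(assign, c), max(maxc, c))
  }
  rec(integer(0), 0L)
  out
}

# exhaustive path-sum oracle: total probability over all length-g paths
path_sum_oracle <- function(P, g) {
  n <- nrow(P)
  out <- matrix(0, n, n, dimnames = dimnames(P))
  paths <- expand.grid(rep(list(seq_len(n)), g - 1))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (g == 1) { out[i, j] <- P[i, j]; next }
    tot <- 0
    for (r in seq_len(nrow(paths))) {
      seqn <- c(i, as.integer(paths[r, ]), j)
      p <- 1
      for (s in seq_len(g)) p <- p * P[seqn[s], seqn[s + 1]]
      tot <- tot + p
    }
    out[i, j] <- tot
  }
  out
}

partition_feasible <- function(M, cl, thr) {
  ids <- unique(cl)
  for (i in seq_along(ids)) for (j in seq_len(i - 1)) {
    a <- which(cl == ids[i]); b <- which(cl == ids[j])
    if (mean(M[a, b]) > thr) return(FALSE)
  }
  TRUE
}

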