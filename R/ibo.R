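#' Least-cost sea distance between sites
#'
#' Shortest over-water path on the sea-cell lattice (8-connected; diagonal
#' steps cost `sqrt(2)` cell sizes), computed with Dijkstra's algorithm.
#' Site coordinates are snapped to the nearest sea cell within `snap_radius`
#' cells. The optional `override` hook replaces individual pair values, for
#' cases where an automatic path is judged unrealistic.
#'
#' @param grid a `seascape_grid`.
#' @param coords data.frame `site`, `lon`, `lat`.
#' @param snap_radius maximum snap distance in cells (default 2).
#' @param override optional list of `list(a = , b = , value = )` manual
#'   replacements (applied symmetrically).
#' @return symmetric km distance matrix (`metric` attribute `"sea_km"`).
#' @export
sea_distance <- function(grid, coords, snap_radius = 2, override = NULL) {
  sea_cells <- which(grid$sea)
  idx_of <- match(seq_len(grid$nx * grid$ny), sea_cells)
  sx <- (sea_cells - 1L) %% grid$nx + 1L
  sy <- (sea_cells - 1L) %/% grid$nx + 1L
  # snap each site to the nearest sea cell
  site_cell <- vapply(seq_len(nrow(coords)), function(i) {
    gx <- (coords$lon[i] - grid$lon[1, 1]) /
      (grid$lon[2, 1] - grid$lon[1, 1]) + 1
    gy <- (coords$lat[i] - grid$lat[1, 1]) /
      (grid$lat[1, 2] - grid$lat[1, 1]) + 1
    d2 <- (sx - gx)^2 + (sy - gy)^2
    j <- which.min(d2)
    if (sqrt(d2[j]) > snap_radius)
      stop("site ", coords$site[i], " is on land beyond the snap radius")
    sea_cells[j]
  }, integer(1))
  ef <- et <- integer(0); ew <- numeric(0)
  for (d in list(c(1L, 0L, 1), c(0L, 1L, 1), c(1L, 1L, sqrt(2)),
                 c(1L, -1L, sqrt(2)))) {
    xn <- sx + d[1]; yn <- sy + d[2]
    okn <- xn >= 1L & xn <= grid$nx & yn >= 1L & yn <= grid$ny
    cn <- xn + (yn - 1L) * grid$nx
    okn[okn] <- grid$sea[cn[okn]]
    ef <- c(ef, which(okn)); et <- c(et, idx_of[cn[okn]])
    ew <- c(ew, rep(d[3] * grid$cell_size, sum(okn)))
  }
  g <- igraph::graph_from_edgelist(cbind(ef, et), directed = FALSE)
  igraph::E(g)$weight <- ew
  if (igraph::vcount(g) < length(sea_cells))
    g <- igraph::add_vertices(g, length(sea_cells) - igraph::vcount(g))
  D <- igraph::distances(g, v = idx_of[site_cell], to = idx_of[site_cell],
                         algorithm = "dijkstra")
  dimnames(D) <- list(coords$site, coords$site)
  for (ov in override) {
    D[ov$a, ov$b] <- D[ov$b, ov$a] <- ov$value
  }
  attr(D, "metric") <- "sea_km"
  D
}

check_mantel_inputs <- function(A, B) {
  stopifnot(nrow(A) == ncol(A), nrow(B) == ncol(B), nrow(A) == nrow(B))
  if (!is.null(rownames(A)) && !is.null(rownames(B)) &&
      !identical(rownames(A), rownames(B)))
    stop("matrix labels differ or are ordered differently")
}

mantel_perm_engine <- function(a_mat, b_vec, pick, permutations, seed,
                               alternative) {
  av <- a_mat[pick]
  if (isTRUE(stats::sd(av, na.rm = TRUE) == 0) ||
      isTRUE(stats::sd(b_vec, na.rm = TRUE) == 0))
    stop("constant matrix: correlation undefined")
  r_obs <- stats::cor(av, b_vec, use = "complete.obs")
  n <- nrow(a_mat)
  exceed <- withr_seed(seed, {
    e <- 0L
    for (k in seq_len(permutations)) {
      p <- sample.int(n)
      rp <- stats::cor(a_mat[p, p][pick], b_vec, use = "complete.obs")
      hit <- switch(alternative,
                    two.sided = abs(rp) >= abs(r_obs) - 1e-12,
                    greater = rp >= r_obs - 1e-12,
                    less = rp <= r_obs + 1e-12)
      if (hit) e <- e + 1L
    }
    e
  })
  structure(list(r = r_obs, p = (1 + exceed) / (1 + permutations),
                 permutations = permutations, alternative = alternative),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("<mantel> r = %.3f, p = %.4g (%d permutations, %s)\n",
              x$r, x$p, x$permutations, x$alternative))
  invisible(x)
}

#' Mantel test between two symmetric distance matrices
#'
#' Pearson correlation over the off-diagonal pairs, with significance from
#' simultaneous row/column permutation of the first matrix. The p-value is
#' `(1 + exceedances) / (1 + permutations)`, so it can never be zero.
#'
#' @param A,B symmetric labelled matrices with matching label order.
#' @param permutations permutation count (default 999; surveys typically
#'   use 1e5 for publication-grade p-values).
#' @param seed integer seed.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return a `mantel_result` with elements `r`, `p`, `permutations`.
#' @export
mantel <- function(A, B, permutations = 999L, seed = 1L,
                   alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  check_mantel_inputs(A, B)
  pick <- which(upper.tri(A))
  mantel_perm_engine(unclass(A), unclass(B)[pick], pick, permutations, seed,
                     alternative)
}

#' Mantel test for asymmetric matrices
#'
#' Correlates all ordered off-diagonal pairs (`A[i,j]` and `A[j,i]` enter as
#' distinct observations, preserving directional information); the null is
#' built by applying one joint row/column permutation to both axes of the
#' first matrix, which keeps each matrix's internal directional structure
#' intact.
#'
#' @inheritParams mantel
#' @export
asymmetric_mantel <- function(A, B, permutations = 999L, seed = 1L,
                              alternative = c("two.sided", "greater",
                                              "less")) {
  alternative <- match.arg(alternative)
  check_mantel_inputs(A, B)
  pick <- which(row(A) != col(A))
  mantel_perm_engine(unclass(A), unclass(B)[pick], pick, permutations, seed,
                     alternative)
}
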