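block_matrix <- function(sizes, within, between = 0) {
  n <- sum(sizes)
  M <- matrix(between, n, n)
  ends <- cumsum(sizes); starts <- c(1, head(ends, -1) + 1)
  for (b in seq_along(sizes))
    M[starts[b]:ends[b], starts[b]:ends[b]] <- within
  diag(M) <- 0
  dimnames(M) <- list(paste0("n", 1:n), paste0("n", 1:n))
  M
}

test_that("disconnected blocks are recovered exactly at any lower threshold", {
  M <- block_matrix(c(3, 4), within = 0.1)
  for (thr in c(0.001, 0.004, 0.05)) {
    p <- cluster_barriers(M, thr)
    expect_equal(p$n_clusters, 2)
    expect_equal(length(unique(p$cluster[1:3])), 1)
    expect_equal(length(unique(p$cluster[4:7])), 1)
    expect_gt(p$within_mean, p$between_mean)
  }
})

test_that("three blocks merge only across the inter-block mean above threshold", {
  # blocks X, Y, Z; between(X,Y) = 0.01 > 0.004, between(X,Z) =
  # between(Y,Z) = 0.001 -> X and Y merge, Z stays
  M <- block_matrix(c(3, 3, 3), within = 0.1, between = 0.001)
  M[1:3, 4:6] <- 0.01; M[4:6, 1:3] <- 0.01
  diag(M) <- 0
  p <- cluster_barriers(M, 0.004)
  expect_equal(p$n_clusters, 2)
  expect_equal(length(unique(p$cluster[1:6])), 1)
  expect_equal(length(unique(p$cluster[7:9])), 1)
  # exhaustive check: the returned partition is feasible (all inter-cluster
  # means <= threshold) and no coarser feasible partition was skipped
  expect_true(partition_feasible(M, p$cluster, 0.004))
})

test_that("partition feasibility holds against exhaustive enumeration on 7 nodes", {
  withr::with_seed(31, {
    n <- 7
    M <- matrix(stats::runif(n * n, 0, 0.05), n, n)
    M <- (M + t(M)) / 2; diag(M) <- 0
    dimnames(M) <- list(paste0("n", 1:n), paste0("n", 1:n))
    thr <- 0.02
    p <- cluster_barriers(M, thr)
    expect_true(partition_feasible(M, p$cluster, thr))
    # exhaustive scan: feasibility is attainable, and the greedy result has
    # at least as many clusters as the coarsest feasible partition demands
    parts <- all_partitions(n)
    feas <- vapply(parts, function(cl) partition_feasible(M, cl, thr),
                   logical(1))
    expect_true(any(feas))
    min_k <- min(vapply(parts[feas], function(cl) length(unique(cl)),
                        integer(1)))
    expect_gte(p$n_clusters, min_k)
  })
})

test_that("label permutation leaves the partition invariant up to relabelling", {
  M <- block_matrix(c(3, 3), within = 0.08, between = 0.001)
  p0 <- cluster_barriers(M, 0.004)
  perm <- withr::with_seed(5, sample(nrow(M)))
  Mp <- M[perm, perm]
  p1 <- cluster_barriers(Mp, 0.004)
  # same co-membership structure
  co0 <- outer(p0$cluster, p0$cluster, "==")[perm, perm]
  co1 <- outer(p1$cluster, p1$cluster, "==")
  expect_equal(unname(co0), unname(co1))
})

test_that("cluster count is monotone non-decreasing in the threshold", {
  withr::with_seed(17, {
    n <- 9
    M <- matrix(stats::runif(n * n, 0, 0.05), n, n)
    M <- (M + t(M)) / 2; diag(M) <- 0
    dimnames(M) <- list(paste0("n", 1:n), paste0("n", 1:n))
    ks <- vapply(c(0.002, 0.01, 0.02, 0.04),
                 function(t) cluster_barriers(M, t)$n_clusters, integer(1))
    expect_true(all(diff(ks) >= 0))
  })
})

test_that("a uniform matrix collapses to a single cluster with a notice", {
  M <- matrix(0.1, 4, 4); diag(M) <- 0
  dimnames(M) <- list(paste0("n", 1:4), paste0("n", 1:4))
  expect_message(p <- cluster_barriers(M, 0.004), "single cluster")
  expect_equal(p$n_clusters, 1)
})

test_that("a flow divide in the seascape splits the dispersal field in two", {
  # two counter-rotating gyres separated by a mid-domain flow divide: the
  # detected cluster boundary must coincide with the divide
  g <- open_grid(24, 30)
  g$habitat_extant[6:18, 4:12] <- TRUE     # southern gyre habitat
  g$habitat_extant[6:18, 19:27] <- TRUE    # northern gyre habitat
  f <- uniform_field(g, 0, 0, days = 35)
  Lx <- g$nx * g$cell_size * 1000; Ly <- g$ny * g$cell_size * 1000
  xs <- ((1:g$nx) - 0.5) / g$nx; ys <- ((1:g$ny) - 0.5) / g$ny
  S <- 0.12 * Ly / (2 * pi)                # psi = S sin(pi X) sin(2 pi Y)
  U <- outer(xs, ys, function(X, Y)
    -S * sin(pi * X) * cos(2 * pi * Y) * 2 * pi / Ly)
  V <- outer(xs, ys, function(X, Y)
    S * cos(pi * X) * sin(2 * pi * Y) * pi / Lx)
  for (t in seq_len(dim(f$years[[1]]$u)[3])) {
    f$years[[1]]$u[, , t] <- U
    f$years[[1]]$v[, , t] <- V
  }
  ep <- track_particles(g, f, release_schedule(particles_per_cell = 60),
                        seed = 2, dt_minutes = 120, diffusion_m2s = 20)
  P <- build_dispersal_matrix(ep, g, "cell", "extant")
  Pm <- unclass(P); Pm[is.na(Pm)] <- 0
  p <- cluster_barriers(Pm, between_threshold = 1e-3)
  cells <- as.integer(sub("c", "", names(p$cluster)))
  south <- ((cells - 1) %/% g$nx + 1) <= 15
  expect_equal(p$n_clusters, 2)
  expect_equal(length(unique(p$cluster[south])), 1)
  expect_equal(length(unique(p$cluster[!south])), 1)
  # the barrier edge list sits on the divide: no 4-adjacent cross pairs
  expect_equal(nrow(barrier_segments(p, g)), 0)
})
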