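tri_matrix <- function(vals) {
  M <- matrix(0, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  M["a", "b"] <- M["b", "a"] <- vals[1]
  M["b", "c"] <- M["c", "b"] <- vals[2]
  M["a", "c"] <- M["c", "a"] <- vals[3]
  M
}

test_that("the informative window brackets completion and fragmentation", {
  M <- tri_matrix(c(0.1, 0.2, 0.9))
  ts <- select_threshold(M, "distance")
  # graph is complete only above 0.9; fragments below 0.2
  expect_equal(ts$window, c(0.2, 0.9))
  expect_gt(ts$selected, 0.2); expect_lt(ts$selected, 0.9)
  # probability mode mirrors the logic with a geometric midpoint
  Mp <- tri_matrix(c(1e-4, 1e-2, 1e-6))
  tp <- select_threshold(Mp, "probability")
  expect_equal(tp$window, c(1e-6, 1e-4))
  expect_equal(tp$selected, 1e-5, tolerance = 1e-9)
})

test_that("degenerate constant matrices admit no window", {
  M <- matrix(0.5, 4, 4); diag(M) <- 0
  dimnames(M) <- list(letters[1:4], letters[1:4])
  expect_error(select_threshold(M, "distance"), "window|constant")
})

test_that("the scan is invariant to node order", {
  M <- withr::with_seed(2, {
    m <- matrix(stats::runif(36), 6, 6); m <- (m + t(m)) / 2; diag(m) <- 0
    dimnames(m) <- list(letters[1:6], letters[1:6])
    m
  })
  t0 <- select_threshold(M, "distance")
  perm <- c(4, 1, 6, 2, 5, 3)
  t1 <- select_threshold(M[perm, perm], "distance")
  expect_equal(t0$window, t1$window)
  expect_equal(t0$selected, t1$selected)
  expect_equal(t0$scan, t1$scan)
})

test_that("edge rules and isolation flags follow the mode", {
  M <- tri_matrix(c(0.1, 0.2, 0.9))
  g_none <- build_network(M, 0.05, "distance")
  expect_equal(igraph::ecount(g_none), 0)
  expect_true(all(igraph::V(g_none)$isolated))
  g_all <- build_network(M, 0, "probability")
  expect_equal(igraph::ecount(g_all), 3)
  # distance mode keeps strictly-below edges
  g_mid <- build_network(M, 0.25, "distance")
  expect_equal(igraph::ecount(g_mid), 2)
  iso <- stats::setNames(igraph::V(g_mid)$isolated, igraph::V(g_mid)$name)
  expect_false(any(iso))               # both retained edges touch all nodes
  g_tight <- build_network(M, 0.15, "distance")
  iso2 <- stats::setNames(igraph::V(g_tight)$isolated,
                          igraph::V(g_tight)$name)
  expect_true(iso2[["c"]])             # only the a-b edge survives
  # monotone edge shrink as the distance threshold tightens
  e <- vapply(c(1, 0.5, 0.15, 0.05), function(t)
    igraph::ecount(build_network(M, t, "distance")), numeric(1))
  expect_true(all(diff(e) <= 0))
})

test_that("node attributes attach, unknown sites warn, isolated nodes can drop", {
  M <- tri_matrix(c(0.1, 0.2, 0.9))
  attrs <- data.frame(site = c("a", "b", "c", "zz"), A_g = c(3, 4, 5, 9))
  expect_warning(g <- build_network(M, 0.25, "distance", node_attrs = attrs),
                 "zz")
  expect_equal(igraph::V(g)$A_g, c(3, 4, 5))
  g2 <- suppressWarnings(build_network(M, 0.15, "distance",
                                       node_attrs = attrs,
                                       drop_isolated = TRUE))
  expect_false("c" %in% igraph::V(g2)$name)
})

test_that("a designed stepping-stone hub ranks highest in centrality", {
  # hub-and-spoke probability matrix: spokes connect only through the hub
  n <- 7
  labs <- c("hub", paste0("sp", 1:6))
  M <- matrix(1e-8, n, n, dimnames = list(labs, labs))
  M["hub", -1] <- M[-1, "hub"] <- 1e-2
  diag(M) <- 0
  g <- build_network(M, 1e-4, "probability")
  deg <- igraph::degree(g)
  btw <- igraph::betweenness(g)
  expect_equal(names(which.max(deg)), "hub")
  expect_equal(names(which.max(btw)), "hub")
})

test_that("block-structured genetic distance fragments into its blocks", {
  # two clusters of demes connected internally; Dps from simulated
  # genotypes splits the network into the simulated blocks
  P <- matrix(0, 6, 6, dimnames = list(sprintf("D%02d", 1:6),
                                       sprintf("D%02d", 1:6)))
  within <- function(i, j) P[i, j] <<- 0.2
  diag(P) <- 0.5
  for (p in list(c(1, 2), c(2, 3), c(1, 3))) { within(p[1], p[2]); within(p[2], p[1]) }
  for (p in list(c(4, 5), c(5, 6), c(4, 6))) { within(p[1], p[2]); within(p[2], p[1]) }
  tb <- simulate_genotypes(P, sim_config(seed = 9, generations = 120,
                                         deme_size = 60, n_loci = 10,
                                         sample_size = 30, clonality = 0))
  D <- shared_allele_distance(clone_reduce(tb))
  blk <- rep(1:2, each = 3)
  same <- outer(blk, blk, "==") & upper.tri(D)
  diff_blk <- !outer(blk, blk, "==") & upper.tri(D)
  expect_lt(max(D[same]), min(D[diff_blk]))   # scales separate cleanly
  thr <- (max(D[same]) + min(D[diff_blk])) / 2   # intermediate cutoff
  g <- build_network(D, thr, "distance")
  m <- igraph::components(g)$membership
  expect_equal(length(unique(m[1:3])), 1)
  expect_equal(length(unique(m[4:6])), 1)
  expect_false(m["D01"] == m["D04"])
})

test_that("network export writes readable edge and node tables", {
  M <- tri_matrix(c(0.1, 0.2, 0.9))
  g <- build_network(M, 0.25, "distance")
  pre <- withr::local_tempfile()
  paths <- export_network(g, pre)
  expect_true(all(file.exists(paths)))
  edges <- utils::read.csv(paths[1])
  expect_equal(nrow(edges), 2)
  expect_true(all(edges$weight < 0.25))
})
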