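#' Oceanographic barrier clustering
#'
#' Partitions sites/cells into partially isolated clusters by minimizing
#' between-cluster connectivity: the directed matrix is symmetrized with the
#' pairwise maximum (connectivity in either direction defines adjacency,
#' unlike the min convention used for distance correlation), and starting
#' from the all-singleton partition the pair of clusters with the highest
#' mean inter-cluster connectivity is merged repeatedly while that mean
#' exceeds `between_threshold`. Ties break on the lexicographically smallest
#' label pair, so the result is fully deterministic; the `seed` argument is
#' accepted for interface uniformity but unused. Raising the threshold can
#' only coarsen the partition (merge order is threshold-independent).
#'
#' @param M non-negative square labelled connectivity matrix.
#' @param between_threshold stop merging once every inter-cluster mean
#'   connectivity is at or below this (default 0.004).
#' @param seed unused; retained for a uniform stage signature.
#' @return list of class `cluster_partition`: `cluster` (named integer
#'   vector), `n_clusters`, `within_mean`, `between_mean` (means of the
#'   input matrix over within/between off-diagonal pairs), `threshold`.
#' @export
cluster_barriers <- function(M, between_threshold = 0.004, seed = NULL) {
  stopifnot(nrow(M) == ncol(M), between_threshold > 0)
  if (any(M < 0, na.rm = TRUE)) stop("connectivity must be non-negative")
  labels <- rownames(M)
  if (is.null(labels)) labels <- paste0("n", seq_len(nrow(M)))
  S <- pmax(unclass(M), t(unclass(M)))
  S[is.na(S)] <- 0
  diag(S) <- 0
  # agglomeration with cached inter-cluster sums: the mean connectivity of a
  # merged pair is additive in the summed matrix, so each step is O(k^2)
  members <- stats::setNames(as.list(seq_along(labels)), labels)
  sizes <- rep(1L, length(labels))
  sums <- S
  repeat {
    k <- length(members)
    if (k <= 1L) break
    means <- sums / outer(sizes, sizes)
    diag(means) <- -Inf
    best_val <- max(means)
    if (best_val <= between_threshold) break
    hits <- which(means >= best_val - 1e-15, arr.ind = TRUE)
    hits <- hits[hits[, 1] < hits[, 2], , drop = FALSE]
    nm <- names(members)
    key <- apply(hits, 1L, function(h) paste(sort(nm[h]), collapse = "\r"))
    pick <- hits[order(key)[1L], ]
    i <- pick[1]; j <- pick[2]
    members[[i]] <- c(members[[i]], members[[j]])
    names(members)[i] <- min(nm[c(i, j)])
    sizes[i] <- sizes[i] + sizes[j]
    sums[i, ] <- sums[i, ] + sums[j, ]
    sums[, i] <- sums[, i] + sums[, j]
    members[[j]] <- NULL
    sizes <- sizes[-j]
    sums <- sums[-j, -j, drop = FALSE]
  }
  if (length(members) == 1L)
    message("matrix is uniformly connected above the threshold; ",
            "single cluster returned")
  cl <- integer(length(labels))
  ord <- order(vapply(members, min, integer(1)))
  for (ci in seq_along(ord)) cl[members[[ord[ci]]]] <- ci
  names(cl) <- labels
  offdiag <- row(S) != col(S)
  same <- outer(cl, cl, "==")
  Mn <- unclass(M); Mn[is.na(Mn)] <- 0
  within_mean <- if (any(same & offdiag)) mean(Mn[same & offdiag]) else
    NA_real_
  between_mean <- if (any(!same)) mean(Mn[!same]) else NA_real_
  structure(list(cluster = cl, n_clusters = length(members),
                 within_mean = within_mean, between_mean = between_mean,
                 threshold = between_threshold),
            class = "cluster_partition")
}

#' @export
print.cluster_partition <- function(x, ...) {
  cat(sprintf(
    "<cluster_partition> %d cluster(s) at threshold %g (within %.3g, between %.3g)\n",
    x$n_clusters, x$threshold, x$within_mean, x$between_mean))
  invisible(x)
}

#' Barrier segments between adjacent cells in different clusters
#'
#' For cell-level partitions on a `seascape_grid`: returns the pairs of
#' 4-adjacent habitat cells assigned to different clusters, i.e. the
#' plottable barrier edges.
#'
#' @param partition a `cluster_partition` with cell labels `c<index>`.
#' @param grid a `seascape_grid`.
#' @return data.frame `cell_a`, `cell_b`, `cluster_a`, `cluster_b`.
#' @export
barrier_segments <- function(partition, grid) {
  cells <- as.integer(sub("^c", "", names(partition$cluster)))
  cl <- stats::setNames(partition$cluster, cells)
  res <- list()
  for (i in seq_along(cells)) {
    c0 <- cells[i]
    x <- (c0 - 1L) %% grid$nx + 1L; y <- (c0 - 1L) %/% grid$nx + 1L
    for (d in list(c(1L, 0L), c(0L, 1L))) {
      xn <- x + d[1]; yn <- y + d[2]
      if (xn > grid$nx || yn > grid$ny) next
      cn <- xn + (yn - 1L) * grid$nx
      j <- match(cn, cells)
      if (is.na(j) || cl[i] == cl[j]) next
      res[[length(res) + 1L]] <- data.frame(
        cell_a = c0, cell_b = cn,
        cluster_a = unname(cl[i]), cluster_b = unname(cl[j]))
    }
  }
  if (!length(res)) return(data.frame(cell_a = integer(), cell_b = integer(),
                                      cluster_a = integer(),
                                      cluster_b = integer()))
  do.call(rbind, res)
}
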