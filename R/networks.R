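#' Intermediate-threshold scan of a connectivity matrix
#'
#' Finds the informative window of edge-inclusion cutoffs for a symmetric
#' matrix. In `distance` mode edges satisfy `value < t`: the graph is
#' complete for `t` above the largest off-diagonal value and fragments once
#' `t` drops below the percolation value (the bottleneck edge of the minimum
#' spanning tree). In `probability` mode edges satisfy `value > t` and the
#' window runs from the smallest off-diagonal value (complete below it) up
#' to the maximum-spanning-tree bottleneck (fragmenting above it). The
#' selected threshold is the window midpoint — arithmetic for distances,
#' geometric for probabilities (whose informative scales span decades).
#'
#' @param M symmetric labelled matrix.
#' @param mode `"distance"` or `"probability"`.
#' @return list of class `threshold_scan`: `window` (complete-end,
#'   fragmenting-end), `selected`, `mode` and a `scan` data.frame
#'   (`threshold`, `n_edges`, `n_components`, `giant`).
#' @export
select_threshold <- function(M, mode = c("distance", "probability")) {
  mode <- match.arg(mode)
  stopifnot(nrow(M) == ncol(M))
  n <- nrow(M)
  vals <- unclass(M)[upper.tri(M)]
  if (length(unique(vals)) < 2L)
    stop("degenerate constant matrix: no informative window")
  # percolation bottleneck via MST on the appropriate weighting
  g <- igraph::graph_from_adjacency_matrix(
    unclass(M), mode = "undirected", weighted = TRUE, diag = FALSE)
  w <- igraph::E(g)$weight
  mst <- igraph::mst(g, weights = if (mode == "distance") w else -w)
  bottleneck <- if (mode == "distance") max(igraph::E(mst)$weight) else
    min(igraph::E(mst)$weight)
  window <- if (mode == "distance") c(bottleneck, max(vals)) else
    c(min(vals), bottleneck)
  if (window[1] >= window[2])
    stop("no informative window: graph completes and fragments at the same value")
  selected <- if (mode == "distance") mean(window) else {
    if (any(window <= 0)) mean(window) else sqrt(prod(window))
  }
  cand <- sort(unique(vals))
  scan <- do.call(rbind, lapply(cand, function(t) {
    adj <- if (mode == "distance") unclass(M) < t else unclass(M) > t
    diag(adj) <- FALSE
    gg <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    comps <- igraph::components(gg)
    data.frame(threshold = t, n_edges = igraph::ecount(gg),
               n_components = comps$no, giant = max(comps$csize))
  }))
  structure(list(window = window, selected = selected, mode = mode,
                 scan = scan),
            class = "threshold_scan")
}

#' @export
print.threshold_scan <- function(x, ...) {
  cat(sprintf("<threshold_scan> %s mode, window [%.4g, %.4g], selected %.4g\n",
              x$mode, x$window[1], x$window[2], x$selected))
  invisible(x)
}

#' Build a thresholded connectivity graph
#'
#' Distance mode keeps edges with value below the threshold; probability
#' mode keeps edges with value above it. Isolated nodes are retained and
#' flagged (set `drop_isolated = TRUE` to remove them, the convention where
#' disconnected populations are dropped from the drawing).
#'
#' @param M symmetric labelled matrix.
#' @param threshold edge-inclusion cutoff (e.g. `select_threshold()$selected`
#'   or an externally chosen value).
#' @param mode `"distance"` or `"probability"`.
#' @param node_attrs optional data.frame with a `site` column and node
#'   attributes (e.g. allelic richness, cluster id, lon/lat); unknown sites
#'   are ignored, unmatched attribute rows warned about.
#' @param drop_isolated drop nodes with no retained edges (default FALSE).
#' @return an `igraph` graph with edge attribute `weight` (the matrix
#'   value) and node attribute `isolated`.
#' @export
build_network <- function(M, threshold, mode = c("distance", "probability"),
                          node_attrs = NULL, drop_isolated = FALSE) {
  mode <- match.arg(mode)
  stopifnot(nrow(M) == ncol(M))
  adj <- if (mode == "distance") unclass(M) < threshold else
    unclass(M) > threshold
  adj[is.na(adj)] <- FALSE
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  ends <- igraph::as_edgelist(g)
  if (nrow(ends))
    igraph::E(g)$weight <- unclass(M)[ends]
  igraph::V(g)$isolated <- igraph::degree(g) == 0
  if (!is.null(node_attrs)) {
    node_attrs <- as.data.frame(node_attrs)
    if (!"site" %in% names(node_attrs))
      stop("node_attrs needs a 'site' column")
    extra <- setdiff(node_attrs$site, igraph::V(g)$name)
    if (length(extra))
      warning("node_attrs rows without matching node skipped: ",
              paste(extra, collapse = ", "))
    m <- match(igraph::V(g)$name, node_attrs$site)
    for (col in setdiff(names(node_attrs), "site")) {
      v <- node_attrs[[col]][m]
      g <- igraph::set_vertex_attr(g, col, value = v)
    }
  }
  if (drop_isolated)
    g <- igraph::delete_vertices(g, igraph::V(g)[igraph::V(g)$isolated])
  g
}

#' Export a network as edge-list CSV and GraphML
#'
#' @param g an igraph graph from [build_network()].
#' @param path_prefix output prefix; writes `<prefix>_edges.csv`,
#'   `<prefix>_nodes.csv` and `<prefix>.graphml`.
#' @return invisible character vector of the written paths.
#' @export
export_network <- function(g, path_prefix) {
  el <- igraph::as_edgelist(g)
  edf <- data.frame(from = el[, 1], to = el[, 2],
                    weight = if (igraph::ecount(g))
                      igraph::E(g)$weight else numeric(0))
  p1 <- paste0(path_prefix, "_edges.csv")
  utils::write.csv(edf, p1, row.names = FALSE)
  ndf <- as.data.frame(igraph::vertex_attr(g))
  p2 <- paste0(path_prefix, "_nodes.csv")
  utils::write.csv(ndf, p2, row.names = FALSE)
  p3 <- paste0(path_prefix, ".graphml")
  igraph::write_graph(g, p3, format = "graphml")
  invisible(c(p1, p2, p3))
}
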