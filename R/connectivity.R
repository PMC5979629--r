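#' Multigeneration stepping-stone connectivity
#'
#' Raises the single-generation dispersal matrix to the g-th power after
#' restricting it to habitat cells, so that entry `(i, j)` sums the
#' probability over every length-g habitat-respecting dispersal route. Uses
#' repeated squaring. `generations = 1` returns the restricted matrix.
#'
#' @param P labelled square (sub-stochastic) dispersal matrix.
#' @param generations number of dispersal events (>= 1, default 32, enough
#'   to span a ~500 km domain by stepping-stone hops).
#' @param habitat_cells labels defining the habitat mask; default all of
#'   `P`'s labels.
#' @return `dispersal_matrix` tagged `multi` over the masked labels.
#' @export
multigeneration_connectivity <- function(P, generations = 32L,
                                         habitat_cells = rownames(P)) {
  stopifnot(generations >= 1, nrow(P) == ncol(P))
  keep <- intersect(rownames(P), habitat_cells)
  if (!length(keep)) stop("habitat mask shares no labels with the matrix")
  M <- unclass(P)[keep, keep, drop = FALSE]
  out <- mat_power(M, as.integer(generations))
  structure(out, generation = "multi", generations = generations,
            level = attr(P, "level"),
            class = c("dispersal_matrix", "matrix", "array"))
}

# dense matrix power by repeated squaring
mat_power <- function(M, g) {
  out <- diag(nrow(M)); dimnames(out) <- dimnames(M)
  base <- M
  while (g > 0L) {
    if (g %% 2L == 1L) out <- out %*% base
    base <- base %*% base
    g <- g %/% 2L
  }
  out
}

#' Symmetrize a dispersal matrix by the pairwise minimum
#'
#' `S[i, j] = min(M[i, j], M[j, i])`: the weaker direction defines the
#' symmetric connectivity, the convention suited to correlating with
#' (symmetric) genetic and geographic distances.
#'
#' @param M labelled square matrix.
#' @return symmetric matrix, elementwise `<= M`.
#' @export
symmetrize_min <- function(M) {
  stopifnot(nrow(M) == ncol(M))
  S <- pmin(unclass(M), t(unclass(M)))
  dimnames(S) <- dimnames(M)
  S
}

#' Log-transform a probability matrix with an offset
#'
#' `log10(M + offset)` elementwise; zeros map to `log10(offset)`. Standard
#' offsets: `1e-10` for single-generation matrices, `1e-30` for
#' multigeneration ones (whose nonzero entries are far smaller).
#'
#' @param M non-negative matrix.
#' @param offset positive offset.
#' @export
log_transform_matrix <- function(M, offset = 1e-10) {
  stopifnot(offset > 0)
  if (any(M < 0, na.rm = TRUE)) stop("negative entries")
  out <- log10(unclass(M) + offset)
  dimnames(out) <- dimnames(M)
  out
}
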