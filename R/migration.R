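#' Directional relative migration from G_ST
#'
#' Asymmetric, relative migration between all ordered site pairs, following
#' the geometric-mean pooling approach: for a pair (A, B) a hypothetical
#' migrant pool is built as the per-allele geometric mean of the two sites'
#' frequencies (renormalized per locus); the differentiation `d_A = G_ST(A,
#' pool)` is converted to the relative migration out of A towards B via
#' `m = (1/d_A - 1) / 4` (a source's alleles dominate the migrant pool, so
#' low `d_A` marks an exporter), and likewise for B. The full matrix is normalized
#' by its maximum, so the strongest ordered flow equals 1. Asymmetry
#' significance comes from bootstrap resampling of genets within sites.
#'
#' @param table a clone-reduced `genotype_table` with >= 2 sites.
#' @param stat differentiation statistic; only `"gst"` is implemented.
#' @param bootstraps bootstrap replicates for asymmetry p-values (default
#'   1000; 0 skips the bootstrap).
#' @param seed integer seed.
#' @return list of class `directional_migration`: `m` (matrix, rows =
#'   source, columns = recipient, diagonal `NA`, max entry 1),
#'   `m_raw` (pre-normalization), `asymmetry_p` (matrix of two-sided
#'   bootstrap p-values for `m[i,j] - m[j,i]`, `NA` when skipped).
#' @export
directional_relative_migration <- function(table, stat = "gst",
                                           bootstraps = 1000L, seed = 1L) {
  stopifnot(identical(stat, "gst"))
  sites <- site_names(table)
  if (length(sites) < 2L) stop("need at least two sites")
  m_raw <- migration_matrix_gst(allele_freqs(table), sites)
  mx <- max(m_raw, na.rm = TRUE)
  if (!is.finite(mx) || mx <= 0) stop("degenerate migration matrix")
  m <- m_raw / mx
  asym_p <- matrix(NA_real_, length(sites), length(sites),
                   dimnames = list(sites, sites))
  if (bootstraps > 0L) {
    diffs <- withr_seed(seed, {
      lapply(seq_len(bootstraps), function(b) {
        idx <- unlist(lapply(sites, function(s) {
          r <- which(table$site == s)
          sample(r, length(r), replace = TRUE)
        }))
        tb <- genotype_table(table$alleles[idx, , drop = FALSE],
                             paste0("b", seq_along(idx)), table$site[idx],
                             table$locus_names, NULL, table$missing_code)
        mb <- migration_matrix_gst(allele_freqs(tb), sites)
        mb / max(mb, na.rm = TRUE)
      })
    })
    for (i in seq_along(sites)) for (j in seq_along(sites)) {
      if (i >= j) next
      d <- vapply(diffs, function(mb) mb[i, j] - mb[j, i], numeric(1))
      d <- d[is.finite(d)]
      if (length(d)) {
        p <- 2 * min(mean(d <= 0), mean(d >= 0))
        p <- max(min(p, 1), 1 / (length(d) + 1))
        asym_p[i, j] <- asym_p[j, i] <- p
      }
    }
  }
  structure(list(m = m, m_raw = m_raw, asymmetry_p = asym_p,
                 bootstraps = bootstraps),
            class = "directional_migration")
}

#' @export
print.directional_migration <- function(x, ...) {
  cat(sprintf("<directional_migration> %d sites, max raw signal %.4g\n",
              nrow(x$m), max(x$m_raw, na.rm = TRUE)))
  invisible(x)
}

# raw directional matrix: entry [from = A, to = B] from d_A = GST(A, pool).
# A source's alleles dominate the hypothetical migrant pool, so low
# differentiation of A from the pool signals outflow from A towards B.
migration_matrix_gst <- function(freqs, sites) {
  n <- length(sites)
  L <- length(freqs[[1]])
  m <- matrix(NA_real_, n, n, dimnames = list(sites, sites))
  undefined <- list()
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    a <- sites[i]; b <- sites[j]
    d <- gst_vs_pool(freqs[[a]], freqs[[b]])
    if (is.na(d) || d <= 0) { undefined[[length(undefined) + 1L]] <- c(i, j) }
    else m[i, j] <- (1 / d - 1) / 4      # outflow from A, towards B
  }
  if (length(undefined)) {
    warning("pair(s) with zero differentiation from pool; set to matrix maximum")
    mx <- suppressWarnings(max(m, na.rm = TRUE))
    if (!is.finite(mx)) mx <- 1       # every pair undefined: flat signal
    for (u in undefined) m[u[1], u[2]] <- mx
  }
  m
}

# multilocus Nei G_ST between population A and the geometric-mean pool of
# A and B: (mean Ht - mean Hs) / mean Ht over loci
gst_vs_pool <- function(fa, fb) {
  ht <- hs <- numeric(0)
  for (l in seq_along(fa)) {
    pa <- fa[[l]]; pb <- fb[[l]]
    if (!length(pa) || !length(pb)) next
    alle <- union(names(pa), names(pb))
    va <- pa[alle]; va[is.na(va)] <- 0
    vb <- pb[alle]; vb[is.na(vb)] <- 0
    pool <- sqrt(va * vb)                 # geometric mean; (p, 0) -> 0
    if (sum(pool) <= 0) next
    pool <- pool / sum(pool)
    hs <- c(hs, mean(c(1 - sum(va^2), 1 - sum(pool^2))))
    ht <- c(ht, 1 - sum(((va + pool) / 2)^2))
  }
  if (!length(ht) || mean(ht) <= 0) return(NA_real_)
  (mean(ht) - mean(hs)) / mean(ht)
}
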