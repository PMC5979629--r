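#' Drift-based power simulation for detecting population structure
#'
#' Evaluates the statistical power of a marker set and sampling design to
#' detect a given true differentiation. Pooled allele frequencies from the
#' observed table serve as the ancestral state; each replicate drifts every
#' site independently for `t` generations of binomial sampling of `2 Ne`
#' gene copies, where `t` is chosen so that the expected differentiation is
#' `F_ST = 1 - (1 - 1/(2 Ne))^t`, then draws samples of the observed sizes
#' and tests overall allele-frequency homogeneity. Power is the fraction of
#' replicates significant at `alpha`; at `F_ST = 0` the result is the
#' realized type-I error, which should sit near `alpha`.
#'
#' @param table a clone-reduced `genotype_table` (sample sizes = genets).
#' @param Ne effective population size used for drift (default 200).
#' @param fst_targets numeric vector of target F_ST values (>= 0).
#' @param reps replicates per target (>= 100 for stable estimates).
#' @param alpha significance level (default 0.05).
#' @param seed integer seed.
#' @param t_max maximum drift generations allowed (default 100).
#' @param test `"chisq"` (Pearson chi-square summed over loci, the default)
#'   or `"fisher"` (per-locus exact tests combined by Fisher's method; slow,
#'   intended as an independent cross-check on small designs).
#' @return data.frame with columns `fst`, `t`, `power`.
#' @export
power_simulation <- function(table, Ne = 200L, fst_targets, reps = 1000L,
                             alpha = 0.05, seed = 1L, t_max = 100L,
                             test = c("chisq", "fisher")) {
  test <- match.arg(test)
  stopifnot(all(fst_targets >= 0), reps >= 1)
  sites <- site_names(table)
  n_i <- vapply(sites, function(s) sum(table$site == s), integer(1))
  L <- n_loci(table)
  pooled <- lapply(seq_len(L), function(l) {
    a <- as.vector(table$alleles[, locus_cols(l)])
    a <- a[a != table$missing_code]
    tb <- table(a)
    as.numeric(tb) / sum(tb)
  })
  gens <- vapply(fst_targets, function(f) {
    if (f == 0) return(0L)
    t <- round(log(1 - f) / log(1 - 1 / (2 * Ne)))
    as.integer(t)
  }, integer(1))
  if (any(gens > t_max))
    stop("target F_ST unreachable within t_max = ", t_max, " generations")
  out <- data.frame(fst = fst_targets, t = gens, power = NA_real_)
  for (k in seq_along(fst_targets)) {
    t <- gens[k]
    hits <- withr_seed(seed + k, {
      sum(vapply(seq_len(reps), function(r) {
        counts <- lapply(seq_len(L), function(l) {
          p0 <- pooled[[l]]
          vapply(seq_along(sites), function(i) {
            p <- p0
            for (gg in seq_len(t)) {
              cc <- stats::rmultinom(1, 2 * Ne, p)[, 1]
              p <- cc / sum(cc)
            }
            stats::rmultinom(1, 2 * n_i[i], p)[, 1]
          }, numeric(length(p0)))              # alleles x sites
        })
        pval <- if (test == "chisq") chisq_over_loci(counts)
        else fisher_over_loci(counts)
        pval < alpha
      }, logical(1)))
    })
    out$power[k] <- hits / reps
  }
  out
}

# Pearson chi-square on each locus's allele x site contingency table,
# statistics and dfs summed over informative loci
chisq_over_loci <- function(counts) {
  stat <- 0; df <- 0L
  for (tab in counts) {
    tab <- tab[rowSums(tab) > 0, , drop = FALSE]
    if (nrow(tab) < 2L || ncol(tab) < 2L) next
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    stat <- stat + sum((tab - E)^2 / E)
    df <- df + (nrow(tab) - 1L) * (ncol(tab) - 1L)
  }
  if (df == 0L) return(1)
  stats::pchisq(stat, df, lower.tail = FALSE)
}

fisher_over_loci <- function(counts) {
  ps <- vapply(counts, function(tab) {
    tab <- tab[rowSums(tab) > 0, , drop = FALSE]
    if (nrow(tab) < 2L || ncol(tab) < 2L) return(NA_real_)
    stats::fisher.test(tab, workspace = 2e6)$p.value
  }, numeric(1))
  ps <- ps[!is.na(ps)]
  if (!length(ps)) return(1)
  if (length(ps) == 1L) return(ps)
  stats::pchisq(-2 * sum(log(ps)), 2 * length(ps), lower.tail = FALSE)
}
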