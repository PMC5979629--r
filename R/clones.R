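#' Probability that a repeated multilocus genotype arose sexually
#'
#' `psex_binomial()` gives the probability of observing a given multilocus
#' genotype (MLG) at least `n_obs` times among `n_samples` independent sexual
#' recruits whose per-recruit genotype probability is `p_gen`; small values
#' mean the repeats are almost certainly ramets of one clone.
#'
#' @param p_gen probability of drawing the MLG in one sexual event.
#' @param n_samples number of sampled ramets at the site.
#' @param n_obs observed number of copies of the MLG.
#' @return `P(X >= n_obs)` with `X ~ Binomial(n_samples, p_gen)`.
#' @export
psex_binomial <- function(p_gen, n_samples, n_obs) {
  stopifnot(p_gen >= 0, p_gen <= 1, n_obs >= 1, n_samples >= n_obs)
  stats::pbinom(n_obs - 1L, n_samples, p_gen, lower.tail = FALSE)
}

#' Per-event genotype probability with inbreeding correction
#'
#' Probability of one multilocus genotype under random mating with
#' inbreeding coefficient `fis`: homozygotes contribute
#' `p^2 + p (1 - p) fis`, heterozygotes `2 p q (1 - fis)`, multiplied across
#' loci. Loci where either allele is missing are skipped (pairwise deletion).
#'
#' @param geno integer vector of length `2 * L` (allele pairs by locus).
#' @param freqs list of per-locus named allele-frequency vectors.
#' @param fis inbreeding coefficient in `[-1, 1]`.
#' @param missing_code missing-allele sentinel.
#' @export
pgen_fis <- function(geno, freqs, fis = 0, missing_code = 0L) {
  L <- length(freqs)
  stopifnot(length(geno) == 2L * L)
  p <- 1
  for (l in seq_len(L)) {
    a <- geno[2L * l - 1L]; b <- geno[2L * l]
    if (a == missing_code || b == missing_code) next
    f <- freqs[[l]]
    pa <- unname(f[as.character(a)]); pb <- unname(f[as.character(b)])
    if (is.na(pa) || is.na(pb)) return(0)
    pl <- if (a == b) pa^2 + pa * (1 - pa) * fis else 2 * pa * pb * (1 - fis)
    p <- p * max(pl, 0)
  }
  p
}

# single-pass multilocus FIS from a set of genotypes (rows of an allele
# matrix restricted to one site's distinct MLGs): 1 - mean(Ho)/mean(He)
site_fis <- function(alleles, missing_code = 0L) {
  L <- ncol(alleles) / 2L
  ho <- he <- numeric(0)
  for (l in seq_len(L)) {
    ab <- alleles[, locus_cols(l), drop = FALSE]
    ok <- ab[, 1] != missing_code & ab[, 2] != missing_code
    if (!any(ok)) next
    a <- as.vector(ab[ok, ])
    f <- as.numeric(table(a)) / length(a)
    he_l <- 1 - sum(f^2)
    if (he_l <= 0) next                       # monomorphic: uninformative
    ho <- c(ho, mean(ab[ok, 1] != ab[ok, 2]))
    he <- c(he, he_l)
  }
  if (!length(he)) return(0)
  max(min(1 - mean(ho) / mean(he), 0.999), -1)
}

#' Discriminate clones (repeated MLGs) from sexual recruits
#'
#' Within each site, ramets sharing an identical multilocus genotype are
#' candidate clones. For each repeated MLG the probability `p_sex` that the
#' repeats arose through independent sexual events is computed from
#' site allele frequencies with a single-pass inbreeding correction
#' ([pgen_fis()] with site-level F_IS estimated from the distinct MLGs), and
#' groups with `p_sex < alpha` are collapsed to one genet, keeping the
#' first-encountered ramet as representative. Repeats that fail the test are
#' treated as coincidental sexual identicals and stay separate genets.
#'
#' @param table a `genotype_table`.
#' @param alpha significance threshold in (0, 1), default 0.05.
#' @return list of class `clone_assignment`: `genet_id` (per ramet),
#'   `representative` (logical per ramet, one `TRUE` per genet),
#'   `psex` data.frame (site, mlg, n_obs, p_gen, p_sex, collapsed),
#'   `alpha`, and `n_genets` (named per-site genet counts).
#' @export
identify_clones <- function(table, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  keys <- mlg_keys(table)
  genet_id <- character(n_ramets(table))
  representative <- logical(n_ramets(table))
  ps_rows <- list()
  for (s in site_names(table)) {
    rows <- which(table$site == s)
    k <- keys[rows]
    uniq <- unique(k)                       # first-appearance order
    # allele freqs + FIS from the site's distinct MLGs (single pass)
    first_of <- rows[match(uniq, k)]
    ga <- table$alleles[first_of, , drop = FALSE]
    fis <- site_fis(ga, table$missing_code)
    freqs <- lapply(seq_len(n_loci(table)), function(l) {
      a <- as.vector(ga[, locus_cols(l)])
      a <- a[a != table$missing_code]
      if (!length(a)) return(stats::setNames(numeric(0), character(0)))
      tb <- table(a)
      stats::setNames(as.numeric(tb) / sum(tb), names(tb))
    })
    gcount <- 0L
    for (u in uniq) {
      members <- rows[k == u]
      n_obs <- length(members)
      collapse <- FALSE
      if (n_obs > 1L && length(rows) > 1L) {
        pg <- pgen_fis(table$alleles[members[1], ], freqs, fis,
                       table$missing_code)
        ps <- psex_binomial(pg, length(rows), n_obs)
        collapse <- ps < alpha
        ps_rows[[length(ps_rows) + 1L]] <-
          data.frame(site = s, mlg = u, n_obs = n_obs, p_gen = pg,
                     p_sex = ps, collapsed = collapse)
      }
      if (collapse || n_obs == 1L) {
        gcount <- gcount + 1L
        genet_id[members] <- sprintf("%s.g%03d", s, gcount)
        representative[members[1]] <- TRUE
      } else {
        for (m in members) {                # distinct sexual genets
          gcount <- gcount + 1L
          genet_id[m] <- sprintf("%s.g%03d", s, gcount)
          representative[m] <- TRUE
        }
      }
    }
  }
  psex <- if (length(ps_rows)) do.call(rbind, ps_rows) else
    data.frame(site = character(), mlg = character(), n_obs = integer(),
               p_gen = numeric(), p_sex = numeric(), collapsed = logical())
  n_genets <- vapply(site_names(table), function(s)
    length(unique(genet_id[table$site == s])), integer(1))
  structure(list(genet_id = genet_id, representative = representative,
                 psex = psex, alpha = alpha, n_genets = n_genets),
            class = "clone_assignment")
}

#' @export
print.clone_assignment <- function(x, ...) {
  cat(sprintf("<clone_assignment> %d ramets -> %d genets (alpha = %g)\n",
              length(x$genet_id), sum(x$representative), x$alpha))
  invisible(x)
}

#' Reduce a genotype table to one ramet per genet
#'
#' @param table a `genotype_table`.
#' @param clones a `clone_assignment` from [identify_clones()]; computed at
#'   the default alpha when omitted.
#' @return a clone-reduced `genotype_table` (genet level).
#' @export
clone_reduce <- function(table, clones = identify_clones(table)) {
  subset_ramets(table, clones$representative)
}

#' Probability of identity per site
#'
#' Discriminating power of the marker set: the probability that two
#' independent sexual individuals share a multilocus genotype by chance.
#' Per locus, `PI = sum(p_i^4) + sum_{i<j} (2 p_i p_j)^2` and the sib-pair
#' variant `PI_sibs = 0.25 + 0.5 sum(p^2) + 0.5 (sum(p^2))^2 -
#' 0.25 sum(p^4)`; loci multiply (independence).
#'
#' @param table a `genotype_table`, normally clone-reduced (frequencies from
#'   genets).
#' @return data.frame with columns `site`, `PI`, `PI_sibs`.
#' @export
probability_of_identity <- function(table) {
  fr <- allele_freqs(table)
  res <- lapply(names(fr), function(s) {
    pi_l <- vapply(fr[[s]], function(p) {
      if (!length(p)) return(1)
      s2 <- sum(p^2); s4 <- sum(p^4)
      # sum over unordered het pairs of (2 p_i p_j)^2 = 2 * (s2^2 - s4)
      s4 + 2 * (s2^2 - s4)
    }, numeric(1))
    sib_l <- vapply(fr[[s]], function(p) {
      if (!length(p)) return(1)
      s2 <- sum(p^2); s4 <- sum(p^4)
      0.25 + 0.5 * s2 + 0.5 * s2^2 - 0.25 * s4
    }, numeric(1))
    data.frame(site = s, PI = prod(pi_l), PI_sibs = prod(sib_l))
  })
  do.call(rbind, res)
}
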