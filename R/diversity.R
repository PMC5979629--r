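#' Genotypic (clonal) richness
#'
#' `R = (MLG - 1) / (N - 1)`: 1 when every sampled ramet is a distinct genet,
#' 0 for a monoclonal stand.
#'
#' @param N ramets sampled (>= 2).
#' @param MLG distinct multilocus genotypes, `1 <= MLG <= N`.
#' @export
genotypic_richness <- function(N, MLG) {
  if (any(N < 2)) stop("genotypic richness is undefined for N < 2")
  if (any(MLG < 1) || any(MLG > N)) stop("MLG must lie in [1, N]")
  (MLG - 1) / (N - 1)
}

# hypergeometric inclusion probability of an allele carried by G_a of G
# genets in a subset of g, computed on the log scale for stability
allele_inclusion_prob <- function(G, Ga, g) {
  if (G - Ga < g) return(1)
  1 - exp(lchoose(G - Ga, g) - lchoose(G, g))
}

#' Allelic richness standardized to g genotypes
#'
#' Rarefaction of allele counts to a common number of genets `g`, enabling
#' comparison of sites with unequal genet numbers. The point estimate is the
#' closed form: for each allele carried by `G_a` of the site's `G` genets,
#' the probability of appearing in a random subset of `g` genets is
#' `1 - choose(G - G_a, g) / choose(G, g)`; summing over alleles and
#' averaging over loci gives `A_g`. The SD comes from Monte-Carlo resampling
#' of genet subsets. Sites with fewer than `g` genets return `NA`.
#'
#' @param table a clone-reduced `genotype_table` (one ramet per genet).
#' @param g standardized genotype number (>= 2), default 21.
#' @param reps Monte-Carlo subsets for the SD (default 1000).
#' @param seed integer seed for the resampling.
#' @return data.frame with columns `site`, `G`, `A_g`, `A_g_sd`.
#' @export
allelic_richness_std <- function(table, g = 21L, reps = 1000L, seed = 1L) {
  if (g < 2) stop("g must be >= 2")
  L <- n_loci(table)
  res <- lapply(site_names(table), function(s) {
    rows <- which(table$site == s)
    G <- length(rows)
    if (G < g)
      return(data.frame(site = s, G = G, A_g = NA_real_, A_g_sd = NA_real_))
    per_locus <- vapply(seq_len(L), function(l) {
      ab <- table$alleles[rows, locus_cols(l), drop = FALSE]
      carriers <- lapply(sort(unique(as.vector(ab[ab != table$missing_code]))),
                         function(a) which(ab[, 1] == a | ab[, 2] == a))
      sum(vapply(carriers, function(ci)
        allele_inclusion_prob(G, length(ci), g), numeric(1)))
    }, numeric(1))
    a_hat <- mean(per_locus)
    sd_hat <- withr_seed(seed + G, {
      draws <- vapply(seq_len(reps), function(r) {
        sub <- sample(rows, g)
        mean(vapply(seq_len(L), function(l) {
          a <- as.vector(table$alleles[sub, locus_cols(l)])
          length(unique(a[a != table$missing_code]))
        }, numeric(1)))
      }, numeric(1))
      stats::sd(draws)
    })
    data.frame(site = s, G = G, A_g = a_hat, A_g_sd = sd_hat)
  })
  do.call(rbind, res)
}

# evaluate expr under a local RNG state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  expr
}

#' Per-site diversity summary
#'
#' Clone-aware population summary: ramet count N, genet count MLG, genotypic
#' richness R, rarefied allelic richness `A_g`, observed and expected
#' heterozygosity with standard errors across loci, and the inbreeding
#' coefficient `F = (H_E - H_O) / H_E` per polymorphic locus (positive =
#' heterozygote deficit) with a two-tailed permutation p-value obtained by
#' shuffling allele copies among genets within each locus.
#'
#' @param table a `genotype_table` at the ramet level (clones present).
#' @param clones optional `clone_assignment`; computed at alpha 0.05 if
#'   missing.
#' @param g rarefaction size for `A_g` (default 21).
#' @param permutations allele permutations for the F test (default 999).
#' @param seed integer seed.
#' @param unbiased if `TRUE`, apply the small-sample correction
#'   `2G/(2G - 1)` to `H_E`. Default `FALSE` (plain `1 - sum(p^2)`).
#' @return data.frame, one row per site, mirroring a genetic-diversity table:
#'   `site, N, MLG, R, A_g, A_g_sd, H_O, H_O_se, H_E, H_E_se, F, F_se, F_p`.
#' @export
diversity_summary <- function(table, clones = identify_clones(table),
                              g = 21L, permutations = 999L, seed = 1L,
                              unbiased = FALSE) {
  genets <- clone_reduce(table, clones)
  ar <- allelic_richness_std(genets, g = g, seed = seed)
  res <- lapply(site_names(table), function(s) {
    N <- sum(table$site == s)
    rows <- which(genets$site == s)
    G <- length(rows)
    ho_l <- he_l <- rep(NA_real_, n_loci(table))
    for (l in seq_len(n_loci(table))) {
      ab <- genets$alleles[rows, locus_cols(l), drop = FALSE]
      ok <- ab[, 1] != genets$missing_code & ab[, 2] != genets$missing_code
      if (!any(ok)) next
      a <- as.vector(ab[ok, ])
      p <- as.numeric(table(a)) / length(a)
      he <- 1 - sum(p^2)
      if (unbiased) he <- he * length(a) / (length(a) - 1)
      ho_l[l] <- mean(ab[ok, 1] != ab[ok, 2])
      he_l[l] <- he
    }
    poly <- which(!is.na(he_l) & he_l > 0)
    f_l <- (he_l[poly] - ho_l[poly]) / he_l[poly]
    f_obs <- if (length(f_l)) mean(f_l) else NA_real_
    f_p <- NA_real_
    if (length(poly) && G > 1 && permutations > 0) {
      f_p <- withr_seed(seed + N + G, {
        exceed <- 0L
        for (b in seq_len(permutations)) {
          fp <- vapply(poly, function(l) {
            ab <- genets$alleles[rows, locus_cols(l), drop = FALSE]
            ok <- ab[, 1] != genets$missing_code &
              ab[, 2] != genets$missing_code
            a <- sample(as.vector(ab[ok, ]))       # shuffle allele copies
            m <- matrix(a, ncol = 2)
            p <- as.numeric(table(a)) / length(a)
            he <- 1 - sum(p^2)
            if (he <= 0) return(NA_real_)
            (he - mean(m[, 1] != m[, 2])) / he
          }, numeric(1))
          fperm <- mean(fp, na.rm = TRUE)
          if (!is.na(fperm) && abs(fperm) >= abs(f_obs)) exceed <- exceed + 1L
        }
        (1 + exceed) / (1 + permutations)
      })
    }
    se <- function(x) if (sum(!is.na(x)) > 1)
      stats::sd(x, na.rm = TRUE) / sqrt(sum(!is.na(x))) else NA_real_
    data.frame(site = s, N = N, MLG = G,
               R = if (N > 1) genotypic_richness(N, G) else NA_real_,
               A_g = ar$A_g[ar$site == s], A_g_sd = ar$A_g_sd[ar$site == s],
               H_O = mean(ho_l, na.rm = TRUE), H_O_se = se(ho_l),
               H_E = mean(he_l, na.rm = TRUE), H_E_se = se(he_l),
               F = f_obs, F_se = se(f_l), F_p = f_p)
  })
  do.call(rbind, res)
}

#' Shared-allele genetic distance between sites
#'
#' `D_ps = 1 - ps`, where `ps` is the proportion of shared alleles. The
#' default population-frequency form takes, per locus, the overlap
#' `sum_a min(p_a^A, p_a^B)` of allele frequency distributions, averaged over
#' loci. The `"individual"` variant averages the per-pair shared-allele
#' proportion over all inter-site genet pairs instead.
#'
#' @param table a clone-reduced `genotype_table` with >= 2 sites.
#' @param method `"frequency"` (default) or `"individual"`.
#' @return symmetric distance matrix (class `matrix`, `metric` attribute
#'   `"Dps"`) with zero diagonal and entries in `[0, 1]`.
#' @export
shared_allele_distance <- function(table,
                                   method = c("frequency", "individual")) {
  method <- match.arg(method)
  sites <- site_names(table)
  counts <- vapply(sites, function(s) sum(table$site == s), integer(1))
  if (any(counts == 0L)) {
    warning("dropping site(s) with zero genets: ",
            paste(sites[counts == 0L], collapse = ", "))
    sites <- sites[counts > 0L]
  }
  if (length(sites) < 2L) stop("need at least two non-empty sites")
  D <- matrix(0, length(sites), length(sites),
              dimnames = list(sites, sites))
  if (method == "frequency") {
    fr <- allele_freqs(table)
    for (i in seq_along(sites)) for (j in seq_len(i - 1L)) {
      ps_l <- vapply(seq_len(n_loci(table)), function(l) {
        pa <- fr[[sites[i]]][[l]]; pb <- fr[[sites[j]]][[l]]
        if (!length(pa) || !length(pb)) return(NA_real_)
        alle <- union(names(pa), names(pb))
        pav <- pa[alle]; pav[is.na(pav)] <- 0
        pbv <- pb[alle]; pbv[is.na(pbv)] <- 0
        sum(pmin(pav, pbv))
      }, numeric(1))
      D[i, j] <- D[j, i] <- 1 - mean(ps_l, na.rm = TRUE)
    }
  } else {
    for (i in seq_along(sites)) for (j in seq_len(i - 1L)) {
      ri <- which(table$site == sites[i]); rj <- which(table$site == sites[j])
      acc <- 0; npairs <- 0L
      for (x in ri) for (y in rj) {
        sh <- vapply(seq_len(n_loci(table)), function(l) {
          gx <- table$alleles[x, locus_cols(l)]
          gy <- table$alleles[y, locus_cols(l)]
          if (any(gx == table$missing_code) || any(gy == table$missing_code))
            return(NA_real_)
          shared_pair(gx, gy) / 2
        }, numeric(1))
        acc <- acc + mean(sh, na.rm = TRUE); npairs <- npairs + 1L
      }
      D[i, j] <- D[j, i] <- 1 - acc / npairs
    }
  }
  attr(D, "metric") <- "Dps"
  D
}

# number of shared alleles (0, 1 or 2) between two diploid genotypes,
# counting multiplicity
shared_pair <- function(gx, gy) {
  s <- 0L
  gy_left <- gy
  for (a in gx) {
    hit <- match(a, gy_left)
    if (!is.na(hit)) { s <- s + 1L; gy_left <- gy_left[-hit] }
  }
  s
}
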