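#' Configuration for forward-time genotype simulation
#'
#' @param seed integer seed.
#' @param deme_size genets per deme (Wright-Fisher N, default 100).
#' @param n_loci microsatellite loci (default 10).
#' @param mutation_rate per-allele, per-generation strict stepwise (+/- 1
#'   repeat) mutation probability (default 1e-3, a typical microsatellite
#'   rate).
#' @param clonality probability that a recruit is a clonal copy of a local
#'   genet rather than a sexual offspring (default 0.3).
#' @param generations forward generations (default 100).
#' @param n_alleles_init ancestral alleles per locus (default 6).
#' @param allele_center central repeat score of the ancestral allele ladder.
#' @param sample_size ramets sampled per deme for the output table
#'   (default 40, capped at `deme_size`).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, deme_size = 100L, n_loci = 10L,
                       mutation_rate = 1e-3, clonality = 0.3,
                       generations = 100L, n_alleles_init = 6L,
                       allele_center = 20L, sample_size = 40L) {
  stopifnot(clonality >= 0, clonality <= 1, mutation_rate >= 0,
            mutation_rate <= 1, deme_size >= 2, n_loci >= 1,
            generations >= 1)
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate ramet-level genotypes along a known dispersal matrix
#'
#' Forward-time Wright-Fisher simulation of partially clonal demes coupled
#' by gene flow proportional to a dispersal matrix (rows = source, columns
#' = destination): each sexual recruit in deme j draws its parent deme with
#' probability proportional to column j, then two parents at random from
#' that deme; clonal recruits copy a random local genet unchanged. Sexual
#' gametes mutate by strict stepwise steps. All demes start from one
#' ancestral allele pool, so differentiation accrues purely from drift
#' shaped by the dispersal matrix. The returned table samples ramets per
#' deme with clones present, ready for the full genetics pipeline.
#'
#' @param dispersal non-negative labelled square matrix, entries in [0, 1].
#' @param config a [sim_config()].
#' @return a `genotype_table` with sites named by the dispersal labels.
#' @export
simulate_genotypes <- function(dispersal, config = sim_config()) {
  stopifnot(nrow(dispersal) == ncol(dispersal))
  P <- unclass(dispersal)
  if (any(P < 0 | P > 1, na.rm = TRUE))
    stop("dispersal entries must lie in [0, 1]")
  P[is.na(P)] <- 0
  demes <- rownames(P)
  if (is.null(demes)) demes <- sprintf("D%02d", seq_len(nrow(P)))
  if (any(rowSums(P) == 0))
    warning("all-zero dispersal row(s) (isolated exporter): ",
            paste(demes[rowSums(P) == 0], collapse = ", "))
  c_ <- config
  nd <- length(demes); N <- c_$deme_size; L <- c_$n_loci
  withr_seed(c_$seed, {
    anc <- lapply(seq_len(L), function(l) {
      alle <- c_$allele_center + seq_len(c_$n_alleles_init) -
        ceiling(c_$n_alleles_init / 2)
      w <- stats::runif(c_$n_alleles_init)
      list(alleles = alle, p = w / sum(w))
    })
    pop <- lapply(seq_len(nd), function(d) {
      m <- matrix(0L, N, 2L * L)
      for (l in seq_len(L))
        m[, locus_cols(l)] <- sample(anc[[l]]$alleles, 2L * N,
                                     replace = TRUE, prob = anc[[l]]$p)
      m
    })
    src_prob <- lapply(seq_len(nd), function(j) {
      q <- P[, j]
      if (sum(q) == 0) q[j] <- 1        # fully isolated sink: local only
      q / sum(q)
    })
    for (gen in seq_len(c_$generations)) {
      newpop <- vector("list", nd)
      for (j in seq_len(nd)) {
        clonal <- stats::runif(N) < c_$clonality
        m <- matrix(0L, N, 2L * L)
        n_cl <- sum(clonal)
        if (n_cl)
          m[clonal, ] <- pop[[j]][sample.int(N, n_cl, replace = TRUE), ]
        n_sx <- N - n_cl
        if (n_sx) {
          sdeme <- sample.int(nd, n_sx, replace = TRUE,
                              prob = src_prob[[j]])
          p1 <- sample.int(N, n_sx, replace = TRUE)
          p2 <- sample.int(N, n_sx, replace = TRUE)
          childs <- matrix(0L, n_sx, 2L * L)
          for (l in seq_len(L)) {
            cc <- locus_cols(l)
            col1 <- cc[1L + (stats::runif(n_sx) < 0.5)]
            col2 <- cc[1L + (stats::runif(n_sx) < 0.5)]
            a1 <- integer(n_sx); a2 <- integer(n_sx)
            for (s in unique(sdeme)) {
              w <- sdeme == s
              a1[w] <- pop[[s]][cbind(p1[w], col1[w])]
              a2[w] <- pop[[s]][cbind(p2[w], col2[w])]
            }
            childs[, cc[1]] <- a1; childs[, cc[2]] <- a2
          }
          if (c_$mutation_rate > 0) {
            mut <- stats::runif(length(childs)) < c_$mutation_rate
            if (any(mut))
              childs[mut] <- childs[mut] +
                sample(c(-1L, 1L), sum(mut), replace = TRUE)
          }
          m[!clonal, ] <- childs
        }
        newpop[[j]] <- m
      }
      pop <- newpop
    }
    k <- min(c_$sample_size, N)
    rows <- lapply(seq_len(nd), function(d)
      pop[[d]][sample.int(N, k), , drop = FALSE])
    genotype_table(do.call(rbind, rows),
                   ramet_id = paste0(rep(demes, each = k), "_r",
                                     rep(seq_len(k), nd)),
                   site = rep(demes, each = k),
                   locus_names = sprintf("L%02d", seq_len(L)))
  })
}

#' Asymmetric 1-D stepping-stone dispersal matrix
#'
#' Convenience generator for a chain of demes with local retention, a
#' dominant downstream direction (emulating a boundary current) and weak
#' upstream leakage. Row = source, column = destination; rows are
#' sub-stochastic.
#'
#' @param n_sites chain length.
#' @param retention probability of staying (default 0.55).
#' @param downstream probability of moving one step down-chain (default
#'   0.25).
#' @param upstream probability of moving one step up-chain (default 0.05).
#' @return labelled `n_sites x n_sites` matrix.
#' @export
stepping_stone_matrix <- function(n_sites, retention = 0.55,
                                  downstream = 0.25, upstream = 0.05) {
  stopifnot(n_sites >= 2, retention + downstream + upstream <= 1)
  labs <- sprintf("D%02d", seq_len(n_sites))
  P <- matrix(0, n_sites, n_sites, dimnames = list(labs, labs))
  diag(P) <- retention
  for (i in seq_len(n_sites - 1L)) P[i, i + 1L] <- downstream
  for (i in 2:n_sites) P[i, i - 1L] <- upstream
  P
}
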