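#' Pipeline configuration
#'
#' Assembles every stage's parameters with defaults matching the standard
#' analysis: clone test alpha 0.05, rarefaction to 21 genotypes, 32
#' stepping-stone generations, log offsets 1e-10 (single generation) and
#' 1e-30 (multigeneration), barrier threshold 0.004. Permutations default to
#' 999 at desk scale (publication runs use 1e5). Unknown keys in `...` or in
#' a loaded file are rejected.
#'
#' @param seed master seed; every stage derives its stream from it.
#' @param ... overrides for any default, possibly nested lists (e.g.
#'   `seascape = list(nx = 60)`).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, ...) {
  sea_def <- ctor_defaults(seascape_config, "seed")
  sea_def$nx <- 60L; sea_def$ny <- 48L; sea_def$n_archipelagos <- 3L
  flow_def <- ctor_defaults(flow_config, "seed")
  flow_def$years <- 1995:1996
  sched_def <- ctor_defaults(release_schedule, character(0))
  sched_def$particles_per_cell <- 8L
  base <- list(
    seed = as.integer(seed),
    stages = list(track = TRUE, genetics = TRUE, migration = TRUE,
                  barriers = TRUE, ibo = TRUE, networks = TRUE),
    seascape = sea_def,
    flow = flow_def,
    schedule = sched_def,
    tracking = list(dt_minutes = 60, diffusion_m2s = 10),
    connectivity = list(generations = 32L, offset_single = 1e-10,
                        offset_multi = 1e-30),
    simulation = {
      sim_def <- ctor_defaults(sim_config, "seed")
      sim_def$deme_size <- 80L; sim_def$generations <- 80L
      sim_def
    },
    genetics = list(alpha = 0.05, g = 21L, permutations = 199L),
    migration = list(bootstraps = 199L),
    barriers = list(between_threshold = 0.004),
    ibo = list(permutations = 999L),
    networks = list(drop_isolated = FALSE))
  merge_config(base, list(...), "pipeline_config")
}

# evaluated formals of a stage constructor, minus dropped args
ctor_defaults <- function(fn, drop) {
  f <- formals(fn)
  f <- f[setdiff(names(f), drop)]
  lapply(f, function(x) if (is.language(x)) eval(x, baseenv()) else x)
}

merge_config <- function(base, upd, cls) {
  for (k in names(upd)) {
    if (!k %in% names(base))
      stop("unknown configuration key: ", k)
    if (is.list(base[[k]]) && is.list(upd[[k]])) {
      for (k2 in names(upd[[k]])) {
        if (!k2 %in% names(base[[k]]))
          stop("unknown configuration key: ", k, "$", k2)
        base[[k]][[k2]] <- upd[[k]][[k2]]
      }
    } else base[[k]] <- upd[[k]]
  }
  structure(base, class = cls)
}

#' Load a pipeline configuration from YAML or JSON
#' @param path config file (`.yml`/`.yaml`/`.json`).
#' @return a `pipeline_config` (unknown keys rejected).
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
  else yaml::read_yaml(path)
  seed <- raw$seed %||% 1L
  raw$seed <- NULL
  do.call(pipeline_config, c(list(seed = seed), raw))
}

#' Run the full connectivity pipeline
#'
#' Seeded, end-to-end run on a synthetic seascape: build grid and currents,
#' track particles, assemble single- and multigeneration (extant and
#' historic) dispersal matrices at cell and site level, simulate genotypes
#' along the site-level dispersal, run the genetics stage (clones,
#' diversity, shared-allele distance, probability of identity), directional
#' migration, barrier clustering, the isolation-by-distance/oceanography
#' Mantel battery and the four threshold networks. All outputs are written
#' to `out_dir` as CSV plus a JSON manifest of seeds, parameters and stage
#' timings; reruns with the same config are bit-reproducible.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created; must not require recursive
#'   parents beyond one level).
#' @return invisibly, a list with the principal in-memory results.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  timings <- list()
  tick <- function(stage, expr) {
    s <- Sys.time()
    val <- force(expr)
    timings[[stage]] <<- round(as.numeric(Sys.time() - s, units = "secs"), 3)
    message(sprintf("[%s] done in %.1fs", stage, timings[[stage]]))
    val
  }
  seed <- config$seed
  res <- list(config = config)

  grid <- tick("seascape", make_seascape(do.call(seascape_config,
    c(config$seascape, list(seed = seed)))))
  coords <- site_coords(grid)
  res$grid <- grid

  if (!config$stages$track)
    stop("stage 'track' is disabled but downstream stages need its output")
  field <- tick("flow", make_velocity_field(grid, do.call(flow_config,
    c(config$flow, list(seed = seed + 1L)))))
  sched <- do.call(release_schedule, config$schedule)
  ep_ex <- tick("track_extant", track_particles(
    grid, field, sched, seed = seed + 2L,
    source_cells = which(grid$habitat_extant),
    dt_minutes = config$tracking$dt_minutes,
    diffusion_m2s = config$tracking$diffusion_m2s))
  ep_hi <- tick("track_historic", track_particles(
    grid, field, sched, seed = seed + 3L,
    source_cells = which(grid$habitat_historic),
    dt_minutes = config$tracking$dt_minutes,
    diffusion_m2s = config$tracking$diffusion_m2s))
  P_ex <- build_dispersal_matrix(ep_ex, grid, "cell", "extant")
  P_hi <- build_dispersal_matrix(ep_hi, grid, "cell", "historic")
  g32 <- config$connectivity$generations
  M_ex <- multigeneration_connectivity(P_ex, g32)
  M_hi <- multigeneration_connectivity(P_hi, g32)
  S_single <- build_dispersal_matrix(ep_ex, grid, "site", "extant")
  S_multi <- aggregate_to_sites(M_ex, grid,
                                released = attr(P_ex, "released"))
  S_multi_hist <- aggregate_to_sites(M_hi, grid,
                                     released = attr(P_hi, "released"))
  res$dispersal <- list(single = S_single, multi = S_multi,
                        multi_historic = S_multi_hist)
  write_matrix_csv(S_single, file.path(out_dir, "dispersal_single_site.csv"),
                   "rows = source site, cols = destination site")
  write_matrix_csv(S_multi, file.path(out_dir, "dispersal_multi_site.csv"),
                   sprintf("%d-generation stepping-stone, extant habitat", g32))
  write_matrix_csv(S_multi_hist,
                   file.path(out_dir, "dispersal_multi_historic_site.csv"),
                   sprintf("%d-generation stepping-stone, historic habitat",
                           g32))

  table <- tick("simulate", simulate_genotypes(S_single, do.call(sim_config,
    c(config$simulation, list(seed = seed + 4L)))))
  write_genotypes(table, file.path(out_dir, "genotypes.genepop"))
  res$genotypes <- table

  if (config$stages$genetics) {
    clones <- tick("clones", identify_clones(table,
                                             alpha = config$genetics$alpha))
    genets <- clone_reduce(table, clones)
    summary <- tick("diversity", diversity_summary(
      table, clones, g = config$genetics$g,
      permutations = config$genetics$permutations, seed = seed + 5L))
    dps <- shared_allele_distance(genets)
    pid <- probability_of_identity(genets)
    utils::write.csv(summary, file.path(out_dir, "diversity_summary.csv"),
                     row.names = FALSE)
    utils::write.csv(pid, file.path(out_dir, "probability_of_identity.csv"),
                     row.names = FALSE)
    write_matrix_csv(dps, file.path(out_dir, "dps.csv"),
                     "shared-allele distance Dps among sites")
    res$clones <- clones; res$summary <- summary; res$dps <- dps
  }

  if (config$stages$migration) {
    if (is.null(res$dps)) stop("stage 'migration' needs stage 'genetics'")
    mig <- tick("migration", directional_relative_migration(
      clone_reduce(table, res$clones),
      bootstraps = config$migration$bootstraps, seed = seed + 6L))
    write_matrix_csv(mig$m, file.path(out_dir, "migration_directional.csv"),
                     "relative migration, rows = source, cols = recipient")
    res$migration <- mig
  }

  if (config$stages$barriers) {
    part <- tick("barriers", cluster_barriers(
      unclass(S_multi_hist), config$barriers$between_threshold))
    utils::write.csv(data.frame(site = names(part$cluster),
                                cluster = part$cluster),
                     file.path(out_dir, "barrier_partition.csv"),
                     row.names = FALSE)
    res$barriers <- part
  }

  if (config$stages$ibo) {
    if (is.null(res$dps) || is.null(res$migration))
      stop("stage 'ibo' needs stages 'genetics' and 'migration'")
    sd_km <- sea_distance(grid, coords)
    perms <- config$ibo$permutations
    off1 <- config$connectivity$offset_single
    off2 <- config$connectivity$offset_multi
    preds_sym <- list(
      sea_distance = log_transform_matrix(sd_km, 1),
      single = log_transform_matrix(symmetrize_min(S_single), off1),
      multi = log_transform_matrix(symmetrize_min(S_multi), off2),
      multi_historic = log_transform_matrix(symmetrize_min(S_multi_hist),
                                            off2))
    preds_dir <- list(
      single = log_transform_matrix(S_single, off1),
      multi = log_transform_matrix(S_multi, off2),
      multi_historic = log_transform_matrix(S_multi_hist, off2))
    rows <- list()
    safe_row <- function(fun, A, B, nm, resp, sd) {
      mt <- tryCatch(fun(A, B, permutations = perms, seed = sd),
                     error = function(e) NULL)   # degenerate predictor: na
      data.frame(predictor = nm, response = resp,
                 r = if (is.null(mt)) NA_real_ else mt$r,
                 p = if (is.null(mt)) NA_real_ else mt$p)
    }
    for (nm in names(preds_sym))
      rows[[length(rows) + 1L]] <- safe_row(mantel, res$dps,
                                            preds_sym[[nm]], nm, "Dps",
                                            seed + 7L)
    mig_m <- res$migration$m
    diag(mig_m) <- NA
    for (nm in names(preds_dir))
      rows[[length(rows) + 1L]] <- safe_row(asymmetric_mantel, mig_m,
                                            preds_dir[[nm]], nm,
                                            "asym_migration", seed + 8L)
    ibo_tab <- do.call(rbind, rows)
    utils::write.csv(ibo_tab, file.path(out_dir, "ibo_correlations.csv"),
                     row.names = FALSE)
    res$ibo <- ibo_tab
    message("[ibo] done")
  }

  if (config$stages$networks) {
    if (is.null(res$dps)) stop("stage 'networks' needs stage 'genetics'")
    attrs <- merge(coords, res$summary[, c("site", "A_g", "MLG")],
                   by = "site", all.x = TRUE)
    nets <- list(
      dps = list(M = res$dps, mode = "distance"),
      single = list(M = symmetrize_min(S_single), mode = "probability"),
      multi = list(M = symmetrize_min(S_multi), mode = "probability"),
      multi_historic = list(M = symmetrize_min(S_multi_hist),
                            mode = "probability"))
    res$networks <- lapply(names(nets), function(nm) {
      M <- nets[[nm]]$M
      scan <- tryCatch(select_threshold(M, nets[[nm]]$mode),
                       error = function(e) NULL)
      if (is.null(scan)) return(NULL)
      gph <- build_network(M, scan$selected, nets[[nm]]$mode,
                           node_attrs = attrs,
                           drop_isolated = config$networks$drop_isolated)
      export_network(gph, file.path(out_dir, paste0("network_", nm)))
      list(name = nm, scan = scan, graph = gph)
    })
    names(res$networks) <- names(nets)
    message("[networks] done")
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("seadrift")),
    seed = seed,
    config = unclass_config(config),
    timings = timings,
    created = "see run log")
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  message(sprintf("pipeline complete in %.1fs",
                  as.numeric(Sys.time() - t0, units = "secs")))
  invisible(res)
}

unclass_config <- function(x) {
  x <- unclass(x)
  lapply(x, function(e) if (is.list(e)) lapply(e, identity) else e)
}
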