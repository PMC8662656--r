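#' Pipeline run configuration
#'
#' One structured configuration object drives [run_pipeline()]: stage
#' toggles, the numeric settings of every stage, and a master seed from
#' which each stage's seed is derived via [derive_seed()]. Serializable to
#' YAML with [write_run_config()] so a saved configuration plus seed
#' reproduces a run.
#'
#' @param master_seed master seed for the whole run
#' @param scenario_id demographic scenario for the simulated dataset
#' @param params optional [scenario_params()]; defaults to a prior draw
#' @param config a [sample_config()]
#' @param n_loci loci simulated
#' @param depth_mean,missing_rate GBS noise settings
#' @param snps_per_scaffold loci grouped per scaffold by the noise stage
#' @param n_perm permutations for the F_ST tests
#' @param abc_n_sims,abc_n_loci reference-table size for the ABC stage
#' @param run_abc,run_ocean stage toggles
#' @param ocean an [ocean_config()] (used when `run_ocean` is `TRUE`)
#' @return an object of class `run_config`
#' @export
run_config <- function(master_seed = 1, scenario_id = 1, params = NULL,
                       config = sample_config(), n_loci = 1000,
                       depth_mean = 20, missing_rate = 0.03,
                       snps_per_scaffold = 4L, n_perm = 1000,
                       abc_n_sims = 900, abc_n_loci = 100,
                       run_abc = TRUE, run_ocean = FALSE,
                       ocean = NULL) {
  structure(as.list(environment()), class = "run_config")
}

#' Write / read a run configuration as YAML
#'
#' @param cfg a [run_config()]
#' @param path output file
#' @return `path` (write) or a `run_config` (read)
#' @export
write_run_config <- function(cfg, path) {
  lst <- unclass(cfg)
  lst$config <- as.list(unclass(lst$config))
  if (!is.null(lst$params)) {
    lst$params <- c(list(scenario_id = lst$params$scenario_id),
                    as.list(lst$params$values))
  }
  if (!is.null(lst$ocean)) lst$ocean <- unclass(lst$ocean)
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  lst <- yaml::read_yaml(path)
  lst$config <- do.call(sample_config, lst$config)
  if (!is.null(lst$params)) {
    sid <- lst$params$scenario_id
    vals <- unlist(lst$params[names(lst$params) != "scenario_id"])
    lst$params <- scenario_params(sid, vals)
  }
  if (!is.null(lst$ocean)) {
    lst$ocean <- do.call(ocean_config,
                         lst$ocean[names(lst$ocean) %in%
                                     names(formals(ocean_config))])
  }
  do.call(run_config, lst)
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> GBS noise -> filter cascade -> population statistics
#' -> directional migration -> ABC (optional) -> ocean experiment
#' (optional), writing every artifact under `out_dir` along with a manifest
#' (file, md5, stage) and the per-stage seeds. Deterministic given the
#' configuration.
#'
#' @param cfg a [run_config()]
#' @param out_dir output directory (created if missing)
#' @return the manifest data.frame, invisibly; also written as
#'   `manifest.json`
#' @export
run_pipeline <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "run_config"))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(out_dir)) stop("cannot create ", out_dir)
  }
  manifest <- data.frame(file = character(0), md5 = character(0),
                         stage = character(0))
  seeds <- list()
  t0 <- Sys.time()
  emit <- function(path, stage) {
    manifest[nrow(manifest) + 1L, ] <<-
      list(basename(path), digest::digest(file = path, algo = "md5"), stage)
  }
  stage_seed <- function(stage) {
    s <- derive_seed(cfg$master_seed, stage)
    seeds[[stage]] <<- s
    s
  }
  path <- function(f) file.path(out_dir, f)

  # simulate + noise
  params <- cfg$params %||%
    draw_scenario_params(prior_spec(), cfg$scenario_id,
                         rng_seed = stage_seed("params"))
  gm <- simulate_dataset(params, cfg$config, cfg$n_loci,
                         rng_seed = stage_seed("simulate"))
  vs <- add_gbs_noise(gm, depth_mean = cfg$depth_mean,
                      missing_rate = cfg$missing_rate,
                      rng_seed = stage_seed("noise"),
                      snps_per_scaffold = cfg$snps_per_scaffold)
  write_vcf(vs, path("genotypes.vcf"))
  emit(path("genotypes.vcf"), "simulate")
  write_popmap(gm, path("popmap.tsv"))
  emit(path("popmap.tsv"), "simulate")

  # filter
  fl <- apply_filters(vs, filter_config())
  write_vcf(fl$records, path("filtered.vcf"))
  emit(path("filtered.vcf"), "filter")
  write.table(fl$report, path("filter_report.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  emit(path("filter_report.tsv"), "filter")

  popmap <- data.frame(sample_id = gm$sample_id, group = gm$group)
  gmf <- as_genotype_matrix(fl$records, popmap)

  # statistics
  gs <- group_summary(gmf)
  write.table(gs, path("group_stats.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  emit(path("group_stats.tsv"), "popgen")
  fm <- fst_matrix(gmf, n_perm = cfg$n_perm,
                   rng_seed = stage_seed("fst_perm"))
  write.table(fm$fst, path("fst_matrix.tsv"), sep = "\t", quote = FALSE)
  emit(path("fst_matrix.tsv"), "popgen")
  pruned <- select_one_snp_per_locus(fl$records)
  pca <- genotype_pca(as_genotype_matrix(pruned, popmap))
  write.table(data.frame(sample_id = rownames(pca$coords), pca$coords),
              path("pca_coords.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  emit(path("pca_coords.tsv"), "popgen")

  # migration
  mig <- relative_migration(gmf)
  write.table(unclass(mig), path("migration.tsv"), sep = "\t", quote = FALSE)
  emit(path("migration.tsv"), "migration")

  # ABC
  if (isTRUE(cfg$run_abc)) {
    obs <- summary_stats(gmf, groups = names(cfg$config))
    tab <- build_reference_table(prior_spec(), 1:3, cfg$config,
                                 n_sims = cfg$abc_n_sims,
                                 n_loci = cfg$abc_n_loci,
                                 rng_seed = stage_seed("abc_table"))
    mc_d <- posterior_prob_direct(tab, obs,
                                  n_closest = min(500, cfg$abc_n_sims %/% 3))
    mc_l <- posterior_prob_logistic(tab, obs, closest_fraction = 0.05)
    choice <- rbind(cbind(method = "direct", as.data.frame(mc_d)),
                    cbind(method = "logistic", as.data.frame(mc_l)))
    write.table(choice, path("abc_model_choice.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    emit(path("abc_model_choice.tsv"), "abc")
    best <- mc_l$scenario[which.max(mc_l$pp)]
    post <- estimate_parameters(tab, obs, best, closest_fraction = 0.05)
    write.table(post$summary, path("abc_params.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    emit(path("abc_params.tsv"), "abc")
  }

  # ocean
  if (isTRUE(cfg$run_ocean)) {
    oc <- cfg$ocean %||% ocean_config(n_days = 120)
    field <- make_synthetic_ocean(oc, rng_seed = stage_seed("ocean_field"))
    rel <- release_particles(field, center = c(124, 27),
                             depth = oc$levels[length(oc$levels)], n = 500,
                             rng_seed = stage_seed("ocean_release"))
    traj <- advect(rel, field, duration_days = min(90, oc$n_days - 1))
    write_trajectories(traj, path("trajectories.csv"))
    emit(path("trajectories.csv"), "ocean")
  }

  wall <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  jsonlite::write_json(
    list(stages = manifest, seeds = seeds, master_seed = cfg$master_seed,
         wall_time_s = wall,
         version = as.character(utils::packageVersion("bathypop"))),
    path("manifest.json"), auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(manifest)
}
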