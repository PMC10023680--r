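## Pipeline orchestration: a YAML config drives the stages, each stage
## writes its outputs plus a machine-readable JSON run manifest (input
## hashes, parameters, in/out counts).

#' Read and validate a pipeline configuration
#'
#' The configuration is a YAML mapping with one section per stage (see
#' [run_stage()] for the stage names and the keys each consumes) and
#' optional top-level `seed`. Paths are resolved relative to the config
#' file's directory.
#'
#' @param path YAML file.
#' @return named list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("config must be a YAML mapping")
  cfg$.dir <- dirname(normalizePath(path))
  structure(cfg, class = "pipeline_config")
}

cfg_path <- function(cfg, p) {
  if (is.null(p)) return(NULL)
  if (startsWith(p, "/")) p else file.path(cfg$.dir %||% ".", p)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

need_keys <- function(section, keys, stage) {
  miss <- keys[vapply(keys, function(k) is.null(section[[k]]), logical(1))]
  if (length(miss))
    stop("stage '", stage, "': missing config key(s): ",
         paste(miss, collapse = ", "))
}

write_manifest <- function(out_dir, stage, params, inputs, counts) {
  hashes <- if (length(inputs)) as.list(tools::md5sum(unlist(inputs)))
            else list()
  manifest <- list(stage = stage,
                   package_version =
                     as.character(utils::packageVersion("funneldock")),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   parameters = params,
                   inputs = hashes,
                   counts = counts)
  path <- file.path(out_dir, paste0(stage, "_manifest.json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  manifest
}

loopdef_from_config <- function(ld) {
  if (is.null(ld)) return(default_loop_definition())
  loop_definition(cdr1 = unlist(ld$cdr1), cdr2 = unlist(ld$cdr2),
                  cdr3 = unlist(ld$cdr3),
                  framework = lapply(ld$framework, unlist),
                  atom_filter = ld$atom_filter %||% "CA")
}

#' Run one pipeline stage
#'
#' Stages: `simulate` (write synthetic fixtures), `curate` (chain
#' metadata -> retained chains + FASTA), `triage` (pose PDBs vs
#' competitor/scaffold -> report), `landscape` (decoy table -> funnel
#' verdicts), `select-round1` (decoy table -> pooled, SASA-filtered,
#' cycle-picked candidates), `maturation` (variant table -> per-variation
#' retention, dedup, delta-FlexddG), `seqspace` (non-redundant variants ->
#' PCA projection, clusters, final candidates), `md-rmsd` (multi-model PDB
#' trajectories -> per-CDR RMSD traces and aggregate). Every stage writes
#' a `<stage>_manifest.json` with input hashes, parameters and in/out
#' counts into `out_dir`.
#'
#' @param stage stage name as above.
#' @param config a [read_pipeline_config()] result (or equivalent list).
#' @param out_dir output directory (created if absent).
#' @param seed RNG seed override (otherwise `config$seed`, default 1).
#' @return the stage result (invisibly), with the manifest attached as
#'   attribute `manifest`.
#' @export
run_stage <- function(stage, config, out_dir = ".", seed = NULL) {
  stages <- c("simulate", "curate", "triage", "landscape",
              "select-round1", "maturation", "seqspace", "md-rmsd")
  if (!stage %in% stages)
    stop("unknown stage '", stage, "'; expected one of: ",
         paste(stages, collapse = ", "))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- seed %||% config$seed %||% 1L
  fn <- switch(stage,
               "simulate" = stage_simulate,
               "curate" = stage_curate,
               "triage" = stage_triage,
               "landscape" = stage_landscape,
               "select-round1" = stage_select_round1,
               "maturation" = stage_maturation,
               "seqspace" = stage_seqspace,
               "md-rmsd" = stage_mdrmsd)
  fn(config, out_dir, seed)
}

stage_simulate <- function(config, out_dir, seed) {
  sc <- config$simulate %||% list()
  n_poses <- sc$n_poses %||% 13L
  n_decoys <- sc$n_decoys %||% 100L
  n_flat <- sc$n_flat_poses %||% 0L
  ens <- c(
    lapply(seq_len(n_poses), function(i)
      gen_decoy_ensemble("funnel", n_decoys, sprintf("pose%03d", i),
                         seed = seed + i)),
    lapply(seq_len(n_flat), function(i)
      gen_decoy_ensemble("flat", n_decoys, sprintf("flat%03d", i),
                         seed = seed + n_poses + i)))
  decoys <- do.call(rbind, lapply(ens, `[[`, "decoys"))
  decoy_path <- file.path(out_dir, "decoys.tsv")
  write_decoy_table(decoys, decoy_path)
  pool <- gen_variant_pool(n = sc$n_variants %||% 1600L,
                           n_unique = sc$n_unique %||% 89L,
                           seed = seed)
  var_path <- file.path(out_dir, "variants.tsv")
  write_variant_table(pool, var_path)
  counts <- list(n_ensembles = length(ens), n_decoys = nrow(decoys),
                 n_variants = nrow(pool))
  res <- list(decoys = decoy_path, variants = var_path)
  attr(res, "manifest") <- write_manifest(out_dir, "simulate",
                                          c(sc, list(seed = seed)),
                                          list(), counts)
  invisible(res)
}

stage_curate <- function(config, out_dir, seed) {
  sc <- config$curate
  need_keys(sc, "metadata", "curate")
  meta_path <- cfg_path(config, sc$metadata)
  records <- read_chain_metadata(meta_path)
  crit <- curation_criteria(
    max_resolution = sc$max_resolution %||% 2.5,
    max_mw = sc$max_mw %||% 20000)
  kept <- curate_chains(records, crit)
  out_tsv <- file.path(out_dir, "curated_chains.tsv")
  utils::write.table(kept, out_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_fasta(kept$sequence, paste0(kept$pdb_id, "_", kept$chain_id),
              file.path(out_dir, "curated_chains.fasta"))
  counts <- list(n_in = nrow(records), n_retained = nrow(kept))
  attr(kept, "manifest") <- write_manifest(out_dir, "curate",
                                           list(max_resolution =
                                                  crit$max_resolution,
                                                max_mw = crit$max_mw),
                                           list(metadata = meta_path),
                                           counts)
  invisible(kept)
}

stage_triage <- function(config, out_dir, seed) {
  sc <- config$triage
  need_keys(sc, c("poses", "competitor", "scaffold"), "triage")
  pose_dir <- cfg_path(config, sc$poses)
  pose_files <- sort(list.files(pose_dir, "\\.pdb$", full.names = TRUE))
  if (!length(pose_files)) stop("no pose PDB files in ", pose_dir)
  poses <- lapply(pose_files, function(f) {
    m <- read_pdb(f, c(stats::setNames("ligand",
                                       sc$pose_chain %||% "A")))[[1L]]
    docked_pose(sub("\\.pdb$", "", basename(f)), model_atoms(m, "ligand"))
  })
  comp_path <- cfg_path(config, sc$competitor)
  scaf_path <- cfg_path(config, sc$scaffold)
  competitor <- model_atoms(read_pdb(
    comp_path, stats::setNames("competitor",
                               sc$competitor_chain %||% "B"))[[1L]])
  scaffold <- model_atoms(read_pdb(
    scaf_path, stats::setNames("scaffold",
                               sc$scaffold_chain %||% "C"))[[1L]])
  thr <- triage_thresholds(
    competitor_overlap_min = sc$competitor_overlap_min %||% 30,
    scaffold_clash_max = sc$scaffold_clash_max %||% 10,
    contact_cutoff = sc$contact_cutoff %||% 5)
  res <- triage_poses(poses, competitor, scaffold, thr)
  utils::write.table(res$report, file.path(out_dir, "triage_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  counts <- list(n_in = length(poses), n_retained = sum(res$report$retained))
  attr(res, "manifest") <- write_manifest(
    out_dir, "triage", unclass(thr),
    list(competitor = comp_path, scaffold = scaf_path), counts)
  invisible(res)
}

stage_landscape <- function(config, out_dir, seed) {
  sc <- config$landscape %||% list()
  need_keys(sc, "decoys", "landscape")
  path <- cfg_path(config, sc$decoys)
  cohort <- split_ensembles(read_decoy_table(path))
  crit <- funnel_criteria(min_designs = sc$min_designs %||% 50L)
  res <- funnel_filter(cohort, crit)
  scores <- vapply(cohort, function(e)
    if (nrow(e$decoys) >= 5L) funnel_score(e) else NA_real_, numeric(1))
  res$verdicts$funnel_score <- scores
  utils::write.table(res$verdicts,
                     file.path(out_dir, "landscape_verdicts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  counts <- list(n_in = length(cohort), n_retained = length(res$retained))
  attr(res, "manifest") <- write_manifest(out_dir, "landscape",
                                          unclass(crit),
                                          list(decoys = path), counts)
  invisible(res)
}

stage_select_round1 <- function(config, out_dir, seed) {
  sc <- config$select_round1 %||% config$`select-round1` %||% list()
  need_keys(sc, "decoys", "select-round1")
  path <- cfg_path(config, sc$decoys)
  ensembles <- split_ensembles(read_decoy_table(path))
  pool <- per_pose_lowest_k(ensembles, sc$k %||% 20L)
  pool_f <- sasa_filter(pool, sc$min_sasa %||% 800)
  scheme <- default_selection_scheme(sc$target_count %||% 16L)
  picks <- cycled_pick(pool_f, scheme)
  write_decoy_table(picks, file.path(out_dir, "round1_candidates.tsv"))
  write_fasta(picks$sequence, picks$design_id,
              file.path(out_dir, "round1_candidates.fasta"))
  counts <- list(n_ensembles = length(ensembles), n_pooled = nrow(pool),
                 n_after_sasa = nrow(pool_f), n_selected = nrow(picks))
  attr(picks, "manifest") <- write_manifest(
    out_dir, "select-round1",
    list(k = sc$k %||% 20L, min_sasa = sc$min_sasa %||% 800,
         target_count = scheme$target_count),
    list(decoys = path), counts)
  invisible(picks)
}

stage_maturation <- function(config, out_dir, seed) {
  sc <- config$maturation %||% list()
  need_keys(sc, "variants", "maturation")
  path <- cfg_path(config, sc$variants)
  pool <- read_variant_table(path)
  kept <- retain_lowest_k(pool, sc$k %||% 100L)
  uniq <- dedupe_variants(kept)
  ref <- sc$reference_flexddg %||% 0
  uniq$delta_flexddg <- delta_flexddg(uniq$flexddg, ref)
  write_variant_table(uniq, file.path(out_dir,
                                      "nonredundant_variants.tsv"))
  grid <- expand_design_grid(design_parameter_grid())
  utils::write.table(grid, file.path(out_dir, "design_grid.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  counts <- list(n_in = nrow(pool), n_retained = nrow(kept),
                 n_unique = nrow(uniq), n_variations = nrow(grid))
  attr(uniq, "manifest") <- write_manifest(
    out_dir, "maturation",
    list(k = sc$k %||% 100L, reference_flexddg = ref),
    list(variants = path), counts)
  invisible(uniq)
}

stage_seqspace <- function(config, out_dir, seed) {
  sc <- config$seqspace %||% list()
  need_keys(sc, "variants", "seqspace")
  path <- cfg_path(config, sc$variants)
  uniq <- read_variant_table(path)
  model <- sequence_space_model(uniq,
                                min_cluster_size =
                                  sc$min_cluster_size %||% 5L)
  proj <- data.frame(variant_id = uniq$variant_id,
                     model$projection, cluster = model$labels)
  utils::write.table(proj, file.path(out_dir, "seqspace_projection.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  picks <- maturation_select(uniq, model,
                             n_score = sc$n_score %||% 20L,
                             n_cluster_picks = sc$n_cluster_picks %||% 3L,
                             excluded_clusters =
                               unlist(sc$excluded_clusters) %||% integer(0))
  write_variant_table(picks, file.path(out_dir, "final_candidates.tsv"))
  write_fasta(picks$sequence, picks$variant_id,
              file.path(out_dir, "final_candidates.fasta"))
  counts <- list(n_in = nrow(uniq),
                 n_clusters = nrow(model$centroids),
                 n_selected = nrow(picks))
  res <- list(model = model, candidates = picks)
  attr(res, "manifest") <- write_manifest(
    out_dir, "seqspace",
    list(min_cluster_size = sc$min_cluster_size %||% 5L,
         n_score = sc$n_score %||% 20L,
         n_cluster_picks = sc$n_cluster_picks %||% 3L),
    list(variants = path), counts)
  invisible(res)
}

stage_mdrmsd <- function(config, out_dir, seed) {
  sc <- config$md_rmsd %||% config$`md-rmsd` %||% list()
  need_keys(sc, c("trajectories", "reference"), "md-rmsd")
  ld <- loopdef_from_config(sc$loops)
  ref_path <- cfg_path(config, sc$reference)
  chain <- sc$chain %||% "A"
  spec <- stats::setNames("ligand", chain)
  reference <- read_pdb(ref_path, spec)[[1L]]
  traj_paths <- vapply(sc$trajectories, function(p) cfg_path(config, p),
                       character(1))
  interval <- sc$interval %||% 100
  traces <- lapply(seq_along(traj_paths), function(i) {
    frames <- read_pdb(traj_paths[i], spec)
    tr <- cdr_rmsd_trace(frames, reference, ld,
                         times = seq_along(frames) * interval,
                         run_id = paste0("run", i))
    write_trace(tr, file.path(out_dir, sprintf("rmsd_run%d.tsv", i)))
    tr
  })
  agg <- aggregate_runs(traces, n_expected = sc$n_expected %||% 5L)
  write_trace(agg, file.path(out_dir, "rmsd_aggregate.tsv"))
  counts <- list(n_runs = length(traces),
                 n_frames = nrow(traces[[1L]]))
  res <- list(traces = traces, aggregate = agg)
  attr(res, "manifest") <- write_manifest(
    out_dir, "md-rmsd", list(interval = interval),
    c(list(reference = ref_path),
      stats::setNames(as.list(traj_paths),
                      paste0("trajectory", seq_along(traj_paths)))),
    counts)
  invisible(res)
}
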