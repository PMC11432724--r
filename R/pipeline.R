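#' Default pipeline configuration
#'
#' Returns the demo configuration: synthetic reference states and a
#' synthetic "predicted" mixture ensemble stand in for external predictor
#' output, so the full chain (mask -> plan -> read -> filter -> classify ->
#' PCA -> correlate -> network -> map) runs end-to-end at desk scale. The
#' demo chain is 100 residues (ids 360-459) so that the activation-loop
#' interval 398-421 falls inside it; community detection on networks this
#' size completes in seconds. Every threshold mirrors the pipeline's
#' analysis conventions: pLDDT filter 70, RMSD assignment 1.5 A, contacts
#' 7.5 A in >= 75% of models (the Calpha-trace contact cutoff), hotspot
#' Z >= 2, proximity mapping < 5 A.
#'
#' Supply `ensembles` (named PDB paths `active`, `I1`, `I2` and a
#' `predicted` path or directory) to analyze real ensembles instead of the
#' synthetic demo.
#'
#' @return nested configuration list; override entries via
#'   [run_pipeline()]'s `config` argument or a YAML file with the same
#'   structure.
#' @export
default_pipeline_config <- function() {
  list(
    seed = 1,
    sequence = NULL,  # native sequence; NULL -> random demo sequence
    ensembles = NULL, # named PDB paths (active, I1, I2, predicted) or NULL
    synthetic = list(
      n_residues = 100L, first_resid = 360L,
      loop_span = c(398L, 421L),
      displacements = list(active = c(0, 0, 0), I1 = c(4, 0, 0), I2 = c(0, 4, 7)),
      n_models_reference = 20L,
      noise_sd = 0.3,
      populations = c(I2 = 0.82, I1 = 0.10, active = 0.08),
      n_models_predicted = 70L,
      low_confidence_models = 1:5),
    masking = list(mode = "full_sequence", regions = NULL,
                   p_min = 0.05, p_max = 0.15, n_sequences = 10L),
    jobs = list(max_seqs = 16L, extra_seqs = 32L, num_recycles = 12L,
                num_seed = 1L, n_models = 5L, use_dropout = TRUE),
    thresholds = list(plddt = 70, rmsd = 1.5, contact_cutoff = 7.5,
                      min_fraction = 0.75, z = 2, proximity = 5),
    regions = list(a_loop = c(398L, 421L), alpha_c = c(291L, 311L)),
    gc_estimator = "gaussian",
    sites = c(269L, 272L, 309L, 320L, 334L, 378L, 389L, 401L, 408L, 415L))
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]) &&
        !is.null(names(override[[nm]])))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else
      base[[nm]] <- override[[nm]]
  }
  base
}

#' Load a pipeline configuration
#'
#' @param config `NULL` (defaults), a named list of overrides, or the path
#'   to a YAML file with the same structure as
#'   [default_pipeline_config()].
#' @return complete configuration list.
#' @export
load_pipeline_config <- function(config = NULL) {
  base <- default_pipeline_config()
  if (is.null(config)) return(base)
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  merge_config(base, config)
}

run_stage <- function(name, log, expr) {
  log(sprintf("stage %-14s started", name))
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
}

random_sequence <- function(n, seed) {
  with_seed(seed, paste(sample(AA_ALPHABET, n, replace = TRUE), collapse = ""))
}

#' Run the full analysis pipeline
#'
#' Orchestrates all stages from one configuration: alanine masking and job
#' planning (the predictor hand-off), ensemble ingestion (synthetic demo or
#' PDB files), confidence filtering, state classification, PCA on the
#' merged reference ensemble with projection of the predicted ensemble,
#' cross-correlation and generalized correlation, residue interaction
#' network construction, betweenness/Z-score hotspot calling, community
#' detection, bridgeness, and mutation-to-hotspot mapping. All stage
#' outputs land under `outdir` as plain-text tables plus a JSON run report;
#' reruns with the same configuration and seed reproduce them byte for
#' byte.
#'
#' @param config see [load_pipeline_config()].
#' @param outdir run directory (created; existing files overwritten).
#' @return the run report, invisibly: list with per-state populations,
#'   hotspot table, community summary, mutation mapping and the echoed
#'   configuration.
#' @export
run_pipeline <- function(config = NULL, outdir) {
  cfg <- load_pipeline_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(outdir, "run.log")
  log_lines <- character(0)
  log <- function(msg) {
    line <- paste0("[alloscan] ", msg)
    message(line)
    log_lines <<- c(log_lines, line)
  }
  on.exit(writeLines(log_lines, log_path))

  yaml::write_yaml(cfg, file.path(outdir, "config_echo.yaml"))
  syn <- cfg$synthetic

  ## ---- masking + job planning (predictor front-end) -------------------
  native <- cfg$sequence
  if (is.null(native))
    native <- random_sequence(syn$n_residues, derive_seed(cfg$seed, 101L))
  masked <- run_stage("mask", log, {
    mcfg <- masking_config(cfg$masking$mode, regions = cfg$masking$regions,
                           p_min = cfg$masking$p_min, p_max = cfg$masking$p_max,
                           n_sequences = cfg$masking$n_sequences,
                           seed = derive_seed(cfg$seed, 102L))
    generate_masked_set(native, mcfg)
  })
  plan <- run_stage("plan", log, {
    jcfg <- job_plan_config(cfg$jobs$max_seqs, cfg$jobs$extra_seqs,
                            cfg$jobs$num_recycles, cfg$jobs$num_seed,
                            cfg$jobs$n_models, cfg$jobs$use_dropout)
    p <- plan_prediction_jobs(masked, jcfg)
    write_job_manifest(p, masked, file.path(outdir, "jobs"))
    p
  })
  log(sprintf("planned %d prediction outputs for %d masked variants",
              plan$total, plan$n_sequences))

  ## ---- ensembles: synthetic demo or external files --------------------
  ens <- run_stage("ingest", log, {
    if (is.null(cfg$ensembles)) {
      refs <- generate_reference_states(
        n_residues = syn$n_residues, loop_span = syn$loop_span,
        displacements = syn$displacements,
        n_models = syn$n_models_reference, noise_sd = syn$noise_sd,
        seed = derive_seed(cfg$seed, 103L), first_resid = syn$first_resid)
      mix <- generate_mixture_ensemble(
        mixture_spec(syn$populations, n_models = syn$n_models_predicted,
                     noise_sd = syn$noise_sd,
                     seed = derive_seed(cfg$seed, 104L)), refs)
      pred <- assign_confidence(mix$ensemble, loop_span = syn$loop_span,
                                low_models = syn$low_confidence_models,
                                seed = derive_seed(cfg$seed, 105L))
      # round-trip the predicted ensemble through the PDB writer/reader,
      # exercising the same path external predictor output takes
      pdb <- file.path(outdir, "predicted_ensemble.pdb")
      write_ensemble_pdb(pred, pdb)
      jsonlite::write_json(
        list(true_labels = mix$labels, populations = as.list(syn$populations)),
        file.path(outdir, "predicted_ensemble_labels.json"),
        auto_unbox = TRUE, digits = NA)
      list(refs = refs, predicted = read_ensemble(pdb, label = "predicted"),
           true_labels = mix$labels)
    } else {
      refs <- lapply(cfg$ensembles[c("active", "I1", "I2")], read_ensemble)
      refs <- lapply(refs, function(e) list(ensemble = e))
      paths <- cfg$ensembles$predicted
      if (length(paths) == 1 && dir.exists(paths))
        paths <- list.files(paths, pattern = "\\.pdb$", full.names = TRUE)
      pred <- merge_ensembles(lapply(paths, read_ensemble))
      list(refs = refs, predicted = pred, true_labels = NULL)
    }
  })

  filtered <- run_stage("filter", log, {
    f <- filter_by_confidence(ens$predicted, cfg$thresholds$plddt)
    log(sprintf("confidence filter (pLDDT >= %g) kept %d / %d models",
                cfg$thresholds$plddt, n_models(f), n_models(ens$predicted)))
    f
  })

  ## ---- state classification ------------------------------------------
  cls <- run_stage("classify", log,
    classify_states(filtered, ens$refs, rmsd_threshold = cfg$thresholds$rmsd))
  cls_tab <- data.frame(model = seq_along(cls$labels), label = cls$labels,
                        cls$rmsd, check.names = FALSE)
  write.csv(cls_tab, file.path(outdir, "classification.csv"), row.names = FALSE)

  ## ---- PCA on the merged reference ensemble ---------------------------
  scores <- run_stage("pca", log, {
    ref_merged <- merge_ensembles(lapply(ens$refs, `[[`, "ensemble"),
                                  labels = names(ens$refs))
    pca <- fit_reference_pca(ref_merged, confidence_threshold = NULL)
    rbind(project_ensemble(ref_merged, pca),
          project_ensemble(filtered, pca))
  })
  write.csv(scores, file.path(outdir, "pca_scores.csv"), row.names = FALSE)

  ## ---- correlations and network --------------------------------------
  dcc <- run_stage("correlate", log, dcc_matrix(filtered))
  gc <- run_stage("correlate", log, gc_matrix(filtered, cfg$gc_estimator))
  write.csv(data.frame(resid = dcc$resid, dcc$matrix),
            file.path(outdir, "dcc.csv"), row.names = FALSE)
  write.csv(data.frame(resid = gc$resid, gc$matrix),
            file.path(outdir, "gc.csv"), row.names = FALSE)

  net_parts <- run_stage("network", log, {
    pers <- contact_persistence(filtered, cutoff = cfg$thresholds$contact_cutoff,
                                min_fraction = cfg$thresholds$min_fraction)
    network <- build_network(pers, gc)
    paths <- shortest_paths(network)
    centrality <- betweenness_profile(paths, z_threshold = cfg$thresholds$z)
    partition <- detect_communities(network)
    bridge <- bridgeness_profile(network, partition)
    log(sprintf("network: %d edges, %d hotspots (Z >= %g), %d communities (Q = %.3f)",
                nrow(network$edges), length(centrality$hotspots),
                cfg$thresholds$z, partition$n_communities,
                partition$modularity))
    list(network = network, centrality = centrality, partition = partition,
         bridge = bridge)
  })
  prof <- merge(net_parts$centrality$profile, net_parts$bridge$profile,
                by = "resid")
  write.csv(prof, file.path(outdir, "network_profile.csv"), row.names = FALSE)
  write_network_graphml(net_parts$network,
                        file.path(outdir, "network.graphml"),
                        centrality = net_parts$centrality,
                        partition = net_parts$partition,
                        bridgeness = net_parts$bridge)

  ## ---- mutation-to-hotspot mapping ------------------------------------
  mapping <- run_stage("map", log, {
    sites <- intersect(cfg$sites, net_parts$network$resid)
    skipped <- setdiff(cfg$sites, sites)
    if (length(skipped))
      log(paste("sites outside the analyzed chain skipped:",
                paste(skipped, collapse = ", ")))
    if (!length(sites)) return(NULL)
    map_mutations(sites, net_parts$centrality,
                  ens$refs[[1]]$ensemble,
                  proximity = cfg$thresholds$proximity)
  })
  if (!is.null(mapping))
    write.csv(mapping, file.path(outdir, "mutation_mapping.csv"),
              row.names = FALSE)

  report <- list(
    populations = as.list(cls$populations),
    n_models_predicted = n_models(ens$predicted),
    n_models_after_filter = n_models(filtered),
    hotspots = net_parts$centrality$hotspots,
    n_communities = net_parts$partition$n_communities,
    modularity = net_parts$partition$modularity,
    mutation_mapping = if (!is.null(mapping)) split(mapping$status, mapping$site),
    job_plan_total = plan$total,
    package_version = as.character(utils::packageVersion("alloscan")),
    config = cfg)
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log("pipeline complete")
  invisible(report)
}
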