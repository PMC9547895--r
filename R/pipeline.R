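# End-to-end orchestration: synthesis/loading -> filters -> rarefaction ->
# enterotyping -> community stats -> RC_bray response -> (optional) response
# potential -> partial-correlation network -> per-taxon associations ->
# (optional) boosted-tree predictability.  Every stage writes a plain TSV and
# the run manifest records seeds, thresholds, the RC context policy and md5
# digests of all outputs, so a rerun with the same config reproduces the
# digests bit-exactly.

#' Default pipeline configuration
#'
#' Thresholds default to the conventional values: depth filter >3000 reads,
#' 20/20 rare-taxa rule, pseudocount 0.5, 999 null replicates, DMM with K =
#' 4.  Stages too heavy for a demo run (response potential, boosted trees)
#' are opt-in.
#'
#' @param seed master seed.
#' @return nested configuration list understood by [run_pipeline()].
#' @export
pipeline_config <- function(seed = 1L) {
  list(
    seed = seed,
    input = NULL,            # list(abundance=, design=, gene_reference=) paths
    synthetic = list(),      # generator_config() overrides when input is NULL
    filters = list(min_reads = 3000, rare_count_thr = 20,
                   rare_sample_thr = 20, apply_rare_taxa = TRUE),
    rarefaction = list(depth = NULL),  # NULL = dataset minimum
    nullmodel = list(n_reps = 999, context = "global"),
    enterotyping = list(enabled = TRUE, K = 4),
    network = list(fdr_alpha = 0.05, random_effect = "intervention"),
    taxa_association = list(enabled = TRUE, mode = "mixed_over_all",
                            adjust_alpha = FALSE, pseudocount = 0.5),
    potential = list(enabled = FALSE, max_reference = 300),
    ml = list(enabled = FALSE)
  )
}

merge_config <- function(base, override) {
  for (k in names(override)) {
    if (is.list(base[[k]]) && is.list(override[[k]])) {
      base[[k]] <- merge_config(base[[k]], override[[k]])
    } else {
      base[[k]] <- override[[k]]
    }
  }
  base
}

#' Run the full analysis pipeline
#'
#' @param config a configuration list (see [pipeline_config()]), or the path
#'   of a YAML file with the same structure; omitted keys take defaults.
#' @param out_dir output directory, created if missing.
#' @return the run manifest (also written to `manifest.json`): config hash,
#'   seeds, rarefaction depth, RC context label and per-output md5 digests.
#' @export
run_pipeline <- function(config = list(), out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(pipeline_config(), config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  emit <- function(obj, name, writer = NULL) {
    path <- file.path(out_dir, name)
    if (is.null(writer)) {
      write.table(obj, path, sep = "\t", quote = FALSE, row.names = FALSE)
    } else {
      writer(obj, path)
    }
    outputs <<- c(outputs, path)
    path
  }

  # -- stage: input ----------------------------------------------------------
  if (!is.null(cfg$input)) {
    tbl <- read_abundance_table(cfg$input$abundance)
    design <- read_study_design(cfg$input$design)
    ref <- read_gene_reference(cfg$input$gene_reference)
  } else {
    gen <- do.call(generator_config,
                   c(cfg$synthetic, list(seed = cfg$seed)))
    study <- generate_study(gen)
    tbl <- study$table
    design <- study$design
    ref <- study$reference
    emit(study$truth$subjects, "ground_truth.tsv")
  }

  # -- stage: filters & rarefaction -----------------------------------------
  tbl <- filter_samples_by_depth(tbl, cfg$filters$min_reads)
  if (isTRUE(cfg$filters$apply_rare_taxa)) {
    tbl <- filter_rare_taxa(tbl, cfg$filters$rare_count_thr,
                            cfg$filters$rare_sample_thr)
  }
  design <- design[design$sample_id %in% sample_ids(tbl), , drop = FALSE]
  rar <- rarefy(tbl, depth = cfg$rarefaction$depth, seed = cfg$seed + 1L)
  emit(rar, "abundance_rarefied.tsv", write_abundance_table)

  # -- stage: enterotyping ---------------------------------------------------
  enterotype_of_baseline <- NULL
  if (isTRUE(cfg$enterotyping$enabled)) {
    genus <- aggregate_taxa(rar, "genus")
    model <- fit_dmm(genus, K = cfg$enterotyping$K, seed = cfg$seed + 2L)
    emit(model, "dmm_model.json", write_dmm_model)
    labels <- classify_by_medoid(genus, model)
    enterotype_of_baseline <- labels
    design$enterotype <- unname(labels[design$sample_id])
    emit(data.frame(sample_id = names(labels), enterotype = labels),
         "enterotypes.tsv")
  }

  # -- stage: community stats (baseline samples) ----------------------------
  base_ids <- design$sample_id[design$timepoint == "baseline"]
  stats <- community_stats(subset_table(rar, samples = base_ids), ref,
                           zero_firmicutes = "inf")
  emit(stats, "community_stats.tsv")

  # -- stage: RC_bray response ----------------------------------------------
  nm_cfg <- null_model_config(rar, n_reps = cfg$nullmodel$n_reps,
                              seed = cfg$seed + 3L,
                              label = cfg$nullmodel$context)
  pairs <- rc_bray_pairs(design, nm_cfg)
  emit(pairs, "response_pairs.tsv")

  # -- stage: response potential (optional) ---------------------------------
  potential <- NULL
  if (isTRUE(cfg$potential$enabled)) {
    ids <- pairs$baseline_sample
    et <- if (!is.null(enterotype_of_baseline)) {
      enterotype_of_baseline[ids]
    } else setNames(rep(1L, length(ids)), ids)
    pot <- vapply(seq_along(ids), function(i) {
      panel <- ids[et == et[i]]
      panel <- setdiff(panel, ids[i])
      if (length(panel) > cfg$potential$max_reference) {
        panel <- with_seed(cfg$seed + 4L,
                           sample(panel, cfg$potential$max_reference))
      }
      suppressWarnings(
        as.numeric(response_potential(ids[i], panel, nm_cfg)))
    }, numeric(1))
    potential <- setNames(pot, ids)
    emit(data.frame(sample_id = ids, response_potential = pot),
         "response_potential.tsv")
  }

  # -- stage: records & network ---------------------------------------------
  records <- build_response_records(
    pairs, stats,
    enterotypes = enterotype_of_baseline,
    potential = potential)
  emit(records, "response_records.tsv")
  components <- c("response", "alpha_baseline", "agn_baseline", "bf_baseline")
  if (!is.null(potential)) components <- c(components, "response_potential")
  random_effect <- cfg$network$random_effect
  if (!is.null(random_effect) &&
      length(unique(records$intervention)) < 2) {
    random_effect <- NULL
  }
  net <- partial_correlation_network(records, components,
                                     random_effect = random_effect,
                                     fdr_alpha = cfg$network$fdr_alpha)
  emit(net, "network.tsv")

  # -- stage: per-taxon associations (optional) -----------------------------
  if (isTRUE(cfg$taxa_association$enabled)) {
    assoc <- taxa_response_association(
      rar, records, mode = cfg$taxa_association$mode,
      adjust_alpha = isTRUE(cfg$taxa_association$adjust_alpha),
      pseudocount = cfg$taxa_association$pseudocount)
    emit(assoc, "taxa_associations.tsv")
  }

  # -- stage: boosted-tree predictability (optional) ------------------------
  if (isTRUE(cfg$ml$enabled)) {
    Xp <- transform_predictors(subset_table(rar,
                                            samples = pairs$baseline_sample))
    ml_cfg <- do.call(ml_config, c(cfg$ml[setdiff(names(cfg$ml), "enabled")],
                                   list(seed = cfg$seed + 5L)))
    cv <- cv_predict_response(Xp, records$response,
                              potentials = records$response_potential,
                              cfg = ml_cfg)
    emit(cv$iterations, "ml_iterations.tsv")
    emit(cv$summary, "ml_summary.tsv")
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("microresp")),
    seed = cfg$seed,
    config_hash = hash31(paste(deparse(cfg), collapse = "\n")),
    rarefaction_depth = attr(rar, "depth"),
    rc_context = cfg$nullmodel$context,
    rc_n_reps = cfg$nullmodel$n_reps,
    outputs = as.list(setNames(unname(tools::md5sum(outputs)),
                               basename(outputs))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
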