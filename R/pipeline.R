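#' Load a pipeline configuration
#'
#' Reads an optional JSON config file, fills in package defaults and
#' applies overrides (e.g., parsed command-line flags). Sections:
#' `inputs` (paths `disease_lncRNA`, `disease_miRNA`, `lncRNA_miRNA`,
#' optional `mesh`), `wknnp` (`k`, `alpha`, `fusion_weights`), `ranks`,
#' `epsilon`, `max_iter`, `seed`, `decay`, `evaluation` (`scheme`,
#' `folds`, `repeats`, `refit_similarity`), `output_dir`.
#'
#' @param path optional path to a JSON config file.
#' @param overrides named list merged over the file values (deep merge
#'   for the nested sections).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(path = NULL, overrides = list()) {
  defaults <- list(
    inputs = list(disease_lncRNA = NULL, disease_miRNA = NULL,
                  lncRNA_miRNA = NULL, mesh = NULL),
    wknnp = list(k = 3L, alpha = 0.1, fusion_weights = c(1, 1, 1)),
    ranks = c(5L, 5L, 5L),
    epsilon = 1e-4,
    max_iter = 500L,
    seed = 1L,
    decay = 0.5,
    evaluation = list(scheme = "kfold", folds = 2L, repeats = 1L,
                      refit_similarity = TRUE),
    output_dir = "."
  )
  cfg <- defaults
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    cfg <- merge_config(cfg, jsonlite::read_json(path,
                                                 simplifyVector = TRUE))
  }
  cfg <- merge_config(cfg, overrides)
  structure(cfg, class = "pipeline_config")
}

merge_config <- function(base, extra) {
  for (nm in names(extra)) {
    if (is.null(extra[[nm]])) next
    if (is.list(base[[nm]]) && is.list(extra[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], extra[[nm]])
    } else {
      base[[nm]] <- extra[[nm]]
    }
  }
  base
}

require_inputs <- function(config, need_mesh = FALSE) {
  need <- c("disease_lncRNA", "disease_miRNA", "lncRNA_miRNA")
  for (nm in need) {
    p <- config$inputs[[nm]]
    if (is.null(p)) stop("config field inputs$", nm, " is required")
    if (!file.exists(p)) stop("inputs$", nm, ": file not found: ", p)
  }
  if (need_mesh && !is.null(config$inputs$mesh) &&
      !file.exists(config$inputs$mesh)) {
    stop("inputs$mesh: file not found: ", config$inputs$mesh)
  }
  invisible(config)
}

load_dataset <- function(config) {
  require_inputs(config, need_mesh = TRUE)
  g1 <- build_bipartite(read_edge_list(config$inputs$disease_lncRNA,
                                       c("disease", "lncRNA")))
  g2 <- build_bipartite(read_edge_list(config$inputs$disease_miRNA,
                                       c("disease", "miRNA")))
  g3 <- build_bipartite(read_edge_list(config$inputs$lncRNA_miRNA,
                                       c("lncRNA", "miRNA")))
  mesh <- if (!is.null(config$inputs$mesh)) {
    read_mesh(config$inputs$mesh)
  }
  assemble_dataset(g1, g2, g3, mesh = mesh, decay = config$decay)
}

write_manifest <- function(dir, stage, config, counts, extra = list()) {
  manifest <- c(list(
    stage = stage,
    package = "tritensor",
    version = as.character(utils::packageVersion("tritensor")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    config = unclass(config),
    counts = counts
  ), extra)
  path <- file.path(dir, paste0("manifest_", stage, ".json"))
  tmp <- paste0(path, ".tmp")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  file.rename(tmp, path)
  invisible(path)
}

dataset_counts <- function(data) {
  d <- dim(data$tensor)
  list(diseases = d[1], lncRNAs = d[2], miRNAs = d[3],
       associations = sum(data$tensor))
}

#' Build stage: tensor and index maps from edge lists
#'
#' Reads the three edge lists, closes the tripartite network, and writes
#' the sparse tensor (`tensor.tsv`), one index-map TSV per axis and a
#' manifest into the output directory. Logs the per-stage entity counts.
#'
#' @param config a [pipeline_config()].
#' @return the assembled `tritensor_data`, invisibly.
#' @export
run_build <- function(config) {
  data <- load_dataset(config)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  counts <- dataset_counts(data)
  message("tripartite network: ", counts$diseases, " diseases, ",
          counts$lncRNAs, " lncRNAs, ", counts$miRNAs, " miRNAs, ",
          counts$associations, " associations")
  write_tensor_tsv(data$tensor, file.path(config$output_dir,
                                          "tensor.tsv"))
  axes <- list(diseases = dimnames(data$tensor)[[1]],
               lncRNAs = dimnames(data$tensor)[[2]],
               miRNAs = dimnames(data$tensor)[[3]])
  for (nm in names(axes)) {
    utils::write.table(
      data.frame(index = seq_along(axes[[nm]]), id = axes[[nm]]),
      file.path(config$output_dir, paste0("index_", nm, ".tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_manifest(config$output_dir, "build", config, counts)
  invisible(data)
}

#' Similarity stage: axis similarity matrices as TSV
#'
#' @inheritParams run_build
#' @return the similarity list, invisibly.
#' @export
run_similarity <- function(config) {
  data <- load_dataset(config)
  sims <- compute_similarities(data)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in c("disease", "lncRNA", "miRNA")) {
    write_matrix_tsv(sims[[nm]],
                     file.path(config$output_dir,
                               paste0("similarity_", nm, ".tsv")))
  }
  write_manifest(config$output_dir, "similarity", config,
                 dataset_counts(data),
                 list(semantic_used = sims$dissem_used))
  invisible(sims)
}

#' Predict stage: WKNNP smoothing, Tucker completion, per-disease rankings
#'
#' Writes `rankings.tsv` (disease, lncRNA, miRNA, score, rank,
#' known-flag), the model checkpoint (core and factor TSVs plus a JSON
#' metadata file with ranks, seed, iterations and final residual) and a
#' manifest.
#'
#' @inheritParams run_build
#' @return list with `tstar`, `model` and `rankings`, invisibly.
#' @export
run_predict <- function(config) {
  data <- load_dataset(config)
  sims <- compute_similarities(data)
  wk <- wknnp_config(config$wknnp$k, config$wknnp$alpha,
                     config$wknnp$fusion_weights)
  fit <- fit_predict(data$tensor, sims, wknnp = wk,
                     ranks = config$ranks, epsilon = config$epsilon,
                     max_iter = config$max_iter, seed = config$seed)
  rankings <- ranking_table(fit$tstar, data$tensor,
                            exclude_known = FALSE)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(rankings,
                     file.path(config$output_dir, "rankings.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  ck_dir <- file.path(config$output_dir, "model")
  dir.create(ck_dir, showWarnings = FALSE)
  core_mat <- unfold(fit$model$core, 1)
  rownames(core_mat) <- paste0("r", seq_len(nrow(core_mat)))
  write_matrix_tsv(core_mat, file.path(ck_dir, "core_unfold1.tsv"))
  for (i in 1:3) {
    z <- fit$model$factors[[i]]
    rownames(z) <- dimnames(data$tensor)[[i]]
    write_matrix_tsv(z, file.path(ck_dir, paste0("factor", i, ".tsv")))
  }
  jsonlite::write_json(
    list(ranks = fit$model$ranks, seed = fit$model$seed,
         iterations = fit$model$iterations,
         converged = fit$model$converged,
         final_residual = utils::tail(fit$model$residual_trace, 1)),
    file.path(ck_dir, "metadata.json"), auto_unbox = TRUE, digits = NA)
  write_manifest(config$output_dir, "predict", config,
                 dataset_counts(data),
                 list(final_residual =
                        utils::tail(fit$model$residual_trace, 1)))
  message("prediction tensor written; ", nrow(rankings),
          " ranked candidate rows")
  invisible(c(fit, list(rankings = rankings)))
}

#' Evaluate stage: cross-validation summaries
#'
#' Runs the scheme selected in `config$evaluation` and writes
#' `cv_summary.tsv` (plus `roc.tsv` for LOOCV schemes or per-disease
#' AUCs for local LOOCV) and a manifest.
#'
#' @inheritParams run_build
#' @return the evaluation result object, invisibly.
#' @export
run_evaluate <- function(config) {
  data <- load_dataset(config)
  ev <- config$evaluation
  wk <- wknnp_config(config$wknnp$k, config$wknnp$alpha,
                     config$wknnp$fusion_weights)
  cfg <- cv_config(scheme = ev$scheme, folds = ev$folds,
                   repeats = ev$repeats, seed = config$seed,
                   wknnp = wk, ranks = config$ranks,
                   epsilon = config$epsilon, max_iter = config$max_iter,
                   refit_similarity = isTRUE(ev$refit_similarity))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  res <- switch(cfg$scheme,
                "global-loocv" = global_loocv(data, cfg),
                "local-loocv" = local_loocv(data, cfg),
                "kfold" = kfold_cv(data, cfg))
  if (cfg$scheme == "kfold") {
    summary_df <- data.frame(scheme = cfg$scheme, folds = cfg$folds,
                             repeats = cfg$repeats, auc_mean = res$mean,
                             auc_sd = res$sd)
  } else {
    summary_df <- data.frame(scheme = cfg$scheme,
                             n_positives = res$n_positives,
                             auc_mean = res$auc, auc_sd = NA_real_)
    if (cfg$scheme == "global-loocv") {
      utils::write.table(res$roc,
                         file.path(config$output_dir, "roc.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    } else {
      utils::write.table(
        data.frame(disease = names(res$per_disease),
                   auc = as.numeric(res$per_disease)),
        file.path(config$output_dir, "local_auc.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  utils::write.table(summary_df,
                     file.path(config$output_dir, "cv_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_manifest(config$output_dir, "evaluate", config,
                 dataset_counts(data),
                 list(auc = if (cfg$scheme == "kfold") res$mean else
                   res$auc))
  message("evaluation (", cfg$scheme, "): AUC = ",
          format(round(if (cfg$scheme == "kfold") res$mean else res$auc,
                       4)))
  invisible(res)
}

#' Simulate stage: write a synthetic fixture dataset
#'
#' Generates the coupled synthetic networks of a [fixture_spec()] and
#' writes the edge lists, MeSH-like descriptor, ground truth and a
#' manifest into `out_dir`.
#'
#' @param out_dir output directory.
#' @param seed integer seed.
#' @param ... further arguments to [fixture_spec()].
#' @return the `fixture`, invisibly.
#' @export
run_simulate <- function(out_dir, seed = 1L, ...) {
  spec <- fixture_spec(seed = seed, ...)
  fx <- simulate_fixture(spec, dir = out_dir)
  cfg <- pipeline_config(overrides = list(seed = spec$seed,
                                          output_dir = out_dir))
  write_manifest(out_dir, "simulate", cfg,
                 list(diseases = spec$n_diseases,
                      lncRNAs = spec$n_lncrnas,
                      miRNAs = spec$n_mirnas,
                      truth_triples = nrow(fx$truth),
                      held_out = sum(fx$truth$held_out)))
  message("fixture written to ", out_dir, ": ", nrow(fx$truth),
          " ground-truth triples (", sum(fx$truth$held_out),
          " held out)")
  invisible(fx)
}
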