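#' Assemble a modeling dataset from the three association networks
#'
#' Closes the bipartite networks into the tripartite network, builds the
#' binary tensor, aligns the disease-lncRNA and disease-miRNA adjacency
#' matrices to the tensor's retained index sets (these supply the GIP
#' interaction profiles and the functional-similarity disease sets), and
#' optionally attaches the MeSH semantic similarity over the retained
#' diseases.
#'
#' @param g1 disease-lncRNA `bipartite_network`.
#' @param g2 disease-miRNA `bipartite_network`.
#' @param g3 lncRNA-miRNA `bipartite_network`.
#' @param mesh optional `mesh_vocab` for disease semantic similarity.
#' @param decay semantic contribution decay factor; default 0.5.
#' @return a `tritensor_data`: list with `tensor`, `tripartite`, `y1`,
#'   `y2` (aligned adjacency matrices), `dissem` (or NULL) and `decay`.
#' @export
assemble_dataset <- function(g1, g2, g3, mesh = NULL, decay = 0.5) {
  tri <- build_tripartite(g1, g2, g3)
  if (!nrow(tri$triples)) {
    stop("no disease-lncRNA-miRNA triangle found; nothing to model")
  }
  tens <- build_tensor(tri)
  g1 <- orient_bipartite(g1, "disease")
  g2 <- orient_bipartite(g2, "disease")
  y1 <- align_adjacency(g1$adjacency, tri$diseases, tri$lncRNAs)
  y2 <- align_adjacency(g2$adjacency, tri$diseases, tri$miRNAs)
  dissem <- if (!is.null(mesh)) {
    disease_semantic_similarity(mesh, tri$diseases, decay)
  }
  structure(list(tensor = tens, tripartite = tri, y1 = y1, y2 = y2,
                 dissem = dissem, decay = decay),
            class = "tritensor_data")
}

# subset/expand an adjacency matrix to given row/column id sets,
# missing entities contributing zero profiles
align_adjacency <- function(adj, row_ids, col_ids) {
  out <- matrix(0, nrow = length(row_ids), ncol = length(col_ids),
                dimnames = list(row_ids, col_ids))
  r <- intersect(row_ids, rownames(adj))
  c <- intersect(col_ids, colnames(adj))
  out[r, c] <- adj[r, c]
  out
}

#' @export
print.tritensor_data <- function(x, ...) {
  d <- dim(x$tensor)
  cat("tritensor dataset: ", d[1], " diseases x ", d[2], " lncRNAs x ",
      d[3], " miRNAs; ", sum(x$tensor), " known associations\n", sep = "")
  cat("  semantic similarity: ",
      if (is.null(x$dissem)) "absent" else "attached", "\n", sep = "")
  invisible(x)
}

#' Axis similarity matrices for a dataset
#'
#' In the default (training) mode the GIP profiles and functional
#' disease sets come from the full input bipartite networks. With
#' `from_tensor = TRUE` they are instead projected from the support of
#' the supplied tensor, which is how cross-validation derives
#' leakage-free similarities from a masked training tensor.
#'
#' @param data a `tritensor_data`.
#' @param from_tensor derive profiles from the tensor support instead of
#'   the input networks.
#' @param tensor tensor to project from when `from_tensor = TRUE`
#'   (defaults to `data$tensor`).
#' @return list with `disease`, `lncRNA`, `miRNA` similarity matrices.
#' @export
compute_similarities <- function(data, from_tensor = FALSE,
                                 tensor = NULL) {
  stopifnot(inherits(data, "tritensor_data"))
  if (from_tensor) {
    tens <- if (is.null(tensor)) data$tensor else tensor
    proj <- project_bipartite(tens)
    build_similarities(proj$y1, proj$y2, data$dissem)
  } else {
    build_similarities(data$y1, data$y2, data$dissem)
  }
}

#' Smooth, decompose and reconstruct: the full prediction pipeline
#'
#' Applies WKNNP smoothing to the tensor, fits the nonnegative Tucker
#' model to the fused tensor and returns the reconstructed prediction
#' tensor together with the model.
#'
#' @param tens binary association tensor.
#' @param sims axis similarity matrices (see [compute_similarities()]).
#' @param wknnp a [wknnp_config()].
#' @param ranks,epsilon,epsilon_type,max_iter,seed,init passed to
#'   [tucker_decompose()].
#' @return list with `tstar` (prediction tensor), `model`
#'   (`tucker_model`) and `fused` (smoothed tensor).
#' @export
fit_predict <- function(tens, sims, wknnp = wknnp_config(),
                        ranks = c(5, 5, 5), epsilon = 1e-4,
                        epsilon_type = "relative", max_iter = 500L,
                        seed = 1L, init = "nhosvd") {
  sm <- wknnp_smooth(tens, sims, wknnp)
  model <- tucker_decompose(sm$fused, ranks = ranks, epsilon = epsilon,
                            epsilon_type = epsilon_type,
                            max_iter = max_iter, seed = seed,
                            init = init)
  tstar <- tucker_reconstruct(model)
  dimnames(tstar) <- dimnames(tens)
  list(tstar = tstar, model = model, fused = sm$fused)
}

#' Rank candidate lncRNA-miRNA pairs for one disease
#'
#' Sorts the disease's slice of the prediction tensor in decreasing
#' score order, flagging training positives; by default known pairs are
#' excluded from the candidate list. Ties are broken by (lncRNA, miRNA)
#' index order and ranks are contiguous from 1.
#'
#' @param tstar prediction tensor.
#' @param train binary training tensor of the same shape.
#' @param disease disease identifier or index.
#' @param exclude_known drop training positives from the table
#'   (default TRUE); when FALSE they are kept and flagged.
#' @return data.frame with columns `disease`, `lncRNA`, `miRNA`,
#'   `score`, `rank`, `known`.
#' @export
rank_pairs <- function(tstar, train, disease, exclude_known = TRUE) {
  stopifnot(identical(dim(tstar), dim(train)))
  di <- if (is.character(disease)) {
    match(disease, dimnames(tstar)[[1]])
  } else {
    as.integer(disease)
  }
  if (is.na(di) || di < 1 || di > dim(tstar)[1]) {
    stop("unknown disease: ", disease)
  }
  slice <- tstar[di, , ]
  known <- train[di, , ] == 1
  nl <- dim(tstar)[2]
  nm <- dim(tstar)[3]
  idx <- expand.grid(l = seq_len(nl), m = seq_len(nm))
  df <- data.frame(
    disease = if (is.null(dimnames(tstar)[[1]])) di else
      dimnames(tstar)[[1]][di],
    lncRNA = if (is.null(dimnames(tstar)[[2]])) idx$l else
      dimnames(tstar)[[2]][idx$l],
    miRNA = if (is.null(dimnames(tstar)[[3]])) idx$m else
      dimnames(tstar)[[3]][idx$m],
    score = slice[cbind(idx$l, idx$m)],
    known = known[cbind(idx$l, idx$m)],
    .li = idx$l, .mi = idx$m,
    stringsAsFactors = FALSE
  )
  if (exclude_known) df <- df[!df$known, , drop = FALSE]
  ord <- order(-df$score, df$.li, df$.mi)
  df <- df[ord, , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  df[, c("disease", "lncRNA", "miRNA", "score", "rank", "known")]
}

#' Ranking table over all diseases
#'
#' Concatenates [rank_pairs()] over every disease of the tensor.
#'
#' @inheritParams rank_pairs
#' @param diseases subset of disease identifiers (default: all).
#' @return data.frame in the [rank_pairs()] format.
#' @export
ranking_table <- function(tstar, train, diseases = NULL,
                          exclude_known = TRUE) {
  if (is.null(diseases)) diseases <- dimnames(tstar)[[1]]
  if (is.null(diseases)) diseases <- seq_len(dim(tstar)[1])
  do.call(rbind, lapply(diseases, function(d) {
    rank_pairs(tstar, train, d, exclude_known)
  }))
}
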