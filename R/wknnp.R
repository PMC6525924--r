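#' WKNNP smoothing configuration
#'
#' Parameters of the weighted K-nearest-neighbor profile step: `k`
#' neighbors per query entity, geometric decay `alpha` applied down the
#' similarity-sorted neighbor list, and the fusion weights of the three
#' axis estimates.
#'
#' @param k neighbor count, positive integer; default 3.
#' @param alpha decay factor in (0, 1); default 0.1.
#' @param fusion_weights nonnegative weights `(a1, a2, a3)` for the
#'   disease-, lncRNA- and miRNA-axis estimates; default `c(1, 1, 1)`.
#' @return a `wknnp_config` list.
#' @export
wknnp_config <- function(k = 3L, alpha = 0.1, fusion_weights = c(1, 1, 1)) {
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k) || k < 1L) stop("k must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (length(fusion_weights) != 3L || any(fusion_weights < 0) ||
      sum(fusion_weights) <= 0) {
    stop("fusion_weights must be three nonnegative values summing > 0")
  }
  structure(list(k = k, alpha = alpha, fusion_weights = fusion_weights),
            class = "wknnp_config")
}

#' Similarity-weighted K-nearest-neighbor profile estimate along one axis
#'
#' For every entity on the chosen axis, its `k` most similar *other*
#' entities that have at least one known association contribute their
#' tensor slices. With neighbors sorted by similarity descending (ties
#' broken by index order), neighbor `t` receives weight
#' `w_t = alpha^(t-1) * sim_t` and the estimate is
#' `sum_t w_t * slice_t / Q` with the normalizer `Q = sum_t sim_t` over
#' the raw (undecayed) similarities. Entities with fewer than `k`
#' eligible neighbors use all of them; an entity with none keeps a zero
#' slice and triggers a warning.
#'
#' @param tens binary association tensor (disease x lncRNA x miRNA).
#' @param sim similarity matrix indexed over the queried axis.
#' @param axis 1 (disease), 2 (lncRNA) or 3 (miRNA).
#' @param config a [wknnp_config()].
#' @return a tensor of the same shape holding the axis estimate.
#' @export
axis_knn_profile <- function(tens, sim, axis, config = wknnp_config()) {
  axis <- check_mode(axis)
  stopifnot(inherits(config, "wknnp_config"))
  n <- dim(tens)[axis]
  if (nrow(sim) != n || ncol(sim) != n) {
    stop("similarity matrix is ", nrow(sim), "x", ncol(sim),
         " but axis ", axis, " has ", n, " entities")
  }
  ids <- dimnames(tens)[[axis]]
  if (!is.null(ids) && !is.null(rownames(sim)) &&
      !identical(ids, rownames(sim))) {
    stop("similarity matrix entities do not match tensor axis ", axis)
  }
  u <- unfold(tens, axis)                    # rows are flattened slices
  eligible <- rowSums(u) > 0
  est <- matrix(0, nrow = n, ncol = ncol(u))
  starved <- character(0)
  for (i in seq_len(n)) {
    cand <- setdiff(which(eligible), i)
    s <- sim[i, cand]
    keep <- s > 0
    cand <- cand[keep]
    s <- s[keep]
    if (!length(cand)) {
      starved <- c(starved, if (is.null(ids)) as.character(i) else ids[i])
      next
    }
    ord <- order(-s, cand)                   # ties broken by index order
    take <- seq_len(min(config$k, length(cand)))
    nb <- cand[ord][take]
    s_nb <- s[ord][take]
    w <- config$alpha^(take - 1) * s_nb
    est[i, ] <- colSums(u[nb, , drop = FALSE] * w) / sum(s_nb)
  }
  if (length(starved)) {
    warning("no eligible neighbor with positive similarity for axis-",
            axis, " entit(y/ies): ", paste(starved, collapse = ", "),
            "; their estimated slices are zero")
  }
  refold(est, axis, dim(tens))
}

#' Fuse axis estimates with the observed tensor
#'
#' Blends the three axis estimates with the fusion weights,
#' `T_DLM = (a1 T_D + a2 T_L + a3 T_M) / (a1 + a2 + a3)`, and replaces
#' unobserved entries by taking the elementwise maximum with the observed
#' tensor, so known associations are always preserved.
#'
#' @param tens observed binary tensor.
#' @param td,tl,tm axis estimates from [axis_knn_profile()].
#' @param config a [wknnp_config()] supplying the fusion weights.
#' @return the fused tensor, entries in `[0, 1]`.
#' @export
wknnp_fuse <- function(tens, td, tl, tm, config = wknnp_config()) {
  w <- config$fusion_weights
  tdlm <- (w[1] * td + w[2] * tl + w[3] * tm) / sum(w)
  fused <- pmax(tens, tdlm)
  dim(fused) <- dim(tens)
  dimnames(fused) <- dimnames(tens)
  clip01(fused)
}

#' Full WKNNP smoothing of an association tensor
#'
#' Runs [axis_knn_profile()] along all three axes with the corresponding
#' similarity matrices and fuses the estimates with [wknnp_fuse()].
#'
#' @param tens binary association tensor.
#' @param sims list with `disease`, `lncRNA`, `miRNA` similarity matrices
#'   (as from [build_similarities()]).
#' @param config a [wknnp_config()].
#' @return list of class `wknnp_tensor` with the `fused` tensor, the
#'   three axis estimates `td`, `tl`, `tm`, and the `config`.
#' @export
wknnp_smooth <- function(tens, sims, config = wknnp_config()) {
  td <- axis_knn_profile(tens, sims$disease, 1, config)
  tl <- axis_knn_profile(tens, sims$lncRNA, 2, config)
  tm <- axis_knn_profile(tens, sims$miRNA, 3, config)
  structure(list(fused = wknnp_fuse(tens, td, tl, tm, config),
                 td = td, tl = tl, tm = tm, config = config),
            class = "wknnp_tensor")
}
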