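#' Area under the ROC curve with midrank tie handling
#'
#' Trapezoidal ROC area, computed through the rank-sum (Mann-Whitney)
#' identity so that tied scores contribute half a concordance.
#'
#' @param labels binary vector (1 = positive).
#' @param scores numeric scores, higher = more positive.
#' @return scalar AUC in `[0, 1]`.
#' @examples
#' auc_score(c(1, 0, 1, 0), c(0.9, 0.8, 0.7, 0.1))  # 0.75
#' @export
auc_score <- function(labels, scores) {
  labels <- as.integer(labels != 0)
  stopifnot(length(labels) == length(scores))
  p <- sum(labels == 1)
  n <- sum(labels == 0)
  if (p == 0 || n == 0) stop("need at least one positive and one negative")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - p * (p + 1) / 2) / (p * n)
}

#' ROC curve points
#'
#' Sweeps the score thresholds from high to low and reports the false-
#' and true-positive rates; the trapezoidal area equals [auc_score()].
#'
#' @inheritParams auc_score
#' @return data.frame with `threshold`, `fpr`, `tpr` (monotone
#'   nondecreasing) and an `auc` attribute.
#' @export
roc_curve <- function(labels, scores) {
  labels <- as.integer(labels != 0)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  l <- labels[o]
  # indices after which the threshold drops (last index of each tied run)
  last <- c(which(diff(s) != 0), length(s))
  tp <- cumsum(l)[last]
  fp <- cumsum(1 - l)[last]
  df <- data.frame(threshold = c(Inf, s[last]),
                   fpr = c(0, fp / sum(labels == 0)),
                   tpr = c(0, tp / sum(labels == 1)))
  attr(df, "auc") <- sum(diff(df$fpr) * (utils::head(df$tpr, -1) +
                                           utils::tail(df$tpr, -1)) / 2)
  df
}

#' Cross-validation configuration
#'
#' Bundles the evaluation scheme with the pipeline parameters used
#' inside each fold.
#'
#' @param scheme `"global-loocv"`, `"local-loocv"` or `"kfold"`.
#' @param folds number of folds for `"kfold"` (2 or 10 in typical use).
#' @param repeats number of repeated random partitions for `"kfold"`.
#' @param seed base seed; fold seeds are derived deterministically.
#' @param wknnp a [wknnp_config()].
#' @param ranks,epsilon,max_iter passed to [tucker_decompose()].
#' @param refit_similarity recompute similarities from the masked
#'   training tensor in every fold (strict, leakage-free; default) or
#'   freeze the full-data similarities (fast).
#' @param stratified stratify k-fold partitions over diseases.
#' @return a `cv_config` list.
#' @export
cv_config <- function(scheme = c("global-loocv", "local-loocv", "kfold"),
                      folds = 2L, repeats = 1L, seed = 1L,
                      wknnp = wknnp_config(), ranks = c(5, 5, 5),
                      epsilon = 1e-3, max_iter = 100L,
                      refit_similarity = TRUE, stratified = TRUE) {
  scheme <- match.arg(scheme)
  folds <- as.integer(folds)
  repeats <- as.integer(repeats)
  if (scheme == "kfold" && folds < 2L) stop("folds must be >= 2")
  if (repeats < 1L) stop("repeats must be >= 1")
  structure(list(scheme = scheme, folds = folds, repeats = repeats,
                 seed = as.integer(seed), wknnp = wknnp, ranks = ranks,
                 epsilon = epsilon, max_iter = as.integer(max_iter),
                 refit_similarity = refit_similarity,
                 stratified = stratified),
            class = "cv_config")
}

# fit the pipeline on a masked tensor under a cv_config
cv_fit <- function(data, train, config, sims_full) {
  sims <- if (config$refit_similarity) {
    compute_similarities(data, from_tensor = TRUE, tensor = train)
  } else {
    sims_full
  }
  fit_predict(train, sims, wknnp = config$wknnp, ranks = config$ranks,
              epsilon = config$epsilon, max_iter = config$max_iter,
              seed = config$seed)$tstar
}

# concordance fraction of one positive score against a negative pool
concordance_frac <- function(pos_score, neg_scores) {
  (sum(neg_scores < pos_score) + 0.5 * sum(neg_scores == pos_score)) /
    length(neg_scores)
}

# shared LOOCV engine; scope = "global" ranks each held-out triple
# against every unobserved triple, "local" only against unobserved
# triples of the same disease
loocv_engine <- function(data, config, scope) {
  tens <- data$tensor
  pos <- which(tens == 1, arr.ind = TRUE)
  if (nrow(pos) < 2) stop("need at least 2 known triples for LOOCV")
  neg_mask <- tens == 0
  sims_full <- if (config$refit_similarity) NULL else
    compute_similarities(data)
  frac <- numeric(nrow(pos))
  for (f in seq_len(nrow(pos))) {
    train <- tens
    train[pos[f, 1], pos[f, 2], pos[f, 3]] <- 0
    tstar <- cv_fit(data, train, config, sims_full)
    held <- tstar[pos[f, 1], pos[f, 2], pos[f, 3]]
    negs <- if (scope == "global") {
      tstar[neg_mask]
    } else {
      sl <- tstar[pos[f, 1], , ]
      sl[neg_mask[pos[f, 1], , ]]
    }
    if (!length(negs)) {
      frac[f] <- NA_real_
      next
    }
    frac[f] <- concordance_frac(held, negs)
  }
  list(positives = pos, frac = frac)
}

# rank-percentile fractions -> pooled ROC curve (x: share of negatives
# ranked above, y: share of positives recovered)
frac_to_roc <- function(frac) {
  fpr_at_pos <- sort(1 - frac)
  grid <- unique(c(0, fpr_at_pos, 1))
  tpr <- vapply(grid, function(t) mean(fpr_at_pos <= t), numeric(1))
  data.frame(fpr = grid, tpr = tpr)
}

#' Global leave-one-out cross-validation
#'
#' Each known triple is masked in turn; the pipeline (similarities if
#' `refit_similarity`, WKNNP smoothing, Tucker completion) is refitted on
#' the masked tensor and the held-out triple's score is ranked against
#' every unobserved triple of the whole tensor. The pooled AUC is the
#' mean concordance of held-out triples against the negative pool.
#'
#' @param data a `tritensor_data`.
#' @param config a [cv_config()].
#' @return list of class `loocv_result` with `auc`, `frac` (per-positive
#'   concordance), `roc` (pooled ROC points) and `n_positives`.
#' @export
global_loocv <- function(data, config = cv_config("global-loocv")) {
  eng <- loocv_engine(data, config, "global")
  ok <- !is.na(eng$frac)
  structure(list(auc = mean(eng$frac[ok]), frac = eng$frac,
                 roc = frac_to_roc(eng$frac[ok]),
                 n_positives = sum(ok), scope = "global"),
            class = "loocv_result")
}

#' Local (per-disease) leave-one-out cross-validation
#'
#' As [global_loocv()], but each held-out triple is ranked only against
#' the unobserved lncRNA-miRNA pairs of its own disease. Reports the
#' per-disease AUCs (mean concordance of that disease's positives) and
#' their mean over diseases with at least one positive.
#'
#' @inheritParams global_loocv
#' @return list of class `loocv_result` with `auc` (mean over diseases),
#'   `per_disease` (named numeric), `frac` and `n_positives`.
#' @export
local_loocv <- function(data, config = cv_config("local-loocv")) {
  eng <- loocv_engine(data, config, "local")
  ids <- dimnames(data$tensor)[[1]]
  d_of <- eng$positives[, 1]
  ok <- !is.na(eng$frac)
  per <- tapply(eng$frac[ok], d_of[ok], mean)
  names(per) <- if (is.null(ids)) names(per) else ids[as.integer(names(per))]
  structure(list(auc = mean(per), per_disease = per, frac = eng$frac,
                 n_positives = sum(ok), scope = "local"),
            class = "loocv_result")
}

#' @export
print.loocv_result <- function(x, ...) {
  cat(x$scope, "LOOCV over", x$n_positives, "known associations: AUC =",
      format(round(x$auc, 4)), "\n")
  invisible(x)
}

# partition row indices of `pos` into folds; stratified deals each
# disease's positives round-robin from a random start
make_folds <- function(pos, folds, stratified) {
  n <- nrow(pos)
  fold_of <- integer(n)
  if (stratified) {
    for (d in unique(pos[, 1])) {
      idx <- sample(which(pos[, 1] == d))
      fold_of[idx] <- (sample.int(folds, 1) + seq_along(idx) - 2) %%
        folds + 1
    }
  } else {
    fold_of <- sample(rep_len(seq_len(folds), n))
  }
  fold_of
}

#' Repeated k-fold cross-validation
#'
#' Known triples are partitioned into `folds` subsets (stratified over
#' diseases by default); each fold is masked in turn, the pipeline is
#' refitted, and the fold AUC pools the masked triples' scores against
#' the unobserved-triple pool. The partition is redrawn `repeats` times
#' and the mean and standard deviation of the per-repeat average AUCs
#' are reported.
#'
#' @inheritParams global_loocv
#' @return list of class `kfold_result` with `mean`, `sd`, `repeat_auc`
#'   (per-repeat averages) and `fold_auc` (matrix repeats x folds).
#' @export
kfold_cv <- function(data, config = cv_config("kfold")) {
  tens <- data$tensor
  pos <- which(tens == 1, arr.ind = TRUE)
  if (nrow(pos) < config$folds) stop("fewer positives than folds")
  neg_mask <- tens == 0
  sims_full <- if (config$refit_similarity) NULL else
    compute_similarities(data)
  fold_auc <- matrix(NA_real_, nrow = config$repeats, ncol = config$folds)
  for (r in seq_len(config$repeats)) {
    fold_of <- with_seed(config$seed + r - 1L,
                         make_folds(pos, config$folds, config$stratified))
    for (f in seq_len(config$folds)) {
      held <- pos[fold_of == f, , drop = FALSE]
      if (!nrow(held)) next
      train <- tens
      train[held] <- 0
      tstar <- cv_fit(data, train, config, sims_full)
      scores <- c(tstar[held], tstar[neg_mask])
      labels <- c(rep(1L, nrow(held)), rep(0L, sum(neg_mask)))
      fold_auc[r, f] <- auc_score(labels, scores)
    }
  }
  rep_auc <- rowMeans(fold_auc, na.rm = TRUE)
  structure(list(mean = mean(rep_auc),
                 sd = if (config$repeats > 1) stats::sd(rep_auc) else
                   NA_real_,
                 repeat_auc = rep_auc, fold_auc = fold_auc,
                 folds = config$folds, repeats = config$repeats),
            class = "kfold_result")
}

#' @export
print.kfold_result <- function(x, ...) {
  cat(x$folds, "-fold CV (", x$repeats, " repeat(s)): AUC = ",
      format(round(x$mean, 4)),
      if (!is.na(x$sd)) paste0(" ± ", format(round(x$sd, 4))) else "",
      "\n", sep = "")
  invisible(x)
}

#' Recall of held-out positives within top-k ranking lists
#'
#' For each `k` of the grid, the fraction of held-out positives whose
#' candidate pair appears within the top `k` ranks of its disease's
#' ranking list. Positives absent from the table (e.g., filtered out)
#' count as never recalled.
#'
#' @param rankings ranking table from [ranking_table()] /
#'   [rank_pairs()].
#' @param positives data.frame with `disease`, `lncRNA`, `miRNA` columns
#'   identifying the held-out positives.
#' @param k_grid integer vector of list lengths.
#' @return data.frame with `k` and `recall` (nondecreasing in `k`).
#' @export
recall_at_k <- function(rankings, positives, k_grid) {
  key <- function(d, l, m) paste(d, l, m, sep = "\r")
  rk <- stats::setNames(rankings$rank,
                        key(rankings$disease, rankings$lncRNA,
                            rankings$miRNA))
  pos_rank <- rk[key(positives$disease, positives$lncRNA,
                     positives$miRNA)]
  pos_rank[is.na(pos_rank)] <- Inf
  data.frame(k = k_grid,
             recall = vapply(k_grid, function(k) mean(pos_rank <= k),
                             numeric(1)))
}

#' AUC over a grid of WKNNP parameters
#'
#' Re-runs a fixed evaluation scheme for every combination of the
#' neighbor count `k` and decay `alpha`, holding all other parameters
#' and the seed fixed.
#'
#' @param data a `tritensor_data`.
#' @param k_values integer vector of neighbor counts.
#' @param alpha_values numeric vector of decay values in (0, 1).
#' @param config a [cv_config()]; its `wknnp` k/alpha fields are
#'   overridden per grid point.
#' @return data.frame with `k`, `alpha`, `auc`, in input grid order.
#' @export
parameter_sweep <- function(data, k_values, alpha_values,
                            config = cv_config("kfold")) {
  grid <- expand.grid(alpha = alpha_values, k = k_values)[, 2:1]
  grid$auc <- vapply(seq_len(nrow(grid)), function(i) {
    cfg <- config
    cfg$wknnp <- wknnp_config(grid$k[i], grid$alpha[i],
                              config$wknnp$fusion_weights)
    switch(config$scheme,
           "global-loocv" = global_loocv(data, cfg)$auc,
           "local-loocv" = local_loocv(data, cfg)$auc,
           "kfold" = kfold_cv(data, cfg)$mean)
  }, numeric(1))
  rownames(grid) <- NULL
  grid
}
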