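#' Gaussian interaction-profile kernel similarity
#'
#' Each row of `profiles` is an entity's binary interaction profile. The
#' kernel bandwidth is set from the mean squared profile norm,
#' `gamma = n / sum_i ||profile_i||^2`, and the similarity between two
#' entities is `exp(-gamma * ||p_i - p_j||^2)`.
#'
#' @param profiles numeric (binary) matrix, entities in rows, with row
#'   names identifying the entities.
#' @return symmetric similarity matrix with unit diagonal and a `gamma`
#'   attribute recording the bandwidth.
#' @examples
#' p <- rbind(a = c(1, 0), b = c(0, 1))
#' gip_similarity(p)["a", "b"]  # exp(-2)
#' @export
gip_similarity <- function(profiles) {
  profiles <- as.matrix(profiles)
  norms <- rowSums(profiles^2)
  total <- sum(norms)
  if (total == 0) {
    stop("all interaction profiles are zero; GIP bandwidth undefined")
  }
  gamma <- nrow(profiles) / total
  # ||p_i - p_j||^2 = ||p_i||^2 + ||p_j||^2 - 2 <p_i, p_j>
  cross <- tcrossprod(profiles)
  d2 <- outer(norms, norms, "+") - 2 * cross
  d2[d2 < 0] <- 0
  sim <- exp(-gamma * d2)
  diag(sim) <- 1
  sim <- clip01(sim)
  dimnames(sim) <- list(rownames(profiles), rownames(profiles))
  attr(sim, "gamma") <- gamma
  sim
}

#' Elementwise mean of two similarity matrices
#'
#' Used to merge the lncRNA- and miRNA-profile GIP kernels for diseases,
#' and generally wherever two similarity sources are averaged.
#'
#' @param a,b similarity matrices with identical dimnames.
#' @return their elementwise mean, clipped to `[0, 1]`.
#' @export
average_similarity <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  if (!is.null(rownames(a)) && !identical(rownames(a), rownames(b))) {
    stop("similarity matrices are indexed over different entities")
  }
  out <- clip01((a + b) / 2)
  dimnames(out) <- dimnames(a)
  out
}

#' Best-match functional similarity from shared disease associations
#'
#' Two entities (lncRNAs or miRNAs) are functionally similar when their
#' associated disease sets are semantically similar. For disease sets
#' `DT_i` and `DT_j` the score is the average of best-match semantic
#' similarities taken in both directions:
#' `(sum_{a in DT_i} max_b S(a, b) + sum_{b in DT_j} max_a S(a, b))
#'  / (|DT_i| + |DT_j|)`.
#' Entities without any associated disease get similarity 0 (including
#' on the diagonal), with a warning.
#'
#' @param assoc binary entity x disease association matrix (row names are
#'   entities, column names diseases).
#' @param dissem disease semantic similarity matrix covering at least the
#'   columns of `assoc`.
#' @return symmetric similarity matrix over the entities.
#' @export
functional_similarity <- function(assoc, dissem) {
  assoc <- as.matrix(assoc)
  if (is.null(colnames(assoc)) || is.null(rownames(dissem))) {
    stop("assoc and dissem must carry disease identifiers as dimnames")
  }
  missing <- setdiff(colnames(assoc), rownames(dissem))
  if (length(missing)) {
    stop("diseases absent from the semantic similarity matrix: ",
         paste(missing, collapse = ", "))
  }
  s <- dissem[colnames(assoc), colnames(assoc), drop = FALSE]
  n <- nrow(assoc)
  sets <- lapply(seq_len(n), function(i) which(assoc[i, ] == 1))
  sizes <- lengths(sets)
  if (any(sizes == 0)) {
    warning(sum(sizes == 0), " entity(ies) with no associated disease; ",
            "their functional similarity is 0")
  }
  # best[a, j] = max over b in DT_j of S(a, b)
  best <- matrix(0, nrow = ncol(assoc), ncol = n)
  for (j in seq_len(n)) {
    if (sizes[j]) {
      best[, j] <- apply(s[, sets[[j]], drop = FALSE], 1, max)
    }
  }
  sim <- matrix(0, n, n, dimnames = list(rownames(assoc), rownames(assoc)))
  for (i in seq_len(n)) {
    if (!sizes[i]) next
    for (j in i:n) {
      if (!sizes[j]) next
      val <- (sum(best[sets[[i]], j]) + sum(best[sets[[j]], i])) /
        (sizes[i] + sizes[j])
      sim[i, j] <- sim[j, i] <- val
    }
  }
  clip01(sim)
}

#' Combine functional/semantic and GIP similarity
#'
#' Elementwise mean of the two sources. When `has_semantic` is supplied
#' (a named logical over the entities, used for the disease axis), pairs
#' where either entity lacks semantic information fall back to the GIP
#' value alone.
#'
#' @param fun functional or semantic similarity matrix.
#' @param gip GIP kernel similarity matrix with the same dimnames.
#' @param has_semantic optional logical vector (named like the rows) that
#'   marks entities with usable semantic information.
#' @return combined symmetric similarity matrix.
#' @export
combine_similarity <- function(fun, gip, has_semantic = NULL) {
  out <- average_similarity(fun, gip)
  if (!is.null(has_semantic)) {
    if (!is.null(rownames(out))) {
      has_semantic <- has_semantic[rownames(out)]
    }
    use_gip <- outer(!has_semantic, !has_semantic, "|")
    out[use_gip] <- gip[use_gip]
    diag(out) <- 1
  }
  clip01(out)
}

#' Compute the three axis similarity matrices of an association tensor
#'
#' From aligned disease x lncRNA (`y1`) and disease x miRNA (`y2`)
#' adjacency matrices this derives, per the model's preprocessing:
#' disease similarity (mean of the MeSH semantic similarity and the
#' averaged lncRNA-/miRNA-profile GIP kernels, GIP alone for diseases
#' without a MeSH DAG), lncRNA similarity (mean of best-match functional
#' and GIP similarity) and miRNA similarity (same construction on `y2`).
#' Without a semantic matrix all three axes use their GIP kernels, the
#' RNA axes averaged with functional similarity computed from the GIP
#' disease similarity.
#'
#' @param y1 binary disease x lncRNA matrix with dimnames.
#' @param y2 binary disease x miRNA matrix with the same row names.
#' @param dissem optional disease semantic similarity matrix (with
#'   `has_dag` attribute) covering the rows of `y1`.
#' @return list with components `disease`, `lncRNA`, `miRNA` (symmetric
#'   similarity matrices) and `dissem_used` (logical).
#' @export
build_similarities <- function(y1, y2, dissem = NULL) {
  stopifnot(identical(rownames(y1), rownames(y2)))
  gip_ld <- gip_similarity(y1)    # disease profiles over lncRNAs
  gip_md <- gip_similarity(y2)    # disease profiles over miRNAs
  gip_d <- average_similarity(gip_ld, gip_md)
  if (!is.null(dissem)) {
    sem <- dissem[rownames(y1), rownames(y1), drop = FALSE]
    has_dag <- attr(dissem, "has_dag")
    has_dag <- if (is.null(has_dag)) {
      stats::setNames(rep(TRUE, nrow(y1)), rownames(y1))
    } else {
      has_dag[rownames(y1)]
    }
    dis <- combine_similarity(sem, gip_d, has_semantic = has_dag)
    fun_source <- sem
  } else {
    dis <- gip_d
    fun_source <- gip_d
  }
  lnc <- combine_similarity(
    suppressWarnings(functional_similarity(t(y1), fun_source)),
    gip_similarity(t(y1))
  )
  mir <- combine_similarity(
    suppressWarnings(functional_similarity(t(y2), fun_source)),
    gip_similarity(t(y2))
  )
  list(disease = dis, lncRNA = lnc, miRNA = mir,
       dissem_used = !is.null(dissem))
}
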