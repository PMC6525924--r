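#' Read a MeSH ASCII descriptor file
#'
#' Parses the plain-text MeSH descriptor format: records separated by
#' `*NEWRECORD`, with `MH = <heading>` naming the term and one or more
#' `MN = <tree number>` lines placing it in the poly-hierarchy. Only
#' records carrying both fields are retained.
#'
#' @param path path to the descriptor file.
#' @return a `mesh_vocab`: list with `terms` (data.frame of `heading`,
#'   `tree`) and `tree_to_heading` (named character vector).
#' @export
read_mesh <- function(path) {
  if (!file.exists(path)) stop("MeSH descriptor file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  rec_start <- grepl("^\\*NEWRECORD", lines)
  if (!any(rec_start)) stop("no *NEWRECORD markers in ", path)
  rec_id <- cumsum(rec_start)
  mh <- grepl("^MH = ", lines)
  mn <- grepl("^MN = ", lines)
  headings <- tapply(ifelse(mh, sub("^MH = ", "", lines), NA_character_),
                     rec_id, function(v) v[!is.na(v)][1])
  rows <- lapply(unique(rec_id[rec_id > 0]), function(r) {
    h <- headings[[as.character(r)]]
    trees <- sub("^MN = ", "", lines[mn & rec_id == r])
    if (is.na(h) || !length(trees)) return(NULL)
    data.frame(heading = trimws(h), tree = trimws(trees),
               stringsAsFactors = FALSE)
  })
  terms <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(terms) || !nrow(terms)) {
    stop("no records with both MH and MN fields in ", path)
  }
  bad <- !grepl("^[A-Za-z][0-9A-Za-z]*(\\.[0-9A-Za-z]+)*$", terms$tree)
  if (any(bad)) {
    stop("unparseable tree number: ", terms$tree[which(bad)[1]])
  }
  t2h <- terms$heading
  names(t2h) <- terms$tree
  structure(list(terms = terms, tree_to_heading = t2h),
            class = "mesh_vocab")
}

#' @export
print.mesh_vocab <- function(x, ...) {
  cat("MeSH vocabulary: ", length(unique(x$terms$heading)), " headings, ",
      nrow(x$terms), " tree numbers\n", sep = "")
  invisible(x)
}

# all proper prefixes of a dotted tree number, shortest first
tree_prefixes <- function(tree) {
  parts <- strsplit(tree, ".", fixed = TRUE)[[1]]
  if (length(parts) < 2) return(character(0))
  vapply(seq_len(length(parts) - 1), function(i) {
    paste(parts[seq_len(i)], collapse = ".")
  }, character(1))
}

#' Ancestor DAG of one disease term in the MeSH hierarchy
#'
#' The node set contains the disease itself plus every ancestor obtained
#' by truncating its tree numbers to all prefixes; edges run from parent
#' to child tree positions. Nodes are identified by tree number, each
#' carrying the heading it maps to (ancestor positions without a heading
#' record keep their tree number as label).
#'
#' @param mesh a `mesh_vocab`.
#' @param disease heading to look up (exact match).
#' @return a `mesh_dag`: list with `disease`, `found`, `nodes`
#'   (data.frame of `tree`, `heading`, `is_self`), `edges` (data.frame of
#'   `parent`, `child` tree numbers).
#' @export
mesh_dag <- function(mesh, disease) {
  stopifnot(inherits(mesh, "mesh_vocab"))
  own <- mesh$terms$tree[mesh$terms$heading == disease]
  if (!length(own)) {
    return(structure(list(disease = disease, found = FALSE,
                          nodes = data.frame(tree = character(0),
                                             heading = character(0),
                                             is_self = logical(0)),
                          edges = data.frame(parent = character(0),
                                             child = character(0))),
                     class = "mesh_dag"))
  }
  trees <- unique(unlist(c(own, lapply(own, tree_prefixes))))
  heading <- ifelse(trees %in% names(mesh$tree_to_heading),
                    unname(mesh$tree_to_heading[trees]), trees)
  # a heading reachable both as self and ancestor position counts as self
  is_self <- trees %in% own | heading == disease
  parent <- sub("\\.[^.]+$", "", trees)
  has_parent <- parent != trees & parent %in% trees
  structure(list(
    disease = disease, found = TRUE,
    nodes = data.frame(tree = trees, heading = heading, is_self = is_self,
                       stringsAsFactors = FALSE),
    edges = data.frame(parent = parent[has_parent],
                       child = trees[has_parent],
                       stringsAsFactors = FALSE)
  ), class = "mesh_dag")
}

#' Decayed semantic contributions of a disease's MeSH ancestors
#'
#' The disease itself contributes 1; every ancestor position contributes
#' `decay` times the largest contribution among its children inside the
#' disease's DAG, evaluated bottom-up. Contributions of tree positions
#' sharing a heading are merged by maximum, and the semantic value
#' `DV(d)` is the sum of the per-heading contributions.
#'
#' @param dag a `mesh_dag` from [mesh_dag()].
#' @param decay semantic contribution decay factor in (0, 1); default 0.5.
#' @return a `semantic_scores`: list with `disease`, `found`,
#'   `contribution` (named numeric over headings) and `dv`.
#' @export
semantic_contribution <- function(dag, decay = 0.5) {
  stopifnot(inherits(dag, "mesh_dag"))
  if (decay <= 0 || decay >= 1) stop("decay must be in (0, 1)")
  if (!dag$found) {
    return(structure(list(disease = dag$disease, found = FALSE,
                          contribution = numeric(0), dv = NA_real_),
                     class = "semantic_scores"))
  }
  trees <- dag$nodes$tree
  depth <- lengths(strsplit(trees, ".", fixed = TRUE))
  d_tree <- stats::setNames(rep(-Inf, length(trees)), trees)
  d_tree[dag$nodes$is_self] <- 1
  # bottom-up over strictly decreasing depth; prefixes guarantee acyclicity
  for (dep in sort(unique(depth), decreasing = TRUE)) {
    for (tr in trees[depth == dep]) {
      kids <- dag$edges$child[dag$edges$parent == tr]
      if (length(kids)) {
        d_tree[tr] <- max(d_tree[tr], decay * max(d_tree[kids]))
      }
    }
  }
  if (any(!is.finite(d_tree))) {
    stop("disconnected ancestor position in DAG of ", dag$disease)
  }
  contribution <- tapply(d_tree, dag$nodes$heading, max)
  contribution <- stats::setNames(as.numeric(contribution),
                                  names(contribution))
  structure(list(disease = dag$disease, found = TRUE,
                 contribution = contribution,
                 dv = sum(contribution)),
            class = "semantic_scores")
}

#' MeSH-based semantic similarity matrix over a disease set
#'
#' For each pair of diseases the similarity is the summed contribution of
#' their shared DAG headings divided by the sum of their semantic values:
#' `sum_t (D_i(t) + D_j(t)) / (DV_i + DV_j)` over headings `t` present in
#' both DAGs. Diseases absent from the vocabulary are flagged
#' (`has_dag` attribute) and get off-diagonal similarity 0; the diagonal
#' is always 1.
#'
#' @param mesh a `mesh_vocab`.
#' @param diseases character vector of disease identifiers (MeSH
#'   headings).
#' @param decay semantic contribution decay factor; default 0.5.
#' @return symmetric numeric matrix with `diseases` dimnames and a
#'   logical `has_dag` attribute.
#' @export
disease_semantic_similarity <- function(mesh, diseases, decay = 0.5) {
  scores <- lapply(diseases, function(d) {
    semantic_contribution(mesh_dag(mesh, d), decay)
  })
  has_dag <- vapply(scores, `[[`, logical(1), "found")
  if (any(!has_dag)) {
    warning(sum(!has_dag), " disease(s) absent from the MeSH ",
            "vocabulary: ", paste(diseases[!has_dag], collapse = ", "))
  }
  n <- length(diseases)
  sim <- diag(1, n)
  dimnames(sim) <- list(diseases, diseases)
  for (i in seq_len(n)) {
    if (!has_dag[i]) next
    for (j in seq_len(n)) {
      if (j <= i || !has_dag[j]) next
      ci <- scores[[i]]$contribution
      cj <- scores[[j]]$contribution
      shared <- intersect(names(ci), names(cj))
      val <- if (length(shared)) {
        sum(ci[shared] + cj[shared]) / (scores[[i]]$dv + scores[[j]]$dv)
      } else {
        0
      }
      sim[i, j] <- sim[j, i] <- val
    }
  }
  sim <- clip01(sim)
  attr(sim, "has_dag") <- stats::setNames(has_dag, diseases)
  sim
}
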