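#' Specification of a synthetic coupled-network fixture
#'
#' Describes three coupled binary bipartite networks whose triangles form
#' a tripartite tensor with planted block structure. Entities of each
#' kind are split into latent blocks; pairs inside a block get edges with
#' high probability, cross-block pairs with low probability, and the
#' observed edge lists are corrupted by false-negative (dropped edge) and
#' false-positive (spurious edge) noise. A MeSH-like descriptor groups
#' same-block diseases under shared ancestors so that semantic similarity
#' correlates with block identity.
#'
#' The defaults — 12 diseases x 10 lncRNAs x 15 miRNAs, 2 blocks,
#' within-block edge probability 0.8, cross-block 0.05, 5% false-negative
#' and 1% false-positive edge noise — give a nondegenerate but
#' seconds-scale dataset whose tensor is approximately multilinear
#' rank (2, 2, 2).
#'
#' @param n_diseases,n_lncrnas,n_mirnas entity counts per axis.
#' @param n_blocks number of planted blocks (per-axis multilinear rank).
#' @param p_within within-block edge probability.
#' @param p_between cross-block edge probability.
#' @param fn_rate probability a true edge is missing from the observed
#'   lists (false negative).
#' @param fp_rate probability a non-edge appears in the observed lists
#'   (false positive).
#' @param seed mandatory integer seed.
#' @return a `fixture_spec` list.
#' @export
fixture_spec <- function(n_diseases = 12L, n_lncrnas = 10L,
                         n_mirnas = 15L, n_blocks = 2L, p_within = 0.8,
                         p_between = 0.05, fn_rate = 0.05,
                         fp_rate = 0.01, seed) {
  if (missing(seed)) stop("seed is mandatory for fixture generation")
  counts <- c(n_diseases, n_lncrnas, n_mirnas)
  if (any(counts < n_blocks)) {
    stop("every axis needs at least as many entities as blocks")
  }
  probs <- c(p_within, p_between, fn_rate, fp_rate)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]")
  structure(list(n_diseases = as.integer(n_diseases),
                 n_lncrnas = as.integer(n_lncrnas),
                 n_mirnas = as.integer(n_mirnas),
                 n_blocks = as.integer(n_blocks),
                 p_within = p_within, p_between = p_between,
                 fn_rate = fn_rate, fp_rate = fp_rate,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

pad_ids <- function(prefix, n) {
  sprintf("%s_%0*d", prefix, nchar(as.character(n)), seq_len(n))
}

# contiguous block assignment: first ceil(n/b) entities in block 1, ...
block_of <- function(n, blocks) {
  sort(rep_len(seq_len(blocks), n))
}

sample_block_edges <- function(bl_row, bl_col, p_in, p_out) {
  p <- ifelse(outer(bl_row, bl_col, "=="), p_in, p_out)
  matrix(stats::rbinom(length(p), 1, p), nrow = length(bl_row))
}

apply_edge_noise <- function(adj, fn_rate, fp_rate) {
  flip_drop <- stats::rbinom(length(adj), 1, fn_rate) == 1
  flip_add <- stats::rbinom(length(adj), 1, fp_rate) == 1
  out <- adj
  out[adj == 1 & flip_drop] <- 0L
  out[adj == 0 & flip_add] <- 1L
  out
}

adj_to_pairs <- function(adj, row_ids, col_ids) {
  hit <- which(adj == 1, arr.ind = TRUE)
  data.frame(source = row_ids[hit[, 1]], target = col_ids[hit[, 2]],
             stringsAsFactors = FALSE)[order(hit[, 1], hit[, 2]), ,
                                       drop = FALSE]
}

triples_of <- function(a1, a2, a3, d_ids, l_ids, m_ids) {
  g1 <- structure(list(adjacency = a1, kinds = c("disease", "lncRNA")),
                  class = "bipartite_network")
  g2 <- structure(list(adjacency = a2, kinds = c("disease", "miRNA")),
                  class = "bipartite_network")
  g3 <- structure(list(adjacency = a3, kinds = c("lncRNA", "miRNA")),
                  class = "bipartite_network")
  build_tripartite(g1, g2, g3)$triples
}

#' Generate a synthetic coupled-network fixture
#'
#' Draws the planted block networks of a [fixture_spec()], applies the
#' edge noise, and returns (optionally writing to `dir`) the three
#' observed edge lists, a MeSH-like descriptor file for the diseases and
#' the ground-truth triple list. Ground-truth triples are the triangles
#' of the noise-free block networks; those lost to noise are flagged
#' `held_out` and serve as "future" associations for recovery tests.
#'
#' Written files: `disease_lncRNA.tsv`, `disease_miRNA.tsv`,
#' `lncRNA_miRNA.tsv`, `mesh.txt`, `ground_truth.tsv`.
#'
#' @param spec a [fixture_spec()].
#' @param dir optional output directory (created if needed).
#' @return list of class `fixture` with `edges` (list of three
#'   `edge_list`s), `mesh_lines` (descriptor text), `truth` (data.frame
#'   of ground-truth triples with `held_out` flag), `blocks` (per-axis
#'   block assignments), `spec`, and `paths` when `dir` was given.
#' @export
simulate_fixture <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  d_ids <- pad_ids("disease", spec$n_diseases)
  l_ids <- pad_ids("lnc", spec$n_lncrnas)
  m_ids <- pad_ids("mir", spec$n_mirnas)
  res <- with_seed(spec$seed, {
    bl_d <- block_of(spec$n_diseases, spec$n_blocks)
    bl_l <- block_of(spec$n_lncrnas, spec$n_blocks)
    bl_m <- block_of(spec$n_mirnas, spec$n_blocks)
    a1 <- sample_block_edges(bl_d, bl_l, spec$p_within, spec$p_between)
    a2 <- sample_block_edges(bl_d, bl_m, spec$p_within, spec$p_between)
    a3 <- sample_block_edges(bl_l, bl_m, spec$p_within, spec$p_between)
    o1 <- apply_edge_noise(a1, spec$fn_rate, spec$fp_rate)
    o2 <- apply_edge_noise(a2, spec$fn_rate, spec$fp_rate)
    o3 <- apply_edge_noise(a3, spec$fn_rate, spec$fp_rate)
    list(bl = list(disease = bl_d, lncRNA = bl_l, miRNA = bl_m),
         truth = list(a1, a2, a3), obs = list(o1, o2, o3))
  })
  dn <- list(list(d_ids, l_ids), list(d_ids, m_ids), list(l_ids, m_ids))
  for (i in 1:3) {
    dimnames(res$truth[[i]]) <- dn[[i]]
    dimnames(res$obs[[i]]) <- dn[[i]]
  }
  kinds <- list(c("disease", "lncRNA"), c("disease", "miRNA"),
                c("lncRNA", "miRNA"))
  edges <- lapply(1:3, function(i) {
    p <- adj_to_pairs(res$obs[[i]], dn[[i]][[1]], dn[[i]][[2]])
    as_edge_list(p, kinds[[i]])
  })
  names(edges) <- c("disease_lncRNA", "disease_miRNA", "lncRNA_miRNA")

  truth_tr <- triples_of(res$truth[[1]], res$truth[[2]], res$truth[[3]],
                         d_ids, l_ids, m_ids)
  obs_tr <- triples_of(res$obs[[1]], res$obs[[2]], res$obs[[3]],
                       d_ids, l_ids, m_ids)
  key <- function(df) paste(df$disease, df$lncRNA, df$miRNA, sep = "\r")
  truth_tr$held_out <- !(key(truth_tr) %in% key(obs_tr))

  mesh_lines <- fixture_mesh_lines(d_ids, res$bl$disease)

  out <- structure(list(edges = edges, mesh_lines = mesh_lines,
                        truth = truth_tr, blocks = res$bl, spec = spec),
                   class = "fixture")
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(
      disease_lncRNA = file.path(dir, "disease_lncRNA.tsv"),
      disease_miRNA = file.path(dir, "disease_miRNA.tsv"),
      lncRNA_miRNA = file.path(dir, "lncRNA_miRNA.tsv"),
      mesh = file.path(dir, "mesh.txt"),
      ground_truth = file.path(dir, "ground_truth.tsv")
    )
    for (nm in names(edges)) {
      utils::write.table(edges[[nm]], paths[[nm]], sep = "\t",
                         quote = FALSE, row.names = FALSE,
                         col.names = FALSE)
    }
    writeLines(mesh_lines, paths[["mesh"]])
    utils::write.table(truth_tr, paths[["ground_truth"]], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    out$paths <- paths
  }
  out
}

# MeSH-like descriptor: one family ancestor per block under a shared
# root, diseases as leaves of their block's family
fixture_mesh_lines <- function(d_ids, blocks) {
  rec <- function(mh, mn) c("*NEWRECORD", paste0("MH = ", mh),
                            paste0("MN = ", mn), "")
  lines <- rec("synthetic disease root", "C99")
  for (b in sort(unique(blocks))) {
    lines <- c(lines, rec(sprintf("synthetic family %d", b),
                          sprintf("C99.%03d", b * 100)))
  }
  for (i in seq_along(d_ids)) {
    lines <- c(lines, rec(d_ids[i],
                          sprintf("C99.%03d.%03d", blocks[i] * 100, i)))
  }
  lines
}

#' @export
print.fixture <- function(x, ...) {
  cat("Synthetic fixture (seed ", x$spec$seed, "): ",
      x$spec$n_diseases, " diseases x ", x$spec$n_lncrnas,
      " lncRNAs x ", x$spec$n_mirnas, " miRNAs, ",
      nrow(x$truth), " ground-truth triples (",
      sum(x$truth$held_out), " held out)\n", sep = "")
  invisible(x)
}

#' Planted nonnegative Tucker tensor
#'
#' Draws a random nonnegative core and factor matrices and returns their
#' multilinear product together with the generating model — the standard
#' fixture for decomposition-recovery tests.
#'
#' @param dims tensor dimensions `(n1, n2, n3)`.
#' @param ranks core dimensions `(R1, R2, R3)`.
#' @param seed integer seed.
#' @return list with `tensor`, `core`, `factors`.
#' @export
simulate_planted_tucker <- function(dims, ranks = c(2, 2, 2), seed) {
  if (missing(seed)) stop("seed is mandatory")
  with_seed(seed, {
    factors <- lapply(1:3, function(n) {
      matrix(stats::runif(dims[n] * ranks[n]), nrow = dims[n])
    })
    core <- array(stats::runif(prod(ranks)), dim = ranks)
    list(tensor = multilinear_product(core, factors[[1]], factors[[2]],
                                      factors[[3]]),
         core = core, factors = factors)
  })
}
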