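#' Read a tab-separated association edge list
#'
#' One association per line, at least two tab-separated fields (extra
#' fields are ignored); lines starting with `#` and blank lines are
#' skipped. Identifiers are whitespace-trimmed, case is preserved, and
#' exact duplicate pairs are dropped with a warning (keeping first file
#' order).
#'
#' @param path path to the TSV file.
#' @param kinds length-2 character vector naming the two entity kinds,
#'   each one of `"disease"`, `"lncRNA"`, `"miRNA"`; must be distinct.
#' @return an `edge_list`: a data.frame with columns `source`, `target`
#'   and attributes `kinds`.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("# demo", "BRCA\tMALAT1", "BRCA\tHOTAIR"), tf)
#' read_edge_list(tf, c("disease", "lncRNA"))
#' @export
read_edge_list <- function(path, kinds) {
  kinds <- check_kinds(kinds)
  if (!file.exists(path)) stop("edge list file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) stop("no associations found in ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, integer(1)) < 2L)
  if (length(bad)) {
    stop("malformed line ", lineno[bad[1]], " in ", path,
         " (need >= 2 tab-separated fields): ", lines[bad[1]])
  }
  src <- trimws(vapply(fields, `[[`, character(1), 1L))
  tgt <- trimws(vapply(fields, `[[`, character(1), 2L))
  if (any(src == "" | tgt == "")) {
    i <- which(src == "" | tgt == "")[1]
    stop("empty identifier on line ", lineno[i], " in ", path)
  }
  dup <- duplicated(paste(src, tgt, sep = "\r"))
  if (any(dup)) {
    warning(sum(dup), " duplicate association(s) dropped from ", path)
  }
  new_edge_list(src[!dup], tgt[!dup], kinds)
}

new_edge_list <- function(source, target, kinds) {
  structure(
    data.frame(source = source, target = target,
               stringsAsFactors = FALSE),
    kinds = kinds, class = c("edge_list", "data.frame")
  )
}

#' Build an edge list from in-memory pairs
#'
#' @param pairs two-column character matrix or data.frame of associations.
#' @inheritParams read_edge_list
#' @return an `edge_list`.
#' @export
as_edge_list <- function(pairs, kinds) {
  kinds <- check_kinds(kinds)
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  stopifnot(ncol(pairs) >= 2)
  src <- trimws(as.character(pairs[[1]]))
  tgt <- trimws(as.character(pairs[[2]]))
  dup <- duplicated(paste(src, tgt, sep = "\r"))
  new_edge_list(src[!dup], tgt[!dup], kinds)
}

check_kinds <- function(kinds) {
  valid <- c("disease", "lncRNA", "miRNA")
  if (length(kinds) != 2L || !all(kinds %in% valid) ||
      kinds[1] == kinds[2]) {
    stop("kinds must be two distinct values among ",
         paste(valid, collapse = ", "))
  }
  kinds
}

#' Edge-list kinds accessor
#' @param x an `edge_list`.
#' @return length-2 character vector of entity kinds.
#' @export
entity_kinds <- function(x) attr(x, "kinds")

# index-map helper: ids in first-appearance order, lexicographic tie-break
# is vacuous for a scan but is applied when merging two id vectors below
index_ids <- function(ids) unique(ids)

#' Build a bipartite association network from an edge list
#'
#' Rows of the adjacency matrix index the edge list's source kind,
#' columns its target kind, both in order of first appearance.
#'
#' @param edges an `edge_list`.
#' @return a `bipartite_network`: a list with `adjacency` (binary matrix
#'   with identifier dimnames) and `kinds`.
#' @export
build_bipartite <- function(edges) {
  stopifnot(inherits(edges, "edge_list"))
  left <- index_ids(edges$source)
  right <- index_ids(edges$target)
  adj <- matrix(0L, nrow = length(left), ncol = length(right),
                dimnames = list(left, right))
  if (nrow(edges)) {
    adj[cbind(match(edges$source, left), match(edges$target, right))] <- 1L
  }
  structure(list(adjacency = adj, kinds = entity_kinds(edges)),
            class = "bipartite_network")
}

#' @export
print.bipartite_network <- function(x, ...) {
  cat("Bipartite network ", x$kinds[1], " x ", x$kinds[2], ": ",
      nrow(x$adjacency), " x ", ncol(x$adjacency), " nodes, ",
      sum(x$adjacency), " edges\n", sep = "")
  invisible(x)
}

# orient a bipartite network so rows carry `row_kind`
orient_bipartite <- function(net, row_kind) {
  stopifnot(inherits(net, "bipartite_network"))
  if (net$kinds[1] == row_kind) {
    net
  } else if (net$kinds[2] == row_kind) {
    structure(list(adjacency = t(net$adjacency),
                   kinds = rev(net$kinds)),
              class = "bipartite_network")
  } else {
    stop("network has kinds ", paste(net$kinds, collapse = "/"),
         ", not ", row_kind)
  }
}

#' Close three bipartite networks into a tripartite association network
#'
#' A triple (disease, lncRNA, miRNA) is retained iff its three projected
#' pairs are edges of the disease-lncRNA, disease-miRNA and lncRNA-miRNA
#' networks respectively (a triangle across the three networks). Entities
#' participating in no triangle are dropped from the index maps. The
#' enumeration is exhaustive and order-independent, so the result does not
#' depend on input edge order.
#'
#' @param g1 disease-lncRNA `bipartite_network` (either orientation).
#' @param g2 disease-miRNA `bipartite_network`.
#' @param g3 lncRNA-miRNA `bipartite_network`.
#' @return a `tripartite_network`: list with `triples` (data.frame of
#'   `disease`, `lncRNA`, `miRNA` identifiers), `diseases`, `lncRNAs`,
#'   `miRNAs` (retained ids, first-appearance order of the input
#'   networks).
#' @export
build_tripartite <- function(g1, g2, g3) {
  g1 <- orient_bipartite(g1, "disease")
  g2 <- orient_bipartite(g2, "disease")
  g3 <- orient_bipartite(g3, "lncRNA")
  if (g1$kinds[2] != "lncRNA") stop("g1 must join disease and lncRNA")
  if (g2$kinds[2] != "miRNA") stop("g2 must join disease and miRNA")
  if (g3$kinds[2] != "miRNA") stop("g3 must join lncRNA and miRNA")

  diseases <- union(rownames(g1$adjacency), rownames(g2$adjacency))
  lncrnas <- union(colnames(g1$adjacency), rownames(g3$adjacency))
  mirnas <- union(colnames(g2$adjacency), colnames(g3$adjacency))

  out <- vector("list", length(diseases))
  for (di in seq_along(diseases)) {
    d <- diseases[di]
    ls_d <- if (d %in% rownames(g1$adjacency)) {
      colnames(g1$adjacency)[g1$adjacency[d, ] == 1]
    } else character(0)
    ms_d <- if (d %in% rownames(g2$adjacency)) {
      colnames(g2$adjacency)[g2$adjacency[d, ] == 1]
    } else character(0)
    ls_d <- intersect(ls_d, rownames(g3$adjacency))
    ms_d <- intersect(ms_d, colnames(g3$adjacency))
    if (!length(ls_d) || !length(ms_d)) next
    sub <- g3$adjacency[ls_d, ms_d, drop = FALSE]
    hit <- which(sub == 1, arr.ind = TRUE)
    if (nrow(hit)) {
      out[[di]] <- data.frame(disease = d,
                              lncRNA = ls_d[hit[, 1]],
                              miRNA = ms_d[hit[, 2]],
                              stringsAsFactors = FALSE)
    }
  }
  triples <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(triples)) {
    triples <- data.frame(disease = character(0), lncRNA = character(0),
                          miRNA = character(0), stringsAsFactors = FALSE)
  }
  keep_d <- diseases[diseases %in% triples$disease]
  keep_l <- lncrnas[lncrnas %in% triples$lncRNA]
  keep_m <- mirnas[mirnas %in% triples$miRNA]
  # deterministic triple order: disease, lncRNA, miRNA index order
  o <- order(match(triples$disease, keep_d), match(triples$lncRNA, keep_l),
             match(triples$miRNA, keep_m))
  triples <- triples[o, , drop = FALSE]
  rownames(triples) <- NULL
  structure(list(triples = triples, diseases = keep_d, lncRNAs = keep_l,
                 miRNAs = keep_m),
            class = "tripartite_network")
}

#' @export
print.tripartite_network <- function(x, ...) {
  cat("Tripartite disease-lncRNA-miRNA network\n")
  cat("  diseases: ", length(x$diseases), ", lncRNAs: ", length(x$lncRNAs),
      ", miRNAs: ", length(x$miRNAs), "\n", sep = "")
  cat("  associations (triangles): ", nrow(x$triples), "\n", sep = "")
  invisible(x)
}

#' Materialize the binary association tensor of a tripartite network
#'
#' `T[i, j, k] = 1` iff the (disease i, lncRNA j, miRNA k) triple is a
#' triangle of the tripartite network; all other entries 0.
#'
#' @param net a `tripartite_network`.
#' @return a binary 3-way array with identifier dimnames
#'   (disease x lncRNA x miRNA).
#' @export
build_tensor <- function(net) {
  stopifnot(inherits(net, "tripartite_network"))
  tens <- array(0, dim = c(length(net$diseases), length(net$lncRNAs),
                           length(net$miRNAs)),
                dimnames = list(net$diseases, net$lncRNAs, net$miRNAs))
  if (nrow(net$triples)) {
    tens[cbind(match(net$triples$disease, net$diseases),
               match(net$triples$lncRNA, net$lncRNAs),
               match(net$triples$miRNA, net$miRNAs))] <- 1
  }
  tens
}

#' Export a (possibly real-valued) association tensor as a sparse TSV
#'
#' Writes one line per nonzero entry: disease, lncRNA, miRNA, value.
#'
#' @param tens a 3-way array with dimnames.
#' @param path output file.
#' @param digits significant digits for the value column.
#' @return the path, invisibly.
#' @export
write_tensor_tsv <- function(tens, path, digits = 10) {
  nz <- which(tens != 0, arr.ind = TRUE)
  df <- data.frame(
    disease = dimnames(tens)[[1]][nz[, 1]],
    lncRNA = dimnames(tens)[[2]][nz[, 2]],
    miRNA = dimnames(tens)[[3]][nz[, 3]],
    value = signif(tens[nz], digits),
    stringsAsFactors = FALSE
  )
  df <- df[order(match(df$disease, dimnames(tens)[[1]]),
                 match(df$lncRNA, dimnames(tens)[[2]]),
                 match(df$miRNA, dimnames(tens)[[3]])), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Project bipartite adjacency matrices from a tensor's support
#'
#' Returns the disease x lncRNA, disease x miRNA and lncRNA x miRNA
#' binary matrices whose entries are 1 iff the pair occurs in at least one
#' nonzero triple. Used to derive leakage-free interaction profiles from a
#' training tensor inside cross-validation.
#'
#' @param tens a 3-way array (entries are tested against 0).
#' @return list with `y1` (disease x lncRNA), `y2` (disease x miRNA),
#'   `y3` (lncRNA x miRNA).
#' @export
project_bipartite <- function(tens) {
  pos <- tens > 0
  list(
    y1 = 1 * (apply(pos, c(1, 2), any)),
    y2 = 1 * (apply(pos, c(1, 3), any)),
    y3 = 1 * (apply(pos, c(2, 3), any))
  )
}
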