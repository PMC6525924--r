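# Independent brute-force oracles used across the suite. These are kept
# deliberately naive (explicit loops, no shared code with the package
# internals) so they can serve as ground truth on small instances.

# mode-n product by triple loop
loop_nmode <- function(x, m, mode) {
  d <- dim(x)
  dn <- d
  dn[mode] <- nrow(m)
  out <- array(0, dn)
  for (i in seq_len(dn[1])) for (j in seq_len(dn[2])) {
    for (k in seq_len(dn[3])) {
      acc <- 0
      for (s in seq_len(d[mode])) {
        idx <- c(i, j, k)
        idx[mode] <- s
        acc <- acc + m[c(i, j, k)[mode], s] * x[idx[1], idx[2], idx[3]]
      }
      out[i, j, k] <- acc
    }
  }
  out
}

# full Tucker reconstruction by quadruple loop
loop_reconstruct <- function(g, z1, z2, z3) {
  n <- c(nrow(z1), nrow(z2), nrow(z3))
  r <- dim(g)
  out <- array(0, n)
  for (i in seq_len(n[1])) for (j in seq_len(n[2])) {
    for (k in seq_len(n[3])) {
      acc <- 0
      for (a in seq_len(r[1])) for (b in seq_len(r[2])) {
        for (cc in seq_len(r[3])) {
          acc <- acc + z1[i, a] * z2[j, b] * z3[k, cc] * g[a, b, cc]
        }
      }
      out[i, j, k] <- acc
    }
  }
  out
}

# GIP kernel by double loop
loop_gip <- function(profiles) {
  n <- nrow(profiles)
  gamma <- n / sum(profiles^2)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    out[i, j] <- exp(-gamma * sum((profiles[i, ] - profiles[j, ])^2))
  }
  out
}

# WKNNP axis estimate by explicit sort + slice loop
loop_axis_knn <- function(tens, sim, axis, k, alpha) {
  n <- dim(tens)[axis]
  out <- array(0, dim(tens))
  slice <- function(t, axis, i) {
    switch(axis, t[i, , ], t[, i, ], t[, , i])
  }
  assign_slice <- function(t, axis, i, v) {
    if (axis == 1) t[i, , ] <- v else if (axis == 2) t[, i, ] <- v else
      t[, , i] <- v
    t
  }
  known <- vapply(seq_len(n), function(i) sum(slice(tens, axis, i)) > 0,
                  logical(1))
  for (i in seq_len(n)) {
    cand <- setdiff(which(known), i)
    s <- sim[i, cand]
    cand <- cand[s > 0]
    s <- s[s > 0]
    if (!length(cand)) next
    o <- order(-s, cand)
    take <- seq_len(min(k, length(cand)))
    est <- array(0, dim(tens)[-axis])
    q <- 0
    for (t in take) {
      w <- alpha^(t - 1) * s[o[t]]
      est <- est + w * slice(tens, axis, cand[o[t]])
      q <- q + s[o[t]]
    }
    out <- assign_slice(out, axis, i, est / q)
  }
  out
}

# AUC by concordant-pair count
loop_auc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  acc <- 0
  for (p in pos) for (q in neg) {
    acc <- acc + (p > q) + 0.5 * (p == q)
  }
  acc / (length(pos) * length(neg))
}

# semantic contribution by exhaustive downward path enumeration over the
# tree-number prefix DAG: D(node) = max over paths to a self position of
# decay^path_length, merged per heading by max
path_semantic <- function(dag, decay) {
  trees <- dag$nodes$tree
  selfs <- trees[dag$nodes$is_self]
  children_of <- function(tr) dag$edges$child[dag$edges$parent == tr]
  best <- function(tr) {
    if (tr %in% selfs) return(1)
    kids <- children_of(tr)
    if (!length(kids)) return(-Inf)
    max(vapply(kids, function(kd) decay * best(kd), numeric(1)))
  }
  d_tree <- vapply(trees, best, numeric(1))
  contribution <- tapply(d_tree, dag$nodes$heading, max)
  list(contribution = stats::setNames(as.numeric(contribution),
                                      names(contribution)),
       dv = sum(contribution))
}

# random tree-number vocabulary for semantic-score property tests
random_mesh <- function(seed, n_terms = 8) {
  withr::local_seed(seed)
  lines <- character(0)
  rec <- function(mh, mns) c("*NEWRECORD", paste0("MH = ", mh),
                             paste0("MN = ", mns), "")
  trees <- c("C01", "C02")
  for (i in seq_len(n_terms)) {
    parent <- sample(trees, 1)
    trees <- c(trees, paste0(parent, ".", sprintf("%03d", i)))
  }
  headings <- paste0("term_", seq_along(trees))
  # a few headings get two tree positions (poly-hierarchy)
  for (i in seq_along(trees)) {
    mns <- trees[i]
    if (i > 4 && stats::runif(1) < 0.3) {
      mns <- c(mns, paste0(sample(trees[seq_len(4)], 1), ".",
                           sprintf("9%02d", i)))
    }
    lines <- c(lines, rec(headings[i], mns))
  }
  tf <- tempfile(fileext = ".txt")
  writeLines(lines, tf)
  tf
}

write_edge_file <- function(lines) {
  tf <- tempfile(fileext = ".tsv")
  writeLines(lines, tf)
  tf
}

# tiny three-network system with a known triangle structure
toy_networks <- function() {
  g1 <- build_bipartite(as_edge_list(
    rbind(c("d1", "l1"), c("d1", "l2"), c("d2", "l1"), c("d3", "l2")),
    c("disease", "lncRNA")))
  g2 <- build_bipartite(as_edge_list(
    rbind(c("d1", "m1"), c("d1", "m2"), c("d2", "m1"), c("d3", "m3")),
    c("disease", "miRNA")))
  g3 <- build_bipartite(as_edge_list(
    rbind(c("l1", "m1"), c("l2", "m2"), c("l2", "m3")),
    c("lncRNA", "miRNA")))
  list(g1 = g1, g2 = g2, g3 = g3)
}

default_fixture_data <- function(seed = 11) {
  fx <- simulate_fixture(fixture_spec(seed = seed))
  tf <- tempfile(fileext = ".txt")
  writeLines(fx$mesh_lines, tf)
  data <- assemble_dataset(
    build_bipartite(fx$edges$disease_lncRNA),
    build_bipartite(fx$edges$disease_miRNA),
    build_bipartite(fx$edges$lncRNA_miRNA),
    mesh = read_mesh(tf)
  )
  list(fixture = fx, data = data)
}
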