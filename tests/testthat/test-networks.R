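test_that("edge lists load with dedup, trimming and comment handling", {
  tf <- write_edge_file(c("# comment", "BRCA\tMALAT1", "BRCA\tMALAT1",
                          " BRCA \tHOTAIR\textra-col", ""))
  expect_warning(el <- read_edge_list(tf, c("disease", "lncRNA")),
                 "duplicate")
  expect_equal(nrow(el), 2)
  expect_equal(el$source, c("BRCA", "BRCA"))
  expect_equal(el$target, c("MALAT1", "HOTAIR"))
  expect_equal(entity_kinds(el), c("disease", "lncRNA"))

  tf3 <- write_edge_file(c("a\tb", "c\td", "e\tf"))
  expect_equal(nrow(read_edge_list(tf3, c("disease", "miRNA"))), 3)
})

test_that("malformed edge lists are rejected with the offending line", {
  tf <- write_edge_file(c("ok\tpair", "single-field"))
  expect_error(read_edge_list(tf, c("disease", "lncRNA")), "line 2")
  expect_error(read_edge_list(tempfile(), c("disease", "lncRNA")),
               "not found")
  expect_error(read_edge_list(write_edge_file("# only comments"),
                              c("disease", "lncRNA")), "no associations")
  expect_error(read_edge_list(write_edge_file("a\tb"),
                              c("disease", "disease")), "distinct")
})

test_that("bipartite adjacency reflects pairs with stable indexing", {
  el <- as_edge_list(rbind(c("d1", "l1"), c("d1", "l2")),
                     c("disease", "lncRNA"))
  net <- build_bipartite(el)
  expect_equal(unname(net$adjacency), rbind(c(1L, 1L)))
  expect_equal(rownames(net$adjacency), "d1")
  expect_equal(colnames(net$adjacency), c("l1", "l2"))

  el2 <- as_edge_list(rbind(c("d1", "l1"), c("d2", "l1")),
                      c("disease", "lncRNA"))
  expect_equal(unname(colSums(build_bipartite(el2)$adjacency)), 2)

  empty <- build_bipartite(as_edge_list(
    data.frame(a = character(0), b = character(0)),
    c("disease", "lncRNA")))
  expect_equal(dim(empty$adjacency), c(0L, 0L))
})

test_that("tripartite closure keeps exactly the cross-network triangles", {
  nets <- toy_networks()
  tri <- build_tripartite(nets$g1, nets$g2, nets$g3)
  expect_equal(nrow(tri$triples), 4)
  expect_setequal(paste(tri$triples$disease, tri$triples$lncRNA,
                        tri$triples$miRNA),
                  c("d1 l1 m1", "d1 l2 m2", "d2 l1 m1", "d3 l2 m3"))
  # every retained entity appears in at least one triangle
  expect_setequal(tri$diseases, unique(tri$triples$disease))
  expect_setequal(tri$lncRNAs, unique(tri$triples$lncRNA))
  expect_setequal(tri$miRNAs, unique(tri$triples$miRNA))
})

test_that("diseases without a completing triangle are dropped", {
  g1 <- build_bipartite(as_edge_list(rbind(c("d1", "l1"), c("d2", "l1")),
                                     c("disease", "lncRNA")))
  g2 <- build_bipartite(as_edge_list(rbind(c("d1", "m1")),
                                     c("disease", "miRNA")))
  g3 <- build_bipartite(as_edge_list(rbind(c("l1", "m1")),
                                     c("lncRNA", "miRNA")))
  tri <- build_tripartite(g1, g2, g3)
  expect_equal(tri$diseases, "d1")
  expect_equal(nrow(tri$triples), 1)
})

test_that("triangle enumeration matches a triple nested loop on random systems", {
  for (seed in 1:6) {
    withr::local_seed(seed)
    nd <- sample(3:8, 1); nl <- sample(3:8, 1); nm <- sample(3:8, 1)
    a1 <- matrix(rbinom(nd * nl, 1, 0.4), nd, nl,
                 dimnames = list(paste0("d", 1:nd), paste0("l", 1:nl)))
    a2 <- matrix(rbinom(nd * nm, 1, 0.4), nd, nm,
                 dimnames = list(paste0("d", 1:nd), paste0("m", 1:nm)))
    a3 <- matrix(rbinom(nl * nm, 1, 0.4), nl, nm,
                 dimnames = list(paste0("l", 1:nl), paste0("m", 1:nm)))
    gg <- function(adj, kinds) structure(
      list(adjacency = adj, kinds = kinds), class = "bipartite_network")
    tri <- build_tripartite(gg(a1, c("disease", "lncRNA")),
                            gg(a2, c("disease", "miRNA")),
                            gg(a3, c("lncRNA", "miRNA")))
    brute <- character(0)
    for (i in 1:nd) for (j in 1:nl) for (k in 1:nm) {
      if (a1[i, j] == 1 && a2[i, k] == 1 && a3[j, k] == 1) {
        brute <- c(brute, paste0("d", i, "|l", j, "|m", k))
      }
    }
    expect_setequal(paste(tri$triples$disease, tri$triples$lncRNA,
                          tri$triples$miRNA, sep = "|"), brute)
    # soundness recheck: each stored triple projects onto edges
    for (r in seq_len(nrow(tri$triples))) {
      expect_equal(a1[tri$triples$disease[r], tri$triples$lncRNA[r]], 1)
      expect_equal(a2[tri$triples$disease[r], tri$triples$miRNA[r]], 1)
      expect_equal(a3[tri$triples$lncRNA[r], tri$triples$miRNA[r]], 1)
    }
  }
})

test_that("tensor entries mirror the triple set exactly", {
  nets <- toy_networks()
  tri <- build_tripartite(nets$g1, nets$g2, nets$g3)
  tens <- build_tensor(tri)
  expect_equal(sum(tens), nrow(tri$triples))
  expect_true(all(tens %in% c(0, 1)))
  expect_equal(tens["d1", "l1", "m1"], 1)
  expect_equal(tens["d2", "l2", "m2"], 0)

  # 1-triple degenerate case
  g1 <- build_bipartite(as_edge_list(rbind(c("d", "l")),
                                     c("disease", "lncRNA")))
  g2 <- build_bipartite(as_edge_list(rbind(c("d", "m")),
                                     c("disease", "miRNA")))
  g3 <- build_bipartite(as_edge_list(rbind(c("l", "m")),
                                     c("lncRNA", "miRNA")))
  expect_equal(unname(build_tensor(build_tripartite(g1, g2, g3))),
               array(1, c(1, 1, 1)))
})

test_that("index maps are deterministic across repeated loads", {
  tf1 <- write_edge_file(c("d2\tl1", "d1\tl2", "d1\tl1"))
  a <- build_bipartite(read_edge_list(tf1, c("disease", "lncRNA")))
  b <- build_bipartite(read_edge_list(tf1, c("disease", "lncRNA")))
  expect_identical(dimnames(a$adjacency), dimnames(b$adjacency))
  expect_equal(rownames(a$adjacency), c("d2", "d1"))  # first appearance
})

test_that("sparse tensor export round-trips the nonzero entries", {
  nets <- toy_networks()
  tens <- build_tensor(build_tripartite(nets$g1, nets$g2, nets$g3))
  tf <- tempfile(fileext = ".tsv")
  write_tensor_tsv(tens, tf)
  df <- read.delim(tf)
  expect_equal(nrow(df), sum(tens != 0))
  expect_equal(sum(df$value), sum(tens))
})

test_that("bipartite projection recovers pair support from the tensor", {
  nets <- toy_networks()
  tens <- build_tensor(build_tripartite(nets$g1, nets$g2, nets$g3))
  proj <- project_bipartite(tens)
  expect_equal(proj$y1["d1", "l1"], 1)
  expect_equal(sum(proj$y1), length(unique(paste(
    which(tens == 1, arr.ind = TRUE)[, 1],
    which(tens == 1, arr.ind = TRUE)[, 2]))))
})
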