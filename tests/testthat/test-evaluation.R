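# a deliberately small coupled system keeps the refit-per-fold schemes fast
small_fixture_data <- function(seed = 21) {
  fx <- simulate_fixture(fixture_spec(n_diseases = 6, n_lncrnas = 5,
                                      n_mirnas = 6, seed = seed))
  tf <- tempfile(fileext = ".txt")
  writeLines(fx$mesh_lines, tf)
  data <- assemble_dataset(
    build_bipartite(fx$edges$disease_lncRNA),
    build_bipartite(fx$edges$disease_miRNA),
    build_bipartite(fx$edges$lncRNA_miRNA),
    mesh = read_mesh(tf))
  list(fixture = fx, data = data)
}

fast_cfg <- function(scheme, ...) {
  cv_config(scheme, max_iter = 60L, epsilon = 1e-3, ...)
}

test_that("auc reproduces the hand-checked and degenerate cases", {
  expect_equal(auc_score(c(1, 0, 1, 0), c(0.9, 0.8, 0.7, 0.1)), 0.75)
  expect_equal(auc_score(c(1, 1, 0, 0), c(9, 8, 2, 1)), 1)
  expect_equal(auc_score(c(1, 0, 1, 0), rep(0.5, 4)), 0.5)
  expect_error(auc_score(c(1, 1), c(0.2, 0.3)), "positive and one neg")
})

test_that("auc agrees with the brute-force concordance count and pROC", {
  for (seed in 1:8) {
    withr::local_seed(seed)
    n <- sample(20:200, 1)
    labels <- rbinom(n, 1, 0.3)
    if (sum(labels) == 0) labels[1] <- 1
    if (sum(labels) == n) labels[1] <- 0
    scores <- round(runif(n), 2)   # induces ties
    got <- auc_score(labels, scores)
    expect_equal(got, loop_auc(labels, scores), tolerance = 1e-12)
    expect_equal(got,
                 as.numeric(pROC::auc(pROC::roc(labels, scores,
                                                quiet = TRUE,
                                                direction = "<"))),
                 tolerance = 1e-12)
    rc <- roc_curve(labels, scores)
    expect_equal(attr(rc, "auc"), got, tolerance = 1e-12)
    expect_true(all(diff(rc$fpr) >= 0) && all(diff(rc$tpr) >= 0))
  }
})

test_that("ranked pairs are sorted, contiguous and exclude training positives", {
  withr::local_seed(5)
  tstar <- array(runif(24), c(2, 3, 4),
                 dimnames = list(c("dA", "dB"), paste0("l", 1:3),
                                 paste0("m", 1:4)))
  train <- array(0, dim(tstar), dimnames = dimnames(tstar))
  train["dA", "l1", "m1"] <- 1
  rk <- rank_pairs(tstar, train, "dA")
  expect_equal(rk$rank, seq_len(nrow(rk)))
  expect_true(all(diff(rk$score) <= 0))
  expect_false(any(rk$lncRNA == "l1" & rk$miRNA == "m1"))
  rk_all <- rank_pairs(tstar, train, "dA", exclude_known = FALSE)
  expect_equal(nrow(rk_all), 12)
  expect_true(any(rk_all$known))
})

test_that("recall@k counts held-out positives and is nondecreasing in k", {
  rankings <- data.frame(disease = "d", lncRNA = paste0("l", 1:4),
                         miRNA = paste0("m", 1:4), score = c(4, 3, 2, 1),
                         rank = 1:4, known = FALSE)
  pos <- data.frame(disease = "d", lncRNA = c("l1", "l3"),
                    miRNA = c("m1", "m3"))
  rc <- recall_at_k(rankings, pos, k_grid = c(1, 2, 3, 10))
  expect_equal(rc$recall, c(0.5, 0.5, 1, 1))
  expect_true(all(diff(rc$recall) >= 0))
  # positives missing from the table are never recalled
  pos2 <- data.frame(disease = "d", lncRNA = "lX", miRNA = "mX")
  expect_equal(recall_at_k(rankings, pos2, 1:3)$recall, c(0, 0, 0))
})

test_that("masking a triple changes its own smoothed value (no leakage)", {
  fd <- small_fixture_data()
  tens <- fd$data$tensor
  pos <- which(tens == 1, arr.ind = TRUE)
  p <- pos[1, , drop = FALSE]
  sims <- compute_similarities(fd$data)
  full <- wknnp_smooth(tens, sims)$fused[p]
  train <- tens
  train[p] <- 0
  sims_m <- compute_similarities(fd$data, from_tensor = TRUE,
                                 tensor = train)
  masked <- wknnp_smooth(train, sims_m)$fused[p]
  expect_equal(full, 1)
  expect_lt(masked, 1)
})

test_that("global LOOCV recovers planted structure and beats a label-free null", {
  fd <- small_fixture_data()
  res <- global_loocv(fd$data, fast_cfg("global-loocv"))
  expect_gt(res$auc, 0.8)
  expect_equal(res$n_positives, sum(fd$data$tensor))
  # same pipeline scored with a seeded random tensor carries no signal
  tens <- fd$data$tensor
  labels <- as.integer(tens == 1)
  withr::local_seed(99)
  null_auc <- mean(vapply(1:10, function(i) {
    auc_score(labels, runif(length(labels)))
  }, numeric(1)))
  expect_lt(abs(null_auc - 0.5), 0.05)
  expect_gt(res$auc, null_auc)
})

test_that("local LOOCV reports per-disease AUCs over the same folds", {
  fd <- small_fixture_data()
  res <- local_loocv(fd$data, fast_cfg("local-loocv"))
  expect_true(all(res$per_disease >= 0 & res$per_disease <= 1))
  expect_equal(res$auc, mean(res$per_disease))
  expect_gt(res$auc, 0.6)
})

test_that("k-fold CV is reproducible and averages fold AUCs", {
  fd <- small_fixture_data()
  cfg <- fast_cfg("kfold", folds = 2, repeats = 2, seed = 7)
  a <- kfold_cv(fd$data, cfg)
  b <- kfold_cv(fd$data, cfg)
  expect_identical(a$fold_auc, b$fold_auc)
  expect_equal(a$mean, mean(rowMeans(a$fold_auc)))
  expect_equal(dim(a$fold_auc), c(2L, 2L))
  expect_false(is.na(a$sd))
  expect_gt(a$mean, 0.7)
})

test_that("parameter sweep returns one AUC per grid point in input order", {
  fd <- small_fixture_data()
  cfg <- fast_cfg("kfold", folds = 2, repeats = 1, seed = 3)
  tab <- parameter_sweep(fd$data, k_values = c(1, 3),
                         alpha_values = 0.5, config = cfg)
  expect_equal(tab$k, c(1, 3))
  expect_equal(tab$alpha, c(0.5, 0.5))
  expect_true(all(tab$auc >= 0 & tab$auc <= 1))
  # a single-point grid equals the direct call
  cfg1 <- cfg
  cfg1$wknnp <- wknnp_config(3, 0.5)
  expect_equal(tab$auc[2], kfold_cv(fd$data, cfg1)$mean)
})
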