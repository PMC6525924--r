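test_that("unfold/refold are inverse and satisfy the Kronecker identity", {
  ones <- array(1, c(2, 2, 2))
  expect_equal(unfold(ones, 1), matrix(1, 2, 4))
  for (seed in 1:5) {
    withr::local_seed(seed)
    x <- array(runif(60), c(3, 4, 5))
    for (mode in 1:3) {
      expect_identical(refold(unfold(x, mode), mode, dim(x)), x)
    }
    g <- array(runif(8), c(2, 2, 2))
    z1 <- matrix(runif(6), 3, 2)
    z2 <- matrix(runif(8), 4, 2)
    z3 <- matrix(runif(10), 5, 2)
    t1 <- multilinear_product(g, z1, z2, z3)
    expect_equal(unfold(t1, 1),
                 z1 %*% unfold(g, 1) %*% t(kronecker(z2, z3)),
                 tolerance = 1e-10)
    expect_equal(unfold(t1, 2),
                 z2 %*% unfold(g, 2) %*% t(kronecker(z1, z3)),
                 tolerance = 1e-10)
    expect_equal(unfold(t1, 3),
                 z3 %*% unfold(g, 3) %*% t(kronecker(z1, z2)),
                 tolerance = 1e-10)
    # column-major vectorization identity used by the core update
    expect_equal(as.vector(t1),
                 as.vector(kronecker(z3, kronecker(z2, z1)) %*%
                             as.vector(g)),
                 tolerance = 1e-10)
  }
})

test_that("mode products respect identity and annihilation and match the loop oracle", {
  withr::local_seed(2)
  x <- array(runif(27), c(3, 3, 3))
  expect_equal(nmode_product(x, diag(3), 2), x)
  expect_equal(nmode_product(x, matrix(0, 2, 3), 1),
               array(0, c(2, 3, 3)))
  for (seed in 1:5) {
    withr::local_seed(seed)
    x <- array(runif(27), c(3, 3, 3))
    for (mode in 1:3) {
      m <- matrix(runif(12), 4, 3)
      expect_equal(nmode_product(x, m, mode), loop_nmode(x, m, mode),
                   tolerance = 1e-12)
    }
  }
  expect_error(nmode_product(x, matrix(0, 2, 4), 1), "does not match")
})

test_that("reconstruction equals the quadruple-loop oracle", {
  for (seed in 1:5) {
    withr::local_seed(seed)
    g <- array(runif(8), c(2, 2, 2))
    z <- lapply(c(4, 3, 5), function(n) matrix(runif(n * 2), n, 2))
    model <- structure(list(core = g, factors = z, ranks = c(2, 2, 2)),
                       class = "tucker_model")
    expect_equal(tucker_reconstruct(model),
                 loop_reconstruct(g, z[[1]], z[[2]], z[[3]]),
                 tolerance = 1e-12)
  }
  zero_core <- structure(
    list(core = array(0, c(2, 2, 2)),
         factors = lapply(c(3, 3, 3), function(n) matrix(1, n, 2)),
         ranks = c(2, 2, 2)), class = "tucker_model")
  expect_equal(tucker_reconstruct(zero_core), array(0, c(3, 3, 3)))
})

test_that("an exactly factorized model is a fixed point of both updates", {
  withr::local_seed(4)
  g <- array(runif(8, 0.2, 1), c(2, 2, 2))
  z <- lapply(c(4, 3, 5), function(n) matrix(runif(n * 2, 0.2, 1), n, 2))
  z[[1]][2, 1] <- 0   # a zero factor entry must stay zero
  model <- structure(list(core = g, factors = z, ranks = c(2, 2, 2)),
                     class = "tucker_model")
  tens <- tucker_reconstruct(model)
  for (mode in 1:3) {
    upd <- update_factor(tens, model, mode)
    expect_equal(upd$factors[[mode]], model$factors[[mode]],
                 tolerance = 1e-8)
  }
  expect_equal(update_factor(tens, model, 1)$factors[[1]][2, 1], 0)
  updc <- update_core(tens, model)
  expect_equal(updc$core, model$core, tolerance = 1e-8)

  model$core[1, 2, 1] <- 0
  tens2 <- tucker_reconstruct(model)
  expect_equal(update_core(tens2, model)$core[1, 2, 1], 0)
})

test_that("a factor update does not increase the mode-1 factorization residual", {
  for (seed in 1:6) {
    withr::local_seed(seed)
    tens <- array(runif(64), c(4, 4, 4))
    g <- array(runif(27, 0.1, 1), c(3, 3, 3))
    z <- lapply(1:3, function(i) matrix(runif(12, 0.1, 1), 4, 3))
    model <- structure(list(core = g, factors = z, ranks = c(3, 3, 3)),
                       class = "tucker_model")
    s1 <- unfold(g, 1) %*% t(kronecker(z[[2]], z[[3]]))
    before <- sum((unfold(tens, 1) - z[[1]] %*% s1)^2)
    upd <- update_factor(tens, model, 1)
    after <- sum((unfold(tens, 1) - upd$factors[[1]] %*% s1)^2)
    expect_lte(after, before + 1e-10)
    expect_true(all(upd$factors[[1]] >= 0))
  }
})

test_that("the core update matches the vectorized Kronecker NMF form", {
  for (seed in 1:5) {
    withr::local_seed(seed)
    tens <- array(runif(8), c(2, 2, 2))
    g <- array(runif(8, 0.1, 1), c(2, 2, 2))
    z <- lapply(1:3, function(i) matrix(runif(4, 0.1, 1), 2, 2))
    model <- structure(list(core = g, factors = z, ranks = c(2, 2, 2)),
                       class = "tucker_model")
    q <- kronecker(z[[3]], kronecker(z[[2]], z[[1]]))
    want <- as.vector(g) * (t(q) %*% as.vector(tens)) /
      (t(q) %*% q %*% as.vector(g) + 1e-12)
    got <- update_core(tens, model)$core
    expect_equal(as.vector(got), as.vector(want), tolerance = 1e-10)
  }
})

test_that("decomposition fits an overparameterized random tensor tightly", {
  withr::local_seed(7)
  tens <- array(runif(64), c(4, 4, 4))
  fit <- tucker_decompose(tens, ranks = c(4, 4, 4), epsilon = 1e-3,
                          max_iter = 2000)
  expect_true(fit$converged)
  expect_lt(tail(fit$residual_trace, 1) / sum(tens^2), 1e-3)
  expect_true(all(fit$core >= 0))
  expect_true(all(vapply(fit$factors, function(z) all(z >= 0),
                         logical(1))))
})

test_that("decomposition recovers a planted low-rank model", {
  pl <- simulate_planted_tucker(c(12, 10, 15), c(2, 2, 2), seed = 5)
  fit <- tucker_decompose(pl$tensor, ranks = c(2, 2, 2), epsilon = 1e-2,
                          max_iter = 500)
  expect_lt(tail(fit$residual_trace, 1) / sum(pl$tensor^2), 1e-2)
})

test_that("fits are deterministic and the residual trace never rises overall", {
  withr::local_seed(9)
  tens <- array(runif(60, 0, 1), c(5, 4, 3))
  a <- tucker_decompose(tens, ranks = c(2, 2, 2), max_iter = 50, seed = 3)
  b <- tucker_decompose(tens, ranks = c(2, 2, 2), max_iter = 50, seed = 3)
  expect_identical(a$core, b$core)
  expect_identical(a$factors, b$factors)
  r <- tucker_decompose(tens, ranks = c(2, 2, 2), max_iter = 50,
                        seed = 3, init = "random")
  r2 <- tucker_decompose(tens, ranks = c(2, 2, 2), max_iter = 50,
                         seed = 3, init = "random")
  expect_identical(r$core, r2$core)
  expect_lte(tail(a$residual_trace, 1), a$residual_trace[1])
})

test_that("decomposition rejects invalid ranks and epsilon", {
  tens <- array(runif(8), c(2, 2, 2))
  expect_error(tucker_decompose(tens, ranks = c(0, 1, 1)), "ranks")
  expect_error(tucker_decompose(tens, ranks = c(3, 2, 2)), "exceed")
  expect_error(tucker_decompose(tens, ranks = c(1, 1, 1), epsilon = 0),
               "epsilon")
})
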