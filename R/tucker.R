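#' Mode-n unfolding (matricization) of a 3-way tensor
#'
#' Rearranges a 3-way array into a matrix whose rows index the chosen mode.
#' Columns enumerate the remaining two modes kept in increasing order with
#' the *last* of them varying fastest, so that for a Tucker product
#' `T = G x1 Z1 x2 Z2 x3 Z3` the identity
#' `unfold(T, 1) == Z1 %*% unfold(G, 1) %*% t(kronecker(Z2, Z3))`
#' holds exactly (and its mode-2/mode-3 analogues with `Z1 %x% Z3` and
#' `Z1 %x% Z2`).
#'
#' @param x a 3-way numeric array.
#' @param mode integer, 1, 2 or 3.
#' @return a matrix with `dim(x)[mode]` rows.
#' @seealso [refold()], [nmode_product()]
#' @export
unfold <- function(x, mode) {
  stopifnot(is.array(x), length(dim(x)) == 3L)
  mode <- check_mode(mode)
  others <- setdiff(1:3, mode)
  # perm (mode, last-other, first-other): column-major vectorisation then
  # yields columns ordered with the last remaining mode fastest
  perm <- c(mode, rev(others))
  matrix(aperm(x, perm), nrow = dim(x)[mode])
}

#' Refold a mode-n unfolded matrix back into a 3-way tensor
#'
#' Inverse of [unfold()] for the same column ordering.
#'
#' @param m matrix produced by (or compatible with) `unfold(x, mode)`.
#' @param mode the unfolding mode used.
#' @param dims the target tensor dimensions; `dims[mode]` must equal
#'   `nrow(m)`.
#' @return a 3-way array of dimension `dims`.
#' @export
refold <- function(m, mode, dims) {
  stopifnot(is.matrix(m), length(dims) == 3L)
  mode <- check_mode(mode)
  if (nrow(m) != dims[mode]) {
    stop("row count ", nrow(m), " does not match dims[", mode, "] = ",
         dims[mode])
  }
  others <- setdiff(1:3, mode)
  perm <- c(mode, rev(others))
  a <- array(m, dim = c(dims[mode], dims[rev(others)]))
  aperm(a, order(perm))
}

#' Mode-n product of a 3-way tensor with a matrix
#'
#' Contracts the tensor's `mode`-th axis with the columns of `m`:
#' the result has `nrow(m)` along that axis.
#'
#' @param x a 3-way numeric array.
#' @param m a matrix with `ncol(m) == dim(x)[mode]`.
#' @param mode integer, 1, 2 or 3.
#' @return a 3-way array.
#' @export
nmode_product <- function(x, m, mode) {
  stopifnot(is.array(x), length(dim(x)) == 3L, is.matrix(m))
  mode <- check_mode(mode)
  if (ncol(m) != dim(x)[mode]) {
    stop("ncol(m) = ", ncol(m), " does not match tensor mode-", mode,
         " dimension ", dim(x)[mode])
  }
  dims <- dim(x)
  dims[mode] <- nrow(m)
  refold(m %*% unfold(x, mode), mode, dims)
}

#' Multilinear (Tucker) product of a core tensor with three matrices
#'
#' Computes `g x1 z1 x2 z2 x3 z3`.
#'
#' @param g core 3-way array.
#' @param z1,z2,z3 factor matrices; `ncol` must match the core dimensions.
#' @return a 3-way array of dimension `c(nrow(z1), nrow(z2), nrow(z3))`.
#' @export
multilinear_product <- function(g, z1, z2, z3) {
  nmode_product(nmode_product(nmode_product(g, z1, 1), z2, 2), z3, 3)
}

check_mode <- function(mode) {
  mode <- as.integer(mode)
  if (length(mode) != 1L || is.na(mode) || !mode %in% 1:3) {
    stop("mode must be 1, 2 or 3")
  }
  mode
}

#' @noRd
frobenius_sq <- function(x) sum(x^2)

#' Construct a nonnegative Tucker model container
#' @noRd
new_tucker_model <- function(core, factors, ranks, seed = NA_integer_) {
  structure(
    list(core = core, factors = factors, ranks = ranks, seed = seed,
         iterations = 0L, residual_trace = numeric(0), converged = NA),
    class = "tucker_model"
  )
}

#' @export
print.tucker_model <- function(x, ...) {
  dims <- vapply(x$factors, nrow, integer(1))
  cat("Nonnegative Tucker model\n")
  cat("  tensor dims : ", paste(dims, collapse = " x "), "\n", sep = "")
  cat("  core ranks  : ", paste(x$ranks, collapse = " x "), "\n", sep = "")
  cat("  iterations  : ", x$iterations, "\n", sep = "")
  if (length(x$residual_trace)) {
    cat("  final ||T-That||_F^2 : ",
        format(utils::tail(x$residual_trace, 1)), "\n", sep = "")
  }
  invisible(x)
}

# S matrix of the factor update for one mode: S_n = G_(n) (Z_a (x) Z_b)^T
# with (a, b) the remaining modes in increasing order.
factor_design <- function(model, mode) {
  others <- setdiff(1:3, mode)
  unfold(model$core, mode) %*%
    t(kronecker(model$factors[[others[1]]], model$factors[[others[2]]]))
}

#' One multiplicative update of a factor matrix
#'
#' Applies the NMF-style update
#' `Z_n <- Z_n * (T_(n) S_n^T) / (Z_n S_n S_n^T)` with
#' `S_n = G_(n) (Z_a %x% Z_b)^T`, which keeps `Z_n` nonnegative and leaves
#' an exactly factorized model unchanged. A small constant guards the
#' denominator.
#'
#' @param tens the (smoothed) association tensor being fitted.
#' @param model a `tucker_model`.
#' @param mode which factor to update (1, 2 or 3).
#' @param guard denominator stabilizer, default `1e-12`.
#' @return the model with the updated factor.
#' @export
update_factor <- function(tens, model, mode, guard = 1e-12) {
  mode <- check_mode(mode)
  s <- factor_design(model, mode)
  z <- model$factors[[mode]]
  num <- unfold(tens, mode) %*% t(s)
  den <- z %*% (s %*% t(s)) + guard
  z_new <- z * num / den
  if (any(!is.finite(z_new))) {
    stop("non-finite values in factor update for mode ", mode)
  }
  model$factors[[mode]] <- z_new
  model
}

#' One multiplicative update of the core tensor
#'
#' Applies `G <- G * num / den` where `num` is the data tensor contracted
#' with the transposed factors (`T x1 Z1^T x2 Z2^T x3 Z3^T`) and `den` is
#' the same contraction applied to the current reconstruction. In
#' vectorized form this is exactly the NMF update
#' `vec(G) <- vec(G) * (Q^T vec(T)) / (Q^T Q vec(G))` with
#' `Q = Z3 %x% Z2 %x% Z1`.
#'
#' @inheritParams update_factor
#' @return the model with the updated core.
#' @export
update_core <- function(tens, model, guard = 1e-12) {
  zt <- lapply(model$factors, t)
  num <- multilinear_product(tens, zt[[1]], zt[[2]], zt[[3]])
  recon <- multilinear_product(model$core, model$factors[[1]],
                               model$factors[[2]], model$factors[[3]])
  den <- multilinear_product(recon, zt[[1]], zt[[2]], zt[[3]]) + guard
  g_new <- model$core * num / den
  if (any(!is.finite(g_new))) stop("non-finite values in core update")
  model$core <- g_new
  model
}

#' Fit a nonnegative Tucker decomposition by alternating multiplicative updates
#'
#' Each sweep updates the three factor matrices in mode order 1, 2, 3 and
#' then the core, and iteration stops when the squared Frobenius residual
#' `||T - [[G; Z1, Z2, Z3]]||_F^2` falls below the threshold or
#' `max_iter` sweeps have run.
#'
#' Initialization matters: multiplicative updates cannot revive an entry
#' (or an entire entity row) that reaches zero, and from unstructured
#' random starts the coupled mode updates can lock all components onto
#' one part of the data, irrecoverably zeroing the rows of the rest (a
#' local minimum, observable on block-structured tensors). The default
#' `"nhosvd"` initialization therefore seeds each factor with the
#' absolute values of the leading left singular vectors of the
#' corresponding unfolding (floored at a small positive constant) and
#' the core with the data contracted by the transposed factors, which
#' starts the components spread over the data's multilinear structure
#' and is deterministic. `"random"` draws all entries uniformly from
#' (0.1, 1.1) under `seed`.
#'
#' @param tens a 3-way nonnegative array (typically a WKNNP-smoothed
#'   association tensor, see [wknnp_smooth()]).
#' @param ranks integer vector `(R1, R2, R3)` of core dimensions;
#'   default `c(5, 5, 5)`.
#' @param epsilon convergence threshold; interpreted according to
#'   `epsilon_type`. Default `1e-4` relative.
#' @param epsilon_type `"relative"` compares
#'   `||T - That||_F^2 / ||T||_F^2` against `epsilon`; `"absolute"`
#'   compares the raw squared residual (the literal stopping rule of the
#'   multiplicative-update pseudocode).
#' @param max_iter maximum number of update sweeps, default 500.
#' @param seed integer seed (drives the `"random"` initialization; the
#'   `"nhosvd"` default is deterministic regardless).
#' @param init initialization scheme, `"nhosvd"` (default) or
#'   `"random"`; see Details.
#' @param guard denominator stabilizer for the updates.
#' @return a `tucker_model` with fields `core`, `factors` (list of Z1, Z2,
#'   Z3), `ranks`, `seed`, `iterations`, `residual_trace` (squared
#'   Frobenius residual after every sweep) and `converged`.
#' @examples
#' tens <- array(runif(4 * 3 * 2), dim = c(4, 3, 2))
#' fit <- tucker_decompose(tens, ranks = c(2, 2, 2), seed = 1,
#'                         max_iter = 50)
#' dim(tucker_reconstruct(fit))
#' @export
tucker_decompose <- function(tens, ranks = c(5, 5, 5), epsilon = 1e-4,
                             epsilon_type = c("relative", "absolute"),
                             max_iter = 500L, seed = 1L,
                             init = c("nhosvd", "random"),
                             guard = 1e-12) {
  stopifnot(is.array(tens), length(dim(tens)) == 3L, all(tens >= 0))
  epsilon_type <- match.arg(epsilon_type)
  init <- match.arg(init)
  ranks <- as.integer(ranks)
  if (length(ranks) != 3L || any(ranks < 1L)) {
    stop("ranks must be three integers >= 1")
  }
  dims <- dim(tens)
  if (any(ranks > dims)) {
    stop("ranks (", paste(ranks, collapse = ","),
         ") exceed tensor dimensions (", paste(dims, collapse = ","), ")")
  }
  if (max(ranks) > min(dims)) {
    warning("max rank ", max(ranks), " is not small relative to min ",
            "tensor dimension ", min(dims))
  }
  if (epsilon <= 0) stop("epsilon must be > 0")

  model <- if (init == "random") {
    with_seed(seed, {
      factors <- lapply(1:3, function(n) {
        matrix(stats::runif(dims[n] * ranks[n], 0.1, 1.1),
               nrow = dims[n], ncol = ranks[n])
      })
      core <- array(stats::runif(prod(ranks), 0.1, 1.1), dim = ranks)
      new_tucker_model(core, factors, ranks, seed = as.integer(seed))
    })
  } else {
    factors <- lapply(1:3, function(n) {
      u <- svd(unfold(tens, n), nu = ranks[n])$u
      if (ncol(u) < ranks[n]) {    # rank-deficient unfolding: pad
        u <- cbind(u, matrix(0, nrow(u), ranks[n] - ncol(u)))
      }
      pmax(abs(u), 1e-6)
    })
    core <- multilinear_product(tens, t(factors[[1]]), t(factors[[2]]),
                                t(factors[[3]]))
    new_tucker_model(core, factors, ranks, seed = as.integer(seed))
  }

  t_norm <- frobenius_sq(tens)
  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    for (mode in 1:3) model <- update_factor(tens, model, mode, guard)
    model <- update_core(tens, model, guard)
    resid <- frobenius_sq(tens - tucker_reconstruct(model))
    if (!is.finite(resid)) {
      stop("non-finite residual at iteration ", it,
           "; trace: ", paste(format(trace), collapse = ", "))
    }
    trace[it] <- resid
    crit <- if (epsilon_type == "relative" && t_norm > 0) {
      resid / t_norm
    } else {
      resid
    }
    if (crit < epsilon) {
      converged <- TRUE
      break
    }
  }
  model$iterations <- length(trace)
  model$residual_trace <- trace
  model$converged <- converged
  if (length(trace) >= 2 &&
      utils::tail(trace, 1) > trace[1] + 1e-8 * (1 + trace[1])) {
    stop("residual increased over the fit (",
         format(trace[1]), " -> ", format(utils::tail(trace, 1)),
         "); trace: ", paste(format(trace), collapse = ", "))
  }
  model
}

#' Reconstruct the prediction tensor from a fitted Tucker model
#'
#' Returns `T* = G x1 Z1 x2 Z2 x3 Z3`, the dense nonnegative tensor of
#' predicted association scores.
#'
#' @param model a `tucker_model`.
#' @return a nonnegative 3-way array.
#' @export
tucker_reconstruct <- function(model) {
  stopifnot(inherits(model, "tucker_model"))
  multilinear_product(model$core, model$factors[[1]], model$factors[[2]],
                      model$factors[[3]])
}
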