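test_that("Laplacian kernel matches closed forms on small inputs", {
  expect_equal(laplacian_kernel(matrix(0, 1, 1)), matrix(1, 1, 1))
  expect_equal(laplacian_kernel(matrix(c(0, 1, 1, 0), 2)),
               matrix(c(0.75, 0.25, 0.25, 0.75), 2))
  expect_error(laplacian_kernel(matrix(1, 2, 3)), "square")
  expect_error(laplacian_kernel(matrix(-1, 2, 2)), "nonnegative")
})

test_that("Laplacian kernel rows sum to 1 and match the geometric-series oracle", {
  for (seed in 1:5) {
    A <- random_sym_count(8, seed)
    K <- laplacian_kernel(A)
    expect_lt(max(abs(rowSums(K) - 1)), 1e-12)
    expect_true(all(K >= -1e-12))
    # independent oracle: sum the series (1/2) sum_k (P/2)^k directly
    AI <- A + diag(8)
    P <- AI / rowSums(AI)
    term <- diag(8); acc <- diag(8)
    for (k in 1:80) { term <- term %*% (P / 2); acc <- acc + term }
    expect_lt(max(abs(K - acc / 2)), 1e-10)
  }
})

test_that("Neumann truncation is monotone in order and converges to the inverse", {
  A <- random_sym_count(6, 11)
  expect_equal(neumann_kernel(A, 0), diag(6) / 2)
  exact <- laplacian_kernel(A)
  errs <- vapply(0:12, function(o) norm(neumann_kernel(A, o) - exact, "F"), 0)
  expect_true(all(diff(errs) < 0))
  expect_lt(norm(neumann_kernel(A, 50) - exact, "F"), 1e-10)
})

test_that("bicubic resize is the identity at equal size and preserves constants", {
  M <- random_sym_count(9, 3) * 1.0
  expect_lt(max(abs(symmetrize_resize(M, 9) - (M + t(M)) / 2)), 1e-9)
  C <- matrix(3.7, 8, 8)
  for (r in c(3, 8, 13)) {
    expect_lt(max(abs(symmetrize_resize(C, r) - 3.7)), 1e-12)
  }
  expect_error(symmetrize_resize(M, 1), "r")
})

test_that("bicubic resize matches a direct per-pixel convolution oracle", {
  # independent dense evaluation of Catmull-Rom cubic convolution with
  # half-pixel-centered coordinates and clamped (replicate) edges
  cubic <- function(x, a = -0.5) {
    x <- abs(x)
    if (x <= 1) (a + 2) * x^3 - (a + 3) * x^2 + 1
    else if (x < 2) a * x^3 - 5 * a * x^2 + 8 * a * x - 4 * a
    else 0
  }
  naive_resize <- function(M, r) {
    n <- nrow(M)
    out <- matrix(0, r, r)
    for (i in seq_len(r)) for (j in seq_len(r)) {
      x <- (i - 0.5) * n / r + 0.5
      y <- (j - 0.5) * n / r + 0.5
      acc <- 0
      for (u in -1:2) for (v in -1:2) {
        px <- min(max(floor(x) + u, 1), n)
        py <- min(max(floor(y) + v, 1), n)
        acc <- acc + cubic(x - floor(x) - u) * cubic(y - floor(y) - v) * M[px, py]
      }
      out[i, j] <- acc
    }
    out
  }
  M <- (random_sym_count(7, 8) + random_sym_count(7, 9)) / 2
  for (r in c(4, 11)) {
    expect_lt(max(abs(symmetrize_resize(M, r) - naive_resize(M, r))), 1e-10)
  }
})

test_that("Gaussian kernel weights match the direct evaluation", {
  G <- gaussian_kernel(3, 0.5)
  expect_equal(sum(G), 1)
  expect_equal(G[2, 2], 0.6193, tolerance = 1e-4)
  expect_equal(G[1, 2], 0.0838, tolerance = 1e-3)
  expect_equal(G[1, 1], 0.0113, tolerance = 1e-2)
  # independent evaluation on the {-1,0,1}^2 grid
  w <- outer(c(1, 0, 1), c(1, 0, 1), "+")
  ref <- exp(-w / (2 * 0.25))
  expect_equal(G, ref / sum(ref))
})

test_that("Gaussian smoothing fixes constants, bounds the range, keeps symmetry", {
  expect_equal(gaussian_smooth(matrix(2.5, 6, 6)), matrix(2.5, 6, 6))
  M <- symmetrize_resize(random_sym_count(10, 4) * 1.0, 10)
  S <- gaussian_smooth(M)
  expect_true(isSymmetric(S, tol = 1e-12))
  expect_gte(min(S), min(M) - 1e-12)
  expect_lte(max(S), max(M) + 1e-12)
})

test_that("corner impulse smoothing matches an explicit padded-array oracle", {
  M <- matrix(0, 5, 5); M[1, 1] <- 1
  G <- gaussian_kernel(3, 0.5)
  idx <- pmin(pmax(0:6, 1), 5) # replicate-padded index map
  P <- M[idx, idx]
  ref <- matrix(0, 5, 5)
  for (i in 1:5) for (j in 1:5) {
    ref[i, j] <- sum(G * P[i:(i + 2), j:(j + 2)])
  }
  expect_equal(gaussian_smooth(M), ref)
  # an interior impulse is mass-conserving
  M2 <- matrix(0, 5, 5); M2[3, 3] <- 1
  expect_equal(sum(gaussian_smooth(M2)), 1)
})

test_that("diffusion matches closed forms and the eigendecomposition oracle", {
  expect_warning(B <- diffuse(matrix(0, 3, 3)), "all-zero")
  expect_equal(B, diag(3))
  A <- matrix(c(0, 1, 1, 0), 2)
  expect_equal(diffuse(A),
               matrix(c(cosh(0.5), -sinh(0.5), -sinh(0.5), cosh(0.5)), 2),
               tolerance = 1e-12)
  # symmetric input: expm(X) = V exp(L) V^T from base eigen
  M <- symmetrize_resize(random_sym_count(10, 6) * 1.0, 10)
  X <- -M / sum(M)
  e <- eigen(X, symmetric = TRUE)
  ref <- e$vectors %*% diag(exp(e$values)) %*% t(e$vectors)
  expect_lt(max(abs(diffuse(M) - ref)), 1e-12)
})

test_that("truncated-Taylor diffusion converges to the exact exponential", {
  M <- symmetrize_resize(random_sym_count(10, 12) * 1.0, 10)
  expect_lt(max(abs(diffuse(M, fast = TRUE, taylor_order = 20) - diffuse(M))), 1e-12)
  errs <- vapply(1:8, function(o) max(abs(diffuse(M, fast = TRUE, taylor_order = o) - diffuse(M))), 0)
  expect_true(all(diff(errs) < 0))
})

test_that("ensemble imputation composes the four stages per map", {
  ens <- tiny_ensemble(n_cells = 2, chrom_sizes = c(20))
  params <- imputation_params()
  imp <- impute_ensemble(ens, params)
  expect_equal(imp$r, 20)
  A <- ens$maps[[1]][[1]]
  manual <- diffuse(gaussian_smooth(symmetrize_resize(laplacian_kernel(A), 20)))
  expect_equal(imp$maps[[1]][[1]], manual)
  # every imputed map is symmetric at the common dimension
  for (s in imp$cells) {
    expect_true(isSymmetric(imp$maps[[s]][[1]], tol = 1e-10))
  }
})

test_that("imputation handles an all-zero chromosome map and parallel workers", {
  zero <- matrix(0, 8, 8)
  maps <- list(c1 = list(chr1 = random_sym_count(8, 2), chr2 = zero),
               c2 = list(chr1 = random_sym_count(8, 3), chr2 = random_sym_count(8, 4)))
  ens <- manual_ensemble(maps)
  imp <- impute_ensemble(ens, imputation_params())
  # the all-zero map diffuses from the smoothed-resized kernel, not to NaN
  expect_false(any(!is.finite(imp$maps$c1$chr2)))
  serial <- impute_ensemble(ens, imputation_params(), cores = 1)
  par2 <- impute_ensemble(ens, imputation_params(), cores = 2)
  expect_identical(serial$maps, par2$maps)
})

test_that("a count perturbation changes the diffused map continuously", {
  A <- random_sym_count(50, 21)
  B1 <- diffuse(gaussian_smooth(symmetrize_resize(laplacian_kernel(A), 50)))
  A2 <- A; A2[3, 9] <- A2[3, 9] + 1; A2[9, 3] <- A2[3, 9]
  B2 <- diffuse(gaussian_smooth(symmetrize_resize(laplacian_kernel(A2), 50)))
  expect_lt(norm(B2 - B1, "F"), 1) # bounded response, no blow-up
  expect_gt(norm(B2 - B1, "F"), 0)
})
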