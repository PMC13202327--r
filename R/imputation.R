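# Imputation of sparse intrachromosomal contact maps: regularized graph
# Laplacian kernel -> bicubic resize to a common dimension -> 3x3 Gaussian
# smoothing -> dissipative matrix exponential.

#' Imputation parameters
#'
#' @param kernel_size Odd Gaussian kernel width (default 3).
#' @param sigma Gaussian standard deviation in bins (default 0.5).
#' @param fast Use the fast approximations (Neumann-series kernel and
#'   truncated-Taylor matrix exponential) instead of the exact routines.
#' @param neumann_order Number of Neumann terms beyond the zeroth in fast
#'   mode (default 8; truncation error decays as 2^-order).
#' @param taylor_order Taylor truncation order for the matrix exponential in
#'   fast mode (default 10).
#' @param bicubic_a Cubic-convolution kernel parameter (default -0.5,
#'   Catmull-Rom; -0.75 is the other common convention).
#' @return A list of class `imputation_params`.
#' @export
imputation_params <- function(kernel_size = 3, sigma = 0.5, fast = FALSE,
                              neumann_order = 8, taylor_order = 10,
                              bicubic_a = -0.5) {
  if (kernel_size < 3 || kernel_size %% 2 == 0) stop("kernel_size must be odd and >= 3")
  if (sigma <= 0) stop("sigma must be positive")
  if (neumann_order < 0) stop("neumann_order must be >= 0")
  if (taylor_order < 1) stop("taylor_order must be >= 1")
  structure(list(kernel_size = kernel_size, sigma = sigma, fast = fast,
                 neumann_order = neumann_order, taylor_order = taylor_order,
                 bicubic_a = bicubic_a),
            class = "imputation_params")
}

row_stochastic <- function(A) {
  n <- nrow(A)
  AI <- A + diag(n)
  AI / rowSums(AI) # degree matrix of A + I is diag(rowSums(A + I))
}

#' Regularized graph Laplacian kernel
#'
#' Computes `(2I - D^-1 (A + I))^-1` where `D` is the degree matrix of
#' `A + I`. Since `P = D^-1 (A + I)` is row-stochastic the inverse always
#' exists, equals the geometric series `1/2 * sum_k (P/2)^k`, and has unit
#' row sums and nonnegative entries.
#'
#' @param A Square matrix of nonnegative counts.
#' @return Dense real matrix of the same dimension.
#' @export
laplacian_kernel <- function(A) {
  stopifnot_square(A, "A")
  if (any(A < 0)) stop("A must be nonnegative")
  P <- row_stochastic(A)
  solve(2 * diag(nrow(A)) - P)
}

#' Neumann-series approximation of the Laplacian kernel
#'
#' Truncates the geometric-series identity for [laplacian_kernel] at
#' `order` terms: `1/2 * sum_{k=0..order} (P/2)^k`. The Frobenius error
#' decreases monotonically and geometrically (factor 1/2) with `order`.
#'
#' @param A Square matrix of nonnegative counts.
#' @param order Truncation order (>= 0; 0 gives `I/2`).
#' @return Dense real matrix.
#' @export
neumann_kernel <- function(A, order) {
  stopifnot_square(A, "A")
  if (order < 0) stop("order must be >= 0")
  P <- row_stochastic(A) / 2
  n <- nrow(A)
  term <- diag(n)
  acc <- diag(n)
  for (k in seq_len(order)) {
    term <- term %*% P
    acc <- acc + term
  }
  acc / 2
}

# Cubic convolution (Keys) kernel weights; a = -0.5 is Catmull-Rom.
cubic_kernel <- function(x, a = -0.5) {
  x <- abs(x)
  ifelse(x <= 1, (a + 2) * x^3 - (a + 3) * x^2 + 1,
         ifelse(x < 2, a * x^3 - 5 * a * x^2 + 8 * a * x - 4 * a, 0))
}

# n_out x n_in row-stochastic resampling operator with half-pixel-centered
# grid alignment and replicate (clamped) edge handling.
bicubic_operator <- function(n_in, n_out, a = -0.5) {
  W <- matrix(0, n_out, n_in)
  scale <- n_in / n_out
  for (i in seq_len(n_out)) {
    x <- (i - 0.5) * scale + 0.5  # position in input index space
    x0 <- floor(x)
    t <- x - x0
    idx <- pmin(pmax(x0 + (-1:2), 1), n_in) # replicate edges
    w <- cubic_kernel(t - (-1:2), a)
    for (j in seq_along(idx)) W[i, idx[j]] <- W[i, idx[j]] + w[j]
  }
  W
}

#' Symmetrize and resize a matrix by bicubic resampling
#'
#' Averages `M` with its transpose, resamples it onto an `r x r` grid with a
#' separable cubic-convolution (bicubic) kernel, and re-symmetrizes.
#' Resampling a matrix to its own dimension is the identity.
#'
#' @param M Square real matrix.
#' @param r Target dimension (>= 2).
#' @param a Cubic kernel parameter (default -0.5).
#' @return Symmetric `r x r` matrix.
#' @export
symmetrize_resize <- function(M, r, a = -0.5) {
  stopifnot_square(M, "M")
  if (r < 2) stop("target dimension r must be >= 2")
  S <- (M + t(M)) / 2
  W <- bicubic_operator(nrow(M), r, a)
  R <- W %*% S %*% t(W)
  (R + t(R)) / 2
}

#' Build the normalized 2-D Gaussian kernel
#' @param size Odd kernel width.
#' @param sigma Standard deviation in bins.
#' @return `size x size` matrix summing to 1.
#' @export
gaussian_kernel <- function(size = 3, sigma = 0.5) {
  h <- (size - 1) / 2
  d <- seq(-h, h)
  G <- exp(-outer(d^2, d^2, "+") / (2 * sigma^2))
  G / sum(G)
}

#' Smooth a matrix with a small Gaussian kernel under replicate padding
#'
#' 2-D convolution with the unit-sum Gaussian of [gaussian_kernel]; values
#' outside the matrix are taken from the nearest border entry, so the output
#' is a convex combination of input entries (global min/max are respected)
#' and constants are fixed points.
#'
#' @param M Square real matrix.
#' @param kernel_size Odd kernel width (default 3).
#' @param sigma Standard deviation (default 0.5).
#' @return Smoothed matrix of the same dimension.
#' @export
gaussian_smooth <- function(M, kernel_size = 3, sigma = 0.5) {
  stopifnot_square(M, "M")
  G <- gaussian_kernel(kernel_size, sigma)
  h <- (kernel_size - 1) / 2
  n <- nrow(M)
  idx <- pmin(pmax(seq(1 - h, n + h), 1), n)
  P <- M[idx, idx] # replicate-padded
  out <- matrix(0, n, n)
  for (dx in seq_len(kernel_size)) {
    for (dy in seq_len(kernel_size)) {
      out <- out + G[dx, dy] * P[(dx - 1) + seq_len(n), (dy - 1) + seq_len(n)]
    }
  }
  out
}

#' Dissipative matrix-exponential diffusion
#'
#' Normalizes `M` by its total and applies the matrix exponential at time
#' t = -1: `B = expm(-M / sum(M))`. The negative time direction acts as a
#' sharpening (high-pass) operator on the contact graph rather than a blur.
#' An all-zero input returns the identity (`expm(0) = I`) with a warning.
#'
#' @param M Square real matrix.
#' @param fast Use the truncated Taylor series instead of the exact
#'   matrix exponential.
#' @param taylor_order Taylor truncation order in fast mode.
#' @return Dense real matrix `B`.
#' @export
diffuse <- function(M, fast = FALSE, taylor_order = 10) {
  stopifnot_square(M, "M")
  tot <- sum(M)
  n <- nrow(M)
  if (tot == 0) {
    warning("all-zero map: diffusion returns the identity", call. = FALSE)
    return(diag(n))
  }
  X <- -M / tot
  if (!fast) {
    B <- as.matrix(Matrix::expm(X))
  } else {
    term <- diag(n)
    B <- diag(n)
    for (k in seq_len(taylor_order)) {
      term <- term %*% X / k
      B <- B + term
    }
  }
  dimnames(B) <- NULL
  B
}

#' Impute every map of an ensemble
#'
#' Applies, per (cell, chromosome) map: [laplacian_kernel] (or
#' [neumann_kernel] in fast mode), [symmetrize_resize] to the common
#' dimension `r = round(mean(n_k))`, [gaussian_smooth], and [diffuse].
#' The computation is deterministic and independent across maps; with
#' `cores > 1` maps are processed in parallel with results identical to the
#' serial run.
#'
#' @param ensemble A [cell_ensemble] (already filtered).
#' @param params An [imputation_params] object.
#' @param cores Number of worker processes (default 1).
#' @return An `imputed_ensemble`: list with `cells`, `chroms`, `r`, `maps`
#'   (nested list of dense symmetric `r x r` matrices) and `labels`.
#' @export
impute_ensemble <- function(ensemble, params = imputation_params(), cores = 1) {
  n_bins <- chrom_bins(ensemble)
  r <- as.integer(round(mean(n_bins)))
  jobs <- expand.grid(cell = ensemble$cells, chrom = ensemble$chroms,
                      stringsAsFactors = FALSE)
  impute_one <- function(j) {
    A <- ensemble$maps[[jobs$cell[j]]][[jobs$chrom[j]]]
    K <- if (params$fast) neumann_kernel(A, params$neumann_order) else laplacian_kernel(A)
    S <- symmetrize_resize(K, r, params$bicubic_a)
    S <- gaussian_smooth(S, params$kernel_size, params$sigma)
    suppressWarnings(diffuse(S, params$fast, params$taylor_order))
  }
  res <- if (cores > 1) {
    parallel::mclapply(seq_len(nrow(jobs)), impute_one, mc.cores = cores)
  } else {
    lapply(seq_len(nrow(jobs)), impute_one)
  }
  maps <- lapply(ensemble$cells, function(s) {
    out <- lapply(ensemble$chroms, function(k) {
      res[[which(jobs$cell == s & jobs$chrom == k)]]
    })
    names(out) <- ensemble$chroms
    out
  })
  names(maps) <- ensemble$cells
  structure(list(cells = ensemble$cells, chroms = ensemble$chroms, r = r,
                 maps = maps, labels = ensemble$labels,
                 bin_size = ensemble$bin_size),
            class = "imputed_ensemble")
}

#' @export
print.imputed_ensemble <- function(x, ...) {
  cat(sprintf("imputed_ensemble: %d cells x %d chromosomes, common dimension r = %d\n",
              length(x$cells), length(x$chroms), x$r))
  invisible(x)
}
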