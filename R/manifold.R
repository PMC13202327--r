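# Dimensionality-reduction cascade: per-offset nonmetric MDS + PCA, feature
# stacking with column softmax, L1 distances, latent MDS embedding, and the
# Shi-Malik random-walk spectral embedding.

# Classical MDS with zero-padding to exactly k columns (cmdscale returns
# fewer when the double-centered matrix is rank deficient).
classical_mds <- function(D, k) {
  # rank deficiency (fewer positive eigenvalues than k) is expected and
  # handled by zero-padding, so cmdscale's warning about it is muted
  X <- suppressWarnings(stats::cmdscale(stats::as.dist(D), k = k))
  if (ncol(X) < k) X <- cbind(X, matrix(0, nrow(X), k - ncol(X)))
  X
}

# Nonmetric MDS (Kruskal stress-1) initialized from classical MDS so runs
# are deterministic and never touch the RNG.
nonmetric_mds <- function(D, k, maxit = 300) {
  d <- stats::as.dist(D)
  y0 <- classical_mds(D, k)
  fit <- vegan::monoMDS(d, y = y0, k = k, model = "global", maxit = maxit,
                        smin = 1e-6, sfgrmin = 1e-7)
  unname(fit$points)
}

mds_embed <- function(D, k, mode = c("nonmetric", "classical"), maxit = 300) {
  mode <- match.arg(mode)
  if (mode == "classical") classical_mds(D, k) else nonmetric_mds(D, k, maxit)
}

#' Reduce one per-offset distance matrix to q dimensions
#'
#' Zeroes the (unit) diagonal of `K`, embeds the cells into `p` dimensions by
#' nonmetric MDS (classical MDS in fast mode), and projects onto the top `q`
#' principal components (centered, unscaled). Deterministic: the nonmetric
#' fit is initialized from classical MDS.
#'
#' @param K Symmetric `a x a` combined distance matrix.
#' @param p Intermediate MDS dimension (default 30); lowered to `a - 1` with
#'   a warning when `a <= p`.
#' @param q Output dimension (default 5).
#' @param mds_mode `"nonmetric"` (default) or `"classical"`.
#' @return `a x q` matrix `U`.
#' @export
reduce_offset <- function(K, p = 30, q = 5, mds_mode = "nonmetric") {
  stopifnot_square(K, "K")
  a <- nrow(K)
  if (a <= p) {
    warning("a = ", a, " <= p = ", p, ": lowering p to ", a - 1, call. = FALSE)
    p <- a - 1
  }
  if (q > p) stop("q must not exceed p")
  D <- K
  diag(D) <- 0
  X <- mds_embed(D, p, mds_mode)
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  U <- pc$x[, seq_len(min(q, ncol(pc$x))), drop = FALSE]
  if (ncol(U) < q) U <- cbind(U, matrix(0, a, q - ncol(U)))
  unname(U)
}

#' Stack per-offset reductions and softmax-normalize feature-wise
#'
#' Concatenates the `U^w` blocks column-wise in offset order into
#' `R` (`a x q(zeta+1)`) and normalizes each feature column over cells with
#' the softmax (max-subtracted for overflow safety):
#' `R'[i, j] = exp(R[i, j]) / sum_theta exp(R[theta, j])`.
#'
#' @param U_blocks List of `a x q` matrices in offset order.
#' @return List with `R` and the column-softmaxed `R_soft`.
#' @export
stack_and_normalize <- function(U_blocks) {
  R <- do.call(cbind, U_blocks)
  Rs <- apply(R, 2, function(col) {
    z <- exp(col - max(col))
    z / sum(z)
  })
  list(R = R, R_soft = Rs)
}

#' L1 (Manhattan) distance matrix between rows
#'
#' @param X `a x m` matrix.
#' @return Symmetric `a x a` matrix `S` with `S[i, j] = sum_l |X[i, l] - X[j, l]|`.
#' @export
l1_distance <- function(X) {
  as.matrix(stats::dist(X, method = "manhattan"))
}

#' Embed the stacked-feature distance matrix into the latent space
#'
#' Nonmetric MDS (classical in fast mode) of `S` into `epsilon` dimensions,
#' giving the latent embedding `V`.
#'
#' @param S Symmetric `a x a` L1 distance matrix.
#' @param epsilon Latent dimension (default 5).
#' @param mds_mode `"nonmetric"` (default) or `"classical"`.
#' @return `a x epsilon` matrix `V`.
#' @export
embed_latent <- function(S, epsilon = 5, mds_mode = "nonmetric") {
  stopifnot_square(S, "S")
  if (epsilon < 1) stop("epsilon must be >= 1")
  unname(mds_embed(S, epsilon, mds_mode))
}

#' Shi-Malik spectral embedding of the latent space
#'
#' Builds the Gaussian similarity `A[i, j] = exp(-Z[i, j]^2)` from pairwise
#' Euclidean distances `Z` of the rows of `V`, sparsifies it to the
#' `ceiling(log(a))` nearest neighbors per cell (self excluded, symmetrized
#' by union), and solves the Shi-Malik generalized eigenproblem of the
#' random-walk Laplacian via the symmetric normalized Laplacian. The columns
#' of `C` are the eigenvectors of the `l - 1` smallest eigenvalues after the
#' trivial one, in ascending order, sign-fixed so each column's
#' largest-magnitude entry is positive.
#'
#' A disconnected neighbor graph (multiple zero eigenvalues) proceeds with
#' the component-indicating eigenvectors and a warning.
#'
#' @param V `a x epsilon` latent matrix.
#' @param l Number of expected clusters (`2 <= l <= a`).
#' @return `a x (l - 1)` spectral embedding `C` with eigenvalues in
#'   attribute `"values"`.
#' @export
spectral_embed <- function(V, l) {
  a <- nrow(V)
  if (l < 2 || l > a) stop("l must lie in [2, ", a, "]")
  Z <- as.matrix(stats::dist(V))
  A <- exp(-Z^2)
  k <- ceiling(log(a))
  W <- matrix(0, a, a)
  for (i in seq_len(a)) {
    nb <- order(Z[i, ])[-1][seq_len(min(k, a - 1))]
    W[i, nb] <- A[i, nb]
  }
  W <- pmax(W, t(W)) # union symmetrization
  deg <- rowSums(W)
  dh <- 1 / sqrt(deg)
  Lsym <- diag(a) - (dh * W) * rep(dh, each = a) # D^-1/2 W D^-1/2
  Lsym <- (Lsym + t(Lsym)) / 2
  eig <- eigen(Lsym, symmetric = TRUE)
  ord <- rev(seq_len(a)) # ascending eigenvalues
  vals <- eig$values[ord]
  vecs <- eig$vectors[, ord, drop = FALSE]
  if (a >= 2 && vals[2] < 1e-10) {
    warning("nearest-neighbor graph is disconnected: ",
            sum(vals < 1e-10), " zero eigenvalues", call. = FALSE)
  }
  sel <- seq(2, l) # drop the trivial first eigenvector
  C <- vecs[, sel, drop = FALSE] * dh # back-transform u = D^-1/2 v
  for (j in seq_len(ncol(C))) {
    if (C[which.max(abs(C[, j])), j] < 0) C[, j] <- -C[, j]
  }
  attr(C, "values") <- vals[sel]
  C
}

#' Write an embedding as TSV
#' @param X Embedding matrix with one row per cell.
#' @param cells Cell identifiers.
#' @param path Output path.
#' @export
write_embedding <- function(X, cells, path) {
  d <- data.frame(cell_id = cells, X, check.names = FALSE)
  colnames(d) <- c("cell_id", paste0("dim", seq_len(ncol(X))))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
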