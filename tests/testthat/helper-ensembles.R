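# Shared fixture builders: everything is generated in code at test time.

# Small two-type synthetic ensemble used across module tests.
tiny_spec <- function(...) {
  defaults <- list(n_cells = 24, n_types = 2, chrom_sizes = c(40, 36),
                   contacts_per_cell = 4000, block_count = 4,
                   boundary_shift = 3, seed = 7)
  do.call(synthetic_spec, utils::modifyList(defaults, list(...)))
}

tiny_ensemble <- function(...) sample_ensemble(tiny_spec(...))

tiny_params <- function(...) {
  defaults <- list(zeta = 6, epsilon = 3, min_total = 0, repeats = 3, seed = 5)
  do.call(pipeline_params, utils::modifyList(defaults, list(...)))
}

# Random symmetric nonnegative integer matrix.
random_sym_count <- function(n, seed, lambda = 2) {
  set.seed(seed)
  M <- matrix(rpois(n * n, lambda), n, n)
  M[lower.tri(M)] <- t(M)[lower.tri(M)]
  M
}

# Hand-built ensemble from a named nested list of matrices.
manual_ensemble <- function(maps, labels = NULL) {
  cell_ensemble(maps, bin_size = 1e6, labels = labels)
}

# A single-chromosome ensemble with prescribed per-cell off-diagonal totals
# (counts placed on distinct off-diagonal pairs of an n x n map).
coverage_ensemble <- function(offdiag_totals, n = 60) {
  maps <- lapply(seq_along(offdiag_totals), function(i) {
    A <- matrix(0, n, n)
    A[1, 2] <- A[2, 1] <- offdiag_totals[i]
    list(chr1 = A)
  })
  names(maps) <- paste0("cell", seq_along(offdiag_totals))
  manual_ensemble(maps)
}

# Independent pair-counting ARI (agreement counts over all cell pairs),
# the oracle route against the contingency-table formula.
pair_counting_ari <- function(x, y) {
  sx <- outer(x, x, "==")[upper.tri(diag(length(x)))]
  sy <- outer(y, y, "==")[upper.tri(diag(length(y)))]
  n11 <- sum(sx & sy); n00 <- sum(!sx & !sy)
  n10 <- sum(sx & !sy); n01 <- sum(!sx & sy)
  den <- (n11 + n10) * (n10 + n00) + (n11 + n01) * (n01 + n00)
  if (den == 0) return(1)
  2 * (n11 * n00 - n10 * n01) / den
}

# Procrustes residual after optimal translation + rotation/reflection
# (no scaling); small residual means X and Y match up to rigid motion.
procrustes_residual <- function(X, Y) {
  Xc <- scale(X, scale = FALSE)
  Yc <- scale(Y, scale = FALSE)
  s <- svd(crossprod(Yc, Xc))
  R <- s$u %*% t(s$v)
  sqrt(sum((Yc %*% R - Xc)^2))
}
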