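# k-means++ labeling of embeddings and the contingency-table clustering
# accuracy metrics (adjusted Rand index, normalized mutual information).

kmeanspp_centers <- function(X, l) {
  a <- nrow(X)
  idx <- sample.int(a, 1)
  d2 <- rowSums((X - matrix(X[idx, ], a, ncol(X), byrow = TRUE))^2)
  for (j in seq_len(l - 1)) {
    if (sum(d2) == 0) return(NULL) # fewer distinct points than centers
    nxt <- sample.int(a, 1, prob = d2)
    idx <- c(idx, nxt)
    d2 <- pmin(d2, rowSums((X - matrix(X[nxt, ], a, ncol(X), byrow = TRUE))^2))
  }
  idx
}

#' k-means++ clustering
#'
#' k-means with distance-proportional (k-means++) seeding of the initial
#' centers and Lloyd refinement (via [stats::kmeans]); `n_init` restarts are
#' run and the solution with the lowest inertia (total within-cluster sum of
#' squares) is kept. Deterministic for a fixed `seed`. Restarts ending in an
#' empty cluster are discarded; an error is raised if every restart fails.
#'
#' @param X `a x d` embedding matrix (rows may be named by cell).
#' @param l Number of clusters (`2 <= l <= a`).
#' @param n_init Number of restarts (default 10).
#' @param seed Integer RNG seed.
#' @param iter_max Lloyd iteration cap (default 300).
#' @return List with `cluster` (integer labels in `1..l`, named when `X` has
#'   row names), `inertia`, `n_init`, `seed`.
#' @export
kmeans_pp <- function(X, l, n_init = 10, seed = 1, iter_max = 300) {
  X <- as.matrix(X)
  a <- nrow(X)
  if (l < 2 || l > a) stop("l must lie in [2, ", a, "]")
  set.seed(seed)
  best <- NULL
  for (i in seq_len(n_init)) {
    idx <- kmeanspp_centers(X, l)
    if (is.null(idx)) next
    km <- tryCatch(
      suppressWarnings(stats::kmeans(X, centers = X[idx, , drop = FALSE],
                                     iter.max = iter_max, algorithm = "Lloyd")),
      error = function(e) NULL
    )
    if (is.null(km) || length(unique(km$cluster)) < l) next
    if (is.null(best) || km$tot.withinss < best$inertia) {
      best <- list(cluster = km$cluster, inertia = km$tot.withinss)
    }
  }
  if (is.null(best)) stop("k-means++ failed in all ", n_init, " restarts")
  if (!is.null(rownames(X))) names(best$cluster) <- rownames(X)
  c(best, list(n_init = n_init, seed = seed))
}

align_labelings <- function(truth, pred) {
  if (!is.null(names(truth)) && !is.null(names(pred))) {
    if (!setequal(names(truth), names(pred))) {
      stop("labelings cover different cell sets")
    }
    pred <- pred[names(truth)]
  } else if (length(truth) != length(pred)) {
    stop("labelings have different lengths")
  }
  list(truth = as.character(truth), pred = as.character(pred))
}

#' Adjusted Rand index
#'
#' Pair-counting agreement between two partitions corrected for chance,
#' computed from the contingency table `beta[i, j] = |X_i intersect Y_j|`
#' with its row sums, column sums and binomial coefficients. 1 for
#' identical partitions, about 0 for random assignment. Invariant to label
#' renaming on either side.
#'
#' @param truth,pred Label vectors over the same cells (aligned by name when
#'   both are named).
#' @return Scalar ARI.
#' @export
adjusted_rand_index <- function(truth, pred) {
  al <- align_labelings(truth, pred)
  a <- length(al$truth)
  if (a < 2) stop("need at least two cells")
  beta <- table(al$truth, al$pred)
  sum_ij <- sum(choose(beta, 2))
  sum_g <- sum(choose(rowSums(beta), 2))
  sum_d <- sum(choose(colSums(beta), 2))
  tot <- choose(a, 2)
  expected <- sum_g * sum_d / tot
  denom <- (sum_g + sum_d) / 2 - expected
  if (abs(denom) < .Machine$double.eps * tot) {
    if (identical_partitions(al$truth, al$pred)) return(1)
    warning("degenerate ARI denominator: returning 0", call. = FALSE)
    return(0)
  }
  (sum_ij - expected) / denom
}

identical_partitions <- function(x, y) {
  all(stats::ave(seq_along(x), x, FUN = min) == stats::ave(seq_along(y), y, FUN = min))
}

#' Normalized mutual information
#'
#' Mutual information between the two partitions (log base 2, with
#' `0 log 0 = 0`) scaled by the geometric mean of their entropies; lies in
#' `[0, 1]`, 1 iff the partitions are identical. A zero-entropy (single
#' cluster) partition on either side returns 0 with a warning.
#'
#' @inheritParams adjusted_rand_index
#' @return Scalar NMI.
#' @export
normalized_mutual_information <- function(truth, pred) {
  al <- align_labelings(truth, pred)
  a <- length(al$truth)
  if (a < 2) stop("need at least two cells")
  # identical partitions have NMI exactly 1 (MI equals the shared entropy);
  # return it without accumulating rounding error
  if (identical_partitions(al$truth, al$pred) &&
      length(unique(al$truth)) > 1) {
    return(1)
  }
  beta <- table(al$truth, al$pred)
  h_ij <- beta / a
  h_i <- rowSums(beta) / a
  h_j <- colSums(beta) / a
  ent <- function(p) -sum(ifelse(p > 0, p * log2(p), 0))
  Hx <- ent(h_i)
  Hy <- ent(h_j)
  if (Hx == 0 || Hy == 0) {
    warning("single-cluster partition: NMI undefined, returning 0", call. = FALSE)
    return(0)
  }
  ratio <- h_ij / outer(h_i, h_j)
  mi <- sum(ifelse(h_ij > 0, h_ij * log2(ratio), 0))
  min(max(mi / sqrt(Hx * Hy), 0), 1)
}

#' Score an embedding against ground-truth labels
#'
#' Runs [kmeans_pp] `repeats` times with distinct seeds derived from the
#' master seed and reports the mean and standard deviation of ARI and NMI
#' against the ground truth.
#'
#' @param X Embedding matrix (rows named by cell when `truth` is named).
#' @param truth Ground-truth labels.
#' @param l Number of clusters (default: number of distinct truth labels).
#' @param repeats Number of independent clusterings (default 10).
#' @param seed Master seed.
#' @param n_init Restarts per clustering (default 10).
#' @return List with `mean_ari`, `sd_ari`, `mean_nmi`, `sd_nmi`, per-repeat
#'   vectors `ari`/`nmi`, `repeats`, `seed`.
#' @export
score_embedding <- function(X, truth, l = length(unique(truth)), repeats = 10,
                            seed = 1, n_init = 10) {
  if (repeats < 1) stop("repeats must be >= 1")
  X <- as.matrix(X)
  ari <- numeric(repeats)
  nmi <- numeric(repeats)
  for (i in seq_len(repeats)) {
    km <- kmeans_pp(X, l, n_init = n_init, seed = derive_seed(seed, "kmeans", i))
    pred <- km$cluster
    if (is.null(names(pred)) && !is.null(names(truth))) names(pred) <- names(truth)
    ari[i] <- adjusted_rand_index(truth, pred)
    nmi[i] <- normalized_mutual_information(truth, pred)
  }
  list(mean_ari = mean(ari), sd_ari = stats::sd(ari),
       mean_nmi = mean(nmi), sd_nmi = stats::sd(nmi),
       ari = ari, nmi = nmi, repeats = repeats, seed = seed)
}

#' Write a score summary as JSON
#' @param scores Result of [score_embedding].
#' @param path Output path.
#' @export
write_scores <- function(scores, path) {
  jsonlite::write_json(
    scores[c("mean_ari", "sd_ari", "mean_nmi", "sd_nmi", "repeats", "seed")],
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
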