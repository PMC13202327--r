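# Per-superdiagonal band features: z-scored band vectors, their trinarized
# signed differences, cosine distances between cells, and the exponentiated
# combined distance matrix K^w for each offset w.

#' Extract the w-th superdiagonal of a matrix
#'
#' @param B Square `r x r` matrix.
#' @param w Offset, `0 <= w <= r - 1`; `w = 0` is the main diagonal.
#' @return Numeric vector `(B[1, 1+w], ..., B[r-w, r])` of length `r - w`.
#' @export
extract_superdiagonal <- function(B, w) {
  stopifnot_square(B, "B")
  r <- nrow(B)
  if (w < 0 || w >= r) stop("offset w must lie in [0, ", r - 1, "]")
  i <- seq_len(r - w)
  B[cbind(i, i + w)]
}

#' Band feature vectors for one cell at one offset
#'
#' Concatenates the w-th superdiagonals of a cell's imputed chromosome maps
#' (in chromosome order) into one band vector, z-scores it (sample standard
#' deviation), and trinarizes consecutive differences into a signed
#' difference vector: `f_alpha = sgn(e'_alpha - e'_{alpha+1})`, with the last
#' entry `sgn(e'_last)` so the vector stays ternary (`literal_last = TRUE`
#' instead copies the raw last z-score).
#'
#' A constant band (zero standard deviation) yields all-zero `e` and `f`
#' with a warning.
#'
#' @param maps List of `r x r` matrices (one per chromosome) for one cell.
#' @param w Superdiagonal offset (`w <= r - 2` so each segment has at least
#'   two entries).
#' @param literal_last Keep the raw z-score as the last entry of `f`.
#' @return List with `w`, `e` (z-scored band vector) and `f` (ternary vector),
#'   both of length `b * (r - w)`.
#' @export
band_features <- function(maps, w, literal_last = FALSE) {
  r <- nrow(maps[[1]])
  if (w > r - 2) stop("offset w must be <= r - 2 = ", r - 2)
  e <- unlist(lapply(maps, extract_superdiagonal, w = w), use.names = FALSE)
  n <- length(e)
  s <- stats::sd(e) # sample sd, denominator n - 1
  if (!is.finite(s) || s == 0) {
    warning("constant band at offset ", w, ": z-score degenerates to zero vector",
            call. = FALSE)
    ep <- numeric(n)
  } else {
    ep <- (e - mean(e)) / s
  }
  f <- c(sign(ep[-n] - ep[-1]),
         if (literal_last) ep[n] else sign(ep[n]))
  list(w = w, e = ep, f = f)
}

#' Cosine distance matrix between row vectors
#'
#' `D[i, j] = 1 - <v_i, v_j> / (|v_i| |v_j|)`, clamped to `[0, 2]`, with
#' zero diagonal. A zero-magnitude vector is assigned distance 1 to any
#' nonzero vector and 0 to another zero vector.
#'
#' @param V Matrix with one vector per row (a rows).
#' @return Symmetric `a x a` matrix.
#' @export
cosine_distance_matrix <- function(V) {
  a <- nrow(V)
  if (a < 2) stop("need at least two vectors")
  nrm <- sqrt(rowSums(V^2))
  G <- tcrossprod(V)
  denom <- outer(nrm, nrm)
  D <- 1 - G / denom
  zero <- nrm == 0
  if (any(zero)) {
    D[zero, ] <- 1
    D[, zero] <- 1
    D[zero, zero] <- 0
  }
  D <- pmin(pmax(D, 0), 2)
  D <- (D + t(D)) / 2
  diag(D) <- 0
  D
}

#' Combine band and difference distances
#'
#' Element-wise exponentiated sum `K[i, j] = exp(D_e[i, j] + D_f[i, j])`;
#' with cosine distances in `[0, 2]` on both arguments, `K` is symmetric
#' with unit diagonal and entries in `[1, exp(4)]`.
#'
#' @param D_e Cosine distance matrix on z-scored band vectors.
#' @param D_f Cosine distance matrix on signed difference vectors.
#' @return Symmetric `a x a` matrix.
#' @export
combine_distances <- function(D_e, D_f) {
  if (!identical(dim(D_e), dim(D_f))) stop("distance matrices must share a dimension")
  exp(D_e + D_f)
}

#' Per-offset combined distance matrices for an imputed ensemble
#'
#' For every offset `w = 0, ..., zeta`, builds the band features of each
#' cell, the two cosine distance matrices, and the exponentiated combined
#' matrix `K^w`. Offsets are independent; with `cores > 1` they are computed
#' in parallel with results identical to the serial run.
#'
#' @param imputed An `imputed_ensemble` from [impute_ensemble].
#' @param zeta Largest offset (default 25); must satisfy `zeta <= r - 2`.
#' @param literal_last Passed to [band_features].
#' @param cores Worker processes (default 1).
#' @return List of `zeta + 1` elements, each a list with `w`, `K`, `D_e`,
#'   `D_f` and the per-cell feature matrices `E`, `F`.
#' @export
distance_sets <- function(imputed, zeta = 25, literal_last = FALSE, cores = 1) {
  r <- imputed$r
  if (zeta < 0) stop("zeta must be >= 0")
  if (zeta > r - 2) {
    stop("zeta = ", zeta, " exceeds the maximum admissible offset r - 2 = ", r - 2)
  }
  one_offset <- function(w) {
    feats <- lapply(imputed$cells, function(s) {
      band_features(imputed$maps[[s]], w, literal_last = literal_last)
    })
    E <- do.call(rbind, lapply(feats, `[[`, "e"))
    F_ <- do.call(rbind, lapply(feats, `[[`, "f"))
    rownames(E) <- rownames(F_) <- imputed$cells
    D_e <- cosine_distance_matrix(E)
    D_f <- cosine_distance_matrix(F_)
    list(w = w, K = combine_distances(D_e, D_f), D_e = D_e, D_f = D_f,
         E = E, F = F_)
  }
  ws <- 0:zeta
  if (cores > 1) {
    parallel::mclapply(ws, one_offset, mc.cores = cores)
  } else {
    lapply(ws, one_offset)
  }
}

#' Export per-offset distance matrices as TSV files
#'
#' Writes one `K_w<offset>.tsv` per offset plus a JSON index mapping offsets
#' to file names.
#'
#' @param dsets Result of [distance_sets].
#' @param dir Output directory.
#' @export
write_distance_sets <- function(dsets, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  index <- list()
  for (d in dsets) {
    fn <- sprintf("K_w%d.tsv", d$w)
    utils::write.table(d$K, file.path(dir, fn), sep = "\t", quote = FALSE,
                       row.names = TRUE, col.names = NA)
    index[[as.character(d$w)]] <- fn
  }
  jsonlite::write_json(index, file.path(dir, "index.json"), auto_unbox = TRUE)
  invisible(dir)
}
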