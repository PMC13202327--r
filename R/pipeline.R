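# End-to-end orchestration: filtering -> imputation -> per-offset band
# distances -> reduction cascade -> spectral embedding -> k-means++ ->
# scoring, plus the hyperparameter-sweep and chromosome-subsampling drivers.

#' Pipeline parameters
#'
#' Bundles every tunable of the embedding/clustering pipeline. `zeta` is the
#' largest superdiagonal offset sampled (offsets `0..zeta`), `epsilon` the
#' latent embedding dimension, `p`/`q` the intermediate and per-offset
#' reduced dimensions. `fast = TRUE` switches on the Neumann-series kernel,
#' the truncated-Taylor matrix exponential, and classical MDS together.
#'
#' @param zeta Number of superdiagonals beyond the main diagonal (default 25).
#' @param epsilon Latent dimension of `V` (default 5).
#' @param p Intermediate MDS dimension (default 30).
#' @param q Per-offset PCA dimension (default 5).
#' @param kernel_size,sigma Gaussian smoothing parameters (defaults 3, 0.5).
#' @param fast Enable all fast-mode approximations (default `FALSE`).
#' @param neumann_order,taylor_order Fast-mode truncation orders (8, 10).
#' @param bicubic_a Bicubic kernel parameter (default -0.5).
#' @param n_clusters Number of clusters l; default (`NULL`) uses the number
#'   of distinct ground-truth labels.
#' @param embedding Which embedding feeds the clusterer: `"C"` (spectral,
#'   default) or `"V"` (latent).
#' @param repeats Scoring repeats (default 10).
#' @param n_init k-means++ restarts per clustering (default 10).
#' @param min_total Cell filter threshold (default 5000).
#' @param max_empty_frac Empty-chromosome threshold (default 0.10).
#' @param literal_last Keep the raw z-score as the last difference-vector
#'   entry (default `FALSE`).
#' @param seed Master seed; stage seeds are derived from it.
#' @param cores Worker processes for the parallelizable stages (default 1).
#' @return A list of class `pipeline_params`.
#' @export
pipeline_params <- function(zeta = 25, epsilon = 5, p = 30, q = 5,
                            kernel_size = 3, sigma = 0.5, fast = FALSE,
                            neumann_order = 8, taylor_order = 10,
                            bicubic_a = -0.5, n_clusters = NULL,
                            embedding = c("C", "V"), repeats = 10,
                            n_init = 10, min_total = 5000,
                            max_empty_frac = 0.10, literal_last = FALSE,
                            seed = 1, cores = 1) {
  embedding <- match.arg(embedding)
  if (zeta < 0) stop("zeta must be >= 0")
  if (epsilon < 1) stop("epsilon must be >= 1")
  if (q > p) stop("q must not exceed p")
  structure(list(zeta = zeta, epsilon = epsilon, p = p, q = q,
                 kernel_size = kernel_size, sigma = sigma, fast = fast,
                 neumann_order = neumann_order, taylor_order = taylor_order,
                 bicubic_a = bicubic_a, n_clusters = n_clusters,
                 embedding = embedding, repeats = repeats, n_init = n_init,
                 min_total = min_total, max_empty_frac = max_empty_frac,
                 literal_last = literal_last, seed = seed, cores = cores),
            class = "pipeline_params")
}

#' Read / write a pipeline configuration file
#'
#' YAML round-trip of a [pipeline_params] object, so any run is reproducible
#' from the config written next to its outputs.
#'
#' @param params A [pipeline_params] object.
#' @param path YAML file path.
#' @return `read_config` returns a [pipeline_params] object.
#' @export
write_config <- function(params, path) {
  yaml::write_yaml(unclass(params), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_params, vals[!vapply(vals, is.null, TRUE)])
}

mds_mode_of <- function(params) if (params$fast) "classical" else "nonmetric"

# Stages downstream of the per-offset distance sets; split out so the sweep
# driver can reuse cached U blocks.
downstream_embed <- function(U_blocks, params, l) {
  st <- stack_and_normalize(U_blocks)
  S <- l1_distance(st$R_soft)
  V <- embed_latent(S, params$epsilon, mds_mode_of(params))
  C <- spectral_embed(V, l)
  list(R = st$R, R_soft = st$R_soft, S = S, V = V, C = C)
}

cluster_and_score <- function(emb, cells, labels, params, l) {
  X <- if (params$embedding == "C") emb$C else emb$V
  rownames(X) <- cells
  km <- kmeans_pp(X, l, n_init = params$n_init,
                  seed = derive_seed(params$seed, "kmeans", 0))
  scores <- if (!is.null(labels)) {
    score_embedding(X, labels, l = l, repeats = params$repeats,
                    seed = params$seed, n_init = params$n_init)
  }
  list(cluster = km, scores = scores)
}

#' Run the full embedding and clustering pipeline
#'
#' Executes: [drop_empty_chromosomes] -> [filter_cells] -> [impute_ensemble]
#' -> [distance_sets] -> per-offset [reduce_offset] -> [stack_and_normalize]
#' -> [l1_distance] -> [embed_latent] -> [spectral_embed] -> [kmeans_pp],
#' scoring against ground-truth labels when the ensemble carries them.
#'
#' @param ensemble A [cell_ensemble].
#' @param params A [pipeline_params] object.
#' @return A list of class `schicdd_fit` with elements `cells`, `chroms`,
#'   `r`, `params`, embeddings `R`, `R_soft`, `S`, `V`, `C`, the k-means++
#'   `cluster`, and `scores` (NULL without labels).
#' @export
run_pipeline <- function(ensemble, params = pipeline_params()) {
  t0 <- Sys.time()
  ens <- drop_empty_chromosomes(ensemble, params$max_empty_frac)
  ens <- filter_cells(ens, params$min_total)
  imp_par <- imputation_params(kernel_size = params$kernel_size,
                               sigma = params$sigma, fast = params$fast,
                               neumann_order = params$neumann_order,
                               taylor_order = params$taylor_order,
                               bicubic_a = params$bicubic_a)
  imputed <- impute_ensemble(ens, imp_par, cores = params$cores)
  dsets <- distance_sets(imputed, zeta = params$zeta,
                         literal_last = params$literal_last,
                         cores = params$cores)
  U_blocks <- lapply(dsets, function(d) {
    reduce_offset(d$K, p = params$p, q = params$q, mds_mode = mds_mode_of(params))
  })
  l <- params$n_clusters %||% length(unique(ens$labels))
  if (l < 2) stop("n_clusters must be given when the ensemble has no labels")
  emb <- downstream_embed(U_blocks, params, l)
  cs <- cluster_and_score(emb, ens$cells, ens$labels, params, l)
  structure(list(cells = ens$cells, chroms = ens$chroms, r = imputed$r,
                 a = length(ens$cells), b = length(ens$chroms), l = l,
                 params = params, R = emb$R, R_soft = emb$R_soft, S = emb$S,
                 V = emb$V, C = emb$C, cluster = cs$cluster,
                 scores = cs$scores, labels = ens$labels,
                 elapsed = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
            class = "schicdd_fit")
}

#' @export
print.schicdd_fit <- function(x, ...) {
  cat(sprintf("schicdd_fit: a = %d cells, b = %d chromosomes, r = %d, l = %d\n",
              x$a, x$b, x$r, x$l))
  cat(sprintf("  zeta = %d, epsilon = %d, embedding = %s, fast = %s\n",
              x$params$zeta, x$params$epsilon, x$params$embedding, x$params$fast))
  if (!is.null(x$scores)) {
    cat(sprintf("  mean ARI = %.3f (sd %.3f), mean NMI = %.3f (sd %.3f) over %d repeats\n",
                x$scores$mean_ari, x$scores$sd_ari, x$scores$mean_nmi,
                x$scores$sd_nmi, x$scores$repeats))
  }
  cat(sprintf("  elapsed: %.1f s\n", x$elapsed))
  invisible(x)
}

#' Write pipeline outputs
#'
#' Writes `V.tsv`, `C.tsv`, predicted `labels.tsv`, `scores.json` (when
#' ground truth was available) and the resolved `config.yaml` into `dir`.
#'
#' @param fit A `schicdd_fit`.
#' @param dir Output directory (created if needed).
#' @export
write_results <- function(fit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_embedding(fit$V, fit$cells, file.path(dir, "V.tsv"))
  write_embedding(fit$C, fit$cells, file.path(dir, "C.tsv"))
  write_labels(stats::setNames(fit$cluster$cluster, fit$cells),
               file.path(dir, "labels.tsv"))
  if (!is.null(fit$scores)) write_scores(fit$scores, file.path(dir, "scores.json"))
  write_config(fit$params, file.path(dir, "config.yaml"))
  invisible(dir)
}

# Shared preparation for sweep: everything upstream of (zeta, epsilon).
prepare_offsets <- function(ensemble, params, zeta_max) {
  ens <- drop_empty_chromosomes(ensemble, params$max_empty_frac)
  ens <- filter_cells(ens, params$min_total)
  imp_par <- imputation_params(kernel_size = params$kernel_size,
                               sigma = params$sigma, fast = params$fast,
                               neumann_order = params$neumann_order,
                               taylor_order = params$taylor_order,
                               bicubic_a = params$bicubic_a)
  imputed <- impute_ensemble(ens, imp_par, cores = params$cores)
  dsets <- distance_sets(imputed, zeta = zeta_max,
                         literal_last = params$literal_last,
                         cores = params$cores)
  U_blocks <- lapply(dsets, function(d) {
    reduce_offset(d$K, p = params$p, q = params$q, mds_mode = mds_mode_of(params))
  })
  list(ens = ens, imputed = imputed, U_blocks = U_blocks)
}

#' Hyperparameter sweep over zeta and epsilon
#'
#' Computes the per-offset distance sets and their reductions once at
#' `max(zeta_grid)` and, for every `(zeta, epsilon)` grid cell, reruns only
#' the downstream stages (stacking, L1, latent MDS, spectral embedding,
#' clustering, scoring) with the same derived seeds as a fresh
#' [run_pipeline] at those values. Failures in individual cells are recorded
#' as `NA` rows, not aborts.
#'
#' @param ensemble A labeled [cell_ensemble].
#' @param params Baseline [pipeline_params].
#' @param zeta_grid,epsilon_grid Integer vectors of values to sweep.
#' @return data.frame with columns zeta, epsilon, mean_ari, sd_ari,
#'   mean_nmi, sd_nmi.
#' @export
sweep_hyperparams <- function(ensemble, params = pipeline_params(),
                              zeta_grid, epsilon_grid) {
  if (length(zeta_grid) == 0 || length(epsilon_grid) == 0) {
    stop("sweep grids must be nonempty")
  }
  prep <- prepare_offsets(ensemble, params, max(zeta_grid))
  l <- params$n_clusters %||% length(unique(prep$ens$labels))
  grid <- expand.grid(zeta = zeta_grid, epsilon = epsilon_grid)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    z <- grid$zeta[i]; e <- grid$epsilon[i]
    res <- tryCatch({
      pp <- params
      pp$zeta <- z; pp$epsilon <- e
      emb <- downstream_embed(prep$U_blocks[seq_len(z + 1)], pp, l)
      cs <- cluster_and_score(emb, prep$ens$cells, prep$ens$labels, pp, l)
      sc <- cs$scores
      data.frame(zeta = z, epsilon = e, mean_ari = sc$mean_ari,
                 sd_ari = sc$sd_ari, mean_nmi = sc$mean_nmi, sd_nmi = sc$sd_nmi)
    }, error = function(err) {
      warning(sprintf("sweep cell (zeta=%d, epsilon=%d) failed: %s",
                      z, e, conditionMessage(err)), call. = FALSE)
      data.frame(zeta = z, epsilon = e, mean_ari = NA_real_, sd_ari = NA_real_,
                 mean_nmi = NA_real_, sd_nmi = NA_real_)
    })
    res
  })
  do.call(rbind, rows)
}

#' Clustering accuracy versus number of chromosomes
#'
#' For each value in `b_values`, restricts the ensemble to its first `b`
#' chromosomes ([restrict_chromosomes]) and reruns the full pipeline.
#'
#' @param ensemble A labeled [cell_ensemble].
#' @param params A [pipeline_params] object.
#' @param b_values Integer vector of chromosome counts.
#' @return data.frame with columns b, mean_ari, sd_ari, mean_nmi, sd_nmi.
#' @export
chromosome_curve <- function(ensemble, params = pipeline_params(), b_values) {
  rows <- lapply(b_values, function(b) {
    fit <- run_pipeline(restrict_chromosomes(ensemble, b), params)
    sc <- fit$scores
    data.frame(b = b, mean_ari = sc$mean_ari, sd_ari = sc$sd_ari,
               mean_nmi = sc$mean_nmi, sd_nmi = sc$sd_nmi)
  })
  do.call(rbind, rows)
}
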