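# Labeled synthetic single-cell Hi-C ensembles: distance-decaying,
# TAD-block-structured, extremely sparse symmetric count matrices with
# cell-type structure planted by shifting block boundaries.

#' Specification for a synthetic single-cell Hi-C ensemble
#'
#' Cell types share a distance-decay background (contact probability
#' proportional to `(1 + |i - j|)^-decay_exponent`) overlaid with TAD-like
#' blocks of elevated self-contact; types differ by shifting the block
#' boundaries by `boundary_shift` bins per type. Each cell samples a fixed
#' number of contact pairs multinomially from its (noise-mixed) type
#' profile, giving exact per-cell count conservation.
#'
#' Defaults describe the strong-signal desk-scale study condition: 120
#' cells of 3 equally likely types over 4 chromosomes sized like mouse
#' chr1-chr4 at 1 Mb, 100,000 contacts per cell, 8 blocks per chromosome,
#' a 4-bin boundary shift between types, and no within-type noise.
#'
#' @param n_cells Number of cells a (default 120).
#' @param n_types Number of planted types l (default 3).
#' @param type_proportions Type probabilities summing to 1 (default equal).
#' @param chrom_sizes Integer vector of chromosome sizes in bins
#'   (default `c(196, 182, 160, 157)`, mouse chr1-chr4 at 1 Mb).
#' @param contacts_per_cell Sampled contact pairs per cell (default 1e5).
#' @param decay_exponent Distance-decay exponent gamma (default 1).
#' @param block_count TAD-like blocks per chromosome (default 8).
#' @param boundary_shift Bins by which consecutive types' block boundaries
#'   are shifted (default 4); 0 plants no type signal.
#' @param within_type_noise Mixing weight in `[0, 1]` of the mean profile
#'   into each cell's type profile (default 0).
#' @param block_boost Multiplicative contact enrichment inside blocks over
#'   the decay background (default 4).
#' @param seed RNG seed (default 1).
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_cells = 120, n_types = 3,
                           type_proportions = rep(1 / n_types, n_types),
                           chrom_sizes = c(196, 182, 160, 157),
                           contacts_per_cell = 1e5, decay_exponent = 1,
                           block_count = 8, boundary_shift = 4,
                           within_type_noise = 0, block_boost = 4, seed = 1) {
  if (n_cells < 2 || n_types < 1) stop("need n_cells >= 2 and n_types >= 1")
  if (abs(sum(type_proportions) - 1) > 1e-9) stop("type_proportions must sum to 1")
  if (length(type_proportions) != n_types) stop("one proportion per type required")
  if (any(chrom_sizes < 2)) stop("chromosome sizes must be >= 2 bins")
  if (contacts_per_cell < 0) stop("contacts_per_cell must be >= 0")
  if (within_type_noise < 0 || within_type_noise > 1) stop("within_type_noise in [0, 1]")
  if (block_count < 1) stop("block_count must be >= 1")
  names(chrom_sizes) <- names(chrom_sizes) %||% paste0("chr", seq_along(chrom_sizes))
  structure(list(n_cells = n_cells, n_types = n_types,
                 type_proportions = type_proportions, chrom_sizes = chrom_sizes,
                 contacts_per_cell = contacts_per_cell,
                 decay_exponent = decay_exponent, block_count = block_count,
                 boundary_shift = boundary_shift,
                 within_type_noise = within_type_noise,
                 block_boost = block_boost, seed = seed),
            class = "synthetic_spec")
}

#' Per-type, per-chromosome contact probability profiles
#'
#' Each profile is the normalized product of the distance-decay term and a
#' block enrichment pattern; type t shifts every interior block boundary by
#' `(t - 1) * boundary_shift` bins. Profiles are symmetric, nonnegative and
#' sum to 1 per chromosome.
#'
#' @param spec A [synthetic_spec].
#' @return List (types) of lists (chromosomes) of probability matrices.
#' @export
type_profiles <- function(spec) {
  smallest_block <- floor(min(spec$chrom_sizes) / spec$block_count)
  if (spec$boundary_shift >= smallest_block) {
    stop("boundary_shift = ", spec$boundary_shift,
         " must be smaller than the smallest block width (", smallest_block, " bins)")
  }
  lapply(seq_len(spec$n_types), function(t) {
    out <- lapply(spec$chrom_sizes, function(n) {
      decay <- (1 + abs(outer(seq_len(n), seq_len(n), "-")))^(-spec$decay_exponent)
      bounds <- round(seq(0, n, length.out = spec$block_count + 1))
      interior <- seq_along(bounds) != 1 & seq_along(bounds) != length(bounds)
      bounds[interior] <- pmin(bounds[interior] + (t - 1) * spec$boundary_shift, n)
      block_id <- findInterval(seq_len(n) - 0.5, bounds)
      same <- outer(block_id, block_id, "==")
      P <- decay * (1 + spec$block_boost * same)
      P / sum(P)
    })
    names(out) <- names(spec$chrom_sizes)
    out
  })
}

#' Sample a labeled synthetic cell ensemble
#'
#' Draws each cell's type from `type_proportions`, mixes the type profile
#' with the across-type mean profile at weight `within_type_noise`, allocates
#' `contacts_per_cell` contacts across chromosomes proportionally to
#' chromosome size, and samples contact pairs multinomially from the upper
#' triangle (diagonal included) of each chromosome profile. Counts are
#' mirrored into both triangles; the upper-triangle total per cell equals
#' `contacts_per_cell` exactly. Deterministic given `spec$seed`.
#'
#' @param spec A [synthetic_spec].
#' @return A [cell_ensemble] with planted labels (`"type1"`, ...) and the
#'   spec stored in attribute `"spec"`.
#' @export
sample_ensemble <- function(spec) {
  set.seed(spec$seed)
  profiles <- type_profiles(spec)
  mean_profile <- lapply(names(spec$chrom_sizes), function(k) {
    Reduce(`+`, lapply(profiles, `[[`, k)) / spec$n_types
  })
  names(mean_profile) <- names(spec$chrom_sizes)
  types <- sample.int(spec$n_types, spec$n_cells, replace = TRUE,
                      prob = spec$type_proportions)
  cells <- sprintf("cell%03d", seq_len(spec$n_cells))
  chroms <- names(spec$chrom_sizes)
  upper_probs <- function(P) {
    # pair-sampling probabilities over the upper triangle incl. diagonal
    Q <- 2 * P
    diag(Q) <- diag(P)
    Q[upper.tri(Q, diag = TRUE)]
  }
  maps <- lapply(seq_len(spec$n_cells), function(s) {
    t <- types[s]
    alloc <- if (spec$contacts_per_cell > 0) {
      as.vector(stats::rmultinom(1, spec$contacts_per_cell,
                                 prob = spec$chrom_sizes))
    } else rep(0L, length(chroms))
    out <- lapply(seq_along(chroms), function(ki) {
      n <- spec$chrom_sizes[[ki]]
      P <- (1 - spec$within_type_noise) * profiles[[t]][[ki]] +
        spec$within_type_noise * mean_profile[[ki]]
      A <- matrix(0, n, n)
      if (alloc[ki] > 0) {
        cnt <- as.vector(stats::rmultinom(1, alloc[ki], prob = upper_probs(P)))
        A[upper.tri(A, diag = TRUE)] <- cnt
        A <- A + t(A)
        diag(A) <- diag(A) / 2
      }
      A
    })
    names(out) <- chroms
    out
  })
  names(maps) <- cells
  labels <- stats::setNames(paste0("type", types), cells)
  ens <- cell_ensemble(maps, bin_size = 1e6, labels = labels)
  attr(ens, "spec") <- spec
  ens
}

#' End-to-end recovery experiment on synthetic data
#'
#' Samples an ensemble from `spec`, runs the full embedding pipeline, and
#' scores the clustering against the planted labels.
#'
#' @param spec A [synthetic_spec].
#' @param params A [pipeline_params] object.
#' @return The fitted pipeline object (see [run_pipeline]), whose `scores`
#'   element holds mean/sd ARI and NMI over the configured repeats.
#' @export
recovery_experiment <- function(spec, params = pipeline_params()) {
  ens <- sample_ensemble(spec)
  run_pipeline(ens, params)
}
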