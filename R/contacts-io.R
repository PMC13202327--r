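# Readers, writers and quality filters for per-cell intrachromosomal
# contact matrices held in a cell_ensemble.

#' Construct a cell ensemble
#'
#' A `cell_ensemble` bundles the a x b grid of per-cell, per-chromosome
#' intrachromosomal contact matrices at a fixed bin size, plus optional
#' ground-truth labels. Matrices must be square, symmetric, nonnegative
#' integer, and of identical dimension within a chromosome.
#'
#' @param maps Nested list: `maps[[cell_id]][[chrom_id]]` is a symmetric
#'   nonnegative integer matrix.
#' @param bin_size Bin size in base pairs (default 1 Mb).
#' @param labels Optional named character/integer vector of ground-truth
#'   labels, one per cell.
#' @return An object of class `cell_ensemble` with elements `cells`,
#'   `chroms`, `maps`, `bin_size`, `labels`.
#' @export
cell_ensemble <- function(maps, bin_size = 1e6, labels = NULL) {
  cells <- names(maps)
  if (is.null(cells) || length(cells) < 1) stop("maps must be a named list of cells")
  chroms <- names(maps[[1]])
  dims <- vapply(maps[[1]], nrow, 0L)
  for (s in cells) {
    if (!identical(names(maps[[s]]), chroms)) {
      stop("every cell must carry the same ordered chromosome set")
    }
    for (k in chroms) {
      A <- maps[[s]][[k]]
      stopifnot_square(A, sprintf("map (%s, %s)", s, k))
      if (nrow(A) != dims[[k]]) stop("matrix dimension varies within chromosome ", k)
      if (any(A < 0) || any(A != round(A))) {
        stop(sprintf("map (%s, %s) must hold nonnegative integers", s, k))
      }
      if (!isSymmetric(unname(A), tol = 0)) {
        stop(sprintf("map (%s, %s) is not symmetric", s, k))
      }
    }
  }
  if (!is.null(labels)) {
    if (is.null(names(labels))) names(labels) <- cells
    if (!all(cells %in% names(labels))) stop("labels must cover every cell")
    labels <- labels[cells]
  }
  structure(
    list(cells = cells, chroms = chroms, maps = maps,
         bin_size = bin_size, labels = labels),
    class = "cell_ensemble"
  )
}

#' @export
print.cell_ensemble <- function(x, ...) {
  dims <- vapply(x$maps[[1]], nrow, 0L)
  cat(sprintf("cell_ensemble: %d cells x %d chromosomes at %s bp bins\n",
              length(x$cells), length(x$chroms), format(x$bin_size, big.mark = ",")))
  cat("  bins per chromosome:", paste(sprintf("%s=%d", x$chroms, dims), collapse = ", "), "\n")
  if (!is.null(x$labels)) {
    cat("  labels:", paste(names(table(x$labels)), table(x$labels), sep = ":", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Number of bins per chromosome
#' @param ensemble A `cell_ensemble`.
#' @return Named integer vector of matrix dimensions n_k.
#' @export
chrom_bins <- function(ensemble) {
  vapply(ensemble$maps[[1]], nrow, 0L)
}

# Fold a possibly one-triangle or contradictory matrix into an exactly
# symmetric one: already-symmetric input is kept; otherwise upper and lower
# triangles are summed into both (diagonal counted once), warning when both
# triangles held contradictory mass.
symmetrize_counts <- function(M, context = "") {
  if (isSymmetric(unname(M), tol = 0)) return(M)
  up <- M[upper.tri(M)]
  lo <- t(M)[upper.tri(M)]
  if (any(up > 0 & lo > 0 & up != lo)) {
    warning("asymmetric counts", context, ": summing upper and lower triangles",
            call. = FALSE)
  }
  S <- M + t(M)
  diag(S) <- diag(M)
  S
}

build_map_from_triplets <- function(bin_i, bin_j, count, n) {
  M <- matrix(0, n, n)
  # accumulate duplicates
  idx <- cbind(bin_i + 1L, bin_j + 1L)
  for (r in seq_along(count)) M[idx[r, 1], idx[r, 2]] <- M[idx[r, 1], idx[r, 2]] + count[r]
  symmetrize_counts(M)
}

#' Read per-cell intrachromosomal contact matrices
#'
#' Ingests single-cell Hi-C contacts from one of four dialects and assembles a
#' [cell_ensemble] of symmetric integer count matrices at `bin_size`
#' resolution. Higher-resolution input is re-binned by summing counts into the
#' coarser bins; interchromosomal (trans) contacts are discarded.
#'
#' Formats:
#' \describe{
#'   \item{`triplets`}{`path` is a directory of one whitespace-delimited file
#'     per cell with columns `chrom  bin_i  bin_j  count` (0-based bins at
#'     `input_bin_size`).}
#'   \item{`pairs`}{`path` is a directory of 4DN-style `.pairs` files (one per
#'     cell; comment lines start with `#`) with columns
#'     `readID chrom1 pos1 chrom2 pos2 ...`; positions are binned as
#'     `floor(pos / bin_size)`.}
#'   \item{`cool` / `scool`}{single- and multi-cell cooler HDF5 containers.}
#' }
#'
#' @param path File (`cool`/`scool`) or directory (`triplets`/`pairs`).
#' @param format One of `"triplets"`, `"pairs"`, `"cool"`, `"scool"`.
#' @param bin_size Target bin size in bp (default 1e6).
#' @param input_bin_size Bin size of triplet input (default `bin_size`); must
#'   divide `bin_size`.
#' @param chrom_sizes Optional named vector of chromosome lengths in bp; when
#'   absent, dimensions are inferred from the largest observed bin.
#' @param keep_sex Keep sex/mitochondrial chromosomes (default `FALSE`).
#' @param labels Optional path to a two-column TSV (cell_id, label).
#' @return A [cell_ensemble].
#' @export
read_contacts <- function(path, format = c("triplets", "pairs", "cool", "scool"),
                          bin_size = 1e6, input_bin_size = bin_size,
                          chrom_sizes = NULL, keep_sex = FALSE, labels = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file or directory: ", path)
  recs <- switch(format,
    triplets = read_triplet_dir(path, bin_size, input_bin_size),
    pairs    = read_pairs_dir(path, bin_size),
    cool     = read_cooler(path, bin_size, single_cell = FALSE),
    scool    = read_cooler(path, bin_size, single_cell = TRUE)
  )
  if (is.null(chrom_sizes)) chrom_sizes <- attr(recs, "chrom_sizes")
  ens <- assemble_ensemble(recs, bin_size, chrom_sizes, keep_sex)
  if (!is.null(labels)) ens$labels <- read_labels(labels)[ens$cells]
  ens
}

# recs: list of per-cell data.tables with columns chrom, bin_i, bin_j, count
assemble_ensemble <- function(recs, bin_size, chrom_sizes, keep_sex) {
  chroms <- unique(unlist(lapply(recs, function(d) unique(d$chrom))))
  if (!is.null(chrom_sizes)) chroms <- union(chroms, names(chrom_sizes))
  if (!keep_sex) chroms <- chroms[!is_sex_chrom(chroms)]
  chroms <- natural_chrom_sort(chroms)
  if (length(chroms) == 0) stop("no chromosomes retained from input")
  if (is.null(chrom_sizes)) {
    n_bins <- vapply(chroms, function(k) {
      mx <- suppressWarnings(max(unlist(lapply(recs, function(d) {
        dd <- d[d$chrom == k, ]
        if (nrow(dd)) max(dd$bin_i, dd$bin_j) else -Inf
      }))))
      as.integer(mx + 1L)
    }, 0L)
  } else {
    n_bins <- vapply(chroms, function(k) {
      as.integer(ceiling(chrom_sizes[[k]] / bin_size))
    }, 0L)
  }
  maps <- lapply(recs, function(d) {
    out <- lapply(chroms, function(k) {
      dd <- d[d$chrom == k, ]
      build_map_from_triplets(dd$bin_i, dd$bin_j, dd$count, n_bins[[k]])
    })
    names(out) <- chroms
    out
  })
  cell_ensemble(maps, bin_size = bin_size)
}

read_triplet_dir <- function(path, bin_size, input_bin_size) {
  if (!dir.exists(path)) stop("triplets format expects a directory of per-cell files")
  f <- bin_size / input_bin_size
  if (f < 1 || f != round(f)) stop("input_bin_size must divide bin_size")
  files <- list.files(path, pattern = "\\.(tsv|txt|triplets)$", full.names = TRUE)
  if (length(files) == 0) stop("no triplet files (*.tsv, *.txt, *.triplets) in ", path)
  recs <- lapply(files, function(fp) {
    d <- tryCatch(
      data.table::fread(fp, header = FALSE, col.names = c("chrom", "bin_i", "bin_j", "count")),
      error = function(e) stop("cannot parse triplet file ", fp, ": ", conditionMessage(e),
                               call. = FALSE)
    )
    if (!is.numeric(d$bin_i) || !is.numeric(d$bin_j) || !is.numeric(d$count)) {
      stop("malformed triplet file ", fp, ": bins and counts must be numeric", call. = FALSE)
    }
    d$bin_i <- d$bin_i %/% f
    d$bin_j <- d$bin_j %/% f
    d
  })
  names(recs) <- sub("\\.(tsv|txt|triplets)$", "", basename(files))
  recs
}

read_pairs_dir <- function(path, bin_size) {
  if (!dir.exists(path)) stop("pairs format expects a directory of per-cell files")
  files <- list.files(path, pattern = "\\.pairs$", full.names = TRUE)
  if (length(files) == 0) stop("no *.pairs files in ", path)
  recs <- lapply(files, function(fp) {
    ln <- readLines(fp)
    ln <- ln[!startsWith(ln, "#")] # header/comment lines
    if (length(ln) == 0) stop("pairs file ", fp, " holds no records", call. = FALSE)
    d <- tryCatch(
      data.table::fread(text = ln, header = FALSE, fill = TRUE),
      error = function(e) stop("cannot parse pairs file ", fp, ": ", conditionMessage(e),
                               call. = FALSE)
    )
    if (ncol(d) < 5) stop("pairs file ", fp, " needs columns readID chrom1 pos1 chrom2 pos2",
                          call. = FALSE)
    cis <- d[[2]] == d[[4]]
    d <- d[cis, ]
    bi <- as.numeric(d[[3]]) %/% bin_size
    bj <- as.numeric(d[[5]]) %/% bin_size
    dt <- data.table::data.table(
      chrom = as.character(d[[2]]),
      bin_i = pmin(bi, bj), bin_j = pmax(bi, bj), count = 1
    )
    dt[, list(count = sum(count)), by = c("chrom", "bin_i", "bin_j")]
  })
  names(recs) <- sub("\\.pairs$", "", basename(files))
  recs
}

# Cooler/scool readers built on rhdf5. Pixel bin ids are container-global;
# they are mapped to per-chromosome bins and re-binned to the target bin size.
read_cooler <- function(path, bin_size, single_cell) {
  if (dir.exists(path)) stop("cool/scool format expects an HDF5 file, not a directory")
  roots <- if (single_cell) {
    cells <- tryCatch(rhdf5::h5ls(path, recursive = 2), error = function(e)
      stop("cannot open ", path, " as HDF5: ", conditionMessage(e), call. = FALSE))
    nm <- cells$name[cells$group == "/cells"]
    if (length(nm) == 0) stop("no /cells groups in scool file ", path)
    stats::setNames(paste0("/cells/", nm), nm)
  } else {
    stats::setNames("", sub("\\.(cool|mcool)$", "", basename(path)))
  }
  recs <- lapply(roots, function(root) read_cooler_cell(path, root, bin_size))
  # chromosome lengths are recorded in the container; carry them so empty
  # trailing bins are not truncated
  root1 <- roots[[1]]
  lens <- as.numeric(rhdf5::h5read(path, paste0(root1, "/chroms/length")))
  nms <- as.character(rhdf5::h5read(path, paste0(root1, "/chroms/name")))
  rhdf5::h5closeAll()
  attr(recs, "chrom_sizes") <- stats::setNames(lens, nms)
  recs
}

read_cooler_cell <- function(path, root, bin_size) {
  g <- function(name) rhdf5::h5read(path, paste0(root, name))
  chrom_names <- as.character(g("/chroms/name"))
  bchrom <- g("/bins/chrom")
  bchrom <- if (is.numeric(bchrom)) chrom_names[bchrom + 1L] else as.character(bchrom)
  bstart <- as.numeric(g("/bins/start"))
  b1 <- as.numeric(g("/pixels/bin1_id"))
  b2 <- as.numeric(g("/pixels/bin2_id"))
  cnt <- as.numeric(g("/pixels/count"))
  cis <- bchrom[b1 + 1L] == bchrom[b2 + 1L]
  dt <- data.table::data.table(
    chrom = bchrom[b1 + 1L][cis],
    bin_i = bstart[b1 + 1L][cis] %/% bin_size,
    bin_j = bstart[b2 + 1L][cis] %/% bin_size,
    count = cnt[cis]
  )
  dt[, list(count = sum(count)), by = c("chrom", "bin_i", "bin_j")]
}

#' Write an ensemble to a single-cell cooler (scool) container
#'
#' Writes the standard scool HDF5 layout: per-cell groups
#' `cells/<cell_id>/{chroms,bins,pixels}` with upper-triangle pixels.
#'
#' @param ensemble A [cell_ensemble].
#' @param path Output file path (overwritten).
#' @return `path`, invisibly.
#' @export
write_scool <- function(ensemble, path) {
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  n_bins <- chrom_bins(ensemble)
  bs <- ensemble$bin_size
  rhdf5::h5createGroup(path, "cells")
  for (s in ensemble$cells) {
    root <- paste0("cells/", s)
    rhdf5::h5createGroup(path, root)
    for (sub in c("chroms", "bins", "pixels")) rhdf5::h5createGroup(path, paste0(root, "/", sub))
    rhdf5::h5write(ensemble$chroms, path, paste0(root, "/chroms/name"))
    rhdf5::h5write(as.numeric(n_bins) * bs, path, paste0(root, "/chroms/length"))
    offs <- c(0L, cumsum(n_bins))
    bchrom <- rep(seq_along(ensemble$chroms) - 1L, n_bins)
    bstart <- unlist(lapply(n_bins, function(n) (seq_len(n) - 1) * bs), use.names = FALSE)
    rhdf5::h5write(as.integer(bchrom), path, paste0(root, "/bins/chrom"))
    rhdf5::h5write(bstart, path, paste0(root, "/bins/start"))
    rhdf5::h5write(bstart + bs, path, paste0(root, "/bins/end"))
    b1 <- integer(0); b2 <- integer(0); cnt <- numeric(0)
    for (ki in seq_along(ensemble$chroms)) {
      A <- ensemble$maps[[s]][[ki]]
      ut <- which(upper.tri(A, diag = TRUE) & A > 0, arr.ind = TRUE)
      b1 <- c(b1, offs[ki] + ut[, 1] - 1L)
      b2 <- c(b2, offs[ki] + ut[, 2] - 1L)
      cnt <- c(cnt, A[ut])
    }
    o <- order(b1, b2)
    rhdf5::h5write(as.integer(b1[o]), path, paste0(root, "/pixels/bin1_id"))
    rhdf5::h5write(as.integer(b2[o]), path, paste0(root, "/pixels/bin2_id"))
    rhdf5::h5write(cnt[o], path, paste0(root, "/pixels/count"))
  }
  rhdf5::h5closeAll()
  invisible(path)
}

#' Write an ensemble as per-cell triplet text files
#'
#' One file per cell, upper triangle (including the diagonal), 0-based bins,
#' columns `chrom  bin_i  bin_j  count`.
#'
#' @param ensemble A [cell_ensemble].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_triplets <- function(ensemble, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in ensemble$cells) {
    rows <- lapply(ensemble$chroms, function(k) {
      A <- ensemble$maps[[s]][[k]]
      ut <- which(upper.tri(A, diag = TRUE) & A > 0, arr.ind = TRUE)
      if (nrow(ut) == 0) return(NULL)
      data.frame(chrom = k, bin_i = ut[, 1] - 1L, bin_j = ut[, 2] - 1L, count = A[ut])
    })
    d <- do.call(rbind, rows)
    if (is.null(d)) d <- data.frame(chrom = character(), bin_i = integer(),
                                    bin_j = integer(), count = numeric())
    utils::write.table(d, file.path(dir, paste0(s, ".tsv")), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(dir)
}

#' Read / write a cell label table
#'
#' Two-column tab-separated text: cell_id, label. No header.
#'
#' @param path File path.
#' @return Named character vector of labels.
#' @export
read_labels <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("cell_id", "label"),
                         colClasses = "character")
  stats::setNames(d$label, d$cell_id)
}

#' @rdname read_labels
#' @param labels Named vector of labels.
#' @export
write_labels <- function(labels, path) {
  utils::write.table(data.frame(cell_id = names(labels), label = unname(labels)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

# Off-diagonal coverage of a symmetric map, counting each unordered contact
# pair once (upper triangle).
off_diagonal_sum <- function(A) sum(A[upper.tri(A)])
off_diagonal_nonzero <- function(A) sum(A[upper.tri(A)] > 0)

subset_cells <- function(ensemble, keep) {
  cell_ensemble(ensemble$maps[keep], bin_size = ensemble$bin_size,
                labels = if (!is.null(ensemble$labels)) ensemble$labels[keep])
}

#' Remove low-coverage cells
#'
#' Drops a cell when the sum of its off-diagonal contact counts (each
#' unordered bin pair counted once) over all intrachromosomal maps is below
#' `min_total`, and additionally when any
#' single chromosome's map of dimension `x` bins has an off-diagonal sum
#' below `x` (the per-chromosome coverage rule; such a cell is removed
#' entirely).
#'
#' @param ensemble A [cell_ensemble].
#' @param min_total Minimum per-cell off-diagonal total (default 5000); cells
#'   at exactly the threshold are retained.
#' @param count_mode `"sum"` (default) compares summed counts; `"nonzero"`
#'   compares the number of nonzero off-diagonal entries instead.
#' @return Filtered [cell_ensemble] (input untouched) with a
#'   `"filter_report"` attribute: data.frame(cell_id, status, reason).
#' @export
filter_cells <- function(ensemble, min_total = 5000, count_mode = c("sum", "nonzero")) {
  count_mode <- match.arg(count_mode)
  f <- if (count_mode == "sum") off_diagonal_sum else off_diagonal_nonzero
  n_bins <- chrom_bins(ensemble)
  status <- character(length(ensemble$cells))
  reason <- character(length(ensemble$cells))
  for (i in seq_along(ensemble$cells)) {
    s <- ensemble$cells[i]
    per_chrom <- vapply(ensemble$maps[[s]], f, 0)
    if (any(per_chrom < n_bins)) {
      k <- ensemble$chroms[which(per_chrom < n_bins)[1]]
      status[i] <- "removed"
      reason[i] <- sprintf("chromosome %s off-diagonal sum %g < %d bins",
                           k, per_chrom[[k]], n_bins[[k]])
    } else if (sum(per_chrom) < min_total) {
      status[i] <- "removed"
      reason[i] <- sprintf("total off-diagonal sum %g < %g", sum(per_chrom), min_total)
    } else {
      status[i] <- "retained"
      reason[i] <- ""
    }
  }
  report <- data.frame(cell_id = ensemble$cells, status = status, reason = reason)
  keep <- ensemble$cells[status == "retained"]
  if (length(keep) == 0) stop("cell filter removed every cell")
  out <- subset_cells(ensemble, keep)
  attr(out, "filter_report") <- report
  out
}

#' Drop chromosomes with too many empty maps
#'
#' A chromosome is dropped (for every cell) when the fraction of cells whose
#' map for it is all-zero exceeds `max_empty_frac`; exactly at the threshold
#' it is kept.
#'
#' @param ensemble A [cell_ensemble].
#' @param max_empty_frac Maximum tolerated empty fraction (default 0.10).
#' @return Filtered [cell_ensemble].
#' @export
drop_empty_chromosomes <- function(ensemble, max_empty_frac = 0.10) {
  empty_frac <- vapply(ensemble$chroms, function(k) {
    mean(vapply(ensemble$cells, function(s) all(ensemble$maps[[s]][[k]] == 0), TRUE))
  }, 0)
  keep <- ensemble$chroms[empty_frac <= max_empty_frac]
  if (length(keep) == 0) stop("all chromosomes exceeded the empty-map fraction")
  if (length(keep) == length(ensemble$chroms)) return(ensemble)
  maps <- lapply(ensemble$maps, function(m) m[keep])
  cell_ensemble(maps, bin_size = ensemble$bin_size, labels = ensemble$labels)
}

#' Keep only the first b chromosomes
#'
#' Restricts the ensemble to the first `b_keep` chromosomes in its (natural
#' sort) chromosome ordering, e.g. `b_keep = 4` keeps chr1-chr4.
#'
#' @param ensemble A [cell_ensemble].
#' @param b_keep Number of leading chromosomes to keep.
#' @return Restricted [cell_ensemble].
#' @export
restrict_chromosomes <- function(ensemble, b_keep) {
  b <- length(ensemble$chroms)
  if (b_keep < 1 || b_keep > b) stop("b_keep must lie in [1, ", b, "]")
  if (b_keep == b) return(ensemble)
  keep <- ensemble$chroms[seq_len(b_keep)]
  maps <- lapply(ensemble$maps, function(m) m[keep])
  cell_ensemble(maps, bin_size = ensemble$bin_size, labels = ensemble$labels)
}

#' Write the cell filter report
#' @param ensemble A filtered ensemble carrying a `"filter_report"` attribute.
#' @param path Output TSV path.
#' @export
write_filter_report <- function(ensemble, path) {
  rep <- attr(ensemble, "filter_report")
  if (is.null(rep)) stop("ensemble carries no filter report; run filter_cells() first")
  utils::write.table(rep, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
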