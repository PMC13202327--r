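#' @keywords internal
"_PACKAGE"

# let data.table syntax work inside this package without importing its
# full namespace
.datatable.aware <- TRUE

#' Natural-sort chromosome names
#'
#' Orders chromosome identifiers so that `chr2` precedes `chr10`, numeric
#' chromosomes precede the sex/mitochondrial ones, and the `chr` prefix is
#' optional.
#'
#' @param chroms Character vector of chromosome names.
#' @return `chroms` reordered.
#' @examples
#' natural_chrom_sort(c("chr10", "chr2", "chrX", "chr1"))
#' @export
natural_chrom_sort <- function(chroms) {
  stripped <- sub("^chr", "", chroms, ignore.case = TRUE)
  num <- suppressWarnings(as.numeric(stripped))
  # non-numeric chromosomes (X, Y, M, ...) sort after autosomes, alphabetically
  key1 <- ifelse(is.na(num), 1L, 0L)
  ord <- order(key1, num, stripped)
  chroms[ord]
}

is_sex_chrom <- function(chroms) {
  grepl("^(chr)?(x|y|m|mt|w|z)$", chroms, ignore.case = TRUE)
}

#' Derive a reproducible stream seed
#'
#' Deterministically maps a master seed plus a stage label (and optional
#' repeat index) to a 31-bit seed, so that independent pipeline stages and
#' repeats draw from reproducible but distinct RNG streams.
#'
#' @param master Integer master seed.
#' @param stage Character label of the consuming stage.
#' @param index Optional nonnegative integer (repeat number).
#' @return A single integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, stage, index = 0L) {
  m <- 2147483647 # 2^31 - 1, keeps exact integer arithmetic in doubles
  h <- as.numeric(master) %% m
  for (c in utf8ToInt(as.character(stage))) h <- (h * 31 + c) %% m
  h <- (h + 1000003 * as.numeric(index)) %% m
  as.integer(h)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stopifnot_square <- function(M, what = "matrix") {
  if (!is.matrix(M) || nrow(M) != ncol(M)) {
    stop(sprintf("%s must be a square matrix", what), call. = FALSE)
  }
}
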