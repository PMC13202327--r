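test_that("triplet records are mirrored into a symmetric matrix", {
  dir <- withr::local_tempdir()
  writeLines("chr1\t3\t7\t2", file.path(dir, "cellA.tsv"))
  ens <- read_contacts(dir, format = "triplets")
  A <- ens$maps$cellA$chr1
  expect_equal(A[4, 8], 2)
  expect_equal(A[8, 4], 2)
  expect_true(isSymmetric(A))
  expect_equal(sum(A), 4)
})

test_that("contradictory triangles are summed into both with a warning", {
  dir <- withr::local_tempdir()
  writeLines(c("chr1\t0\t1\t3", "chr1\t1\t0\t5"), file.path(dir, "c.tsv"))
  expect_warning(ens <- read_contacts(dir, format = "triplets"), "asymmetric")
  expect_equal(ens$maps$c$chr1[1, 2], 8)
  expect_equal(ens$maps$c$chr1[2, 1], 8)
})

test_that("higher-resolution input re-bins by summing and conserves counts", {
  dir <- withr::local_tempdir()
  # 100 kb bins 0..9 all fall in 1 Mb bin 0
  set.seed(1)
  recs <- data.frame(chrom = "chr1",
                     i = sample(0:9, 20, TRUE), j = sample(0:9, 20, TRUE),
                     count = sample(1:5, 20, TRUE))
  recs[c("i", "j")] <- list(pmin(recs$i, recs$j), pmax(recs$i, recs$j))
  recs <- aggregate(count ~ chrom + i + j, recs, sum)
  write.table(recs[, c("chrom", "i", "j", "count")], file.path(dir, "c.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  ens <- read_contacts(dir, format = "triplets", bin_size = 1e6, input_bin_size = 1e5)
  A <- ens$maps$c$chr1
  expect_equal(dim(A), c(1, 1))
  expect_equal(A[1, 1], sum(recs$count))
})

test_that("pairs files are binned by position and trans contacts dropped", {
  dir <- withr::local_tempdir()
  writeLines(c("## pairs format v1.0",
               "r1\tchr1\t1500000\tchr1\t3500000\t+\t-",
               "r2\tchr1\t3500001\tchr1\t1500001\t+\t-",
               "r3\tchr1\t100\tchr2\t100\t+\t-"),
             file.path(dir, "cell1.pairs"))
  ens <- read_contacts(dir, format = "pairs", bin_size = 1e6,
                       chrom_sizes = c(chr1 = 5e6))
  A <- ens$maps$cell1$chr1
  expect_equal(nrow(A), 5)
  expect_equal(A[2, 4], 2) # both cis reads land in bins 1 and 3 (0-based)
  expect_equal(sum(A), 4)
  expect_false("chr2" %in% ens$chroms) # only appeared in a trans pair
})

test_that("an scool container written by the package round-trips entrywise", {
  maps <- list(
    cellA = list(chr1 = random_sym_count(6, 1), chr2 = random_sym_count(4, 2)),
    cellB = list(chr1 = random_sym_count(6, 3), chr2 = random_sym_count(4, 4))
  )
  ens <- manual_ensemble(maps)
  f <- withr::local_tempfile(fileext = ".scool")
  write_scool(ens, f)
  back <- read_contacts(f, format = "scool")
  expect_identical(back$cells, ens$cells)
  expect_identical(back$chroms, ens$chroms)
  for (s in ens$cells) for (k in ens$chroms) {
    expect_equal(back$maps[[s]][[k]], ens$maps[[s]][[k]],
                 ignore_attr = TRUE)
  }
})

test_that("triplet writer round-trips through the triplet reader", {
  ens <- tiny_ensemble(n_cells = 3, contacts_per_cell = 500)
  dir <- withr::local_tempdir()
  write_triplets(ens, dir)
  back <- read_contacts(dir, format = "triplets",
                        chrom_sizes = chrom_bins(ens) * ens$bin_size)
  for (s in ens$cells) for (k in ens$chroms) {
    expect_equal(back$maps[[s]][[k]], ens$maps[[s]][[k]], ignore_attr = TRUE)
  }
})

test_that("cell filter applies the 5000-count boundary inclusively", {
  ens <- coverage_ensemble(c(4999, 5000, 8000))
  out <- filter_cells(ens)
  expect_identical(out$cells, c("cell2", "cell3"))
  rep <- attr(out, "filter_report")
  expect_identical(rep$status, c("removed", "retained", "retained"))
  expect_match(rep$reason[1], "4999")
})

test_that("a chromosome under its per-bin coverage floor removes the whole cell", {
  n <- 50
  weak <- matrix(0, n, n); weak[1, 2] <- weak[2, 1] <- 49
  ok <- matrix(0, n, n); ok[1, 2] <- ok[2, 1] <- 50
  strong <- random_sym_count(30, 9, lambda = 20) # plenty of contacts
  maps <- list(cellA = list(chr1 = weak, chr2 = strong),
               cellB = list(chr1 = ok, chr2 = strong))
  out <- filter_cells(manual_ensemble(maps), min_total = 0)
  expect_identical(out$cells, "cellB")
  expect_match(attr(out, "filter_report")$reason[1], "chr1")
})

test_that("cell filtering is idempotent and errors when nothing survives", {
  ens <- coverage_ensemble(c(6000, 7000))
  once <- filter_cells(ens)
  twice <- filter_cells(once)
  expect_identical(twice$maps, once$maps)
  expect_error(filter_cells(coverage_ensemble(c(10, 20))), "every cell")
})

test_that("empty-chromosome drop uses a strict 10% boundary", {
  n_cells <- 100
  zero <- matrix(0, 4, 4)
  some <- random_sym_count(4, 5)
  build <- function(n_empty) {
    maps <- lapply(seq_len(n_cells), function(i) {
      list(chr1 = some,
           chr2 = if (i <= n_empty) zero else some)
    })
    names(maps) <- paste0("c", seq_len(n_cells))
    manual_ensemble(maps)
  }
  expect_identical(drop_empty_chromosomes(build(11))$chroms, "chr1") # 11% > 10%
  kept <- drop_empty_chromosomes(build(10)) # exactly 10%: kept
  expect_identical(kept$chroms, c("chr1", "chr2"))
  none <- drop_empty_chromosomes(build(0))
  expect_identical(none$maps, build(0)$maps)
  all_empty <- manual_ensemble(list(c1 = list(chr1 = zero), c2 = list(chr1 = zero)))
  expect_error(drop_empty_chromosomes(all_empty), "all chromosomes")
})

test_that("restrict_chromosomes keeps a natural-sorted prefix", {
  maps <- lapply(1:3, function(i) {
    m <- lapply(1:4, function(k) random_sym_count(5, i * 10 + k))
    names(m) <- c("chr1", "chr2", "chr3", "chr4")
    m
  })
  names(maps) <- paste0("c", 1:3)
  ens <- manual_ensemble(maps)
  expect_identical(restrict_chromosomes(ens, 2)$chroms, c("chr1", "chr2"))
  expect_identical(restrict_chromosomes(ens, 4)$maps, ens$maps)
  expect_error(restrict_chromosomes(ens, 5), "b_keep")
  expect_error(restrict_chromosomes(ens, 0), "b_keep")
})

test_that("chromosome names natural-sort and sex chromosomes are optional", {
  expect_identical(natural_chrom_sort(c("chr10", "chr2", "chrX", "chr1")),
                   c("chr1", "chr2", "chr10", "chrX"))
  dir <- withr::local_tempdir()
  writeLines(c("chr2\t0\t1\t1", "chr10\t0\t1\t1", "chrX\t0\t1\t1", "chr1\t0\t1\t1"),
             file.path(dir, "c.tsv"))
  expect_identical(read_contacts(dir, format = "triplets")$chroms,
                   c("chr1", "chr2", "chr10"))
  expect_identical(read_contacts(dir, format = "triplets", keep_sex = TRUE)$chroms,
                   c("chr1", "chr2", "chr10", "chrX"))
})

test_that("labels round-trip as TSV", {
  labs <- c(cell1 = "typeA", cell2 = "typeB")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_labels(labs, f)
  expect_identical(read_labels(f), labs)
})
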