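gmat <- function(...) {
  rows <- list(...)
  do.call(rbind, rows)
}

test_that("biallelic cell fraction implements the counting rules", {
  # all cells heterozygous on one variant, diploid 17p: no biallelic cell
  g <- matrix("HET", 1, 50, dimnames = list("mutA", NULL))
  expect_equal(biallelicCellFraction(CellGenotypeMatrix(g)), 0)
  # 32 of 100 cells carry both variants
  g <- matrix("WT", 2, 100, dimnames = list(c("mutA", "mutB"), NULL))
  g[, 1:32] <- "HET"
  expect_equal(biallelicCellFraction(CellGenotypeMatrix(g)), 0.32)
  # 10 of 100 cells HET with 17p loss (hemizygous rule)
  g <- matrix("WT", 1, 100, dimnames = list("mutA", NULL))
  g[, 1:10] <- "HET"
  cn <- rep(2L, 100); cn[1:10] <- 1L
  expect_equal(biallelicCellFraction(CellGenotypeMatrix(g, cn17p = cn)), 0.10)
  # any HOM_OR_HEMI call is biallelic
  g <- matrix(c("HOM_OR_HEMI", rep("WT", 19)), 1, 20,
              dimnames = list("mutA", NULL))
  expect_equal(biallelicCellFraction(CellGenotypeMatrix(g)), 0.05)
  # MISSING treated as WT; dropout-corrected estimate attached on request
  g <- matrix("MISSING", 2, 10, dimnames = list(c("mutA", "mutB"), NULL))
  g[, 1] <- "HET"
  raw <- biallelicCellFraction(CellGenotypeMatrix(g), dropout = 0.1)
  expect_equal(as.numeric(raw), 0.1)
  expect_equal(attr(raw, "dropout_corrected"), 0.1 / 0.81)
})

test_that("biallelic fraction is permutation invariant and bounded", {
  sc <- simulateSingleCellMatrix(
    cloneArchitecture(0.4, "mutA", "mutB", "compound_het"), 500,
    dropout = 0.2, error = 0.01, seed = 3)
  g <- SummarizedExperiment::assay(sc$matrix, "genotype")
  f0 <- biallelicCellFraction(sc$matrix)
  perm <- CellGenotypeMatrix(g[rev(seq_len(nrow(g))), sample(ncol(g))])
  expect_equal(biallelicCellFraction(perm), f0)
  mutant_frac <- mean(colSums(g != "WT" & g != "MISSING") > 0)
  expect_lte(f0, mutant_frac)
})

test_that("biallelic fraction matches the simulated clone fraction", {
  for (seed in 1:5) {
    f <- runif(1, 0.1, 0.6)
    sc <- simulateSingleCellMatrix(
      cloneArchitecture(f, "mutA", "mutB", "compound_het"), 2000,
      dropout = 0, error = 0, seed = seed)
    se <- sqrt(f * (1 - f) / 2000)
    expect_lt(abs(biallelicCellFraction(sc$matrix) - f), 3 * se + 1e-9)
  }
})

test_that("clone decomposition groups cells by genotype signature", {
  # one pure clone
  sc <- simulateSingleCellMatrix(
    cloneArchitecture(1.0, "mutA", "wt", "het_mono"), 300,
    dropout = 0, error = 0, seed = 5)
  dc <- decomposeClones(sc$matrix)
  expect_equal(nrow(dc$clones), 1)
  expect_equal(dc$clones$fraction, 1)
  # mosaic without noise: exactly two mutant clones plus wild-type background
  sc2 <- simulateSingleCellMatrix(
    cloneArchitecture(c(0.3, 0.3), c("mutA", "mutB"), c("wt", "wt"),
                      "mosaic_two_mono"), 2000, dropout = 0, error = 0,
    seed = 7)
  dc2 <- decomposeClones(sc2$matrix, min_cells = 5)
  expect_equal(nrow(dc2$clones), 3)
  mutant_sigs <- grepl("HET", dc2$clones$signature)
  expect_equal(sum(mutant_sigs), 2)
  # threshold larger than the matrix: everything unassigned
  dc3 <- decomposeClones(sc$matrix, min_cells = 1000)
  expect_equal(nrow(dc3$clones), 0)
  expect_equal(dc3$n_unassigned, 300)
})

test_that("mosaic vs biallelic verdicts follow co-occurrence evidence", {
  comp <- simulateSingleCellMatrix(
    cloneArchitecture(0.3, "mutA", "mutB", "compound_het"), 600,
    dropout = 0.1, error = 0.01, seed = 11)
  v1 <- mosaicVsBiallelic(comp$matrix)
  expect_equal(v1$verdict, "biallelic")
  mos <- simulateSingleCellMatrix(
    cloneArchitecture(c(0.25, 0.25), c("mutA", "mutB"), c("wt", "wt"),
                      "mosaic_two_mono"), 600, dropout = 0.1, error = 0.01,
    seed = 13)
  v2 <- mosaicVsBiallelic(mos$matrix)
  expect_equal(v2$verdict, "mosaic")
  # tiny matrices are indeterminate
  tiny <- simulateSingleCellMatrix(
    cloneArchitecture(0.3, "mutA", "mutB", "compound_het"), 10,
    dropout = 0, error = 0, seed = 17)
  expect_warning(v3 <- mosaicVsBiallelic(tiny$matrix), "informative")
  expect_equal(v3$verdict, "indeterminate")
  expect_error(mosaicVsBiallelic(comp$matrix, c("mutA", "nope")), "not found")
})

test_that("bulk reconciliation recovers the cell-composition VAF", {
  # 100% HET cells and observed bulk VAF 0.5: zero discrepancy
  g <- matrix("HET", 1, 200, dimnames = list("mutA", NULL))
  rec <- reconcileBulk(CellGenotypeMatrix(g), c(mutA = 0.5))
  expect_equal(rec$discrepancy, 0)
  # hemizygous composition uses per-cell copy number
  g <- matrix(c(rep("HOM_OR_HEMI", 50), rep("WT", 50)), 1, 100,
              dimnames = list("mutA", NULL))
  cn <- c(rep(1L, 50), rep(2L, 50))
  rec2 <- reconcileBulk(CellGenotypeMatrix(g, cn17p = cn), c(mutA = 1/3))
  expect_equal(rec2$expected_vaf, 50 / 150)
  expect_equal(rec2$discrepancy, 0)
  # simulator pair: small discrepancy at depth 500 without dropout
  for (seed in 1:5) {
    f <- runif(1, 0.2, 0.8)
    arch <- cloneArchitecture(f, "mutA", "mutB", "compound_het")
    sc <- simulateSingleCellMatrix(arch, 1500, dropout = 0, error = 0,
                                   seed = seed)
    bulk <- c(mutA = sampleBulkVAF(expectedVAF(arch, "mutA"), 500,
                                   seed = seed + 100))
    rec3 <- reconcileBulk(sc$matrix, bulk)
    expect_lt(abs(rec3$discrepancy), 0.05)
  }
  # uncorrected dropout biases the expectation downward
  sc_do <- simulateSingleCellMatrix(
    cloneArchitecture(0.6, "mutA", "wt", "het_mono"), 4000,
    dropout = 0.4, error = 0, seed = 31)
  rec4 <- reconcileBulk(sc_do$matrix, c(mutA = 0.3))
  expect_gt(rec4$discrepancy, 0.02)  # observed exceeds dropout-deflated expectation
  expect_warning(reconcileBulk(sc_do$matrix, c(mutA = 0.3, ghost = 0.1)),
                 "skipped")
})

test_that("cell matrix CSV round-trips genotypes and copy state", {
  sc <- simulateSingleCellMatrix(
    cloneArchitecture(0.5, "mutA", "deleted", "hemizygous"), 80,
    dropout = 0.1, error = 0.01, seed = 37)
  path <- tempfile(fileext = ".csv")
  writeCellMatrixCSV(sc$matrix, path)
  back <- readCellMatrixCSV(path)
  expect_equal(SummarizedExperiment::assay(back, "genotype"),
               SummarizedExperiment::assay(sc$matrix, "genotype"))
  expect_equal(SummarizedExperiment::colData(back)$cn17p,
               SummarizedExperiment::colData(sc$matrix)$cn17p)
})
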