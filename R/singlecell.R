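## Single-cell genotype matrix container and analyses: biallelic cell
## fraction, clone decomposition, mosaicism-vs-biallelic discrimination, and
## bulk reconciliation.

#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
#' @importFrom S4Vectors DataFrame metadata
NULL

#' Cell-by-variant genotype matrix
#'
#' Thin extension of [SummarizedExperiment::SummarizedExperiment] holding one
#' `genotype` assay (character codes `WT`, `HET`, `HOM_OR_HEMI`, `MISSING`;
#' rows = variants, columns = cells) and an optional per-cell `cn17p` column
#' (17p copy number, 2 or 1) in `colData`.
#'
#' @seealso [CellGenotypeMatrix()], [biallelicCellFraction()],
#'   [decomposeClones()], [mosaicVsBiallelic()], [reconcileBulk()]
#' @export
setClass("CellGenotypeMatrix", contains = "SummarizedExperiment")

setValidity("CellGenotypeMatrix", function(object) {
  if (!"genotype" %in% SummarizedExperiment::assayNames(object)) {
    return("must contain a 'genotype' assay")
  }
  g <- SummarizedExperiment::assay(object, "genotype")
  bad <- setdiff(unique(as.vector(g)), GENOTYPE_CODES)
  if (length(bad)) {
    return(paste0("invalid genotype codes: ", paste(bad, collapse = ", ")))
  }
  cd <- SummarizedExperiment::colData(object)
  if ("cn17p" %in% names(cd) && !all(cd$cn17p %in% c(1L, 2L))) {
    return("cn17p must be 1 or 2")
  }
  TRUE
})

#' Construct a CellGenotypeMatrix
#'
#' @param genotypes character matrix of genotype codes, variants as rows and
#'   cells as columns (a cells-by-variants matrix is accepted and transposed
#'   when orientation is unambiguous from dimnames).
#' @param cn17p optional integer vector of per-cell 17p copy number (2 or 1).
#' @return a [CellGenotypeMatrix-class].
#' @examples
#' g <- matrix(c("HET", "WT", "HET", "HET"), nrow = 2,
#'             dimnames = list(c("mutA", "mutB"), c("c1", "c2")))
#' biallelicCellFraction(CellGenotypeMatrix(g))
#' @export
CellGenotypeMatrix <- function(genotypes, cn17p = NULL) {
  genotypes <- as.matrix(genotypes)
  if (is.null(rownames(genotypes))) {
    rownames(genotypes) <- paste0("variant", seq_len(nrow(genotypes)))
  }
  if (is.null(colnames(genotypes))) {
    colnames(genotypes) <- paste0("cell", seq_len(ncol(genotypes)))
  }
  cd <- S4Vectors::DataFrame(row.names = colnames(genotypes))
  if (!is.null(cn17p)) {
    stopifnot(length(cn17p) == ncol(genotypes))
    cd$cn17p <- as.integer(cn17p)
  }
  new("CellGenotypeMatrix",
      SummarizedExperiment::SummarizedExperiment(
        assays = list(genotype = genotypes), colData = cd))
}

genotype_matrix <- function(x) SummarizedExperiment::assay(x, "genotype")

cell_cn17p <- function(x) {
  cd <- SummarizedExperiment::colData(x)
  if ("cn17p" %in% names(cd)) cd$cn17p else rep(2L, ncol(x))
}

setMethod("show", "CellGenotypeMatrix", function(object) {
  g <- genotype_matrix(object)
  cat("CellGenotypeMatrix:", nrow(g), "variant(s) x", ncol(g), "cells\n")
  tab <- table(factor(as.vector(g), levels = GENOTYPE_CODES))
  cat("  codes:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  cn <- cell_cn17p(object)
  if (any(cn == 1L)) cat("  cells with 17p loss:", sum(cn == 1L), "\n")
})

#' Fraction of cells with biallelic TP53 inactivation
#'
#' A cell is biallelic when it carries two or more distinct non-WT variants,
#' or any `HOM_OR_HEMI` call, or any non-WT call together with a 17p copy
#' number of 1. `MISSING` is treated as WT (conservative undercall; see
#' `dropout_corrected` for a first-order correction).
#'
#' @param x a [CellGenotypeMatrix-class].
#' @param dropout optional assumed per-allele dropout rate; when supplied, a
#'   dropout-corrected estimate is attached as attribute
#'   `dropout_corrected`, inflating the raw fraction by the probability that
#'   a truly biallelic compound-heterozygous cell retains both variant calls
#'   (`(1 - dropout)^2`).
#' @return raw biallelic cell fraction.
#' @export
biallelicCellFraction <- function(x, dropout = NULL) {
  g <- genotype_matrix(x)
  if (ncol(g) == 0) stop("empty cell matrix")
  g[g == "MISSING"] <- "WT"
  non_wt <- g != "WT"
  n_mut_vars <- colSums(non_wt)
  any_hom <- apply(g == "HOM_OR_HEMI", 2, any)
  cn1 <- cell_cn17p(x) == 1L
  bi <- n_mut_vars >= 2 | any_hom | (n_mut_vars >= 1 & cn1)
  out <- mean(bi)
  if (!is.null(dropout)) {
    attr(out, "dropout_corrected") <- min(1, out / (1 - dropout)^2)
  }
  out
}

#' Decompose cells into clones by genotype signature
#'
#' Cells are grouped by their exact genotype signature across variants
#' (including the 17p copy state when available); groups smaller than
#' `min_cells` are set aside as noise.
#'
#' @param x a [CellGenotypeMatrix-class].
#' @param min_cells minimum cells for a retained clone.
#' @return list with `clones` (`data.frame`: `signature`, `n_cells`,
#'   `fraction`, ordered by decreasing size) and `n_unassigned` (cells in
#'   discarded groups).
#' @export
decomposeClones <- function(x, min_cells = 1L) {
  stopifnot(min_cells >= 1)
  g <- genotype_matrix(x)
  cn <- cell_cn17p(x)
  sig <- apply(g, 2, paste, collapse = "/")
  sig <- paste0(sig, ";cn17p=", cn)
  tab <- sort(table(sig), decreasing = TRUE)
  keep <- tab >= min_cells
  clones <- data.frame(signature = names(tab)[keep],
                       n_cells = as.integer(tab[keep]),
                       fraction = as.numeric(tab[keep]) / ncol(g),
                       stringsAsFactors = FALSE)
  rownames(clones) <- NULL
  list(clones = clones, n_unassigned = as.integer(sum(tab[!keep])))
}

#' Discriminate compound-heterozygous (biallelic) clones from subclonal
#' mosaicism
#'
#' Builds the 2x2 co-occurrence table of mutant calls (non-WT, with MISSING
#' excluded as uninformative) for the two variants across cells and tests
#' for positive association with Fisher's exact test. Verdict `biallelic`
#' when co-mutant cells significantly exceed the independence expectation
#' (one-sided p < `alpha`) and the co-mutant fraction reaches `co_floor`;
#' `mosaic` when the co-mutant fraction stays below the level explainable by
#' genotype error/dropout noise (below `co_floor`) or co-occurrence is
#' significantly depleted; otherwise `indeterminate`. Fewer than
#' `min_informative` cells informative for both variants gives
#' `indeterminate` with a warning.
#'
#' @param x a [CellGenotypeMatrix-class].
#' @param variant_pair two variant (row) names; defaults to the first two
#'   rows.
#' @param alpha significance level for the exact test.
#' @param co_floor minimal co-mutant cell fraction for a biallelic verdict.
#' @param min_informative minimal number of doubly informative cells.
#' @return list with `verdict` (`"biallelic"`, `"mosaic"`,
#'   `"indeterminate"`), `table` (2x2 co-occurrence), `p_enriched`,
#'   `p_depleted`, `co_fraction`, `n_informative`.
#' @export
mosaicVsBiallelic <- function(x, variant_pair = NULL, alpha = 0.01,
                              co_floor = 0.01, min_informative = 20L) {
  g <- genotype_matrix(x)
  if (is.null(variant_pair)) {
    if (nrow(g) < 2) stop("matrix has fewer than two variants")
    variant_pair <- rownames(g)[1:2]
  }
  if (!all(variant_pair %in% rownames(g))) {
    stop("variant(s) not found in matrix: ",
         paste(setdiff(variant_pair, rownames(g)), collapse = ", "))
  }
  ga <- g[variant_pair[1], ]
  gb <- g[variant_pair[2], ]
  informative <- ga != "MISSING" & gb != "MISSING"
  n_inf <- sum(informative)
  if (n_inf < min_informative) {
    warning("only ", n_inf, " doubly informative cells; verdict indeterminate")
    return(list(verdict = "indeterminate", table = NULL,
                p_enriched = NA_real_, p_depleted = NA_real_,
                co_fraction = NA_real_, n_informative = n_inf))
  }
  mut_a <- ga[informative] != "WT"
  mut_b <- gb[informative] != "WT"
  tab <- table(factor(mut_a, levels = c(TRUE, FALSE)),
               factor(mut_b, levels = c(TRUE, FALSE)),
               dnn = c(variant_pair[1], variant_pair[2]))
  p_enr <- stats::fisher.test(tab, alternative = "greater")$p.value
  p_dep <- stats::fisher.test(tab, alternative = "less")$p.value
  co_frac <- sum(mut_a & mut_b) / n_inf
  verdict <- if (p_enr < alpha && co_frac >= co_floor) {
    "biallelic"
  } else if (co_frac < co_floor || p_dep < alpha) {
    "mosaic"
  } else {
    "indeterminate"
  }
  list(verdict = verdict, table = unclass(tab), p_enriched = p_enr,
       p_depleted = p_dep, co_fraction = co_frac, n_informative = n_inf)
}

#' Reconcile single-cell composition with observed bulk VAFs
#'
#' The expected bulk VAF of each variant is computed from the cell genotype
#' composition, treating cells as clones: each `HET` cell contributes one
#' mutant copy out of its locus copy number, each `HOM_OR_HEMI` cell all of
#' its copies (1 when `cn17p` is 1, else 2), `WT` and `MISSING` cells none.
#' The discrepancy is observed minus expected; uncorrected allelic dropout
#' biases the expectation downward.
#'
#' @param x a [CellGenotypeMatrix-class].
#' @param observed_bulk_vafs named numeric vector of bulk VAF fractions;
#'   names must match variant (row) names. Variants absent from the matrix
#'   are skipped with a warning.
#' @return `data.frame` with columns `variant`, `expected_vaf`,
#'   `observed_vaf`, `discrepancy`.
#' @export
reconcileBulk <- function(x, observed_bulk_vafs) {
  g <- genotype_matrix(x)
  cn <- cell_cn17p(x)
  vars <- names(observed_bulk_vafs)
  if (is.null(vars)) stop("observed_bulk_vafs must be named by variant")
  missing_vars <- setdiff(vars, rownames(g))
  if (length(missing_vars)) {
    warning("variant(s) absent from matrix skipped: ",
            paste(missing_vars, collapse = ", "))
    vars <- setdiff(vars, missing_vars)
  }
  total_copies <- sum(cn)
  rows <- lapply(vars, function(v) {
    gv <- g[v, ]
    mut_copies <- sum((gv == "HET") * 1 + (gv == "HOM_OR_HEMI") * cn)
    exp_vaf <- mut_copies / total_copies
    data.frame(variant = v, expected_vaf = exp_vaf,
               observed_vaf = unname(observed_bulk_vafs[v]),
               discrepancy = unname(observed_bulk_vafs[v]) - exp_vaf,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Read / write a cell-by-variant genotype CSV
#'
#' The on-disk layout is cells as rows and variants as columns, with an
#' optional trailing `cn17p` column; the in-memory object is variant-by-cell.
#'
#' @param path CSV file path.
#' @return [readCellMatrixCSV()]: a [CellGenotypeMatrix-class].
#' @export
readCellMatrixCSV <- function(path) {
  d <- utils::read.csv(path, row.names = 1, stringsAsFactors = FALSE,
                       check.names = FALSE)
  cn <- NULL
  if ("cn17p" %in% names(d)) {
    cn <- as.integer(d$cn17p)
    d$cn17p <- NULL
  }
  CellGenotypeMatrix(t(as.matrix(d)), cn17p = cn)
}

#' @rdname readCellMatrixCSV
#' @param x a [CellGenotypeMatrix-class].
#' @export
writeCellMatrixCSV <- function(x, path) {
  g <- t(genotype_matrix(x))
  out <- data.frame(cell = rownames(g), g, check.names = FALSE,
                    stringsAsFactors = FALSE)
  cd <- SummarizedExperiment::colData(x)
  if ("cn17p" %in% names(cd)) out$cn17p <- cd$cn17p
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
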