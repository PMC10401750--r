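#' @import methods
NULL

## ---------------------------------------------------------------------------
## TP53Cohort
## ---------------------------------------------------------------------------

PATIENT_COLS <- c("patient_id", "subtype", "blast_pct", "os_time", "os_event",
                  "del17p", "del17p_clonality", "complex_karyotype",
                  "tp53_upd", "upd_clonality")

MUTATION_COLS <- c("patient_id", "variant_id", "protein_change", "aa_position",
                   "consequence", "vaf", "depth")

#' Cohort of patients with TP53 mutation, cytogenetics and survival data
#'
#' `TP53Cohort` holds one row per patient (clinical, cytogenetic and
#' overall-survival data) together with a long-format mutation table (one row
#' per TP53 variant call, keyed by `patient_id`). VAFs are stored as fractions
#' in \[0, 1\]; survival time is in months.
#'
#' @slot patients `data.frame` with columns `patient_id`, `subtype`,
#'   `blast_pct` (percent scale, may be `NA`), `os_time` (months),
#'   `os_event` (logical, `TRUE` = death observed), `del17p`,
#'   `del17p_clonality` (fraction or `NA`), `complex_karyotype`, `tp53_upd`,
#'   `upd_clonality`.
#' @slot mutations `data.frame` with columns `patient_id`, `variant_id`,
#'   `protein_change`, `aa_position`, `consequence` (one of `missense`,
#'   `truncating`, `splice`, `other`), `vaf` (fraction), `depth`.
#' @slot metadata free-form provenance list.
#'
#' @seealso [TP53Cohort()], [readCohortTSV()], [simulateCohort()]
#' @export
setClass("TP53Cohort",
         representation(patients = "data.frame",
                        mutations = "data.frame",
                        metadata = "list"))

setValidity("TP53Cohort", function(object) {
  p <- object@patients
  m <- object@mutations
  msgs <- character()
  miss <- setdiff(PATIENT_COLS, names(p))
  if (length(miss)) {
    msgs <- c(msgs, paste0("missing patient columns: ", paste(miss, collapse = ", ")))
  }
  miss <- setdiff(MUTATION_COLS, names(m))
  if (length(miss)) {
    msgs <- c(msgs, paste0("missing mutation columns: ", paste(miss, collapse = ", ")))
  }
  if (length(msgs)) return(msgs)
  if (anyDuplicated(p$patient_id)) {
    msgs <- c(msgs, "patient_id must be unique within a cohort")
  }
  if (any(!is.finite(p$os_time)) || any(p$os_time < 0)) {
    msgs <- c(msgs, "os_time must be finite and non-negative")
  }
  if (any(!is.na(p$del17p_clonality) & !p$del17p)) {
    msgs <- c(msgs, "del17p_clonality present requires del17p TRUE")
  }
  if (any(!is.na(p$upd_clonality) & !p$tp53_upd)) {
    msgs <- c(msgs, "upd_clonality present requires tp53_upd TRUE")
  }
  if (nrow(m)) {
    if (any(is.na(m$vaf)) || any(m$vaf < 0 | m$vaf > 1)) {
      msgs <- c(msgs, "mutation vaf must be a fraction in [0, 1] and non-missing")
    }
    if (anyDuplicated(m[, c("patient_id", "variant_id")])) {
      msgs <- c(msgs, "duplicate (patient_id, variant_id) mutation rows")
    }
    orphan <- setdiff(m$patient_id, p$patient_id)
    if (length(orphan)) {
      msgs <- c(msgs, paste0("mutation rows for unknown patients: ",
                             paste(head(orphan, 3), collapse = ", ")))
    }
    bad <- setdiff(unique(m$consequence), CONSEQUENCE_LEVELS)
    if (length(bad)) {
      msgs <- c(msgs, paste0("unknown consequence values: ", paste(bad, collapse = ", ")))
    }
  }
  if (length(msgs)) msgs else TRUE
})

empty_mutation_table <- function() {
  data.frame(patient_id = character(), variant_id = character(),
             protein_change = character(), aa_position = integer(),
             consequence = character(), vaf = numeric(), depth = integer(),
             stringsAsFactors = FALSE)
}

#' Construct a TP53Cohort
#'
#' @param patients patient-level `data.frame`; missing optional columns
#'   (`subtype`, `blast_pct`, cytogenetics flags, clonalities) are filled with
#'   defaults (`"other"`, `NA`, `FALSE`).
#' @param mutations long-format mutation `data.frame` (zero rows allowed);
#'   missing optional columns are filled with `NA`.
#' @param metadata free-form list.
#' @return A validated [TP53Cohort-class] object.
#' @examples
#' co <- TP53Cohort(
#'   patients = data.frame(patient_id = "P1", os_time = 12, os_event = TRUE),
#'   mutations = data.frame(patient_id = "P1", variant_id = "v1", vaf = 0.4))
#' nPatients(co)
#' @export
TP53Cohort <- function(patients, mutations = empty_mutation_table(),
                       metadata = list()) {
  patients <- as.data.frame(patients, stringsAsFactors = FALSE)
  mutations <- as.data.frame(mutations, stringsAsFactors = FALSE)
  defaults_p <- list(subtype = "other", blast_pct = NA_real_,
                     del17p = FALSE, del17p_clonality = NA_real_,
                     complex_karyotype = FALSE, tp53_upd = FALSE,
                     upd_clonality = NA_real_)
  for (nm in names(defaults_p)) {
    if (is.null(patients[[nm]])) patients[[nm]] <- defaults_p[[nm]]
  }
  defaults_m <- list(variant_id = NA_character_, protein_change = NA_character_,
                     aa_position = NA_integer_, consequence = "other",
                     depth = NA_integer_)
  for (nm in names(defaults_m)) {
    if (is.null(mutations[[nm]])) mutations[[nm]] <- defaults_m[[nm]]
  }
  if (nrow(mutations)) {
    mutations$consequence[is.na(mutations$consequence)] <- "other"
    if (any(is.na(mutations$variant_id))) {
      mutations$variant_id <- ifelse(
        is.na(mutations$variant_id),
        paste0("var", seq_len(nrow(mutations))), mutations$variant_id)
    }
  }
  patients$patient_id <- as.character(patients$patient_id)
  patients$os_time <- as.numeric(patients$os_time)
  patients$os_event <- as.logical(patients$os_event)
  for (nm in c("del17p", "complex_karyotype", "tp53_upd")) {
    patients[[nm]] <- as.logical(patients[[nm]])
    patients[[nm]][is.na(patients[[nm]])] <- FALSE
  }
  mutations$patient_id <- as.character(mutations$patient_id)
  new("TP53Cohort",
      patients = patients[, PATIENT_COLS, drop = FALSE],
      mutations = mutations[, MUTATION_COLS, drop = FALSE],
      metadata = metadata)
}

#' @describeIn TP53Cohort-class patient-level table accessor
#' @param x a `TP53Cohort`
#' @export
patients <- function(x) {
  stopifnot(is(x, "TP53Cohort"))
  x@patients
}

#' @describeIn TP53Cohort-class mutation-level table accessor
#' @export
mutations <- function(x) {
  stopifnot(is(x, "TP53Cohort"))
  x@mutations
}

#' @describeIn TP53Cohort-class number of patients
#' @export
nPatients <- function(x) nrow(patients(x))

#' @describeIn TP53Cohort-class patient identifiers, in cohort order
#' @export
patientIDs <- function(x) patients(x)$patient_id

setMethod("show", "TP53Cohort", function(object) {
  p <- object@patients
  m <- object@mutations
  n_mut <- length(unique(m$patient_id))
  cat("TP53Cohort with", nrow(p), "patients (", n_mut, "TP53-mutant,",
      sum(m$patient_id %in% p$patient_id), "variant calls )\n")
  cat("  del(17p):", sum(p$del17p), " TP53 UPD:", sum(p$tp53_upd),
      " events:", sum(p$os_event), "\n")
  if (length(object@metadata)) {
    cat("  metadata:", paste(names(object@metadata), collapse = ", "), "\n")
  }
})

## ---------------------------------------------------------------------------
## ClonalArchitecture
## ---------------------------------------------------------------------------

ALLELE_CODES <- c("wt", "mutA", "mutB", "deleted")

ARCH_LABELS <- c("het_mono", "hemizygous", "upd_hom", "compound_het",
                 "mosaic_two_mono", "nested_biallelic_subclone", "wild_type")

#' Ground-truth clonal architecture at the TP53 locus
#'
#' Describes a set of disjoint clones, each occupying a fraction of cells and
#' carrying a genotype on the two TP53 alleles (`wt`, `mutA`, `mutB`, or
#' `deleted`; at most one allele deleted per clone). Cells not covered by any
#' clone are wild type. This is the simulator's ground truth from which bulk
#' VAFs, del(17p) clonality and single-cell matrices are derived.
#'
#' @slot clones `data.frame` with columns `fraction` (in (0, 1\]),
#'   `allele_a`, `allele_b` (allele codes). May have zero rows (pure wild
#'   type).
#' @slot label configuration label, one of `het_mono`, `hemizygous`,
#'   `upd_hom`, `compound_het`, `mosaic_two_mono`,
#'   `nested_biallelic_subclone`, `wild_type`.
#' @seealso [cloneArchitecture()], [expectedVAF()], [biallelicCloneFraction()]
#' @export
setClass("ClonalArchitecture",
         representation(clones = "data.frame", label = "character"))

setValidity("ClonalArchitecture", function(object) {
  cl <- object@clones
  msgs <- character()
  need <- c("fraction", "allele_a", "allele_b")
  if (!all(need %in% names(cl))) {
    return(paste0("clones must have columns ", paste(need, collapse = ", ")))
  }
  if (nrow(cl)) {
    if (any(cl$fraction <= 0 | cl$fraction > 1)) {
      msgs <- c(msgs, "clone fractions must lie in (0, 1]")
    }
    if (sum(cl$fraction) > 1 + 1e-9) {
      msgs <- c(msgs, "clone fractions must sum to at most 1")
    }
    if (!all(cl$allele_a %in% ALLELE_CODES) || !all(cl$allele_b %in% ALLELE_CODES)) {
      msgs <- c(msgs, "allele codes must be wt/mutA/mutB/deleted")
    }
    both_del <- cl$allele_a == "deleted" & cl$allele_b == "deleted"
    if (any(both_del)) {
      msgs <- c(msgs, "at most one allele may be deleted per clone")
    }
  }
  if (length(object@label) != 1L || !object@label %in% ARCH_LABELS) {
    msgs <- c(msgs, paste0("label must be one of ", paste(ARCH_LABELS, collapse = ", ")))
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "ClonalArchitecture", function(object) {
  cat("ClonalArchitecture <", object@label, "> with ", nrow(object@clones),
      " clone(s); wild-type remainder ",
      sprintf("%.3f", 1 - sum(object@clones$fraction)), "\n", sep = "")
  if (nrow(object@clones)) print(object@clones, row.names = FALSE)
})

#' @describeIn ClonalArchitecture-class clone table accessor
#' @param x a `ClonalArchitecture`
#' @export
clones <- function(x) {
  stopifnot(is(x, "ClonalArchitecture"))
  x@clones
}

#' @describeIn ClonalArchitecture-class configuration label accessor
#' @export
archLabel <- function(x) {
  stopifnot(is(x, "ClonalArchitecture"))
  x@label
}

## ---------------------------------------------------------------------------
## CutoffSearchResult
## ---------------------------------------------------------------------------

#' Result of the survival-concordance VAF cutoff search
#'
#' @slot grid candidate cutoffs (fractions), strictly increasing.
#' @slot runs matrix of held-out Harrell's C values, `n_runs` rows by
#'   `length(grid)` columns; `NA` marks a degenerate split for that cutoff.
#' @slot mean_c,sd_c per-cutoff mean and SD of held-out C over defined runs.
#' @slot n_undefined per-cutoff count of runs dropped as degenerate.
#' @slot selected_cutoff the grid value with maximal mean held-out C (ties
#'   broken toward the smaller cutoff).
#' @slot selection_rule human-readable description of the selection rule.
#' @slot config the [cutoffSearchConfig()] list used.
#' @seealso [crossValidateCutoff()]
#' @export
setClass("CutoffSearchResult",
         representation(grid = "numeric", runs = "matrix",
                        mean_c = "numeric", sd_c = "numeric",
                        n_undefined = "integer",
                        selected_cutoff = "numeric",
                        selection_rule = "character",
                        config = "list"))

setValidity("CutoffSearchResult", function(object) {
  msgs <- character()
  if (ncol(object@runs) != length(object@grid)) {
    msgs <- c(msgs, "runs must have one column per grid cutoff")
  }
  vals <- object@runs[!is.na(object@runs)]
  if (length(vals) && (any(vals < 0) || any(vals > 1))) {
    msgs <- c(msgs, "held-out C values must lie in [0, 1]")
  }
  if (is.unsorted(object@grid, strictly = TRUE)) {
    msgs <- c(msgs, "grid must be strictly increasing")
  }
  if (!is.na(object@selected_cutoff) &&
      !any(abs(object@grid - object@selected_cutoff) < 1e-12)) {
    msgs <- c(msgs, "selected_cutoff must be a grid value")
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "CutoffSearchResult", function(object) {
  cat("CutoffSearchResult:", nrow(object@runs), "runs x",
      length(object@grid), "candidate cutoffs\n")
  cat("  selected cutoff:", object@selected_cutoff,
      sprintf("(mean held-out C = %.4f)\n",
              object@mean_c[which.min(abs(object@grid - object@selected_cutoff))]))
  cat("  rule:", object@selection_rule, "\n")
})

#' @describeIn CutoffSearchResult-class selected cutoff accessor
#' @param x a `CutoffSearchResult`
#' @export
selectedCutoff <- function(x) {
  stopifnot(is(x, "CutoffSearchResult"))
  x@selected_cutoff
}

#' @describeIn CutoffSearchResult-class per-cutoff summary table
#' @export
cutoffGridSummary <- function(x) {
  stopifnot(is(x, "CutoffSearchResult"))
  data.frame(cutoff = x@grid, mean_c = x@mean_c, sd_c = x@sd_c,
             n_undefined = x@n_undefined)
}
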