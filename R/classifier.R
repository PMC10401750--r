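## Allelic-state classification: traditional single/double hit counting and
## the three-group combined-VAF algorithm.

#' Combined VAF per patient
#'
#' Sum of VAFs over all of a patient's TP53 mutations, capped at 1 (a warning
#' reports patients whose raw sum exceeds 1); 0 for patients without
#' mutations.
#'
#' @param cohort a [TP53Cohort-class].
#' @return named numeric vector (names = `patient_id`, cohort order).
#' @export
combinedVAF <- function(cohort) {
  p <- patients(cohort)
  m <- mutations(cohort)
  cv <- setNames(numeric(nrow(p)), p$patient_id)
  if (nrow(m)) {
    sums <- tapply(m$vaf, m$patient_id, sum)
    cv[names(sums)] <- as.numeric(sums)
  }
  over <- cv > 1
  if (any(over)) {
    warning(sum(over), " patient(s) with combined VAF > 1 capped at 1 (",
            paste(head(names(cv)[over], 3), collapse = ", "), ")")
    cv[over] <- 1
  }
  cv
}

per_patient_stats <- function(cohort) {
  p <- patients(cohort)
  m <- mutations(cohort)
  n_mut <- setNames(integer(nrow(p)), p$patient_id)
  max_vaf <- setNames(numeric(nrow(p)), p$patient_id)
  if (nrow(m)) {
    tab <- table(m$patient_id)
    n_mut[names(tab)] <- as.integer(tab)
    mx <- tapply(m$vaf, m$patient_id, max)
    max_vaf[names(mx)] <- as.numeric(mx)
  }
  cv <- suppressWarnings(combinedVAF(cohort))
  list(n_mut = unname(n_mut), max_vaf = unname(max_vaf), combined = unname(cv))
}

#' Traditional single/double TP53 hit classification
#'
#' A hit is any of: a distinct TP53 mutation, a 17p deletion, or TP53-locus
#' UPD accompanying at least one mutation (UPD without a mutation is not
#' counted). Zero hits give `wild_type`, one `single_hit`, two or more
#' `double_hit`.
#'
#' @param cohort a [TP53Cohort-class].
#' @return `data.frame` with columns `patient_id`, `label` (`wild_type`,
#'   `single_hit`, `double_hit`), `n_hits`, and `basis` (comma-separated
#'   reason codes among `mutation`, `second_mutation`, `del17p`, `upd`).
#' @examples
#' co <- simulateCohort(simulationParams(n_patients = 20, seed = 1))$cohort
#' table(classifyTraditional(co)$label)
#' @export
classifyTraditional <- function(cohort) {
  p <- patients(cohort)
  st <- per_patient_stats(cohort)
  n_hits <- st$n_mut + as.integer(p$del17p) +
    as.integer(p$tp53_upd & st$n_mut >= 1)
  label <- ifelse(n_hits == 0, "wild_type",
                  ifelse(n_hits == 1, "single_hit", "double_hit"))
  basis <- vapply(seq_len(nrow(p)), function(i) {
    b <- character()
    if (st$n_mut[i] >= 1) b <- c(b, "mutation")
    if (st$n_mut[i] >= 2) b <- c(b, "second_mutation")
    if (p$del17p[i]) b <- c(b, "del17p")
    if (p$tp53_upd[i] && st$n_mut[i] >= 1) b <- c(b, "upd")
    paste(b, collapse = ",")
  }, character(1))
  data.frame(patient_id = p$patient_id, label = label, n_hits = n_hits,
             basis = basis, stringsAsFactors = FALSE)
}

#' Three-group allelic-state classification
#'
#' Assigns each patient one of `wild_type`, `del17p_only`,
#' `obligatory_biallelic`, `probable_biallelic`, `probable_monoallelic`.
#' Decision order: patients without mutations are `wild_type` (or
#' `del17p_only` if they carry an isolated 17p deletion, excluded from the
#' three mutant groups). Obligatory biallelic status is called when any of
#' the following holds: a single mutation with VAF > 0.5; two or more
#' mutations with combined VAF > 0.5; a mutation plus del(17p) with known
#' clonality such that max single-mutation VAF + clonality > 0.5; or a
#' mutation plus documented TP53-locus UPD. Remaining (ambiguous) patients
#' are split by the combined VAF: `probable_biallelic` when combined VAF is
#' at or above `cutoff`, else `probable_monoallelic` (boundary assigned to
#' the higher-risk class).
#'
#' del(17p) with missing clonality disables only the VAF + clonality rule;
#' this is reported via a message.
#'
#' @param cohort a [TP53Cohort-class].
#' @param cutoff combined-VAF cutoff separating probable biallelic from
#'   probable monoallelic, a fraction in (0, 0.5). Default 0.23, the value
#'   selected by the survival-concordance search (see
#'   [crossValidateCutoff()]).
#' @return `data.frame` with columns `patient_id`, `state`, `rule` (reason
#'   code: `single_vaf_gt50`, `combined_vaf_gt50`, `vaf_plus_del17p_gt50`,
#'   `mutation_with_upd`, `combined_vaf_ge_cutoff`, `combined_vaf_lt_cutoff`,
#'   `no_mutation`, `isolated_del17p`), `combined_vaf`, `cutoff_used`.
#' @examples
#' co <- TP53Cohort(
#'   patients = data.frame(patient_id = c("A", "B"), os_time = c(10, 20),
#'                         os_event = c(TRUE, FALSE)),
#'   mutations = data.frame(patient_id = c("A", "B"),
#'                          variant_id = c("v1", "v2"), vaf = c(0.55, 0.08)))
#' classifyNovel(co)$state
#' @export
classifyNovel <- function(cohort, cutoff = 0.23) {
  stopifnot(is_scalar_number(cutoff), cutoff > 0, cutoff < 0.5)
  p <- patients(cohort)
  st <- per_patient_stats(cohort)
  n <- nrow(p)
  state <- character(n)
  rule <- character(n)

  miss_clon <- p$del17p & is.na(p$del17p_clonality) & st$n_mut >= 1
  if (any(miss_clon)) {
    message(sum(miss_clon), " patient(s) with del(17p) but unknown clonality: ",
            "VAF + clonality rule not applicable")
  }
  for (i in seq_len(n)) {
    if (st$n_mut[i] == 0L) {
      if (p$del17p[i]) {
        state[i] <- "del17p_only"; rule[i] <- "isolated_del17p"
      } else {
        state[i] <- "wild_type"; rule[i] <- "no_mutation"
      }
      next
    }
    if (st$n_mut[i] == 1L && st$max_vaf[i] > 0.5) {
      state[i] <- "obligatory_biallelic"; rule[i] <- "single_vaf_gt50"
    } else if (st$n_mut[i] >= 2L && st$combined[i] > 0.5) {
      state[i] <- "obligatory_biallelic"; rule[i] <- "combined_vaf_gt50"
    } else if (p$del17p[i] && !is.na(p$del17p_clonality[i]) &&
               st$max_vaf[i] + p$del17p_clonality[i] > 0.5) {
      state[i] <- "obligatory_biallelic"; rule[i] <- "vaf_plus_del17p_gt50"
    } else if (p$tp53_upd[i]) {
      state[i] <- "obligatory_biallelic"; rule[i] <- "mutation_with_upd"
    } else if (st$combined[i] >= cutoff) {
      state[i] <- "probable_biallelic"; rule[i] <- "combined_vaf_ge_cutoff"
    } else {
      state[i] <- "probable_monoallelic"; rule[i] <- "combined_vaf_lt_cutoff"
    }
  }
  data.frame(patient_id = p$patient_id, state = state, rule = rule,
             combined_vaf = st$combined, cutoff_used = rep(cutoff, n),
             stringsAsFactors = FALSE)
}

#' Classify a whole cohort and summarise group counts
#'
#' @param cohort a [TP53Cohort-class].
#' @param cutoff see [classifyNovel()].
#' @return list with `calls` (per-patient [classifyNovel()] output) and
#'   `summary`: a `data.frame` of per-state counts with `share_pct`, the
#'   percentage among TP53-mutant patients (integer-rounded; `NA` for the
#'   non-mutant states), plus an attribute `n_mutant`.
#' @export
classifyCohort <- function(cohort, cutoff = 0.23) {
  calls <- classifyNovel(cohort, cutoff = cutoff)
  summary <- stateShareTable(calls$state)
  list(calls = calls, summary = summary)
}

#' Per-state counts and shares among TP53-mutant patients
#'
#' @param states character vector of allelic states (as produced by
#'   [classifyNovel()]), or a named count vector/table of states.
#' @return `data.frame` with columns `state`, `n`, `share_pct` (percent of
#'   TP53-mutant patients, rounded to the nearest integer; `NA` for
#'   `wild_type` and `del17p_only`). Attribute `n_mutant` holds the
#'   denominator.
#' @examples
#' stateShareTable(c(obligatory_biallelic = 579, probable_biallelic = 239,
#'                   probable_monoallelic = 192))
#' @export
stateShareTable <- function(states) {
  if (!is.null(names(states)) || is.table(states)) {
    counts <- setNames(as.integer(states), names(states))
  } else {
    tab <- table(factor(states, levels = STATE_LEVELS))
    counts <- setNames(as.integer(tab), names(tab))
    counts <- counts[counts > 0 | names(counts) %in% MUTANT_STATES]
  }
  all_states <- union(names(counts), MUTANT_STATES)
  n <- setNames(integer(length(all_states)), all_states)
  n[names(counts)] <- counts
  n_mutant <- sum(n[MUTANT_STATES])
  share <- ifelse(names(n) %in% MUTANT_STATES & n_mutant > 0,
                  round(100 * n / n_mutant), NA_real_)
  out <- data.frame(state = names(n), n = as.integer(n), share_pct = share,
                    row.names = NULL, stringsAsFactors = FALSE)
  ord <- order(match(out$state, STATE_LEVELS))
  out <- out[rev(ord), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_mutant") <- n_mutant
  out
}

#' Cross-tabulate traditional hit classes against allelic states
#'
#' Restricted to patients that are TP53-mutant under the three-group scheme
#' (states `obligatory_biallelic`, `probable_biallelic`,
#' `probable_monoallelic`) and `single_hit`/`double_hit` under the
#' traditional scheme. The upstage share is the percentage of single-hit
#' patients reclassified as `probable_biallelic`; the downstage share is the
#' percentage of double-hit patients reclassified as `probable_monoallelic`.
#' Both are reported to one decimal.
#'
#' @param traditional `data.frame` from [classifyTraditional()] or a
#'   character vector of labels.
#' @param novel `data.frame` from [classifyNovel()] or a character vector of
#'   states, aligned with `traditional`.
#' @return list with `table` (2 x 3 contingency matrix), `upstage_pct`,
#'   `downstage_pct`, `n_single`, `n_double`, `n_upstaged`, `n_downstaged`.
#' @export
reclassificationTable <- function(traditional, novel) {
  tl <- if (is.data.frame(traditional)) traditional$label else traditional
  nv <- if (is.data.frame(novel)) novel$state else novel
  if (length(tl) != length(nv)) {
    stop("traditional and novel classifications must have equal length")
  }
  keep <- tl %in% c("single_hit", "double_hit") & nv %in% MUTANT_STATES
  tab <- table(factor(tl[keep], levels = c("single_hit", "double_hit")),
               factor(nv[keep], levels = MUTANT_STATES))
  n_single <- sum(tab["single_hit", ])
  n_double <- sum(tab["double_hit", ])
  n_up <- tab["single_hit", "probable_biallelic"]
  n_down <- tab["double_hit", "probable_monoallelic"]
  list(table = unclass(tab),
       upstage_pct = if (n_single > 0) round(100 * n_up / n_single, 1) else 0,
       downstage_pct = if (n_double > 0) round(100 * n_down / n_double, 1) else 0,
       n_single = n_single, n_double = n_double,
       n_upstaged = as.integer(n_up), n_downstaged = as.integer(n_down))
}
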