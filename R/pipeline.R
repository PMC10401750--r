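## End-to-end pipeline: (simulate | read) -> classify -> optional cutoff
## search -> summary report.

#' Pipeline configuration
#'
#' @param input path to a cohort TSV, or `NULL` to simulate with
#'   `sim_params`.
#' @param cutoff combined-VAF cutoff for [classifyNovel()].
#' @param run_cutoff_search logical; re-estimate the cutoff on the ambiguous
#'   zone of the input cohort before classification reporting.
#' @param search_config a [cutoffSearchConfig()].
#' @param sim_params a [simulationParams()] used when `input` is `NULL`.
#' @param outdir output directory (created if missing); `NULL` suppresses
#'   file output.
#' @param seed integer seed stamped into all outputs.
#' @return list of class `pipeline_config`.
#' @export
pipelineConfig <- function(input = NULL, cutoff = 0.23,
                           run_cutoff_search = FALSE,
                           search_config = cutoffSearchConfig(),
                           sim_params = simulationParams(),
                           outdir = NULL, seed = 1L) {
  stopifnot(cutoff > 0, cutoff < 0.5)
  structure(list(input = input, cutoff = cutoff,
                 run_cutoff_search = isTRUE(run_cutoff_search),
                 search_config = search_config, sim_params = sim_params,
                 outdir = outdir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Summarise allelic-state groups with survival
#'
#' @param calls per-patient calls from [classifyNovel()].
#' @param cohort the matching [TP53Cohort-class].
#' @return list with `groups` (`data.frame`: `state`, `n`, `share_pct`,
#'   `km_median_months`, `observed_time_iqr`), and `pairwise_logrank`
#'   (`data.frame` of unadjusted pairwise log-rank p-values between states
#'   with at least one patient each; `NULL` when fewer than two states
#'   occur).
#' @export
summarizeGroups <- function(calls, cohort) {
  p <- patients(cohort)
  idx <- match(calls$patient_id, p$patient_id)
  stopifnot(!anyNA(idx))
  times <- p$os_time[idx]
  events <- p$os_event[idx]
  tab <- stateShareTable(calls$state)
  present <- tab$state[tab$n > 0]
  km_med <- iqr_lo <- iqr_hi <- rep(NA_real_, nrow(tab))
  for (i in seq_len(nrow(tab))) {
    s <- tab$state[i]
    sel <- calls$state == s
    if (!any(sel)) next
    km_med[i] <- kmEstimate(times[sel], events[sel])$median
    q <- stats::quantile(times[sel], c(0.25, 0.75))
    iqr_lo[i] <- q[1]; iqr_hi[i] <- q[2]
  }
  groups <- cbind(tab, km_median_months = km_med,
                  obs_time_q1 = iqr_lo, obs_time_q3 = iqr_hi)
  omitted <- tab$state[tab$n == 0]
  pw <- NULL
  if (length(present) >= 2) {
    combos <- utils::combn(present, 2)
    pw <- do.call(rbind, lapply(seq_len(ncol(combos)), function(k) {
      a <- combos[1, k]; b <- combos[2, k]
      sel <- calls$state %in% c(a, b)
      lr <- logrankTest(times[sel], events[sel], calls$state[sel])
      data.frame(group1 = a, group2 = b, chi2 = lr$chi2,
                 p_unadjusted = lr$p, stringsAsFactors = FALSE)
    }))
  }
  list(groups = groups, pairwise_logrank = pw,
       omitted_states = omitted, n_mutant = attr(tab, "n_mutant"))
}

#' Run the full classification pipeline
#'
#' Reads (or simulates) a cohort, applies both classifiers, cross-tabulates
#' them, optionally re-runs the cutoff search on the ambiguous zone, and
#' summarises survival by allelic-state group. When `outdir` is set, writes
#' `calls.tsv`, `summary.json` and (when requested) `cutoff_result.json`,
#' each stamped with the seed and a configuration hash.
#'
#' @param config a [pipelineConfig()].
#' @return list with `cohort`, `calls`, `traditional`, `reclassification`,
#'   `group_summary`, `cutoff_search` (`NULL` unless requested), `summary`
#'   (the JSON-ready report list).
#' @examples
#' res <- runPipeline(pipelineConfig(
#'   sim_params = simulationParams(n_patients = 100, seed = 3), seed = 3))
#' res$summary$group_counts
#' @export
runPipeline <- function(config = pipelineConfig()) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  cohort <- stage("input", {
    if (!is.null(config$input)) {
      if (!file.exists(config$input)) {
        stop("input path does not exist: ", config$input)
      }
      readCohortTSV(config$input)
    } else {
      sp <- config$sim_params
      sp$seed <- config$seed
      simulateCohort(sp)$cohort
    }
  })
  search <- NULL
  cutoff <- config$cutoff
  if (config$run_cutoff_search) {
    search <- stage("cutoff_search", {
      cv <- suppressWarnings(combinedVAF(cohort))
      calls0 <- suppressMessages(classifyNovel(cohort, cutoff = cutoff))
      amb <- calls0$state %in% c("probable_biallelic", "probable_monoallelic")
      p <- patients(cohort)
      cfg <- config$search_config
      cfg$seed <- config$seed
      crossValidateCutoff(cv[amb], p$os_time[amb], p$os_event[amb], cfg)
    })
    if (!is.na(selectedCutoff(search))) cutoff <- selectedCutoff(search)
  }
  calls <- stage("classify", suppressMessages(classifyNovel(cohort, cutoff = cutoff)))
  trad <- stage("classify", classifyTraditional(cohort))
  reclass <- reclassificationTable(trad, calls)
  gs <- stage("summarize", summarizeGroups(calls, cohort))
  cfg_hash <- object_hash(list(cutoff = cutoff,
                               search = config$run_cutoff_search,
                               seed = config$seed))
  summary <- list(
    schema_version = "1.0",
    seed = config$seed,
    config_hash = cfg_hash,
    cutoff_used = cutoff,
    n_patients = nPatients(cohort),
    n_mutant = gs$n_mutant,
    group_counts = setNames(as.list(gs$groups$n), gs$groups$state),
    group_shares_pct = setNames(as.list(gs$groups$share_pct), gs$groups$state),
    km_median_months = setNames(as.list(gs$groups$km_median_months),
                                gs$groups$state),
    reclassification = reclass[c("upstage_pct", "downstage_pct", "n_single",
                                 "n_double", "n_upstaged", "n_downstaged")],
    pairwise_logrank = gs$pairwise_logrank)
  if (!is.null(config$outdir)) {
    stage("write", {
      dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
      writeClassifiedTSV(cohort, calls, file.path(config$outdir, "calls.tsv"))
      jsonlite::write_json(summary, file.path(config$outdir, "summary.json"),
                           auto_unbox = TRUE, digits = NA, null = "null",
                           na = "null", pretty = TRUE)
      if (!is.null(search)) {
        jsonlite::write_json(
          list(schema_version = "1.0", seed = config$seed,
               config_hash = cfg_hash,
               selected_cutoff = selectedCutoff(search),
               grid = cutoffGridSummary(search)),
          file.path(config$outdir, "cutoff_result.json"),
          auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
      }
    })
  }
  list(cohort = cohort, calls = calls, traditional = trad,
       reclassification = reclass, group_summary = gs,
       cutoff_search = search, summary = summary)
}
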