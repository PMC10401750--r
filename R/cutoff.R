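## Survival-driven VAF cutoff search: log-rank split proposal under a
## minimum node size, and grid validation by repeated 80/20 subsampling with
## held-out Harrell's C.

#' Configuration for the VAF cutoff search
#'
#' Defaults mirror the published procedure: candidate cutoffs from 5 to 50
#' percent in 1-percent steps, minimum node size 15, 30 random 80/20
#' train/test splits.
#'
#' @param grid strictly increasing candidate cutoffs within (0, 0.5\].
#' @param min_node minimum number of subjects required on each side of a
#'   split (both when proposing cutpoints and when scoring grid cutoffs on a
#'   training set).
#' @param n_runs number of random train/test splits.
#' @param test_fraction held-out fraction per run.
#' @param seed integer seed; the whole search is reproducible from
#'   (data, seed).
#' @param stratify_events logical; when `TRUE`, splits preserve the event
#'   rate (off by default, matching plain random splitting).
#' @return list of class `cutoff_search_config`.
#' @export
cutoffSearchConfig <- function(grid = seq(0.05, 0.50, by = 0.01),
                               min_node = 15L, n_runs = 30L,
                               test_fraction = 0.20, seed = 1L,
                               stratify_events = FALSE) {
  stopifnot(test_fraction > 0, test_fraction < 1, min_node >= 1,
            n_runs >= 1, length(grid) >= 1,
            all(grid > 0), all(grid <= 0.5))
  if (is.unsorted(grid, strictly = TRUE)) {
    stop("grid must be strictly increasing")
  }
  structure(list(grid = as.numeric(grid), min_node = as.integer(min_node),
                 n_runs = as.integer(n_runs),
                 test_fraction = test_fraction, seed = as.integer(seed),
                 stratify_events = isTRUE(stratify_events)),
            class = "cutoff_search_config")
}

#' Propose candidate VAF cutpoints by log-rank score
#'
#' Candidate cutpoints are midpoints between consecutive distinct VAF values;
#' only cutpoints leaving at least `min_node` subjects on each side are
#' scored. Each admissible cutpoint is scored by the two-group log-rank
#' chi-square of the induced split.
#'
#' @param vafs per-subject (combined) VAFs, aligned with the sample.
#' @param times,events survival sample.
#' @param min_node minimum group size per side.
#' @return `data.frame` with columns `cutpoint`, `chi2`, `n_low`, `n_high`,
#'   sorted by decreasing `chi2`. Zero rows (with a warning) when no
#'   admissible cutpoint exists.
#' @export
proposeSplits <- function(vafs, times, events, min_node = 15L) {
  events <- check_surv(times, events)
  stopifnot(length(vafs) == length(times))
  if (length(vafs) < 2 * min_node) {
    stop("need at least 2 * min_node subjects")
  }
  u <- sort(unique(vafs))
  if (length(u) < 2) {
    warning("all VAFs identical: no admissible cutpoint")
    return(data.frame(cutpoint = numeric(), chi2 = numeric(),
                      n_low = integer(), n_high = integer()))
  }
  mids <- (u[-1] + u[-length(u)]) / 2
  rows <- lapply(mids, function(cp) {
    hi <- vafs >= cp
    n_hi <- sum(hi); n_lo <- sum(!hi)
    if (n_hi < min_node || n_lo < min_node) return(NULL)
    lr <- logrankTest(times, events, hi)
    data.frame(cutpoint = cp, chi2 = lr$chi2, n_low = n_lo, n_high = n_hi)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows) || nrow(rows) == 0) {
    warning("no cutpoint satisfies the minimum node size")
    return(data.frame(cutpoint = numeric(), chi2 = numeric(),
                      n_low = integer(), n_high = integer()))
  }
  rows <- rows[order(-rows$chi2), , drop = FALSE]
  rownames(rows) <- NULL
  rows
}

# KM median of one group; +Inf when the curve never reaches 0.5, so that a
# group with undefined median always counts as the better-surviving side.
# Direct product-limit computation (same convention as kmEstimate, which the
# tests verify); kept free of model-object overhead because the cutoff grid
# evaluates it hundreds of thousands of times.
group_km_median <- function(times, events) {
  o <- order(times)
  t <- times[o]
  e <- as.numeric(events[o])
  n <- length(t)
  ends <- which(c(diff(t) != 0, TRUE))   # last index of each tied-time block
  d <- diff(c(0, cumsum(e)[ends]))       # events per distinct time
  cnt <- diff(c(0, ends))                # at-risk decrement per block
  n_risk <- n - c(0, cumsum(cnt)[-length(cnt)])
  s <- cumprod(1 - d / n_risk)
  i <- which(s <= 0.5 + 1e-9)
  if (length(i)) t[ends[i[1]]] else Inf
}

#' Held-out concordance of a binary VAF split
#'
#' The risk orientation is learned on the training set: the side of the
#' cutoff (VAF at/above vs below) with the lower KM median survival receives
#' the higher risk score. When the two training medians are equal or both
#' undefined, the high-VAF side is assigned the higher risk. Test subjects
#' then receive the learned binary risks and Harrell's C is computed on the
#' test set.
#'
#' @param cutoff VAF cutoff in (0, 1).
#' @param train,test lists with elements `vafs`, `times`, `events`.
#' @param min_node minimum per-side size in the training set; splits leaving
#'   a smaller side are degenerate.
#' @return held-out C, or `NA` when the split is degenerate (a side empty in
#'   test, undersized in train, or no comparable test pair).
#' @export
evaluateCutoff <- function(cutoff, train, test, min_node = 1L) {
  stopifnot(cutoff > 0, cutoff < 1)
  tr_hi <- train$vafs >= cutoff
  te_hi <- test$vafs >= cutoff
  if (sum(tr_hi) < min_node || sum(!tr_hi) < min_node) return(NA_real_)
  if (!any(te_hi) || all(te_hi)) return(NA_real_)
  med_hi <- group_km_median(train$times[tr_hi], train$events[tr_hi])
  med_lo <- group_km_median(train$times[!tr_hi], train$events[!tr_hi])
  hi_risk_side_is_high_vaf <- med_hi <= med_lo
  risks <- if (hi_risk_side_is_high_vaf) as.numeric(te_hi) else as.numeric(!te_hi)
  harrellC(test$times, test$events, risks)$c
}

#' Cross-validated VAF cutoff selection
#'
#' For each of `n_runs` seeded random train/test splits, every grid cutoff is
#' scored by [evaluateCutoff()] on that same split. Per-cutoff mean and SD of
#' the held-out C are aggregated over defined runs (degenerate runs are
#' dropped and counted), and the selected cutoff is the grid value with the
#' maximal mean C, ties broken toward the smaller cutoff.
#'
#' The input is intended to be the ambiguous zone only: patients not already
#' resolved by the obligatory rules, i.e. combined VAF at or below 0.5 (a
#' warning is emitted otherwise).
#'
#' @param vafs,times,events aligned per-subject data.
#' @param config a [cutoffSearchConfig()].
#' @return a [CutoffSearchResult-class].
#' @examples
#' sim <- simulateAmbiguousCohort(n = 200, changepoint = 0.3, seed = 7)
#' res <- crossValidateCutoff(sim$vafs, sim$times, sim$events,
#'                            cutoffSearchConfig(n_runs = 5, seed = 7))
#' selectedCutoff(res)
#' @export
crossValidateCutoff <- function(vafs, times, events,
                                config = cutoffSearchConfig()) {
  events <- check_surv(times, events)
  stopifnot(length(vafs) == length(times))
  n <- length(vafs)
  if (n < 2 * config$min_node) {
    stop("fewer than 2 * min_node subjects in the ambiguous zone")
  }
  if (any(vafs > 0.5 + 1e-9)) {
    warning("subjects with combined VAF > 0.5 present; the search is meant ",
            "for the ambiguous zone left by the obligatory rules")
  }
  grid <- config$grid
  n_test <- max(1L, round(config$test_fraction * n))
  runs <- with_seed(config$seed, {
    t(vapply(seq_len(config$n_runs), function(run) {
      test_idx <- if (config$stratify_events) {
        ev <- which(events); cs <- which(!events)
        c(sample(ev, round(length(ev) * config$test_fraction)),
          sample(cs, n_test - round(length(ev) * config$test_fraction)))
      } else {
        sample.int(n, n_test)
      }
      tr <- list(vafs = vafs[-test_idx], times = times[-test_idx],
                 events = events[-test_idx])
      te <- list(vafs = vafs[test_idx], times = times[test_idx],
                 events = events[test_idx])
      vapply(grid, evaluateCutoff, numeric(1), train = tr, test = te,
             min_node = config$min_node)
    }, numeric(length(grid))))
  })
  runs <- matrix(runs, nrow = config$n_runs, ncol = length(grid))
  mean_c <- apply(runs, 2, function(x) mean(x, na.rm = TRUE))
  mean_c[is.nan(mean_c)] <- NA_real_
  sd_c <- apply(runs, 2, function(x) stats::sd(x, na.rm = TRUE))
  n_undef <- apply(runs, 2, function(x) sum(is.na(x)))
  sel <- if (all(is.na(mean_c))) NA_real_ else grid[which.max(mean_c)]
  new("CutoffSearchResult", grid = grid, runs = runs, mean_c = mean_c,
      sd_c = sd_c, n_undefined = as.integer(n_undef),
      selected_cutoff = sel,
      selection_rule = "argmax of mean held-out Harrell's C; ties to smaller cutoff",
      config = unclass(config))
}
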