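# Independent oracles, coded naively and separately from the package
# implementations they check.

# Brute-force three-group rule oracle for one patient.
oracle_novel <- function(vafs, del17p, del17p_clonality, tp53_upd, cutoff) {
  n_mut <- length(vafs)
  combined <- min(sum(vafs), 1)
  if (n_mut == 0) {
    if (del17p) return("del17p_only") else return("wild_type")
  }
  if (n_mut == 1 && vafs[1] > 0.5) return("obligatory_biallelic")
  if (n_mut >= 2 && combined > 0.5) return("obligatory_biallelic")
  if (del17p && !is.na(del17p_clonality) &&
      max(vafs) + del17p_clonality > 0.5) return("obligatory_biallelic")
  if (tp53_upd) return("obligatory_biallelic")
  if (combined >= cutoff) return("probable_biallelic")
  "probable_monoallelic"
}

# Brute-force traditional hit-count oracle for one patient.
oracle_traditional <- function(n_mut, del17p, tp53_upd) {
  hits <- n_mut + (if (del17p) 1 else 0) +
    (if (tp53_upd && n_mut >= 1) 1 else 0)
  if (hits == 0) "wild_type" else if (hits == 1) "single_hit" else "double_hit"
}

# Exhaustive pair enumeration for Harrell's C (double loop, no vectorization).
oracle_harrell_c <- function(times, events, risks) {
  n <- length(times)
  conc <- 0; comp <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      first_fails <- (times[i] < times[j] && events[i]) ||
        (times[i] == times[j] && events[i] && !events[j])
      if (!first_fails) next
      comp <- comp + 1
      if (risks[i] > risks[j]) conc <- conc + 1
      else if (risks[i] == risks[j]) conc <- conc + 0.5
    }
  }
  if (comp == 0) NA_real_ else conc / comp
}

# Random patient records exercising boundaries (VAF at 0.5 and at the
# cutoff, missing clonality, UPD without mutation, empty mutation lists).
random_test_cohort <- function(n, seed, cutoff = 0.23) {
  set.seed(seed)
  pat <- data.frame(
    patient_id = sprintf("R%05d", seq_len(n)),
    os_time = round(rexp(n, 1 / 24), 3),
    os_event = runif(n) < 0.6,
    del17p = runif(n) < 0.25,
    tp53_upd = runif(n) < 0.15,
    stringsAsFactors = FALSE)
  pat$del17p_clonality <- ifelse(
    pat$del17p & runif(n) < 0.7, round(runif(n), 3), NA_real_)
  pat$upd_clonality <- NA_real_
  n_mut <- sample(0:3, n, replace = TRUE, prob = c(0.25, 0.4, 0.25, 0.1))
  muts <- list()
  for (i in seq_len(n)) {
    if (n_mut[i] == 0) next
    v <- round(runif(n_mut[i], 0.01, 0.65), 3)
    # plant exact boundary values occasionally
    if (runif(1) < 0.1) v[1] <- cutoff
    if (runif(1) < 0.1) v[1] <- 0.5
    muts[[length(muts) + 1]] <- data.frame(
      patient_id = pat$patient_id[i],
      variant_id = paste0(pat$patient_id[i], "_", seq_len(n_mut[i])),
      vaf = v, stringsAsFactors = FALSE)
  }
  muts <- if (length(muts)) do.call(rbind, muts) else NULL
  co <- if (is.null(muts)) TP53Cohort(pat) else TP53Cohort(pat, muts)
  list(cohort = co, n_mut = n_mut)
}

# Apply the per-patient oracles across a cohort.
oracle_classify_cohort <- function(cohort, cutoff = 0.23) {
  p <- patients(cohort)
  m <- mutations(cohort)
  novel <- character(nrow(p))
  trad <- character(nrow(p))
  for (i in seq_len(nrow(p))) {
    vafs <- m$vaf[m$patient_id == p$patient_id[i]]
    novel[i] <- oracle_novel(vafs, p$del17p[i], p$del17p_clonality[i],
                             p$tp53_upd[i], cutoff)
    trad[i] <- oracle_traditional(length(vafs), p$del17p[i], p$tp53_upd[i])
  }
  list(novel = novel, traditional = trad)
}
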