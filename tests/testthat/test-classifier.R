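one_patient <- function(vafs = numeric(), del17p = FALSE,
                        del17p_clonality = NA_real_, tp53_upd = FALSE) {
  pat <- data.frame(patient_id = "P1", os_time = 10, os_event = TRUE,
                    del17p = del17p, del17p_clonality = del17p_clonality,
                    tp53_upd = tp53_upd, stringsAsFactors = FALSE)
  if (length(vafs)) {
    TP53Cohort(pat, data.frame(patient_id = "P1",
                               variant_id = paste0("v", seq_along(vafs)),
                               vaf = vafs, stringsAsFactors = FALSE))
  } else TP53Cohort(pat)
}

state_of <- function(...) suppressMessages(classifyNovel(one_patient(...)))$state
rule_of <- function(...) suppressMessages(classifyNovel(one_patient(...)))$rule

test_that("combined VAF sums mutations, caps at 1, and is 0 without mutations", {
  expect_equal(unname(combinedVAF(one_patient(c(0.30, 0.25)))), 0.55)
  expect_equal(unname(combinedVAF(one_patient())), 0)
  co <- one_patient(c(0.70, 0.60))
  expect_equal(sum(mutations(co)$vaf), 1.30)  # uncapped oracle
  expect_warning(cv <- combinedVAF(co), "capped")
  expect_equal(unname(cv), 1.0)
})

test_that("traditional classification counts hits", {
  expect_equal(classifyTraditional(one_patient(0.3))$label, "single_hit")
  expect_equal(classifyTraditional(one_patient(0.3, del17p = TRUE))$label,
               "double_hit")
  trad <- classifyTraditional(one_patient(del17p = TRUE))
  expect_equal(trad$label, "single_hit")
  expect_equal(trad$basis, "del17p")
  # UPD without a mutation is not a hit
  expect_equal(classifyTraditional(one_patient(tp53_upd = TRUE))$label,
               "wild_type")
  expect_equal(classifyTraditional(one_patient(c(0.2, 0.1)))$basis,
               "mutation,second_mutation")
})

test_that("three-group classifier follows the decision rules", {
  expect_equal(state_of(0.55), "obligatory_biallelic")
  expect_equal(rule_of(0.55), "single_vaf_gt50")
  expect_equal(state_of(0.08), "probable_monoallelic")
  expect_equal(state_of(0.33), "probable_biallelic")
  expect_equal(state_of(c(0.12, 0.08)), "probable_monoallelic")
  expect_equal(state_of(c(0.30, 0.25)), "obligatory_biallelic")
  expect_equal(rule_of(c(0.30, 0.25)), "combined_vaf_gt50")
  expect_equal(state_of(0.30, del17p = TRUE, del17p_clonality = 0.30),
               "obligatory_biallelic")
  expect_equal(rule_of(0.30, del17p = TRUE, del17p_clonality = 0.30),
               "vaf_plus_del17p_gt50")
  expect_equal(state_of(0.10, tp53_upd = TRUE), "obligatory_biallelic")
  expect_equal(rule_of(0.10, tp53_upd = TRUE), "mutation_with_upd")
  expect_equal(state_of(), "wild_type")
  expect_equal(state_of(del17p = TRUE), "del17p_only")
})

test_that("boundary cases resolve as documented", {
  # exactly at the cutoff goes to the higher-risk class
  expect_equal(state_of(0.23), "probable_biallelic")
  expect_equal(state_of(0.2299), "probable_monoallelic")
  # obligatory thresholds are strict
  expect_equal(state_of(0.5), "probable_biallelic")
  expect_equal(state_of(0.25, del17p = TRUE, del17p_clonality = 0.25),
               "probable_biallelic")
  # missing clonality disables only the VAF + clonality rule
  expect_equal(suppressMessages(
    classifyNovel(one_patient(0.45, del17p = TRUE)))$state,
    "probable_biallelic")
  expect_message(classifyNovel(one_patient(0.45, del17p = TRUE)),
                 "unknown clonality")
})

test_that("a traditional double hit can be probable monoallelic", {
  co <- one_patient(c(0.08, 0.06))
  expect_equal(classifyTraditional(co)$label, "double_hit")
  expect_equal(suppressMessages(classifyNovel(co))$state,
               "probable_monoallelic")
})

test_that("cohort classification matches the brute-force rule oracle", {
  rc <- random_test_cohort(2000, seed = 31)
  calls <- suppressMessages(classifyNovel(rc$cohort))
  trad <- classifyTraditional(rc$cohort)
  oracle <- oracle_classify_cohort(rc$cohort)
  expect_identical(calls$state, oracle$novel)
  expect_identical(trad$label, oracle$traditional)
})

test_that("probable calls respect the cutoff bands", {
  rc <- random_test_cohort(1500, seed = 37)
  for (cutoff in c(0.15, 0.23, 0.40)) {
    calls <- suppressMessages(classifyNovel(rc$cohort, cutoff = cutoff))
    mono <- calls$state == "probable_monoallelic"
    bi <- calls$state == "probable_biallelic"
    expect_true(all(calls$combined_vaf[mono] < cutoff))
    expect_true(all(calls$combined_vaf[bi] >= cutoff))
    expect_true(all(calls$combined_vaf[mono | bi] <= 0.5 + 1e-12))
  }
})

test_that("raising a VAF never lowers classification severity", {
  sev <- function(s) match(s, c("probable_monoallelic", "probable_biallelic",
                                "obligatory_biallelic"))
  set.seed(41)
  for (r in 1:200) {
    n_mut <- sample(1:3, 1)
    vafs <- runif(n_mut, 0.01, 0.55)
    del17p <- runif(1) < 0.3
    clon <- if (del17p && runif(1) < 0.7) runif(1) else NA_real_
    s0 <- sev(state_of(vafs, del17p = del17p, del17p_clonality = clon))
    k <- sample(n_mut, 1)
    vafs[k] <- min(1, vafs[k] + runif(1, 0, 0.4))
    s1 <- sev(state_of(vafs, del17p = del17p, del17p_clonality = clon))
    expect_gte(s1, s0)
  }
})

test_that("state shares are computed against TP53-mutant patients", {
  cohort4 <- TP53Cohort(
    data.frame(patient_id = c("A", "B", "C", "D"),
               os_time = c(5, 10, 15, 20), os_event = TRUE),
    data.frame(patient_id = c("A", "B", "C"),
               variant_id = c("v1", "v2", "v3"), vaf = c(0.55, 0.33, 0.08)))
  cc <- classifyCohort(cohort4)
  counts <- setNames(cc$summary$n, cc$summary$state)
  expect_equal(counts[["obligatory_biallelic"]], 1)
  expect_equal(counts[["probable_biallelic"]], 1)
  expect_equal(counts[["probable_monoallelic"]], 1)
  expect_equal(counts[["wild_type"]], 1)
  expect_equal(attr(cc$summary, "n_mutant"), 3)
  # all wild type: mutant share undefined (0 denominator)
  co_wt <- TP53Cohort(data.frame(patient_id = c("A", "B"),
                                 os_time = c(1, 2), os_event = TRUE))
  tab <- classifyCohort(co_wt)$summary
  expect_equal(attr(tab, "n_mutant"), 0)
})

test_that("reclassification table counts upstage and downstage moves", {
  # all single hits called probable monoallelic: nothing upstaged
  r0 <- reclassificationTable(rep("single_hit", 10),
                              rep("probable_monoallelic", 10))
  expect_equal(r0$upstage_pct, 0)
  expect_error(reclassificationTable(c("single_hit"), rep("x", 2)),
               "equal length")
  # table margins equal input label counts
  set.seed(5)
  tl <- sample(c("single_hit", "double_hit"), 500, replace = TRUE)
  nv <- sample(c("obligatory_biallelic", "probable_biallelic",
                 "probable_monoallelic"), 500, replace = TRUE)
  r <- reclassificationTable(tl, nv)
  expect_equal(rowSums(r$table), c(single_hit = sum(tl == "single_hit"),
                                   double_hit = sum(tl == "double_hit")))
  expect_equal(unname(colSums(r$table)),
               as.vector(table(nv)[colnames(r$table)]))
})
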