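test_that("expected VAF matches the closed forms on a clone-fraction grid", {
  for (f in seq(0.1, 1.0, by = 0.1)) {
    expect_equal(expectedVAF(cloneArchitecture(f, "mutA", "wt", "het_mono")),
                 f / 2, tolerance = 1e-12)
    expect_equal(expectedVAF(cloneArchitecture(f, "mutA", "deleted",
                                               "hemizygous")),
                 f / (2 - f), tolerance = 1e-12)
    expect_equal(expectedVAF(cloneArchitecture(f, "mutA", "mutA", "upd_hom")),
                 f, tolerance = 1e-12)
    comp <- cloneArchitecture(f, "mutA", "mutB", "compound_het")
    va <- expectedVAF(comp, "mutA"); vb <- expectedVAF(comp, "mutB")
    expect_equal(va, f / 2, tolerance = 1e-12)
    expect_equal(va + vb, f, tolerance = 1e-12)  # compound-het sum rule
  }
  # mosaic: each clone contributes f/2 on its own variant
  mos <- cloneArchitecture(c(0.2, 0.2), c("mutA", "mutB"), c("wt", "wt"),
                           "mosaic_two_mono")
  expect_equal(expectedVAF(mos, "mutA"), 0.1)
  expect_equal(expectedVAF(mos, "mutB"), 0.1)
  expect_equal(summedVAFEvidence(mos), 0.2)
})

test_that("architecture validity constraints are enforced", {
  expect_error(cloneArchitecture(0.5, "deleted", "deleted", "hemizygous"),
               "one allele")
  expect_error(cloneArchitecture(c(0.7, 0.6), c("mutA", "mutB"),
                                 c("wt", "wt"), "mosaic_two_mono"),
               "at most 1")
  expect_error(cloneArchitecture(0.5, "mutA", "wt", "not_a_label"), "label")
})

test_that("binomial read sampling concentrates on the true VAF", {
  expect_equal(sampleBulkVAF(0, 100, seed = 1), 0)
  obs <- sampleBulkVAF(0.5, 1e6, seed = 2)
  expect_lt(abs(obs - 0.5), 0.002)
  draws <- sampleBulkVAF(rep(0.3, 1e4), 100, seed = 3)
  se <- sqrt(0.3 * 0.7 / 100) / sqrt(1e4)
  expect_lt(abs(mean(draws) - 0.3), 3 * se)
})

test_that("survival simulation responds to the biallelic flag", {
  p <- simulationParams(seed = 5)
  # zero horizon: everything censored at ~0
  p0 <- simulationParams(horizon = 1e-9, seed = 5)
  s0 <- simulateSurvival(rep(TRUE, 100), p0, seed = 5)
  expect_true(all(!s0$os_event))
  expect_true(all(s0$os_time < 1e-9))
  # equal hazards: group medians agree within 10%
  pn <- simulationParams(lambda_low = log(2) / 30, lambda_high = log(2) / 30,
                         seed = 7)
  flag <- rep(c(TRUE, FALSE), each = 1000)
  sn <- simulateSurvival(flag, pn, seed = 7)
  m1 <- kmEstimate(sn$os_time[flag], sn$os_event[flag])$median
  m2 <- kmEstimate(sn$os_time[!flag], sn$os_event[!flag])$median
  expect_lt(abs(m1 - m2) / m2, 0.10)
  # hazard ratio 3 recovered by Cox regression
  s3 <- simulateSurvival(flag, p, seed = 9)
  fit <- coxFit(s3$os_time, s3$os_event, as.numeric(flag))
  expect_gt(fit$hr, 2.6)
  expect_lt(fit$hr, 3.4)
})

test_that("cohort generation is deterministic and truth-consistent", {
  params <- simulationParams(n_patients = 150, seed = 101)
  sim1 <- simulateCohort(params)
  sim2 <- simulateCohort(params)
  expect_identical(patients(sim1$cohort), patients(sim2$cohort))
  expect_identical(mutations(sim1$cohort), mutations(sim2$cohort))
  expect_identical(sim1$truth, sim2$truth)
  # pure heterozygous-monoallelic mixture: nobody is truly biallelic
  p_het <- simulationParams(n_patients = 100, mixture = c(het_mono = 1),
                            wt_fraction = 0, seed = 103)
  sim_het <- simulateCohort(p_het)
  expect_true(all(!sim_het$truth$has_biallelic))
  expect_true(all(sim_het$truth$config_label == "het_mono"))
  # truth table aligns with architectures
  for (i in sample(150, 10)) {
    expect_equal(sim1$truth$biallelic_fraction[i],
                 biallelicCloneFraction(sim1$architectures[[i]]))
  }
})

test_that("UPD-flagged mutant patients are always called obligatory biallelic", {
  p <- simulationParams(n_patients = 200,
                        mixture = c(upd_hom = 0.5, het_mono = 0.5),
                        wt_fraction = 0, clone_beta = c(8, 2),
                        depth_fixed = 500, seed = 107)
  sim <- simulateCohort(p)
  calls <- suppressMessages(classifyNovel(sim$cohort))
  pat <- patients(sim$cohort)
  upd_mut <- pat$tp53_upd & pat$patient_id %in% mutations(sim$cohort)$patient_id
  expect_gt(sum(upd_mut), 50)
  expect_true(all(calls$state[match(pat$patient_id[upd_mut],
                                    calls$patient_id)] ==
                    "obligatory_biallelic"))
})

test_that("classifier recovers obligatory biallelic truth at high clonality", {
  # large clones, deep sequencing: bulk arithmetic nearly always decides
  p <- simulationParams(n_patients = 400,
                        mixture = c(het_mono = 0.3, hemizygous = 0.2,
                                    upd_hom = 0.2, compound_het = 0.3),
                        wt_fraction = 0, clone_beta = c(30, 8),
                        depth_fixed = 300, seed = 109)
  sim <- simulateCohort(p)
  calls <- suppressMessages(classifyNovel(sim$cohort))
  truth <- sim$truth$has_biallelic
  obl <- calls$state == "obligatory_biallelic"
  sens <- sum(obl & truth) / sum(truth)
  specificity <- sum(!obl & !truth) / sum(!truth)
  expect_gte(sens, 0.95)
  expect_gte(specificity, 0.95)
})

test_that("single-cell matrices reflect clone fractions and dropout model", {
  comp <- cloneArchitecture(0.32, "mutA", "mutB", "compound_het")
  sc <- simulateSingleCellMatrix(comp, 1e4, dropout = 0, error = 0, seed = 11)
  g <- SummarizedExperiment::assay(sc$matrix, "genotype")
  both <- colSums(g != "WT") == 2
  expect_lt(abs(mean(both) - 0.32), 0.01)
  # mosaic clones never co-occur in one cell without noise
  mos <- cloneArchitecture(c(0.3, 0.3), c("mutA", "mutB"), c("wt", "wt"),
                           "mosaic_two_mono")
  sc2 <- simulateSingleCellMatrix(mos, 3000, dropout = 0, error = 0, seed = 13)
  g2 <- SummarizedExperiment::assay(sc2$matrix, "genotype")
  expect_equal(sum(colSums(g2 != "WT") == 2), 0)
  # dropout on homozygous cells: per-allele model gives
  # MISSING = d^2, HOM retained otherwise
  hom <- cloneArchitecture(1.0, "mutA", "mutA", "upd_hom")
  sc3 <- simulateSingleCellMatrix(hom, 8000, dropout = 0.5, error = 0,
                                  seed = 17)
  g3 <- SummarizedExperiment::assay(sc3$matrix, "genotype")
  expect_lt(abs(mean(g3 == "MISSING") - 0.25), 0.02)
  expect_lt(abs(mean(g3 == "HOM_OR_HEMI") - 0.75), 0.02)
  # heterozygous cells miscall as WT or HOM when one allele drops
  het <- cloneArchitecture(1.0, "mutA", "wt", "het_mono")
  sc4 <- simulateSingleCellMatrix(het, 8000, dropout = 0.5, error = 0,
                                  seed = 19)
  g4 <- SummarizedExperiment::assay(sc4$matrix, "genotype")
  expect_lt(abs(mean(g4 == "HET") - 0.25), 0.02)
  expect_lt(abs(mean(g4 == "WT") - 0.25), 0.02)
  expect_lt(abs(mean(g4 == "HOM_OR_HEMI") - 0.25), 0.02)
  # hemizygous cells carry the 17p copy state
  hemi <- cloneArchitecture(0.6, "mutA", "deleted", "hemizygous")
  sc5 <- simulateSingleCellMatrix(hemi, 2000, dropout = 0, error = 0,
                                  seed = 23)
  cn <- SummarizedExperiment::colData(sc5$matrix)$cn17p
  expect_equal(unname(cn == 1L), unname(sc5$clone == 1L))
})

test_that("bulk evidence separates biallelic-majority from purely monoallelic", {
  set.seed(201)
  for (r in 1:300) {
    arch <- randomArchitecture()
    s <- summedVAFEvidence(arch)
    if (biallelicCloneFraction(arch) > 0.5) expect_gt(s, 0.5)
    if (biallelicCloneFraction(arch) == 0) expect_lt(s, 0.5)
  }
})
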