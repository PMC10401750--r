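## Clonal-architecture simulator: ground-truth clone sets, analytic and
## read-sampled bulk VAFs, survival with biallelic-dependent hazards, and
## cohort generation.

#' Construct a clonal architecture
#'
#' @param fractions numeric clone fractions in (0, 1\], summing to at most 1
#'   (the remainder is wild-type cells).
#' @param allele_a,allele_b character vectors of allele codes (`wt`, `mutA`,
#'   `mutB`, `deleted`), one entry per clone; at most one allele deleted per
#'   clone.
#' @param label configuration label (see [ClonalArchitecture-class]).
#' @return a validated [ClonalArchitecture-class].
#' @examples
#' hemi <- cloneArchitecture(0.8, "mutA", "deleted", "hemizygous")
#' expectedVAF(hemi, "mutA")  # 0.8 / (2 - 0.8)
#' @export
cloneArchitecture <- function(fractions, allele_a, allele_b, label) {
  new("ClonalArchitecture",
      clones = data.frame(fraction = as.numeric(fractions),
                          allele_a = as.character(allele_a),
                          allele_b = as.character(allele_b),
                          stringsAsFactors = FALSE),
      label = label)
}

#' Analytic expected VAF of a variant under a clonal architecture
#'
#' VAF(v) = sum_c f_c m_c(v) / (sum_c f_c k_c + (1 - sum_c f_c) * 2), where
#' m_c is the number of copies of variant v in clone c and k_c the locus copy
#' number of clone c (2, or 1 when one allele is deleted). Closed forms for
#' single-clone architectures: f/2 (heterozygous), f/(2-f) (hemizygous), f
#' (UPD-homozygous), f/2 per variant (compound heterozygous).
#'
#' @param arch a [ClonalArchitecture-class].
#' @param variant `"mutA"` or `"mutB"`.
#' @return expected VAF as a fraction in \[0, 1\].
#' @export
expectedVAF <- function(arch, variant = "mutA") {
  stopifnot(variant %in% c("mutA", "mutB"))
  cl <- clones(arch)
  if (!nrow(cl)) return(0)
  m <- (cl$allele_a == variant) + (cl$allele_b == variant)
  k <- 2L - ((cl$allele_a == "deleted") + (cl$allele_b == "deleted"))
  f_tot <- sum(cl$fraction)
  denom <- sum(cl$fraction * k) + (1 - f_tot) * 2
  sum(cl$fraction * m) / denom
}

#' @describeIn expectedVAF variants carried by at least one clone
#' @export
variantsPresent <- function(arch) {
  cl <- clones(arch)
  vars <- c("mutA", "mutB")
  vars[vars %in% c(cl$allele_a, cl$allele_b)]
}

#' Ground-truth quantities of a clonal architecture
#'
#' `biallelicCloneFraction` is the largest fraction among clones with both
#' alleles inactivated (mutated or deleted); 0 when no such clone exists.
#' `del17pClonality` is the total fraction of cells carrying a deleted
#' allele. `summedVAFEvidence` is the bulk-arithmetic evidence used by the
#' obligatory rules: the sum of per-variant expected VAFs plus the del(17p)
#' clonality.
#'
#' @param arch a [ClonalArchitecture-class].
#' @return a fraction.
#' @export
biallelicCloneFraction <- function(arch) {
  cl <- clones(arch)
  if (!nrow(cl)) return(0)
  bi <- cl$allele_a != "wt" & cl$allele_b != "wt"
  if (!any(bi)) return(0)
  max(cl$fraction[bi])
}

#' @rdname biallelicCloneFraction
#' @export
del17pClonality <- function(arch) {
  cl <- clones(arch)
  if (!nrow(cl)) return(0)
  sum(cl$fraction[cl$allele_a == "deleted" | cl$allele_b == "deleted"])
}

#' @rdname biallelicCloneFraction
#' @export
summedVAFEvidence <- function(arch) {
  vs <- variantsPresent(arch)
  sum(vapply(vs, function(v) expectedVAF(arch, v), numeric(1))) +
    del17pClonality(arch)
}

#' @describeIn biallelicCloneFraction does the architecture contain a UPD
#'   (homozygous-mutant, copy-neutral) clone?
#' @export
hasUPDClone <- function(arch) {
  cl <- clones(arch)
  if (!nrow(cl)) return(FALSE)
  any(cl$allele_a %in% c("mutA", "mutB") & cl$allele_a == cl$allele_b)
}

MUTANT_ARCH_LABELS <- setdiff(ARCH_LABELS, "wild_type")

#' Draw a random clonal architecture of a given configuration
#'
#' Clone fractions are drawn from a Beta distribution; mosaic and nested
#' configurations split/subset that fraction. Intended as the building block
#' of [simulateCohort()] and of property tests over the architecture space.
#'
#' @param label one of the mutant configuration labels, or `NULL` to sample a
#'   label uniformly.
#' @param clone_beta length-2 Beta shape parameters for clone fractions.
#' @param seed optional integer seed.
#' @return a [ClonalArchitecture-class].
#' @export
randomArchitecture <- function(label = NULL, clone_beta = c(2, 2),
                               seed = NULL) {
  with_seed(seed, {
    if (is.null(label)) label <- sample(MUTANT_ARCH_LABELS, 1)
    f <- stats::rbeta(1, clone_beta[1], clone_beta[2])
    f <- min(max(f, 1e-3), 1)
    switch(label,
      het_mono = cloneArchitecture(f, "mutA", "wt", label),
      hemizygous = cloneArchitecture(f, "mutA", "deleted", label),
      upd_hom = cloneArchitecture(f, "mutA", "mutA", label),
      compound_het = cloneArchitecture(f, "mutA", "mutB", label),
      mosaic_two_mono = {
        u <- runif(1, 0.25, 0.75)
        cloneArchitecture(c(f * u, f * (1 - u)), c("mutA", "mutB"),
                          c("wt", "wt"), label)
      },
      nested_biallelic_subclone = {
        child <- f * runif(1, 0.1, 0.9)
        second <- if (runif(1) < 0.5) c("mutA", "mutA") else c("mutA", "mutB")
        cloneArchitecture(c(f - child, child),
                          c("mutA", second[1]), c("wt", second[2]), label)
      },
      stop("unknown architecture label: ", label))
  })
}

#' Binomial read-sampling of a bulk VAF
#'
#' @param true_vaf expected VAF fraction(s).
#' @param depth read depth(s), positive integers (recycled).
#' @param seed optional integer seed.
#' @return observed VAF(s): Binomial(depth, true_vaf) / depth.
#' @export
sampleBulkVAF <- function(true_vaf, depth, seed = NULL) {
  stopifnot(all(depth >= 1), all(true_vaf >= 0 & true_vaf <= 1))
  with_seed(seed, rbinom(length(true_vaf) * 1L, size = depth,
                         prob = true_vaf) / depth)
}

#' Simulation parameters
#'
#' Defaults describe a myeloid-neoplasia-like cohort: configuration mixture
#' spanning all clonal architectures, Beta(2, 2) clone fractions, negative
#' binomial panel depths around 500x, exponential survival with hazards
#' anchored to median overall survival of 42 months (no biallelic clone) and
#' 14 months (biallelic clone present), uniform censoring over a 120-month
#' horizon, subtype frequencies matching a TP53-mutant myeloid cohort, and
#' single-cell allelic dropout of 0.1.
#'
#' @param n_patients cohort size.
#' @param mixture named probabilities over the mutant configuration labels.
#' @param wt_fraction fraction of patients with no TP53 lesion at all.
#' @param clone_beta Beta shape parameters for clone fractions.
#' @param depth_mean,depth_disp negative binomial mean and size for read
#'   depths (minimum enforced at 30); set `depth_fixed` to override.
#' @param depth_fixed optional fixed read depth.
#' @param lambda_low,lambda_high exponential hazards (per month) without /
#'   with a biallelic clone of size at least `tau`.
#' @param tau minimal biallelic clone fraction that elevates the hazard
#'   (default 0: any biallelic clone).
#' @param horizon censoring horizon in months (censoring ~ Uniform(0, horizon)).
#' @param dropout,genotype_error single-cell per-allele dropout and genotype
#'   miscall probabilities.
#' @param clonality_sd Gaussian noise SD on observed del(17p)/UPD clonality
#'   (truncated to \[0, 1\]).
#' @param clonality_missing_rate probability that a del(17p) clonality is
#'   unreported.
#' @param subtype_probs named probabilities over disease subtypes.
#' @param seed integer seed.
#' @return list of class `simulation_params`.
#' @export
simulationParams <- function(n_patients = 1000L,
                             mixture = c(het_mono = 0.25, hemizygous = 0.15,
                                         upd_hom = 0.12, compound_het = 0.18,
                                         mosaic_two_mono = 0.12,
                                         nested_biallelic_subclone = 0.18),
                             wt_fraction = 0.25,
                             clone_beta = c(2, 2),
                             depth_mean = 500, depth_disp = 5,
                             depth_fixed = NULL,
                             lambda_low = log(2) / 42,
                             lambda_high = log(2) / 14,
                             tau = 0,
                             horizon = 120,
                             dropout = 0.1, genotype_error = 0.01,
                             clonality_sd = 0.02,
                             clonality_missing_rate = 0,
                             subtype_probs = c(pAML = 0.31, sAML = 0.11,
                                               HR_MDS = 0.23, LR_MDS = 0.24,
                                               MDS_MPN = 0.10, other = 0.01),
                             seed = 1L) {
  stopifnot(lambda_high >= lambda_low, lambda_low > 0,
            dropout >= 0, dropout < 1, tau >= 0, tau <= 1,
            wt_fraction >= 0, wt_fraction < 1,
            all(names(mixture) %in% MUTANT_ARCH_LABELS))
  mixture <- mixture / sum(mixture)
  subtype_probs <- subtype_probs / sum(subtype_probs)
  structure(list(n_patients = as.integer(n_patients), mixture = mixture,
                 wt_fraction = wt_fraction, clone_beta = clone_beta,
                 depth_mean = depth_mean, depth_disp = depth_disp,
                 depth_fixed = depth_fixed, lambda_low = lambda_low,
                 lambda_high = lambda_high, tau = tau, horizon = horizon,
                 dropout = dropout, genotype_error = genotype_error,
                 clonality_sd = clonality_sd,
                 clonality_missing_rate = clonality_missing_rate,
                 subtype_probs = subtype_probs, seed = as.integer(seed)),
            class = "simulation_params")
}

#' Simulate an overall-survival observation
#'
#' Event time is exponential with rate `lambda_high` when a biallelic clone
#' of size at least `tau` is present, else `lambda_low`; censoring is uniform
#' on (0, horizon); the observation is the minimum with an event indicator.
#'
#' @param has_biallelic logical vector (one entry per subject).
#' @param params a [simulationParams()].
#' @param seed optional integer seed.
#' @return `data.frame` with `os_time`, `os_event`.
#' @export
simulateSurvival <- function(has_biallelic, params = simulationParams(),
                             seed = NULL) {
  n <- length(has_biallelic)
  with_seed(seed, {
    rate <- ifelse(has_biallelic, params$lambda_high, params$lambda_low)
    t_event <- rexp(n, rate = rate)
    t_cens <- runif(n, 0, params$horizon)
    data.frame(os_time = pmin(t_event, t_cens),
               os_event = t_event <= t_cens)
  })
}

random_protein_change <- function(n) {
  csq <- sample(c("missense", "truncating", "splice"), n, replace = TRUE,
                prob = c(0.78, 0.17, 0.05))
  canon <- c(175L, 220L, 237L, 248L, 273L, 282L)
  aa <- setdiff(unname(AA_3TO1), "*")
  out <- character(n)
  for (i in seq_len(n)) {
    if (csq[i] == "missense") {
      pos <- if (runif(1) < 0.69) {
        canon[sample.int(6, 1)] + sample(-5:5, 1)
      } else sample(30:360, 1)
      pair <- sample(aa, 2)
      out[i] <- sprintf("p.%s%d%s", pair[1], pos, pair[2])
    } else if (csq[i] == "truncating") {
      pos <- sample(30:360, 1)
      out[i] <- if (runif(1) < 0.5) {
        sprintf("p.%s%d*", sample(aa, 1), pos)
      } else sprintf("p.%s%dfs", sample(aa, 1), pos)
    } else {
      out[i] <- ""  # splice variants carry no protein change
    }
  }
  list(protein_change = out, consequence = csq)
}

truncnorm01 <- function(x, sd) {
  if (sd <= 0) return(x)
  pmin(pmax(x + rnorm(length(x), 0, sd), 0), 1)
}

#' Generate a synthetic cohort with ground truth
#'
#' Per patient: a configuration label is drawn from the mixture (or the
#' patient is TP53 wild type), clone fractions are drawn, analytic VAFs are
#' computed and observed through binomial read sampling at a drawn depth,
#' del(17p)/UPD clonalities are observed with optional noise, and survival is
#' drawn with a hazard depending on the presence of a biallelic clone of size
#' at least `tau`. Mutations whose sampled VAF is 0 are not reported (below
#' the detection floor), mirroring real variant calling.
#'
#' @param params a [simulationParams()].
#' @return list with `cohort` (a [TP53Cohort-class]) and `truth`
#'   (`data.frame`: `patient_id`, `config_label`, `biallelic_fraction`,
#'   `has_biallelic`, `true_vaf_sum`, `del17p_true_clonality`) and
#'   `architectures` (list of [ClonalArchitecture-class]).
#' @examples
#' sim <- simulateCohort(simulationParams(n_patients = 50, seed = 42))
#' table(classifyNovel(sim$cohort)$state)
#' @export
simulateCohort <- function(params = simulationParams()) {
  with_seed(params$seed, {
    n <- params$n_patients
    ids <- sprintf("P%04d", seq_len(n))
    is_wt <- runif(n) < params$wt_fraction
    labels <- ifelse(is_wt, "wild_type",
                     sample(names(params$mixture), n, replace = TRUE,
                            prob = params$mixture))
    archs <- vector("list", n)
    pat_rows <- vector("list", n)
    mut_rows <- vector("list", n)
    truth_rows <- vector("list", n)
    subtypes <- sample(names(params$subtype_probs), n, replace = TRUE,
                       prob = params$subtype_probs)
    for (i in seq_len(n)) {
      arch <- if (labels[i] == "wild_type") {
        cloneArchitecture(numeric(), character(), character(), "wild_type")
      } else {
        randomArchitecture(labels[i], params$clone_beta)
      }
      archs[[i]] <- arch
      vs <- variantsPresent(arch)
      true_vafs <- vapply(vs, function(v) expectedVAF(arch, v), numeric(1))
      if (length(vs)) {
        depth <- if (!is.null(params$depth_fixed)) {
          rep(params$depth_fixed, length(vs))
        } else {
          pmax(30L, rnbinom(length(vs), mu = params$depth_mean,
                            size = params$depth_disp))
        }
        obs <- rbinom(length(vs), size = depth, prob = true_vafs) / depth
        keep <- obs > 0
        if (any(keep)) {
          ann <- random_protein_change(sum(keep))
          mut_rows[[i]] <- data.frame(
            patient_id = ids[i],
            variant_id = paste0(ids[i], "_", sub("mut", "", vs[keep])),
            protein_change = ann$protein_change,
            aa_position = NA_integer_,
            consequence = ann$consequence,
            vaf = obs[keep], depth = as.integer(depth[keep]),
            stringsAsFactors = FALSE)
        }
      }
      del_clon_true <- del17pClonality(arch)
      del17p <- del_clon_true > 0
      del_clon_obs <- NA_real_
      if (del17p && runif(1) >= params$clonality_missing_rate) {
        del_clon_obs <- truncnorm01(del_clon_true, params$clonality_sd)
      }
      upd <- hasUPDClone(arch)
      upd_clon_obs <- NA_real_
      if (upd) {
        cl <- clones(arch)
        upd_f <- sum(cl$fraction[cl$allele_a %in% c("mutA", "mutB") &
                                   cl$allele_a == cl$allele_b])
        upd_clon_obs <- truncnorm01(upd_f, params$clonality_sd)
      }
      blast <- switch(subtypes[i],
                      pAML = runif(1, 20, 90), sAML = runif(1, 20, 90),
                      HR_MDS = runif(1, 5, 19), LR_MDS = runif(1, 0, 4.9),
                      runif(1, 0, 19))
      bi_frac <- biallelicCloneFraction(arch)
      truth_rows[[i]] <- data.frame(
        patient_id = ids[i], config_label = labels[i],
        biallelic_fraction = bi_frac,
        has_biallelic = bi_frac > 0 & bi_frac >= params$tau,
        true_vaf_sum = sum(true_vafs),
        del17p_true_clonality = del_clon_true,
        stringsAsFactors = FALSE)
      pat_rows[[i]] <- data.frame(
        patient_id = ids[i], subtype = subtypes[i], blast_pct = blast,
        os_time = NA_real_, os_event = NA,
        del17p = del17p, del17p_clonality = del_clon_obs,
        complex_karyotype = runif(1) < if (labels[i] == "wild_type") 0.10 else 0.72,
        tp53_upd = upd, upd_clonality = upd_clon_obs,
        stringsAsFactors = FALSE)
    }
    truth <- do.call(rbind, truth_rows)
    pat <- do.call(rbind, pat_rows)
    surv <- simulateSurvival(truth$has_biallelic, params)
    pat$os_time <- surv$os_time
    pat$os_event <- surv$os_event
    muts <- if (length(Filter(Negate(is.null), mut_rows))) {
      do.call(rbind, Filter(Negate(is.null), mut_rows))
    } else empty_mutation_table()
    if (nrow(muts)) {
      parsed <- parseProteinChange(muts$protein_change)
      muts$aa_position <- parsed$aa_position
    }
    cohort <- TP53Cohort(pat, muts,
                         metadata = list(simulated = TRUE,
                                         seed = params$seed,
                                         params_hash = object_hash(unclass(params))))
    list(cohort = cohort, truth = truth, architectures = archs)
  })
}

#' Simulate an ambiguous-zone cohort with a planted VAF change-point
#'
#' Subjects carry combined VAFs uniform on (0.02, 0.5); those at or above
#' `changepoint` have their hazard multiplied by `hazard_ratio`. This is the
#' test bed for the cutoff search: the survival-optimal split lies at the
#' planted change-point.
#'
#' @param n number of subjects.
#' @param changepoint planted VAF change-point (fraction).
#' @param hazard_ratio hazard ratio above vs below the change-point.
#' @param lambda_low baseline hazard per month.
#' @param horizon censoring horizon (months).
#' @param seed integer seed.
#' @return list with `vafs`, `times`, `events`, `above` (truth flags).
#' @export
simulateAmbiguousCohort <- function(n = 800L, changepoint = 0.23,
                                    hazard_ratio = 3,
                                    lambda_low = log(2) / 42,
                                    horizon = 120, seed = 1L) {
  with_seed(seed, {
    vafs <- runif(n, 0.02, 0.5)
    above <- vafs >= changepoint
    rate <- ifelse(above, lambda_low * hazard_ratio, lambda_low)
    t_event <- rexp(n, rate)
    t_cens <- runif(n, 0, horizon)
    list(vafs = vafs, times = pmin(t_event, t_cens),
         events = t_event <= t_cens, above = above)
  })
}

#' Simulate a single-cell genotype matrix from a clonal architecture
#'
#' Cells are assigned to clones (or the wild-type remainder) multinomially.
#' Each cell's true genotype per variant follows its clone's alleles. Each
#' physical allele is then observed independently with probability
#' `1 - dropout`; the observed genotype call is made from the observed
#' alleles: none observed = `MISSING`, only wild-type/other observed = `WT`,
#' only the variant observed = `HOM_OR_HEMI`, both = `HET`. Finally, with
#' probability `error` a non-missing call is flipped to one of the other two
#' codes.
#'
#' @param arch a [ClonalArchitecture-class].
#' @param n_cells number of cells.
#' @param dropout per-allele dropout probability in \[0, 1).
#' @param error genotype miscall probability.
#' @param seed optional integer seed.
#' @return list with `matrix` (a [CellGenotypeMatrix-class], variants x
#'   cells, with per-cell `cn17p` in `colData`), `truth` (dropout-free
#'   genotype matrix), and `clone` (per-cell clone index, 0 = wild type).
#' @export
simulateSingleCellMatrix <- function(arch, n_cells, dropout = 0.1,
                                     error = 0.01, seed = NULL) {
  stopifnot(n_cells >= 1, dropout >= 0, dropout < 1, error >= 0, error < 1)
  with_seed(seed, {
    cl <- clones(arch)
    probs <- c(cl$fraction, 1 - sum(cl$fraction))
    assign <- sample.int(length(probs), n_cells, replace = TRUE, prob = probs)
    assign[assign > nrow(cl)] <- 0L  # wild-type remainder
    vars <- variantsPresent(arch)
    if (!length(vars)) vars <- "mutA"
    truth <- matrix("WT", nrow = length(vars), ncol = n_cells,
                    dimnames = list(vars, sprintf("cell%05d", seq_len(n_cells))))
    obs <- truth
    cn17p <- rep(2L, n_cells)
    for (ci in seq_len(n_cells)) {
      k <- 2L
      alleles <- c("wt", "wt")
      if (assign[ci] > 0) {
        alleles <- c(cl$allele_a[assign[ci]], cl$allele_b[assign[ci]])
        k <- 2L - sum(alleles == "deleted")
        if (k == 1L) cn17p[ci] <- 1L
        alleles <- alleles[alleles != "deleted"]
      }
      for (vi in seq_along(vars)) {
        m <- sum(alleles == vars[vi])
        o <- length(alleles) - m
        truth[vi, ci] <- if (m == 0L) "WT" else if (o == 0L) "HOM_OR_HEMI" else "HET"
        om <- rbinom(1, m, 1 - dropout)
        oo <- rbinom(1, o, 1 - dropout)
        code <- if (om + oo == 0L) "MISSING" else if (om == 0L) "WT" else
          if (oo == 0L) "HOM_OR_HEMI" else "HET"
        if (code != "MISSING" && error > 0 && runif(1) < error) {
          code <- sample(setdiff(c("WT", "HET", "HOM_OR_HEMI"), code), 1)
        }
        obs[vi, ci] <- code
      }
    }
    list(matrix = CellGenotypeMatrix(obs, cn17p = cn17p),
         truth = truth, clone = assign)
  })
}
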