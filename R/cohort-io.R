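## Readers/writers for the long-format cohort TSV and TP53 VCF import.

COHORT_TSV_COLS <- c("patient_id", "subtype", "blast_pct", "os_time_months",
                     "os_event", "del17p", "del17p_clonality",
                     "complex_karyotype", "tp53_upd", "upd_clonality",
                     "variant_id", "protein_change", "consequence", "vaf",
                     "depth")

as_flag <- function(x) {
  if (is.logical(x)) return(ifelse(is.na(x), FALSE, x))
  x <- tolower(as.character(x))
  out <- x %in% c("1", "true", "t", "yes")
  out
}

num_or_na <- function(x) suppressWarnings(as.numeric(x))

#' Read a cohort from a long-format TSV
#'
#' One row per TP53 variant call, with patient-level columns (cytogenetics,
#' survival, subtype) repeated across a patient's rows; patients without
#' mutations appear as a single row with empty variant fields. Required
#' columns: `patient_id`, `os_time_months`, `os_event`; mutation rows are
#' recognised by a non-empty `variant_id` (or `protein_change`) and must carry
#' a VAF. VAF values greater than 1 are interpreted as percentages and divided
#' by 100 (reported via a message). Missing `consequence` on a mutation row
#' is derived from `protein_change` when possible.
#'
#' @param path TSV file path.
#' @param percent_vaf_message logical; emit a message when percent-scale VAFs
#'   are rescaled.
#' @return A [TP53Cohort-class].
#' @seealso [writeCohortTSV()]
#' @export
readCohortTSV <- function(path, percent_vaf_message = TRUE) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  d <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                  na.strings = c("NA", ""), colClasses = "character")
  required <- c("patient_id", "os_time_months", "os_event")
  miss <- setdiff(required, names(d))
  if (length(miss)) {
    stop("cohort TSV is missing required column(s): ",
         paste(miss, collapse = ", "))
  }
  for (nm in setdiff(COHORT_TSV_COLS, names(d))) d[[nm]] <- NA_character_
  os_time <- num_or_na(d$os_time_months)
  if (any(is.na(os_time))) stop("non-numeric os_time_months values")
  if (any(os_time < 0)) stop("negative os_time_months values")

  is_mut <- !is.na(d$variant_id) | !is.na(d$protein_change)
  vaf <- num_or_na(d$vaf)
  if (any(is_mut & is.na(vaf))) {
    stop("mutation row(s) with missing VAF at line(s): ",
         paste(head(which(is_mut & is.na(vaf)), 5), collapse = ", "))
  }
  pct <- is_mut & !is.na(vaf) & vaf > 1
  if (any(pct)) {
    if (percent_vaf_message) {
      message(sum(pct), " VAF value(s) > 1 interpreted as percent and divided by 100")
    }
    vaf[pct] <- vaf[pct] / 100
  }

  firsts <- !duplicated(d$patient_id)
  pat <- data.frame(
    patient_id = d$patient_id[firsts],
    subtype = ifelse(is.na(d$subtype[firsts]), "other", d$subtype[firsts]),
    blast_pct = num_or_na(d$blast_pct[firsts]),
    os_time = os_time[firsts],
    os_event = as_flag(d$os_event[firsts]),
    del17p = as_flag(d$del17p[firsts]),
    del17p_clonality = num_or_na(d$del17p_clonality[firsts]),
    complex_karyotype = as_flag(d$complex_karyotype[firsts]),
    tp53_upd = as_flag(d$tp53_upd[firsts]),
    upd_clonality = num_or_na(d$upd_clonality[firsts]),
    stringsAsFactors = FALSE)

  if (any(is_mut)) {
    md <- d[is_mut, , drop = FALSE]
    mut <- data.frame(
      patient_id = md$patient_id,
      variant_id = ifelse(is.na(md$variant_id),
                          paste0(md$patient_id, ":", md$protein_change),
                          md$variant_id),
      protein_change = md$protein_change,
      aa_position = NA_integer_,
      consequence = md$consequence,
      vaf = vaf[is_mut],
      depth = suppressWarnings(as.integer(md$depth)),
      stringsAsFactors = FALSE)
    if (anyDuplicated(mut[, c("patient_id", "variant_id")])) {
      stop("duplicate (patient_id, variant_id) mutation rows")
    }
    parsed <- parseProteinChange(mut$protein_change)
    mut$aa_position <- parsed$aa_position
    fill <- is.na(mut$consequence) | !(mut$consequence %in% CONSEQUENCE_LEVELS)
    mut$consequence[fill] <- parsed$consequence[fill]
  } else {
    mut <- empty_mutation_table()
  }
  TP53Cohort(patients = pat, mutations = mut,
             metadata = list(source = path))
}

fmt_num <- function(x, digits) {
  ifelse(is.na(x), NA_character_, formatC(x, digits = digits, format = "f"))
}

cohort_to_long <- function(cohort, vaf_digits = 6) {
  p <- patients(cohort)
  m <- mutations(cohort)
  idx <- match(m$patient_id, p$patient_id)
  no_mut <- !(p$patient_id %in% m$patient_id)
  rows <- rbind(
    data.frame(pidx = idx, variant_id = m$variant_id,
               protein_change = m$protein_change, consequence = m$consequence,
               vaf = fmt_num(m$vaf, vaf_digits), depth = m$depth,
               stringsAsFactors = FALSE),
    data.frame(pidx = which(no_mut), variant_id = NA_character_,
               protein_change = NA_character_, consequence = NA_character_,
               vaf = NA_character_, depth = NA_integer_,
               stringsAsFactors = FALSE))
  rows <- rows[order(rows$pidx), , drop = FALSE]
  out <- data.frame(
    patient_id = p$patient_id[rows$pidx],
    subtype = p$subtype[rows$pidx],
    blast_pct = fmt_num(p$blast_pct[rows$pidx], 2),
    os_time_months = fmt_num(p$os_time[rows$pidx], 4),
    os_event = as.integer(p$os_event[rows$pidx]),
    del17p = as.integer(p$del17p[rows$pidx]),
    del17p_clonality = fmt_num(p$del17p_clonality[rows$pidx], 4),
    complex_karyotype = as.integer(p$complex_karyotype[rows$pidx]),
    tp53_upd = as.integer(p$tp53_upd[rows$pidx]),
    upd_clonality = fmt_num(p$upd_clonality[rows$pidx], 4),
    variant_id = rows$variant_id,
    protein_change = rows$protein_change,
    consequence = rows$consequence,
    vaf = rows$vaf,
    depth = rows$depth,
    stringsAsFactors = FALSE)
  out
}

#' Write a cohort to the long-format TSV
#'
#' Inverse of [readCohortTSV()] up to float formatting (VAFs and clonalities
#' at 6 and 4 decimals respectively).
#'
#' @param cohort a [TP53Cohort-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeCohortTSV <- function(cohort, path) {
  out <- cohort_to_long(cohort)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' Write per-patient allelic-state calls alongside clinical columns
#'
#' @param cohort a [TP53Cohort-class].
#' @param calls `data.frame` of calls from [classifyNovel()] (one row per
#'   patient, same order or keyed by `patient_id`).
#' @param path output TSV path. Floats are written with 4 decimals; the file
#'   is re-readable with `read.delim`.
#' @return `path`, invisibly.
#' @export
writeClassifiedTSV <- function(cohort, calls, path) {
  p <- patients(cohort)
  if (nrow(calls) != nrow(p)) {
    stop("calls must contain exactly one row per patient (",
         nrow(calls), " calls vs ", nrow(p), " patients)")
  }
  idx <- match(p$patient_id, calls$patient_id)
  if (anyNA(idx)) stop("calls missing for some patients")
  calls <- calls[idx, , drop = FALSE]
  out <- data.frame(
    patient_id = p$patient_id,
    subtype = p$subtype,
    os_time_months = fmt_num(p$os_time, 4),
    os_event = as.integer(p$os_event),
    del17p = as.integer(p$del17p),
    tp53_upd = as.integer(p$tp53_upd),
    state = calls$state,
    rule = calls$rule,
    combined_vaf = fmt_num(calls$combined_vaf, 4),
    cutoff_used = fmt_num(calls$cutoff_used, 4),
    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' Import TP53 variant calls from a VCF
#'
#' Per sample and record, the VAF is taken from the `AF` FORMAT field when
#' present, otherwise computed as alt/(ref+alt) from `AD` allele depths.
#' Records/samples offering neither are skipped with a warning. Only carrier
#' calls (VAF > 0) are returned. Consequence is derived from an INFO
#' annotation field (`Consequence`, `CSQ`, or `ANN`) when available, else
#' `"other"`.
#'
#' @param path VCF (v4.x) file path.
#' @return `data.frame` with columns `patient_id` (the sample name),
#'   `variant_id`, `protein_change`, `aa_position`, `consequence`, `vaf`,
#'   `depth`; suitable as the `mutations` table of [TP53Cohort()].
#' @export
readTP53VCF <- function(path) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  vcf <- VariantAnnotation::readVcf(path)
  g <- VariantAnnotation::geno(vcf)
  samples <- colnames(vcf)
  vids <- rownames(vcf)
  info <- VariantAnnotation::info(vcf)
  csq_field <- intersect(c("Consequence", "CSQ", "ANN"), names(info))
  csq <- rep("other", length(vids))
  hgvsp <- rep(NA_character_, length(vids))
  if (length(csq_field)) {
    raw <- info[[csq_field[1]]]
    raw <- vapply(seq_along(vids), function(i) {
      v <- raw[[i]]
      if (length(v)) paste(as.character(v), collapse = "|") else ""
    }, character(1))
    csq <- map_consequence(raw)
  }
  if ("HGVSP" %in% names(info)) {
    hp <- info[["HGVSP"]]
    hgvsp <- vapply(seq_along(vids), function(i) {
      v <- hp[[i]]
      if (length(v) && nzchar(v[1])) as.character(v[1]) else NA_character_
    }, character(1))
  }
  has_af <- "AF" %in% names(g)
  has_ad <- "AD" %in% names(g)
  out <- list()
  n_skipped <- 0L
  for (s in seq_along(samples)) {
    for (i in seq_along(vids)) {
      vaf <- NA_real_
      depth <- NA_integer_
      if (has_af) {
        afv <- g$AF[i, s]
        if (is.list(afv) || inherits(afv, "List")) afv <- unlist(afv)
        afv <- suppressWarnings(as.numeric(afv[1]))
        if (!is.na(afv)) vaf <- afv
      }
      if (has_ad) {
        adv <- g$AD[i, s]
        if (is.list(adv) || inherits(adv, "List")) adv <- unlist(adv)
        adv <- suppressWarnings(as.integer(adv))
        if (length(adv) >= 2 && !anyNA(adv[1:2])) {
          depth <- sum(adv[1:2])
          if (is.na(vaf) && depth > 0) vaf <- adv[2] / depth
        }
      }
      if (is.na(vaf)) {
        n_skipped <- n_skipped + 1L
        next
      }
      if (vaf <= 0) next
      out[[length(out) + 1L]] <- data.frame(
        patient_id = samples[s], variant_id = vids[i],
        protein_change = hgvsp[i], aa_position = NA_integer_,
        consequence = csq[i], vaf = vaf, depth = depth,
        stringsAsFactors = FALSE)
    }
  }
  if (n_skipped > 0L) {
    warning(n_skipped, " sample record(s) had neither AF nor usable AD; skipped")
  }
  if (!length(out)) {
    res <- empty_mutation_table()
  } else {
    res <- do.call(rbind, out)
    parsed <- parseProteinChange(res$protein_change)
    res$aa_position <- parsed$aa_position
  }
  res
}

map_consequence <- function(x) {
  x <- tolower(as.character(x))
  out <- rep("other", length(x))
  out[grepl("missense", x)] <- "missense"
  out[grepl("frameshift|stop_gained|stop gained|nonsense", x)] <- "truncating"
  out[grepl("splice", x)] <- "splice"
  out
}
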