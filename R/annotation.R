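## Variant annotation: HGVS-p parsing, canonical-hotspot membership,
## blast-count risk labelling.

#' Canonical TP53 hotspot catalog
#'
#' The six recurrently mutated codons (R175, Y220, M237, R248, R273, R282)
#' with a symmetric amino-acid window: a missense position within `window`
#' residues of any catalog codon counts as canonical.
#'
#' @param positions integer codon positions (1-based, within the 393-residue
#'   protein).
#' @param window non-negative integer half-width in amino acids (inclusive
#'   boundary).
#' @return list with elements `positions` and `window`.
#' @examples
#' isCanonical(170, hotspotCatalog())  # within 5 residues of 175
#' @export
hotspotCatalog <- function(positions = c(175L, 220L, 237L, 248L, 273L, 282L),
                           window = 5L) {
  positions <- as.integer(positions)
  window <- as.integer(window)
  stopifnot(window >= 0L, all(positions >= 1L), all(positions <= 393L))
  list(positions = sort(unique(positions)), window = window)
}

#' Read a hotspot catalog from a YAML file
#'
#' Expects top-level keys `positions` (integer list) and optional `window`.
#'
#' @param path YAML file path.
#' @return A catalog as from [hotspotCatalog()].
#' @export
readHotspotCatalog <- function(path) {
  cfg <- yaml::read_yaml(path)
  hotspotCatalog(positions = unlist(cfg$positions),
                 window = cfg$window %||% 5L)
}

#' Parse HGVS-p protein changes
#'
#' Extracts the first residue position and assigns a consequence class:
#' `missense` for a substitution to a different residue, `truncating` for
#' stop-gains (`*`, `Ter`, `X`) and frameshifts (`fs`), `other` for anything
#' else (synonymous, in-frame indels, unparseable strings). Both 1-letter and
#' 3-letter amino-acid codes are accepted, with or without the `p.` prefix.
#'
#' @param hgvs_p character vector of protein-change strings; `NA` or empty
#'   entries yield `NA` position and consequence `other`.
#' @return `data.frame` with columns `protein_change`, `aa_position`
#'   (integer, `NA` when not extractable), `consequence`.
#' @examples
#' parseProteinChange(c("p.R175H", "p.Q192fs", "p.R213*"))
#' @export
parseProteinChange <- function(hgvs_p) {
  hgvs_p <- as.character(hgvs_p)
  n <- length(hgvs_p)
  pos <- rep(NA_integer_, n)
  csq <- rep("other", n)
  aa3 <- "(Ala|Arg|Asn|Asp|Cys|Gln|Glu|Gly|His|Ile|Leu|Lys|Met|Phe|Pro|Ser|Thr|Trp|Tyr|Val|Ter)"
  pat1 <- "^p\\.?\\(?([A-Z])([0-9]+)(.*?)\\)?$"                 # 1-letter
  pat3 <- paste0("^p\\.?\\(?", aa3, "([0-9]+)(.*?)\\)?$")       # 3-letter
  n_warn <- 0L
  for (i in seq_len(n)) {
    s <- hgvs_p[i]
    if (is.na(s) || !nzchar(s)) next
    ref <- NA_character_; alt <- NA_character_
    if (grepl(pat3, s)) {
      ref <- sub(pat3, "\\1", s)
      pos[i] <- as.integer(sub(pat3, "\\2", s))
      alt <- sub(pat3, "\\3", s)
    } else if (grepl(pat1, s)) {
      ref <- sub(pat1, "\\1", s)
      pos[i] <- as.integer(sub(pat1, "\\2", s))
      alt <- sub(pat1, "\\3", s)
    } else {
      n_warn <- n_warn + 1L
      next
    }
    if (grepl("fs", alt, ignore.case = TRUE)) {
      csq[i] <- "truncating"
    } else if (alt %in% c("*", "Ter", "X") || grepl("^\\*", alt)) {
      csq[i] <- "truncating"
    } else if (grepl("^(del|ins|dup|delins)", alt, ignore.case = TRUE)) {
      csq[i] <- "other"
    } else if (grepl("^[A-Z]$", alt) || grepl(paste0("^", aa3, "$"), alt)) {
      same <- identical(alt, ref) ||
        (nchar(alt) != nchar(ref) && aa_to_one(alt) == aa_to_one(ref))
      csq[i] <- if (same || identical(alt, "=")) "other" else "missense"
    } else if (identical(alt, "=")) {
      csq[i] <- "other"
    } else {
      csq[i] <- "other"
    }
  }
  if (n_warn > 0L) {
    warning(n_warn, " protein change string(s) could not be parsed; ",
            "consequence set to 'other' with missing position")
  }
  data.frame(protein_change = hgvs_p, aa_position = pos, consequence = csq,
             stringsAsFactors = FALSE)
}

AA_3TO1 <- c(Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C", Gln = "Q",
             Glu = "E", Gly = "G", His = "H", Ile = "I", Leu = "L", Lys = "K",
             Met = "M", Phe = "F", Pro = "P", Ser = "S", Thr = "T", Trp = "W",
             Tyr = "Y", Val = "V", Ter = "*")

aa_to_one <- function(x) {
  ifelse(nchar(x) == 1L, x, unname(AA_3TO1[x]))
}

#' Is a protein position within the canonical hotspot windows?
#'
#' @param aa_position integer vector of residue positions; `NA` yields `FALSE`
#'   with a warning.
#' @param catalog a [hotspotCatalog()].
#' @return logical vector: `TRUE` iff the position lies within
#'   `catalog$window` residues (inclusive) of any catalog codon. Intended for
#'   missense variants; the caller restricts to those.
#' @export
isCanonical <- function(aa_position, catalog = hotspotCatalog()) {
  aa_position <- as.integer(aa_position)
  if (anyNA(aa_position)) {
    warning(sum(is.na(aa_position)),
            " missing position(s); reported as non-canonical")
  }
  out <- vapply(aa_position, function(p) {
    if (is.na(p)) return(FALSE)
    any(abs(p - catalog$positions) <= catalog$window)
  }, logical(1))
  out
}

#' MDS risk label from blast count
#'
#' High-risk MDS is defined by a marrow blast count of at least 5 percent.
#'
#' @param blast_pct numeric vector on the percent scale (0-100); `NA` yields
#'   `NA`.
#' @return character vector with values `"HR"`, `"LR"`, or `NA`.
#' @examples
#' classifyMDSRisk(c(5, 4.9, 0, NA))
#' @export
classifyMDSRisk <- function(blast_pct) {
  stopifnot(all(is.na(blast_pct) | (blast_pct >= 0 & blast_pct <= 100)))
  ifelse(is.na(blast_pct), NA_character_, ifelse(blast_pct >= 5, "HR", "LR"))
}
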