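## Internal helpers shared across modules.

#' @importFrom stats runif rbinom rexp rnorm rnbinom median setNames
#' @importFrom utils read.delim write.table head
NULL

# Evaluate `expr` under a temporary RNG seed, restoring global RNG state.
# All stochastic operations in the package route through this so that no
# call leaves a footprint on the caller's random number stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a child seed from a parent seed; keeps results < 2^31 - 1.
derive_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 7919 + 104729 * k) %% (.Machine$integer.max - 1L) + 1)
}

# Stable hash of an R object (serialization md5); used to stamp outputs.
object_hash <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(x, tf, version = 2)
  unname(tools::md5sum(tf))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Genotype codes used by single-cell matrices.
GENOTYPE_CODES <- c("WT", "HET", "HOM_OR_HEMI", "MISSING")

# Allelic-state labels, ordered by severity (used by monotonicity checks).
STATE_LEVELS <- c("wild_type", "del17p_only", "probable_monoallelic",
                  "probable_biallelic", "obligatory_biallelic")

MUTANT_STATES <- c("obligatory_biallelic", "probable_biallelic",
                   "probable_monoallelic")

CONSEQUENCE_LEVELS <- c("missense", "truncating", "splice", "other")

SUBTYPE_LEVELS <- c("pAML", "sAML", "HR_MDS", "LR_MDS", "MDS_MPN", "other")
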