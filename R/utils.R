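#' @keywords internal
#' @importFrom stats cor sd var median lm coef complete.cases pt pf qt qf
#'   pnorm chisq.test p.adjust rnorm runif rbinom setNames as.dist hclust
#'   cutree
#' @importFrom graphics par image
#' @importFrom grDevices hcl.colors
"_PACKAGE"

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Derive a reproducible substream seed from a global seed
#'
#' Each simulation stage consumes its own RNG stream so that adding or
#' reordering stages does not perturb the draws of the others. The substream
#' seed is a deterministic hash of the global seed and a stream label, kept
#' within the 32-bit integer range R requires of `set.seed()`.
#'
#' @param seed Integer global seed.
#' @param stream Character label of the stream (e.g. `"genotypes"`).
#' @return An integer seed.
#' @export
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((abs(seed) * 7919 + h * 104729) %% (.Machine$integer.max - 1L)) + 1L
}

## Complement of single-base alleles; used for strand resolution.
.complement <- function(alleles) {
  chartr("ACGTacgt", "TGCAtgca", alleles)
}

## A/T and C/G pairs cannot be resolved from allele labels alone.
.is_strand_ambiguous <- function(a1, a2) {
  .complement(a1) == a2
}

.assert_scalar_number <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi) {
    stop(sprintf("`%s` must be a single number in [%s, %s]", name, lo, hi),
         call. = FALSE)
  }
  invisible(x)
}

## Run `expr` under a local RNG state seeded with `seed`, restoring the
## caller's stream afterwards.
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
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
  expr
}
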