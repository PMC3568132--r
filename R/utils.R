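# shared internal helpers

# round half away from zero (base round() is round-half-even)
round_half_up <- function(x, digits = 0L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# run expr with a fixed RNG seed, restoring the caller's RNG state afterwards
# so generators behave as pure functions of their config
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Variant identity keys
#'
#' A variant is identified by its `(chrom, pos, ref, alt)` tuple; two calls
#' are the same variant for all filtering purposes iff their keys match.
#' Coordinates are 1-based as in VCF and chromosome labels are opaque
#' strings, so the keying is assembly-agnostic.
#'
#' @param chrom chromosome labels, or a variant table (data frame with
#'   columns `chrom`, `pos`, `ref`, `alt`) from which the other arguments
#'   are taken.
#' @param pos 1-based positions.
#' @param ref,alt reference and alternate alleles.
#' @return Character vector of keys, one per variant.
#' @examples
#' variant_key("c1", 100, "A", "G")
#' @export
variant_key <- function(chrom, pos = NULL, ref = NULL, alt = NULL) {
  if (is.data.frame(chrom)) {
    vt <- chrom
    return(paste(vt$chrom, vt$pos, vt$ref, vt$alt, sep = ":"))
  }
  paste(chrom, pos, ref, alt, sep = ":")
}
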