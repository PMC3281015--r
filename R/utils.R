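# Internal helpers shared across modules.

# Canonical chromosome ordering: autosomes numerically, then X, Y, M, then
# anything else alphabetically. Chromosomes are categorical strings throughout.
chrom_levels <- function(chr) {
  chr <- unique(as.character(chr))
  num <- suppressWarnings(as.numeric(chr))
  auto <- chr[!is.na(num)][order(num[!is.na(num)])]
  special <- intersect(c("X", "Y", "M", "MT"), chr)
  rest <- sort(setdiff(chr, c(auto, special)))
  c(auto, special, rest)
}

chrom_factor <- function(chr, levels = NULL) {
  chr <- as.character(chr)
  if (is.null(levels)) levels <- chrom_levels(chr)
  factor(chr, levels = levels)
}

# Order by (chromosome, position), chromosomes in canonical order.
genome_order <- function(chr, pos) {
  order(chrom_factor(chr), pos)
}

#' Constant linking the likelihood ratio statistic to the LOD score
#'
#' The likelihood ratio statistic (LRS) used throughout this package equals
#' the LOD score times `2 * log(10)` (= 4.60517...), since the LOD is the
#' base-10 logarithm of the same likelihood ratio whose natural logarithm
#' (doubled) is the LRS.
#'
#' @return The scalar `2 * log(10)`.
#' @examples
#' lrs_per_lod()
#' @export
lrs_per_lod <- function() 2 * log(10)

# set.seed only when a seed is supplied; NULL leaves the RNG stream alone.
maybe_seed <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
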