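# Single-marker likelihood-ratio mapping of strain means.
#
# For a trait y over N strains split into two genotype groups, the LRS is
#   LRS = N * ln(RSS0 / RSS1)
# where RSS0 is the residual sum of squares about the grand mean and RSS1
# about the two group means (Gaussian maximum likelihood, variance profiled
# out). Equivalently LRS = -N * ln(1 - r^2) with r the Pearson correlation
# between the trait and the genotype coded 0/1. LOD = LRS / (2 ln 10).

#' Likelihood ratio statistic for one trait at one marker
#'
#' Strains with a missing trait value or a missing genotype are dropped
#' pairwise. Both allele groups must retain at least 2 strains, otherwise the
#' marker is skipped with a reason code. A perfect fit (zero within-group
#' residual) is reported as the configured cap with `capped = TRUE` rather
#' than as an infinite LRS.
#'
#' @param trait Numeric per-strain trait values.
#' @param geno Per-strain genotype codes (`"A"`/`"B"`/`NA`), same order.
#' @param cap LRS value substituted for a perfect fit (default 300).
#' @return A list: `lrs`, `lod`, `effect_sign` (+1 if B-allele strains have
#'   the higher mean, -1 if lower, 0 only on exact equality), `n_used`,
#'   `capped`, `skipped`, `reason`.
#' @examples
#' compute_lrs(c(1, 2, 1, 2, 3, 4, 3, 4),
#'             c("A", "A", "A", "A", "B", "B", "B", "B"))
#' @export
compute_lrs <- function(trait, geno, cap = 300) {
  stopifnot(length(trait) == length(geno))
  keep <- !is.na(trait) & !is.na(geno)
  x <- as.numeric(trait[keep])
  g <- geno[keep]
  is_a <- g == "A"
  is_b <- g == "B"
  n_a <- sum(is_a)
  n_b <- sum(is_b)
  skipped <- function(reason) {
    list(lrs = NA_real_, lod = NA_real_, effect_sign = NA_integer_,
         n_used = n_a + n_b, capped = FALSE, skipped = TRUE, reason = reason)
  }
  if (n_a < 2) return(skipped("fewer than 2 usable A-allele strains"))
  if (n_b < 2) return(skipped("fewer than 2 usable B-allele strains"))
  n <- n_a + n_b
  m_a <- mean(x[is_a])
  m_b <- mean(x[is_b])
  rss0 <- sum((x - mean(x))^2)
  rss1 <- sum((x[is_a] - m_a)^2) + sum((x[is_b] - m_b)^2)
  sgn <- sign(m_b - m_a)
  if (rss0 <= 0) {          # constant trait
    lrs <- 0; capped <- FALSE
  } else if (rss1 <= 0) {   # perfect genotype fit
    lrs <- cap; capped <- TRUE
  } else {
    lrs <- min(n * log(rss0 / rss1), cap)
    capped <- lrs >= cap
  }
  list(lrs = lrs, lod = lrs / lrs_per_lod(), effect_sign = as.integer(sgn),
       n_used = n, capped = capped, skipped = FALSE, reason = NA_character_)
}

# Genotype codes -> 0/1 numeric matrix (B = 1), strains x markers.
geno_numeric <- function(geno, markers = NULL) {
  codes <- geno$codes
  if (!is.null(markers)) codes <- codes[, markers, drop = FALSE]
  g <- matrix(NA_real_, nrow(codes), ncol(codes), dimnames = dimnames(codes))
  g[codes == "A"] <- 0
  g[codes == "B"] <- 1
  g
}

# Vectorized LRS over a whole trait matrix at many markers.
#   X: strains x traits, G: strains x markers (0/1, NA allowed).
# Returns list(lrs, sign) of traits x markers matrices. Used by the
# permutation engine and the batch scans; per-marker group-size checks are the
# caller's responsibility (markers are pre-filtered to informative ones).
lrs_matrix <- function(X, G, cap = 300) {
  if (!anyNA(X) && !anyNA(G)) {
    n <- matrix(nrow(X), ncol(X), ncol(G))
    r <- suppressWarnings(stats::cor(X, G))
  } else {
    n <- crossprod(!is.na(X) + 0, !is.na(G) + 0)
    r <- suppressWarnings(stats::cor(X, G, use = "pairwise.complete.obs"))
  }
  sgn <- sign(r)
  r2 <- r^2
  r2[is.na(r2)] <- 0          # constant trait/genotype in the used strains
  sgn[is.na(sgn)] <- 0
  lrs <- -n * log1p(-pmin(r2, 1))
  lrs[!is.finite(lrs) | lrs > cap] <- cap
  dimnames(lrs) <- list(colnames(X), colnames(G))
  list(lrs = lrs, sign = sgn)
}

# Align one condition's trait matrix (traits x strains) with a genotype
# matrix; returns X (strains x traits) and G (strains x informative markers).
align_condition <- function(traits_mat, geno, markers = NULL) {
  strains <- intersect(colnames(traits_mat), geno$strains)
  if (!length(strains)) stop("no strains shared between traits and genotypes")
  if (is.null(markers)) markers <- geno$markers$marker[geno$informative]
  list(X = t(traits_mat[, strains, drop = FALSE]),
       G = geno_numeric(geno, markers)[strains, , drop = FALSE],
       strains = strains, markers = markers)
}

#' Genome scan of one trait against all markers of a panel
#'
#' Runs [compute_lrs()] at every marker; uninformative markers (fewer than 2
#' strains per allele panel-wide) and markers skipped for per-marker missing
#' data carry a reason code instead of an LRS.
#'
#' @param trait Named numeric vector of strain-mean trait values (names are
#'   strain ids) or a 1-row trait matrix.
#' @param geno A [geno_matrix()].
#' @param cap Perfect-fit LRS cap.
#' @return `data.frame` with one row per marker: `marker`, `chr`, `pos_mb`,
#'   `lrs`, `effect_sign`, `n_used`, `skipped`, `reason`.
#' @export
genome_scan <- function(trait, geno, cap = 300) {
  if (is.matrix(trait)) trait <- trait[1, ]
  strains <- intersect(names(trait), geno$strains)
  if (!length(strains)) stop("no strains shared between trait and genotypes")
  x <- trait[strains]
  codes <- geno$codes[strains, , drop = FALSE]
  map <- geno$markers
  res <- lapply(seq_len(nrow(map)), function(j) {
    if (!geno$informative[[map$marker[j]]]) {
      return(list(lrs = NA_real_, effect_sign = NA_integer_, n_used = NA_integer_,
                  skipped = TRUE, reason = "uninformative marker"))
    }
    compute_lrs(x, codes[, map$marker[j]], cap = cap)
  })
  data.frame(
    marker = map$marker, chr = map$chr, pos_mb = map$pos_mb,
    lrs = vapply(res, function(z) z$lrs, numeric(1)),
    effect_sign = vapply(res, function(z) as.integer(z$effect_sign), integer(1)),
    n_used = vapply(res, function(z) as.integer(z$n_used), integer(1)),
    skipped = vapply(res, function(z) z$skipped, logical(1)),
    reason = vapply(res, function(z) as.character(z$reason), character(1)),
    stringsAsFactors = FALSE
  )
}

#' Per-chromosome maximum-LRS QTLs from a scan profile
#'
#' One QTL per chromosome that has at least one usable marker: the marker with
#' the maximum LRS, ties broken by smallest genomic position. Chromosomes
#' whose markers were all skipped yield no hit.
#'
#' @param profile A scan `data.frame` from [genome_scan()].
#' @param trait_id Optional trait id to attach to the hits.
#' @return `data.frame` of hits: `trait_id`, `marker`, `chr`, `pos_mb`, `lrs`,
#'   `effect_sign`, `n_used`.
#' @export
chromosome_max_qtls <- function(profile, trait_id = NA_character_) {
  stopifnot(nrow(profile) > 0)
  usable <- profile[!profile$skipped & !is.na(profile$lrs), , drop = FALSE]
  if (!nrow(usable)) {
    return(data.frame(trait_id = character(), marker = character(),
                      chr = character(), pos_mb = numeric(), lrs = numeric(),
                      effect_sign = integer(), n_used = integer(),
                      stringsAsFactors = FALSE))
  }
  usable <- usable[order(chrom_factor(usable$chr), usable$pos_mb), , drop = FALSE]
  picks <- lapply(split(seq_len(nrow(usable)), chrom_factor(usable$chr), drop = TRUE),
                  function(idx) idx[which.max(usable$lrs[idx])])  # first max = lowest pos
  idx <- unlist(picks, use.names = FALSE)
  out <- usable[idx, c("marker", "chr", "pos_mb", "lrs", "effect_sign", "n_used"),
                drop = FALSE]
  out <- data.frame(trait_id = trait_id, out, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Chromosome-maximum QTLs for every trait of one condition
#'
#' Batch version of [genome_scan()] + [chromosome_max_qtls()] over a full
#' trait x strain matrix, used for transcriptome-wide scans.
#'
#' @param traits_mat Numeric trait x strain matrix (one condition).
#' @param geno A [geno_matrix()].
#' @param cap Perfect-fit LRS cap.
#' @return `data.frame` of hits (one row per trait per chromosome with
#'   informative markers): `trait_id`, `marker`, `chr`, `pos_mb`, `lrs`,
#'   `effect_sign`.
#' @export
scan_condition <- function(traits_mat, geno, cap = 300) {
  al <- align_condition(traits_mat, geno)
  sc <- lrs_matrix(al$X, al$G, cap = cap)
  map <- geno$markers[match(al$markers, geno$markers$marker), ]
  chr_f <- chrom_factor(map$chr)
  blocks <- split(seq_along(al$markers), chr_f, drop = TRUE)
  hits <- lapply(names(blocks), function(ch) {
    idx <- blocks[[ch]]
    sub <- sc$lrs[, idx, drop = FALSE]
    j <- max.col(sub, ties.method = "first")   # markers sorted by position
    pick <- idx[j]
    data.frame(trait_id = rownames(sub),
               marker = map$marker[pick],
               chr = map$chr[pick],
               pos_mb = map$pos_mb[pick],
               lrs = sub[cbind(seq_len(nrow(sub)), j)],
               effect_sign = as.integer(sc$sign[cbind(seq_len(nrow(sub)), pick)]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, hits)
  out <- out[order(out$trait_id, chrom_factor(out$chr), out$pos_mb), , drop = FALSE]
  rownames(out) <- NULL
  out
}
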