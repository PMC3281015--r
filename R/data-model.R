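# Shared data model: marker maps, genotype matrices, conditioned trait sets.
#
# Conventions used throughout:
#   * genotype codes are "A" (first parental allele, ISS/C57BL6-like),
#     "B" (second parental allele, ILS/DBA2-like) or NA (no call);
#     RI strains are homozygous so two codes suffice;
#   * all genomic positions are in megabases (Mb);
#   * the treatment conditions are ordered SC, EC, SR, ER everywhere.

#' Default treatment condition order
#'
#' The four treatment arms of the study design, in the fixed order used by all
#' activity-pattern computations: SC (saline control), EC (ethanol), SR
#' (saline + restraint stress), ER (ethanol + restraint stress).
#'
#' @return Character vector of length 4.
#' @export
default_conditions <- function() c("SC", "EC", "SR", "ER")

#' Construct a marker map
#'
#' @param marker Character vector of unique marker identifiers.
#' @param chr Chromosome of each marker (character; "1".."19", "X", ...).
#' @param pos_mb Position of each marker in megabases.
#' @return A `data.frame` with columns `marker`, `chr`, `pos_mb`, sorted by
#'   (chromosome, position) with chromosomes in canonical order.
#' @export
marker_map <- function(marker, chr, pos_mb) {
  marker <- as.character(marker)
  chr <- as.character(chr)
  pos_mb <- as.numeric(pos_mb)
  stopifnot(length(marker) == length(chr), length(marker) == length(pos_mb))
  if (anyDuplicated(marker)) {
    stop("duplicate marker id(s): ",
         paste(unique(marker[duplicated(marker)]), collapse = ", "))
  }
  if (any(!is.finite(pos_mb)) || any(pos_mb < 0)) {
    stop("marker positions must be finite and non-negative (Mb)")
  }
  ord <- genome_order(chr, pos_mb)
  out <- data.frame(marker = marker[ord], chr = chr[ord], pos_mb = pos_mb[ord],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Construct a genotype matrix for one RI panel
#'
#' @param panel_id Panel label (e.g. `"LXS"`).
#' @param codes Character matrix, strains x markers, with entries `"A"`, `"B"`
#'   or `NA`. Row names are strain ids, column names marker ids.
#' @param map Marker map (see [marker_map()]) covering the matrix columns.
#' @return An object of class `geno_matrix`: a list with elements `panel_id`,
#'   `strains`, `markers` (the map, matrix column order), `codes`, and
#'   `informative` (logical per marker: at least 2 strains carry each allele).
#' @export
geno_matrix <- function(panel_id, codes, map) {
  stopifnot(is.matrix(codes))
  if (is.null(rownames(codes)) || is.null(colnames(codes))) {
    stop("codes must have strain row names and marker column names")
  }
  bad <- setdiff(unique(as.vector(codes)), c("A", "B", NA))
  if (length(bad)) stop("invalid genotype code(s): ", paste(bad, collapse = ", "))
  if (!setequal(colnames(codes), map$marker)) {
    stop("marker map and code columns disagree")
  }
  codes <- codes[, map$marker, drop = FALSE]   # map defines genome order
  n_a <- colSums(codes == "A", na.rm = TRUE)
  n_b <- colSums(codes == "B", na.rm = TRUE)
  structure(
    list(panel_id = as.character(panel_id),
         strains = rownames(codes),
         markers = map,
         codes = codes,
         informative = n_a >= 2 & n_b >= 2),
    class = "geno_matrix"
  )
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("geno_matrix '%s': %d strains x %d markers (%d informative), %d chromosome(s)\n",
              x$panel_id, length(x$strains), nrow(x$markers),
              sum(x$informative), length(unique(x$markers$chr))))
  invisible(x)
}

#' Construct a conditioned trait set
#'
#' Strain-mean trait values for one panel under each treatment condition, plus
#' trait annotations. Strain sets may differ between conditions (unequal group
#' sizes); within each condition the matrix is trait x strain.
#'
#' @param panel_id Panel label.
#' @param values Named list (one element per condition, in condition order) of
#'   numeric trait x strain matrices. Row names are trait ids, column names
#'   strain ids.
#' @param annotation `data.frame` with columns `trait_id`, `kind`
#'   (`"expression"` or `"behavioral"`), and for expression traits
#'   `gene_symbol`, `gene_chr`, `gene_pos_mb` (NA for behavioral traits).
#' @param conditions Condition order; defaults to the names of `values`.
#' @return An object of class `trait_set`.
#' @export
trait_set <- function(panel_id, values, annotation,
                      conditions = names(values)) {
  stopifnot(is.list(values), !is.null(names(values)))
  if (!setequal(names(values), conditions)) {
    stop("conditions must match the names of `values`")
  }
  values <- values[conditions]
  traits <- rownames(values[[1]])
  for (cond in conditions) {
    m <- values[[cond]]
    if (!is.matrix(m) || !is.numeric(m)) {
      stop("values[['", cond, "']] must be a numeric matrix")
    }
    if (!identical(rownames(m), traits)) {
      stop("trait rows must be identical across conditions")
    }
  }
  need <- c("trait_id", "kind")
  if (!all(need %in% names(annotation))) {
    stop("annotation needs columns: ", paste(need, collapse = ", "))
  }
  if (!all(traits %in% annotation$trait_id)) {
    stop("annotation missing trait(s): ",
         paste(utils::head(setdiff(traits, annotation$trait_id), 5), collapse = ", "))
  }
  annotation <- annotation[match(traits, annotation$trait_id), , drop = FALSE]
  rownames(annotation) <- NULL
  structure(
    list(panel_id = as.character(panel_id),
         conditions = conditions,
         values = values,
         annotation = annotation),
    class = "trait_set"
  )
}

#' @export
print.trait_set <- function(x, ...) {
  ns <- vapply(x$values, ncol, integer(1))
  cat(sprintf("trait_set '%s': %d traits (%d expression, %d behavioral); conditions %s; strains per condition %s\n",
              x$panel_id, nrow(x$values[[1]]),
              sum(x$annotation$kind == "expression"),
              sum(x$annotation$kind == "behavioral"),
              paste(x$conditions, collapse = ","),
              paste(ns, collapse = ",")))
  invisible(x)
}

# Trait values for one trait under one condition, as a named numeric vector
# (names = strain ids).
trait_values <- function(traits, trait_id, condition) {
  m <- traits$values[[condition]]
  if (is.null(m)) stop("unknown condition: ", condition)
  if (!trait_id %in% rownames(m)) {
    stop("unknown trait: ", trait_id)
  }
  m[trait_id, ]
}
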