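# QTL activity patterns: the per-condition LRS vector of a trait-marker pair
# and the binary significance vector it induces, plus cross-population
# conservation via nearest-marker matching.
#
# With four treatment conditions there are 15 possible non-null patterns.
# The pattern index encodes the bits with SC as the most significant bit,
# so e.g. bits (SC,EC,SR,ER) = (1,1,0,0) -> index 12.

#' LRS of one trait at one fixed marker under every condition
#'
#' @param trait_id Trait identifier.
#' @param marker Marker identifier.
#' @param traits A [trait_set()].
#' @param geno The matching [geno_matrix()].
#' @param cap Perfect-fit LRS cap.
#' @return Named numeric vector, one LRS per condition (NA where the trait is
#'   not measured in that condition). Errors if the trait is absent from all
#'   conditions or the marker unknown.
#' @export
lrs_across_conditions <- function(trait_id, marker, traits, geno, cap = 300) {
  if (!marker %in% geno$markers$marker) stop("unknown marker: ", marker)
  if (!trait_id %in% rownames(traits$values[[1]])) {
    stop("unknown trait: ", trait_id)
  }
  vapply(traits$conditions, function(cond) {
    x <- trait_values(traits, trait_id, cond)
    strains <- intersect(names(x), geno$strains)
    if (!length(strains)) return(NA_real_)
    res <- compute_lrs(x[strains], geno$codes[strains, marker], cap = cap)
    if (res$skipped) NA_real_ else res$lrs
  }, numeric(1))
}

#' Turn a per-condition LRS vector into an activity pattern
#'
#' A condition's bit is set when its LRS strictly exceeds the panel
#' threshold (an LRS exactly at the threshold is not significant). A vector
#' with no bit set yields a null pattern (index NA) with a reason.
#'
#' @param lrs_vector Named numeric LRS per condition (condition order is the
#'   vector order; missing entries count as not significant).
#' @param threshold Panel significance threshold (> 0).
#' @return Object of class `activity_pattern`: list with `lrs`, `bits`
#'   (logical), `pattern_index` (1..2^n-1, NA for null), `null`, `reason`.
#' @examples
#' make_activity_pattern(c(SC = 30, EC = 25, SR = 10, ER = 5), threshold = 24)
#' @export
make_activity_pattern <- function(lrs_vector, threshold) {
  stopifnot(threshold > 0)
  bits <- !is.na(lrs_vector) & lrs_vector > threshold
  idx <- pattern_index_from_bits(bits)
  structure(
    list(lrs = lrs_vector, bits = bits, threshold = threshold,
         pattern_index = if (idx == 0) NA_integer_ else idx,
         null = idx == 0,
         reason = if (idx == 0) "no condition exceeds the threshold" else NA_character_),
    class = "activity_pattern"
  )
}

#' @export
print.activity_pattern <- function(x, ...) {
  if (x$null) {
    cat("activity_pattern: null (", x$reason, ")\n", sep = "")
  } else {
    cat(sprintf("activity_pattern %s (index %d), threshold %g\n",
                paste(as.integer(x$bits), collapse = ""), x$pattern_index,
                x$threshold))
  }
  invisible(x)
}

# bits (first = most significant) -> integer index
pattern_index_from_bits <- function(bits) {
  sum(as.integer(bits) * 2^(rev(seq_along(bits)) - 1))
}

#' Enumerate all possible activity patterns
#'
#' All non-null binary significance vectors over `n_conditions` conditions:
#' `2^n - 1` patterns (15 for the four-condition design).
#'
#' @param n_conditions Number of conditions (>= 1).
#' @param conditions Optional condition names for the bit columns.
#' @return `data.frame` with `pattern_index`, one logical column per
#'   condition, and `n_active` (number of set bits), ordered by index.
#' @export
enumerate_patterns <- function(n_conditions = 4, conditions = NULL) {
  if (n_conditions <= 0) stop("n_conditions must be >= 1")
  if (is.null(conditions)) {
    conditions <- if (n_conditions == 4) default_conditions() else
      paste0("C", seq_len(n_conditions))
  }
  stopifnot(length(conditions) == n_conditions)
  idx <- seq_len(2^n_conditions - 1)
  bits <- t(vapply(idx, function(i) {
    as.logical(bitwAnd(i, 2^(rev(seq_len(n_conditions)) - 1)) > 0)
  }, logical(n_conditions)))
  colnames(bits) <- conditions
  out <- data.frame(pattern_index = idx, bits, n_active = rowSums(bits))
  rownames(out) <- NULL
  out
}

#' Nearest marker on the same chromosome in another panel's map
#'
#' @param chr Chromosome of the query position.
#' @param pos_mb Query position (Mb).
#' @param map Marker map of the other panel.
#' @return The marker id minimizing the absolute distance; ties broken by the
#'   lower position. Errors when the chromosome has no marker in `map`.
#' @export
nearest_marker <- function(chr, pos_mb, map) {
  cand <- map[map$chr == as.character(chr), , drop = FALSE]
  if (!nrow(cand)) stop("no marker on chromosome ", chr, " in the other map")
  d <- abs(cand$pos_mb - pos_mb)
  cand$marker[order(d, cand$pos_mb)[1]]
}

#' Activity patterns for a table of QTL hits
#'
#' Computes the per-condition LRS vector of every (trait, marker) hit in
#' batch and attaches bits and pattern index at the panel threshold.
#'
#' @param hits `data.frame` with columns `trait_id`, `marker`.
#' @param traits The panel's [trait_set()].
#' @param geno The panel's [geno_matrix()].
#' @param threshold Panel significance threshold.
#' @param cap Perfect-fit LRS cap.
#' @return `hits` with added columns `lrs_<cond>` and `bit_<cond>` per
#'   condition, plus `pattern_index` (NA = null pattern).
#' @export
activity_patterns <- function(hits, traits, geno, threshold, cap = 300) {
  conds <- traits$conditions
  markers <- unique(hits$marker)
  trait_ids <- unique(hits$trait_id)
  per_cond <- lapply(conds, function(cond) {
    tm <- traits$values[[cond]][trait_ids, , drop = FALSE]
    al <- align_condition(tm, geno, markers = markers)
    lrs_matrix(al$X, al$G, cap = cap)$lrs
  })
  names(per_cond) <- conds
  bit_mat <- matrix(NA, nrow(hits), length(conds))
  for (i in seq_along(conds)) {
    lrs_i <- per_cond[[i]][cbind(match(hits$trait_id, trait_ids),
                                 match(hits$marker, markers))]
    hits[[paste0("lrs_", conds[i])]] <- lrs_i
    bit <- !is.na(lrs_i) & lrs_i > threshold
    hits[[paste0("bit_", conds[i])]] <- bit
    bit_mat[, i] <- bit
  }
  idx <- as.integer(bit_mat %*% 2^(rev(seq_along(conds)) - 1))
  idx[idx == 0] <- NA_integer_
  hits$pattern_index <- idx
  hits
}

#' Cross-population conservation of one eQTL
#'
#' Matches the hit's marker into the other panel's map (nearest marker on the
#' same chromosome, or the identical marker id in `"identical"` mode),
#' recomputes the trait's per-condition LRS there, and applies the OTHER
#' panel's threshold. `conserved_any` is TRUE when at least one condition is
#' significant in the other panel; `pattern_identical` additionally requires
#' the same significance bits as the source pattern.
#'
#' @param trait_id Trait identifier (must exist in the other panel's traits).
#' @param marker Source-panel marker id of the hit.
#' @param source_bits Logical significance bits of the source-panel pattern.
#' @param source_geno,other_geno The two panels' [geno_matrix()] objects.
#' @param other_traits The other panel's [trait_set()].
#' @param other_threshold The other panel's significance threshold.
#' @param mode `"nearest"` (default) or `"identical"` marker matching.
#' @param cap Perfect-fit LRS cap.
#' @return List: `trait_id`, `matched_marker`, `other_lrs`, `other_bits`,
#'   `conserved_any`, `pattern_identical`, `skipped`, `reason`. Traits or
#'   markers that cannot be matched yield a record with missing flags.
#' @export
cross_population_conservation <- function(trait_id, marker, source_bits,
                                          source_geno, other_geno,
                                          other_traits, other_threshold,
                                          mode = c("nearest", "identical"),
                                          cap = 300) {
  mode <- match.arg(mode)
  skip <- function(reason) {
    list(trait_id = trait_id, matched_marker = NA_character_,
         other_lrs = NULL, other_bits = NULL,
         conserved_any = NA, pattern_identical = NA,
         skipped = TRUE, reason = reason)
  }
  if (!trait_id %in% rownames(other_traits$values[[1]])) {
    return(skip("trait absent from other panel"))
  }
  src <- source_geno$markers[source_geno$markers$marker == marker, ]
  if (!nrow(src)) return(skip("marker absent from source panel"))
  if (mode == "identical") {
    if (!marker %in% other_geno$markers$marker) {
      return(skip("identical marker absent from other panel"))
    }
    matched <- marker
  } else {
    matched <- tryCatch(nearest_marker(src$chr, src$pos_mb, other_geno$markers),
                        error = function(e) NA_character_)
    if (is.na(matched)) return(skip("no marker on chromosome in other panel"))
  }
  other_lrs <- lrs_across_conditions(trait_id, matched, other_traits,
                                     other_geno, cap = cap)
  other_bits <- !is.na(other_lrs) & other_lrs > other_threshold
  list(trait_id = trait_id, matched_marker = matched,
       other_lrs = other_lrs, other_bits = other_bits,
       conserved_any = any(other_bits),
       pattern_identical = identical(unname(other_bits),
                                     unname(as.logical(source_bits))),
       skipped = FALSE, reason = NA_character_)
}

#' Cross-population conservation for a table of patterned hits
#'
#' Batch wrapper around [cross_population_conservation()] over the rows of an
#' [activity_patterns()] table.
#'
#' @param hits Patterned hits (`trait_id`, `marker`, `bit_*` columns).
#' @param source_geno,other_geno,other_traits,other_threshold,mode,cap See
#'   [cross_population_conservation()].
#' @return `hits` with added `matched_marker`, `other_lrs_<cond>`,
#'   `conserved_any`, `pattern_identical`, `xp_skipped` columns.
#' @export
cross_panel_records <- function(hits, source_geno, other_geno, other_traits,
                                other_threshold, mode = "nearest", cap = 300) {
  conds <- other_traits$conditions
  bit_cols <- paste0("bit_", conds)
  recs <- lapply(seq_len(nrow(hits)), function(i) {
    cross_population_conservation(
      hits$trait_id[i], hits$marker[i],
      as.logical(hits[i, bit_cols]),
      source_geno, other_geno, other_traits, other_threshold,
      mode = mode, cap = cap)
  })
  hits$matched_marker <- vapply(recs, function(r) r$matched_marker, character(1))
  for (j in seq_along(conds)) {
    hits[[paste0("other_lrs_", conds[j])]] <-
      vapply(recs, function(r) if (r$skipped) NA_real_ else r$other_lrs[[j]],
             numeric(1))
  }
  hits$conserved_any <- vapply(recs, function(r) r$conserved_any, logical(1))
  hits$pattern_identical <- vapply(recs, function(r) r$pattern_identical, logical(1))
  hits$xp_skipped <- vapply(recs, function(r) r$skipped, logical(1))
  hits
}

#' Summarize activity patterns by eQTL class
#'
#' For each class, the distribution over the 15 possible patterns (histogram
#' summing to 1), the treatment-specific fraction (exactly one bit set) and
#' the conserved-in-all fraction (all bits set).
#'
#' @param hits Patterned hits with columns `eqtl_class` and `pattern_index`
#'   (null-pattern rows are dropped).
#' @param n_conditions Number of conditions (default 4).
#' @param classes Classes to tabulate (default: those present in `hits`);
#'   classes without hits get an all-zero histogram and are flagged.
#' @return List with `histogram` (class x pattern-index matrix of
#'   proportions), `summary` (`data.frame`: class, n, treatment-specific
#'   fraction, all-conditions fraction), and `empty_classes`.
#' @export
summarize_patterns <- function(hits, n_conditions = 4, classes = NULL) {
  pat <- enumerate_patterns(n_conditions)
  specific_idx <- pat$pattern_index[pat$n_active == 1]
  all_idx <- 2^n_conditions - 1
  hits <- hits[!is.na(hits$pattern_index), , drop = FALSE]
  stopifnot(nrow(hits) > 0)
  if (is.null(classes)) classes <- sort(unique(hits$eqtl_class))
  hist <- matrix(0, length(classes), all_idx,
                 dimnames = list(classes, as.character(seq_len(all_idx))))
  summ <- data.frame(eqtl_class = classes, n = 0L,
                     frac_treatment_specific = NA_real_,
                     frac_all_conditions = NA_real_)
  for (i in seq_along(classes)) {
    idx <- hits$pattern_index[hits$eqtl_class == classes[i]]
    summ$n[i] <- length(idx)
    if (!length(idx)) next
    tab <- tabulate(idx, nbins = all_idx)
    hist[i, ] <- tab / length(idx)
    summ$frac_treatment_specific[i] <- mean(idx %in% specific_idx)
    summ$frac_all_conditions[i] <- mean(idx == all_idx)
  }
  list(histogram = hist, summary = summ,
       empty_classes = classes[summ$n == 0])
}
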