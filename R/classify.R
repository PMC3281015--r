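# Classification of eQTLs by gene-marker geometry, and the probe-SNP cis
# filter for panels whose parental genomes are sequenced.

#' Classify one eQTL by gene-marker geometry
#'
#' `cis` when gene and marker lie on the same chromosome within the cis
#' window (boundary inclusive); `syntenic_trans` when on the same chromosome
#' but farther apart; `nonsyntenic_trans` when on different chromosomes;
#' `not_applicable` for traits without a genomic location (behavioral traits).
#'
#' @param marker_chr,marker_pos Marker location (chromosome, Mb).
#' @param gene_chr,gene_pos Gene location (chromosome, Mb); NA for traits
#'   with no location.
#' @param cis_window_mb Cis window half-width in Mb (default 5).
#' @return One of `"cis"`, `"syntenic_trans"`, `"nonsyntenic_trans"`,
#'   `"not_applicable"` (vectorized).
#' @examples
#' classify_eqtl("3", 103, "3", 100)   # cis
#' classify_eqtl("3", 120, "3", 100)   # syntenic_trans
#' classify_eqtl("5", 120, "3", 100)   # nonsyntenic_trans
#' @export
classify_eqtl <- function(marker_chr, marker_pos, gene_chr, gene_pos,
                          cis_window_mb = 5) {
  n <- max(length(marker_chr), length(gene_chr))
  marker_chr <- rep_len(as.character(marker_chr), n)
  gene_chr <- rep_len(as.character(gene_chr), n)
  marker_pos <- rep_len(as.numeric(marker_pos), n)
  gene_pos <- rep_len(as.numeric(gene_pos), n)
  out <- rep("not_applicable", n)
  known <- !is.na(gene_chr) & !is.na(gene_pos)
  same <- known & marker_chr == gene_chr
  out[known & !same] <- "nonsyntenic_trans"
  out[same] <- ifelse(abs(marker_pos[same] - gene_pos[same]) <= cis_window_mb,
                      "cis", "syntenic_trans")
  out
}

#' Classify a table of QTL hits against a trait annotation
#'
#' @param hits `data.frame` of hits with columns `trait_id`, `chr`, `pos_mb`.
#' @param annotation Trait annotation with `trait_id`, `kind`, `gene_chr`,
#'   `gene_pos_mb` (as in a [trait_set()]).
#' @param cis_window_mb Cis window in Mb.
#' @return `hits` with an `eqtl_class` column added.
#' @export
classify_eqtls <- function(hits, annotation, cis_window_mb = 5) {
  idx <- match(hits$trait_id, annotation$trait_id)
  gene_chr <- annotation$gene_chr[idx]
  gene_pos <- annotation$gene_pos_mb[idx]
  gene_chr[annotation$kind[idx] != "expression"] <- NA
  hits$eqtl_class <- classify_eqtl(hits$chr, hits$pos_mb, gene_chr, gene_pos,
                                   cis_window_mb = cis_window_mb)
  hits
}

#' Probe-SNP cis-eQTL filter
#'
#' A cis-eQTL called with an expression probe that overlaps a segregating SNP
#' can be a hybridization artifact: the allele mismatching the probe sequence
#' hybridizes less, producing an apparent expression difference that favors
#' the reference (A/B6-like) allele in every treatment. Such hits are removed
#' when all three clauses hold: the probe contains a SNP, the effect sign is
#' negative (higher expression for A-allele strains under the B-coded
#' convention), and the activity pattern is significant in all conditions.
#' Trans hits always pass. Traits absent from `probe_flags` are treated as
#' SNP-free and counted in the log.
#'
#' @param hits `data.frame` with columns `trait_id`, `eqtl_class`,
#'   `effect_sign`, and `pattern_index` (all-condition pattern = `2^k - 1`
#'   for `k` conditions, 15 for four).
#' @param probe_flags `data.frame` with columns `trait_id`, `contains_snp`.
#' @param n_conditions Number of treatment conditions (default 4).
#' @return List: `kept` (filtered hits), `removed` (the removed rows),
#'   `n_missing_flag` (traits without a probe flag).
#' @export
filter_probe_snp_cis <- function(hits, probe_flags, n_conditions = 4) {
  idx <- match(hits$trait_id, probe_flags$trait_id)
  contains_snp <- probe_flags$contains_snp[idx]
  n_missing <- sum(is.na(contains_snp))
  contains_snp[is.na(contains_snp)] <- FALSE
  all_idx <- 2^n_conditions - 1
  drop <- hits$eqtl_class == "cis" & contains_snp &
    hits$effect_sign == -1 &
    !is.na(hits$pattern_index) & hits$pattern_index == all_idx
  drop[is.na(drop)] <- FALSE
  list(kept = hits[!drop, , drop = FALSE],
       removed = hits[drop, , drop = FALSE],
       n_missing_flag = n_missing)
}
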