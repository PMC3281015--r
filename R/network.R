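# Candidate-gene selection at behavioral QTL regions and QTL-activity-pattern
# correlation networks across the eight panel x condition combinations.

#' Region specification for a behavioral QTL
#'
#' @param chr Chromosome of the region.
#' @param start_mb,end_mb Region bounds in Mb (`start < end`).
#' @param focal_panel Panel in which the behavioral QTL is significant.
#' @param focal_condition Condition of interest (default `"EC"`, the
#'   ethanol-only arm).
#' @param phenotype Behavioral trait id anchoring the region.
#' @return A `region_spec` list.
#' @export
region_spec <- function(chr, start_mb, end_mb, focal_panel,
                        focal_condition = "EC", phenotype = NULL) {
  stopifnot(start_mb < end_mb)
  structure(list(chr = as.character(chr), start_mb = start_mb, end_mb = end_mb,
                 focal_panel = focal_panel, focal_condition = focal_condition,
                 phenotype = phenotype),
            class = "region_spec")
}

markers_in_region <- function(region, map) {
  map$marker[map$chr == region$chr &
               map$pos_mb >= region$start_mb & map$pos_mb <= region$end_mb]
}

#' Region-maximum LRS vector across both panels and all conditions
#'
#' For one trait, the maximum LRS over the region's markers, per panel and
#' condition, ordered (panel1-SC, panel1-EC, panel1-SR, panel1-ER, panel2-SC,
#' ...). A panel with no marker inside the region, or missing the trait,
#' contributes missing entries.
#'
#' @param trait_id Trait identifier.
#' @param region A [region_spec()].
#' @param panels Named list of two panels, each `list(geno = , traits = )`.
#' @param cap Perfect-fit LRS cap.
#' @return Named numeric vector of length `2 * n_conditions`.
#' @export
region_lrs_vector <- function(trait_id, region, panels, cap = 300) {
  m <- region_lrs_matrix(trait_id, region, panels, cap = cap)
  m[1, ]
}

#' Region-maximum LRS vectors for many traits at once
#'
#' Batch version of [region_lrs_vector()]: one row per trait.
#'
#' @param trait_ids Character vector of trait ids.
#' @param region A [region_spec()].
#' @param panels Named list of two panels, each `list(geno = , traits = )`.
#' @param cap Perfect-fit LRS cap.
#' @return Numeric matrix, traits x (2 * n_conditions), columns named
#'   `<panel>_<condition>`.
#' @export
region_lrs_matrix <- function(trait_ids, region, panels, cap = 300) {
  stopifnot(length(panels) == 2)
  cols <- unlist(lapply(names(panels), function(p) {
    paste(p, panels[[p]]$traits$conditions, sep = "_")
  }))
  out <- matrix(NA_real_, length(trait_ids), length(cols),
                dimnames = list(trait_ids, cols))
  for (p in names(panels)) {
    geno <- panels[[p]]$geno
    traits <- panels[[p]]$traits
    mk <- markers_in_region(region, geno$markers)
    if (!length(mk)) next
    present <- intersect(trait_ids, rownames(traits$values[[1]]))
    if (!length(present)) next
    for (cond in traits$conditions) {
      tm <- traits$values[[cond]][present, , drop = FALSE]
      al <- align_condition(tm, geno, markers = mk)
      lrs <- lrs_matrix(al$X, al$G, cap = cap)$lrs
      out[present, paste(p, cond, sep = "_")] <- apply(lrs, 1, max)
    }
  }
  out
}

#' Select candidate genes matching a behavioral QTL's activity pattern
#'
#' A gene with an eQTL at markers inside the region is kept iff all three
#' criteria hold: (1) not significant in the focal panel's control SC group,
#' (2) significant in the focal panel's ethanol-treated EC group, and (3) not
#' conserved in the other panel (no condition significant there). Genes whose
#' cross-panel record is missing cannot satisfy criterion 3 and are dropped.
#'
#' @param hits Patterned, cross-panel-annotated hits for the focal panel
#'   (columns `trait_id`, `chr`, `pos_mb`, `bit_SC`, `bit_EC`, ...,
#'   `conserved_any`), e.g. from [cross_panel_records()].
#' @param region A [region_spec()].
#' @return Sorted character vector of selected trait ids (empty when no hit
#'   falls inside the region).
#' @export
select_candidates <- function(hits, region) {
  inside <- hits$chr == region$chr &
    hits$pos_mb >= region$start_mb & hits$pos_mb <= region$end_mb
  h <- hits[inside, , drop = FALSE]
  if (!nrow(h)) return(character(0))
  keep <- !h$bit_SC & h$bit_EC & !is.na(h$conserved_any) & !h$conserved_any
  sort(unique(h$trait_id[keep]))
}

#' QTL-activity-pattern correlation network around a behavioral QTL
#'
#' Transcripts are prefiltered by their region LRS in the focal panel under
#' the focal condition (`> prefilter_lrs`, FDR ~25% at the default 20). A
#' transcript enters the network when the Pearson correlation between its
#' 8-entry region-LRS vector and the phenotype's exceeds `include_r`; edges
#' (phenotype-transcript and transcript-transcript) are drawn at
#' `r > edge_r`. Correlations use pairwise-complete entries; pairs sharing
#' fewer than `min_shared` entries yield no edge.
#'
#' @param pheno_vec Named numeric vector: the phenotype's region-LRS vector
#'   (see [region_lrs_vector()]).
#' @param transcript_mat Numeric matrix of transcript region-LRS vectors
#'   (rows = transcripts, columns matching `pheno_vec`).
#' @param focal_col Column name of the focal panel x condition entry (e.g.
#'   `"LXS_EC"`) used for the prefilter.
#' @param prefilter_lrs LRS prefilter (default 20).
#' @param include_r Node inclusion threshold on r with the phenotype
#'   (default 0.7).
#' @param edge_r Edge threshold (default 0.8).
#' @param min_shared Minimum shared non-missing entries per pair (default 4).
#' @param phenotype Node name for the phenotype (default `"phenotype"`).
#' @return Object of class `pattern_network`: list with `graph` (igraph),
#'   `nodes` (`data.frame`: node, type, r with phenotype), `edges`
#'   (`data.frame`: from, to, r, edge type).
#' @export
build_pattern_network <- function(pheno_vec, transcript_mat, focal_col,
                                  prefilter_lrs = 20, include_r = 0.7,
                                  edge_r = 0.8, min_shared = 4,
                                  phenotype = "phenotype") {
  stopifnot(focal_col %in% colnames(transcript_mat))
  if (all(is.na(pheno_vec)) || stats::sd(pheno_vec, na.rm = TRUE) == 0) {
    stop("phenotype activity-pattern vector is constant; correlation undefined")
  }
  pair_cor <- function(a, b) {
    keep <- !is.na(a) & !is.na(b)
    if (sum(keep) < min_shared) return(NA_real_)
    if (stats::sd(a[keep]) == 0 || stats::sd(b[keep]) == 0) return(NA_real_)
    stats::cor(a[keep], b[keep])
  }
  pass <- !is.na(transcript_mat[, focal_col]) &
    transcript_mat[, focal_col] > prefilter_lrs
  cand <- transcript_mat[pass, , drop = FALSE]
  r_pheno <- apply(cand, 1, pair_cor, b = pheno_vec)
  nodes_tr <- rownames(cand)[!is.na(r_pheno) & r_pheno > include_r]
  nodes <- data.frame(
    node = c(phenotype, nodes_tr),
    type = c("phenotype", rep("transcript", length(nodes_tr))),
    r_with_phenotype = c(NA_real_, r_pheno[nodes_tr]),
    stringsAsFactors = FALSE)
  vecs <- rbind(phenotype = pheno_vec, cand[nodes_tr, , drop = FALSE])
  rownames(vecs)[1] <- phenotype
  edges <- list()
  nn <- nrow(vecs)
  if (nn >= 2) {
    for (i in seq_len(nn - 1)) {
      for (j in seq((i + 1), nn)) {
        r <- pair_cor(vecs[i, ], vecs[j, ])
        if (!is.na(r) && r > edge_r) {
          edges[[length(edges) + 1]] <- data.frame(
            from = rownames(vecs)[i], to = rownames(vecs)[j], r = r,
            edge_type = if (i == 1) "phenotype-transcript" else
              "transcript-transcript",
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(from = character(), to = character(), r = numeric(),
               edge_type = character(), stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = nodes)
  structure(list(graph = g, nodes = nodes, edges = edges,
                 include_r = include_r, edge_r = edge_r,
                 prefilter_lrs = prefilter_lrs),
            class = "pattern_network")
}

#' @export
print.pattern_network <- function(x, ...) {
  cat(sprintf("pattern_network: %d node(s) (r > %.2f with phenotype), %d edge(s) (r > %.2f)\n",
              nrow(x$nodes), x$include_r, nrow(x$edges), x$edge_r))
  invisible(x)
}
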