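# End-to-end orchestration: simulate -> scan -> FDR thresholds -> classify ->
# activity patterns -> cross-panel conservation -> candidates/network, with
# one config and deterministic per-stage seeding.

# Per-stage seeds derived from the global seed by a fixed counter scheme, so
# any stage can be re-run in isolation.
stage_seed <- function(seed, stage) {
  offsets <- c(simulate = 0L, fdr = 1L, pheno = 2L, network = 3L)
  (as.integer(seed) * 101L + offsets[[stage]]) %% .Machine$integer.max
}

#' Run the full analysis pipeline on a synthetic two-panel study
#'
#' Stages: (1) simulate the study from `config`; (2) scan every trait in
#' every panel x condition and take per-chromosome maxima; (3) estimate each
#' panel's significance threshold by permutation FDR (smallest grid theta
#' with FDR at or below `fdr_target` in every condition; configurable fixed
#' thresholds override); (4) classify significant eQTLs by gene-marker
#' geometry; (5) compute activity patterns and per-class summaries;
#' (6) cross-panel conservation plus eQTL and SNP conservation-ratio tracks
#' and their correlation; (7) candidate selection and a pattern-correlation
#' network around the first behavioral QTL region. All stage outputs are
#' written as TSV/CSV under `out_dir` and a manifest (config echo, seeds,
#' file digests, timings) is returned.
#'
#' @param config A [sim_config()], or a path to a YAML file of `sim_config`
#'   arguments (scalar fields only).
#' @param out_dir Output directory (created if needed).
#' @param n_perm Permutations for the FDR stage.
#' @param fdr_target FDR target for threshold selection.
#' @param thresholds Optional fixed per-panel LRS thresholds (named numeric),
#'   bypassing stage 3 (e.g. `c(LXS = 24, BXD = 26)` for replication-style
#'   runs).
#' @return List of class `run_manifest`: `config`, `seeds`, `thresholds`,
#'   `files` (paths), `digests` (md5 per file), `timings` (seconds per
#'   stage), plus the in-memory `results`.
#' @export
run_pipeline <- function(config = sim_config(), out_dir = tempfile("qtlrun"),
                         n_perm = 200, fdr_target = 0.05, thresholds = NULL) {
  if (is.character(config)) {
    args <- yaml::read_yaml(config)
    config <- do.call(sim_config, args)
  }
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- list(simulate = stage_seed(config$seed, "simulate"),
                fdr = stage_seed(config$seed, "fdr"))
  timings <- c()
  tic <- function() proc.time()[["elapsed"]]
  files <- list()
  emit <- function(name, writer) {
    path <- file.path(out_dir, name)
    writer(path)
    files[[name]] <<- path
    path
  }

  # 1: simulate ------------------------------------------------------------
  t0 <- tic()
  config$seed <- seeds$simulate
  study <- make_two_panel_study(config)
  panels <- config$panels
  conds <- default_conditions()
  for (p in panels) {
    emit(paste0(p, ".geno"), function(f) write_geno(study$geno[[p]], f))
    for (cond in conds) {
      emit(sprintf("%s_%s_traits.csv", p, cond), function(f)
        write_trait_table(study$traits[[p]]$values[[cond]], f))
    }
  }
  emit("snp_panel.csv", function(f)
    utils::write.csv(study$snps, f, row.names = FALSE, quote = FALSE))
  emit("ground_truth.tsv", function(f)
    utils::write.table(study$truth, f, sep = "\t", quote = FALSE,
                       row.names = FALSE))
  timings["simulate"] <- tic() - t0

  # 2: scans ---------------------------------------------------------------
  t0 <- tic()
  scans <- lapply(panels, function(p) {
    out <- lapply(conds, function(cond) {
      scan_condition(study$traits[[p]]$values[[cond]], study$geno[[p]])
    })
    names(out) <- conds
    out
  })
  names(scans) <- panels
  timings["scan"] <- tic() - t0

  # 3: thresholds ----------------------------------------------------------
  t0 <- tic()
  fdr_tables <- list()
  if (is.null(thresholds)) {
    thresholds <- stats::setNames(numeric(length(panels)), panels)
    for (p in panels) {
      per_cond <- lapply(conds, function(cond) {
        permutation_fdr(study$traits[[p]]$values[[cond]], study$geno[[p]],
                        n_perm = n_perm, target = fdr_target,
                        seed = seeds$fdr)
      })
      names(per_cond) <- conds
      fdr_tables[[p]] <- per_cond
      th <- vapply(per_cond, function(f) f$theta_at_target, numeric(1))
      thresholds[p] <- if (all(is.na(th))) NA_real_ else max(th, na.rm = TRUE)
      emit(sprintf("%s_fdr.tsv", p), function(f)
        utils::write.table(per_cond[[1]]$table, f, sep = "\t", quote = FALSE,
                           row.names = FALSE))
    }
  } else {
    thresholds <- thresholds[panels]
  }
  timings["fdr"] <- tic() - t0

  # 4-5: significant hits, classes, patterns -------------------------------
  t0 <- tic()
  patterned <- list()
  summaries <- list()
  for (p in panels) {
    th <- thresholds[[p]]
    sig <- unique(do.call(rbind, lapply(conds, function(cond) {
      s <- scans[[p]][[cond]]
      s[s$lrs > th, c("trait_id", "marker", "chr", "pos_mb", "lrs",
                      "effect_sign")]
    })))
    # one record per (trait, marker) pair significant in any condition
    sig <- sig[!duplicated(sig[, c("trait_id", "marker")]), , drop = FALSE]
    sig$significant <- TRUE
    sig <- classify_eqtls(sig, study$traits[[p]]$annotation)
    sig <- sig[sig$eqtl_class != "not_applicable", , drop = FALSE]
    if (nrow(sig)) {
      sig <- activity_patterns(sig, study$traits[[p]], study$geno[[p]], th)
      summaries[[p]] <- summarize_patterns(sig)
      emit(sprintf("%s_patterns.tsv", p), function(f)
        utils::write.table(sig, f, sep = "\t", quote = FALSE,
                           row.names = FALSE))
      emit(sprintf("%s_pattern_summary.tsv", p), function(f)
        utils::write.table(summaries[[p]]$summary, f, sep = "\t",
                           quote = FALSE, row.names = FALSE))
      emit(sprintf("%s_qtl.tsv", p), function(f) write_qtl_table(sig, f))
    }
    patterned[[p]] <- sig
  }
  timings["patterns"] <- tic() - t0

  # 6: cross-panel conservation + tracks -----------------------------------
  t0 <- tic()
  p1 <- panels[1]; p2 <- panels[2]
  xp <- NULL
  tracks <- list()
  track_r <- NA_real_
  if (nrow(patterned[[p2]])) {
    xp <- cross_panel_records(patterned[[p2]], study$geno[[p2]],
                              study$geno[[p1]], study$traits[[p1]],
                              thresholds[[p1]])
    emit(sprintf("%s_in_%s_conservation.tsv", p2, p1), function(f)
      utils::write.table(xp, f, sep = "\t", quote = FALSE, row.names = FALSE))
    feats <- data.frame(chr = xp$chr, pos_mb = xp$pos_mb,
                        conserved = xp$conserved_any)
    feats <- feats[!is.na(feats$conserved), , drop = FALSE]
    if (nrow(feats) && any(feats$conserved) && !all(feats$conserved)) {
      tracks$eqtl <- sliding_conservation_ratio(
        feats, chrom_lengths_mb = config$chrom_lengths_mb)
      tracks$snp <- sliding_conservation_ratio(
        study$snps, chrom_lengths_mb = config$chrom_lengths_mb)
      track_r <- tryCatch(track_correlation(tracks$eqtl, tracks$snp),
                          error = function(e) NA_real_)
      emit("conservation_eqtl.tsv", function(f)
        utils::write.table(as.data.frame(tracks$eqtl), f, sep = "\t",
                           quote = FALSE, row.names = FALSE))
      emit("conservation_snp.tsv", function(f)
        utils::write.table(as.data.frame(tracks$snp), f, sep = "\t",
                           quote = FALSE, row.names = FALSE))
    }
  }
  timings["conservation"] <- tic() - t0

  # 7: candidates + network around the first behavioral QTL ----------------
  t0 <- tic()
  candidates <- character(0)
  network <- NULL
  beh <- study$truth[study$truth$kind == "behavioral" &
                       study$truth$panel == p1 &
                       !is.na(study$truth$causal_marker), , drop = FALSE]
  if (nrow(beh) && nrow(patterned[[p1]])) {
    reg <- region_spec(beh$causal_chr[1],
                       max(0, beh$causal_pos_mb[1] - 10),
                       beh$causal_pos_mb[1] + 10,
                       focal_panel = p1, phenotype = beh$trait_id[1])
    xp1 <- cross_panel_records(patterned[[p1]], study$geno[[p1]],
                               study$geno[[p2]], study$traits[[p2]],
                               thresholds[[p2]])
    candidates <- select_candidates(xp1, reg)
    writeLines(candidates, file.path(out_dir, "candidates.txt"))
    files[["candidates.txt"]] <- file.path(out_dir, "candidates.txt")
    pan <- stats::setNames(lapply(panels, function(p)
      list(geno = study$geno[[p]], traits = study$traits[[p]])), panels)
    pheno_vec <- region_lrs_vector(beh$trait_id[1], reg, pan)
    expr_ids <- study$truth$trait_id[study$truth$kind == "expression" &
                                       study$truth$panel == p1]
    tr_mat <- region_lrs_matrix(unique(expr_ids), reg, pan)
    network <- tryCatch(
      build_pattern_network(pheno_vec, tr_mat,
                            focal_col = paste(p1, "EC", sep = "_"),
                            phenotype = beh$trait_id[1]),
      error = function(e) NULL)
    if (!is.null(network)) {
      emit("network_edges.tsv", function(f)
        utils::write.table(network$edges, f, sep = "\t", quote = FALSE,
                           row.names = FALSE))
    }
  }
  timings["network"] <- tic() - t0

  files <- unlist(files)
  structure(list(config = config, seeds = seeds, thresholds = thresholds,
                 files = files, digests = tools::md5sum(files),
                 timings = timings,
                 results = list(study = study, scans = scans,
                                fdr = fdr_tables, patterned = patterned,
                                summaries = summaries, cross_panel = xp,
                                tracks = tracks, track_correlation = track_r,
                                candidates = candidates, network = network)),
            class = "run_manifest")
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("run_manifest\n")
  cat("  thresholds:", paste(names(x$thresholds), signif(x$thresholds, 4),
                             sep = "=", collapse = ", "), "\n")
  cat("  files:", length(x$files), "written\n")
  cat("  timings (s):", paste(names(x$timings), signif(x$timings, 2),
                              sep = "=", collapse = ", "), "\n")
  invisible(x)
}
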