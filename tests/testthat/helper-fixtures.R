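# Shared fixtures: tiny maps/panels built in code, plus independent oracles.

toy_map <- function() {
  marker_map(c("m1", "m2", "m3", "m4"), c("1", "1", "2", "2"),
             c(10, 20, 5, 15))
}

# Deterministic 8-strain genotype matrix over toy_map(); every marker
# informative.
toy_geno <- function(panel_id = "TOY") {
  codes <- rbind(
    c("A", "A", "A", "B"),
    c("A", "A", "B", "B"),
    c("A", "B", "A", "A"),
    c("A", "B", "B", "A"),
    c("B", "A", "A", "B"),
    c("B", "A", "B", "A"),
    c("B", "B", "A", "B"),
    c("B", "B", "B", "A"))
  dimnames(codes) <- list(paste0("S", 1:8), c("m1", "m2", "m3", "m4"))
  geno_matrix(panel_id, codes, toy_map())
}

# Small two-panel study configuration used across tests (scaled-down marker
# and trait counts; 4 chromosomes of 80 Mb).
small_cfg <- function(seed = 1, ...) {
  args <- list(
    n_strains = c(40, 40), n_markers = c(100, 120),
    chrom_lengths_mb = c("1" = 80, "2" = 80, "3" = 80, "4" = 80),
    n_traits = 40, n_cis = 8, n_syntenic_trans = 4, n_nonsyntenic_trans = 8,
    n_snps = 1000, seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(sim_config, args)
}

# Independent maximum-likelihood oracle for the LRS: twice the log-likelihood
# difference between the genotype-group model and the grand-mean model, both
# fitted with stats::lm (variance profiled out by logLik).
lrs_lm_oracle <- function(y, g) {
  keep <- !is.na(y) & !is.na(g)
  y <- y[keep]
  g <- factor(g[keep])
  2 * as.numeric(stats::logLik(stats::lm(y ~ g)) -
                   stats::logLik(stats::lm(y ~ 1)))
}

# Correlation route for the same statistic.
lrs_cor_route <- function(y, g01) {
  keep <- !is.na(y) & !is.na(g01)
  r <- stats::cor(y[keep], g01[keep])
  -sum(keep) * log(1 - r^2)
}

# Independent brute force for the conservation track: every feature tested
# against every window.
brute_force_track <- function(features, window_mb, step_mb, lengths) {
  gf <- mean(features$conserved)
  rows <- list()
  for (ch in names(lengths)) {
    starts <- seq(0, max(0, lengths[[ch]] - step_mb), by = step_mb)
    for (s in starts) {
      n <- 0; k <- 0
      for (i in seq_len(nrow(features))) {
        if (features$chr[i] == ch && features$pos_mb[i] >= s &&
            features$pos_mb[i] < s + window_mb) {
          n <- n + 1
          if (features$conserved[i]) k <- k + 1
        }
      }
      rows[[length(rows) + 1]] <- data.frame(
        chr = ch, start_mb = s, n_features = n, n_conserved = k,
        ratio = if (n * gf > 0) k / (n * gf) else NA_real_)
    }
  }
  do.call(rbind, rows)
}

# Write a GeneNetwork-style .geno text fixture; returns the path.
write_toy_geno_file <- function(rows, path = tempfile(fileext = ".geno"),
                                header = "Chr\tLocus\tMb\tS1\tS2\tS3") {
  writeLines(c("#comment line", "@type:riset", header, rows), path)
  path
}
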