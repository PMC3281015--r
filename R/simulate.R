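# Synthetic two-panel, four-condition study generator with planted,
# treatment-dependent genetic effects and full ground truth.
#
# RI genotypes are simulated as a two-state Markov chain along each
# chromosome: the first marker is A or B with probability 1/2 and the
# transition probability between adjacent markers d Mb apart is
#   p = (1 - exp(-2 r d)) / 2   (capped at 1/2),
# with r the effective breakpoint rate per Mb. Trait values are strain means:
#   y[strain, cond] = baseline(trait) + beta[cond] * I(B at causal marker)
#                     + Normal(0, sigma),
# drawn independently per strain x condition.

# Mouse chromosome lengths (Mb, approximate), autosomes 1..19 plus X.
mouse_chrom_lengths <- function() {
  c("1" = 195, "2" = 182, "3" = 160, "4" = 157, "5" = 152, "6" = 150,
    "7" = 145, "8" = 129, "9" = 124, "10" = 131, "11" = 122, "12" = 120,
    "13" = 121, "14" = 125, "15" = 104, "16" = 98, "17" = 95, "18" = 91,
    "19" = 61, "X" = 171)
}

#' Simulate a marker map
#'
#' Markers are allocated to chromosomes proportionally to length (at least 2
#' per chromosome) and placed uniformly at random, then sorted.
#'
#' @param n_markers Total number of markers.
#' @param chrom_lengths_mb Named chromosome lengths in Mb.
#' @param prefix Marker id prefix.
#' @param seed Optional RNG seed.
#' @return A [marker_map()] `data.frame`.
#' @export
simulate_marker_map <- function(n_markers,
                                chrom_lengths_mb = mouse_chrom_lengths(),
                                prefix = "m", seed = NULL) {
  maybe_seed(seed)
  stopifnot(n_markers >= 2 * length(chrom_lengths_mb))
  alloc <- round(n_markers * chrom_lengths_mb / sum(chrom_lengths_mb))
  alloc[alloc < 2] <- 2
  # trim/pad to hit the requested total exactly
  while (sum(alloc) != n_markers) {
    i <- which.max(alloc)
    alloc[i] <- alloc[i] + sign(n_markers - sum(alloc))
  }
  chr <- rep(names(chrom_lengths_mb), alloc)
  pos <- unlist(lapply(names(chrom_lengths_mb), function(ch) {
    sort(stats::runif(alloc[[ch]], 0, chrom_lengths_mb[[ch]]))
  }))
  marker_map(sprintf("%s%04d", prefix, seq_len(n_markers)), chr, pos)
}

#' Simulate RI-panel genotypes along a marker map
#'
#' Each strain's chromosome is an independent two-state Markov chain (see the
#' file header for the transition model). `d = 0` between adjacent markers
#' gives complete linkage; `r = 0` gives a fully linked chromosome.
#'
#' @param map A [marker_map()].
#' @param n_strains Number of strains (or a character vector of strain ids).
#' @param rate Breakpoint rate per Mb (default 0.02).
#' @param panel_id Panel label.
#' @param seed Optional RNG seed.
#' @return A [geno_matrix()].
#' @export
simulate_ri_genotypes <- function(map, n_strains, rate = 0.02,
                                  panel_id = "SIM", seed = NULL) {
  maybe_seed(seed)
  if (!nrow(map)) stop("empty marker map")
  strains <- if (is.character(n_strains)) n_strains else
    sprintf("%s-%03d", panel_id, seq_len(n_strains))
  n <- length(strains)
  codes <- matrix(NA_character_, n, nrow(map),
                  dimnames = list(strains, map$marker))
  for (ch in unique(map$chr)) {
    idx <- which(map$chr == ch)
    d <- diff(map$pos_mb[idx])
    p <- pmin(0.5, (1 - exp(-2 * rate * d)) / 2)
    state <- matrix(0L, n, length(idx))
    state[, 1] <- stats::rbinom(n, 1, 0.5)
    if (length(idx) > 1) {
      flips <- matrix(stats::rbinom(n * length(d), 1, rep(p, each = n)),
                      n, length(d))
      state[, -1] <- (state[, 1] + matrixcumsum(flips)) %% 2L
    }
    codes[, idx] <- ifelse(state == 1L, "B", "A")
  }
  geno_matrix(panel_id, codes, map)
}

# row-wise cumulative sum of an integer matrix
matrixcumsum <- function(m) {
  t(apply(m, 1, cumsum))
}

#' Transition probability of the RI genotype chain
#'
#' @param d Distance between adjacent markers in Mb.
#' @param rate Breakpoint rate per Mb.
#' @return `pmin(0.5, (1 - exp(-2 * rate * d)) / 2)`.
#' @export
ri_transition_prob <- function(d, rate) {
  pmin(0.5, (1 - exp(-2 * rate * d)) / 2)
}

#' Table of planted effects
#'
#' Helper building the `effects` input of [plant_traits()]: one row per
#' trait, with a causal marker, one additive effect size per condition
#' (shift of the B-allele strains, trait units) and the intended activity
#' pattern (bit set iff the condition's effect is nonzero).
#'
#' @param trait_id,causal_marker Character vectors.
#' @param beta Numeric matrix (traits x conditions) of effect sizes, or a
#'   single row recycled.
#' @param gene_chr,gene_pos_mb Gene location of each (expression) trait.
#' @param kind `"expression"` or `"behavioral"` per trait.
#' @param conditions Condition order.
#' @return `data.frame` with columns `trait_id`, `causal_marker`,
#'   `beta_<cond>`, `gene_chr`, `gene_pos_mb`, `kind`, `intended_pattern`
#'   (e.g. `"0100"`).
#' @export
planted_effects <- function(trait_id, causal_marker, beta,
                            gene_chr = NA, gene_pos_mb = NA,
                            kind = "expression",
                            conditions = default_conditions()) {
  n <- length(trait_id)
  beta <- matrix(beta, nrow = n, ncol = length(conditions), byrow = FALSE)
  out <- data.frame(trait_id = trait_id, causal_marker = causal_marker,
                    stringsAsFactors = FALSE)
  for (j in seq_along(conditions)) out[[paste0("beta_", conditions[j])]] <- beta[, j]
  out$gene_chr <- as.character(rep_len(gene_chr, n))
  out$gene_pos_mb <- as.numeric(rep_len(gene_pos_mb, n))
  out$kind <- rep_len(kind, n)
  out$intended_pattern <- apply(beta != 0, 1, function(b)
    paste(as.integer(b), collapse = ""))
  out
}

#' Plant trait values on simulated genotypes
#'
#' Generates a [trait_set()] whose strain means follow the additive model in
#' the file header. Rows of `effects` with all-zero effect sizes produce pure
#' noise (null) traits. The per-trait baseline is drawn once from
#' Normal(8, 1) (log-intensity-like units).
#'
#' @param geno A [geno_matrix()].
#' @param effects A [planted_effects()] table; every `causal_marker` must
#'   exist in the panel (rows with `NA` marker are unplanted null traits).
#' @param sigma Residual standard deviation (>= 0; 0 gives the noise-free
#'   limit).
#' @param conditions Condition order.
#' @param condition_strains Optional named list giving the strain subset
#'   measured in each condition (default: all strains in all conditions).
#' @param seed Optional RNG seed.
#' @return List: `traits` (a [trait_set()]), `truth` (the effects table with
#'   `causal_chr`/`causal_pos_mb` added).
#' @export
plant_traits <- function(geno, effects, sigma = 1,
                         conditions = default_conditions(),
                         condition_strains = NULL, seed = NULL) {
  maybe_seed(seed)
  stopifnot(sigma >= 0)
  planted <- !is.na(effects$causal_marker)
  unknown <- setdiff(effects$causal_marker[planted], geno$markers$marker)
  if (length(unknown)) {
    stop("unknown causal marker(s): ", paste(unknown, collapse = ", "))
  }
  strains <- geno$strains
  if (is.null(condition_strains)) {
    condition_strains <- stats::setNames(
      rep(list(strains), length(conditions)), conditions)
  }
  n_tr <- nrow(effects)
  baseline <- stats::rnorm(n_tr, 8, 1)
  g01 <- geno_numeric(geno)
  values <- stats::setNames(vector("list", length(conditions)), conditions)
  for (cond in conditions) {
    ss <- condition_strains[[cond]]
    mat <- matrix(baseline, n_tr, length(ss),
                  dimnames = list(effects$trait_id, ss))
    bcol <- effects[[paste0("beta_", cond)]]
    for (i in which(planted & bcol != 0)) {
      carrier <- g01[ss, effects$causal_marker[i]]
      carrier[is.na(carrier)] <- 0
      mat[i, ] <- mat[i, ] + bcol[i] * carrier
    }
    mat <- mat + stats::rnorm(length(mat), 0, sigma)
    values[[cond]] <- mat
  }
  ann <- data.frame(trait_id = effects$trait_id, kind = effects$kind,
                    gene_symbol = effects$trait_id,
                    gene_chr = effects$gene_chr,
                    gene_pos_mb = effects$gene_pos_mb,
                    stringsAsFactors = FALSE)
  truth <- effects
  mi <- match(truth$causal_marker, geno$markers$marker)
  truth$causal_chr <- geno$markers$chr[mi]
  truth$causal_pos_mb <- geno$markers$pos_mb[mi]
  list(traits = trait_set(geno$panel_id, values, ann, conditions),
       truth = truth)
}

#' Position-dependent sharing function with 50-Mb patches
#'
#' Returns a function of (chromosome, position) giving the probability that a
#' causal variant (or SNP) at that position segregates in both panels.
#' Alternating 50-Mb patches take the `high` and `low` sharing probabilities,
#' emulating the patchy genome-wide distribution of variants shared between
#' two RI panels' parental contrasts.
#'
#' @param high,low Sharing probabilities inside/outside conserved patches.
#' @param patch_mb Patch width in Mb (default 50).
#' @return `function(chr, pos_mb)` vectorized over positions.
#' @export
patch_sharing_fn <- function(high = 0.8, low = 0.1, patch_mb = 50) {
  force(high); force(low); force(patch_mb)
  function(chr, pos_mb) {
    ifelse(floor(pos_mb / patch_mb) %% 2 == 0, high, low)
  }
}

#' Simulation configuration for a two-panel study
#'
#' Defaults describe the emulated study design: two RI panels with 31 and 30
#' strains, 2659 and 3796 markers, four treatment conditions, planted cis
#' effects that are mostly active in all conditions and non-syntenic trans
#' effects that are mostly single-condition (EC-biased), residual sd 1 and
#' effect size 3 in residual-sd units, a 78881-SNP panel, and patchy 50-Mb
#' position-dependent sharing of causal variants between panels.
#'
#' @param panels Two panel labels.
#' @param n_strains,n_markers Named (per panel) counts.
#' @param chrom_lengths_mb Chromosome lengths (Mb).
#' @param breakpoint_rate Breakpoints per Mb for the genotype chain.
#' @param n_traits Total expression traits (planted + null).
#' @param n_cis,n_syntenic_trans,n_nonsyntenic_trans Planted effect counts.
#' @param n_behavioral Behavioral traits (planted EC-only QTL in panel 1).
#' @param effect_size Planted |beta| in units of `sigma`.
#' @param sigma Residual standard deviation.
#' @param cis_all_fraction Fraction of cis effects active in all conditions.
#' @param trans_single_fraction Fraction of non-syntenic trans effects active
#'   in exactly one condition.
#' @param sharing_fn Sharing probability `function(chr, pos_mb)`; constants
#'   are accepted.
#' @param n_snps SNP-panel size.
#' @param unequal_groups Drop a few strains at random per condition to mimic
#'   unequal treatment-group sizes?
#' @param seed RNG seed for the whole study.
#' @return A `sim_config` list.
#' @export
sim_config <- function(panels = c("LXS", "BXD"),
                       n_strains = c(31, 30),
                       n_markers = c(2659, 3796),
                       chrom_lengths_mb = mouse_chrom_lengths(),
                       breakpoint_rate = 0.02,
                       n_traits = 200,
                       n_cis = 30, n_syntenic_trans = 10,
                       n_nonsyntenic_trans = 30,
                       n_behavioral = 2,
                       effect_size = 3, sigma = 1,
                       cis_all_fraction = 0.6,
                       trans_single_fraction = 0.85,
                       sharing_fn = patch_sharing_fn(),
                       n_snps = 78881,
                       unequal_groups = FALSE,
                       seed = 1) {
  if (is.numeric(sharing_fn)) {
    const <- sharing_fn
    sharing_fn <- function(chr, pos_mb) rep(const, length(pos_mb))
  }
  stopifnot(length(panels) == 2, breakpoint_rate > 0, sigma >= 0,
            n_cis + n_syntenic_trans + n_nonsyntenic_trans <= n_traits)
  structure(list(panels = panels,
                 n_strains = stats::setNames(rep_len(n_strains, 2), panels),
                 n_markers = stats::setNames(rep_len(n_markers, 2), panels),
                 chrom_lengths_mb = chrom_lengths_mb,
                 breakpoint_rate = breakpoint_rate,
                 n_traits = n_traits, n_cis = n_cis,
                 n_syntenic_trans = n_syntenic_trans,
                 n_nonsyntenic_trans = n_nonsyntenic_trans,
                 n_behavioral = n_behavioral,
                 effect_size = effect_size, sigma = sigma,
                 cis_all_fraction = cis_all_fraction,
                 trans_single_fraction = trans_single_fraction,
                 sharing_fn = sharing_fn, n_snps = n_snps,
                 unequal_groups = unequal_groups, seed = seed),
            class = "sim_config")
}

# Draw an activity-pattern bit vector for one planted effect.
draw_pattern <- function(class, cfg, conditions = default_conditions()) {
  nc <- length(conditions)
  single <- function() {
    # EC-biased single-condition patterns (ethanol is the activating arm)
    b <- rep(0L, nc)
    b[sample.int(nc, 1, prob = c(0.15, 0.55, 0.15, 0.15))] <- 1L
    b
  }
  any_nonnull <- function() {
    repeat {
      b <- stats::rbinom(nc, 1, 0.5)
      if (sum(b) > 0) return(b)
    }
  }
  if (class == "cis") {
    if (stats::runif(1) < cfg$cis_all_fraction) rep(1L, nc) else any_nonnull()
  } else if (class == "nonsyntenic_trans") {
    if (stats::runif(1) < cfg$trans_single_fraction) single() else any_nonnull()
  } else {
    any_nonnull()
  }
}

# Random genomic position, chromosomes weighted by length.
random_position <- function(n, chrom_lengths_mb) {
  chr <- sample(names(chrom_lengths_mb), n, replace = TRUE,
                prob = chrom_lengths_mb / sum(chrom_lengths_mb))
  pos <- stats::runif(n, 0, chrom_lengths_mb[chr])
  data.frame(chr = chr, pos_mb = pos, stringsAsFactors = FALSE)
}

#' Generate a complete synthetic two-panel study
#'
#' Produces genotypes, conditioned trait sets, a SNP panel and a ground-truth
#' table. Causal variants are drawn at genome positions; each is shared
#' between the panels with probability `sharing_fn(chr, pos)` (shared effects
#' are planted in both panels, at each panel's nearest marker to the common
#' position, with equal effect sizes; private effects are planted in one
#' panel only, the trait staying null in the other). SNP `conserved` flags
#' follow the same sharing function, so eQTL and SNP conservation-ratio
#' tracks are positively associated by construction.
#'
#' @param config A [sim_config()].
#' @return List of class `two_panel_study`: `geno` (named list of two
#'   [geno_matrix()]), `traits` (named list of two [trait_set()]), `snps`
#'   (SNP panel `data.frame`), `truth` (ground-truth `data.frame`: one row
#'   per planted panel effect plus null traits), `config`.
#' @export
make_two_panel_study <- function(config = sim_config()) {
  cfg <- config
  maybe_seed(cfg$seed)
  conds <- default_conditions()
  nc <- length(conds)
  panels <- cfg$panels

  maps <- lapply(panels, function(p) {
    simulate_marker_map(cfg$n_markers[[p]], cfg$chrom_lengths_mb,
                        prefix = paste0(substr(p, 1, 1), "m"))
  })
  names(maps) <- panels
  geno <- lapply(panels, function(p) {
    simulate_ri_genotypes(maps[[p]], cfg$n_strains[[p]],
                          rate = cfg$breakpoint_rate, panel_id = p)
  })
  names(geno) <- panels

  # --- planted expression effects -----------------------------------------
  classes <- c(rep("cis", cfg$n_cis),
               rep("syntenic_trans", cfg$n_syntenic_trans),
               rep("nonsyntenic_trans", cfg$n_nonsyntenic_trans))
  n_planted <- length(classes)
  pos <- random_position(n_planted, cfg$chrom_lengths_mb)
  shared <- stats::runif(n_planted) < cfg$sharing_fn(pos$chr, pos$pos_mb)
  owner <- sample(panels, n_planted, replace = TRUE)   # focal panel if private
  patt <- t(vapply(classes, draw_pattern, integer(nc), cfg = cfg))
  beta <- patt * cfg$effect_size * cfg$sigma

  # gene location per trait, by class geometry relative to the causal locus
  gene_chr <- pos$chr
  gene_pos <- pos$pos_mb
  for (i in seq_len(n_planted)) {
    len <- cfg$chrom_lengths_mb[[pos$chr[i]]]
    if (classes[i] == "cis") {
      gene_pos[i] <- min(max(pos$pos_mb[i] + stats::runif(1, -2, 2), 0), len)
    } else if (classes[i] == "syntenic_trans") {
      shift <- sample(c(-1, 1), 1) * stats::runif(1, 15, 50)
      gp <- pos$pos_mb[i] + shift
      if (gp < 0 || gp > len) gp <- pos$pos_mb[i] - shift
      gene_pos[i] <- min(max(gp, 0), len)
    } else {
      other <- setdiff(names(cfg$chrom_lengths_mb), pos$chr[i])
      gene_chr[i] <- sample(other, 1)
      gene_pos[i] <- stats::runif(1, 0, cfg$chrom_lengths_mb[[gene_chr[i]]])
    }
  }
  trait_ids <- sprintf("gene%04d", seq_len(cfg$n_traits))
  planted_ids <- trait_ids[seq_len(n_planted)]

  # null expression traits: random gene locations, no effect anywhere
  n_null <- cfg$n_traits - n_planted
  null_pos <- random_position(n_null, cfg$chrom_lengths_mb)

  # behavioral traits: EC-only QTL in panel 1, none in panel 2
  beh_ids <- if (cfg$n_behavioral > 0)
    sprintf("pheno%02d", seq_len(cfg$n_behavioral)) else character(0)
  beh_pos <- random_position(cfg$n_behavioral, cfg$chrom_lengths_mb)

  effects <- list()
  truth <- list()
  for (p in panels) {
    map <- maps[[p]]
    near <- vapply(seq_len(n_planted), function(i) {
      nearest_marker(pos$chr[i], pos$pos_mb[i], map)
    }, character(1))
    active <- shared | owner == p
    beta_p <- beta * as.numeric(active)
    eff <- planted_effects(
      trait_id = planted_ids, causal_marker = ifelse(active, near, NA),
      beta = beta_p, gene_chr = gene_chr, gene_pos_mb = gene_pos,
      kind = "expression", conditions = conds)
    eff$class <- classes
    eff$shared <- shared
    null_eff <- planted_effects(
      trait_id = trait_ids[seq_len(n_null) + n_planted],
      causal_marker = NA,
      beta = matrix(0, n_null, nc),
      gene_chr = null_pos$chr, gene_pos_mb = null_pos$pos_mb,
      kind = "expression", conditions = conds)
    null_eff$class <- "null"
    null_eff$shared <- NA
    beh_eff <- NULL
    if (cfg$n_behavioral > 0) {
      beh_beta <- matrix(0, cfg$n_behavioral, nc,
                         dimnames = list(NULL, conds))
      beh_marker <- rep(NA_character_, cfg$n_behavioral)
      if (p == panels[1]) {
        beh_beta[, "EC"] <- cfg$effect_size * cfg$sigma
        beh_marker <- vapply(seq_len(cfg$n_behavioral), function(i) {
          nearest_marker(beh_pos$chr[i], beh_pos$pos_mb[i], map)
        }, character(1))
      }
      beh_eff <- planted_effects(
        trait_id = beh_ids, causal_marker = beh_marker, beta = beh_beta,
        gene_chr = NA, gene_pos_mb = NA, kind = "behavioral",
        conditions = conds)
      beh_eff$class <- "not_applicable"
      beh_eff$shared <- FALSE
    }
    effects[[p]] <- rbind(eff, null_eff, beh_eff)
  }

  condition_strains <- lapply(panels, function(p) {
    ss <- geno[[p]]$strains
    if (!cfg$unequal_groups) {
      stats::setNames(rep(list(ss), nc), conds)
    } else {
      stats::setNames(lapply(conds, function(cond) {
        sort(sample(ss, length(ss) - sample(0:3, 1)))
      }), conds)
    }
  })
  names(condition_strains) <- panels

  traits <- list()
  for (p in panels) {
    pl <- plant_traits(geno[[p]], effects[[p]], sigma = cfg$sigma,
                       conditions = conds,
                       condition_strains = condition_strains[[p]])
    traits[[p]] <- pl$traits
    tr <- pl$truth
    tr$panel <- p
    truth[[p]] <- tr
  }

  snp_pos <- random_position(cfg$n_snps, cfg$chrom_lengths_mb)
  snps <- data.frame(
    chr = snp_pos$chr, pos_mb = snp_pos$pos_mb,
    conserved = stats::runif(cfg$n_snps) <
      cfg$sharing_fn(snp_pos$chr, snp_pos$pos_mb),
    stringsAsFactors = FALSE)
  snps <- snps[genome_order(snps$chr, snps$pos_mb), ]
  rownames(snps) <- NULL

  structure(list(geno = geno, traits = traits, snps = snps,
                 truth = do.call(rbind, truth), config = cfg),
            class = "two_panel_study")
}

#' @export
print.two_panel_study <- function(x, ...) {
  cat("two_panel_study\n")
  for (p in names(x$geno)) {
    cat("  "); print(x$geno[[p]])
    cat("  "); print(x$traits[[p]])
  }
  cat(sprintf("  SNP panel: %d SNPs (%.1f%% conserved)\n", nrow(x$snps),
              100 * mean(x$snps$conserved)))
  invisible(x)
}
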