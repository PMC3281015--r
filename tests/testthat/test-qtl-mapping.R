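# The LRS statistic, genome scans, chromosome-max QTL calling and
# genome-wide empirical p-values.

test_that("compute_lrs matches the maximum-likelihood oracle on the worked example", {
  y <- c(1, 2, 1, 2, 3, 4, 3, 4)
  g <- c("A", "A", "A", "A", "B", "B", "B", "B")
  res <- compute_lrs(y, g)
  expect_equal(res$lrs, 8 * log(5))
  expect_equal(res$lrs, lrs_lm_oracle(y, g), tolerance = 1e-9)
  expect_equal(res$lod, 8 * log(5) / (2 * log(10)))
  expect_equal(res$effect_sign, 1L)
  expect_equal(res$n_used, 8)
})

test_that("the two closed-form routes and the lm oracle agree on random instances", {
  set.seed(101)
  for (i in 1:400) {
    n <- sample(6:40, 1)
    g01 <- c(0, 0, 1, 1, sample(0:1, n - 4, replace = TRUE))
    y <- rnorm(n) + g01 * rnorm(1)
    g <- ifelse(g01 == 1, "B", "A")
    lrs <- compute_lrs(y, g)$lrs
    expect_equal(lrs, lrs_lm_oracle(y, g), tolerance = 1e-9)
    expect_equal(lrs, lrs_cor_route(y, g01), tolerance = 1e-9)
  }
})

test_that("equal group means give LRS 0 and sign 0", {
  res <- compute_lrs(c(1, 3, 1, 3), c("A", "A", "B", "B"))
  expect_equal(res$lrs, 0)
  expect_equal(res$effect_sign, 0L)
})

test_that("LRS is invariant to joint strain permutation and affine trait maps", {
  set.seed(7)
  y <- rnorm(12)
  g <- rep(c("A", "B"), each = 6)
  base <- compute_lrs(y, g)
  perm <- sample(12)
  after <- compute_lrs(y[perm], g[perm])
  expect_equal(after$lrs, base$lrs)
  expect_equal(after$effect_sign, base$effect_sign)
  aff <- compute_lrs(2.5 * y - 7, g)
  expect_equal(aff$lrs, base$lrs)
})

test_that("small groups and missing data are handled pairwise", {
  res <- compute_lrs(c(1, 2, 3, NA, 5), c("A", "A", "B", "B", NA))
  expect_true(res$skipped)
  expect_match(res$reason, "B-allele")
  ok <- compute_lrs(c(1, 2, NA, 3, 4, 5, 6), c("A", "A", "A", "A", "B", NA, "B"))
  expect_false(ok$skipped)
  expect_equal(ok$n_used, 5)
})

test_that("genome_scan peaks at the causal marker and ignores uninformative markers", {
  g <- toy_geno()
  eff <- planted_effects("t1", "m3", beta = matrix(c(2, 2, 2, 2), 1),
                         gene_chr = "2", gene_pos_mb = 5)
  pl <- plant_traits(g, eff, sigma = 0.05, seed = 21)
  prof <- genome_scan(pl$traits$values$SC["t1", ], g)
  expect_equal(prof$marker[which.max(prof$lrs)], "m3")
  # dropping an uninformative marker does not change the rest of the profile
  codes <- g$codes
  codes[, "m4"] <- c("A", rep("B", 7))   # 1 A-carrier -> uninformative
  g2 <- geno_matrix("TOY", codes, g$markers)
  prof2 <- genome_scan(pl$traits$values$SC["t1", ], g2)
  expect_true(prof2$skipped[prof2$marker == "m4"])
  keep <- prof2$marker != "m4"
  expect_equal(prof2$lrs[keep], prof$lrs[prof$marker != "m4"])
})

test_that("chromosome_max_qtls returns one hit per usable chromosome, ties to the lower position", {
  prof <- data.frame(
    marker = c("a", "b", "c", "d"), chr = c("1", "1", "2", "2"),
    pos_mb = c(5, 10, 5, 10), lrs = c(7, 7, 3, 9),
    effect_sign = 1L, n_used = 8L, skipped = FALSE, reason = NA,
    stringsAsFactors = FALSE)
  hits <- chromosome_max_qtls(prof, trait_id = "t")
  expect_equal(nrow(hits), 2)
  expect_equal(hits$marker[hits$chr == "1"], "a")   # tie -> position 5
  expect_equal(hits$marker[hits$chr == "2"], "d")
  prof$skipped[prof$chr == "2"] <- TRUE
  expect_equal(nrow(chromosome_max_qtls(prof)), 1)
})

test_that("the batch scan agrees with the per-trait scan path", {
  st <- make_two_panel_study(small_cfg(seed = 31))
  tm <- st$traits$LXS$values$EC[1:5, , drop = FALSE]
  batch <- scan_condition(tm, st$geno$LXS)
  for (tr in rownames(tm)) {
    solo <- chromosome_max_qtls(genome_scan(tm[tr, ], st$geno$LXS), tr)
    got <- batch[batch$trait_id == tr, ]
    expect_equal(got$marker, solo$marker)
    expect_equal(got$lrs, solo$lrs, tolerance = 1e-9)
  }
})

test_that("genome-wide empirical p-values follow the permutation formula", {
  g <- toy_geno()
  flat <- stats::setNames(rep(1, 8), g$strains)
  expect_equal(genomewide_pvalue(flat, g, n_perm = 99, seed = 1)$p_value, 1)
  map <- simulate_marker_map(12, c("1" = 100, "2" = 100), seed = 4)
  big <- simulate_ri_genotypes(map, 30, rate = 0.02, seed = 5)
  causal <- map$marker[1]
  eff <- planted_effects("t1", causal, beta = matrix(rep(4, 4), 1),
                         gene_chr = map$chr[1], gene_pos_mb = map$pos_mb[1])
  pl <- plant_traits(big, eff, sigma = 0.3, seed = 2)
  strong <- genomewide_pvalue(pl$traits$values$SC["t1", ], big,
                              n_perm = 199, seed = 3)
  expect_equal(strong$p_value, 1 / 200)
  expect_equal(strong$best_marker, causal)
})
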