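# Synthetic-data generator: genotype chain, planted effects, two-panel study.

test_that("transition probability follows the two-state chain formula", {
  expect_equal(ri_transition_prob(0, 0.02), 0)          # complete linkage
  expect_equal(ri_transition_prob(10, 0.02), (1 - exp(-0.4)) / 2)
  expect_equal(ri_transition_prob(1e6, 0.02), 0.5)      # cap at free recomb.
})

test_that("simulated adjacent-marker discordance matches the formula", {
  map <- marker_map(c("a", "b"), c("1", "1"), c(0, 10))
  g <- simulate_ri_genotypes(map, 40000, rate = 0.02, seed = 11)
  phat <- mean(g$codes[, "a"] != g$codes[, "b"])
  p <- ri_transition_prob(10, 0.02)    # 0.16484...
  expect_lt(abs(phat - p), 3 * sqrt(p * (1 - p) / 40000))
})

test_that("marginal allele frequency is 1/2 at every marker", {
  map <- simulate_marker_map(40, c("1" = 100, "2" = 100), seed = 3)
  g <- simulate_ri_genotypes(map, 2000, rate = 0.02, seed = 4)
  freq <- colMeans(g$codes == "B")
  se <- sqrt(0.25 / 2000)
  expect_true(all(abs(freq - 0.5) < 4 * se))
})

test_that("breakpoint counts grow linearly with the breakpoint rate", {
  map <- simulate_marker_map(60, c("1" = 150), seed = 5)
  d <- diff(map$pos_mb)
  for (rate in c(0.01, 0.02, 0.04)) {
    g <- simulate_ri_genotypes(map, 500, rate = rate, seed = 6)
    bp <- mean(rowSums(g$codes[, -1] != g$codes[, -ncol(g$codes)]))
    expected <- sum(ri_transition_prob(d, rate))
    expect_lt(abs(bp - expected) / expected, 0.1)
  }
})

test_that("the generator is bit-identical under a fixed seed", {
  s1 <- make_two_panel_study(small_cfg(seed = 42))
  s2 <- make_two_panel_study(small_cfg(seed = 42))
  expect_identical(s1$geno$LXS$codes, s2$geno$LXS$codes)
  expect_identical(s1$traits$BXD$values, s2$traits$BXD$values)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$snps, s2$snps)
})

test_that("noise-free planted effects shift exactly the carrier group in the intended condition", {
  g <- toy_geno()
  eff <- planted_effects("t1", "m1", beta = matrix(c(0, 1, 0, 0), 1),
                         gene_chr = "1", gene_pos_mb = 10)
  pl <- plant_traits(g, eff, sigma = 0, seed = 9)
  carriers <- g$codes[, "m1"] == "B"
  for (cond in default_conditions()) {
    vals <- pl$traits$values[[cond]]["t1", ]
    gap <- mean(vals[carriers]) - mean(vals[!carriers])
    expect_equal(gap, if (cond == "EC") 1 else 0)
  }
  # effect-sign recovery at the causal marker in the active condition
  res <- compute_lrs(pl$traits$values$EC["t1", ], g$codes[, "m1"])
  expect_equal(res$effect_sign, 1L)
  expect_true(res$capped)   # perfect fit reported at the cap
})

test_that("planting rejects unknown causal markers", {
  eff <- planted_effects("t1", "nope", beta = matrix(1, 1, 4))
  expect_error(plant_traits(toy_geno(), eff, sigma = 1), "unknown causal marker")
})

test_that("intended_pattern bits are set exactly where effects are nonzero", {
  st <- make_two_panel_study(small_cfg(seed = 8))
  tr <- st$truth[st$truth$class %in% c("cis", "syntenic_trans",
                                       "nonsyntenic_trans") &
                   !is.na(st$truth$causal_marker), ]
  beta <- as.matrix(tr[, paste0("beta_", default_conditions())])
  expect_equal(tr$intended_pattern,
               unname(apply(beta != 0, 1,
                            function(b) paste(as.integer(b), collapse = ""))))
  expect_true(all(rowSums(beta != 0) >= 1))
})

test_that("sharing 1 plants every effect in both panels with equal betas; sharing 0 shares none", {
  st1 <- make_two_panel_study(small_cfg(seed = 10, sharing_fn = 1))
  planted <- st1$truth[st1$truth$class != "null" &
                         st1$truth$kind == "expression", ]
  expect_true(all(planted$shared))
  wide <- split(planted, planted$trait_id)
  for (tr in wide) {
    expect_equal(nrow(tr), 2)
    expect_false(any(is.na(tr$causal_marker)))
    expect_equal(tr[1, paste0("beta_", default_conditions())],
                 tr[2, paste0("beta_", default_conditions())],
                 ignore_attr = TRUE)
  }
  expect_true(all(st1$snps$conserved))
  st0 <- make_two_panel_study(small_cfg(seed = 10, sharing_fn = 0))
  planted0 <- st0$truth[st0$truth$class != "null" &
                          st0$truth$kind == "expression", ]
  expect_false(any(planted0$shared))
  # a private effect leaves the trait null in the other panel
  per_trait <- tapply(!is.na(planted0$causal_marker), planted0$trait_id, sum)
  expect_true(all(per_trait == 1))
  expect_false(any(st0$snps$conserved))
})

test_that("unequal treatment-group sizes stay subsets of the panel strains", {
  st <- make_two_panel_study(small_cfg(seed = 12, unequal_groups = TRUE))
  for (p in names(st$traits)) {
    for (cond in default_conditions()) {
      ss <- colnames(st$traits[[p]]$values[[cond]])
      expect_true(all(ss %in% st$geno[[p]]$strains))
    }
  }
})
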