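# Activity patterns, pattern enumeration, nearest-marker matching and
# cross-population conservation.

test_that("enumerate_patterns lists every non-null significance vector", {
  p4 <- enumerate_patterns(4)
  expect_equal(nrow(p4), 15)
  expect_equal(names(p4)[2:5], default_conditions())
  expect_equal(nrow(enumerate_patterns(1)), 1)
  expect_equal(nrow(enumerate_patterns(3)), 7)
  expect_error(enumerate_patterns(0))
  # bits <-> index is a bijection
  bits <- as.matrix(p4[, 2:5])
  recomputed <- apply(bits, 1, function(b)
    sum(as.integer(b) * 2^(3:0)))
  expect_equal(recomputed, p4$pattern_index)
  expect_equal(anyDuplicated(recomputed), 0)
})

test_that("activity patterns threshold LRS vectors with strict inequality", {
  ap <- make_activity_pattern(c(SC = 30, EC = 25, SR = 10, ER = 5),
                              threshold = 24)
  expect_equal(unname(ap$bits), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(ap$pattern_index, 12L)
  expect_false(ap$null)
  at <- make_activity_pattern(c(SC = 24, EC = 0, SR = 0, ER = 0),
                              threshold = 24)
  expect_true(at$null)               # exactly at the threshold is not sig.
  expect_true(is.na(at$pattern_index))
  none <- make_activity_pattern(c(SC = 0, EC = 0, SR = 0, ER = 0), 24)
  expect_true(none$null)
  expect_match(none$reason, "no condition")
})

test_that("per-condition LRS vectors reflect the planted activity pattern", {
  g <- toy_geno()
  eff <- planted_effects("t1", "m2", beta = matrix(c(0, 2, 0, 0), 1),
                         gene_chr = "1", gene_pos_mb = 20)
  pl <- plant_traits(g, eff, sigma = 0, seed = 71)
  v <- lrs_across_conditions("t1", "m2", pl$traits, g)
  expect_equal(unname(v[c("SC", "SR", "ER")]), c(0, 0, 0))
  expect_gt(v[["EC"]], 0)
  # invariant to condition-wise strain reordering
  shuffled <- pl$traits
  shuffled$values$EC <- shuffled$values$EC[, sample(colnames(shuffled$values$EC)),
                                           drop = FALSE]
  expect_equal(lrs_across_conditions("t1", "m2", shuffled, g), v)
  expect_error(lrs_across_conditions("t1", "zz", pl$traits, g), "unknown marker")
  expect_error(lrs_across_conditions("zz", "m2", pl$traits, g), "unknown trait")
})

test_that("nearest_marker minimizes distance with ties to the lower position", {
  map <- marker_map(c("a", "b", "c"), c("1", "1", "2"), c(10, 20, 5))
  expect_equal(nearest_marker("1", 14, map), "a")
  expect_equal(nearest_marker("1", 15, map), "a")   # tie -> lower position
  expect_equal(nearest_marker("1", 16, map), "b")
  expect_error(nearest_marker("3", 5, map), "no marker on chromosome")
})

test_that("shared noise-free effects are conserved with identical patterns across panels", {
  cfg <- small_cfg(seed = 72, sharing_fn = 1, sigma = 0.05, effect_size = 4)
  st <- make_two_panel_study(cfg)
  th <- c(LXS = 18, BXD = 18)
  hits <- scan_condition(st$traits$LXS$values$EC, st$geno$LXS)
  truth <- st$truth[st$truth$panel == "LXS" & st$truth$class != "null" &
                      st$truth$kind == "expression" & st$truth$beta_EC != 0, ]
  mi <- match(hits$trait_id, truth$trait_id)
  keep <- !is.na(mi) & hits$marker == truth$causal_marker[mi]
  keep[is.na(keep)] <- FALSE
  hits <- hits[keep, ]
  expect_gt(nrow(hits), 0)
  hits <- activity_patterns(hits, st$traits$LXS, st$geno$LXS, th[["LXS"]])
  rec <- cross_panel_records(hits, st$geno$LXS, st$geno$BXD, st$traits$BXD,
                             th[["BXD"]])
  expect_true(all(rec$conserved_any))
  expect_true(mean(rec$pattern_identical) > 0.9)
})

test_that("conservation is threshold-monotone and identical-mode matches on shared maps", {
  g <- toy_geno()
  eff <- planted_effects("t1", "m2", beta = matrix(c(2, 2, 0, 0), 1),
                         gene_chr = "1", gene_pos_mb = 20)
  pl <- plant_traits(g, eff, sigma = 0.1, seed = 73)
  other <- pl$traits
  rec_lo <- cross_population_conservation("t1", "m2", c(TRUE, TRUE, FALSE, FALSE),
                                          g, g, other, other_threshold = 5)
  rec_hi <- cross_population_conservation("t1", "m2", c(TRUE, TRUE, FALSE, FALSE),
                                          g, g, other, other_threshold = 500)
  expect_true(rec_lo$conserved_any)
  expect_false(rec_hi$conserved_any)   # raising the threshold cannot conserve
  rec_id <- cross_population_conservation("t1", "m2", c(TRUE, TRUE, FALSE, FALSE),
                                          g, g, other, other_threshold = 5,
                                          mode = "identical")
  expect_equal(rec_id$other_lrs, rec_lo$other_lrs)
  expect_equal(rec_id$matched_marker, rec_lo$matched_marker)
  miss <- cross_population_conservation("nope", "m2", rep(TRUE, 4),
                                        g, g, other, 5)
  expect_true(miss$skipped)
  expect_true(is.na(miss$conserved_any))
})

test_that("pattern summaries are normalized histograms with headline fractions", {
  hits <- data.frame(
    eqtl_class = c(rep("cis", 4), rep("nonsyntenic_trans", 4)),
    pattern_index = c(15L, 15L, 15L, 12L, 4L, 2L, 8L, 15L))
  s <- summarize_patterns(hits)
  expect_equal(unname(rowSums(s$histogram)), c(1, 1))
  cisrow <- s$summary[s$summary$eqtl_class == "cis", ]
  expect_equal(cisrow$frac_all_conditions, 0.75)
  expect_equal(cisrow$frac_treatment_specific, 0)
  trans <- s$summary[s$summary$eqtl_class == "nonsyntenic_trans", ]
  expect_equal(trans$frac_treatment_specific, 0.75)
  s2 <- summarize_patterns(hits, classes = c("cis", "nonsyntenic_trans",
                                             "syntenic_trans"))
  expect_equal(s2$empty_classes, "syntenic_trans")
  expect_equal(unname(rowSums(s2$histogram)["syntenic_trans"]), 0)
})
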