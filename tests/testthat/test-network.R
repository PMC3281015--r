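# Region LRS vectors, candidate selection and pattern-correlation networks.

two_panel_fixture <- function(seed = 91, sigma = 0.05, effect = 4) {
  make_two_panel_study(small_cfg(seed = seed, sigma = sigma,
                                 effect_size = effect))
}

test_that("a single-marker region reproduces the per-condition LRS vector", {
  st <- two_panel_fixture()
  pan <- list(LXS = list(geno = st$geno$LXS, traits = st$traits$LXS),
              BXD = list(geno = st$geno$BXD, traits = st$traits$BXD))
  mk <- st$geno$LXS$markers[5, ]
  reg <- region_spec(mk$chr, mk$pos_mb - 1e-6, mk$pos_mb + 1e-6,
                     focal_panel = "LXS")
  # region contains exactly this LXS marker
  expect_equal(markers_in_region <- qtlactivity:::markers_in_region(reg, st$geno$LXS$markers),
               mk$marker)
  tr <- rownames(st$traits$LXS$values$SC)[1]
  v <- region_lrs_vector(tr, reg, pan)
  direct <- lrs_across_conditions(tr, mk$marker, st$traits$LXS, st$geno$LXS)
  expect_equal(unname(v[paste0("LXS_", default_conditions())]),
               unname(direct))
})

test_that("widening a region never decreases any vector entry", {
  st <- two_panel_fixture()
  pan <- list(LXS = list(geno = st$geno$LXS, traits = st$traits$LXS),
              BXD = list(geno = st$geno$BXD, traits = st$traits$BXD))
  tr <- rownames(st$traits$LXS$values$SC)[3]
  narrow <- region_spec("1", 20, 40, "LXS")
  wide <- region_spec("1", 5, 70, "LXS")
  vn <- region_lrs_vector(tr, narrow, pan)
  vw <- region_lrs_vector(tr, wide, pan)
  keep <- !is.na(vn) & !is.na(vw)
  expect_true(all(vw[keep] >= vn[keep] - 1e-12))
})

test_that("candidate selection applies the three pattern criteria exactly", {
  hits <- data.frame(
    trait_id = c("keep", "sigSC", "notEC", "conserved", "faraway"),
    chr = c("1", "1", "1", "1", "2"),
    pos_mb = c(10, 12, 14, 16, 10),
    bit_SC = c(FALSE, TRUE, FALSE, FALSE, FALSE),
    bit_EC = c(TRUE, TRUE, FALSE, TRUE, TRUE),
    conserved_any = c(FALSE, FALSE, FALSE, TRUE, FALSE),
    stringsAsFactors = FALSE)
  reg <- region_spec("1", 0, 20, "LXS")
  expect_equal(select_candidates(hits, reg), "keep")
  # invariant to input row order
  expect_equal(select_candidates(hits[sample(nrow(hits)), ], reg), "keep")
  empty <- region_spec("3", 0, 20, "LXS")
  expect_equal(select_candidates(hits, empty), character(0))
})

test_that("network thresholds at 0.7 (inclusion) and 0.8 (edges) act as specified", {
  pheno <- c(LXS_SC = 2, LXS_EC = 35, LXS_SR = 4, LXS_ER = 6,
             BXD_SC = 1, BXD_EC = 3, BXD_SR = 2, BXD_ER = 5)
  # transcript at a chosen exact correlation with the phenotype vector
  at_r <- function(r, seed) {
    set.seed(seed)
    z <- rnorm(8)
    zp <- resid(lm(z ~ pheno))                 # orthogonal to pheno
    p_std <- (pheno - mean(pheno)) / sd(pheno)
    v <- p_std + sqrt(1 / r^2 - 1) * zp / sd(zp)
    v <- v * 5 + 30                            # affine: keeps r, passes prefilter
    names(v) <- names(pheno)
    v
  }
  tmat <- rbind(twin = pheno,
                mid = at_r(0.75, 1),
                weak = at_r(0.3, 2),
                filtered = c(2, 15, 2, 2, 1, 1, 1, 1))
  colnames(tmat) <- names(pheno)
  net <- build_pattern_network(pheno, tmat, focal_col = "LXS_EC")
  expect_setequal(net$nodes$node[net$nodes$type == "transcript"],
                  c("twin", "mid"))
  pe <- net$edges[net$edges$edge_type == "phenotype-transcript", ]
  expect_true("twin" %in% pe$to | "twin" %in% pe$from)   # r = 1 edge
  expect_false("mid" %in% c(pe$from, pe$to))             # 0.7 < r <= 0.8: node only
  # failing the LRS > 20 prefilter excludes regardless of correlation
  expect_false("filtered" %in% net$nodes$node)
  expect_false("weak" %in% net$nodes$node)
})

test_that("edge sets shrink monotonically as the edge threshold rises", {
  set.seed(93)
  pheno <- c(LXS_SC = 1, LXS_EC = 30, LXS_SR = 2, LXS_ER = 3,
             BXD_SC = 2, BXD_EC = 4, BXD_SR = 1, BXD_ER = 2)
  tmat <- t(replicate(6, pheno + rnorm(8, sd = 4)))
  tmat[tmat < 21] <- 22   # everyone passes the prefilter
  rownames(tmat) <- paste0("t", 1:6)
  colnames(tmat) <- names(pheno)
  lo <- build_pattern_network(pheno, tmat, "LXS_EC", edge_r = 0.7)
  hi <- build_pattern_network(pheno, tmat, "LXS_EC", edge_r = 0.9)
  key <- function(e) paste(pmin(e$from, e$to), pmax(e$from, e$to))
  expect_true(all(key(hi$edges) %in% key(lo$edges)))
  expect_error(build_pattern_network(rep(1, 8), tmat, "LXS_EC"), "constant")
})
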