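test_that("fit_model reproduces a hand-computed LOD", {
  # n=4, y=(0,0,1,2), single-marker backcross genotype (1,1,2,2):
  # RSS0 = 2.75, RSS1 = 0.5, LOD = 2*log10(2.75/0.5)
  m <- make_map(list("1" = c(0)))
  cr <- make_cross(m, cross_design("bc", sexes = "female"),
                   list("1" = matrix(c(1L, 1L, 2L, 2L), 4L)),
                   pheno = c(0, 0, 1, 2))
  prep <- scan_prep(cr)
  f <- fit_model(prep, qtl_model("1", 0))
  expect_equal(f$rss_null, 2.75, tolerance = 1e-12)
  expect_equal(f$rss_model, 0.5, tolerance = 1e-12)
  expect_equal(f$lod, 2 * log10(2.75 / 0.5), tolerance = 1e-12)
  expect_equal(f$lod, 1.4807, tolerance = 1e-4)
  # empty model has LOD exactly 0
  expect_equal(fit_model(prep, qtl_model())$lod, 0)
})

test_that("scanone and scantwo equal brute-force regression on a toy genome", {
  set.seed(31)
  cr <- toy_cross(70)
  prep <- scan_prep(cr)
  s1 <- scanone(prep)
  bf1 <- bf_scanone_bc(cr, cr$pheno)
  expect_equal(s1$lod, bf1$lod, tolerance = 1e-10)

  s2 <- scantwo(prep)
  bf2 <- bf_scantwo_bc(cr, cr$pheno)
  # same pair order (both enumerate grid pairs i<j); A:A and X:X pairs have
  # identical models; the mixed pairs add stratified epistasis columns to
  # the full model, so compare those against an explicitly augmented fit
  same <- s2$region != "AX"
  expect_equal(s2$lod_add, bf2$lod_add, tolerance = 1e-10)
  expect_equal(s2$lod_full[same], bf2$lod_full[same], tolerance = 1e-10)
  ax <- which(!same)
  X0 <- cbind(1, cr$sex)
  rss0 <- bf_rss(X0, cr$pheno)
  for (k in ax) {
    ia <- which(prep$grid$chr == s2$chr1[k] & prep$grid$pos == s2$pos1[k])
    ix <- which(prep$grid$chr == s2$chr2[k] & prep$grid$pos == s2$pos2[k])
    Ca <- prep$cols[[ia]]; Cx <- prep$cols[[ix]]
    prods <- qtlx:::interaction_columns(Ca, Cx)
    extra <- qtlx:::interaction_columns(if (prep$grid$is_X[ia]) Cx else Ca,
                                        cbind(cr$sex))
    lf <- n_ind(cr) / 2 *
      log10(rss0 / bf_rss(cbind(X0, Ca, Cx, prods, extra), cr$pheno))
    expect_equal(s2$lod_full[k], lf, tolerance = 1e-10)
  }
})

test_that("nestedness holds on every pair", {
  set.seed(32)
  cr <- toy_cross(60)
  prep <- scan_prep(cr)
  s1 <- scanone(prep)
  s2 <- scantwo(prep)
  expect_true(all(s2$lod_full >= s2$lod_add - 1e-9))
  for (k in seq_len(nrow(s2))) {
    m1 <- max(s1$lod[s1$chr == s2$chr1[k] & s1$pos == s2$pos1[k]],
              s1$lod[s1$chr == s2$chr2[k] & s1$pos == s2$pos2[k]])
    expect_gte(s2$lod_add[k], m1 - 1e-9)
  }
})

test_that("LOD surfaces are invariant under affine phenotype transforms", {
  set.seed(33)
  cr <- toy_cross(50)
  prep <- scan_prep(cr)
  s1a <- scanone(prep, cr$pheno)
  s1b <- scanone(prep, -3.2 * cr$pheno + 17)
  expect_equal(s1a$lod, s1b$lod, tolerance = 1e-8)
  s2a <- scantwo(prep, cr$pheno)
  s2b <- scantwo(prep, 0.01 * cr$pheno - 5)
  expect_equal(s2a$lod_full, s2b$lod_full, tolerance = 1e-8)
  expect_equal(s2a$lod_int, s2b$lod_int, tolerance = 1e-8)
})

test_that("scanone with a context model adds no span at the context QTL", {
  set.seed(34)
  cr <- toy_cross(80)
  ctx <- qtl_model("1", 10)
  prep <- scan_prep(cr)
  s1 <- scanone(prep, context = ctx)
  expect_lt(s1$lod[s1$chr == "1" & s1$pos == 10], 1e-9)
})

test_that("a strong simulated QTL is localized at its marker", {
  set.seed(35)
  m <- mouse_map(10)
  cr <- sim_cross(200, m, cross_design("bc"))
  g <- cr$geno[["5"]][, 3]  # marker 5@20
  cr$pheno <- (g - 1) + rnorm(200, sd = 0.05)
  prep <- scan_prep(cr)
  s1 <- scanone(prep)
  top <- s1[which.max(s1$lod), ]
  expect_equal(top$chr, "5")
  expect_equal(top$pos, 20)
})

test_that("pair counts follow the region combinatorics", {
  g <- grid_positions(mouse_map(10))
  nA <- sum(!g$is_X); nX <- sum(g$is_X)
  pt <- qtlx:::pair_table(g)
  expect_equal(sum(pt$region == "AA"),
               choose(nA, 2) - sum(table(g$chr[!g$is_X]) * 0))
  expect_equal(sum(pt$region == "AX"), nA * nX)
  expect_equal(sum(pt$region == "XX"), choose(nX, 2))
  expect_equal(nrow(pt), choose(nA + nX, 2))
})

test_that("region_max partitions and bounds correctly", {
  set.seed(36)
  cr <- toy_cross(40)
  prep <- scan_prep(cr)
  s1 <- scanone(prep)
  expect_equal(max(region_max(s1, "A"), region_max(s1, "X")),
               region_max(s1, "all"))
  s2 <- scantwo(prep)
  expect_lte(region_max(s2, "AA", "int"), region_max(s2, "all", "int"))
  # brute-force check of the region maximum on the toy
  bf2 <- bf_scantwo_bc(cr, cr$pheno)
  both_auto <- bf2$chr1 != "X" & bf2$chr2 != "X"
  expect_equal(region_max(s2, "AA", "full"),
               max(bf2$lod_full[both_auto]), tolerance = 1e-10)
  expect_error(region_max(s1, "Z"), "region")
})
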