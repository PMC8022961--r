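test_that("alpha apportionment satisfies the multiplicative closure exactly", {
  m <- mouse_map(10)
  al <- apportion_alpha(0.05, m)
  expect_lt(abs((1 - al$alpha_A) * (1 - al$alpha_X) - 0.95), 1e-12)
  expect_lt(abs((1 - al$alpha_AA) * (1 - al$alpha_AX) * (1 - al$alpha_XX) -
                  0.95), 1e-12)
  expect_identical(al$S_AA + al$S_AX + al$S_XX, al$L^2 / 2)
  expect_equal(al$alpha_A, 0.04736, tolerance = 1e-4)
  expect_equal(al$alpha_X, 0.002769, tolerance = 1e-4)
  expect_equal(al$alpha_AA, 0.04486, tolerance = 1e-4)
  expect_equal(al$alpha_AX, 0.005232, tolerance = 1e-4)
  expect_equal(al$alpha_XX, 1.4986e-4, tolerance = 1e-4)
  expect_equal(c(al$S_AA, al$S_AX, al$S_XX), c(980000, 112000, 3200))
  # closure holds for arbitrary alpha and maps
  for (a in c(0.01, 0.2, 0.63)) {
    al2 <- apportion_alpha(a, make_map(list("1" = c(0, 37), X = c(0, 81)),
                                       x_chr = "X"))
    expect_lt(abs((1 - al2$alpha_A) * (1 - al2$alpha_X) - (1 - a)), 1e-12)
    expect_lt(abs((1 - al2$alpha_AA) * (1 - al2$alpha_AX) *
                    (1 - al2$alpha_XX) - (1 - a)), 1e-12)
  }
  # no X chromosome: X alphas undefined
  al0 <- apportion_alpha(0.05, make_map(list("1" = c(0, 100))))
  expect_true(is.na(al0$alpha_X))
  expect_equal(al0$alpha_A, 0.05)
})

test_that("replicate allocation follows the area ratios", {
  al <- apportion_alpha(0.05, mouse_map(10))
  reps <- allocate_replicates(1056, al)
  expect_equal(unname(reps["AA"]), 1056L)
  # S_AA/S_AX = L_A/(2 L_X) = 8.75; S_AA/S_XX = (L_A/L_X)^2 = 306.25
  expect_equal(unname(reps["AX"]), round(1056 * 8.75))
  expect_equal(unname(reps["XX"]), round(1056 * 306.25))
  # symmetric map: L_A = L_X makes reps_AX = base/2
  sym <- apportion_alpha(0.05, make_map(list("1" = c(0, 80), X = c(0, 80)),
                                        x_chr = "X"))
  expect_equal(unname(allocate_replicates(100, sym)["AX"]), 50L)
})

test_that("the tail quantile matches a sorting oracle and flags thin tails", {
  set.seed(40)
  x <- rnorm(400)
  for (p in c(0.5, 0.9, 0.95)) {
    # type-7: interpolate order statistics at 1 + (n-1)p
    h <- 1 + (length(x) - 1) * p
    s <- sort(x)
    oracle <- s[floor(h)] + (h - floor(h)) * (s[floor(h) + 1] - s[floor(h)])
    expect_equal(qtlx:::tail_quantile(x, p), oracle, tolerance = 1e-12)
  }
  expect_equal(suppressWarnings(qtlx:::tail_quantile(rep(3, 50), 0.999)), 3)
  expect_warning(qtlx:::tail_quantile(x, 0.999), "exceedances")
})

test_that("penalty estimation produces a coherent penalty set", {
  ps <- suppressWarnings(
    estimate_penalties(mouse_map(10), base_reps = 48, seed = 3,
                       phenos_per_geno = c(scan1 = 8, scan1X = 40, AA = 12,
                                           AX = 40, XX = 400)))
  expect_s3_class(ps$XneA, "qtlx_penalties")
  expect_s3_class(ps$XeqA, "qtlx_penalties")
  for (f in c("T_mA", "T_mX", "T_iAAH", "T_iAAL", "T_iAX", "T_iXX"))
    expect_gt(ps$XneA[[f]], 0)
  # X main threshold above the autosomal one in this backcross design
  # (more stringent alpha_X and a 2-df test)
  expect_gt(ps$XneA$T_mX, ps$XneA$T_mA)
  # the far-tail A:X penalty exceeds the A:A heavy penalty, and the light
  # A:A penalty sits below the heavy one
  expect_gt(ps$XneA$T_iAX, ps$XneA$T_iAAH)
  expect_lt(ps$XneA$T_iAAL, ps$XneA$T_iAAH)
  expect_equal(unname(ps$reps["scan1"]), 48L)
})

test_that("permutation mode reuses the observed cross", {
  set.seed(41)
  m <- make_map(list("1" = seq(0, 40, 10), "2" = seq(0, 40, 10),
                     X = seq(0, 20, 10)), x_chr = "X")
  cr <- sim_cross(80, m, cross_design("bc"))
  cr <- sim_phenotype(cr)
  ps <- suppressWarnings(
    estimate_penalties(mode = "permute", cross = cr, pheno = cr$pheno,
                       base_reps = 24, seed = 5, phenos_per_geno = 24))
  expect_s3_class(ps$XneA, "qtlx_penalties")
  expect_true(all(unlist(ps$XneA[c("T_mA", "T_mX", "T_iAAH")]) > 0))
})
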