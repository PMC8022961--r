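toy_pen <- function() penalties("XneA", T_mA = 1.5, T_mX = 1.9, T_iAAH = 2.2,
                                T_iAAL = 1.0, T_iAX = 2.8, T_iXX = 2.6,
                                alpha = 0.05)

test_that("forward selection from the null model is a plain scanone", {
  set.seed(50)
  cr <- toy_cross(80)
  prep <- scan_prep(cr)
  y <- cr$pheno
  st <- forward_step(prep, y, qtl_model(), toy_pen())
  s1 <- scanone(prep, y)
  b <- which.max(s1$lod)
  expect_equal(n_qtl(st$model), 1L)
  expect_equal(st$model$chr, s1$chr[b])
  expect_equal(st$model$pos, s1$pos[b])
  expect_equal(st$lod, s1$lod[b], tolerance = 1e-9)
})

test_that("backward elimination drops a spurious QTL first", {
  set.seed(51)
  m <- mouse_map(10)
  cr <- sim_cross(200, m, cross_design("bc"))
  cr <- sim_phenotype(cr, data.frame(chr = "1", pos = 50, pve = 0.3))
  prep <- scan_prep(cr)
  # a real QTL at 1@50 plus a spurious one on chromosome 12
  model <- qtl_model(c("1", "12"), c(50, 30))
  st <- backward_step(prep, cr$pheno, model, toy_pen())
  expect_equal(st$model$chr, "1")
  expect_equal(st$model$pos, 50)
  # and from a 1-QTL model the only candidate is the null model
  st2 <- backward_step(prep, cr$pheno, st$model, toy_pen())
  expect_equal(n_qtl(st2$model), 0L)
})

test_that("refinement moves an offset QTL to the true locus, never losing LOD", {
  set.seed(52)
  m <- mouse_map(10)
  cr <- sim_cross(300, m, cross_design("bc"))
  g <- cr$geno[["3"]][, 5]  # marker 3@40
  cr$pheno <- 1.5 * (g - 1) + rnorm(300, sd = 0.7)
  prep <- scan_prep(cr)
  before <- qtl_model("3", 70)
  lod_before <- qtlx:::.model_lod(prep, cr$pheno, before)
  refined <- refine_positions(prep, cr$pheno, before)
  lod_after <- qtlx:::.model_lod(prep, cr$pheno, refined)
  expect_equal(refined$pos, 40)
  expect_gte(lod_after, lod_before)
  # an already-optimal model is a fixed point
  expect_equal(refine_positions(prep, cr$pheno, refined), refined)
})

test_that("the search returns the best-pLOD model over the whole trace", {
  set.seed(53)
  cr <- sim_scenario("1-auto", n = 200)
  fit <- stepwise_qtl(cr, toy_pen(), max_qtl = 4)
  expect_equal(max(fit$trace$plod), fit$plod)
  # trace: start + 4 forward + backward steps down to the null model
  expect_equal(sum(fit$trace$dir == "forward"), 4L)
  expect_equal(fit$trace$n_qtl[nrow(fit$trace)], 0L)
  expect_gte(n_qtl(fit$model), 1L)
  # the known strong QTL is in the model within 20 cM
  hit <- fit$model$chr == "1" & abs(fit$model$pos - 50) <= 20
  expect_true(any(hit))
})

test_that("stepwise matches the exhaustive search on toy genomes", {
  set.seed(54)
  hits <- 0L
  for (rep in 1:40) {
    cr <- toy_cross(60)
    prep <- scan_prep(cr)
    fit <- stepwise_qtl(cr, toy_pen(), max_qtl = 2, refine = FALSE)
    best <- bf_best_model(prep, cr$pheno, toy_pen())
    if (abs(fit$plod - best$plod) < 1e-6) hits <- hits + 1L
  }
  expect_gte(hits, 36L)  # stepwise is a heuristic; allow rare misses
})

test_that("fit methods expose coefficients, residuals and simulation", {
  set.seed(55)
  cr <- sim_scenario("1-auto", n = 150)
  fit <- stepwise_qtl(cr, toy_pen(), max_qtl = 3)
  expect_equal(length(fitted(fit)) + 0L, 150L)
  expect_equal(fitted(fit) + residuals(fit), cr$pheno, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_true(all(is.finite(coef(fit))))
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(150L, 3L))
  out <- capture.output(print(fit))
  expect_true(any(grepl("pLOD", out)))
})
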