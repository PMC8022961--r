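grid20 <- grid_positions(mouse_map(10))

test_that("model construction enforces hierarchy and uniqueness", {
  expect_error(qtl_model("1", 50, matrix(c(1L, 2L), 1L)), "hierarchy")
  expect_error(qtl_model(c("1", "1"), c(50, 50)), "duplicate")
  expect_error(qtl_model(c("1", "2"), c(50, 50), matrix(c(1L, 1L), 1L)),
               "self")
  m <- qtl_model(c("1", "X"), c(50, 40), matrix(c(2L, 1L), 1L))
  expect_equal(n_qtl(m), 2L)
  expect_equal(m$edges, matrix(c(1L, 2L), 1L))  # edges stored sorted
  expect_equal(qtlx:::edge_regions(m, grid20), "AX")
})

xnea <- penalties("XneA", T_mA = 2.88, T_mX = 3.61, T_iAAH = 4.34,
                  T_iAAL = 1.83, T_iAX = 5.74, T_iXX = 5.15, alpha = 0.05)
xeqa <- penalties("XeqA", T_m = 2.98, T_iH = 4.83, T_iL = 2.28, alpha = 0.05)

test_that("interaction penalties follow the light/heavy component rule", {
  # no edges
  expect_equal(interaction_penalty(qtl_model("1", 50), xnea, grid20), 0)
  # one component with an A:A and an A:X edge: one light allowed for the
  # A:A edge only: 4.34 + 5.74 - (4.34 - 1.83) = 7.57
  m <- qtl_model(c("1", "2", "X"), c(50, 50, 40),
                 rbind(c(1L, 2L), c(2L, 3L)))
  expect_equal(interaction_penalty(m, xnea, grid20), 7.57, tolerance = 1e-12)
  # a single X:X edge gets the heavy penalty, no light allowed
  mx <- qtl_model(c("X", "X"), c(10, 60), matrix(c(1L, 2L), 1L))
  expect_equal(interaction_penalty(mx, xnea, grid20), 5.15, tolerance = 1e-12)
  # XeqA: one light per connected component regardless of region
  expect_equal(interaction_penalty(m, xeqa, grid20),
               2 * 4.83 - (4.83 - 2.28), tolerance = 1e-12)
  expect_equal(interaction_penalty(mx, xeqa, grid20), 2.28, tolerance = 1e-12)
  # two components: each gets its own light discount
  m2 <- qtl_model(c("1", "2", "3", "4"), c(50, 50, 40, 40),
                  rbind(c(1L, 2L), c(3L, 4L)))
  expect_equal(interaction_penalty(m2, xnea, grid20), 2 * 1.83,
               tolerance = 1e-12)
})

test_that("interaction penalty is additive over components and order-invariant", {
  m_a <- qtl_model(c("1", "2", "3", "X"), c(50, 50, 40, 40),
                   rbind(c(1L, 2L), c(3L, 4L)))
  m_b <- qtl_model(c("3", "X", "1", "2"), c(40, 40, 50, 50),
                   rbind(c(4L, 3L), c(1L, 2L)))
  expect_equal(interaction_penalty(m_a, xnea, grid20),
               interaction_penalty(m_b, xnea, grid20))
  # equals the sum of the isolated-component penalties
  c1 <- qtl_model(c("1", "2"), c(50, 50), matrix(c(1L, 2L), 1L))
  c2 <- qtl_model(c("3", "X"), c(40, 40), matrix(c(1L, 2L), 1L))
  expect_equal(interaction_penalty(m_a, xnea, grid20),
               interaction_penalty(c1, xnea, grid20) +
                 interaction_penalty(c2, xnea, grid20))
})

test_that("penalized LOD applies region-specific main penalties", {
  expect_equal(plod(0, qtl_model(), xnea, grid20), 0)
  # 2 autosomal + 1 X additive QTL: 12 - 2*2.88 - 3.61 = 2.63
  m <- qtl_model(c("1", "2", "X"), c(50, 50, 40))
  expect_equal(plod(12, m, xnea, grid20), 2.63, tolerance = 1e-12)
  # XeqA at the threshold: LOD = T_m gives pLOD exactly 0
  expect_equal(plod(2.98, qtl_model("1", 50), xeqa, grid20), 0,
               tolerance = 1e-12)
  # XneA without X penalties cannot price an X QTL
  incomplete <- penalties("XneA", T_mA = 2.88, T_iAAH = 4.34, T_iAAL = 1.83)
  expect_error(plod(5, qtl_model("X", 40), incomplete, grid20), "X")
})

test_that("penalty constructors validate their inputs", {
  expect_error(penalties("XneA", T_mA = 2.88), "missing required")
  expect_error(penalties("XeqA", T_m = -1, T_iH = 2, T_iL = 1), "positive")
  expect_warning(penalties("XneA", T_mA = 2.88, T_iAAH = 2, T_iAAL = 3),
                 "light")
})
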