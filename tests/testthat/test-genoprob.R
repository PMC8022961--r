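test_that("complete error-free genotypes give 0/1 probabilities at markers", {
  set.seed(11)
  cr <- toy_cross(40)
  pr <- calc_genoprob(cr)
  for (ch in names(pr$chroms)) {
    a <- pr$chroms[[ch]]
    expect_true(all(a %in% c(0, 1)))
    # the unit state is the observed genotype
    expect_equal(a[cbind(rep(1:40, ncol(cr$geno[[ch]])),
                         rep(seq_len(ncol(cr$geno[[ch]])), each = 40),
                         as.vector(cr$geno[[ch]]))],
                 rep(1, 40 * ncol(cr$geno[[ch]])))
  }
})

test_that("probabilities are row-stochastic everywhere", {
  set.seed(12)
  m <- make_map(list("1" = c(0, 7, 20, 33), X = c(0, 15, 30)), x_chr = "X")
  cr <- sim_cross(30, m, cross_design("f2"), missing_prob = 0.3)
  pr <- calc_genoprob(cr, step = 5, error_prob = 0.01)
  for (a in pr$chroms) {
    sums <- apply(a, c(1, 2), sum)
    expect_lt(max(abs(sums - 1)), 1e-9)
  }
})

test_that("HMM output equals brute-force hidden-state enumeration", {
  set.seed(13)
  pos <- c(0, 8, 19, 31, 45)
  # backcross autosome with missing data and genotyping error
  m <- make_map(list("1" = pos))
  cr <- sim_cross(12, m, cross_design("bc", sexes = "female"),
                  missing_prob = 0.4)
  ep <- 0.02
  pr <- calc_genoprob(cr, error_prob = ep)
  tr2 <- function(r) matrix(c(1 - r, r, r, 1 - r), 2, 2)
  for (i in 1:12) {
    post <- bf_genoprob_chr(cr$geno[["1"]][i, ], pos, 2L, ep,
                            c(0.5, 0.5), tr2)
    expect_lt(max(abs(pr$chroms[["1"]][i, , ] - post)), 1e-10)
  }
  # intercross autosome, 3 states
  f2 <- sim_cross(8, m, cross_design("f2", sexes = "female"),
                  missing_prob = 0.4)
  prf <- calc_genoprob(f2, error_prob = ep)
  tr3 <- function(r) {
    a <- 1 - r
    matrix(c(a^2, a * r, r^2, 2 * a * r, a^2 + r^2, 2 * a * r,
             r^2, a * r, a^2), 3, 3)
  }
  for (i in 1:8) {
    post <- bf_genoprob_chr(f2$geno[["1"]][i, ], pos, 3L, ep,
                            c(0.25, 0.5, 0.25), tr3)
    expect_lt(max(abs(prf$chroms[["1"]][i, , ] - post)), 1e-10)
  }
})

test_that("a single missing marker gets the three-point conditional", {
  # markers at 0/10/20; middle observation missing; flanks observed equal.
  m <- make_map(list("1" = c(0, 10, 20)))
  geno <- list("1" = matrix(c(1L, NA, 1L), 1L))
  cr <- make_cross(m, cross_design("bc", sexes = "female"), geno)
  pr <- calc_genoprob(cr)
  r <- haldane(10)
  # P(mid = 1 | flanks = 1,1) = (1-r)^2 / ((1-r)^2 + r^2)
  expect_equal(unname(pr$chroms[["1"]][1, 2, 1]),
               (1 - r)^2 / ((1 - r)^2 + r^2), tolerance = 1e-12)
})

test_that("pseudomarker probabilities follow the two-locus conditional", {
  m <- make_map(list("1" = c(0, 10)))
  geno <- list("1" = matrix(c(1L, 2L), 1L))
  cr <- make_cross(m, cross_design("bc", sexes = "female"), geno)
  pr <- calc_genoprob(cr, step = 5)
  r5 <- haldane(5); r10 <- haldane(10)
  # P(recombinant class at the midpoint | flanks recombinant)
  expect_equal(unname(pr$chroms[["1"]][1, 2, 1]),
               (1 - r5) * r5 / r10, tolerance = 1e-12)
})

test_that("with complete data, HK regression equals regression on true genotypes", {
  set.seed(14)
  cr <- toy_cross(80)
  prep <- scan_prep(cr, calc_genoprob(cr))
  s1 <- scanone(prep)
  bf <- bf_scanone_bc(cr, cr$pheno)
  expect_equal(s1$lod, bf$lod, tolerance = 1e-10)
})

test_that("genotyping error in the emission model dilutes certainty", {
  m <- make_map(list("1" = c(0, 10, 20)))
  geno <- list("1" = matrix(c(1L, 1L, 1L), 1L))
  cr <- make_cross(m, cross_design("bc", sexes = "female"), geno)
  p0 <- unname(calc_genoprob(cr, error_prob = 0)$chroms[["1"]][1, 2, 1])
  p1 <- unname(calc_genoprob(cr, error_prob = 0.05)$chroms[["1"]][1, 2, 1])
  expect_equal(p0, 1)
  expect_lt(p1, 1)
  expect_gt(p1, 0.8)
})
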