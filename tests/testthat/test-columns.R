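# the six design configurations and their X-column schemes
design_cases <- list(
  list(d = cross_design("bc", "both", "one"),        null = 1L, x = 2L),
  list(d = cross_design("bc", "female", "one"),      null = 0L, x = 1L),
  list(d = cross_design("f2", "both", "one"),        null = 1L, x = 2L),
  list(d = cross_design("f2", "both", "both"),       null = 2L, x = 3L),
  list(d = cross_design("f2", "female", "both"),     null = 1L, x = 2L),
  list(d = cross_design("f2", "female", "one"),      null = 0L, x = 1L))

test_that("null covariates span the design strata", {
  m <- make_map(list("1" = c(0, 10), X = c(0, 10)), x_chr = "X")
  for (case in design_cases) {
    set.seed(20)
    cr <- sim_cross(40, m, case$d)
    nc <- null_covariates(cr)
    expect_equal(ncol(nc), case$null, info = format(case$d))
    # intercept + null covariates are full rank
    expect_equal(qr(cbind(1, nc))$rank, 1L + case$null)
  }
})

test_that("X-chromosome QTL columns follow the published scheme", {
  m <- make_map(list("1" = c(0, 10), X = c(0, 10)), x_chr = "X")
  for (case in design_cases) {
    set.seed(21)
    cr <- sim_cross(60, m, case$d)
    prep <- scan_prep(cr)
    xrow <- which(prep$grid$is_X)[1L]
    arow <- which(!prep$grid$is_X)[1L]
    expect_equal(ncol(prep$cols[[xrow]]), case$x, info = format(case$d))
    expect_equal(ncol(prep$cols[[arow]]),
                 if (case$d$type == "bc") 1L else 2L)
    # design from complete error-free genotypes is 0/1
    expect_true(all(unlist(prep$cols) %in% c(0, 1)))
    # the null model is nested in the single-QTL alternative at every position
    X0 <- cbind(1, null_covariates(cr))
    for (i in c(arow, xrow)) {
      Xa <- cbind(X0, prep$cols[[i]])
      expect_equal(qr(Xa)$rank, qr(X0)$rank + ncol(prep$cols[[i]]))
    }
  }
})

test_that("backcross X linkage test has two degrees of freedom", {
  m <- make_map(list("1" = c(0, 10), X = c(0, 10)), x_chr = "X")
  set.seed(22)
  cr <- sim_cross(100, m, cross_design("bc"))
  prep <- scan_prep(cr)
  xrow <- which(prep$grid$is_X)[1L]
  X0 <- cbind(1, null_covariates(cr))
  expect_equal(qr(cbind(X0, prep$cols[[xrow]]))$rank - qr(X0)$rank, 2L)
})

test_that("interaction columns are the cartesian product and need both mains", {
  a1 <- cbind(runif(10))
  a2 <- cbind(runif(10), runif(10))
  expect_equal(ncol(interaction_columns(a1, a1)), 1L)
  expect_equal(ncol(interaction_columns(a2, a2)), 4L)
  expect_equal(ncol(interaction_columns(a2, a1)), 2L)
  expect_equal(interaction_columns(a1, a2),
               cbind(a1[, 1] * a2[, 1], a1[, 1] * a2[, 2]),
               ignore_attr = TRUE)
  expect_error(interaction_columns(a1, NULL), "hierarchy")
})

test_that("A:X interaction columns have sex-stratified support", {
  m <- make_map(list("1" = c(0, 10), X = c(0, 10)), x_chr = "X")
  set.seed(23)
  cr <- sim_cross(50, m, cross_design("f2"))
  prep <- scan_prep(cr)
  arow <- which(!prep$grid$is_X)[1L]
  xrow <- which(prep$grid$is_X)[1L]
  ic <- interaction_columns(prep$cols[[arow]], prep$cols[[xrow]])
  expect_equal(ncol(ic), 4L)  # 2 autosomal x (1 female + 1 male)
  f_cols <- ic[, c(1, 3)]     # products with the female column
  expect_true(all(f_cols[cr$sex == 1L, ] == 0))
})
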