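test_that("empty domain gives the uniform field g = 1", {
  occ <- matrix(FALSE, 9, 9)
  f <- solve_gdnf(occ, field_params(d_g = 2))
  expect_equal(f$values, matrix(1, 9, 9))
  expect_equal(f$residual, 0)
})

test_that("solver matches the dense direct-solve oracle", {
  # 5x5, single cell at the centre, d_g = 1
  occ <- matrix(FALSE, 5, 5); occ[3, 3] <- TRUE
  f <- solve_gdnf(occ, field_params(d_g = 1, tolerance = 1e-12))
  expect_lt(max(abs(f$values - dense_field_oracle(occ, 1))), 1e-8)

  # random occupancies on grids up to 15, several diffusion strengths
  set.seed(42)
  for (rep in 1:6) {
    n <- sample(5:15, 1)
    occ <- matrix(runif(n^2) < 0.35, n, n)
    occ[c(1, n), ] <- FALSE; occ[, c(1, n)] <- FALSE
    d_g <- sample(c(0.5, 1, 5, 20), 1)
    f <- solve_gdnf(occ, field_params(d_g = d_g, tolerance = 1e-12))
    expect_lt(max(abs(f$values - dense_field_oracle(occ, d_g))), 1e-8)
  }
})

test_that("diffusion-dominated limit flattens the field to 1", {
  set.seed(7)
  occ <- matrix(runif(121) < 0.4, 11, 11)
  f <- solve_gdnf(occ, field_params(d_g = 1e6, tolerance = 1e-9))
  expect_lt(max(abs(f$values - 1)), 1e-3)
  expect_lt(max(abs(f$values - dense_field_oracle(occ, 1e6))), 1e-6)
})

test_that("discrete maximum principle holds for random occupancies", {
  set.seed(11)
  for (rep in 1:25) {
    n <- sample(7:21, 1)
    occ <- matrix(runif(n^2) < runif(1, 0.1, 0.7), n, n)
    f <- solve_gdnf(occ, field_params(d_g = 10^runif(1, -1, 2)))
    expect_gte(min(f$values), 0)
    expect_equal(max(f$values), 1)  # boundary ring is clamped at 1
  }
})

test_that("adding an occupied site never increases the field", {
  set.seed(3)
  for (rep in 1:8) {
    occ <- matrix(runif(49) < 0.3, 7, 7)
    occ[c(1, 7), ] <- FALSE; occ[, c(1, 7)] <- FALSE
    free <- which(!occ, arr.ind = TRUE)
    free <- free[free[, 1] %in% 2:6 & free[, 2] %in% 2:6, , drop = FALSE]
    pick <- free[sample(nrow(free), 1), ]
    occ2 <- occ; occ2[pick[1], pick[2]] <- TRUE
    g1 <- dense_field_oracle(occ, 1.5)
    g2 <- dense_field_oracle(occ2, 1.5)
    expect_true(all(g2 <= g1 + 1e-12))
    # and the iterative solver agrees with both
    expect_lt(max(abs(solve_gdnf(occ2, field_params(d_g = 1.5,
      tolerance = 1e-12))$values - g2)), 1e-8)
  }
})

test_that("warm-started and cold-started solves agree", {
  set.seed(5)
  occ <- matrix(runif(225) < 0.3, 15, 15)
  fp <- field_params(d_g = 3, tolerance = 1e-8)
  cold <- solve_gdnf(occ, fp)
  # warm start from a perturbed previous field
  warm0 <- pmin(pmax(cold$values + 0.05 * matrix(runif(225), 15), 0), 1)
  warm <- solve_gdnf(occ, fp, warm_start = warm0)
  expect_lt(max(abs(warm$values - cold$values)), 10 * fp$tolerance)
})

test_that("field respects symmetries of a symmetric occupancy", {
  occ <- matrix(FALSE, 13, 13)
  occ[6:8, 6:8] <- TRUE  # centred square: fully symmetric
  f <- solve_gdnf(occ, field_params(d_g = 2, tolerance = 1e-10))$values
  expect_lt(max(abs(f - t(f))), 1e-8)                  # mirror
  expect_lt(max(abs(f - f[, 13:1])), 1e-8)             # flip
  expect_lt(max(abs(f - t(f[13:1, ])[, 13:1])), 1e-8)  # 90 degrees
})

test_that("invalid inputs and non-convergence raise errors", {
  expect_error(solve_gdnf(matrix(FALSE, 3, 4)), "square")
  expect_error(solve_gdnf(matrix(FALSE, 2, 2)), "at least 3 x 3")
  expect_error(solve_gdnf(matrix(FALSE, 5, 5), warm_start = matrix(1, 4, 4)),
               "warm start")
  occ <- matrix(TRUE, 15, 15)
  err <- tryCatch(
    solve_gdnf(occ, field_params(d_g = 1, tolerance = 1e-12,
                                 max_iterations = 2L)),
    branchca_no_convergence = function(e) e)
  expect_s3_class(err, "branchca_no_convergence")
  expect_gt(err$residual, 1e-12)
})
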