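test_that("division gate is the probit switch of the local GDNF level", {
  # midpoint: p = 0.5 exactly at g = -c1/c2, for any admissible pair
  for (pars in list(c(-25, 120), c(-40, 280), c(-20, 40), c(-33, 200)))
    expect_equal(division_probability(-pars[1] / pars[2], pars[1],
                                      pars[2]), 0.5, tolerance = 1e-12)
  expect_equal(division_probability(0.7, 0, 0), 0.5)
  # without growth factor, division is effectively shut off
  expect_lt(division_probability(0, -25, 120), 1e-100)
  # deep upper tail against an independent error-function evaluation
  expect_equal(division_probability(0.1, -25, 400),
               pracma::erfc(-15 / sqrt(2)) / 2, tolerance = 1e-12)
  expect_equal(division_probability(0.1, -25, 400), 1)
})

test_that("site selection is the softmax of neighbour levels", {
  expect_equal(site_selection_probs(rep(0.3, 4), beta = 7), rep(0.25, 4))
  expect_equal(site_selection_probs(c(0.9, 0.1, 0.5), beta = 0),
               rep(1 / 3, 3))
  e <- exp(1)
  expect_equal(site_selection_probs(c(1, 0), beta = 1),
               c(e / (1 + e), 1 / (1 + e)), tolerance = 1e-12)
  set.seed(1)
  for (rep in 1:20) {
    k <- sample(1:4, 1)
    p <- site_selection_probs(runif(k), beta = runif(1, 0, 30))
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_true(all(p >= 0))
  }
  expect_error(site_selection_probs(numeric(0), 1), "at least one")
})

test_that("large beta concentrates selection on the argmax neighbour", {
  # single cell with three empty neighbours at distinct field levels
  occ <- matrix(FALSE, 5, 5); occ[3, 3] <- TRUE; occ[2, 3] <- TRUE
  g <- matrix(0.1, 5, 5)
  g[4, 3] <- 0.9; g[3, 2] <- 0.5; g[3, 4] <- 0.2  # argmax: south
  p <- model_params(grid_size = 5L, p_move = 1, beta_move = 1e3)
  set.seed(99)
  hits <- 0L
  for (rep in 1:100) {
    st <- ca_step(lattice_state(occ), g, p)
    # the cell at (3,3) moved; (2,3) has no empty neighbour except where
    # (3,3) vacated, so check where the mover went
    if (st$occupancy[4, 3]) hits <- hits + 1L
  }
  expect_gte(hits, 99L)
})

test_that("sweeps conserve cells under pure movement", {
  set.seed(2)
  occ <- matrix(runif(144) < 0.4, 12, 12)
  occ[c(1, 12), ] <- FALSE; occ[, c(1, 12)] <- FALSE
  st <- lattice_state(occ)
  g <- solve_gdnf(occ, field_params(d_g = 5))
  p <- model_params(grid_size = 12L, p_move = 1)
  for (i in 1:5) {
    st2 <- ca_step(st, solve_gdnf(st$occupancy, field_params(d_g = 5)), p)
    expect_identical(sum(st2$occupancy), sum(st$occupancy))
    expect_identical(attr(st2, "divisions"), 0L)
    st <- st2
  }
})

test_that("a saturated lattice does not change", {
  occ <- matrix(TRUE, 4, 4)
  g <- matrix(0.5, 4, 4)
  st <- ca_step(lattice_state(occ), g, model_params(grid_size = 4L))
  expect_identical(st$occupancy, occ)
})

test_that("a certain division places a daughter in the neighbourhood", {
  occ <- matrix(FALSE, 5, 5); occ[3, 3] <- TRUE
  g <- matrix(1, 5, 5)
  p <- model_params(grid_size = 5L, p_move = 0, c1 = 0, c2 = 100)
  set.seed(4)
  st <- ca_step(lattice_state(occ), g, p)
  expect_identical(sum(st$occupancy), 2L)
  expect_true(st$occupancy[3, 3])
  daughter <- which(st$occupancy & !occ, arr.ind = TRUE)
  expect_equal(abs(daughter[1] - 3) + abs(daughter[2] - 3), 1)
})

test_that("cell count never decreases and increments match divisions", {
  occ <- make_initial_mass(shape_spec("ellipse"), 40)
  p <- model_params(grid_size = 40L, p_move = 0.6)
  st <- lattice_state(occ)
  set.seed(8)
  for (i in 1:10) {
    f <- solve_gdnf(st$occupancy,
                    field_params(d_g = lattice_diffusion(p)))
    st2 <- ca_step(st, f, p)
    expect_identical(sum(st2$occupancy),
                     sum(st$occupancy) + attr(st2, "divisions"))
    st <- st2
  }
})

test_that("the attachment rule vetoes moves that would detach cells", {
  occ <- matrix(FALSE, 5, 5); occ[3, 3] <- TRUE; occ[3, 4] <- TRUE
  g <- matrix(0.5, 5, 5)
  p_off <- model_params(grid_size = 5L, p_move = 1)
  p_on <- model_params(grid_size = 5L, p_move = 1,
                       attachment_rule = TRUE)
  # every destination of either cell touches only the mover's own
  # origin, so with the rule on nothing can move
  set.seed(21)
  st <- ca_step(lattice_state(occ), g, p_on)
  expect_identical(st$occupancy, occ)
  # with the rule off the pair does shuffle eventually
  set.seed(21)
  moved <- FALSE
  st <- lattice_state(occ)
  for (i in 1:5) {
    st <- ca_step(st, g, p_off)
    if (!identical(st$occupancy, occ)) moved <- TRUE
  }
  expect_true(moved)
})

test_that("trajectories are reproducible and respect the time grid", {
  mask <- make_initial_mass(shape_spec("t_bud"), 50)
  p <- model_params(grid_size = 50L, steps_per_hour = 1)
  tr0 <- simulate_branching(mask, p, record_times_h = 0, seed = 5)
  expect_length(tr0$snapshots, 1L)
  expect_identical(tr0$snapshots[[1]], mask)

  tr1 <- simulate_branching(mask, p, c(0, 3, 6), seed = 5)
  tr2 <- simulate_branching(mask, p, c(0, 3, 6), seed = 5)
  expect_identical(tr1$snapshots, tr2$snapshots)
  tr3 <- simulate_branching(mask, p, c(0, 3, 6), seed = 6)
  expect_false(identical(tr1$snapshots[[3]], tr3$snapshots[[3]]))
  # no cell death over the trajectory
  expect_true(all(diff(tr1$cell_counts) >= 0))
})

test_that("the simulation does not disturb the caller's RNG stream", {
  mask <- make_initial_mass(shape_spec("ellipse"), 40)
  p <- model_params(grid_size = 40L)
  set.seed(123)
  ref <- runif(3)
  set.seed(123)
  invisible(simulate_branching(mask, p, c(0, 2), seed = 77))
  expect_identical(runif(3), ref)
})

test_that("masks touching the boundary ring are rejected", {
  p <- model_params(grid_size = 20L)
  bad <- matrix(FALSE, 20, 20); bad[1, 5] <- TRUE; bad[10, 10] <- TRUE
  expect_error(simulate_branching(bad, p, c(0, 1)), "boundary ring")
  expect_error(simulate_branching(matrix(FALSE, 30, 30),
                                  model_params(grid_size = 30L), c(0, 1)),
               "empty")
  ok <- matrix(FALSE, 20, 20); ok[10, 10] <- TRUE
  expect_error(simulate_branching(ok, p, c(1, 2)), "start at 0")
})
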