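# a deterministic fake library: particle i has summaries centred on i
make_grid_library <- function(m = 12L, n_rep = 2L) {
  set.seed(500)
  thetas <- sample_prior(prior_spec(), m)
  summaries <- array(0, c(m, n_rep, 6))
  for (i in seq_len(m)) for (r in seq_len(n_rep))
    summaries[i, r, ] <- i + 0.1 * r + (0:5) / 10
  fake_library(thetas, summaries)
}

test_that("Epanechnikov weights follow the kernel and the cutoff", {
  lib <- make_grid_library()
  k <- 4L
  th <- lib$thetas[1, ]
  w <- epanechnikov_weights(th, lib, k = k)
  scl <- lib$theta_scale
  d <- sqrt(rowSums(sweep(lib$thetas, 2, th)^2 / rep(scl^2,
                                                     each = 12)))
  h <- sort(d)[k + 1]
  # theta* coincides with pilot 1: maximal weight 3 / (4 h)
  expect_equal(w[1], 0.75 / h)
  expect_equal(which.max(w), 1L)
  # exactly the k nearest carry weight; all others are exactly zero
  expect_identical(which(w > 0), sort(order(d)[1:k]))
  expect_true(all(w[order(d)[(k + 1):12]] == 0))
  # and the kernel formula holds for the interior neighbours
  sel <- order(d)[2:k]
  expect_equal(w[sel], 0.75 / h * (1 - (d[sel] / h)^2))
})

test_that("weight ties at the bandwidth break by particle index", {
  prior <- prior_spec(c1 = c(-40, -20), c2 = c(40, 280),
                      p_move = c(0, 1))
  thetas <- rbind(c(-30, 100, 0.2), c(-30, 140, 0.2))
  colnames(thetas) <- c("c1", "c2", "p_move")
  lib <- fake_library(thetas, array(1:12, c(2, 1, 6)), prior = prior)
  w <- epanechnikov_weights(c(-30, 120, 0.2), lib, k = 1L)
  expect_identical(sum(w > 0), 1L)
  expect_gt(w[1], 0)  # first index wins the tie
  # duplicated theta* beyond k copies is degenerate
  lib2 <- fake_library(rbind(thetas[1, ], thetas[1, ]),
                       array(1:12, c(2, 1, 6)), prior = prior)
  expect_error(epanechnikov_weights(thetas[1, ], lib2, k = 1L),
               "degenerate")
  expect_error(epanechnikov_weights(c(-30, 120, 0.2), lib, k = 2L),
               "k must satisfy")
})

test_that("pseudo-datasets resample whole stored replicate vectors", {
  lib <- make_grid_library()
  w <- epanechnikov_weights(lib$thetas[3, ], lib, k = 5L)
  set.seed(31)
  xs <- pseudo_dataset(lib, w, n_replicates = 40L)
  expect_identical(dim(xs), c(40L, 6L))
  stored <- matrix(aperm(lib$summaries, c(2, 1, 3)), ncol = 6)
  for (j in seq_len(nrow(xs)))
    expect_true(any(apply(stored, 1, function(s)
      isTRUE(all.equal(s, unname(xs[j, ]))))))
  expect_error(pseudo_dataset(lib, rep(0, 12)), "zero")

  # a single positive weight: every replicate comes from that particle
  w1 <- rep(0, 12); w1[7] <- 2
  xs1 <- pseudo_dataset(lib, w1, n_replicates = 6L, seed = 3)
  expect_true(all(floor(xs1[, 1]) == 7))
})

test_that("concentrated weights dominate the resampling frequency", {
  lib <- make_grid_library()
  w <- rep(0, 12); w[2] <- 1000; w[9] <- 1e-3
  set.seed(77)
  xs <- pseudo_dataset(lib, w, n_replicates = 10000L)
  # phi_2 ~ 1 for Dirichlet(1000, 0.001): frequency within 2 s.e. of 1
  freq <- mean(floor(xs[, 1]) == 2)
  expect_gte(freq, 1 - 2 * sqrt(0.01 * 0.99 / 10000) - 0.01)
})

test_that("AABC accepts the prescribed fraction and stays in support", {
  lib <- make_grid_library(m = 30L)
  obs <- lib$summaries[4, , ]  # observed = one particle's replicates
  fit <- aabc_infer(obs, lib, n_proposals = 1000L, k = 5L,
                    accept_quantile = 0.05, seed = 9)
  expect_identical(nrow(fit$theta), 50L)
  expect_equal(fit$acceptance_fraction, 0.05)
  # accepted distances never exceed the threshold (equality only under
  # rank ties from the discrete resampling)
  expect_true(all(fit$distances[fit$accepted] <= fit$epsilon))
  expect_true(all(fit$distances[!fit$accepted] >= fit$epsilon))
  b <- fit$prior$bounds
  for (p in colnames(fit$theta))
    expect_true(all(fit$theta[, p] >= b[p, "low"] &
                    fit$theta[, p] <= b[p, "high"]))
  # determinism under a fixed seed
  fit2 <- aabc_infer(obs, lib, n_proposals = 1000L, k = 5L,
                     accept_quantile = 0.05, seed = 9)
  expect_identical(fit$theta, fit2$theta)
})

test_that("accepting everything recovers the prior", {
  lib <- make_grid_library(m = 20L)
  obs <- lib$summaries[1, , ]
  fit <- aabc_infer(obs, lib, n_proposals = 2000L, k = 5L,
                    accept_quantile = 1, seed = 2)
  expect_identical(nrow(fit$theta), 2000L)
  b <- fit$prior$bounds
  for (p in c("c1", "c2", "p_move")) {
    ks <- suppressWarnings(
      stats::ks.test(fit$theta[, p], "punif", b[p, "low"],
                     b[p, "high"]))
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("degenerate priors collapse every pilot particle", {
  prior <- prior_spec(c1 = c(-25, -25), c2 = c(120, 120),
                      p_move = c(0.5, 0.5))
  th <- sample_prior(prior, 5)
  expect_true(all(th[, "c1"] == -25 & th[, "c2"] == 120 &
                  th[, "p_move"] == 0.5))
})
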