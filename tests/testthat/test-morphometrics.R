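test_that("bulk-mass extraction thresholds, fills and keeps the blob", {
  # already-binary image with one component is returned unchanged
  blob <- plus_mask() * 255
  expect_identical(extract_bulk_mass(blob), plus_mask())

  # bright blob plus dim isolated noise pixels: only the blob survives
  img <- matrix(0, 40, 40)
  img[random_blob(1, 40, discs = 1)] <- 200
  set.seed(10)
  noise <- cbind(sample(1:40, 10), sample(1:40, 10))
  blobmask <- img > 0
  for (r in seq_len(10))
    if (!blobmask[noise[r, 1], noise[r, 2]])
      img[noise[r, 1], noise[r, 2]] <- 180
  got <- extract_bulk_mass(img)
  expect_identical(got, largest_component_oracle(img > 0))

  expect_error(extract_bulk_mass(matrix(0, 8, 8)),
               class = "branchca_empty_mask")
})

test_that("path-like masks have no branch points", {
  sk <- skeletonize(bar_mask(), spur_min_length = 0,
                    presmooth_radius = 0)
  expect_identical(sk$n_branch_points, 0L)
  expect_identical(junction_cluster_oracle(sk$pixels), 0L)
})

test_that("crossing and forking masks have exactly one branch point", {
  for (m in list(plus_mask(), y_mask(), y_mask(fourth = TRUE))) {
    sk <- skeletonize(m, spur_min_length = 3, presmooth_radius = 0)
    expect_identical(sk$n_branch_points, 1L)
    expect_identical(junction_cluster_oracle(sk$pixels), 1L)
  }
})

test_that("skeleton pixels stay inside the (smoothed) mask", {
  for (seed in 1:4) {
    m <- random_blob(seed)
    sk <- skeletonize(m, spur_min_length = 0, presmooth_radius = 0)
    expect_true(all(m[sk$pixels]))
    sk2 <- skeletonize(m, spur_min_length = 5, presmooth_radius = 2)
    expect_true(all(sk2$mask[sk2$pixels]))
  }
})

test_that("branch counts are invariant under rotation and mirroring", {
  for (seed in c(2, 5, 9)) {
    m <- random_blob(seed)
    b <- branch_count(m, spur_min_length = 4, presmooth_radius = 1)
    expect_identical(branch_count(t(m), spur_min_length = 4,
                                  presmooth_radius = 1), b)
    expect_identical(branch_count(m[nrow(m):1, ], spur_min_length = 4,
                                  presmooth_radius = 1), b)
    expect_identical(branch_count(t(m)[ncol(m):1, ],
                                  spur_min_length = 4,
                                  presmooth_radius = 1), b)
  }
})

test_that("raising the spur threshold never adds branch points", {
  for (seed in c(1, 3, 6, 8)) {
    m <- random_blob(seed)
    counts <- vapply(c(0, 2, 5, 8, 12), function(sp)
      branch_count(m, spur_min_length = sp, presmooth_radius = 0),
      integer(1))
    expect_true(all(diff(counts) <= 0L))
  }
})

test_that("trajectory summaries normalise area by the initial mass", {
  mk <- function(k) {
    m <- matrix(FALSE, 20, 20); m[seq_len(k)] <- TRUE; m
  }
  traj <- structure(list(
    times_h = c(0, 10), steps = c(0L, 10L),
    snapshots = list(mk(20), mk(37)),
    cell_counts = c(20L, 37L), fields = NULL,
    params = model_params(grid_size = 20L), seed = 1L),
    class = "ca_trajectory")
  s <- summarise_trajectory(traj, presmooth_radius = 0,
                            spur_min_length = 0)
  expect_equal(s$normalised_area, c(1, 1.85))

  # identical masks at all times: area identically 1
  traj$snapshots <- list(mk(25), mk(25))
  s2 <- summarise_trajectory(traj, presmooth_radius = 0)
  expect_equal(s2$normalised_area, c(1, 1))

  # a single-time request at t = 0
  s3 <- summarise_trajectory(traj, times_h = 0, presmooth_radius = 0)
  expect_equal(nrow(s3), 1L)
  expect_equal(s3$normalised_area, 1)

  traj$times_h <- c(5, 10)
  expect_error(summarise_trajectory(traj), "t = 0")
})

test_that("summary vectors order areas before branch counts", {
  ds <- data.frame(replicate_id = 1L, time_h = c(0, 10, 20, 30),
                   normalised_area = c(1, 1.5, 2, 2.5),
                   branch_count = c(0L, 1L, 2L, 4L))
  class(ds) <- c("summary_dataset", "data.frame")
  v <- summary_vector(ds)
  expect_identical(names(v), c("area_t10", "area_t20", "area_t30",
                               "branches_t10", "branches_t20",
                               "branches_t30"))
  expect_equal(unname(v), c(1.5, 2, 2.5, 1, 2, 4))
  expect_error(summary_vector(ds, times_h = c(10, 40)), "lacks")
})
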