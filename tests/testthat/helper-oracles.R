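# Independent oracles and small constructed fixtures used across tests.

# Dense direct solve of the 5-point discretisation: assemble the full
# interior linear system and solve it exactly with base::solve().
dense_field_oracle <- function(occ, d_g) {
  n <- nrow(occ)
  ins <- 2:(n - 1)
  idx <- matrix(0L, n, n)
  idx[ins, ins] <- seq_len((n - 2)^2)
  m <- (n - 2)^2
  A <- matrix(0, m, m)
  b <- numeric(m)
  for (j in ins) for (i in ins) {
    r <- idx[i, j]
    A[r, r] <- -(4 * d_g + as.numeric(occ[i, j]))
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      ii <- i + d[1]; jj <- j + d[2]
      if (idx[ii, jj] > 0L) {
        A[r, idx[ii, jj]] <- A[r, idx[ii, jj]] + d_g
      } else {
        b[r] <- b[r] - d_g  # Dirichlet neighbour, g = 1
      }
    }
  }
  x <- solve(A, b)
  g <- matrix(1, n, n)
  g[ins, ins] <- matrix(x, n - 2)
  g
}

# Largest 8-connected component by explicit flood fill (queue-based,
# independent of the package's labelling code).
largest_component_oracle <- function(mask) {
  n <- nrow(mask); m <- ncol(mask)
  seen <- matrix(FALSE, n, m)
  best <- NULL; best_size <- 0L
  for (j0 in seq_len(m)) for (i0 in seq_len(n)) {
    if (!mask[i0, j0] || seen[i0, j0]) next
    comp <- matrix(FALSE, n, m)
    queue <- list(c(i0, j0)); seen[i0, j0] <- TRUE; comp[i0, j0] <- TRUE
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (di in -1:1) for (dj in -1:1) {
        if (di == 0 && dj == 0) next
        i <- p[1] + di; j <- p[2] + dj
        if (i < 1 || i > n || j < 1 || j > m) next
        if (mask[i, j] && !seen[i, j]) {
          seen[i, j] <- TRUE; comp[i, j] <- TRUE
          queue[[length(queue) + 1L]] <- c(i, j)
        }
      }
    }
    if (sum(comp) > best_size) { best <- comp; best_size <- sum(comp) }
  }
  best
}

# Enumerate 8-neighbour degrees of a skeleton raster and count junction
# clusters by a second, independent pass (merging adjacent junction
# pixels with a simple union over pairwise adjacency).
junction_cluster_oracle <- function(skel) {
  px <- which(skel, arr.ind = TRUE)
  deg <- apply(px, 1, function(p) {
    s <- 0L
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      i <- p[1] + di; j <- p[2] + dj
      if (i >= 1 && i <= nrow(skel) && j >= 1 && j <= ncol(skel) &&
          skel[i, j]) s <- s + 1L
    }
    s
  })
  jx <- px[deg >= 3L, , drop = FALSE]
  if (nrow(jx) == 0L) return(0L)
  grp <- seq_len(nrow(jx))
  repeat {
    changed <- FALSE
    for (a in seq_len(nrow(jx))) for (b in seq_len(nrow(jx))) {
      if (grp[a] != grp[b] &&
          max(abs(jx[a, ] - jx[b, ])) <= 1L) {
        grp[grp == grp[b]] <- grp[a]; changed <- TRUE
      }
    }
    if (!changed) break
  }
  length(unique(grp))
}

# constructed morphometric fixtures (row x col logical rasters)
bar_mask <- function(len = 40L, thick = 3L, pad = 6L) {
  n <- len + 2L * pad
  m <- matrix(FALSE, 2L * pad + thick, n)
  m[pad + seq_len(thick), pad + seq_len(len)] <- TRUE
  m
}

plus_mask <- function(arm = 12L, thick = 3L) {
  n <- 2L * arm + thick + 12L
  c0 <- (n + 1) %/% 2
  m <- matrix(FALSE, n, n)
  hw <- (thick - 1L) %/% 2L
  m[(c0 - hw):(c0 + hw), (c0 - arm):(c0 + arm)] <- TRUE
  m[(c0 - arm):(c0 + arm), (c0 - hw):(c0 + hw)] <- TRUE
  m
}

# three (or four) 3-px-thick arms meeting at one junction: up, left,
# right, and optionally down (diagonal X-crossings are avoided because
# thinning legitimately resolves them into two nearby 3-junctions)
y_mask <- function(arm = 14L, fourth = FALSE) {
  n <- 2L * arm + 16L
  c0 <- (n + 1L) %/% 2L
  m <- matrix(FALSE, n, n)
  stamp <- function(i, j) {
    m[max(1, i - 1):min(n, i + 1), max(1, j - 1):min(n, j + 1)] <<- TRUE
  }
  for (t in 0:arm) {
    stamp(c0 - t, c0)          # arm straight up
    stamp(c0, c0 - t)          # arm left
    stamp(c0, c0 + t)          # arm right
    if (fourth) stamp(c0 + t, c0)
  }
  m
}

# random blob mask: union of discs, reproducible from a seed
random_blob <- function(seed, n = 48L, discs = 6L) {
  set.seed(seed)
  rows <- matrix(seq_len(n), n, n)
  cols <- matrix(seq_len(n), n, n, byrow = TRUE)
  m <- matrix(FALSE, n, n)
  for (k in seq_len(discs)) {
    cr <- runif(1, n * 0.3, n * 0.7); cc <- runif(1, n * 0.3, n * 0.7)
    r <- runif(1, 3, 8)
    m <- m | ((rows - cr)^2 + (cols - cc)^2 <= r^2)
  }
  m
}

# small fake pilot library with hand-set summaries, for unit-testing the
# AABC operations without running simulations
fake_library <- function(thetas, summaries, times_h = c(10, 20, 30),
                         prior = prior_spec()) {
  stopifnot(nrow(thetas) == dim(summaries)[1])
  flat <- matrix(summaries, nrow = dim(summaries)[1] * dim(summaries)[2])
  ssd <- apply(flat, 2, stats::sd)
  structure(list(thetas = thetas, summaries = summaries,
                 times_h = times_h, prior = prior,
                 params = model_params(),
                 n_replicates = dim(summaries)[2],
                 theta_scale = prior$bounds[, "high"] -
                   prior$bounds[, "low"],
                 summary_sd = ssd, seed = 0L, mask = NULL),
            class = "pilot_library")
}
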