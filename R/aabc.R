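#' Uniform prior specification for the inferred parameters
#'
#' Independent uniform priors for the division-switch location `c1`, the
#' switch sensitivity `c2`, and the move probability `p_move`. The
#' defaults are the ranges used throughout the inference experiments.
#'
#' @param c1,c2,p_move numeric `(low, high)` bounds; `low <= high`
#'   (equal bounds give a degenerate point prior, useful in tests).
#' @return An object of class `prior_spec` wrapping a 3 x 2 bounds
#'   matrix.
#' @export
prior_spec <- function(c1 = c(-40, -20), c2 = c(40, 280),
                       p_move = c(0, 1)) {
  b <- rbind(c1 = sort(c1)[1:2], c2 = sort(c2)[1:2],
             p_move = sort(p_move)[1:2])
  colnames(b) <- c("low", "high")
  stopifnot(is.numeric(b), all(is.finite(b)),
            all(b[, "low"] <= b[, "high"]))
  structure(list(bounds = b), class = "prior_spec")
}

#' @export
print.prior_spec <- function(x, ...) {
  cat("Uniform priors:\n")
  for (p in rownames(x$bounds))
    cat(sprintf("  %-7s [%g, %g]\n", p, x$bounds[p, 1], x$bounds[p, 2]))
  invisible(x)
}

#' Draw parameter triples from the prior
#'
#' @param prior a [prior_spec()].
#' @param n number of draws.
#' @return An `n` x 3 matrix with columns `c1`, `c2`, `p_move`.
#' @export
sample_prior <- function(prior, n) {
  stopifnot(inherits(prior, "prior_spec"), n >= 1)
  b <- prior$bounds
  m <- vapply(rownames(b),
              function(p) runif(n, b[p, "low"], b[p, "high"]),
              numeric(n))
  if (n == 1L) m <- matrix(m, 1L, dimnames = list(NULL, rownames(b)))
  m
}

theta_in_prior <- function(theta, prior) {
  b <- prior$bounds
  all(theta >= b[, "low"] & theta <= b[, "high"])
}

#' Build a pilot library of true simulations
#'
#' Step one of AABC: draw `m` parameter triples from the prior, run the
#' real automaton `n_replicates` times for each, and store the summary
#' vectors. The library also records the per-dimension scalings later
#' used for distances: the prior range of each parameter, and the pooled
#' standard deviation of each summary dimension.
#'
#' @param prior a [prior_spec()].
#' @param m number of pilot particles (>= 2).
#' @param n_replicates replicates per particle (default 2).
#' @param params a [model_params()] template (grid size, toggles, ...).
#' @param seed integer master seed.
#' @param times_h post-initial summary time points.
#' @param mask optional initial mass (default: `t_bud` shape).
#' @param progress print a dot every 25 particles.
#' @return An object of class `pilot_library`: `thetas` (`m` x 3),
#'   `summaries` (array `m` x `n_replicates` x `2 * length(times_h)`),
#'   `times_h`, `prior`, `params`, scalings. Particles whose simulation
#'   fails are dropped with a warning.
#' @export
build_pilot_library <- function(prior, m, n_replicates = 2L,
                                params = model_params(), seed = 1L,
                                times_h = c(10, 20, 30), mask = NULL,
                                progress = FALSE) {
  stopifnot(inherits(prior, "prior_spec"), m >= 2, n_replicates >= 1)
  if (is.null(mask))
    mask <- make_initial_mass(shape_spec("t_bud"), params$grid_size)
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  thetas <- sample_prior(prior, m)
  seeds <- matrix(sample.int(2^30, m * n_replicates), m, n_replicates)

  d <- 2L * length(times_h)
  summaries <- array(NA_real_, c(m, n_replicates, d))
  ok <- rep(TRUE, m)
  for (i in seq_len(m)) {
    p <- modifyList(params, list(c1 = thetas[i, "c1"],
                                 c2 = thetas[i, "c2"],
                                 p_move = thetas[i, "p_move"]))
    class(p) <- "model_params"
    for (r in seq_len(n_replicates)) {
      x <- tryCatch({
        tr <- simulate_branching(mask, p, record_times_h = c(0, times_h),
                                 seed = seeds[i, r])
        summary_vector(summarise_trajectory(tr, replicate_id = r),
                       times_h)
      }, error = function(e) {
        warning(sprintf("particle %d dropped: %s", i,
                        conditionMessage(e)), call. = FALSE)
        NULL
      })
      if (is.null(x)) { ok[i] <- FALSE; break }
      summaries[i, r, ] <- x
    }
    if (progress && i %% 25L == 0L) cat(".")
  }
  if (progress) cat("\n")
  thetas <- thetas[ok, , drop = FALSE]
  summaries <- summaries[ok, , , drop = FALSE]
  flat <- matrix(summaries, nrow = sum(ok) * n_replicates)
  ssd <- apply(flat, 2, sd)
  structure(list(thetas = thetas, summaries = summaries,
                 times_h = times_h, prior = prior, params = params,
                 n_replicates = as.integer(n_replicates),
                 theta_scale = prior$bounds[, "high"] -
                   prior$bounds[, "low"],
                 summary_sd = ssd, seed = seed, mask = mask),
            class = "pilot_library")
}

#' @export
print.pilot_library <- function(x, ...) {
  cat(sprintf(
    "AABC pilot library: m = %d particles x %d replicates, t = %s h\n",
    nrow(x$thetas), x$n_replicates, paste(x$times_h, collapse = ", ")))
  invisible(x)
}

#' Epanechnikov kernel weights over a pilot library
#'
#' Computes the AABC weights of a proposed parameter triple against the
#' pilot particles. Distances are Euclidean after rescaling each
#' parameter dimension to unit prior range. With `d_i` the distance to
#' pilot `i` and `d_(k+1)` the `(k+1)`-th smallest distance, the `k`
#' nearest particles receive
#' `w_i = (3/4) (1/d_(k+1)) (1 - (d_i / d_(k+1))^2)` and all others
#' weight 0. Distance ties at the bandwidth are broken by particle
#' index: exactly the `k` first-ranked particles can carry weight, and
#' if the kernel value vanishes for all of them (an exact tie with the
#' `(k+1)`-th) they are given equal positive weight instead.
#'
#' @param theta_star numeric triple `(c1, c2, p_move)`.
#' @param library a [build_pilot_library()] result.
#' @param k number of nearest neighbours carrying weight
#'   (`1 <= k < m`).
#' @return Numeric weight vector of length `m` (rows of
#'   `library$thetas`).
#' @export
epanechnikov_weights <- function(theta_star, library, k = 50L) {
  stopifnot(inherits(library, "pilot_library"))
  theta_star <- as_theta(theta_star)
  m <- nrow(library$thetas)
  if (k < 1 || k >= m) stop("k must satisfy 1 <= k < m")
  scl <- ifelse(library$theta_scale > 0, library$theta_scale, 1)
  z <- sweep(library$thetas, 2, theta_star) / rep(scl, each = m)
  d <- sqrt(rowSums(z^2))
  ord <- order(d)  # ties broken by index
  h <- d[ord[k + 1L]]
  if (h == 0)
    stop("degenerate kernel: theta_star duplicated at least k+1 times ",
         "in the pilot library")
  w <- numeric(m)
  sel <- ord[seq_len(k)]
  w[sel] <- 0.75 / h * (1 - (d[sel] / h)^2)
  if (all(w[sel] <= 0)) w[sel] <- 0.75 / h
  w
}

#' Kernel-weighted pseudo-dataset (AABC resampling step)
#'
#' Draws resampling probabilities `phi` from a Dirichlet distribution
#' parameterised by the positive weights, then builds each pseudo
#' replicate by sampling a pilot particle from `phi` and one of its
#' stored replicate summary vectors uniformly. Whole replicate vectors
#' are resampled (never individual components), so within-replicate
#' correlation between area and branch count is preserved.
#'
#' @param library a [build_pilot_library()] result.
#' @param weights weight vector over pilot particles (from
#'   [epanechnikov_weights()]); at least one entry must be positive.
#' @param n_replicates number of pseudo replicates to draw.
#' @param seed optional integer seed (otherwise the current RNG stream
#'   is consumed).
#' @return Matrix with `n_replicates` rows of summary vectors.
#' @export
pseudo_dataset <- function(library, weights, n_replicates = 2L,
                           seed = NULL) {
  stopifnot(inherits(library, "pilot_library"),
            length(weights) == nrow(library$thetas))
  pos <- which(weights > 0)
  if (length(pos) == 0L) stop("all weights are zero")
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()),
              add = TRUE)
    }
    set.seed(seed)
  }
  # Dirichlet(omega) via normalised gammas
  gam <- rgamma(length(pos), shape = weights[pos], rate = 1)
  while (sum(gam) == 0)
    gam <- rgamma(length(pos), shape = weights[pos], rate = 1)
  phi <- gam / sum(gam)
  nrep_lib <- dim(library$summaries)[2]
  out <- t(vapply(seq_len(n_replicates), function(j) {
    i <- pos[sample.int(length(pos), 1L, prob = phi)]
    r <- sample.int(nrep_lib, 1L)
    library$summaries[i, r, ]
  }, numeric(dim(library$summaries)[3])))
  colnames(out) <- c(paste0("area_t", library$times_h),
                     paste0("branches_t", library$times_h))
  out
}

# coerce observed data to a replicate x summary matrix on the library's
# time points
as_summary_group <- function(observed, times_h) {
  if (is.matrix(observed)) {
    if (ncol(observed) != 2L * length(times_h))
      stop("observed summary matrix has the wrong number of columns")
    return(observed)
  }
  if (inherits(observed, "summary_dataset") || is.data.frame(observed)) {
    reps <- split(observed, observed$replicate_id)
    return(t(vapply(reps, summary_vector, numeric(2L * length(times_h)),
                    times_h = times_h)))
  }
  if (is.list(observed) && !is.null(observed$summaries))
    return(as_summary_group(observed$summaries, times_h))
  stop("cannot interpret the observed data")
}

#' Approximate Approximate Bayesian Computation inference
#'
#' Infers `(c1, c2, p_move)` from observed summary statistics. For each
#' of `n_proposals` prior draws, pilot-library weights are computed with
#' [epanechnikov_weights()], `n_pseudo` pseudo-datasets are resampled
#' with [pseudo_dataset()], and the recorded distance is the mean over
#' those draws of the Euclidean distance between the replicate-mean
#' observed and pseudo summary vectors (per-dimension standardisation
#' by the pilot-library standard deviations by default). Averaging over
#' several pseudo-datasets is pure variance reduction -- resampling is
#' essentially free next to a true simulation -- and sharpens the
#' implied likelihood; `n_pseudo = 1` reproduces the single-draw
#' scheme. The acceptance threshold `epsilon` is set so that exactly
#' the `accept_quantile` fraction of proposals (the smallest distances,
#' rank ties broken by proposal index) enters the posterior sample.
#'
#' @param observed observed summaries: a replicate x summary matrix, a
#'   `summary_dataset` with a `replicate_id` column, or a
#'   [make_reference_observed()] bundle.
#' @param library a [build_pilot_library()] result.
#' @param prior a [prior_spec()]; defaults to the library's.
#' @param n_proposals number of prior proposals.
#' @param k neighbour count for the kernel weights.
#' @param accept_quantile acceptance fraction (0 < q <= 1); `q = 1`
#'   accepts everything (prior recovery).
#' @param n_pseudo number of pseudo-datasets averaged per proposal.
#' @param seed integer seed.
#' @param standardise logical; divide summary dimensions by the pilot
#'   standard deviations before the Euclidean distance (`FALSE` = raw
#'   distances).
#' @return An object of class `aabc` with accepted draws in `$theta`,
#'   all `$distances`, `$epsilon` and `$acceptance_fraction`; see
#'   [summary.aabc()], [coef.aabc()], [plot.aabc()].
#' @export
aabc_infer <- function(observed, library, prior = library$prior,
                       n_proposals = 2000L, k = 50L,
                       accept_quantile = 0.05, n_pseudo = 10L,
                       seed = 1L, standardise = TRUE) {
  stopifnot(inherits(library, "pilot_library"),
            inherits(prior, "prior_spec"), n_pseudo >= 1,
            n_proposals >= 1, accept_quantile > 0, accept_quantile <= 1)
  obs <- as_summary_group(observed, library$times_h)
  obs_mean <- colMeans(obs)
  scl <- if (standardise) {
    s <- library$summary_sd
    ifelse(is.finite(s) & s > 0, s, 1)
  } else rep(1, length(obs_mean))

  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)

  thetas <- sample_prior(prior, n_proposals)
  dists <- numeric(n_proposals)
  for (p in seq_len(n_proposals)) {
    w <- epanechnikov_weights(thetas[p, ], library, k = k)
    d <- 0
    for (j in seq_len(n_pseudo)) {
      xs <- pseudo_dataset(library, w,
                           n_replicates = library$n_replicates)
      d <- d + sqrt(sum(((obs_mean - colMeans(xs)) / scl)^2))
    }
    dists[p] <- d / n_pseudo
  }
  # epsilon is chosen so that exactly the accept_quantile fraction of
  # proposals enters the posterior: accept the n_acc smallest distances
  # (rank ties broken by proposal index) and report the smallest
  # rejected distance as the threshold
  if (accept_quantile >= 1) {
    eps <- Inf
    acc <- rep(TRUE, n_proposals)
  } else {
    n_acc <- max(1L, round(accept_quantile * n_proposals))
    ord <- order(dists)
    acc <- rep(FALSE, n_proposals)
    acc[ord[seq_len(n_acc)]] <- TRUE
    eps <- dists[ord[n_acc + 1L]]
  }
  structure(list(theta = thetas[acc, , drop = FALSE],
                 proposals = thetas, distances = dists, accepted = acc,
                 epsilon = eps,
                 acceptance_fraction = mean(acc), prior = prior, k = k,
                 n_pseudo = as.integer(n_pseudo),
                 n_proposals = as.integer(n_proposals), seed = seed,
                 standardise = standardise,
                 observed_mean = obs_mean, call = match.call()),
            class = "aabc")
}

#' @export
print.aabc <- function(x, ...) {
  cat(sprintf(
    "AABC posterior sample: %d / %d proposals accepted (%.1f%%), epsilon = %.4g\n",
    nrow(x$theta), x$n_proposals, 100 * x$acceptance_fraction,
    x$epsilon))
  if (nrow(x$theta)) {
    cat("Posterior means:\n")
    print(round(colMeans(x$theta), 4))
  }
  invisible(x)
}

#' Posterior summary of an AABC fit
#'
#' @param object an `aabc` object.
#' @param probs quantile probabilities to report.
#' @param ... unused.
#' @return A matrix of posterior means, standard deviations and
#'   quantiles per parameter.
#' @export
summary.aabc <- function(object, probs = c(0.025, 0.5, 0.975), ...) {
  th <- object$theta
  if (nrow(th) == 0L) stop("no accepted draws")
  out <- cbind(mean = colMeans(th), sd = apply(th, 2, sd),
               t(apply(th, 2, quantile, probs = probs)))
  class(out) <- c("summary.aabc", class(out))
  out
}

#' @export
print.summary.aabc <- function(x, ...) {
  y <- x
  class(y) <- NULL
  print(round(y, 4))
  invisible(x)
}

#' @export
coef.aabc <- function(object, ...) colMeans(object$theta)

#' @export
as.data.frame.aabc <- function(x, ...) {
  data.frame(x$theta,
             distance = x$distances[x$accepted])
}

#' Corner-style posterior plot
#'
#' Marginal histograms on the diagonal and pairwise scatter plots of the
#' accepted draws below it, with the prior bounds as axis limits.
#'
#' @param x an `aabc` object.
#' @param ... unused.
#' @export
plot.aabc <- function(x, ...) {
  th <- x$theta
  b <- x$prior$bounds
  pars <- colnames(th)
  np <- length(pars)
  op <- graphics::par(mfrow = c(np, np), mar = c(2.5, 2.5, 1.2, 0.5),
                      mgp = c(1.4, 0.4, 0))
  on.exit(graphics::par(op))
  for (i in seq_len(np)) for (j in seq_len(np)) {
    if (i == j) {
      graphics::hist(th[, i], breaks = 20, main = pars[i], xlab = "",
                     col = "grey70", border = "white",
                     xlim = b[pars[i], ])
    } else if (i > j) {
      graphics::plot(th[, j], th[, i], pch = 16, cex = 0.4,
                     col = grDevices::adjustcolor("steelblue", 0.5),
                     xlim = b[pars[j], ], ylim = b[pars[i], ],
                     xlab = pars[j], ylab = pars[i], main = "")
    } else graphics::plot.new()
  }
  invisible(x)
}
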