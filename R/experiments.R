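#' @noRd
run_condition_replicates <- function(params, n_replicates, times_h, seed,
                                     mask, spur_min_length = 5L,
                                     presmooth_radius = 2L) {
  seeds <- derive_seeds(seed, n_replicates)
  res <- lapply(seq_len(n_replicates), function(r) {
    tr <- simulate_branching(mask, params, record_times_h = times_h,
                             seed = seeds[r])
    summarise_trajectory(tr, replicate_id = r,
                         spur_min_length = spur_min_length,
                         presmooth_radius = presmooth_radius)
  })
  do.call(rbind, res)
}

# percentile bootstrap CI for a mean over replicates
boot_ci <- function(x, B = 1000L, level = 0.95) {
  if (length(x) < 2L) return(c(lo = min(x), hi = max(x)))
  means <- vapply(seq_len(B),
                  function(b) mean(sample(x, replace = TRUE)),
                  numeric(1))
  a <- (1 - level) / 2
  setNames(quantile(means, c(a, 1 - a), names = FALSE), c("lo", "hi"))
}

#' Mechanism-ablation experiment
#'
#' Runs all 8 combinations of the three GDNF-coupling toggles
#' (GDNF-stimulated division, chemotaxis, anisotropic cell division)
#' over replicate simulations, and reports mean branch-count
#' trajectories with percentile-bootstrap 95% intervals plus the
#' final-time ordering of the conditions. When GDNF-stimulated division
#' is off, cells divide with the constant probability
#' `params$p_const`.
#'
#' @param params a [model_params()] template (its toggles are
#'   overridden per condition).
#' @param n_replicates replicates per condition.
#' @param times_h recording times (hours), starting at 0.
#' @param seed integer master seed.
#' @param mask optional initial mass; default `t_bud` shape.
#' @param boot bootstrap resamples for the intervals.
#' @return An object of class `ca_experiment`: `trajectories` (data
#'   frame of per-time means and intervals per condition), `final`
#'   (final-time summary per condition), `raw` per-replicate data.
#' @export
run_ablation_experiment <- function(params = model_params(),
                                    n_replicates = 50L,
                                    times_h = c(0, 10, 20, 30),
                                    seed = 1L, mask = NULL,
                                    boot = 1000L) {
  stopifnot(inherits(params, "model_params"))
  if (is.null(mask))
    mask <- make_initial_mass(shape_spec("t_bud"), params$grid_size)
  # all 8 (division, chemotaxis, ACD) off/on combinations
  combos <- expand.grid(gdnf_division = c(FALSE, TRUE),
                        chemotaxis = c(FALSE, TRUE),
                        acd = c(FALSE, TRUE))
  labels <- apply(combos, 1, function(r)
    paste0("division", ifelse(r[["gdnf_division"]], "+", "-"),
           " chemotaxis", ifelse(r[["chemotaxis"]], "+", "-"),
           " acd", ifelse(r[["acd"]], "+", "-")))
  seeds <- derive_seeds(seed, nrow(combos))

  raw <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    p <- modifyList(params, as.list(combos[i, ]))
    class(p) <- "model_params"
    df <- run_condition_replicates(p, n_replicates, times_h, seeds[i],
                                   mask)
    df$condition <- labels[i]
    raw[[i]] <- df
  }
  raw <- do.call(rbind, raw)

  agg <- do.call(rbind, lapply(split(
    raw, list(raw$condition, raw$time_h), drop = TRUE),
    function(d) {
      ci <- boot_ci(d$branch_count, B = boot)
      data.frame(condition = d$condition[1], time_h = d$time_h[1],
                 mean_branches = mean(d$branch_count),
                 lo = ci[["lo"]], hi = ci[["hi"]],
                 mean_area = mean(d$normalised_area))
    }))
  agg <- agg[order(match(agg$condition, labels), agg$time_h), ]
  rownames(agg) <- NULL
  final <- agg[agg$time_h == max(times_h), ]
  final <- final[order(-final$mean_branches), ]
  structure(list(trajectories = agg, final = final, raw = raw,
                 conditions = labels, combos = combos, seed = seed,
                 n_replicates = n_replicates),
            class = "ca_experiment")
}

#' @export
print.ca_experiment <- function(x, ...) {
  cat(sprintf("CA experiment: %d condition(s) x %d replicates\n",
              length(x$conditions), x$n_replicates))
  cat("Final-time branch counts (mean [95% CI]):\n")
  f <- x$final
  for (i in seq_len(nrow(f)))
    cat(sprintf("  %-38s %6.2f [%5.2f, %5.2f]\n", f$condition[i],
                f$mean_branches[i], f$lo[i], f$hi[i]))
  invisible(x)
}

#' @export
plot.ca_experiment <- function(x, ...) {
  agg <- x$trajectories
  conds <- unique(agg$condition)
  cols <- grDevices::hcl.colors(length(conds), "Dark 3")
  graphics::plot(NULL, xlim = range(agg$time_h),
                 ylim = c(0, max(agg$hi)), xlab = "time (h)",
                 ylab = "branch points", ...)
  for (i in seq_along(conds)) {
    d <- agg[agg$condition == conds[i], ]
    graphics::lines(d$time_h, d$mean_branches, col = cols[i], lwd = 2)
    graphics::arrows(d$time_h, d$lo, d$time_h, d$hi, length = 0.02,
                     angle = 90, code = 3, col = cols[i])
  }
  graphics::legend("topleft", legend = conds, col = cols, lwd = 2,
                   cex = 0.6, bty = "n")
  invisible(x)
}

#' Division-switch shape sweep
#'
#' Sweeps the switch sensitivity `c2` at fixed `c1` and reports the
#' branch-count trajectory per value, flagging the `c2` with maximal
#' mean final branching. A shallow switch (low `c2`) never gates
#' division spatially; a very steep one (high `c2`, threshold deep in
#' the mass) slows growth -- an intermediate sensitivity maximises
#' branching.
#'
#' @param params a [model_params()] template (`c1` is taken from it).
#' @param c2_values numeric vector of sensitivities to sweep.
#' @inheritParams run_ablation_experiment
#' @return A `ca_experiment` with one condition per `c2`, plus
#'   `$best_c2`.
#' @export
run_switch_sweep <- function(params = model_params(),
                             c2_values = c(20, 120, 400),
                             n_replicates = 50L,
                             times_h = c(0, 10, 20, 30), seed = 1L,
                             mask = NULL, boot = 1000L) {
  stopifnot(inherits(params, "model_params"))
  if (length(c2_values) == 0L) stop("c2_values must be non-empty")
  if (is.null(mask))
    mask <- make_initial_mass(shape_spec("t_bud"), params$grid_size)
  labels <- paste0("c2=", c2_values)
  seeds <- derive_seeds(seed, length(c2_values))
  raw <- vector("list", length(c2_values))
  for (i in seq_along(c2_values)) {
    p <- modifyList(params, list(c2 = c2_values[i]))
    class(p) <- "model_params"
    df <- run_condition_replicates(p, n_replicates, times_h, seeds[i],
                                   mask)
    df$condition <- labels[i]
    raw[[i]] <- df
  }
  raw <- do.call(rbind, raw)
  agg <- do.call(rbind, lapply(split(
    raw, list(raw$condition, raw$time_h), drop = TRUE),
    function(d) {
      ci <- boot_ci(d$branch_count, B = boot)
      data.frame(condition = d$condition[1], time_h = d$time_h[1],
                 mean_branches = mean(d$branch_count),
                 lo = ci[["lo"]], hi = ci[["hi"]],
                 mean_area = mean(d$normalised_area))
    }))
  agg <- agg[order(match(agg$condition, labels), agg$time_h), ]
  rownames(agg) <- NULL
  final <- agg[agg$time_h == max(times_h), ]
  final <- final[order(-final$mean_branches), ]
  out <- structure(list(trajectories = agg, final = final, raw = raw,
                        conditions = labels, seed = seed,
                        n_replicates = n_replicates,
                        c2_values = c2_values,
                        best_c2 = c2_values[match(final$condition[1],
                                                  labels)]),
                   class = "ca_experiment")
  out
}

#' Parameter-recovery inference experiment
#'
#' End-to-end AABC run against synthetic observed data with known
#' truth: builds (or reuses) a pilot library, generates observed
#' summaries at `theta_true` with [make_reference_observed()], runs
#' [aabc_infer()], and reports the posterior together with the
#' `(c1, c2)` posterior correlation.
#'
#' @param theta_true known generating parameters for the synthetic
#'   observed data.
#' @param params a [model_params()] template for the simulations.
#' @param prior a [prior_spec()].
#' @param m pilot-library size.
#' @param n_obs_replicates replicates in the observed dataset.
#' @param n_proposals,k,accept_quantile passed to [aabc_infer()].
#' @param seed integer master seed.
#' @param library optional prebuilt [build_pilot_library()] result.
#' @return List with the `aabc` fit, `theta_true`, the posterior
#'   `(c1, c2)` correlation, and the library used.
#' @export
run_inference_experiment <- function(theta_true = c(c1 = -25, c2 = 120,
                                                    p_move = 0.5),
                                     params = model_params(grid_size = 80L),
                                     prior = prior_spec(), m = 500L,
                                     n_obs_replicates = 3L,
                                     n_proposals = 2000L, k = 50L,
                                     accept_quantile = 0.05, seed = 1L,
                                     library = NULL) {
  seeds <- derive_seeds(seed, 3L)
  if (is.null(library))
    library <- build_pilot_library(prior, m = m, params = params,
                                   seed = seeds[1])
  obs <- make_reference_observed(theta_true, params,
                                 n_replicates = n_obs_replicates,
                                 seed = seeds[2],
                                 times_h = library$times_h)
  fit <- aabc_infer(obs, library, prior = prior,
                    n_proposals = n_proposals, k = k,
                    accept_quantile = accept_quantile, seed = seeds[3])
  list(fit = fit, theta_true = as_theta(theta_true),
       cor_c1_c2 = if (nrow(fit$theta) > 2)
         cor(fit$theta[, "c1"], fit$theta[, "c2"]) else NA_real_,
       library = library, seed = seed)
}
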