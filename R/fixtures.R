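#' Specify a synthetic initial epithelial mass
#'
#' Parameterises the deterministic shapes used to stand in for initial
#' explant masks: an ellipse, a blob with two terminal buds (`t_bud`,
#' the default starting shape, resembling an explant that has already
#' formed its first buds), or a cross (used to exercise the
#' morphometrics). Sizes default to fractions of the grid so the same
#' spec scales across resolutions.
#'
#' @param kind `"ellipse"`, `"t_bud"` or `"cross"`.
#' @param semi_axes ellipse semi-axes in pixels, `(row, col)`.
#' @param bud_radius radius of the terminal buds (`t_bud`).
#' @param arm_length,arm_width cross-arm half-length and full width.
#' @param centre_offset `(row, col)` offset of the shape centre from the
#'   grid centre.
#' @return An object of class `shape_spec`.
#' @export
shape_spec <- function(kind = c("t_bud", "ellipse", "cross"),
                       semi_axes = NULL, bud_radius = NULL,
                       arm_length = NULL, arm_width = NULL,
                       centre_offset = c(0, 0)) {
  kind <- match.arg(kind)
  stopifnot(length(centre_offset) == 2L, is.numeric(centre_offset))
  structure(list(kind = kind, semi_axes = semi_axes,
                 bud_radius = bud_radius, arm_length = arm_length,
                 arm_width = arm_width, centre_offset = centre_offset),
            class = "shape_spec")
}

#' Rasterise a synthetic initial mass
#'
#' Deterministically renders a [shape_spec()] onto an `N x N` logical
#' grid, centred (plus offset). The shape must keep a margin of at
#' least 10 pixels to the clamped boundary ring.
#'
#' @param spec a [shape_spec()].
#' @param grid_size lattice side length.
#' @return Logical occupancy matrix.
#' @examples
#' sum(make_initial_mass(shape_spec("ellipse", semi_axes = c(20, 10)),
#'                       120))  # close to pi * 20 * 10
#' @export
make_initial_mass <- function(spec, grid_size = 120L) {
  stopifnot(inherits(spec, "shape_spec"), grid_size >= 23)
  n <- as.integer(grid_size)
  cr <- (n + 1) / 2 + spec$centre_offset[1]
  cc <- (n + 1) / 2 + spec$centre_offset[2]
  rows <- matrix(seq_len(n), n, n)
  cols <- matrix(seq_len(n), n, n, byrow = TRUE)
  ellipse <- function(r0, c0, a_r, a_c)
    ((rows - r0) / a_r)^2 + ((cols - c0) / a_c)^2 <= 1

  mask <- switch(spec$kind,
    ellipse = {
      ax <- spec$semi_axes %||% c(round(n / 8), round(n / 12))
      ellipse(cr, cc, ax[1], ax[2])
    },
    t_bud = {
      ax <- spec$semi_axes %||% c(round(n / 12), round(n / 7.5))
      br <- spec$bud_radius %||% max(3, round(n / 20))
      ellipse(cr, cc, ax[1], ax[2]) |
        ellipse(cr, cc - ax[2], br, br) |
        ellipse(cr, cc + ax[2], br, br)
    },
    cross = {
      len <- spec$arm_length %||% round(n / 6)
      wid <- spec$arm_width %||% 3
      hw <- (wid - 1) / 2
      (abs(rows - cr) <= hw & abs(cols - cc) <= len) |
        (abs(cols - cc) <= hw & abs(rows - cr) <= len)
    })
  occ <- which(mask, arr.ind = TRUE)
  if (min(occ) <= 10 || max(occ) > n - 10)
    stop("shape does not keep a 10-pixel margin to the boundary ring")
  mask
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Synthetic "observed" summary trajectories with known truth
#'
#' Stands in for the (undeposited) explant movies: runs the real
#' simulator at a known parameter triple and summarises the replicates
#' at the usual time points, returning both the dataset and the truth so
#' parameter-recovery experiments can score against it.
#'
#' @param theta_true named numeric triple `c(c1, c2, p_move)`; must lie
#'   inside `prior`.
#' @param params a [model_params()] template; `c1`, `c2`, `p_move` are
#'   overridden by `theta_true`.
#' @param n_replicates number of replicate simulations.
#' @param seed integer seed (replicate seeds are derived from it).
#' @param times_h post-initial summary time points (hours).
#' @param mask optional initial mass; defaults to the `t_bud` shape for
#'   `params$grid_size`.
#' @param prior a [prior_spec()] used to validate `theta_true`.
#' @return List with `summaries` (matrix, `n_replicates` rows of
#'   [summary_vector()]s), `theta_true`, `times_h`, `seed`.
#' @export
make_reference_observed <- function(theta_true, params = model_params(),
                                    n_replicates = 3L, seed = 1L,
                                    times_h = c(10, 20, 30), mask = NULL,
                                    prior = prior_spec()) {
  theta_true <- as_theta(theta_true)
  if (!theta_in_prior(theta_true, prior))
    stop("theta_true lies outside the prior support")
  if (is.null(mask))
    mask <- make_initial_mass(shape_spec("t_bud"), params$grid_size)
  p <- modifyList(params, list(c1 = unname(theta_true["c1"]),
                               c2 = unname(theta_true["c2"]),
                               p_move = unname(theta_true["p_move"])))
  class(p) <- "model_params"
  seeds <- derive_seeds(seed, n_replicates)
  summaries <- t(vapply(seq_len(n_replicates), function(r) {
    tr <- simulate_branching(mask, p, record_times_h = c(0, times_h),
                             seed = seeds[r])
    summary_vector(summarise_trajectory(tr, replicate_id = r), times_h)
  }, numeric(2L * length(times_h))))
  list(summaries = summaries, theta_true = theta_true,
       times_h = times_h, seed = seed)
}

# reproducible sub-seeds derived from one master seed (kept < 2^30)
derive_seeds <- function(seed, n) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  sample.int(2^30, n)
}

as_theta <- function(theta) {
  stopifnot(is.numeric(theta), length(theta) == 3L)
  if (is.null(names(theta))) names(theta) <- c("c1", "c2", "p_move")
  theta[c("c1", "c2", "p_move")]
}
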