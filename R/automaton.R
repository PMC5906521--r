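#' Probability that a cell divides given its local growth-factor level
#'
#' The division gate is a probit switch, `p_cd = Phi(c1 + c2 * g)`, with
#' `Phi` the standard normal cumulative distribution function. With
#' `c1 < 0 < c2` the gate is sigmoidal in `g` with midpoint
#' `g = -c1/c2` (where `p_cd = 0.5`) and steepness set by `c2`; at
#' `g = 0` division is effectively shut off.
#'
#' @param g_local local dimensionless growth-factor concentration(s) in
#'   `[0, 1]` (vectorised).
#' @param c1 switch location parameter.
#' @param c2 switch sensitivity parameter.
#' @return Division probabilities in `[0, 1]`, same length as `g_local`.
#' @examples
#' division_probability(25 / 120, c1 = -25, c2 = 120)  # 0.5, the midpoint
#' @export
division_probability <- function(g_local, c1, c2) {
  stopifnot(is.numeric(g_local), is.numeric(c1), is.numeric(c2))
  pnorm(c1 + c2 * g_local)
}

#' Softmax selection probabilities over candidate sites
#'
#' Given growth-factor levels at the `K` empty neighbouring sites of a
#' cell (`1 <= K <= 4` in the von Neumann neighbourhood), returns the
#' probability of selecting each site,
#' `p_i = exp(beta g_i) / sum_j exp(beta g_j)`. With `beta = 0` the
#' choice is uniform; large `beta` concentrates on the highest-`g` site.
#' Used both for chemotactic moves (`beta_move`) and anisotropic daughter
#' placement (`beta_div`).
#'
#' @param g_neighbours numeric vector of candidate-site levels (length
#'   1--4).
#' @param beta non-negative sensitivity.
#' @return Probability vector of the same length, summing to 1.
#' @examples
#' site_selection_probs(c(1, 0), beta = 1)  # c(e, 1) / (1 + e)
#' @export
site_selection_probs <- function(g_neighbours, beta) {
  if (length(g_neighbours) == 0L)
    stop("at least one candidate site is required")
  stopifnot(length(g_neighbours) <= 4L, is.numeric(g_neighbours),
            is.numeric(beta), length(beta) == 1L, beta >= 0)
  w <- exp(beta * (g_neighbours - max(g_neighbours)))
  w / sum(w)
}

#' Lattice state constructor
#'
#' @param occupancy square logical (or 0/1) matrix; `TRUE` marks an
#'   epithelial cell.
#' @param step_index non-negative sweep counter.
#' @return An object of class `lattice_state`.
#' @export
lattice_state <- function(occupancy, step_index = 0L) {
  occ <- as_occupancy(occupancy)
  if (!any(occ)) stop("lattice must contain at least one cell")
  stopifnot(step_index >= 0)
  structure(list(occupancy = occ, step_index = as.integer(step_index)),
            class = "lattice_state")
}

#' @export
print.lattice_state <- function(x, ...) {
  cat(sprintf("Lattice state: %d x %d, %d cells, step %d\n",
              nrow(x$occupancy), ncol(x$occupancy), sum(x$occupancy),
              x$step_index))
  invisible(x)
}

#' Advance the automaton by one sweep
#'
#' Visits every cell present at sweep start exactly once, in a fresh
#' uniformly random permutation. A cell with no empty von Neumann
#' neighbour does nothing. Otherwise a move is proposed with probability
#' `p_move` (always executed, to a neighbour drawn by
#' [site_selection_probs()] with `beta_move`, subject to the optional
#' attachment rule) or a division with probability `1 - p_move`
#' (executed with probability [division_probability()], or `p_const`
#' when `gdnf_division` is off; the daughter is placed by
#' [site_selection_probs()] with `beta_div`). Cells created or moved
#' during the sweep are not revisited. Draws consume R's RNG stream in a
#' fixed order (permutation, then per cell: action, gate, site), so
#' `set.seed()` makes sweeps reproducible.
#'
#' @param state a [lattice_state()].
#' @param field a `gdnf_field` solved for `state`'s occupancy.
#' @param params a [model_params()].
#' @return The updated `lattice_state`, with attributes `divisions` and
#'   `moves` recording the number of executed events.
#' @export
ca_step <- function(state, field, params) {
  stopifnot(inherits(state, "lattice_state"),
            inherits(params, "model_params"))
  g <- if (inherits(field, "gdnf_field")) field$values else field
  if (!is.matrix(g) || !all(dim(g) == dim(state$occupancy)))
    stop("field and occupancy raster shapes differ")
  ans <- .ca_sweep(state$occupancy, g, params$p_move, params$c1,
                   params$c2,
                   if (params$chemotaxis) params$beta_move else 0,
                   if (params$acd) params$beta_div else 0,
                   params$gdnf_division, params$p_const,
                   params$attachment_rule)
  out <- lattice_state(ans$occupancy, state$step_index + 1L)
  attr(out, "divisions") <- ans$divisions
  attr(out, "moves") <- ans$moves
  out
}

#' Simulate the coupled automaton / growth-factor model
#'
#' Alternates a quasi-steady field solve (warm-started from the previous
#' sweep's field) with one automaton sweep, and records the occupancy at
#' each requested time. The sweep-to-hours mapping is
#' `params$steps_per_hour`; requested times are mapped to the nearest
#' sweep. Identical `seed`, `params` and mask give a bit-identical
#' trajectory. The caller's RNG state is restored on exit.
#'
#' @param initial_mask square logical matrix of the initial epithelial
#'   mass; must match `params$grid_size` and keep clear of the clamped
#'   boundary ring.
#' @param params a [model_params()].
#' @param record_times_h strictly increasing times (hours) at which to
#'   record; the first must be 0.
#' @param seed integer seed for the simulation's RNG stream.
#' @param record_fields logical; also keep the solved field at each
#'   recorded time.
#' @return An object of class `ca_trajectory`: list with `times_h`,
#'   `snapshots` (list of logical matrices), `cell_counts`, optional
#'   `fields`, `params`, `seed`.
#' @examples
#' mask <- make_initial_mass(shape_spec("ellipse", semi_axes = c(6, 4)),
#'                           grid_size = 40)
#' p <- model_params(grid_size = 40, steps_per_hour = 1)
#' tr <- simulate_branching(mask, p, record_times_h = c(0, 2), seed = 1)
#' tr$cell_counts
#' @export
simulate_branching <- function(initial_mask, params = model_params(),
                               record_times_h = c(0, 10, 20, 30),
                               seed = 1L, record_fields = FALSE) {
  occ <- as_occupancy(initial_mask)
  stopifnot(inherits(params, "model_params"))
  n <- nrow(occ)
  if (n != params$grid_size)
    stop("initial mask does not match params$grid_size")
  if (!any(occ)) stop("initial mask is empty")
  ring <- c(occ[1, ], occ[n, ], occ[, 1], occ[, n])
  if (any(ring))
    stop("initial mask touches the clamped boundary ring")
  stopifnot(is.numeric(record_times_h), length(record_times_h) >= 1,
            all(diff(record_times_h) > 0))
  if (record_times_h[1] != 0)
    stop("record_times_h must start at 0 (the initial mass)")

  fp <- field_params(d_g = lattice_diffusion(params),
                     tolerance = params$field$tolerance,
                     max_iterations = params$field$max_iterations,
                     omega = params$field$omega)
  record_steps <- as.integer(round(record_times_h * params$steps_per_hour))
  total_steps <- max(record_steps)

  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()),
            add = TRUE)
  }
  set.seed(seed)

  snapshots <- vector("list", length(record_steps))
  fields <- if (record_fields) vector("list", length(record_steps)) else NULL
  counts <- integer(length(record_steps))
  state <- lattice_state(occ)
  fld <- NULL
  rec <- function(idx, state, fld) {
    snapshots[[idx]] <<- state$occupancy
    counts[idx] <<- sum(state$occupancy)
    if (record_fields) fields[[idx]] <<- fld
  }
  if (record_steps[1] == 0L) {
    if (record_fields) fld <- solve_gdnf(state$occupancy, fp, fld)
    rec(1L, state, fld)
  }
  if (total_steps > 0L) {
    for (s in seq_len(total_steps)) {
      fld <- solve_gdnf(state$occupancy, fp, fld)
      state <- ca_step(state, fld, params)
      hit <- which(record_steps == s)
      if (length(hit)) rec(hit[1L], state, fld)
    }
  }
  structure(list(times_h = record_times_h, steps = record_steps,
                 snapshots = snapshots, cell_counts = counts,
                 fields = fields, params = params, seed = seed),
            class = "ca_trajectory")
}

#' @export
print.ca_trajectory <- function(x, ...) {
  cat(sprintf(
    "CA trajectory: %d x %d grid, %d snapshots (t = %s h), seed %d\n",
    x$params$grid_size, x$params$grid_size, length(x$snapshots),
    paste(x$times_h, collapse = ", "), x$seed))
  cat("  cell counts:", paste(x$cell_counts, collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.ca_trajectory <- function(x, which = length(x$snapshots), ...) {
  m <- x$snapshots[[which]]
  graphics::image(t(m)[, nrow(m):1], asp = 1, axes = FALSE,
                  col = c("white", "black"),
                  main = sprintf("t = %g h (%d cells)", x$times_h[which],
                                 x$cell_counts[which]), ...)
  invisible(x)
}
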