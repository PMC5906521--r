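#' Solver settings for the quasi-steady growth-factor field
#'
#' @param d_g positive working (lattice) diffusion coefficient: the
#'   dimensionless diffusion coefficient of the continuum equation with
#'   the unit grid spacing absorbed, so the discrete equation is
#'   `d_g * lap(g) = g` on occupied sites (see [solve_gdnf()]).
#' @param tolerance positive convergence tolerance on the max-norm
#'   residual of the discrete equation.
#' @param max_iterations positive integer iteration cap.
#' @param omega SOR over-relaxation factor in `(0, 2)`, or `NULL` for
#'   the classical near-optimal factor `2 / (1 + sin(pi / (N - 1)))`.
#' @return An object of class `field_params`.
#' @seealso [solve_gdnf()], [model_params()]
#' @export
field_params <- function(d_g = 1, tolerance = 1e-6,
                         max_iterations = 100000L, omega = NULL) {
  stopifnot(is.numeric(d_g), length(d_g) == 1L, is.finite(d_g), d_g > 0,
            is.numeric(tolerance), length(tolerance) == 1L, tolerance > 0,
            length(max_iterations) == 1L, max_iterations >= 1,
            is.null(omega) || (is.numeric(omega) && omega > 0 &&
                               omega < 2))
  structure(list(d_g = as.numeric(d_g), tolerance = as.numeric(tolerance),
                 max_iterations = as.integer(max_iterations),
                 omega = omega),
            class = "field_params")
}

#' Cellular-automaton model parameters
#'
#' Collects every constant of the coupled automaton / growth-factor model
#' plus the three mechanism toggles used in the ablation experiments.
#'
#' `d_g` is the dimensionless diffusion coefficient of the continuum
#' problem posed on the unit square. On an `N x N` grid the working
#' lattice coefficient passed to the solver is `d_g * (N - 1)^2`, so the
#' screening length of the field scales with the domain when the same
#' continuum problem is discretised at different resolutions. The
#' default (0.0015 on the default 120-grid, lattice value about 21) is
#' calibrated so that with the default initial mass the growth-factor
#' level at the rim of the mass straddles the division-switch midpoint
#' `-c1/c2`, the regime in which buds self-amplify and the explant
#' branches; larger values flood the mass with growth factor and give
#' compact, unbranched growth (see the methods vignette).
#'
#' @param grid_size lattice side length `N` (the domain is `N x N`).
#' @param d_g dimensionless continuum diffusion coefficient (> 0).
#' @param c1 location parameter of the probit division switch (usually
#'   negative, so cells do not divide without growth factor).
#' @param c2 sensitivity (slope) of the probit division switch.
#' @param p_move probability in `[0, 1]` that a proposed action is a move
#'   rather than a division.
#' @param beta_move chemotaxis sensitivity (softmax inverse temperature
#'   for move-site selection, >= 0).
#' @param beta_div anisotropic-cell-division sensitivity (softmax inverse
#'   temperature for daughter placement, >= 0).
#' @param gdnf_division logical; if `TRUE` the division gate is
#'   `Phi(c1 + c2 g)`, otherwise the constant `p_const`.
#' @param chemotaxis logical; if `FALSE` move destinations are chosen
#'   uniformly (equivalent to `beta_move = 0`).
#' @param acd logical; if `FALSE` daughter sites are chosen uniformly
#'   (equivalent to `beta_div = 0`).
#' @param p_const division probability used when `gdnf_division` is off.
#' @param attachment_rule logical; if `TRUE` a move is rejected when the
#'   destination site touches no occupied von Neumann neighbour other
#'   than the mover's origin.
#' @param steps_per_hour positive number of automaton sweeps per
#'   simulated hour.
#' @param field a [field_params()] object providing solver tolerance and
#'   iteration cap; its `d_g` is ignored (recomputed from `d_g` and
#'   `grid_size`).
#' @return An object of class `model_params`.
#' @export
model_params <- function(grid_size = 120L, d_g = 0.0015, c1 = -25,
                         c2 = 120, p_move = 0.5, beta_move = 50,
                         beta_div = 50, gdnf_division = TRUE,
                         chemotaxis = TRUE, acd = TRUE, p_const = 0.5,
                         attachment_rule = FALSE, steps_per_hour = 1,
                         field = field_params()) {
  stopifnot(length(grid_size) == 1L, grid_size >= 3,
            is.numeric(d_g), d_g > 0,
            is.numeric(c1), length(c1) == 1L, is.finite(c1),
            is.numeric(c2), length(c2) == 1L, is.finite(c2),
            is.numeric(p_move), p_move >= 0, p_move <= 1,
            is.numeric(beta_move), beta_move >= 0,
            is.numeric(beta_div), beta_div >= 0,
            is.logical(gdnf_division), is.logical(chemotaxis),
            is.logical(acd), is.logical(attachment_rule),
            is.numeric(p_const), p_const >= 0, p_const <= 1,
            is.numeric(steps_per_hour), steps_per_hour > 0,
            inherits(field, "field_params"))
  structure(list(grid_size = as.integer(grid_size), d_g = d_g, c1 = c1,
                 c2 = c2, p_move = p_move, beta_move = beta_move,
                 beta_div = beta_div, gdnf_division = gdnf_division,
                 chemotaxis = chemotaxis, acd = acd, p_const = p_const,
                 attachment_rule = attachment_rule,
                 steps_per_hour = steps_per_hour, field = field),
            class = "model_params")
}

#' Working lattice diffusion coefficient for a parameter set
#'
#' Converts the continuum dimensionless diffusion coefficient to the
#' lattice value used by the discrete solver, `d_g * (N - 1)^2`.
#'
#' @param params a [model_params()] object.
#' @return A positive scalar.
#' @export
lattice_diffusion <- function(params) {
  stopifnot(inherits(params, "model_params"))
  params$d_g * (params$grid_size - 1)^2
}

#' @export
print.model_params <- function(x, ...) {
  cat("Cellular-automaton model parameters\n")
  cat(sprintf("  grid %d x %d, d_g = %g (lattice %.3g), %g sweeps/h\n",
              x$grid_size, x$grid_size, x$d_g, lattice_diffusion(x),
              x$steps_per_hour))
  cat(sprintf("  division switch: Phi(%g + %g g)  (midpoint g = %.4g)\n",
              x$c1, x$c2, -x$c1 / x$c2))
  cat(sprintf("  p_move = %g, beta_move = %g, beta_div = %g, p_const = %g\n",
              x$p_move, x$beta_move, x$beta_div, x$p_const))
  cat(sprintf(
    "  toggles: gdnf_division=%s chemotaxis=%s acd=%s attachment=%s\n",
    x$gdnf_division, x$chemotaxis, x$acd, x$attachment_rule))
  invisible(x)
}

#' @export
print.field_params <- function(x, ...) {
  cat(sprintf("Field solver: d_g = %g, tol = %g, max %d iterations\n",
              x$d_g, x$tolerance, x$max_iterations))
  invisible(x)
}
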