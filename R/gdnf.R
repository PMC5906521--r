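#' Solve the quasi-steady growth-factor field
#'
#' Solves the dimensionless quasi-steady reaction--diffusion problem
#' `d_g lap(g) = g` on occupied (epithelial) lattice sites and
#' `lap(g) = 0` on empty (ECM) sites, with `g = 1` clamped on the
#' outermost ring of grid points (the far-field supply). The 5-point
#' finite-difference discretisation is relaxed by red--black
#' Gauss--Seidel sweeps until the max-norm residual of the discrete
#' equation falls below `params$tolerance`.
#'
#' Because uptake is linear each relaxation update is a convex map of
#' values in `[0, 1]`, so every iterate -- and therefore the returned
#' field -- satisfies the discrete maximum principle `0 <= g <= 1`.
#' Occupied sites on the clamped boundary ring keep `g = 1`: the
#' boundary condition takes precedence over uptake (initial masses are
#' required to stay clear of the ring, see [simulate_branching()]).
#'
#' @param occupancy square logical (or 0/1) matrix, `TRUE` = epithelial
#'   cell, `FALSE` = ECM; side length at least 3.
#' @param params a [field_params()] object; `params$d_g` is the working
#'   lattice diffusion coefficient (unit grid spacing absorbed).
#' @param warm_start optional previous `gdnf_field` (or plain matrix) of
#'   matching shape used as the starting iterate.
#' @return An object of class `gdnf_field` with elements `values`
#'   (numeric matrix), `residual`, `iterations` and `d_g`.
#' @examples
#' occ <- matrix(FALSE, 21, 21); occ[9:13, 9:13] <- TRUE
#' f <- solve_gdnf(occ, field_params(d_g = 5))
#' range(f$values)
#' @export
solve_gdnf <- function(occupancy, params = field_params(),
                       warm_start = NULL) {
  occ <- as_occupancy(occupancy)
  stopifnot(inherits(params, "field_params"))
  ws <- NULL
  if (!is.null(warm_start)) {
    ws <- if (inherits(warm_start, "gdnf_field")) warm_start$values
          else warm_start
    if (!is.matrix(ws) || !all(dim(ws) == dim(occ)))
      stop("warm start does not match the occupancy raster shape")
    storage.mode(ws) <- "double"
  }
  ans <- .gdnf_sor(occ, params$d_g, params$tolerance,
                   params$max_iterations, ws, params$omega %||% -1)
  if (!ans$converged) {
    cond <- structure(
      class = c("branchca_no_convergence", "error", "condition"),
      list(message = sprintf(
             "field solve did not converge: residual %.3e > %.3e after %d iterations",
             ans$residual, params$tolerance, ans$iterations),
           call = sys.call(-1), residual = ans$residual))
    stop(cond)
  }
  structure(list(values = ans$values, residual = ans$residual,
                 iterations = ans$iterations, d_g = params$d_g),
            class = "gdnf_field")
}

# coerce to a validated square logical occupancy matrix
as_occupancy <- function(x) {
  if (inherits(x, "lattice_state")) x <- x$occupancy
  if (!is.matrix(x)) stop("occupancy must be a matrix")
  if (nrow(x) != ncol(x)) stop("occupancy raster must be square")
  if (nrow(x) < 3) stop("occupancy raster must be at least 3 x 3")
  if (is.numeric(x)) {
    if (!all(x %in% c(0, 1))) stop("numeric occupancy must be 0/1")
    x <- x > 0.5
  }
  if (!is.logical(x)) stop("occupancy must be logical or 0/1 numeric")
  if (anyNA(x)) stop("occupancy contains missing values")
  x
}

#' @export
print.gdnf_field <- function(x, ...) {
  cat(sprintf(
    "Quasi-steady GDNF field: %d x %d, d_g = %g\n  residual %.3e after %d iterations, range [%.4f, %.4f]\n",
    nrow(x$values), ncol(x$values), x$d_g, x$residual, x$iterations,
    min(x$values), max(x$values)))
  invisible(x)
}

#' @export
as.matrix.gdnf_field <- function(x, ...) x$values

#' @export
plot.gdnf_field <- function(x, ...) {
  v <- x$values
  graphics::image(t(v)[, nrow(v):1], asp = 1, axes = FALSE,
                  col = grDevices::hcl.colors(64, "viridis"),
                  main = "dimensionless GDNF concentration", ...)
  invisible(x)
}

#' Write a field snapshot to disk
#'
#' @param field a `gdnf_field`.
#' @param path output file; format chosen by extension (`.csv` headerless
#'   grid, or `.tif`/`.tiff` 32-bit float, requires the tiff package).
#' @return `path`, invisibly.
#' @export
write_field <- function(field, path) {
  stopifnot(inherits(field, "gdnf_field"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    write.table(field$values, path, sep = ",", row.names = FALSE,
                col.names = FALSE)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("the tiff package is required to write TIFF snapshots")
    tiff::writeTIFF(field$values, path, bits.per.sample = 32L)
  } else stop("unsupported field format: ", ext)
  invisible(path)
}
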