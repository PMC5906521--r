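#' Extract the bulk epithelial mass from a grayscale frame
#'
#' Thresholds the image (Otsu's method by default), fills interior
#' holes, and keeps the largest 8-connected foreground component -- the
#' same bulk-mass extraction applied to explant movie frames and to
#' automaton rasters before skeletonisation.
#'
#' @param image numeric matrix of intensities; any non-negative scale
#'   (values are rescaled to `[0, 1]` internally).
#' @param threshold `"otsu"` or a fixed numeric cut on the rescaled
#'   intensities.
#' @return Square-free logical mask of the bulk mass.
#' @export
extract_bulk_mass <- function(image, threshold = "otsu") {
  if (!is.matrix(image) || !is.numeric(image) || length(image) == 0L)
    stop("image must be a non-empty numeric matrix")
  img <- image
  mx <- max(img)
  if (mx > 1) img <- img / mx
  if (identical(threshold, "otsu")) {
    if (length(unique(as.vector(img))) < 2L) {
      # flat image: Otsu is undefined; treat positives as foreground
      mask <- img > 0
    } else {
      th <- EBImage::otsu(EBImage::Image(img))
      mask <- img > th
    }
  } else {
    stopifnot(is.numeric(threshold), length(threshold) == 1L)
    mask <- img > threshold
  }
  if (!any(mask)) {
    cond <- structure(
      class = c("branchca_empty_mask", "error", "condition"),
      list(message = "no foreground pixels after thresholding",
           call = sys.call(-1)))
    stop(cond)
  }
  mask <- EBImage::fillHull(EBImage::Image(mask + 0)) > 0.5
  mask <- matrix(as.logical(mask), nrow(image), ncol(image))
  lab <- .label8(mask)
  sizes <- tabulate(lab[lab > 0])
  mask & (lab == which.max(sizes))
}

#' Medial-axis skeleton and branch points of a binary mass
#'
#' Optionally smooths the mask morphologically (closing followed by
#' opening with a disc: automaton rasters are jagged at the lattice
#' scale, and both single-cell indentations and single-cell protrusions
#' would otherwise spawn spurious skeleton branches), thins it to a
#' topology-preserving medial-axis skeleton, prunes terminal spurs
#' shorter than `spur_min_length` pixels, and marks branch points:
#' 8-connected clusters of skeleton pixels with at least 3 skeleton
#' neighbours, each cluster counted once (thinning emits 2--3 adjacent
#' junction pixels for a single biological branch point).
#'
#' @param mask logical matrix with at least one `TRUE` pixel.
#' @param spur_min_length non-negative integer; terminal skeleton
#'   branches shorter than this are removed before counting.
#' @param presmooth_radius non-negative integer radius of the disc used
#'   for the morphological smoothing before thinning (0 = no smoothing;
#'   use 0 for already-smooth masks, and note that structures thinner
#'   than the disc do not survive the opening).
#' @return An object of class `skeleton`: list with `pixels` (logical
#'   matrix), `branch_points` (two-column matrix of cluster centroids,
#'   row/col), `n_branch_points`, and the smoothed `mask` that was
#'   thinned.
#' @examples
#' m <- matrix(FALSE, 30, 30); m[14:16, 4:26] <- TRUE; m[4:26, 14:16] <- TRUE
#' skeletonize(m, spur_min_length = 0, presmooth_radius = 0)$n_branch_points
#' @export
skeletonize <- function(mask, spur_min_length = 5L, presmooth_radius = 2L) {
  if (!is.matrix(mask)) stop("mask must be a matrix")
  if (is.numeric(mask)) mask <- mask > 0.5
  if (!any(mask)) stop("mask is empty")
  stopifnot(spur_min_length >= 0, presmooth_radius >= 0)
  sm <- mask
  if (presmooth_radius > 0) {
    brush <- EBImage::makeBrush(2L * as.integer(presmooth_radius) + 1L,
                                shape = "disc")
    img <- EBImage::closing(EBImage::Image(mask + 0), brush)
    img <- EBImage::opening(img, brush)
    sm <- matrix(as.logical(img > 0.5), nrow(mask), ncol(mask))
    if (!any(sm)) sm <- mask  # mask thinner than the brush: skip smoothing
  }
  skel <- .thin_mask(sm)
  skel <- .prune_spurs(skel, as.integer(spur_min_length))
  deg <- .neighbour_degree8(skel)
  bp_mask <- !is.na(deg) & deg >= 3L
  bp <- matrix(numeric(0), 0, 2,
               dimnames = list(NULL, c("row", "col")))
  if (any(bp_mask)) {
    lab <- .label8(bp_mask)
    ids <- sort(unique(lab[lab > 0]))
    bp <- t(vapply(ids, function(id) {
      w <- which(lab == id, arr.ind = TRUE)
      colMeans(w)
    }, numeric(2)))
    colnames(bp) <- c("row", "col")
  }
  structure(list(pixels = skel, branch_points = bp,
                 n_branch_points = nrow(bp), mask = sm),
            class = "skeleton")
}

# bulk-mass cleanup shared with extract_bulk_mass(): fill interior
# holes, keep the largest 8-connected component
bulk_mask <- function(m) {
  m <- EBImage::fillHull(EBImage::Image(m + 0)) > 0.5
  m <- matrix(as.logical(m), nrow(m), ncol(m))
  lab <- .label8(m)
  m & (lab == which.max(tabulate(lab[lab > 0])))
}

#' Branch-point count of a mask or skeleton
#'
#' @param x a logical mask or a `skeleton` object.
#' @param ... passed to [skeletonize()] when `x` is a mask.
#' @return Integer number of branch points.
#' @export
branch_count <- function(x, ...) {
  if (inherits(x, "skeleton")) return(x$n_branch_points)
  skeletonize(x, ...)$n_branch_points
}

#' @export
print.skeleton <- function(x, ...) {
  cat(sprintf("Skeleton: %d pixels, %d branch point(s)\n",
              sum(x$pixels), x$n_branch_points))
  invisible(x)
}

#' @export
plot.skeleton <- function(x, ...) {
  m <- matrix(0, nrow(x$mask), ncol(x$mask))
  m[x$mask] <- 1
  m[x$pixels] <- 2
  graphics::image(t(m)[, nrow(m):1], asp = 1, axes = FALSE,
                  col = c("white", "grey80", "black"), ...)
  if (nrow(x$branch_points)) {
    nr <- nrow(x$mask); nc <- ncol(x$mask)
    graphics::points((x$branch_points[, "col"] - 1) / (nc - 1),
                     1 - (x$branch_points[, "row"] - 1) / (nr - 1),
                     col = "red", pch = 4, lwd = 2)
  }
  invisible(x)
}

#' Summary statistics of a simulated trajectory
#'
#' Computes the two summary statistics used throughout: the area of the
#' mass normalised by its area at `t = 0` (the cell-number proxy, taken
#' from the raw occupancy), and the skeleton branch-point count, at
#' each requested time. Before skeletonisation each snapshot gets the
#' same bulk-mass cleanup applied to experimental frames: interior
#' holes are filled and only the largest 8-connected component is kept,
#' so stray detached cells do not contaminate the skeleton.
#'
#' @param traj a `ca_trajectory` from [simulate_branching()], recorded
#'   at (at least) the requested times including `t = 0`.
#' @param times_h times (hours) to summarise; defaults to all recorded
#'   times.
#' @param spur_min_length,presmooth_radius passed to [skeletonize()].
#' @param replicate_id integer identifier stored with the rows.
#' @return A `summary_dataset`: data frame with columns `replicate_id`,
#'   `time_h`, `normalised_area`, `branch_count`.
#' @export
summarise_trajectory <- function(traj, times_h = traj$times_h,
                                 spur_min_length = 5L,
                                 presmooth_radius = 2L,
                                 replicate_id = 1L) {
  stopifnot(inherits(traj, "ca_trajectory"))
  if (!0 %in% traj$times_h)
    stop("trajectory has no t = 0 snapshot to normalise by")
  idx <- match(times_h, traj$times_h)
  if (anyNA(idx))
    stop("requested times not present in the trajectory: ",
         paste(times_h[is.na(idx)], collapse = ", "))
  area0 <- sum(traj$snapshots[[match(0, traj$times_h)]])
  rows <- lapply(idx, function(i) {
    m <- traj$snapshots[[i]]
    data.frame(replicate_id = as.integer(replicate_id),
               time_h = traj$times_h[i],
               normalised_area = sum(m) / area0,
               branch_count = branch_count(
                 bulk_mask(m), spur_min_length = spur_min_length,
                 presmooth_radius = presmooth_radius))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("summary_dataset", "data.frame")
  out
}

#' Flatten a summary dataset into the AABC summary vector
#'
#' The comparison vector used by inference: normalised areas then branch
#' counts at the post-initial time points (default 10, 20, 30 h).
#'
#' @param ds a `summary_dataset` (single replicate).
#' @param times_h time points to include.
#' @return Named numeric vector of length `2 * length(times_h)`.
#' @export
summary_vector <- function(ds, times_h = c(10, 20, 30)) {
  idx <- match(times_h, ds$time_h)
  if (anyNA(idx)) stop("summary dataset lacks requested time points")
  setNames(c(ds$normalised_area[idx], ds$branch_count[idx]),
           c(paste0("area_t", times_h), paste0("branches_t", times_h)))
}
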