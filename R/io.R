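#' Read and write binary masks
#'
#' Masks travel as PNG (0/255), headerless CSV grids of 0/1, or TIFF
#' (if the tiff package is installed); the format follows the file
#' extension.
#'
#' @param path file path.
#' @return `read_mask()` returns a logical matrix; `write_mask()`
#'   returns `path` invisibly.
#' @export
read_mask <- function(path) {
  ext <- tolower(tools::file_ext(path))
  m <- switch(ext,
    png = png::readPNG(path),
    csv = as.matrix(read.csv(path, header = FALSE)),
    tif = , tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("the tiff package is required to read TIFF masks")
      tiff::readTIFF(path)
    },
    stop("unsupported mask format: ", ext))
  if (length(dim(m)) == 3L) m <- m[, , 1]
  matrix(m > 0.5, nrow(m), ncol(m))
}

#' @param mask logical matrix.
#' @rdname read_mask
#' @export
write_mask <- function(mask, path) {
  stopifnot(is.matrix(mask))
  if (is.numeric(mask)) mask <- mask > 0.5
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(mask * 1, path),
    csv = write.table(mask * 1L, path, sep = ",", row.names = FALSE,
                      col.names = FALSE),
    tif = , tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("the tiff package is required to write TIFF masks")
      tiff::writeTIFF(mask * 1, path)
    },
    stop("unsupported mask format: ", ext))
  invisible(path)
}

#' Read and write summary-statistic tables
#'
#' CSV with columns `replicate_id`, `time_h`, `normalised_area`,
#' `branch_count`.
#'
#' @param path file path.
#' @return `read_summaries()` returns a `summary_dataset` data frame.
#' @export
read_summaries <- function(path) {
  df <- read.csv(path)
  need <- c("replicate_id", "time_h", "normalised_area", "branch_count")
  if (!all(need %in% names(df)))
    stop("summary CSV must have columns: ", paste(need, collapse = ", "))
  class(df) <- c("summary_dataset", "data.frame")
  df
}

#' @param ds a `summary_dataset` (or rbind of several).
#' @rdname read_summaries
#' @export
write_summaries <- function(ds, path) {
  write.csv(as.data.frame(ds), path, row.names = FALSE)
  invisible(path)
}

#' Resolve a configuration list into model parameters
#'
#' Configurations round-trip through YAML: top-level keys `model`
#' (arguments of [model_params()]), `field` (`tolerance`,
#' `max_iterations`), `morphometrics` (`spur_min_length`,
#' `presmooth_radius`), `times_h`, and `seed`. Unknown keys are
#' rejected.
#'
#' @param config a list (e.g. from [read_config()]).
#' @return List with `params` ([model_params()]), `morphometrics`,
#'   `times_h` and `seed`.
#' @export
resolve_config <- function(config) {
  stopifnot(is.list(config))
  known <- c("model", "field", "morphometrics", "times_h", "seed")
  extra <- setdiff(names(config), known)
  if (length(extra)) stop("unknown config keys: ",
                          paste(extra, collapse = ", "))
  fld <- do.call(field_params,
                 c(list(d_g = 1), config$field %||% list()))
  params <- do.call(model_params,
                    c(config$model %||% list(), list(field = fld)))
  morpho <- modifyList(list(spur_min_length = 5L, presmooth_radius = 2L),
                       config$morphometrics %||% list())
  list(params = params,
       morphometrics = morpho,
       times_h = config$times_h %||% c(0, 10, 20, 30),
       seed = config$seed %||% 1L)
}

#' Read or write a YAML run configuration
#'
#' @param path YAML file path.
#' @return `read_config()` returns the resolved configuration (see
#'   [resolve_config()]); `write_config()` returns `path` invisibly.
#' @export
read_config <- function(path) resolve_config(yaml::read_yaml(path))

#' @param config a plain configuration list (the YAML structure, not the
#'   resolved form).
#' @rdname read_config
#' @export
write_config <- function(config, path) {
  resolve_config(config)  # validate before writing
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Persist or reload a pilot library
#'
#' A pilot library is stored as a directory holding `thetas.json` (the
#' parameter triples plus prior bounds, time points, scalings and
#' seed) and `summaries.csv` (one row per particle x replicate with
#' the stored summary vector).
#'
#' @param library a [build_pilot_library()] result.
#' @param dir directory to create/read.
#' @return `write_pilot_library()` returns `dir` invisibly;
#'   `read_pilot_library()` returns a `pilot_library`.
#' @export
write_pilot_library <- function(library, dir) {
  stopifnot(inherits(library, "pilot_library"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(thetas = as.data.frame(library$thetas),
               prior = as.data.frame(library$prior$bounds),
               times_h = library$times_h,
               n_replicates = library$n_replicates,
               summary_sd = library$summary_sd,
               seed = library$seed)
  jsonlite::write_json(meta, file.path(dir, "thetas.json"),
                       auto_unbox = TRUE, digits = NA)
  m <- dim(library$summaries)[1]
  nrep <- dim(library$summaries)[2]
  rows <- do.call(rbind, lapply(seq_len(m), function(i)
    do.call(rbind, lapply(seq_len(nrep), function(r)
      data.frame(particle = i, replicate = r,
                 t(library$summaries[i, r, ]))))))
  names(rows)[-(1:2)] <- c(paste0("area_t", library$times_h),
                           paste0("branches_t", library$times_h))
  write.csv(rows, file.path(dir, "summaries.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_pilot_library
#' @export
read_pilot_library <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "thetas.json"),
                              simplifyVector = TRUE)
  thetas <- as.matrix(meta$thetas)
  prior <- prior_spec(c1 = unlist(meta$prior["c1", ]),
                      c2 = unlist(meta$prior["c2", ]),
                      p_move = unlist(meta$prior["p_move", ]))
  rows <- read.csv(file.path(dir, "summaries.csv"))
  m <- max(rows$particle)
  nrep <- max(rows$replicate)
  d <- ncol(rows) - 2L
  summaries <- array(NA_real_, c(m, nrep, d))
  for (idx in seq_len(nrow(rows)))
    summaries[rows$particle[idx], rows$replicate[idx], ] <-
      as.numeric(rows[idx, -(1:2)])
  structure(list(thetas = thetas, summaries = summaries,
                 times_h = meta$times_h, prior = prior,
                 params = NULL,
                 n_replicates = as.integer(nrep),
                 theta_scale = prior$bounds[, "high"] -
                   prior$bounds[, "low"],
                 summary_sd = meta$summary_sd, seed = meta$seed,
                 mask = NULL),
            class = "pilot_library")
}

#' Write a reproducibility manifest for a run
#'
#' Records the resolved configuration, seeds, package version and input
#' file digests as JSON next to a run's outputs.
#'
#' @param path output JSON path.
#' @param config the plain configuration list used.
#' @param inputs named character vector of input file paths (digested
#'   with MD5).
#' @param extra optional named list of additional fields.
#' @export
write_manifest <- function(path, config = list(), inputs = character(),
                           extra = list()) {
  digests <- if (length(inputs)) as.list(tools::md5sum(inputs)) else NULL
  manifest <- c(list(
    package = "branchca",
    version = as.character(utils::packageVersion("branchca")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    config = config,
    input_md5 = digests), extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}
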