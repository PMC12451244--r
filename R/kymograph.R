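#' Space-time kymograph container
#'
#' A scalar field sampled on a rectangular (time x position) grid, with
#' explicit units and position-axis convention. Missing cells are carried in
#' a logical mask (and as `NA` in `values`).
#'
#' @param field_name name of the field (e.g. `"curvature"`).
#' @param times strictly increasing sample times (h).
#' @param positions strictly increasing positions (mm).
#' @param values numeric matrix, `length(times)` rows x `length(positions)`
#'   columns.
#' @param units unit string for the values.
#' @param axis_origin `"from_base"` or `"from_apex"`: whether `positions`
#'   are measured from the clamped base or as apex distances.
#' @param mask optional logical matrix, `TRUE` where data are missing;
#'   defaults to `is.na(values)`.
#' @return an object of class `kymograph`.
#' @export
kymograph <- function(field_name, times, positions, values, units,
                      axis_origin = c("from_base", "from_apex"),
                      mask = NULL) {
  axis_origin <- match.arg(axis_origin)
  values <- as.matrix(values)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(diff(positions) <= 0)) stop("positions must be strictly increasing")
  if (!all(dim(values) == c(length(times), length(positions)))) {
    stop("values must be a length(times) x length(positions) matrix")
  }
  if (is.null(mask)) mask <- is.na(values)
  values[mask] <- NA_real_
  dimnames(values) <- NULL
  dimnames(mask) <- NULL
  structure(list(field_name = field_name, times = as.numeric(times),
                 positions = as.numeric(positions), values = values,
                 units = units, axis_origin = axis_origin, mask = mask),
            class = "kymograph")
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf("kymograph '%s' [%s]: %d times x %d positions (%s), %.1f%% masked\n",
              x$field_name, x$units, length(x$times), length(x$positions),
              x$axis_origin, 100 * mean(x$mask)))
  invisible(x)
}

#' @export
as.data.frame.kymograph <- function(x, ...) {
  data.frame(t = rep(x$times, times = length(x$positions)),
             position = rep(x$positions, each = length(x$times)),
             value = as.vector(x$values))
}

#' Write / read a kymograph as tabular text with a JSON header
#'
#' The on-disk format is a `#` JSON header line carrying the field name,
#' units and axis convention, followed by a CSV table whose first column is
#' time and remaining columns are positions. The round trip is lossless.
#'
#' @param kymo a [kymograph()].
#' @param path file path.
#' @return `write_kymograph` returns `path` invisibly; `read_kymograph`
#'   returns the [kymograph()].
#' @export
write_kymograph <- function(kymo, path) {
  hdr <- jsonlite::toJSON(list(field_name = kymo$field_name, units = kymo$units,
                               axis_origin = kymo$axis_origin,
                               time_units = "h", position_units = "mm"),
                          auto_unbox = TRUE, digits = NA)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", hdr), con)
  m <- cbind(kymo$times, kymo$values)
  colnames(m) <- c("t", format(kymo$positions, digits = 17, trim = TRUE, scientific = FALSE))
  utils::write.csv(format(as.data.frame(m), digits = 17, trim = TRUE),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_kymograph
#' @export
read_kymograph <- function(path) {
  first <- readLines(path, n = 1L)
  if (!startsWith(first, "#")) stop("missing JSON header line in ", path)
  hdr <- jsonlite::fromJSON(sub("^#", "", first))
  tab <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  times <- tab[[1L]]
  positions <- as.numeric(colnames(tab)[-1L])
  kymograph(hdr$field_name, times, positions, as.matrix(tab[, -1L, drop = FALSE]),
            units = hdr$units, axis_origin = hdr$axis_origin)
}

#' Serialize a rachis trajectory to tabular text
#'
#' One row per marker per time (`id, t, s, C, theta, x, y`), with the
#' generating parameters in a JSON sidecar (same path with extension
#' `.params.json`).
#'
#' @param traj a `rachis_trajectory`.
#' @param path CSV file path.
#' @return `write_trajectory` returns `path` invisibly; `read_trajectory`
#'   the reconstructed `rachis_trajectory`.
#' @export
write_trajectory <- function(traj, path) {
  nt <- length(traj$times); nm <- length(traj$material_ids)
  df <- data.frame(id = rep(traj$material_ids, each = nt),
                   t = rep(traj$times, times = nm),
                   s = as.vector(traj$s), C = as.vector(traj$C),
                   theta = as.vector(traj$theta),
                   x = as.vector(traj$x), y = as.vector(traj$y))
  utils::write.csv(format(df, digits = 17, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(unclass(traj$params),
                       paste0(tools::file_path_sans_ext(path), ".params.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- utils::read.csv(path)
  pfile <- paste0(tools::file_path_sans_ext(path), ".params.json")
  params <- if (file.exists(pfile)) {
    do.call(growth_params, jsonlite::fromJSON(pfile))
  } else NULL
  ids <- sort(unique(df$id))
  times <- sort(unique(df$t))
  df <- df[order(df$id, df$t), ]
  shape <- function(v) matrix(v, length(times), length(ids))
  structure(list(times = times, material_ids = ids,
                 s = shape(df$s), C = shape(df$C), theta = shape(df$theta),
                 x = shape(df$x), y = shape(df$y),
                 apex_s = shape(df$s)[, length(ids)],
                 params = params),
            class = "rachis_trajectory")
}
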