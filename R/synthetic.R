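#' Synthetic fluorescent node-marker tracks
#'
#' Places `n_nodes` markers at fixed material coordinates along the organ
#' (emulating the leaflet nodes), advects them with the simulated growth,
#' projects them into the requested observation plane, and corrupts them
#' with Gaussian positional jitter and random frame dropouts (emulating
#' marker fading/occlusion). With zero noise and zero dropout the tracks
#' equal the projected material positions exactly; identical seeds give
#' identical tracks.
#'
#' @param traj a `rachis_trajectory`.
#' @param n_nodes number of nodes (>= 2, at most the marker count).
#' @param noise_sd positional jitter standard deviation (mm).
#' @param dropout_p per-frame probability that a node is invisible.
#' @param seed integer seed.
#' @param frame_dt frame interval (h); default 2.5 min, the top-view
#'   acquisition cadence emulated by this generator.
#' @param setup a [projection_setup()]; default top view.
#' @param span fraction `c(lo, hi)` of the initial length covered by the
#'   node material positions.
#' @return an object of class `node_tracks`: a data.frame with columns
#'   `node_id`, `t` (h), `u`, `v` (image-plane mm) and `visible`, plus the
#'   apex track as attribute `apex` (data.frame `t`, `apex_pos`).
#' @export
make_node_tracks <- function(traj, n_nodes = 12L, noise_sd = 0.05,
                             dropout_p = 0.02, seed = 1L,
                             frame_dt = 2.5 / 60,
                             setup = projection_setup("top"),
                             span = c(0.05, 0.98)) {
  nm <- length(traj$material_ids)
  if (n_nodes < 2L) stop("n_nodes must be >= 2")
  if (n_nodes > nm) stop("n_nodes exceeds the trajectory marker count")
  times <- seq(min(traj$times), max(traj$times), by = frame_dt)
  # fixed material coordinates: fractions of initial arclength
  s0 <- seq(span[1L], span[2L], length.out = n_nodes) * traj$s[1L, nm]
  pos <- node_positions(traj, s0, times, setup)
  old_seed <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  nt <- length(times)
  df <- data.frame(node_id = rep(seq_len(n_nodes), each = nt),
                   t = rep(times, n_nodes),
                   u = as.vector(pos$u) + stats::rnorm(nt * n_nodes, 0, noise_sd),
                   v = as.vector(pos$v) + stats::rnorm(nt * n_nodes, 0, noise_sd),
                   visible = stats::runif(nt * n_nodes) >= dropout_p)
  nmk <- ncol(traj$s)
  apex_uv <- node_positions(traj, traj$s[1L, nmk] * (1 - 1e-9), times, setup)
  apex <- data.frame(t = times,
                     apex_pos = stats::approx(traj$times, traj$apex_s, times, rule = 2)$y,
                     u = apex_uv$u[, 1L] + stats::rnorm(nt, 0, noise_sd),
                     v = apex_uv$v[, 1L] + stats::rnorm(nt, 0, noise_sd))
  structure(df, class = c("node_tracks", "data.frame"), apex = apex)
}

# interpolate material points (initial arclengths s0) through the trajectory
# and project: returns u, v matrices (time x node), image-plane mm
node_positions <- function(traj, s0, times, setup) {
  n_nodes <- length(s0)
  nt <- length(times)
  u <- v <- matrix(NA_real_, nt, n_nodes)
  # material interpolation weights fixed at t = 0
  s_init <- traj$s[1L, ]
  idx <- findInterval(s0, s_init, rightmost.closed = TRUE)
  w <- (s0 - s_init[idx]) / (s_init[idx + 1L] - s_init[idx])
  interp_t <- function(m) {
    # columns: markers; interpolate each needed marker column in time
    vapply(seq_len(n_nodes), function(j) {
      a <- stats::approx(traj$times, m[, idx[j]], times, rule = 2)$y
      b <- stats::approx(traj$times, m[, idx[j] + 1L], times, rule = 2)$y
      (1 - w[j]) * a + w[j] * b
    }, numeric(nt))
  }
  x <- interp_t(traj$x)
  y <- interp_t(traj$y)
  if (setup$plane_label == "top") {
    u[] <- x; v[] <- y
  } else {
    # side view: image abscissa = in-plane coordinate along view_angle,
    # ordinate = out-of-plane height (0 for planar bending)
    u[] <- x * cos(setup$view_angle) + y * sin(setup$view_angle)
    v[] <- 0
  }
  list(u = u, v = v)
}

#' Render speckle-textured frames of the projected organ
#'
#' Draws the organ as a band of width `W` carrying a random speckle texture
#' defined in material coordinates, so that texture features are advected by
#' growth and their contrast is diluted where the tissue stretches, plus
#' additive sensor noise. Side views show the planar organ edge-on (a
#' horizontal band whose texture moves by the projected material
#' displacement); top views show the bent midline.
#'
#' @param traj a `rachis_trajectory`.
#' @param texture_corr_len speckle correlation length (mm); must exceed
#'   `2 * mm_per_px`.
#' @param mm_per_px image scale.
#' @param noise_sd additive intensity noise SD (intensity units, images are
#'   in `[0, 1]`).
#' @param seed integer seed.
#' @param frame_dt frame interval (h); default 1 min, the side-view cadence.
#' @param t_max render frames up to this time (default: full trajectory).
#' @param setup a [projection_setup()]; default side view.
#' @param pad_mm margin around the organ (mm).
#' @return an object of class `frame_sequence`: list with `times`, `images`
#'   (list of matrices, rows = image y downward, cols = image x),
#'   `mm_per_px`, `plane_label`, `origin_mm` (image-plane coordinates of
#'   pixel (1,1) centre).
#' @export
render_frames <- function(traj, texture_corr_len = 1.5, mm_per_px = 0.25,
                          noise_sd = 0.01, seed = 1L, frame_dt = 1 / 60,
                          t_max = NULL, setup = projection_setup("side"),
                          pad_mm = 2) {
  if (texture_corr_len < 2 * mm_per_px) {
    stop("resolution too coarse for texture_corr_len (need >= 2 px per correlation length)")
  }
  t_max <- t_max %||% max(traj$times)
  times <- seq(min(traj$times), t_max, by = frame_dt)
  old_seed <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  # material speckle on a fine fixed grid of initial arclength
  du <- mm_per_px / 2
  ugrid <- seq(0, traj$s[1L, ncol(traj$s)], by = du)
  k <- max(3L, 2L * ceiling(texture_corr_len / du) + 1L)
  tex <- stats::filter(stats::runif(length(ugrid) + 2L * k) - 0.5, rep(1 / k, k),
                       sides = 2)
  tex <- tex[(k + 1L):(k + length(ugrid))]
  tex <- tex / stats::sd(tex, na.rm = TRUE) * 0.35
  tex[is.na(tex)] <- 0
  W <- traj$params$W
  # interpolate marker states at frame times
  interp_all <- function(m, tt) apply(m, 2L, function(col) stats::approx(traj$times, col, tt, rule = 2)$y)
  images <- vector("list", length(times))
  if (setup$plane_label == "side") {
    x_end <- max(traj$x) * 1.02 + pad_mm
    ncol_px <- ceiling((x_end + pad_mm) / mm_per_px)
    nrow_px <- ceiling((W + 2 * pad_mm) / mm_per_px)
    band <- abs((seq_len(nrow_px) - (nrow_px + 1) / 2) * mm_per_px) <= W / 2
    xs_px <- (seq_len(ncol_px) - 0.5) * mm_per_px - pad_mm
    for (i in seq_along(times)) {
      st <- lapply(traj[c("s", "x")], function(m) {
        apply(m, 2L, function(col) stats::approx(traj$times, col, times[i], rule = 2)$y)
      })
      # projected abscissa of material fine grid + local stretch
      s_of_u <- stats::approx(traj$s[1L, ], st$s, xout = ugrid)$y
      x_of_u <- stats::approx(st$s, st$x, xout = s_of_u)$y
      stretch <- c(diff(s_of_u), NA) / c(diff(ugrid), NA)
      stretch[is.na(stretch)] <- 1
      # intensity profile along image x: invert x(u) (monotone for |theta|<90deg)
      prof <- stats::approx(x_of_u, tex / pmax(stretch, 1), xout = xs_px, rule = 1)$y
      img <- matrix(0.05, nrow_px, ncol_px)
      img[band, ] <- rep(0.55 + ifelse(is.na(prof), -0.5, prof), each = sum(band))
      img <- img + stats::rnorm(length(img), 0, noise_sd)
      images[[i]] <- pmin(pmax(img, 0), 1)
    }
    origin <- c(-pad_mm, -(W / 2 + pad_mm))
  } else {
    xr <- range(traj$x) + c(-1, 1) * (pad_mm + W)
    yr <- range(traj$y) + c(-1, 1) * (pad_mm + W)
    ncol_px <- ceiling(diff(xr) / mm_per_px)
    nrow_px <- ceiling(diff(yr) / mm_per_px)
    xs_px <- xr[1L] + (seq_len(ncol_px) - 0.5) * mm_per_px
    ys_px <- yr[1L] + (seq_len(nrow_px) - 0.5) * mm_per_px
    for (i in seq_along(times)) {
      xi <- apply(traj$x, 2L, function(col) stats::approx(traj$times, col, times[i], rule = 2)$y)
      yi <- apply(traj$y, 2L, function(col) stats::approx(traj$times, col, times[i], rule = 2)$y)
      # treat the midline as a graph y(x): valid for the gentle bending here
      ymid <- stats::approx(xi, yi, xout = xs_px, rule = 1)$y
      img <- matrix(0.05, nrow_px, ncol_px)
      for (j in seq_len(ncol_px)) {
        if (!is.na(ymid[j])) {
          img[abs(ys_px - ymid[j]) <= W / 2, j] <- 0.8
        }
      }
      img <- img + stats::rnorm(length(img), 0, noise_sd)
      images[[i]] <- pmin(pmax(img, 0), 1)
    }
    origin <- c(xr[1L], yr[1L])
  }
  structure(list(times = times, images = images, mm_per_px = mm_per_px,
                 plane_label = setup$plane_label, origin_mm = origin),
            class = "frame_sequence")
}

#' Write a frame sequence as a numbered PNG series
#'
#' @param frames a `frame_sequence`.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return the vector of file paths, invisibly. A JSON sidecar
#'   `<prefix>_meta.json` records times, scale and plane.
#' @export
write_frames <- function(frames, dir, prefix = "frame") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, sprintf("%s_%04d.png", prefix, seq_along(frames$images)))
  for (i in seq_along(frames$images)) png::writePNG(frames$images[[i]], paths[i])
  jsonlite::write_json(list(times = frames$times, mm_per_px = frames$mm_per_px,
                            plane_label = frames$plane_label,
                            origin_mm = frames$origin_mm),
                       file.path(dir, paste0(prefix, "_meta.json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Read a PNG frame series written by [write_frames()]
#' @param dir directory containing the series.
#' @param prefix file-name prefix used at write time.
#' @return a `frame_sequence`.
#' @export
read_frames <- function(dir, prefix = "frame") {
  meta <- jsonlite::fromJSON(file.path(dir, paste0(prefix, "_meta.json")))
  paths <- sort(list.files(dir, pattern = paste0("^", prefix, "_\\d+\\.png$"),
                           full.names = TRUE))
  images <- lapply(paths, function(p) {
    im <- png::readPNG(p)
    if (length(dim(im)) == 3L) im <- im[, , 1L]
    im
  })
  structure(list(times = meta$times, images = images,
                 mm_per_px = meta$mm_per_px, plane_label = meta$plane_label,
                 origin_mm = meta$origin_mm),
            class = "frame_sequence")
}

#' Bundle a full synthetic dataset with ground truth
#'
#' Simulates the growth model, then derives every product the measurement
#' chain consumes: a curvature kymograph and a (midline) elongation-rate
#' kymograph on stated grids with independent Gaussian noise, node-marker
#' tracks, and (optionally) speckle frames. All noise realizations come from
#' independent substreams fanned out from one master seed, so each product
#' is independently reproducible.
#'
#' @param params a [growth_params()].
#' @param t_end simulated duration (h), default 5 nutation periods.
#' @param pos_grid spatial grid (mm, apex distances) for the kymographs.
#' @param time_grid time grid (h) for the kymographs; default the top-view
#'   cadence of 2.5 min.
#' @param noise_sd named list with per-product noise levels: `curvature`
#'   (1/mm), `elong` (1/h), `tracks` (mm).
#' @param n_nodes nodes for the track product.
#' @param dropout_p track dropout probability.
#' @param seed master seed.
#' @param frames logical: also render a (short) side-view frame sequence.
#' @param ... further arguments to [simulate_rachis()].
#' @return an object of class `synthetic_dataset`: list with `truth`
#'   (`params` + `trajectory`), `curvature_kymo`, `elong_kymo`,
#'   `node_tracks`, `frames` (or `NULL`) and `seed`.
#' @export
make_kymograph_dataset <- function(params = growth_params(),
                                   t_end = 5 * params$T,
                                   pos_grid = seq(0, 150, by = 2.5),
                                   time_grid = NULL,
                                   noise_sd = list(curvature = 0, elong = 0, tracks = 0.05),
                                   n_nodes = 12L, dropout_p = 0.02,
                                   seed = 1L, frames = FALSE, ...) {
  validate_growth_params(params)
  traj <- simulate_rachis(params, t_end = t_end, ...)
  if (is.null(time_grid)) {
    time_grid <- seq(0, max(traj$times), by = 2.5 / 60)
  }
  seeds <- fan_seed(seed, 4L)
  curv <- resample_kymo(trajectory_kymograph(traj, "C", positions = pos_grid,
                                             axis_origin = "from_apex"),
                        time_grid)
  curv <- add_noise(curv, noise_sd$curvature %||% 0, seeds[1L], "curvature")
  # true midline elongation field on the same grid (time-independent profile)
  ev <- matrix(rep(mean_elongation_profile(params, pos_grid),
                   each = length(time_grid)),
               length(time_grid), length(pos_grid))
  # mask cells beyond the organ extent at that time
  apex_at <- stats::approx(traj$times, traj$apex_s, time_grid, rule = 2)$y
  ev[outer(apex_at, pos_grid, `<`)] <- NA_real_
  elong <- kymograph("elongation_rate", time_grid, pos_grid, ev, units = "1/h",
                     axis_origin = "from_apex")
  elong <- add_noise(elong, noise_sd$elong %||% 0, seeds[2L], "elongation_rate")
  tracks <- make_node_tracks(traj, n_nodes = n_nodes,
                             noise_sd = noise_sd$tracks %||% 0,
                             dropout_p = dropout_p, seed = seeds[3L])
  fr <- if (isTRUE(frames)) {
    render_frames(traj, seed = seeds[4L], t_max = min(params$T, max(traj$times)))
  } else NULL
  structure(list(truth = list(params = params, trajectory = traj),
                 curvature_kymo = curv, elong_kymo = elong,
                 node_tracks = tracks, frames = fr, seed = seed),
            class = "synthetic_dataset")
}

# resample a kymograph in time (linear)
resample_kymo <- function(kymo, time_grid) {
  vals <- apply(kymo$values, 2L, function(col) {
    ok <- !is.na(col)
    if (sum(ok) < 2L) return(rep(NA_real_, length(time_grid)))
    stats::approx(kymo$times[ok], col[ok], xout = time_grid, rule = 1)$y
  })
  kymograph(kymo$field_name, time_grid, kymo$positions, vals,
            units = kymo$units, axis_origin = kymo$axis_origin)
}

add_noise <- function(kymo, sd, seed, field_name) {
  if (sd <= 0) return(kymo)
  old_seed <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  v <- kymo$values + stats::rnorm(length(kymo$values), 0, sd)
  v[kymo$mask] <- NA_real_
  kymograph(field_name, kymo$times, kymo$positions, v, units = kymo$units,
            axis_origin = kymo$axis_origin)
}
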