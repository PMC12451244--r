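#' Extract the organ midline from an intensity image
#'
#' Thresholds the organ band (Otsu's method by default), reduces the pixel
#' cloud to one transverse median per longitudinal bin, smooths the result
#' with a moving median filter, and returns an ordered, arclength-
#' parameterized polyline in mm. The longitudinal direction is the principal
#' axis of the thresholded cloud; the base is the end with the smaller
#' abscissa.
#'
#' @param image numeric matrix in `[0, 1]` (rows = image y, cols = image x).
#' @param mm_per_px image scale (mm per pixel).
#' @param threshold intensity threshold; default Otsu.
#' @param window moving-median window (odd number of longitudinal bins).
#' @return a data.frame with columns `x`, `y` (mm, image frame) and `s`
#'   (arclength from the base, mm), ordered base to apex.
#' @export
extract_midline <- function(image, mm_per_px = 1, threshold = NULL,
                            window = 9L) {
  if (is.null(threshold)) threshold <- otsu_threshold(image)
  sel <- which(image > threshold, arr.ind = TRUE)
  if (nrow(sel) == 0L) stop("detection error: no organ above threshold")
  px <- sel[, 2L]  # image x = column
  py <- sel[, 1L]  # image y = row
  # principal axis of the cloud
  mx <- mean(px); my <- mean(py)
  cv <- stats::cov(cbind(px - mx, py - my))
  ev <- eigen(cv, symmetric = TRUE)$vectors[, 1L]
  if (ev[1L] < 0) ev <- -ev
  a <- (px - mx) * ev[1L] + (py - my) * ev[2L]   # along-organ coordinate
  b <- -(px - mx) * ev[2L] + (py - my) * ev[1L]  # transverse coordinate
  bins <- round(a)
  ub <- sort(unique(bins))
  bmed <- vapply(ub, function(k) stats::median(b[bins == k]), numeric(1))
  if (length(ub) >= 3L) {
    w <- min(window, length(ub) - (1 - length(ub) %% 2L))
    if (w %% 2L == 0L) w <- w - 1L
    if (w >= 3L) bmed <- stats::runmed(bmed, w, endrule = "median")
  }
  # back to image frame (pixel centres at index - 0.5), then to mm
  X <- (mx + ub * ev[1L] - bmed * ev[2L] - 0.5) * mm_per_px
  Y <- (my + ub * ev[2L] + bmed * ev[1L] - 0.5) * mm_per_px
  s <- c(0, cumsum(sqrt(diff(X)^2 + diff(Y)^2)))
  data.frame(x = X, y = Y, s = s)
}

# Otsu threshold on a 256-bin histogram
otsu_threshold <- function(image) {
  v <- as.vector(image)
  h <- graphics::hist(v, breaks = seq(min(v), max(v), length.out = 257L),
                      plot = FALSE)
  p <- h$counts / sum(h$counts)
  mids <- h$mids
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  muT <- mu[length(mu)]
  sigma_b <- (muT * w0 - mu)^2 / (w0 * (1 - w0))
  sigma_b[!is.finite(sigma_b)] <- 0
  mids[which.max(sigma_b)]
}

#' Taubin algebraic circle fit
#'
#' Fits a circle to points by Taubin's gradient-weighted algebraic method
#' (low bias on small arcs). Returns centre, radius, and the smallest
#' eigenvalue as a degeneracy diagnostic.
#'
#' @param x,y point coordinates.
#' @return list with `xc`, `yc`, `r`, `rmse`.
#' @export
taubin_circle_fit <- function(x, y) {
  n <- length(x)
  stopifnot(n >= 3L)
  mx <- mean(x); my <- mean(y)
  u <- x - mx; v <- y - my
  z <- u^2 + v^2
  zm <- mean(z)
  # Taubin's reduced eigenproblem via Newton iteration on the characteristic poly
  Mxx <- mean(u^2); Myy <- mean(v^2); Mxy <- mean(u * v)
  Mxz <- mean(u * z); Myz <- mean(v * z); Mzz <- mean(z^2)
  # characteristic polynomial of Taubin's reduced eigenproblem
  Mz <- zm
  Cov_xy <- Mxx * Myy - Mxy^2
  A3 <- 4 * Mz
  A2 <- -3 * Mz * Mz - Mzz
  A1 <- Mzz * Mz + 4 * Cov_xy * Mz - Mxz * Mxz - Myz * Myz - Mz * Mz * Mz
  A0 <- Mxz * Mxz * Myy + Myz * Myz * Mxx - Mzz * Cov_xy -
    2 * Mxz * Myz * Mxy + Mz * Mz * Cov_xy
  # Newton from 0 (standard initialisation for Taubin's fit)
  xx <- 0
  for (i in 1:32) {
    f <- A0 + xx * (A1 + xx * (A2 + xx * A3))
    fp <- A1 + xx * (2 * A2 + 3 * xx * A3)
    if (fp == 0) break
    step <- f / fp
    xx <- xx - step
    if (abs(step) < 1e-14 * max(1, abs(xx))) break
  }
  eta <- xx
  DET <- eta * eta - eta * Mz + Cov_xy
  if (!is.finite(DET) || abs(DET) < .Machine$double.eps * 100) {
    return(list(xc = NA_real_, yc = NA_real_, r = Inf, rmse = NA_real_))
  }
  xc <- (Mxz * (Myy - eta) - Myz * Mxy) / DET / 2
  yc <- (Myz * (Mxx - eta) - Mxz * Mxy) / DET / 2
  r <- sqrt(xc^2 + yc^2 + Mz)
  xc <- xc + mx; yc <- yc + my
  rmse <- sqrt(mean((sqrt((x - xc)^2 + (y - yc)^2) - r)^2))
  list(xc = xc, yc = yc, r = r, rmse = rmse)
}

#' Signed curvature along a midline by local circle fitting
#'
#' Slides a window of the given arclength extent along the polyline, fits a
#' circle (Taubin fit) to the points in the window, and reports the signed
#' inverse radius. Sign convention: bending towards the left of the
#' direction of travel (base to apex) is positive (counter-clockwise).
#' Collinear windows give curvature 0.
#'
#' @param midline data.frame with `x`, `y`, `s` as from [extract_midline()].
#' @param window window arclength (mm); must span at least 5 points.
#' @return signed curvature (1/mm) per midline point.
#' @export
local_curvature <- function(midline, window = 10) {
  x <- midline$x; y <- midline$y; s <- midline$s
  n <- length(x)
  ds <- stats::median(diff(s))
  half <- window / 2
  if (window / ds < 4) stop("window must span at least 5 points")
  vapply(seq_len(n), function(i) {
    j <- which(abs(s - s[i]) <= half)
    if (length(j) < 5L) j <- max(1L, i - 2L):min(n, i + 2L)
    ft <- taubin_circle_fit(x[j], y[j])
    if (!is.finite(ft$r) || ft$r <= 0) return(0)
    # orientation: cross product of local tangent with vector to centre
    i0 <- max(1L, i - 1L); i1 <- min(n, i + 1L)
    tx <- x[i1] - x[i0]; ty <- y[i1] - y[i0]
    sgn <- sign(tx * (ft$yc - y[i]) - ty * (ft$xc - x[i]))
    if (sgn == 0) 0 else sgn / ft$r
  }, numeric(1))
}

#' Link per-frame marker detections into node tracks
#'
#' Implements conservation-based linking rules: when the detection count is
#' conserved, detections are matched to tracks by their rank order along the
#' organ (which forbids two dots swapping); otherwise greedy nearest-
#' neighbour assignment constrained by a maximum displacement is used, with
#' gap closing across up to `max_gap` missing frames. Frames whose
#' assignment violates the rules are flagged for manual correction rather
#' than guessed.
#'
#' @param detections list (one element per frame) of data.frames or
#'   matrices with columns `u`, `v` (mm).
#' @param times frame times (h).
#' @param max_disp maximum plausible displacement between frames (mm).
#' @param max_gap maximum number of consecutive missed frames bridged.
#' @return a `node_tracks` data.frame (`node_id`, `t`, `u`, `v`, `visible`)
#'   with attribute `flagged` (indices of frames needing manual review).
#' @export
track_nodes <- function(detections, times = seq_along(detections),
                        max_disp = 5, max_gap = 3L) {
  get_uv <- function(d) {
    d <- as.data.frame(d)
    names(d)[1:2] <- c("u", "v")
    d
  }
  f1 <- get_uv(detections[[1L]])
  ord_axis <- function(d) order(d$u + 1e-9 * d$v)
  o <- ord_axis(f1)
  n_tracks <- nrow(f1)
  last <- f1[o, , drop = FALSE]
  gap <- integer(n_tracks)
  flagged <- integer(0)
  res <- vector("list", length(detections))
  res[[1L]] <- data.frame(node_id = seq_len(n_tracks), t = times[1L],
                          u = last$u, v = last$v, visible = TRUE)
  for (f in 2:length(detections)) {
    d <- get_uv(detections[[f]])
    nd <- nrow(d)
    assigned <- rep(NA_integer_, n_tracks)
    if (nd == n_tracks) {
      # conservation + ordering rule: match by rank along the organ
      od <- ord_axis(d)
      dists <- sqrt((d$u[od] - last$u)^2 + (d$v[od] - last$v)^2)
      if (all(dists <= max_disp * pmax(1, gap + 1))) {
        assigned <- od
      } else {
        flagged <- c(flagged, f)
      }
    }
    if (nd != n_tracks || all(is.na(assigned))) {
      # greedy nearest neighbour under the displacement bound
      free <- rep(TRUE, nd)
      dd <- outer(seq_len(n_tracks), seq_len(nd), function(i, j) {
        sqrt((last$u[i] - d$u[j])^2 + (last$v[i] - d$v[j])^2)
      })
      repeat {
        m <- which(dd == min(dd), arr.ind = TRUE)[1L, , drop = FALSE]
        if (!is.finite(dd[m])) break
        i <- m[1L]; j <- m[2L]
        if (dd[i, j] > max_disp * pmax(1, gap[i] + 1)) break
        assigned[i] <- j
        dd[i, ] <- Inf; dd[, j] <- Inf
      }
      # ordering rule: assigned detections must preserve track order
      au <- d$u[assigned]
      ok <- !is.na(au)
      if (any(diff(au[ok]) < 0)) {
        flagged <- c(flagged, f)
        assigned[] <- NA_integer_
      }
      if (nd != n_tracks && !(f %in% flagged) && any(is.na(assigned))) {
        # dropouts: tolerated up to max_gap
      }
    }
    vis <- !is.na(assigned)
    gap <- ifelse(vis, 0L, gap + 1L)
    if (any(gap > max_gap)) flagged <- c(flagged, f)
    uu <- ifelse(vis, d$u[assigned], last$u)
    vv <- ifelse(vis, d$v[assigned], last$v)
    last$u <- uu; last$v <- vv
    res[[f]] <- data.frame(node_id = seq_len(n_tracks), t = times[f],
                           u = uu, v = vv, visible = vis)
  }
  out <- do.call(rbind, res)
  out <- out[order(out$node_id, out$t), ]
  rownames(out) <- NULL
  structure(out, class = c("node_tracks", "data.frame"),
            flagged = unique(flagged))
}

#' Segment elongation-rate kymograph from node tracks
#'
#' For each pair of consecutive nodes, the average elongation rate of the
#' interfoliolar segment between them is `d log d / dt` of their image-plane
#' distance `d`, by centered finite differences (forward/backward at the
#' edges), optionally smoothed with a 3x3 mean filter followed by a 3x3
#' median filter. Frames where either node is invisible propagate as masked
#' cells.
#'
#' @param tracks a `node_tracks` data.frame.
#' @param smooth apply the 2D smoothing filters.
#' @return an object of class `segment_kymograph`: list with `times`,
#'   `values` (time x segment rates, 1/h), `positions` (time x segment
#'   midpoint distances from the base along the node chain, mm), `mask`,
#'   and `apex` (the apex track attribute, if present).
#' @export
segment_elongation <- function(tracks, smooth = TRUE) {
  ids <- sort(unique(tracks$node_id))
  times <- sort(unique(tracks$t))
  if (length(ids) < 2L) stop("need at least two nodes per frame")
  nt <- length(times); nn <- length(ids)
  U <- matrix(NA_real_, nt, nn); V <- U; VIS <- matrix(FALSE, nt, nn)
  key <- match(paste(tracks$node_id, tracks$t), paste(rep(ids, each = nt), rep(times, nn)))
  U[key] <- tracks$u; V[key] <- tracks$v; VIS[key] <- tracks$visible
  d <- sqrt((U[, -1L, drop = FALSE] - U[, -nn, drop = FALSE])^2 +
              (V[, -1L, drop = FALSE] - V[, -nn, drop = FALSE])^2)
  seg_vis <- VIS[, -1L, drop = FALSE] & VIS[, -nn, drop = FALSE]
  d[!seg_vis] <- NA_real_
  rate <- ddt(log(d), times)
  if (isTRUE(smooth)) {
    rate <- filter2_median(filter2_mean(rate, 3L), 3L)
  }
  # positions: gap-fill inter-node distances in time so a dropout does not
  # shift the chain, then accumulate chord distances from the apex end when
  # the apex point is tracked (giving apex distances directly), else from
  # the first node
  d_fill <- apply(d, 2L, function(col) {
    ok <- !is.na(col)
    if (sum(ok) < 2L) return(col)
    stats::approx(times[ok], col[ok], xout = times, rule = 2)$y
  })
  d_fill <- matrix(d_fill, nrow = nt)
  apex <- attr(tracks, "apex")
  if (!is.null(apex) && all(c("u", "v") %in% names(apex))) {
    au <- stats::approx(apex$t, apex$u, times, rule = 2)$y
    av <- stats::approx(apex$t, apex$v, times, rule = 2)$y
    d_apex <- sqrt((U[, nn] - au)^2 + (V[, nn] - av)^2)
    # distance of each node from the apex, accumulated apicalward
    dist_ap <- cbind(t(apply(d_fill[, rev(seq_len(nn - 1L)), drop = FALSE],
                             1L, cumsum))[, rev(seq_len(nn - 1L)), drop = FALSE], 0) +
      d_apex
    mid <- (dist_ap[, -1L, drop = FALSE] + dist_ap[, -nn, drop = FALSE]) / 2
    origin <- "from_apex"
  } else {
    dist0 <- cbind(0, t(apply(d_fill, 1L, cumsum)))
    mid <- (dist0[, -1L, drop = FALSE] + dist0[, -nn, drop = FALSE]) / 2
    origin <- "from_base"
  }
  structure(list(times = times, values = rate, positions = mid,
                 axis_origin = origin, mask = is.na(rate), apex = apex),
            class = "segment_kymograph")
}

#' Apparent elongation-rate kymograph by image-to-image correlation
#'
#' Samples the intensity profile along the organ in each frame, measures the
#' frame-to-frame displacement of overlapping windows by normalized
#' cross-correlation with parabolic sub-pixel peak interpolation, and
#' differentiates the displacement field along the organ to give the
#' apparent elongation rate (negative values permitted). Windows whose
#' correlation peak falls below `corr_min` are masked. The estimate is
#' invariant to global intensity rescaling.
#'
#' @param frames a `frame_sequence` (side view).
#' @param window_px correlation window length (px).
#' @param step_px spacing of window centres (px).
#' @param search_px maximum displacement searched (px).
#' @param corr_min minimum acceptable correlation peak.
#' @param lag number of frame intervals between the correlated pair; a lag
#'   of a few frames trades time resolution for displacement signal-to-noise
#'   (sub-pixel errors are independent of the lag, displacements grow with
#'   it).
#' @param strain_pts number of window centres (odd) in the local linear
#'   regression that turns displacement into strain.
#' @return a [kymograph()] of apparent elongation rate (1/h), positions =
#'   image abscissa from the organ base (mm), `from_base` axis.
#' @export
dic_elongation <- function(frames, window_px = 32L, step_px = 8L,
                           search_px = 12L, corr_min = 0.5, lag = 1L,
                           strain_pts = 5L) {
  profs <- lapply(frames$images, band_profile)
  np <- length(profs[[1L]])
  centers <- seq(1L + window_px %/% 2L + search_px,
                 np - window_px %/% 2L - search_px, by = step_px)
  if (length(centers) < 3L) stop("frames too small for the correlation window")
  nt <- length(profs)
  if (nt <= lag) stop("not enough frames for the requested lag")
  pairs <- seq_len(nt - lag)
  disp <- matrix(NA_real_, length(pairs), length(centers))
  nc0 <- length(centers)
  dxc <- step_px
  for (f in pairs) {
    a <- profs[[f]]; b <- profs[[f + lag]]
    u1 <- vapply(seq_len(nc0), function(k) {
      ncc_shift(a, b, centers[k], window_px, search_px, corr_min)
    }, numeric(1))
    # second pass: re-correlate against the target window warped by the
    # first-pass local strain, removing the rigid-shift distortion bias
    strain1 <- rep(NA_real_, nc0)
    if (nc0 > 2L) {
      strain1[2:(nc0 - 1L)] <- (u1[3:nc0] - u1[1:(nc0 - 2L)]) / (2 * dxc)
      strain1[1L] <- strain1[2L]; strain1[nc0] <- strain1[nc0 - 1L]
    }
    disp[f, ] <- vapply(seq_len(nc0), function(k) {
      if (is.na(u1[k]) || is.na(strain1[k]) || abs(strain1[k]) > 0.5) {
        return(u1[k])
      }
      ncc_shift_warped(a, b, centers[k], window_px, u1[k], strain1[k], corr_min)
    }, numeric(1))
  }
  dt <- (frames$times[2L] - frames$times[1L]) * lag
  # strain rate: local linear-regression slope of the displacement field
  dx <- step_px * frames$mm_per_px
  half <- (strain_pts - 1L) %/% 2L
  nc <- length(centers)
  rate <- t(apply(disp, 1L, function(u) {
    vapply(seq_len(nc), function(k) {
      j <- max(1L, k - half):min(nc, k + half)
      j <- j[!is.na(u[j])]
      if (length(j) < 2L || !(k %in% j)) return(NA_real_)
      xj <- j * dx
      stats::cov(xj, u[j]) / stats::var(xj)
    }, numeric(1))
  })) * frames$mm_per_px / dt
  mid_t <- (frames$times[pairs] + frames$times[pairs + lag]) / 2
  positions <- (centers - 0.5) * frames$mm_per_px + frames$origin_mm[1L]
  kymograph("apparent_elongation_rate", mid_t, positions, rate, units = "1/h",
            axis_origin = "from_base")
}

# mean intensity across the organ band rows (rows above background)
band_profile <- function(img) {
  rm <- rowMeans(img)
  if (diff(range(rm)) < 1e-6) return(colMeans(img))
  band <- rm > (min(rm) + diff(range(rm)) * 0.5)
  colMeans(img[band, , drop = FALSE])
}

# NCC displacement of the window centred at i from profile a to b
ncc_shift <- function(a, b, i, window_px, search_px, corr_min) {
  h <- window_px %/% 2L
  wa <- a[(i - h):(i + h)]
  wa <- wa - mean(wa)
  na <- sqrt(sum(wa^2))
  if (na < .Machine$double.eps) return(NA_real_)
  shifts <- -search_px:search_px
  cc <- vapply(shifts, function(s) {
    wb <- b[(i - h + s):(i + h + s)]
    wb <- wb - mean(wb)
    nb <- sqrt(sum(wb^2))
    if (nb < .Machine$double.eps) return(-Inf)
    sum(wa * wb) / (na * nb)
  }, numeric(1))
  k <- which.max(cc)
  if (!is.finite(cc[k]) || cc[k] < corr_min) return(NA_real_)
  # exact match: the integer peak is the answer
  if (cc[k] >= 1 - 1e-12) return(shifts[k])
  # parabolic sub-pixel refinement
  if (k > 1L && k < length(cc) && is.finite(cc[k - 1L]) && is.finite(cc[k + 1L])) {
    den <- cc[k - 1L] - 2 * cc[k] + cc[k + 1L]
    frac <- if (den < 0) 0.5 * (cc[k - 1L] - cc[k + 1L]) / den else 0
    frac <- max(-0.5, min(0.5, frac))
  } else frac <- 0
  shifts[k] + frac
}

# residual NCC shift of window at i against b resampled with the estimated
# displacement u0 and local stretch e0 (affine window matching)
ncc_shift_warped <- function(a, b, i, window_px, u0, e0, corr_min) {
  h <- window_px %/% 2L
  d <- -h:h
  wa <- a[i + d]
  wa <- wa - mean(wa)
  na <- sqrt(sum(wa^2))
  if (na < .Machine$double.eps) return(u0)
  xb <- seq_along(b)
  resid_shifts <- seq(-2, 2, by = 1)
  cc <- vapply(resid_shifts, function(s) {
    wb <- stats::approx(xb, b, xout = i + u0 + s + (1 + e0) * d, rule = 2)$y
    wb <- wb - mean(wb)
    nb <- sqrt(sum(wb^2))
    if (nb < .Machine$double.eps) return(-Inf)
    sum(wa * wb) / (na * nb)
  }, numeric(1))
  k <- which.max(cc)
  if (!is.finite(cc[k]) || cc[k] < corr_min) return(u0)
  if (cc[k] >= 1 - 1e-12) return(u0 + resid_shifts[k])
  if (k > 1L && k < length(cc)) {
    den <- cc[k - 1L] - 2 * cc[k] + cc[k + 1L]
    frac <- if (den < 0) 0.5 * (cc[k - 1L] - cc[k + 1L]) / den else 0
    frac <- max(-0.5, min(0.5, frac))
  } else frac <- 0
  u0 + resid_shifts[k] + frac
}

#' Oscillation envelope of a kymograph via the Hilbert transform
#'
#' Per position, removes the time mean, takes the magnitude of the analytic
#' signal, and smooths it with a running mean. For a pure sine of amplitude
#' `A` the result is `A` (away from record edges). The record should cover
#' at least a few oscillation periods.
#'
#' @param kymo a [kymograph()].
#' @param smooth_window running-mean window (samples).
#' @param min_samples minimum record length accepted.
#' @return a [kymograph()] of the non-negative envelope, same grid/units.
#' @export
envelope <- function(kymo, smooth_window = 9L, min_samples = 16L) {
  nt <- length(kymo$times)
  if (nt < min_samples) stop("contract error: time series too short for envelope estimation")
  vals <- apply(kymo$values, 2L, function(col) {
    ok <- !is.na(col)
    if (sum(ok) < min_samples) return(rep(NA_real_, nt))
    col[!ok] <- mean(col[ok])
    env <- Mod(analytic_signal(col - mean(col)))
    env <- run_mean(env, smooth_window)
    env[!ok] <- NA_real_
    env
  })
  kymograph(paste0(kymo$field_name, "_envelope"), kymo$times, kymo$positions,
            vals, units = kymo$units, axis_origin = kymo$axis_origin)
}

#' Time-averaged spatial profiles in the apex frame
#'
#' Because the growth profile is steady in the frame attached to the apex,
#' kymographs can be rebinned to apex-distance coordinates and averaged over
#' time, yielding the mean elongation-rate profile and (optionally) the
#' differential-rate envelope profile on a common grid.
#'
#' @param elong_kymo a [kymograph()] or `segment_kymograph` of elongation
#'   rate.
#' @param diff_kymo optional second kymograph (e.g. a differential-rate
#'   envelope) averaged onto the same bins.
#' @param apex_track data.frame `t`, `apex_pos` giving the apex position in
#'   the same coordinate as the kymograph positions; not needed for
#'   `from_apex` kymographs.
#' @param bin_width apex-distance bin width (mm).
#' @param max_dist largest apex distance binned (mm).
#' @return an object of class `profile_pair`: data.frame with `apex_dist`
#'   (bin centres, mm), `mean_rate`, `diff_rate_envelope` (1/h, `NA` where
#'   absent) and counts `n_mean`, `n_diff`; empty bins are `NA`.
#' @export
time_average_profiles <- function(elong_kymo, diff_kymo = NULL,
                                  apex_track = NULL, bin_width = 10,
                                  max_dist = NULL) {
  g1 <- apex_frame_samples(elong_kymo, apex_track)
  max_dist <- max_dist %||% max(g1$ad, na.rm = TRUE)
  breaks <- seq(0, max_dist + bin_width, by = bin_width)
  centers <- breaks[-length(breaks)] + bin_width / 2
  bin_of <- function(ad) findInterval(ad, breaks, rightmost.closed = TRUE)
  avg <- function(g) {
    b <- bin_of(g$ad)
    ok <- !is.na(g$val) & b >= 1L & b <= length(centers)
    m <- rep(NA_real_, length(centers)); n <- integer(length(centers))
    if (any(ok)) {
      agg <- tapply(g$val[ok], b[ok], mean)
      cnt <- table(b[ok])
      m[as.integer(names(agg))] <- agg
      n[as.integer(names(cnt))] <- as.integer(cnt)
    }
    list(m = m, n = n)
  }
  a1 <- avg(g1)
  out <- data.frame(apex_dist = centers, mean_rate = a1$m,
                    diff_rate_envelope = NA_real_,
                    n_mean = a1$n, n_diff = 0L)
  if (!is.null(diff_kymo)) {
    a2 <- avg(apex_frame_samples(diff_kymo, apex_track))
    out$diff_rate_envelope <- a2$m
    out$n_diff <- a2$n
  }
  structure(out, class = c("profile_pair", "data.frame"))
}

# flatten a kymograph (or segment_kymograph) into apex-distance samples
apex_frame_samples <- function(kymo, apex_track) {
  if (inherits(kymo, "segment_kymograph")) {
    if (identical(kymo$axis_origin, "from_apex")) {
      return(list(ad = as.vector(kymo$positions), val = as.vector(kymo$values)))
    }
    apex_track <- apex_track %||% kymo$apex
    if (is.null(apex_track)) stop("apex track required for segment kymographs")
    apex_at <- stats::approx(apex_track$t, apex_track$apex_pos, kymo$times,
                             rule = 2)$y
    ad <- apex_at - kymo$positions  # positions: time x segment matrix
    return(list(ad = as.vector(ad), val = as.vector(kymo$values)))
  }
  if (kymo$axis_origin == "from_apex") {
    ad <- matrix(rep(kymo$positions, each = length(kymo$times)),
                 length(kymo$times), length(kymo$positions))
  } else {
    if (is.null(apex_track)) stop("apex track required for base-origin kymographs")
    apex_at <- stats::approx(apex_track$t, apex_track$apex_pos, kymo$times,
                             rule = 2)$y
    ad <- outer(apex_at, kymo$positions, `-`)
  }
  list(ad = as.vector(ad), val = as.vector(kymo$values))
}
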