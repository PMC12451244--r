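#' Camera / observation-plane setup
#'
#' The bending plane of the model is horizontal. A top view looks along its
#' normal and sees the true planar midline; a side view looks along a
#' direction inside the bending plane and sees the organ's orthogonal
#' projection onto the vertical image plane, so segments foreshorten by
#' `|cos(theta - view_angle)|`.
#'
#' @param plane `"side"` or `"top"`.
#' @param view_angle for a side view, the in-plane angle (rad) of the image
#'   x-axis; the camera line of sight is orthogonal to it. Default 0: image
#'   abscissa is the model x-axis.
#' @return an object of class `projection_setup`.
#' @export
projection_setup <- function(plane = c("side", "top"), view_angle = 0) {
  plane <- match.arg(plane)
  structure(list(plane_label = plane, view_angle = view_angle),
            class = "projection_setup")
}

# per-time projected and true (face-resolved) segment lengths for a trajectory.
# Returns list of matrices (time x segment): proj (projected length),
# true (face arclength), mid_ad (segment midpoint apex distance),
# costh (projection factor).
segment_geometry <- function(traj, setup, face = c("midline", "outer", "inner")) {
  face <- match.arg(face)
  nm <- ncol(traj$s)
  ds <- traj$s[, -1L, drop = FALSE] - traj$s[, -nm, drop = FALSE]
  Cmid <- (traj$C[, -1L, drop = FALSE] + traj$C[, -nm, drop = FALSE]) / 2
  W <- traj$params$W
  fac <- switch(face, midline = 1, outer = 1 + Cmid * W / 2, inner = 1 - Cmid * W / 2)
  ds_face <- ds * fac
  th_mid <- (traj$theta[, -1L, drop = FALSE] + traj$theta[, -nm, drop = FALSE]) / 2
  if (setup$plane_label == "top") {
    costh <- matrix(1, nrow(ds), ncol(ds))
  } else {
    costh <- abs(cos(th_mid - setup$view_angle))
  }
  mid_s <- (traj$s[, -1L, drop = FALSE] + traj$s[, -nm, drop = FALSE]) / 2
  mid_ad <- traj$apex_s - mid_s
  list(proj = ds_face * costh, true = ds_face, costh = costh, mid_ad = mid_ad)
}

#' Apparent elongation-rate kymograph seen by a camera
#'
#' For each material segment of the (optionally face-resolved) midline, the
#' apparent rate is `d/dt log` of its orthogonally projected length. For a
#' side view of planar bending this equals the true material rate plus the
#' geometric term `d/dt log |cos theta|`; it reduces to the true rate where
#' `theta == 0`, and can be negative even while both faces elongate.
#' Segments nearly perpendicular to the image plane
#' (`|cos theta| < mask_eps`) are masked, not errors.
#'
#' @param traj a `rachis_trajectory`.
#' @param setup a [projection_setup()].
#' @param face `"midline"`, or `"outer"`/`"inner"` to resolve the observed
#'   lateral face (adds the face's differential-elongation fluctuation to
#'   the material term, as an image-correlation measurement on that face
#'   does).
#' @param positions apex-distance grid (mm) for the output; default 2-mm
#'   spacing over `[0, 0.9 * initial length]`.
#' @param mask_eps projection-degeneracy threshold on `|cos theta|`.
#' @return a [kymograph()] of apparent elongation rate (1/h), apex-origin
#'   axis.
#' @export
apparent_elongation <- function(traj, setup, face = "midline",
                                positions = NULL, mask_eps = 1e-6) {
  g <- segment_geometry(traj, setup, face)
  lp <- g$proj
  lp[g$costh < mask_eps] <- NA_real_
  rate <- ddt(log(lp), traj$times)
  segment_rate_kymograph(rate, g$mid_ad, traj$times, positions,
                         field_name = "apparent_elongation_rate")
}

#' Split the apparent rate into geometric and material contributions
#'
#' The apparent rate decomposes exactly as
#' `d/dt log(proj length) = d/dt log(true length) + d/dt log |cos theta|`:
#' a material term (the face's true elongation rate, oscillating at the
#' nutation period where differential growth acts) and a geometric
#' projection term (an even function of `theta`, hence oscillating at half
#' the nutation period for symmetric nutation about the straight state,
#' largest where the angular excursion is largest, i.e. apically). The two
#' kymographs sum to [apparent_elongation()] exactly.
#'
#' @inheritParams apparent_elongation
#' @return a list of two [kymograph()]s, `geometric` and `material`.
#' @export
mode_origin_decomposition <- function(traj, setup, face = "midline",
                                      positions = NULL, mask_eps = 1e-6) {
  g <- segment_geometry(traj, setup, face)
  costh <- g$costh
  costh[costh < mask_eps] <- NA_real_
  geo <- ddt(log(costh), traj$times)
  mat <- ddt(log(g$true), traj$times)
  list(geometric = segment_rate_kymograph(geo, g$mid_ad, traj$times, positions,
                                          field_name = "geometric_rate"),
       material = segment_rate_kymograph(mat, g$mid_ad, traj$times, positions,
                                         field_name = "material_rate"))
}

# interpolate per-segment rates (time x segment, at drifting apex distances)
# onto a fixed apex-distance grid
segment_rate_kymograph <- function(rate, mid_ad, times, positions, field_name) {
  if (is.null(positions)) {
    positions <- seq(0, 0.9 * max(mid_ad[1L, ]), by = 2)
  }
  vals <- matrix(NA_real_, length(times), length(positions))
  for (i in seq_along(times)) {
    ad <- mid_ad[i, ]
    o <- order(ad)
    ok <- !is.na(rate[i, o])
    if (sum(ok) >= 2L) {
      vals[i, ] <- stats::approx(ad[o][ok], rate[i, o][ok], xout = positions,
                                 rule = 1)$y
    }
  }
  kymograph(field_name, times, positions, vals, units = "1/h",
            axis_origin = "from_apex")
}
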