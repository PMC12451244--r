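#' Mean (midline) elongation-rate profile
#'
#' The relative elemental growth rate of the midline as a function of
#' distance from the apex: a time-independent sigmoid
#' \deqn{\dot E(s') = \frac{\dot E_{max}}{2}\left(1 - \tanh\frac{s' - L_{gz}}{\lambda}\right)}
#' describing an apical growth zone of constant length. The profile is
#' monotonically non-increasing in apex distance and bounded in
#' `[0, Edot_max]`.
#'
#' @param params a [growth_params()] object.
#' @param apex_dist distances from the apex, mm (non-negative).
#' @return elongation rates (1/h), same length as `apex_dist`.
#' @examples
#' p <- growth_params()
#' mean_elongation_profile(p, c(0, p$L_gz, 100))
#' @export
mean_elongation_profile <- function(params, apex_dist) {
  if (params$lambda_gz <= 0) stop("parameter 'lambda_gz' must be > 0")
  if (any(apex_dist < 0)) stop("apex_dist must be non-negative")
  params$Edot_max / 2 * (1 - tanh((apex_dist - params$L_gz) / params$lambda_gz))
}

#' Differential elongation-rate field
#'
#' The difference between the elongation rates of the two lateral faces,
#' \deqn{\delta\dot E(s', t) = \delta E_{max}\,
#'   \mathrm{sech}^2\!\frac{s' - s_{bz}}{L_{bz}}\, \sin\frac{2\pi t}{T},}
#' a unit-peak envelope centred at `s_bz` (by default the edge of the growth
#' zone, where the mean rate drops) modulated by a sine of the nutation
#' period.
#'
#' @inheritParams mean_elongation_profile
#' @param t time (h, scalar, >= 0).
#' @return differential rates (1/h), same length as `apex_dist`.
#' @export
differential_elongation <- function(params, apex_dist, t) {
  stopifnot(length(t) == 1L)
  if (t < 0) stop("t must be >= 0")
  params$dE_max * sech2((apex_dist - params$s_bz) / params$L_bz) * sin(2 * pi * t / params$T)
}

# unit-peak spatial envelope of the differential elongation
diff_envelope <- function(params, apex_dist) {
  sech2((apex_dist - params$s_bz) / params$L_bz)
}

#' Elongation rates of the two lateral faces
#'
#' With a transverse elongation profile linear in the bulk, the outer and
#' inner faces (at transverse offsets +W/2 and -W/2) elongate at
#' `mean_rate + diff_rate/2` and `mean_rate - diff_rate/2`; their difference
#' is exactly the differential rate and their mean the midline rate. A
#' negative face rate is a local contraction event.
#'
#' @param mean_rate midline elongation rate(s), 1/h.
#' @param diff_rate differential elongation rate(s), 1/h.
#' @return a list with components `outer` and `inner` (1/h).
#' @examples
#' face_rates(0.02, 0.05) # inner face contracts
#' @export
face_rates <- function(mean_rate, diff_rate) {
  list(outer = mean_rate + diff_rate / 2, inner = mean_rate - diff_rate / 2)
}

#' Rate of change of curvature driven by differential elongation
#'
#' For a thin beam of width `W`, differential elongation and curvature rate
#' are kinematically equivalent. The face arclength elements are
#' `ds (1 +/- C W / 2)`, so (neglecting curvature advection)
#' \deqn{\delta\dot E = \frac{d}{dt}\,2\,\mathrm{artanh}\frac{CW}{2}
#'   = \frac{W\,\partial_t C}{1 - (CW/2)^2}}
#' giving
#' \deqn{\partial_t C = \frac{\delta\dot E}{W}\left(1 - \left(\frac{CW}{2}\right)^2\right),}
#' i.e. the leading order `diff_rate / W` with a second-order correction in
#' `C W` that vanishes as `C W -> 0`.
#'
#' @param diff_rate differential elongation rate (1/h).
#' @param curvature signed curvature `C` (1/mm).
#' @param width beam width `W` (mm).
#' @return curvature rate (1/(mm h)).
#' @export
curvature_rate <- function(diff_rate, curvature, width) {
  if (any(abs(curvature) * width >= 1)) {
    stop("thin-beam validity requires |C| * W < 1")
  }
  diff_rate / width * (1 - (curvature * width / 2)^2)
}

#' Advance the rachis state by one explicit Euler step
#'
#' Each material segment length grows as `ds(t + dt) = ds(t) exp(Edot dt)`
#' with the mean rate evaluated at the segment's current apex distance (the
#' growth-zone profile is anchored at the advancing apex); marker curvature
#' is updated per [curvature_rate()] with the differential rate at the
#' marker's apex distance (curvature advection neglected); angles and
#' positions are re-integrated from the clamped base.
#'
#' @param state a list with fields `s` (marker arclengths from base, mm,
#'   strictly increasing), `C` (signed curvature per marker, 1/mm) and `t`
#'   (current time, h).
#' @param params a [growth_params()] object.
#' @param dt time step (h); must not exceed `T / 200`.
#' @return the updated state (with `theta`, `x`, `y` re-integrated).
#' @export
rachis_step <- function(state, params, dt) {
  if (dt > params$T / 200) stop("dt must be <= T / 200 for stability/accuracy")
  s <- state$s; C <- state$C; t <- state$t
  n <- length(s)
  L <- s[n]
  # grow material segments at the mean rate of their midpoint apex distance
  mid_ad <- L - (s[-1L] + s[-n]) / 2
  ds_new <- diff(s) * exp(mean_elongation_profile(params, mid_ad) * dt)
  s_new <- c(0, cumsum(ds_new))
  if (any(diff(s_new) <= 0)) stop("integration error: non-monotone arclength after step")
  # update curvature with the differential rate at the marker apex distance
  dE <- differential_elongation(params, pmax(L - s, 0), t)
  C_new <- C + curvature_rate(dE, C, params$W) * dt
  st <- list(s = s_new, C = C_new, t = t + dt)
  c(st, integrate_midline(s_new, C_new, params$theta_base))
}

# angles from curvature and planar coordinates from angles, base clamped at origin
integrate_midline <- function(s, C, theta_base) {
  theta <- theta_base + cumtrapz(s, C)
  list(theta = theta,
       x = cumtrapz(s, cos(theta)),
       y = cumtrapz(s, sin(theta)))
}

#' Simulate the nutating, elongating rachis
#'
#' Forward-integrates the kinematic growth model on a Lagrangian material
#' grid: mean elongation advances the apex and stretches material segments,
#' differential elongation drives curvature in the bending zone, and the
#' midline is rebuilt from the base at every saved instant. Deterministic
#' given its inputs.
#'
#' With `init = "steady"` (default) the curvature starts on the steady
#' zero-mean oscillation `C(s, 0) = -dE_max g(s') T / (2 pi W)`, so the
#' organ nutates about the rectilinear state from the first frame; with
#' `init = "straight"` it starts uncurved (the sine forcing then leaves a
#' constant curvature offset of the same magnitude).
#'
#' @param params a [growth_params()] object.
#' @param t_end final time (h); several nutation periods are needed to
#'   observe the steady oscillatory regime.
#' @param dt integration step (h), default `T / 500`.
#' @param n_markers number of Lagrangian markers along the organ.
#' @param init initial curvature state, `"steady"` or `"straight"`.
#' @param save_every store every `save_every`-th step (the initial and final
#'   states are always stored).
#' @return an object of class `rachis_trajectory`: list with `times` (h),
#'   `material_ids`, matrices `s`, `C`, `theta`, `x`, `y` (time x marker),
#'   `apex_s` (total length per time, mm) and the generating `params`.
#' @examples
#' traj <- simulate_rachis(growth_params(), t_end = 2.5, dt = 2.5 / 250,
#'                         n_markers = 41)
#' range(traj$apex_s)
#' @export
simulate_rachis <- function(params, t_end, dt = params$T / 500,
                            n_markers = 151L, init = c("steady", "straight"),
                            save_every = 1L) {
  init <- match.arg(init)
  stopifnot(t_end > 0, n_markers >= 2L, save_every >= 1L)
  s <- seq(0, params$L0, length.out = n_markers)
  C <- if (init == "steady") {
    -params$dE_max * diff_envelope(params, params$L0 - s) *
      params$T / (2 * pi * params$W)
  } else {
    rep(0, n_markers)
  }
  n_steps <- max(1L, ceiling(t_end / dt))
  dt <- t_end / n_steps
  keep <- unique(c(seq(0L, n_steps, by = save_every), n_steps))
  n_keep <- length(keep)
  out <- list(times = numeric(n_keep),
              material_ids = seq_len(n_markers),
              s = matrix(NA_real_, n_keep, n_markers),
              C = matrix(NA_real_, n_keep, n_markers),
              theta = matrix(NA_real_, n_keep, n_markers),
              x = matrix(NA_real_, n_keep, n_markers),
              y = matrix(NA_real_, n_keep, n_markers),
              apex_s = numeric(n_keep),
              params = params)
  state <- c(list(s = s, C = C, t = 0), integrate_midline(s, C, params$theta_base))
  ik <- 1L
  store <- function(state, ik) {
    out$times[ik] <<- state$t
    out$s[ik, ] <<- state$s
    out$C[ik, ] <<- state$C
    out$theta[ik, ] <<- state$theta
    out$x[ik, ] <<- state$x
    out$y[ik, ] <<- state$y
    out$apex_s[ik] <<- state$s[n_markers]
  }
  store(state, ik)
  for (k in seq_len(n_steps)) {
    state <- rachis_step(state, params, dt)
    if (k %in% keep) {
      ik <- ik + 1L
      store(state, ik)
    }
  }
  structure(out, class = "rachis_trajectory")
}

#' @export
print.rachis_trajectory <- function(x, ...) {
  cat(sprintf("rachis_trajectory: %d markers, %d times over [%g, %g] h, length %g -> %g mm\n",
              length(x$material_ids), length(x$times),
              min(x$times), max(x$times),
              x$apex_s[1], x$apex_s[length(x$apex_s)]))
  invisible(x)
}

#' Resample a trajectory field onto a fixed spatial grid
#'
#' Interpolates a per-marker field onto a regular grid of distances, in
#' base-origin or apex-origin coordinates, returning a [kymograph()].
#'
#' @param traj a `rachis_trajectory`.
#' @param field one of `"C"`, `"theta"`, and the per-marker coordinates
#'   `"x"`, `"y"`.
#' @param positions grid of distances (mm); default 2-mm spacing over the
#'   initial length.
#' @param axis_origin `"from_apex"` (distances are apex distances) or
#'   `"from_base"`.
#' @return a [kymograph()]; grid cells outside the organ are masked.
#' @export
trajectory_kymograph <- function(traj, field = c("C", "theta", "x", "y"),
                                 positions = NULL,
                                 axis_origin = c("from_apex", "from_base")) {
  field <- match.arg(field)
  axis_origin <- match.arg(axis_origin)
  if (is.null(positions)) positions <- seq(0, traj$apex_s[1L], by = 2)
  vals <- matrix(NA_real_, length(traj$times), length(positions))
  for (i in seq_along(traj$times)) {
    pos_i <- if (axis_origin == "from_apex") traj$apex_s[i] - traj$s[i, ] else traj$s[i, ]
    o <- order(pos_i)
    vals[i, ] <- stats::approx(pos_i[o], traj[[field]][i, o], xout = positions,
                               rule = 1)$y
  }
  units <- c(C = "1/mm", theta = "rad", x = "mm", y = "mm")[[field]]
  kymograph(field, traj$times, positions, vals, units = units,
            axis_origin = axis_origin)
}
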