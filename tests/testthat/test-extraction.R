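# Measurement chain: midline, curvature, tracking, elongation, envelopes,
# apex-frame profiles.

test_that("midline extraction recovers straight and curved centrelines", {
  p <- growth_params(dE_max = 0, L0 = 120)
  traj <- simulate_rachis(p, t_end = 0.1, n_markers = 121L, save_every = 10L)
  fr <- render_frames(traj, noise_sd = 0, seed = 1L, frame_dt = 0.1,
                      setup = projection_setup("top"))
  ml <- extract_midline(fr$images[[1]], mm_per_px = fr$mm_per_px)
  # true centreline is the y = 0 axis; image origin offsets it by pad_mm
  y0 <- ml$y - (-fr$origin_mm[2])
  expect_lt(max(abs(y0[ml$s > 5 & ml$s < max(ml$s) - 5])),
            0.5 * fr$mm_per_px)
  # arc of radius 100 mm: recovered radius within 2%
  arc <- arc_trajectory(radius = 100)
  fra <- render_frames(arc, mm_per_px = 0.5, noise_sd = 0, seed = 1L,
                       frame_dt = 1, setup = projection_setup("top"))
  mla <- extract_midline(fra$images[[1]], mm_per_px = 0.5)
  fit <- taubin_circle_fit(mla$x, mla$y)
  expect_rel_equal(fit$r, 100, 0.02)
  expect_error(extract_midline(matrix(0, 50, 50)), "detection")
})

test_that("circle-fit curvature is exact on circles and zero on lines", {
  th <- seq(0, pi / 2, length.out = 200)
  ml <- data.frame(x = 10 * cos(th), y = 10 * sin(th), s = 10 * th)
  cc <- local_curvature(ml, window = 10)
  interior <- 20:180
  expect_equal(abs(cc[interior]), rep(0.1, length(interior)), tolerance = 1e-9)
  # counter-clockwise travel: left bending, positive sign
  expect_true(all(cc[interior] > 0))
  line <- data.frame(x = seq(0, 100, by = 0.5), y = 0,
                     s = seq(0, 100, by = 0.5))
  expect_equal(local_curvature(line, window = 10), rep(0, nrow(line)))
  expect_error(local_curvature(line, window = 1), "at least 5 points")
})

test_that("curvature from noisy circles has bounded median error", {
  set.seed(42)
  errs <- replicate(20, {
    th <- seq(0, pi, length.out = 300)
    r <- 10
    # jitter 1% of the radius, then the extraction pipeline's moving-median
    # presmoothing before the circle fit
    x <- stats::runmed(r * cos(th) + rnorm(300, 0, 0.01 * r), 9)
    y <- stats::runmed(r * sin(th) + rnorm(300, 0, 0.01 * r), 9)
    ml <- data.frame(x = x, y = y)
    ml$s <- c(0, cumsum(sqrt(diff(ml$x)^2 + diff(ml$y)^2)))
    cc <- local_curvature(ml, window = 10)
    median(abs(abs(cc[30:270]) - 1 / r)) / (1 / r)
  })
  expect_lt(median(errs), 0.1)
})

test_that("node tracking links detections under dropout and forbids swaps", {
  traj <- default_traj_coarse()
  clean <- make_node_tracks(traj, n_nodes = 8L, noise_sd = 0, dropout_p = 0,
                            seed = 1L)
  frames_from_tracks <- function(tr) {
    lapply(split(as.data.frame(tr)[tr$visible, ], tr$t[tr$visible]),
           function(d) d[order(d$node_id), c("u", "v")])
  }
  dets <- frames_from_tracks(clean)
  linked <- track_nodes(dets, times = sort(unique(clean$t)), max_disp = 5)
  expect_equal(linked$u, clean$u, tolerance = 1e-12)
  # 5% dropout: over 95% of links still match the ground truth
  noisy <- make_node_tracks(traj, n_nodes = 8L, noise_sd = 0.02,
                            dropout_p = 0.05, seed = 2L)
  dets2 <- frames_from_tracks(noisy)
  linked2 <- track_nodes(dets2, times = sort(unique(noisy$t)), max_disp = 5)
  truth_u <- matrix(noisy$u, ncol = 8L)
  link_u <- matrix(linked2$u, ncol = 8L)
  ok <- abs(truth_u - link_u) < 0.5
  expect_gt(mean(ok), 0.95)
  # an approaching pair whose nearest-neighbour match would swap order
  dets3 <- list(data.frame(u = c(0, 3), v = c(0, 0)),
                data.frame(u = c(2.9, 3.1), v = c(0, 0)))
  linked3 <- track_nodes(dets3, times = c(0, 1), max_disp = 10)
  u2 <- linked3$u[linked3$t == 1]
  expect_true(u2[1] < u2[2])
})

test_that("segment elongation recovers exponential separation exactly", {
  t <- seq(0, 5, by = 0.1)
  k <- 0.04; d0 <- 20
  tr <- data.frame(node_id = rep(1:2, each = length(t)), t = rep(t, 2),
                   u = c(rep(0, length(t)), d0 * exp(k * t)),
                   v = 0, visible = TRUE)
  class(tr) <- c("node_tracks", "data.frame")
  seg <- segment_elongation(tr, smooth = FALSE)
  expect_equal(as.vector(seg$values), rep(k, length(t)), tolerance = 1e-9)
  # constant distances: exactly zero before smoothing
  tr$u[tr$node_id == 2] <- d0
  seg0 <- segment_elongation(tr, smooth = FALSE)
  expect_equal(max(abs(seg0$values)), 0)
})

test_that("mature-zone segments show no systematic elongation", {
  traj <- default_traj_coarse()
  tr <- make_node_tracks(traj, n_nodes = 12L, noise_sd = 0.05,
                         dropout_p = 0.02, seed = 5L)
  seg <- segment_elongation(tr, smooth = FALSE)
  mature <- colMeans(seg$positions) > 120
  rates <- colMeans(seg$values[, mature, drop = FALSE], na.rm = TRUE)
  expect_lt(max(abs(rates)), 2e-3)
})

test_that("Hilbert envelope recovers constant and slowly varying amplitudes", {
  t <- seq(0, 12.5, by = 0.04)
  pos <- c(10, 20, 30)
  A <- 0.02
  vals <- cbind(A * sin(2 * pi * t / 2.5),
                A * (1 + 0.5 * t / max(t)) * sin(2 * pi * t / 2.5),
                0 * t)
  k <- kymograph("x", t, pos, vals, units = "1/h", axis_origin = "from_apex")
  env <- envelope(k)
  interior <- t > 2 & t < 10.5
  expect_lt(max(abs(env$values[interior, 1] - A)) / A, 0.03)
  truth2 <- A * (1 + 0.5 * t / max(t))
  expect_lt(max(abs(env$values[interior, 2] - truth2[interior]) /
                  truth2[interior]), 0.05)
  expect_equal(max(env$values[, 3]), 0)
  expect_true(all(env$values >= 0, na.rm = TRUE))
  short <- kymograph("x", t[1:8], pos, vals[1:8, ], units = "1/h",
                     axis_origin = "from_apex")
  expect_error(envelope(short), "too short")
})

test_that("apex-frame averaging is the identity for steady apex-origin fields", {
  t <- seq(0, 5, by = 0.25)
  pos <- seq(5, 145, by = 10)
  p <- growth_params()
  vals <- matrix(rep(mean_elongation_profile(p, pos), each = length(t)),
                 length(t), length(pos))
  k <- kymograph("elong", t, pos, vals, units = "1/h", axis_origin = "from_apex")
  prof <- time_average_profiles(k, bin_width = 10, max_dist = 145)
  keep <- !is.na(prof$mean_rate)
  expect_equal(prof$mean_rate[keep],
               mean_elongation_profile(p, prof$apex_dist[keep]),
               tolerance = 1e-12)
})

test_that("zero-noise extraction recovers the generating profile end to end", {
  traj <- default_traj_coarse()
  p <- traj$params
  tr <- make_node_tracks(traj, n_nodes = 12L, noise_sd = 0, dropout_p = 0,
                         seed = 1L)
  seg <- segment_elongation(tr, smooth = FALSE)
  prof <- time_average_profiles(seg, max_dist = 150)
  keep <- !is.na(prof$mean_rate) & prof$n_mean > 20
  # segment rates average the sigmoid over ~20 mm segments: compare to the
  # box-averaged truth
  truth <- sapply(prof$apex_dist[keep], function(ad) {
    mean(mean_elongation_profile(p, pmax(seq(ad - 10, ad + 10, by = 0.5), 0)))
  })
  expect_lt(max(abs(prof$mean_rate[keep] - truth)), 0.15 * p$Edot_max)
  fit <- fit_mean_profile(prof, n_boot = 0)
  expect_rel_equal(fit$estimates[["L_gz"]], p$L_gz, 0.1)
})

test_that("curvature-rate times width matches the differential rate at leading order", {
  traj <- default_traj()
  p <- traj$params
  dt <- diff(traj$times)[1]
  n <- length(traj$times)
  i <- seq(2, n - 1)
  Cdot <- (traj$C[i + 1, ] - traj$C[i - 1, ]) / (2 * dt)
  sp <- traj$apex_s[i] - traj$s[i, ]
  dE <- t(sapply(seq_along(i), function(k) {
    differential_elongation(p, sp[k, ], traj$times[i[k]])
  }))
  sel <- abs(traj$C[i, ] * p$W) < 0.05 & abs(dE) > 0.2 * p$dE_max
  expect_lt(max(abs(Cdot[sel] * p$W / dE[sel] - 1)), 0.05)
})

test_that("image-correlation elongation handles rest, stretch and simulation", {
  # uniform stretch between two frames: recovered rate within 5%
  eps <- 0.02; n <- 600
  set.seed(9)
  tex <- stats::filter(runif(n + 40) - 0.5, rep(1 / 9, 9), sides = 2)
  tex <- as.numeric(tex)[21:(20 + n)]
  prof1 <- 0.55 + tex
  prof2 <- approx(seq_len(n), prof1, xout = seq_len(n) / (1 + eps),
                  rule = 2)$y
  mk <- function(pr) matrix(rep(pr, each = 20), 20)
  frs <- structure(list(times = c(0, 0.5), images = list(mk(prof1), mk(prof2)),
                        mm_per_px = 0.25, plane_label = "side",
                        origin_mm = c(0, 0)), class = "frame_sequence")
  dks <- dic_elongation(frs)
  expect_rel_equal(mean(dks$values, na.rm = TRUE), eps / 0.5, 0.05)
  # identical frames: displacement and rate exactly zero
  fr0 <- frs; fr0$images <- list(mk(prof1), mk(prof1))
  dk0 <- dic_elongation(fr0)
  expect_equal(max(abs(dk0$values), na.rm = TRUE), 0)
  # intensity rescaling invariance
  fr2 <- frs; fr2$images <- lapply(frs$images, function(m) 0.5 * m)
  expect_equal(dic_elongation(fr2)$values, dks$values, tolerance = 1e-9)
})

test_that("image-correlation rates track the projected truth on synthetic nutation", {
  p <- growth_params(L0 = 120, dE_max = 0.1)
  traj <- simulate_rachis(p, t_end = 2 * p$T, save_every = 5L,
                          n_markers = 121L)
  ak <- apparent_elongation(traj, projection_setup("side"),
                            positions = seq(5, 115, by = 1))
  fr <- render_frames(traj, noise_sd = 0.01, seed = 3L, t_max = 2 * p$T)
  dk <- dic_elongation(fr, lag = 15L)
  x_apex <- approx(traj$times, traj$x[, ncol(traj$x)], dk$times, rule = 2)$y
  err <- c(); tru <- c()
  truth_at <- function(tt) {
    sapply(seq_along(ak$positions), function(j) {
      approx(ak$times, ak$values[, j], tt, rule = 2)$y
    })
  }
  for (i in seq(1, length(dk$times), by = 5)) {
    ad <- x_apex[i] - dk$positions
    ok <- ad > 5 & ad < 60
    tv <- approx(ak$positions, truth_at(dk$times[i]), xout = ad[ok])$y
    err <- c(err, dk$values[i, ok] - tv)
    tru <- c(tru, tv)
  }
  rms <- sqrt(mean(err^2, na.rm = TRUE))
  expect_lt(rms, 0.15 * sd(tru, na.rm = TRUE))
})
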