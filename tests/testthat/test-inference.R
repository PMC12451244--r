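# Model fitting, the amplitude relation and the contraction criterion.

make_profile <- function(p, noise = 0, seed = NULL, bins = seq(5, 145, by = 10)) {
  if (!is.null(seed)) set.seed(seed)
  y <- mean_elongation_profile(p, bins)
  if (noise > 0) y <- y * (1 + noise * rnorm(length(bins)))
  structure(data.frame(apex_dist = bins, mean_rate = y,
                       diff_rate_envelope = NA_real_, n_mean = 50L,
                       n_diff = 0L),
            class = c("profile_pair", "data.frame"))
}

test_that("sigmoid fit recovers noise-free profiles exactly", {
  p <- growth_params()
  fit <- fit_mean_profile(make_profile(p), n_boot = 0)
  expect_equal(unname(fit$estimates),
               c(p$Edot_max, p$L_gz, p$lambda_gz), tolerance = 1e-6)
  expect_lt(max(abs(fit$residuals)), 1e-8)
})

test_that("sigmoid fit recovers the growth-zone length under multiplicative noise", {
  p <- growth_params()
  ests <- sapply(1:100, function(s) {
    fit_mean_profile(make_profile(p, noise = 0.1, seed = s),
                     n_boot = 0)$estimates[["L_gz"]]
  })
  expect_rel_equal(median(ests), p$L_gz, 0.1)
})

test_that("profiles without decay are rejected, not silently fitted", {
  p <- growth_params()
  flat <- make_profile(p, bins = seq(1, 30, length.out = 10))
  expect_error(fit_mean_profile(flat, n_boot = 0), "decay")
  expect_error(fit_mean_profile(make_profile(p)[1:5, ], n_boot = 0),
               "8 valid bins")
})

test_that("bootstrap intervals cover the generating parameters", {
  p <- growth_params()
  fit <- fit_mean_profile(make_profile(p, noise = 0.1, seed = 2),
                          n_boot = 100, seed = 1)
  expect_true(fit$ci["L_gz", 1] < p$L_gz && p$L_gz < fit$ci["L_gz", 2])
})

test_that("differential amplitude is fitted with the envelope shape fixed", {
  p <- growth_params()
  bins <- seq(5, 145, by = 10)
  mean_fit <- fit_mean_profile(make_profile(p), n_boot = 0)
  prof <- data.frame(apex_dist = bins,
                     diff_rate_envelope = p$dE_max *
                       (1 / cosh((bins - p$L_gz) / p$lambda_gz))^2,
                     n_diff = 30L)
  set.seed(3)
  prof$diff_rate_envelope <- prof$diff_rate_envelope +
    rnorm(length(bins), 0, 0.02 * p$dE_max)
  fit <- fit_differential_profile(prof, mean_fit, n_boot = 50, seed = 1)
  expect_rel_equal(fit$dE_max, p$dE_max, 0.05)
  # envelope peak sits within lambda of the fitted growth-zone edge
  expect_lt(abs(fit$envelope_peak - mean_fit$estimates[["L_gz"]]),
            p$lambda_gz)
  prof$diff_rate_envelope <- 0
  expect_equal(fit_differential_profile(prof, mean_fit, n_boot = 0)$dE_max, 0)
})

test_that("the amplitude relation inverts the apex-deflection chain", {
  # 25 degrees, beam radius 1.5 mm, period 2.5 h, bending zone 15 mm
  expect_equal(amplitude_relation(25 * pi / 180, 1.5, 2.5, 15),
               0.01745329, tolerance = 1e-6)
  expect_equal(amplitude_relation(0.4, 1.5, 5, 15),
               amplitude_relation(0.4, 1.5, 2.5, 15) / 2)
  expect_error(amplitude_relation(-0.1, 1.5, 2.5, 15), "> 0")
})

test_that("the simulated apex amplitude round-trips through the closed-form relation", {
  A <- 25 * pi / 180
  p0 <- growth_params()
  dE <- amplitude_relation(A, p0$W / 2, p0$T, p0$L_bz, prefactor = 2 * pi)
  p <- growth_params(Edot_max = 0, dE_max = dE)
  traj <- simulate_rachis(p, t_end = 5 * p$T)
  th <- traj$theta[, ncol(traj$theta)]
  A_sim <- (max(th) - min(th)) / 2
  expect_rel_equal(A_sim, A, 0.25)
})

test_that("contraction requires the differential amplitude to exceed the threshold", {
  p <- growth_params(dE_max = 0)
  ct <- contraction_test(p)
  expect_false(ct$flag)
  expect_gte(ct$margin, 0)
  ct2 <- contraction_test(growth_params(dE_max = 2 * 0.05))
  expect_true(ct2$flag)
  # monotone: increasing the amplitude never rescues a contracting organ
  margins <- sapply(seq(0.005, 0.12, by = 0.005), function(d) {
    contraction_test(growth_params(dE_max = d))$margin
  })
  expect_true(all(diff(margins) <= 1e-12))
  # sufficiency: any amplitude above the plateau rate contracts
  for (d in c(0.051, 0.075, 0.2)) {
    expect_true(contraction_test(growth_params(dE_max = d))$flag)
  }
})

test_that("the growth-zone contraction threshold equals the plateau rate", {
  # within the growth zone the exact threshold is Edot_max, attained at the
  # growth-zone edge where the envelope peaks; basally the exponential tails
  # lower the formal threshold toward Edot_max / 2
  Edot <- 0.05
  gz_margin <- function(d) {
    contraction_test(growth_params(Edot_max = Edot, dE_max = d),
                     domain = c(0, 50))$margin
  }
  thr <- uniroot(gz_margin, c(0.01, 0.2), tol = 1e-8)$root
  expect_rel_equal(thr, Edot, 1e-3)
  full_margin <- function(d) {
    contraction_test(growth_params(Edot_max = Edot, dE_max = d))$margin
  }
  thr_full <- uniroot(full_margin, c(0.01, 0.2), tol = 1e-8)$root
  expect_rel_equal(thr_full, Edot / 2, 0.01)
})

test_that("the wavelet-kymograph fit recovers the differential amplitude", {
  traj <- default_traj()
  p <- traj$params
  ak <- apparent_elongation(traj, projection_setup("side"), face = "outer",
                            positions = seq(10, 90, by = 5))
  obs <- energy_kymograph(ak)
  fit <- fit_wavelet_kymograph(obs, p, free = list(dE_max = 2 * p$dE_max),
                               sim_opts = list(n_markers = 121L),
                               grid_n = 4L, maxit = 20L)
  expect_true(fit$convergence)
  expect_rel_equal(fit$free[["dE_max"]], p$dE_max, 0.1)
  expect_equal(fit$fixed$T$provenance, "measured and fixed before fitting")
  # the best-fit model reproduces the two-mode layout
  expect_equal(obs$n_modes, 2L)
  # ablation: the midline (no differential material term) energy map loses
  # the basal nutation-period mode and fits the observation worse
  ak0 <- apparent_elongation(traj, projection_setup("side"), face = "midline",
                             positions = obs$positions)
  em0 <- energy_kymograph(ak0, periods = obs$periods)
  d0 <- em0$energy - obs$energy
  expect_gt(sqrt(sum(d0[is.finite(d0)]^2)), 2 * fit$objective)
})

test_that("objectives invariant to global energy rescaling of the observation", {
  traj <- default_traj()
  p <- traj$params
  ak <- apparent_elongation(traj, projection_setup("side"), face = "outer",
                            positions = seq(20, 80, by = 10))
  obs <- energy_kymograph(ak)
  # per-position normalization makes a global rescaling of the underlying
  # signal invisible to the map
  ak2 <- ak
  ak2$values <- ak$values * 3
  obs2 <- energy_kymograph(ak2, periods = obs$periods)
  expect_equal(obs2$energy, obs$energy, tolerance = 1e-9)
})
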