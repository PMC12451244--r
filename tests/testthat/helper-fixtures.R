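# Shared fixtures; expensive simulations are computed once per test run.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# default study conditions, full nutation record (5 periods)
default_traj <- function() {
  fixture("default_traj", {
    p <- growth_params()
    simulate_rachis(p, t_end = 5 * p$T,
                    save_every = round((2.5 / 60) / (p$T / 500)))
  })
}

# same organ, coarser save cadence for track-based work
default_traj_coarse <- function() {
  fixture("default_traj_coarse", {
    p <- growth_params()
    simulate_rachis(p, t_end = 5 * p$T, save_every = 5L)
  })
}

# non-growing organ with strong differential elongation (pure bending)
bending_only_traj <- function() {
  fixture("bending_only_traj", {
    p <- growth_params(Edot_max = 0, dE_max = 0.05)
    simulate_rachis(p, t_end = 5 * p$T)
  })
}

# hand-built trajectory of a static arc (constant curvature), for rendering
arc_trajectory <- function(radius = 100, length = 150, n = 101,
                           params = growth_params()) {
  s <- seq(0, length, length.out = n)
  th <- s / radius
  structure(list(times = c(0, 1), material_ids = seq_len(n),
                 s = rbind(s, s), C = rbind(rep(1 / radius, n), rep(1 / radius, n)),
                 theta = rbind(th, th),
                 x = rbind(radius * sin(th), radius * sin(th)),
                 y = rbind(radius * (1 - cos(th)), radius * (1 - cos(th))),
                 apex_s = c(length, length), params = params),
            class = "rachis_trajectory")
}

# hand-built oscillating trajectory: fixed arclengths, uniform angle
# theta(t) = theta0 sin(2 pi t / T), no growth (pure projection fixture)
swinging_trajectory <- function(theta0 = 0.2, T = 2.5, L = 100, n_m = 21,
                                dt = 0.01) {
  times <- seq(0, 5 * T, by = dt)
  s <- seq(0, L, length.out = n_m)
  nt <- length(times)
  th <- outer(sin(2 * pi * times / T) * theta0, rep(1, n_m))
  xs <- matrix(NA_real_, nt, n_m)
  ys <- matrix(NA_real_, nt, n_m)
  for (i in seq_len(nt)) {
    xs[i, ] <- s * cos(th[i, 1])
    ys[i, ] <- s * sin(th[i, 1])
  }
  structure(list(times = times, material_ids = seq_len(n_m),
                 s = matrix(s, nt, n_m, byrow = TRUE),
                 C = matrix(0, nt, n_m), theta = th, x = xs, y = ys,
                 apex_s = rep(L, nt), params = growth_params(theta_base = 0)),
            class = "rachis_trajectory")
}

expect_rel_equal <- function(object, expected, tol) {
  expect_lt(abs(object / expected - 1), tol)
}
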