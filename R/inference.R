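#' Fit the sigmoid growth law to a time-averaged elongation profile
#'
#' Weighted least-squares fit of
#' `Edot(s') = Edot_max / 2 * (1 - tanh((s' - L_gz) / lambda))`
#' to the mean-rate column of a [time_average_profiles()] result, with bin
#' counts as weights and bootstrap (over bins) confidence intervals.
#'
#' @param profile a `profile_pair` (or data.frame with `apex_dist`,
#'   `mean_rate`, optionally `n_mean`).
#' @param n_boot bootstrap resamples for the CIs (0 to skip).
#' @param seed seed for the bootstrap.
#' @param conf confidence level.
#' @return list of class `profile_fit`: `estimates` (named
#'   `Edot_max`, `L_gz`, `lambda_gz`), `ci` (matrix), `fitted`, `residuals`,
#'   `objective` (weighted RSS), `convergence`, `n_bins`, `boot_seed`.
#' @export
fit_mean_profile <- function(profile, n_boot = 200L, seed = 1L, conf = 0.95) {
  d <- data.frame(s = profile$apex_dist, y = profile$mean_rate,
                  w = if ("n_mean" %in% names(profile)) profile$n_mean else 1)
  d <- d[stats::complete.cases(d) & d$w > 0, ]
  if (nrow(d) < 8L) stop("fit error: need at least 8 valid bins spanning the transition")
  ymax <- max(d$y)
  ymin <- min(d$y)
  if (!(ymin < 0.5 * ymax) || ymax <= 0) {
    stop("fit error: profile does not decay within the window (unidentifiable)")
  }
  fit1 <- function(dd) {
    start <- list(Emax = max(dd$y),
                  Lgz = dd$s[which.min(abs(dd$y - max(dd$y) / 2))],
                  lam = diff(range(dd$s)) / 6)
    ft <- minpack.lm::nlsLM(y ~ Emax / 2 * (1 - tanh((s - Lgz) / lam)),
                            data = dd, start = start, weights = dd$w,
                            lower = c(0, 0, 1e-6),
                            control = minpack.lm::nls.lm.control(maxiter = 200))
    stats::coef(ft)
  }
  co <- tryCatch(fit1(d), error = function(e) stop("fit error: ", conditionMessage(e)))
  est <- c(Edot_max = unname(co["Emax"]), L_gz = unname(co["Lgz"]),
           lambda_gz = unname(co["lam"]))
  fitted <- est[1] / 2 * (1 - tanh((d$s - est[2]) / est[3]))
  resid <- d$y - fitted
  ci <- NULL
  if (n_boot > 0L) {
    old_seed <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
    set.seed(as.integer(seed))
    bs <- replicate(n_boot, {
      dd <- d[sample.int(nrow(d), replace = TRUE), ]
      tryCatch(fit1(dd), error = function(e) c(Emax = NA, Lgz = NA, lam = NA))
    })
    al <- (1 - conf) / 2
    ci <- t(apply(bs, 1L, stats::quantile, probs = c(al, 1 - al), na.rm = TRUE))
    rownames(ci) <- names(est)
  }
  structure(list(estimates = est, ci = ci, fitted = fitted, residuals = resid,
                 objective = sum(d$w * resid^2), convergence = TRUE,
                 n_bins = nrow(d), boot_seed = seed),
            class = "profile_fit")
}

#' Fit the differential-elongation amplitude with a fixed envelope shape
#'
#' The spatial shape of the differential-rate envelope is fixed to the
#' normalized derivative of the fitted mean-rate sigmoid,
#' `g(s') = sech^2((s' - L_gz) / lambda)`, and only the amplitude is
#' estimated (weighted linear least squares), with bootstrap CIs.
#'
#' @param envelope_profile a `profile_pair` (uses `diff_rate_envelope` and
#'   `n_diff`), or a data.frame with `apex_dist` and `diff_rate_envelope`.
#' @param mean_fit a `profile_fit` from [fit_mean_profile()].
#' @param n_boot,seed,conf as in [fit_mean_profile()].
#' @return list of class `amplitude_fit`: `dE_max`, `ci`, `envelope_peak`
#'   (the fitted peak location `L_gz`), `n_bins`.
#' @export
fit_differential_profile <- function(envelope_profile, mean_fit,
                                     n_boot = 200L, seed = 1L, conf = 0.95) {
  d <- data.frame(s = envelope_profile$apex_dist,
                  y = envelope_profile$diff_rate_envelope,
                  w = if ("n_diff" %in% names(envelope_profile)) {
                    envelope_profile$n_diff
                  } else 1)
  d <- d[stats::complete.cases(d) & d$w > 0, ]
  if (nrow(d) < 3L) stop("fit error: too few valid envelope bins")
  L <- mean_fit$estimates[["L_gz"]]
  lam <- mean_fit$estimates[["lambda_gz"]]
  g <- sech2((d$s - L) / lam)
  amp <- function(dd, gg) sum(dd$w * gg * dd$y) / sum(dd$w * gg^2)
  a <- amp(d, g)
  ci <- NULL
  if (n_boot > 0L) {
    old_seed <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
    set.seed(as.integer(seed))
    bs <- replicate(n_boot, {
      i <- sample.int(nrow(d), replace = TRUE)
      amp(d[i, ], g[i])
    })
    al <- (1 - conf) / 2
    ci <- stats::quantile(bs, probs = c(al, 1 - al), na.rm = TRUE)
  }
  structure(list(dE_max = a, ci = ci, envelope_peak = L, n_bins = nrow(d)),
            class = "amplitude_fit")
}

#' Differential-growth amplitude from the apex oscillation amplitude
#'
#' Order-of-magnitude inversion of the amplitude chain: the differential
#' growth accumulated over one nutation period, `dE_max * T`, divided by the
#' beam radius `R` gives the curvature amplitude, and integrated over the
#' bending-zone length `L_bz` gives the apex angular deviation `A`; hence
#' \deqn{\delta E_{max} = \kappa\, \frac{A\,R}{T\,L_{bz}}}
#' with `prefactor` \eqn{\kappa = 1} by default (the order-of-magnitude
#' form). The exact small-amplitude closed form of the simulated model has
#' \eqn{\kappa = 2\pi}: sine forcing integrates to `T / (2 pi)` rather than
#' `T`, the `sech^2` envelope integrates to `2 L_bz`, and `W = 2 R`, so
#' `A_exact = dE_max T L_bz / (2 pi R)`. Use `prefactor = 2 * pi` when a
#' quantitative round trip against [simulate_rachis()] is intended.
#'
#' @param A apex angular amplitude (rad).
#' @param R beam radius `W / 2` (mm).
#' @param T nutation period (h).
#' @param L_bz bending-zone envelope width (mm).
#' @param prefactor dimensionless O(1)--O(2 pi) constant, see Details.
#' @return differential-elongation amplitude (1/h).
#' @examples
#' amplitude_relation(25 * pi / 180, R = 1.5, T = 2.5, L_bz = 15)
#' @export
amplitude_relation <- function(A, R, T, L_bz, prefactor = 1) {
  if (any(c(A, R, T, L_bz, prefactor) <= 0)) stop("all inputs must be > 0")
  prefactor * A * R / (T * L_bz)
}

#' Test whether the growth law implies local tissue contractions
#'
#' Evaluates the minimum over apex distance, time phase, and face of the
#' face elongation rates `Edot(s') +/- dE_max g(s') / 2` (the sine
#' modulation attains both extremes over a period, so the minimum face rate
#' is `min_s [Edot(s) - dE_max g(s) / 2]`). The organ locally contracts iff
#' this minimum is negative. With the envelope centred at the sigmoid
#' midpoint (`s_bz = L_gz`), `dE_max > Edot_max` is a sufficient condition:
#' within the growth zone (`s' <= L_gz`) the exact threshold is
#' `Edot_max / (1 + tanh((s' - L_gz)/lambda)) >= Edot_max`, attained at the
#' growth-zone edge; basally the required amplitude keeps decreasing toward
#' `Edot_max / 2` while both rates decay exponentially, so the full-organ
#' margin is reported along with the location of the minimum.
#'
#' @param params a [growth_params()].
#' @param domain apex-distance range `c(lo, hi)` scanned (mm); default the
#'   whole organ `c(0, L0)`.
#' @param n_s grid resolution.
#' @return list with `flag` (`TRUE` if a face contracts), `margin` (the
#'   minimum face rate, 1/h) and `s_min` (apex distance of the minimum, mm).
#' @export
contraction_test <- function(params, domain = c(0, params$L0), n_s = 2001L) {
  s <- seq(domain[1L], domain[2L], length.out = n_s)
  mrate <- mean_elongation_profile(params, s)
  denv <- params$dE_max * diff_envelope(params, s)
  worst <- mrate - denv / 2
  i <- which.min(worst)
  list(flag = worst[i] < 0, margin = worst[i], s_min = s[i])
}

#' Fit the kinematic model to an observed wavelet energy map
#'
#' Simulates the model, projects it to the observed view, computes the
#' apparent elongation-rate energy map on the observed position/period
#' grids, and minimizes the Frobenius distance between the per-position
#' normalized maps over the requested free parameters (coarse grid search
#' followed by Nelder--Mead refinement). All other parameters are fixed, as
#' when geometry and period are measured before fitting. Deterministic
#' given its inputs.
#'
#' @param observed a `wavelet_energy_map` (per-position normalization).
#' @param fixed a [growth_params()] carrying the fixed parameter values.
#' @param free named list of initial values for the free parameters (names
#'   among the [growth_params()] fields).
#' @param lower,upper named bounds for the free parameters; defaults are
#'   `init / 4` and `init * 4`.
#' @param sim_opts list of simulation options: `t_end`, `dt`, `n_markers`,
#'   `face`, and the `setup` projection.
#' @param grid_n points per free parameter in the coarse grid stage.
#' @param maxit Nelder--Mead iteration budget.
#' @return list of class `fit_result`: `free` (estimates), `fixed` (with
#'   provenance `"measured and fixed before fitting"`), `objective`,
#'   `convergence`, `contraction` (flag + margin at the optimum),
#'   `n_evals`.
#' @export
fit_wavelet_kymograph <- function(observed, fixed, free,
                                  lower = NULL, upper = NULL,
                                  sim_opts = list(), grid_n = 5L,
                                  maxit = 60L) {
  stopifnot(length(free) >= 1L, !is.null(names(free)))
  so <- utils::modifyList(list(t_end = 5 * fixed$T, dt = fixed$T / 500,
                               n_markers = 121L, face = "outer",
                               setup = projection_setup("side")),
                          sim_opts)
  pn <- names(free)
  init <- unlist(free)
  lower <- unlist(lower %||% as.list(init / 4))[pn]
  upper <- unlist(upper %||% as.list(init * 4))[pn]
  n_evals <- 0L
  obs_E <- observed$energy
  objective <- function(theta) {
    if (any(theta < lower) || any(theta > upper) || any(!is.finite(theta))) {
      return(1e6)
    }
    p <- tryCatch(update_growth_params(fixed, as.list(stats::setNames(theta, pn))),
                  error = function(e) NULL)
    if (is.null(p)) return(1e6)
    n_evals <<- n_evals + 1L
    traj <- simulate_rachis(p, t_end = so$t_end, dt = so$dt,
                            n_markers = so$n_markers,
                            save_every = max(1L, round((2.5 / 60) / so$dt)))
    ak <- apparent_elongation(traj, so$setup, face = so$face,
                              positions = observed$positions)
    em <- energy_kymograph(ak, periods = observed$periods,
                           normalize = observed$normalization %||% "position")
    d <- em$energy - obs_E
    ok <- is.finite(d)
    if (!any(ok)) return(1e6)
    sqrt(sum(d[ok]^2))
  }
  # coarse grid
  axes <- lapply(seq_along(pn), function(k) seq(lower[k], upper[k], length.out = grid_n))
  grid <- as.matrix(expand.grid(axes))
  vals <- apply(grid, 1L, objective)
  if (diff(range(vals)) < 1e-10 * max(abs(vals), 1e-12)) {
    return(structure(list(free = NULL, fixed = fixed, objective = NA_real_,
                          convergence = FALSE, unidentifiable = TRUE,
                          contraction = NULL, n_evals = n_evals),
                     class = "fit_result"))
  }
  best <- grid[which.min(vals), ]
  opt <- if (length(pn) == 1L) {
    stats::optim(best, objective, method = "Brent", lower = lower,
                 upper = upper, control = list(maxit = maxit, reltol = 1e-4))
  } else {
    stats::optim(best, objective, method = "Nelder-Mead",
                 control = list(maxit = maxit, reltol = 1e-4))
  }
  est <- stats::setNames(as.numeric(opt$par), pn)
  p_hat <- update_growth_params(fixed, as.list(est))
  ctr <- contraction_test(p_hat)
  structure(list(free = est,
                 fixed = stats::setNames(
                   lapply(setdiff(names(unclass(fixed)), pn), function(f) {
                     list(value = fixed[[f]],
                          provenance = "measured and fixed before fitting")
                   }), setdiff(names(unclass(fixed)), pn)),
                 objective = opt$value, convergence = opt$convergence == 0L,
                 unidentifiable = FALSE, contraction = ctr,
                 n_evals = n_evals),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  if (isTRUE(x$unidentifiable)) {
    cat("fit_result: objective flat over the search grid (unidentifiable); no estimate\n")
    return(invisible(x))
  }
  cat("fit_result:\n  free parameters:\n")
  for (nm in names(x$free)) cat(sprintf("    %-10s %.5g\n", nm, x$free[[nm]]))
  cat(sprintf("  objective %.5g after %d model evaluations (converged: %s)\n",
              x$objective, x$n_evals, x$convergence))
  if (!is.null(x$contraction)) {
    cat(sprintf("  local contraction: %s (margin %.4g /h at s' = %.3g mm)\n",
                x$contraction$flag, x$contraction$margin, x$contraction$s_min))
  }
  invisible(x)
}
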