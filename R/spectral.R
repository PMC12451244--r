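#' Second-order complex-Gaussian mother wavelet
#'
#' The analytic form of the `cgau2` wavelet: the second derivative of the
#' modulated Gaussian `exp(-i x) exp(-x^2)`, L2-normalized,
#' \deqn{\psi(x) = \frac{4x^2 - 3 + 4ix}{\sqrt{5\sqrt{2\pi}}}\, e^{-ix - x^2}.}
#' Its amplitude spectrum peaks at angular frequency `(1 + sqrt(17)) / 2`,
#' i.e. a centre frequency of about 0.40768 cycles per unit `x`, which is
#' what maps wavelet scale to signal period.
#'
#' @param x evaluation points.
#' @return complex wavelet values.
#' @export
cgau2 <- function(x) {
  (4 * x^2 - 3 + 4i * x) * exp(-1i * x - x^2) / sqrt(5 * sqrt(2 * pi))
}

#' Centre frequency of the cgau2 wavelet (cycles per unit x)
#' @export
cgau2_center_frequency <- function() (1 + sqrt(17)) / (4 * pi)

#' Continuous wavelet transform energy of a time series
#'
#' Computes complex CWT coefficients `C(a, b)` with the [cgau2()] mother
#' wavelet by direct convolution, `C(a, b) = sum_t x(t) conj(psi((t - b) / a))
#' / a` (L1 normalization, so a pure tone's energy peaks at the tone's
#' period under the centre-frequency scale mapping), on scales chosen so
#' that each requested signal period maps to the wavelet's centre frequency.
#' The per-cell energy is `|C(a, b)|^2`. Cells inside the cone of influence
#' (within two scales of either record edge, where coefficients are
#' edge-contaminated) are flagged.
#'
#' @param series real time series (equally spaced; mean removed internally).
#' @param periods analyzed periods (h), strictly increasing; must lie within
#'   `[4 dt, record length / 4]`.
#' @param dt sampling interval (h).
#' @param detrend remove the series mean before transforming.
#' @return list with `periods`, `times` (sample index times, h), `energy`
#'   (period x time matrix), `coi` (logical matrix, `TRUE` where
#'   edge-contaminated) and `coef` (complex coefficients).
#' @export
cwt_energy <- function(series, periods, dt, detrend = TRUE) {
  n <- length(series)
  if (any(diff(periods) <= 0)) stop("periods must be strictly increasing")
  # the record-length bound gets a 10% grace (the cone of influence already
  # flags edge-contaminated cells); the Nyquist-side bound is hard
  if (min(periods) < 4 * dt * (1 - 1e-9) || max(periods) > n * dt / 4 * 1.1) {
    stop("period range outside the Nyquist / record-length bounds [4 dt, n dt / 4]")
  }
  x <- series
  if (detrend) x <- x - mean(x)
  fc <- cgau2_center_frequency()
  scales <- fc * periods / dt  # in samples
  coef <- matrix(0i, length(periods), n)
  coi <- matrix(FALSE, length(periods), n)
  for (k in seq_along(scales)) {
    a <- scales[k]
    K <- ceiling(5 * a)
    kern <- Conj(cgau2((-K:K) / a)) / a
    # C(b) = sum_t x[t] conj(psi((t-b)/a))/a: correlation of x with kern
    full <- conv_full(x, rev(kern))
    coef[k, ] <- full[(K + 1L):(K + n)]
    edge <- ceiling(2 * a)
    if (edge >= 1L) {
      idx <- unique(c(seq_len(min(edge, n)), seq.int(max(1L, n - edge + 1L), n)))
      coi[k, idx] <- TRUE
    }
  }
  list(periods = periods, times = (seq_len(n) - 1L) * dt,
       energy = Mod(coef)^2, coi = coi, coef = coef)
}

# full linear convolution via FFT (complex-safe)
conv_full <- function(x, y) {
  nx <- length(x); ny <- length(y)
  N <- stats::nextn(nx + ny - 1L, 2L)
  xf <- stats::fft(c(x, rep(0, N - nx)))
  yf <- stats::fft(c(y, rep(0i, N - ny)))
  stats::fft(xf * yf, inverse = TRUE)[seq_len(nx + ny - 1L)] / N
}

#' Default logarithmic period grid (32 voices per octave)
#'
#' @param dt sampling interval (h).
#' @param n record length (samples).
#' @param voices grid points per octave.
#' @return strictly increasing periods spanning `[4 dt, n dt / 4]`.
#' @export
default_periods <- function(dt, n, voices = 32L) {
  lo <- 4 * dt
  hi <- n * dt / 4
  if (hi <= lo) stop("record too short for wavelet analysis")
  2^seq(log2(lo), log2(hi), by = 1 / voices)
}

#' Wavelet energy map of a kymograph
#'
#' Wavelet-transforms the time series at every position of a kymograph,
#' aggregates energy over time (mean of `|C|^2` outside the cone of
#' influence), and normalizes. The dominant period per position is the
#' argmax of the aggregated energy; the number of distinct dominant modes is
#' the count of dominant-period plateaus separated by more than one grid
#' step and each spanning at least 10% of the positions.
#'
#' @param kymo a [kymograph()].
#' @param periods analyzed periods (h); default [default_periods()].
#' @param normalize `"position"` (each position's aggregated energy scaled
#'   to unit maximum, the default), `"global"`, or `"none"`.
#' @param min_frac minimum fraction of unmasked samples for a position to be
#'   analyzed.
#' @return an object of class `wavelet_energy_map`: list with `positions`,
#'   `axis_origin`, `periods`, `energy` (period x position), `dominant_period`
#'   (per position, `NA` where excluded) and `n_modes`.
#' @export
energy_kymograph <- function(kymo, periods = NULL,
                             normalize = c("position", "global", "none"),
                             min_frac = 0.9) {
  normalize <- match.arg(normalize)
  dt <- stats::median(diff(kymo$times))
  nt <- length(kymo$times)
  if (is.null(periods)) periods <- default_periods(dt, nt)
  np <- length(kymo$positions)
  E <- matrix(NA_real_, length(periods), np)
  for (j in seq_len(np)) {
    col <- kymo$values[, j]
    ok <- !is.na(col)
    if (mean(ok) < min_frac) next
    col[!ok] <- mean(col[ok])
    cw <- cwt_energy(col, periods, dt)
    e <- cw$energy
    e[cw$coi] <- NA_real_
    E[, j] <- rowMeans(e, na.rm = TRUE)
  }
  if (normalize == "position") {
    mx <- apply(E, 2L, function(col) if (all(is.na(col))) NA_real_ else max(col, na.rm = TRUE))
    E <- sweep(E, 2L, mx, "/")
    E[!is.finite(E)] <- NA_real_
  } else if (normalize == "global") {
    E <- E / max(E, na.rm = TRUE)
  }
  idx <- apply(E, 2L, function(col) {
    if (all(is.na(col))) NA_integer_ else which.max(col)
  })
  dom <- refine_peak_period(E, idx, periods)
  structure(list(positions = kymo$positions, axis_origin = kymo$axis_origin,
                 periods = periods, energy = E, dominant_period = dom,
                 n_modes = count_modes_idx(idx),
                 normalization = normalize),
            class = "wavelet_energy_map")
}

# parabolic (sub-grid) refinement of the energy peak in log-period space
refine_peak_period <- function(E, idx, periods) {
  lp <- log2(periods)
  vapply(seq_along(idx), function(j) {
    i <- idx[j]
    if (is.na(i)) return(NA_real_)
    if (i <= 1L || i >= length(periods)) return(periods[i])
    y0 <- E[i - 1L, j]; y1 <- E[i, j]; y2 <- E[i + 1L, j]
    if (anyNA(c(y0, y1, y2))) return(periods[i])
    den <- y0 - 2 * y1 + y2
    frac <- if (den < 0) 0.5 * (y0 - y2) / den else 0
    frac <- max(-0.5, min(0.5, frac))
    2^(lp[i] + frac * (lp[2L] - lp[1L]))
  }, numeric(1))
}

# plateaus of the dominant period: levels separated by > 1 grid step, each
# spanning >= 10% of positions
count_modes_idx <- function(idx, min_span = 0.1) {
  ok <- !is.na(idx)
  if (!any(ok)) return(0L)
  idx <- idx[ok]
  # two dominant-period values belong to the same mode if they are linked by
  # a chain of occupied grid indices no more than one step apart (a slowly
  # drifting ridge is one mode); isolated handover points are not
  u <- sort(unique(idx))
  level_id <- cumsum(c(1L, diff(u) > 1L))
  spans <- vapply(split(u, level_id), function(lev) sum(idx %in% lev),
                  integer(1))
  sum(spans >= min_span * length(idx))
}

#' @export
print.wavelet_energy_map <- function(x, ...) {
  cat(sprintf("wavelet_energy_map: %d positions x %d periods [%.3g, %.3g] h, %d dominant mode(s)\n",
              length(x$positions), length(x$periods), min(x$periods),
              max(x$periods), x$n_modes))
  invisible(x)
}

#' Write / read a wavelet energy map as tabular text with a JSON header
#' @param emap a `wavelet_energy_map`.
#' @param path file path.
#' @return `write_energy_map` returns `path` invisibly; `read_energy_map`
#'   the reconstructed map.
#' @export
write_energy_map <- function(emap, path) {
  hdr <- jsonlite::toJSON(list(kind = "wavelet_energy_map",
                               axis_origin = emap$axis_origin,
                               normalization = emap$normalization,
                               n_modes = emap$n_modes,
                               period_units = "h", position_units = "mm"),
                          auto_unbox = TRUE, digits = NA)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", hdr), con)
  m <- cbind(emap$periods, emap$energy)
  colnames(m) <- c("period", format(emap$positions, digits = 17, trim = TRUE,
                                    scientific = FALSE))
  utils::write.csv(format(as.data.frame(m), digits = 17, trim = TRUE), con,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_energy_map
#' @export
read_energy_map <- function(path) {
  first <- readLines(path, n = 1L)
  hdr <- jsonlite::fromJSON(sub("^#", "", first))
  tab <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  periods <- tab[[1L]]
  positions <- as.numeric(colnames(tab)[-1L])
  E <- as.matrix(tab[, -1L, drop = FALSE])
  idx <- apply(E, 2L, function(col) {
    if (all(is.na(col))) NA_integer_ else which.max(col)
  })
  structure(list(positions = positions, axis_origin = hdr$axis_origin,
                 periods = periods, energy = E,
                 dominant_period = refine_peak_period(E, idx, periods),
                 n_modes = count_modes_idx(idx),
                 normalization = hdr$normalization),
            class = "wavelet_energy_map")
}
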