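# Internal numerical helpers shared across modules.

# cumulative trapezoid of y(x); returns vector same length as x, starting at 0
cumtrapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(rep(0, n))
  c(0, cumsum(diff(x) * (y[-1] + y[-n]) / 2))
}

sech2 <- function(x) 1 / cosh(x)^2

# analytic signal via the FFT half-spectrum construction; x must be real
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[c(1L, n / 2L + 1L)] <- 1
    h[2:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1L) / 2L)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# centered first difference in time; forward/backward at the edges.
# x may be a matrix (differenced along rows); t must be equally spaced
ddt <- function(x, t) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 2L) stop("need at least two time samples")
  dt <- t[2L] - t[1L]
  d <- x
  if (n > 2L) d[2:(n - 1L), ] <- (x[3:n, , drop = FALSE] - x[1:(n - 2L), , drop = FALSE]) / (2 * dt)
  d[1L, ] <- (x[2L, ] - x[1L, ]) / dt
  d[n, ] <- (x[n, ] - x[n - 1L, ]) / dt
  d
}

# NA-aware moving-window filters on matrices (time x position), k odd
filter2_mean <- function(m, k = 3L) {
  stopifnot(k %% 2L == 1L)
  r <- (k - 1L) %/% 2L
  out <- m
  nr <- nrow(m); nc <- ncol(m)
  for (i in seq_len(nr)) {
    ii <- max(1L, i - r):min(nr, i + r)
    for (j in seq_len(nc)) {
      jj <- max(1L, j - r):min(nc, j + r)
      v <- m[ii, jj]
      out[i, j] <- if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    }
  }
  out
}

filter2_median <- function(m, k = 3L) {
  stopifnot(k %% 2L == 1L)
  r <- (k - 1L) %/% 2L
  out <- m
  nr <- nrow(m); nc <- ncol(m)
  for (i in seq_len(nr)) {
    ii <- max(1L, i - r):min(nr, i + r)
    for (j in seq_len(nc)) {
      jj <- max(1L, j - r):min(nc, j + r)
      v <- m[ii, jj]
      out[i, j] <- if (all(is.na(v))) NA_real_ else stats::median(v, na.rm = TRUE)
    }
  }
  out
}

# running mean with edge shrinkage, NA-aware
run_mean <- function(x, k) {
  if (k <= 1L) return(x)
  r <- (k - 1L) %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(i) {
    v <- x[max(1L, i - r):min(n, i + r)]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))
}

# deterministic per-product substreams from one master seed
fan_seed <- function(seed, k) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  s <- sample.int(.Machine$integer.max - 1L, k)
  s
}

`%||%` <- function(a, b) if (is.null(a)) b else a
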