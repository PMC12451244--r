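#' Parameters of the kinematic nutation growth model
#'
#' Bundles all constants of the growth law and beam geometry. The mean
#' elongation-rate profile is an apex-anchored sigmoid of plateau `Edot_max`,
#' midpoint `L_gz` (the growth-zone length) and transition width `lambda_gz`;
#' differential elongation between the two lateral faces is a unit-peak
#' `sech^2` envelope of width `L_bz` centred at apex distance `s_bz`
#' (defaulting to the edge of the growth zone, where the mean rate drops),
#' modulated in time by a sine of period `T`.
#'
#' Defaults are calibrated to nutation of the *Averrhoa carambola* compound
#' leaf rachis: growth-zone length scale 50 mm with growth undetectable
#' beyond 100 mm, nutation period 2.5 h (typical range 2--3 h), apex angular
#' amplitude of order 25 degrees. `Edot_max = 0.05` per hour and beam width
#' `W = 3` mm are order-of-magnitude typical values for a growing rachis.
#' The default differential amplitude `dE_max` is obtained by inverting the
#' amplitude relation [amplitude_relation()] at an apex amplitude of 25
#' degrees with the default geometry, giving about 0.0174 per hour.
#'
#' @param Edot_max plateau mean elongation rate (1/h), >= 0.
#' @param L_gz growth-zone length measured from the apex (mm), > 0.
#' @param lambda_gz sigmoid transition width (mm), > 0.
#' @param dE_max differential-elongation amplitude (1/h), >= 0. Default:
#'   `amplitude_relation(25 * pi / 180, W / 2, T, L_bz)`.
#' @param L_bz bending-zone envelope width (mm), > 0.
#' @param s_bz envelope centre as distance from the apex (mm); defaults to
#'   `L_gz` so the differential peak sits where the mean rate drops.
#' @param T nutation period (h), > 0.
#' @param W beam width `2 R` (mm), > 0; must be small compared to `L_bz`
#'   (thin-beam regime).
#' @param L0 initial rachis length (mm), must exceed `L_gz`.
#' @param theta_base clamped base angle (rad).
#' @return An object of class `growth_params` (a validated named list).
#' @examples
#' p <- growth_params()
#' p$dE_max
#' @export
growth_params <- function(Edot_max = 0.05, L_gz = 50, lambda_gz = 15,
                          dE_max = NULL, L_bz = 15, s_bz = L_gz,
                          T = 2.5, W = 3, L0 = 250, theta_base = 0) {
  p <- list(Edot_max = Edot_max, L_gz = L_gz, lambda_gz = lambda_gz,
            dE_max = dE_max %||% 0, L_bz = L_bz, s_bz = s_bz, T = T, W = W,
            L0 = L0, theta_base = theta_base)
  validate_growth_params(p)
  if (is.null(dE_max)) {
    p$dE_max <- amplitude_relation(25 * pi / 180, W / 2, T, L_bz)
  }
  structure(p, class = "growth_params")
}

validate_growth_params <- function(p) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (f in names(p)) if (!num1(p[[f]])) stop("parameter '", f, "' must be a finite scalar")
  for (f in c("L_gz", "lambda_gz", "L_bz", "W", "L0")) {
    if (p[[f]] <= 0) stop("parameter '", f, "' must be > 0")
  }
  if (p$T <= 0) stop("parameter 'T' must be > 0")
  if (p$Edot_max < 0) stop("parameter 'Edot_max' must be >= 0")
  if (p$dE_max < 0) stop("parameter 'dE_max' must be >= 0")
  if (p$s_bz < 0) stop("parameter 's_bz' must be >= 0")
  if (p$W >= p$L_bz) {
    stop("thin-beam regime requires W << L_bz (got W = ", p$W,
         ", L_bz = ", p$L_bz, ")")
  }
  if (p$L0 <= p$L_gz) stop("initial length L0 must exceed the growth-zone length L_gz")
  invisible(p)
}

#' @export
print.growth_params <- function(x, ...) {
  cat("Nutation growth-model parameters:\n")
  cat(sprintf("  mean rate     : plateau %.4g /h, growth zone %g mm, width %g mm\n",
              x$Edot_max, x$L_gz, x$lambda_gz))
  cat(sprintf("  differential  : amplitude %.4g /h, envelope %g mm at s' = %g mm\n",
              x$dE_max, x$L_bz, x$s_bz))
  cat(sprintf("  nutation      : period %g h\n", x$T))
  cat(sprintf("  geometry      : width %g mm, initial length %g mm, base angle %g rad\n",
              x$W, x$L0, x$theta_base))
  invisible(x)
}

# merge a partial named list of overrides into a growth_params object
update_growth_params <- function(p, overrides) {
  if (length(overrides) == 0L) return(p)
  bad <- setdiff(names(overrides), names(unclass(p)))
  if (length(bad)) stop("unknown growth parameter(s): ", paste(bad, collapse = ", "))
  q <- unclass(p)
  q[names(overrides)] <- overrides
  validate_growth_params(q)
  structure(q, class = "growth_params")
}
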