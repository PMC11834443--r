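#' Coupled-assay absorbance trace
#'
#' Container for a single well of the lactate-dehydrogenase-coupled
#' pyruvate kinase assay: pyruvate formed by pyruvate kinase oxidizes NADH
#' 1:1, and NADH loss is followed as absorbance at 340 nm.
#'
#' @param time_s Time points in seconds, strictly increasing, >= 5 points.
#' @param a340 Absorbance at 340 nm (AU), same length as `time_s`.
#' @param pathlength_cm Optical path length (cm, > 0).
#' @param enzyme_conc_nM Enzyme concentration in the well (nM), optional
#'   metadata used when converting rates to turnover numbers.
#' @return An object of class `assay_trace`.
#' @export
assay_trace <- function(time_s, a340, pathlength_cm = 1,
                        enzyme_conc_nM = NA_real_) {
  if (length(time_s) < 5L) stop("an assay trace needs at least 5 points")
  if (length(a340) != length(time_s)) stop("time_s and a340 lengths differ")
  if (any(diff(time_s) <= 0)) stop("time_s must be strictly increasing")
  if (!is.finite(pathlength_cm) || pathlength_cm <= 0) {
    stop("pathlength_cm must be > 0")
  }
  structure(list(time_s = as.numeric(time_s), a340 = as.numeric(a340),
                 pathlength_cm = pathlength_cm,
                 enzyme_conc_nM = enzyme_conc_nM),
            class = "assay_trace")
}

#' Initial rate from an NADH absorbance trace
#'
#' Fits a least-squares line to the early part of the A340 trace and
#' converts the slope to an initial velocity via Beer-Lambert:
#' `V0 = -slope / (extinction * pathlength)` in mol L^-1 s^-1 of NADH
#' oxidized, which equals pyruvate formed under 1:1 coupling. Because the
#' assay consumes NADH, a well-behaved trace has a negative slope; a
#' positive slope yields `V0 = 0` with a warning.
#'
#' @param trace An [assay_trace()].
#' @param extinction_M_cm Molar extinction coefficient of NADH at 340 nm
#'   (M^-1 cm^-1); default 6220, the standard literature value.
#' @param window Initial-rate window: a fraction in (0, 1) selecting the
#'   first part of the trace, or an integer >= 2 giving a point count. The
#'   effective window is at least 10 points (or the whole trace if shorter).
#' @return A list with `v0_M_s` (initial rate, M s^-1), `slope_AU_s`,
#'   `n_points`, and `r_squared` of the window fit.
#' @export
#' @examples
#' tr <- assay_trace(time_s = 0:59, a340 = 1 - 0.001 * (0:59))
#' trace_to_rate(tr)$v0_M_s  # 0.001 / 6220
trace_to_rate <- function(trace, extinction_M_cm = 6220, window = 0.2) {
  stopifnot(inherits(trace, "assay_trace"))
  if (!is.finite(extinction_M_cm) || extinction_M_cm <= 0) {
    stop("extinction coefficient must be > 0")
  }
  n <- length(trace$time_s)
  n_win <- if (window < 1) ceiling(window * n) else as.integer(window)
  n_win <- min(n, max(n_win, 10L, 2L))
  if (n_win < 2L) stop("initial-rate window must contain at least 2 points")
  t <- trace$time_s[seq_len(n_win)]
  a <- trace$a340[seq_len(n_win)]
  fit <- lm(a ~ t)
  slope <- unname(coef(fit)[2L])
  ss_tot <- sum((a - mean(a))^2)
  r2 <- if (ss_tot > 0) 1 - sum(residuals(fit)^2) / ss_tot else 1
  v0 <- -slope / (extinction_M_cm * trace$pathlength_cm)
  if (v0 < 0) {
    warning("positive A340 slope: NADH gain, not consumption; reporting V0 = 0")
    v0 <- 0
  }
  list(v0_M_s = v0, slope_AU_s = slope, n_points = n_win, r_squared = r2)
}
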