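#' Normalize metabolome ion counts to internal standard and/or OD
#'
#' Implements the two-tier normalization used for targeted LC-MS
#' metabolomics with a fully 13C-labeled internal-standard pool: a
#' metabolite whose internal-standard channel is robust (median IS counts
#' >= `robust_threshold`) is normalized as `count / is_count / od600`;
#' otherwise only `count / od600`. The mode chosen for each metabolite is
#' recorded. In IS mode, samples with a zero IS count are flagged and their
#' value set to `NA` (excluded, not silently zeroed).
#'
#' @param table Long-format data.frame with columns `sample_id`,
#'   `metabolite`, `ion_count` and optionally `is_count` (the 13C
#'   internal-standard channel; may be `NA` for some metabolites).
#' @param meta Data.frame with `sample_id` and `od600` (> 0); extra columns
#'   (condition, replicate, carbon_source) are carried through.
#' @param robust_threshold Minimum median IS count for IS-mode
#'   normalization (default 1000 counts).
#' @return The input table with columns `normalized` and `norm_mode`
#'   (`"internal_standard"` or `"od_only"`) added, merged with `meta`.
#' @export
normalize_counts <- function(table, meta, robust_threshold = 1000) {
  stopifnot(all(c("sample_id", "metabolite", "ion_count") %in% names(table)),
            all(c("sample_id", "od600") %in% names(meta)))
  if (anyDuplicated(meta$sample_id)) stop("sample ids must be unique")
  if (any(!table$sample_id %in% meta$sample_id)) {
    stop("samples in the count table lack metadata")
  }
  if (any(meta$od600 <= 0 | !is.finite(meta$od600))) {
    stop("od600 must be finite and > 0 for every sample")
  }
  if (any(table$ion_count < 0, na.rm = TRUE)) stop("ion counts must be >= 0")
  if (!"is_count" %in% names(table)) table$is_count <- NA_real_

  out <- merge(table, meta, by = "sample_id", sort = FALSE)
  out$normalized <- NA_real_
  out$norm_mode <- NA_character_
  for (m in unique(out$metabolite)) {
    idx <- out$metabolite == m
    is_counts <- out$is_count[idx]
    robust <- !all(is.na(is_counts)) &&
      median(is_counts, na.rm = TRUE) >= robust_threshold
    if (robust) {
      bad <- is.na(is_counts) | is_counts <= 0
      val <- out$ion_count[idx] / is_counts / out$od600[idx]
      val[bad] <- NA_real_
      if (any(bad)) {
        warning("metabolite '", m, "': ", sum(bad),
                " sample(s) with unusable internal-standard counts set to NA")
      }
      out$normalized[idx] <- val
      out$norm_mode[idx] <- "internal_standard"
    } else {
      out$normalized[idx] <- out$ion_count[idx] / out$od600[idx]
      out$norm_mode[idx] <- "od_only"
    }
  }
  out
}

#' Z-score a vector of normalized abundances
#'
#' `Z = (x - mean(x)) / sigma` across conditions, the standardization used
#' for metabolome heatmaps. The default sigma is the sample standard
#' deviation (n - 1 denominator).
#'
#' @param values Numeric vector, length >= 2.
#' @param sigma `"sample"` (default) or `"population"`.
#' @return Z vector with mean 0 and unit sigma; all-`NaN` with a warning if
#'   the values are constant.
#' @export
#' @examples
#' zscore(c(1, 2, 3))  # -1 0 1
zscore <- function(values, sigma = c("sample", "population")) {
  sigma <- match.arg(sigma)
  if (length(values) < 2L) stop("zscore needs at least 2 values")
  s <- sd(values)
  if (sigma == "population") s <- s * sqrt((length(values) - 1) / length(values))
  if (!is.finite(s) || s == 0) {
    warning("constant values: Z-scores undefined")
    return(rep(NaN, length(values)))
  }
  (values - mean(values)) / s
}

#' Absolute quantification by standard addition
#'
#' Fits `signal = a + b * spike_conc` by ordinary least squares and
#' extrapolates to the endogenous concentration `a / b` (the x-intercept
#' magnitude). The standard error follows by first-order error propagation
#' from the coefficient covariance matrix. Spike designs of
#' 0x/0.1x/1x/10x an estimated concentration are typical.
#'
#' @param spike_conc_mM Spiked concentrations (mM), >= 3 distinct levels,
#'   non-negative.
#' @param signal Measured signals (unlabeled ion counts or
#'   unlabeled/labeled ratios), same length.
#' @return A list: `endogenous_mM`, `se_mM`, `slope`, `intercept`,
#'   `r_squared`, and `flags` (character vector; `"negative_estimate"`
#'   and/or `"nonincreasing_signal"` when applicable).
#' @export
#' @examples
#' standard_addition_quant(c(0, 1, 5, 10), 10 + 2 * c(0, 1, 5, 10))
standard_addition_quant <- function(spike_conc_mM, signal) {
  if (length(spike_conc_mM) < 3L) stop("need at least 3 spike levels")
  if (length(signal) != length(spike_conc_mM)) stop("length mismatch")
  if (any(spike_conc_mM < 0)) stop("spike concentrations must be >= 0")
  if (length(unique(spike_conc_mM)) < 2L) {
    stop("spike concentrations are collinear (no spread)")
  }
  flags <- character(0)
  ord <- order(spike_conc_mM)
  if (any(diff(signal[ord]) < 0)) flags <- c(flags, "nonincreasing_signal")
  fit <- lm(signal ~ spike_conc_mM)
  a <- unname(coef(fit)[1L]); b <- unname(coef(fit)[2L])
  if (b <= 0) stop("non-positive slope: signal does not respond to spikes")
  # noiseless calibration lines are legitimate input; silence the
  # "essentially perfect fit" note from summary.lm
  V <- suppressWarnings(vcov(fit))
  endo <- a / b
  # delta method on a/b
  se <- sqrt(V[1, 1] / b^2 + a^2 * V[2, 2] / b^4 - 2 * a * V[1, 2] / b^3)
  if (endo < 0) flags <- c(flags, "negative_estimate")
  ss_tot <- sum((signal - mean(signal))^2)
  r2 <- if (ss_tot > 0) 1 - sum(residuals(fit)^2) / ss_tot else 1
  list(endogenous_mM = endo, se_mM = se, slope = b, intercept = a,
       r_squared = r2, flags = flags)
}

#' Carbon-use efficiency from media depletion versus culture density
#'
#' Regresses remaining carbon-source concentration in the medium on culture
#' OD600; the negative of the slope is the carbon consumed per OD unit. A
#' steeper slope means more carbon spent per unit biomass, i.e. lower
#' efficiency of carbon use (more overflow).
#'
#' @param media_conc_mM Remaining carbon source (mM) at each time point.
#' @param od600 Matched culture densities (>= 3 points with spread).
#' @return A list: `efficiency_mM_per_od` (= -slope), `slope`, `intercept`,
#'   `r_squared`.
#' @export
carbon_use_efficiency <- function(media_conc_mM, od600) {
  if (length(media_conc_mM) != length(od600)) stop("length mismatch")
  if (length(od600) < 3L) stop("need at least 3 points")
  if (sd(od600) == 0) stop("degenerate OD spread")
  fit <- lm(media_conc_mM ~ od600)
  slope <- unname(coef(fit)[2L])
  ss_tot <- sum((media_conc_mM - mean(media_conc_mM))^2)
  r2 <- if (ss_tot > 0) 1 - sum(residuals(fit)^2) / ss_tot else 1
  list(efficiency_mM_per_od = -slope, slope = slope,
       intercept = unname(coef(fit)[1L]), r_squared = r2)
}

# Longest contiguous run of >= min_pts points whose log-linear fit has
# R^2 >= r2_min; returns indices. Falls back to the best-R^2 window.
auto_exponential_window <- function(time_h, log_od, min_pts = 4L,
                                    r2_min = 0.99) {
  n <- length(time_h)
  best <- NULL; best_len <- 0; best_r2 <- -Inf
  for (i in seq_len(n - min_pts + 1L)) {
    for (j in seq(i + min_pts - 1L, n)) {
      idx <- i:j
      f <- lm(log_od[idx] ~ time_h[idx])
      ss_tot <- sum((log_od[idx] - mean(log_od[idx]))^2)
      r2 <- if (ss_tot > 0) 1 - sum(residuals(f)^2) / ss_tot else 1
      len <- length(idx)
      if (r2 >= r2_min && len > best_len) {
        best <- idx; best_len <- len
      }
      if (is.null(best) && r2 > best_r2) { best_r2 <- r2; best <- idx }
    }
  }
  best
}

#' Exponential growth rate from an OD time series
#'
#' Fits a line to `ln(OD)` versus time over the exponential phase. The
#' window is either supplied or selected automatically as the longest
#' contiguous run of points whose log-linear fit has local R^2 >= 0.99.
#'
#' @param time_h Time points (h), increasing.
#' @param od600 Optical densities (> 0), same length.
#' @param window Optional integer indices of the exponential phase
#'   (>= 4 points); `NULL` selects automatically.
#' @return A list: `rate_per_h` (slope of ln OD), `doubling_time_h`
#'   (`ln(2)/rate`), `window` (indices used), `r_squared`.
#' @export
#' @examples
#' t <- seq(0, 5, 0.5)
#' growth_rate(t, 0.01 * exp(0.6 * t))$rate_per_h  # 0.6
growth_rate <- function(time_h, od600, window = NULL) {
  if (length(time_h) != length(od600)) stop("length mismatch")
  if (is.null(window)) {
    if (any(od600 <= 0)) stop("OD must be positive for log transformation")
    window <- auto_exponential_window(time_h, log(od600))
  }
  if (length(window) < 4L) stop("exponential window needs >= 4 points")
  if (any(od600[window] <= 0)) stop("non-positive OD inside the window")
  t <- time_h[window]; y <- log(od600[window])
  fit <- lm(y ~ t)
  rate <- unname(coef(fit)[2L])
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - sum(residuals(fit)^2) / ss_tot else 1
  list(rate_per_h = rate,
       doubling_time_h = if (rate > 0) log(2) / rate else Inf,
       window = window, r_squared = r2)
}

#' Overflow (excretion) rate of a metabolite into the medium
#'
#' Least-squares slope of extracellular concentration against time (default)
#' or against OD. Use [overflow_ratio()] to compare two conditions (e.g.
#' mutant vs wild-type pyruvate overflow).
#'
#' @param conc_mM Extracellular metabolite concentrations (mM), >= 3 points.
#' @param time_h Time points (h); used when `basis = "time"`.
#' @param od600 Optional culture densities; used when `basis = "od"`.
#' @param basis `"time"` (mM/h, default) or `"od"` (mM per OD unit).
#' @return A list: `rate` (slope on the chosen basis), `basis`,
#'   `intercept`, `r_squared`.
#' @export
overflow_rate <- function(conc_mM, time_h = NULL, od600 = NULL,
                          basis = c("time", "od")) {
  basis <- match.arg(basis)
  x <- if (basis == "time") time_h else od600
  if (is.null(x)) stop("supply ", if (basis == "time") "time_h" else "od600")
  if (length(conc_mM) < 3L || length(x) != length(conc_mM)) {
    stop("need >= 3 matched points")
  }
  if (sd(x) == 0) stop("degenerate predictor spread")
  fit <- lm(conc_mM ~ x)
  ss_tot <- sum((conc_mM - mean(conc_mM))^2)
  r2 <- if (ss_tot > 0) 1 - sum(residuals(fit)^2) / ss_tot else 1
  list(rate = unname(coef(fit)[2L]), basis = basis,
       intercept = unname(coef(fit)[1L]), r_squared = r2)
}

#' Ratio of overflow rates between two conditions
#'
#' @param rate_a,rate_b Results of [overflow_rate()] (or bare slopes).
#' @return `rate_a / rate_b`.
#' @export
overflow_ratio <- function(rate_a, rate_b) {
  a <- if (is.list(rate_a)) rate_a$rate else rate_a
  b <- if (is.list(rate_b)) rate_b$rate else rate_b
  if (b == 0) stop("reference overflow rate is zero")
  a / b
}
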