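#' Rate observation table
#'
#' Validates and standardizes a table of initial-rate measurements. Missing
#' effector columns are filled with zeros, matching plate layouts where an
#' effector was simply absent.
#'
#' @param df A data.frame with column `rate` plus any of `substrate_mM`,
#'   `activator_mM`, `inhibitor_mM`, `adp_mM`, `replicate_id`.
#' @return A data.frame of class `rate_observations` with all five
#'   concentration/rate columns present.
#' @export
rate_observations <- function(df) {
  stopifnot(is.data.frame(df), "rate" %in% names(df))
  for (col in c("substrate_mM", "activator_mM", "inhibitor_mM", "adp_mM")) {
    if (!col %in% names(df)) df[[col]] <- 0
    check_nonneg(df[[col]], col)
  }
  check_nonneg(df$rate, "rate")
  if (!"replicate_id" %in% names(df)) df$replicate_id <- "r1"
  class(df) <- c("rate_observations", "data.frame")
  df
}

# Free parameters of each fit model, in reporting order.
model_param_names <- function(model) {
  switch(model,
    sigmoidal = c("vmax", "k_half_S", "h"),
    nonessential_activation = c("vmax", "k_half_S", "h", "K_A", "alpha", "beta"),
    mm_adp = c("vmax", "K_m_ADP"),
    inhibition = c("vmax", "K_i"),
    stop("unknown model: ", model)
  )
}

model_predict <- function(model, par, obs) {
  p <- do.call(kinetic_params, as.list(par))
  switch(model,
    sigmoidal = rate_allosteric_sigmoidal(p, obs$substrate_mM),
    nonessential_activation =
      rate_nonessential_activation(p, obs$substrate_mM, obs$activator_mM),
    mm_adp = rate_michaelis_menten_adp(p, obs$adp_mM),
    inhibition = rate_with_inhibitor(p, p$vmax, obs$inhibitor_mM)
  )
}

# Data-driven starting values; the paper-style grids make these robust.
default_init <- function(model, obs) {
  vmax0 <- max(obs$rate) * 1.2
  half_point <- function(x) {
    ok <- x > 0
    if (!any(ok)) return(1)
    i <- which.min(abs(obs$rate[ok] - max(obs$rate) / 2))
    max(x[ok][i], min(x[ok]) / 2, 1e-3)
  }
  switch(model,
    sigmoidal = c(vmax = vmax0, k_half_S = half_point(obs$substrate_mM), h = 1),
    nonessential_activation = c(vmax = vmax0,
                                k_half_S = half_point(obs$substrate_mM),
                                h = 1, K_A = 0.5, alpha = 0.5, beta = 1.5),
    mm_adp = c(vmax = vmax0, K_m_ADP = half_point(obs$adp_mM)),
    inhibition = c(vmax = max(obs$rate), K_i = half_point(obs$inhibitor_mM))
  )
}

#' Fit a kinetic rate law by nonlinear least squares
#'
#' Estimates the parameters of one of the package's rate laws from
#' initial-rate observations using Levenberg-Marquardt least squares
#' (`minpack.lm::nls.lm`) with positivity bounds. Standard errors are the
#' usual asymptotic estimates from the residual Jacobian at the solution.
#' If the first start does not converge, up to `n_starts - 1` deterministic
#' jittered restarts are attempted.
#'
#' @param obs A [rate_observations()] table (or a data.frame coercible to
#'   one).
#' @param model One of `"sigmoidal"`, `"nonessential_activation"`,
#'   `"mm_adp"`, `"inhibition"`.
#' @param init Optional named vector (or [kinetic_params()]) of starting
#'   values; defaults come from data heuristics (vmax = 1.2 x max rate,
#'   half-saturation from the half-max point, h = 1).
#' @param fixed Optional named vector of parameters to hold fixed.
#' @param weights `"none"` (default, unweighted residuals) or `"relative"`
#'   (residuals divided by predicted rate, floored to avoid zero division).
#' @param n_starts Maximum number of starts (>= 1).
#' @return A `fit_result` list: `parameters` ([kinetic_params()] including
#'   fixed values), `estimates` (free-parameter vector), `standard_errors`,
#'   `residual_sum_squares`, `n_obs`, `converged`, `model`, and `K_S_raw`
#'   (`k_half_S^h`, the raw denominator constant in mM^h) when applicable.
#' @export
#' @examples
#' p <- pyk_reference_params("dectd")
#' obs <- gen_rate_grid(p, activator_grid = 0, cv = 0, replicates = 1,
#'                      seed = 1, model = "sigmoidal")
#' fit <- fit_kinetic_model(obs, "sigmoidal")
#' fit$estimates["h"]  # ~1.3
fit_kinetic_model <- function(obs,
                              model = c("sigmoidal", "nonessential_activation",
                                        "mm_adp", "inhibition"),
                              init = NULL, fixed = NULL,
                              weights = c("none", "relative"),
                              n_starts = 5L) {
  model <- match.arg(model)
  weights <- match.arg(weights)
  if (!inherits(obs, "rate_observations")) obs <- rate_observations(obs)
  pnames <- model_param_names(model)
  fixed <- fixed %||% numeric(0)
  if (length(fixed) && !all(names(fixed) %in% pnames)) {
    stop("fixed parameters must be among: ", paste(pnames, collapse = ", "))
  }
  free <- setdiff(pnames, names(fixed))
  if (nrow(obs) < 2L * length(free)) {
    stop("need at least 2x more observations than free parameters")
  }

  start <- default_init(model, obs)
  if (!is.null(init)) {
    init <- unlist(init[intersect(names(init), pnames)])
    start[names(init)] <- init
  }
  if (any(start[free] <= 0)) stop("initial values must be positive")

  residual_fn <- function(par_free) {
    par <- c(par_free, fixed)[pnames]
    names(par) <- pnames
    pred <- model_predict(model, par, obs)
    r <- pred - obs$rate
    if (weights == "relative") r <- r / pmax(abs(pred), 1e-8)
    r
  }

  run_start <- function(p0) {
    minpack.lm::nls.lm(
      par = p0, fn = residual_fn,
      lower = rep(1e-9, length(p0)),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-12,
                                           ptol = 1e-12)
    )
  }

  jitters <- c(1, 0.5, 2, 0.25, 4, 8, 0.125)[seq_len(max(1L, n_starts))]
  best <- NULL
  for (j in jitters) {
    fit <- tryCatch(run_start(start[free] * j), error = function(e) NULL)
    if (is.null(fit)) next
    conv <- fit$info %in% 1:4
    if (is.null(best) || (conv && fit$deviance < best$deviance)) best <- fit
    if (conv && j == 1) break
  }
  if (is.null(best)) stop("all optimizer starts failed for model '", model, "'")

  est <- setNames(best$par, free)
  rss <- best$deviance
  n <- nrow(obs)
  dof <- n - length(free)

  # Asymptotic SEs from a central-difference Jacobian of the residuals.
  J <- vapply(seq_along(est), function(i) {
    hstep <- max(abs(est[i]) * 1e-6, 1e-10)
    up <- est; up[i] <- up[i] + hstep
    dn <- est; dn[i] <- dn[i] - hstep
    (residual_fn(up) - residual_fn(dn)) / (2 * hstep)
  }, numeric(n))
  JtJ <- crossprod(J)
  se <- rep(NA_real_, length(est))
  singular <- FALSE
  cv <- tryCatch(solve(JtJ) * rss / max(dof, 1), error = function(e) NULL)
  if (is.null(cv)) {
    singular <- TRUE
    warning("singular Jacobian: standard errors unavailable")
  } else {
    se <- sqrt(pmax(diag(cv), 0))
  }
  names(se) <- free

  full <- c(est, fixed)[pnames]
  names(full) <- pnames
  params <- do.call(kinetic_params, as.list(full))
  out <- list(
    parameters = params,
    estimates = est,
    standard_errors = se,
    residual_sum_squares = rss,
    n_obs = n,
    converged = best$info %in% 1:4 && !singular,
    model = model,
    message = best$message
  )
  if ("k_half_S" %in% pnames) {
    out$K_S_raw <- unname(full["k_half_S"]^full["h"])
  }
  class(out) <- "fit_result"
  out
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Kinetic fit: %s model, n = %d, RSS = %.4g, converged: %s\n",
              x$model, x$n_obs, x$residual_sum_squares, x$converged))
  tab <- data.frame(estimate = x$estimates,
                    std_error = x$standard_errors[names(x$estimates)])
  print(tab, ...)
  invisible(x)
}
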