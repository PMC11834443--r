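#' Assay design grids for the PEP x R5P rate surface
#'
#' The substrate and activator titration grids used for the pyruvate kinase
#' rate-surface assay: PEP at 0-1.5 mM (8 levels) and R5P at 0-700 uM
#' (12 levels).
#'
#' @return Numeric vector of concentrations in mM.
#' @export
pep_assay_grid <- function() c(0, 0.2, 0.4, 0.6, 0.8, 1.0, 1.2, 1.5)

#' @rdname pep_assay_grid
#' @export
r5p_assay_grid <- function() {
  c(0, 20, 40, 60, 80, 100, 200, 300, 400, 500, 600, 700) / 1000
}

# Multiplicative plate-reader-like noise, truncated so rates stay positive.
mult_noise <- function(n, cv) pmax(1 + rnorm(n, 0, cv), 0.01)

#' Generate synthetic initial-rate observations on a design grid
#'
#' Evaluates the chosen rate law on the design grid and applies
#' multiplicative Gaussian noise `rate = v * (1 + eps)`, `eps ~ N(0, cv)`
#' truncated at -0.99. Identical arguments (including `seed`) give
#' bit-identical tables; the caller's RNG state is untouched.
#'
#' @param params A [kinetic_params()] set (see [pyk_reference_params()]).
#' @param pep_grid PEP concentrations (mM) for substrate-based models;
#'   default [pep_assay_grid()].
#' @param activator_grid Activator concentrations (mM) crossed with
#'   `pep_grid` for the nonessential-activation model; default
#'   [r5p_assay_grid()].
#' @param adp_grid ADP concentrations (mM) for `model = "mm_adp"`.
#' @param inhibitor_grid Inhibitor concentrations (mM) for
#'   `model = "inhibition"`.
#' @param cv Coefficient of variation of the multiplicative noise (>= 0).
#' @param replicates Replicates per grid point.
#' @param seed Integer seed.
#' @param model Rate law to simulate from (see [fit_kinetic_model()]).
#' @return A [rate_observations()] data.frame.
#' @export
#' @examples
#' obs <- gen_rate_grid(pyk_reference_params("wt"), cv = 0.02,
#'                      replicates = 3, seed = 7)
#' nrow(obs)  # 8 x 12 x 3
gen_rate_grid <- function(params,
                          pep_grid = pep_assay_grid(),
                          activator_grid = r5p_assay_grid(),
                          adp_grid = NULL, inhibitor_grid = NULL,
                          cv = 0.02, replicates = 3, seed = 1,
                          model = c("nonessential_activation", "sigmoidal",
                                    "mm_adp", "inhibition")) {
  model <- match.arg(model)
  if (cv < 0) stop("cv must be >= 0")
  design <- switch(model,
    nonessential_activation = {
      if (!length(pep_grid) || !length(activator_grid)) {
        stop("pep_grid and activator_grid must be non-empty")
      }
      expand.grid(substrate_mM = pep_grid, activator_mM = activator_grid)
    },
    sigmoidal = data.frame(substrate_mM = pep_grid, activator_mM = 0),
    mm_adp = data.frame(adp_mM = adp_grid %||%
                          stop("adp_grid required for mm_adp")),
    inhibition = data.frame(inhibitor_mM = inhibitor_grid %||%
                              stop("inhibitor_grid required for inhibition"))
  )
  design <- design[rep(seq_len(nrow(design)), replicates), , drop = FALSE]
  design$replicate_id <- paste0("rep", rep(seq_len(replicates),
                                           each = nrow(design) / replicates))
  for (col in c("substrate_mM", "activator_mM", "inhibitor_mM", "adp_mM")) {
    if (!col %in% names(design)) design[[col]] <- 0
  }
  mu <- model_predict(model, unlist(unclass(params)), design)
  design$rate <- withr::with_seed(seed, mu * mult_noise(length(mu), cv))
  rownames(design) <- NULL
  rate_observations(design)
}

#' Generate a synthetic NADH absorbance trace
#'
#' `a340(t) = a0 - extinction * pathlength * v0 * t + N(0, noise_sd)`,
#' floored at 0 — a linear NADH-consumption trace as produced by the
#' coupled pyruvate kinase assay at constant initial velocity.
#'
#' @param v0_M_s True initial rate (M/s, >= 0).
#' @param duration_s Trace duration (s).
#' @param sampling_hz Sampling frequency (points per second).
#' @param a0 Starting absorbance (AU, > 0).
#' @param noise_sd Additive absorbance noise SD (AU).
#' @param extinction_M_cm,pathlength_cm Beer-Lambert constants.
#' @param seed Integer seed.
#' @return An [assay_trace()]; the true rate is carried in attribute
#'   `"true_v0"`.
#' @export
gen_assay_trace <- function(v0_M_s, duration_s = 120, sampling_hz = 1,
                            a0 = 1.0, noise_sd = 0, extinction_M_cm = 6220,
                            pathlength_cm = 1, seed = 1) {
  if (v0_M_s < 0) stop("v0 must be >= 0")
  if (a0 <= 0) stop("starting absorbance must be > 0")
  t <- seq(0, duration_s, by = 1 / sampling_hz)
  a <- a0 - extinction_M_cm * pathlength_cm * v0_M_s * t
  if (noise_sd > 0) {
    a <- a + withr::with_seed(seed, rnorm(length(t), 0, noise_sd))
  }
  tr <- assay_trace(t, pmax(a, 0), pathlength_cm = pathlength_cm)
  attr(tr, "true_v0") <- v0_M_s
  tr
}

#' Generate multinomial isotopologue replicates
#'
#' Draws replicate ion-count vectors from a multinomial distribution over
#' mass shifts M0..Mn — the sampling model for isotopologue ion counts at a
#' given sequencing-like depth.
#'
#' @param true_fractions Probability vector over M0..Mn (sums to 1).
#' @param depth Total counts per replicate (>= 1).
#' @param replicates Number of replicates.
#' @param seed Integer seed.
#' @param metabolite,condition Labels attached to each replicate.
#' @return List of [isotopologue_distribution()] objects.
#' @export
gen_isotopologues <- function(true_fractions, depth = 1e5, replicates = 3,
                              seed = 1, metabolite = "pyruvate",
                              condition = "WT") {
  if (abs(sum(true_fractions) - 1) > 1e-8 || any(true_fractions < 0)) {
    stop("true_fractions must be a probability simplex over M0..Mn")
  }
  if (depth < 1) stop("depth must be >= 1")
  draws <- withr::with_seed(seed,
    rmultinom(replicates, size = depth, prob = true_fractions))
  lapply(seq_len(replicates), function(i) {
    isotopologue_distribution(metabolite, draws[, i],
                              sample_id = paste0(condition, "_rep", i),
                              condition = condition)
  })
}

#' Default condition fold-changes for the metabolome generator
#'
#' Encodes the gluconeogenic phenotype of the dysregulated pyruvate kinase
#' mutant: PEP depleted 3.5-fold, with correlated depletion of the
#' downstream gluconeogenic/pentose-phosphate intermediates (BPG, 3PG, G6P,
#' R5P, S7P); pyruvate accumulates.
#'
#' @return Named vector of mutant/WT fold changes.
#' @export
mutant_fold_changes <- function() {
  c(pep = 1 / 3.5, bpg = 0.5, `3pg` = 0.5, g6p = 0.45, r5p = 0.5,
    s7p = 0.5, fbp = 0.6, pyruvate = 1.8)
}

#' Generate a synthetic metabolome ion-count table
#'
#' Counts are `base * fold * LogNormal` with log-normal multiplicative
#' noise of coefficient of variation `cv` (mean 1); the paired fully
#' 13C-labeled internal-standard channel is `base * LogNormal` at `cv/2`
#' (the IS pool is shared across samples, so it carries no condition
#' effect).
#'
#' @param base_levels Named vector of WT mean ion counts per metabolite
#'   (> 0).
#' @param condition_fold_changes Named list: condition -> named fold-change
#'   vector (metabolites absent from a vector default to fold 1). The
#'   default encodes a WT reference and the PEP-depleted mutant
#'   ([mutant_fold_changes()]).
#' @param cv Log-normal coefficient of variation (>= 0).
#' @param replicates Replicates per condition.
#' @param od600 Culture density recorded for every sample (harvested at
#'   matched OD).
#' @param seed Integer seed.
#' @return A list: `table` (long ion-count table with `is_count`) and
#'   `meta` (sample metadata), ready for [normalize_counts()].
#' @export
gen_metabolome <- function(base_levels = c(pep = 5e5, bpg = 8e4, `3pg` = 3e5,
                                           g6p = 2e5, r5p = 1.2e5, s7p = 9e4,
                                           fbp = 1.5e5, pyruvate = 4e5),
                           condition_fold_changes =
                             list(WT = c(), mutant = mutant_fold_changes()),
                           cv = 0.15, replicates = 3, od600 = 0.5, seed = 1) {
  if (any(base_levels <= 0)) stop("base levels must be > 0")
  if (cv < 0) stop("cv must be >= 0")
  sdlog <- sqrt(log1p(cv^2))
  sdlog_is <- sqrt(log1p((cv / 2)^2))
  mets <- names(base_levels)
  conds <- names(condition_fold_changes)
  grid <- expand.grid(metabolite = mets, condition = conds,
                      replicate = seq_len(replicates),
                      stringsAsFactors = FALSE)
  grid$sample_id <- paste0(grid$condition, "_rep", grid$replicate)
  fold <- mapply(function(m, cond) {
    fc <- condition_fold_changes[[cond]]
    if (m %in% names(fc)) fc[[m]] else 1
  }, grid$metabolite, grid$condition)
  base <- base_levels[grid$metabolite]
  withr::with_seed(seed, {
    noise <- exp(rnorm(nrow(grid), -sdlog^2 / 2, sdlog))
    noise_is <- exp(rnorm(nrow(grid), -sdlog_is^2 / 2, sdlog_is))
  })
  tab <- data.frame(sample_id = grid$sample_id,
                    metabolite = grid$metabolite,
                    ion_count = unname(base * fold * noise),
                    is_count = unname(base * noise_is))
  meta <- unique(data.frame(sample_id = grid$sample_id,
                            od600 = od600,
                            condition = grid$condition,
                            replicate = paste0("rep", grid$replicate),
                            carbon_source = "pyruvate"))
  rownames(meta) <- NULL
  list(table = tab, meta = meta)
}

#' Generate a logistic growth curve with matched media measurements
#'
#' OD follows logistic growth `K / (1 + (K/od0 - 1) exp(-r t))`; the carbon
#' source declines linearly with biomass,
#' `c(t) = c0 - consumption_per_od * (OD - od0)`; an overflow metabolite
#' accumulates linearly in time at `excretion_rate`. Gaussian noise is
#' added to each observable.
#'
#' @param rate Intrinsic growth rate (h^-1, > 0).
#' @param capacity Carrying capacity (OD units, > 0).
#' @param consumption_per_od Carbon consumed per OD unit (mM/OD).
#' @param excretion_rate Overflow metabolite excretion rate (mM/h).
#' @param times Sampling times (h).
#' @param od0 Inoculation density.
#' @param c0 Starting carbon concentration (mM).
#' @param noise_od,noise_conc Additive noise SDs.
#' @param seed Integer seed.
#' @return A data.frame: `time_h`, `od600`, `media_conc_mM`,
#'   `excreted_mM`.
#' @export
gen_growth_and_media <- function(rate = 0.6, capacity = 1.5,
                                 consumption_per_od = 30,
                                 excretion_rate = 0.5,
                                 times = seq(0, 10, by = 0.25),
                                 od0 = 0.01, c0 = 60,
                                 noise_od = 0, noise_conc = 0, seed = 1) {
  if (rate <= 0 || capacity <= 0) stop("rate and capacity must be > 0")
  od <- capacity / (1 + (capacity / od0 - 1) * exp(-rate * times))
  conc <- c0 - consumption_per_od * (od - od0)
  excr <- excretion_rate * times
  if (noise_od > 0 || noise_conc > 0) {
    withr::with_seed(seed, {
      od <- pmax(od + rnorm(length(times), 0, noise_od), 1e-4)
      conc <- conc + rnorm(length(times), 0, noise_conc)
      excr <- pmax(excr + rnorm(length(times), 0, noise_conc), 0)
    })
  }
  data.frame(time_h = times, od600 = od, media_conc_mM = conc,
             excreted_mM = excr)
}

#' Generate a noisy standard-addition spike series
#'
#' Signal responds linearly to the spiked amount on top of the endogenous
#' pool: `signal = k * (endogenous + spike)`, with multiplicative noise.
#' Spike levels default to the 0x/0.1x/1x/10x design around an estimated
#' concentration.
#'
#' @param endogenous_mM True endogenous concentration (mM).
#' @param spike_multipliers Spike design as multiples of
#'   `estimated_mM`.
#' @param estimated_mM Estimated concentration the design is scaled to
#'   (defaults to the true value).
#' @param k Signal per mM (instrument response).
#' @param cv Multiplicative noise CV.
#' @param seed Integer seed.
#' @return A data.frame: `spike_conc_mM`, `signal`.
#' @export
gen_spike_series <- function(endogenous_mM, spike_multipliers = c(0, 0.1, 1, 10),
                             estimated_mM = endogenous_mM, k = 1000,
                             cv = 0, seed = 1) {
  spikes <- spike_multipliers * estimated_mM
  mu <- k * (endogenous_mM + spikes)
  sig <- withr::with_seed(seed, mu * mult_noise(length(mu), cv))
  data.frame(spike_conc_mM = spikes, signal = sig)
}
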