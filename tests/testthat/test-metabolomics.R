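test_that("normalization chooses internal-standard or OD mode per metabolite", {
  tab <- data.frame(sample_id = c("s1", "s1"),
                    metabolite = c("pep", "oaa"),
                    ion_count = c(1000, 1000),
                    is_count = c(500, NA))
  meta <- data.frame(sample_id = "s1", od600 = 0.5)
  out <- normalize_counts(tab, meta, robust_threshold = 100)
  pep <- out[out$metabolite == "pep", ]
  expect_equal(pep$normalized, 1000 / 500 / 0.5)  # 4.0
  expect_equal(pep$norm_mode, "internal_standard")
  oaa <- out[out$metabolite == "oaa", ]
  expect_equal(oaa$normalized, 1000 / 0.5)
  expect_equal(oaa$norm_mode, "od_only")
})

test_that("normalization is equivariant under count and OD rescaling", {
  sim <- gen_metabolome(seed = 4)
  out <- normalize_counts(sim$table, sim$meta, robust_threshold = 1)
  # doubling every IS count halves IS-mode values only
  tab2 <- sim$table
  tab2$is_count <- tab2$is_count * 2
  out2 <- normalize_counts(tab2, sim$meta, robust_threshold = 1)
  is_mode <- out$norm_mode == "internal_standard"
  expect_true(all(is_mode))
  expect_equal(out2$normalized, out$normalized / 2, tolerance = 1e-12)
  # below the robust threshold everything falls back to count/OD,
  # and doubling OD halves those values
  out3 <- normalize_counts(sim$table, sim$meta, robust_threshold = Inf)
  expect_true(all(out3$norm_mode == "od_only"))
  meta2 <- sim$meta
  meta2$od600 <- meta2$od600 * 2
  out4 <- normalize_counts(sim$table, meta2, robust_threshold = Inf)
  expect_equal(out4$normalized, out3$normalized / 2, tolerance = 1e-12)
})

test_that("IS-mode samples with zero internal-standard counts become NA", {
  tab <- data.frame(sample_id = c("s1", "s2", "s3"),
                    metabolite = "pep",
                    ion_count = c(100, 200, 300),
                    is_count = c(1000, 0, 2000))
  meta <- data.frame(sample_id = c("s1", "s2", "s3"), od600 = 1)
  expect_warning(out <- normalize_counts(tab, meta, robust_threshold = 10),
                 "unusable internal-standard")
  expect_true(is.na(out$normalized[out$sample_id == "s2"]))
  expect_false(anyNA(out$normalized[out$sample_id != "s2"]))
})

test_that("Z-scores standardize exactly and respect affine invariance", {
  expect_equal(zscore(c(1, 2, 3)), c(-1, 0, 1))
  x <- rnorm(25)
  z <- zscore(x)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  expect_equal(zscore(3 * x + 7), z, tolerance = 1e-12)
  zp <- zscore(c(1, 2, 3), sigma = "population")
  expect_equal(sd(zp) * sqrt(2 / 3), 1, tolerance = 1e-12)
  expect_warning(zc <- zscore(c(2, 2, 2)), "constant")
  expect_true(all(is.nan(zc)))
})

test_that("standard addition extrapolates the exact line and flags edge cases", {
  res <- standard_addition_quant(c(0, 1, 5, 10), 10 + 2 * c(0, 1, 5, 10))
  expect_equal(res$endogenous_mM, 5)
  expect_equal(res$slope, 2)
  expect_equal(res$r_squared, 1)
  # a = 0: nothing endogenous
  res0 <- standard_addition_quant(c(0, 1, 5, 10), 2 * c(0, 1, 5, 10))
  expect_equal(res0$endogenous_mM, 0, tolerance = 1e-12)
  expect_error(standard_addition_quant(c(0, 1), c(1, 2)), "3 spike levels")
  expect_error(standard_addition_quant(c(1, 1, 1), c(1, 2, 3)), "collinear")
  expect_error(standard_addition_quant(c(0, 1, 2), c(3, 2, 1)),
               "non-positive slope")
})

test_that("standard addition agrees with the closed-form OLS oracle", {
  sp <- gen_spike_series(1.2, cv = 0.03, seed = 8)
  res <- standard_addition_quant(sp$spike_conc_mM, sp$signal)
  ab <- ols_oracle(sp$spike_conc_mM, sp$signal)
  expect_equal(res$intercept, ab[1], tolerance = 1e-10)
  expect_equal(res$slope, ab[2], tolerance = 1e-10)
  expect_equal(res$endogenous_mM, ab[1] / ab[2], tolerance = 1e-10)
})

test_that("standard addition recovery is within 3 SE across 20 seeds", {
  truth <- 1.2
  hits <- vapply(1:20, function(s) {
    sp <- gen_spike_series(truth, cv = 0.03, seed = s)
    res <- standard_addition_quant(sp$spike_conc_mM, sp$signal)
    abs(res$endogenous_mM - truth) <= 3 * res$se_mM
  }, logical(1))
  expect_gte(sum(hits), 18)
})

test_that("carbon-use efficiency is the negative media-vs-OD slope", {
  od <- c(0.1, 0.3, 0.6, 1.0)
  res <- carbon_use_efficiency(10 - 5 * od, od)
  expect_equal(res$efficiency_mM_per_od, 5)
  expect_equal(res$r_squared, 1)
  flat <- carbon_use_efficiency(rep(8, 4), od)
  expect_equal(flat$efficiency_mM_per_od, 0)
  ab <- ols_oracle(od, 10 - 5 * od + c(0.1, -0.2, 0.05, 0))
  noisy <- carbon_use_efficiency(10 - 5 * od + c(0.1, -0.2, 0.05, 0), od)
  expect_equal(noisy$slope, ab[2], tolerance = 1e-10)
  expect_error(carbon_use_efficiency(c(1, 2, 3), rep(0.5, 3)), "degenerate")
})

test_that("growth rate fits ln(OD) in the exponential window", {
  t <- seq(0, 5, 0.5)
  res <- growth_rate(t, 0.01 * exp(0.6 * t))
  expect_equal(res$rate_per_h, 0.6, tolerance = 1e-9)
  expect_equal(res$doubling_time_h, log(2) / 0.6, tolerance = 1e-9)
  # constant OD: zero rate, infinite doubling time
  res0 <- growth_rate(t, rep(0.3, length(t)), window = seq_along(t))
  expect_equal(res0$rate_per_h, 0)
  expect_equal(res0$doubling_time_h, Inf)
  expect_error(growth_rate(t[1:3], c(0.1, 0.2, 0.3)), ">= 4 points")
})

test_that("overflow rates and condition ratios follow the generated slopes", {
  t <- seq(0, 6, 0.5)
  res <- overflow_rate(0.1 * t, time_h = t)
  expect_equal(res$rate, 0.1, tolerance = 1e-12)
  flat <- overflow_rate(rep(2, length(t)), time_h = t)
  expect_equal(flat$rate, 0)
  # two conditions generated with a 4x slope ratio
  a <- gen_growth_and_media(excretion_rate = 2.0, noise_conc = 0.05, seed = 1)
  b <- gen_growth_and_media(excretion_rate = 0.5, noise_conc = 0.05, seed = 2)
  ra <- overflow_rate(a$excreted_mM, time_h = a$time_h)
  rb <- overflow_rate(b$excreted_mM, time_h = b$time_h)
  expect_equal(overflow_ratio(ra, rb), 4, tolerance = 0.1)
})
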