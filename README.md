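# pepflux

Quantitative analysis of pyruvate kinase regulation and the
thermodynamics of the phosphoenolpyruvate (PEP) node in bacterial central
carbon metabolism.

Bacillota pyruvate kinases carry an extra C-terminal domain through which
the enzyme is inhibited by ATP and activated by ribose-5-phosphate or AMP.
Switching the enzyme off during gluconeogenic growth lets the cell
accumulate a large PEP pool — and that pool is what keeps the
near-equilibrium reactions just downstream of PEP thermodynamically
forward-favorable. `pepflux` is for researchers studying this kind of
regulatory logic: it provides the enzyme kinetics, pathway thermodynamics,
isotope-tracing and metabolomics computations as tested, composable R
functions, plus seeded synthetic-data generators so every analysis runs
end to end without instrument data.

## What it computes

**Allosteric kinetics.** The Hill-adapted nonessential activation rate law

$$v = \frac{V_{max}[S]^h}{K_S\frac{1+[A]/K_A}{1+\beta[A]/(\alpha K_A)} +
[S]^h\frac{1+[A]/(\alpha K_A)}{1+\beta[A]/(\alpha K_A)}}$$

and its special cases (allosteric sigmoidal, Michaelis–Menten in ADP,
hyperbolic ATP inhibition $v_0/(1+I/K_i)$), conversion of NADH-coupled
A340 assay traces to initial rates, and Levenberg–Marquardt least-squares
estimation with asymptotic standard errors (`fit_kinetic_model()`).

**Pathway thermodynamics.** The max–min driving force (MDF) linear
program: maximize the smallest $-\Delta G'$ along a pathway over metabolite
concentrations within bounds, in log-concentration space
(`solve_mdf()`), with cumulative Gibbs-energy profiles, tie-aware
bottleneck detection, and the flux–force efficacy relation
$(J^+{-}J^-)/(J^+{+}J^-) = \tanh(-\Delta G/2RT)$ (`flux_force()`).

**Isotope tracing.** Unlabeled (M0) fractions of mass-isotopologue
distributions, replicate summaries, and optional natural-abundance
correction (`unlabeled_fraction()`, `summarize_labeling()`).

**Metabolomics & phenotypes.** Internal-standard/OD normalization with
per-metabolite mode selection, Z-scoring, standard-addition absolute
quantification, carbon-use efficiency, exponential growth rates, and
overflow (excretion) rates.

**Synthetic data.** Deterministic seeded generators for rate surfaces on
the PEP×R5P assay grid, absorbance traces, multinomial isotopologues,
log-normal metabolome tables with condition fold-changes, logistic growth
with media depletion, and a packaged 10-step gluconeogenesis fixture with
wild-type-like (high PEP) and mutant-like (PEP depleted 3.5-fold) bounds.

## Worked example

Simulate a wild-type rate surface on the assay design grid (PEP 0–1.5 mM ×
R5P 0–700 µM, 3 replicates, 2% noise), refit it, and ask what the fitted
thermodynamics imply:

```r
library(pepflux)

p   <- pyk_reference_params("wt")
obs <- gen_rate_grid(p, cv = 0.02, replicates = 3, seed = 11)
fit_kinetic_model(obs, "nonessential_activation")
#> Kinetic fit: nonessential_activation model, n = 288, RSS = 328.7, converged: TRUE
#>             estimate   std_error
#> vmax     54.26749099 0.507841448
#> k_half_S  0.83852726 0.006413497
#> h         3.11528465 0.024719320
#> K_A       0.59362704 0.025058444
#> alpha     0.09636319 0.004263024
#> beta      1.98602504 0.019311825
```

The recovered Hill coefficient (3.12 ± 0.02) and half-saturation
constant (0.839 ± 0.006 mM) match the generating values (3.1, 0.84 mM):
strongly cooperative PEP kinetics, with the activator improving apparent
affinity tenfold (`alpha` ≈ 0.1) and doubling the plateau (`beta` ≈ 2).

```r
fx  <- gluconeogenesis_fixture()
wt  <- solve_mdf(fx$pathway, fx$bounds_wt)
mut <- solve_mdf(fx$pathway, fx$bounds_mutant)
#> WT-like MDF:     3.37 kJ/mol (bottlenecks: pyc, eno, pgm, pgk, tpi, fba, pgi)
#> mutant-like MDF: 1.53 kJ/mol (bottlenecks: pyc, eno, pgk)
```

With a large PEP pool the pathway sustains a driving force of 3.37 kJ/mol
at every step; depleting PEP 3.5-fold drops the best achievable
bottleneck force to 1.53 kJ/mol, with the enolase step (`eno`, the
PEP-consuming reaction) among the binding constraints. (The fixture's
standard Gibbs energies are documented placeholders; the meaningful output
is the ordering, not the absolute values.)

```r
flux_force(c(-2.97, -0.27))
#>   forward_ratio reverse_ratio net_ratio
#> 1        0.7682        0.2318    0.5364
#> 2        0.5272        0.4728    0.0544
```

A bottleneck at −2.97 kJ/mol converts 54% of its gross flux into net flux;
at −0.27 kJ/mol — nearly at equilibrium — only 5.4% of the enzyme's gross
turnover is productive, a ~10-fold loss of catalytic efficacy.

## Documentation

The methods vignette (`vignettes/pep-node-methods.Rmd`) describes the rate
laws and their parameterization, the MDF linear program and its oracle
tests, the bounds conventions, what the synthetic generators do and do not
emulate, and the package's numerical choices and limitations.
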