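---
title: "Methods: pyruvate kinase regulation and PEP-node thermodynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pyruvate kinase regulation and PEP-node thermodynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepflux)
```

## The scientific problem

During gluconeogenic growth a bacterium must run the lower glycolytic
reactions backwards, and several of those steps are close to equilibrium.
Bacillota pyruvate kinases carry an extra C-terminal domain (ECTD) through
which the enzyme is switched off by ATP and on by ribose-5-phosphate (R5P)
or AMP. When the enzyme is off, phosphoenolpyruvate (PEP) accumulates, and a
large PEP pool is exactly what pushes the near-equilibrium steps after PEP
forward. `pepflux` implements the quantitative analyses needed to study
this regulatory logic: allosteric enzyme kinetics, pathway thermodynamics by
max–min driving force (MDF), isotope-tracing label fractions, and the
supporting metabolomics and growth computations — plus seeded synthetic-data
generators so every analysis can be exercised end to end without instrument
data.

## Allosteric rate laws

The central rate law is a Hill-adapted *nonessential activation* model. The
activator A is not required for turnover but, when bound (dissociation
constant $K_A$), rescales the apparent substrate affinity by $\alpha$ and
the maximal rate by $\beta$:

$$v \;=\; \frac{V_{max}\,[S]^h}
  {K_S\,\dfrac{1+[A]/K_A}{1+\beta [A]/(\alpha K_A)}
   \;+\; [S]^h\,\dfrac{1+[A]/(\alpha K_A)}{1+\beta [A]/(\alpha K_A)}}$$

Three algebraic facts anchor the implementation and are asserted by tests:
at $[A]=0$ the model collapses to the allosteric sigmoidal law
$v = V_{max}S^h/(K_S + S^h)$; at $\alpha=\beta=1$ the activator terms cancel
for every $(S, A)$; and as $S \to \infty$ the rate saturates at
$V_{max}(1+\beta A/(\alpha K_A))/(1+A/(\alpha K_A))$.

**Parameterization of $K_S$.** Written as above, $K_S$ has awkward units of
mM$^h$. We expose instead the half-saturation concentration `k_half_S` in mM
— the substrate concentration at $v = V_{max}/2$ when no activator is
present — and compute $K_S = \texttt{k\_half\_S}^h$ internally. Fit results
also report the raw $K_S$ (`K_S_raw`) for completeness. This keeps the
reported constant in interpretable concentration units regardless of the
Hill coefficient.

**ATP inhibition.** Only a dissociation constant $K_i = [E][I]/[EI]$ is
defined for the inhibitor, so we use the simplest consistent form, pure
hyperbolic (noncompetitive) inhibition $v = v_0/(1+I/K_i)$. With the
wild-type $K_i = 0.52$ mM this predicts $\approx 9.4\%$ residual activity at
5 mM ATP. A competitive variant was considered and not implemented: the
operation's contract is to scale an observed $v_0$, and a competitive
mechanism cannot be expressed without re-introducing the substrate
dependence (a full-model refit does that job better).

**Reference parameters.** `pyk_reference_params()` carries published
estimates for the *B. subtilis* enzyme (wild type: $k_{cat}$ 54.1,
$K'_{PEP}$ 0.84 mM, $h$ 3.1, $K_{m,ADP}$ 1.01 mM, $K_{A,R5P}$ 0.57 mM,
$K_{i,ATP}$ 0.52 mM; ECTD-truncated variant: 53.8, 0.32 mM, 1.3, 1.83 mM).
Two values of $K_{A,R5P}$ circulate — 0.57 mM from the tabulated fit and
0.29 mM from a rate-surface fit; both are available via the `K_A_variant`
argument, with the tabulated value as default. The activation shape factors
$\alpha = 0.1$, $\beta = 2.0$ are *generator defaults*, not measurements:
they encode an activator that both improves apparent affinity and raises
the plateau, which is the qualitative behavior of R5P, and they are
documented as such wherever they appear.

## Absorbance traces

The coupled assay reads pyruvate production as NADH loss at 340 nm.
`trace_to_rate()` fits a line to the early window of the trace (default:
the first 20% of points, but never fewer than 10) and converts via
Beer–Lambert with $\varepsilon_{340} = 6220$ M$^{-1}$cm$^{-1}$ (the
standard literature value; configurable). Rising traces — NADH gain — are
reported as $V_0 = 0$ with a warning rather than as a negative rate.

## Nonlinear fitting

`fit_kinetic_model()` uses Levenberg–Marquardt least squares
(`minpack.lm::nls.lm`) with positivity bounds. Starting values come from
data heuristics ($V_{max} = 1.2\times$ max rate, half-saturation from the
half-max point, $h = 1$); if the first start fails, a deterministic ladder
of jittered starts (halving/doubling) is tried. Standard errors are the
asymptotic estimates $\hat\sigma^2 (J^\top J)^{-1}$ with $J$ a
central-difference Jacobian of the residuals at the solution; a singular
Jacobian is flagged, never silently ignored. Residuals are unweighted by
default (`weights = "relative"` is available). On noiseless
generator output the fits recover the generating parameters to $10^{-6}$
relative error; on 2% CV noise the estimates cover the truth at the usual
asymptotic rates (tested over 20 seeds, expecting at least 18/20 inside 3
standard errors — the binomially sensible criterion for a 99.7% interval).

## Max–min driving force

For a pathway of reactions with standard transformed energies
$\Delta G'^0_j$ and stoichiometric matrix $S$, the MDF problem is the
linear program

$$\max_{x, B} B \quad\text{s.t.}\quad
  \Delta G'^0_j + RT\,(S^\top x)_j \le -B \;\;\forall j, \qquad
  \ln \mathrm{lb} \le x \le \ln \mathrm{ub}$$

over log-concentrations $x$, solved with the simplex method
(`boot::simplex`; variables are shifted so all are nonnegative, and $B$ is
offset by a conservative constant so it may be negative). $R = 8.314\times
10^{-3}$ kJ mol$^{-1}$K$^{-1}$, $T$ defaults to 298.15 K; pH (7) and ionic
strength (250 mM) are provenance metadata carried with the
$\Delta G'^0$ inputs — no Legendre transform is computed here, which also
means $\Delta G'^0$ values are *inputs*, not estimates this package makes.
Water is held at activity 1 and excluded from the program. Optimal
concentrations can be degenerate; only $B$, the per-reaction $\Delta G'$ at
the optimum, and bottleneck membership are contractual, and the
concentration vector is reported as one witness. Bottlenecks are all
reactions within 0.1 kJ/mol (configurable) of $-B$ — ties are reported in
full, since co-limiting triplets are a real phenomenon in gluconeogenesis.

The LP is verified against an exhaustive grid-search maximin oracle on
randomly generated pathways of up to 4 metabolites and 3 reactions (21 grid
points per dimension; the test asserts the LP is never below the grid
optimum and exceeds it by at most the grid-resolution bound
$RT\max_j\sum_i |s_{ij}|\,\Delta x_i/2$), and for monotonicity under bound
widening.

**Percent bounds.** Measured intracellular concentrations enter as bounds
$[c(1-p/100),\, c(1+p/100)]$; a 100% range on a 4 mM mean spans ~0–8 mM,
matching how such ranges are used in practice for ATP. Non-positive lower
bounds are clipped to a $10^{-9}$ M floor.

**Flux–force efficacy.** A reaction's free energy bounds the fraction of
its gross flux that is net forward:
$(J^+-J^-)/(J^++J^-) = (e^{-\Delta G/RT}-1)/(e^{-\Delta G/RT}+1)
= \tanh(-\Delta G/2RT)$. At $\Delta G = -2.97$ kJ/mol this gives 53.6% (54%
to the nearest integer); at $-0.27$ kJ/mol it gives 5.44%. Note that a
published rounding of the latter as "6%" does not match the formula value
of 5.4% — presumably it was computed from an unrounded driving force — so
this package reports the formula value and documents the difference here.

## The gluconeogenesis fixture

`gluconeogenesis_fixture()` ships a 10-step gluconeogenic pathway
(2 pyruvate → glucose 6-phosphate: pyruvate carboxylase, PEP carboxykinase,
enolase, phosphoglycerate mutase, phosphoglycerate kinase, GAPDH, triose
phosphate isomerase, aldolase, FBPase, phosphoglucose isomerase). Its
$\Delta G'^0$ values are **literature-style placeholders**, clearly marked
synthetic in the packaged TSV: component-contribution estimates are
version-dependent and outside this package's scope, so no conclusion here
rests on their absolute values — only on orderings. Each reaction carries a
relative flux (2 before the triose condensation, 1 after) used solely to
weight cumulative profiles, so that the flux-weighted cumulative
$\Delta G'$ telescopes to the net pathway energy; the MDF itself ignores
flux magnitudes, as is standard.

Wild-type-like bounds put PEP, ATP and ADP at 40%, 100% and 40% of
synthetic "measured" concentrations (2.8, 4 and 0.6 mM — plausible
magnitudes for gluconeogenic growth), everything else at the 1 µM–10 mM
default. Mutant-like bounds are *derived*, mimicking how conservative
mutant profiles are built when only relative data exist: each non-special
metabolite is bounded at ±40% of its wild-type MDF-optimized concentration,
while PEP drops 3.5-fold (to 0.8 mM). Under this construction the wild type
attains a strictly higher MDF, and the mutant's bottleneck set contains the
enolase step — the PEP-consuming reaction — as an emergent consequence of
the depleted PEP bound, not of any per-case tuning.

## Isotope tracing

Growth on a 1-position-labeled carbon source makes the unlabeled (M0)
fraction of pyruvate an in vivo reporter of pyruvate kinase activity: PEP
made through the TCA-cycle detour loses the label, so active pyruvate
kinase raises the unlabeled pyruvate fraction. `unlabeled_fraction()` is
simply $M_0/\sum_i M_i$; `summarize_labeling()` aggregates means and SEMs
per metabolite × condition, dropping zero-count replicates with a warning
(a missing measurement is not a fraction of zero). Alanine (3 C) and valine
(5 C) serve as proxies whose carbon backbones derive entirely from
pyruvate. Natural-abundance correction (binomial convolution-matrix
inversion, $p_{13C} = 0.0107$) is available but **off by default**, since
raw unlabeled ratios are the primary readout; the correction satisfies
a round-trip identity (correct ∘ convolve = identity, tested to $10^{-8}$).

## Metabolomics and phenotype computations

* `normalize_counts()`: a metabolite whose fully ¹³C-labeled
  internal-standard channel is robust (median IS counts ≥ a threshold,
  default 1000 counts — an order of magnitude over a typical noise floor)
  is normalized as count/IS/OD, otherwise count/OD; the mode is recorded
  per metabolite, and IS-mode samples with unusable IS counts become `NA`
  with a warning.
* `zscore()`: $(x-\mu)/\sigma$ with the **sample** standard deviation by
  default (the convention of metabolome heatmaps; population σ available),
  refusing constant vectors.
* `standard_addition_quant()`: OLS of signal on spiked concentration
  (0×/0.1×/1×/10× designs); endogenous level $= a/b$ with a delta-method
  standard error. Estimates are per-extract concentrations; converting to
  intracellular molarity needs a user-supplied volume-per-OD factor, which
  is deliberately not baked in.
* `carbon_use_efficiency()`: −slope of remaining medium carbon vs OD; a
  larger value means more carbon consumed per unit biomass (more
  overflow, less efficient growth).
* `growth_rate()`: slope of ln OD vs time; the exponential window is
  either given or auto-selected as the longest contiguous run with local
  $R^2 \ge 0.99$.
* `overflow_rate()`: slope of excreted metabolite vs time (default) or OD.

All regressions are plain `stats::lm` fits and are cross-checked in the
test suite against a closed-form $(X^\top X)^{-1}X^\top y$ oracle.

## Synthetic data: what it emulates, and what it does not

The generators are pure functions of their arguments and seed
(`withr::with_seed`, leaving the caller's RNG untouched):

* `gen_rate_grid()` — the 8-level PEP (0–1.5 mM) × 12-level R5P (0–700 µM)
  assay design with multiplicative Gaussian noise (default CV 2%, a typical
  plate-reader figure), 3 replicates.
* `gen_assay_trace()` — linear NADH-consumption traces with additive
  absorbance noise.
* `gen_isotopologues()` — multinomial ion counts at a chosen depth.
* `gen_metabolome()` — log-normal ion counts (mean-1 noise at a chosen CV,
  default 15%, typical for targeted LC-MS) with condition fold-changes;
  the default scenario encodes the mutant phenotype: PEP at fold 1/3.5
  and correlated depletion of BPG, 3PG, G6P, R5P and S7P, with pyruvate
  accumulating. The IS channel is shared across samples (no condition
  effect, half the noise).
* `gen_growth_and_media()` — logistic growth with linear carbon
  consumption per OD and linear overflow excretion.

These reproduce the *statistical structure* the analyses assume — design
grids, noise families, effect directions — not the chemistry: no
chromatographic drift, ion suppression, carry-over, natural-abundance
structure beyond the binomial model, or growth-phase metabolic shifts.
Passing round-trip tests therefore demonstrates correctness of the
estimators under their stated models, not robustness to every artifact of
real instruments.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run on deliberately compact
problems: 288-point rate surfaces (3 replicates), 24-point titrations,
50 random MDF instances with ≤4 metabolites at 21 grid points per
dimension, 20-seed Monte-Carlo recovery loops, and isotopologue depths up
to $10^7$. These sizes were chosen so the full suite executes in seconds
while leaving the statistical assertions well-powered. Optimizer
tolerances are `ftol = ptol = 1e-12` (LM) and `eps = 1e-10` (simplex);
equality assertions on closed-form quantities use $10^{-12}$ relative
tolerance, stochastic assertions use binomially justified coverage counts.

## Known limitations

* $\Delta G'^0$ estimation (component contribution, Legendre transforms
  across pH/ionic strength) is out of scope; the fixture energies are
  placeholders and all fixture conclusions are orderings.
* The inhibition operation is hyperbolic only; mechanistic discrimination
  (competitive vs noncompetitive) requires a substrate-resolved design and
  a full-model fit.
* No EMU/cumomer flux modeling: label fractions are summaries, not flux
  estimates.
* Cofactor ratios (ATP/ADP, NAD/NADH) are independent bounded species by
  default; fixed-ratio constraints would need an additional linear
  constraint, which the LP formulation admits but the API does not
  currently expose.
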