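#' Kinetic parameter set for an allosterically regulated pyruvate kinase
#'
#' Bundles every constant used by the rate laws in this package. All
#' constants must be strictly positive where supplied; parameters not needed
#' by a given rate law may be left `NA`.
#'
#' @param vmax Maximal rate (assay units, e.g. µmol min^-1 mg^-1, or an
#'   arbitrary normalized unit). Strictly positive.
#' @param k_half_S Half-saturation concentration for the substrate PEP (mM).
#'   This is the apparent Michaelis constant K'_PEP of the Hill-type model:
#'   the rate is `vmax/2` at `S = k_half_S`. Internally the sigmoidal
#'   denominator uses `k_half_S^h` (units mM^h), so the exposed constant
#'   keeps interpretable mM units whatever the Hill coefficient.
#' @param h Hill coefficient for PEP (dimensionless, > 0). `h > 1` means
#'   cooperative, sigmoidal kinetics.
#' @param K_A Activator dissociation constant (mM), `[E][A]/[EA]`.
#' @param alpha Factor by which a bound activator changes the apparent
#'   substrate affinity (dimensionless, > 0; `alpha < 1` improves affinity).
#' @param beta Factor by which a bound activator changes the maximal rate
#'   (dimensionless, > 0; `beta > 1` raises the plateau).
#' @param K_i Inhibitor dissociation constant (mM), `[E][I]/[EI]`.
#' @param K_m_ADP Michaelis constant for the co-substrate ADP (mM).
#' @param kcat Turnover number (time^-1). Carried for reporting; the rate
#'   laws use `vmax` (set `vmax = kcat` to work on a per-active-site scale).
#'
#' @return An object of class `kinetic_params` (a named list).
#' @seealso [rate_allosteric_sigmoidal()], [rate_nonessential_activation()],
#'   [fit_kinetic_model()], [pyk_reference_params()]
#' @export
#' @examples
#' p <- kinetic_params(vmax = 54.1, k_half_S = 0.84, h = 3.1)
#' rate_allosteric_sigmoidal(p, S = 0.84)  # vmax / 2
kinetic_params <- function(vmax = NA_real_, k_half_S = NA_real_, h = 1,
                           K_A = NA_real_, alpha = 1, beta = 1,
                           K_i = NA_real_, K_m_ADP = NA_real_,
                           kcat = NA_real_) {
  p <- list(vmax = vmax, k_half_S = k_half_S, h = h, K_A = K_A,
            alpha = alpha, beta = beta, K_i = K_i, K_m_ADP = K_m_ADP,
            kcat = kcat)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.na(v) && (!is.finite(v) || v <= 0)) {
      stop("kinetic parameter '", nm, "' must be finite and > 0, got ", v)
    }
  }
  structure(p, class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("Kinetic parameters:\n")
  shown <- x[!vapply(x, is.na, logical(1))]
  for (nm in names(shown)) cat(sprintf("  %-9s %g\n", nm, shown[[nm]]))
  invisible(x)
}

#' Reference kinetic parameter sets for B. subtilis pyruvate kinase
#'
#' Published estimates for the full-length (wild-type) enzyme and the
#' constitutively active variant lacking the extra C-terminal domain
#' (ECTD-truncated). These drive the synthetic-data generators and parameter
#' recovery studies. `vmax` is set equal to `kcat` (per-active-site scale).
#'
#' For the wild type the activator constant for R5P has been reported both
#' as 0.57 mM (tabulated fit) and 0.29 mM (rate-surface fit); choose with
#' `K_A_variant`. The activation shape factors `alpha = 0.1`, `beta = 2.0`
#' are generator defaults (the activator both improves apparent affinity and
#' raises the plateau), not measured constants.
#'
#' @param variant `"wt"` (full-length) or `"dectd"` (ECTD-truncated).
#' @param K_A_variant `"table"` (0.57 mM) or `"surface"` (0.29 mM); wild
#'   type only.
#' @return A [kinetic_params()] object.
#' @export
#' @examples
#' pyk_reference_params("wt")$h      # 3.1
#' pyk_reference_params("dectd")$h   # 1.3
pyk_reference_params <- function(variant = c("wt", "dectd"),
                                 K_A_variant = c("table", "surface")) {
  variant <- match.arg(variant)
  K_A_variant <- match.arg(K_A_variant)
  if (variant == "wt") {
    kinetic_params(vmax = 54.1, kcat = 54.1, k_half_S = 0.84, h = 3.1,
                   K_A = if (K_A_variant == "table") 0.57 else 0.29,
                   alpha = 0.1, beta = 2.0,
                   K_i = 0.52, K_m_ADP = 1.01)
  } else {
    kinetic_params(vmax = 53.8, kcat = 53.8, k_half_S = 0.32, h = 1.3,
                   K_m_ADP = 1.83)
  }
}

check_nonneg <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0)) {
    stop(what, " must be finite and >= 0")
  }
  invisible(x)
}

#' Allosteric sigmoidal (Hill) rate law
#'
#' `v = vmax * S^h / (k_half_S^h + S^h)`. Describes cooperative substrate
#' kinetics without activator terms; it is the zero-activator limit of
#' [rate_nonessential_activation()].
#'
#' @param p [kinetic_params()] with `vmax`, `k_half_S`, `h`.
#' @param S Substrate (PEP) concentration, mM (vectorized, >= 0).
#' @return Rate(s) in the units of `vmax`; non-decreasing in `S`, bounded by
#'   `vmax`, equal to `vmax/2` at `S = k_half_S`.
#' @export
#' @examples
#' p <- kinetic_params(vmax = 1, k_half_S = 0.84, h = 3.1)
#' rate_allosteric_sigmoidal(p, c(0, 0.84, 10))
rate_allosteric_sigmoidal <- function(p, S) {
  check_nonneg(S, "substrate concentration S")
  Sh <- S^p$h
  p$vmax * Sh / (p$k_half_S^p$h + Sh)
}

#' Hill-adapted nonessential activation rate law
#'
#' Modifier kinetics in which an activator A (R5P or AMP for pyruvate
#' kinase) is not required for catalysis but changes the apparent substrate
#' affinity (through `alpha`) and the maximal rate (through `beta`):
#'
#' \deqn{v = \frac{V_{max} S^h}{K_S\frac{1 + A/K_A}{1 + \beta A/(\alpha K_A)}
#'   + S^h\frac{1 + A/(\alpha K_A)}{1 + \beta A/(\alpha K_A)}}}
#'
#' with `K_S = k_half_S^h`. At `A = 0` this reduces exactly to
#' [rate_allosteric_sigmoidal()]; at `alpha = beta = 1` the activator terms
#' cancel and A has no effect; as `S` grows the rate saturates at
#' `vmax * (1 + beta*A/(alpha*K_A)) / (1 + A/(alpha*K_A))`.
#'
#' @param p [kinetic_params()] with `vmax`, `k_half_S`, `h`, `K_A`,
#'   `alpha`, `beta`.
#' @param S Substrate (PEP) concentration, mM (>= 0, vectorized).
#' @param A Activator concentration, mM (>= 0, vectorized or scalar).
#' @return Rate(s) in the units of `vmax`.
#' @export
#' @examples
#' p <- pyk_reference_params("wt")
#' rate_nonessential_activation(p, S = 0.6, A = 0.29)
rate_nonessential_activation <- function(p, S, A) {
  check_nonneg(S, "substrate concentration S")
  check_nonneg(A, "activator concentration A")
  KS <- p$k_half_S^p$h
  aKA <- p$alpha * p$K_A
  denom_scale <- 1 + p$beta * A / aKA
  term_K <- KS * (1 + A / p$K_A) / denom_scale
  term_S <- S^p$h * (1 + A / aKA) / denom_scale
  p$vmax * S^p$h / (term_K + term_S)
}

#' Hyperbolic (noncompetitive) inhibition of an observed rate
#'
#' Scales an uninhibited rate by `1 / (1 + I/K_i)`, the hyperbolic form
#' implied by a single dissociation constant `K_i = [E][I]/[EI]`. At
#' `I = K_i` exactly half the activity remains.
#'
#' @param p [kinetic_params()] with `K_i`.
#' @param v0 Uninhibited rate(s) (>= 0).
#' @param I Inhibitor (ATP) concentration, mM (>= 0, vectorized).
#' @return Inhibited rate(s); equal to `v0` at `I = 0`, strictly decreasing
#'   in `I`.
#' @export
#' @examples
#' p <- kinetic_params(vmax = 1, k_half_S = 1, K_i = 0.52)
#' rate_with_inhibitor(p, v0 = 1, I = 5)  # < 0.15 of the uninhibited rate
rate_with_inhibitor <- function(p, v0, I) {
  check_nonneg(I, "inhibitor concentration I")
  check_nonneg(v0, "uninhibited rate v0")
  v0 / (1 + I / p$K_i)
}

#' Michaelis-Menten rate law in the co-substrate ADP
#'
#' `v = vmax * ADP / (K_m_ADP + ADP)`; used for ADP titrations at saturating
#' PEP.
#'
#' @param p [kinetic_params()] with `vmax`, `K_m_ADP`.
#' @param ADP ADP concentration, mM (>= 0, vectorized).
#' @return Rate(s) in the units of `vmax`.
#' @export
rate_michaelis_menten_adp <- function(p, ADP) {
  check_nonneg(ADP, "ADP concentration")
  p$vmax * ADP / (p$K_m_ADP + ADP)
}

#' Normalize rates against a reference condition
#'
#' @param v Rates to normalize (vectorized).
#' @param v_ref Rate at the reference condition (scalar, > 0), e.g. the rate
#'   in the absence of inhibitor.
#' @return `v / v_ref`; the reference condition maps to 1.
#' @export
normalize_activity <- function(v, v_ref) {
  if (length(v_ref) != 1L || !is.finite(v_ref) || v_ref <= 0) {
    stop("v_ref must be a single finite value > 0")
  }
  v / v_ref
}

#' Size-exclusion chromatography partition coefficient
#'
#' `Kav = (Ve - Vo) / (Vc - Vo)` for elution volume `Ve`, column void volume
#' `Vo` and total column volume `Vc`; used with a standard curve to estimate
#' apparent molecular mass (e.g. the oligomeric state of pyruvate kinase).
#'
#' @param Ve Elution volume at the peak apex (mL, vectorized).
#' @param Vo Void volume (mL).
#' @param Vc Total column volume (mL, must exceed `Vo`).
#' @return Partition coefficient(s) in `[0, 1]` for `Ve` within the column.
#' @export
#' @examples
#' sec_partition_coefficient(Ve = 200, Vo = 100, Vc = 300)  # 0.5
sec_partition_coefficient <- function(Ve, Vo, Vc) {
  if (Vc <= Vo) stop("total column volume Vc must exceed void volume Vo")
  if (any(Ve < Vo)) stop("elution volume Ve cannot precede the void volume")
  (Ve - Vo) / (Vc - Vo)
}
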