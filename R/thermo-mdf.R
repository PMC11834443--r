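#' Reaction with a standard transformed Gibbs energy
#'
#' @param reaction_id Reaction label (e.g. an enzyme name).
#' @param stoichiometry Named numeric vector of signed stoichiometric
#'   coefficients (negative = consumed, positive = produced). Must contain
#'   at least one consumed and one produced species. Water (`"h2o"` or
#'   `"water"`) may appear; its activity is fixed at 1 and it is excluded
#'   from concentration terms.
#' @param dg0_prime Standard transformed Gibbs energy of reaction
#'   (kJ/mol) at the pathway's pH/ionic strength.
#' @param flux Relative pathway flux multiplier (default 1); used only when
#'   weighting cumulative Gibbs-energy profiles, never by the max-min
#'   driving force optimization itself.
#' @return An object of class `reaction_spec`.
#' @export
#' @examples
#' reaction_spec("eno", c(pep = -1, h2o = -1, `2pg` = 1), dg0_prime = 4.0)
reaction_spec <- function(reaction_id, stoichiometry, dg0_prime, flux = 1) {
  stopifnot(is.character(reaction_id), length(reaction_id) == 1L)
  if (is.null(names(stoichiometry)) || any(names(stoichiometry) == "")) {
    stop("stoichiometry must be a fully named numeric vector")
  }
  if (!any(stoichiometry < 0) || !any(stoichiometry > 0)) {
    stop("reaction '", reaction_id,
         "' needs at least one consumed and one produced metabolite")
  }
  if (!is.finite(dg0_prime)) stop("dg0_prime must be finite")
  structure(list(reaction_id = reaction_id,
                 stoichiometry = stoichiometry,
                 dg0_prime = dg0_prime,
                 flux = flux),
            class = "reaction_spec")
}

WATER_NAMES <- c("h2o", "water")

#' Ordered pathway of reactions
#'
#' @param reactions List of [reaction_spec()] objects; their order defines
#'   the x-axis of cumulative Gibbs-energy profiles.
#' @param pH,ionic_strength_mM,temperature_K Conditions at which the
#'   `dg0_prime` values were estimated. pH and ionic strength are carried as
#'   provenance metadata (no Legendre transform is performed here);
#'   temperature enters the RT concentration terms. Defaults: pH 7, 250 mM,
#'   298.15 K.
#' @return An object of class `pathway_spec` with a `metabolites` element
#'   (union of species, water excluded).
#' @export
pathway_spec <- function(reactions, pH = 7, ionic_strength_mM = 250,
                         temperature_K = 298.15) {
  stopifnot(length(reactions) >= 1L,
            all(vapply(reactions, inherits, logical(1), "reaction_spec")))
  if (temperature_K <= 0 || ionic_strength_mM < 0) {
    stop("conditions must be positive")
  }
  ids <- vapply(reactions, `[[`, character(1), "reaction_id")
  if (anyDuplicated(ids)) stop("duplicate reaction ids")
  mets <- sort(unique(unlist(lapply(reactions, function(r) names(r$stoichiometry)))))
  mets <- setdiff(mets, WATER_NAMES)
  structure(list(reactions = reactions, metabolites = mets,
                 pH = pH, ionic_strength_mM = ionic_strength_mM,
                 temperature_K = temperature_K),
            class = "pathway_spec")
}

#' @export
print.pathway_spec <- function(x, ...) {
  cat(sprintf("Pathway: %d reactions, %d metabolites (pH %.3g, I = %g mM, T = %g K)\n",
              length(x$reactions), length(x$metabolites),
              x$pH, x$ionic_strength_mM, x$temperature_K))
  for (r in x$reactions) {
    s <- r$stoichiometry
    fmt <- function(v) paste(ifelse(abs(v) == 1, names(v),
                                    paste(abs(v), names(v))), collapse = " + ")
    cat(sprintf("  %-8s %s = %s   (dG'0 = %+.2f kJ/mol)\n", r$reaction_id,
                fmt(s[s < 0]), fmt(s[s > 0]), r$dg0_prime))
  }
  invisible(x)
}

# Stoichiometric matrix, metabolites x reactions, water excluded.
stoich_matrix <- function(pathway) {
  S <- matrix(0, length(pathway$metabolites), length(pathway$reactions),
              dimnames = list(pathway$metabolites,
                              vapply(pathway$reactions, `[[`, character(1),
                                     "reaction_id")))
  for (j in seq_along(pathway$reactions)) {
    st <- pathway$reactions[[j]]$stoichiometry
    st <- st[!names(st) %in% WATER_NAMES]
    S[names(st), j] <- st
  }
  S
}

#' Transformed Gibbs energy of one reaction at given concentrations
#'
#' `dG' = dG'0 + RT * sum_i s_i ln(c_i)` with R = 8.314e-3 kJ/(mol K) and
#' concentrations in M. Water is excluded (activity 1).
#'
#' @param rxn A [reaction_spec()].
#' @param concentrations Named numeric vector of concentrations (M, > 0)
#'   covering every non-water participant.
#' @param temperature_K Temperature in K (default 298.15).
#' @return dG' in kJ/mol.
#' @export
#' @examples
#' r <- reaction_spec("r", c(a = -1, b = 1), dg0_prime = 0)
#' driving_force(r, c(a = 1e-2, b = 1e-6))  # ~ -22.83 kJ/mol
driving_force <- function(rxn, concentrations, temperature_K = 298.15) {
  st <- rxn$stoichiometry
  st <- st[!names(st) %in% WATER_NAMES]
  missing <- setdiff(names(st), names(concentrations))
  if (length(missing)) {
    stop("missing concentrations for: ", paste(missing, collapse = ", "))
  }
  conc <- concentrations[names(st)]
  if (any(!is.finite(conc)) || any(conc <= 0)) {
    stop("all concentrations must be finite and > 0")
  }
  rxn$dg0_prime + R_KJ * temperature_K * sum(st * log(conc))
}

#' Concentration bounds for metabolites
#'
#' @param lb,ub Named numeric vectors (M) of lower and upper bounds over the
#'   same metabolite set; `0 < lb <= ub` (equal bounds fix a concentration).
#' @return An object of class `concentration_bounds`.
#' @seealso [make_bounds_from_measured()], [default_bounds()]
#' @export
concentration_bounds <- function(lb, ub) {
  stopifnot(!is.null(names(lb)), setequal(names(lb), names(ub)))
  ub <- ub[names(lb)]
  if (any(lb <= 0)) stop("lower bounds must be strictly positive")
  if (any(ub < lb)) stop("upper bounds must be >= lower bounds")
  structure(list(lb = lb, ub = ub), class = "concentration_bounds")
}

#' Default physiological concentration range
#'
#' `[1 uM, 10 mM]` for every metabolite, the conventional range for
#' intracellular metabolites without direct measurements.
#'
#' @param metabolites Character vector of metabolite names.
#' @param lb_M,ub_M Range applied to each (M).
#' @return A [concentration_bounds()] object.
#' @export
default_bounds <- function(metabolites, lb_M = 1e-6, ub_M = 1e-2) {
  concentration_bounds(setNames(rep(lb_M, length(metabolites)), metabolites),
                       setNames(rep(ub_M, length(metabolites)), metabolites))
}

#' Bounds from measured concentrations with a percent range
#'
#' Converts absolute intracellular concentration estimates into bounds
#' `[c*(1 - p/100), c*(1 + p/100)]`. A 100% range therefore spans ~0 to 2c
#' (e.g. ATP at a 4 mM mean ranging up to 8 mM); non-positive lower bounds
#' are clipped to `floor_M`. Metabolites in `metabolites` without a
#' measurement get the default range.
#'
#' @param measured Named numeric vector of measured concentrations (M, > 0).
#' @param percent_range Percent half-width per metabolite: a single number
#'   recycled to all, or a named vector matched to `measured`. Must be in
#'   `[0, 200)`.
#' @param floor_M Positive clip floor for lower bounds (default 1e-9 M).
#' @param metabolites Optional full metabolite set; unmeasured members get
#'   `[default_lb_M, default_ub_M]`.
#' @param default_lb_M,default_ub_M Default range for unmeasured metabolites.
#' @return A [concentration_bounds()] object.
#' @export
#' @examples
#' make_bounds_from_measured(c(atp = 4e-3), percent_range = 100)
make_bounds_from_measured <- function(measured, percent_range,
                                      floor_M = 1e-9, metabolites = NULL,
                                      default_lb_M = 1e-6,
                                      default_ub_M = 1e-2) {
  if (any(measured <= 0)) stop("measured concentrations must be > 0")
  if (length(percent_range) == 1L) {
    percent_range <- setNames(rep(percent_range, length(measured)),
                              names(measured))
  }
  percent_range <- percent_range[names(measured)]
  if (any(is.na(percent_range)) || any(percent_range < 0) ||
      any(percent_range >= 200)) {
    stop("percent_range must be in [0, 200) for every measured metabolite")
  }
  lb <- measured * (1 - percent_range / 100)
  ub <- measured * (1 + percent_range / 100)
  lb[lb <= 0] <- floor_M
  lb <- pmax(lb, floor_M)
  if (!is.null(metabolites)) {
    rest <- setdiff(metabolites, names(measured))
    lb <- c(lb, setNames(rep(default_lb_M, length(rest)), rest))
    ub <- c(ub, setNames(rep(default_ub_M, length(rest)), rest))
  }
  concentration_bounds(lb, ub)
}

#' Max-min driving force (MDF) of a pathway
#'
#' Finds metabolite concentrations, within bounds, that maximize the
#' smallest driving force (-dG') along the pathway. In log-concentration
#' space this is the linear program
#'
#' \deqn{\max_{x, B} B \quad s.t.\quad dG'^0_j + RT (S^T x)_j \le -B\ \forall j,
#'   \quad \ln lb \le x \le \ln ub}
#'
#' solved here with the simplex method. The optimal `B` and the per-reaction
#' dG' at the optimum are unique; the optimal concentrations need not be,
#' and are reported as one witness.
#'
#' @param pathway A [pathway_spec()].
#' @param bounds A [concentration_bounds()] covering (at least) the
#'   pathway's metabolites; missing metabolites get the default 1 uM - 10 mM
#'   range.
#' @param bottleneck_tol Reactions with dG' within this tolerance (kJ/mol)
#'   of `-B` are reported as bottlenecks (default 0.1).
#' @return An object of class `mdf_solution`: `mdf_B` (kJ/mol), `log_conc`
#'   (natural log of M), `concentrations_M`, `dg_prime` (per reaction),
#'   `bottlenecks`, `cumulative` and `reference_cumulative` (flux-weighted
#'   running sums of dG', optimized and with all metabolites at 1 mM),
#'   `conditions`, `status`.
#' @export
#' @examples
#' rxn <- reaction_spec("r", c(a = -1, b = 1), dg0_prime = 0)
#' pw <- pathway_spec(list(rxn))
#' sol <- solve_mdf(pw, default_bounds(pw$metabolites))
#' sol$mdf_B  # ~22.83: a at 10 mM, b at 1 uM
solve_mdf <- function(pathway, bounds, bottleneck_tol = 0.1) {
  stopifnot(inherits(pathway, "pathway_spec"),
            inherits(bounds, "concentration_bounds"))
  mets <- pathway$metabolites
  missing <- setdiff(mets, names(bounds$lb))
  if (length(missing)) {
    extra <- default_bounds(missing)
    bounds <- concentration_bounds(c(bounds$lb, extra$lb),
                                   c(bounds$ub, extra$ub))
  }
  lb <- log(bounds$lb[mets])
  ub <- log(bounds$ub[mets])
  S <- stoich_matrix(pathway)
  RT <- R_KJ * pathway$temperature_K
  dg0 <- vapply(pathway$reactions, `[[`, numeric(1), "dg0_prime")
  n_met <- length(mets)
  n_rxn <- length(dg0)

  # Shift to y = x - ln(lb) >= 0 and B = Bp - M >= -M so all simplex
  # variables are nonnegative; M is a conservative bound on |B|.
  M <- max(1000, 10 * max(abs(dg0)) + RT * sum(ub - lb))
  d <- ub - lb
  a_obj <- c(rep(0, n_met), 1)
  A1 <- rbind(cbind(RT * t(S), 1),
              cbind(diag(n_met), 0))
  b1 <- c(-dg0 - RT * as.numeric(crossprod(S, lb)) + M, d)
  res <- boot::simplex(a = a_obj, A1 = A1, b1 = b1, maxi = TRUE,
                       n.iter = 50 * (n_met + n_rxn + 2), eps = 1e-10)
  if (res$solved != 1) {
    status <- if (res$solved == 0) "not converged" else "infeasible"
    stop("MDF linear program ", status,
         " (check that bounds are feasible)")
  }
  x <- res$soln[seq_len(n_met)] + lb
  B <- unname(res$soln[n_met + 1L] - M)
  conc <- setNames(exp(x), mets)
  dg <- vapply(pathway$reactions, driving_force, numeric(1),
               concentrations = conc, temperature_K = pathway$temperature_K)
  names(dg) <- colnames(S)
  flux <- vapply(pathway$reactions, `[[`, numeric(1), "flux")
  ref_conc <- setNames(rep(1e-3, n_met), mets)
  dg_ref <- vapply(pathway$reactions, driving_force, numeric(1),
                   concentrations = ref_conc,
                   temperature_K = pathway$temperature_K)
  sol <- structure(list(
    mdf_B = B,
    log_conc = setNames(x, mets),
    concentrations_M = conc,
    dg_prime = dg,
    cumulative = cumsum(flux * dg),
    reference_cumulative = cumsum(flux * dg_ref),
    conditions = list(pH = pathway$pH,
                      ionic_strength_mM = pathway$ionic_strength_mM,
                      temperature_K = pathway$temperature_K),
    status = "optimal"
  ), class = "mdf_solution")
  sol$bottlenecks <- identify_bottlenecks(sol, tol = bottleneck_tol)
  sol
}

#' @export
print.mdf_solution <- function(x, ...) {
  cat(sprintf("MDF solution: B = %.3f kJ/mol (%s)\n", x$mdf_B, x$status))
  cat("Per-reaction dG' (kJ/mol):\n")
  print(round(x$dg_prime, 3))
  cat("Bottlenecks:", paste(x$bottlenecks, collapse = ", "), "\n")
  invisible(x)
}

#' Reactions at the thermodynamic bottleneck
#'
#' Returns every reaction whose dG' lies within `tol` of `-B`, the binding
#' constraint of the max-min optimization. Ties are all reported: a pathway
#' can have several co-limiting reactions.
#'
#' @param solution An [solve_mdf()] result.
#' @param tol Tolerance in kJ/mol (default 0.1).
#' @return Character vector of reaction ids (never empty for a solved
#'   pathway).
#' @export
identify_bottlenecks <- function(solution, tol = 0.1) {
  stopifnot(inherits(solution, "mdf_solution"))
  if (!identical(solution$status, "optimal")) {
    stop("bottlenecks are defined only for a solved pathway")
  }
  names(solution$dg_prime)[solution$dg_prime >= -solution$mdf_B - tol]
}

#' Cumulative Gibbs-energy profile along a pathway
#'
#' Running (flux-weighted) sum of per-reaction dG' in pathway order, both at
#' the optimized concentrations and at the 1 mM reference used for
#' comparison profiles. The final cumulative value depends only on the net
#' pathway stoichiometry and the endpoint/cofactor concentrations.
#'
#' @param solution An [solve_mdf()] result.
#' @param pathway The [pathway_spec()] it was solved for.
#' @return A data.frame with `reaction_id`, `dg_prime`, `cumulative`,
#'   `reference_cumulative`.
#' @export
cumulative_profile <- function(solution, pathway) {
  stopifnot(inherits(solution, "mdf_solution"),
            inherits(pathway, "pathway_spec"))
  ids <- vapply(pathway$reactions, `[[`, character(1), "reaction_id")
  if (!identical(ids, names(solution$dg_prime))) {
    stop("solution does not correspond to this pathway")
  }
  data.frame(reaction_id = ids,
             dg_prime = unname(solution$dg_prime),
             cumulative = unname(solution$cumulative),
             reference_cumulative = unname(solution$reference_cumulative))
}

#' Flux-force efficacy of a reaction free energy
#'
#' For a reaction with free energy dG at temperature T, microscopic
#' reversibility ties the one-way fluxes to the driving force:
#' `J+/J- = exp(-dG/RT)`. The net fraction of gross flux is
#'
#' \deqn{\frac{J^+ - J^-}{J^+ + J^-} = \frac{e^{-dG/RT} - 1}{e^{-dG/RT} + 1}
#'   = \tanh\!\left(\frac{-dG}{2RT}\right)}
#'
#' A reaction at equilibrium (dG = 0) has net ratio 0; strongly negative dG
#' drives the ratio toward 1.
#'
#' @param dg_prime Reaction free energy (kJ/mol, vectorized).
#' @param temperature_K Temperature (K, > 0), default 298.15.
#' @return A data.frame with `forward_ratio` (`J+/(J+ + J-)`),
#'   `reverse_ratio`, `net_ratio`; `forward + reverse = 1` and
#'   `net = forward - reverse` to machine precision.
#' @export
#' @examples
#' flux_force(-2.97)$net_ratio  # ~0.536: barely half the gross flux is net
flux_force <- function(dg_prime, temperature_K = 298.15) {
  if (temperature_K <= 0) stop("temperature must be > 0")
  z <- -dg_prime / (R_KJ * temperature_K)
  forward <- stats::plogis(z)       # e^z / (1 + e^z), overflow-safe
  net <- tanh(z / 2)
  data.frame(forward_ratio = forward,
             reverse_ratio = 1 - forward,
             net_ratio = net)
}
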