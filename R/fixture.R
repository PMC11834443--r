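#' Packaged gluconeogenesis fixture: pathway and WT/mutant-like bounds
#'
#' Loads the synthetic 10-step gluconeogenesis pathway (2 pyruvate ->
#' glucose 6-phosphate: pyruvate carboxylase, PEP carboxykinase, enolase,
#' phosphoglycerate mutase, phosphoglycerate kinase, GAPDH, triosephosphate
#' isomerase, aldolase, FBPase, phosphoglucose isomerase) and constructs two
#' concentration-bound sets emulating a wild-type culture (large PEP pool)
#' and a dysregulated pyruvate-kinase mutant (PEP depleted 3.5-fold):
#'
#' * WT-like: PEP, ATP and ADP bounds at 40%, 100% and 40% of synthetic
#'   "measured" concentrations (PEP 2.8 mM, ATP 4 mM, ADP 0.6 mM); all
#'   other metabolites at the default 1 uM - 10 mM range.
#' * Mutant-like: built the way conservative mutant profiles are
#'   constructed when only relative data exist — every non-special
#'   metabolite is bounded at +/-40% of its WT MDF-optimized concentration,
#'   while PEP uses the depleted mutant level (0.8 mM, +/-40%) and ATP/ADP
#'   keep their measured-based bounds.
#'
#' The shipped standard Gibbs energies are documented placeholder values
#' (see the packaged TSV); conclusions drawn from this fixture are
#' qualitative orderings, not absolute MDF values.
#'
#' @return A list: `pathway` ([pathway_spec()]), `bounds_wt`,
#'   `bounds_mutant` ([concentration_bounds()]), `measured` (the synthetic
#'   measured concentrations, M), and `wt_solution` (the WT
#'   [solve_mdf()] solution the mutant bounds derive from).
#' @export
#' @examples
#' fx <- gluconeogenesis_fixture()
#' solve_mdf(fx$pathway, fx$bounds_wt)$mdf_B >
#'   solve_mdf(fx$pathway, fx$bounds_mutant)$mdf_B
gluconeogenesis_fixture <- function() {
  path <- system.file("extdata", "gluconeogenesis_pathway_synthetic.tsv",
                      package = "pepflux", mustWork = TRUE)
  pathway <- read_pathway_tsv(path)

  measured_wt <- c(pep = 2.8e-3, atp = 4e-3, adp = 0.6e-3)
  percent <- c(pep = 40, atp = 100, adp = 40)
  bounds_wt <- make_bounds_from_measured(measured_wt, percent,
                                         metabolites = pathway$metabolites)
  wt_sol <- solve_mdf(pathway, bounds_wt)

  measured_mut <- c(pep = measured_wt[["pep"]] / 3.5,
                    atp = 4e-3, adp = 0.6e-3)
  other <- setdiff(pathway$metabolites, names(measured_mut))
  derived <- wt_sol$concentrations_M[other]
  bounds_mutant <- make_bounds_from_measured(
    c(measured_mut, derived),
    c(percent, setNames(rep(40, length(derived)), names(derived)))
  )

  list(pathway = pathway,
       bounds_wt = bounds_wt,
       bounds_mutant = bounds_mutant,
       measured = list(wt = measured_wt, mutant = measured_mut),
       wt_solution = wt_sol)
}
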