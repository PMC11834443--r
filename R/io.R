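#' Read an initial-rate table
#'
#' Expects tab-separated columns `sample_id`, `pep_mM`, `r5p_mM`, `amp_mM`,
#' `atp_mM`, `adp_mM`, `rate`, `replicate`; missing effector columns are
#' treated as 0. R5P and AMP are alternative activators — whichever is
#' present (their sum) becomes `activator_mM`.
#'
#' @param path File path.
#' @return A [rate_observations()] data.frame.
#' @export
read_rate_table <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  if (!"rate" %in% names(df)) stop("rate table needs a 'rate' column")
  get0col <- function(nm) if (nm %in% names(df)) df[[nm]] else 0
  out <- data.frame(
    substrate_mM = get0col("pep_mM"),
    activator_mM = get0col("r5p_mM") + get0col("amp_mM"),
    inhibitor_mM = get0col("atp_mM"),
    adp_mM = get0col("adp_mM"),
    rate = df$rate,
    replicate_id = if ("replicate" %in% names(df)) df$replicate else "r1"
  )
  rate_observations(out)
}

#' Read absorbance traces
#'
#' Reads a CSV with columns `time_s`, `a340` (single trace) or
#' `well_id`, `time_s`, `a340` (long format, one trace per well).
#'
#' @param path File path.
#' @param pathlength_cm Optical path length applied to every trace.
#' @return A single [assay_trace()] or a named list of them.
#' @export
read_trace_csv <- function(path, pathlength_cm = 1) {
  df <- utils::read.csv(path)
  if (!all(c("time_s", "a340") %in% names(df))) {
    stop("trace file needs 'time_s' and 'a340' columns")
  }
  if ("well_id" %in% names(df)) {
    lapply(split(df, df$well_id), function(w) {
      assay_trace(w$time_s, w$a340, pathlength_cm = pathlength_cm)
    })
  } else {
    assay_trace(df$time_s, df$a340, pathlength_cm = pathlength_cm)
  }
}

#' Parse a reaction formula string
#'
#' Grammar: `+`-separated terms with optional integer coefficients on
#' either side of `=`, e.g. `"pyruvate + atp + hco3 = oaa + adp + pi"` or
#' `"2 pyruvate = ..."`. Left-hand species are consumed (negative
#' coefficients).
#'
#' @param formula Formula string.
#' @return Named numeric vector of signed stoichiometric coefficients.
#' @export
#' @examples
#' parse_reaction_formula("2 pg3 + 2 atp = 2 bpg + 2 adp")
parse_reaction_formula <- function(formula) {
  sides <- strsplit(formula, "=", fixed = TRUE)[[1]]
  if (length(sides) != 2L) stop("formula must contain exactly one '='")
  parse_side <- function(s, sign) {
    terms <- trimws(strsplit(s, "+", fixed = TRUE)[[1]])
    terms <- terms[nzchar(terms)]
    if (!length(terms)) stop("empty side in formula: ", formula)
    out <- numeric(0)
    for (tm in terms) {
      parts <- strsplit(tm, "[[:space:]]+")[[1]]
      if (length(parts) == 2L && grepl("^[0-9]+$", parts[1])) {
        out <- c(out, setNames(sign * as.numeric(parts[1]), parts[2]))
      } else if (length(parts) == 1L) {
        out <- c(out, setNames(sign, parts))
      } else {
        stop("cannot parse term '", tm, "' in formula: ", formula)
      }
    }
    out
  }
  both <- c(parse_side(sides[1], -1), parse_side(sides[2], +1))
  mets <- unique(names(both))
  vapply(mets, function(m) sum(both[names(both) == m]), numeric(1))
}

#' Read a pathway definition table
#'
#' Tab-separated columns: `reaction_id`, `formula` (see
#' [parse_reaction_formula()]), `dg0_prime_kj_mol`, and optionally `flux`.
#'
#' @param path File path.
#' @param pH,ionic_strength_mM,temperature_K Conditions recorded on the
#'   resulting [pathway_spec()].
#' @return A [pathway_spec()].
#' @export
read_pathway_tsv <- function(path, pH = 7, ionic_strength_mM = 250,
                             temperature_K = 298.15) {
  df <- read.delim(path, comment.char = "#")
  need <- c("reaction_id", "formula", "dg0_prime_kj_mol")
  if (!all(need %in% names(df))) {
    stop("pathway table needs columns: ", paste(need, collapse = ", "))
  }
  reactions <- lapply(seq_len(nrow(df)), function(i) {
    reaction_spec(df$reaction_id[i],
                  parse_reaction_formula(df$formula[i]),
                  df$dg0_prime_kj_mol[i],
                  flux = if ("flux" %in% names(df)) df$flux[i] else 1)
  })
  pathway_spec(reactions, pH = pH, ionic_strength_mM = ionic_strength_mM,
               temperature_K = temperature_K)
}

#' Read metabolite concentration bounds
#'
#' Tab-separated with either explicit bounds (`metabolite`, `lb_M`, `ub_M`)
#' or measured concentrations plus a percent range (`metabolite`,
#' `measured_M`, `percent_range`), converted via
#' [make_bounds_from_measured()].
#'
#' @param path File path.
#' @param ... Passed to [make_bounds_from_measured()] in measured mode.
#' @return A [concentration_bounds()].
#' @export
read_bounds_tsv <- function(path, ...) {
  df <- read.delim(path, comment.char = "#")
  if (all(c("lb_M", "ub_M") %in% names(df))) {
    concentration_bounds(setNames(df$lb_M, df$metabolite),
                         setNames(df$ub_M, df$metabolite))
  } else if (all(c("measured_M", "percent_range") %in% names(df))) {
    make_bounds_from_measured(setNames(df$measured_M, df$metabolite),
                              setNames(df$percent_range, df$metabolite), ...)
  } else {
    stop("bounds table needs (lb_M, ub_M) or (measured_M, percent_range)")
  }
}

#' Read an isotopologue ion-count table
#'
#' Tab-separated columns: `sample_id`, `condition`, `metabolite`,
#' `mass_shift` (0 = M0), `ion_count`. Each sample x metabolite block
#' becomes one distribution; mass shifts absent from the file are zero.
#'
#' @param path File path.
#' @param carbon_counts Optional named vector of carbon counts; defaults to
#'   [proxy_metabolite_carbons()] plus the maximum observed shift.
#' @return List of [isotopologue_distribution()] objects.
#' @export
read_isotopologue_tsv <- function(path, carbon_counts = NULL) {
  df <- read.delim(path)
  need <- c("sample_id", "condition", "metabolite", "mass_shift", "ion_count")
  if (!all(need %in% names(df))) {
    stop("isotopologue table needs columns: ", paste(need, collapse = ", "))
  }
  carbon_counts <- carbon_counts %||% proxy_metabolite_carbons()
  blocks <- split(df, list(df$sample_id, df$metabolite), drop = TRUE)
  lapply(unname(blocks), function(b) {
    m <- b$metabolite[1L]
    nC <- if (m %in% names(carbon_counts)) carbon_counts[[m]] else max(b$mass_shift)
    counts <- numeric(nC + 1L)
    counts[b$mass_shift + 1L] <- b$ion_count
    isotopologue_distribution(m, counts, nC, b$sample_id[1L], b$condition[1L])
  })
}

#' Read a metabolome ion-count table with sample metadata
#'
#' @param counts_path TSV with `sample_id`, `metabolite`, `ion_count` and
#'   optional `is_count`.
#' @param meta_path TSV with `sample_id`, `od600` and optional `condition`,
#'   `replicate`, `carbon_source`.
#' @return A list with elements `table` and `meta`, ready for
#'   [normalize_counts()].
#' @export
read_metabolome_tsv <- function(counts_path, meta_path) {
  list(table = read.delim(counts_path), meta = read.delim(meta_path))
}
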