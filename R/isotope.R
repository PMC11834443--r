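#' Mass-isotopologue distribution of one metabolite in one sample
#'
#' Ion counts for the M0..Mn mass shifts of a metabolite after an isotope
#' labeling experiment (e.g. growth on \[1-13C\]pyruvate). M0 is the fully
#' unlabeled species; `M0 / total` is the unlabeled fraction used as an in
#' vivo readout of pyruvate kinase activity.
#'
#' @param metabolite Metabolite name.
#' @param counts Numeric vector of ion counts for M0..Mn, all >= 0. Its
#'   length must be `carbon_count + 1`.
#' @param carbon_count Number of carbons (defaults to `length(counts) - 1`).
#' @param sample_id,condition Sample labels (e.g. condition `"WT"` or
#'   `"mutant"`).
#' @return An object of class `isotopologue_distribution`.
#' @export
isotopologue_distribution <- function(metabolite, counts,
                                      carbon_count = length(counts) - 1L,
                                      sample_id = "s1", condition = "WT") {
  if (length(counts) != carbon_count + 1L) {
    stop("counts must have carbon_count + 1 entries (M0..Mn)")
  }
  if (carbon_count < 1L) stop("carbon_count must be >= 1")
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("ion counts must be finite and >= 0")
  }
  structure(list(metabolite = metabolite, carbon_count = carbon_count,
                 counts = as.numeric(counts), sample_id = sample_id,
                 condition = condition),
            class = "isotopologue_distribution")
}

#' Unlabeled (M0) fraction of an isotopologue distribution
#'
#' @param d An [isotopologue_distribution()] (or a bare counts vector with
#'   M0 first).
#' @return `M0 / sum(counts)`, in `[0, 1]`.
#' @export
#' @examples
#' unlabeled_fraction(c(50, 50))  # 0.5
unlabeled_fraction <- function(d) {
  counts <- if (inherits(d, "isotopologue_distribution")) d$counts else d
  total <- sum(counts)
  if (total <= 0) stop("cannot compute a fraction from all-zero counts")
  counts[1L] / total
}

# Convolution matrix: column j (true shift j-1) spread over observed shifts
# by natural 13C on the remaining unlabeled carbons.
na_convolution_matrix <- function(carbon_count, p13C) {
  n <- carbon_count
  C <- matrix(0, n + 1L, n + 1L)
  for (j in 0:n) {
    k <- j:n
    C[k + 1L, j + 1L] <- dbinom(k - j, n - j, p13C)
  }
  C
}

#' Correct an isotopologue distribution for natural 13C abundance
#'
#' Inverts the binomial convolution by which natural-abundance 13C on
#' unlabeled carbon positions shifts signal from Mj to Mj+1, Mj+2, ...
#' Small negative corrected counts are clipped to zero (and flagged via the
#' `"clipped"` attribute). With `p13C = 0` the input is returned unchanged.
#' Raw (uncorrected) ratios are the package default elsewhere; apply this
#' only when an analysis calls for abundance-corrected fractions.
#'
#' @param d An [isotopologue_distribution()].
#' @param p13C Natural 13C probability per carbon, in `[0, 0.5)`; default
#'   0.0107.
#' @return A corrected [isotopologue_distribution()].
#' @export
natural_abundance_correction <- function(d, p13C = 0.0107) {
  stopifnot(inherits(d, "isotopologue_distribution"))
  if (p13C < 0 || p13C >= 0.5) stop("p13C must be in [0, 0.5)")
  if (p13C == 0) return(d)
  C <- na_convolution_matrix(d$carbon_count, p13C)
  corrected <- tryCatch(solve(C, d$counts), error = function(e) {
    stop("natural-abundance correction matrix is singular for p13C = ", p13C)
  })
  clipped <- any(corrected < -sqrt(.Machine$double.eps) * sum(d$counts))
  corrected <- pmax(corrected, 0)
  out <- isotopologue_distribution(d$metabolite, corrected, d$carbon_count,
                                   d$sample_id, d$condition)
  attr(out, "clipped") <- clipped
  out
}

#' Summarize unlabeled fractions by metabolite and condition
#'
#' Computes the mean and standard error of the unlabeled fraction across
#' replicates for each metabolite x condition group. Replicates with zero
#' total counts are dropped with a warning (a missing measurement, not a
#' fraction of 0).
#'
#' @param ds List of [isotopologue_distribution()] objects.
#' @return A data.frame (`metabolite`, `condition`,
#'   `mean_unlabeled_fraction`, `sem`, `n`) ordered by metabolite then
#'   condition. `sem` is 0 when `n = 1`.
#' @export
summarize_labeling <- function(ds) {
  stopifnot(length(ds) >= 1L,
            all(vapply(ds, inherits, logical(1), "isotopologue_distribution")))
  totals <- vapply(ds, function(d) sum(d$counts), numeric(1))
  if (any(totals <= 0)) {
    warning(sum(totals <= 0), " replicate(s) with zero total counts excluded")
    ds <- ds[totals > 0]
    if (!length(ds)) stop("no usable replicates remain")
  }
  df <- data.frame(
    metabolite = vapply(ds, `[[`, character(1), "metabolite"),
    condition = vapply(ds, `[[`, character(1), "condition"),
    fraction = vapply(ds, unlabeled_fraction, numeric(1))
  )
  groups <- split(df, list(df$metabolite, df$condition), drop = TRUE)
  out <- do.call(rbind, lapply(groups, function(g) {
    n <- nrow(g)
    data.frame(metabolite = g$metabolite[1L], condition = g$condition[1L],
               mean_unlabeled_fraction = mean(g$fraction),
               sem = if (n > 1L) sd(g$fraction) / sqrt(n) else 0,
               n = n)
  }))
  out <- out[order(out$metabolite, out$condition), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Carbon counts of the proxy metabolites used in labeling readouts
#'
#' Alanine (3 C) and valine (5 C) carbon backbones derive entirely from
#' pyruvate, so their labeling proxies intracellular pyruvate labeling.
#'
#' @return Named integer vector of carbon counts, extensible by the caller.
#' @export
proxy_metabolite_carbons <- function() {
  c(pyruvate = 3L, pep = 3L, alanine = 3L, valine = 5L)
}
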