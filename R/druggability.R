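#' Default Lipinski rule-of-five thresholds
#'
#' MW <= 500 Da, H-bond donors <= 5, H-bond acceptors <= 10, AlogP <= 5.
#' Equality at a threshold is not a violation; a compound violating two or
#' more criteria is deemed unlikely to be orally active.
#'
#' @export
lipinski_criteria <- function() {
  c(mw = 500, hbd = 5, hba = 10, alogp = 5)
}

#' Count Lipinski rule-of-five violations
#'
#' @param record one-row [compound_catalog] slice, or any list/data frame
#'   with `mw`, `alogp`, `hbd`, `hba` fields (vectors allowed: violations
#'   are counted element-wise).
#' @param criteria named upper bounds, see [lipinski_criteria()].
#' @return integer vector of violation counts in 0--4; `NA` where any of
#'   the four descriptors is missing (an indeterminate record is never
#'   silently counted as pass or fail).
#' @export
lipinski_violations <- function(record, criteria = lipinski_criteria()) {
  stopifnot(all(c("mw", "hbd", "hba", "alogp") %in% names(criteria)))
  v <- (record$mw    > criteria["mw"])  +
       (record$hbd   > criteria["hbd"]) +
       (record$hba   > criteria["hba"]) +
       (record$alogp > criteria["alogp"])
  as.integer(v)
}

#' Tanimoto drug-likeness index between descriptor vectors
#'
#' Computes `F(A, B) = (A.B) / (A.A + B.B - A.B)` where `A` is a compound's
#' molecular property vector and `B` a reference profile (the average
#' property vector of a drug collection). Equals 1 iff `A == B`; lies in
#' \[0, 1\] for non-negative vectors. The index is scale-sensitive:
#' rescaling one vector changes it (it is not a cosine).
#'
#' @param a numeric descriptor vector of the compound.
#' @param b numeric reference profile, same length and property order.
#' @return the drug-likeness index, a single number.
#' @export
druglikeness_tanimoto <- function(a, b) {
  if (length(a) != length(b))
    stop_usage("descriptor vector and reference profile differ in length (",
               length(a), " vs ", length(b), ")")
  if (!all(is.finite(a)) || !all(is.finite(b)))
    stop_usage("descriptor vectors must be finite")
  ab <- sum(a * b)
  den <- sum(a * a) + sum(b * b) - ab
  if (den <= 0) stop_usage("degenerate descriptor vectors: zero denominator")
  ab / den
}

#' Read a reference descriptor profile
#'
#' Two-column TSV (`property`, `mean`) giving the average molecular
#' properties of a reference drug collection; the row order defines the
#' property order that compound descriptor vectors must follow. The profile
#' shipped with the package (`reference_profile_synthetic.tsv`) is a
#' synthetic stand-in with plausible magnitudes, not derived from any drug
#' database.
#'
#' @param path TSV path; default is the shipped synthetic profile.
#' @return named numeric vector of property means.
#' @export
read_reference_profile <- function(path = system.file("extdata",
                                     "reference_profile_synthetic.tsv",
                                     package = "netpharm")) {
  df <- utils::read.table(path, sep = "\t", header = TRUE)
  stats::setNames(as.numeric(df$mean), df$property)
}

#' Screen a catalog for druggable compounds
#'
#' Applies the three-part druggability screen: Lipinski's rule (at most
#' `max_violations` violations), oral bioavailability `ob >= ob_min`, and
#' drug-likeness `dl >= dl_min`. All comparisons are inclusive. Records
#' missing any required descriptor are indeterminate: excluded from the
#' retained set and flagged, never silently passed or failed.
#'
#' @param catalog a [compound_catalog].
#' @param ob_min minimum oral bioavailability, percent (default 30).
#' @param dl_min minimum drug-likeness index (default 0.18).
#' @param max_violations maximum tolerated Lipinski violations (default 1).
#' @param criteria Lipinski thresholds, see [lipinski_criteria()].
#' @return list with `retained` (the passing [compound_catalog]) and
#'   `verdicts`, a data frame with one row per input record:
#'   `compound_id`, `lipinski_violations`, `lipinski_pass`, `ob_pass`,
#'   `dl_pass`, `overall_pass`, `indeterminate`.
#' @export
screen_druggable <- function(catalog, ob_min = 30, dl_min = 0.18,
                             max_violations = 1,
                             criteria = lipinski_criteria()) {
  stopifnot(inherits(catalog, "compound_catalog"))
  viol <- lipinski_violations(catalog, criteria)
  lr <- viol <= max_violations
  obp <- catalog$ob >= ob_min
  dlp <- catalog$dl >= dl_min
  indeterminate <- is.na(lr) | is.na(obp) | is.na(dlp)
  overall <- !indeterminate & lr & obp & dlp
  verdicts <- data.frame(
    compound_id = catalog$compound_id,
    lipinski_violations = viol,
    lipinski_pass = lr, ob_pass = obp, dl_pass = dlp,
    overall_pass = overall, indeterminate = indeterminate,
    stringsAsFactors = FALSE)
  list(retained = new_compound_catalog(catalog[overall, , drop = FALSE]),
       verdicts = verdicts)
}

#' Per-herb druggability summary table
#'
#' For each herb: total records, count and percentage passing Lipinski's
#' rule, count and percentage with OB and DL above threshold, and count and
#' percentage passing all criteria. Percentages are `100 * count / total`
#' rounded half-away-from-zero to one decimal; a herb with zero compounds
#' gets a zero row (percentage 0.0, no division error). Operates on
#' herb-level records, so run [expand_herbs()] first if records carry
#' multiple herbs.
#'
#' @param catalog herb-level [compound_catalog].
#' @param verdicts verdict data frame from [screen_druggable()] run on the
#'   same catalog (row-aligned).
#' @return data frame with columns `herb`, `n_compounds`, `n_lipinski`,
#'   `pct_lipinski`, `n_ob_dl`, `pct_ob_dl`, `n_all`, `pct_all`.
#' @export
herb_summary <- function(catalog, verdicts) {
  stopifnot(inherits(catalog, "compound_catalog"),
            nrow(catalog) == nrow(verdicts))
  herbs <- catalog$herbs
  if (any(grepl(";", herbs)))
    stop_usage("herb_summary needs herb-level records; call expand_herbs() first")
  pct <- function(n, total) ifelse(total == 0, 0, round_half_away(100 * n / total, 1))
  agg <- function(flag) as.integer(tapply(flag, herbs, sum, default = 0L))
  levels <- sort(unique(herbs))
  herbs <- factor(herbs, levels = levels)
  total <- as.integer(table(herbs))
  n_lr <- agg(verdicts$lipinski_pass %in% TRUE)
  n_obdl <- agg((verdicts$ob_pass & verdicts$dl_pass) %in% TRUE)
  n_all <- agg(verdicts$overall_pass)
  data.frame(herb = levels, n_compounds = total,
             n_lipinski = n_lr, pct_lipinski = pct(n_lr, total),
             n_ob_dl = n_obdl, pct_ob_dl = pct(n_obdl, total),
             n_all = n_all, pct_all = pct(n_all, total),
             row.names = NULL, stringsAsFactors = FALSE)
}
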