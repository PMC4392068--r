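# Bundled reference counts from a published nationwide 1133-trio diagnostic
# sequencing study of undiagnosed developmental disorders. These are inputs
# for validating the bookkeeping arithmetic of the report module: the
# package recomputes totals, predictive values and yields from them rather
# than asserting any published rate directly.

#' Published per-mechanism flagged-variant counts (1133-trio reference cohort)
#'
#' SNV/indel candidates flagged by the clinical reporting workflow of a
#' published 1133-trio developmental-disorder study, per allelic-requirement
#' category, split into family-trio (inherited / de novo) and proband-only
#' analysis columns.
#'
#' @return Tibble with columns `category`, `trio_inherited`, `trio_de_novo`,
#'   `proband_only`.
#' @export
reference_flag_counts <- function() {
  readr::read_tsv(
    system.file("extdata", "reference_flag_counts.tsv",
                package = "triotriage", mustWork = TRUE),
    show_col_types = FALSE, progress = FALSE)
}

#' Published review/reported counts by variant class (reference cohort)
#'
#' Candidates manually reviewed (split into SNV/indel and CNV counts) and
#' reported as likely diagnostic, per variant class, from the same reference
#' cohort. Chromosomal-event classes (uniparental disomy, mosaicism) carry
#' reported findings only; they were detected outside the automated flag and
#' have no reviewed-candidate count.
#'
#' @return Tibble with columns `variant_class`, `inheritance_class`,
#'   `reviewed_snv`, `reviewed_cnv`, `reported`.
#' @export
reference_review_counts <- function() {
  readr::read_tsv(
    system.file("extdata", "reference_review_counts.tsv",
                package = "triotriage", mustWork = TRUE),
    show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      variant_class = readr::col_character(),
      inheritance_class = readr::col_character(),
      reviewed_snv = readr::col_integer(),
      reviewed_cnv = readr::col_integer(),
      reported = readr::col_integer()))
}

#' Expand the reference review counts to candidate-level outcomes
#'
#' Builds a candidate-level review-outcome table consistent with the
#' published class-level counts, for exercising [review_cohort()]: one row
#' per reviewed candidate (plus one per reported chromosomal event), with
#' `decision = "reported"` for the reported count in each class. Reported
#' findings are distributed over probands to match the published cohort
#' structure, in which `two_finding_probands` probands received two
#' contributory findings and every other diagnosed proband received one.
#'
#' @param counts Class-level count tibble, by default
#'   [reference_review_counts()].
#' @param cohort_size Number of probands (default 1133).
#' @param two_finding_probands Number of probands with two reported findings
#'   (default 17, the published cohort structure).
#' @return Outcome tibble suitable for [review_cohort()].
#' @export
reference_review_outcomes <- function(counts = reference_review_counts(),
                                      cohort_size = 1133L,
                                      two_finding_probands = 17L) {
  rows <- lapply(seq_len(nrow(counts)), function(i) {
    cl <- counts[i, ]
    n_snv <- ifelse(is.na(cl$reviewed_snv), 0L, cl$reviewed_snv)
    n_cnv <- ifelse(is.na(cl$reviewed_cnv), 0L, cl$reviewed_cnv)
    reviewed_types <- c(rep("snv", n_snv), rep("cnv", n_cnv))
    n_rep <- cl$reported
    if (length(reviewed_types)) {
      tibble::tibble(
        variant_class = cl$variant_class,
        inheritance_class = cl$inheritance_class,
        variant_type = reviewed_types,
        decision = c(rep("reported", n_rep),
                     rep("not_reported", length(reviewed_types) - n_rep)))
    } else {
      # chromosomal events: reported findings only
      tibble::tibble(
        variant_class = cl$variant_class,
        inheritance_class = cl$inheritance_class,
        variant_type = cl$variant_class,
        decision = rep("reported", n_rep))
    }
  })
  out <- dplyr::bind_rows(rows)
  out$candidate_id <- sprintf("cand%05d", seq_len(nrow(out)))
  # assign probands: reported findings first, so that exactly
  # `two_finding_probands` probands carry two findings and the remaining
  # reported findings land on distinct probands
  n_reported <- sum(out$decision == "reported")
  n_single <- n_reported - 2L * two_finding_probands
  reported_probands <- c(
    rep(sprintf("P%04d", seq_len(two_finding_probands)), each = 2L),
    sprintf("P%04d", two_finding_probands + seq_len(n_single)))
  out$proband_id <- NA_character_
  out$proband_id[out$decision == "reported"] <- reported_probands
  # unreported candidates cycle over the cohort
  n_un <- sum(out$decision != "reported")
  out$proband_id[out$decision != "reported"] <-
    sprintf("P%04d", rep_len(seq_len(cohort_size), n_un))
  out
}
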