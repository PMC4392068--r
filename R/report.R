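# Cohort-level bookkeeping: flagged-count tables by genetic mechanism,
# review outcomes, predictive value and diagnostic yield.

snv_categories <- function() {
  c("autosomal_dominant", "autosomal_recessive_homozygous",
    "autosomal_recessive_compound_het", "x_linked_dominant",
    "x_linked_recessive")
}

# Nearest-integer rounding, half away from zero (base round() is
# round-half-even, which does not match clinical-table conventions).
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Predictive value of the variant flag
#'
#' The probability that a flagged (reviewed) candidate was reported as
#' likely diagnostic, as a nearest-integer percentage.
#'
#' @param reviewed Number of candidates reviewed.
#' @param reported Number reported as likely diagnostic (`<= reviewed`).
#' @return Integer-valued percentage, or `NA` when nothing was reviewed.
#' @export
predictive_value <- function(reviewed, reported) {
  stopifnot(all(is.na(reviewed) | is.na(reported) | reported <= reviewed))
  ifelse(is.na(reviewed) | reviewed == 0, NA_real_,
         round_half_up(100 * reported / reviewed))
}

#' Diagnostic yield
#'
#' Contribution of a variant class to the cohort's diagnostic yield, as a
#' percentage of the cohort size: nearest integer, or one decimal place for
#' classes contributing less than 1%.
#'
#' @param diagnosed_count Number of diagnoses attributed to the class.
#' @param cohort_size Number of probands in the cohort.
#' @return Numeric percentage.
#' @export
diagnostic_yield <- function(diagnosed_count, cohort_size) {
  if (any(cohort_size <= 0)) stop("cohort_size must be positive", call. = FALSE)
  stopifnot(all(diagnosed_count <= cohort_size))
  pct <- 100 * diagnosed_count / cohort_size
  ifelse(pct >= 1, round_half_up(pct), round_half_up(pct, 1))
}

# one counting unit ("event") per flagged candidate; compound-het events are
# additionally collapsed to one per (proband, gene).
candidate_events <- function(candidates) {
  if (!nrow(candidates)) {
    return(tibble::tibble(proband_id = character(0), category = character(0),
                          gene = character(0), event_id = character(0),
                          de_novo = logical(0)))
  }
  ev <- dplyr::summarise(
    dplyr::group_by(candidates, .data$proband_id, .data$category,
                    .data$gene, .data$event_id),
    de_novo = any(.data$inheritance == "de_novo"),
    .groups = "drop")
  comphet <- ev$category == "autosomal_recessive_compound_het" |
    (ev$category == "x_linked_recessive" &
       grepl("|pair|", ev$event_id, fixed = TRUE))
  ev_ch <- ev[comphet, , drop = FALSE]
  if (nrow(ev_ch)) {
    ev_ch <- dplyr::summarise(
      dplyr::group_by(ev_ch, .data$proband_id, .data$category, .data$gene),
      event_id = min(.data$event_id),
      de_novo = any(.data$de_novo),
      .groups = "drop")
  }
  dplyr::bind_rows(ev[!comphet, , drop = FALSE], ev_ch)
}

#' Summarise flagged SNV/indel candidates by genetic mechanism
#'
#' Counts flagged events per allelic-requirement category. In trio mode the
#' counts are split into inherited and de novo columns; in proband-only mode
#' a single `flagged` column is produced. Compound-heterozygote events are
#' counted once per gene per proband; an event is de novo when any member of
#' it is de novo. CNV candidates are excluded (see
#' [summarize_cnv_flags()]).
#'
#' @param candidates Candidate tibble from [triage_cohort()].
#' @param mode `"trio"` or `"proband_only"`.
#' @return Tibble with one row per mechanism category (all five always
#'   present) plus count columns.
#' @export
summarize_flags <- function(candidates, mode = c("trio", "proband_only")) {
  mode <- match.arg(gsub("-", "_", mode), c("trio", "proband_only"))
  ev <- candidate_events(
    candidates[candidates$category %in% snv_categories(), , drop = FALSE])
  skeleton <- tibble::tibble(category = snv_categories())
  if (mode == "trio") {
    counts <- dplyr::summarise(
      dplyr::group_by(ev, .data$category),
      inherited = sum(!.data$de_novo),
      de_novo = sum(.data$de_novo),
      .groups = "drop")
    out <- dplyr::left_join(skeleton, counts, by = "category")
    out$inherited[is.na(out$inherited)] <- 0L
    out$de_novo[is.na(out$de_novo)] <- 0L
  } else {
    counts <- dplyr::count(ev, .data$category, name = "flagged")
    out <- dplyr::left_join(skeleton, counts, by = "category")
    out$flagged[is.na(out$flagged)] <- 0L
  }
  out
}

#' Column totals for a flag-count table
#'
#' @param counts Per-category count tibble (e.g. from [summarize_flags()] or
#'   [reference_flag_counts()]).
#' @return One-row tibble with `category = "total"` and the sum of every
#'   numeric column.
#' @export
flag_totals <- function(counts) {
  totals <- dplyr::summarise(counts, dplyr::across(dplyr::where(is.numeric),
                                                   ~ sum(.x, na.rm = TRUE)))
  dplyr::bind_cols(tibble::tibble(category = "total"), totals)
}

#' Summarise flagged copy-number candidates
#'
#' @param candidates Candidate tibble from [triage_cohort()].
#' @param n_probands Cohort size for the per-proband rate.
#' @return Tibble with per-route counts (`cnv_panel`, `cnv_size_rule`) and
#'   the mean flagged CNVs per proband.
#' @export
summarize_cnv_flags <- function(candidates, n_probands) {
  cnv <- candidates[candidates$payload_type == "cnv", , drop = FALSE]
  ev <- dplyr::distinct(cnv, .data$category, .data$event_id)
  counts <- dplyr::count(ev, .data$category, name = "flagged")
  skeleton <- tibble::tibble(category = c("cnv_panel", "cnv_size_rule"))
  out <- dplyr::left_join(skeleton, counts, by = "category")
  out$flagged[is.na(out$flagged)] <- 0L
  out$per_proband <- out$flagged / n_probands
  out
}

#' Read review outcomes from TSV
#'
#' The manual multidisciplinary review is out of scope for the automated
#' workflow; its decisions arrive as a table with one row per reviewed
#' candidate: `candidate_id`, `proband_id`, `variant_class`,
#' `inheritance_class`, `variant_type`, `decision`
#' (`reported`/`not_reported`), `reviewer_note`.
#'
#' @param path TSV path.
#' @return Tibble of review outcomes.
#' @export
read_review_outcomes <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(.default = readr::col_character()))
}

#' Cohort summary from candidate-level review outcomes
#'
#' Computes, per variant class and overall: candidates reviewed, candidates
#' reported as likely diagnostic, the predictive value of the flag, and the
#' diagnostic yield. The overall yield counts distinct diagnosed probands
#' (a proband with two reported findings is one diagnosis), while per-class
#' yields count reported findings. Rows whose `variant_type` is neither
#' `snv` nor `cnv` (e.g. uniparental disomy, mosaicism) contribute reported
#' findings but are not part of the reviewed flag count.
#'
#' @param outcomes Outcome tibble (see [read_review_outcomes()]) with
#'   columns `proband_id`, `variant_class`, `inheritance_class`,
#'   `variant_type` and `decision`.
#' @param cohort_size Number of probands in the cohort.
#' @return Object of class `cohort_summary`; see [tidy.cohort_summary()] and
#'   [glance.cohort_summary()].
#' @export
review_cohort <- function(outcomes, cohort_size) {
  o <- tibble::as_tibble(outcomes)
  o$reported <- o$decision == "reported"
  o$reviewed <- o$variant_type %in% c("snv", "cnv")
  by_class <- dplyr::summarise(
    dplyr::group_by(o, .data$variant_class, .data$inheritance_class),
    reviewed = sum(.data$reviewed),
    reported = sum(.data$reported),
    .groups = "drop")
  by_class$predictive_value <- predictive_value(
    ifelse(by_class$reviewed == 0, NA_integer_, by_class$reviewed),
    by_class$reported)
  by_class$diagnostic_yield <- ifelse(
    by_class$reported == 0, NA_real_,
    diagnostic_yield(by_class$reported, cohort_size))

  reported_rows <- o[o$reported, , drop = FALSE]
  per_proband <- dplyr::count(reported_rows, .data$proband_id)
  diagnosed <- nrow(per_proband)
  two_finding <- sum(per_proband$n >= 2)
  structure(list(
    by_class = by_class,
    cohort_size = cohort_size,
    reviewed_total = sum(o$reviewed),
    reported_total = sum(o$reported),
    reported_variant_total = sum(o$reported & o$reviewed),
    de_novo_reported = sum(o$reported & o$inheritance_class == "de_novo"),
    diagnosed_probands = diagnosed,
    two_finding_probands = two_finding,
    predictive_value_overall = predictive_value(sum(o$reviewed),
                                                sum(o$reported)),
    diagnostic_yield_overall = diagnostic_yield(diagnosed, cohort_size)
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf(
    "<cohort_summary> %d probands: %d candidates reviewed, %d reported\n",
    x$cohort_size, x$reviewed_total, x$reported_total))
  cat(sprintf(
    "  predictive value %s%%, diagnostic yield %s%% (%d diagnosed probands, %d with two findings)\n",
    format(x$predictive_value_overall), format(x$diagnostic_yield_overall),
    x$diagnosed_probands, x$two_finding_probands))
  print(x$by_class, ...)
  invisible(x)
}

#' Tidy a cohort summary
#'
#' @param x A `cohort_summary`.
#' @param ... Unused.
#' @return Per-class tibble with reviewed/reported counts, predictive value
#'   and diagnostic yield.
#' @export
tidy.cohort_summary <- function(x, ...) {
  x$by_class
}

#' One-row glance at a cohort summary
#'
#' @param x A `cohort_summary`.
#' @param ... Unused.
#' @return One-row tibble with the overall totals and rates.
#' @export
glance.cohort_summary <- function(x, ...) {
  tibble::tibble(
    cohort_size = x$cohort_size,
    reviewed_total = x$reviewed_total,
    reported_total = x$reported_total,
    reported_variant_total = x$reported_variant_total,
    de_novo_reported = x$de_novo_reported,
    diagnosed_probands = x$diagnosed_probands,
    two_finding_probands = x$two_finding_probands,
    predictive_value = x$predictive_value_overall,
    diagnostic_yield = x$diagnostic_yield_overall)
}

#' Write reporting records for reported candidates
#'
#' One row per reported candidate with the reporting tuple used for
#' clinical feedback: chromosome, position, gene(s), allele (ref/alt, or
#' CNV loss/gain), genotype, inheritance and most severe predicted
#' consequence, plus the triage category and the shared event identifier
#' (both members of a compound-het pair are reported together under one
#' event). Deterministically ordered.
#'
#' @param candidates Candidate tibble from [triage_cohort()].
#' @param outcomes Tibble with `event_id` and `decision` columns (candidates
#'   without an outcome default to not reported).
#' @param path Output TSV path.
#' @return The written tibble, invisibly.
#' @export
write_report_records <- function(candidates, outcomes, path) {
  decisions <- outcomes$decision[match(candidates$event_id,
                                       outcomes$event_id)]
  rep_rows <- candidates[!is.na(decisions) & decisions == "reported", ,
                         drop = FALSE]
  out <- tibble::tibble(
    event_id = rep_rows$event_id,
    proband_id = rep_rows$proband_id,
    chromosome = rep_rows$chromosome,
    position = rep_rows$position,
    gene = rep_rows$gene,
    allele = ifelse(rep_rows$payload_type == "cnv", rep_rows$alt,
                    paste0(rep_rows$ref, ">", rep_rows$alt)),
    genotype = rep_rows$genotype,
    inheritance = rep_rows$inheritance,
    most_severe_consequence = rep_rows$consequence,
    category = rep_rows$category,
    phenotype_note = rep_rows$phenotype_note)
  out <- out[order(out$proband_id, chrom_rank(out$chromosome), out$position,
                   out$event_id), , drop = FALSE]
  readr::write_tsv(out, path, progress = FALSE, na = "")
  invisible(out)
}
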