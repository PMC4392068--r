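test_that("predictive value and diagnostic yield follow the clinical rounding rules", {
  expect_equal(predictive_value(1696, 328), 19)
  expect_equal(predictive_value(528, 27), 5)
  expect_equal(predictive_value(10, 10), 100)
  expect_true(is.na(predictive_value(0, 0)))
  expect_equal(diagnostic_yield(311, 1133), 27)
  expect_equal(diagnostic_yield(184, 1133), 16)
  expect_equal(diagnostic_yield(6, 1133), 0.5)  # sub-1% to one decimal
  expect_error(diagnostic_yield(1, 0), "positive")
})

test_that("flag summaries equal an independent recount of the candidate list", {
  co <- simulate_cohort(small_params(
    30, seed = 21,
    spike_in = c(de_novo_dominant = 4, compound_het_trans = 3,
                 recessive_hom = 2)))
  cand <- triage_cohort(co$variants, co$pedigree, co$panel, NULL,
                        filter_config(mode = "trio"))
  tbl <- summarize_flags(cand, "trio")
  # brute-force recount: one unit per event, compound hets once per gene
  snv <- cand[cand$payload_type != "cnv", ]
  recount <- function(cat, dn) {
    rows <- snv[snv$category == cat, ]
    if (cat == "autosomal_recessive_compound_het") {
      keys <- unique(paste(rows$proband_id, rows$gene))
      dn_keys <- unique(paste(rows$proband_id, rows$gene)[
        rows$inheritance == "de_novo"])
      if (dn) length(dn_keys) else length(setdiff(keys, dn_keys))
    } else {
      ev <- unique(rows$event_id)
      dn_ev <- unique(rows$event_id[rows$inheritance == "de_novo"])
      if (dn) length(dn_ev) else length(setdiff(ev, dn_ev))
    }
  }
  for (cat in tbl$category) {
    expect_equal(tbl$de_novo[tbl$category == cat], recount(cat, TRUE),
                 label = paste(cat, "de novo"))
    expect_equal(tbl$inherited[tbl$category == cat], recount(cat, FALSE),
                 label = paste(cat, "inherited"))
  }
  # empty cohort: all zeros
  empty <- summarize_flags(cand[0, ], "trio")
  expect_true(all(empty$inherited == 0) && all(empty$de_novo == 0))
})

test_that("grand totals are invariant to proband processing order", {
  co <- simulate_cohort(small_params(20, seed = 31))
  cand <- triage_cohort(co$variants, co$pedigree, co$panel, NULL,
                        filter_config(mode = "trio"))
  shuffled <- cand[sample(nrow(cand)), ]
  expect_equal(flag_totals(summarize_flags(cand, "trio")),
               flag_totals(summarize_flags(shuffled, "trio")))
})

test_that("review bookkeeping derives the published cohort quantities from counts", {
  s <- review_cohort(reference_review_outcomes(), 1133L)
  g <- glance(s)
  expect_equal(g$reviewed_total, 1696)
  expect_equal(g$reported_total, 328)
  expect_equal(g$reported_variant_total, 317)   # SNV/indel/CNV findings
  expect_equal(g$de_novo_reported, 215)
  expect_equal(g$diagnosed_probands, 311)
  expect_equal(g$two_finding_probands, 17)
  expect_equal(g$predictive_value, 19)
  expect_equal(g$diagnostic_yield, 27)
  expect_equal(g$reported_total - g$diagnosed_probands,
               g$two_finding_probands)
  t <- tidy(s)
  ad_inh <- t[t$variant_class == "autosomal_dominant" &
                t$inheritance_class == "inherited", ]
  expect_equal(ad_inh$predictive_value, 5)
  ad_dn <- t[t$variant_class == "autosomal_dominant" &
               t$inheritance_class == "de_novo", ]
  expect_equal(ad_dn$diagnostic_yield, 16)
})

test_that("report records carry the reporting tuple; compound hets share an event", {
  co <- simulate_cohort(small_params(
    10, seed = 41, spike_in = c(de_novo_dominant = 2,
                                compound_het_trans = 2)))
  cand <- triage_cohort(co$variants, co$pedigree, co$panel, NULL,
                        filter_config(mode = "trio"))
  outcomes <- tibble::tibble(event_id = unique(cand$event_id),
                             decision = "reported")
  path <- withr::local_tempfile(fileext = ".tsv")
  written <- write_report_records(cand, outcomes, path)
  back <- readr::read_tsv(path, show_col_types = FALSE)
  expect_equal(nrow(back), nrow(written))
  expect_true(all(c("chromosome", "position", "gene", "allele", "genotype",
                    "inheritance", "most_severe_consequence") %in%
                    names(back)))
  pair_events <- table(written$event_id[grepl("|pair|", written$event_id,
                                              fixed = TRUE)])
  expect_true(length(pair_events) > 0 && all(pair_events == 2))
  # zero reported -> header-only file
  none <- write_report_records(cand, outcomes[0, ], path)
  expect_equal(nrow(none), 0)
  expect_equal(nrow(readr::read_tsv(path, show_col_types = FALSE)), 0)
})

test_that("plot helpers return ggplot objects", {
  p1 <- plot_flag_counts(reference_flag_counts())
  expect_s3_class(p1, "ggplot")
  p2 <- autoplot(review_cohort(reference_review_outcomes(), 1133L))
  expect_s3_class(p2, "ggplot")
})
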