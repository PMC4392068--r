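test_that("generation is deterministic given the seed", {
  p <- small_params(8, seed = 123, spike_in = c(de_novo_dominant = 2))
  a <- simulate_cohort(p)
  b <- simulate_cohort(p)
  expect_identical(a$variants, b$variants)
  expect_identical(a$cnvs, b$cnvs)
  expect_identical(a$pedigree, b$pedigree)
  expect_identical(a$truth, b$truth)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_cohort(a, d1)
  write_cohort(b, d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_identical(f1, list.files(d2, recursive = TRUE))
  for (f in f1) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  c2 <- simulate_cohort(small_params(8, seed = 124))
  expect_false(identical(a$variants, c2$variants))
})

test_that("an empty cohort writes valid, parseable outputs", {
  co <- simulate_cohort(small_params(0, seed = 1))
  expect_equal(nrow(co$variants), 0)
  expect_equal(nrow(co$pedigree), 0)
  d <- withr::local_tempdir()
  write_cohort(co, d)
  back <- read_cohort(d)
  expect_equal(nrow(back$pedigree), 0)
  expect_equal(nrow(back$cnvs), 0)
})

test_that("per-proband rare-functional counts match the configured mean", {
  n <- 200
  co <- simulate_cohort(simulation_params(
    n_trios = n, seed = 77, common_variant_count = 0L,
    nonfunctional_variant_count = 0L, de_novo_rate = 0,
    comphet_gene_rate = 0, cnv_count_per_proband = 0))
  per <- table(factor(co$variants$proband_id,
                      levels = co$pedigree$proband_id))
  m <- mean(per)
  se <- stats::sd(per) / sqrt(n)
  expect_lt(abs(m - 400), 3 * se + 1e-9)
  # ~30 of ~400 rare functional variants fall in panel genes
  in_panel <- startsWith(co$variants$gene, "PGENE")
  panel_per <- tapply(in_panel, co$variants$proband_id, sum)
  expect_lt(abs(mean(panel_per) - 30), 3 * stats::sd(panel_per) / sqrt(n) +
              1e-9)
})

test_that("generated cohorts respect Mendelian transmission and X hemizygosity", {
  co <- simulate_cohort(small_params(40, seed = 19))
  v <- classify_inheritance(co$variants, co$pedigree)
  expect_false(any(v$inheritance == "mendelian_error"))
  male_x <- v[v$on_x & v$proband_male, ]
  expect_true(all(male_x$child_ploidy == 1))
  expect_true(all(male_x$child_gt <= 1))
  female <- v[!v$proband_male, ]
  expect_true(all(female$child_ploidy == 2))
  # the optional genotyping-error rate produces mendelian errors on demand
  err <- simulate_cohort(small_params(20, seed = 19,
                                      genotyping_error_rate = 0.05))
  verr <- classify_inheritance(err$variants, err$pedigree)
  expect_gt(sum(verr$inheritance == "mendelian_error"), 0)
})

test_that("affected-parent fractions follow the configured rates", {
  co <- simulate_cohort(simulation_params(
    n_trios = 1000, seed = 55, mean_rare_functional = 0,
    mean_panel_overlapping = 0, common_variant_count = 0L,
    nonfunctional_variant_count = 0L, de_novo_rate = 0,
    comphet_gene_rate = 0, cnv_count_per_proband = 0))
  counts <- table(factor(n_affected_parents(co$pedigree), levels = 0:2))
  one <- counts[["1"]] / 1000
  both <- counts[["2"]] / 1000
  expect_lt(abs(one - 0.11), 3 * sqrt(0.11 * 0.89 / 1000))
  expect_lt(abs(both - 0.02), 3 * sqrt(0.02 * 0.98 / 1000))
})

test_that("written cohorts parse back through the package readers unchanged", {
  co <- simulate_cohort(small_params(6, seed = 8,
                                     spike_in = c(compound_het_trans = 2)))
  d <- withr::local_tempdir()
  write_cohort(co, d)
  back <- read_cohort(d)
  v1 <- as.data.frame(co$variants[order(co$variants$variant_id), ])
  v2 <- as.data.frame(back$variants[order(back$variants$variant_id),
                                    names(co$variants)])
  rownames(v1) <- rownames(v2) <- NULL
  expect_equal(v2, v1, tolerance = 1e-6)
  expect_equal(as.data.frame(back$panel), as.data.frame(co$panel),
               ignore_attr = TRUE)
  expect_equal(back$pedigree$proband_id, co$pedigree$proband_id)
  expect_equal(back$pedigree$family_history, co$pedigree$family_history)
  expect_equal(back$truth$variant_ids, co$truth$variant_ids)
})

test_that("truth evaluation scores spikes and a permutation control behaves", {
  co <- simulate_cohort(small_params(
    30, seed = 99,
    spike_in = c(de_novo_dominant = 10, common_control = 10)))
  cand <- triage_cohort(co$variants, co$pedigree, co$panel, NULL,
                        filter_config(mode = "trio"))
  ev <- truth_eval(cand, co$truth, "trio")
  expect_equal(ev$flagged_fraction[ev$spike_category == "de_novo_dominant"],
               1.0)
  expect_equal(ev$flagged_fraction[ev$spike_category == "common_control"],
               0.0)
  # permutation control: scoring shuffled variant ids breaks the signal
  shuffled <- co$truth
  shuffled$variant_ids <- sample(paste0("PX:", seq_len(nrow(shuffled)),
                                        ":1:A:T"))
  ev_sh <- truth_eval(cand, shuffled, "trio")
  expect_true(all(ev_sh$n_flagged == 0))
  # mismatched cohorts are rejected
  foreign <- co$truth
  foreign$proband_id <- "P9999"
  expect_error(truth_eval(cand, foreign, "trio"), "outside")
})
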