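test_that("frequency filter keeps rare and missing-frequency variants, inclusive boundary", {
  cfg <- filter_config()
  expect_false(frequency_filter(0.02, cfg))
  expect_true(frequency_filter(0.01, cfg))   # MAF <= 1% kept
  expect_true(frequency_filter(NA_real_, cfg))
  strict <- filter_config(dominant_maf_threshold = 0.001)
  expect_true(frequency_filter(0.005, strict))
  expect_false(frequency_filter(0.005, strict, dominant_context = TRUE))
  expect_true(frequency_filter(0.001, strict, dominant_context = TRUE))
})

test_that("X-linked inherited-missense exclusion honours its two exceptions", {
  expect_true(x_missense_exclusion("missense_variant", "maternal",
                                   FALSE, FALSE))
  expect_false(x_missense_exclusion("missense_variant", "de_novo",
                                    FALSE, FALSE))
  expect_false(x_missense_exclusion("missense_variant", "maternal",
                                    TRUE, FALSE))   # family history
  expect_false(x_missense_exclusion("missense_variant", "maternal",
                                    FALSE, TRUE))   # known database
  expect_false(x_missense_exclusion("stop_gained", "maternal",
                                    FALSE, FALSE))
})

comphet_members <- function(modes) {
  v <- dplyr::bind_rows(lapply(seq_along(modes), function(i) {
    make_variant(position = 1000L + i, gene = "RECLOF", chromosome = "3")
  }))
  v <- as_variant_tbl(v)
  v$inheritance <- modes
  v
}

test_that("compound-het pairing requires trans configuration in trio mode", {
  trio_cfg <- filter_config(mode = "trio")
  po_cfg <- filter_config(mode = "proband_only")
  expect_equal(nrow(find_compound_hets(
    comphet_members(c("maternal", "paternal")), trio_cfg)), 1)
  expect_equal(nrow(find_compound_hets(
    comphet_members(c("maternal", "maternal")), trio_cfg)), 0)
  expect_equal(nrow(find_compound_hets(
    comphet_members(c("paternal", "paternal")), trio_cfg)), 0)
  # a de novo member may pair with either inherited member
  expect_equal(nrow(find_compound_hets(
    comphet_members(c("de_novo", "maternal")), trio_cfg)), 1)
  # ambiguous phase pairs with a definite member
  expect_equal(nrow(find_compound_hets(
    comphet_members(c("inherited_ambiguous", "maternal")), trio_cfg)), 1)
  # mendelian errors never pair
  expect_equal(nrow(find_compound_hets(
    comphet_members(c("mendelian_error", "paternal")), trio_cfg)), 0)
  # proband-only: all C(3,2) pairs are candidates
  expect_equal(nrow(find_compound_hets(
    comphet_members(rep("uninformative", 3)), po_cfg)), 3)
})

test_that("genotype configurations match allelic requirements", {
  trio <- make_trio()
  male <- make_trio(sex = "male")
  het <- as_variant_tbl(make_variant(gene = "G"))
  hom <- as_variant_tbl(make_variant(gene = "G", child_gt = 2L,
                                     mother_gt = 1L, father_gt = 1L))
  two_hets <- as_variant_tbl(dplyr::bind_rows(
    make_variant(gene = "G", position = 1L),
    make_variant(gene = "G", position = 2L)))
  hemi <- as_variant_tbl(make_variant(chromosome = "X", gene = "G",
                                      child_gt = 1L, child_ploidy = 1L))
  mono <- list(allelic_requirement = "monoallelic")
  bi <- list(allelic_requirement = "biallelic")
  xlr <- list(allelic_requirement = "x_linked_recessive")
  expect_true(genotype_matches_requirement(het, mono, trio))
  expect_false(genotype_matches_requirement(het, bi, trio))
  expect_true(genotype_matches_requirement(hom, bi, trio))
  expect_true(genotype_matches_requirement(two_hets, bi, trio))
  expect_true(genotype_matches_requirement(hemi, xlr, male))
  expect_false(genotype_matches_requirement(het, xlr, trio))
  expect_true(genotype_matches_requirement(hom, xlr, trio))
})

test_that("CNV size rule applies strict thresholds by type and inheritance", {
  cfg <- filter_config()
  cnv <- function(len, type, inh, genes = "G1") {
    tibble::tibble(proband_id = "P1", chromosome = "1", start = 1L,
                   end = as.integer(len), cnv_type = type,
                   inheritance_status = inh, overlapped_genes = genes,
                   fully_contained_genes = "", maf = NA_real_)
  }
  expect_true(cnv_size_filter(cnv(120000, "loss", "de_novo"), cfg))
  expect_false(cnv_size_filter(cnv(100000, "loss", "de_novo"), cfg))
  expect_false(cnv_size_filter(cnv(200000, "gain", "de_novo"), cfg))
  expect_true(cnv_size_filter(cnv(250001, "gain", "inherited_segregating"),
                              cfg))
  expect_true(cnv_size_filter(cnv(500001, "loss", "unknown"), cfg))
  expect_false(cnv_size_filter(cnv(500000, "gain", "unknown"), cfg))
  # non-segregating inherited CNVs are never flagged by the size rule
  expect_false(cnv_size_filter(
    cnv(900000, "loss", "inherited_non_segregating"), cfg))
  # non-genic CNVs are never flagged
  expect_false(cnv_size_filter(cnv(900000, "loss", "de_novo", genes = ""),
                               cfg))
})

test_that("CNV panel matching distinguishes containment (losses) from overlap (gains)", {
  panel <- tiny_panel()
  cnv <- function(type, overlapped, contained) {
    tibble::tibble(proband_id = "P1", chromosome = "1", start = 1L,
                   end = 80000L, cnv_type = type,
                   inheritance_status = "de_novo",
                   overlapped_genes = overlapped,
                   fully_contained_genes = contained, maf = NA_real_)
  }
  # small loss fully containing a LOF-mechanism gene is flagged
  m <- cnv_panel_filter(cnv("loss", "DOMLOF", "DOMLOF"), panel)
  expect_equal(m$gene, "DOMLOF")
  # loss merely overlapping it is not
  expect_equal(nrow(cnv_panel_filter(cnv("loss", "DOMLOF", ""), panel)), 0)
  # gain overlapping (not containing) a dosage gene is flagged
  g <- cnv_panel_filter(cnv("gain", "DOSE", ""), panel)
  expect_equal(g$gene, "DOSE")
  expect_equal(g$mutation_consequence, "increased_gene_dosage")
  # gain over a LOF gene is not flagged by the panel route
  expect_equal(nrow(cnv_panel_filter(cnv("gain", "DOMLOF", "DOMLOF"),
                                     panel)), 0)
  # losses over missense-mechanism genes do not match
  expect_equal(nrow(cnv_panel_filter(cnv("loss", "DOMMIS", "DOMMIS"),
                                     panel)), 0)
})

test_that("the cascade flags the canonical candidate classes and drops the rest", {
  panel <- tiny_panel()
  trio <- make_trio()
  # de novo het stop-gained in a monoallelic LOF gene, frequency missing
  dn <- make_variant(gene = "DOMLOF", consequence = "stop_gained")
  cand <- triage_proband(dn, trio, panel)
  expect_equal(nrow(cand), 1)
  expect_equal(cand$category, "autosomal_dominant")
  expect_equal(cand$inheritance, "de_novo")
  expect_match(cand$reason_trail, "frequency>functional>panel_gene")
  # inherited het missense in a dominant gene, unaffected parents: trio
  # mode drops it, proband-only mode flags it
  inh <- make_variant(gene = "DOMMIS", chromosome = "2", mother_gt = 1L)
  expect_equal(nrow(triage_proband(inh, trio, panel)), 0)
  expect_equal(nrow(triage_proband(
    inh, trio, panel, config = filter_config(mode = "proband_only"))), 1)
  # same variant inherited from an affected parent is flagged in trio mode
  aff <- make_trio(mother_affected = TRUE)
  expect_equal(nrow(triage_proband(inh, aff, panel)), 1)
  # common and non-functional variants never flag
  common <- make_variant(gene = "DOMLOF", maf = 0.02)
  syn <- make_variant(gene = "DOMLOF", consequence = "synonymous_variant")
  expect_equal(nrow(triage_proband(common, trio, panel)), 0)
  expect_equal(nrow(triage_proband(syn, trio, panel)), 0)
  # non-panel genes never flag
  off_panel <- make_variant(gene = "NOTINPANEL",
                            consequence = "stop_gained")
  expect_equal(nrow(triage_proband(off_panel, trio, panel)), 0)
  # single het in a recessive-only gene is no candidate; hom-alt is
  rec_het <- make_variant(gene = "RECLOF", chromosome = "3",
                          mother_gt = 1L)
  expect_equal(nrow(triage_proband(rec_het, trio, panel)), 0)
  rec_hom <- make_variant(gene = "RECLOF", chromosome = "3", child_gt = 2L,
                          mother_gt = 1L, father_gt = 1L)
  hom_cand <- triage_proband(rec_hom, trio, panel)
  expect_equal(hom_cand$category, "autosomal_recessive_homozygous")
  # dosage-mechanism entries are CNV-only: sequence variants do not match
  dose <- make_variant(gene = "DOSE", chromosome = "4",
                       consequence = "stop_gained")
  expect_equal(nrow(triage_proband(dose, trio, panel)), 0)
})

test_that("X-chromosome rules: hemizygous flags, inherited missense excluded with exceptions", {
  panel <- tiny_panel()
  male <- make_trio(sex = "male")
  hemi_lof <- make_variant(chromosome = "X", gene = "XLRGENE",
                           child_gt = 1L, child_ploidy = 1L, mother_gt = 1L,
                           consequence = "stop_gained")
  expect_equal(triage_proband(hemi_lof, male, panel)$category,
               "x_linked_recessive")
  # inherited missense on X: excluded without family history or database hit
  hemi_mis <- make_variant(chromosome = "X", gene = "XLRGENE",
                           child_gt = 1L, child_ploidy = 1L, mother_gt = 1L)
  expect_equal(nrow(triage_proband(hemi_mis, male, panel)), 0)
  fh <- make_trio(sex = "male", family_history = TRUE)
  expect_equal(nrow(triage_proband(hemi_mis, fh, panel)), 1)
  known <- hemi_mis
  known$known_pathogenic <- TRUE
  expect_equal(nrow(triage_proband(known, male, panel)), 1)
  # de novo X missense is retained
  dn_mis <- make_variant(chromosome = "X", gene = "XLRGENE",
                         child_gt = 1L, child_ploidy = 1L, mother_gt = 0L)
  expect_equal(nrow(triage_proband(dn_mis, male, panel)), 1)
  # proband-only mode cannot establish inheritance, so no exclusion
  expect_equal(nrow(triage_proband(
    hemi_mis, male, panel, config = filter_config(mode = "proband_only"))), 1)
})

test_that("mendelian errors are diverted to diagnostics, never flagged", {
  panel <- tiny_panel()
  trio <- make_trio()
  bad <- make_variant(gene = "DOMLOF", consequence = "stop_gained",
                      child_gt = 2L, mother_gt = 0L, father_gt = 1L)
  cand <- triage_proband(bad, trio, panel)
  expect_equal(nrow(cand), 0)
  expect_equal(nrow(attr(cand, "mendelian_errors")), 1)
})

test_that("optional benign-missense exclusion drops low-scoring inherited missense only", {
  panel <- tiny_panel()
  aff <- make_trio(mother_affected = TRUE)
  v <- make_variant(gene = "DOMMIS", chromosome = "2", mother_gt = 1L,
                    polyphen = 0.05)
  cfg <- filter_config(benign_missense_score_cutoff = 0.15)
  expect_equal(nrow(triage_proband(v, aff, panel)), 1)  # disabled by default
  expect_equal(nrow(triage_proband(v, aff, panel, config = cfg)), 0)
  high <- v
  high$polyphen <- 0.9
  expect_equal(nrow(triage_proband(high, aff, panel, config = cfg)), 1)
  # de novo missense is untouched by the rule
  dn <- make_variant(gene = "DOMMIS", chromosome = "2", polyphen = 0.05)
  expect_equal(nrow(triage_proband(dn, aff, panel, config = cfg)), 1)
})

test_that("phenotype-term gates annotate but never remove candidates", {
  entries <- tibble::as_tibble(tiny_panel())
  entries$required_phenotype_terms[entries$gene_symbol == "DOMLOF"] <-
    "HP:0000365;HP:0001250"
  panel <- gene_panel(entries)
  trio <- make_trio()
  v <- make_variant(gene = "DOMLOF", consequence = "stop_gained")
  match_ph <- tibble::tibble(proband_id = "P1", term = "HP:0000365")
  miss_ph <- tibble::tibble(proband_id = "P1", term = "HP:0009999")
  c1 <- triage_proband(v, trio, panel, phenotypes = match_ph)
  c2 <- triage_proband(v, trio, panel, phenotypes = miss_ph)
  expect_equal(c1$phenotype_note, "phenotype_match")
  expect_equal(c2$phenotype_note, "phenotype_mismatch")
  expect_equal(nrow(c2), 1)  # annotated, not removed
})

test_that("trio-mode candidates are a subset of proband-only candidates (unaffected parents)", {
  co <- simulate_cohort(small_params(
    25, seed = 5, fraction_one_parent_affected = 0,
    fraction_both_parents_affected = 0,
    spike_in = c(de_novo_dominant = 5, compound_het_trans = 3)))
  trio_cand <- triage_cohort(co$variants, co$pedigree, co$panel, co$cnvs,
                             filter_config(mode = "trio"))
  po_cand <- triage_cohort(co$variants, co$pedigree, co$panel, co$cnvs,
                           filter_config(mode = "proband_only"))
  expect_true(all(trio_cand$variant_id %in% po_cand$variant_id))
  for (p in unique(trio_cand$proband_id)) {
    expect_true(all(trio_cand$variant_id[trio_cand$proband_id == p] %in%
                      po_cand$variant_id[po_cand$proband_id == p]))
  }
})

test_that("marking a transmitting parent affected only ever adds candidates", {
  co <- simulate_cohort(small_params(
    20, seed = 9, fraction_one_parent_affected = 0,
    fraction_both_parents_affected = 0))
  base <- triage_cohort(co$variants, co$pedigree, co$panel, NULL,
                        filter_config(mode = "trio"))
  ped_aff <- co$pedigree
  ped_aff$mother_affected <- TRUE
  more <- triage_cohort(co$variants, ped_aff, co$panel, NULL,
                        filter_config(mode = "trio"))
  expect_true(all(base$event_id %in% more$event_id))
  added <- more[!(more$event_id %in% base$event_id), ]
  expect_true(all(added$category %in%
                    c("autosomal_dominant", "x_linked_dominant")))
  expect_true(all(added$inheritance %in%
                    c("maternal", "inherited_ambiguous", "biparental")))
})

test_that("triage output ordering and reason trails are deterministic", {
  co <- simulate_cohort(small_params(10, seed = 3,
                                     spike_in = c(de_novo_dominant = 3)))
  a <- triage_cohort(co$variants, co$pedigree, co$panel, co$cnvs)
  b <- triage_cohort(co$variants[sample(nrow(co$variants)), ],
                     co$pedigree, co$panel, co$cnvs)
  expect_equal(as.data.frame(a), as.data.frame(b))
  expect_true(all(nzchar(a$reason_trail)))
})
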