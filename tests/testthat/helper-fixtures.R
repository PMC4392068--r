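# In-code fixtures shared across test files.

make_trio <- function(proband_id = "P1", sex = "female",
                      mother_affected = FALSE, father_affected = FALSE,
                      family_history = FALSE, proband_only = FALSE) {
  tibble::tibble(
    family_id = paste0("F", proband_id),
    proband_id = proband_id,
    father_id = if (proband_only) NA_character_ else paste0("D", proband_id),
    mother_id = if (proband_only) NA_character_ else paste0("M", proband_id),
    proband_sex = sex,
    proband_affected = TRUE,
    mother_affected = if (proband_only) NA else mother_affected,
    father_affected = if (proband_only) NA else father_affected,
    family_history = family_history)
}

make_variant <- function(proband_id = "P1", chromosome = "1",
                         position = 1000L, ref = "A", alt = "T",
                         gene = "GENE1", consequence = "missense_variant",
                         maf = NA_real_, child_gt = 1L, mother_gt = 0L,
                         father_gt = 0L, child_ploidy = 2L,
                         known_pathogenic = FALSE, polyphen = NA_real_) {
  tibble::tibble(proband_id = proband_id, chromosome = chromosome,
                 position = position, ref = ref, alt = alt, gene = gene,
                 consequence = consequence, maf = maf, child_gt = child_gt,
                 mother_gt = mother_gt, father_gt = father_gt,
                 child_ploidy = child_ploidy,
                 known_pathogenic = known_pathogenic, polyphen = polyphen)
}

tiny_panel <- function() {
  gene_panel(tibble::tibble(
    gene_symbol = c("DOMLOF", "DOMMIS", "RECLOF", "DOSE", "XLRGENE",
                    "XLDGENE", "WEAK"),
    chromosome = c("1", "2", "3", "4", "X", "X", "5"),
    allelic_requirement = c("monoallelic", "monoallelic", "biallelic",
                            "monoallelic", "x_linked_recessive",
                            "x_linked_dominant", "monoallelic"),
    mutation_consequence = c("loss_of_function", "all_missense_or_in_frame",
                             "loss_of_function", "increased_gene_dosage",
                             "loss_of_function", "loss_of_function",
                             "uncertain"),
    reportable = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE)),
    label = "tiny")
}

empty_candidate_file <- function() {
  co <- simulate_cohort(small_params(0, seed = 1))
  triage_cohort(co$variants, co$pedigree, co$panel, NULL)
}

small_params <- function(n_trios, seed, ...) {
  simulation_params(n_trios = n_trios, seed = seed,
                    mean_rare_functional = 40, mean_panel_overlapping = 6,
                    common_variant_count = 10L,
                    nonfunctional_variant_count = 10L,
                    cnv_count_per_proband = 1, ...)
}
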