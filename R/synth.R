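# Seeded synthetic trio-cohort generator. Emulates the statistical structure
# of a large developmental-disorder trio cohort: ~400 rare protein-altering
# variants per proband of which ~30 fall in panel genes, 11%/2% of trios
# with one/both parents affected, Mendelian-consistent transmission except
# for de novo events, and optional spike-ins with a truth table so triage
# sensitivity/specificity can be measured exactly.

#' Simulation parameters for a synthetic trio cohort
#'
#' Defaults reproduce the stated structure of the reference cohort: a mean
#' of 400 rare protein-altering variants per proband, 30 of them in panel
#' genes, and 11% / 2% of trios with one / both parents affected. The
#' remaining rates are generator choices documented in the methods
#' vignette.
#'
#' @param n_trios Number of trios.
#' @param seed Integer seed; the whole cohort is deterministic given it.
#' @param mean_rare_functional Mean rare protein-altering variants per
#'   proband (Poisson).
#' @param mean_panel_overlapping Mean of those falling in panel genes.
#' @param common_variant_count Common-background variants (MAF > 1%) per
#'   proband.
#' @param nonfunctional_variant_count Rare non-protein-altering variants per
#'   proband.
#' @param de_novo_rate Mean de novo coding variants per proband (Poisson).
#' @param fraction_one_parent_affected,fraction_both_parents_affected
#'   Fractions of trios with one / both parents affected by a (typically
#'   milder) developmental phenotype.
#' @param comphet_gene_rate Per-proband probability of carrying a trans
#'   compound-het pair in a recessive panel gene.
#' @param hom_rate Fraction of inherited rare variants that are homozygous
#'   in the child (both parents carriers).
#' @param cnv_count_per_proband Mean CNV calls per proband (Poisson).
#' @param cnv_size_log10_range Log10 length range for CNVs; the default
#'   spans the 100/250/500 kb size thresholds.
#' @param genotyping_error_rate Fraction of inherited autosomal variants
#'   rewritten into Mendelian-inconsistent genotypes, to exercise
#'   `mendelian_error` handling. Off by default.
#' @param spike_in Named integer vector of spike-ins, e.g.
#'   `c(de_novo_dominant = 10, compound_het_cis = 5)`. Supported categories:
#'   `de_novo_dominant`, `recessive_hom`, `compound_het_trans`,
#'   `compound_het_cis`, `common_control`, `nonfunctional_control`,
#'   `x_inherited_missense`.
#' @return List of class `simulation_params`.
#' @export
simulation_params <- function(n_trios,
                              seed = 1L,
                              mean_rare_functional = 400,
                              mean_panel_overlapping = 30,
                              common_variant_count = 100L,
                              nonfunctional_variant_count = 100L,
                              de_novo_rate = 1.5,
                              fraction_one_parent_affected = 0.11,
                              fraction_both_parents_affected = 0.02,
                              comphet_gene_rate = 0.05,
                              hom_rate = 0.01,
                              cnv_count_per_proband = 2,
                              cnv_size_log10_range = c(4.3, 6.1),
                              genotyping_error_rate = 0,
                              spike_in = NULL) {
  stopifnot(n_trios >= 0, mean_rare_functional >= 0,
            mean_panel_overlapping >= 0,
            mean_panel_overlapping <= mean_rare_functional || mean_rare_functional == 0,
            de_novo_rate >= 0, comphet_gene_rate >= 0, hom_rate >= 0,
            cnv_count_per_proband >= 0, genotyping_error_rate >= 0,
            fraction_one_parent_affected + fraction_both_parents_affected <= 1)
  structure(as.list(environment()), class = "simulation_params")
}

functional_consequence_mix <- function() {
  c(missense_variant = 0.70, in_frame_deletion = 0.04,
    in_frame_insertion = 0.03, splice_donor_variant = 0.05,
    splice_acceptor_variant = 0.04, stop_gained = 0.06,
    frameshift_variant = 0.07, stop_lost = 0.01)
}

# Synthetic gene universe: panel genes plus non-panel background genes, each
# with an interval on a synthetic coordinate system.
simulate_gene_universe <- function() {
  mk <- function(prefix, n, chroms) {
    tibble::tibble(
      gene = sprintf("%s%04d", prefix, seq_len(n)),
      chromosome = chroms)
  }
  panel_auto <- mk("PGENE", 106, sample(as.character(1:22), 106, replace = TRUE))
  panel_x <- tibble::tibble(gene = sprintf("PGENE%04d", 106 + 1:20),
                            chromosome = "X")
  bg_auto <- mk("BGENE", 500, sample(as.character(1:22), 500, replace = TRUE))
  bg_x <- tibble::tibble(gene = sprintf("BGENE%04d", 500 + 1:25),
                         chromosome = "X")
  genes <- dplyr::bind_rows(panel_auto, panel_x, bg_auto, bg_x)
  genes <- genes[order(genes$chromosome, genes$gene), ]
  idx <- stats::ave(seq_len(nrow(genes)), genes$chromosome,
                    FUN = seq_along)
  genes$start <- 1e6 * idx + 1
  genes$end <- genes$start + 5e4 - 1
  genes$is_panel <- startsWith(genes$gene, "PGENE")
  genes
}

simulate_panel <- function(genes) {
  auto <- genes$gene[genes$is_panel & genes$chromosome != "X"]
  xg <- genes$gene[genes$is_panel & genes$chromosome == "X"]
  req <- c(rep("monoallelic", 60), rep("biallelic", 40),
           rep("monoallelic", 6))  # last 6 become dosage entries
  mech <- c(sample(c("loss_of_function", "all_missense_or_in_frame",
                     "dominant_negative", "activating", "uncertain"),
                   60, replace = TRUE,
                   prob = c(0.5, 0.2, 0.15, 0.1, 0.05)),
            sample(c("loss_of_function", "all_missense_or_in_frame",
                     "uncertain"), 40, replace = TRUE,
                   prob = c(0.7, 0.2, 0.1)),
            rep("increased_gene_dosage", 6))
  entries_auto <- tibble::tibble(gene_symbol = auto,
                                 allelic_requirement = req,
                                 mutation_consequence = mech,
                                 reportable = TRUE)
  entries_x <- tibble::tibble(
    gene_symbol = xg,
    allelic_requirement = c(rep("x_linked_dominant", 8),
                            rep("x_linked_recessive", 12)),
    mutation_consequence = sample(c("loss_of_function",
                                    "all_missense_or_in_frame"),
                                  20, replace = TRUE, prob = c(0.6, 0.4)),
    reportable = TRUE)
  # a few genes carry a second mode/mechanism entry
  second <- entries_auto[1:6, ]
  second$allelic_requirement <- ifelse(second$allelic_requirement ==
                                         "monoallelic",
                                       "biallelic", "monoallelic")
  second$mutation_consequence <- "uncertain"
  # and a few non-reportable (insufficient-evidence) entries, on genes whose
  # only reportable entries are dosage entries so the triples stay unique
  nonrep <- tibble::tibble(
    gene_symbol = auto[101:105],
    allelic_requirement = "biallelic",
    mutation_consequence = "uncertain",
    reportable = FALSE)
  entries <- dplyr::bind_rows(entries_auto, entries_x, second, nonrep)
  idx <- match(entries$gene_symbol, genes$gene)
  entries$chromosome <- genes$chromosome[idx]
  entries$interval_start <- genes$start[idx]
  entries$interval_end <- genes$end[idx]
  entries$required_phenotype_terms <- NA_character_
  entries$notes <- NA_character_
  # a couple of frequently-hit genes require a specific clinical feature
  entries$required_phenotype_terms[1:2] <- "HP:0000365"
  gene_panel(entries, label = "synthetic-v1")
}

simulate_pedigrees <- function(params) {
  n <- params$n_trios
  if (n == 0) {
    return(tibble::tibble(family_id = character(0), proband_id = character(0),
                          father_id = character(0), mother_id = character(0),
                          proband_sex = character(0),
                          proband_affected = logical(0),
                          mother_affected = logical(0),
                          father_affected = logical(0),
                          family_history = logical(0)))
  }
  u <- stats::runif(n)
  both <- u < params$fraction_both_parents_affected
  one <- !both & u < params$fraction_both_parents_affected +
    params$fraction_one_parent_affected
  one_is_mother <- stats::runif(n) < 0.5
  tibble::tibble(
    family_id = sprintf("F%04d", seq_len(n)),
    proband_id = sprintf("P%04d", seq_len(n)),
    father_id = sprintf("D%04d", seq_len(n)),
    mother_id = sprintf("M%04d", seq_len(n)),
    proband_sex = sample(c("male", "female"), n, replace = TRUE,
                         prob = c(0.51, 0.49)),
    proband_affected = TRUE,
    mother_affected = both | (one & one_is_mother),
    father_affected = both | (one & !one_is_mother),
    family_history = both | one | stats::runif(n) < 0.02)
}

# Vectorised genotype assignment respecting Mendelian transmission and male
# X hemizygosity. `kind`: inherited / de_novo. Returns a tibble of genotype
# columns for `n` rows.
assign_genotypes <- function(n, on_x, male, kind, hom_rate) {
  child_ploidy <- ifelse(on_x & male, 1L, 2L)
  mother <- integer(n)
  father <- integer(n)
  child <- integer(n)
  inh <- kind == "inherited"
  hom <- inh & !on_x & stats::runif(n) < hom_rate
  carrier_mother <- stats::runif(n) < 0.5
  # inherited het
  m_carrier <- inh & !hom & (carrier_mother | (on_x & male))
  f_carrier <- inh & !hom & !carrier_mother & !(on_x & male)
  mother[m_carrier] <- 1L
  father[f_carrier] <- 1L
  child[inh & !hom] <- 1L
  # inherited hom (autosomal only)
  mother[hom] <- 1L
  father[hom] <- 1L
  child[hom] <- 2L
  # de novo rows: parents stay 0, child carries one copy
  child[kind == "de_novo"] <- 1L
  tibble::tibble(child_gt = child, mother_gt = mother, father_gt = father,
                 child_ploidy = child_ploidy)
}

random_alleles <- function(n) {
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  shift <- sample(1:3, n, replace = TRUE)
  alt <- bases[((match(ref, bases) - 1 + shift) %% 4) + 1]
  list(ref = ref, alt = alt)
}

build_variant_block <- function(proband_idx, ped, genes, gene_pick,
                                consequence, maf, kind, hom_rate) {
  n <- length(proband_idx)
  if (!n) return(NULL)
  g <- genes[match(gene_pick, genes$gene), ]
  on_x <- g$chromosome == "X"
  male <- ped$proband_sex[proband_idx] == "male"
  al <- random_alleles(n)
  gt <- assign_genotypes(n, on_x, male, kind, hom_rate)
  tibble::tibble(
    proband_id = ped$proband_id[proband_idx],
    chromosome = g$chromosome,
    position = as.integer(g$start + floor(stats::runif(n) * (g$end - g$start))),
    ref = al$ref, alt = al$alt,
    gene = g$gene,
    consequence = consequence,
    maf = maf,
    child_gt = gt$child_gt, mother_gt = gt$mother_gt,
    father_gt = gt$father_gt, child_ploidy = gt$child_ploidy,
    sift = round(stats::runif(n), 3),
    polyphen = round(stats::runif(n), 3),
    known_pathogenic = stats::runif(n) < 0.01)
}

sample_consequences <- function(n) {
  mix <- functional_consequence_mix()
  sample(names(mix), n, replace = TRUE, prob = mix)
}

rare_maf <- function(n) {
  ifelse(stats::runif(n) < 0.3, NA_real_,
         round(stats::runif(n, 0, 0.01), 6))
}

spike_categories <- function() {
  c("de_novo_dominant", "recessive_hom", "compound_het_trans",
    "compound_het_cis", "common_control", "nonfunctional_control",
    "x_inherited_missense")
}

#' Generate a synthetic trio cohort
#'
#' Deterministic given `params$seed`. Mendelian transmission is respected
#' for every non-spiked variant except the optional genotyping-error rows;
#' X-chromosome variants respect proband sex (males are hemizygous). The
#' truth table records every spiked candidate with its expected flag
#' decision in both trio and proband-only modes.
#'
#' @param params A [simulation_params()].
#' @return List of class `trio_cohort` with elements `params`, `pedigree`,
#'   `panel`, `genes`, `variants`, `cnvs`, `truth`.
#' @export
simulate_cohort <- function(params) {
  stopifnot(inherits(params, "simulation_params"))
  set.seed(params$seed)
  genes <- simulate_gene_universe()
  panel <- simulate_panel(genes)
  ped <- simulate_pedigrees(params)
  n <- params$n_trios

  panel_genes <- genes$gene[genes$is_panel]
  bg_genes <- genes$gene[!genes$is_panel]
  p_panel <- if (params$mean_rare_functional > 0) {
    params$mean_panel_overlapping / params$mean_rare_functional
  } else {
    0
  }

  blocks <- list()
  truth <- list()
  if (n > 0) {
    # rare functional background (inherited)
    n_rare <- stats::rpois(n, params$mean_rare_functional)
    idx <- rep(seq_len(n), n_rare)
    m <- length(idx)
    in_panel <- stats::runif(m) < p_panel
    gene_pick <- character(m)
    gene_pick[in_panel] <- sample(panel_genes, sum(in_panel), replace = TRUE)
    gene_pick[!in_panel] <- sample(bg_genes, sum(!in_panel), replace = TRUE)
    blocks$rare <- build_variant_block(idx, ped, genes, gene_pick,
                                       sample_consequences(m), rare_maf(m),
                                       "inherited", params$hom_rate)

    # de novo events
    n_dn <- stats::rpois(n, params$de_novo_rate)
    idx <- rep(seq_len(n), n_dn)
    m <- length(idx)
    if (m) {
      in_panel <- stats::runif(m) < p_panel
      gene_pick <- character(m)
      gene_pick[in_panel] <- sample(panel_genes, sum(in_panel), replace = TRUE)
      gene_pick[!in_panel] <- sample(bg_genes, sum(!in_panel), replace = TRUE)
      blocks$de_novo <- build_variant_block(idx, ped, genes, gene_pick,
                                            sample_consequences(m),
                                            rep(NA_real_, m), "de_novo",
                                            params$hom_rate)
    }

    # trans compound-het pairs in recessive panel genes
    ch <- which(stats::runif(n) < params$comphet_gene_rate)
    if (length(ch)) {
      bi_genes <- unique(tibble::as_tibble(panel)$gene_symbol[
        panel$allelic_requirement == "biallelic" & panel$reportable])
      gpick <- sample(bi_genes, length(ch), replace = TRUE)
      b1 <- build_variant_block(ch, ped, genes, gpick,
                                sample_consequences(length(ch)),
                                rare_maf(length(ch)), "inherited", 0)
      b2 <- build_variant_block(ch, ped, genes, gpick,
                                sample_consequences(length(ch)),
                                rare_maf(length(ch)), "inherited", 0)
      b1$mother_gt <- 1L; b1$father_gt <- 0L
      b2$mother_gt <- 0L; b2$father_gt <- 1L
      b2$position <- b1$position + 7L  # force distinct sites
      blocks$comphet <- dplyr::bind_rows(b1, b2)
    }

    # common background (MAF > 1%)
    m <- n * params$common_variant_count
    if (m) {
      idx <- rep(seq_len(n), each = params$common_variant_count)
      in_panel <- stats::runif(m) < p_panel
      gene_pick <- character(m)
      gene_pick[in_panel] <- sample(panel_genes, sum(in_panel), replace = TRUE)
      gene_pick[!in_panel] <- sample(bg_genes, sum(!in_panel), replace = TRUE)
      blocks$common <- build_variant_block(
        idx, ped, genes, gene_pick, sample_consequences(m),
        round(stats::runif(m, 0.011, 0.4), 6), "inherited", params$hom_rate)
    }

    # rare non-protein-altering background
    m <- n * params$nonfunctional_variant_count
    if (m) {
      idx <- rep(seq_len(n), each = params$nonfunctional_variant_count)
      gene_pick <- sample(c(panel_genes, bg_genes), m, replace = TRUE)
      blocks$nonfunc <- build_variant_block(
        idx, ped, genes, gene_pick,
        sample(c("synonymous_variant", "intron_variant",
                 "5_prime_UTR_variant"), m, replace = TRUE),
        rare_maf(m), "inherited", params$hom_rate)
    }

    sp <- simulate_spikes(params, ped, genes, panel)
    blocks$spikes <- sp$variants
    truth <- sp$truth

    if (params$genotyping_error_rate > 0 && !is.null(blocks$rare)) {
      auto <- which(blocks$rare$child_ploidy == 2 &
                      blocks$rare$chromosome != "X")
      err <- auto[stats::runif(length(auto)) < params$genotyping_error_rate]
      # child hom-alt with a het/ref parent pair: Mendelian-inconsistent
      blocks$rare$child_gt[err] <- 2L
      blocks$rare$mother_gt[err] <- 0L
      blocks$rare$father_gt[err] <- 1L
    }
  }

  variants <- dplyr::bind_rows(blocks)
  if (is.null(variants) || !nrow(variants)) {
    variants <- as_variant_tbl(tibble::tibble(
      proband_id = character(0), chromosome = character(0),
      position = integer(0), ref = character(0), alt = character(0),
      gene = character(0), consequence = character(0),
      child_gt = integer(0)))
  } else {
    variants <- as_variant_tbl(variants)
    # collapse accidental duplicate (proband, site, alt) draws
    variants <- variants[!duplicated(variants$variant_id), ]
    variants <- variants[order(variants$proband_id,
                               chrom_rank(variants$chromosome),
                               variants$position, variants$alt), ]
  }

  cnvs <- simulate_cnvs(params, ped, genes)
  truth_tbl <- if (length(truth)) {
    dplyr::bind_rows(truth)
  } else {
    tibble::tibble(proband_id = character(0), spike_category = character(0),
                   gene = character(0), variant_ids = character(0),
                   expect_trio = logical(0), expect_proband_only = logical(0))
  }
  structure(list(params = params, pedigree = ped, panel = panel,
                 genes = genes, variants = variants, cnvs = cnvs,
                 truth = truth_tbl),
            class = "trio_cohort")
}

simulate_spikes <- function(params, ped, genes, panel) {
  spec <- params$spike_in
  empty <- list(variants = NULL, truth = list())
  if (is.null(spec) || !length(spec)) return(empty)
  bad <- setdiff(names(spec), spike_categories())
  if (length(bad)) {
    stop("unknown spike-in categories: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  ptbl <- tibble::as_tibble(panel)
  mono_genes <- unique(ptbl$gene_symbol[
    ptbl$allelic_requirement == "monoallelic" & ptbl$reportable &
      ptbl$mutation_consequence != "increased_gene_dosage"])
  bi_genes <- unique(ptbl$gene_symbol[
    ptbl$allelic_requirement == "biallelic" & ptbl$reportable])
  xlr_genes <- unique(ptbl$gene_symbol[
    ptbl$allelic_requirement == "x_linked_recessive" & ptbl$reportable])
  males <- which(ped$proband_sex == "male" & !ped$family_history)

  out_v <- list()
  out_t <- list()
  pick_probands <- function(k, pool = seq_len(nrow(ped))) {
    pool[((seq_len(k) - 1L) %% length(pool)) + 1L]
  }
  add <- function(block, category, expect_trio, expect_po, pair = FALSE) {
    block$variant_id <- paste(block$proband_id, block$chromosome,
                              block$position, block$ref, block$alt,
                              sep = ":")
    if (pair) {
      half <- nrow(block) / 2
      ids <- paste(block$variant_id[seq_len(half)],
                   block$variant_id[half + seq_len(half)], sep = ";")
      probands <- block$proband_id[seq_len(half)]
      gene <- block$gene[seq_len(half)]
    } else {
      ids <- block$variant_id
      probands <- block$proband_id
      gene <- block$gene
    }
    out_t[[category]] <<- tibble::tibble(
      proband_id = probands, spike_category = category, gene = gene,
      variant_ids = ids, expect_trio = expect_trio,
      expect_proband_only = expect_po)
    block$variant_id <- NULL
    out_v[[category]] <<- block
  }

  for (cat in names(spec)) {
    k <- spec[[cat]]
    if (k == 0) next
    if (cat == "x_inherited_missense") {
      if (!length(males)) {
        warning("no male probands without family history; ",
                "skipping x_inherited_missense spikes", call. = FALSE)
        next
      }
      idx <- pick_probands(k, males)
      b <- build_variant_block(idx, ped, genes,
                               sample(xlr_genes, k, replace = TRUE),
                               rep("missense_variant", k),
                               rep(NA_real_, k), "inherited", 0)
      b$known_pathogenic <- FALSE
      add(b, cat, expect_trio = FALSE, expect_po = TRUE)
      next
    }
    idx <- pick_probands(k)
    if (cat == "de_novo_dominant") {
      b <- build_variant_block(idx, ped, genes,
                               sample(mono_genes, k, replace = TRUE),
                               rep("stop_gained", k), rep(NA_real_, k),
                               "de_novo", 0)
      # keep spikes on autosomes so the candidate class is unambiguous
      add(b, cat, TRUE, TRUE)
    } else if (cat == "recessive_hom") {
      b <- build_variant_block(idx, ped, genes,
                               sample(bi_genes, k, replace = TRUE),
                               rep("missense_variant", k), rep(NA_real_, k),
                               "inherited", 1)  # hom_rate 1 => hom child
      add(b, cat, TRUE, TRUE)
    } else if (cat %in% c("compound_het_trans", "compound_het_cis")) {
      gpick <- sample(bi_genes, k, replace = TRUE)
      b1 <- build_variant_block(idx, ped, genes, gpick,
                                rep("missense_variant", k), rep(NA_real_, k),
                                "inherited", 0)
      b2 <- build_variant_block(idx, ped, genes, gpick,
                                rep("missense_variant", k), rep(NA_real_, k),
                                "inherited", 0)
      b2$position <- b1$position + 11L
      b1$mother_gt <- 1L; b1$father_gt <- 0L
      if (cat == "compound_het_trans") {
        b2$mother_gt <- 0L; b2$father_gt <- 1L
      } else {
        b2$mother_gt <- 1L; b2$father_gt <- 0L
      }
      add(dplyr::bind_rows(b1, b2), cat,
          expect_trio = cat == "compound_het_trans", expect_po = TRUE,
          pair = TRUE)
    } else if (cat == "common_control") {
      b <- build_variant_block(idx, ped, genes,
                               sample(mono_genes, k, replace = TRUE),
                               rep("missense_variant", k),
                               round(stats::runif(k, 0.02, 0.2), 6),
                               "de_novo", 0)
      add(b, cat, FALSE, FALSE)
    } else if (cat == "nonfunctional_control") {
      b <- build_variant_block(idx, ped, genes,
                               sample(mono_genes, k, replace = TRUE),
                               rep("synonymous_variant", k),
                               rep(NA_real_, k), "de_novo", 0)
      add(b, cat, FALSE, FALSE)
    }
  }
  list(variants = dplyr::bind_rows(out_v), truth = out_t)
}

simulate_cnvs <- function(params, ped, genes) {
  n <- params$n_trios
  empty <- tibble::tibble(
    proband_id = character(0), chromosome = character(0), start = integer(0),
    end = integer(0), cnv_type = character(0),
    inheritance_status = character(0), overlapped_genes = character(0),
    fully_contained_genes = character(0), maf = double(0))
  if (n == 0 || params$cnv_count_per_proband == 0) return(empty)
  counts <- stats::rpois(n, params$cnv_count_per_proband)
  idx <- rep(seq_len(n), counts)
  m <- length(idx)
  if (!m) return(empty)
  chroms <- sample(as.character(1:22), m, replace = TRUE)
  len <- round(10^stats::runif(m, params$cnv_size_log10_range[1],
                               params$cnv_size_log10_range[2]))
  start <- as.integer(1 + floor(stats::runif(m) * 5e7))
  genes_by_chrom <- split(genes$gene, genes$chromosome)
  n_genes <- stats::rpois(m, 1.2)
  pick_genes <- vapply(seq_len(m), function(i) {
    pool <- genes_by_chrom[[chroms[i]]]
    k <- min(n_genes[i], length(pool))
    if (k == 0) return("")
    paste(sort(sample(pool, k)), collapse = ";")
  }, character(1))
  contained <- vapply(pick_genes, function(gs) {
    if (gs == "") return("")
    g <- strsplit(gs, ";", fixed = TRUE)[[1]]
    keep <- g[stats::runif(length(g)) < 0.5]
    paste(keep, collapse = ";")
  }, character(1), USE.NAMES = FALSE)
  tibble::tibble(
    proband_id = ped$proband_id[idx],
    chromosome = chroms,
    start = start,
    end = as.integer(start + len - 1),
    cnv_type = sample(c("loss", "gain"), m, replace = TRUE),
    inheritance_status = sample(
      c("de_novo", "inherited_segregating", "inherited_non_segregating",
        "unknown"), m, replace = TRUE, prob = c(0.1, 0.1, 0.4, 0.4)),
    overlapped_genes = pick_genes,
    fully_contained_genes = contained,
    maf = ifelse(stats::runif(m) < 0.7, NA_real_,
                 round(stats::runif(m, 0, 0.05), 6)))
}

#' Evaluate triage output against a spike-in truth table
#'
#' For single-variant spikes a truth row counts as flagged when its variant
#' appears in any flagged event; for pair spikes both members must share one
#' event. Sensitivity for positive spikes and the flagged fraction for
#' negative controls follow directly.
#'
#' @param candidates Candidate tibble from [triage_cohort()].
#' @param truth Truth tibble from [simulate_cohort()].
#' @param mode Which expectation column to compare against.
#' @return Tibble per spike category: `n`, `n_flagged`, `flagged_fraction`
#'   and `expected_fraction`.
#' @export
truth_eval <- function(candidates, truth,
                       mode = c("trio", "proband_only")) {
  mode <- match.arg(gsub("-", "_", mode), c("trio", "proband_only"))
  known <- attr(candidates, "proband_ids")
  if (!is.null(known) && nrow(truth) &&
      length(setdiff(truth$proband_id, known))) {
    stop("truth table refers to probands outside the triaged cohort",
         call. = FALSE)
  }
  flagged_row <- function(ids) {
    ids <- strsplit(ids, ";", fixed = TRUE)[[1]]
    if (length(ids) == 1) {
      ids %in% candidates$variant_id
    } else {
      ev1 <- candidates$event_id[candidates$variant_id == ids[1]]
      ev2 <- candidates$event_id[candidates$variant_id == ids[2]]
      length(intersect(ev1, ev2)) > 0
    }
  }
  truth$flagged <- vapply(truth$variant_ids, flagged_row, logical(1),
                          USE.NAMES = FALSE)
  expect <- if (mode == "trio") truth$expect_trio else
    truth$expect_proband_only
  truth$expected <- expect
  dplyr::summarise(
    dplyr::group_by(truth, .data$spike_category),
    n = dplyr::n(),
    n_flagged = sum(.data$flagged),
    flagged_fraction = mean(.data$flagged),
    expected_fraction = mean(.data$expected),
    .groups = "drop")
}

#' Write a synthetic cohort to disk
#'
#' Emits one VCF per trio under `dir/vcf/`, a PED file, the family-history
#' sidecar, the panel TSV, the CNV table, the truth table and the
#' parameters as YAML. All files are plain text and parse back through the
#' package readers.
#'
#' @param cohort A `trio_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "vcf"), recursive = TRUE, showWarnings = FALSE)
  write_ped(cohort$pedigree, file.path(dir, "pedigree.ped"),
            file.path(dir, "family_history.tsv"))
  write_panel(cohort$panel, file.path(dir, "panel.tsv"))
  readr::write_tsv(cohort$cnvs, file.path(dir, "cnvs.tsv"), progress = FALSE)
  readr::write_tsv(cohort$truth, file.path(dir, "truth.tsv"),
                   progress = FALSE)
  p <- cohort$params
  yaml::write_yaml(p[setdiff(names(p), "spike_in")],
                   file.path(dir, "params.yaml"))
  for (i in seq_len(nrow(cohort$pedigree))) {
    trio <- cohort$pedigree[i, ]
    v <- cohort$variants[cohort$variants$proband_id == trio$proband_id, ]
    write_trio_vcf(v, file.path(dir, "vcf",
                                paste0(trio$family_id, ".vcf")), trio)
  }
  invisible(dir)
}

#' Read a written synthetic cohort back into memory
#'
#' @param dir Directory written by [write_cohort()].
#' @return List with `pedigree`, `panel`, `variants`, `cnvs`, `truth`.
#' @export
read_cohort <- function(dir) {
  ped <- read_ped(file.path(dir, "pedigree.ped"),
                  file.path(dir, "family_history.tsv"))
  panel <- load_panel(file.path(dir, "panel.tsv"))
  cnvs <- readr::read_tsv(file.path(dir, "cnvs.tsv"), show_col_types = FALSE,
                          progress = FALSE,
                          col_types = readr::cols(
                            proband_id = readr::col_character(),
                            chromosome = readr::col_character(),
                            overlapped_genes = readr::col_character(),
                            fully_contained_genes = readr::col_character()))
  truth <- readr::read_tsv(file.path(dir, "truth.tsv"),
                           show_col_types = FALSE, progress = FALSE)
  vcfs <- list.files(file.path(dir, "vcf"), pattern = "\\.vcf$",
                     full.names = TRUE)
  fam <- sub("\\.vcf$", "", basename(vcfs))
  variants <- dplyr::bind_rows(lapply(seq_along(vcfs), function(i) {
    trio <- ped[ped$family_id == fam[i], ]
    read_trio_vcf(vcfs[i], trio)
  }))
  if (!is.null(cnvs$overlapped_genes)) {
    cnvs$overlapped_genes[is.na(cnvs$overlapped_genes)] <- ""
    cnvs$fully_contained_genes[is.na(cnvs$fully_contained_genes)] <- ""
  }
  list(pedigree = ped, panel = panel, variants = variants, cnvs = cnvs,
       truth = truth)
}
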