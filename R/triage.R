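# The automated triage cascade: frequency -> functional consequence ->
# panel-gene restriction -> genotype/allelic-requirement matching (including
# compound heterozygotes) -> inheritance rules, plus the CNV dosage and size
# rules. The filters are a pure conjunction, so their order does not change
# the flagged set; the order fixed here fixes the reason trails.

#' Triage filter configuration
#'
#' @param maf_threshold Keep variants with minor allele frequency at or below
#'   this value (missing frequency is treated as rare). Default 0.01 (1%).
#' @param dominant_maf_threshold Optional stricter threshold applied to
#'   candidates matched against dominant-acting (monoallelic or X-linked
#'   dominant) panel entries, e.g. 0.001; `NULL` uses `maf_threshold`.
#' @param cnv_loss_min_bp,cnv_gain_min_bp Strict minimum lengths for genic
#'   copy-number losses/gains that are de novo or segregate with disease.
#' @param cnv_unknown_inheritance_min_bp Strict minimum length for any genic
#'   CNV of unknown inheritance.
#' @param apply_x_missense_exclusion Drop inherited missense variants on the
#'   X chromosome unless the patient has a family history of developmental
#'   disorders or the variant is present in a known-pathogenic database
#'   (trio mode only).
#' @param xld_require_segregation Whether X-linked dominant candidates are
#'   subject to the same segregation rule as autosomal dominant candidates
#'   in trio mode.
#' @param benign_missense_score_cutoff Optional PolyPhen-style score below
#'   which inherited missense candidates are excluded as predicted benign;
#'   `NULL` (default) disables the rule.
#' @param mode `"trio"` (parental genotypes and affected status are used) or
#'   `"proband_only"`.
#' @param consequence_table Severity table from [consequence_table()].
#' @return List of class `filter_config`.
#' @export
filter_config <- function(maf_threshold = 0.01,
                          dominant_maf_threshold = NULL,
                          cnv_loss_min_bp = 100000L,
                          cnv_gain_min_bp = 250000L,
                          cnv_unknown_inheritance_min_bp = 500000L,
                          apply_x_missense_exclusion = TRUE,
                          xld_require_segregation = TRUE,
                          benign_missense_score_cutoff = NULL,
                          mode = c("trio", "proband_only"),
                          consequence_table = triotriage::consequence_table()) {
  mode <- gsub("-", "_", mode)
  mode <- match.arg(mode, c("trio", "proband_only"))
  stopifnot(maf_threshold > 0, cnv_loss_min_bp > 0, cnv_gain_min_bp > 0,
            cnv_unknown_inheritance_min_bp > 0)
  if (cnv_loss_min_bp > cnv_unknown_inheritance_min_bp) {
    stop("cnv_loss_min_bp must not exceed cnv_unknown_inheritance_min_bp",
         call. = FALSE)
  }
  structure(list(
    maf_threshold = maf_threshold,
    dominant_maf_threshold = dominant_maf_threshold,
    cnv_loss_min_bp = cnv_loss_min_bp,
    cnv_gain_min_bp = cnv_gain_min_bp,
    cnv_unknown_inheritance_min_bp = cnv_unknown_inheritance_min_bp,
    apply_x_missense_exclusion = apply_x_missense_exclusion,
    xld_require_segregation = xld_require_segregation,
    benign_missense_score_cutoff = benign_missense_score_cutoff,
    mode = mode,
    consequence_table = consequence_table
  ), class = "filter_config")
}

#' Population-frequency filter
#'
#' @param maf Numeric vector of minor allele frequencies (`NA` = unknown,
#'   treated as rare and kept).
#' @param config A [filter_config()].
#' @param dominant_context Apply the (optionally stricter) dominant
#'   threshold.
#' @return Logical vector, `TRUE` = keep. The boundary is inclusive
#'   (MAF equal to the threshold is kept).
#' @export
frequency_filter <- function(maf, config = filter_config(),
                             dominant_context = FALSE) {
  thr <- config$maf_threshold
  if (dominant_context && !is.null(config$dominant_maf_threshold)) {
    thr <- config$dominant_maf_threshold
  }
  is.na(maf) | maf <= thr
}

#' X-linked inherited-missense exclusion
#'
#' Inherited missense variants on the X chromosome have low prior
#' probability of causality and are excluded unless the patient has a family
#' history of developmental disorders or the variant is already present in a
#' known-pathogenic database. De novo X missense variants are retained.
#'
#' @param consequence Consequence terms (normalised).
#' @param inheritance Inheritance calls.
#' @param family_history Logical vector.
#' @param known_pathogenic Logical vector.
#' @return Logical vector, `TRUE` = exclude.
#' @export
x_missense_exclusion <- function(consequence, inheritance, family_history,
                                 known_pathogenic) {
  normalise_consequence(consequence) == "missense_variant" &
    inheritance %in% inherited_modes() &
    !(family_history %in% TRUE) &
    !(known_pathogenic %in% TRUE)
}

# Can two het variants lie on opposite copies of the gene? A de novo member
# may sit on either copy; unknown phase (uninformative) is permissive.
pair_in_trans <- function(mode1, mode2) {
  if (mode1 %in% c("de_novo", "uninformative") ||
      mode2 %in% c("de_novo", "uninformative")) {
    return(TRUE)
  }
  set_of <- function(m) switch(m,
    maternal = "M", paternal = "P",
    inherited_ambiguous = c("M", "P"), character(0))
  s1 <- set_of(mode1)
  s2 <- set_of(mode2)
  ("M" %in% s1 && "P" %in% s2) || ("P" %in% s1 && "M" %in% s2)
}

#' Find compound-heterozygote candidate pairs in one gene
#'
#' In trio mode a pair qualifies only if the two variants can lie on
#' different copies of the gene: one maternal and one paternal, a de novo
#' member paired with any other member, or members of unknown phase. Pairs
#' inherited from the same parent (cis) are excluded. In proband-only mode
#' every het pair is a candidate.
#'
#' @param variants Variant tibble of child-heterozygous, frequency/function
#'   filtered variants in a single gene for one proband, carrying an
#'   `inheritance` column (see [classify_inheritance()]); rows classified
#'   `mendelian_error` are ignored.
#' @param config A [filter_config()]; only `mode` is consulted.
#' @return Tibble with columns `variant_id_1`, `variant_id_2`, one row per
#'   qualifying pair (each unordered pair at most once).
#' @export
find_compound_hets <- function(variants, config = filter_config()) {
  v <- tibble::as_tibble(variants)
  if (!"inheritance" %in% names(v)) v$inheritance <- "uninformative"
  v <- v[v$inheritance != "mendelian_error", , drop = FALSE]
  v <- v[!duplicated(v$variant_id), , drop = FALSE]
  empty <- tibble::tibble(variant_id_1 = character(0),
                          variant_id_2 = character(0))
  if (nrow(v) < 2) return(empty)
  idx <- utils::combn(nrow(v), 2)
  keep <- vapply(seq_len(ncol(idx)), function(k) {
    if (config$mode != "trio") return(TRUE)
    pair_in_trans(v$inheritance[idx[1, k]], v$inheritance[idx[2, k]])
  }, logical(1))
  idx <- idx[, keep, drop = FALSE]
  if (!ncol(idx)) return(empty)
  tibble::tibble(variant_id_1 = v$variant_id[idx[1, ]],
                 variant_id_2 = v$variant_id[idx[2, ]])
}

#' Does a gene's genotype configuration satisfy a panel entry?
#'
#' Monoallelic (and X-linked dominant) entries are satisfied by any single
#' het or hom-alt variant; biallelic entries by a hom-alt variant or at
#' least two het variants (a compound-het candidate); X-linked recessive
#' entries by a hemizygous alt in males, or a hom-alt/compound-het
#' configuration in females.
#'
#' @param variants Variant tibble of filtered variants in the entry's gene
#'   for one proband.
#' @param entry One-row tibble (or list) with `allelic_requirement`.
#' @param trio One-row trio tibble (for proband sex).
#' @return Single logical.
#' @export
genotype_matches_requirement <- function(variants, entry, trio) {
  v <- tibble::as_tibble(variants)
  if (!nrow(v)) return(FALSE)
  male <- trio$proband_sex == "male"
  het <- sum(v$child_gt == 1 & v$child_ploidy == 2, na.rm = TRUE)
  hom <- any(v$child_gt == 2 & v$child_ploidy == 2, na.rm = TRUE)
  hemi <- any(v$child_gt >= 1 & v$child_ploidy == 1, na.rm = TRUE)
  switch(entry$allelic_requirement,
    monoallelic = ,
    x_linked_dominant = any(v$child_gt >= 1, na.rm = TRUE),
    biallelic = hom || het >= 2,
    x_linked_recessive = if (male) hemi else hom || het >= 2,
    FALSE)
}

#' Copy-number variant size rule
#'
#' Flags large, rare genic CNVs that do not match the gene panel: losses
#' longer than the loss threshold and gains longer than the gain threshold
#' when the event is de novo or segregates with disease, and any genic CNV
#' longer than the unknown-inheritance threshold when inheritance is
#' unclear. All thresholds are strict; inherited events that do not
#' segregate are never flagged by this rule. Length is `end - start + 1`
#' (1-based closed intervals).
#'
#' @param cnvs CNV tibble with `start`, `end`, `cnv_type`
#'   (`"loss"`/`"gain"`), `inheritance_status` (`de_novo`,
#'   `inherited_segregating`, `inherited_non_segregating`, `unknown`) and
#'   `overlapped_genes` (semicolon-joined, `""`/`NA` = non-genic).
#' @param config A [filter_config()].
#' @return Logical vector, `TRUE` = flag.
#' @export
cnv_size_filter <- function(cnvs, config = filter_config()) {
  len <- cnvs$end - cnvs$start + 1
  genic <- !is.na(cnvs$overlapped_genes) & cnvs$overlapped_genes != ""
  seg <- cnvs$inheritance_status %in% c("de_novo", "inherited_segregating")
  (genic & seg & ((cnvs$cnv_type == "loss" & len > config$cnv_loss_min_bp) |
                  (cnvs$cnv_type == "gain" & len > config$cnv_gain_min_bp))) |
    (genic & cnvs$inheritance_status == "unknown" &
       len > config$cnv_unknown_inheritance_min_bp)
}

#' Match copy-number variants against the gene panel
#'
#' Losses are considered only when they fully contain a reportable gene in
#' which loss-of-function or dominant-negative mutations are known; gains
#' only when they overlap a reportable gene in which increased gene dosage
#' is the known mechanism.
#'
#' @param cnvs CNV tibble (rare events; apply [frequency_filter()] first)
#'   with `overlapped_genes` and `fully_contained_genes` semicolon-joined
#'   columns.
#' @param panel A [gene_panel()].
#' @return Tibble of CNV-entry matches: the CNV columns plus `gene` and the
#'   matched `mutation_consequence`.
#' @export
cnv_panel_filter <- function(cnvs, panel) {
  c0 <- tibble::as_tibble(cnvs)
  entries <- tibble::as_tibble(panel)
  entries <- entries[entries$reportable %in% TRUE, ]
  explode <- function(tbl, col) {
    out <- tidyr::separate_rows(tbl, dplyr::all_of(col), sep = ";")
    out[!is.na(out[[col]]) & out[[col]] != "", , drop = FALSE]
  }
  loss <- c0[c0$cnv_type == "loss", , drop = FALSE]
  gain <- c0[c0$cnv_type == "gain", , drop = FALSE]
  loss_g <- explode(loss, "fully_contained_genes")
  gain_g <- explode(gain, "overlapped_genes")
  loss_m <- dplyr::inner_join(
    loss_g,
    entries[entries$mutation_consequence %in%
              c("loss_of_function", "dominant_negative"),
            c("gene_symbol", "mutation_consequence")],
    by = c(fully_contained_genes = "gene_symbol"),
    relationship = "many-to-many")
  loss_m$gene <- loss_m$fully_contained_genes
  gain_m <- dplyr::inner_join(
    gain_g,
    entries[entries$mutation_consequence == "increased_gene_dosage",
            c("gene_symbol", "mutation_consequence")],
    by = c(overlapped_genes = "gene_symbol"),
    relationship = "many-to-many")
  gain_m$gene <- gain_m$overlapped_genes
  shared <- intersect(names(loss_m), names(gain_m))
  dplyr::bind_rows(loss_m[shared], gain_m[shared])
}

chrom_rank <- function(chrom) {
  lev <- c(as.character(1:22), "X", "Y", "MT")
  r <- match(toupper(sub("^chr", "", chrom)), lev)
  ifelse(is.na(r), length(lev) + 1L, r)
}

candidate_columns <- function() {
  c("proband_id", "category", "payload_type", "event_id", "pair_member",
    "chromosome", "position", "end", "ref", "alt", "gene", "consequence",
    "maf", "genotype", "inheritance", "allelic_requirement",
    "mutation_consequence", "known_pathogenic", "sift", "polyphen",
    "phenotype_note", "reason_trail", "variant_id")
}

empty_candidates <- function() {
  tibble::tibble(
    proband_id = character(0), category = character(0),
    payload_type = character(0), event_id = character(0),
    pair_member = integer(0), chromosome = character(0),
    position = integer(0), end = integer(0), ref = character(0),
    alt = character(0), gene = character(0), consequence = character(0),
    maf = double(0), genotype = character(0), inheritance = character(0),
    allelic_requirement = character(0), mutation_consequence = character(0),
    known_pathogenic = logical(0), sift = double(0), polyphen = double(0),
    phenotype_note = character(0), reason_trail = character(0),
    variant_id = character(0))
}

genotype_label <- function(gt, ploidy) {
  dplyr::case_when(
    is.na(gt) ~ NA_character_,
    ploidy == 1L & gt >= 1 ~ "hemizygous",
    ploidy == 1L ~ "hemizygous_ref",
    gt == 2L ~ "homozygous",
    gt == 1L ~ "heterozygous",
    TRUE ~ "reference")
}

snv_candidate_rows <- function(hits, category, rule_tags) {
  if (!nrow(hits)) return(empty_candidates())
  tibble::tibble(
    proband_id = hits$proband_id,
    category = category,
    payload_type = "snv",
    event_id = paste(hits$proband_id, hits$gene, category, hits$chromosome,
                     hits$position, hits$ref, hits$alt, sep = "|"),
    pair_member = NA_integer_,
    chromosome = hits$chromosome,
    position = hits$position,
    end = NA_integer_,
    ref = hits$ref,
    alt = hits$alt,
    gene = hits$gene,
    consequence = hits$consequence,
    maf = hits$maf,
    genotype = genotype_label(hits$child_gt, hits$child_ploidy),
    inheritance = hits$inheritance,
    allelic_requirement = hits$allelic_requirement,
    mutation_consequence = hits$mutation_consequence,
    known_pathogenic = hits$known_pathogenic,
    sift = hits$sift,
    polyphen = hits$polyphen,
    phenotype_note = hits$required_phenotype_terms,
    reason_trail = paste("frequency", "functional",
                         paste0("panel_gene:", hits$gene),
                         paste0("requirement:", hits$allelic_requirement),
                         paste0("inheritance:", hits$inheritance),
                         rule_tags, sep = ">"),
    variant_id = hits$variant_id)
}

comphet_candidate_rows <- function(members, category, trio_mode) {
  if (!nrow(members)) return(empty_candidates())
  groups <- split(members,
                  paste(members$proband_id, members$gene, sep = "\r"))
  out <- lapply(groups, function(g) {
    g <- g[order(g$position, g$ref, g$alt), , drop = FALSE]
    cfg <- filter_config(mode = if (trio_mode) "trio" else "proband_only")
    pairs <- find_compound_hets(g, cfg)
    if (!nrow(pairs)) return(NULL)
    rows <- lapply(seq_len(nrow(pairs)), function(k) {
      m <- g[match(c(pairs$variant_id_1[k], pairs$variant_id_2[k]),
                   g$variant_id), , drop = FALSE]
      r <- snv_candidate_rows(
        m, category,
        if (trio_mode) "comphet_trans" else "comphet_pair")
      r$payload_type <- "comphet_member"
      r$pair_member <- 1:2
      r$event_id <- paste(m$proband_id[1], m$gene[1], category, "pair",
                          min(m$variant_id), max(m$variant_id), sep = "|")
      r
    })
    dplyr::bind_rows(rows)
  })
  dplyr::bind_rows(out)
}

#' Run the triage cascade over a cohort
#'
#' Applies, in order: population-frequency filter, functional-consequence
#' filter, panel-gene restriction, genotype/allelic-requirement matching
#' (including compound-heterozygote detection) and, in trio mode, the
#' inheritance rules (dominant candidates must be de novo or inherited from
#' an affected parent; recessive homozygotes require consistent biparental
#' transmission; X-linked inherited missense variants are excluded unless
#' there is a family history or a known-pathogenic database record).
#' Rare copy-number variants are matched against the panel by mechanism
#' (losses containing loss-of-function/dominant-negative genes; gains
#' overlapping increased-dosage genes) and non-panel genic CNVs are flagged
#' by the size rule. Variants classified `mendelian_error` are diverted to a
#' diagnostics table (attribute `"mendelian_errors"`), not flagged.
#'
#' In trio mode, variants whose parental genotypes are missing fall back to
#' proband-only semantics for the inheritance-dependent rules (logged via
#' `message()`).
#'
#' @param variants Variant tibble for the whole cohort
#'   (see [as_variant_tbl()]); may be `NULL`.
#' @param trios Trio tibble from [read_ped()].
#' @param panel A [gene_panel()].
#' @param cnvs Optional CNV tibble (`proband_id`, `chromosome`, `start`,
#'   `end`, `cnv_type`, `inheritance_status`, `overlapped_genes`,
#'   `fully_contained_genes`, `maf`).
#' @param config A [filter_config()].
#' @param phenotypes Optional tibble (`proband_id`, `term`) of patient
#'   phenotype terms; candidates in panel entries with required phenotype
#'   terms are annotated (`phenotype_match`/`phenotype_mismatch`), never
#'   removed.
#' @return Tibble of flagged candidates, one row per flagged variant
#'   occurrence (compound-het pairs contribute two rows sharing an
#'   `event_id`), deterministically ordered. Attributes: `mendelian_errors`
#'   (diagnostics tibble) and `proband_ids`.
#' @export
triage_cohort <- function(variants, trios, panel, cnvs = NULL,
                          config = filter_config(), phenotypes = NULL) {
  if (!inherits(panel, "gene_panel")) panel <- gene_panel(panel)
  trio_mode <- config$mode == "trio"
  snv_cand <- empty_candidates()
  mend_tbl <- NULL

  if (!is.null(variants) && nrow(variants)) {
    v <- classify_inheritance(variants, trios)
    idx <- match(v$proband_id, trios$proband_id)
    v$family_history <- trios$family_history[idx] %in% TRUE
    v$mother_affected <- trios$mother_affected[idx]
    v$father_affected <- trios$father_affected[idx]
    if (!trio_mode) v$inheritance <- "uninformative"

    v <- v[frequency_filter(v$maf, config) &
             is_functional(v$consequence, config$consequence_table), ,
           drop = FALSE]
    mend_tbl <- v[v$inheritance == "mendelian_error", , drop = FALSE]
    v <- v[v$inheritance != "mendelian_error", , drop = FALSE]
    if (trio_mode) {
      n_fallback <- sum(v$inheritance == "uninformative" & v$child_gt >= 1,
                        na.rm = TRUE)
      if (n_fallback > 0) {
        message(n_fallback, " variant(s) lack parental genotypes; ",
                "inheritance-dependent rules fall back to proband-only ",
                "semantics for them")
      }
    }

    vg <- tidyr::separate_rows(v, "gene", sep = ";")
    vg <- vg[!is.na(vg$gene) & vg$gene != "", , drop = FALSE]
    entries <- tibble::as_tibble(panel)
    entries <- entries[entries$reportable %in% TRUE &
                         entries$mutation_consequence != "increased_gene_dosage",
                       c("gene_symbol", "allelic_requirement",
                         "mutation_consequence", "required_phenotype_terms")]
    hits <- dplyr::inner_join(vg, entries, by = c(gene = "gene_symbol"),
                              relationship = "many-to-many")

    if (trio_mode && isTRUE(config$apply_x_missense_exclusion) && nrow(hits)) {
      drop <- hits$on_x &
        x_missense_exclusion(hits$consequence, hits$inheritance,
                             hits$family_history, hits$known_pathogenic)
      hits <- hits[!drop, , drop = FALSE]
    }
    if (!is.null(config$benign_missense_score_cutoff) && nrow(hits)) {
      drop <- hits$consequence == "missense_variant" &
        hits$inheritance %in% inherited_modes() &
        !is.na(hits$polyphen) &
        hits$polyphen < config$benign_missense_score_cutoff
      hits <- hits[!drop, , drop = FALSE]
    }

    # collapse multiple mechanism entries for the same gene/requirement
    if (nrow(hits)) {
      mech <- dplyr::summarise(
        dplyr::group_by(hits, .data$proband_id, .data$variant_id, .data$gene,
                        .data$allelic_requirement),
        mutation_consequence = paste(sort(unique(.data$mutation_consequence)),
                                     collapse = ";"),
        required_phenotype_terms = {
          terms <- unique(stats::na.omit(.data$required_phenotype_terms))
          if (length(terms)) paste(terms, collapse = ";") else NA_character_
        },
        .groups = "drop")
      base <- dplyr::distinct(
        hits[setdiff(names(hits),
                     c("mutation_consequence", "required_phenotype_terms"))],
        .data$proband_id, .data$variant_id, .data$gene,
        .data$allelic_requirement, .keep_all = TRUE)
      hits <- dplyr::left_join(
        base, mech,
        by = c("proband_id", "variant_id", "gene", "allelic_requirement"))
    }

    x_tag <- if (trio_mode && isTRUE(config$apply_x_missense_exclusion)) {
      "x_missense_check"
    } else {
      NULL
    }
    tag <- function(hits, extra = NULL) {
      # rule tags appended per-row after the inheritance step
      tags <- rep("", nrow(hits))
      if (!is.null(x_tag)) tags <- ifelse(hits$on_x, x_tag, tags)
      if (!is.null(extra)) {
        tags <- ifelse(tags == "", extra, paste(tags, extra, sep = ">"))
      }
      ifelse(tags == "", "flagged", paste0(tags, ">flagged"))
    }

    # dominant-acting entries
    dom <- hits[hits$allelic_requirement %in%
                  c("monoallelic", "x_linked_dominant") &
                  !is.na(hits$child_gt) & hits$child_gt >= 1, , drop = FALSE]
    dom <- dom[frequency_filter(dom$maf, config, dominant_context = TRUE), ,
               drop = FALSE]
    if (trio_mode && nrow(dom)) {
      seg <- segregates_with_disease(dom$inheritance, dom$mother_affected,
                                     dom$father_affected)
      keep <- seg | dom$inheritance == "uninformative"
      if (!isTRUE(config$xld_require_segregation)) {
        keep <- keep | (dom$allelic_requirement == "x_linked_dominant" &
                          dom$inheritance %in% inherited_modes())
      }
      dom <- dom[keep, , drop = FALSE]
    }
    dom_ad <- dom[dom$allelic_requirement == "monoallelic", , drop = FALSE]
    dom_xl <- dom[dom$allelic_requirement == "x_linked_dominant", ,
                  drop = FALSE]

    # recessive homozygotes: trio mode requires each parent to carry >= 1
    # alt allele, which is exactly the `biparental` call (violations are
    # mendelian_error and already diverted); de novo homozygotes are kept
    hom <- hits[hits$allelic_requirement == "biallelic" &
                  !is.na(hits$child_gt) & hits$child_gt == 2 &
                  hits$child_ploidy == 2, , drop = FALSE]
    if (trio_mode && nrow(hom)) {
      hom <- hom[hom$inheritance %in%
                   c("biparental", "de_novo", "uninformative"), ,
                 drop = FALSE]
    }

    # X-linked recessive
    xlr <- hits[hits$allelic_requirement == "x_linked_recessive", ,
                drop = FALSE]
    xlr_hemi <- xlr[xlr$proband_male & xlr$child_ploidy == 1 &
                      !is.na(xlr$child_gt) & xlr$child_gt >= 1, ,
                    drop = FALSE]
    if (trio_mode && nrow(xlr_hemi)) {
      xlr_hemi <- xlr_hemi[xlr_hemi$inheritance %in%
                             c("maternal", "de_novo", "uninformative"), ,
                           drop = FALSE]
    }
    xlr_hom <- xlr[!xlr$proband_male & !is.na(xlr$child_gt) &
                     xlr$child_gt == 2, , drop = FALSE]
    if (trio_mode && nrow(xlr_hom)) {
      xlr_hom <- xlr_hom[xlr_hom$inheritance %in%
                           c("biparental", "de_novo", "uninformative"), ,
                         drop = FALSE]
    }

    # compound-het members
    ch_ar <- hits[hits$allelic_requirement == "biallelic" &
                    !is.na(hits$child_gt) & hits$child_gt == 1 &
                    hits$child_ploidy == 2, , drop = FALSE]
    ch_xlr <- xlr[!xlr$proband_male & !is.na(xlr$child_gt) &
                    xlr$child_gt == 1, , drop = FALSE]

    snv_cand <- dplyr::bind_rows(
      snv_candidate_rows(dom_ad, "autosomal_dominant", tag(dom_ad)),
      snv_candidate_rows(dom_xl, "x_linked_dominant", tag(dom_xl)),
      snv_candidate_rows(hom, "autosomal_recessive_homozygous", tag(hom)),
      snv_candidate_rows(xlr_hemi, "x_linked_recessive", tag(xlr_hemi)),
      snv_candidate_rows(xlr_hom, "x_linked_recessive", tag(xlr_hom)),
      comphet_candidate_rows(ch_ar, "autosomal_recessive_compound_het",
                             trio_mode),
      comphet_candidate_rows(ch_xlr, "x_linked_recessive", trio_mode))
  }

  cnv_cand <- empty_candidates()
  if (!is.null(cnvs) && nrow(cnvs)) {
    c0 <- tibble::as_tibble(cnvs)
    if (!"maf" %in% names(c0)) c0$maf <- NA_real_
    stopifnot(all(c0$start <= c0$end))
    c0$cnv_id <- paste(c0$proband_id, c0$chromosome, c0$start, c0$end,
                       c0$cnv_type, sep = ":")
    c0 <- c0[frequency_filter(c0$maf, config), , drop = FALSE]
    pm <- cnv_panel_filter(c0, panel)
    if (nrow(pm)) {
      cnv_panel_cand <- tibble::tibble(
        proband_id = pm$proband_id,
        category = "cnv_panel",
        payload_type = "cnv",
        event_id = paste(pm$cnv_id, pm$gene, sep = "|"),
        pair_member = NA_integer_,
        chromosome = pm$chromosome,
        position = as.integer(pm$start),
        end = as.integer(pm$end),
        ref = NA_character_,
        alt = pm$cnv_type,
        gene = pm$gene,
        consequence = NA_character_,
        maf = pm$maf,
        genotype = NA_character_,
        inheritance = pm$inheritance_status,
        allelic_requirement = NA_character_,
        mutation_consequence = pm$mutation_consequence,
        known_pathogenic = FALSE,
        sift = NA_real_, polyphen = NA_real_,
        phenotype_note = NA_character_,
        reason_trail = paste0("frequency>cnv_panel:", pm$cnv_type, ":",
                              pm$mutation_consequence, ":", pm$gene,
                              ">flagged"),
        variant_id = pm$cnv_id)
      cnv_panel_cand <- dplyr::distinct(
        cnv_panel_cand, .data$event_id, .keep_all = TRUE)
    } else {
      cnv_panel_cand <- empty_candidates()
    }
    size_ok <- cnv_size_filter(c0, config)
    size_rows <- c0[size_ok & !(c0$cnv_id %in% cnv_panel_cand$variant_id), ,
                    drop = FALSE]
    if (nrow(size_rows)) {
      len <- size_rows$end - size_rows$start + 1
      cnv_size_cand <- tibble::tibble(
        proband_id = size_rows$proband_id,
        category = "cnv_size_rule",
        payload_type = "cnv",
        event_id = size_rows$cnv_id,
        pair_member = NA_integer_,
        chromosome = size_rows$chromosome,
        position = as.integer(size_rows$start),
        end = as.integer(size_rows$end),
        ref = NA_character_,
        alt = size_rows$cnv_type,
        gene = size_rows$overlapped_genes,
        consequence = NA_character_,
        maf = size_rows$maf,
        genotype = NA_character_,
        inheritance = size_rows$inheritance_status,
        allelic_requirement = NA_character_,
        mutation_consequence = NA_character_,
        known_pathogenic = FALSE,
        sift = NA_real_, polyphen = NA_real_,
        phenotype_note = NA_character_,
        reason_trail = paste0("frequency>cnv_size:",
                              size_rows$inheritance_status, ":",
                              size_rows$cnv_type, ":", len, "bp>flagged"),
        variant_id = size_rows$cnv_id)
    } else {
      cnv_size_cand <- empty_candidates()
    }
    cnv_cand <- dplyr::bind_rows(cnv_panel_cand, cnv_size_cand)
  }

  cand <- dplyr::bind_rows(snv_cand, cnv_cand)
  cand <- annotate_phenotype_match(cand, phenotypes)
  cand <- cand[order(cand$proband_id, chrom_rank(cand$chromosome),
                     cand$position, cand$category, cand$event_id,
                     cand$pair_member), , drop = FALSE]
  cand <- cand[, candidate_columns()]
  attr(cand, "mendelian_errors") <-
    if (is.null(mend_tbl)) tibble::tibble() else mend_tbl
  attr(cand, "proband_ids") <- trios$proband_id
  cand
}

# Required-phenotype annotation (the manual phenotype review is out of
# scope; candidates are annotated, never removed).
annotate_phenotype_match <- function(cand, phenotypes) {
  required <- cand$phenotype_note  # holds required terms at this point
  note <- rep(NA_character_, nrow(cand))
  has_req <- !is.na(required) & required != ""
  if (!is.null(phenotypes) && any(has_req)) {
    terms_by_proband <- split(phenotypes$term, phenotypes$proband_id)
    note[has_req] <- vapply(which(has_req), function(i) {
      req <- strsplit(required[i], ";", fixed = TRUE)[[1]]
      obs <- terms_by_proband[[cand$proband_id[i]]]
      if (length(intersect(req, obs))) "phenotype_match" else
        "phenotype_mismatch"
    }, character(1))
  }
  cand$phenotype_note <- note
  cand
}

#' Triage a single proband
#'
#' Convenience wrapper around [triage_cohort()] for one trio.
#'
#' @param variants Variant tibble for the proband.
#' @param trio One-row trio tibble.
#' @param panel A [gene_panel()].
#' @param cnvs Optional CNV tibble for the proband.
#' @param config A [filter_config()].
#' @param phenotypes Optional phenotype-term tibble.
#' @return Candidate tibble (see [triage_cohort()]).
#' @export
triage_proband <- function(variants, trio, panel, cnvs = NULL,
                           config = filter_config(), phenotypes = NULL) {
  triage_cohort(variants, trio, panel, cnvs = cnvs, config = config,
                phenotypes = phenotypes)
}
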