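# Variant data model and VCF I/O.
#
# The canonical in-memory representation is one tibble row per
# (proband, site, alt allele), with trio genotypes stored as alt-allele
# counts (0/1/2, NA = missing) plus the child's ploidy (1 on X/Y in males).

#' Functional-consequence severity table
#'
#' The twelve sequence-ontology terms treated as functional
#' (protein-altering) by the triage cascade, ordered from most to least
#' severe, together with the subset regarded as loss-of-function
#' (truncating/ablating). Terms outside the list are non-functional for
#' triage purposes (e.g. synonymous, intronic, intergenic).
#'
#' @return List with character vectors `terms` (severity-ordered) and `lof`.
#' @export
consequence_table <- function() {
  terms <- c(
    "transcript_ablation",
    "splice_acceptor_variant",
    "splice_donor_variant",
    "stop_gained",
    "frameshift_variant",
    "stop_lost",
    "initiator_codon_variant",
    "transcript_amplification",
    "in_frame_insertion",
    "in_frame_deletion",
    "missense_variant",
    "coding_sequence_variant"
  )
  lof <- c(
    "transcript_ablation", "splice_donor_variant", "splice_acceptor_variant",
    "stop_gained", "frameshift_variant", "stop_lost",
    "initiator_codon_variant"
  )
  list(terms = terms, lof = lof)
}

normalise_consequence <- function(term) {
  tolower(gsub("[ \\-]+", "_", trimws(as.character(term))))
}

#' Is a consequence term functional (protein altering)?
#'
#' @param term Character vector of sequence-ontology terms; space- and
#'   underscore-delimited spellings are both accepted.
#' @param table A [consequence_table()].
#' @return Logical vector; unknown terms are `FALSE`.
#' @export
is_functional <- function(term, table = consequence_table()) {
  normalise_consequence(term) %in% table$terms
}

#' Is a consequence term loss-of-function?
#'
#' @inheritParams is_functional
#' @return Logical vector; `TRUE` only for the truncating/ablating subset.
#' @export
is_lof <- function(term, table = consequence_table()) {
  normalise_consequence(term) %in% table$lof
}

#' Maximum minor allele frequency across populations
#'
#' Aggregates per-population allele frequencies conservatively by taking the
#' maximum, so a variant common in any reference population is treated as
#' common.
#'
#' @param per_population_afs Numeric vector (possibly named) of allele
#'   frequencies in `[0, 1]`; `NA` entries are ignored.
#' @return The maximum frequency, or `NA` when no frequency is available.
#' @export
max_maf <- function(per_population_afs) {
  x <- unlist(per_population_afs, use.names = FALSE)
  x <- x[!is.na(x)]
  if (!length(x)) return(NA_real_)
  x <- as.numeric(x)
  if (any(x < 0 | x > 1)) {
    stop("allele frequencies must lie in [0, 1]", call. = FALSE)
  }
  max(x)
}

variant_columns <- function() {
  c("proband_id", "chromosome", "position", "ref", "alt", "gene",
    "consequence", "maf", "child_gt", "mother_gt", "father_gt",
    "child_ploidy", "sift", "polyphen", "known_pathogenic")
}

#' Coerce a data frame to the canonical variant table
#'
#' Fills optional annotation columns with `NA`, normalises consequence-term
#' spelling and adds a `variant_id` key. One row must describe one
#' (proband, site, alt allele); multi-allelic sites are decomposed upstream.
#'
#' @param x Data frame with at least `proband_id`, `chromosome`, `position`,
#'   `ref`, `alt`, `gene`, `consequence` and `child_gt`.
#' @return Tibble with the canonical variant columns plus `variant_id`.
#' @export
as_variant_tbl <- function(x) {
  x <- tibble::as_tibble(x)
  need <- c("proband_id", "chromosome", "position", "ref", "alt", "gene",
            "consequence", "child_gt")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols)) {
    stop("variant table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  optional <- list(maf = NA_real_, mother_gt = NA_integer_,
                   father_gt = NA_integer_, child_ploidy = 2L,
                   sift = NA_real_, polyphen = NA_real_,
                   known_pathogenic = FALSE)
  for (nm in names(optional)) {
    if (!nm %in% names(x)) x[[nm]] <- optional[[nm]]
  }
  if (any(!is.na(x$ref) & x$ref == x$alt)) {
    stop("ref and alt alleles must differ", call. = FALSE)
  }
  x$consequence <- normalise_consequence(x$consequence)
  x$chromosome <- as.character(x$chromosome)
  x$position <- as.integer(x$position)
  for (gt in c("child_gt", "mother_gt", "father_gt")) {
    x[[gt]] <- as.integer(x[[gt]])
  }
  x$child_ploidy <- as.integer(x$child_ploidy)
  x$known_pathogenic <- as.logical(x$known_pathogenic) %in% TRUE
  bad <- !is.na(x$child_gt) & x$child_gt > x$child_ploidy
  if (any(bad)) {
    stop("child alt-allele count exceeds ploidy at row(s) ",
         paste(which(bad), collapse = ", "), call. = FALSE)
  }
  x$variant_id <- paste(x$proband_id, x$chromosome, x$position,
                        x$ref, x$alt, sep = ":")
  dplyr::relocate(x, dplyr::all_of(c(variant_columns(), "variant_id")))
}

#' VCF annotation-key configuration
#'
#' Names the INFO keys used to recover annotations from an input VCF.
#'
#' @param gene_key INFO key carrying the annotated gene symbol(s)
#'   (semicolon- or ampersand-joined for multi-gene sites).
#' @param consequence_key INFO key with the most severe consequence term.
#' @param af_keys INFO keys holding per-population allele frequencies; the
#'   maximum over the available values becomes the variant's MAF.
#' @param sift_key,polyphen_key Optional pathogenicity-score keys.
#' @param known_db_key Flag-type INFO key marking presence in a database of
#'   known pathogenic variants.
#' @return List of class `vcf_config`.
#' @export
vcf_config <- function(gene_key = "GENE", consequence_key = "CSQ",
                       af_keys = c("MAF", "AF", "AF_AFR", "AF_AMR",
                                   "AF_EAS", "AF_EUR", "AF_SAS"),
                       sift_key = "SIFT", polyphen_key = "POLYPHEN",
                       known_db_key = "KNOWNDB") {
  structure(list(gene_key = gene_key, consequence_key = consequence_key,
                 af_keys = af_keys, sift_key = sift_key,
                 polyphen_key = polyphen_key, known_db_key = known_db_key),
            class = "vcf_config")
}

# Parse a vector of VCF GT strings into per-alt-allele counts.
# Returns list(count per alt index requested, ploidy).
parse_gt <- function(gt, alt_index) {
  gt <- sub(":.*$", "", gt)
  alleles <- strsplit(gt, "[/|]")
  counts <- mapply(function(a, k) {
    if (!length(a) || all(a == ".") || anyNA(a)) return(NA_integer_)
    sum(a == as.character(k))
  }, alleles, alt_index, USE.NAMES = FALSE)
  ploidy <- vapply(alleles, function(a) {
    if (!length(a) || all(a == ".") || anyNA(a)) return(NA_integer_)
    length(a)
  }, integer(1))
  list(count = as.integer(counts), ploidy = ploidy)
}

info_field <- function(info, key) {
  pattern <- paste0("(?:^|;)", key, "=([^;]*)")
  m <- regexpr(pattern, info, perl = TRUE)
  out <- rep(NA_character_, length(info))
  hit <- !is.na(m) & m != -1L
  vals <- regmatches(info, m)
  out[hit] <- sub(paste0("^;?", key, "="), "", vals)
  out
}

info_flag <- function(info, key) {
  grepl(paste0("(?:^|;)", key, "(?:;|$)"), info)
}

#' Read a trio VCF into the canonical variant table
#'
#' Reads a multi-sample VCF (via \pkg{vcfR}), decomposes multi-allelic sites
#' into one record per alt allele, extracts annotations according to
#' `config`, and normalises allele frequency as the maximum over the
#' configured population keys. Samples absent from the VCF header among the
#' two parents yield missing genotypes (proband-only analysis); a missing
#' proband sample is an error.
#'
#' @param path Path to a VCF 4.x file.
#' @param trio One-row trio pedigree tibble (see [read_ped()]).
#' @param config A [vcf_config()].
#' @return A variant tibble as produced by [as_variant_tbl()].
#' @export
read_trio_vcf <- function(path, trio, config = vcf_config()) {
  if (!file.exists(path)) stop("VCF file does not exist: ", path, call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(fix)  # single-record files drop dims
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  info <- vcfR::getINFO(v)
  gt <- v@gt
  samples <- colnames(gt)[-1]
  if (!trio$proband_id %in% samples) {
    stop("proband sample '", trio$proband_id, "' not found in ", path,
         call. = FALSE)
  }
  get_sample <- function(id) {
    if (!is.na(id) && id %in% samples) gt[, id, drop = TRUE] else
      rep(NA_character_, nrow(fix))
  }
  child_raw <- get_sample(trio$proband_id)
  mother_raw <- get_sample(trio$mother_id)
  father_raw <- get_sample(trio$father_id)

  for (key in c(config$gene_key, config$consequence_key)) {
    if (!any(grepl(paste0("(?:^|;)", key, "="), info))) {
      warning("annotation key '", key, "' absent from INFO in ", path,
              call. = FALSE)
    }
  }

  alts <- strsplit(fix$ALT, ",", fixed = TRUE)
  n_alt <- lengths(alts)
  site <- rep(seq_len(nrow(fix)), n_alt)
  alt_index <- unlist(lapply(n_alt, seq_len), use.names = FALSE)

  afs <- lapply(config$af_keys, function(k) {
    suppressWarnings(as.numeric(info_field(info, k)))
  })
  af_mat <- do.call(cbind, afs)
  maf_site <- apply(af_mat, 1, function(row) max_maf(row))

  rows <- tibble::tibble(
    proband_id = trio$proband_id,
    chromosome = fix$CHROM[site],
    position = as.integer(fix$POS[site]),
    ref = fix$REF[site],
    alt = unlist(alts, use.names = FALSE),
    gene = gsub("&", ";", info_field(info, config$gene_key))[site],
    consequence = info_field(info, config$consequence_key)[site],
    maf = maf_site[site],
    sift = suppressWarnings(as.numeric(info_field(info, config$sift_key)))[site],
    polyphen = suppressWarnings(
      as.numeric(info_field(info, config$polyphen_key)))[site],
    known_pathogenic = info_flag(info, config$known_db_key)[site]
  )
  cg <- parse_gt(child_raw[site], alt_index)
  mg <- parse_gt(mother_raw[site], alt_index)
  fg <- parse_gt(father_raw[site], alt_index)
  rows$child_gt <- cg$count
  rows$child_ploidy <- ifelse(is.na(cg$ploidy), 2L, cg$ploidy)
  rows$mother_gt <- mg$count
  rows$father_gt <- fg$count
  as_variant_tbl(rows)
}

gt_string <- function(count, ploidy) {
  out <- rep("./.", length(count))
  dip <- !is.na(count) & ploidy == 2L
  out[dip & count == 0] <- "0/0"
  out[dip & count == 1] <- "0/1"
  out[dip & count == 2] <- "1/1"
  hap <- !is.na(count) & ploidy == 1L
  out[hap] <- as.character(count[hap])
  out[is.na(count) & ploidy == 1L] <- "."
  out
}

#' Write one trio's variants as a VCF 4.2 file
#'
#' Inverse of [read_trio_vcf()] for generator output: one line per record
#' (already decomposed), GT-only FORMAT, annotations in INFO.
#'
#' @param variants Variant tibble for a single proband.
#' @param path Output path.
#' @param trio One-row trio pedigree tibble.
#' @return `path`, invisibly.
#' @export
write_trio_vcf <- function(variants, path, trio) {
  v <- as_variant_tbl(variants)
  v <- v[order(v$chromosome, v$position, v$ref, v$alt), ]
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=triotriage-synth",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Annotated gene symbol(s), semicolon-joined\">",
    "##INFO=<ID=CSQ,Number=1,Type=String,Description=\"Most severe consequence term\">",
    "##INFO=<ID=MAF,Number=1,Type=Float,Description=\"Maximum population minor allele frequency\">",
    "##INFO=<ID=SIFT,Number=1,Type=Float,Description=\"SIFT score (pass-through)\">",
    "##INFO=<ID=POLYPHEN,Number=1,Type=Float,Description=\"PolyPhen score (pass-through)\">",
    "##INFO=<ID=KNOWNDB,Number=0,Type=Flag,Description=\"Present in known-pathogenic variant database\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", trio$proband_id,
          if (!is.na(trio$mother_id)) trio$mother_id,
          if (!is.na(trio$father_id)) trio$father_id,
          sep = "\t")
  )
  info <- paste0("GENE=", gsub(";", "&", v$gene), ";CSQ=", v$consequence)
  info <- ifelse(is.na(v$maf), info,
                 paste0(info, ";MAF=", sprintf("%.8g", v$maf)))
  info <- ifelse(is.na(v$sift), info, paste0(info, ";SIFT=", v$sift))
  info <- ifelse(is.na(v$polyphen), info,
                 paste0(info, ";POLYPHEN=", v$polyphen))
  info <- ifelse(v$known_pathogenic, paste0(info, ";KNOWNDB"), info)

  on_x <- is_x_chrom(v$chromosome)
  father_ploidy <- ifelse(on_x, 1L, 2L)
  fields <- list(
    v$chromosome, v$position, ".", v$ref, v$alt, ".", "PASS", info, "GT",
    gt_string(v$child_gt, v$child_ploidy)
  )
  if (!is.na(trio$mother_id)) {
    fields <- c(fields, list(gt_string(v$mother_gt, rep(2L, nrow(v)))))
  }
  if (!is.na(trio$father_id)) {
    fields <- c(fields, list(gt_string(v$father_gt, father_ploidy)))
  }
  body <- do.call(paste, c(fields, sep = "\t"))
  writeLines(c(header, body), path)
  invisible(path)
}
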