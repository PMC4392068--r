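#' @importFrom rlang .data :=
#' @importFrom dplyr %>%
NULL

# Controlled vocabularies for panel entries. Published panels use looser
# labels ("autosomal dominant"); aliases are normalised on load because the
# triage cascade only consumes these distinctions.
allelic_requirements <- function() {
  c("monoallelic", "biallelic", "x_linked_dominant", "x_linked_recessive")
}

mutation_consequences <- function() {
  c("loss_of_function", "dominant_negative", "activating",
    "increased_gene_dosage", "all_missense_or_in_frame", "uncertain")
}

.requirement_aliases <- c(
  "autosomal dominant"  = "monoallelic",
  "autosomal_dominant"  = "monoallelic",
  "autosomal recessive" = "biallelic",
  "autosomal_recessive" = "biallelic",
  "x-linked dominant"   = "x_linked_dominant",
  "x-linked recessive"  = "x_linked_recessive"
)

normalise_requirement <- function(x) {
  x <- tolower(trimws(x))
  hit <- unname(.requirement_aliases[x])
  ifelse(is.na(hit), x, hit)
}

is_x_chrom <- function(chrom) {
  toupper(sub("^chr", "", as.character(chrom))) %in% c("X", "23")
}

#' Construct a validated gene panel
#'
#' A panel is a tibble of genotype-to-phenotype entries in the style of
#' DDG2P: each row links a gene to an allelic requirement (mode of
#' inheritance needed for disease) and a mutation consequence (mechanism by
#' which variants in the gene act). A gene may carry several entries with
#' distinct requirement/mechanism pairs. Non-reportable entries (insufficient
#' evidence) are retained in the object but ignored by triage.
#'
#' @param entries Data frame with columns `gene_symbol`, `chromosome`,
#'   `interval_start`, `interval_end` (optional, `NA` allowed),
#'   `allelic_requirement`, `mutation_consequence`, `reportable` (logical),
#'   `required_phenotype_terms` (semicolon-joined, may be `NA`), `notes`.
#' @param label Version label for the panel (e.g. a release date).
#' @return A tibble of class `gene_panel` with a `label` attribute.
#' @export
gene_panel <- function(entries, label = "unversioned") {
  entries <- tibble::as_tibble(entries)
  defaults <- list(
    interval_start = NA_real_, interval_end = NA_real_,
    required_phenotype_terms = NA_character_, notes = NA_character_
  )
  for (nm in names(defaults)) {
    if (!nm %in% names(entries)) entries[[nm]] <- defaults[[nm]]
  }
  required <- c("gene_symbol", "chromosome", "allelic_requirement",
                "mutation_consequence", "reportable")
  missing_cols <- setdiff(required, names(entries))
  if (length(missing_cols)) {
    stop("panel is missing required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  entries$allelic_requirement <- normalise_requirement(entries$allelic_requirement)
  entries$mutation_consequence <- tolower(trimws(entries$mutation_consequence))
  entries$reportable <- as.logical(entries$reportable)
  entries <- entries[, c("gene_symbol", "chromosome", "interval_start",
                         "interval_end", "allelic_requirement",
                         "mutation_consequence", "reportable",
                         "required_phenotype_terms", "notes")]
  validate_panel(entries)
  structure(entries, label = label,
            class = c("gene_panel", class(tibble::tibble())))
}

validate_panel <- function(entries) {
  row_err <- function(rows, msg) {
    stop(sprintf("invalid panel row(s) %s: %s",
                 paste(rows, collapse = ", "), msg), call. = FALSE)
  }
  bad <- which(is.na(entries$gene_symbol) | entries$gene_symbol == "")
  if (length(bad)) row_err(bad, "empty gene_symbol")
  unknown_req <- !entries$allelic_requirement %in% allelic_requirements()
  if (any(unknown_req)) {
    row_err(which(unknown_req), sprintf(
      "unknown allelic_requirement token(s): %s",
      paste(unique(entries$allelic_requirement[unknown_req]), collapse = ", ")))
  }
  unknown_mc <- !entries$mutation_consequence %in% mutation_consequences()
  if (any(unknown_mc)) {
    row_err(which(unknown_mc), sprintf(
      "unknown mutation_consequence token(s): %s",
      paste(unique(entries$mutation_consequence[unknown_mc]), collapse = ", ")))
  }
  x_req <- grepl("^x_linked", entries$allelic_requirement)
  bad_x <- x_req & !is_x_chrom(entries$chromosome)
  if (any(bad_x)) {
    row_err(which(bad_x),
            "x_linked allelic requirement on a non-X chromosome")
  }
  key <- paste(entries$gene_symbol, entries$allelic_requirement,
               entries$mutation_consequence)
  if (anyDuplicated(key)) {
    row_err(which(duplicated(key)),
            "duplicate (gene, allelic_requirement, mutation_consequence) entry")
  }
  bad_iv <- !is.na(entries$interval_start) & !is.na(entries$interval_end) &
    entries$interval_start > entries$interval_end
  if (any(bad_iv)) row_err(which(bad_iv), "interval_start > interval_end")
  invisible(entries)
}

#' Read a gene panel from a TSV file
#'
#' Expects one header line and tab-separated columns matching the fields of
#' [gene_panel()]; phenotype-term sets are semicolon-joined tokens.
#'
#' @param path Path to the panel TSV.
#' @param label Version label; defaults to the file name.
#' @return A `gene_panel` tibble.
#' @export
load_panel <- function(path, label = basename(path)) {
  if (!file.exists(path)) {
    stop("panel file does not exist: ", path, call. = FALSE)
  }
  raw <- readr::read_tsv(
    path, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      gene_symbol = readr::col_character(),
      chromosome = readr::col_character(),
      interval_start = readr::col_double(),
      interval_end = readr::col_double(),
      allelic_requirement = readr::col_character(),
      mutation_consequence = readr::col_character(),
      reportable = readr::col_logical(),
      required_phenotype_terms = readr::col_character(),
      notes = readr::col_character()
    )
  )
  gene_panel(raw, label = label)
}

#' Write a gene panel to TSV
#'
#' @param panel A `gene_panel`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  readr::write_tsv(tibble::as_tibble(panel), path, progress = FALSE)
  invisible(path)
}

#' Reportable gene symbols in a panel
#'
#' @param panel A `gene_panel`.
#' @return Character vector of distinct gene symbols with at least one
#'   reportable entry.
#' @export
reportable_genes <- function(panel) {
  sort(unique(panel$gene_symbol[panel$reportable %in% TRUE]))
}

#' Reportable entries for one gene
#'
#' @param panel A `gene_panel`.
#' @param gene Gene symbol.
#' @return Tibble of reportable entries for `gene` (zero rows if the gene is
#'   absent or has no reportable entry).
#' @export
reportable_entries_for_gene <- function(panel, gene) {
  tibble::as_tibble(panel)[panel$gene_symbol == gene &
                             panel$reportable %in% TRUE, ]
}

#' Diff the reportable gene sets of two panel versions
#'
#' @param old,new `gene_panel` objects.
#' @return List with character vectors `added` (reportable in `new` only) and
#'   `removed` (reportable in `old` only); the two sets are disjoint.
#' @export
diff_panels <- function(old, new) {
  old_genes <- reportable_genes(old)
  new_genes <- reportable_genes(new)
  list(added = setdiff(new_genes, old_genes),
       removed = setdiff(old_genes, new_genes))
}

#' @export
print.gene_panel <- function(x, ...) {
  cat(sprintf("<gene_panel> version %s: %d entries, %d reportable genes\n",
              attr(x, "label"), nrow(x), length(reportable_genes(x))))
  NextMethod()
}
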