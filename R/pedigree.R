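# PED parsing and the trio data model. One row per proband; parents are
# optional (missing parents => proband-only analysis). A sidecar table
# supplies the family-history flag, which standard PED cannot encode but
# which the X-linked inherited-missense exception needs.

#' Read trios from a PED file
#'
#' Standard 6-column whitespace-delimited PED (family, individual, father,
#' mother, sex, phenotype) with affected coded 2, unaffected 1, missing 0.
#' A proband is an individual who is not listed as anyone's parent and whose
#' parent IDs (if any) resolve within the file; parent IDs of "0" denote an
#' absent parent.
#'
#' @param path Path to a PED file.
#' @param family_history_path Optional path to a two-column TSV
#'   (`proband_id`, `family_history`) supplying the family-history flag;
#'   probands absent from the table default to `FALSE`.
#' @return Tibble with one row per proband: `family_id`, `proband_id`,
#'   `father_id`, `mother_id` (`NA` when absent), `proband_sex`
#'   (`"male"`/`"female"`), `mother_affected`, `father_affected`
#'   (`NA` when the parent is absent), `proband_affected`, `family_history`.
#' @export
read_ped <- function(path, family_history_path = NULL) {
  if (!file.exists(path)) stop("PED file does not exist: ", path, call. = FALSE)
  raw <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("family_id", "id", "father_id",
                                         "mother_id", "sex", "phenotype"),
                           colClasses = c(rep("character", 4),
                                          "integer", "integer"))
  if (anyDuplicated(raw$id)) {
    stop("duplicate individual IDs in PED: ",
         paste(unique(raw$id[duplicated(raw$id)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(!raw$sex %in% 0:2)) {
    stop("sex codes must be 0, 1 or 2; found: ",
         paste(unique(raw$sex[!raw$sex %in% 0:2]), collapse = ", "),
         call. = FALSE)
  }
  # cycle check: walk parent links from every individual
  parent_of <- stats::setNames(
    lapply(seq_len(nrow(raw)),
           function(i) setdiff(c(raw$father_id[i], raw$mother_id[i]), "0")),
    raw$id)
  for (id in raw$id) {
    seen <- character(0)
    frontier <- id
    while (length(frontier)) {
      if (any(frontier %in% seen)) {
        stop("circular parentage involving individual ", id, call. = FALSE)
      }
      seen <- c(seen, frontier)
      frontier <- unique(unlist(parent_of[intersect(frontier, raw$id)]))
    }
  }
  referenced_as_parent <- unique(c(raw$father_id, raw$mother_id))
  is_proband <- !(raw$id %in% referenced_as_parent)
  probands <- raw[is_proband, , drop = FALSE]

  lookup <- function(ids, field) {
    idx <- match(ids, raw$id)
    out <- raw[[field]][idx]
    out
  }
  resolve_parent <- function(ids) {
    out <- ifelse(ids == "0", NA_character_, ids)
    unresolved <- !is.na(out) & !(out %in% raw$id)
    out[unresolved] <- NA_character_
    out
  }
  father <- resolve_parent(probands$father_id)
  mother <- resolve_parent(probands$mother_id)
  if (any(probands$sex == 0)) {
    stop("proband sex is required (code 1 or 2) for: ",
         paste(probands$id[probands$sex == 0], collapse = ", "),
         call. = FALSE)
  }
  aff <- function(pheno) ifelse(is.na(pheno), NA, pheno == 2L)
  trios <- tibble::tibble(
    family_id = probands$family_id,
    proband_id = probands$id,
    father_id = father,
    mother_id = mother,
    proband_sex = ifelse(probands$sex == 1L, "male", "female"),
    proband_affected = probands$phenotype == 2L,
    mother_affected = ifelse(is.na(mother), NA,
                             aff(lookup(mother, "phenotype"))),
    father_affected = ifelse(is.na(father), NA,
                             aff(lookup(father, "phenotype"))),
    family_history = FALSE
  )
  if (!is.null(family_history_path)) {
    fh <- readr::read_tsv(family_history_path, show_col_types = FALSE,
                          progress = FALSE,
                          col_types = readr::cols(
                            proband_id = readr::col_character(),
                            family_history = readr::col_logical()))
    idx <- match(trios$proband_id, fh$proband_id)
    trios$family_history <- ifelse(is.na(idx), FALSE, fh$family_history[idx])
  }
  trios
}

#' Number of affected parents per trio
#'
#' Absent parents count as unaffected.
#'
#' @param trios Trio tibble from [read_ped()].
#' @return Integer vector in `{0, 1, 2}`.
#' @export
n_affected_parents <- function(trios) {
  (trios$mother_affected %in% TRUE) + (trios$father_affected %in% TRUE)
}

#' Write trios to PED plus family-history sidecar
#'
#' @param trios Trio tibble.
#' @param path PED output path.
#' @param family_history_path Optional sidecar TSV output path.
#' @return `path`, invisibly.
#' @export
write_ped <- function(trios, path, family_history_path = NULL) {
  parent_rows <- function(id, sex, affected) {
    keep <- which(!is.na(id))
    data.frame(family_id = trios$family_id[keep], id = id[keep],
               father_id = rep("0", length(keep)),
               mother_id = rep("0", length(keep)),
               sex = rep(sex, length(keep)),
               phenotype = ifelse(is.na(affected[keep]), 0L,
                                  ifelse(affected[keep], 2L, 1L)),
               stringsAsFactors = FALSE)
  }
  child <- data.frame(
    family_id = trios$family_id, id = trios$proband_id,
    father_id = ifelse(is.na(trios$father_id), "0", trios$father_id),
    mother_id = ifelse(is.na(trios$mother_id), "0", trios$mother_id),
    sex = ifelse(trios$proband_sex == "male", 1L, 2L),
    phenotype = ifelse(trios$proband_affected %in% TRUE, 2L, 1L),
    stringsAsFactors = FALSE)
  out <- rbind(parent_rows(trios$father_id, 1L, trios$father_affected),
               parent_rows(trios$mother_id, 2L, trios$mother_affected),
               child)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  if (!is.null(family_history_path)) {
    readr::write_tsv(
      tibble::tibble(proband_id = trios$proband_id,
                     family_history = trios$family_history),
      family_history_path, progress = FALSE)
  }
  invisible(path)
}
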