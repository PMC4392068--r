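# Inheritance classification from trio genotypes.
#
# The classifier is deterministic on the given genotypes (no quality-based
# posterior): it reproduces exactly the call implied by enumerating every
# Mendelian-consistent (maternal gamete, paternal gamete) pair. De novo
# status is only assigned when both parental genotypes are present and carry
# zero copies of the alternate allele; genotype configurations impossible
# under transmission are labelled `mendelian_error` and treated downstream
# as genotyping artefacts.

inheritance_modes <- function() {
  c("de_novo", "maternal", "paternal", "biparental", "inherited_ambiguous",
    "uninformative", "mendelian_error")
}

inherited_modes <- function() {
  c("maternal", "paternal", "biparental", "inherited_ambiguous")
}

# Vectorised core. `child`, `mother`, `father` are alt-allele counts
# (NA = missing); `on_x` and `male` are logicals. Male X genotypes are
# hemizygous (counts in {0,1}); the father's genotype is ignored for
# transmission to a male child on X.
inheritance_call <- function(child, mother, father, on_x, male) {
  n <- length(child)
  out <- rep("uninformative", n)
  hemi <- on_x & male

  # male child on X: child's single allele comes from the mother
  idx <- hemi & !is.na(mother) & !is.na(child)
  out[idx & child >= 1 & mother >= 1] <- "maternal"
  out[idx & child >= 1 & mother == 0] <- "de_novo"
  out[idx & child == 0 & mother == 2] <- "mendelian_error"

  # diploid child (autosome, or X in a female; on X the father is hemizygous
  # and transmits his single allele deterministically)
  dip <- !hemi
  idx2 <- dip & !is.na(mother) & !is.na(father) & !is.na(child)
  fmin <- ifelse(on_x, father, as.integer(father == 2))
  fmax <- ifelse(on_x, father, as.integer(father >= 1))
  mmin <- as.integer(mother == 2)
  mmax <- as.integer(mother >= 1)
  cmin <- mmin + fmin
  cmax <- mmax + fmax
  incons <- idx2 & (child < cmin | child > cmax)
  out[incons & mother == 0 & father == 0] <- "de_novo"
  out[incons & !(mother == 0 & father == 0)] <- "mendelian_error"
  cons <- idx2 & !(child < cmin | child > cmax)
  out[cons & child == 2] <- "biparental"
  c1 <- cons & child == 1
  mat_pos <- mmax >= 1 & fmin == 0  # mother can transmit alt while father transmits ref
  pat_pos <- fmax >= 1 & mmin == 0
  out[c1 & mat_pos & pat_pos] <- "inherited_ambiguous"
  out[c1 & mat_pos & !pat_pos] <- "maternal"
  out[c1 & !mat_pos & pat_pos] <- "paternal"
  out
}

#' Classify inheritance of each variant from trio genotypes
#'
#' Adds an `inheritance` column with one of `de_novo`, `maternal`,
#' `paternal`, `biparental`, `inherited_ambiguous`, `uninformative`
#' (missing parental data or no alternate allele in the child) or
#' `mendelian_error` (child genotype impossible under transmission from the
#' stated parental genotypes, unless both parents carry zero alt copies, in
#' which case the call is `de_novo`).
#'
#' @param variants Variant tibble (see [as_variant_tbl()]).
#' @param trios Trio tibble from [read_ped()]; matched by `proband_id`.
#' @return `variants` with columns `inheritance`, `on_x` and
#'   `proband_male` appended.
#' @export
classify_inheritance <- function(variants, trios) {
  v <- as_variant_tbl(variants)
  idx <- match(v$proband_id, trios$proband_id)
  if (anyNA(idx)) {
    stop("probands absent from pedigree: ",
         paste(unique(v$proband_id[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  }
  v$on_x <- is_x_chrom(v$chromosome)
  v$proband_male <- trios$proband_sex[idx] == "male"
  v$inheritance <- inheritance_call(v$child_gt, v$mother_gt, v$father_gt,
                                    v$on_x, v$proband_male)
  v
}

#' Does an inheritance call segregate with disease?
#'
#' Only de novo variants and variants inherited from an affected parent are
#' of clinical interest for dominant-acting genes. Biparental or ambiguous
#' transmission segregates when at least one potentially transmitting parent
#' is affected. `uninformative` and `mendelian_error` calls never segregate.
#'
#' @param mode Character vector of inheritance calls.
#' @param mother_affected,father_affected Logical vectors (`NA` treated as
#'   unaffected).
#' @return Logical vector.
#' @export
segregates_with_disease <- function(mode, mother_affected, father_affected) {
  ma <- mother_affected %in% TRUE
  fa <- father_affected %in% TRUE
  mode == "de_novo" |
    (mode == "maternal" & ma) |
    (mode == "paternal" & fa) |
    (mode %in% c("biparental", "inherited_ambiguous") & (ma | fa))
}
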