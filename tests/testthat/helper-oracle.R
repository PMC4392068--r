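# Independent gamete-enumeration oracle for inheritance classification:
# lists every (maternal gamete, paternal gamete) pair consistent with the
# parental genotypes and classifies the child's alt source by set
# membership. Kept deliberately brute-force and separate from the package
# implementation.

oracle_classify <- function(child, mother, father, chromosome = "1",
                            sex = "female") {
  on_x <- chromosome == "X"
  gametes <- function(g) unique(c(if (g <= 1) 0L, if (g >= 1) 1L))
  if (on_x && sex == "male") {
    if (is.na(mother) || is.na(child)) return("uninformative")
    gm <- gametes(mother)
    if (!(child %in% gm)) {
      return(if (mother == 0 && child > 0) "de_novo" else "mendelian_error")
    }
    return(if (child == 0) "uninformative" else "maternal")
  }
  if (is.na(mother) || is.na(father) || is.na(child)) return("uninformative")
  gm <- gametes(mother)
  gf <- if (on_x) father else gametes(father)  # X: father transmits his allele
  pairs <- expand.grid(gm = gm, gf = gf)
  ok <- pairs[pairs$gm + pairs$gf == child, , drop = FALSE]
  if (!nrow(ok)) {
    return(if (mother == 0 && father == 0) "de_novo" else "mendelian_error")
  }
  if (child == 0) return("uninformative")
  if (child == 2) return("biparental")
  mat <- any(ok$gm == 1)
  pat <- any(ok$gf == 1)
  if (mat && pat) "inherited_ambiguous" else if (mat) "maternal" else "paternal"
}

classify_one <- function(child, mother, father, chromosome = "1",
                         sex = "female", ploidy = 2L) {
  trio <- make_trio(sex = sex)
  v <- make_variant(chromosome = chromosome, child_gt = child,
                    mother_gt = mother, father_gt = father,
                    child_ploidy = ploidy)
  classify_inheritance(v, trio)$inheritance
}
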