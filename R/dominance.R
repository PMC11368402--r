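#' Define a set of S-alleles with dominance classes
#'
#' In sporophytic self-incompatibility (SSI) of the Brassicaceae, S-alleles
#' fall into phylogenetic dominance classes. In *Arabidopsis halleri* and
#' *A. lyrata* four classes are recognised, with pollen-side dominance
#' increasing from class I (most recessive) to class IV (most dominant);
#' alleles within a class are codominant with each other.
#'
#' @param ids character vector of unique allele labels.
#' @param classes integer vector of dominance class ranks (1 = class I,
#'   most recessive; 4 = class IV, most dominant), parallel to `ids`.
#' @return An object of class `dominance_hierarchy`: a data.frame with
#'   columns `id` and `class`.
#' @examples
#' h <- dominance_hierarchy(c("S01", "S20"), c(1L, 4L))
#' pollen_phenotype(c("S01", "S20"), h)
#' @export
dominance_hierarchy <- function(ids, classes) {
  ids <- as.character(ids)
  classes <- as.integer(classes)
  if (length(ids) != length(classes))
    stop("`ids` and `classes` must have the same length")
  if (anyDuplicated(ids))
    stop("S-allele ids must be unique: ", paste(ids[duplicated(ids)], collapse = ", "))
  if (any(is.na(classes)) || any(classes < 1L) || any(classes > 4L))
    stop("dominance classes must be integers in 1..4 (I..IV)")
  structure(data.frame(id = ids, class = classes, stringsAsFactors = FALSE),
            class = c("dominance_hierarchy", "data.frame"))
}

#' Default S-allele roster
#'
#' The 14-allele roster mirroring the Nivelle population of *A. halleri*:
#' eight class-IV alleles, three class-III, two class-II, and one class-I.
#'
#' @return A [dominance_hierarchy()] with 14 alleles.
#' @export
default_s_allele_roster <- function() {
  dominance_hierarchy(
    ids = c("S01",
            "S02", "S03",
            "S04", "S05", "S06",
            sprintf("S%02d", 7:14)),
    classes = c(1L, 2L, 2L, 3L, 3L, 3L, rep(4L, 8L))
  )
}

#' @export
print.dominance_hierarchy <- function(x, ...) {
  cat("SSI dominance hierarchy:", nrow(x), "S-alleles;",
      "class counts (I..IV):",
      paste(tabulate(x$class, nbins = 4L), collapse = "/"), "\n")
  NextMethod()
}

.allele_class <- function(alleles, hierarchy) {
  i <- match(alleles, hierarchy$id)
  if (anyNA(i)) {
    bad <- unique(alleles[is.na(i)])
    stop("unknown S-allele label(s): ", paste(bad, collapse = ", "))
  }
  hierarchy$class[i]
}

#' Pollen S-phenotype of a diploid genotype
#'
#' Pollen dominance is sporophytic: the S-phenotype of a pollen grain is set
#' by the diploid genotype of its father. Between classes the higher class is
#' dominant (I < II < III < IV); within a class alleles are codominant, so a
#' heterozygote for two same-class alleles expresses both.
#'
#' @param genotype character vector of length 2 (the two S-allele labels;
#'   identical labels for a homozygote).
#' @param hierarchy a [dominance_hierarchy()].
#' @return Character vector of expressed allele labels (length 1 or 2).
#' @export
pollen_phenotype <- function(genotype, hierarchy) {
  stopifnot(length(genotype) == 2L)
  cl <- .allele_class(genotype, hierarchy)
  if (genotype[1L] == genotype[2L]) return(genotype[1L])
  if (cl[1L] > cl[2L]) genotype[1L]
  else if (cl[2L] > cl[1L]) genotype[2L]
  else sort(genotype)
}

#' Pistil S-phenotype of a diploid genotype
#'
#' On the pistil side dominance interactions are much weaker than in pollen;
#' by default both alleles are expressed (codominance). Set
#' `pistil_dominance = TRUE` to apply the pollen hierarchy to the pistil as a
#' sensitivity analysis.
#'
#' @inheritParams pollen_phenotype
#' @param pistil_dominance logical; apply the dominance hierarchy on the
#'   pistil side as well (default `FALSE`).
#' @return Character vector of expressed allele labels.
#' @export
pistil_phenotype <- function(genotype, hierarchy, pistil_dominance = FALSE) {
  stopifnot(length(genotype) == 2L)
  .allele_class(genotype, hierarchy)  # label validation
  if (pistil_dominance) return(pollen_phenotype(genotype, hierarchy))
  sort(unique(genotype))
}

#' Compatibility of a cross under sporophytic SI
#'
#' A pollination is compatible when the pollen S-phenotype of the father
#' shares no specificity with the pistil S-phenotype of the mother. Because
#' dominant alleles mask recessive ones in pollen, a father carrying a
#' recessive allele masked by a dominant one can fertilise a pistil carrying
#' that same recessive allele — the route by which S-locus homozygotes arise.
#'
#' @param pistil_genotype,pollen_parent_genotype character vectors of length
#'   2: S-genotypes of the maternal and paternal plants.
#' @inheritParams pistil_phenotype
#' @return `TRUE` if the cross is compatible.
#' @export
is_compatible <- function(pistil_genotype, pollen_parent_genotype, hierarchy,
                          pistil_dominance = FALSE) {
  pol <- pollen_phenotype(pollen_parent_genotype, hierarchy)
  pis <- pistil_phenotype(pistil_genotype, hierarchy, pistil_dominance)
  length(intersect(pol, pis)) == 0L
}
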