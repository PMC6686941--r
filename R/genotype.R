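as_individual_list <- function(x) {
  if (inherits(x, "population")) return(setNames(x$individuals, x$labels))
  if (inherits(x, "individual")) return(setNames(list(x), x$id))
  if (is.list(x) && length(x) &&
      all(vapply(x, inherits, logical(1), "individual"))) {
    nm <- names(x) %||% vapply(x, `[[`, character(1), "id")
    return(setNames(x, nm))
  }
  stop_input("expected a population, an individual, or a list of individuals")
}

#' Numeric genotypes
#'
#' Per-locus allele dosage of every individual: the alpha-strand bit plus the
#' beta-strand bit, in `{0, 1, 2}` (`coding = "dosage"`), or centered to
#' `{-1, 0, 1}` (`coding = "centered"`, dosage minus one) for kinship
#' formulations that use that scale.
#'
#' @param population a `population`, `individual`, or list of individuals
#'   sharing one specie.
#' @param coding `"dosage"` (default) or `"centered"`.
#' @return integer matrix, loci in rows (named by locus), individuals in
#'   columns.
#' @examples
#' spp <- make_specie(fixture_map(1, 4, 1))
#' genotype_numeric(founder(spp, "AA"))
#' @export
genotype_numeric <- function(population, coding = c("dosage", "centered")) {
  coding <- match.arg(coding)
  inds <- as_individual_list(population)
  if (!same_specie(inds)) stop_incompatible("individuals from mixed species")
  spp <- inds[[1]]$specie
  M <- vapply(inds, function(ind) {
    unlist(lapply(spp$chr_names, function(ch) {
      pair <- ind$genome[[ch]]
      .bits_dosage(pair$alpha$bits, pair$beta$bits, pair$alpha$n)
    }), use.names = FALSE)
  }, integer(sum(spp$n_loci)))
  M <- matrix(M, nrow = sum(spp$n_loci),
              dimnames = list(spp$map$snp, names(inds)))
  if (coding == "centered") M <- M - 1L
  M
}

#' Phased genotypes
#'
#' Character genotypes that keep linkage phase: per locus the string
#' `"x|y"` where `x` encodes the alpha-strand bit and `y` the beta-strand
#' bit, with bit 1 written `"A"` and bit 0 written `"a"` (matching the
#' founder codes). The alpha strand — inherited from the first parent of a
#' cross — is always listed first.
#'
#' @inheritParams genotype_numeric
#' @return character matrix, loci in rows, individuals in columns.
#' @export
genotype_phased <- function(population) {
  inds <- as_individual_list(population)
  if (!same_specie(inds)) stop_incompatible("individuals from mixed species")
  spp <- inds[[1]]$specie
  code <- c("a", "A")
  M <- vapply(inds, function(ind) {
    unlist(lapply(spp$chr_names, function(ch) {
      pair <- ind$genome[[ch]]
      a <- as.integer(as.logical(pair$alpha))
      b <- as.integer(as.logical(pair$beta))
      paste0(code[a + 1L], "|", code[b + 1L])
    }), use.names = FALSE)
  }, character(sum(spp$n_loci)))
  matrix(M, nrow = sum(spp$n_loci),
         dimnames = list(spp$map$snp, names(inds)))
}

#' Fraction of heterozygous calls
#'
#' @inheritParams genotype_numeric
#' @return proportion of (locus, individual) entries with dosage 1.
#' @export
heterozygosity <- function(population) {
  mean(genotype_numeric(population) == 1L)
}
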