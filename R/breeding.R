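#' Populations
#'
#' An ordered, indexable collection of individuals sharing one specie.
#' Ordering fixes the column order of genotype matrices and kinship matrices.
#'
#' @param individuals list of `individual`s of one specie.
#' @param labels optional character labels; default the individuals' ids.
#' @return a `population`.
#' @export
population <- function(individuals, labels = NULL) {
  if (!length(individuals)) stop_input("population must not be empty")
  if (inherits(individuals, "individual")) individuals <- list(individuals)
  if (!all(vapply(individuals, inherits, logical(1), "individual")))
    stop_input("all members must be individuals")
  if (!same_specie(individuals))
    stop_incompatible("all members must share one specie")
  labels <- labels %||% vapply(individuals, `[[`, character(1), "id")
  if (length(labels) != length(individuals))
    stop_input("labels length must match individuals")
  structure(list(individuals = individuals, labels = labels,
                 specie = individuals[[1]]$specie),
            class = "population")
}

#' @export
length.population <- function(x) length(x$individuals)

#' @export
`[[.population` <- function(x, i) x$individuals[[i]]

#' @export
`[.population` <- function(x, i) {
  population(x$individuals[i], x$labels[i])
}

#' @export
print.population <- function(x, ...) {
  cat("<population> ", length(x), " individual(s) of a ",
      sum(x$specie$n_loci), "-locus specie\n", sep = "")
  invisible(x)
}

#' @export
c.population <- function(...) {
  pops <- list(...)
  population(do.call(c, lapply(pops, function(p) p$individuals)),
             do.call(c, lapply(pops, function(p) p$labels)))
}

#' Pedigree of a population
#'
#' @param pop a `population`.
#' @param ancestors include all recorded ancestors of the members (needed for
#'   the tabular-method A matrix), not just the members themselves.
#' @return tibble with columns `id`, `mother`, `father` (NA for founders),
#'   parents preceding offspring.
#' @export
pedigree <- function(pop, ancestors = TRUE) {
  if (!inherits(pop, "population")) stop_input("not a population")
  ped <- pop$specie$pedigree
  all_ids <- names(ped)
  full <- tibble::tibble(
    id = all_ids,
    mother = unname(vapply(ped, `[`, character(1), 1L)),
    father = unname(vapply(ped, `[`, character(1), 2L)))
  if (!ancestors) {
    return(full[match(vapply(pop$individuals, `[[`, character(1), "id"),
                      full$id), ])
  }
  wanted <- vapply(pop$individuals, `[[`, character(1), "id")
  keep <- character(0)
  frontier <- wanted
  while (length(frontier)) {
    keep <- union(keep, frontier)
    rows <- match(frontier, full$id)
    frontier <- setdiff(stats::na.omit(c(full$mother[rows], full$father[rows])),
                        keep)
  }
  full[full$id %in% keep, ] # creation order: parents precede offspring
}

# draw one gamete per call inside an open specie-RNG window
offspring_genome <- function(gm, gf) {
  mapply(function(a, b) list(alpha = a, beta = b), gm, gf, SIMPLIFY = FALSE)
}

#' Breeding operations
#'
#' `cross()` mates two individuals of the same specie: each offspring takes
#' its alpha strands from a fresh maternal gamete and its beta strands from a
#' fresh paternal gamete (so phased output lists the first parent's
#' contribution first). `selfcross()` is a self-fertilization — two
#' independent gametes of the same individual. `dh()` produces doubled
#' haploids: one gamete per offspring, copied into both strands, giving fully
#' homozygous lines after a single meiosis. Parents are never modified;
#' offspring pedigree records the parents. Gamete draw order per offspring is
#' mother first, then father.
#'
#' @param n number of offspring.
#' @param mother,father,individual parent individuals.
#' @return a `population` of `n` offspring.
#' @examples
#' spp <- make_specie(fixture_map(1, 6, 1), seed = 2)
#' F1 <- cross(1, founder(spp, "AA"), founder(spp, "aa"))[[1]]
#' F2 <- selfcross(20, F1)
#' @export
cross <- function(n, mother, father) {
  if (!inherits(mother, "individual") || !inherits(father, "individual"))
    stop_input("parents must be individuals")
  if (!identical(mother$specie, father$specie))
    stop_incompatible("parents belong to different species")
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop_input("n must be >= 1")
  spp <- mother$specie
  kids <- with_specie_rng(spp, {
    lapply(seq_len(n), function(i) {
      gm <- meiosis_once(mother)
      gf <- meiosis_once(father)
      new_individual(spp, offspring_genome(gm, gf),
                     mother = mother$id, father = father$id)
    })
  })
  population(kids)
}

#' @rdname cross
#' @export
selfcross <- function(n, individual) {
  cross(n, individual, individual)
}

#' @rdname cross
#' @export
dh <- function(n, individual) {
  if (!inherits(individual, "individual")) stop_input("not an individual")
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop_input("n must be >= 1")
  spp <- individual$specie
  kids <- with_specie_rng(spp, {
    lapply(seq_len(n), function(i) {
      g <- meiosis_once(individual)
      new_individual(spp, offspring_genome(g, g),
                     mother = individual$id, father = individual$id)
    })
  })
  population(kids)
}

#' Write a pedigree file
#'
#' Delimited text (id, mother, father) for downstream relationship-matrix
#' construction; `NA` marks unknown (founder) parents.
#'
#' @param pop a `population`.
#' @param path output path.
#' @param header named character vector for the reproducibility header.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(pop, path, header = character()) {
  write_with_header(as.data.frame(pedigree(pop)), path, header)
  invisible(path)
}
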