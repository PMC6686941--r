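#' Define a specie
#'
#' A specie is the generator object shared by all individuals that can
#' interbreed: it holds the genetic map, the recombination (meiosis) model
#' that samples chiasma positions, a private seeded random-number stream, and
#' the pedigree registry of every individual it founds. Two individuals are
#' cross-compatible if and only if they reference the same specie object.
#'
#' All stochastic operations (meiosis, orientation flips) draw from the
#' specie's own RNG stream in documented order — per meiosis, chromosomes are
#' processed in map order and within each chromosome the chiasmata are
#' sampled before the single orientation draw — so simulations are exactly
#' reproducible from the seed.
#'
#' @param map a `genetic_map` (see [load_map()]) or a data frame coercible to
#'   one.
#' @param meiosis a meiosis model (see [meiosis_count_location()]) or the name
#'   of a registered model. Default: count-location with Poisson chiasma
#'   count of mean equal to the chromosome length in Morgans and uniform
#'   locations.
#' @param seed integer seed of the specie's private RNG stream.
#' @return a `specie` object (an environment, so individuals share it by
#'   reference).
#' @examples
#' spp <- make_specie(fixture_map(1, 10, 1), seed = 1)
#' @export
make_specie <- function(map, meiosis = meiosis_count_location(), seed = 1L) {
  if (!inherits(map, "genetic_map")) map <- load_map(map)
  if (is.character(meiosis)) meiosis <- get_meiosis_model(meiosis)
  if (!inherits(meiosis, "meiosis_model"))
    stop_input("meiosis must be a meiosis_model or a registered model name")
  seed <- as.integer(seed)
  if (is.na(seed)) stop_input("seed must be an integer")

  spp <- new.env(parent = emptyenv())
  spp$map <- map
  chrom <- attr(map, "chrom")
  spp$chr_names <- chrom$chr
  spp$n_loci <- setNames(chrom$n_loci, chrom$chr)
  spp$lengths <- setNames(chrom$length_m, chrom$chr)
  spp$positions <- map_positions(map)
  spp$meiosis <- meiosis
  spp$seed <- seed
  spp$rng_state <- NULL
  spp$counter <- 0L
  spp$pedigree <- list() # id -> c(mother, father); insertion order = creation order
  class(spp) <- "specie"
  spp
}

#' @export
print.specie <- function(x, ...) {
  cat("<specie> ", sum(x$n_loci), " loci on ", length(x$chr_names),
      " chromosome(s); meiosis model: ", x$meiosis$name,
      "; seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' @rdname make_specie
#' @param x object to test.
#' @export
is_specie <- function(x) inherits(x, "specie")

# Run `expr` under the specie's private RNG stream, preserving the caller's
# global RNG state. One swap per batch keeps call order well defined.
with_specie_rng <- function(specie, expr) {
  had_global <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_global) get(".Random.seed", envir = globalenv()) else NULL
  if (is.null(specie$rng_state)) set.seed(specie$seed)
  else assign(".Random.seed", specie$rng_state, envir = globalenv())
  on.exit({
    specie$rng_state <- get(".Random.seed", envir = globalenv())
    if (had_global) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  expr
}

next_id <- function(specie) {
  specie$counter <- specie$counter + 1L
  paste0("I", specie$counter)
}

new_individual <- function(specie, genome, mother = NA_character_,
                           father = NA_character_, id = NULL) {
  id <- id %||% next_id(specie)
  specie$pedigree[[id]] <- c(mother, father)
  structure(list(specie = specie, id = id, genome = genome,
                 mother = mother, father = father),
            class = "individual")
}

#' @export
print.individual <- function(x, ...) {
  cat("<individual> ", x$id, " (", sum(x$specie$n_loci), " loci, ",
      length(x$genome), " chromosome pair(s))\n", sep = "")
  invisible(x)
}

#' Create a homozygous founder
#'
#' Builds a fully homozygous individual from a founder code: `"AA"` sets
#' every bit of both strands to one on every chromosome, `"aa"` to zero. By
#' the package's allele convention, bit 1 is the allele carried by the `"AA"`
#' founder and bit 0 the allele of `"aa"`. Heterozygous genomes are obtained
#' by crossing founders, not by codes.
#'
#' @param specie a [make_specie()] object.
#' @param code `"AA"` or `"aa"`.
#' @return an `individual`.
#' @examples
#' spp <- make_specie(fixture_map(1, 4, 1))
#' AA <- founder(spp, "AA")
#' @export
founder <- function(specie, code = c("AA", "aa")) {
  if (!is_specie(specie)) stop_input("not a specie")
  if (!is.character(code) || length(code) != 1L || !code %in% c("AA", "aa"))
    stop_input("founder code must be \"AA\" or \"aa\"")
  make <- if (code == "AA") strand_ones else strand_zeros
  genome <- lapply(setNames(specie$chr_names, specie$chr_names), function(ch) {
    n <- specie$n_loci[[ch]]
    list(alpha = make(n), beta = make(n))
  })
  new_individual(specie, genome)
}

#' Complement an individual's genome
#'
#' Returns a new individual whose every bit, on both strands of every
#' chromosome, is flipped. The mirror of the all-one founder is the all-zero
#' founder; mirroring twice is the identity. Heterozygous loci stay
#' heterozygous (the strand contents swap), so numeric dosage 1 is preserved
#' while phase is inverted.
#'
#' @param individual an `individual`.
#' @return a new `individual` of the same specie.
#' @export
mirror <- function(individual) {
  if (!inherits(individual, "individual")) stop_input("not an individual")
  genome <- lapply(individual$genome, function(pair)
    list(alpha = strand_not(pair$alpha), beta = strand_not(pair$beta)))
  new_individual(individual$specie, genome)
}

same_specie <- function(individuals) {
  spp <- individuals[[1]]$specie
  for (ind in individuals)
    if (!identical(ind$specie, spp)) return(FALSE)
  TRUE
}
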