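#' Upper-bound locus index of a chiasma
#'
#' For a chiasma coordinate and the sorted locus positions of one chromosome,
#' returns the number of loci strictly below the chiasma — equivalently the
#' 0-based index of the first locus whose position is greater than or equal
#' to the chiasma. Right-shifting a replete bit set by this count produces
#' the event mask whose flipped tail starts at that locus; a chiasma beyond
#' the last locus yields the locus count (an empty event).
#'
#' @param chiasma chiasma coordinate(s) in Morgans (vectorized).
#' @param positions sorted ascending locus positions of the chromosome.
#' @return integer shift count(s) in `0..length(positions)`.
#' @examples
#' upper_bound(0.25, c(0.1, 0.2, 0.3, 0.4)) # 2
#' @export
upper_bound <- function(chiasma, positions) {
  findInterval(chiasma, positions, left.open = TRUE)
}

#' Build a crossover mask from chiasma positions
#'
#' Starts from an all-zero mask and, for every chiasma, XORs in an event mask
#' equal to a replete bit set right-shifted by the chiasma's [upper_bound()].
#' Bit j of the result is therefore the parity of the number of chiasmata at
#' or below locus j's position, so two chiasmata at the same coordinate
#' cancel and the chain is order-independent.
#'
#' @param chiasmata numeric chiasma coordinates (any order; may be empty).
#' @param positions sorted ascending locus positions.
#' @return a `bit_strand` mask of the same length as the chromosome.
#' @examples
#' as.logical(crossover_mask(0.25, c(0.1, 0.2, 0.3, 0.4)))
#' @export
crossover_mask <- function(chiasmata, positions) {
  breaks <- upper_bound(chiasmata, positions)
  new_strand(.bits_xor_chain(length(positions), as.integer(breaks)),
             length(positions))
}

#' Randomly orient a mask
#'
#' Independent assortment: with probability one half the mask is complemented
#' before use, so a chromosome with no chiasma still transmits either parental
#' strand with equal probability. Applied once per chromosome per meiosis,
#' independently across chromosomes.
#'
#' @param mask a `bit_strand` mask.
#' @param flip optional logical forcing the branch (for deterministic use);
#'   default draws from the current RNG.
#' @return the mask or its complement.
#' @export
orient_mask <- function(mask, flip = NULL) {
  if (is.null(flip)) flip <- runif(1) > 0.5
  if (flip) strand_not(mask) else mask
}

#' Recombine two strands under a mask
#'
#' The mosaic gamete strand: bit j is taken from `alpha` where the mask bit
#' is 1 and from `beta` where it is 0, computed as a single bitwise
#' statement `(mask & alpha) | (~mask & beta)` over the packed strands.
#'
#' @param alpha,beta parental `bit_strand`s of equal length.
#' @param mask a `bit_strand` gating inheritance.
#' @return the recombinant `bit_strand`.
#' @examples
#' recombine(strand_ones(4), strand_zeros(4), strand(c(FALSE, FALSE, TRUE, TRUE)))
#' @export
recombine <- function(alpha, beta, mask) {
  if (alpha$n != beta$n || alpha$n != mask$n)
    stop_input("strands and mask must have equal lengths")
  new_strand(.bits_recombine(mask$bits, alpha$bits, beta$bits, alpha$n),
             alpha$n)
}

# ---- recombination models (chiasmata samplers) -----------------------------

new_meiosis_model <- function(name, sample) {
  structure(list(name = name, sample = sample), class = "meiosis_model")
}

#' @export
print.meiosis_model <- function(x, ...) {
  cat("<meiosis_model> ", x$name, "\n", sep = "")
  invisible(x)
}

#' Recombination models
#'
#' A meiosis model is a sampler called once per chromosome per meiosis with
#' the chromosome length in Morgans and the locus positions; it returns the
#' chiasma coordinates for that meiosis (sorted, within `[0, length]`). Any
#' model satisfying this contract — including user-defined ones registered
#' with [register_meiosis_model()] — composes unchanged with the mask
#' construction.
#'
#' * `meiosis_count_location()`: the default count-location process — the
#'   chiasma count is Poisson with mean equal to the chromosome length in
#'   Morgans and locations are independent uniform. No interference; implies
#'   Haldane's map function r(d) = (1 - exp(-2d))/2 between loci d Morgans
#'   apart.
#' * `meiosis_independent()`: markers segregate independently of map
#'   distance — for each adjacent pair of distinct positions a chiasma is
#'   placed at their midpoint with probability one half, making every
#'   crossover mask equally likely.
#' * `meiosis_hotspot()`: count-location count, but locations drawn from a
#'   normalized mixture of a uniform background (weight `background`) and
#'   Gaussian hotspot kernels truncated to the chromosome.
#'
#' @param hotspots data frame with columns `center` (Morgans), `weight`
#'   (>= 0) and `width` (kernel standard deviation, Morgans).
#' @param background non-negative weight of the uniform background component.
#' @return a `meiosis_model`.
#' @examples
#' spp <- make_specie(fixture_map(1, 10, 1), meiosis = meiosis_independent())
#' @export
meiosis_count_location <- function() {
  new_meiosis_model("count_location", function(length_m, positions) {
    k <- rpois(1L, length_m)
    if (k == 0L) numeric(0) else sort(runif(k, 0, length_m))
  })
}

#' @rdname meiosis_count_location
#' @export
meiosis_independent <- function() {
  new_meiosis_model("independent", function(length_m, positions) {
    p <- unique(positions)
    if (length(p) < 2L) return(numeric(0))
    mids <- (p[-length(p)] + p[-1L]) / 2
    mids[runif(length(mids)) < 0.5]
  })
}

#' @rdname meiosis_count_location
#' @export
meiosis_hotspot <- function(hotspots, background = 0) {
  hotspots <- as.data.frame(hotspots)
  if (!all(c("center", "weight", "width") %in% names(hotspots)))
    stop_input("hotspots needs columns center, weight, width")
  if (any(hotspots$weight < 0) || background < 0)
    stop_input("weights must be non-negative")
  if (background == 0 && (!nrow(hotspots) || all(hotspots$weight == 0)))
    stop_input("all mixture weights are zero")
  w <- c(background, hotspots$weight)
  w <- w / sum(w)
  new_meiosis_model("hotspot", function(length_m, positions) {
    if (any(hotspots$center < 0) || any(hotspots$center > length_m))
      stop_input("hotspot centers must lie within [0, chromosome length]")
    k <- rpois(1L, length_m)
    if (k == 0L) return(numeric(0))
    comp <- sample.int(length(w), k, replace = TRUE, prob = w)
    pos <- numeric(k)
    for (i in seq_len(k)) {
      if (comp[i] == 1L) {
        pos[i] <- runif(1, 0, length_m)
      } else {
        h <- comp[i] - 1L
        repeat { # truncate the kernel to the chromosome by rejection
          x <- rnorm(1, hotspots$center[h], hotspots$width[h])
          if (x >= 0 && x <= length_m) break
        }
        pos[i] <- x
      }
    }
    sort(pos)
  })
}

.model_registry <- new.env(parent = emptyenv())

#' Register or fetch a recombination model by name
#'
#' @param name model name.
#' @param model a `meiosis_model`, or a zero-argument constructor returning
#'   one.
#' @param ... arguments passed to the registered constructor.
#' @return `get_meiosis_model` returns the `meiosis_model`.
#' @export
register_meiosis_model <- function(name, model) {
  if (!(inherits(model, "meiosis_model") || is.function(model)))
    stop_input("model must be a meiosis_model or a constructor function")
  assign(name, model, envir = .model_registry)
  invisible(name)
}

#' @rdname register_meiosis_model
#' @export
get_meiosis_model <- function(name, ...) {
  if (!exists(name, envir = .model_registry))
    stop_input(paste0("unknown meiosis model: ", name))
  m <- get(name, envir = .model_registry)
  if (is.function(m)) m <- m(...)
  if (!inherits(m, "meiosis_model")) stop_input("registered object is not a meiosis_model")
  m
}

#' @rdname register_meiosis_model
#' @export
list_meiosis_models <- function() sort(ls(.model_registry))

register_builtin_models <- function() {
  register_meiosis_model("count_location", meiosis_count_location)
  register_meiosis_model("independent", meiosis_independent)
  register_meiosis_model("hotspot", meiosis_hotspot)
}

.onLoad <- function(libname, pkgname) register_builtin_models()

# ---- gamete formation ------------------------------------------------------

# one meiosis under the caller's current RNG; per chromosome:
# chiasmata -> mask -> random orientation -> mosaic strand
meiosis_once <- function(individual) {
  spp <- individual$specie
  sampler <- spp$meiosis$sample
  g <- vector("list", length(spp$chr_names))
  names(g) <- spp$chr_names
  for (ch in spp$chr_names) {
    pos <- spp$positions[[ch]]
    chiasmata <- sampler(spp$lengths[[ch]], pos)
    mask <- new_strand(
      .bits_xor_chain(length(pos),
                      findInterval(chiasmata, pos, left.open = TRUE)),
      length(pos))
    if (runif(1) > 0.5) mask <- strand_not(mask)
    pair <- individual$genome[[ch]]
    g[[ch]] <- new_strand(
      .bits_recombine(mask$bits, pair$alpha$bits, pair$beta$bits, mask$n),
      mask$n)
  }
  structure(g, class = "gamete")
}

#' Simulate meioses
#'
#' `meiosis()` performs one meiosis and returns a single gamete (one strand
#' per chromosome); `gametes()` performs `n` independent meioses. Chiasmata
#' are sampled afresh for every meiosis from the specie's model and all
#' randomness comes from the specie's seeded stream, so the gamete sequence
#' is reproducible.
#'
#' @param individual an `individual`.
#' @param n number of gametes.
#' @return a `gamete` (named list of `bit_strand`, one per chromosome), or a
#'   list of `n` gametes.
#' @examples
#' spp <- make_specie(fixture_map(1, 4, 1), seed = 7)
#' gam <- gametes(cross(1, founder(spp, "AA"), founder(spp, "aa"))[[1]], 3)
#' @export
meiosis <- function(individual) {
  if (!inherits(individual, "individual")) stop_input("not an individual")
  with_specie_rng(individual$specie, meiosis_once(individual))
}

#' @rdname meiosis
#' @export
gametes <- function(individual, n) {
  if (!inherits(individual, "individual")) stop_input("not an individual")
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop_input("n must be >= 1")
  with_specie_rng(individual$specie, {
    out <- vector("list", n)
    for (i in seq_len(n)) out[[i]] <- meiosis_once(individual)
    out
  })
}

#' Gamete alleles as a matrix
#'
#' @param gams list of gametes (from [gametes()]).
#' @param chr chromosome id; default the first.
#' @return integer matrix, loci in rows, gametes in columns.
#' @export
gamete_matrix <- function(gams, chr = NULL) {
  if (!length(gams)) stop_input("no gametes")
  chr <- chr %||% names(gams[[1]])[1]
  nloci <- length(gams[[1]][[chr]])
  matrix(vapply(gams, function(g) as.integer(as.logical(g[[chr]])),
                integer(nloci)),
         nrow = nloci)
}
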