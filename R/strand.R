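#' Bit strands
#'
#' A strand is one of the two homologous DNA copies of a chromosome, encoded
#' as a packed bit vector with one bit per mapped locus. Bit index 1 (R
#' convention) is the locus with the smallest map position. Strands are
#' created from logical vectors or as all-zero / all-one constants; all
#' bitwise work happens on the packed representation.
#'
#' @param bits logical vector of allele states, one per locus.
#' @param n number of loci.
#' @return a `bit_strand` object.
#' @examples
#' s <- strand(c(TRUE, FALSE, TRUE, TRUE))
#' as.logical(s)
#' @export
strand <- function(bits) {
  if (anyNA(bits)) stop_input("strand bits must not contain NA")
  new_strand(.bits_pack(as.logical(bits)), length(bits))
}

new_strand <- function(raw_bits, n) {
  structure(list(bits = raw_bits, n = as.integer(n)), class = "bit_strand")
}

#' @rdname strand
#' @export
strand_zeros <- function(n) new_strand(.bits_new(as.integer(n), FALSE), n)

#' @rdname strand
#' @export
strand_ones <- function(n) new_strand(.bits_new(as.integer(n), TRUE), n)

#' @export
length.bit_strand <- function(x) x$n

#' @export
as.logical.bit_strand <- function(x, ...) .bits_unpack(x$bits, x$n)

#' @export
as.integer.bit_strand <- function(x, ...) as.integer(as.logical(x))

#' @export
print.bit_strand <- function(x, ...) {
  cat("<bit_strand> ", x$n, " loci: ", strand_to_string(x), "\n", sep = "")
  invisible(x)
}

#' @export
`==.bit_strand` <- function(e1, e2) {
  e1$n == e2$n && identical(e1$bits, e2$bits)
}

# first character = locus 1 (smallest position)
strand_to_string <- function(s) {
  paste(as.integer(as.logical(s)), collapse = "")
}

strand_from_string <- function(str) {
  strand(strsplit(str, "", fixed = TRUE)[[1]] == "1")
}

strand_not <- function(s) new_strand(.bits_not(s$bits, s$n), s$n)

strand_xor <- function(a, b) {
  stopifnot(a$n == b$n)
  new_strand(.bits_xor(a$bits, b$bits), a$n)
}

#' Toggle allele states at given loci
#'
#' Point mutation / gene editing: flips the bits of a strand at the given
#' locus indices. The flip mask is assembled from right-shifted replete bit
#' sets (one single-bit event per index, merged by an XOR chain, exactly as
#' crossover masks are) and applied to the strand with one XOR, so toggling
#' twice with the same indices is the identity.
#'
#' @param strand a [strand()].
#' @param indices 1-based locus indices to flip.
#' @return a new `bit_strand`; the input is not modified.
#' @examples
#' toggle_loci(strand_zeros(4), 3)
#' @export
toggle_loci <- function(strand, indices) {
  if (!inherits(strand, "bit_strand")) stop_input("not a bit_strand")
  indices <- as.integer(indices)
  if (length(indices) && (anyNA(indices) || any(indices < 1L) ||
                          any(indices > strand$n)))
    stop_input("locus index out of range")
  new_strand(.bits_toggle(strand$bits, strand$n, indices - 1L), strand$n)
}

#' Storage requirement of a binary encoding
#'
#' Computes the number of bits needed to encode `n_units` units at
#' `bits_per_unit` bits each (for instance a chromosome of base pairs at two
#' bits per nucleotide) and errors if the total exceeds the single-bitset
#' capacity of 2^32 - 1 bits. Arithmetic is exact: operands are validated to
#' stay below 2^53 where double-precision integer arithmetic is lossless.
#'
#' @param n_units number of units to encode (e.g. base pairs or loci).
#' @param bits_per_unit bits per unit (2 encodes the four nucleotides).
#' @return required bit count.
#' @examples
#' check_capacity(248956422, 2)
#' @export
check_capacity <- function(n_units, bits_per_unit) {
  if (length(n_units) != 1L || length(bits_per_unit) != 1L ||
      !is.finite(n_units) || !is.finite(bits_per_unit) ||
      n_units < 0 || bits_per_unit < 1 ||
      n_units != trunc(n_units) || bits_per_unit != trunc(bits_per_unit))
    stop_input("n_units must be a non-negative integer and bits_per_unit a positive integer")
  if (n_units > 2^52 || bits_per_unit > 2^52 ||
      (n_units > 0 && bits_per_unit > 2^53 / n_units))
    stop_capacity("operands too large for exact arithmetic")
  bits <- n_units * bits_per_unit
  limit <- 2^32 - 1
  if (bits > limit)
    stop_capacity(sprintf("%.0f bits exceeds the bitset capacity of 2^32-1", bits))
  bits
}
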