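#' Load a genetic map
#'
#' Validates and canonicalizes a genetic map given as a data frame with one
#' row per locus: chromosome id (`chr`), map position in Morgans (`pos`) and
#' a unique locus name (`snp`). Column aliases `chromosome`, `position` and
#' `name`/`locus` are accepted. Loci are sorted by position within chromosome
#' (stable, so loci sharing a position keep their input order and behave as
#' one linked group); chromosomes keep their order of first appearance.
#'
#' @param map data frame of loci.
#' @return a `genetic_map`: a tibble with columns `chr`, `pos`, `snp`, sorted
#'   by (chromosome, position), carrying a `chrom` attribute that summarizes
#'   each chromosome (locus count and length in Morgans, the maximum
#'   position).
#' @examples
#' load_map(data.frame(chr = 1, pos = c(0.3, 0.1, 0.2), snp = c("a", "b", "c")))
#' @export
load_map <- function(map) {
  map <- as.data.frame(map)
  names(map) <- tolower(names(map))
  aliases <- c(chromosome = "chr", position = "pos", pos_m = "pos",
               name = "snp", locus = "snp", marker = "snp")
  for (a in names(aliases)) {
    if (a %in% names(map) && !(aliases[[a]] %in% names(map)))
      names(map)[names(map) == a] <- aliases[[a]]
  }
  missing_cols <- setdiff(c("chr", "pos", "snp"), names(map))
  if (length(missing_cols))
    stop_input(paste0("map is missing column(s): ",
                      paste(missing_cols, collapse = ", ")))
  if (!nrow(map)) stop_input("map has no loci")
  if (!is.numeric(map$pos) || anyNA(map$pos) || any(!is.finite(map$pos)))
    stop_input("map positions must be finite numeric Morgans")
  if (any(map$pos < 0)) stop_input("map positions must be non-negative")
  map$snp <- as.character(map$snp)
  if (anyDuplicated(map$snp)) stop_input("locus names must be unique")
  map$chr <- as.character(map$chr)

  chr_levels <- unique(map$chr)
  ord <- order(match(map$chr, chr_levels), map$pos) # stable: ties keep input order
  out <- tibble::tibble(chr = map$chr[ord], pos = map$pos[ord],
                        snp = map$snp[ord])

  per_chr <- dplyr::summarise(dplyr::group_by(out, .data$chr),
                              n_loci = dplyr::n(),
                              length_m = max(.data$pos), .groups = "drop")
  per_chr <- per_chr[match(chr_levels, per_chr$chr), ]
  if (any(per_chr$n_loci > 2^32 - 1))
    stop_capacity("a chromosome exceeds the per-bitset locus capacity of 2^32-1")

  structure(out, chrom = per_chr, class = c("genetic_map", class(out)))
}

#' @export
print.genetic_map <- function(x, ...) {
  ch <- attr(x, "chrom")
  cat("<genetic_map> ", nrow(x), " loci on ", nrow(ch), " chromosome(s); ",
      "lengths (M): ", paste(format(ch$length_m), collapse = ", "), "\n",
      sep = "")
  NextMethod()
}

#' Chromosome summary of a map
#'
#' @param map a `genetic_map`.
#' @return tibble with columns `chr`, `n_loci`, `length_m`.
#' @export
map_chromosomes <- function(map) {
  if (!inherits(map, "genetic_map")) stop_input("not a genetic_map")
  attr(map, "chrom")
}

# per-chromosome position vectors, in map chromosome order
map_positions <- function(map) {
  split(map$pos, factor(map$chr, levels = attr(map, "chrom")$chr))
}

#' Groups of loci sharing one map position
#'
#' Loci assigned to the same position act as a single multi-bit factor:
#' crossover masks depend on positions only, so their linkage never breaks.
#'
#' @param map a `genetic_map`.
#' @return tibble `chr`, `pos`, `group`, `snp`, `index` (row in the map),
#'   restricted to groups with at least two members.
#' @export
locus_groups <- function(map) {
  if (!inherits(map, "genetic_map")) stop_input("not a genetic_map")
  d <- tibble::tibble(chr = map$chr, pos = map$pos, snp = map$snp,
                      index = seq_len(nrow(map)))
  d <- dplyr::group_by(d, .data$chr, .data$pos)
  d <- dplyr::mutate(d, group = dplyr::cur_group_id(),
                     size = dplyr::n())
  d <- dplyr::ungroup(d)
  d <- dplyr::filter(d, .data$size > 1L)
  dplyr::select(d, "chr", "pos", "group", "snp", "index")
}

#' Generate an equally spaced fixture map
#'
#' Builds a map with `chromosomes` chromosomes, each carrying
#' `loci_per_chromosome` loci equally spaced from 0 to `length_m` Morgans
#' inclusive, named `s1 ... sN` across the whole map. The default geometry —
#' five chromosomes of 1000 loci spanning two Morgans — is the standard
#' infinitesimal-trait test bed used by the F2:3 study.
#'
#' @param chromosomes number of chromosomes.
#' @param loci_per_chromosome loci per chromosome.
#' @param length_m chromosome length in Morgans.
#' @return a `genetic_map`.
#' @examples
#' fixture_map(1, 5, 1)
#' @export
fixture_map <- function(chromosomes = 5, loci_per_chromosome = 1000,
                        length_m = 2) {
  if (chromosomes < 1 || loci_per_chromosome < 1 || length_m <= 0)
    stop_input("chromosomes and loci_per_chromosome must be >= 1, length_m > 0")
  pos <- if (loci_per_chromosome == 1) 0 else
    seq(0, length_m, length.out = loci_per_chromosome)
  n <- chromosomes * loci_per_chromosome
  load_map(data.frame(
    chr = rep(as.character(seq_len(chromosomes)), each = loci_per_chromosome),
    pos = rep(pos, chromosomes),
    snp = paste0("s", seq_len(n))))
}

#' Read / write a map file
#'
#' Delimited text with columns `chr`, `pos` (Morgans), `snp`; lines starting
#' with `#` are ignored on read and used for the reproducibility header on
#' write.
#'
#' @param path file path.
#' @param map a `genetic_map`.
#' @param header named character vector recorded as `## key=value` lines.
#' @return `read_map`: a `genetic_map`; `write_map`: `path`, invisibly.
#' @export
read_map <- function(path) {
  if (!file.exists(path)) stop_io(paste0("no such file: ", path))
  load_map(read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                      stringsAsFactors = FALSE))
}

#' @rdname read_map
#' @export
write_map <- function(map, path, header = character()) {
  if (!inherits(map, "genetic_map")) stop_input("not a genetic_map")
  write_with_header(as.data.frame(map), path, header)
  invisible(path)
}

# shared writer: "## key=value" comment lines, then a TSV with column header
write_with_header <- function(df, path, header = character()) {
  con <- tryCatch(file(path, "w"), error = function(e)
    stop_io(paste0("cannot open for writing: ", path)))
  on.exit(close(con))
  writeLines(paste0("## bitqg=", as.character(packageVersion("bitqg"))), con)
  if (length(header))
    writeLines(paste0("## ", names(header), "=", unname(header)), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}
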